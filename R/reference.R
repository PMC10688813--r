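# Ground-truth objects of the workflow: the taxonomic training set built
# from the mock's expected full-length 16S rRNA sequences, and the
# theoretical composition the sequencing output is compared against.
# Only bacterial/archaeal 16S references are supported; eukaryotic mock
# members (e.g. the fungi of larger standards) must simply be omitted from
# the training set and the theoretical table.

#' Build the taxonomic training set
#'
#' Indexes the expected mock members' reference sequences by their distinct
#' forward-strand k-mers, grouped by species. Several records may share a
#' species (strains, operon variants); their k-mer sets are unioned.
#' K-mers containing IUPAC ambiguity codes or N are skipped, not expanded.
#'
#' @param records data.frame with columns \code{record_id}, \code{species},
#'   \code{sequence} (uppercase DNA, IUPAC codes permitted).
#' @param k word size, default 8 (range 4--12).
#' @param both_strands if TRUE, each species' index is unioned with the
#'   reverse-complement k-mers, for ASV tables whose orientation is not
#'   guaranteed to match the references. Default FALSE: dada2 output is
#'   orientation-consistent with the references.
#' @return an object of class \code{training_set} with fields
#'   \code{records}, \code{species_labels} (lexicographic), \code{k},
#'   \code{kmer_index} (named list of distinct k-mer sets per species) and
#'   \code{record_counts}.
#' @export
build_training_set <- function(records, k = 8L, both_strands = FALSE) {
  k <- as.integer(k)
  if (k < 4L || k > 12L) stop("k must be in 4..12, got ", k)
  req <- c("record_id", "species", "sequence")
  if (!all(req %in% colnames(records)))
    stop("records must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(records$record_id))
    stop("duplicate record_id(s): ",
         paste(unique(records$record_id[duplicated(records$record_id)]),
               collapse = ", "))
  if (any(!nzchar(records$species))) stop("empty species label(s) in records")
  short <- nchar(records$sequence) < 2L * k
  if (any(short))
    stop("reference sequence(s) shorter than 2k (", 2L * k, " nt): ",
         paste(records$record_id[short], collapse = ", "))
  species_labels <- sort(unique(records$species))
  if (length(species_labels) < 2L)
    stop("training set needs >= 2 species; got ",
         length(species_labels), " ('", species_labels, "')")

  index_of <- function(seqs) {
    km <- unique(unlist(lapply(seqs, kmer_set, k = k), use.names = FALSE))
    if (both_strands) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(km)))
      km <- unique(c(km, rc))
    }
    km
  }
  kmer_index <- lapply(species_labels, function(s)
    index_of(records$sequence[records$species == s]))
  names(kmer_index) <- species_labels
  record_counts <- vapply(species_labels, function(s)
    sum(records$species == s), integer(1))

  structure(list(records = records, species_labels = species_labels,
                 k = k, kmer_index = kmer_index,
                 record_counts = record_counts,
                 both_strands = both_strands),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat("Training set:", length(x$species_labels), "species,",
      nrow(x$records), "reference records, k =", x$k, "\n")
  for (s in x$species_labels)
    cat("  ", s, ": ", x$record_counts[[s]], " record(s), ",
        length(x$kmer_index[[s]]), " distinct k-mers\n", sep = "")
  invisible(x)
}

#' Construct a theoretical mock composition
#'
#' @param expected named numeric vector: species label -> expected percent.
#'   Percents must be positive and sum to exactly 100 (within 1e-6); they
#'   are deliberately NOT renormalized, so a mis-transcribed vendor table
#'   surfaces as an error instead of being silently absorbed.
#' @param mock_name label for the mock community.
#' @return object of class \code{theoretical_composition}.
#' @export
theoretical_composition <- function(expected, mock_name = "mock") {
  if (is.null(names(expected)) || any(!nzchar(names(expected))))
    stop("every species label must be nonempty")
  if (anyDuplicated(names(expected)))
    stop("duplicate species in theoretical composition: ",
         paste(unique(names(expected)[duplicated(names(expected))]),
               collapse = ", "))
  if (any(!is.finite(expected)) || any(expected <= 0))
    stop("every theoretical percent must be positive")
  if (abs(sum(expected) - 100) > 1e-6)
    stop("theoretical percents sum to ", format(sum(expected), digits = 10),
         ", not 100")
  structure(list(mock_name = mock_name,
                 expected = expected),
            class = "theoretical_composition")
}

#' @export
print.theoretical_composition <- function(x, ...) {
  cat("Theoretical composition '", x$mock_name, "': ",
      length(x$expected), " species\n", sep = "")
  for (s in names(x$expected))
    cat(sprintf("  %-30s %6.2f%%\n", s, x$expected[[s]]))
  invisible(x)
}

#' Read a theoretical composition TSV
#'
#' Two-column TSV with header \code{species<TAB>percent}.
#'
#' @param path path to the TSV file.
#' @param mock_name label for the mock community.
#' @return a \code{\link{theoretical_composition}}.
#' @export
read_theoretical_composition <- function(path, mock_name = "mock") {
  df <- read_tsv_strict(path, "theoretical composition")
  if (!identical(colnames(df)[1:2], c("species", "percent")))
    stop("theoretical composition must have header 'species\\tpercent'")
  pct <- suppressWarnings(as.numeric(df$percent))
  if (anyNA(pct)) stop("non-numeric percent for species: ",
                       paste(df$species[is.na(pct)], collapse = ", "))
  theoretical_composition(stats::setNames(pct, df$species), mock_name)
}

#' Write a theoretical composition TSV
#' @param tc a \code{\link{theoretical_composition}}.
#' @param path output path.
#' @export
write_theoretical_composition <- function(tc, path) {
  df <- data.frame(species = names(tc$expected),
                   percent = unname(tc$expected))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compare training-set and theoretical species label sets
#'
#' Pure report; callers enforce the policy. The pipeline refuses to proceed
#' when the training set contains species absent from the theoretical table
#' (such calls could never be scored); the converse — theoretical species
#' with no reference — only warrants a warning, since that species can
#' never be observed and will sit at 0 percent.
#'
#' @param ts a \code{\link{build_training_set}} result.
#' @param tc a \code{\link{theoretical_composition}}.
#' @return list with \code{training_only} and \code{theoretical_only}
#'   character vectors and logical \code{concordant} (TRUE iff
#'   training labels are a subset of theoretical labels).
#' @export
check_label_concordance <- function(ts, tc) {
  train <- ts$species_labels
  theo <- names(tc$expected)
  training_only <- setdiff(train, theo)
  theoretical_only <- setdiff(theo, train)
  list(training_only = training_only,
       theoretical_only = theoretical_only,
       concordant = length(training_only) == 0L)
}
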