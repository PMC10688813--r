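# On-disk formats: FASTA (via Biostrings) and a strict TSV dialect
# (tab-separated, UTF-8, '#' comment lines ignored, header row mandatory).
# Everything downstream consumes only the in-memory objects built here.

#' Read a multi-record FASTA file
#'
#' Parses standard (possibly line-wrapped) FASTA. Record IDs are the header
#' token up to the first whitespace; sequences are uppercased and validated
#' against the IUPAC nucleotide alphabet.
#'
#' @param path path to a FASTA file.
#' @return named character vector: names are record IDs, values the
#'   uppercased sequences, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0L) stop("FASTA file is empty: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA record ID(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  bad <- grepl(paste0("[^", paste(IUPAC_CODES, collapse = ""), "]"), seqs)
  if (any(bad)) {
    stop("non-IUPAC characters in FASTA record(s): ",
         paste(ids[bad], collapse = ", "))
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param sequences named character vector (names become headers).
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

read_tsv_strict <- function(path, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 1L || nrow(df) < 0L) stop(what, " file is empty: ", path)
  df
}

#' Construct and validate an ASV count table
#'
#' The table follows the dada2 convention that ASVs are identified by their
#' sequence string, not by opaque IDs. Orientation is fixed: rows are ASVs,
#' columns are samples (note dada2's \code{seqtab} is the transpose).
#'
#' @param counts integer matrix, one row per ASV, one column per sample.
#' @param asv_sequences character vector of uppercase DNA strings over
#'   \{A,C,G,T,N\}, one per row of \code{counts}.
#' @param sample_ids character vector of unique sample labels, one per
#'   column of \code{counts}.
#' @return an object of class \code{asv_table}.
#' @export
asv_table <- function(counts, asv_sequences = rownames(counts),
                      sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(asv_sequences) || is.null(sample_ids))
    stop("asv_table requires ASV sequences and sample IDs")
  asv_sequences <- toupper(as.character(asv_sequences))
  sample_ids <- as.character(sample_ids)
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stop("ASV table needs at least 1 ASV and 1 sample")
  if (length(asv_sequences) != nrow(counts) ||
      length(sample_ids) != ncol(counts))
    stop("dimension mismatch between counts and labels")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ID(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(asv_sequences))
    stop("duplicate ASV sequence(s) at row(s): ",
         paste(which(duplicated(asv_sequences)), collapse = ", "))
  bad <- grepl("[^ACGTN]", asv_sequences)
  if (any(bad))
    stop("ASV sequence(s) outside alphabet {A,C,G,T,N} at row(s): ",
         paste(which(bad), collapse = ", "))
  if (anyNA(counts) || any(counts < 0L))
    stop("ASV counts must be nonnegative integers")
  dimnames(counts) <- list(asv_sequences, sample_ids)
  structure(list(sample_ids = sample_ids, asv_sequences = asv_sequences,
                 counts = counts),
            class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat("ASV table:", length(x$asv_sequences), "ASVs x",
      length(x$sample_ids), "samples\n")
  cat("  samples:", paste(x$sample_ids, collapse = ", "), "\n")
  cat("  total reads:", sum(x$counts), "\n")
  invisible(x)
}

#' Read an ASV count table from TSV
#'
#' Expected layout: first column header \code{asv_sequence}, remaining
#' column headers are sample IDs, cells are nonnegative integers. Rows with
#' all-zero counts are retained.
#'
#' @param path path to the TSV file.
#' @return an \code{\link{asv_table}}.
#' @export
read_asv_table <- function(path) {
  df <- read_tsv_strict(path, "ASV table")
  if (colnames(df)[1L] != "asv_sequence")
    stop("ASV table must have first column header 'asv_sequence', got '",
         colnames(df)[1L], "'")
  if (ncol(df) < 2L) stop("ASV table has no sample columns")
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample column(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  cells <- as.matrix(df[, -1L, drop = FALSE])
  ok <- grepl("^[0-9]+$", cells)
  dim(ok) <- dim(cells)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)
    stop("non-integer or negative count '", cells[bad[1L, 1L], bad[1L, 2L]],
         "' in sample '", samples[bad[1L, 2L]], "'")
  }
  counts <- matrix(as.integer(cells), nrow = nrow(df),
                   dimnames = list(NULL, samples))
  asv_table(counts, asv_sequences = df[[1L]], sample_ids = samples)
}

#' Write an ASV table to TSV
#'
#' Inverse of \code{\link{read_asv_table}}; integer round-trips are exact.
#'
#' @param tbl an \code{\link{asv_table}}.
#' @param path output path.
#' @export
write_asv_table <- function(tbl, path) {
  stopifnot(inherits(tbl, "asv_table"))
  df <- data.frame(asv_sequence = tbl$asv_sequences, tbl$counts,
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a reference-ID to species-label map
#'
#' Two-column TSV with header \code{record_id<TAB>species}. Several records
#' may share one species label (multiple reference operons/strains).
#'
#' @param path path to the TSV file.
#' @return named character vector mapping record_id to species label.
#' @export
read_species_map <- function(path) {
  df <- read_tsv_strict(path, "species map")
  if (!identical(colnames(df)[1:2], c("record_id", "species")))
    stop("species map must have header 'record_id\\tspecies'")
  if (nrow(df) == 0L) stop("species map has no rows")
  if (anyDuplicated(df$record_id))
    stop("duplicate record_id row(s): ",
         paste(unique(df$record_id[duplicated(df$record_id)]), collapse = ", "))
  if (any(!nzchar(df$species)))
    stop("empty species label for record(s): ",
         paste(df$record_id[!nzchar(df$species)], collapse = ", "))
  stats::setNames(df$species, df$record_id)
}

#' Write a species map TSV
#' @param species_map named character vector (names = record IDs).
#' @param path output path.
#' @export
write_species_map <- function(species_map, path) {
  df <- data.frame(record_id = names(species_map),
                   species = unname(species_map))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

fmt6 <- function(x) ifelse(is.na(x), "NA", sprintf("%.6f", x))

#' Write the three result TSVs of a QC run
#'
#' Writes \code{asv_assignments.tsv} (asv_sequence, species, confidence),
#' \code{species_profiles.tsv} (species x samples, percent) and
#' \code{correlation_table.tsv} (sample, rho, n_taxa, unknown_percent) to
#' \code{out_dir}. Numbers are rendered with 6 decimal places; an undefined
#' Spearman rho is rendered as \code{NA}.
#'
#' @param assignments data.frame from \code{\link{classify_table}}.
#' @param profiles species-by-sample percent matrix from
#'   \code{\link{to_relative_abundance}}.
#' @param results data.frame from \code{\link{compare_to_theoretical}}.
#' @param out_dir output directory (created if absent).
#' @return invisibly, the three file paths.
#' @export
write_tsv_outputs <- function(assignments, profiles, results, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)

  f_assign <- file.path(out_dir, "asv_assignments.tsv")
  adf <- data.frame(asv_sequence = assignments$asv_sequence,
                    species = assignments$species,
                    confidence = fmt6(assignments$confidence))
  utils::write.table(adf, f_assign, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  f_prof <- file.path(out_dir, "species_profiles.tsv")
  if (is.null(profiles) || ncol(profiles) == 0L) {
    writeLines("species", f_prof)
  } else {
    pdf <- data.frame(species = rownames(profiles),
                      apply(profiles, 2L, fmt6),
                      check.names = FALSE, row.names = NULL)
    colnames(pdf) <- c("species", colnames(profiles))
    utils::write.table(pdf, f_prof, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  f_corr <- file.path(out_dir, "correlation_table.tsv")
  cdf <- data.frame(sample = results$sample_id,
                    rho = fmt6(results$rho),
                    n_taxa = results$n_taxa,
                    unknown_percent = fmt6(results$unknown_percent))
  utils::write.table(cdf, f_corr, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  invisible(c(assignments = f_assign, profiles = f_prof,
              correlation = f_corr))
}
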