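# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")
# IUPAC nucleotide codes accepted in reference sequences.
IUPAC_CODES <- c(DNA_BASES, "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
UNKNOWN_LABEL <- "Unknown"

#' Extract the distinct k-mers of a DNA sequence
#'
#' Returns the set of distinct k-length words over \{A,C,G,T\} occurring on
#' the forward strand of \code{sequence}. Windows containing any other
#' character (N or an IUPAC ambiguity code) are skipped, so a degenerate
#' reference base simply removes the k windows covering it rather than being
#' expanded.
#'
#' @param sequence a single uppercase DNA string.
#' @param k word size (integer >= 1).
#' @return character vector of distinct k-mers, in order of first occurrence;
#'   empty if the sequence is shorter than \code{k}.
#' @examples
#' kmer_set("ACGTACGT", 4)
#' @export
kmer_set <- function(sequence, k) {
  stopifnot(is.character(sequence), length(sequence) == 1L, k >= 1L)
  n <- nchar(sequence)
  if (n < k) return(character(0))
  kmers <- substring(sequence, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  kmers <- kmers[!grepl(paste0("[^", paste(DNA_BASES, collapse = ""), "]"), kmers)]
  unique(kmers)
}

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is untouched.
with_local_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a per-stream 32-bit seed from a base seed and a stream index, so
# results are invariant to the order in which streams are consumed.
substream_seed <- function(seed, index) {
  as.integer((as.double(seed) %% 2147483647 + as.double(index) * 1000003) %% 2147483647)
}

msg <- function(...) message("[mockqc] ", ...)

`%||%` <- function(a, b) if (is.null(a)) b else a
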