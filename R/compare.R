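# Aggregation of classified ASVs to species-level profiles and comparison
# against the theoretical composition: per-sample Spearman rho plus the
# percentage of "Unknown" reads (the contamination/artifact diagnostic).

#' Aggregate ASV counts to species-level counts
#'
#' Sums the counts of ASVs assigned to the same species, per sample. Species
#' labels absent from the theoretical table are folded into "Unknown" (with
#' a warning): they are, by definition, not expected in the mock. The output
#' row order is the theoretical species order with "Unknown" last.
#'
#' @param tbl an \code{\link{asv_table}}.
#' @param assignments data.frame from \code{\link{classify_table}} (one row
#'   per ASV, in table row order).
#' @param tc a \code{\link{theoretical_composition}}.
#' @return integer matrix of raw counts, (theoretical species + "Unknown")
#'   by samples.
#' @export
aggregate_to_species <- function(tbl, assignments, tc) {
  stopifnot(inherits(tbl, "asv_table"),
            inherits(tc, "theoretical_composition"))
  if (nrow(assignments) != length(tbl$asv_sequences))
    stop("got ", nrow(assignments), " assignments for ",
         length(tbl$asv_sequences), " ASVs")
  theo <- names(tc$expected)
  labels <- assignments$species
  unexpected <- setdiff(labels, c(theo, UNKNOWN_LABEL))
  if (length(unexpected) > 0L) {
    warning("species not in the theoretical table folded into Unknown: ",
            paste(unexpected, collapse = ", "))
    labels[labels %in% unexpected] <- UNKNOWN_LABEL
  }
  out_levels <- c(theo, UNKNOWN_LABEL)
  grp <- factor(labels, levels = out_levels)
  agg <- rowsum(tbl$counts, group = grp, reorder = FALSE)
  # rowsum drops empty levels; rebuild the full species x sample matrix
  counts <- matrix(0L, nrow = length(out_levels), ncol = ncol(tbl$counts),
                   dimnames = list(out_levels, tbl$sample_ids))
  counts[rownames(agg), ] <- agg
  storage.mode(counts) <- "integer"
  counts
}

#' Convert species counts to percent relative abundance
#'
#' Samples with zero total reads are dropped with a warning (the remaining
#' samples proceed); they carry no compositional information.
#'
#' @param species_counts matrix from \code{\link{aggregate_to_species}}.
#' @return numeric matrix of percents with the same rows; each retained
#'   column sums to 100 (within 1e-9).
#' @export
to_relative_abundance <- function(species_counts) {
  depths <- colSums(species_counts)
  zero <- depths == 0
  if (any(zero))
    warning("zero-depth sample(s) dropped: ",
            paste(colnames(species_counts)[zero], collapse = ", "))
  kept <- species_counts[, !zero, drop = FALSE]
  sweep(kept, 2L, colSums(kept), "/") * 100
}

#' Spearman rank correlation with midrank ties
#'
#' Assigns average (midrank) ranks to \code{x} and \code{y} independently
#' and returns the Pearson correlation of the two rank vectors. Computed on
#' the ranks explicitly (not the 6*sum(d^2) shortcut) because mock profiles
#' routinely contain ties (zeros). If either rank vector is constant the
#' correlation is undefined and \code{NA} is returned — never a silently
#' propagated NaN.
#'
#' @param x,y numeric vectors of equal length n >= 3.
#' @return rho in [-1, 1], or NA if undefined.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y))
    stop("length mismatch: ", length(x), " vs ", length(y))
  if (length(x) < 3L) stop("need n >= 3, got ", length(x))
  if (anyNA(x) || anyNA(y)) stop("NA values not allowed")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::var(rx) == 0 || stats::var(ry) == 0) return(NA_real_)
  stats::cor(rx, ry, method = "pearson")
}

#' Compare species profiles to the theoretical composition
#'
#' Per sample, the observed percents over the theoretical species ONLY are
#' rank-correlated with the theoretical percents; the "Unknown" fraction is
#' excluded from the correlation vector (the theoretical table has no
#' Unknown entry, and including it at 0 would inflate rho) and reported as
#' its own diagnostic. The observed vector is not renormalized after
#' excluding Unknown: Spearman is rank-based, so renormalization would be a
#' no-op.
#'
#' @param profiles percent matrix from \code{\link{to_relative_abundance}}.
#' @param tc a \code{\link{theoretical_composition}} with >= 3 species.
#' @return data.frame with one row per sample: \code{sample_id}, \code{rho}
#'   (NA if undefined), \code{n_taxa} (number of theoretical species
#'   compared) and \code{unknown_percent}.
#' @export
compare_to_theoretical <- function(profiles, tc) {
  stopifnot(inherits(tc, "theoretical_composition"))
  theo <- names(tc$expected)
  if (length(theo) < 3L)
    stop("need >= 3 theoretical species for a rank correlation, got ",
         length(theo))
  if (!all(theo %in% rownames(profiles)))
    stop("profiles are missing theoretical species row(s): ",
         paste(setdiff(theo, rownames(profiles)), collapse = ", "))
  samples <- colnames(profiles)
  rho <- vapply(samples, function(s)
    spearman_rho(profiles[theo, s], unname(tc$expected)), numeric(1))
  unknown <- if (UNKNOWN_LABEL %in% rownames(profiles))
    profiles[UNKNOWN_LABEL, samples] else rep(0, length(samples))
  data.frame(sample_id = samples,
             rho = unname(rho),
             n_taxa = length(theo),
             unknown_percent = unname(unknown),
             row.names = NULL)
}
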