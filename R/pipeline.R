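# The assembled QC pipeline: classify -> aggregate -> compare. This is the
# in-memory core behind the `check` command.

#' Run the mock-community QC pipeline
#'
#' Classifies every ASV against the training set, aggregates counts to
#' species level, converts to percent relative abundance and compares each
#' sample to the theoretical composition. Refuses to proceed when the
#' training set contains species absent from the theoretical table; the
#' converse (expected species with no reference) proceeds with a warning,
#' since such species simply can never be observed.
#'
#' @param tbl an \code{\link{asv_table}}.
#' @param ts a \code{\link{build_training_set}} result.
#' @param tc a \code{\link{theoretical_composition}}.
#' @param params a \code{\link{classifier_params}}.
#' @return list with \code{assignments} (per-ASV data.frame),
#'   \code{species_counts} (species x sample integer matrix),
#'   \code{profiles} (percent matrix) and \code{results} (per-sample
#'   data.frame: sample_id, rho, n_taxa, unknown_percent).
#' @export
run_mock_check <- function(tbl, ts, tc, params = classifier_params()) {
  conc <- check_label_concordance(ts, tc)
  if (!conc$concordant)
    stop("training-set species absent from the theoretical composition: ",
         paste(conc$training_only, collapse = ", "),
         " (theoretical species: ",
         paste(names(tc$expected), collapse = ", "), ")")
  if (length(conc$theoretical_only) > 0L)
    warning("theoretical species without reference sequences (can never ",
            "be observed): ", paste(conc$theoretical_only, collapse = ", "))
  assignments <- classify_table(tbl, ts, params)
  species_counts <- aggregate_to_species(tbl, assignments, tc)
  profiles <- to_relative_abundance(species_counts)
  results <- compare_to_theoretical(profiles, tc)
  list(assignments = assignments, species_counts = species_counts,
       profiles = profiles, results = results)
}
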