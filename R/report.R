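# Diagnostic visuals: composition stacked bars (observed + theoretical),
# per-sample Spearman rho, per-taxon bias panels and the Unknown fraction.
# Plots are views of the pipeline's result objects — every number shown is
# the same number the TSV outputs carry, never a recomputation.

#' Stable color palette keyed by species label
#'
#' Colors are assigned to the lexicographically sorted species labels, so a
#' species keeps its color in every plot of a report; "Unknown" is always
#' a reserved grey.
#'
#' @param species_labels character vector of species labels (without
#'   "Unknown").
#' @return named character vector of colors, including an "Unknown" entry.
#' @export
species_palette <- function(species_labels) {
  labs <- sort(setdiff(unique(species_labels), UNKNOWN_LABEL))
  cols <- grDevices::hcl.colors(max(length(labs), 2L), palette = "Dark 3")
  c(stats::setNames(cols[seq_along(labs)], labs),
    stats::setNames("grey60", UNKNOWN_LABEL))
}

profiles_long <- function(profiles) {
  data.frame(species = rep(rownames(profiles), times = ncol(profiles)),
             sample = rep(colnames(profiles), each = nrow(profiles)),
             percent = as.vector(profiles))
}

#' Stacked composition bars: samples plus the theoretical composition
#'
#' One stacked bar per sample in input order, plus a "Theoretical" bar;
#' segments of each bar sum to 100. Legend order is the theoretical species
#' order with Unknown last.
#'
#' @param profiles percent matrix from \code{\link{to_relative_abundance}}.
#' @param tc a \code{\link{theoretical_composition}}.
#' @return a ggplot object.
#' @export
plot_composition <- function(profiles, tc) {
  theo <- names(tc$expected)
  df <- profiles_long(profiles)
  theo_df <- data.frame(species = c(theo, UNKNOWN_LABEL),
                        sample = "Theoretical",
                        percent = c(unname(tc$expected), 0))
  df <- rbind(df, theo_df)
  df$sample <- factor(df$sample, levels = c(colnames(profiles), "Theoretical"))
  df$species <- factor(df$species, levels = c(theo, UNKNOWN_LABEL))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$percent,
                                   fill = .data$species)) +
    ggplot2::geom_col(position = "stack", width = 0.8) +
    ggplot2::scale_fill_manual(values = species_palette(theo)) +
    ggplot2::labs(x = NULL, y = "Relative abundance (%)", fill = "Species",
                  title = "Observed vs theoretical composition") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Per-sample Spearman rho bars
#'
#' One bar per sample in input order, y-limits [-1, 1], value printed to 2
#' decimals. Samples whose rho is undefined get no bar and an "n/a"
#' annotation.
#'
#' @param results data.frame from \code{\link{compare_to_theoretical}}.
#' @return a ggplot object.
#' @export
plot_rho <- function(results) {
  df <- results
  df$sample <- factor(df$sample_id, levels = df$sample_id)
  df$label <- ifelse(is.na(df$rho), "n/a", sprintf("%.2f", df$rho))
  df$label_y <- ifelse(is.na(df$rho), 0.05, df$rho)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$rho)) +
    ggplot2::geom_col(fill = "steelblue", na.rm = TRUE, width = 0.7) +
    ggplot2::geom_text(ggplot2::aes(y = .data$label_y,
                                    label = .data$label), vjust = -0.4,
                       size = 3) +
    ggplot2::scale_y_continuous(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = "Spearman rho vs theoretical",
                  title = "Agreement with theoretical composition") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Per-taxon abundance panels
#'
#' One panel per theoretical species: observed percent per sample as bars,
#' with a horizontal reference line at the species' theoretical percent —
#' the panel makes taxon-specific biases directly visible.
#'
#' @param profiles percent matrix from \code{\link{to_relative_abundance}}.
#' @param tc a \code{\link{theoretical_composition}}.
#' @return a ggplot object.
#' @export
plot_per_taxon <- function(profiles, tc) {
  theo <- names(tc$expected)
  df <- profiles_long(profiles[theo, , drop = FALSE])
  df$sample <- factor(df$sample, levels = colnames(profiles))
  df$species <- factor(df$species, levels = theo)
  ref <- data.frame(species = factor(theo, levels = theo),
                    expected = unname(tc$expected))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$percent,
                                   fill = .data$species)) +
    ggplot2::geom_col(width = 0.7, show.legend = FALSE) +
    ggplot2::geom_hline(data = ref,
                        ggplot2::aes(yintercept = .data$expected),
                        linetype = "dashed") +
    ggplot2::scale_fill_manual(values = species_palette(theo)) +
    ggplot2::facet_wrap(~species) +
    ggplot2::labs(x = NULL, y = "Relative abundance (%)",
                  title = "Per-taxon abundance vs theoretical (dashed)") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}

#' Unknown-fraction bars
#'
#' Percent of reads not classifiable to any expected mock member, per
#' sample, y-limits [0, 100]. In a dilution series this is the panel where
#' contamination becomes visible as a rising staircase.
#'
#' @param profiles percent matrix from \code{\link{to_relative_abundance}}.
#' @return a ggplot object.
#' @export
plot_unknown <- function(profiles) {
  unk <- if (UNKNOWN_LABEL %in% rownames(profiles))
    profiles[UNKNOWN_LABEL, ] else
    stats::setNames(rep(0, ncol(profiles)), colnames(profiles))
  df <- data.frame(sample = factor(colnames(profiles),
                                   levels = colnames(profiles)),
                   percent = unname(unk))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$percent)) +
    ggplot2::geom_col(fill = "grey60", width = 0.7) +
    ggplot2::scale_y_continuous(limits = c(0, 100)) +
    ggplot2::labs(x = NULL, y = "Unknown reads (%)",
                  title = "Unclassified (\"Unknown\") fraction") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Assemble the report bundle
#'
#' @param check result list of \code{\link{run_mock_check}}.
#' @param tc a \code{\link{theoretical_composition}}.
#' @return list with the four ggplot objects (\code{composition},
#'   \code{rho}, \code{per_taxon}, \code{unknown}) and \code{summary_text}.
#' @export
report_bundle <- function(check, tc) {
  lines <- c(
    sprintf("mockqc run summary (mock: %s)", tc$mock_name),
    sprintf("samples: %s", paste(check$results$sample_id, collapse = ", ")),
    sprintf("theoretical species: %d", length(tc$expected)),
    "per-sample agreement:",
    sprintf("  %-12s rho=%-10s unknown=%7.3f%%",
            check$results$sample_id,
            ifelse(is.na(check$results$rho), "n/a",
                   sprintf("%.6f", check$results$rho)),
            check$results$unknown_percent))
  list(composition = plot_composition(check$profiles, tc),
       rho = plot_rho(check$results),
       per_taxon = plot_per_taxon(check$profiles, tc),
       unknown = plot_unknown(check$profiles),
       summary_text = paste(lines, collapse = "\n"))
}

save_plot <- function(p, path, format, width = 7, height = 5) {
  if (format == "svg") grDevices::svg(path, width = width, height = height)
  else if (format == "png") grDevices::png(path, width = width * 100,
                                           height = height * 100, res = 100)
  else stop("unsupported plot format: ", format)
  on.exit(grDevices::dev.off())
  print(p)
  invisible(path)
}

#' Write the report to disk
#'
#' Writes the four diagnostic plots and \code{run_summary.txt}. SVG is the
#' canonical format (deterministic and diffable); PNG is available via
#' \code{format = "png"}.
#'
#' @param bundle result of \code{\link{report_bundle}}.
#' @param out_dir output directory (created if absent).
#' @param format "svg" (default) or "png".
#' @return invisibly, the five file paths.
#' @export
write_report <- function(bundle, out_dir, format = c("svg", "png")) {
  format <- match.arg(format)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  names <- c(composition = "composition", rho = "correlation",
             per_taxon = "per_taxon", unknown = "unknown_fraction")
  paths <- character(0)
  for (key in names(names)) {
    f <- file.path(out_dir, paste0(names[[key]], ".", format))
    save_plot(bundle[[key]], f, format)
    paths[key] <- f
  }
  f_sum <- file.path(out_dir, "run_summary.txt")
  writeLines(bundle$summary_text, f_sum)
  paths["summary"] <- f_sum
  invisible(paths)
}
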