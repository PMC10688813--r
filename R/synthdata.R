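# Fully synthetic mock communities: reference panels, theoretical
# compositions, ASV variant sets and simulated count tables, including a
# 3-fold-style dilution series (D0..D8) with an increasing contamination
# schedule. Everything is seeded and deterministic, so the whole pipeline
# is testable without any external data. No vendor sequences or percentages
# are shipped; real mocks are supplied by the user as FASTA + TSV.

#' Simulation configuration
#'
#' @param n_species number of mock members (>= 2), default 8 (a
#'   D6300-style 8-bacterial-species standard).
#' @param seq_length reference length in nt, default 1500
#'   (full-length-16S-like).
#' @param depth reads per sample, default 1e5.
#' @param asv_error_rate per-base substitution probability used to derive
#'   ASV variants from references (must be < 0.1), default 0.02.
#' @param n_variants_per_species ASVs per species (the reference itself plus
#'   mutated copies), default 3.
#' @param contamination_rate probability mass routed to contaminant ASVs in
#'   each sample, in [0,1]. NULL (default) selects the dilution-series
#'   design, where contamination follows an increasing schedule instead.
#' @param n_samples number of samples in constant-contamination designs,
#'   default 3. Ignored for the dilution series (always 9: D0..D8).
#' @param n_contaminants size of the contaminant ASV pool, default 5.
#' @param k classifier word size used for the separability guarantees,
#'   default 8.
#' @param rng_seed base seed for all generation, default 42.
#' @return object of class \code{simulation_config}.
#' @export
simulation_config <- function(n_species = 8L, seq_length = 1500L,
                              depth = 100000L, asv_error_rate = 0.02,
                              n_variants_per_species = 3L,
                              contamination_rate = NULL, n_samples = 3L,
                              n_contaminants = 5L, k = 8L, rng_seed = 42L) {
  n_species <- as.integer(n_species)
  if (n_species < 2L) stop("n_species must be >= 2")
  if (seq_length < 2L * k) stop("seq_length must be >= 2k")
  if (depth < 1L) stop("depth must be >= 1")
  if (asv_error_rate < 0 || asv_error_rate >= 0.1)
    stop("asv_error_rate must be in [0, 0.1)")
  if (!is.null(contamination_rate) &&
      (contamination_rate < 0 || contamination_rate > 1))
    stop("contamination_rate must be in [0, 1]")
  if (n_variants_per_species < 1L) stop("n_variants_per_species must be >= 1")
  if (n_contaminants < 1L) stop("n_contaminants must be >= 1")
  structure(list(n_species = n_species,
                 seq_length = as.integer(seq_length),
                 depth = as.integer(depth),
                 asv_error_rate = asv_error_rate,
                 n_variants_per_species = as.integer(n_variants_per_species),
                 contamination_rate = contamination_rate,
                 n_samples = as.integer(n_samples),
                 n_contaminants = as.integer(n_contaminants),
                 k = as.integer(k),
                 rng_seed = as.integer(rng_seed)),
            class = "simulation_config")
}

random_dna <- function(length) {
  paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
}

kmer_jaccard <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}

# Expected percents: Dirichlet-like draw (normalized gammas) in tenths of a
# percent, largest component absorbs the rounding residue so the sum is
# exactly 100; redrawn until all values are distinct and >= 1 percent.
draw_theoretical_percents <- function(n) {
  for (attempt in seq_len(1000L)) {
    w <- stats::rgamma(n, shape = 5, rate = 1)
    tenths <- round(1000 * w / sum(w))
    tenths[which.max(tenths)] <- tenths[which.max(tenths)] + 1000L - sum(tenths)
    if (all(tenths >= 10L) && !anyDuplicated(tenths))
      return(tenths / 10)
  }
  stop("could not draw valid theoretical percents after 1000 attempts")
}

#' Generate a synthetic reference panel and theoretical composition
#'
#' References are i.i.d. uniform-random ACGT sequences; pairwise k-mer-set
#' Jaccard similarity < 0.05 is enforced by regeneration, which guarantees
#' the species are separable by the k-mer classifier. Expected percents are
#' drawn from a seeded Dirichlet-like scheme, rounded to 1 decimal and
#' adjusted to sum to exactly 100, all distinct and >= 1.
#'
#' @param cfg a \code{\link{simulation_config}}.
#' @return list with \code{records} (data.frame: record_id, species,
#'   sequence) and \code{tc} (a \code{\link{theoretical_composition}}).
#' @export
generate_reference_panel <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_local_seed(substream_seed(cfg$rng_seed, 1L), {
    n <- cfg$n_species
    seqs <- vapply(seq_len(n), function(i) random_dna(cfg$seq_length),
                   character(1))
    ksets <- lapply(seqs, kmer_set, k = cfg$k)
    retries <- 0L
    repeat {
      clash <- NULL
      for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
        if (kmer_jaccard(ksets[[i]], ksets[[j]]) >= 0.05) { clash <- j; break }
      }
      if (is.null(clash)) break
      retries <- retries + 1L
      if (retries > 100L)
        stop("could not generate a k-mer-separable panel after 100 retries; ",
             "seq_length is too small for k = ", cfg$k)
      seqs[clash] <- random_dna(cfg$seq_length)
      ksets[[clash]] <- kmer_set(seqs[clash], cfg$k)
    }
    species <- sprintf("Mock_species_%02d", seq_len(n))
    records <- data.frame(record_id = sprintf("ref_%02d", seq_len(n)),
                          species = species,
                          sequence = seqs)
    pct <- draw_theoretical_percents(n)
    tc <- theoretical_composition(stats::setNames(pct, species),
                                  mock_name = "synthetic_mock")
    list(records = records, tc = tc)
  })
}

mutate_sequence <- function(sequence, rate) {
  bases <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(bases)) < rate)
  for (p in hit)
    bases[p] <- sample(setdiff(DNA_BASES, bases[p]), 1L)
  paste(bases, collapse = "")
}

#' Generate ASV variants from a reference panel
#'
#' Emulates the structure of dada2 output: per species, the reference
#' sequence itself plus seeded substitution-mutated copies (no indels, so
#' variant length stays fixed). All emitted variants are unique; duplicates
#' after mutation are redrawn (bounded retries). With
#' \code{asv_error_rate = 0} the mutated copies collapse onto the reference
#' and each species contributes a single variant.
#'
#' @param panel result of \code{\link{generate_reference_panel}}.
#' @param cfg a \code{\link{simulation_config}}.
#' @return data.frame with columns \code{asv_sequence}, \code{species}.
#' @export
generate_asv_variants <- function(panel, cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_local_seed(substream_seed(cfg$rng_seed, 2L), {
    rows <- lapply(seq_len(nrow(panel$records)), function(i) {
      ref <- panel$records$sequence[i]
      variants <- ref
      n_extra <- cfg$n_variants_per_species - 1L
      if (n_extra > 0L && cfg$asv_error_rate > 0) {
        for (v in seq_len(n_extra)) {
          for (try in seq_len(50L)) {
            cand <- mutate_sequence(ref, cfg$asv_error_rate)
            if (!cand %in% variants) break
            cand <- NULL
          }
          if (is.null(cand))
            stop("could not generate a unique variant after 50 redraws")
          variants <- c(variants, cand)
        }
      }
      data.frame(asv_sequence = variants,
                 species = panel$records$species[i])
    })
    out <- do.call(rbind, rows)
    stopifnot(!anyDuplicated(out$asv_sequence))
    out
  })
}

# Build one contaminant sequence sharing NO k-mer with the panel, by a
# base-by-base walk that never closes a window present in the panel index
# (plain rejection of whole random sequences is hopeless at this length:
# nearly every random 1500-mer shares some 8-mer with an 8-species panel).
walk_disjoint_sequence <- function(length, k, panel_env) {
  for (attempt in seq_len(1000L)) {
    repeat {
      seed_kmer <- random_dna(k)
      if (!exists(seed_kmer, envir = panel_env, inherits = FALSE)) break
    }
    bases <- character(length)
    bases[seq_len(k)] <- strsplit(seed_kmer, "", fixed = TRUE)[[1L]]
    pos <- k
    dead <- FALSE
    while (pos < length) {
      tail <- paste(bases[(pos - k + 2L):pos], collapse = "")
      cand <- sample(DNA_BASES)
      ok <- cand[!vapply(paste0(tail, cand), exists, logical(1),
                         envir = panel_env, inherits = FALSE)]
      if (length(ok) == 0L) { dead <- TRUE; break }
      pos <- pos + 1L
      bases[pos] <- ok[1L]
    }
    if (!dead) return(paste(bases, collapse = ""))
  }
  stop("could not build a panel-disjoint contaminant after 1000 attempts")
}

#' Generate the contaminant ASV pool
#'
#' Contaminants are random sequences constructed to be k-mer-disjoint from
#' every panel reference, so the "Unknown" ground truth of simulated
#' samples is unambiguous. Realism of contaminant phylogeny is a non-goal.
#'
#' @param panel result of \code{\link{generate_reference_panel}}.
#' @param cfg a \code{\link{simulation_config}}.
#' @return character vector of contaminant sequences.
#' @export
generate_contaminants <- function(panel, cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_local_seed(substream_seed(cfg$rng_seed, 3L), {
    panel_env <- new.env(hash = TRUE, parent = emptyenv())
    for (s in panel$records$sequence)
      for (w in kmer_set(s, cfg$k)) assign(w, TRUE, envir = panel_env)
    out <- character(cfg$n_contaminants)
    for (i in seq_len(cfg$n_contaminants)) {
      repeat {
        cand <- walk_disjoint_sequence(cfg$seq_length, cfg$k, panel_env)
        if (!cand %in% out) break
      }
      out[i] <- cand
    }
    out
  })
}

# Per-ASV sampling probabilities for one sample at contamination rate c:
# variant i of species s gets (1 - c) * (theoretical_s / 100) / n_variants_s,
# the contaminant pool shares c equally.
sample_probabilities <- function(variants, contaminants, tc, c) {
  n_var <- table(variants$species)
  p_var <- (1 - c) * (tc$expected[variants$species] / 100) /
    as.numeric(n_var[variants$species])
  p_con <- rep(c / length(contaminants), length(contaminants))
  c(unname(p_var), p_con)
}

#' Simulate the read counts of one mock sample
#'
#' Allocates \code{depth} reads by a single multinomial draw over all ASVs
#' (species variants plus the contaminant pool). With
#' \code{exact_counts = TRUE} the multinomial draw is replaced by
#' deterministic expected counts \code{round(depth * p)}, giving a
#' noise-free surface for end-to-end identity checks.
#'
#' @param variants data.frame from \code{\link{generate_asv_variants}}.
#' @param contaminants character vector from
#'   \code{\link{generate_contaminants}}.
#' @param tc the panel's \code{\link{theoretical_composition}}.
#' @param depth reads in the sample.
#' @param contamination_rate mass routed to the contaminant pool, in [0,1].
#' @param exact_counts logical; see above.
#' @return integer vector of counts, one per ASV (variants then
#'   contaminants).
#' @export
simulate_sample_counts <- function(variants, contaminants, tc, depth,
                                   contamination_rate, exact_counts = FALSE) {
  p <- sample_probabilities(variants, contaminants, tc, contamination_rate)
  if (exact_counts) as.integer(round(depth * p))
  else as.integer(stats::rmultinom(1L, size = depth, prob = p))
}

#' Contamination schedule of the dilution series
#'
#' Strictly increasing in the dilution index: c_i = 1 - (1 - c0) * g^i,
#' with g chosen so that the final dilution reaches \code{c_final}. The
#' schedule models the qualitative behavior of diluting a mock standard —
#' lower input biomass inflates the relative contribution of contaminant
#' reads — not any particular laboratory's contamination load.
#'
#' @param n_dilutions number of samples (default 9: D0..D8).
#' @param c0 contamination rate of the undiluted sample, default 0.01.
#' @param c_final contamination rate of the last dilution, default 0.6.
#' @return numeric vector of length \code{n_dilutions}, named D0, D1, ...
#' @export
dilution_schedule <- function(n_dilutions = 9L, c0 = 0.01, c_final = 0.6) {
  stopifnot(n_dilutions >= 2L, c0 >= 0, c0 < c_final, c_final <= 1)
  g <- ((1 - c_final) / (1 - c0))^(1 / (n_dilutions - 1L))
  i <- seq_len(n_dilutions) - 1L
  stats::setNames(1 - (1 - c0) * g^i, paste0("D", i))
}

#' Simulate a D0..D8-style dilution series
#'
#' Nine samples at constant depth whose contamination rate follows
#' \code{\link{dilution_schedule}}.
#'
#' @param panel,variants,contaminants synthetic inputs (see the respective
#'   generators).
#' @param cfg a \code{\link{simulation_config}}.
#' @param exact_counts logical, see \code{\link{simulate_sample_counts}}.
#' @return an \code{\link{asv_table}} with samples D0..D8 and the schedule
#'   attached as attribute \code{"schedule"}.
#' @export
simulate_dilution_series <- function(panel, variants, contaminants, cfg,
                                     exact_counts = FALSE) {
  schedule <- dilution_schedule()
  counts <- with_local_seed(substream_seed(cfg$rng_seed, 4L),
    vapply(schedule, function(c)
      simulate_sample_counts(variants, contaminants, panel$tc, cfg$depth,
                             c, exact_counts),
      integer(nrow(variants) + length(contaminants))))
  tbl <- asv_table(counts,
                   asv_sequences = c(variants$asv_sequence, contaminants),
                   sample_ids = names(schedule))
  attr(tbl, "schedule") <- schedule
  tbl
}

#' Simulate a full synthetic mock experiment
#'
#' Generates the reference panel, theoretical composition, ASV variants,
#' contaminant pool and a count table — either the dilution series (when
#' \code{cfg$contamination_rate} is NULL) or \code{cfg$n_samples} samples
#' S1..Sn at a constant contamination rate.
#'
#' @param cfg a \code{\link{simulation_config}}.
#' @param exact_counts logical, see \code{\link{simulate_sample_counts}}.
#' @return list with \code{records}, \code{species_map}, \code{tc},
#'   \code{variants}, \code{contaminants}, \code{table}.
#' @export
simulate_mock_experiment <- function(cfg = simulation_config(),
                                     exact_counts = FALSE) {
  panel <- generate_reference_panel(cfg)
  variants <- generate_asv_variants(panel, cfg)
  contaminants <- generate_contaminants(panel, cfg)
  if (is.null(cfg$contamination_rate)) {
    tbl <- simulate_dilution_series(panel, variants, contaminants, cfg,
                                    exact_counts)
  } else {
    counts <- with_local_seed(substream_seed(cfg$rng_seed, 4L),
      vapply(seq_len(cfg$n_samples), function(i)
        simulate_sample_counts(variants, contaminants, panel$tc, cfg$depth,
                               cfg$contamination_rate, exact_counts),
        integer(nrow(variants) + length(contaminants))))
    tbl <- asv_table(counts,
                     asv_sequences = c(variants$asv_sequence, contaminants),
                     sample_ids = paste0("S", seq_len(cfg$n_samples)))
  }
  list(records = panel$records,
       species_map = stats::setNames(panel$records$species,
                                     panel$records$record_id),
       tc = panel$tc,
       variants = variants,
       contaminants = contaminants,
       table = tbl)
}

#' Write a simulated experiment's four input files
#'
#' Writes \code{reference.fasta}, \code{species_map.tsv},
#' \code{theoretical.tsv} and \code{asv_table.tsv} to \code{out_dir} — the
#' exact inputs the QC pipeline consumes, so a simulated run exercises the
#' same readers as a real one.
#'
#' @param sim result of \code{\link{simulate_mock_experiment}}.
#' @param out_dir output directory (created if absent).
#' @return invisibly, the four file paths.
#' @export
write_simulation <- function(sim, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  f_fa <- file.path(out_dir, "reference.fasta")
  write_fasta(stats::setNames(sim$records$sequence, sim$records$record_id),
              f_fa)
  f_map <- file.path(out_dir, "species_map.tsv")
  write_species_map(sim$species_map, f_map)
  f_tc <- file.path(out_dir, "theoretical.tsv")
  write_theoretical_composition(sim$tc, f_tc)
  f_tab <- file.path(out_dir, "asv_table.tsv")
  write_asv_table(sim$table, f_tab)
  invisible(c(reference = f_fa, species_map = f_map, theoretical = f_tc,
              asv_table = f_tab))
}
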