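test_that("simulation_config validates rates and sizes", {
  expect_error(simulation_config(n_species = 1), "n_species")
  expect_error(simulation_config(asv_error_rate = 0.2), "asv_error_rate")
  expect_error(simulation_config(contamination_rate = 1.5),
               "contamination_rate")
  expect_error(simulation_config(seq_length = 10, k = 8), "2k")
  expect_error(simulation_config(depth = 0), "depth")
})

test_that("reference panels are deterministic, separable, and sum to 100", {
  cfg <- small_config()
  p1 <- generate_reference_panel(cfg)
  p2 <- generate_reference_panel(cfg)
  expect_identical(p1, p2)

  pct <- p1$tc$expected
  expect_equal(sum(pct), 100)
  expect_true(all(pct >= 1))
  expect_false(any(duplicated(pct)))

  ksets <- lapply(p1$records$sequence, kmer_set, k = cfg$k)
  n <- length(ksets)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    jac <- length(intersect(ksets[[i]], ksets[[j]])) /
      length(union(ksets[[i]], ksets[[j]]))
    expect_lt(jac, 0.05)
  }
})

test_that("zero error rate collapses variants onto the references", {
  cfg <- small_config(asv_error_rate = 0)
  panel <- generate_reference_panel(cfg)
  variants <- generate_asv_variants(panel, cfg)
  expect_equal(nrow(variants), cfg$n_species)  # deduplicated to 1/species
  expect_setequal(variants$asv_sequence, panel$records$sequence)
})

test_that("mutated variants are unique with binomial substitution load", {
  cfg <- simulation_config(n_species = 4L, seq_length = 1500L,
                           asv_error_rate = 0.02,
                           n_variants_per_species = 6L, rng_seed = 17L)
  panel <- generate_reference_panel(cfg)
  mismatches <- integer(0)
  for (seed in 1:10) {
    cfg$rng_seed <- seed
    variants <- generate_asv_variants(panel, cfg)
    expect_false(any(duplicated(variants$asv_sequence)))
    muts <- variants[!variants$asv_sequence %in% panel$records$sequence, ]
    ref_of <- stats::setNames(panel$records$sequence, panel$records$species)
    mismatches <- c(mismatches, vapply(seq_len(nrow(muts)), function(i) {
      a <- strsplit(muts$asv_sequence[i], "")[[1]]
      b <- strsplit(ref_of[[muts$species[i]]], "")[[1]]
      sum(a != b)
    }, integer(1)))
  }
  # mean substitutions per variant ~ Binomial(1500, 0.02) mean = 30;
  # 200 draws put the sample mean well within +/- 2 of it
  expect_equal(mean(mismatches), 1500 * 0.02, tolerance = 2 / 30)
})

test_that("contaminants share no k-mer with any panel reference", {
  cfg <- small_config()
  panel <- generate_reference_panel(cfg)
  contaminants <- generate_contaminants(panel, cfg)
  expect_equal(length(contaminants), cfg$n_contaminants)
  expect_false(any(duplicated(contaminants)))
  panel_kmers <- unique(unlist(lapply(panel$records$sequence, kmer_set,
                                      k = cfg$k)))
  for (cs in contaminants) {
    expect_equal(nchar(cs), cfg$seq_length)
    expect_length(intersect(kmer_set(cs, cfg$k), panel_kmers), 0)
  }
})

test_that("sample probabilities split mass by theoretical percent and c", {
  cfg <- small_config(contamination_rate = 0.25, asv_error_rate = 0)
  sim <- simulate_mock_experiment(cfg, exact_counts = TRUE)
  depths <- colSums(sim$table$counts)
  contam_counts <- sim$table$counts[sim$contaminants, , drop = FALSE]
  expect_equal(unname(colSums(contam_counts) / depths),
               rep(0.25, cfg$n_samples), tolerance = 1e-3)
  # c = 1: every read lands on contaminants
  cfg1 <- small_config(contamination_rate = 1)
  sim1 <- simulate_mock_experiment(cfg1)
  species_counts <- sim1$table$counts[sim1$variants$asv_sequence, ]
  expect_equal(sum(species_counts), 0L)
  expect_equal(unname(colSums(sim1$table$counts)),
               rep(cfg1$depth, cfg1$n_samples))
})

test_that("constant-contamination unknown fraction concentrates near c", {
  # binomial concentration at depth 1e5: Unknown% within [25, 35] at c = 0.3
  cfg <- simulation_config(n_species = 6L, seq_length = 400L,
                           contamination_rate = 0.3, rng_seed = 23L)
  panel <- generate_reference_panel(cfg)
  variants <- generate_asv_variants(panel, cfg)
  contaminants <- generate_contaminants(panel, cfg)
  ts <- build_training_set(panel$records, k = cfg$k)
  asvs <- c(variants$asv_sequence, contaminants)
  hits <- vapply(1:100, function(seed) {
    counts <- mockqc:::with_local_seed(seed,
      simulate_sample_counts(variants, contaminants, panel$tc,
                             cfg$depth, 0.3))
    tbl <- asv_table(matrix(counts, ncol = 1), asvs, "s1")
    asg <- classify_table(tbl, ts, classifier_params(rng_seed = 1L))
    prof <- to_relative_abundance(aggregate_to_species(tbl, asg, panel$tc))
    unk <- prof["Unknown", "s1"]
    unk >= 25 && unk <= 35
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("dilution series has 9 samples with a strictly increasing schedule", {
  sched <- dilution_schedule()
  expect_equal(names(sched), paste0("D", 0:8))
  expect_true(all(diff(sched) > 0))
  expect_equal(unname(sched[1]), 0.01)
  expect_equal(unname(sched[9]), 0.6, tolerance = 1e-12)

  cfg <- small_config()
  sim <- simulate_mock_experiment(cfg)
  expect_equal(sim$table$sample_ids, paste0("D", 0:8))
  expect_equal(unname(colSums(sim$table$counts)), rep(cfg$depth, 9L))
})

test_that("simulation output files are deterministic under the seed", {
  cfg <- small_config()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(simulate_mock_experiment(cfg), d1)
  write_simulation(simulate_mock_experiment(cfg), d2)
  for (f in c("reference.fasta", "species_map.tsv", "theoretical.tsv",
              "asv_table.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # and the files round-trip through the package readers
  tbl <- read_asv_table(file.path(d1, "asv_table.tsv"))
  expect_identical(tbl$counts, simulate_mock_experiment(cfg)$table$counts)
  tc <- read_theoretical_composition(file.path(d1, "theoretical.tsv"))
  expect_equal(sum(tc$expected), 100)
})
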