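test_that("score_species matches the hand-evaluated two-species case", {
  ts <- tiny_training_set()
  # one k-mer present only in A, N = 2 species:
  # p_w = (1 + 0.5)/3 = 0.5; score(A) = log(1.5/2), score(B) = log(0.5/2)
  s <- score_species("ACGT", ts)
  expect_equal(unname(s["A"]), log(0.75), tolerance = 1e-12)
  expect_equal(unname(s["B"]), log(0.25), tolerance = 1e-12)
  expect_gt(s["A"], s["B"])
})

test_that("shared or absent k-mers leave all species tied", {
  records <- data.frame(record_id = c("r1", "r2"),
                        species = c("A", "B"),
                        sequence = c("ACGTACGT", "TACGTACG"))
  ts <- build_training_set(records, k = 4)
  shared <- intersect(ts$kmer_index$A, ts$kmer_index$B)[1]
  s1 <- score_species(shared, ts)
  expect_equal(unname(s1["A"]), unname(s1["B"]), tolerance = 1e-12)
  s2 <- score_species("AAAA", ts)  # in neither index
  expect_equal(unname(s2["A"]), unname(s2["B"]), tolerance = 1e-12)
})

test_that("score_species equals the brute-force oracle on random cases", {
  cfg <- simulation_config(n_species = 5L, seq_length = 60L, k = 6L,
                           rng_seed = 3L)
  panel <- generate_reference_panel(cfg)
  ts <- build_training_set(panel$records, k = 6L)
  all_kmers <- unique(unlist(ts$kmer_index))
  withr::with_seed(99, {
    for (i in 1:20) {
      q <- c(sample(all_kmers, sample(3:25, 1), replace = TRUE),
             kmer_set(paste(sample(c("A", "C", "G", "T"), 12,
                                   replace = TRUE), collapse = ""), 6))
      q <- q[seq_len(min(30, length(q)))]
      expect_equal(score_species(q, ts), oracle_score_species(q, ts),
                   tolerance = 1e-12)
    }
  })
})

test_that("duplicate query k-mers contribute once", {
  ts <- tiny_training_set()
  expect_equal(score_species(c("ACGT", "ACGT", "CCCC"), ts),
               score_species(c("ACGT", "CCCC"), ts))
})

test_that("exact reference copies classify to their species with confidence 1", {
  cfg <- small_config()
  panel <- generate_reference_panel(cfg)
  ts <- build_training_set(panel$records, k = cfg$k)
  for (i in seq_len(nrow(panel$records))) {
    got <- classify_asv(panel$records$sequence[i], ts,
                        classifier_params(rng_seed = 5L), asv_index = i)
    expect_equal(got$species, panel$records$species[i])
    expect_equal(got$confidence, 1.0)
  }
})

test_that("zero shared k-mers always yields (Unknown, 0)", {
  ts <- tiny_training_set()
  got <- classify_asv(strrep("A", 40), ts,
                      classifier_params(k = 4, rng_seed = 1))
  expect_equal(got$species, "Unknown")
  expect_equal(got$confidence, 0)
})

test_that("too-short and all-ambiguous ASVs fall back to Unknown", {
  ts <- tiny_training_set()
  p <- classifier_params(k = 4, rng_seed = 1)
  expect_warning(got <- classify_asv("ACG", ts, p), "shorter than k")
  expect_equal(got$species, "Unknown")
  expect_equal(got$confidence, 0)
  got2 <- classify_asv("NNNNNNNN", ts, p)
  expect_equal(got2$species, "Unknown")
  expect_equal(got2$confidence, 0)
})

test_that("mutated references recover their species; k-mer overlap agrees", {
  cfg <- small_config()
  panel <- generate_reference_panel(cfg)
  ts <- build_training_set(panel$records, k = cfg$k)
  variants <- generate_asv_variants(panel, cfg)  # includes 2% mutants
  mutants <- variants[!variants$asv_sequence %in% panel$records$sequence, ]
  expect_gt(nrow(mutants), 0)
  for (i in seq_len(nrow(mutants))) {
    asv <- mutants$asv_sequence[i]
    truth <- mutants$species[i]
    # brute-force check that the true species dominates the k-mer overlap
    overlap <- vapply(ts$species_labels, function(s)
      length(intersect(kmer_set(asv, cfg$k), ts$kmer_index[[s]])),
      integer(1))
    expect_equal(names(which.max(overlap)), truth)
    got <- classify_asv(asv, ts, classifier_params(rng_seed = 2L),
                        asv_index = i)
    expect_equal(got$species, truth)
    expect_gte(got$confidence, 0.60)
  }
})

test_that("classification is deterministic and order-invariant", {
  cfg <- small_config()
  sim <- simulate_mock_experiment(cfg)
  ts <- build_training_set(sim$records, k = cfg$k)
  p <- classifier_params(rng_seed = 123L)
  a1 <- classify_table(sim$table, ts, p)
  a2 <- classify_table(sim$table, ts, p)
  expect_identical(a1, a2)
  expect_equal(nrow(a1), length(sim$table$asv_sequences))
  expect_equal(a1$asv_sequence, sim$table$asv_sequences)
  # per-ASV substreams: classifying ASV 3 alone matches its in-table call
  alone <- classify_asv(sim$table$asv_sequences[3], ts, p, asv_index = 3L)
  expect_equal(alone$species, a1$species[3])
  expect_equal(alone$confidence, a1$confidence[3])
})

test_that("species calls for exact reference copies are seed-invariant", {
  cfg <- small_config(asv_error_rate = 0, n_variants_per_species = 1L)
  sim <- simulate_mock_experiment(cfg)
  ts <- build_training_set(sim$records, k = cfg$k)
  a1 <- classify_table(sim$table, ts, classifier_params(rng_seed = 1L))
  a2 <- classify_table(sim$table, ts, classifier_params(rng_seed = 999L))
  expect_equal(a1$species, a2$species)
})

test_that("raising the threshold never converts Unknown to a species call", {
  cfg <- small_config()
  sim <- simulate_mock_experiment(cfg)
  ts <- build_training_set(sim$records, k = cfg$k)
  thresholds <- c(0, 0.6, 0.9, 1)
  calls <- lapply(thresholds, function(t)
    classify_table(sim$table, ts,
                   classifier_params(rng_seed = 4L,
                                     confidence_threshold = t)))
  for (i in seq_len(length(thresholds) - 1L)) {
    lo <- calls[[i]]$species
    hi <- calls[[i + 1L]]$species
    expect_true(all(hi[lo == "Unknown"] == "Unknown"))
  }
})
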