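test_that("generators are deterministic given the seed and leave the RNG intact", {
  set.seed(999)
  before <- .Random.seed
  a <- simulate_snapshots(n_universe_pairs = 500L, seed = 7L)
  expect_identical(.Random.seed, before)
  b <- simulate_snapshots(n_universe_pairs = 500L, seed = 7L)
  expect_identical(a, b)
  c <- simulate_snapshots(n_universe_pairs = 500L, seed = 8L)
  expect_false(identical(a$truth$sets, c$truth$sets))

  o1 <- simulate_orthology(n_group_pairs = 50L, seed = 7L)
  o2 <- simulate_orthology(n_group_pairs = 50L, seed = 7L)
  expect_identical(o1, o2)

  f1 <- simulate_sequences(2L, 4L, 0.1, 50L, seed = 7L)
  expect_identical(f1, simulate_sequences(2L, 4L, 0.1, 50L, seed = 7L))

  e1 <- simulate_ensemble(n_models = 5L, seed = 7L)
  expect_identical(e1, simulate_ensemble(n_models = 5L, seed = 7L))
})

test_that("snapshot simulation honours containment exactly", {
  sim <- simulate_snapshots(n_universe_pairs = 1000L, seed = 3L)
  specs <- sim$truth$db_specs
  sub <- specs$name[!is.na(specs$subset_of)]
  sup <- specs$subset_of[!is.na(specs$subset_of)]
  expect_true(all(sim$truth$sets[[sub]] %in% sim$truth$sets[[sup]]))
  expect_equal(overlap_coefficient(sim$snapshots[[sub]],
                                   sim$snapshots[[sup]]), 1.0)
  # snapshots reproduce the truth sets exactly
  for (nm in names(sim$snapshots)) {
    expect_setequal(snapshot_keys(sim$snapshots[[nm]]), sim$truth$sets[[nm]])
  }
  # infeasible subset spec is rejected
  bad <- default_db_specs()
  bad$size[8] <- bad$size[3] + 1L
  expect_error(simulate_snapshots(db_specs = bad, seed = 1L), "infeasible")
})

test_that("pipeline overlap statistics match truth-set enumeration", {
  sim <- simulate_snapshots(n_universe_pairs = 800L, seed = 5L)
  m_pipeline <- overlap_matrix(sim$snapshots)
  m_truth <- overlap_matrix(sim$truth$sets)
  expect_equal(m_pipeline$values, m_truth$values)
  expect_equal(m_pipeline$median_offdiag, m_truth$median_offdiag)
})

test_that("planted conservation spans are recovered exactly", {
  orth <- simulate_orthology(n_group_pairs = 120L, seed = 2L)
  spans <- build_spans(orth$snapshots, orth$accession_to_group)
  truth <- orth$truth_spans
  expect_equal(nrow(spans), nrow(truth))
  expect_identical(spans$group_a, truth$group_a)
  expect_identical(spans$group_b, truth$group_b)
  expect_identical(spans$span, truth$span)
  expect_identical(spans$taxa, truth$taxa)
  # recovered histogram == planted histogram, bin by bin
  expect_identical(span_histogram(spans, 6L),
                   span_histogram(
                     structure(truth, class = c("ppi_spans", "data.frame")), 6L))

  # distribution concentrated at span 1
  flat <- simulate_orthology(n_group_pairs = 40L, span_distribution = 1,
                             seed = 2L)
  expect_true(all(build_spans(flat$snapshots,
                              flat$accession_to_group)$span == 1L))
})

test_that("structure-index simulation inverts the planted odds correctly", {
  # baseline 0.05, OR 80 implies p ~ 0.808
  base_odds <- 0.05 / 0.95
  p80 <- base_odds * 80 / (1 + base_odds * 80)
  expect_equal(p80, 0.8081, tolerance = 1e-4)
  spans <- make_level_spans(4000L, 4L)
  sim <- simulate_structure_index(spans, baseline_rate = 0.05,
                                  planted_or = c(1, 6, 22, 80), seed = 1L)
  expect_equal(sim$truth$p_by_level[4], p80, tolerance = 1e-12)
  lvl4 <- spans$span == 4L
  prop <- mean(span_key(spans)[lvl4] %in% sim$index$solved)
  ci <- stats::binom.test(round(prop * sum(lvl4)), sum(lvl4))$conf.int
  expect_true(p80 >= ci[1] && p80 <= ci[2])
  expect_error(simulate_structure_index(spans, planted_or = c(2, 6, 22, 80)))
})

test_that("sequence families have the planted divergence structure", {
  exact <- simulate_sequences(2L, 5L, divergence = 0, length = 60L, seed = 1L)
  expect_length(unique(exact$sequences[exact$labels == 1]), 1L)

  fam <- simulate_sequences(2L, 3L, divergence = 0.1, length = 200L, seed = 1L)
  within <- pairwise_identity(fam$sequences[[1]], fam$sequences[[2]])
  expect_gt(within, 0.75)
  across <- pairwise_identity(fam$sequences[[1]],
                              fam$sequences[[which(fam$labels == 2)[1]]])
  expect_lt(across, 0.4)   # unrelated centroids sit near the 1/20 baseline
})

test_that("ensemble simulation plants amplitudes and exact contact occupancy", {
  quiet <- simulate_ensemble(n_models = 10L, amplitude = rep(0, 100),
                             seed = 2L)
  prof <- rmsf(quiet$ensemble, fit_selection = quiet$truth$core)
  expect_true(all(prof$rmsf[quiet$truth$core] < 1e-10))

  sim <- simulate_ensemble(n_models = 40L, seed = 2L)
  cm <- contact_frequency(sim$ensemble, "A", "B", 8)
  expect_equal(cm$freq["30", "20"], sim$truth$contact$frac_exact)
  expect_equal(sim$truth$contact$frac_exact, 0.3)
})
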