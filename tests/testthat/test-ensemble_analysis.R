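rot_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

test_that("Kabsch superposition recovers rigid motions exactly", {
  set.seed(1)
  ref <- matrix(rnorm(30), 10, 3)
  sp0 <- kabsch_superpose(ref, ref)
  expect_equal(sp0$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp0$rotation, diag(3), tolerance = 1e-8)

  mov <- ref %*% t(rot_z(pi / 2)) + matrix(rep(c(3, -1, 2), each = 10), 10, 3)
  sp <- kabsch_superpose(ref, mov)
  expect_lt(sp$rmsd, 1e-8)
  expect_equal(apply_superposition(mov, sp), ref, tolerance = 1e-8)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-8)
  expect_equal(t(sp$rotation) %*% sp$rotation, diag(3), tolerance = 1e-8)

  expect_error(kabsch_superpose(ref[1:2, ], mov[1:2, ]), "3 points")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("Kabsch RMSD beats a random-rotation search", {
  # 4-point toy: one point displaced 1 A from an otherwise matching set
  ref <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(0, 0, 3))
  mov <- ref
  mov[4, ] <- mov[4, ] + c(0, 0, 1)
  sp <- kabsch_superpose(ref, mov)
  set.seed(8)
  opt <- oracle_opt_rmsd(ref, mov)
  expect_lte(sp$rmsd, opt + 1e-10)
  expect_equal(sp$rmsd, opt, tolerance = 1e-4)

  for (i in 1:5) {
    ref <- matrix(rnorm(30), 10, 3)
    mov <- matrix(rnorm(30), 10, 3)
    expect_lte(kabsch_superpose(ref, mov)$rmsd,
               oracle_min_rmsd(ref, mov, 1000L) + 1e-12)
  }
})

test_that("RMSF is zero for identical models and recovers a planted displacement", {
  base <- matrix(rnorm(60), 20, 3) * 5
  ens_id <- new_ensemble(rep("A", 20), 1:20,
                         array(rep(base, each = 4), c(4, 20, 3)))
  expect_true(all(rmsf(ens_id)$rmsf < 1e-10))
  expect_error(rmsf(new_ensemble(rep("A", 20), 1:20, base)), "at least 2")

  # large fixed core, one residue alternating +/- 1 A along x
  set.seed(2)
  core <- matrix(rnorm(150), 50, 3) * 8
  m <- 20L
  coords <- array(rep(core, each = m), c(m, 50, 3))
  coords[, 50, 1] <- core[50, 1] + rep(c(1, -1), m / 2)
  ens <- new_ensemble(rep("A", 50), 1:50, coords)
  prof <- rmsf(ens, fit_selection = 1:49)
  expect_equal(prof$rmsf[50], 1.0, tolerance = 0.02)
  expect_true(all(prof$rmsf[1:49] < 0.05))
})

test_that("RMSF is invariant under a global rigid motion of all conformations", {
  sim <- simulate_ensemble(n_models = 15L, n_res_a = 20L, n_res_b = 10L,
                           seed = 3L)
  ens <- sim$ensemble
  r <- rot_z(0.7)
  moved <- ens
  for (m in seq_len(n_models(ens))) {
    moved$coords[m, , ] <- ens$coords[m, , ] %*% t(r) +
      matrix(rep(c(5, 6, 7), each = dim(ens$coords)[2]), ncol = 3)
  }
  expect_equal(rmsf(moved)$rmsf, rmsf(ens)$rmsf, tolerance = 1e-6)
})

test_that("contact frequency counts models within the cutoff", {
  # two chains: residue pair within cutoff in 3 of 10 models
  m <- 10L
  a <- cbind(3.8 * (1:5), 0, 0)
  b <- cbind(3.8 * (1:4), 30, 0)
  coords <- array(0, c(m, 9, 3))
  for (k in seq_len(m)) coords[k, , ] <- rbind(a, b)
  coords[1:3, 8, ] <- matrix(rep(a[2, ] + c(0, 5, 0), 3), 3, byrow = TRUE)
  ens <- new_ensemble(rep(c("A", "B"), c(5, 4)), c(1:5, 1:4), coords)
  cm <- contact_frequency(ens, "A", "B", cutoff = 8)
  expect_equal(cm$freq["2", "3"], 0.3)
  expect_true(all(cm$freq >= 0 & cm$freq <= 1))
  expect_equal(cm$freq["5", "1"], 0)   # far apart in every model
  expect_error(contact_frequency(ens, "A", "C"), "not present")

  far <- new_ensemble(rep(c("A", "B"), c(5, 4)), c(1:5, 1:4),
                      array(rep(rbind(a, b), each = 2), c(2, 9, 3)))
  expect_true(all(contact_frequency(far, "A", "B", 8)$freq == 0))
})

test_that("TM-score is 1 for identity, rigid-invariant, and d0 follows the closed form", {
  expect_equal(tm_d0(21), 1.24 * 6^(1 / 3) - 1.8, tolerance = 1e-12)
  expect_equal(tm_d0(21), 0.4532295, tolerance = 1e-6)
  expect_error(tm_d0(15), ">= 16")

  set.seed(4)
  ref <- matrix(rnorm(60), 20, 3) * 4
  expect_equal(tm_score(ref, ref)$tm, 1.0, tolerance = 1e-12)

  moved <- ref %*% t(rot_z(1.1)) + matrix(rep(c(9, -4, 2), each = 20), 20, 3)
  expect_equal(tm_score(moved, ref)$tm, 1.0, tolerance = 1e-6)

  # invariance on a noisy model too
  noisy <- ref + matrix(rnorm(60, 0, 1), 20, 3)
  tm1 <- tm_score(noisy, ref)$tm
  tm2 <- tm_score(noisy %*% t(rot_z(2)) + 5, ref)$tm
  expect_equal(tm1, tm2, tolerance = 1e-6)

  expect_error(tm_score(ref, ref, correspondence = matrix(0, 0, 2)), "empty")
})

test_that("a model with every residue at distance d0 scores exactly 0.5", {
  fx <- d0_displacement_fixture()
  got <- tm_score(fx$model, fx$ref)
  expect_equal(got$tm, 0.5, tolerance = 1e-6)
})

test_that("TM-score decays in expectation as Gaussian noise grows", {
  set.seed(10)
  ref <- matrix(rnorm(120), 40, 3) * 4
  mean_tm <- vapply(c(0.5, 1, 2, 4), function(sigma) {
    mean(vapply(1:10, function(i) {
      tm_score(ref + matrix(rnorm(120, 0, sigma), 40, 3), ref)$tm
    }, 0))
  }, 0)
  expect_true(all(diff(mean_tm) < 0))
  expect_true(all(mean_tm <= 1))
})

test_that("fold consistency reports the fraction of models in the reference fold", {
  set.seed(6)
  ref <- matrix(rnorm(90), 30, 3) * 4
  coords <- array(0, c(4, 30, 3))
  for (m in 1:3) coords[m, , ] <- ref
  coords[4, , ] <- matrix(rnorm(90), 30, 3) * 4   # scrambled fold
  ens <- new_ensemble(rep("A", 30), 1:30, coords)
  fc <- fold_consistency(ens, ref)
  expect_equal(fc$fraction_above, 0.75)

  same <- new_ensemble(rep("A", 30), 1:30, array(rep(ref, each = 2), c(2, 30, 3)))
  expect_equal(fold_consistency(same, ref)$fraction_above, 1.0)

  # pure-noise ensembles score far below the fold threshold
  noise <- new_ensemble(rep("A", 30), 1:30,
                        array(rnorm(5 * 30 * 3) * 6, c(5, 30, 3)))
  expect_lt(fold_consistency(noise, ref)$mean_tm, 0.3)
})
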