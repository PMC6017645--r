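test_that("bound fraction matches the iterative mass-action oracle", {
  expect_equal(bound_fraction(0.3, 0, 1.3), 0)
  expect_equal(bound_fraction(0.3, 3.0, 1e-9), 1, tolerance = 1e-6)

  expect_equal(bound_fraction(0.3, 3.0, 1.3),
               oracle_bound_fraction(0.3, 3.0, 1.3), tolerance = 1e-10)
  expect_equal(bound_fraction(0.3, 1.2, 1.3),
               oracle_bound_fraction(0.3, 1.2, 1.3), tolerance = 1e-10)
  # the two worked cases are ~0.683 and ~0.450
  expect_equal(bound_fraction(0.3, 3.0, 1.3), 0.683, tolerance = 1e-3)
  expect_equal(bound_fraction(0.3, 1.2, 1.3), 0.450, tolerance = 1e-3)

  # random parameter sweep
  set.seed(21)
  for (i in 1:50) {
    P <- runif(1, 0.01, 5); L <- runif(1, 0, 20); K <- 10^runif(1, -3, 2)
    expect_equal(bound_fraction(P, L, K), oracle_bound_fraction(P, L, K),
                 tolerance = 1e-10)
  }

  expect_error(bound_fraction(0, 1, 1), "positive")
  expect_error(bound_fraction(0.3, 1, -1), "positive")
})

test_that("bound fraction is monotone and bounded over a parameter lattice", {
  P <- c(0.1, 0.3, 1)
  L <- seq(0, 10, by = 0.5)
  K <- c(0.1, 0.5, 1.3, 5)
  for (p in P) for (k in K) {
    f <- bound_fraction(p, L, k)
    expect_true(all(diff(f) >= -1e-12))            # non-decreasing in L
    expect_true(all(f <= pmin(1, L / p) + 1e-12))  # stoichiometric cap
  }
  for (p in P) for (l in L[-1]) {
    f <- bound_fraction(p, l, K)
    expect_true(all(diff(f) <= 1e-12))             # non-increasing in K
  }
})

test_that("responsive-residue selection applies the mean - 0.8 sd criterion", {
  r <- setNames(c(0.9, 0.8, 0.5, 0.4, 0.85, 0.95), 401:406)
  # direct computation: threshold = mean - 0.8 * sd(n-1) ~ 0.55
  thr <- mean(r) - 0.8 * sd(r)
  expect_equal(sort(select_responsive_residues(r)),
               sort(as.integer(names(r)[r < thr])))
  expect_identical(sort(select_responsive_residues(r)), c(403L, 404L))

  # all equal: sd = 0 and the strict inequality excludes everyone
  expect_length(select_responsive_residues(setNames(rep(0.7, 5), 1:5)), 0)

  # sigma_factor 0 selects exactly the residues strictly below the mean
  expect_identical(sort(select_responsive_residues(r, 0)),
                   sort(as.integer(names(r)[r < mean(r)])))

  expect_error(select_responsive_residues(c(a = 0.5)), "at least 2")
})

test_that("selection is invariant under increasing affine transforms", {
  set.seed(5)
  r <- setNames(runif(20, 0.2, 1), 400 + 1:20)
  base <- select_responsive_residues(r)
  for (ab in list(c(2, 0), c(0.5, 3), c(10, -4))) {
    expect_identical(select_responsive_residues(ab[1] * r + ab[2]), base)
  }
})

test_that("the global fit recovers K_D exactly on noiseless data", {
  sim <- gen_titration(kd_true = 1.3, seed = 1, noise_frac = 0)
  fit <- fit_kd(sim$series)
  expect_equal(fit$kd, 1.3, tolerance = 1e-6)
  expect_s3_class(fit, "kd_fit")
  expect_equal(unname(coef(fit)), fit$kd)
  # predictions reproduce the generating isotherm
  expect_equal(predict(fit), bound_fraction(0.3, titration_schedule(), 1.3),
               tolerance = 1e-6)
})

test_that("the global fit recovers K_D within 10% at 3% noise", {
  sim <- gen_titration(kd_true = 1.3, seed = 42, noise_frac = 0.03,
                       n_residues = 28)
  fit <- fit_kd(sim$series)
  expect_lt(abs(fit$kd - 1.3) / 1.3, 0.1)
})

test_that("fit preconditions and the degenerate no-binding case are handled", {
  sim <- gen_titration(seed = 2, noise_frac = 0)
  expect_error(fit_kd(sim$series, residues = 999), "999")

  short <- titration_series(0.3, c(0.5, 1), sim$series$intensities[, 1:2],
                            sim$series$i0, sim$series$residues)
  expect_error(fit_kd(short), "3 ligand")

  # strictly increasing intensities: no binding signal
  flat <- titration_series(0.3, c(0.5, 1, 2),
                           matrix(c(10, 11, 12), 1), 10, 401L)
  expect_warning(fit <- fit_kd(flat), "not identifiable")
  expect_equal(fit$kd, fit$interval[2])
})

test_that("Monte-Carlo K_D uncertainty is deterministic and sane", {
  sim <- gen_titration(seed = 3, noise_frac = 0.03)
  u1 <- kd_uncertainty_mc(sim$series, n_replicates = 100, seed = 9)
  u2 <- kd_uncertainty_mc(sim$series, n_replicates = 100, seed = 9)
  expect_identical(u1, u2)
  expect_gt(u1, 0)

  # zero intensity sd everywhere -> zero uncertainty
  s0 <- gen_titration(seed = 4, noise_frac = 0)
  expect_equal(kd_uncertainty_mc(s0$series, n_replicates = 100, seed = 1), 0)

  # missing sds are an error naming the residue
  s_bad <- sim$series
  s_bad$intensity_sd[2, 1] <- NA
  expect_error(kd_uncertainty_mc(s_bad, n_replicates = 100, seed = 1),
               as.character(s_bad$residues[2]))
  s_none <- titration_series(0.3, c(0.5, 1, 2), matrix(c(10, 8, 6), 1),
                             10, 401L)
  expect_error(kd_uncertainty_mc(s_none, n_replicates = 100, seed = 1),
               "uncertainties")
})

test_that("Monte-Carlo uncertainty tracks the regeneration spread", {
  # replicate-based sd within a factor of 2 of the spread of K_D over
  # independent noisy regenerations
  sim <- gen_titration(seed = 10, noise_frac = 0.03)
  mc_sd <- kd_uncertainty_mc(sim$series, n_replicates = 400, seed = 11)
  kds <- vapply(1:50, function(s)
    fit_kd(gen_titration(seed = 100 + s, noise_frac = 0.03)$series)$kd,
    numeric(1))
  expect_gt(mc_sd, sd(kds) / 2)
  expect_lt(mc_sd, sd(kds) * 2)
})
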