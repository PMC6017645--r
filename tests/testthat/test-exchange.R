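test_that("without exchange the spectrum is two Lorentzians of FWHM R2/pi", {
  m <- two_state_exchange(58, 21, p_bound = 0.5, k_off = 0)
  ls <- simulate_lineshape(m, resolution = 0.02)
  expect_identical(nrow(ls$peaks), 2L)
  expect_equal(sort(ls$peaks$position_hz), c(0, 58), tolerance = 1e-3)

  # peak heights p / R2 (Lorentzian maximum of a population-p line, up to
  # the far tail of the other line)
  expect_equal(sort(ls$peaks$height), rep(0.5 / 21, 2), tolerance = 0.01)

  # measured FWHM of each line equals R2/pi
  fwhm <- function(center) {
    half <- 0.5 / 21 / 2
    near <- abs(ls$freq_hz - center) < 5
    x <- ls$freq_hz[near]; y <- ls$intensity[near]
    above <- x[y >= half]
    diff(range(above))
  }
  expect_equal(fwhm(0), 21 / pi, tolerance = 0.02)
  expect_equal(fwhm(58), 21 / pi, tolerance = 0.02)
})

test_that("no-exchange peak heights are proportional to population / R2", {
  m <- two_state_exchange(100, r2_free = 10, r2_bound = 40,
                          p_bound = 0.3, k_off = 0)
  ls <- simulate_lineshape(m, resolution = 0.02)
  pk <- ls$peaks[order(ls$peaks$position_hz), ]
  expect_equal(pk$height[1], 0.7 / 10, tolerance = 0.01)  # free line
  expect_equal(pk$height[2], 0.3 / 40, tolerance = 0.01)  # bound line
})

test_that("fast exchange collapses to the population-weighted frequency", {
  p_b <- 0.4
  k_off <- 1e5 * (1 - p_b)  # k_ex = 1e5 >> 2*pi*58
  m <- two_state_exchange(58, 21, p_bound = p_b, k_off = k_off)
  ls <- simulate_lineshape(m, resolution = 0.05)
  expect_identical(nrow(ls$peaks), 1L)
  expect_equal(ls$peaks$position_hz, p_b * 58, tolerance = 0.1)
})

test_that("peak positions match the eigenvalue oracle in the weak-mixing regime", {
  # the eigenvalue imaginary parts are the exact resonance frequencies; the
  # absorption maximum coincides with them only while line overlap and
  # eigenvector mixing are negligible (narrow lines, k_ex well below the
  # separation), which is where the oracle equivalence is checked
  p_b <- bound_fraction(0.3, 3.0, 1.3)
  res <- 0.05
  for (k_off in c(0.5, 1, 2, 5)) {
    m <- two_state_exchange(58, 2, p_bound = p_b, k_off = k_off)
    ls <- simulate_lineshape(m, resolution = res)
    oracle <- oracle_peak_positions(58, 2, 2, p_b, k_off)
    got <- sort(ls$peaks$position_hz)
    expect_lt(max(abs(got - oracle)), 2 * res,
              label = sprintf("max position error at k_off = %g", k_off))
  }
})

test_that("lineshape integral is conserved across k_off", {
  p_b <- 0.68
  integrals <- vapply(c(0, 10, 30, 100, 1000), function(k) {
    ls <- simulate_lineshape(two_state_exchange(58, 21, p_bound = p_b,
                                                k_off = k))
    sum(ls$intensity) * ls$resolution
  }, numeric(1))
  # each unit-population absorption Lorentzian integrates to 1/2 in Hz
  expect_true(all(abs(integrals - 0.5) / 0.5 < 0.01))
  expect_lt(max(integrals) - min(integrals), 0.01 * 0.5)
})

test_that("grid peak positions converge to the eigenvalue oracle with resolution", {
  p_b <- 0.68
  m <- two_state_exchange(58, 2, p_bound = p_b, k_off = 1)
  oracle <- oracle_peak_positions(58, 2, 2, p_b, 1)
  err <- vapply(c(0.1, 0.01), function(res) {
    got <- sort(simulate_lineshape(m, resolution = res)$peaks$position_hz)
    max(abs(got - oracle))
  }, numeric(1))
  expect_lt(err[1], 2 * 0.1)
  expect_lt(err[2], 2 * 0.01)
})

test_that("free-peak shift is zero without exchange and monotone in k_off", {
  p_b <- bound_fraction(0.3, 3.0, 1.3)
  expect_equal(free_peak_shift(two_state_exchange(58, 21, p_bound = p_b,
                                                  k_off = 0)), 0)
  # up to ~35 s^-1 the free peak stays resolved at these linewidths
  ks <- c(1, 5, 10, 20, 30, 35)
  shifts <- vapply(ks, function(k)
    free_peak_shift(two_state_exchange(58, 21, p_bound = p_b, k_off = k)),
    numeric(1))
  expect_true(all(diff(shifts) >= -1e-6))
})

test_that("grid-based free-peak shift agrees with the eigenvalue oracle for narrow lines", {
  p_b <- bound_fraction(0.3, 3.0, 1.3)
  for (k_off in c(0.5, 2, 5)) {
    m <- two_state_exchange(58, 2, p_bound = p_b, k_off = k_off)
    grid_shift <- free_peak_shift(m, resolution = 0.01)
    oracle_shift <- min(abs(oracle_peak_positions(58, 2, 2, p_b, k_off)))
    expect_lt(abs(grid_shift - oracle_shift), 2 * 0.01 + 0.05,
              label = sprintf("shift error at k_off = %g", k_off))
  }
})

test_that("free-peak shift requires a resolved slow-exchange free peak", {
  expect_error(free_peak_shift(two_state_exchange(58, 21, p_bound = 0.5,
                                                  k_off = 500)),
               "slow-exchange")
})

test_that("maximum k_off search honours its tolerance contracts", {
  # tolerance -> 0 forces k_off -> 0
  small <- max_koff_for_shift(58, 21, 0.3, 3.0, 1.3, 0.01)
  expect_lt(small, 1)

  # monotone non-decreasing in the shift tolerance
  ks <- vapply(c(1, 2, 5, 10), function(tol)
    max_koff_for_shift(58, 21, 0.3, 3.0, 1.3, tol), numeric(1))
  expect_true(all(diff(ks) >= -0.2))

  # invariant to grid refinement within the bisection tolerance
  k1 <- max_koff_for_shift(58, 21, 0.3, 3.0, 1.3, 5, resolution = 0.05)
  k2 <- max_koff_for_shift(58, 21, 0.3, 3.0, 1.3, 5, resolution = 0.025)
  expect_lt(abs(k1 - k2), 0.1 + 0.2)
})

test_that("k_on derivation converts mM to M", {
  expect_equal(kon_from_koff_kd(30, 1.3), 30 / 1.3e-3)
  expect_equal(kon_from_koff_kd(0, 2.5), 0)
  expect_equal(kon_from_koff_kd(12.5, 0.625), 2e4)
  expect_error(kon_from_koff_kd(30, 0), "positive")
})

test_that("exchange-regime classification follows the shift-timescale rule", {
  expect_identical(classify_regime(0, 58), "slow")
  expect_identical(classify_regime(30 / (1 - 0.683), 58), "slow")
  expect_identical(classify_regime(1e5, 58), "fast")
  expect_identical(classify_regime(2 * pi * 58 * 2, 58), "intermediate")
  expect_error(classify_regime(-1, 58), "non-negative")
})

test_that("detailed balance holds in the exchange model", {
  m <- two_state_exchange(58, 21, p_bound = 0.683, k_off = 30)
  expect_equal((1 - m$p_bound) * m$k_fb, m$p_bound * m$k_off)
  expect_equal(m$k_ex, m$k_off / (1 - m$p_bound))
})
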