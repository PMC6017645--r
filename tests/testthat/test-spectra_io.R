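test_that("nine-point averaging matches direct 3x3 means", {
  g_const <- spectrum_grid(matrix(3.7, 7, 7), c(5, 10), c(10, 130))
  expect_equal(nine_point_intensity(g_const, c(4, 4)), 3.7)

  m <- matrix(0, 7, 7); m[4, 4] <- 9
  expect_equal(nine_point_intensity(spectrum_grid(m, c(5, 10), c(10, 130)),
                                    c(4, 4)), 1)

  # discretised 2D Gaussian peak vs loop oracle, at and off the maximum
  x <- seq(-3, 3, length.out = 21)
  gm <- exp(-outer(x^2, x^2, "+") / 0.8)
  g <- spectrum_grid(gm, c(5, 10), c(10, 130))
  expect_equal(nine_point_intensity(g, c(11, 11)), oracle_nine_point(gm, 11, 11))
  expect_equal(nine_point_intensity(g, c(9, 13)), oracle_nine_point(gm, 9, 13))

  expect_error(nine_point_intensity(g, c(1, 5)), "edge")
  expect_error(nine_point_intensity(g, c(5, 21)), "edge")
})

test_that("nine-point averaging is linear in the grid", {
  set.seed(11)
  m1 <- matrix(rnorm(64), 8); m2 <- matrix(rnorm(64), 8)
  hz <- c(5, 10); or <- c(10, 130)
  for (center in list(c(2, 2), c(4, 6), c(7, 7))) {
    lhs <- nine_point_intensity(spectrum_grid(2.5 * m1 - 1.5 * m2, hz, or),
                                center)
    rhs <- 2.5 * nine_point_intensity(spectrum_grid(m1, hz, or), center) -
      1.5 * nine_point_intensity(spectrum_grid(m2, hz, or), center)
    expect_equal(lhs, rhs)
  }
})

test_that("noise estimation uses the sample sd and honours preconditions", {
  g0 <- spectrum_grid(matrix(5, 10, 10), c(5, 10), c(10, 130))
  expect_equal(estimate_noise(g0, c(1, 4, 1, 4)), 0)

  # {-1, 1} repeated equally over 16 points vs the direct formula
  m <- matrix(rep(c(-1, 1), 8), 4, 4)
  g <- spectrum_grid(m, c(5, 10), c(10, 130))
  expect_equal(estimate_noise(g, c(1, 4, 1, 4)),
               sqrt(sum((as.vector(m) - mean(m))^2) / 15))

  # generator truth: Gaussian noise of known sd
  set.seed(42)
  gn <- spectrum_grid(matrix(rnorm(2500, sd = 0.05), 50), c(5, 10), c(10, 130))
  est <- estimate_noise(gn, c(1, 50, 1, 50))
  expect_lt(abs(est - 0.05) / 0.05, 0.2)

  expect_error(estimate_noise(g, c(1, 3, 1, 3)), "16")
  expect_error(estimate_noise(g, c(1, 8, 1, 4)), "outside")
})

test_that("noise estimate is invariant under a constant offset", {
  set.seed(7)
  m <- matrix(rnorm(400), 20)
  g1 <- spectrum_grid(m, c(5, 10), c(10, 130))
  g2 <- spectrum_grid(m + 123.4, c(5, 10), c(10, 130))
  expect_equal(estimate_noise(g1, c(1, 20, 1, 20)),
               estimate_noise(g2, c(1, 20, 1, 20)))
})

test_that("ppm/Hz conversion round-trips and peak centring rounds half away from zero", {
  g <- spectrum_grid(matrix(0, 64, 64), c(6, 12), c(10.5, 133), sf_mhz = 700)
  ppm <- c(9.73, 8.1, 7.02)
  expect_equal(hz_to_ppm(g, ppm_to_hz(g, ppm, 1), 1), ppm, tolerance = 1e-9)
  expect_equal(hz_to_ppm(g, ppm_to_hz(g, ppm, 2), 2), ppm, tolerance = 1e-9)

  # tie-breaking rounds half away from zero
  expect_identical(sbdnmr:::.round_half_away(c(4.5, -4.5, 2.3, -2.3)),
                   c(5, -5, 2, -2))
  # a position clearly nearest grid point 6 snaps to 6
  ppm_near <- hz_to_ppm(g, 5.1 * g$hz_per_point[1], 1)
  expect_identical(nearest_grid_point(g, ppm_near, g$origin_ppm[2])[1], 6L)
})

test_that("peak tables round-trip losslessly and reject bad input", {
  tab <- peak_table(residue_id = c(406L, 431L, 432L),
                    residue_name = c("ALA", "TYR", "SER"),
                    h_ppm = c(8.1234567891234, 7.5, 9.01),
                    n_ppm = c(120.5, 118.123456789, 129.9),
                    intensity = c(1.5e6, -2.3, 0.123456789012345),
                    intensity_sd = c(1e3, 0.1, 0),
                    condition = "ligand_mm=1.2")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_peak_table(tab, path)
  back <- read_peak_table(path)
  expect_identical(attr(back, "condition"), "ligand_mm=1.2")
  for (col in names(tab)) expect_identical(back[[col]], tab[[col]], label = col)

  # header-only file reads as an empty table
  writeLines(c("# condition: empty",
               paste(c("residue_id", "residue_name", "h_ppm", "n_ppm",
                       "intensity", "intensity_sd"), collapse = "\t")), path)
  expect_identical(nrow(read_peak_table(path)), 0L)

  # duplicated residue is named in the error
  writeLines(c(paste(c("residue_id", "residue_name", "h_ppm", "n_ppm",
                       "intensity", "intensity_sd"), collapse = "\t"),
               "432\tSER\t8.0\t120\t10\t1",
               "432\tSER\t8.1\t121\t11\t1"), path)
  expect_error(read_peak_table(path), "432")

  # malformed numeric field carries the line number
  writeLines(c(paste(c("residue_id", "residue_name", "h_ppm", "n_ppm",
                       "intensity", "intensity_sd"), collapse = "\t"),
               "406\tALA\t8.0\tnot_a_number\t10\t1"), path)
  expect_error(read_peak_table(path), "line 2")
})

test_that("spectral grids round-trip through the text format", {
  set.seed(3)
  g <- spectrum_grid(matrix(rnorm(35), 5, 7), c(5.5, 11.25), c(10.2, 131.7),
                     sf_mhz = 700)
  path <- withr::local_tempfile(fileext = ".txt")
  write_spectrum_grid(g, path)
  back <- read_spectrum_grid(path)
  expect_equal(back$intensities, g$intensities, ignore_attr = TRUE)
  expect_equal(back$hz_per_point, g$hz_per_point)
  expect_equal(back$origin_ppm, g$origin_ppm)
  expect_equal(back$sf_mhz, g$sf_mhz)
})
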