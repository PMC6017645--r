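toy_model <- function(coords, resno = seq_len(nrow(coords)) + 400L,
                      chain = "A", elety = "CA") {
  data.frame(resno = resno, resid = "ALA", chain = chain, elety = elety,
             x = coords[, 1], y = coords[, 2], z = coords[, 3],
             stringsAsFactors = FALSE)
}

test_that("multi-model and single-model PDB files parse correctly", {
  path <- withr::local_tempfile(fileext = ".pdb")
  ens2 <- structure_ensemble(list(
    toy_model(rbind(c(0, 0, 0), c(3, 4, 0))),
    toy_model(rbind(c(0, 0, 0), c(0, 6, 0)))), source_id = "toy2")
  write_pdb_ensemble(ens2, path)
  back <- read_pdb_ensemble(path)
  expect_length(back$models, 2L)
  expect_equal(ca_distance(back$models[[1]], 401, 402), 5)
  expect_equal(ca_distance(back$models[[2]], 401, 402), 6)

  ens1 <- structure_ensemble(list(toy_model(rbind(c(0, 0, 0), c(3, 4, 0)))),
                             source_id = "xtal")
  write_pdb_ensemble(ens1, path)
  expect_length(read_pdb_ensemble(path)$models, 1L)
})

test_that("PDB round-trip preserves coordinates to 1e-3 A", {
  ens <- gen_ensemble(template_structure(30), n_models = 3, jitter_sd = 0.7,
                      seed = 4)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_ensemble(ens, path)
  back <- read_pdb_ensemble(path)
  for (m in 1:3) {
    expect_equal(back$models[[m]]$x, ens$models[[m]]$x, tolerance = 1e-3)
    expect_equal(back$models[[m]]$y, ens$models[[m]]$y, tolerance = 1e-3)
    expect_equal(back$models[[m]]$z, ens$models[[m]]$z, tolerance = 1e-3)
    expect_identical(back$models[[m]]$resno, ens$models[[m]]$resno)
    expect_identical(back$models[[m]]$elety, ens$models[[m]]$elety)
  }
})

test_that("malformed PDB files produce parse errors", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HEADER    NOTHING", "END"), path)
  expect_error(read_pdb_ensemble(path), "ATOM")

  writeLines(c("MODEL        1",
               "ATOM      1  CA  ALA A 401       0.000   0.000   0.000  1.00  0.00           C",
               "END"), path)
  expect_error(read_pdb_ensemble(path), "unterminated")
})

test_that("Calpha distances are symmetric and match the arithmetic oracle", {
  set.seed(6)
  co <- matrix(rnorm(15, sd = 10), 5)
  model <- toy_model(co)
  expect_equal(ca_distance(model, 401, 401), 0)
  expect_equal(ca_distance(model, 402, 404), ca_distance(model, 404, 402))
  d_oracle <- sqrt(sum((co[2, ] - c(co[4, ]))^2))
  expect_equal(ca_distance(model, 402, 404), d_oracle)

  expect_error(ca_distance(model, 401, 999), "999")
})

test_that("distances are invariant under rigid rotation and translation", {
  set.seed(9)
  model <- toy_model(matrix(rnorm(30, sd = 8), 10))
  d0 <- ca_distance(model, 403, 408)
  for (i in 1:5) {
    tr <- transform_model(model, random_rotation(), rnorm(3, sd = 20))
    expect_equal(ca_distance(tr, 403, 408), d0, tolerance = 1e-9)
  }
})

test_that("ensemble distance statistics match brute-force two-pass values", {
  ens <- structure_ensemble(list(
    toy_model(rbind(c(0, 0, 0), c(4, 0, 0))),
    toy_model(rbind(c(0, 0, 0), c(6, 0, 0)))), source_id = "toy")
  ds <- ensemble_distance(ens, 401, 402)
  expect_equal(ds$mean, 5)
  expect_equal(ds$sd, sqrt(2))
  expect_identical(ds$n_models, 2L)

  # identical models: zero spread
  same <- structure_ensemble(rep(list(toy_model(rbind(c(0, 0, 0), c(3, 4, 0)))), 5),
                             source_id = "same")
  expect_equal(ensemble_distance(same, 401, 402)$sd, 0)

  # single model: sd 0 by convention, flagged
  single <- structure_ensemble(list(toy_model(rbind(c(0, 0, 0), c(3, 4, 0)))),
                               source_id = "one")
  ds1 <- ensemble_distance(single, 401, 402)
  expect_true(ds1$single_model)
  expect_equal(ds1$sd, 0)

  # brute-force mean/sd over a jittered ensemble
  ens_j <- gen_ensemble(template_structure(20), n_models = 12,
                        jitter_sd = 0.4, seed = 13)
  ds_all <- ensemble_distance(ens_j, 405, 415, models = 1:12)
  oracle <- oracle_mean_sd(ds_all$values)
  expect_equal(ds_all$mean, oracle$mean, tolerance = 1e-9)
  expect_equal(ds_all$sd, oracle$sd, tolerance = 1e-9)

  # the default subset is the first 10 models
  ds_def <- ensemble_distance(ens_j, 405, 415)
  expect_identical(ds_def$n_models, 10L)
  expect_equal(ds_def$values,
               vapply(1:10, function(m)
                 ca_distance(ens_j$models[[m]], 405, 415), numeric(1)))
})

test_that("missing residues in a selected model name the model index", {
  m_ok <- toy_model(rbind(c(0, 0, 0), c(3, 4, 0)))
  m_bad <- m_ok[1, ]
  ens <- structure_ensemble(list(m_ok, m_bad), source_id = "broken")
  expect_error(ensemble_distance(ens, 401, 402, chain = "A", models = 1:2),
               "model 2")
})

test_that("ensemble comparison recovers constructed distance offsets", {
  tmpl <- template_structure(60)
  pairs <- rbind(c(416L, 443L), c(442L, 446L), c(421L, 439L))
  ens_a <- gen_ensemble(tmpl, n_models = 10, jitter_sd = 0.15, seed = 31)

  # identical ensembles: all differences zero
  cmp0 <- compare_ensembles(ens_a, ens_a, pairs)
  expect_true(all(cmp0$diff_mean == 0))

  # rigid translation leaves all distances unchanged
  ens_t <- structure_ensemble(lapply(ens_a$models, transform_model,
                                     shift = c(10, 0, 0)),
                              source_id = "shifted")
  cmp_t <- compare_ensembles(ens_a, ens_t, pairs)
  expect_true(all(abs(cmp_t$diff_mean) < 1e-9))

  # a constructed displacement of residue 443 changes only its pair, by a
  # predictable amount
  lab <- unlist(tmpl[tmpl$resno == 443L & tmpl$elety == "CA", c("x", "y", "z")])
  oth <- unlist(tmpl[tmpl$resno == 416L & tmpl$elety == "CA", c("x", "y", "z")])
  u <- (lab - oth); u <- u / sqrt(sum(u^2))
  ens_b <- gen_ensemble(tmpl, n_models = 10, jitter_sd = 0.15,
                        residue_shifts = list(`443` = 5 * u), seed = 32)
  cmp <- compare_ensembles(ens_a, ens_b, pairs)
  jitter_tol <- 4 * 0.15
  expect_equal(cmp$diff_mean[1], -5, tolerance = 0.2)
  expect_lt(abs(cmp$diff_mean[3]), jitter_tol)

  # unresolvable pairs are reported as such
  expect_error(compare_ensembles(ens_a, ens_b, rbind(c(416L, 999L))), "999")
})
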