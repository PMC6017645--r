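# Seeded synthetic-data generators.
#
# Each generator is a pure function of its arguments including the mandatory
# seed (same seed, same bytes), emulates the statistical structure one stage
# of the analysis assumes, and returns the generating truth alongside the
# data so every fitting routine has a parameter-recovery test. Noise is
# additive Gaussian on intensities, expressed as a fraction of the reference
# intensity. When an output directory is given the data are written in the
# same TSV/PDB dialects the analysis stages read, with a truth sidecar in
# YAML.

#' Ligand concentration schedule of the reference titration
#'
#' The seven-point peptide titration schedule (mM) into 0.3 mM protein.
#' @return numeric vector of ligand concentrations in mM.
#' @export
titration_schedule <- function() c(0.075, 0.15, 0.30, 0.60, 1.2, 3.0, 6.0)

.write_truth <- function(out_dir, name, truth) {
  yaml::write_yaml(truth, file.path(out_dir, paste0(name, "_truth.yaml")))
}

#' Generate a synthetic HSQC titration
#'
#' Free-state intensities decay with the bound fraction under slow exchange:
#' \code{I_r(L) = I0_r * (1 - f_bound(P, L, kd_true)) + noise}, with
#' additive Gaussian noise of sd \code{noise_frac * I0_r}. The observed
#' zero-ligand reference carries the same noise. Optional unresponsive
#' residues keep \code{I = I0 + noise} at every point.
#'
#' @param kd_true generating dissociation constant (mM); default 1.3.
#' @param protein_mm total protein (mM); default 0.3.
#' @param ligand_mm titration points (mM); default
#'   \code{\link{titration_schedule}}.
#' @param n_residues number of responsive residues; default 28.
#' @param n_unresponsive residues with no binding response; default 0.
#' @param noise_frac Gaussian noise sd as a fraction of I0; default 0.03.
#' @param seed RNG seed (mandatory).
#' @param i0_range range of the per-residue reference intensities.
#' @param out_dir if given, peak tables (one per titration point, plus the
#'   zero-ligand reference), a manifest TSV and a truth YAML are written
#'   there.
#' @return a list with \code{series} (a \code{\link{titration_series}}),
#'   \code{truth} (kd_true, per-residue I0) and, when written,
#'   \code{manifest} (the manifest path).
#' @examples
#' sim <- gen_titration(seed = 7)
#' fit_kd(sim$series)
#' @export
gen_titration <- function(kd_true = 1.3, protein_mm = 0.3,
                          ligand_mm = titration_schedule(),
                          n_residues = 28, n_unresponsive = 0,
                          noise_frac = 0.03, seed,
                          i0_range = c(5e5, 2e6), out_dir = NULL) {
  if (missing(seed)) stop("an explicit seed is required")
  if (n_residues < 1) stop("n_residues must be >= 1")
  if (noise_frac < 0) stop("noise_frac must be non-negative")
  set.seed(seed)
  n_tot <- n_residues + n_unresponsive
  residues <- 400L + seq_len(n_tot)
  responsive <- c(rep(TRUE, n_residues), rep(FALSE, n_unresponsive))
  i0_true <- runif(n_tot, i0_range[1], i0_range[2])
  f <- bound_fraction(protein_mm, ligand_mm, kd_true)
  clean <- outer(i0_true, 1 - f)
  clean[!responsive, ] <- i0_true[!responsive]
  sd_mat <- matrix(noise_frac * i0_true, n_tot, length(ligand_mm))
  ints <- clean + matrix(rnorm(length(clean)), n_tot) * sd_mat
  i0_obs <- i0_true + rnorm(n_tot) * noise_frac * i0_true
  h_ppm <- runif(n_tot, 7, 10)
  n_ppm <- runif(n_tot, 105, 130)

  series <- titration_series(protein_mm, ligand_mm, ints, i0_obs, residues,
                             intensity_sd = sd_mat,
                             i0_sd = noise_frac * i0_true)
  out <- list(series = series,
              truth = list(kd_true = kd_true, protein_mm = protein_mm,
                           i0 = setNames(i0_true, residues),
                           responsive = setNames(responsive, residues),
                           noise_frac = noise_frac, seed = seed))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    conc_all <- c(0, ligand_mm)
    paths <- character(length(conc_all))
    for (j in seq_along(conc_all)) {
      int_j <- if (j == 1L) i0_obs else ints[, j - 1L]
      sd_j <- noise_frac * i0_true
      tab <- peak_table(residues, "XXX", h_ppm, n_ppm, int_j, sd_j,
                        condition = sprintf("ligand_mm=%g", conc_all[j]))
      paths[j] <- file.path(out_dir, sprintf("titration_L%g.tsv", conc_all[j]))
      write_peak_table(tab, paths[j])
    }
    manifest <- file.path(out_dir, "titration_manifest.tsv")
    writeLines(c("ligand_mm\tpath",
                 paste(conc_all, basename(paths), sep = "\t")), manifest)
    .write_truth(out_dir, "titration", out$truth[c("kd_true", "protein_mm",
                                                   "noise_frac", "seed")])
    out$manifest <- manifest
  }
  out
}

#' Generate a synthetic relaxation decay series
#'
#' \code{I(t) = A * exp(-rate_true * t / 1000) + noise} at the given delay
#' schedule (ms, duplicates preserved), noise sd \code{noise_frac * A}.
#'
#' @param rate_true generating rate (s^-1).
#' @param delays_ms delay schedule; default \code{\link{delays_r1}()}.
#' @param n_residues number of residues (all share \code{rate_true});
#'   default 1.
#' @param noise_frac noise sd as a fraction of the amplitude; default 0.02.
#' @param amplitude reference amplitude A; default 100.
#' @param kind \code{"R1"} or \code{"R2"} label.
#' @param seed RNG seed (mandatory).
#' @param out_dir optional output directory (peak table per delay, manifest,
#'   truth YAML).
#' @return list with \code{series} (a \code{\link{relaxation_series}}) and
#'   \code{truth}.
#' @export
gen_relaxation <- function(rate_true, delays_ms = delays_r1(),
                           n_residues = 1, noise_frac = 0.02,
                           amplitude = 100, kind = "R1", seed,
                           out_dir = NULL) {
  if (missing(seed)) stop("an explicit seed is required")
  if (noise_frac < 0) stop("noise_frac must be non-negative")
  set.seed(seed)
  residues <- 400L + seq_len(n_residues)
  clean <- matrix(amplitude * exp(-rate_true * delays_ms / 1000),
                  n_residues, length(delays_ms), byrow = TRUE)
  ints <- clean + matrix(rnorm(length(clean), sd = noise_frac * amplitude),
                         n_residues)
  series <- relaxation_series(delays_ms, ints, residues, kind = kind)
  out <- list(series = series,
              truth = list(rate_true = rate_true, amplitude = amplitude,
                           noise_frac = noise_frac, seed = seed))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- character(length(delays_ms))
    for (j in seq_along(delays_ms)) {
      tab <- peak_table(residues, "XXX", rep(8, n_residues),
                        rep(120, n_residues), ints[, j],
                        noise_frac * amplitude,
                        condition = sprintf("delay_ms=%g", delays_ms[j]))
      paths[j] <- file.path(out_dir, sprintf("relax_%s_%02d.tsv", kind, j))
      write_peak_table(tab, paths[j])
    }
    manifest <- file.path(out_dir, sprintf("relax_%s_manifest.tsv", kind))
    writeLines(c("delay_ms\tpath",
                 paste(delays_ms, basename(paths), sep = "\t")), manifest)
    .write_truth(out_dir, paste0("relax_", kind),
                 out$truth[c("rate_true", "amplitude", "noise_frac", "seed")])
    out$manifest <- manifest
  }
  out
}

# PRE forward model: Gamma2 = K / r^6; ratio = R2d/(R2d+Gamma2) * exp(-Gamma2*t)
# K is calibrated so that ratio(r_anchor) = ratio_anchor at the given R2 and
# evolution time; with the defaults (R2 = 21 s^-1, t = 1 ms, anchor 10 A ->
# 0.02) the model also gives ratio(25 A) ~ 0.90, i.e. complete bleaching
# inside ~10 A and detectable attenuation out to ~25 A.
.pre_ratio_model <- function(r, k_scale, r2_dia, t_evol_s) {
  g2 <- k_scale / r^6
  r2_dia / (r2_dia + g2) * exp(-g2 * t_evol_s)
}

.pre_calibrate <- function(r2_dia, t_evol_s, r_anchor = 10,
                           ratio_anchor = 0.02) {
  f <- function(log10_k)
    .pre_ratio_model(r_anchor, 10^log10_k, r2_dia, t_evol_s) - ratio_anchor
  10^uniroot(f, c(0, 20), tol = 1e-12)$root
}

#' Generate synthetic paired paramagnetic/diamagnetic peak tables
#'
#' Distances from the spin-label site (CB atom, CA if absent) to each
#' residue's CA are measured on model 1 of the ensemble and turned into PRE
#' intensity ratios through an r^-6 law:
#' \eqn{\Gamma_2 = K/r^6}, \eqn{ratio = R_2/(R_2+\Gamma_2)\,e^{-\Gamma_2 t}},
#' with \eqn{K} calibrated so a residue 10 A from the label has ratio 0.02
#' (complete bleaching) and, under the defaults, a residue at 25 A has ratio
#' about 0.9 (attenuation detectable to roughly 25 A). Gaussian noise of sd
#' \code{noise_frac * i_dia} is added to both spectra.
#'
#' @param ensemble a \code{structure_ensemble}.
#' @param label_residue residue number carrying the spin label.
#' @param r2_dia diamagnetic transverse relaxation rate (s^-1); default 21.
#' @param t_evol_ms effective evolution time (ms); default 1.
#' @param noise_frac noise sd as a fraction of the diamagnetic intensity;
#'   default 0.02.
#' @param i_dia diamagnetic reference intensity; default 1e6.
#' @param chain chain id; default first chain of model 1.
#' @param condition condition label; default "apo".
#' @param seed RNG seed (mandatory).
#' @param out_dir optional output directory.
#' @return list with \code{para} and \code{dia} (\code{\link{peak_table}}s),
#'   and \code{truth} (per-residue distance and noise-free ratio).
#' @export
gen_pre <- function(ensemble, label_residue, r2_dia = 21, t_evol_ms = 1,
                    noise_frac = 0.02, i_dia = 1e6, chain = NULL,
                    condition = "apo", seed, out_dir = NULL) {
  if (missing(seed)) stop("an explicit seed is required")
  stopifnot(inherits(ensemble, "structure_ensemble"))
  model <- ensemble$models[[1]]
  if (is.null(chain)) chain <- model$chain[1]
  mc <- model[model$chain == chain, ]
  lab <- mc[mc$resno == label_residue & mc$elety == "CB", ]
  if (!nrow(lab)) lab <- mc[mc$resno == label_residue & mc$elety == "CA", ]
  if (!nrow(lab))
    stop(sprintf("label residue %d not found in chain %s", label_residue, chain))
  lab_xyz <- as.numeric(lab[1, c("x", "y", "z")])
  ca <- mc[mc$elety == "CA", ]
  r <- sqrt((ca$x - lab_xyz[1])^2 + (ca$y - lab_xyz[2])^2 +
            (ca$z - lab_xyz[3])^2)
  r <- pmax(r, 1e-3)  # the labelled residue itself: r -> 0, ratio -> 0
  k_scale <- .pre_calibrate(r2_dia, t_evol_ms / 1000)
  ratio_true <- .pre_ratio_model(r, k_scale, r2_dia, t_evol_ms / 1000)

  set.seed(seed)
  n <- nrow(ca)
  i_dia_obs <- i_dia + rnorm(n, sd = noise_frac * i_dia)
  i_para_obs <- ratio_true * i_dia + rnorm(n, sd = noise_frac * i_dia)
  dia <- peak_table(ca$resno, ca$resid, runif(n, 7, 10), runif(n, 105, 130),
                    i_dia_obs, noise_frac * i_dia,
                    condition = paste0(condition, "_dia"))
  para <- peak_table(ca$resno, ca$resid, dia$h_ppm, dia$n_ppm,
                     i_para_obs, noise_frac * i_dia,
                     condition = paste0(condition, "_para"))
  out <- list(para = para, dia = dia,
              truth = list(label_residue = label_residue,
                           distance = setNames(r, ca$resno),
                           ratio_true = setNames(ratio_true, ca$resno),
                           noise_sd = noise_frac * i_dia, seed = seed))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_peak_table(para, file.path(out_dir, sprintf("pre_%s_para.tsv", condition)))
    write_peak_table(dia, file.path(out_dir, sprintf("pre_%s_dia.tsv", condition)))
    .write_truth(out_dir, paste0("pre_", condition),
                 list(label_residue = label_residue,
                      noise_sd = noise_frac * i_dia, seed = seed))
  }
  out
}

#' Deterministic template structure for ensemble generation
#'
#' A single-model synthetic polypeptide trace laid out on an ideal helix
#' (2.3 A radius, 1.5 A rise, 100 degrees per residue) with CA atoms and
#' radially displaced CB pseudo-atoms. Purely geometric; it stands in for a
#' folded chain wherever tests need known coordinates.
#'
#' @param n_residues chain length.
#' @param first_residue author number of the first residue; default 401.
#' @param chain chain id.
#' @return a model data frame usable as \code{\link{gen_ensemble}} template.
#' @export
template_structure <- function(n_residues, first_residue = 401L,
                               chain = "A") {
  i <- seq_len(n_residues)
  theta <- i * 100 * pi / 180
  ca <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
  cb <- cbind(3.8 * cos(theta), 3.8 * sin(theta), 1.5 * i)
  resno <- first_residue - 1L + i
  data.frame(resno = rep(resno, each = 2L),
             resid = "ALA", chain = chain,
             elety = rep(c("CA", "CB"), times = n_residues),
             x = as.vector(rbind(ca[, 1], cb[, 1])),
             y = as.vector(rbind(ca[, 2], cb[, 2])),
             z = as.vector(rbind(ca[, 3], cb[, 3])),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic structural ensemble
#'
#' Models are the template plus isotropic Gaussian coordinate jitter;
#' optional constructed displacements move whole named residues by stated
#' vectors in every model, so the generating pairwise-distance truths are
#' known exactly.
#'
#' @param template a model data frame; default
#'   \code{template_structure(160)}.
#' @param n_models number of models; default 10.
#' @param jitter_sd per-coordinate Gaussian jitter sd (Angstrom).
#' @param residue_shifts optional named list: residue number (as character)
#'   -> length-3 displacement vector applied to all atoms of that residue.
#' @param seed RNG seed (mandatory).
#' @param source_id ensemble identifier; default
#'   \code{"synthetic-ensemble"}.
#' @param out_dir optional output directory (PDB file + truth YAML).
#' @return a \code{structure_ensemble}.
#' @export
gen_ensemble <- function(template = template_structure(160), n_models = 10,
                         jitter_sd = 0.5, residue_shifts = NULL, seed,
                         source_id = "synthetic-ensemble", out_dir = NULL) {
  if (missing(seed)) stop("an explicit seed is required")
  if (jitter_sd < 0) stop("jitter_sd must be non-negative")
  base <- template
  if (!is.null(residue_shifts)) {
    for (res in names(residue_shifts)) {
      idx <- base$resno == as.integer(res)
      if (!any(idx)) stop(sprintf("residue %s not in the template", res))
      v <- residue_shifts[[res]]
      base$x[idx] <- base$x[idx] + v[1]
      base$y[idx] <- base$y[idx] + v[2]
      base$z[idx] <- base$z[idx] + v[3]
    }
  }
  set.seed(seed)
  models <- lapply(seq_len(n_models), function(m) {
    mod <- base
    n <- nrow(mod)
    mod$x <- mod$x + rnorm(n, sd = jitter_sd)
    mod$y <- mod$y + rnorm(n, sd = jitter_sd)
    mod$z <- mod$z + rnorm(n, sd = jitter_sd)
    mod
  })
  ens <- structure_ensemble(models, source_id = source_id)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_pdb_ensemble(ens, file.path(out_dir, paste0(source_id, ".pdb")))
    .write_truth(out_dir, source_id,
                 list(n_models = n_models, jitter_sd = jitter_sd,
                      residue_shifts = residue_shifts, seed = seed))
  }
  ens
}

#' Generate a synthetic single-site ITC run
#'
#' Per-injection heats from the single-site n = 1 model with stepwise
#' overflow dilution (\code{\link{itc_heats}}) plus additive Gaussian noise,
#' under the reference protocol: 1.5 µL injections of 5 mM ligand into a
#' 200 µL cell of 0.1 mM protein.
#'
#' @param kd_true generating dissociation constant (mM); default 1.5.
#' @param dh_true generating enthalpy (cal/mol); default -1000.
#' @param n_injections number of injections; default 25.
#' @param injection_ul injection volume (µL); default 1.5.
#' @param syringe_mm,cell_mm,cell_ul protocol concentrations/volumes.
#' @param noise_ucal additive heat noise sd (µcal); default 0.02.
#' @param seed RNG seed (mandatory).
#' @param out_dir optional output directory (heat table + truth YAML).
#' @return list with \code{experiment} (an \code{\link{itc_experiment}} with
#'   observed heats) and \code{truth}.
#' @export
gen_itc <- function(kd_true = 1.5, dh_true = -1000, n_injections = 25,
                    injection_ul = 1.5, syringe_mm = 5, cell_mm = 0.1,
                    cell_ul = 200, noise_ucal = 0.02, seed, out_dir = NULL) {
  if (missing(seed)) stop("an explicit seed is required")
  if (noise_ucal < 0) stop("noise_ucal must be non-negative")
  exp0 <- itc_experiment(rep(injection_ul, n_injections), syringe_mm,
                         cell_mm, cell_ul)
  clean <- itc_heats(exp0, kd_true, dh_true)
  set.seed(seed)
  heats <- clean + rnorm(n_injections, sd = noise_ucal)
  exp0$heats_ucal <- heats
  out <- list(experiment = exp0,
              truth = list(kd_true = kd_true, dh_true = dh_true,
                           noise_ucal = noise_ucal, seed = seed))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_itc_table(exp0, file.path(out_dir, "itc_heats.tsv"))
    .write_truth(out_dir, "itc", out$truth)
  }
  out
}
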