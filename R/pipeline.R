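# Run-level entry points: read the on-disk dialects, run one analysis stage,
# and write TSV reports plus a YAML run manifest (package version, resolved
# configuration with its checksum, input checksums). Every stochastic stage
# takes an explicit seed; existing outputs are never overwritten without
# force = TRUE.

.check_out <- function(paths, force) {
  exists <- file.exists(paths)
  if (any(exists) && !force)
    stop(sprintf("output '%s' already exists (use force = TRUE to overwrite)",
                 paths[exists][1]))
  invisible(paths)
}

.config_md5 <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a run manifest
#'
#' Records the package version, the resolved configuration and its MD5, and
#' MD5 checksums of all input files, as YAML next to the stage's report.
#'
#' @param out_dir output directory.
#' @param stage stage name.
#' @param config named list of resolved parameters.
#' @param inputs character vector of input file paths.
#' @return the manifest path, invisibly.
#' @export
write_run_manifest <- function(out_dir, stage, config, inputs = character(0)) {
  manifest <- list(
    package = "sbdnmr",
    version = as.character(packageVersion("sbdnmr")),
    stage = stage,
    config = config,
    config_md5 = .config_md5(config),
    inputs = if (length(inputs))
      as.list(setNames(unname(tools::md5sum(inputs)), inputs)) else list())
  path <- file.path(out_dir, paste0(stage, "_manifest.yaml"))
  yaml::write_yaml(manifest, path)
  invisible(path)
}

# titration manifest: TSV 'ligand_mm\tpath' (paths relative to the manifest)
.read_titration_manifest <- function(manifest, protein_mm) {
  tab <- read.table(manifest, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  tab$path <- ifelse(file.exists(tab$path), tab$path,
                     file.path(dirname(manifest), tab$path))
  missing <- !file.exists(tab$path)
  if (any(missing))
    stop(sprintf("input '%s' listed in the manifest does not exist",
                 tab$path[missing][1]))
  tab <- tab[order(tab$ligand_mm), ]
  if (tab$ligand_mm[1] != 0)
    stop("the manifest must include a zero-ligand reference table")
  tabs <- lapply(tab$path, read_peak_table)
  ref <- tabs[[1]]
  residues <- ref$residue_id
  ints <- sapply(tabs[-1], function(t) t$intensity[match(residues, t$residue_id)])
  sds <- sapply(tabs[-1], function(t) t$intensity_sd[match(residues, t$residue_id)])
  list(series = titration_series(protein_mm, tab$ligand_mm[-1],
                                 ints, ref$intensity, residues,
                                 intensity_sd = sds, i0_sd = ref$intensity_sd),
       paths = tab$path)
}

#' Run the titration K_D analysis on peak tables
#'
#' Reads a titration manifest (TSV with columns \code{ligand_mm} and
#' \code{path}, one peak table per concentration including the zero-ligand
#' reference), selects responsive residues, fits the global \eqn{K_D} with
#' Monte-Carlo uncertainty, and writes \code{kd_report.tsv} plus a run
#' manifest to \code{out_dir}.
#'
#' @param manifest path to the manifest TSV.
#' @param protein_mm total protein concentration (mM).
#' @param select_sigma sigma multiple of the selection criterion; default 0.8.
#' @param ref_ligand_mm reference point of the selection ratio; default 1.2.
#' @param mc Monte-Carlo replicates; default 1000.
#' @param seed RNG seed (mandatory when \code{mc > 0}).
#' @param out_dir output directory (created if needed).
#' @param force overwrite existing outputs.
#' @return the \code{\link{fit_kd}} object, invisibly.
#' @export
run_fit_kd <- function(manifest, protein_mm, select_sigma = 0.8,
                       ref_ligand_mm = 1.2, mc = 1000, seed = NULL,
                       out_dir = ".", force = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- file.path(out_dir, "kd_report.tsv")
  .check_out(report, force)
  inp <- .read_titration_manifest(manifest, protein_mm)
  ratios <- intensity_ratios(inp$series, ref_ligand_mm)
  selected <- select_responsive_residues(ratios, select_sigma)
  if (!length(selected)) {
    warning("selection criterion matched no residues; fitting all residues")
    selected <- inp$series$residues
  }
  fit <- fit_kd(inp$series, selected, mc_replicates = mc, seed = seed)
  lines <- c(sprintf("kd_mm\t%.6g", fit$kd),
             sprintf("kd_sd_mm\t%.6g", fit$kd_sd),
             sprintf("n_selected\t%d", length(selected)),
             sprintf("selected_residues\t%s", paste(selected, collapse = ",")),
             sprintf("rss\t%.6g", fit$rss))
  writeLines(c("quantity\tvalue", lines), report)
  write_run_manifest(out_dir, "fit_kd",
                     list(manifest = manifest, protein_mm = protein_mm,
                          select_sigma = select_sigma,
                          ref_ligand_mm = ref_ligand_mm, mc = mc, seed = seed),
                     inputs = c(manifest, inp$paths))
  invisible(fit)
}

#' Run the maximum-k_off bound and k_on derivation
#'
#' Computes \code{\link{max_koff_for_shift}} at the given exchange and
#' concentration parameters, derives \code{k_on = k_off / K_D} and the
#' exchange-regime class, and writes \code{koff_report.tsv}.
#'
#' @param delta_nu_hz,r2,protein_mm,ligand_mm,kd_mm,tol_hz model parameters
#'   (see \code{\link{max_koff_for_shift}}).
#' @param out_dir,force as in \code{\link{run_fit_kd}}.
#' @return a list with \code{max_koff}, \code{kon}, \code{p_bound},
#'   \code{k_ex} and \code{regime}, invisibly.
#' @export
run_koff_bound <- function(delta_nu_hz, r2, protein_mm, ligand_mm, kd_mm,
                           tol_hz, out_dir = ".", force = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- file.path(out_dir, "koff_report.tsv")
  .check_out(report, force)
  koff <- max_koff_for_shift(delta_nu_hz, r2, protein_mm, ligand_mm, kd_mm,
                             tol_hz)
  p_b <- bound_fraction(protein_mm, ligand_mm, kd_mm)
  k_ex <- koff / (1 - p_b)
  res <- list(max_koff = koff, kon = kon_from_koff_kd(koff, kd_mm),
              p_bound = p_b, k_ex = k_ex,
              regime = classify_regime(k_ex, delta_nu_hz))
  writeLines(c("quantity\tvalue",
               sprintf("max_koff_s1\t%.6g", res$max_koff),
               sprintf("kon_M1s1\t%.6g", res$kon),
               sprintf("p_bound\t%.6g", res$p_bound),
               sprintf("k_ex_s1\t%.6g", res$k_ex),
               sprintf("regime\t%s", res$regime)), report)
  write_run_manifest(out_dir, "koff_bound",
                     list(delta_nu_hz = delta_nu_hz, r2 = r2,
                          protein_mm = protein_mm, ligand_mm = ligand_mm,
                          kd_mm = kd_mm, tol_hz = tol_hz))
  invisible(res)
}

#' Run a lineshape simulation to a two-column TSV
#'
#' @param koff,delta_nu_hz,r2,p_bound exchange-model parameters.
#' @param resolution grid resolution (Hz).
#' @param out output TSV path (columns \code{freq_hz}, \code{intensity}).
#' @param force overwrite an existing file.
#' @return the \code{\link{simulate_lineshape}} object, invisibly.
#' @export
run_lineshape <- function(koff, delta_nu_hz, r2, p_bound, resolution = 0.05,
                          out = "spectrum.tsv", force = FALSE) {
  .check_out(out, force)
  model <- two_state_exchange(delta_nu_hz, r2, p_bound = p_bound,
                              k_off = koff)
  ls <- simulate_lineshape(model, resolution = resolution)
  writeLines(c("freq_hz\tintensity",
               sprintf("%.6g\t%.8g", ls$freq_hz, ls$intensity)), out)
  invisible(ls)
}

#' Run relaxation-rate fitting on a delay-series manifest
#'
#' Reads a manifest (TSV with columns \code{delay_ms} and \code{path}), fits
#' every residue's mono-exponential decay with Monte-Carlo uncertainties,
#' and writes \code{relax_report.tsv}.
#'
#' @param manifest manifest TSV path.
#' @param kind \code{"R1"} or \code{"R2"}.
#' @param mc Monte-Carlo replicates per residue; default 500.
#' @param seed RNG seed (mandatory when \code{mc > 0}).
#' @param out_dir,force as in \code{\link{run_fit_kd}}.
#' @return data frame of per-residue rates, invisibly.
#' @export
run_fit_relax <- function(manifest, kind = c("R1", "R2"), mc = 500,
                          seed = NULL, out_dir = ".", force = FALSE) {
  kind <- match.arg(kind)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- file.path(out_dir, sprintf("relax_%s_report.tsv", kind))
  .check_out(report, force)
  tab <- read.table(manifest, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  tab$path <- ifelse(file.exists(tab$path), tab$path,
                     file.path(dirname(manifest), tab$path))
  missing <- !file.exists(tab$path)
  if (any(missing))
    stop(sprintf("input '%s' listed in the manifest does not exist",
                 tab$path[missing][1]))
  tabs <- lapply(tab$path, read_peak_table)
  residues <- tabs[[1]]$residue_id
  ints <- sapply(tabs, function(t) t$intensity[match(residues, t$residue_id)])
  series <- relaxation_series(tab$delay_ms, ints, residues, kind = kind)
  rows <- lapply(residues, function(res) {
    fit <- fit_relaxation(series, res)
    rate_sd <- if (mc > 0) {
      if (is.null(seed)) stop("a seed is required for the Monte-Carlo step")
      rate_uncertainty_mc(series, res, n_replicates = mc, seed = seed)
    } else NA_real_
    data.frame(residue_id = res, rate_s1 = fit$rate, rate_sd_s1 = rate_sd,
               amplitude = fit$amplitude)
  })
  out <- do.call(rbind, rows)
  write.table(out, report, sep = "\t", quote = FALSE, row.names = FALSE)
  write_run_manifest(out_dir, paste0("fit_relax_", kind),
                     list(manifest = manifest, kind = kind, mc = mc,
                          seed = seed),
                     inputs = c(manifest, tab$path))
  invisible(out)
}

#' Run PRE profiling from para/dia peak tables
#'
#' @param para_path,dia_path peak-table paths for the paramagnetic and
#'   diamagnetic samples.
#' @param noise_sd spectral noise sd.
#' @param label_site spin-label residue number (metadata in the manifest).
#' @param out_dir,force as in \code{\link{run_fit_kd}}.
#' @return the \code{\link{pre_profile}}, invisibly.
#' @export
run_pre <- function(para_path, dia_path, noise_sd = 0, label_site = NA,
                    out_dir = ".", force = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- file.path(out_dir, "pre_profile.tsv")
  .check_out(report, force)
  prof <- pre_profile(read_peak_table(para_path), read_peak_table(dia_path),
                      noise_sd = noise_sd)
  write.table(as.data.frame(prof), report, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_run_manifest(out_dir, "pre",
                     list(para = para_path, dia = dia_path,
                          noise_sd = noise_sd, label_site = label_site),
                     inputs = c(para_path, dia_path))
  invisible(prof)
}

#' Run ensemble Calpha-distance reporting
#'
#' @param pdb_path PDB file.
#' @param pairs character like \code{"406:431,456:509"} or a 2-column
#'   matrix of residue pairs.
#' @param models integer model indices, or a character range like
#'   \code{"1-10"}; default the first 10 models.
#' @param chain optional chain id.
#' @param out_dir,force as in \code{\link{run_fit_kd}}.
#' @return data frame of per-pair statistics, invisibly.
#' @export
run_ens_dist <- function(pdb_path, pairs, models = NULL, chain = NULL,
                         out_dir = ".", force = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- file.path(out_dir, "ens_dist_report.tsv")
  .check_out(report, force)
  if (is.character(pairs)) {
    pr <- strsplit(strsplit(pairs, ",")[[1]], ":")
    pairs <- do.call(rbind, lapply(pr, as.integer))
  }
  if (is.character(models)) {
    rng <- as.integer(strsplit(models, "-")[[1]])
    models <- seq(rng[1], rng[length(rng)])
  }
  ens <- read_pdb_ensemble(pdb_path)
  rows <- apply(pairs, 1, function(pr) {
    ds <- ensemble_distance(ens, pr[1], pr[2], chain = chain, models = models)
    data.frame(pair = sprintf("%d:%d", pr[1], pr[2]), chain = ds$chain,
               n_models = ds$n_models, mean_A = ds$mean, sd_A = ds$sd,
               per_model_values = paste(sprintf("%.3f", ds$values),
                                        collapse = ","))
  })
  out <- do.call(rbind, rows)
  write.table(out, report, sep = "\t", quote = FALSE, row.names = FALSE)
  write_run_manifest(out_dir, "ens_dist",
                     list(pdb = pdb_path,
                          pairs = paste(sprintf("%d:%d", pairs[, 1],
                                                pairs[, 2]), collapse = ","),
                          models = models, chain = chain),
                     inputs = pdb_path)
  invisible(out)
}

#' Run the single-site ITC fit on an injection-heat table
#'
#' @param heats_path heat-table path (see \code{\link{read_itc_table}}).
#' @param out_dir,force as in \code{\link{run_fit_kd}}.
#' @return the \code{\link{fit_itc}} object, invisibly.
#' @export
run_itc_fit <- function(heats_path, out_dir = ".", force = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- file.path(out_dir, "itc_report.tsv")
  .check_out(report, force)
  fit <- fit_itc(read_itc_table(heats_path))
  writeLines(c("quantity\tvalue",
               sprintf("kd_mm\t%.6g", fit$kd_mm),
               sprintf("dh_cal_mol\t%.6g", fit$dh_cal_mol),
               sprintf("rss_ucal2\t%.6g", fit$rss),
               sprintf("unidentifiable\t%s", fit$unidentifiable)), report)
  write_run_manifest(out_dir, "itc_fit", list(heats = heats_path),
                     inputs = heats_path)
  invisible(fit)
}
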