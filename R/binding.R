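# Single-site ligand-depletion binding analysis from HSQC peak intensities.
#
# Under slow exchange the free-state peak of a responsive residue loses
# intensity in proportion to the bound fraction, so f_bound = 1 - I/I0 and a
# single shared K_D can be fitted globally across residues with the
# depletion-corrected (quadratic) isotherm. Concentrations are mM throughout.

#' Bound fraction under ligand depletion
#'
#' Fraction of protein in complex for single-site binding, from the exact
#' mass-action solution with ligand depletion:
#' \deqn{f = \frac{(P + L + K_D) - \sqrt{(P + L + K_D)^2 - 4 P L}}{2 P}}
#' where \eqn{P} and \eqn{L} are the \emph{total} protein and ligand
#' concentrations. At the weak affinities where free and bound peaks are both
#' observable, the ligand is appreciably depleted and the hyperbolic
#' approximation would bias \eqn{K_D}.
#'
#' @param protein_total total protein concentration (mM), > 0.
#' @param ligand_total total ligand concentration(s) (mM), >= 0. Vectorised.
#' @param kd dissociation constant (mM), > 0.
#' @return bound fraction(s) in [0, 1].
#' @examples
#' bound_fraction(0.3, 3.0, 1.3)   # ~0.68
#' bound_fraction(0.3, c(0.075, 0.15, 0.3, 0.6, 1.2, 3, 6), 1.3)
#' @export
bound_fraction <- function(protein_total, ligand_total, kd) {
  if (!is.numeric(protein_total) || any(protein_total <= 0))
    stop("protein_total must be positive")
  if (!is.numeric(kd) || any(kd <= 0))
    stop("kd must be positive")
  if (any(ligand_total < 0))
    stop("ligand_total must be non-negative")
  b <- protein_total + ligand_total + kd
  disc <- b * b - 4 * protein_total * ligand_total
  disc[disc < 0] <- 0  # guard rounding at near-stoichiometric saturation
  (b - sqrt(disc)) / (2 * protein_total)
}

#' Construct a titration series
#'
#' Per-residue free-state peak intensities across a ligand titration into a
#' fixed amount of protein, with the zero-ligand reference intensities.
#'
#' @param protein_mm total protein concentration (mM), > 0.
#' @param ligand_mm ligand concentrations of the titration points (mM),
#'   non-negative and strictly increasing.
#' @param intensities numeric matrix, one row per residue and one column per
#'   ligand concentration.
#' @param i0 reference intensities at zero ligand, one per residue, > 0.
#' @param residues integer residue ids (author numbering), one per row.
#' @param intensity_sd optional matrix of intensity uncertainties (same shape
#'   as \code{intensities}).
#' @param i0_sd optional reference-intensity uncertainties, one per residue.
#' @return an object of class \code{titration_series}.
#' @export
titration_series <- function(protein_mm, ligand_mm, intensities, i0, residues,
                             intensity_sd = NULL, i0_sd = NULL) {
  if (!is.numeric(protein_mm) || length(protein_mm) != 1L || protein_mm <= 0)
    stop("protein_mm must be a single positive concentration")
  ligand_mm <- as.numeric(ligand_mm)
  if (any(ligand_mm < 0) || is.unsorted(ligand_mm, strictly = TRUE))
    stop("ligand_mm must be non-negative and strictly increasing")
  intensities <- as.matrix(intensities)
  if (ncol(intensities) != length(ligand_mm))
    stop("one intensity column per ligand concentration is required")
  residues <- as.integer(residues)
  if (length(residues) != nrow(intensities) || anyDuplicated(residues))
    stop("residues must be unique, one per intensity row")
  i0 <- as.numeric(i0)
  if (length(i0) != nrow(intensities) || any(i0 <= 0))
    stop("every residue needs a positive reference intensity i0")
  if (!is.null(intensity_sd)) {
    intensity_sd <- as.matrix(intensity_sd)
    stopifnot(all(dim(intensity_sd) == dim(intensities)), all(intensity_sd >= 0))
  }
  if (!is.null(i0_sd)) {
    i0_sd <- as.numeric(i0_sd)
    stopifnot(length(i0_sd) == length(i0), all(i0_sd >= 0))
  }
  rownames(intensities) <- residues
  structure(
    list(protein_mm = protein_mm, ligand_mm = ligand_mm,
         intensities = intensities, i0 = i0, residues = residues,
         intensity_sd = intensity_sd, i0_sd = i0_sd),
    class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("<titration_series> %d residues, %d ligand points (%g-%g mM) into %g mM protein\n",
              length(x$residues), length(x$ligand_mm),
              min(x$ligand_mm), max(x$ligand_mm), x$protein_mm))
  invisible(x)
}

#' Intensity ratios at a reference titration point
#'
#' Per-residue ratio I(L_ref)/I0 used by the responsive-residue selection
#' criterion. The default reference is the 1.2 mM titration point.
#'
#' @param series a \code{\link{titration_series}}.
#' @param ref_ligand_mm reference ligand concentration; must match one of the
#'   titration points.
#' @return named numeric vector of ratios (names are residue ids).
#' @export
intensity_ratios <- function(series, ref_ligand_mm = 1.2) {
  stopifnot(inherits(series, "titration_series"))
  j <- which(abs(series$ligand_mm - ref_ligand_mm) < 1e-9)
  if (length(j) != 1L)
    stop(sprintf("no titration point at %g mM ligand", ref_ligand_mm))
  setNames(series$intensities[, j] / series$i0, series$residues)
}

#' Select residues responsive to ligand binding
#'
#' Residues whose intensity ratio at the reference point falls strictly below
#' \code{mean(ratio) - sigma_factor * sd(ratio)} (sample sd, n - 1) are taken
#' as reporting on binding and used in the global fit.
#'
#' @param ratios named numeric vector of I(ref)/I0 ratios (see
#'   \code{\link{intensity_ratios}}); at least 2 finite values.
#' @param sigma_factor multiple of the sd subtracted from the mean
#'   (default 0.8).
#' @return integer vector of selected residue ids.
#' @export
select_responsive_residues <- function(ratios, sigma_factor = 0.8) {
  r <- ratios[is.finite(ratios)]
  if (length(r) < 2L)
    stop("at least 2 finite intensity ratios are required")
  thr <- mean(r) - sigma_factor * sd(r)
  as.integer(names(r)[r < thr])
}

# sum of squared deviations between observed and model bound fractions
.kd_objective <- function(kd, f_obs, protein_mm, ligand_mm) {
  f_mod <- bound_fraction(protein_mm, ligand_mm, kd)
  sum((sweep(f_obs, 2, f_mod))^2)
}

#' Global dissociation-constant fit from titration intensities
#'
#' Fits a single shared \eqn{K_D} to the free-state intensity losses of the
#' selected residues: the observed bound fraction of residue \eqn{r} at
#' ligand concentration \eqn{L} is \eqn{1 - I_r(L)/I_{0,r}} and the model is
#' the ligand-depletion isotherm \code{\link{bound_fraction}}. The summed
#' squared deviation over all selected residues and titration points is
#' minimised over \eqn{K_D} alone (no per-residue nuisance parameters) by
#' bounded 1-D optimisation.
#'
#' @param series a \code{\link{titration_series}}.
#' @param residues residue ids to fit (e.g. from
#'   \code{\link{select_responsive_residues}}); default all residues.
#' @param interval search interval for \eqn{K_D} in mM.
#' @param tol absolute optimisation tolerance on \eqn{K_D} (mM).
#' @param mc_replicates if > 0, Monte-Carlo replicates used to attach an
#'   uncertainty via \code{\link{kd_uncertainty_mc}} (requires intensity sds
#'   and a \code{seed}).
#' @param seed RNG seed for the Monte-Carlo step.
#' @return an object of class \code{kd_fit} with components \code{kd} (mM),
#'   \code{kd_sd} (mM or NA), \code{residues}, \code{f_obs}, \code{fitted}
#'   (model bound fractions per titration point), and \code{rss}.
#' @examples
#' sim <- gen_titration(seed = 1, noise_frac = 0)
#' fit <- fit_kd(sim$series)
#' coef(fit)
#' @export
fit_kd <- function(series, residues = NULL, interval = c(1e-4, 1e3),
                   tol = 1e-8, mc_replicates = 0, seed = NULL) {
  stopifnot(inherits(series, "titration_series"))
  if (is.null(residues)) residues <- series$residues
  idx <- match(residues, series$residues)
  if (anyNA(idx))
    stop(sprintf("residue(s) %s not present in the series",
                 paste(residues[is.na(idx)], collapse = ", ")))
  if (length(idx) < 1L) stop("at least one residue is required")
  if (length(series$ligand_mm) < 3L)
    stop("at least 3 ligand concentrations are required")

  int_sel <- series$intensities[idx, , drop = FALSE]
  f_obs <- 1 - sweep(int_sel, 1, series$i0[idx], "/")

  # no binding signal: every residue's intensity non-decreasing with ligand
  decaying <- apply(int_sel, 1, function(z) any(diff(z) < 0))
  degenerate <- !any(decaying)

  opt <- optimize(.kd_objective, interval = interval, f_obs = f_obs,
                  protein_mm = series$protein_mm, ligand_mm = series$ligand_mm,
                  tol = tol)
  kd <- opt$minimum
  if (degenerate) {
    warning("no decaying intensity profile among the selected residues; K_D is not identifiable and is reported at the upper search bound")
    kd <- interval[2]
  }
  fit <- structure(
    list(kd = kd, kd_sd = NA_real_, residues = as.integer(residues),
         f_obs = f_obs, fitted = bound_fraction(series$protein_mm,
                                                series$ligand_mm, kd),
         rss = .kd_objective(kd, f_obs, series$protein_mm, series$ligand_mm),
         degenerate = degenerate, series = series, interval = interval,
         tol = tol, call = match.call()),
    class = "kd_fit")
  if (mc_replicates > 0) {
    if (is.null(seed)) stop("a seed is required for the Monte-Carlo step")
    fit$kd_sd <- kd_uncertainty_mc(series, residues, n_replicates = mc_replicates,
                                   seed = seed, interval = interval, tol = tol)
  }
  fit
}

#' Monte-Carlo uncertainty of the global K_D
#'
#' Resamples every intensity (including the zero-ligand references) from a
#' normal distribution centred on its observed value with its recorded
#' uncertainty, refits \eqn{K_D} for each replicate, and returns the standard
#' deviation of the replicate estimates.
#'
#' @param series a \code{\link{titration_series}} carrying \code{intensity_sd}
#'   and \code{i0_sd}.
#' @param residues residue ids used in the fit; default all.
#' @param n_replicates number of replicates, >= 100.
#' @param seed RNG seed (mandatory; results are deterministic given the seed).
#' @param interval,tol passed to the internal refits.
#' @return the Monte-Carlo standard deviation of \eqn{K_D} (mM).
#' @export
kd_uncertainty_mc <- function(series, residues = NULL, n_replicates = 1000,
                              seed, interval = c(1e-4, 1e3), tol = 1e-8) {
  stopifnot(inherits(series, "titration_series"))
  if (missing(seed)) stop("an explicit seed is required")
  if (n_replicates < 100) stop("at least 100 replicates are required")
  if (is.null(residues)) residues <- series$residues
  idx <- match(residues, series$residues)
  if (anyNA(idx)) stop("unknown residue in 'residues'")
  if (is.null(series$intensity_sd) || is.null(series$i0_sd))
    stop("intensity uncertainties are required for Monte-Carlo error estimation")
  sds <- series$intensity_sd[idx, , drop = FALSE]
  i0sd <- series$i0_sd[idx]
  bad <- !is.finite(rowSums(sds)) | !is.finite(i0sd)
  if (any(bad))
    stop(sprintf("missing intensity sd for residue %s",
                 paste(residues[bad], collapse = ", ")))
  ints <- series$intensities[idx, , drop = FALSE]
  i0 <- series$i0[idx]
  P <- series$protein_mm
  L <- series$ligand_mm

  set.seed(seed)
  kds <- vapply(seq_len(n_replicates), function(rep) {
    int_r <- ints + matrix(rnorm(length(ints)), nrow(ints)) * sds
    i0_r <- i0 + rnorm(length(i0)) * i0sd
    f_obs <- 1 - sweep(int_r, 1, i0_r, "/")
    optimize(.kd_objective, interval = interval, f_obs = f_obs,
             protein_mm = P, ligand_mm = L, tol = tol)$minimum
  }, numeric(1))
  sd(kds)
}

#' @export
print.kd_fit <- function(x, ...) {
  cat("Global single-site K_D fit (ligand-depletion isotherm)\n")
  cat(sprintf("  K_D: %.4g mM%s\n", x$kd,
              if (is.na(x$kd_sd)) "" else sprintf(" +/- %.2g mM (Monte Carlo)", x$kd_sd)))
  cat(sprintf("  residues: %d, titration points: %d, RSS: %.4g\n",
              length(x$residues), length(x$series$ligand_mm), x$rss))
  if (x$degenerate)
    cat("  WARNING: fit degenerate (no binding signal); K_D at upper bound\n")
  invisible(x)
}

#' @export
coef.kd_fit <- function(object, ...) c(kd_mm = object$kd)

#' @export
summary.kd_fit <- function(object, ...) {
  res <- object$f_obs - matrix(object$fitted, nrow(object$f_obs),
                               ncol(object$f_obs), byrow = TRUE)
  structure(list(fit = object, rmsd = sqrt(mean(res^2)),
                 per_residue_rmsd = sqrt(rowMeans(res^2))),
            class = "summary.kd_fit")
}

#' @export
print.summary.kd_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  bound-fraction RMSD: %.4g\n", x$rmsd))
  invisible(x)
}

#' @export
predict.kd_fit <- function(object, ligand_mm = NULL, ...) {
  if (is.null(ligand_mm)) ligand_mm <- object$series$ligand_mm
  bound_fraction(object$series$protein_mm, ligand_mm, object$kd)
}

#' @export
residuals.kd_fit <- function(object, ...) {
  object$f_obs - matrix(object$fitted, nrow(object$f_obs),
                        ncol(object$f_obs), byrow = TRUE)
}

#' @export
plot.kd_fit <- function(x, ...) {
  L <- x$series$ligand_mm
  grid <- seq(0, max(L) * 1.05, length.out = 200)
  matplot(L, t(x$f_obs), pch = 1, col = "grey40", log = "",
          xlab = "[ligand] (mM)", ylab = "bound fraction",
          main = sprintf("Global K_D = %.3g mM", x$kd), ...)
  lines(grid, predict(x, grid), lwd = 2, col = "firebrick")
  invisible(x)
}
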