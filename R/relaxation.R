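# Mono-exponential fitting of 15N R1/R2 decay series and steady-state
# heteronuclear NOE ratios. Decays are fitted as I(t) = A exp(-R t) with no
# baseline offset; delays are stored in ms and rates reported in s^-1.
# Duplicated delays in the schedule provide the noise estimate for
# Monte-Carlo rate uncertainties.

#' R1 and R2 relaxation delay schedules
#'
#' The delay schedules (ms) used by the relaxation experiments and by the
#' synthetic generator: 11 delays for R1 with 10.3 and 615.7 ms duplicated,
#' 7 delays for R2 with 16.0 and 80.0 ms duplicated.
#'
#' @return numeric vector of delays in ms (with duplicates).
#' @export
delays_r1 <- function() c(10.3, 10.3, 153.9, 307.9, 461.8, 615.7, 615.7,
                          769.6, 923.6, 1128.8, 1539.3)

#' @rdname delays_r1
#' @export
delays_r2 <- function() c(0.0, 16.0, 16.0, 40.0, 80.0, 80.0, 160.0)

#' Construct a relaxation decay series
#'
#' @param delays_ms relaxation delays in ms (duplicates allowed and needed
#'   for Monte-Carlo errors); non-negative, at least 5 distinct values.
#' @param intensities numeric matrix, one row per residue and one column per
#'   delay.
#' @param residues integer residue ids, one per row.
#' @param kind \code{"R1"} or \code{"R2"}.
#' @return an object of class \code{relaxation_series}.
#' @export
relaxation_series <- function(delays_ms, intensities, residues,
                              kind = c("R1", "R2")) {
  kind <- match.arg(kind)
  delays_ms <- as.numeric(delays_ms)
  if (any(delays_ms < 0)) stop("delays must be non-negative")
  if (length(unique(delays_ms)) < 5L)
    stop("at least 5 distinct delays are required")
  intensities <- as.matrix(intensities)
  if (ncol(intensities) != length(delays_ms))
    stop("one intensity column per delay is required")
  residues <- as.integer(residues)
  if (length(residues) != nrow(intensities) || anyDuplicated(residues))
    stop("residues must be unique, one per intensity row")
  rownames(intensities) <- residues
  structure(list(delays_ms = delays_ms, intensities = intensities,
                 residues = residues, kind = kind),
            class = "relaxation_series")
}

#' @export
print.relaxation_series <- function(x, ...) {
  cat(sprintf("<relaxation_series> %s, %d residues, %d delays (%g-%g ms)\n",
              x$kind, length(x$residues), length(x$delays_ms),
              min(x$delays_ms), max(x$delays_ms)))
  invisible(x)
}

.series_row <- function(series, residue) {
  i <- match(as.integer(residue), series$residues)
  if (is.na(i)) stop(sprintf("residue %d not present in the series", residue))
  series$intensities[i, ]
}

#' Fit a mono-exponential relaxation decay
#'
#' Fits \eqn{I(t) = A e^{-R t}} to one residue's decay by nonlinear least
#' squares (Levenberg-Marquardt), initialised from the log-linear regression
#' of the positive intensities. Non-decaying data produce a warning and a
#' rate pinned near zero rather than a failure.
#'
#' @param series a \code{\link{relaxation_series}}.
#' @param residue residue id to fit.
#' @return an object of class \code{relax_fit} with components \code{rate}
#'   (s^-1), \code{amplitude}, \code{rate_sd} (NA until
#'   \code{\link{rate_uncertainty_mc}}), \code{fitted} and \code{kind}.
#' @examples
#' sim <- gen_relaxation(rate_true = 1.5, seed = 1, noise_frac = 0)
#' fit_relaxation(sim$series, sim$series$residues[1])
#' @export
fit_relaxation <- function(series, residue) {
  stopifnot(inherits(series, "relaxation_series"))
  y <- .series_row(series, residue)
  t_s <- series$delays_ms / 1000
  if (length(y) < 5L) stop("at least 5 delay points are required")
  est <- .fit_monoexp(t_s, y)
  if (est$rate < 1e-6)
    warning(sprintf("residue %d: intensities do not decay; rate is ~0", residue))
  structure(list(rate = est$rate, amplitude = est$amplitude,
                 rate_sd = NA_real_, residue = as.integer(residue),
                 delays_ms = series$delays_ms, intensities = y,
                 fitted = est$amplitude * exp(-est$rate * t_s),
                 kind = series$kind),
            class = "relax_fit")
}

# core 2-parameter exponential fit on (t seconds, y)
.fit_monoexp <- function(t_s, y) {
  pos <- y > 0
  if (sum(pos) >= 2) {
    init <- lm(log(y[pos]) ~ t_s[pos])
    A0 <- unname(exp(coef(init)[1])); R0 <- unname(max(-coef(init)[2], 1e-8))
  } else {
    A0 <- max(abs(y)); R0 <- 1
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-R * t_s),
                      start = list(A = A0, R = R0),
                      lower = c(A = -Inf, R = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200,
                                                           ftol = 1e-14,
                                                           ptol = 1e-14)),
    error = function(e) NULL)
  if (is.null(fit)) return(list(amplitude = A0, rate = R0))
  cf <- coef(fit)
  list(amplitude = unname(cf["A"]), rate = unname(cf["R"]))
}

#' Duplicate-based noise estimate for a decay series
#'
#' The intensity noise is taken from the duplicated delays: with pairwise
#' differences \eqn{\Delta_j} between duplicate measurements, the per-point
#' noise sd is \eqn{\sqrt{\mathrm{mean}_j(\Delta_j^2)/2}} (each difference of
#' two equally noisy points has variance \eqn{2\sigma^2}).
#'
#' @param series a \code{\link{relaxation_series}}.
#' @param residue residue id.
#' @return the noise standard deviation.
#' @export
duplicate_noise_sd <- function(series, residue) {
  stopifnot(inherits(series, "relaxation_series"))
  y <- .series_row(series, residue)
  d <- series$delays_ms
  dup_vals <- unique(d[duplicated(d)])
  if (!length(dup_vals)) stop("no duplicated delays in the series")
  deltas <- vapply(dup_vals, function(v) {
    yy <- y[d == v]
    yy[1] - yy[2]
  }, numeric(1))
  sqrt(mean(deltas^2) / 2)
}

#' Monte-Carlo uncertainty of a relaxation rate
#'
#' Resamples every intensity with the duplicate-based noise sd
#' (\code{\link{duplicate_noise_sd}}), refits the exponential, and returns
#' the sd of the fitted rates. Deterministic given the seed.
#'
#' @param series a \code{\link{relaxation_series}} with duplicated delays.
#' @param residue residue id.
#' @param n_replicates number of replicates (default 500).
#' @param seed RNG seed (mandatory).
#' @return Monte-Carlo rate sd (s^-1).
#' @export
rate_uncertainty_mc <- function(series, residue, n_replicates = 500, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  noise <- duplicate_noise_sd(series, residue)
  if (noise == 0) return(0)
  y <- .series_row(series, residue)
  t_s <- series$delays_ms / 1000
  set.seed(seed)
  rates <- vapply(seq_len(n_replicates), function(i) {
    .fit_monoexp(t_s, y + rnorm(length(y), sd = noise))$rate
  }, numeric(1))
  sd(rates)
}

#' @export
print.relax_fit <- function(x, ...) {
  cat(sprintf("Mono-exponential %s fit, residue %d\n", x$kind, x$residue))
  cat(sprintf("  rate: %.4g s^-1%s,  amplitude: %.4g\n", x$rate,
              if (is.na(x$rate_sd)) "" else sprintf(" +/- %.2g s^-1", x$rate_sd),
              x$amplitude))
  invisible(x)
}

#' @export
coef.relax_fit <- function(object, ...)
  c(rate = object$rate, amplitude = object$amplitude)

#' @export
predict.relax_fit <- function(object, delays_ms = NULL, ...) {
  if (is.null(delays_ms)) delays_ms <- object$delays_ms
  object$amplitude * exp(-object$rate * delays_ms / 1000)
}

#' @export
residuals.relax_fit <- function(object, ...) object$intensities - object$fitted

#' @export
plot.relax_fit <- function(x, ...) {
  plot(x$delays_ms, x$intensities, pch = 16, xlab = "delay (ms)",
       ylab = "intensity",
       main = sprintf("%s residue %d: rate = %.3g s^-1", x$kind, x$residue, x$rate),
       ...)
  tt <- seq(0, max(x$delays_ms), length.out = 200)
  lines(tt, predict(x, tt), col = "firebrick", lwd = 2)
  invisible(x)
}

#' Steady-state heteronuclear NOE with propagated uncertainty
#'
#' \code{hNOE = I_sat / I_unsat}, with the uncertainty from first-order
#' propagation of the spectral noise sd through the ratio:
#' \eqn{\sigma_{hNOE} = \sqrt{(\sigma/I_{unsat})^2 +
#' (I_{sat}\,\sigma/I_{unsat}^2)^2}}.
#'
#' @param i_sat intensity with 1H saturation.
#' @param i_unsat intensity without saturation; must be non-zero.
#' @param noise_sd spectral noise standard deviation, >= 0.
#' @return a data frame with columns \code{hnoe} and \code{sd}. Vectorised.
#' @examples
#' heteronuclear_noe(40, 50, 2)
#' @export
heteronuclear_noe <- function(i_sat, i_unsat, noise_sd) {
  if (any(i_unsat == 0)) stop("unsaturated intensity must be non-zero")
  if (any(noise_sd < 0)) stop("noise_sd must be non-negative")
  hnoe <- i_sat / i_unsat
  sd <- sqrt((noise_sd / i_unsat)^2 + (i_sat * noise_sd / i_unsat^2)^2)
  data.frame(hnoe = hnoe, sd = sd)
}
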