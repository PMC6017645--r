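# Two-site Bloch-McConnell chemical-exchange lineshape analysis.
#
# A closed two-site system free <-> bound with pseudo-first-order kinetics:
# the free->bound rate is k_fb = k_off * p_bound / (1 - p_bound), so detailed
# balance p_free k_fb = p_bound k_off holds exactly and the populations are
# fixed by the equilibrium bound fraction at the stated total concentrations.
# The absorption spectrum is the real part of the steady-state solution of
# the McConnell equations, S(nu) = Re[ 1' (i 2 pi nu I - A)^(-1) p ] with
# A = i Omega - R2 + K. The free resonance is placed at 0 Hz and the bound
# resonance at +delta_nu.

#' Construct a two-state exchange model
#'
#' @param delta_nu_hz free/bound resonance separation (Hz), >= 0.
#' @param r2_free,r2_bound transverse relaxation rates (s^-1), > 0. The bound
#'   rate defaults to the free rate (one average rate for both states).
#' @param p_bound bound population in [0, 1).
#' @param k_off bound -> free rate (s^-1), >= 0.
#' @return an object of class \code{two_state_exchange}; the derived fields
#'   \code{k_fb} (free -> bound rate) and \code{k_ex = k_off / (1 - p_bound)}
#'   are attached.
#' @examples
#' two_state_exchange(58, 21, p_bound = 0.68, k_off = 30)
#' @export
two_state_exchange <- function(delta_nu_hz, r2_free, r2_bound = r2_free,
                               p_bound, k_off) {
  if (delta_nu_hz < 0) stop("delta_nu_hz must be non-negative")
  if (r2_free <= 0 || r2_bound <= 0) stop("R2 rates must be positive")
  if (p_bound < 0 || p_bound >= 1) stop("p_bound must lie in [0, 1)")
  if (k_off < 0) stop("k_off must be non-negative")
  structure(
    list(delta_nu_hz = delta_nu_hz, r2_free = r2_free, r2_bound = r2_bound,
         p_bound = p_bound, k_off = k_off,
         k_fb = k_off * p_bound / (1 - p_bound),
         k_ex = k_off / (1 - p_bound)),
    class = "two_state_exchange")
}

#' @export
print.two_state_exchange <- function(x, ...) {
  cat(sprintf("<two_state_exchange> dnu = %g Hz, R2 = %g/%g s^-1, p_bound = %.3f, k_off = %g s^-1 (k_ex = %.3g s^-1, %s exchange)\n",
              x$delta_nu_hz, x$r2_free, x$r2_bound, x$p_bound, x$k_off,
              x$k_ex, classify_regime(x$k_ex, x$delta_nu_hz)))
  invisible(x)
}

# evolution matrix A = i*Omega - R2 + K (free state first)
.exchange_matrix <- function(model) {
  omega <- 2 * pi * c(0, model$delta_nu_hz)
  K <- rbind(c(-model$k_fb, model$k_off),
             c(model$k_fb, -model$k_off))
  diag(1i * omega - c(model$r2_free, model$r2_bound)) + K
}

#' Simulate a two-site exchange absorption lineshape
#'
#' Evaluates the steady-state absorption spectrum of the two-site McConnell
#' equations on a frequency grid. The integral of the returned spectrum
#' equals half the total magnetization (each unit-population Lorentzian
#' integrates to 1/2 in Hz units), which is checked to 1 per cent.
#'
#' @param model a \code{\link{two_state_exchange}}.
#' @param freq_range length-2 numeric, grid limits in Hz (default
#'   \code{c(-300, 300)} around the free resonance at 0 Hz). The grid must
#'   extend at least \code{5 * R2 / pi} Hz beyond each resonance.
#' @param resolution grid spacing in Hz, <= 0.1 (default 0.05).
#' @return an object of class \code{lineshape}: \code{freq_hz},
#'   \code{intensity}, and a \code{peaks} data frame of interpolated peak
#'   positions (Hz) and heights.
#' @examples
#' m <- two_state_exchange(58, 21, p_bound = 0.68, k_off = 30)
#' ls <- simulate_lineshape(m)
#' ls$peaks
#' @export
simulate_lineshape <- function(model, freq_range = c(-300, 300),
                               resolution = 0.05) {
  stopifnot(inherits(model, "two_state_exchange"))
  if (resolution > 0.1) stop("grid resolution must be <= 0.1 Hz")
  margin <- 5 * max(model$r2_free, model$r2_bound) / pi
  if (freq_range[1] > 0 - margin || freq_range[2] < model$delta_nu_hz + margin)
    stop(sprintf("frequency grid must span both resonances (0 and %g Hz) with a %.1f Hz margin",
                 model$delta_nu_hz, margin))
  nu <- seq(freq_range[1], freq_range[2], by = resolution)
  A <- .exchange_matrix(model)
  p <- c(1 - model$p_bound, model$p_bound)
  # closed-form inverse of the 2x2 system B x = p with B = i*2pi*nu*I - A
  iw <- 1i * 2 * pi * nu
  b11 <- iw - A[1, 1]; b22 <- iw - A[2, 2]
  b12 <- -A[1, 2];     b21 <- -A[2, 1]
  det <- b11 * b22 - b12 * b21
  x1 <- (b22 * p[1] - b12 * p[2]) / det
  x2 <- (b11 * p[2] - b21 * p[1]) / det
  intensity <- Re(x1 + x2)
  structure(list(freq_hz = nu, intensity = intensity,
                 resolution = resolution, model = model,
                 peaks = .find_peaks(nu, intensity, resolution)),
            class = "lineshape")
}

# local maxima with three-point parabolic interpolation
.find_peaks <- function(x, y, res, min_rel_height = 1e-4) {
  n <- length(y)
  i <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  i <- i[y[i] > min_rel_height * max(y)]
  if (!length(i))
    return(data.frame(position_hz = numeric(0), height = numeric(0)))
  denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  delta <- ifelse(denom == 0, 0, 0.5 * (y[i - 1L] - y[i + 1L]) / denom)
  data.frame(position_hz = x[i] + delta * res,
             height = y[i] - 0.25 * (y[i - 1L] - y[i + 1L]) * delta)
}

#' @export
print.lineshape <- function(x, ...) {
  cat(sprintf("<lineshape> %d points (%g to %g Hz, %g Hz resolution), %d peak(s)\n",
              length(x$freq_hz), min(x$freq_hz), max(x$freq_hz),
              x$resolution, nrow(x$peaks)))
  if (nrow(x$peaks)) print(x$peaks, row.names = FALSE)
  invisible(x)
}

#' @export
plot.lineshape <- function(x, ...) {
  plot(x$freq_hz, x$intensity, type = "l", xlab = "frequency (Hz)",
       ylab = "intensity", ...)
  points(x$peaks$position_hz, x$peaks$height, pch = 4, col = "firebrick")
  invisible(x)
}

#' Exchange-induced displacement of the free-state peak
#'
#' Displacement, in Hz, of the free-state peak maximum from its position in
#' the absence of exchange (the free resonance). Requires the slow-exchange
#' regime \code{k_ex < 2*pi*delta_nu}; once the two lines merge the free peak
#' is no longer defined and an error is raised.
#'
#' @param model a \code{\link{two_state_exchange}} in slow exchange.
#' @param resolution lineshape grid resolution (Hz).
#' @param freq_range lineshape grid limits (Hz).
#' @return non-negative shift in Hz.
#' @export
free_peak_shift <- function(model, resolution = 0.05,
                            freq_range = c(-300, 300)) {
  stopifnot(inherits(model, "two_state_exchange"))
  if (model$k_ex >= 2 * pi * model$delta_nu_hz)
    stop("model is not in the slow-exchange regime (k_ex >= 2*pi*delta_nu)")
  if (model$k_off == 0) return(0)
  ls <- simulate_lineshape(model, freq_range = freq_range,
                           resolution = resolution)
  if (nrow(ls$peaks) < 2L)
    stop("free peak unresolvable: the two lines have merged")
  # the free peak is the one nearer the free resonance at 0 Hz
  pos <- ls$peaks$position_hz
  abs(pos[which.min(abs(pos))])
}

#' Maximum k_off compatible with a free-peak shift bound
#'
#' Searches, by bisection, for the largest \code{k_off} at which the
#' exchange-induced displacement of the free-state peak stays within
#' \code{shift_tolerance_hz}. The bound population is the equilibrium bound
#' fraction at the stated total concentrations
#' (\code{\link{bound_fraction}}). Loss of the resolved free peak (merged
#' lines or departure from slow exchange) is treated as exceeding the
#' tolerance.
#'
#' @param delta_nu_hz free/bound separation (Hz).
#' @param r2 transverse relaxation rate used for both states (s^-1).
#' @param protein_mm,ligand_mm,kd_mm total concentrations and dissociation
#'   constant (mM) fixing the bound population.
#' @param shift_tolerance_hz maximum acceptable free-peak displacement (Hz),
#'   > 0.
#' @param koff_tol absolute bisection tolerance on k_off (s^-1).
#' @param resolution lineshape grid resolution (Hz).
#' @return the maximum \code{k_off} in s^-1.
#' @examples
#' \donttest{
#' max_koff_for_shift(58, 21, 0.3, 3.0, 1.3, 5)  # ~30 s^-1
#' }
#' @export
max_koff_for_shift <- function(delta_nu_hz, r2, protein_mm, ligand_mm, kd_mm,
                               shift_tolerance_hz, koff_tol = 0.1,
                               resolution = 0.05) {
  if (shift_tolerance_hz <= 0) stop("shift_tolerance_hz must be positive")
  p_b <- bound_fraction(protein_mm, ligand_mm, kd_mm)
  shift_at <- function(k_off) {
    m <- two_state_exchange(delta_nu_hz, r2, p_bound = p_b, k_off = k_off)
    if (m$k_ex >= 2 * pi * delta_nu_hz) return(Inf)  # regime lost
    tryCatch(free_peak_shift(m, resolution = resolution), error = function(e) Inf)
  }
  lo <- 0
  hi <- koff_tol
  while (is.finite(shift_at(hi)) && shift_at(hi) <= shift_tolerance_hz) {
    lo <- hi
    hi <- hi * 2
    if (hi > 1e6) return(lo)  # tolerance never exceeded at any sensible rate
  }
  if (lo == 0 && shift_at(koff_tol) > shift_tolerance_hz &&
      shift_at(koff_tol / 100) > shift_tolerance_hz)
    stop("shift tolerance unreachable even as k_off approaches 0")
  while (hi - lo > koff_tol) {
    mid <- (lo + hi) / 2
    if (shift_at(mid) <= shift_tolerance_hz) lo <- mid else hi <- mid
  }
  lo
}

#' k_on from k_off and K_D
#'
#' \code{k_on = k_off / K_D} with the dissociation constant converted from
#' mM to M at this interface, so the association rate is returned in the
#' conventional M^-1 s^-1.
#'
#' @param k_off dissociation rate (s^-1), >= 0.
#' @param kd_mm dissociation constant (mM), > 0.
#' @return k_on in M^-1 s^-1.
#' @examples
#' kon_from_koff_kd(30, 1.3)  # ~2.3e4
#' @export
kon_from_koff_kd <- function(k_off, kd_mm) {
  if (kd_mm <= 0) stop("kd_mm must be positive")
  if (k_off < 0) stop("k_off must be non-negative")
  k_off / (kd_mm * 1e-3)
}

#' Classify the chemical-shift exchange regime
#'
#' Slow when the exchange rate is below the angular frequency separation
#' (\code{k_ex < 2*pi*delta_nu}, the same slow-exchange condition under
#' which \code{\link{free_peak_shift}} is defined), fast when
#' \code{k_ex > 5 * 2*pi*delta_nu}, intermediate between.
#'
#' @param k_ex exchange rate (s^-1), >= 0.
#' @param delta_nu_hz resonance separation (Hz), >= 0.
#' @return one of \code{"slow"}, \code{"intermediate"}, \code{"fast"}.
#' @export
classify_regime <- function(k_ex, delta_nu_hz) {
  if (k_ex < 0 || delta_nu_hz < 0) stop("arguments must be non-negative")
  dw <- 2 * pi * delta_nu_hz
  if (k_ex == 0) "slow"
  else if (k_ex < dw) "slow"
  else if (k_ex > 5 * dw) "fast"
  else "intermediate"
}
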