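# Single-site ITC isotherm with stoichiometry fixed at n = 1.
#
# The cell is modelled as a well-stirred overflow cell: each injection
# displaces an equal volume of the current mixture, so after injection i
#   [L]_i = [L]_{i-1} (1 - v/V0) + [L]_syr v/V0,   [P]_i = [P]_{i-1} (1 - v/V0)
# and the heat of injection i is the enthalpy of the net complex formed,
#   q_i = dH * V0 * ([PL]_i - [PL]_{i-1} (1 - v/V0)),
# which accounts for complex carried out with the displaced volume. For weak
# binding the stoichiometry cannot be resolved from the isotherm, so n is
# fixed at 1 and only (K_D, dH) are fitted.

#' Construct an ITC experiment
#'
#' @param injection_ul injection volumes (µL), one per injection, > 0.
#' @param syringe_mm ligand concentration in the syringe (mM), > 0.
#' @param cell_mm protein concentration initially in the cell (mM), > 0.
#' @param cell_ul active cell volume (µL), > 0.
#' @param heats_ucal observed heats per injection (µcal); optional when the
#'   object is only used for forward simulation.
#' @return an object of class \code{itc_experiment}.
#' @examples
#' itc_experiment(rep(1.5, 25), syringe_mm = 5, cell_mm = 0.1, cell_ul = 200)
#' @export
itc_experiment <- function(injection_ul, syringe_mm, cell_mm, cell_ul,
                           heats_ucal = NULL) {
  injection_ul <- as.numeric(injection_ul)
  if (any(injection_ul <= 0)) stop("injection volumes must be positive")
  if (syringe_mm <= 0 || cell_mm <= 0 || cell_ul <= 0)
    stop("concentrations and cell volume must be positive")
  if (!is.null(heats_ucal) && length(heats_ucal) != length(injection_ul))
    stop("one observed heat per injection is required")
  structure(list(injection_ul = injection_ul, syringe_mm = syringe_mm,
                 cell_mm = cell_mm, cell_ul = cell_ul,
                 heats_ucal = heats_ucal, n = 1),
            class = "itc_experiment")
}

#' @export
print.itc_experiment <- function(x, ...) {
  cat(sprintf("<itc_experiment> %d x %.2g µL of %g mM ligand into %g µL x %g mM protein (n = 1)\n",
              length(x$injection_ul), mean(x$injection_ul), x$syringe_mm,
              x$cell_ul, x$cell_mm))
  invisible(x)
}

# cell composition trajectory: per-injection total concentrations (mM)
.itc_trajectory <- function(exp) {
  V0 <- exp$cell_ul
  n_inj <- length(exp$injection_ul)
  P <- L <- numeric(n_inj)
  p <- exp$cell_mm; l <- 0
  for (i in seq_len(n_inj)) {
    f <- exp$injection_ul[i] / V0
    p <- p * (1 - f)
    l <- l * (1 - f) + exp$syringe_mm * f
    P[i] <- p; L[i] <- l
  }
  list(P = P, L = L)
}

#' Model injection heats for a single-site ITC experiment
#'
#' Forward model: the heat of each injection is the binding enthalpy of the
#' net complex formed in the cell between consecutive equilibria, with the
#' stepwise-overflow dilution correction (see the module description above).
#'
#' @param exp an \code{\link{itc_experiment}}.
#' @param kd_mm dissociation constant (mM), > 0.
#' @param dh_cal_mol binding enthalpy (cal/mol of complex).
#' @return numeric vector of per-injection heats (µcal).
#' @export
itc_heats <- function(exp, kd_mm, dh_cal_mol) {
  stopifnot(inherits(exp, "itc_experiment"))
  if (kd_mm <= 0) stop("kd_mm must be positive")
  traj <- .itc_trajectory(exp)
  pl <- traj$P * bound_fraction(traj$P, traj$L, kd_mm)  # complex, mM
  pl_prev <- c(0, pl[-length(pl)])
  keep <- 1 - exp$injection_ul / exp$cell_ul
  # mM * µL * cal/mol: 1e-3 mol/m^3 * 1e-9 m^3 = 1e-12 mol; cal -> µcal: 1e6
  dh_cal_mol * exp$cell_ul * (pl - pl_prev * keep) * 1e-3
}

#' Fit the single-site ITC isotherm (n = 1)
#'
#' Least-squares fit of the observed injection heats to \code{\link{itc_heats}}
#' over \eqn{(K_D, \Delta H)} with the stoichiometry fixed at 1. Because the
#' model is linear in \eqn{\Delta H}, the enthalpy is profiled out analytically
#' and only \eqn{K_D} is optimised numerically (bounded 1-D search on
#' \eqn{\log_{10} K_D}).
#'
#' @param exp an \code{\link{itc_experiment}} with observed heats.
#' @param interval search interval for \eqn{K_D} (mM).
#' @return an object of class \code{itc_fit} with components \code{kd_mm},
#'   \code{dh_cal_mol}, \code{fitted}, \code{rss} and \code{unidentifiable}
#'   (TRUE when all heats are zero).
#' @examples
#' sim <- gen_itc(kd_true = 1.5, dh_true = -1000, seed = 2, noise_ucal = 0)
#' fit_itc(sim$experiment)
#' @export
fit_itc <- function(exp, interval = c(1e-4, 1e3)) {
  stopifnot(inherits(exp, "itc_experiment"))
  q <- exp$heats_ucal
  if (is.null(q)) stop("the experiment carries no observed heats")
  if (length(q) < 5L) stop("at least 5 injections are required")
  if (all(q == 0)) {
    fit <- list(kd_mm = NA_real_, dh_cal_mol = 0,
                fitted = rep(0, length(q)), rss = 0,
                unidentifiable = TRUE, experiment = exp)
    class(fit) <- "itc_fit"
    warning("all heats are zero: dH = 0 and K_D is unidentifiable")
    return(fit)
  }
  # per-injection heats at dH = 1; dH enters linearly
  shape <- function(log10_kd) itc_heats(exp, 10^log10_kd, 1)
  obj <- function(log10_kd) {
    g <- shape(log10_kd)
    dh <- sum(q * g) / sum(g * g)
    sum((q - dh * g)^2)
  }
  opt <- optimize(obj, interval = log10(interval), tol = 1e-10)
  kd <- 10^opt$minimum
  g <- shape(opt$minimum)
  dh <- sum(q * g) / sum(g * g)
  structure(list(kd_mm = kd, dh_cal_mol = dh, fitted = dh * g,
                 rss = sum((q - dh * g)^2), unidentifiable = FALSE,
                 experiment = exp),
            class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  cat("Single-site ITC fit (n fixed at 1)\n")
  if (x$unidentifiable) {
    cat("  all heats zero: dH = 0, K_D unidentifiable\n")
  } else {
    cat(sprintf("  K_D: %.4g mM,  dH: %.5g cal/mol,  RSS: %.4g µcal²\n",
                x$kd_mm, x$dh_cal_mol, x$rss))
  }
  invisible(x)
}

#' @export
coef.itc_fit <- function(object, ...)
  c(kd_mm = object$kd_mm, dh_cal_mol = object$dh_cal_mol)

#' @export
predict.itc_fit <- function(object, ...) object$fitted

#' @export
residuals.itc_fit <- function(object, ...)
  object$experiment$heats_ucal - object$fitted

#' @export
plot.itc_fit <- function(x, ...) {
  q <- x$experiment$heats_ucal
  plot(seq_along(q), q, pch = 16, xlab = "injection",
       ylab = "heat (µcal)", main = sprintf("ITC fit: K_D = %.3g mM", x$kd_mm), ...)
  lines(seq_along(q), x$fitted, col = "firebrick", lwd = 2)
  invisible(x)
}

#' Read/write an ITC injection-heat table
#'
#' Tab-separated with header \code{injection injection_ul heat_ucal} and
#' \code{#} comments carrying the protocol
#' (\code{# syringe_mm:}, \code{# cell_mm:}, \code{# cell_ul:}).
#'
#' @param path file to read.
#' @return an \code{\link{itc_experiment}}.
#' @export
read_itc_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("ITC table '%s' does not exist", path))
  lines <- readLines(path)
  get <- function(key) {
    ln <- grep(paste0("^#\\s*", key, ":"), lines, value = TRUE)
    if (!length(ln)) stop(sprintf("'%s': missing header '# %s:'", path, key))
    as.numeric(trimws(sub(".*:", "", ln[1])))
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  tab <- read.table(text = body, header = TRUE, sep = "\t")
  itc_experiment(injection_ul = tab$injection_ul, syringe_mm = get("syringe_mm"),
                 cell_mm = get("cell_mm"), cell_ul = get("cell_ul"),
                 heats_ucal = tab$heat_ucal)
}

#' @rdname read_itc_table
#' @param exp an \code{\link{itc_experiment}} with heats to write.
#' @export
write_itc_table <- function(exp, path) {
  stopifnot(inherits(exp, "itc_experiment"), !is.null(exp$heats_ucal))
  hdr <- c(sprintf("# syringe_mm: %.17g", exp$syringe_mm),
           sprintf("# cell_mm: %.17g", exp$cell_mm),
           sprintf("# cell_ul: %.17g", exp$cell_ul),
           paste("injection", "injection_ul", "heat_ucal", sep = "\t"))
  body <- paste(seq_along(exp$injection_ul),
                sprintf("%.17g", exp$injection_ul),
                sprintf("%.17g", exp$heats_ucal), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
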