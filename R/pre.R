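# Paramagnetic relaxation enhancement (PRE) intensity-ratio analysis.
#
# A nitroxide spin label (MTSL) attenuates the HSQC peaks of residues near
# the unpaired electron: PRE = I_para / I_dia per residue, where the
# diamagnetic analog provides the reference spectrum. Residues within about
# 10 A of the label are bleached completely; attenuation remains detectable
# out to about 25 A. The analysis here is deliberately qualitative - ratios
# and proximity classes, not fitted Gamma2 rates or distances.

#' PRE intensity ratios from paired para/diamagnetic peak tables
#'
#' Matches residues between the paramagnetic (MTSL) and diamagnetic
#' (MTSL-analog) peak tables and computes \code{ratio = I_para / I_dia} with
#' first-order error propagation of the spectral noise sd. Residues present
#' in only one table are reported with status \code{"missing"} (ratio NA),
#' except residues with good diamagnetic signal but absent from the
#' paramagnetic table, which are flagged \code{"candidate_bleached"}.
#' Residues whose diamagnetic intensity does not exceed the noise are
#' flagged unreliable.
#'
#' @param para,dia \code{\link{peak_table}}s for the paramagnetic and
#'   diamagnetic samples.
#' @param noise_sd spectral noise standard deviation (applies to both
#'   spectra), >= 0.
#' @param bleach_cut,attenuate_cut ratio thresholds passed to
#'   \code{\link{classify_proximity}}.
#' @param condition label for the profile (e.g. \code{"apo"} or
#'   \code{"bound"}); defaults to the paramagnetic table's condition.
#' @return a data frame of class \code{pre_profile} with columns
#'   \code{residue_id}, \code{ratio}, \code{ratio_sd}, \code{class},
#'   \code{reliable} and \code{status}.
#' @export
pre_profile <- function(para, dia, noise_sd = 0, bleach_cut = 0.1,
                        attenuate_cut = 0.85, condition = NULL) {
  stopifnot(inherits(para, "peak_table"), inherits(dia, "peak_table"))
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (is.null(condition)) condition <- attr(para, "condition")
  all_res <- sort(union(para$residue_id, dia$residue_id))
  ip <- match(all_res, para$residue_id)
  id <- match(all_res, dia$residue_id)
  i_para <- para$intensity[ip]
  i_dia <- dia$intensity[id]

  status <- rep("ok", length(all_res))
  status[is.na(ip) & !is.na(id) & !is.na(i_dia) & i_dia > 3 * noise_sd] <-
    "candidate_bleached"
  status[is.na(ip) & status != "candidate_bleached"] <- "missing"
  status[is.na(id)] <- "missing"

  matched <- status == "ok"
  if (any(matched & i_dia <= 0))
    stop("diamagnetic intensities must be positive for matched residues")
  ratio <- ratio_sd <- rep(NA_real_, length(all_res))
  ratio[matched] <- i_para[matched] / i_dia[matched]
  ratio_sd[matched] <- sqrt((noise_sd / i_dia[matched])^2 +
                            (i_para[matched] * noise_sd / i_dia[matched]^2)^2)
  reliable <- rep(NA, length(all_res))
  reliable[matched] <- i_dia[matched] > noise_sd

  cls <- rep(NA_character_, length(all_res))
  # noise can push a fully bleached peak's ratio slightly negative
  cls[matched] <- vapply(pmax(ratio[matched], 0), classify_proximity,
                         character(1), bleach_cut = bleach_cut,
                         attenuate_cut = attenuate_cut)
  cls[status == "candidate_bleached"] <- "bleached"

  out <- data.frame(residue_id = all_res, ratio = ratio, ratio_sd = ratio_sd,
                    class = cls, reliable = reliable, status = status,
                    stringsAsFactors = FALSE)
  attr(out, "condition") <- condition
  class(out) <- c("pre_profile", "data.frame")
  out
}

#' Classify spatial proximity to the spin label from a PRE ratio
#'
#' Operational thresholds on the intensity ratio: ratios below
#' \code{bleach_cut} (default 0.1) indicate a residue within roughly 10 A of
#' the label ("bleached"), ratios up to \code{attenuate_cut} (default 0.85)
#' indicate detectable proximity out to roughly 25 A ("attenuated"), and
#' higher ratios are "unaffected". The cut-offs are package
#' operationalisations of those distance statements and are configurable.
#'
#' @param ratio PRE intensity ratio, >= 0.
#' @param bleach_cut,attenuate_cut class boundaries, with
#'   \code{bleach_cut < attenuate_cut}.
#' @return \code{"bleached"}, \code{"attenuated"} or \code{"unaffected"}.
#' @export
classify_proximity <- function(ratio, bleach_cut = 0.1, attenuate_cut = 0.85) {
  if (is.na(ratio) || ratio < 0) stop("ratio must be non-negative")
  if (bleach_cut >= attenuate_cut) stop("bleach_cut must be below attenuate_cut")
  if (ratio < bleach_cut) "bleached"
  else if (ratio < attenuate_cut) "attenuated"
  else "unaffected"
}

#' Compare PRE profiles between two states
#'
#' Per-residue change in PRE ratio between two profiles from the same label
#' site (e.g. apo vs peptide-bound), with propagated uncertainties. Residues
#' whose change exceeds twice the combined sd are flagged \code{"closer"}
#' (ratio decreased: the residue approached the label) or \code{"farther"}
#' (ratio increased).
#'
#' @param apo,bound \code{\link{pre_profile}}s for the two states.
#' @return a data frame with columns \code{residue_id}, \code{ratio_apo},
#'   \code{ratio_bound}, \code{delta} (bound - apo), \code{delta_sd} and
#'   \code{flag} (\code{""}, \code{"closer"} or \code{"farther"}).
#' @export
compare_pre_states <- function(apo, bound) {
  stopifnot(inherits(apo, "pre_profile"), inherits(bound, "pre_profile"))
  common <- intersect(apo$residue_id[!is.na(apo$ratio)],
                      bound$residue_id[!is.na(bound$ratio)])
  if (!length(common)) {
    warning("the two profiles share no residues with ratios; empty comparison")
    return(data.frame(residue_id = integer(0), ratio_apo = numeric(0),
                      ratio_bound = numeric(0), delta = numeric(0),
                      delta_sd = numeric(0), flag = character(0)))
  }
  ia <- match(common, apo$residue_id)
  ib <- match(common, bound$residue_id)
  delta <- bound$ratio[ib] - apo$ratio[ia]
  delta_sd <- sqrt(apo$ratio_sd[ia]^2 + bound$ratio_sd[ib]^2)
  flag <- rep("", length(common))
  sig <- abs(delta) > 2 * delta_sd
  flag[sig & delta < 0] <- "closer"
  flag[sig & delta > 0] <- "farther"
  data.frame(residue_id = common, ratio_apo = apo$ratio[ia],
             ratio_bound = bound$ratio[ib], delta = delta,
             delta_sd = delta_sd, flag = flag, stringsAsFactors = FALSE)
}

#' @export
print.pre_profile <- function(x, ...) {
  cat(sprintf("<pre_profile> %s: %d residues (%d bleached, %d attenuated, %d unaffected, %d missing)\n",
              attr(x, "condition"), nrow(x),
              sum(x$class == "bleached", na.rm = TRUE),
              sum(x$class == "attenuated", na.rm = TRUE),
              sum(x$class == "unaffected", na.rm = TRUE),
              sum(x$status == "missing")))
  invisible(x)
}

#' @export
plot.pre_profile <- function(x, ...) {
  ok <- !is.na(x$ratio)
  plot(x$residue_id[ok], x$ratio[ok], type = "h", lwd = 2,
       xlab = "residue", ylab = "I_para / I_dia", ylim = c(0, max(1, x$ratio[ok])),
       main = sprintf("PRE profile (%s)", attr(x, "condition")), ...)
  abline(h = c(0.1, 0.85), lty = 3, col = "grey50")
  invisible(x)
}
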