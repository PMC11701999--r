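# Dosimetric predictors on differential DVHs.  All three metrics follow the
# mass-at-bin-dose convention: each differential bin's volume sits at its
# representative dose.  D_xcm3 interpolates linearly between adjacent points
# of the cumulative curve; V_D counts bins at or above the threshold.

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Generalized equivalent uniform dose (gEUD)
#'
#' Power-mean summary of a DVH, `EUD(n) = (sum_i v_i D_i^(1/n))^n` with
#' `v_i` the relative bin volumes.  The volume exponent `n` is the
#' Niemierko/Lyman volume parameter: `n = 1` gives the mean dose, small `n`
#' weights the hottest subvolume (serial-organ behavior; late rectal
#' bleeding models typically use n around 0.06-0.24).  Evaluated in
#' log-space so that very small `n` does not overflow.
#'
#' @param x a `dvh` object (physical or BED axis; the result is on the same
#'   axis).
#' @param n volume exponent, 0 < n <= 1.
#' @return gEUD in Gy; always between the mean and maximum bin dose.
#' @examples
#' d <- dvh(c(60, 80), c(30, 30))
#' eud(d, 1)    # mean dose, 70
#' eud(d, 0.1)  # 75.05, pulled toward the hot bin
#' @export
eud <- function(x, n) {
  stopifnot(inherits(x, "dvh"))
  if (length(n) != 1L || !is.finite(n) || n <= 0 || n > 1)
    stop("volume exponent `n` must lie in (0, 1]")
  if (x$total_volume <= 0) stop("DVH has zero total volume")
  keep <- x$bin_volume > 0
  v <- x$bin_volume[keep] / x$total_volume
  d <- x$bin_dose[keep]
  if (any(d == 0)) {
    # zero-dose bins contribute zero mass to the power sum
    v <- v[d > 0]; d <- d[d > 0]
    if (length(d) == 0L) return(0)
  }
  exp(n * logsumexp(log(v) + (1 / n) * log(d)))
}

#' Relative volume receiving at least a dose (V_D)
#'
#' Percentage of the organ volume in bins whose representative dose is at
#' or above `threshold` (inclusive).  Thresholds in this field are quoted
#' at one-decimal precision (e.g. V111.9, the BED of physical 70 Gy under
#' 39 x 2 Gy at alpha/beta = 3), so the comparison allows a small dose
#' tolerance, by default 0.05 Gy = half the printed precision.
#'
#' @param x a `dvh` object.
#' @param threshold dose threshold in Gy (same axis as the DVH), >= 0.
#' @param tol inclusive comparison tolerance in Gy.
#' @return volume percentage in `[0, 100]`; `v_d(x, 0)` is 100.
#' @export
v_d <- function(x, threshold, tol = 0.05) {
  stopifnot(inherits(x, "dvh"))
  if (length(threshold) != 1L || !is.finite(threshold) || threshold < 0)
    stop("`threshold` must be a single non-negative dose in Gy")
  if (x$total_volume <= 0) stop("DVH has zero total volume")
  100 * sum(x$bin_volume[x$bin_dose >= threshold - tol]) / x$total_volume
}

#' Minimum dose to the hottest x cm^3 (D_xcm3)
#'
#' The dose received by the most-exposed `x` cm^3 of the organ: the dose at
#' which the cumulative absolute-volume curve V(D) equals `x`, located by
#' linear interpolation between adjacent cumulative points.  Non-increasing
#' in `x`; `d_cc(x, total_volume(x))` is the minimum bin dose.
#'
#' @param x a `dvh` object.
#' @param volume_cm3 hottest volume in cm^3, 0 < volume_cm3 <= total volume.
#' @return dose in Gy on the DVH's axis.
#' @examples
#' d <- dvh(c(60, 70, 75), c(36, 3, 1))
#' d_cc(d, 2)  # 73.33: interpolated between V(70)=4 and V(75)=1
#' @export
d_cc <- function(x, volume_cm3) {
  stopifnot(inherits(x, "dvh"))
  if (length(volume_cm3) != 1L || !is.finite(volume_cm3) || volume_cm3 <= 0)
    stop("`volume_cm3` must be a single positive volume")
  if (x$total_volume <= 0) stop("DVH has zero total volume")
  if (volume_cm3 > x$total_volume * (1 + 1e-9))
    stop(sprintf(paste0("requested hottest volume (%.3g cm3) exceeds the ",
                        "organ volume (%.3g cm3)"),
         volume_cm3, x$total_volume))
  cum <- cumulative_dvh(x)
  keep <- x$bin_volume > 0            # flat cumulative segments carry no mass
  cum <- cum[keep, , drop = FALSE]
  k <- nrow(cum)
  if (volume_cm3 <= cum$cum_volume[k]) return(cum$dose[k])  # inside top bin
  # V is strictly decreasing over the kept points; invert by interpolation
  stats::approx(x = rev(cum$cum_volume), y = rev(cum$dose),
                xout = min(volume_cm3, cum$cum_volume[1]),
                ties = "ordered")$y
}

#' Dose-metric specification
#'
#' Names one candidate dosimetric predictor: a gEUD volume exponent, a V_D
#' threshold (Gy, BED axis), or a D_xcm3 hottest volume (cm^3).
#'
#' @param kind `"EUD"`, `"V_D"` or `"D_cc"`.
#' @param parameter the exponent n, the threshold in Gy, or the volume in
#'   cm^3 respectively.
#' @return An object of class `"dose_metric"`.
#' @examples
#' dose_metric("EUD", 0.1)
#' dose_metric("V_D", 111.9)
#' dose_metric("D_cc", 0.1)
#' @export
dose_metric <- function(kind = c("EUD", "V_D", "D_cc"), parameter) {
  kind <- match.arg(kind)
  if (length(parameter) != 1L || !is.finite(parameter) || parameter <= 0)
    stop("`parameter` must be a single positive number")
  if (kind == "EUD" && parameter > 1)
    stop("EUD volume exponent must lie in (0, 1]")
  structure(list(kind = kind, parameter = parameter), class = "dose_metric")
}

#' @export
print.dose_metric <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.dose_metric <- function(x, ...) {
  switch(x$kind,
         EUD = sprintf("EUD(n=%g)", x$parameter),
         V_D = sprintf("V%.1f", x$parameter),
         D_cc = sprintf("D_%gcm3", x$parameter))
}

#' Compute a dosimetric predictor from a physical-dose DVH
#'
#' Dispatch helper composing [bed_dvh()] with the metric named by a
#' [dose_metric()] spec: the DVH is BED-transformed under the patient's
#' fractionation scheme and assumed alpha/beta, then the gEUD, V_D or
#' D_xcm3 is evaluated on the BED axis.
#'
#' @param x a `dvh` with physical dose axis.
#' @param spec a [dose_metric()].
#' @inheritParams physical_to_bed
#' @param dose_scale `"bed"` (default) or `"physical"` to skip the BED
#'   transform (used by the sensitivity analysis to demonstrate that
#'   physical-dose metrics do not transfer across fractionation schedules).
#' @return gEUD or D_xcm3 in Gy (BED), or V_D in percent.
#' @export
compute_metric <- function(x, spec, scheme, alpha_beta = 3,
                           dose_scale = c("bed", "physical")) {
  stopifnot(inherits(x, "dvh"), inherits(spec, "dose_metric"))
  dose_scale <- match.arg(dose_scale)
  if (x$dose_kind != "physical")
    stop("compute_metric expects a physical-dose DVH")
  y <- if (dose_scale == "bed") bed_dvh(x, scheme, alpha_beta) else x
  switch(spec$kind,
         EUD = eud(y, spec$parameter),
         V_D = v_d(y, spec$parameter),
         D_cc = d_cc(y, spec$parameter))
}
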