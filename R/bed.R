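#' Fractionation scheme
#'
#' A radiotherapy prescription: total physical dose delivered in a fixed
#' number of equal fractions.  Under the linear-quadratic model the dose
#' per fraction of a voxel receiving total dose D is D / n_fractions.
#'
#' @param n_fractions positive integer number of fractions.
#' @param prescribed_dose total prescribed physical dose in Gy.
#' @return An object of class `"fractionation"` with fields `n_fractions`,
#'   `prescribed_dose` and `dose_per_fraction`.
#' @examples
#' scheme_cf()  # 78 Gy in 39 x 2 Gy
#' scheme_hf()  # 64.6 Gy in 19 x 3.4 Gy
#' @export
fractionation <- function(n_fractions, prescribed_dose) {
  if (length(n_fractions) != 1L || n_fractions < 1 ||
      n_fractions != round(n_fractions))
    stop("`n_fractions` must be a single positive integer")
  if (length(prescribed_dose) != 1L || !is.finite(prescribed_dose) ||
      prescribed_dose <= 0)
    stop("`prescribed_dose` must be a single positive dose in Gy")
  structure(
    list(n_fractions = as.integer(n_fractions),
         prescribed_dose = as.numeric(prescribed_dose),
         dose_per_fraction = prescribed_dose / n_fractions),
    class = "fractionation"
  )
}

#' @rdname fractionation
#' @export
scheme_cf <- function() fractionation(39L, 78)

#' @rdname fractionation
#' @export
scheme_hf <- function() fractionation(19L, 64.6)

#' @export
print.fractionation <- function(x, ...) {
  cat(sprintf("%g Gy in %d fractions of %.3g Gy\n", x$prescribed_dose,
              x$n_fractions, x$dose_per_fraction))
  invisible(x)
}

check_alpha_beta <- function(alpha_beta) {
  if (length(alpha_beta) != 1L || !is.finite(alpha_beta) || alpha_beta <= 0)
    stop("`alpha_beta` must be a single positive value in Gy")
  alpha_beta
}

#' Physical dose to biologically effective dose (BED)
#'
#' Linear-quadratic conversion of a voxel's total physical dose to BED:
#' `BED = D * (1 + d / (alpha/beta))` where `d = D / n_fractions` is the
#' voxel's dose per fraction.  Makes doses delivered under different
#' fractionation schedules comparable; the late-rectum default is
#' alpha/beta = 3 Gy.
#'
#' @param total_dose voxel total physical dose in Gy (vectorized, >= 0).
#' @param scheme a [fractionation()] scheme supplying the fraction count.
#' @param alpha_beta tissue alpha/beta ratio in Gy (default 3).
#' @return BED in Gy, same length as `total_dose`; strictly increasing in
#'   dose and always >= the physical dose.
#' @examples
#' physical_to_bed(70, scheme_cf())       # 111.9 Gy at 1 d.p.
#' physical_to_bed(75, scheme_cf(), 2)    # 147.1 Gy at 1 d.p.
#' @export
physical_to_bed <- function(total_dose, scheme, alpha_beta = 3) {
  stopifnot(inherits(scheme, "fractionation"))
  check_alpha_beta(alpha_beta)
  if (any(!is.finite(total_dose)) || any(total_dose < 0))
    stop("`total_dose` must be finite and non-negative")
  total_dose * (1 + (total_dose / scheme$n_fractions) / alpha_beta)
}

#' BED-transform a DVH
#'
#' Map every bin dose of a physical-dose differential DVH through
#' [physical_to_bed()].  The conversion is strictly monotone in dose for a
#' fixed scheme and alpha/beta, so bin membership, bin volumes and the
#' total volume are unchanged; only the dose axis moves.
#'
#' @param x a `dvh` with `dose_kind = "physical"`.
#' @inheritParams physical_to_bed
#' @return a `dvh` with `dose_kind = "bed"`.
#' @export
bed_dvh <- function(x, scheme, alpha_beta = 3) {
  stopifnot(inherits(x, "dvh"))
  if (x$dose_kind != "physical")
    stop("input DVH is already on a BED axis")
  out <- x
  out$bin_dose <- physical_to_bed(x$bin_dose, scheme, alpha_beta)
  out$dose_kind <- "bed"
  out
}

#' Prescription-BED crossover alpha/beta
#'
#' The alpha/beta ratio at which two fractionation schemes deliver the same
#' prescription BED, from `D_a (1 + d_a/x) = D_b (1 + d_b/x)`:
#' `x = (D_a d_a - D_b d_b) / (D_b - D_a)`.  Below the crossover the
#' larger-dose-per-fraction scheme has the higher BED.  For the pooled
#' trial arms (78 Gy / 39 fx vs 64.6 Gy / 19 fx) the crossover is 4.7 Gy.
#'
#' @param scheme_a,scheme_b two distinct [fractionation()] schemes.
#' @return the positive crossover alpha/beta in Gy, or `NA_real_` (with a
#'   `"reason"` attribute) when no positive solution exists, e.g. equal
#'   total doses with unequal fraction doses.
#' @examples
#' alpha_beta_crossover(scheme_cf(), scheme_hf())  # 4.7 at 1 d.p.
#' @export
alpha_beta_crossover <- function(scheme_a, scheme_b) {
  stopifnot(inherits(scheme_a, "fractionation"),
            inherits(scheme_b, "fractionation"))
  Da <- scheme_a$prescribed_dose; da <- scheme_a$dose_per_fraction
  Db <- scheme_b$prescribed_dose; db <- scheme_b$dose_per_fraction
  if (isTRUE(all.equal(Da, Db)) && isTRUE(all.equal(da, db)))
    stop("schemes are identical: crossover alpha/beta is undefined")
  if (isTRUE(all.equal(Da, Db)))
    return(structure(NA_real_, reason = "equal total doses: no positive crossover"))
  x <- (Da * da - Db * db) / (Db - Da)
  if (!is.finite(x) || x <= 0)
    return(structure(NA_real_, reason = "no positive crossover"))
  x
}
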