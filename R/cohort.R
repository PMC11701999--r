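#' Toxicity follow-up visits
#'
#' Builds the per-patient longitudinal toxicity table.  Each visit carries
#' the month of follow-up, whether the case report form recorded any
#' medication or medical intervention for rectal bleeding, and the
#' patient-reported bleeding score on the 4-level questionnaire scale
#' ("none" < "little" < "moderate" < "severe"; `NA` = missing).
#'
#' @param month follow-up months (scheduled visits are 6/12/24/36/48/60).
#' @param crf_intervention logical: bleeding intervention on the CRF.
#' @param questionnaire character/factor on the 4-level scale, or `NA`.
#' @return data.frame with class-checked columns, sorted by month.
#' @export
toxicity_visits <- function(month, crf_intervention, questionnaire) {
  levs <- c("none", "little", "moderate", "severe")
  if (any(!is.na(questionnaire) & !questionnaire %in% levs))
    stop("questionnaire scores must be one of: ", paste(levs, collapse = ", "))
  if (any(month <= 0)) stop("visit months must be positive")
  out <- data.frame(
    month = as.numeric(month),
    crf_intervention = as.logical(crf_intervention),
    questionnaire = factor(questionnaire, levels = levs, ordered = TRUE)
  )
  out[order(out$month), , drop = FALSE]
}

#' Patient record
#'
#' One trial patient: arm assignment with its fractionation scheme, the
#' planned rectal DVH, the prior-abdominal-surgery covariate, longitudinal
#' toxicity visits, and censoring information.
#'
#' @param patient_id unique identifier (character or integer).
#' @param arm `"CF"` (conventional, 39 x 2 Gy) or `"HF"` (hypofractionated,
#'   19 x 3.4 Gy); must match `scheme`.
#' @param scheme a [fractionation()]; defaults to the arm's trial scheme.
#' @param dvh a [dvh()] with physical dose axis, or `NULL` when no 3D
#'   planning data exist (the patient is then dropped by
#'   [eligibility_filter()]).
#' @param abd_surg logical: history of abdominal surgery.
#' @param visits a [toxicity_visits()] data.frame.
#' @param recurrence_month month of clinical recurrence, or `NA`.
#' @param hemorrhoid_attribution logical: bleeding adjudicated as caused by
#'   severe hemorrhoids (excluded from the endpoint).
#' @param last_followup_month last month with follow-up contact.
#' @return An object of class `"patient_record"`.
#' @export
patient_record <- function(patient_id, arm = c("CF", "HF"), scheme = NULL,
                           dvh = NULL, abd_surg = FALSE,
                           visits = toxicity_visits(numeric(), logical(),
                                                    character()),
                           recurrence_month = NA_real_,
                           hemorrhoid_attribution = FALSE,
                           last_followup_month = 60) {
  arm <- match.arg(arm)
  if (is.null(scheme)) scheme <- if (arm == "CF") scheme_cf() else scheme_hf()
  stopifnot(inherits(scheme, "fractionation"))
  expected_fx <- if (arm == "CF") 39L else 19L
  if (scheme$n_fractions != expected_fx)
    stop(sprintf("arm %s requires %d fractions, got %d",
                 arm, expected_fx, scheme$n_fractions))
  if (!is.null(dvh)) stopifnot(inherits(dvh, "dvh"))
  if (!is.na(recurrence_month) && recurrence_month > last_followup_month)
    stop("recurrence_month cannot exceed last_followup_month")
  structure(
    list(patient_id = as.character(patient_id), arm = arm, scheme = scheme,
         dvh = dvh, abd_surg = isTRUE(abd_surg), visits = visits,
         recurrence_month = as.numeric(recurrence_month),
         hemorrhoid_attribution = isTRUE(hemorrhoid_attribution),
         last_followup_month = as.numeric(last_followup_month)),
    class = "patient_record"
  )
}

#' Cohort of patient records
#'
#' @param patients list of [patient_record()]s with unique ids.
#' @param provenance free-form list recording where the cohort came from
#'   (generator preset and seed, or source file paths).
#' @return An object of class `"ntcp_cohort"`.
#' @export
ntcp_cohort <- function(patients, provenance = list()) {
  if (length(patients) == 0L) stop("cohort must contain at least one patient")
  ids <- vapply(patients, function(p) p$patient_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate patient_id: ",
                               ids[duplicated(ids)][1])
  structure(list(patients = patients, provenance = provenance),
            class = "ntcp_cohort")
}

#' @export
print.ntcp_cohort <- function(x, ...) {
  arms <- table(vapply(x$patients, function(p) p$arm, character(1)))
  cat(sprintf("NTCP cohort: %d patients (CF %d, HF %d)\n",
              length(x$patients),
              if ("CF" %in% names(arms)) arms[["CF"]] else 0L,
              if ("HF" %in% names(arms)) arms[["HF"]] else 0L))
  invisible(x)
}

#' @export
length.ntcp_cohort <- function(x) length(x$patients)

#' Score the grade >=2 late rectal bleeding endpoint
#'
#' A patient is an event when, among visits up to `horizon_months` and not
#' after clinical recurrence, (a) the case report form records any
#' bleeding medication or intervention, or (b) "moderate" bleeding is
#' reported on at least two questionnaires at distinct visits, or (c)
#' "severe" bleeding on at least one questionnaire.  Bleeding adjudicated
#' as caused by severe hemorrhoids is never an event.  Missing
#' questionnaires are non-informative.
#'
#' @param record a [patient_record()].
#' @param horizon_months scoring horizon (default 60).
#' @return logical; attribute `"reason"` is one of `"crf"`,
#'   `"questionnaire"`, `"none"`, `"hemorrhoid"`.
#' @export
score_g2_lrb <- function(record, horizon_months = 60) {
  stopifnot(inherits(record, "patient_record"))
  if (record$hemorrhoid_attribution)
    return(structure(FALSE, reason = "hemorrhoid"))
  v <- record$visits
  keep <- v$month <= horizon_months
  if (!is.na(record$recurrence_month))
    keep <- keep & v$month <= record$recurrence_month
  v <- v[keep, , drop = FALSE]
  if (nrow(v) == 0L) return(structure(FALSE, reason = "none"))
  if (any(v$crf_intervention, na.rm = TRUE))
    return(structure(TRUE, reason = "crf"))
  q <- v$questionnaire
  n_moderate <- length(unique(v$month[!is.na(q) & q == "moderate"]))
  n_severe <- sum(!is.na(q) & q == "severe")
  if (n_severe >= 1L || n_moderate >= 2L)
    return(structure(TRUE, reason = "questionnaire"))
  structure(FALSE, reason = "none")
}

#' Eligibility filter
#'
#' Retains patients with at least 12 months of follow-up, no clinical
#' recurrence before month 12, at least one visit after month 12 carrying
#' a toxicity evaluation (a non-missing CRF field or questionnaire), and
#' available 3D planning data (a DVH).
#'
#' @param cohort an [ntcp_cohort()].
#' @return list with `cohort` (the retained subset) and `exclusions`, a
#'   data.frame of `patient_id` and `reason` for every dropped patient.
#' @export
eligibility_filter <- function(cohort) {
  stopifnot(inherits(cohort, "ntcp_cohort"))
  reason_of <- function(p) {
    if (is.null(p$dvh)) return("no_3d_planning_data")
    if (p$last_followup_month < 12) return("followup<12m")
    if (!is.na(p$recurrence_month) && p$recurrence_month < 12)
      return("recurrence<12m")
    v <- p$visits
    evaluated <- v$month > 12 &
      (!is.na(v$crf_intervention) | !is.na(v$questionnaire))
    if (!any(evaluated)) return("no_toxicity_evaluation_after_12m")
    NA_character_
  }
  reasons <- vapply(cohort$patients, reason_of, character(1))
  keep <- is.na(reasons)
  exclusions <- data.frame(
    patient_id = vapply(cohort$patients[!keep],
                        function(p) p$patient_id, character(1)),
    reason = reasons[!keep],
    stringsAsFactors = FALSE
  )
  if (!any(keep)) stop("no patients remain after eligibility filtering")
  list(cohort = ntcp_cohort(cohort$patients[keep],
                            provenance = cohort$provenance),
       exclusions = exclusions)
}

#' Events-per-variable adequacy check
#'
#' The conventional rule of thumb for logistic prediction models: at least
#' 10 events per candidate predictor.
#'
#' @param n_events number of events.
#' @param n_candidate_predictors number of candidate predictors (>= 1).
#' @return list with `epv` and logical `pass`; warns when EPV < 10.
#' @export
epv_check <- function(n_events, n_candidate_predictors) {
  if (n_candidate_predictors <= 0)
    stop("`n_candidate_predictors` must be positive")
  if (n_events < 0) stop("`n_events` must be non-negative")
  epv <- n_events / n_candidate_predictors
  pass <- epv >= 10
  if (!pass)
    warning(sprintf("events per variable = %.1f is below the 10 EPV rule",
                    epv))
  list(epv = epv, pass = pass)
}

#' Read / write a cohort as plain-text files
#'
#' The on-disk layout is a patient table CSV
#' (`patient_id,arm,n_fractions,prescribed_dose_gy,abd_surg,
#' recurrence_month,last_followup_month,hemorrhoid_attribution`), a
#' long-format visits CSV (`patient_id,month,crf_intervention,
#' questionnaire_score`) and one DVH CSV per patient named
#' `<patient_id>.csv` in `dvh_dir` (see [read_dvh()]).  Numeric fields
#' round-trip at full double precision.  A patient whose DVH file is
#' missing is loaded with `dvh = NULL` (later removed by
#' [eligibility_filter()]).
#'
#' @param dir directory holding `patients.csv`, `visits.csv` and `dvh/`.
#' @param cohort an [ntcp_cohort()].
#' @return [read_cohort()] returns an `ntcp_cohort`; [write_cohort()]
#'   returns `dir` invisibly.
#' @export
read_cohort <- function(dir) {
  pt_path <- file.path(dir, "patients.csv")
  vs_path <- file.path(dir, "visits.csv")
  tab <- utils::read.csv(pt_path, stringsAsFactors = FALSE,
                         colClasses = c(patient_id = "character"))
  need <- c("patient_id", "arm", "n_fractions", "prescribed_dose_gy",
            "abd_surg", "recurrence_month", "last_followup_month",
            "hemorrhoid_attribution")
  if (!all(need %in% names(tab)))
    stop("patient table misses columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  if (anyDuplicated(tab$patient_id))
    stop("duplicate patient_id in ", pt_path, ": ",
         tab$patient_id[duplicated(tab$patient_id)][1])
  vis <- utils::read.csv(vs_path, stringsAsFactors = FALSE,
                         colClasses = c(patient_id = "character"))
  patients <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    if (!row$arm %in% c("CF", "HF"))
      stop(sprintf("malformed patient table row %d: unknown arm '%s'",
                   i, row$arm))
    dvh_path <- file.path(dir, "dvh", paste0(row$patient_id, ".csv"))
    d <- if (file.exists(dvh_path)) read_dvh(dvh_path) else NULL
    vr <- vis[vis$patient_id == row$patient_id, , drop = FALSE]
    qs <- as.character(vr$questionnaire_score)
    qs[!is.na(qs) & qs == ""] <- NA_character_
    patient_record(
      patient_id = row$patient_id, arm = row$arm,
      scheme = fractionation(row$n_fractions, row$prescribed_dose_gy),
      dvh = d, abd_surg = as.logical(row$abd_surg),
      visits = toxicity_visits(vr$month, as.logical(vr$crf_intervention), qs),
      recurrence_month = row$recurrence_month,
      hemorrhoid_attribution = as.logical(row$hemorrhoid_attribution),
      last_followup_month = row$last_followup_month)
  })
  ntcp_cohort(patients, provenance = list(source = normalizePath(dir)))
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ntcp_cohort"))
  dir.create(file.path(dir, "dvh"), recursive = TRUE, showWarnings = FALSE)
  num <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  pt <- data.frame(
    patient_id = vapply(cohort$patients, `[[`, character(1), "patient_id"),
    arm = vapply(cohort$patients, `[[`, character(1), "arm"),
    n_fractions = vapply(cohort$patients,
                         function(p) p$scheme$n_fractions, integer(1)),
    prescribed_dose_gy = num(vapply(cohort$patients,
                            function(p) p$scheme$prescribed_dose, numeric(1))),
    abd_surg = vapply(cohort$patients, `[[`, logical(1), "abd_surg"),
    recurrence_month = num(vapply(cohort$patients, `[[`, numeric(1),
                                  "recurrence_month")),
    last_followup_month = num(vapply(cohort$patients, `[[`, numeric(1),
                                     "last_followup_month")),
    hemorrhoid_attribution = vapply(cohort$patients, `[[`, logical(1),
                                    "hemorrhoid_attribution"),
    stringsAsFactors = FALSE
  )
  utils::write.csv(pt, file.path(dir, "patients.csv"), row.names = FALSE,
                   quote = FALSE)
  vis <- do.call(rbind, lapply(cohort$patients, function(p) {
    if (nrow(p$visits) == 0L) return(NULL)
    data.frame(patient_id = p$patient_id,
               month = num(p$visits$month),
               crf_intervention = p$visits$crf_intervention,
               questionnaire_score = ifelse(is.na(p$visits$questionnaire), "",
                                            as.character(p$visits$questionnaire)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(vis))
    vis <- data.frame(patient_id = character(), month = character(),
                      crf_intervention = logical(),
                      questionnaire_score = character())
  utils::write.csv(vis, file.path(dir, "visits.csv"), row.names = FALSE,
                   quote = FALSE)
  for (p in cohort$patients)
    if (!is.null(p$dvh))
      write_dvh(p$dvh, file.path(dir, "dvh", paste0(p$patient_id, ".csv")))
  invisible(dir)
}
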