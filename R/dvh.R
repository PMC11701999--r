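#' Differential dose-volume histogram
#'
#' Construct a differential DVH: a set of strictly increasing
#' bin-representative doses with the absolute volume (cm^3) found in each
#' bin.  Cumulative input (volume receiving at least each dose) is accepted
#' via `kind = "cumulative"` and differenced on construction.  The dose axis
#' is tagged as physical Gy or BED Gy; dosimetric predictors are defined on
#' the BED axis (see [bed_dvh()]).
#'
#' @param dose numeric vector of bin doses in Gy, strictly increasing.
#' @param volume numeric vector of volumes in cm^3, same length as `dose`.
#'   Differential volumes must be non-negative; cumulative volumes must be
#'   non-increasing.
#' @param dose_kind `"physical"` (default) or `"bed"`.
#' @param kind `"differential"` (default) or `"cumulative"` input flavor.
#' @return An object of class `"dvh"` with fields `bin_dose`, `bin_volume`
#'   (differential, cm^3), `dose_kind` and `total_volume`.
#' @examples
#' d <- dvh(c(60, 80), c(30, 30))
#' total_volume(d)
#' @export
dvh <- function(dose, volume, dose_kind = c("physical", "bed"),
                kind = c("differential", "cumulative")) {
  dose_kind <- match.arg(dose_kind)
  kind <- match.arg(kind)
  if (length(dose) == 0L) stop("empty DVH: at least one bin is required")
  if (length(dose) != length(volume))
    stop("`dose` and `volume` must have equal length")
  if (anyNA(dose) || anyNA(volume)) stop("DVH dose/volume must not contain NA")
  if (any(dose < 0)) stop("bin doses must be non-negative")
  if (is.unsorted(dose, strictly = TRUE))
    stop("bin doses must be strictly increasing")
  if (kind == "cumulative") {
    if (any(diff(volume) > 1e-9 * max(volume, 1)))
      stop("cumulative volumes must be non-increasing in dose")
    # volume in the last bin is everything still at/above the last dose
    volume <- c(-diff(volume), volume[length(volume)])
  }
  if (any(volume < -1e-12)) stop("bin volumes must be non-negative")
  volume <- pmax(volume, 0)
  structure(
    list(bin_dose = as.numeric(dose), bin_volume = as.numeric(volume),
         dose_kind = dose_kind, total_volume = sum(volume)),
    class = "dvh"
  )
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("Differential DVH (%s dose): %d bins, %.2f cm3, %.1f-%.1f Gy\n",
              x$dose_kind, length(x$bin_dose), x$total_volume,
              min(x$bin_dose), max(x$bin_dose)))
  invisible(x)
}

#' @rdname dvh
#' @param x a `dvh` object.
#' @export
total_volume <- function(x) {
  stopifnot(inherits(x, "dvh"))
  x$total_volume
}

#' Cumulative dose-volume curve
#'
#' Absolute volume (cm^3) receiving at least each bin dose, the
#' non-increasing curve V(D) derived from the differential histogram.
#'
#' @param x a `dvh` object.
#' @return data.frame with columns `dose` and `cum_volume`; `cum_volume[1]`
#'   equals the total volume.
#' @export
cumulative_dvh <- function(x) {
  stopifnot(inherits(x, "dvh"))
  data.frame(dose = x$bin_dose,
             cum_volume = rev(cumsum(rev(x$bin_volume))))
}

#' Read / write a DVH CSV file
#'
#' Plain-text DVH interchange: a metadata line `# dvh_kind: differential`
#' or `# dvh_kind: cumulative`, then a header `dose_gy,volume_cm3`
#' (differential) or `dose_gy,cum_volume_cm3` (cumulative) and one row per
#' bin.  Doses are physical Gy.  Files written by [write_dvh()] round-trip
#' numerics at full double precision.
#'
#' @param path file path.
#' @return [read_dvh()] returns a `dvh` object (always stored
#'   differentially); [write_dvh()] returns `path` invisibly.
#' @export
read_dvh <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("malformed DVH file: ", path)
  kind <- "differential"
  if (grepl("^#", lines[1])) {
    m <- regmatches(lines[1], regexec("dvh_kind:\\s*(\\w+)", lines[1]))[[1]]
    if (length(m) == 2L) kind <- m[2]
    lines <- lines[-1]
  }
  tab <- utils::read.csv(text = lines, stringsAsFactors = FALSE)
  if (kind == "cumulative") {
    if (!all(c("dose_gy", "cum_volume_cm3") %in% names(tab)))
      stop("cumulative DVH file needs columns dose_gy,cum_volume_cm3: ", path)
    dvh(tab$dose_gy, tab$cum_volume_cm3, kind = "cumulative")
  } else {
    if (!all(c("dose_gy", "volume_cm3") %in% names(tab)))
      stop("differential DVH file needs columns dose_gy,volume_cm3: ", path)
    dvh(tab$dose_gy, tab$volume_cm3)
  }
}

#' @rdname read_dvh
#' @param x a `dvh` object with physical dose axis.
#' @export
write_dvh <- function(x, path) {
  stopifnot(inherits(x, "dvh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# dvh_kind: differential", con)
  writeLines("dose_gy,volume_cm3", con)
  writeLines(paste(sprintf("%.17g", x$bin_dose),
                   sprintf("%.17g", x$bin_volume), sep = ","), con)
  invisible(path)
}
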