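#' Extracellular flux time series for one well
#'
#' Holds OCR (pmol O2/min) and ECAR (mpH/min) measurements over time
#' for a single well, with the per-well protein mass used for
#' normalization.
#'
#' @param time_min measurement times in minutes, strictly increasing.
#' @param ocr oxygen consumption rate at each time point.
#' @param ecar extracellular acidification rate at each time point
#'   (optional; NA if not measured).
#' @param protein_ug protein mass in the well, micrograms.
#' @param well well identifier.
#' @param condition experimental condition label.
#' @return An object of class `flux_time_series`.
#' @export
flux_time_series <- function(time_min, ocr, ecar = rep(NA_real_,
                             length(time_min)), protein_ug,
                             well = "A1", condition = NA_character_) {
  time_min <- as.numeric(time_min)
  if (length(time_min) < 2L || any(diff(time_min) <= 0))
    stop("timepoints must be strictly increasing", call. = FALSE)
  if (length(ocr) != length(time_min) || length(ecar) != length(time_min))
    stop("ocr/ecar must match the timepoints in length", call. = FALSE)
  if (!is.finite(protein_ug) || protein_ug <= 0)
    stop("protein mass must be positive", call. = FALSE)
  structure(
    list(well = well, condition = condition,
         time_min = time_min, ocr = as.numeric(ocr),
         ecar = as.numeric(ecar), protein_ug = protein_ug),
    class = "flux_time_series"
  )
}

#' Injection schedule for a mitochondrial stress test
#'
#' Ordered injection events. Compound names are canonicalized:
#' `rotenone`, `antimycin`, and `rotenone/antimycin` are treated as the
#' same electron-transport-chain block (`etc_block`), since either
#' reveals non-mitochondrial OCR.
#'
#' @param time_min injection times, strictly increasing.
#' @param compound compound names: `oligomycin`, `fccp`, or an ETC
#'   blocker (`rotenone`/`antimycin`).
#' @param concentration optional concentrations (free text or numeric).
#' @return An object of class `injection_schedule`.
#' @export
injection_schedule <- function(time_min, compound,
                               concentration = rep(NA, length(time_min))) {
  time_min <- as.numeric(time_min)
  if (length(time_min) && any(diff(time_min) <= 0))
    stop("injection times must be strictly increasing", call. = FALSE)
  if (length(compound) != length(time_min))
    stop("one compound per injection time", call. = FALSE)
  structure(
    list(time_min = time_min,
         compound = canonical_compound(compound),
         concentration = concentration),
    class = "injection_schedule"
  )
}

canonical_compound <- function(x) {
  x <- tolower(trimws(x))
  x[grepl("rotenone|antimycin|etc", x)] <- "etc_block"
  x[grepl("fccp", x)] <- "fccp"
  x[grepl("oligomycin", x)] <- "oligomycin"
  ok <- c("oligomycin", "fccp", "etc_block")
  if (any(!x %in% ok))
    stop("unknown injection compound: ",
         paste(setdiff(x, ok), collapse = ", "), call. = FALSE)
  x
}

#' Read an injection schedule from YAML
#'
#' Expects a list of events each with `time`, `compound`, and
#' optionally `concentration`.
#'
#' @param path path to a YAML file.
#' @return An [injection_schedule()].
#' @export
read_injection_schedule <- function(path) {
  raw <- yaml::read_yaml(path)
  injection_schedule(
    time_min = vapply(raw, function(e) as.numeric(e$time), numeric(1)),
    compound = vapply(raw, function(e) as.character(e$compound),
                      character(1)),
    concentration = vapply(raw, function(e)
      if (is.null(e$concentration)) NA_character_
      else as.character(e$concentration), character(1))
  )
}

#' Derive stress-test bioenergetics from a flux time series
#'
#' Splits the series at the injection times and summarizes each segment
#' by the mean of its last `window` measurements (discarding mixing
#' transients). From the segment plateaus it derives, per microgram of
#' protein:
#' \describe{
#'   \item{nonmito_ocr}{post-ETC-block plateau (non-mitochondrial OCR)}
#'   \item{basal_ocr_raw}{pre-injection plateau, uncorrected}
#'   \item{basal_ocr}{pre-injection plateau minus non-mitochondrial OCR}
#'   \item{maximal_ocr}{post-FCCP plateau minus non-mitochondrial OCR}
#'   \item{reserve_ocr}{maximal minus basal}
#'   \item{basal_ecar}{pre-injection ECAR plateau}
#' }
#' Both the raw and the non-mitochondria-corrected basal OCR are
#' reported. Metrics whose segment is missing from the schedule are NA;
#' negative derived rates are floored at zero with a warning.
#'
#' @param series a [flux_time_series()].
#' @param schedule an [injection_schedule()].
#' @param window number of trailing measurements averaged per segment.
#' @return Named list of metrics (NA where not derivable).
#' @export
derive_bioenergetics <- function(series, schedule, window = 3L) {
  stopifnot(inherits(series, "flux_time_series"),
            inherits(schedule, "injection_schedule"))
  if (length(schedule$time_min) &&
      (min(schedule$time_min) <= min(series$time_min) ||
       max(schedule$time_min) > max(series$time_min)))
    stop("injection times must fall within the measurement range",
         call. = FALSE)

  bounds <- c(-Inf, schedule$time_min, Inf)
  seg_of <- findInterval(series$time_min, bounds, left.open = TRUE)
  seg_labels <- c("baseline", schedule$compound)

  plateau <- function(label, signal) {
    k <- match(label, seg_labels)
    if (is.na(k)) return(NA_real_)
    idx <- which(seg_of == k)
    if (length(idx) < window)
      stop(sprintf("segment '%s' has fewer than %d measurements",
                   label, window), call. = FALSE)
    mean(signal[utils::tail(idx, window)])
  }

  p <- series$protein_ug
  nonmito <- plateau("etc_block", series$ocr)
  basal_raw <- plateau("baseline", series$ocr)
  maximal_raw <- plateau("fccp", series$ocr)
  ecar_raw <- plateau("baseline", series$ecar)

  basal <- if (is.na(basal_raw) || is.na(nonmito)) NA_real_
           else basal_raw - nonmito
  maximal <- if (is.na(maximal_raw) || is.na(nonmito)) NA_real_
             else maximal_raw - nonmito
  reserve <- if (is.na(maximal) || is.na(basal)) NA_real_
             else maximal - basal

  out <- list(
    basal_ocr = basal / p,
    basal_ocr_raw = basal_raw / p,
    maximal_ocr = maximal / p,
    reserve_ocr = reserve / p,
    nonmito_ocr = nonmito / p,
    basal_ecar = ecar_raw / p
  )
  neg <- vapply(out, function(v) isTRUE(v < 0), logical(1))
  if (any(neg)) {
    warning("negative derived rates floored at zero: ",
            paste(names(out)[neg], collapse = ", "), call. = FALSE)
    out[neg] <- 0
  }
  out
}

#' Read Seahorse-style flux measurements from CSV
#'
#' Expects columns `well`, `condition`, `time_min`, `ocr`, `ecar`,
#' `protein_ug` (one row per well and time point).
#'
#' @param path CSV path.
#' @return A list of [flux_time_series()], one per well.
#' @export
read_flux_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "time_min", "ocr", "protein_ug")
  if (!all(need %in% names(df)))
    stop("flux CSV must contain columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  if (!"ecar" %in% names(df)) df$ecar <- NA_real_
  if (!"condition" %in% names(df)) df$condition <- NA_character_
  lapply(split(df, df$well), function(d) {
    d <- d[order(d$time_min), ]
    flux_time_series(d$time_min, d$ocr, d$ecar,
                     protein_ug = d$protein_ug[1],
                     well = d$well[1], condition = d$condition[1])
  })
}
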