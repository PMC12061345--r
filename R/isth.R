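#' @title Quantitative ISTH adjudication of major bleeding
#'
#' @description
#' Major bleeding follows the ISTH definition: fatal or symptomatic bleeding
#' in a critical area or organ, or bleeding causing a fall in hemoglobin of
#' >= 2 g/dL, or transfusion of >= 2 units of erythrocyte concentrate. The
#' adjudicator combines the hemoglobin laboratory series, structured
#' transfusion records, and a text-pattern critical-site detector, and also
#' supplies the catalog's category-3 ("structured recognition") feature.
#' Fatal bleeding is out of detection scope (the schema carries no death
#' records); missing data conservatively leaves the corresponding criterion
#' false.
#'
#' @name isth-rule
NULL

#' ISTH decision thresholds
#'
#' @param hb_drop_threshold hemoglobin fall threshold in g/dL (default 2.0,
#'   i.e. 20 g/L; the comparison is inclusive)
#' @param rbc_units_threshold erythrocyte-unit threshold (default 2.0,
#'   inclusive)
#' @param ml_per_unit mL per erythrocyte unit for converting volume-recorded
#'   transfusions (default 200, the Chinese blood-banking convention)
#' @return an `isth_thresholds` list
#' @export
isth_thresholds <- function(hb_drop_threshold = 2.0,
                            rbc_units_threshold = 2.0,
                            ml_per_unit = 200) {
  stopifnot(hb_drop_threshold > 0, rbc_units_threshold > 0, ml_per_unit > 0)
  structure(list(hb_drop_threshold = hb_drop_threshold,
                 rbc_units_threshold = rbc_units_threshold,
                 ml_per_unit = ml_per_unit),
            class = "isth_thresholds")
}

#' Harmonize a hemoglobin measurement to g/dL
#'
#' @param measurement an `hb_measurement`
#' @return numeric value in g/dL
#' @export
to_g_per_dL <- function(measurement) {
  unit <- measurement$unit
  if (is.null(unit) || is.na(unit)) stop("hb unit missing", call. = FALSE)
  switch(unit,
         g_per_L = measurement$value / 10,
         g_per_dL = measurement$value,
         stop(sprintf("unknown hb unit '%s'", unit), call. = FALSE))
}

#' Maximum postoperative hemoglobin drop
#'
#' Baseline = last measurement at or before `surgery_time`; if none exists,
#' the first postoperative measurement serves as baseline. Drop = baseline
#' minus the postoperative minimum (negative when hemoglobin rose). Returns
#' `NULL` when no postoperative measurement (or no baseline) is determinable
#' -- missing data is not an error for a screening rule.
#'
#' @param series list of `hb_measurement`
#' @param surgery_time POSIXct or ISO-8601 string
#' @return drop in g/dL, or `NULL`
#' @export
max_postop_hb_drop <- function(series, surgery_time) {
  if (length(series) == 0L) return(NULL)
  st <- parse_timestamp(surgery_time, "surgery_time")
  ts <- vapply(series, function(m) as.numeric(m$timestamp), 0)
  vals <- vapply(series, to_g_per_dL, 0)
  pre <- which(ts <= as.numeric(st))
  post <- which(ts > as.numeric(st))
  if (length(post) == 0L) return(NULL)
  baseline <- if (length(pre) > 0L) {
    vals[pre[which.max(ts[pre])]]
  } else {
    vals[post[which.min(ts[post])]]
  }
  baseline - min(vals[post])
}

#' Total erythrocyte units transfused in a time window
#'
#' Sums `rbc_concentrate` and `whole_blood` events whose timestamp falls in
#' `[window[1], window[2]]`; volumes recorded in mL are converted at
#' `thresholds$ml_per_unit`.
#'
#' @param transfusions list of `transfusion_event`
#' @param thresholds an `isth_thresholds`
#' @param window length-2 vector (start, end); `NULL` bounds are open
#' @return numeric unit count (0 when no qualifying events)
#' @export
total_rbc_units <- function(transfusions, thresholds = isth_thresholds(),
                            window = list(NULL, NULL)) {
  if (length(transfusions) == 0L) return(0)
  total <- 0
  for (ev in transfusions) {
    if (is.na(ev$quantity) || ev$quantity < 0) {
      stop("negative transfusion quantity", call. = FALSE)
    }
    if (!ev$product %in% c("rbc_concentrate", "whole_blood")) next
    t <- as.numeric(ev$timestamp)
    if (length(window) >= 1L && !is.null(window[[1]]) &&
        t < as.numeric(parse_timestamp(window[[1]], "window start"))) next
    if (length(window) >= 2L && !is.null(window[[2]]) &&
        t > as.numeric(parse_timestamp(window[[2]], "window end"))) next
    units <- if (ev$unit == "U") ev$quantity else ev$quantity / thresholds$ml_per_unit
    total <- total + units
  }
  total
}

#' Default critical-site detector built from the catalog
#'
#' Returns a predicate over raw note text that is true when any
#' critical-site-flagged cat1 pattern matches the normalized text.
#'
#' @param catalog a `feature_catalog`
#' @return function(text) -> logical
#' @export
critical_site_detector <- function(catalog = load_catalog()) {
  pats <- catalog$pattern[catalog$feature_id %in% critical_site_ids(catalog)]
  function(text) {
    txt <- normalize_text(text)
    any(vapply(pats, function(p) {
      any(nzchar(txt) & grepl(p, txt, perl = TRUE))
    }, TRUE))
  }
}

#' Adjudicate major bleeding for one visit
#'
#' Major iff (postoperative hemoglobin drop >= `hb_drop_threshold` g/dL) OR
#' (postoperative erythrocyte transfusion >= `rbc_units_threshold` units) OR
#' (critical-site bleeding narrative detected in any note). Both numeric
#' comparisons are inclusive. The postoperative transfusion window runs from
#' surgery to the end of the stay; set `include_intraop = TRUE` to also count
#' earlier transfusions.
#'
#' @param visit a `patient_visit`
#' @param thresholds an `isth_thresholds`
#' @param critical_site_detector predicate over note text (default: the
#'   catalog's critical-site patterns)
#' @param include_intraop count pre/intra-operative transfusions too
#' @return an `isth_decision`: list with `label` (`"major"`/`"not_major"`),
#'   `triggered_criteria` (subset of `hb_drop`, `transfusion`,
#'   `critical_site`) and `evidence` (drop, units, critical-site flag,
#'   provenance strings)
#' @export
adjudicate <- function(visit, thresholds = isth_thresholds(),
                       critical_site_detector = NULL,
                       include_intraop = FALSE) {
  validate_visit(visit)
  if (is.null(critical_site_detector)) {
    critical_site_detector <- hemobleed::critical_site_detector()
  }
  sources <- character(0)

  drop <- max_postop_hb_drop(visit$hb_series, visit$surgery_time)
  hb_crit <- !is.null(drop) && drop >= thresholds$hb_drop_threshold
  if (hb_crit) sources <- c(sources, "lab:hb_series")

  window_start <- if (include_intraop) NULL else visit$surgery_time
  units <- total_rbc_units(visit$transfusions, thresholds,
                           window = list(window_start, NULL))
  tr_crit <- units >= thresholds$rbc_units_threshold
  if (tr_crit) sources <- c(sources, "transfusion:structured_records")

  site_hits <- vapply(visit$notes, function(n) critical_site_detector(n$text),
                      TRUE)
  site_crit <- any(site_hits)
  if (site_crit) {
    sources <- c(sources, paste0("note:", vapply(
      visit$notes[site_hits], `[[`, "", "note_id")))
  }

  triggered <- c("hb_drop", "transfusion", "critical_site")[
    c(hb_crit, tr_crit, site_crit)]
  structure(list(
    label = if (length(triggered) > 0L) "major" else "not_major",
    triggered_criteria = triggered,
    evidence = list(max_postop_hb_drop = drop,
                    total_rbc_units = units,
                    critical_site_or_fatal = site_crit,
                    sources = sources)),
    class = "isth_decision")
}

#' The catalog's category-3 structured feature
#'
#' 1 iff [adjudicate()] returns `"major"` for the visit under the supplied
#' thresholds and critical-site detector.
#'
#' @param visit a `patient_visit`
#' @param thresholds an `isth_thresholds`
#' @param detector critical-site predicate (defaults to the shipped catalog's)
#' @return integer 0 or 1
#' @export
structured_feature <- function(visit, thresholds = isth_thresholds(),
                               detector = NULL) {
  d <- adjudicate(visit, thresholds, critical_site_detector = detector)
  as.integer(d$label == "major")
}

#' Adjudicate a whole corpus
#'
#' @param visits list of `patient_visit`
#' @param thresholds an `isth_thresholds`
#' @param detector critical-site predicate shared across visits (built once)
#' @return data.frame: visit_id, label, criteria (collapsed by `+`),
#'   hb_drop_g_dl, rbc_units
#' @export
adjudicate_corpus <- function(visits, thresholds = isth_thresholds(),
                              detector = NULL) {
  if (is.null(detector)) detector <- critical_site_detector()
  rows <- lapply(visits, function(v) {
    d <- adjudicate(v, thresholds, critical_site_detector = detector)
    data.frame(visit_id = v$visit_id,
               label = d$label,
               criteria = paste(d$triggered_criteria, collapse = "+"),
               hb_drop_g_dl = d$evidence$max_postop_hb_drop %||% NA_real_,
               rbc_units = d$evidence$total_rbc_units,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
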