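#' @title Corpus data model for postoperative visit records
#'
#' @description
#' A hospitalization ("visit") is the unit of classification: it bundles the
#' free-text course notes written during the stay, the hemoglobin laboratory
#' series, structured transfusion events, the surgery timestamp, basic
#' demographics, and (when available) a gold-standard major-bleeding label.
#' Visits are serialized one-per-line as UTF-8 JSONL; see
#' `system.file("extdata", "visit.schema.json", package = "hemobleed")`.
#'
#' @name corpus-model
NULL

NOTE_TYPES <- c("admission", "progress", "operative", "transfusion", "discharge")
HB_UNITS <- c("g_per_L", "g_per_dL")
TRANSFUSION_PRODUCTS <- c("rbc_concentrate", "whole_blood", "other")
QUANTITY_UNITS <- c("U", "mL")
SEXES <- c("female", "male")
LABELS <- c("major_bleeding_present", "major_bleeding_absent")

#' Construct a course note
#'
#' @param note_id opaque identifier
#' @param visit_id identifier of the owning visit
#' @param note_type one of `"admission"`, `"progress"`, `"operative"`,
#'   `"transfusion"`, `"discharge"`
#' @param timestamp ISO-8601 string or POSIXct
#' @param text non-empty Chinese free text
#' @return an object of class `course_note`
#' @export
course_note <- function(note_id, visit_id, note_type, timestamp, text) {
  out <- structure(
    list(note_id = as.character(note_id),
         visit_id = as.character(visit_id),
         note_type = as.character(note_type),
         timestamp = parse_timestamp(timestamp, "note timestamp"),
         text = as.character(text)),
    class = "course_note")
  validate_course_note(out)
  out
}

validate_course_note <- function(x) {
  stopifnot(inherits(x, "course_note"))
  if (!x$note_type %in% NOTE_TYPES) {
    stop(sprintf("note %s: note_type '%s' not one of %s",
                 x$note_id, x$note_type, paste(NOTE_TYPES, collapse = "/")),
         call. = FALSE)
  }
  if (is.na(x$text) || !nzchar(x$text)) {
    stop(sprintf("note %s: text must be non-empty", x$note_id), call. = FALSE)
  }
  invisible(x)
}

#' Construct a hemoglobin measurement
#'
#' @param timestamp ISO-8601 string or POSIXct
#' @param value measured concentration, strictly positive
#' @param unit `"g_per_L"` (Chinese laboratory convention) or `"g_per_dL"`
#' @return an object of class `hb_measurement`
#' @export
hb_measurement <- function(timestamp, value, unit = "g_per_L") {
  out <- structure(
    list(timestamp = parse_timestamp(timestamp, "hb timestamp"),
         value = as.numeric(value),
         unit = as.character(unit)),
    class = "hb_measurement")
  validate_hb_measurement(out)
  out
}

validate_hb_measurement <- function(x) {
  stopifnot(inherits(x, "hb_measurement"))
  if (!x$unit %in% HB_UNITS) {
    stop(sprintf("hb unit '%s' not one of %s", x$unit,
                 paste(HB_UNITS, collapse = "/")), call. = FALSE)
  }
  if (is.na(x$value) || x$value <= 0) {
    stop("hb value must be > 0", call. = FALSE)
  }
  # plausible physiologic range, expressed in g/L
  g_per_L <- if (x$unit == "g_per_dL") x$value * 10 else x$value
  if (g_per_L < 30 || g_per_L > 250) {
    stop(sprintf("hb value %s %s outside plausible range (30-250 g/L)",
                 format(x$value), x$unit), call. = FALSE)
  }
  invisible(x)
}

#' Construct a transfusion event
#'
#' @param timestamp ISO-8601 string or POSIXct
#' @param product `"rbc_concentrate"`, `"whole_blood"` or `"other"`
#' @param quantity strictly positive amount
#' @param unit `"U"` (blood-bank units) or `"mL"`
#' @return an object of class `transfusion_event`
#' @export
transfusion_event <- function(timestamp, product, quantity, unit) {
  out <- structure(
    list(timestamp = parse_timestamp(timestamp, "transfusion timestamp"),
         product = as.character(product),
         quantity = as.numeric(quantity),
         unit = as.character(unit)),
    class = "transfusion_event")
  validate_transfusion_event(out)
  out
}

validate_transfusion_event <- function(x) {
  stopifnot(inherits(x, "transfusion_event"))
  if (!x$product %in% TRANSFUSION_PRODUCTS) {
    stop(sprintf("transfusion product '%s' not one of %s", x$product,
                 paste(TRANSFUSION_PRODUCTS, collapse = "/")), call. = FALSE)
  }
  if (!x$unit %in% QUANTITY_UNITS) {
    stop(sprintf("transfusion unit '%s' not one of %s", x$unit,
                 paste(QUANTITY_UNITS, collapse = "/")), call. = FALSE)
  }
  if (is.na(x$quantity) || x$quantity <= 0) {
    stop("transfusion quantity must be > 0", call. = FALSE)
  }
  invisible(x)
}

#' Construct a patient visit (one hospitalization)
#'
#' @param visit_id opaque identifier
#' @param age integer years, at least 18 (study inclusion criterion)
#' @param sex `"female"` or `"male"`
#' @param surgery_time ISO-8601 string or POSIXct
#' @param notes list of [course_note()] objects, at least one; sorted by
#'   timestamp on construction
#' @param hb_series list of [hb_measurement()] objects (may be empty)
#' @param transfusions list of [transfusion_event()] objects (may be empty)
#' @param label optional gold label, `"major_bleeding_present"` or
#'   `"major_bleeding_absent"`; `NULL` for unlabeled (prediction-mode) visits
#' @return an object of class `patient_visit`
#' @export
patient_visit <- function(visit_id, age, sex, surgery_time, notes,
                          hb_series = list(), transfusions = list(),
                          label = NULL) {
  notes <- notes[order(vapply(notes, function(n) as.numeric(n$timestamp), 0))]
  out <- structure(
    list(visit_id = as.character(visit_id),
         age = as.integer(age),
         sex = as.character(sex),
         surgery_time = parse_timestamp(surgery_time, "surgery_time"),
         notes = notes,
         hb_series = hb_series,
         transfusions = transfusions,
         label = if (is.null(label)) NULL else as.character(label)),
    class = "patient_visit")
  validate_visit(out)
  out
}

#' Validate a patient visit against the schema invariants
#'
#' Checks the study inclusion criterion (age >= 18), enum membership, note
#' ordering and non-emptiness, and recursively validates the nested records.
#'
#' @param x a `patient_visit`
#' @return `x`, invisibly; errors name the offending field and visit
#' @export
validate_visit <- function(x) {
  if (!inherits(x, "patient_visit")) stop("not a patient_visit", call. = FALSE)
  vid <- x$visit_id
  if (is.na(x$age) || x$age < 18L) {
    stop(sprintf("visit %s: age %s violates inclusion criterion (age >= 18)",
                 vid, x$age), call. = FALSE)
  }
  if (!x$sex %in% SEXES) {
    stop(sprintf("visit %s: sex '%s' not one of %s", vid, x$sex,
                 paste(SEXES, collapse = "/")), call. = FALSE)
  }
  if (length(x$notes) < 1L) {
    stop(sprintf("visit %s: at least one course note required", vid),
         call. = FALSE)
  }
  ts <- vapply(x$notes, function(n) as.numeric(n$timestamp), 0)
  if (is.unsorted(ts)) {
    stop(sprintf("visit %s: notes not sorted by timestamp", vid), call. = FALSE)
  }
  lapply(x$notes, validate_course_note)
  lapply(x$hb_series, validate_hb_measurement)
  lapply(x$transfusions, validate_transfusion_event)
  if (!is.null(x$label) && !x$label %in% LABELS) {
    stop(sprintf("visit %s: label '%s' not one of %s", vid, x$label,
                 paste(LABELS, collapse = "/")), call. = FALSE)
  }
  invisible(x)
}

visit_to_list <- function(v) {
  list(
    visit_id = v$visit_id,
    age = v$age,
    sex = v$sex,
    surgery_time = format_timestamp(v$surgery_time),
    notes = lapply(v$notes, function(n) {
      list(note_id = n$note_id, visit_id = n$visit_id, note_type = n$note_type,
           timestamp = format_timestamp(n$timestamp), text = n$text)
    }),
    hb_series = lapply(v$hb_series, function(m) {
      list(timestamp = format_timestamp(m$timestamp), value = m$value,
           unit = m$unit)
    }),
    transfusions = lapply(v$transfusions, function(t) {
      list(timestamp = format_timestamp(t$timestamp), product = t$product,
           quantity = t$quantity, unit = t$unit)
    }),
    label = v$label
  )
}

visit_from_list <- function(obj) {
  if (is.null(obj$visit_id)) stop("missing field visit_id", call. = FALSE)
  notes <- lapply(obj$notes, function(n) {
    course_note(n$note_id, n$visit_id, n$note_type, n$timestamp, n$text)
  })
  hb <- lapply(obj$hb_series, function(m) {
    hb_measurement(m$timestamp, m$value, m$unit)
  })
  tr <- lapply(obj$transfusions, function(t) {
    transfusion_event(t$timestamp, t$product, t$quantity, t$unit)
  })
  patient_visit(obj$visit_id, obj$age, obj$sex, obj$surgery_time,
                notes, hb, tr, label = obj$label)
}

#' Read a JSONL visit corpus
#'
#' One JSON object per line; every record is validated against the schema
#' invariants (see [validate_visit()]). Errors cite the offending line number
#' or visit id.
#'
#' @param path path to a UTF-8 JSONL file
#' @return list of `patient_visit`, file order preserved
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
      error = function(e) {
        stop(sprintf("line %d: malformed JSON (%s)", i, conditionMessage(e)),
             call. = FALSE)
      })
    out[[i]] <- tryCatch(
      visit_from_list(obj),
      error = function(e) {
        stop(sprintf("line %d (visit %s): %s", i,
                     obj$visit_id %||% "<missing id>", conditionMessage(e)),
             call. = FALSE)
      })
  }
  out
}

#' Write a JSONL visit corpus
#'
#' UTF-8, one visit per line; absent labels serialize as JSON `null`.
#' `read_corpus(write_corpus(x))` is the identity on all fields, including
#' non-ASCII text.
#'
#' @param visits list of `patient_visit`
#' @param path destination path
#' @return `path`, invisibly
#' @export
write_corpus <- function(visits, path) {
  lapply(visits, validate_visit)
  lines <- vapply(visits, function(v) {
    jsonlite::toJSON(visit_to_list(v), auto_unbox = TRUE, null = "null",
                     digits = NA)
  }, "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Split a corpus into training and test partitions
#'
#' Splitting happens at the visit (patient-stay) level so that no patient's
#' notes straddle the partitions. With `stratified = TRUE` the split is drawn
#' independently within each label stratum, preserving prevalence to within
#' one visit per stratum.
#'
#' @param visits list of `patient_visit`
#' @param train_fraction proportion in (0, 1) allocated to training
#' @param seed integer; identical seeds give identical partitions
#' @param stratified draw within label strata (requires labels on all visits)
#' @return list with elements `train` and `test` (disjoint, exhaustive)
#' @export
split_corpus <- function(visits, train_fraction = 0.8, seed = 1L,
                         stratified = FALSE) {
  n <- length(visits)
  stopifnot(n >= 2L, train_fraction > 0, train_fraction < 1)
  if (stratified) {
    labels <- vapply(visits, function(v) v$label %||% NA_character_, "")
    if (anyNA(labels)) {
      stop("stratified split requested but some visits are unlabeled",
           call. = FALSE)
    }
    idx_train <- with_seed(seed, {
      unlist(lapply(split(seq_len(n), labels), function(idx) {
        k <- round(train_fraction * length(idx))
        k <- max(min(k, length(idx) - 1L), 1L)
        if (length(idx) == 1L) idx else sample(idx, k)
      }), use.names = FALSE)
    })
  } else {
    k <- round(train_fraction * n)
    k <- max(min(k, n - 1L), 1L)
    idx_train <- with_seed(seed, sample.int(n, k))
  }
  idx_train <- sort(idx_train)
  list(train = visits[idx_train],
       test = visits[setdiff(seq_len(n), idx_train)])
}

#' Gold labels of a corpus as a 0/1 vector
#'
#' @param visits list of `patient_visit`
#' @return integer vector, 1 = major bleeding present; `NA` where unlabeled
#' @export
corpus_labels <- function(visits) {
  vapply(visits, function(v) {
    if (is.null(v$label)) NA_integer_
    else if (v$label == "major_bleeding_present") 1L
    else 0L
  }, 0L)
}

#' Prevalence as a printed percentage
#'
#' @param n_pos positive count
#' @param n total count
#' @param digits decimal places (default 2)
#' @return `100 * n_pos / n`, rounded
#' @export
prevalence_percent <- function(n_pos, n, digits = 2L) {
  stopifnot(n >= 1, n_pos >= 0, n_pos <= n)
  round(100 * n_pos / n, digits)
}
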