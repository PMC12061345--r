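test_that("unit harmonization to g/dL", {
  expect_equal(to_g_per_dL(hb_measurement("2021-01-01T00:00:00", 128,
                                          "g_per_L")), 12.8)
  expect_equal(to_g_per_dL(hb_measurement("2021-01-01T00:00:00", 12.8,
                                          "g_per_dL")), 12.8)
  bad <- structure(list(timestamp = Sys.time(), value = 120, unit = NA),
                   class = "hb_measurement")
  expect_error(to_g_per_dL(bad), "unit missing")
})

test_that("max postoperative hemoglobin drop follows the baseline rule", {
  st <- "2021-05-10T10:00:00"
  series <- list(hb_point("2021-05-09T08:00:00", 130),   # 13.0 g/dL
                 hb_point("2021-05-11T08:00:00", 110),
                 hb_point("2021-05-12T08:00:00", 105))   # nadir 10.5
  expect_equal(max_postop_hb_drop(series, st), 2.5)
  # hemoglobin rise gives a non-positive drop
  up <- list(hb_point("2021-05-09T08:00:00", 120),
             hb_point("2021-05-11T08:00:00", 125))
  expect_lte(max_postop_hb_drop(up, st), 0)
  # no preoperative values: first postoperative value is the baseline
  post_only <- list(hb_point("2021-05-11T08:00:00", 110),
                    hb_point("2021-05-12T08:00:00", 90))
  expect_equal(max_postop_hb_drop(post_only, st), 2.0)
  # missing data -> NULL, not an error
  expect_null(max_postop_hb_drop(list(), st))
  expect_null(max_postop_hb_drop(list(hb_point("2021-05-09T08:00:00", 130)),
                                 st))
})

test_that("transfused units sum with the mL-per-unit convention", {
  th <- isth_thresholds()
  ev <- function(q, u, when = "2021-05-11T12:00:00", product = "rbc_concentrate") {
    transfusion_event(when, product, q, u)
  }
  expect_equal(total_rbc_units(list(ev(2, "U")), th), 2)
  expect_equal(total_rbc_units(list(ev(400, "mL")), th), 2)
  expect_equal(total_rbc_units(list(ev(1, "U"), ev(150, "mL")), th), 1.75)
  # non-red-cell products do not count
  expect_equal(total_rbc_units(list(ev(2, "U", product = "other")), th), 0)
  # window filtering
  expect_equal(total_rbc_units(list(ev(2, "U", "2021-05-01T00:00:00")), th,
                               window = list("2021-05-10T00:00:00", NULL)), 0)
  bad <- structure(list(timestamp = Sys.time(), product = "rbc_concentrate",
                        quantity = -1, unit = "U"),
                   class = "transfusion_event")
  expect_error(total_rbc_units(list(bad), th), "negative")
})

detector_none <- function(text) FALSE

test_that("adjudication implements the inclusive ISTH disjunction", {
  st <- "2021-05-10T10:00:00"
  mk <- function(hb = list(), tr = list(), texts = "术后第1日，病情平稳。") {
    make_tiny_visit(hb = hb, transfusions = tr, note_texts = texts,
                    surgery = st)
  }
  drop28 <- list(hb_point("2021-05-09T08:00:00", 130),
                 hb_point("2021-05-11T08:00:00", 102))
  d <- adjudicate(mk(hb = drop28), critical_site_detector = detector_none)
  expect_identical(d$label, "major")
  expect_identical(d$triggered_criteria, "hb_drop")
  expect_equal(d$evidence$max_postop_hb_drop, 2.8)

  drop19_1u <- mk(hb = list(hb_point("2021-05-09T08:00:00", 130),
                            hb_point("2021-05-11T08:00:00", 111)),
                  tr = list(transfusion_event("2021-05-11T12:00:00",
                                              "rbc_concentrate", 1, "U")))
  d2 <- adjudicate(drop19_1u, critical_site_detector = detector_none)
  expect_identical(d2$label, "not_major")
  expect_length(d2$triggered_criteria, 0L)

  # threshold exactness: both comparisons are inclusive
  exactly2 <- mk(hb = list(hb_point("2021-05-09T08:00:00", 130),
                           hb_point("2021-05-11T08:00:00", 110)))
  expect_identical(
    adjudicate(exactly2, critical_site_detector = detector_none)$label,
    "major")
  units2 <- mk(tr = list(transfusion_event("2021-05-11T12:00:00",
                                           "rbc_concentrate", 400, "mL")))
  d3 <- adjudicate(units2, critical_site_detector = detector_none)
  expect_identical(d3$label, "major")
  expect_identical(d3$triggered_criteria, "transfusion")

  # critical-site text alone is sufficient
  site <- mk(texts = "术后腹腔引流出血性液体，急诊行剖腹探查止血术。")
  d4 <- adjudicate(site)
  expect_identical(d4$label, "major")
  expect_true("critical_site" %in% d4$triggered_criteria)
  expect_match(d4$evidence$sources, "note:", all = FALSE)
})

test_that("adjudication is invariant to the recorded hemoglobin unit", {
  st <- "2021-05-10T10:00:00"
  gl <- make_tiny_visit(hb = list(hb_point("2021-05-09T08:00:00", 130),
                                  hb_point("2021-05-11T08:00:00", 105)),
                        surgery = st)
  gdl <- make_tiny_visit(hb = list(
    hb_point("2021-05-09T08:00:00", 13.0, "g_per_dL"),
    hb_point("2021-05-11T08:00:00", 10.5, "g_per_dL")), surgery = st)
  da <- adjudicate(gl, critical_site_detector = detector_none)
  db <- adjudicate(gdl, critical_site_detector = detector_none)
  expect_identical(da$label, db$label)
  expect_equal(da$evidence$max_postop_hb_drop,
               db$evidence$max_postop_hb_drop)
})

test_that("increasing evidence never flips major to not_major", {
  st <- "2021-05-10T10:00:00"
  drops <- c(0, 1, 1.9, 2, 2.5, 4)
  units <- c(0, 1, 2, 3)
  prev_major <- FALSE
  for (dr in drops) {
    v <- make_tiny_visit(
      hb = list(hb_point("2021-05-09T08:00:00", 140),
                hb_point("2021-05-11T08:00:00", 140 - 10 * dr)),
      surgery = st)
    is_major <- adjudicate(v, critical_site_detector = detector_none)$label ==
      "major"
    expect_true(is_major >= prev_major, label = paste("drop", dr))
    prev_major <- is_major
  }
  prev_major <- FALSE
  for (u in units) {
    tr <- if (u > 0) list(transfusion_event("2021-05-11T12:00:00",
                                            "rbc_concentrate", u, "U"))
          else list()
    v <- make_tiny_visit(transfusions = tr, surgery = st)
    is_major <- adjudicate(v, critical_site_detector = detector_none)$label ==
      "major"
    expect_true(is_major >= prev_major, label = paste("units", u))
    prev_major <- is_major
  }
})

test_that("structured feature equals the adjudicator pointwise", {
  g <- noise_free_corpus(80L)
  det <- critical_site_detector(shipped_catalog())
  th <- isth_thresholds()
  for (v in g$visits[1:40]) {
    d <- adjudicate(v, th, critical_site_detector = det)
    expect_identical(structured_feature(v, th, det),
                     as.integer(d$label == "major"))
  }
  # empty-ish visit (no labs, no transfusions, bland note) -> 0
  expect_identical(structured_feature(make_tiny_visit(), detector = det), 0L)
})
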