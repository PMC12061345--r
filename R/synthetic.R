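#' @title Synthetic postoperative EMR corpus generator
#'
#' @description
#' Generates labeled synthetic Chinese postoperative visit corpora with the
#' statistical structure the pipeline assumes: ~4.3% major-bleeding
#' prevalence, ~21 course records per visit, ages ~ Normal(62.86, 9.16)
#' truncated at 18, 48.5% female, hemoglobin recorded in g/L (the Chinese
#' laboratory convention, deliberately exercising the g/L -> g/dL conversion
#' path). Every positive visit realizes at least one ISTH mechanism
#' (hemoglobin fall, >= 2-unit erythrocyte transfusion, or a critical-site
#' bleeding narrative); negative visits contain no qualifying mechanism but
#' may carry distractors (sub-threshold blood-loss mentions, negated
#' bleeding phrases, preoperative anemia, 1-unit transfusions). Each visit's
#' ground truth records *why* it is positive, enabling stage-wise testing.
#'
#' @name synthetic-notes
NULL

#' Configuration for the synthetic corpus generator
#'
#' @param n_visits number of visits (>= 1)
#' @param prevalence major-bleeding proportion in `[0, 1]` (default 0.0431)
#' @param mean_notes_per_visit Poisson mean for course-record count
#'   (default 21)
#' @param seed integer seed; identical configs give byte-identical corpora
#' @param noise_rate probability a negative visit carries a distractor
#'   bleeding-like phrase (default 0.3)
#' @param hb_unit `"g_per_L"` (default) or `"g_per_dL"`
#' @param hb_noise_sd measurement noise SD on hemoglobin points, in g/L
#'   (default 2; set 0 for a noise-free corpus)
#' @return a `synthetic_config`
#' @export
synthetic_config <- function(n_visits, prevalence = 0.0431,
                             mean_notes_per_visit = 21, seed = 1L,
                             noise_rate = 0.3, hb_unit = "g_per_L",
                             hb_noise_sd = 2) {
  stopifnot(n_visits >= 1, prevalence >= 0, prevalence <= 1,
            mean_notes_per_visit >= 1, noise_rate >= 0, noise_rate <= 1,
            hb_unit %in% HB_UNITS, hb_noise_sd >= 0)
  structure(list(n_visits = as.integer(n_visits), prevalence = prevalence,
                 mean_notes_per_visit = mean_notes_per_visit,
                 seed = as.integer(seed), noise_rate = noise_rate,
                 hb_unit = hb_unit, hb_noise_sd = hb_noise_sd),
            class = "synthetic_config")
}

# ---- template bank ---------------------------------------------------------
# Each template documents which published key pattern(s) it is designed to
# trigger ("triggers"), so catalog changes can be cross-checked. "kind" is
# neutral / positive_mechanism / distractor.
TEMPLATES <- list(
  list(id = "admission_generic", note_type = "admission", kind = "neutral",
       text = "患者因{diagnosis}入院，拟行手术治疗。", triggers = ""),
  list(id = "admission_history", note_type = "admission", kind = "neutral",
       text = "患者{age}岁，因{diagnosis}收入院，既往体健，无出血性疾病史。",
       triggers = ""),
  list(id = "admission_exam", note_type = "admission", kind = "neutral",
       text = "入院查体：神清，生命体征平稳，腹部平软，无压痛。", triggers = ""),
  list(id = "operative_generic", note_type = "operative", kind = "neutral",
       text = "在全麻下行{procedure}，手术顺利，麻醉满意，安返病房。",
       triggers = ""),
  list(id = "operative_thoracic", note_type = "operative", kind = "neutral",
       text = "在全麻下行胸腔镜下{procedure}，术程顺利，安返监护室。",
       triggers = ""),
  list(id = "operative_lowloss", note_type = "operative", kind = "distractor",
       text = "在全麻下行{procedure}，术程顺利，术中出血约{loss_ml}ml，未予输血。",
       triggers = "table2:17 (sub-threshold quantity)"),
  list(id = "progress_day", note_type = "progress", kind = "neutral",
       text = "术后第{day}日，患者一般情况可，体温正常，切口敷料干燥。",
       triggers = "table2:1"),
  list(id = "progress_stable", note_type = "progress", kind = "neutral",
       text = "患者今日查房，病情平稳，生命体征正常，腹部无明显压痛。",
       triggers = ""),
  list(id = "progress_diet", note_type = "progress", kind = "neutral",
       text = "术后第{day}日，患者已排气，进流食，继续补液治疗。",
       triggers = "table2:1"),
  list(id = "progress_vitals", note_type = "progress", kind = "neutral",
       text = "术后第{day}日，体温36.8度，心率80次/分，血压正常。",
       triggers = "table2:1"),
  list(id = "progress_pain", note_type = "progress", kind = "neutral",
       text = "患者诉切口疼痛较前减轻，余无特殊不适。", triggers = ""),
  list(id = "progress_drain_clear", note_type = "progress", kind = "neutral",
       text = "术后第{day}日，腹腔引流管引流出淡黄清亮液体{vol_ml}ml。",
       triggers = "table2:1"),
  list(id = "progress_labs_normal", note_type = "progress", kind = "neutral",
       text = "复查血常规未见明显异常，血红蛋白{hb}g/l。", triggers = ""),
  list(id = "progress_mobilize", note_type = "progress", kind = "neutral",
       text = "术后第{day}日，患者可下床活动，伤口愈合良好。",
       triggers = "table2:1"),
  list(id = "discharge_generic", note_type = "discharge", kind = "neutral",
       text = "患者恢复良好，伤口愈合佳，予今日出院，嘱定期复查。",
       triggers = ""),
  list(id = "discharge_advice", note_type = "discharge", kind = "neutral",
       text = "术后恢复顺利，无发热，办理出院，门诊随诊。",
       triggers = "table2:1"),
  # -- positive mechanisms --
  list(id = "hb_drop", note_type = "progress", kind = "positive_mechanism",
       text = paste0("术后复查血常规示血红蛋白由{pre_hb}g/l降至{post_hb}g/l，",
                     "考虑术后出血可能，予对症处理。"),
       triggers = "table2:1,4"),
  list(id = "hb_drop_progressive", note_type = "progress",
       kind = "positive_mechanism",
       text = "术后第{day}日，血红蛋白进行性下降，由{pre_hb}g/l降至{post_hb}g/l。",
       triggers = "table2:1"),
  list(id = "transfusion", note_type = "progress", kind = "positive_mechanism",
       text = "患者术后贫血，予输注悬浮少白红细胞{units}u，输血过程顺利，无不良反应。",
       triggers = "table2:16,18"),
  list(id = "transfusion_ml", note_type = "progress",
       kind = "positive_mechanism",
       text = "术后予输注悬浮少白红细胞{ml}ml纠正贫血。",
       triggers = "table2:16,18"),
  list(id = "transfusion_order_b", note_type = "progress",
       kind = "positive_mechanism",
       text = "给予{units}单位红细胞悬液输注，复查血红蛋白回升。",
       triggers = "table2:16"),
  list(id = "transfusion_record", note_type = "transfusion",
       kind = "positive_mechanism",
       text = "今日输注悬浮少白红细胞{units}u，输注过程顺利。",
       triggers = "table2:16,18"),
  list(id = "critical_drain", note_type = "progress",
       kind = "positive_mechanism",
       text = "术后第{day}日，腹腔引流出血性液体约{vol_ml}ml，颜色鲜红，考虑腹腔出血。",
       triggers = "table2:13,5,17"),
  list(id = "critical_reop", note_type = "operative",
       kind = "positive_mechanism",
       text = "患者术后吻合口出血，急诊行剖腹探查止血术，术中清除血凝块。",
       triggers = "table2:13,7,9,10"),
  list(id = "critical_pelvic", note_type = "progress",
       kind = "positive_mechanism",
       text = "盆腔引流液呈血性液，量约{vol_ml}ml，暗红色，警惕盆腔出血。",
       triggers = "table2:15,8,13"),
  list(id = "critical_vaginal", note_type = "progress",
       kind = "positive_mechanism",
       text = "阴道大量出血，急诊行缝扎止血，申请备血。",
       triggers = "table2:13,9,12"),
  list(id = "critical_gastric", note_type = "progress",
       kind = "positive_mechanism",
       text = "胃管引流出鲜红色血液，考虑消化道出血，予止血药物治疗。",
       triggers = "table2:13,6"),
  # -- distractors (hard negatives) --
  list(id = "distractor_no_bleed", note_type = "progress", kind = "distractor",
       text = "术后恢复可，无出血及渗液，伤口干燥。", triggers = "table2:1,4 (negated)"),
  list(id = "distractor_small_loss", note_type = "progress",
       kind = "distractor",
       text = "术中出血约{loss_ml}ml，量少，未特殊处理。",
       triggers = "table2:17 (sub-threshold)"),
  list(id = "distractor_one_unit", note_type = "progress", kind = "distractor",
       text = "术后予输注悬浮少白红细胞1u。",
       triggers = "table2:16 (below 2-unit threshold)"),
  list(id = "distractor_preop_anemia", note_type = "admission",
       kind = "distractor",
       text = "患者术前贫血，血红蛋白{hb}g/l，予纠正贫血治疗后手术。",
       triggers = ""),
  list(id = "distractor_oozing", note_type = "progress", kind = "distractor",
       text = "切口少量渗血，予压迫止血后好转。", triggers = "table2:6")
)

#' The synthetic note template bank
#'
#' @return data.frame with columns `template_id`, `note_type`, `kind`,
#'   `text` (with `{slot}` placeholders), `triggers` (which published key
#'   patterns the template is designed to fire)
#' @export
note_templates <- function() {
  data.frame(
    template_id = vapply(TEMPLATES, `[[`, "", "id"),
    note_type = vapply(TEMPLATES, `[[`, "", "note_type"),
    kind = vapply(TEMPLATES, `[[`, "", "kind"),
    text = vapply(TEMPLATES, `[[`, "", "text"),
    triggers = vapply(TEMPLATES, `[[`, "", "triggers"),
    stringsAsFactors = FALSE)
}

fill_template <- function(template_text, slots) {
  needed <- unlist(regmatches(template_text,
                              gregexpr("\\{([^}]+)\\}", template_text)))
  needed <- unique(gsub("[{}]", "", needed))
  missing <- setdiff(needed, names(slots))
  if (length(missing) > 0L) {
    stop(sprintf("missing slot '%s' for template", missing[[1]]),
         call. = FALSE)
  }
  out <- template_text
  for (nm in needed) {
    val <- slots[[nm]]
    if (is.numeric(val)) val <- format(val, scientific = FALSE, trim = TRUE)
    out <- gsub(paste0("{", nm, "}"), val, out, fixed = TRUE)
  }
  out
}

#' Render one course note from a template
#'
#' Slot values are inserted verbatim. Note metadata (`note_id`, `visit_id`,
#' `timestamp`) may be passed as slots; defaults are supplied for standalone
#' use.
#'
#' @param template_id id from [note_templates()]
#' @param slots named list of slot values (text or numbers)
#' @return a `course_note`
#' @export
render_note <- function(template_id, slots = list()) {
  idx <- match(template_id, vapply(TEMPLATES, `[[`, "", "id"))
  if (is.na(idx)) {
    stop(sprintf("unknown template_id '%s'", template_id), call. = FALSE)
  }
  tpl <- TEMPLATES[[idx]]
  course_note(note_id = slots$note_id %||% "N00001-01",
              visit_id = slots$visit_id %||% "V00001",
              note_type = tpl$note_type,
              timestamp = slots$timestamp %||% "2021-01-05T08:00:00",
              text = fill_template(tpl$text, slots))
}

#' Generate a hemoglobin series around surgery
#'
#' Produces at least one preoperative and one postoperative point; the
#' postoperative nadir equals `baseline - postop_drop` plus measurement
#' noise; other postoperative points lie between nadir and baseline
#' (recovery). All values in g/L internally; `unit` controls the recorded
#' unit (converting to g/dL when asked).
#'
#' @param baseline preoperative hemoglobin in g/L
#' @param postop_drop intended drop in g/L (`> baseline` is an error)
#' @param n_points total number of measurements (>= 2)
#' @param noise_sd measurement noise SD in g/L (default 2)
#' @param surgery_time POSIXct or ISO string anchoring the series
#' @param unit recorded unit, `"g_per_L"` or `"g_per_dL"`
#' @return list of `hb_measurement`
#' @export
generate_hb_series <- function(baseline, postop_drop, n_points = 5L,
                               noise_sd = 2,
                               surgery_time = "2021-01-05T10:00:00",
                               unit = "g_per_L") {
  stopifnot(n_points >= 2L, baseline > 0)
  if (postop_drop > baseline) stop("drop exceeds baseline", call. = FALSE)
  st <- parse_timestamp(surgery_time, "surgery_time")
  n_pre <- max(1L, min(2L, n_points - 1L))
  n_post <- n_points - n_pre
  pre_vals <- baseline + stats::rnorm(n_pre, 0, noise_sd)
  nadir <- baseline - postop_drop + stats::rnorm(1, 0, noise_sd)
  other <- integer(0)
  if (n_post > 1L) {
    # recovery points at or above the nadir; offsets scale with the noise so
    # a noise-free zero-drop series is exactly flat
    other <- nadir + abs(stats::rnorm(n_post - 1L, 0, noise_sd)) +
      seq_len(n_post - 1L) * 0.25 * noise_sd
  }
  post_vals <- c(nadir, other)
  times <- c(st - (n_pre:1) * 86400, st + seq_len(n_post) * 86400)
  vals <- pmin(pmax(c(pre_vals, post_vals), 31), 249)
  lapply(seq_along(vals), function(i) {
    v <- if (unit == "g_per_dL") vals[i] / 10 else vals[i]
    hb_measurement(times[i], round(v, 1), unit)
  })
}

#' Generate a labeled synthetic corpus with ground truth
#'
#' Deterministic under a fixed seed. Each positive visit realizes exactly one
#' recorded mechanism (`hb_drop`, `transfusion_2u`, or `critical_site_text`);
#' negative visits carry no qualifying mechanism, with distractor phrases at
#' `noise_rate`. On a noise-free configuration (`hb_noise_sd = 0`,
#' `noise_rate = 0`) [adjudicate()] reproduces the ground-truth labels
#' exactly.
#'
#' @param config a [synthetic_config()]
#' @return list with `visits` (list of `patient_visit`) and `truth`
#'   (data.frame: visit_id, label, mechanism)
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    n <- config$n_visits
    positive <- stats::runif(n) < config$prevalence
    if (config$prevalence > 0 && !any(positive)) {
      warning("prevalence * n_visits < 1; forcing one positive visit")
      positive[sample.int(n, 1L)] <- TRUE
    }
    visits <- vector("list", n)
    mech <- character(n)
    base_day <- parse_timestamp("2021-03-01T09:00:00")
    for (i in seq_len(n)) {
      vid <- pad_id("V", i)
      age <- 17
      while (age < 18) age <- round(stats::rnorm(1, 62.86, 9.16))
      sex <- if (stats::runif(1) < 0.485) "female" else "male"
      surgery <- base_day + (i %% 365) * 86400 +
        round(stats::runif(1, 0, 8)) * 3600
      diagnosis <- sample(c("胃恶性肿瘤", "结肠恶性肿瘤", "肺恶性肿瘤",
                            "卵巢恶性肿瘤", "直肠恶性肿瘤"), 1)
      procedure <- sample(c("根治性胃大部切除术", "结肠癌根治术",
                            "肺叶切除术", "卵巢肿瘤切除术"), 1)
      baseline_hb <- round(stats::runif(1, 110, 150))

      mech_i <- "none"
      drop_gL <- stats::runif(1, 0, 10)
      transfusion_units <- 0
      if (positive[i]) {
        mech_i <- sample(c("hb_drop", "transfusion_2u",
                           "critical_site_text"), 1)
        if (mech_i == "hb_drop") drop_gL <- stats::runif(1, 28, 45)
        if (mech_i == "transfusion_2u") transfusion_units <- sample(2:4, 1)
      }

      hb_series <- generate_hb_series(baseline_hb, drop_gL,
                                      n_points = sample(4:7, 1),
                                      noise_sd = config$hb_noise_sd,
                                      surgery_time = surgery,
                                      unit = config$hb_unit)
      transfusions <- list()
      if (transfusion_units > 0) {
        transfusions <- list(transfusion_event(
          surgery + 86400, "rbc_concentrate", transfusion_units, "U"))
      }

      n_notes <- max(4L, stats::rpois(1, config$mean_notes_per_visit))
      slots_base <- list(visit_id = vid, diagnosis = diagnosis,
                         procedure = procedure, age = age, hb = baseline_hb)
      notes <- list()
      add_note <- function(tid, day_offset_h, extra = list()) {
        k <- length(notes) + 1L
        s <- c(slots_base, extra,
               list(note_id = sprintf("%s-%02d", vid, k),
                    timestamp = format_timestamp(surgery + day_offset_h * 3600)))
        notes[[k]] <<- render_note(tid, s)
      }
      add_note("admission_generic", -48)
      add_note("operative_generic", 2)
      n_progress <- n_notes - 3L
      for (d in seq_len(n_progress)) {
        day <- d
        tid <- sample(c("progress_day", "progress_stable", "progress_diet",
                        "progress_vitals", "progress_pain",
                        "progress_drain_clear", "progress_mobilize"), 1)
        add_note(tid, 24 * day + 8,
                 list(day = day, vol_ml = round(stats::runif(1, 20, 80))))
      }
      # mechanism note for positives, distractor for some negatives
      if (mech_i == "hb_drop") {
        add_note("hb_drop", 24 * 2 + 10,
                 list(pre_hb = baseline_hb,
                      post_hb = round(baseline_hb - drop_gL)))
      } else if (mech_i == "transfusion_2u") {
        add_note("transfusion", 24 * 2 + 12,
                 list(units = transfusion_units))
      } else if (mech_i == "critical_site_text") {
        add_note(sample(c("critical_drain", "critical_reop",
                          "critical_pelvic", "critical_gastric"), 1),
                 24 * 2 + 14,
                 list(day = 2, vol_ml = round(stats::runif(1, 200, 600))))
      } else if (stats::runif(1) < config$noise_rate) {
        tid <- sample(c("distractor_no_bleed", "distractor_small_loss",
                        "distractor_one_unit", "distractor_preop_anemia",
                        "distractor_oozing"), 1)
        off <- if (tid == "distractor_preop_anemia") -36 else 24 * 3 + 9
        add_note(tid, off, list(loss_ml = round(stats::runif(1, 50, 150))))
        if (tid == "distractor_one_unit") {
          transfusions <- c(transfusions, list(transfusion_event(
            surgery + 2 * 86400, "rbc_concentrate", 1, "U")))
        }
      }
      add_note("discharge_generic", 24 * (n_progress + 2))

      visits[[i]] <- patient_visit(
        vid, age, sex, surgery, notes, hb_series, transfusions,
        label = if (positive[i]) "major_bleeding_present"
                else "major_bleeding_absent")
      mech[i] <- mech_i
    }
    truth <- data.frame(
      visit_id = vapply(visits, `[[`, "", "visit_id"),
      label = ifelse(positive, "major_bleeding_present",
                     "major_bleeding_absent"),
      mechanism = mech, stringsAsFactors = FALSE)
    list(visits = visits, truth = truth)
  })
}
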