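# Shared fixtures, generated in code and cached across test files.
# Seeds are fixed a priori; the larger corpora are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

shipped_catalog <- function() cached("catalog", load_catalog())

# 2000 visits at the published training prevalence; used by the synthetic
# module tests and the imbalanced-learning acceptance criterion.
big_corpus <- function() {
  cached("big", generate_corpus(
    synthetic_config(n_visits = 2000, prevalence = 0.0431, seed = 207L)))
}

big_split_features <- function() {
  cached("bigfeat", {
    g <- big_corpus()
    sp <- split_corpus(g$visits, 0.8, seed = 207L, stratified = TRUE)
    list(split = sp,
         x_train = extract_feature_matrix(sp$train, shipped_catalog()),
         x_test = extract_feature_matrix(sp$test, shipped_catalog()),
         y_train = corpus_labels(sp$train),
         y_test = corpus_labels(sp$test))
  })
}

# Noise-free corpus for exact generator/adjudicator agreement.
noise_free_corpus <- function(n = 500L) {
  cached(paste0("nf", n), generate_corpus(
    synthetic_config(n_visits = n, prevalence = 0.0431, seed = 31L,
                     hb_noise_sd = 0, noise_rate = 0)))
}

# Minimal hand-built visit for unit tests.
make_tiny_visit <- function(visit_id = "T00001", label = NULL,
                            note_texts = "术后第1日，患者一般情况可。",
                            hb = list(), transfusions = list(),
                            surgery = "2021-05-10T10:00:00") {
  notes <- lapply(seq_along(note_texts), function(i) {
    course_note(sprintf("%s-%02d", visit_id, i), visit_id, "progress",
                sprintf("2021-05-%02dT08:00:00", 10 + i), note_texts[[i]])
  })
  patient_visit(visit_id, 60L, "female", surgery, notes, hb, transfusions,
                label = label)
}

hb_point <- function(ts, value, unit = "g_per_L") {
  hb_measurement(ts, value, unit)
}

# Random Chinese-ish clinical strings for property tests: mixes template
# fragments with random Han characters.
random_clinical_strings <- function(n, seed) {
  frags <- c("术后", "出血", "止血", "无", "引流", "血性液体", "腹腔",
             "患者", "病情平稳", "输注悬浮少白红细胞2u", "约300ml",
             "暗红", "急诊", "剖腹探查", "血红蛋白", "下降", "切口",
             "敷料干燥", "失血", "肿胀", "盆腔", "阴道", "胃", "。", "，")
  han <- strsplit("的了和在是病人体温药物检查治疗恢复观察记录医嘱今日明显", "")[[1]]
  with_seed <- get("with_seed", envir = asNamespace("hemobleed"))
  with_seed(seed, {
    vapply(seq_len(n), function(i) {
      k <- sample(2:8, 1)
      paste(sample(c(frags, han), k, replace = TRUE), collapse = "")
    }, "")
  })
}
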