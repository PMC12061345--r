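#' @title Feature extraction: from note text to the 270-dimensional vector
#'
#' @description
#' Three feature categories are combined into one binary vector per visit:
#' manually curated bleeding regexes (cat1), frequency-selected segmentation
#' tokens (cat2), and the quantitative ISTH structured feature (cat3).
#' Feature semantics are presence/absence per visit: a cat1/cat2 position is
#' 1 if its pattern matches anywhere in any of the visit's notes.
#'
#' @name feature-extraction
NULL

#' Normalize clinical text
#'
#' Unicode NFKC (which folds full-width ASCII to half-width), lower-cases
#' Latin, collapses whitespace runs to single spaces and trims. Idempotent:
#' `normalize_text(normalize_text(x)) == normalize_text(x)`.
#'
#' @param text character vector
#' @return normalized character vector
#' @export
normalize_text <- function(text) {
  out <- stringi::stri_trans_nfkc(text)
  out <- stringi::stri_trans_tolower(out)
  out <- gsub("\\s+", " ", out, perl = TRUE)
  trimws(out)
}

# Built-in segmentation lexicon (forward maximum matching). Deliberately
# small: enough to give clinically meaningful tokens over the synthetic
# register; the segmenter is pluggable behind segment_text()'s coverage
# contract, so a richer dictionary can be swapped in without touching
# downstream code.
segmentation_lexicon <- function() {
  c("悬浮少白红细胞", "少白悬浮红细胞", "红细胞悬液", "悬浮红细胞",
    "血红蛋白", "血性液体", "失血性休克", "剖腹探查", "无出血",
    "引流液", "引流管", "血常规", "红细胞", "血小板", "凝血酶",
    "术后", "术中", "出血", "止血", "渗血", "失血", "血肿", "血性",
    "引流", "输注", "输血", "全血", "血浆", "血压", "贫血", "凝血",
    "补液", "患者", "今日", "查房", "病情", "平稳", "稳定", "生命",
    "体征", "腹腔", "盆腔", "胸腔", "吻合口", "手术", "切口", "敷料",
    "干燥", "渗出", "疼痛", "体温", "正常", "腹部", "伤口", "愈合",
    "良好", "复查", "下降", "降至", "暗红", "鲜红", "单位", "毫升",
    "约", "无", "有", "给予", "嘱", "继续", "观察", "治疗", "予",
    "行", "急诊", "肿胀", "清亮", "淡黄", "少量", "大量", "明显")
}

#' Segment normalized Chinese text into tokens
#'
#' Forward maximum matching against a built-in clinical lexicon; characters
#' outside the lexicon become single-character tokens, and ASCII digit/letter
#' runs are kept whole. The concatenation of the returned tokens always
#' recovers the input exactly (coverage property), so any segmenter honoring
#' that contract can be substituted.
#'
#' @param text a single normalized string
#' @param lexicon character vector of dictionary words
#' @return character vector of tokens (empty for empty input)
#' @export
segment_text <- function(text, lexicon = segmentation_lexicon()) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(character(0))
  chars <- strsplit(text, "", fixed = FALSE)[[1]]
  n <- length(chars)
  max_w <- max(nchar(lexicon))
  lex <- new.env(parent = emptyenv())
  for (w in lexicon) assign(w, TRUE, envir = lex)
  tokens <- character(0)
  i <- 1L
  while (i <= n) {
    matched <- FALSE
    widths <- if (n - i + 1L >= 2L) seq.int(min(max_w, n - i + 1L), 2L) else integer(0)
    for (w in widths) {
      cand <- paste(chars[i:(i + w - 1L)], collapse = "")
      if (exists(cand, envir = lex, inherits = FALSE)) {
        tokens <- c(tokens, cand)
        i <- i + w
        matched <- TRUE
        break
      }
    }
    if (matched) next
    ch <- chars[i]
    if (grepl("[0-9]", ch)) {
      j <- i
      while (j < n && grepl("[0-9.]", chars[j + 1L])) j <- j + 1L
      tokens <- c(tokens, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else if (grepl("[a-z]", ch)) {
      j <- i
      while (j < n && grepl("[a-z]", chars[j + 1L])) j <- j + 1L
      tokens <- c(tokens, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else {
      tokens <- c(tokens, ch)
      i <- i + 1L
    }
  }
  tokens
}

#' Frequency-based token selection (category 2)
#'
#' Tokenizes every note text in the corpus, counts total term frequency
#' (occurrences, not document frequency), excludes tokens already covered by
#' a cat1 pattern, and selects up to `max_features` tokens at or above the
#' frequency threshold.
#'
#' The default threshold of 900 is calibrated to a ~33,000-record corpus; for
#' smaller corpora scale it proportionally (about 26.7 per 1,000 notes).
#'
#' @param corpus list of `patient_visit`
#' @param threshold minimum corpus frequency (>= 1)
#' @param exclusions character vector of cat1 patterns (or a
#'   `feature_catalog`, from which cat1 patterns are taken)
#' @param max_features maximum tokens to select (default 8)
#' @return data.frame with columns `token`, `corpus_frequency`, `selected`,
#'   `threshold_used`, sorted by frequency descending
#' @export
build_frequency_features <- function(corpus, threshold = 900L,
                                     exclusions = character(0),
                                     max_features = 8L) {
  stopifnot(threshold >= 1L)
  if (length(corpus) == 0L) stop("empty corpus", call. = FALSE)
  if (inherits(exclusions, "feature_catalog")) {
    exclusions <- exclusions$pattern[exclusions$category == "cat1_manual"]
  }
  texts <- normalize_text(unlist(lapply(corpus, function(v) {
    vapply(v$notes, `[[`, "", "text")
  })))
  tokens <- unlist(lapply(texts, segment_text))
  # drop whitespace/punctuation/number-only tokens: not lexical candidates
  tokens <- tokens[grepl("[\\p{Han}a-z]", tokens, perl = TRUE)]
  tab <- sort(table(tokens), decreasing = TRUE)
  tok <- names(tab)
  covered <- rep(FALSE, length(tok))
  for (p in exclusions) {
    covered <- covered | grepl(p, tok, perl = TRUE)
  }
  eligible <- !covered & as.integer(tab) >= threshold
  selected <- rep(FALSE, length(tok))
  selected[which(eligible)[seq_len(min(max_features, sum(eligible)))]] <- TRUE
  data.frame(token = tok,
             corpus_frequency = as.integer(tab),
             selected = selected,
             threshold_used = as.integer(threshold),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Match catalog patterns against one text
#'
#' Returns the partial feature vector for a single normalized text: position
#' i is 1 iff pattern i matches anywhere (presence/absence, not counts). The
#' cat3 position is left `NA` — it is a visit-level quantity filled in by
#' [extract_features()].
#'
#' @param text a single normalized string
#' @param catalog a `feature_catalog`
#' @return integer vector of length 270 in \{0, 1, NA\}
#' @export
match_features <- function(text, catalog) {
  stopifnot(is.character(text), length(text) == 1L)
  values <- rep(NA_integer_, nrow(catalog))
  regex_rows <- which(catalog$category != "cat3_structured")
  if (is.na(text) || !nzchar(text)) {
    values[regex_rows] <- 0L
    return(values)
  }
  for (i in regex_rows) {
    values[i] <- as.integer(grepl(catalog$pattern[i], text, perl = TRUE))
  }
  values
}

CN_NUM <- c("一" = 1, "二" = 2, "三" = 3, "四" = 4, "五" = 5,
            "六" = 6, "七" = 7, "八" = 8, "九" = 9, "十" = 10, "两" = 2)

parse_quantity <- function(x) {
  ifelse(x %in% names(CN_NUM), unname(CN_NUM[x]), suppressWarnings(as.numeric(x)))
}

normalize_unit <- function(u) {
  ifelse(u %in% c("u", "单位"), "U", "mL")
}

NUM_RE <- "([0-9]+(?:\\.[0-9]+)?|[一二三四五六七八九十两])"
UNIT_RE <- "(u|ml|cc|毫升|单位)"
RBC_PRODUCT_RE <- paste0("(?:悬浮少白红细胞|少白悬浮红细胞|红细胞悬液|",
                         "悬浮红细胞|红悬|红细胞|全血)")
TRANSFUSE_VERB_RE <- "(?:输注|输入|给予|输|予|给)"

#' Extract transfusion / blood-loss / drainage quantities from text
#'
#' Recognizes red-cell transfusion mentions (number before or after the
#' product name, both orders occur in clinical prose), blood-loss amounts,
#' and drainage volumes. Chinese numerals 一..十 and 两 are normalized.
#' Overlapping matches are resolved by precedence: transfusion, then
#' drainage, then blood loss.
#'
#' @param text a single normalized string
#' @return data.frame with columns `kind` (`transfusion_rbc`, `blood_loss`,
#'   `drainage`), `quantity` (numeric), `unit` (`"U"` or `"mL"`); zero rows
#'   when nothing matches
#' @export
extract_quantities <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(kind = character(0), quantity = numeric(0),
                      unit = character(0), stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)

  rules <- list(
    list(kind = "transfusion_rbc",
         pattern = paste0(TRANSFUSE_VERB_RE, ".{0,20}?", RBC_PRODUCT_RE,
                          "[^0-9一二三四五六七八九十两]{0,10}?",
                          NUM_RE, " ?", UNIT_RE)),
    list(kind = "transfusion_rbc",
         pattern = paste0(TRANSFUSE_VERB_RE, ".{0,8}?", NUM_RE, " ?", UNIT_RE,
                          ".{0,10}?", RBC_PRODUCT_RE)),
    list(kind = "drainage",
         pattern = paste0("(?:引流|引出)[^0-9一二三四五六七八九十两。;]{0,10}?",
                          NUM_RE, " ?", "(ml|cc|毫升)")),
    list(kind = "blood_loss",
         pattern = paste0("(?:出血|失血|血性渗出)",
                          "[^0-9一二三四五六七八九十两。;]{0,8}?",
                          NUM_RE, " ?", UNIT_RE))
  )
  out <- empty
  claimed <- matrix(numeric(0), ncol = 2)
  for (rule in rules) {
    loc <- stringi::stri_locate_all_regex(text, rule$pattern)[[1]]
    if (anyNA(loc[, 1])) next
    caps <- stringi::stri_match_all_regex(text, rule$pattern)[[1]]
    for (r in seq_len(nrow(loc))) {
      span <- loc[r, ]
      overlaps <- nrow(claimed) > 0 &&
        any(claimed[, 1] <= span[2] & claimed[, 2] >= span[1])
      if (overlaps) next
      grp <- caps[r, -1]
      grp <- grp[!is.na(grp)]
      # last two capture groups are always (number, unit)
      num <- grp[length(grp) - 1L]
      unit <- grp[length(grp)]
      out <- rbind(out, data.frame(kind = rule$kind,
                                   quantity = parse_quantity(num),
                                   unit = normalize_unit(unit),
                                   stringsAsFactors = FALSE))
      claimed <- rbind(claimed, span)
    }
  }
  out
}

#' Extract the full 270-dimensional feature vector for one visit
#'
#' cat1/cat2 positions are the OR of [match_features()] over all note texts;
#' the cat3 position is [structured_feature()] (the quantitative ISTH rule).
#'
#' @param visit a `patient_visit`
#' @param catalog a `feature_catalog`
#' @param thresholds ISTH thresholds for the structured feature
#' @return a `feature_vector`: list with `visit_id` and a 0/1 integer
#'   `values` vector of length 270 aligned to catalog order
#' @export
extract_features <- function(visit, catalog = load_catalog(),
                             thresholds = isth_thresholds()) {
  validate_visit(visit)
  mat <- extract_feature_matrix(list(visit), catalog, thresholds)
  structure(list(visit_id = visit$visit_id, values = as.integer(mat[1, ])),
            class = "feature_vector")
}

#' Extract the feature matrix for a corpus
#'
#' Vectorized equivalent of per-visit [extract_features()]: one row per
#' visit, 270 columns in catalog order, entries in \{0, 1\}.
#'
#' @param visits list of `patient_visit`
#' @param catalog a `feature_catalog`
#' @param thresholds ISTH thresholds for the structured feature
#' @return integer matrix `length(visits)` x 270, rownames = visit ids,
#'   colnames `f000..f269`; attribute `catalog_version` records alignment
#' @export
extract_feature_matrix <- function(visits, catalog = load_catalog(),
                                   thresholds = isth_thresholds()) {
  n <- length(visits)
  stopifnot(n >= 1L)
  visit_idx <- rep(seq_len(n),
                   vapply(visits, function(v) length(v$notes), 0L))
  texts <- normalize_text(unlist(lapply(visits, function(v) {
    vapply(v$notes, `[[`, "", "text")
  })))
  mat <- matrix(0L, nrow = n, ncol = nrow(catalog),
                dimnames = list(vapply(visits, `[[`, "", "visit_id"),
                                sprintf("f%03d", catalog$feature_id)))
  regex_rows <- which(catalog$category != "cat3_structured")
  nonempty <- nzchar(texts)
  for (i in regex_rows) {
    hit <- logical(length(texts))
    hit[nonempty] <- grepl(catalog$pattern[i], texts[nonempty], perl = TRUE)
    if (any(hit)) {
      mat[unique(visit_idx[hit]), i] <- 1L
    }
  }
  cat3 <- which(catalog$category == "cat3_structured")
  detector <- critical_site_detector(catalog)
  for (v in seq_len(n)) {
    mat[v, cat3] <- structured_feature(visits[[v]], thresholds, detector)
  }
  attr(mat, "catalog_version") <- catalog_version(catalog)
  mat
}

#' Write a feature matrix (plus optional labels) as CSV
#'
#' Columns: `visit_id`, `f000`..`f269`, and `label` when supplied.
#'
#' @param mat matrix from [extract_feature_matrix()]
#' @param path destination
#' @param labels optional 0/1 vector aligned to rows
#' @return `path`, invisibly
#' @export
write_feature_csv <- function(mat, path, labels = NULL) {
  df <- data.frame(visit_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(labels)) df$label <- as.integer(labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a feature matrix CSV written by [write_feature_csv()]
#'
#' @param path CSV path
#' @return list with `matrix` (integer, rownames = visit ids) and `labels`
#'   (0/1 vector or `NULL`)
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        encoding = "UTF-8")
  has_label <- "label" %in% colnames(df)
  feat_cols <- setdiff(colnames(df), c("visit_id", "label"))
  mat <- as.matrix(df[, feat_cols, drop = FALSE])
  storage.mode(mat) <- "integer"
  rownames(mat) <- df$visit_id
  list(matrix = mat,
       labels = if (has_label) as.integer(df$label) else NULL)
}
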