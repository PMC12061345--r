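test_that("normalize_text folds width, case and whitespace, idempotently", {
  expect_identical(normalize_text("ＭＬ"), "ml")  # full-width ML
  expect_identical(normalize_text("输血４００ｍｌ"), "输血400ml")
  expect_identical(normalize_text("  a \t b  "), "a b")
  strs <- random_clinical_strings(50, seed = 12L)
  once <- normalize_text(strs)
  expect_identical(normalize_text(once), once)
})

test_that("segment_text covers the input exactly", {
  toks <- segment_text("术后出血")
  expect_identical(paste(toks, collapse = ""), "术后出血")
  expect_identical(segment_text(""), character(0))
  toks2 <- segment_text("。，！")
  expect_identical(paste(toks2, collapse = ""), "。，！")
  for (s in random_clinical_strings(60, seed = 4L)) {
    expect_identical(paste(segment_text(normalize_text(s)), collapse = ""),
                     normalize_text(s))
  }
  # deterministic
  expect_identical(segment_text("腹腔引流出血性液体300ml"),
                   segment_text("腹腔引流出血性液体300ml"))
})

test_that("frequency selection counts term frequency and applies exclusions", {
  # toy corpus: 血肿 occurs 7 times total across 5 notes, 补液 3 times,
  # 出血 5 times (covered by a cat1 pattern)
  texts <- c("血肿血肿补液", "血肿出血出血", "血肿血肿补液",
             "血肿出血出血", "血肿补液出血")
  visits <- lapply(seq_along(texts), function(i) {
    make_tiny_visit(sprintf("F%02d", i), note_texts = texts[[i]])
  })
  res <- build_frequency_features(visits, threshold = 3L,
                                  exclusions = character(0),
                                  max_features = 8L)
  # brute-force oracle: count occurrences by string counting
  oracle_count <- function(tok) {
    sum(vapply(texts, function(t) {
      lengths(regmatches(t, gregexpr(tok, t, fixed = TRUE)))
    }, 0L))
  }
  r_xz <- res[res$token == "血肿", ]
  expect_equal(r_xz$corpus_frequency, oracle_count("血肿"))
  expect_equal(r_xz$corpus_frequency, 7L)
  expect_true(r_xz$selected)
  # sorted descending
  expect_false(is.unsorted(rev(res$corpus_frequency)))
  # with the shipped catalog, tokens covered by cat1 patterns (血肿 is in
  # the hematoma alternation, 出血 is itself a pattern) are excluded
  # regardless of frequency
  res_ex <- build_frequency_features(visits, threshold = 3L,
                                     exclusions = shipped_catalog(),
                                     max_features = 8L)
  expect_false(res_ex[res_ex$token == "血肿", "selected"])
  expect_false(res_ex[res_ex$token == "出血", "selected"])
  expect_true(res_ex[res_ex$token == "补液", "selected"])
  # threshold above every frequency -> nothing selected
  res_hi <- build_frequency_features(visits, threshold = 100L,
                                     exclusions = shipped_catalog())
  expect_false(any(res_hi$selected))
  expect_error(build_frequency_features(list(), threshold = 1L), "empty")
})

test_that("match_features flags the expected catalog positions", {
  catalog <- shipped_catalog()
  v <- match_features(normalize_text("术后恢复良好"), catalog)
  expect_equal(v[1], 1L)         # feature 0: postoperative
  v2 <- match_features(normalize_text("腹腔引流出血性液体"), catalog)
  expect_equal(v2[2], 1L)        # cavity-site alternation
  expect_equal(v2[4], 1L)        # bleeding
  expect_equal(v2[5], 1L)        # bloody fluid
  expect_equal(v2[13], 1L)       # critical-site compound
  v0 <- match_features("", catalog)
  expect_true(all(v0[-270] == 0L))
  expect_true(is.na(v0[270]))    # cat3 left unset
  # only the cat3 position may be NA; everything else binary
  expect_true(all(v2[-270] %in% 0:1))
})

test_that("extract_quantities matches the 50-snippet hand-annotated oracle", {
  fix <- read.delim(test_path("fixtures", "quantity_snippets.tsv"),
                    stringsAsFactors = FALSE, encoding = "UTF-8")
  for (i in seq_len(nrow(fix))) {
    got <- extract_quantities(normalize_text(fix$text[i]))
    if (fix$kind[i] == "none") {
      expect_equal(nrow(got), 0L, label = fix$text[i])
    } else {
      expect_gte(nrow(got), 1L)
      expect_identical(got$kind[1], fix$kind[i], label = fix$text[i])
      expect_equal(got$quantity[1], as.numeric(fix$quantity[i]),
                   label = fix$text[i])
      expect_identical(got$unit[1], fix$unit[i], label = fix$text[i])
    }
  }
})

test_that("extract_feature_matrix equals the per-note brute-force oracle", {
  g <- noise_free_corpus(80L)
  catalog <- shipped_catalog()
  mat <- extract_feature_matrix(g$visits, catalog)
  expect_identical(dim(mat), c(80L, 270L))
  expect_true(all(mat %in% 0:1))
  # oracle: per-visit, per-note loop with scalar matching, OR-aggregated
  oracle <- t(vapply(g$visits, function(v) {
    acc <- rep(0L, 270L)
    for (n in v$notes) {
      m <- match_features(normalize_text(n$text), catalog)
      acc <- pmax(acc, ifelse(is.na(m), 0L, m))
    }
    acc[270] <- structured_feature(v)
    acc
  }, integer(270)))
  dimnames(oracle) <- dimnames(mat)
  expect_equal(unname(mat), unname(oracle), ignore_attr = TRUE)
  # determinism and single-visit agreement
  fv <- extract_features(g$visits[[5]], catalog)
  expect_identical(fv$values, as.integer(mat[5, ]))
})

test_that("appending text is monotone: features flip only 0 -> 1", {
  catalog <- shipped_catalog()
  base <- random_clinical_strings(40, seed = 21L)
  suffix <- random_clinical_strings(40, seed = 22L)
  for (i in seq_along(base)) {
    a <- match_features(normalize_text(base[i]), catalog)
    ab <- match_features(normalize_text(paste0(base[i], suffix[i])), catalog)
    expect_true(all(ab[-270] >= a[-270]),
                label = paste(base[i], "+", suffix[i]))
  }
})
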