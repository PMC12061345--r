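#' Feature catalog: the ordered 270-feature definition
#'
#' The catalog is the contract between text and models: an ordered, versioned
#' list of 270 binary feature definitions, partitioned into
#' * **cat1_manual** (261): manually curated bleeding regular expressions,
#'   including the 20 published key patterns (flagged `key` in `source`; the
#'   structured-rule key feature is one of the 20, so 19 of them are regexes),
#' * **cat2_frequency** (8): corpus-frequency-selected segmentation tokens,
#' * **cat3_structured** (1): the quantitative ISTH adjudication feature.
#'
#' The ordering is stable and defines the 1-D axis the convolutional model
#' convolves over. Patterns are PCRE expressions evaluated against
#' [normalize_text()] output (hence lowercase Latin).
#'
#' @name feature-catalog
NULL

CATALOG_SIZE <- 270L
CATALOG_COUNTS <- c(cat1_manual = 261L, cat2_frequency = 8L,
                    cat3_structured = 1L)

#' Path of the default shipped catalog
#'
#' @return filesystem path of `catalog_v1.tsv`
#' @export
default_catalog_path <- function() {
  system.file("extdata", "catalog_v1.tsv", package = "hemobleed",
              mustWork = TRUE)
}

#' Load and validate a feature catalog
#'
#' @param path TSV file with columns `feature_id`, `category`, `pattern`,
#'   `gloss`, `source` (lines starting with `#` are comments); defaults to
#'   the shipped `catalog_v1.tsv`
#' @return a `feature_catalog`: a data.frame of 270 patterns plus a
#'   `version` attribute
#' @export
load_catalog <- function(path = default_catalog_path()) {
  df <- utils::read.delim(path, comment.char = "#", quote = "",
                          stringsAsFactors = FALSE, encoding = "UTF-8",
                          colClasses = c(feature_id = "integer",
                                         category = "character",
                                         pattern = "character",
                                         gloss = "character",
                                         source = "character"))
  df$pattern[is.na(df$pattern)] <- ""
  cat <- structure(df, class = c("feature_catalog", "data.frame"))
  attr(cat, "version") <- sub("\\.tsv$", "", basename(path))
  validate_catalog(cat)
  cat
}

#' Validate the catalog invariants
#'
#' Length exactly 270; feature ids contiguous from 0; category counts
#' 261/8/1; every non-structured pattern compiles; the 20 published key
#' features present.
#'
#' @param cat a `feature_catalog`
#' @return `cat`, invisibly
#' @export
validate_catalog <- function(cat) {
  if (nrow(cat) != CATALOG_SIZE) {
    stop(sprintf("catalog has %d features, expected %d", nrow(cat),
                 CATALOG_SIZE), call. = FALSE)
  }
  if (!identical(cat$feature_id, seq_len(CATALOG_SIZE) - 1L)) {
    stop("catalog feature_ids must be contiguous 0-based", call. = FALSE)
  }
  counts <- table(factor(cat$category, levels = names(CATALOG_COUNTS)))
  if (!identical(as.integer(counts), unname(CATALOG_COUNTS))) {
    stop(sprintf("catalog category counts %s, expected 261/8/1",
                 paste(counts, collapse = "/")), call. = FALSE)
  }
  regex_rows <- cat$category != "cat3_structured"
  if (any(!nzchar(cat$pattern[regex_rows]))) {
    stop("empty pattern in a regex category", call. = FALSE)
  }
  for (i in which(regex_rows)) {
    ok <- tryCatch({grepl(cat$pattern[i], "x", perl = TRUE); TRUE},
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) {
      stop(sprintf("feature %d: pattern does not compile: %s",
                   cat$feature_id[i], cat$pattern[i]), call. = FALSE)
    }
  }
  if (sum(grepl("\\bkey\\b", cat$source)) != 20L) {
    stop("catalog must flag exactly 20 key features", call. = FALSE)
  }
  invisible(cat)
}

catalog_version <- function(cat) attr(cat, "version") %||% "unversioned"

# Feature ids (0-based) whose patterns count as critical-site bleeding
# evidence for the ISTH rule.
critical_site_ids <- function(cat) {
  cat$feature_id[grepl("critical_site", cat$source, fixed = TRUE)]
}
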