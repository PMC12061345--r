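# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded operations inside the
#' package never disturb the caller's RNG stream.
#'
#' @param seed integer seed
#' @param code expression to evaluate
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Parse an ISO-8601 timestamp ("2020-01-02T03:04:05", optional fractional
# seconds / "Z" / space separator) into POSIXct (UTC).  Errors on failure.
parse_timestamp <- function(x, what = "timestamp") {
  if (inherits(x, "POSIXct")) {
    return(x)
  }
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop(sprintf("%s must be a non-empty ISO-8601 string", what), call. = FALSE)
  }
  s <- sub("Z$", "", x)
  s <- sub("T", " ", s, fixed = TRUE)
  out <- as.POSIXct(s, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  if (is.na(out)) {
    stop(sprintf("%s does not parse as ISO-8601: %s", what, x), call. = FALSE)
  }
  out
}

format_timestamp <- function(x) {
  format(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic pseudo-random id strings: "V0001", "N0001-03", ...
pad_id <- function(prefix, i, width = 5L) {
  sprintf("%s%0*d", prefix, width, i)
}
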