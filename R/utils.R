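# Internal helpers: dates as integer day offsets, seeded RNG scopes,
# rounding conventions shared across the pipeline.

# All window arithmetic runs on integer day offsets from this epoch;
# files render dates as ISO-8601 via day_to_date().
.EPOCH <- as.Date("2000-01-01")

day_to_date <- function(day) .EPOCH + as.integer(day)

date_to_day <- function(date) as.integer(as.Date(date) - .EPOCH)

#' Round half away from zero
#'
#' Rounding convention used by the points scoring system: 0.5 rounds to 1,
#' -0.5 rounds to -1 (unlike base `round()`'s round-half-even).
#'
#' @param x numeric vector.
#' @return integer vector.
#' @keywords internal
round_half_away <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Deterministic per-stage / per-patient seed derivation from one global
# seed. Named streams keep cohort assembly reproducible independently of
# data synthesis. Result stays inside the 32-bit signed range.
derive_seed <- function(seed, stream, index = 0L) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 10007 + h * 101 + as.numeric(index)) %% 2147483629)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stopf("`%s` must be a single probability in [0, 1], got %s", name,
          paste(format(x), collapse = ", "))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stopf("`%s` must be an integer >= %d", name, min)
  }
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
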