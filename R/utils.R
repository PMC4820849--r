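# Internal helpers: seed scoping and argument validation.

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("`%s` must be a single finite number", name)
  }
  if (integer && x != round(x)) stopf("`%s` must be an integer", name)
  if (x < lower || x > upper) {
    stopf("`%s` must be in [%s, %s], got %s", name, lower, upper, x)
  }
  invisible(x)
}

check_prob <- function(x, name) check_number(x, name, 0, 1)

check_year_span <- function(span, name) {
  if (!is.numeric(span) || length(span) != 2L || any(!is.finite(span)) ||
      span[1] > span[2] || any(span != round(span))) {
    stopf("`%s` must be an inclusive integer year span c(start, end) with start <= end", name)
  }
  invisible(as.integer(span))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
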