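#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid("`%s` must be a single finite number", name)
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_invalid("`%s` = %g is outside the allowed range", name, x)
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stop_invalid("`%s` must be an integer >= %d", name, min)
  as.integer(x)
}

# Deterministic 31-bit hash of a string, used to derive per-unit RNG streams
# (e.g. one seed per mediator) that do not depend on list position.
string_seed <- function(base_seed, label) {
  codes <- utf8ToInt(as.character(label))
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 2147483647
  as.integer((base_seed + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
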