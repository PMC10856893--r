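# Internal helpers shared across modules.

# Evaluate `code` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so generators never leak global state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_param("`seed` must be a single finite integer")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

stop_param <- function(...) stop(..., call. = FALSE)

# Scalar numeric validation with open/closed bounds.
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE,
                         allow_vector = FALSE) {
  if (!is.numeric(x) || (!allow_vector && length(x) != 1L) || anyNA(x) ||
      any(!is.finite(x)))
    stop_param(sprintf("`%s` must be finite numeric", name))
  lo_ok <- if (strict_lower) all(x > lower) else all(x >= lower)
  hi_ok <- if (strict_upper) all(x < upper) else all(x <= upper)
  if (!lo_ok || !hi_ok)
    stop_param(sprintf(
      "`%s` must lie in %s%s, %s%s", name,
      if (strict_lower) "(" else "[", format(lower), format(upper),
      if (strict_upper) ")" else "]"))
  invisible(x)
}

check_columns <- function(df, cols, name) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop_param(sprintf("`%s` is missing column(s): %s", name,
                       paste(miss, collapse = ", ")))
  invisible(df)
}

# Consecutive calendar days (Date) or consecutive integer day indices.
check_consecutive <- function(dates, name = "date") {
  d <- if (inherits(dates, "Date")) as.numeric(diff(dates)) else diff(as.numeric(dates))
  if (any(d != 1))
    stop_param(sprintf("`%s` must be consecutive days (gap at position %d)",
                       name, which(d != 1)[1] + 1L))
  invisible(dates)
}
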