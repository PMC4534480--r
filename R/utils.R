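# Internal helpers: classed conditions and RNG hygiene.

abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "perfvec_error", "error")))
}

# Run `expr` with a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, class = "perfvec_invalid_parameter") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name), class)
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  if (!lo_ok || x > upper) {
    abort(sprintf("`%s` = %g is outside its valid range", name, x), class)
  }
  invisible(as.numeric(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
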