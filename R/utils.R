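# Internal helpers: classed conditions and seeded evaluation.

hrvc_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "hrvc_error", "error")))
}

config_error <- function(field, msg) {
  hrvc_error(sprintf("invalid configuration: field '%s' %s", field, msg),
             "hrvc_config_error")
}

#' @noRd
check_scalar <- function(x, field, min = -Inf, max = Inf,
                         strict_min = FALSE, strict_max = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    config_error(field, "must be a single finite number")
  if (strict_min && x <= min) config_error(field, sprintf("must be > %g", min))
  if (!strict_min && x < min) config_error(field, sprintf("must be >= %g", min))
  if (strict_max && x >= max) config_error(field, sprintf("must be < %g", max))
  if (!strict_max && x > max) config_error(field, sprintf("must be <= %g", max))
  invisible(x)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
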