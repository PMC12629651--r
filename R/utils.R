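#' @keywords internal
"_PACKAGE"

#' Round half away from zero
#'
#' Deterministic half-up rounding used everywhere a real quantity is mapped
#' to an integer grid (quality classes, millisecond-to-frame conversion).
#' Base \code{round()} rounds half to even, which would make boundary cases
#' depend on parity; the pipeline instead commits to the conventional
#' half-up rule.
#'
#' @param x numeric vector.
#' @return numeric vector of integers (as doubles).
#' @examples
#' round_half_up(c(0.5, 1.5, 2.4, -0.5))
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Structured validation error naming the offending object and field.
ep_stop <- function(msg, field = NULL, where = NULL, class = "echopipe_validation_error") {
  loc <- paste(c(where, field), collapse = "/")
  full <- if (nzchar(loc)) sprintf("%s [%s]", msg, loc) else msg
  cond <- structure(
    class = c(class, "error", "condition"),
    list(message = full, call = sys.call(-1), field = field, where = where)
  )
  stop(cond)
}

# Exclusion "signal": exclusions are data, not errors. Used by timing and
# segmentation stages to report why a recording cannot contribute.
ep_signal <- function(reason, detail = NULL) {
  structure(list(excluded = TRUE, reason = reason, detail = detail),
            class = "echopipe_exclusion")
}

is_exclusion <- function(x) inherits(x, "echopipe_exclusion")

# Run code under a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards. All package randomness flows through this so
# that no function leaves a footprint on the global generator.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

check_scalar_number <- function(x, field, where = NULL, lower = -Inf, upper = Inf,
                                allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    ep_stop("value is missing", field, where)
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    ep_stop("value must be a finite number", field, where)
  if (x <= lower || x >= upper)
    ep_stop(sprintf("value %g outside open interval (%g, %g)", x, lower, upper),
            field, where)
  invisible(x)
}
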