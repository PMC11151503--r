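#' @keywords internal
"_PACKAGE"

# Validation helpers used across modules. Errors name the offending field so
# that spec-style messages ("non-positive lifetime ...") point at the input.

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_positive <- function(x, field, strict = TRUE) {
  if (!is.numeric(x) || length(x) == 0 || anyNA(x)) {
    stop_field(field, "must be numeric and non-missing")
  }
  if (strict && any(x <= 0)) stop_field(field, "must be > 0")
  if (!strict && any(x < 0)) stop_field(field, "must be >= 0")
  invisible(x)
}

check_flag <- function(x, choices, field) {
  x <- match.arg(x, choices)
  x
}

# Evaluate `expr` with a temporarily-seeded RNG, restoring the caller's RNG
# state afterwards so generators are reproducible without side effects.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop_field("seed", "must be a single finite number")
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
  })
  set.seed(as.integer(seed))
  expr
}

# Wrap angles (degrees) into [-90, 90). Orientations are axial: theta and
# theta + 180 are the same fiber direction.
wrap_angle_deg <- function(theta) {
  ((theta + 90) %% 180) - 90
}

`%||%` <- function(a, b) if (is.null(a)) b else a
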