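#' @keywords internal
#' @useDynLib myouq, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

## 1 mmHg in kPa; applied only at the forward-model boundary where cavity
## pressure (clinical units) meets the constitutive law (kPa).
MMHG_TO_KPA <- 0.133322

#' Convert a pressure from mmHg to kPa
#'
#' @param p_mmHg pressure in mmHg.
#' @return pressure in kPa.
#' @export
mmhg_to_kpa <- function(p_mmHg) p_mmHg * MMHG_TO_KPA

## Structured condition helpers.  All package errors carry class
## "myouq_error" plus a specific subclass so callers (and the battery
## drivers, which must record rather than die on solver failures) can
## discriminate.
myouq_error <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "myouq_error", "error")))
}

abort_validation <- function(msg, ...) myouq_error(msg, "myouq_validation_error", ...)
abort_numeric <- function(msg, ...) myouq_error(msg, "myouq_numeric_error", ...)
abort_solver <- function(msg, ...) myouq_error(msg, "myouq_solver_error", ...)
abort_degenerate <- function(msg, ...) myouq_error(msg, "myouq_degenerate_error", ...)

## exp() with an overflow guard: the sensitivity priors allow exponents b up
## to 10, and extreme deformations can push the exponential arguments past
## double range.  A structured error naming the offending term is raised
## instead of returning Inf.
guarded_exp <- function(x, term) {
  if (any(!is.finite(x)) || any(x > 700)) {
    abort_numeric(
      sprintf("exponential overflow in term '%s' (argument %.3g)", term, max(x)),
      term = term
    )
  }
  exp(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Derive a stream-specific RNG seed from a base seed.  Keeps derived seeds
## within the 32-bit integer range R requires.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 9973) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

## Gauss-Legendre nodes/weights on [a, b].
gauss_legendre <- function(n, a = -1, b = 1) {
  gl <- pracma::gaussLegendre(n, a, b)
  list(x = gl$x, w = gl$w)
}
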