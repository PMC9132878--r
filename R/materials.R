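## Material parameters of the Holzapfel-Ogden passive-myocardium law.

## Literature values used by the reduced four-parameter form: the sheet and
## fibre-sheet shear constants are held fixed at these published estimates.
HO_FIXED_SHEET_SHEAR <- c(a_s = 0.69, b_s = 1.11, a_fs = 0.31, b_fs = 2.58)

#' Holzapfel-Ogden material parameters
#'
#' Constructs the set of eight constants of the orthotropic
#' Holzapfel-Ogden strain-energy function: `a` (kPa) and `b` (-) for the
#' isotropic matrix response, `a_f`/`b_f` for the myofibre reinforcement,
#' `a_s`/`b_s` for the sheet reinforcement and `a_fs`/`b_fs` for the
#' fibre-sheet shear coupling.
#'
#' @param a,b isotropic stiffness (kPa) and exponent (dimensionless).
#' @param a_f,b_f fibre stiffness (kPa) and exponent.
#' @param a_s,b_s sheet stiffness (kPa) and exponent.
#' @param a_fs,b_fs fibre-sheet shear stiffness (kPa) and exponent.
#' @return an object of class `ho_params` (named list of eight positive
#'   numbers).
#' @seealso [ho_params_reduced()]
#' @export
ho_params <- function(a, b, a_f, b_f, a_s, b_s, a_fs, b_fs) {
  p <- list(a = a, b = b, a_f = a_f, b_f = b_f,
            a_s = a_s, b_s = b_s, a_fs = a_fs, b_fs = b_fs)
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort_validation("ho_params: all eight material constants must be strictly positive and finite")
  }
  structure(p, class = "ho_params")
}

#' Reduced four-parameter Holzapfel-Ogden material set
#'
#' The reduced parameterization retains `a`, `b`, `a_f`, `b_f` as free
#' parameters and fixes the weakly influential sheet and shear constants to
#' published literature values (`a_s = 0.69` kPa, `b_s = 1.11`,
#' `a_fs = 0.31` kPa, `b_fs = 2.58`).
#'
#' @param a,b,a_f,b_f free material constants (see [ho_params()]).
#' @return an object of class `ho_params`.
#' @export
ho_params_reduced <- function(a, b, a_f, b_f) {
  f <- HO_FIXED_SHEET_SHEAR
  ho_params(a, b, a_f, b_f,
            a_s = f[["a_s"]], b_s = f[["b_s"]],
            a_fs = f[["a_fs"]], b_fs = f[["b_fs"]])
}

#' @export
print.ho_params <- function(x, ...) {
  cat("Holzapfel-Ogden material parameters:\n")
  v <- unlist(x)
  cat(sprintf("  %-4s = %8.4g %s\n", names(v), v,
              ifelse(grepl("^a", names(v)), "kPa", "")), sep = "")
  invisible(x)
}

#' @export
as.data.frame.ho_params <- function(x, ...) {
  as.data.frame(unclass(x))
}
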