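## Push-forward of posterior parameter samples to uni-axial stress-stretch
## curves of a virtual myocardial strip, and identifiability/accuracy
## summaries in stress space.

#' Uni-axial stress-stretch curve
#'
#' Evaluates the homogeneous uni-axial Cauchy stress of a myocardial strip
#' over a grid of stretches `lambda = l/L`, along the myocyte or sheet
#' direction.
#'
#' @param params an [ho_params()] object.
#' @param direction `"fibre"` or `"sheet"`.
#' @param grid strictly increasing stretch values (default
#'   `c(1.02, 1.05, 1.1, 1.15, 1.2, 1.25, 1.3)`).
#' @return object of class `stress_stretch_curve`: list with `stretch`,
#'   `stress` (kPa) and `direction`.
#' @export
stress_stretch_curve <- function(params, direction = "fibre",
                                 grid = c(1.02, 1.05, 1.1, 1.15, 1.2, 1.25, 1.3)) {
  if (any(diff(grid) <= 0)) abort_validation("stress_stretch_curve: grid must be strictly increasing")
  if (any(grid <= 0.9) || any(grid > 1.4)) {
    abort_validation("stress_stretch_curve: grid outside the supported range (0.9, 1.4]")
  }
  structure(list(stretch = grid,
                 stress = uniaxial_stress(params, grid, direction),
                 direction = direction),
            class = "stress_stretch_curve")
}

#' Posterior distribution of stress-stretch curves
#'
#' Pushes (thinned) posterior parameter draws through the uni-axial
#' protocol: one stress-stretch curve per draw.  Draws whose lateral
#' solve fails are dropped and counted.
#'
#' @param theta_draws matrix of posterior draws (columns `a`, `b`, `a_f`,
#'   `b_f`, natural scale), e.g. from [posterior_theta()].
#' @param direction `"fibre"` or `"sheet"`.
#' @param grid stretch grid.
#' @param thin maximum number of draws pushed forward (default 500);
#'   draws are subsampled deterministically.
#' @return object of class `curve_distribution`: list with `stretch`,
#'   `stress` (matrix draws x stretch), `direction`, `n_failed`.
#' @export
posterior_stress_curves <- function(theta_draws, direction = "fibre",
                                    grid = c(1.02, 1.05, 1.1, 1.15, 1.2, 1.25, 1.3),
                                    thin = 500) {
  n <- nrow(theta_draws)
  keep <- if (n > thin) round(seq(1, n, length.out = thin)) else seq_len(n)
  out <- matrix(NA_real_, length(keep), length(grid))
  failed <- 0L
  for (i in seq_along(keep)) {
    th <- theta_draws[keep[i], ]
    row <- tryCatch(
      uniaxial_stress(do.call(ho_params_reduced, as.list(th[REDUCED_NAMES])),
                      grid, direction),
      myouq_error = function(e) NULL)
    if (is.null(row)) failed <- failed + 1L else out[i, ] <- row
  }
  ok <- stats::complete.cases(out)
  structure(list(stretch = grid, stress = out[ok, , drop = FALSE],
                 direction = direction, n_failed = failed),
            class = "curve_distribution")
}

stretch_col <- function(dist, stretch) {
  j <- which(abs(dist$stretch - stretch) < 1e-9)
  if (length(j) != 1) abort_validation("stretch value not on the curve grid")
  dist$stress[, j]
}

#' Stress identifiability score at a stretch level
#'
#' Inverse interquartile range of the posterior stress distribution at a
#' given stretch (kPa^-1): large values mean the inferred tissue response
#' is tightly constrained there.
#'
#' @param dist a [posterior_stress_curves()] result.
#' @param stretch one of the grid values.
#' @return scalar I-IQR (kPa^-1).
#' @export
stress_iiqr <- function(dist, stretch) {
  s <- stretch_col(dist, stretch)
  if (length(s) < 4) abort_validation("stress_iiqr: need >= 4 draws")
  iiqr(s)
}

#' Median inverse absolute error of inferred stress
#'
#' Accuracy of the stress posterior against the ground-truth curve:
#' the median over draws of `1 / |stress_draw - stress_true|` at one
#' stretch.  Draws with zero error are capped at `cap` (flagged via the
#' `"capped"` attribute) rather than propagating infinities.
#'
#' @param dist a [posterior_stress_curves()] result.
#' @param truth a [stress_stretch_curve()] at the true parameters (same
#'   grid and direction).
#' @param stretch one of the grid values.
#' @param cap value substituted for infinite inverse errors.
#' @return scalar (kPa^-1), possibly with attribute `capped = TRUE`.
#' @export
median_inverse_abs_error <- function(dist, truth, stretch, cap = 1e6) {
  s <- stretch_col(dist, stretch)
  jt <- which(abs(truth$stretch - stretch) < 1e-9)
  if (length(jt) != 1) abort_validation("median_inverse_abs_error: stretch not on truth grid")
  err <- abs(s - truth$stress[jt])
  inv <- ifelse(err == 0, Inf, 1 / err)
  v <- stats::median(inv)
  if (!is.finite(v) || v > cap) {
    v <- cap
    attr(v, "capped") <- TRUE
  }
  v
}
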