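## Desk-scale forward model geometry: an incompressible thick-walled
## cylinder standing in for the image-derived left ventricle, with
## rule-based transmural rotation of the fibre and sheet directions.

#' Cylinder geometry and fibre-rule specification
#'
#' Defines the reference geometry of the ventricular stand-in (a
#' thick-walled cylinder) and the rule-based fibre architecture: the fibre
#' helix angle varies linearly across the wall from `alpha_endo` at the
#' endocardium to `alpha_epi` at the epicardium, and the sheet angle varies
#' linearly from `sheet_endo` to `sheet_epi`.
#'
#' The default radii and length give a reference cavity volume of
#' `pi R_i^2 L` of about 157 ml, so that simulated end-diastolic volumes
#' across the parameter priors span a realistic adult range.
#'
#' @param R_i inner (endocardial) radius, mm.
#' @param R_o outer (epicardial) radius, mm.
#' @param L reference length, mm.
#' @param alpha_endo,alpha_epi fibre helix angles (degrees) at the
#'   endocardial and epicardial surfaces, measured from the circumferential
#'   direction in the circumferential-axial plane.
#' @param sheet_endo,sheet_epi sheet angles (degrees) at the two surfaces,
#'   measured in the radial-(fibre-normal) plane.
#' @param n_quad Gauss-Legendre quadrature order across the wall.
#' @param max_inner_stretch excessive-distortion guard: an equilibrium
#'   solution whose endocardial circumferential stretch `r_i / R_i`
#'   exceeds this value is treated as a failed simulation (the deformation
#'   is far outside the physiological range, where a finite-element
#'   counterpart loses mesh quality and diverges).
#' @return an object of class `lv_geometry`.
#' @export
lv_geometry <- function(R_i = 25, R_o = 35, L = 80,
                        alpha_endo = 60, alpha_epi = -90,
                        sheet_endo = 45, sheet_epi = -45,
                        n_quad = 16, max_inner_stretch = 2) {
  if (!(R_i > 0 && R_o > R_i && L > 0)) {
    abort_validation("lv_geometry: need 0 < R_i < R_o and L > 0")
  }
  if (n_quad < 4) abort_validation("lv_geometry: quadrature order must be at least 4")
  structure(list(R_i = R_i, R_o = R_o, L = L,
                 alpha_endo = alpha_endo, alpha_epi = alpha_epi,
                 sheet_endo = sheet_endo, sheet_epi = sheet_epi,
                 n_quad = as.integer(n_quad),
                 max_inner_stretch = max_inner_stretch),
            class = "lv_geometry")
}

#' Reference cavity volume (ml)
#'
#' @param spec an [lv_geometry()].
#' @return cavity volume of the undeformed cylinder in ml.
#' @export
reference_cavity_volume <- function(spec) {
  pi * spec$R_i^2 * spec$L / 1000
}

#' Segment layout for the 24 wall segments
#'
#' Mimics the clinical segmentation of the ventricular wall: 4 short-axis
#' slices from base to mid-ventricle, each divided into 6 AHA-style
#' segments (24 segments).  On the cylinder the slices are geometrically
#' identical, so segmental heterogeneity of the image-derived wall is
#' emulated by deterministic, seeded per-segment wall-thickness multipliers
#' (within +/-10%, mean exactly 1); each segment reports strains at its own
#' mid-wall radius, making the 24 strain outputs non-degenerate.
#'
#' @param seed integer seed fixing the multipliers.
#' @param spread half-width of the multiplier range (default 0.1).
#' @return an object of class `segment_layout` with components `slice`,
#'   `segment`, `label` and `thickness_mult` (length 24 each).
#' @export
segment_layout <- function(seed = 1234, spread = 0.1) {
  aha <- c("infsept", "antsept", "ant", "antlat", "inflat", "inf")
  slice <- rep(1:4, each = 6)
  segment <- rep(1:6, times = 4)
  mult <- with_seed(derive_seed(seed, 77L), stats::runif(24, 1 - spread, 1 + spread))
  mult <- mult / mean(mult)
  structure(list(
    slice = slice, segment = segment,
    label = paste0("s", slice, "_", aha[segment]),
    thickness_mult = mult, seed = seed
  ), class = "segment_layout")
}

#' Index of the pre-selected ("starred") segment
#'
#' The segment whose strains are used as scalar sensitivity-analysis
#' outputs: the inferior lateral segment of the second short-axis slice.
#'
#' @param layout a [segment_layout()].
#' @return integer index into the 24 segments.
#' @export
star_segment_index <- function(layout = segment_layout()) {
  which(layout$slice == 2 & layout$segment == 5)
}
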