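## Semi-analytic passive inflation of the thick-walled cylinder.
##
## The deformation is the classical incompressible inflation-extension
## field: a material point at reference radius R moves to
##   r(R) = sqrt(r_i^2 + (R^2 - R_i^2)/lambda_z),
## with principal stretches (lambda_r, lambda_theta, lambda_z) =
## (R/(r lambda_z), r/R, lambda_z).  The two scalar unknowns (r_i,
## lambda_z) are determined by
##   (i)  radial equilibrium: P = int_{r_i}^{r_o} (tau_qq - tau_rr)/r dr,
##   (ii) the reduced axial balance of a closed tube:
##        int_{r_i}^{r_o} (2 tau_zz - tau_rr - tau_qq) r dr = 0,
## both p-free because only stress differences enter.  Because the passive
## response is hyperelastic and quasi-static, the ramped pressure loading
## is path-independent and only the end-diastolic pressure needs to be
## solved; a pressure continuation is used as a fallback when the direct
## Newton solve fails for very soft configurations.

#' Forward-model input vector
#'
#' Assembles the eleven inputs of the forward model: the eight material
#' constants, the end-diastolic pressure (mmHg) and the two fibre-rule
#' helix angles (degrees).  Bounds follow the model-input table used for
#' the sensitivity and inference studies: material parameters in
#' `[0.1, 10]`, EDP in `[4, 30]` mmHg, `alpha_endo` in `[0, 90]` degrees,
#' `alpha_epi` in `[-90, 0]` degrees.
#'
#' @param params an [ho_params()] object.
#' @param edp end-diastolic pressure, mmHg (`>= 0`; 0 is the unloaded
#'   reference, values above 0 are not bound-checked below 4 to allow
#'   pressure sweeps).
#' @param alpha_endo,alpha_epi fibre helix angles, degrees.
#' @param check validate bounds (default TRUE warns outside the study
#'   bounds).
#' @return a named list of class `lv_input`.
#' @export
lv_input <- function(params, edp, alpha_endo = 60, alpha_epi = -90, check = TRUE) {
  if (!inherits(params, "ho_params")) abort_validation("lv_input: params must be ho_params")
  if (!is.finite(edp) || edp < 0) abort_validation("lv_input: edp must be >= 0")
  if (check) {
    if (alpha_endo < 0 || alpha_endo > 90 || alpha_epi < -90 || alpha_epi > 0) {
      abort_validation("lv_input: fibre angles outside study bounds [0,90] / [-90,0]")
    }
  }
  structure(list(params = params, edp = edp,
                 alpha_endo = alpha_endo, alpha_epi = alpha_epi),
            class = "lv_input")
}

## Deviatoric normal stresses (tau_rr', tau_qq', tau_zz') at quadrature
## points, for stretch fields and transmural fibre/sheet angles.
## lr, lq: vectors over quadrature points; lz scalar.
cylinder_wall_stress <- function(params, lr, lq, lz, alpha, beta) {
  ca <- cos(alpha); sa <- sin(alpha)
  cb <- cos(beta); sb <- sin(beta)
  ## local frame (r, theta, z): fibre m0 = (0, ca, sa),
  ## sheet s0 = (cb, -sb*sa, sb*ca); F diag -> push-forwards:
  m_q <- lq * ca; m_z <- lz * sa
  s_r <- lr * cb; s_q <- -lq * sb * sa; s_z <- lz * sb * ca
  I1 <- lr^2 + lq^2 + lz^2
  I4f <- m_q^2 + m_z^2
  I4s <- s_r^2 + s_q^2 + s_z^2
  I8 <- m_q * s_q + m_z * s_z
  p <- params
  W1 <- p$a / 2 * guarded_exp(p$b * (I1 - 3), "isotropic")
  e4f <- pmax(I4f - 1, 0)
  W4f <- p$a_f * e4f * guarded_exp(p$b_f * e4f^2, "fibre")
  e4s <- pmax(I4s - 1, 0)
  W4s <- p$a_s * e4s * guarded_exp(p$b_s * e4s^2, "sheet")
  W8 <- p$a_fs * I8 * guarded_exp(p$b_fs * I8^2, "fibre-sheet shear")
  list(
    rr = 2 * W1 * lr^2 + 2 * W4s * s_r^2,
    qq = 2 * W1 * lq^2 + 2 * W4f * m_q^2 + 2 * W4s * s_q^2 + 2 * W8 * m_q * s_q,
    zz = 2 * W1 * lz^2 + 2 * W4f * m_z^2 + 2 * W4s * s_z^2 + 2 * W8 * m_z * s_z
  )
}

## Equilibrium residuals for unknowns (r_i, lambda_z) at cavity pressure
## P_kpa.  Returns c(radial residual [kPa], scaled axial residual [kPa]).
inflation_residual <- function(ri, lz, x, spec, quad) {
  R <- quad$x; w <- quad$w
  r2 <- ri^2 + (R^2 - spec$R_i^2) / lz
  if (any(r2 <= 0)) return(c(NA_real_, NA_real_))
  r <- sqrt(r2)
  lq <- r / R
  lr <- R / (r * lz)
  t <- (R - spec$R_i) / (spec$R_o - spec$R_i)
  alpha <- (spec$alpha_endo + (spec$alpha_epi - spec$alpha_endo) * t) * pi / 180
  beta <- (spec$sheet_endo + (spec$sheet_epi - spec$sheet_endo) * t) * pi / 180
  tau <- cylinder_wall_stress(x$params, lr, lq, lz, alpha, beta)
  ## dr = R/(lz r) dR
  g1 <- sum(w * (tau$qq - tau$rr) / r * R / (lz * r)) - mmhg_to_kpa(x$edp)
  g2 <- sum(w * (2 * tau$zz - tau$rr - tau$qq) * R / lz) / (spec$R_o^2 - spec$R_i^2)
  c(g1, g2)
}

solve_inflation_once <- function(x, spec, quad, init, tol) {
  u <- init # (log(r_i/R_i), log lambda_z)
  fn <- function(u) inflation_residual(spec$R_i * exp(u[1]), exp(u[2]), x, spec, quad)
  r <- fn(u)
  if (any(!is.finite(r))) return(NULL)
  for (it in 1:80) {
    if (max(abs(r)) < tol) {
      return(list(u = u, resid = max(abs(r))))
    }
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      h <- 1e-7 * max(1, abs(u[j]))
      up <- u; up[j] <- up[j] + h
      rp <- fn(up)
      if (any(!is.finite(rp))) return(NULL)
      J[, j] <- (rp - r) / h
    }
    step <- tryCatch(solve(J, r), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    ## cap step length for robustness far from the solution
    step <- step * min(1, 0.5 / max(abs(step)))
    damp <- 1
    repeat {
      un <- u - damp * step
      rn <- tryCatch(fn(un), error = function(e) NULL)
      if (!is.null(rn) && all(is.finite(rn)) &&
          (sum(rn^2) < sum(r^2) || damp < 1e-4)) break
      damp <- damp / 2
    }
    if (damp < 1e-4) return(NULL)
    u <- u - damp * step
    r <- fn(u)
    if (any(!is.finite(r))) return(NULL)
  }
  if (max(abs(r)) < tol) list(u = u, resid = max(abs(r))) else NULL
}

#' Solve passive inflation of the cylinder model
#'
#' Finds the deformed inner radius and axial stretch at which the wall is
#' in radial and axial equilibrium with the cavity pressure (the mmHg to
#' kPa conversion is applied here, at the forward-model boundary).
#'
#' @param x an [lv_input()].
#' @param spec an [lv_geometry()].
#' @param tol equilibrium residual tolerance, kPa.
#' @return an object of class `lv_deformation` with fields `r_i` (mm),
#'   `lambda_z`, `residual` (kPa), plus the input and geometry.
#' @export
solve_inflation <- function(x, spec = lv_geometry(), tol = 1e-9) {
  if (!inherits(x, "lv_input")) abort_validation("solve_inflation: x must be an lv_input")
  quad <- gauss_legendre(spec$n_quad, spec$R_i, spec$R_o)
  if (x$edp == 0) {
    return(structure(list(r_i = spec$R_i, lambda_z = 1, residual = 0,
                          input = x, spec = spec), class = "lv_deformation"))
  }
  sol <- solve_inflation_once(x, spec, quad, c(log(1.05), 0), tol)
  if (is.null(sol)) {
    ## pressure continuation: ramp the cavity pressure up in stages,
    ## re-using each converged state as the next initial guess
    for (nstep in c(8, 32)) {
      u <- c(log(1.02), 0)
      ok <- TRUE
      for (pfrac in seq_len(nstep) / nstep) {
        xi <- x; xi$edp <- x$edp * pfrac
        s <- solve_inflation_once(xi, spec, quad, u, tol)
        if (is.null(s)) { ok <- FALSE; break }
        u <- s$u
        sol <- s
      }
      if (ok) break else sol <- NULL
    }
  }
  if (is.null(sol)) {
    abort_solver(sprintf(
      "solve_inflation: equilibrium solve failed at EDP %.3g mmHg (a=%.3g, b=%.3g)",
      x$edp, x$params$a, x$params$b))
  }
  guard <- spec$max_inner_stretch %||% Inf
  if (exp(sol$u[1]) > guard) {
    abort_solver(sprintf(
      "solve_inflation: excessive distortion (endocardial stretch %.2f > %.2f) at EDP %.3g mmHg",
      exp(sol$u[1]), guard, x$edp))
  }
  structure(list(r_i = spec$R_i * exp(sol$u[1]), lambda_z = exp(sol$u[2]),
                 residual = sol$resid, input = x, spec = spec),
            class = "lv_deformation")
}

## Principal stretches at reference radius R for a solved configuration.
deformation_stretches <- function(config, R) {
  spec <- config$spec
  r <- sqrt(config$r_i^2 + (R^2 - spec$R_i^2) / config$lambda_z)
  list(lr = R / (r * config$lambda_z), lq = r / R, lz = config$lambda_z, r = r)
}

#' Quantities of interest of a solved inflation
#'
#' Computes the cavity volume (ml) and the 24 segmental circumferential,
#' longitudinal and radial strains.  Following clinical convention the
#' strains are referenced to the end-diastolic configuration: with
#' `Ftilde = F^{-1}` (deformation from end-diastole back to the reference)
#' the Green-Lagrange tensor is `E = (Ftilde' Ftilde - I)/2`, so for a
#' principal stretch `lambda` the reported strain is
#' `(1/lambda^2 - 1)/2`.  All strains vanish identically at zero pressure.
#'
#' @param config an `lv_deformation` from [solve_inflation()].
#' @param layout a [segment_layout()].
#' @return an object of class `lv_qoi`: list with `lvv` (ml) and numeric
#'   vectors `eps_cc`, `eps_ll`, `eps_rr` (length 24, named by segment).
#' @export
compute_qois <- function(config, layout = segment_layout()) {
  spec <- config$spec
  lvv <- pi * config$r_i^2 * (config$lambda_z * spec$L) / 1000
  half_wall <- (spec$R_o - spec$R_i) / 2
  R_seg <- spec$R_i + half_wall * layout$thickness_mult
  st <- deformation_stretches(config, R_seg)
  eps <- function(lam) (1 / lam^2 - 1) / 2
  out <- list(
    lvv = lvv,
    eps_cc = stats::setNames(eps(st$lq), layout$label),
    eps_ll = stats::setNames(eps(rep(st$lz, 24)), layout$label),
    eps_rr = stats::setNames(eps(st$lr), layout$label)
  )
  structure(out, class = "lv_qoi")
}

#' Flatten a QoI object to a named numeric vector
#'
#' @param q an `lv_qoi`.
#' @return named numeric vector of length 73 (`lvv`, `eps_cc_*`,
#'   `eps_ll_*`, `eps_rr_*`).
#' @export
qoi_vector <- function(q) {
  c(lvv = q$lvv,
    stats::setNames(q$eps_cc, paste0("eps_cc_", seq_len(24))),
    stats::setNames(q$eps_ll, paste0("eps_ll_", seq_len(24))),
    stats::setNames(q$eps_rr, paste0("eps_rr_", seq_len(24))))
}
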