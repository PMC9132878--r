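## Holzapfel-Ogden constitutive model: invariants, strain energy, Cauchy
## stress and virtual homogeneous uni-axial stretch protocols.
##
## The strain-energy density is
##   Psi = a/(2b) [exp(b(I1 - 3)) - 1]
##       + sum_{i in {f,s}} a_i/(2 b_i) [exp(b_i (max(I4i,1) - 1)^2) - 1]
##       + a_fs/(2 b_fs) [exp(b_fs I8fs^2) - 1],
## with the max() switch expressing that fibre/sheet families bear load in
## extension only.  The switch makes Psi C^1 but not C^2 at I4 = 1; the
## derivative exactly at I4 = 1 is defined to be 0 (compression branch).

#' Deformation state for the constitutive model
#'
#' Bundles a deformation gradient with the reference fibre and sheet unit
#' directions.  Incompressibility (`det F = 1`), unit length of the
#' direction vectors and their mutual orthogonality are validated.
#'
#' @param F 3x3 deformation gradient (dimensionless, `det F = 1`).
#' @param m0 reference unit fibre direction.
#' @param s0 reference unit sheet direction, orthogonal to `m0`.
#' @param tol validation tolerance.
#' @return an object of class `deformation_state`.
#' @export
deformation_state <- function(F, m0 = c(1, 0, 0), s0 = c(0, 1, 0), tol = 1e-8) {
  F <- matrix(as.numeric(F), 3, 3)
  m0 <- as.numeric(m0); s0 <- as.numeric(s0)
  if (abs(det(F) - 1) > max(tol, 1e-6)) {
    abort_validation(sprintf("deformation_state: det(F) = %.8f violates incompressibility", det(F)))
  }
  if (abs(sum(m0^2) - 1) > 1e-8 || abs(sum(s0^2) - 1) > 1e-8) {
    abort_validation("deformation_state: fibre and sheet directions must be unit vectors")
  }
  if (abs(sum(m0 * s0)) > 1e-8) {
    abort_validation("deformation_state: fibre and sheet directions must be orthogonal")
  }
  structure(list(F = F, m0 = m0, s0 = s0), class = "deformation_state")
}

#' Strain invariants of the Holzapfel-Ogden model
#'
#' Computes `I1 = tr(C)`, the squared fibre and sheet stretches
#' `I4f = m0 . (C m0)`, `I4s = s0 . (C s0)` and the fibre-sheet coupling
#' invariant `I8fs = m0 . (C s0)`, with `C = F'F` the right Cauchy-Green
#' tensor.
#'
#' @param state a [deformation_state()].
#' @return a list with components `I1`, `I4f`, `I4s`, `I8fs`.
#' @export
strain_invariants <- function(state) {
  if (!inherits(state, "deformation_state")) state <- do.call(deformation_state, state)
  C <- crossprod(state$F)
  list(
    I1 = sum(diag(C)),
    I4f = as.numeric(state$m0 %*% C %*% state$m0),
    I4s = as.numeric(state$s0 %*% C %*% state$s0),
    I8fs = as.numeric(state$m0 %*% C %*% state$s0)
  )
}

#' Holzapfel-Ogden strain-energy density
#'
#' Evaluates the orthotropic strain-energy density (kPa) from a set of
#' invariants.  The anisotropic terms use `max(I4i, 1)`, so fibres and
#' sheets contribute no energy in compression.  Overflowing exponentials
#' raise a structured numeric-range error naming the offending term.
#'
#' @param params an [ho_params()] object.
#' @param inv invariant list as returned by [strain_invariants()].
#' @return energy density in kPa (non-negative; zero at the reference
#'   configuration).
#' @export
strain_energy <- function(params, inv) {
  p <- params
  e1 <- guarded_exp(p$b * (inv$I1 - 3), "isotropic")
  q4f <- (max(inv$I4f, 1) - 1)^2
  q4s <- (max(inv$I4s, 1) - 1)^2
  e4f <- guarded_exp(p$b_f * q4f, "fibre")
  e4s <- guarded_exp(p$b_s * q4s, "sheet")
  e8 <- guarded_exp(p$b_fs * inv$I8fs^2, "fibre-sheet shear")
  p$a / (2 * p$b) * (e1 - 1) +
    p$a_f / (2 * p$b_f) * (e4f - 1) +
    p$a_s / (2 * p$b_s) * (e4s - 1) +
    p$a_fs / (2 * p$b_fs) * (e8 - 1)
}

## Partial derivatives of Psi with respect to the invariants.  The
## tension-only switch zeroes dPsi/dI4i for I4i <= 1 (including exactly 1).
ho_dpsi <- function(params, inv) {
  p <- params
  dI1 <- p$a / 2 * guarded_exp(p$b * (inv$I1 - 3), "isotropic")
  d4 <- function(a_i, b_i, I4, term) {
    if (I4 <= 1) return(0)
    a_i * (I4 - 1) * guarded_exp(b_i * (I4 - 1)^2, term)
  }
  list(
    dI1 = dI1,
    dI4f = d4(p$a_f, p$b_f, inv$I4f, "fibre"),
    dI4s = d4(p$a_s, p$b_s, inv$I4s, "sheet"),
    dI8 = p$a_fs * inv$I8fs * guarded_exp(p$b_fs * inv$I8fs^2, "fibre-sheet shear")
  )
}

#' Cauchy stress of the Holzapfel-Ogden model
#'
#' Analytic Cauchy stress for an incompressible material,
#' `tau = 2 W1 B + 2 W4f m x m + 2 W4s s x s + W8 (m x s + s x m) - p I`,
#' where `B = F F'`, `m = F m0`, `s = F s0` and `W*` are the partial
#' derivatives of the strain energy with respect to the invariants.
#'
#' @param params an [ho_params()] object.
#' @param state a [deformation_state()].
#' @param p Lagrange multiplier enforcing incompressibility (kPa).
#' @return a list with the symmetric 3x3 Cauchy stress `tau` (kPa) and the
#'   multiplier `p`.
#' @export
cauchy_stress <- function(params, state, p = 0) {
  if (!inherits(state, "deformation_state")) state <- do.call(deformation_state, state)
  inv <- strain_invariants(state)
  W <- ho_dpsi(params, inv)
  F <- state$F
  B <- tcrossprod(F)
  m <- as.numeric(F %*% state$m0)
  s <- as.numeric(F %*% state$s0)
  tau <- 2 * W$dI1 * B +
    2 * W$dI4f * tcrossprod(m) +
    2 * W$dI4s * tcrossprod(s) +
    W$dI8 * (tcrossprod(m, s) + tcrossprod(s, m)) -
    p * diag(3)
  list(tau = (tau + t(tau)) / 2, p = p)
}

## Deviatoric (p-free) normal Cauchy stresses for a principal-stretch state
## F = diag(l1, l2, l3) with fibre along axis `fibre_axis` and sheet along
## `sheet_axis`.  Used by the uni-axial protocol and the cylinder model.
ho_diag_stress <- function(params, l, fibre_axis = 1, sheet_axis = 2) {
  I4f <- l[fibre_axis]^2
  I4s <- l[sheet_axis]^2
  inv <- list(I1 = sum(l^2), I4f = I4f, I4s = I4s, I8fs = 0)
  W <- ho_dpsi(params, inv)
  t_dev <- 2 * W$dI1 * l^2
  t_dev[fibre_axis] <- t_dev[fibre_axis] + 2 * W$dI4f * I4f
  t_dev[sheet_axis] <- t_dev[sheet_axis] + 2 * W$dI4s * I4s
  t_dev
}

#' Uni-axial Cauchy stress of a myocardial strip
#'
#' Simulates the virtual uni-axial stretch of a homogeneous myocardial
#' strip along the myocyte or sheet direction.  The stretch is
#' `lambda = l/L` (current over reference length).  The two lateral
#' stretches are solved jointly with the incompressibility constraint so
#' that both lateral Cauchy stresses vanish; orthotropy makes the lateral
#' directions inequivalent, so a full two-variable root find is used with
#' the equal-lateral isotropic solution as the initial guess.
#'
#' @param params an [ho_params()] object.
#' @param stretch axial stretch `lambda > 0`.
#' @param direction `"fibre"` or `"sheet"`: the strip axis.
#' @param tol residual tolerance (kPa).
#' @return axial Cauchy stress in kPa.
#' @export
uniaxial_stress <- function(params, stretch, direction = c("fibre", "sheet"),
                            tol = 1e-10) {
  direction <- match.arg(direction)
  if (length(stretch) > 1) {
    return(vapply(stretch, uniaxial_stress, numeric(1),
                  params = params, direction = direction, tol = tol))
  }
  lam <- stretch
  if (!is.finite(lam) || lam <= 0) abort_validation("uniaxial_stress: stretch must be positive")
  ## strip axis = axis 1; fibre/sheet occupy axes 1 and 2
  fa <- if (direction == "fibre") 1 else 2
  sa <- if (direction == "fibre") 2 else 1
  ## unknowns u = (log lambda2, p); lambda3 = 1/(lam*lambda2)
  resid <- function(u) {
    l2 <- exp(u[1])
    l <- c(lam, l2, 1 / (lam * l2))
    t_dev <- ho_diag_stress(params, l, fibre_axis = fa, sheet_axis = sa)
    c(t_dev[2] - u[2], t_dev[3] - u[2])
  }
  l2_0 <- lam^(-1 / 2)
  t0 <- ho_diag_stress(params, c(lam, l2_0, l2_0), fibre_axis = fa, sheet_axis = sa)
  u <- c(log(l2_0), t0[3])
  ok <- FALSE
  for (it in 1:60) {
    r <- resid(u)
    if (max(abs(r)) < tol) { ok <- TRUE; break }
    ## finite-difference Jacobian of the 2x2 system
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      h <- 1e-7 * max(1, abs(u[j]))
      up <- u; up[j] <- up[j] + h
      J[, j] <- (resid(up) - r) / h
    }
    step <- tryCatch(solve(J, r), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    ## damped update
    lam_d <- 1
    for (k in 1:30) {
      un <- u - lam_d * step
      rn <- tryCatch(resid(un), error = function(e) NULL)
      if (!is.null(rn) && all(is.finite(rn)) && sum(rn^2) < sum(r^2)) break
      lam_d <- lam_d / 2
    }
    u <- u - lam_d * step
  }
  r <- resid(u)
  if (!ok && max(abs(r)) > 1e-8) {
    abort_solver(sprintf(
      "uniaxial_stress: lateral-stretch root find did not converge (residual %.3g kPa)",
      max(abs(r))), residual = max(abs(r)))
  }
  l2 <- exp(u[1])
  l <- c(lam, l2, 1 / (lam * l2))
  t_dev <- ho_diag_stress(params, l, fibre_axis = fa, sheet_axis = sa)
  t_dev[1] - u[2]
}
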