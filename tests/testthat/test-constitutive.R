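test_that("strain invariants match their definitions", {
  ## identity deformation
  st <- deformation_state(diag(3))
  inv <- strain_invariants(st)
  expect_equal(inv$I1, 3)
  expect_equal(inv$I4f, 1)
  expect_equal(inv$I4s, 1)
  expect_equal(inv$I8fs, 0)

  ## axis-aligned incompressible stretch: I4f = lambda^2
  lam <- 1.2
  st <- deformation_state(diag(c(lam, lam^-0.5, lam^-0.5)))
  inv <- strain_invariants(st)
  expect_equal(inv$I4f, lam^2)
  expect_equal(inv$I8fs, 0)

  ## simple shear: compare against explicit dense matrix products
  gam <- 0.3
  F <- diag(3); F[1, 2] <- gam
  st <- deformation_state(F)
  inv <- strain_invariants(st)
  C <- t(F) %*% F
  expect_equal(inv$I1, sum(diag(C)))
  expect_equal(inv$I8fs, (C %*% c(0, 1, 0))[1])
  expect_equal(inv$I8fs, gam)
})

test_that("deformation state validates its invariants", {
  expect_error(deformation_state(2 * diag(3)), class = "myouq_validation_error")
  expect_error(deformation_state(diag(3), m0 = c(2, 0, 0)),
               class = "myouq_validation_error")
  expect_error(deformation_state(diag(3), m0 = c(1, 0, 0), s0 = c(1, 0, 0)),
               class = "myouq_validation_error")
})

test_that("strain energy is zero at reference and obeys the tension-only switch", {
  p <- fix_params()
  ref <- list(I1 = 3, I4f = 1, I4s = 1, I8fs = 0)
  expect_equal(strain_energy(p, ref), 0)

  ## fibre compression contributes nothing
  compressed <- list(I1 = 3, I4f = 0.8, I4s = 1, I8fs = 0)
  expect_equal(strain_energy(p, compressed), 0)

  ## isotropic term closed form: a/(2b) (exp(b (I1-3)) - 1)
  iso <- ho_params(1, 1, 1e-12, 1, 1e-12, 1, 1e-12, 1)
  expect_equal(strain_energy(iso, list(I1 = 3.5, I4f = 1, I4s = 1, I8fs = 0)),
               0.5 * (exp(0.5) - 1), tolerance = 1e-9)
})

test_that("overflowing exponentials raise a structured numeric error", {
  p <- fix_params()
  expect_error(strain_energy(p, list(I1 = 1e4, I4f = 1, I4s = 1, I8fs = 0)),
               class = "myouq_numeric_error")
})

test_that("analytic Cauchy stress matches the finite-difference oracle", {
  set.seed(101)
  for (rep in 1:20) {
    p <- random_ho_params()
    st <- deformation_state(random_F())
    tau <- cauchy_stress(p, st, p = 0)$tau
    tau_fd <- fd_cauchy(p, st)
    expect_lt(max(abs(tau - tau_fd)) / max(abs(tau)), 1e-6)
    expect_lt(max(abs(tau - t(tau))), 1e-12)
  }
})

test_that("the unloaded reference is stress-free with the equilibrium multiplier", {
  p <- fix_params()
  st <- deformation_state(diag(3))
  ## at identity the stress is hydrostatic 2*W1*I = a*I; the multiplier that
  ## enforces a traction-free reference is p = a
  tau <- cauchy_stress(p, st, p = p$a)$tau
  expect_lt(max(abs(tau)), 1e-12)
  tau0 <- cauchy_stress(p, st, p = 0)$tau
  expect_lt(max(abs(tau0 - diag(3) * tau0[1, 1])), 1e-12) # purely hydrostatic
})

test_that("energy is objective under rotations", {
  set.seed(7)
  for (rep in 1:10) {
    p <- random_ho_params()
    F <- random_F()
    qr_ <- qr(matrix(stats::rnorm(9), 3))
    Q <- qr.Q(qr_)
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    inv1 <- strain_invariants(deformation_state(F))
    inv2 <- strain_invariants(deformation_state(Q %*% F))
    expect_equal(strain_energy(p, inv1), strain_energy(p, inv2),
                 tolerance = 1e-10)
  }
})

test_that("uni-axial stress matches the isotropic closed form", {
  iso <- ho_params(1.3, 0.9, 1e-12, 1, 1e-12, 1, 1e-12, 1)
  for (lam in c(0.95, 1.05, 1.2, 1.3)) {
    I1 <- lam^2 + 2 / lam
    closed <- iso$a * exp(iso$b * (I1 - 3)) * (lam^2 - 1 / lam)
    expect_equal(uniaxial_stress(iso, lam, "fibre"), closed, tolerance = 1e-7)
  }
})

test_that("uni-axial stress vanishes at unit stretch and is monotone in tension", {
  p <- fix_params()
  expect_equal(uniaxial_stress(p, 1, "fibre"), 0)
  expect_equal(uniaxial_stress(p, 1, "sheet"), 0)
  grid <- seq(1, 1.3, by = 0.025)
  s <- uniaxial_stress(p, grid, "fibre")
  expect_true(all(diff(s) > 0))
  ## continuity at lambda = 1
  expect_lt(abs(uniaxial_stress(p, 1 + 1e-6, "fibre")), 1e-4)
})

test_that("fibre direction is stiffer than sheet direction when a_f >> a_s", {
  p <- ho_params(1, 2, 8, 4, 0.5, 1.1, 0.3, 2.6)
  expect_gt(uniaxial_stress(p, 1.1, "fibre"), uniaxial_stress(p, 1.1, "sheet"))
  ## monotone in a_f
  s_af <- vapply(c(2, 4, 8), function(af) {
    uniaxial_stress(ho_params(1, 2, af, 4, 0.5, 1.1, 0.3, 2.6), 1.1, "fibre")
  }, numeric(1))
  expect_true(all(diff(s_af) > 0))
})

test_that("material parameter constructors enforce positivity and reduced values", {
  expect_error(ho_params(0, 1, 1, 1, 1, 1, 1, 1), class = "myouq_validation_error")
  expect_error(ho_params(1, -1, 1, 1, 1, 1, 1, 1), class = "myouq_validation_error")
  r <- ho_params_reduced(2, 3, 4, 5)
  expect_identical(r$a_s, 0.69)
  expect_identical(r$b_s, 1.11)
  expect_identical(r$a_fs, 0.31)
  expect_identical(r$b_fs, 2.58)
})
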