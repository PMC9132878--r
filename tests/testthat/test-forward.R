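test_that("geometry and segment layout invariants", {
  expect_error(lv_geometry(R_i = 30, R_o = 25), class = "myouq_validation_error")
  expect_equal(reference_cavity_volume(lv_geometry()), pi * 25^2 * 80 / 1000)
  lay <- segment_layout(99)
  expect_length(lay$thickness_mult, 24)
  expect_equal(mean(lay$thickness_mult), 1)
  expect_true(all(lay$thickness_mult > 0))
  expect_identical(lay$thickness_mult, segment_layout(99)$thickness_mult)
  ## starred segment: inferior lateral, second slice
  expect_identical(star_segment_index(lay), 11L)
})

test_that("unloaded configuration is exact and strains vanish at zero pressure", {
  x <- lv_input(fix_params(), edp = 0)
  cfg <- solve_inflation(x)
  expect_identical(cfg$r_i, 25)
  expect_identical(cfg$lambda_z, 1)
  q <- compute_qois(cfg)
  expect_equal(q$lvv, reference_cavity_volume(cfg$spec))
  expect_true(all(c(q$eps_cc, q$eps_ll, q$eps_rr) == 0))
})

test_that("equilibrium solve satisfies its contract", {
  p <- ho_params_reduced(2, 5, 3, 4)
  cfg <- solve_inflation(lv_input(p, 10))
  expect_lt(cfg$residual, 1e-8)
  expect_gt(cfg$r_i, 25)
  ## incompressibility at quadrature radii: r(R)^2 = r_i^2 + (R^2 - R_i^2)/lz
  R <- seq(25, 35, length.out = 9)
  st <- myouq:::deformation_stretches(cfg, R)
  expect_lt(max(abs(st$r^2 - (cfg$r_i^2 + (R^2 - 25^2) / cfg$lambda_z))), 1e-10)
  ## principal stretches multiply to 1 (incompressible deformation field)
  expect_lt(max(abs(st$lr * st$lq * st$lz - 1)), 1e-12)
})

test_that("wall quadrature is converged at the default order", {
  p <- ho_params_reduced(2, 5, 3, 4)
  lvv <- vapply(c(8, 16, 32), function(nq) {
    compute_qois(solve_inflation(lv_input(p, 20), lv_geometry(n_quad = nq)))$lvv
  }, numeric(1))
  ## default order 16 agrees with a doubled rule far below physical accuracy
  expect_lt(abs(lvv[2] - lvv[3]) / lvv[3], 1e-6)
})

test_that("a high simulation-failure rate aborts dataset generation", {
  soft <- data.frame(a = 0.1, b = 0.1, a_f = 0.1, b_f = 0.1,
                     a_s = 0.1, b_s = 0.1, a_fs = 0.1, b_fs = 0.1,
                     edp = 30, alpha_endo = 60, alpha_epi = -90)[rep(1, 5), ]
  expect_error(generate_training_set(soft), class = "myouq_solver_error")
})

test_that("volume responds monotonically to pressure and stiffness", {
  p <- ho_params_reduced(2, 5, 3, 4)
  lvv <- vapply(c(5, 10, 20, 30), function(edp) {
    compute_qois(solve_inflation(lv_input(p, edp)))$lvv
  }, numeric(1))
  expect_true(all(diff(lvv) > 0))
  lvv_a <- vapply(c(1, 2, 4, 8), function(a) {
    compute_qois(solve_inflation(lv_input(ho_params_reduced(a, 5, 3, 4), 10)))$lvv
  }, numeric(1))
  expect_true(all(diff(lvv_a) < 0))
})

test_that("strain sign convention follows the end-diastolic reference", {
  cfg <- solve_inflation(lv_input(ho_params_reduced(2, 5, 3, 4), 15))
  q <- compute_qois(cfg)
  expect_true(all(q$eps_cc < 0)) # circumference grew: (1/lq^2 - 1)/2 < 0
  expect_true(all(q$eps_rr > 0)) # wall thinned
  ## scalar oracle at one segment's mid-wall radius
  lay <- segment_layout()
  R_seg <- 25 + 5 * lay$thickness_mult[3]
  lq <- myouq:::deformation_stretches(cfg, R_seg)$lq
  expect_equal(unname(q$eps_cc[3]), (1 / lq^2 - 1) / 2)
})

test_that("designs respect bounds, spaces and the two-block structure", {
  b <- default_input_bounds()
  des <- sobol_design(128, b, space = "linear")
  for (nm in names(b)) {
    expect_true(all(des[[nm]] >= b[[nm]][1] & des[[nm]] <= b[[nm]][2]))
  }
  expect_error(sobol_design(8, list(x = c(-1, 1)), space = "log"),
               class = "myouq_validation_error")
  ## two-block design: first half linear, second half log-mapped materials
  n <- 512
  two <- sa_training_design(n)
  u <- sobol_sequence(n, 11)
  expect_equal(two$a[1:(n / 2)], (0.1 + u[1:(n / 2), 1] * 9.9))
  expect_equal(two$a[(n / 2 + 1):n],
               exp(log(0.1) + u[(n / 2 + 1):n, 1] * (log(10) - log(0.1))))
  ## EDP stays linear in both halves
  expect_equal(two$edp, 4 + u[, 9] * 26)
  ## log-space samples uniform in log(a)
  ks <- stats::ks.test(log(two$a[(n / 2 + 1):n]),
                       "punif", log(0.1), log(10))
  expect_gt(ks$p.value, 0.01)
})

test_that("training-set generation is deterministic and tracks failures", {
  des <- sobol_design(40, space = c(rep("log", 8), "linear", "linear", "linear"))
  ds1 <- generate_training_set(des)
  ds2 <- generate_training_set(des)
  expect_identical(ds1$qois, ds2$qois)
  expect_equal(nrow(ds1$qois), 40 - ds1$n_failed)
  expect_equal(sum(ds1$status == "ok"), nrow(ds1$inputs))
})

test_that("observation noise model matches its contract", {
  q <- compute_qois(solve_inflation(lv_input(ho_params_reduced(2, 5, 3, 4), 10)))
  clean <- add_observation_noise(q, 0, 0, seed = 1)
  expect_equal(clean$y0, q$lvv)
  expect_equal(clean$y_tilde, as.numeric(q$eps_cc))
  ## Monte-Carlo variance check per channel
  y0s <- vapply(1:4000, function(s) add_observation_noise(q, 5, 0.03, seed = s)$y0,
                numeric(1))
  expect_lt(abs(stats::var(y0s) - 25) / 25, 0.05)
  s1 <- vapply(1:4000, function(s) add_observation_noise(q, 5, 0.03, seed = s)$y_tilde[7],
               numeric(1))
  expect_lt(abs(stats::var(s1) - 0.03^2) / 0.03^2, 0.05)
  ## same seed, same observation
  expect_identical(add_observation_noise(q, 5, 0.03, seed = 11),
                   add_observation_noise(q, 5, 0.03, seed = 11))
})

test_that("test battery reuses configurations across pressures", {
  bat <- generate_test_battery(12, edp_list = c(5, 10), seed = 4)
  expect_s3_class(bat, "iuq_battery")
  for (case in bat) {
    expect_identical(names(case$obs), c("5", "10"))
    expect_length(case$obs[["5"]]$obs$y_tilde, 24)
  }
  ## marginal log-uniformity of the truths
  th <- do.call(rbind, lapply(bat, `[[`, "theta"))
  ks <- stats::ks.test(log(as.numeric(th)), "punif", log(0.1), log(10))
  expect_gt(ks$p.value, 0.01)
  ## determinism
  bat2 <- generate_test_battery(12, edp_list = c(5, 10), seed = 4)
  expect_identical(bat[[3]]$obs[["10"]]$obs$y_tilde,
                   bat2[[3]]$obs[["10"]]$obs$y_tilde)
})
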