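## Shared fixtures, built once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

## a representative full parameter set
fix_params <- function() ho_params(a = 1.2, b = 2.3, a_f = 2.9, b_f = 3.1,
                                   a_s = 0.7, b_s = 1.1, a_fs = 0.3, b_fs = 2.6)

## random admissible incompressible deformation gradient
random_F <- function(scale = 0.15) {
  A <- matrix(stats::rnorm(9, sd = scale), 3)
  F <- diag(3) + A
  F / det(F)^(1 / 3)
}

random_ho_params <- function() {
  v <- exp(stats::runif(8, log(0.2), log(5)))
  ho_params(v[1], v[2], v[3], v[4], v[5], v[6], v[7], v[8])
}

## finite-difference first Piola stress of the energy, pushed forward
fd_cauchy <- function(params, state, h = 1e-6) {
  F <- state$F
  psi_of <- function(FF) {
    C <- crossprod(FF)
    strain_energy(params, list(
      I1 = sum(diag(C)),
      I4f = as.numeric(state$m0 %*% C %*% state$m0),
      I4s = as.numeric(state$s0 %*% C %*% state$s0),
      I8fs = as.numeric(state$m0 %*% C %*% state$s0)))
  }
  P <- matrix(0, 3, 3)
  for (i in 1:3) {
    for (j in 1:3) {
      Fp <- F; Fp[i, j] <- Fp[i, j] + h
      Fm <- F; Fm[i, j] <- Fm[i, j] - h
      P[i, j] <- (psi_of(Fp) - psi_of(Fm)) / (2 * h)
    }
  }
  P %*% t(F)
}

## small 5-input training set + fitted emulator stack (volume + 24 strains)
## used by the inference and stress-stretch tests
small_iuq_fit <- function() {
  cached_fixture("iuq300", {
    cfg <- default_config()
    cfg$iuq$n_train <- 300
    cfg$iuq$gp_restarts <- 1
    ems <- myouq:::fit_iuq_emulators(cfg)
    list(ems = ems, stack = emulator_stack(c(list(ems$lvv), ems$eps_cc)))
  })
}

## emulator with prescribed hyperparameters (no optimization), used for
## dense-oracle comparisons
make_toy_emulator <- function(X, y, hyp) {
  X <- as.matrix(X)
  em <- list(transform = list(log_cols = character(0),
                              center = rep(0, ncol(X)), scale = rep(1, ncol(X))),
             y_mean = 0, y_sd = 1, hyp = hyp, X_train = X, y_train = y,
             n = nrow(X), D = ncol(X), col_names = colnames(X))
  K <- ard_kernel(X, X, hyp, nugget = TRUE)
  ch <- chol(K)
  em$L <- ch
  em$alpha <- backsolve(ch, forwardsolve(t(ch), y))
  em$jitter <- 0
  class(em) <- "gp_emulator"
  em
}

## independent uniform prior on [0,1]^d for estimator tests
unit_prior <- function(d) {
  nm <- paste0("x", seq_len(d))
  sa_prior(nm, bounds = stats::setNames(rep(list(c(0, 1)), d), nm))
}

## brute-force double-loop Monte-Carlo oracle for the first-order index of
## input i: V[E[Y|X_i]] / V[Y] with nested sampling.  The naive variance of
## the inner means overestimates V[E[Y|X_i]] by E[V_inner]/n_inner; that
## bias is subtracted.
brute_force_S <- function(f, d, i, n_outer = 1000, n_inner = 3000, lo = 0, hi = 1) {
  set.seed(1000 + i)
  inner <- vapply(seq_len(n_outer), function(o) {
    xi <- stats::runif(1, lo, hi)
    X <- matrix(stats::runif(n_inner * d, lo, hi), n_inner, d)
    X[, i] <- xi
    y <- f(X)
    c(mean(y), stats::var(y))
  }, numeric(2))
  v_cond <- stats::var(inner[1, ]) - mean(inner[2, ]) / n_inner
  Xbig <- matrix(stats::runif(1e5 * d, lo, hi), ncol = d)
  v_cond / stats::var(f(Xbig))
}

## a synthetic observation at known parameters
fix_observation <- function(theta = c(a = 1.5, b = 4, a_f = 2.5, b_f = 3),
                            edp = 10, seed = 42) {
  pars <- do.call(ho_params_reduced, as.list(theta))
  q <- compute_qois(solve_inflation(lv_input(pars, edp)), segment_layout(1234))
  list(theta = theta, qoi = q,
       obs = add_observation_noise(q, 5, 0.03, seed = seed))
}
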