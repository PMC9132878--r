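## Bayesian inverse uncertainty quantification: two-component Gaussian
## likelihood over cavity volume and 24 circumferential strains, uniform
## priors, No-U-Turn sampling through the emulator, Gelman-Rubin
## convergence diagnostics and inverse-interquartile-range summaries.

#' Observation vector for inference
#'
#' @param y0 measured end-diastolic volume, ml.
#' @param y_tilde the 24 measured segmental circumferential strains.
#' @return object of class `lv_observation`.
#' @export
lv_observation <- function(y0, y_tilde) {
  if (length(y_tilde) != 24) abort_validation("lv_observation: need exactly 24 strains")
  structure(list(y0 = y0, y_tilde = as.numeric(y_tilde)), class = "lv_observation")
}

#' Stack of per-output GP emulators with fast joint prediction
#'
#' Bundles the 25 independent emulators (volume + 24 circumferential
#' strains) trained on a common input space into a single structure whose
#' posterior means and input gradients at one point are evaluated with a
#' handful of matrix products — the hot path of gradient-based MCMC.
#' All emulators must share identical training inputs and input
#' transforms.
#'
#' @param emulators list of `gp_emulator`s (first = volume, then the 24
#'   strains, in segment order).
#' @return object of class `emulator_stack`.
#' @export
emulator_stack <- function(emulators) {
  if (length(emulators) < 1) abort_validation("emulator_stack: empty emulator list")
  e1 <- emulators[[1]]
  for (e in emulators) {
    if (max(abs(e$X_train - e1$X_train)) > 0 ||
        !identical(e$transform$log_cols, e1$transform$log_cols)) {
      abort_validation("emulator_stack: emulators must share training inputs and transform")
    }
  }
  D <- e1$D
  m <- length(emulators)
  structure(list(
    X = e1$X_train,                                   # n x D standardized
    transform = e1$transform,
    alpha = vapply(emulators, `[[`, numeric(e1$n), "alpha"),   # n x m
    invlam2 = vapply(emulators, function(e) 1 / e$hyp$lengthscales^2, numeric(D)), # D x m
    sigf2 = vapply(emulators, function(e) e$hyp$sigma_f^2, numeric(1)),
    y_mean = vapply(emulators, `[[`, numeric(1), "y_mean"),
    y_sd = vapply(emulators, `[[`, numeric(1), "y_sd"),
    emulators = emulators, n = e1$n, D = D, m = m
  ), class = "emulator_stack")
}

## Joint posterior means (and optionally gradients with respect to the raw
## emulator inputs u, i.e. before standardization but after any log
## transform) of all stacked outputs at a single point u (length D).
## Thin wrapper over the compiled kernel.
stack_predict_point <- function(st, u, grad = FALSE) {
  stack_predict_cpp(st$X, st$alpha, st$invlam2, st$sigf2,
                    st$y_mean, st$y_sd,
                    st$transform$center, st$transform$scale,
                    as.numeric(u), grad)
}

#' Log-likelihood of volume and strain observations
#'
#' The two-component Gaussian log-likelihood
#' `-1/2 log(sigma0^2) - (y0 - f0)^2 / (2 sigma0^2)
#'  - 24/2 log(sigmat^2) - sum_i (y_i - f_i)^2 / (2 sigmat^2)`
#' with the model predictions `f` replaced by the emulator posterior
#' means.  The volume noise variance `sigma0^2` is fixed (non-identifiable
#' from a single volume measurement); the strain noise variance is a free
#' parameter.  Additive constants are omitted consistently.
#'
#' @param y an [lv_observation()].
#' @param theta named reduced material parameters (`a`, `b`, `a_f`, `b_f`)
#'   on the natural scale.
#' @param sigma_tilde_sq strain noise variance (> 0).
#' @param stack an [emulator_stack()] over inputs
#'   `(a, b, a_f, b_f, edp)` (volume first, then the 24 strains).
#' @param edp end-diastolic pressure of the observation, mmHg.
#' @param sigma0_sq fixed volume noise variance, ml^2 (default 25).
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(y, theta, sigma_tilde_sq, stack, edp, sigma0_sq = 25) {
  if (sigma_tilde_sq <= 0) abort_validation("log_likelihood: sigma_tilde_sq must be > 0")
  th <- if (!is.null(names(theta))) as.numeric(theta[REDUCED_NAMES]) else as.numeric(theta)
  if (length(th) != 4 || any(!is.finite(th)) || any(th <= 0)) {
    abort_validation("log_likelihood: theta must be the four positive reduced parameters")
  }
  u <- c(log(th), edp)
  pr <- stack_predict_point(stack, u)
  if (any(!is.finite(pr$mean))) abort_numeric("log_likelihood: non-finite emulator prediction")
  f0 <- pr$mean[1]; fs <- pr$mean[-1]
  -0.5 * log(sigma0_sq) - (y$y0 - f0)^2 / (2 * sigma0_sq) -
    12 * log(sigma_tilde_sq) - sum((y$y_tilde - fs)^2) / (2 * sigma_tilde_sq)
}

#' Log-posterior factory for the reduced-parameter inverse problem
#'
#' Returns a function evaluating the log posterior (and, on request, its
#' gradient) in the log-scale parameterization
#' `q = (log a, log b, log a_f, log b_f, log sigma_tilde^2)`.  Uniform
#' priors on the natural scales (material parameters on `theta_bounds`,
#' strain-noise SD on `sigma_bounds`) are expressed exactly through the
#' Jacobian; the value is `-Inf` outside the prior support.
#'
#' @param y an [lv_observation()].
#' @param stack an [emulator_stack()].
#' @param edp observation pressure, mmHg.
#' @param sigma0_sq fixed volume noise variance, ml^2.
#' @param theta_bounds,sigma_bounds prior supports.
#' @return `function(q, grad = FALSE)` returning `list(value, grad)`.
#' @export
make_log_posterior <- function(y, stack, edp, sigma0_sq = 25,
                               theta_bounds = c(0.1, 10),
                               sigma_bounds = c(1e-4, 0.2)) {
  ql <- log(theta_bounds[1]); qu <- log(theta_bounds[2])
  vl <- 2 * log(sigma_bounds[1]); vu <- 2 * log(sigma_bounds[2])
  ys <- y$y_tilde; y0 <- y$y0
  function(q, grad = FALSE) {
    th_q <- q[1:4]; v <- q[5]
    if (any(th_q < ql) || any(th_q > qu) || v < vl || v > vu) {
      return(list(value = -Inf, grad = rep(NA_real_, 5)))
    }
    u <- c(th_q, edp)
    pr <- stack_predict_point(stack, u, grad = grad)
    if (any(!is.finite(pr$mean))) return(list(value = -Inf, grad = rep(NA_real_, 5)))
    f0 <- pr$mean[1]; fs <- pr$mean[-1]
    s2 <- exp(v)
    r0 <- y0 - f0; rs <- ys - fs
    ll <- -0.5 * log(sigma0_sq) - r0^2 / (2 * sigma0_sq) -
      12 * v - sum(rs^2) / (2 * s2)
    ## log-prior: uniform theta -> + sum(log theta) = sum(th_q);
    ## uniform sigma_tilde -> density on v is sigma/2 -> + v/2 (+const)
    lp <- ll + sum(th_q) + v / 2
    if (!grad) return(list(value = lp))
    Gm <- pr$grad # 5 x 25, rows = d/du_k (u5 = edp, fixed)
    gth <- Gm[1:4, 1] * (r0 / sigma0_sq) + Gm[1:4, -1, drop = FALSE] %*% (rs / s2)
    gv <- -12 + sum(rs^2) / (2 * s2) + 0.5
    list(value = lp, grad = c(as.numeric(gth) + 1, gv))
  }
}

## Log-posterior in the unconstrained sampling parameterization
## t_j, where log theta_j = ql + (qu - ql) * sigmoid(t_j) (and likewise for
## log sigma_tilde^2).  The map is a smooth bijection onto the prior box,
## so the uniform natural-scale priors are preserved exactly through the
## Jacobian while NUTS sees no hard support boundaries.
make_log_posterior_t <- function(y, stack, edp, sigma0_sq = 25,
                                 theta_bounds = c(0.1, 10),
                                 sigma_bounds = c(1e-4, 0.2)) {
  ql <- log(theta_bounds[1]); qu <- log(theta_bounds[2])
  vl <- 2 * log(sigma_bounds[1]); vu <- 2 * log(sigma_bounds[2])
  w <- c(rep(qu - ql, 4), vu - vl)
  lo <- c(rep(ql, 4), vl)
  ys <- y$y_tilde; y0 <- y$y0
  function(t, grad = FALSE) {
    s <- 1 / (1 + exp(-t))
    qv <- lo + w * s
    u <- c(qv[1:4], edp)
    pr <- stack_predict_point(stack, u, grad = grad)
    if (any(!is.finite(pr$mean))) return(list(value = -Inf, grad = rep(NA_real_, 5)))
    f0 <- pr$mean[1]; fs <- pr$mean[-1]
    s2 <- exp(qv[5])
    r0 <- y0 - f0; rs <- ys - fs
    ll <- -0.5 * log(sigma0_sq) - r0^2 / (2 * sigma0_sq) -
      12 * qv[5] - sum(rs^2) / (2 * s2)
    ## priors (uniform on theta and on sigma_tilde) + Jacobian of the map:
    ## log p(t) = sum(q_theta) + v/2 + sum(log s + log(1 - s)) + const
    lp <- ll + sum(qv[1:4]) + qv[5] / 2 + sum(log(s) + log1p(-s))
    if (!grad) return(list(value = lp))
    Gm <- pr$grad
    dll_dq <- c(
      Gm[1:4, 1] * (r0 / sigma0_sq) + Gm[1:4, -1, drop = FALSE] %*% (rs / s2),
      -12 + sum(rs^2) / (2 * s2))
    dprior_dq <- c(rep(1, 4), 0.5)
    dq_dt <- w * s * (1 - s)
    g <- (as.numeric(dll_dq) + dprior_dq) * dq_dt + (1 - 2 * s)
    list(value = lp, grad = g)
  }
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (1992) construction from the between- and within-chain
#' variances: `PSRF = sqrt(((n-1)/n W + B/n) / W)` with `W` the mean
#' within-chain variance and `B/n` the variance of the chain means.
#'
#' @param chains a matrix (draws x chains) for one parameter, or a list of
#'   equal-length numeric vectors.
#' @param split split each chain in half first (the split-chain variant,
#'   which also flags non-stationarity within chains); default `FALSE`,
#'   the classic construction.
#' @return scalar PSRF.
#' @export
psrf <- function(chains, split = FALSE) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  if (split) {
    h <- floor(nrow(chains) / 2)
    chains <- cbind(chains[seq_len(h), , drop = FALSE],
                    chains[h + seq_len(h), , drop = FALSE])
  }
  n <- nrow(chains); m <- ncol(chains)
  if (m < 2 || n < 10) abort_validation("psrf: need >= 2 chains with >= 10 draws")
  W <- mean(apply(chains, 2, stats::var))
  if (W <= 0) abort_degenerate("psrf: zero within-chain variance")
  B_over_n <- stats::var(colMeans(chains))
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Inverse interquartile range
#'
#' `1 / (q75 - q25)` of a posterior sample: a practical-identifiability
#' score in the spirit of a sensitivity index — the more peaked the
#' marginal posterior, the larger the value.
#'
#' @param x numeric sample (length >= 4).
#' @return scalar I-IQR in the inverse units of `x`.
#' @export
iiqr <- function(x) {
  if (length(x) < 4) abort_validation("iiqr: need at least 4 samples")
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  if (q[2] - q[1] <= 0) {
    abort_degenerate("iiqr: zero interquartile range (degenerate posterior)")
  }
  1 / (q[2] - q[1])
}

## ---- No-U-Turn Sampler --------------------------------------------------

## Metric (mass-matrix) helpers.  The metric is represented by the upper
## Cholesky factor U of the estimated posterior covariance (M^-1 = U'U);
## NULL means the unit metric.  Momenta are drawn from N(0, M); the
## velocity is M^-1 p.
metric_vel <- function(U, p) if (is.null(U)) p else drop(crossprod(U, U %*% p))
metric_draw <- function(U, D) {
  z <- stats::rnorm(D)
  if (is.null(U)) z else drop(backsolve(U, z))
}
metric_kin <- function(U, p) 0.5 * sum(p * metric_vel(U, p))

leapfrog <- function(lp, q, p, eps, U) {
  g <- lp(q, grad = TRUE)
  p <- p + 0.5 * eps * g$grad
  q <- q + eps * metric_vel(U, p)
  g2 <- lp(q, grad = TRUE)
  if (!is.finite(g2$value) || any(!is.finite(g2$grad))) {
    return(list(q = q, p = p, lp = -Inf, ok = FALSE))
  }
  p <- p + 0.5 * eps * g2$grad
  list(q = q, p = p, lp = g2$value, ok = TRUE)
}

nuts_build_tree <- function(lp, q, p, logu, dir, depth, eps, U, H0) {
  DMAX <- 1000
  if (depth == 0) {
    st <- leapfrog(lp, q, p, dir * eps, U)
    H <- st$lp - metric_kin(U, st$p)
    n_ok <- if (is.finite(H) && logu <= H) 1L else 0L
    div <- !is.finite(H) || (logu > H + DMAX)
    a <- if (is.finite(H)) min(1, exp(H - H0)) else 0
    return(list(q_minus = st$q, p_minus = st$p, q_plus = st$q, p_plus = st$p,
                q_prop = st$q, lp_prop = st$lp, n = n_ok, stop = div,
                alpha = a, n_alpha = 1L))
  }
  t1 <- nuts_build_tree(lp, q, p, logu, dir, depth - 1, eps, U, H0)
  if (t1$stop) return(t1)
  if (dir == -1) {
    t2 <- nuts_build_tree(lp, t1$q_minus, t1$p_minus, logu, dir, depth - 1, eps, U, H0)
    t1$q_minus <- t2$q_minus; t1$p_minus <- t2$p_minus
  } else {
    t2 <- nuts_build_tree(lp, t1$q_plus, t1$p_plus, logu, dir, depth - 1, eps, U, H0)
    t1$q_plus <- t2$q_plus; t1$p_plus <- t2$p_plus
  }
  if (t2$n > 0 && stats::runif(1) < t2$n / max(t1$n + t2$n, 1L)) {
    t1$q_prop <- t2$q_prop; t1$lp_prop <- t2$lp_prop
  }
  dq <- t1$q_plus - t1$q_minus
  uturn <- (sum(dq * metric_vel(U, t1$p_minus)) < 0) ||
    (sum(dq * metric_vel(U, t1$p_plus)) < 0)
  t1$n <- t1$n + t2$n
  t1$stop <- t2$stop || uturn
  t1$alpha <- t1$alpha + t2$alpha
  t1$n_alpha <- t1$n_alpha + t2$n_alpha
  t1
}

## One NUTS chain with dual-averaging step-size adaptation and a diagonal
## metric estimated midway through warmup.
nuts_chain <- function(lp, q0, n_warmup, n_draws, seed,
                       target_accept = 0.8, max_treedepth = 10) {
  set.seed(seed)
  D <- length(q0)
  U_m <- NULL # unit metric until the warmup window closes
  q <- q0
  g <- lp(q, grad = TRUE)
  if (!is.finite(g$value)) abort_solver("nuts: initial point has zero posterior density")
  ## initial step size: aim for ~50% acceptance of a single leapfrog
  eps <- 0.1
  for (t in 1:30) {
    p <- metric_draw(U_m, D)
    st <- leapfrog(lp, q, p, eps, U_m)
    dH <- (st$lp - metric_kin(U_m, st$p)) - (g$value - metric_kin(U_m, p))
    if (!is.finite(dH) || dH < log(0.5)) eps <- eps / 2 else break
  }
  ## dual averaging state
  mu_da <- log(10 * eps); log_eps_bar <- 0; H_bar <- 0
  gamma <- 0.05; t0 <- 10; kappa <- 0.75
  total <- n_warmup + n_draws
  draws <- matrix(NA_real_, n_draws, D)
  accept_sum <- 0
  ## two covariance-adaptation windows (the second refines the metric with
  ## draws collected under the first estimate)
  windows <- list(c(floor(n_warmup * 0.25), floor(n_warmup * 0.5)),
                  c(floor(n_warmup * 0.5), floor(n_warmup * 0.85)))
  win_idx <- 1L
  win_lo <- windows[[1]][1]; win_hi <- windows[[1]][2]
  win_buf <- matrix(NA_real_, max(win_hi - win_lo, 1), D)
  n_div <- 0L
  for (it in seq_len(total)) {
    p0 <- metric_draw(U_m, D)
    g <- lp(q, grad = TRUE)
    H0 <- g$value - metric_kin(U_m, p0)
    logu <- H0 + log(stats::runif(1))
    tree <- list(q_minus = q, p_minus = p0, q_plus = q, p_plus = p0,
                 q_prop = q, lp_prop = g$value, n = 1L, stop = FALSE)
    alpha <- 0; n_alpha <- 1L
    depth <- 0
    while (!tree$stop && depth < max_treedepth) {
      dir <- if (stats::runif(1) < 0.5) -1 else 1
      sub <- if (dir == -1) {
        nuts_build_tree(lp, tree$q_minus, tree$p_minus, logu, dir, depth, eps, U_m, H0)
      } else {
        nuts_build_tree(lp, tree$q_plus, tree$p_plus, logu, dir, depth, eps, U_m, H0)
      }
      if (dir == -1) {
        tree$q_minus <- sub$q_minus; tree$p_minus <- sub$p_minus
      } else {
        tree$q_plus <- sub$q_plus; tree$p_plus <- sub$p_plus
      }
      if (!sub$stop && sub$n > 0 && stats::runif(1) < sub$n / max(tree$n, 1L)) {
        tree$q_prop <- sub$q_prop; tree$lp_prop <- sub$lp_prop
      }
      tree$n <- tree$n + sub$n
      dq <- tree$q_plus - tree$q_minus
      uturn <- (sum(dq * metric_vel(U_m, tree$p_minus)) < 0) ||
        (sum(dq * metric_vel(U_m, tree$p_plus)) < 0)
      tree$stop <- tree$stop || sub$stop || uturn
      alpha <- alpha + (sub$alpha %||% 0); n_alpha <- n_alpha + (sub$n_alpha %||% 0L)
      if (sub$stop && depth == 0) n_div <- n_div + 1L
      depth <- depth + 1
    }
    q <- tree$q_prop
    a_frac <- if (n_alpha > 0) alpha / n_alpha else 0
    if (it <= n_warmup) {
      ## dual averaging
      H_bar <- (1 - 1 / (it + t0)) * H_bar + (target_accept - a_frac) / (it + t0)
      log_eps <- mu_da - sqrt(it) / gamma * H_bar
      w <- it^(-kappa)
      log_eps_bar <- w * log_eps + (1 - w) * log_eps_bar
      eps <- exp(log_eps)
      if (it > win_lo && it <= win_hi) win_buf[it - win_lo, ] <- q
      if (it == win_hi) {
        ## dense metric: M^-1 = regularized covariance estimate from the
        ## warmup window, so strong parameter correlations no longer force
        ## long trajectories; shrinkage toward the identity grows as the
        ## window shrinks (as in Stan's windowed adaptation)
        n_win <- nrow(win_buf)
        lam <- n_win / (n_win + 5)
        Sg <- lam * stats::cov(win_buf) + (1 - lam) * 1e-3 * diag(D) + 1e-8 * diag(D)
        U_try <- tryCatch(chol(Sg), error = function(e) NULL)
        if (!is.null(U_try)) U_m <- U_try
        ## restart step-size adaptation under the new metric
        eps <- exp(log_eps_bar)
        mu_da <- log(10 * eps); H_bar <- 0; log_eps_bar <- log(eps)
        if (win_idx < length(windows)) {
          win_idx <- win_idx + 1L
          win_lo <- windows[[win_idx]][1]; win_hi <- windows[[win_idx]][2]
          win_buf <- matrix(NA_real_, max(win_hi - win_lo, 1), D)
        }
      }
      if (it == n_warmup) eps <- exp(log_eps_bar)
    } else {
      draws[it - n_warmup, ] <- q
      accept_sum <- accept_sum + a_frac
    }
  }
  list(draws = draws, eps = eps, accept = accept_sum / max(n_draws, 1),
       n_divergent = n_div, metric_chol = U_m)
}

#' Posterior sampling with the No-U-Turn Sampler
#'
#' Samples the joint posterior of the reduced material parameters and the
#' strain noise variance in log space (`log a`, `log b`, `log a_f`,
#' `log b_f`, `log sigma_tilde^2`), with the uniform natural-scale priors
#' enforced exactly through the Jacobian.  Multiple chains start from
#' dispersed points of a Sobol sequence over the prior box; convergence is
#' assessed per parameter with the Gelman-Rubin PSRF (threshold 1.01).
#'
#' @param y an [lv_observation()].
#' @param stack an [emulator_stack()] (volume + 24 strains over inputs
#'   `a, b, a_f, b_f, edp`).
#' @param edp pressure of the observation, mmHg.
#' @param n_chains number of chains (default 5).
#' @param n_warmup,n_draws warmup and retained draws per chain.
#' @param seed integer seed.
#' @param sigma0_sq fixed volume noise variance, ml^2.
#' @param theta_bounds,sigma_bounds prior supports.
#' @param target_accept,max_treedepth NUTS tuning.
#' @return object of class `posterior_samples`: list with `draws`
#'   (array draws x chains x 5, dimnames on parameters), `psrf` (named),
#'   `converged`, `accept`, and metadata.
#' @export
run_mcmc <- function(y, stack, edp, n_chains = 5, n_warmup = 1000,
                     n_draws = 2000, seed = 1, sigma0_sq = 25,
                     theta_bounds = c(0.1, 10), sigma_bounds = c(1e-4, 0.2),
                     target_accept = 0.8, max_treedepth = 8) {
  ## dispersed starts: Sobol points over the interior of the prior box,
  ## mapped to the unconstrained sampling scale
  U <- sobol_sequence(n_chains, 5, skip = 32)
  shrink <- 0.1 + 0.8 * U
  starts <- log(shrink / (1 - shrink))
  ql <- log(theta_bounds[1]); qu <- log(theta_bounds[2])
  vl <- 2 * log(sigma_bounds[1]); vu <- 2 * log(sigma_bounds[2])
  wdt <- c(rep(qu - ql, 4), vu - vl)
  lo <- c(rep(ql, 4), vl)
  par_names <- c("log_a", "log_b", "log_a_f", "log_b_f", "log_sigma_tilde_sq")
  chains <- vector("list", n_chains)
  tr <- stack$transform
  for (c in seq_len(n_chains)) {
    chains[[c]] <- with_seed(derive_seed(seed, 400L + c),
      nuts_chain_stack_cpp(stack$X, stack$alpha, stack$invlam2, stack$sigf2,
                           stack$y_mean, stack$y_sd, tr$center, tr$scale,
                           y$y0, y$y_tilde, sigma0_sq, edp,
                           ql, qu, vl, vu,
                           starts[c, ], n_warmup, n_draws,
                           target_accept, max_treedepth))
  }
  draws <- array(NA_real_, c(n_draws, n_chains, 5),
                 dimnames = list(NULL, NULL, par_names))
  for (c in seq_len(n_chains)) {
    tdr <- chains[[c]]$draws
    draws[, c, ] <- sweep(sweep(1 / (1 + exp(-tdr)), 2, wdt, "*"), 2, lo, "+")
  }
  rhat <- vapply(seq_len(5), function(j) psrf(draws[, , j]), numeric(1))
  names(rhat) <- par_names
  structure(list(
    draws = draws, psrf = rhat, converged = max(rhat) < 1.01,
    accept = vapply(chains, `[[`, numeric(1), "accept"),
    n_divergent = vapply(chains, function(ch) as.integer(ch$n_divergent), integer(1)),
    edp = edp, seed = seed, n_chains = n_chains,
    n_warmup = n_warmup, n_draws = n_draws
  ), class = "posterior_samples")
}

#' Pooled natural-scale parameter draws
#'
#' @param samples a `posterior_samples` object.
#' @return matrix (all draws x 4) of `a`, `b`, `a_f`, `b_f` on the
#'   natural (kPa / dimensionless) scale.
#' @export
posterior_theta <- function(samples) {
  d <- samples$draws
  out <- exp(cbind(as.numeric(d[, , 1]), as.numeric(d[, , 2]),
                   as.numeric(d[, , 3]), as.numeric(d[, , 4])))
  colnames(out) <- REDUCED_NAMES
  out
}

#' Write posterior draws and convergence report to disk
#'
#' Draws go to CSV in long-friendly wide form (`chain`, `draw`, one column
#' per sampled parameter); the convergence report (per-parameter PSRF,
#' flag, acceptance and divergence counts) goes to JSON next to it when
#' `report_path` is given.
#'
#' @param samples a `posterior_samples` object from [run_mcmc()].
#' @param path CSV output path.
#' @param report_path optional JSON path for the convergence report.
#' @return `path`, invisibly.
#' @export
write_posterior_draws <- function(samples, path, report_path = NULL) {
  d <- samples$draws
  n_draws <- dim(d)[1]; n_chains <- dim(d)[2]
  out <- data.frame(
    chain = rep(seq_len(n_chains), each = n_draws),
    draw = rep(seq_len(n_draws), times = n_chains)
  )
  for (j in seq_len(dim(d)[3])) {
    out[[dimnames(d)[[3]][j]]] <- as.numeric(d[, , j])
  }
  utils::write.csv(out, path, row.names = FALSE)
  if (!is.null(report_path)) {
    jsonlite::write_json(list(
      psrf = as.list(samples$psrf),
      converged = samples$converged,
      accept = samples$accept,
      n_divergent = samples$n_divergent,
      edp = samples$edp, seed = samples$seed,
      n_chains = samples$n_chains, n_warmup = samples$n_warmup,
      n_draws = samples$n_draws
    ), report_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Battery-level inverse-UQ study
#'
#' Runs the posterior inference for every battery case at every pressure
#' and summarizes practical identifiability: the marginal I-IQR of each
#' reduced material parameter (natural scale), convergence flags and
#' volume-quartile bin labels (bins from the battery's own noiseless
#' volumes at 10 mmHg).
#'
#' @param battery an [generate_test_battery()] result.
#' @param stack an [emulator_stack()].
#' @param n_chains,n_warmup,n_draws,seed MCMC settings per case.
#' @param sigma0_sq fixed volume noise variance.
#' @param progress print per-case progress.
#' @return list with `table` (tidy data.frame: case, edp, lvv_bin,
#'   parameter, iiqr, q25, q75, psrf_max, converged) and `lvv_cuts`.
#' @export
run_iuq_battery <- function(battery, stack, n_chains = 5, n_warmup = 400,
                            n_draws = 800, seed = 1, sigma0_sq = 25,
                            progress = FALSE) {
  lvv10 <- vapply(battery, `[[`, numeric(1), "lvv10")
  cuts <- stats::quantile(lvv10, c(0.25, 0.5, 0.75), names = FALSE)
  bin_of <- function(v) 1L + findInterval(v, cuts)
  rows <- list()
  for (case in battery) {
    for (edp in names(case$obs)) {
      res <- tryCatch({
        fit <- run_mcmc(case$obs[[edp]]$obs, stack, edp = as.numeric(edp),
                        n_chains = n_chains, n_warmup = n_warmup,
                        n_draws = n_draws,
                        seed = derive_seed(seed, case$id * 100L + as.integer(as.numeric(edp))),
                        sigma0_sq = sigma0_sq)
        th <- posterior_theta(fit)
        data.frame(
          case = case$id, edp = as.numeric(edp),
          lvv_bin = bin_of(case$lvv10),
          parameter = REDUCED_NAMES,
          truth = as.numeric(case$theta[REDUCED_NAMES]),
          iiqr = vapply(REDUCED_NAMES, function(p) iiqr(th[, p]), numeric(1)),
          q25 = vapply(REDUCED_NAMES, function(p) stats::quantile(th[, p], 0.25), numeric(1)),
          q75 = vapply(REDUCED_NAMES, function(p) stats::quantile(th[, p], 0.75), numeric(1)),
          psrf_max = max(fit$psrf), converged = fit$converged,
          row.names = NULL, stringsAsFactors = FALSE
        )
      }, myouq_error = function(e) NULL)
      if (!is.null(res)) rows[[paste(case$id, edp)]] <- res
      if (progress) message(sprintf("case %d edp %s done", case$id, edp))
    }
  }
  list(table = do.call(rbind, rows), lvv_cuts = cuts)
}
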