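## Variance-based global sensitivity analysis: Saltelli pick-freeze
## designs, first-order (Saltelli-2010) and total-effect (Jansen)
## estimators, and ensembles of indices over GP posterior draws.

#' Prior specification for sensitivity analysis
#'
#' One row per forward-model input: distribution `"uniform"`,
#' `"loguniform"` or `"fixed"`, with bounds (or the fixed value).
#'
#' @param names input names.
#' @param dist character vector of distributions (recycled).
#' @param bounds named list of `c(lower, upper)` (ignored for fixed).
#' @param fixed named numeric vector of fixed values for `"fixed"` inputs.
#' @return data.frame of class `sa_prior`.
#' @export
sa_prior <- function(names, dist = "uniform", bounds = default_input_bounds(),
                     fixed = NULL) {
  dist <- rep_len(dist, length(names))
  lo <- hi <- numeric(length(names))
  for (i in seq_along(names)) {
    if (dist[i] == "fixed") {
      v <- fixed[[names[i]]]
      if (is.null(v)) abort_validation(sprintf("sa_prior: no fixed value for '%s'", names[i]))
      lo[i] <- hi[i] <- v
    } else {
      b <- bounds[[names[i]]]
      if (is.null(b)) abort_validation(sprintf("sa_prior: no bounds for '%s'", names[i]))
      if (dist[i] == "loguniform" && b[1] <= 0) {
        abort_validation("sa_prior: log-uniform needs positive bounds")
      }
      lo[i] <- b[1]; hi[i] <- b[2]
    }
  }
  structure(data.frame(name = names, dist = dist, lower = lo, upper = hi,
                       stringsAsFactors = FALSE),
            class = c("sa_prior", "data.frame"))
}

## Material-parameter prior used in the SA experiments: material constants
## uniform or log-uniform, EDP and angles always uniform.
#' @rdname sa_prior
#' @param material_dist `"uniform"` or `"loguniform"` for the eight
#'   material constants.
#' @export
sa1_prior <- function(material_dist = c("uniform", "loguniform")) {
  material_dist <- match.arg(material_dist)
  nm <- names(default_input_bounds())
  sa_prior(nm, dist = ifelse(nm %in% MATERIAL_NAMES, material_dist, "uniform"))
}

prior_quantile <- function(prior, U) {
  ## map uniform [0,1) matrix (cols = varying inputs) through inverse CDFs
  vary <- prior$dist != "fixed"
  out <- matrix(NA_real_, nrow(U), nrow(prior))
  colnames(out) <- prior$name
  j <- 0
  for (i in seq_len(nrow(prior))) {
    if (!vary[i]) {
      out[, i] <- prior$lower[i]
    } else {
      j <- j + 1
      u <- U[, j]
      out[, i] <- if (prior$dist[i] == "loguniform") {
        exp(log(prior$lower[i]) + u * (log(prior$upper[i]) - log(prior$lower[i])))
      } else {
        prior$lower[i] + u * (prior$upper[i] - prior$lower[i])
      }
    }
  }
  as.data.frame(out)
}

#' Saltelli pick-freeze design
#'
#' Builds the `A`, `B` and `A_B^(i)` matrices of the pick-freeze scheme
#' from a single `2d`-dimensional Sobol stream mapped through the prior's
#' inverse CDFs: `A_B^(i)` equals `A` with column `i` replaced by the
#' corresponding column of `B`.  The full design has `N (d + 2)` model
#' evaluation points for `d` varying inputs.
#'
#' @param prior an [sa_prior()].
#' @param N base sample count (powers of 2 recommended).
#' @param skip Sobol points to skip.
#' @return list with data.frames `A`, `B`, list `AB` (one per varying
#'   input), `varying` (names), and `N`.
#' @export
saltelli_design <- function(prior, N, skip = 0) {
  if (N < 1) abort_validation("saltelli_design: N must be >= 1")
  vary <- which(prior$dist != "fixed")
  d <- length(vary)
  if (d == 0) abort_validation("saltelli_design: no varying inputs")
  U <- sobol_sequence(N, 2 * d, skip = skip)
  A <- prior_quantile(prior, U[, seq_len(d), drop = FALSE])
  B <- prior_quantile(prior, U[, d + seq_len(d), drop = FALSE])
  AB <- lapply(seq_len(d), function(k) {
    M <- A
    M[[prior$name[vary[k]]]] <- B[[prior$name[vary[k]]]]
    M
  })
  names(AB) <- prior$name[vary]
  list(A = A, B = B, AB = AB, varying = prior$name[vary], N = N)
}

#' First-order Sobol index estimator
#'
#' Saltelli-2010 pick-freeze estimator of
#' `S_i = V[E[Y|X_i]] / V[Y]`, using
#' `mean(y_B * (y_ABi - y_A)) / V` with the variance taken over the
#' pooled `A` and `B` evaluations.  Estimates are clipped to
#' `[-0.05, 1.05]` with a warning outside `[0, 1]`.
#'
#' @param y_A,y_B,y_ABi model evaluations on the design matrices.
#' @return estimated first-order index.
#' @export
sobol_first_order <- function(y_A, y_B, y_ABi) {
  check_pickfreeze(y_A, y_B, y_ABi)
  V <- stats::var(c(y_A, y_B))
  if (V <= 0) abort_degenerate("sobol_first_order: zero total variance")
  s <- mean(y_B * (y_ABi - y_A)) / V
  clip_index(s, "first-order")
}

#' Total-effect Sobol index estimator
#'
#' Jansen estimator of `T_i = E[V[Y|X_~i]] / V[Y]`, using
#' `0.5 mean((y_A - y_ABi)^2) / V`.
#'
#' @inheritParams sobol_first_order
#' @return estimated total-effect index.
#' @export
sobol_total_effect <- function(y_A, y_B, y_ABi) {
  check_pickfreeze(y_A, y_B, y_ABi)
  V <- stats::var(c(y_A, y_B))
  if (V <= 0) abort_degenerate("sobol_total_effect: zero total variance")
  clip_index(0.5 * mean((y_A - y_ABi)^2) / V, "total-effect")
}

check_pickfreeze <- function(y_A, y_B, y_ABi) {
  if (length(y_A) != length(y_B) || length(y_A) != length(y_ABi)) {
    abort_validation("pick-freeze estimator: unequal evaluation lengths")
  }
}

clip_index <- function(s, what) {
  if (s < -0.05 || s > 1.05) {
    warning(sprintf("%s index estimate %.3f outside [0, 1]; clipped", what, s))
  }
  min(max(s, -0.05), 1.05)
}

## raw (unclipped) index pair for ensemble computation on an evaluation
## matrix: y has columns (A, B, AB_1..AB_d) stacked; returns d x 2.
pickfreeze_indices <- function(y, N, d) {
  y_A <- y[seq_len(N)]
  y_B <- y[N + seq_len(N)]
  V <- stats::var(c(y_A, y_B))
  if (V <= 0) abort_degenerate("pick-freeze: zero total variance")
  S <- Ti <- numeric(d)
  for (k in seq_len(d)) {
    y_AB <- y[2 * N + (k - 1) * N + seq_len(N)]
    S[k] <- mean(y_B * (y_AB - y_A)) / V
    Ti[k] <- 0.5 * mean((y_A - y_AB)^2) / V
  }
  cbind(S = S, T = Ti)
}

#' Sobol index ensembles from a GP emulator
#'
#' Draws joint posterior samples of the emulated response over the whole
#' pick-freeze design (pathwise sampling, so the draws are coherent across
#' all design rows) and computes the first-order and total-effect index of
#' every varying input for every draw, giving an ensemble that quantifies
#' emulator-induced uncertainty in the indices.  Negative draws are
#' retained (not clipped) so that ensemble quantiles are unbiased.
#'
#' @param em a `gp_emulator` for one scalar output.
#' @param prior an [sa_prior()].
#' @param N Saltelli base sample count.
#' @param n_gp_samples number of GP posterior draws (default 250).
#' @param seed integer seed.
#' @param mean_only if `TRUE`, skip the ensemble and return plug-in
#'   posterior-mean indices only.
#' @param n_features random Fourier features for the pathwise draws.
#' @return an object of class `sobol_ensemble`: list with `S`, `T`
#'   (matrices draws x input), `summary` (tidy data.frame), `varying`.
#' @export
sobol_from_emulator <- function(em, prior, N = 512, n_gp_samples = 250,
                                seed = 1, mean_only = FALSE, n_features = 768) {
  des <- saltelli_design(prior, N)
  d <- length(des$varying)
  Xall <- rbind(des$A, des$B, do.call(rbind, des$AB))
  mu <- gp_predict(em, Xall)$mean
  plug <- pickfreeze_indices(mu, N, d)
  if (mean_only) {
    return(structure(list(S = NULL, T = NULL, plug_in = plug,
                          summary = ensemble_summary(array(plug[, 1], c(1, d)),
                                                     array(plug[, 2], c(1, d)),
                                                     des$varying),
                          varying = des$varying, N = N), class = "sobol_ensemble"))
  }
  draws <- gp_sample_pathwise(em, Xall, n_samples = n_gp_samples,
                              n_features = n_features, seed = seed)
  S <- matrix(NA_real_, n_gp_samples, d, dimnames = list(NULL, des$varying))
  Tm <- S
  for (s in seq_len(n_gp_samples)) {
    idx <- pickfreeze_indices(draws[, s], N, d)
    S[s, ] <- idx[, 1]
    Tm[s, ] <- idx[, 2]
  }
  structure(list(S = S, T = Tm, plug_in = plug,
                 summary = ensemble_summary(S, Tm, des$varying),
                 varying = des$varying, N = N),
            class = "sobol_ensemble")
}

ensemble_summary <- function(S, Tm, varying) {
  summarize <- function(M, type) {
    data.frame(
      input = varying, index_type = type,
      mean = colMeans(M),
      q25 = apply(M, 2, stats::quantile, 0.25),
      q75 = apply(M, 2, stats::quantile, 0.75),
      ci95_lo = apply(M, 2, stats::quantile, 0.025),
      ci95_hi = apply(M, 2, stats::quantile, 0.975),
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  rbind(summarize(S, "first_order"), summarize(Tm, "total_effect"))
}

#' Sensitivity analysis one: all eleven inputs random
#'
#' Runs the first sensitivity experiment: emulators for the four output
#' quantities (cavity volume and the starred circumferential, longitudinal
#' and radial strains of the pre-selected segment) are analysed under both
#' the uniform and the log-uniform material-parameter prior, with EDP and
#' the fibre angles uniform in all cases.
#'
#' @param emulators named list of `gp_emulator`s for outputs
#'   `lvv`, `eps_cc_star`, `eps_ll_star`, `eps_rr_star` (11 inputs each).
#' @param N Saltelli base sample count.
#' @param n_gp_samples GP posterior draws per ensemble.
#' @param seed integer seed.
#' @return tidy data.frame: output, prior, input, index_type, mean,
#'   quartiles and 95% interval.
#' @export
run_sa1 <- function(emulators, N = 512, n_gp_samples = 250, seed = 1) {
  stopifnot(all(c("lvv", "eps_cc_star", "eps_ll_star", "eps_rr_star") %in% names(emulators)))
  out <- list()
  for (prior_name in c("uniform", "loguniform")) {
    prior <- sa1_prior(prior_name)
    for (qoi in names(emulators)) {
      ens <- sobol_from_emulator(emulators[[qoi]], prior, N = N,
                                 n_gp_samples = n_gp_samples,
                                 seed = derive_seed(seed, match(qoi, names(emulators))))
      s <- ens$summary
      s$output <- qoi
      s$prior <- prior_name
      out[[paste(prior_name, qoi)]] <- s
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("output", "prior", "input", "index_type",
          "mean", "q25", "q75", "ci95_lo", "ci95_hi")]
}

#' Sensitivity analysis two: per-pressure indices of the reduced model
#'
#' For each fixed end-diastolic pressure on the grid (default 5 to 25 mmHg
#' in steps of 2.5), computes total-effect (and first-order) ensembles for
#' the four free material constants `a`, `b`, `a_f`, `b_f`, with the sheet
#' and shear constants fixed at their literature values and fibre angles
#' fixed at 60 / -90 degrees.
#'
#' @param emulators named list with `gp_emulator`s for `lvv` and
#'   `eps_cc_star`, trained over the joint (material, EDP) space used here
#'   (5 inputs: `a`, `b`, `a_f`, `b_f`, `edp`).
#' @param edp_grid pressures, mmHg.
#' @param material_dist `"uniform"`, `"loguniform"` or both.
#' @param N,n_gp_samples,seed as in [run_sa1()].
#' @return tidy data.frame with an `edp` column.
#' @export
run_sa2 <- function(emulators, edp_grid = seq(5, 25, by = 2.5),
                    material_dist = c("uniform", "loguniform"),
                    N = 512, n_gp_samples = 250, seed = 1) {
  stopifnot(all(c("lvv", "eps_cc_star") %in% names(emulators)))
  out <- list()
  for (md in material_dist) {
    for (edp in edp_grid) {
      prior <- sa_prior(c(REDUCED_NAMES, "edp"),
                        dist = c(rep(if (md == "uniform") "uniform" else "loguniform", 4), "fixed"),
                        fixed = c(edp = edp))
      for (qoi in c("lvv", "eps_cc_star")) {
        ens <- sobol_from_emulator(emulators[[qoi]], prior, N = N,
                                   n_gp_samples = n_gp_samples,
                                   seed = derive_seed(seed, round(edp * 10) + match(qoi, names(emulators))))
        s <- ens$summary
        s$output <- qoi
        s$prior <- md
        s$edp <- edp
        out[[paste(md, edp, qoi)]] <- s
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("output", "prior", "edp", "input", "index_type",
          "mean", "q25", "q75", "ci95_lo", "ci95_hi")]
}
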