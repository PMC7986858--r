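#' Fitting configuration for the Bernoulli grade-of-membership model
#'
#' Collects the number of motifs, optimizer controls, prior hyperparameters
#' and the seed governing initialization. The priors are a symmetric
#' Dirichlet(`dirichlet_alpha`) on each site's mixing-proportion row and an
#' independent Beta(`beta_a`, `beta_b`) on each occurrence probability; the
#' defaults (1 + 1e-2) are weakly informative and keep every M-step update
#' strictly interior to the parameter space.
#'
#' @param K number of motifs (>= 1).
#' @param max_iter maximum EM iterations.
#' @param tol convergence threshold on the change in the penalized objective.
#' @param n_restarts number of independent initializations for
#'   [multi_restart()].
#' @param dirichlet_alpha symmetric Dirichlet prior parameter on mixing rows.
#' @param beta_a,beta_b Beta prior parameters on occurrence probabilities.
#' @param eps probability clamp keeping the log-likelihood finite
#'   (must be < 0.5).
#' @param seed integer seed; per-restart seeds are derived from it by counter.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(K = 2L, max_iter = 500L, tol = 1e-6, n_restarts = 50L,
                       dirichlet_alpha = 1 + 1e-2, beta_a = 1 + 1e-2,
                       beta_b = 1 + 1e-2, eps = 1e-6, seed = 1L) {
  stopifnot(
    K >= 1L, max_iter >= 1L, tol > 0, n_restarts >= 1L,
    dirichlet_alpha > 0, beta_a > 0, beta_b > 0, eps > 0, eps < 0.5
  )
  structure(
    list(
      K = as.integer(K), max_iter = as.integer(max_iter), tol = tol,
      n_restarts = as.integer(n_restarts), dirichlet_alpha = dirichlet_alpha,
      beta_a = beta_a, beta_b = beta_b, eps = eps, seed = as.integer(seed)
    ),
    class = "fit_config"
  )
}

#' Bernoulli mixed-membership log-likelihood
#'
#' Computes the observed-data log-likelihood of a binary assemblage matrix
#' under per-site motif mixtures: each presence probability is
#' `p_ng = sum_k omega_nk * theta_kg`, and each cell contributes
#' `m_ng * log(p_ng) + (1 - m_ng) * log(1 - p_ng)`, with `p_ng` clamped to
#' `[eps, 1 - eps]` so the sum stays finite.
#'
#' @param data a [presence_absence] object.
#' @param omega N x K matrix of mixing proportions; rows on the simplex.
#' @param theta K x G matrix of occurrence probabilities in \[0, 1\].
#' @param eps probability clamp.
#' @return The log-likelihood (a single non-positive number).
#' @export
gom_log_likelihood <- function(data, omega, theta, eps = 1e-6) {
  stopifnot(inherits(data, "presence_absence"))
  m <- data$m
  omega <- as.matrix(omega)
  theta <- as.matrix(theta)
  if (nrow(omega) != nrow(m) || ncol(theta) != ncol(m) ||
      ncol(omega) != nrow(theta)) {
    stop("dimension mismatch between data, omega and theta")
  }
  if (any(abs(rowSums(omega) - 1) > 1e-6) || any(omega < -1e-12)) {
    stop("omega rows must lie on the probability simplex")
  }
  if (any(theta < -1e-12) || any(theta > 1 + 1e-12)) {
    stop("theta entries must lie in [0, 1]")
  }
  p <- clamp(omega %*% theta, eps, 1 - eps)
  sum(m * log(p) + (1 - m) * log1p(-p))
}

# Log of the Dirichlet + Beta prior density (up to normalizing constants),
# the penalty added to the likelihood to form the MAP objective.
log_prior <- function(omega, theta, config) {
  (config$dirichlet_alpha - 1) * sum(log(pmax(omega, 1e-300))) +
    (config$beta_a - 1) * sum(log(pmax(theta, 1e-300))) +
    (config$beta_b - 1) * sum(log(pmax(1 - theta, 1e-300)))
}

#' Fit the Bernoulli grade-of-membership model by MAP-EM
#'
#' Runs expectation-maximization on the latent allocation of each presence
#' record to a motif. The E-step computes responsibilities
#' `r_ngk` proportional to `omega_nk * theta_kg^m_ng * (1-theta_kg)^(1-m_ng)`;
#' the M-step updates `omega_nk` proportional to `sum_g r_ngk + (alpha - 1)`
#' and `theta_kg = (sum_n r_ngk m_ng + a - 1) / (sum_n r_ngk + a + b - 2)`.
#' The penalized objective (log-likelihood plus log-prior) is non-decreasing
#' across iterations; iteration stops when its change drops below
#' `config$tol` or `config$max_iter` is reached.
#'
#' @param data a [presence_absence] object.
#' @param config a [fit_config]; `config$seed` determines the random
#'   initialization (mixing rows from a symmetric Dirichlet(1), occurrence
#'   probabilities uniform on (0.2, 0.8)).
#' @return An object of class `motif_fit`: list with `K`, `omega` (N x K),
#'   `theta` (K x G), `log_likelihood`, `penalized_objective`,
#'   `objective_trace`, `n_iter`, `converged`, `seed`, `degenerate`
#'   (TRUE for an all-zero matrix), plus the id vectors from `data`.
#' @examples
#' pa <- presence_absence(matrix(rbinom(40, 1, 0.5), 8, 5))
#' fit <- fit_gom(pa, fit_config(K = 2, seed = 7))
#' fit$converged
#' @export
fit_gom <- function(data, config) {
  stopifnot(inherits(data, "presence_absence"), inherits(config, "fit_config"))
  m <- data$m
  N <- nrow(m); G <- ncol(m); K <- config$K
  if (K > G) warning("K exceeds the number of taxa; fit may be degenerate")
  degenerate <- all(m == 0)
  alpha <- config$dirichlet_alpha
  a <- config$beta_a; b <- config$beta_b
  eps <- config$eps

  init <- with_seed(config$seed, {
    w <- matrix(stats::rexp(N * K), N, K)
    list(
      omega = w / rowSums(w),
      theta = matrix(stats::runif(K * G, 0.2, 0.8), K, G)
    )
  })
  omega <- init$omega
  theta <- init$theta

  objective <- function() {
    p <- clamp(omega %*% theta, eps, 1 - eps)
    sum(m * log(p) + (1 - m) * log1p(-p)) + log_prior(omega, theta, config)
  }

  obj <- objective()
  trace <- numeric(config$max_iter + 1L)
  trace[1L] <- obj
  converged <- FALSE
  n_iter <- 0L
  m1 <- 1 - m
  for (it in seq_len(config$max_iter)) {
    # E-step: per-cell mixture components f_kg = theta if present else 1-theta
    num <- vector("list", K)
    p <- matrix(0, N, G)
    for (k in seq_len(K)) {
      fk <- m * rep(theta[k, ], each = N) + m1 * rep(1 - theta[k, ], each = N)
      num[[k]] <- omega[, k] * fk
      p <- p + num[[k]]
    }
    p[p < 1e-300] <- 1e-300
    # M-step accumulators
    rsum <- matrix(0, N, K)
    t_num <- matrix(0, K, G)
    t_den <- matrix(0, K, G)
    for (k in seq_len(K)) {
      r <- num[[k]] / p
      rsum[, k] <- rowSums(r)
      t_num[k, ] <- colSums(r * m)
      t_den[k, ] <- colSums(r)
    }
    omega <- (rsum + alpha - 1) / (G + K * (alpha - 1))
    omega <- omega / rowSums(omega) # guard against rounding drift
    theta <- clamp((t_num + a - 1) / (t_den + a + b - 2), eps, 1 - eps)
    new_obj <- objective()
    n_iter <- it
    trace[it + 1L] <- new_obj
    if (abs(new_obj - obj) < config$tol) {
      converged <- TRUE
      obj <- new_obj
      break
    }
    obj <- new_obj
  }
  p <- clamp(omega %*% theta, eps, 1 - eps)
  ll <- sum(m * log(p) + (1 - m) * log1p(-p))
  if (degenerate) {
    warning("all-zero presence matrix: fit is degenerate")
  }
  structure(
    list(
      K = K, omega = omega, theta = theta,
      log_likelihood = ll, penalized_objective = obj,
      objective_trace = trace[seq_len(n_iter + 1L)],
      n_iter = n_iter, converged = converged, seed = config$seed,
      degenerate = degenerate, eps = eps,
      site_ids = data$site_ids, taxon_ids = data$taxon_ids
    ),
    class = "motif_fit"
  )
}

#' @export
print.motif_fit <- function(x, ...) {
  cat(sprintf(
    "motif_fit: K = %d, %d sites x %d taxa\n  log-likelihood %.3f, %d iterations (%s)\n",
    x$K, nrow(x$omega), ncol(x$theta), x$log_likelihood, x$n_iter,
    if (x$converged) "converged" else "not converged"
  ))
  invisible(x)
}

#' Predicted presence probabilities from a fitted model
#'
#' @param fit a `motif_fit`.
#' @return The N x G matrix `omega %*% theta`; all entries in \[0, 1\].
#' @export
predict_presence_prob <- function(fit) {
  stopifnot(inherits(fit, "motif_fit"))
  p <- fit$omega %*% fit$theta
  dimnames(p) <- list(fit$site_ids, fit$taxon_ids)
  p
}

#' Bayesian information criterion for a motif fit
#'
#' Uses `BIC = -2 * log-likelihood + nu * log(N * G)` with
#' `nu = K * G + N * (K - 1)` free parameters (K x G occurrence probabilities
#' plus N simplex-constrained mixing rows) and `N * G` binary observations.
#' The parameter-count convention is recorded in fit metadata wherever BIC
#' values are written out.
#'
#' @param fit a `motif_fit`.
#' @param data the [presence_absence] the fit was computed on.
#' @return A list with `bic`, `nu` and `n_obs`.
#' @export
gom_bic <- function(fit, data) {
  stopifnot(inherits(fit, "motif_fit"), inherits(data, "presence_absence"))
  N <- nrow(data$m); G <- ncol(data$m)
  if (nrow(fit$omega) != N || ncol(fit$theta) != G) {
    stop("fit dimensions do not match data")
  }
  nu <- fit$K * G + N * (fit$K - 1)
  list(bic = -2 * fit$log_likelihood + nu * log(N * G), nu = nu, n_obs = N * G)
}

#' Best-of-many-restarts fit
#'
#' Runs [fit_gom()] from `config$n_restarts` independent initializations
#' (restart `i` uses seed `config$seed + i - 1`) and returns the fit with the
#' lowest BIC; ties are broken by higher log-likelihood, then by the earlier
#' restart. Fully reproducible given `config$seed`.
#'
#' @inheritParams fit_gom
#' @return The selected `motif_fit`, with an attached `restart_table`
#'   (data frame of seed, log-likelihood, BIC, iterations per restart).
#' @export
multi_restart <- function(data, config) {
  stopifnot(inherits(config, "fit_config"))
  fits <- vector("list", config$n_restarts)
  tab <- data.frame(
    restart = seq_len(config$n_restarts),
    seed = config$seed + seq_len(config$n_restarts) - 1L,
    log_likelihood = NA_real_, bic = NA_real_, n_iter = NA_integer_,
    converged = NA
  )
  for (i in seq_len(config$n_restarts)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i - 1L
    fits[[i]] <- fit_gom(data, cfg_i)
    tab$log_likelihood[i] <- fits[[i]]$log_likelihood
    tab$bic[i] <- gom_bic(fits[[i]], data)$bic
    tab$n_iter[i] <- fits[[i]]$n_iter
    tab$converged[i] <- fits[[i]]$converged
  }
  best <- order(tab$bic, -tab$log_likelihood, tab$restart)[1L]
  fit <- fits[[best]]
  fit$restart_table <- tab
  fit$selected_restart <- best
  fit
}

#' Sweep the number of motifs and select by BIC
#'
#' Runs [multi_restart()] for each candidate `K` and tabulates model-selection
#' statistics.
#'
#' @param data a [presence_absence] object.
#' @param k_values integer vector of candidate motif counts (each >= 1).
#' @param config a [fit_config]; its `K` field is overridden per candidate.
#' @return A list with `fits` (one `motif_fit` per K), `table` (data frame of
#'   K, log_likelihood, nu, bic) and `best_k` (the BIC-minimizing K).
#' @export
fit_k_sweep <- function(data, k_values, config) {
  stopifnot(length(k_values) >= 1L, all(k_values >= 1L))
  k_values <- as.integer(k_values)
  fits <- vector("list", length(k_values))
  tab <- data.frame(
    K = k_values, log_likelihood = NA_real_, nu = NA_real_, bic = NA_real_
  )
  for (i in seq_along(k_values)) {
    cfg <- config
    cfg$K <- k_values[i]
    fits[[i]] <- multi_restart(data, cfg)
    b <- gom_bic(fits[[i]], data)
    tab$log_likelihood[i] <- fits[[i]]$log_likelihood
    tab$nu[i] <- b$nu
    tab$bic[i] <- b$bic
  }
  names(fits) <- paste0("K", k_values)
  list(fits = fits, table = tab, best_k = tab$K[which.min(tab$bic)])
}

#' Resolve label switching against a reference
#'
#' Mixture likelihoods are invariant to motif relabeling, so fitted motifs
#' must be matched to a reference before parameters can be compared. Finds
#' the permutation of the fit's motifs maximizing the summed cosine
#' similarity between matched occurrence-probability rows (exact assignment
#' for K <= 8) and returns the fit with columns of `omega` and rows of
#' `theta` permuted accordingly.
#'
#' @param reference_theta K x G reference occurrence-probability matrix.
#' @param fit a `motif_fit` with the same K and G.
#' @return A list with `perm` (reference motif i matches fit motif `perm[i]`)
#'   and `fit` (the permuted `motif_fit`).
#' @export
align_motifs <- function(reference_theta, fit) {
  stopifnot(inherits(fit, "motif_fit"))
  reference_theta <- as.matrix(reference_theta)
  if (nrow(reference_theta) != fit$K) stop("K mismatch with reference")
  if (ncol(reference_theta) != ncol(fit$theta)) stop("G mismatch with reference")
  K <- fit$K
  cosine <- function(u, v) {
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu == 0 || nv == 0) return(0)
    sum(u * v) / (nu * nv)
  }
  score <- matrix(0, K, K)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      score[i, j] <- cosine(reference_theta[i, ], fit$theta[j, ])
    }
  }
  perm <- best_assignment(score)
  out <- fit
  out$omega <- fit$omega[, perm, drop = FALSE]
  out$theta <- fit$theta[perm, , drop = FALSE]
  list(perm = perm, fit = out)
}

#' Write a fitted model to disk
#'
#' Writes `omega` and `theta` as CSV tables with site/taxon ids and a JSON
#' sidecar recording K, seed, BIC and its parameter-count convention,
#' iteration counts and prior hyperparameters.
#'
#' @param fit a `motif_fit`.
#' @param data the [presence_absence] used for the fit (for BIC).
#' @param dir output directory (created if needed).
#' @param prefix filename prefix, default `"fit_K<K>"`.
#' @return The directory, invisibly.
#' @export
write_motif_fit <- function(fit, data, dir, prefix = NULL) {
  stopifnot(inherits(fit, "motif_fit"))
  prefix <- prefix %||% paste0("fit_K", fit$K)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  omega_df <- data.frame(site_id = fit$site_ids, fit$omega, check.names = FALSE)
  colnames(omega_df)[-1L] <- paste0("motif_", seq_len(fit$K))
  theta_df <- data.frame(motif = paste0("motif_", seq_len(fit$K)), fit$theta,
                         check.names = FALSE)
  colnames(theta_df)[-1L] <- fit$taxon_ids
  utils::write.csv(omega_df, file.path(dir, paste0(prefix, "_omega.csv")),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(theta_df, file.path(dir, paste0(prefix, "_theta.csv")),
                   row.names = FALSE, quote = FALSE)
  b <- gom_bic(fit, data)
  write_sidecar(
    list(
      K = fit$K, seed = fit$seed, log_likelihood = fit$log_likelihood,
      penalized_objective = fit$penalized_objective, bic = b$bic, nu = b$nu,
      n_obs = b$n_obs, bic_convention = "nu = K*G + N*(K-1); n_obs = N*G",
      n_iter = fit$n_iter, converged = fit$converged
    ),
    file.path(dir, paste0(prefix, "_meta.json"))
  )
  invisible(dir)
}
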