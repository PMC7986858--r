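test_that("log-likelihood matches hand-evaluated mixtures", {
  pa1 <- presence_absence(matrix(c(1L, 0L), 1, 2))
  expect_equal(
    gom_log_likelihood(pa1, matrix(1, 1, 1), matrix(c(0.5, 0.5), 1, 2)),
    2 * log(0.5), tolerance = 1e-9
  )
  # two motifs mixing to p = 0.5 for both taxa
  pa2 <- presence_absence(matrix(c(1L, 1L), 1, 2))
  expect_equal(
    gom_log_likelihood(pa2, matrix(c(0.5, 0.5), 1, 2),
                       rbind(c(0.9, 0.1), c(0.1, 0.9))),
    2 * log(0.5), tolerance = 1e-9
  )
  # perfect-fit limit under clamping
  pa3 <- presence_absence(matrix(1L, 3, 4))
  ll <- gom_log_likelihood(pa3, matrix(1, 3, 1), matrix(1, 1, 4), eps = 1e-6)
  expect_equal(ll, 12 * log(1 - 1e-6), tolerance = 1e-12)
  expect_error(
    gom_log_likelihood(pa1, matrix(1, 2, 1), matrix(0.5, 1, 2)),
    "dimension"
  )
})

test_that("K = 1 with flat Beta prior recovers column means exactly", {
  m <- matrix(c(1L, 1L, 0L, 0L, 1L, 0L), 2, 3)
  pa <- presence_absence(m)
  fit <- fit_gom(pa, fit_config(K = 1, beta_a = 1, beta_b = 1,
                                dirichlet_alpha = 1, seed = 3))
  expect_equal(unname(fit$omega[, 1]), rep(1, 2))
  expect_equal(as.numeric(fit$theta),
               pmin(pmax(colMeans(m), 1e-6), 1 - 1e-6), tolerance = 1e-12)
})

test_that("EM objective is monotone and simplex constraints hold", {
  for (seed in 1:5) {
    set.seed(seed)
    N <- sample(10:40, 1); G <- sample(8:25, 1); K <- sample(2:4, 1)
    pa <- presence_absence(matrix(rbinom(N * G, 1, runif(1, 0.2, 0.7)), N, G))
    fit <- fit_gom(pa, fit_config(K = K, seed = seed, max_iter = 150))
    expect_gte(min(diff(fit$objective_trace)), -1e-8)
    expect_lt(max(abs(rowSums(fit$omega) - 1)), 1e-10)
    expect_true(all(fit$theta >= 1e-6 & fit$theta <= 1 - 1e-6))
    expect_lte(fit$log_likelihood, 0)
  }
})

test_that("saturated data drives predicted probabilities to the clamp", {
  pa <- presence_absence(matrix(1L, 15, 10))
  # flat priors: no shrinkage away from the saturation limit
  fit <- fit_gom(pa, fit_config(K = 2, seed = 1, beta_a = 1, beta_b = 1,
                                dirichlet_alpha = 1))
  expect_true(all(predict_presence_prob(fit) >= 1 - 2e-6))
})

test_that("predicted presence probabilities follow the mixture identity", {
  fit <- structure(
    list(K = 2, omega = rbind(c(1, 0), c(0.25, 0.75)),
         theta = rbind(c(0.7, 0.8), c(0.7, 0.2)),
         site_ids = c("s1", "s2"), taxon_ids = c("a", "b")),
    class = "motif_fit"
  )
  p <- predict_presence_prob(fit)
  expect_equal(unname(p[1, ]), c(0.7, 0.8))       # pure membership
  expect_equal(unname(p[2, 2]), 0.25 * 0.8 + 0.75 * 0.2) # = 0.35
  expect_equal(unname(p[2, 1]), 0.7)              # theta equal across motifs
})

test_that("BIC matches the hand-computed penalty and is monotone in fit", {
  pa <- presence_absence(matrix(rbinom(200, 1, 0.5), 10, 20))
  f <- function(K, ll) {
    structure(list(K = K, omega = matrix(1 / K, 10, K),
                   theta = matrix(0.5, K, 20), log_likelihood = ll),
              class = "motif_fit")
  }
  b2 <- gom_bic(f(2, -100), pa)
  expect_equal(b2$nu, 50)
  expect_equal(b2$bic, 200 + 50 * log(200), tolerance = 1e-9)
  b1 <- gom_bic(f(1, -100), pa)
  expect_equal(b1$nu, 20)
  expect_equal(b1$bic, 200 + 20 * log(200), tolerance = 1e-9)
  expect_lt(gom_bic(f(2, -90), pa)$bic, b2$bic)
})

test_that("multi-restart selection is reproducible and picks the best run", {
  sim <- simulate_scenario(small_scenario(seed = 7))
  cfg <- fit_config(K = 2, n_restarts = 4, seed = 10, max_iter = 200)
  fit_a <- multi_restart(sim$data, cfg)
  fit_b <- multi_restart(sim$data, cfg)
  expect_identical(fit_a$omega, fit_b$omega)
  expect_identical(fit_a$theta, fit_b$theta)
  expect_equal(fit_a$log_likelihood, max(fit_a$restart_table$log_likelihood))
  expect_equal(min(fit_a$restart_table$bic),
               gom_bic(fit_a, sim$data)$bic)

  single <- fit_gom(sim$data, fit_config(K = 2, seed = 10, max_iter = 200))
  one <- multi_restart(sim$data, fit_config(K = 2, n_restarts = 1, seed = 10,
                                            max_iter = 200))
  expect_identical(one$omega, single$omega)
})

test_that("parameter recovery on the reference scenario is accurate", {
  sim <- simulate_scenario(archipelago_scenario(seed = 21))
  fit <- multi_restart(sim$data, fit_config(K = 2, n_restarts = 5, seed = 2))
  al <- align_motifs(sim$truth$theta, fit)
  expect_lt(sqrt(mean((al$fit$theta - sim$truth$theta)^2)), 0.05)
  expect_lt(mean(abs(al$fit$omega - sim$truth$omega)), 0.05)
  # mixing field recovered per motif
  for (k in 1:2) {
    expect_gt(cor(al$fit$omega[, k], sim$truth$omega[, k]), 0.95)
  }
})

test_that("k sweep tabulates fits and finds the supported K", {
  sim <- simulate_scenario(small_scenario(seed = 13))
  cfg <- fit_config(n_restarts = 4, seed = 5)
  sw <- fit_k_sweep(sim$data, c(1, 2, 3), cfg)
  expect_equal(sw$table$K, 1:3)
  expect_equal(sw$best_k, 2)
  # nesting: log-likelihood non-decreasing in K (small tolerance for
  # finite restarts)
  expect_true(all(diff(sw$table$log_likelihood) > -abs(sw$table$log_likelihood[1]) * 1e-3))
  # singleton sweep equals a direct multi-restart
  cfg2 <- cfg; cfg2$K <- 2L
  expect_equal(sw$fits[["K2"]]$log_likelihood,
               multi_restart(sim$data, cfg2)$log_likelihood)
})

test_that("motif alignment undoes label switching", {
  set.seed(31)
  K <- 4; G <- 30
  ref <- matrix(runif(K * G), K, G)
  perm_true <- sample(K)
  fit <- structure(
    list(K = K, omega = matrix(1 / K, 5, K)[, perm_true],
         theta = ref[perm_true, ],
         site_ids = paste0("s", 1:5), taxon_ids = paste0("t", 1:G)),
    class = "motif_fit"
  )
  al <- align_motifs(ref, fit)
  expect_equal(al$fit$theta, ref)
  expect_equal(al$perm, order(perm_true))

  # noisy permutation still matched as by exhaustive search
  for (rep in 1:10) {
    K2 <- sample(2:5, 1)
    ref2 <- matrix(runif(K2 * G), K2, G)
    p2 <- sample(K2)
    noisy <- pmin(pmax(ref2[p2, ] + rnorm(K2 * G, 0, 0.01), 0), 1)
    fit2 <- structure(
      list(K = K2, omega = matrix(1 / K2, 3, K2), theta = noisy,
           site_ids = paste0("s", 1:3), taxon_ids = paste0("t", 1:G)),
      class = "motif_fit"
    )
    al2 <- align_motifs(ref2, fit2)
    # brute-force assignment oracle
    cosim <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    S <- outer(seq_len(K2), seq_len(K2),
               Vectorize(function(i, j) cosim(ref2[i, ], noisy[j, ])))
    perms <- do.call(rbind, combinat_perms(K2))
    best <- perms[which.max(apply(perms, 1, function(p)
      sum(S[cbind(seq_len(K2), p)]))), ]
    expect_equal(al2$perm, best)
  }
})
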