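test_that("resampling draws indices proportionally to the weights", {
  set.seed(501)
  # equal weights + systematic scheme: a permutation of 1..K
  idx <- resample(rep(0, 10), scheme = "systematic")
  expect_setequal(idx, 1:10)
  # a single dominant weight takes every slot
  lw <- c(-Inf, 0, -Inf, -Inf)
  expect_true(all(resample(lw, 8, "systematic") == 2L))
  expect_true(all(resample(lw, 8, "multinomial") == 2L))
  # multinomial counts match the weights within 3 binomial SEs
  w <- c(0.1, 0.2, 0.3, 0.4)
  n <- 1e5
  counts <- tabulate(resample(log(w), n, "multinomial"), nbins = 4)
  se <- sqrt(w * (1 - w) / n)
  expect_true(all(abs(counts / n - w) < 3 * se))
  # systematic counts too (variance is smaller, same bound applies)
  counts_s <- tabulate(resample(log(w), n, "systematic"), nbins = 4)
  expect_true(all(abs(counts_s / n - w) < 3 * se))
  expect_error(resample(c(-Inf, -Inf)), class = "ordssm_degeneracy_error")
})

test_that("zero innovation noise collapses the filter onto the deterministic trajectory", {
  model <- toy_linear_model(items_per_state = 1, loading = 0, error_var = 1)
  dat <- tibble::tibble(y1_1 = rnorm(20), y2_1 = rnorm(20))
  out <- particle_filter(dat, matrix(0, 2, 2), model,
    K = 50, seed = 1, sigma_zero = TRUE
  )
  # A = 0 maps every particle to exactly 0 from t = 1 on
  expect_true(all(as.matrix(out$filtered_means[, -1]) == 0))
})

test_that("particle-filter log-likelihood agrees with the exact Kalman filter", {
  set.seed(502)
  A <- matrix(c(0.6, 0, 0.2, 0.5), 2, 2)
  model <- toy_linear_model(items_per_state = 3, loading = 0.9, error_var = 0.8)
  traj <- simulate_states(A, 50, seed = 21)
  dat <- simulate_measurements(traj, model, seed = 22)
  kal <- kalman_filter(dat, A, model = model)
  lls <- vapply(1:8, function(s) {
    particle_filter(dat, A, model, K = 2000, seed = 100 + s)$loglik
  }, numeric(1))
  expect_lt(abs(mean(lls) - kal$loglik), 4 * stats::sd(lls))
  # filtered means approach the exact ones as the particle count grows
  mad_at_K <- vapply(c(100, 1000, 8000), function(K) {
    mads <- vapply(1:3, function(s) {
      pf <- particle_filter(dat, A, model, K = K, seed = 10 * K + s)
      mean(abs(as.matrix(pf$filtered_means[-1]) - as.matrix(kal$filtered_means[-1])))
    }, numeric(1))
    mean(mads)
  }, numeric(1))
  expect_true(all(diff(mad_at_K) < 0))
  expect_lt(mad_at_K[3], 0.1)
})

test_that("the Kalman filter matches the brute-force joint Gaussian density", {
  A <- matrix(c(0.5, 0, 0.3, 0.4), 2, 2)
  covs <- identify_innovations(A)
  model <- toy_linear_model(items_per_state = 1, loading = 1.2, error_var = 0.6)
  set.seed(503)
  T <- 3
  dat <- tibble::tibble(y1_1 = rnorm(T, 0, 1.5), y2_1 = rnorm(T, 0, 1.5))
  kal <- kalman_filter(dat, A, covs, model)
  # joint law of x_{1:3}: x1 ~ N(0, A A' + Sigma) under f0 = N(0, I)
  p <- 2
  P1 <- A %*% t(A) + covs$Sigma
  V <- matrix(0, T * p, T * p)
  V[1:2, 1:2] <- P1
  for (t in 2:T) {
    V[(t - 1) * p + 1:2, (t - 1) * p + 1:2] <-
      A %*% V[(t - 2) * p + 1:2, (t - 2) * p + 1:2] %*% t(A) + covs$Sigma
  }
  for (t in 2:T) {
    for (s in 1:(t - 1)) {
      blk <- V[(s - 1) * p + 1:2, (s - 1) * p + 1:2]
      for (k in (s + 1):t) blk <- blk %*% t(A)
      V[(s - 1) * p + 1:2, (t - 1) * p + 1:2] <- blk
      V[(t - 1) * p + 1:2, (s - 1) * p + 1:2] <- t(blk)
    }
  }
  C <- matrix(0, 2, 2)
  C[1, 1] <- 1.2
  C[2, 2] <- 1.2
  Cbig <- kronecker(diag(T), C)
  Vy <- Cbig %*% V %*% t(Cbig) + diag(0.6, T * 2)
  yvec <- as.numeric(t(as.matrix(dat)))
  expect_equal(kal$loglik, dmvnorm_log(yvec, rep(0, T * 2), Vy), tolerance = 1e-8)
})

test_that("zero loadings give an information-free filter", {
  model <- toy_linear_model(items_per_state = 2, loading = 0, error_var = 1.3)
  set.seed(504)
  dat <- tibble::tibble(
    y1_1 = rnorm(15), y1_2 = rnorm(15), y2_1 = rnorm(15), y2_2 = rnorm(15)
  )
  A <- diag(0.4, 2)
  kal <- kalman_filter(dat, A, model = model)
  expect_true(all(as.matrix(kal$filtered_means[, -1]) == 0))
  iid_ll <- sum(stats::dnorm(as.matrix(dat), 0, sqrt(1.3), log = TRUE))
  expect_equal(kal$loglik, iid_ll, tolerance = 1e-10)
})

test_that("steady-state filtered variance solves the scalar Riccati recursion", {
  a <- 0.8
  covs <- identify_innovations(matrix(a, 1, 1))
  s2 <- diag(covs$Sigma)[1]
  lam <- 1.1
  psi <- 0.7
  model <- measurement_model(linear_item("y", 1, loading = lam, error_var = psi))
  set.seed(505)
  dat <- tibble::tibble(y = rnorm(200))
  kal <- kalman_filter(dat, matrix(a, 1, 1), covs, model)
  # independent scalar Riccati iteration
  P <- 1
  for (i in 1:500) {
    Pp <- a^2 * P + s2
    P <- Pp - (Pp * lam)^2 / (lam^2 * Pp + psi)
  }
  expect_equal(kal$filtered_vars[200, 1], P, tolerance = 1e-8)
})

test_that("near-noiseless graded measurement pins the filtered states to the truth", {
  # high discrimination + dense thresholds approximates direct observation
  A <- matrix(c(0.6, 0, 0.2, 0.6), 2, 2)
  dense <- seq(-2.8, 2.8, by = 0.4)
  items <- list()
  for (s in 1:2) {
    for (k in 1:2) {
      items[[length(items) + 1L]] <- grm_item(
        sprintf("s%d_%d", s, k), s, beta = dense, alpha = 50
      )
    }
  }
  model <- measurement_model(items, p = 2)
  traj <- simulate_states(A, 200, seed = 31)
  dat <- simulate_measurements(traj, model, seed = 32)
  pf <- particle_filter(dat, A, model, K = 2000, seed = 33)
  for (j in 1:2) {
    expect_gt(stats::cor(traj$states[, j], dplyr::pull(pf$filtered_means, j + 1)), 0.95)
  }
})

test_that("state recovery does not degrade as measurement informativeness rises", {
  A <- matrix(c(0.5, 0, 0.2, 0.5), 2, 2)
  meds <- vapply(c(0.5, 2, 8), function(alpha) {
    rhos <- vapply(1:3, function(r) {
      model <- toy_grm_model(items_per_state = 3, beta = c(-1, 0, 1), alpha = alpha)
      traj <- simulate_states(A, 150, seed = 600 + r)
      dat <- simulate_measurements(traj, model, seed = 700 + r)
      pf <- particle_filter(dat, A, model, K = 500, seed = 800 + r)
      spearman_state_recovery(traj$states, pf$filtered_means[-1])
    }, numeric(1))
    stats::median(rhos)
  }, numeric(1))
  expect_true(all(diff(meds) > -0.05))
})

test_that("schema violations in the observation table are reported", {
  model <- toy_grm_model(items_per_state = 1, beta = c(-1, 1))
  dat <- tibble::tibble(y1_1 = c(1, 2, 9), y2_1 = c(1, 1, 1))
  expect_error(
    particle_filter(dat, diag(0.3, 2), model, K = 10),
    class = "ordssm_data_error"
  )
  expect_error(
    particle_filter(tibble::tibble(a = 1:3), diag(0.3, 2), model, K = 10),
    class = "ordssm_schema_error"
  )
})
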