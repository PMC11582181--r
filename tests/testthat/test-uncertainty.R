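test_that("quadratic curvature recovers exact parabola information", {
  th <- seq(-2, 4, length.out = 7)
  # l = -(theta - 1)^2 / 2: unit information, se = 1
  g1 <- tibble::tibble(theta = th, loglik = -(th - 1)^2 / 2)
  res <- quadratic_curvature(g1)
  expect_equal(res$se, 1, tolerance = 1e-10)
  expect_equal(res$curvature, -1, tolerance = 1e-10)
  # l = -2 theta^2: -2c = 4, se = .5
  g2 <- tibble::tibble(theta = th, loglik = -2 * th^2)
  expect_equal(quadratic_curvature(g2)$se, 0.5, tolerance = 1e-10)
  # convex/flat fits are under-identification signals, not SEs
  expect_error(
    quadratic_curvature(tibble::tibble(theta = th, loglik = th^2)),
    class = "ordssm_curvature_error"
  )
  expect_error(
    quadratic_curvature(tibble::tibble(theta = th[1:4], loglik = -th[1:4]^2)),
    class = "ordssm_slice_error"
  )
})

test_that("noisy slices still localize the standard error", {
  set.seed(701)
  th <- seq(-1, 3, length.out = 11)
  ses <- vapply(1:100, function(i) {
    g <- tibble::tibble(
      theta = rep(th, each = 3),
      loglik = -(rep(th, each = 3) - 1)^2 / 2 + stats::rnorm(33, 0, 0.1)
    )
    quadratic_curvature(g)$se
  }, numeric(1))
  expect_lt(abs(mean(ses) - 1), 0.1)
})

test_that("Wald intervals use the published critical values", {
  expect_equal(wald_ci(0, 1, 0.95), c(-1.96, 1.96))
  expect_equal(wald_ci(0, 1, 0.998), c(-3.09, 3.09))
  ci1 <- wald_ci(0.5, 0.1, 0.95)
  ci2 <- wald_ci(0.5, 0.2, 0.95)
  expect_equal(diff(ci2) / diff(ci1), 2)
  expect_error(wald_ci(0, -1, 0.95))
})

test_that("the Kalman backend reproduces the exact slice pointwise", {
  A <- matrix(c(0.5, 0, 0.2, 0.4), 2, 2)
  model <- toy_linear_model(items_per_state = 2, loading = 1, error_var = 0.7)
  traj <- simulate_states(A, 60, seed = 41)
  dat <- simulate_measurements(traj, model, seed = 42)
  est <- encode_params(A)
  sl <- slice_loglik(
    dat, model, est, "A[1,1]",
    spec = slice_spec(half_width = 0.2, n_points = 7, n_reps = 1, seed = 1),
    backend = "kalman"
  )
  direct <- vapply(unique(sl$theta), function(g) {
    A2 <- A
    A2[1, 1] <- g
    kalman_filter(dat, A2, model = model)$loglik
  }, numeric(1))
  expect_equal(dplyr::distinct(sl, theta, .keep_all = TRUE)$loglik, direct)
  # exact slices are replicate-free: zero spread across reps
  sl3 <- slice_loglik(
    dat, model, est, "A[2,2]",
    spec = slice_spec(half_width = 0.2, n_points = 7, n_reps = 2, seed = 1),
    backend = "kalman"
  )
  spread <- dplyr::summarise(dplyr::group_by(sl3, theta), s = stats::sd(loglik))
  expect_true(all(spread$s == 0))
})

test_that("a slice centered at the maximizer peaks at its center point", {
  A <- matrix(c(0.5, 0, 0.2, 0.4), 2, 2)
  model <- toy_linear_model(items_per_state = 3, loading = 1, error_var = 0.5)
  traj <- simulate_states(A, 150, seed = 43)
  dat <- simulate_measurements(traj, model, seed = 44)
  # maximize the exact likelihood along A[1,1]
  f <- function(g) {
    A2 <- A
    A2[1, 1] <- g
    kalman_filter(dat, A2, model = model)$loglik
  }
  opt <- stats::optimize(f, c(0.1, 0.9), maximum = TRUE)
  est <- encode_params(A)
  est[1] <- opt$maximum
  sl <- slice_loglik(
    dat, model, est, "A[1,1]",
    spec = slice_spec(half_width = 0.15, n_points = 9, n_reps = 1, seed = 1),
    backend = "kalman"
  )
  agg <- dplyr::summarise(dplyr::group_by(sl, theta), m = mean(loglik))
  expect_equal(agg$theta[which.max(agg$m)], opt$maximum, tolerance = 0.05)
})

test_that("infeasible grid points are dropped and tiny slices error", {
  model <- toy_linear_model(items_per_state = 2)
  traj <- simulate_states(diag(0.3, 2), 30, seed = 45)
  dat <- simulate_measurements(traj, model, seed = 46)
  est <- encode_params(diag(0.9, 2))
  # a wide slice walks A[1,1] across the stationarity boundary
  expect_warning(
    sl <- slice_loglik(
      dat, model, est, "A[1,1]",
      spec = slice_spec(half_width = 0.5, n_points = 11, n_reps = 1, seed = 2),
      backend = "kalman"
    ),
    "infeasible"
  )
  expect_lt(length(unique(sl$theta)), 11)
  expect_error(
    suppressWarnings(slice_loglik(
      dat, model, est, "A[1,1]",
      spec = slice_spec(half_width = 2, n_points = 5, n_reps = 1, seed = 2),
      backend = "kalman"
    )),
    class = "ordssm_slice_error"
  )
})

test_that("slice SEs from a fit come with both Wald intervals", {
  cond <- sim_condition(T = 60, J = 3, AR = 0.5, thresholds = "equal",
                        replicate_seed = 16)
  ds <- make_condition_dataset(cond)
  cfg <- mif2_config(particles = 100, iterations = 10, n_runs = 1, seed = 6,
                     estimate_measurement = FALSE)
  fit <- mif2_fit(ds$observations, ds$truth$model, cfg)
  se_tbl <- suppressWarnings(slice_se(
    fit, ds$observations,
    params = c("A[1,1]", "A[2,2]"),
    spec = slice_spec(half_width = 0.25, n_points = 7, n_reps = 2, K = 200, seed = 7)
  ))
  expect_equal(nrow(se_tbl), 2)
  ok <- !is.na(se_tbl$std.error)
  expect_true(any(ok))
  expect_true(all(se_tbl$std.error[ok] > 0))
  # 99.8% interval is wider than the 95% one by the ratio of critical values
  w95 <- se_tbl$conf.high[ok] - se_tbl$conf.low[ok]
  w998 <- se_tbl$conf.high.998[ok] - se_tbl$conf.low.998[ok]
  expect_equal(w998 / w95, rep(3.09 / 1.96, sum(ok)), tolerance = 1e-10)
})
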