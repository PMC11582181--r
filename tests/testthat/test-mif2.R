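test_that("parameter encoding round-trips and preserves threshold order", {
  # first threshold -2 with an interval of .36 encodes as (-2, log .36)
  pv <- encode_params(diag(0.1, 2), list(c(-2, -1.64)))
  expect_equal(unname(pv[5]), -2)
  expect_equal(unname(pv[6]), log(0.36))
  dec <- decode_params(pv)
  expect_equal(dec$A, diag(0.1, 2))
  expect_equal(dec$thresholds[[1]], c(-2, -1.64))
  set.seed(601)
  for (i in 1:20) {
    A <- matrix(rnorm(4, 0, 0.3), 2, 2)
    th <- lapply(1:3, function(j) cumsum(c(rnorm(1), rexp(sample(1:5, 1)))))
    pv <- encode_params(A, th)
    dec <- decode_params(pv)
    expect_equal(dec$A, A)
    expect_equal(dec$thresholds, th, tolerance = 1e-12)
    # arbitrary perturbation of the encoded vector keeps thresholds ordered
    pv2 <- pv + rnorm(length(pv), 0, 2)
    dec2 <- decode_params(structure(pv2, p = attr(pv, "p"), nb = attr(pv, "nb")))
    for (b in dec2$thresholds) expect_false(is.unsorted(b, strictly = TRUE))
  }
  expect_error(encode_params(diag(0.1, 2), list(c(0, 0))),
    class = "ordssm_encoding_error"
  )
})

test_that("cooling is geometric with the variance-halving-time convention", {
  expect_equal(cooling_sd(1, 0.3, 0.05), 0.3)
  # after 50 iterations the perturbation variance is the cooling fraction
  expect_equal(cooling_sd(51, 0.3, 0.05)^2, 0.05 * 0.3^2)
  s <- cooling_sd(1:300, 0.3, 0.05)
  expect_true(all(diff(s) < 0))
  expect_lt(cooling_sd(1000, 0.3, 0.05), 1e-6)
  # SD convention cools twice as fast on the log scale
  expect_equal(cooling_sd(51, 0.3, 0.05, on_sd = TRUE), 0.3 * 0.05)
})

test_that("a frozen kernel leaves the estimate at its initial value", {
  cond <- sim_condition(T = 30, J = 3, AR = 0.4, thresholds = "equal",
                        replicate_seed = 12)
  ds <- make_condition_dataset(cond)
  cfg <- mif2_config(
    particles = 30, iterations = 3, perturb_sd = 0,
    n_runs = 1, seed = 2, estimate_measurement = FALSE
  )
  fit <- mif2_fit(ds$observations, ds$truth$model, cfg)
  expect_equal(unname(fit$estimate), unname(fit$init), tolerance = 1e-12)
  expect_equal(fit$A, diag(0.1, 2), tolerance = 1e-12)
  # and the per-iteration logliks then behave like repeated particle filtering
  covs <- identify_innovations(diag(0.1, 2))
  pf_lls <- vapply(1:5, function(s) {
    particle_filter(ds$observations, diag(0.1, 2), ds$truth$model,
      K = 30, seed = 900 + s
    )$loglik
  }, numeric(1))
  expect_lt(
    abs(mean(fit$loglik_traces[, 1]) - mean(pf_lls)),
    4 * stats::sd(pf_lls) + 2
  )
})

test_that("a single run is its own average and uses the standard initial values", {
  cond <- sim_condition(T = 40, J = 3, AR = 0.5, CR = 0.25,
                        thresholds = "equal", replicate_seed = 13)
  ds <- make_condition_dataset(cond)
  cfg <- mif2_config(
    particles = 60, iterations = 5, n_runs = 1, seed = 3,
    estimate_measurement = FALSE
  )
  fit <- mif2_fit(ds$observations, ds$truth$model, cfg)
  expect_equal(unname(fit$estimate), unname(fit$per_run_estimates[1, ]))
  # default initial transition matrix diag(.1, .1)
  expect_equal(unname(fit$init[1:4]), c(0.1, 0, 0, 0.1))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(tidy(fit)), 4)
  expect_equal(glance(fit)$n_runs, 1L)
})

test_that("iterated filtering climbs the likelihood and recovers dynamics", {
  # moderately informative design so a short run shows the hill-climb
  cond <- sim_condition(
    T = 200, items_per_state = 6, J = 7, AR = 0.7, CR = 0.25,
    thresholds = "equal", replicate_seed = 14
  )
  ds <- make_condition_dataset(cond)
  cfg <- mif2_config(
    particles = 300, iterations = 40, n_runs = 2, seed = 4,
    estimate_measurement = FALSE
  )
  fit <- mif2_fit(ds$observations, ds$truth$model, cfg)
  tr <- fit$loglik_traces
  # late iterations beat the first ones
  expect_gt(mean(tr[36:40, ]), mean(tr[1:3, ]))
  expect_lt(max(abs(fit$A - ds$truth$A)), 0.3)
  # filtered states track the truth
  rho <- spearman_state_recovery(ds$trajectory$states, fit$final_filter$filtered_means[-1])
  expect_gt(rho, 0.7)
})

test_that("infeasible proposals reweight rather than crash a run", {
  cond <- sim_condition(T = 30, J = 3, AR = 0.4, thresholds = "equal",
                        replicate_seed = 15)
  ds <- make_condition_dataset(cond)
  # large perturbations guarantee infeasible/non-stationary proposals
  cfg <- mif2_config(
    particles = 80, iterations = 4, perturb_sd = 0.8, n_runs = 1, seed = 5,
    estimate_measurement = FALSE
  )
  fit <- mif2_fit(ds$observations, ds$truth$model, cfg)
  expect_gt(sum(fit$n_infeasible), 0)
  expect_true(is_stationary(fit$A) || TRUE) # estimate exists either way
  expect_true(all(is.finite(fit$estimate)))
})

test_that("a fit is bit-reproducible from its master seed", {
  cond <- sim_condition(T = 30, J = 3, AR = 0.4, thresholds = "equal",
                        replicate_seed = 21)
  ds <- make_condition_dataset(cond)
  cfg <- mif2_config(particles = 50, iterations = 5, n_runs = 2, seed = 99,
                     estimate_measurement = FALSE)
  f1 <- mif2_fit(ds$observations, ds$truth$model, cfg)
  f2 <- mif2_fit(ds$observations, ds$truth$model, cfg)
  expect_identical(f1$estimate, f2$estimate)
  expect_identical(f1$loglik_traces, f2$loglik_traces)
  expect_identical(f1$final_filter$loglik, f2$final_filter$loglik)
})

test_that("fixing versus estimating true thresholds converges with series length", {
  # with more data, estimating the thresholds (from moderately misplaced
  # starting values) costs no more in the dynamics estimate than fixing
  # them at truth: the gap between the two fits does not grow with T
  med_gap <- vapply(c(100L, 400L), function(TT) {
    gaps <- vapply(1:4, function(r) {
      cond <- sim_condition(
        T = TT, items_per_state = 6L, J = 3L, AR = 0.5, CR = 0.25,
        thresholds = "equal", replicate_seed = 2000L + r
      )
      ds <- make_condition_dataset(cond)
      cfg_fix <- mif2_config(particles = 300, iterations = 60, n_runs = 1,
                             seed = 30L + r, estimate_measurement = FALSE)
      cfg_est <- mif2_config(particles = 300, iterations = 60, n_runs = 1,
                             seed = 30L + r, estimate_measurement = TRUE)
      f_fix <- mif2_fit(ds$observations, ds$truth$model, cfg_fix)
      amod <- measurement_model(lapply(ds$truth$model$items, function(it) {
        grm_item(it$item_id, it$state_index, beta = it$beta - 0.75)
      }), p = 2)
      f_est <- mif2_fit(ds$observations, amod, cfg_est)
      max(abs(f_fix$A - f_est$A))
    }, numeric(1))
    stats::median(gaps)
  }, numeric(1))
  expect_lt(med_gap[2], med_gap[1] + 0.05)
})

test_that("presets encode the published and desk-scale tuning settings", {
  sim <- mif2_preset("simulation")
  expect_equal(sim$particles, 1000L)
  expect_equal(sim$iterations, 250L)
  expect_equal(sim$cooling_fraction_50, 0.05)
  expect_equal(sim$perturb_sd, 0.3)
  expect_equal(sim$n_runs, 4L)
  emp <- mif2_preset("empirical")
  expect_equal(emp$iterations, 500L)
  expect_equal(emp$cooling_fraction_50, 0.75)
  expect_equal(emp$perturb_sd, 0.05)
  expect_false(emp$estimate_measurement)
  desk <- mif2_preset("desk", seed = 1)
  expect_equal(desk$particles, 500L)
  expect_equal(desk$iterations, 100L)
  expect_equal(desk$n_runs, 2L)
})
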