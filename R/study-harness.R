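#' Spearman state-recovery correlation
#'
#' Rank correlation between the true and the estimated (filtered) state
#' trajectories, computed per state column and averaged over states: a
#' scale-free measure of how well the latent trajectories were recovered
#' (invariant to monotone transforms of the estimates).
#'
#' @param true_states T x p matrix/tibble of true state values.
#' @param est_states T x p matrix/tibble of estimated state values.
#' @return Average Spearman correlation (scalar); per-state values attached
#'   as attribute `per_state`.
#' @export
spearman_state_recovery <- function(true_states, est_states) {
  xt <- state_matrix(true_states)
  xe <- state_matrix(est_states)
  if (!all(dim(xt) == dim(xe))) {
    rlang::abort("True and estimated state matrices must have equal shapes.",
      class = "ordssm_dimension_error"
    )
  }
  per_state <- vapply(seq_len(ncol(xt)), function(j) {
    if (stats::sd(xt[, j]) == 0 || stats::sd(xe[, j]) == 0) {
      rlang::abort(sprintf("State %d is constant; Spearman correlation undefined.", j),
        class = "ordssm_undefined_correlation_error"
      )
    }
    stats::cor(xt[, j], xe[, j], method = "spearman")
  }, numeric(1))
  structure(mean(per_state), per_state = per_state)
}

#' Signed relative bias
#'
#' `(est - true) / true`; used for the autoregressive entries of `A`. For a
#' parameter whose true value is 0 (the null cross-regressive condition)
#' relative bias is undefined — use plain bias there.
#'
#' @param est Estimated value.
#' @param true True value (nonzero).
#' @return Relative bias.
#' @export
relative_bias <- function(est, true) {
  if (any(true == 0)) {
    rlang::abort("`true` = 0: relative bias undefined; use bias (est - true) instead.",
      class = "ordssm_parameter_error"
    )
  }
  (est - true) / true
}

analysis_model <- function(cond, model_kind, estimate_measurement) {
  truth_model <- condition_measurement(cond)
  if (model_kind == "grm") {
    if (!estimate_measurement) return(truth_model)
    # initial thresholds: first at -2, intervals of .36
    items <- lapply(truth_model$items, function(it) {
      grm_item(it$item_id, it$state_index,
        beta = -2 + 0.36 * (seq_len(it$J - 1L) - 1L), alpha = 1
      )
    })
    measurement_model(items, p = truth_model$p)
  } else {
    items <- lapply(truth_model$items, function(it) {
      linear_item(it$item_id, it$state_index, loading = 1, error_var = 1)
    })
    measurement_model(items, p = truth_model$p)
  }
}

#' Run replicated fits for one simulation condition
#'
#' For each replicate: generate a dataset under the condition, fit it by
#' MIF2 (graded response or linear-approximation measurement), and record
#' the study outcomes — average Spearman state recovery, signed relative
#' bias of both autoregressive entries, bias of the cross-regressive entry,
#' and (optionally) 95%/99.8% Wald coverage from slice-likelihood SEs.
#' Fits use the standard initial values: `A = diag(.1, 2)`; GRM thresholds
#' starting at -2 with intervals .36; linear loadings 1 and error variances
#' 1, items centered at their sample means.
#'
#' @param cond A [sim_condition()]; its `replicate_seed` seeds replicate 1,
#'   later replicates use [condition_seed()] offsets.
#' @param n_replicates Number of replicate datasets.
#' @param config An [mif2_config()] (its `estimate_measurement` flag decides
#'   whether GRM thresholds / linear measurement parameters are estimated).
#' @param model_kind `"grm"` or `"linear"`.
#' @param coverage Compute slice-likelihood SEs and Wald coverage of the
#'   `A` entries (slower).
#' @param spec [slice_spec()] used when `coverage = TRUE`.
#' @return Tibble with one row per replicate (class `ordssm_outcomes`);
#'   failed replicates are kept with `failed = TRUE` and a reason.
#' @export
run_condition <- function(cond, n_replicates, config = mif2_preset("desk"),
                          model_kind = c("grm", "linear"), coverage = FALSE,
                          spec = slice_spec()) {
  model_kind <- match.arg(model_kind)
  stopifnot(inherits(cond, "sim_condition"), n_replicates >= 0)
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    rows[[r]] <- run_one_replicate(cond, r, config, model_kind, coverage, spec)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ordssm_outcomes", class(out))
  out
}

run_one_replicate <- function(cond, replicate, config, model_kind, coverage, spec) {
  cond_r <- cond
  cond_r$replicate_seed <- condition_seed(replicate, 1L, cond$replicate_seed)
  ds <- make_condition_dataset(cond_r)
  fit_config <- config
  fit_config$seed <- condition_seed(replicate, 2L, cond$replicate_seed)
  amod <- analysis_model(cond_r, model_kind, config$estimate_measurement)
  t0 <- proc.time()[["elapsed"]]
  base <- tibble::tibble(
    T = cond$T, items_per_state = cond$items_per_state, J = cond$J,
    AR = cond$AR, CR = cond$CR, thresholds = cond$thresholds,
    replicate = replicate, model_kind = model_kind
  )
  res <- tryCatch(
    {
      fit <- mif2_fit(ds$observations, amod, fit_config)
      truth <- ds$truth$A
      rho <- spearman_state_recovery(
        ds$trajectory$states, fit$final_filter$filtered_means[-1]
      )
      rec <- dplyr::mutate(base,
        spearman_recovery = as.numeric(rho),
        rel_bias_AR1 = relative_bias(fit$A[1, 1], truth[1, 1]),
        rel_bias_AR2 = relative_bias(fit$A[2, 2], truth[2, 2]),
        bias_CR = fit$A[1, 2] - truth[1, 2],
        est_A11 = fit$A[1, 1], est_A22 = fit$A[2, 2],
        est_A12 = fit$A[1, 2], est_A21 = fit$A[2, 1],
        failed = FALSE, failure_reason = NA_character_
      )
      if (coverage) {
        se_tbl <- slice_se(fit, ds$observations, spec = spec)
        truth_by_term <- c(
          "A[1,1]" = truth[1, 1], "A[2,1]" = truth[2, 1],
          "A[1,2]" = truth[1, 2], "A[2,2]" = truth[2, 2]
        )
        cov95 <- se_tbl$conf.low <= truth_by_term[se_tbl$term] &
          truth_by_term[se_tbl$term] <= se_tbl$conf.high
        cov998 <- se_tbl$conf.low.998 <= truth_by_term[se_tbl$term] &
          truth_by_term[se_tbl$term] <= se_tbl$conf.high.998
        names(cov95) <- se_tbl$term
        names(cov998) <- se_tbl$term
        rec <- dplyr::mutate(rec,
          covered95_AR1 = cov95[["A[1,1]"]], covered95_AR2 = cov95[["A[2,2]"]],
          covered95_CR = cov95[["A[1,2]"]],
          covered998_AR1 = cov998[["A[1,1]"]], covered998_AR2 = cov998[["A[2,2]"]],
          covered998_CR = cov998[["A[1,2]"]],
          se_AR1 = se_tbl$std.error[se_tbl$term == "A[1,1]"],
          se_AR2 = se_tbl$std.error[se_tbl$term == "A[2,2]"],
          se_CR = se_tbl$std.error[se_tbl$term == "A[1,2]"]
        )
      }
      rec
    },
    error = function(e) {
      dplyr::mutate(base,
        spearman_recovery = NA_real_, rel_bias_AR1 = NA_real_,
        rel_bias_AR2 = NA_real_, bias_CR = NA_real_,
        est_A11 = NA_real_, est_A22 = NA_real_, est_A12 = NA_real_,
        est_A21 = NA_real_,
        failed = TRUE, failure_reason = conditionMessage(e)
      )
    }
  )
  dplyr::mutate(res, runtime = proc.time()[["elapsed"]] - t0)
}

#' Aggregate replicate outcomes into condition summaries
#'
#' Medians and interquartile ranges of the recovery and bias outcomes, plus
#' coverage proportions when present, per condition and model kind.
#'
#' @param records Outcome tibble from [run_condition()] (rows from several
#'   conditions/model kinds may be bound together).
#' @return Summary tibble, one row per condition x model kind.
#' @export
aggregate_outcomes <- function(records) {
  if (nrow(records) == 0L) {
    rlang::abort("No outcome records to aggregate.", class = "ordssm_parameter_error")
  }
  med_iqr <- function(x) {
    x <- x[!is.na(x)]
    list(median = stats::median(x), iqr = stats::IQR(x))
  }
  grp <- dplyr::group_by(
    records, .data$T, .data$items_per_state, .data$J, .data$AR, .data$CR,
    .data$thresholds, .data$model_kind
  )
  out <- dplyr::summarise(grp,
    n = dplyr::n(),
    n_failed = sum(.data$failed),
    median_recovery = stats::median(.data$spearman_recovery, na.rm = TRUE),
    iqr_recovery = stats::IQR(.data$spearman_recovery, na.rm = TRUE),
    median_rel_bias_AR = stats::median(
      c(.data$rel_bias_AR1, .data$rel_bias_AR2), na.rm = TRUE
    ),
    median_bias_CR = stats::median(.data$bias_CR, na.rm = TRUE),
    coverage95_AR = if ("covered95_AR1" %in% names(records)) {
      mean(c(.data$covered95_AR1, .data$covered95_AR2), na.rm = TRUE)
    } else NA_real_,
    coverage95_CR = if ("covered95_CR" %in% names(records)) {
      mean(.data$covered95_CR, na.rm = TRUE)
    } else NA_real_,
    coverage998_AR = if ("covered998_AR1" %in% names(records)) {
      mean(c(.data$covered998_AR1, .data$covered998_AR2), na.rm = TRUE)
    } else NA_real_,
    .groups = "drop"
  )
  out
}

#' Posterior-predictive item mean squared error
#'
#' Goodness of fit at the item level: compute the filtered expected state
#' trajectory under the fitted parameters, simulate `n_sims` measurement
#' time series conditional on that trajectory, and score each simulated
#' series against the observed data by per-item mean squared error (for
#' graded response items, on the integer category scale). Comparable across
#' measurement kinds.
#'
#' @param data Observed table.
#' @param model Fitted `measurement_model`.
#' @param A Fitted transition matrix.
#' @param n_sims Number of simulated series (>= 1).
#' @param seed Optional integer seed.
#' @param K Particles for the filtering pass.
#' @return Tibble with `item_id`, `mse_mean`, `mse_sd`.
#' @export
posterior_predictive_item_mse <- function(data, model, A, n_sims = 1000,
                                          seed = NULL, K = 1000) {
  stopifnot(n_sims >= 1)
  if (!is.null(seed)) set.seed(seed)
  flt <- particle_filter(data, A, model, K = K)
  xhat <- state_matrix(flt$filtered_means[-1])
  y <- obs_matrix(data, model)
  mse <- matrix(NA_real_, n_sims, model$q)
  for (s in seq_len(n_sims)) {
    ysim <- simulate_measurements(xhat, model, seed = NULL)
    ysim <- as.matrix(ysim[, -1])
    mse[s, ] <- colMeans((ysim - y)^2, na.rm = TRUE)
  }
  tibble::tibble(
    item_id = model$item_ids,
    mse_mean = colMeans(mse),
    mse_sd = apply(mse, 2, stats::sd)
  )
}
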