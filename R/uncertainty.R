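#' Slice-likelihood evaluation settings
#'
#' A slice fixes every parameter at the MLE except one, evaluates replicated
#' particle-filter log-likelihoods on a symmetric grid around the estimate,
#' and summarizes the curvature with a quadratic fit. Replicates share seeds
#' across grid points (common random numbers) so only the sliced parameter
#' varies.
#'
#' @param half_width Half-span of the grid around the estimate. Default
#'   (NULL): 5 times the final cooled perturbation SD of the fit.
#' @param n_points Number of grid points (odd, >= 5).
#' @param n_reps Particle-filter replicates per grid point.
#' @param K Particles per evaluation (default: the fit's particle count).
#' @param seed Optional integer seed.
#' @return A list of class `slice_spec`.
#' @export
slice_spec <- function(half_width = NULL, n_points = 11L, n_reps = 3L,
                       K = NULL, seed = NULL) {
  n_points <- as.integer(n_points)
  if (n_points < 5L || n_points %% 2L == 0L) {
    rlang::abort("`n_points` must be an odd integer >= 5.",
      class = "ordssm_parameter_error"
    )
  }
  stopifnot(is.null(half_width) || half_width > 0, n_reps >= 1)
  structure(
    list(half_width = half_width, n_points = n_points,
         n_reps = as.integer(n_reps), K = K, seed = seed),
    class = "slice_spec"
  )
}

# Log-likelihood of the data at a template-shaped parameter vector.
eval_loglik <- function(theta, data, model, estimate_measurement,
                        backend = "particle", K = 1000, seed = NULL) {
  dec <- decode_into_model(theta, model, estimate_measurement)
  if (!is_feasible(dec$A)) return(NA_real_)
  if (backend == "kalman") {
    kalman_filter(data, dec$A, model = dec$model)$loglik
  } else {
    particle_filter(data, dec$A, dec$model, K = K, seed = seed)$loglik
  }
}

#' Evaluate a likelihood slice along one parameter
#'
#' @param data Observation table.
#' @param model A `measurement_model` (parameter values at the estimate).
#' @param estimate Named parameter vector on the estimation scale (e.g.
#'   `fit$estimate`).
#' @param param Name (or index) of the parameter to slice.
#' @param spec A [slice_spec()]; `half_width` must be set here or via `...`.
#' @param estimate_measurement Does `estimate` include measurement
#'   parameters (matching the fit's layout)?
#' @param backend `"particle"` (default) or `"kalman"` (exact; linear models
#'   only, used as an oracle).
#' @return Tibble of class `ordssm_slice`: one row per (grid point,
#'   replicate) with `theta`, `rep`, `loglik`; infeasible grid points are
#'   dropped with a warning.
#' @export
slice_loglik <- function(data, model, estimate, param, spec = slice_spec(),
                         estimate_measurement = FALSE,
                         backend = c("particle", "kalman")) {
  backend <- match.arg(backend)
  stopifnot(inherits(spec, "slice_spec"))
  if (is.null(spec$half_width)) {
    rlang::abort("`spec$half_width` must be set (e.g. via slice_se()).",
      class = "ordssm_parameter_error"
    )
  }
  if (is.character(param)) param <- match(param, names(estimate))
  stopifnot(!is.na(param), param >= 1, param <= length(estimate))
  K <- spec$K %||% 1000L
  if (!is.null(spec$seed)) set.seed(spec$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_reps)
  grid <- estimate[param] + seq(-spec$half_width, spec$half_width,
    length.out = spec$n_points
  )
  rows <- list()
  n_dropped <- 0L
  for (g in grid) {
    theta <- estimate
    theta[param] <- g
    lls <- vapply(seq_len(spec$n_reps), function(r) {
      eval_loglik(theta, data, model, estimate_measurement,
        backend = backend, K = K, seed = rep_seeds[r]
      )
    }, numeric(1))
    if (anyNA(lls)) {
      n_dropped <- n_dropped + 1L
      next
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      theta = g, rep = seq_len(spec$n_reps), loglik = lls
    )
  }
  if (n_dropped > 0L) {
    rlang::warn(sprintf("%d infeasible grid points dropped from the slice.", n_dropped))
  }
  out <- dplyr::bind_rows(rows)
  if (length(unique(out$theta)) < 5L) {
    rlang::abort("Fewer than 5 feasible slice points.", class = "ordssm_slice_error")
  }
  class(out) <- c("ordssm_slice", class(out))
  out
}

#' Curvature and standard error from a quadratic slice fit
#'
#' Least-squares fit of `loglik ~ a + b theta + c theta^2` to the slice;
#' under local asymptotic normality the negative curvature `-2c`
#' approximates the (per-parameter, diagonal) Fisher information, giving
#' `se = (-2c)^(-1/2)`. A convex or flat fit signals an (empirically)
#' under-identified parameter and raises an error rather than returning a
#' bogus SE.
#'
#' @param grid Tibble with columns `theta` and `loglik` (replicates allowed;
#'   the regression pools them).
#' @return List with `curvature` (`2c`, negative) and `se`.
#' @export
quadratic_curvature <- function(grid) {
  stopifnot(all(c("theta", "loglik") %in% names(grid)))
  if (length(unique(grid$theta)) < 5L) {
    rlang::abort("Need at least 5 distinct slice points.", class = "ordssm_slice_error")
  }
  fit <- stats::lm(loglik ~ theta + I(theta^2), data = grid)
  cc <- stats::coef(fit)[[3]]
  if (!is.finite(cc) || cc >= 0) {
    rlang::abort(
      "Slice is flat or convex at the estimate (under-identified parameter); no SE available.",
      class = "ordssm_curvature_error"
    )
  }
  list(curvature = 2 * cc, se = (-2 * cc)^(-0.5))
}

#' Wald confidence interval
#'
#' `estimate +/- z * se` with z = 1.96 at the 95% level and z = 3.09 at the
#' 99.8% level (the stricter interval recommended with liberal slice SEs,
#' which empirically restores roughly nominal 95% coverage).
#'
#' @param estimate Point estimate.
#' @param se Positive standard error.
#' @param level 0.95 or 0.998 (other levels use `qnorm`).
#' @return Numeric vector `c(lower, upper)`.
#' @export
wald_ci <- function(estimate, se, level = 0.95) {
  stopifnot(se > 0)
  z <- if (isTRUE(all.equal(level, 0.95))) {
    1.96
  } else if (isTRUE(all.equal(level, 0.998))) {
    3.09
  } else {
    stats::qnorm((1 + level) / 2)
  }
  c(estimate - z * se, estimate + z * se)
}

#' Slice-likelihood standard errors for a fit
#'
#' Slices each requested parameter of an [mif2_fit()] around the averaged
#' estimate, fits the quadratic, and returns per-parameter standard errors
#' with 95% and 99.8% Wald intervals. These SEs use each parameter's own
#' slice only (a diagonal information approximation) and are known to be
#' liberal; prefer the 99.8% intervals for inference.
#'
#' @param fit An `ordssm_fit`.
#' @param data The observation table the model was fit to.
#' @param params Character vector of parameter names to slice (default: the
#'   entries of `A`).
#' @param spec A [slice_spec()]; a NULL `half_width` defaults to 5 times the
#'   fit's final cooled perturbation SD.
#' @return Tibble with `term`, `estimate`, `std.error`, `curvature`, and
#'   the Wald bounds `conf.low`/`conf.high` (95%) and `conf.low.998`/
#'   `conf.high.998`. Parameters whose slice is flat get NA SEs with a
#'   warning.
#' @export
slice_se <- function(fit, data, params = NULL, spec = slice_spec()) {
  stopifnot(inherits(fit, "ordssm_fit"))
  if (is.null(params)) {
    params <- grep("^A\\[", names(fit$estimate), value = TRUE)
  }
  if (is.null(spec$half_width)) {
    base_sd <- max(rep_len(fit$config$perturb_sd, length(fit$estimate)))
    spec$half_width <- 5 * cooling_sd(
      fit$config$iterations, base_sd,
      fit$config$cooling_fraction_50, fit$config$cooling_on_sd
    )
  }
  if (is.null(spec$K)) spec$K <- fit$config$particles
  rows <- lapply(params, function(pm) {
    est <- fit$estimate[[pm]]
    res <- tryCatch(
      {
        sl <- slice_loglik(
          data, fit$model, fit$estimate, pm,
          spec = spec, estimate_measurement = FALSE
        )
        qc <- quadratic_curvature(sl)
        ci95 <- wald_ci(est, qc$se, 0.95)
        ci998 <- wald_ci(est, qc$se, 0.998)
        tibble::tibble(
          term = pm, estimate = est, std.error = qc$se,
          curvature = qc$curvature,
          conf.low = ci95[1], conf.high = ci95[2],
          conf.low.998 = ci998[1], conf.high.998 = ci998[2]
        )
      },
      ordssm_curvature_error = function(e) {
        rlang::warn(sprintf("Parameter '%s': %s", pm, conditionMessage(e)))
        tibble::tibble(
          term = pm, estimate = est, std.error = NA_real_,
          curvature = NA_real_, conf.low = NA_real_, conf.high = NA_real_,
          conf.low.998 = NA_real_, conf.high.998 = NA_real_
        )
      }
    )
    res
  })
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
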