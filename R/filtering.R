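#' Resample particle indices from log-weights
#'
#' Systematic resampling (the default; one uniform draw per call, lower
#' Monte Carlo variance) or plain multinomial resampling with replacement.
#' With exactly equal weights the systematic scheme returns every index
#' once.
#'
#' @param log_weights Numeric vector of unnormalized log-weights; `-Inf`
#'   marks an impossible particle.
#' @param K Number of indices to draw (default: one per particle).
#' @param scheme `"systematic"` or `"multinomial"`.
#' @return Integer vector of length `K` of resampled particle indices.
#' @export
resample <- function(log_weights, K = length(log_weights),
                     scheme = c("systematic", "multinomial")) {
  scheme <- match.arg(scheme)
  mx <- max(log_weights)
  if (mx == -Inf) {
    rlang::abort("All log-weights are -Inf: particle degeneracy.",
      class = "ordssm_degeneracy_error"
    )
  }
  w <- exp(log_weights - mx)
  w <- w / sum(w)
  if (scheme == "multinomial") {
    return(sample.int(length(w), K, replace = TRUE, prob = w))
  }
  u <- stats::runif(1)
  targets <- (seq_len(K) - 1 + u) / K
  findInterval(targets, cumsum(w), left.open = TRUE) + 1L
}

# Extract the T x q observation matrix in model item order; validates
# GRM categories against each item's J.
obs_matrix <- function(data, model) {
  stopifnot(inherits(model, "measurement_model"))
  if (inherits(data, "latent_trajectory")) {
    rlang::abort("`data` must be an observation table, not a trajectory.")
  }
  df <- as.data.frame(data)
  missing_cols <- setdiff(model$item_ids, names(df))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0("Observation table lacks item columns: ",
             paste(missing_cols, collapse = ", ")),
      class = "ordssm_schema_error"
    )
  }
  y <- as.matrix(df[model$item_ids])
  storage.mode(y) <- "double"
  if (model$kind == "grm") {
    for (i in seq_len(model$q)) {
      it <- model$items[[i]]
      yi <- y[, i]
      bad <- which(!is.na(yi) & (yi < 1 | yi > it$J | yi != round(yi)))
      if (length(bad) > 0) {
        rlang::abort(
          sprintf("Item '%s': category %s at row %d outside 1..%d.",
                  it$item_id, format(yi[bad[1]]), bad[1], it$J),
          class = "ordssm_data_error"
        )
      }
    }
  }
  y
}

draw_seed <- function(seed = NULL) {
  if (!is.null(seed)) return(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, 1L)
}

new_filter_output <- function(fm, loglik, ess, p, K = NA_integer_) {
  colnames(fm) <- paste0("x", seq_len(p))
  structure(
    list(
      filtered_means = dplyr::bind_cols(
        tibble::tibble(time = seq_len(nrow(fm))), tibble::as_tibble(fm)
      ),
      loglik = loglik, ess = ess, K = K
    ),
    class = "filter_output"
  )
}

#' @export
print.filter_output <- function(x, ...) {
  cat(sprintf(
    "<filter_output> T = %d, loglik = %.3f, min ESS = %.1f\n",
    nrow(x$filtered_means), x$loglik,
    if (all(is.na(x$ess))) NA_real_ else min(x$ess)
  ))
  invisible(x)
}

#' Bootstrap particle filter
#'
#' Sequential importance resampling for the latent VAR(1) model with a
#' graded response or linear-Gaussian measurement model. Particles start
#' from `f0 = N(0, I)`, propagate through `N(A x, Sigma)` with the
#' identification-implied innovation covariance, are weighted by the
#' measurement likelihood, and are resampled at every timepoint. Filtered
#' means are the pre-resampling weighted particle averages, and the
#' log-likelihood estimate accumulates the per-timepoint log-mean-weights.
#'
#' @param data Observation table (tibble/data frame with one column per
#'   item; an optional `time` column is ignored).
#' @param A Stationary, feasible transition matrix.
#' @param model A `measurement_model`.
#' @param K Number of particles (>= 2).
#' @param seed Optional integer seed (otherwise drawn from the session RNG).
#' @param scheme Resampling scheme, `"systematic"` (default) or
#'   `"multinomial"`.
#' @param covs Optional `ordssm_covs` to reuse a precomputed identification
#'   solve.
#' @param sigma_zero Development hook: propagate with zero innovation noise.
#' @return A `filter_output`: `filtered_means` tibble (time, x1..xp),
#'   `loglik`, per-timepoint `ess`.
#' @export
particle_filter <- function(data, A, model, K = 1000, seed = NULL,
                            scheme = c("systematic", "multinomial"),
                            covs = NULL, sigma_zero = FALSE) {
  scheme <- match.arg(scheme)
  A <- as_dyn_matrix(A)
  stopifnot(K >= 2)
  if (is.null(covs)) covs <- identify_innovations(A)
  y <- obs_matrix(data, model)
  ma <- meas_cpp_args(model)
  res <- pf_cpp(
    y, ma$kind, ma$state_idx, ma$alpha, ma$beta, ma$beta_ptr,
    ma$loading, ma$error_var, ma$center, A, diag(covs$Sigma),
    as.integer(K), draw_seed(seed),
    scheme = if (scheme == "systematic") 0L else 1L,
    sigma_zero = sigma_zero
  )
  new_filter_output(res$filtered_means, res$loglik, as.numeric(res$ess),
                    p = nrow(A), K = as.integer(K))
}

#' Exact Kalman filter for the linear-Gaussian comparator
#'
#' Prediction-error-decomposition filtering for the linear measurement
#' model, with the same initial condition as the particle filter
#' (`x0 ~ N(0, I)` before the first propagation). Missing observations are
#' handled by dropping the corresponding rows of the loading matrix at that
#' timepoint. Serves as the exact-likelihood oracle for the particle filter
#' and as the backend for linear slice likelihoods.
#'
#' @param data Observation table.
#' @param A Stationary transition matrix.
#' @param covs Optional `ordssm_covs` (defaults to [identify_innovations()]).
#' @param model A `measurement_model` of kind `"linear"`.
#' @return A `filter_output` with exact `filtered_means` and `loglik`
#'   (`ess` is `NA`; also carries `filtered_vars`, the T x p filtered state
#'   variances).
#' @export
kalman_filter <- function(data, A, covs = NULL, model) {
  A <- as_dyn_matrix(A)
  stopifnot(inherits(model, "measurement_model"), model$kind == "linear")
  if (is.null(covs)) covs <- identify_innovations(A)
  y <- obs_matrix(data, model)
  y <- sweep(y, 2, model$center)
  p <- nrow(A)
  q <- model$q
  C <- matrix(0, q, p)
  for (i in seq_len(q)) C[i, model$items[[i]]$state_index] <- model$items[[i]]$loading
  Psi <- diag(vapply(model$items, `[[`, numeric(1), "error_var"), q)
  Sigma <- covs$Sigma
  T <- nrow(y)
  a <- rep(0, p)
  P <- diag(p)  # matches the particle filter's f0 = N(0, I)
  fm <- matrix(0, T, p)
  fv <- matrix(0, T, p)
  loglik <- 0
  for (t in seq_len(T)) {
    a <- drop(A %*% a)
    P <- A %*% P %*% t(A) + Sigma
    obs <- which(!is.na(y[t, ]))
    if (length(obs) > 0) {
      Ct <- C[obs, , drop = FALSE]
      v <- y[t, obs] - drop(Ct %*% a)
      Ft <- Ct %*% P %*% t(Ct) + Psi[obs, obs, drop = FALSE]
      Ft <- (Ft + t(Ft)) / 2
      ch <- tryCatch(chol(Ft), error = function(e) {
        rlang::abort("Non-positive-definite innovation covariance in the Kalman filter.",
          class = "ordssm_numerical_error", parent = e
        )
      })
      logdet <- 2 * sum(log(diag(ch)))
      z <- backsolve(ch, v, transpose = TRUE)
      loglik <- loglik - 0.5 * (length(obs) * log(2 * pi) + logdet + sum(z^2))
      Kt <- P %*% t(Ct) %*% chol2inv(ch)
      a <- a + drop(Kt %*% v)
      P <- P - Kt %*% Ct %*% P
      P <- (P + t(P)) / 2
    }
    fm[t, ] <- a
    fv[t, ] <- diag(P)
  }
  out <- new_filter_output(fm, loglik, rep(NA_real_, T), p = p)
  out$filtered_vars <- fv
  out
}

#' @rdname as_tibble.latent_trajectory
#' @export
as_tibble.filter_output <- function(x, ...) x$filtered_means

#' Plot filtered state trajectories
#'
#' @param object A `filter_output`.
#' @param ... Unused.
#' @return A ggplot of the filtered state means over time.
#' @export
autoplot.filter_output <- function(object, ...) {
  long <- tidyr::pivot_longer(object$filtered_means, -"time",
    names_to = "state", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~state, ncol = 1) +
    ggplot2::labs(x = "time", y = "filtered state mean")
}
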