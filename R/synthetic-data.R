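#' Equal-threshold construction
#'
#' Thresholds for an item with J response categories built by centering the
#' integer sequence 1..(J-1) on zero: consecutive unit spacing, mean zero.
#' Every item in the "equal" design shares this set, i.e. identical
#' measurement properties across items.
#'
#' @param J Number of response categories (>= 2).
#' @return Increasing numeric vector of length J-1.
#' @examples
#' equal_thresholds(7) # -2.5 -1.5 -0.5 0.5 1.5 2.5
#' @export
equal_thresholds <- function(J) {
  J <- as.integer(J)
  if (is.na(J) || J < 2L) {
    rlang::abort("`J` must be an integer >= 2.", class = "ordssm_parameter_error")
  }
  s <- seq_len(J - 1L)
  s - mean(s)
}

#' Offset-threshold construction
#'
#' Items within a state get mutually shifted copies of the equal-threshold
#' set, emulating a scale whose items were written to cover different
#' regions of the latent continuum. The shift between adjacent items is
#' `min(n_items / (J - 1), 1.25)` and the whole collection is symmetric
#' about zero.
#'
#' @param n_items Number of items sharing a state (>= 1).
#' @param J Number of response categories per item (>= 2).
#' @return List of `n_items` increasing threshold vectors.
#' @examples
#' offset_thresholds(3, 7)
#' @export
offset_thresholds <- function(n_items, J) {
  n_items <- as.integer(n_items)
  if (is.na(n_items) || n_items < 1L) {
    rlang::abort("`n_items` must be an integer >= 1.", class = "ordssm_parameter_error")
  }
  base <- equal_thresholds(J)
  off <- min(n_items / (J - 1), 1.25)
  lapply(seq_len(n_items), function(k) base + (k - (n_items + 1) / 2) * off)
}

#' Simulation condition
#'
#' One cell of the synthetic-study design: two latent states with
#' transition matrix `[[AR, CR], [0, AR]]`, `items_per_state` graded
#' response items per state (identical item sets for both states, alpha = 1),
#' and thresholds built by [equal_thresholds()] or [offset_thresholds()].
#'
#' @param T Number of timepoints (the study grid uses 100 and 500).
#' @param items_per_state Items per latent state (grid: 3 or 6).
#' @param J Response categories per item (grid: 3 or 7).
#' @param AR Autoregressive coefficient (grid: .3 or .7).
#' @param CR Cross-regressive coefficient of state 1 on state 2 (grid: 0 or .25).
#' @param thresholds `"equal"` or `"offset"`.
#' @param replicate_seed Integer seed for this replicate.
#' @return A list of class `sim_condition`.
#' @export
sim_condition <- function(T = 100L, items_per_state = 3L, J = 3L,
                          AR = 0.3, CR = 0, thresholds = c("equal", "offset"),
                          replicate_seed = 1L) {
  thresholds <- match.arg(thresholds)
  stopifnot(T >= 2L, items_per_state >= 1L, J >= 2L)
  structure(
    list(
      T = as.integer(T), items_per_state = as.integer(items_per_state),
      J = as.integer(J), AR = AR, CR = CR, thresholds = thresholds,
      replicate_seed = as.integer(replicate_seed)
    ),
    class = "sim_condition"
  )
}

#' The fully crossed condition grid
#'
#' All 64 combinations of timepoints (100, 500), items per state (3, 6),
#' response categories (3, 7), AR (.3, .7), CR (0, .25) and threshold design
#' (equal, offset).
#'
#' @return A 64-row tibble, one condition per row, with a `condition_id` key.
#' @export
condition_grid <- function() {
  g <- tidyr::expand_grid(
    T = c(100L, 500L), items_per_state = c(3L, 6L), J = c(3L, 7L),
    AR = c(0.3, 0.7), CR = c(0, 0.25), thresholds = c("equal", "offset")
  )
  dplyr::mutate(g, condition_id = dplyr::row_number(), .before = 1)
}

#' Deterministic seed for a (condition, replicate) pair
#'
#' A pure function of its arguments, so a whole study is re-runnable
#' bit-identically from a manifest.
#'
#' @param condition_id Integer condition key.
#' @param replicate Integer replicate number.
#' @param base_seed Integer study-level seed.
#' @return An integer seed below 2^31.
#' @export
condition_seed <- function(condition_id, replicate, base_seed = 1L) {
  as.integer((as.double(base_seed) + 104729 * as.double(condition_id) +
    7919 * as.double(replicate)) %% 2147483629)
}

#' Simulate a stationary latent VAR(1) trajectory
#'
#' Draws `x_1 ~ N(0, Gamma)` (exact stationarity, no burn-in) and iterates
#' `x_{t+1} = A x_t + eps_t`, `eps_t ~ N(0, Sigma)`, with (`Gamma`, `Sigma`)
#' implied by the unit-variance identification constraint.
#'
#' @param A Stationary, feasible transition matrix.
#' @param T Number of timepoints.
#' @param seed Optional integer seed (omit to draw from the session RNG).
#' @return A list of class `latent_trajectory` with `states` (T x p matrix),
#'   `A`, `covs` and `seed`.
#' @export
simulate_states <- function(A, T, seed = NULL) {
  A <- as_dyn_matrix(A)
  covs <- identify_innovations(A)
  if (!is.null(seed)) set.seed(seed)
  p <- nrow(A)
  T <- as.integer(T)
  L <- chol(covs$Gamma)
  sds <- sqrt(diag(covs$Sigma))
  x <- matrix(0, T, p)
  x[1, ] <- drop(crossprod(L, stats::rnorm(p)))
  if (T > 1L) {
    eps <- matrix(stats::rnorm((T - 1L) * p), T - 1L, p) *
      matrix(sds, T - 1L, p, byrow = TRUE)
    for (t in 2:T) {
      x[t, ] <- A %*% x[t - 1L, ] + eps[t - 1L, ]
    }
  }
  structure(
    list(states = x, A = A, covs = covs, seed = seed),
    class = "latent_trajectory"
  )
}

#' @export
print.latent_trajectory <- function(x, ...) {
  cat(sprintf(
    "<latent_trajectory> T = %d, p = %d states\n", nrow(x$states), ncol(x$states)
  ))
  invisible(x)
}

#' Coerce a latent trajectory to a tibble
#'
#' @param x A `latent_trajectory`.
#' @param ... Unused.
#' @return Tibble with a `time` column and one column per state (`x1`, ...).
#' @export
as_tibble.latent_trajectory <- function(x, ...) {
  m <- x$states
  colnames(m) <- paste0("x", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(time = seq_len(nrow(m))), tibble::as_tibble(m))
}

state_matrix <- function(traj) {
  if (inherits(traj, "latent_trajectory")) return(traj$states)
  if (is.data.frame(traj)) {
    return(as.matrix(traj[setdiff(names(traj), "time")]))
  }
  as.matrix(traj)
}

#' Simulate measurements from a latent trajectory
#'
#' GRM items draw categories from [category_probs()] by inverse-CDF on the
#' exceedance curves; linear items add `N(0, error_var)` noise to
#' `center + loading * x`.
#'
#' @param traj A `latent_trajectory`, or a T x p matrix / tibble of state
#'   values (e.g. a filtered trajectory for posterior-predictive checks).
#' @param model A `measurement_model`.
#' @param seed Optional integer seed.
#' @return Tibble with a `time` column and one column per item.
#' @export
simulate_measurements <- function(traj, model, seed = NULL) {
  stopifnot(inherits(model, "measurement_model"))
  if (!is.null(seed)) set.seed(seed)
  x <- state_matrix(traj)
  T <- nrow(x)
  stopifnot(ncol(x) >= model$p)
  out <- matrix(NA_real_, T, model$q)
  for (i in seq_len(model$q)) {
    it <- model$items[[i]]
    xi <- x[, it$state_index]
    if (model$kind == "grm") {
      u <- stats::runif(T)
      y <- rep(1L, T)
      for (j in seq_along(it$beta)) {
        y <- y + (u < stats::plogis(it$alpha * (xi - it$beta[[j]])))
      }
      out[, i] <- y
    } else {
      out[, i] <- model$center[[i]] + it$loading * xi +
        stats::rnorm(T, 0, sqrt(it$error_var))
    }
  }
  colnames(out) <- model$item_ids
  dplyr::bind_cols(tibble::tibble(time = seq_len(T)), tibble::as_tibble(out))
}

#' Measurement model of a simulation condition
#'
#' Builds the graded response item set a [sim_condition()] prescribes:
#' `items_per_state` items per state, alpha = 1, identical sets on both
#' states, thresholds per the equal/offset rule.
#'
#' @param cond A `sim_condition`.
#' @return A `measurement_model` of kind `"grm"` with p = 2.
#' @export
condition_measurement <- function(cond) {
  stopifnot(inherits(cond, "sim_condition"))
  beta_sets <- switch(cond$thresholds,
    equal = rep(list(equal_thresholds(cond$J)), cond$items_per_state),
    offset = offset_thresholds(cond$items_per_state, cond$J)
  )
  items <- list()
  for (s in 1:2) {
    for (k in seq_len(cond$items_per_state)) {
      items[[length(items) + 1L]] <- grm_item(
        item_id = sprintf("s%d_i%d", s, k), state_index = s,
        beta = beta_sets[[k]], alpha = 1
      )
    }
  }
  measurement_model(items, p = 2L)
}

#' Transition matrix of a simulation condition
#'
#' @param cond A `sim_condition`.
#' @return The 2 x 2 matrix `[[AR, CR], [0, AR]]`.
#' @export
condition_dynamics <- function(cond) {
  matrix(c(cond$AR, 0, cond$CR, cond$AR), 2, 2)
}

#' Generate one dataset under a simulation condition
#'
#' Simulates the latent trajectory and the graded response observations for
#' one replicate; the whole draw is determined by `cond$replicate_seed`.
#'
#' @param cond A `sim_condition`.
#' @return A list with `trajectory` (`latent_trajectory`), `observations`
#'   (tibble), and `truth` (list: `A`, `Gamma`, `Sigma`, `thresholds`,
#'   `model`).
#' @export
make_condition_dataset <- function(cond) {
  stopifnot(inherits(cond, "sim_condition"))
  A <- condition_dynamics(cond)
  model <- condition_measurement(cond)
  set.seed(cond$replicate_seed)
  traj <- simulate_states(A, cond$T, seed = NULL)
  obs <- simulate_measurements(traj, model, seed = NULL)
  list(
    trajectory = traj,
    observations = obs,
    truth = list(
      A = A, Gamma = traj$covs$Gamma, Sigma = traj$covs$Sigma,
      thresholds = lapply(model$items, `[[`, "beta"), model = model
    )
  )
}
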