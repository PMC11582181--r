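#' Graded response item
#'
#' One ordinal item under the homogeneous-or-not graded response model:
#' the probability of exceeding category j given latent value x is
#' `plogis(alpha * (x - beta_j))`. Each item measures exactly one state
#' (simple structure), indexed by `state_index`.
#'
#' @param item_id Character label, unique within a model.
#' @param state_index Integer in 1..p: which latent state the item measures.
#' @param beta Strictly increasing numeric vector of J-1 thresholds.
#' @param alpha Positive discrimination (default 1, the homogeneous GRM).
#' @return A list of class `grm_item` with fields `item_id`, `state_index`,
#'   `alpha`, `beta`, `J`.
#' @export
grm_item <- function(item_id, state_index, beta, alpha = 1) {
  beta <- as.numeric(beta)
  if (length(beta) < 1L || is.unsorted(beta, strictly = TRUE)) {
    rlang::abort(sprintf("Item '%s': thresholds must be strictly increasing.", item_id),
      class = "ordssm_validation_error"
    )
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    rlang::abort(sprintf("Item '%s': `alpha` must be a positive scalar.", item_id),
      class = "ordssm_validation_error"
    )
  }
  structure(
    list(
      item_id = as.character(item_id), state_index = as.integer(state_index),
      alpha = alpha, beta = beta, J = length(beta) + 1L
    ),
    class = "grm_item"
  )
}

#' Linear-Gaussian item
#'
#' One continuous-measurement item for the linear-approximation comparator:
#' `y = center + loading * x + e`, `e ~ N(0, error_var)`.
#'
#' @param item_id Character label, unique within a model.
#' @param state_index Integer in 1..p.
#' @param loading Real factor loading (entry of the loading matrix C).
#' @param error_var Positive measurement-error variance.
#' @return A list of class `linear_item`.
#' @export
linear_item <- function(item_id, state_index, loading = 1, error_var = 1) {
  if (!is.numeric(error_var) || length(error_var) != 1L || error_var <= 0) {
    rlang::abort(sprintf("Item '%s': `error_var` must be positive.", item_id),
      class = "ordssm_parameter_error"
    )
  }
  structure(
    list(
      item_id = as.character(item_id), state_index = as.integer(state_index),
      loading = as.numeric(loading), error_var = as.numeric(error_var)
    ),
    class = "linear_item"
  )
}

#' Measurement model
#'
#' Bundles a set of items of one kind (`"grm"` or `"linear"`) into the
#' measurement half of the state-space model. For the linear kind, `center`
#' holds per-item offsets subtracted from the data before the loading acts;
#' integer-coded ordinal data have nonzero means while the latent states are
#' mean-zero, so the linear comparator centers each item at its sample mean
#' (set at fit time by [mif2_fit()] unless supplied here).
#'
#' @param items List of [grm_item()] or [linear_item()] objects (a single
#'   item may be passed bare).
#' @param kind `"grm"` or `"linear"`; inferred from the items when omitted.
#' @param center Optional numeric vector of per-item centering offsets
#'   (linear kind only; default 0).
#' @param p Number of latent states; defaults to the largest `state_index`.
#' @return An object of class `measurement_model`.
#' @export
measurement_model <- function(items, kind = NULL, center = NULL, p = NULL) {
  if (inherits(items, "grm_item") || inherits(items, "linear_item")) items <- list(items)
  if (length(items) == 0L) {
    rlang::abort("`items` must contain at least one item.", class = "ordssm_validation_error")
  }
  kinds <- vapply(items, function(it) {
    if (inherits(it, "grm_item")) "grm" else if (inherits(it, "linear_item")) "linear" else NA_character_
  }, character(1))
  if (anyNA(kinds) || length(unique(kinds)) != 1L) {
    rlang::abort("All items must be `grm_item`s or all `linear_item`s.",
      class = "ordssm_validation_error"
    )
  }
  if (is.null(kind)) kind <- kinds[[1]] else stopifnot(kind == kinds[[1]])
  ids <- vapply(items, `[[`, character(1), "item_id")
  if (anyDuplicated(ids)) {
    rlang::abort("Item ids must be unique.", class = "ordssm_validation_error")
  }
  sidx <- vapply(items, `[[`, integer(1), "state_index")
  if (is.null(p)) p <- max(sidx)
  if (any(sidx < 1L | sidx > p)) {
    rlang::abort("Every `state_index` must lie in 1..p.", class = "ordssm_validation_error")
  }
  q <- length(items)
  if (kind == "linear") {
    if (is.null(center)) center <- rep(0, q)
    stopifnot(length(center) == q)
  } else {
    center <- NULL
  }
  structure(
    list(items = items, kind = kind, center = center, p = as.integer(p), q = q,
         item_ids = ids),
    class = "measurement_model"
  )
}

#' @export
print.measurement_model <- function(x, ...) {
  cat(sprintf(
    "<measurement_model> kind = %s, %d items, %d states\n", x$kind, x$q, x$p
  ))
  print(tidy(x), n = x$q)
  invisible(x)
}

#' Tidy a measurement model into an item table
#'
#' @param x A `measurement_model`.
#' @param ... Unused.
#' @return A tibble with one row per item; for the GRM kind `beta` is a
#'   list-column of threshold vectors.
#' @export
tidy.measurement_model <- function(x, ...) {
  if (x$kind == "grm") {
    tibble::tibble(
      item_id = x$item_ids,
      state_index = vapply(x$items, `[[`, integer(1), "state_index"),
      alpha = vapply(x$items, `[[`, numeric(1), "alpha"),
      J = vapply(x$items, `[[`, integer(1), "J"),
      beta = lapply(x$items, `[[`, "beta")
    )
  } else {
    tibble::tibble(
      item_id = x$item_ids,
      state_index = vapply(x$items, `[[`, integer(1), "state_index"),
      loading = vapply(x$items, `[[`, numeric(1), "loading"),
      error_var = vapply(x$items, `[[`, numeric(1), "error_var"),
      center = x$center
    )
  }
}

#' Exceedance probabilities of a graded response item
#'
#' The cumulative ("operating characteristic") curves
#' `P(y > j | x) = plogis(alpha * (x - beta_j))`, j = 1..J-1: strictly
#' decreasing in j, increasing in x.
#'
#' @param item A [grm_item()].
#' @param x Scalar latent value.
#' @return Numeric vector of length J-1.
#' @export
exceedance_probs <- function(item, x) {
  stopifnot(inherits(item, "grm_item"), length(x) == 1L)
  stats::plogis(item$alpha * (x - item$beta))
}

#' Category probabilities of a graded response item
#'
#' Successive differences of the exceedance curves, with `P(y > 0) = 1` and
#' `P(y > J) = 0`; a probability vector over the J ordered categories.
#'
#' @inheritParams exceedance_probs
#' @return Probability vector of length J summing to 1.
#' @export
category_probs <- function(item, x) {
  e <- c(1, exceedance_probs(item, x), 0)
  -diff(e)
}

#' Ordinal (graded response) measurement log-likelihood at one timepoint
#'
#' Sums `log P(y_i = j | x)` over the non-missing items; missing responses
#' contribute nothing (per-item likelihood omission).
#'
#' @param y Integer vector of observed categories (1..J per item), NA = missing.
#' @param x Numeric state vector of length p.
#' @param model A `measurement_model` of kind `"grm"`.
#' @return Scalar log-likelihood.
#' @export
ordinal_loglik <- function(y, x, model) {
  stopifnot(inherits(model, "measurement_model"), model$kind == "grm")
  stopifnot(length(y) == model$q, length(x) == model$p)
  ll <- 0
  for (i in seq_len(model$q)) {
    yi <- y[[i]]
    if (is.na(yi)) next
    it <- model$items[[i]]
    if (yi < 1 || yi > it$J || yi != round(yi)) {
      rlang::abort(
        sprintf("Item '%s': category %s outside 1..%d.", it$item_id, format(yi), it$J),
        class = "ordssm_data_error"
      )
    }
    ll <- ll + log(category_probs(it, x[[it$state_index]])[[yi]])
  }
  ll
}

#' Linear-Gaussian measurement log-likelihood at one timepoint
#'
#' Sum of independent normal log-densities of
#' `y_i - center_i - loading_i * x[state_index_i]` with variance
#' `error_var_i`; missing entries are skipped.
#'
#' @param y Numeric vector of observations, NA = missing.
#' @param x Numeric state vector of length p.
#' @param model A `measurement_model` of kind `"linear"`.
#' @return Scalar log-likelihood.
#' @export
linear_loglik <- function(y, x, model) {
  stopifnot(inherits(model, "measurement_model"), model$kind == "linear")
  stopifnot(length(y) == model$q, length(x) == model$p)
  ll <- 0
  for (i in seq_len(model$q)) {
    yi <- y[[i]]
    if (is.na(yi)) next
    it <- model$items[[i]]
    mu <- model$center[[i]] + it$loading * x[[it$state_index]]
    ll <- ll + stats::dnorm(yi, mu, sqrt(it$error_var), log = TRUE)
  }
  ll
}

# Marshal a measurement model into the flat vectors the C++ backend takes.
meas_cpp_args <- function(model) {
  if (model$kind == "grm") {
    beta_list <- lapply(model$items, `[[`, "beta")
    nb <- vapply(beta_list, length, integer(1))
    list(
      kind = 0L,
      state_idx = vapply(model$items, `[[`, integer(1), "state_index") - 1L,
      alpha = vapply(model$items, `[[`, numeric(1), "alpha"),
      beta = as.numeric(unlist(beta_list)),
      beta_ptr = c(0L, cumsum(nb)),
      loading = numeric(0), error_var = numeric(0), center = numeric(0)
    )
  } else {
    list(
      kind = 1L,
      state_idx = vapply(model$items, `[[`, integer(1), "state_index") - 1L,
      alpha = numeric(0), beta = numeric(0),
      beta_ptr = integer(0),
      loading = vapply(model$items, `[[`, numeric(1), "loading"),
      error_var = vapply(model$items, `[[`, numeric(1), "error_var"),
      center = model$center
    )
  }
}
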