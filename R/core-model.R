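#' Check stationarity of a VAR(1) transition matrix
#'
#' A latent VAR(1) process `x_{t+1} = A x_t + eps_t` is (covariance)
#' stationary when the spectral radius of `A` is strictly below one; only
#' then does the marginal state covariance exist, which the identification
#' constraint relies on.
#'
#' @param A Square numeric matrix of transition coefficients.
#' @return `TRUE` if the spectral radius of `A` is strictly less than 1.
#' @examples
#' is_stationary(matrix(c(0.7, 0, 0.25, 0.7), 2, 2))
#' @export
is_stationary <- function(A) {
  A <- as_dyn_matrix(A)
  max(Mod(eigen(A, only.values = TRUE)$values)) < 1
}

as_dyn_matrix <- function(A) {
  if (is.numeric(A) && is.null(dim(A)) && length(A) == 1L) {
    A <- matrix(A, 1L, 1L)
  }
  if (!is.matrix(A) || !is.numeric(A)) {
    rlang::abort("`A` must be a numeric matrix.", class = "ordssm_dimension_error")
  }
  if (nrow(A) != ncol(A)) {
    rlang::abort(
      sprintf("`A` must be square, got %d x %d.", nrow(A), ncol(A)),
      class = "ordssm_dimension_error"
    )
  }
  if (anyNA(A) || any(!is.finite(A))) {
    rlang::abort("`A` must have finite entries.", class = "ordssm_dimension_error")
  }
  A
}

# Column-major positions of the diagonal of vec(G) for a p x p matrix G.
vec_diag_positions <- function(p) (seq_len(p) - 1L) * p + seq_len(p)

#' Selection structure for the variance-identification solve
#'
#' Builds the selection matrix `S` (rows of the p^2 x p^2 identity picking the
#' off-diagonal positions of `vec(Gamma)`, column-major) and the indicator
#' vector `c` marking the diagonal positions. These implement the linear
#' solve that pins every marginal state variance to 1.
#'
#' @param p Number of latent states.
#' @return A list with elements `S` ((p^2 - p) x p^2 matrix) and `c`
#'   (length-p^2 0/1 vector).
#' @export
selection_structure <- function(p) {
  p <- as.integer(p)
  if (p < 1L) rlang::abort("`p` must be >= 1.", class = "ordssm_parameter_error")
  dpos <- vec_diag_positions(p)
  I <- diag(p^2)
  S <- I[-dpos, , drop = FALSE]
  cvec <- as.numeric(seq_len(p^2) %in% dpos)
  list(S = S, c = cvec)
}

#' Stationary marginal covariance of a VAR(1) process
#'
#' Solves the discrete Lyapunov relation `Gamma = A Gamma A' + Sigma` through
#' the p^2-dimensional linear system
#' `vec(Gamma) = (I - A \%x\% A)^{-1} vec(Sigma)` (exact at the small state
#' dimensions used here, typically p <= 4).
#'
#' @param A Square transition matrix with spectral radius < 1.
#' @param Sigma Innovation covariance matrix (diagonal, nonnegative).
#' @return The stationary covariance matrix `Gamma` (symmetric PSD).
#' @export
stationary_covariance <- function(A, Sigma) {
  A <- as_dyn_matrix(A)
  if (!is_stationary(A)) {
    rlang::abort("`A` is not stationary (spectral radius >= 1).",
      class = "ordssm_stationarity_error"
    )
  }
  p <- nrow(A)
  if (is.numeric(Sigma) && is.null(dim(Sigma))) Sigma <- diag(Sigma, p)
  stopifnot(nrow(Sigma) == p, ncol(Sigma) == p)
  M <- diag(p^2) - kronecker(A, A)
  vecG <- solve(M, as.vector(Sigma))
  G <- matrix(vecG, p, p)
  (G + t(G)) / 2
}

#' Identification-implied covariances for unit-variance states
#'
#' Given stationary dynamics `A`, solves for the unique pair
#' (`Gamma`, `Sigma`) such that the marginal state covariance `Gamma` has
#' unit diagonal, `Sigma` is diagonal, and the stationarity relation
#' `vec(Gamma) = (I - A \%x\% A)^{-1} vec(Sigma)` holds. The off-diagonal
#' entries of `Gamma` come from the selection-matrix solve
#' `-(S (I - A \%x\% A) S')^{-1} S (I - A \%x\% A) c`; the innovation
#' variances are then back-solved. This pins the scale of every latent state
#' to 1, making estimates of `A` comparable across measurement models.
#'
#' Not every stationary `A` is compatible with the constraint: if an implied
#' innovation variance is non-positive the matrix is rejected with an
#' `ordssm_infeasible_error` (the MIF2 sampler treats such proposals as
#' zero-weight).
#'
#' @param A Square stationary transition matrix.
#' @param tol Positive feasibility floor for the implied innovation variances.
#' @return An object of class `ordssm_covs`: list with `Gamma` (symmetric,
#'   unit diagonal) and `Sigma` (diagonal matrix).
#' @examples
#' identify_innovations(diag(0.3, 2)) # Gamma = I, Sigma = 0.91 I
#' @export
identify_innovations <- function(A, tol = 1e-8) {
  A <- as_dyn_matrix(A)
  if (!is_stationary(A)) {
    rlang::abort("`A` is not stationary (spectral radius >= 1).",
      class = "ordssm_stationarity_error"
    )
  }
  p <- nrow(A)
  M <- diag(p^2) - kronecker(A, A)
  sel <- selection_structure(p)
  S <- sel$S
  cvec <- sel$c
  if (nrow(S) > 0L) {
    lhs <- S %*% M %*% t(S)
    rhs <- S %*% M %*% cvec
    off <- tryCatch(
      -solve(lhs, rhs),
      error = function(e) {
        rlang::abort("Singular identification system for this `A`.",
          class = "ordssm_numerical_error", parent = e
        )
      }
    )
    vecG <- cvec + as.vector(t(S) %*% off)
  } else {
    vecG <- cvec
  }
  Gamma <- matrix(vecG, p, p)
  Gamma <- (Gamma + t(Gamma)) / 2
  vecSigma <- as.vector(M %*% as.vector(Gamma))
  dpos <- vec_diag_positions(p)
  sigma <- vecSigma[dpos]
  if (any(sigma <= tol) || min(eigen(Gamma, symmetric = TRUE, only.values = TRUE)$values) <= tol) {
    rlang::abort(
      "Dynamics `A` are incompatible with unit marginal state variances (implied innovation variance <= 0).",
      class = "ordssm_infeasible_error"
    )
  }
  structure(
    list(Gamma = Gamma, Sigma = diag(sigma, p)),
    class = "ordssm_covs"
  )
}

#' Is a transition matrix feasible under the identification constraint?
#'
#' @param A Square transition matrix.
#' @return `TRUE` when `A` is stationary and [identify_innovations()] succeeds.
#' @export
is_feasible <- function(A) {
  !inherits(
    tryCatch(identify_innovations(A), error = function(e) e),
    "error"
  )
}

#' @export
print.ordssm_covs <- function(x, ...) {
  cat("Identification-implied covariances (unit marginal state variance)\n")
  cat("Gamma:\n")
  print(round(x$Gamma, 4))
  cat("Sigma (diagonal):", paste(round(diag(x$Sigma), 4), collapse = ", "), "\n")
  invisible(x)
}
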