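#' Read an observation table
#'
#' Reads a delimited wide-format table (one row per timepoint, one column
#' per item, optional `time` column) and validates it: strictly increasing
#' time, categories inside the declared coding, blanks preserved as missing.
#' Observed category codes are remapped onto 1..J via `coding` (e.g.
#' `coding = 0:6` for 0-based 7-point items); the original-to-internal map
#' is recorded in the `coding` attribute, never silently shifted.
#'
#' @param path File path of a delimited text file with a header.
#' @param items Optional character vector restricting/ordering the item
#'   columns (default: every non-`time` column).
#' @param coding Optional vector of permitted observed codes, in order;
#'   position k maps to internal category k. NULL skips categorical
#'   validation (continuous data).
#' @param delim Field delimiter (default comma).
#' @return Tibble with `time` and item columns; attribute `coding` holds
#'   the applied map.
#' @export
read_observations <- function(path, items = NULL, coding = NULL, delim = ",") {
  if (!file.exists(path)) {
    rlang::abort(sprintf("File not found: %s", path), class = "ordssm_io_error")
  }
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  if (!"time" %in% names(df)) {
    df <- dplyr::mutate(df, time = dplyr::row_number(), .before = 1)
  }
  if (is.unsorted(df$time, strictly = TRUE)) {
    rlang::abort("`time` must be strictly increasing.", class = "ordssm_schema_error")
  }
  if (is.null(items)) items <- setdiff(names(df), "time")
  unknown <- setdiff(items, names(df))
  if (length(unknown) > 0) {
    rlang::abort(paste0("Unknown item columns: ", paste(unknown, collapse = ", ")),
      class = "ordssm_schema_error"
    )
  }
  df <- df[c("time", items)]
  if (!is.null(coding)) {
    for (col in items) {
      v <- df[[col]]
      bad <- which(!is.na(v) & !(v %in% coding))
      if (length(bad) > 0) {
        rlang::abort(
          sprintf("Column '%s', row %d: value %s outside the declared coding.",
                  col, bad[1], format(v[bad[1]])),
          class = "ordssm_schema_error"
        )
      }
      df[[col]] <- match(v, coding)
    }
  }
  attr(df, "coding") <- coding
  df
}

#' Read a measurement-parameter table
#'
#' Parses a delimited table of a priori (externally calibrated) measurement
#' parameters into a [measurement_model()]. Expected columns: `item_id`,
#' `state_index`, and either `alpha` plus `beta_1 .. beta_{J-1}` (GRM kind;
#' trailing blank thresholds allowed for items with fewer categories) or
#' `loading` plus optional `error_var` (linear kind, default variance 1).
#' Threshold rows must be strictly increasing.
#'
#' @param path File path.
#' @param kind `"grm"` or `"linear"`.
#' @param delim Field delimiter.
#' @return A `measurement_model`.
#' @export
read_measurement_table <- function(path, kind = c("grm", "linear"), delim = ",") {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    rlang::abort(sprintf("File not found: %s", path), class = "ordssm_io_error")
  }
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  need <- c("item_id", "state_index", if (kind == "grm") "alpha" else "loading")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("Measurement table lacks columns: ",
                        paste(missing_cols, collapse = ", ")),
      class = "ordssm_validation_error"
    )
  }
  if (anyDuplicated(df$item_id)) {
    rlang::abort("Duplicate item_id in measurement table.",
      class = "ordssm_validation_error"
    )
  }
  items <- vector("list", nrow(df))
  if (kind == "grm") {
    beta_cols <- grep("^beta_", names(df), value = TRUE)
    beta_cols <- beta_cols[order(as.integer(sub("^beta_", "", beta_cols)))]
    if (length(beta_cols) == 0) {
      rlang::abort("GRM measurement table needs beta_1.. columns.",
        class = "ordssm_validation_error"
      )
    }
    for (r in seq_len(nrow(df))) {
      b <- as.numeric(df[r, beta_cols])
      b <- b[!is.na(b)]
      if (length(b) < 1L || is.unsorted(b, strictly = TRUE)) {
        rlang::abort(
          sprintf("Item '%s': thresholds not strictly increasing.", df$item_id[r]),
          class = "ordssm_validation_error"
        )
      }
      items[[r]] <- grm_item(df$item_id[r], df$state_index[r], beta = b,
                             alpha = df$alpha[r])
    }
  } else {
    evar <- if ("error_var" %in% names(df)) df$error_var else rep(1, nrow(df))
    for (r in seq_len(nrow(df))) {
      items[[r]] <- linear_item(df$item_id[r], df$state_index[r],
        loading = df$loading[r], error_var = evar[r]
      )
    }
  }
  measurement_model(items, kind = kind)
}

FIT_SCHEMA_VERSION <- "ordssm-fit-1"

#' Serialize a fit to JSON
#'
#' Writes every estimate, per-run trace, seed and configuration field of an
#' [mif2_fit()] result, plus the identification-implied covariances at the
#' estimate, to a versioned JSON file that [read_fit_result()] restores
#' losslessly.
#'
#' @param fit An `ordssm_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "ordssm_fit"))
  covs <- identify_innovations(fit$A)
  payload <- list(
    schema_version = FIT_SCHEMA_VERSION,
    package_version = as.character(utils::packageVersion("ordssm")),
    kind = fit$model$kind,
    estimate = as.list(fit$estimate),
    A = fit$A,
    Gamma = covs$Gamma,
    Sigma = diag(covs$Sigma),
    per_run_estimates = fit$per_run_estimates,
    loglik_traces = fit$loglik_traces,
    loglik = fit$final_filter$loglik,
    config = fit$config[setdiff(names(fit$config), "scheme")],
    scheme = fit$config$scheme,
    seeds = fit$seeds,
    init = as.list(fit$init),
    n_infeasible = fit$n_infeasible
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a serialized fit
#'
#' @param path JSON file written by [write_fit_result()].
#' @return A list mirroring the serialized fields (estimates as named
#'   vectors, matrices restored).
#' @export
read_fit_result <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("File not found: %s", path), class = "ordssm_io_error")
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema_version, FIT_SCHEMA_VERSION)) {
    rlang::abort(
      sprintf("Fit schema version mismatch: file has '%s', package expects '%s'.",
              obj$schema_version %||% "<none>", FIT_SCHEMA_VERSION),
      class = "ordssm_schema_error"
    )
  }
  obj$estimate <- unlist(obj$estimate)
  obj$init <- unlist(obj$init)
  obj$A <- as.matrix(obj$A)
  obj$Gamma <- as.matrix(obj$Gamma)
  obj
}
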