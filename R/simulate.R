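#' Draw correlated standard-normal item scores
#'
#' Generates `n` rows of latent continuous scores with population correlation
#' `R`, as `Z %*% chol(R)` for i.i.d. standard-normal `Z` — the standard
#' square-root realization of a prescribed relational pattern.
#'
#' @param n Number of rows.
#' @param R Symmetric positive semi-definite correlation matrix, or a
#'   [population_model()] whose implied matrix is used.
#' @param seed Optional integer seed; identical seeds give identical output.
#' @return An `n x p` tibble of continuous scores.
#' @examples
#' z <- sim_latent(100, population_model(p = 5), seed = 1)
#' @export
sim_latent <- function(n, R, seed = NULL) {
  if (inherits(R, "mdcfa_population")) R <- population_cor(R)
  R <- as.matrix(R)
  p <- ncol(R)
  if (!isTRUE(all.equal(R, t(R), tolerance = 1e-10))) {
    rlang::abort("`R` must be symmetric.")
  }
  C <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(C)) {
    ev <- eigen(R, symmetric = TRUE)
    if (min(ev$values) < -1e-8) {
      rlang::abort("`R` is not positive semi-definite; cannot decompose.")
    }
    C <- diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
  }
  Z <- with_seed(seed, matrix(stats::rnorm(n * p), n, p))
  out <- Z %*% C
  colnames(out) <- if (!is.null(colnames(R))) colnames(R) else item_names(p)
  tibble::as_tibble(out)
}

#' Dichotomize continuous scores at normal quantile cut points
#'
#' Each column is cut so that the expected proportion of ones equals the
#' target probability: an entry becomes 1 exactly when the continuous value
#' exceeds the standard-normal `(1 - prob)` quantile (so `prob = 0.5` cuts at
#' zero).
#'
#' @param data Continuous matrix or data frame (rows = participants).
#' @param probs Per-column target success probabilities, strictly in (0, 1);
#'   a single value is recycled. A [population_model()] may be given, in
#'   which case its `probs` are used.
#' @return A tibble of 0/1 values with the same shape as `data`.
#' @examples
#' z <- sim_latent(200, population_model(p = 5), seed = 1)
#' b <- dichotomize(z, population_model(p = 5))
#' colMeans(b)
#' @export
dichotomize <- function(data, probs) {
  if (inherits(probs, "mdcfa_population")) probs <- probs$probs
  X <- as.matrix(data)
  p <- ncol(X)
  if (length(probs) == 1L) probs <- rep(probs, p)
  if (length(probs) != p) {
    rlang::abort("`probs` must have one entry per column.")
  }
  if (any(probs <= 0 | probs >= 1)) {
    rlang::abort("`probs` must lie strictly in (0, 1).")
  }
  out <- sweep(X, 2L, stats::qnorm(1 - probs), ">") * 1
  colnames(out) <- if (!is.null(colnames(X))) colnames(X) else item_names(p)
  tibble::as_tibble(out)
}

#' Remove entries according to a planned missing data design
#'
#' Replaces exactly `round(percent * n)` entries per selected column with
#' `NA`, using the design's row-selection scheme (see [missing_design()]).
#' Unselected columns are untouched. The same seed reproduces the same
#' pattern bitwise.
#'
#' @param data 0/1 data frame or matrix (rows = participants).
#' @param design A [missing_design()]; its `n` and `p` must match `data`.
#' @param seed Optional integer seed for the row draw.
#' @return A tibble of 0/1/NA values carrying the design in attribute
#'   `"design"`.
#' @examples
#' pop <- population_model(p = 20)
#' b <- dichotomize(sim_latent(500, pop, seed = 1), pop)
#' d <- missing_design(500, 20, 17:20, 0.1)
#' incomplete <- impose_missing(b, d, seed = 2)
#' colSums(is.na(incomplete))
#' @export
impose_missing <- function(data, design, seed = NULL) {
  stopifnot(inherits(design, "mdcfa_design"))
  X <- as_binary_matrix(data)
  if (nrow(X) != design$n || ncol(X) != design$p) {
    rlang::abort(sprintf(
      "`data` is %d x %d but the design expects %d x %d.",
      nrow(X), ncol(X), design$n, design$p
    ))
  }
  k <- as.integer(round(design$percent * design$n))
  if (k > 0L && length(design$columns) > 0L) {
    rows <- with_seed(seed, {
      if (design$scheme == "shared") {
        shared <- sample.int(design$n, k)
        lapply(design$columns, function(j) shared)
      } else {
        lapply(design$columns, function(j) sample.int(design$n, k))
      }
    })
    for (i in seq_along(design$columns)) {
      X[rows[[i]], design$columns[i]] <- NA_real_
    }
  }
  out <- tibble::as_tibble(X)
  attr(out, "design") <- design
  out
}

#' Generate one binary dataset with planned missingness
#'
#' Convenience wrapper chaining [sim_latent()], [dichotomize()] and
#' [impose_missing()]. The latent draw and the missingness draw use seeds
#' derived from `seed` so that the complete and incomplete variants of the
#' same dataset can also be produced separately (see `latent_seed` /
#' `missing_seed`).
#'
#' @param model A [population_model()].
#' @param design A [missing_design()] (optional; complete data if omitted).
#' @param seed Integer seed; `NULL` uses the session RNG.
#' @return A tibble of 0/1/NA values with attributes `"design"` and
#'   `"population"`.
#' @export
sim_binary_data <- function(model, design = NULL, seed = NULL) {
  stopifnot(inherits(model, "mdcfa_population"))
  if (is.null(design)) {
    design <- missing_design(n = 500, p = model$p)
  }
  stopifnot(inherits(design, "mdcfa_design"))
  seeds <- derive_seeds(seed)
  z <- sim_latent(design$n, model, seed = seeds$latent)
  b <- dichotomize(z, model)
  out <- impose_missing(b, design, seed = seeds$missing)
  attr(out, "population") <- model
  out
}

# Split one master seed into a latent-draw seed and a missingness seed.
derive_seeds <- function(seed) {
  if (is.null(seed)) return(list(latent = NULL, missing = NULL))
  m <- .Machine$integer.max
  list(latent = (as.integer(seed) %% m), missing = ((as.integer(seed) + 77003L) %% m))
}

#' Read and write binary datasets as CSV
#'
#' Plain CSV with a header row `item1..itemP`; cells are `0`, `1` or the
#' missing marker.
#'
#' @param data A 0/1/NA data frame.
#' @param path File path.
#' @param missing Missing-value marker string (default `"NA"`).
#' @return `write_dataset()` returns `path` invisibly; `read_dataset()`
#'   returns a tibble of 0/1/NA values.
#' @export
write_dataset <- function(data, path, missing = "NA") {
  X <- as_binary_matrix(data)
  utils::write.csv(as.data.frame(X), path, row.names = FALSE, na = missing)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path, missing = "NA") {
  df <- utils::read.csv(path, na.strings = missing, check.names = FALSE)
  tibble::as_tibble(as_binary_matrix(df))
}
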