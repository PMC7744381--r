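#' Estimate item and pairwise success probabilities
#'
#' Computes `Pr(X_i = 1)` and `Pr(X_i = 1 & X_j = 1)` for every item and item
#' pair, counting a missing response as "not 1" and dividing by the full
#' sample size N. Only occurrences of the coded response matter, so incorrect
#' and missing responses need not be distinguished. Under a design that
#' removes a fraction pi of item i's entries this makes the estimated margin
#' `Pr(X_i = 1 | trait) * (1 - pi)` in expectation — the attenuation that the
#' missing-data factor is built to absorb. Complete-case or pairwise
#' denominators would erase exactly that signal.
#'
#' @param data Participants x items data frame or matrix of 0/1/NA.
#' @return An object of class `mdcfa_margins`: list with `p_hat` (length-p),
#'   `joint` (p x p, diagonal equal to `p_hat`), `n`, `items`.
#' @examples
#' estimate_margins(data.frame(a = c(1, NA, 0, 1), b = c(1, 1, 0, 0)))
#' @export
estimate_margins <- function(data) {
  X <- as_binary_matrix(data)
  n <- nrow(X)
  if (n < 2L || ncol(X) < 2L) {
    rlang::abort("`data` must have at least 2 rows and 2 columns.")
  }
  ones <- (X == 1) & !is.na(X)
  storage.mode(ones) <- "double"
  p_hat <- colMeans(ones)
  joint <- crossprod(ones) / n
  structure(
    list(p_hat = p_hat, joint = joint, n = n, items = colnames(X)),
    class = "mdcfa_margins"
  )
}

#' @export
print.mdcfa_margins <- function(x, ...) {
  cat(sprintf("<mdcfa_margins> %d items, N = %d, Pr(X=1) in [%.3f, %.3f]\n",
              length(x$p_hat), x$n, min(x$p_hat), max(x$p_hat)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mdcfa_margins <- function(x, ...) {
  tibble::tibble(item = x$items, p_hat = x$p_hat, n_ones = round(x$p_hat * x$n))
}

#' Probability-based covariance matrix of binary items
#'
#' `cov(X_i, X_j) = Pr(X_i = 1 & X_j = 1) - Pr(X_i = 1) Pr(X_j = 1)`, the
#' covariance of the 0/1 indicators (population version of the phi-coefficient
#' numerator). The diagonal is `p_hat (1 - p_hat)`.
#'
#' @param margins An [estimate_margins()] result, or raw data (margins are
#'   then estimated first).
#' @return A `p x p` matrix of class `mdcfa_cov` with attributes
#'   `kind = "raw"` and `margins`.
#' @examples
#' b <- data.frame(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0))
#' prob_cov(estimate_margins(b))
#' @export
prob_cov <- function(margins) {
  if (!inherits(margins, "mdcfa_margins")) margins <- estimate_margins(margins)
  S <- margins$joint - outer(margins$p_hat, margins$p_hat)
  dimnames(S) <- list(margins$items, margins$items)
  structure(S, class = c("mdcfa_cov", "matrix", "array"),
            kind = "raw", margins = margins)
}

#' Rescale a binary covariance matrix to the latent-normal metric
#'
#' Binary indicators live on a different scale than the normally distributed
#' latent variables of the factor model. To first order, dichotomizing a
#' standard-normal variable at the `(1 - q)` quantile scales covariances by
#' the normal density at the cut point, `f(q) = dnorm(qnorm(q))`. The
#' `"ogive"` link therefore divides every cell (i, j) by `f(p_hat_i) *
#' f(p_hat_j)`. Off-diagonal cells of complete data then approximate the
#' latent correlations; the diagonal becomes `p q / f(p)^2`, the sampling
#' metric of the binary item mapped to the latent scale. The diagonal is
#' deliberately kept on that metric rather than forced to one: it carries the
#' information weight of each item, and maximum-likelihood fitting relies on
#' it (easy items have little information about latent covariances, and their
#' rescaled cells are correspondingly noisy). `diagonal = "unit"` forces unit
#' diagonals for sensitivity analysis.
#'
#' By default the densities are evaluated at the observed margins, which is
#' all the transformation needs for complete data and keeps the covariance
#' module independent of any design information. When a missingness `design`
#' is supplied the densities are instead evaluated at the *genuine* success
#' probabilities `p_hat / (1 - pi_i)`, de-attenuating the observed margins by
#' the known per-item missing rates `pi_i` — a sensitivity variant that
#' relocates the cut points of incomplete columns to the dichotomization
#' margins of the respondents who saw the item. For complete data the two
#' coincide.
#'
#' @param S A raw `mdcfa_cov` matrix (or any covariance matrix).
#' @param margins The margins used to build `S`; defaults to its attribute.
#' @param method `"ogive"` (default) or `"none"` (identity).
#' @param diagonal `"latent"` (default) or `"unit"`.
#' @param design Optional [missing_design()] used to de-attenuate margins
#'   before evaluating the link densities.
#' @return A `p x p` matrix of class `mdcfa_cov`, `kind = "linked"`.
#' @examples
#' b <- dichotomize(sim_latent(5000, population_model(p = 4), seed = 1),
#'                  population_model(p = 4))
#' link_transform(prob_cov(estimate_margins(b)))
#' @export
link_transform <- function(S, margins = NULL,
                           method = c("ogive", "none"),
                           diagonal = c("latent", "unit"),
                           design = NULL) {
  method <- match.arg(method)
  diagonal <- match.arg(diagonal)
  if (method == "none") return(S)
  if (is.null(margins)) margins <- attr(S, "margins")
  if (is.null(margins)) {
    rlang::abort("`margins` are required for the ogive link.")
  }
  p_hat <- margins$p_hat
  if (!is.null(design)) {
    stopifnot(inherits(design, "mdcfa_design"))
    retained <- 1 - design$n_missing / design$n
    if (any(retained <= 0)) {
      rlang::abort("The design removes all entries of some column.")
    }
    p_hat <- pmin(p_hat / retained, 1)
  }
  degen <- p_hat <= 0 | p_hat >= 1
  if (any(degen)) {
    rlang::abort(sprintf(
      "Degenerate item(s) with Pr(X=1) of 0 or 1: %s.",
      paste(margins$items[degen], collapse = ", ")
    ))
  }
  f <- stats::dnorm(stats::qnorm(p_hat))
  out <- unclass(S) / outer(f, f)
  if (diagonal == "unit") diag(out) <- 1
  structure(out, class = c("mdcfa_cov", "matrix", "array"),
            kind = "linked", margins = margins, link = method,
            diagonal = diagonal)
}

#' Probability-based, link-transformed covariance of a binary dataset
#'
#' One-call pipeline: [estimate_margins()], [prob_cov()], [link_transform()].
#'
#' @inheritParams estimate_margins
#' @inheritParams link_transform
#' @return A `mdcfa_cov` matrix ready for [fit_cfa_cov()].
#' @export
cov_binary <- function(data, method = c("ogive", "none"),
                       diagonal = c("latent", "unit"),
                       design = NULL) {
  m <- estimate_margins(data)
  link_transform(prob_cov(m), m, method = match.arg(method),
                 diagonal = match.arg(diagonal), design = design)
}

# Ridge a non-positive-definite matrix back to PD: add delta * I, doubling
# delta from 1e-8. Returns list(S, ridge).
ensure_pd <- function(S) {
  delta_used <- 0
  M <- unclass(S)
  ok <- function(M) {
    ch <- tryCatch(chol(M), error = function(e) NULL)
    !is.null(ch) && all(diag(ch) > 0)
  }
  if (!ok(M)) {
    delta <- 1e-8
    repeat {
      if (ok(M + delta * diag(nrow(M)))) break
      delta <- delta * 2
      if (delta > 1e6) rlang::abort("Covariance matrix cannot be ridged to PD.")
    }
    delta_used <- delta
    M <- M + delta * diag(nrow(M))
    rlang::warn(sprintf(
      "Covariance matrix not positive definite; ridge %.2e added.", delta
    ))
  }
  list(S = M, ridge = delta_used)
}

#' Write / read a covariance matrix as CSV with a JSON sidecar
#'
#' The matrix round-trips as a square CSV with header; the kind tag and link
#' metadata go to `<path>.json`.
#'
#' @param S A `mdcfa_cov` matrix.
#' @param path CSV file path.
#' @return `write_cov()` returns `path` invisibly; `read_cov()` the matrix.
#' @export
write_cov <- function(S, path) {
  utils::write.csv(as.data.frame(unclass(S)), path, row.names = FALSE)
  meta <- list(kind = attr(S, "kind") %||% "raw",
               link = attr(S, "link") %||% "none",
               diagonal = attr(S, "diagonal") %||% "latent")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cov
#' @export
read_cov <- function(path) {
  M <- as.matrix(utils::read.csv(path, check.names = FALSE))
  rownames(M) <- colnames(M)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  structure(M, class = c("mdcfa_cov", "matrix", "array"),
            kind = meta$kind %||% "raw", link = meta$link,
            diagonal = meta$diagonal)
}
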