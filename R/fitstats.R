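#' Root mean square error of approximation
#'
#' `sqrt(max(chi2 - df, 0) / (df * (n - 1)))`; zero when the statistic does
#' not exceed its degrees of freedom. Conventional cut-off for good fit:
#' 0.06.
#'
#' @param chi2 Test statistic.
#' @param df Degrees of freedom (> 0).
#' @param n Sample size (> 1).
#' @return Scalar RMSEA.
#' @examples
#' rmsea(644.2, 189, 500)  # 0.069
#' @export
rmsea <- function(chi2, df, n) {
  if (any(df <= 0)) rlang::abort("`df` must be positive.")
  check_number(n, "n", lower = 1, strict_lower = TRUE)
  sqrt(pmax(chi2 - df, 0) / (df * (n - 1)))
}

#' Standardized root mean square residual
#'
#' Root mean square of the correlation-metric residuals over the unique
#' (lower-triangle plus diagonal) cells. Cut-off for good fit: 0.08.
#'
#' @param S Observed covariance matrix (positive diagonal).
#' @param Sigma Model-implied covariance matrix of the same dimension.
#' @return Scalar SRMR.
#' @examples
#' srmr(matrix(c(1, .2, .2, 1), 2), diag(2))  # sqrt(0.04 / 3)
#' @export
srmr <- function(S, Sigma) {
  S <- unclass(S); Sigma <- unclass(Sigma)
  if (!all(dim(S) == dim(Sigma))) rlang::abort("Dimension mismatch.")
  d <- diag(S)
  if (any(d <= 0)) rlang::abort("`S` has non-positive diagonal entries.")
  sc <- sqrt(outer(d, d))
  res <- ((S - Sigma) / sc)[lower.tri(S, diag = TRUE)]
  sqrt(mean(res^2))
}

#' Independence-baseline fit in closed form
#'
#' The null model for the incremental indices (TLI, CFI): all covariances
#' zero, variances free. Its ML solution is `Sigma = diag(S)`, giving
#' `chi2_b = -(n - 1) * log det(R)` with `R` the correlation form of `S`,
#' and `df_b = p(p-1)/2`.
#'
#' @param S Covariance matrix (positive definite).
#' @param n Sample size.
#' @return List with `chi2` and `df`.
#' @export
baseline_fit <- function(S, n) {
  S <- unclass(S)
  p <- nrow(S)
  R <- stats::cov2cor(S)
  ld <- determinant(R)$modulus
  list(chi2 = as.numeric(-(n - 1) * ld), df = (p * (p - 1L)) %/% 2L)
}

#' Tucker-Lewis and comparative fit indices
#'
#' `TLI = (chi2_b/df_b - chi2/df) / (chi2_b/df_b - 1)` and
#' `CFI = 1 - max(chi2 - df, 0) / max(chi2_b - df_b, chi2 - df, 0)`, the CFI
#' clamped to `[0, 1]`. Cut-off for good fit: 0.95 for both.
#'
#' @param chi2,df Target-model statistic and degrees of freedom.
#' @param chi2_b,df_b Baseline-model statistic and degrees of freedom.
#' @return List with `tli` and `cfi`.
#' @export
tli_cfi <- function(chi2, df, chi2_b, df_b) {
  if (df <= 0 || df_b <= 0) rlang::abort("Degrees of freedom must be positive.")
  rb <- chi2_b / df_b
  tli <- if (abs(rb - 1) < 1e-12) {
    rlang::warn("Baseline chi2/df equals 1; TLI undefined.")
    NA_real_
  } else {
    (rb - chi2 / df) / (rb - 1)
  }
  num <- max(chi2 - df, 0)
  den <- max(chi2_b - df_b, chi2 - df, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  list(tli = tli, cfi = min(max(cfi, 0), 1))
}

#' AIC from the chi-square statistic
#'
#' `AIC = chi2 + 2q` with `q` the number of free parameters.
#'
#' @param chi2 Test statistic.
#' @param q Free-parameter count (>= 0).
#' @return Scalar AIC.
#' @examples
#' aic_chi2(205.6, 21)  # 247.6
#' @export
aic_chi2 <- function(chi2, q) {
  if (any(q < 0)) rlang::abort("`q` must be nonnegative.")
  chi2 + 2 * q
}

#' CFI-difference model comparison
#'
#' Two models are judged substantially different when their CFIs differ by
#' more than `threshold` (conventionally 0.01).
#'
#' @param cfi_a,cfi_b CFI values in `[0, 1]`.
#' @param threshold Decision threshold.
#' @return Logical: is the difference substantial?
#' @examples
#' cfi_difference(0.969, 0.972)  # FALSE
#' @export
cfi_difference <- function(cfi_a, cfi_b, threshold = 0.01) {
  check_number(cfi_a, "cfi_a", 0, 1)
  check_number(cfi_b, "cfi_b", 0, 1)
  abs(cfi_a - cfi_b) > threshold
}

#' Fit-index report for a fitted model
#'
#' One row in the conventional reporting order, with pass flags at the
#' conventional criteria (RMSEA <= 0.06, SRMR <= 0.08, TLI >= 0.95,
#' CFI >= 0.95).
#'
#' @param fit A [fit_cfa()] result.
#' @return One-row tibble: chi2, df, rmsea, srmr, tli, cfi, aic and
#'   `good_*` flags.
#' @export
fit_indices <- function(fit) {
  stopifnot(inherits(fit, "mdcfa_fit"))
  tibble::tibble(
    chi2 = fit$chi2, df = fit$df, rmsea = fit$rmsea, srmr = fit$srmr,
    tli = fit$tli, cfi = fit$cfi, aic = fit$aic,
    good_rmsea = fit$rmsea <= 0.06, good_srmr = fit$srmr <= 0.08,
    good_tli = fit$tli >= 0.95, good_cfi = fit$cfi >= 0.95
  )
}
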