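#' Model-implied covariance matrix of a fixed-links specification
#'
#' `Sigma = phi_g L_g L_g' + phi_m L_m L_m' + diag(theta)` with
#' `L_g = w_with * lambda_genuine` and `L_m = w_without * lambda_missing`.
#'
#' @param spec A [cfa_model()] specification.
#' @param phi_genuine,phi_missing Factor variances.
#' @param theta Length-`p` vector of error variances.
#' @return A `p x p` matrix.
#' @export
implied_sigma <- function(spec, phi_genuine, phi_missing = 0, theta) {
  stopifnot(inherits(spec, "mdcfa_spec"), length(theta) == spec$p)
  Lg <- spec$w_with * spec$lambda_genuine
  Lm <- spec$w_without * spec$lambda_missing
  phi_genuine * tcrossprod(Lg) + phi_missing * tcrossprod(Lm) + diag(theta, spec$p)
}

#' Maximum-likelihood discrepancy between two covariance matrices
#'
#' `F = log det(Sigma) - log det(S) + trace(S Sigma^-1) - p`; nonnegative,
#' zero exactly when `S = Sigma`.
#'
#' @param S Empirical covariance matrix (symmetric positive definite).
#' @param Sigma Model-implied covariance matrix (symmetric positive definite).
#' @return Scalar discrepancy value.
#' @examples
#' ml_discrepancy(diag(2), 2 * diag(2))  # log(4) + 1 - 2
#' @export
ml_discrepancy <- function(S, Sigma) {
  S <- unclass(S); Sigma <- unclass(Sigma)
  p <- nrow(S)
  ch_s <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch_s)) rlang::abort("`S` is not positive definite.")
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) rlang::abort("`Sigma` is not positive definite.")
  2 * sum(log(diag(ch))) - 2 * sum(log(diag(ch_s))) +
    sum(S * chol2inv(ch)) - p
}

# objective + analytic gradient for the free parameters
# par = c(phi_g, [phi_m], theta_1..theta_p)
make_objective <- function(spec, S) {
  Lg <- spec$w_with * spec$lambda_genuine
  Lm <- spec$w_without * spec$lambda_missing
  two <- spec$kind != "one_factor"
  p <- spec$p
  ld_s <- as.numeric(determinant(S)$modulus)
  Gg <- tcrossprod(Lg)
  Gm <- tcrossprod(Lm)
  sigma_of <- function(par) {
    par[1] * Gg + (if (two) par[2] * Gm else 0) + diag(par[(2 + two):(p + 1 + two)], p)
  }
  list(
    two = two,
    sigma = sigma_of,
    fn = function(par) {
      ch <- tryCatch(chol(sigma_of(par)), error = function(e) NULL)
      if (is.null(ch)) return(.Machine$double.xmax / 1e10)
      2 * sum(log(diag(ch))) - ld_s + sum(S * chol2inv(ch)) - p
    },
    gr = function(par) {
      ch <- tryCatch(chol(sigma_of(par)), error = function(e) NULL)
      if (is.null(ch)) return(rep(0, length(par)))
      Si <- chol2inv(ch)
      A <- Si - Si %*% S %*% Si      # dF = tr(A dSigma)
      c(sum(A * Gg), if (two) sum(A * Gm), diag(A))
    }
  )
}

#' Fit a fixed-links model to a covariance matrix
#'
#' Minimizes the maximum-likelihood discrepancy over the free parameters
#' (factor variance(s) and error variances) with bounded quasi-Newton
#' (L-BFGS-B) iterations and analytic gradients. Error variances are bounded
#' below by `1e-6` instead of allowing improper (Heywood) solutions;
#' boundary hits are flagged. Non-convergence is flagged on the result, not
#' raised. A non-positive-definite `S` is ridged (smallest `delta * I`
#' restoring positive definiteness, `delta` doubled from 1e-8) with a
#' warning; the ridge is recorded.
#'
#' @param S Covariance matrix, typically from [cov_binary()].
#' @param spec A [cfa_model()] specification.
#' @param n Sample size behind `S`; the test statistic is `(n - 1) * F_min`.
#' @param start Optional start values `c(phi_g, [phi_m], theta)`. Default:
#'   variances 1, `theta_i = max(0.5 s_ii, 0.05)`.
#' @return An object of class `mdcfa_fit`; see [glance.mdcfa_fit()] and
#'   [tidy.mdcfa_fit()] for tidy views. Contains parameter estimates,
#'   `f_min`, `chi2`, `df`, the implied matrix, fit indices against the
#'   independence baseline, and the loadings table (fixed, weighted,
#'   adjusted, standardized).
#' @seealso [fit_cfa()] for the data-frame interface.
#' @export
fit_cfa_cov <- function(S, spec, n, start = NULL) {
  stopifnot(inherits(spec, "mdcfa_spec"))
  check_number(n, "n", lower = spec$p + 1)
  margins <- attr(S, "margins")
  pd <- ensure_pd(unclass(S))
  M <- pd$S
  p <- spec$p
  if (nrow(M) != p) rlang::abort("`S` dimension does not match `spec$p`.")
  obj <- make_objective(spec, M)
  two <- obj$two
  if (is.null(start)) {
    start <- c(1, if (two) 1, pmax(0.5 * diag(M), 0.05))
  }
  lower <- c(0, if (two) 0, rep(1e-6, p))
  opt <- stats::optim(
    start, obj$fn, obj$gr, method = "L-BFGS-B", lower = lower,
    control = list(maxit = 1000L, factr = 1e4, pgtol = 1e-8)
  )
  phi_genuine <- unname(opt$par[1])
  phi_missing <- if (two) unname(opt$par[2]) else 0
  theta <- unname(opt$par[(2 + two):(p + 1 + two)])
  Sigma <- implied_sigma(spec, phi_genuine, phi_missing, theta)
  dimnames(Sigma) <- dimnames(M)
  f_min <- opt$value
  chi2 <- (n - 1) * f_min
  base <- baseline_fit(M, n)
  tc <- tli_cfi(chi2, spec$df, base$chi2, base$df)
  fit <- structure(
    list(
      spec = spec, S = M, n = as.integer(n),
      phi_genuine = phi_genuine, phi_missing = phi_missing, theta = theta,
      f_min = f_min, chi2 = chi2, df = spec$df, implied = Sigma,
      rmsea = rmsea(chi2, spec$df, n),
      srmr = srmr(M, Sigma),
      tli = tc$tli, cfi = tc$cfi,
      aic = aic_chi2(chi2, spec$q),
      baseline = base,
      converged = opt$convergence == 0L,
      iterations = unname(opt$counts[1]),
      message = opt$message,
      theta_at_bound = any(theta <= 1e-6 + 1e-12),
      ridge = pd$ridge,
      margins = margins
    ),
    class = "mdcfa_fit"
  )
  fit$loadings <- loading_table(fit)
  fit
}

#' Fit a fixed-links model to a binary dataset
#'
#' Data-frame-first pipeline: margins, probability-based covariance, link
#' transformation, then [fit_cfa_cov()].
#'
#' @param data Participants x items data frame of 0/1/NA.
#' @param spec A [cfa_model()] specification.
#' @param method Link method passed to [link_transform()].
#' @param design Optional missingness design passed to [link_transform()]
#'   to evaluate the link densities at genuine rather than observed margins
#'   (sensitivity variant; the default uses observed margins).
#' @return A `mdcfa_fit` object.
#' @examples
#' pop <- population_model(p = 6)
#' b <- sim_binary_data(pop, missing_design(300, 6), seed = 1)
#' fit <- fit_cfa(b, cfa_model("one_factor", p = 6))
#' glance(fit)
#' @export
fit_cfa <- function(data, spec, method = c("ogive", "none"),
                    design = NULL) {
  fit_cfa_cov(cov_binary(data, method = match.arg(method), design = design),
              spec, n = nrow(as.matrix(data)))
}

# loadings table: fixed, weighted, adjusted (inverse-weight correction where
# w_with < 1), standardized on the latent metric.
loading_table <- function(fit) {
  spec <- fit$spec
  weighted <- spec$w_with * spec$lambda_genuine
  adj_factor <- rep(1, spec$p)
  needs_adj <- spec$w_with < 1
  if (any(needs_adj)) {
    n_with <- spec$design$n_with
    if (any(n_with[needs_adj] == 0L)) {
      rlang::abort("Cannot adjust loadings: some items were never administered.")
    }
    adj_factor[needs_adj] <- sqrt(spec$design$n / n_with[needs_adj])
  }
  adjusted <- weighted * adj_factor
  std <- adjusted * sqrt(fit$phi_genuine) *
    sqrt(diag(fit$S) / diag(fit$implied))
  tibble::tibble(
    item = colnames(fit$S) %||% item_names(spec$p),
    lambda_genuine = spec$lambda_genuine,
    lambda_missing = spec$w_without * spec$lambda_missing,
    weighted = weighted,
    adjusted = adjusted,
    standardized = std
  )
}

#' Adjusted genuine-factor loadings
#'
#' Reverses the subsample weight attached to a genuine-factor loading:
#' `lambda_adj_i = sqrt(lambda_est_i^2 * N / n_with_i)`. For the
#' semi-hierarchical model, whose estimated loading on item i is
#' `w_with_i * lambda_i` with `w_with_i = sqrt(n_with_i / N)`, the adjustment
#' recovers `lambda_i` exactly; items without missing data (weight one) are
#' unchanged, as are the unweighted models. The adjustment precedes the
#' per-item standardization.
#'
#' @param fit A [fit_cfa()] result.
#' @return Tibble with `item`, `weighted`, `adjusted`.
#' @export
adjust_loadings <- function(fit) {
  stopifnot(inherits(fit, "mdcfa_fit"))
  fit$loadings[c("item", "weighted", "adjusted")]
}

#' Standardized genuine-factor loadings
#'
#' The adjusted loading scaled to the standardized-factor, latent-item
#' metric: `lambda_std_i = lambda_adj_i * sqrt(phi_g) * sqrt(s_ii /
#' sigma_ii)`, where `s_ii` and `sigma_ii` are the observed and
#' model-implied item variances. For a well-fitting model the variance ratio
#' is ~1 and all items share the value `lambda * sqrt(phi_g)`; under misfit
#' the ratio lets individual items deviate.
#'
#' @param fit A [fit_cfa()] result.
#' @return Tibble with `item`, `standardized`.
#' @export
standardize_loadings <- function(fit) {
  stopifnot(inherits(fit, "mdcfa_fit"))
  fit$loadings[c("item", "standardized")]
}

#' @export
print.mdcfa_fit <- function(x, ...) {
  cat(sprintf("<mdcfa_fit> %s model, N = %d\n", x$spec$kind, x$n))
  cat(sprintf(
    "  chi2(%d) = %.1f, RMSEA %.3f, SRMR %.3f, TLI %.3f, CFI %.3f, AIC %.1f\n",
    x$df, x$chi2, x$rmsea, x$srmr, x$tli, x$cfi, x$aic
  ))
  cat(sprintf("  phi_genuine = %.4f", x$phi_genuine))
  if (x$spec$kind != "one_factor") cat(sprintf(", phi_missing = %.4f", x$phi_missing))
  if (!x$converged) cat("  [NOT CONVERGED]")
  if (x$theta_at_bound) cat("  [theta at lower bound]")
  cat("\n")
  invisible(x)
}

#' Tidy a fitted model: one row per item
#'
#' @param x A `mdcfa_fit` object.
#' @param ... Unused.
#' @return Tibble with the fixed, weighted, adjusted and standardized
#'   loadings and the error variance per item.
#' @exportS3Method generics::tidy
tidy.mdcfa_fit <- function(x, ...) {
  dplyr::mutate(x$loadings, theta = x$theta)
}

#' One-row summary of a fitted model
#'
#' @param x A `mdcfa_fit` object.
#' @param ... Unused.
#' @return One-row tibble: chi2, df, rmsea, srmr, tli, cfi, aic, factor
#'   variances, convergence information.
#' @exportS3Method generics::glance
glance.mdcfa_fit <- function(x, ...) {
  tibble::tibble(
    model = x$spec$kind, n = x$n,
    chi2 = x$chi2, df = x$df, rmsea = x$rmsea, srmr = x$srmr,
    tli = x$tli, cfi = x$cfi, aic = x$aic,
    phi_genuine = x$phi_genuine, phi_missing = x$phi_missing,
    f_min = x$f_min, converged = x$converged, ridge = x$ridge
  )
}

#' Serialize a fit to JSON / export the loadings table
#'
#' @param fit A `mdcfa_fit` object.
#' @param path File path (`.json` for `fit_to_json`, `.tsv` for
#'   `write_loadings`).
#' @return The path, invisibly (or the JSON string when `path` is `NULL`).
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "mdcfa_fit"))
  obj <- c(
    as.list(glance.mdcfa_fit(fit)),
    list(theta = fit$theta, loadings = fit$loadings,
         baseline = fit$baseline, iterations = fit$iterations)
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(path))
  }
  as.character(js)
}

#' @rdname fit_to_json
#' @export
write_loadings <- function(fit, path) {
  stopifnot(inherits(fit, "mdcfa_fit"))
  utils::write.table(tidy.mdcfa_fit(fit), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
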