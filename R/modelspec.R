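#' Build a fixed-links CFA model specification
#'
#' Constructs one of the three measurement models for binary data with
#' planned missingness. All factor loadings are *fixed*; only the factor
#' variances and the error variances are estimated (a fixed-links model).
#'
#' * `"one_factor"`: the genuine trait only, loadings all equal to
#'   `loading`. Free parameters: `phi_genuine` and p error variances
#'   (`q = p + 1`).
#' * `"missing_data"`: adds a second latent variable representing the
#'   missingness layout, with loadings fixed to `c * n_missing_i` (zero for
#'   complete columns) and its variance `phi_missing` free (`q = p + 2`).
#'   Both factors apply to every participant.
#' * `"semi_hierarchical"`: the same two factors, but each loading is
#'   weighted by the square root of the relevant subsample share,
#'   `w_with = sqrt(n_with/N)` on the genuine factor and
#'   `w_without = sqrt(n_missing/N)` on the missing-data factor, so each
#'   factor contributes only in proportion to the subsample in which it is
#'   active (`q = p + 2`).
#'
#' The scaling constant `c` only sets the numerical size of the fixed
#' missing-data loadings; the free variance `phi_missing` absorbs it, so the
#' fit is invariant to `c` (`phi_missing` scales as `1/c^2`). The default
#' `c = 0.3 / max(n_missing)` puts the largest fixed loading at a typical
#' loading size, 0.3.
#'
#' @param kind `"one_factor"`, `"missing_data"` or `"semi_hierarchical"`.
#' @param p Number of items. Defaults to `design$p` when a design is given.
#' @param loading Fixed loading on the genuine factor (default 0.35).
#' @param design A [missing_design()]; required (with at least one missing
#'   column) for the two-factor kinds.
#' @param scale_c Scaling constant `c > 0` for the missing-data loadings;
#'   `NULL` uses the default rule above.
#' @param weights `"sqrt"` (default) or `"linear"` subsample weights for the
#'   semi-hierarchical kind.
#' @return An object of class `mdcfa_spec`: list with `kind`, `p`,
#'   `lambda_genuine`, `lambda_missing`, `w_with`, `w_without`, `scale_c`,
#'   `q` (free-parameter count), `df` (`p(p+1)/2 - q`), `design`.
#' @examples
#' cfa_model("one_factor", p = 20)$df      # 189
#' d <- missing_design(500, 20, 17:20, 0.5)
#' cfa_model("missing_data", design = d)$df  # 188
#' @export
cfa_model <- function(kind = c("one_factor", "missing_data", "semi_hierarchical"),
                      p = NULL, loading = 0.35, design = NULL,
                      scale_c = NULL, weights = c("sqrt", "linear")) {
  kind <- match.arg(kind)
  weights <- match.arg(weights)
  if (is.null(p)) {
    if (is.null(design)) rlang::abort("Give `p` or a `design`.")
    p <- design$p
  }
  check_number(p, "p", lower = 2)
  check_number(loading, "loading", lower = 0, upper = 1)
  p <- as.integer(p)
  lambda_genuine <- rep(loading, p)
  two_factor <- kind != "one_factor"

  if (two_factor) {
    if (is.null(design) || !inherits(design, "mdcfa_design")) {
      rlang::abort(sprintf("kind = \"%s\" requires a `missing_design()`.", kind))
    }
    if (design$p != p) rlang::abort("`design$p` does not match `p`.")
    if (all(design$n_missing == 0L)) {
      rlang::abort(sprintf(
        "kind = \"%s\" needs at least one column with missing data; the design is complete.",
        kind
      ))
    }
    lambda_missing <- build_missing_lambda(
      design, scale_c %||% (0.3 / max(design$n_missing))
    )
    scale_c <- attr(lambda_missing, "scale_c")
  } else {
    lambda_missing <- rep(0, p)
    scale_c <- NA_real_
  }

  if (kind == "semi_hierarchical") {
    w <- design_weights(design, form = weights)
    w_with <- w$w_with
    w_without <- w$w_without
  } else {
    w_with <- rep(1, p)
    w_without <- rep(if (two_factor) 1 else 0, p)
  }

  q <- p + 1L + as.integer(two_factor)
  structure(
    list(kind = kind, p = p,
         lambda_genuine = lambda_genuine,
         lambda_missing = as.numeric(lambda_missing),
         w_with = w_with, w_without = w_without,
         scale_c = scale_c, weights = if (two_factor) weights else NA_character_,
         q = q, df = (p * (p + 1L)) %/% 2L - q,
         design = design),
    class = "mdcfa_spec"
  )
}

#' Fixed loadings of the missing-data factor
#'
#' Entry i is `c * n_missing_i`: proportional to the expected number of
#' participants who do not get to respond to item i, zero for complete
#' columns. Only the profile matters for the fit; `c` is absorbed by the
#' free variance of the missing-data factor.
#'
#' @param design A [missing_design()].
#' @param scale_c Positive scaling constant.
#' @return Numeric length-`p` vector with attribute `scale_c`.
#' @examples
#' build_missing_lambda(missing_design(500, 20, 17:20, 0.5), 0.3 / 250)
#' @export
build_missing_lambda <- function(design, scale_c) {
  stopifnot(inherits(design, "mdcfa_design"))
  check_number(scale_c, "scale_c", lower = 0, strict_lower = TRUE)
  structure(scale_c * design$n_missing, scale_c = scale_c)
}

#' @export
print.mdcfa_spec <- function(x, ...) {
  cat(sprintf("<mdcfa_spec> %s, p = %d, q = %d free parameters, df = %d\n",
              x$kind, x$p, x$q, x$df))
  cat(sprintf("  lambda_genuine fixed at %.3f", x$lambda_genuine[1]))
  if (x$kind != "one_factor") {
    nz <- which(x$lambda_missing != 0)
    cat(sprintf("; lambda_missing %.4f on items %d-%d (c = %.3g)",
                max(x$lambda_missing), min(nz), max(nz), x$scale_c))
  }
  cat("\n")
  invisible(x)
}

#' Serialize a model specification to JSON
#'
#' Loading vectors, weights and the free-parameter map, for audit and re-fit.
#'
#' @param spec A [cfa_model()] specification.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
spec_to_json <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "mdcfa_spec"))
  obj <- list(
    kind = spec$kind, p = spec$p,
    lambda_genuine = spec$lambda_genuine,
    lambda_missing = spec$lambda_missing,
    w_with = spec$w_with, w_without = spec$w_without,
    scale_c = spec$scale_c,
    free_parameters = c("phi_genuine",
                        if (spec$kind != "one_factor") "phi_missing",
                        paste0("theta_", seq_len(spec$p))),
    q = spec$q, df = spec$df
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}
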