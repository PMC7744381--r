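#' Describe a planned missing data design
#'
#' A planned (design-based) missingness layout: a fixed set of columns loses a
#' fixed percentage of its entries, missing completely at random by
#' construction. The expected missing count per item, `n_missing`, is what the
#' missing-data factor's fixed loadings are built from.
#'
#' Two row-selection schemes are provided. Under `"shared"` (default) one
#' random subset of participants loses the whole selected block, as when a
#' test booklet omits a block of items for a subsample; missingness is then
#' perfectly correlated across the selected columns, which is the structure
#' the missing-data latent variable is designed to absorb. Under
#' `"independent"` rows are drawn separately for every column, so the
#' missingness of different items is unrelated.
#'
#' @param n Sample size (rows).
#' @param p Number of items.
#' @param columns Integer vector of 1-based column indices that lose entries
#'   (e.g. `17:20`). Empty for a complete design.
#' @param percent Fraction of entries removed from each selected column, in
#'   `[0, 1]`.
#' @param scheme `"shared"` or `"independent"` row selection (see Details).
#' @return An object of class `mdcfa_design`: list with `n`, `p`, `columns`,
#'   `percent`, `scheme`, `n_missing` (length-`p`), `n_with` (`n - n_missing`).
#' @examples
#' missing_design(500, 20, columns = 17:20, percent = 0.5)
#' @export
missing_design <- function(n, p, columns = integer(), percent = 0,
                           scheme = c("shared", "independent")) {
  check_number(n, "n", lower = 1)
  check_number(p, "p", lower = 1)
  check_number(percent, "percent", lower = 0, upper = 1)
  scheme <- match.arg(scheme)
  columns <- as.integer(columns)
  if (anyDuplicated(columns) || any(columns < 1L | columns > p)) {
    rlang::abort("`columns` must be distinct 1-based indices within 1..p.")
  }
  n_missing <- integer(p)
  n_missing[columns] <- as.integer(round(percent * n))
  structure(
    list(n = as.integer(n), p = as.integer(p), columns = sort(columns),
         percent = percent, scheme = scheme,
         n_missing = n_missing, n_with = as.integer(n) - n_missing),
    class = "mdcfa_design"
  )
}

#' Subsample weights of the semi-hierarchical model
#'
#' For each item, the weights relating the subsamples with and without the
#' response option to the full sample: `w_with = sqrt(n_with / N)` and
#' `w_without = sqrt(n_missing / N)`. The square root is taken because the
#' covariance decomposition squares whatever multiplies a loading; the
#' `"linear"` form (plain ratios) is kept for sensitivity analysis.
#'
#' @param design A [missing_design()].
#' @param form `"sqrt"` (default) or `"linear"`.
#' @return A tibble with columns `item`, `n_missing`, `w_with`, `w_without`.
#' @examples
#' design_weights(missing_design(500, 20, 17:20, 0.5))
#' @export
design_weights <- function(design, form = c("sqrt", "linear")) {
  stopifnot(inherits(design, "mdcfa_design"))
  form <- match.arg(form)
  with_ratio <- design$n_with / design$n
  without_ratio <- design$n_missing / design$n
  if (form == "sqrt") {
    with_ratio <- sqrt(with_ratio)
    without_ratio <- sqrt(without_ratio)
  }
  tibble::tibble(
    item = item_names(design$p),
    n_missing = design$n_missing,
    w_with = with_ratio,
    w_without = without_ratio
  )
}

#' @export
print.mdcfa_design <- function(x, ...) {
  if (length(x$columns) == 0L || x$percent == 0) {
    cat(sprintf("<mdcfa_design> complete, N = %d, p = %d\n", x$n, x$p))
  } else {
    cat(sprintf(
      "<mdcfa_design> N = %d, p = %d, %.0f%% missing in items %s (%s rows)\n",
      x$n, x$p, 100 * x$percent,
      paste(range(x$columns), collapse = "-"), x$scheme
    ))
  }
  invisible(x)
}
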