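#' Define the one-factor population generating binary items
#'
#' Describes the population from which synthetic datasets are drawn: a single
#' latent trait with a common loading on every item, and per-item success
#' probabilities (item easiness) decreasing linearly from `first_prob` to
#' `last_prob`. The implied latent correlation matrix has unit diagonal and
#' `loading^2` everywhere off the diagonal, so the data are exactly consistent
#' with a one-factor model.
#'
#' @param p Number of items (columns).
#' @param loading Common population factor loading, in `[0, 1]`. The default
#'   0.35 is a typical size for a single binary indicator.
#' @param first_prob,last_prob Success probability of the first and last item;
#'   intermediate items interpolate linearly. Both must lie strictly in (0, 1).
#'
#' @return An object of class `mdcfa_population`: a list with elements `p`,
#'   `loading`, `probs` (length-`p` vector of success probabilities) and
#'   `thresholds` (the standard-normal cut points `qnorm(1 - probs)`).
#' @seealso [population_cor()], [sim_binary_data()]
#' @examples
#' pop <- population_model(p = 20, loading = 0.35)
#' item_probs(pop)
#' @export
population_model <- function(p = 20, loading = 0.35,
                             first_prob = 0.95, last_prob = 0.50) {
  check_number(p, "p", lower = 2)
  check_number(loading, "loading", lower = 0, upper = 1)
  check_number(first_prob, "first_prob", 0, 1, TRUE, TRUE)
  check_number(last_prob, "last_prob", 0, 1, TRUE, TRUE)
  probs <- seq(first_prob, last_prob, length.out = p)
  structure(
    list(p = as.integer(p), loading = loading, probs = probs,
         thresholds = stats::qnorm(1 - probs)),
    class = "mdcfa_population"
  )
}

#' Population correlation matrix of the latent item variables
#'
#' Unit diagonal, `loading^2` off-diagonal. Positive semi-definite for any
#' loading in `[0, 1]` (eigenvalues `1 + (p-1) loading^2` and `1 - loading^2`).
#'
#' @param model A [population_model()].
#' @return A `p x p` correlation matrix.
#' @export
population_cor <- function(model) {
  stopifnot(inherits(model, "mdcfa_population"))
  R <- matrix(model$loading^2, model$p, model$p)
  diag(R) <- 1
  dimnames(R) <- list(item_names(model$p), item_names(model$p))
  R
}

#' Per-item success probabilities and dichotomization thresholds
#'
#' @param model A [population_model()].
#' @return A tibble with columns `item`, `prob`, `threshold`.
#' @export
item_probs <- function(model) {
  stopifnot(inherits(model, "mdcfa_population"))
  tibble::tibble(
    item = item_names(model$p),
    prob = model$probs,
    threshold = model$thresholds
  )
}

#' @export
print.mdcfa_population <- function(x, ...) {
  cat(sprintf(
    "<mdcfa_population> %d items, loading %.3f, Pr(X=1) %.3f -> %.3f\n",
    x$p, x$loading, x$probs[1], x$probs[x$p]
  ))
  invisible(x)
}
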