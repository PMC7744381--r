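# internal helpers

# Run `expr` under a temporary RNG state when `seed` is given; otherwise use
# (and advance) the session RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    rlang::abort("`seed` must be a single non-missing number or NULL.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# coerce a participants x items data frame / matrix of {0, 1, NA} to a matrix
as_binary_matrix <- function(data, arg = "data") {
  X <- as.matrix(data)
  if (!is.numeric(X)) {
    rlang::abort(sprintf("`%s` must be numeric (0/1 with NA for missing).", arg))
  }
  bad <- !(X %in% c(0, 1)) & !is.na(X)
  if (any(bad)) {
    rlang::abort(sprintf("`%s` contains values other than 0, 1, NA.", arg))
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("item", seq_len(ncol(X)))
  X
}

item_names <- function(p) paste0("item", seq_len(p))

check_number <- function(x, arg, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict_lower) x > lower else x >= lower) &&
    (if (strict_upper) x < upper else x <= upper)
  if (!ok) {
    rlang::abort(sprintf(
      "`%s` must be a single number in %s%s, %s%s.", arg,
      if (strict_lower) "(" else "[", format(lower),
      format(upper), if (strict_upper) ")" else "]"
    ))
  }
  invisible(x)
}
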