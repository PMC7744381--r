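#' Configuration of the Monte Carlo study
#'
#' Defines the full simulation grid: replications of an `n x p` one-factor
#' binary dataset (loading `loading`, success probabilities decreasing
#' linearly `first_prob -> last_prob`), each turned into incomplete variants
#' by removing `percents` of the entries of each `column_sets` block, and
#' analyzed with the requested models. The same master seed reproduces the
#' whole study bitwise; every replication derives its own seed, and the
#' complete and incomplete variants of a replication share one latent draw.
#'
#' @param replications Number of Monte Carlo replications (default 500).
#' @param n,p Sample size and item count per dataset.
#' @param loading,first_prob,last_prob Population parameters, see
#'   [population_model()].
#' @param column_sets Named list of 1-based column blocks that lose entries.
#' @param percents Fractions of entries removed per selected column.
#' @param models Models fitted to every incomplete dataset.
#' @param link Link method for [cov_binary()].
#' @param scheme Row-selection scheme, see [missing_design()].
#' @param seed Master seed.
#' @return An object of class `mdcfa_config`.
#' @examples
#' cfg <- study_config(replications = 10, seed = 7)
#' @export
study_config <- function(replications = 500, n = 500, p = 20, loading = 0.35,
                         first_prob = 0.95, last_prob = 0.50,
                         column_sets = list("17-20" = 17:20,
                                            "14-20" = 14:20,
                                            "11-20" = 11:20),
                         percents = seq(0.1, 0.5, by = 0.1),
                         models = c("one_factor", "missing_data",
                                    "semi_hierarchical"),
                         link = c("ogive", "none"),
                         scheme = c("shared", "independent"),
                         seed = 1L) {
  check_number(replications, "replications", lower = 1)
  models <- match.arg(models, several.ok = TRUE)
  if (is.null(names(column_sets))) {
    names(column_sets) <- vapply(column_sets, function(x) {
      paste(range(x), collapse = "-")
    }, character(1))
  }
  structure(
    list(replications = as.integer(replications), n = as.integer(n),
         p = as.integer(p), loading = loading,
         first_prob = first_prob, last_prob = last_prob,
         column_sets = column_sets, percents = percents, models = models,
         link = match.arg(link), scheme = match.arg(scheme),
         seed = as.integer(seed)),
    class = "mdcfa_config"
  )
}

#' @export
print.mdcfa_config <- function(x, ...) {
  cat(sprintf(
    "<mdcfa_config> %d replications of %d x %d data (loading %.2f), %d column sets x %d percents, models: %s, seed %d\n",
    x$replications, x$n, x$p, x$loading, length(x$column_sets),
    length(x$percents), paste(x$models, collapse = ", "), x$seed
  ))
  invisible(x)
}

# one seed per replication, derived from the master seed
study_seeds <- function(config) {
  with_seed(config$seed,
            sample.int(.Machine$integer.max - 200000L, config$replications))
}

# condition-specific offset so missingness draws differ between conditions
# but are reproducible regardless of which conditions are run
condition_offset <- function(columns, percent) {
  as.integer(131L * min(columns) + 7919L * length(columns) +
               round(1000 * percent))
}

#' Percentage of the expected loading value
#'
#' Rescales a mean loading so that the generating value `ev` reads 100.
#'
#' @param mean_loading Mean standardized loading.
#' @param ev Expected (generating) loading value.
#' @return `100 * mean_loading / ev`.
#' @examples
#' percent_of_ev(0.35)  # 100
#' @export
percent_of_ev <- function(mean_loading, ev = 0.35) {
  check_number(ev, "ev", lower = 0, strict_lower = TRUE)
  100 * mean_loading / ev
}

#' Standardized absolute difference between column-group mean loadings
#'
#' The absolute difference between the mean loadings of items without and
#' with missing data, divided by the reference difference `d0` observed for
#' the one-factor model on complete data. Values less than or equal to one
#' count as good (the missingness did not separate the groups more than
#' sampling alone does).
#'
#' @param mean_load_nomiss,mean_load_miss Group mean standardized loadings.
#' @param d0 Reference difference (> 0).
#' @return Scalar ratio.
#' @export
std_abs_diff <- function(mean_load_nomiss, mean_load_miss, d0) {
  if (!is.numeric(d0) || any(d0 <= 0)) {
    rlang::abort("`d0` must be positive (degenerate reference difference).")
  }
  abs(mean_load_nomiss - mean_load_miss) / d0
}

# Fit all requested models to the per-replication datasets of one condition.
# `columns = integer()` denotes the complete-data condition (one-factor only).
# Returns list(replications = tibble, item_loadings = list of matrices).
run_grid_condition <- function(config, columns, percent, models, seeds,
                               reps = config$replications) {
  pop <- population_model(config$p, config$loading,
                          config$first_prob, config$last_prob)
  R <- population_cor(pop)
  complete <- length(columns) == 0L || percent == 0
  if (complete) {
    design <- NULL
    specs <- list(one_factor = cfa_model("one_factor", p = config$p,
                                         loading = config$loading))
    models <- "one_factor"
  } else {
    design <- missing_design(config$n, config$p, columns, percent,
                             scheme = config$scheme)
    specs <- lapply(stats::setNames(models, models), function(m) {
      cfa_model(m, loading = config$loading, design = design)
    })
  }
  rows <- vector("list", reps * length(models))
  load_sum <- lapply(specs, function(s) numeric(config$p))
  load_n <- stats::setNames(numeric(length(models)), models)
  k <- 0L
  for (r in seq_len(reps)) {
    z <- sim_latent(config$n, R, seed = seeds[r])
    B <- as.matrix(dichotomize(z, pop$probs))
    if (!complete) {
      B <- as.matrix(impose_missing(
        B, design, seed = seeds[r] + condition_offset(columns, percent)
      ))
    }
    S <- cov_binary(B, method = config$link)
    for (m in models) {
      fit <- fit_cfa_cov(S, specs[[m]], config$n)
      std <- fit$loadings$standardized
      nomiss <- if (complete) std else std[-columns]
      miss <- if (complete) NA_real_ else mean(std[columns])
      k <- k + 1L
      rows[[k]] <- tibble::tibble(
        rep = r, model = m, converged = fit$converged,
        chi2 = fit$chi2, df = fit$df, rmsea = fit$rmsea, srmr = fit$srmr,
        tli = fit$tli, cfi = fit$cfi, aic = fit$aic,
        phi_genuine = fit$phi_genuine, phi_missing = fit$phi_missing,
        mean_load = mean(std), mean_load_nomiss = mean(nomiss),
        mean_load_miss = miss, ridge = fit$ridge
      )
      if (fit$converged) {
        load_sum[[m]] <- load_sum[[m]] + std
        load_n[m] <- load_n[m] + 1
      }
    }
  }
  list(
    replications = dplyr::bind_rows(rows),
    item_means = lapply(stats::setNames(models, models), function(m) {
      load_sum[[m]] / max(load_n[m], 1)
    })
  )
}

#' Run one condition of the Monte Carlo study
#'
#' Generates `reps` datasets (generation, dichotomization, missingness),
#' computes the linked probability-based covariance of each, fits the
#' requested model, and aggregates fit statistics and standardized loadings.
#' Deterministic given the config's master seed; replication seeds are
#' derived by a fixed rule, so the same replication uses the same latent
#' draw in every condition.
#'
#' @param config A [study_config()].
#' @param columns 1-based column block losing entries; empty for the
#'   complete-data condition.
#' @param percent Fraction of entries removed (0 for complete data).
#' @param model Model kind (ignored for complete data: one-factor).
#' @param reps Number of replications (defaults to the config value).
#' @return An object of class `mdcfa_condition`: list with `summary` (one
#'   row of means over converged replications), `replications` (per-rep
#'   tibble), `item_means` (per-item mean standardized loadings), and the
#'   condition identifiers.
#' @examples
#' cfg <- study_config(replications = 5, seed = 42)
#' run_condition(cfg, 17:20, 0.5, "missing_data")
#' @export
run_condition <- function(config, columns = integer(), percent = 0,
                          model = config$models[1],
                          reps = config$replications) {
  stopifnot(inherits(config, "mdcfa_config"))
  if (percent > 0 && length(columns) == 0L) {
    rlang::abort("`columns` must be given when `percent` > 0.")
  }
  if ((percent == 0 || length(columns) == 0L) && model != "one_factor") {
    rlang::abort(
      "Only the one-factor model applies to the complete-data condition."
    )
  }
  seeds <- study_seeds(config)[seq_len(reps)]
  res <- run_grid_condition(config, columns, percent, model, seeds, reps)
  out <- list(
    columns = columns, percent = percent, model = model, reps = reps,
    summary = summarize_replications(res$replications),
    replications = res$replications,
    item_means = tibble::tibble(
      item = item_names(config$p), position = seq_len(config$p),
      mean_std = res$item_means[[model]]
    )
  )
  class(out) <- "mdcfa_condition"
  out
}

summarize_replications <- function(df) {
  counts <- df |>
    dplyr::group_by(.data$model) |>
    dplyr::summarize(n_reps = dplyr::n(), n_converged = sum(.data$converged),
                     df = .data$df[1], .groups = "drop")
  means <- df |>
    dplyr::filter(.data$converged) |>
    dplyr::group_by(.data$model) |>
    dplyr::summarize(dplyr::across(
      c("chi2", "rmsea", "srmr", "tli", "cfi", "aic",
        "mean_load", "mean_load_nomiss", "mean_load_miss"),
      ~ mean(.x, na.rm = TRUE)
    ), .groups = "drop")
  out <- dplyr::left_join(counts, means, by = "model")
  fail <- 1 - out$n_converged / out$n_reps
  if (any(fail > 0.05)) {
    rlang::warn(sprintf("Convergence failure rate above 5%% (max %.1f%%).",
                        100 * max(fail)))
  }
  out
}

#' @export
print.mdcfa_condition <- function(x, ...) {
  lab <- if (length(x$columns) == 0L || x$percent == 0) "complete data" else
    sprintf("%.0f%% missing in items %s", 100 * x$percent,
            paste(range(x$columns), collapse = "-"))
  cat(sprintf("<mdcfa_condition> %s, %s, %d replications\n",
              x$model, lab, x$reps))
  print(x$summary)
  invisible(x)
}

#' Run the full Monte Carlo study grid
#'
#' One complete-data one-factor reference condition plus every combination
#' of column set, missing percentage and model. Produces tidy analogues of
#' the three standard report tables — mean fit statistics, mean standardized
#' loadings (with percent-of-expected-value), and standardized absolute
#' differences between the column groups (reference `d0` taken from the
#' complete-data run, per column split) — plus per-item mean loading curves.
#'
#' @param config A [study_config()].
#' @param progress Print a line per condition?
#' @return An object of class `mdcfa_study`: list of tibbles `fit`,
#'   `loadings`, `differences`, `curves`, `d0`, plus `config`.
#' @seealso [write_study()], [autoplot.mdcfa_study()]
#' @export
run_study <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "mdcfa_config"))
  seeds <- study_seeds(config)
  fit_rows <- list(); load_rows <- list(); curve_rows <- list()

  complete <- run_grid_condition(config, integer(), 0, "one_factor", seeds)
  comp_items <- complete$item_means$one_factor
  comp_sum <- summarize_replications(complete$replications)
  fit_rows[["complete"]] <- dplyr::mutate(
    comp_sum, item_range = "none", percent = 0, .before = 1
  )
  d0 <- purrr::imap(config$column_sets, function(cols, lab) {
    tibble::tibble(
      item_range = lab,
      d0 = abs(mean(comp_items[-cols]) - mean(comp_items[cols]))
    )
  }) |> dplyr::bind_rows()

  for (lab in names(config$column_sets)) {
    cols <- config$column_sets[[lab]]
    for (pct in config$percents) {
      if (progress) message(sprintf("items %s, %.0f%% missing", lab, 100 * pct))
      res <- run_grid_condition(config, cols, pct, config$models, seeds)
      summ <- summarize_replications(res$replications)
      fit_rows[[paste(lab, pct)]] <- dplyr::mutate(
        summ, item_range = lab, percent = pct, .before = 1
      )
      for (m in config$models) {
        curve_rows[[paste(lab, pct, m)]] <- tibble::tibble(
          item_range = lab, percent = pct, model = m,
          item = item_names(config$p), position = seq_len(config$p),
          mean_std = res$item_means[[m]]
        )
      }
    }
  }

  fit <- dplyr::bind_rows(fit_rows)
  loadings <- fit |>
    dplyr::filter(.data$item_range != "none") |>
    dplyr::transmute(
      .data$item_range, .data$percent, .data$model,
      mean_std = .data$mean_load,
      percent_ev = percent_of_ev(.data$mean_load, config$loading),
      mean_std_nomiss = .data$mean_load_nomiss,
      mean_std_miss = .data$mean_load_miss
    )
  differences <- loadings |>
    dplyr::left_join(d0, by = "item_range") |>
    dplyr::transmute(
      .data$item_range, .data$percent, .data$model,
      std_abs_diff = std_abs_diff(.data$mean_std_nomiss,
                                  .data$mean_std_miss, .data$d0),
      good = .data$std_abs_diff <= 1
    )

  structure(
    list(fit = fit, loadings = loadings, differences = differences,
         curves = dplyr::bind_rows(curve_rows), d0 = d0, config = config),
    class = "mdcfa_study"
  )
}

#' @export
print.mdcfa_study <- function(x, ...) {
  cat(sprintf("<mdcfa_study> %d replications, seed %d\n",
              x$config$replications, x$config$seed))
  cat("Mean fit statistics:\n")
  print(x$fit, n = Inf)
  invisible(x)
}

#' Export the study tables as TSV
#'
#' Writes `fit.tsv`, `loadings.tsv`, `differences.tsv` and `curves.tsv`
#' into `dir`.
#'
#' @param study A [run_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "mdcfa_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("fit", "loadings", "differences", "curves")) {
    utils::write.table(study[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
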