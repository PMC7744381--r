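test_that("implied covariance assembles the two-factor decomposition", {
  of <- cfa_model("one_factor", p = 5)
  sig <- implied_sigma(of, 1, 0, rep(1 - 0.1225, 5))
  expect_equal(diag(sig), rep(1, 5))
  expect_equal(sig[lower.tri(sig)], rep(0.1225, 10))

  expect_equal(implied_sigma(cfa_model("one_factor", p = 4, loading = 0),
                             1, 0, 1:4), diag(1:4))

  d <- missing_design(500, 5, 5L, 0.5)
  sh <- cfa_model("semi_hierarchical", design = d)
  sig_sh <- implied_sigma(sh, 1, 0, rep(0, 5))
  expect_equal(sig_sh[5, 5], 0.5 * 0.35^2)   # w^2 lambda^2 phi = 0.06125
})

test_that("the ML discrepancy has its closed-form values and positivity", {
  S <- random_pd(4)
  expect_equal(ml_discrepancy(S, S), 0, tolerance = 1e-10)
  expect_equal(ml_discrepancy(diag(2), 2 * diag(2)), log(4) + 1 - 2)

  set.seed(2)
  for (k in 1:200) {
    A <- random_pd(3); B <- random_pd(3)
    expect_gt(ml_discrepancy(A, B), 0)
  }
  expect_error(ml_discrepancy(matrix(c(1, 2, 2, 1), 2), diag(2)),
               "positive definite")
})

test_that("a zero-residual matrix recovers the generating parameters", {
  spec <- cfa_model("one_factor", p = 6)
  set.seed(3)
  theta <- runif(6, 0.5, 1.5)
  S <- implied_sigma(spec, 1.3, 0, theta)
  fit <- fit_cfa_cov(S, spec, n = 500)
  expect_lt(fit$chi2, 1e-4)
  expect_equal(fit$phi_genuine, 1.3, tolerance = 1e-4)
  expect_equal(fit$theta, theta, tolerance = 1e-4)
  expect_true(fit$converged)

  # near recovery under a small perturbation, approaching exact as it vanishes
  for (eps in c(1e-2, 1e-4)) {
    fit_eps <- fit_cfa_cov(S + eps * diag(6), spec, n = 500)
    expect_equal(fit_eps$phi_genuine, 1.3, tolerance = 50 * eps + 1e-4)
  }
})

test_that("optimizer agrees with an independent coordinate-descent oracle", {
  set.seed(4)
  for (k in 1:3) {
    spec <- cfa_model("one_factor", p = 3, loading = 0.6)
    S <- random_pd(3)
    fit <- fit_cfa_cov(S, spec, n = 100)
    oracle <- coord_descent_fit(S, spec)
    expect_equal(fit$f_min, oracle$value, tolerance = 1e-4)
  }
  # and for a two-factor spec
  d <- missing_design(100, 4, 3:4, 0.4)
  spec2 <- cfa_model("missing_data", p = 4, loading = 0.5, design = d)
  S2 <- random_pd(4)
  fit2 <- fit_cfa_cov(S2, spec2, n = 100)
  expect_equal(fit2$f_min, coord_descent_fit(S2, spec2)$value, tolerance = 1e-4)
})

test_that("analytic gradients match central differences", {
  set.seed(5)
  d <- missing_design(100, 5, 4:5, 0.4)
  spec <- cfa_model("missing_data", p = 5, loading = 0.4, design = d)
  S <- random_pd(5)
  obj <- mdcfa:::make_objective(spec, S)
  for (k in 1:5) {
    par <- c(runif(2, 0.5, 2), runif(5, 0.3, 2))
    g_a <- obj$gr(par)
    g_n <- num_grad(obj$fn, par)
    expect_lt(max(abs(g_a - g_n) / pmax(abs(g_n), 1e-4)), 1e-5)
  }
})

test_that("the fit is invariant to the missing-loading scale constant", {
  pop <- population_model()
  d <- missing_design(500, 20, 17:20, 0.5)
  b <- sim_binary_data(pop, d, seed = 12)
  S <- cov_binary(b)
  f1 <- fit_cfa_cov(S, cfa_model("missing_data", design = d), 500)
  f2 <- fit_cfa_cov(S, cfa_model("missing_data", design = d,
                                 scale_c = 2 * 0.3 / 250), 500)
  expect_equal(f1$f_min, f2$f_min, tolerance = 1e-6)
  expect_equal(f1$phi_missing / f2$phi_missing, 4, tolerance = 1e-2)
  expect_equal(f1$chi2, f2$chi2, tolerance = 1e-3)
})

test_that("the loading adjustment inverts the subsample weight exactly", {
  d <- missing_design(500, 20, 17:20, 0.5)
  pop <- population_model()
  b <- sim_binary_data(pop, d, seed = 13)
  fit <- fit_cfa(b, cfa_model("semi_hierarchical", design = d))
  tab <- fit$loadings
  # weighted loading on a 50%-missing item is 0.35 * sqrt(0.5) ~ 0.24749;
  # the adjustment recovers 0.35 exactly
  expect_equal(tab$weighted[20], 0.35 * sqrt(0.5), tolerance = 1e-12)
  expect_equal(tab$adjusted, rep(0.35, 20), tolerance = 1e-12)
  # complete columns are untouched by the adjustment
  expect_equal(tab$weighted[1:16], tab$adjusted[1:16])

  # unweighted models are left as estimated
  fit_md <- fit_cfa(b, cfa_model("missing_data", design = d))
  expect_equal(fit_md$loadings$adjusted, fit_md$loadings$weighted)

  # an item administered to nobody cannot be adjusted
  d_all <- missing_design(500, 20, 17:20, 1)
  spec_all <- cfa_model("semi_hierarchical", design = d_all)
  expect_error(fit_cfa_cov(random_pd(20), spec_all, 500), "never administered")
})

test_that("standardization is exact on perfectly fitting input and symmetric across items", {
  # implied input with unit variances: standardized loading = fixed loading
  spec <- cfa_model("one_factor", p = 6)
  S <- implied_sigma(spec, 1, 0, rep(1 - 0.1225, 6))
  fit <- fit_cfa_cov(S, spec, n = 500)
  expect_equal(standardize_loadings(fit)$standardized, rep(0.35, 6),
               tolerance = 1e-5)

  # exchangeable items => identical standardized loadings (size equivalence)
  m <- pop_margins(rep(0.7, 5), 0.1225)
  St <- link_transform(prob_cov(m), m)
  fit2 <- fit_cfa_cov(St, cfa_model("one_factor", p = 5), n = 500)
  std <- standardize_loadings(fit2)$standardized
  expect_lt(max(std) - min(std), 1e-6)
})

test_that("population-level ordering: one-factor misfit exceeds the missing-data model", {
  probs <- study_probs(20)
  St <- pop_linked_cov(probs, 0.1225, columns = 14:20, percent = 0.3)
  d <- missing_design(500, 20, 14:20, 0.3)
  of <- fit_cfa_cov(St, cfa_model("one_factor", p = 20), 500)
  md <- fit_cfa_cov(St, cfa_model("missing_data", design = d), 500)
  expect_gt(of$chi2, md$chi2)
})

test_that("semi-hierarchical loadings are size-equivalent on population input", {
  probs <- study_probs(20)
  St <- pop_linked_cov(probs, 0.1225, columns = 17:20, percent = 0.5)
  d <- missing_design(500, 20, 17:20, 0.5)
  fit <- fit_cfa_cov(St, cfa_model("semi_hierarchical", design = d), 500)
  std <- standardize_loadings(fit)$standardized
  expect_lt(max(std) - min(std), 0.02)
})

test_that("tidy and glance views expose the fit", {
  pop <- population_model(p = 6)
  b <- sim_binary_data(pop, missing_design(200, 6), seed = 21)
  fit <- fit_cfa(b, cfa_model("one_factor", p = 6))
  td <- tidy(fit)
  expect_equal(nrow(td), 6)
  expect_true(all(c("item", "standardized", "theta") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$aic, gl$chi2 + 2 * 7)
  js <- jsonlite::fromJSON(fit_to_json(fit))
  expect_equal(js$df, 14)  # 21 - 7
})
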