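test_that("margins count the coded response over the full sample", {
  m <- estimate_margins(cbind(a = c(1, NA, 0, 1), b = c(1, 1, 1, 1)))
  expect_equal(unname(m$p_hat), c(0.5, 1))
  expect_equal(m$joint["a", "b"], 0.5, ignore_attr = TRUE)
  expect_equal(diag(m$joint), m$p_hat, ignore_attr = TRUE)

  expect_error(estimate_margins(cbind(a = c(1, 2), b = c(0, 1))), "other than")
  expect_error(estimate_margins(matrix(1, 1, 2)), "at least 2 rows")
})

test_that("margins attenuate by the missing rate", {
  # Pr(X=1 | trait) = 0.8 with 50% planned missingness -> p_hat ~ 0.4
  pop <- population_model(p = 2, first_prob = 0.8, last_prob = 0.8)
  b <- dichotomize(sim_latent(20000, pop, seed = 6), pop)
  m <- impose_missing(b, missing_design(20000, 2, 1:2, 0.5), seed = 7)
  expect_lt(max(abs(estimate_margins(m)$p_hat - 0.4)), 0.01)
})

test_that("probability-based covariance matches brute-force counting", {
  S1 <- prob_cov(estimate_margins(cbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0))))
  expect_equal(S1["a", "b"], 0, ignore_attr = TRUE)

  S2 <- prob_cov(estimate_margins(cbind(a = c(1, 1, 1, 0), b = c(1, 1, 0, 0))))
  expect_equal(S2["a", "b"], 2 / 4 - 0.75 * 0.5, ignore_attr = TRUE)  # 0.125

  # self-covariance at p = 0.5
  S3 <- prob_cov(estimate_margins(cbind(a = c(1, 1, 0, 0), b = c(1, 1, 0, 0))))
  expect_equal(S3["a", "b"], 0.25, ignore_attr = TRUE)

  # equals the N-denominator sample covariance of indicators with NA -> 0
  set.seed(42)
  for (k in 1:10) {
    X <- matrix(rbinom(8 * 5, 1, 0.6), 8, 5)
    X[sample(length(X), 6)] <- NA
    X0 <- X; X0[is.na(X0)] <- 0
    expect_equal(unclass(prob_cov(estimate_margins(X))),
                 cov(X0) * 7 / 8, ignore_attr = TRUE)
  }
})

test_that("ogive link recovers latent correlations from population margins", {
  # two median-split items, latent correlation 0.1225:
  # binary covariance asin(rho)/(2*pi), linked value ~ 0.1228
  m <- pop_margins(c(0.5, 0.5), 0.1225)
  expect_equal(m$joint[1, 2] - 0.25, asin(0.1225) / (2 * pi), tolerance = 1e-6)
  St <- link_transform(prob_cov(m), m)
  expect_equal(St[1, 2], 0.1228, tolerance = 1e-3)

  # first-order ogive error at the study correlation: below 0.01 for item
  # probabilities up to 0.9, below 0.02 over the full 0.5-0.95 range; the
  # approximation degrades for extreme margins and larger correlations
  probs <- study_probs(20)
  St <- link_transform(prob_cov(pop_margins(probs, 0.1225)))
  err <- abs(St - 0.1225); diag(err) <- 0
  expect_lt(max(err[probs <= 0.9, probs <= 0.9]), 0.01)
  expect_lt(max(err), 0.02)
})

test_that("link transform keeps the latent-metric diagonal and honors options", {
  m <- pop_margins(study_probs(4)[c(1, 2, 3, 4)], 0.1225)
  raw <- prob_cov(m)
  St <- link_transform(raw, m)
  f <- dnorm(qnorm(m$p_hat))
  expect_equal(diag(St), m$p_hat * (1 - m$p_hat) / f^2, ignore_attr = TRUE)

  expect_equal(unclass(link_transform(raw, m, method = "none")), unclass(raw))
  expect_equal(diag(link_transform(raw, m, diagonal = "unit")), rep(1, 4),
               ignore_attr = TRUE)

  degen <- structure(list(p_hat = c(1, 0.5), joint = diag(c(1, 0.5)),
                          n = 10, items = c("i1", "i2")),
                     class = "mdcfa_margins")
  expect_error(link_transform(prob_cov(degen), degen), "i1")
})

test_that("a supplied design de-attenuates the link densities to genuine margins", {
  probs <- study_probs(6)
  m <- pop_margins(probs, 0.1225, columns = 5:6, percent = 0.5)
  design <- missing_design(500, 6, 5:6, 0.5)
  St <- link_transform(prob_cov(m), m, design = design)
  f_gen <- dnorm(qnorm(probs))          # densities at the genuine probabilities
  raw <- unclass(prob_cov(m))
  expect_equal(unclass(St), raw / outer(f_gen, f_gen), ignore_attr = TRUE)

  # without the design, densities sit at the attenuated margins instead
  St0 <- link_transform(prob_cov(m), m)
  f_att <- dnorm(qnorm(m$p_hat))
  expect_equal(unclass(St0), raw / outer(f_att, f_att), ignore_attr = TRUE)
})

test_that("non-positive-definite input is ridged with a warning and recorded", {
  S <- matrix(0.99, 3, 3); diag(S) <- c(1, 1, 0.5)
  S[1, 3] <- S[3, 1] <- -0.9
  expect_lt(min(eigen(S)$values), 0)
  spec <- cfa_model("one_factor", p = 3, loading = 0.3)
  expect_warning(fit <- fit_cfa_cov(S, spec, n = 100), "ridge")
  expect_gt(fit$ridge, 0)
})

test_that("covariance matrices round-trip through CSV with sidecar metadata", {
  pop <- population_model(p = 4)
  b <- dichotomize(sim_latent(200, pop, seed = 8), pop)
  S <- cov_binary(b)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cov(S, path)
  S2 <- read_cov(path)
  expect_equal(unclass(S2), unclass(S), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(attr(S2, "kind"), "linked")
})
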