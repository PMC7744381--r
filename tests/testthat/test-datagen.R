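test_that("population correlation matrix has unit diagonal and loading^2 off-diagonal", {
  R <- population_cor(population_model(p = 20, loading = 0.35))
  expect_equal(diag(R), rep(1, 20), ignore_attr = TRUE)
  expect_equal(R[upper.tri(R)], rep(0.1225, 190))

  expect_equal(unclass(population_cor(population_model(p = 5, loading = 0))),
               diag(5), ignore_attr = TRUE)

  R1 <- population_cor(population_model(p = 3, loading = 1))
  expect_equal(unclass(R1), matrix(1, 3, 3), ignore_attr = TRUE)
  expect_equal(qr(R1)$rank, 1L)

  expect_error(population_model(p = 5, loading = 1.2), "loading")
})

test_that("latent generation is seed-deterministic and matches the target correlation", {
  pop <- population_model(p = 4, loading = 0.35)
  z1 <- sim_latent(50, pop, seed = 7)
  z2 <- sim_latent(50, pop, seed = 7)
  expect_identical(z1, z2)

  big <- as.matrix(sim_latent(100000, pop, seed = 1))
  sc <- cor(big)
  expect_lt(max(abs(sc[upper.tri(sc)] - 0.1225)), 0.01)

  id <- as.matrix(sim_latent(100000, diag(4), seed = 2))
  ci <- cor(id)
  expect_lt(max(abs(ci[upper.tri(ci)])), 0.02)

  expect_error(sim_latent(10, matrix(c(1, 2, 2, 1), 2)), "positive semi-definite")
})

test_that("dichotomization cuts at normal quantiles with linear probability decrease", {
  # median split: threshold 0
  x <- matrix(c(-0.1, 0.1, 2, -3), 4, 1)
  expect_equal(as.matrix(dichotomize(x, 0.5))[, 1], c(0, 1, 1, 0),
               ignore_attr = TRUE)

  pop <- population_model(p = 20, first_prob = 0.95, last_prob = 0.50)
  expect_equal(pop$probs[10], 0.95 - 9 * (0.45 / 19))

  z <- sim_latent(100000, diag(1), seed = 3)
  b <- dichotomize(z, 0.95)
  expect_lt(abs(mean(b[[1]]) - 0.95), 0.005)

  expect_error(dichotomize(x, 1), "strictly in")
})

test_that("imposed missingness has exact per-column counts", {
  pop <- population_model()
  b <- dichotomize(sim_latent(500, pop, seed = 4), pop)

  d10 <- missing_design(500, 20, 17:20, 0.10)
  m <- impose_missing(b, d10, seed = 1)
  expect_equal(unname(colSums(is.na(m))), c(rep(0, 16), rep(50, 4)))

  d0 <- missing_design(500, 20, 17:20, 0)
  expect_equal(as.matrix(impose_missing(b, d0, seed = 1)), as.matrix(b))

  d50 <- missing_design(500, 20, 11:20, 0.50)
  m50 <- impose_missing(b, d50, seed = 1)
  expect_equal(sum(is.na(m50)), 2500)  # 25% of the 10000 cells

  expect_error(missing_design(500, 20, 17:20, 1.2), "percent")
  expect_error(impose_missing(b[1:10, ], d10), "expects")
})

test_that("row-selection schemes behave as documented and reproduce bitwise", {
  pop <- population_model()
  b <- dichotomize(sim_latent(500, pop, seed = 5), pop)

  shared <- impose_missing(b, missing_design(500, 20, 17:20, 0.3), seed = 9)
  na_rows <- apply(as.matrix(shared)[, 17:20], 2, function(col) which(is.na(col)))
  expect_true(all(na_rows[, 1] == na_rows[, 2]) && all(na_rows[, 1] == na_rows[, 4]))

  indep <- impose_missing(
    b, missing_design(500, 20, 17:20, 0.3, scheme = "independent"), seed = 9
  )
  ni <- apply(as.matrix(indep)[, 17:20], 2, function(col) which(is.na(col)))
  expect_false(all(ni[, 1] == ni[, 2]))

  again <- impose_missing(b, missing_design(500, 20, 17:20, 0.3), seed = 9)
  expect_identical(as.matrix(shared), as.matrix(again))
})

test_that("one-shot generation is deterministic and round-trips through CSV", {
  pop <- population_model(p = 6)
  d <- missing_design(100, 6, 5:6, 0.2)
  b1 <- sim_binary_data(pop, d, seed = 11)
  b2 <- sim_binary_data(pop, d, seed = 11)
  expect_identical(as.matrix(b1), as.matrix(b2))
  expect_equal(unname(colSums(is.na(b1))), c(0, 0, 0, 0, 20, 20))

  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(b1, path)
  expect_equal(as.matrix(read_dataset(path)), as.matrix(b1))
})
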