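# Independent oracles used across the test files.

# Upper orthant probability Pr(Z1 > h, Z2 > k) for standard bivariate normal
# with correlation rho, via the single-integral representation
#   Pr = Pr(Z1>h) Pr(Z2>k) + int_0^rho phi2(h, k, r) dr.
orthant_upper <- function(h, k, rho) {
  phi2 <- function(r) {
    exp(-(h^2 - 2 * r * h * k + k^2) / (2 * (1 - r^2))) /
      (2 * pi * sqrt(1 - r^2))
  }
  (1 - pnorm(h)) * (1 - pnorm(k)) +
    stats::integrate(Vectorize(phi2), 0, rho)$value
}

# Population probability-based covariance pieces of dichotomized one-factor
# normal data: success probabilities `probs`, latent correlation rho.
pop_binary_joint <- function(probs, rho) {
  p <- length(probs)
  z <- qnorm(1 - probs)
  J <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) {
    for (j in i:p) {
      J[i, j] <- J[j, i] <- if (i == j) probs[i] else
        orthant_upper(z[i], z[j], rho)
    }
  }
  J
}

# mdcfa_margins object holding exact population values, with optional
# shared-row planned missingness in `columns` at rate `percent`
# (missing counted as "not 1", denominator N).
pop_margins <- function(probs, rho, n = 500, columns = integer(), percent = 0) {
  p <- length(probs)
  J <- pop_binary_joint(probs, rho)
  p_hat <- probs
  if (length(columns) && percent > 0) {
    keep <- 1 - percent
    for (i in seq_len(p)) {
      for (j in seq_len(p)) {
        if (i != j && (i %in% columns || j %in% columns)) {
          J[i, j] <- keep * J[i, j]
        }
      }
    }
    p_hat[columns] <- keep * p_hat[columns]
    diag(J) <- p_hat
  } else {
    diag(J) <- p_hat
  }
  structure(
    list(p_hat = p_hat, joint = J, n = n, items = paste0("item", seq_len(p))),
    class = "mdcfa_margins"
  )
}

# Population linked covariance matrix for the standard study setup.
pop_linked_cov <- function(probs, rho, n = 500, columns = integer(),
                           percent = 0) {
  m <- pop_margins(probs, rho, n, columns, percent)
  design <- missing_design(n, length(probs), columns, percent)
  link_transform(prob_cov(m), m, design = design)
}

# Central-difference numeric gradient.
num_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    hi <- x; lo <- x
    hi[i] <- hi[i] + eps
    lo[i] <- lo[i] - eps
    (f(hi) - f(lo)) / (2 * eps)
  }, numeric(1))
}

# Independent fit oracle: cyclic coordinate descent with 1-D golden-section
# minimization (stats::optimize) of the ML discrepancy. Shares no code with
# the package's gradient-based optimizer.
coord_descent_fit <- function(S, spec, sweeps = 400, upper = 20) {
  two <- spec$kind != "one_factor"
  par <- c(1, if (two) 1, pmax(0.5 * diag(S), 0.05))
  fval <- function(par) {
    theta <- par[(2 + two):length(par)]
    sig <- implied_sigma(spec, par[1], if (two) par[2] else 0, theta)
    tryCatch(ml_discrepancy(S, sig), error = function(e) Inf)
  }
  for (s in seq_len(sweeps)) {
    old <- fval(par)
    for (i in seq_along(par)) {
      lo <- if (i <= 1 + two) 0 else 1e-6
      opt <- stats::optimize(function(v) {
        pp <- par; pp[i] <- v; fval(pp)
      }, lower = lo, upper = upper, tol = 1e-10)
      par[i] <- opt$minimum
    }
    if (old - fval(par) < 1e-12) break
  }
  list(par = par, value = fval(par))
}

# Random positive-definite covariance matrix.
random_pd <- function(p, n = 50) {
  X <- matrix(rnorm(n * p), n, p)
  crossprod(X) / n + 0.1 * diag(p)
}

study_probs <- function(p = 20) seq(0.95, 0.50, length.out = p)
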