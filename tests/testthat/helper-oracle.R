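# Independent oracles and fixture builders shared across tests.
#
# The oracle log-likelihood is written directly from the model definition
# with a parameter layout deliberately different from the package's
# (grouped as intercepts first, then the three slope vectors), and is
# maximized with a generic quasi-Newton optimizer. It never calls package
# internals.

# theta = (a01, a10, a11, b01[1:m], b10[1:m], b11[1:m])
oracle_loglik <- function(theta, x, y, z) {
  m <- ncol(z)
  a <- theta[1:3]
  b01 <- theta[3 + seq_len(m)]
  b10 <- theta[3 + m + seq_len(m)]
  b11 <- theta[3 + 2 * m + seq_len(m)]
  ll <- 0
  for (i in seq_along(x)) {
    zi <- z[i, ]
    e <- c(0,
           a[1] + sum(b01 * zi),
           a[2] + sum(b10 * zi),
           a[3] + sum(b11 * zi))
    cat_i <- 2 * x[i] + y[i] + 1  # 1..4 in the order 00, 01, 10, 11
    ll <- ll + e[cat_i] - log(sum(exp(e)))
  }
  ll
}

# reparameterized likelihood under the homogeneity constraint:
# free = (a01, a10, a11, b01, b10), with b11 = b01 + b10
oracle_loglik_constrained <- function(free, x, y, z) {
  m <- ncol(z)
  b01 <- free[3 + seq_len(m)]
  b10 <- free[3 + m + seq_len(m)]
  oracle_loglik(c(free[1:3], b01, b10, b01 + b10), x, y, z)
}

# generic numerical maximization of either likelihood
oracle_maximize <- function(x, y, z, constrained = FALSE) {
  m <- ncol(z)
  npar <- if (constrained) 3 + 2 * m else 3 + 3 * m
  fn <- if (constrained) oracle_loglik_constrained else oracle_loglik
  opt <- stats::optim(rep(0, npar), fn, x = x, y = y, z = z,
                      method = "BFGS",
                      control = list(fnscale = -1, maxit = 2000,
                                     reltol = 1e-14))
  opt$value
}

# central-difference Hessian of a scalar function (for information checks)
numeric_hessian <- function(f, theta, h = 1e-4) {
  p <- length(theta)
  H <- matrix(0, p, p)
  for (i in seq_len(p)) {
    for (j in i:p) {
      tpp <- tpm <- tmp <- tmm <- theta
      tpp[i] <- tpp[i] + h; tpp[j] <- tpp[j] + h
      tpm[i] <- tpm[i] + h; tpm[j] <- tpm[j] - h
      tmp[i] <- tmp[i] - h; tmp[j] <- tmp[j] + h
      tmm[i] <- tmm[i] - h; tmm[j] <- tmm[j] - h
      H[i, j] <- H[j, i] <- (f(tpp) - f(tpm) - f(tmp) + f(tmm)) / (4 * h^2)
    }
  }
  H
}

# standard simulation conditions: delta = 0, common log OR = log 2,
# one continuous and one binary confounder
hom_alpha <- c(0.25, -0.125, log(2) + 0.125)
hom_beta <- matrix(c(0.5, 0.25, 0.75,
                     0.25, 0.125, 0.375), nrow = 3)  # each column: b11 = b01 + b10
hom_covs <- list(z1 = cov_normal(), z2 = cov_bernoulli(0.4))

sim_hom_data <- function(n, seed) {
  d <- simulate_mh_data(n, hom_alpha, hom_beta, hom_covs, seed = seed)
  mh_data(d, "x", "y", c("z1", "z2"), quiet = TRUE)
}

# random stratified dataset whose saturated fit exists (all cells positive
# in every stratum); used for the categorical-covariate identity checks
sim_strata_data <- function(k, n_per = 80, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    probs <- matrix(runif(4 * k, 0.10, 0.40), k, 4)
    probs <- probs / rowSums(probs)
    d <- simulate_stratified(probs, n_per)
    tab <- table(d$stratum, paste0(d$x, d$y))
    if (ncol(tab) == 4L && all(tab > 0)) return(d)
  }
}
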