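test_that("saturated m = 0 fit reproduces the closed-form intercepts", {
  # equal cell counts: all intercepts zero
  df <- data.frame(x = rep(c(0, 0, 1, 1), 8), y = rep(c(0, 1, 0, 1), 8))
  fit <- fit_mh_multinomial(mh_data(df, "x", "y"))
  expect_equal(unname(fit$alpha), c(0, 0, 0), tolerance = 1e-8)

  # general counts: alpha_xy = log(n_xy / n_00)
  counts <- c(n00 = 12, n01 = 7, n10 = 9, n11 = 20)
  df2 <- data.frame(x = rep(c(0, 0, 1, 1), counts),
                    y = rep(c(0, 1, 0, 1), counts))
  fit2 <- fit_mh_multinomial(mh_data(df2, "x", "y"))
  expect_equal(unname(fit2$alpha),
               log(counts[c("n01", "n10", "n11")] / counts["n00"]),
               tolerance = 1e-8, ignore_attr = TRUE)
  # and the fitted probabilities equal the observed cell fractions
  P <- mh_probs(fit2)
  expect_equal(unname(P[1, ]), unname(counts / sum(counts)), tolerance = 1e-8)
})

test_that("unconstrained log-likelihood matches independent optimizers", {
  d <- sim_hom_data(500, seed = 101)
  fit <- fit_mh_multinomial(d)
  # oracle 1: generic quasi-Newton on the likelihood written from scratch
  ll_oracle <- oracle_maximize(d$x, d$y, d$z)
  expect_lt(abs(fit$loglik - ll_oracle), 1e-6)
  # oracle 2: nnet::multinom on the same 4-category response
  cat4 <- factor(2 * d$x + d$y, levels = 0:3)
  nn <- nnet::multinom(cat4 ~ d$z, trace = FALSE, reltol = 1e-14)
  expect_lt(abs(fit$loglik - stats::logLik(nn)), 1e-6)
})

test_that("constrained fit maximizes the reparameterized likelihood and nests", {
  d <- sim_hom_data(500, seed = 102)
  fit_u <- fit_mh_multinomial(d)
  fit_c <- fit_mh_multinomial(d, constrained = TRUE)
  # the constraint holds exactly by construction
  expect_equal(unname(fit_c$beta["11", ]),
               unname(fit_c$beta["01", ] + fit_c$beta["10", ]))
  # nested models: constrained log-likelihood never exceeds unconstrained
  expect_lte(fit_c$loglik, fit_u$loglik + 1e-10)
  # independent maximization of the reparameterized likelihood
  ll_oracle <- oracle_maximize(d$x, d$y, d$z, constrained = TRUE)
  expect_lt(abs(fit_c$loglik - ll_oracle), 1e-6)
})

test_that("gradient vanishes at the optimum and information matches a numeric Hessian", {
  d <- sim_hom_data(200, seed = 103)
  for (constrained in c(FALSE, TRUE)) {
    fit <- fit_mh_multinomial(d, constrained = constrained)
    Zd <- cbind(1, d$z)
    idx <- 2L * d$x + d$y
    Yind <- matrix(0, d$n, 3L)
    for (k in 1:3) Yind[idx == k, k] <- 1
    A <- genmh:::constraint_map(d$m, constrained)
    theta_free <- if (constrained) {
      p1 <- d$m + 1L
      c(fit$coefficients[1:(2 * p1)], fit$coefficients[2 * p1 + 1L])
    } else {
      fit$coefficients
    }
    g <- genmh:::mlogit_grad_hess(theta_free, A, Zd, Yind, hess = FALSE)$grad
    expect_lt(max(abs(g)), 1e-7)
    # observed information vs central-difference Hessian of the likelihood
    H_num <- numeric_hessian(
      function(th) genmh:::mlogit_loglik(th, A, Zd, Yind),
      unname(theta_free))
    H_ana <- genmh:::mlogit_grad_hess(theta_free, A, Zd, Yind)$hess
    expect_lt(max(abs(H_num - H_ana)) / max(abs(H_ana)), 1e-4)
  }
})

test_that("likelihood value is invariant to affine covariate rescaling", {
  d <- sim_hom_data(300, seed = 104)
  fit <- fit_mh_multinomial(d)
  z2 <- d$z
  z2[, 1] <- 10 * z2[, 1] + 5
  d2 <- genmh:::mh_data_from_parts(d$x, d$y, z2, template = d)
  fit2 <- fit_mh_multinomial(d2)
  expect_equal(fit$loglik, fit2$loglik, tolerance = 1e-8)
  # slopes transform contragradiently
  expect_equal(unname(fit2$beta[, 1]) * 10, unname(fit$beta[, 1]),
               tolerance = 1e-5)
})

test_that("classification probabilities are a proper, interior simplex", {
  d <- sim_hom_data(400, seed = 105)
  P <- mh_probs(fit_mh_multinomial(d))
  expect_true(all(abs(rowSums(P) - 1) < 1e-12))
  expect_true(all(P > 0 & P < 1))
  # dimension mismatch is caught
  d0 <- mh_data(data.frame(x = rep(c(0, 0, 1, 1), 5),
                           y = rep(c(0, 1, 0, 1), 5)), "x", "y")
  expect_error(mh_probs(fit_mh_multinomial(d), d0), "dimension mismatch")
})

test_that("separated data raise an informative error", {
  # category (1,1) occurs exactly when z > 0: divergent slope
  z <- c(seq(-3, -0.5, length.out = 20), seq(0.5, 3, length.out = 20))
  x <- as.integer(z > 0)
  y <- as.integer(z > 0)
  x[1] <- 1; y[2] <- 1  # keep all four cells occupied
  d <- mh_data(data.frame(x = x, y = y, z = z), "x", "y", "z")
  expect_error(fit_mh_multinomial(d), "separation|convergence|Step-halving")
})

test_that("a missing (x, y) cell is rejected up front", {
  df <- data.frame(x = rep(0, 20), y = rep(c(0, 1), 10))
  expect_error(fit_mh_multinomial(mh_data(df, "x", "y")), "four")
})

test_that("tidy and glance return the fit as tibbles", {
  d <- sim_hom_data(300, seed = 106)
  fit <- fit_mh_multinomial(d)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 3 * (d$m + 1))
  expect_named(td, c("category", "term", "estimate", "std.error",
                     "statistic", "p.value"))
  gl <- glance(fit)
  expect_equal(gl$logLik, fit$loglik)
  expect_equal(gl$df, 3 + 3 * d$m)
  expect_equal(glance(fit_mh_multinomial(d, constrained = TRUE))$df,
               3 + 2 * d$m)
})
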