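test_that("classical MH reduces to the crude OR for a single stratum", {
  s <- tibble::tibble(stratum = "a", n00 = 10, n01 = 5, n10 = 5, n11 = 10)
  est <- or_classical_mh(s)
  expect_equal(est$or, 4)
  # replication invariance: two identical strata give the same OR
  est2 <- or_classical_mh(dplyr::bind_rows(s, s))
  expect_equal(est2$or, 4)
  # RBG SE of one stratum equals the crude closed form
  expect_equal(est$se_log_or, sqrt(1 / 10 + 1 / 5 + 1 / 5 + 1 / 10))
})

test_that("zero-margin strata contribute nothing to the MH sums", {
  s <- tibble::tibble(stratum = c("a", "b"),
                      n00 = c(10, 0), n01 = c(5, 0),
                      n10 = c(5, 3), n11 = c(10, 7))
  est <- or_classical_mh(s)
  expect_equal(est$or, 4)
  # all-degenerate strata: infinite / undefined cases are reported distinctly
  s_inf <- tibble::tibble(n00 = 5, n01 = 0, n10 = 0, n11 = 5)
  est_inf <- or_classical_mh(s_inf)
  expect_equal(est_inf$log_or, Inf)
  expect_true(is.na(est_inf$se_log_or))
  s_zero <- tibble::tibble(n00 = 0, n01 = 5, n10 = 5, n11 = 0)
  expect_equal(or_classical_mh(s_zero)$log_or, -Inf)
})

test_that("classical MH agrees with the reference stratified test", {
  d <- sim_strata_data(k = 4, n_per = 60, seed = 21)
  s <- mh_stratify(d, "stratum")
  est <- or_classical_mh(s)
  arr <- array(0, dim = c(2, 2, nrow(s)))
  for (i in seq_len(nrow(s))) {
    arr[, , i] <- matrix(c(s$n11[i], s$n01[i], s$n10[i], s$n00[i]), 2, 2)
  }
  ref <- stats::mantelhaen.test(arr, correct = FALSE)
  expect_equal(est$or, unname(ref$estimate), tolerance = 1e-10)
})

test_that("generalized MH from a saturated fit reproduces count-based estimators", {
  # m = 0: equals the crude OR of the marginal table
  counts <- c(14, 9, 11, 22)
  df <- data.frame(x = rep(c(0, 0, 1, 1), counts),
                   y = rep(c(0, 1, 0, 1), counts))
  d0 <- mh_data(df, "x", "y")
  gmh <- or_generalized_mh(fit_mh_multinomial(d0))
  expect_equal(gmh$or, (22 * 14) / (11 * 9), tolerance = 1e-8)
  # one categorical covariate: equals the classical stratified estimator
  ds <- sim_strata_data(k = 3, n_per = 70, seed = 22)
  d <- mh_data(ds, "x", "y", "stratum")
  gmh_s <- or_generalized_mh(fit_mh_multinomial(d), se = FALSE)
  cls <- or_classical_mh(mh_stratify(ds, "stratum"))
  expect_equal(gmh_s$or, cls$or, tolerance = 1e-6)
})

test_that("generalized MH is a weighted mean of subject-specific odds ratios", {
  d <- sim_hom_data(400, seed = 23)
  fit <- fit_mh_multinomial(d)
  P <- mh_probs(fit)
  subject_or <- (P[, "p11"] * P[, "p00"]) / (P[, "p10"] * P[, "p01"])
  est <- or_generalized_mh(fit, se = FALSE)
  expect_gte(est$or, min(subject_or) - 1e-12)
  expect_lte(est$or, max(subject_or) + 1e-12)
})

test_that("subject-specific log ORs are affine in z and constant when constrained", {
  het_beta <- matrix(c(0.4, 0.2, 1.1, 0.3, 0.1, -0.2), nrow = 3)
  sim <- simulate_mh_data(600, hom_alpha, het_beta, hom_covs, seed = 24)
  d <- mh_data(sim, "x", "y", c("z1", "z2"), quiet = TRUE)
  fit_u <- fit_mh_multinomial(d)
  eta <- subject_log_or(fit_u)$eta
  # regressing eta on z recovers the fitted delta exactly (affine identity)
  co <- coef(stats::lm(eta ~ d$z))
  delta_hat <- fit_u$beta["11", ] - fit_u$beta["10", ] - fit_u$beta["01", ]
  expect_equal(unname(co[-1]), unname(delta_hat), tolerance = 1e-10)
  expect_equal(unname(co[1]),
               unname(fit_u$alpha["11"] - fit_u$alpha["10"] - fit_u$alpha["01"]),
               tolerance = 1e-10)
  # constrained fit: constant vector equal to the intercept contrast
  fit_c <- fit_mh_multinomial(d, constrained = TRUE)
  eta_c <- subject_log_or(fit_c)$eta
  expect_equal(sd(eta_c), 0)
  expect_equal(eta_c[1],
               unname(fit_c$alpha["11"] - fit_c$alpha["10"] - fit_c$alpha["01"]))
})

test_that("constrained ML estimator: closed form at m = 0 and identity with the probability formula", {
  counts <- c(18, 7, 12, 25)
  df <- data.frame(x = rep(c(0, 0, 1, 1), counts),
                   y = rep(c(0, 1, 0, 1), counts))
  d0 <- mh_data(df, "x", "y")
  fit_c0 <- fit_mh_multinomial(d0, constrained = TRUE)
  est0 <- or_constrained_ml(fit_c0)
  expect_equal(est0$log_or, log(25 * 18 / (12 * 7)), tolerance = 1e-8)
  expect_equal(est0$se_log_or, sqrt(sum(1 / counts)), tolerance = 1e-6)

  d <- sim_hom_data(800, seed = 25)
  fit_c <- fit_mh_multinomial(d, constrained = TRUE)
  est <- or_constrained_ml(fit_c)
  gmh_c <- or_generalized_mh(fit_c, se = FALSE)
  expect_equal(est$log_or, gmh_c$log_or, tolerance = 1e-6)
  # unconstrained fits are rejected
  expect_error(or_constrained_ml(fit_mh_multinomial(d)), "constrained")
})

test_that("constrained estimator recovers a known common log OR in simulation", {
  study <- run_mh_study(800, hom_alpha, hom_beta, hom_covs,
                        replicates = 60, seed = 26)
  mc_se <- study$summary$empirical_se_cml / sqrt(nrow(study$replicates))
  expect_lt(abs(study$summary$mean_log_or_cml - log(2)), 3 * mc_se)
})

test_that("estimators respond correctly to relabelling X and swapping X with Y", {
  d <- sim_hom_data(500, seed = 27)
  fit_u <- fit_mh_multinomial(d)
  fit_c <- fit_mh_multinomial(d, constrained = TRUE)
  # X <-> Y swap leaves every estimator invariant
  d_swap <- genmh:::mh_data_from_parts(d$y, d$x, d$z, template = d)
  fu_s <- fit_mh_multinomial(d_swap)
  fc_s <- fit_mh_multinomial(d_swap, constrained = TRUE)
  expect_equal(or_generalized_mh(fu_s)$log_or,
               or_generalized_mh(fit_u)$log_or, tolerance = 1e-10)
  expect_equal(or_constrained_ml(fc_s)$log_or,
               or_constrained_ml(fit_c)$log_or, tolerance = 1e-10)
  expect_equal(or_crude(d_swap)$log_or, or_crude(d)$log_or)
  # relabelling X (0 <-> 1) maps every OR to its reciprocal
  d_rel <- genmh:::mh_data_from_parts(1L - d$x, d$y, d$z, template = d)
  expect_equal(or_generalized_mh(fit_mh_multinomial(d_rel), se = FALSE)$log_or,
               -or_generalized_mh(fit_u, se = FALSE)$log_or, tolerance = 1e-8)
  expect_equal(or_constrained_ml(fit_mh_multinomial(d_rel, constrained = TRUE))$log_or,
               -or_constrained_ml(fit_c)$log_or, tolerance = 1e-8)
  expect_equal(or_crude(d_rel)$log_or, -or_crude(d)$log_or)
})

test_that("confidence limits are the exponentiated log-scale limits", {
  d <- sim_hom_data(300, seed = 28)
  est <- or_crude(d)
  zq <- qnorm(0.975)
  expect_equal(est$ci_low, exp(est$log_or - zq * est$se_log_or))
  expect_equal(est$ci_high, exp(est$log_or + zq * est$se_log_or))
  expect_true(est$ci_low < est$or && est$or < est$ci_high)
})
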