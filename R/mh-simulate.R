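#' Covariate distribution specifications for the simulator
#'
#' Constructors for the per-column covariate laws understood by
#' [simulate_mh_data()]: normal, Bernoulli, and uniform. These three
#' families are enough to emulate typical epidemiological covariates
#' (a continuous age-type variable, binary group indicators, and
#' dummy-coded ordinal groupings).
#'
#' @param mean,sd Normal parameters.
#' @param p Bernoulli success probability.
#' @param min,max Uniform endpoints.
#' @return A covariate-law object used in the `covariates` list.
#' @name covariate_laws
NULL

#' @rdname covariate_laws
#' @export
cov_normal <- function(mean = 0, sd = 1) {
  stopifnot(is.finite(mean), is.finite(sd), sd > 0)
  structure(list(law = "normal", mean = mean, sd = sd), class = "mh_cov_law")
}

#' @rdname covariate_laws
#' @export
cov_bernoulli <- function(p = 0.5) {
  stopifnot(is.finite(p), p > 0, p < 1)
  structure(list(law = "bernoulli", p = p), class = "mh_cov_law")
}

#' @rdname covariate_laws
#' @export
cov_uniform <- function(min = 0, max = 1) {
  stopifnot(is.finite(min), is.finite(max), max > min)
  structure(list(law = "uniform", min = min, max = max), class = "mh_cov_law")
}

draw_covariate <- function(law, n) {
  switch(law$law,
         normal = rnorm(n, law$mean, law$sd),
         bernoulli = rbinom(n, 1L, law$p),
         uniform = runif(n, law$min, law$max),
         abort(paste0("Unknown covariate law: ", law$law)))
}

#' Simulate subject-level data from the joint multinomial logistic model
#'
#' Draws covariates i.i.d. from the given laws, computes the four
#' (x, y)-category probabilities from the multinomial logistic model with
#' the supplied intercepts and slopes, samples one category per subject,
#' and decodes it to the pair (x, y). Because the generator and the fitted
#' model share one parameterization, the implied heterogeneity vector
#' `delta = beta_11 - beta_01 - beta_10` and the subject-specific log odds
#' ratio `(alpha_11 - alpha_10 - alpha_01) + delta' z` are known exactly
#' and are attached to the result.
#'
#' @param n Number of subjects.
#' @param alpha Numeric length-3 intercepts for categories (0,1), (1,0),
#'   (1,1); the (0,0) category is the reference with zero intercept.
#' @param beta `NULL` (no covariates) or a 3-by-m numeric matrix of slopes,
#'   rows in the category order (0,1), (1,0), (1,1).
#' @param covariates Named list of covariate laws (see [covariate_laws]);
#'   length must equal `ncol(beta)`.
#' @param seed Optional integer seed; the same seed reproduces the dataset
#'   exactly.
#' @return A tibble with columns `x`, `y` and one column per covariate,
#'   carrying a `truth` attribute (list with `alpha`, `beta`, `delta`,
#'   `log_psi0 = alpha_11 - alpha_10 - alpha_01`, and `eta` — the true
#'   subject-specific log odds ratios).
#'
#' @examples
#' d <- simulate_mh_data(200, alpha = c(0, 0, log(2)), seed = 7)
#' table(d$x, d$y)
#' @export
simulate_mh_data <- function(n, alpha, beta = NULL,
                             covariates = list(), seed = NULL) {
  stopifnot(length(alpha) == 3L, all(is.finite(alpha)))
  m <- length(covariates)
  if (is.null(beta)) beta <- matrix(0, 3L, m)
  if (!is.matrix(beta) || nrow(beta) != 3L || ncol(beta) != m ||
      any(!is.finite(beta))) {
    abort("`beta` must be a finite 3-by-m matrix matching `covariates`.")
  }
  if (m > 0 && is.null(names(covariates))) {
    names(covariates) <- paste0("z", seq_len(m))
  }
  if (!is.null(seed)) set.seed(seed)
  Z <- if (m > 0) {
    vapply(covariates, draw_covariate, numeric(n), n = n)
  } else {
    matrix(numeric(0), n, 0)
  }
  if (m > 0 && n == 1L) Z <- matrix(Z, 1L, m)
  Eta <- matrix(alpha, n, 3L, byrow = TRUE)
  if (m > 0) Eta <- Eta + Z %*% t(beta)
  M <- pmax(0, apply(Eta, 1L, max))
  E0 <- exp(-M)
  E <- exp(Eta - M)
  P <- cbind(E0, E) / (E0 + rowSums(E))
  u <- runif(n)
  cum <- t(apply(P, 1L, cumsum))
  cat_idx <- rowSums(u > cum[, 1:3, drop = FALSE])   # 0..3 = 00,01,10,11
  x <- as.integer(cat_idx >= 2L)
  y <- as.integer(cat_idx %% 2L)
  delta <- if (m > 0) beta[3L, ] - beta[1L, ] - beta[2L, ] else numeric(0)
  log_psi0 <- alpha[3L] - alpha[2L] - alpha[1L]
  eta_true <- rep(log_psi0, n)
  if (m > 0) eta_true <- eta_true + as.vector(Z %*% delta)
  out <- tibble::tibble(x = x, y = y)
  if (m > 0) out <- dplyr::bind_cols(out, tibble::as_tibble(Z))
  attr(out, "truth") <- list(alpha = alpha, beta = beta, delta = delta,
                             log_psi0 = log_psi0, eta = eta_true)
  out
}

#' Simulate stratified 2-by-2 data with a categorical covariate
#'
#' Each stratum's (x, y) pair is drawn from its own four-cell multinomial
#' distribution, and the stratum label is attached as a single categorical
#' covariate. This is the sampling design under which a saturated joint
#' multinomial fit followed by the generalized Mantel-Haenszel formula
#' reproduces the classical stratified Mantel-Haenszel estimator exactly.
#'
#' @param probs A k-by-4 matrix of cell probabilities per stratum, columns
#'   in the order (0,0), (0,1), (1,0), (1,1); rows must sum to one.
#' @param n_per_stratum Integer vector of stratum sizes (length k, or a
#'   single size recycled).
#' @param seed Optional integer seed.
#' @return A tibble with columns `x`, `y`, `stratum` (factor).
#' @export
simulate_stratified <- function(probs, n_per_stratum, seed = NULL) {
  probs <- as.matrix(probs)
  k <- nrow(probs)
  stopifnot(k >= 1L, ncol(probs) == 4L, all(probs >= 0),
            all(abs(rowSums(probs) - 1) < 1e-8))
  n_per_stratum <- as.integer(rep(n_per_stratum, length.out = k))
  if (any(n_per_stratum < 1L)) abort("Stratum sizes must be positive.")
  if (!is.null(seed)) set.seed(seed)
  rows <- purrr::map(seq_len(k), function(i) {
    ni <- n_per_stratum[i]
    cat_idx <- sample.int(4L, ni, replace = TRUE, prob = probs[i, ]) - 1L
    tibble::tibble(x = as.integer(cat_idx >= 2L),
                   y = as.integer(cat_idx %% 2L),
                   stratum = paste0("s", i))
  })
  out <- dplyr::bind_rows(rows)
  out$stratum <- factor(out$stratum, levels = paste0("s", seq_len(k)))
  out
}

#' Simulation study: bias, coverage, and homogeneity-test operating
#' characteristics
#'
#' Repeatedly simulates from the joint multinomial logistic model, fits
#' the unconstrained and homogeneity-constrained models to each replicate,
#' and records the constrained ML and generalized MH estimates with their
#' model standard errors, interval coverage of the true common log odds
#' ratio (when `delta = 0`), and the Wald and likelihood-ratio homogeneity
#' tests. One master seed spawns an independent sub-seed per replicate, so
#' the study is reproducible and replicates are independent. Replicate-level
#' fit failures are caught, counted, and excluded from summaries.
#'
#' @inheritParams simulate_mh_data
#' @param replicates Number of simulated datasets.
#' @param seed Master integer seed.
#' @param conf_level Confidence level used for coverage.
#' @param alpha_level Significance level used for rejection rates.
#' @return A list of class `mh_study` with `replicates` (one tibble row per
#'   successful replicate), `summary` (a one-row tibble: mean estimate,
#'   bias, empirical SE, mean model SE, coverage, rejection rates, failure
#'   rate), and the generating `truth`.
#' @export
run_mh_study <- function(n, alpha, beta = NULL, covariates = list(),
                         replicates = 100L, seed = 1L, conf_level = 0.95,
                         alpha_level = 0.05) {
  stopifnot(replicates >= 1L)
  m <- length(covariates)
  if (is.null(beta)) beta <- matrix(0, 3L, m)
  delta <- if (m > 0) beta[3L, ] - beta[1L, ] - beta[2L, ] else numeric(0)
  homogeneous <- m == 0L || all(abs(delta) < 1e-12)
  true_log_psi <- if (homogeneous) alpha[3L] - alpha[2L] - alpha[1L] else NA_real_
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, replicates)
  zq <- qnorm(1 - (1 - conf_level) / 2)
  one_rep <- function(r) {
    sim <- simulate_mh_data(n, alpha, beta, covariates, seed = rep_seeds[r])
    zc <- setdiff(names(sim), c("x", "y"))
    d <- mh_data(sim, "x", "y", zc, quiet = TRUE)
    fu <- fit_mh_multinomial(d)
    fc <- fit_mh_multinomial(d, constrained = TRUE)
    cml <- or_constrained_ml(fc, conf_level)
    gmh <- or_generalized_mh(fu, se = TRUE, conf_level = conf_level)
    tests <- test_homogeneity(fu, fc)
    tibble::tibble(
      replicate = r,
      log_or_cml = cml$log_or, se_cml = cml$se_log_or,
      log_or_gmh = gmh$log_or, se_gmh = gmh$se_log_or,
      covered = !is.na(true_log_psi) &
        abs(cml$log_or - true_log_psi) <= zq * cml$se_log_or,
      wald_stat = tests$statistic[tests$method == "wald"],
      wald_p = tests$p_value[tests$method == "wald"],
      lr_stat = tests$statistic[tests$method == "lr"],
      lr_p = tests$p_value[tests$method == "lr"]
    )
  }
  res <- purrr::map(seq_len(replicates), function(r) {
    tryCatch(one_rep(r), error = function(e) NULL)
  })
  failures <- sum(purrr::map_lgl(res, is.null))
  reps <- dplyr::bind_rows(res)
  if (nrow(reps) == 0L) abort("All replicates failed to fit.")
  summary <- tibble::tibble(
    n = n, m = m, replicates = replicates,
    n_failed = failures,
    true_log_psi = true_log_psi,
    mean_log_or_cml = mean(reps$log_or_cml),
    bias_cml = mean(reps$log_or_cml) - true_log_psi,
    empirical_se_cml = sd(reps$log_or_cml),
    mean_model_se_cml = mean(reps$se_cml),
    coverage_cml = if (homogeneous) mean(reps$covered) else NA_real_,
    mean_log_or_gmh = mean(reps$log_or_gmh),
    wald_reject = mean(reps$wald_p < alpha_level),
    lr_reject = mean(reps$lr_p < alpha_level),
    mean_lr_stat = mean(reps$lr_stat)
  )
  structure(list(replicates = reps, summary = summary,
                 truth = list(alpha = alpha, beta = beta, delta = delta,
                              log_psi = true_log_psi)),
            class = "mh_study")
}

#' @export
print.mh_study <- function(x, ...) {
  cat("<mh_study> ", nrow(x$replicates), " successful replicate(s)\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @rdname run_mh_study
#' @param x An `mh_study` object.
#' @param ... Unused.
#' @method tidy mh_study
#' @export
tidy.mh_study <- function(x, ...) x$replicates

#' @rdname run_mh_study
#' @method glance mh_study
#' @export
glance.mh_study <- function(x, ...) x$summary
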