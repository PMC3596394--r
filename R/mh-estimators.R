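#' @keywords internal
#' @noRd
new_or_summary <- function(estimator, log_or, se_log_or, n,
                           conf_level = 0.95) {
  zq <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    estimator = estimator,
    or = exp(log_or),
    log_or = log_or,
    se_log_or = se_log_or,
    ci_low = exp(log_or - zq * se_log_or),
    ci_high = exp(log_or + zq * se_log_or),
    n = n
  )
}

#' Crude (unadjusted) odds ratio
#'
#' Odds ratio of the marginal 2-by-2 table of (x, y), with the standard
#' large-sample log-scale standard error
#' `sqrt(1/n00 + 1/n01 + 1/n10 + 1/n11)`.
#'
#' @param data An [mh_data] object.
#' @param conf_level Confidence level for the interval.
#' @return A one-row tibble with columns `estimator`, `or`, `log_or`,
#'   `se_log_or`, `ci_low`, `ci_high`, `n`.
#' @export
or_crude <- function(data, conf_level = 0.95) {
  tab <- marginal_table(data)
  log_or <- log(tab["n11"]) + log(tab["n00"]) - log(tab["n10"]) - log(tab["n01"])
  se <- sqrt(sum(1 / tab))
  new_or_summary("crude", unname(log_or), unname(se), data$n, conf_level)
}

#' Classical Mantel-Haenszel odds ratio over discrete strata
#'
#' The stratum-pooled estimator
#' `sum_i(n11_i n00_i / n_i) / sum_i(n10_i n01_i / n_i)`, with the
#' Robins-Breslow-Greenland variance for the log odds ratio. Strata with a
#' zero margin contribute zero to both sums and are effectively ignored.
#' When a sum is zero the log odds ratio is reported as +/-Inf with a
#' missing standard error rather than an error.
#'
#' @param strata An `mh_strata` table from [mh_stratify()], or any data
#'   frame with columns `n00`, `n01`, `n10`, `n11`.
#' @param conf_level Confidence level for the interval.
#' @return A one-row tibble (see [or_crude()] for columns).
#' @export
or_classical_mh <- function(strata, conf_level = 0.95) {
  need <- c("n00", "n01", "n10", "n11")
  stopifnot(all(need %in% names(strata)))
  ni <- strata$n00 + strata$n01 + strata$n10 + strata$n11
  keep <- ni > 0
  s <- strata[keep, , drop = FALSE]
  ni <- ni[keep]
  R <- s$n11 * s$n00 / ni
  S <- s$n10 * s$n01 / ni
  Rs <- sum(R)
  Ss <- sum(S)
  n_total <- sum(ni)
  if (Rs == 0 && Ss == 0) {
    abort("Mantel-Haenszel odds ratio undefined: all strata have zero margins.")
  }
  if (Ss == 0) {
    return(new_or_summary("classical_mh", Inf, NA_real_, n_total, conf_level))
  }
  if (Rs == 0) {
    return(new_or_summary("classical_mh", -Inf, NA_real_, n_total, conf_level))
  }
  log_or <- log(Rs) - log(Ss)
  P <- (s$n11 + s$n00) / ni
  Q <- (s$n10 + s$n01) / ni
  v <- sum(P * R) / (2 * Rs^2) +
    sum(P * S + Q * R) / (2 * Rs * Ss) +
    sum(Q * S) / (2 * Ss^2)
  new_or_summary("classical_mh", log_or, sqrt(v), n_total, conf_level)
}

#' Generalized (model-based) Mantel-Haenszel odds ratio
#'
#' Replaces observed stratum cell counts with subject-specific
#' classification probabilities from a joint multinomial logistic fit:
#' `OR = sum_i(p11_i p00_i) / sum_i(p10_i p01_i)`, summing over subjects.
#' The estimate can be read as a weighted mean of the subject-specific
#' odds ratios `(p11_i p00_i) / (p10_i p01_i)`. The standard error of the
#' log odds ratio is the delta-method propagation of the maximum-likelihood
#' parameter covariance through the softmax probabilities (see
#' [delta_se_log_gmh()]).
#'
#' By default the unconstrained fit supplies the probabilities; passing a
#' constrained fit evaluates the same formula on homogeneity-model
#' probabilities, where it coincides with the constrained ML estimator.
#'
#' @param fit An `mh_mlogit` fit (unconstrained or constrained).
#' @param se Attach the delta-method standard error? If `FALSE` the SE and
#'   interval are `NA` (point estimate only).
#' @param conf_level Confidence level for the interval.
#' @return A one-row tibble (see [or_crude()] for columns).
#' @export
or_generalized_mh <- function(fit, se = TRUE, conf_level = 0.95) {
  stopifnot(inherits(fit, "mh_mlogit"))
  P <- mh_probs(fit)
  log_or <- log(sum(P[, "p11"] * P[, "p00"])) -
    log(sum(P[, "p10"] * P[, "p01"]))
  se_val <- if (se) delta_se_log_gmh(fit) else NA_real_
  new_or_summary("generalized_mh", log_or, se_val, fit$n, conf_level)
}

#' Subject-specific log odds ratios
#'
#' Under the joint multinomial logistic model the log odds ratio of subject
#' i is `eta_i = (alpha_11 - alpha_10 - alpha_01) +
#' (beta_11 - beta_10 - beta_01)' z_i`. It is constant across subjects
#' exactly when `delta = beta_11 - beta_01 - beta_10 = 0` (homogeneity); a
#' constrained fit therefore yields a constant vector. Under apparent
#' heterogeneity these values can be regressed on covariates to explore
#' effect modification.
#'
#' @param fit An `mh_mlogit` fit.
#' @param data Optional `mh_data` (defaults to the fitted data).
#' @return A tibble with columns `subject` and `eta` (log odds ratio).
#' @export
subject_log_or <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "mh_mlogit"))
  data <- data %||% fit$data
  if (data$m != fit$m) abort("Covariate dimension mismatch.")
  a <- fit$alpha
  const <- unname(a["11"] - a["10"] - a["01"])
  eta <- rep(const, data$n)
  if (fit$m > 0) {
    d <- fit$beta["11", ] - fit$beta["10", ] - fit$beta["01", ]
    eta <- eta + as.vector(data$z %*% d)
  }
  tibble::tibble(subject = seq_len(data$n), eta = eta)
}

#' Average-of-subject-specific log odds ratio estimator
#'
#' The mean of the subject-specific log odds ratios `eta_i`, an alternative
#' summary estimator of log(OR). Its standard error is obtained by the
#' delta method with gradient equal to the average of the per-subject
#' gradients (which are linear in the parameters, so the gradient is exact).
#'
#' @inheritParams or_generalized_mh
#' @return A one-row tibble (see [or_crude()] for columns).
#' @export
or_avg_subject <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "mh_mlogit"))
  eta <- subject_log_or(fit)$eta
  log_or <- mean(eta)
  # eta_bar = c(-u, -u, u)' theta with u = (1, mean(z)); exact linear form
  u <- c(1, if (fit$m > 0) colMeans(fit$data$z) else numeric(0))
  g <- c(-u, -u, u)
  se <- sqrt(as.numeric(t(g) %*% fit$vcov %*% g))
  new_or_summary("avg_subject_specific", log_or, se, fit$n, conf_level)
}

#' Constrained maximum-likelihood odds ratio (homogeneity model)
#'
#' Under the homogeneity constraint `delta = 0` the common log odds ratio
#' is the intercept contrast `alpha_11 - alpha_10 - alpha_01` of the
#' constrained fit; its standard error comes from the corresponding
#' contrast of the constrained-fit covariance. This estimator is identical
#' to the generalized Mantel-Haenszel formula evaluated on the
#' constrained-fit classification probabilities.
#'
#' @param fit A constrained `mh_mlogit` fit (from
#'   `fit_mh_multinomial(data, constrained = TRUE)`).
#' @param conf_level Confidence level for the interval.
#' @return A one-row tibble (see [or_crude()] for columns).
#' @export
or_constrained_ml <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "mh_mlogit"))
  if (!fit$constrained) {
    abort("`fit` must be a constrained (homogeneity) fit; see fit_mh_multinomial(constrained = TRUE).")
  }
  p1 <- fit$m + 1L
  cvec <- rep(0, 3L * p1)
  cvec[1L] <- -1          # alpha_01
  cvec[p1 + 1L] <- -1     # alpha_10
  cvec[2L * p1 + 1L] <- 1 # alpha_11
  log_or <- as.numeric(cvec %*% fit$coefficients)
  se <- sqrt(as.numeric(t(cvec) %*% fit$vcov %*% cvec))
  new_or_summary("constrained_ml", log_or, se, fit$n, conf_level)
}
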