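#' Delta-method standard error of the log generalized MH odds ratio
#'
#' Propagates the maximum-likelihood parameter covariance to the variance
#' of `log(sum_i p11_i p00_i / sum_i p10_i p01_i)` by a first-order Taylor
#' expansion: `SE = sqrt(g' Sigma g)` where `g` is the gradient of the
#' log-ratio with respect to the full parameter vector, obtained
#' analytically by the chain rule through the softmax probabilities. A
#' central finite-difference path is available for verification.
#'
#' @param fit An `mh_mlogit` fit (unconstrained or constrained; the
#'   constrained fit's covariance is already expanded to the full
#'   parameterization).
#' @param method `"analytic"` (default) or `"fd"` (central finite
#'   differences on the log-ratio, step `h`).
#' @param h Finite-difference step for `method = "fd"`.
#' @return The nonnegative standard error of the log odds ratio.
#' @export
delta_se_log_gmh <- function(fit, method = c("analytic", "fd"), h = 1e-6) {
  stopifnot(inherits(fit, "mh_mlogit"))
  method <- match.arg(method)
  g <- if (method == "analytic") grad_log_gmh(fit) else grad_log_gmh_fd(fit, h)
  V <- fit$vcov
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    abort("Covariance matrix is not positive semidefinite.")
  }
  sqrt(max(0, as.numeric(t(g) %*% V %*% g)))
}

# analytic gradient of log(sum p11 p00 / sum p10 p01) wrt the full
# stacked parameter vector (theta_01, theta_10, theta_11)
grad_log_gmh <- function(fit, data = NULL) {
  data <- data %||% fit$data
  P <- mh_probs(fit, data)
  Zd <- cbind(1, data$z)
  N <- sum(P[, "p11"] * P[, "p00"])
  D <- sum(P[, "p10"] * P[, "p01"])
  # dp_c/deta_k = p_c (1{c=k} - p_k) for non-reference k in {01, 10, 11}
  # => d(p11 p00)/deta_k = p11 p00 (1{k=11} - 2 p_k)
  #    d(p10 p01)/deta_k = p10 p01 (1{k=01} + 1{k=10} - 2 p_k)
  num <- P[, "p11"] * P[, "p00"]
  den <- P[, "p10"] * P[, "p01"]
  g <- numeric(3L * ncol(Zd))
  cats <- c("p01", "p10", "p11")
  for (k in 1:3) {
    dN <- num * ((k == 3) - 2 * P[, cats[k]])
    dD <- den * ((k == 1) + (k == 2) - 2 * P[, cats[k]])
    w <- dN / N - dD / D
    g[((k - 1L) * ncol(Zd) + 1L):(k * ncol(Zd))] <- crossprod(Zd, w)
  }
  g
}

# central finite-difference gradient of the same log-ratio
grad_log_gmh_fd <- function(fit, h = 1e-6) {
  data <- fit$data
  Zd <- cbind(1, data$z)
  p1 <- ncol(Zd)
  f <- function(theta) {
    B <- matrix(theta, nrow = p1)
    Eta <- Zd %*% B
    M <- pmax(0, apply(Eta, 1L, max))
    E0 <- exp(-M)
    E <- exp(Eta - M)
    denom <- E0 + rowSums(E)
    P <- cbind(E0, E) / denom
    log(sum(P[, 4L] * P[, 1L])) - log(sum(P[, 3L] * P[, 2L]))
  }
  theta <- unname(fit$coefficients)
  vapply(seq_along(theta), function(j) {
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    (f(tp) - f(tm)) / (2 * h)
  }, numeric(1))
}

#' Test homogeneity of the odds ratio across covariate values
#'
#' Tests `H0: delta = beta_11 - beta_01 - beta_10 = 0`, under which the
#' subject-specific odds ratio does not depend on the covariates and a
#' single summary odds ratio is meaningful. The Wald statistic is
#' `delta' V_delta^{-1} delta` from the unconstrained fit; the
#' likelihood-ratio statistic is twice the log-likelihood difference
#' between the unconstrained and constrained fits. Both are referred to a
#' chi-square distribution with m degrees of freedom (m = number of design
#' columns). With m = 0 the hypothesis is vacuous and p = 1 is returned.
#'
#' @param fit_u An unconstrained `mh_mlogit` fit.
#' @param fit_c A constrained fit on the same data; required for
#'   `method = "lr"` (fitted automatically if omitted).
#' @param method Which test(s): `"lr"`, `"wald"`, or both (default).
#' @return A tibble with columns `method`, `statistic`, `df`, `p_value`.
#' @export
test_homogeneity <- function(fit_u, fit_c = NULL,
                             method = c("wald", "lr")) {
  stopifnot(inherits(fit_u, "mh_mlogit"))
  if (fit_u$constrained) abort("`fit_u` must be an unconstrained fit.")
  method <- match.arg(method, several.ok = TRUE)
  m <- fit_u$m
  rows <- list()
  if ("wald" %in% method) {
    if (m == 0L) {
      rows$wald <- tibble::tibble(method = "wald", statistic = 0,
                                  df = 0L, p_value = 1)
    } else {
      dc <- delta_contrast(fit_u)
      Vi <- tryCatch(solve(dc$vcov), error = function(e)
        abort("Singular covariance of the delta contrast; Wald test unavailable."))
      stat <- as.numeric(t(dc$delta) %*% Vi %*% dc$delta)
      rows$wald <- tibble::tibble(method = "wald", statistic = stat, df = m,
                                  p_value = pchisq(stat, m, lower.tail = FALSE))
    }
  }
  if ("lr" %in% method) {
    if (is.null(fit_c)) fit_c <- fit_mh_multinomial(fit_u$data, constrained = TRUE)
    if (!fit_c$constrained) abort("`fit_c` must be a constrained fit.")
    stat <- 2 * (fit_u$loglik - fit_c$loglik)
    if (stat < -1e-6) {
      abort(paste0("Negative LR statistic (", signif(stat, 3),
                   "): optimizer failure in one of the fits."))
    }
    stat <- max(0, stat)
    if (m == 0L) {
      rows$lr <- tibble::tibble(method = "lr", statistic = stat,
                                df = 0L, p_value = 1)
    } else {
      rows$lr <- tibble::tibble(method = "lr", statistic = stat, df = m,
                                p_value = pchisq(stat, m, lower.tail = FALSE))
    }
  }
  dplyr::bind_rows(rows)
}

#' Bootstrap standard error of a log odds-ratio estimator
#'
#' Nonparametric bootstrap over subjects: resamples rows with replacement,
#' re-estimates, and reports the standard deviation of the log odds ratio
#' across replicates. Resamples with an empty (x, y) cell are redrawn and
#' the redraw count is recorded as an attribute. Used as an independent
#' cross-check of the delta-method standard errors.
#'
#' @param data An [mh_data] object.
#' @param estimator One of `"generalized_mh"`, `"constrained_ml"`,
#'   `"avg_subject"`, `"crude"`.
#' @param B Number of bootstrap replicates (at least 100 recommended).
#' @param seed Integer seed; the same seed reproduces the same value.
#' @return The bootstrap standard error, with attributes `replicates`
#'   (the B log odds ratios) and `n_redrawn`.
#' @export
bootstrap_se <- function(data, estimator = c("generalized_mh",
                                             "constrained_ml",
                                             "avg_subject", "crude"),
                         B = 500L, seed = 1L) {
  stopifnot(inherits(data, "mh_data"))
  estimator <- match.arg(estimator)
  if (B < 2L) abort("B must be at least 2.")
  point_fun <- switch(
    estimator,
    crude = function(d) or_crude(d)$log_or,
    generalized_mh = function(d)
      or_generalized_mh(fit_mh_multinomial(d), se = FALSE)$log_or,
    avg_subject = function(d) or_avg_subject(fit_mh_multinomial(d))$log_or,
    constrained_ml = function(d)
      or_constrained_ml(fit_mh_multinomial(d, constrained = TRUE))$log_or
  )
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  vals <- numeric(B)
  n_redrawn <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(data$n, data$n, replace = TRUE)
      db <- mh_data_from_parts(data$x[idx], data$y[idx],
                               data$z[idx, , drop = FALSE], template = data)
      if (length(unique(2L * db$x + db$y)) == 4L) break
      n_redrawn <- n_redrawn + 1L
    }
    vals[b] <- point_fun(db)
  }
  structure(sd(vals), replicates = vals, n_redrawn = n_redrawn)
}
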