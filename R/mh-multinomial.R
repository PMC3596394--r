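#' Fit the joint multinomial logistic model for (X, Y) given Z
#'
#' Maximum-likelihood fit of the four-category multinomial logistic model
#' for the joint distribution of two dichotomous variables given covariates.
#' The categories are ordered (00, 01, 10, 11) with (0, 0) as the reference
#' (its intercept and slopes are fixed at zero); each non-reference category
#' `xy` has an intercept `alpha_xy` and a slope vector `beta_xy` of length m.
#'
#' With `constrained = TRUE` the model is fitted under the homogeneity
#' hypothesis that the subject-specific odds ratio does not depend on Z,
#' i.e. `delta = beta_11 - beta_01 - beta_10 = 0`. The constraint is imposed
#' by reparameterization: the free parameters are the three intercepts plus
#' `beta_01` and `beta_10`, and category (1, 1) uses slope
#' `beta_01 + beta_10`. The returned covariance is always expanded to the
#' full `3(m+1)`-dimensional parameterization (via the Jacobian of the
#' constraint map) so downstream delta-method code is fit-agnostic.
#'
#' The log-likelihood is concave; the fitter is Newton-Raphson on the
#' observed information with step-halving, started at zero (uniform
#' category probabilities).
#'
#' @param data An [mh_data] object.
#' @param constrained Fit under the homogeneity constraint `delta = 0`?
#' @param max_iter Iteration cap for Newton-Raphson.
#' @param tol_loglik Convergence tolerance on the relative log-likelihood
#'   change.
#' @param tol_grad Convergence tolerance on the gradient max-norm.
#' @param diverge Declare separation when any parameter exceeds this
#'   magnitude on the linear-predictor scale while the likelihood is still
#'   increasing.
#'
#' @return An object of class `mh_mlogit`: a list with `alpha` (three named
#'   intercepts), `beta` (3-by-m slope matrix with rows "01", "10", "11"),
#'   `coefficients` (full stacked parameter vector), `vcov` (full
#'   `3(m+1)`-square covariance), `loglik`, `converged`, `iterations`,
#'   `constrained`, `n`, `m`, and the fitted `data`.
#'
#' @examples
#' sim <- simulate_mh_data(300, alpha = c(0, 0, log(2)),
#'                         beta = matrix(0.3, 3, 1),
#'                         covariates = list(z1 = cov_normal()), seed = 1)
#' md <- mh_data(sim, "x", "y", "z1")
#' fit <- fit_mh_multinomial(md)
#' fit$loglik
#' @export
fit_mh_multinomial <- function(data, constrained = FALSE, max_iter = 200L,
                               tol_loglik = 1e-10, tol_grad = 1e-8,
                               diverge = 30) {
  stopifnot(inherits(data, "mh_data"))
  n <- data$n
  m <- data$m
  Zd <- cbind(`(Intercept)` = rep(1, n), data$z)
  p1 <- m + 1L                          # block size per category
  idx <- 2L * data$x + data$y           # 0=00, 1=01, 2=10, 3=11
  if (length(unique(idx)) < 4L) {
    abort("All four (x, y) cells must be observed at least once.")
  }
  Yind <- matrix(0, n, 3L)              # indicators for categories 01, 10, 11
  for (k in 1:3) Yind[idx == k, k] <- 1

  A <- constraint_map(m, constrained)   # full (3*p1) x free
  pfree <- ncol(A)

  theta_free <- rep(0, pfree)
  ll <- mlogit_loglik(theta_free, A, Zd, Yind)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    gH <- mlogit_grad_hess(theta_free, A, Zd, Yind)
    gmax <- max(abs(gH$grad))
    step <- tryCatch(solve(-gH$hess, gH$grad),
                     error = function(e) abort(
                       "Newton step failed (singular information); consider reducing covariates."))
    # step-halving to guarantee ascent on the concave likelihood
    lambda <- 1
    repeat {
      cand <- theta_free + lambda * step
      ll_new <- mlogit_loglik(cand, A, Zd, Yind)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) {
        abort(paste0("Step-halving failed at iteration ", iter,
                     "; gradient max-norm ", signif(gmax, 3), "."))
      }
    }
    rel_change <- abs(ll_new - ll) / (abs(ll) + 1e-12)
    theta_free <- cand
    ll <- ll_new
    theta_full <- as.vector(A %*% theta_free)
    if (max(abs(theta_full)) > diverge) {
      abort(paste0("Apparent separation: a parameter exceeded ", diverge,
                   " on the linear-predictor scale. ",
                   "Consider reducing or recoding covariates."))
    }
    gmax_new <- max(abs(mlogit_grad_hess(theta_free, A, Zd, Yind,
                                         hess = FALSE)$grad))
    if (rel_change < tol_loglik && gmax_new < tol_grad) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  if (!converged) {
    gfin <- max(abs(mlogit_grad_hess(theta_free, A, Zd, Yind, hess = FALSE)$grad))
    abort(paste0("No convergence in ", max_iter,
                 " iterations; gradient max-norm ", signif(gfin, 3), "."))
  }

  gH <- mlogit_grad_hess(theta_free, A, Zd, Yind)
  vcov_free <- solve(-gH$hess)
  vcov_full <- A %*% vcov_free %*% t(A)
  theta_full <- as.vector(A %*% theta_free)

  nm <- param_names(colnames(data$z))
  names(theta_full) <- nm
  dimnames(vcov_full) <- list(nm, nm)
  B <- matrix(theta_full, nrow = 3L, byrow = TRUE,
              dimnames = list(c("01", "10", "11"),
                              c("(Intercept)", colnames(data$z))))
  structure(
    list(
      alpha = setNames(B[, 1L], c("01", "10", "11")),
      beta = B[, -1L, drop = FALSE],
      coefficients = theta_full,
      vcov = vcov_full,
      loglik = ll,
      converged = converged,
      iterations = iter,
      constrained = constrained,
      n = n, m = m,
      covariate_names = colnames(data$z),
      data = data
    ),
    class = "mh_mlogit"
  )
}

# linear map from free parameters to the full (theta_01, theta_10, theta_11)
# stacked parameterization, each block (alpha, beta) of length m + 1.
# Unconstrained: identity. Constrained: beta_11 = beta_01 + beta_10, so the
# free vector is (theta_01, theta_10, alpha_11).
constraint_map <- function(m, constrained) {
  p1 <- m + 1L
  pfull <- 3L * p1
  if (!constrained) return(diag(pfull))
  pfree <- 2L * p1 + 1L
  A <- matrix(0, pfull, pfree)
  A[1:p1, 1:p1] <- diag(p1)                       # theta_01
  A[(p1 + 1):(2 * p1), (p1 + 1):(2 * p1)] <- diag(p1)  # theta_10
  A[2 * p1 + 1L, 2 * p1 + 1L] <- 1                # alpha_11
  if (m > 0) {
    for (j in seq_len(m)) {
      A[2 * p1 + 1L + j, 1L + j] <- 1             # beta_11j <- beta_01j
      A[2 * p1 + 1L + j, p1 + 1L + j] <- 1        #          + beta_10j
    }
  }
  A
}

param_names <- function(znames) {
  base <- c("(Intercept)", znames)
  as.vector(vapply(c("01", "10", "11"),
                   function(k) paste0(k, ":", base), character(length(base))))
}

# linear predictors (n x 3) for categories 01, 10, 11 from a free parameter
mlogit_eta <- function(theta_free, A, Zd) {
  p1 <- ncol(Zd)
  theta_full <- as.vector(A %*% theta_free)
  B <- matrix(theta_full, nrow = p1)   # p1 x 3, columns are categories
  Zd %*% B
}

mlogit_loglik <- function(theta_free, A, Zd, Yind) {
  Eta <- mlogit_eta(theta_free, A, Zd)
  sum(Eta * Yind) - sum(log1p_sum_exp(Eta))
}

# gradient and observed-information Hessian in the FREE parameterization
mlogit_grad_hess <- function(theta_free, A, Zd, Yind, hess = TRUE) {
  p1 <- ncol(Zd)
  Eta <- mlogit_eta(theta_free, A, Zd)
  # softmax over (0, Eta): P is n x 3 for the non-reference categories
  M <- pmax(0, apply(Eta, 1L, max))
  E <- exp(Eta - M)
  denom <- exp(-M) + rowSums(E)
  P <- E / denom
  R <- Yind - P
  g_full <- as.vector(vapply(1:3, function(k) crossprod(Zd, R[, k])[, 1L],
                             numeric(p1)))
  out <- list(grad = as.vector(crossprod(A, g_full)))
  if (hess) {
    H <- matrix(0, 3L * p1, 3L * p1)
    for (k in 1:3) {
      for (l in k:3) {
        w <- if (k == l) P[, k] * (1 - P[, k]) else -P[, k] * P[, l]
        blk <- -crossprod(Zd * w, Zd)
        rows <- ((k - 1L) * p1 + 1L):(k * p1)
        cols <- ((l - 1L) * p1 + 1L):(l * p1)
        H[rows, cols] <- blk
        if (l > k) H[cols, rows] <- t(blk)
      }
    }
    out$hess <- crossprod(A, H %*% A)
  }
  out
}

#' Subject-specific classification probabilities
#'
#' Softmax probabilities of the four (x, y) categories for each subject,
#' from a fitted joint multinomial model. Rows are exactly normalized.
#'
#' @param fit An `mh_mlogit` fit.
#' @param data Optional `mh_data` to predict for (defaults to the fitted
#'   data); its covariate dimension must match the fit.
#' @return An n-by-4 numeric matrix with columns `p00`, `p01`, `p10`, `p11`;
#'   every row sums to one and all entries are strictly inside (0, 1).
#' @export
mh_probs <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "mh_mlogit"))
  data <- data %||% fit$data
  if (data$m != fit$m) {
    abort(paste0("Covariate dimension mismatch: fit has m = ", fit$m,
                 ", data has m = ", data$m, "."))
  }
  Zd <- cbind(1, data$z)
  B <- matrix(fit$coefficients, nrow = fit$m + 1L)   # p1 x 3
  Eta <- Zd %*% B
  M <- pmax(0, apply(Eta, 1L, max))
  E0 <- exp(-M)
  E <- exp(Eta - M)
  denom <- E0 + rowSums(E)
  P <- cbind(E0, E) / denom
  colnames(P) <- c("p00", "p01", "p10", "p11")
  P
}

#' @export
print.mh_mlogit <- function(x, ...) {
  cat("<mh_mlogit> joint multinomial logistic fit",
      if (x$constrained) " (homogeneity-constrained: delta = 0)", "\n", sep = "")
  cat("  n = ", x$n, ", m = ", x$m, ", logLik = ", format(x$loglik),
      ", iterations = ", x$iterations, "\n", sep = "")
  cat("  intercepts (alpha_01, alpha_10, alpha_11): ",
      paste(signif(x$alpha, 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @rdname fit_mh_multinomial
#' @param x An `mh_mlogit` object.
#' @param ... Unused.
#' @method tidy mh_mlogit
#' @export
tidy.mh_mlogit <- function(x, ...) {
  est <- x$coefficients
  se <- sqrt(diag(x$vcov))
  lab <- strsplit(names(est), ":", fixed = TRUE)
  stat <- ifelse(se > 0, est / se, NA_real_)
  tibble::tibble(
    category = vapply(lab, `[[`, "", 1L),
    term = vapply(lab, function(v) paste(v[-1L], collapse = ":"), ""),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(stat),
    p.value = 2 * pnorm(-abs(unname(stat)))
  )
}

#' @rdname fit_mh_multinomial
#' @method glance mh_mlogit
#' @export
glance.mh_mlogit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    df = if (x$constrained) 3L + 2L * x$m else 3L + 3L * x$m,
    constrained = x$constrained,
    converged = x$converged,
    iterations = x$iterations,
    nobs = x$n
  )
}

# delta contrast: beta_11 - beta_01 - beta_10 (m-vector) and its covariance
delta_contrast <- function(fit) {
  m <- fit$m
  if (m == 0L) {
    return(list(delta = numeric(0), vcov = matrix(numeric(0), 0, 0)))
  }
  p1 <- m + 1L
  C <- matrix(0, m, 3L * p1)
  for (j in seq_len(m)) {
    C[j, 1L + j] <- -1          # beta_01j
    C[j, p1 + 1L + j] <- -1     # beta_10j
    C[j, 2L * p1 + 1L + j] <- 1 # beta_11j
  }
  list(delta = as.vector(C %*% fit$coefficients),
       vcov = C %*% fit$vcov %*% t(C))
}
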