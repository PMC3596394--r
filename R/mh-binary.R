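#' Adjusted odds ratio from binary logistic regression
#'
#' Fits the two asymmetrical binary logistic regressions conventionally
#' used to adjust an odds ratio: y on (x, z) or x on (y, z), optionally
#' with the full set of exposure-by-covariate interaction terms. Without
#' interactions both directions estimate essentially the same common log
#' odds ratio as the homogeneity-constrained joint multinomial model
#' (their likelihoods differ, so the estimates differ slightly in finite
#' samples). With interactions, the interaction coefficients `gamma3`
#' correspond to the heterogeneity vector `delta` of the joint model, and
#' a Wald test of `gamma3 = 0` is an alternative homogeneity test.
#'
#' Fitting is delegated to [stats::glm()] with a logit link.
#'
#' @param data An [mh_data] object.
#' @param direction `"y_on_x"` (regress y on x and z) or `"x_on_y"`.
#' @param interaction Include exposure-by-covariate interaction terms?
#' @param conf_level Confidence level for the odds-ratio interval.
#' @return An object of class `mh_binlogit`: a list with `gamma0`
#'   (intercept), `gamma1` (main-effect log odds ratio), `gamma2`
#'   (covariate slopes), `gamma3` (interaction slopes, `NULL` when
#'   `interaction = FALSE`), `direction`, `or_summary` (a one-row tibble as
#'   in [or_crude()], labelled `logistic_y_on_x` or `logistic_x_on_y`),
#'   `interaction_test` (Wald test tibble, only with interactions), and the
#'   underlying `glm` fit.
#' @export
fit_binary_logistic <- function(data, direction = c("y_on_x", "x_on_y"),
                                interaction = FALSE, conf_level = 0.95) {
  stopifnot(inherits(data, "mh_data"))
  direction <- match.arg(direction)
  resp <- if (direction == "y_on_x") data$y else data$x
  expo <- if (direction == "y_on_x") data$x else data$y
  m <- data$m
  df <- data.frame(.resp = resp, .expo = expo)
  if (m > 0) {
    zdf <- as.data.frame(data$z)
    names(zdf) <- paste0(".z", seq_len(m))
    df <- cbind(df, zdf)
    rhs <- paste(c(".expo", names(zdf)), collapse = " + ")
    if (interaction) {
      rhs <- paste(rhs, "+", paste(paste0(".expo:", names(zdf)), collapse = " + "))
    }
  } else {
    rhs <- ".expo"
  }
  g <- glm(stats::as.formula(paste(".resp ~", rhs)), family = binomial(),
           data = df)
  if (!g$converged) abort("Binary logistic fit did not converge.")
  cf <- coef(g)
  if (max(abs(cf)) > 30) {
    abort("Apparent separation in the binary logistic fit.")
  }
  V <- vcov(g)
  se1 <- sqrt(V[".expo", ".expo"])
  label <- paste0("logistic_", if (direction == "y_on_x") "y_on_x" else "x_on_y")
  orr <- new_or_summary(label, unname(cf[".expo"]), se1, data$n, conf_level)
  gamma2 <- if (m > 0) unname(cf[paste0(".z", seq_len(m))]) else numeric(0)
  out <- list(
    gamma0 = unname(cf["(Intercept)"]),
    gamma1 = unname(cf[".expo"]),
    gamma2 = setNames(gamma2, data$covariate_names),
    gamma3 = NULL,
    direction = direction,
    or_summary = orr,
    interaction_test = NULL,
    glm_fit = g
  )
  if (interaction && m > 0) {
    inm <- paste0(".expo:.z", seq_len(m))
    g3 <- unname(cf[inm])
    V3 <- V[inm, inm, drop = FALSE]
    stat <- as.numeric(t(g3) %*% solve(V3) %*% g3)
    out$gamma3 <- setNames(g3, data$covariate_names)
    out$interaction_test <- tibble::tibble(
      method = "wald_interaction", statistic = stat, df = m,
      p_value = pchisq(stat, m, lower.tail = FALSE))
  }
  class(out) <- "mh_binlogit"
  out
}

#' @export
print.mh_binlogit <- function(x, ...) {
  cat("<mh_binlogit> binary logistic fit, direction ", x$direction, "\n", sep = "")
  print(x$or_summary)
  if (!is.null(x$interaction_test)) {
    cat("  interaction (gamma3 = 0) Wald test:\n")
    print(x$interaction_test)
  }
  invisible(x)
}

#' Conditional-model parameters implied by a joint multinomial fit
#'
#' The joint multinomial logistic model implies a binary logistic model
#' for each conditional distribution. For y given (x, z) the implied
#' coefficients are `gamma0 = alpha_01`, `gamma1 = alpha_11 - alpha_10 -
#' alpha_01` (the common log odds ratio when `delta = 0`), `gamma2 =
#' beta_01`, and `gamma3 = beta_11 - beta_10 - beta_01 = delta`; for x
#' given (y, z) the roles of the (0,1) and (1,0) categories are mirrored.
#' A constrained fit therefore implies `gamma3 = 0` exactly: homogeneity of
#' the odds ratio is the absence of exposure-covariate interaction in the
#' conditional model.
#'
#' @param fit An `mh_mlogit` fit.
#' @param direction `"y_on_x"` or `"x_on_y"`.
#' @return A list with elements `gamma0`, `gamma1`, `gamma2`, `gamma3`,
#'   `direction`.
#' @export
gamma_from_multinomial <- function(fit, direction = c("y_on_x", "x_on_y")) {
  stopifnot(inherits(fit, "mh_mlogit"))
  direction <- match.arg(direction)
  a <- fit$alpha
  B <- fit$beta
  m <- fit$m
  b01 <- if (m > 0) B["01", ] else numeric(0)
  b10 <- if (m > 0) B["10", ] else numeric(0)
  b11 <- if (m > 0) B["11", ] else numeric(0)
  delta <- b11 - b10 - b01
  if (direction == "y_on_x") {
    out <- list(gamma0 = unname(a["01"]),
                gamma1 = unname(a["11"] - a["10"] - a["01"]),
                gamma2 = b01, gamma3 = delta, direction = direction)
  } else {
    out <- list(gamma0 = unname(a["10"]),
                gamma1 = unname(a["11"] - a["10"] - a["01"]),
                gamma2 = b10, gamma3 = delta, direction = direction)
  }
  out
}
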