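#' Full symmetrical odds-ratio analysis report
#'
#' Runs the complete analysis on one dataset: the crude odds ratio, the
#' unconstrained and homogeneity-constrained joint multinomial fits, the
#' generalized Mantel-Haenszel and constrained ML estimators, the average
#' subject-specific estimator, both binary logistic adjusted odds ratios,
#' and the Wald and likelihood-ratio homogeneity tests. Following the
#' recommended workflow, the constrained ML estimate is recommended when
#' homogeneity is not rejected at `alpha_level`; under apparent
#' heterogeneity the report instead flags effect modification and
#' summarizes the subject-specific log odds ratios, which can be explored
#' against covariates.
#'
#' With `m = 0` (no covariates) all estimators coincide with the crude
#' odds ratio and the homogeneity tests are not applicable.
#'
#' @param data An [mh_data] object, or a data frame together with `x`,
#'   `y`, `z` column names.
#' @param x,y,z Column names, used when `data` is a data frame.
#' @param alpha_level Significance level for the homogeneity decision rule.
#' @param conf_level Confidence level for all intervals.
#' @return An object of class `mh_report`: a list with `estimates` (tidy
#'   tibble, one row per estimator), `tests`, `eta_summary`
#'   (min/median/max of the subject-specific log odds ratios from the
#'   unconstrained fit), `recommended` (estimator label), `heterogeneity`
#'   (logical flag), `n`, `m`, `n_dropped`, and the two multinomial fits.
#'
#' @examples
#' sim <- simulate_mh_data(400, alpha = c(0.2, -0.1, log(2)),
#'                         beta = matrix(c(0.5, 0.3, 0.8), 3, 1),
#'                         covariates = list(age = cov_normal()), seed = 11)
#' rep <- mh_report(sim, x = "x", y = "y", z = "age")
#' rep$estimates
#' @export
mh_report <- function(data, x = NULL, y = NULL, z = NULL,
                      alpha_level = 0.05, conf_level = 0.95) {
  if (!inherits(data, "mh_data")) {
    if (is.null(x) || is.null(y)) {
      abort("Supply an mh_data object, or `x`/`y` column names.")
    }
    data <- mh_data(data, x = x, y = y, z = z %||% character())
  }
  est <- list(or_crude(data, conf_level))
  tests <- NULL
  eta_summary <- NULL
  heterogeneity <- FALSE
  fit_u <- fit_c <- NULL
  if (data$m > 0) {
    fit_u <- fit_mh_multinomial(data)
    fit_c <- fit_mh_multinomial(data, constrained = TRUE)
    est <- c(est, list(
      or_generalized_mh(fit_u, conf_level = conf_level),
      or_avg_subject(fit_u, conf_level),
      or_constrained_ml(fit_c, conf_level),
      fit_binary_logistic(data, "y_on_x", conf_level = conf_level)$or_summary,
      fit_binary_logistic(data, "x_on_y", conf_level = conf_level)$or_summary
    ))
    tests <- test_homogeneity(fit_u, fit_c)
    eta <- subject_log_or(fit_u)$eta
    eta_summary <- tibble::tibble(min = min(eta), median = stats::median(eta),
                                  max = max(eta))
    heterogeneity <- any(tests$p_value < alpha_level)
    recommended <- if (heterogeneity) "none (heterogeneity)" else "constrained_ml"
  } else {
    recommended <- "crude"
  }
  structure(
    list(
      estimates = dplyr::bind_rows(est),
      tests = tests,
      eta_summary = eta_summary,
      recommended = recommended,
      heterogeneity = heterogeneity,
      n = data$n, m = data$m, n_dropped = data$n_dropped,
      alpha_level = alpha_level,
      fit_unconstrained = fit_u,
      fit_constrained = fit_c
    ),
    class = "mh_report"
  )
}

#' @export
print.mh_report <- function(x, digits = 3, ...) {
  cat("Symmetrical adjusted odds-ratio analysis\n")
  cat("  n = ", x$n, ", design columns m = ", x$m,
      if (x$n_dropped > 0) paste0(", rows dropped = ", x$n_dropped),
      "\n\n", sep = "")
  tab <- x$estimates |>
    dplyr::mutate(dplyr::across(c("or", "ci_low", "ci_high", "se_log_or"),
                                ~ signif(.x, digits)))
  print(as.data.frame(tab[, c("estimator", "or", "ci_low", "ci_high",
                              "se_log_or", "n")]), row.names = FALSE)
  if (!is.null(x$tests)) {
    cat("\nHomogeneity of the odds ratio (H0: delta = 0):\n")
    tt <- x$tests |>
      dplyr::mutate(statistic = signif(.data$statistic, digits),
                    p_value = signif(.data$p_value, digits))
    print(as.data.frame(tt), row.names = FALSE)
  } else {
    cat("\nHomogeneity tests: not applicable (no covariates).\n")
  }
  if (x$heterogeneity) {
    cat("\nHeterogeneity detected at alpha = ", x$alpha_level,
        "; subject-specific log OR (min / median / max): ",
        paste(signif(unlist(x$eta_summary), digits), collapse = " / "),
        "\nExplore the subject-specific odds ratios against covariates.\n",
        sep = "")
  } else {
    cat("\nRecommended estimate: ", x$recommended, "\n", sep = "")
  }
  invisible(x)
}

#' @rdname mh_report
#' @param ... Unused.
#' @method tidy mh_report
#' @export
tidy.mh_report <- function(x, ...) x$estimates

#' @rdname mh_report
#' @method glance mh_report
#' @export
glance.mh_report <- function(x, ...) {
  cml <- x$estimates[x$estimates$estimator ==
                       if (x$m > 0) "constrained_ml" else "crude", ]
  tibble::tibble(
    n = x$n, m = x$m, n_dropped = x$n_dropped,
    or_recommended = cml$or,
    recommended = x$recommended,
    heterogeneity = x$heterogeneity,
    lr_p = if (!is.null(x$tests)) x$tests$p_value[x$tests$method == "lr"] else NA_real_,
    wald_p = if (!is.null(x$tests)) x$tests$p_value[x$tests$method == "wald"] else NA_real_
  )
}

#' Forest plot of the estimator table
#'
#' Point estimates and confidence intervals of all estimators in a report,
#' on a log-scaled odds-ratio axis.
#'
#' @param object An `mh_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mh_report
#' @export
autoplot.mh_report <- function(object, ...) {
  df <- object$estimates
  df$estimator <- factor(df$estimator, levels = rev(df$estimator))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or, y = .data$estimator)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CI, log scale)", y = NULL,
                  title = "Covariate-adjusted odds-ratio estimates") +
    ggplot2::theme_minimal()
}

#' Histogram of subject-specific log odds ratios
#'
#' Diagnostic display of the distribution of the subject-specific log odds
#' ratios from an unconstrained fit; a degenerate spike indicates
#' homogeneity.
#'
#' @param object An `mh_mlogit` fit.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mh_mlogit
#' @export
autoplot.mh_mlogit <- function(object, bins = 30, ...) {
  df <- subject_log_or(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$eta)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(x = "Subject-specific log odds ratio", y = "Subjects",
                  title = "Distribution of subject-specific log odds ratios") +
    ggplot2::theme_minimal()
}

#' Read a simulation specification from a JSON file
#'
#' Parses a declarative specification with fields `n`, `alpha` (length 3),
#' optional `beta` (3-by-m, row-major list of rows), `covariates` (named
#' object mapping column name to `{law, ...}` with law-specific
#' parameters), and optional `seed`. Used by the command-line `simulate`
#' entry point; the generated dataset round-trips through [mh_data()].
#'
#' @param path Path to a JSON file.
#' @return A list with elements `n`, `alpha`, `beta`, `covariates`, `seed`
#'   suitable for [simulate_mh_data()].
#' @export
read_sim_spec <- function(path) {
  sp <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(sp$n) || is.null(sp$alpha) || length(sp$alpha) != 3L) {
    abort("Simulation spec must contain `n` and a length-3 `alpha`.")
  }
  covs <- list()
  if (!is.null(sp$covariates)) {
    covs <- purrr::imap(sp$covariates, function(cv, nm) {
      switch(cv$law %||% abort(paste0("Covariate `", nm, "` has no `law`.")),
             normal = cov_normal(cv$mean %||% 0, cv$sd %||% 1),
             bernoulli = cov_bernoulli(cv$p %||% 0.5),
             uniform = cov_uniform(cv$min %||% 0, cv$max %||% 1),
             abort(paste0("Unknown law `", cv$law, "` for covariate `", nm, "`.")))
    })
  }
  beta <- NULL
  if (!is.null(sp$beta)) {
    # jsonlite simplifies a rectangular list of rows to a matrix already
    beta <- if (is.matrix(sp$beta)) sp$beta
            else matrix(unlist(sp$beta), nrow = 3L, byrow = TRUE)
    if (ncol(beta) != length(covs)) {
      abort("`beta` must have one column per covariate.")
    }
    if (any(!is.finite(beta))) abort("`beta` must be finite.")
  }
  if (any(!is.finite(sp$alpha))) abort("`alpha` must be finite.")
  list(n = as.integer(sp$n), alpha = as.numeric(sp$alpha), beta = beta,
       covariates = covs, seed = sp$seed)
}
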