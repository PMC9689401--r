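## formula -> (design matrix, outcome vector) for the IRLS engine
build_model_inputs <- function(formula, data, weights = NULL) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- as_binary01(stats::model.response(mf), "outcome")
  x <- stats::model.matrix(attr(mf, "terms"), mf)
  list(x = x, y = y, weights = weights, terms = attr(mf, "terms"))
}

rr_fit <- function(fit, model, conf_level, robust, call) {
  terms <- if (fit$converged) {
    term_table(fit, robust = robust, conf_level = conf_level)
  } else {
    NULL
  }
  structure(
    list(fit = fit, model = model, terms = terms,
         conf_level = conf_level, robust = robust,
         converged = fit$converged, call = call),
    class = "rr_fit")
}

#' @export
print.rr_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("%s regression did not converge after %d iterations.\n",
                x$model, x$fit$n_iter))
    if (x$model == "log-binomial") {
      cat("The log-binomial likelihood often fails on the boundary (fitted",
          "probability at 1);\nconsider fit_modified_poisson(), which",
          "estimates the same risk ratios without the constraint.\n")
    }
    return(invisible(x))
  }
  cat(sprintf("%s regression, n = %g\n", x$model, x$fit$n_obs))
  print(x$terms)
  invisible(x)
}

#' Logistic regression (odds ratios)
#'
#' Fits a Bernoulli GLM with logit link by the package's IRLS engine and
#' reports exponentiated coefficients as odds ratios. Remember that with a
#' common outcome the OR can substantially overstate the relative risk;
#' see [compare_models()] and [fit_modified_poisson()].
#'
#' @param formula Model formula; the response must be binary (0/1, logical,
#'   or a two-level factor whose second level is the event).
#' @param data A data.frame with no missing values in the model variables.
#' @param conf_level Confidence level for Wald intervals, default 0.95.
#' @param robust Use the HC0 sandwich covariance instead of the model-based
#'   one. Default `FALSE`: the binomial model-based variance is already
#'   correct for genuinely Bernoulli data.
#' @param weights Optional frequency weights (row multiplicities); fitting
#'   grouped counts equals fitting the expanded data exactly.
#' @return An object of class `"rr_fit"` whose `terms` element is a
#'   [term_table()] of ORs.
#' @examples
#' cohort <- expand_counts(breast_cancer_table(),
#'                         exposure_name = "mixed", outcome_name = "death")
#' fit_logistic(death ~ mixed, cohort)
#' @export
fit_logistic <- function(formula, data, conf_level = 0.95, robust = FALSE,
                         weights = NULL) {
  inp <- build_model_inputs(formula, data, weights)
  fit <- irls_fit(inp$x, inp$y, link = "logit", family = "bernoulli",
                  weights = inp$weights)
  rr_fit(fit, "logistic", conf_level, robust, match.call())
}

#' Modified (robust) Poisson regression (relative risks)
#'
#' Fits a log-link GLM with a Poisson working likelihood to a binary
#' outcome and reports exponentiated coefficients as relative risks. The
#' Poisson working variance overstates the Bernoulli variance p(1-p), so
#' the HC0 sandwich covariance is mandatory by default: with `robust =
#' FALSE` (library use only) a warning reminds that model-based SEs are
#' conservative for binary data.
#'
#' With a single binary predictor the fit is saturated and the estimates
#' reproduce the crude 2x2 relative risk and its closed-form robust SE
#' exactly.
#'
#' @inheritParams fit_logistic
#' @param robust Default `TRUE`; the sandwich covariance is the point of
#'   the method.
#' @return An `"rr_fit"` whose `terms` element reports RRs.
#' @examples
#' cohort <- expand_counts(breast_cancer_table(),
#'                         exposure_name = "mixed", outcome_name = "death")
#' fit_modified_poisson(death ~ mixed, cohort)
#' @export
fit_modified_poisson <- function(formula, data, conf_level = 0.95,
                                 robust = TRUE, weights = NULL) {
  if (!robust) {
    warning("model-based Poisson SEs are conservative for binary outcomes; ",
            "robust = TRUE is strongly recommended", call. = FALSE)
  }
  inp <- build_model_inputs(formula, data, weights)
  fit <- irls_fit(inp$x, inp$y, link = "log", family = "poisson",
                  weights = inp$weights)
  rr_fit(fit, "modified Poisson", conf_level, robust, match.call())
}

#' Log-binomial regression (relative risks)
#'
#' Fits a Bernoulli GLM with log link, which models the risk ratio
#' directly but constrains every fitted probability below 1. The maximum
#' likelihood search therefore often fails on the boundary, especially
#' with continuous covariates; a non-converged fit is returned as a
#' structured result (`converged = FALSE`, no term table) advising
#' [fit_modified_poisson()], not as an error.
#'
#' @inheritParams fit_logistic
#' @param robust Use the sandwich covariance. Default `FALSE` (the
#'   Bernoulli model-based variance is correctly specified when the model
#'   converges).
#' @return An `"rr_fit"`; check its `converged` element before using the
#'   term table.
#' @export
fit_log_binomial <- function(formula, data, conf_level = 0.95,
                             robust = FALSE, weights = NULL) {
  inp <- build_model_inputs(formula, data, weights)
  fit <- irls_fit(inp$x, inp$y, link = "log", family = "bernoulli",
                  weights = inp$weights)
  rr_fit(fit, "log-binomial", conf_level, robust, match.call())
}

#' Side-by-side OR and RR analysis of one exposure
#'
#' The recommended workflow for a binary risk factor: cross-tabulate
#' exposure against outcome, compute the crude OR and RR, fit both the
#' logistic and the modified Poisson model (optionally adjusting for
#' covariates), and flag the analysis when the outcome incidence exceeds
#' `incidence_threshold` — the regime in which the OR no longer
#' approximates the RR and a risk-ratio model should be preferred.
#'
#' @param data A data.frame of individual records.
#' @param outcome Name of the binary outcome column.
#' @param exposure Name of the binary exposure column.
#' @param covariates Character vector of adjustment covariates (default
#'   none).
#' @param conf_level Confidence level, default 0.95.
#' @param incidence_threshold Incidence above which the common-outcome flag
#'   is raised. Default 0.10.
#' @param include_log_binomial Also attempt a log-binomial fit. Default
#'   `FALSE`.
#' @return An object of class `"comparison_report"`: crude measures,
#'   model term tables, incidence, the OR/RR inflation diagnostics and the
#'   common-outcome flag.
#' @examples
#' cohort <- expand_counts(breast_cancer_table(),
#'                         exposure_name = "mixed", outcome_name = "death")
#' compare_models(cohort, outcome = "death", exposure = "mixed")
#' @export
compare_models <- function(data, outcome, exposure,
                           covariates = character(),
                           conf_level = 0.95,
                           incidence_threshold = 0.10,
                           include_log_binomial = FALSE) {
  stopifnot(is.data.frame(data),
            outcome %in% names(data), exposure %in% names(data))
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov)) {
    stop("covariate(s) not in data: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  }
  y <- as_binary01(data[[outcome]], outcome)
  tab <- tabulate_2x2(data[[exposure]], y)
  incidence <- mean(y)

  rhs <- paste(c(exposure, covariates), collapse = " + ")
  fml <- stats::as.formula(paste(outcome, "~", rhs))
  logistic <- fit_logistic(fml, data, conf_level = conf_level)
  poisson <- fit_modified_poisson(fml, data, conf_level = conf_level)
  logbin <- if (include_log_binomial) {
    fit_log_binomial(fml, data, conf_level = conf_level)
  }

  crude_or <- odds_ratio(tab, conf_level)
  crude_rr <- relative_risk(tab, conf_level)
  structure(
    list(n = nrow(data), outcome = outcome, exposure = exposure,
         covariates = covariates, incidence = incidence,
         common_outcome = incidence > incidence_threshold,
         incidence_threshold = incidence_threshold,
         table = tab, crude_or = crude_or, crude_rr = crude_rr,
         inflation_factor = or_rr_inflation_factor(tab),
         or_rr_ratio = crude_or$estimate / crude_rr$estimate,
         logistic = logistic, modified_poisson = poisson,
         log_binomial = logbin, conf_level = conf_level),
    class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, digits = 3, ...) {
  cat(sprintf("Model comparison for %s ~ %s%s (n = %d)\n",
              x$outcome, x$exposure,
              if (length(x$covariates)) {
                paste0(" + ", paste(x$covariates, collapse = " + "))
              } else "",
              x$n))
  cat(sprintf("outcome incidence: %.1f%%%s\n", 100 * x$incidence,
              if (x$common_outcome) {
                sprintf(" -- COMMON OUTCOME (> %.0f%%): the OR overstates the RR; report the RR",
                        100 * x$incidence_threshold)
              } else ""))
  cat(sprintf("crude OR = %.*g, crude RR = %.*g (OR/RR inflation = %.*g)\n",
              digits, x$crude_or$estimate, digits, x$crude_rr$estimate,
              digits, x$or_rr_ratio))
  cat("\n"); print(x$logistic)
  cat("\n"); print(x$modified_poisson)
  if (!is.null(x$log_binomial)) {
    cat("\n"); print(x$log_binomial)
  }
  invisible(x)
}
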