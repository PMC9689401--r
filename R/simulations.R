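#' Configure a simulation scenario
#'
#' Declarative input for the scenario engine. A scenario draws cohorts of
#' size `n` with a Bernoulli exposure and a binary outcome whose risk is
#' `baseline_risk` in the unexposed and `baseline_risk * true_rr` in the
#' exposed, repeats that `replicates` times per grid point, and aggregates
#' the fitted measures. Grid points with `baseline_risk * true_rr > 1` are
#' rejected: they do not define a probability model.
#'
#' @param kind One of `"inflation"`, `"coverage"`, `"collapsibility"`,
#'   `"reciprocity"`.
#' @param baseline_risk Numeric vector: grid of unexposed risks p0. For
#'   `"collapsibility"` exactly two values, the baseline risk in each level
#'   of the non-confounding covariate.
#' @param true_rr True relative risk of the exposure.
#' @param n Subjects per replicate.
#' @param replicates Number of Monte-Carlo replicates per grid point.
#' @param seed Integer RNG seed; identical config + seed gives identical
#'   results.
#' @param exposure_prevalence P(exposed), default 0.5.
#' @param covariate_prevalence P(covariate = 1) for the collapsibility
#'   scenario, default 0.5.
#' @param conf_level Confidence level for interval-based summaries.
#' @return A `"scenario_config"` list.
#' @export
scenario_config <- function(kind = c("inflation", "coverage",
                                     "collapsibility", "reciprocity"),
                            baseline_risk, true_rr, n, replicates, seed,
                            exposure_prevalence = 0.5,
                            covariate_prevalence = 0.5,
                            conf_level = 0.95) {
  kind <- match.arg(kind)
  stopifnot(replicates >= 1, n >= 4, true_rr > 0,
            all(baseline_risk > 0), all(baseline_risk < 1),
            exposure_prevalence > 0, exposure_prevalence < 1,
            covariate_prevalence > 0, covariate_prevalence < 1)
  if (any(baseline_risk * true_rr > 1)) {
    stop("invalid scenario: baseline_risk * true_rr exceeds 1 at some grid point",
         call. = FALSE)
  }
  if (kind == "collapsibility" && length(baseline_risk) != 2L) {
    stop("collapsibility scenarios need exactly two baseline risks (one per covariate level)",
         call. = FALSE)
  }
  structure(list(kind = kind, baseline_risk = baseline_risk,
                 true_rr = true_rr, n = as.integer(n),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed),
                 exposure_prevalence = exposure_prevalence,
                 covariate_prevalence = covariate_prevalence,
                 conf_level = conf_level),
            class = "scenario_config")
}

#' Population odds ratio implied by a risk-ratio scenario
#'
#' For unexposed risk `p0` and true relative risk `rr`, the exposed risk
#' is `p0 * rr` and the population odds ratio is
#' \eqn{OR = RR \, (1 - p_0) / (1 - p_0 RR)} — the closed form of the
#' OR-inflates-RR identity, used as the exact target in the inflation
#' scenario.
#'
#' @param p0 Unexposed risk in (0, 1).
#' @param rr True relative risk with `p0 * rr < 1`.
#' @return The population odds ratio.
#' @export
population_odds_ratio <- function(p0, rr) {
  stopifnot(all(p0 > 0), all(p0 < 1), all(p0 * rr < 1))
  rr * (1 - p0) / (1 - p0 * rr)
}

simulation_result <- function(kind, table, config, failures, extra = list()) {
  structure(c(list(kind = kind, table = table, replicates = config$replicates,
                   seed = config$seed, config = config, failures = failures),
              extra),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("'%s' scenario: %d replicate(s), seed %d, %d failed fit(s)\n",
              x$kind, x$replicates, x$seed, sum(x$failures)))
  print(x$table, row.names = FALSE)
  invisible(x)
}

## one replicate: binary exposure, outcome risk p0 * rr^x; returns the 2x2
## or NULL when a cell that the estimators need is empty
sim_replicate_table <- function(n, p0, rr, p_exp) {
  x <- stats::rbinom(n, 1L, p_exp)
  y <- stats::rbinom(n, 1L, p0 * rr^x)
  tab <- tabulate_2x2(x, y)
  if (tab$a == 0 || tab$b == 0 || tab$c == 0 || tab$d == 0) NULL else tab
}

#' Quantify how the odds ratio inflates the relative risk
#'
#' For each baseline risk in the grid, simulates cohorts with the
#' configured true RR, computes the fitted OR and RR per replicate (the
#' single-binary-predictor logistic and modified-Poisson fits are
#' saturated, so the crude table estimators are the exact maximum
#' likelihood estimates), and compares the Monte-Carlo mean OR with the
#' exact population value from [population_odds_ratio()]. The mean OR
#' inflates monotonically with the baseline risk while the mean RR stays
#' at the true RR.
#'
#' @param config A [scenario_config()] of kind `"inflation"`.
#' @return A `"simulation_result"` whose `table` has one row per baseline
#'   risk: mean/median/sd of the fitted OR and RR, the exact population
#'   OR, and the failure count.
#' @export
run_inflation <- function(config) {
  stopifnot(inherits(config, "scenario_config"), config$kind == "inflation")
  set.seed(config$seed)
  rows <- lapply(config$baseline_risk, function(p0) {
    or_hat <- rr_hat <- numeric(0L)
    fail <- 0L
    for (r in seq_len(config$replicates)) {
      tab <- sim_replicate_table(config$n, p0, config$true_rr,
                                 config$exposure_prevalence)
      if (is.null(tab)) { fail <- fail + 1L; next }
      or_hat <- c(or_hat, odds_ratio(tab)$estimate)
      rr_hat <- c(rr_hat, relative_risk(tab)$estimate)
    }
    data.frame(p0 = p0, true_rr = config$true_rr,
               population_or = population_odds_ratio(p0, config$true_rr),
               mean_or = mean(or_hat), median_or = stats::median(or_hat),
               sd_or = stats::sd(or_hat),
               mean_rr = mean(rr_hat), median_rr = stats::median(rr_hat),
               sd_rr = stats::sd(rr_hat),
               n_fits = length(or_hat), failures = fail)
  })
  tab <- do.call(rbind, rows)
  simulation_result("inflation", tab, config, tab$failures)
}

#' Empirical coverage of robust-Poisson confidence intervals
#'
#' Per grid point, fits the modified Poisson model to each replicate and
#' records whether the robust (HC0) and the naive model-based Wald
#' intervals cover the true log RR. The naive Poisson variance p exceeds
#' the Bernoulli variance p(1-p), so the model-based interval
#' over-covers; the sandwich interval is calibrated.
#'
#' @param config A [scenario_config()] of kind `"coverage"`.
#' @return A `"simulation_result"`; `table` has per-p0 coverage of both
#'   interval types, mean interval widths (log scale) and the mean fitted
#'   RR.
#' @export
run_coverage <- function(config) {
  stopifnot(inherits(config, "scenario_config"), config$kind == "coverage")
  set.seed(config$seed)
  log_rr <- log(config$true_rr)
  z <- stats::qnorm(1 - (1 - config$conf_level) / 2)
  rows <- lapply(config$baseline_risk, function(p0) {
    cover_r <- cover_n <- logical(0L)
    width_r <- width_n <- rr_hat <- numeric(0L)
    fail <- 0L
    for (r in seq_len(config$replicates)) {
      x <- stats::rbinom(config$n, 1L, config$exposure_prevalence)
      y <- stats::rbinom(config$n, 1L, p0 * config$true_rr^x)
      fit <- tryCatch(
        irls_fit(cbind("(Intercept)" = 1, exposure = x), y,
                 link = "log", family = "poisson"),
        error = function(e) NULL)
      if (is.null(fit) || !fit$converged) { fail <- fail + 1L; next }
      b <- fit$coefficients[["exposure"]]
      se_r <- sqrt(fit$robust_cov["exposure", "exposure"])
      se_n <- sqrt(fit$model_cov["exposure", "exposure"])
      cover_r <- c(cover_r, abs(b - log_rr) <= z * se_r)
      cover_n <- c(cover_n, abs(b - log_rr) <= z * se_n)
      width_r <- c(width_r, 2 * z * se_r)
      width_n <- c(width_n, 2 * z * se_n)
      rr_hat <- c(rr_hat, exp(b))
    }
    data.frame(p0 = p0, true_rr = config$true_rr,
               coverage_robust = mean(cover_r),
               coverage_naive = mean(cover_n),
               mean_width_robust = mean(width_r),
               mean_width_naive = mean(width_n),
               mean_rr = mean(rr_hat),
               n_fits = length(rr_hat), failures = fail)
  })
  tab <- do.call(rbind, rows)
  simulation_result("coverage", tab, config, tab$failures)
}

## exact 2x2x2 population for the collapsibility design: exposure X and a
## covariate Z independent of X (no confounding), outcome risk
## p0[z] * rr^x. Returns the 8 cell probabilities and exact crude and
## adjusted measures (adjusted = population MLE of the x + z model, fitted
## with cell probabilities as weights).
enumerate_collapsibility <- function(p0, rr, p_exp, p_cov) {
  grid <- expand.grid(x = c(0, 1), z = c(0, 1))
  grid$p_xz <- ifelse(grid$x == 1, p_exp, 1 - p_exp) *
    ifelse(grid$z == 1, p_cov, 1 - p_cov)
  grid$risk <- p0[grid$z + 1L] * rr^grid$x
  if (any(grid$risk >= 1)) {
    stop("enumerated risk reaches 1; choose smaller baseline risks or RR",
         call. = FALSE)
  }
  # crude measures from the collapsed exposure margins
  risk1 <- sum(grid$p_xz[grid$x == 1] * grid$risk[grid$x == 1]) /
    sum(grid$p_xz[grid$x == 1])
  risk0 <- sum(grid$p_xz[grid$x == 0] * grid$risk[grid$x == 0]) /
    sum(grid$p_xz[grid$x == 0])
  crude_rr <- risk1 / risk0
  crude_or <- (risk1 / (1 - risk1)) / (risk0 / (1 - risk0))
  # population fits: expand each (x, z) cell into y = 1 / y = 0 rows
  # weighted by its probability mass; the weighted IRLS solution is the
  # exact population (infinite-n) maximum likelihood estimate
  X <- as.matrix(cbind("(Intercept)" = 1,
                       exposure = rep(grid$x, 2L),
                       covariate = rep(grid$z, 2L)))
  yy <- rep(c(1L, 0L), each = nrow(grid))
  # cell masses scaled to a nominal population; the scale cancels in the MLE
  wts <- 1e6 * c(grid$p_xz * grid$risk, grid$p_xz * (1 - grid$risk))
  adj_logit <- irls_fit(X, yy, link = "logit", family = "bernoulli",
                        weights = wts)
  adj_log <- irls_fit(X, yy, link = "log", family = "poisson",
                      weights = wts)
  stratum_or <- vapply(c(0, 1), function(zv) {
    r1 <- grid$risk[grid$x == 1 & grid$z == zv]
    r0 <- grid$risk[grid$x == 0 & grid$z == zv]
    (r1 / (1 - r1)) / (r0 / (1 - r0))
  }, numeric(1L))
  list(cells = grid,
       crude_or = crude_or, crude_rr = crude_rr,
       adjusted_or = exp(adj_logit$coefficients[["exposure"]]),
       adjusted_rr = exp(adj_log$coefficients[["exposure"]]),
       stratum_or = stratum_or)
}

#' Non-collapsibility of the odds ratio without confounding
#'
#' Builds a population in which a binary covariate shifts the outcome risk
#' but is independent of the exposure — so it is not a confounder — and
#' computes crude and covariate-adjusted OR and RR two ways: exactly, by
#' enumerating the eight-cell joint distribution (the population
#' quantities), and by Monte-Carlo simulation with both models fitted per
#' replicate. The RR is collapsible (adjusted = crude = true RR, exactly,
#' in the enumeration) while the adjusted OR moves further from 1 than the
#' crude OR even though nothing is confounded.
#'
#' @param config A [scenario_config()] of kind `"collapsibility"`;
#'   `baseline_risk` gives the unexposed risk at covariate levels 0 and 1.
#' @return A `"simulation_result"` with the exact `population` quantities
#'   and, when `replicates > 0`, simulation means in `table`.
#' @export
run_collapsibility <- function(config) {
  stopifnot(inherits(config, "scenario_config"),
            config$kind == "collapsibility")
  pop <- enumerate_collapsibility(config$baseline_risk, config$true_rr,
                                  config$exposure_prevalence,
                                  config$covariate_prevalence)
  set.seed(config$seed)
  or_c <- or_a <- rr_c <- rr_a <- numeric(0L)
  fail <- 0L
  for (r in seq_len(config$replicates)) {
    x <- stats::rbinom(config$n, 1L, config$exposure_prevalence)
    zc <- stats::rbinom(config$n, 1L, config$covariate_prevalence)
    y <- stats::rbinom(config$n, 1L,
                       config$baseline_risk[zc + 1L] * config$true_rr^x)
    X <- cbind("(Intercept)" = 1, exposure = x, covariate = zc)
    fits <- tryCatch(list(
      crude_logit = irls_fit(X[, 1:2], y, "logit", "bernoulli"),
      adj_logit = irls_fit(X, y, "logit", "bernoulli"),
      crude_log = irls_fit(X[, 1:2], y, "log", "poisson"),
      adj_log = irls_fit(X, y, "log", "poisson")),
      error = function(e) NULL)
    if (is.null(fits) || !all(vapply(fits, `[[`, logical(1L), "converged"))) {
      fail <- fail + 1L
      next
    }
    or_c <- c(or_c, exp(fits$crude_logit$coefficients[["exposure"]]))
    or_a <- c(or_a, exp(fits$adj_logit$coefficients[["exposure"]]))
    rr_c <- c(rr_c, exp(fits$crude_log$coefficients[["exposure"]]))
    rr_a <- c(rr_a, exp(fits$adj_log$coefficients[["exposure"]]))
  }
  tab <- data.frame(
    quantity = c("crude_or", "adjusted_or", "crude_rr", "adjusted_rr"),
    population = c(pop$crude_or, pop$adjusted_or,
                   pop$crude_rr, pop$adjusted_rr),
    mc_mean = if (length(or_c)) c(mean(or_c), mean(or_a),
                                  mean(rr_c), mean(rr_a)) else NA_real_,
    mc_sd = if (length(or_c)) c(stats::sd(or_c), stats::sd(or_a),
                                stats::sd(rr_c), stats::sd(rr_a)) else NA_real_,
    n_fits = length(or_c))
  simulation_result("collapsibility", tab, config, fail,
                    extra = list(population = pop))
}

#' Reciprocity contrast between logistic and modified Poisson fits
#'
#' Fits each replicate twice — against the event and against its
#' complement — with both models. Logistic ORs are exact reciprocals with
#' identical p-values; modified-Poisson RRs are not, and with a common
#' outcome the two analyses can even disagree on statistical significance.
#' Passing `data` analyses a fixed dataset once instead of simulating.
#'
#' @param config A [scenario_config()] of kind `"reciprocity"` (only the
#'   first `baseline_risk` is used).
#' @param data Optional data.frame with binary columns `exposure` and
#'   `outcome` for a single deterministic analysis.
#' @param alpha Significance threshold for the discordance summary,
#'   default 0.05.
#' @return A `"simulation_result"`; `table` has one row per replicate with
#'   the event/complement RRs and ORs, their p-values, and reciprocity
#'   products; the `discordant_significance` element is the fraction of
#'   replicates where only one of the two Poisson analyses is significant.
#' @export
run_reciprocity <- function(config, data = NULL, alpha = 0.05) {
  stopifnot(inherits(config, "scenario_config"),
            config$kind == "reciprocity")
  set.seed(config$seed)
  analyse <- function(x, y) {
    X <- cbind("(Intercept)" = 1, exposure = x)
    out <- lapply(list(event = y, complement = 1L - y), function(yy) {
      pois <- irls_fit(X, yy, "log", "poisson")
      logi <- irls_fit(X, yy, "logit", "bernoulli")
      c(rr = exp(pois$coefficients[["exposure"]]),
        rr_p = term_table(pois, robust = TRUE)$p_value,
        or = exp(logi$coefficients[["exposure"]]),
        or_p = term_table(logi, robust = FALSE)$p_value)
    })
    data.frame(
      rr_event = out$event[["rr"]], rr_complement = out$complement[["rr"]],
      rr_product = out$event[["rr"]] * out$complement[["rr"]],
      rr_p_event = out$event[["rr_p"]],
      rr_p_complement = out$complement[["rr_p"]],
      or_event = out$event[["or"]], or_complement = out$complement[["or"]],
      or_product = out$event[["or"]] * out$complement[["or"]],
      or_p_event = out$event[["or_p"]],
      or_p_complement = out$complement[["or_p"]])
  }
  rows <- list()
  fail <- 0L
  if (!is.null(data)) {
    rows[[1L]] <- analyse(as_binary01(data$exposure, "exposure"),
                          as_binary01(data$outcome, "outcome"))
  } else {
    p0 <- config$baseline_risk[1L]
    for (r in seq_len(config$replicates)) {
      x <- stats::rbinom(config$n, 1L, config$exposure_prevalence)
      y <- stats::rbinom(config$n, 1L, p0 * config$true_rr^x)
      row <- tryCatch(analyse(x, y), error = function(e) NULL)
      if (is.null(row)) fail <- fail + 1L else rows[[length(rows) + 1L]] <- row
    }
  }
  tab <- do.call(rbind, rows)
  disc <- mean(xor(tab$rr_p_event < alpha, tab$rr_p_complement < alpha))
  simulation_result("reciprocity", tab, config, fail,
                    extra = list(discordant_significance = disc,
                                 alpha = alpha))
}

#' Run a scenario from its config
#'
#' @param config A [scenario_config()].
#' @param ... Passed to the kind-specific runner.
#' @return A `"simulation_result"`.
#' @export
run_scenario <- function(config, ...) {
  stopifnot(inherits(config, "scenario_config"))
  switch(config$kind,
         inflation = run_inflation(config),
         coverage = run_coverage(config),
         collapsibility = run_collapsibility(config),
         reciprocity = run_reciprocity(config, ...))
}

#' Read a scenario config from JSON or YAML
#'
#' The file maps 1:1 onto the [scenario_config()] arguments.
#'
#' @param path Path to a `.json` or `.yaml`/`.yml` file.
#' @return A `"scenario_config"`.
#' @export
read_scenario_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    }
    vals <- yaml::read_yaml(path)
    # YAML 1.1 parses a bare `n` key as boolean FALSE; map it back
    names(vals)[names(vals) == "FALSE"] <- "n"
    vals
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(scenario_config, vals)
}

#' Write simulation results as TSV plus a JSON provenance block
#'
#' @param result A `"simulation_result"`.
#' @param tsv_path Where to write the per-grid-point table (TSV).
#' @param json_path Optional path for the provenance JSON (config, seed,
#'   replicate and failure counts).
#' @return `tsv_path`, invisibly.
#' @export
write_simulation_result <- function(result, tsv_path, json_path = NULL) {
  stopifnot(inherits(result, "simulation_result"))
  utils::write.table(result$table, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json_path)) {
    prov <- list(kind = result$kind, seed = result$seed,
                 replicates = result$replicates,
                 failures = sum(result$failures),
                 config = unclass(result$config))
    jsonlite::write_json(prov, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(tsv_path)
}
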