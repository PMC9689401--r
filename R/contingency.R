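#' Construct a 2x2 exposure-outcome contingency table
#'
#' Stores the four cell counts of the classical epidemiological 2x2 layout:
#' `a` exposed with the event, `b` exposed without, `c` unexposed with the
#' event, `d` unexposed without. All closed-form measures of association in
#' this package ([relative_risk()], [odds_ratio()], [prevalence_ratio()],
#' [prevalence_odds_ratio()], [or_rr_inflation_factor()]) operate on this
#' object.
#'
#' @param a,b,c,d Non-negative integer cell counts. Both exposure margins
#'   must be non-empty (`a + b >= 1`, `c + d >= 1`).
#' @return An object of class `"contingency_2x2"`: a list with elements
#'   `a`, `b`, `c`, `d` and the total `n`.
#' @examples
#' contingency_2x2(26, 8, 38, 60)
#' @export
contingency_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (length(counts) != 4L || anyNA(counts)) {
    stop("all four cell counts (a, b, c, d) must be supplied", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  if (a + b < 1) stop("exposed margin is empty (a + b = 0)", call. = FALSE)
  if (c + d < 1) stop("unexposed margin is empty (c + d = 0)", call. = FALSE)
  structure(
    list(a = as.numeric(a), b = as.numeric(b),
         c = as.numeric(c), d = as.numeric(d),
         n = as.numeric(a + b + c + d)),
    class = "contingency_2x2"
  )
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$a + x$b,
                x$c, x$d, x$c + x$d,
                x$a + x$c, x$b + x$d, x$n),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("exposed", "unexposed", "total"),
                              c("event", "no event", "total")))
  cat("2x2 contingency table (n =", format(x$n), ")\n")
  print(m)
  invisible(x)
}

#' Cross-tabulate two binary vectors into a 2x2 table
#'
#' @param exposure,outcome Binary vectors of equal length (0/1, logical, or
#'   two-level factors whose second level is taken as exposed / event).
#' @return A [contingency_2x2()] object.
#' @export
tabulate_2x2 <- function(exposure, outcome) {
  x <- as_binary01(exposure, "exposure")
  y <- as_binary01(outcome, "outcome")
  if (length(x) != length(y)) {
    stop("exposure and outcome must have the same length", call. = FALSE)
  }
  contingency_2x2(
    a = sum(x == 1 & y == 1), b = sum(x == 1 & y == 0),
    c = sum(x == 0 & y == 1), d = sum(x == 0 & y == 0)
  )
}

## coerce 0/1 numeric, logical, or two-level factor/character to 0/1 integer
as_binary01 <- function(v, what = "variable") {
  if (is.factor(v) || is.character(v)) {
    lev <- if (is.factor(v)) levels(v) else sort(unique(v))
    if (length(lev) != 2L) {
      stop(sprintf("%s must have exactly two levels, found %d", what,
                   length(lev)), call. = FALSE)
    }
    return(as.integer(v == lev[2L]))
  }
  v <- as.numeric(v)
  if (anyNA(v) || !all(v %in% c(0, 1))) {
    stop(sprintf("%s must be binary (0/1) with no missing values", what),
         call. = FALSE)
  }
  as.integer(v)
}

#' Ratio-scale estimate with log-scale Wald inference
#'
#' Internal constructor shared by all measures: given a point estimate and
#' the standard error of its natural logarithm, builds the exponentiated
#' Wald interval and a two-sided Wald p-value against a null ratio of 1.
#'
#' @param estimate Positive ratio-scale point estimate.
#' @param log_se Non-negative SE of `log(estimate)`.
#' @param conf_level Confidence level in (0, 1).
#' @param measure Label, e.g. `"RR"`, `"OR"`, `"PR"`, `"POR"`, `"MH-RR"`.
#' @param corrected Logical; `TRUE` when a continuity correction was applied.
#' @return An object of class `"ratio_estimate"`.
#' @keywords internal
ratio_estimate <- function(estimate, log_se, conf_level = 0.95,
                           measure = "RR", corrected = FALSE) {
  stopifnot(estimate > 0, log_se >= 0,
            conf_level > 0, conf_level < 1)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(log(estimate) + c(-1, 1) * z * log_se)
  p <- if (log_se > 0) {
    2 * stats::pnorm(-abs(log(estimate) / log_se))
  } else {
    as.numeric(estimate == 1)  # degenerate: no sampling variation
  }
  structure(
    list(estimate = estimate, log_se = log_se,
         ci_lower = ci[1L], ci_upper = ci[2L],
         conf_level = conf_level, p_value = p,
         measure = measure, corrected = corrected),
    class = "ratio_estimate"
  )
}

#' @export
print.ratio_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("%s = %s, %d%% CI (%s, %s), p = %s%s\n",
              x$measure, format(x$estimate, digits = digits),
              round(100 * x$conf_level),
              format(x$ci_lower, digits = digits),
              format(x$ci_upper, digits = digits),
              format.pval(x$p_value, digits = digits, eps = 1e-4),
              if (x$corrected) " [continuity corrected]" else ""))
  invisible(x)
}

## zero-cell guard: error naming the offending cell, or +0.5 Haldane-Anscombe
## correction to all four cells when correction = TRUE
check_cells <- function(table, needed, correction) {
  zero <- needed[unlist(table[needed]) == 0]
  if (length(zero) == 0L) {
    return(list(table = table, corrected = FALSE))
  }
  if (!correction) {
    stop(sprintf(
      "zero-cell: cell '%s' is 0; the log-scale SE is undefined (set correction = TRUE for the Haldane-Anscombe +0.5 adjustment)",
      zero[1L]), call. = FALSE)
  }
  tab <- table
  tab$a <- tab$a + 0.5; tab$b <- tab$b + 0.5
  tab$c <- tab$c + 0.5; tab$d <- tab$d + 0.5
  tab$n <- tab$n + 2
  list(table = tab, corrected = TRUE)
}

#' Relative risk from a 2x2 table
#'
#' Estimates the risk ratio \eqn{RR = \frac{a/(a+b)}{c/(c+d)}} with the
#' log-scale standard error
#' \eqn{\sqrt{1/a - 1/(a+b) + 1/c - 1/(c+d)}}, an exponentiated Wald
#' confidence interval, and a two-sided Wald test of RR = 1.
#'
#' @param table A [contingency_2x2()] object.
#' @param conf_level Confidence level, default 0.95.
#' @param correction Apply the Haldane-Anscombe +0.5 correction to all four
#'   cells when an event cell is zero. Default `FALSE`: a zero event count
#'   is an error naming the cell, because silent correction hides data
#'   problems.
#' @return A `"ratio_estimate"` object with `measure = "RR"`.
#' @examples
#' relative_risk(contingency_2x2(26, 8, 38, 60))
#' @seealso [odds_ratio()], [or_rr_inflation_factor()], [mantel_haenszel_rr()]
#' @export
relative_risk <- function(table, conf_level = 0.95, correction = FALSE) {
  risk_ratio_estimate(table, conf_level, correction, measure = "RR")
}

#' Prevalence ratio from a 2x2 table
#'
#' Arithmetically identical to [relative_risk()], but labelled `PR`: in a
#' cross-sectional study the same ratio compares prevalences, not incidence
#' risks, and the output should say so.
#'
#' @inheritParams relative_risk
#' @return A `"ratio_estimate"` with `measure = "PR"`.
#' @export
prevalence_ratio <- function(table, conf_level = 0.95, correction = FALSE) {
  risk_ratio_estimate(table, conf_level, correction, measure = "PR")
}

risk_ratio_estimate <- function(table, conf_level, correction, measure) {
  stopifnot(inherits(table, "contingency_2x2"))
  chk <- check_cells(table, c("a", "c"), correction)
  t <- chk$table
  est <- (t$a / (t$a + t$b)) / (t$c / (t$c + t$d))
  se <- sqrt(1 / t$a - 1 / (t$a + t$b) + 1 / t$c - 1 / (t$c + t$d))
  ratio_estimate(est, se, conf_level, measure, chk$corrected)
}

#' Odds ratio from a 2x2 table
#'
#' Estimates the cross-product ratio \eqn{OR = ad/bc} with log-scale
#' standard error \eqn{\sqrt{1/a + 1/b + 1/c + 1/d}} and an exponentiated
#' Wald interval. Unlike the relative risk, the OR is reciprocal under
#' relabelling of the outcome ([swap_outcome()]) but is not collapsible and
#' overstates the RR when the outcome is common (see
#' [or_rr_inflation_factor()]).
#'
#' @inheritParams relative_risk
#' @param correction Apply the +0.5 correction when any cell is zero.
#' @return A `"ratio_estimate"` with `measure = "OR"`.
#' @examples
#' odds_ratio(contingency_2x2(26, 8, 38, 60))
#' @export
odds_ratio <- function(table, conf_level = 0.95, correction = FALSE) {
  odds_ratio_estimate(table, conf_level, correction, measure = "OR")
}

#' Prevalence odds ratio from a 2x2 table
#'
#' Same arithmetic as [odds_ratio()], labelled `POR` for cross-sectional
#' prevalence data.
#'
#' @inheritParams odds_ratio
#' @return A `"ratio_estimate"` with `measure = "POR"`.
#' @export
prevalence_odds_ratio <- function(table, conf_level = 0.95,
                                  correction = FALSE) {
  odds_ratio_estimate(table, conf_level, correction, measure = "POR")
}

odds_ratio_estimate <- function(table, conf_level, correction, measure) {
  stopifnot(inherits(table, "contingency_2x2"))
  chk <- check_cells(table, c("a", "b", "c", "d"), correction)
  t <- chk$table
  est <- (t$a * t$d) / (t$b * t$c)
  se <- sqrt(1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d)
  ratio_estimate(est, se, conf_level, measure, chk$corrected)
}

#' Factor by which the odds ratio inflates the relative risk
#'
#' On any 2x2 table the identity \eqn{OR = f \cdot RR} holds exactly with
#' \eqn{f = \frac{1 - c/(c+d)}{1 - a/(a+b)}}. When the outcome is rare in
#' both arms the factor is near 1 and OR approximates RR; as the exposed
#' risk grows the factor, and with it the OR's overstatement of the RR,
#' grows without bound.
#'
#' @param table A [contingency_2x2()] object with exposed risk strictly
#'   below 1 (`b >= 1`).
#' @return The inflation factor, a positive scalar.
#' @examples
#' t2 <- contingency_2x2(26, 8, 38, 60)
#' or_rr_inflation_factor(t2) * relative_risk(t2)$estimate  # equals the OR
#' @export
or_rr_inflation_factor <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  if (table$b == 0) {
    stop("exposed risk is 1 (b = 0): inflation factor is undefined (division by zero)",
         call. = FALSE)
  }
  (1 - table$c / (table$c + table$d)) / (1 - table$a / (table$a + table$b))
}

#' Approximate a relative risk from an odds ratio
#'
#' Converts an odds ratio (e.g. an adjusted OR from logistic regression) to
#' an approximate relative risk given the risk in the unexposed, using
#' \eqn{RR \approx OR / ((1 - p_0) + p_0 \cdot OR)}. For a crude 2x2 table
#' with `p0 = c/(c+d)` the conversion is exact. The approximation is known
#' to be biased away from 1 for common outcomes with heterogeneous baseline
#' risk; prefer [fit_modified_poisson()] when individual-level data are
#' available.
#'
#' @param or_value Positive odds ratio.
#' @param p0 Risk of the outcome among the unexposed, in (0, 1).
#' @return The approximated relative risk.
#' @examples
#' rr_from_or(5.1316, 38 / 98)
#' @export
rr_from_or <- function(or_value, p0) {
  if (!is.numeric(or_value) || or_value <= 0) {
    stop("or_value must be a positive number", call. = FALSE)
  }
  if (!is.numeric(p0) || p0 <= 0 || p0 >= 1) {
    stop("p0 must lie strictly between 0 and 1", call. = FALSE)
  }
  or_value / ((1 - p0) + p0 * or_value)
}

#' Relabel the outcome of a 2x2 table
#'
#' Swaps event and non-event columns, i.e. models the complement of the
#' outcome (survival instead of death). The odds ratio of the swapped table
#' is exactly the reciprocal of the original; the relative risk is not —
#' the RR's definition depends on which outcome category is modelled.
#'
#' @param table A [contingency_2x2()] object.
#' @return The relabelled `"contingency_2x2"`.
#' @examples
#' t2 <- contingency_2x2(26, 8, 38, 60)
#' odds_ratio(swap_outcome(t2))$estimate * odds_ratio(t2)$estimate  # 1
#' @export
swap_outcome <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  contingency_2x2(a = table$b, b = table$a, c = table$d, d = table$c)
}

#' Collect 2x2 tables into strata
#'
#' @param ... `"contingency_2x2"` objects, or a single list of them.
#' @param labels Optional character vector of stratum names.
#' @return An object of class `"stratified_2x2"`.
#' @seealso [mantel_haenszel_rr()]
#' @export
stratified_2x2 <- function(..., labels = NULL) {
  strata <- list(...)
  if (length(strata) == 1L && is.list(strata[[1L]]) &&
      !inherits(strata[[1L]], "contingency_2x2")) {
    strata <- strata[[1L]]
  }
  if (length(strata) < 1L) {
    stop("at least one stratum is required", call. = FALSE)
  }
  ok <- vapply(strata, inherits, logical(1L), "contingency_2x2")
  if (!all(ok)) {
    stop("all strata must be contingency_2x2 objects", call. = FALSE)
  }
  if (!is.null(labels) && length(labels) != length(strata)) {
    stop("labels must match the number of strata", call. = FALSE)
  }
  structure(list(strata = strata, labels = labels), class = "stratified_2x2")
}

#' Mantel-Haenszel pooled relative risk across strata
#'
#' Pools the stratum-specific risk ratios as
#' \deqn{RR_{MH} = \frac{\sum_k a_k (c_k + d_k) / n_k}
#'                     {\sum_k c_k (a_k + b_k) / n_k},}
#' adjusting for the stratifying (categorical) confounder. The confidence
#' interval uses the Greenland-Robins variance estimator for the log pooled
#' ratio, which for a single stratum reduces exactly to the crude log-RR
#' variance.
#'
#' @param strata A [stratified_2x2()] object (or a single
#'   `"contingency_2x2"`, treated as one stratum).
#' @param conf_level Confidence level, default 0.95.
#' @return A `"ratio_estimate"` with `measure = "MH-RR"`.
#' @examples
#' s <- stratified_2x2(contingency_2x2(10, 10, 5, 15),
#'                     contingency_2x2(8, 2, 12, 8))
#' mantel_haenszel_rr(s)
#' @export
mantel_haenszel_rr <- function(strata, conf_level = 0.95) {
  if (inherits(strata, "contingency_2x2")) {
    strata <- stratified_2x2(strata)
  }
  stopifnot(inherits(strata, "stratified_2x2"))
  tabs <- strata$strata
  R <- vapply(tabs, function(t) t$a * (t$c + t$d) / t$n, numeric(1L))
  S <- vapply(tabs, function(t) t$c * (t$a + t$b) / t$n, numeric(1L))
  if (sum(R) == 0 || sum(S) == 0) {
    stop("no information: every stratum has a zero event count in one arm",
         call. = FALSE)
  }
  est <- sum(R) / sum(S)
  # Greenland-Robins variance of log(RR_MH)
  num <- vapply(tabs, function(t) {
    ((t$a + t$b) * (t$c + t$d) * (t$a + t$c) - t$a * t$c * t$n) / t$n^2
  }, numeric(1L))
  se <- sqrt(sum(num) / (sum(R) * sum(S)))
  ratio_estimate(est, se, conf_level, measure = "MH-RR")
}
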