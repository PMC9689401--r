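# shared fixtures and small generators (everything built in code)

breast_fixture <- function() breast_cancer_table()

breast_fixture_cohort <- function() {
  expand_counts(breast_cancer_table(),
                exposure_name = "mixed", outcome_name = "death")
}

# random 2x2 table with all cells >= min_count
random_table <- function(min_count = 1, max_count = 40) {
  counts <- sample(min_count:max_count, 4, replace = TRUE)
  contingency_2x2(counts[1], counts[2], counts[3], counts[4])
}

# random small regression dataset: binary y, mix of binary and continuous
# covariates, moderate effects so both logit and log-Poisson fits converge
random_regression_data <- function(n = NULL, k = NULL) {
  if (is.null(n)) n <- sample(60:200, 1)
  if (is.null(k)) k <- sample(1:4, 1)
  X <- matrix(0, n, k)
  for (j in seq_len(k)) {
    X[, j] <- if (j %% 2 == 0) rbinom(n, 1, 0.4) else rnorm(n, 0, 0.5)
  }
  colnames(X) <- paste0("x", seq_len(k))
  eta <- -1.2 + drop(X %*% rnorm(k, 0, 0.4))
  y <- rbinom(n, 1, plogis(eta))
  # re-draw until both outcome classes are well represented
  while (sum(y) < 5 || sum(1 - y) < 5) y <- rbinom(n, 1, plogis(eta))
  list(x = cbind("(Intercept)" = 1, X), y = y)
}
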