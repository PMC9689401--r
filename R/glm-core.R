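#' Control parameters for the IRLS fitter
#'
#' Convergence requires BOTH a relative deviance change below `epsilon` and
#' a maximum absolute score (gradient of the working log-likelihood) below
#' `score_tol`. The printed 2-decimal coefficients of typical reports need
#' far less, but cross-checks against reference implementations require the
#' tight default.
#'
#' @param epsilon Relative deviance-change tolerance. Default `1e-10`.
#' @param score_tol Maximum absolute score *per observation*
#'   (`max|U|/n`) at convergence; per-observation scaling keeps the
#'   criterion meaningful from desk-sized tables to cohorts of 10^5.
#'   Default `1e-12`, tight enough that saturated-model estimates agree
#'   with their closed forms to ten decimal places.
#' @param max_iter Iteration cap. Default 100.
#' @param max_halvings Maximum step-halvings per iteration used to keep
#'   log-link Bernoulli fitted probabilities below 1. Default 30.
#' @return A list of class `"irls_control"`.
#' @export
irls_control <- function(epsilon = 1e-10, score_tol = 1e-12,
                         max_iter = 100L, max_halvings = 30L) {
  stopifnot(epsilon > 0, score_tol > 0, max_iter >= 1, max_halvings >= 0)
  structure(list(epsilon = epsilon, score_tol = score_tol,
                 max_iter = as.integer(max_iter),
                 max_halvings = as.integer(max_halvings)),
            class = "irls_control")
}

## family/link internals ----------------------------------------------------

## Each working model is defined by the inverse link (mu from eta), the
## derivative dmu/deta, the working variance V(mu), and a deviance. The
## three models of interest:
##   logistic          = (logit, bernoulli)
##   modified Poisson  = (log,   poisson)   -- quasi-likelihood on binary y
##   log-binomial      = (log,   bernoulli) -- mu constrained below 1
irls_family <- function(link, family) {
  link <- match.arg(link, c("logit", "log"))
  family <- match.arg(family, c("bernoulli", "poisson"))
  linkinv <- switch(link,
    logit = function(eta) stats::plogis(eta),
    log = function(eta) exp(eta)
  )
  mu_eta <- switch(link,
    logit = function(eta, mu) mu * (1 - mu),
    log = function(eta, mu) mu
  )
  variance <- switch(family,
    bernoulli = function(mu) mu * (1 - mu),
    poisson = function(mu) mu
  )
  deviance <- switch(family,
    bernoulli = function(y, mu, w) {
      -2 * sum(w * (y * log(mu) + (1 - y) * log1p(-mu)))
    },
    poisson = function(y, mu, w) {
      # binary y: y*log(y/mu) term is 0 at y = 0 and -log(mu) at y = 1
      2 * sum(w * (ifelse(y > 0, y * log(y / mu), 0) - (y - mu)))
    }
  )
  list(link = link, family = family, linkinv = linkinv, mu_eta = mu_eta,
       variance = variance, deviance = deviance,
       # feasibility of a candidate eta: log-Bernoulli needs mu < 1
       feasible = if (link == "log" && family == "bernoulli") {
         function(eta) all(eta < log(1 - 1e-10))
       } else {
         function(eta) all(eta < 700)  # overflow guard only
       })
}

default_start <- function(x, y, w, fam) {
  beta <- numeric(ncol(x))
  mbar <- sum(w * y) / sum(w)
  mbar <- min(max(mbar, 1e-8), 1 - 1e-8)
  beta[1L] <- if (fam$link == "logit") stats::qlogis(mbar) else log(mbar)
  beta
}

#' Fit a binary-outcome GLM by iteratively reweighted least squares
#'
#' The computational engine behind [fit_logistic()], [fit_modified_poisson()]
#' and [fit_log_binomial()]. Maximises the working likelihood (Bernoulli or
#' Poisson) under a logit or log link by IRLS, with optional frequency
#' weights (fitting grouped counts is exactly equivalent to fitting the
#' row-expanded data). On convergence both the model-based covariance
#' \eqn{(X'WX)^{-1}} and the HC0 sandwich covariance are attached.
#'
#' For the log-link Bernoulli model (log-binomial regression) candidate
#' steps are halved until all fitted probabilities stay below 1; if the
#' iteration cap is reached the fit is returned with `converged = FALSE` —
#' never a silent success. For the log-link Poisson working model fitted
#' "probabilities" can legitimately exceed 1; the maximum is reported as
#' `max_fitted_prob`, never hidden.
#'
#' @param x Design matrix, n x (k+1), including the intercept column. Must
#'   be full column rank.
#' @param y Binary response vector (0/1) of length n.
#' @param link `"logit"` or `"log"`.
#' @param family Working likelihood: `"bernoulli"` or `"poisson"`.
#' @param weights Optional positive frequency weights (row multiplicities).
#' @param start Optional starting coefficients; by default the intercept is
#'   initialised at the link-transformed outcome mean and all slopes at 0,
#'   which for the log link guarantees initial fitted values in (0, 1).
#' @param control An [irls_control()] list.
#' @return An object of class `"irls_fit"`: coefficients (log scale),
#'   `model_cov`, `robust_cov`, `converged`, `n_iter`, `deviance`,
#'   `max_fitted_prob`, `n_obs`, plus the inputs needed to recompute the
#'   covariances.
#' @seealso [sandwich_covariance()], [term_table()]
#' @export
irls_fit <- function(x, y, link = c("logit", "log"),
                     family = c("bernoulli", "poisson"),
                     weights = NULL, start = NULL,
                     control = irls_control()) {
  fam <- irls_family(match.arg(link), match.arg(family))
  x <- as.matrix(x)
  if (is.null(colnames(x))) {
    colnames(x) <- c("(Intercept)",
                     if (ncol(x) > 1) paste0("x", seq_len(ncol(x) - 1L)))
  }
  y <- as_binary01(y, "outcome")
  n <- nrow(x)
  p <- ncol(x)
  if (length(y) != n) stop("nrow(x) must equal length(y)", call. = FALSE)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w <= 0) || anyNA(w)) {
    stop("weights must be positive and match the number of rows", call. = FALSE)
  }
  if (sum(w) < p + 1) {
    stop("too few observations: need at least k + 2 rows", call. = FALSE)
  }
  qx <- qr(x)
  if (qx$rank < p) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1L):p]]
    stop(sprintf("singular design: column(s) %s are collinear with earlier columns",
                 paste(sQuote(bad), collapse = ", ")), call. = FALSE)
  }

  beta <- if (is.null(start)) default_start(x, y, w, fam) else as.numeric(start)
  if (length(beta) != p) stop("start has wrong length", call. = FALSE)
  eta <- drop(x %*% beta)
  if (!fam$feasible(eta)) {
    stop("starting values give infeasible fitted values", call. = FALSE)
  }
  mu <- fam$linkinv(eta)
  dev <- fam$deviance(y, mu, w)

  converged <- FALSE
  iter <- 0L
  boundary <- FALSE
  repeat {
    iter <- iter + 1L
    mudot <- fam$mu_eta(eta, mu)
    V <- fam$variance(mu)
    ww <- w * mudot^2 / V          # working weights
    z <- eta + (y - mu) / mudot    # working response

    sw <- sqrt(ww)
    fit_wls <- qr(x * sw)
    beta_new <- qr.coef(fit_wls, z * sw)
    step <- beta_new - beta

    # step-halving: keep the candidate feasible and non-increasing in deviance
    lambda <- 1
    halved <- 0L
    repeat {
      cand <- beta + lambda * step
      eta_c <- drop(x %*% cand)
      if (fam$feasible(eta_c)) {
        mu_c <- fam$linkinv(eta_c)
        dev_c <- fam$deviance(y, mu_c, w)
        if (is.finite(dev_c)) break
      }
      halved <- halved + 1L
      if (halved > control$max_halvings) {
        boundary <- TRUE
        cand <- beta; eta_c <- eta; mu_c <- mu; dev_c <- dev
        break
      }
      lambda <- lambda / 2
    }
    beta <- cand; eta <- eta_c; mu <- mu_c
    rel_change <- abs(dev_c - dev) / (abs(dev_c) + 0.1)
    dev <- dev_c

    mudot <- fam$mu_eta(eta, mu)
    V <- fam$variance(mu)
    score <- drop(crossprod(x, w * (y - mu) * mudot / V))
    if (rel_change < control$epsilon &&
        max(abs(score)) / sum(w) < control$score_tol) {
      converged <- TRUE
      break
    }
    if (iter >= control$max_iter || boundary) break
  }

  names(beta) <- colnames(x)
  ww <- w * fam$mu_eta(eta, mu)^2 / fam$variance(mu)
  info <- crossprod(x * sqrt(ww))           # X'WX (expected information)
  model_cov <- tryCatch(chol2inv(chol(info)), error = function(e) {
    matrix(NA_real_, p, p)
  })
  dimnames(model_cov) <- list(colnames(x), colnames(x))

  fit <- structure(
    list(coefficients = beta, link = fam$link, family = fam$family,
         model_cov = model_cov, robust_cov = NULL,
         converged = converged, n_iter = iter,
         deviance = dev, max_fitted_prob = max(mu),
         fitted = mu, linear_predictors = eta,
         n_obs = sum(w), rank = p,
         design = x, outcome = y, prior_weights = w,
         score = score, boundary = boundary),
    class = "irls_fit")
  if (converged) {
    fit$robust_cov <- sandwich_covariance(fit)
  }
  fit
}

#' @export
print.irls_fit <- function(x, ...) {
  model <- switch(paste(x$link, x$family),
                  "logit bernoulli" = "logistic",
                  "log poisson" = "modified Poisson",
                  "log bernoulli" = "log-binomial")
  cat(sprintf("%s regression (IRLS), n = %g, %s in %d iteration(s)\n",
              model, x$n_obs,
              if (x$converged) "converged" else "DID NOT CONVERGE",
              x$n_iter))
  print(x$coefficients)
  if (x$link == "log" && x$max_fitted_prob > 1) {
    cat(sprintf("note: max fitted probability %.3f exceeds 1\n",
                x$max_fitted_prob))
  }
  invisible(x)
}

#' Sandwich (robust) covariance of an IRLS fit
#'
#' Heteroscedasticity-consistent covariance
#' \deqn{(X'WX)^{-1} \Big[\sum_i w_i x_i x_i' s_i^2\Big] (X'WX)^{-1},}
#' where W holds the working weights at the solution and \eqn{s_i} is the
#' per-observation score residual — for the canonical logit-Bernoulli and
#' log-Poisson pairs simply \eqn{y_i - \mu_i}, so the meat is
#' \eqn{\sum_i x_i x_i' (y_i - \mu_i)^2}. Frequency weights enter both
#' bread and meat as row multiplicities, so grouped and expanded data give
#' identical results. This is the correction that makes Poisson-working
#' standard errors valid for binary outcomes, where the true variance
#' p(1-p) is smaller than the Poisson variance p.
#'
#' @param fit A converged [irls_fit()] object.
#' @param type `"HC0"` (default; no small-sample factor — it reproduces the
#'   closed-form robust SE of the saturated one-predictor model exactly) or
#'   `"HC1"` (multiplies by n/(n-k-1)).
#' @return A symmetric covariance matrix for the coefficients.
#' @export
sandwich_covariance <- function(fit, type = c("HC0", "HC1")) {
  stopifnot(inherits(fit, "irls_fit"))
  type <- match.arg(type)
  if (!fit$converged) {
    stop("refusing to compute a sandwich covariance for a non-converged fit",
         call. = FALSE)
  }
  fam <- irls_family(fit$link, fit$family)
  x <- fit$design
  mu <- fit$fitted
  eta <- fit$linear_predictors
  w <- fit$prior_weights
  mudot <- fam$mu_eta(eta, mu)
  V <- fam$variance(mu)
  ww <- w * mudot^2 / V
  s <- (fit$outcome - mu) * mudot / V      # score residual per observation
  bread <- chol2inv(chol(crossprod(x * sqrt(ww))))
  meat <- crossprod(x * sqrt(w) * abs(s))  # sum w_i s_i^2 x_i x_i'
  vc <- bread %*% meat %*% bread
  if (type == "HC1") {
    vc <- vc * fit$n_obs / (fit$n_obs - fit$rank)
  }
  dimnames(vc) <- dimnames(fit$model_cov)
  vc
}

#' Per-term ratio estimates from a fitted model
#'
#' One row per non-intercept term: coefficient B, exponentiated ratio
#' (`exp(B)`, an OR under the logit link, an RR under the log link), its
#' log-scale SE, Wald z, two-sided p, and the exponentiated Wald interval.
#'
#' @param fit An [irls_fit()] object.
#' @param robust Use the sandwich covariance (`TRUE`) or the model-based
#'   one (`FALSE`).
#' @param conf_level Confidence level, default 0.95.
#' @param include_intercept Also report the intercept row (its exponential
#'   is a baseline odds or risk, not a ratio). Default `FALSE`.
#' @return A data.frame of class `"term_table"` with attribute
#'   `ratio_label` (`"OR"` or `"RR"`).
#' @export
term_table <- function(fit, robust = TRUE, conf_level = 0.95,
                       include_intercept = FALSE) {
  stopifnot(inherits(fit, "irls_fit"), conf_level > 0, conf_level < 1)
  vc <- if (robust) {
    if (is.null(fit$robust_cov)) sandwich_covariance(fit) else fit$robust_cov
  } else {
    fit$model_cov
  }
  b <- fit$coefficients
  se <- sqrt(diag(vc))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  wald_z <- b / se
  out <- data.frame(
    term = names(b),
    coefficient = unname(b),
    ratio = exp(unname(b)),
    log_se = unname(se),
    ci_lower = exp(unname(b) - z * se),
    ci_upper = exp(unname(b) + z * se),
    wald_z = unname(wald_z),
    p_value = 2 * stats::pnorm(-abs(unname(wald_z))),
    stringsAsFactors = FALSE
  )
  if (!include_intercept) {
    out <- out[out$term != "(Intercept)", , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out,
            ratio_label = if (fit$link == "logit") "OR" else "RR",
            conf_level = conf_level, robust = robust,
            class = c("term_table", "data.frame"))
}

#' @export
print.term_table <- function(x, digits = 3, ...) {
  lab <- attr(x, "ratio_label")
  cat(sprintf("term estimates (%s scale, %s SEs, %d%% CI)\n", lab,
              if (attr(x, "robust")) "robust" else "model-based",
              round(100 * attr(x, "conf_level"))))
  df <- data.frame(
    term = x$term,
    B = round(x$coefficient, digits),
    ratio = round(x$ratio, digits),
    p = format.pval(x$p_value, digits = digits, eps = 1e-4),
    ci = sprintf("%.*f-%.*f", digits - 1, x$ci_lower, digits - 1, x$ci_upper)
  )
  names(df)[3] <- lab
  names(df)[5] <- sprintf("%d%% CI", round(100 * attr(x, "conf_level")))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Complement a binary outcome vector
#'
#' Maps y to 1 - y, i.e. models survival instead of death. Exponentiated
#' logistic coefficients are exact reciprocals under this relabelling;
#' risk ratios from log-link models are not.
#'
#' @param y Binary vector (0/1, logical, or two-level factor).
#' @return An integer 0/1 vector. Applying the function twice returns the
#'   original coding.
#' @export
relabel_outcome <- function(y) {
  1L - as_binary01(y, "outcome")
}
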