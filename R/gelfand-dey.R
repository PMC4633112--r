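#' Gelfand-Dey estimate of the log marginal likelihood
#'
#' Reciprocal-importance-sampling estimator of `Pr(y | model)` from
#' posterior draws: with importance density `f`, the marginal likelihood
#' is approximated by the reciprocal of the posterior mean of
#' `f(w) / (Pr(y | w) * Pr(w))`. All arithmetic is done in log space; the
#' reciprocal-of-mean structure is a negated log-sum-exp. The importance
#' density is a multivariate t with `df` equal to the number of retained
#' draws, centered at the posterior mean, with the correlation matrix of
#' the draws as its scale (the covariance matrix is available as an
#' alternative). A delete-one jackknife Monte-Carlo standard error is
#' reported.
#'
#' @param draws numeric matrix of posterior draws (rows) of the model's
#'   parameter vector (columns), on the scale the callables expect; a
#'   zero-column matrix denotes a model with no free parameters.
#' @param loglik function of one parameter vector returning the log
#'   likelihood of the data.
#' @param logprior function of one parameter vector returning the log
#'   prior density (must be proper).
#' @param df degrees of freedom of the t importance density; default the
#'   number of draws.
#' @param scale `"correlation"` (default) or `"covariance"` scale matrix.
#' @param jitter non-negative ridge added to the scale matrix diagonal if
#'   it is near-singular.
#' @return A list: `log_marginal`, `se` (jackknife MC standard error),
#'   `n_draws`, and `importance` (df, center, scale matrix).
#' @examples
#' # Beta(1,1)-Bernoulli with 3 successes in 10 trials: the closed-form
#' # log marginal is log(beta(4, 8)) = -7.1846
#' set.seed(1)
#' p <- rbeta(5000, 4, 8)
#' draws <- matrix(qlogis(p), ncol = 1)
#' loglik <- function(w) {
#'   pr <- plogis(w[1]); 3 * log(pr) + 7 * log(1 - pr)
#' }
#' logprior <- function(w) {
#'   pr <- plogis(w[1]); log(pr * (1 - pr))  # U(0,1) with logit Jacobian
#' }
#' gd_log_marginal(draws, loglik, logprior)$log_marginal
#' @export
gd_log_marginal <- function(draws, loglik, logprior, df = NULL,
                            scale = c("correlation", "covariance"),
                            jitter = 0) {
  scale <- match.arg(scale)
  draws <- as.matrix(draws)
  c_n <- nrow(draws)
  if (c_n < 2L) stop("need at least 2 posterior draws", call. = FALSE)
  d <- ncol(draws)
  if (is.null(df)) df <- c_n

  if (d > 0) {
    center <- colMeans(draws)
    S <- if (scale == "correlation") stats::cor(draws) else
      stats::cov(draws)
    if (jitter > 0) S <- S + diag(jitter, d)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch))
      stop("scale matrix is (near-)singular; supply a small jitter",
           call. = FALSE)
    logf <- dmvt_log(draws, center, ch, df)
  } else {
    center <- numeric(0)
    S <- matrix(numeric(0), 0, 0)
    logf <- rep(0, c_n)
  }
  ll <- apply(draws, 1, loglik)
  lp <- apply(draws, 1, logprior)
  term <- logf - ll - lp
  bad <- which(!is.finite(term))
  if (length(bad))
    stop("non-finite log-density at draw ", bad[1],
         " (loglik = ", signif(ll[bad[1]], 4),
         ", logprior = ", signif(lp[bad[1]], 4), ")", call. = FALSE)
  lse <- logsumexp(term)
  log_ml <- log(c_n) - lse
  # delete-one jackknife on the log-marginal
  lse_minus <- lse + log1p(-exp(pmin(term - lse, -1e-12)))
  ml_jack <- log(c_n - 1) - lse_minus
  se <- sqrt((c_n - 1) / c_n * sum((ml_jack - mean(ml_jack))^2))
  list(log_marginal = log_ml, se = se, n_draws = c_n,
       importance = list(df = df, center = center, scale = S,
                         type = scale))
}

# log density of a multivariate t given the Cholesky factor of its scale
dmvt_log <- function(x, center, chol_scale, df) {
  d <- length(center)
  xc <- sweep(as.matrix(x), 2, center)
  z <- backsolve(chol_scale, t(xc), transpose = TRUE)
  q <- colSums(z^2)
  lgamma((df + d) / 2) - lgamma(df / 2) - (d / 2) * log(df * pi) -
    sum(log(diag(chol_scale))) - (df + d) / 2 * log1p(q / df)
}

#' Gelfand-Dey log marginal likelihood of a fitted SCR model
#'
#' Assembles the transformed parameter vector (log `lam0`, `beta_sex`,
#' log sigmas, scaled-logit `theta`, logit `psi` and `psi_sex`, as
#' applicable to the model), the Jacobian-adjusted proper priors, and the
#' integrated likelihood ([integrated_loglik()]) for a fit, and calls
#' [gd_log_marginal()].
#'
#' @param fit an [scr_fit()] result.
#' @param data the [capture_history()] the model was fitted to.
#' @param space the `statespace` used in the fit.
#' @param gd_draws optional number of evenly-spaced retained draws to use
#'   (defaults to all; reduce for speed at some Monte-Carlo cost).
#' @param ... passed to [gd_log_marginal()] (`scale`, `jitter`).
#' @return As [gd_log_marginal()].
#' @export
scr_log_marginal <- function(fit, data, space, gd_draws = NULL, ...) {
  spec <- fit$meta$spec
  pr <- fit$meta$priors
  est_theta <- is.null(spec$theta_fixed)
  cols <- c("log_lam0",
            if (spec$sex_on_lam0) "beta_sex",
            "log_sigma_f",
            if (spec$sex_on_sigma) "log_sigma_m",
            if (est_theta) "theta_t",
            "psi_t", "psi_sex_t")
  dr <- fit$draws
  tmat <- cbind(
    log_lam0 = log(dr[, "lam0_female"]),
    beta_sex = dr[, "beta_sex"],
    log_sigma_f = log(dr[, "sigma_female"]),
    log_sigma_m = log(dr[, "sigma_male"]),
    theta_t = stats::qlogis(pmin(pmax((dr[, "theta"] - 0.5) / 0.5,
                                      1e-12), 1 - 1e-12)),
    psi_t = stats::qlogis(dr[, "psi"]),
    psi_sex_t = stats::qlogis(dr[, "psi_sex"]))[, cols, drop = FALSE]
  if (!is.null(gd_draws) && gd_draws < nrow(tmat)) {
    keep <- unique(round(seq(1, nrow(tmat), length.out = gd_draws)))
    tmat <- tmat[keep, , drop = FALSE]
  }
  vec_to_params <- function(w) {
    w <- stats::setNames(as.numeric(w), cols)
    theta <- if (est_theta) 0.5 + 0.5 * stats::plogis(w["theta_t"]) else
      spec$theta_fixed
    sf <- exp(w["log_sigma_f"])
    scr_params(
      lam0_female = exp(w["log_lam0"]),
      beta_sex = if (spec$sex_on_lam0) unname(w["beta_sex"]) else 0,
      sigma_female = sf,
      sigma_male = if (spec$sex_on_sigma) exp(w["log_sigma_m"]) else sf,
      theta = unname(theta),
      psi = stats::plogis(unname(w["psi_t"])),
      psi_sex = stats::plogis(unname(w["psi_sex_t"])))
  }
  logit_beta_logpdf <- function(t, ab) {
    p <- stats::plogis(t)
    stats::dbeta(p, ab[1], ab[2], log = TRUE) + log(p) + log1p(-p)
  }
  logprior <- function(w) {
    w <- stats::setNames(as.numeric(w), cols)
    lp <- (w["log_lam0"] - log(pr$lam0_max)) +
      (if (exp(w["log_lam0"]) >= pr$lam0_max) -Inf else 0) +
      (w["log_sigma_f"] - log(pr$sigma_max)) +
      (if (exp(w["log_sigma_f"]) >= pr$sigma_max) -Inf else 0) +
      logit_beta_logpdf(w["psi_t"], pr$psi_beta) +
      logit_beta_logpdf(w["psi_sex_t"], pr$psi_sex_beta)
    if (spec$sex_on_lam0)
      lp <- lp + stats::dnorm(w["beta_sex"], 0, pr$beta_sd, log = TRUE)
    if (spec$sex_on_sigma)
      lp <- lp + (w["log_sigma_m"] - log(pr$sigma_max)) +
        (if (exp(w["log_sigma_m"]) >= pr$sigma_max) -Inf else 0)
    if (est_theta) {
      q <- stats::plogis(w["theta_t"])
      lp <- lp + log(q * (1 - q))    # U(0.5, 1) with scaled-logit Jacobian
    }
    unname(lp)
  }
  loglik <- function(w) {
    integrated_loglik(vec_to_params(w), data, space, spec)
  }
  out <- gd_log_marginal(tmat, loglik, logprior, ...)
  out$model <- spec$model
  out
}

#' Posterior model probabilities and Bayes factors
#'
#' Normalizes marginal likelihoods into posterior model probabilities
#' (via log-sum-exp) and reports Bayes factors against a reference model
#' together with the `log10` and `2 ln` reporting transforms.
#'
#' @param log_marginals numeric vector of log marginal likelihoods.
#' @param prior_probs prior model probabilities (default uniform); must
#'   sum to 1.
#' @param reference index of the reference (null) model for Bayes
#'   factors.
#' @param model_names optional model labels.
#' @return A data.frame of class `model_comparison` with columns
#'   `model`, `log_marginal`, `prior_prob`, `post_prob`, `bayes_factor`,
#'   `log10_bf`, `two_ln_bf`.
#' @examples
#' compare_models(c(-10, -10 + log(3)), reference = 1)  # B = 3, 75/25
#' @export
compare_models <- function(log_marginals, prior_probs = NULL,
                           reference = 1, model_names = NULL) {
  L <- length(log_marginals)
  if (is.null(prior_probs)) prior_probs <- rep(1 / L, L)
  if (length(prior_probs) != L)
    stop("prior_probs length must match log_marginals", call. = FALSE)
  if (abs(sum(prior_probs) - 1) > 1e-8)
    stop("prior_probs must sum to 1", call. = FALSE)
  if (is.null(model_names)) model_names <- paste0("M", seq_len(L) - 1L)
  lw <- log_marginals + log(prior_probs)
  post <- exp(lw - logsumexp(lw))
  dl <- log_marginals - log_marginals[reference]
  out <- data.frame(model = model_names,
                    log_marginal = log_marginals,
                    prior_prob = prior_probs,
                    post_prob = post,
                    bayes_factor = exp(dl),
                    log10_bf = dl / log(10),
                    two_ln_bf = 2 * dl)
  class(out) <- c("model_comparison", "data.frame")
  attr(out, "reference") <- reference
  out
}

#' @export
print.model_comparison <- function(x, digits = 3, ...) {
  cat("Bayesian model comparison (reference: ",
      x$model[attr(x, "reference")], ")\n\n", sep = "")
  df <- data.frame(Model = x$model,
                   `Pr(Model|data)` = signif(x$post_prob, digits),
                   B_l0 = signif(x$bayes_factor, digits + 1),
                   log10_B = round(x$log10_bf, 2),
                   two_ln_B = round(x$two_ln_bf, 2),
                   check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}
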