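#' SCR model parameters
#'
#' Bundles the parameters of the spatial detection model. The baseline
#' encounter hazard at distance zero is `lam0_female`; males get
#' `lam0_female * exp(beta_sex)` (log-scale sex effect). Movement scales
#' `sigma_female`/`sigma_male` set the spatial decay of the kernel, and
#' `theta` interpolates its shape between exponential (0.5) and Gaussian
#' (1.0). `psi` is the data-augmentation inclusion probability and
#' `psi_sex` the proportion of the population that is male.
#'
#' @param lam0_female baseline per-occasion encounter hazard, > 0.
#' @param beta_sex log-scale sex effect on the baseline hazard (0 in
#'   models without it).
#' @param sigma_female,sigma_male movement scales, > 0 (equal in models
#'   without the sex covariate on sigma).
#' @param theta kernel shape in \[0.5, 1\].
#' @param psi inclusion probability in \[0, 1\].
#' @param psi_sex proportion male in \[0, 1\].
#' @return An object of class `scr_params`.
#' @export
scr_params <- function(lam0_female, beta_sex = 0,
                       sigma_female, sigma_male = sigma_female,
                       theta = 1, psi = 0.5, psi_sex = 0.5) {
  p <- list(lam0_female = lam0_female, beta_sex = beta_sex,
            sigma_female = sigma_female, sigma_male = sigma_male,
            theta = theta, psi = psi, psi_sex = psi_sex)
  validate_scr_params(p)
  structure(p, class = "scr_params")
}

validate_scr_params <- function(p) {
  stopifnot(p$lam0_female > 0, p$sigma_female > 0, p$sigma_male > 0)
  if (p$theta < 0.5 || p$theta > 1)
    stop("theta must lie in [0.5, 1]", call. = FALSE)
  if (p$psi < 0 || p$psi > 1 || p$psi_sex < 0 || p$psi_sex > 1)
    stop("psi and psi_sex must lie in [0, 1]", call. = FALSE)
  invisible(p)
}

#' @export
print.scr_params <- function(x, ...) {
  cat("scr_params: lam0_f =", signif(x$lam0_female, 4),
      " beta_sex =", signif(x$beta_sex, 4),
      " sigma_f =", signif(x$sigma_female, 4),
      " sigma_m =", signif(x$sigma_male, 4),
      " theta =", signif(x$theta, 4),
      " psi =", signif(x$psi, 4),
      " psi_sex =", signif(x$psi_sex, 4), "\n")
  invisible(x)
}

lam0_for_sex <- function(params, male) {
  params$lam0_female * ifelse(male, exp(params$beta_sex), 1)
}

sigma_for_sex <- function(params, male) {
  ifelse(male, params$sigma_male, params$sigma_female)
}

#' Model parameterization
#'
#' Selects the covariate structure of the four standard SCR
#' parameterizations: `"distance"` (no sex effects), `"sex"` (sex on the
#' baseline hazard), `"sigma-sex"` (sex on the movement scale), and
#' `"sex+sigma-sex"` (both), together with the kernel-shape mode, the
#' augmented population size M, and proper priors (required for marginal
#' likelihoods).
#'
#' @param model one of `"distance"`, `"sex"`, `"sigma-sex"`,
#'   `"sex+sigma-sex"`.
#' @param M augmented population size; must exceed the number of observed
#'   individuals.
#' @param theta_fixed `NULL` to estimate the kernel shape, or a value in
#'   \[0.5, 1\] to fix it (1 = Gaussian half-normal hazard).
#' @param priors named list of prior hyperparameters; see Details.
#' @details Default priors (all proper): `lam0_female ~ U(0, lam0_max)`
#'   with `lam0_max = 5`; `beta_sex ~ N(0, beta_sd^2)` with `beta_sd = 10`;
#'   `sigma ~ U(0, sigma_max)` where `sigma_max` defaults to the statespace
#'   diagonal at fit time; `theta ~ U(0.5, 1)`; `psi, psi_sex ~ Beta(1, 1)`
#'   (giving population size a uniform prior on 0..M).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(model = c("distance", "sex", "sigma-sex",
                                 "sex+sigma-sex"),
                       M, theta_fixed = 1, priors = list()) {
  model <- match.arg(model)
  M <- suppressWarnings(as.integer(M))
  if (!is.na(M) && M < 1L) stop("M must be positive", call. = FALSE)
  if (!is.null(theta_fixed) &&
      (theta_fixed < 0.5 || theta_fixed > 1))
    stop("theta_fixed must lie in [0.5, 1]", call. = FALSE)
  pr <- utils::modifyList(
    list(lam0_max = 5, beta_sd = 10, sigma_max = NULL,
         psi_beta = c(1, 1), psi_sex_beta = c(1, 1)),
    priors)
  structure(
    list(model = model,
         sex_on_lam0 = model %in% c("sex", "sex+sigma-sex"),
         sex_on_sigma = model %in% c("sigma-sex", "sex+sigma-sex"),
         theta_fixed = theta_fixed,
         M = M, priors = pr),
    class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec:", x$model, "; M =", x$M, "; theta",
      if (is.null(x$theta_fixed)) "estimated" else
        paste("fixed at", x$theta_fixed), "\n")
  invisible(x)
}

#' Distance-dependent detection probability
#'
#' Per-occasion detection probability at distance `d` from an activity
#' center: `p = 1 - exp(-lam0 * exp(-0.5 * (d/sigma)^(2*theta)))`, the
#' complementary log-log map of an encounter hazard with a kernel that is
#' exponential at `theta = 0.5` and Gaussian (half-normal hazard) at
#' `theta = 1`.
#'
#' @param d distance(s) >= 0.
#' @param lam0 baseline hazard > 0.
#' @param sigma movement scale > 0.
#' @param theta kernel shape in \[0.5, 1\].
#' @return Detection probabilities in (0, 1 - exp(-lam0)\], strictly
#'   decreasing in `d`.
#' @examples
#' detection_prob(0, lam0 = 0.05, sigma = 1)    # 1 - exp(-0.05)
#' detection_prob(1, lam0 = 0.05, sigma = 1)    # ~0.0299
#' @export
detection_prob <- function(d, lam0, sigma, theta = 1) {
  if (any(d < 0)) stop("distance must be >= 0", call. = FALSE)
  if (any(lam0 <= 0) || any(sigma <= 0))
    stop("lam0 and sigma must be > 0", call. = FALSE)
  if (any(theta < 0.5) || any(theta > 1))
    stop("theta must lie in [0.5, 1]", call. = FALSE)
  1 - exp(-lam0 * exp(-0.5 * ((d / sigma)^2)^theta))
}

# log detection probability matrices for a pixel/center x trap squared
# distance matrix; returns list(logp, log1mp)
kernel_logp <- function(d2, lam0, sigma, theta) {
  e <- d2 / sigma^2
  h <- lam0 * exp(-0.5 * if (theta == 1) e else e^theta)
  log1mp <- -h                       # log(1 - p) = -hazard
  p <- -expm1(-h)
  list(logp = log(p), log1mp = log1mp)
}

#' Log-likelihood of one individual's capture history
#'
#' Sums Bernoulli log-masses over traps and occasions for a single
#' individual with known activity center and sex. Occasions during which
#' a trap was not operating contribute nothing.
#'
#' @param y_i binary trap x occasion matrix for the individual.
#' @param s length-2 activity-center coordinate.
#' @param sex `"F"` or `"M"`.
#' @param params an [scr_params()].
#' @param traps a [trap_array()] (its `operation` mask, if any, is
#'   respected).
#' @return The log-probability of `y_i`.
#' @export
per_individual_loglik <- function(y_i, s, sex, params, traps) {
  y_i <- as.matrix(y_i)
  J <- n_traps(traps)
  if (nrow(y_i) != J)
    stop("y_i rows must match trap count", call. = FALSE)
  male <- identical(toupper(sex), "M")
  d2 <- (traps$coords[, "x"] - s[1])^2 + (traps$coords[, "y"] - s[2])^2
  kp <- kernel_logp(d2, lam0_for_sex(params, male),
                    sigma_for_sex(params, male), params$theta)
  op <- traps$operation
  if (is.null(op)) op <- matrix(1L, J, ncol(y_i))
  if (any(y_i == 1L & op == 0L))
    stop("detection recorded at a non-operating trap-occasion",
         call. = FALSE)
  sum(op * (y_i * kp$logp + (1 - y_i) * kp$log1mp))
}
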