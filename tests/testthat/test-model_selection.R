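# Conjugate toys with closed-form marginal likelihoods serve as the
# independent oracle for the Gelfand-Dey estimator; gd_beta_bernoulli
# lives in helper-oracles.R (shared with the acceptance suite).

test_that("Gelfand-Dey recovers the Beta-Bernoulli marginal", {
  truth <- lbeta(4, 8)                     # -7.1846 for 3/10
  expect_equal(truth, log(gamma(4) * gamma(8) / gamma(12)))
  res <- gd_beta_bernoulli(10000, seed = 1)
  expect_lt(abs(res$log_marginal - truth), 3 * res$se)
  expect_lt(abs(res$log_marginal - truth), 0.05)
})

test_that("Gelfand-Dey error decays like c^(-1/2)", {
  truth <- lbeta(4, 8)
  err <- function(c_draws) sapply(1:12, function(s)
    gd_beta_bernoulli(c_draws, seed = 100 + s)$log_marginal - truth)
  rmse_small <- sqrt(mean(err(500)^2))
  rmse_big <- sqrt(mean(err(8000)^2))
  # 16x the draws: expect ~4x smaller RMSE, allow [1.5, 12]
  expect_gt(rmse_small / rmse_big, 1.5)
  expect_lt(rmse_small / rmse_big, 12)
})

test_that("Gelfand-Dey recovers a Normal-Normal marginal", {
  # y_i ~ N(mu, 1), mu ~ N(0, 1); closed-form log m(y)
  set.seed(42)
  y <- c(0.3, -1.2, 0.8, 1.9, 0.4)
  n <- length(y)
  post_var <- 1 / (n + 1); post_mean <- sum(y) * post_var
  # closed form: marginally y ~ N(0, I + 11^T)
  S <- diag(n) + 1
  log_m <- -0.5 * (n * log(2 * pi) + determinant(S)$modulus[1] +
                     drop(y %*% solve(S, y)))
  mu <- rnorm(8000, post_mean, sqrt(post_var))
  # covariance scale: the posterior sd here is far from 1, so the
  # unit-variance correlation scale would overlap the posterior poorly
  res <- gd_log_marginal(matrix(mu, ncol = 1),
                         loglik = function(w) sum(dnorm(y, w[1], 1,
                                                        log = TRUE)),
                         logprior = function(w) dnorm(w[1], 0, 1,
                                                      log = TRUE),
                         scale = "covariance")
  expect_lt(abs(res$log_marginal - log_m), 3 * res$se)
  expect_lt(abs(res$log_marginal - log_m), 0.05)
})

test_that("a model with no free parameters returns its likelihood", {
  draws <- matrix(numeric(0), nrow = 50, ncol = 0)
  res <- gd_log_marginal(draws, loglik = function(w) -3.25,
                         logprior = function(w) 0)
  expect_equal(res$log_marginal, -3.25, tolerance = 1e-12)
  expect_equal(res$se, 0, tolerance = 1e-9)
})

test_that("degenerate importance scales are reported", {
  x <- rnorm(200)
  draws <- cbind(x, x)                     # perfectly correlated
  expect_error(gd_log_marginal(draws, function(w) 0, function(w) 0),
               "singular")
  # jitter rescues it
  res <- gd_log_marginal(draws, function(w) dnorm(w[1], log = TRUE) - 10,
                         function(w) dnorm(w[1], log = TRUE),
                         jitter = 0.05)
  expect_true(is.finite(res$log_marginal))
})

test_that("model comparison arithmetic is exact", {
  # equal marginals, uniform prior: all probabilities 0.25, B = 1
  cmp <- compare_models(rep(-100, 4))
  expect_equal(cmp$post_prob, rep(0.25, 4))
  expect_equal(cmp$bayes_factor, rep(1, 4))
  expect_equal(cmp$log10_bf, rep(0, 4))
  expect_equal(cmp$two_ln_bf, rep(0, 4))

  # log-marginal gap of ln 3: probabilities 0.75/0.25, B = 3
  cmp2 <- compare_models(c(-10, -10 + log(3)))
  expect_equal(cmp2$post_prob, c(0.25, 0.75), tolerance = 1e-12)
  expect_equal(cmp2$bayes_factor[2], 3, tolerance = 1e-12)

  # internal consistency of the transforms
  set.seed(1)
  lm <- rnorm(5, -500, 3)
  cmp3 <- compare_models(lm, reference = 2)
  expect_equal(sum(cmp3$post_prob), 1, tolerance = 1e-12)
  expect_equal(cmp3$bayes_factor[2], 1)
  expect_lt(max(abs(cmp3$two_ln_bf -
                      2 * log(exp(lm - lm[2])))), 1e-12)
  # invariance: shifting all log-marginals changes nothing
  cmp4 <- compare_models(lm + 123.4, reference = 2)
  expect_equal(cmp4$post_prob, cmp3$post_prob, tolerance = 1e-12)
  expect_equal(cmp4$bayes_factor, cmp3$bayes_factor, tolerance = 1e-10)

  expect_error(compare_models(c(-1, -2), prior_probs = c(1, 1, 1) / 3),
               "length")
  expect_error(compare_models(c(-1, -2), prior_probs = c(0.7, 0.7)),
               "sum to 1")
})

test_that("a fitted SCR model yields a finite Gelfand-Dey marginal", {
  cfg <- sim_config(n_female = 25, n_male = 15, extent = 8,
                    trap_rows = 5, trap_cols = 5, trap_spacing = 1.2,
                    n_occasions = 12,
                    params = scr_params(0.4, beta_sex = -0.7,
                                        sigma_female = 1))
  sim <- simulate_scr(cfg, seed = 21)
  sp <- build_statespace(sim$traps, buffer = 2, spacing = 1)
  fit <- scr_fit(sim$history, sp, model_spec("sex", M = 100),
                 iters = 600, burnin = 200, thin = 2, seed = 3,
                 keep_pixel_counts = FALSE)
  res <- scr_log_marginal(fit, sim$history, sp, gd_draws = 100)
  expect_true(is.finite(res$log_marginal))
  expect_true(res$se >= 0)
  # the marginal is far below 0 for data of this size
  expect_lt(res$log_marginal, -100)
})
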