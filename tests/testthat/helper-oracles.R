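# Independent oracles and small fixture builders, used across test files.

# Brute-force integrated likelihood: direct enumeration over every latent
# configuration (pixel x sex x inclusion) per augmented slot, written
# with explicit loops and detection_prob() only -- independent of the
# vectorised log-space implementation it checks.
brute_integrated_loglik <- function(params, data, space, spec) {
  npix <- nrow(space$pixel_centers)
  nobs <- dim(data$y)[1]
  nJ <- dim(data$y)[2]; nK <- dim(data$y)[3]
  op <- data$traps$operation
  if (is.null(op)) op <- matrix(1L, nJ, nK)
  sex_w <- c(F = 1 - params$psi_sex, M = params$psi_sex)
  slot_lik <- function(y_i, sex_label) {
    sexes <- if (sex_label %in% c("F", "M")) sex_label else c("F", "M")
    tot <- 0
    for (g in sexes) {
      lam0 <- if (g == "M") params$lam0_female * exp(params$beta_sex) else
        params$lam0_female
      sig <- if (g == "M") params$sigma_male else params$sigma_female
      for (px in seq_len(npix)) {
        lik <- 1
        for (j in seq_len(nJ)) {
          d <- sqrt(sum((space$pixel_centers[px, ] -
                           data$traps$coords[j, ])^2))
          p <- detection_prob(d, lam0, sig, params$theta)
          for (k in seq_len(nK)) {
            if (op[j, k] == 0L) next
            lik <- lik * if (y_i[j, k] == 1L) p else (1 - p)
          }
        }
        tot <- tot + sex_w[[g]] * lik / npix
      }
    }
    tot
  }
  total <- 0
  for (i in seq_len(nobs))
    total <- total + log(params$psi *
                           slot_lik(matrix(data$y[i, , ], nJ, nK),
                                    data$sex[i]))
  n_aug <- spec$M - nobs
  if (n_aug > 0) {
    zero_y <- matrix(0L, nJ, nK)
    l0 <- slot_lik(zero_y, "U")
    total <- total + n_aug * log((1 - params$psi) + params$psi * l0)
  }
  total
}

# a small trap grid centered at the origin
toy_traps <- function(n = 4) {
  g <- expand.grid(x = seq_len(ceiling(sqrt(n))) - 1,
                   y = seq_len(ceiling(sqrt(n))) - 1)[seq_len(n), ]
  trap_array(paste0("T", seq_len(n)), g$x, g$y)
}

# capture history built from explicit records
toy_history <- function(records, traps, n_days = 5,
                        scheme = "daily") {
  cal <- occasion_calendar(n_days, scheme)
  captures_from_records(records, traps, cal)
}

# Gelfand-Dey on the Beta(1,1)-Bernoulli toy (k successes in n trials),
# whose exact log marginal is lbeta(k + 1, n - k + 1)
gd_beta_bernoulli <- function(c_draws, seed, k = 3, n = 10) {
  set.seed(seed)
  p <- rbeta(c_draws, k + 1, n - k + 1)
  draws <- matrix(qlogis(p), ncol = 1)
  loglik <- function(w) {
    pr <- plogis(w[1]); k * log(pr) + (n - k) * log(1 - pr)
  }
  logprior <- function(w) {
    pr <- plogis(w[1]); log(pr) + log(1 - pr)  # U(0,1) + logit Jacobian
  }
  gd_log_marginal(draws, loglik, logprior)
}

# length-41 sorted sample whose type-7 quantiles at 2.5/50/97.5% hit the
# requested values exactly (positions 2, 21 and 40 are integral there)
quantile_matching_sample <- function(lo, med, hi) {
  c(lo * 0.99, seq(lo, med, length.out = 20),
    seq(med, hi, length.out = 20)[-1], hi * 1.01)
}

# random small capture history (for property tests)
random_history <- function(n_ind, traps, n_days, seed) {
  set.seed(seed)
  nJ <- length(traps$trap_id)
  repeat {
    y <- array(rbinom(n_ind * nJ * n_days, 1, 0.3),
               dim = c(n_ind, nJ, n_days))
    if (n_ind == 0 || all(apply(y, 1, sum) > 0)) break
  }
  sex <- sample(c("F", "M", "U"), n_ind, replace = TRUE)
  capture_history(y, sex, occasion_calendar(n_days, "daily"), traps)
}
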