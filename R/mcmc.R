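#' Fit a spatial capture-recapture model by data-augmentation MCMC
#'
#' Samples the joint posterior of the detection parameters and the latent
#' state (inclusion indicators `z`, activity-center pixels `s`, and latent
#' sex) for one of the four standard parameterizations. Top-level
#' parameters move by random-walk Metropolis on unconstrained scales
#' (log for `lam0` and `sigma`, identity for `beta_sex`, scaled logit for
#' `theta`), with proposal scales auto-tuned toward 25-45% acceptance
#' during burn-in and then frozen. `z`, latent sex, `psi` and `psi_sex`
#' have conjugate Gibbs updates; activity centers are redrawn by an exact
#' full-conditional categorical scan over statespace pixels.
#'
#' @param data a [capture_history()]; must contain at least one capture.
#' @param space a `statespace` from [build_statespace()].
#' @param spec a [model_spec()]; if its `M` is `NA`, the default 10x the
#'   number of observed individuals is used.
#' @param iters total MCMC iterations.
#' @param burnin iterations discarded as burn-in.
#' @param thin keep every `thin`-th post-burn-in iteration (2 keeps every
#'   other one).
#' @param seed integer RNG seed; identical data + configuration + seed
#'   give bit-identical draws.
#' @param keep_pixel_counts store per-draw active-center counts per pixel
#'   (needed by [density_surface()]).
#' @param tune_interval burn-in window length for proposal adaptation.
#' @return An object of class `scr_fit`: `draws` (matrix with one row per
#'   retained draw: parameters, `N`, `density`), `pixel_counts`
#'   (pixels x draws integer matrix or `NULL`), and `meta` (model spec,
#'   resolved priors, schedule, seed, acceptance rates, convergence
#'   diagnostics, and an `M_warning` flag set when posterior `N` pushes
#'   against `M`).
#' @export
scr_fit <- function(data, space, spec, iters = 20000, burnin = 5000,
                    thin = 2, seed = 1, keep_pixel_counts = TRUE,
                    tune_interval = 50) {
  nobs <- n_individuals(data)
  if (nobs == 0L || sum(data$y) == 0L)
    stop("refusing to fit: data contain no captures", call. = FALSE)
  M <- spec$M
  if (is.na(M)) M <- 10L * nobs
  if (M <= nobs)
    stop("M must exceed the number of observed individuals", call. = FALSE)
  set.seed(as.integer(seed))

  pre <- precompute_counts(data)
  npix <- n_pixels(space)
  d2 <- pairwise_dist2(space$pixel_centers, data$traps$coords)
  pr <- spec$priors
  if (is.null(pr$sigma_max)) {
    ext <- space$extent
    pr$sigma_max <- sqrt((ext["xmax"] - ext["xmin"])^2 +
                         (ext["ymax"] - ext["ymin"])^2)
  }
  pr$sigma_max <- unname(pr$sigma_max)

  est_theta <- is.null(spec$theta_fixed)
  # --- initial values -------------------------------------------------
  phat <- sum(pre$n) / max(1, nobs * sum(pre$Kj))
  lam0 <- min(max(-log(1 - min(0.95, 10 * phat)), 0.01),
              0.9 * pr$lam0_max)
  mean_caploc <- t(vapply(seq_len(nobs), function(i) {
    w <- pre$n[i, ]
    c(sum(w * data$traps$coords[, "x"]),
      sum(w * data$traps$coords[, "y"])) / sum(w)
  }, numeric(2)))
  spread <- vapply(seq_len(nobs), function(i) {
    jj <- which(pre$n[i, ] > 0)
    if (length(jj) < 2) return(NA_real_)
    max(dist(data$traps$coords[jj, , drop = FALSE]))
  }, numeric(1))
  sig0 <- stats::median(spread, na.rm = TRUE) / 2
  if (!is.finite(sig0) || sig0 <= 0) sig0 <- max(space$spacing, 1e-2)
  sig0 <- min(sig0, 0.5 * pr$sigma_max)
  par <- list(lam0 = lam0, beta = 0, sigma_f = sig0, sigma_m = sig0,
              theta = if (est_theta) 0.75 else spec$theta_fixed)
  psi <- min(0.9, (1.5 * nobs + 1) / M)
  sex_known <- data$sex %in% c("F", "M")
  male <- c(ifelse(data$sex == "M", 1L, ifelse(data$sex == "F", 0L, NA)),
            rep(NA_integer_, M - nobs))
  latent_sex <- is.na(male)
  obs_m <- sum(male[seq_len(nobs)] == 1L, na.rm = TRUE)
  obs_f <- sum(male[seq_len(nobs)] == 0L, na.rm = TRUE)
  psi_sex <- (obs_m + 1) / (obs_m + obs_f + 2)
  male[latent_sex] <- stats::rbinom(sum(latent_sex), 1L, psi_sex)
  z <- c(rep(TRUE, nobs), stats::runif(M - nobs) < psi)
  s <- integer(M)
  s[seq_len(nobs)] <- vapply(seq_len(nobs), function(i)
    which.min((space$pixel_centers[, 1] - mean_caploc[i, 1])^2 +
              (space$pixel_centers[, 2] - mean_caploc[i, 2])^2),
    integer(1))
  if (M > nobs) s[(nobs + 1):M] <- sample.int(npix, M - nobs, replace = TRUE)

  # --- kernel cache ---------------------------------------------------
  # shape G = exp(-0.5 (d/sigma)^(2 theta)) is the expensive part; the
  # hazard is lam0 * G, so lam0/beta proposals reuse a cached shape
  kshape <- function(d2x, sigma, theta) {
    e <- d2x / sigma^2
    exp(-0.5 * if (theta == 1) e else e^theta)
  }
  kfromG <- function(G, lam0) {
    h <- lam0 * G
    list(logp = log(-expm1(-h)), log1mp = -h)
  }
  kernels <- function(p, d2x = d2) {
    list(F = kfromG(kshape(d2x, p$sigma_f, p$theta), p$lam0),
         M = kfromG(kshape(d2x, p$sigma_m, p$theta),
                    p$lam0 * exp(p$beta)))
  }
  zll <- function(kp) list(F = as.vector(kp$F$log1mp %*% pre$Kj),
                           M = as.vector(kp$M$log1mp %*% pre$Kj))
  # log-likelihood of all active slots given latent state; `rows` maps a
  # slot's pixel into the rows of the kernel matrices supplied
  active_loglik <- function(kp, z0, rows = s) {
    tot <- 0
    for (g in c(0L, 1L)) {
      io <- which(male[seq_len(nobs)] == g)
      if (length(io)) {
        kg <- if (g == 1L) kp$M else kp$F
        rr <- rows[io]
        tot <- tot + sum(pre$n[io, , drop = FALSE] *
                           kg$logp[rr, , drop = FALSE]) +
          sum(Kn_obs[io, , drop = FALSE] *
                kg$log1mp[rr, , drop = FALSE])
      }
    }
    ia <- which(z & seq_len(M) > nobs)
    if (length(ia))
      tot <- tot + sum(ifelse(male[ia] == 1L, z0$M[rows[ia]],
                              z0$F[rows[ia]]))
    tot
  }
  Kn_obs <- t(pre$tKn)                 # (K - n), observed x traps
  kp <- kernels(par); z0 <- zll(kp)

  # --- transformed-scale log prior per RW parameter -------------------
  lprior <- function(name, value) {
    switch(name,
      lam0 = if (value >= pr$lam0_max || value <= 0) -Inf else
        log(value) - log(pr$lam0_max),
      beta = stats::dnorm(value, 0, pr$beta_sd, log = TRUE),
      sigma_f = ,
      sigma_m = if (value >= pr$sigma_max || value <= 0) -Inf else
        log(value) - log(pr$sigma_max),
      theta = {
        q <- (value - 0.5) / 0.5
        if (q <= 0 || q >= 1) -Inf else log(q * (1 - q))
      })
  }
  rw_names <- c("lam0",
                if (spec$sex_on_lam0) "beta",
                "sigma_f",
                if (spec$sex_on_sigma) "sigma_m",
                if (est_theta) "theta")
  rw_sd <- stats::setNames(rep(0.2, length(rw_names)), rw_names)
  acc <- win <- stats::setNames(numeric(length(rw_names)), rw_names)
  acc_total <- prop_total <- acc

  to_nat <- function(name, t) switch(name,
    lam0 = exp(t), beta = t, sigma_f = exp(t), sigma_m = exp(t),
    theta = 0.5 + 0.5 * stats::plogis(t))
  to_t <- function(name, v) switch(name,
    lam0 = log(v), beta = v, sigma_f = log(v), sigma_m = log(v),
    theta = stats::qlogis((v - 0.5) / 0.5))

  n_keep <- floor((iters - burnin) / thin)
  par_cols <- c("lam0_female", "beta_sex", "sigma_female", "sigma_male",
                "theta", "psi", "psi_sex", "N", "density")
  draws <- matrix(NA_real_, n_keep, length(par_cols),
                  dimnames = list(NULL, par_cols))
  pix_counts <- if (keep_pixel_counts)
    matrix(0L, npix, n_keep) else NULL
  keep_i <- 0L
  idx_aug <- if (M > nobs) (nobs + 1L):M else integer(0)

  for (it in seq_len(iters)) {
    ## 1. random-walk Metropolis on top-level parameters, evaluated on
    ## the pixels currently occupied by active slots only
    occ <- sort(unique(s[z]))
    smap <- match(s, occ)
    d2s <- d2[occ, , drop = FALSE]
    Kjs <- pre$Kj
    zll_s <- function(kq) list(F = as.vector(kq$F$log1mp %*% Kjs),
                               M = as.vector(kq$M$log1mp %*% Kjs))
    kq <- kernels(par, d2s)
    ll_cur <- active_loglik(kq, zll_s(kq), smap)
    any_acc <- FALSE
    for (name in rw_names) {
      cur_t <- to_t(name, par[[name]])
      prop_t <- cur_t + stats::rnorm(1, 0, rw_sd[name])
      prop_v <- to_nat(name, prop_t)
      lp_new <- lprior(name, prop_v)
      if (is.finite(lp_new)) {
        par2 <- par
        par2[[name]] <- prop_v
        if (!spec$sex_on_sigma) par2$sigma_m <- par2$sigma_f
        kq2 <- kq
        upd_M <- name %in% c("lam0", "beta", "sigma_m", "theta") ||
          (name == "sigma_f" && !spec$sex_on_sigma)
        upd_F <- name %in% c("lam0", "sigma_f", "theta")
        if (upd_F)
          kq2$F <- kfromG(kshape(d2s, par2$sigma_f, par2$theta),
                          par2$lam0)
        if (upd_M)
          kq2$M <- kfromG(kshape(d2s, par2$sigma_m, par2$theta),
                          par2$lam0 * exp(par2$beta))
        ll_new <- active_loglik(kq2, zll_s(kq2), smap)
        lr <- (ll_new + lp_new) - (ll_cur + lprior(name, par[[name]]))
        if (log(stats::runif(1)) < lr) {
          par <- par2; kq <- kq2; ll_cur <- ll_new; any_acc <- TRUE
          acc[name] <- acc[name] + 1; acc_total[name] <- acc_total[name] + 1
        }
      }
      win[name] <- win[name] + 1; prop_total[name] <- prop_total[name] + 1
      if (it <= burnin && win[name] >= tune_interval) {
        rate <- acc[name] / win[name]
        if (rate < 0.25) rw_sd[name] <- rw_sd[name] * 0.8
        else if (rate > 0.45) rw_sd[name] <- rw_sd[name] * 1.25
        acc[name] <- 0; win[name] <- 0
      }
    }
    if (any_acc) { kp <- kernels(par); z0 <- zll(kp) }

    ## 2. inclusion indicators for augmented slots (Gibbs)
    if (length(idx_aug)) {
      zl <- ifelse(male[idx_aug] == 1L, z0$M[s[idx_aug]], z0$F[s[idx_aug]])
      pz <- stats::plogis(stats::qlogis(psi) + zl)
      z[idx_aug] <- stats::runif(length(idx_aug)) < pz
    }

    ## 3. psi (conjugate Beta)
    psi <- stats::rbeta(1, pr$psi_beta[1] + sum(z),
                        pr$psi_beta[2] + M - sum(z))

    ## 4. activity centers: exact categorical scan
    for (g in c(0L, 1L)) {
      kg <- if (g == 1L) kp$M else kp$F
      io <- which(male[seq_len(nobs)] == g)
      if (length(io)) {
        A <- kg$logp %*% pre$tn[, io, drop = FALSE] +
          kg$log1mp %*% pre$tKn[, io, drop = FALSE]
        G <- matrix(-log(stats::rexp(npix * length(io))),
                    npix, length(io))
        s[io] <- max.col(t(A + G), ties.method = "first")
      }
      zg <- if (g == 1L) z0$M else z0$F
      ia <- idx_aug[z[idx_aug] & male[idx_aug] == g]
      if (length(ia)) {
        w <- exp(zg - max(zg))
        s[ia] <- sample.int(npix, length(ia), replace = TRUE, prob = w)
      }
    }
    id <- idx_aug[!z[idx_aug]]
    if (length(id)) s[id] <- sample.int(npix, length(id), replace = TRUE)

    ## 5. latent sex (Gibbs); likelihood term only for active slots
    il <- which(latent_sex)
    if (length(il)) {
      dll <- numeric(length(il))
      ia <- il[z[il] & il > nobs]
      if (length(ia))
        dll[match(ia, il)] <- z0$M[s[ia]] - z0$F[s[ia]]
      iu <- il[il <= nobs]           # observed, unknown sex (always active)
      if (length(iu)) {
        rows <- s[iu]
        llM <- rowSums(pre$n[iu, , drop = FALSE] *
                         kp$M$logp[rows, , drop = FALSE]) +
          rowSums(Kn_obs[iu, , drop = FALSE] *
                    kp$M$log1mp[rows, , drop = FALSE])
        llF <- rowSums(pre$n[iu, , drop = FALSE] *
                         kp$F$logp[rows, , drop = FALSE]) +
          rowSums(Kn_obs[iu, , drop = FALSE] *
                    kp$F$log1mp[rows, , drop = FALSE])
        dll[match(iu, il)] <- llM - llF
      }
      pm <- stats::plogis(stats::qlogis(psi_sex) + dll)
      male[il] <- as.integer(stats::runif(length(il)) < pm)
    }

    ## 6. psi_sex (conjugate Beta over all slots with modelled sex)
    nm <- obs_m + sum(male[latent_sex] == 1L)
    nf <- obs_f + sum(male[latent_sex] == 0L)
    psi_sex <- stats::rbeta(1, pr$psi_sex_beta[1] + nm,
                            pr$psi_sex_beta[2] + nf)

    ## 7. record
    if (it > burnin && (it - burnin) %% thin == 0L) {
      keep_i <- keep_i + 1L
      N <- sum(z)
      draws[keep_i, ] <- c(par$lam0, if (spec$sex_on_lam0) par$beta else 0,
                           par$sigma_f,
                           if (spec$sex_on_sigma) par$sigma_m else
                             par$sigma_f,
                           par$theta, psi, psi_sex,
                           N, N / space$total_area)
      if (keep_pixel_counts)
        pix_counts[, keep_i] <- tabulate(s[z], nbins = npix)
    }
  }

  draws <- draws[seq_len(keep_i), , drop = FALSE]
  if (keep_pixel_counts)
    pix_counts <- pix_counts[, seq_len(keep_i), drop = FALSE]
  M_warning <- any(draws[, "N"] > 0.9 * M)
  if (M_warning)
    warning("posterior N exceeded 0.9*M; increase the augmentation M",
            call. = FALSE)
  spec$M <- M
  structure(
    list(draws = draws,
         pixel_counts = pix_counts,
         meta = list(spec = spec, priors = pr, iters = iters,
                     burnin = burnin, thin = thin, seed = seed,
                     n_draws = keep_i, M = M, n_obs = nobs,
                     total_area = space$total_area,
                     acceptance = ifelse(prop_total > 0,
                                         acc_total / prop_total, NA),
                     proposal_sd = rw_sd,
                     M_warning = M_warning,
                     diagnostics = chain_diagnostics(draws, rw_names))),
    class = "scr_fit")
}

# split-chain R-hat and crude effective sample size for the sampled
# top-level parameters; reporting only, never used to reject a run
chain_diagnostics <- function(draws, rw_names) {
  cols <- c(lam0 = "lam0_female", beta = "beta_sex",
            sigma_f = "sigma_female", sigma_m = "sigma_male",
            theta = "theta")[rw_names]
  cols <- c(unname(cols), "psi", "N")
  out <- lapply(cols, function(cn) {
    x <- draws[, cn]
    n <- length(x)
    if (n < 8 || stats::sd(x) == 0)
      return(c(rhat = NA_real_, ess = NA_real_))
    half <- floor(n / 2)
    ch <- cbind(x[seq_len(half)], x[(n - half + 1):n])
    W <- mean(apply(ch, 2, stats::var))
    B <- half * stats::var(colMeans(ch))
    rhat <- sqrt(((half - 1) / half * W + B / half) / W)
    rho <- stats::acf(x, lag.max = min(100, n - 1), plot = FALSE)$acf[-1]
    below <- which(rho < 0.05)
    cut <- if (length(below)) below[1] else length(rho)
    ess <- n / (1 + 2 * sum(rho[seq_len(cut)]))
    c(rhat = rhat, ess = ess)
  })
  m <- do.call(rbind, out)
  rownames(m) <- cols
  if (any(is.finite(m[, "rhat"]) & m[, "rhat"] > 1.1))
    attr(m, "warn") <- "split-chain R-hat > 1.1 for some parameters"
  m
}

#' @export
print.scr_fit <- function(x, ...) {
  cat("scr_fit:", x$meta$spec$model, "model;", x$meta$n_draws,
      "retained draws (", x$meta$iters, "iterations, burn-in",
      x$meta$burnin, ", thin", x$meta$thin, ")\n")
  cat("  observed individuals:", x$meta$n_obs, "; M =", x$meta$M, "\n")
  s <- credible_summary(x$draws[, "density"])
  cat("  density:", signif(s$median, 4), "(",
      signif(s$lower95, 4), "-", signif(s$upper95, 4),
      ") per area unit; SW =", signif(s$sw, 3), "\n")
  invisible(x)
}

#' Direct draws from the model's prior
#'
#' Samples the proper priors of a [model_spec()] (parameters fixed or
#' tied in the model are returned at their constrained values), plus the
#' implied prior on population size `N`: `z_i ~ Bernoulli(psi)` over the
#' `M` augmented slots, so under the default `psi ~ Beta(1, 1)` prior
#' `N` is marginally uniform on `0..M`. Used to check the prior end of
#' the sampler without involving data.
#'
#' @param spec a [model_spec()] with a finite `M`.
#' @param n_draws number of prior draws.
#' @param sigma_max upper bound of the uniform movement-scale prior
#'   (supplied by the statespace diagonal at fit time).
#' @param seed RNG seed.
#' @return A data.frame of prior draws with columns matching the fit's
#'   parameter draws plus `N`.
#' @export
sample_scr_prior <- function(spec, n_draws, sigma_max, seed = 1) {
  set.seed(as.integer(seed))
  pr <- spec$priors
  if (is.null(pr$sigma_max)) pr$sigma_max <- sigma_max
  n <- n_draws
  sf <- stats::runif(n, 0, pr$sigma_max)
  psi <- stats::rbeta(n, pr$psi_beta[1], pr$psi_beta[2])
  data.frame(
    lam0_female = stats::runif(n, 0, pr$lam0_max),
    beta_sex = if (spec$sex_on_lam0)
      stats::rnorm(n, 0, pr$beta_sd) else 0,
    sigma_female = sf,
    sigma_male = if (spec$sex_on_sigma)
      stats::runif(n, 0, pr$sigma_max) else sf,
    theta = if (is.null(spec$theta_fixed))
      stats::runif(n, 0.5, 1) else spec$theta_fixed,
    psi = psi,
    psi_sex = stats::rbeta(n, pr$psi_sex_beta[1], pr$psi_sex_beta[2]),
    N = stats::rbinom(n, spec$M, psi))
}

#' Median, 95% credibility interval and standardized width
#'
#' Equal-tailed 2.5/97.5% interval around the posterior median, plus the
#' standardized width `(upper - lower) / median`, a scale-free precision
#' measure.
#'
#' @param x numeric vector of posterior draws.
#' @return A list with `median`, `lower95`, `upper95`, `sw`.
#' @examples
#' credible_summary(rnorm(1000, 10, 1))
#' @export
credible_summary <- function(x) {
  q <- unname(stats::quantile(x, c(0.025, 0.5, 0.975), type = 7))
  list(median = q[2], lower95 = q[1], upper95 = q[3],
       sw = (q[3] - q[1]) / q[2])
}

#' Posterior summaries of an SCR fit
#'
#' @param fit an [scr_fit()] result.
#' @return A data.frame with one row per parameter (plus `N` and
#'   `density`): posterior mean, median, 95% interval bounds and
#'   standardized width.
#' @export
summarize_draws <- function(fit) {
  stopifnot(inherits(fit, "scr_fit"))
  rows <- lapply(colnames(fit$draws), function(cn) {
    cs <- credible_summary(fit$draws[, cn])
    data.frame(parameter = cn, mean = mean(fit$draws[, cn]),
               median = cs$median, lower95 = cs$lower95,
               upper95 = cs$upper95, sw = cs$sw)
  })
  do.call(rbind, rows)
}

#' Posterior density surface and regional abundance
#'
#' Per-pixel posterior mean density of active (included) activity
#' centers, and the posterior of the number of active centers inside an
#' optional region.
#'
#' @param fit an [scr_fit()] run with `keep_pixel_counts = TRUE`.
#' @param space the `statespace` the model was fitted with.
#' @param region optional logical vector over pixels (`TRUE` = inside);
#'   default whole statespace.
#' @return A list: `pixel_density` (posterior mean density per pixel),
#'   `abundance` (a [credible_summary()] of the per-draw region count)
#'   and `region_area`.
#' @export
density_surface <- function(fit, space, region = NULL) {
  if (is.null(fit$pixel_counts))
    stop("fit was run without keep_pixel_counts", call. = FALSE)
  npix <- n_pixels(space)
  if (nrow(fit$pixel_counts) != npix)
    stop("statespace does not match the fit", call. = FALSE)
  if (is.null(region)) region <- rep(TRUE, npix)
  if (length(region) != npix)
    stop("region mask must have one entry per pixel", call. = FALSE)
  mean_count <- rowMeans(fit$pixel_counts)
  ab_draws <- colSums(fit$pixel_counts[region, , drop = FALSE])
  list(pixel_density = mean_count / space$pixel_area,
       abundance = credible_summary(ab_draws),
       region_area = sum(region) * space$pixel_area)
}
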