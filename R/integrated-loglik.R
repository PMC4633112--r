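#' Integrated observation likelihood of an augmented SCR dataset
#'
#' Log-likelihood of the capture data with all latent state removed by
#' summation: for each of the `M` augmented slots the activity center is
#' summed over statespace pixels (uniform weight `1/npix`), sex is summed
#' over female/male with weights `(1 - psi_sex, psi_sex)` when unknown,
#' and the inclusion indicator is summed over in (probability `psi`,
#' emitting the Bernoulli product over traps and occasions) and out
#' (probability `1 - psi`, carrying mass only for an all-zero history).
#' Observed sex labels are data: a sexed individual contributes the
#' factor `psi_sex` (male) or `1 - psi_sex` (female). Augmented slots are
#' exchangeable and no binomial multiplicity term is included, the
#' standard data-augmentation convention; Bayes factors between models
#' sharing this convention are unaffected.
#'
#' @param params an [scr_params()].
#' @param data a [capture_history()].
#' @param space a `statespace` from [build_statespace()].
#' @param spec a [model_spec()]; only `M` is used here.
#' @return The log integrated likelihood (a scalar).
#' @export
integrated_loglik <- function(params, data, space, spec) {
  nobs <- n_individuals(data)
  if (spec$M < nobs)
    stop("M must be at least the number of observed individuals",
         call. = FALSE)
  pre <- precompute_counts(data)
  d2 <- pairwise_dist2(space$pixel_centers, data$traps$coords)
  npix <- n_pixels(space)
  kpF <- kernel_logp(d2, params$lam0_female, params$sigma_female,
                     params$theta)
  kpM <- kernel_logp(d2, lam0_for_sex(params, TRUE), params$sigma_male,
                     params$theta)
  # all-zero history log-mass per pixel, per sex
  zllF <- as.vector(kpF$log1mp %*% pre$Kj)
  zllM <- as.vector(kpM$log1mp %*% pre$Kj)
  lpsi <- log(params$psi); l1mpsi <- log1p(-params$psi)
  lsexM <- log(params$psi_sex); lsexF <- log1p(-params$psi_sex)

  total <- 0
  if (nobs > 0) {
    # npix x nobs per-pixel log-likelihoods under each sex
    llF <- kpF$logp %*% pre$tn + kpF$log1mp %*% pre$tKn
    llM <- kpM$logp %*% pre$tn + kpM$log1mp %*% pre$tKn
    lseF <- apply(llF, 2, logsumexp) - log(npix)
    lseM <- apply(llM, 2, logsumexp) - log(npix)
    per_obs <- ifelse(
      data$sex == "F", lsexF + lseF,
      ifelse(data$sex == "M", lsexM + lseM,
             mapply(function(a, b) logsumexp(c(lsexF + a, lsexM + b)),
                    lseF, lseM)))
    total <- sum(lpsi + per_obs)
  }
  n_aug <- spec$M - nobs
  if (n_aug > 0) {
    mix0 <- logsumexp(c(lsexF + logsumexp(zllF) - log(npix),
                        lsexM + logsumexp(zllM) - log(npix)))
    total <- total + n_aug * logsumexp(c(l1mpsi, lpsi + mix0))
  }
  total
}

# detection counts per individual x trap under the operation mask, and
# per-trap numbers of operating occasions; pre-transposed for the
# pixel-likelihood matrix products used everywhere
precompute_counts <- function(data) {
  y <- data$y
  nI <- dim(y)[1]; nJ <- dim(y)[2]; nK <- dim(y)[3]
  op <- data$traps$operation
  if (!is.null(op)) {
    if (nI > 0) {
      op3 <- aperm(array(op, c(nJ, nK, nI)), c(3, 1, 2))
      if (any(y == 1L & op3 == 0L))
        stop("detection recorded at a non-operating trap-occasion",
             call. = FALSE)
    }
    Kj <- rowSums(op)
  } else {
    Kj <- rep(nK, nJ)
  }
  n <- if (nI > 0) rowSums(y, dims = 2) else matrix(0, 0, nJ)
  Kmat <- if (nI > 0) matrix(Kj, nrow = nI, ncol = nJ, byrow = TRUE) else
    matrix(0, 0, nJ)
  list(n = n, Kj = Kj, tn = t(n), tKn = t(Kmat - n))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
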