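# scrdens

Bayesian spatial capture-recapture (SCR) density estimation with
Bayes-factor model selection, for camera-trap (and similar detector
array) studies of individually identifiable animals — the setting of
low-density, hard-to-detect species such as large carnivores, where
estimates must come with honest uncertainty.

SCR gives each individual a latent activity center $s_i$ and lets the
probability that trap $j$ detects it in one sampling occasion decay with
distance:

$$p_{ij} = 1 - \exp\{-\lambda_0 e^{-\frac{1}{2}(d_{ij}/\sigma)^{2\theta}}\},$$

with baseline hazard $\lambda_0$, movement scale $\sigma$, and kernel
shape $\theta$ (0.5 = exponential, 1 = Gaussian). The unknown population
size is handled by data augmentation ($M$ slots with inclusion
indicators $z_i \sim \mathrm{Bernoulli}(\psi)$, giving $N$ a uniform
prior on $[0, M]$), and density is $N$ over the area of a discretized,
buffered statespace. Four parameterizations let sex shift the baseline
hazard and/or the movement scale (`distance`, `sex`, `sigma-sex`,
`sex+sigma-sex`); competing fits are compared through Gelfand–Dey
marginal likelihoods, posterior model probabilities, and Bayes factors
with the conventional $\log_{10}$ and $2\ln$ transforms. Capture
histories can be collapsed from daily records to weekly, monthly or
quarterly occasions to study how sampling-interval length trades off
against precision.

## Worked example

```r
library(scrdens)

# a simulated camera-trap study: 250 animals (150 F / 100 M) on an
# 11 x 11 statespace, 8 x 8 trap grid, 90 daily occasions,
# sigma = 1, lam0_female = 0.05, beta_sex = -1.61
sim <- simulate_scr(sim_config(), seed = 3)
sim$history
#> capture_history: 232 individuals x 64 traps x 90 occasions ( daily )
#>   detections: 2558 ; sex: 146 F / 86 M / 0 U

space <- build_statespace(sim$traps, buffer = 2.25, spacing = 0.5)
fit <- scr_fit(sim$history, space, model_spec("sex", M = 400),
               iters = 1500, burnin = 500, thin = 2, seed = 11)
fit
#> scr_fit: sex model; 500 retained draws ( 1500 iterations, burn-in 500 , thin 2 )
#>   observed individuals: 232 ; M = 400
#>   density: 2.064 ( 1.962 - 2.178 ) per area unit; SW = 0.105
```

The posterior median density 2.06 animals/unit² comes with an
equal-tailed 95% credibility interval and its standardized width
SW = (upper − lower)/median, a scale-free precision measure. The
generated truth is 250/11² ≈ 2.07 animals/unit² (see the methods
vignette for how the slightly larger fitted statespace interacts with
this). Generating parameters are recovered closely: posterior medians
here are
$\hat\lambda_0 = 0.052$, $\hat\beta_{\text{sex}} = -1.58$,
$\hat\sigma = 1.00$.

Model selection on a coarser, faster example:

```r
cfg <- sim_config(n_female = 25, n_male = 15, extent = 8,
                  trap_rows = 5, trap_cols = 5, trap_spacing = 1.2,
                  n_occasions = 12,
                  params = scr_params(0.4, beta_sex = -0.7, sigma_female = 1))
sim <- simulate_scr(cfg, seed = 21)
sp <- build_statespace(sim$traps, buffer = 2, spacing = 1)
fits <- lapply(c("distance", "sex"), function(m)
  scr_fit(sim$history, sp, model_spec(m, M = 100),
          iters = 2000, burnin = 500, thin = 2, seed = 3,
          keep_pixel_counts = FALSE))
lml <- sapply(fits, function(f) scr_log_marginal(f, sim$history, sp)$log_marginal)
compare_models(lml, model_names = c("distance", "sex"))
#> Bayesian model comparison (reference: distance)
#>
#>     Model Pr(Model|data)  B_l0 log10_B two_ln_B
#>  distance         0.0473  1.00     0.0     0.00
#>       sex         0.9530 20.16     1.3     6.01
```

Here the data were generated with a sex effect on the baseline hazard,
and the Bayes factor is decisive for the `sex` model over `distance`
($B = 20.2$, $2\ln B = 6.0$) even at this small sample size.

Real data enter as two delimited files — traps (`trap_id,x,y` with
optional per-occasion `op_k` columns) and long-format captures
(`individual,trap_id,day,sex`):

```r
traps <- read_traps("traps.csv")
hist  <- read_captures("captures.csv", traps, occasion_calendar(91, "daily"))
weekly <- aggregate_occasions(hist, "weekly")   # 13 occasions
space <- build_statespace(traps, buffer = 10, spacing = 1)  # km
fit <- scr_fit(weekly, space, model_spec("sigma-sex", M = NA), seed = 1)
density_surface(fit, space)   # per-pixel posterior mean density + abundance
```

A command-line interface with `simulate`, `fit`, `compare` and `study`
subcommands lives at `inst/cli/scrdens.R`
(`Rscript $(Rscript -e 'cat(system.file("cli/scrdens.R", package="scrdens"))') simulate --seed 1 --out simdata`).

## Layout

* `R/` — data structures and IO, detection model, simulator, MCMC,
  Gelfand–Dey model selection, study orchestration
* `tests/testthat/` — unit, property and acceptance suites (all
  fixtures built in code)
* `vignettes/scr-methods.Rmd` — model, priors, sampler, estimator
  derivations, simulator scope, numerical choices
* `scripts/acceptance.R` — the acceptance report above
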