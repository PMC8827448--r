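# copulagp

Conditional copula mixtures with Gaussian-process parameters, for
dependence and information analysis of simultaneously recorded continuous
variables — typically neuronal activity (calcium traces, firing rates) and
behavioral readouts observed along a task covariate such as time or
position in an environment.

## What it does

The joint distribution of an observation vector **y** given a covariate
*x* is factorized, by Sklar's theorem, into conditional marginals and a
conditional copula:

    p(y | x) = c(F_1(y_1|x), ..., F_m(y_m|x) | x) × Π_i p_i(y_i | x)

With conditional marginals, the copula describes pure trial-to-trial
co-variability ("noise correlations") rather than shared covariate
tuning. `copulagp` models that copula as a mixture of parametric
bivariate families,

    c(u | x) = Σ_j φ_j(x) c_j(u; θ_j(x)),   Σ_j φ_j(x) = 1,

with Gaussian, Frank, Clayton and Gumbel elements (the tail families in
all four rotations). Every parameter θ_j(x) and every weight φ_j(x) is a
latent Gaussian-process function of *x*, fitted by stochastic variational
inference with grid inducing points. Mixture structure is chosen by WAIC
(greedy forward selection, or a faster corner-diagnostic heuristic);
pairs no better than the Independence copula (WAIC ≥ −0.005) are stored
as parameter-free Independence markers. Bivariate models compose into a
conditional canonical vine for m > 2 variables. On top of the fitted
models the package computes conditional copula entropy and the mutual
information I(x, y) — by direct nested Monte-Carlo integration
("integrated") or by two-model differencing ("estimated") — in bits,
with uncertainty that combines the GP-posterior spread and the
Monte-Carlo tolerance as sqrt(SE² + MCtol²).

A synthetic-data module generates every validation input with known
answers: a two-neuron GLM/calcium simulator (uncoupled and coupled
variants), and Gaussian / Student-t / morphed-Gaussian benchmark
distributions with analytic or quadrature ground truth.

## Worked example

Fit a conditional copula to a pair with covariate-varying dependence and
estimate how much information the dependence carries about the covariate:

```r
library(copulagp)

b <- gen_benchmark("gaussian", N = 2, n = 5000, seed = 1) # rho(x) = -0.1 + 1.1x
model <- fit_gpcop(bicop_spec("gauss"), b$x, b$U,
                   gpc_config(max_steps = 350), seed = 2)
model
#> <mixcop_gp> mixture: gauss | WAIC = -0.2532

glance(model)
#> # A tibble: 1 x 5
#>       M n_latents   waic aborted steps
#>   <int>     <int>  <dbl> <lgl>   <int>
#> 1     1         1 -0.253 FALSE     350

predict_params(model, c(0.25, 0.75))
#> # A tibble: 2 x 7
#>       x component theta theta_lo theta_hi   phi    tau
#>   <dbl> <chr>     <dbl>    <dbl>    <dbl> <dbl>  <dbl>
#> 1  0.25 gauss     0.146  -0.0397    0.323     1 0.0931
#> 2  0.75 gauss     0.687   0.595    0.764      1 0.482

est <- mi_integrated(model, b$x, seed = 3)
est
#> integrated: 0.2010 bits  [0.1517, 0.2502]  (SE 0.0239, MCtol 0.0060, n_mc 10000)

truth_oracle("gaussian", N = 2, seed = 4)$mi
#> [1] 0.2068608
```

The fitted correlation trajectory tracks rho(x) = -0.1 + 1.1x (theta ~ 0.15 at
x = 0.25, ~ 0.69 at x = 0.75, against true values 0.175 and 0.725), the WAIC
of -0.25 says the dependence model clearly beats independence, and the
integrated mutual-information estimate of 0.201 bits sits just below the
ground truth of 0.207 bits - the integrated estimator is conservative by
construction, and its interval combines the posterior spread with the
Monte-Carlo tolerance.
`autoplot(model)` draws the θ(x) trajectory with its 95% band, and
`conditional_copula_entropy()` + `plot_entropy_profile()` profile the
dependence strength along the covariate.

For m > 2 variables, `fit_margins()` + `fit_cvine()` build the
conditional vine, `cvine_sample()` / `cvine_logpdf()` evaluate it, and
`effective_dim()` reports how many vine trees carry a target fraction of
the total copula entropy.

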