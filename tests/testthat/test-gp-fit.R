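## Variational GP copula fitting: priors, ELBO, recovery, abort behavior.

test_that("default configuration matches the standard hyper-parameter table", {
  cfg <- gpc_config()
  expect_equal(cfg$base_lr, 0.05)
  expect_equal(cfg$var_lr, 0.02)
  expect_equal(cfg$grid_size, 60)
  expect_equal(cfg$waic_tol, 0.005)
  expect_equal(cfg$loss_tol, 1e-4)
  expect_equal(cfg$check_waic, 0.005)
})

test_that("a zero-latent (prior) model gives equal weights and link-of-zero", {
  comps <- list(bicop_spec("gauss"), bicop_spec("clayton"), bicop_spec("gumbel"))
  lat <- replicate(5, copulagp:::new_latent(10), simplify = FALSE)
  for (l in seq_along(lat)) lat[[l]]$logs <- -20   # pin draws at the mean 0
  mdl <- copulagp:::build_model(comps, lat, c(0, 1), gpc_config(),
                                numeric(0), NA, FALSE)
  pars <- copulagp:::model_params_at(mdl, c(.2, .8))
  expect_equal(as.vector(pars$phi), rep(1 / 3, 6), tolerance = 1e-9)
  expect_equal(pars$theta[1, ], c(0, 1, 2), tolerance = 1e-9)
})

test_that("ELBO decomposes: KL vanishes at the prior, independence has zero loglik", {
  set.seed(1)
  n <- 200
  x <- runif(n); u <- cbind(runif(n), runif(n))
  lat <- copulagp:::new_latent(15)          # m = 0, logS = 0: q equals prior
  mdl <- copulagp:::build_model(list(bicop_spec("gauss")), list(lat),
                                c(0, 1), gpc_config(grid_size = 15),
                                numeric(0), NA, FALSE)
  e <- elbo(mdl, x, u, draws = 5, seed = 2)
  expect_equal(e$kl, 0, tolerance = 1e-9)
  expect_equal(elbo(indep_model(), x, u)$loss, 0)
})

test_that("GP-linked parameter trajectories are recovered for every family", {
  set.seed(3)
  n <- 3000
  x <- runif(n)
  fx <- 1.8 * sin(2 * pi * x)
  for (fam in c("gauss", "frank", "clayton", "gumbel")) {
    sp <- bicop_spec(fam)
    th <- gplink(sp, fx)
    u1 <- runif(n)
    u2 <- copulagp:::bicop_ppcf_v(sp, th, u1, runif(n))
    m <- fit_gpcop(sp, x, cbind(u1, u2), fast_cfg(grid_size = 40), seed = 4)
    th_hat <- copulagp:::model_params_at(m, x)$theta[, 1]
    tau_err <- vapply(seq_len(n), function(i)
      bicop_tau(sp, th_hat[i]) - bicop_tau(sp, th[i]), 0)
    expect_lt(sqrt(mean(tau_err^2)), 0.1, label = fam)
  }
})

test_that("fitting a dependence model to independent data aborts via WAIC", {
  set.seed(5)
  n <- 2000
  m <- fit_gpcop(bicop_spec("gauss"), runif(n), cbind(runif(n), runif(n)),
                 fast_cfg(max_steps = 400), seed = 6)
  expect_true(m$aborted)
  expect_gt(m$waic, -gpc_config()$waic_tol)
})

test_that("credible band is the link image of mean +/- two posterior sd", {
  set.seed(7)
  n <- 1500
  x <- runif(n)
  u <- bicop_sample(bicop_spec("gauss"), 0.5, n, seed = 8)
  m <- fit_gpcop(bicop_spec("gauss"), x, u, fast_cfg(), seed = 9)
  xg <- seq(0.1, 0.9, length.out = 5)
  pred <- predict_params(m, xg)
  xs <- copulagp:::standardize_x(xg, m$x_range)
  z <- seq(0, 1, length.out = length(m$latents[[1]]$m))
  mo <- copulagp:::latent_moments(m$latents[[1]], xs, z)
  expect_equal(pred$theta_hi, gplink(bicop_spec("gauss"), mo$mu + 2 * mo$sigma),
               tolerance = 1e-9)
  expect_equal(pred$theta_lo, gplink(bicop_spec("gauss"), mo$mu - 2 * mo$sigma),
               tolerance = 1e-9)
  ## posterior uncertainty grows where x data is sparse
  set.seed(10)
  xs2 <- c(runif(1400, 0, 0.5), runif(40, 0.5, 1))
  u2 <- bicop_sample(bicop_spec("gauss"), 0.5, 1440, seed = 11)
  m2 <- fit_gpcop(bicop_spec("gauss"), xs2, u2, fast_cfg(), seed = 12)
  zz <- seq(0, 1, length.out = length(m2$latents[[1]]$m))
  mo2 <- copulagp:::latent_moments(m2$latents[[1]],
                                   copulagp:::standardize_x(c(.25, .95), m2$x_range), zz)
  expect_gt(mo2$sigma[2], mo2$sigma[1])
})

test_that("sampling from a fitted conditional model matches its parameters", {
  mdl <- manual_model(bicop_spec("clayton"), 2.5)
  s <- gpcop_sample(mdl, runif(8000), seed = 13)
  expect_equal(cor(s[, 1], s[, 2], method = "kendall"),
               bicop_tau(bicop_spec("clayton"), 2.5), tolerance = 0.03)
  expect_gt(suppressWarnings(ks.test(s[, 2], "punif")$p.value), 0.01)
})
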