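## Entropy and mutual-information estimators (all in bits).

test_that("Independence models carry zero copula entropy everywhere", {
  h <- conditional_copula_entropy(indep_model(), c(.2, .8), n_mc = 500,
                                  S = 0, seed = 1)
  expect_equal(h$value, c(0, 0))
})

test_that("bivariate Gaussian copula entropy matches the closed form", {
  mdl <- manual_model(bicop_spec("gauss"), 0.7)
  h <- conditional_copula_entropy(mdl, 0.5, n_mc = 60000, S = 0, seed = 2)
  expect_equal(h$value, gauss_copula_entropy(0.7, 2), tolerance = 0.01)
})

test_that("3D equicorrelated Gaussian vine entropy matches the determinant", {
  ## build the vine by hand: tree-1 edges rho = .5, tree-2 partial = 1/3
  e11 <- manual_model(bicop_spec("gauss"), 0.5)
  e12 <- manual_model(bicop_spec("gauss"), 0.5)
  e21 <- manual_model(bicop_spec("gauss"), 1 / 3)
  v <- structure(list(order = 1:3,
                      edges = list(list(e11, e12), list(e21)),
                      x_range = c(0, 1), m = 3L, config = gpc_config()),
                 class = "cvine")
  h <- conditional_copula_entropy(v, 0.4, n_mc = 40000, S = 0, seed = 3)
  expect_equal(h$value, gauss_copula_entropy(0.5, 3), tolerance = 0.02)
})

test_that("an x-constant copula carries no information about x", {
  mdl <- manual_model(bicop_spec("gauss"), 0.6)
  est <- mi_integrated(mdl, runif(2000), n_mc_outer = 4000,
                       n_mc_inner = 200, S = 0, seed = 4)
  expect_lt(abs(est$value), 3 * est$mc_tol + 0.01)
})

test_that("mi_integrated matches an independent quadrature-plus-MC truth", {
  ## known conditional model theta(x) = -0.1 + x (kept away from the
  ## comonotone limit, where entropy is hypersensitive to theta)
  rho_fun <- function(x) -0.1 + x
  mdl <- manual_gauss_xmodel(rho_fun)
  set.seed(5)
  xs <- runif(4000)
  est <- mi_integrated(mdl, xs, n_mc_outer = 8000, n_mc_inner = 600,
                       S = 0, seed = 6)
  ## independent oracle: closed-form conditional term integrated by
  ## Gauss-Legendre; marginal-entropy term by MC over exact samples
  gl <- copulagp:::gauss_legendre(64)
  xq <- (gl$x + 1) / 2; wq <- gl$w / 2
  term1 <- -sum(wq * gauss_copula_entropy(rho_fun(xq), 2))
  set.seed(7)
  nmc <- 150000
  r <- rho_fun(runif(nmc))
  Z <- matrix(rnorm(2 * nmc), nmc, 2)
  l1 <- 1 + r; l2 <- 1 - r
  Y <- sqrt(l2) * Z + (sqrt(l1) - sqrt(l2)) * rowMeans(Z)
  Umc <- pnorm(Y)
  lp <- copulagp:::gauss_mixture_log2density(Umc, rho_fun(xq), wq)
  truth <- term1 - mean(lp)
  expect_lt(abs(est$value - truth), 0.02)
})

test_that("mi_estimated reduces to a copula-entropy difference and agrees with mi_integrated", {
  mdl <- manual_gauss_xmodel(function(x) -0.1 + x)
  ## unconditional model for the same data: single correlation matched to
  ## the x-averaged dependence
  b <- gen_benchmark("gaussian", 2, 6000, seed = 8)
  tau_bar <- cor(b$U[, 1], b$U[, 2], method = "kendall")
  uncond <- manual_model(bicop_spec("gauss"), sin(pi * tau_bar / 2))
  est2 <- mi_estimated(mdl, uncond, 0, b$x, n_mc = 20000, S = 0, seed = 9)
  est1 <- mi_integrated(mdl, b$x, n_mc_outer = 8000, n_mc_inner = 500,
                        S = 0, seed = 10)
  expect_lt(abs(est2$value - est1$value), 0.05)
  ## an x-constant model used as both inputs with zero marginal MI gives
  ## zero (both entropy terms estimate the same quantity)
  mdl_const <- manual_model(bicop_spec("frank"), 4)
  estc <- mi_estimated(mdl_const, mdl_const, 0, b$x, n_mc = 40000, S = 0,
                       seed = 13)
  expect_lt(abs(estc$value), 0.03)
})

test_that("mismatched variable counts are rejected and marginal MI must be >= 0", {
  mdl <- manual_model(bicop_spec("gauss"), .5)
  v <- structure(list(order = 1:3, edges = list(), x_range = c(0, 1),
                      m = 3L), class = "cvine")
  expect_error(mi_estimated(mdl, v, 0, runif(10)), "different variables")
  expect_error(mi_estimated(mdl, mdl, -0.1, runif(10)), "non-negative")
})

test_that("reported uncertainty combines SE and MC tolerance in quadrature", {
  e <- copulagp:::new_info_estimate(1, 0.03, 0.04, 1000, "integrated")
  expect_equal(e$ci_hi - e$value, 2 * 0.05)
  expect_equal(e$value - e$ci_lo, 2 * 0.05)
})

test_that("KSG baseline hits closed forms in low dimension", {
  set.seed(14)
  n <- 4000
  expect_lt(abs(ksg_mi(rnorm(n), matrix(rnorm(n), ncol = 1), k = 5)), 0.05)
  rho <- 0.6
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  expect_equal(ksg_mi(x, matrix(y, ncol = 1), k = 5),
               -0.5 * log2(1 - rho^2), tolerance = 0.05)
})

test_that("KSG recovers a shrinking fraction of the truth as dimension grows", {
  fr <- vapply(c(2, 6), function(N) {
    b <- gen_benchmark("gaussian", N, 4000, seed = 15 + N)
    truth <- truth_oracle("gaussian", N, n_mc = 100000, seed = 16)$mi
    ksg_mi(b$x, b$U, k = 5) / truth
  }, 0)
  expect_gt(fr[1], fr[2])
})

test_that("histogram marginal MI is zero for uniform benchmark marginals", {
  b <- gen_benchmark("gaussian", 2, 4000, seed = 17)
  expect_lt(marginal_mi_hist(b$x, b$U[, 1]), 0.1)
})
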