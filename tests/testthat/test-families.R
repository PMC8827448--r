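## Bivariate family primitives: densities, CDFs, h-functions, sampling,
## Kendall maps and GP links.

quad_grid <- function(n = 120) {
  gl <- copulagp:::gauss_legendre(n)
  list(x = (gl$x + 1) / 2, w = gl$w / 2)
}

test_that("densities integrate to one over the unit square", {
  g <- quad_grid()
  pts <- as.matrix(expand.grid(u1 = g$x, u2 = g$x))
  W <- outer(g$w, g$w)
  cases <- list(
    list(bicop_spec("gauss"), 0.7),
    list(bicop_spec("frank"), 5),
    list(bicop_spec("clayton"), 2),
    list(bicop_spec("gumbel"), 2),
    list(bicop_spec("clayton", 90), 3),
    list(bicop_spec("gumbel", 270), 1.5)
  )
  for (cs in cases) {
    total <- sum(W * matrix(bicop_pdf(cs[[1]], cs[[2]], pts), length(g$x)))
    expect_equal(total, 1, tolerance = 0.01,
                 label = paste("integral of", format(cs[[1]])))
  }
})

test_that("independence and zero-parameter limits give unit density", {
  u <- cbind(runif(50), runif(50))
  expect_equal(bicop_pdf(bicop_spec("indep"), 0, u), rep(1, 50))
  expect_equal(bicop_pdf(bicop_spec("gauss"), 0, u), rep(1, 50),
               tolerance = 1e-10)
})

test_that("cdf boundary and product-copula anchors hold", {
  for (fam in list(bicop_spec("gauss"), bicop_spec("frank"),
                   bicop_spec("clayton"), bicop_spec("gumbel", 90))) {
    th <- switch(fam$family, gauss = 0.5, frank = 4, clayton = 2, gumbel = 2)
    expect_equal(bicop_cdf(fam, th, c(1, 1)), 1, tolerance = 1e-6)
    u <- runif(10)
    expect_equal(bicop_cdf(fam, th, cbind(u, 1)), u, tolerance = 1e-4)
    expect_equal(bicop_cdf(fam, th, cbind(1, u)), u, tolerance = 1e-4)
  }
  expect_equal(bicop_cdf(bicop_spec("gauss"), 0, c(0.3, 0.7)), 0.21,
               tolerance = 1e-6)
  ## Gumbel cdf against quadrature of its own density over [0, .5]^2
  g <- quad_grid(200)
  x5 <- g$x / 2; w5 <- g$w / 2
  pts <- as.matrix(expand.grid(u1 = x5, u2 = x5))
  q <- sum(outer(w5, w5) * matrix(bicop_pdf(bicop_spec("gumbel"), 2, pts), 200))
  expect_equal(bicop_cdf(bicop_spec("gumbel"), 2, c(0.5, 0.5)), q,
               tolerance = 1e-3)
})

test_that("h-function is the partial derivative of the cdf", {
  set.seed(1)
  u <- cbind(runif(40, .05, .95), runif(40, .05, .95))
  h <- 1e-5
  for (spec in list(bicop_spec("gauss"), bicop_spec("frank"),
                    bicop_spec("clayton"), bicop_spec("gumbel"),
                    bicop_spec("clayton", 90), bicop_spec("gumbel", 180))) {
    th <- switch(spec$family, gauss = 0.7, frank = -4, clayton = 2, gumbel = 2.5)
    if (spec$family == "frank" && spec$rotation != 0) th <- 4
    fd <- (bicop_cdf(spec, th, cbind(u[, 1] + h, u[, 2])) -
             bicop_cdf(spec, th, cbind(u[, 1] - h, u[, 2]))) / (2 * h)
    expect_lt(max(abs(fd - bicop_hfun(spec, th, u))), 1e-4)
  }
})

test_that("ppcf inverts hfun on a grid for every family", {
  g <- seq(0.05, 0.95, length.out = 20)
  u <- as.matrix(expand.grid(u1 = g, u2 = g))
  for (spec in list(bicop_spec("gauss"), bicop_spec("frank"),
                    bicop_spec("clayton"), bicop_spec("gumbel"),
                    bicop_spec("clayton", 270), bicop_spec("gumbel", 90))) {
    th <- switch(spec$family, gauss = -0.6, frank = 6, clayton = 3, gumbel = 2)
    q <- bicop_hfun(spec, th, u)
    back <- bicop_ppcf(spec, th, u[, 1], q)
    expect_lt(max(abs(back - u[, 2])), 1e-6, label = format(spec))
  }
})

test_that("sampling reproduces the closed-form Kendall tau", {
  n <- 10000
  expect_lt(abs(cor(bicop_sample(bicop_spec("indep"), 0, n, seed = 1)[, 1],
                    bicop_sample(bicop_spec("indep"), 0, n, seed = 1)[, 2],
                    method = "kendall")), 0.03)
  s <- bicop_sample(bicop_spec("clayton"), 2, n, seed = 2)
  expect_equal(cor(s[, 1], s[, 2], method = "kendall"), 0.5, tolerance = 0.03)
  s90 <- bicop_sample(bicop_spec("clayton", 90), 2, n, seed = 3)
  expect_equal(cor(s90[, 1], s90[, 2], method = "kendall"), -0.5,
               tolerance = 0.03)
  ## 90-degree rotation moves the Clayton tail off the lower-left corner
  ll <- mean(s90[, 1] < 0.1 & s90[, 2] < 0.1)
  opp <- mean(s90[, 1] > 0.9 & s90[, 2] < 0.1)
  expect_gt(opp, 5 * max(ll, 1e-4))
})

test_that("Frank tau via the Debye integral matches sampling", {
  tau <- bicop_tau(bicop_spec("frank"), 5)
  s <- bicop_sample(bicop_spec("frank"), 5, 40000, seed = 4)
  expect_equal(cor(s[, 1], s[, 2], method = "kendall"), tau, tolerance = 0.01)
})

test_that("Kendall tau limits and signs are correct", {
  expect_equal(bicop_tau(bicop_spec("gauss"), 1), 1)
  expect_equal(bicop_tau(bicop_spec("gumbel"), 1), 0)
  expect_equal(bicop_tau(bicop_spec("indep"), 0), 0)
  expect_lt(bicop_tau(bicop_spec("gumbel", 90), 3), 0)
  expect_equal(bicop_tau(bicop_spec("frank"), -5),
               -bicop_tau(bicop_spec("frank"), 5))
})

test_that("GP link functions hit their printed anchors and stay in domain", {
  expect_equal(gplink(bicop_spec("gauss"), 0), 0)
  expect_equal(gplink(bicop_spec("clayton"), 0), 1)
  expect_equal(gplink(bicop_spec("gumbel"), 0), 2)
  f <- seq(-30, 30, length.out = 101)
  for (fam in c("gauss", "frank", "clayton", "gumbel")) {
    spec <- bicop_spec(fam)
    th <- gplink(spec, f)
    dom <- copulagp:::theta_domain(spec)
    expect_true(all(th >= dom[1] & th <= dom[2]), label = fam)
    expect_true(all(diff(th) >= 0), label = paste(fam, "monotone"))
  }
})

test_that("rotation identities relate the rotated and base densities", {
  set.seed(5)
  u <- cbind(runif(30), runif(30))
  for (fam in c("clayton", "gumbel")) {
    th <- 2.5
    base <- bicop_spec(fam)
    expect_equal(bicop_pdf(bicop_spec(fam, 180), th, u),
                 bicop_pdf(base, th, cbind(1 - u[, 1], 1 - u[, 2])))
    expect_equal(bicop_pdf(bicop_spec(fam, 90), th, u),
                 bicop_pdf(base, th, cbind(1 - u[, 1], u[, 2])))
    expect_equal(bicop_pdf(bicop_spec(fam, 270), th, u),
                 bicop_pdf(base, th, cbind(u[, 1], 1 - u[, 2])))
  }
})

test_that("unrotated densities are exchangeable in their arguments", {
  set.seed(6)
  u <- cbind(runif(30), runif(30))
  for (fam in c("gauss", "frank", "clayton", "gumbel")) {
    th <- switch(fam, gauss = 0.6, frank = 3, clayton = 1.5, gumbel = 2)
    expect_equal(bicop_pdf(bicop_spec(fam), th, u),
                 bicop_pdf(bicop_spec(fam), th, u[, 2:1]),
                 tolerance = 1e-10)
  }
})

test_that("domain violations and invalid rotations are rejected", {
  expect_error(bicop_pdf(bicop_spec("clayton"), -1, c(.5, .5)), "domain")
  expect_error(bicop_pdf(bicop_spec("gumbel"), 0.5, c(.5, .5)), "domain")
  expect_error(bicop_spec("gauss", 90), "rotation")
  expect_error(bicop_spec("clayton", 45), "rotation")
})

test_that("vectorized-theta log densities match the scalar implementations", {
  set.seed(7)
  u1 <- runif(100, .02, .98); u2 <- runif(100, .02, .98)
  for (spec in list(bicop_spec("gauss"), bicop_spec("frank"),
                    bicop_spec("clayton", 90), bicop_spec("gumbel", 270))) {
    th <- switch(spec$family, gauss = runif(100, -.9, .9),
                 frank = runif(100, -6, 6), clayton = runif(100, .1, 4),
                 gumbel = runif(100, 1.05, 4))
    vec <- copulagp:::bicop_lpdf_v(spec, th, u1, u2)
    ref <- vapply(seq_len(100), function(i)
      log(bicop_pdf(spec, th[i], cbind(u1[i], u2[i]))), 0)
    expect_equal(vec, ref, tolerance = 1e-8, label = format(spec))
  }
})
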