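## C-vine construction, evaluation, sampling and persistence.

test_that("variable ordering follows total absolute Kendall correlation", {
  set.seed(1)
  n <- 800
  ## var1 is a noisy copy of var2; var3 independent
  v2 <- runif(n)
  U <- cbind(clamp_unit(v2 + rnorm(n, 0, .05)), v2, runif(n))
  ord <- order_variables(U)
  expect_equal(ord[3], 3)
  expect_true(ord[1] %in% 1:2)
  ## exactly tied scores: the stable tie-break keeps the column order
  set.seed(2)
  vv <- runif(300)
  expect_equal(order_variables(cbind(vv, vv, vv)), 1:3)
  ## hub variable correlated with all others comes first
  set.seed(3)
  hub <- runif(n)
  Uh <- cbind(runif(n), clamp_unit(hub + rnorm(n, 0, .2)), hub,
              clamp_unit(hub + rnorm(n, 0, .2)))
  expect_equal(order_variables(Uh)[1], 3)
})

test_that("pair-copula count is m(m-1)/2, including the published 109-variable case", {
  expect_equal(cvine_n_pairs(109), 5886)
  expect_equal(cvine_n_pairs(2), 1)
  expect_equal(cvine_n_pairs(5), 10)
})

test_that("fully independent data yields an all-Independence vine with zero logpdf", {
  set.seed(4)
  n <- 1200; m <- 4
  x <- runif(n)
  U <- matrix(runif(n * m), n, m)
  v <- fit_cvine(x, U, fast_cfg(), seed = 5, method = "gauss")
  edges <- unlist(v$edges, recursive = FALSE)
  expect_true(all(vapply(edges, is_indep, TRUE)))
  expect_equal(cvine_logpdf(v, x[1:50], U[1:50, ]), rep(0, 50))
  expect_equal(cvine_n_params(v), 0L)
  ed <- effective_dim(v, x, n_mc = 500, seed = 6)
  expect_equal(ed$trees, 0L)
})

test_that("a 2-variable vine equals its single bivariate copula", {
  set.seed(7)
  n <- 1500
  x <- runif(n)
  u <- bicop_sample(bicop_spec("gauss"), 0.6, n, seed = 8)
  v <- fit_cvine(x, u, fast_cfg(), seed = 9, method = "gauss",
                 order = c(1, 2))
  e <- v$edges[[1]][[1]]
  expect_lt(max(abs(cvine_logpdf(v, x, u) - gpcop_logpdf(e, x, u))), 1e-9)
})

test_that("equicorrelated Gaussian vine recovers partial dependence and entropy", {
  n <- 2500; m <- 4; rho <- 0.5
  U <- equicorr_u(n, m, rho, seed = 10)
  set.seed(11)
  x <- runif(n)
  v <- fit_cvine(x, U, fast_cfg(grid_size = 30, max_steps = 250),
                 seed = 12, method = "gauss")
  edges <- unlist(v$edges, recursive = FALSE)
  expect_true(all(!vapply(edges, is_indep, TRUE)))
  ## tree-2 partial correlation of an equicorrelated Gaussian is 1/3
  th2 <- mean(copulagp:::model_params_at(v$edges[[2]][[1]], x)$theta)
  expect_equal(th2, 1 / 3, tolerance = 0.07)
  ## sampling/evaluation duality: copula entropy matches 0.5 log2 det R
  set.seed(13)
  xs <- runif(4000) * diff(v$x_range) + v$x_range[1]
  Us <- cvine_sample(v, xs, seed = 14)
  R <- matrix(rho, m, m); diag(R) <- 1
  expect_equal(-mean(cvine_logpdf(v, xs, Us)) / log(2), 0.5 * log2(det(R)),
               tolerance = 0.05)
  ## pairwise tau of samples matches the data
  for (pair in list(c(1, 2), c(2, 4))) {
    expect_equal(cor(Us[, pair[1]], Us[, pair[2]], method = "kendall"),
                 cor(U[, pair[1]], U[, pair[2]], method = "kendall"),
                 tolerance = 0.05)
  }
  expect_gt(suppressWarnings(ks.test(Us[, 2], "punif")$p.value), 0.01)
  ## single-tree dependence dominates; effective dimension is small
  ed <- effective_dim(v, x, coverage = 0.9, n_mc = 3000, seed = 15)
  expect_lte(ed$trees, 3L)
  expect_gte(ed$trees, 1L)
  ## truncation forces deeper trees to Independence
  vt <- fit_cvine(x, U, fast_cfg(grid_size = 30, max_steps = 150),
                  seed = 16, method = "gauss", trunc_tree = 1)
  expect_true(all(vapply(unlist(vt$edges[-1], recursive = FALSE),
                         is_indep, TRUE)))
})

test_that("model persistence round-trips log densities bit-identically", {
  mdl <- manual_model(list(bicop_spec("gauss"), bicop_spec("clayton", 90)),
                      c(0.5, 2), c(0.4, 0.6))
  set.seed(17)
  x <- runif(100); u <- cbind(runif(100), runif(100))
  path <- tempfile(fileext = ".json")
  save_model(mdl, path)
  back <- load_model(path)
  expect_identical(gpcop_logpdf(back, x, u), gpcop_logpdf(mdl, x, u))
  ## vine round-trip through a real (cheap) fit
  set.seed(18)
  n <- 800
  U <- equicorr_u(n, 3, 0.5, seed = 19)
  xv <- runif(n)
  v <- fit_cvine(xv, U, fast_cfg(grid_size = 20, max_steps = 120),
                 seed = 20, method = "gauss")
  pv <- tempfile(fileext = ".json")
  save_model(v, pv)
  vback <- load_model(pv)
  expect_identical(cvine_logpdf(vback, xv[1:60], U[1:60, ]),
                   cvine_logpdf(v, xv[1:60], U[1:60, ]))
  ## corrupted files and foreign versions are rejected
  writeLines("{not json", pv)
  expect_error(load_model(pv), "parse")
  writeLines('{"format_version": "99", "type": "indep"}', pv)
  expect_error(load_model(pv), "version")
})
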