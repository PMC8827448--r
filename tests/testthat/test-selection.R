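## WAIC and mixture model selection.

test_that("WAIC of the Independence model is exactly zero on any input", {
  set.seed(1)
  for (n in c(10, 500)) {
    w <- waic(indep_model(), runif(n), cbind(runif(n), runif(n)), S = 10)
    expect_identical(w$waic, 0)
    expect_identical(w$lppd, 0)
    expect_identical(w$p_waic, 0)
  }
})

test_that("p_waic vanishes when all posterior draws coincide", {
  mdl <- manual_model(bicop_spec("gauss"), 0.6)   # posterior sd pinned ~ 0
  set.seed(2)
  u <- bicop_sample(bicop_spec("gauss"), 0.6, 400, seed = 3)
  w <- waic(mdl, runif(400), u, S = 50, seed = 4)
  expect_lt(w$p_waic, 1e-6)
  expect_lt(w$waic, 0)
})

test_that("a well-fit model beats independence by more than the tolerance", {
  set.seed(5)
  n <- 2000
  u <- bicop_sample(bicop_spec("gauss"), 0.7, n, seed = 6)
  m <- fit_gpcop(bicop_spec("gauss"), runif(n), u, fast_cfg(), seed = 7)
  expect_lt(m$waic, -gpc_config()$waic_tol)
})

test_that("waic requires at least two posterior draws", {
  mdl <- manual_model(bicop_spec("gauss"), 0.5)
  expect_error(waic(mdl, runif(10), cbind(runif(10), runif(10)), S = 1),
               "at least 2")
})

test_that("greedy selection returns Independence on independent uniforms", {
  set.seed(8)
  n <- 1500
  m <- select_greedy(runif(n), cbind(runif(n), runif(n)),
                     candidates = list(bicop_spec("gauss"), bicop_spec("clayton")),
                     config = fast_cfg(), seed = 9)
  expect_true(is_indep(m))
  expect_identical(m$waic, 0)
})

test_that("greedy recovers a single constant-parameter family and is monotone", {
  set.seed(10)
  n <- 2000
  u <- bicop_sample(bicop_spec("clayton"), 2, n, seed = 11)
  m <- select_greedy(runif(n), u,
                     candidates = list(bicop_spec("gauss"), bicop_spec("clayton"),
                                       bicop_spec("gumbel"), bicop_spec("clayton", 90)),
                     config = fast_cfg(), seed = 12)
  fams <- vapply(m$components, format, "")
  expect_true("clayton" %in% fams)
  hist <- attr(m, "history")
  expect_lte(m$waic, min(hist$waic[hist$M == 1]) + 1e-9)
})

test_that("heuristic screen discards independent pairs within the capped budget", {
  set.seed(13)
  n <- 1500
  t0 <- Sys.time()
  m <- select_heuristic(runif(n), cbind(runif(n), runif(n)),
                        fast_cfg(), seed = 14)
  expect_true(is_indep(m))
  expect_equal(attr(m, "history")$model, "gauss(screen)")
})

test_that("heuristic ranks the tail candidate matching the data's corner first", {
  set.seed(15)
  n <- 2000
  u <- bicop_sample(bicop_spec("clayton"), 5, n, seed = 16)
  m <- select_heuristic(runif(n), u, fast_cfg(), seed = 17)
  sl <- attr(m, "shortlist")
  tail_cands <- sl[!sl %in% c("gauss", "frank")]
  expect_equal(tail_cands[1], "clayton")   # lower-left corner: Clayton 0
  expect_true("clayton" %in% vapply(m$components, format, ""))
})

test_that("mixture components with everywhere-negligible weight are pruned", {
  set.seed(18)
  n <- 2000
  u <- bicop_sample(bicop_spec("gauss"), 0.6, n, seed = 19)
  x <- runif(n)
  m2 <- fit_gpcop(list(bicop_spec("gauss"), bicop_spec("clayton", 90)),
                  x, u, fast_cfg(), seed = 20)
  pruned <- copulagp:::prune_mixture(m2, x, u, fast_cfg(), seed = 21)
  phi <- copulagp:::model_params_at(pruned, seq(0, 1, length.out = 51))$phi
  expect_true(all(apply(phi, 2, max) >= 1e-4))
})
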