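## Synthetic generators: GLM/calcium toys, benchmarks, ground truth.

test_that("the stimulus drive is scaled to the requested peak rate", {
  cfg <- glm_config()
  stim <- copulagp:::glm_stimulus(cfg)
  roll <- stats::filter(c(stim, rep(0, cfg$T_filter)), rep(1, cfg$T_filter),
                        sides = 1)
  expect_equal(max(roll, na.rm = TRUE), log(cfg$stim_peak), tolerance = 1e-9)
  expect_equal(stim[seq(ceiling(0.6 * cfg$tau_trial) + 1, cfg$tau_trial)],
               rep(0, cfg$tau_trial - ceiling(0.6 * cfg$tau_trial)))
})

test_that("coupling filters have the prescribed shapes and uncoupled variant zeroes them", {
  h <- copulagp:::glm_filters(glm_config(coupled = TRUE))
  T_ <- 20
  s <- seq_len(T_)
  expect_equal(h[1, 1, ], rep(-0.1, T_))
  expect_equal(h[1, 2, ], 0.4 * (s / T_)^2 - 0.1)
  expect_equal(h[2, 1, ], -0.1 * (1 - s / T_)^2)
  h0 <- copulagp:::glm_filters(glm_config(coupled = FALSE))
  expect_equal(h0[1, 2, ], rep(0, T_))
  expect_equal(h0[2, 1, ], rep(0, T_))
})

test_that("with zero stimulus and no history the rate equals the base rate", {
  ## stim_peak = 1 makes the stimulus identically zero; self-history of a
  ## silent neuron contributes nothing, so counts are Poisson(0.2) at the
  ## trial start
  sim <- simulate_glm(glm_config(n_trials = 600, tau_trial = 3,
                                 stim_peak = 1, coupled = FALSE), seed = 1)
  first <- as.vector(sim$spikes[, 1, ])
  ## Poisson(0.2) over 1200 draws: allow three standard errors
  expect_lt(abs(mean(first) - 0.2), 3 * sqrt(0.2 / length(first)))
})

test_that("generators are seed-deterministic", {
  a <- simulate_glm(glm_config(n_trials = 3, tau_trial = 30), seed = 7)
  b <- simulate_glm(glm_config(n_trials = 3, tau_trial = 30), seed = 7)
  expect_identical(a$spikes, b$spikes)
  g1 <- gen_benchmark("student", 3, 100, seed = 5)
  g2 <- gen_benchmark("student", 3, 100, seed = 5)
  expect_identical(g1$U, g2$U)
})

test_that("calcium traces are the exponential-kernel convolution of spikes", {
  sim <- simulate_glm(glm_config(n_trials = 2, tau_trial = 40), seed = 2)
  d <- exp(-1 / 4)
  y <- sim$spikes[1, , 1]
  manual <- as.numeric(stats::filter(y, d, method = "recursive"))
  expect_equal(sim$calcium[1, , 1], manual)
})

test_that("benchmark parameter maps follow their definitions", {
  b <- gen_benchmark("gaussian", 2, 50, seed = 3)
  expect_true(all(b$rho >= -0.1 - 1e-9 & b$rho <= 1 - 1e-6 + 1e-12))
  expect_equal(b$rho, pmin(-0.1 + 1.1 * b$x, 1 - 1e-6))
  s <- gen_benchmark("student", 2, 50, seed = 4)
  expect_equal(s$df, exp(5 * s$x) + 1)
  expect_equal(min(exp(5 * 0) + 1), 2)   # df at x = 0
  expect_error(gen_benchmark("gaussian", 30, 50, seed = 5),
               "positive definite")
})

test_that("benchmark marginals are uniform and the morph preserves monotone structure", {
  b <- gen_benchmark("gaussian", 3, 4000, seed = 6)
  for (j in 1:3) {
    expect_gt(suppressWarnings(ks.test(b$U[, j], "punif")$p.value), 0.01)
  }
  s <- gen_benchmark("student", 2, 4000, seed = 7)
  expect_gt(suppressWarnings(ks.test(s$U[, 1], "punif")$p.value), 0.01)
  ## morphed N = 1: the transform is monotone, PIT restores exact uniformity
  m1 <- gen_benchmark("morphed", 1, 500, seed = 8)
  expect_equal(sort(m1$U[, 1]), (1:500) / 501, tolerance = 1e-12)
  m <- gen_benchmark("morphed", 3, 2000, seed = 9)
  expect_true(all(m$U > 0 & m$U < 1))
})

test_that("oracle entropies are self-consistent with Monte Carlo", {
  ## fixed-rho equicorrelated Gaussian copula: MC entropy of exact samples
  ## against the closed-form determinant expression
  n <- 200000
  U <- equicorr_u(n, 3, 0.5, seed = 10)
  lp <- copulagp:::gauss_mixture_log2density(U, 0.5, 1)
  expect_equal(-mean(lp), gauss_copula_entropy(0.5, 3), tolerance = 0.01)
  expect_equal(gauss_copula_entropy(0.5, 3), -0.5)   # 0.5 log2 det R
  expect_equal(gauss_copula_entropy(0, 2), 0)
})

test_that("Student-t copula entropy converges to the Gaussian limit", {
  expect_equal(student_copula_entropy(1e7, 2, 0.7),
               gauss_copula_entropy(0.7, 2), tolerance = 1e-3)
  ## heavier tails mean more dependence: entropy decreases as df drops
  expect_lt(student_copula_entropy(2, 2, 0.7),
            student_copula_entropy(50, 2, 0.7))
})

test_that("morphed conditional entropy has no ground truth", {
  o <- truth_oracle("morphed", 2, n_mc = 20000, seed = 11)
  expect_null(o$hc)
  og <- truth_oracle("gaussian", 2, n_mc = 20000, seed = 11)
  expect_equal(o$mi, og$mi, tolerance = 0.02)   # morph shares the Gaussian MI
})
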