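#' Synthetic two-neuron GLM / calcium simulator
#'
#' Generates spike counts from a two-neuron generalized linear model with
#' exponential nonlinearity and Poisson emission,
#' \eqn{\lambda_i = 0.2 \exp(1^T x^{-T:0} + \sum_j h_{ij} \cdot y_j^{-T:0})},
#' and calcium-like traces by convolving the counts with a causal
#' exponential kernel (decay constant 4 steps).  The stimulus filter is a
#' vector of ones of length `T`; the coupling filters of the coupled
#' variant give slow excitation from neuron 2 onto neuron 1
#' (\eqn{0.4 (t/T)^2 - 0.1}) and fast inhibition from neuron 1 onto neuron
#' 2 (\eqn{-0.1 (1 + t/T)^2} for lag \eqn{t \in [-T, 0]}), plus constant
#' self-history terms of -0.1; the uncoupled variant zeroes the
#' off-diagonal filters.  The stimulus waveform is a smooth unimodal pulse
#' occupying the first 60% of the trial, scaled so the peak rate is about
#' five times the base rate.
#'
#' @param T_filter filter length in steps.
#' @param tau_trial trial length in steps.
#' @param n_trials number of identical trials.
#' @param base_rate baseline rate multiplier.
#' @param coupled logical: include the cross-coupling filters.
#' @param ca_decay calcium decay constant in steps.
#' @param stim_peak peak rate as a multiple of the base rate.
#' @return a `glm_config` list.
#' @export
glm_config <- function(T_filter = 20, tau_trial = 100, n_trials = 100,
                       base_rate = 0.2, coupled = TRUE, ca_decay = 4,
                       stim_peak = 5) {
  structure(as.list(environment()), class = "glm_config")
}

glm_filters <- function(config) {
  T_ <- config$T_filter
  s <- seq_len(T_)            # lag s steps back corresponds to t' = -s
  h <- array(0, c(2, 2, T_))
  h[1, 1, ] <- -0.1
  h[2, 2, ] <- -0.1
  if (config$coupled) {
    h[1, 2, ] <- 0.4 * (s / T_)^2 - 0.1        # slow excitation 2 -> 1
    h[2, 1, ] <- -0.1 * (1 - s / T_)^2         # fast inhibition 1 -> 2
  }
  h
}

glm_stimulus <- function(config) {
  tau <- config$tau_trial; T_ <- config$T_filter
  t <- seq_len(tau)
  span <- floor(0.6 * tau)
  x <- ifelse(t <= span, sin(pi * t / span)^2, 0)
  ## scale so max rolling T-step sum of the stimulus drive = log(stim_peak)
  roll <- stats::filter(c(x, rep(0, T_)), rep(1, T_), sides = 1)
  x * log(config$stim_peak) / max(roll, na.rm = TRUE)
}

#' @rdname glm_config
#' @param config a [glm_config()].
#' @param seed integer seed (generators are seed-deterministic).
#' @return `simulate_glm` returns a list with `spikes` and `calcium`
#'   (arrays `n_trials x tau_trial x 2`), the stimulus waveform `stim`, and
#'   the trial-time grid `t` on (0, 1].
#' @export
simulate_glm <- function(config = glm_config(), seed = 1) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  T_ <- config$T_filter; tau <- config$tau_trial
  h <- glm_filters(config)
  stim <- glm_stimulus(config)
  spikes <- array(0L, c(config$n_trials, tau, 2))
  lam_base <- config$base_rate
  for (tr in seq_len(config$n_trials)) {
    ybuf <- matrix(0, T_ + tau, 2)   # zero history before trial start
    xbuf <- c(rep(0, T_), stim)
    for (t in seq_len(tau)) {
      drive <- sum(xbuf[t:(t + T_ - 1)])
      for (i in 1:2) {
        hist_term <- 0
        for (j in 1:2) {
          ## y_j at lags 1..T: ybuf rows t+T-1 .. t mapped to h[i, j, 1..T]
          hist_term <- hist_term + sum(h[i, j, ] * ybuf[(t + T_ - 1):t, j])
        }
        lam <- lam_base * exp(drive + hist_term)
        if (!is.finite(lam) || lam > 1e6) {
          stop("rate overflow in GLM simulation (unstable coupling filter h[",
               i, ",", j, "])")
        }
        spikes[tr, t, i] <- stats::rpois(1, lam)
      }
      ybuf[t + T_, ] <- spikes[tr, t, ]
    }
  }
  d <- exp(-1 / config$ca_decay)
  calcium <- spikes
  for (i in 1:2) {
    for (tr in seq_len(config$n_trials)) {
      calcium[tr, , i] <- stats::filter(spikes[tr, , i], d,
                                        method = "recursive")
    }
  }
  list(spikes = spikes, calcium = calcium, stim = stim,
       t = seq_len(tau) / tau, config = config)
}

#' Flatten a GLM simulation into a conditioned dataset
#'
#' Stacks all trials: the covariate is within-trial time on (0, 1] and the
#' two columns are the calcium traces of the two neurons.  Small
#' jitter breaks Poisson ties so marginal transforms are well defined.
#'
#' @param sim output of [simulate_glm()].
#' @param jitter_sd Gaussian jitter added to the calcium traces.
#' @param seed seed for the jitter.
#' @return a [cond_dataset()].
#' @export
glm_dataset <- function(sim, jitter_sd = 1e-3, seed = 1) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  n <- dim(sim$calcium)[1] * dim(sim$calcium)[2]
  Y <- cbind(as.vector(sim$calcium[, , 1]), as.vector(sim$calcium[, , 2]))
  Y <- Y + matrix(stats::rnorm(2 * n, 0, jitter_sd), n, 2)
  colnames(Y) <- c("neuron1", "neuron2")
  x <- rep(sim$t, each = dim(sim$calcium)[1])
  cond_dataset(x = x, Y = Y)
}

## ---- benchmark distributions ----------------------------------------------

#' Benchmark datasets with known information content
#'
#' Three synthetic validation distributions on the unit hypercube, each
#' conditioned on \eqn{x \sim U(0,1)}:
#'
#' * `"gaussian"`: equicorrelated Gaussian copula with
#'   \eqn{\rho(x) = -0.1 + 1.1 x} (clipped just below 1);
#' * `"student"`: equicorrelated Student-t copula with fixed
#'   \eqn{\rho = 0.7} and degrees of freedom \eqn{df(x) = \exp(5 x) + 1};
#' * `"morphed"`: the Gaussian samples pushed through
#'   \eqn{\tilde y_i = y_i + (\prod_j y_j)^{1/N}} followed by an empirical
#'   probability integral transform - a distribution that matches none of
#'   the parametric families yet has the same mutual information with x as
#'   the Gaussian dataset (the morph does not involve x).
#'
#' @param kind one of `"gaussian"`, `"student"`, `"morphed"`.
#' @param N dimension (at least 2 for dependence; must satisfy
#'   \eqn{\rho > -1/(N-1)} for the equicorrelation to be positive
#'   definite).
#' @param n sample count.
#' @param seed integer seed.
#' @param rho_student fixed correlation of the Student-t benchmark.
#' @return list with `x` (length n), `U` (n x N unit-cube matrix), `kind`,
#'   and the per-sample parameter (`rho` or `df`).
#' @export
gen_benchmark <- function(kind = c("gaussian", "student", "morphed"),
                          N = 2, n = 5000, seed = 1, rho_student = 0.7) {
  kind <- match.arg(kind)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  x <- stats::runif(n)
  if (kind == "gaussian" || kind == "morphed") {
    rho <- benchmark_rho(x)
    check_equicorr(min(rho), N)
    Y <- equicorr_normal(n, N, rho)
    U <- stats::pnorm(Y)
    if (kind == "morphed") {
      Yt <- U + exp(rowMeans(log(pmax(U, 1e-300))))   # y_i + (prod y_j)^(1/N)
      U <- apply(Yt, 2, function(col) rank(col) / (n + 1))
    }
    list(x = x, U = U, kind = kind, rho = rho)
  } else {
    df <- exp(5 * x) + 1
    check_equicorr(rho_student, N)
    Z <- equicorr_normal(n, N, rep(rho_student, n))
    W <- Z * sqrt(df / stats::rchisq(n, df))
    U <- matrix(stats::pt(W, df), n, N)
    list(x = x, U = U, kind = kind, df = df, rho = rho_student)
  }
}

benchmark_rho <- function(x) pmin(-0.1 + 1.1 * x, 1 - 1e-6)

check_equicorr <- function(rho_min, N) {
  if (rho_min <= -1 / (N - 1)) {
    stop("equicorrelation rho = ", rho_min,
         " is not positive definite at N = ", N)
  }
  invisible(TRUE)
}

## samples from N(0, R(rho_i)) with per-sample equicorrelation, via the
## analytic eigenstructure of the equicorrelation matrix
equicorr_normal <- function(n, N, rho) {
  Z <- matrix(stats::rnorm(n * N), n, N)
  l1 <- 1 + (N - 1) * rho
  l2 <- 1 - rho
  zbar <- rowMeans(Z)
  sqrt(l2) * Z + (sqrt(l1) - sqrt(l2)) * zbar
}

## ---- ground-truth oracles --------------------------------------------------

#' Ground-truth entropy and mutual information for the benchmarks
#'
#' Closed forms where they exist, numerical integration elsewhere:
#'
#' * Gaussian copula entropy: \eqn{\frac12 \log_2 \det R(\rho)} with the
#'   equicorrelation determinant \eqn{(1-\rho)^{N-1}(1 + (N-1)\rho)};
#' * Student-t copula entropy: the multivariate-t entropy closed form minus
#'   the t marginal entropies;
#' * \eqn{I(x, y)}: the conditional term integrates the closed-form copula
#'   entropy over x (Gauss-Legendre); the marginal-entropy term
#'   \eqn{H(\bar u)} is computed by Monte Carlo over exact samples with the
#'   mixture density evaluated on an x-quadrature grid.  The morphed
#'   benchmark shares the Gaussian mutual information (the morph is
#'   x-independent); its conditional entropy has no ground truth.
#'
#' @param kind `"gaussian"`, `"student"`, or `"morphed"`.
#' @param N dimension.
#' @param x covariate values at which to report the conditional-entropy
#'   curve.
#' @param n_mc Monte-Carlo samples for the marginal-entropy term.
#' @param n_quad x-quadrature nodes for the mixture density.
#' @param seed integer seed.
#' @param rho_student fixed correlation of the Student-t benchmark.
#' @return list with `hc` (per-x copula entropy in bits, `NULL` for
#'   morphed), `mi` (bits), and `mi_se` (Monte-Carlo standard error).
#' @export
truth_oracle <- function(kind = c("gaussian", "student", "morphed"), N = 2,
                         x = seq(0, 1, length.out = 101), n_mc = 400000,
                         n_quad = 64, seed = 1, rho_student = 0.7) {
  kind <- match.arg(kind)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  gl <- gauss_legendre(n_quad)
  xq <- (gl$x + 1) / 2; wq <- gl$w / 2
  if (kind %in% c("gaussian", "morphed")) {
    hc_fun <- function(t) gauss_copula_entropy(benchmark_rho(t), N)
    hc <- if (kind == "gaussian") hc_fun(x) else NULL
    term1 <- -sum(wq * hc_fun(xq))        # E log2 p(u|x)
    ## H(u-bar) by MC over exact samples; density as x-mixture
    b <- gen_benchmark("gaussian", N, n_mc, seed = seed + 1)
    lp <- gauss_mixture_log2density(b$U, benchmark_rho(xq), wq)
    mi <- term1 - mean(lp)    # I = E log2 p(u|x) + H(u-bar)
    mi_se <- stats::sd(lp) / sqrt(n_mc)
  } else {
    hc_fun <- function(t) student_copula_entropy(exp(5 * t) + 1, N, rho_student)
    hc <- hc_fun(x)
    term1 <- -sum(wq * hc_fun(xq))
    b <- gen_benchmark("student", N, n_mc, seed = seed + 1,
                       rho_student = rho_student)
    lp <- student_mixture_log2density(b$U, exp(5 * xq) + 1, wq, rho_student)
    mi <- term1 - mean(lp)
    mi_se <- stats::sd(lp) / sqrt(n_mc)
  }
  list(hc = hc, mi = mi, mi_se = mi_se, x = x, kind = kind, N = N)
}

#' Closed-form equicorrelated Gaussian copula entropy (bits)
#' @param rho equicorrelation (vectorized).
#' @param N dimension.
#' @return \eqn{\frac12 \log_2((1-\rho)^{N-1}(1+(N-1)\rho))}.
#' @export
gauss_copula_entropy <- function(rho, N) {
  0.5 * ((N - 1) * log2(1 - rho) + log2(1 + (N - 1) * rho))
}

## entropy (nats) of a multivariate t with correlation R (log-det ldR)
mvt_entropy_nats <- function(df, N, ldR) {
  -lgamma((df + N) / 2) + lgamma(df / 2) + (N / 2) * log(df * pi) +
    0.5 * ldR + (df + N) / 2 * (digamma((df + N) / 2) - digamma(df / 2))
}

#' Closed-form equicorrelated Student-t copula entropy (bits)
#'
#' Multivariate-t entropy minus the N univariate t marginal entropies
#' (marginals of a correlation-scaled multivariate t are t with the same
#' degrees of freedom).
#' @param df degrees of freedom (vectorized).
#' @param N dimension.
#' @param rho equicorrelation.
#' @return entropy in bits (non-positive).
#' @export
student_copula_entropy <- function(df, N, rho = 0.7) {
  ldR <- (N - 1) * log(1 - rho) + log(1 + (N - 1) * rho)
  (mvt_entropy_nats(df, N, ldR) - N * mvt_entropy_nats(df, 1, 0)) / log(2)
}

## log2 of the x-mixture density of the Gaussian benchmark copula at U
gauss_mixture_log2density <- function(U, rho_k, w_k, chunk = 20000L) {
  n <- nrow(U); N <- ncol(U)
  Z <- stats::qnorm(clamp_unit(U))
  out <- numeric(n)
  for (s in seq(1, n, by = chunk)) {
    idx <- s:min(s + chunk - 1, n)
    q <- rowSums(Z[idx, , drop = FALSE]^2)
    t1 <- rowSums(Z[idx, , drop = FALSE]) / sqrt(N)
    acc <- 0
    for (k in seq_along(rho_k)) {
      l1 <- 1 + (N - 1) * rho_k[k]; l2 <- 1 - rho_k[k]
      ## copula density = mvn density / prod of standard normal marginals
      lc <- -0.5 * (log(l1) + (N - 1) * log(l2)) -
        t1^2 / (2 * l1) - (q - t1^2) / (2 * l2) + q / 2
      acc <- acc + w_k[k] * exp(lc)
    }
    out[idx] <- log2(pmax(acc, 1e-300))
  }
  out
}

## log2 of the x-mixture density of the Student-t benchmark copula at U
student_mixture_log2density <- function(U, df_k, w_k, rho, chunk = 20000L) {
  n <- nrow(U); N <- ncol(U)
  U <- clamp_unit(U)
  l1 <- 1 + (N - 1) * rho; l2 <- 1 - rho
  ldR <- log(l1) + (N - 1) * log(l2)
  out <- numeric(n)
  for (s in seq(1, n, by = chunk)) {
    idx <- s:min(s + chunk - 1, n)
    acc <- 0
    for (k in seq_along(df_k)) {
      df <- df_k[k]
      W <- matrix(stats::qt(U[idx, , drop = FALSE], df), length(idx), N)
      q <- rowSums(W^2); t1 <- rowSums(W) / sqrt(N)
      quad <- t1^2 / l1 + (q - t1^2) / l2
      ljoint <- lgamma((df + N) / 2) - lgamma(df / 2) -
        (N / 2) * log(df * pi) - 0.5 * ldR -
        (df + N) / 2 * log1p(quad / df)
      lmarg <- rowSums(matrix(stats::dt(W, df, log = TRUE),
                              length(idx), N))
      acc <- acc + w_k[k] * exp(ljoint - lmarg)
    }
    out[idx] <- log2(pmax(acc, 1e-300))
  }
  out
}
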