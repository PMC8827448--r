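## Shared fixtures: all data is generated in code under fixed seeds.

fast_cfg <- function(...) {
  over <- list(...)
  args <- list(grid_size = 25, max_steps = 200)
  args[names(over)] <- over
  do.call(gpc_config, args)
}

## invert the GP link: f such that gplink(spec, f) = theta
link_inverse <- function(spec, theta) {
  switch(spec$family,
    indep = 0,
    gauss = 1.4 * stats::qnorm((theta + 1) / 2) / sqrt(2),
    clayton = log(theta) / 0.2,
    gumbel = log(theta - 1) / 0.1,
    frank = {
      a <- abs(theta)
      f <- (-0.1 + sqrt(0.01 + 0.04 * a)) / 0.02
      sign(theta) * f
    }
  )
}

## invert the stick-breaking map: latent values giving the target weights
stick_inverse <- function(phi) {
  M <- length(phi)
  if (M == 1) return(numeric(0))
  off <- stats::qnorm((M - seq_len(M - 1)) / (M - seq_len(M - 1) + 1))
  f <- numeric(M - 1)
  carry <- 1
  for (m in seq_len(M - 1)) {
    t_m <- 1 - phi[m] / carry
    f[m] <- stats::qnorm(min(max(t_m, 1e-12), 1 - 1e-12)) - off[m]
    carry <- carry * t_m
  }
  f
}

## a mixcop_gp with covariate-constant parameters and (numerically) zero
## posterior uncertainty: exact density evaluations without any fitting
manual_model <- function(components, thetas, phis = NULL,
                         x_range = c(0, 1), G = 10) {
  if (inherits(components, "bicop_spec")) components <- list(components)
  M <- length(components)
  if (is.null(phis)) phis <- rep(1 / M, M)
  L <- 2L * M - 1L
  latents <- replicate(L, copulagp:::new_latent(G), simplify = FALSE)
  fstick <- stick_inverse(phis)
  for (j in seq_len(M)) {
    latents[[j]]$mu0 <- link_inverse(components[[j]], thetas[j])
    latents[[j]]$logs <- -20
  }
  for (m in seq_len(max(M - 1, 0))) {
    latents[[M + m]]$mu0 <- fstick[m]
    latents[[M + m]]$logs <- -20
  }
  copulagp:::build_model(components, latents, x_range, gpc_config(),
                         numeric(0), waic = NA, aborted = FALSE)
}

## a mixcop_gp whose Gaussian-copula parameter follows theta_fun(x),
## built by placing the exact latent values at the inducing grid
manual_gauss_xmodel <- function(theta_fun, x_range = c(0, 1), G = 60) {
  sp <- bicop_spec("gauss")
  lat <- copulagp:::new_latent(G)
  ## encode theta(x) exactly at the grid through the whitened mean weights
  lat$loglam <- log(0.08)
  lat$logs <- 0
  z <- seq(0, 1, length.out = G)
  f_target <- link_inverse_vec(sp, theta_fun(x_range[1] + z * diff(x_range)))
  U <- copulagp:::grid_chol(z, 0.08)
  Bt <- backsolve(U, copulagp:::rbf_cross(z, z, 0.08), transpose = TRUE)
  ## whitened m with Bt' m ~ f_target via a truncated SVD pseudo-inverse
  ## (the grid correlation matrix is numerically rank-deficient)
  sv <- svd(t(Bt))
  keep <- sv$d > 1e-9 * sv$d[1]
  lat$m <- drop(sv$v[, keep] %*% ((crossprod(sv$u[, keep], f_target)) / sv$d[keep]))
  lat$logS <- rep(-40, G)
  copulagp:::build_model(list(sp), list(lat), x_range, gpc_config(),
                         numeric(0), waic = NA, aborted = FALSE)
}

link_inverse_vec <- function(spec, theta) {
  vapply(theta, function(t) link_inverse(spec, t), 0)
}

## equicorrelated Gaussian copula samples at fixed rho
equicorr_u <- function(n, m, rho, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  z0 <- rnorm(n); Z <- matrix(rnorm(n * m), n, m)
  pnorm(sqrt(rho) * z0 + sqrt(1 - rho) * Z)
}
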