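## Latent Gaussian-process machinery for conditional copula mixtures.
##
## Each latent function (one per copula parameter, plus M-1 stick-breaking
## variables for the mixture weights) is an independent GP of the covariate
## with an RBF kernel, approximated by variational inference with inducing
## points on a regular grid over the standardized covariate domain [0, 1].
## The variational distribution is a whitened mean-field Gaussian q(u') =
## N(m, diag(S)) against the standard-normal prior, so KL(q || p) vanishes
## at initialization and the prior model has zero-mean latents.

rbf_cross <- function(x, z, lam) {
  exp(-0.5 * (outer(x, z, "-") / lam)^2)
}

## Cholesky (upper) of the grid correlation matrix with jitter
grid_chol <- function(z, lam, jitter = 1e-6) {
  R <- rbf_cross(z, z, lam)
  chol(R + diag(jitter, length(z)))
}

new_latent <- function(G) {
  list(
    m      = rep(0, G),     # whitened variational mean
    logS   = rep(0, G),     # log variational variances (mean-field)
    mu0    = 0,             # constant GP mean
    loglam = log(0.5),      # RBF lengthscale on the unit interval
    logs   = 0              # log kernel output scale
  )
}

## Deterministic kernel interpolation state for a fixed lengthscale:
## Bt = L_R^{-1} r(Z, x)  (G x n), so that whitened f = mu0 + s * Bt' m.
latent_kcache <- function(loglam, xs, z) {
  lam <- exp(loglam)
  U <- grid_chol(z, lam)
  Bt <- backsolve(U, rbf_cross(z, xs, lam), transpose = TRUE)
  list(Bt = Bt, bt2 = Bt^2)
}

## Predictive moments given a kernel cache
moments_from_kcache <- function(lat, kc) {
  s <- exp(lat$logs)
  mu <- lat$mu0 + s * drop(crossprod(kc$Bt, lat$m))
  sig2 <- s^2 * pmax(1 + 1e-6 + drop(crossprod(kc$bt2, exp(lat$logS) - 1)), 1e-12)
  list(mu = mu, sigma = sqrt(sig2))
}

## One-shot moments (used outside the optimizer hot loop)
latent_moments <- function(lat, xs, z) {
  kc <- latent_kcache(lat$loglam, xs, z)
  c(moments_from_kcache(lat, kc), list(kc = kc))
}

## Correlated functional draws from the posterior over a latent function,
## evaluated at xs.  Returns an S x n matrix.
latent_fdraws <- function(lat, xs, z, S_draws) {
  lam <- exp(lat$loglam); s <- exp(lat$logs)
  kc <- latent_kcache(lat$loglam, xs, z)
  Bt <- kc$Bt
  n <- length(xs)
  Rxx <- rbf_cross(xs, xs, lam)
  Sv <- exp(lat$logS)
  Cov <- s^2 * (Rxx - crossprod(Bt) + crossprod(Bt * sqrt(Sv)))
  Cov <- (Cov + t(Cov)) / 2 + diag(1e-8 * s^2, n)
  mu <- lat$mu0 + s * drop(crossprod(Bt, lat$m))
  Ch <- tryCatch(chol(Cov), error = function(e) chol(Cov + diag(1e-5 * s^2, n)))
  eps <- matrix(stats::rnorm(S_draws * n), S_draws, n)
  sweep(eps %*% Ch, 2, mu, "+")
}

## ---- theta-vectorized log densities ---------------------------------------

## log copula density with elementwise parameter vector theta (same length
## as u1/u2); rotations handled by reflecting arguments.
bicop_lpdf_v <- function(spec, theta, u1, u2) {
  a <- rotate_args(spec$rotation, u1, u2)
  cc <- comp_cache_base(spec$family, a$u1, a$u2)
  comp_lpdf(spec$family, cc, theta)
}

## Family-specific transforms of the (already rotated) arguments that do
## not depend on theta; computed once per fit and reused across draws.
comp_cache_base <- function(family, u1, u2) {
  switch(family,
    indep = list(n = length(u1)),
    gauss = {
      z1 <- stats::qnorm(u1); z2 <- stats::qnorm(u2)
      list(z1 = z1, z2 = z2, z11 = z1^2 + z2^2, z12 = z1 * z2)
    },
    frank = list(u1 = u1, u2 = u2, w = (1 - 2 * u1) * (1 - 2 * u2),
                 usum = u1 + u2),
    clayton = {
      lu1 <- log(u1); lu2 <- log(u2)
      list(lu1 = lu1, lu2 = lu2, lsum = lu1 + lu2)
    },
    gumbel = {
      x <- -log(u1); y <- -log(u2)
      list(x = x, y = y, lx = log(x), ly = log(y))
    }
  )
}

comp_cache <- function(spec, u1, u2) {
  a <- rotate_args(spec$rotation, u1, u2)
  comp_cache_base(spec$family, a$u1, a$u2)
}

rep_cache <- function(cc, times) {
  lapply(cc, function(v) if (length(v) > 1) rep(v, times) else v)
}

## log density from a cache
comp_lpdf <- function(family, cc, theta) {
  switch(family,
    indep = numeric(cc$n),
    gauss = {
      r <- pmin(pmax(theta, -1 + 1e-7), 1 - 1e-7)
      om <- 1 - r^2
      -0.5 * log(om) - (r^2 * cc$z11 - 2 * r * cc$z12) / (2 * om)
    },
    frank = {
      th <- theta
      small <- abs(th) < 1e-4
      out <- numeric(length(th))
      if (any(small)) {
        out[small] <- log1p(th[small] * cc$w[small] / 2)
      }
      if (any(!small)) {
        t2 <- pmin(pmax(th[!small], -35), 35)
        e <- expm1(-t2)
        a1 <- expm1(-t2 * cc$u1[!small]); b1 <- expm1(-t2 * cc$u2[!small])
        out[!small] <- log(-t2 * e) - t2 * cc$usum[!small] -
          2 * log(abs(e + a1 * b1))
      }
      out
    },
    clayton = {
      th <- pmin(pmax(theta, 1e-10), 30)
      s <- exp(-th * cc$lu1) + exp(-th * cc$lu2) - 1
      log1p(th) - (th + 1) * cc$lsum - (2 + 1 / th) * log(pmax(s, 1e-300))
    },
    gumbel = {
      th <- pmin(pmax(theta, 1), 30)
      ls <- log(exp(th * cc$lx) + exp(th * cc$ly))
      s1t <- exp(ls / th)
      -s1t + (th - 1) * (cc$lx + cc$ly) + cc$x + cc$y +
        (1 / th - 2) * ls + log(s1t + th - 1)
    }
  )
}

## log density and its derivative with respect to theta, from a cache
comp_lpdf_grad <- function(family, cc, theta) {
  switch(family,
    indep = list(lc = numeric(cc$n), dlc = numeric(cc$n)),
    gauss = {
      r <- pmin(pmax(theta, -1 + 1e-7), 1 - 1e-7)
      om <- 1 - r^2
      lc <- -0.5 * log(om) - (r^2 * cc$z11 - 2 * r * cc$z12) / (2 * om)
      dlc <- r / om + (cc$z12 * (1 + r^2) - r * cc$z11) / om^2
      list(lc = lc, dlc = dlc)
    },
    frank = {
      th <- theta
      small <- abs(th) < 1e-4
      lc <- dlc <- numeric(length(th))
      if (any(small)) {
        ws <- cc$w[small]
        lc[small] <- log1p(th[small] * ws / 2)
        dlc[small] <- (ws / 2) / (1 + th[small] * ws / 2)
      }
      if (any(!small)) {
        i <- !small
        t2 <- pmin(pmax(th[i], -35), 35)
        em <- exp(-t2)
        e <- em - 1
        ea <- exp(-t2 * cc$u1[i]); eb <- exp(-t2 * cc$u2[i])
        a1 <- ea - 1; b1 <- eb - 1
        de <- -em; da <- -cc$u1[i] * ea; db <- -cc$u2[i] * eb
        den <- e + a1 * b1
        lc[i] <- log(-t2 * e) - t2 * cc$usum[i] - 2 * log(abs(den))
        dlc[i] <- (e + t2 * de) / (t2 * e) - cc$usum[i] -
          2 * (de + da * b1 + a1 * db) / den
      }
      list(lc = lc, dlc = dlc)
    },
    clayton = {
      th <- pmin(pmax(theta, 1e-10), 30)
      e1 <- exp(-th * cc$lu1); e2 <- exp(-th * cc$lu2)
      s <- pmax(e1 + e2 - 1, 1e-300)
      ls <- log(s)
      lc <- log1p(th) - (th + 1) * cc$lsum - (2 + 1 / th) * ls
      dlc <- 1 / (1 + th) - cc$lsum + ls / th^2 -
        (2 + 1 / th) * (-cc$lu1 * e1 - cc$lu2 * e2) / s
      list(lc = lc, dlc = dlc)
    },
    gumbel = {
      th <- pmin(pmax(theta, 1), 30)
      tx <- exp(th * cc$lx); ty <- exp(th * cc$ly)
      s <- tx + ty
      ls <- log(s)
      s1t <- exp(ls / th)
      dsdth <- tx * cc$lx + ty * cc$ly
      ds1t <- s1t * (-ls / th^2 + dsdth / (th * s))
      lc <- -s1t + (th - 1) * (cc$lx + cc$ly) + cc$x + cc$y +
        (1 / th - 2) * ls + log(s1t + th - 1)
      dlc <- -ds1t + (cc$lx + cc$ly) - ls / th^2 +
        (1 / th - 2) * dsdth / s + (ds1t + 1) / (s1t + th - 1)
      list(lc = lc, dlc = dlc)
    }
  )
}

## derivative of the link function theta = GPlink(f)
gplink_deriv <- function(spec, f) {
  switch(spec$family,
    indep   = rep(0, length(f)),
    gauss   = 2 / sqrt(pi) * exp(-(f / 1.4)^2) / 1.4,
    frank   = 0.1 + 0.02 * abs(f),
    clayton = 0.2 * exp(0.2 * f),
    gumbel  = 0.1 * exp(0.1 * f)
  )
}
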