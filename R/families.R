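#' Bivariate parametric copula families
#'
#' The building blocks of all conditional dependence models in this package
#' are one-parameter bivariate copula families: Gaussian, Frank, Clayton and
#' Gumbel, plus the parameter-free Independence copula.  Clayton and Gumbel
#' are additionally available in 90/180/270-degree rotated variants so that
#' negative dependence and upper-tail concentration can be expressed.  A
#' `bicop_spec` is a lightweight descriptor of one such family+rotation; the
#' copula parameter `theta` is always passed separately (it may vary with the
#' conditioning covariate).
#'
#' @param family one of `"indep"`, `"gauss"`, `"frank"`, `"clayton"`,
#'   `"gumbel"`.
#' @param rotation one of 0, 90, 180, 270.  Only Clayton and Gumbel support
#'   non-zero rotations (the Gaussian and Frank densities are symmetric under
#'   them up to a sign change of the parameter).
#' @return an object of class `bicop_spec`.
#' @examples
#' sp <- bicop_spec("clayton", 90)
#' bicop_pdf(sp, 2, cbind(0.3, 0.7))
#' @export
bicop_spec <- function(family = c("indep", "gauss", "frank", "clayton", "gumbel"),
                       rotation = 0) {
  family <- match.arg(family)
  if (!rotation %in% c(0L, 90L, 180L, 270L)) {
    stop("rotation must be one of 0, 90, 180, 270")
  }
  rotation <- as.integer(rotation)
  if (rotation != 0L && !family %in% c("clayton", "gumbel")) {
    stop("only Clayton and Gumbel copulas support non-zero rotations")
  }
  structure(list(family = family, rotation = rotation), class = "bicop_spec")
}

#' @export
format.bicop_spec <- function(x, ...) {
  if (x$rotation == 0L) x$family else paste0(x$family, x$rotation)
}

#' @export
print.bicop_spec <- function(x, ...) {
  cat("<bicop_spec>", format(x), "\n")
  invisible(x)
}

## parameter domain per family (rotation does not change it)
theta_domain <- function(spec) {
  switch(spec$family,
    indep   = c(0, 0),
    gauss   = c(-1, 1),
    frank   = c(-Inf, Inf),
    clayton = c(0, Inf),
    gumbel  = c(1, Inf)
  )
}

check_theta <- function(spec, theta) {
  dom <- theta_domain(spec)
  if (spec$family == "indep") return(invisible(TRUE))
  if (any(theta < dom[1] | theta > dom[2])) {
    stop(sprintf("theta outside the %s domain [%g, %g]",
                 spec$family, dom[1], dom[2]))
  }
  invisible(TRUE)
}

#' Clamp pseudo-observations away from the unit-square boundary
#'
#' All copula evaluations clip their arguments to `[eps, 1-eps]` so that
#' densities and h-functions stay finite; `eps = 1e-6` throughout.
#' @param u numeric vector or matrix of pseudo-observations.
#' @param eps clipping margin.
#' @return clamped object of the same shape.
#' @export
clamp_unit <- function(u, eps = 1e-6) {
  pmin(pmax(u, eps), 1 - eps)
}

as_u_matrix <- function(u) {
  u <- if (is.null(dim(u))) matrix(u, ncol = 2) else as.matrix(u)
  if (ncol(u) != 2) stop("u must have two columns")
  u
}

## Map arguments into the 0-degree frame of the base family.
## Convention: 90 degrees reflects u1, 270 degrees reflects u2,
## 180 degrees reflects both.  90/270 express negative dependence.
rotate_args <- function(rotation, u1, u2) {
  switch(as.character(rotation),
    "0"   = list(u1 = u1, u2 = u2),
    "90"  = list(u1 = 1 - u1, u2 = u2),
    "180" = list(u1 = 1 - u1, u2 = 1 - u2),
    "270" = list(u1 = u1, u2 = 1 - u2)
  )
}

## ---- base (0-degree) family densities -------------------------------------

pdf0 <- function(family, theta, u1, u2) {
  switch(family,
    indep = rep(1, length(u1)),
    gauss = {
      r <- pmin(pmax(theta, -1 + 1e-10), 1 - 1e-10)
      z1 <- stats::qnorm(u1); z2 <- stats::qnorm(u2)
      om <- 1 - r^2
      exp(-(r^2 * (z1^2 + z2^2) - 2 * r * z1 * z2) / (2 * om)) / sqrt(om)
    },
    frank = {
      if (abs(theta) < 1e-4) {
        ## series expansion around the independence singularity
        1 + theta * (1 - 2 * u1) * (1 - 2 * u2) / 2
      } else {
        e <- expm1(-theta)
        a <- expm1(-theta * u1); b <- expm1(-theta * u2)
        num <- -theta * e * exp(-theta * (u1 + u2))
        num / (e + a * b)^2
      }
    },
    clayton = {
      if (theta < 1e-8) return(rep(1, length(u1)))
      lu1 <- log(u1); lu2 <- log(u2)
      s <- exp(-theta * lu1) + exp(-theta * lu2) - 1
      exp(log1p(theta) - (theta + 1) * (lu1 + lu2) - (2 + 1 / theta) * log(s))
    },
    gumbel = {
      if (theta < 1 + 1e-10) return(rep(1, length(u1)))
      x <- -log(u1); y <- -log(u2)
      tx <- x^theta; ty <- y^theta
      s <- tx + ty
      s1t <- s^(1 / theta)
      ## c = C(u,v) (xy)^(th-1)/(uv) s^(2/th-2) (s^(1/th) + th - 1)
      exp(-s1t + (theta - 1) * (log(x) + log(y)) + x + y +
            (1 / theta - 2) * log(s) + log(s1t + theta - 1))
    }
  )
}

cdf0 <- function(family, theta, u1, u2) {
  switch(family,
    indep = u1 * u2,
    gauss = {
      ## C(u1,u2) = int_0^u1 h(u2|s) ds by Gauss-Legendre (no closed form)
      r <- pmin(pmax(theta, -1 + 1e-10), 1 - 1e-10)
      gl <- gauss_legendre(64)
      out <- numeric(length(u1))
      z2 <- stats::qnorm(u2)
      for (i in seq_along(u1)) {
        s <- u1[i] / 2 * (gl$x + 1)
        w <- u1[i] / 2 * gl$w
        h <- stats::pnorm((z2[i] - r * stats::qnorm(s)) / sqrt(1 - r^2))
        out[i] <- sum(w * h)
      }
      out
    },
    frank = {
      if (abs(theta) < 1e-4) {
        u1 * u2 * (1 + theta * (1 - u1) * (1 - u2) / 2)
      } else {
        -log1p(expm1(-theta * u1) * expm1(-theta * u2) / expm1(-theta)) / theta
      }
    },
    clayton = {
      if (theta < 1e-8) return(u1 * u2)
      pmax(u1^(-theta) + u2^(-theta) - 1, 0)^(-1 / theta)
    },
    gumbel = {
      if (theta < 1 + 1e-10) return(u1 * u2)
      exp(-((-log(u1))^theta + (-log(u2))^theta)^(1 / theta))
    }
  )
}

## h(u2 | u1) = d C / d u1, the conditional cdf of u2 given u1
hfun0 <- function(family, theta, u1, u2) {
  switch(family,
    indep = u2,
    gauss = {
      r <- pmin(pmax(theta, -1 + 1e-10), 1 - 1e-10)
      stats::pnorm((stats::qnorm(u2) - r * stats::qnorm(u1)) / sqrt(1 - r^2))
    },
    frank = {
      if (abs(theta) < 1e-4) {
        u2 + theta * u2 * (1 - u2) * (1 - 2 * u1) / 2
      } else {
        a <- exp(-theta * u1)
        b <- expm1(-theta * u2)
        a * b / (expm1(-theta) + expm1(-theta * u1) * b)
      }
    },
    clayton = {
      if (theta < 1e-8) return(u2)
      s <- u1^(-theta) + u2^(-theta) - 1
      u1^(-theta - 1) * s^(-(theta + 1) / theta)
    },
    gumbel = {
      if (theta < 1 + 1e-10) return(u2)
      x <- -log(u1); y <- -log(u2)
      s <- x^theta + y^theta
      exp(-s^(1 / theta)) * s^(1 / theta - 1) * x^(theta - 1) / u1
    }
  )
}

## inverse of hfun0 in u2 for fixed u1: u2 such that h(u2|u1) = q
ppcf0 <- function(family, theta, u1, q) {
  switch(family,
    indep = q,
    gauss = {
      r <- pmin(pmax(theta, -1 + 1e-10), 1 - 1e-10)
      stats::pnorm(r * stats::qnorm(u1) + sqrt(1 - r^2) * stats::qnorm(q))
    },
    frank = {
      if (abs(theta) < 1e-4) {
        bisect_h(function(v) hfun0("frank", theta, u1, v), q)
      } else {
        a <- exp(-theta * u1)
        ## solve a*(e^{-th v}-1) = q*(e^{-th}-1 + (a-1)(e^{-th v}-1)) for v
        e <- expm1(-theta)
        w <- q * e / (a - q * (a - 1))
        v <- -log1p(w) / theta
        pmin(pmax(v, 1e-12), 1 - 1e-12)
      }
    },
    clayton = {
      if (theta < 1e-8) return(q)
      v <- (q^(-theta / (theta + 1)) - 1) * u1^(-theta) + 1
      pmin(pmax(v, 1e-300), Inf)^(-1 / theta)
    },
    gumbel = bisect_h(function(v) hfun0("gumbel", theta, u1, v), q)
  )
}

## vectorized bisection for h-function inversion (used where no closed form)
bisect_h <- function(h, q, tol = 1e-9, maxit = 80) {
  lo <- rep(1e-10, length(q)); hi <- rep(1 - 1e-10, length(q))
  for (it in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    v <- h(mid)
    up <- v < q
    lo[up] <- mid[up]; hi[!up] <- mid[!up]
    if (max(hi - lo) < tol) break
  }
  if (max(hi - lo) > 1e-6) {
    stop("h-function inversion failed to converge")
  }
  (lo + hi) / 2
}

gauss_legendre <- function(n) {
  ## Golub-Welsch: nodes/weights on [-1, 1]
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = rev(e$values), w = rev(2 * e$vectors[1, ]^2))
}

## ---- public rotated interface ---------------------------------------------

#' Copula density, CDF, h-function, inverse h-function
#'
#' Vectorized evaluations of a bivariate copula family at parameter `theta`.
#' `bicop_hfun` is the conditional CDF \eqn{C(u_2 | u_1)} ("h-function");
#' `bicop_ppcf` is its inverse in \eqn{u_2} (the conditional quantile
#' function used for sequential sampling and vine transforms).  Rotations are
#' handled by reflecting arguments into the 0-degree frame: 90 degrees
#' reflects \eqn{u_1}, 270 degrees reflects \eqn{u_2}, 180 degrees both.
#'
#' @param spec a [bicop_spec()].
#' @param theta copula parameter (scalar, inside the family domain).
#' @param u two-column matrix (or length-2 vector) of points in the open unit
#'   square.
#' @param u1,q for `bicop_ppcf`: conditioning coordinate and target
#'   conditional probability.
#' @return numeric vector.
#' @export
bicop_pdf <- function(spec, theta, u) {
  check_theta(spec, theta)
  u <- clamp_unit(as_u_matrix(u))
  a <- rotate_args(spec$rotation, u[, 1], u[, 2])
  pdf0(spec$family, theta, a$u1, a$u2)
}

#' @rdname bicop_pdf
#' @export
bicop_cdf <- function(spec, theta, u) {
  check_theta(spec, theta)
  u <- as_u_matrix(u)
  u1 <- pmin(pmax(u[, 1], 0), 1); u2 <- pmin(pmax(u[, 2], 0), 1)
  rot <- spec$rotation
  if (rot == 0L) {
    cdf0(spec$family, theta, pmax(u1, 1e-12), pmax(u2, 1e-12))
  } else if (rot == 90L) {
    u2 - cdf0(spec$family, theta, pmax(1 - u1, 1e-12), pmax(u2, 1e-12))
  } else if (rot == 180L) {
    u1 + u2 - 1 + cdf0(spec$family, theta, pmax(1 - u1, 1e-12), pmax(1 - u2, 1e-12))
  } else {
    u1 - cdf0(spec$family, theta, pmax(u1, 1e-12), pmax(1 - u2, 1e-12))
  }
}

#' @rdname bicop_pdf
#' @export
bicop_hfun <- function(spec, theta, u) {
  check_theta(spec, theta)
  u <- clamp_unit(as_u_matrix(u))
  u1 <- u[, 1]; u2 <- u[, 2]
  rot <- spec$rotation
  out <- if (rot == 0L) {
    hfun0(spec$family, theta, u1, u2)
  } else if (rot == 90L) {
    hfun0(spec$family, theta, 1 - u1, u2)
  } else if (rot == 180L) {
    1 - hfun0(spec$family, theta, 1 - u1, 1 - u2)
  } else {
    1 - hfun0(spec$family, theta, u1, 1 - u2)
  }
  pmin(pmax(out, 0), 1)
}

#' @rdname bicop_pdf
#' @export
bicop_ppcf <- function(spec, theta, u1, q) {
  check_theta(spec, theta)
  u1 <- clamp_unit(u1); q <- clamp_unit(q)
  rot <- spec$rotation
  out <- if (rot == 0L) {
    ppcf0(spec$family, theta, u1, q)
  } else if (rot == 90L) {
    ppcf0(spec$family, theta, 1 - u1, q)
  } else if (rot == 180L) {
    1 - ppcf0(spec$family, theta, 1 - u1, 1 - q)
  } else {
    1 - ppcf0(spec$family, theta, u1, 1 - q)
  }
  pmin(pmax(out, 1e-12), 1 - 1e-12)
}

#' Sample from a bivariate copula
#'
#' Draws `n` pairs by the conditional method: \eqn{u_1 \sim U(0,1)} and
#' \eqn{u_2 = h^{-1}(q | u_1)} with \eqn{q \sim U(0,1)}.
#'
#' @inheritParams bicop_pdf
#' @param n number of samples.
#' @param seed optional integer seed (local to this call).
#' @return an `n x 2` matrix.
#' @export
bicop_sample <- function(spec, theta, n, seed = NULL) {
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  u1 <- stats::runif(n)
  q <- stats::runif(n)
  cbind(u1, bicop_ppcf(spec, theta, u1, q))
}

#' Kendall's tau of a copula family at a given parameter
#'
#' Closed-form maps: Gaussian \eqn{(2/\pi)\arcsin\theta}; Clayton
#' \eqn{\theta/(\theta+2)}; Gumbel \eqn{1 - 1/\theta}; Frank via the Debye
#' function \eqn{1 - 4(1 - D_1(\theta))/\theta}.  Rotations by 90 or 270
#' degrees flip the sign.
#'
#' @inheritParams bicop_pdf
#' @return tau in `[-1, 1]`.
#' @export
bicop_tau <- function(spec, theta) {
  check_theta(spec, theta)
  tau0 <- switch(spec$family,
    indep = 0,
    gauss = 2 / pi * asin(pmin(pmax(theta, -1), 1)),
    frank = {
      if (abs(theta) < 1e-6) theta / 9
      else {
        d1 <- stats::integrate(function(t) t / expm1(t), 0, abs(theta),
                               rel.tol = 1e-10)$value / abs(theta)
        sign(theta) * (1 - 4 / abs(theta) * (1 - d1))
      }
    },
    clayton = theta / (theta + 2),
    gumbel = 1 - 1 / theta
  )
  if (spec$rotation %in% c(90L, 270L)) -tau0 else tau0
}

#' GP link functions mapping latent reals onto copula parameter domains
#'
#' Fixed monotone maps from an unconstrained latent Gaussian-process value
#' `f` to each family's parameter domain: Gaussian `erf(f/1.4)`; Frank
#' `0.1 f + sign(f) (0.1 f)^2`; Clayton `exp(0.2 f)`; Gumbel
#' `1 + exp(0.1 f)`.  The Independence copula has no parameter and maps to 0.
#'
#' @inheritParams bicop_pdf
#' @param f latent value(s), any real.
#' @return parameter value(s) in the family domain.
#' @export
gplink <- function(spec, f) {
  switch(spec$family,
    indep   = rep(0, length(f)),
    gauss   = erf(f / 1.4),
    frank   = 0.1 * f + sign(f) * (0.1 * f)^2,
    clayton = exp(0.2 * f),
    gumbel  = 1 + exp(0.1 * f)
  )
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

## All ten mixture building blocks (plus the Gaussian/Frank pair covers
## negative dependence through the sign of theta).
#' The default candidate set of copula elements
#'
#' Gaussian + Frank + Clayton and Gumbel in all four rotations: the ten
#' elements from which copula mixtures are composed.
#' @return list of [bicop_spec()] objects.
#' @export
default_candidates <- function() {
  c(
    list(bicop_spec("gauss"), bicop_spec("frank")),
    lapply(c(0, 90, 180, 270), function(r) bicop_spec("clayton", r)),
    lapply(c(0, 90, 180, 270), function(r) bicop_spec("gumbel", r))
  )
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}
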