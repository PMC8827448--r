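#' Linear copula mixtures
#'
#' A copula mixture combines up to five bivariate copula elements with
#' simplex weights: \eqn{c(u) = \sum_j \phi_j c_j(u; \theta_j)}.  A mixture
#' of copulas is itself a copula (uniform marginals are preserved), and the
#' mixture h-function is the weight-average of component h-functions, which
#' keeps vine transforms and sequential sampling exact.
#'
#' @param components list of [bicop_spec()] (length `M`, at most 5, no
#'   duplicated family+rotation pairs).
#' @param thetas numeric vector of per-component parameters.
#' @param phis simplex weights (non-negative, summing to one).
#' @return object of class `mix_spec`.
#' @export
mix_spec <- function(components, thetas, phis) {
  if (inherits(components, "bicop_spec")) components <- list(components)
  M <- length(components)
  stopifnot(M >= 1, M <= 5, length(thetas) == M, length(phis) == M)
  keys <- vapply(components, format, "")
  if (anyDuplicated(keys)) stop("duplicate (family, rotation) components")
  if (any(phis < -1e-12) || abs(sum(phis) - 1) > 1e-9) {
    stop("phis must be a simplex (non-negative, sum to 1)")
  }
  for (j in seq_len(M)) check_theta(components[[j]], thetas[j])
  structure(list(components = components, thetas = as.numeric(thetas),
                 phis = pmax(as.numeric(phis), 0)),
            class = "mix_spec")
}

#' Stick-breaking map from latent reals to mixture weights
#'
#' Transforms `M - 1` unconstrained reals into an `M`-point simplex via
#' \eqn{\phi_j = (1 - t_j)\prod_{m<j} t_m} with
#' \eqn{t_m = \Phi(\tilde f_m + \Phi^{-1}((M-m)/(M-m+1)))} and
#' \eqn{t_M = 0}.  The offsets are chosen so that all-zero latents give
#' exactly equal weights \eqn{\phi_j = 1/M}, matching a zero-mean latent
#' prior.
#'
#' @param f_tilde numeric vector (length `M - 1`) or matrix (`n x (M-1)`) of
#'   latent values; a zero-column matrix gives the trivial simplex `(1)`.
#' @return weight vector of length `M`, or an `n x M` matrix.
#' @export
stick_break <- function(f_tilde) {
  if (is.matrix(f_tilde)) {
    n <- nrow(f_tilde); M <- ncol(f_tilde) + 1L
    if (M == 1L) return(matrix(1, n, 1))
    m <- seq_len(M - 1)
    off <- stats::qnorm((M - m) / (M - m + 1))
    t_ <- stats::pnorm(sweep(f_tilde, 2, off, "+"))
    phi <- matrix(0, n, M)
    carry <- rep(1, n)
    for (j in seq_len(M - 1)) {
      phi[, j] <- (1 - t_[, j]) * carry
      carry <- carry * t_[, j]
    }
    phi[, M] <- carry
    phi
  } else {
    drop(stick_break(matrix(f_tilde, nrow = 1)))
  }
}

#' Mixture copula density, h-function, inverse h-function and sampling
#'
#' `mix_pdf` evaluates \eqn{\sum_j \phi_j c_j}; `mix_hfun` the weighted
#' conditional CDF \eqn{\sum_j \phi_j h_j(u_2|u_1)}; `mix_ppcf` inverts it by
#' bisection; `mix_sample` draws a component from the weights and then
#' samples from it.
#'
#' @param spec a [mix_spec()].
#' @param u two-column matrix of unit-square points.
#' @param u1,q conditioning coordinate and conditional probability for the
#'   inverse h-function.
#' @param n,seed sample count and optional seed.
#' @return numeric vector, or an `n x 2` matrix for `mix_sample`.
#' @export
mix_pdf <- function(spec, u) {
  u <- as_u_matrix(u)
  out <- numeric(nrow(u))
  for (j in seq_along(spec$components)) {
    if (spec$phis[j] > 0) {
      out <- out + spec$phis[j] * bicop_pdf(spec$components[[j]], spec$thetas[j], u)
    }
  }
  out
}

#' @rdname mix_pdf
#' @export
mix_hfun <- function(spec, u) {
  u <- as_u_matrix(u)
  out <- numeric(nrow(u))
  for (j in seq_along(spec$components)) {
    if (spec$phis[j] > 0) {
      out <- out + spec$phis[j] * bicop_hfun(spec$components[[j]], spec$thetas[j], u)
    }
  }
  pmin(pmax(out, 0), 1)
}

#' @rdname mix_pdf
#' @export
mix_ppcf <- function(spec, u1, q) {
  if (length(spec$components) == 1L) {
    return(bicop_ppcf(spec$components[[1]], spec$thetas[1], u1, q))
  }
  u1 <- clamp_unit(u1); q <- clamp_unit(q)
  bisect_h(function(v) mix_hfun(spec, cbind(u1, v)), q)
}

#' @rdname mix_pdf
#' @export
mix_sample <- function(spec, n, seed = NULL) {
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  comp <- sample.int(length(spec$components), n, replace = TRUE, prob = spec$phis)
  u1 <- stats::runif(n); q <- stats::runif(n)
  u2 <- numeric(n)
  for (j in unique(comp)) {
    idx <- comp == j
    u2[idx] <- bicop_ppcf(spec$components[[j]], spec$thetas[j], u1[idx], q[idx])
  }
  cbind(u1, u2)
}
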