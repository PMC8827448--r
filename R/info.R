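#' Entropy and mutual information estimators
#'
#' All information quantities are reported in bits.  The conditional copula
#' entropy \eqn{H_c(u|x=t) = -E_{p(u|x=t)} \log_2 p(u|x=t)} is estimated by
#' Monte Carlo from model samples.  Mutual information between the
#' covariate and the modelled variables comes in two flavours:
#'
#' * **integrated** (direct nested Monte-Carlo integration):
#'   \eqn{I(x,u) = E_{p(u,x)} \log_2 p(u|x) - E_{p(u)} \log_2 E_{p(x)} p(u|x)},
#'   valid when the marginals do not depend on x;
#' * **estimated** (two-model differencing):
#'   \eqn{I(x,y) = \sum_i I(x,y_i) + H_c(u_1..u_N) - \int H_c(u^x|x=t) p(t) dt},
#'   which trades the inner integral for a second (unconditional) copula
#'   model.
#'
#' Reported uncertainty combines the spread over posterior functional draws
#' (SE) with the Monte-Carlo standard error (MCtol) as
#' \eqn{\sqrt{SE^2 + MCtol^2}}; the 95% interval is the value plus/minus
#' twice that.
#'
#' @name info
NULL

new_info_estimate <- function(value, se, mc_tol, n_mc, method) {
  tol <- sqrt(se^2 + mc_tol^2)
  structure(list(value = value, ci_lo = value - 2 * tol,
                 ci_hi = value + 2 * tol, se = se, mc_tol = mc_tol,
                 n_mc = n_mc, method = method),
            class = "info_estimate")
}

#' @export
print.info_estimate <- function(x, ...) {
  cat(sprintf("%s: %.4f bits  [%.4f, %.4f]  (SE %.4f, MCtol %.4f, n_mc %d)\n",
              x$method, x$value, x$ci_lo, x$ci_hi, x$se, x$mc_tol, x$n_mc))
  invisible(x)
}

## ---- unified model interface (bivariate mixture or vine) -------------------

info_dim <- function(model) if (inherits(model, "cvine")) model$m else 2L

## fd: for mixcop_gp a fdraw function; for cvine a named list of them
info_sample <- function(model, x, fd = NULL) {
  if (inherits(model, "cvine")) {
    cvine_sample(model, x, fdraws = fd)
  } else {
    pars <- if (is_indep(model)) NULL else
      model_params_at(model, x, if (is.null(fd)) NULL else fd(x))
    gpcop_sample(model, x, params = pars)
  }
}

info_logpdf <- function(model, x, U, fd = NULL) {
  if (inherits(model, "cvine")) {
    cvine_logpdf_detail(model, x, U, fdraws = fd)$logpdf
  } else {
    pars <- if (is_indep(model)) NULL else
      model_params_at(model, x, if (is.null(fd)) NULL else fd(x))
    gpcop_logpdf(model, x, U, pars)
  }
}

info_fdraw_sets <- function(model, S, seed = NULL) {
  if (inherits(model, "cvine")) cvine_fdraw_funs(model, S, seed)
  else gpcop_fdraw_funs(model, S, seed)
}

## ---- conditional copula entropy -------------------------------------------

#' Conditional copula entropy along the covariate
#'
#' For every grid value the entropy of the conditional copula is estimated
#' by Monte Carlo: sample from the model at that covariate value and
#' average the negative log2 density.  The GP-posterior band comes from
#' repeating the estimate under `S` functional posterior draws.
#'
#' @param model a fitted [fit_gpcop()] or [fit_cvine()] model.
#' @param x_grid covariate values at which to evaluate.
#' @param n_mc Monte-Carlo samples per grid value.
#' @param S posterior functional draws for the confidence band.
#' @param seed integer seed.
#' @return a tibble with one row per grid value: `x`, `value` (bits),
#'   `ci_lo`, `ci_hi`, `se`, `mc_tol`, `n_mc`, `method`.
#' @export
conditional_copula_entropy <- function(model, x_grid, n_mc = 10000, S = 20,
                                       seed = 1) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  fds <- if (S > 0) info_fdraw_sets(model, S) else list()
  rows <- lapply(x_grid, function(t) {
    xv <- rep(t, n_mc)
    U <- info_sample(model, xv)
    lp <- info_logpdf(model, xv, U) / log(2)
    value <- -mean(lp)
    mc_tol <- stats::sd(lp) / sqrt(n_mc)
    hs <- vapply(fds, function(fd) {
      ns <- max(min(n_mc, 2000L), n_mc %/% 10L)
      xv2 <- rep(t, ns)
      U2 <- info_sample(model, xv2, fd)
      -mean(info_logpdf(model, xv2, U2, fd)) / log(2)
    }, 0)
    se <- if (length(hs) > 1) stats::sd(hs) else 0
    tol <- sqrt(se^2 + mc_tol^2)
    tibble::tibble(x = t, value = value, ci_lo = value - 2 * tol,
                   ci_hi = value + 2 * tol, se = se, mc_tol = mc_tol,
                   n_mc = n_mc, method = "conditional_entropy")
  })
  dplyr::bind_rows(rows)
}

## ---- mutual information ----------------------------------------------------

## core nested-MC integral for one parameter set
mi_integrated_once <- function(model, x_samples, n_outer, n_inner, fd = NULL) {
  xk <- sample(x_samples, n_outer, replace = TRUE)
  U <- info_sample(model, xk, fd)
  lp_cond <- info_logpdf(model, xk, U, fd) / log(2)
  ## inner covariate draws are stratified over the empirical quantiles:
  ## a deterministic midpoint rule over the ECDF of x, which removes the
  ## Jensen bias a noisy inner average would add to log E_x p(u|x)
  xr <- stats::quantile(x_samples, (seq_len(n_inner) - 0.5) / n_inner,
                        names = FALSE, type = 8)
  psum <- numeric(n_outer)
  for (r in seq_len(n_inner)) {
    psum <- psum + exp(info_logpdf(model, rep(xr[r], n_outer), U, fd))
  }
  lp_marg <- log2(pmax(psum / n_inner, 1e-300))
  diff <- lp_cond - lp_marg
  list(mi = mean(diff), mc_tol = stats::sd(diff) / sqrt(n_outer))
}

#' Mutual information by direct nested Monte-Carlo integration
#'
#' Estimates \eqn{I(x, u)} from a single conditional copula model by
#' integrating the model density over both the unit cube and the covariate
#' distribution (taken as the empirical distribution of `x_samples`).
#' Requires marginals that do not depend on x; a warning reminds the caller
#' of this assumption.
#'
#' @param model a fitted [fit_gpcop()] or [fit_cvine()] model.
#' @param x_samples covariate sample defining p(x).
#' @param n_mc_outer outer Monte-Carlo samples (over (u, x)).
#' @param n_mc_inner inner samples for the marginal-density integral.
#' @param S posterior functional draws for the SE band.
#' @param seed integer seed.
#' @param assume_const_marginals set `FALSE` to acknowledge x-dependent
#'   marginals (a warning is issued since the estimate is then invalid).
#' @return an `info_estimate`.
#' @export
mi_integrated <- function(model, x_samples, n_mc_outer = 10000,
                          n_mc_inner = 1000, S = 20, seed = 1,
                          assume_const_marginals = TRUE) {
  if (!assume_const_marginals) {
    warning("mi_integrated is only valid when marginals are independent of x")
  }
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  main <- mi_integrated_once(model, x_samples, n_mc_outer, n_mc_inner)
  fds <- if (S > 0) info_fdraw_sets(model, S) else list()
  mis <- vapply(fds, function(fd) {
    mi_integrated_once(model, x_samples,
                       max(n_mc_outer %/% 5L, 1000L),
                       max(n_mc_inner %/% 2L, 100L), fd)$mi
  }, 0)
  se <- if (length(mis) > 1) stats::sd(mis) else 0
  new_info_estimate(main$mi, se, main$mc_tol, n_mc_outer, "integrated")
}

#' Mutual information by two-model differencing
#'
#' Combines a conditional and an unconditional copula model:
#' marginal MI terms plus the unconditional copula entropy minus the
#' average conditional copula entropy.  With uniform (x-independent)
#' marginals the marginal MI terms are zero and the formula reduces to a
#' copula-entropy difference.
#'
#' @param cond_model conditional model fitted against x.
#' @param uncond_model unconditional model (fitted with a constant
#'   covariate) of the same variables.
#' @param marginal_mi per-variable \eqn{I(x, y_i)} in bits (non-negative);
#'   scalar 0 is recycled.
#' @param x_samples covariate sample defining p(x).
#' @param n_mc Monte-Carlo samples per entropy term.
#' @param S posterior functional draws.
#' @param seed integer seed.
#' @return an `info_estimate`.
#' @export
mi_estimated <- function(cond_model, uncond_model, marginal_mi = 0,
                         x_samples, n_mc = 10000, S = 20, seed = 1) {
  if (info_dim(cond_model) != info_dim(uncond_model)) {
    stop("conditional and unconditional models describe different variables")
  }
  if (any(marginal_mi < 0)) stop("marginal_mi entries must be non-negative")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  mi_marg <- sum(rep(marginal_mi, length.out = info_dim(cond_model)))
  est_once <- function(fd_c, fd_u, n) {
    xk <- sample(x_samples, n, replace = TRUE)
    Uc <- info_sample(cond_model, xk, fd_c)
    lp_c <- info_logpdf(cond_model, xk, Uc, fd_c) / log(2)
    xu <- rep(stats::median(x_samples), n)
    Uu <- info_sample(uncond_model, xu, fd_u)
    lp_u <- info_logpdf(uncond_model, xu, Uu, fd_u) / log(2)
    ## I = sum I(x, y_i) + H_c(u) - int H_c(u^x | x) p(x) dx
    ##   = sum I(x, y_i) + (-E log2 p_u) * (-1) ... kept explicit below
    hc_uncond <- -mean(lp_u)
    hc_cond <- -mean(lp_c)
    list(mi = mi_marg + hc_uncond - hc_cond,
         mc_tol = sqrt(stats::var(lp_u) / n + stats::var(lp_c) / n))
  }
  main <- est_once(NULL, NULL, n_mc)
  fdc <- if (S > 0) info_fdraw_sets(cond_model, S) else list()
  fdu <- if (S > 0) info_fdraw_sets(uncond_model, S) else list()
  mis <- if (S > 0) {
    vapply(seq_len(S), function(s) {
      est_once(fdc[[s]], fdu[[s]], max(n_mc %/% 5L, 1000L))$mi
    }, 0)
  } else numeric(0)
  se <- if (length(mis) > 1) stats::sd(mis) else 0
  new_info_estimate(main$mi, se, main$mc_tol, n_mc, "estimated")
}

## ---- KSG baseline ----------------------------------------------------------

#' Kraskov-Stoegbauer-Grassberger k-nearest-neighbour mutual information
#'
#' The classic non-parametric baseline (algorithm 1): in the joint
#' max-norm space the distance to the k-th neighbour defines a box, and the
#' counts of neighbours within that box in each marginal space enter a
#' digamma formula.  Used here only as a benchmark comparator.
#'
#' @param x covariate vector.
#' @param U matrix of the remaining variables (n x m).
#' @param k neighbour count (k >= 1).
#' @return MI estimate in bits (can be slightly negative by chance).
#' @export
ksg_mi <- function(x, U, k = 5) {
  stopifnot(k >= 1)
  U <- as.matrix(U)
  n <- length(x)
  ## scale to unit variance so the max-norm treats coordinates comparably
  xx <- as.numeric(scale(x))
  UU <- scale(U)
  nx <- integer(n); nu <- integer(n)
  chunk <- max(1L, floor(2e6 / n))
  for (s in seq(1, n, by = chunk)) {
    idx <- s:min(s + chunk - 1, n)
    Dx <- abs(outer(xx[idx], xx, "-"))
    Du <- abs(outer(UU[idx, 1], UU[, 1], "-"))
    if (ncol(UU) > 1) {
      for (j in 2:ncol(UU)) {
        Du <- pmax(Du, abs(outer(UU[idx, j], UU[, j], "-")))
      }
    }
    D <- pmax(Dx, Du)
    D[cbind(seq_along(idx), idx)] <- Inf
    eps <- apply(D, 1, function(d) sort(d, partial = k)[k])
    nx[idx] <- rowSums(Dx < eps) - 1L
    nu[idx] <- rowSums(Du < eps) - 1L
  }
  (digamma(k) + digamma(n) - mean(digamma(nx + 1) + digamma(nu + 1))) / log(2)
}

#' Marginal mutual information between x and one variable (histogram)
#'
#' Plug-in MI on a quantile-binned 2D histogram (32 adaptive bins per
#' axis) with the Miller-Madow bias correction, used for the marginal
#' terms of [mi_estimated()] when marginals depend on x.
#'
#' @param x covariate vector.
#' @param y variable vector.
#' @param bins bins per axis.
#' @return MI in bits (non-negative).
#' @export
marginal_mi_hist <- function(x, y, bins = 32) {
  qx <- cut(rank(x, ties.method = "first"), bins, labels = FALSE)
  qy <- cut(rank(y, ties.method = "first"), bins, labels = FALSE)
  tab <- table(qx, qy) / length(x)
  px <- rowSums(tab); py <- colSums(tab)
  num <- tab / outer(px, py)
  plugin <- sum(tab[tab > 0] * log2(num[tab > 0]))
  ## Miller-Madow: plug-in MI is biased up by ~ (Kx-1)(Ky-1)/(2 n ln 2)
  bias <- (sum(px > 0) - 1) * (sum(py > 0) - 1) / (2 * length(x) * log(2))
  max(plugin - bias, 0)
}
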