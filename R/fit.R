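#' Configuration for bivariate copula-GP fitting
#'
#' Defaults follow the model's standard hyper-parameter table: two Adam
#' learning rates (`base_lr` for GP hyper-parameters, `var_lr` for the
#' variational distribution), the inducing-grid size, the WAIC tolerance
#' used both as an independence threshold and a model-selection stopping
#' rule, the loss tolerance declaring convergence, and the loss tolerance at
#' which WAIC is first checked.  Loss is monitored as a 50-step average; the
#' fit stops early (aborted) when the WAIC check finds the model no better
#' than Independence.
#'
#' @param base_lr learning rate for GP hyper-parameters (mean, lengthscale,
#'   scale).
#' @param var_lr learning rate for variational parameters.
#' @param grid_size number of inducing points on the regular grid.
#' @param waic_tol WAIC tolerance (a model is "better than independence"
#'   when its WAIC is below `-waic_tol`).
#' @param loss_tol 50-step loss change declaring convergence.
#' @param check_waic 50-step loss change at which WAIC is evaluated once.
#' @param max_steps hard cap on optimization steps.
#' @param mc_draws Monte-Carlo draws per step for the ELBO expectation.
#' @param waic_draws posterior draws used in WAIC.
#' @param screen_steps capped step budget for the quick independence screen
#'   used by heuristic model selection.
#' @param lam_every lengthscale update period (the RBF lengthscale is
#'   updated in blocks so kernel interpolation weights can be cached).
#' @return a list of class `gpc_config`.
#' @export
gpc_config <- function(base_lr = 0.05, var_lr = 0.02, grid_size = 60,
                       waic_tol = 0.005, loss_tol = 1e-4, check_waic = 0.005,
                       max_steps = 1500, mc_draws = 10, waic_draws = 100,
                       screen_steps = 200, lam_every = 5) {
  structure(as.list(environment()), class = "gpc_config")
}

stick_offsets <- function(M) {
  if (M < 2) return(numeric(0))
  m <- seq_len(M - 1)
  stats::qnorm((M - m) / (M - m + 1))
}

standardize_x <- function(x, x_range) {
  if (diff(x_range) <= 0) return(rep(0.5, length(x)))
  (x - x_range[1]) / diff(x_range)
}

## number of latent functions for an M-component mixture: M theta latents
## followed by M-1 stick-breaking latents
n_latents <- function(M) 2L * M - 1L

is_indep_spec <- function(spec) spec$family == "indep"

## empirical Kendall tau on a subsample (cheap, used for initialization)
emp_tau <- function(u, max_n = 2000) {
  idx <- if (nrow(u) > max_n) {
    seq(1, nrow(u), length.out = max_n)
  } else seq_len(nrow(u))
  stats::cor(u[idx, 1], u[idx, 2], method = "kendall")
}

## latent value whose linked parameter reproduces tau (0 if unattainable,
## e.g. a positive-dependence family on negative-tau data)
tau_init_f <- function(spec, tau) {
  if (spec$family == "indep" || !is.finite(tau)) return(0)
  g <- function(f) bicop_tau(spec, gplink(spec, f)) - tau
  lo <- g(-8); hi <- g(8)
  if (sign(lo) == sign(hi)) return(0)
  r <- tryCatch(stats::uniroot(g, c(-8, 8), tol = 1e-4)$root,
                error = function(e) 0)
  min(max(r, -8), 8)
}

#' The Independence copula model
#'
#' A fitted-model placeholder carrying no GP state: density 1 everywhere,
#' WAIC exactly 0.  Returned by model selection when no dependence model
#' beats the independence threshold.
#' @param x_range covariate domain covered by the (non-)fit.
#' @return object of classes `indep_cop` and `mixcop_gp`.
#' @export
indep_model <- function(x_range = c(0, 1)) {
  structure(list(components = list(bicop_spec("indep")),
                 latents = list(), x_range = as.numeric(x_range),
                 waic = 0, trace = numeric(0), aborted = FALSE),
            class = c("indep_cop", "mixcop_gp"))
}

#' Test whether a fitted model is the Independence copula
#' @param model a `mixcop_gp` object.
#' @return logical.
#' @export
is_indep <- function(model) inherits(model, "indep_cop")

## ---- mixture likelihood core ----------------------------------------------
##
## All Monte-Carlo draws are flattened: every per-latent f is a vector of
## length nd = n * draws, and the per-latent d log p / d f gradients come
## from the analytic family derivatives in comp_lpdf_grad().

## stick weights (nd x M) and t-variables from the stick latent values
stick_forward <- function(fstick, M) {
  nd <- nrow(fstick)
  off <- stick_offsets(M)
  tmat <- stats::pnorm(sweep(fstick, 2, off, "+"))
  phi <- matrix(0, nd, M)
  carry <- rep(1, nd)
  for (j in seq_len(M - 1)) {
    phi[, j] <- (1 - tmat[, j]) * carry
    carry <- carry * tmat[, j]
  }
  phi[, M] <- carry
  list(phi = phi, tmat = tmat)
}

## Objective (total-scale ELBO + lengthscale log-prior) and gradients.
## ccaches: per-component transform caches at length nd; kcaches: per-latent
## kernel caches; eps_list: per-latent n x draws standard normals.
gpc_objective <- function(components, latents, kcaches, ccaches,
                          n, draws, eps_list, want_grads = TRUE,
                          xs = NULL, z = NULL, lam_fd = FALSE) {
  M <- length(components)
  L <- n_latents(M)
  nd <- n * draws
  mom <- vector("list", L)
  fl <- vector("list", L)
  for (l in seq_len(L)) {
    mom[[l]] <- moments_from_kcache(latents[[l]], kcaches[[l]])
    fl[[l]] <- rep(mom[[l]]$mu, draws) + rep(mom[[l]]$sigma, draws) * as.vector(eps_list[[l]])
  }
  cvals <- matrix(0, nd, M)
  dcdf <- if (want_grads) matrix(0, nd, M) else NULL
  for (j in seq_len(M)) {
    sp <- components[[j]]
    th <- gplink(sp, fl[[j]])
    if (want_grads) {
      lg <- comp_lpdf_grad(sp$family, ccaches[[j]], th)
      cvals[, j] <- exp(lg$lc)
      dcdf[, j] <- cvals[, j] * lg$dlc * gplink_deriv(sp, fl[[j]])
    } else {
      cvals[, j] <- exp(comp_lpdf(sp$family, ccaches[[j]], th))
    }
  }
  if (M > 1L) {
    fstick <- do.call(cbind, fl[M + seq_len(M - 1)])
    sf <- stick_forward(fstick, M)
    phi <- sf$phi
  } else {
    phi <- matrix(1, nd, 1)
  }
  p <- pmax(rowSums(phi * cvals), 1e-300)
  loglik <- sum(log(p)) / draws
  kl <- 0
  lprior <- 0
  for (l in seq_len(L)) {
    lat <- latents[[l]]; S <- exp(lat$logS)
    kl <- kl + 0.5 * (sum(lat$m^2) + sum(S) - length(S) - sum(lat$logS))
    lam <- exp(lat$loglam)
    lprior <- lprior - 0.5 * (lam - 0.5)^2   # lengthscale ~ N(0.5, 1) on unit scale
  }
  out <- list(elbo = loglik - kl + lprior, loglik = loglik, kl = kl, mom = mom)
  if (!want_grads) return(out)

  ## d log p / d f per latent (length nd)
  gl <- vector("list", L)
  for (j in seq_len(M)) gl[[j]] <- phi[, j] * dcdf[, j] / p
  if (M > 1L) {
    off <- stick_offsets(M)
    pc <- phi * cvals
    ## cumulative products prod_{k<m} t_k
    carry <- rep(1, nd)
    tailmat <- matrix(0, nd, M + 1)        # tailmat[, m] = sum_{j>=m} phi_j c_j
    for (j in M:1) tailmat[, j] <- tailmat[, j + 1] + pc[, j]
    for (m in seq_len(M - 1)) {
      d_m <- stats::dnorm(fstick[, m] + off[m])
      gl[[M + m]] <- d_m * (tailmat[, m + 1] / pmax(sf$tmat[, m], 1e-12) -
                              carry * cvals[, m]) / p
      carry <- carry * sf$tmat[, m]
    }
  }
  grads <- vector("list", L)
  for (l in seq_len(L)) {
    lat <- latents[[l]]; mo <- mom[[l]]; kc <- kcaches[[l]]
    s_out <- exp(lat$logs); S <- exp(lat$logS)
    gmat <- matrix(gl[[l]], n, draws)
    gbar <- rowSums(gmat) / draws
    geps <- rowSums(gmat * eps_list[[l]]) / draws
    g_m <- s_out * drop(kc$Bt %*% gbar) - lat$m
    g_logS <- s_out^2 * drop(kc$bt2 %*% (geps / mo$sigma)) * S / 2 - 0.5 * (S - 1)
    g_mu0 <- sum(gbar)
    g_logs <- sum(gbar * (mo$mu - lat$mu0)) + sum(geps * mo$sigma)
    g_loglam <- NA_real_
    if (lam_fd) {
      h <- 1e-4
      kp <- latent_kcache(lat$loglam + h, xs, z)
      km <- latent_kcache(lat$loglam - h, xs, z)
      mp <- moments_from_kcache(lat, kp)
      mm <- moments_from_kcache(lat, km)
      lam <- exp(lat$loglam)
      g_loglam <- sum(gbar * (mp$mu - mm$mu) / (2 * h)) +
        sum(geps * (mp$sigma - mm$sigma) / (2 * h)) - (lam - 0.5) * lam
    }
    grads[[l]] <- list(m = g_m, logS = g_logS, mu0 = g_mu0,
                       logs = g_logs, loglam = g_loglam)
  }
  out$grads <- grads
  out
}

adam_new <- function(latents) {
  lapply(latents, function(lat) list(
    m1 = lapply(lat, function(p) p * 0),
    m2 = lapply(lat, function(p) p * 0),
    t_lam = 0L
  ))
}

## one Adam update; loglam is updated only when its gradient was computed
adam_step <- function(latents, grads, state, step, config) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (l in seq_along(latents)) {
    for (nm in names(latents[[l]])) {
      g <- grads[[l]][[nm]]
      if (nm == "loglam") {
        if (is.na(g)) next
        state[[l]]$t_lam <- state[[l]]$t_lam + 1L
        tt <- state[[l]]$t_lam
      } else tt <- step
      g <- -g   # descend on loss = -ELBO
      lr <- if (nm %in% c("m", "logS")) config$var_lr else config$base_lr
      state[[l]]$m1[[nm]] <- b1 * state[[l]]$m1[[nm]] + (1 - b1) * g
      state[[l]]$m2[[nm]] <- b2 * state[[l]]$m2[[nm]] + (1 - b2) * g^2
      mhat <- state[[l]]$m1[[nm]] / (1 - b1^tt)
      vhat <- state[[l]]$m2[[nm]] / (1 - b2^tt)
      latents[[l]][[nm]] <- latents[[l]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
    ## box constraints keep latent draws (and so copula parameters) in the
    ## numerically safe range of the family densities
    latents[[l]]$logs <- min(max(latents[[l]]$logs, -4), 2.5)
    latents[[l]]$loglam <- min(max(latents[[l]]$loglam, log(0.03)), log(3))
    latents[[l]]$mu0 <- min(max(latents[[l]]$mu0, -20), 20)
    latents[[l]]$logS <- pmin(latents[[l]]$logS, 3)
  }
  list(latents = latents, state = state)
}

## ---- fitting ---------------------------------------------------------------

#' Fit a conditional copula mixture with GP-varying parameters
#'
#' Fits the model \eqn{c(u | x) = \sum_j \phi_j(x) c_j(u; \theta_j(x))} by
#' stochastic variational inference.  Each copula parameter (through its
#' fixed link function) and each stick-breaking weight variable is an
#' independent latent GP of the standardized covariate.  Optimization uses
#' Adam with separate learning rates for GP hyper-parameters and variational
#' parameters, monitors the 50-step-averaged loss, evaluates WAIC once the
#' loss change falls below `check_waic` (aborting if the model is no better
#' than Independence), and stops when the change falls below `loss_tol`.
#'
#' @param components a [bicop_spec()] or list of them (the mixture elements).
#' @param x covariate vector.
#' @param u two-column matrix of pseudo-observations in (0,1).
#' @param config a [gpc_config()].
#' @param seed integer seed; on numerical divergence the fit restarts once
#'   with `seed + 1`.
#' @param max_steps optional override of `config$max_steps`.
#' @return object of class `mixcop_gp` with elements `components`, `latents`,
#'   `x_range`, `trace` (per-step loss), `waic`, `aborted`.
#' @export
fit_gpcop <- function(components, x, u, config = gpc_config(), seed = 1,
                      max_steps = NULL) {
  if (inherits(components, "bicop_spec")) components <- list(components)
  if (length(components) == 1L && is_indep_spec(components[[1]])) {
    return(indep_model(range(x)))
  }
  if (!is.null(max_steps)) config$max_steps <- max_steps
  res <- NULL
  for (attempt in 0:1) {
    res <- try(fit_gpcop_once(components, x, u, config, seed + attempt),
               silent = TRUE)
    if (!inherits(res, "try-error") && is.finite(res$waic)) return(res)
  }
  stop("copula-GP fit diverged twice: ", attr(res, "condition")$message)
}

fit_gpcop_once <- function(components, x, u, config, seed) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  u <- clamp_unit(as_u_matrix(u))
  n <- nrow(u)
  x_range <- range(x)
  xs <- standardize_x(x, x_range)
  z <- seq(0, 1, length.out = config$grid_size)
  M <- length(components)
  L <- n_latents(M)
  draws <- config$mc_draws
  latents <- replicate(L, new_latent(config$grid_size), simplify = FALSE)
  ## moment-matched start: set each theta-latent mean so the implied
  ## Kendall tau matches the empirical tau (inference-for-margins style
  ## initialization); stick latents start at zero (equal weights)
  tau_emp <- emp_tau(u)
  for (j in seq_len(M)) {
    latents[[j]]$mu0 <- tau_init_f(components[[j]], tau_emp)
    latents[[j]]$logS <- rep(-1, config$grid_size)
  }
  state <- adam_new(latents)
  ccaches <- lapply(components, function(sp)
    rep_cache(comp_cache(sp, u[, 1], u[, 2]), draws))
  kcaches <- vector("list", L)
  cur_loglam <- rep(NA_real_, L)
  loss_hist <- numeric(0)
  waic_checked <- FALSE
  aborted <- FALSE
  for (step in seq_len(config$max_steps)) {
    lam_fd <- (step %% config$lam_every == 1L) || config$lam_every == 1L
    for (l in seq_len(L)) {
      if (!identical(cur_loglam[l], latents[[l]]$loglam)) {
        kcaches[[l]] <- latent_kcache(latents[[l]]$loglam, xs, z)
        cur_loglam[l] <- latents[[l]]$loglam
      }
    }
    eps_list <- replicate(L, matrix(stats::rnorm(n * draws), n), simplify = FALSE)
    eg <- gpc_objective(components, latents, kcaches, ccaches, n, draws,
                        eps_list, want_grads = TRUE, xs = xs, z = z,
                        lam_fd = lam_fd)
    if (!is.finite(eg$elbo)) stop("non-finite loss at step ", step)
    loss_hist[step] <- -eg$elbo / n
    upd <- adam_step(latents, eg$grads, state, step, config)
    latents <- upd$latents; state <- upd$state
    if (step >= 100 && step %% 50 == 0) {
      dloss <- mean(loss_hist[(step - 99):(step - 50)]) -
               mean(loss_hist[(step - 49):step])
      if (!waic_checked && dloss < config$check_waic) {
        waic_checked <- TRUE
        mdl <- build_model(components, latents, x_range, config,
                           loss_hist, waic = NA, aborted = FALSE)
        w <- waic(mdl, x, u, S = config$waic_draws, seed = seed + 1000L)
        if (w$waic > -config$waic_tol) { aborted <- TRUE; break }
      }
      if (waic_checked && dloss < config$loss_tol) break
    }
  }
  mdl <- build_model(components, latents, x_range, config, loss_hist,
                     waic = NA, aborted = aborted)
  w <- waic(mdl, x, u, S = config$waic_draws, seed = seed + 2000L)
  mdl$waic <- w$waic
  mdl$waic_detail <- w
  mdl
}

build_model <- function(components, latents, x_range, config, trace,
                        waic, aborted) {
  structure(list(components = components, latents = latents,
                 x_range = as.numeric(x_range), config = config,
                 trace = trace, waic = waic, aborted = aborted),
            class = "mixcop_gp")
}

#' @export
print.mixcop_gp <- function(x, ...) {
  if (is_indep(x)) {
    cat("<mixcop_gp> Independence copula (WAIC = 0)\n")
    return(invisible(x))
  }
  fams <- vapply(x$components, format, "")
  cat("<mixcop_gp> mixture:", paste(fams, collapse = " + "),
      sprintf("| WAIC = %.4f%s\n", x$waic,
              if (isTRUE(x$aborted)) " (aborted: not better than independence)" else ""))
  invisible(x)
}

## ---- model evaluation ------------------------------------------------------

model_grid <- function(model) {
  seq(0, 1, length.out = length(model$latents[[1]]$m))
}

## Per-point mixture parameters. fdraw = NULL -> posterior mean functions.
## Returns list(theta n x M, phi n x M, f n x L).
model_params_at <- function(model, x, fdraw = NULL) {
  M <- length(model$components)
  if (is_indep(model)) {
    n <- length(x)
    return(list(theta = matrix(0, n, 1), phi = matrix(1, n, 1)))
  }
  ## constant-x fast path: evaluate the latents once and broadcast
  const_x <- length(x) > 1 && is.null(fdraw) && all(x == x[1])
  xs <- standardize_x(if (const_x) x[1] else x, model$x_range)
  z <- model_grid(model)
  L <- n_latents(M)
  fmat <- matrix(0, length(xs), L)
  for (l in seq_len(L)) {
    fmat[, l] <- if (is.null(fdraw)) {
      latent_moments(model$latents[[l]], xs, z)$mu
    } else fdraw[[l]]
  }
  if (const_x) fmat <- matrix(fmat, length(x), L, byrow = TRUE)
  theta <- matrix(0, length(x), M)
  for (j in seq_len(M)) theta[, j] <- gplink(model$components[[j]], fmat[, j])
  phi <- if (M == 1L) matrix(1, length(x), 1) else
    stick_break(fmat[, M + seq_len(M - 1), drop = FALSE])
  if (!is.matrix(phi)) phi <- matrix(phi, nrow = length(x))
  list(theta = theta, phi = phi, f = fmat)
}

## S correlated functional posterior draws of all latents, drawn jointly on
## a grid over the covariate domain and returned as interpolating functions:
## each element is a function(x) giving the per-latent f values at x,
## usable as `fdraw` in model_params_at.
gpcop_fdraw_funs <- function(model, S, seed = NULL, grid_n = 101) {
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  if (is_indep(model)) {
    return(replicate(S, function(x) NULL, simplify = FALSE))
  }
  xg <- seq(model$x_range[1], model$x_range[2], length.out = grid_n)
  if (diff(model$x_range) <= 0) xg <- rep(model$x_range[1], grid_n)
  xs <- standardize_x(xg, model$x_range)
  z <- model_grid(model)
  per_latent <- lapply(model$latents, latent_fdraws, xs = xs, z = z, S_draws = S)
  lapply(seq_len(S), function(s) {
    fs <- lapply(per_latent, function(D) D[s, ])
    function(x) lapply(fs, function(v) {
      if (diff(model$x_range) <= 0) return(rep(v[1], length(x)))
      stats::approx(xg, v, xout = pmin(pmax(x, xg[1]), xg[grid_n]))$y
    })
  })
}

#' Conditional mixture density and log-density of a fitted model
#'
#' Evaluates \eqn{c(u | x)} at per-sample covariate values using either the
#' posterior-mean latent functions (default) or a supplied parameter set.
#'
#' @param model a fitted [fit_gpcop()] model.
#' @param x covariate vector (length n).
#' @param u `n x 2` matrix of unit-square points.
#' @param params optional precomputed parameter set (internal use).
#' @return density (or log-density) vector of length n.
#' @export
gpcop_pdf <- function(model, x, u, params = NULL) exp(gpcop_logpdf(model, x, u, params))

#' @rdname gpcop_pdf
#' @export
gpcop_logpdf <- function(model, x, u, params = NULL) {
  u <- clamp_unit(as_u_matrix(u))
  if (is_indep(model)) return(numeric(nrow(u)))
  if (is.null(params)) params <- model_params_at(model, x)
  M <- length(model$components)
  dens <- numeric(nrow(u))
  for (j in seq_len(M)) {
    dens <- dens + params$phi[, j] *
      exp(bicop_lpdf_v(model$components[[j]], params$theta[, j], u[, 1], u[, 2]))
  }
  log(pmax(dens, 1e-300))
}

## theta-vectorized h-function (conditional cdf of u2 given u1)
bicop_hfun_v <- function(spec, theta, u1, u2) {
  rot <- spec$rotation
  hv <- function(a1, a2) {
    switch(spec$family,
      indep = a2,
      gauss = {
        r <- pmin(pmax(theta, -1 + 1e-7), 1 - 1e-7)
        stats::pnorm((stats::qnorm(a2) - r * stats::qnorm(a1)) / sqrt(1 - r^2))
      },
      frank = {
        th <- ifelse(abs(theta) < 1e-5, sign(theta + 1e-300) * 1e-5, theta)
        a <- exp(-th * a1); b <- expm1(-th * a2)
        a * b / (expm1(-th) + expm1(-th * a1) * b)
      },
      clayton = {
        th <- pmax(theta, 1e-10)
        s <- a1^(-th) + a2^(-th) - 1
        a1^(-th - 1) * s^(-(th + 1) / th)
      },
      gumbel = {
        th <- pmax(theta, 1)
        xx <- -log(a1); yy <- -log(a2)
        s <- xx^th + yy^th
        exp(-s^(1 / th)) * s^(1 / th - 1) * xx^(th - 1) / a1
      }
    )
  }
  out <- if (rot == 0L) hv(u1, u2)
    else if (rot == 90L) hv(1 - u1, u2)
    else if (rot == 180L) 1 - hv(1 - u1, 1 - u2)
    else 1 - hv(u1, 1 - u2)
  pmin(pmax(out, 0), 1)
}

## theta-vectorized inverse h-function
bicop_ppcf_v <- function(spec, theta, u1, q) {
  u1 <- clamp_unit(u1); q <- clamp_unit(q)
  rot <- spec$rotation
  inv0 <- function(a1, qq) {
    switch(spec$family,
      indep = qq,
      gauss = {
        r <- pmin(pmax(theta, -1 + 1e-7), 1 - 1e-7)
        stats::pnorm(r * stats::qnorm(a1) + sqrt(1 - r^2) * stats::qnorm(qq))
      },
      frank = {
        th <- ifelse(abs(theta) < 1e-5, sign(theta + 1e-300) * 1e-5, theta)
        a <- exp(-th * a1)
        w <- qq * expm1(-th) / (a - qq * (a - 1))
        pmin(pmax(-log1p(w) / th, 1e-12), 1 - 1e-12)
      },
      clayton = {
        th <- pmax(theta, 1e-10)
        v <- (qq^(-th / (th + 1)) - 1) * a1^(-th) + 1
        pmax(v, 1e-300)^(-1 / th)
      },
      gumbel = bisect_h(function(v) bicop_hfun_v(bicop_spec("gumbel"), theta, a1, v), qq)
    )
  }
  out <- if (rot == 0L) inv0(u1, q)
    else if (rot == 90L) inv0(1 - u1, q)
    else if (rot == 180L) 1 - inv0(1 - u1, 1 - q)
    else 1 - inv0(u1, 1 - q)
  pmin(pmax(out, 1e-12), 1 - 1e-12)
}

## mixture h-function / inverse with per-point parameters
gpcop_hfun_at <- function(model, params, u1, u2) {
  if (is_indep(model)) return(u2)
  M <- length(model$components)
  out <- numeric(length(u1))
  for (j in seq_len(M)) {
    out <- out + params$phi[, j] *
      bicop_hfun_v(model$components[[j]], params$theta[, j], u1, u2)
  }
  pmin(pmax(out, 0), 1)
}

gpcop_ppcf_at <- function(model, params, u1, q) {
  if (is_indep(model)) return(q)
  if (length(model$components) == 1L) {
    return(bicop_ppcf_v(model$components[[1]], params$theta[, 1], u1, q))
  }
  bisect_h(function(v) gpcop_hfun_at(model, params, u1, v), clamp_unit(q))
}

#' Sample pseudo-observations from a fitted conditional copula
#'
#' Draws one `(u1, u2)` pair for every covariate value in `x` using the
#' posterior-mean parameter functions (or a supplied parameter set).
#'
#' @inheritParams gpcop_pdf
#' @param seed optional seed.
#' @return an `n x 2` matrix.
#' @export
gpcop_sample <- function(model, x, seed = NULL, params = NULL) {
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  n <- length(x)
  u1 <- stats::runif(n); q <- stats::runif(n)
  if (is_indep(model)) return(cbind(u1, q))
  if (is.null(params)) params <- model_params_at(model, x)
  M <- length(model$components)
  comp <- if (M == 1L) rep(1L, n) else {
    cum <- params$phi
    for (j in 2:M) cum[, j] <- cum[, j - 1] + cum[, j]
    1L + rowSums(stats::runif(n) > cum)
  }
  comp <- pmin(pmax(comp, 1L), M)
  u2 <- numeric(n)
  for (j in unique(comp)) {
    idx <- which(comp == j)
    u2[idx] <- bicop_ppcf_v(model$components[[j]],
                            params$theta[idx, j], u1[idx], q[idx])
  }
  cbind(u1, u2)
}

#' Evidence lower bound of a fitted (or initial) model on a batch
#'
#' Returns the per-sample negative ELBO (`loss`) along with its expected
#' log-likelihood and KL components; the expectation over latent functions
#' is taken by Monte Carlo.
#'
#' @inheritParams gpcop_pdf
#' @param draws Monte-Carlo draws.
#' @param seed optional seed.
#' @return list with `loss` (per sample), `elbo`, `loglik`, `kl` (totals).
#' @export
elbo <- function(model, x, u, draws = 10, seed = NULL) {
  u <- clamp_unit(as_u_matrix(u))
  if (is_indep(model)) {
    return(list(loss = 0, elbo = 0, loglik = 0, kl = 0))
  }
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  xs <- standardize_x(x, model$x_range)
  z <- model_grid(model)
  L <- length(model$latents)
  n <- nrow(u)
  ccaches <- lapply(model$components, function(sp)
    rep_cache(comp_cache(sp, u[, 1], u[, 2]), draws))
  kcaches <- lapply(model$latents, function(lat) latent_kcache(lat$loglam, xs, z))
  eps_list <- replicate(L, matrix(stats::rnorm(n * draws), n), simplify = FALSE)
  eg <- gpc_objective(model$components, model$latents, kcaches, ccaches,
                      n, draws, eps_list, want_grads = FALSE)
  list(loss = -eg$elbo / n, elbo = eg$elbo, loglik = eg$loglik, kl = eg$kl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predicted copula parameters along the covariate
#'
#' Evaluates the posterior-mean parameter trajectories \eqn{\theta_j(x)} and
#' mixing weights \eqn{\phi_j(x)} of a fitted model, with 95% credible
#' bands obtained by pushing the latent mean plus/minus two posterior
#' standard deviations through the link functions.
#'
#' @param model a fitted [fit_gpcop()] model.
#' @param x covariate values at which to predict (values outside the
#'   training domain trigger a warning).
#' @return a tibble with one row per (x, component): columns `x`,
#'   `component`, `theta`, `theta_lo`, `theta_hi`, `phi`, `tau`.
#' @export
predict_params <- function(model, x) {
  if (is_indep(model)) {
    return(tibble::tibble(x = x, component = "indep", theta = 0,
                          theta_lo = 0, theta_hi = 0, phi = 1, tau = 0))
  }
  if (any(x < model$x_range[1] - 1e-9 | x > model$x_range[2] + 1e-9)) {
    warning("x outside the training domain: GP predictions are extrapolations")
  }
  xs <- standardize_x(x, model$x_range)
  z <- model_grid(model)
  M <- length(model$components)
  pars <- model_params_at(model, x)
  rows <- lapply(seq_len(M), function(j) {
    mo <- latent_moments(model$latents[[j]], xs, z)
    sp <- model$components[[j]]
    lo <- gplink(sp, mo$mu - 2 * mo$sigma)
    hi <- gplink(sp, mo$mu + 2 * mo$sigma)
    tibble::tibble(x = x, component = format(sp),
                   theta = pars$theta[, j],
                   theta_lo = pmin(lo, hi), theta_hi = pmax(lo, hi),
                   phi = pars$phi[, j],
                   tau = vapply(pars$theta[, j], function(t) bicop_tau(sp, t), 0))
  })
  dplyr::bind_rows(rows)
}

## ---- WAIC -------------------------------------------------------------------

#' Watanabe-Akaike information criterion of a fitted conditional copula
#'
#' Computes the pointwise log posterior predictive density over `S`
#' posterior draws of the latent functions,
#' \eqn{lppd = \sum_i \log(S^{-1} \sum_s p(u_i | \theta^s))}, the effective
#' parameter count \eqn{p_{WAIC} = \sum_i Var_s \log p(u_i|\theta^s)}, and
#' reports `waic = -(lppd - p_waic)/n`.  Zero corresponds to the
#' Independence model; negative values beat it.
#'
#' @inheritParams gpcop_pdf
#' @param S posterior draws (at least 2).
#' @param seed optional seed.
#' @return list of class `waic_result`: `waic`, `lppd`, `p_waic`, `S`.
#' @export
waic <- function(model, x, u, S = 100, seed = NULL) {
  if (S < 2) stop("S must be at least 2 (a variance over draws is required)")
  u <- clamp_unit(as_u_matrix(u))
  n <- nrow(u)
  if (is_indep(model)) {
    return(structure(list(waic = 0, lppd = 0, p_waic = 0, S = S),
                     class = "waic_result"))
  }
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  xs <- standardize_x(x, model$x_range)
  z <- model_grid(model)
  M <- length(model$components)
  L <- n_latents(M)
  mom <- lapply(model$latents, latent_moments, xs = xs, z = z)
  ccaches <- lapply(model$components, function(sp) comp_cache(sp, u[, 1], u[, 2]))
  lp <- matrix(0, n, S)
  for (s in seq_len(S)) {
    f <- matrix(0, n, L)
    for (l in seq_len(L)) f[, l] <- mom[[l]]$mu + mom[[l]]$sigma * stats::rnorm(n)
    cvals <- matrix(0, n, M)
    for (j in seq_len(M)) {
      sp <- model$components[[j]]
      cvals[, j] <- exp(comp_lpdf(sp$family, ccaches[[j]], gplink(sp, f[, j])))
    }
    phi <- if (M == 1L) matrix(1, n, 1) else
      stick_forward(f[, M + seq_len(M - 1), drop = FALSE], M)$phi
    lp[, s] <- log(pmax(rowSums(phi * cvals), 1e-300))
  }
  mx <- apply(lp, 1, max)
  lppd <- sum(mx + log(rowMeans(exp(lp - mx))))
  p_waic <- sum(apply(lp, 1, stats::var))
  structure(list(waic = -(lppd - p_waic) / n, lppd = lppd, p_waic = p_waic,
                 S = S),
            class = "waic_result")
}

#' @export
print.waic_result <- function(x, ...) {
  cat(sprintf("WAIC = %.5f  (lppd = %.2f, p_waic = %.2f, S = %d)\n",
              x$waic, x$lppd, x$p_waic, x$S))
  invisible(x)
}
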