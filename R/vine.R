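#' Canonical vine construction for conditional copulas
#'
#' A C-vine factorizes an m-dimensional copula into m(m-1)/2 bivariate
#' copulas arranged in trees: tree 1 pairs a root variable with every other
#' variable, and each deeper tree works on h-function-transformed
#' pseudo-observations from the tree below.  Every edge here is a
#' conditional copula mixture (fitted by WAIC model selection), and the
#' simplifying assumption is made throughout: an edge copula depends on the
#' conditioning covariate x, but on its u-conditioners only through the
#' transformed arguments.
#'
#' @name cvine
NULL

#' Order variables for a C-vine by total absolute Kendall correlation
#'
#' Variables are sorted by the descending sum of absolute pairwise Kendall
#' tau with all other variables, so the most globally dependent variable
#' roots the first tree.  Ties keep the original column order.  For speed
#' the tau matrix is estimated on a subsample of at most `max_n` rows.
#'
#' @param U unit-cube matrix (n x m).
#' @param max_n subsample cap for the pairwise tau estimates.
#' @return integer permutation of `1:m`.
#' @export
order_variables <- function(U, max_n = 2000) {
  U <- as.matrix(U)
  m <- ncol(U)
  if (m < 2) stop("need at least 2 variables")
  idx <- if (nrow(U) > max_n) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(1L)
    sample.int(nrow(U), max_n)
  } else seq_len(nrow(U))
  tau <- stats::cor(U[idx, , drop = FALSE], method = "kendall")
  score <- rowSums(abs(tau)) - 1   # drop the diagonal
  order(score, decreasing = TRUE)  # stable: ties keep column order
}

#' Fit a conditional C-vine copula
#'
#' Fits tree by tree: each tree-1 edge pairs the root with another variable;
#' pseudo-observations for tree t+1 are conditional CDF (h-function)
#' transforms through the fitted tree-t edges.  Each edge model is chosen by
#' [select_heuristic()] (default) or [select_greedy()]; edges whose best
#' model is no better than Independence are stored as Independence markers
#' carrying no GP state.  An edge fit failure demotes the edge to
#' Independence with a warning.
#'
#' @param x covariate vector.
#' @param U unit-cube pseudo-observation matrix (n x m), e.g. from
#'   [fit_margins()].
#' @param config a [gpc_config()].
#' @param seed integer seed.
#' @param method edge model selection: `"heuristic"`, `"greedy"`, or
#'   `"gauss"` (single Gaussian-copula edges with the independence screen;
#'   fast path for well-behaved elliptical data).
#' @param trunc_tree fit only the first `trunc_tree` trees, treating deeper
#'   edges as Independence (`Inf` = full vine).
#' @param order optional explicit variable order (permutation); default
#'   [order_variables()].
#' @return object of class `cvine`, with `order`, `edges` (list of trees,
#'   each a list of `mixcop_gp`), `x_range`, timing per edge.
#' @export
fit_cvine <- function(x, U, config = gpc_config(), seed = 1,
                      method = c("heuristic", "greedy", "gauss"),
                      trunc_tree = Inf, order = NULL) {
  method <- match.arg(method)
  U <- clamp_unit(as.matrix(U))
  m <- ncol(U)
  if (m < 2) stop("a vine needs at least 2 variables")
  ord <- if (is.null(order)) order_variables(U) else as.integer(order)
  V <- U[, ord, drop = FALSE]
  edges <- vector("list", m - 1)
  for (t in seq_len(m - 1)) {
    edges[[t]] <- vector("list", m - t)
    if (t > trunc_tree) {
      for (j in seq_len(m - t)) edges[[t]][[j]] <- indep_model(range(x))
      next
    }
    newV <- matrix(0, nrow(V), m - t)
    for (j in seq_len(m - t)) {
      upair <- cbind(V[, 1], V[, j + 1])
      eseed <- seed + 1000L * t + j
      mdl <- tryCatch(
        switch(method,
          heuristic = select_heuristic(x, upair, config, seed = eseed),
          greedy    = select_greedy(x, upair, config = config, seed = eseed),
          gauss     = {
            g <- fit_gpcop(bicop_spec("gauss"), x, upair, config, seed = eseed)
            if (g$waic > -config$waic_tol) indep_model(range(x)) else g
          }),
        error = function(e) {
          warning("edge (", t, ",", j, ") failed to fit (",
                  conditionMessage(e), "): demoted to Independence")
          indep_model(range(x))
        })
      edges[[t]][[j]] <- mdl
      ## pseudo-observations for the next tree
      pars <- if (is_indep(mdl)) NULL else model_params_at(mdl, x)
      newV[, j] <- if (is_indep(mdl)) V[, j + 1] else
        clamp_unit(gpcop_hfun_at(mdl, pars, V[, 1], V[, j + 1]))
    }
    V <- newV
  }
  structure(list(order = ord, edges = edges, x_range = range(x),
                 m = m, config = config),
            class = "cvine")
}

#' @export
print.cvine <- function(x, ...) {
  nI <- sum(vapply(unlist(x$edges, recursive = FALSE), Negate(is_indep), TRUE))
  cat(sprintf("<cvine> %d variables, %d pair copulas (%d non-independence)\n",
              x$m, x$m * (x$m - 1) / 2, nI))
  cat("order:", paste(x$order, collapse = " "), "\n")
  invisible(x)
}

#' Number of pair copulas in an m-dimensional regular vine
#' @param m number of variables.
#' @return `m (m - 1) / 2`.
#' @export
cvine_n_pairs <- function(m) m * (m - 1) / 2

#' Number of free parameters of a fitted vine
#'
#' Each M-component mixture edge contributes `max(0, 2M - 1)` parameter
#' functions; Independence edges contribute none.
#' @param vine a fitted [fit_cvine()] model.
#' @return integer.
#' @export
cvine_n_params <- function(vine) {
  sum(vapply(unlist(vine$edges, recursive = FALSE), function(e) {
    if (is_indep(e)) 0L else n_latents(length(e$components))
  }, 0L))
}

## per-edge log densities and the h-transform chain, shared by logpdf and
## entropy accounting; returns list(logpdf, per_edge tibble)
cvine_logpdf_detail <- function(vine, x, U, fdraws = NULL) {
  U <- clamp_unit(as.matrix(U))
  m <- vine$m
  V <- U[, vine$order, drop = FALSE]
  total <- numeric(nrow(U))
  rows <- list()
  for (t in seq_along(vine$edges)) {
    newV <- matrix(0, nrow(V), m - t)
    for (j in seq_along(vine$edges[[t]])) {
      e <- vine$edges[[t]][[j]]
      if (is_indep(e)) {
        newV[, j] <- V[, j + 1]
        rows[[length(rows) + 1]] <- tibble::tibble(
          tree = t, edge = j, mean_nlog2 = 0)
        next
      }
      fd <- if (is.null(fdraws)) NULL else fdraws[[edge_key(t, j)]]
      pars <- model_params_at(e, x, if (is.null(fd)) NULL else fd(x))
      lp <- gpcop_logpdf(e, x, cbind(V[, 1], V[, j + 1]), pars)
      total <- total + lp
      newV[, j] <- clamp_unit(gpcop_hfun_at(e, pars, V[, 1], V[, j + 1]))
      rows[[length(rows) + 1]] <- tibble::tibble(
        tree = t, edge = j, mean_nlog2 = -mean(lp) / log(2))
    }
    V <- newV
  }
  list(logpdf = total, per_edge = dplyr::bind_rows(rows))
}

edge_key <- function(t, j) paste0("t", t, "e", j)

#' Log density of a fitted C-vine
#'
#' Sum of the edge copula log densities at the h-transformed arguments;
#' Independence edges contribute zero.
#'
#' @param vine a fitted [fit_cvine()] model.
#' @param x covariate vector (length n).
#' @param U unit-cube matrix (n x m), columns in the original variable
#'   order.
#' @return per-sample log density vector.
#' @export
cvine_logpdf <- function(vine, x, U) {
  cvine_logpdf_detail(vine, x, U)$logpdf
}

#' Sample from a fitted C-vine at given covariate values
#'
#' Standard sequential C-vine sampling: uniform seeds are pushed through
#' the inverse h-function chain.  Independence edges are skipped (their
#' inverse is the identity).
#'
#' @param vine a fitted [fit_cvine()] model.
#' @param x covariate vector (one sample is drawn per element; values
#'   outside the training domain trigger a warning).
#' @param seed optional seed.
#' @param fdraws optional named list (by edge) of latent functional-draw
#'   interpolators (internal use, posterior sampling).
#' @return an `n x m` matrix of unit-cube samples in the original variable
#'   order.
#' @export
cvine_sample <- function(vine, x, seed = NULL, fdraws = NULL) {
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  if (any(x < vine$x_range[1] - 1e-9 | x > vine$x_range[2] + 1e-9)) {
    warning("x outside the training domain: sampling is an extrapolation")
  }
  n <- length(x)
  m <- vine$m
  W <- matrix(stats::runif(n * m), n, m)
  Usamp <- matrix(0, n, m)   # in vine order
  Usamp[, 1] <- W[, 1]
  pars_cache <- list()
  get_pars <- function(t, j) {
    key <- edge_key(t, j)
    if (is.null(pars_cache[[key]])) {
      e <- vine$edges[[t]][[j]]
      fd <- if (is.null(fdraws)) NULL else fdraws[[key]]
      pars_cache[[key]] <<- if (is_indep(e)) NULL else
        model_params_at(e, x, if (is.null(fd)) NULL else fd(x))
    }
    pars_cache[[key]]
  }
  ## Vdiag[, t] = F(u_t | u_1..u_{t-1}), the conditioned root of tree t
  Vdiag <- matrix(0, n, m)
  Vdiag[, 1] <- W[, 1]
  for (i in 2:m) {
    q <- W[, i]
    for (t in (i - 1):1) {
      e <- vine$edges[[t]][[i - t]]
      if (!is_indep(e)) {
        q <- gpcop_ppcf_at(e, get_pars(t, i - t), Vdiag[, t], q)
      }
    }
    Usamp[, i] <- q
    ## forward transforms needed as conditioners for later variables
    if (i < m) {
      v <- q
      for (t in seq_len(i - 1)) {
        e <- vine$edges[[t]][[i - t]]
        v <- if (is_indep(e)) v else
          clamp_unit(gpcop_hfun_at(e, get_pars(t, i - t), Vdiag[, t], v))
      }
      Vdiag[, i] <- v
    }
  }
  out <- matrix(0, n, m)
  out[, vine$order] <- Usamp
  out
}

#' Effective dimensionality of a fitted vine
#'
#' The smallest number of trees whose cumulative copula entropy reaches a
#' `coverage` fraction of the total vine copula entropy (entropies by Monte
#' Carlo over samples from the model itself, in bits).  An all-Independence
#' vine has zero entropy and effective dimension 0.
#'
#' @param vine a fitted [fit_cvine()] model.
#' @param x covariate values used for the Monte-Carlo average.
#' @param coverage entropy fraction in (0, 1), default 0.9.
#' @param n_mc Monte-Carlo sample count.
#' @param seed optional seed.
#' @return list with `trees` (the effective tree count), `per_tree` entropy
#'   (bits) and `total` (bits).
#' @export
effective_dim <- function(vine, x, coverage = 0.9, n_mc = 5000, seed = NULL) {
  stopifnot(coverage > 0, coverage < 1)
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  xmc <- sample(x, n_mc, replace = TRUE)
  Umc <- cvine_sample(vine, xmc)
  det <- cvine_logpdf_detail(vine, xmc, Umc)
  per_tree <- det$per_edge |>
    dplyr::group_by(.data$tree) |>
    dplyr::summarise(H = sum(.data$mean_nlog2), .groups = "drop")
  total <- sum(per_tree$H)
  if (abs(total) < 1e-12) {
    return(list(trees = 0L, per_tree = per_tree, total = 0))
  }
  cum <- cumsum(abs(per_tree$H))
  list(trees = min(which(cum >= coverage * abs(total))),
       per_tree = per_tree, total = total)
}

## One posterior functional draw per edge, as interpolating functions; a
## list of S named lists keyed by edge, usable as `fdraws` in
## cvine_logpdf_detail / cvine_sample.
cvine_fdraw_funs <- function(vine, S, seed = NULL, grid_n = 101) {
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  out <- replicate(S, list(), simplify = FALSE)
  for (t in seq_along(vine$edges)) {
    for (j in seq_along(vine$edges[[t]])) {
      e <- vine$edges[[t]][[j]]
      if (is_indep(e)) next
      funs <- gpcop_fdraw_funs(e, S, grid_n = grid_n)
      for (s in seq_len(S)) out[[s]][[edge_key(t, j)]] <- funs[[s]]
    }
  }
  out
}
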