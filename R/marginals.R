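#' Marginal models and the probability integral transform
#'
#' Copula modelling is done in two stages ("inference for margins"): each
#' variable is first mapped onto the unit interval through an estimate of its
#' (possibly covariate-conditional) marginal CDF, and the dependence model is
#' then fitted to the transformed pseudo-observations.  Two marginal
#' estimators are provided:
#'
#' * **unconditional empirical CDF** with the rank/(n+1) convention, which
#'   keeps all transformed values strictly inside (0,1);
#' * **conditional kernel CDF**: a Nadaraya-Watson weighted smoothed
#'   empirical CDF, \eqn{F(y|x) = \sum_i K_h(x - x_i)\Phi((y - y_i)/b) /
#'   \sum_i K_h(x - x_i)}, with Gaussian kernels and Silverman bandwidths on
#'   each axis.  It assumes the marginal varies smoothly with `x` and yields
#'   pseudo-observations that are uniform within every x-slice.
#'
#' With fewer than 200 samples the conditional estimator falls back to the
#' unconditional eCDF with a warning (kernel conditional estimates are too
#' noisy to be useful there).
#'
#' @param y numeric vector of observations (one variable).
#' @param x numeric covariate vector (conditional estimator only).
#' @return an object of class `marginal_model`.
#' @name marginals
NULL

#' @rdname marginals
#' @export
fit_unconditional_ecdf <- function(y) {
  y <- as.numeric(y)
  if (length(y) < 2) stop("need at least 2 observations")
  if (stats::sd(y) == 0) stop("degenerate marginal: column is constant")
  structure(list(kind = "ecdf", y_sorted = sort(y), n = length(y)),
            class = "marginal_model")
}

#' @rdname marginals
#' @export
fit_conditional_marginal <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) == length(y))
  if (stats::sd(y) == 0) stop("degenerate marginal: column is constant")
  if (length(y) < 200) {
    warning("fewer than 200 samples: falling back to the unconditional eCDF")
    return(fit_unconditional_ecdf(y))
  }
  n <- length(y)
  ## Repeated-trial designs: when the covariate takes few distinct values
  ## with many observations each (e.g. a fixed within-trial time grid),
  ## the conditional CDF is estimated exactly by the within-group
  ## empirical CDF, which makes the transform uniform in every x-slice by
  ## construction.
  ux <- sort(unique(x))
  if (length(ux) <= n / 30 && min(table(x)) >= 20) {
    groups <- lapply(ux, function(v) sort(y[x == v]))
    return(structure(list(kind = "grouped", x_levels = ux, groups = groups,
                          x_range = range(x), n = n),
                     class = "marginal_model"))
  }
  ## Conditional spread of y, estimated from first differences between
  ## x-neighbours (removes the smooth x-trend without fitting it).
  ord <- order(x)
  sd_resid <- max(stats::sd(diff(y[ord])) / sqrt(2), 1e-12)
  sd_y <- stats::sd(y)
  ## Silverman-type rates; the x-bandwidth shrinks when the trend dominates
  ## the conditional spread, so that F(y|x) is resolved on the scale over
  ## which it actually varies.
  hy <- 0.9 * sd_resid * n^(-1/5)
  hx <- 0.9 * stats::sd(x) * n^(-1/5) * min(1, sd_resid / sd_y)
  structure(list(kind = "ckde", x = x, y = y,
                 hx = max(hx, 1e-12), hy = max(hy, 1e-12),
                 x_range = range(x), n = n),
            class = "marginal_model")
}

#' Evaluate a marginal CDF
#'
#' @param model a `marginal_model`.
#' @param y values at which to evaluate.
#' @param x covariate values (required for conditional models; recycled if
#'   scalar).  Values outside the training domain trigger an extrapolation
#'   warning.
#' @return CDF values clamped strictly inside (0,1).
#' @export
marginal_cdf <- function(model, y, x = NULL) {
  if (model$kind == "ecdf") {
    ## rank/(n+1) convention: r = #{y_i <= y}
    r <- findInterval(y, model$y_sorted)
    return(clamp_unit(r / (model$n + 1)))
  }
  if (is.null(x)) stop("conditional marginal model requires x")
  if (length(x) == 1L) x <- rep(x, length(y))
  if (any(x < model$x_range[1] - 1e-9 | x > model$x_range[2] + 1e-9)) {
    warning("x outside the training domain: extrapolating the conditional marginal")
  }
  if (model$kind == "grouped") {
    gi <- pmin(pmax(findInterval(x, model$x_levels +
                                   c(diff(model$x_levels) / 2, Inf)) + 1L,
                    1L), length(model$x_levels))
    out <- numeric(length(y))
    for (g in unique(gi)) {
      idx <- gi == g
      yg <- model$groups[[g]]
      out[idx] <- findInterval(y[idx], yg) / (length(yg) + 1)
    }
    return(clamp_unit(out))
  }
  out <- numeric(length(y))
  chunk <- max(1L, floor(2e6 / model$n))
  for (s in seq(1, length(y), by = chunk)) {
    idx <- s:min(s + chunk - 1, length(y))
    W <- exp(-0.5 * (outer(x[idx], model$x, "-") / model$hx)^2)
    P <- stats::pnorm(outer(y[idx], model$y, "-") / model$hy)
    out[idx] <- rowSums(W * P) / rowSums(W)
  }
  clamp_unit(out)
}

#' Inverse marginal CDF (quantile transform)
#'
#' Inverts [marginal_cdf()] by monotone bisection on the observed data
#' range; used for mapping copula samples back to the data scale.
#' @inheritParams marginal_cdf
#' @param u probabilities in (0,1).
#' @return quantile values.
#' @export
marginal_quantile <- function(model, u, x = NULL) {
  if (model$kind == "ecdf") {
    q <- stats::quantile(model$y_sorted, probs = pmin(pmax(u, 0), 1),
                         names = FALSE, type = 8)
    return(q)
  }
  if (is.null(x)) stop("conditional marginal model requires x")
  if (length(x) == 1L) x <- rep(x, length(u))
  if (model$kind == "grouped") {
    gi <- pmin(pmax(findInterval(x, model$x_levels +
                                   c(diff(model$x_levels) / 2, Inf)) + 1L,
                    1L), length(model$x_levels))
    out <- numeric(length(u))
    for (g in unique(gi)) {
      idx <- gi == g
      out[idx] <- stats::quantile(model$groups[[g]], probs = u[idx],
                                  names = FALSE, type = 8)
    }
    return(out)
  }
  lo <- rep(min(model$y) - 4 * model$hy, length(u))
  hi <- rep(max(model$y) + 4 * model$hy, length(u))
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    v <- marginal_cdf(model, mid, x)
    up <- v < u
    lo[up] <- mid[up]; hi[!up] <- mid[!up]
  }
  (lo + hi) / 2
}

#' Probability integral transform of a data matrix
#'
#' Maps each column of `Y` through its marginal model onto the unit
#' hypercube.  With conditional marginal models, the transformed values are
#' uniform within every x-slice, which is what makes the downstream copula a
#' model of covariate-conditional ("noise") dependence rather than of shared
#' covariate tuning.
#'
#' @param x covariate vector (may be `NULL` if all models are unconditional).
#' @param Y numeric matrix (`n x m`).
#' @param models list of `m` marginal models (one per column).
#' @return an `n x m` matrix with entries strictly inside (0,1).
#' @export
pit <- function(x, Y, models) {
  Y <- as.matrix(Y)
  if (length(models) != ncol(Y)) {
    stop("need exactly one marginal model per column of Y")
  }
  U <- matrix(0, nrow(Y), ncol(Y), dimnames = dimnames(Y))
  for (j in seq_len(ncol(Y))) {
    U[, j] <- marginal_cdf(models[[j]], Y[, j], x)
  }
  U
}

#' Bundle a covariate and observation matrix into a conditioned dataset
#'
#' Accepts a data frame with an `x` column (all remaining numeric columns are
#' the observations) or an explicit pair `(x, Y)`.  Validates the invariants:
#' no missing values, at least two rows.
#'
#' @param data data frame with a column named `x`, or `NULL` when `x`/`Y`
#'   are given directly.
#' @param x,Y covariate vector and observation matrix (alternative
#'   interface).
#' @return object of class `cond_dataset` with elements `x`, `Y`, `domain`.
#' @export
cond_dataset <- function(data = NULL, x = NULL, Y = NULL) {
  if (!is.null(data)) {
    if (!"x" %in% names(data)) stop("data must contain a column named 'x'")
    x <- data[["x"]]
    Y <- as.matrix(data[setdiff(names(data), "x")])
  } else {
    Y <- as.matrix(Y)
  }
  x <- as.numeric(x)
  if (length(x) != nrow(Y)) stop("x and Y must have the same number of rows")
  if (length(x) < 2) stop("need at least 2 samples")
  bad <- which(!stats::complete.cases(cbind(x, Y)))
  if (length(bad)) {
    stop("missing values in rows: ", paste(utils::head(bad, 10), collapse = ", "))
  }
  structure(list(x = x, Y = Y, domain = range(x)), class = "cond_dataset")
}

#' Fit marginal models for every variable of a conditioned dataset
#'
#' @param dataset a [cond_dataset()].
#' @param conditional if `TRUE` (default) fit x-conditional kernel CDFs,
#'   otherwise unconditional eCDFs.
#' @return list with `models` (per-column marginal models) and `U` (the
#'   transformed unit-cube matrix).
#' @export
fit_margins <- function(dataset, conditional = TRUE) {
  stopifnot(inherits(dataset, "cond_dataset"))
  models <- lapply(seq_len(ncol(dataset$Y)), function(j) {
    if (conditional) fit_conditional_marginal(dataset$x, dataset$Y[, j])
    else fit_unconditional_ecdf(dataset$Y[, j])
  })
  list(models = models, U = pit(dataset$x, dataset$Y, models))
}
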