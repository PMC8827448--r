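#' Proportion of variance explained for a conditional bivariate copula
#'
#' Compares, within a covariate interval, the empirical conditional CDF
#' \eqn{ecdf(u_2 | u_1 \in I_i)} against the model conditional CDF
#' evaluated at the interval's covariate centre of mass, on the grid
#' \eqn{u_2 = 0.05 k, k = 0..20}, in 20 equal-width bins of \eqn{u_1}.
#' Per bin,
#' \eqn{R^2 = 1 - \sum (ecdf - ccdf)^2 / \sum (ecdf - \bar u_2)^2} with
#' \eqn{\bar u_2 = 0.5}; the report averages over bins.  The literal
#' per-point ratio form \eqn{1 - \sum ((ecdf - ccdf)/(ecdf - \bar u_2))^2}
#' is available behind `literal = TRUE` (it is unbounded below whenever a
#' grid point has \eqn{ecdf \approx 0.5}, so the variance-normalized form
#' is the default).
#'
#' @param model a fitted [fit_gpcop()] model.
#' @param x covariate vector for the samples.
#' @param u two-column matrix of pseudo-observations.
#' @param x_interval length-2 numeric: the covariate window to assess.
#' @param bins number of equal-width u1 bins.
#' @param literal use the per-point ratio form.
#' @return object of class `r2_report`: tibble of per-bin R2 plus
#'   attributes `r2_bar`, `x_mu`, `x_interval`.
#' @export
r2_interval <- function(model, x, u, x_interval, bins = 20, literal = FALSE) {
  u <- clamp_unit(as_u_matrix(u))
  sel <- x >= x_interval[1] & x <= x_interval[2]
  if (sum(sel) < 20) stop("need at least 20 samples in the x interval")
  u1 <- u[sel, 1]; u2 <- u[sel, 2]
  x_mu <- mean(x[sel])
  grid <- seq(0, 1, by = 0.05)
  edges <- seq(0, 1, length.out = bins + 1)
  bin <- pmin(pmax(findInterval(u1, edges, rightmost.closed = TRUE), 1), bins)
  pars <- model_params_at(model, rep(x_mu, length(grid)))
  rows <- list()
  for (i in seq_len(bins)) {
    idx <- bin == i
    if (!any(idx)) {
      warning("empty u1 bin ", i, " skipped")
      next
    }
    ec <- vapply(grid, function(g) mean(u2[idx] <= g), 0)
    cc <- gpcop_hfun_at(model, pars, rep(mean(u1[idx]), length(grid)), grid)
    r2 <- if (literal) {
      1 - sum(((ec - cc) / (ec - 0.5))^2)
    } else {
      1 - sum((ec - cc)^2) / sum((ec - 0.5)^2)
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      bin = i, u1_mid = mean(u1[idx]), n = sum(idx), r2 = r2)
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("r2_report", class(out)),
            r2_bar = mean(out$r2), x_mu = x_mu, x_interval = x_interval)
}

#' @export
print.r2_report <- function(x, ...) {
  cat(sprintf("R2 over %d u1 bins in x in [%.3g, %.3g] (x_mu = %.3g): mean R2 = %.4f\n",
              nrow(x), attr(x, "x_interval")[1], attr(x, "x_interval")[2],
              attr(x, "x_mu"), attr(x, "r2_bar")))
  NextMethod()
}

#' Mean proportion of variance explained
#' @param report an [r2_interval()] report.
#' @return scalar mean R2 over bins.
#' @export
r2_bar <- function(report) attr(report, "r2_bar")
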