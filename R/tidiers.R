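#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted conditional copula mixture
#'
#' One row per mixture component with its family, rotation, covariate-mean
#' parameter, Kendall tau and weight.
#' @param x a `mixcop_gp` model.
#' @param ... unused.
#' @return a tibble.
#' @method tidy mixcop_gp
#' @export
tidy.mixcop_gp <- function(x, ...) {
  if (is_indep(x)) {
    return(tibble::tibble(component = "indep", family = "indep",
                          rotation = 0L, theta = 0, tau = 0, phi = 1))
  }
  grid <- seq(x$x_range[1], x$x_range[2], length.out = 101)
  pars <- model_params_at(x, grid)
  tibble::tibble(
    component = vapply(x$components, format, ""),
    family = vapply(x$components, function(s) s$family, ""),
    rotation = vapply(x$components, function(s) s$rotation, 0L),
    theta = colMeans(pars$theta),
    tau = vapply(seq_along(x$components), function(j)
      bicop_tau(x$components[[j]], mean(pars$theta[, j])), 0),
    phi = colMeans(pars$phi)
  )
}

#' @rdname tidy.mixcop_gp
#' @method glance mixcop_gp
#' @export
glance.mixcop_gp <- function(x, ...) {
  tibble::tibble(
    M = if (is_indep(x)) 0L else length(x$components),
    n_latents = if (is_indep(x)) 0L else length(x$latents),
    waic = x$waic,
    aborted = isTRUE(x$aborted),
    steps = length(x$trace)
  )
}

#' Tidy a fitted C-vine
#'
#' One row per pair copula: tree, edge, the selected model (component
#' summary) and its WAIC.
#' @param x a `cvine` model.
#' @param ... unused.
#' @return a tibble.
#' @method tidy cvine
#' @export
tidy.cvine <- function(x, ...) {
  rows <- list()
  for (t in seq_along(x$edges)) {
    for (j in seq_along(x$edges[[t]])) {
      e <- x$edges[[t]][[j]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        tree = t, edge = j,
        model = if (is_indep(e)) "indep" else
          paste(vapply(e$components, format, ""), collapse = "+"),
        M = if (is_indep(e)) 0L else length(e$components),
        waic = e$waic)
    }
  }
  dplyr::bind_rows(rows)
}

#' @rdname tidy.cvine
#' @method glance cvine
#' @export
glance.cvine <- function(x, ...) {
  ed <- unlist(x$edges, recursive = FALSE)
  tibble::tibble(
    m = x$m,
    n_pairs = cvine_n_pairs(x$m),
    n_indep = sum(vapply(ed, is_indep, TRUE)),
    n_params = cvine_n_params(x)
  )
}

#' @rdname tidy.mixcop_gp
#' @method tidy waic_result
#' @export
tidy.waic_result <- function(x, ...) {
  tibble::tibble(waic = x$waic, lppd = x$lppd, p_waic = x$p_waic, S = x$S)
}

#' @rdname tidy.mixcop_gp
#' @method tidy info_estimate
#' @export
tidy.info_estimate <- function(x, ...) {
  tibble::tibble(method = x$method, value = x$value, ci_lo = x$ci_lo,
                 ci_hi = x$ci_hi, se = x$se, mc_tol = x$mc_tol,
                 n_mc = x$n_mc)
}

#' Plot the parameter trajectories of a conditional copula mixture
#'
#' Posterior-mean \eqn{\theta_j(x)} with 95% credible ribbons, one facet
#' per mixture component.
#' @param object a fitted `mixcop_gp`.
#' @param n_grid covariate grid resolution.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot mixcop_gp
#' @export
autoplot.mixcop_gp <- function(object, n_grid = 201, ...) {
  grid <- seq(object$x_range[1], object$x_range[2], length.out = n_grid)
  df <- predict_params(object, grid)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$theta)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$theta_lo,
                                      ymax = .data$theta_hi),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "covariate x", y = expression(theta(x)),
                  title = "Copula parameter trajectories (95% CI)")
}

#' Plot a conditional-entropy or information profile
#'
#' @param object a tibble from [conditional_copula_entropy()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_entropy_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$value)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                         fill = "firebrick", alpha = 0.25) +
    ggplot2::geom_line(color = "firebrick") +
    ggplot2::labs(x = "covariate x", y = "copula entropy (bits)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
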