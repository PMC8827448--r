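#' WAIC-guided construction of copula mixtures
#'
#' Two strategies pick a close-to-optimal mixture of copula elements for a
#' pair of variables conditioned on a covariate.
#'
#' **Greedy** forward selection fits every candidate single family, keeps
#' the best by WAIC, then repeatedly tries adding each unused element to the
#' current mixture, keeping the addition with the largest WAIC decrease,
#' stopping when the best decrease falls below `waic_tol` or five components
#' are reached.  If no model beats `-waic_tol` the Independence model is
#' returned.
#'
#' **Heuristic** selection first runs a short-budget independence screen (a
#' Gaussian-copula fit with a capped step budget); if that fit is no better
#' than Independence the pair is declared independent immediately.
#' Otherwise candidates are ranked by cheap empirical diagnostics - excess
#' mass in the four 0.1 x 0.1 corner squares relative to the independence
#' expectation ranks the Clayton/Gumbel rotations (each rotation
#' concentrates its tail in one corner), and the magnitude of Kendall's tau
#' ranks the radially symmetric Gaussian/Frank elements - and greedy
#' selection is run over the top of that ordered short-list.  The ranking is
#' tuned to these specific ten elements, trading generality for speed.
#'
#' @param x covariate vector.
#' @param u two-column matrix of pseudo-observations.
#' @param candidates list of [bicop_spec()] candidates (default: the ten
#'   standard elements).
#' @param config a [gpc_config()].
#' @param seed integer seed.
#' @param shortlist_k number of top-ranked candidates the heuristic keeps.
#' @return a fitted [fit_gpcop()] model (possibly [indep_model()]), with a
#'   `history` attribute recording every (model, WAIC) pair tried.
#' @export
select_greedy <- function(x, u, candidates = default_candidates(),
                          config = gpc_config(), seed = 1) {
  stopifnot(length(candidates) >= 1)
  u <- clamp_unit(as_u_matrix(u))
  history <- list()
  log_entry <- function(specs, waic) {
    history[[length(history) + 1]] <<-
      tibble::tibble(model = paste(vapply(specs, format, ""), collapse = "+"),
                     M = length(specs), waic = waic)
  }
  fits <- vector("list", length(candidates))
  for (k in seq_along(candidates)) {
    fits[[k]] <- fit_gpcop(candidates[[k]], x, u, config, seed = seed + k)
    log_entry(list(candidates[[k]]), fits[[k]]$waic)
  }
  waics <- vapply(fits, function(m) m$waic, 0)
  best_k <- which.min(waics)
  best <- fits[[best_k]]
  if (best$waic > -config$waic_tol) {
    out <- indep_model(range(x))
    attr(out, "history") <- dplyr::bind_rows(history)
    return(out)
  }
  used <- format(candidates[[best_k]])
  repeat {
    if (length(best$components) >= 5L) break
    pool <- candidates[!vapply(candidates, format, "") %in% used]
    if (!length(pool)) break
    trial_best <- NULL
    for (k in seq_along(pool)) {
      specs <- c(best$components, list(pool[[k]]))
      m <- fit_gpcop(specs, x, u, config, seed = seed + 100L + k)
      log_entry(specs, m$waic)
      if (is.null(trial_best) || m$waic < trial_best$waic) trial_best <- m
    }
    if (is.null(trial_best) || best$waic - trial_best$waic < config$waic_tol) break
    best <- trial_best
    used <- vapply(best$components, format, "")
  }
  best <- prune_mixture(best, x, u, config, seed)
  attr(best, "history") <- dplyr::bind_rows(history)
  best
}

## Drop mixture components whose posterior-mean weight stays below 1e-4
## over the whole covariate domain, refitting the reduced model.
prune_mixture <- function(model, x, u, config, seed) {
  M <- length(model$components)
  if (is_indep(model) || M == 1L) return(model)
  grid <- seq(model$x_range[1], model$x_range[2], length.out = 101)
  phi <- model_params_at(model, grid)$phi
  keep <- apply(phi, 2, max) >= 1e-4
  if (all(keep)) return(model)
  fit_gpcop(model$components[keep], x, u, config, seed = seed + 999L)
}

#' @rdname select_greedy
#' @export
select_heuristic <- function(x, u, config = gpc_config(), seed = 1,
                             shortlist_k = 4) {
  u <- clamp_unit(as_u_matrix(u))
  n <- nrow(u)
  ## stage 1: capped-budget independence screen with a Gaussian copula
  screen_cfg <- config
  screen_cfg$max_steps <- min(config$screen_steps, config$max_steps)
  screen <- fit_gpcop(bicop_spec("gauss"), x, u, screen_cfg, seed = seed)
  if (screen$waic > -config$waic_tol) {
    out <- indep_model(range(x))
    attr(out, "history") <- tibble::tibble(model = "gauss(screen)", M = 1L,
                                           waic = screen$waic)
    return(out)
  }
  ## stage 2: rank candidates by tail/corner diagnostics
  corner <- c(
    ll = mean(u[, 1] < 0.1 & u[, 2] < 0.1),
    lr = mean(u[, 1] > 0.9 & u[, 2] < 0.1),
    ul = mean(u[, 1] < 0.1 & u[, 2] > 0.9),
    ur = mean(u[, 1] > 0.9 & u[, 2] > 0.9)
  )
  excess <- corner / 0.01 - 1       # independence expectation: 0.01 n per corner
  tau_emp <- stats::cor(u[, 1], u[, 2], method = "kendall")
  corner_of <- c(clayton0 = "ll", clayton90 = "lr", clayton180 = "ur",
                 clayton270 = "ul", gumbel0 = "ur", gumbel90 = "ul",
                 gumbel180 = "ll", gumbel270 = "lr")
  cands <- default_candidates()
  is_sym <- vapply(cands, function(sp) sp$family %in% c("gauss", "frank"), TRUE)
  tail_score <- vapply(cands, function(sp) {
    if (sp$family %in% c("gauss", "frank")) return(-Inf)
    excess[[corner_of[[paste0(sp$family, sp$rotation)]]]]
  }, 0)
  ## the symmetric elements are always candidates (ordered Gaussian first);
  ## the tail elements compete for the remaining slots by corner excess
  n_tail <- max(min(shortlist_k, length(cands)) - 2L, 1L)
  tails <- cands[!is_sym][order(tail_score[!is_sym], decreasing = TRUE)][seq_len(n_tail)]
  shortlist <- c(list(bicop_spec("gauss")), tails, list(bicop_spec("frank")))
  out <- select_greedy(x, u, shortlist, config, seed = seed + 1L)
  attr(out, "shortlist") <- vapply(shortlist, format, "")
  out
}
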