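#' Read and write conditioned datasets
#'
#' Delimited tables with one row per sample: a column named `x` holds the
#' conditioning covariate, every other column is an observed variable.
#' TSV or CSV is chosen by file extension.  Missing or non-numeric cells
#' are an error naming the offending rows.
#'
#' @param path file path (`.tsv`/`.txt` tab-delimited, `.csv` comma).
#' @return a [cond_dataset()].
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
  cond_dataset(as.data.frame(df))
}

#' @rdname read_dataset
#' @param dataset a [cond_dataset()].
#' @export
write_dataset <- function(dataset, path) {
  df <- tibble::as_tibble(cbind(x = dataset$x, dataset$Y))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(df, path)
  } else {
    readr::write_tsv(df, path)
  }
  invisible(path)
}

## ---- model persistence -----------------------------------------------------

MODEL_FORMAT_VERSION <- "1"

spec_to_list <- function(spec) list(family = spec$family, rotation = spec$rotation)
spec_from_list <- function(l) bicop_spec(l$family, l$rotation)

mixcop_to_list <- function(model) {
  if (is_indep(model)) {
    return(list(type = "indep", x_range = model$x_range))
  }
  list(type = "mixcop_gp",
       components = lapply(model$components, spec_to_list),
       latents = model$latents,
       x_range = model$x_range,
       waic = model$waic,
       aborted = model$aborted,
       grid_size = length(model$latents[[1]]$m))
}

mixcop_from_list <- function(l) {
  if (identical(l$type, "indep")) return(indep_model(unlist(l$x_range)))
  latents <- lapply(l$latents, function(la) {
    list(m = as.numeric(la$m), logS = as.numeric(la$logS),
         mu0 = as.numeric(la$mu0), loglam = as.numeric(la$loglam),
         logs = as.numeric(la$logs))
  })
  mdl <- build_model(lapply(l$components, spec_from_list), latents,
                     unlist(l$x_range), gpc_config(), numeric(0),
                     waic = l$waic, aborted = isTRUE(l$aborted))
  mdl$waic <- l$waic
  mdl
}

#' Save and load fitted models as structured JSON
#'
#' Serializes a bivariate mixture model or a whole C-vine (component list,
#' GP hyper-parameters, variational state, variable order, covariate
#' domain) to human-diffable JSON at full double precision, so a reloaded
#' model reproduces log densities bit-identically.  A format version field
#' is checked on load.
#'
#' @param model a `mixcop_gp` or `cvine` object.
#' @param path output path.
#' @return `save_model` the path, invisibly; `load_model` the
#'   reconstructed model.
#' @export
save_model <- function(model, path) {
  obj <- if (inherits(model, "cvine")) {
    list(format_version = MODEL_FORMAT_VERSION, type = "cvine",
         order = model$order, m = model$m, x_range = model$x_range,
         edges = lapply(model$edges, function(tr) lapply(tr, mixcop_to_list)))
  } else if (inherits(model, "mixcop_gp")) {
    c(list(format_version = MODEL_FORMAT_VERSION), mixcop_to_list(model))
  } else stop("cannot serialize object of class ", class(model)[1])
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE,
                                      simplifyDataFrame = FALSE,
                                      simplifyMatrix = FALSE),
                  error = function(e) stop("cannot parse model file: ",
                                           conditionMessage(e)))
  if (!identical(as.character(obj$format_version), MODEL_FORMAT_VERSION)) {
    stop("unsupported model format version: ", obj$format_version)
  }
  if (identical(obj$type, "cvine")) {
    structure(list(order = as.integer(obj$order),
                   edges = lapply(obj$edges, function(tr)
                     lapply(tr, mixcop_from_list)),
                   x_range = unlist(obj$x_range), m = as.integer(obj$m),
                   config = gpc_config()),
              class = "cvine")
  } else {
    mixcop_from_list(obj)
  }
}
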