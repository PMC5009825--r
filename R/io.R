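#' Read and write kinetics datasets
#'
#' CSV schema: columns `tissue`, `population`, `day`, `mean`, `sd`, `n`
#' (header required). Numeric values are written with 17 significant
#' digits so that read/write round-trips preserve doubles exactly and are
#' locale-independent.
#'
#' @param data a kinetics data.frame.
#' @param path file path.
#' @return `read_kinetics_csv` returns a `leuk_kinetics` data.frame;
#'   `write_kinetics_csv` returns `path` invisibly.
#' @export
write_kinetics_csv <- function(data, path) {
  data <- as.data.frame(data)
  need <- c("tissue", "population", "day", "mean", "sd", "n")
  stopifnot(all(need %in% names(data)))
  out <- data[need]
  for (col in c("day", "mean", "sd")) {
    out[[col]] <- sprintf("%.17g", as.numeric(out[[col]]))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_kinetics_csv
#' @export
read_kinetics_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(tissue = "character",
                                       population = "character"))
  need <- c("tissue", "population", "day", "mean", "sd", "n")
  if (!all(need %in% names(df))) {
    .stopf("kinetics CSV must have columns %s", paste(need, collapse = ", "))
  }
  df$n <- as.integer(df$n)
  attr(df, "provenance") <- list(scenario = "file", seed = NA, cv = NA,
                                 n = NA)
  class(df) <- c("leuk_kinetics", "data.frame")
  df
}

# serialize a rate form / modifier to plain lists
.form_to_list <- function(form) {
  c(list(kind = form$kind), form$params)
}

.modifier_to_list <- function(mod) {
  if (mod$direction == "none") return(list(direction = "none"))
  out <- list(direction = mod$direction, theta_L = mod$theta_L,
              h_L = mod$h_L)
  if (mod$direction == "stimulative") out$beta <- mod$beta
  if (mod$direction == "suppressive") out$w <- mod$w
  out
}

.form_from_list <- function(x) {
  do.call(rate_form, c(list(type = x$kind),
                       x[setdiff(names(x), "kind")]))
}

.modifier_from_list <- function(x) {
  do.call(leuk_modifier, x)
}

#' Serialize model specifications
#'
#' Writes a [model_spec()] to a JSON document (compartments, populations,
#' processes with their forms and modifiers, mobility mode, G0 flag,
#' hierarchy level, initial state, free parameters, bounds, forcing) and
#' reads it back losslessly.
#'
#' @param spec a [model_spec()].
#' @param path file path.
#' @return `read_model_spec` returns the `model_spec`;
#'   `write_model_spec` returns `path` invisibly.
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "model_spec"))
  procs <- lapply(unname(spec$processes), function(p) {
    list(kind = p$kind, pool = p$pool,
         source = p$source, sink = p$sink, driver = p$driver,
         burden = p$burden,
         form = .form_to_list(p$form),
         modifier = .modifier_to_list(p$modifier))
  })
  doc <- list(name = spec$name,
              hierarchy_level = spec$hierarchy_level,
              mobility_mode = spec$mobility_mode,
              g0_reentry = spec$g0_reentry,
              init = as.list(spec$init),
              obs_days = spec$obs_days,
              processes = procs,
              free = spec$free,
              lower = as.list(spec$lower),
              upper = as.list(spec$upper),
              forcing = spec$forcing)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  procs <- lapply(doc$processes, function(p) {
    process_spec(kind = p$kind, pool = p$pool,
                 form = .form_from_list(p$form),
                 source = p$source, sink = p$sink, driver = p$driver,
                 modifier = .modifier_from_list(p$modifier),
                 burden = p$burden)
  })
  forcing <- NULL
  if (!is.null(doc$forcing)) {
    forcing <- list(times = as.numeric(unlist(doc$forcing$times)),
                    values = as.numeric(unlist(doc$forcing$values)))
  }
  spec <- model_spec(name = doc$name,
                     init = unlist(doc$init),
                     processes = procs,
                     mobility_mode = doc$mobility_mode,
                     g0_reentry = doc$g0_reentry,
                     hierarchy_level = doc$hierarchy_level,
                     forcing = forcing,
                     free = as.character(unlist(doc$free)),
                     obs_days = as.numeric(unlist(doc$obs_days)))
  lw <- unlist(doc$lower); up <- unlist(doc$upper)
  spec$lower[names(lw)] <- lw
  spec$upper[names(up)] <- up
  spec
}

#' Serialize a fit result
#'
#' Writes a `leuk_fit` to JSON: the full parameter set, free-parameter
#' names, per-series `d`/`s` table with pass flags, aggregate objective,
#' seed, GA history and configuration.
#'
#' @param fit a `leuk_fit`.
#' @param path file path.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "leuk_fit"))
  doc <- list(spec = fit$spec_name,
              objective = fit$objective,
              seed = fit$seed,
              refined = fit$refined,
              params = as.list(fit$params),
              free = fit$free,
              series = fit$series,
              history = fit$history,
              ga = unclass(fit$ga))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Export a trajectory as tidy CSV
#'
#' Columns: `day`, `compartment`, `population`, `count`, full precision.
#'
#' @param traj a `leuk_trajectory`.
#' @param path file path.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- as.data.frame(traj)
  df$day <- sprintf("%.17g", df$day)
  df$count <- sprintf("%.17g", df$count)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
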