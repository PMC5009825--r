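#' Default leukemic bone-marrow forcing
#'
#' The noise-free `BM.leukemic` time course of the default
#' [tissue_model()], tabulated on a 0.1-day grid. Used as the exogenous
#' leukemic burden driving the nested HSC/HPC and G0 sub-models
#' (hierarchical fitting: the tissue level is fitted first and its leukemic
#' trajectory is frozen into the sub-models).
#'
#' @param spec tissue-level [model_spec()] (default [tissue_model()]).
#' @param params optional parameter override for `spec`.
#' @return list with `times` and `values`.
#' @export
default_forcing <- function(spec = tissue_model(), params = NULL) {
  cacheable <- missing(spec) && is.null(params)
  if (cacheable && !is.null(.leukodyn_cache$default_forcing)) {
    return(.leukodyn_cache$default_forcing)
  }
  traj <- simulate_model(spec, params = params)
  out <- list(times = traj$times,
              values = unname(traj$state[, "BM.leukemic"]))
  if (cacheable) .leukodyn_cache$default_forcing <- out
  out
}

.leukodyn_cache <- new.env(parent = emptyenv())

#' Synthetic measurement scenarios
#'
#' A scenario bundles a generating model (spec + parameters + initial
#' state), an observation schedule, and a measurement-noise model
#' (multiplicative lognormal with coefficient of variation `cv`, `n_rep`
#' replicates per point). [generate_kinetics()] turns a scenario into a
#' noisy dataset.
#'
#' `default_scenario()` is the tri-tissue leukemia time course: leukemic
#' expansion in all tissues, a PB normal-cell rise after day 7, a spleen
#' rise peaking before day 21, and a BM decline with its minimum at day 21.
#'
#' `hsc_hpc_scenario()` is the nested stem/progenitor scenario: both BM
#' HSCs and HPCs decline under the leukemic forcing, HPCs much more
#' sharply.
#'
#' `quiescence_scenario()` is the G0 scenario: the quiescent fraction of
#' HSCs sits at 40 % at day 0, stays nearly flat through day 10, climbs
#' steeply between days 10 and 14, and exceeds 92 % from day 14 on.
#'
#' @param cv coefficient of variation of the multiplicative lognormal
#'   measurement noise (default 0.15).
#' @param n_rep replicates per time point (default 3).
#' @return an object of class `leuk_scenario`.
#' @export
default_scenario <- function(cv = 0.15, n_rep = 3) {
  .scenario(tissue_model("pb_coupled"), cv, n_rep, "default_tissue")
}

#' @rdname default_scenario
#' @param forcing optional leukemic forcing override (list of `times`,
#'   `values`); defaults to [default_forcing()].
#' @export
hsc_hpc_scenario <- function(cv = 0.15, n_rep = 3, forcing = NULL) {
  .scenario(hsc_hpc_model(forcing), cv, n_rep, "hsc_hpc")
}

#' @rdname default_scenario
#' @param g0_reentry `"on"` (the generating mechanism) or `"off"` (the
#'   selective-exhaustion counterpart used as a rival structure in model
#'   selection).
#' @export
quiescence_scenario <- function(g0_reentry = c("on", "off"), cv = 0.15,
                                n_rep = 3, forcing = NULL) {
  g0_reentry <- match.arg(g0_reentry)
  .scenario(g0_model(reentry = g0_reentry == "on", forcing),
            cv, n_rep, paste0("quiescence_", g0_reentry))
}

.scenario <- function(spec, cv, n_rep, label) {
  stopifnot(cv >= 0, n_rep >= 1)
  structure(list(spec = spec, cv = cv, n_rep = n_rep,
                 obs_days = spec$obs_days, label = label),
            class = "leuk_scenario")
}

#' @export
print.leuk_scenario <- function(x, ...) {
  cat("<leuk_scenario> ", x$label, ": cv=", x$cv, ", n=", x$n_rep,
      ", days {", paste(x$obs_days, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Generate a synthetic kinetics dataset
#'
#' Simulates the scenario's ground truth, samples it at the observation
#' days, draws `n_rep` multiplicative-lognormal replicates per state and
#' day (the lognormal is parameterized so that the replicate mean equals
#' the true count and its coefficient of variation equals `cv`), derives
#' the observable series per replicate (for the G0 level: total HSC count
#' and quiescent fraction, so the fraction noise respects its 0-1 range),
#' and records the replicate mean and sample standard deviation. `cv = 0`
#' returns the ground truth exactly with zero SDs.
#'
#' @param scenario a `leuk_scenario`.
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @return data.frame of class `leuk_kinetics` with columns `tissue`,
#'   `population`, `day`, `mean`, `sd`, `n`, and attributes `provenance`
#'   (scenario label, seed, cv, n).
#' @export
generate_kinetics <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "leuk_scenario"))
  span <- range(c(0, scenario$obs_days))
  traj <- simulate_model(scenario$spec, obs_days = scenario$obs_days,
                         span = span,
                         solver = solver_control(dense_dt = diff(span)))
  st <- .traj_at(traj, scenario$obs_days)
  cv <- scenario$cv
  n_rep <- scenario$n_rep
  sdlog <- sqrt(log(1 + cv^2))
  g0 <- all(c("BM.HSC_G0", "BM.HSC_active") %in% colnames(st))
  rows <- .with_seed(seed, {
    out <- list()
    for (di in seq_along(scenario$obs_days)) {
      day <- scenario$obs_days[di]
      # replicate matrix: n_rep x states
      truth <- st[di, ]
      reps <- if (cv == 0) {
        matrix(rep(truth, each = n_rep), n_rep,
               dimnames = list(NULL, names(truth)))
      } else {
        m <- matrix(stats::rlnorm(n_rep * length(truth),
                                  meanlog = rep(log(pmax(truth, 1e-300)),
                                                each = n_rep) - sdlog^2 / 2,
                                  sdlog = sdlog),
                    n_rep, dimnames = list(NULL, names(truth)))
        m[, truth == 0] <- 0
        m
      }
      if (g0) {
        tot <- reps[, "BM.HSC_G0"] + reps[, "BM.HSC_active"]
        frac <- reps[, "BM.HSC_G0"] / tot
        out[[length(out) + 1L]] <- data.frame(
          tissue = "BM", population = c("HSC", "HSC_G0"), day = day,
          mean = c(mean(tot), mean(frac)),
          sd = c(stats::sd(tot), stats::sd(frac)))
      } else {
        out[[length(out) + 1L]] <- data.frame(
          tissue = sub("\\..*", "", colnames(reps)),
          population = sub("^[^.]*\\.", "", colnames(reps)),
          day = day,
          mean = colMeans(reps),
          sd = apply(reps, 2, stats::sd))
      }
    }
    out
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df$sd[is.na(df$sd)] <- 0  # n_rep = 1
  df$n <- as.integer(n_rep)
  df <- df[order(df$tissue, df$population, df$day), ]
  rownames(df) <- NULL
  attr(df, "provenance") <- list(scenario = scenario$label, seed = seed,
                                 cv = cv, n = n_rep)
  class(df) <- c("leuk_kinetics", "data.frame")
  df
}
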