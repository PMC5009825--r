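#' Mechanistic rate decomposition along a trajectory
#'
#' Evaluates every process rate on the states of a simulated trajectory
#' (parametric analysis): projecting the net cell dynamics onto its acting
#' factors. Each process contributes a row per population it touches, with
#' `signed_rate` positive for the gaining side and negative for the losing
#' side; cross-compartment migration therefore appears as an export (loss)
#' for the source tissue and an import (gain) for the sink tissue. At
#' every time point the signed rates of a population sum to its
#' instantaneous derivative.
#'
#' @param spec a [model_spec()].
#' @param params optional parameter override.
#' @param traj a `leuk_trajectory` produced from the same spec/params.
#' @param times evaluation times (must lie on the trajectory grid;
#'   default: the full grid).
#' @return data.frame of class `leuk_decomposition` with columns `time`,
#'   `compartment`, `population`, `process`, `kind`, `role`
#'   (`"gain"`/`"loss"`), `rate` (the nonnegative process rate) and
#'   `signed_rate`.
#' @export
decompose <- function(spec, params = NULL, traj = NULL, times = NULL) {
  cm <- compile_model(spec, params)
  if (is.null(traj)) traj <- simulate_model(spec, params)
  if (!identical(colnames(traj$state), cm$states)) {
    .stopf("trajectory populations do not match the model spec")
  }
  if (is.null(times)) times <- traj$times
  st <- .traj_at(traj, times)
  P <- cm$P
  rates <- matrix(0, length(times), P)
  for (ti in seq_along(times)) {
    rates[ti, ] <- .process_rates(cm, st[ti, ], times[ti])
  }
  labels <- unname(vapply(spec$processes, `[[`, "", "label"))
  kinds <- unname(vapply(spec$processes, `[[`, "", "kind"))
  rows <- list()
  for (j in seq_len(P)) {
    for (role in c("loss", "gain")) {
      stt <- if (role == "loss") spec$processes[[j]]$source
             else spec$processes[[j]]$sink
      if (is.null(stt)) next
      rows[[length(rows) + 1L]] <- data.frame(
        time = times,
        compartment = sub("\\..*", "", stt),
        population = sub("^[^.]*\\.", "", stt),
        process = labels[j], kind = kinds[j], role = role,
        rate = rates[, j],
        signed_rate = if (role == "loss") -rates[, j] else rates[, j])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("leuk_decomposition", "data.frame")
  out
}

#' Conservation check of a decomposition
#'
#' Maximum absolute discrepancy, over populations and times, between the
#' signed-rate sum of the decomposition and the model right-hand side
#' evaluated on the same states (should be at numerical zero).
#'
#' @param dec a `leuk_decomposition`.
#' @param spec,params,traj the model and trajectory it was computed from.
#' @export
decomposition_residual <- function(dec, spec, params = NULL, traj) {
  rhs <- build_rhs(spec, params)
  times <- sort(unique(dec$time))
  st <- .traj_at(traj, times)
  worst <- 0
  sums <- stats::aggregate(signed_rate ~ time + compartment + population,
                           data = dec, FUN = sum)
  for (ti in seq_along(times)) {
    dy <- rhs(times[ti], st[ti, ])
    sel <- sums$time == times[ti]
    key <- paste(sums$compartment[sel], sums$population[sel], sep = ".")
    worst <- max(worst, max(abs(sums$signed_rate[sel] - dy[key])))
  }
  worst
}

#' Interval fluxes of a process
#'
#' Absolute numbers of cells processed by one named process in consecutive
#' time intervals: the integral of the process rate over each interval,
#' computed by adaptive quadrature on a spline through the dense
#' trajectory. The default intervals are the 21 unit intervals
#' `[0,1], [1,2], ..., [20,21]` days.
#'
#' @param spec a [model_spec()].
#' @param params optional parameter override.
#' @param traj a dense `leuk_trajectory`.
#' @param process process label (e.g. `"BM.HSC.HSC_to_HPC"`).
#' @param breaks interval boundaries (days).
#' @return data.frame of class `leuk_flux` with columns `from`, `to`,
#'   `flux` (cells).
#' @export
interval_flux <- function(spec, params = NULL, traj, process,
                          breaks = 0:21) {
  cm <- compile_model(spec, params)
  if (!process %in% names(spec$processes)) {
    .stopf("unknown process '%s'", process)
  }
  j <- match(process, names(spec$processes))
  if (min(breaks) < min(traj$times) || max(breaks) > max(traj$times)) {
    .stopf("intervals outside the trajectory span")
  }
  vals <- vapply(seq_along(traj$times), function(ti) {
    .process_rates(cm, traj$state[ti, ], traj$times[ti])[j]
  }, 0)
  if (all(vals == 0)) {
    ratef <- function(t) rep_len(0, length(t))
  } else {
    sf <- stats::splinefun(traj$times, vals, method = "monoH.FC")
    ratef <- function(t) pmax(sf(t), 0)
  }
  flux <- vapply(seq_len(length(breaks) - 1L), function(i) {
    stats::integrate(ratef, breaks[i], breaks[i + 1L],
                     rel.tol = 1e-8, abs.tol = 1e-10)$value
  }, 0)
  out <- data.frame(from = breaks[-length(breaks)], to = breaks[-1L],
                    flux = flux)
  class(out) <- c("leuk_flux", "data.frame")
  out
}

#' Rank acting factors of a population
#'
#' Scores each process acting on a population over a time window by the
#' mean absolute rate and by the variation amplitude (max minus min of the
#' signed rate). Processes are ranked by mean absolute rate; the amplitude
#' is reported alongside. Ties break lexicographically by process label.
#'
#' @param dec a `leuk_decomposition`.
#' @param population `"<compartment>.<population>"` label.
#' @param window `c(t_a, t_b)` analysis window (default: full range).
#' @return data.frame of class `leuk_ranking` with columns `process`,
#'   `kind`, `mean_abs_rate`, `amplitude`, `rank`.
#' @export
rank_factors <- function(dec, population, window = NULL) {
  comp <- sub("\\..*", "", population)
  pop <- sub("^[^.]*\\.", "", population)
  d <- dec[dec$compartment == comp & dec$population == pop, ]
  if (nrow(d) == 0) .stopf("population '%s' not in decomposition", population)
  if (!is.null(window)) {
    d <- d[d$time >= window[1] & d$time <= window[2], ]
    if (nrow(d) == 0) .stopf("empty analysis window")
  }
  sp <- split(d, d$process)
  out <- data.frame(
    process = names(sp),
    kind = vapply(sp, function(x) x$kind[1], ""),
    mean_abs_rate = vapply(sp, function(x) mean(abs(x$signed_rate)), 0),
    amplitude = vapply(sp, function(x) {
      max(x$signed_rate) - min(x$signed_rate)
    }, 0),
    row.names = NULL)
  ord <- order(-out$mean_abs_rate, out$process)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("leuk_ranking", "data.frame")
  out
}

#' One-tailed comparison of model-variant errors
#'
#' Welch (unequal-variance) one-tailed two-sample t-test on per-restart
#' fit-error samples of two model variants, testing whether variant A's
#' mean error is lower (`alternative = "a_lower"`) or higher
#' (`"b_lower"`) than variant B's. The winner is the lower-mean variant
#' when `p < alpha`, otherwise `"inconclusive"`. Two identical
#' zero-variance samples are degenerate and reported as `p = 0.5`.
#'
#' @param errors_a,errors_b numeric vectors (length >= 2) of fit errors.
#' @param alternative which variant is hypothesized to have lower mean
#'   error.
#' @param labels variant names `c(a, b)`.
#' @param alpha significance level for declaring a winner.
#' @return list of class `leuk_selection`: `t`, `p`, `winner`, `labels`,
#'   `means`, `alternative`, `degenerate`, `errors`.
#' @export
compare_variants <- function(errors_a, errors_b,
                             alternative = c("a_lower", "b_lower"),
                             labels = c("A", "B"), alpha = 0.05) {
  alternative <- match.arg(alternative)
  stopifnot(length(errors_a) >= 2, length(errors_b) >= 2)
  degenerate <- FALSE
  if (stats::sd(errors_a) == 0 && stats::sd(errors_b) == 0) {
    degenerate <- TRUE
    if (isTRUE(all.equal(mean(errors_a), mean(errors_b)))) {
      tstat <- 0; p <- 0.5
    } else {
      lower <- mean(errors_a) < mean(errors_b)
      p <- if (xor(alternative == "a_lower", lower)) 1 else 0
      tstat <- if (lower) -Inf else Inf
    }
  } else {
    tt <- stats::t.test(errors_a, errors_b, var.equal = FALSE,
                        alternative = if (alternative == "a_lower") "less"
                                      else "greater")
    tstat <- unname(tt$statistic)
    p <- tt$p.value
  }
  means <- c(mean(errors_a), mean(errors_b))
  winner <- if (p < alpha) {
    labels[which.min(means)]
  } else "inconclusive"
  structure(list(t = tstat, p = p, winner = winner, labels = labels,
                 means = means, alternative = alternative,
                 degenerate = degenerate,
                 errors = list(a = errors_a, b = errors_b),
                 test = "Welch one-tailed t"),
            class = "leuk_selection")
}

#' @export
print.leuk_selection <- function(x, ...) {
  cat("<leuk_selection> ", x$labels[1], " vs ", x$labels[2],
      ": t=", format(x$t, digits = 4), ", one-tail p=",
      format(x$p, digits = 4), ", winner: ", x$winner,
      if (x$degenerate) " (degenerate samples)" else "", "\n", sep = "")
  invisible(x)
}

#' Model-selection experiment across variants
#'
#' Fits every candidate variant to the same dataset with `n_restarts`
#' GA restarts (seeds `seed0 ... seed0 + n_restarts - 1`, shared across
#' variants), extracts per-restart error samples (aggregate `d/s`
#' objective, optionally restricted to the contested series), and runs
#' pairwise one-tailed Welch tests, each oriented toward the lower-mean
#' variant of the pair.
#'
#' @param data kinetics dataset.
#' @param variant_specs named list of [model_spec()] variants.
#' @param ga a [ga_config()].
#' @param n_restarts restarts per variant.
#' @param seed0 first seed.
#' @param tissue,population optional filters selecting the contested
#'   series for the error samples (see [series_objective()]).
#' @param alpha significance level.
#' @param ... passed to [fit_model()] (e.g. `solver`).
#' @return list of class `leuk_selection_experiment`: `errors` (named
#'   list of per-variant samples), `pairs` (list of `leuk_selection`,
#'   named `"A_vs_B"`), `fits` (per-variant ensembles), `seeds`.
#' @export
run_selection_experiment <- function(data, variant_specs,
                                     ga = ga_config(), n_restarts = 10,
                                     seed0 = 0L, tissue = NULL,
                                     population = NULL, alpha = 0.05,
                                     ...) {
  stopifnot(length(variant_specs) >= 2, !is.null(names(variant_specs)))
  fits <- lapply(variant_specs, function(sp) {
    multi_restart(sp, data, n_restarts = n_restarts, seed0 = seed0,
                  ga = ga, ...)
  })
  errors <- lapply(fits, function(ens) {
    vapply(ens, series_objective, 0, tissue = tissue,
           population = population)
  })
  nms <- names(variant_specs)
  pairs <- list()
  for (i in seq_along(nms)) {
    for (j in seq_along(nms)) {
      if (j <= i) next
      a <- errors[[i]]; b <- errors[[j]]
      alt <- if (mean(a) <= mean(b)) "a_lower" else "b_lower"
      pairs[[paste(nms[i], "vs", nms[j], sep = "_")]] <-
        compare_variants(a, b, alternative = alt,
                         labels = c(nms[i], nms[j]), alpha = alpha)
    }
  }
  structure(list(errors = errors, pairs = pairs, fits = fits,
                 seeds = seed0 + seq_len(n_restarts) - 1L,
                 contested = list(tissue = tissue, population = population)),
            class = "leuk_selection_experiment")
}

#' @export
print.leuk_selection_experiment <- function(x, ...) {
  cat("<leuk_selection_experiment> ", length(x$errors), " variants, ",
      length(x$seeds), " restarts\n", sep = "")
  for (nm in names(x$errors)) {
    cat("  ", nm, ": mean error ", format(mean(x$errors[[nm]]), digits = 5),
        "\n", sep = "")
  }
  for (p in x$pairs) print(p)
  invisible(x)
}
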