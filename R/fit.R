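#' Root-mean-square deviation
#'
#' The fitness degree `d` of a simulated series against observed means:
#' `sqrt(mean((sim - obs)^2))`.
#'
#' @param sim,obs numeric vectors of equal length.
#' @export
rmsd <- function(sim, obs) {
  if (length(sim) != length(obs) || length(sim) < 1) {
    .stopf("rmsd: sim and obs must have equal length >= 1")
  }
  sqrt(mean((sim - obs)^2))
}

#' Fitness acceptance criterion
#'
#' A series fit is accepted when its root-mean-square deviation is no
#' larger than the experimental standard deviation: `d <= s` (boundary
#' inclusive). `s` is expected to be floored already (see
#' [series_sd()]).
#'
#' @param d root-mean-square deviation (cells).
#' @param s experimental standard deviation (cells).
#' @export
fitness_criterion <- function(d, s) {
  stopifnot(all(d >= 0), all(s >= 0))
  d <= s
}

#' Per-series experimental standard deviation
#'
#' Pools the per-timepoint sample SDs of one series into the scalar `s` of
#' the `d <= s` criterion as the root-mean-square SD, floored at
#' `floor_frac` times the series mean so that near-noiseless synthetic
#' series cannot blow up the normalized objective.
#'
#' @param sd per-timepoint sample standard deviations.
#' @param means per-timepoint means.
#' @param floor_frac flooring fraction (default 0.05).
#' @export
series_sd <- function(sd, means, floor_frac = 0.05) {
  max(sqrt(mean(sd^2)), floor_frac * mean(abs(means)))
}

#' Genetic-algorithm configuration
#'
#' @param pop_size population size (>= 4).
#' @param generations number of generations (>= 1).
#' @param crossover_rate probability of uniform crossover per offspring.
#' @param mutation_scale initial Gaussian mutation SD as a fraction of the
#'   bound width; decays linearly to `mutation_scale_final`.
#' @param mutation_scale_final final mutation scale.
#' @param tournament_size tournament selection size.
#' @param elitism number of elite individuals copied unchanged.
#' @param refine run bounded Levenberg-Marquardt (trust-region style)
#'   least-squares refinement from the GA best.
#' @param refine_maxit maximum refinement iterations.
#' @param refine_starts number of distinct GA elites used as refinement
#'   starts (multi-start descent; the best refined point wins).
#' @export
#' @param polish after refinement, if some series still violates `d <= s`,
#'   run a derivative-free minimax polish that minimizes the worst
#'   per-series `d/s` ratio (the acceptance criterion is per-series, so
#'   the final stage optimizes toward it rather than toward the
#'   aggregate).
#' @param polish_maxit maximum Nelder-Mead iterations of the polish.
ga_config <- function(pop_size = 96, generations = 150,
                      crossover_rate = 0.7, mutation_scale = 0.1,
                      mutation_scale_final = 0.02, tournament_size = 3,
                      elitism = 2, refine = TRUE, refine_maxit = 50,
                      refine_starts = 1, polish = FALSE,
                      polish_maxit = 600) {
  stopifnot(pop_size >= 4, generations >= 1, elitism >= 0,
            elitism < pop_size, tournament_size >= 1)
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_scale = mutation_scale,
                 mutation_scale_final = mutation_scale_final,
                 tournament_size = as.integer(tournament_size),
                 elitism = as.integer(elitism),
                 refine = refine, refine_maxit = as.integer(refine_maxit),
                 refine_starts = as.integer(refine_starts),
                 polish = polish, polish_maxit = as.integer(polish_maxit)),
            class = "ga_config")
}

# Internal: matches dataset series to model observables and returns the
# machinery shared by the GA objective, the LM residual function, and the
# reporting of per-series d/s tables.
.make_objective <- function(spec, data, free, solver) {
  stopifnot(inherits(spec, "model_spec"))
  data <- as.data.frame(data)
  need <- c("tissue", "population", "day", "mean", "sd", "n")
  if (!all(need %in% names(data))) {
    .stopf("dataset must have columns %s", paste(need, collapse = ", "))
  }
  obs_days <- sort(unique(data$day))
  key <- paste(data$tissue, data$population, sep = ".")
  series <- split(data, key)
  # validate series against the spec's observables
  probe <- observe(simulate_model(spec, obs_days = obs_days,
                                  solver = solver_control(rtol = 1e-6,
                                                          atol = 1e-3,
                                                          dense_dt = diff(range(obs_days)))),
                   obs_days)
  obs_key <- unique(paste(probe$tissue, probe$population, sep = "."))
  missing <- setdiff(names(series), obs_key)
  if (length(missing)) {
    .stopf("dataset series %s not observable in model '%s'",
           paste(missing, collapse = ", "), spec$name)
  }
  sinfo <- lapply(series, function(s) {
    s <- s[order(s$day), ]
    list(days = s$day, mean = s$mean,
         s = series_sd(s$sd, s$mean))
  })
  bad <- setdiff(free, names(spec$params))
  if (length(bad)) .stopf("free parameter(s) not in model: %s",
                          paste(bad, collapse = ", "))
  lower <- spec$lower[free]; upper <- spec$upper[free]
  if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(upper < lower)) {
    .stopf("invalid bounds for free parameters")
  }
  # fit in log10 space when positive bounds span more than two decades
  logsc <- lower > 0 & upper / lower > 100
  enc <- function(p) ifelse(logsc, log10(p), p)
  dec <- function(z) ifelse(logsc, 10^z, z)
  tlower <- enc(lower); tupper <- enc(upper)

  sim_series <- function(z) {
    p <- spec$params
    p[free] <- dec(z)
    traj <- tryCatch(
      simulate_model(spec, params = p, obs_days = obs_days,
                     span = range(c(0, obs_days)),
                     solver = solver),
      error = function(e) NULL)
    if (is.null(traj)) return(NULL)
    ob <- observe(traj, obs_days)
    okey <- paste(ob$tissue, ob$population, sep = ".")
    lapply(names(sinfo), function(k) {
      sel <- okey == k
      ob$value[sel][match(sinfo[[k]]$days, ob$day[sel])]
    })
  }
  list(
    free = free, lower = lower, upper = upper,
    tlower = tlower, tupper = tupper, enc = enc, dec = dec,
    series = sinfo, obs_days = obs_days,
    # scalar objective: sum over series of d/s
    value = function(z) {
      sims <- sim_series(z)
      if (is.null(sims)) return(Inf)
      tot <- 0
      for (i in seq_along(sims)) {
        si <- sinfo[[i]]
        tot <- tot + rmsd(sims[[i]], si$mean) / si$s
      }
      tot
    },
    # residual vector for least-squares refinement; sum of squares equals
    # sum over series of (d/s)^2
    residuals = function(z) {
      sims <- sim_series(z)
      if (is.null(sims)) {
        return(rep(1e6, sum(vapply(sinfo, function(s) length(s$days), 0L))))
      }
      unlist(lapply(seq_along(sims), function(i) {
        si <- sinfo[[i]]
        (sims[[i]] - si$mean) / (si$s * sqrt(length(si$days)))
      }))
    },
    # per-series d/s table at a parameter vector
    table = function(z) {
      sims <- sim_series(z)
      if (is.null(sims)) .stopf("simulation failed at reported parameters")
      keys <- names(sinfo)
      data.frame(
        tissue = sub("\\..*", "", keys),
        population = sub("^[^.]*\\.", "", keys),
        d = vapply(seq_along(sims),
                   function(i) rmsd(sims[[i]], sinfo[[i]]$mean), 0),
        s = vapply(sinfo, `[[`, 0, "s"),
        row.names = NULL
      )
    }
  )
}

#' Fit model parameters to a kinetics dataset
#'
#' Genetic-algorithm minimization of the normalized aggregate objective
#' `sum over series of d/s` (root-mean-square deviation over pooled
#' experimental SD, so series whose counts differ by orders of magnitude
#' contribute comparably), followed by bounded Levenberg-Marquardt
#' least-squares refinement from the GA optimum. Parameters whose positive
#' bounds span more than two decades are searched in log10 space. The GA
#' uses tournament selection, uniform crossover, decaying Gaussian
#' mutation with reflection at the bounds, and elitism (so the best
#' objective is non-increasing across generations). Fully reproducible
#' given `seed`; the caller's RNG state is untouched.
#'
#' @param spec a [model_spec()].
#' @param data a kinetics dataset (columns `tissue`, `population`, `day`,
#'   `mean`, `sd`, `n`); every series must map to an observable of `spec`.
#' @param free names of free parameters (default `spec$free`); all others
#'   are held at the spec's current values.
#' @param ga a [ga_config()].
#' @param seed integer seed.
#' @param solver a [solver_control()] for the fitting simulations.
#' @return object of class `leuk_fit`: `params` (full vector), `free`,
#'   `objective`, `series` (per-series `d`, `s` and `pass = d <= s`),
#'   `history` (best objective per generation), `seed`, `refined`,
#'   `convergence`.
#' @export
fit_model <- function(spec, data, free = spec$free, ga = ga_config(),
                      seed = 1L,
                      solver = solver_control(rtol = 1e-6, atol = 1e-3,
                                              dense_dt = 21)) {
  stopifnot(inherits(ga, "ga_config"))
  seed <- as.integer(seed)
  if (length(free) == 0) .stopf("no free parameters to fit")
  obj <- .make_objective(spec, data, free, solver)
  d <- length(free)
  width <- obj$tupper - obj$tlower
  out <- .with_seed(seed, {
    pop <- matrix(stats::runif(ga$pop_size * d), ga$pop_size, d)
    pop <- sweep(sweep(pop, 2, width, "*"), 2, obj$tlower, "+")
    fitn <- apply(pop, 1, obj$value)
    history <- numeric(ga$generations)
    for (g in seq_len(ga$generations)) {
      scale <- ga$mutation_scale +
        (ga$mutation_scale_final - ga$mutation_scale) *
        (g - 1) / max(1, ga$generations - 1)
      ord <- order(fitn)
      newpop <- matrix(0, ga$pop_size, d)
      nelite <- ga$elitism
      if (nelite > 0) newpop[seq_len(nelite), ] <- pop[ord[seq_len(nelite)], ]
      for (i in seq(nelite + 1, ga$pop_size)) {
        pick <- function() {
          cand <- sample.int(ga$pop_size, ga$tournament_size)
          cand[which.min(fitn[cand])]
        }
        child <- pop[pick(), ]
        if (stats::runif(1) < ga$crossover_rate) {
          mate <- pop[pick(), ]
          mask <- stats::runif(d) < 0.5
          child[mask] <- mate[mask]
        }
        child <- child + stats::rnorm(d, 0, scale * width)
        # reflect into bounds
        for (r in 1:3) {
          lo <- child < obj$tlower; child[lo] <- 2 * obj$tlower[lo] - child[lo]
          hi <- child > obj$tupper; child[hi] <- 2 * obj$tupper[hi] - child[hi]
        }
        child <- pmin(pmax(child, obj$tlower), obj$tupper)
        newpop[i, ] <- child
      }
      fresh <- seq(nelite + 1, ga$pop_size)
      newfit <- c(fitn[ord[seq_len(nelite)]],
                  apply(newpop[fresh, , drop = FALSE], 1, obj$value))
      pop <- newpop; fitn <- newfit
      history[g] <- min(fitn)
    }
    best <- pop[which.min(fitn), ]
    bestval <- min(fitn)
    refined <- FALSE
    conv <- NA_integer_
    if (ga$refine) {
      # multi-start refinement: the final population usually straddles
      # several basins, so descend from the few most distinct elites and
      # keep the best, instead of trusting the single GA incumbent
      ord <- order(fitn)
      starts <- list(pop[ord[1], ])
      i <- 2L
      while (length(starts) < ga$refine_starts && i <= ga$pop_size) {
        cand <- pop[ord[i], ]
        dist <- min(vapply(starts, function(s) {
          max(abs(cand - s) / pmax(width, 1e-12))
        }, 0))
        if (dist > 0.05) starts[[length(starts) + 1L]] <- cand
        i <- i + 1L
      }
      for (z0 in starts) {
        # reaching maxiter is an accepted stopping rule here, not a fault
        lm <- tryCatch(
          suppressWarnings(
            minpack.lm::nls.lm(par = z0, lower = obj$tlower,
                               upper = obj$tupper, fn = obj$residuals,
                               control = minpack.lm::nls.lm.control(
                                 maxiter = ga$refine_maxit))),
          error = function(e) NULL)
        if (!is.null(lm)) {
          val <- obj$value(lm$par)
          if (is.finite(val) && val <= bestval) {
            best <- pmin(pmax(lm$par, obj$tlower), obj$tupper)
            bestval <- obj$value(best)
            refined <- TRUE
            conv <- lm$info
          }
        }
      }
    }
    if (ga$polish) {
      # minimax stage: the acceptance criterion is per-series d <= s, so
      # when the aggregate optimum leaves a series failing, trade a little
      # aggregate error for the worst series ratio
      tab0 <- obj$table(best)
      if (any(tab0$d > tab0$s)) {
        fmax <- function(z) {
          z <- pmin(pmax(z, obj$tlower), obj$tupper)
          tt <- obj$table(z)
          r <- tt$d / tt$s
          max(r) + 0.01 * sum(r)
        }
        opt <- tryCatch(
          stats::optim(best, fmax, method = "Nelder-Mead",
                       control = list(maxit = ga$polish_maxit,
                                      reltol = 1e-8)),
          error = function(e) NULL)
        if (!is.null(opt)) {
          cand <- pmin(pmax(opt$par, obj$tlower), obj$tupper)
          tab1 <- obj$table(cand)
          better <- sum(tab1$d > tab1$s) < sum(tab0$d > tab0$s) ||
            (sum(tab1$d > tab1$s) == sum(tab0$d > tab0$s) &&
               max(tab1$d / tab1$s) < max(tab0$d / tab0$s))
          if (better) {
            best <- cand
            bestval <- obj$value(best)
          }
        }
      }
    }
    list(best = best, bestval = bestval, history = history,
         refined = refined, conv = conv)
  })
  params <- spec$params
  params[free] <- obj$dec(out$best)
  tab <- obj$table(out$best)
  tab$pass <- fitness_criterion(tab$d, tab$s)
  structure(list(params = params, free = free, objective = out$bestval,
                 series = tab, history = out$history, seed = seed,
                 refined = out$refined, convergence = out$conv,
                 spec_name = spec$name, ga = ga),
            class = "leuk_fit")
}

#' @export
print.leuk_fit <- function(x, ...) {
  cat("<leuk_fit> ", x$spec_name, ": objective=",
      format(x$objective, digits = 5), " (seed ", x$seed,
      if (x$refined) ", refined" else "", ")\n", sep = "")
  print(x$series, digits = 4)
  invisible(x)
}

#' Aggregate objective restricted to a subset of series
#'
#' Recomputes `sum(d/s)` from a fit's stored per-series table, optionally
#' restricted to the named series (used for contested-series model
#' comparisons).
#'
#' @param fit a `leuk_fit`.
#' @param tissue,population optional filters.
#' @export
series_objective <- function(fit, tissue = NULL, population = NULL) {
  tab <- fit$series
  if (!is.null(tissue)) tab <- tab[tab$tissue %in% tissue, ]
  if (!is.null(population)) tab <- tab[tab$population %in% population, ]
  if (nrow(tab) == 0) .stopf("no series left after filtering")
  sum(tab$d / tab$s)
}

#' Multi-restart fitting
#'
#' Independent fits with seeds `seed0, seed0 + 1, ..., seed0 + n - 1`,
#' returned sorted by objective (best first).
#'
#' @inheritParams fit_model
#' @param n_restarts number of restarts (>= 2).
#' @param seed0 first seed.
#' @return list of `leuk_fit` objects of class `leuk_fit_ensemble`.
#' @export
multi_restart <- function(spec, data, n_restarts = 10, seed0 = 0L,
                          free = spec$free, ga = ga_config(), ...) {
  stopifnot(n_restarts >= 2)
  seed0 <- as.integer(seed0)
  fits <- lapply(seq_len(n_restarts) - 1L, function(i) {
    fit_model(spec, data, free = free, ga = ga, seed = seed0 + i, ...)
  })
  fits <- fits[order(vapply(fits, `[[`, 0, "objective"))]
  class(fits) <- "leuk_fit_ensemble"
  fits
}

#' @export
print.leuk_fit_ensemble <- function(x, ...) {
  objs <- vapply(x, `[[`, 0, "objective")
  cat("<leuk_fit_ensemble> ", length(x), " fits; objective ",
      format(min(objs), digits = 5), " .. ", format(max(objs), digits = 5),
      "\n", sep = "")
  invisible(x)
}

#' Fit a pool of candidate model structures
#'
#' Fits every candidate specification (e.g. from
#' [enumerate_structures()]) to the same dataset with the same seed and
#' ranks them by aggregate objective; ties are broken by fewer free
#' parameters, then by pool order. Candidates whose fit fails are ranked
#' last with the failure recorded.
#'
#' @param pool list of [model_spec()] objects.
#' @inheritParams fit_model
#' @return data.frame with columns `rank`, `name`, `objective`,
#'   `n_free`, `failed`; the fits themselves in `attr(, "fits")`.
#' @export
fit_structure_pool <- function(pool, data, ga = ga_config(), seed = 1L,
                               ...) {
  stopifnot(length(pool) >= 1)
  fits <- lapply(pool, function(sp) {
    tryCatch(fit_model(sp, data, ga = ga, seed = seed, ...),
             error = function(e) e)
  })
  failed <- vapply(fits, inherits, TRUE, "error")
  objs <- ifelse(failed, Inf, vapply(fits, function(f) {
    if (inherits(f, "leuk_fit")) f$objective else Inf
  }, 0))
  nfree <- vapply(pool, function(sp) length(sp$free), 0L)
  ord <- order(objs, nfree, seq_along(pool))
  out <- data.frame(
    rank = seq_along(pool),
    name = vapply(pool, `[[`, "", "name")[ord],
    objective = objs[ord],
    n_free = nfree[ord],
    failed = failed[ord]
  )
  attr(out, "fits") <- fits[ord]
  out
}

#' Practically identifiable parameters under a noise model
#'
#' Linearized (Fisher-information) identifiability analysis: the expected
#' sampling standard error of each free parameter is computed from the
#' sensitivity Jacobian of the noise-free observables at the current
#' parameter values, with per-point measurement noise `cv / sqrt(n_rep)`
#' times the observable (the standard error of a replicate mean under the
#' multiplicative noise model). A parameter counts as identifiable at
#' relative tolerance `tol` when its predicted 95 % half-width
#' (`1.96 * SE`) does not exceed `tol`. Observation points with zero true
#' value carry no relative information and are dropped.
#'
#' @param spec a [model_spec()].
#' @param free free parameter names (default `spec$free`).
#' @param cv,n_rep noise model of the planned experiment.
#' @param obs_days observation schedule (default `spec$obs_days`).
#' @param tol relative-error tolerance defining identifiability.
#' @param solver a [solver_control()].
#' @return character vector: the identifiable subset of `free`, with the
#'   predicted relative standard errors in `attr(, "rel_se")`.
#' @export
identifiable_parameters <- function(spec, free = spec$free, cv = 0.15,
                                    n_rep = 3, obs_days = spec$obs_days,
                                    tol = 0.25,
                                    solver = solver_control(rtol = 1e-6,
                                                            atol = 1e-3,
                                                            dense_dt = 21)) {
  stopifnot(length(free) >= 1, cv > 0)
  truth <- spec$params[free]
  simfun <- function(p) {
    ob <- observe(simulate_model(spec, params = p, obs_days = obs_days,
                                 span = range(c(0, obs_days)),
                                 solver = solver), obs_days)
    ob$value
  }
  base <- simfun(spec$params)
  keep <- base > 0
  sigma <- cv / sqrt(n_rep) * base[keep]
  J <- matrix(0, sum(keep), length(free))
  for (j in seq_along(free)) {
    p <- spec$params
    h <- max(truth[j] * 1e-4, 1e-10)
    p[free[j]] <- truth[j] + h
    # sensitivity w.r.t. the relative parameter, in noise units
    J[, j] <- ((simfun(p) - base)[keep] / sigma) * truth[j] / h
  }
  V <- tryCatch(solve(crossprod(J)), error = function(e) NULL)
  if (is.null(V)) .stopf("singular information matrix: no parameter is identifiable")
  rel_se <- sqrt(diag(V))
  names(rel_se) <- free
  out <- free[1.96 * rel_se <= tol]
  attr(out, "rel_se") <- rel_se
  out
}

#' Hierarchical fit of the nested model family
#'
#' Fits the model hierarchy in the order the levels are nested: the
#' tissue-level model first; then the HSC/HPC sub-model with the fitted
#' tissue-level leukemic BM trajectory frozen in as its exogenous forcing;
#' then (optionally) the G0 sub-model against the quiescent-fraction and
#' total-HSC series, under the same forcing.
#'
#' @param tissue_data tissue-level kinetics dataset.
#' @param hsc_data HSC/HPC dataset, or `NULL` to skip that level.
#' @param g0_data G0-level dataset, or `NULL` to skip.
#' @param tissue_spec,hsc_spec,g0_spec model specs; defaults are the
#'   canonical models. `hsc_spec`/`g0_spec` may be functions taking the
#'   fitted forcing and returning a spec (the defaults are
#'   [hsc_hpc_model()] and [g0_model()]).
#' @param ga a [ga_config()].
#' @param seed integer seed (levels use `seed`, `seed + 1`, `seed + 2`).
#' @param ... passed to [fit_model()].
#' @return list with elements `tissue`, `hsc_hpc`, `g0` (each a
#'   `leuk_fit` or `NULL`) and `forcing`.
#' @export
fit_hierarchical <- function(tissue_data, hsc_data = NULL, g0_data = NULL,
                             tissue_spec = tissue_model(),
                             hsc_spec = hsc_hpc_model,
                             g0_spec = g0_model,
                             ga = ga_config(), seed = 1L, ...) {
  ft <- fit_model(tissue_spec, tissue_data, ga = ga, seed = seed, ...)
  forcing <- default_forcing(tissue_spec, params = ft$params)
  fh <- fg <- NULL
  if (!is.null(hsc_data)) {
    sp <- if (is.function(hsc_spec)) hsc_spec(forcing) else hsc_spec
    fh <- fit_model(sp, hsc_data, ga = ga, seed = seed + 1L, ...)
  }
  if (!is.null(g0_data)) {
    sp <- if (is.function(g0_spec)) g0_spec(forcing = forcing) else g0_spec
    fg <- fit_model(sp, g0_data, ga = ga, seed = seed + 2L, ...)
  }
  list(tissue = ft, hsc_hpc = fh, g0 = fg, forcing = forcing)
}
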