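#' Solver configuration
#'
#' @param method deSolve integration method; the default `"lsoda"`
#'   automatically switches to a Gear-type backward-differentiation scheme
#'   on stiff stretches.
#' @param rtol,atol relative / absolute (cells) solver tolerances.
#' @param dense_dt spacing (days) of the dense output grid.
#' @param neg_tol nonnegativity guard: integration aborts if any state
#'   falls below `-neg_tol * sum(x0)`.
#' @return a list of class `solver_control`.
#' @export
solver_control <- function(method = "lsoda", rtol = 1e-8, atol = 1e-6,
                           dense_dt = 0.1, neg_tol = 1e-9) {
  structure(list(method = method, rtol = rtol, atol = atol,
                 dense_dt = dense_dt, neg_tol = neg_tol),
            class = "solver_control")
}

#' Simulate a compartment model
#'
#' Integrates the assembled ODE system over `span` with a stiff-capable
#' adaptive multistep solver and returns the dense trajectory. Observation
#' days are inserted into the solver's output grid, so values at those days
#' come from the integrator's dense output rather than interpolation of
#' coarse steps. Rates of consumptive processes are evaluated on
#' `max(X, 0)` and states are clipped at zero afterwards; a violation
#' beyond the guard tolerance aborts with an error.
#'
#' @param spec a [model_spec()].
#' @param params optional named parameter vector overriding spec values.
#' @param x0 initial state (default `spec$init`).
#' @param span `c(t0, t1)` in days.
#' @param obs_days observation days to include in the grid (default
#'   `spec$obs_days`).
#' @param solver a [solver_control()].
#' @return object of class `leuk_trajectory`: list with `times`, `state`
#'   (time x populations matrix), `obs_days`, `solver`.
#' @export
simulate_model <- function(spec, params = NULL, x0 = NULL,
                           span = c(0, 21), obs_days = NULL,
                           solver = solver_control()) {
  stopifnot(inherits(spec, "model_spec"), length(span) == 2,
            span[2] > span[1])
  cm <- compile_model(spec, params)
  if (is.null(x0)) x0 <- cm$init
  if (any(x0 < 0)) .stopf("initial state must be nonnegative")
  if (is.null(obs_days)) obs_days <- spec$obs_days
  obs_days <- obs_days[obs_days >= span[1] & obs_days <= span[2]]
  times <- sort(unique(c(seq(span[1], span[2], by = solver$dense_dt),
                         span[2], obs_days)))
  func <- function(t, y, p) list(as.vector(cm$S %*% .process_rates(cm, y, t)))
  sol <- deSolve::ode(y = unname(x0), times = times, func = func,
                      parms = NULL, method = solver$method,
                      rtol = solver$rtol, atol = solver$atol)
  istate <- attr(sol, "istate")[1]
  if (!is.null(istate) && istate < 0) {
    .stopf("integration failed (istate=%d) near t=%.3f", istate,
           max(sol[, 1], na.rm = TRUE))
  }
  state <- unclass(sol)[, -1, drop = FALSE]
  if (anyNA(state)) .stopf("integration produced NA states")
  colnames(state) <- cm$states
  guard <- -solver$neg_tol * sum(x0)
  if (min(state) < guard) {
    .stopf("state went negative beyond guard tolerance (min=%g)", min(state))
  }
  state[state < 0] <- 0
  structure(list(times = sol[, 1], state = state, obs_days = obs_days,
                 solver = solver, spec_name = spec$name),
            class = "leuk_trajectory")
}

#' @export
print.leuk_trajectory <- function(x, ...) {
  cat("<leuk_trajectory> ", x$spec_name, ": ", length(x$times),
      " time points over [", min(x$times), ", ", max(x$times), "] days, ",
      ncol(x$state), " populations\n", sep = "")
  invisible(x)
}

#' Tidy view of a trajectory
#'
#' @param x a `leuk_trajectory`.
#' @param row.names,optional,... passed for S3 compatibility (unused).
#' @return data.frame with columns `day`, `compartment`, `population`,
#'   `count`.
#' @export
as.data.frame.leuk_trajectory <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  pops <- colnames(x$state)
  data.frame(
    day = rep(x$times, times = length(pops)),
    compartment = rep(sub("\\..*", "", pops), each = length(x$times)),
    population = rep(sub("^[^.]*\\.", "", pops), each = length(x$times)),
    count = as.vector(x$state)
  )
}

# state rows of a trajectory at requested days (must be grid points)
.traj_at <- function(traj, days) {
  i <- match(round(days, 9), round(traj$times, 9))
  if (anyNA(i)) .stopf("day(s) %s not on the trajectory grid",
                       paste(days[is.na(i)], collapse = ", "))
  traj$state[i, , drop = FALSE]
}

#' Observe a trajectory as series means
#'
#' Projects a simulated trajectory onto the observable series of its
#' hierarchy level, without noise:
#' * tissue level: one series per `(tissue, normal/leukemic)` state;
#' * HSC/HPC level: the `BM.HSC` and `BM.HPC` counts;
#' * G0 level: the total HSC count (`HSC_G0 + HSC_active`, population
#'   `"HSC"`) and the quiescent fraction `HSC_G0 / (HSC_G0 + HSC_active)`
#'   (population `"HSC_G0"`, dimensionless).
#'
#' @param traj a `leuk_trajectory`.
#' @param obs_days days to observe at (default: the trajectory's).
#' @return data.frame with columns `tissue`, `population`, `day`, `value`.
#' @export
observe <- function(traj, obs_days = NULL) {
  stopifnot(inherits(traj, "leuk_trajectory"))
  if (is.null(obs_days)) obs_days <- traj$obs_days
  st <- .traj_at(traj, obs_days)
  pops <- colnames(st)
  if (all(c("BM.HSC_G0", "BM.HSC_active") %in% pops)) {
    q <- st[, "BM.HSC_G0"]; a <- st[, "BM.HSC_active"]
    tot <- q + a
    frac <- ifelse(tot > 0, q / tot, NA_real_)
    return(rbind(
      data.frame(tissue = "BM", population = "HSC", day = obs_days,
                 value = tot),
      data.frame(tissue = "BM", population = "HSC_G0", day = obs_days,
                 value = frac)
    ))
  }
  do.call(rbind, lapply(pops, function(p) {
    data.frame(tissue = sub("\\..*", "", p),
               population = sub("^[^.]*\\.", "", p),
               day = obs_days, value = unname(st[, p]))
  }))
}
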