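#' Cellular process specification
#'
#' Declares one process (proliferation, death, migration, differentiation,
#' G0 transitions, ...) acting on a population of a compartment model. A
#' process removes cells from `source`, adds them to `sink` (either may be
#' `NULL`, meaning an external source/sink), is driven by the cell count of
#' the `driver` state through a [rate_form()], and may be scaled by a
#' [leuk_modifier()] evaluated on the `burden` state (a leukemic cell count,
#' or the exogenous forcing of a nested sub-model).
#'
#' @param kind process kind: one of `"Prolif"`, `"Death"`, `"Export"`,
#'   `"Import"`, `"Expn"`, `"Diff"`, `"HSC_to_HPC"`, `"G0_exit"`,
#'   `"G0_reentry"`.
#' @param pool the `"<compartment>.<population>"` label the process belongs
#'   to (used for naming and decomposition).
#' @param form a [rate_form()].
#' @param source,sink state names (or `NULL` for an external source/sink).
#' @param driver state whose count the form is evaluated on; defaults to
#'   `source` if present, else `sink`.
#' @param modifier a [leuk_modifier()] (default: none).
#' @param burden state feeding the modifier, or `"forcing"` for the
#'   exogenous leukemic forcing of a sub-model, or `NULL`.
#' @return An object of class `process_spec`.
#' @export
process_spec <- function(kind, pool, form, source = NULL, sink = NULL,
                         driver = NULL, modifier = leuk_modifier("none"),
                         burden = NULL) {
  kind <- match.arg(kind, c("Prolif", "Death", "Export", "Import", "Expn",
                            "Diff", "HSC_to_HPC", "G0_exit", "G0_reentry"))
  stopifnot(inherits(form, "rate_form"), inherits(modifier, "leuk_modifier"))
  if (is.null(driver)) driver <- if (!is.null(source)) source else sink
  if (is.null(driver) && form$kind != "zero_order") {
    .stopf("process %s.%s: non-constant form needs a driver state", pool, kind)
  }
  # consumptive zero-order rates are gated to zero when the source is empty
  gate <- form$kind == "zero_order" && !is.null(source)
  structure(list(label = paste(pool, kind, sep = "."), kind = kind,
                 pool = pool, source = source, sink = sink, driver = driver,
                 modifier = modifier, burden = burden, form = form,
                 gate = gate),
            class = "process_spec")
}

#' Compartment model specification
#'
#' Assembles processes, initial state and metadata into a declarative model
#' specification. State names follow the `"<compartment>.<population>"`
#' convention (e.g. `"SP.normal"`, `"BM.leukemic"`, `"BM.HSC_G0"`).
#'
#' @param name model label.
#' @param init named nonnegative initial state vector (cells).
#' @param processes list of [process_spec()] objects.
#' @param mobility_mode `"pb_coupled"`, `"constant"` or `"zero"` (normal-cell
#'   mobility between tissues).
#' @param g0_reentry `"on"` or `"off"`.
#' @param hierarchy_level `"tissue"`, `"hsc_hpc"` or `"g0"`.
#' @param forcing `NULL`, or a list with components `times` and `values`
#'   giving the exogenous leukemic-burden time course driving a nested
#'   sub-model.
#' @param free character vector of default free parameter names for fitting.
#' @param bounds named list of `c(lower, upper)` overrides for parameter
#'   bounds (defaults are derived from the parameter values).
#' @param obs_days default observation days.
#' @return An object of class `model_spec` with components `params`,
#'   `lower`, `upper` (the flat parameter set and its bounds).
#' @export
model_spec <- function(name, init, processes,
                       mobility_mode = c("pb_coupled", "constant", "zero"),
                       g0_reentry = c("off", "on"),
                       hierarchy_level = c("tissue", "hsc_hpc", "g0"),
                       forcing = NULL, free = character(),
                       bounds = list(), obs_days = c(0, 7, 10, 12, 14, 21)) {
  mobility_mode <- match.arg(mobility_mode)
  g0_reentry <- match.arg(g0_reentry)
  hierarchy_level <- match.arg(hierarchy_level)
  stopifnot(is.numeric(init), !is.null(names(init)), all(init >= 0))
  labels <- vapply(processes, `[[`, "", "label")
  if (anyDuplicated(labels)) {
    .stopf("duplicated process labels: %s",
           paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  names(processes) <- labels
  spec <- structure(list(name = name, init = init, processes = processes,
                         mobility_mode = mobility_mode,
                         g0_reentry = g0_reentry,
                         hierarchy_level = hierarchy_level,
                         forcing = forcing, free = free,
                         obs_days = obs_days),
                    class = "model_spec")
  ps <- .collect_params(spec)
  spec$params <- ps
  bl <- .default_bounds(ps)
  for (nm in names(bounds)) {
    if (!nm %in% names(ps)) .stopf("bounds given for unknown parameter '%s'", nm)
    bl$lower[nm] <- bounds[[nm]][1]
    bl$upper[nm] <- bounds[[nm]][2]
  }
  spec$lower <- bl$lower
  spec$upper <- bl$upper
  bad <- setdiff(free, names(ps))
  if (length(bad)) .stopf("free parameter(s) not in model: %s",
                          paste(bad, collapse = ", "))
  spec
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", x$name, " (", x$hierarchy_level,
      " level, mobility=", x$mobility_mode, ")\n", sep = "")
  cat("  states:   ", paste(names(x$init), collapse = ", "), "\n", sep = "")
  cat("  processes:", length(x$processes), " | parameters: ",
      length(x$params), " (", length(x$free), " free)\n", sep = "")
  invisible(x)
}

.modifier_param_names <- function(direction) {
  switch(direction,
         none = character(),
         suppressive = c("w", "theta_L", "h_L"),
         stimulative = c("beta", "theta_L", "h_L"))
}

.collect_params <- function(spec) {
  out <- numeric()
  for (p in spec$processes) {
    fp <- unlist(p$form$params)
    names(fp) <- paste(p$label, names(fp), sep = ".")
    out <- c(out, fp)
    mp <- .modifier_param_names(p$modifier$direction)
    if (length(mp)) {
      mv <- unlist(p$modifier[mp])
      names(mv) <- paste(p$label, "coupling", mp, sep = ".")
      out <- c(out, mv)
    }
  }
  out
}

# Default parameter bounds: Hill coefficients on [1, 30], coupling weights on
# [0, 1], stimulation strengths on [0, 8], saturation scales two decades
# around the default, rate constants a factor of 8 around the default.
.default_bounds <- function(params) {
  lower <- params
  upper <- params
  for (nm in names(params)) {
    v <- params[[nm]]
    leaf <- sub(".*\\.", "", nm)
    if (leaf %in% c("h", "h_L")) {
      lower[nm] <- 1; upper[nm] <- 30
    } else if (leaf == "w") {
      lower[nm] <- 0; upper[nm] <- 1
    } else if (leaf == "beta") {
      lower[nm] <- 0; upper[nm] <- 8
    } else if (leaf %in% c("theta_L", "theta", "km") ||
               (leaf == "k" && grepl("\\.coupling\\.", nm))) {
      lower[nm] <- if (v > 0) v / 10 else 1
      upper[nm] <- if (v > 0) v * 10 else 1e7
    } else {
      # rate constants / vmax / zero-order constants
      lower[nm] <- if (v > 0) v / 8 else 0
      upper[nm] <- if (v > 0) v * 8 else 1
    }
  }
  list(lower = lower, upper = upper)
}

#' Update model parameters
#'
#' Writes values from a flat named parameter vector back into the process
#' forms and modifiers of a specification.
#'
#' @param spec a [model_spec()].
#' @param params named numeric vector; names must be a subset of
#'   `names(spec$params)`.
#' @return the updated `model_spec`.
#' @export
set_params <- function(spec, params) {
  stopifnot(inherits(spec, "model_spec"))
  bad <- setdiff(names(params), names(spec$params))
  if (length(bad)) .stopf("unknown parameter(s): %s", paste(bad, collapse = ", "))
  full <- spec$params
  full[names(params)] <- params
  for (i in seq_along(spec$processes)) {
    p <- spec$processes[[i]]
    for (fn in names(p$form$params)) {
      p$form$params[[fn]] <- unname(full[[paste(p$label, fn, sep = ".")]])
    }
    for (mn in .modifier_param_names(p$modifier$direction)) {
      p$modifier[[mn]] <- unname(full[[paste(p$label, "coupling", mn, sep = ".")]])
    }
    spec$processes[[i]] <- p
  }
  spec$params <- full
  spec
}

#' Reduce a model to its leukemia-free (control) counterpart
#'
#' Sets every leukemic-coupling parameter (names containing `".coupling."`)
#' to zero and every leukemic initial condition to zero, leaving all other
#' parameters bit-identical. All leukemic-influence modifiers then evaluate
#' to `K == 1` and leukemic populations stay identically zero, so the model
#' reduces to its unmodified normal-hematopoiesis form.
#'
#' @param spec a [model_spec()].
#' @return the control-reduced `model_spec`. Idempotent.
#' @export
reduce_to_control <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  params <- spec$params
  params[grepl(".coupling.", names(params), fixed = TRUE)] <- 0
  spec <- set_params(spec, params)
  leuk <- grepl("\\.leukemic$", names(spec$init))
  spec$init[leuk] <- 0
  if (!is.null(spec$forcing)) {
    spec$forcing$values[] <- 0
  }
  spec
}

#' Validate a model specification
#'
#' Checks the structural invariants of the tri-tissue topology:
#' no direct spleen-bone-marrow migration (all inter-tissue connection is
#' via the peripheral blood), no proliferation process on the PB normal
#' population, existing source/sink/driver/burden states, and G0 processes
#' only in a G0-level model (with the re-entry process present iff
#' `g0_reentry == "on"`).
#'
#' @param spec a [model_spec()].
#' @return character vector of violations (empty if the spec is valid).
#' @export
validate_spec <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  v <- character()
  states <- names(spec$init)
  comp_of <- function(s) sub("\\..*", "", s)
  for (p in spec$processes) {
    for (role in c("source", "sink", "driver")) {
      s <- p[[role]]
      if (!is.null(s) && !s %in% states) {
        v <- c(v, sprintf("%s: %s state '%s' not in model", p$label, role, s))
      }
    }
    if (!is.null(p$burden) && p$burden != "forcing" &&
        !p$burden %in% states) {
      v <- c(v, sprintf("%s: burden state '%s' not in model", p$label, p$burden))
    }
    if (!is.null(p$burden) && p$burden == "forcing" && is.null(spec$forcing)) {
      v <- c(v, sprintf("%s: burden is 'forcing' but spec has no forcing", p$label))
    }
    if (!is.null(p$source) && !is.null(p$sink)) {
      cs <- comp_of(p$source); ct <- comp_of(p$sink)
      if (cs != ct && !("PB" %in% c(cs, ct))) {
        v <- c(v, sprintf("%s: direct %s-%s edge; inter-tissue migration must be via PB",
                          p$label, cs, ct))
      }
    }
    if (p$pool == "PB.normal" && p$kind %in% c("Prolif", "Expn")) {
      v <- c(v, sprintf("%s: PB normal cells have no proliferation", p$label))
    }
    if (p$kind %in% c("G0_exit", "G0_reentry") &&
        spec$hierarchy_level != "g0") {
      v <- c(v, sprintf("%s: G0 process outside a g0-level model", p$label))
    }
    if (p$kind == "HSC_to_HPC") {
      if (is.null(p$source) || !grepl("HSC", p$source) ||
          is.null(p$sink) || !grepl("HPC", p$sink)) {
        v <- c(v, sprintf("%s: HSC_to_HPC must take HSC (or HSC_active) to HPC", p$label))
      }
    }
  }
  kinds <- vapply(spec$processes, `[[`, "", "kind")
  has_reentry <- any(kinds == "G0_reentry")
  if (spec$hierarchy_level == "g0") {
    if (spec$g0_reentry == "on" && !has_reentry) {
      v <- c(v, "g0_reentry is 'on' but no G0_reentry process present")
    }
    if (spec$g0_reentry == "off" && has_reentry) {
      v <- c(v, "g0_reentry is 'off' but a G0_reentry process is present")
    }
  }
  v
}

#' Enumerate candidate model structures
#'
#' Expands a template specification into the finite pool of concrete models
#' obtained by assigning each listed process one of its candidate kinetic
#' forms (Cartesian product). Ordering is deterministic: lexicographic by
#' process label, then by form kind, with the alphabetically first process
#' varying slowest.
#'
#' @param template a [model_spec()].
#' @param candidates named list: process label -> list of candidate
#'   [rate_form()] objects (with default parameter values).
#' @param cap maximum number of structures returned; excess candidates are
#'   dropped with a warning.
#' @return list of `model_spec` objects.
#' @export
enumerate_structures <- function(template, candidates, cap = 64L) {
  stopifnot(inherits(template, "model_spec"), cap >= 1)
  if (length(candidates) == 0) .stopf("no candidate lists supplied")
  bad <- setdiff(names(candidates), names(template$processes))
  if (length(bad)) .stopf("candidates for unknown process(es): %s",
                          paste(bad, collapse = ", "))
  labels <- sort(names(candidates))
  kinds <- lapply(labels, function(l) {
    forms <- candidates[[l]]
    if (length(forms) == 0) .stopf("empty candidate list for process '%s'", l)
    forms[order(vapply(forms, `[[`, "", "kind"))]
  })
  names(kinds) <- labels
  idx <- lapply(kinds, seq_along)
  grid <- rev(expand.grid(rev(idx), KEEP.OUT.ATTRS = FALSE))
  total <- nrow(grid)
  if (total > cap) {
    warning(sprintf("structure pool truncated: %d candidates capped to %d",
                    total, cap), call. = FALSE)
    grid <- grid[seq_len(cap), , drop = FALSE]
  }
  out <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    procs <- template$processes
    newfree <- character()
    for (j in seq_along(labels)) {
      l <- labels[j]
      form <- kinds[[l]][[grid[r, j]]]
      procs[[l]]$form <- form
      newfree <- c(newfree, paste(l, names(form$params), sep = "."))
    }
    sp <- model_spec(name = sprintf("%s#%d", template$name, r),
                     init = template$init, processes = unname(procs),
                     mobility_mode = template$mobility_mode,
                     g0_reentry = template$g0_reentry,
                     hierarchy_level = template$hierarchy_level,
                     forcing = template$forcing,
                     obs_days = template$obs_days)
    sp$free <- unique(c(intersect(template$free, names(sp$params)),
                        intersect(newfree, names(sp$params))))
    # keep template bounds for parameters that survived the swap
    keep <- intersect(names(template$lower), names(sp$lower))
    sp$lower[keep] <- template$lower[keep]
    sp$upper[keep] <- template$upper[keep]
    out[[r]] <- sp
  }
  out
}
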