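#' Canonical tri-tissue model of hematopoiesis under leukemia
#'
#' Builds the default three-compartment (peripheral blood `PB`, spleen `SP`,
#' bone marrow `BM`) model with a normal and a leukemic population per
#' tissue. Leukemic cells grow by first-order proliferation limited by a
#' suppressive Hill term in their own count (logistic-like saturation), die
#' at a small first-order rate, and migrate between tissues via PB. Normal
#' cells proliferate in SP (mildly stimulated by the local leukemic burden,
#' a compensatory response) and in BM (suppressed by the BM leukemic
#' burden), die first-order, and migrate via PB; tissue export is
#' stimulated by the local leukemic burden (escape from the deteriorating
#' environment). PB normal cells have no proliferation process.
#'
#' The default parameter values place the leukemia-free (control) system at
#' an exact steady state, and generate the characteristic leukemia
#' kinetics: monotone leukemic expansion in all tissues, a PB normal-cell
#' rise after day 7, a spleen rise-then-fall with the maximum before day
#' 21, and a BM decline reaching its minimum at day 21.
#'
#' @param mobility `"pb_coupled"` (imports into SP/BM are first-order in
#'   the PB count of the same population, and tissue exports feed the PB
#'   pool: mass-balanced migration), `"constant"` (imports are zero-order
#'   constants unrelated to PB kinetics; no mass balance), or `"zero"` (no
#'   normal-cell migration at all). Leukemic-cell transport stays
#'   PB-coupled in every variant so that the variants contest only the
#'   normal-cell mobility mechanism.
#' @return a [model_spec()] with default parameters, bounds and free set.
#' @export
tissue_model <- function(mobility = c("pb_coupled", "constant", "zero")) {
  mobility <- match.arg(mobility)
  init <- c(PB.normal = 2e4, SP.normal = 1e5, BM.normal = 2e5,
            PB.leukemic = 0, SP.leukemic = 0, BM.leukemic = 1e3)

  fo <- function(k) rate_form("first_order", k = k)
  zo <- function(k) rate_form("zero_order", k = k)
  supp <- function(theta, h, w = 1) {
    leuk_modifier("suppressive", theta_L = theta, h_L = h, w = w)
  }
  stim <- function(beta, theta, h) {
    leuk_modifier("stimulative", beta = beta, theta_L = theta, h_L = h)
  }

  # leukemic populations: PB-coupled transport in every variant
  procs <- list(
    process_spec("Prolif", "BM.leukemic", fo(0.65), sink = "BM.leukemic",
                 driver = "BM.leukemic",
                 modifier = supp(6e5, 2), burden = "BM.leukemic"),
    process_spec("Death", "BM.leukemic", fo(0.05), source = "BM.leukemic"),
    process_spec("Export", "BM.leukemic", fo(0.05), source = "BM.leukemic",
                 sink = "PB.leukemic"),
    process_spec("Import", "BM.leukemic", fo(0.10), source = "PB.leukemic",
                 sink = "BM.leukemic", driver = "PB.leukemic"),
    process_spec("Prolif", "SP.leukemic", fo(0.55), sink = "SP.leukemic",
                 driver = "SP.leukemic",
                 modifier = supp(6e5, 2), burden = "SP.leukemic"),
    process_spec("Death", "SP.leukemic", fo(0.05), source = "SP.leukemic"),
    process_spec("Export", "SP.leukemic", fo(0.05), source = "SP.leukemic",
                 sink = "PB.leukemic"),
    process_spec("Import", "SP.leukemic", fo(0.20), source = "PB.leukemic",
                 sink = "SP.leukemic", driver = "PB.leukemic"),
    process_spec("Death", "PB.leukemic", fo(0.05), source = "PB.leukemic")
  )

  # normal populations
  procs <- c(procs, list(
    process_spec("Prolif", "SP.normal", fo(0.2), sink = "SP.normal",
                 driver = "SP.normal",
                 modifier = stim(0.3, 8e4, 2), burden = "SP.leukemic"),
    process_spec("Death", "SP.normal", fo(0.2), source = "SP.normal"),
    process_spec("Prolif", "BM.normal", fo(0.125), sink = "BM.normal",
                 driver = "BM.normal",
                 modifier = supp(1.2e5, 2), burden = "BM.leukemic"),
    process_spec("Death", "BM.normal", fo(0.1), source = "BM.normal"),
    process_spec("Death", "PB.normal", fo(0.25), source = "PB.normal")
  ))

  mob <- switch(mobility,
    pb_coupled = list(
      process_spec("Export", "SP.normal", fo(0.1), source = "SP.normal",
                   sink = "PB.normal",
                   modifier = stim(4, 1.2e5, 2), burden = "SP.leukemic"),
      process_spec("Import", "SP.normal", fo(0.5), source = "PB.normal",
                   sink = "SP.normal", driver = "PB.normal"),
      process_spec("Export", "BM.normal", fo(0.05), source = "BM.normal",
                   sink = "PB.normal",
                   modifier = stim(3, 8e4, 2), burden = "BM.leukemic"),
      process_spec("Import", "BM.normal", fo(0.25), source = "PB.normal",
                   sink = "BM.normal", driver = "PB.normal")
    ),
    constant = list(
      process_spec("Export", "SP.normal", fo(0.1), source = "SP.normal",
                   modifier = stim(4, 1.2e5, 2), burden = "SP.leukemic"),
      process_spec("Import", "SP.normal", zo(1e4), sink = "SP.normal"),
      process_spec("Export", "BM.normal", fo(0.05), source = "BM.normal",
                   modifier = stim(3, 8e4, 2), burden = "BM.leukemic"),
      process_spec("Import", "BM.normal", zo(5e3), sink = "BM.normal"),
      process_spec("Export", "PB.normal", fo(0.75), source = "PB.normal"),
      process_spec("Import", "PB.normal", zo(2e4), sink = "PB.normal")
    ),
    zero = list()
  )
  procs <- c(procs, mob)

  free <- switch(mobility,
    pb_coupled = c("BM.leukemic.Prolif.k", "SP.leukemic.Prolif.k",
                   "PB.normal.Death.k", "BM.normal.Prolif.k",
                   "SP.normal.Import.k", "SP.normal.Export.k",
                   "BM.normal.Export.k"),
    constant = c("BM.leukemic.Prolif.k", "SP.leukemic.Prolif.k",
                 "PB.normal.Death.k", "BM.normal.Prolif.k",
                 "SP.normal.Import.k", "BM.normal.Import.k",
                 "PB.normal.Import.k", "SP.normal.Export.k",
                 "BM.normal.Export.k"),
    zero = c("BM.leukemic.Prolif.k", "SP.leukemic.Prolif.k",
             "PB.normal.Death.k", "BM.normal.Prolif.k",
             "SP.normal.Prolif.k", "SP.normal.Death.k",
             "BM.normal.Death.k")
  )

  model_spec(name = paste0("tissue_", mobility), init = init,
             processes = procs, mobility_mode = mobility,
             hierarchy_level = "tissue", free = free)
}

#' Nested HSC/HPC sub-model of the leukemic bone marrow
#'
#' Two-pool sub-model of the primitive hematopoietic populations in BM:
#' stem cells (`BM.HSC`) expand (self-renew), die, and differentiate
#' towards progenitors (`BM.HPC`); progenitors expand, differentiate out
#' towards mature lineages (a sink at this level), and die. The leukemic BM
#' burden enters as an exogenous forcing `L(t)`: it suppresses HSC
#' expansion, HSC-to-HPC differentiation (the differentiation blockade) and
#' HPC expansion (earlier and more sharply, which is why HPCs collapse
#' faster than HSCs), and mildly stimulates HPC death.
#'
#' @param forcing list with `times` and `values`: the leukemic BM time
#'   course driving the modifiers. Defaults to the noise-free
#'   `BM.leukemic` trajectory of [tissue_model()] at its default
#'   parameters.
#' @return a [model_spec()] at hierarchy level `"hsc_hpc"`.
#' @export
hsc_hpc_model <- function(forcing = NULL) {
  if (is.null(forcing)) forcing <- default_forcing()
  fo <- function(k) rate_form("first_order", k = k)
  supp <- function(theta, h) {
    leuk_modifier("suppressive", theta_L = theta, h_L = h)
  }
  init <- c(BM.HSC = 5e3, BM.HPC = 5e4)
  procs <- list(
    process_spec("Expn", "BM.HSC", fo(0.12), sink = "BM.HSC",
                 driver = "BM.HSC", modifier = supp(1.8e5, 3),
                 burden = "forcing"),
    process_spec("Death", "BM.HSC", fo(0.02), source = "BM.HSC"),
    process_spec("HSC_to_HPC", "BM.HSC", fo(0.1), source = "BM.HSC",
                 sink = "BM.HPC", modifier = supp(6e5, 4),
                 burden = "forcing"),
    process_spec("Expn", "BM.HPC", fo(0.5), sink = "BM.HPC",
                 driver = "BM.HPC", modifier = supp(1.2e5, 3),
                 burden = "forcing"),
    process_spec("Diff", "BM.HPC", fo(0.5), source = "BM.HPC"),
    process_spec("Death", "BM.HPC", fo(0.01), source = "BM.HPC",
                 modifier = leuk_modifier("stimulative", beta = 0.5,
                                          theta_L = 3e5, h_L = 2),
                 burden = "forcing")
  )
  # HSC expansion and HSC differentiation are mutually compensating on
  # six-point series (either can absorb the stem-cell turnover), so the
  # default free set holds Expn.k and frees the differentiation arm
  free <- c("BM.HSC.HSC_to_HPC.k", "BM.HSC.HSC_to_HPC.coupling.theta_L",
            "BM.HPC.Expn.k", "BM.HPC.Expn.coupling.theta_L")
  model_spec(name = "hsc_hpc", init = init, processes = procs,
             hierarchy_level = "hsc_hpc", forcing = forcing, free = free)
}

#' Quiescence (G0) sub-model of bone-marrow HSCs
#'
#' Splits the BM HSC pool into quiescent (`BM.HSC_G0`) and cycling
#' (`BM.HSC_active`) cells. Activation (`G0_exit`) moves cells out of G0 at
#' a first-order rate sharply suppressed by the leukemic burden; the
#' re-entry variant (`reentry = TRUE`) adds a `G0_reentry` process moving
#' cycling cells back into G0, strongly stimulated by the leukemic burden.
#' Expansion and differentiation act on the cycling pool only; death acts
#' on both pools with separate constants. The no-re-entry counterpart
#' (`reentry = FALSE`) instead carries leukemia-stimulated death of the
#' cycling pool (selective exhaustion of cycling HSCs), so that model
#' selection contrasts two mechanisms rather than two parameter counts.
#'
#' The leukemic coupling of the G0 transitions is a steep Hill switch
#' (`h_L = 6`, threshold at the leukemic burden reached around day 12):
#' this keeps the G0 fraction flat (about 40 %) through day 10 and pushes
#' it above 92 % by day 14, the climb the cell-cycle data show.
#'
#' @param reentry logical; include the G0 re-entry process.
#' @inheritParams hsc_hpc_model
#' @return a [model_spec()] at hierarchy level `"g0"`.
#' @export
g0_model <- function(reentry = TRUE, forcing = NULL) {
  if (is.null(forcing)) forcing <- default_forcing()
  fo <- function(k) rate_form("first_order", k = k)
  theta_sw <- 4.8e5  # leukemic burden at the quiescence switch (~ day 11.8)
  h_sw <- 6
  init <- c(BM.HSC_G0 = 4e3, BM.HSC_active = 6e3)
  procs <- list(
    process_spec("G0_exit", "BM.HSC_G0", fo(0.3), source = "BM.HSC_G0",
                 sink = "BM.HSC_active",
                 modifier = leuk_modifier("suppressive", theta_L = theta_sw,
                                          h_L = h_sw),
                 burden = "forcing"),
    process_spec("Expn", "BM.HSC_active", fo(0.21), sink = "BM.HSC_active",
                 driver = "BM.HSC_active",
                 modifier = leuk_modifier("suppressive", theta_L = 2.5e5,
                                          h_L = 3),
                 burden = "forcing"),
    process_spec("Diff", "BM.HSC_active", fo(0.2), source = "BM.HSC_active",
                 modifier = leuk_modifier("suppressive", theta_L = 3e5,
                                          h_L = 3),
                 burden = "forcing"),
    process_spec("Death", "BM.HSC_active", fo(0.01),
                 source = "BM.HSC_active"),
    process_spec("Death", "BM.HSC_G0", fo(0), source = "BM.HSC_G0")
  )
  if (reentry) {
    procs <- c(procs, list(
      process_spec("G0_reentry", "BM.HSC_active", fo(0.2),
                   source = "BM.HSC_active", sink = "BM.HSC_G0",
                   modifier = leuk_modifier("stimulative", beta = 6,
                                            theta_L = theta_sw, h_L = h_sw),
                   burden = "forcing")
    ))
    free <- c("BM.HSC_G0.G0_exit.k",
              "BM.HSC_G0.G0_exit.coupling.theta_L",
              "BM.HSC_active.G0_reentry.k",
              "BM.HSC_active.G0_reentry.coupling.beta")
  } else {
    # exhaustion counterpart: leukemia-stimulated death of cycling HSCs
    procs[[4]] <- process_spec("Death", "BM.HSC_active", fo(0.01),
                               source = "BM.HSC_active",
                               modifier = leuk_modifier("stimulative",
                                                        beta = 6,
                                                        theta_L = theta_sw,
                                                        h_L = h_sw),
                               burden = "forcing")
    procs[[1]] <- process_spec("G0_exit", "BM.HSC_G0", fo(0),
                               source = "BM.HSC_G0", sink = "BM.HSC_active",
                               modifier = leuk_modifier("suppressive",
                                                        theta_L = theta_sw,
                                                        h_L = h_sw),
                               burden = "forcing")
    free <- c("BM.HSC_G0.G0_exit.k",
              "BM.HSC_active.Death.k",
              "BM.HSC_active.Death.coupling.beta",
              "BM.HSC_active.Death.coupling.theta_L")
  }
  model_spec(name = if (reentry) "g0_reentry_on" else "g0_reentry_off",
             init = init, processes = procs,
             g0_reentry = if (reentry) "on" else "off",
             hierarchy_level = "g0", forcing = forcing, free = free)
}
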