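test_that("decomposition conserves the trajectory derivative", {
  spec <- tissue_model()
  traj <- simulate_model(spec)
  times <- seq(0, 21, by = 0.5)
  dec <- decompose(spec, traj = traj, times = times)
  # exact against the assembled rhs
  expect_lt(decomposition_residual(dec, spec, traj = traj), 1e-8)
  # and against a central finite difference of the dense trajectory
  sums <- aggregate(signed_rate ~ time + compartment + population,
                    data = dec, FUN = sum)
  dt <- 0.1
  for (pop in c("SP.normal", "BM.leukemic")) {
    comp <- sub("\\..*", "", pop)
    p <- sub("^[^.]*\\.", "", pop)
    x <- traj$state[, pop]
    mid <- times[times >= dt & times <= 21 - dt]
    i <- match(round(mid, 9), round(traj$times, 9))
    fd <- (x[i + 1] - x[i - 1]) / (2 * dt)
    got <- sums$signed_rate[sums$compartment == comp & sums$population == p]
    got <- got[match(mid, sums$time[sums$compartment == comp &
                                      sums$population == p])]
    # dt = 0.1 central differences carry ~1e-2 truncation here
    expect_lt(max(abs(got - fd) / (abs(fd) + max(abs(fd)) * 1e-3)), 0.05)
  }
})

test_that("steady control models decompose to zero net rates", {
  ctrl <- reduce_to_control(tissue_model())
  traj <- simulate_model(ctrl)
  dec <- decompose(ctrl, traj = traj, times = c(0, 7, 14, 21))
  sums <- aggregate(signed_rate ~ time + compartment + population,
                    data = dec, FUN = sum)
  norm <- sums[sums$population == "normal", ]
  expect_lt(max(abs(norm$signed_rate)), 1e-4 * max(ctrl$init))
  # control-reduced rates equal the unmodified forms: every modifier is
  # silenced so each rate is the raw form evaluated on the state
  one <- dec[dec$time == 14 & dec$process == "BM.normal.Death" &
               dec$role == "loss", ]
  st <- traj$state[match(14, traj$times), "BM.normal"]
  expect_equal(one$rate, ctrl$params[["BM.normal.Death.k"]] * unname(st))
})

test_that("interval fluxes integrate rates and are additive", {
  # constant rate c: every unit-interval flux equals c
  c0 <- 37
  spec <- model_spec("const", init = c(BM.normal = 1000), processes = list(
    process_spec("Import", "BM.normal", rate_form("zero_order", k = c0),
                 sink = "BM.normal"),
    process_spec("Death", "BM.normal",
                 rate_form("first_order", k = c0 / 1000),
                 source = "BM.normal")))
  traj <- simulate_model(spec, span = c(0, 21))
  fl <- interval_flux(spec, traj = traj, process = "BM.normal.Import")
  expect_equal(nrow(fl), 21)
  expect_equal(fl$from, 0:20)
  expect_equal(fl$to, 1:21)
  expect_equal(fl$flux, rep(c0, 21), tolerance = 1e-8)
  # zero rate: all fluxes zero
  spec0 <- set_params(spec, c(BM.normal.Import.k = 0))
  fl0 <- interval_flux(spec0, traj = simulate_model(spec0, span = c(0, 21)),
                       process = "BM.normal.Import")
  expect_equal(fl0$flux, rep(0, 21))
  # additivity over a split interval
  hs <- hsc_hpc_model()
  trj <- simulate_model(hs)
  whole <- interval_flux(hs, traj = trj, process = "BM.HSC.HSC_to_HPC",
                         breaks = c(0, 14))
  parts <- interval_flux(hs, traj = trj, process = "BM.HSC.HSC_to_HPC",
                         breaks = c(0, 6, 14))
  expect_equal(whole$flux, sum(parts$flux), tolerance = 1e-6)
  expect_error(interval_flux(hs, traj = trj, process = "nope"),
               "unknown process")
})

test_that("factor ranking orders by mean absolute rate", {
  spec <- hsc_hpc_model()
  dec <- decompose(spec, traj = simulate_model(spec))
  rk <- rank_factors(dec, "BM.HSC")
  # by construction, HSC death is small and flat: last by both metrics
  expect_equal(rk$process[nrow(rk)], "BM.HSC.Death")
  expect_equal(rk$amplitude[nrow(rk)], min(rk$amplitude))
  expect_true(all(diff(rk$mean_abs_rate) <= 0))
  # the dominant factors are expansion and differentiation
  expect_setequal(rk$process[1:2], c("BM.HSC.Expn", "BM.HSC.HSC_to_HPC"))
  # deterministic tie-break on identical processes
  two <- model_spec("two", init = c(BM.normal = 10), processes = list(
    process_spec("Death", "BM.normal", rate_form("first_order", k = 0.1),
                 source = "BM.normal"),
    process_spec("Export", "BM.normal", rate_form("first_order", k = 0.1),
                 source = "BM.normal")))
  dec2 <- decompose(two, traj = simulate_model(two, span = c(0, 5)))
  rk2 <- rank_factors(dec2, "BM.normal")
  expect_equal(rk2$process, c("BM.normal.Death", "BM.normal.Export"))
  expect_error(rank_factors(dec2, "BM.normal", window = c(90, 99)),
               "empty")
})

test_that("variant comparison implements the one-tailed Welch test", {
  # identical samples: symmetric null
  same <- c(1.2, 1.5, 1.9, 2.2)
  cmp <- compare_variants(same, same, "a_lower")
  expect_equal(cmp$t, 0)
  expect_equal(cmp$p, 0.5)
  expect_equal(cmp$winner, "inconclusive")
  # reference statistic: hand-computed Welch t and one-tail p
  a <- c(1, 2, 3); b <- c(11, 12, 13)
  cmp2 <- compare_variants(a, b, "a_lower", labels = c("a", "b"))
  se <- sqrt(var(a) / 3 + var(b) / 3)
  tref <- (mean(a) - mean(b)) / se
  df <- se^4 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(cmp2$t, tref)
  expect_equal(cmp2$p, pt(tref, df))
  expect_equal(cmp2$winner, "a")
  # swapping the arguments complements the one-tail p
  cmp3 <- compare_variants(b, a, "a_lower")
  expect_equal(cmp3$p, 1 - cmp2$p)
  # degenerate zero-variance samples
  cmp4 <- compare_variants(c(1, 1), c(1, 1), "a_lower")
  expect_true(cmp4$degenerate)
  expect_equal(cmp4$p, 0.5)
})

test_that("null comparisons on exchangeable restart errors rarely reject", {
  spec <- toy_pool_model()
  data <- toy_dataset(spec, cv = 0.15, seed = 9)
  fits <- multi_restart(spec, data, n_restarts = 8, seed0 = 0,
                        ga = quick_ga(8, 5))
  errs <- vapply(fits, `[[`, 0, "objective")
  # random splits of the same variant's restarts: effect size zero
  set.seed(21)
  rejections <- 0
  for (i in 1:50) {
    pick <- sample(8, 4)
    a <- errs[pick]; b <- errs[-pick]
    if (sd(a) == 0 && sd(b) == 0) next
    p <- compare_variants(a, b, "a_lower")$p
    if (p < 0.05) rejections <- rejections + 1
  }
  expect_lte(rejections, 10)
})

test_that("two copies of the same variant are inconclusive", {
  spec <- toy_pool_model()
  data <- toy_dataset(spec, cv = 0.15, seed = 2)
  sel <- run_selection_experiment(
    data, list(copy1 = spec, copy2 = spec), ga = quick_ga(8, 5),
    n_restarts = 4, seed0 = 0)
  expect_length(sel$pairs, 1)
  expect_equal(sel$pairs[[1]]$winner, "inconclusive")
})
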