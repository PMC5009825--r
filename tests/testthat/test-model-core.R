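test_that("build_rhs assembles signed process sums", {
  # one-term sum: a single death process
  one <- model_spec("one", init = c(BM.normal = 100), processes = list(
    process_spec("Death", "BM.normal", rate_form("first_order", k = 0.3),
                 source = "BM.normal")))
  rhs <- build_rhs(one)
  expect_equal(rhs(0, c(BM.normal = 100)),
               c(BM.normal = -30))
  # exact balance: proliferation equals death at the initial state
  bal <- model_spec("bal", init = c(BM.normal = 200), processes = list(
    process_spec("Prolif", "BM.normal", rate_form("first_order", k = 0.2),
                 sink = "BM.normal", driver = "BM.normal"),
    process_spec("Death", "BM.normal", rate_form("first_order", k = 0.2),
                 source = "BM.normal")))
  expect_equal(unname(build_rhs(bal)(0, c(BM.normal = 200))), 0)
  # pure migration conserves the total over pools
  mig <- model_spec("mig", init = c(SP.normal = 80, PB.normal = 20),
                    processes = list(
    process_spec("Export", "SP.normal", rate_form("first_order", k = 0.4),
                 source = "SP.normal", sink = "PB.normal"),
    process_spec("Import", "SP.normal", rate_form("first_order", k = 0.1),
                 source = "PB.normal", sink = "SP.normal",
                 driver = "PB.normal")))
  dy <- build_rhs(mig)(0, c(SP.normal = 80, PB.normal = 20))
  expect_equal(sum(dy), 0)
})

test_that("rhs is linear in the assembled processes", {
  spec <- tissue_model()
  x <- spec$init + c(1000, 2000, 3000, 500, 700, 900)
  full <- build_rhs(spec)(1, x)
  drop_label <- "SP.normal.Death"
  reduced <- spec
  reduced$processes[[drop_label]] <- NULL
  reduced <- model_spec("reduced", init = spec$init,
                        processes = unname(reduced$processes),
                        mobility_mode = spec$mobility_mode,
                        hierarchy_level = spec$hierarchy_level)
  part <- build_rhs(reduced)(1, x)
  k <- spec$params[["SP.normal.Death.k"]]
  expect_equal(full[["SP.normal"]] - part[["SP.normal"]],
               -k * x[["SP.normal"]])
  others <- setdiff(names(full), "SP.normal")
  expect_equal(full[others], part[others])
})

test_that("structure enumeration is a deterministic cartesian product", {
  tpl <- model_spec("tpl", init = c(BM.normal = 100), processes = list(
    process_spec("Prolif", "BM.normal", rate_form("first_order", k = 0.2),
                 sink = "BM.normal", driver = "BM.normal"),
    process_spec("Death", "BM.normal", rate_form("first_order", k = 0.1),
                 source = "BM.normal")))
  cands <- list(
    "BM.normal.Prolif" = list(rate_form("first_order", k = 0.2),
                              rate_form("michaelis_menten", vmax = 30,
                                        km = 100),
                              rate_form("zero_order", k = 20)),
    "BM.normal.Death" = list(rate_form("first_order", k = 0.1),
                             rate_form("hill", vmax = 15, k = 80, h = 2),
                             rate_form("exponential_saturating", k = 12,
                                       theta = 50)))
  pool <- enumerate_structures(tpl, cands)
  expect_length(pool, 9)
  # lexicographic: first process label varies slowest, kinds sorted
  kinds <- t(vapply(pool, function(sp) {
    c(sp$processes[["BM.normal.Death"]]$form$kind,
      sp$processes[["BM.normal.Prolif"]]$form$kind)
  }, c("", "")))
  expect_equal(unique(kinds[1:3, 1]), "exponential_saturating")
  expect_equal(kinds[1:3, 2],
               c("first_order", "michaelis_menten", "zero_order"))
  expect_equal(unique(kinds[4:6, 1]), "first_order")
  # cap truncates deterministically with a warning
  expect_warning(pool4 <- enumerate_structures(tpl, cands, cap = 4),
                 "truncated")
  expect_length(pool4, 4)
  for (i in 1:4) expect_equal(pool4[[i]]$processes, pool[[i]]$processes)
  # single-candidate enumeration returns the template's structure
  pool1 <- enumerate_structures(tpl, cands["BM.normal.Death"][1], cap = 10)
  expect_length(pool1, 3)
  expect_error(enumerate_structures(tpl, list("BM.normal.Death" = list())),
               "empty candidate")
})

test_that("reduce_to_control purges couplings and leukemic cells only", {
  spec <- tissue_model()
  ctrl <- reduce_to_control(spec)
  cpl <- grepl(".coupling.", names(ctrl$params), fixed = TRUE)
  expect_true(all(ctrl$params[cpl] == 0))
  expect_identical(ctrl$params[!cpl], spec$params[!cpl])
  expect_true(all(ctrl$init[grepl("leukemic", names(ctrl$init))] == 0))
  # idempotent
  expect_identical(reduce_to_control(ctrl), ctrl)
  # leukemic series identically zero, normal series steady
  tr <- simulate_model(ctrl)
  expect_true(all(tr$state[, grepl("leukemic", colnames(tr$state))] == 0))
  for (s in c("PB.normal", "SP.normal", "BM.normal")) {
    expect_lt(max(abs(tr$state[, s] - tr$state[1, s])) / tr$state[1, s],
              1e-6)
  }
})

test_that("control reduction equals a model built with none modifiers", {
  spec <- tissue_model()
  ctrl <- reduce_to_control(spec)
  bare_procs <- lapply(unname(spec$processes), function(p) {
    p$modifier <- leuk_modifier("none")
    p$burden <- NULL
    p
  })
  bare <- model_spec("bare", init = ctrl$init, processes = bare_procs,
                     mobility_mode = spec$mobility_mode,
                     hierarchy_level = spec$hierarchy_level)
  bare <- set_params(bare, spec$params[!grepl(".coupling.",
                                              names(spec$params),
                                              fixed = TRUE)])
  t1 <- simulate_model(ctrl)
  t2 <- simulate_model(bare)
  expect_equal(t1$state, t2$state, tolerance = 1e-10)
})

test_that("validate_spec reports topology and proliferation violations", {
  expect_length(validate_spec(tissue_model()), 0)
  expect_length(validate_spec(tissue_model("constant")), 0)
  expect_length(validate_spec(tissue_model("zero")), 0)
  expect_length(validate_spec(g0_model(TRUE)), 0)
  expect_length(validate_spec(g0_model(FALSE)), 0)

  bad1 <- model_spec("bad1", init = c(PB.normal = 10), processes = list(
    process_spec("Prolif", "PB.normal", rate_form("first_order", k = 0.1),
                 sink = "PB.normal", driver = "PB.normal")))
  expect_match(validate_spec(bad1), "no proliferation", all = FALSE)

  bad2 <- model_spec("bad2", init = c(SP.normal = 10, BM.normal = 10),
                     processes = list(
    process_spec("Export", "SP.normal", rate_form("first_order", k = 0.1),
                 source = "SP.normal", sink = "BM.normal")))
  expect_match(validate_spec(bad2), "via PB", all = FALSE)

  # G0 process outside a g0-level model
  bad3 <- model_spec("bad3", init = c(BM.HSC_G0 = 1, BM.HSC_active = 1),
                     processes = list(
    process_spec("G0_exit", "BM.HSC_G0", rate_form("first_order", k = 0.1),
                 source = "BM.HSC_G0", sink = "BM.HSC_active")),
                     hierarchy_level = "tissue")
  expect_match(validate_spec(bad3), "g0-level", all = FALSE)
})

test_that("parameter vectors round-trip through set_params", {
  spec <- g0_model(TRUE)
  p <- spec$params
  p["BM.HSC_G0.G0_exit.k"] <- 0.123
  p["BM.HSC_active.G0_reentry.coupling.beta"] <- 2.5
  sp2 <- set_params(spec, p)
  expect_equal(sp2$params, p)
  expect_equal(sp2$processes[["BM.HSC_G0.G0_exit"]]$form$params$k, 0.123)
  expect_equal(sp2$processes[["BM.HSC_active.G0_reentry"]]$modifier$beta,
               2.5)
  expect_error(set_params(spec, c(nonsense = 1)), "unknown parameter")
})

test_that("model specs serialize to JSON losslessly", {
  for (spec in list(tissue_model(), tissue_model("constant"),
                    g0_model(TRUE))) {
    path <- withr::local_tempfile(fileext = ".json")
    write_model_spec(spec, path)
    back <- read_model_spec(path)
    expect_equal(back$params, spec$params)
    expect_equal(back$init, spec$init)
    expect_equal(back$lower, spec$lower)
    expect_equal(back$upper, spec$upper)
    expect_equal(names(back$processes), names(spec$processes))
    expect_equal(back$free, spec$free)
    # identical dynamics
    sv <- quick_solver()
    expect_equal(simulate_model(back, solver = sv)$state,
                 simulate_model(spec, solver = sv)$state)
  }
})
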