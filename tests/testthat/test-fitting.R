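test_that("rmsd matches hand arithmetic and its sampling behavior", {
  expect_equal(rmsd(c(10, 10, 10), c(10, 10, 10)), 0)
  expect_equal(rmsd(c(1, 3), c(1, 1)), sqrt(2), tolerance = 1e-5)
  expect_error(rmsd(1:3, 1:2), "equal length")
  # Monte-Carlo: for sim = obs + iid noise of SD sigma, mean d is near sigma
  set.seed(11)
  sigma <- 2.5
  d <- replicate(1e4, rmsd(rnorm(6, 0, sigma), rep(0, 6)))
  expect_lt(abs(mean(d) - sigma) / sigma, 0.05)
})

test_that("the d <= s criterion is boundary-inclusive", {
  expect_true(fitness_criterion(0.9, 1))
  expect_true(fitness_criterion(1, 1))
  expect_false(fitness_criterion(1.1, 1))
})

test_that("series SD pooling floors near-zero noise", {
  expect_equal(series_sd(c(8, 8, 8), c(100, 100, 100)), 8)
  expect_equal(series_sd(c(30, 40), c(100, 100)), sqrt(1250))
  # near-noiseless series are floored at 5 % of the mean
  expect_equal(series_sd(c(0, 0, 0), c(100, 100, 100)), 5)
  expect_equal(series_sd(c(2, 2, 2), c(100, 100, 100)), 5)
})

test_that("objective is invariant to series order and joint rescaling", {
  spec <- tissue_model()
  data <- default_data_noisy(1)
  sv <- quick_solver()
  obj1 <- leukodyn:::.make_objective(spec, data, spec$free, sv)
  shuffled <- data[rev(seq_len(nrow(data))), ]
  obj2 <- leukodyn:::.make_objective(spec, shuffled, spec$free, sv)
  z <- obj1$enc(spec$params[spec$free])
  expect_equal(obj1$value(z), obj2$value(z))
  # rescaling one series jointly with its sd only rescales that d and s;
  # d/s and hence the aggregate cannot change when the model series is
  # scaled identically, checked here on the stored table identity
  tab <- obj1$table(z)
  expect_equal(sum(tab$d / tab$s), obj1$value(z))
})

test_that("noise-free generate-and-refit recovers the truth", {
  spec <- tissue_model()
  data <- default_data_noisefree()
  free3 <- c("BM.leukemic.Prolif.k", "SP.leukemic.Prolif.k",
             "PB.normal.Death.k")
  fit <- fit_model(spec, data, free = free3, ga = quick_ga(),
                   seed = 1, solver = quick_solver())
  truth <- spec$params[free3]
  expect_lt(max(abs(fit$params[free3] - truth) / truth), 0.01)
  expect_lt(fit$objective, 0.05)
  expect_true(all(fit$series$pass))
})

test_that("fits are reproducible and elitism keeps history monotone", {
  spec <- toy_pool_model()
  data <- toy_dataset(spec, cv = 0.1, seed = 3)
  f1 <- fit_model(spec, data, ga = quick_ga(12, 8), seed = 5)
  f2 <- fit_model(spec, data, ga = quick_ga(12, 8), seed = 5)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$objective, f2$objective)
  expect_true(all(diff(f1$history) <= 1e-12))
  # criterion flags recomputable from the stored d and s
  expect_identical(f1$series$pass, f1$series$d <= f1$series$s)
})

test_that("multi_restart returns sorted, seed-stamped fits", {
  spec <- toy_pool_model()
  data <- toy_dataset(spec, cv = 0.1, seed = 4)
  fits <- multi_restart(spec, data, n_restarts = 5, seed0 = 10,
                        ga = quick_ga(8, 5))
  expect_length(fits, 5)
  expect_setequal(vapply(fits, `[[`, 0L, "seed"), 10:14)
  objs <- vapply(fits, `[[`, 0, "objective")
  expect_true(all(diff(objs) >= 0))
  expect_equal(objs[1], min(objs))
  # the toy objective is effectively convex: restarts agree closely
  expect_lt(max(objs) - min(objs), 1e-3)
})

test_that("structure pools rank the generating structure first", {
  truth_spec <- toy_pool_model(k_death = 0.15, x0 = 1000)
  data <- toy_dataset(truth_spec, cv = 0)
  tpl <- truth_spec
  cands <- list("BM.normal.Death" = list(
    rate_form("first_order", k = 0.1),
    rate_form("zero_order", k = 50),
    rate_form("michaelis_menten", vmax = 100, km = 200)))
  pool <- enumerate_structures(tpl, cands)
  ranked <- fit_structure_pool(pool, data, ga = quick_ga(16, 10), seed = 2)
  expect_false(ranked$failed[1])
  best <- attr(ranked, "fits")[[1]]
  expect_equal(
    pool[[match(ranked$name[1], vapply(pool, `[[`, "", "name"))]]$processes[["BM.normal.Death"]]$form$kind,
    "first_order")
  expect_lt(best$objective, 0.1)
  # pool of one returns that spec; identical specs tie by order
  single <- fit_structure_pool(pool[1], data, ga = quick_ga(8, 4), seed = 2)
  expect_equal(nrow(single), 1)
})

test_that("identifiability analysis flags the sloppy mobility pair", {
  spec <- tissue_model()
  idf <- identifiable_parameters(spec)
  expect_true(all(c("BM.leukemic.Prolif.k", "SP.leukemic.Prolif.k",
                    "BM.normal.Prolif.k") %in% idf))
  rel_se <- attr(idf, "rel_se")
  # the spleen import/export pair is strongly correlated and should carry
  # the largest predicted uncertainty
  expect_gt(max(rel_se[c("SP.normal.Import.k", "SP.normal.Export.k")]),
            max(rel_se[setdiff(names(rel_se),
                               c("SP.normal.Import.k",
                                 "SP.normal.Export.k"))]))
})

test_that("hierarchical fitting conditions sub-models on the tissue fit", {
  tissue_data <- default_data_noisefree()
  g0_data <- generate_kinetics(quiescence_scenario("on", cv = 0), 1)
  hier <- fit_hierarchical(
    tissue_data, g0_data = g0_data,
    tissue_spec = tissue_model(),
    ga = quick_ga(16, 10), seed = 2, solver = quick_solver())
  expect_s3_class(hier$tissue, "leuk_fit")
  expect_null(hier$hsc_hpc)
  expect_s3_class(hier$g0, "leuk_fit")
  # the forcing handed to the G0 level is the fitted leukemic BM course
  expect_equal(hier$forcing$values[1],
               unname(tissue_model()$init["BM.leukemic"]))
  expect_true(all(hier$g0$series$pass))
})
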