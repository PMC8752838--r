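# Microsimulation oracle: determinism, analytic truth, empirical consistency.

test_that("a fixed seed makes the simulation bit-reproducible", {
  cfg <- default_sim_config(n_individuals = 5e3, seed = 123)
  s1 <- simulate_population(cfg)
  s2 <- simulate_population(cfg)
  expect_identical(s1$exposure, s2$exposure)
  expect_identical(s1$incidence, s2$incidence)
  expect_identical(s1$truth, s2$truth)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_population(cfg, dir = d1)
  simulate_population(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # the seed is recorded in every emitted file header
  expect_match(readLines(file.path(d1, "exposure.csv"), n = 1), "seed=123")
})

test_that("null relative risks give identically zero attributable fractions", {
  cfg <- sim_config(
    n_individuals = 2e4, seed = 42,
    factors = list(f1 = list(levels = c(ref = 0.5, exposed = 0.5),
                             rr = list(c1 = c(exposed = 1)))),
    cancers = c(c1 = 0.01)
  )
  sim <- simulate_population(cfg)
  expect_true(all(sim$truth$analytic_paf == 0))
  # coupled counterfactual draws make the empirical fraction exactly zero too
  expect_true(all(sim$truth$simulated_paf == 0))
})

test_that("analytic truth equals the Levin formula for a single factor", {
  cfg <- sim_config(
    n_individuals = 100, seed = 1,
    factors = list(f1 = list(levels = c(ref = 0.6, low = 0.3, high = 0.1),
                             rr = list(c1 = c(low = 1.5, high = 3.0)))),
    cancers = c(c1 = 0.01)
  )
  # E[RR] = 0.6 + 0.3*1.5 + 0.1*3 = 1.35; PAF = 1 - 1/1.35
  a <- analytic_true_paf(cfg, "f1", "c1")
  expect_equal(a, 0.2592593, tolerance = 1e-6)
  expect_equal(a, as.numeric(paf_levin(c(0.3, 0.1), c(0.5, 2.0))),
               tolerance = 1e-12)
  # single factor p = 0.5, RR = 2: 1 - 1/1.5 = 1/3
  cfg2 <- sim_config(
    n_individuals = 100, seed = 1,
    factors = list(f1 = list(levels = c(ref = 0.5, exposed = 0.5),
                             rr = list(c1 = c(exposed = 2)))),
    cancers = c(c1 = 0.01)
  )
  expect_equal(analytic_true_paf(cfg2, "f1", "c1"), 1 / 3, tolerance = 1e-12)
})

test_that("joint analytic truth factorizes over independent factors", {
  cfg <- default_sim_config(n_individuals = 100, seed = 1)
  fids <- names(cfg$factors)
  for (cn in names(cfg$cancers)) {
    singles <- vapply(fids, analytic_true_paf, numeric(1), config = cfg,
                      cancer_type = cn)
    expect_equal(analytic_true_paf(cfg, fids, cn),
                 1 - prod(1 - singles), tolerance = 1e-12)
  }
  expect_identical(analytic_true_paf(cfg, character(0), "lung"), 0)
  expect_error(analytic_true_paf(cfg, "nope", "lung"),
               class = "paf_lookup_error")
  expect_error(analytic_true_paf(cfg, fids, "nope"),
               class = "paf_lookup_error")
})

test_that("empirical prevalences converge to the configured ones", {
  cfg <- default_sim_config(n_individuals = 5e4, seed = 11)
  sim <- simulate_population(cfg)
  for (fid in names(cfg$factors)) {
    prev <- cfg$factors[[fid]]$levels
    for (lv in names(prev)) {
      emp <- sim$exposure$proportion[sim$exposure$factor_id == fid &
                                       sim$exposure$level_id == lv]
      tol <- 3 * sqrt(prev[[lv]] * (1 - prev[[lv]]) / cfg$n_individuals)
      expect_true(all(abs(emp - prev[[lv]]) <= tol))
    }
  }
})

test_that("excessive probability capping aborts with configuration guidance", {
  cfg <- sim_config(
    n_individuals = 1e3, seed = 2,
    factors = list(f1 = list(levels = c(ref = 0.5, exposed = 0.5),
                             rr = list(c1 = c(exposed = 10)))),
    cancers = c(c1 = 0.5)
  )
  expect_error(simulate_population(cfg), "capped",
               class = "paf_config_error")
})

test_that("a tiny cohort still yields a well-defined comparison", {
  sim <- simulate_population(default_sim_config(n_individuals = 100, seed = 8))
  expect_s3_class(sim$truth, "data.frame")
  expect_true(all(is.na(sim$truth$mc_standard_error) |
                    sim$truth$mc_standard_error > 0))
})

test_that("the pipeline recovers simulated truth at moderate cohort size", {
  rec <- recovery_experiment(default_sim_config(n_individuals = 5e4, seed = 3))
  expect_true(all(is.finite(rec$z)))
  expect_true(all(abs(rec$z) <= 3))
  # the pipeline estimate differs from analytic truth only through the
  # empirical prevalences, so it sits far inside the Monte-Carlo band
  expect_lt(max(abs(rec$err_vs_analytic)), 0.01)
})

test_that("declaring a factor non-significant zeroes its pipeline cells", {
  cfg <- default_sim_config(n_individuals = 2e4, seed = 17)
  sim <- simulate_population(cfg)
  rr <- sim$rr
  rr$significant[rr$factor_id == "smoking"] <- FALSE
  specs <- lapply(names(cfg$factors), function(fid) {
    risk_factor_spec(fid, exposure_year = 2008, latency_years = 10)
  })
  fit <- paf_burden(sim$incidence, specs, exposure = sim$exposure, rr = rr,
                    incidence_year = 2018)
  att <- as.data.frame(fit$attribution)
  expect_true(all(att$paf[att$factor_id == "smoking"] == 0))
  # the simulated truth for smoking is far from zero; the forced null is a
  # deliberate statement, not an estimate
  smoke_truth <- sim$truth[sim$truth$factor_id == "smoking" &
                             sim$truth$cancer_type_id == "lung", ]
  expect_gt(min(smoke_truth$simulated_paf), 0.2)
})
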