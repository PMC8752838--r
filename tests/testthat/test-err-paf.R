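# Mathematical core: ERR derivation, the multi-level Levin formula, and
# order-free combination.

test_that("err_from_rr applies the framing transforms", {
  expect_identical(err_from_rr(1.0, "harmful"), 0)
  expect_identical(err_from_rr(2.0, "harmful"), 1)
  # protectively framed RR: harmful-direction ERR is log(1/RR), per unit
  expect_equal(err_from_rr(0.5, "reduction"), 0.693147, tolerance = 1e-6)
  expect_equal(err_from_rr(0.5, "reduction"), log(2), tolerance = 1e-12)
  expect_equal(err_from_rr(0.5, "reduction", n_units = 5), 0.1386294,
               tolerance = 1e-6)
  expect_equal(err_from_rr(0.5, "reduction", n_units = 5), log(2) / 5,
               tolerance = 1e-12)
  # the alternative per-unit rescaling is exact in RR space
  expect_equal(err_from_rr(0.5, "reduction", n_units = 5,
                           reduction_transform = "power"),
               2^(1 / 5) - 1, tolerance = 1e-12)
})

test_that("unsupported associations are forced to a null effect", {
  expect_identical(err_from_rr(3.7, "harmful", significant = FALSE), 0)
  expect_identical(err_from_rr(0.4, "reduction", significant = FALSE), 0)
  expect_equal(err_from_rr(c(2, 3), "harmful", significant = c(TRUE, FALSE)),
               c(1, 0))
})

test_that("err_from_rr rejects non-positive RRs and warns on ignored units", {
  expect_error(err_from_rr(0, "harmful"), class = "paf_domain_error")
  expect_error(err_from_rr(-1, "reduction"), class = "paf_domain_error")
  expect_warning(err_from_rr(2, "harmful", n_units = 3), "ignored")
})

test_that("reduction and harmful framings agree to first order near RR = 1", {
  for (rr in seq(0.9, 1.1, by = 0.01)) {
    red <- err_from_rr(rr, "reduction")
    harm_of_reciprocal <- err_from_rr(1 / rr, "harmful")
    expect_lte(abs(red - harm_of_reciprocal), (rr - 1)^2)
  }
})

test_that("paf_levin reproduces exact stratified-population enumeration", {
  # single level, half the population at RR 2: excess fraction 1/3
  expect_equal(as.numeric(paf_levin(0.5, 1)), 0.3333333, tolerance = 1e-6)
  expect_equal(as.numeric(paf_levin(0.5, 1)), oracle_paf(0.5, 2),
               tolerance = 1e-12)
  # two levels: S = 0.3*0.5 + 0.1*2 = 0.35, PAF = 0.35/1.35
  expect_equal(as.numeric(paf_levin(c(0.3, 0.1), c(0.5, 2.0))), 0.2592593,
               tolerance = 1e-6)
  expect_equal(as.numeric(paf_levin(c(0.3, 0.1), c(0.5, 2.0))),
               oracle_paf(c(0.3, 0.1), c(1.5, 3.0)), tolerance = 1e-12)
  expect_identical(as.numeric(paf_levin(c(0.2, 0.3), c(0, 0))), 0)
})

test_that("paf_levin equals the enumeration oracle over random configurations", {
  set.seed(42)
  for (i in 1:250) {
    cs <- random_levin_case()
    err <- cs$rr - 1
    if (sum(cs$p * err) < 0) {
      got <- as.numeric(paf_levin(cs$p, err, allow_negative_paf = TRUE))
    } else {
      got <- as.numeric(paf_levin(cs$p, err))
    }
    expect_equal(got, oracle_paf(cs$p, cs$rr), tolerance = 1e-12)
  }
})

test_that("paf_levin is monotone in each proportion and each ERR", {
  set.seed(7)
  for (i in 1:50) {
    p <- stats::runif(3, 0, 0.2)
    err <- stats::runif(3, 0, 3)
    base <- as.numeric(paf_levin(p, err))
    j <- sample(3, 1)
    p_up <- p; p_up[j] <- p_up[j] + 0.05
    err_up <- err; err_up[j] <- err_up[j] + 0.5
    expect_gte(as.numeric(paf_levin(p_up, err)), base)
    expect_gte(as.numeric(paf_levin(p, err_up)), base)
  }
})

test_that("paf_levin validates its domain", {
  expect_error(paf_levin(c(0.6, 0.6), c(1, 1)), class = "paf_domain_error")
  expect_error(paf_levin(0.5, -2), class = "paf_domain_error")
  expect_error(paf_levin(1.2, 1), class = "paf_domain_error")
  expect_error(paf_levin(c(0.5, 0.1), 1), class = "paf_domain_error")
  # net-protective inputs are rejected unless explicitly permitted
  expect_error(paf_levin(0.5, -0.5), class = "paf_domain_error")
  expect_equal(as.numeric(paf_levin(0.5, -0.5, allow_negative_paf = TRUE)),
               -0.25 / 0.75, tolerance = 1e-12)
})

test_that("combine_pafs is the order-free sequential combination", {
  expect_identical(as.numeric(combine_pafs(c(0.5, 0.5))), 0.75)
  expect_identical(as.numeric(combine_pafs(0.3)), 0.3)
  expect_identical(as.numeric(combine_pafs(c(0.3, 0, 0))), 0.3)
  expect_error(combine_pafs(c(0.5, 1.2)), class = "paf_domain_error")
  expect_error(combine_pafs(c(-0.1)), class = "paf_domain_error")
})

test_that("combine_pafs respects bounds and permutation invariance", {
  set.seed(11)
  for (i in 1:100) {
    pafs <- stats::runif(sample(2:6, 1))
    comb <- as.numeric(combine_pafs(pafs))
    expect_gte(comb, max(pafs))
    expect_lte(comb, min(1, sum(pafs)))
    expect_equal(as.numeric(combine_pafs(sample(pafs))), comb,
                 tolerance = 1e-12)
  }
})

test_that("paf_for_cell passes published fractions through unchanged", {
  uv <- risk_factor_spec("uv", evidence_mode = "direct_paf",
                         linked_cancer_types = "melanoma",
                         exposure_year = 2008, latency_years = 10)
  got <- paf_for_cell(uv, direct = 0.932)
  expect_identical(as.numeric(got), 0.932)
  expect_identical(attr(got, "source"), "direct")
  expect_error(paf_for_cell(uv, direct = 1.2), class = "paf_validation_error")
  expect_error(paf_for_cell(uv), class = "paf_data_gap_error")
})

test_that("paf_for_cell matches the single-level closed form on a grid", {
  spec <- risk_factor_spec("f", exposure_year = 2008, latency_years = 10)
  for (p in seq(0.1, 0.9, by = 0.2)) {
    for (rr in c(1.1, 2, 3.5, 5)) {
      dist <- data.frame(level_id = c("exposed", "ref"),
                         proportion = c(p, 1 - p))
      rrs <- data.frame(level_id = "exposed", cancer_type_id = "c",
                        sex = "male", rr = rr, significant = TRUE)
      got <- as.numeric(paf_for_cell(spec, dist = dist, rrs = rrs))
      expect_equal(got, p * (rr - 1) / (1 + p * (rr - 1)), tolerance = 1e-12)
      expect_equal(got, oracle_paf(p, rr), tolerance = 1e-12)
    }
  }
})

test_that("paf_for_cell flags data gaps and honours forced nulls", {
  spec <- risk_factor_spec("f", exposure_year = 2008, latency_years = 10)
  dist <- data.frame(level_id = c("low", "high", "ref"),
                     proportion = c(0.2, 0.1, 0.7))
  rrs <- data.frame(level_id = "low", cancer_type_id = "c", sex = "male",
                    rr = 1.5, significant = TRUE)
  expect_error(paf_for_cell(spec, dist = dist, rrs = rrs),
               class = "paf_data_gap_error")
  # null level only: RR = 1 at the single exposed level gives PAF 0
  dist1 <- data.frame(level_id = c("exposed", "ref"), proportion = c(0.25, 0.75))
  rrs1 <- data.frame(level_id = "exposed", cancer_type_id = "c", sex = "male",
                     rr = 1, significant = TRUE)
  expect_identical(as.numeric(paf_for_cell(spec, dist = dist1, rrs = rrs1)), 0)
  # a declared non-significant association is forced to zero
  rrs2 <- rrs1; rrs2$rr <- 3.7; rrs2$significant <- FALSE
  expect_identical(as.numeric(paf_for_cell(spec, dist = dist1, rrs = rrs2)), 0)
})
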