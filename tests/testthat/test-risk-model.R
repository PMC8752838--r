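# Interchange tables: schema validation, reference-level normalization,
# and lossless round trips.

test_that("exposure reader materializes an implicit reference level", {
  tf <- write_csv_fixture(c(
    "factor_id,sex,level_id,proportion,exposure_year",
    "smoking,male,current,0.25,2008"
  ))
  tab <- read_exposure_table(tf)
  expect_s3_class(tab, "exposure_table")
  expect_setequal(tab$level_id, c("current", "ref"))
  expect_equal(tab$proportion[tab$level_id == "ref"], 0.75)
})

test_that("exposure reader accepts an explicit reference level", {
  tf <- write_csv_fixture(c(
    "factor_id,sex,level_id,proportion,exposure_year",
    "smoking,male,current,0.2,2008",
    "smoking,male,former,0.25,2008",
    "smoking,male,ref,0.55,2008"
  ))
  tab <- read_exposure_table(tf)
  expect_equal(nrow(tab), 3L)
  expect_equal(sum(tab$proportion), 1)
})

test_that("exposure reader rejects malformed input with named locations", {
  # empty file: no partial output
  tf <- write_csv_fixture("factor_id,sex,level_id,proportion,exposure_year")
  expect_error(read_exposure_table(tf), class = "paf_validation_error")
  # schema mismatch names the missing column
  tf <- write_csv_fixture(c("factor_id,sex,level_id,exposure_year",
                            "smoking,male,current,2008"))
  expect_error(read_exposure_table(tf), "proportion",
               class = "paf_input_error")
  # proportions summing past 1 cite the factor
  tf <- write_csv_fixture(c(
    "factor_id,sex,level_id,proportion,exposure_year",
    "smoking,male,current,0.62,2008",
    "smoking,male,former,0.40,2008"
  ))
  expect_error(read_exposure_table(tf), "smoking",
               class = "paf_validation_error")
  # proportion outside [0, 1] names row and column
  tf <- write_csv_fixture(c(
    "factor_id,sex,level_id,proportion,exposure_year",
    "smoking,male,current,1.25,2008"
  ))
  expect_error(read_exposure_table(tf), "proportion.*row 2",
               class = "paf_validation_error")
  # unknown sex literal
  tf <- write_csv_fixture(c(
    "factor_id,sex,level_id,proportion,exposure_year",
    "smoking,m,current,0.25,2008"
  ))
  expect_error(read_exposure_table(tf), class = "paf_validation_error")
  # missing file
  expect_error(read_exposure_table(tempfile()), class = "paf_input_error")
})

test_that("relative-risk reader enforces rr > 0 and parses significance", {
  tf <- write_csv_fixture(c(
    "factor_id,cancer_type_id,sex,level_id,rr,significant",
    "smoking,lung,male,current,0,TRUE"
  ))
  expect_error(read_rr_table(tf), class = "paf_validation_error")
  tf <- write_csv_fixture(c(
    "factor_id,cancer_type_id,sex,level_id,rr,significant",
    "smoking,lung,male,current,8.0,true",
    "smoking,lung,male,former,2.5,FALSE"
  ))
  tab <- read_rr_table(tf)
  expect_identical(tab$significant, c(TRUE, FALSE))
  tf <- write_csv_fixture(c(
    "factor_id,cancer_type_id,sex,level_id,rr,significant",
    "smoking,lung,male,current,8.0,maybe"
  ))
  expect_error(read_rr_table(tf), "significant",
               class = "paf_validation_error")
})

test_that("incidence reader enforces counts, uniqueness and subtype bounds", {
  tf <- write_csv_fixture(c(
    "cancer_type_id,subtype_of,sex,year,cases",
    "lung,,male,2018,-5"
  ))
  expect_error(read_incidence_table(tf), class = "paf_validation_error")
  tf <- write_csv_fixture(c(
    "cancer_type_id,subtype_of,sex,year,cases",
    "lung,,male,2018,100",
    "lung,,male,2018,90"
  ))
  expect_error(read_incidence_table(tf), "duplicate",
               class = "paf_validation_error")
  # a subtype may never exceed its parent
  tf <- write_csv_fixture(c(
    "cancer_type_id,subtype_of,sex,year,cases",
    "oesophagus,,male,2018,100",
    "oesophagus_adeno,oesophagus,male,2018,120"
  ))
  expect_error(read_incidence_table(tf), "exceed",
               class = "paf_validation_error")
  tf <- write_csv_fixture(c(
    "cancer_type_id,subtype_of,sex,year,cases",
    "oesophagus,,male,2018,100",
    "oesophagus_adeno,oesophagus,male,2018,60"
  ))
  tab <- read_incidence_table(tf)
  expect_identical(tab$subtype_of, c(NA_character_, "oesophagus"))
})

test_that("direct-PAF reader keeps fractions inside [0, 1)", {
  tf <- write_csv_fixture(c("factor_id,cancer_type_id,sex,paf",
                            "uv,melanoma,male,1.0"))
  expect_error(read_direct_paf_table(tf), class = "paf_validation_error")
  tf <- write_csv_fixture(c("factor_id,cancer_type_id,sex,paf",
                            "uv,melanoma,male,0.932"))
  expect_equal(read_direct_paf_table(tf)$paf, 0.932)
})

test_that("write then read is the identity on all four table kinds", {
  d <- tempfile(); dir.create(d)
  exp_tab <- validate_exposure(data.frame(
    factor_id = "smoking", sex = c("male", "male", "female"),
    level_id = c("current", "former", "current"),
    proportion = c(0.2 + 1e-13, 1 / 3, 0.18),
    exposure_year = 2008
  ))
  write_exposure_table(exp_tab, file.path(d, "e.csv"))
  expect_equal(read_exposure_table(file.path(d, "e.csv")), exp_tab,
               tolerance = 0)

  rr_tab <- validate_rr(data.frame(
    factor_id = "smoking", cancer_type_id = "lung",
    sex = "male", level_id = c("current", "former"),
    rr = c(8.123456789012345, 2.5), significant = c(TRUE, FALSE)
  ))
  write_rr_table(rr_tab, file.path(d, "r.csv"))
  expect_equal(read_rr_table(file.path(d, "r.csv")), rr_tab, tolerance = 0)

  inc_tab <- validate_incidence(data.frame(
    cancer_type_id = c("lung", "lung_adeno"),
    subtype_of = c(NA, "lung"), sex = "male", year = 2018,
    cases = c(3612, 1200)
  ))
  write_incidence_table(inc_tab, file.path(d, "i.csv"))
  expect_equal(read_incidence_table(file.path(d, "i.csv")), inc_tab,
               tolerance = 0)

  dp_tab <- validate_direct_paf(data.frame(
    factor_id = "uv", cancer_type_id = "melanoma",
    sex = c("male", "female"), paf = c(0.932, 0.895)
  ))
  write_direct_paf_table(dp_tab, file.path(d, "d.csv"))
  expect_equal(read_direct_paf_table(file.path(d, "d.csv")), dp_tab,
               tolerance = 0)

  att <- attribution_table(
    data.frame(
      factor_id = c("smoking", "__combined__"), cancer_type_id = "lung",
      sex = "male", paf = c(1 / 3, 1 / 3),
      attributable_cases = c(100 + 1 / 7, 100 + 1 / 7)
    ),
    total_cases = 300, total_attributable = 100 + 1 / 7,
    overall_paf = (100 + 1 / 7) / 300
  )
  write_attribution_table(att, file.path(d, "a.csv"))
  back <- read_attribution_table(file.path(d, "a.csv"))
  expect_equal(back, att, tolerance = 0)
  expect_identical(attr(back, "overall"), attr(att, "overall"))
})

test_that("risk_factor_spec enforces its invariants", {
  direct <- risk_factor_spec("hpv", evidence_mode = "direct_paf",
                             linked_cancer_types = "cervix",
                             exposure_year = 2008, latency_years = 10)
  expect_null(direct$framing)
  expect_null(direct$n_units)
  reduction <- risk_factor_spec("inactivity", framing = "reduction",
                                n_units = 7, exposure_year = 2008,
                                latency_years = 10)
  expect_identical(reduction$n_units, 7L)
  expect_error(risk_factor_spec("x", n_units = 0, exposure_year = 2008,
                                latency_years = 10),
               class = "paf_validation_error")
  expect_error(risk_factor_spec("x", linked_cancer_types = character(0),
                                exposure_year = 2008, latency_years = 10),
               class = "paf_validation_error")
  expect_error(risk_factor_spec("x", exposure_year = 1850, latency_years = 10),
               class = "paf_validation_error")
})
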