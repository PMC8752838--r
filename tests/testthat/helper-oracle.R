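# Independent oracle: exact excess-case fraction of a fully enumerated
# stratified population. The population is split into a reference stratum and
# one stratum per exposure level; each stratum carries a multiplicative risk
# baseline * RR. The attributable fraction is the excess of expected cases
# over the all-at-baseline counterfactual, as a share of expected cases.
oracle_paf <- function(p, rr, baseline = 0.01) {
  stopifnot(sum(p) <= 1 + 1e-12)
  props <- c(1 - sum(p), p)
  risks <- baseline * c(1, rr)
  expected <- sum(props * risks)
  counterfactual <- baseline # every stratum at reference risk
  (expected - counterfactual) / expected
}

# random multi-level exposure/RR configurations for property tests
random_levin_case <- function() {
  k <- sample(1:4, 1)
  p <- stats::runif(k)
  p <- p / sum(p) * stats::runif(1, 0.05, 0.95) # total exposed mass < 1
  rr <- stats::runif(k, 0.2, 6)
  list(p = p, rr = rr)
}

write_csv_fixture <- function(lines) {
  tf <- tempfile(fileext = ".csv")
  writeLines(lines, tf)
  tf
}

tiny_incidence <- function(cases = 300, cancer = "lung", sex = "male",
                           year = 2018, subtype_of = NA) {
  data.frame(cancer_type_id = cancer, subtype_of = subtype_of, sex = sex,
             year = year, cases = cases, stringsAsFactors = FALSE)
}
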