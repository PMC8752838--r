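# Individual-level microsimulator with a known multiplicative risk structure.
# It emits the three pipeline input tables plus a ground-truth table, so the
# whole estimator can be validated against analytic and empirical truth
# without any external data.

#' Configure a synthetic population
#'
#' Defines an individual-level population in which each person is assigned an
#' exposure level per risk factor (independently across factors and people)
#' and develops each cancer type in the simulated year as an independent
#' Bernoulli draw with probability `baseline * prod(RR at the person's
#' levels)`. Factors act multiplicatively and independently — exactly the
#' assumptions under which the Levin estimator and the order-free combination
#' are consistent, so the simulator is the estimator's validation harness, not
#' a model of dependent or synergistic exposures.
#'
#' @param n_individuals cohort size per sex.
#' @param seed integer seed; a run is bit-reproducible given the seed, which
#'   is recorded in the header of every emitted file.
#' @param factors named list, one entry per risk factor:
#'   `list(levels = c(ref = ..., <level> = ...), rr = list(<cancer> =
#'   c(<level> = RR, ...)))`. Level prevalences must include the reference
#'   level `"ref"` and sum to 1; RR vectors cover the non-reference levels
#'   (reference RR is 1) and omit cancers the factor is not linked to.
#' @param cancers named numeric vector of baseline annual risks per person,
#'   each in `(0, 1)`.
#' @param sexes sexes to simulate; parameters are shared across sexes unless
#'   overridden.
#' @param overrides optional per-sex parameter overrides:
#'   `list(<sex> = list(cancers = c(...), factors = list(<id> =
#'   list(levels = ..., rr = ...))))`; entries replace the corresponding
#'   defaults for that sex only.
#' @param exposure_year,latency_years vintage metadata stamped on the emitted
#'   tables; incidence is simulated for `exposure_year + latency_years`.
#' @return an object of class `"paf_sim_config"`.
#' @seealso [default_sim_config()], [simulate_population()]
#' @export
sim_config <- function(n_individuals, seed, factors, cancers,
                       sexes = c("male", "female"), overrides = NULL,
                       exposure_year = 2008, latency_years = 10) {
  if (length(n_individuals) != 1L || !is_count(n_individuals) ||
      n_individuals < 1) {
    paf_config_error("n_individuals must be a positive integer")
  }
  if (length(seed) != 1L || !is.finite(seed)) {
    paf_config_error("seed must be a single integer")
  }
  sexes <- match.arg(sexes, several.ok = TRUE)
  if (!is_year(exposure_year) || !is_count(latency_years)) {
    paf_config_error("exposure_year must be a calendar year and latency_years a non-negative integer")
  }
  check_params <- function(factors, cancers, where) {
    if (!is.numeric(cancers) || is.null(names(cancers)) ||
        any(!nzchar(names(cancers)))) {
      paf_config_error(sprintf("%s: cancers must be a named numeric vector", where))
    }
    if (any(cancers <= 0 | cancers >= 1)) {
      paf_config_error(sprintf("%s: baseline risks must lie in (0, 1)", where))
    }
    if (!is.list(factors) || is.null(names(factors)) ||
        any(!nzchar(names(factors)))) {
      paf_config_error(sprintf("%s: factors must be a named list", where))
    }
    for (fid in names(factors)) {
      f <- factors[[fid]]
      prev <- f$levels
      if (!is.numeric(prev) || is.null(names(prev)) ||
          !.ref_level %in% names(prev)) {
        paf_config_error(sprintf(
          "%s: factor '%s' needs named level prevalences including '%s'",
          where, fid, .ref_level))
      }
      if (any(prev < 0) || abs(sum(prev) - 1) > 1e-9) {
        paf_config_error(sprintf(
          "%s: factor '%s' level prevalences must be non-negative and sum to 1",
          where, fid))
      }
      for (cn in names(f$rr)) {
        rrv <- f$rr[[cn]]
        if (!cn %in% names(cancers)) {
          paf_config_error(sprintf(
            "%s: factor '%s' has relative risks for unknown cancer '%s'",
            where, fid, cn))
        }
        if (any(rrv <= 0)) {
          paf_config_error(sprintf(
            "%s: factor '%s' x '%s': relative risks must be > 0", where, fid, cn))
        }
        if (!all(names(rrv) %in% names(prev))) {
          paf_config_error(sprintf(
            "%s: factor '%s' x '%s': relative-risk levels not among the factor's levels",
            where, fid, cn))
        }
      }
    }
  }
  check_params(factors, cancers, "config")
  if (!is.null(overrides)) {
    for (sx in names(overrides)) {
      if (!sx %in% sexes) {
        paf_config_error(sprintf("override for unknown sex '%s'", sx))
      }
    }
  }
  structure(
    list(n_individuals = as.integer(n_individuals), seed = as.integer(seed),
         factors = factors, cancers = cancers, sexes = sexes,
         overrides = overrides, exposure_year = as.integer(exposure_year),
         latency_years = as.integer(latency_years)),
    class = "paf_sim_config"
  )
}

# parameters for one sex after applying overrides
sex_params <- function(config, sex) {
  factors <- config$factors
  cancers <- config$cancers
  ov <- config$overrides[[sex]]
  if (!is.null(ov$cancers)) cancers[names(ov$cancers)] <- ov$cancers
  for (fid in names(ov$factors)) {
    for (part in names(ov$factors[[fid]])) {
      factors[[fid]][[part]] <- ov$factors[[fid]][[part]]
    }
  }
  list(factors = factors, cancers = cancers)
}

#' Default validation fixture
#'
#' Three risk factors (a tobacco-like, an alcohol-like and an adiposity-like
#' exposure, each with two non-reference levels) crossed with four cancer
#' types, simulated for cohorts of one million individuals per sex with
#' exposure vintage 2008 and a 10-year latency. Prevalences and relative risks
#' are in the range typical of the lifestyle exposures the estimator targets
#' (level prevalences 0.10-0.30, relative risks 1.1-8), and baseline annual
#' risks (6e-4 to 3e-3) give per-cell case counts of registry-like magnitude.
#'
#' @param n_individuals cohort size per sex (default 1e6).
#' @param seed RNG seed (default 20180101).
#' @return a [sim_config()].
#' @export
default_sim_config <- function(n_individuals = 1e6, seed = 20180101) {
  sim_config(
    n_individuals = n_individuals,
    seed = seed,
    factors = list(
      smoking = list(
        levels = c(ref = 0.55, former = 0.25, current = 0.20),
        rr = list(
          lung       = c(former = 2.5, current = 8.0),
          bladder    = c(former = 1.5, current = 3.0),
          oesophagus = c(former = 1.5, current = 2.5),
          colorectal = c(former = 1.1, current = 1.3)
        )
      ),
      alcohol = list(
        levels = c(ref = 0.60, moderate = 0.30, heavy = 0.10),
        rr = list(
          oesophagus = c(moderate = 1.4, heavy = 2.5),
          colorectal = c(moderate = 1.1, heavy = 1.6),
          bladder    = c(moderate = 1.0, heavy = 1.2),
          lung       = c(moderate = 1.0, heavy = 1.0)
        )
      ),
      obesity = list(
        levels = c(ref = 0.55, overweight = 0.30, obese = 0.15),
        rr = list(
          colorectal = c(overweight = 1.2, obese = 1.5),
          oesophagus = c(overweight = 1.5, obese = 2.4),
          bladder    = c(overweight = 1.1, obese = 1.2),
          lung       = c(overweight = 1.0, obese = 1.0)
        )
      )
    ),
    cancers = c(lung = 0.0030, colorectal = 0.0025, bladder = 0.0012,
                oesophagus = 0.0006)
  )
}

# E[RR] of one factor for one cancer under the configured prevalences
expected_rr <- function(params, fid, cancer) {
  prev <- params$factors[[fid]]$levels
  rrv <- params$factors[[fid]]$rr[[cancer]]
  full <- stats::setNames(rep(1, length(prev)), names(prev))
  full[names(rrv)] <- rrv
  sum(prev * full[names(prev)])
}

#' Analytic ground-truth attributable fraction
#'
#' Under the simulator's multiplicative independent-factor construction, the
#' fraction of cases of `cancer_type` attributable to a subset of factors is
#' exactly `1 - 1 / prod(E[RR_f])` with `E[RR_f] = sum(p_level * RR_level)`.
#' For a single factor this coincides with the Levin formula `S/(1+S)`, since
#' `S = sum(p * (RR - 1)) = E[RR] - 1`.
#'
#' @param config a [sim_config()].
#' @param factor_ids subset of factor ids to remove jointly; the empty subset
#'   gives 0.
#' @param cancer_type one cancer type id from the configuration.
#' @param sex sex whose (possibly overridden) parameters to use.
#' @return the analytic attributable fraction.
#' @examples
#' cfg <- default_sim_config(n_individuals = 100, seed = 1)
#' analytic_true_paf(cfg, "smoking", "lung")
#' @export
analytic_true_paf <- function(config, factor_ids, cancer_type,
                              sex = config$sexes[1]) {
  stopifnot(inherits(config, "paf_sim_config"))
  if (!cancer_type %in% names(config$cancers)) {
    paf_lookup_error(sprintf("unknown cancer type '%s'", cancer_type))
  }
  if (!sex %in% config$sexes) {
    paf_lookup_error(sprintf("unknown sex '%s'", sex))
  }
  if (length(factor_ids) == 0L) return(0)
  unknown <- setdiff(factor_ids, names(config$factors))
  if (length(unknown)) {
    paf_lookup_error(sprintf("unknown factor '%s'", unknown[1]))
  }
  params <- sex_params(config, sex)
  e <- vapply(factor_ids, expected_rr, numeric(1), params = params,
              cancer = cancer_type)
  1 - 1 / prod(e)
}

#' Simulate a synthetic population and its pipeline tables
#'
#' Assigns each individual an exposure level per factor, draws per-type cancer
#' outcomes with probability `baseline * prod(RR)` (capped below 1; the run
#' aborts if more than 0.1% of probabilities hit the cap), and emits:
#'
#' * an exposure table with the cohort's *empirical* level prevalences,
#' * a relative-risk table with the true configured RRs (all
#'   `significant = TRUE`),
#' * an incidence table with the simulated case counts for
#'   `exposure_year + latency_years`, and
#' * a truth table with, per factor x cancer x sex (plus `"combined"` rows),
#'   the analytic attributable fraction, the empirical attributable fraction
#'   measured by coupled counterfactual removal (the same uniform draw decides
#'   each person's outcome under factual and counterfactual risk), and its
#'   Monte-Carlo standard error.
#'
#' @param config a [sim_config()].
#' @param dir optional directory; when given, `exposure.csv`, `rr.csv`,
#'   `incidence.csv` and `truth.csv` are written there, each headed by a
#'   `#! seed=` line.
#' @return an object of class `"paf_simulation"`: list with `exposure`, `rr`,
#'   `incidence`, `truth`, `config`, `capped` (number of capped
#'   individual-cancer probabilities) and, if written, `paths`.
#' @examples
#' sim <- simulate_population(default_sim_config(n_individuals = 2000, seed = 7))
#' head(sim$truth)
#' @export
simulate_population <- function(config, dir = NULL) {
  stopifnot(inherits(config, "paf_sim_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  inc_year <- config$exposure_year + config$latency_years
  exposure <- list(); rrs <- list(); incidence <- list(); truth <- list()
  capped <- 0L
  draws <- 0

  for (sx in config$sexes) {
    params <- sex_params(config, sx)
    fids <- names(params$factors)
    assigned <- lapply(fids, function(fid) {
      prev <- params$factors[[fid]]$levels
      sample(names(prev), n, replace = TRUE, prob = prev)
    })
    names(assigned) <- fids

    for (fid in fids) {
      prev <- params$factors[[fid]]$levels
      emp <- table(factor(assigned[[fid]], levels = names(prev))) / n
      exposure[[length(exposure) + 1L]] <- data.frame(
        factor_id = fid, sex = sx, level_id = names(prev),
        proportion = as.numeric(emp), exposure_year = config$exposure_year,
        stringsAsFactors = FALSE
      )
      for (cn in names(params$factors[[fid]]$rr)) {
        rrv <- params$factors[[fid]]$rr[[cn]]
        rrv <- rrv[names(rrv) != .ref_level]
        rrs[[length(rrs) + 1L]] <- data.frame(
          factor_id = fid, cancer_type_id = cn, sex = sx,
          level_id = names(rrv), rr = as.numeric(rrv), significant = TRUE,
          stringsAsFactors = FALSE
        )
      }
    }

    for (cn in names(params$cancers)) {
      base <- params$cancers[[cn]]
      mult <- lapply(fids, function(fid) {
        prev <- params$factors[[fid]]$levels
        rrv <- params$factors[[fid]]$rr[[cn]]
        full <- stats::setNames(rep(1, length(prev)), names(prev))
        if (!is.null(rrv)) full[names(rrv)] <- rrv
        unname(full[assigned[[fid]]])
      })
      names(mult) <- fids
      risk_raw <- base * Reduce(`*`, mult)
      capped <- capped + sum(risk_raw > 1)
      draws <- draws + n
      risk <- pmin(risk_raw, 1)
      u <- stats::runif(n)
      case <- u < risk
      o <- sum(case)
      incidence[[length(incidence) + 1L]] <- data.frame(
        cancer_type_id = cn, subtype_of = NA_character_, sex = sx,
        year = inc_year, cases = as.numeric(o), stringsAsFactors = FALSE
      )
      mc_se <- function(paf_hat) {
        if (o == 0) return(NA_real_)
        # Wilson-style floor keeps the error estimate positive at any count
        p <- min(max(paf_hat, 1 / (o + 1)), o / (o + 1))
        sqrt(p * (1 - p) / o)
      }
      for (fid in fids) {
        o_cf <- sum(u < pmin(risk_raw / mult[[fid]], 1))
        sim_paf <- if (o > 0) (o - o_cf) / o else NA_real_
        truth[[length(truth) + 1L]] <- data.frame(
          factor_id = fid, cancer_type_id = cn, sex = sx,
          analytic_paf = analytic_true_paf(config, fid, cn, sx),
          simulated_paf = sim_paf,
          mc_standard_error = if (o > 0) mc_se(sim_paf) else NA_real_,
          stringsAsFactors = FALSE
        )
      }
      o_joint <- sum(u < base)
      sim_comb <- if (o > 0) (o - o_joint) / o else NA_real_
      truth[[length(truth) + 1L]] <- data.frame(
        factor_id = "combined", cancer_type_id = cn, sex = sx,
        analytic_paf = analytic_true_paf(config, fids, cn, sx),
        simulated_paf = sim_comb,
        mc_standard_error = if (o > 0) mc_se(sim_comb) else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }

  if (capped / draws > 0.001) {
    paf_config_error(sprintf(
      paste0("%.2f%% of individual-cancer probabilities exceeded 1 and were ",
             "capped; lower the baseline risks or relative risks in the ",
             "simulation config"),
      100 * capped / draws
    ))
  }

  out <- structure(
    list(
      exposure = validate_exposure(do.call(rbind, exposure), "<simulated>"),
      rr = validate_rr(do.call(rbind, rrs), "<simulated>"),
      incidence = validate_incidence(do.call(rbind, incidence), "<simulated>"),
      truth = do.call(rbind, truth),
      config = config,
      capped = capped
    ),
    class = "paf_simulation"
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    prelude <- sprintf("#! seed=%d", config$seed)
    paths <- file.path(dir, c("exposure.csv", "rr.csv", "incidence.csv",
                              "truth.csv"))
    write_paf_csv(out$exposure, paths[1],
                  c("proportion", "exposure_year"), prelude)
    write_paf_csv(out$rr, paths[2], "rr", prelude)
    write_paf_csv(out$incidence, paths[3], c("year", "cases"), prelude)
    write_paf_csv(out$truth, paths[4],
                  c("analytic_paf", "simulated_paf", "mc_standard_error"),
                  prelude)
    out$paths <- paths
  }
  out
}

#' @export
print.paf_simulation <- function(x, ...) {
  cat(sprintf("synthetic population: %s per sex (%s), seed %d\n",
              fmt_num(x$config$n_individuals),
              paste(x$config$sexes, collapse = ", "), x$config$seed))
  cat(sprintf("  %d factor(s) x %d cancer type(s); %s simulated cases\n",
              length(x$config$factors), length(x$config$cancers),
              fmt_num(sum(x$incidence$cases))))
  if (x$capped > 0) {
    cat(sprintf("  %d capped individual-cancer probabilities\n", x$capped))
  }
  invisible(x)
}

#' Parameter-recovery experiment
#'
#' Simulates a population, runs the full burden pipeline on the emitted
#' tables, and compares every pipeline attributable fraction (single-factor
#' and combined) with the simulation's analytic and empirical ground truth.
#'
#' @param config a [sim_config()]; default [default_sim_config()].
#' @param min_incidence exclusion threshold passed to [paf_burden()].
#' @return an object of class `"paf_recovery"`: a data frame with one row per
#'   factor (or `"combined"`) x cancer type x sex holding `pipeline_paf`,
#'   `analytic_paf`, `simulated_paf`, `mc_standard_error`, the errors
#'   `err_vs_analytic` and `err_vs_simulated`, and `z = err_vs_simulated /
#'   mc_standard_error`. The underlying fit and simulation ride along as
#'   attributes `fit` and `sim`.
#' @examples
#' rec <- recovery_experiment(default_sim_config(n_individuals = 5e4, seed = 3))
#' max(abs(rec$z), na.rm = TRUE)
#' @export
recovery_experiment <- function(config = default_sim_config(),
                                min_incidence = 10) {
  stopifnot(inherits(config, "paf_sim_config"))
  sim <- simulate_population(config)
  specs <- lapply(names(config$factors), function(fid) {
    risk_factor_spec(fid, evidence_mode = "rr_based", framing = "harmful",
                     sexes = config$sexes,
                     exposure_year = config$exposure_year,
                     latency_years = config$latency_years)
  })
  fit <- paf_burden(
    incidence = sim$incidence, factors = specs, exposure = sim$exposure,
    rr = sim$rr, incidence_year = config$exposure_year + config$latency_years,
    min_incidence = min_incidence
  )
  att <- as.data.frame(fit$attribution)
  att$factor_id[att$factor_id == .combined_id] <- "combined"
  rep <- merge(sim$truth, att[c("factor_id", "cancer_type_id", "sex", "paf")],
               by = c("factor_id", "cancer_type_id", "sex"), all.x = TRUE)
  names(rep)[names(rep) == "paf"] <- "pipeline_paf"
  rep$err_vs_analytic <- rep$pipeline_paf - rep$analytic_paf
  rep$err_vs_simulated <- rep$pipeline_paf - rep$simulated_paf
  rep$z <- rep$err_vs_simulated / rep$mc_standard_error
  rep <- rep[order(rep$factor_id != "combined", rep$factor_id,
                   rep$cancer_type_id, rep$sex), ]
  rownames(rep) <- NULL
  structure(rep, fit = fit, sim = sim,
            class = c("paf_recovery", "data.frame"))
}

#' @export
print.paf_recovery <- function(x, digits = 4, ...) {
  df <- as.data.frame(x)
  cat(sprintf("parameter recovery over %d cells:\n", nrow(df)))
  cat(sprintf("  max |pipeline - analytic|  : %.2e\n",
              max(abs(df$err_vs_analytic), na.rm = TRUE)))
  cat(sprintf("  max |pipeline - simulated| : %.2e (max |z| = %.2f SE)\n",
              max(abs(df$err_vs_simulated), na.rm = TRUE),
              max(abs(df$z), na.rm = TRUE)))
  print.data.frame(utils::head(df, 10), digits = digits)
  if (nrow(df) > 10) cat(sprintf("  ... %d more rows\n", nrow(df) - 10))
  invisible(x)
}
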