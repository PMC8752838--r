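# Burden pipeline: latency linkage, incidence filtering, per-cell PAF
# computation, combination across factors, and sex-stratified rollups.

#' Exclude rare diagnoses from an incidence table
#'
#' Diagnoses with an annual population incidence below the threshold are
#' excluded before attribution. The default reading of "population incidence"
#' sums a diagnosis's cases over the sexes within each year; set
#' `per_sex = TRUE` to apply the threshold within each sex instead.
#'
#' @param records an `incidence_table` (or data frame with its columns).
#' @param threshold positive integer; a diagnosis is excluded iff its annual
#'   cases are strictly below this (default 10, so 9 cases are excluded and 10
#'   retained).
#' @param per_sex logical; apply the threshold within sex.
#' @return a list with components `kept` and `excluded` (both
#'   `incidence_table`s, either possibly empty) and a `log` attribute listing
#'   each exclusion with its count.
#' @examples
#' inc <- data.frame(cancer_type_id = c("a", "b"), subtype_of = NA,
#'                   sex = "male", year = 2018, cases = c(9, 10))
#' filter_low_incidence(inc)$excluded$cancer_type_id  # "a"
#' @export
filter_low_incidence <- function(records, threshold = 10, per_sex = FALSE) {
  records <- validate_incidence(records, src = "<in-memory>")
  if (length(threshold) != 1L || !is_count(threshold) || threshold < 1) {
    paf_domain_error("threshold must be a positive integer")
  }
  key <- if (per_sex) {
    paste(records$cancer_type_id, records$year, records$sex, sep = "\r")
  } else {
    paste(records$cancer_type_id, records$year, sep = "\r")
  }
  totals <- tapply(records$cases, key, sum)
  drop <- totals[totals < threshold]
  out <- key %in% names(drop)
  kept <- records[!out, , drop = FALSE]
  excluded <- records[out, , drop = FALSE]
  rownames(kept) <- rownames(excluded) <- NULL
  class(kept) <- class(excluded) <- c("incidence_table", "data.frame")
  log <- if (length(drop)) {
    parts <- strsplit(names(drop), "\r", fixed = TRUE)
    vapply(seq_along(drop), function(i) {
      sprintf("excluded diagnosis '%s' (%s): %s annual cases < %d",
              parts[[i]][1],
              paste(parts[[i]][-1], collapse = ", "),
              fmt_num(unname(drop[i])), threshold)
    }, character(1))
  } else {
    character(0)
  }
  structure(list(kept = kept, excluded = excluded), log = log)
}

#' Check the exposure-vintage / latency / incidence-year linkage
#'
#' A run binds each factor's exposure-table vintage to the incidence year
#' through an assumed latency: prevalences measured in `exposure_year` are
#' linked to incidence `latency_years` later. Returns whether
#' `incidence_year - exposure_year` equals the stated latency (e.g. 2008
#' exposures with a 10-year latency link to 2018 incidence; a 20-year
#' sensitivity run instead uses 1998 exposure data).
#'
#' @param exposure_year,incidence_year calendar years in 1900-2100.
#' @param latency_years non-negative integer.
#' @return `TRUE` iff the linkage is consistent. [paf_burden()] turns a
#'   `FALSE` into a configuration error naming the factor.
#' @examples
#' link_latency(2008, 2018, 10)  # TRUE
#' link_latency(1998, 2018, 20)  # TRUE
#' link_latency(2008, 2018, 20)  # FALSE
#' @export
link_latency <- function(exposure_year, incidence_year, latency_years) {
  if (!is_year(exposure_year) || !is_year(incidence_year)) {
    paf_domain_error("years must be calendar years in 1900-2100")
  }
  if (length(latency_years) != 1L || !is_count(latency_years)) {
    paf_domain_error("latency_years must be a non-negative integer")
  }
  incidence_year - exposure_year == latency_years
}

#' Attributable case count from a fraction and an incident count
#'
#' @param paf attributable fraction(s) in `[0, 1]`.
#' @param cases non-negative incident case count(s).
#' @return `paf * cases`, unrounded. Reports round to the nearest integer via
#'   [round_half_away()]; internal arithmetic always keeps the exact product.
#' @examples
#' attributable_cases(0.25, 1000)  # 250
#' @export
attributable_cases <- function(paf, cases) {
  paf <- as.numeric(paf)
  if (any(!is.finite(paf) | paf < 0 | paf > 1)) {
    paf_domain_error("attributable fractions must lie in [0, 1]")
  }
  if (any(!is.finite(cases) | cases < 0)) {
    paf_domain_error("case counts must be non-negative")
  }
  paf * cases
}

#' Overall burden summary from combined attribution rows
#'
#' Sums the combined (`"__combined__"`) attributable cases of an attribution
#' table and expresses them as a fraction of the total incident cases, with
#' the percentage reported to one decimal (ties away from zero).
#'
#' @param table an [attribution_table()] or data frame of attribution rows
#'   containing combined rows.
#' @param total_cases positive total incident case count (the denominator).
#' @return list with `total_cases`, `total_attributable`, `overall_paf`
#'   (unrounded fraction) and `overall_paf_pct` (percentage, one decimal).
#' @examples
#' tab <- data.frame(factor_id = "__combined__", cancer_type_id = "all",
#'                   sex = "male", paf = NA, attributable_cases = 14235)
#' aggregate_overall(tab, total_cases = 23078 + 21196)$overall_paf_pct  # 32.2
#' @export
aggregate_overall <- function(table, total_cases) {
  if (length(total_cases) != 1L || !is.finite(total_cases) || total_cases <= 0) {
    paf_domain_error("total_cases must be a single positive count")
  }
  df <- as.data.frame(table)
  comb <- df[df$factor_id == .combined_id, , drop = FALSE]
  if (nrow(comb) == 0L) {
    paf_config_error("attribution table has no combined ('__combined__') rows")
  }
  total_attributable <- sum(comb$attributable_cases)
  overall_paf <- total_attributable / total_cases
  list(
    total_cases = as.numeric(total_cases),
    total_attributable = total_attributable,
    overall_paf = overall_paf,
    overall_paf_pct = round_half_away(100 * overall_paf, 1)
  )
}

as_table <- function(x, reader, validator, what) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L) return(reader(x))
  if (is.data.frame(x)) return(validator(x, src = "<data.frame>"))
  paf_config_error(sprintf("%s must be a file path or a data frame", what))
}

#' Estimate the attributable cancer burden of a set of risk factors
#'
#' The package's central fitting function. Given registry-style incidence, a
#' set of [risk_factor_spec()]s, exposure prevalences and relative risks (and
#' optionally published direct fractions), it runs the full burden estimate
#' for one incidence year:
#'
#' 1. checks each factor's exposure-vintage/latency linkage against the
#'    incidence year ([link_latency()]);
#' 2. excludes diagnoses below the annual-incidence threshold
#'    ([filter_low_incidence()]);
#' 3. computes the attributable fraction of every factor x cancer type x sex
#'    cell ([paf_for_cell()]: the multi-level Levin formula for `rr_based`
#'    factors, pass-through for `direct_paf` factors);
#' 4. converts fractions to attributable cases, rolling subtype attributions
#'    up into their parent diagnosis;
#' 5. combines factors within each cancer type and sex via
#'    `1 - prod(1 - PAF)` ([combine_pafs()]); and
#' 6. aggregates to per-factor, per-cancer, per-sex and overall burden.
#'
#' The run is fully deterministic: identical inputs and options give
#' byte-identical report files from [write_burden_report()].
#'
#' @param incidence incidence table: path or data frame
#'   (see [read_incidence_table()]). Required.
#' @param factors a [risk_factor_spec()] or list of them.
#' @param exposure exposure-prevalence table (path or data frame); required
#'   when any factor is `rr_based`.
#' @param rr relative-risk table (path or data frame); required when any
#'   factor is `rr_based`.
#' @param direct_paf table of published fractions (path or data frame);
#'   required when any factor is `direct_paf`.
#' @param incidence_year the incidence year to attribute.
#' @param min_incidence annual-incidence exclusion threshold (default 10).
#' @param filter_per_sex apply the exclusion threshold within sex rather than
#'   to the diagnosis's total across sexes.
#' @param reduction_transform per-unit transform for reduction-framed RRs; see
#'   [err_from_rr()].
#' @param allow_negative_paf admit net-protective factors as signed fractions;
#'   see [paf_levin()].
#' @return an object of class `"paf_burden"` with components
#'   \describe{
#'     \item{attribution}{the [attribution_table()]: factor rows plus
#'       `"__combined__"` rows, unrounded.}
#'     \item{by_factor}{per-factor rollup: attributable cases (total and per
#'       sex) and share of all incident cases.}
#'     \item{by_cancer}{per-cancer rollup: incident cases, combined
#'       attributable cases and combined fraction.}
#'     \item{overall}{totals and overall fraction, also per sex.}
#'     \item{excluded}{incidence rows removed by the threshold.}
#'     \item{log}{structured text log: exclusions, forced-RR-1 cells, skipped
#'       cells, warnings.}
#'   }
#'   Methods: [print.paf_burden()], [summary.paf_burden()],
#'   [coef.paf_burden()], [plot.paf_burden()].
#' @examples
#' inc <- data.frame(cancer_type_id = "lung", subtype_of = NA, sex = "male",
#'                   year = 2018, cases = 300)
#' exp <- data.frame(factor_id = "smoking", sex = "male", level_id = "current",
#'                   proportion = 0.5, exposure_year = 2008)
#' rr <- data.frame(factor_id = "smoking", cancer_type_id = "lung",
#'                  sex = "male", level_id = "current", rr = 2,
#'                  significant = TRUE)
#' spec <- risk_factor_spec("smoking", exposure_year = 2008, latency_years = 10)
#' fit <- paf_burden(inc, spec, exposure = exp, rr = rr, incidence_year = 2018)
#' coef(fit)
#' @export
paf_burden <- function(incidence, factors, exposure = NULL, rr = NULL,
                       direct_paf = NULL, incidence_year,
                       min_incidence = 10, filter_per_sex = FALSE,
                       reduction_transform = c("log", "power"),
                       allow_negative_paf = FALSE) {
  cl <- match.call()
  reduction_transform <- match.arg(reduction_transform)
  if (missing(incidence) || is.null(incidence)) {
    paf_config_error("run configuration must name an incidence table")
  }
  if (missing(factors) || length(factors) == 0L) {
    paf_config_error("run configuration must include at least one risk factor")
  }
  if (inherits(factors, "risk_factor_spec")) factors <- list(factors)
  if (!all(vapply(factors, inherits, logical(1), "risk_factor_spec"))) {
    paf_config_error("factors must be risk_factor_spec objects")
  }
  fids <- vapply(factors, `[[`, character(1), "factor_id")
  if (anyDuplicated(fids)) {
    paf_config_error("duplicate factor_id in the factor list")
  }
  inc <- as_table(incidence, read_incidence_table, validate_incidence,
                  "incidence")
  if (missing(incidence_year)) {
    paf_config_error("run configuration must name the incidence year")
  }
  if (!is_year(incidence_year)) {
    paf_config_error("incidence_year must be a calendar year in 1900-2100")
  }
  incidence_year <- as.integer(incidence_year)
  exp_tab <- as_table(exposure, read_exposure_table, validate_exposure,
                      "exposure")
  rr_tab <- as_table(rr, read_rr_table, validate_rr, "rr")
  direct_tab <- as_table(direct_paf, read_direct_paf_table,
                         validate_direct_paf, "direct_paf")
  modes <- vapply(factors, `[[`, character(1), "evidence_mode")
  if (any(modes == "rr_based") && (is.null(exp_tab) || is.null(rr_tab))) {
    paf_config_error(
      "rr_based factors require both an exposure table and a relative-risk table"
    )
  }
  if (any(modes == "direct_paf") && is.null(direct_tab)) {
    paf_config_error("direct_paf factors require a direct_paf table")
  }

  log <- character(0)

  # latency linkage: each factor's exposure vintage must match the run year
  for (spec in factors) {
    if (!link_latency(spec$exposure_year, incidence_year, spec$latency_years)) {
      paf_config_error(sprintf(
        "factor '%s': exposure year %d with latency %d y does not link to incidence year %d",
        spec$factor_id, spec$exposure_year, spec$latency_years, incidence_year
      ))
    }
  }

  inc <- inc[inc$year == incidence_year, , drop = FALSE]
  if (nrow(inc) == 0L) {
    paf_config_error(sprintf(
      "incidence table has no records for year %d", incidence_year
    ))
  }
  class(inc) <- c("incidence_table", "data.frame")
  flt <- filter_low_incidence(inc, threshold = min_incidence,
                              per_sex = filter_per_sex)
  kept <- flt$kept
  log <- c(log, attr(flt, "log"))
  if (nrow(kept) == 0L) {
    paf_config_error("all incidence records fall below the exclusion threshold")
  }

  inc_cases <- function(cancer, sex) {
    i <- which(kept$cancer_type_id == cancer & kept$sex == sex)
    if (length(i)) kept[i[1], , drop = FALSE] else NULL
  }

  cells <- list()
  add_cell <- function(fid, cancer, sex, paf) {
    row <- inc_cases(cancer, sex)
    if (is.null(row)) {
      if (cancer %in% flt$excluded$cancer_type_id) {
        log <<- c(log, sprintf(
          "skipped factor '%s' x '%s' (%s): diagnosis excluded by incidence filter",
          fid, cancer, sex))
      } else {
        log <<- c(log, sprintf(
          "skipped factor '%s' x '%s' (%s): no incidence record in %d",
          fid, cancer, sex, incidence_year))
      }
      return(invisible(NULL))
    }
    report_type <- if (is.na(row$subtype_of)) row$cancer_type_id else row$subtype_of
    if (!is.na(row$subtype_of) && is.null(inc_cases(report_type, sex))) {
      paf_validation_error(sprintf(
        "subtype '%s' (%s) has no parent incidence row '%s' to roll up into",
        cancer, sex, report_type
      ))
    }
    cells[[length(cells) + 1L]] <<- data.frame(
      factor_id = fid, target_type = cancer, cancer_type_id = report_type,
      sex = sex, attributable_cases = attributable_cases(as.numeric(paf),
                                                         row$cases),
      stringsAsFactors = FALSE
    )
    invisible(NULL)
  }

  for (spec in factors) {
    fid <- spec$factor_id
    if (spec$evidence_mode == "rr_based") {
      frows <- rr_tab[rr_tab$factor_id == fid, , drop = FALSE]
      linked <- spec$linked_cancer_types %||% unique(frows$cancer_type_id)
      if (length(linked) == 0L) {
        paf_validation_error(sprintf(
          "factor '%s' is linked to no cancer types (none in the relative-risk table)",
          fid
        ))
      }
      erows <- exp_tab[exp_tab$factor_id == fid, , drop = FALSE]
      if (nrow(erows) == 0L) {
        paf_data_gap_error(sprintf(
          "factor '%s' has no exposure distribution", fid
        ))
      }
      sexes <- intersect(spec$sexes, unique(erows$sex))
      for (cancer in linked) {
        for (sx in sexes) {
          dist <- erows[erows$sex == sx, , drop = FALSE]
          rrs <- frows[frows$cancer_type_id == cancer & frows$sex == sx, ,
                       drop = FALSE]
          if (nrow(rrs) == 0L) {
            paf_data_gap_error(sprintf(
              "no relative risks for factor '%s', cancer type '%s', sex '%s'",
              fid, cancer, sx
            ))
          }
          forced <- rrs$level_id[!rrs$significant]
          if (length(forced)) {
            log <- c(log, sprintf(
              "factor '%s' x '%s' (%s): RR forced to 1 at level(s) %s (not statistically supported)",
              fid, cancer, sx, paste(forced, collapse = ", ")))
          }
          paf <- paf_for_cell(spec, dist = dist, rrs = rrs,
                              reduction_transform = reduction_transform,
                              allow_negative_paf = allow_negative_paf)
          add_cell(fid, cancer, sx, max(0, as.numeric(paf)))
        }
      }
    } else {
      drows <- direct_tab[direct_tab$factor_id == fid, , drop = FALSE]
      if (nrow(drows) == 0L) {
        paf_data_gap_error(sprintf(
          "factor '%s' has no rows in the direct_paf table", fid
        ))
      }
      linked <- spec$linked_cancer_types %||% unique(drows$cancer_type_id)
      if (length(linked) == 0L) {
        paf_validation_error(sprintf(
          "factor '%s' is linked to no cancer types", fid
        ))
      }
      drows <- drows[drows$cancer_type_id %in% linked &
                     drows$sex %in% spec$sexes, , drop = FALSE]
      for (i in seq_len(nrow(drows))) {
        paf <- paf_for_cell(spec, direct = drows$paf[i])
        add_cell(fid, drows$cancer_type_id[i], drows$sex[i], paf)
      }
    }
  }

  if (length(cells) == 0L) {
    paf_config_error("no computable factor x cancer x sex cells in this run")
  }
  cells <- do.call(rbind, cells)

  # roll up to (factor, reported cancer type, sex); subtype attributions are
  # summed into the parent and re-expressed against the parent's incidence
  agg_key <- paste(cells$factor_id, cells$cancer_type_id, cells$sex, sep = "\r")
  att <- tapply(cells$attributable_cases, agg_key, sum)
  parts <- strsplit(names(att), "\r", fixed = TRUE)
  factor_rows <- data.frame(
    factor_id = vapply(parts, `[[`, character(1), 1L),
    cancer_type_id = vapply(parts, `[[`, character(1), 2L),
    sex = vapply(parts, `[[`, character(1), 3L),
    attributable_cases = as.numeric(att),
    stringsAsFactors = FALSE
  )
  factor_rows$cell_cases <- mapply(function(cn, sx) inc_cases(cn, sx)$cases,
                                   factor_rows$cancer_type_id, factor_rows$sex)
  factor_rows$paf <- factor_rows$attributable_cases / factor_rows$cell_cases
  over <- factor_rows$paf > 1 + 1e-9
  if (any(over)) {
    paf_validation_error(sprintf(
      "factor '%s' x '%s' (%s): attributable cases exceed incident cases",
      factor_rows$factor_id[over][1], factor_rows$cancer_type_id[over][1],
      factor_rows$sex[over][1]
    ))
  }
  factor_rows$paf <- pmin(factor_rows$paf, 1)
  factor_rows <- factor_rows[order(factor_rows$factor_id,
                                   factor_rows$cancer_type_id,
                                   factor_rows$sex), , drop = FALSE]

  # combined rows per (cancer type, sex): order-free sequential combination
  comb_key <- paste(factor_rows$cancer_type_id, factor_rows$sex, sep = "\r")
  comb_list <- lapply(split(seq_len(nrow(factor_rows)), comb_key), function(idx) {
    cp <- as.numeric(combine_pafs(factor_rows$paf[idx]))
    cases <- factor_rows$cell_cases[idx[1]]
    data.frame(
      factor_id = .combined_id,
      cancer_type_id = factor_rows$cancer_type_id[idx[1]],
      sex = factor_rows$sex[idx[1]],
      paf = cp,
      attributable_cases = cp * cases,
      cell_cases = cases,
      stringsAsFactors = FALSE
    )
  })
  comb_rows <- do.call(rbind, comb_list)
  comb_rows <- comb_rows[order(comb_rows$cancer_type_id, comb_rows$sex), ,
                         drop = FALSE]

  # denominators: top-level kept diagnoses only (subtype rows would double count)
  top <- kept[is.na(kept$subtype_of), , drop = FALSE]
  sex_totals <- tapply(top$cases, top$sex, sum)
  total_cases <- sum(top$cases)
  sex_attributable <- tapply(comb_rows$attributable_cases, comb_rows$sex, sum)
  total_attributable <- sum(comb_rows$attributable_cases)

  cols <- c("factor_id", "cancer_type_id", "sex", "paf", "attributable_cases")
  attribution <- attribution_table(
    rbind(factor_rows[cols], comb_rows[cols]),
    total_cases = total_cases,
    total_attributable = total_attributable,
    overall_paf = total_attributable / total_cases
  )

  by_factor <- do.call(rbind, lapply(factors, function(spec) {
    idx <- factor_rows$factor_id == spec$factor_id
    att_sex <- vapply(.sexes, function(sx) {
      sum(factor_rows$attributable_cases[idx & factor_rows$sex == sx])
    }, numeric(1))
    tot <- sum(factor_rows$attributable_cases[idx])
    data.frame(
      factor_id = spec$factor_id,
      display_name = spec$display_name,
      attributable_cases = tot,
      attributable_male = att_sex[["male"]],
      attributable_female = att_sex[["female"]],
      paf_of_total = tot / total_cases,
      paf_pct = round_half_away(100 * tot / total_cases, 1),
      stringsAsFactors = FALSE
    )
  }))
  by_factor <- by_factor[order(-by_factor$attributable_cases), , drop = FALSE]
  rownames(by_factor) <- NULL

  cancer_cases <- tapply(comb_rows$cell_cases,
                         comb_rows$cancer_type_id, sum)
  cancer_att <- tapply(comb_rows$attributable_cases,
                       comb_rows$cancer_type_id, sum)
  by_cancer <- data.frame(
    cancer_type_id = names(cancer_cases),
    cases = as.numeric(cancer_cases),
    attributable_cases = as.numeric(cancer_att),
    combined_paf = as.numeric(cancer_att) / as.numeric(cancer_cases),
    paf_pct = round_half_away(100 * as.numeric(cancer_att) /
                                as.numeric(cancer_cases), 1),
    stringsAsFactors = FALSE
  )
  by_cancer <- by_cancer[order(-by_cancer$attributable_cases), , drop = FALSE]
  rownames(by_cancer) <- NULL

  structure(
    list(
      attribution = attribution,
      by_factor = by_factor,
      by_cancer = by_cancer,
      overall = list(
        total_cases = total_cases,
        total_attributable = total_attributable,
        overall_paf = total_attributable / total_cases,
        overall_paf_pct = round_half_away(100 * total_attributable / total_cases, 1),
        by_sex = data.frame(
          sex = .sexes,
          cases = vapply(.sexes, function(sx) {
            v <- sex_totals[sx]
            if (is.na(v)) 0 else as.numeric(v)
          }, numeric(1)),
          attributable_cases = vapply(.sexes, function(sx) {
            v <- sex_attributable[sx]
            if (is.na(v)) 0 else as.numeric(v)
          }, numeric(1)),
          stringsAsFactors = FALSE
        )
      ),
      excluded = flt$excluded,
      log = log,
      incidence_year = incidence_year,
      options = list(min_incidence = min_incidence,
                     filter_per_sex = filter_per_sex,
                     reduction_transform = reduction_transform,
                     allow_negative_paf = allow_negative_paf),
      call = cl
    ),
    class = "paf_burden"
  )
}

#' Write the report files of a burden run
#'
#' Writes `attribution.csv` (full precision, see [write_attribution_table()]),
#' `factor_summary.csv` and `cancer_summary.csv` (report rounding: case counts
#' to the nearest integer, percentages to one decimal) and `run_log.txt` into
#' `dir`. Output is deterministic: identical fits give byte-identical files.
#'
#' @param object a [paf_burden()] fit.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_burden_report <- function(object, dir) {
  stopifnot(inherits(object, "paf_burden"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("attribution.csv", "factor_summary.csv",
                            "cancer_summary.csv", "run_log.txt"))
  write_attribution_table(object$attribution, paths[1])

  bf <- object$by_factor
  writeLines(c(
    "factor_id,display_name,attributable_cases,attributable_male,attributable_female,paf_pct",
    sprintf("%s,%s,%s,%s,%s,%s", bf$factor_id, bf$display_name,
            fmt_num(round_half_away(bf$attributable_cases)),
            fmt_num(round_half_away(bf$attributable_male)),
            fmt_num(round_half_away(bf$attributable_female)),
            sprintf("%.1f", bf$paf_pct))
  ), paths[2], useBytes = TRUE)

  bc <- object$by_cancer
  writeLines(c(
    "cancer_type_id,cases,attributable_cases,paf_pct",
    sprintf("%s,%s,%s,%s", bc$cancer_type_id, fmt_num(bc$cases),
            fmt_num(round_half_away(bc$attributable_cases)),
            sprintf("%.1f", bc$paf_pct))
  ), paths[3], useBytes = TRUE)

  ov <- object$overall
  writeLines(c(
    sprintf("incidence year %d: %s cases, %s attributable (%.1f%%)",
            object$incidence_year, fmt_num(ov$total_cases),
            fmt_num(round_half_away(ov$total_attributable)),
            ov$overall_paf_pct),
    object$log
  ), paths[4], useBytes = TRUE)
  invisible(paths)
}
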