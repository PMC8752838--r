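#' Describe one risk factor
#'
#' A risk-factor specification binds together everything the burden estimator
#' needs to know about one exposure: which cancer types it is causally linked
#' to, which sexes it applies to, whether its evidence is a set of relative
#' risks (`rr_based`) or a published attributable fraction adopted as-is
#' (`direct_paf`), how an `rr_based` risk is framed, and the exposure-table
#' vintage together with the assumed latency to incidence.
#'
#' Latency is metadata, not modelling: an alternative latency assumption means
#' binding an alternative exposure-table vintage (e.g. prevalences measured 20
#' rather than 10 years before the incidence year), and [paf_burden()] checks
#' that `exposure_year + latency_years` equals the incidence year of the run.
#'
#' @param factor_id short identifier used in the input tables.
#' @param evidence_mode `"rr_based"` or `"direct_paf"`. Direct factors carry no
#'   exposure distribution and no relative-risk rows.
#' @param display_name human-readable name used in reports.
#' @param framing `"harmful"` or `"reduction"`; only for `rr_based` factors.
#' @param n_units positive integer; number of exposure units a
#'   reduction-framed RR spans. Only meaningful for `framing = "reduction"`.
#' @param linked_cancer_types character vector of cancer-type ids this factor
#'   is linked to. May be `NULL`, in which case [paf_burden()] derives the set
#'   from the relative-risk (or direct-fraction) table; the derived set must
#'   be non-empty.
#' @param sexes subset of `c("male", "female")` the factor applies to.
#' @param exposure_year calendar year the exposure prevalences refer to.
#' @param latency_years non-negative integer; assumed exposure-to-incidence
#'   interval.
#' @return an object of class `"risk_factor_spec"`.
#' @examples
#' risk_factor_spec("smoking", exposure_year = 2008, latency_years = 10)
#' risk_factor_spec("physical_inactivity", framing = "reduction", n_units = 1,
#'                  exposure_year = 2008, latency_years = 10)
#' risk_factor_spec("hpv", evidence_mode = "direct_paf",
#'                  linked_cancer_types = c("cervix", "anus"),
#'                  exposure_year = 2008, latency_years = 10)
#' @export
risk_factor_spec <- function(factor_id,
                             evidence_mode = c("rr_based", "direct_paf"),
                             display_name = factor_id,
                             framing = c("harmful", "reduction"),
                             n_units = 1L,
                             linked_cancer_types = NULL,
                             sexes = c("male", "female"),
                             exposure_year,
                             latency_years) {
  evidence_mode <- match.arg(evidence_mode)
  if (!is.character(factor_id) || length(factor_id) != 1L || !nzchar(factor_id)) {
    paf_validation_error("factor_id must be a single non-empty string")
  }
  sexes <- match.arg(sexes, several.ok = TRUE)
  if (!is_year(exposure_year)) {
    paf_validation_error(sprintf(
      "factor '%s': exposure_year must be a calendar year in 1900-2100", factor_id
    ))
  }
  if (length(latency_years) != 1L || !is_count(latency_years)) {
    paf_validation_error(sprintf(
      "factor '%s': latency_years must be a non-negative integer", factor_id
    ))
  }
  if (!is.null(linked_cancer_types)) {
    linked_cancer_types <- unique(as.character(linked_cancer_types))
    if (length(linked_cancer_types) == 0L) {
      paf_validation_error(sprintf(
        "factor '%s': linked_cancer_types must be non-empty", factor_id
      ))
    }
  }
  if (evidence_mode == "rr_based") {
    framing <- match.arg(framing)
    if (length(n_units) != 1L || !is_count(n_units) || n_units < 1) {
      paf_validation_error(sprintf(
        "factor '%s': n_units must be an integer >= 1", factor_id
      ))
    }
    n_units <- as.integer(n_units)
  } else {
    framing <- NULL
    n_units <- NULL
  }
  structure(
    list(
      factor_id = factor_id,
      display_name = display_name,
      evidence_mode = evidence_mode,
      framing = framing,
      n_units = n_units,
      linked_cancer_types = linked_cancer_types,
      sexes = sexes,
      exposure_year = as.integer(exposure_year),
      latency_years = as.integer(latency_years)
    ),
    class = "risk_factor_spec"
  )
}

#' @export
print.risk_factor_spec <- function(x, ...) {
  cat(sprintf("risk factor '%s' (%s)\n", x$factor_id, x$evidence_mode))
  if (x$evidence_mode == "rr_based") {
    cat(sprintf("  framing: %s", x$framing))
    if (identical(x$framing, "reduction")) cat(sprintf(", %d unit(s)", x$n_units))
    cat("\n")
  }
  cat(sprintf("  sexes: %s\n", paste(x$sexes, collapse = ", ")))
  cat(sprintf("  exposure year %d, latency %d y\n", x$exposure_year, x$latency_years))
  if (!is.null(x$linked_cancer_types)) {
    cat(sprintf("  linked cancer types: %s\n",
                paste(x$linked_cancer_types, collapse = ", ")))
  }
  invisible(x)
}
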