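# Computational core: ERR derivation, the multi-level Levin formula, and
# order-free combination of several factors. Pure functions, no file I/O.

#' Excess relative risk from a published relative risk
#'
#' Converts a relative risk to the excess relative risk (ERR) used by the
#' attributable-fraction formula. Two framings are supported:
#'
#' * `"harmful"` — the RR describes the exposed (higher-risk) group relative to
#'   the reference, and `ERR = RR - 1`.
#' * `"reduction"` — the published RR describes a lower-risk comparison (for
#'   example active versus inactive), so the harmful-direction excess is
#'   derived as `log(1/RR)`, divided by `n_units` when the RR spans several
#'   exposure units. `reduction_transform = "power"` instead uses the exact
#'   per-unit rescaling `(1/RR)^(1/n_units) - 1`; the two agree to first order
#'   in `RR - 1` and the option makes the choice auditable in sensitivity
#'   analyses.
#'
#' Associations without statistical support (`significant = FALSE`) are forced
#' to a null effect: the effective RR is 1 and the ERR is exactly 0, whatever
#' the published point estimate.
#'
#' @param rr positive relative risk(s).
#' @param framing `"harmful"` or `"reduction"`.
#' @param n_units positive integer; number of exposure units the published RR
#'   spans. Used only for `framing = "reduction"`; a value above 1 under
#'   harmful framing triggers a warning and is ignored.
#' @param significant logical; `FALSE` forces a zero ERR.
#' @param reduction_transform `"log"` (default, `log(1/RR)/n_units`) or
#'   `"power"` (`(1/RR)^(1/n_units) - 1`).
#' @return numeric vector of ERRs, each `>= -1` for `RR <= e`.
#' @examples
#' err_from_rr(2.0, "harmful")                # 1
#' err_from_rr(0.5, "reduction")              # log(2)
#' err_from_rr(0.5, "reduction", n_units = 5) # log(2)/5
#' err_from_rr(3.7, "harmful", significant = FALSE)  # 0
#' @seealso [paf_levin()], [paf_for_cell()]
#' @export
err_from_rr <- function(rr, framing = c("harmful", "reduction"), n_units = 1L,
                        significant = TRUE,
                        reduction_transform = c("log", "power")) {
  framing <- match.arg(framing)
  reduction_transform <- match.arg(reduction_transform)
  if (!is.numeric(rr) || any(!is.finite(rr)) || any(rr <= 0)) {
    paf_domain_error("relative risks must be finite and strictly positive")
  }
  if (length(n_units) != 1L || !is_count(n_units) || n_units < 1) {
    paf_domain_error("n_units must be a single integer >= 1")
  }
  significant <- rep_len(as.logical(significant), length(rr))
  if (framing == "harmful") {
    if (n_units > 1) {
      warning("n_units is ignored under harmful framing", call. = FALSE)
    }
    err <- rr - 1
  } else {
    err <- switch(reduction_transform,
      log   = log(1 / rr) / n_units,
      power = (1 / rr)^(1 / n_units) - 1
    )
  }
  err[!significant] <- 0
  err
}

#' Multi-level Levin attributable fraction
#'
#' Computes `PAF = S / (1 + S)` with `S = sum(p * err)` over the non-reference
#' exposure levels, where `p` is the proportion of the population at each level
#' and `err` the excess relative risk at that level. For a population whose
#' strata carry multiplicative risks this equals the exact excess-case
#' fraction `1 - 1/E[RR]`.
#'
#' @param p proportions of the population in each non-reference exposure level;
#'   each in `[0, 1]`, summing to at most 1 (the reference level holds the
#'   remainder and contributes zero excess).
#' @param err excess relative risks aligned with `p`; each `>= -1`.
#' @param allow_negative_paf logical. Net-protective inputs (`S < 0`) are
#'   rejected by default, since the estimator considers only the harmful
#'   direction of each factor; set `TRUE` to obtain the signed value for
#'   methodological work.
#' @return a single attributable fraction; in `[0, 1)` whenever all
#'   `err >= 0`, exactly 0 when all `err = 0`. Carries class `"paf_value"`
#'   with a `source = "computed"` attribute.
#' @examples
#' paf_levin(0.5, 1)                      # RR 2 in half the population: 1/3
#' paf_levin(c(0.3, 0.1), c(0.5, 2.0))    # 0.35 / 1.35
#' @seealso [err_from_rr()], [combine_pafs()]
#' @export
paf_levin <- function(p, err, allow_negative_paf = FALSE) {
  if (length(p) != length(err)) {
    paf_domain_error("p and err must align one-to-one over exposure levels")
  }
  if (length(p) == 0L) {
    return(paf_value(0, "computed"))
  }
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    paf_domain_error("exposure proportions must lie in [0, 1]")
  }
  if (sum(p) > 1 + 1e-9) {
    paf_domain_error(sprintf(
      "exposure proportions sum to %.6f; non-reference levels may not exceed 1",
      sum(p)
    ))
  }
  if (!is.numeric(err) || any(!is.finite(err)) || any(err < -1)) {
    paf_domain_error("excess relative risks must be finite and >= -1")
  }
  s <- sum(p * err)
  if (1 + s <= 0) {
    paf_domain_error("1 + sum(p * err) <= 0: inconsistent exposure/risk inputs")
  }
  if (s < 0 && !allow_negative_paf) {
    paf_domain_error(paste0(
      "net-protective input (sum(p * err) < 0); only the harmful direction is ",
      "considered unless allow_negative_paf = TRUE"
    ))
  }
  paf_value(s / (1 + s), "computed")
}

#' Combine attributable fractions of several independent factors
#'
#' Joint attributable fraction over several risk factors, computed so that
#' cases attributed to one factor are not re-attributed to another:
#' `1 - prod(1 - paf)`. This closed form is exactly the result of applying each
#' factor's fraction sequentially to the cases not yet attributed by earlier
#' factors, and is independent of the ordering.
#'
#' @param pafs numeric vector of attributable fractions, each in `[0, 1]`.
#' @return the combined fraction, in `[max(pafs), 1]` and at most `sum(pafs)`.
#' @examples
#' combine_pafs(c(0.5, 0.5))  # 0.75
#' combine_pafs(0.3)          # 0.3
#' @export
combine_pafs <- function(pafs) {
  pafs <- as.numeric(pafs)
  if (length(pafs) == 0L) {
    return(paf_value(0, "computed"))
  }
  if (any(!is.finite(pafs)) || any(pafs < 0) || any(pafs > 1)) {
    paf_domain_error("attributable fractions must lie in [0, 1]")
  }
  pafs <- pafs[pafs > 0] # null factors contribute nothing, exactly
  if (length(pafs) == 0L) return(paf_value(0, "computed"))
  if (length(pafs) == 1L) return(paf_value(pafs, "computed"))
  paf_value(1 - prod(1 - pafs), "computed")
}

#' Attributable fraction for one factor x cancer type x sex cell
#'
#' Dispatches on the factor's evidence mode: `direct_paf` factors pass a
#' published attributable fraction through unchanged; `rr_based` factors build
#' the ERR vector from the factor's exposure distribution and relative risks
#' and evaluate the Levin formula.
#'
#' @param spec a [risk_factor_spec()].
#' @param dist for `rr_based` factors, the exposure distribution for this
#'   factor and sex: a data frame with columns `level_id` and `proportion`
#'   including an explicit reference row (level id `"ref"`), as returned by
#'   [read_exposure_table()].
#' @param rrs for `rr_based` factors, the relative-risk rows for this factor,
#'   cancer type and sex: a data frame with columns `level_id`, `rr`,
#'   `significant`. The reference level may be omitted (RR 1 implied); every
#'   non-reference exposure level must have a row — a missing level is a
#'   data-gap error, never a silent RR of 1.
#' @param direct for `direct_paf` factors, the published fraction in `[0, 1)`.
#' @param reduction_transform,allow_negative_paf passed to [err_from_rr()] and
#'   [paf_levin()].
#' @return a `"paf_value"`: the fraction with a `source` attribute
#'   (`"computed"` or `"direct"`).
#' @examples
#' uv <- risk_factor_spec("uv", evidence_mode = "direct_paf",
#'                        linked_cancer_types = "melanoma",
#'                        exposure_year = 2008, latency_years = 10)
#' paf_for_cell(uv, direct = 0.932)
#' @export
paf_for_cell <- function(spec, dist = NULL, rrs = NULL, direct = NULL,
                         reduction_transform = c("log", "power"),
                         allow_negative_paf = FALSE) {
  stopifnot(inherits(spec, "risk_factor_spec"))
  if (spec$evidence_mode == "direct_paf") {
    if (is.null(direct)) {
      paf_data_gap_error(sprintf(
        "factor '%s' uses direct published fractions but none was supplied",
        spec$factor_id
      ))
    }
    if (!is.numeric(direct) || length(direct) != 1L || !is.finite(direct) ||
        direct < 0 || direct >= 1) {
      paf_validation_error(sprintf(
        "direct attributable fraction for factor '%s' must lie in [0, 1)",
        spec$factor_id
      ))
    }
    return(paf_value(direct, "direct"))
  }
  if (is.null(dist) || is.null(rrs)) {
    paf_data_gap_error(sprintf(
      "factor '%s' is rr_based and needs both an exposure distribution and relative risks",
      spec$factor_id
    ))
  }
  nonref <- dist[dist$level_id != .ref_level, , drop = FALSE]
  err <- numeric(nrow(nonref))
  for (i in seq_len(nrow(nonref))) {
    hit <- rrs$level_id == nonref$level_id[i]
    if (!any(hit)) {
      paf_data_gap_error(sprintf(
        "no relative risk for factor '%s', cancer type '%s', sex '%s', level '%s'",
        spec$factor_id,
        if (nrow(rrs)) rrs$cancer_type_id[1] else "?",
        if (nrow(rrs)) rrs$sex[1] else "?",
        nonref$level_id[i]
      ))
    }
    row <- rrs[which(hit)[1], ]
    err[i] <- err_from_rr(row$rr, spec$framing, spec$n_units,
                          significant = row$significant,
                          reduction_transform = reduction_transform)
  }
  paf_levin(nonref$proportion, err, allow_negative_paf = allow_negative_paf)
}

paf_value <- function(value, source = c("computed", "direct")) {
  source <- match.arg(source)
  structure(as.numeric(value), class = "paf_value", source = source)
}

#' @export
print.paf_value <- function(x, ...) {
  cat(sprintf("attributable fraction: %.6f (%s)\n",
              as.numeric(x), attr(x, "source")))
  invisible(x)
}
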