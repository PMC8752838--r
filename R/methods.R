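# S3 methods for paf_burden fits.

#' @export
print.paf_burden <- function(x, ...) {
  ov <- x$overall
  cat(sprintf("Attributable cancer burden, incidence year %d\n",
              x$incidence_year))
  cat(sprintf("  %s incident cases; %s attributable to %d risk factor(s): %.1f%%\n",
              fmt_num(ov$total_cases),
              fmt_num(round_half_away(ov$total_attributable)),
              nrow(x$by_factor), ov$overall_paf_pct))
  bs <- ov$by_sex
  for (i in seq_len(nrow(bs))) {
    if (bs$cases[i] > 0) {
      cat(sprintf("  %s: %s of %s cases (%.1f%%)\n", bs$sex[i],
                  fmt_num(round_half_away(bs$attributable_cases[i])),
                  fmt_num(bs$cases[i]),
                  round_half_away(100 * bs$attributable_cases[i] / bs$cases[i], 1)))
    }
  }
  if (nrow(x$excluded)) {
    cat(sprintf("  %d diagnosis record(s) excluded below %d annual cases\n",
                nrow(x$excluded), x$options$min_incidence))
  }
  cat("\nLeading factors (share of all incident cases):\n")
  top <- utils::head(x$by_factor, 5L)
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  %-24s %6s cases  %5.1f%%\n", top$display_name[i],
                fmt_num(round_half_away(top$attributable_cases[i])),
                top$paf_pct[i]))
  }
  invisible(x)
}

#' Summarize a burden fit
#'
#' @param object a [paf_burden()] fit.
#' @param ... unused.
#' @return an object of class `"summary.paf_burden"` bundling the per-factor
#'   and per-cancer rollups, per-sex totals and the exclusion log.
#' @export
summary.paf_burden <- function(object, ...) {
  structure(
    list(
      incidence_year = object$incidence_year,
      overall = object$overall,
      by_factor = object$by_factor,
      by_cancer = object$by_cancer,
      excluded = object$excluded,
      log = object$log
    ),
    class = "summary.paf_burden"
  )
}

#' @export
print.summary.paf_burden <- function(x, ...) {
  ov <- x$overall
  cat(sprintf("Attributable cancer burden, incidence year %d\n",
              x$incidence_year))
  cat(sprintf("Overall: %s of %s cases attributable (%.1f%%)\n\n",
              fmt_num(round_half_away(ov$total_attributable)),
              fmt_num(ov$total_cases), ov$overall_paf_pct))
  cat("By risk factor:\n")
  bf <- x$by_factor
  print(data.frame(
    factor = bf$display_name,
    attributable = round_half_away(bf$attributable_cases),
    male = round_half_away(bf$attributable_male),
    female = round_half_away(bf$attributable_female),
    `paf_%` = sprintf("%.1f", bf$paf_pct),
    check.names = FALSE
  ), row.names = FALSE)
  cat("\nBy cancer type (combined over factors):\n")
  bc <- x$by_cancer
  print(data.frame(
    cancer = bc$cancer_type_id,
    cases = bc$cases,
    attributable = round_half_away(bc$attributable_cases),
    `paf_%` = sprintf("%.1f", bc$paf_pct),
    check.names = FALSE
  ), row.names = FALSE)
  if (length(x$log)) {
    cat("\nLog:\n")
    cat(paste0("  ", x$log), sep = "\n")
  }
  invisible(x)
}

#' Per-factor attributable fractions of a burden fit
#'
#' @param object a [paf_burden()] fit.
#' @param ... unused.
#' @return named numeric vector: each factor's attributable cases as a
#'   fraction of all incident cases in the run (unrounded).
#' @export
coef.paf_burden <- function(object, ...) {
  stats::setNames(object$by_factor$paf_of_total, object$by_factor$factor_id)
}

#' Plot a burden fit
#'
#' Horizontal bar chart of attributable cases by risk factor (the per-factor
#' rollup), annotated with each factor's share of all incident cases.
#'
#' @param x a [paf_burden()] fit.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the bar midpoints.
#' @export
plot.paf_burden <- function(x, ...) {
  bf <- x$by_factor[order(x$by_factor$attributable_cases), , drop = FALSE]
  op <- graphics::par(mar = c(5, 10, 3, 2))
  on.exit(graphics::par(op))
  mid <- graphics::barplot(
    bf$attributable_cases,
    names.arg = sprintf("%s (%.1f%%)", bf$display_name, bf$paf_pct),
    horiz = TRUE, las = 1,
    xlab = "attributable cases",
    main = sprintf("Attributable cancer burden, %d", x$incidence_year),
    ...
  )
  invisible(mid)
}

#' @export
as.data.frame.paf_burden <- function(x, ...) {
  as.data.frame(x$attribution, ...)
}
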