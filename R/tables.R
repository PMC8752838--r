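# Schema-validated readers and writers for the four interchange tables.
# All files are UTF-8, comma-delimited, one header row, decimal point
# regardless of locale. Numeric columns are written with 17 significant
# digits so that write followed by read reproduces every double exactly.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  # trim a plain integer representation where exact
  whole <- is.finite(x) & x == round(x) & abs(x) < 2^53
  out[whole] <- sprintf("%.0f", x[whole])
  out
}

write_paf_csv <- function(df, path, numeric_cols, prelude = character()) {
  cols <- names(df)
  body <- vapply(seq_len(nrow(df)), function(i) {
    cells <- vapply(cols, function(cl) {
      v <- df[[cl]][i]
      if (cl %in% numeric_cols) fmt_num(v)
      else if (is.logical(v)) ifelse(is.na(v), "", ifelse(v, "TRUE", "FALSE"))
      else if (is.na(v)) "" else as.character(v)
    }, character(1))
    paste(cells, collapse = ",")
  }, character(1))
  writeLines(c(prelude, paste(cols, collapse = ","), body), path, useBytes = TRUE)
  invisible(path)
}

read_raw_csv <- function(path, kind) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    paf_input_error(sprintf("%s table: file '%s' does not exist", kind, path))
  }
  df <- tryCatch(
    utils::read.csv(path, colClasses = "character", check.names = FALSE,
                    comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) {
      paf_input_error(sprintf("%s table '%s': unreadable CSV (%s)",
                              kind, path, conditionMessage(e)))
    }
  )
  df
}

check_schema <- function(df, required, src, kind) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    paf_input_error(sprintf(
      "%s table '%s': missing column(s) %s; expected header '%s'",
      kind, src, paste(sprintf("'%s'", missing), collapse = ", "),
      paste(required, collapse = ",")
    ))
  }
  df[required]
}

num_col <- function(df, col, src, kind) {
  raw <- df[[col]]
  out <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(out) & !(is.na(raw) | raw == ""))
  if (length(bad)) {
    paf_validation_error(sprintf(
      "%s table '%s': column '%s' row %d: '%s' is not a number",
      kind, src, col, bad[1] + 1L, raw[bad[1]]
    ))
  }
  out
}

check_filled <- function(df, col, src, kind) {
  bad <- which(is.na(df[[col]]) | df[[col]] == "")
  if (length(bad)) {
    paf_validation_error(sprintf(
      "%s table '%s': column '%s' row %d is empty",
      kind, src, col, bad[1] + 1L
    ))
  }
  df[[col]]
}

check_sex <- function(sex, src, kind) {
  bad <- which(!sex %in% .sexes)
  if (length(bad)) {
    paf_validation_error(sprintf(
      "%s table '%s': column 'sex' row %d: '%s' is not 'male' or 'female'",
      kind, src, bad[1] + 1L, sex[bad[1]]
    ))
  }
  sex
}

check_nonempty <- function(df, src, kind) {
  if (nrow(df) == 0L) {
    paf_validation_error(sprintf("%s table '%s' contains no data rows", kind, src))
  }
  df
}

# ---- exposure ---------------------------------------------------------------

exposure_cols <- c("factor_id", "sex", "level_id", "proportion", "exposure_year")

validate_exposure <- function(df, src = "<data.frame>") {
  kind <- "exposure"
  df <- check_schema(as.data.frame(df, stringsAsFactors = FALSE),
                     exposure_cols, src, kind)
  check_nonempty(df, src, kind)
  df$factor_id <- check_filled(df, "factor_id", src, kind)
  df$level_id <- check_filled(df, "level_id", src, kind)
  df$sex <- check_sex(check_filled(df, "sex", src, kind), src, kind)
  df$proportion <- num_col(df, "proportion", src, kind)
  df$exposure_year <- num_col(df, "exposure_year", src, kind)
  bad <- which(!is.finite(df$proportion) | df$proportion < 0 | df$proportion > 1)
  if (length(bad)) {
    paf_validation_error(sprintf(
      "exposure table '%s': column 'proportion' row %d: %s outside [0, 1] for factor '%s'",
      src, bad[1] + 1L, format(df$proportion[bad[1]]), df$factor_id[bad[1]]
    ))
  }
  bad <- which(!is_year(df$exposure_year))
  if (length(bad)) {
    paf_validation_error(sprintf(
      "exposure table '%s': column 'exposure_year' row %d is not a calendar year",
      src, bad[1] + 1L
    ))
  }
  df$exposure_year <- as.integer(df$exposure_year)
  key <- paste(df$factor_id, df$sex, df$level_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    paf_validation_error(sprintf(
      "exposure table '%s': duplicate level for factor '%s'",
      src, strsplit(d, "\r", fixed = TRUE)[[1]][1]
    ))
  }
  groups <- split(seq_len(nrow(df)), paste(df$factor_id, df$sex, sep = "\r"))
  extra <- list()
  for (idx in groups) {
    tot <- sum(df$proportion[idx])
    fid <- df$factor_id[idx[1]]
    if (tot > 1 + 1e-9) {
      paf_validation_error(sprintf(
        "exposure table '%s': proportions for factor '%s' (%s) sum to %.6f > 1",
        src, fid, df$sex[idx[1]], tot
      ))
    }
    if (length(unique(df$exposure_year[idx])) != 1L) {
      paf_validation_error(sprintf(
        "exposure table '%s': factor '%s' (%s) mixes exposure years",
        src, fid, df$sex[idx[1]]
      ))
    }
    if (!.ref_level %in% df$level_id[idx]) {
      # materialize the implicit reference level with the remaining mass
      extra[[length(extra) + 1L]] <- data.frame(
        factor_id = fid, sex = df$sex[idx[1]], level_id = .ref_level,
        proportion = 1 - tot, exposure_year = df$exposure_year[idx[1]],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(extra)) df <- rbind(df, do.call(rbind, extra))
  df <- df[order(df$factor_id, df$sex, df$level_id == .ref_level, df$level_id), ]
  rownames(df) <- NULL
  class(df) <- c("exposure_table", "data.frame")
  df
}

#' Read / write an exposure-prevalence table
#'
#' The exposure table gives, for each risk factor and sex, the proportion of
#' the population in each exposure level in the reference exposure year.
#' Columns: `factor_id,sex,level_id,proportion,exposure_year`. The reserved
#' level id `"ref"` marks the reference (unexposed / lowest-risk) level; it may
#' be listed explicitly or left implicit, in which case it is materialized with
#' proportion `1 - sum(others)`. Proportions must lie in `[0, 1]` and sum to at
#' most 1 within each factor and sex.
#'
#' @param path file to read or write.
#' @param x a validated `exposure_table` (for writing).
#' @return `read_exposure_table()` returns a data frame of class
#'   `"exposure_table"` with an explicit reference row per factor and sex;
#'   `write_exposure_table()` writes `x` losslessly (a read-back equals `x`
#'   field by field) and returns `path` invisibly.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("factor_id,sex,level_id,proportion,exposure_year",
#'              "smoking,male,current,0.25,2008"), tf)
#' read_exposure_table(tf)  # reference level gets proportion 0.75
#' @export
read_exposure_table <- function(path) {
  validate_exposure(read_raw_csv(path, "exposure"), src = path)
}

#' @rdname read_exposure_table
#' @export
write_exposure_table <- function(x, path) {
  x <- validate_exposure(x, src = "<in-memory>")
  write_paf_csv(x, path, numeric_cols = c("proportion", "exposure_year"))
}

# ---- relative risks ---------------------------------------------------------

rr_cols <- c("factor_id", "cancer_type_id", "sex", "level_id", "rr", "significant")

validate_rr <- function(df, src = "<data.frame>") {
  kind <- "relative-risk"
  df <- check_schema(as.data.frame(df, stringsAsFactors = FALSE),
                     rr_cols, src, kind)
  check_nonempty(df, src, kind)
  for (cl in c("factor_id", "cancer_type_id", "level_id")) {
    df[[cl]] <- check_filled(df, cl, src, kind)
  }
  df$sex <- check_sex(check_filled(df, "sex", src, kind), src, kind)
  df$rr <- num_col(df, "rr", src, kind)
  bad <- which(!is.finite(df$rr) | df$rr <= 0)
  if (length(bad)) {
    paf_validation_error(sprintf(
      "relative-risk table '%s': column 'rr' row %d: relative risk must be > 0",
      src, bad[1] + 1L
    ))
  }
  if (!is.logical(df$significant)) {
    sig <- toupper(trimws(as.character(df$significant)))
    parsed <- ifelse(sig %in% c("TRUE", "T", "1"), TRUE,
              ifelse(sig %in% c("FALSE", "F", "0"), FALSE, NA))
    bad <- which(is.na(parsed))
    if (length(bad)) {
      paf_validation_error(sprintf(
        "relative-risk table '%s': column 'significant' row %d: '%s' is not a logical",
        src, bad[1] + 1L, df$significant[bad[1]]
      ))
    }
    df$significant <- parsed
  }
  key <- paste(df$factor_id, df$cancer_type_id, df$sex, df$level_id, sep = "\r")
  if (anyDuplicated(key)) {
    paf_validation_error(sprintf(
      "relative-risk table '%s': duplicate (factor, cancer type, sex, level) row",
      src
    ))
  }
  rownames(df) <- NULL
  class(df) <- c("rr_table", "data.frame")
  df
}

#' Read / write a relative-risk table
#'
#' One row per risk factor x cancer type x sex x exposure level. Columns:
#' `factor_id,cancer_type_id,sex,level_id,rr,significant`. The reference level
#' (RR 1) may be omitted. `significant = FALSE` marks an association the
#' evidence review did not support statistically: the RR is forced to 1 in all
#' downstream attributable-fraction calculations, so deliberate nulls are
#' stated explicitly rather than left as data gaps.
#'
#' @inheritParams read_exposure_table
#' @param x a validated `rr_table` (for writing).
#' @return `read_rr_table()` returns a data frame of class `"rr_table"`;
#'   the writer is lossless and returns `path` invisibly.
#' @export
read_rr_table <- function(path) {
  validate_rr(read_raw_csv(path, "relative-risk"), src = path)
}

#' @rdname read_rr_table
#' @export
write_rr_table <- function(x, path) {
  x <- validate_rr(x, src = "<in-memory>")
  write_paf_csv(x, path, numeric_cols = "rr")
}

# ---- incidence --------------------------------------------------------------

incidence_cols <- c("cancer_type_id", "subtype_of", "sex", "year", "cases")

validate_incidence <- function(df, src = "<data.frame>") {
  kind <- "incidence"
  df <- check_schema(as.data.frame(df, stringsAsFactors = FALSE),
                     incidence_cols, src, kind)
  check_nonempty(df, src, kind)
  df$cancer_type_id <- check_filled(df, "cancer_type_id", src, kind)
  df$sex <- check_sex(check_filled(df, "sex", src, kind), src, kind)
  df$subtype_of <- as.character(df$subtype_of)
  df$subtype_of[is.na(df$subtype_of) | df$subtype_of == ""] <- NA_character_
  df$year <- num_col(df, "year", src, kind)
  bad <- which(!is_year(df$year))
  if (length(bad)) {
    paf_validation_error(sprintf(
      "incidence table '%s': column 'year' row %d is not a calendar year",
      src, bad[1] + 1L
    ))
  }
  df$year <- as.integer(df$year)
  df$cases <- num_col(df, "cases", src, kind)
  bad <- which(!is_count(df$cases))
  if (length(bad)) {
    paf_validation_error(sprintf(
      "incidence table '%s': column 'cases' row %d: case counts must be non-negative integers",
      src, bad[1] + 1L
    ))
  }
  df$cases <- as.numeric(df$cases)
  key <- paste(df$cancer_type_id, df$sex, df$year, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    paf_validation_error(sprintf(
      "incidence table '%s': duplicate record for cancer type '%s' (%s, %d)",
      src, df$cancer_type_id[d], df$sex[d], df$year[d]
    ))
  }
  # a subtype can never exceed its parent in the same sex and year
  sub <- which(!is.na(df$subtype_of))
  for (i in sub) {
    p <- which(df$cancer_type_id == df$subtype_of[i] &
               df$sex == df$sex[i] & df$year == df$year[i])
    if (length(p) && df$cases[i] > df$cases[p[1]]) {
      paf_validation_error(sprintf(
        "incidence table '%s': subtype '%s' (%s, %d) has %s cases, exceeding parent '%s' (%s)",
        src, df$cancer_type_id[i], df$sex[i], df$year[i], fmt_num(df$cases[i]),
        df$subtype_of[i], fmt_num(df$cases[p[1]])
      ))
    }
  }
  rownames(df) <- NULL
  class(df) <- c("incidence_table", "data.frame")
  df
}

#' Read / write a registry-style incidence table
#'
#' One row per cancer type x sex x year with the diagnosed case count.
#' Columns: `cancer_type_id,subtype_of,sex,year,cases`. `subtype_of` is empty
#' for top-level diagnoses; when a risk estimate targets a histologic or site
#' subtype, the subtype's incidence row links to its parent type and its
#' attributable cases roll up into the parent in reports. A subtype's cases may
#' never exceed its parent's in the same sex and year.
#'
#' @inheritParams read_exposure_table
#' @param x a validated `incidence_table` (for writing).
#' @return `read_incidence_table()` returns a data frame of class
#'   `"incidence_table"`; the writer is lossless and returns `path` invisibly.
#' @export
read_incidence_table <- function(path) {
  validate_incidence(read_raw_csv(path, "incidence"), src = path)
}

#' @rdname read_incidence_table
#' @export
write_incidence_table <- function(x, path) {
  x <- validate_incidence(x, src = "<in-memory>")
  write_paf_csv(x, path, numeric_cols = c("year", "cases"))
}

# ---- direct published fractions --------------------------------------------

direct_paf_cols <- c("factor_id", "cancer_type_id", "sex", "paf")

validate_direct_paf <- function(df, src = "<data.frame>") {
  kind <- "direct-PAF"
  df <- check_schema(as.data.frame(df, stringsAsFactors = FALSE),
                     direct_paf_cols, src, kind)
  check_nonempty(df, src, kind)
  df$factor_id <- check_filled(df, "factor_id", src, kind)
  df$cancer_type_id <- check_filled(df, "cancer_type_id", src, kind)
  df$sex <- check_sex(check_filled(df, "sex", src, kind), src, kind)
  df$paf <- num_col(df, "paf", src, kind)
  bad <- which(!is.finite(df$paf) | df$paf < 0 | df$paf >= 1)
  if (length(bad)) {
    paf_validation_error(sprintf(
      "direct-PAF table '%s': column 'paf' row %d: fraction must lie in [0, 1)",
      src, bad[1] + 1L
    ))
  }
  key <- paste(df$factor_id, df$cancer_type_id, df$sex, sep = "\r")
  if (anyDuplicated(key)) {
    paf_validation_error(sprintf(
      "direct-PAF table '%s': duplicate (factor, cancer type, sex) row", src
    ))
  }
  rownames(df) <- NULL
  class(df) <- c("direct_paf_table", "data.frame")
  df
}

#' Read / write a table of published attributable fractions
#'
#' For some exposures a published attributable fraction is adopted as-is
#' instead of being computed from prevalence and relative risk (in the source
#' study: human papillomavirus, Epstein-Barr virus, occupational exposures and
#' UV radiation). Columns: `factor_id,cancer_type_id,sex,paf` with the fraction
#' in `[0, 1)`.
#'
#' @inheritParams read_exposure_table
#' @param x a validated `direct_paf_table` (for writing).
#' @return `read_direct_paf_table()` returns a data frame of class
#'   `"direct_paf_table"`; the writer is lossless and returns `path` invisibly.
#' @export
read_direct_paf_table <- function(path) {
  validate_direct_paf(read_raw_csv(path, "direct-PAF"), src = path)
}

#' @rdname read_direct_paf_table
#' @export
write_direct_paf_table <- function(x, path) {
  x <- validate_direct_paf(x, src = "<in-memory>")
  write_paf_csv(x, path, numeric_cols = "paf")
}

# ---- attribution (output) ---------------------------------------------------

attribution_cols <- c("factor_id", "cancer_type_id", "sex", "paf",
                      "attributable_cases")

#' Construct an attribution table
#'
#' The principal output of a burden run: one row per risk factor x cancer type
#' x sex with the attributable fraction and (unrounded) attributable case
#' count, plus combined rows (factor id `"__combined__"`) per cancer type and
#' sex, and an overall summary (total cases, total attributable, overall
#' fraction) carried as the `"overall"` attribute.
#'
#' @param rows data frame with columns
#'   `factor_id,cancer_type_id,sex,paf,attributable_cases`.
#' @param total_cases total incident cases in the run's denominator.
#' @param total_attributable overall attributable cases (sum of combined rows).
#' @param overall_paf overall attributable fraction
#'   (`total_attributable / total_cases`).
#' @return a data frame of class `"attribution_table"`.
#' @seealso [paf_burden()], [write_attribution_table()]
#' @export
attribution_table <- function(rows, total_cases, total_attributable,
                              overall_paf) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)[attribution_cols]
  if (nrow(rows)) {
    if (any(!is.finite(rows$paf) | rows$paf < 0 | rows$paf > 1)) {
      paf_validation_error("attribution table: every paf must lie in [0, 1]")
    }
    if (any(!is.finite(rows$attributable_cases) | rows$attributable_cases < 0)) {
      paf_validation_error("attribution table: attributable_cases must be >= 0")
    }
  }
  rownames(rows) <- NULL
  structure(rows,
            overall = list(total_cases = as.numeric(total_cases),
                           total_attributable = as.numeric(total_attributable),
                           overall_paf = as.numeric(overall_paf)),
            class = c("attribution_table", "data.frame"))
}

#' Read / write an attribution table
#'
#' Writes the rows as CSV preceded by an overall-summary block of `#!`
#' comment lines (`total_cases`, `total_attributable`, `overall_paf`), all
#' numbers at full double precision, so that the file round-trips exactly.
#'
#' @param x an [attribution_table()].
#' @param path file to read or write.
#' @return `read_attribution_table()` returns the `"attribution_table"`;
#'   `write_attribution_table()` returns `path` invisibly.
#' @export
write_attribution_table <- function(x, path) {
  stopifnot(inherits(x, "attribution_table"))
  ov <- attr(x, "overall")
  prelude <- sprintf("#! %s=%s",
                     c("total_cases", "total_attributable", "overall_paf"),
                     fmt_num(c(ov$total_cases, ov$total_attributable,
                               ov$overall_paf)))
  write_paf_csv(as.data.frame(x), path,
                numeric_cols = c("paf", "attributable_cases"),
                prelude = prelude)
}

#' @rdname write_attribution_table
#' @export
read_attribution_table <- function(path) {
  if (!file.exists(path)) {
    paf_input_error(sprintf("attribution table: file '%s' does not exist", path))
  }
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#!", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^#!\\s*", "", meta_lines), "=", fixed = TRUE))
  if (is.null(kv) ||
      !all(c("total_cases", "total_attributable", "overall_paf") %in% kv[, 1])) {
    paf_input_error(sprintf(
      "attribution table '%s': missing overall summary block (#! lines)", path
    ))
  }
  ov <- as.list(as.numeric(kv[, 2]))
  names(ov) <- kv[, 1]
  df <- utils::read.csv(text = grep("^#!", lines, value = TRUE, invert = TRUE),
                        colClasses = "character", stringsAsFactors = FALSE)
  df <- check_schema(df, attribution_cols, path, "attribution")
  df$paf <- num_col(df, "paf", path, "attribution")
  df$attributable_cases <- num_col(df, "attributable_cases", path, "attribution")
  attribution_table(df, ov$total_cases, ov$total_attributable, ov$overall_paf)
}
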