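# Stratification and rendered group-comparison tables, plus the
# shipped reference summaries of the 41-patient SSRI cohort.

#' Stratify a cohort table
#'
#' Adds responder/remitter flags, percent BDI change and the
#' median-split LDAEP group to a cohort table.
#'
#' @param tab data frame with `bdi_pre`, `bdi_post` and an LDAEP
#'   column.
#' @param ldaep_col column holding the pretreatment N1/P2 slope used
#'   for the median split (default `"ldaep_n1p2"`).
#' @return The table with columns `bdi_change_pct`, `responder`,
#'   `remitter`, `ldaep_group` (re)computed.
#' @export
stratify_cohort <- function(tab, ldaep_col = "ldaep_n1p2") {
  stopifnot(is.data.frame(tab))
  if (!ldaep_col %in% names(tab)) stopf("no column '%s'", ldaep_col)
  cls <- classify_response(tab$bdi_pre, tab$bdi_post)
  tab$bdi_change_pct <- cls$bdi_change_pct
  tab$responder <- cls$responder
  tab$remitter <- cls$remitter
  tab$ldaep_group <- median_split(tab[[ldaep_col]])
  tab
}

row_compare <- function(values, grp, variable, lv) {
  a <- values[grp == lv[1]]
  b <- values[grp == lv[2]]
  cmp <- tryCatch(two_sample_t(a, b, mode = "auto"), error = function(e) NULL)
  data.frame(
    variable = variable,
    n_1 = length(a), mean_1 = mean(a), sd_1 = stats::sd(a),
    n_2 = length(b), mean_2 = mean(b), sd_2 = stats::sd(b),
    statistic = if (is.null(cmp)) NA_real_ else cmp$value,
    kind = if (is.null(cmp)) "not-computable" else cmp$kind,
    df = if (is.null(cmp)) NA_real_ else cmp$df[1],
    p = if (is.null(cmp)) NA_real_ else cmp$p
  )
}

row_count_compare <- function(flag, grp, variable, lv) {
  tbl <- table(factor(grp, levels = lv), factor(flag, levels = c(TRUE, FALSE)))
  cmp <- tryCatch(chi_square_2x2(as.matrix(tbl)), error = function(e) NULL)
  data.frame(
    variable = variable,
    n_1 = sum(grp == lv[1]), mean_1 = tbl[1, 1], sd_1 = tbl[1, 2],
    n_2 = sum(grp == lv[2]), mean_2 = tbl[2, 1], sd_2 = tbl[2, 2],
    statistic = if (is.null(cmp)) NA_real_ else cmp$value,
    kind = if (is.null(cmp)) "not-computable" else "chi2",
    df = if (is.null(cmp)) NA_real_ else cmp$df,
    p = if (is.null(cmp)) NA_real_ else cmp$p
  )
}

#' Build report tables for a stratified cohort
#'
#' Renders the three standard group-comparison tables of a
#' treatment-response LDAEP study: demographics and LDAEP by
#' responder status, by remitter status, and by median LDAEP split
#' (the latter including percent BDI change, responder counts and the
#' responder percentage per group).  Rows whose comparison is not
#' computable (e.g. a single-sex cohort) are kept with kind
#' `"not-computable"`.
#'
#' @param tab a cohort table; [stratify_cohort()] is applied if the
#'   stratification columns are absent.
#' @param ldaep_cols named character vector mapping report labels to
#'   LDAEP columns present in `tab`.
#' @return Object of class `cohort_report`: list of data frames
#'   `by_response`, `by_remission`, `by_ldaep`, plus `responder_pct`
#'   per LDAEP group and `n_tests` (count of statistical tests, no
#'   multiplicity adjustment is applied).
#' @export
build_summary_tables <- function(tab,
                                 ldaep_cols = c(n1 = "ldaep_n1",
                                                p2 = "ldaep_p2",
                                                n1p2 = "ldaep_n1p2")) {
  if (!all(c("responder", "remitter", "ldaep_group") %in% names(tab))) {
    tab <- stratify_cohort(tab)
  }
  numeric_vars <- c(age = "age", bdi_pre = "bdi_pre", bdi_post = "bdi_post")
  ldaep_vars <- ldaep_cols[ldaep_cols %in% names(tab)]
  names(ldaep_vars) <- paste0("ldaep_", names(ldaep_vars))
  one_strat <- function(grp, lv, with_change) {
    rows <- list()
    for (v in names(numeric_vars)) {
      rows[[v]] <- row_compare(tab[[numeric_vars[v]]], grp, v, lv)
    }
    for (v in names(ldaep_vars)) {
      rows[[v]] <- row_compare(tab[[ldaep_vars[v]]], grp, v, lv)
    }
    if (with_change) {
      rows$bdi_change <- row_compare(tab$bdi_change_pct, grp,
                                     "bdi_change_pct", lv)
    }
    rows$sex <- row_count_compare(tab$sex == "male", grp, "sex_male", lv)
    rows$episode <- row_count_compare(tab$episode == "first", grp,
                                      "first_episode", lv)
    rows$smoker <- row_count_compare(tab$smoker, grp, "smoker", lv)
    do.call(rbind, rows)
  }
  by_response <- one_strat(
    factor(ifelse(tab$responder, "responder", "nonresponder"),
           levels = c("nonresponder", "responder")),
    c("nonresponder", "responder"), with_change = FALSE)
  by_remission <- one_strat(
    factor(ifelse(tab$remitter, "remitter", "nonremitter"),
           levels = c("nonremitter", "remitter")),
    c("nonremitter", "remitter"), with_change = FALSE)
  by_ldaep <- one_strat(tab$ldaep_group, c("low", "high"), with_change = TRUE)
  resp_row <- row_count_compare(tab$responder, tab$ldaep_group,
                                "responder", c("low", "high"))
  by_ldaep <- rbind(by_ldaep, resp_row)
  rownames(by_response) <- rownames(by_remission) <- rownames(by_ldaep) <- NULL
  pct <- tapply(tab$responder, tab$ldaep_group, function(x) 100 * mean(x))
  n_tests <- sum(!is.na(by_response$p)) + sum(!is.na(by_remission$p)) +
    sum(!is.na(by_ldaep$p))
  structure(
    list(by_response = by_response, by_remission = by_remission,
         by_ldaep = by_ldaep, responder_pct = pct, n_tests = n_tests),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort report (", x$n_tests, " tests, no multiplicity adjustment)\n",
      sep = "")
  for (nm in c("by_response", "by_remission", "by_ldaep")) {
    cat("\n--", nm, "--\n")
    df <- x[[nm]]
    df[] <- lapply(df, function(c) if (is.numeric(c)) signif(c, 4) else c)
    print(df, row.names = FALSE)
  }
  cat(sprintf("\nResponder rate: low %.1f%%, high %.1f%%\n",
              x$responder_pct[["low"]], x$responder_pct[["high"]]))
  invisible(x)
}

#' Write a cohort report as markdown + CSV
#'
#' @param report a [build_summary_tables()] object.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "cohort_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  md <- file.path(dir, "report.md")
  con <- file(md, "w")
  on.exit(close(con))
  writeLines("# Cohort LDAEP report", con)
  for (nm in c("by_response", "by_remission", "by_ldaep")) {
    writeLines(c("", paste("##", gsub("_", " ", nm)), ""), con)
    df <- x_round <- report[[nm]]
    x_round[] <- lapply(df, function(c) if (is.numeric(c)) signif(c, 4) else c)
    writeLines(paste("|", paste(names(df), collapse = " | "), "|"), con)
    writeLines(paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"),
               con)
    for (i in seq_len(nrow(df))) {
      writeLines(paste("|", paste(unlist(x_round[i, ]), collapse = " | "),
                       "|"), con)
    }
  }
  writeLines(c("", sprintf("Responder rate: low %.1f%%, high %.1f%%",
                           report$responder_pct[["low"]],
                           report$responder_pct[["high"]]),
               sprintf("Statistical tests performed: %d", report$n_tests)),
             con)
  paths <- md
  for (nm in c("by_response", "by_remission", "by_ldaep")) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(report[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Published group summaries of the reference SSRI cohort
#'
#' Returns the printed group summary statistics (n, mean, SD per
#' group and stratification) and responder counts of the 41-patient
#' SSRI treatment-response cohort that this package's statistics
#' reproduce.  These are inputs for summary-statistic re-analysis,
#' not outputs of the package.
#'
#' @return list with `summaries` and `counts` data frames.
#' @export
reference_cohort_tables <- function() {
  pth <- function(f) system.file("extdata", f, package = "ldaepr",
                                 mustWork = TRUE)
  list(
    summaries = utils::read.csv(pth("reference_group_summaries.csv")),
    counts = utils::read.csv(pth("reference_group_counts.csv"))
  )
}

#' Fetch one group summary as a `list(n, mean, sd)`
#'
#' Convenience accessor over [reference_cohort_tables()].
#'
#' @param summaries the `summaries` data frame.
#' @param stratification,variable,group row selector.
#' @return `list(n, mean, sd)` suitable for [two_sample_t()].
#' @export
reference_group <- function(summaries, stratification, variable, group) {
  r <- summaries[summaries$stratification == stratification &
                   summaries$variable == variable &
                   summaries$group == group, ]
  if (nrow(r) != 1) {
    stopf("no unique reference row for %s/%s/%s",
          stratification, variable, group)
  }
  list(n = r$n, mean = r$mean, sd = r$sd)
}
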