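# The audit pipeline: one constructor that runs eligibility filtering,
# partograph assembly, rule-based classification, completeness scoring and
# referral linkage, returning a single classed result object.

#' Audit a cohort of partographs
#'
#' Runs the full audit over the three register tables: filters cases eligible
#' for partograph analysis (cervical dilatation on arrival of at most 8 cm),
#' assembles a partograph per eligible case with plotted observations,
#' classifies each against the abnormal-labour rules, scores charting
#' completeness per component against the WHO monitoring intervals (comparing
#' the abnormal and no-indication groups with the pooled two-proportion
#' z-test), links the referral register with the partograph-scope filter, and
#' assembles the cohort flow report.
#'
#' @param cases Case data frame from [read_cases()] (or a path to
#'   `cases.csv`).
#' @param observations Observation data frame from [read_observations()] (or
#'   a path).
#' @param referrals Optional referral data frame from [read_referrals()] (or
#'   a path); `NULL` for a cohort with no referral register.
#' @param rules A [rule_config()].
#' @param schedule An [interval_schedule()].
#' @param completeness_rule `"lenient"` (default) or `"strict"`, see
#'   [component_complete()].
#' @param scope A [scope_filter()].
#' @param max_dilatation_cm Eligibility bound (default 8, inclusive).
#' @return An object of class `partograph_audit` with elements `flow`
#'   ([build_flow_report()] result), `completeness` (component table),
#'   `flags` (per-case classification), `evidence`, `linkage`, `partographs`,
#'   and `notes` (audit log lines: record counts per stage, configuration
#'   choices, no-anchor tallies).
#' @examples
#' sim <- simulate_cohort(sim_params(n_cases = 40, seed = 1))
#' audit <- partograph_audit(sim$cases, sim$observations, sim$referrals)
#' audit
#' @export
partograph_audit <- function(cases, observations, referrals = NULL,
                             rules = rule_config(),
                             schedule = interval_schedule(),
                             completeness_rule = c("lenient", "strict"),
                             scope = scope_filter(),
                             max_dilatation_cm = 8) {
  completeness_rule <- match.arg(completeness_rule)
  if (is.character(cases)) cases <- read_cases(cases)
  if (is.character(observations)) observations <- read_observations(observations)
  if (is.character(referrals)) referrals <- read_referrals(referrals)

  notes <- character()
  note <- function(...) notes <<- c(notes, sprintf(...))
  note("cases loaded: %d", nrow(cases))
  note("observation rows loaded: %d", nrow(observations))
  note("referral rows loaded: %d",
       if (is.null(referrals)) 0L else nrow(referrals))

  eligible <- filter_eligible(cases, max_dilatation_cm)
  note("eligible cases (dilatation <= %d cm): %d", max_dilatation_cm,
       nrow(eligible))

  obs_eligible <- observations[observations$case_id %in% eligible$case_id, ,
                               drop = FALSE]
  partographs <- lapply(
    split(obs_eligible, obs_eligible$case_id),
    build_partograph
  )
  partographs <- unname(partographs)
  note("partographs assembled: %d", length(partographs))

  flags <- classify_cohort(partographs, rules)
  if (attr(flags, "n_no_anchor") > 0) {
    note("partographs with dilatation plotted but never >= 4 cm: %d",
         attr(flags, "n_no_anchor"))
  }
  note("partographs with any indication of abnormal labour: %d",
       sum(flags$any_indication))

  completeness <- cohort_completeness(partographs, flags, schedule,
                                      completeness_rule)
  note("completeness rule: %s; blood-pressure interval: %d min",
       completeness_rule, schedule[["bp"]])

  p_ids <- vapply(partographs, function(p) p$case_id, character(1))
  linkage <- link_referrals(cases, referrals, scope, flags, p_ids)
  if (length(attr(linkage, "orphans")) > 0) {
    note("orphan referrals (no matching case): %d",
         length(attr(linkage, "orphans")))
  }
  if (nrow(attr(linkage, "collapsed")) > 0) {
    note("duplicate referrals collapsed to earliest event: %d",
         nrow(attr(linkage, "collapsed")))
  }

  flow <- build_flow_report(cases, partographs, flags, linkage,
                            max_dilatation_cm)
  out <- list(
    flow = flow,
    completeness = completeness,
    flags = flags,
    evidence = attr(flags, "evidence"),
    linkage = linkage,
    partographs = partographs,
    notes = notes,
    config = list(rules = rules, schedule = unclass(schedule),
                  completeness_rule = completeness_rule,
                  scope = scope, max_dilatation_cm = max_dilatation_cm)
  )
  class(out) <- "partograph_audit"
  out
}

#' @export
print.partograph_audit <- function(x, ...) {
  cat("Partograph audit\n")
  print(x$flow)
  cat("\nCompleteness (% appropriately recorded; p: abnormal vs no indication)\n")
  tab <- x$completeness
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-18s %3d min   overall %5.1f  abnormal %5.1f  none %5.1f  p %s\n",
                tab$component[i], tab$interval_min[i], tab$pct_overall[i],
                tab$pct_abnormal[i], tab$pct_no_indication[i],
                if (isTRUE(tab$degenerate[i]) || is.na(tab$p_value[i])) "-"
                else sprintf("%.3f", tab$p_value[i])))
  }
  invisible(x)
}

#' @export
summary.partograph_audit <- function(object, ...) {
  print(object)
  cat("\nIndication breakdown among flagged partographs\n")
  fl <- object$flags[object$flags$any_indication, , drop = FALSE]
  n <- nrow(fl)
  for (cond in c("foetal_distress", "prolonged_labour",
                 "obstructed_labour", "preeclampsia")) {
    cat(sprintf("  %-18s %4d (%5.1f%% of %d)\n", cond, sum(fl[[cond]]),
                if (n > 0) round_half_up(100 * sum(fl[[cond]]) / n) else 0, n))
  }
  cat("\nAudit log\n")
  cat(paste0("  ", object$notes, collapse = "\n"), "\n")
  invisible(object)
}

# -- report serialisation ------------------------------------------------------

.report_as_list <- function(audit) {
  tab <- audit$completeness
  list(
    flow = list(counts = audit$flow$counts, pct = audit$flow$pct),
    background_tables = audit$flow$background_tables,
    completeness = tab[, c("component", "interval_min", "pct_overall",
                           "pct_abnormal", "pct_no_indication", "z",
                           "p_value", "degenerate")],
    group_sizes = list(
      n_total = attr(tab, "n_total"),
      n_abnormal = attr(tab, "n_abnormal"),
      n_no_indication = attr(tab, "n_no_indication")
    ),
    notes = audit$notes
  )
}

#' Write and re-read audit reports
#'
#' `write_report()` emits the audit results to a directory: `report.json`
#' (machine-readable: flow counts and percentages, background tables,
#' completeness table, group sizes, audit log), `report.md` (human-readable
#' summary in the layout of the flow diagram and the background/completeness
#' tables), `flags.csv` (one classification row per case) and
#' `completeness_table.csv` (per-component table, p-value printed as a dash
#' when degenerate). `read_report()` parses `report.json` back to the same
#' in-memory representation, so write-then-read is the identity.
#'
#' @param audit A `partograph_audit` object.
#' @param out_dir Output directory (created if needed).
#' @param path Path of a `report.json` written by `write_report()`.
#' @return `write_report()`: the paths written, invisibly. `read_report()`:
#'   the report list.
#' @rdname write_report
#' @export
write_report <- function(audit, out_dir) {
  stopifnot(inherits(audit, "partograph_audit"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) {
      stop(sprintf("write_report: cannot create directory %s", out_dir))
    }
  }
  report <- .report_as_list(audit)
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null", pretty = TRUE)

  flags_path <- file.path(out_dir, "flags.csv")
  utils::write.csv(audit$flags, flags_path, row.names = FALSE)

  comp_path <- file.path(out_dir, "completeness_table.csv")
  tab <- audit$completeness
  out_tab <- data.frame(
    component = tab$component,
    interval_min = tab$interval_min,
    pct_overall = tab$pct_overall,
    pct_abnormal = tab$pct_abnormal,
    pct_no_indication = tab$pct_no_indication,
    p_value = ifelse(tab$degenerate | is.na(tab$p_value), "-",
                     sprintf("%.3f", tab$p_value)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out_tab, comp_path, row.names = FALSE)

  md_path <- file.path(out_dir, "report.md")
  bg <- lapply(names(report$background_tables), function(nm) {
    t <- report$background_tables[[nm]]
    c(sprintf("### %s", nm),
      sprintf("- %s: %d (%.1f%%)", t$category, t$n, t$pct), "")
  })
  md <- c(
    "# Partograph audit report", "",
    "## Case flow", "",
    utils::capture.output(print(audit$flow))[-1],
    "", "## Background characteristics", "",
    unlist(bg),
    "## Completeness of charting", "",
    sprintf("- %-18s (%3d min): overall %.1f%%, abnormal %.1f%%, no indication %.1f%%, p %s",
            out_tab$component, out_tab$interval_min, out_tab$pct_overall,
            out_tab$pct_abnormal, out_tab$pct_no_indication, out_tab$p_value),
    "", "## Audit log", "",
    paste0("- ", audit$notes)
  )
  writeLines(md, md_path)
  invisible(c(json = json_path, md = md_path, flags = flags_path,
              completeness = comp_path))
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  report <- jsonlite::read_json(path, simplifyVector = TRUE)
  report$completeness <- as.data.frame(report$completeness,
                                       stringsAsFactors = FALSE)
  report$background_tables <- lapply(report$background_tables, function(t) {
    as.data.frame(t, stringsAsFactors = FALSE)
  })
  report
}
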