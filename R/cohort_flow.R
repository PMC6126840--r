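# Cohort flow: eligibility filtering, referral-register linkage with the
# partograph-scope filter, and the flow/background summary report.

#' Partograph-scope filter for referral reasons
#'
#' Referral reasons outside the scope of partograph-based indication:
#' maternal general illness, postpartum reasons (postpartum haemorrhage,
#' retained placenta) and neonatal conditions (birth asphyxia, low birth
#' weight, stillbirth, neonatal death). Rows with these reasons are retained
#' and marked, never dropped; they are simply not counted as referred cases
#' in the partograph analysis.
#'
#' @param out_of_scope_reasons Character vector of reason codes to mark out
#'   of scope.
#' @return An object of class `scope_filter`.
#' @export
scope_filter <- function(out_of_scope_reasons = c(
                           "general_illness", "pph", "retained_placenta",
                           "birth_asphyxia", "low_birth_weight",
                           "stillbirth", "neonatal_death")) {
  stopifnot(all(out_of_scope_reasons %in% referral_reasons()))
  f <- list(out_of_scope_reasons = out_of_scope_reasons)
  class(f) <- "scope_filter"
  f
}

#' Filter cases eligible for partograph analysis
#'
#' Retains admitted cases that arrived in the active phase with cervical
#' dilatation of 8 cm or less (inclusive). Women arriving at more than 8 cm
#' are near or at full dilatation and a partograph no longer contributes to
#' decision making.
#'
#' @param cases Case data frame from [read_cases()].
#' @param max_dilatation_cm Inclusive eligibility bound (default 8).
#' @return The eligible subset of `cases`.
#' @export
filter_eligible <- function(cases, max_dilatation_cm = 8) {
  cases[!is.na(cases$dilatation_on_arrival_cm) &
          cases$dilatation_on_arrival_cm <= max_dilatation_cm, , drop = FALSE]
}

#' Link the referral register to cases and classifications
#'
#' One-to-one matching of referral rows to cases by `case_id`. Duplicate
#' referrals for one case collapse to a single referral event (the earliest
#' by `referral_time`, first row on ties); collapsed rows are enumerated in
#' the `collapsed` attribute. Referrals whose `case_id` matches no case are
#' logged as orphans (attribute `orphans`, plus a warning) and excluded from
#' counts. Rows without a `case_id` are referrals without admission and are
#' retained unmatched.
#'
#' @param cases Case data frame.
#' @param referrals Referral data frame from [read_referrals()].
#' @param scope A [scope_filter()].
#' @param flags Optional classification data frame from [classify_cohort()];
#'   adds per-case `any_indication` to the linkage.
#' @param partograph_case_ids Optional character vector of case ids that have
#'   a partograph; adds `has_partograph` to the linkage.
#' @return Linkage data frame: one row per referral event with `case_id`,
#'   `referral_time`, `reason_code`, `admitted_flag`, `matched`, `in_scope`,
#'   `has_partograph`, `any_indication`.
#' @export
link_referrals <- function(cases, referrals, scope = scope_filter(),
                           flags = NULL, partograph_case_ids = NULL) {
  if (is.null(referrals) || nrow(referrals) == 0) {
    out <- data.frame(
      case_id = character(), referral_time = as.POSIXct(character(), tz = "UTC"),
      reason_code = character(), admitted_flag = logical(),
      matched = logical(), in_scope = logical(), has_partograph = logical(),
      any_indication = logical(), stringsAsFactors = FALSE
    )
    attr(out, "collapsed") <- out[0, c("case_id", "reason_code")]
    attr(out, "orphans") <- character()
    return(out)
  }
  ref <- referrals
  # collapse duplicate referrals per case to the earliest event
  with_id <- !is.na(ref$case_id)
  ord <- order(!with_id, ref$case_id,
               ifelse(is.na(ref$referral_time), Inf,
                      as.numeric(ref$referral_time)))
  ref <- ref[ord, , drop = FALSE]
  dup <- with_id[ord] & duplicated(ref$case_id, incomparables = NA)
  collapsed <- ref[dup, c("case_id", "reason_code"), drop = FALSE]
  ref <- ref[!dup, , drop = FALSE]

  matched <- ifelse(is.na(ref$case_id), NA, ref$case_id %in% cases$case_id)
  orphans <- ref$case_id[!is.na(matched) & !matched]
  if (length(orphans) > 0) {
    warning(sprintf("link_referrals: %d referral(s) match no case: %s",
                    length(orphans), paste(orphans, collapse = ", ")),
            call. = FALSE)
  }
  in_scope <- !(ref$reason_code %in% scope$out_of_scope_reasons)
  has_partograph <- if (is.null(partograph_case_ids)) {
    rep(NA, nrow(ref))
  } else {
    !is.na(ref$case_id) & ref$case_id %in% partograph_case_ids
  }
  any_indication <- if (is.null(flags)) {
    rep(NA, nrow(ref))
  } else {
    flags$any_indication[match(ref$case_id, flags$case_id)]
  }
  out <- data.frame(
    case_id = ref$case_id,
    referral_time = ref$referral_time,
    reason_code = ref$reason_code,
    admitted_flag = ref$admitted_flag,
    matched = matched,
    in_scope = in_scope,
    has_partograph = has_partograph,
    any_indication = any_indication,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "collapsed") <- collapsed
  attr(out, "orphans") <- orphans
  out
}

.pct_table <- function(values, levels, n, missing_label = "missing") {
  counts <- vapply(levels, function(l) sum(values == l, na.rm = TRUE), 0)
  data.frame(
    category = levels,
    n = as.integer(counts),
    pct = round_half_up(100 * counts / max(n, 1)),
    stringsAsFactors = FALSE
  )
}

.age_band <- function(age) {
  ifelse(is.na(age), "missing",
    ifelse(age <= 19, "15-19",
      ifelse(age <= 24, "20-24",
        ifelse(age <= 29, "25-29", "30+"))))
}

#' Build the cohort flow report
#'
#' Assembles the counts at every node of the case-flow diagram (presented,
#' admitted, referred without admission, eligible at <= 8 cm, partograph
#' initiated, abnormal indication, in-scope referrals among partograph cases
#' and those with a charted indication) together with background
#' characteristic tables (facility, age band, parity, dilatation band,
#' membrane status, each with an explicit "No information recorded"
#' category). Percentages are rounded half-up to one decimal; conservation
#' identities among the counts hold by construction.
#'
#' @param cases Admitted-case data frame.
#' @param partographs List of `partograph` objects for eligible cases that
#'   have one.
#' @param flags Classification data frame from [classify_cohort()].
#' @param linkage Linkage data frame from [link_referrals()].
#' @param max_dilatation_cm Eligibility bound passed to [filter_eligible()].
#' @return An object of class `cohort_flow_report`.
#' @export
build_flow_report <- function(cases, partographs, flags, linkage,
                              max_dilatation_cm = 8) {
  n_admitted <- nrow(cases)
  n_unadmitted <- sum(is.na(linkage$case_id))
  eligible <- filter_eligible(cases, max_dilatation_cm)
  n_eligible <- nrow(eligible)
  p_ids <- vapply(partographs, function(p) p$case_id, character(1))
  n_partograph <- sum(p_ids %in% eligible$case_id)
  n_abnormal <- sum(flags$any_indication[flags$case_id %in% p_ids])
  ref_scope <- !is.na(linkage$case_id) & linkage$matched %in% TRUE &
    linkage$in_scope & linkage$case_id %in% p_ids
  n_ref_scope <- sum(ref_scope)
  n_ref_ind <- sum(ref_scope & linkage$any_indication %in% TRUE)

  pct <- function(num, den) {
    if (den > 0) round_half_up(100 * num / den) else NA_real_
  }
  report <- list(
    counts = list(
      n_presented = n_admitted + n_unadmitted,
      n_admitted = n_admitted,
      n_referred_without_admission = n_unadmitted,
      n_eligible = n_eligible,
      n_with_partograph = n_partograph,
      n_abnormal_indication = n_abnormal,
      n_referred_with_partograph_in_scope = n_ref_scope,
      n_referred_with_indication = n_ref_ind
    ),
    pct = list(
      pct_admitted = pct(n_admitted, n_admitted + n_unadmitted),
      pct_referred_without_admission = pct(n_unadmitted,
                                           n_admitted + n_unadmitted),
      pct_eligible = pct(n_eligible, n_admitted),
      pct_partograph_initiated = pct(n_partograph, n_eligible),
      pct_abnormal = pct(n_abnormal, n_partograph),
      pct_referred_with_indication = pct(n_ref_ind, n_abnormal)
    ),
    background_tables = list(
      facility = .pct_table(cases$facility,
                            sort(unique(cases$facility)), n_admitted),
      age_band = .pct_table(.age_band(cases$age_years),
                            c("15-19", "20-24", "25-29", "30+", "missing"),
                            n_admitted),
      parity = .pct_table(cases$parity, .parity_levels, n_admitted),
      dilatation_band = .pct_table(
        ifelse(cases$dilatation_on_arrival_cm <= max_dilatation_cm,
               "8cm_or_less", "more_than_8cm"),
        c("8cm_or_less", "more_than_8cm"), n_admitted),
      membrane_status = .pct_table(cases$membrane_status, .membrane_levels,
                                   n_admitted)
    )
  )
  class(report) <- "cohort_flow_report"
  report
}

#' @export
print.cohort_flow_report <- function(x, ...) {
  cat("Cohort flow\n")
  c_ <- x$counts
  p_ <- x$pct
  fmt <- function(label, n, pct = NULL) {
    cat(sprintf("  %-42s %6d%s\n", label, n,
                if (is.null(pct) || is.na(pct)) "" else sprintf(" (%.1f%%)", pct)))
  }
  fmt("presented in labour", c_$n_presented)
  fmt("admitted for childbirth", c_$n_admitted, p_$pct_admitted)
  fmt("referred without admission", c_$n_referred_without_admission,
      p_$pct_referred_without_admission)
  fmt("eligible (dilatation <= 8 cm)", c_$n_eligible, p_$pct_eligible)
  fmt("partograph initiated", c_$n_with_partograph, p_$pct_partograph_initiated)
  fmt("indication of abnormal labour", c_$n_abnormal_indication, p_$pct_abnormal)
  fmt("in-scope referrals among partograph cases",
      c_$n_referred_with_partograph_in_scope)
  fmt("referred with charted indication", c_$n_referred_with_indication)
  invisible(x)
}
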