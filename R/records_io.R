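# Register I/O: strict CSV schemas for the three flat tables the audit
# consumes (intrapartum case records, long-format partograph observations,
# referral register) and the report outputs it emits.
#
# Loaders never silently drop rows: rows_in = rows_accepted + rows_rejected,
# and every reject is enumerated (row number + reason) in the "rejected"
# attribute, with a summarising warning.

# -- component domains ---------------------------------------------------------

#' Partograph observation components
#'
#' Names and value domains of the eleven monitored components of the WHO
#' modified partograph as they appear in the long observation table. Blood
#' pressure is stored as two numeric components (`sbp`, `dbp`) observed at the
#' same time point; a BP "pair" is any sbp and dbp sharing `t_min`.
#'
#' @return Character vector of valid `component` codes.
#' @export
observation_components <- function() {
  c(names(.numeric_components), names(.coded_domains))
}

.numeric_components <- list(
  fhr = c(0, 250),               # beats/min
  dilatation = c(0, 10),         # cm
  descent = c(0, 5),             # fifths of head palpable
  contraction_freq = c(0, 10),   # contractions per 10 min
  sbp = c(0, 300),               # mmHg
  dbp = c(0, 200),               # mmHg
  pulse = c(0, 250),             # beats/min
  temperature = c(30, 45),       # degrees C
  urine_volume = c(0, 2000)      # mL
)

.coded_domains <- list(
  liquor = c("I", "C", "M", "A", "B"),
  moulding = c("0", "+", "++", "+++"),
  contraction_duration = c("lt20s", "s20to40", "gt40s"),
  urine_albumin = c("neg", "trace", "plus1", "plus2", "plus3")
)

.parity_levels <- c("nullipara", "multipara", "missing")
.membrane_levels <- c("ruptured", "intact", "missing")
.outcome_levels <- c("live", "stillbirth", "neonatal_death", "missing")

#' Referral reason codes
#'
#' All reason codes accepted in the referral register. Reasons unrelated to
#' intrapartum partograph monitoring (maternal general illness, postpartum and
#' neonatal reasons) are retained at load but marked out of partograph scope
#' downstream by [scope_filter()].
#'
#' @return Character vector of valid `reason_code` values.
#' @export
referral_reasons <- function() {
  c(
    "foetal_distress", "prolonged_labour", "obstructed_labour", "preeclampsia",
    "general_illness", "pph", "retained_placenta", "birth_asphyxia",
    "low_birth_weight", "stillbirth", "neonatal_death", "other"
  )
}

.require_columns <- function(df, cols, what) {
  if (!all(cols %in% names(df))) {
    stop(sprintf(
      "%s: header must contain columns: %s (found: %s)",
      what, paste(cols, collapse = ", "), paste(names(df), collapse = ", ")
    ), call. = FALSE)
  }
}

.read_raw <- function(path, cols, what) {
  if (!file.exists(path)) stop(sprintf("%s: file not found: %s", what, path), call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        na.strings = character(), fileEncoding = "UTF-8")
  .require_columns(df, cols, what)
  df
}

.finish_load <- function(accepted, rejected_idx, reasons, raw, what) {
  rejected <- data.frame(
    row = rejected_idx,
    reason = reasons,
    stringsAsFactors = FALSE
  )
  if (nrow(rejected) > 0) {
    warning(sprintf(
      "%s: rejected %d of %d rows (%s)", what, nrow(rejected), nrow(raw),
      paste(sprintf("row %d: %s", utils::head(rejected$row, 5),
                    utils::head(rejected$reason, 5)), collapse = "; ")
    ), call. = FALSE)
  }
  attr(accepted, "rejected") <- rejected
  attr(accepted, "rows_in") <- nrow(raw)
  accepted
}

# -- cases ---------------------------------------------------------------------

.case_columns <- c(
  "case_id", "facility", "admission_time", "age_years", "parity",
  "gestation_weeks", "membrane_status", "dilatation_on_arrival_cm",
  "delivery_time", "birth_outcome"
)

.parse_enum <- function(x, levels, missing_ok = TRUE) {
  x <- trimws(x)
  out <- x
  blank <- !nzchar(x)
  out[blank] <- "missing"
  bad <- !(out %in% levels)
  list(value = out, bad = bad)
}

#' Read an intrapartum case register
#'
#' Parses `cases.csv` (one row per admitted woman) with strict validation.
#' Blank `age_years`, `parity`, `gestation_weeks`, `membrane_status`,
#' `delivery_time` and `birth_outcome` fields are mapped to explicit missing
#' values (the "No information recorded" category of the facility summaries),
#' never left as empty-string sentinels. Rows with malformed values (cervical
#' dilatation outside 0--10 cm, unknown enum codes, delivery before admission)
#' are rejected with their row number and reason; a duplicated `case_id` is a
#' hard error.
#'
#' @param path Path to a UTF-8, comma-separated, RFC 4180-quoted CSV with
#'   header columns `case_id, facility, admission_time, age_years, parity,
#'   gestation_weeks, membrane_status, dilatation_on_arrival_cm,
#'   delivery_time, birth_outcome`. Timestamps are ISO-8601 and converted to
#'   POSIXct (UTC) at load.
#' @return A data frame of accepted cases with typed columns; attributes
#'   `rejected` (data frame of row numbers and reasons) and `rows_in`.
#' @seealso [read_observations()], [read_referrals()], [write_cases()]
#' @export
read_cases <- function(path) {
  raw <- .read_raw(path, .case_columns, "read_cases")
  n <- nrow(raw)
  case_id <- trimws(raw$case_id)
  facility <- trimws(raw$facility)
  admission_time <- parse_timestamp(raw$admission_time)
  delivery_time <- parse_timestamp(raw$delivery_time)
  age <- parse_integer(raw$age_years)
  gest <- parse_integer(raw$gestation_weeks)
  dil <- parse_integer(raw$dilatation_on_arrival_cm)
  parity <- .parse_enum(raw$parity, .parity_levels)
  membranes <- .parse_enum(raw$membrane_status, .membrane_levels)
  outcome <- .parse_enum(raw$birth_outcome, .outcome_levels)

  reason <- rep(NA_character_, n)
  flag <- function(bad, msg) {
    bad <- which(bad & is.na(reason))
    reason[bad] <<- if (length(msg) > 1) msg[bad] else msg
  }
  flag(!nzchar(case_id), "blank case_id")
  flag(is.na(admission_time) &
         nzchar(trimws(raw$admission_time)), "unparseable admission_time")
  flag(!nzchar(trimws(raw$admission_time)), "blank admission_time")
  flag(is.nan(age), "malformed age_years")
  flag(is.nan(gest), "malformed gestation_weeks")
  flag(is.nan(dil) | is.na(dil), "blank or malformed dilatation_on_arrival_cm")
  flag(!is.na(dil) & !is.nan(dil) & (dil < 0 | dil > 10),
       paste0("dilatation_on_arrival_cm outside 0-10 (case_id ", case_id, ")"))
  flag(parity$bad, "unknown parity code")
  flag(membranes$bad, "unknown membrane_status code")
  flag(outcome$bad, "unknown birth_outcome code")
  flag(is.na(delivery_time) & nzchar(trimws(raw$delivery_time)),
       "unparseable delivery_time")
  flag(!is.na(delivery_time) & !is.na(admission_time) &
         delivery_time < admission_time, "delivery_time before admission_time")

  keep <- is.na(reason)
  accepted <- data.frame(
    case_id = case_id[keep],
    facility = facility[keep],
    admission_time = admission_time[keep],
    age_years = as.integer(age[keep]),
    parity = parity$value[keep],
    gestation_weeks = as.integer(gest[keep]),
    membrane_status = membranes$value[keep],
    dilatation_on_arrival_cm = as.integer(dil[keep]),
    delivery_time = delivery_time[keep],
    birth_outcome = outcome$value[keep],
    stringsAsFactors = FALSE
  )
  dup <- duplicated(accepted$case_id)
  if (any(dup)) {
    stop(sprintf("read_cases: duplicate case_id: %s",
                 paste(unique(accepted$case_id[dup]), collapse = ", ")),
         call. = FALSE)
  }
  .finish_load(accepted, which(!keep), reason[!keep], raw, "read_cases")
}

# -- observations --------------------------------------------------------------

.obs_columns <- c("case_id", "component", "t_min", "value_num", "value_code")

#' Read a long-format partograph observation table
#'
#' Parses `partograph_obs.csv`, one row per plotted value: `case_id`,
#' `component`, `t_min` (integer minutes since admission), and exactly one of
#' `value_num` (numeric components) or `value_code` (coded components).
#' Accepted rows are sorted by `(case_id, component, t_min)` with ties kept in
#' input order; numeric/coded domains are enforced per component and
#' violations rejected row-wise.
#'
#' @param path Path to the observations CSV.
#' @return A data frame of accepted observations (`case_id`, `component`,
#'   `t_min`, `value_num`, `value_code`) with `rejected` and `rows_in`
#'   attributes.
#' @export
read_observations <- function(path) {
  raw <- .read_raw(path, .obs_columns, "read_observations")
  n <- nrow(raw)
  case_id <- trimws(raw$case_id)
  component <- trimws(raw$component)
  t_min <- parse_integer(raw$t_min)
  vnum_raw <- trimws(raw$value_num)
  vcode <- trimws(raw$value_code)
  has_num <- nzchar(vnum_raw)
  has_code <- nzchar(vcode)
  vnum <- suppressWarnings(as.numeric(vnum_raw))

  reason <- rep(NA_character_, n)
  flag <- function(bad, msg) {
    bad <- which(bad & is.na(reason))
    reason[bad] <<- if (length(msg) > 1) msg[bad] else msg
  }
  flag(!nzchar(case_id), "blank case_id")
  flag(!(component %in% observation_components()), "unknown component")
  flag(is.na(t_min) | is.nan(t_min), "blank or malformed t_min")
  flag(!is.na(t_min) & !is.nan(t_min) & t_min < 0, "negative t_min")
  flag(has_num == has_code, "exactly one of value_num/value_code required")
  is_numeric_comp <- component %in% names(.numeric_components)
  flag(is_numeric_comp & has_code, "coded value for numeric component")
  flag(!is_numeric_comp & has_num, "numeric value for coded component")
  flag(has_num & is.na(vnum), "malformed value_num")
  for (comp in names(.numeric_components)) {
    rng <- .numeric_components[[comp]]
    flag(component == comp & has_num & !is.na(vnum) &
           (vnum < rng[1] | vnum > rng[2]),
         sprintf("%s value outside [%g, %g]", comp, rng[1], rng[2]))
  }
  for (comp in names(.coded_domains)) {
    flag(component == comp & has_code & !(vcode %in% .coded_domains[[comp]]),
         sprintf("%s code outside {%s}", comp,
                 paste(.coded_domains[[comp]], collapse = ",")))
  }

  keep <- is.na(reason)
  accepted <- data.frame(
    case_id = case_id[keep],
    component = component[keep],
    t_min = as.integer(t_min[keep]),
    value_num = ifelse(has_num[keep], vnum[keep], NA_real_),
    value_code = ifelse(has_code[keep], vcode[keep], NA_character_),
    stringsAsFactors = FALSE
  )
  ord <- order(accepted$case_id, accepted$component, accepted$t_min)
  accepted <- accepted[ord, , drop = FALSE]
  rownames(accepted) <- NULL
  .finish_load(accepted, which(!keep), reason[!keep], raw, "read_observations")
}

# -- referrals -----------------------------------------------------------------

.referral_columns <- c("case_id", "referral_time", "reason_code", "admitted_flag")

#' Read a referral register
#'
#' Parses `referrals.csv`, one row per referred woman. A blank `case_id`
#' denotes a woman referred after initial assessment without admission (no
#' intrapartum case record exists for her); `admitted_flag = TRUE` with a
#' blank `case_id` is therefore a hard error, not a row-level reject.
#'
#' @param path Path to the referral register CSV with columns `case_id,
#'   referral_time, reason_code, admitted_flag`.
#' @return A data frame of accepted referrals (`case_id` is `NA` for
#'   referrals without admission; `admitted_flag` logical) with `rejected` and
#'   `rows_in` attributes.
#' @export
read_referrals <- function(path) {
  raw <- .read_raw(path, .referral_columns, "read_referrals")
  n <- nrow(raw)
  case_id <- trimws(raw$case_id)
  referral_time <- parse_timestamp(raw$referral_time)
  reason <- trimws(raw$reason_code)
  flag_raw <- tolower(trimws(raw$admitted_flag))
  admitted <- rep(NA, n)
  admitted[flag_raw %in% c("true", "t", "1", "yes")] <- TRUE
  admitted[flag_raw %in% c("false", "f", "0", "no")] <- FALSE

  bad_admitted_orphan <- which(admitted %in% TRUE & !nzchar(case_id))
  if (length(bad_admitted_orphan) > 0) {
    stop(sprintf(
      "read_referrals: admitted_flag is true but case_id is absent (rows %s)",
      paste(bad_admitted_orphan, collapse = ", ")
    ), call. = FALSE)
  }

  why <- rep(NA_character_, n)
  flag <- function(bad, msg) {
    bad <- which(bad & is.na(why))
    why[bad] <<- msg
  }
  flag(is.na(admitted), "malformed admitted_flag")
  flag(!(reason %in% referral_reasons()), "unknown reason_code")
  flag(is.na(referral_time) & nzchar(trimws(raw$referral_time)),
       "unparseable referral_time")

  keep <- is.na(why)
  accepted <- data.frame(
    case_id = ifelse(nzchar(case_id[keep]), case_id[keep], NA_character_),
    referral_time = referral_time[keep],
    reason_code = reason[keep],
    admitted_flag = admitted[keep],
    stringsAsFactors = FALSE
  )
  rownames(accepted) <- NULL
  .finish_load(accepted, which(!keep), why[!keep], raw, "read_referrals")
}

# -- writers (round-trip inverses of the readers) ------------------------------

#' Write register tables
#'
#' Inverse of the corresponding readers: writing a valid parsed table and
#' re-reading it is the identity on the parsed representation. Missing values
#' are written as empty fields; timestamps as ISO-8601.
#'
#' @param cases,observations,referrals Data frames in the parsed
#'   representation produced by the readers (or by [simulate_cohort()]).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @rdname write_registers
#' @export
write_cases <- function(cases, path) {
  out <- data.frame(
    case_id = cases$case_id,
    facility = cases$facility,
    admission_time = format_timestamp(cases$admission_time),
    age_years = ifelse(is.na(cases$age_years), "", cases$age_years),
    parity = ifelse(cases$parity == "missing", "", cases$parity),
    gestation_weeks = ifelse(is.na(cases$gestation_weeks), "",
                             cases$gestation_weeks),
    membrane_status = ifelse(cases$membrane_status == "missing", "",
                             cases$membrane_status),
    dilatation_on_arrival_cm = cases$dilatation_on_arrival_cm,
    delivery_time = format_timestamp(cases$delivery_time),
    birth_outcome = ifelse(cases$birth_outcome == "missing", "",
                           cases$birth_outcome),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_registers
#' @export
write_observations <- function(observations, path) {
  out <- data.frame(
    case_id = observations$case_id,
    component = observations$component,
    t_min = observations$t_min,
    value_num = ifelse(is.na(observations$value_num), "",
                       format(observations$value_num, trim = TRUE,
                              scientific = FALSE)),
    value_code = ifelse(is.na(observations$value_code), "",
                        observations$value_code),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_registers
#' @export
write_referrals <- function(referrals, path) {
  out <- data.frame(
    case_id = ifelse(is.na(referrals$case_id), "", referrals$case_id),
    referral_time = format_timestamp(referrals$referral_time),
    reason_code = referrals$reason_code,
    admitted_flag = ifelse(referrals$admitted_flag, "true", "false"),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
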