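# Deterministic reference cohort: a synthetic stand-in for a one-year,
# five-facility register set, constructed (not sampled) so that the audit's
# flow counts and background margins take fixed, documented values. Used by
# tests and the acceptance script as a known-answer fixture.

#' Deterministic reference cohort
#'
#' Builds a fixed synthetic cohort whose audited case flow is, by
#' construction: 1548 women presented, 1198 admitted, 350 referred without
#' admission, 663 eligible (cervical dilatation of 8 cm or less on arrival),
#' 648 with a partograph initiated, 71 partographs with at least one
#' indication of abnormal labour (44 foetal distress, 20 prolonged labour,
#' 4 obstructed labour, 3 pre-eclampsia, no overlap), 5 in-scope referrals
#' among partograph cases of which exactly 1 belongs to a case with a charted
#' indication. Background margins (facility, age band, parity, arrival
#' dilatation band, membrane status) are fixed to realistic first-level
#' facility values. The cohort is fully deterministic: no random number is
#' drawn.
#'
#' @param out_dir Optional directory; when given, `cases.csv`,
#'   `partograph_obs.csv` and `referrals.csv` are written there.
#' @return `list(cases, observations, referrals)` of data frames in the
#'   parsed representation used by the readers.
#' @examples
#' ref <- make_reference_cohort()
#' audit <- partograph_audit(ref$cases, ref$observations, ref$referrals)
#' audit$flow$counts$n_abnormal_indication # 71
#' @export
make_reference_cohort <- function(out_dir = NULL) {
  n <- 1198L
  i <- seq_len(n)
  case_id <- sprintf("C%04d", i)
  base <- as.POSIXct("2013-07-01 00:00:00", tz = "UTC")
  admission <- base + (i - 1) * 438 * 60

  # condition blocks among the 648 partograph cases
  distress <- i <= 44
  prolonged <- i >= 45 & i <= 64
  obstructed <- i >= 65 & i <= 68
  preeclampsia <- i >= 69 & i <= 71
  has_partograph <- i <= 648
  eligible <- i <= 663

  d0 <- ifelse(eligible, ifelse(prolonged, 4L, 4L + (i %% 5L)), 9L + (i %% 2L))
  duration_min <- ifelse(prolonged, 420L, 360L)
  delivery <- admission + duration_min * 60

  outcome <- rep("live", n)
  outcome[i <= 3] <- "stillbirth"            # 3/71 flagged (4.2%)
  outcome[i >= 72 & i <= 90] <- "stillbirth" # 19/577 unflagged (3.3%)

  cases <- data.frame(
    case_id = case_id,
    facility = rep(c("Shibpasha", "Kakailsheo", "Murakuri", "Doulatpur",
                     "Khagaura"), c(338L, 302L, 250L, 232L, 76L)),
    admission_time = admission,
    age_years = rep(c(17L, 22L, 27L, 33L, NA_integer_),
                    c(43L, 505L, 430L, 205L, 15L)),
    parity = rep(c("nullipara", "multipara", "missing"),
                 c(403L, 777L, 18L)),
    gestation_weeks = 38L + (i %% 3L),
    membrane_status = rep(c("ruptured", "intact", "missing"),
                          c(1015L, 67L, 116L)),
    dilatation_on_arrival_cm = as.integer(d0),
    delivery_time = delivery,
    birth_outcome = outcome,
    stringsAsFactors = FALSE
  )

  # one partograph per case i <= 648: a compact normal observation set with
  # the case's condition signature substituted in
  pid <- case_id[has_partograph]
  pd0 <- as.integer(d0[has_partograph])
  np <- length(pid)
  f1 <- ifelse(distress[has_partograph], 110, 140)
  f2 <- ifelse(distress[has_partograph], 108, 138)
  cdur <- ifelse(obstructed[has_partograph], "gt40s", "s20to40")
  mould <- ifelse(obstructed[has_partograph], "+++", "0")
  sbp <- ifelse(preeclampsia[has_partograph], 150, 120)
  alb <- ifelse(preeclampsia[has_partograph], "plus1", "neg")
  # dilatation: prolonged cases plot (0, 4) then (300, 6), right of the alert
  # line; all others plot (0, d0) then (120, d0 + 2), exactly on it
  dil_t2 <- ifelse(prolonged[has_partograph], 300L, 120L)
  dil_v2 <- ifelse(prolonged[has_partograph], 6L, pd0 + 2L)

  num_row <- function(comp, t, v) {
    data.frame(case_id = pid, component = comp, t_min = as.integer(t),
               value_num = as.numeric(v), value_code = NA_character_,
               stringsAsFactors = FALSE)
  }
  code_row <- function(comp, t, v) {
    data.frame(case_id = pid, component = comp, t_min = as.integer(t),
               value_num = NA_real_, value_code = as.character(v),
               stringsAsFactors = FALSE)
  }
  observations <- rbind(
    num_row("fhr", 0L, f1), num_row("fhr", 30L, f2),
    code_row("liquor", 0L, "C"),
    num_row("dilatation", 0L, pd0), num_row("dilatation", dil_t2, dil_v2),
    code_row("contraction_duration", 0L, cdur),
    code_row("contraction_duration", 30L, cdur),
    num_row("contraction_freq", 0L, 3), num_row("contraction_freq", 30L, 3),
    num_row("descent", 0L, 5), num_row("descent", 120L, 4),
    code_row("moulding", 0L, mould),
    num_row("sbp", 0L, sbp), num_row("dbp", 0L, 80),
    num_row("pulse", 0L, 88),
    num_row("temperature", 0L, 36.8),
    code_row("urine_albumin", 0L, alb),
    num_row("urine_volume", 0L, 150)
  )
  ord <- order(observations$case_id, observations$component, observations$t_min)
  observations <- observations[ord, , drop = FALSE]
  rownames(observations) <- NULL

  # referral register: 350 without admission; 5 admitted in-scope referrals
  # among partograph cases, exactly one of them (case 45) with a charted
  # indication (prolonged labour)
  referred_idx <- c(45L, 100L, 150L, 200L, 250L)
  admitted_refs <- data.frame(
    case_id = case_id[referred_idx],
    referral_time = admission[referred_idx] + 200 * 60,
    reason_code = "prolonged_labour",
    admitted_flag = TRUE,
    stringsAsFactors = FALSE
  )
  unadm_reasons <- rep(c("prolonged_labour", "foetal_distress", "preeclampsia",
                         "obstructed_labour", "other", "general_illness"),
                       c(120L, 60L, 50L, 40L, 40L, 40L))
  unadmitted_refs <- data.frame(
    case_id = NA_character_,
    referral_time = base + (seq_len(350L) - 1) * 1500 * 60,
    reason_code = unadm_reasons,
    admitted_flag = FALSE,
    stringsAsFactors = FALSE
  )
  referrals <- rbind(admitted_refs, unadmitted_refs)
  rownames(referrals) <- NULL

  out <- list(cases = cases, observations = observations,
              referrals = referrals)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_cases(cases, file.path(out_dir, "cases.csv"))
    write_observations(observations, file.path(out_dir, "partograph_obs.csv"))
    write_referrals(referrals, file.path(out_dir, "referrals.csv"))
  }
  invisible(out)
}
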