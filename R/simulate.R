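# Synthetic labour-cohort simulator.
#
# Emits the three register tables (cases, long-format partograph
# observations, referrals) with known per-case ground truth, so every stage
# of the audit pipeline can be tested without facility data. Labour
# trajectories are linear in the active phase; the four abnormal-labour
# conditions are drawn independently per case and their partograph signatures
# constructed so that, under full charting, the rule engine recovers exactly
# the drawn condition; charting dropout is an independent per-due-interval
# Bernoulli thinning; referral behaviour follows ground truth with a
# compliance probability plus out-of-scope noise.
#
# Reproducibility: one root seed; per-case substreams derived by counter, so
# cohorts are reproducible and per-component thinning uses common random
# numbers (lowering a charting probability deterministically removes
# observations, never adds them).

#' Simulation parameters
#'
#' Defaults emulate the margins of a one-year cohort at first-level
#' facilities: ~55% of admissions arrive at 8 cm or less, partographs are
#' initiated for ~98% of eligible cases, ~11% of partographs carry at least
#' one indication of abnormal labour (foetal distress the most common, then
#' prolonged labour), charting completeness varies widely by component, and
#' referral compliance for flagged cases is low (~7%).
#'
#' @param n_cases Number of admitted cases to simulate.
#' @param seed Root seed (integer).
#' @param prevalence Named probabilities for the four conditions
#'   (`foetal_distress`, `prolonged_labour`, `obstructed_labour`,
#'   `preeclampsia`), drawn independently per case.
#' @param admission_dilatation_distribution Probabilities over arrival
#'   dilatation 0--10 cm.
#' @param normal_dilatation_rate,normal_dilatation_sd Mean and sd (cm/h) of
#'   the active-phase dilatation rate for cases not drawn prolonged; the rate
#'   is truncated to `[1, 2]` cm/h so that a case not drawn prolonged never
#'   plots right of the alert line and every labour lasts at least an hour.
#' @param prolonged_dilatation_rate Dilatation rate (cm/h) for cases drawn
#'   prolonged (default 0.4, guaranteeing an alert-line crossing).
#' @param fhr_baseline,fhr_sd Baseline FHR distribution (bpm); values for
#'   cases not in a distress episode are clamped inside (120, 160).
#' @param distress_episode_fhr The two FHR levels (low, high bpm) used for
#'   distress episodes.
#' @param charting_probability Named per-due-interval plotting probabilities,
#'   one per scored component (`bp` thins sbp/dbp pairs jointly;
#'   `contraction_freq` governs the contraction frequency/duration cell).
#' @param partograph_initiation Probability a partograph is started for an
#'   eligible case.
#' @param referral_compliance Probability a case with a true condition
#'   appears in the referral register.
#' @param out_of_scope_referral_rate Probability an unflagged case acquires
#'   an out-of-partograph-scope referral (postpartum/neonatal reasons).
#' @param unadmitted_referral_rate Expected referrals without admission per
#'   admitted case.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_cases = 500,
                       seed = 1,
                       prevalence = c(foetal_distress = 0.068,
                                      prolonged_labour = 0.031,
                                      obstructed_labour = 0.006,
                                      preeclampsia = 0.006),
                       admission_dilatation_distribution =
                         c(`0` = 0, `1` = 0.01, `2` = 0.02, `3` = 0.05,
                           `4` = 0.08, `5` = 0.10, `6` = 0.10, `7` = 0.10,
                           `8` = 0.093, `9` = 0.247, `10` = 0.20),
                       normal_dilatation_rate = 1.2,
                       normal_dilatation_sd = 0.3,
                       prolonged_dilatation_rate = 0.4,
                       fhr_baseline = 140, fhr_sd = 8,
                       distress_episode_fhr = c(105, 175),
                       charting_probability =
                         c(fhr = 0.55, contraction_freq = 0.75, pulse = 0.08,
                           temperature = 0.50, urine_volume = 0.55,
                           urine_albumin = 0.95, liquor = 0.70,
                           moulding = 0.30, dilatation = 0.85,
                           descent = 0.80, bp = 0.75),
                       partograph_initiation = 0.977,
                       referral_compliance = 0.07,
                       out_of_scope_referral_rate = 0.02,
                       unadmitted_referral_rate = 0.292) {
  conds <- c("foetal_distress", "prolonged_labour", "obstructed_labour",
             "preeclampsia")
  stopifnot(
    is_count(n_cases), n_cases > 0,
    all(conds %in% names(prevalence)),
    all(prevalence >= 0 & prevalence <= 1),
    length(admission_dilatation_distribution) == 11,
    abs(sum(admission_dilatation_distribution) - 1) < 1e-8,
    normal_dilatation_rate > 0, prolonged_dilatation_rate > 0,
    all(names(unclass(interval_schedule())) %in% names(charting_probability)),
    all(charting_probability >= 0 & charting_probability <= 1),
    partograph_initiation >= 0, partograph_initiation <= 1,
    referral_compliance >= 0, referral_compliance <= 1,
    out_of_scope_referral_rate >= 0, out_of_scope_referral_rate <= 1,
    unadmitted_referral_rate >= 0
  )
  p <- list(
    n_cases = as.integer(n_cases), seed = as.integer(seed),
    prevalence = prevalence[conds],
    admission_dilatation_distribution = admission_dilatation_distribution,
    normal_dilatation_rate = normal_dilatation_rate,
    normal_dilatation_sd = normal_dilatation_sd,
    prolonged_dilatation_rate = prolonged_dilatation_rate,
    fhr_baseline = fhr_baseline, fhr_sd = fhr_sd,
    distress_episode_fhr = distress_episode_fhr,
    charting_probability = charting_probability,
    partograph_initiation = partograph_initiation,
    referral_compliance = referral_compliance,
    out_of_scope_referral_rate = out_of_scope_referral_rate,
    unadmitted_referral_rate = unadmitted_referral_rate
  )
  class(p) <- "sim_params"
  p
}

.case_seed <- function(root_seed, case_index) {
  # per-case substream: counter-derived, kept below 2^31
  (as.integer(root_seed) %% 1000003L) * 2039L + case_index * 7L + 11L
}

.rtruncnorm1 <- function(mean, sd, lower, upper) {
  # single truncated-normal draw via inverse CDF (one uniform consumed)
  a <- stats::pnorm((lower - mean) / sd)
  b <- stats::pnorm((upper - mean) / sd)
  stats::qnorm(a + stats::runif(1) * (b - a)) * sd + mean
}

.grid_slots <- function(interval, t_d) {
  # due times: schedule grid from admission, plus the delivery examination
  unique(c(seq(0L, max(0L, t_d - 1L), by = interval), t_d))
}

#' Simulate one labour
#'
#' Generates one admitted case: arrival characteristics, a linear
#' active-phase dilatation trajectory at the case's rate (monotone
#' non-decreasing, plotted in whole centimetres on the component's schedule
#' grid plus a delivery examination), partograph signatures for any condition
#' the case was drawn with, per-due-interval Bernoulli charting dropout, and
#' the case's referral behaviour. Construction guarantees that under full
#' charting the rule engine flags exactly the drawn conditions.
#'
#' @param params A [sim_params()] object.
#' @param case_index Counter used to derive the case's RNG substream.
#' @param admission_time Admission timestamp (POSIXct).
#' @return `list(case = <one-row case data frame>, observations = <data
#'   frame>, truth = <one-row ground-truth data frame>, referral = <referral
#'   data frame or NULL>)`.
#' @export
simulate_labour <- function(params, case_index,
                            admission_time = as.POSIXct("2013-07-01 00:00:00",
                                                        tz = "UTC")) {
  set.seed(.case_seed(params$seed, case_index))
  case_id <- sprintf("S%05d", case_index)

  facility <- sample(c("Shibpasha", "Kakailsheo", "Murakuri", "Doulatpur",
                       "Khagaura"), 1,
                     prob = c(0.282, 0.252, 0.209, 0.194, 0.063))
  age <- round(.rtruncnorm1(24.9, 4.5, 15, 45))
  age_missing <- stats::runif(1) < 0.013
  parity <- sample(.parity_levels, 1, prob = c(0.336, 0.649, 0.015))
  gestation <- sample(37:41, 1)
  membranes <- sample(.membrane_levels, 1, prob = c(0.847, 0.056, 0.097))
  d0 <- sample(0:10, 1, prob = params$admission_dilatation_distribution)

  truth_flags <- stats::runif(4) < params$prevalence
  names(truth_flags) <- names(params$prevalence)

  rate <- .rtruncnorm1(params$normal_dilatation_rate,
                       params$normal_dilatation_sd, 1.0, 2.0)
  if (truth_flags[["prolonged_labour"]]) rate <- params$prolonged_dilatation_rate
  t_d <- max(1L, as.integer(round(60 * (10 - d0) / rate)))
  delivery_time <- admission_time + t_d * 60

  eligible <- d0 <= 8
  initiated <- eligible && stats::runif(1) < params$partograph_initiation

  obs <- NULL
  if (initiated) {
    obs <- .sim_case_obs(case_id, d0, rate, t_d, truth_flags, membranes, params)
  }

  any_ind <- any(truth_flags)
  outcome_p <- if (any_ind) 0.042 else 0.033
  outcome <- if (stats::runif(1) < outcome_p) "stillbirth" else "live"

  referral <- NULL
  u_ref <- stats::runif(1)
  u_oos <- stats::runif(1)
  if (any_ind && u_ref < params$referral_compliance) {
    priority <- c("prolonged_labour", "foetal_distress", "obstructed_labour",
                  "preeclampsia")
    reason <- priority[which(truth_flags[priority])[1]]
    referral <- data.frame(
      case_id = case_id,
      referral_time = admission_time + round(0.7 * t_d) * 60,
      reason_code = reason,
      admitted_flag = TRUE,
      stringsAsFactors = FALSE
    )
  } else if (u_oos < params$out_of_scope_referral_rate) {
    referral <- data.frame(
      case_id = case_id,
      referral_time = delivery_time + 3600,
      reason_code = sample(c("pph", "retained_placenta", "general_illness",
                             "birth_asphyxia", "low_birth_weight"), 1),
      admitted_flag = TRUE,
      stringsAsFactors = FALSE
    )
  }

  case <- data.frame(
    case_id = case_id,
    facility = facility,
    admission_time = admission_time,
    age_years = if (age_missing) NA_integer_ else as.integer(age),
    parity = parity,
    gestation_weeks = as.integer(gestation),
    membrane_status = membranes,
    dilatation_on_arrival_cm = as.integer(d0),
    delivery_time = delivery_time,
    birth_outcome = outcome,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    case_id = case_id,
    foetal_distress = truth_flags[["foetal_distress"]],
    prolonged_labour = truth_flags[["prolonged_labour"]],
    obstructed_labour = truth_flags[["obstructed_labour"]],
    preeclampsia = truth_flags[["preeclampsia"]],
    any_indication = any_ind,
    eligible = eligible,
    partograph_initiated = initiated,
    referred = !is.null(referral) && isTRUE(referral$admitted_flag[1]) &&
      referral$reason_code[1] %in% names(truth_flags),
    dilatation_rate = rate,
    labour_minutes = t_d,
    stringsAsFactors = FALSE
  )
  list(case = case, observations = obs, truth = truth, referral = referral)
}

# Build the full (pre-thinning) observation set for one case, then thin with
# common random numbers. Values are drawn so that a condition's signature is
# present iff the condition was drawn:
#   distress   - two consecutive out-of-range FHR plottings or meconium;
#   prolonged  - slow rate makes every post-anchor plot fall right of alert;
#   obstructed - moderate/severe contractions plus +++ moulding or a descent
#                plateau; otherwise descent is strictly decreasing;
#   pre-eclampsia - elevated BP pairs plus albuminuria throughout.
.sim_case_obs <- function(case_id, d0, rate, t_d, truth, membranes, params) {
  g30 <- .grid_slots(30L, t_d)
  g120 <- .grid_slots(120L, t_d)
  g240 <- .grid_slots(240L, t_d)
  n30 <- length(g30)
  n120 <- length(g120)
  n240 <- length(g240)

  # fhr
  fhr <- round(stats::rnorm(n30, params$fhr_baseline, params$fhr_sd))
  fhr <- pmin(pmax(fhr, 121), 159)
  distress_by_meconium <- FALSE
  if (truth[["foetal_distress"]]) {
    distress_by_meconium <- stats::runif(1) < 0.3
    if (!distress_by_meconium) {
      episode <- sample(params$distress_episode_fhr, 1)
      start <- if (n30 > 2) sample(n30 - 1, 1) else 1
      fhr[start:(start + 1)] <- episode
    }
  }

  # liquor
  liquor <- rep(if (membranes == "intact") "I" else "C", n240)
  if (distress_by_meconium) {
    onset <- sample(n240, 1)
    liquor[onset:n240] <- "M"
  }

  # contractions (frequency + duration share the partograph cell)
  cfreq <- sample(2:5, n30, replace = TRUE)
  if (truth[["obstructed_labour"]]) {
    cdur <- sample(c("s20to40", "gt40s"), n30, replace = TRUE)
  } else {
    cdur <- sample(c("lt20s", "s20to40", "gt40s"), n30, replace = TRUE,
                   prob = c(0.2, 0.5, 0.3))
  }

  # moulding / descent: the obstruction signature
  obstruct_by_moulding <- FALSE
  if (truth[["obstructed_labour"]]) obstruct_by_moulding <- stats::runif(1) < 0.5
  moulding <- sample(c("0", "+", "++"), n240, replace = TRUE,
                     prob = c(0.75, 0.20, 0.05))
  if (obstruct_by_moulding) moulding[] <- "+++"

  if (truth[["obstructed_labour"]] && !obstruct_by_moulding) {
    descent_t <- g240
    descent_v <- rep(3L, n240) # plateau: head not descending
  } else {
    # strictly decreasing fifths palpable; charting stops once the head is
    # engaged (0/5), so no plateau can arise for an unobstructed case
    kgrid <- seq(0L, max(0L, t_d - 1L), by = 240L)
    k <- seq_along(kgrid) - 1L
    keep <- k <= 5L
    descent_t <- kgrid[keep]
    descent_v <- 5L - k[keep]
    last <- descent_v[length(descent_v)]
    if (last > 0L) {
      descent_t <- c(descent_t, t_d)
      descent_v <- c(descent_v, last - 1L)
    }
  }

  # dilatation: whole centimetres, floor of the linear trajectory, delivery
  # examination plots full dilatation
  dil_grid <- seq(0L, max(0L, t_d - 1L), by = 240L)
  dil_v <- pmin(9L, as.integer(floor(d0 + rate * dil_grid / 60)))
  dil_t <- c(dil_grid, t_d)
  dil_v <- c(dil_v, 10L)

  # blood pressure pairs
  if (truth[["preeclampsia"]]) {
    sbp <- round(stats::runif(n240, 150, 170))
    dbp <- round(stats::runif(n240, 95, 105))
  } else {
    sbp <- pmin(pmax(round(stats::rnorm(n240, 120, 8)), 95), 138)
    dbp <- pmin(pmax(round(stats::rnorm(n240, 75, 6)), 55), 88)
  }

  # maternal observations
  pulse <- pmin(pmax(round(stats::rnorm(n30, 85, 8)), 60), 120)
  temperature <- pmin(pmax(round(stats::rnorm(n120, 36.8, 0.3), 1), 36), 38)
  urine_vol <- round(stats::runif(n120, 80, 300))
  if (truth[["preeclampsia"]]) {
    albumin <- sample(c("plus1", "plus2", "plus3"), n120, replace = TRUE,
                      prob = c(0.5, 0.3, 0.2))
  } else {
    albumin <- sample(c("neg", "trace"), n120, replace = TRUE,
                      prob = c(0.9, 0.1))
  }

  comp_t <- list(
    fhr = g30, contraction_freq = g30, contraction_duration = g30,
    pulse = g30, temperature = g120, urine_volume = g120,
    urine_albumin = g120, liquor = g240, moulding = g240,
    dilatation = dil_t, descent = descent_t, sbp = g240, dbp = g240
  )
  comp_num <- list(
    fhr = fhr, contraction_freq = cfreq, contraction_duration = NULL,
    pulse = pulse, temperature = temperature, urine_volume = urine_vol,
    urine_albumin = NULL, liquor = NULL, moulding = NULL,
    dilatation = dil_v, descent = descent_v, sbp = sbp, dbp = dbp
  )
  comp_code <- list(
    contraction_duration = cdur, urine_albumin = albumin, liquor = liquor,
    moulding = moulding
  )

  # thinning: one uniform per due slot per charted cell, common random
  # numbers; contraction freq/duration share a draw, as do sbp/dbp pairs
  q <- params$charting_probability
  keep30_contr <- stats::runif(length(g30)) <= q[["contraction_freq"]]
  keep_bp <- stats::runif(length(g240)) <= q[["bp"]]
  keep <- list(
    fhr = stats::runif(length(g30)) <= q[["fhr"]],
    contraction_freq = keep30_contr,
    contraction_duration = keep30_contr,
    pulse = stats::runif(length(g30)) <= q[["pulse"]],
    temperature = stats::runif(length(g120)) <= q[["temperature"]],
    urine_volume = stats::runif(length(g120)) <= q[["urine_volume"]],
    urine_albumin = stats::runif(length(g120)) <= q[["urine_albumin"]],
    liquor = stats::runif(length(g240)) <= q[["liquor"]],
    moulding = stats::runif(length(g240)) <= q[["moulding"]],
    dilatation = stats::runif(length(dil_t)) <= q[["dilatation"]],
    descent = stats::runif(length(descent_t)) <= q[["descent"]],
    sbp = keep_bp,
    dbp = keep_bp
  )

  rows <- lapply(names(comp_t), function(comp) {
    kp <- keep[[comp]]
    if (!any(kp)) return(NULL)
    tt <- comp_t[[comp]][kp]
    if (comp %in% names(.coded_domains)) {
      data.frame(case_id = case_id, component = comp, t_min = as.integer(tt),
                 value_num = NA_real_, value_code = comp_code[[comp]][kp],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(case_id = case_id, component = comp, t_min = as.integer(tt),
                 value_num = as.numeric(comp_num[[comp]][kp]),
                 value_code = NA_character_, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}

#' Simulate a labour cohort
#'
#' Generates `params$n_cases` admitted cases plus referrals without
#' admission, and optionally writes `cases.csv`, `partograph_obs.csv`,
#' `referrals.csv` and `ground_truth.csv` (the latter is never an input to
#' the audit). Identical parameters and seed give identical output, byte for
#' byte.
#'
#' @param params A [sim_params()] object.
#' @param out_dir Optional directory; when given, the four CSVs are written
#'   there.
#' @return `list(cases, observations, referrals, ground_truth)` of data
#'   frames in the parsed representation used by the readers.
#' @export
simulate_cohort <- function(params, out_dir = NULL) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$n_cases
  set.seed(params$seed)
  period_min <- 365 * 24 * 60
  base <- as.POSIXct("2013-07-01 00:00:00", tz = "UTC")
  admission_offsets <- sort(round(stats::runif(n, 0, period_min - 1)))
  n_unadmitted <- stats::rbinom(1, n, min(1, params$unadmitted_referral_rate))
  unadm_offsets <- sort(round(stats::runif(max(n_unadmitted, 1), 0, period_min - 1)))
  unadm_reasons <- sample(c("prolonged_labour", "foetal_distress",
                            "preeclampsia", "obstructed_labour", "other"),
                          max(n_unadmitted, 1), replace = TRUE,
                          prob = c(0.4, 0.2, 0.15, 0.15, 0.1))

  cases <- vector("list", n)
  obs <- vector("list", n)
  truth <- vector("list", n)
  refs <- vector("list", n)
  for (i in seq_len(n)) {
    sim <- simulate_labour(params, i, base + admission_offsets[i] * 60)
    cases[[i]] <- sim$case
    obs[[i]] <- sim$observations
    truth[[i]] <- sim$truth
    refs[[i]] <- sim$referral
  }
  cases <- do.call(rbind, cases)
  observations <- do.call(rbind, obs[!vapply(obs, is.null, TRUE)])
  if (is.null(observations)) {
    observations <- data.frame(case_id = character(), component = character(),
                               t_min = integer(), value_num = numeric(),
                               value_code = character(),
                               stringsAsFactors = FALSE)
  }
  ord <- order(observations$case_id, observations$component, observations$t_min)
  observations <- observations[ord, , drop = FALSE]
  rownames(observations) <- NULL
  ground_truth <- do.call(rbind, truth)

  admitted_refs <- do.call(rbind, refs[!vapply(refs, is.null, TRUE)])
  unadmitted_refs <- if (n_unadmitted > 0) {
    data.frame(
      case_id = NA_character_,
      referral_time = base + unadm_offsets[seq_len(n_unadmitted)] * 60,
      reason_code = unadm_reasons[seq_len(n_unadmitted)],
      admitted_flag = FALSE,
      stringsAsFactors = FALSE
    )
  } else {
    NULL
  }
  referrals <- rbind(admitted_refs, unadmitted_refs)
  if (is.null(referrals)) {
    referrals <- data.frame(case_id = character(),
                            referral_time = as.POSIXct(character(), tz = "UTC"),
                            reason_code = character(), admitted_flag = logical(),
                            stringsAsFactors = FALSE)
  }
  rownames(referrals) <- NULL

  out <- list(cases = cases, observations = observations,
              referrals = referrals, ground_truth = ground_truth)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_cases(cases, file.path(out_dir, "cases.csv"))
    write_observations(observations, file.path(out_dir, "partograph_obs.csv"))
    write_referrals(referrals, file.path(out_dir, "referrals.csv"))
    utils::write.csv(ground_truth, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
  }
  invisible(out)
}
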