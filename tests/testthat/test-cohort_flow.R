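mk_cases <- function(ids, dil) {
  data.frame(
    case_id = ids, facility = "F",
    admission_time = as.POSIXct("2013-07-01 08:00:00", tz = "UTC"),
    age_years = 25L, parity = "multipara", gestation_weeks = 39L,
    membrane_status = "ruptured", dilatation_on_arrival_cm = as.integer(dil),
    delivery_time = as.POSIXct("2013-07-01 16:00:00", tz = "UTC"),
    birth_outcome = "live", stringsAsFactors = FALSE
  )
}

mk_referrals <- function(ids, reasons, times = NULL, admitted = NULL) {
  n <- length(reasons)
  data.frame(
    case_id = ids,
    referral_time = times %||% as.POSIXct("2013-07-01 12:00:00", tz = "UTC"),
    reason_code = reasons,
    admitted_flag = admitted %||% !is.na(ids),
    stringsAsFactors = FALSE
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("eligibility keeps arrivals at 8 cm or less, inclusive", {
  cases <- mk_cases(c("a", "b", "c"), c(6, 8, 9))
  expect_equal(filter_eligible(cases)$case_id, c("a", "b"))
  expect_equal(nrow(filter_eligible(mk_cases(c("x", "y"), c(9, 10)))), 0)
})

test_that("referral linkage scopes reasons, collapses duplicates, logs orphans", {
  cases <- mk_cases(c("X", "Y", "Z"), c(5, 6, 7))
  flags <- data.frame(case_id = c("X", "Y", "Z"),
                      any_indication = c(TRUE, FALSE, FALSE),
                      stringsAsFactors = FALSE)
  t0 <- as.POSIXct("2013-07-01 10:00:00", tz = "UTC")
  refs <- mk_referrals(
    c("X", "Y", "Z", "Z", "Q", NA),
    c("prolonged_labour", "pph", "prolonged_labour", "foetal_distress",
      "prolonged_labour", "preeclampsia"),
    times = t0 + c(0, 0, 3600, 60, 0, 0),
    admitted = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  expect_warning(
    link <- link_referrals(cases, refs, scope_filter(), flags,
                           partograph_case_ids = c("X", "Y", "Z")),
    "match no case"
  )
  # duplicate Z referrals collapse to the earliest event
  z <- link[!is.na(link$case_id) & link$case_id == "Z", ]
  expect_equal(nrow(z), 1)
  expect_equal(z$reason_code, "foetal_distress")
  expect_equal(nrow(attr(link, "collapsed")), 1)
  # pph is retained but marked out of partograph scope
  y <- link[!is.na(link$case_id) & link$case_id == "Y", ]
  expect_false(y$in_scope)
  # orphan is flagged unmatched
  expect_equal(attr(link, "orphans"), "Q")
  expect_false(link$matched[!is.na(link$case_id) & link$case_id == "Q"])
  # case X: referred with charted indication
  x <- link[!is.na(link$case_id) & link$case_id == "X", ]
  expect_true(x$in_scope && x$any_indication)
  # the unadmitted row survives with NA case_id
  expect_equal(sum(is.na(link$case_id)), 1)
})

test_that("flow conservation identities hold on random simulated cohorts", {
  for (seed in c(21, 22, 23)) {
    sim <- simulate_cohort(sim_params(n_cases = 120, seed = seed))
    audit <- partograph_audit(sim$cases, sim$observations, sim$referrals)
    k <- audit$flow$counts
    expect_equal(k$n_presented, k$n_admitted + k$n_referred_without_admission)
    expect_lte(k$n_eligible, k$n_admitted)
    expect_lte(k$n_with_partograph, k$n_eligible)
    expect_lte(k$n_abnormal_indication, k$n_with_partograph)
    expect_lte(k$n_referred_with_indication,
               min(k$n_abnormal_indication, k$n_referred_with_partograph_in_scope))
    # reported percentages recompute from reported counts
    expect_equal(audit$flow$pct$pct_admitted,
                 partoaudit:::round_half_up(100 * k$n_admitted / k$n_presented))
    expect_equal(audit$flow$pct$pct_abnormal,
                 partoaudit:::round_half_up(
                   100 * k$n_abnormal_indication / k$n_with_partograph))
    # background tables count every admitted case exactly once
    for (tab in audit$flow$background_tables) {
      expect_equal(sum(tab$n), k$n_admitted)
    }
  }
})

test_that("an empty referral register zeroes referral counts only", {
  sim <- simulate_cohort(sim_params(n_cases = 60, seed = 31))
  with_refs <- partograph_audit(sim$cases, sim$observations, sim$referrals)
  without <- partograph_audit(sim$cases, sim$observations, referrals = NULL)
  expect_equal(without$flow$counts$n_referred_with_partograph_in_scope, 0)
  expect_equal(without$flow$counts$n_referred_with_indication, 0)
  expect_equal(without$flow$counts$n_referred_without_admission, 0)
  expect_equal(without$flow$counts$n_admitted, with_refs$flow$counts$n_admitted)
  expect_equal(without$flow$counts$n_eligible, with_refs$flow$counts$n_eligible)
  expect_equal(without$flow$counts$n_abnormal_indication,
               with_refs$flow$counts$n_abnormal_indication)
})

test_that("out-of-scope marking never changes admission or eligibility counts", {
  sim <- simulate_cohort(sim_params(n_cases = 80, seed = 41,
                                    out_of_scope_referral_rate = 0.3))
  all_in_scope <- scope_filter(out_of_scope_reasons = character())
  a1 <- partograph_audit(sim$cases, sim$observations, sim$referrals)
  a2 <- partograph_audit(sim$cases, sim$observations, sim$referrals,
                         scope = all_in_scope)
  expect_equal(a1$flow$counts$n_admitted, a2$flow$counts$n_admitted)
  expect_equal(a1$flow$counts$n_eligible, a2$flow$counts$n_eligible)
  expect_equal(a1$flow$counts$n_with_partograph, a2$flow$counts$n_with_partograph)
  expect_lte(a1$flow$counts$n_referred_with_partograph_in_scope,
             a2$flow$counts$n_referred_with_partograph_in_scope)
})
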