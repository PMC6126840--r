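times_pgraph <- function(component, times, case_id = "C1") {
  numeric_comps <- c("fhr", "dilatation", "descent", "contraction_freq",
                     "sbp", "dbp", "pulse", "temperature", "urine_volume")
  if (component %in% numeric_comps) {
    v <- switch(component, dilatation = 5, descent = 3, temperature = 37, 120)
    obs <- data.frame(case_id = case_id, component = component,
                      t_min = as.integer(times), value_num = v,
                      value_code = NA_character_, stringsAsFactors = FALSE)
  } else {
    v <- switch(component, liquor = "C", moulding = "0",
                contraction_duration = "s20to40", urine_albumin = "neg")
    obs <- data.frame(case_id = case_id, component = component,
                      t_min = as.integer(times), value_num = NA_real_,
                      value_code = v, stringsAsFactors = FALSE)
  }
  build_partograph(obs, case_id = case_id)
}

test_that("a component is complete with two plottings within its interval", {
  sched <- interval_schedule()
  expect_true(component_complete(times_pgraph("fhr", c(0, 30)), "fhr", sched))
  expect_false(component_complete(times_pgraph("fhr", c(0, 90)), "fhr", sched))
  expect_false(component_complete(times_pgraph("dilatation", 0), "dilatation",
                                  sched)) # a single plotting is never enough
  # lenient needs one adjacent pair within the interval; strict needs all
  p <- times_pgraph("fhr", c(0, 30, 120))
  expect_true(component_complete(p, "fhr", sched, rule = "lenient"))
  expect_false(component_complete(p, "fhr", sched, rule = "strict"))
  expect_error(component_complete(p, "weight", sched), "unknown component")
})

test_that("blood pressure is scored on sbp/dbp pairs sharing a time", {
  sched <- interval_schedule()
  obs <- rbind(
    data.frame(case_id = "C1", component = "sbp", t_min = c(0L, 240L, 480L),
               value_num = 120, value_code = NA_character_),
    data.frame(case_id = "C1", component = "dbp", t_min = c(0L, 240L, 600L),
               value_num = 80, value_code = NA_character_)
  )
  p <- build_partograph(obs)
  expect_true(component_complete(p, "bp", sched)) # pairs at 0 and 240
  # unpaired readings do not count
  obs2 <- obs[obs$t_min != 240, , drop = FALSE]
  expect_false(component_complete(build_partograph(obs2), "bp", sched))
  # half-hourly convention is selectable
  expect_false(component_complete(p, "bp", interval_schedule(bp_interval_min = 30)))
})

test_that("deleting an observation never makes an incomplete component complete", {
  sched <- interval_schedule()
  set.seed(404)
  for (rep in 1:50) {
    times <- sort(sample(seq(0, 960, by = 30), sample(2:8, 1)))
    for (rule in c("lenient", "strict")) {
      before <- component_complete(times_pgraph("fhr", times), "fhr", sched, rule)
      drop <- sample(length(times), 1)
      after <- component_complete(times_pgraph("fhr", times[-drop]), "fhr",
                                  sched, rule)
      expect_true(before >= after)
    }
  }
})

test_that("the pooled two-proportion z-test matches its closed form and chi-square", {
  # identical proportions
  res <- two_proportion_test(10, 20, 10, 20)
  expect_equal(res$z, 0)
  expect_equal(res$p_value, 1)
  expect_false(res$significant)

  # degenerate when the pooled proportion is 0 or 1
  res <- two_proportion_test(0, 71, 0, 577)
  expect_true(res$degenerate)
  expect_true(is.na(res$p_value))
  expect_true(two_proportion_test(20, 20, 577, 577)$degenerate)

  expect_error(two_proportion_test(5, 4, 1, 10), "x must not exceed n")

  # z^2 equals the 1-df chi-square statistic without continuity correction
  set.seed(405)
  for (rep in 1:40) {
    n1 <- sample(5:200, 1); n2 <- sample(5:200, 1)
    x1 <- sample(0:n1, 1); x2 <- sample(0:n2, 1)
    res <- two_proportion_test(x1, n1, x2, n2)
    if (!res$degenerate) {
      chi <- suppressWarnings(
        stats::prop.test(c(x1, x2), c(n1, n2), correct = FALSE))
      expect_equal(res$z^2, unname(chi$statistic), tolerance = 1e-9)
      expect_equal(res$p_value, chi$p.value, tolerance = 1e-9)
      # swapping groups negates z and preserves p
      swapped <- two_proportion_test(x2, n2, x1, n1)
      expect_equal(swapped$z, -res$z)
      expect_equal(swapped$p_value, res$p_value)
    }
  }
})

test_that("cohort completeness aggregates per group with conserved sizes", {
  sched <- interval_schedule()
  complete_p <- times_pgraph("fhr", c(0, 30), case_id = "A")
  incomplete_p <- times_pgraph("fhr", c(0, 90), case_id = "B")
  flags <- data.frame(
    case_id = c("A", "B"),
    foetal_distress = c(TRUE, FALSE), prolonged_labour = FALSE,
    obstructed_labour = FALSE, preeclampsia = FALSE,
    any_indication = c(TRUE, FALSE), stringsAsFactors = FALSE
  )
  tab <- cohort_completeness(list(complete_p, incomplete_p), flags, sched)
  fhr <- tab[tab$component == "fhr", ]
  expect_equal(fhr$pct_overall, 50.0)
  expect_equal(fhr$pct_abnormal, 100.0)
  expect_equal(fhr$pct_no_indication, 0.0)
  expect_equal(attr(tab, "n_abnormal") + attr(tab, "n_no_indication"),
               attr(tab, "n_total"))
  expect_error(
    cohort_completeness(list(complete_p), flags[flags$case_id == "B", ], sched),
    "every partograph needs a classification"
  )
})
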