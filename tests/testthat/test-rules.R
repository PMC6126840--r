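obs_row <- function(case_id, component, t, num = NA, code = NA) {
  data.frame(case_id = case_id, component = component, t_min = as.integer(t),
             value_num = as.numeric(num), value_code = as.character(code),
             stringsAsFactors = FALSE)
}

pgraph <- function(...) build_partograph(rbind(...), case_id = "T1")

test_that("foetal distress needs two out-of-range FHR observations or meconium", {
  cfg <- rule_config()
  p <- pgraph(obs_row("T1", "fhr", 0, 118), obs_row("T1", "fhr", 30, 115))
  expect_true(detect_foetal_distress(p, cfg)$flag)

  p <- pgraph(obs_row("T1", "fhr", 0, 118), obs_row("T1", "fhr", 30, 140),
              obs_row("T1", "fhr", 60, 150))
  expect_false(detect_foetal_distress(p, cfg)$flag) # single violation

  p <- pgraph(obs_row("T1", "fhr", 0, 130), obs_row("T1", "fhr", 30, 150),
              obs_row("T1", "liquor", 0, code = "C"),
              obs_row("T1", "liquor", 240, code = "M"))
  res <- detect_foetal_distress(p, cfg)
  expect_true(res$flag) # meconium alone suffices
  expect_equal(res$evidence$component, "liquor")

  # boundary values are not violations (strict inequalities)
  p <- pgraph(obs_row("T1", "fhr", 0, 120), obs_row("T1", "fhr", 30, 160))
  expect_false(detect_foetal_distress(p, cfg)$flag)

  # violations in opposite directions both count
  p <- pgraph(obs_row("T1", "fhr", 0, 105), obs_row("T1", "fhr", 30, 175))
  expect_true(detect_foetal_distress(p, cfg)$flag)
})

test_that("the consecutive-FHR switch tightens the two-observation rule", {
  p <- pgraph(obs_row("T1", "fhr", 0, 118), obs_row("T1", "fhr", 30, 140),
              obs_row("T1", "fhr", 60, 115))
  expect_true(detect_foetal_distress(p, rule_config())$flag)
  expect_false(
    detect_foetal_distress(p, rule_config(fhr_require_consecutive = TRUE))$flag
  )
  p2 <- pgraph(obs_row("T1", "fhr", 0, 118), obs_row("T1", "fhr", 30, 112))
  expect_true(
    detect_foetal_distress(p2, rule_config(fhr_require_consecutive = TRUE))$flag
  )
})

test_that("prolonged labour follows the alert/action line tests", {
  cfg <- rule_config()
  p <- pgraph(obs_row("T1", "dilatation", 0, 4),
              obs_row("T1", "dilatation", 300, 6))
  res <- detect_prolonged_labour(p, cfg)
  expect_true(res$flag) # alert_time(6) = 120 < 300
  expect_equal(res$evidence$t_min, 300L)

  # exactly 1 cm/h: on the line, never right of it
  p <- pgraph(obs_row("T1", "dilatation", 0, 4),
              obs_row("T1", "dilatation", 120, 6),
              obs_row("T1", "dilatation", 360, 10))
  expect_false(detect_prolonged_labour(p, cfg)$flag)

  # no dilatation >= 4 cm: geometry undefined, false with a warning
  p <- pgraph(obs_row("T1", "dilatation", 0, 2),
              obs_row("T1", "dilatation", 120, 3))
  expect_warning(res <- detect_prolonged_labour(p, cfg), "never >= 4 cm")
  expect_false(res$flag)

  # charted regression below the anchor is ignored by the line tests
  p <- pgraph(obs_row("T1", "dilatation", 0, 6),
              obs_row("T1", "dilatation", 400, 5))
  res <- detect_prolonged_labour(p, cfg)
  expect_false(res$flag)
  expect_equal(nrow(res$ignored), 1)
})

test_that("obstructed labour is a conjunction of contractions and moulding/plateau", {
  cfg <- rule_config()
  p <- pgraph(obs_row("T1", "contraction_duration", 0, code = "gt40s"),
              obs_row("T1", "moulding", 0, code = "+++"))
  expect_true(detect_obstructed_labour(p, cfg)$flag)

  p <- pgraph(obs_row("T1", "contraction_duration", 0, code = "lt20s"),
              obs_row("T1", "moulding", 0, code = "+++"))
  expect_false(detect_obstructed_labour(p, cfg)$flag) # no moderate contraction

  p <- pgraph(obs_row("T1", "contraction_duration", 0, code = "s20to40"),
              obs_row("T1", "descent", 0, 3), obs_row("T1", "descent", 240, 3))
  res <- detect_obstructed_labour(p, cfg)
  expect_true(res$flag) # plateau: consecutive non-decreasing descent
  expect_true(any(res$evidence$component == "descent"))

  p <- pgraph(obs_row("T1", "contraction_duration", 0, code = "s20to40"),
              obs_row("T1", "descent", 0, 3), obs_row("T1", "descent", 240, 2))
  expect_false(detect_obstructed_labour(p, cfg)$flag) # head descending
})

test_that("pre-eclampsia needs an elevated BP pair and albuminuria", {
  cfg <- rule_config()
  p <- pgraph(obs_row("T1", "sbp", 0, 150), obs_row("T1", "dbp", 0, 85),
              obs_row("T1", "urine_albumin", 0, code = "plus1"))
  expect_true(detect_preeclampsia(p, cfg)$flag)

  # thresholds are strict ("more than")
  p <- pgraph(obs_row("T1", "sbp", 0, 140), obs_row("T1", "dbp", 0, 90),
              obs_row("T1", "urine_albumin", 0, code = "plus2"))
  expect_false(detect_preeclampsia(p, cfg)$flag)

  p <- pgraph(obs_row("T1", "sbp", 0, 160), obs_row("T1", "dbp", 0, 100),
              obs_row("T1", "urine_albumin", 0, code = "neg"))
  expect_false(detect_preeclampsia(p, cfg)$flag)

  # trace counts only when configured to
  p <- pgraph(obs_row("T1", "sbp", 0, 160), obs_row("T1", "dbp", 0, 100),
              obs_row("T1", "urine_albumin", 0, code = "trace"))
  expect_false(detect_preeclampsia(p, cfg)$flag)
  expect_true(detect_preeclampsia(p, rule_config(include_trace_albumin = TRUE))$flag)

  # an unpaired elevated sbp (no dbp at the same time) is not a BP pair
  p <- pgraph(obs_row("T1", "sbp", 0, 180),
              obs_row("T1", "urine_albumin", 0, code = "plus3"))
  expect_false(detect_preeclampsia(p, cfg)$flag)
})

test_that("classify combines the four detectors and backs flags with evidence", {
  empty <- build_partograph(obs_row("x", "fhr", 0, 140)[0, ], case_id = "E1")
  res <- classify_partograph(empty)
  expect_false(res$any_indication)
  expect_equal(nrow(res$evidence), 0)

  p <- pgraph(obs_row("T1", "fhr", 0, 110), obs_row("T1", "fhr", 30, 112),
              obs_row("T1", "dilatation", 0, 4),
              obs_row("T1", "dilatation", 300, 5))
  res <- classify_partograph(p)
  expect_true(res$foetal_distress)
  expect_true(res$prolonged_labour)
  expect_false(res$obstructed_labour)
  expect_true(res$any_indication)
  expect_setequal(unique(res$evidence$condition),
                  c("foetal_distress", "prolonged_labour"))
})

test_that("classification is invariant to input row order", {
  set.seed(402)
  for (rep in 1:60) {
    obs <- random_partograph_obs("S1")
    p1 <- build_partograph(obs, case_id = "S1")
    shuffled <- obs[sample(nrow(obs)), , drop = FALSE]
    p2 <- build_partograph(shuffled, case_id = "S1")
    r1 <- suppressWarnings(classify_partograph(p1))
    r2 <- suppressWarnings(classify_partograph(p2))
    expect_identical(
      r1[c("foetal_distress", "prolonged_labour", "obstructed_labour",
           "preeclampsia", "any_indication")],
      r2[c("foetal_distress", "prolonged_labour", "obstructed_labour",
           "preeclampsia", "any_indication")]
    )
  }
})

test_that("adding an observation never clears a flag (monotonicity)", {
  flag_vec <- function(res) {
    unlist(res[c("foetal_distress", "prolonged_labour", "obstructed_labour",
                 "preeclampsia", "any_indication")])
  }
  set.seed(403)
  for (rep in 1:60) {
    obs <- random_partograph_obs("M1")
    before <- flag_vec(suppressWarnings(
      classify_partograph(build_partograph(obs, case_id = "M1"))))
    comps <- c("fhr", "descent", "contraction_freq", "sbp", "dbp", "pulse",
               "temperature", "urine_volume", "liquor", "moulding",
               "contraction_duration", "urine_albumin", "dilatation")
    comp <- sample(comps, 1)
    if (comp == "dilatation") {
      # keep the cervicograph physically valid: dilatation cannot regress,
      # so the added plot extends the trajectory at or past its latest value
      dil <- obs[obs$component == "dilatation", , drop = FALSE]
      t_new <- if (nrow(dil) > 0) max(dil$t_min) + 30L else 0L
      v_new <- if (nrow(dil) > 0) {
        min(10, max(dil$value_num) + sample(0:2, 1))
      } else {
        sample(0:10, 1)
      }
      add <- obs_row("M1", "dilatation", t_new, v_new)
    } else {
      taken <- obs$t_min[obs$component == comp]
      t_free <- setdiff(seq(0L, 990L, by = 30L), taken)
      add <- random_obs_row("M1", comp, t_free[sample.int(length(t_free), 1)])
    }
    after <- flag_vec(suppressWarnings(
      classify_partograph(build_partograph(rbind(obs, add), case_id = "M1"))))
    expect_true(all(after >= before))
  }
})
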