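# Charting-completeness audit: scores each partograph component against the
# WHO monitoring interval for that component, aggregates cohort proportions,
# and compares the abnormal-labour and no-indication groups with a pooled
# two-proportion z-test.

#' WHO monitoring-interval schedule
#'
#' Required plotting interval, in minutes, for each scored component:
#' half-hourly for foetal heart rate, uterine contractions and maternal
#' pulse; two-hourly for temperature and urine output/albumin; four-hourly
#' for liquor, moulding, cervical dilatation, descent of the head, and blood
#' pressure. The blood-pressure interval is configurable because the two
#' conventions in circulation disagree (four-hourly in monitoring protocols,
#' half-hourly on some partograph forms); the audit report records which one
#' was used.
#'
#' @param bp_interval_min Blood-pressure interval in minutes (default 240;
#'   set 30 for the half-hourly convention).
#' @return Named integer vector of intervals, class `interval_schedule`. The
#'   `bp` component scores blood-pressure *pairs* (an `sbp` and `dbp`
#'   observation sharing `t_min`).
#' @export
interval_schedule <- function(bp_interval_min = 240) {
  stopifnot(bp_interval_min > 0, bp_interval_min %% 30 == 0)
  s <- c(
    fhr = 30L, contraction_freq = 30L, pulse = 30L,
    temperature = 120L, urine_volume = 120L, urine_albumin = 120L,
    liquor = 240L, moulding = 240L, dilatation = 240L, descent = 240L,
    bp = as.integer(bp_interval_min)
  )
  class(s) <- "interval_schedule"
  s
}

.component_times <- function(p, component) {
  if (component == "bp") {
    tt <- intersect(.series(p, "sbp")$t_min, .series(p, "dbp")$t_min)
    sort(tt)
  } else {
    .series(p, component)$t_min
  }
}

#' Is a component appropriately recorded?
#'
#' A component counts as appropriately recorded when it has at least two
#' plottings at the required time interval. Under the default (`lenient`)
#' reading this means at least one consecutive pair of observations separated
#' by no more than the scheduled interval; under `strict`, every consecutive
#' gap must be within the interval. Labours shorter than the interval get no
#' exemption: fewer than two plottings is always incomplete (which may
#' understate completeness for fast labours).
#'
#' @param p A `partograph`.
#' @param component A component named in the schedule (use `"bp"` for
#'   blood-pressure pairs).
#' @param schedule An [interval_schedule()].
#' @param rule `"lenient"` (default) or `"strict"`.
#' @return Logical.
#' @export
component_complete <- function(p, component, schedule = interval_schedule(),
                               rule = c("lenient", "strict")) {
  rule <- match.arg(rule)
  if (!(component %in% names(schedule))) {
    stop(sprintf("component_complete: unknown component '%s'", component))
  }
  interval <- schedule[[component]]
  tt <- .component_times(p, component)
  if (length(tt) < 2) return(FALSE)
  gaps <- diff(sort(tt))
  if (rule == "lenient") any(gaps <= interval) else all(gaps <= interval)
}

#' Pooled two-proportion z-test
#'
#' Two-sided test of equality of two binomial proportions using the pooled
#' variance and no continuity correction:
#' \deqn{z = \frac{\hat p_1 - \hat p_2}{\sqrt{\hat p (1-\hat p)(1/n_1 + 1/n_2)}},
#'   \quad \hat p = \frac{x_1 + x_2}{n_1 + n_2}.}
#' The squared statistic equals the 1-df chi-square statistic (without
#' continuity correction) on the same 2x2 table. When the pooled proportion
#' is 0 or 1 the statistic is undefined and the result is marked degenerate
#' (reported as a dash in the audit tables).
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @param alpha Significance level for the `significant` field (default
#'   0.05).
#' @return An object of class `two_proportion_test` with fields `x1, n1, x2,
#'   n2, p1_hat, p2_hat, z, p_value, significant, degenerate`.
#' @examples
#' two_proportion_test(10, 20, 10, 20) # identical proportions: z = 0, p = 1
#' @export
two_proportion_test <- function(x1, n1, x2, n2, alpha = 0.05) {
  stopifnot(is_count(x1), is_count(n1), is_count(x2), is_count(n2),
            n1 > 0, n2 > 0)
  if (x1 > n1 || x2 > n2) stop("two_proportion_test: x must not exceed n")
  p1 <- x1 / n1
  p2 <- x2 / n2
  pooled <- (x1 + x2) / (n1 + n2)
  degenerate <- pooled == 0 || pooled == 1
  if (degenerate) {
    z <- NA_real_
    p_value <- NA_real_
    significant <- NA
  } else {
    se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
    z <- (p1 - p2) / se
    p_value <- 2 * stats::pnorm(-abs(z))
    significant <- p_value < alpha
  }
  out <- list(x1 = x1, n1 = n1, x2 = x2, n2 = n2,
              p1_hat = p1, p2_hat = p2, z = z, p_value = p_value,
              significant = significant, degenerate = degenerate)
  class(out) <- "two_proportion_test"
  out
}

#' @export
print.two_proportion_test <- function(x, ...) {
  cat(sprintf("Two-proportion z-test (pooled, no continuity correction)\n"))
  cat(sprintf("  group 1: %d/%d = %.4f   group 2: %d/%d = %.4f\n",
              x$x1, x$n1, x$p1_hat, x$x2, x$n2, x$p2_hat))
  if (x$degenerate) {
    cat("  degenerate (pooled proportion 0 or 1): no test statistic\n")
  } else {
    cat(sprintf("  z = %.4f, two-sided p = %.4f%s\n", x$z, x$p_value,
                if (isTRUE(x$significant)) " *" else ""))
  }
  invisible(x)
}

#' Cohort completeness table
#'
#' Scores every scheduled component for every partograph, then aggregates:
#' percent appropriately recorded overall, among partographs with an
#' indication of abnormal labour, and among those without, with the pooled
#' two-proportion z-test comparing the two groups. Percentages are rounded
#' half-up to one decimal.
#'
#' @param partographs List of `partograph` objects.
#' @param flags Classification data frame from [classify_cohort()] covering
#'   every partograph (matched by `case_id`).
#' @param schedule An [interval_schedule()].
#' @param rule Completeness rule, `"lenient"` or `"strict"` (see
#'   [component_complete()]).
#' @return Data frame with one row per component: `component`,
#'   `interval_min`, `pct_overall`, `pct_abnormal`, `pct_no_indication`,
#'   `x_abnormal`, `n_abnormal`, `x_no_indication`, `n_no_indication`, `z`,
#'   `p_value`, `degenerate`. Group sizes are in attributes `n_total`,
#'   `n_abnormal`, `n_no_indication`; the per-case verdict matrix in
#'   attribute `verdicts`.
#' @export
cohort_completeness <- function(partographs, flags,
                                schedule = interval_schedule(),
                                rule = c("lenient", "strict")) {
  rule <- match.arg(rule)
  comps <- names(unclass(schedule))
  ids <- vapply(partographs, function(p) p$case_id, character(1))
  if (!all(ids %in% flags$case_id)) {
    stop("cohort_completeness: every partograph needs a classification")
  }
  abnormal <- flags$any_indication[match(ids, flags$case_id)]
  verdicts <- matrix(FALSE, nrow = length(partographs), ncol = length(comps),
                     dimnames = list(ids, comps))
  for (i in seq_along(partographs)) {
    for (comp in comps) {
      verdicts[i, comp] <- component_complete(partographs[[i]], comp,
                                              schedule, rule)
    }
  }
  n_total <- length(partographs)
  n_abn <- sum(abnormal)
  n_no <- n_total - n_abn
  rows <- lapply(comps, function(comp) {
    v <- verdicts[, comp]
    x_abn <- sum(v[abnormal])
    x_no <- sum(v[!abnormal])
    test <- if (n_abn > 0 && n_no > 0) {
      two_proportion_test(x_abn, n_abn, x_no, n_no)
    } else {
      NULL
    }
    data.frame(
      component = comp,
      interval_min = schedule[[comp]],
      pct_overall = if (n_total > 0) round_half_up(100 * sum(v) / n_total) else NA_real_,
      pct_abnormal = if (n_abn > 0) round_half_up(100 * x_abn / n_abn) else NA_real_,
      pct_no_indication = if (n_no > 0) round_half_up(100 * x_no / n_no) else NA_real_,
      x_abnormal = x_abn, n_abnormal = n_abn,
      x_no_indication = x_no, n_no_indication = n_no,
      z = if (is.null(test)) NA_real_ else test$z,
      p_value = if (is.null(test)) NA_real_ else test$p_value,
      degenerate = if (is.null(test)) TRUE else test$degenerate,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_total") <- n_total
  attr(out, "n_abnormal") <- n_abn
  attr(out, "n_no_indication") <- n_no
  attr(out, "rule") <- rule
  attr(out, "verdicts") <- verdicts
  out
}
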