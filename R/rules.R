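# Rule-based classification of a partograph against four abnormal-labour
# definitions used for referral decisions at first-level facilities:
#
#   foetal distress   - FHR < 120 or > 160 bpm on at least two observations,
#                       or meconium-stained liquor;
#   prolonged labour  - dilatation plotted right of the alert line or
#                       reaching the action line;
#   obstructed labour - moderate/severe uterine contractions together with
#                       severe (+++) moulding or a descent plateau;
#   pre-eclampsia     - SBP > 140 or DBP > 90 mmHg together with albuminuria.
#
# Every true flag carries the triggering observations as evidence. The
# classifier is deterministic, independent of input row order, and monotone:
# adding an observation can only flip a flag false -> true.

#' Configuration of the abnormal-labour rules
#'
#' Thresholds and interpretation switches for the four detectors. Defaults
#' follow the strict printed wording of the definitions: FHR boundaries 120
#' and 160 bpm are *excluded* ("less than" / "more than"), the two violating
#' FHR observations need not be consecutive, BP thresholds are strict, a
#' single qualifying BP pair suffices, and trace albuminuria does not count
#' as "presence of albumin".
#'
#' @param fhr_low,fhr_high FHR bounds in bpm; values strictly outside
#'   `(fhr_low, fhr_high)` are violations.
#' @param fhr_min_violations Minimum number of violating FHR observations
#'   (default 2, "at least two observations").
#' @param fhr_require_consecutive If `TRUE`, the violating observations must
#'   be consecutive FHR plottings (stricter reading; default `FALSE`).
#' @param sbp_threshold,dbp_threshold BP thresholds in mmHg (strict `>`).
#' @param contraction_moderate_levels Contraction-duration codes counted as
#'   moderate or severe (WHO partograph shading: 20--40 s and > 40 s).
#' @param descent_plateau_min_obs Minimum number of consecutive descent
#'   observations with no decrease in fifths palpable that constitutes a
#'   plateau (default 2).
#' @param include_trace_albumin If `TRUE`, `trace` counts as albuminuria.
#' @return An object of class `rule_config`.
#' @export
rule_config <- function(fhr_low = 120, fhr_high = 160,
                        fhr_min_violations = 2L,
                        fhr_require_consecutive = FALSE,
                        sbp_threshold = 140, dbp_threshold = 90,
                        contraction_moderate_levels = c("s20to40", "gt40s"),
                        descent_plateau_min_obs = 2L,
                        include_trace_albumin = FALSE) {
  stopifnot(
    fhr_low > 0, fhr_high > fhr_low, fhr_min_violations >= 1,
    sbp_threshold > 0, dbp_threshold > 0, descent_plateau_min_obs >= 2,
    all(contraction_moderate_levels %in% .coded_domains$contraction_duration),
    is.logical(fhr_require_consecutive), is.logical(include_trace_albumin)
  )
  cfg <- list(
    fhr_low = fhr_low, fhr_high = fhr_high,
    fhr_min_violations = as.integer(fhr_min_violations),
    fhr_require_consecutive = fhr_require_consecutive,
    sbp_threshold = sbp_threshold, dbp_threshold = dbp_threshold,
    contraction_moderate_levels = contraction_moderate_levels,
    descent_plateau_min_obs = as.integer(descent_plateau_min_obs),
    include_trace_albumin = include_trace_albumin
  )
  class(cfg) <- "rule_config"
  cfg
}

.evidence <- function(condition, component, t_min, value) {
  n <- length(t_min)
  data.frame(
    condition = rep_len(as.character(condition), n),
    component = rep_len(as.character(component), n),
    t_min = as.integer(t_min),
    value = as.character(value),
    stringsAsFactors = FALSE
  )
}

.empty_evidence <- function() .evidence(character(), character(), integer(), character())

.series <- function(p, component) {
  s <- p$series[[component]]
  if (is.null(s)) data.frame(t_min = integer(), value = numeric()) else s
}

.max_run <- function(x) {
  # longest run of TRUE
  if (length(x) == 0) return(0L)
  r <- rle(x)
  hits <- r$lengths[r$values]
  if (length(hits) == 0) 0L else max(hits)
}

#' Detect foetal distress
#'
#' Flags a partograph when the foetal heart rate is below `fhr_low` or above
#' `fhr_high` bpm on at least `fhr_min_violations` observations (boundary
#' values are not violations; violations in opposite directions both count),
#' or when any liquor observation is meconium-stained (`M`).
#'
#' @param p A [build_partograph()] object.
#' @param cfg A [rule_config()].
#' @return `list(flag = logical, evidence = data.frame)`.
#' @rdname detectors
#' @export
detect_foetal_distress <- function(p, cfg = rule_config()) {
  fhr <- .series(p, "fhr")
  viol <- fhr$value < cfg$fhr_low | fhr$value > cfg$fhr_high
  n_viol <- if (cfg$fhr_require_consecutive) .max_run(viol) else sum(viol)
  fhr_hit <- n_viol >= cfg$fhr_min_violations
  liquor <- .series(p, "liquor")
  mec <- liquor$value == "M"
  ev <- .empty_evidence()
  if (fhr_hit) {
    ev <- rbind(ev, .evidence("foetal_distress", "fhr",
                              fhr$t_min[viol], fhr$value[viol]))
  }
  if (any(mec)) {
    ev <- rbind(ev, .evidence("foetal_distress", "liquor",
                              liquor$t_min[mec], liquor$value[mec]))
  }
  list(flag = fhr_hit || any(mec), evidence = ev)
}

#' Detect prolonged labour
#'
#' Flags a partograph when any dilatation observation lies strictly right of
#' the alert line or reaches (inclusively) the action line. When no
#' dilatation >= 4 cm was plotted the line geometry is undefined and the flag
#' is `FALSE`; if dilatation was plotted but never reached 4 cm a warning is
#' issued. Observations below the anchor dilatation (charted regression,
#' which is anatomically impossible) are ignored by the line tests and
#' returned in the `ignored` element.
#'
#' @rdname detectors
#' @export
detect_prolonged_labour <- function(p, cfg = rule_config()) {
  dil <- .series(p, "dilatation")
  if (is.null(p$anchor)) {
    if (nrow(dil) > 0) {
      warning(sprintf(
        "case %s: dilatation plotted but never >= 4 cm; alert line undefined",
        p$case_id), call. = FALSE)
    }
    return(list(flag = FALSE, evidence = .empty_evidence(),
                ignored = .empty_evidence()))
  }
  g <- alert_geometry(p)
  regress <- dil$value < g$d0_cm
  test <- dil[!regress, , drop = FALSE]
  hit <- is_right_of_alert(g, test$t_min, test$value) |
    reaches_action(g, test$t_min, test$value)
  ev <- if (any(hit)) {
    .evidence("prolonged_labour", "dilatation", test$t_min[hit], test$value[hit])
  } else {
    .empty_evidence()
  }
  list(flag = any(hit), evidence = ev,
       ignored = .evidence("prolonged_labour", "dilatation",
                           dil$t_min[regress], dil$value[regress]))
}

.descent_plateau <- function(descent, min_obs) {
  # indices of observations in some run of >= min_obs consecutive descent
  # observations with non-decreasing fifths palpable (head not descending)
  n <- nrow(descent)
  if (n < min_obs) return(integer())
  nondec <- diff(descent$value) >= 0
  r <- rle(nondec)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  idx <- integer()
  for (k in seq_along(r$lengths)) {
    if (r$values[k] && r$lengths[k] >= min_obs - 1) {
      idx <- c(idx, starts[k]:(ends[k] + 1)) # steps -> observations
    }
  }
  sort(unique(idx))
}

#' Detect obstructed labour
#'
#' Flags a partograph when moderate or severe uterine contractions (duration
#' 20--40 s or > 40 s) are charted *and* either severe (`+++`) moulding of
#' the foetal skull is present or the descent of the foetal head is at a
#' plateau (at least `descent_plateau_min_obs` consecutive descent
#' observations with no decrease in fifths palpable).
#'
#' @rdname detectors
#' @export
detect_obstructed_labour <- function(p, cfg = rule_config()) {
  contr <- .series(p, "contraction_duration")
  mod <- contr$value %in% cfg$contraction_moderate_levels
  if (!any(mod)) return(list(flag = FALSE, evidence = .empty_evidence()))
  moulding <- .series(p, "moulding")
  severe <- moulding$value == "+++"
  descent <- .series(p, "descent")
  plateau_idx <- .descent_plateau(descent, cfg$descent_plateau_min_obs)
  flag <- any(severe) || length(plateau_idx) > 0
  ev <- .empty_evidence()
  if (flag) {
    ev <- rbind(ev, .evidence("obstructed_labour", "contraction_duration",
                              contr$t_min[mod], contr$value[mod]))
    if (any(severe)) {
      ev <- rbind(ev, .evidence("obstructed_labour", "moulding",
                                moulding$t_min[severe], moulding$value[severe]))
    }
    if (length(plateau_idx) > 0) {
      ev <- rbind(ev, .evidence("obstructed_labour", "descent",
                                descent$t_min[plateau_idx],
                                descent$value[plateau_idx]))
    }
  }
  list(flag = flag, evidence = ev)
}

#' Detect pre-eclampsia
#'
#' Flags a partograph when some blood-pressure pair (an `sbp` and `dbp`
#' observation sharing `t_min`) has SBP strictly above `sbp_threshold` or DBP
#' strictly above `dbp_threshold`, *and* albumin is present in urine
#' (`plus1`--`plus3`; `trace` only if `include_trace_albumin`).
#'
#' @rdname detectors
#' @export
detect_preeclampsia <- function(p, cfg = rule_config()) {
  sbp <- .series(p, "sbp")
  dbp <- .series(p, "dbp")
  tt <- intersect(sbp$t_min, dbp$t_min)
  ev <- .empty_evidence()
  bp_hit <- FALSE
  if (length(tt) > 0) {
    s <- sbp$value[match(tt, sbp$t_min)]
    d <- dbp$value[match(tt, dbp$t_min)]
    hit <- s > cfg$sbp_threshold | d > cfg$dbp_threshold
    bp_hit <- any(hit)
    if (bp_hit) {
      ev <- rbind(ev,
        .evidence("preeclampsia", "sbp", tt[hit], s[hit]),
        .evidence("preeclampsia", "dbp", tt[hit], d[hit]))
    }
  }
  alb_codes <- c("plus1", "plus2", "plus3",
                 if (cfg$include_trace_albumin) "trace")
  alb <- .series(p, "urine_albumin")
  alb_hit <- alb$value %in% alb_codes
  if (bp_hit && any(alb_hit)) {
    ev <- rbind(ev, .evidence("preeclampsia", "urine_albumin",
                              alb$t_min[alb_hit], alb$value[alb_hit]))
    list(flag = TRUE, evidence = ev)
  } else {
    list(flag = FALSE, evidence = .empty_evidence())
  }
}

#' Classify a partograph against the abnormal-labour rules
#'
#' Runs all four detectors and combines them: a partograph carries an
#' indication of abnormal labour if *any* of the four conditions is flagged.
#' The result is deterministic and independent of input row order, and every
#' true flag is backed by at least one evidence observation.
#'
#' @param p A [build_partograph()] object.
#' @param cfg A [rule_config()].
#' @return An object of class `abnormality_result`: `case_id`, the four
#'   logical flags, `any_indication`, and an `evidence` data frame
#'   (`condition`, `component`, `t_min`, `value`).
#' @export
classify_partograph <- function(p, cfg = rule_config()) {
  fd <- detect_foetal_distress(p, cfg)
  pl <- detect_prolonged_labour(p, cfg)
  ob <- detect_obstructed_labour(p, cfg)
  pe <- detect_preeclampsia(p, cfg)
  res <- list(
    case_id = p$case_id,
    foetal_distress = fd$flag,
    prolonged_labour = pl$flag,
    obstructed_labour = ob$flag,
    preeclampsia = pe$flag,
    any_indication = fd$flag || pl$flag || ob$flag || pe$flag,
    evidence = rbind(fd$evidence, pl$evidence, ob$evidence, pe$evidence)
  )
  class(res) <- "abnormality_result"
  res
}

#' @export
print.abnormality_result <- function(x, ...) {
  cat(sprintf("Abnormality screen for case %s\n", x$case_id))
  for (cond in c("foetal_distress", "prolonged_labour",
                 "obstructed_labour", "preeclampsia")) {
    cat(sprintf("  %-18s %s\n", cond, if (x[[cond]]) "FLAGGED" else "-"))
  }
  cat(sprintf("  any indication:    %s (%d evidence observation(s))\n",
              x$any_indication, nrow(x$evidence)))
  invisible(x)
}

#' Classify a cohort of partographs
#'
#' Applies [classify_partograph()] to each partograph. Warnings from cases
#' whose dilatation never reached 4 cm are tallied (not repeated per case)
#' and reported once.
#'
#' @param partographs List of `partograph` objects.
#' @param cfg A [rule_config()].
#' @return Data frame with one row per partograph (`case_id`, four flags,
#'   `any_indication`); the combined evidence table is in the `evidence`
#'   attribute, the no-anchor tally in attribute `n_no_anchor`.
#' @export
classify_cohort <- function(partographs, cfg = rule_config()) {
  n_no_anchor <- 0L
  rows <- vector("list", length(partographs))
  evidence <- vector("list", length(partographs))
  for (i in seq_along(partographs)) {
    res <- withCallingHandlers(
      classify_partograph(partographs[[i]], cfg),
      warning = function(w) {
        if (grepl("alert line undefined", conditionMessage(w))) {
          n_no_anchor <<- n_no_anchor + 1L
          invokeRestart("muffleWarning")
        }
      }
    )
    rows[[i]] <- data.frame(
      case_id = res$case_id,
      foetal_distress = res$foetal_distress,
      prolonged_labour = res$prolonged_labour,
      obstructed_labour = res$obstructed_labour,
      preeclampsia = res$preeclampsia,
      any_indication = res$any_indication,
      stringsAsFactors = FALSE
    )
    if (nrow(res$evidence) > 0) {
      evidence[[i]] <- cbind(case_id = res$case_id, res$evidence)
    }
  }
  flags <- do.call(rbind, rows)
  if (is.null(flags)) {
    flags <- data.frame(
      case_id = character(), foetal_distress = logical(),
      prolonged_labour = logical(), obstructed_labour = logical(),
      preeclampsia = logical(), any_indication = logical(),
      stringsAsFactors = FALSE
    )
  }
  rownames(flags) <- NULL
  attr(flags, "evidence") <- do.call(rbind, evidence[!vapply(evidence, is.null, TRUE)])
  attr(flags, "n_no_anchor") <- n_no_anchor
  flags
}
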