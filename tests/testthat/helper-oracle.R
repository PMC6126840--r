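# Independent brute-force oracle for the abnormal-labour rules: a literal,
# per-observation scan of the four clause definitions, written against the
# raw long observation table (never against the package's partograph or
# geometry code paths).

oracle_classify <- function(obs) {
  comp <- function(name) {
    s <- obs[obs$component == name, , drop = FALSE]
    s[order(s$t_min), , drop = FALSE]
  }

  # foetal distress: FHR < 120 or > 160 on at least two observations, or
  # meconium-stained liquor
  fhr <- comp("fhr")$value_num
  n_bad <- 0
  for (v in fhr) if (v < 120 || v > 160) n_bad <- n_bad + 1
  meconium <- FALSE
  for (v in comp("liquor")$value_code) if (v == "M") meconium <- TRUE
  distress <- (n_bad >= 2) || meconium

  # prolonged labour: dilatation right of the alert line (strict) or at/past
  # the action line (inclusive); line from the first plot >= 4 cm, 1 cm/h
  dil <- comp("dilatation")
  prolonged <- FALSE
  first_active <- which(dil$value_num >= 4)
  if (length(first_active) > 0) {
    t0 <- dil$t_min[first_active[1]]
    d0 <- dil$value_num[first_active[1]]
    for (j in seq_len(nrow(dil))) {
      d <- dil$value_num[j]
      if (d < d0) next # charted regression: outside the line's domain
      line_t <- t0 + (d - d0) * 60
      if (dil$t_min[j] > line_t) prolonged <- TRUE
      if (dil$t_min[j] >= line_t + 240) prolonged <- TRUE
    }
  }

  # obstructed labour: moderate/severe contraction AND (+++ moulding OR a
  # descent plateau: two consecutive descent plots with no decrease)
  moderate <- FALSE
  for (v in comp("contraction_duration")$value_code) {
    if (v %in% c("s20to40", "gt40s")) moderate <- TRUE
  }
  severe_moulding <- FALSE
  for (v in comp("moulding")$value_code) if (v == "+++") severe_moulding <- TRUE
  des <- comp("descent")$value_num
  plateau <- FALSE
  if (length(des) >= 2) {
    for (j in seq_len(length(des) - 1)) if (des[j + 1] >= des[j]) plateau <- TRUE
  }
  obstructed <- moderate && (severe_moulding || plateau)

  # pre-eclampsia: some sbp/dbp pair (same t_min) with SBP > 140 or
  # DBP > 90, and albumin present in urine (trace excluded)
  sbp <- comp("sbp")
  dbp <- comp("dbp")
  bp_hit <- FALSE
  for (j in seq_len(nrow(sbp))) {
    k <- which(dbp$t_min == sbp$t_min[j])
    if (length(k) == 1) {
      if (sbp$value_num[j] > 140 || dbp$value_num[k] > 90) bp_hit <- TRUE
    }
  }
  albumin <- FALSE
  for (v in comp("urine_albumin")$value_code) {
    if (v %in% c("plus1", "plus2", "plus3")) albumin <- TRUE
  }
  pre <- bp_hit && albumin

  c(foetal_distress = distress, prolonged_labour = prolonged,
    obstructed_labour = obstructed, preeclampsia = pre,
    any_indication = distress || prolonged || obstructed || pre)
}
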