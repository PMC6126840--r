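# Random-case generators for property-style tests. All draws happen under
# the caller's seed; no (component, t_min) pair is duplicated within a case,
# matching real partographs (one plot per grid cell).

.gen_numeric_value <- function(component) {
  switch(component,
    fhr = sample(95:185, 1),
    dilatation = sample(0:10, 1),
    descent = sample(0:5, 1),
    contraction_freq = sample(1:6, 1),
    sbp = sample(95:185, 1),
    dbp = sample(55:115, 1),
    pulse = sample(55:130, 1),
    temperature = round(runif(1, 36, 39), 1),
    urine_volume = sample(50:400, 1)
  )
}

.gen_coded_value <- function(component) {
  domains <- list(
    liquor = c("I", "C", "M", "A", "B"),
    moulding = c("0", "+", "++", "+++"),
    contraction_duration = c("lt20s", "s20to40", "gt40s"),
    urine_albumin = c("neg", "trace", "plus1", "plus2", "plus3")
  )
  sample(domains[[component]], 1)
}

random_obs_row <- function(case_id, component, t_min) {
  numeric_comps <- c("fhr", "dilatation", "descent", "contraction_freq",
                     "sbp", "dbp", "pulse", "temperature", "urine_volume")
  if (component %in% numeric_comps) {
    data.frame(case_id = case_id, component = component,
               t_min = as.integer(t_min),
               value_num = as.numeric(.gen_numeric_value(component)),
               value_code = NA_character_, stringsAsFactors = FALSE)
  } else {
    data.frame(case_id = case_id, component = component,
               t_min = as.integer(t_min), value_num = NA_real_,
               value_code = .gen_coded_value(component),
               stringsAsFactors = FALSE)
  }
}

# a random small partograph: up to max_obs observations on a 30-min grid,
# components drawn with replacement, duplicate (component, t) slots excluded
random_partograph_obs <- function(case_id = "R1", max_obs = 20) {
  comps <- c("fhr", "dilatation", "descent", "contraction_freq", "sbp", "dbp",
             "pulse", "temperature", "urine_volume", "liquor", "moulding",
             "contraction_duration", "urine_albumin")
  times <- seq(0L, 720L, by = 30L)
  grid <- expand.grid(component = comps, t_min = times,
                      stringsAsFactors = FALSE)
  n <- sample(0:max_obs, 1)
  pick <- grid[sample(nrow(grid), n), , drop = FALSE]
  rows <- lapply(seq_len(nrow(pick)), function(j) {
    random_obs_row(case_id, pick$component[j], pick$t_min[j])
  })
  out <- do.call(rbind, c(rows, list(random_obs_row(case_id, "fhr", 990L)[0, ])))
  out[order(out$component, out$t_min), , drop = FALSE]
}
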