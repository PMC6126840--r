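# Partograph assembly and alert/action-line geometry.
#
# The WHO modified partograph charts the active phase of labour only. The
# alert line is anchored at the first plotted cervical dilatation >= 4 cm and
# rises at 1 cm per hour; the action line runs parallel, 4 hours (240 min) to
# its right. All line arithmetic is in integer minutes — no floating point.

#' Assemble a partograph from observation rows
#'
#' Groups the long observation rows of a single case into per-component
#' time-ordered series and sets the active-phase anchor: the first dilatation
#' observation with value >= 4 cm, the point from which the alert line is
#' drawn. An empty input yields an empty partograph with no anchor.
#'
#' @param rows Data frame of observation rows for one case (columns as
#'   returned by [read_observations()]). All rows must share one `case_id`.
#' @param case_id Case identifier; required only when `rows` is empty.
#' @return An object of class `partograph`: a list with `case_id`, `series`
#'   (one data frame of `t_min`/`value` per component, sorted by `t_min`,
#'   ties in input order), and `anchor` (`list(t0_min, d0_cm)` or `NULL`).
#' @examples
#' obs <- data.frame(
#'   case_id = "A", component = "dilatation", t_min = c(0L, 120L),
#'   value_num = c(3, 4), value_code = NA_character_
#' )
#' build_partograph(obs)$anchor # anchored at (120, 4)
#' @export
build_partograph <- function(rows, case_id = NULL) {
  if (nrow(rows) == 0) {
    if (is.null(case_id)) stop("empty observation set: case_id must be given")
    p <- list(case_id = case_id, series = list(), anchor = NULL)
    class(p) <- "partograph"
    return(p)
  }
  ids <- unique(rows$case_id)
  if (length(ids) != 1) {
    stop(sprintf("build_partograph: rows span multiple case_ids: %s",
                 paste(ids, collapse = ", ")))
  }
  series <- lapply(split(seq_len(nrow(rows)), rows$component), function(idx) {
    sub <- rows[idx, , drop = FALSE]
    ord <- order(sub$t_min) # stable: ties keep input order
    numeric_comp <- sub$component[1] %in% names(.numeric_components)
    data.frame(
      t_min = as.integer(sub$t_min[ord]),
      value = if (numeric_comp) sub$value_num[ord] else sub$value_code[ord],
      stringsAsFactors = FALSE
    )
  })
  anchor <- NULL
  dil <- series[["dilatation"]]
  if (!is.null(dil)) {
    hit <- which(dil$value >= 4)
    if (length(hit) > 0) {
      anchor <- list(t0_min = dil$t_min[hit[1]], d0_cm = dil$value[hit[1]])
    }
  }
  p <- list(case_id = ids, series = series, anchor = anchor)
  class(p) <- "partograph"
  p
}

#' @export
print.partograph <- function(x, ...) {
  cat(sprintf("Partograph for case %s\n", x$case_id))
  if (is.null(x$anchor)) {
    cat("  active-phase anchor: absent (no dilatation >= 4 cm plotted)\n")
  } else {
    cat(sprintf("  active-phase anchor: %d cm at t = %d min\n",
                as.integer(x$anchor$d0_cm), as.integer(x$anchor$t0_min)))
  }
  for (comp in names(x$series)) {
    cat(sprintf("  %-20s %d observation(s)\n", comp, nrow(x$series[[comp]])))
  }
  invisible(x)
}

#' Alert-line geometry for a partograph
#'
#' The alert line passes through the active-phase anchor `(t0_min, d0_cm)`
#' with a fixed slope of 1 cm per 60 min; the action line is offset 240 min
#' (4 h) to the right. The geometry is a pure value: no observation mutates
#' it.
#'
#' @param partograph A `partograph` with a non-absent anchor, or `NULL` if
#'   `t0_min`/`d0_cm` are given directly.
#' @param t0_min,d0_cm Anchor coordinates, used when `partograph` is `NULL`.
#' @return An object of class `alert_geometry`.
#' @export
alert_geometry <- function(partograph = NULL, t0_min = NULL, d0_cm = NULL) {
  if (!is.null(partograph)) {
    if (is.null(partograph$anchor)) {
      stop("alert_geometry: partograph has no active-phase anchor")
    }
    t0_min <- partograph$anchor$t0_min
    d0_cm <- partograph$anchor$d0_cm
  }
  stopifnot(is.numeric(t0_min), is.numeric(d0_cm), d0_cm >= 0, d0_cm <= 10)
  g <- list(t0_min = as.integer(t0_min), d0_cm = as.integer(d0_cm),
            slope_min_per_cm = 60L, action_offset_min = 240L)
  class(g) <- "alert_geometry"
  g
}

#' Alert- and action-line crossing times
#'
#' `alert_time(g, d)` is the minute at which the alert line reaches
#' dilatation `d`: `t0 + (d - d0) * 60`. `action_time()` adds the fixed
#' 240-min offset. Both are strictly increasing in `d` and defined only for
#' `d >= d0`.
#'
#' @param geometry An [alert_geometry()] object.
#' @param d Dilatation in cm, `d >= d0_cm`.
#' @return Time in integer minutes since admission.
#' @rdname alert_time
#' @export
alert_time <- function(geometry, d) {
  stopifnot(inherits(geometry, "alert_geometry"))
  if (any(d < geometry$d0_cm)) {
    stop(sprintf("alert_time: d < anchor dilatation (%d cm)", geometry$d0_cm))
  }
  geometry$t0_min + (as.integer(d) - geometry$d0_cm) * geometry$slope_min_per_cm
}

#' @rdname alert_time
#' @export
action_time <- function(geometry, d) {
  alert_time(geometry, d) + geometry$action_offset_min
}

#' Line tests for a plotted dilatation observation
#'
#' `is_right_of_alert()` is strict ("on right side" of the line excludes the
#' line itself): `t_min > alert_time(d)`. `reaches_action()` is inclusive
#' ("reach" includes the line): `t_min >= alert_time(d) + 240`. Reaching the
#' action line implies being right of the alert line.
#'
#' @param geometry An [alert_geometry()] object.
#' @param t_min Observation time in minutes since admission.
#' @param d Observed dilatation in cm, `d >= d0_cm`.
#' @return Logical.
#' @rdname line_tests
#' @export
is_right_of_alert <- function(geometry, t_min, d) {
  t_min > alert_time(geometry, d)
}

#' @rdname line_tests
#' @export
reaches_action <- function(geometry, t_min, d) {
  t_min >= action_time(geometry, d)
}

#' Plot a partograph's cervicograph panel
#'
#' Base-graphics rendering of the dilatation series against the alert and
#' action lines (when an anchor exists). Intended for quick inspection of
#' single cases, not publication figures.
#'
#' @param x A `partograph`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.partograph <- function(x, ...) {
  dil <- x$series[["dilatation"]]
  if (is.null(dil) || nrow(dil) == 0) {
    stop("plot.partograph: no dilatation observations to plot")
  }
  tmax <- max(dil$t_min, 720)
  graphics::plot(dil$t_min / 60, dil$value, type = "b", pch = 19,
                 xlim = c(0, tmax / 60), ylim = c(0, 10),
                 xlab = "Hours since admission", ylab = "Cervical dilatation (cm)",
                 main = sprintf("Case %s", x$case_id), ...)
  if (!is.null(x$anchor)) {
    g <- alert_geometry(x)
    dd <- seq(g$d0_cm, 10)
    graphics::lines(alert_time(g, dd) / 60, dd, lty = 2, col = "orange")
    graphics::lines(action_time(g, dd) / 60, dd, lty = 2, col = "red")
    graphics::legend("bottomright", legend = c("alert line", "action line"),
                     lty = 2, col = c("orange", "red"), bty = "n")
  }
  invisible(x)
}
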