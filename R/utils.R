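# Internal helpers shared across modules.

# Round half away from zero, the convention used by the register summaries
# (base round() is banker's rounding).
round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  out <- floor(abs(x) * s + 0.5) / s * sign(x)
  out[is.na(x)] <- NA_real_
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ISO-8601 timestamp parsing at minute resolution (UTC; registers carry no
# timezone information).
parse_timestamp <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(as.POSIXct(NA, tz = "UTC"), length(x))
  nonblank <- !is.na(x) & nzchar(x)
  if (any(nonblank)) {
    parsed <- as.POSIXct(x[nonblank],
      tryFormats = c(
        "%Y-%m-%dT%H:%M:%S", "%Y-%m-%dT%H:%M",
        "%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M", "%Y-%m-%d"
      ),
      tz = "UTC", optional = TRUE
    )
    out[nonblank] <- parsed
  }
  out
}

format_timestamp <- function(x) {
  out <- rep("", length(x))
  ok <- !is.na(x)
  out[ok] <- format(x[ok], "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  out
}

# Strict integer parse: "" / NA -> NA, non-integer text -> NaN marker so the
# caller can distinguish "missing" from "malformed".
parse_integer <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  nonblank <- !is.na(x) & nzchar(x)
  num <- suppressWarnings(as.numeric(x[nonblank]))
  bad <- is.na(num) | (num != floor(num))
  num[bad] <- NaN
  out[nonblank] <- num
  out
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x == floor(x)
}
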