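# Time-unit handling. All internal computations use seconds; configuration
# files and helpers accept explicit unit suffixes so that a "45.6" can never
# silently mean minutes in one place and hours in another.

.sec_per_unit <- c(
  us = 1e-6, ms = 1e-3, s = 1, min = 60, h = 3600, d = 86400
)

#' Parse a duration with an explicit unit suffix into seconds
#'
#' Accepts strings such as `"9.9 d"`, `"45.6 min"`, `"32 ms"`, `"3.72 us"`,
#' or a bare number (already seconds). Vectorised.
#'
#' @param x Character vector of `"<number> <unit>"` strings (units one of
#'   `us`, `ms`, `s`, `min`, `h`, `d`) or a numeric vector of seconds.
#' @return Numeric vector of durations in seconds.
#' @examples
#' parse_duration("9.9 d")
#' parse_duration(c("45.6 min", "32 ms"))
#' @export
parse_duration <- function(x) {
  if (is.numeric(x)) {
    return(as.numeric(x))
  }
  stopifnot(is.character(x))
  vapply(x, function(s) {
    s <- trimws(s)
    m <- regmatches(s, regexec("^([-+0-9.eE]+)\\s*([a-zA-Z]+)?$", s))[[1]]
    if (length(m) == 0 || m[2] == "") {
      abort(paste0("cannot parse duration: '", s, "'"), class = "alphadose3d_unit_error")
    }
    val <- as.numeric(m[2])
    unit <- m[3]
    if (is.na(unit) || unit == "") {
      return(val)
    }
    if (!unit %in% names(.sec_per_unit)) {
      abort(paste0("unknown time unit '", unit, "' in '", s, "'"),
            class = "alphadose3d_unit_error")
    }
    val * .sec_per_unit[[unit]]
  }, numeric(1), USE.NAMES = FALSE)
}

#' Convert seconds to another time unit
#'
#' @param seconds Numeric vector of durations in seconds.
#' @param unit One of `"us"`, `"ms"`, `"s"`, `"min"`, `"h"`, `"d"`.
#' @return Numeric vector in the requested unit.
#' @export
seconds_to <- function(seconds, unit = "h") {
  unit <- match.arg(unit, names(.sec_per_unit))
  seconds / .sec_per_unit[[unit]]
}

# trapezoidal integral helpers (internal)
.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

.cumtrapz <- function(x, y) c(0, cumsum(diff(x) * (head(y, -1) + tail(y, -1)) / 2))
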