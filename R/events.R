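#' Event series (beats or breaths)
#'
#' Sorted event times in seconds. Duplicate times are collapsed.
#'
#' @param times Numeric vector of event times in seconds (non-negative).
#' @param label Event kind, `"beat"` or `"breath"`.
#' @param source `"reference"` or `"detected"`.
#' @return An object of class `event_series`.
#' @export
event_series <- function(times, label = c("beat", "breath"),
                         source = c("detected", "reference")) {
  label <- match.arg(label)
  source <- match.arg(source)
  times <- as.numeric(times)
  if (any(!is.finite(times)) || any(times < 0))
    stop_invalid("event times must be finite and non-negative")
  if (is.unsorted(times)) times <- sort(times)
  times <- unique(times)
  structure(list(times = times, label = label, source = source),
            class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series> %d %s %s events", length(x$times), x$source,
              x$label))
  if (length(x$times))
    cat(sprintf(", t = [%.3f, %.3f] s", min(x$times), max(x$times)))
  cat("\n")
  invisible(x)
}

#' @export
length.event_series <- function(x) length(x$times)

#' Beat-wise modulation series
#'
#' A beat-anchored feature sequence (R-peak amplitude, R-R interval, or
#' Q-trough depth) used as one component of the ECG-derived respiration
#' composite.
#'
#' @param times Anchor times in seconds, strictly increasing.
#' @param values Feature values (finite).
#' @param kind One of `"r_amplitude"`, `"rr_interval"`, `"q_trough"`.
#' @return An object of class `modulation_series`.
#' @export
modulation_series <- function(times,
                              values,
                              kind = c("r_amplitude", "rr_interval",
                                       "q_trough")) {
  kind <- match.arg(kind)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop_invalid("'times' and 'values' must have equal length")
  if (length(times) && (is.unsorted(times, strictly = TRUE)))
    stop_invalid("'times' must be strictly increasing")
  if (!all(is.finite(values)))
    stop_invalid("'values' must be finite")
  structure(list(times = times, values = values, kind = kind),
            class = "modulation_series")
}

#' @export
print.modulation_series <- function(x, ...) {
  cat(sprintf("<modulation_series> %s, %d points\n", x$kind,
              length(x$times)))
  invisible(x)
}
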