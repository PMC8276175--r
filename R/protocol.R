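#' Exposure protocols: dose, dose-rate and fractionation
#'
#' A protocol is an ordered set of exposure segments.  A segment with
#' `duration > 0` delivers `dose` Gy at constant rate `dose / duration`;
#' a segment with `duration == 0` is an acute impulse.  Fractionation is
#' expressed naturally as impulses (or short segments) separated by gaps
#' during which the dose rate is zero.
#'
#' @param segments A data frame with columns `start` (h), `duration` (h)
#'   and `dose` (Gy).
#' @param particle Optional list tagging the radiation quality, e.g.
#'   `list(species = "proton", let = 10)` with LET in keV/um.  `NULL`
#'   means reference photons.
#' @return An object of class `dose_protocol` (a tibble with attributes).
#' @examples
#' acute_exposure(2)
#' fractionated_exposure(2, n_fractions = 5, interval = 24)
#' continuous_exposure(2, dose_rate = 0.05)
#' @export
dose_protocol <- function(segments, particle = NULL) {
  segments <- as_tibble(segments)
  req <- c("start", "duration", "dose")
  if (!all(req %in% names(segments))) {
    abort("`segments` needs columns start, duration, dose.")
  }
  segments <- segments[order(segments$start), req]
  if (nrow(segments) == 0) abort("a protocol needs at least one segment.")
  if (any(segments$start < 0) || any(segments$duration < 0) ||
      any(segments$dose < 0)) {
    abort("segment times, durations and doses must be non-negative.")
  }
  ends <- segments$start + segments$duration
  if (nrow(segments) > 1 &&
      any(segments$start[-1] < ends[-nrow(segments)] - 1e-12)) {
    abort("protocol segments must not overlap.")
  }
  structure(segments,
            class = c("dose_protocol", class(segments)),
            particle = particle,
            total_dose = sum(segments$dose))
}

#' @rdname dose_protocol
#' @param dose Total dose in Gy.
#' @param time Start time (h) of the acute impulse.
#' @export
acute_exposure <- function(dose, time = 0, particle = NULL) {
  dose_protocol(tibble(start = time, duration = 0, dose = dose),
                particle = particle)
}

#' @rdname dose_protocol
#' @param dose_per_fraction Dose per fraction in Gy.
#' @param n_fractions Number of acute fractions.
#' @param interval Time between fraction starts in h.
#' @export
fractionated_exposure <- function(dose_per_fraction, n_fractions, interval,
                                  particle = NULL) {
  stopifnot(n_fractions >= 1, interval > 0)
  dose_protocol(tibble(start = (seq_len(n_fractions) - 1) * interval,
                       duration = 0,
                       dose = dose_per_fraction),
                particle = particle)
}

#' @rdname dose_protocol
#' @param dose_rate Dose rate in Gy/h for a continuous exposure.
#' @export
continuous_exposure <- function(dose, dose_rate, time = 0, particle = NULL) {
  stopifnot(dose_rate > 0)
  dose_protocol(tibble(start = time, duration = dose / dose_rate,
                       dose = dose),
                particle = particle)
}

#' Total dose of a protocol
#' @param protocol A [dose_protocol()].
#' @return Total dose in Gy.
#' @export
total_dose <- function(protocol) {
  stopifnot(inherits(protocol, "dose_protocol"))
  attr(protocol, "total_dose")
}

#' Instantaneous dose rate of a protocol
#'
#' Impulse segments carry no finite dose rate and are excluded; they are
#' handled as discrete events by the solvers.
#'
#' @param protocol A [dose_protocol()].
#' @param t Times (h).
#' @return Dose rate in Gy/h at each `t`.
#' @export
dose_rate_at <- function(protocol, t) {
  stopifnot(inherits(protocol, "dose_protocol"))
  out <- numeric(length(t))
  seg <- protocol[protocol$duration > 0, , drop = FALSE]
  for (i in seq_len(nrow(seg))) {
    inside <- t >= seg$start[i] & t < seg$start[i] + seg$duration[i]
    out[inside] <- seg$dose[i] / seg$duration[i]
  }
  out
}

# End of the last segment (h); all induction is complete after this.
protocol_end <- function(protocol) {
  max(protocol$start + protocol$duration)
}

#' @export
print.dose_protocol <- function(x, ...) {
  cat(sprintf("<dose_protocol> total %.4g Gy, %d segment(s)",
              attr(x, "total_dose"), nrow(x)))
  p <- attr(x, "particle")
  if (!is.null(p)) cat(sprintf(" [%s, LET %g keV/um]",
                               p$species %||% "ion", p$let))
  cat("\n")
  NextMethod()
}
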