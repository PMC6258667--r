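#' Exogenous TGF-beta dose protocols
#'
#' A dose protocol is an ordered set of contiguous, non-overlapping time
#' segments, each with a constant exogenous TGF-beta dose (a.u.). The
#' integrator restarts at segment boundaries so dose discontinuities are
#' handled exactly.
#'
#' @param segments a data.frame with columns \code{start}, \code{end},
#'   \code{dose}; segments must tile \verb{[0, total_duration]} without gaps
#'   or overlap, and doses must be non-negative.
#' @return an object of class \code{dose_protocol}.
#' @seealso [protocol_constant()], [protocol_pulse()], [protocol_withdrawal()]
#' @export
dose_protocol <- function(segments) {
  stopifnot(is.data.frame(segments),
            all(c("start", "end", "dose") %in% names(segments)))
  segments <- segments[order(segments$start), , drop = FALSE]
  if (nrow(segments) == 0) stop("protocol needs at least one segment")
  if (any(segments$dose < 0)) stop("doses must be non-negative")
  if (any(segments$end < segments$start)) stop("segment end before start")
  if (abs(segments$start[1]) > 1e-12) stop("first segment must start at 0")
  if (nrow(segments) > 1) {
    gaps <- segments$start[-1] - segments$end[-nrow(segments)]
    if (any(abs(gaps) > 1e-9)) stop("segments must be contiguous")
  }
  structure(list(segments = segments,
                 total_duration = segments$end[nrow(segments)]),
            class = "dose_protocol")
}

#' @param dose constant exogenous dose (a.u.).
#' @param duration protocol length (time units).
#' @rdname dose_protocol
#' @export
protocol_constant <- function(dose, duration) {
  dose_protocol(data.frame(start = 0, end = duration, dose = dose))
}

#' @param pulse_duration duration of the initial dose pulse, after which the
#'   exogenous dose drops to zero.
#' @rdname dose_protocol
#' @export
protocol_pulse <- function(dose, pulse_duration, duration) {
  if (pulse_duration > duration)
    stop("pulse_duration must not exceed total duration")
  if (pulse_duration == duration) return(protocol_constant(dose, duration))
  if (pulse_duration == 0) return(protocol_constant(0, duration))
  dose_protocol(data.frame(start = c(0, pulse_duration),
                           end = c(pulse_duration, duration),
                           dose = c(dose, 0)))
}

#' @param pre_dose,pre_duration conditioning dose and its duration.
#' @param post_duration time simulated after withdrawal (dose 0).
#' @rdname dose_protocol
#' @export
protocol_withdrawal <- function(pre_dose, pre_duration, post_duration) {
  protocol_pulse(pre_dose, pre_duration, pre_duration + post_duration)
}

#' Dose at a given time
#'
#' @param protocol a \code{dose_protocol}.
#' @param t time (vectorised); times outside all segments give dose 0.
#' @return numeric vector of doses.
#' @export
dose_at <- function(protocol, t) {
  stopifnot(inherits(protocol, "dose_protocol"))
  seg <- protocol$segments
  out <- numeric(length(t))
  for (i in seq_len(nrow(seg))) {
    # half-open [start, end); final segment closed at the right edge
    sel <- t >= seg$start[i] & (t < seg$end[i] |
             (i == nrow(seg) & t <= seg$end[i]))
    out[sel] <- seg$dose[i]
  }
  out
}

#' @export
print.dose_protocol <- function(x, ...) {
  cat("<dose_protocol> duration", x$total_duration, "\n")
  print(x$segments, row.names = FALSE)
  invisible(x)
}
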