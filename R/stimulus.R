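#' Stimulation protocol container
#'
#' A stimulation protocol is a time-indexed external-current schedule.
#' It can hold rectangular pulses (per stimulator: onset, duration,
#' amplitude) and/or continuous current samples (one column per
#' stimulator at a fixed sampling rate). Pulse entries address a
#' \code{stimulator} id, resolved to a neuron through the topology's
#' stimulator bindings at simulation time, or a \code{neuron} id
#' directly (used by the supervised "teacher" electrode).
#'
#' @param pulses data frame with columns \code{stimulator} (or
#'   \code{neuron}), \code{onset}, \code{duration}, \code{amplitude}
#'   (ms, ms, current units).
#' @param continuous \code{NULL}, or a list with \code{samples} (matrix,
#'   one column per stimulator), \code{fs} (sampling rate, Hz) and
#'   \code{stimulators} (column-to-stimulator ids).
#' @param duration protocol duration in ms.
#' @return An object of class \code{"stim_protocol"}.
#' @export
stim_protocol <- function(pulses = NULL, continuous = NULL, duration) {
  if (is.null(pulses))
    pulses <- data.frame(stimulator = integer(), onset = numeric(),
                         duration = numeric(), amplitude = numeric())
  if (!"neuron" %in% names(pulses))
    pulses$neuron <- rep(NA_integer_, nrow(pulses))
  if (!"stimulator" %in% names(pulses))
    pulses$stimulator <- rep(NA_integer_, nrow(pulses))
  p <- structure(list(pulses = pulses, continuous = continuous,
                      duration = duration), class = "stim_protocol")
  validate_protocol(p)
  p
}

validate_protocol <- function(p) {
  pu <- p$pulses
  if (!all(c("onset", "duration", "amplitude") %in% names(pu)))
    stop("pulse table needs onset, duration, amplitude", call. = FALSE)
  if (nrow(pu)) {
    if (any(!is.finite(pu$onset)) || any(pu$onset < 0) ||
        any(pu$onset > p$duration))
      stop("pulse onsets must lie in [0, duration]", call. = FALSE)
    if (any(!is.finite(pu$amplitude)))
      stop("pulse amplitudes must be finite", call. = FALSE)
    if (any(is.na(pu$stimulator) & is.na(pu$neuron)))
      stop("every pulse needs a stimulator or neuron id", call. = FALSE)
  }
  co <- p$continuous
  if (!is.null(co)) {
    stopifnot(is.matrix(co$samples), is.numeric(co$fs), co$fs > 0,
              length(co$stimulators) == ncol(co$samples))
    if (any(!is.finite(co$samples)))
      stop("continuous current samples must be finite", call. = FALSE)
  }
  if (!is.numeric(p$duration) || p$duration < 0)
    stop("duration must be >= 0", call. = FALSE)
  invisible(p)
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("Stimulation protocol: %.0f ms, %d pulses", x$duration,
              nrow(x$pulses)))
  if (!is.null(x$continuous))
    cat(sprintf(", continuous current on %d channels @ %g Hz",
                ncol(x$continuous$samples), x$continuous$fs))
  cat("\n")
  invisible(x)
}

#' Merge stimulation protocols
#'
#' @param ... \code{stim_protocol} objects; at most one may carry a
#'   continuous block.
#' @return A single protocol spanning the longest duration.
#' @export
merge_protocols <- function(...) {
  ps <- list(...)
  stopifnot(all(vapply(ps, inherits, TRUE, "stim_protocol")))
  cont <- Filter(Negate(is.null), lapply(ps, `[[`, "continuous"))
  if (length(cont) > 1)
    stop("cannot merge more than one continuous protocol", call. = FALSE)
  stim_protocol(
    pulses = do.call(rbind, lapply(ps, `[[`, "pulses")),
    continuous = if (length(cont)) cont[[1]] else NULL,
    duration = max(vapply(ps, `[[`, 0, "duration")))
}

default_pulse <- function() list(duration = 0.5, amplitude = 180)

#' Repeating temporal pulse pattern
#'
#' Builds the temporal-coding stimulus: within each repetition cycle,
#' stimulator \code{j} fires one suprathreshold pulse at offset
#' \eqn{(j - 1)\,\Delta t}, so the \code{n} stimulators emit a fixed
#' spike sequence with inter-pulse interval \code{delta_t}; the whole
#' sequence repeats at \code{repetition_hz}.
#'
#' @param delta_t inter-pulse interval in ms (> 0).
#' @param n number of stimulators (default 10).
#' @param repetition_hz repetition rate of the sequence (default 1 Hz).
#' @param duration total protocol duration in ms.
#' @param pulse_dur,amplitude rectangular pulse shape. The defaults
#'   (0.5 ms, 180 current units) are strongly suprathreshold so a
#'   driven neuron follows its stimulator exactly one-to-one — one
#'   spike per pulse, verified against a fine-step reference — at every
#'   commanded rate up to 50 Hz and through refractory-floor gaps.
#' @return A \code{stim_protocol}.
#' @examples
#' p <- temporal_pattern(5, duration = 3000)
#' head(p$pulses)
#' @export
temporal_pattern <- function(delta_t, n = 10, repetition_hz = 1, duration,
                             pulse_dur = default_pulse()$duration,
                             amplitude = default_pulse()$amplitude) {
  if (!is.numeric(delta_t) || delta_t <= 0)
    stop("delta_t must be > 0", call. = FALSE)
  period <- 1000 / repetition_hz
  if ((n - 1) * delta_t + pulse_dur > period)
    stop("temporal pattern longer than the repetition period",
         call. = FALSE)
  starts <- seq(0, duration - 1e-9, by = period)
  starts <- starts[starts + (n - 1) * delta_t < duration]
  pulses <- expand.grid(offset = (seq_len(n) - 1) * delta_t,
                        start = starts)
  pulses <- data.frame(
    stimulator = rep(seq_len(n), times = length(starts)),
    onset = pulses$start + pulses$offset,
    duration = pulse_dur, amplitude = amplitude)
  p <- stim_protocol(pulses, duration = duration)
  attr(p, "n") <- n
  attr(p, "delta_t") <- delta_t
  p
}

#' Familiar / unknown split of a temporal pattern
#'
#' Splits a temporal pattern into its first and second halves by
#' stimulator rank: the familiar test pattern drives stimulators
#' \code{1..n/2} at their original offsets, the unknown pattern drives
#' stimulators \code{n/2+1..n} at theirs. Pulse timing within each half
#' is preserved.
#'
#' @param pattern a protocol built by [temporal_pattern()] with even
#'   \code{n}.
#' @return list with elements \code{familiar} and \code{unknown}.
#' @export
familiar_unknown_split <- function(pattern) {
  n <- attr(pattern, "n")
  if (is.null(n)) n <- max(pattern$pulses$stimulator)
  if (n %% 2 != 0)
    stop("familiar/unknown split needs an even stimulator count",
         call. = FALSE)
  lo <- pattern$pulses$stimulator <= n / 2
  fam <- stim_protocol(pattern$pulses[lo, , drop = FALSE],
                       duration = pattern$duration)
  unk <- stim_protocol(pattern$pulses[!lo, , drop = FALSE],
                       duration = pattern$duration)
  list(familiar = fam, unknown = unk)
}

#' Stochastic rate pattern
#'
#' One pulse train per stimulator with the requested mean rates. Trains
#' are Poisson (independent exponential intervals) with a refractory
#' floor between pulses; the exponential part is rescaled so the mean
#' inter-pulse interval stays \code{1/rate}. Periodic trains are
#' available as an alternative.
#'
#' @param rates_hz mean rates, one per stimulator; the default is the
#'   10-step ladder 0.1 to 50 Hz used by the rate-coding experiments.
#' @param duration protocol duration in ms.
#' @param kind \code{"poisson"} (default) or \code{"periodic"}.
#' @param refractory_ms minimum gap between successive pulses of one
#'   train (default 5 ms).
#' @param pulse_dur,amplitude pulse shape.
#' @return A \code{stim_protocol} (uses the current RNG state).
#' @export
rate_pattern <- function(rates_hz = default_rates(), duration,
                         kind = c("poisson", "periodic"),
                         refractory_ms = 5,
                         pulse_dur = default_pulse()$duration,
                         amplitude = default_pulse()$amplitude) {
  kind <- match.arg(kind)
  if (any(rates_hz < 0)) stop("rates must be >= 0", call. = FALSE)
  pulses <- lapply(seq_along(rates_hz), function(j) {
    r <- rates_hz[j]
    if (r == 0) return(NULL)
    mean_iv <- 1000 / r
    if (kind == "periodic") {
      onsets <- seq(0, duration, by = mean_iv)
      onsets <- onsets[onsets < duration]
    } else {
      if (mean_iv <= refractory_ms)
        stop("rate ", r, " Hz incompatible with the refractory floor",
             call. = FALSE)
      n_max <- ceiling(duration / mean_iv + 6 * sqrt(duration / mean_iv)) + 10
      gaps <- refractory_ms + stats::rexp(n_max,
                                          1 / (mean_iv - refractory_ms))
      onsets <- cumsum(gaps)
      while (onsets[length(onsets)] < duration) {
        extra <- refractory_ms + stats::rexp(n_max,
                                             1 / (mean_iv - refractory_ms))
        onsets <- c(onsets, onsets[length(onsets)] + cumsum(extra))
      }
      onsets <- onsets[onsets < duration]
    }
    if (!length(onsets)) return(NULL)
    data.frame(stimulator = j, onset = onsets, duration = pulse_dur,
               amplitude = amplitude)
  })
  pulses <- do.call(rbind, pulses)
  p <- stim_protocol(pulses, duration = duration)
  attr(p, "rates_hz") <- rates_hz
  p
}

#' The default rate ladder of the rate-coding experiments
#' @return 0.1, 0.2, 0.5, 1, 2, 3, 6, 12, 25, 50 Hz.
#' @export
default_rates <- function() c(0.1, 0.2, 0.5, 1, 2, 3, 6, 12, 25, 50)

#' Reverse a rate assignment
#'
#' The unknown test pattern of the rate-coding experiment: the learned
#' per-stimulator rates in reverse order, so the stimulator that was
#' slowest becomes the fastest and vice versa.
#'
#' @param rates_hz rate vector.
#' @return The reversed vector.
#' @export
reversed_rate_pattern <- function(rates_hz) {
  if (!length(rates_hz)) stop("empty rate list", call. = FALSE)
  rev(rates_hz)
}

#' EMG-associated stimulus current
#'
#' Converts an EMG sample (volts) to a stimulus current
#' \eqn{I = k\,|EMG|}. The raw signal is full-wave rectified before
#' scaling: surface EMG is zero-mean, and the injected current must
#' grow with contraction amplitude rather than cancel on average.
#'
#' @param emg_sample EMG sample(s) in volts.
#' @param k scaling coefficient (default \code{2e6}).
#' @return Current value(s).
#' @examples
#' emg_current(5e-6) # 10
#' @export
emg_current <- function(emg_sample, k = 2e6) {
  if (any(!is.finite(emg_sample)))
    stop("EMG samples must be finite", call. = FALSE)
  k * abs(emg_sample)
}

#' Continuous stimulus from an EMG recording
#'
#' Maps each EMG channel to the same-numbered stimulator and converts
#' samples to currents with [emg_current()].
#'
#' @param emg an [emg_recording()].
#' @param k scaling coefficient.
#' @return A \code{stim_protocol} with a continuous block.
#' @export
emg_to_stimulus <- function(emg, k = 2e6) {
  stopifnot(inherits(emg, "emg_recording"))
  cur <- emg_current(emg$samples, k = k)
  stim_protocol(continuous = list(samples = cur, fs = emg$fs,
                                  stimulators = seq_len(ncol(cur))),
                duration = nrow(cur) / emg$fs * 1000)
}

#' Supervised "teacher" stimulation electrode
#'
#' A virtual stimulation electrode delivering a suprathreshold periodic
#' pulse train (default 40 Hz) to one target neuron, confined to the
#' given time intervals. Used to force a chosen classifier to win during
#' the presentation of its assigned pattern.
#'
#' @param target neuron id of the stimulated classifier.
#' @param intervals two-column matrix or data frame of (start, end)
#'   times in ms.
#' @param rate_hz pulse rate within each interval (default 40).
#' @param duration protocol duration in ms (default: end of the last
#'   interval).
#' @param pulse_dur,amplitude pulse shape.
#' @return A \code{stim_protocol} addressing the neuron directly.
#' @examples
#' p <- teacher_stimulus(20, rbind(c(0, 3000)))
#' nrow(p$pulses) # 120 pulses at 40 Hz over 3 s
#' @export
teacher_stimulus <- function(target, intervals, rate_hz = 40,
                             duration = NULL,
                             pulse_dur = default_pulse()$duration,
                             amplitude = default_pulse()$amplitude) {
  intervals <- as.matrix(intervals)
  if (is.null(duration))
    duration <- if (nrow(intervals)) max(intervals[, 2]) else 0
  if (nrow(intervals) && max(intervals[, 2]) > duration)
    stop("teacher intervals exceed the protocol duration", call. = FALSE)
  period <- 1000 / rate_hz
  onsets <- unlist(lapply(seq_len(nrow(intervals)), function(i) {
    s <- intervals[i, 1]; e <- intervals[i, 2]
    out <- seq(s, e - 1e-9, by = period)
    out[out + pulse_dur <= e]
  }))
  pulses <- if (length(onsets))
    data.frame(stimulator = NA_integer_, neuron = target, onset = onsets,
               duration = pulse_dur, amplitude = amplitude)
  else NULL
  stim_protocol(pulses, duration = duration)
}

#' Write / read a pulse protocol as CSV
#'
#' @param protocol a \code{stim_protocol} (pulses only).
#' @param path file path.
#' @return \code{read_protocol} returns a \code{stim_protocol};
#'   \code{write_protocol} returns \code{path} invisibly.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "stim_protocol"))
  df <- protocol$pulses[, c("stimulator", "neuron", "onset", "duration",
                            "amplitude")]
  df$total_duration <- protocol$duration
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  df <- utils::read.csv(path)
  dur <- if (nrow(df)) df$total_duration[1] else 0
  df$total_duration <- NULL
  stim_protocol(df, duration = dur)
}
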