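#' Multi-channel EMG recording container
#'
#' @param samples numeric matrix, one column per channel (volts).
#' @param fs sampling rate in Hz.
#' @param labels per-sample gesture label (character), or \code{NULL}.
#' @param effort per-sample effort scalar in [0, 1], or \code{NULL}.
#' @return An object of class \code{"emg_recording"}.
#' @export
emg_recording <- function(samples, fs, labels = NULL, effort = NULL) {
  samples <- as.matrix(samples)
  n <- nrow(samples)
  if (!is.null(labels) && length(labels) != n)
    stop("labels length must equal the number of samples", call. = FALSE)
  if (!is.null(effort) && length(effort) != n)
    stop("effort length must equal the number of samples", call. = FALSE)
  structure(list(samples = samples, fs = fs, labels = labels,
                 effort = effort), class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("EMG recording: %d channels, %.1f s @ %g Hz",
              ncol(x$samples), nrow(x$samples) / x$fs, x$fs))
  if (!is.null(x$labels))
    cat(" | gestures:", paste(unique(x$labels), collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Default gesture-to-channel amplitude profiles
#'
#' Relative per-channel amplitude weights for the three default
#' gestures on an 8-channel forearm bracelet: flexion activates mostly
#' channels 1-3, extension mostly channels 5-7 (each with a weaker
#' secondary channel), rest activates none. The two movement profiles
#' occupy disjoint dominant channel groups, so their cosine similarity
#' is low by construction.
#'
#' @param n_channels number of channels (default 8; profiles scale by
#'   cyclic placement for other counts).
#' @param baseline_rms baseline noise level (volts RMS) common to all
#'   gestures.
#' @param max_rms carrier RMS (volts) of a weight-1 channel at effort 1.
#'   The default puts full-effort dominant-channel currents (after the
#'   EMG-current scaling k = 2e6) in the 20-60 range, driving sensory
#'   neurons at the vigorous tens-of-Hz rates the classifier's
#'   competitive learning requires.
#' @return Named list of profiles; each has \code{weights},
#'   \code{baseline_rms}, \code{max_rms}.
#' @export
gesture_profiles <- function(n_channels = 8, baseline_rms = 1.5e-7,
                             max_rms = 2e-5) {
  w_flex <- numeric(n_channels)
  w_ext <- numeric(n_channels)
  flex_idx <- intersect(1:3, seq_len(n_channels))
  ext_idx <- intersect(5:7, seq_len(n_channels))
  if (!length(ext_idx)) ext_idx <- n_channels
  w_flex[flex_idx] <- c(1, 0.8, 0.6)[seq_along(flex_idx)]
  w_flex[min(4, n_channels)] <- max(w_flex[min(4, n_channels)], 0.1)
  w_ext[ext_idx] <- c(0.6, 1, 0.8)[seq_along(ext_idx)]
  w_ext[min(4, n_channels)] <- max(w_ext[min(4, n_channels)], 0.1)
  mk <- function(w) list(weights = w, baseline_rms = baseline_rms,
                         max_rms = max_rms)
  list(rest = mk(numeric(n_channels)), flexion = mk(w_flex),
       extension = mk(w_ext))
}

#' Default alternating-gesture schedule
#'
#' About one minute of alternating hand gestures, each lasting 3 s:
#' rest, flexion, rest, extension, repeated six times (72 s).
#'
#' @param effort effort level of the movement gestures.
#' @param gesture_s duration of each gesture in seconds.
#' @param cycles number of rest/flexion/rest/extension cycles.
#' @return Data frame with columns \code{gesture}, \code{duration},
#'   \code{effort}.
#' @export
default_gesture_schedule <- function(effort = 1, gesture_s = 3,
                                     cycles = 6) {
  data.frame(
    gesture = rep(c("rest", "flexion", "rest", "extension"), cycles),
    duration = gesture_s,
    effort = rep(c(0, effort, 0, effort), cycles))
}

#' Generate a synthetic multi-channel EMG recording
#'
#' Surrogate surface EMG: each channel is a zero-mean band-limited
#' Gaussian carrier (white noise band-passed 20-95 Hz, unit RMS) whose
#' envelope is \code{baseline_rms + effort * weight * max_rms} for the
#' scheduled gesture. The envelope is therefore affine in the effort
#' parameter, so the recording's mean absolute value grows linearly
#' with effort. Gesture transitions are smoothed with a raised-cosine
#' ramp (default 400 ms, the scale of a deliberate change of hand
#' posture); the per-sample label and effort tracks follow the
#' schedule without smoothing.
#'
#' @param schedule data frame with columns \code{gesture},
#'   \code{duration} (s), \code{effort} in [0, 1]; see
#'   [default_gesture_schedule()].
#' @param profiles gesture profiles from [gesture_profiles()].
#' @param fs sampling rate in Hz (default 200).
#' @param seed integer seed (\code{NULL} leaves the RNG state alone).
#' @param band carrier pass band in Hz.
#' @param transition_ms length of the raised-cosine envelope ramp at
#'   gesture boundaries.
#' @return An [emg_recording()] with labels and effort tracks.
#' @examples
#' emg <- generate_emg(default_gesture_schedule(), seed = 1)
#' emg
#' @export
generate_emg <- function(schedule = default_gesture_schedule(),
                         profiles = NULL, fs = 200, seed = NULL,
                         band = c(20, 95), transition_ms = 400) {
  if (any(schedule$duration <= 0))
    stop("gesture durations must be > 0", call. = FALSE)
  if (any(schedule$effort < 0 | schedule$effort > 1))
    stop("effort must lie in [0, 1]", call. = FALSE)
  if (is.null(profiles)) profiles <- gesture_profiles()
  unknown <- setdiff(unique(schedule$gesture), names(profiles))
  if (length(unknown))
    stop("unknown gesture name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  n_channels <- length(profiles[[1]]$weights)
  seg_n <- round(schedule$duration * fs)
  n <- sum(seg_n)
  labels <- rep(schedule$gesture, seg_n)
  effort <- rep(schedule$effort, seg_n)

  # piecewise-constant envelope per channel, then raised-cosine smoothing
  env <- matrix(0, n, n_channels)
  row0 <- 0
  for (i in seq_len(nrow(schedule))) {
    pr <- profiles[[schedule$gesture[i]]]
    rows <- row0 + seq_len(seg_n[i])
    env[rows, ] <- rep(pr$baseline_rms + schedule$effort[i] *
                         pr$weights * pr$max_rms,
                       each = seg_n[i])
    row0 <- row0 + seg_n[i]
  }
  ramp_n <- max(1, round(transition_ms / 1000 * fs))
  if (ramp_n > 1 && n > 2 * ramp_n) {
    kern <- 0.5 * (1 - cos(2 * pi * seq_len(ramp_n) / (ramp_n + 1)))
    kern <- kern / sum(kern)
    pad <- function(x) c(rep(x[1], ramp_n), x, rep(x[length(x)], ramp_n))
    env <- apply(env, 2, function(col)
      stats::filter(pad(col), kern, sides = 2)[ramp_n + seq_len(n)])
  }

  # unit-RMS band-limited carrier
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  carrier <- apply(matrix(stats::rnorm(n * n_channels), n), 2,
                   function(x) {
                     y <- signal::filtfilt(bf, x)
                     y / stats::sd(y)
                   })
  emg_recording(carrier * env, fs = fs, labels = labels, effort = effort)
}

#' Mean absolute value of an EMG segment
#'
#' MAV: the mean of |sample| over a time window and a channel
#' selection; the standard proxy for muscle effort.
#'
#' @param emg an [emg_recording()].
#' @param window \code{c(start, end)} in seconds; default the whole
#'   recording.
#' @param channels channel indices; default all.
#' @return MAV in volts.
#' @examples
#' rec <- emg_recording(matrix(2, 100, 1), fs = 100)
#' mav(rec) # 2
#' @export
mav <- function(emg, window = NULL, channels = NULL) {
  stopifnot(inherits(emg, "emg_recording"))
  n <- nrow(emg$samples)
  if (is.null(window)) window <- c(0, n / emg$fs)
  idx <- which(seq_len(n) / emg$fs > window[1] &
                 seq_len(n) / emg$fs <= window[2])
  if (!length(idx)) stop("empty MAV window", call. = FALSE)
  if (is.null(channels)) channels <- seq_len(ncol(emg$samples))
  mean(abs(emg$samples[idx, channels, drop = FALSE]))
}

#' Write / read an EMG recording as CSV
#'
#' One column per channel (\code{ch1..chK}) plus \code{label} and
#' \code{effort} columns; the sampling rate is stored in a leading
#' comment-free \code{fs} column repeated per row for self-containment.
#'
#' @param emg an [emg_recording()].
#' @param path file path.
#' @return \code{read_emg} returns an \code{emg_recording}.
#' @export
write_emg <- function(emg, path) {
  stopifnot(inherits(emg, "emg_recording"))
  df <- as.data.frame(emg$samples)
  names(df) <- paste0("ch", seq_len(ncol(emg$samples)))
  df$label <- if (is.null(emg$labels)) NA else emg$labels
  df$effort <- if (is.null(emg$effort)) NA else emg$effort
  df$fs <- emg$fs
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_emg
#' @export
read_emg <- function(path) {
  df <- utils::read.csv(path)
  ch <- grep("^ch[0-9]+$", names(df), value = TRUE)
  emg_recording(as.matrix(df[, ch]), fs = df$fs[1],
                labels = if (all(is.na(df$label))) NULL else df$label,
                effort = if (all(is.na(df$effort))) NULL else df$effort)
}
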