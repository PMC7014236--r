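#' Fit a spiking winner-take-all EMG gesture classifier
#'
#' High-level model interface: builds the two-layer classifier network,
#' trains it on a labeled EMG recording by unsupervised or supervised
#' competitive learning (triplet STDP with synaptic forgetting under
#' lateral inhibition), assigns gesture labels to the classifier
#' neurons, and scores the training recording with the rate-ratio
#' accuracy metric.
#'
#' @param emg a labeled [emg_recording()] (gesture labels are used for
#'   evaluation always, and during training only in supervised mode,
#'   where they gate the teacher electrode).
#' @param method \code{"unsupervised"} or \code{"supervised"}.
#' @param targets supervised mode only: named vector mapping gestures
#'   to classifier neuron ids; default maps gestures in order of first
#'   appearance to the classifiers.
#' @param n_classes number of classifier neurons.
#' @param seed integer seed covering weight initialization, teacher
#'   scheduling and simulation noise.
#' @param dt integration step (ms).
#' @param k EMG-current scaling coefficient.
#' @param ... passed to [build_emg_classifier()].
#' @return An object of class \code{"snn_emg_fit"} with components
#'   \code{net} (trained topology), \code{assignment},
#'   \code{report} (training-data [classification_accuracy()]),
#'   \code{method}, \code{seed}.
#' @examples
#' \donttest{
#' emg <- generate_emg(default_gesture_schedule(), seed = 3)
#' fit <- snn_emg_classifier(emg, seed = 3)
#' fit
#' }
#' @export
snn_emg_classifier <- function(emg, method = c("unsupervised",
                                               "supervised"),
                               targets = NULL, n_classes = NULL,
                               seed = 1, dt = 0.5, k = 2e6, ...) {
  method <- match.arg(method)
  stopifnot(inherits(emg, "emg_recording"), !is.null(emg$labels))
  gestures <- unique(emg$labels)
  if (is.null(n_classes)) n_classes <- length(gestures)
  set.seed(seed)
  net <- build_emg_classifier(n_channels = ncol(emg$samples),
                              n_classes = n_classes, ...)
  if (method == "unsupervised") {
    trained <- train_unsupervised(net, emg, dt = dt, k = k)
    assignment <- assign_labels(trained, emg, dt = dt, k = k)
  } else {
    if (is.null(targets))
      targets <- stats::setNames(attr(net, "classifiers")[
        seq_along(gestures)], gestures)
    trained <- train_supervised(net, emg, targets, dt = dt, k = k)
    assignment <- assign_labels(trained, emg, dt = dt, k = k)
  }
  report <- classification_accuracy(trained, emg, assignment,
                                    dt = dt, k = k)
  structure(list(net = trained, assignment = assignment,
                 report = report, method = method, seed = seed,
                 dt = dt, k = k,
                 targets = if (method == "supervised") targets else NULL),
            class = "snn_emg_fit")
}

#' @export
print.snn_emg_fit <- function(x, ...) {
  cat("Spiking winner-take-all EMG classifier (", x$method,
      " learning)\n", sep = "")
  print(x$report)
  invisible(x)
}

#' @export
summary.snn_emg_fit <- function(object, ...) {
  cat("Spiking winner-take-all EMG classifier\n")
  cat("  method:", object$method, "| seed:", object$seed,
      "| dt:", object$dt, "ms\n")
  print(object$report)
  cat("  gesture-by-classifier response matrix (Hz):\n")
  print(round(object$report$responses, 2))
  cat("  learned input weights (rows: sensory channels + rest):\n")
  print(round(coef(object), 3))
  invisible(object)
}

#' Learned classifier input weights
#'
#' @param object an \code{snn_emg_fit}.
#' @param ... unused.
#' @return Matrix of plastic weights, one row per input (sensory
#'   channels and the rest detector), one column per classifier
#'   (labeled by its assigned gesture where available).
#' @export
coef.snn_emg_fit <- function(object, ...) {
  net <- object$net
  sens <- attr(net, "sensory"); rest <- attr(net, "rest")
  cls <- attr(net, "classifiers")
  sy <- plastic_synapses(net)
  m <- matrix(NA_real_, length(sens) + 1, length(cls),
              dimnames = list(c(paste0("ch", seq_along(sens)), "rest"),
                              as.character(cls)))
  for (j in seq_along(cls)) {
    m[, j] <- sy$w[match(c(sens, rest),
                         sy$pre[sy$post == cls[j]])]
    m[, j] <- sy$w[sy$post == cls[j]][match(c(sens, rest),
                                            sy$pre[sy$post == cls[j]])]
  }
  gl <- names(object$assignment)[match(cls, object$assignment)]
  colnames(m) <- ifelse(is.na(gl), as.character(cls),
                        paste0(gl, " (", cls, ")"))
  m
}

#' Classify new EMG with a fitted network
#'
#' Runs the trained network over a new recording with learning frozen
#' and, per evaluation window, declares the gesture of the classifier
#' with the highest spike count (rest wins silent windows only through
#' the rest detector pathway, i.e. through its classifier).
#'
#' @param object an \code{snn_emg_fit}.
#' @param newdata an [emg_recording()].
#' @param window_ms evaluation window length (default 500).
#' @param ... unused.
#' @return Data frame with one row per window: \code{start_ms},
#'   \code{end_ms}, \code{gesture} (predicted), per-classifier rates;
#'   if \code{newdata} carries labels, attribute
#'   \code{"report"} holds the rate-ratio accuracy report.
#' @export
predict.snn_emg_fit <- function(object, newdata, window_ms = 500, ...) {
  stopifnot(inherits(newdata, "emg_recording"))
  net <- object$net
  cls <- attr(net, "classifiers")
  sim <- simulate_snn(net, emg_to_stimulus(newdata, k = object$k),
                      dt = object$dt, learning = FALSE)
  dur <- sim$duration
  starts <- seq(0, dur - 1e-9, by = window_ms)
  gest_of <- stats::setNames(names(object$assignment),
                             object$assignment)
  rows <- lapply(starts, function(s) {
    e <- min(s + window_ms, dur)
    rates <- firing_rates(sim, cls, c(s, e))
    win <- cls[which.max(rates)]
    out <- data.frame(start_ms = s, end_ms = e,
                      gesture = unname(gest_of[as.character(win)]))
    cbind(out, stats::setNames(as.data.frame(t(rates)),
                               paste0("rate_", cls)))
  })
  out <- do.call(rbind, rows)
  if (!is.null(newdata$labels))
    attr(out, "report") <- classification_accuracy(
      net, newdata, object$assignment, dt = object$dt, k = object$k)
  out
}

#' Plot learned weight profiles by channel
#'
#' @param x an \code{snn_emg_fit}.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.snn_emg_fit <- function(x, ...) {
  m <- coef(x)
  graphics::matplot(seq_len(nrow(m) - 1), m[-nrow(m), ], type = "b",
                    pch = 19, lty = 1, xlab = "EMG channel",
                    ylab = "learned weight", ylim = c(0, 1), ...)
  graphics::legend("topright", legend = colnames(m), col = seq_len(ncol(m)),
                   lty = 1, pch = 19, bty = "n")
  invisible(x)
}
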