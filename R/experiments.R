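#' Single-neuron temporal-coding experiment
#'
#' Trains the 10-to-1 testbed on a repeating temporal pulse sequence
#' (one pulse per presynaptic neuron, inter-pulse interval
#' \code{delta_t}, sequence repeated at 1 Hz), then freezes learning and
#' measures the postsynaptic response to the familiar pattern (first
#' half of the sequence) and the unknown pattern (second half).
#'
#' @param delta_t inter-pulse interval in ms.
#' @param rule \code{"pair"} or \code{"triplet"}.
#' @param train_s training duration in seconds. The default runs the
#'   repeating pattern to the learning rule's fixed point; see the
#'   methods vignette for the convergence analysis.
#' @param test_s test duration per pattern in seconds (learning off).
#' @param n_pre number of presynaptic neurons.
#' @param seed integer seed.
#' @param dt integration step in ms.
#' @return A list of class \code{"coding_report"}: trained
#'   \code{weights} (by rank of spiking), \code{rank_cor} (Spearman
#'   correlation of weight with spike rank), \code{familiar_response}
#'   and \code{unknown_response} (postsynaptic rates in Hz),
#'   \code{response_ratio}, and the training simulation's final net.
#' @export
run_temporal_coding <- function(delta_t, rule = c("pair", "triplet"),
                                train_s = 3000, test_s = 30, n_pre = 10,
                                seed = 1, dt = 0.5) {
  rule <- match.arg(rule)
  set.seed(seed)
  net <- build_single_neuron_testbed(n_pre, rule = rule, init_w = 0.5)
  post <- n_pre + 1L
  train <- temporal_pattern(delta_t, n = n_pre, duration = train_s * 1000)
  sim <- simulate_snn(net, train, dt = dt, learning = TRUE)
  trained <- net
  trained$synapses$w <- sim$final_weights$w

  test_pattern <- temporal_pattern(delta_t, n = n_pre,
                                   duration = test_s * 1000)
  halves <- familiar_unknown_split(test_pattern)
  fam <- simulate_snn(trained, halves$familiar, dt = dt, learning = FALSE)
  unk <- simulate_snn(trained, halves$unknown, dt = dt, learning = FALSE)
  fam_rate <- unname(firing_rates(fam, post))
  unk_rate <- unname(firing_rates(unk, post))
  w <- trained$synapses$w
  structure(list(
    rule = rule, delta_t = delta_t, weights = w,
    rank_cor = suppressWarnings(
      stats::cor(w, seq_len(n_pre), method = "spearman")),
    familiar_response = fam_rate, unknown_response = unk_rate,
    response_ratio = fam_rate / max(unk_rate, .Machine$double.eps),
    net = trained), class = "coding_report")
}

#' Single-neuron rate-coding experiment
#'
#' Trains the 10-to-1 testbed on stochastic pulse trains whose mean
#' rates follow the default 0.1-50 Hz ladder, then freezes learning and
#' measures the response to the familiar pattern and to the reversed
#' (order-inverted) rate pattern.
#'
#' @param rule \code{"pair"}, \code{"triplet"} or
#'   \code{"triplet_forgetting"}.
#' @param rates_hz per-stimulator mean rates.
#' @param train_s,test_s training / per-pattern test durations (s).
#' @param seed integer seed.
#' @param dt integration step (ms).
#' @return A \code{"coding_report"} as in [run_temporal_coding()], with
#'   \code{rate_cor} (Spearman correlation of weight with presynaptic
#'   rate) in place of \code{rank_cor}.
#' @export
run_rate_coding <- function(rule = c("pair", "triplet",
                                     "triplet_forgetting"),
                            rates_hz = default_rates(), train_s = 3000,
                            test_s = 30, seed = 1, dt = 0.5) {
  rule <- match.arg(rule)
  set.seed(seed)
  n_pre <- length(rates_hz)
  net <- build_single_neuron_testbed(n_pre, rule = rule,
                                     init_w = c(0.25, 0.75))
  post <- n_pre + 1L
  train <- rate_pattern(rates_hz, duration = train_s * 1000)
  sim <- simulate_snn(net, train, dt = dt, learning = TRUE)
  trained <- net
  trained$synapses$w <- sim$final_weights$w

  fam_stim <- rate_pattern(rates_hz, duration = test_s * 1000)
  unk_stim <- rate_pattern(reversed_rate_pattern(rates_hz),
                           duration = test_s * 1000)
  fam <- simulate_snn(trained, fam_stim, dt = dt, learning = FALSE)
  unk <- simulate_snn(trained, unk_stim, dt = dt, learning = FALSE)
  fam_rate <- unname(firing_rates(fam, post))
  unk_rate <- unname(firing_rates(unk, post))
  w <- trained$synapses$w
  structure(list(
    rule = rule, rates_hz = rates_hz, weights = w,
    rate_cor = suppressWarnings(
      stats::cor(w, rates_hz, method = "spearman")),
    familiar_response = fam_rate, unknown_response = unk_rate,
    response_ratio = fam_rate / max(unk_rate, .Machine$double.eps),
    net = trained), class = "coding_report")
}

#' @export
print.coding_report <- function(x, ...) {
  cat("Single-neuron coding experiment (", x$rule, " rule)\n", sep = "")
  if (!is.null(x$rank_cor))
    cat(sprintf("  weight~rank Spearman rho: %.3f\n", x$rank_cor))
  if (!is.null(x$rate_cor))
    cat(sprintf("  weight~rate Spearman rho: %.3f\n", x$rate_cor))
  cat(sprintf("  familiar response: %.2f Hz | unknown: %.2f Hz | ratio %.2f\n",
              x$familiar_response, x$unknown_response, x$response_ratio))
  invisible(x)
}

label_segments <- function(emg) {
  stopifnot(!is.null(emg$labels))
  r <- rle(emg$labels)
  ends <- cumsum(r$lengths)
  starts <- c(0, ends[-length(ends)])
  data.frame(gesture = r$values, start_ms = starts / emg$fs * 1000,
             end_ms = ends / emg$fs * 1000)
}

#' Unsupervised competitive training of the classifier network
#'
#' Drives the sensory layer with EMG-derived currents for the full
#' recording while the plastic synapses learn online (triplet STDP +
#' forgetting under winner-take-all lateral inhibition). Labels, if
#' present, are ignored during training; they are used only by later
#' evaluation.
#'
#' @param net an [build_emg_classifier()] topology.
#' @param emg an [emg_recording()].
#' @param seed integer seed for the simulation noise.
#' @param dt integration step (ms).
#' @param k EMG-current scaling coefficient.
#' @return The trained topology (weights updated); the training
#'   simulation is attached as attribute \code{"training_sim"}.
#' @export
train_unsupervised <- function(net, emg, seed = NULL, dt = 0.5, k = 2e6) {
  stim <- emg_to_stimulus(emg, k = k)
  sim <- simulate_snn(net, stim, dt = dt, learning = TRUE, seed = seed)
  trained <- net
  trained$synapses$w <- sim$final_weights$w
  attr(trained, "sensory") <- attr(net, "sensory")
  attr(trained, "rest") <- attr(net, "rest")
  attr(trained, "classifiers") <- attr(net, "classifiers")
  attr(trained, "training_sim") <- sim
  trained
}

#' Supervised training by target-neuron stimulation
#'
#' As [train_unsupervised()], but during each labeled gesture segment a
#' virtual teacher electrode delivers 40 Hz suprathreshold pulses to the
#' classifier mapped to that gesture, forcing it to win the competition
#' and associate itself with the pattern. Learning stays active
#' throughout, including between teacher stimuli.
#'
#' @param net classifier topology.
#' @param emg labeled [emg_recording()].
#' @param targets named integer vector mapping every gesture label to a
#'   distinct classifier neuron id (a bijection).
#' @param teacher_hz teacher pulse rate (default 40).
#' @param seed,dt,k as in [train_unsupervised()].
#' @return The trained topology.
#' @export
train_supervised <- function(net, emg, targets, teacher_hz = 40,
                             seed = NULL, dt = 0.5, k = 2e6) {
  stopifnot(!is.null(emg$labels))
  gestures <- unique(emg$labels)
  if (!all(gestures %in% names(targets)))
    stop("targets must map every gesture label", call. = FALSE)
  tg <- targets[gestures]
  if (anyDuplicated(tg) || !all(tg %in% attr(net, "classifiers")))
    stop("targets must be a bijection onto distinct classifier neurons",
         call. = FALSE)
  segs <- label_segments(emg)
  dur <- nrow(emg$samples) / emg$fs * 1000
  teachers <- lapply(gestures, function(g) {
    iv <- segs[segs$gesture == g, c("start_ms", "end_ms")]
    teacher_stimulus(targets[[g]], as.matrix(iv), rate_hz = teacher_hz,
                     duration = dur)
  })
  stim <- do.call(merge_protocols,
                  c(list(emg_to_stimulus(emg, k = k)), teachers))
  sim <- simulate_snn(net, stim, dt = dt, learning = TRUE, seed = seed)
  trained <- net
  trained$synapses$w <- sim$final_weights$w
  attr(trained, "sensory") <- attr(net, "sensory")
  attr(trained, "rest") <- attr(net, "rest")
  attr(trained, "classifiers") <- attr(net, "classifiers")
  attr(trained, "training_sim") <- sim
  trained
}

#' Gesture-by-classifier response matrix
#'
#' Mean spike rate (Hz) of each classifier during the samples of each
#' gesture, from a learning-off simulation of the labeled recording.
#'
#' @param net trained classifier topology.
#' @param emg labeled recording.
#' @param seed,dt,k simulation controls.
#' @return list with \code{matrix} (gesture x classifier rates) and the
#'   evaluation \code{sim}.
#' @export
response_matrix <- function(net, emg, seed = NULL, dt = 0.5, k = 2e6) {
  cls <- attr(net, "classifiers")
  stopifnot(!is.null(cls))
  sim <- simulate_snn(net, emg_to_stimulus(emg, k = k), dt = dt,
                      learning = FALSE, seed = seed)
  segs <- label_segments(emg)
  gestures <- unique(segs$gesture)
  m <- matrix(0, length(gestures), length(cls),
              dimnames = list(gestures, as.character(cls)))
  for (g in gestures) {
    sg <- segs[segs$gesture == g, , drop = FALSE]
    total_ms <- sum(sg$end_ms - sg$start_ms)
    counts <- numeric(length(cls))
    for (i in seq_len(nrow(sg))) {
      inw <- sim$raster$time > sg$start_ms[i] &
        sim$raster$time <= sg$end_ms[i]
      counts <- counts + vapply(cls, function(id)
        sum(inw & sim$raster$neuron == id), numeric(1))
    }
    m[g, ] <- counts / total_ms * 1000
  }
  list(matrix = m, sim = sim)
}

#' Assign gesture labels to classifier neurons
#'
#' Exhaustive search over all bijections between gestures and
#' classifiers for the one maximizing the total own-class spike rate
#' (the sum of the response matrix entries selected by the assignment).
#'
#' @param net trained classifier topology.
#' @param emg labeled recording.
#' @param seed,dt,k passed to [response_matrix()].
#' @return Named integer vector: gesture -> classifier neuron id, with
#'   the response matrix as attribute \code{"responses"} and a
#'   \code{"degenerate"} flag when no classifier ever fired.
#' @export
assign_labels <- function(net, emg, seed = NULL, dt = 0.5, k = 2e6) {
  rm_ <- response_matrix(net, emg, seed = seed, dt = dt, k = k)
  out <- assign_labels_from_matrix(rm_$matrix)
  attr(out, "responses") <- rm_$matrix
  out
}

#' @rdname assign_labels
#' @param responses gesture-by-classifier rate matrix.
#' @export
assign_labels_from_matrix <- function(responses) {
  gestures <- rownames(responses)
  cls <- as.integer(colnames(responses))
  stopifnot(length(gestures) == length(cls))
  perms <- all_permutations(length(cls))
  scores <- vapply(perms, function(p)
    sum(responses[cbind(seq_along(gestures), p)]), numeric(1))
  best <- perms[[which.max(scores)]]
  out <- stats::setNames(cls[best], gestures)
  attr(out, "degenerate") <- all(responses == 0)
  out
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  do.call(c, lapply(seq_len(n), function(i)
    lapply(all_permutations(n - 1L), function(p)
      c(i, ifelse(p >= i, p + 1L, p)))))
}

#' Classification accuracy of a trained network
#'
#' For each gesture, accuracy is the spike rate of the classifier
#' assigned to that gesture divided by the summed rates of all
#' classifiers during that gesture's samples; the overall accuracy is
#' the duration-weighted mean across gestures. A gesture during which
#' no classifier fired at all has undefined accuracy and is reported as
#' \code{NA}.
#'
#' @param net trained classifier topology.
#' @param emg labeled recording.
#' @param assignment gesture -> classifier map from [assign_labels()].
#' @param exclude_transition_ms optionally drop this many ms after each
#'   label change before scoring (default 0: all samples count).
#' @param seed,dt,k simulation controls.
#' @return list of class \code{"classifier_report"}: \code{per_gesture}
#'   accuracies, \code{overall}, \code{assignment}, \code{responses}.
#' @export
classification_accuracy <- function(net, emg, assignment,
                                    exclude_transition_ms = 0,
                                    seed = NULL, dt = 0.5, k = 2e6) {
  cls <- attr(net, "classifiers")
  if (anyDuplicated(assignment) || !all(assignment %in% cls))
    stop("assignment must be a bijection onto the classifiers",
         call. = FALSE)
  sim <- simulate_snn(net, emg_to_stimulus(emg, k = k), dt = dt,
                      learning = FALSE, seed = seed)
  segs <- label_segments(emg)
  segs$start_ms <- pmin(segs$start_ms + exclude_transition_ms,
                        segs$end_ms)
  gestures <- names(assignment)
  per <- stats::setNames(rep(NA_real_, length(gestures)), gestures)
  wt <- stats::setNames(numeric(length(gestures)), gestures)
  resp <- matrix(0, length(gestures), length(cls),
                 dimnames = list(gestures, as.character(cls)))
  for (g in gestures) {
    sg <- segs[segs$gesture == g, , drop = FALSE]
    if (!nrow(sg)) next
    total_ms <- sum(sg$end_ms - sg$start_ms)
    counts <- numeric(length(cls))
    for (i in seq_len(nrow(sg))) {
      inw <- sim$raster$time > sg$start_ms[i] &
        sim$raster$time <= sg$end_ms[i]
      counts <- counts + vapply(cls, function(id)
        sum(inw & sim$raster$neuron == id), numeric(1))
    }
    resp[g, ] <- counts / total_ms * 1000
    wt[g] <- total_ms
    if (sum(counts) > 0)
      per[g] <- counts[match(assignment[[g]], cls)] / sum(counts)
  }
  ok <- !is.na(per)
  overall <- if (any(ok)) sum(per[ok] * wt[ok]) / sum(wt[ok]) else NA_real_
  structure(list(per_gesture = per, overall = overall,
                 assignment = assignment, responses = resp),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("EMG classification report\n")
  for (g in names(x$assignment))
    cat(sprintf("  %-10s -> neuron %d  accuracy %.3f\n", g,
                x$assignment[[g]], x$per_gesture[[g]]))
  cat(sprintf("  overall (duration-weighted): %.3f\n", x$overall))
  invisible(x)
}

#' Graded response to muscle effort
#'
#' For each effort level, generates a fixed-length single-gesture
#' recording, runs the trained network with learning off, and records
#' the recording's MAV and the winning classifier's mean rate. Returns
#' the per-level values together with the Pearson correlation and the
#' slope of the linear fit of rate on MAV.
#'
#' @param net trained classifier topology.
#' @param gesture the movement gesture to grade.
#' @param classifier id of that gesture's classifier; default: argmax
#'   response at the highest effort level.
#' @param effort_levels at least 3 levels in (0, 1].
#' @param pattern_s duration per level (default 10 s).
#' @param profiles gesture profiles.
#' @param seed,dt,k controls.
#' @return list with \code{mav}, \code{rate} (per level),
#'   \code{pearson_r}, \code{slope}, \code{classifier}.
#' @export
gradual_response <- function(net, gesture = "flexion", classifier = NULL,
                             effort_levels = c(0.25, 0.5, 0.75, 1),
                             pattern_s = 10, profiles = NULL,
                             seed = 1, dt = 0.5, k = 2e6) {
  if (length(effort_levels) < 3)
    stop("need at least 3 effort levels for a linear fit", call. = FALSE)
  if (is.null(profiles)) profiles <- gesture_profiles()
  cls <- attr(net, "classifiers")
  set.seed(seed)
  mavs <- rates <- matrix(NA_real_, length(effort_levels), length(cls))
  mv <- numeric(length(effort_levels))
  for (i in seq_along(effort_levels)) {
    sched <- data.frame(gesture = gesture, duration = pattern_s,
                        effort = effort_levels[i])
    emg <- generate_emg(sched, profiles)
    mv[i] <- mav(emg)
    sim <- simulate_snn(net, emg_to_stimulus(emg, k = k), dt = dt,
                        learning = FALSE)
    rates[i, ] <- firing_rates(sim, cls)
  }
  if (is.null(classifier))
    classifier <- cls[which.max(rates[length(effort_levels), ])]
  r <- rates[, match(classifier, cls)]
  fit <- stats::lm(r ~ mv)
  list(effort = effort_levels, mav = mv, rate = r,
       all_rates = rates,
       pearson_r = suppressWarnings(stats::cor(mv, r)),
       slope = unname(stats::coef(fit)[2]), classifier = classifier)
}

#' Correlation of learned weights with channel amplitude profiles
#'
#' For each movement gesture: Pearson correlation between the
#' per-channel mean rectified EMG amplitude during that gesture and the
#' learned weights from the corresponding sensory neurons to the
#' gesture's classifier.
#'
#' @param net trained classifier topology.
#' @param emg labeled recording.
#' @param assignment gesture -> classifier map.
#' @param gestures gestures to evaluate (default: all non-rest).
#' @return Named vector of correlations.
#' @export
weight_amplitude_profile <- function(net, emg, assignment,
                                     gestures = NULL) {
  sens <- attr(net, "sensory")
  if (is.null(gestures))
    gestures <- setdiff(names(assignment), "rest")
  segs <- label_segments(emg)
  out <- stats::setNames(rep(NA_real_, length(gestures)), gestures)
  for (g in gestures) {
    sg <- segs[segs$gesture == g, , drop = FALSE]
    idx <- unlist(lapply(seq_len(nrow(sg)), function(i)
      seq(floor(sg$start_ms[i] / 1000 * emg$fs) + 1,
          floor(sg$end_ms[i] / 1000 * emg$fs))))
    amp <- colMeans(abs(emg$samples[idx, , drop = FALSE]))
    amp <- amp / max(amp)
    sy <- net$synapses
    w <- vapply(sens, function(s)
      sy$w[sy$pre == s & sy$post == assignment[[g]]], numeric(1))
    out[g] <- suppressWarnings(stats::cor(amp, w))
  }
  out
}
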