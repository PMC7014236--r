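#' Simulate a spiking network
#'
#' Time-stepped simulation of an [snn_topology()] under a stimulation
#' protocol: forward-Euler integration of the Izhikevich membrane
#' equations (membrane potential advanced in two half-steps per step),
#' current-based synapses driven by the presynaptic synaptic-output
#' trace, per-step Gaussian noise, and — when \code{learning = TRUE} —
#' the synapse table's plasticity rules (pair / triplet STDP with
#' multiplicative soft bounds, optional activity-dependent forgetting).
#' The full update order within a step is documented in the methods
#' vignette. Given the same topology, stimuli, seed and step the result
#' is bit-identical across runs.
#'
#' @param net an \code{snn_topology}.
#' @param stim a [stim_protocol()] or \code{NULL}.
#' @param duration simulated time in ms; defaults to the protocol
#'   duration.
#' @param dt integration step in ms (must satisfy 0 < dt <= 1).
#' @param learning if \code{FALSE}, all weights are frozen.
#' @param seed integer seed for the noise stream (\code{NULL} leaves the
#'   RNG state alone).
#' @param snapshot_every interval (ms) between weight snapshots; 0
#'   disables snapshots.
#' @return An object of class \code{"snn_sim"}: list with \code{raster}
#'   (data frame \code{neuron}, \code{time}), \code{final_weights}
#'   (synapse table with updated \code{w}), \code{snapshots} (matrix,
#'   one row per snapshot time), \code{snapshot_times}, \code{duration},
#'   \code{dt}, and the input \code{net}.
#' @examples
#' net <- build_single_neuron_testbed(2, rule = "pair")
#' stim <- temporal_pattern(5, n = 2, duration = 2000)
#' sim <- simulate_snn(net, stim, seed = 1)
#' head(sim$raster)
#' @export
simulate_snn <- function(net, stim = NULL, duration = NULL, dt = 0.5,
                         learning = TRUE, seed = NULL,
                         snapshot_every = 0) {
  stopifnot(inherits(net, "snn_topology"))
  if (!is.null(stim)) stopifnot(inherits(stim, "stim_protocol"))
  if (is.null(duration))
    duration <- if (is.null(stim)) stop("duration required without stimuli",
                                        call. = FALSE) else stim$duration
  if (duration < 0) stop("duration must be >= 0", call. = FALSE)
  if (dt <= 0 || dt > 1) stop("dt must satisfy 0 < dt <= 1", call. = FALSE)

  nn <- net$neurons
  sy <- net$synapses
  id_index <- match_id <- function(ids) match(ids, nn$id)

  # resolve stimulator bindings before stepping
  pulses <- if (is.null(stim)) NULL else stim$pulses
  if (!is.null(pulses) && nrow(pulses)) {
    tgt <- pulses$neuron
    needs <- is.na(tgt)
    if (any(needs)) {
      m <- match(pulses$stimulator[needs], net$stimulators$stimulator)
      if (anyNA(m))
        stop("stimulus bound to unknown stimulator id(s): ",
             paste(unique(pulses$stimulator[needs][is.na(m)]),
                   collapse = ", "), call. = FALSE)
      tgt[needs] <- net$stimulators$neuron[m]
    }
    if (anyNA(match_id(tgt)))
      stop("stimulus bound to unknown neuron id", call. = FALSE)
    ord <- order(tgt, pulses$onset)
    pulse_neuron <- match_id(tgt)[ord] - 1L
    pulse_onset <- pulses$onset[ord]
    pulse_dur <- pulses$duration[ord]
    pulse_amp <- pulses$amplitude[ord]
  } else {
    pulse_neuron <- integer(); pulse_onset <- numeric()
    pulse_dur <- numeric(); pulse_amp <- numeric()
  }

  co <- if (is.null(stim)) NULL else stim$continuous
  if (!is.null(co)) {
    m <- match(co$stimulators, net$stimulators$stimulator)
    if (anyNA(m))
      stop("continuous stimulus bound to unknown stimulator id",
           call. = FALSE)
    cont_neuron <- match_id(net$stimulators$neuron[m]) - 1L
    cont_current <- co$samples
    cont_fs <- co$fs
  } else {
    cont_neuron <- integer()
    cont_current <- matrix(numeric(), 0, 0)
    cont_fs <- 1
  }

  v0 <- rep(-70, nrow(nn))
  u0 <- nn$b * v0

  if (!is.null(seed)) set.seed(seed)
  res <- cpp_simulate(
    nn$a, nn$b, nn$c, nn$d, nn$D, nn$g, nn$threshold, v0, u0,
    match_id(sy$pre) - 1L, match_id(sy$post) - 1L, sy$w,
    rule_codes[sy$rule], sy$lambda, sy$alpha, sy$tau_f,
    net$taus$tau_syn, net$taus$tau1, net$taus$tau2, net$taus$tau_o,
    pulse_neuron, pulse_onset, pulse_dur, pulse_amp,
    cont_neuron, cont_current, cont_fs,
    duration, dt, learning, snapshot_every)

  fw <- sy
  fw$w <- res$w_final
  raster <- data.frame(neuron = nn$id[res$spike_neuron],
                       time = res$spike_time)
  structure(list(raster = raster, final_weights = fw,
                 snapshots = res$snapshots,
                 snapshot_times = res$snapshot_times,
                 duration = duration, dt = dt, net = net,
                 learning = learning),
            class = "snn_sim")
}

#' @export
print.snn_sim <- function(x, ...) {
  cat(sprintf("SNN simulation: %.0f ms at dt = %g ms, %d spikes from %d neurons%s\n",
              x$duration, x$dt, nrow(x$raster),
              length(unique(x$raster$neuron)),
              if (x$learning) ", learning on" else ", learning frozen"))
  invisible(x)
}

#' Mean firing rates over a window
#'
#' Spike counts divided by window length, in Hz.
#'
#' @param sim an \code{snn_sim} (or a raster data frame).
#' @param neurons neuron ids of interest.
#' @param window \code{c(start, end)} in ms; default the whole run.
#' @return Named numeric vector of rates (Hz), one per requested neuron.
#' @export
firing_rates <- function(sim, neurons, window = NULL) {
  raster <- if (inherits(sim, "snn_sim")) sim$raster else sim
  if (is.null(window))
    window <- c(0, if (inherits(sim, "snn_sim")) sim$duration
                   else max(raster$time, 0))
  if (diff(window) <= 0) stop("empty window", call. = FALSE)
  inw <- raster$time > window[1] & raster$time <= window[2]
  counts <- vapply(neurons, function(id)
    sum(inw & raster$neuron == id), numeric(1))
  stats::setNames(counts / diff(window) * 1000, neurons)
}

#' Write / read a spike raster as CSV
#'
#' @param sim an \code{snn_sim} or a raster data frame with columns
#'   \code{neuron}, \code{time}.
#' @param path file path.
#' @return \code{read_raster} returns the raster data frame.
#' @export
write_raster <- function(sim, path) {
  raster <- if (inherits(sim, "snn_sim")) sim$raster else sim
  utils::write.csv(raster[, c("neuron", "time")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  utils::read.csv(path, colClasses = c(neuron = "integer",
                                       time = "numeric"))
}

#' Write weight snapshots as CSV
#'
#' Long format: one row per (time, synapse) pair with the weight then in
#' force.
#'
#' @param sim an \code{snn_sim} simulated with \code{snapshot_every > 0}.
#' @param path file path.
#' @export
write_weights <- function(sim, path) {
  stopifnot(inherits(sim, "snn_sim"))
  sy <- sim$net$synapses
  if (!length(sim$snapshot_times)) {
    df <- data.frame(pre_id = sy$pre, post_id = sy$post,
                     weight = sim$final_weights$w,
                     time_ms = sim$duration)
  } else {
    df <- do.call(rbind, lapply(seq_along(sim$snapshot_times), function(i)
      data.frame(pre_id = sy$pre, post_id = sy$post,
                 weight = sim$snapshots[i, ],
                 time_ms = sim$snapshot_times[i])))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Raster plot of a simulation
#'
#' @param x an \code{snn_sim}.
#' @param ... passed to [graphics::plot()].
#' @export
plot.snn_sim <- function(x, ...) {
  r <- x$raster
  ids <- sort(unique(x$net$neurons$id))
  graphics::plot(r$time, match(r$neuron, ids), pch = "|", cex = 0.6,
                 xlab = "time (ms)", ylab = "neuron", yaxt = "n",
                 xlim = c(0, x$duration), ylim = c(0.5, length(ids) + 0.5),
                 ...)
  graphics::axis(2, at = seq_along(ids), labels = ids, las = 1)
  invisible(x)
}
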