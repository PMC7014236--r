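#' Default decay time of the synaptic forgetting rule
#'
#' Decay time (ms) of the activity-dependent weight-forgetting rule
#' \eqn{dw/dt = -w\, y_i / \tau_f} used by the classifier network and
#' the rate-coding experiments. See the methods vignette for the
#' time-scale analysis behind the default.
#'
#' @return The default \code{tau_f} in ms.
#' @export
forgetting_tau_default <- function() 2e6

#' Exponential trace update over one step
#'
#' A synaptic trace decays as \eqn{dy/dt = -y/\tau} and jumps by
#' \code{increment} at each spike of its source neuron. The step applies
#' decay first and the spike increment after, so a spike never decays
#' within its own step.
#'
#' @param value current trace value (>= 0).
#' @param tau decay time in ms (> 0).
#' @param dt elapsed time in ms (> 0).
#' @param spiked did the source neuron spike at the end of this step?
#' @param increment jump size per spike (default 1).
#' @return Updated trace value.
#' @examples
#' decay_and_bump_trace(1, tau = 100, dt = 100, spiked = FALSE) # exp(-1)
#' @export
decay_and_bump_trace <- function(value, tau, dt, spiked = FALSE,
                                 increment = 1) {
  if (!is.numeric(tau) || tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  value * exp(-dt / tau) + as.numeric(spiked) * increment
}

#' Multiplicative soft-bound factors
#'
#' The weight-dependent amplitudes of the multiplicative STDP rule:
#' \eqn{F^+(w) = \lambda (1 - w)} scales potentiation and
#' \eqn{F^-(w) = \lambda \alpha w} scales depression, confining plastic
#' weights to \eqn{[0, 1]}.
#'
#' @param w synaptic weight in [0, 1].
#' @param lambda learning rate.
#' @param alpha depression/potentiation asymmetry.
#' @return list with elements \code{F_plus} and \code{F_minus}.
#' @examples
#' bound_factors(0.5, 0.001, 1) # both 5e-4
#' @export
bound_factors <- function(w, lambda = 0.001, alpha = 1) {
  if (any(!is.finite(w)) || any(w < 0 | w > 1))
    stop("weight w must lie in [0, 1]", call. = FALSE)
  list(F_plus = lambda * (1 - w), F_minus = lambda * alpha * w)
}

#' Pair-rule potentiation at a postsynaptic spike
#'
#' @param w current weight.
#' @param y_pre1 fast presynaptic trace read just before the spike's own
#'   increment.
#' @param lambda learning rate.
#' @return Non-negative weight change \eqn{F^+(w)\, y^1_{pre}}.
#' @export
pair_ltp_delta <- function(w, y_pre1, lambda = 0.001) {
  bound_factors(w, lambda)$F_plus * y_pre1
}

#' Pair-rule depression at a presynaptic spike
#'
#' @param w current weight.
#' @param y_post1 fast postsynaptic trace.
#' @param lambda learning rate.
#' @param alpha asymmetry factor.
#' @return Non-positive weight change \eqn{-F^-(w)\, y^1_{post}}.
#' @export
pair_ltd_delta <- function(w, y_post1, lambda = 0.001, alpha = 1) {
  -bound_factors(w, lambda, alpha)$F_minus * y_post1
}

#' Triplet-rule potentiation at a postsynaptic spike
#'
#' The minimal triplet rule gates pair potentiation by the slow
#' postsynaptic trace \code{y_post2}, read just before the triggering
#' spike's own increment, which makes potentiation grow with the
#' postsynaptic firing rate. A first-ever postsynaptic spike (zero slow
#' trace) therefore produces no potentiation.
#'
#' @param w current weight.
#' @param y_pre1 fast presynaptic trace.
#' @param y_post2 slow postsynaptic trace (pre-increment).
#' @param lambda learning rate.
#' @return Non-negative weight change
#'   \eqn{F^+(w)\, y^1_{pre}\, y^2_{post}}.
#' @export
triplet_ltp_delta <- function(w, y_pre1, y_post2, lambda = 0.001) {
  bound_factors(w, lambda)$F_plus * y_pre1 * y_post2
}

#' Activity-dependent forgetting over one step
#'
#' Integrates \eqn{dw/dt = -w\, y_i/\tau_f} over \code{dt} holding the
#' postsynaptic averaged-activity trace \code{y_post_avg} constant,
#' giving the exact multiplicative decay
#' \eqn{w \exp(-y_i\, dt/\tau_f)}. Silent postsynaptic neurons
#' (\code{y_post_avg = 0}) forget nothing.
#'
#' @param w current weight.
#' @param y_post_avg averaged-activity trace of the postsynaptic neuron.
#' @param dt step length in ms.
#' @param tau_f forgetting decay time in ms (> 0).
#' @return Updated weight.
#' @examples
#' forgetting_step(1, y_post_avg = 1, dt = 10, tau_f = 10) # exp(-1)
#' @export
forgetting_step <- function(w, y_post_avg, dt, tau_f = 10) {
  if (!is.numeric(tau_f) || tau_f <= 0)
    stop("tau_f must be > 0", call. = FALSE)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  w * exp(-y_post_avg * dt / tau_f)
}

#' Event-driven plasticity replay over a fixed spike raster
#'
#' Evolves the plastic weights of a synapse set exactly (closed-form
#' exponentials between events, no time grid) for a given, fixed spike
#' raster. At every spike time: depression is applied for synapses whose
#' presynaptic neuron spiked, then potentiation for synapses whose
#' postsynaptic neuron spiked; both read the traces as decayed to that
#' instant but before the spiking neurons' own increments; the
#' forgetting decay is integrated analytically between events. This is
#' the reference "event-driven mode" against which the stepped engine
#' converges as \code{dt} shrinks.
#'
#' @param events data frame with columns \code{neuron} and \code{time}
#'   (ms), time-sorted or not (it is sorted internally). Simultaneous
#'   spikes are processed together under the documented tie-break.
#' @param synapses synapse table as in [snn_topology()] (columns
#'   \code{pre}, \code{post}, \code{w}, \code{rule}, \code{lambda},
#'   \code{alpha}, \code{tau_f}).
#' @param taus trace decay times, as in [snn_topology()].
#' @param until final time (ms) to which forgetting is integrated;
#'   defaults to the last event time.
#' @return list with \code{w} (final weights, one per synapse row) and
#'   \code{history} (data frame of per-event weights, one column per
#'   plastic synapse).
#' @export
stdp_replay <- function(events, synapses,
                        taus = list(tau_syn = 100, tau1 = 10,
                                    tau2 = 100, tau_o = 100),
                        until = NULL) {
  stopifnot(all(c("neuron", "time") %in% names(events)))
  ev <- events[order(events$time), , drop = FALSE]
  ids <- unique(c(synapses$pre, synapses$post, ev$neuron))
  y1 <- y2 <- yo <- stats::setNames(numeric(length(ids)), ids)
  t_last <- stats::setNames(numeric(length(ids)), ids)
  w <- synapses$w
  plastic <- which(synapses$rule != "none")
  forgetful <- which(synapses$rule == "triplet_forgetting")
  t_forg <- 0

  val <- function(y, id, t, tau) {
    y[[as.character(id)]] * exp(-(t - t_last[[as.character(id)]]) / tau)
  }
  # exact integral of the post trace over [t1, t2]: yo(t1) tau_o (1 - e^(-dt/tau_o))
  advance_forgetting <- function(t2) {
    for (s in forgetful) {
      post <- as.character(synapses$post[s])
      y_at <- yo[[post]] * exp(-(t_forg - t_last[[post]]) / taus$tau_o)
      integ <- y_at * taus$tau_o * (1 - exp(-(t2 - t_forg) / taus$tau_o))
      w[s] <<- w[s] * exp(-integ / synapses$tau_f[s])
    }
    t_forg <<- t2
  }

  times <- unique(ev$time)
  hist_w <- matrix(NA_real_, length(times), length(plastic))
  for (k in seq_along(times)) {
    t <- times[k]
    spikers <- ev$neuron[ev$time == t]
    advance_forgetting(t)
    # depression first, then potentiation, on pre-increment traces
    for (s in plastic) {
      if (synapses$pre[s] %in% spikers) {
        yp <- val(y1, synapses$post[s], t, taus$tau1)
        w[s] <- w[s] + pair_ltd_delta(w[s], yp, synapses$lambda[s],
                                      synapses$alpha[s])
      }
    }
    for (s in plastic) {
      if (synapses$post[s] %in% spikers) {
        ypre <- val(y1, synapses$pre[s], t, taus$tau1)
        if (synapses$rule[s] == "pair") {
          w[s] <- w[s] + pair_ltp_delta(w[s], ypre, synapses$lambda[s])
        } else {
          ypost2 <- val(y2, synapses$post[s], t, taus$tau2)
          w[s] <- w[s] + triplet_ltp_delta(w[s], ypre, ypost2,
                                           synapses$lambda[s])
        }
      }
    }
    for (id in unique(spikers)) {
      key <- as.character(id)
      y1[[key]] <- val(y1, id, t, taus$tau1) + 1
      y2[[key]] <- val(y2, id, t, taus$tau2) + 1
      yo[[key]] <- val(yo, id, t, taus$tau_o) + 1
      t_last[[key]] <- t
    }
    hist_w[k, ] <- w[plastic]
  }
  if (!is.null(until)) {
    if (length(times) && until < max(times))
      stop("'until' must not precede the last event", call. = FALSE)
    advance_forgetting(until)
  }
  history <- data.frame(time = times)
  if (length(plastic))
    history <- cbind(history, stats::setNames(
      as.data.frame(hist_w),
      paste0("syn_", synapses$pre[plastic], "_", synapses$post[plastic])))
  list(w = w, history = history)
}
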