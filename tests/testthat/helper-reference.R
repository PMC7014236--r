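# Independent reference implementations used as oracles. These
# deliberately share no code with the package internals: a plain-R
# fine-step Izhikevich integrator, and a hand-rolled event-driven STDP
# calculator based on closed-form exponentials.

# Integrate one Izhikevich neuron with forward Euler at a (typically
# very small) step; I_fun(t) gives the driving current. Returns spike
# times.
ref_izhikevich <- function(I_fun, duration, dt = 0.01,
                           a = 0.02, b = 0.2, c = -65, d = 8,
                           threshold = 30, v0 = -70) {
  v <- v0; u <- b * v0
  spikes <- numeric()
  n <- round(duration / dt)
  for (k in seq_len(n)) {
    t <- (k - 1) * dt
    I <- I_fun(t)
    v <- v + 0.5 * dt * (0.04 * v^2 + 5 * v + 140 - u + I)
    v <- v + 0.5 * dt * (0.04 * v^2 + 5 * v + 140 - u + I)
    u <- u + dt * a * (b * v - u)
    if (v >= threshold) {
      spikes <- c(spikes, k * dt)
      v <- c
      u <- u + d
    }
  }
  spikes
}

# Closed-form trace value at time t given past spike times of the
# source neuron (unit increments, exponential decay).
ref_trace <- function(spike_times, t, tau) {
  s <- spike_times[spike_times < t]
  if (!length(s)) return(0)
  sum(exp(-(t - s) / tau))
}

# Event-driven weight evolution for ONE synapse given fixed pre/post
# spike trains. Mirrors the documented tie-break (LTD before LTP,
# pre-increment traces) but is computed directly from the closed-form
# trace sums above.
ref_stdp_one <- function(pre_sp, post_sp, w0, rule = "pair",
                         lambda = 0.001, alpha = 1, tau1 = 10,
                         tau2 = 100, tau_o = 100, tau_f = 10,
                         until = NULL) {
  events <- sort(unique(c(pre_sp, post_sp)))
  w <- w0
  t_prev <- 0
  for (t in events) {
    if (rule == "triplet_forgetting") {
      # integrate forgetting over (t_prev, t): yo is piecewise between
      # post spikes, but post spikes ARE events, so yo is one
      # exponential arc here
      yo0 <- ref_trace(post_sp, t_prev + 1e-12, tau_o) *
        exp(-0 / tau_o)
      yo_at_prev <- ref_trace(post_sp, t_prev + 1e-12, tau_o)
      integral <- yo_at_prev * tau_o * (1 - exp(-(t - t_prev) / tau_o))
      w <- w * exp(-integral / tau_f)
    }
    if (t %in% pre_sp)  # LTD
      w <- w - lambda * alpha * w * ref_trace(post_sp, t, tau1)
    if (t %in% post_sp) {  # LTP
      dw <- lambda * (1 - w) * ref_trace(pre_sp, t, tau1)
      if (rule %in% c("triplet", "triplet_forgetting"))
        dw <- dw * ref_trace(post_sp, t, tau2)
      w <- w + dw
    }
    t_prev <- t
  }
  if (!is.null(until) && rule == "triplet_forgetting") {
    yo_at_prev <- ref_trace(post_sp, t_prev + 1e-12, tau_o)
    integral <- yo_at_prev * tau_o * (1 - exp(-(until - t_prev) / tau_o))
    w <- w * exp(-integral / tau_f)
  }
  w
}

# A minimal single-synapse topology used across plasticity tests.
two_neuron_net <- function(rule = "pair", w0 = 0.5, lambda = 0.001,
                           alpha = 1, tau_f = 10, D = 0) {
  p <- neuron_params("regular", D = D)
  snn_topology(
    rbind(neuron_row_test(1L, "presynaptic", p),
          neuron_row_test(2L, "postsynaptic", p)),
    data.frame(pre = 1L, post = 2L, w = w0, rule = rule,
               lambda = lambda, alpha = alpha, tau_f = tau_f),
    data.frame(stimulator = 1:2, neuron = 1:2))
}

neuron_row_test <- function(id, layer, p) {
  data.frame(id = id, layer = layer, a = p$a, b = p$b, c = p$c, d = p$d,
             D = p$D, g = p$g, threshold = p$threshold)
}
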