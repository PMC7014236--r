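#' Izhikevich neuron parameters
#'
#' Builds a parameter set for the two-variable Izhikevich neuron
#' \deqn{v' = 0.04 v^2 + 5 v + 140 - u + I, \quad u' = a (b v - u),}
#' with the spike rule: when \eqn{v \ge} \code{threshold}, a spike is
#' emitted and \eqn{v \leftarrow c}, \eqn{u \leftarrow u + d}.
#'
#' Two canonical presets are provided: \code{"regular"} (regular-spiking
#' cortical pyramidal parameters, used for excitatory neurons) and
#' \code{"fast"} (fast-spiking interneuron parameters, used for
#' inhibitory neurons). Any field can be overridden.
#'
#' @param type preset, \code{"regular"} or \code{"fast"}.
#' @param a recovery time scale (1/ms).
#' @param b recovery sensitivity (dimensionless).
#' @param c post-spike reset potential (mV).
#' @param d post-spike recovery increment.
#' @param D variance of the per-step white Gaussian noise current
#'   (current^2 units); 0 disables noise.
#' @param g synaptic scaling factor of the neuron's outgoing synapses:
#'   +2 for excitatory neurons, -2 for inhibitory neurons.
#' @param threshold spike threshold (mV), default 30.
#'
#' @return An object of class \code{"neuron_params"}: a named list with
#'   fields \code{a, b, c, d, D, g, threshold}.
#' @examples
#' neuron_params("regular")
#' neuron_params("fast", D = 70, g = 2) # noisy excitatory rest detector
#' @export
neuron_params <- function(type = c("regular", "fast"),
                          a = NULL, b = NULL, c = NULL, d = NULL,
                          D = 0, g = NULL, threshold = 30) {
  type <- match.arg(type)
  def <- switch(type,
    regular = list(a = 0.02, b = 0.2, c = -65, d = 8, g = 2),
    fast    = list(a = 0.1,  b = 0.2, c = -65, d = 2, g = -2))
  p <- list(
    a = if (is.null(a)) def$a else a,
    b = if (is.null(b)) def$b else b,
    c = if (is.null(c)) def$c else c,
    d = if (is.null(d)) def$d else d,
    D = D,
    g = if (is.null(g)) def$g else g,
    threshold = threshold)
  validate_neuron_params(p)
  structure(p, class = "neuron_params")
}

validate_neuron_params <- function(p) {
  for (f in c("a", "b", "c", "d", "D", "g", "threshold")) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || !is.finite(p[[f]]))
      stop("neuron parameter '", f, "' must be a single finite number",
           call. = FALSE)
  }
  if (!p$g %in% c(2, -2))
    stop("scaling factor g must be +2 (excitatory) or -2 (inhibitory)",
         call. = FALSE)
  if (p$D < 0) stop("noise variance D must be >= 0", call. = FALSE)
  if (p$threshold <= p$c)
    stop("spike threshold must exceed the reset potential c", call. = FALSE)
  invisible(p)
}

#' @export
print.neuron_params <- function(x, ...) {
  cat(sprintf(
    "Izhikevich neuron: a=%g b=%g c=%g d=%g | D=%g g=%+g threshold=%g mV\n",
    x$a, x$b, x$c, x$d, x$D, x$g, x$threshold))
  invisible(x)
}

#' Total driving current of a neuron
#'
#' The driving current is the sum of three terms: an uncorrelated
#' zero-mean white Gaussian noise sample, the synaptic current, and the
#' external stimulus current.
#'
#' @param noise_sample,syn_current,stim_current the three current terms.
#' @return Their sum.
#' @examples
#' total_current(0.3, 1.0, 10.0) # 11.3
#' @export
total_current <- function(noise_sample, syn_current, stim_current) {
  terms <- list(noise_sample = noise_sample, syn_current = syn_current,
                stim_current = stim_current)
  for (nm in names(terms))
    if (!all(is.finite(terms[[nm]])))
      stop("non-finite current term: ", nm, call. = FALSE)
  noise_sample + syn_current + stim_current
}

#' Sample the white-noise current term
#'
#' Draws the per-step samples of the white Gaussian noise current under
#' the Euler-Maruyama convention the simulation engine uses: each step
#' of length \code{dt} receives an independent draw with variance
#' \code{D / dt}, so the variance of the integrated noise contribution
#' over any fixed time interval is independent of the step size.
#'
#' @param D noise intensity; \code{D = 0} returns exact zeros.
#' @param n number of samples.
#' @param dt integration step in ms.
#' @return Numeric vector of length \code{n}.
#' @export
sample_noise <- function(D, n = 1, dt = 0.5) {
  if (!is.numeric(D) || length(D) != 1 || !is.finite(D) || D < 0)
    stop("noise variance D must be a single finite number >= 0",
         call. = FALSE)
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (D == 0) return(numeric(n) + 0)
  stats::rnorm(n, mean = 0, sd = sqrt(D / dt))
}
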