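#' Construct a spiking-network topology
#'
#' Low-level constructor tying together the neuron table, the synapse
#' table and the stimulator-to-neuron bindings. Most users will call
#' [build_single_neuron_testbed()] or [build_emg_classifier()] instead.
#'
#' @param neurons data frame with columns \code{id}, \code{layer},
#'   \code{a}, \code{b}, \code{c}, \code{d}, \code{D}, \code{g},
#'   \code{threshold}.
#' @param synapses data frame with columns \code{pre}, \code{post},
#'   \code{w}, \code{rule} (one of \code{"none"}, \code{"pair"},
#'   \code{"triplet"}, \code{"triplet_forgetting"}), \code{lambda},
#'   \code{alpha}, \code{tau_f}. Synapses with rule \code{"none"} are
#'   non-plastic and keep their weight forever.
#' @param stimulators data frame mapping \code{stimulator} ids to
#'   \code{neuron} ids (may be empty).
#' @param taus named list of shared trace decay times in ms:
#'   \code{tau_syn} (synaptic output), \code{tau1} (fast plasticity
#'   trace), \code{tau2} (slow plasticity trace), \code{tau_o}
#'   (averaged-activity trace driving forgetting).
#'
#' @return An object of class \code{"snn_topology"}.
#' @export
snn_topology <- function(neurons, synapses, stimulators = NULL,
                         taus = list(tau_syn = 100, tau1 = 10,
                                     tau2 = 100, tau_o = 100)) {
  if (is.null(stimulators))
    stimulators <- data.frame(stimulator = integer(), neuron = integer())
  net <- structure(list(neurons = neurons, synapses = synapses,
                        stimulators = stimulators, taus = taus),
                   class = "snn_topology")
  validate_topology(net)
  net
}

rule_codes <- c(none = 0L, pair = 1L, triplet = 2L, triplet_forgetting = 3L)

validate_topology <- function(net) {
  nn <- net$neurons
  sy <- net$synapses
  need <- c("id", "layer", "a", "b", "c", "d", "D", "g", "threshold")
  if (!all(need %in% names(nn)))
    stop("neuron table lacks columns: ",
         paste(setdiff(need, names(nn)), collapse = ", "), call. = FALSE)
  if (anyDuplicated(nn$id)) stop("duplicated neuron ids", call. = FALSE)
  if (!all(nn$g %in% c(2, -2)))
    stop("every neuron must have g = +2 or g = -2", call. = FALSE)
  if (any(nn$D < 0)) stop("noise variance D must be >= 0", call. = FALSE)
  if (nrow(sy)) {
    if (!all(c(sy$pre, sy$post) %in% nn$id))
      stop("synapse endpoint refers to an unknown neuron id", call. = FALSE)
    if (any(sy$pre == sy$post)) stop("self-synapses are not allowed",
                                     call. = FALSE)
    if (!all(sy$rule %in% names(rule_codes)))
      stop("unknown plasticity rule; use one of: ",
           paste(names(rule_codes), collapse = ", "), call. = FALSE)
    plast <- sy$rule != "none"
    if (any(sy$w[plast] < 0 | sy$w[plast] > 1))
      stop("plastic synaptic weights must lie in [0, 1]", call. = FALSE)
    if (any(sy$w < 0)) stop("synaptic weights must be >= 0", call. = FALSE)
    if (any(sy$tau_f <= 0)) stop("tau_f must be > 0", call. = FALSE)
  }
  st <- net$stimulators
  if (nrow(st) && !all(st$neuron %in% nn$id))
    stop("stimulator bound to an unknown neuron id", call. = FALSE)
  for (tn in c("tau_syn", "tau1", "tau2", "tau_o"))
    if (!is.numeric(net$taus[[tn]]) || net$taus[[tn]] <= 0)
      stop("trace decay time ", tn, " must be > 0", call. = FALSE)
  invisible(net)
}

neuron_row <- function(id, layer, p) {
  data.frame(id = id, layer = layer, a = p$a, b = p$b, c = p$c, d = p$d,
             D = p$D, g = p$g, threshold = p$threshold)
}

synapse_rows <- function(pre, post, w, rule = "none", lambda = 0.001,
                         alpha = 1, tau_f = 10) {
  data.frame(pre = pre, post = post, w = w, rule = rule,
             lambda = lambda, alpha = alpha, tau_f = tau_f)
}

#' Single-neuron coding testbed
#'
#' Builds the 10-to-1 feed-forward motif used for the temporal- and
#' rate-coding experiments: \code{n_pre} excitatory presynaptic neurons,
#' each driven 1:1 by its own stimulator, all projecting with plastic
#' synapses onto one postsynaptic neuron.
#'
#' @param n_pre number of presynaptic neurons (default 10).
#' @param rule plasticity rule of the converging synapses:
#'   \code{"pair"}, \code{"triplet"} or \code{"triplet_forgetting"}.
#' @param init_w either a single weight for all synapses or a range
#'   \code{c(lo, hi)} sampled uniformly (uses the current RNG state).
#' @param plasticity list overriding \code{lambda}, \code{alpha},
#'   \code{tau_f} of the plastic synapses.
#' @param pre_params,post_params [neuron_params()] for the two layers.
#' @return An \code{snn_topology}; neuron \code{n_pre + 1} is the
#'   postsynaptic neuron.
#' @examples
#' net <- build_single_neuron_testbed(10, rule = "pair")
#' net
#' @export
build_single_neuron_testbed <- function(n_pre = 10,
                                        rule = c("pair", "triplet",
                                                 "triplet_forgetting"),
                                        init_w = 0.5,
                                        plasticity = list(),
                                        pre_params = neuron_params("regular"),
                                        post_params = neuron_params("regular")) {
  rule <- match.arg(rule)
  if (!is.numeric(n_pre) || n_pre < 1)
    stop("n_pre must be >= 1", call. = FALSE)
  n_pre <- as.integer(n_pre)
  pl <- utils::modifyList(list(lambda = 0.001, alpha = 1,
                               tau_f = forgetting_tau_default()),
                          plasticity)
  neurons <- do.call(rbind, c(
    lapply(seq_len(n_pre), function(i)
      neuron_row(i, "presynaptic", pre_params)),
    list(neuron_row(n_pre + 1L, "postsynaptic", post_params))))
  w <- if (length(init_w) == 2) stats::runif(n_pre, init_w[1], init_w[2])
       else rep(init_w, n_pre)
  synapses <- synapse_rows(seq_len(n_pre), n_pre + 1L, w, rule,
                           pl$lambda, pl$alpha, pl$tau_f)
  stimulators <- data.frame(stimulator = seq_len(n_pre),
                            neuron = seq_len(n_pre))
  snn_topology(neurons, synapses, stimulators)
}

#' Two-layer winner-take-all EMG classifier network
#'
#' Builds the classifier network: a sensory layer of \code{n_channels}
#' excitatory neurons (one per EMG channel), each with an inhibitory
#' partner implementing lateral inhibition, plus one noise-driven
#' rest-detector neuron that fires only when the sensory layer is
#' silent; and an output layer of \code{n_classes} excitatory classifier
#' neurons with inhibitory partners providing all-to-other lateral
#' inhibition. All sensory-layer excitatory neurons and the rest
#' detector project to every classifier through plastic synapses
#' (triplet STDP + forgetting); all other synapses are fixed.
#'
#' Wiring defaults (configurable through \code{lateral}): each sensory
#' neuron excites its inhibitory partner (weight 2) and each partner
#' mildly inhibits all other sensory neurons (weight 0.3, contrasting
#' the channel profile without silencing secondary channels); the rest
#' detector receives inhibition (weight 2) from every sensory
#' inhibitory partner and carries strong intrinsic noise so it fires
#' tonically whenever uninhibited; each classifier excites its
#' inhibitory partner (weight 3) and each partner inhibits the other
#' classifiers (weight 4), implementing winner-take-all competition.
#' Fixed synapses
#' are not subject to the multiplicative [0, 1] bound of plastic ones;
#' these gains are chosen so an active classifier reliably drives its
#' interneuron and suppresses its rivals (see the methods vignette).
#'
#' @param n_channels number of EMG channels / sensory neurons (>= 2).
#' @param n_classes number of classifier neurons (>= 2).
#' @param init_w range of the uniform initial plastic weights
#'   (uses the current RNG state).
#' @param plasticity list overriding \code{lambda}, \code{alpha},
#'   \code{tau_f} (forgetting time of the sensory input synapses) and
#'   \code{tau_f_rest} (forgetting time of the rest-detector synapses;
#'   slower, so the tonic rest pathway is pruned by disuse on the
#'   session scale rather than within one gesture).
#' @param lateral list overriding the fixed weights
#'   \code{sens_to_inh}, \code{inh_to_sens}, \code{inh_to_rest},
#'   \code{cls_to_inh}, \code{inh_to_cls}.
#' @param rest_D noise intensity of the rest-detector neuron.
#' @param neuron_D noise intensity of ordinary (sensory and classifier)
#'   neurons; the default keeps an unstimulated neuron below 0.2 Hz
#'   while providing symmetry-breaking jitter.
#' @return An \code{snn_topology} with attributes \code{sensory},
#'   \code{rest}, \code{classifiers} holding the relevant neuron ids;
#'   stimulator \code{j} drives sensory neuron \code{j}.
#' @examples
#' set.seed(1)
#' net <- build_emg_classifier(8, 3)
#' sum(net$synapses$rule != "none") # 27 plastic synapses
#' @export
build_emg_classifier <- function(n_channels = 8, n_classes = 3,
                                 init_w = c(0.25, 0.75),
                                 plasticity = list(),
                                 lateral = list(),
                                 rest_D = 700, neuron_D = 2) {
  if (!is.numeric(n_channels) || n_channels < 2)
    stop("n_channels must be >= 2", call. = FALSE)
  if (!is.numeric(n_classes) || n_classes < 2)
    stop("n_classes must be >= 2", call. = FALSE)
  n_channels <- as.integer(n_channels); n_classes <- as.integer(n_classes)
  pl <- utils::modifyList(
    list(lambda = 0.02, alpha = 1, tau_f = 5e3, tau_f_rest = 6e4),
    plasticity)
  lw <- utils::modifyList(list(sens_to_inh = 2, inh_to_sens = 0.3,
                               inh_to_rest = 2, cls_to_inh = 3,
                               inh_to_cls = 4), lateral)

  sens <- seq_len(n_channels)
  sens_inh <- n_channels + seq_len(n_channels)
  rest <- 2L * n_channels + 1L
  cls <- rest + seq_len(n_classes)
  cls_inh <- rest + n_classes + seq_len(n_classes)

  exc <- neuron_params("regular", D = neuron_D)
  inh <- neuron_params("fast")
  rest_p <- neuron_params("regular", D = rest_D)

  neurons <- do.call(rbind, c(
    lapply(sens, function(i) neuron_row(i, "sensory", exc)),
    lapply(sens_inh, function(i) neuron_row(i, "sensory_inhibitory", inh)),
    list(neuron_row(rest, "rest_detector", rest_p)),
    lapply(cls, function(i) neuron_row(i, "classifier", exc)),
    lapply(cls_inh, function(i) neuron_row(i, "classifier_inhibitory", inh))))

  fixed <- list()
  # sensory lateral inhibition
  fixed$s2i <- synapse_rows(sens, sens_inh, lw$sens_to_inh)
  cross <- expand.grid(i = seq_len(n_channels), j = seq_len(n_channels))
  cross <- cross[cross$i != cross$j, ]
  fixed$i2s <- synapse_rows(sens_inh[cross$i], sens[cross$j], lw$inh_to_sens)
  # rest detector silenced by any sensory activity
  fixed$i2r <- synapse_rows(sens_inh, rest, lw$inh_to_rest)
  # output lateral inhibition
  fixed$c2i <- synapse_rows(cls, cls_inh, lw$cls_to_inh)
  crossc <- expand.grid(i = seq_len(n_classes), j = seq_len(n_classes))
  crossc <- crossc[crossc$i != crossc$j, ]
  fixed$i2c <- synapse_rows(cls_inh[crossc$i], cls[crossc$j], lw$inh_to_cls)
  # plastic inputs to the classifiers
  inputs <- c(sens, rest)
  grid <- expand.grid(pre = inputs, post = cls)
  w0 <- stats::runif(nrow(grid), init_w[1], init_w[2])
  plastic <- synapse_rows(grid$pre, grid$post, w0, "triplet_forgetting",
                          pl$lambda, pl$alpha,
                          ifelse(grid$pre == rest, pl$tau_f_rest,
                                 pl$tau_f))

  synapses <- do.call(rbind, c(fixed, list(plastic)))
  rownames(synapses) <- NULL
  stimulators <- data.frame(stimulator = sens, neuron = sens)

  net <- snn_topology(neurons, synapses, stimulators)
  attr(net, "sensory") <- sens
  attr(net, "rest") <- rest
  attr(net, "classifiers") <- cls
  net
}

#' @export
print.snn_topology <- function(x, ...) {
  cat("Spiking network topology\n")
  tab <- table(x$neurons$layer)
  cat("  neurons: ", nrow(x$neurons), " (",
      paste(names(tab), tab, sep = ": ", collapse = ", "), ")\n", sep = "")
  np <- sum(x$synapses$rule != "none")
  cat("  synapses:", nrow(x$synapses), "of which plastic:", np, "\n")
  if (np)
    cat("  plastic rule:",
        paste(unique(x$synapses$rule[x$synapses$rule != "none"]),
              collapse = ", "), "\n")
  cat("  stimulator bindings:", nrow(x$stimulators), "\n")
  invisible(x)
}

#' Plastic-synapse view of a topology
#'
#' @param net an \code{snn_topology}.
#' @return The rows of the synapse table whose rule is not "none".
#' @export
plastic_synapses <- function(net) {
  net$synapses[net$synapses$rule != "none", , drop = FALSE]
}
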