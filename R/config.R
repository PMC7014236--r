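#' Default run configuration
#'
#' The fully-resolved default configuration covering every tunable of
#' the simulator: neuron dynamics, integration, plasticity, network
#' wiring, stimulation pulse shape, EMG scaling and experiment
#' durations.
#'
#' @return Nested named list of defaults.
#' @export
default_config <- function() {
  list(
    neuron = list(a = 0.02, b = 0.2, c = -65, d = 8, D = 0, g = 2,
                  threshold = 30),
    integration = list(dt_ms = 0.5),
    plasticity = list(rule = "triplet_forgetting", lambda = 0.001,
                      alpha = 1, tau1_ms = 10, tau2_ms = 100,
                      tau_f_ms = forgetting_tau_default(),
                      tau_o_ms = 100),
    network = list(n_channels = 8, n_classes = 3,
                   init_weight_range = c(0.25, 0.75),
                   lateral_weights = list(sens_to_inh = 2,
                                          inh_to_sens = 0.3,
                                          inh_to_rest = 2,
                                          cls_to_inh = 3,
                                          inh_to_cls = 4),
                   rest_detector_D = 700, neuron_D = 2,
                   classifier_lambda = 0.02,
                   classifier_tau_f_ms = 5e3,
                   classifier_tau_f_rest_ms = 6e4),
    stimulation = list(pulse_duration_ms = 3, pulse_amplitude = 15,
                       refractory_ms = 5),
    emg = list(fs_hz = 200, k = 2e6),
    experiment = list(train_s = 1000, test_s = 30, n_seeds = 5),
    seed = 1,
    outdir = "snnemg-run")
}

merge_config <- function(defaults, overrides, path = character()) {
  for (key in names(overrides)) {
    here <- c(path, key)
    if (!key %in% names(defaults)) {
      cand <- names(defaults)[utils::adist(key, names(defaults)) <= 2]
      stop("unknown config key '", paste(here, collapse = "."), "'",
           if (length(cand)) paste0("; did you mean '",
                                    paste(c(path, cand[1]),
                                          collapse = "."), "'?"),
           call. = FALSE)
    }
    d <- defaults[[key]]; o <- overrides[[key]]
    if (is.list(d) && !is.null(names(d))) {
      if (!is.list(o))
        stop("config key '", paste(here, collapse = "."),
             "' must be a section", call. = FALSE)
      defaults[[key]] <- merge_config(d, o, here)
    } else {
      if (is.numeric(d) && !is.numeric(o))
        stop("config key '", paste(here, collapse = "."),
             "' must be numeric", call. = FALSE)
      defaults[[key]] <- o
    }
  }
  defaults
}

#' Load a run configuration file
#'
#' Reads a YAML configuration, validates every key against
#' [default_config()] (unknown keys are rejected with a spelling
#' suggestion, type mismatches are named), and returns the defaults
#' merged with the overrides. An empty or absent override set yields
#' the full defaults.
#'
#' @param path YAML file path.
#' @return The resolved configuration list, classed \code{"snn_config"}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  overrides <- yaml::read_yaml(path)
  if (is.null(overrides)) overrides <- list()
  cfg <- merge_config(default_config(), overrides)
  structure(cfg, class = "snn_config")
}

#' Persist run artifacts with a checksum manifest
#'
#' Writes the standard artifact set of a simulation run — spike raster
#' CSV, weight CSV, a JSON report, the resolved configuration and a
#' plain-text log — and a manifest listing each file with its MD5
#' checksum, so any published run can be verified and reproduced from
#' its persisted configuration and seed.
#'
#' @param sim an [simulate_snn()] result (or \code{NULL}).
#' @param report any JSON-serializable report object (or \code{NULL}).
#' @param config resolved configuration list (or \code{NULL} for
#'   defaults).
#' @param outdir output directory (created if needed).
#' @param log character vector of log lines (time-stamped on write).
#' @return Data frame manifest (file, md5), invisibly; written as
#'   \code{manifest.csv}.
#' @export
write_artifacts <- function(sim = NULL, report = NULL, config = NULL,
                            outdir, log = character()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  if (!is.null(sim)) {
    write_raster(sim, file.path(outdir, "raster.csv"))
    write_weights(sim, file.path(outdir, "weights.csv"))
    files <- c(files, "raster.csv", "weights.csv")
  }
  if (!is.null(report)) {
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    files <- c(files, "report.json")
  }
  if (is.null(config)) config <- default_config()
  yaml::write_yaml(unclass(config), file.path(outdir, "config.yaml"))
  files <- c(files, "config.yaml")
  stamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  writeLines(paste(stamp, c("run artifacts written", log)),
             file.path(outdir, "log.txt"))
  files <- c(files, "log.txt")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(outdir, files))))
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Verify an artifact directory against its manifest
#'
#' @param outdir directory written by [write_artifacts()].
#' @return \code{TRUE} if every checksum matches; otherwise a character
#'   vector of mismatching files.
#' @export
verify_manifest <- function(outdir) {
  manifest <- utils::read.csv(file.path(outdir, "manifest.csv"))
  now <- unname(tools::md5sum(file.path(outdir, manifest$file)))
  bad <- manifest$file[is.na(now) | now != manifest$md5]
  if (!length(bad)) TRUE else bad
}
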