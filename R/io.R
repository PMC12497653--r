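# Experiment container I/O.
#
# An experiment is stored as a directory holding meta.json (schema version,
# sampling attributes, design bookkeeping, ground truth and spontaneous-event
# log when present) plus whitespace-delimited numeric tables ("traces.txt",
# "powers.txt") written with %.17g precision, so a write/read round trip is
# bitwise lossless.

.SCHEMA_VERSION <- 1L

write_mat_txt <- function(m, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(m))) {
    writeLines(paste(sprintf("%.17g", m[i, ]), collapse = " "), con)
  }
}

read_mat_txt <- function(file) {
  lines <- readLines(file)
  do.call(rbind, lapply(strsplit(lines, " ", fixed = TRUE), as.numeric))
}

#' Write an experiment container
#'
#' Serializes an \code{\link{simulate_trialwise}} /
#' \code{\link{simulate_continuous}} record (traces, stimulus design, ground
#' truth and spontaneous-event log when present, plus sampling attributes
#' and a schema version) to a directory of JSON + full-precision text
#' tables. The round trip through \code{\link{read_experiment}} is lossless.
#'
#' @param record an \code{experiment_record}.
#' @param path directory to create/overwrite.
#' @return \code{path}, invisibly.
#' @export
write_experiment <- function(record, path) {
  stopifnot(inherits(record, "experiment_record"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    schema_version = .SCHEMA_VERSION,
    sample_rate = record$sample_rate,
    stim_onset = record$stim_onset,
    dt = record$dt,
    mode = record$mode,
    design = list(power_set = record$design$power_set,
                  holo_targets = unlist(record$design$holograms),
                  holo_sizes = lengths(record$design$holograms),
                  trial_hologram = record$design$trial_hologram,
                  sweep = record$design$sweep,
                  stim_rate = record$design$stim_rate),
    truth = if (!is.null(record$truth)) unclass(record$truth),
    spont = record$spont)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_mat_txt(record$traces, file.path(path, "traces.txt"))
  write_mat_txt(record$design$powers, file.path(path, "powers.txt"))
  if (!is.null(record$target_traces)) {
    write_mat_txt(record$target_traces, file.path(path, "target_traces.txt"))
  }
  invisible(path)
}

#' Read an experiment container
#'
#' @param path directory written by \code{\link{write_experiment}}.
#' @return An \code{experiment_record}.
#' @export
read_experiment <- function(path) {
  meta_file <- file.path(path, "meta.json")
  stop_if(!file.exists(meta_file), "not an experiment container: ", path)
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  stop_if(!identical(as.integer(meta$schema_version), .SCHEMA_VERSION),
          "unsupported schema version: ", meta$schema_version)
  stop_if(!file.exists(file.path(path, "powers.txt")),
          "container is missing the powers dataset")
  traces <- read_mat_txt(file.path(path, "traces.txt"))
  powers <- read_mat_txt(file.path(path, "powers.txt"))
  stop_if(ncol(traces) != .TRIAL_LEN,
          "trace length does not match the 900-sample trial window")
  stop_if(nrow(traces) != ncol(powers),
          "trial count mismatch between traces and powers")
  sizes <- as.integer(meta$design$holo_sizes)
  holograms <- split(as.integer(meta$design$holo_targets),
                     rep(seq_along(sizes), sizes))
  names(holograms) <- NULL
  design <- structure(list(
    powers = powers,
    power_set = meta$design$power_set,
    holograms = holograms,
    trial_hologram = as.integer(meta$design$trial_hologram),
    sweep = as.integer(meta$design$sweep),
    stim_rate = meta$design$stim_rate), class = "stim_design")
  truth <- NULL
  if (!is.null(meta$truth)) {
    truth <- structure(meta$truth, class = "ground_truth")
    truth$phi <- matrix(unlist(meta$truth$phi), ncol = 2,
                        dimnames = list(NULL, c("phi0", "phi1")))
  }
  target <- NULL
  if (file.exists(file.path(path, "target_traces.txt"))) {
    target <- read_mat_txt(file.path(path, "target_traces.txt"))
  }
  structure(list(traces = traces, target_traces = target, design = design,
                 truth = truth, spont = meta$spont, mode = meta$mode,
                 dt = meta$dt, stim_onset = meta$stim_onset,
                 sample_rate = meta$sample_rate),
            class = "experiment_record")
}

#' Export a connectivity table
#'
#' Writes one row per candidate neuron: estimated weight, isotonic spike
#' rate at maximal power, and the connected flag.
#'
#' @param fit a \code{\link{caviar_fit}}.
#' @param file CSV path.
#' @return The table, invisibly.
#' @export
export_connectivity <- function(fit, file) {
  fmax <- vapply(fit$power_curves, curve_at_max, numeric(1))
  tab <- data.frame(neuron = seq_along(fit$weights),
                    weight = fit$weights,
                    spike_rate_max_power = fmax,
                    connected = fit$connected)
  utils::write.csv(tab, file, row.names = FALSE)
  invisible(tab)
}
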