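# Container and configuration IO: versioned binary container for the
# pipeline's array-carrying objects, TSV serialisation for trial
# sequences/events, YAML round-tripping for run configurations.

.container_format <- "nbackerp-container"
.container_version <- 1L

#' Write a dataset to the internal container format
#'
#' Serialises a pipeline object (continuous recording, epoch set, ICA
#' model, cleaning montage, evoked) together with a typed, versioned
#' metadata block. Files are validated on read.
#'
#' @param dataset one of the pipeline's S3 objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_container <- function(dataset, path) {
  ok <- c("continuous_recording", "epoch_set", "ica_model",
          "cleaning_montage", "evoked", "cohort")
  if (!inherits(dataset, ok))
    stop("unsupported dataset class: ", class(dataset)[1])
  obj <- list(meta = list(format = .container_format,
                          version = .container_version,
                          type = class(dataset)[1],
                          created = format(Sys.time(), tz = "UTC")),
              payload = dataset)
  saveRDS(obj, path, version = 2)
  invisible(path)
}

#' Read a dataset from the internal container format
#'
#' @param path file written by [write_container()].
#' @return the stored object.
#' @export
read_container <- function(path) {
  if (!file.exists(path)) stop("no such container: ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("truncated or unreadable container: ",
                                           path, call. = FALSE))
  if (!is.list(obj) || is.null(obj$meta))
    stop("container is missing its metadata block: ", path)
  m <- obj$meta
  if (!identical(m$format, .container_format))
    stop("not a ", .container_format, " file: ", path)
  if (!identical(as.integer(m$version), .container_version))
    stop("container version mismatch: file has ", m$version,
         ", reader expects ", .container_version)
  if (!identical(class(obj$payload)[1], m$type))
    stop("container payload type does not match its metadata")
  obj$payload
}

#' Write a trial sequence or event table to TSV
#'
#' One row per trial: block, level, position, symbol, is_target,
#' onset_ms and any response columns present.
#'
#' @param x a `trial_sequence` or event data.frame.
#' @param path output path.
#' @export
write_events_tsv <- function(x, path) {
  df <- as.data.frame(x)
  if (inherits(x, "trial_sequence")) {
    df$level <- attr(x, "level")
    df$block <- 1L
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

.config_defaults <- function() {
  list(
    n_per_group = 16L, seed = 1L, out_dir = "nbackerp-out",
    rate = 512, target_rate = 200,
    highpass = 0.1, lowpass = 120, notch = c(48, 52),
    epoch_window = c(-600, 1400), baseline = c(-100, 0),
    crop = c(-100, 900), lowpass_post = 30,
    rejection_uV = 120, n_components = 32L, z_threshold = 2,
    bad_channel_force = "TP7",
    block_levels = c(1, 2, 2, 1), n_trials = 100L, n_targets = 25L,
    windows = list(full = c(300, 700), early = c(300, 500),
                   late = c(500, 700)),
    alpha = 0.05, fdr_q = 0.10,
    group_scale = 1, noise_rms_uV = 12
  )
}

#' Pipeline run configuration
#'
#' Builds a validated configuration with the study defaults; unknown
#' keys are rejected. Round-trips losslessly through YAML via
#' [write_run_config()] / [read_run_config()].
#'
#' @param ... overrides of the default fields.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- .config_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Stable hash of a configuration (for cache validation)
#'
#' @param config any serialisable object.
#' @return md5 hex string.
#' @export
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f, version = 2)
  unname(tools::md5sum(f))
}
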