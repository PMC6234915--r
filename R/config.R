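phasefuse_defaults <- function() {
  list(
    variant = "gray",
    filter_blue = FALSE,
    blue_delta = 0.05,
    crop = FALSE,
    crop_pad = 0,
    h_threshold = 0.03,
    scale_min = 0.1,
    scale_max = 1.0,
    step = 0.02,
    bounds = default_bounds(),
    interpolation = list(intensity = "bilinear", mask = "nearest"),
    seed = NULL,
    log_level = "info"
  )
}

#' Load a run configuration
#'
#' Reads a YAML configuration file and fills in package defaults for any
#' key not present. Defaults mirror the standard operating point:
#' peak-height gate `h_threshold = 0.03`, scale sweep from 0.1 to 1.0 in
#' steps of 0.02, grayscale preprocessing. Unknown keys are rejected so
#' typos fail loudly. `path = NULL` or an empty file returns the defaults.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A `run_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- phasefuse_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- tryCatch(yaml::read_yaml(path), error = function(e)
      stop("config parse error in '", path, "': ", conditionMessage(e),
           call. = FALSE))
    if (is.null(user)) user <- list()
    if (!is.list(user)) stop("config must be a YAML mapping", call. = FALSE)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown) > 0)
      stop("unknown config keys: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    for (k in names(user)) {
      if (k %in% c("bounds", "interpolation") && is.list(user[[k]])) {
        sub_unknown <- setdiff(names(user[[k]]), names(cfg[[k]]))
        if (length(sub_unknown) > 0)
          stop("unknown config keys: ",
               paste(paste0(k, ".", sub_unknown), collapse = ", "),
               call. = FALSE)
        cfg[[k]][names(user[[k]])] <- user[[k]]
      } else {
        cfg[[k]] <- user[[k]]
      }
    }
  }
  structure(cfg, class = "run_config")
}

#' Sweep configuration from a run configuration
#'
#' @param cfg A `run_config` from [load_config()].
#' @return A [scale_sweep_config()].
#' @export
as_sweep_config <- function(cfg) {
  scale_sweep_config(
    scale_min = cfg$scale_min, scale_max = cfg$scale_max, step = cfg$step,
    variant = cfg$variant, h_threshold = cfg$h_threshold,
    bounds = do.call(default_bounds, cfg$bounds),
    filter_blue = isTRUE(cfg$filter_blue))
}

#' Serialize a run configuration
#'
#' Writes the effective configuration next to a run's outputs so every
#' result is reproducible from its directory.
#' @param cfg A `run_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
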