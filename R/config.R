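#' @include AllClasses.R
NULL

#' Default run configuration
#'
#' All defaults are the acquisition protocol's values: the 24-frame
#' 8x30/8x60/6x180/2x300 s schedule, Patlak window 16-40 min,
#' Km = 130 mg/dL, threshold fractions 0.40 (myocardium, last frame)
#' and 0.60 (vena cava, first uptake frame), 10-voxel/10-slice muscle
#' cylinders.
#'
#' @return A named list of class `RunConfig`.
#' @export
defaultConfig <- function() {
  structure(list(
    seed = 1L,
    frame_schedule = list(durations_s = c(rep(30, 8), rep(60, 8),
                                          rep(180, 6), rep(300, 2))),
    patlak = list(window_min = c(16, 40), eps_fraction = 1e-3),
    mrglu = list(km_mg_dl = 130),
    roi = list(threshold_fraction = 0.40,
               cava_fraction = 0.60,
               uptake_fraction = 0.05,
               cylinder = list(diameter_px = 10, n_slices = 10)),
    units = list(insulin_factor = 25.0),
    noise = list(scale = 0, floor = 0.01)),
    class = "RunConfig")
}

.mergeConfig <- function(base, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste(path, key, sep = ".") else key
    if (!key %in% names(base))
      stop("unknown configuration key: ", full)
    if (is.list(base[[key]]) && !is.null(user[[key]])) {
      if (!is.list(user[[key]]))
        stop("configuration key ", full, " must be a mapping")
      base[[key]] <- .mergeConfig(base[[key]], user[[key]], full)
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

.validateConfig <- function(cfg) {
  bad <- character()
  w <- cfg$patlak$window_min
  if (length(w) != 2L || !(w[1] < w[2]))
    bad <- c(bad, "patlak.window_min: lower bound must be below upper")
  if (cfg$mrglu$km_mg_dl <= 0)
    bad <- c(bad, "mrglu.km_mg_dl: Km must be > 0")
  for (k in c("threshold_fraction", "cava_fraction", "uptake_fraction")) {
    v <- cfg$roi[[k]]
    if (!is.numeric(v) || v <= 0 || v >= 1)
      bad <- c(bad, sprintf("roi.%s: must be in (0, 1)", k))
  }
  if (any(cfg$frame_schedule$durations_s <= 0))
    bad <- c(bad, "frame_schedule.durations_s: durations must be > 0")
  if (cfg$noise$scale < 0)
    bad <- c(bad, "noise.scale: must be >= 0")
  if (cfg$units$insulin_factor <= 0)
    bad <- c(bad, "units.insulin_factor: must be > 0")
  if (length(bad))
    stop("invalid configuration:\n  ", paste(bad, collapse = "\n  "))
  cfg
}

#' Load and validate a run configuration
#'
#' Reads a YAML file, fills unspecified entries from [defaultConfig()],
#' rejects unknown keys, and validates every constraint, reporting all
#' violations at once. `path = NULL` (or an empty file) yields the full
#' default configuration.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A validated `RunConfig` list.
#' @examples
#' cfg <- loadConfig()
#' cfg$mrglu$km_mg_dl  # 130
#' @export
loadConfig <- function(path = NULL) {
  cfg <- defaultConfig()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (!is.null(user)) {
      if (!is.list(user)) stop("config file must be a YAML mapping")
      cfg <- structure(.mergeConfig(unclass(cfg), user), class = "RunConfig")
    }
  }
  .validateConfig(cfg)
}
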