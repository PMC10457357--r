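#' @include AllClasses.R
NULL

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE))
}

.configHash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(unclass(cfg), f, version = 2)
  unname(tools::md5sum(f))
}

# derive search volumes for the phantom anatomy from its geometry
.phantomSearches <- function(image, spec) {
  geo <- spec@geometry
  dm <- spec@dim
  hc <- geo$heartCenter; hr <- ceiling(geo$heartOuterR) + 2L
  heart <- boxMask(image,
                   c(max(1L, hc[1] - hr), min(dm[1], hc[1] + hr)),
                   c(max(1L, hc[2] - hr), min(dm[2], hc[2] + hr)),
                   c(max(1L, hc[3] - hr), min(dm[3], hc[3] + hr)))
  cc <- geo$cavaCenter; cr <- ceiling(geo$cavaRadius) + 3L
  cava <- boxMask(image,
                  c(max(1L, cc[1] - cr), min(dm[1], cc[1] + cr)),
                  c(max(1L, cc[2] - cr), min(dm[2], cc[2] + cr)),
                  c(geo$cavaZ[1], geo$cavaZ[2]))
  list(heart = heart, cava = cava)
}

#' Run the full quantification pipeline
#'
#' Ties simulation, ROI construction, TAC extraction, Patlak fitting
#' and the MRglu computation into one reproducible run. Every numeric
#' stage is the corresponding exported function — the pipeline only
#' orchestrates.
#'
#' Input is either a phantom request (`phantom =` a
#' [PhantomSpec-class]; the image is simulated with the config's seed
#' and noise scale, and search volumes are derived from the phantom
#' geometry) or a measured `image` plus explicit search volumes in
#' `searches` (a list with elements `heart` and `cava`, each an
#' [ROIMask-class], plus optionally `muscleCenters`, a list of
#' length-3 voxel indices for the muscle cylinders).
#'
#' @param config A `RunConfig` from [loadConfig()].
#' @param phantom Optional [PhantomSpec-class] simulation request.
#' @param image Optional [DynamicImage-class] (ignored when `phantom`
#'   is given).
#' @param searches Search volumes for a measured image (see above).
#' @param glucose Blood glucose samples taken during the scan.
#' @param glucoseUnit Their unit, default `"mmol/L"`.
#' @param plasma Plasma model driving a phantom simulation.
#' @param kiMap Also compute the voxelwise Ki map? Default `FALSE`.
#' @return A result bundle: list with `config`, `image`, `masks`,
#'   `tacs`, `idif`, `fits`, `mrglu` (per region), optionally `kiMap`,
#'   and `manifest` (config hash, derived thresholds, stage timings,
#'   warnings).
#' @examples
#' \donttest{
#' bundle <- runPipeline(loadConfig(),
#'                       phantom = phantomSpec(dim = c(32, 32, 24)),
#'                       glucose = c(10, 11, 12))
#' bundle$fits$muscle
#' }
#' @export
runPipeline <- function(config = loadConfig(), phantom = NULL, image = NULL,
                        searches = NULL, glucose = NULL,
                        glucoseUnit = "mmol/L", plasma = plasmaModel(),
                        kiMap = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    timings[[name]] <<- t1 - t0
    t0 <<- t1
  }
  warningsSeen <- character()

  sch <- frameSchedule(config$frame_schedule$durations_s)
  muscleCenters <- NULL
  if (!is.null(phantom)) {
    image <- .stage("simulate", {
      stopifnot(methods::is(phantom, "PhantomSpec"))
      spec <- phantom
      spec@schedule <- sch
      spec@noiseScale <- config$noise$scale
      spec@seed <- as.integer(config$seed)
      buildPhantom(spec, plasma)
    })
    searches <- .phantomSearches(image, phantom)
    muscleCenters <- lapply(phantom@geometry$muscleCenters, function(ctr)
      c(ctr, phantom@geometry$muscleZ1))
    tick("simulate")
  }
  if (is.null(image)) stop("stage 'input': either an image or a phantom request is required")
  if (is.null(searches$heart) || is.null(searches$cava))
    stop("stage 'input': search volumes 'heart' and 'cava' are required")
  if (is.null(muscleCenters)) muscleCenters <- searches$muscleCenters
  if (is.null(muscleCenters))
    stop("stage 'input': muscle cylinder centers are required")

  cyl <- config$roi$cylinder
  masks <- .stage("roi", {
    muscles <- lapply(muscleCenters, function(ctr)
      cylinderROI(image, ctr, cyl$diameter_px, cyl$n_slices))
    muscleMask <- Reduce(`|`, lapply(muscles, maskArray))
    list(muscle = methods::new("ROIMask", mask = muscleMask,
                               provenance = list(kind = "cylinder_union",
                                                 n = length(muscles))),
         myocardium = thresholdROILastFrame(image, searches$heart,
                                            config$roi$threshold_fraction),
         vena_cava = venaCavaROI(image, searches$cava,
                                 config$roi$cava_fraction,
                                 config$roi$uptake_fraction))
  })
  tick("roi")

  tacs <- .stage("tac", lapply(masks, function(m)
    extractTAC(image, m)))
  idif <- tacs$vena_cava
  tick("tac")

  fits <- .stage("patlak", {
    lapply(tacs[c("muscle", "myocardium")], function(tac)
      fitPatlak(patlakTransform(tac, idif, config$patlak$eps_fraction),
                config$patlak$window_min))
  })
  tick("patlak")

  mrgluRes <- .stage("mrglu", {
    if (is.null(glucose))
      stop("blood glucose samples are missing (argument 'glucose')")
    panel <- meanCglu(glucose, glucoseUnit)
    lapply(fits, function(f) mrgluMax(f, panel, config$mrglu$km_mg_dl))
  })
  tick("mrglu")

  kiMapRes <- NULL
  if (isTRUE(kiMap)) {
    kiMapRes <- .stage("ki_map", {
      body <- if (!is.null(tissueLabels(image)))
        tissueLabels(image) > 0 else array(TRUE, dim(image@data)[1:3])
      patlakParametricMap(image, idif, config$patlak$window_min, body,
                          config$patlak$eps_fraction)
    })
    tick("ki_map")
  }

  manifest <- list(
    config_hash = .configHash(config),
    package_version = as.character(utils::packageVersion("PatlakPET")),
    thresholds = list(
      myocardium_kBq_ml = maskProvenance(masks$myocardium)$threshold_kBq_ml,
      vena_cava_kBq_ml = maskProvenance(masks$vena_cava)$threshold_kBq_ml,
      vena_cava_reference_frame =
        maskProvenance(masks$vena_cava)$reference_frame),
    stage_seconds = as.list(timings),
    warnings = warningsSeen)

  list(config = config, image = image, masks = masks, tacs = tacs,
       idif = idif, fits = fits, mrglu = mrgluRes, kiMap = kiMapRes,
       manifest = manifest)
}
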