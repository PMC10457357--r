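#' @include AllClasses.R
NULL

#' Specify a simulated mito-stress plate
#'
#' @param ocr OCR plateau means per phase (pmol O2/min), in the fixed
#'   order baseline, oligomycin, FCCP, rotenone+antimycin.
#' @param ecar ECAR plateau means per phase (mpH/min).
#' @param nPerPhase Measurements per phase, default 3.
#' @param nWells Replicate wells, default 5.
#' @param ocrSd,ecarSd Gaussian measurement noise SDs, default 2 and 0.5.
#' @param condition Condition label.
#' @param seed Integer seed.
#' @return A [MitoTraceSpec-class].
#' @seealso [mitoPreset()] for ready-made control/uncoupled plateaus.
#' @export
mitoTraceSpec <- function(ocr, ecar, nPerPhase = 3L, nWells = 5L,
                          ocrSd = 2, ecarSd = 0.5,
                          condition = "condition", seed = 1L) {
  methods::new("MitoTraceSpec",
               ocr = stats::setNames(as.numeric(ocr), .mitoPhases),
               ecar = stats::setNames(as.numeric(ecar), .mitoPhases),
               nPerPhase = as.integer(nPerPhase), nWells = as.integer(nWells),
               ocrSd = as.numeric(ocrSd), ecarSd = as.numeric(ecarSd),
               condition = condition, seed = as.integer(seed))
}

#' Preset mito-stress plate specifications
#'
#' `"control"`: ordinary coupled respiration (baseline 100, oligomycin
#' 40, FCCP 160, rotenone+antimycin 10 pmol O2/min). `"uncoupled"`:
#' an uncoupler-treated culture — baseline raised, and crucially the
#' post-oligomycin plateau raised (70 vs 40), i.e. a larger proton
#' leak, with a higher basal OCR/ECAR ratio (oxidative preference).
#'
#' @param condition `"control"` or `"uncoupled"`.
#' @param ... Passed on to [mitoTraceSpec()] (e.g. `nWells`, `seed`,
#'   noise SDs).
#' @return A [MitoTraceSpec-class].
#' @export
mitoPreset <- function(condition = c("control", "uncoupled"), ...) {
  condition <- match.arg(condition)
  if (condition == "control")
    mitoTraceSpec(ocr = c(100, 40, 160, 10), ecar = c(20, 25, 30, 15),
                  condition = "control", ...)
  else
    mitoTraceSpec(ocr = c(130, 70, 165, 10), ecar = c(18, 22, 30, 14),
                  condition = "uncoupled", ...)
}

#' Simulate a mito-stress plate
#'
#' Per-well OCR and ECAR sequences: `nPerPhase` measurements at each
#' phase plateau plus Gaussian noise (clipped at zero), with phase
#' annotations and a running measurement index.
#'
#' @param spec A [MitoTraceSpec-class].
#' @return Data frame with columns `well`, `condition`,
#'   `measurement_index`, `phase`, `ocr`, `ecar` — the on-disk plate
#'   CSV layout.
#' @examples
#' plate <- simulateMitoPlate(mitoPreset("control", ocrSd = 0, ecarSd = 0))
#' @export
simulateMitoPlate <- function(spec) {
  stopifnot(methods::is(spec, "MitoTraceSpec"))
  phase <- rep(.mitoPhases, each = spec@nPerPhase)
  nm <- length(phase)
  withSeed(spec@seed, {
    out <- do.call(rbind, lapply(seq_len(spec@nWells), function(w) {
      ocr <- spec@ocr[phase] + stats::rnorm(nm, 0, spec@ocrSd)
      ecar <- spec@ecar[phase] + stats::rnorm(nm, 0, spec@ecarSd)
      data.frame(well = sprintf("%s_W%02d", spec@condition, w),
                 condition = spec@condition,
                 measurement_index = seq_len(nm), phase = phase,
                 ocr = pmax(ocr, 0), ecar = pmax(ecar, 0))
    }))
    rownames(out) <- NULL
    out
  })
}
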