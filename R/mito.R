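#' @include AllClasses.R
NULL

.defaultPhaseRules <- c(baseline = "last", oligomycin = "min",
                        fccp = "max", rot_aa = "min")

.applyRule <- function(values, rule) {
  switch(rule,
         last = values[length(values)],
         first = values[1],
         min = min(values),
         max = max(values),
         mean = mean(values),
         stop("unknown phase rule: ", rule))
}

#' Per-phase OCR summaries of a mito-stress trace
#'
#' Vendor-convention defaults: the last baseline measurement, the
#' minimum within the oligomycin phase, the maximum within the FCCP
#' phase, and the minimum within the rotenone+antimycin phase. Each
#' rule is configurable (`"last"`, `"first"`, `"min"`, `"max"`,
#' `"mean"`).
#'
#' @param trace Data frame for one well with columns `phase` and `ocr`
#'   (rows in measurement order).
#' @param rules Named character vector of summary rules per phase.
#' @return Named numeric length-4 of summary OCR values.
#' @examples
#' tr <- data.frame(phase = rep(c("baseline", "oligomycin", "fccp",
#'                                "rot_aa"), each = 3),
#'                  ocr = c(98, 101, 100, 45, 40, 42, 150, 160, 155,
#'                          12, 10, 11))
#' phaseSummaries(tr)  # 100, 40, 160, 10
#' @export
phaseSummaries <- function(trace, rules = .defaultPhaseRules) {
  stopifnot(is.data.frame(trace), all(c("phase", "ocr") %in% names(trace)))
  missing <- setdiff(.mitoPhases, unique(trace$phase))
  if (length(missing))
    stop("trace is missing phase(s): ", paste(missing, collapse = ", "))
  vapply(.mitoPhases, function(ph)
    .applyRule(trace$ocr[trace$phase == ph], rules[[ph]]), numeric(1))
}

#' Mito-stress respirometry parameters of one well
#'
#' From the phase summaries: non-mitochondrial respiration is the
#' rotenone+antimycin summary; basal = baseline - non-mito; proton
#' leak = oligomycin - non-mito; ATP-linked = basal - proton leak;
#' maximal = FCCP - non-mito; spare capacity = maximal - basal;
#' coupling efficiency = ATP-linked / basal (NA when basal <= 0). The
#' conservation identities `basal = atp_linked + proton_leak` and
#' `spare_capacity = maximal - basal` hold exactly by construction.
#' A negative basal or maximal rate is flagged, not raised.
#'
#' If the trace carries an `ecar` column and a measurement index, the
#' basal OCR/ECAR preference ratio at the last baseline measurement is
#' included (see [ocrEcarRatio()]).
#'
#' @inheritParams phaseSummaries
#' @return One-row data frame: `non_mito`, `basal`, `atp_linked`,
#'   `proton_leak`, `maximal`, `spare_capacity`,
#'   `coupling_efficiency`, `ocr_ecar_ratio` (NA when ECAR is absent),
#'   `flags`.
#' @examples
#' tr <- data.frame(phase = rep(c("baseline", "oligomycin", "fccp",
#'                                "rot_aa"), each = 1),
#'                  ocr = c(100, 40, 160, 10))
#' mitoParams(tr)
#' @export
mitoParams <- function(trace, rules = .defaultPhaseRules) {
  s <- phaseSummaries(trace, rules)
  nonMito <- s[["rot_aa"]]
  basal <- s[["baseline"]] - nonMito
  leak <- s[["oligomycin"]] - nonMito
  atp <- basal - leak
  maximal <- s[["fccp"]] - nonMito
  spare <- maximal - basal
  flags <- character()
  if (basal < 0) flags <- c(flags, "negative_basal")
  if (maximal < 0) flags <- c(flags, "negative_maximal")
  ratio <- if ("ecar" %in% names(trace)) {
    r <- try(ocrEcarRatio(trace), silent = TRUE)
    if (inherits(r, "try-error")) NA_real_ else r
  } else NA_real_
  data.frame(non_mito = nonMito, basal = basal, atp_linked = atp,
             proton_leak = leak, maximal = maximal, spare_capacity = spare,
             coupling_efficiency = if (basal > 0) atp / basal else NA_real_,
             ocr_ecar_ratio = ratio,
             flags = paste(flags, collapse = ";"))
}

#' Basal oxidative-vs-glycolytic preference ratio
#'
#' OCR divided by ECAR at the last baseline measurement (measurement 3
#' under the default three-measurement baseline) — a higher ratio
#' indicates preference for oxidative over glycolytic metabolism.
#'
#' @param trace Data frame for one well with columns
#'   `measurement_index`, `phase`, `ocr`, `ecar`.
#' @param measurementIndex Which measurement to use; default 3. Must
#'   exist and be a baseline measurement.
#' @return Scalar ratio; `NA` when ECAR is zero there.
#' @export
ocrEcarRatio <- function(trace, measurementIndex = 3L) {
  stopifnot(is.data.frame(trace),
            all(c("measurement_index", "phase", "ocr", "ecar") %in%
                  names(trace)))
  row <- trace[trace$measurement_index == measurementIndex, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("measurement ", measurementIndex, " not present (or not unique)")
  if (row$phase != "baseline")
    stop("measurement ", measurementIndex, " is not a baseline measurement")
  if (row$ecar <= 0) return(NA_real_)
  row$ocr / row$ecar
}

#' Mito-stress parameters per well and per condition
#'
#' Applies [mitoParams()] to every well of a plate table, then
#' summarises each condition as mean and standard error of the mean
#' over its wells.
#'
#' @param plate Plate data frame with columns `well`, `condition`,
#'   `measurement_index`, `phase`, `ocr`, `ecar` (the
#'   [simulateMitoPlate()] layout).
#' @param rules Phase summary rules (see [phaseSummaries()]).
#' @return List with `perWell` (one row per well, with `well` and
#'   `condition` columns) and `perCondition` (mean and `sem_` columns
#'   per parameter).
#' @export
mitoParamsByWell <- function(plate, rules = .defaultPhaseRules) {
  need <- c("well", "condition", "measurement_index", "phase", "ocr", "ecar")
  if (!all(need %in% names(plate)))
    stop("plate table must have columns: ", paste(need, collapse = ", "))
  wells <- split(plate, plate$well)
  perWell <- do.call(rbind, lapply(names(wells), function(w) {
    d <- wells[[w]][order(wells[[w]]$measurement_index), ]
    cbind(data.frame(well = w, condition = d$condition[1]),
          mitoParams(d, rules))
  }))
  rownames(perWell) <- NULL
  params <- c("non_mito", "basal", "atp_linked", "proton_leak", "maximal",
              "spare_capacity", "coupling_efficiency", "ocr_ecar_ratio")
  conds <- split(perWell, perWell$condition)
  perCondition <- do.call(rbind, lapply(names(conds), function(cn) {
    d <- conds[[cn]]
    row <- data.frame(condition = cn, n = nrow(d))
    for (p in params) {
      row[[p]] <- mean(d[[p]], na.rm = TRUE)
      row[[paste0("sem_", p)]] <-
        stats::sd(d[[p]], na.rm = TRUE) / sqrt(sum(is.finite(d[[p]])))
    }
    row
  }))
  rownames(perCondition) <- NULL
  list(perWell = perWell, perCondition = perCondition)
}
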