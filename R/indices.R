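#' @include AllClasses.R
NULL

#' HOMA-IR insulin resistance index
#'
#' Homeostasis-model surrogate of insulin resistance from a fasted
#' sample pair:
#' \deqn{HOMA\mbox{-}IR = \frac{glucose\ (mmol/L) \times
#'   insulin\ (\mu U/mL)}{22.5}.}
#' Vectorised over samples; bilinear in both inputs.
#'
#' @param glucose Fasting blood glucose, mmol/L; must be positive.
#' @param insulin Fasting plasma insulin, microU/mL; must be >= 0.
#' @return Unitless index values.
#' @examples
#' homaIR(22.5, 1)   # 1
#' homaIR(7, 30)     # 9.333...
#' @export
homaIR <- function(glucose, insulin) {
  if (any(!is.finite(glucose)) || any(glucose <= 0))
    stop("glucose must be positive (mmol/L)")
  if (any(!is.finite(insulin)) || any(insulin < 0))
    stop("insulin must be >= 0 (uU/mL)")
  glucose * insulin / 22.5
}

#' HOMA-beta beta-cell function index
#'
#' \deqn{HOMA\mbox{-}\beta = \frac{20 \times insulin\ (\mu U/mL)}
#'   {glucose\ (mmol/L) - 3.5}.}
#' At glucose at or below 3.5 mmol/L the denominator leaves the model's
#' physiological range; such samples return `NA` (a typed undefined,
#' not an error or an infinity).
#'
#' @inheritParams homaIR
#' @return Index values; `NA` where glucose <= 3.5 mmol/L.
#' @examples
#' homaBeta(4.5, 20)    # 400
#' homaBeta(23.5, 10)   # 10
#' homaBeta(3.5, 20)    # NA
#' @export
homaBeta <- function(glucose, insulin) {
  if (any(!is.finite(glucose)) || any(glucose <= 0))
    stop("glucose must be positive (mmol/L)")
  if (any(!is.finite(insulin)) || any(insulin < 0))
    stop("insulin must be >= 0 (uU/mL)")
  ifelse(glucose > 3.5, 20 * insulin / (glucose - 3.5), NA_real_)
}

.unitAliases <- c("uU/mL" = "uU/mL", "µU/mL" = "uU/mL",
                  "mg/dL" = "mg/dL", "mmol/L" = "mmol/L",
                  "ng/mL" = "ng/mL")

#' Convert glucose and insulin concentration units
#'
#' Glucose converts between mg/dL and mmol/L at 18.016 mg/dL per
#' mmol/L. Insulin converts between ng/mL (typical ELISA output) and
#' microU/mL (what HOMA needs) via `insulinFactor` microU per ng; the
#' factor is configurable because published mass-to-activity factors
#' vary.
#'
#' @param value Numeric value(s).
#' @param from,to Unit strings: `"mg/dL"`, `"mmol/L"`, `"ng/mL"`,
#'   `"uU/mL"`.
#' @param insulinFactor microU/mL per ng/mL, default 25.
#' @return Converted value(s).
#' @examples
#' convertUnits(1, "mmol/L", "mg/dL")    # 18.016
#' convertUnits(0.4, "ng/mL", "uU/mL")   # 10
#' @export
convertUnits <- function(value, from, to, insulinFactor = 25.0) {
  norm <- function(u) {
    if (!u %in% names(.unitAliases)) stop("unknown unit: ", u)
    .unitAliases[[u]]
  }
  from <- norm(from); to <- norm(to)
  if (from == to) return(value)
  key <- paste(from, to, sep = "->")
  switch(key,
    "mmol/L->mg/dL" = value * 18.016,
    "mg/dL->mmol/L" = value / 18.016,
    "ng/mL->uU/mL" = value * insulinFactor,
    "uU/mL->ng/mL" = value / insulinFactor,
    stop("no conversion defined for ", key))
}

#' Trapezoid area under a longitudinal curve
#'
#' Composite trapezoid rule over the observed span, in value-weeks (or
#' value times whatever the time unit is). Pairs with a missing value
#' are excluded with a warning.
#'
#' @param times Strictly increasing observation times (>= 2 after
#'   missing-value removal).
#' @param values Observed values; may contain `NA`.
#' @return Scalar AUC.
#' @examples
#' trapezoidAUC(0:9, rep(5, 10))   # 45
#' trapezoidAUC(c(0, 10), c(0, 10))  # 50
#' @export
trapezoidAUC <- function(times, values) {
  if (length(times) != length(values)) stop("times and values must match")
  keep <- is.finite(values) & is.finite(times)
  if (!all(keep)) {
    warning(sum(!keep), " missing value(s) excluded from AUC")
    times <- times[keep]; values <- values[keep]
  }
  if (length(times) < 2L)
    stop("insufficient data: AUC needs >= 2 observed points")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  sum((values[-1] + values[-length(values)]) / 2 * diff(times))
}

#' Per-subject and per-arm metabolic indices of a cohort table
#'
#' Adds HOMA-IR and HOMA-beta per record (converting insulin to
#' microU/mL when recorded in ng/mL), then summarises per subject
#' (AUC of glucose, insulin and both indices over the observed weeks)
#' and per arm (means of the subject AUCs).
#'
#' @param cohort Long-format data frame with columns `subject`, `arm`,
#'   `week`, `glucose`, `glucose_unit`, `insulin`, `insulin_unit` (the
#'   layout written by [simulateCohort()]).
#' @param insulinFactor microU/mL per ng/mL for ELISA-reported insulin.
#' @return List with `samples` (input plus `homa_ir`, `homa_beta`
#'   columns), `perSubject` and `perArm` data frames.
#' @export
cohortIndices <- function(cohort, insulinFactor = 25.0) {
  need <- c("subject", "arm", "week", "glucose", "glucose_unit",
            "insulin", "insulin_unit")
  if (!all(need %in% names(cohort)))
    stop("cohort table must have columns: ", paste(need, collapse = ", "))
  glu <- ifelse(cohort$glucose_unit == "mg/dL",
                cohort$glucose / 18.016, cohort$glucose)
  ins <- ifelse(cohort$insulin_unit == "ng/mL",
                cohort$insulin * insulinFactor, cohort$insulin)
  samples <- cohort
  samples$homa_ir <- homaIR(glu, ins)
  samples$homa_beta <- homaBeta(glu, ins)
  aucOf <- function(col) {
    vapply(split(samples, samples$subject), function(d) {
      d <- d[order(d$week), ]
      suppressWarnings(trapezoidAUC(d$week, d[[col]]))
    }, numeric(1))
  }
  subjects <- split(samples, samples$subject)
  perSubject <- data.frame(
    subject = names(subjects),
    arm = vapply(subjects, function(d) d$arm[1], character(1)),
    glucose_auc = aucOf("glucose"),
    insulin_auc = aucOf("insulin"),
    homa_ir_auc = aucOf("homa_ir"),
    homa_beta_auc = vapply(subjects, function(d) {
      d <- d[order(d$week), ]
      if (sum(is.finite(d$homa_beta)) < 2L) NA_real_
      else suppressWarnings(trapezoidAUC(d$week, d$homa_beta))
    }, numeric(1)),
    row.names = NULL)
  arms <- split(perSubject, perSubject$arm)
  perArm <- data.frame(
    arm = names(arms),
    n = vapply(arms, nrow, integer(1)),
    glucose_auc = vapply(arms, function(d) mean(d$glucose_auc), numeric(1)),
    insulin_auc = vapply(arms, function(d) mean(d$insulin_auc), numeric(1)),
    homa_ir_auc = vapply(arms, function(d) mean(d$homa_ir_auc), numeric(1)),
    homa_beta_auc = vapply(arms, function(d)
      mean(d$homa_beta_auc, na.rm = TRUE), numeric(1)),
    row.names = NULL)
  list(samples = samples, perSubject = perSubject, perArm = perArm)
}
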