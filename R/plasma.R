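#' @include AllClasses.R
NULL

#' Construct a parametric plasma input model
#'
#' Defaults describe a mouse FDG bolus: a sharp peak near 0.4 min of a
#' few hundred kBq/mL, a fast clearance component and a slowly decaying
#' tail that still holds tens of kBq/mL at 40 min.
#'
#' @param amplitudes Term amplitudes, kBq/mL.
#' @param decayRates Term decay rates, 1/min.
#' @param riseRate Common rise rate, 1/min; must exceed every decay rate.
#' @return A [PlasmaModel-class].
#' @examples
#' pm <- plasmaModel()
#' evalPlasma(pm, c(0, 0.5, 5, 40))
#' @export
plasmaModel <- function(amplitudes = c(350, 80),
                        decayRates = c(0.9, 0.008),
                        riseRate = 5) {
  methods::new("PlasmaModel", amplitudes = as.numeric(amplitudes),
               decayRates = as.numeric(decayRates),
               riseRate = as.numeric(riseRate))
}

#' Evaluate a plasma model
#'
#' \eqn{C_p(t) = \sum_j A_j (e^{-\lambda_j t} - e^{-\mu t})}: zero at
#' injection, a single early peak, then monotone decay.
#'
#' @param model A [PlasmaModel-class].
#' @param times Times in minutes, all >= 0.
#' @return Concentrations in kBq/mL, nonnegative.
#' @export
evalPlasma <- function(model, times) {
  stopifnot(methods::is(model, "PlasmaModel"))
  if (any(times < 0)) stop("times must be >= 0")
  out <- numeric(length(times))
  for (j in seq_along(model@amplitudes)) {
    out <- out + model@amplitudes[j] *
      (exp(-model@decayRates[j] * times) - exp(-model@riseRate * times))
  }
  pmax(out, 0)
}

#' Closed-form running integral of a plasma model
#'
#' \eqn{\int_0^t C_p(\tau)\,d\tau} evaluated analytically:
#' \eqn{\sum_j A_j [(1 - e^{-\lambda_j t})/\lambda_j -
#' (1 - e^{-\mu t})/\mu]}. Serves as the exact reference for the
#' frame-wise trapezoid integral used on measured curves
#' ([cumulativeInputIntegral()]).
#'
#' @inheritParams evalPlasma
#' @return Integral values, kBq.min/mL.
#' @export
plasmaIntegral <- function(model, times) {
  stopifnot(methods::is(model, "PlasmaModel"))
  if (any(times < 0)) stop("times must be >= 0")
  out <- numeric(length(times))
  mu <- model@riseRate
  for (j in seq_along(model@amplitudes)) {
    lam <- model@decayRates[j]
    out <- out + model@amplitudes[j] *
      ((1 - exp(-lam * times)) / lam - (1 - exp(-mu * times)) / mu)
  }
  out
}

setMethod("show", "PlasmaModel", function(object) {
  cat(sprintf(
    "PlasmaModel: %d term(s), decay %s 1/min, rise %.3g 1/min\n",
    length(object@amplitudes),
    paste(signif(object@decayRates, 3), collapse = "/"),
    object@riseRate))
})
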