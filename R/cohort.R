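#' @include AllClasses.R
NULL

#' Design a simulated three-arm longitudinal cohort
#'
#' Defaults sketch a 9-week diabetes treatment study in mmol/L and
#' microU/mL: controls flat near 7 mmol/L glucose; untreated diabetics
#' climbing towards ~28 mmol/L while insulin falls (beta-cell failure);
#' a treated arm whose glucose excursion re-normalises and whose insulin
#' is partially preserved. Arm means are piecewise linear between knots.
#'
#' @param arms List of arm definitions; each a list with `name`,
#'   `weeks` (knot times), `glucose` (mmol/L knots), `insulin`
#'   (microU/mL knots).
#' @param n Animals per arm, default 8.
#' @param weeks Observation weeks, default `0:9`.
#' @param cv Coefficient of variation of the multiplicative lognormal
#'   noise, default 0.08.
#' @param seed Integer seed, default 1.
#' @return A [CohortDesign-class].
#' @export
cohortDesign <- function(arms = list(
                           list(name = "control",
                                weeks = c(0, 9), glucose = c(7, 7),
                                insulin = c(15, 15)),
                           list(name = "diabetic",
                                weeks = c(0, 2, 9), glucose = c(8, 15, 28),
                                insulin = c(12, 9, 4)),
                           list(name = "treated",
                                weeks = c(0, 2, 9), glucose = c(8, 12, 9),
                                insulin = c(12, 10, 8))),
                         n = 8L, weeks = 0:9, cv = 0.08, seed = 1L) {
  methods::new("CohortDesign", arms = arms, n = as.integer(n),
               weeks = as.numeric(weeks), cv = as.numeric(cv),
               seed = as.integer(seed))
}

#' Simulate a longitudinal glucose/insulin table
#'
#' One record per animal and observation week. Values are the arm's
#' piecewise-linear mean at that week times mean-one lognormal noise
#' (`sdlog = sqrt(log(1 + cv^2))`), so `cv = 0` returns the arm means
#' exactly and expectations equal the designed trajectories.
#'
#' @param design A [CohortDesign-class].
#' @return Data frame with columns `subject`, `arm`, `week`,
#'   `glucose`, `glucose_unit` (mmol/L), `insulin`, `insulin_unit`
#'   (uU/mL).
#' @examples
#' head(simulateCohort(cohortDesign(cv = 0)))
#' @export
simulateCohort <- function(design) {
  stopifnot(methods::is(design, "CohortDesign"))
  sdlog <- sqrt(log(1 + design@cv^2))
  withSeed(design@seed, {
    rows <- lapply(design@arms, function(arm) {
      gmean <- stats::approx(arm$weeks, arm$glucose, design@weeks,
                             rule = 2)$y
      imean <- stats::approx(arm$weeks, arm$insulin, design@weeks,
                             rule = 2)$y
      nw <- length(design@weeks)
      do.call(rbind, lapply(seq_len(design@n), function(s) {
        noise <- function(m) {
          if (design@cv == 0) m
          else m * stats::rlnorm(nw, meanlog = -sdlog^2 / 2, sdlog = sdlog)
        }
        data.frame(subject = sprintf("%s_%02d", arm$name, s),
                   arm = arm$name, week = design@weeks,
                   glucose = noise(gmean), glucose_unit = "mmol/L",
                   insulin = noise(imean), insulin_unit = "uU/mL")
      }))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
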