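# Shared dosage/scale constants. The simulator's generative model and the
# callers' expected-magnitude annotations use these same values, so the two
# sides of every recovery test share a single source of truth.

#' Simulator and calibration constants
#'
#' \code{defaultCY1()} is the expected chrY y-statistic (fraction of
#' high-quality reads in the seven chrY marker regions, PAR excluded) per
#' fetal Y copy at fetal fraction 1. \code{simulatorDefaults()} returns the
#' default generative parameters of the cohort simulator: negative-binomial
#' overdispersion (fractional excess variance over Poisson), the female chrY
#' mismapping background (mean and SD of the chrY read fraction in female
#' pregnancies), and \code{cY1}. These defaults are chosen so that the 0.01
#' chrY-ratio sex threshold separates male from female pregnancies at fetal
#' fractions of 4\% and above.
#'
#' @return \code{defaultCY1()}: a number. \code{simulatorDefaults()}: a list
#'   with \code{dispersion}, \code{mismapMean}, \code{mismapSD}, \code{cY1},
#'   \code{signatureSD}.
#' @export
defaultCY1 <- function() 0.4

#' @rdname defaultCY1
#' @export
simulatorDefaults <- function() {
  list(dispersion = 0.02, mismapMean = 0.0015, mismapSD = 5e-4,
       cY1 = defaultCY1(), signatureSD = 0.10)
}

# Fetal dosage factor for a locus of fetal copy number k at fetal fraction f:
# maternal contribution (1-f) at 2 copies + fetal f at k copies.
.dosage <- function(k, f) 1 + f * (k - 2) / 2
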