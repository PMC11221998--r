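#' @importFrom glmnet cv.glmnet
NULL

#' Fetal fraction from the chrY statistic (male pregnancies)
#'
#' Linear scaling of the chrY y-statistic between two calibration points:
#' \code{cFemale}, the female-pregnancy background (mismapping) level, and
#' \code{cMale}, the expected statistic at fetal fraction 1 (one Y copy per
#' diploid fetal genome). The estimate
#' \eqn{(y - c_{female}) / (c_{male} - c_{female})} is clipped to [0,1]
#' (a warning is raised when clipping at 1). Applicable to male pregnancies
#' only.
#'
#' @param yStatistic observed chrY y-statistic.
#' @param cFemale female background calibration point (default: the
#'   simulator's mismap mean).
#' @param cMale statistic expected at fetal fraction 1 (default:
#'   \code{cFemale + defaultCY1()}).
#' @return list with \code{method = "ffy"}, \code{value}, \code{applicable},
#'   \code{detail} (calibration constants).
#' @examples
#' ffY(0.021, cFemale = 0.001, cMale = 0.401)$value  # 0.05
#' @export
ffY <- function(yStatistic, cFemale = simulatorDefaults()$mismapMean,
                cMale = cFemale + defaultCY1()) {
  if (cFemale < 0 || cMale <= cFemale) stop("need cMale > cFemale >= 0")
  raw <- (yStatistic - cFemale) / (cMale - cFemale)
  if (raw > 1) warning("y-statistic above male calibration point; ",
                       "fetal fraction clipped to 1")
  list(method = "ffy", value = min(max(raw, 0), 1), applicable = TRUE,
       detail = list(cFemale = cFemale, cMale = cMale))
}

#' Fetal fraction from chrY read counts against a panel
#'
#' Convenience wrapper: the chrY read-ratio statistic of the sample is scaled
#' by [ffY()] with \code{cFemale} taken from the panel's female chrY
#' background mean and \code{cMale = cFemale + cY1} from the panel's per-Y
#' calibration constant.
#'
#' @param bc a [BinCounts-class].
#' @param panel a [ReferencePanel-class] with chrY background statistics.
#' @return as [ffY()].
#' @export
ffYFromPanel <- function(bc, panel) {
  if (is.na(panel@yMean)) stop("panel lacks chrY background statistics")
  y <- sexByChrYRatio(bc)$statistic
  ffY(y, cFemale = panel@yMean, cMale = panel@yMean + panel@cY1)
}

#' Train the elastic-net fetal-fraction regressor
#'
#' Fits a penalized linear model from GC-corrected normalized autosomal bin
#' depths to known fetal fractions (seqFF-style, elastic-net variant). Only
#' usable autosomal bins enter, so the model is sex-independent by
#' construction. The penalty strength is chosen by internal cross-validation;
#' the fit is deterministic given \code{seed}. The default mixing parameter
#' is ridge-dominant (\code{alpha = 0.01}): the fetal-fraction signal is
#' spread across thousands of bins with individually tiny coefficients, so
#' heavy L1 selection discards most of it, while a small L1 component still
#' zeroes truly uninformative bins. Real-world use requires training on site
#' data of known fetal fraction; the package ships no pretrained weights.
#'
#' @param samples list of [BinCounts-class] on one grid (>= 50).
#' @param ff numeric vector of true fetal fractions, one per sample.
#' @param alpha elastic-net mixing parameter (default 0.01).
#' @param seed RNG seed for the cross-validation folds.
#' @param nfolds cross-validation folds (default 10).
#' @return an [FFRegressionModel-class].
#' @export
trainFFRegression <- function(samples, ff, alpha = 0.01, seed = 1,
                              nfolds = 10) {
  if (length(samples) < 50) stop("need >= 50 training samples")
  if (length(ff) != length(samples)) stop("one ff per sample required")
  if (stats::var(ff) == 0) stop("all training ff identical; nothing to fit")
  grid <- binGrid(samples[[1]])
  for (s in samples[-1])
    if (!.sameGrid(binGrid(s), grid)) stop("grid mismatch between samples")
  idx <- which(.autosomeBins(grid) & mcols(bins(grid))$usable)
  X <- t(vapply(samples, function(s) gcCorrect(s)[idx],
                numeric(length(idx))))
  if (all(apply(X, 2, stats::var) == 0))
    stop("degenerate design: constant depths")
  set.seed(seed)
  fit <- cv.glmnet(X, ff, alpha = alpha, nfolds = nfolds)
  co <- as.numeric(stats::coef(fit, s = "lambda.min"))
  new("FFRegressionModel", intercept = co[1], weights = co[-1],
      binIndex = as.integer(idx), grid = grid,
      meta = list(n = length(samples), seed = seed, alpha = alpha,
                  lambda = fit$lambda.min))
}

#' Apply the fetal-fraction regressor to a sample
#'
#' Predicts \code{intercept + weights . depths} from the sample's
#' GC-corrected autosomal depths, clipped to [0,1]. Applicable to either
#' fetal sex.
#'
#' @param model an [FFRegressionModel-class].
#' @param bc a [BinCounts-class] on the model's grid.
#' @return list with \code{method = "regression"}, \code{value},
#'   \code{applicable}, \code{detail}.
#' @export
applyFFRegression <- function(model, bc) {
  if (!.sameGrid(binGrid(bc), model@grid))
    stop("grid mismatch between sample and model")
  d <- gcCorrect(bc)[model@binIndex]
  raw <- model@intercept + sum(model@weights * d)
  list(method = "regression", value = min(max(raw, 0), 1),
       applicable = TRUE, detail = list(lambda = model@meta$lambda))
}

#' Serialize / read an FFRegressionModel as TSV
#'
#' A JSON header line stores the intercept and training metadata; rows hold
#' (bin index, weight) for nonzero-weight bins.
#'
#' @param model an [FFRegressionModel-class].
#' @param path file path.
#' @param grid the model's [BinGrid-class] (for reading).
#' @return \code{readFFRegressionModel} returns an [FFRegressionModel-class].
#' @export
writeFFRegressionModel <- function(model, path) {
  hdr <- paste0("#", jsonlite::toJSON(c(list(intercept = model@intercept,
    nBins = length(model@weights)), model@meta), auto_unbox = TRUE,
    digits = NA))
  df <- data.frame(bin = model@binIndex, weight = model@weights)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFFRegressionModel
#' @export
readFFRegressionModel <- function(path, grid) {
  meta <- jsonlite::fromJSON(sub("^#", "", readLines(path, n = 1)))
  df <- utils::read.delim(path, skip = 1)
  new("FFRegressionModel", intercept = meta$intercept,
      weights = df$weight, binIndex = as.integer(df$bin), grid = grid,
      meta = list(n = meta$n, seed = meta$seed, alpha = meta$alpha,
                  lambda = meta$lambda))
}
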