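#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats anova aov coef dist integrate lm mad median model.matrix na.omit
#'   p.adjust pf phyper prcomp ptukey pt quantile rbinom rexp rlnorm rnbinom
#'   rnorm runif sd setNames var vcov
#' @importFrom utils read.delim write.table head combn
NULL

#' Container for a grafted-vineyard expression study
#'
#' `GraftExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment-class] and couples an integer
#' gene-by-sample count matrix (assay `"counts"`) with the per-sample design
#' metadata of a replicated rootstock trial: tissue, year, phenological stage,
#' rootstock genotype, irrigation level, block and sampling datetime.
#'
#' The declared factor domains (which rootstock names, tissues, phenologies
#' are legal) are carried in `metadata(x)$factorLevels`, so studies with
#' rootstocks other than the default \{ungrafted, 1103P, 3309C, SO4\} validate
#' cleanly.
#'
#' @slot .Data inherited SummarizedExperiment representation.
#' @seealso [GraftExperiment()] for the validating constructor,
#'   [validateStudy()] for design diagnostics.
#' @export
setClass("GraftExperiment", contains = "SummarizedExperiment")

#' Hourly weather record from an on-site station
#'
#' Holds a strictly increasing hourly timestamp vector and a numeric matrix of
#' named weather features (by default the ten recorded by the vineyard
#' station: temperature, precipitation, wind speed, relative humidity, solar
#' radiance, radiation density, pressure, dew point, reference
#' evapotranspiration and clear-sky radiation). Units are carried as free-text
#' metadata strings. Timestamps are timezone-naive local time; the station
#' clock and the sampling clock are assumed to agree.
#'
#' @slot time POSIXct, strictly increasing, nominally hourly.
#' @slot features numeric matrix, one row per timestamp, named columns.
#' @slot units named character vector of unit strings (may be empty).
#' @export
setClass("HourlyWeather",
  representation(time = "POSIXct", features = "matrix", units = "character"))

setValidity("HourlyWeather", function(object) {
  msg <- character()
  if (length(object@time) != nrow(object@features))
    msg <- c(msg, "length(time) must equal nrow(features)")
  if (length(object@time) > 1 && any(diff(as.numeric(object@time)) <= 0))
    msg <- c(msg, "timestamps must be strictly increasing")
  if (is.null(colnames(object@features)) ||
      anyDuplicated(colnames(object@features)))
    msg <- c(msg, "features must have unique column names")
  if (length(msg)) msg else TRUE
})

#' Parametric mean-dispersion trend of a count matrix
#'
#' Negative-binomial dispersion as a function of the normalized mean,
#' `alpha(mu) = a1 / mu + a0`: `a1` captures the Poisson-like extra spread of
#' weakly expressed genes, `a0` the asymptotic biological dispersion. The
#' closed-form variance-stabilizing transform ([vst()]) is derived from this
#' trend.
#'
#' @slot a0 asymptotic dispersion, `>= 0`.
#' @slot a1 coefficient of the `1/mu` term, `>= 0`.
#' @slot nGenes number of genes used in the fit.
#' @slot residSpread median absolute residual of gene dispersions around the
#'   trend (diagnostic).
#' @slot degenerate TRUE when all gene-wise dispersion estimates were zero and
#'   the trend collapsed to (0, 0).
#' @export
setClass("DispersionTrend",
  representation(a0 = "numeric", a1 = "numeric", nGenes = "integer",
                 residSpread = "numeric", degenerate = "logical"))

setValidity("DispersionTrend", function(object) {
  if (object@a0 < 0 || object@a1 < 0) "a0 and a1 must be non-negative" else TRUE
})

#' Principal component decomposition with fixed sign convention
#'
#' Scores, orthonormal loadings and per-component variance fractions of a
#' centered (optionally unit-scaled) data table, used both for the
#' environmental PCA (ePCA, rows = days) and the gene-expression PCA (gPCA,
#' rows = samples). The sign of each component is fixed so that its
#' largest-magnitude loading is positive, making outputs reproducible across
#' platforms.
#'
#' @slot scores observations x components matrix.
#' @slot loadings variables x components matrix, orthonormal columns.
#' @slot varFrac variance fraction per component, non-increasing.
#' @slot center,scale centering and scaling vectors applied to the input.
#' @slot dropped names of zero-variance columns dropped before scaling.
#' @export
setClass("PCAResult",
  representation(scores = "matrix", loadings = "matrix", varFrac = "numeric",
                 center = "numeric", scale = "numeric", dropped = "character"))

setValidity("PCAResult", function(object) {
  msg <- character()
  if (ncol(object@scores) != ncol(object@loadings))
    msg <- c(msg, "scores and loadings must agree on component count")
  if (length(object@varFrac) != ncol(object@loadings))
    msg <- c(msg, "one variance fraction per component required")
  if (any(diff(object@varFrac) > 1e-8))
    msg <- c(msg, "variance fractions must be non-increasing")
  if (length(msg)) msg else TRUE
})

#' Trained self-organizing map codebook
#'
#' Node weight vectors of a hexagonally connected SOM grid, together with the
#' planar node coordinates (odd rows offset by half a spacing, unit
#' nearest-neighbor distance), the training schedule that produced them, and
#' the final quantization error (mean distance of inputs to their
#' best-matching unit).
#'
#' @slot weights node x feature weight matrix.
#' @slot gridCoords node x 2 planar coordinates.
#' @slot nRows,nCols grid dimensions.
#' @slot topology currently `"hexagonal"`.
#' @slot schedule list recording epochs, learning-rate range, radius range,
#'   neighborhood type and seed (provenance; empty before training).
#' @slot qerror final quantization error (NA before training).
#' @export
setClass("Codebook",
  representation(weights = "matrix", gridCoords = "matrix",
                 nRows = "integer", nCols = "integer", topology = "character",
                 schedule = "list", qerror = "numeric"))

setValidity("Codebook", function(object) {
  msg <- character()
  if (nrow(object@weights) != object@nRows * object@nCols)
    msg <- c(msg, "one weight vector per grid node required")
  if (nrow(object@gridCoords) != nrow(object@weights))
    msg <- c(msg, "gridCoords must have one row per node")
  if (any(!is.finite(object@weights)))
    msg <- c(msg, "weights must be finite")
  if (length(msg)) msg else TRUE
})

#' @describeIn GraftExperiment-class brief display.
#' @param object a `GraftExperiment`.
#' @export
setMethod("show", "GraftExperiment", function(object) {
  callNextMethod()
  fl <- S4Vectors::metadata(object)$factorLevels
  if (!is.null(fl))
    cat("declared factors:", paste(names(fl), collapse = ", "), "\n")
})

setMethod("show", "HourlyWeather", function(object) {
  cat(sprintf("HourlyWeather: %d hours x %d features (%s .. %s)\n",
              length(object@time), ncol(object@features),
              format(min(object@time)), format(max(object@time))))
  cat(" features:", paste(colnames(object@features), collapse = ", "), "\n")
})

setMethod("show", "DispersionTrend", function(object) {
  cat(sprintf("DispersionTrend: alpha(mu) = %.4g/mu + %.4g (fit on %d genes%s)\n",
              object@a1, object@a0, object@nGenes,
              if (object@degenerate) "; degenerate" else ""))
})

setMethod("show", "PCAResult", function(object) {
  cat(sprintf("PCAResult: %d obs x %d vars, %d components\n",
              nrow(object@scores), nrow(object@loadings), ncol(object@scores)))
  k <- min(4L, length(object@varFrac))
  cat(" top variance fractions:",
      paste(sprintf("%.3f", object@varFrac[seq_len(k)]), collapse = " "), "\n")
})

setMethod("show", "Codebook", function(object) {
  cat(sprintf("Codebook: %dx%d %s grid, %d features%s\n",
              object@nRows, object@nCols, object@topology,
              ncol(object@weights),
              if (is.na(object@qerror)) " (untrained)"
              else sprintf(", quantization error %.4g", object@qerror)))
})

# ---- accessors -------------------------------------------------------------

#' Node weight matrix of a codebook
#' @param x a [Codebook-class].
#' @return node x feature numeric matrix.
#' @export
somWeights <- function(x) {
  stopifnot(is(x, "Codebook"))
  x@weights
}

#' Planar node coordinates of a codebook grid
#' @param x a [Codebook-class].
#' @return node x 2 matrix of hexagonal-layout coordinates.
#' @export
somGridCoords <- function(x) {
  stopifnot(is(x, "Codebook"))
  x@gridCoords
}

#' Quantization error of a trained codebook
#' @param x a [Codebook-class].
#' @return mean Euclidean distance from inputs to their best-matching unit,
#'   `NA` before training.
#' @export
somQuantizationError <- function(x) {
  stopifnot(is(x, "Codebook"))
  x@qerror
}

#' PCA scores
#' @param x a [PCAResult-class].
#' @return observations x components score matrix.
#' @export
pcaScores <- function(x) {
  stopifnot(is(x, "PCAResult"))
  x@scores
}

#' PCA loadings
#' @param x a [PCAResult-class].
#' @return variables x components orthonormal loading matrix.
#' @export
pcaLoadings <- function(x) {
  stopifnot(is(x, "PCAResult"))
  x@loadings
}

#' Per-component variance fractions
#' @param x a [PCAResult-class].
#' @return numeric vector of variance fractions, non-increasing.
#' @export
pcaVarFrac <- function(x) {
  stopifnot(is(x, "PCAResult"))
  x@varFrac
}

#' Dispersion-trend coefficients
#' @param x a [DispersionTrend-class].
#' @return named numeric vector `c(a0 = ..., a1 = ...)`.
#' @export
trendCoefficients <- function(x) {
  stopifnot(is(x, "DispersionTrend"))
  c(a0 = x@a0, a1 = x@a1)
}

#' Weather timestamps
#' @param x an [HourlyWeather-class].
#' @return POSIXct vector of record times.
#' @export
weatherTime <- function(x) {
  stopifnot(is(x, "HourlyWeather"))
  x@time
}

#' Weather feature matrix
#' @param x an [HourlyWeather-class].
#' @return numeric matrix, one named column per feature.
#' @export
weatherFeatures <- function(x) {
  stopifnot(is(x, "HourlyWeather"))
  x@features
}
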