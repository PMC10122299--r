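#' Composite statistics of one weather window
#'
#' Summaries of the `windowH` hours preceding (and including) an anchor
#' time: for averaged features the minimum, maximum, change (max - min by
#' default, last - first via `changeMode`) and mean; for accumulating
#' features (precipitation and radiation density by default) the sum only.
#' Missing hours inside the window are tolerated up to `maxMissingFrac`.
#'
#' @param weather an [HourlyWeather-class].
#' @param anchor POSIXct (or parseable string): the window is
#'   `(anchor - windowH hours, anchor]`.
#' @param windowH window length in hours (default 24).
#' @param sumFeatures features summarized by their sum.
#' @param changeMode `"range"` (max - min) or `"lastFirst"`.
#' @param maxMissingFrac tolerated fraction of absent hours (default 0.25).
#' @return one-row data.frame of composite columns named
#'   `<feature>_<stat>`.
#' @examples
#' w <- HourlyWeather(seq(as.POSIXct("2018-06-11 08:00", tz = "UTC"),
#'                        by = "hour", length.out = 4),
#'                    data.frame(temperature = c(10, 12, 14, 16),
#'                               precipitation = c(0, 1, 0, 2)))
#' compositeStats(w, "2018-06-11 11:00", windowH = 4)
#' @export
compositeStats <- function(weather, anchor, windowH = 24,
                           sumFeatures = c("precipitation",
                                           "radiationDensity"),
                           changeMode = c("range", "lastFirst"),
                           maxMissingFrac = 0.25) {
  changeMode <- match.arg(changeMode)
  if (!inherits(anchor, "POSIXct"))
    anchor <- as.POSIXct(anchor, tz = "UTC")
  tm <- weatherTime(weather)
  sel <- tm > anchor - windowH * 3600 & tm <= anchor
  if (!any(sel))
    stop("weather window ending ", format(anchor), " is entirely missing")
  if (1 - sum(sel) / windowH > maxMissingFrac)
    stop(sprintf("window ending %s has %d of %d hours (> %.0f%% missing)",
                 format(anchor), sum(sel), as.integer(windowH),
                 100 * maxMissingFrac))
  X <- weatherFeatures(weather)[sel, , drop = FALSE]
  out <- list()
  for (f in colnames(X)) {
    x <- X[, f]
    if (f %in% sumFeatures) {
      out[[paste0(f, "_sum")]] <- sum(x)
    } else {
      chg <- if (changeMode == "range") max(x) - min(x)
             else x[length(x)] - x[1]
      out[[paste0(f, "_min")]] <- min(x)
      out[[paste0(f, "_max")]] <- max(x)
      out[[paste0(f, "_change")]] <- chg
      out[[paste0(f, "_mean")]] <- mean(x)
    }
  }
  as.data.frame(out)
}

#' Daily composite-statistic table
#'
#' One row of [compositeStats()] per day: either every recorded day
#' (`allDays = TRUE`, window = that calendar day) or the distinct sampling
#' dates of a metadata table (window = the 24 h preceding the day's first
#' sampling time; duplicate dates collapse to one row).
#'
#' @param weather an [HourlyWeather-class].
#' @param meta sample metadata with a `datetime` column (ignored when
#'   `allDays = TRUE`).
#' @param allDays build a row for every recorded day.
#' @param windowH window length in hours.
#' @param ... passed on to [compositeStats()].
#' @return data.frame with a `date` column followed by composite columns.
#' @export
buildEnvTable <- function(weather, meta = NULL, allDays = is.null(meta),
                          windowH = 24, ...) {
  if (allDays) {
    days <- unique(format(weatherTime(weather), "%Y-%m-%d"))
    anchors <- as.POSIXct(paste(days, "23:00"), tz = "UTC")
  } else {
    if (is.null(meta)) stop("need metadata when allDays = FALSE")
    dt <- meta$datetime
    if (!inherits(dt, "POSIXct")) dt <- as.POSIXct(dt, tz = "UTC")
    days <- format(dt, "%Y-%m-%d")
    first <- tapply(as.numeric(dt), days, min)
    days <- names(first)
    anchors <- as.POSIXct(as.numeric(first), origin = "1970-01-01",
                          tz = "UTC")
  }
  rows <- lapply(seq_along(days), function(i)
    compositeStats(weather, anchors[i], windowH = windowH, ...))
  out <- cbind(data.frame(date = days, stringsAsFactors = FALSE),
               do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Principal component analysis with a fixed sign convention
#'
#' Centers (and by default unit-scales) the columns, then decomposes by SVD.
#' Zero-variance columns are dropped with a warning when standardizing. Each
#' component's sign is fixed so its largest-magnitude loading is positive,
#' making results platform-reproducible.
#'
#' @param x numeric matrix or data.frame (observations x variables); a
#'   non-numeric `date` first column is used for row names.
#' @param standardize scale columns to unit variance (default TRUE).
#' @return a [PCAResult-class].
#' @export
pcaTable <- function(x, standardize = TRUE) {
  x <- as.data.frame(x)
  if ("date" %in% colnames(x) && !is.numeric(x$date)) {
    rownames(x) <- x$date
    x$date <- NULL
  }
  X <- as.matrix(x)
  if (nrow(X) < 2) stop("PCA needs at least two observations")
  v <- apply(X, 2, var)
  dropped <- character()
  if (standardize && any(v == 0)) {
    dropped <- colnames(X)[v == 0]
    warning("dropping zero-variance column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, v > 0, drop = FALSE]
  }
  pc <- prcomp(X, center = TRUE, scale. = standardize)
  L <- pc$rotation
  S <- pc$x
  for (k in seq_len(ncol(L))) {
    j <- which.max(abs(L[, k]))
    if (L[j, k] < 0) { L[, k] <- -L[, k]; S[, k] <- -S[, k] }
  }
  varFrac <- pc$sdev^2 / sum(pc$sdev^2)
  new("PCAResult", scores = S, loadings = L,
      varFrac = varFrac[seq_len(ncol(L))],
      center = pc$center,
      scale = if (standardize) pc$scale else setNames(rep(1, ncol(X)),
                                                      colnames(X)),
      dropped = dropped)
}

#' Smallest component prefix reaching a cumulative variance target
#'
#' @param pca a [PCAResult-class].
#' @param cumVar cumulative variance fraction to reach (default 0.80).
#' @return integer vector of component indices `1..k`; all components if the
#'   target is never reached.
#' @export
selectComponents <- function(pca, cumVar = 0.80) {
  cs <- cumsum(pcaVarFrac(pca))
  k <- which(cs >= cumVar - 1e-12)[1]
  if (is.na(k)) k <- length(cs)
  seq_len(k)
}

#' Attach per-day environmental PC scores to samples
#'
#' Each sample inherits the ePC scores of its sampling date. A sample whose
#' date is absent from the environmental table is an error naming it.
#'
#' @param meta sample metadata with `sample` and `datetime` columns.
#' @param envTable the table the ePCA was computed on (its `date` column, or
#'   row names, give the day of each score row).
#' @param epcScores score matrix from the ePCA ([pcaScores()]), rows aligned
#'   with `envTable`.
#' @param components which score columns to attach (default all).
#' @return data.frame: sample, date, then one column per ePC.
#' @export
attachEnv <- function(meta, envTable, epcScores,
                      components = seq_len(ncol(epcScores))) {
  dates <- if (!is.null(envTable$date)) as.character(envTable$date)
           else rownames(envTable)
  dt <- meta$datetime
  if (!inherits(dt, "POSIXct")) dt <- as.POSIXct(dt, tz = "UTC")
  sampleDay <- format(dt, "%Y-%m-%d")
  idx <- match(sampleDay, dates)
  if (anyNA(idx))
    stop("sample(s) with no matching environmental row: ",
         paste(head(meta$sample[is.na(idx)], 5), collapse = ", "))
  sc <- epcScores[idx, components, drop = FALSE]
  colnames(sc) <- paste0("ePC", components)
  data.frame(sample = meta$sample, date = sampleDay, sc,
             stringsAsFactors = FALSE, row.names = NULL)
}
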