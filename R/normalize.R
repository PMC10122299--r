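#' Median-of-ratios size factors
#'
#' Per-sample depth factors: each sample's counts are divided by the per-gene
#' geometric mean over samples (computed on the reference set of genes with
#' strictly positive counts everywhere) and the median of those ratios is the
#' sample's factor. Factors are rescaled to geometric mean 1 so the
#' normalized scale stays comparable to raw counts.
#'
#' @param counts gene x sample matrix.
#' @param pseudoReference when TRUE, the geometric mean is taken over the
#'   positive counts of each gene (ratio medians over positive entries),
#'   allowing sparse matrices with no all-positive gene.
#' @return named numeric vector of positive per-sample factors.
#' @examples
#' m <- rbind(g1 = c(10, 20, 40), g2 = c(100, 200, 400), g3 = c(1, 2, 4))
#' colnames(m) <- paste0("s", 1:3)
#' estimateSizeFactors(m)  # proportional to 1, 2, 4
#' @export
estimateSizeFactors <- function(counts, pseudoReference = FALSE) {
  .validateCounts(counts)
  if (pseudoReference) {
    logGeo <- apply(counts, 1, function(x) {
      pos <- x > 0
      if (!any(pos)) -Inf else mean(log(x[pos]))
    })
    use <- is.finite(logGeo)
    sf <- apply(counts, 2, function(x) {
      r <- log(x[use]) - logGeo[use]
      exp(median(r[is.finite(r)]))
    })
  } else {
    ref <- rowSums(counts > 0) == ncol(counts)
    if (!any(ref))
      stop("no gene has positive counts in every sample; ",
           "set pseudoReference = TRUE to use a pseudo-reference")
    logGeo <- rowMeans(log(counts[ref, , drop = FALSE]))
    sf <- apply(log(counts[ref, , drop = FALSE]) - logGeo, 2,
                function(r) exp(median(r)))
  }
  sf <- sf / exp(mean(log(sf)))
  if (any(!is.finite(sf) | sf <= 0)) stop("degenerate size factors")
  sf
}

#' Filter weakly expressed genes
#'
#' Retains gene g iff its count exceeds `minCount` (strictly) in at least
#' `minSamples` samples. By default the rule is applied on the normalized
#' scale (counts divided by median-of-ratios size factors); `scale = "raw"`
#' applies it to raw counts.
#'
#' @param counts gene x sample matrix.
#' @param minCount count that must be strictly exceeded (default 4).
#' @param minSamples number of samples in which it must be exceeded
#'   (default 4).
#' @param scale `"normalized"` or `"raw"`.
#' @param sizeFactors optional precomputed factors (recomputed otherwise).
#' @return the filtered count matrix (possibly zero rows).
#' @export
filterGenes <- function(counts, minCount = 4, minSamples = 4,
                        scale = c("normalized", "raw"), sizeFactors = NULL) {
  scale <- match.arg(scale)
  .validateCounts(counts)
  if (minSamples > ncol(counts))
    stop("minSamples (", minSamples, ") exceeds sample count (",
         ncol(counts), ")")
  q <- counts
  if (scale == "normalized") {
    if (is.null(sizeFactors)) sizeFactors <- estimateSizeFactors(counts)
    q <- sweep(counts, 2, sizeFactors, "/")
  }
  keep <- rowSums(q > minCount) >= minSamples
  counts[keep, , drop = FALSE]
}

#' Fit the parametric mean-dispersion trend
#'
#' Method-of-moments gene-wise dispersions
#' `alpha_g = max(0, (var_g - mu_g) / mu_g^2)` on normalized counts are
#' regressed on `1/mu_g` by iteratively reweighted (Tukey bisquare) least
#' squares, giving the trend `alpha(mu) = a1/mu + a0`. Negative fitted
#' coefficients are clamped to zero and the companion coefficient refit.
#'
#' @param counts gene x sample matrix (raw).
#' @param sizeFactors per-sample factors from [estimateSizeFactors()].
#' @param minMean genes with normalized mean below this are excluded from the
#'   fit (default 1).
#' @return a [DispersionTrend-class]; all-zero dispersions give the flagged
#'   degenerate trend (0, 0).
#' @export
fitDispersionTrend <- function(counts, sizeFactors, minMean = 1) {
  .validateCounts(counts)
  if (nrow(counts) < 20) stop("need at least 20 genes to fit a trend")
  q <- sweep(counts, 2, sizeFactors, "/")
  mu <- rowMeans(q)
  v <- apply(q, 1, var)
  alpha <- pmax(0, (v - mu) / mu^2)
  use <- mu > minMean & is.finite(alpha)
  if (all(alpha[use] == 0))
    return(new("DispersionTrend", a0 = 0, a1 = 0, nGenes = sum(use),
               residSpread = 0, degenerate = TRUE))
  x <- 1 / mu[use]; y <- alpha[use]
  w <- rep(1, length(y))
  fit <- c(a0 = 0, a1 = 0)
  for (it in 1:20) {
    X <- cbind(1, x)
    b <- solve(crossprod(X * sqrt(w)), crossprod(X * w, y))
    b <- drop(b)
    # non-negativity: clamp and refit the free coefficient
    if (b[1] < 0) b <- c(0, sum(w * x * y) / sum(w * x^2))
    if (b[2] < 0) b <- c(sum(w * y) / sum(w), 0)
    b <- pmax(b, 0)
    r <- y - (b[1] + b[2] * x)
    s <- median(abs(r)) / 0.6745
    wNew <- if (s > 0) pmax(0, (1 - (r / (4.685 * s))^2))^2 else rep(1, length(r))
    if (max(abs(b - fit)) < 1e-10) { fit <- b; break }
    fit <- b; w <- wNew
  }
  new("DispersionTrend", a0 = unname(fit[1]), a1 = unname(fit[2]),
      nGenes = sum(use),
      residSpread = median(abs(y - (fit[1] + fit[2] * x))),
      degenerate = FALSE)
}

#' Closed-form variance-stabilizing transform of a normalized count
#'
#' For NB counts with dispersion trend `alpha(mu) = a1/mu + a0` the variance
#' of a normalized count q is `q (1 + a1) + a0 q^2`; the stabilizing
#' transform is the integral of its inverse square root,
#' `vst(q) = log2( (2 a0 q + b + 2 sqrt(a0 q (a0 q + b))) / (4 a0) )` with
#' `b = 1 + a1`, rescaled so that `vst(q) - log2(q) -> 0` for large q. In the
#' `a0 -> 0` limit the transform degenerates to `2 sqrt(q / b)` (no log
#' asymptote exists).
#'
#' @param q non-negative normalized count(s).
#' @param trend a [DispersionTrend-class] or `c(a0 =, a1 =)` vector.
#' @return transformed values, same shape as `q`; strictly increasing in q.
#' @export
vstTransform <- function(q, trend) {
  if (is(trend, "DispersionTrend")) trend <- trendCoefficients(trend)
  a0 <- trend[["a0"]]; a1 <- trend[["a1"]]
  if (any(q < 0)) stop("normalized counts must be non-negative")
  b <- 1 + a1
  if (a0 <= 0) return(2 * sqrt(q / b))
  log2((2 * a0 * q + b + 2 * sqrt(a0 * q * (a0 * q + b))) / (4 * a0))
}

#' Variance-stabilized expression matrix
#'
#' Applies [vstTransform()] to size-factor-normalized counts. Equal counts
#' with equal size factors map to equal values; for strongly expressed genes
#' the scale is asymptotically log2.
#'
#' @param counts gene x sample matrix (raw, typically filtered).
#' @param sizeFactors per-sample factors.
#' @param trend a fitted [DispersionTrend-class].
#' @return numeric matrix on the VST scale with the same dimnames, carrying
#'   the size factors and trend in attributes `"sizeFactors"` / `"trend"`.
#' @export
vst <- function(counts, sizeFactors, trend) {
  .validateCounts(counts)
  q <- sweep(counts, 2, sizeFactors, "/")
  out <- vstTransform(q, trend)
  attr(out, "sizeFactors") <- sizeFactors
  attr(out, "trend") <- trend
  out
}

#' Per-gene z-scoring of an expression matrix
#'
#' Centers and scales each gene to mean 0, sd 1 across samples. Constant
#' genes become all-zero rows and are flagged in the `"constantGenes"`
#' attribute. Idempotent.
#'
#' @param expr numeric gene x sample matrix (finite values).
#' @return scaled matrix with attribute `constantGenes`.
#' @export
scaleGenes <- function(expr) {
  if (any(!is.finite(expr))) stop("expression matrix must be finite")
  mu <- rowMeans(expr)
  s <- apply(expr, 1, sd)
  const <- s == 0
  s[const] <- 1
  out <- (expr - mu) / s
  out[const, ] <- 0
  attr(out, "constantGenes") <- rownames(expr)[const]
  out
}

#' Survey of housekeeping-gene families across design factors
#'
#' For named sets of constitutively expressed genes (e.g. ubiquitin-domain
#' and actin-domain families), summarizes VST expression per gene and per
#' level of each requested design factor, to check that their expression is
#' broadly stable across the experiment.
#'
#' @param expr VST gene x sample matrix.
#' @param geneSets named list of gene-id vectors.
#' @param meta sample metadata aligned with `colnames(expr)`.
#' @param factors metadata columns to stratify by.
#' @return long-format data.frame: set, gene, factor, level, n, mean, sd.
#' @export
housekeepingProfile <- function(expr, geneSets, meta,
                                factors = c("tissue", "year", "phenology",
                                            "rootstock")) {
  stopifnot(is.list(geneSets), length(geneSets) > 0)
  meta <- as.data.frame(meta)
  rows <- list()
  for (setName in names(geneSets)) {
    genes <- intersect(geneSets[[setName]], rownames(expr))
    if (length(genes) == 0)
      stop("gene set '", setName, "' has no genes in the expression matrix")
    for (g in genes) for (f in factors) {
      lev <- as.character(meta[[f]])
      for (l in unique(lev)) {
        x <- expr[g, lev == l]
        rows[[length(rows) + 1L]] <-
          data.frame(set = setName, gene = g, factor = f, level = l,
                     n = length(x), mean = mean(x), sd = sd(x),
                     stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
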