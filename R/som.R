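#' Hexagonal SOM grid coordinates
#'
#' Planar node coordinates of an `nRows x nCols` hexagonally connected grid
#' in odd-row offset layout: row i sits at height `i * sqrt(3)/2`, odd rows
#' shifted right by half a spacing, so nearest neighbors are at unit
#' distance. Nodes are numbered row-major from 1.
#'
#' @param nRows,nCols grid dimensions (default 9 x 9, 81 nodes).
#' @return node x 2 coordinate matrix with attribute `"dims"`.
#' @export
somGrid <- function(nRows = 9L, nCols = 9L) {
  i <- rep(seq_len(nRows) - 1L, each = nCols)
  j <- rep(seq_len(nCols) - 1L, nRows)
  xy <- cbind(x = j + 0.5 * (i %% 2), y = i * sqrt(3) / 2)
  attr(xy, "dims") <- c(nRows = nRows, nCols = nCols)
  xy
}

.gridDiameter <- function(coords) {
  rng <- apply(coords, 2, range)
  # max planar distance is attained between extreme corners
  max(dist(coords[c(which.min(coords[, 1] + coords[, 2]),
                    which.max(coords[, 1] + coords[, 2]),
                    which.min(coords[, 1] - coords[, 2]),
                    which.max(coords[, 1] - coords[, 2])), , drop = FALSE]))
}

.pairwiseD2 <- function(a, b) {
  # squared Euclidean distances, rows of a vs rows of b
  outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
}

#' Initialize a SOM codebook
#'
#' `"sample"` (default): weights are a seeded random sample of distinct input
#' profiles. `"pca"`: weights form a regular lattice in the plane of the
#' first two principal components of the inputs, spanning +/- 2 sd of the
#' scores.
#'
#' @param data gene x feature matrix (z-scored profiles).
#' @param grid coordinates from [somGrid()].
#' @param seed integer seed (sample init).
#' @param method `"sample"` or `"pca"`.
#' @return an untrained [Codebook-class].
#' @export
initCodebook <- function(data, grid = somGrid(), seed = 1L,
                         method = c("sample", "pca")) {
  method <- match.arg(method)
  data <- as.matrix(data)
  m <- nrow(grid)
  if (nrow(data) < m)
    stop("fewer inputs (", nrow(data), ") than grid nodes (", m,
         "); use a smaller grid")
  dims <- attr(grid, "dims")
  if (method == "sample") {
    set.seed(seed)
    W <- data[sample.int(nrow(data), m), , drop = FALSE]
  } else {
    pc <- prcomp(data, center = TRUE, scale. = FALSE)
    u <- scale(grid[, 1], center = TRUE, scale = FALSE)
    v <- scale(grid[, 2], center = TRUE, scale = FALSE)
    s1 <- 2 * sd(pc$x[, 1]) / max(abs(u))
    s2 <- if (ncol(pc$x) > 1 && max(abs(v)) > 0)
      2 * sd(pc$x[, 2]) / max(abs(v)) else 0
    W <- matrix(colMeans(data), m, ncol(data), byrow = TRUE) +
      (u * s1) %*% t(pc$rotation[, 1]) +
      if (ncol(pc$rotation) > 1) (v * s2) %*% t(pc$rotation[, 2]) else 0
  }
  dimnames(W) <- list(NULL, colnames(data))
  new("Codebook", weights = W, gridCoords = unclass(grid[, 1:2]),
      nRows = as.integer(dims[["nRows"]]), nCols = as.integer(dims[["nCols"]]),
      topology = "hexagonal", schedule = list(), qerror = NA_real_)
}

#' Train a SOM by online competitive learning
#'
#' Inputs are presented one at a time in a seeded random order, re-shuffled
#' each epoch. For every presentation the best-matching unit (BMU, nearest
#' node weight in Euclidean distance; ties to the lowest node index) is
#' found and all node weights move toward the input,
#' `w_k <- w_k + alpha * h(d(BMU, k)) * (x - w_k)`, with a Gaussian
#' neighborhood `h = exp(-d^2 / (2 r^2))` in the grid plane. The learning
#' rate falls linearly from `alphaRange[1]` to `alphaRange[2]` over all
#' updates, the radius from two thirds of the grid diameter down to 0.5.
#'
#' @param data gene x feature matrix of z-scored profiles (no NAs).
#' @param codebook an initialized [Codebook-class].
#' @param epochs full presentations of the data (default 500).
#' @param alphaRange start and end learning rate, default `c(0.05, 0.01)`.
#' @param radiusRange start and end neighborhood radius; default
#'   `c(2/3 * grid diameter, 0.5)`.
#' @param neighborhood `"gaussian"` (default) or `"bubble"`.
#' @param seed integer seed driving the presentation order.
#' @return the trained [Codebook-class]; `schedule` records the parameters
#'   and the per-epoch mean BMU distance (`epochQE`), `qerror` the final
#'   quantization error.
#' @export
trainSOM <- function(data, codebook, epochs = 500L,
                     alphaRange = c(0.05, 0.01), radiusRange = NULL,
                     neighborhood = c("gaussian", "bubble"), seed = 1L) {
  neighborhood <- match.arg(neighborhood)
  data <- as.matrix(data)
  bad <- rownames(data)[!stats::complete.cases(data) |
                          rowSums(!is.finite(data)) > 0]
  if (length(bad))
    stop("non-finite values in input profile(s): ",
         paste(head(bad, 5), collapse = ", "))
  if (ncol(data) != ncol(somWeights(codebook)))
    stop("input feature dimension does not match the codebook")
  if (any(diff(alphaRange) > 0) || any(alphaRange < 0))
    stop("learning rate must be non-negative and non-increasing")
  coords <- somGridCoords(codebook)
  if (is.null(radiusRange))
    radiusRange <- c(2 / 3 * .gridDiameter(coords), 0.5)
  if (diff(radiusRange) > 0 || any(radiusRange <= 0))
    stop("radius must be positive and non-increasing")
  set.seed(seed)
  ord <- t(vapply(seq_len(epochs), function(e) sample.int(nrow(data)),
                  integer(nrow(data))))
  d2 <- .pairwiseD2(coords, coords)
  d2[d2 < 0] <- 0
  fit <- som_train_cpp(data, somWeights(codebook), d2, ord,
                       alphaRange[1], alphaRange[2],
                       radiusRange[1], radiusRange[2],
                       if (neighborhood == "bubble") 1L else 0L)
  W <- fit$weights
  dimnames(W) <- dimnames(somWeights(codebook))
  out <- codebook
  out@weights <- W
  out@schedule <- list(epochs = epochs, alphaRange = alphaRange,
                       radiusRange = radiusRange,
                       neighborhood = neighborhood, seed = seed,
                       epochQE = fit$epochQE)
  d2in <- .pairwiseD2(data, W)
  out@qerror <- mean(sqrt(pmax(0, apply(d2in, 1, min))))
  out
}

#' Assign genes to their best-matching unit
#'
#' Maps every input profile to the nearest codebook node by Euclidean
#' distance (ties to the lowest node index) and records the distance.
#'
#' @param data gene x feature matrix.
#' @param codebook a trained [Codebook-class].
#' @return object of class `"ClusterTable"`: list with `genes` (gene, node,
#'   dist, retained) and `nodes` (node, size, retainedSize, tested, p,
#'   significant) data.frames.
#' @export
assignBMU <- function(data, codebook) {
  data <- as.matrix(data)
  W <- somWeights(codebook)
  d2 <- .pairwiseD2(data, W)
  node <- max.col(-d2, ties.method = "first")
  dist <- sqrt(pmax(0, d2[cbind(seq_len(nrow(data)), node)]))
  nNodes <- nrow(W)
  genes <- data.frame(gene = rownames(data), node = node, dist = dist,
                      retained = NA, stringsAsFactors = FALSE)
  nodes <- data.frame(node = seq_len(nNodes),
                      size = tabulate(node, nNodes),
                      retainedSize = NA_integer_, tested = FALSE,
                      p = NA_real_, significant = NA)
  structure(list(genes = genes, nodes = nodes, nNodes = nNodes),
            class = "ClusterTable")
}

#' Retain core genes of each cluster
#'
#' Within each node, keeps the genes whose distance to the node weight lies
#' at or below the node's `q` distance quantile (default the median;
#' inclusive, so all-equal distances retain everything and a singleton node
#' retains its gene).
#'
#' @param table a `"ClusterTable"` from [assignBMU()].
#' @param q distance quantile, default 0.5.
#' @return the table with the `retained` flag and per-node retained sizes
#'   filled in.
#' @export
retainCoreGenes <- function(table, q = 0.5) {
  stopifnot(inherits(table, "ClusterTable"))
  g <- table$genes
  g$retained <- FALSE
  for (nd in unique(g$node)) {
    idx <- which(g$node == nd)
    thr <- quantile(g$dist[idx], q, type = 7)
    g$retained[idx] <- g$dist[idx] <= thr
  }
  table$genes <- g
  table$nodes$retainedSize <- vapply(table$nodes$node, function(nd)
    sum(g$retained[g$node == nd]), integer(1))
  table
}

#' Mean scaled expression of clusters by design groups
#'
#' For each cluster with retained genes, the mean of the scaled expression
#' over its retained genes within every combination of the grouping factors
#' (default rootstock x year) — the cluster profile summaries used to read
#' off archetypal rootstock patterns.
#'
#' @param scaledExpr z-scored gene x sample matrix.
#' @param table a `"ClusterTable"` with retention done.
#' @param meta sample metadata aligned with `colnames(scaledExpr)`.
#' @param groupFactors metadata columns to group by.
#' @return long data.frame: node, one column per grouping factor, n (genes),
#'   mean.
#' @export
clusterSummary <- function(scaledExpr, table, meta,
                           groupFactors = c("rootstock", "year")) {
  stopifnot(inherits(table, "ClusterTable"))
  meta <- as.data.frame(meta)
  g <- table$genes[table$genes$retained %in% TRUE, , drop = FALSE]
  if (nrow(g) == 0) stop("no retained genes; run retainCoreGenes() first")
  grp <- interaction(meta[groupFactors], drop = TRUE, sep = "|")
  out <- list()
  for (nd in sort(unique(g$node))) {
    genes <- g$gene[g$node == nd]
    prof <- colMeans(scaledExpr[genes, , drop = FALSE])
    mns <- tapply(prof, grp, mean)
    lev <- do.call(rbind, strsplit(names(mns), "|", fixed = TRUE))
    df <- data.frame(node = nd, lev, n = length(genes), mean = as.numeric(mns),
                     stringsAsFactors = FALSE)
    colnames(df)[1 + seq_along(groupFactors)] <- groupFactors
    out[[length(out) + 1L]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Post-clustering rootstock tests per cluster
#'
#' Every cluster whose retained size reaches `minSize` is summarized as the
#' per-sample mean of its retained genes' scaled expression; that summary is
#' fit with a one-way linear model on rootstock and the overall F-test
#' p-value recorded. Significance is Bonferroni-corrected by the node count:
#' a cluster is significant iff `p < alpha / nNodes`. Smaller clusters are
#' marked untested.
#'
#' @param scaledExpr z-scored gene x sample matrix.
#' @param table a `"ClusterTable"` with retention done.
#' @param meta sample metadata aligned with `colnames(scaledExpr)`.
#' @param alpha nominal level before correction (default 0.05).
#' @param minSize minimum retained cluster size to test (default 16).
#' @return the table with per-node `tested`, `p` and `significant` filled;
#'   attribute `"alphaCorrected"` records `alpha / nNodes`.
#' @export
clusterRootstockTest <- function(scaledExpr, table, meta, alpha = 0.05,
                                 minSize = 16L) {
  stopifnot(inherits(table, "ClusterTable"))
  meta <- as.data.frame(meta)
  rs <- factor(meta$rootstock)
  alphaC <- alpha / table$nNodes
  g <- table$genes[table$genes$retained %in% TRUE, , drop = FALSE]
  nd <- table$nodes
  for (i in seq_len(nrow(nd))) {
    genes <- g$gene[g$node == nd$node[i]]
    if (length(genes) < minSize) next
    y <- colMeans(scaledExpr[genes, , drop = FALSE])
    fit <- lm(y ~ rs)
    a <- anova(fit)
    p <- a[["Pr(>F)"]][1]
    nd$tested[i] <- TRUE
    nd$p[i] <- p
    nd$significant[i] <- p < alphaC
  }
  table$nodes <- nd
  attr(table, "alphaCorrected") <- alphaC
  table
}
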