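#' Build the per-gene model design matrix
#'
#' Treatment-coded design over the requested main effects (in the fixed order
#' given) followed by the requested pairwise interactions. Year and phenology
#' are treated as unordered factors. Columns made aliased by missing design
#' cells (e.g. the reproductive harvest of a lost year) are dropped and
#' reported, keeping the matrix full column rank.
#'
#' @param meta sample metadata data.frame.
#' @param mains main-effect columns, in the order their sums of squares will
#'   be attributed.
#' @param interactions character vector of `"a:b"` pairwise interaction
#'   labels; default all pairs among tissue, year, phenology and rootstock.
#' @return list of class `"DesignMatrix"`: `X` (samples x coefficients,
#'   full rank), `assign` (term index per column), `terms` (term labels),
#'   `aliased` (dropped coefficient names).
#' @export
buildDesign <- function(meta,
                        mains = c("tissue", "year", "phenology", "irrigation",
                                  "rootstock"),
                        interactions = {
                          f <- intersect(c("tissue", "year", "phenology",
                                           "rootstock"), mains)
                          if (length(f) >= 2)
                            combn(f, 2, paste, collapse = ":") else character()
                        }) {
  meta <- as.data.frame(meta)
  missing <- setdiff(mains, colnames(meta))
  if (length(missing))
    stop("metadata lacks term column(s): ", paste(missing, collapse = ", "))
  mf <- meta[mains]
  for (v in mains) {
    mf[[v]] <- factor(mf[[v]])
    if (nlevels(mf[[v]]) < 2)
      stop("factor '", v, "' has fewer than two levels")
  }
  termLabels <- c(mains, interactions)
  form <- stats::reformulate(termLabels)
  X <- model.matrix(form, data = mf,
                    contrasts.arg = lapply(mf, function(x) "contr.treatment"))
  asgn <- attr(X, "assign")
  qrX <- qr(X)
  keep <- sort(qrX$pivot[seq_len(qrX$rank)])
  aliased <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
  structure(list(X = X[, keep, drop = FALSE], assign = asgn[keep],
                 terms = termLabels, aliased = aliased,
                 samples = meta$sample),
            class = "DesignMatrix")
}

# Orthonormal bases per term (sequential / Type-I scheme): each term's design
# block is residualized against everything before it (intercept first) and
# orthonormalized; near-null directions (aliased within the sequence) drop out.
.sequentialBasis <- function(design) {
  X <- design$X
  n <- nrow(X)
  blocks <- split(seq_len(ncol(X)), design$assign)
  Qacc <- matrix(0, n, 0)
  bases <- list()
  for (bn in names(blocks)) {
    B <- X[, blocks[[bn]], drop = FALSE]
    if (ncol(Qacc) > 0) B <- B - Qacc %*% crossprod(Qacc, B)
    qrB <- qr(B)
    r <- sum(abs(diag(qrB$qr)[seq_len(min(dim(B)))]) > 1e-8 * sqrt(n))
    Qb <- if (r > 0) qr.Q(qrB)[, seq_len(r), drop = FALSE] else
      matrix(0, n, 0)
    bases[[bn]] <- Qb
    Qacc <- cbind(Qacc, Qb)
  }
  bases   # named by term index as character ("0" = intercept)
}

#' Per-gene sequential variance partitioning
#'
#' For each gene, decomposes the total sum of squares of its (VST-scale)
#' expression over the model terms by sequential (Type-I) attribution in the
#' design's fixed term order, then divides by the total SS. Term fractions
#' plus the residual fraction sum to one exactly. Constant genes have no
#' defined decomposition; they are excluded and listed.
#'
#' @param expr gene x sample numeric matrix.
#' @param design a `"DesignMatrix"` from [buildDesign()], rows aligned with
#'   `colnames(expr)`.
#' @return object of class `"VariancePartition"`: list with `fractions`
#'   (gene x term matrix including a `residual` column) and `excluded`
#'   (constant gene ids).
#' @export
varianceExplained <- function(expr, design) {
  stopifnot(inherits(design, "DesignMatrix"))
  if (ncol(expr) != nrow(design$X))
    stop("expression columns and design rows disagree")
  Y <- t(expr)                               # samples x genes
  bases <- .sequentialBasis(design)
  termIdx <- setdiff(names(bases), "0")
  labels <- design$terms[as.integer(termIdx)]
  interceptSS <- colSums(crossprod(bases[["0"]], Y)^2)
  totalSS <- colSums(Y^2) - interceptSS
  SS <- sapply(termIdx, function(i) {
    Qb <- bases[[i]]
    if (ncol(Qb) == 0) return(numeric(ncol(Y)))
    colSums(crossprod(Qb, Y)^2)
  })
  if (is.null(dim(SS))) SS <- matrix(SS, nrow = 1)
  colnames(SS) <- labels
  resid <- pmax(0, totalSS - rowSums(SS))
  const <- totalSS <= 1e-12 * nrow(Y)
  frac <- cbind(SS, residual = resid) / ifelse(const, NA, totalSS)
  rownames(frac) <- rownames(expr)
  structure(list(fractions = frac[!const, , drop = FALSE],
                 excluded = rownames(expr)[const],
                 terms = labels, aliased = design$aliased),
            class = "VariancePartition")
}

#' Select genes in or above a percentile of a term's variance fraction
#'
#' Computes the requested quantile (linear interpolation between order
#' statistics) of the per-gene variance-explained fraction for one model term
#' and retains genes at or above it (inclusive threshold, so ties at the
#' threshold are kept).
#'
#' @param partition a `"VariancePartition"`.
#' @param term model term to rank by (default `"rootstock"`).
#' @param q percentile in (0, 1), default 0.75 (the upper quartile).
#' @return list: `genes` (ids retained), `threshold` (the fraction cut-off),
#'   `fractions` (named vector used for ranking).
#' @export
selectTopPercentile <- function(partition, term = "rootstock", q = 0.75) {
  stopifnot(inherits(partition, "VariancePartition"))
  if (q <= 0 || q >= 1) stop("q must lie strictly inside (0, 1)")
  if (!term %in% colnames(partition$fractions))
    stop("term '", term, "' not in partition (has: ",
         paste(setdiff(colnames(partition$fractions), "residual"),
               collapse = ", "), ")")
  fr <- partition$fractions[, term]
  thr <- unname(quantile(fr, q, type = 7))
  list(genes = names(fr)[fr >= thr], threshold = thr, fractions = fr)
}
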