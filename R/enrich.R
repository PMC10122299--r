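#' Filter an annotation map on E-value
#'
#' Keeps records whose E-value is strictly below the threshold (the
#' conventional 1e-10 cut; a record at exactly the threshold is removed).
#' Records lacking an E-value are dropped unless `keepMissing = TRUE`.
#'
#' @param annotation data.frame from [readAnnotation()] / [makeAnnotation()].
#' @param maxEvalue strict upper bound (default 1e-10).
#' @param keepMissing keep records with `NA` E-values.
#' @return the filtered annotation data.frame.
#' @export
filterAnnotation <- function(annotation, maxEvalue = 1e-10,
                             keepMissing = FALSE) {
  keep <- !is.na(annotation$evalue) & annotation$evalue < maxEvalue
  if (keepMissing) keep <- keep | is.na(annotation$evalue)
  out <- annotation[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric enrichment of a gene set
#'
#' For every term of the annotation (intersected with the universe), the
#' upper-tail probability that a random draw of the query's size from the
#' universe overlaps the term at least as much as observed:
#' `p = P(X >= k)` for X hypergeometric with `N` universe genes of which `K`
#' carry the term and `n` drawn. The observed overlap is included in the
#' tail, so `k = 0` gives `p = 1`.
#'
#' @param queryGenes gene ids of the query set (must lie in the universe).
#' @param annotation (filtered) annotation data.frame.
#' @param universeGenes gene ids of the background universe.
#' @return data.frame of class `"EnrichmentResult"`: term, source, N, K, n,
#'   k, p (one row per term, sorted by p). An empty query yields all
#'   `p = 1`.
#' @export
hypergeomEnrich <- function(queryGenes, annotation, universeGenes) {
  universeGenes <- unique(universeGenes)
  if (length(universeGenes) == 0) stop("empty universe")
  extra <- setdiff(queryGenes, universeGenes)
  if (length(extra))
    stop("query gene(s) outside the universe: ",
         paste(head(extra, 5), collapse = ", "))
  queryGenes <- unique(queryGenes)
  ann <- annotation[annotation$gene %in% universeGenes, , drop = FALSE]
  N <- length(universeGenes)
  n <- length(queryGenes)
  terms <- unique(ann$term)
  res <- lapply(terms, function(t) {
    tg <- unique(ann$gene[ann$term == t])
    K <- length(tg)
    k <- length(intersect(tg, queryGenes))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = t,
               source = ann$source[ann$term == t][1],
               N = N, K = K, n = n, k = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(term = character(), source = character(),
                      N = integer(), K = integer(), n = integer(),
                      k = integer(), p = numeric())
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("EnrichmentResult", "data.frame")
  out
}

#' Multiple-testing correction and significance flags
#'
#' Default scheme corrects each hypergeometric p-value by the Bonferroni
#' factor equal to the number of genes in the universe (`"gene-bonferroni"`,
#' the unconventional but explicitly stated procedure this pipeline
#' reproduces); `"term-bonferroni"` corrects by the number of terms tested
#' and `"bh"` applies Benjamini–Hochberg. Corrected p-values are capped at
#' 1; a term is significant iff its corrected p is below `alpha`.
#'
#' @param result an `"EnrichmentResult"` from [hypergeomEnrich()].
#' @param alpha significance threshold (the study used 1e-5 for PC- and
#'   SOM-derived sets and 4.6e-4 for rootstock contrasts).
#' @param scheme correction scheme.
#' @return the result with `p.corrected`, `significant`, plus attributes
#'   `alpha` and `scheme`.
#' @export
correctAndFlag <- function(result, alpha = 1e-5,
                           scheme = c("gene-bonferroni", "term-bonferroni",
                                      "bh")) {
  scheme <- match.arg(scheme)
  pc <- switch(scheme,
    "gene-bonferroni" = pmin(1, result$p * result$N),
    "term-bonferroni" = pmin(1, result$p * nrow(result)),
    "bh" = p.adjust(result$p, "BH"))
  result$p.corrected <- pc
  result$significant <- pc < alpha
  attr(result, "alpha") <- alpha
  attr(result, "scheme") <- scheme
  result
}

#' One-call enrichment of a gene set
#'
#' Convenience wrapper: E-value filter, hypergeometric test against the
#' annotated universe, correction and flagging.
#'
#' @param queryGenes query gene ids.
#' @param annotation unfiltered annotation data.frame.
#' @param universeGenes background universe (by default the annotated genes
#'   appearing in the filtered annotation).
#' @param maxEvalue strict E-value bound (default 1e-10).
#' @param alpha significance threshold (default 1e-5).
#' @param scheme correction scheme, see [correctAndFlag()].
#' @return a flagged `"EnrichmentResult"` sorted by corrected p.
#' @export
enrichGeneSet <- function(queryGenes, annotation, universeGenes = NULL,
                          maxEvalue = 1e-10, alpha = 1e-5,
                          scheme = "gene-bonferroni") {
  ann <- filterAnnotation(annotation, maxEvalue)
  if (is.null(universeGenes)) universeGenes <- unique(ann$gene)
  queryGenes <- intersect(queryGenes, universeGenes)
  res <- hypergeomEnrich(queryGenes, ann, universeGenes)
  correctAndFlag(res, alpha = alpha, scheme = scheme)
}
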