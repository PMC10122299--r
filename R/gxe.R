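#' Fit one gene-expression PC against one environmental PC
#'
#' Linear model of a gPC score on the ePC score (continuous), tissue and
#' rootstock, with all two- and three-way interactions:
#' `gPC ~ ePC * tissue * rootstock`. Each term's share of the response's
#' total sum of squares is attributed sequentially (Type-I, main effects
#' before interactions), so the fractions plus the residual sum to one.
#' The focal terms of the screen are the environment main effect and the
#' interactions `ePC:rootstock`, `tissue:rootstock` and
#' `ePC:tissue:rootstock`.
#'
#' @param gpc numeric per-sample gPC scores.
#' @param epc numeric per-sample ePC values (from [attachEnv()]).
#' @param meta sample metadata with `tissue` and `rootstock`.
#' @return object of class `"GxEModelResult"`: list with `fractions` (named,
#'   includes `residual`), `fit` (the `lm`), `aliased` (names of inestimable
#'   coefficients) and `df` (residual degrees of freedom).
#' @export
fitGpcModel <- function(gpc, epc, meta) {
  meta <- as.data.frame(meta)
  d <- data.frame(gpc = gpc, epc = epc,
                  tissue = factor(meta$tissue),
                  rootstock = factor(meta$rootstock))
  form <- if (nlevels(d$tissue) >= 2) gpc ~ epc * tissue * rootstock
          else gpc ~ epc * rootstock
  fit <- lm(form, data = d)
  a <- anova(fit)
  ss <- a[["Sum Sq"]]
  names(ss) <- rownames(a)
  tot <- sum(ss)
  frac <- ss / tot
  names(frac)[names(frac) == "Residuals"] <- "residual"
  structure(list(fractions = frac, fit = fit,
                 aliased = names(coef(fit))[is.na(coef(fit))],
                 df = fit$df.residual),
            class = "GxEModelResult")
}

#' Fit the full gPC x ePC model grid
#'
#' Runs [fitGpcModel()] for every combination of selected gene-expression
#' and environmental components and collects the per-term variance
#' fractions in long format.
#'
#' @param gpcScores sample x gPC score matrix.
#' @param epcPerSample data.frame from [attachEnv()] (columns `ePC<k>`),
#'   aligned with the rows of `gpcScores`.
#' @param meta sample metadata aligned the same way.
#' @param gpcComponents,epcComponents column indices to cross (default all).
#' @return list: `table` (long data.frame gpc, epc, term, fraction) and
#'   `models` (nested list of `"GxEModelResult"` keyed `[[gpc]][[epc]]`).
#' @export
fitGpcModels <- function(gpcScores, epcPerSample, meta,
                         gpcComponents = seq_len(ncol(gpcScores)),
                         epcComponents = NULL) {
  epcCols <- grep("^ePC", colnames(epcPerSample), value = TRUE)
  if (is.null(epcComponents))
    epcComponents <- as.integer(sub("^ePC", "", epcCols))
  rows <- list()
  models <- list()
  for (gk in gpcComponents) {
    models[[as.character(gk)]] <- list()
    for (ek in epcComponents) {
      res <- fitGpcModel(gpcScores[, gk], epcPerSample[[paste0("ePC", ek)]],
                         meta)
      models[[as.character(gk)]][[as.character(ek)]] <- res
      rows[[length(rows) + 1L]] <-
        data.frame(gpc = gk, epc = ek, term = names(res$fractions),
                   fraction = unname(res$fractions),
                   stringsAsFactors = FALSE)
    }
  }
  list(table = do.call(rbind, rows), models = models)
}

#' Flag model terms exceeding the effect-size threshold
#'
#' Strict rule: a (gPC, ePC, term) triple is flagged iff its variance
#' fraction exceeds the threshold (`> 0.05` by default; a fraction of
#' exactly 0.05 is not flagged). The residual row is never flagged.
#'
#' @param table long fraction table from [fitGpcModels()] (or a compatible
#'   data.frame with `term` and `fraction`).
#' @param threshold variance fraction that must be exceeded (default 0.05).
#' @param terms optional subset of term labels to consider (default: all
#'   non-residual terms).
#' @return the flagged subset of `table`, possibly empty.
#' @export
screenEffects <- function(table, threshold = 0.05, terms = NULL) {
  if (is.null(table) || nrow(table) == 0) return(table[integer(0), ])
  keep <- table$term != "residual" & table$fraction > threshold
  if (!is.null(terms)) keep <- keep & table$term %in% terms
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Contrast row giving rootstock r's marginal slope of gPC on ePC, averaging
# over tissue levels (treatment coding).
.slopeContrast <- function(fit, level) {
  cf <- names(coef(fit))
  L <- setNames(numeric(length(cf)), cf)
  L["epc"] <- 1
  tis <- grep("^epc:tissue[^:]*$", cf, value = TRUE)
  nT <- length(tis) + 1          # dummies + reference level
  if (length(tis)) L[tis] <- 1 / nT
  own <- grep(paste0(":rootstock", level, "$"), cf, value = TRUE)
  ownSlope <- own[grepl("^epc:", own)]
  L[intersect(ownSlope, paste0("epc:rootstock", level))] <- 1
  three <- grep(paste0("^epc:tissue.*:rootstock", level, "$"), cf,
                value = TRUE)
  if (length(three)) L[three] <- 1 / nT
  L
}

#' Tukey post-hoc comparison of per-rootstock environmental slopes
#'
#' From a fitted gPC x ePC model, estimates each rootstock's marginal slope
#' of the gPC on the ePC (averaged over tissue levels) and tests all
#' pairwise slope differences with the Tukey studentized-range adjustment on
#' the model's residual degrees of freedom (Tukey–Kramer for unequal
#' standard errors). With two rootstocks the adjusted p-value coincides with
#' the unadjusted two-sample slope t-test.
#'
#' @param result a `"GxEModelResult"` from [fitGpcModel()].
#' @param alpha significance level for the `significant` flag (default
#'   0.05).
#' @return list: `slopes` (rootstock, slope, se) and `contrasts` (pair,
#'   diff, se, t, p.tukey, significant).
#' @export
posthocSlopes <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "GxEModelResult"))
  fit <- result$fit
  rs <- levels(fit$model$rootstock)
  k <- length(rs)
  if (k < 2) stop("need at least two rootstock levels")
  if (length(result$aliased))
    stop("model has inestimable coefficients: ",
         paste(result$aliased, collapse = ", "))
  V <- vcov(fit)
  L <- t(vapply(rs, function(r) .slopeContrast(fit, r),
                numeric(length(coef(fit)))))
  est <- drop(L %*% coef(fit))
  se <- sqrt(diag(L %*% V %*% t(L)))
  slopes <- data.frame(rootstock = rs, slope = est, se = se,
                       row.names = NULL)
  pairs <- combn(k, 2)
  ctr <- apply(pairs, 2, function(ij) {
    l <- L[ij[1], ] - L[ij[2], ]
    d <- sum(l * coef(fit))
    s <- sqrt(drop(t(l) %*% V %*% l))
    tval <- d / s
    # for two groups the range statistic is sqrt(2)|t| and the adjusted p
    # reduces exactly to the two-sided t-test; use that closed form rather
    # than the ptukey quadrature
    p <- if (k == 2) 2 * pt(abs(tval), df = result$df, lower.tail = FALSE)
         else ptukey(sqrt(2) * abs(tval), nmeans = k, df = result$df,
                     lower.tail = FALSE)
    c(diff = d, se = s, t = tval, p = p)
  })
  contrasts <- data.frame(pair = apply(pairs, 2, function(ij)
                            paste(rs[ij[1]], "-", rs[ij[2]])),
                          diff = ctr["diff", ], se = ctr["se", ],
                          t = ctr["t", ], p.tukey = ctr["p", ],
                          significant = ctr["p", ] < alpha,
                          row.names = NULL)
  list(slopes = slopes, contrasts = contrasts)
}

#' Heavy-loader gene sets of a principal component
#'
#' Genes whose loading on a component lies beyond `z` standard deviations of
#' the mean loading: the positive set above `mean + z sd`, the negative set
#' below `mean - z sd`. Degenerate all-equal loadings (sd 0) give empty
#' sets.
#'
#' @param pca a [PCAResult-class] (typically the gPCA, variables = genes).
#' @param component component index.
#' @param z threshold in loading standard deviations (default 1.96).
#' @return list: `positive` and `negative` gene-id vectors, `bounds`
#'   (`c(lower, upper)`) and `z`.
#' @export
heavyLoaders <- function(pca, component, z = 1.96) {
  stopifnot(z > 0)
  L <- pcaLoadings(pca)
  if (component > ncol(L)) stop("component ", component, " not available")
  l <- L[, component]
  mu <- mean(l); s <- sd(l)
  if (s == 0)
    return(list(positive = character(), negative = character(),
                bounds = c(mu, mu), z = z))
  list(positive = names(l)[l > mu + z * s],
       negative = names(l)[l < mu - z * s],
       bounds = c(lower = mu - z * s, upper = mu + z * s), z = z)
}
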