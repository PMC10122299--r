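test_that("composite statistics reproduce hand-computed window summaries", {
  w <- toyWeather(c(10, 12, 14, 16),
                  extra = list(precipitation = c(0, 1, 0, 2)))
  cs <- compositeStats(w, "2018-06-11 11:00", windowH = 4)
  expect_equal(cs$temperature_min, 10)
  expect_equal(cs$temperature_max, 16)
  expect_equal(cs$temperature_change, 6)
  expect_equal(cs$temperature_mean, 13)
  # accumulating feature: sum only, no min/max/mean columns
  expect_equal(cs$precipitation_sum, 3)
  expect_false(any(grepl("precipitation_(min|max|mean|change)",
                         colnames(cs))))
  # constant window has zero change; lastFirst mode can differ from range
  w2 <- toyWeather(c(5, 9, 5, 7))
  expect_equal(compositeStats(w2, "2018-06-11 11:00",
                              windowH = 4)$temperature_change, 4)
  expect_equal(compositeStats(w2, "2018-06-11 11:00", windowH = 4,
                              changeMode = "lastFirst")$temperature_change, 2)
  expect_equal(compositeStats(toyWeather(rep(8, 4)), "2018-06-11 11:00",
                              windowH = 4)$temperature_change, 0)
})

test_that("composite window is the 24 hours preceding the anchor, missing data bounded", {
  vals <- 1:30
  w <- toyWeather(vals, start = "2018-06-10 00:00")
  cs <- compositeStats(w, "2018-06-11 00:00")  # hours 01:00..00:00 next day
  expect_equal(cs$temperature_min, 2)
  expect_equal(cs$temperature_max, 25)
  expect_equal(cs$temperature_mean, mean(2:25))
  # a window before the record is an error; a few missing hours are tolerated
  expect_error(compositeStats(w, "2018-06-01 00:00"), "entirely missing")
  wGap <- suppressMessages(HourlyWeather(weatherTime(w)[-(3:8)],
                                         weatherFeatures(w)[-(3:8), ,
                                                            drop = FALSE]))
  expect_silent(cs2 <- compositeStats(wGap, "2018-06-11 00:00"))
  expect_error(compositeStats(wGap, "2018-06-11 00:00",
                              maxMissingFrac = 0.1), "missing")
})

test_that("environmental table has one row per sampling day across the study", {
  sim <- smallStudy()
  env <- buildEnvTable(sim$weather, sim$design, allDays = FALSE)
  # 3 years x 3 phenologies of distinct dates
  expect_equal(nrow(env), 9)
  expect_setequal(env$date, unique(format(sim$design$datetime, "%Y-%m-%d")))
  # 8 averaged features x 4 stats + 2 summed features
  expect_equal(ncol(env) - 1, 8 * 4 + 2)
  all <- buildEnvTable(sim$weather, allDays = TRUE)
  expect_equal(nrow(all), length(unique(format(weatherTime(sim$weather),
                                               "%Y-%m-%d"))))
  expect_identical(colnames(all), colnames(env))
})

test_that("PCA has orthonormal loadings, a fixed sign and exact reconstruction", {
  set.seed(21)
  X <- matrix(rnorm(20 * 6), 20, 6,
              dimnames = list(paste0("d", 1:20), paste0("v", 1:6)))
  pca <- pcaTable(X, standardize = TRUE)
  L <- pcaLoadings(pca); S <- pcaScores(pca)
  expect_equal(crossprod(L), diag(ncol(L)), ignore_attr = TRUE,
               tolerance = 1e-10)
  # largest-magnitude loading of every component is positive
  for (k in seq_len(ncol(L))) expect_gt(L[which.max(abs(L[, k])), k], 0)
  # scores reconstruct the standardized data
  Z <- scale(X)
  expect_equal(S %*% t(L), Z, ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(sum(pcaVarFrac(pca)), 1)
  # a one-axis table concentrates all variance on PC1
  one <- outer(rnorm(15), c(1, 2, -1)) +
    matrix(5, 15, 3, dimnames = list(NULL, c("a", "b", "c")))
  p1 <- pcaTable(one, standardize = FALSE)
  expect_equal(pcaVarFrac(p1)[1], 1, tolerance = 1e-10)
  # zero-variance columns are dropped with a warning when standardizing
  Xz <- cbind(X, flat = 3)
  expect_warning(pz <- pcaTable(Xz), "zero-variance")
  expect_equal(pz@dropped, "flat")
})

test_that("component selection takes the smallest prefix reaching the target", {
  mk <- function(vf) {
    k <- length(vf)
    new("PCAResult", scores = matrix(0, 2, k), loadings = diag(k),
        varFrac = vf, center = numeric(k), scale = numeric(k),
        dropped = character())
  }
  expect_equal(selectComponents(mk(c(0.5, 0.3, 0.15, 0.05)), 0.80), 1:2)
  expect_equal(selectComponents(mk(c(0.85, 0.1, 0.05)), 0.80), 1L)
  expect_equal(selectComponents(mk(c(0.4, 0.3, 0.2, 0.1)), 0.95), 1:4)
  # exact boundary counts as reached
  expect_equal(selectComponents(mk(c(0.6, 0.2, 0.2)), 0.80), 1:2)
})

test_that("samples inherit the ePC scores of their sampling date", {
  sim <- smallStudy()
  env <- buildEnvTable(sim$weather, sim$design, allDays = FALSE)
  # nocturnal radiation minima are structurally zero every day
  pca <- suppressWarnings(pcaTable(env))
  ps <- attachEnv(sim$design, env, pcaScores(pca), components = 1:2)
  expect_equal(nrow(ps), nrow(sim$design))
  expect_identical(colnames(ps), c("sample", "date", "ePC1", "ePC2"))
  # all samples of one day share one score
  expect_lte(length(unique(ps$ePC1)), 9)
  d <- ps$date[1]
  expect_equal(length(unique(ps$ePC1[ps$date == d])), 1)
  expect_equal(ps$ePC1[ps$date == d][1],
               unname(pcaScores(pca)[match(d, env$date), 1]))
  bad <- sim$design; bad$datetime[1] <- as.POSIXct("1999-01-01", tz = "UTC")
  expect_error(attachEnv(bad, env, pcaScores(pca)),
               bad$sample[1])
})

test_that("leading ePCs capture the planted environmental axis", {
  sim <- smallStudy()
  env <- buildEnvTable(sim$weather, sim$design, allDays = FALSE)
  pca <- suppressWarnings(pcaTable(env))
  keep <- selectComponents(pca, 0.80)
  S <- pcaScores(pca)[, keep, drop = FALSE]
  idx <- sim$envIndex[env$date]
  r2 <- summary(lm(idx ~ S))$r.squared
  expect_gt(r2, 0.8)
})

test_that("gPC model fractions are sequential and detect a planted slope", {
  set.seed(31)
  n <- 120
  meta <- toyMeta(n,
                  rootstock = rep(c("ungrafted", "1103P", "3309C", "SO4"),
                                  each = n / 4),
                  tissue = rep(c("leaf", "reproductive"), n / 2))
  epc <- rnorm(n)
  slopes <- c(ungrafted = 1, `1103P` = -1, `3309C` = 1, SO4 = -1)
  gpc <- slopes[meta$rootstock] * epc + rnorm(n, sd = 0.3)
  res <- fitGpcModel(gpc, epc, meta)
  fr <- res$fractions
  expect_equal(sum(fr), 1)
  # the signal lives in the epc:rootstock interaction
  expect_gt(fr[["epc:rootstock"]], 0.5)
  expect_lt(fr[["residual"]], 0.2)
  # pure-noise response leaves nearly everything in the residual
  resN <- fitGpcModel(rnorm(n), epc, meta)
  expect_gt(resN$fractions[["residual"]], 0.8)
  # a strong environmental main effect lands on the epc term
  resE <- fitGpcModel(2 * epc + rnorm(n, sd = 0.2), epc, meta)
  expect_gt(resE$fractions[["epc"]], 0.9)
})

test_that("model fractions agree with anova() on the same fit", {
  set.seed(32)
  n <- 60
  meta <- toyMeta(n, rootstock = sample(c("ungrafted", "SO4"), n, TRUE),
                  tissue = sample(c("leaf", "reproductive"), n, TRUE))
  epc <- rnorm(n)
  gpc <- rnorm(n)
  res <- fitGpcModel(gpc, epc, meta)
  a <- anova(lm(gpc ~ epc * factor(meta$tissue) * factor(meta$rootstock)))
  expect_equal(unname(res$fractions[["epc"]]),
               a[["Sum Sq"]][1] / sum(a[["Sum Sq"]]), tolerance = 1e-10)
})

test_that("effect screen flags strictly above the threshold", {
  tab <- data.frame(gpc = 1, epc = 1,
                    term = c("epc", "epc:rootstock", "rootstock", "residual"),
                    fraction = c(0.05, 0.0500001, 0.9, 0.3))
  out <- screenEffects(tab, 0.05)
  # exactly 0.05 is not flagged; the residual is never flagged
  expect_setequal(out$term, c("epc:rootstock", "rootstock"))
  out2 <- screenEffects(tab, 0.05, terms = c("epc", "epc:rootstock"))
  expect_equal(out2$term, "epc:rootstock")
  expect_equal(nrow(screenEffects(tab[0, ], 0.05)), 0)
})

test_that("Tukey slope contrasts match emmeans and the k = 2 t-test identity", {
  set.seed(33)
  n <- 96
  meta4 <- toyMeta(n,
                   rootstock = rep(c("ungrafted", "1103P", "3309C", "SO4"),
                                   each = n / 4),
                   tissue = rep(c("leaf", "reproductive"), n / 2))
  epc <- rnorm(n)
  gpc <- c(1, -1, 0.5, 0)[match(meta4$rootstock,
                                c("ungrafted", "1103P", "3309C", "SO4"))] *
    epc + rnorm(n, sd = 0.5)
  res <- fitGpcModel(gpc, epc, meta4)
  ph <- posthocSlopes(res)
  em <- emmeans::emtrends(res$fit, pairwise ~ rootstock, var = "epc",
                          adjust = "tukey")
  emc <- as.data.frame(em$contrasts)
  # same slope differences and adjusted p-values (up to ordering/sign)
  expect_equal(sort(abs(ph$contrasts$diff)), sort(abs(emc$estimate)),
               tolerance = 1e-8)
  expect_equal(sort(ph$contrasts$p.tukey), sort(emc$p.value),
               tolerance = 1e-6)
  # two rootstocks: Tukey p equals the plain slope t-test p
  meta2 <- toyMeta(n, rootstock = rep(c("ungrafted", "SO4"), each = n / 2))
  gpc2 <- (meta2$rootstock == "SO4") * 0.4 * epc + rnorm(n, sd = 1)
  res2 <- fitGpcModel(gpc2, epc, meta2)
  ph2 <- posthocSlopes(res2)
  cfName <- grep("^epc:rootstock", rownames(summary(res2$fit)$coefficients),
                 value = TRUE)
  tt <- summary(res2$fit)$coefficients[cfName, ]
  expect_lt(abs(ph2$contrasts$p.tukey - tt["Pr(>|t|)"]), 1e-10)
})

test_that("heavy loaders are the tails of the loading distribution", {
  set.seed(34)
  l1 <- rnorm(5000)
  L <- cbind(PC1 = l1 / sqrt(sum(l1^2)))
  rownames(L) <- paste0("g", seq_along(l1))
  pca <- new("PCAResult", scores = matrix(0, 2, 1), loadings = L,
             varFrac = 1, center = 0, scale = 1, dropped = character())
  hl <- heavyLoaders(pca, 1, z = 1.96)
  frac <- (length(hl$positive) + length(hl$negative)) / length(l1)
  expect_lt(abs(frac - 0.05), 0.015)
  expect_true(all(L[hl$positive, 1] > hl$bounds[["upper"]]))
  expect_true(all(L[hl$negative, 1] < hl$bounds[["lower"]]))
  # one extreme gene in otherwise flat loadings
  L2 <- cbind(PC1 = c(rep(0.01, 99), 0.9))
  rownames(L2) <- paste0("g", 1:100)
  pca2 <- new("PCAResult", scores = matrix(0, 2, 1), loadings = L2,
              varFrac = 1, center = 0, scale = 1, dropped = character())
  hl2 <- heavyLoaders(pca2, 1)
  expect_equal(hl2$positive, "g100")
  expect_length(hl2$negative, 0)
  expect_error(heavyLoaders(pca2, 3), "not available")
})
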