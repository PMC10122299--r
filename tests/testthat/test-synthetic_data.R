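test_that("design enumerates the factorial minus the lost final-year cell", {
  d <- simulateDesign(simulationConfig())
  # 2*3*3*4*9*2 = 1296 minus the 72 reproductive-harvest samples of 2019
  expect_equal(nrow(d), 1224)
  expect_false(any(d$tissue == "reproductive" & d$phenology == "harvest" &
                   d$year == 2019))
  expect_equal(sum(d$tissue == "reproductive" & d$phenology == "harvest" &
                   d$year == 2018), 4 * 9 * 2)
  expect_false(anyDuplicated(d$sample) > 0)
  keepAll <- simulateDesign(simulationConfig(
    dropFinalReproductiveHarvest = FALSE))
  expect_equal(nrow(keepAll), 1296)
})

test_that("design is deterministic and uses no RNG", {
  cfg <- simulationConfig(nBlocks = 2L)
  set.seed(99); before <- runif(1)
  set.seed(99)
  d1 <- simulateDesign(cfg)
  expect_equal(runif(1), before)  # RNG stream untouched
  expect_identical(d1, simulateDesign(cfg))
})

test_that("sampling datetimes fall on the phenology date, staggered by block", {
  d <- simulateDesign(simulationConfig(nBlocks = 3L))
  ver <- d[d$phenology == "veraison" & d$year == 2018, ]
  expect_true(all(format(ver$datetime, "%m-%d") == "08-01"))
  expect_equal(sort(unique(format(ver$datetime, "%H:%M"))),
               c("11:00", "11:15", "11:30"))
})

test_that("weather covers the growing seasons hourly with planted year-2 anomalies", {
  cfg <- simulationConfig(seed = 21L, noiseSd = 0, humidityNoiseSd = 0,
                          precipProb = 0)
  w <- suppressMessages(simulateWeather(cfg))
  tm <- weatherTime(w)
  expect_setequal(unique(format(tm, "%Y")), c("2017", "2018", "2019"))
  expect_setequal(unique(format(tm, "%m")), sprintf("%02d", 4:10))
  X <- weatherFeatures(w)
  yr <- format(tm, "%Y")
  tempMeans <- tapply(X[, "temperature"], yr, mean)
  # noise-free: 2018 warmer by exactly the configured offset
  expect_equal(unname(tempMeans["2018"] - tempMeans["2017"]),
               cfg$tempOffsetYear2, tolerance = 1e-10)
  expect_equal(unname(tempMeans["2019"]), unname(tempMeans["2017"]),
               tolerance = 1e-10)
  et0 <- tapply(X[, "refEvapotranspiration"], yr, mean)
  expect_gt(et0["2018"] - et0["2017"], cfg$et0OffsetYear2 * 0.8)
})

test_that("year-2 humidity is drier and more variable, rain scarcer", {
  w <- suppressMessages(simulateWeather(simulationConfig(seed = 22L)))
  yr <- format(weatherTime(w), "%Y")
  X <- weatherFeatures(w)
  hum <- split(X[, "relHumidity"], yr)
  expect_lt(mean(hum[["2018"]]), mean(hum[["2017"]]) - 3)
  expect_gt(var(hum[["2018"]]), var(hum[["2017"]]) * 1.3)
  rain <- tapply(X[, "precipitation"] > 0, yr, mean)
  expect_lt(rain[["2018"]], rain[["2017"]])
})

test_that("environment index is the standardized day-mean temperature", {
  w <- toyWeather(rep(c(10, 20, 30), each = 24),
                  start = "2018-06-01 00:00")
  idx <- environmentIndex(w)
  expect_length(idx, 3)
  expect_equal(mean(idx), 0)
  expect_equal(sd(idx), 1)
  expect_equal(unname(idx), (c(10, 20, 30) - 20) / 10)
})

test_that("null generator counts behave as Poisson around the planted mean", {
  cfg <- simulationConfig(nGenes = 300L, nBlocks = 2L, seed = 31L,
                          dispersion = c(a0 = 0, a1 = 0),
                          tissueFrac = 0, yearFrac = 0, phenologyFrac = 0,
                          rootstockFrac = 0, gxeFrac = 0, silentFrac = 0,
                          librarySizeSd = 0)
  sim <- suppressMessages(simulateStudy(cfg))
  cnt <- counts(sim$experiment)
  mu <- rowMeans(cnt)
  v <- apply(cnt, 1, var)
  # index of dispersion ~ 1 for Poisson
  expect_equal(median(v / mu), 1, tolerance = 0.1)
})

test_that("negative-binomial counts obey the dispersion-trend moment relation", {
  cfg <- simulationConfig(nGenes = 1200L, nBlocks = 2L, seed = 32L,
                          dispersion = c(a0 = 0.15, a1 = 1),
                          tissueFrac = 0, yearFrac = 0, phenologyFrac = 0,
                          rootstockFrac = 0, gxeFrac = 0, silentFrac = 0,
                          librarySizeSd = 0)
  sim <- suppressMessages(simulateStudy(cfg))
  cnt <- counts(sim$experiment)
  mu <- rowMeans(cnt)
  keep <- mu > 50            # where the quadratic term dominates
  alphaHat <- (apply(cnt, 1, var) - mu) / mu^2
  expect_lt(abs(median(alphaHat[keep]) - 0.15), 0.05)
})

test_that("planted effects show up with the configured magnitude", {
  sim <- smallStudy()
  cnt <- counts(sim$experiment)
  meta <- sim$design
  lg <- log2(cnt + 1)
  tr <- sim$truth
  # tissue effect: mean log2 difference near +-tissueLog2FC for flagged genes
  dTis <- rowMeans(lg[, meta$tissue == "reproductive"]) -
    rowMeans(lg[, meta$tissue == "leaf"])
  flag <- tr$tissueEffect != 0 & tr$baselineLog2 > 4
  expect_equal(mean(abs(dTis[flag])), 2, tolerance = 0.35)
  expect_lt(mean(abs(dTis[tr$tissueEffect == 0 & tr$baselineLog2 > 4])), 0.3)
  # rootstock archetype: ungraftedHigh genes higher in ungrafted vines
  uh <- tr$archetype %in% "ungraftedHigh" & tr$baselineLog2 > 4
  dRs <- rowMeans(lg[, meta$rootstock == "ungrafted"]) -
    rowMeans(lg[, meta$rootstock != "ungrafted"])
  expect_gt(min(dRs[uh]), 0.5)
})

test_that("gxe genes track the environmental index with the planted slope pattern", {
  sim <- smallStudy()
  meta <- sim$design
  lg <- log2(counts(sim$experiment) + 1)
  e <- sim$envIndex[format(meta$datetime, "%Y-%m-%d")]
  tr <- sim$truth
  g <- which(tr$gxeFlag & tr$baselineLog2 > 5)[1:10]
  slopeIn <- function(gene, rs) {
    sel <- meta$rootstock == rs
    coef(lm(lg[gene, sel] ~ e[sel]))[2]
  }
  sUngr <- vapply(g, slopeIn, numeric(1), rs = "ungrafted")
  s1103 <- vapply(g, slopeIn, numeric(1), rs = "1103P")
  expect_gt(mean(sUngr), 0.5)   # pattern +1 on the reference stock
  expect_lt(mean(s1103), -0.5)  # pattern -1 on 1103P
  # disjoint from the rootstock-archetype block
  expect_false(any(tr$gxeFlag & tr$rootstockFlag))
})

test_that("silent genes are weakly expressed and never carry planted effects", {
  sim <- smallStudy()
  tr <- sim$truth
  expect_gt(sum(tr$silent), 0)
  expect_true(all(tr$tissueEffect[tr$silent] == 0))
  expect_false(any(tr$rootstockFlag[tr$silent] | tr$gxeFlag[tr$silent]))
  cnt <- counts(sim$experiment)
  expect_lt(max(rowMeans(cnt[tr$silent, ])), 5)
})

test_that("generator is deterministic in the seed and responsive to it", {
  cfg <- simulationConfig(nGenes = 120L, nBlocks = 1L, seed = 41L)
  s1 <- suppressMessages(simulateStudy(cfg))
  s2 <- suppressMessages(simulateStudy(cfg))
  expect_identical(counts(s1$experiment), counts(s2$experiment))
  expect_identical(s1$truth, s2$truth)
  expect_identical(weatherFeatures(s1$weather), weatherFeatures(s2$weather))
  cfg$seed <- 42L
  s3 <- suppressMessages(simulateStudy(cfg))
  expect_false(identical(counts(s1$experiment), counts(s3$experiment)))
})

test_that("annotation generator plants one enriched term at the configured odds", {
  sim <- smallStudy()
  ann <- sim$annotation
  tr <- sim$truth
  expect_true(all(c("gene", "term", "source", "evalue") %in% colnames(ann)))
  expect_false(any(duplicated(ann[, c("gene", "term")])))
  # per-term membership probabilities over repeated generations
  cfg <- simulationConfig(nGenes = 400L, nBlocks = 2L, seed = 11L)
  inT1 <- outT1 <- 0L
  nRep <- 60L
  for (r in seq_len(nRep)) {
    cfg$seed <- 1000L + r
    a <- simulateAnnotation(cfg, tr)
    t1 <- unique(a$gene[a$term == "TERM0001"])
    inT1 <- inT1 + sum(tr$gene[tr$rootstockFlag] %in% t1)
    outT1 <- outT1 + sum(tr$gene[!tr$rootstockFlag] %in% t1)
  }
  pIn <- inT1 / (nRep * sum(tr$rootstockFlag))
  pOut <- outT1 / (nRep * sum(!tr$rootstockFlag))
  oddsHat <- (pIn / (1 - pIn)) / (pOut / (1 - pOut))
  expect_gt(oddsHat, cfg$enrichmentOdds * 0.6)
  expect_lt(oddsHat, cfg$enrichmentOdds * 1.6)
  # E-value split around the 1e-10 threshold
  expect_equal(mean(ann$evalue < 1e-10), 0.9, tolerance = 0.06)
  empty <- simulateAnnotation(simulationConfig(nTerms = 0L), tr)
  expect_equal(nrow(empty), 0)
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(simulationConfig(gxeFrac = 1.2), "gxeFrac")
  expect_error(simulationConfig(silentFrac = -0.1), "silentFrac")
  expect_error(simulationConfig(dispersion = c(a0 = -1, a1 = 0)),
               "non-negative")
  expect_error(simulationConfig(gxePattern = c(1, -1)), "one entry per")
  expect_error(simulationConfig(samplingDates = c(anthesis = "06-01")),
               "samplingDates")
})
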