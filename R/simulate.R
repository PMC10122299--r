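#' Configuration for the synthetic study generator
#'
#' Defines the simulated study: a replicated grafted-vineyard design (two
#' tissues, three years, three phenological stages, four rootstocks, blocks
#' of vines sampled twice), negative-binomial counts with a mean-dispersion
#' trend `alpha(mu) = a1/mu + a0`, planted design effects, rootstock-pattern
#' archetypes, rootstock-specific responses to an environmental index, and a
#' structured hourly weather record whose second year is anomalous (warmer,
#' higher evapotranspiration, more variable and drier air) — the situation in
#' which genotype-by-environment signal becomes visible.
#'
#' The reproductive x harvest cell of the final year is absent from the
#' design, mirroring a season in which fruit was lost before harvest.
#'
#' @param nGenes number of genes.
#' @param tissues,years,phenologies,rootstocks factor levels of the design.
#' @param nBlocks replicated blocks per rootstock (9 emulates the source
#'   vineyard; reduce for quick runs).
#' @param vinesPerBlock vines sampled per block (the middle two).
#' @param dropFinalReproductiveHarvest drop the reproductive x harvest cell of
#'   the last year.
#' @param baselineLog2Mean,baselineLog2Sd normal distribution of per-gene
#'   baseline log2 mean counts.
#' @param silentFrac fraction of genes that are essentially unexpressed
#'   (baseline log2 mean drawn from N(-2, 1)), giving the expression filter
#'   realistic work.
#' @param dispersion `c(a0 =, a1 =)` of the NB dispersion trend, both `>= 0`.
#' @param librarySizeSd sd of the lognormal per-sample depth factors.
#' @param tissueFrac,tissueLog2FC fraction of genes with a tissue effect and
#'   its log2 magnitude (sign random per gene); analogous `yearFrac` /
#'   `yearLog2FC` and `phenologyFrac` / `phenologyLog2FC` pick one random
#'   level to shift.
#' @param rootstockFrac,rootstockLog2FC fraction of genes carrying a
#'   rootstock-pattern archetype and the log2 magnitude of the pattern.
#' @param gxeFrac,gxeSlopeLog2,gxePattern fraction of genes whose expression
#'   tracks the environmental index with rootstock-specific slopes; the slope
#'   of rootstock r is `gxeSlopeLog2 * gxePattern[r]` (log2 units per sd of
#'   the index). The default pattern (+, -, +, -) opposes own-rooted/3309C
#'   vines to 1103P/SO4 vines.
#' @param baseTemp,seasonalAmplitude,diurnalAmplitude,noiseSd temperature
#'   model (deg C): seasonal arc plus diurnal cycle plus AR(1) noise.
#' @param tempOffsetYear2,et0OffsetYear2 additive year-2 anomalies on
#'   temperature (deg C) and reference evapotranspiration (mm/h equivalent
#'   scale).
#' @param humidityNoiseSd,humidityVarMultYear2,humidityMeanOffsetYear2 relative
#'   humidity noise sd, its year-2 variance multiplier, and the year-2 mean
#'   shift (percentage points).
#' @param precipProb,precipRateMultYear2 hourly rain probability and the
#'   year-2 multiplier on it.
#' @param samplingDates named month-day strings, one per phenology.
#' @param samplingHour local hour at which sampling starts.
#' @param nTerms,termSize,enrichmentOdds,evalueBelowFrac annotation generator:
#'   number of terms, expected genes per term, odds ratio by which term 1 is
#'   enriched in the rootstock-flagged gene set, and the fraction of records
#'   with E-values below 1e-10.
#' @param seed integer RNG seed.
#' @return a validated `simulationConfig` list.
#' @export
simulationConfig <- function(nGenes = 2000L,
                             tissues = c("leaf", "reproductive"),
                             years = c(2017L, 2018L, 2019L),
                             phenologies = c("anthesis", "veraison", "harvest"),
                             rootstocks = c("ungrafted", "1103P", "3309C", "SO4"),
                             nBlocks = 9L, vinesPerBlock = 2L,
                             dropFinalReproductiveHarvest = TRUE,
                             baselineLog2Mean = 5, baselineLog2Sd = 2,
                             silentFrac = 0.05,
                             dispersion = c(a0 = 0.1, a1 = 1),
                             librarySizeSd = 0.3,
                             tissueFrac = 0.4, tissueLog2FC = 2,
                             yearFrac = 0.3, yearLog2FC = 1,
                             phenologyFrac = 0.3, phenologyLog2FC = 1,
                             rootstockFrac = 0.05, rootstockLog2FC = 1.5,
                             gxeFrac = 0.1, gxeSlopeLog2 = 1,
                             gxePattern = c(1, -1, 1, -1),
                             baseTemp = 18, seasonalAmplitude = 8,
                             diurnalAmplitude = 6, noiseSd = 2,
                             tempOffsetYear2 = 3, et0OffsetYear2 = 0.1,
                             humidityNoiseSd = 8, humidityVarMultYear2 = 2,
                             humidityMeanOffsetYear2 = -8,
                             precipProb = 0.05, precipRateMultYear2 = 0.6,
                             samplingDates = c(anthesis = "06-01",
                                               veraison = "08-01",
                                               harvest = "09-15"),
                             samplingHour = 11L,
                             nTerms = 50L, termSize = 40L,
                             enrichmentOdds = 8, evalueBelowFrac = 0.9,
                             seed = 1L) {
  cfg <- as.list(environment())
  fr <- c("tissueFrac", "yearFrac", "phenologyFrac", "rootstockFrac",
          "gxeFrac", "evalueBelowFrac", "silentFrac")
  for (f in fr)
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  if (any(dispersion < 0)) stop("dispersion parameters must be non-negative")
  if (nGenes < 1) stop("nGenes must be >= 1")
  if (length(gxePattern) != length(rootstocks))
    stop("gxePattern needs one entry per rootstock")
  if (!all(phenologies %in% names(samplingDates)))
    stop("samplingDates must name every phenology")
  structure(cfg, class = "simulationConfig")
}

# rootstock-pattern archetypes, scaled to unit max magnitude; rows are
# patterns over the rootstock levels in declared order
.archetypeCatalog <- function(rootstocks) {
  k <- length(rootstocks)
  grafted <- as.numeric(seq_len(k) > 1)
  alt <- rep_len(c(0, 1), k)
  cat <- rbind(
    ungraftedHigh = 1 - grafted,          # down-regulated in grafted vines
    ungraftedLow  = grafted - 1,          # up-regulated in grafted vines
    vigorHigh     = alt,                  # high under vigor-inducing stocks
    vigorLow      = -alt)
  colnames(cat) <- rootstocks
  cat
}

#' Simulate the sample design of the study
#'
#' Full factorial over tissue x year x phenology x rootstock x block x vine,
#' minus (by default) the reproductive x harvest cell of the final year.
#' Irrigation level rotates over blocks; sampling datetimes fall on the
#' phenology's calendar date of each year, staggered by block within the
#' morning sampling window. Deterministic given the config (no RNG used).
#'
#' @param config a [simulationConfig()].
#' @return data.frame with the standard metadata columns, one row per sample.
#' @examples
#' nrow(simulateDesign(simulationConfig())) # 1224
#' @export
simulateDesign <- function(config) {
  stopifnot(inherits(config, "simulationConfig"))
  if (any(lengths(config[c("tissues", "years", "phenologies",
                           "rootstocks")]) == 0))
    stop("every design factor needs at least one level")
  g <- expand.grid(vine = seq_len(config$vinesPerBlock),
                   block = seq_len(config$nBlocks),
                   rootstock = config$rootstocks,
                   phenology = config$phenologies,
                   year = config$years,
                   tissue = config$tissues,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (config$dropFinalReproductiveHarvest &&
      "reproductive" %in% config$tissues &&
      "harvest" %in% config$phenologies) {
    drop <- g$tissue == "reproductive" & g$phenology == "harvest" &
      g$year == max(config$years)
    g <- g[!drop, , drop = FALSE]
  }
  irrLevels <- defaultFactorLevels()$irrigation
  g$irrigation <- irrLevels[((g$block - 1L) %% length(irrLevels)) + 1L]
  md <- config$samplingDates[g$phenology]
  start <- as.POSIXct(sprintf("%d-%s %02d:00", g$year, md,
                              config$samplingHour), tz = "UTC")
  g$datetime <- start + 900 * (g$block - 1L)   # 15-min stagger down the rows
  g$sample <- sprintf("%s_%d_%s_%s_b%02d_v%d",
                      substr(g$tissue, 1, 1), g$year,
                      substr(g$phenology, 1, 3), g$rootstock, g$block, g$vine)
  rownames(g) <- NULL
  g[, c("sample", "tissue", "year", "phenology", "rootstock", "irrigation",
        "block", "vine", "datetime")]
}

#' Simulate the hourly weather record
#'
#' One growing season (April through October) per study year, hourly. The
#' temperature combines a seasonal arc, a diurnal cycle peaking mid-afternoon
#' and AR(1) noise; humidity moves against temperature; solar radiance is the
#' deterministic clear-sky curve damped by a slowly varying cloud process;
#' evapotranspiration follows temperature and radiation. The second study
#' year receives the configured anomalies: warmer, higher
#' evapotranspiration, more variable and drier air, less rain.
#'
#' @param config a [simulationConfig()].
#' @return an [HourlyWeather-class] covering all study years.
#' @export
simulateWeather <- function(config) {
  stopifnot(inherits(config, "simulationConfig"))
  set.seed(config$seed + 101L)
  years <- config$years
  out <- vector("list", length(years))
  for (i in seq_along(years)) {
    yr <- years[i]
    tm <- seq(as.POSIXct(sprintf("%d-04-01 00:00", yr), tz = "UTC"),
              as.POSIXct(sprintf("%d-10-31 23:00", yr), tz = "UTC"),
              by = "hour")
    n <- length(tm)
    h <- as.numeric(format(tm, "%H"))
    doy <- as.numeric(format(tm, "%j"))
    s <- (doy - min(doy)) / diff(range(doy))          # 0..1 over the season
    isYear2 <- (i == 2L && length(years) >= 2L)

    ar <- function(sdv, phi = 0.8) {
      if (sdv == 0) return(numeric(n))
      e <- rnorm(n, 0, sdv * sqrt(1 - phi^2))
      as.numeric(stats::filter(e, phi, method = "recursive"))
    }
    temp <- config$baseTemp +
      config$seasonalAmplitude * sin(pi * s) +
      config$diurnalAmplitude * sin(2 * pi * (h - 9) / 24) +
      ar(config$noiseSd) +
      if (isYear2) config$tempOffsetYear2 else 0

    humSd <- config$humidityNoiseSd *
      (if (isYear2) sqrt(config$humidityVarMultYear2) else 1)
    humidity <- pmin(100, pmax(5,
      70 - 0.8 * (temp - config$baseTemp) + ar(humSd) +
        if (isYear2) config$humidityMeanOffsetYear2 else 0))

    clearSky <- pmax(0, sin(pi * (h - 6) / 12)) * (700 + 300 * sin(pi * s))
    cloud <- pmin(1, pmax(0, 0.55 + ar(0.25, phi = 0.95)))
    solar <- clearSky * cloud
    radDensity <- solar * 0.0036                       # MJ m-2 per hour

    pRain <- config$precipProb *
      (if (isYear2) config$precipRateMultYear2 else 1)
    precip <- rbinom(n, 1, pRain) * rexp(n, rate = 0.5)

    wind <- abs(rnorm(n, 3, 1.5))
    pressure <- 1013 - 0.1 * (temp - config$baseTemp) + ar(1.5, phi = 0.9)
    dew <- temp - (100 - humidity) / 5
    et0 <- pmax(0, 0.01 * (temp - 5) + 0.0004 * solar) +
      if (isYear2) config$et0OffsetYear2 else 0

    out[[i]] <- data.frame(timestamp = tm, temperature = temp,
                           precipitation = precip, windSpeed = wind,
                           relHumidity = humidity, solarRadiance = solar,
                           radiationDensity = radDensity, pressure = pressure,
                           dewPoint = dew, refEvapotranspiration = et0,
                           clearSkyRadiation = clearSky)
  }
  all <- do.call(rbind, out)
  HourlyWeather(all$timestamp, all[, -1],
                units = c(temperature = "degC", precipitation = "mm",
                          windSpeed = "m/s", relHumidity = "%",
                          solarRadiance = "W/m2", radiationDensity = "MJ/m2",
                          pressure = "hPa", dewPoint = "degC",
                          refEvapotranspiration = "mm",
                          clearSkyRadiation = "W/m2"))
}

#' Standardized day-mean temperature of a weather record
#'
#' The generator's planted environmental axis: the mean temperature of each
#' calendar day, standardized over all recorded days. Downstream recovery
#' tests compare estimated environmental components against this index.
#'
#' @param weather an [HourlyWeather-class].
#' @return named numeric vector, one value per day (`names` are dates).
#' @export
environmentIndex <- function(weather) {
  day <- format(weatherTime(weather), "%Y-%m-%d")
  m <- tapply(weatherFeatures(weather)[, "temperature"], day, mean)
  s <- sd(m)
  v <- if (s > 0) (m - mean(m)) / s else m * 0
  setNames(as.numeric(v), names(m))
}

#' Simulate negative-binomial counts with planted truth
#'
#' Counts for gene g in sample j are drawn NB with
#' `log2 mu = baseline_g + design effects + slope_g(rootstock_j) * E(day_j)
#' + log2(depth_j)` and dispersion `alpha(mu) = a1/mu + a0`, where `E` is the
#' standardized day-mean temperature ([environmentIndex()]) and `depth_j` are
#' lognormal library-size factors (geometric mean 1). Rootstock-flagged genes
#' follow one of four archetypal patterns over rootstocks (down/up in all
#' grafted vines; high/low under the vigor-inducing stocks); a disjoint gene
#' block carries rootstock-specific environmental slopes.
#'
#' @param design output of [simulateDesign()].
#' @param weather output of [simulateWeather()] covering the design's years.
#' @param config the same [simulationConfig()].
#' @return list with `experiment` (a [GraftExperiment-class]) and `truth`
#'   (data.frame of per-gene planted flags, magnitudes, archetype ids and
#'   per-rootstock slopes).
#' @export
simulateCounts <- function(design, weather, config) {
  stopifnot(inherits(config, "simulationConfig"))
  if (any(config$dispersion < 0)) stop("dispersion parameters must be non-negative")
  dDay <- format(design$datetime, "%Y-%m-%d")
  env <- environmentIndex(weather)
  if (!all(dDay %in% names(env)))
    stop("weather does not cover all sampling days of the design")
  set.seed(config$seed + 202L)
  n <- config$nGenes
  m <- nrow(design)
  genes <- sprintf("gene%05d", seq_len(n))
  rs <- config$rootstocks
  cat <- .archetypeCatalog(rs)

  baseline <- rnorm(n, config$baselineLog2Mean, config$baselineLog2Sd)
  silent <- runif(n) < config$silentFrac
  baseline[silent] <- rnorm(sum(silent), -2, 1)
  expressed <- which(!silent)
  # planted effects land on expressed genes only
  nPick <- function(frac) {
    k <- min(round(frac * n), length(expressed))
    if (k == 0) integer() else sample(expressed, k)
  }

  tIdx <- nPick(config$tissueFrac)
  tEff <- numeric(n)
  tEff[tIdx] <- config$tissueLog2FC * sample(c(-1, 1), length(tIdx), TRUE)

  yIdx <- nPick(config$yearFrac)
  yEff <- numeric(n); yLev <- rep(NA_integer_, n)
  yEff[yIdx] <- config$yearLog2FC * sample(c(-1, 1), length(yIdx), TRUE)
  yLev[yIdx] <- sample(config$years, length(yIdx), TRUE)

  pIdx <- nPick(config$phenologyFrac)
  pEff <- numeric(n); pLev <- rep(NA_character_, n)
  pEff[pIdx] <- config$phenologyLog2FC * sample(c(-1, 1), length(pIdx), TRUE)
  pLev[pIdx] <- sample(config$phenologies, length(pIdx), TRUE)

  rIdx <- nPick(config$rootstockFrac)
  arch <- rep(NA_character_, n)
  arch[rIdx] <- rownames(cat)[sample.int(nrow(cat), length(rIdx), TRUE)]

  pool <- setdiff(expressed, rIdx)
  kG <- min(round(config$gxeFrac * n), length(pool))
  gIdx <- if (kG == 0) integer() else sample(pool, kG)
  slopes <- matrix(0, n, length(rs), dimnames = list(genes, rs))
  if (length(gIdx))
    slopes[gIdx, ] <- matrix(config$gxeSlopeLog2 * config$gxePattern,
                             length(gIdx), length(rs), byrow = TRUE)

  depth <- rlnorm(m, 0, config$librarySizeSd)
  depth <- depth / exp(mean(log(depth)))

  log2mu <- matrix(baseline, n, m)
  isRep <- design$tissue == "reproductive"
  if (any(isRep)) log2mu[, isRep] <- log2mu[, isRep] + tEff
  for (g in yIdx)
    log2mu[g, design$year == yLev[g]] <- log2mu[g, design$year == yLev[g]] + yEff[g]
  for (g in pIdx)
    log2mu[g, design$phenology == pLev[g]] <-
      log2mu[g, design$phenology == pLev[g]] + pEff[g]
  rsCol <- match(design$rootstock, rs)
  if (length(rIdx)) {
    patt <- cat[arch[rIdx], , drop = FALSE] * config$rootstockLog2FC
    log2mu[rIdx, ] <- log2mu[rIdx, ] + patt[, rsCol, drop = FALSE]
  }
  eSamp <- env[dDay]
  log2mu <- log2mu + slopes[, rsCol, drop = FALSE] *
    matrix(eSamp, n, m, byrow = TRUE)
  log2mu <- log2mu + matrix(log2(depth), n, m, byrow = TRUE)

  mu <- 2^log2mu
  a0 <- config$dispersion[["a0"]]; a1 <- config$dispersion[["a1"]]
  alpha <- a1 / mu + a0
  cnt <- matrix(0, n, m, dimnames = list(genes, design$sample))
  if (a0 == 0 && a1 == 0) {
    cnt[] <- stats::rpois(n * m, lambda = mu)
  } else {
    cnt[] <- rnbinom(n * m, mu = mu, size = 1 / alpha)
  }
  truth <- data.frame(gene = genes, baselineLog2 = baseline, silent = silent,
                      tissueEffect = tEff, yearEffect = yEff, yearLevel = yLev,
                      phenologyEffect = pEff, phenologyLevel = pLev,
                      rootstockFlag = seq_len(n) %in% rIdx, archetype = arch,
                      rootstockLog2FC = ifelse(seq_len(n) %in% rIdx,
                                               config$rootstockLog2FC, 0),
                      gxeFlag = seq_len(n) %in% gIdx,
                      stringsAsFactors = FALSE)
  truth <- cbind(truth, setNames(as.data.frame(slopes),
                                 paste0("slope_", rs)))
  rownames(truth) <- NULL
  list(experiment = GraftExperiment(cnt, design,
         factorLevels = list(tissue = config$tissues,
                             phenology = config$phenologies,
                             rootstock = config$rootstocks,
                             irrigation = defaultFactorLevels()$irrigation)),
       truth = truth)
}

#' Simulate a gene-to-term annotation with one planted enriched term
#'
#' Every term recruits genes independently with a baseline probability of
#' `termSize / nGenes`; the first term's recruitment odds are multiplied by
#' `enrichmentOdds` inside the rootstock-flagged gene set, so enrichment
#' analyses have a known positive. E-values are drawn below or above the
#' conventional 1e-10 filter threshold in the configured proportion.
#'
#' @param config a [simulationConfig()].
#' @param truth the truth table from [simulateCounts()].
#' @return annotation data.frame (gene, term, source, evalue); the planted
#'   term is `"TERM0001"`.
#' @export
simulateAnnotation <- function(config, truth) {
  stopifnot(inherits(config, "simulationConfig"))
  set.seed(config$seed + 303L)
  if (config$nTerms == 0)
    return(makeAnnotation(data.frame(gene = character(), term = character())))
  p0 <- min(1, config$termSize / config$nGenes)
  odds0 <- p0 / (1 - p0)
  pEnr <- (odds0 * config$enrichmentOdds) / (1 + odds0 * config$enrichmentOdds)
  flagged <- truth$rootstockFlag
  recs <- vector("list", config$nTerms)
  for (t in seq_len(config$nTerms)) {
    p <- rep(p0, nrow(truth))
    if (t == 1L) p[flagged] <- pEnr
    member <- runif(nrow(truth)) < p
    if (!any(member)) next
    k <- sum(member)
    below <- runif(k) < config$evalueBelowFrac
    ev <- ifelse(below, 10^runif(k, -30, -11), 10^runif(k, -9, -2))
    recs[[t]] <- data.frame(gene = truth$gene[member],
                            term = sprintf("TERM%04d", t),
                            source = "pfam", evalue = ev,
                            stringsAsFactors = FALSE)
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (length(recs) == 0)
    return(makeAnnotation(data.frame(gene = character(),
                                     term = character())))
  makeAnnotation(do.call(rbind, recs))
}

#' Simulate the full study
#'
#' Convenience wrapper: design, weather, counts-with-truth and annotation
#' from a single config, deterministic given the config's seed.
#'
#' @param config a [simulationConfig()].
#' @return list with `experiment`, `design`, `weather`, `truth`,
#'   `annotation` and `envIndex`.
#' @export
simulateStudy <- function(config = simulationConfig()) {
  design <- simulateDesign(config)
  weather <- simulateWeather(config)
  cw <- simulateCounts(design, weather, config)
  ann <- simulateAnnotation(config, cw$truth)
  list(experiment = cw$experiment, design = design, weather = weather,
       truth = cw$truth, annotation = ann,
       envIndex = environmentIndex(weather))
}
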