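# Shared small fixtures, computed once per test file.

# A compact full-featured simulated study (2 blocks => 272 samples).
smallStudy <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressMessages(simulateStudy(
        simulationConfig(nGenes = 400L, nBlocks = 2L, seed = 11L)))
    cache
  }
})

# A null study: no planted effects, no silent genes, equal depths.
nullStudy <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressMessages(simulateStudy(simulationConfig(
        nGenes = 400L, nBlocks = 2L, seed = 12L,
        tissueFrac = 0, yearFrac = 0, phenologyFrac = 0,
        rootstockFrac = 0, gxeFrac = 0, silentFrac = 0,
        librarySizeSd = 0)))
    cache
  }
})

# Minimal valid metadata for n samples (single-level factors allowed).
toyMeta <- function(n, rootstock = rep("ungrafted", n),
                    tissue = rep("leaf", n), year = rep(2017L, n),
                    phenology = rep("anthesis", n)) {
  data.frame(sample = paste0("s", seq_len(n)), tissue = tissue,
             year = year, phenology = phenology, rootstock = rootstock,
             irrigation = rep("none", n), block = rep(1L, n),
             datetime = as.POSIXct("2017-06-01 11:00", tz = "UTC") +
               3600 * seq_len(n),
             stringsAsFactors = FALSE)
}

# Random named count matrix.
toyCounts <- function(nGenes, nSamples, lambda = 50, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(nGenes * nSamples, lambda), nGenes, nSamples,
              dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                              sprintf("s%03d", seq_len(nSamples))))
  m
}

# Toy hourly weather starting at a given time.
toyWeather <- function(values, start = "2018-06-11 08:00",
                       extra = list()) {
  n <- length(values)
  tm <- seq(as.POSIXct(start, tz = "UTC"), by = "hour", length.out = n)
  feats <- c(list(temperature = values), extra)
  HourlyWeather(tm, as.data.frame(feats))
}
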