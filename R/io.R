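#' Default factor-level domains for a rootstock trial
#'
#' The declared levels the metadata validator accepts. Studies with other
#' rootstock names (or more irrigation levels, years, ...) pass their own list
#' with the same element names; `NULL` for an element disables domain checking
#' of that column.
#'
#' @param rootstocks character vector of legal rootstock labels; the first is
#'   treated as the ungrafted / own-rooted reference.
#' @return named list of level vectors for tissue, phenology, rootstock and
#'   irrigation.
#' @export
defaultFactorLevels <- function(rootstocks = c("ungrafted", "1103P", "3309C", "SO4")) {
  list(tissue     = c("leaf", "reproductive"),
       phenology  = c("anthesis", "veraison", "harvest"),
       rootstock  = rootstocks,
       irrigation = c("none", "partial", "full"))
}

.requiredMetaCols <- c("sample", "tissue", "year", "phenology", "rootstock",
                       "irrigation", "block", "datetime")

.validateCounts <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene rownames and sample colnames")
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup))
    stop("duplicate gene identifiers: ", paste(unique(dup), collapse = ", "))
  dup <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup))
    stop("duplicate sample identifiers: ", paste(unique(dup), collapse = ", "))
  if (anyNA(counts)) stop("counts must not contain NA")
  if (any(counts < 0)) stop("counts must be non-negative")
  invisible(counts)
}

.validateMeta <- function(meta, factorLevels = defaultFactorLevels()) {
  missing <- setdiff(.requiredMetaCols, colnames(meta))
  if (length(missing))
    stop("metadata is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(meta$sample))
    stop("duplicate sample identifiers in metadata")
  for (col in intersect(names(factorLevels), colnames(meta))) {
    dom <- factorLevels[[col]]
    if (is.null(dom)) next
    bad <- setdiff(unique(as.character(meta[[col]])), dom)
    if (length(bad))
      stop(sprintf("unknown %s level(s): %s (declared: %s)", col,
                   paste(bad, collapse = ", "), paste(dom, collapse = ", ")))
  }
  dt <- meta$datetime
  if (!inherits(dt, "POSIXct")) {
    parsed <- tryCatch(
      as.POSIXct(as.character(dt), tz = "UTC",
                 tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%dT%H:%M",
                                "%Y-%m-%d")),
      error = function(e) rep(as.POSIXct(NA), length(dt)))
    if (anyNA(parsed))
      stop("unparseable sampling datetime(s): ",
           paste(head(as.character(dt)[is.na(parsed)], 5), collapse = ", "))
    meta$datetime <- parsed
  }
  meta
}

#' Construct a validated GraftExperiment
#'
#' Couples a gene x sample count matrix with per-sample design metadata.
#' Counts must be non-negative with unique gene and sample identifiers;
#' metadata must have one row per count column (matched by the `sample`
#' column) with factor levels drawn from the declared domains and a parseable
#' sampling datetime.
#'
#' @param counts integer-like matrix, genes x samples, with dimnames.
#' @param meta data.frame of sample metadata with columns
#'   `sample, tissue, year, phenology, rootstock, irrigation, block, datetime`.
#' @param factorLevels declared factor domains, see [defaultFactorLevels()].
#' @return a [GraftExperiment-class].
#' @examples
#' sim <- simulateStudy(simulationConfig(nGenes = 50, nBlocks = 1, seed = 1))
#' sim$experiment
#' @export
GraftExperiment <- function(counts, meta, factorLevels = defaultFactorLevels()) {
  .validateCounts(counts)
  meta <- .validateMeta(as.data.frame(meta), factorLevels)
  if (!setequal(meta$sample, colnames(counts)))
    stop("metadata samples and count columns disagree; see validateStudy() ",
         "for a non-fatal report")
  meta <- meta[match(colnames(counts), meta$sample), , drop = FALSE]
  cd <- S4Vectors::DataFrame(meta, row.names = meta$sample)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd,
    metadata = list(factorLevels = factorLevels))
  new("GraftExperiment", se)
}

#' Raw counts of a GraftExperiment
#' @param object a [GraftExperiment-class].
#' @param ... unused.
#' @return the integer gene x sample matrix.
#' @importMethodsFrom BiocGenerics counts
#' @importFrom BiocGenerics counts
#' @exportMethod counts
#' @aliases counts
setMethod("counts", "GraftExperiment", function(object, ...) {
  SummarizedExperiment::assay(object, "counts")
})

#' Sample design table of a GraftExperiment
#' @param x a [GraftExperiment-class].
#' @return sample metadata as a base data.frame.
#' @export
sampleTable <- function(x) {
  stopifnot(is(x, "GraftExperiment"))
  as.data.frame(SummarizedExperiment::colData(x))
}

.mtxSidecars <- function(path) {
  base <- sub("\\.mtx$", "", path)
  c(rows = paste0(base, "_genes.txt"), cols = paste0(base, "_samples.txt"))
}

#' Read a count matrix
#'
#' TSV dialect: genes as rows, first column gene identifiers, header line of
#' sample identifiers. MatrixMarket dialect: coordinate `.mtx` file with
#' sidecar `<base>_genes.txt` / `<base>_samples.txt` name files (one
#' identifier per line).
#'
#' @param path file to read.
#' @param format `"tsv"` or `"mtx"`.
#' @return validated integer matrix, genes x samples, order preserved.
#' @export
readCounts <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") {
    df <- tryCatch(read.delim(path, check.names = FALSE, sep = "\t"),
                   error = function(e)
                     stop("malformed count TSV '", path, "': ",
                          conditionMessage(e), call. = FALSE))
    if (ncol(df) < 1) stop("malformed count TSV '", path, "': no columns")
    genes <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (nrow(m) > 0 && !is.numeric(m)) {
      bad <- which(apply(df[, -1, drop = FALSE], 1,
                         function(r) anyNA(suppressWarnings(as.numeric(r)))))[1]
      stop(sprintf("malformed count TSV '%s': non-numeric value at data line %d",
                   path, bad))
    }
    storage.mode(m) <- "double"
    rownames(m) <- genes
  } else {
    side <- .mtxSidecars(path)
    if (!all(file.exists(side)))
      stop("missing MatrixMarket sidecar name file(s): ",
           paste(side[!file.exists(side)], collapse = ", "))
    sm <- Matrix::readMM(path)
    m <- as.matrix(sm)
    rownames(m) <- readLines(side["rows"])
    colnames(m) <- readLines(side["cols"])
  }
  .validateCounts(m)
  m
}

#' Write a count matrix
#'
#' Inverse of [readCounts()]; round-trips are exact for integer counts.
#'
#' @param counts validated gene x sample matrix.
#' @param path destination file.
#' @param format `"tsv"` or `"mtx"` (writes sidecar name files next to the
#'   `.mtx`).
#' @return `path`, invisibly.
#' @export
writeCounts <- function(counts, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  .validateCounts(counts)
  if (format == "tsv") {
    df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
    ok <- tryCatch({
      write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("cannot write to ", path)
  } else {
    side <- .mtxSidecars(path)
    Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                "generalMatrix"), path)
    writeLines(rownames(counts), side["rows"])
    writeLines(colnames(counts), side["cols"])
  }
  invisible(path)
}

#' Read a sample metadata table
#'
#' TSV with columns `sample, tissue, year, phenology, rootstock, irrigation,
#' block, datetime`; factor columns are validated against the declared
#' domains and the sampling datetime is parsed (timezone-naive local time).
#'
#' @param path TSV file.
#' @param factorLevels declared domains, see [defaultFactorLevels()].
#' @return validated data.frame, one row per sample.
#' @export
readSampleTable <- function(path, factorLevels = defaultFactorLevels()) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  for (col in c("year", "block")) if (col %in% colnames(df)) {
    num <- suppressWarnings(as.numeric(df[[col]]))
    if (!anyNA(num)) df[[col]] <- num
  }
  .validateMeta(df, factorLevels)
}

#' Write a sample metadata table
#' @param meta data.frame as returned by [sampleTable()] or [simulateDesign()].
#' @param path destination TSV.
#' @return `path`, invisibly.
#' @export
writeSampleTable <- function(meta, path) {
  out <- meta
  if (inherits(out$datetime, "POSIXct"))
    out$datetime <- format(out$datetime, "%Y-%m-%d %H:%M")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an HourlyWeather object
#'
#' @param time POSIXct vector (or parseable character), strictly increasing.
#' @param features numeric matrix or data.frame, one row per timestamp.
#' @param units optional named character vector of unit strings.
#' @return an [HourlyWeather-class]; gaps in the hourly grid are allowed but
#'   flagged with a message.
#' @export
HourlyWeather <- function(time, features, units = character()) {
  if (!inherits(time, "POSIXct"))
    time <- as.POSIXct(as.character(time), tz = "UTC",
                       tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                      "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%dT%H:%M"))
  if (anyNA(time)) stop("unparseable weather timestamp(s)")
  features <- as.matrix(as.data.frame(features))
  storage.mode(features) <- "double"
  obj <- new("HourlyWeather", time = time, features = features,
             units = units)
  d <- diff(as.numeric(time)) / 3600
  gaps <- sum(d > 1.5)
  if (gaps > 0)
    message(gaps, " gap(s) in the hourly weather grid")
  obj
}

#' Read an hourly weather CSV
#'
#' First column `timestamp` (ISO-8601), remaining columns numeric features.
#'
#' @param path CSV file.
#' @return an [HourlyWeather-class]; non-monotone timestamps are an error.
#' @export
readWeather <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, sep = ",", check.names = FALSE)
  tcol <- if ("timestamp" %in% colnames(df)) "timestamp" else colnames(df)[1]
  HourlyWeather(df[[tcol]], df[, setdiff(colnames(df), tcol), drop = FALSE])
}

#' Write an hourly weather CSV
#' @param weather an [HourlyWeather-class].
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
writeWeather <- function(weather, path) {
  df <- data.frame(timestamp = format(weatherTime(weather), "%Y-%m-%dT%H:%M"),
                   weatherFeatures(weather), check.names = FALSE)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-to-term annotation table
#'
#' TSV with columns `gene`, `term`, optional `source` (pfam / interpro / go /
#' other) and optional `evalue`. Rows lacking an E-value are kept with
#' `evalue = NA`; negative E-values are an error. Duplicate (gene, term) pairs
#' are collapsed to their smallest E-value.
#'
#' @param path TSV file.
#' @return data.frame with columns gene, term, source, evalue.
#' @export
readAnnotation <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, check.names = FALSE)
  if (!all(c("gene", "term") %in% colnames(df)))
    stop("annotation table needs 'gene' and 'term' columns")
  if (!"source" %in% colnames(df)) df$source <- "other"
  if (!"evalue" %in% colnames(df)) df$evalue <- NA_real_
  df$evalue <- as.numeric(df$evalue)
  makeAnnotation(df)
}

#' Validate an annotation map held in memory
#' @param df data.frame with columns gene, term and optionally source, evalue.
#' @return validated data.frame with unique (gene, term) pairs.
#' @export
makeAnnotation <- function(df) {
  df <- as.data.frame(df)
  if (!"source" %in% colnames(df)) df$source <- rep("other", nrow(df))
  if (!"evalue" %in% colnames(df)) df$evalue <- rep(NA_real_, nrow(df))
  if (any(df$evalue < 0, na.rm = TRUE)) stop("negative E-value in annotation")
  df <- df[order(df$gene, df$term, df$evalue, na.last = TRUE), ,
           drop = FALSE]
  df <- df[!duplicated(df[, c("gene", "term")]), , drop = FALSE]
  rownames(df) <- NULL
  df[, c("gene", "term", "source", "evalue")]
}

#' Cross-check counts against design metadata
#'
#' Pure diagnostic: reports samples present in only one input, design cells
#' (tissue x year x phenology x rootstock) with zero replicates among matched
#' samples, and replicate imbalance across the occupied cells. An entirely
#' empty design cell — such as the reproductive harvest of a year lost to
#' powdery mildew — is reported, not raised. Only an empty intersection of
#' samples is an error.
#'
#' @param counts gene x sample matrix.
#' @param meta sample metadata data.frame.
#' @return list with elements `unmatched` (character), `emptyCells`
#'   (data.frame of absent factor combinations), `imbalance` (range of
#'   replicate counts over occupied cells) and `ok` (no issues found).
#' @export
validateStudy <- function(counts, meta) {
  inBoth <- intersect(colnames(counts), meta$sample)
  if (length(inBoth) == 0)
    stop("no samples shared between counts and metadata")
  unmatched <- c(setdiff(colnames(counts), meta$sample),
                 setdiff(meta$sample, colnames(counts)))
  m <- meta[meta$sample %in% inBoth, , drop = FALSE]
  fac <- c("tissue", "year", "phenology", "rootstock")
  fac <- fac[fac %in% colnames(m)]
  tab <- table(lapply(m[fac], factor))
  cells <- as.data.frame(tab, stringsAsFactors = FALSE)
  empty <- cells[cells$Freq == 0, fac, drop = FALSE]
  rownames(empty) <- NULL
  occ <- cells$Freq[cells$Freq > 0]
  res <- list(unmatched = unmatched, emptyCells = empty,
              imbalance = range(occ),
              ok = length(unmatched) == 0 && nrow(empty) == 0 &&
                   length(unique(occ)) == 1)
  res
}
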