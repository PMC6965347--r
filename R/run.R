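# ---- pipeline entry points (also driven by inst/scripts/tpa.R) -------------

paramsToList <- function(params)
  list(alpha = params@alpha, nMin = params@nMin,
       dMax = if (is.na(params@dMax)) NULL else params@dMax,
       maxLevels = params@maxLevels, maxLength = params@maxLength,
       mode = params@mode)

writeManifest <- function(outputDir, inputs, params, extra = list()) {
  manifest <- c(list(
    package = "tpattern",
    version = as.character(utils::packageVersion("tpattern")),
    inputs = lapply(inputs, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))),
    params = paramsToList(params)
  ), extra)
  jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run T-pattern detection end to end
#'
#' Reads a two-column event file, runs [detectTPatterns()], writes the
#' pattern table (\code{patterns.tsv}), optional per-pattern diagrams and
#' a run manifest (\code{manifest.json}: parameters, seeds and input
#' hashes, sufficient to reproduce the run bit-for-bit).
#'
#' @param input Path to a two-column \code{<time>\\t<event-type>} file.
#' @param outputDir Output directory (created if needed).
#' @param params A [DetectionParams-class] object.
#' @param diagrams Write DOT/JSON diagrams for each pattern.
#' @return Invisibly, the list of detected patterns.
#' @export
runDetect <- function(input, outputDir, params = detectionParams(),
                      diagrams = FALSE) {
  if (!file.exists(input)) stop("input file not found: ", input)
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  data <- readTData(input)
  patterns <- detectTPatterns(data, params)
  exportPatternTable(patterns, file.path(outputDir, "patterns.tsv"))
  if (diagrams)
    for (i in seq_along(patterns))
      exportPatternDiagram(patterns[[i]], data,
        dotTarget = file.path(outputDir, sprintf("pattern_%03d.dot", i)),
        jsonTarget = file.path(outputDir, sprintf("pattern_%03d.json", i)))
  writeManifest(outputDir, list(input), params,
                list(command = "detect", nPatterns = length(patterns)))
  invisible(patterns)
}

#' Run surrogate-data Monte Carlo validation end to end
#'
#' Reads an event file, runs [monteCarloValidate()] and writes the
#' per-length comparison as TSV (\code{validation.tsv}: length, observed,
#' mean, sd), JSON (\code{validation.json}) and a manifest.
#'
#' @inheritParams runDetect
#' @param method \code{"shuffle"} or \code{"rotation"}.
#' @param nRandomizations Number of surrogates.
#' @param seed Integer seed.
#' @return Invisibly, the [MonteCarloResult-class].
#' @export
runValidate <- function(input, outputDir, params = detectionParams(),
                        method = "shuffle", nRandomizations = 50,
                        seed = 1) {
  if (!file.exists(input)) stop("input file not found: ", input)
  if (nRandomizations < 1) stop("nRandomizations must be >= 1")
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  data <- readTData(input)
  res <- monteCarloValidate(data, params, method, nRandomizations, seed)
  tab <- as.data.frame(res)
  utils::write.table(tab, file.path(outputDir, "validation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(method = res@method, nRandomizations = res@nRandomizations,
         table = tab),
    file.path(outputDir, "validation.json"), auto_unbox = TRUE, digits = NA)
  writeManifest(outputDir, list(input), params,
                list(command = "validate", method = method,
                     nRandomizations = nRandomizations, seed = seed))
  invisible(res)
}

#' Run [1,1]-restricted substring discovery on sequences
#'
#' Reads plain text (one sequence, whitespace and characters outside the
#' alphabet dropped) or FASTA (leading \code{>}; one analysis per record),
#' converts with [sequenceToTData()], runs detection in \code{"fixed11"}
#' mode and writes the recovered strings (concatenated terminals) with
#' their occurrence counts to \code{strings.tsv} (one file per record,
#' suffixed by record name for multi-record FASTA).
#'
#' @inheritParams runDetect
#' @param params [DetectionParams-class]; the mode is forced to
#'   \code{"fixed11"}. Defaults allow strings up to 30 letters.
#' @param alphabet Passed to [sequenceToTData()].
#' @return Invisibly, a named list (per record) of data.frames with
#'   columns \code{string}, \code{m}, \code{n}, \code{rootP}.
#' @export
runSequence <- function(input, outputDir,
                        params = detectionParams(mode = "fixed11",
                                                 maxLength = 30,
                                                 maxLevels = 30),
                        alphabet = "abcdefghijklmnopqrstuvwxyz") {
  if (!file.exists(input)) stop("input file not found: ", input)
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  params@mode <- "fixed11"
  first <- readLines(input, n = 1L, warn = FALSE)
  tdatas <- if (length(first) && startsWith(first, ">")) {
    readFastaTData(input, alphabet)
  } else {
    txt <- paste(readLines(input, warn = FALSE), collapse = "")
    list(sequence = sequenceToTData(txt, alphabet))
  }
  results <- lapply(names(tdatas), function(nm) {
    patterns <- detectTPatterns(tdatas[[nm]], params)
    tab <- data.frame(
      string = vapply(patterns, function(p)
        paste(patternTerminals(p), collapse = ""), ""),
      m = vapply(patterns, patternLength, 0L),
      n = vapply(patterns, nOccurrences, 0L),
      rootP = vapply(patterns, function(p) p@ci@pValue, 0),
      stringsAsFactors = FALSE)
    suffix <- if (length(tdatas) > 1L)
      paste0("_", gsub("[^A-Za-z0-9._-]", "_", nm)) else ""
    utils::write.table(tab,
      file.path(outputDir, paste0("strings", suffix, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    tab
  })
  names(results) <- names(tdatas)
  writeManifest(outputDir, list(input), params,
                list(command = "sequence", records = names(tdatas)))
  invisible(results)
}

#' Write a synthetic fixture to disk
#'
#' Generates noise T-data, optionally plants a pattern template, and
#' writes the two-column event file plus a ground-truth JSON.
#'
#' @param outputDir Output directory.
#' @param nSeries,pointsPerSeries,T,seed Passed to [generateNoiseTData()].
#' @param template Optional [patternTemplate()] to plant.
#' @return Invisibly, list with the [TData-class] and the truth matrix
#'   (or \code{NULL}).
#' @export
runSimulate <- function(outputDir, nSeries = 5, pointsPerSeries = 20,
                        T = 10000, seed = 1, template = NULL) {
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  data <- generateNoiseTData(nSeries, pointsPerSeries, T, seed)
  truth <- NULL
  if (!is.null(template)) {
    res <- plantPattern(data, template, seed = seed + 1L)
    data <- res$data
    truth <- res$truth
  }
  writeTData(data, file.path(outputDir, "tdata.txt"))
  jsonlite::write_json(
    list(seed = seed, nSeries = nSeries, pointsPerSeries = pointsPerSeries,
         T = T,
         truth = if (is.null(truth)) NULL else
           as.data.frame(truth, stringsAsFactors = FALSE)),
    file.path(outputDir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(data = data, truth = truth))
}
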