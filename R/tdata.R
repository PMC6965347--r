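#' Read time-stamped event data
#'
#' Parses the two-column tab-separated dialect \code{<time>\\t<label>} (one
#' event occurrence per line, UTF-8, LF or CRLF) into a [TData-class]
#' object. Times are positive integers in coded time units; sub-second data
#' are expected to be pre-scaled by the caller. Duplicate (time, label)
#' rows are rejected rather than deduplicated: they usually indicate coding
#' errors and are surfaced as such.
#'
#' @param source File path or connection.
#' @param period Observation-period length T. If \code{NULL}, the maximum
#'   observed time is used.
#' @return A [TData-class] object with one series per distinct label.
#' @examples
#' f <- tempfile()
#' writeLines(c("3\ta", "5\tb", "9\ta"), f)
#' readTData(f)
#' @export
readTData <- function(source, period = NULL) {
  lines <- readLines(source, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineNo <- which(keep)
  if (!length(lines)) stop("no events: input contains no data lines")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("parse error at line ", lineNo[bad[1L]],
         ": expected '<time><TAB><event-type>'")
  times <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
  labels <- vapply(parts, `[`, "", 2L)
  bad <- which(is.na(times) | times < 1L)
  if (length(bad))
    stop("parse error at line ", lineNo[bad[1L]],
         ": time must be a positive integer, got '",
         vapply(parts[bad[1L]], `[`, "", 1L), "'")
  dup <- duplicated(paste(times, labels, sep = "\r"))
  if (any(dup)) {
    d <- unique(sprintf("(%d, %s)", times[dup], labels[dup]))
    stop("duplicate (time, event-type) rows (possible coding errors): ",
         paste(d, collapse = ", "))
  }
  if (!is.null(period) && any(times > period))
    stop("range error: time ", max(times), " exceeds stated period ", period)
  TData(split(times, factor(labels, levels = unique(labels))), period = period)
}

#' Write time-stamped event data
#'
#' Writes a [TData-class] object in the same two-column dialect read by
#' [readTData()]; rows are sorted by time with ties broken by label, so a
#' read/write round trip reproduces the object exactly.
#'
#' @param data A [TData-class] object.
#' @param target File path or connection.
#' @return Invisibly, \code{target}.
#' @export
writeTData <- function(data, target) {
  stopifnot(is(data, "TData"))
  labs <- eventLabels(data)
  if (any(grepl("\t", labs, fixed = TRUE)))
    stop("event-type labels containing a tab cannot be represented")
  times <- unlist(data@series, use.names = FALSE)
  labels <- rep(labs, lengths(data@series))
  ord <- order(times, labels, method = "radix")
  writeLines(sprintf("%d\t%s", times[ord], labels[ord]), target)
  invisible(target)
}

#' Concatenate single-sample recordings into a multi-sample TData
#'
#' Sample k is shifted by the sum of the preceding observation periods;
#' sample boundaries record each sample's end so that detection windows
#' never cross recordings. Series with equal labels are merged. All
#' baseline probabilities downstream use the concatenated period and total
#' counts.
#'
#' @param samples List of single- (or multi-) sample [TData-class] objects.
#' @return A [TData-class] object with \code{T} equal to the summed periods.
#' @examples
#' concatenateSamples(list(TData(list(a = 2L), period = 10),
#'                         TData(list(a = 1L), period = 5)))
#' @export
concatenateSamples <- function(samples) {
  if (!length(samples)) stop("need at least one sample")
  stopifnot(all(vapply(samples, is, logical(1), "TData")))
  offset <- 0L
  series <- list()
  boundaries <- integer()
  for (s in samples) {
    for (lab in eventLabels(s))
      series[[lab]] <- c(series[[lab]], s@series[[lab]] + offset)
    boundaries <- c(boundaries, s@sampleBoundaries + offset)
    offset <- offset + s@period
  }
  TData(series, period = offset, sampleBoundaries = boundaries)
}

#' Convert a symbol sequence to TData
#'
#' Maps a character sequence (text with separators removed, DNA, protein)
#' to occurrence-point series: position i of symbol s becomes point i of
#' series s, so \code{T} equals the sequence length and the series sizes
#' sum to \code{T}. This is the input representation for the
#' \code{"fixed11"} detection mode, which discovers recurrent contiguous
#' strings as hierarchical patterns.
#'
#' Normalization: the sequence is lowercased and characters outside
#' \code{alphabet} are dropped before conversion.
#'
#' @param sequence A single character string.
#' @param alphabet Characters to keep (a string); default the letters a-z.
#'   For nucleotide or protein input pass e.g. \code{"acgt"} or the
#'   one-letter amino-acid codes.
#' @return A [TData-class] object.
#' @examples
#' sequenceToTData("abca")
#' @export
sequenceToTData <- function(sequence, alphabet = "abcdefghijklmnopqrstuvwxyz") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(tolower(sequence), "", fixed = TRUE)[[1L]]
  keep <- chars %in% strsplit(tolower(alphabet), "", fixed = TRUE)[[1L]]
  chars <- chars[keep]
  if (!length(chars)) stop("empty sequence after normalization")
  TData(split(seq_along(chars), factor(chars, levels = unique(chars))),
        period = length(chars))
}

#' Read FASTA records as TData objects
#'
#' Reads a FASTA file and converts each record with [sequenceToTData()].
#'
#' @param path FASTA file path.
#' @param alphabet Passed to [sequenceToTData()]; default keeps letters
#'   a-z, which covers nucleotide and amino-acid one-letter codes.
#' @return Named list of [TData-class] objects, one per record.
#' @export
readFastaTData <- function(path, alphabet = "abcdefghijklmnopqrstuvwxyz") {
  seqs <- Biostrings::readBStringSet(path)
  setNames(lapply(as.character(seqs), sequenceToTData, alphabet = alphabet),
           names(seqs))
}

#' Parse event-type labels into actor / phase / behavior
#'
#' Labels following the "actor,phase,behavior" convention (e.g.
#' \code{"x,b,look"}: actor x, beginning of the behavior look) are split
#' into their components; phase must be \code{b} (begin) or \code{e} (end).
#' Labels not matching the convention get empty components and are excluded
#' from actor statistics rather than guessed.
#'
#' @param labels Character vector of event-type labels.
#' @return data.frame with columns \code{label}, \code{actor},
#'   \code{phase}, \code{behavior}.
#' @examples
#' parseEventLabels(c("x,b,look", "noise_1"))
#' @export
parseEventLabels <- function(labels) {
  parts <- strsplit(labels, ",", fixed = TRUE)
  ok <- lengths(parts) == 3L &
    vapply(parts, function(p) p[2L] %in% c("b", "e") && all(nzchar(p)),
           logical(1))
  data.frame(
    label = labels,
    actor = ifelse(ok, vapply(parts, `[`, "", 1L), ""),
    phase = ifelse(ok, vapply(parts, `[`, "", 2L), ""),
    behavior = ifelse(ok, vapply(parts, `[`, "", 3L), ""),
    stringsAsFactors = FALSE
  )
}

#' Serialize TData to JSON (debugging aid)
#'
#' @param data A [TData-class] object.
#' @return A JSON string with period, sample boundaries and per-series
#'   points.
#' @export
tdataToJSON <- function(data) {
  stopifnot(is(data, "TData"))
  jsonlite::toJSON(list(period = data@period,
                        sampleBoundaries = data@sampleBoundaries,
                        series = data@series), auto_unbox = TRUE)
}
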