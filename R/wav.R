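#' Read and write mono 16-bit PCM WAV files
#'
#' Minimal RIFF/WAVE codec for the package's interchange format: mono,
#' 16-bit signed PCM. `writeWavPcm` clips samples to [-1, 1] before
#' quantization; `readWavPcm` returns samples rescaled to [-1, 1].
#'
#' @param samples numeric vector in [-1, 1].
#' @param sampleRate sampling rate in Hz.
#' @param path file path.
#' @return `readWavPcm` returns `list(samples, sampleRate)`;
#'   `writeWavPcm` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".wav")
#' writeWavPcm(sin(2 * pi * 440 * seq(0, 0.1, by = 1/8000)), 8000, f)
#' w <- readWavPcm(f)
#' @export
writeWavPcm <- function(samples, sampleRate, path) {
  stopifnot(length(samples) > 0L, all(is.finite(samples)))
  x <- pmax(pmin(samples, 1), -1)
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  dataSize <- length(pcm) * 2L
  writeChar("RIFF", con, 4, eos = NULL)
  writeBin(as.integer(36L + dataSize), con, size = 4, endian = "little")
  writeChar("WAVE", con, 4, eos = NULL)
  writeChar("fmt ", con, 4, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")        # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")         # PCM
  writeBin(1L, con, size = 2, endian = "little")         # mono
  writeBin(as.integer(sampleRate), con, size = 4, endian = "little")
  writeBin(as.integer(sampleRate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")         # block align
  writeBin(16L, con, size = 2, endian = "little")        # bits per sample
  writeChar("data", con, 4, eos = NULL)
  writeBin(dataSize, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname writeWavPcm
#' @export
readWavPcm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE"))
    stop("not a RIFF/WAVE file: ", path)
  sampleRate <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM WAV is supported")
      channels <- fmt[2]
      sampleRate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (size > 16L) readBin(con, "raw", size - 16L)
    } else if (identical(id, "data")) {
      if (is.null(bits)) stop("malformed WAV: data before fmt chunk")
      if (bits != 16L) stop("only 16-bit PCM is supported")
      samples <- readBin(con, "integer", size / 2L, size = 2,
                         signed = TRUE, endian = "little")
      break
    } else {
      readBin(con, "raw", size + size %% 2L)
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  if (channels != 1L) stop("only mono WAV is supported")
  list(samples = samples / 32767, sampleRate = sampleRate)
}

#' Write a CallSet to disk as WAV files plus a metadata CSV
#'
#' One mono 16-bit PCM WAV per call and a metadata table with columns
#' call_id, wav_path, pig_id, team_id, age_days, age_class, context,
#' valence. `readCallSet` reads the same layout back (also accepting
#' externally produced recordings with the same schema).
#'
#' @param x a [CallSet].
#' @param dir output directory (created if needed).
#' @param metaFile metadata CSV path; default `file.path(dir, "meta.csv")`.
#' @return the metadata data.frame (invisibly for the writer).
#' @export
writeCallSet <- function(x, dir, metaFile = file.path(dir, "meta.csv")) {
  stopifnot(is(x, "CallSet"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  md <- x@callData
  md$wav_path <- file.path(dir, paste0(md$call_id, ".wav"))
  for (i in seq_along(x@calls)) {
    writeWavPcm(x@calls[[i]]@waveform, x@calls[[i]]@sampleRate,
                md$wav_path[i])
  }
  out <- md[, c("call_id", "wav_path", "pig_id", "team_id", "age_days",
                "age_class", "context", "valence")]
  write.csv(out, metaFile, row.names = FALSE)
  invisible(out)
}

#' @rdname writeCallSet
#' @export
readCallSet <- function(metaFile) {
  md <- read.csv(metaFile, stringsAsFactors = FALSE)
  calls <- lapply(seq_len(nrow(md)), function(i) {
    w <- readWavPcm(md$wav_path[i])
    new("CallRecording",
        callId = as.character(md$call_id[i]),
        waveform = w$samples, sampleRate = w$sampleRate,
        pigId = as.character(md$pig_id[i]),
        teamId = as.character(md$team_id[i]),
        ageDays = md$age_days[i], ageClass = as.integer(md$age_class[i]),
        context = md$context[i], valence = md$valence[i])
  })
  md2 <- md[, setdiff(names(md), "wav_path")]
  new("CallSet", calls = calls, callData = md2)
}
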