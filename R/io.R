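#' Speech segment container
#'
#' A sampled audio segment with its rate and cohort label.
#'
#' @param samples Numeric vector of amplitudes in `[-1, 1]`.
#' @param fs Sampling rate in Hz.
#' @param label Class tag: one of `"normative"`, `"pathological"`,
#'   `"unknown"`.
#' @param subject_id Opaque subject identifier.
#' @return Object of class `speech_segment`.
#' @export
speech_segment <- function(samples, fs,
                           label = c("unknown", "normative", "pathological"),
                           subject_id = "") {
  label <- match.arg(label)
  assert_scalar_pos(fs, "fs")
  if (!is.numeric(samples) || length(samples) == 0L) {
    stop_input("`samples` must be a non-empty numeric vector")
  }
  if (!all(is.finite(samples))) stop_input("`samples` must be finite")
  structure(list(samples = as.numeric(samples), fs = fs, label = label,
                 subject_id = subject_id),
            class = "speech_segment")
}

#' @export
print.speech_segment <- function(x, ...) {
  cat(sprintf("speech_segment: %d samples @ %g Hz (%.3f s), label = %s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs, x$label))
  invisible(x)
}

# --- minimal RIFF/WAVE reader and writer -------------------------------
# PCM 16-bit and IEEE float 32-bit, mono preferred; multichannel keeps
# channel 1 with a warning. No R package in the dependency set reads WAV,
# so the chunk walk is done directly with readBin.

#' Read a WAV file
#'
#' Reads a mono (or first-channel) PCM 16-bit or IEEE-float WAV file and
#' returns the samples scaled to `[-1, 1]` at the file's native rate.
#'
#' @param path Path to a `.wav` file.
#' @param label,subject_id Passed through to [speech_segment()].
#' @return A [speech_segment()].
#' @export
read_wav <- function(path, label = "unknown", subject_id = basename(path)) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  if (file.size(path) < 44) stop_input("not a valid WAV file (too short): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop_input("not a RIFF/WAVE file: ", path)
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      buf <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(buf[1:2], "integer", 1, 2, signed = FALSE,
                               endian = "little"),
        n_channels = readBin(buf[3:4], "integer", 1, 2, signed = FALSE,
                             endian = "little"),
        fs = readBin(buf[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(buf[15:16], "integer", 1, 2, signed = FALSE,
                       endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))  # chunks are word-aligned
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw) || length(data_raw) == 0L) {
    stop_input("WAV file has no audio data: ", path)
  }
  x <- switch(
    as.character(fmt$audio_format),
    "1" = {
      if (fmt$bits != 16L) stop_input("only 16-bit PCM WAV supported")
      readBin(data_raw, "integer", length(data_raw) / 2, 2,
              signed = TRUE, endian = "little") / 32768
    },
    "3" = {
      if (fmt$bits != 32L) stop_input("only 32-bit float WAV supported")
      readBin(data_raw, "double", length(data_raw) / 4, 4, endian = "little")
    },
    stop_input("unsupported WAV encoding (format tag ", fmt$audio_format, ")")
  )
  if (fmt$n_channels > 1L) {
    warning("multichannel WAV: keeping channel 1 of ", fmt$n_channels)
    x <- x[seq(1, length(x), by = fmt$n_channels)]
  }
  if (length(x) == 0L) stop_input("WAV file has zero samples: ", path)
  speech_segment(x, fmt$fs, label = label, subject_id = subject_id)
}

#' Write a WAV file
#'
#' Writes a [speech_segment()] as mono PCM 16-bit or IEEE-float 32-bit WAV.
#'
#' @param seg A [speech_segment()].
#' @param path Output path.
#' @param bits 16 (PCM) or 32 (float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(seg, path, bits = 16) {
  stopifnot(inherits(seg, "speech_segment"), bits %in% c(16, 32))
  x <- pmax(pmin(seg$samples, 1), -1)
  n <- length(x)
  bytes_per <- bits / 8
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(as.integer(if (bits == 16) 1 else 3), con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")                     # mono
  writeBin(as.integer(round(seg$fs)), con, 4, endian = "little")
  writeBin(as.integer(round(seg$fs) * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bits == 16) {
    writeBin(as.integer(pmax(pmin(round(x * 32768), 32767), -32768)),
             con, 2, endian = "little")
  } else {
    writeBin(as.numeric(x), con, 4, endian = "little")
  }
  invisible(path)
}

#' Preprocess a vowel segment
#'
#' Resamples to the working rate (8 kHz by default), extracts the
#' energy-maximal analysis window (500 ms by default; onset transients are
#' avoided by not taking the literal segment start), and compensates lip
#' radiation with a fixed first-order de-emphasis
#' \eqn{y[n] = x[n] - \alpha x[n-1]}.
#'
#' @param seg A [speech_segment()].
#' @param cfg An [akv_config()].
#' @return A preprocessed [speech_segment()] at `cfg$target_fs`.
#' @export
preprocess <- function(seg, cfg = akv_config()) {
  stopifnot(inherits(seg, "speech_segment"))
  x <- seg$samples
  fs <- seg$fs
  if (fs != cfg$target_fs) {
    frac <- ratio_approx(cfg$target_fs / fs)
    x <- as.numeric(signal::resample(x, frac[1], frac[2]))
    fs <- cfg$target_fs
  }
  n_frame <- round(cfg$win_ms / 1000 * fs)
  if (length(x) < 4 * n_frame) {
    stop_input("signal too short for analysis (< 4 frames)")
  }
  n_seg <- round(cfg$segment_ms / 1000 * fs)
  if (length(x) > n_seg) {
    # energy-maximal window via cumulative sum of squared samples
    cs <- cumsum(c(0, x^2))
    e <- cs[(n_seg + 1):length(cs)] - cs[1:(length(cs) - n_seg)]
    start <- which.max(e)
    x <- x[start:(start + n_seg - 1)]
  } else if (length(x) < n_seg) {
    warning(sprintf("segment shorter than %g ms: using full %.0f ms signal",
                    cfg$segment_ms, 1000 * length(x) / fs))
  }
  x <- x - cfg$deemph_alpha * c(0, x[-length(x)])
  peak <- max(abs(x))
  if (peak > 0) x <- x / peak
  speech_segment(x, fs, label = seg$label, subject_id = seg$subject_id)
}

# Rational approximation of a resampling ratio (continued fractions).
ratio_approx <- function(r, max_den = 10000) {
  pq <- c(1, 0)
  pq_prev <- c(0, 1)
  x <- r
  repeat {
    a <- floor(x)
    pq_new <- a * pq + pq_prev
    if (pq_new[2] > max_den) break
    pq_prev <- pq
    pq <- pq_new
    frac <- x - a
    if (frac < 1e-12 || abs(pq[1] / pq[2] - r) < 1e-12) break
    x <- 1 / frac
  }
  as.integer(pq)
}

#' Write / read a feature matrix
#'
#' Serialises a subject-by-bin feature matrix with class labels to CSV:
#' header row of bin identifiers, one row per subject, label column last.
#' The round trip is lossless to full double precision.
#'
#' @param features Numeric matrix, rows = subjects, columns = bins.
#' @param labels Character vector (`"normative"` / `"pathological"`), one
#'   per row.
#' @param path CSV file path.
#' @return `write_features`: `path` invisibly. `read_features`: a list
#'   with elements `features` and `labels`.
#' @export
write_features <- function(features, labels, path) {
  features <- as.matrix(features)
  if (nrow(features) == 0L || ncol(features) == 0L) {
    stop_input("empty feature matrix")
  }
  if (nrow(features) != length(labels)) {
    stop_input("number of rows must match number of labels")
  }
  df <- as.data.frame(features)
  names(df) <- sprintf("bin%03d", seq_len(ncol(features)))
  df$label <- as.character(labels)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"label" %in% names(df)) stop_input("feature file lacks a label column")
  labels <- as.character(df$label)
  mat <- as.matrix(df[setdiff(names(df), "label")])
  if (any(!is.finite(mat))) stop_input("non-numeric feature values in ", path)
  list(features = unname(mat), labels = labels)
}

#' Write / read a JSON report
#'
#' Detection and Monte Carlo reports are serialised as JSON with full
#' numeric precision.
#'
#' @param report A list-like report object.
#' @param path JSON file path.
#' @return `write_report`: `path` invisibly. `read_report`: the list.
#' @export
write_report <- function(report, path) {
  cls <- class(report)
  out <- list(class = cls[1], payload = unclass(report))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  payload <- obj$payload
  if (!is.null(obj$class)) class(payload) <- c(obj$class, "list")
  payload
}
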