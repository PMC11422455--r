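#' Read one channel of an EDF/EDF+ file
#'
#' Minimal reader for the European Data Format: fixed 256-byte header,
#' per-signal header fields, then data records of 16-bit little-endian
#' integers scaled between the declared digital and physical ranges.
#' Physical units are converted to microvolts (`mV` and `V` are rescaled;
#' an unrecognised dimension triggers a warning and is assumed to be µV).
#'
#' @param path EDF/EDF+ file.
#' @param channel Pattern matched case-insensitively (fixed substring) against
#'   channel labels; exactly one data channel must match.
#' @return An [emg_signal()] carrying the channel's native sampling rate.
#' @export
read_edf <- function(path, channel = "chin") {
  hdr <- .read_edf_header(path)
  is_ann <- grepl("^EDF Annotations$", hdr$label)
  hit <- which(grepl(channel, hdr$label, ignore.case = TRUE, fixed = FALSE) & !is_ann)
  if (length(hit) == 0L) {
    stop(sprintf(
      "no channel matching '%s'; available: %s",
      channel, paste(hdr$label[!is_ann], collapse = ", ")
    ))
  }
  if (length(hit) > 1L) {
    stop(sprintf(
      "pattern '%s' is ambiguous; matches: %s",
      channel, paste(hdr$label[hit], collapse = ", ")
    ))
  }
  raw_sig <- .read_edf_signal(path, hdr, hit)
  scale <- (hdr$phys_max[hit] - hdr$phys_min[hit]) /
    (hdr$dig_max[hit] - hdr$dig_min[hit])
  phys <- hdr$phys_min[hit] + scale * (raw_sig - hdr$dig_min[hit])
  unit <- trimws(hdr$phys_dim[hit])
  mult <- switch(tolower(unit), "uv" = 1, "µv" = 1, "mv" = 1e3, "v" = 1e6, NA_real_)
  if (is.na(mult)) {
    warning(sprintf("unknown physical dimension '%s'; assuming microvolts", unit))
    mult <- 1
  }
  rate <- hdr$samples_per_record[hit] / hdr$record_duration
  emg_signal(phys * mult, rate = rate, label = trimws(hdr$label[hit]))
}

#' List channels of an EDF file
#' @param path EDF/EDF+ file.
#' @return A tibble with `label`, `rate`, `phys_dim` per data channel.
#' @export
edf_channels <- function(path) {
  hdr <- .read_edf_header(path)
  keep <- !grepl("^EDF Annotations$", hdr$label)
  tibble::tibble(
    label = trimws(hdr$label[keep]),
    rate = hdr$samples_per_record[keep] / hdr$record_duration,
    phys_dim = trimws(hdr$phys_dim[keep])
  )
}

#' Write signals to an EDF file
#'
#' Encodes signals as 16-bit EDF with one-second data records (sampling rates
#' must therefore be integer Hz). The physical range is the symmetric range
#' covering the data, so the quantization step of a round trip is
#' `(phys_max - phys_min) / (dig_max - dig_min)`.
#'
#' @param signals An [emg_signal()] or list of them (equal durations).
#' @param path Output file.
#' @param phys_range Optional symmetric physical half-range in µV; default is
#'   the max absolute sample value (at least 1 µV).
#' @return `path`, invisibly.
#' @export
write_edf <- function(signals, path, phys_range = NULL) {
  if (inherits(signals, "emg_signal")) signals <- list(signals)
  stopifnot(length(signals) >= 1L, all(vapply(signals, inherits, TRUE, "emg_signal")))
  rates <- vapply(signals, function(s) s$rate, 1)
  if (any(abs(rates - round(rates)) > 1e-9)) {
    stop("EDF writing with 1-s records requires integer sampling rates")
  }
  dur <- vapply(signals, duration, 1)
  n_rec <- as.integer(ceiling(max(dur)))
  ns <- length(signals)
  label <- vapply(signals, function(s) s$label, "")
  # integer half-range so the header's 8-char numeric fields are exact
  pr <- vapply(signals, function(s) {
    ceiling(if (is.null(phys_range)) max(1, max(abs(s$samples))) else phys_range)
  }, 1)
  dig_min <- -32768L; dig_max <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  .edf_write_header(con,
    n_rec = n_rec, rec_dur = 1, label = label,
    phys_dim = rep("uV", ns), phys_min = -pr, phys_max = pr,
    dig_min = rep(dig_min, ns), dig_max = rep(dig_max, ns),
    spr = as.integer(round(rates)), reserved_global = ""
  )
  scale <- (2 * pr) / (dig_max - dig_min)
  for (rec in seq_len(n_rec) - 1L) {
    for (j in seq_len(ns)) {
      spr <- as.integer(round(rates[j]))
      idx <- rec * spr + seq_len(spr)
      x <- signals[[j]]$samples[idx]
      x[is.na(x)] <- 0
      dig <- as.integer(round((x - (-pr[j])) / scale[j]) + dig_min)
      dig <- pmin(pmax(dig, dig_min), dig_max)
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read the annotations channel of an EDF+ file
#'
#' Parses the time-stamped annotation lists (TAL) of the `EDF Annotations`
#' signal: each annotation is `+onset[\\x15duration]\\x14text\\x14`.
#'
#' @param path EDF+ file.
#' @return A tibble with `onset` (s), `duration` (s, `NA` if absent), `text`.
#' @export
read_edf_annotations <- function(path) {
  hdr <- .read_edf_header(path)
  ai <- which(grepl("^EDF Annotations$", hdr$label))
  if (length(ai) == 0L) stop("file has no 'EDF Annotations' channel")
  out <- list()
  for (j in ai) {
    bytes <- .read_edf_signal(path, hdr, j, raw_bytes = TRUE)
    txt <- rawToChar(bytes[bytes != as.raw(0)])
    tals <- strsplit(txt, "\x14\\s*(?=[+-])", perl = TRUE)[[1]]
    for (tal in tals) {
      fields <- strsplit(tal, "\x14")[[1]]
      head_f <- strsplit(fields[1], "\x15")[[1]]
      onset <- suppressWarnings(as.numeric(head_f[1]))
      dur <- if (length(head_f) > 1L) suppressWarnings(as.numeric(head_f[2])) else NA_real_
      texts <- fields[-1]
      texts <- texts[nzchar(trimws(texts))]
      for (tx in texts) {
        out[[length(out) + 1L]] <- tibble::tibble(
          onset = onset, duration = dur, text = trimws(tx)
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(onset = numeric(), duration = numeric(), text = character()))
  }
  res <- dplyr::bind_rows(out)
  res[order(res$onset), , drop = FALSE]
}

#' Write an annotations-only EDF+ file
#'
#' Emits a valid EDF+C file whose single signal is an `EDF Annotations`
#' channel; used to exchange hypnograms as EDF+ stage annotations.
#'
#' @param onset Numeric onsets in seconds.
#' @param duration Numeric durations in seconds (`NA` omits the field).
#' @param text Annotation texts (e.g. stage tokens).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_edf_annotations <- function(onset, duration, text, path) {
  stopifnot(length(onset) == length(text))
  if (length(duration) == 1L) duration <- rep(duration, length(onset))
  n <- length(onset)
  rec_dur <- 30
  n_rec <- max(1L, as.integer(ceiling((max(onset) + 1) / rec_dur)))
  # bucket annotations into records by onset
  recs <- character(n_rec)
  for (r in seq_len(n_rec)) {
    t0 <- (r - 1L) * rec_dur
    recs[r] <- sprintf("+%g\x14\x14", t0) # record timestamp TAL
    sel <- which(onset >= t0 & onset < t0 + rec_dur)
    for (i in sel) {
      dtxt <- if (is.na(duration[i])) "" else sprintf("\x15%g", duration[i])
      recs[r] <- paste0(recs[r], sprintf("+%g%s\x14%s\x14", onset[i], dtxt, text[i]))
    }
  }
  spr_bytes <- max(nchar(recs, type = "bytes")) + 2L
  if (spr_bytes %% 2L == 1L) spr_bytes <- spr_bytes + 1L
  spr <- spr_bytes %/% 2L

  con <- file(path, "wb")
  on.exit(close(con))
  .edf_write_header(con,
    n_rec = n_rec, rec_dur = rec_dur, label = "EDF Annotations",
    phys_dim = "", phys_min = -1, phys_max = 1,
    dig_min = -32768L, dig_max = 32767L, spr = spr,
    reserved_global = "EDF+C"
  )
  for (r in seq_len(n_rec)) {
    b <- charToRaw(recs[r])
    writeBin(c(b, raw(spr_bytes - length(b))), con)
  }
  invisible(path)
}

# ---- low-level header plumbing ----------------------------------------------

.edf_pad <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

.edf_num <- function(x, width) {
  .edf_pad(trimws(formatC(x, format = "g", digits = 7)), width)
}

.edf_write_header <- function(con, n_rec, rec_dur, label, phys_dim, phys_min,
                              phys_max, dig_min, dig_max, spr, reserved_global) {
  ns <- length(label)
  hdr_bytes <- 256L + 256L * ns
  writeChar(paste0(
    .edf_pad("0", 8),
    .edf_pad("X X X X", 80),
    .edf_pad("Startdate 01-JAN-2000 X X X", 80),
    "01.01.00", "00.00.00",
    .edf_num(hdr_bytes, 8),
    .edf_pad(reserved_global, 44),
    .edf_num(n_rec, 8),
    .edf_num(rec_dur, 8),
    .edf_num(ns, 4)
  ), con, eos = NULL)
  blank <- function(width) .edf_pad(rep("", ns), width)
  fields <- list(
    .edf_pad(label, 16), blank(80), .edf_pad(phys_dim, 8),
    .edf_num(phys_min, 8), .edf_num(phys_max, 8),
    .edf_num(dig_min, 8), .edf_num(dig_max, 8),
    blank(80), .edf_num(spr, 8), blank(32)
  )
  for (f in fields) writeChar(paste(f, collapse = ""), con, eos = NULL)
  invisible(NULL)
}

.read_edf_header <- function(path) {
  if (!file.exists(path)) stop(sprintf("EDF file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  fixed <- readChar(con, 256L, useBytes = TRUE)
  if (nchar(fixed, type = "bytes") < 256L) stop("not a valid EDF file (short header)")
  gf <- function(from, len) substr(fixed, from, from + len - 1L)
  n_rec <- as.integer(trimws(gf(237, 8)))
  rec_dur <- as.numeric(trimws(gf(245, 8)))
  ns <- as.integer(trimws(gf(253, 4)))
  if (is.na(ns) || ns < 1L) stop("not a valid EDF file (bad signal count)")
  per <- readChar(con, 256L * ns, useBytes = TRUE)
  # headers are ASCII by the format; latin1 marking keeps substr byte-exact
  # even on malformed files
  Encoding(per) <- "latin1"
  gs <- function(offset, width) {
    vapply(seq_len(ns), function(j) {
      substr(per, offset + (j - 1L) * width + 1L, offset + j * width)
    }, "")
  }
  off <- cumsum(c(0L, 16L, 80L, 8L, 8L, 8L, 8L, 8L, 80L, 8L)) * ns
  list(
    n_records = n_rec,
    record_duration = rec_dur,
    ns = ns,
    label = trimws(gs(off[1], 16L)),
    phys_dim = gs(off[3], 8L),
    phys_min = as.numeric(trimws(gs(off[4], 8L))),
    phys_max = as.numeric(trimws(gs(off[5], 8L))),
    dig_min = as.numeric(trimws(gs(off[6], 8L))),
    dig_max = as.numeric(trimws(gs(off[7], 8L))),
    samples_per_record = as.integer(trimws(gs(off[9], 8L))),
    header_bytes = 256L + 256L * ns
  )
}

# Pull one signal's samples across all records. raw_bytes = TRUE returns the
# undecoded byte stream (for annotation channels).
.read_edf_signal <- function(path, hdr, j, raw_bytes = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, hdr$header_bytes)
  spr <- hdr$samples_per_record
  rec_samples <- sum(spr)
  n_rec <- hdr$n_records
  if (is.na(n_rec) || n_rec < 0L) {
    # -1 records: infer from file size
    data_bytes <- file.size(path) - hdr$header_bytes
    n_rec <- as.integer(data_bytes %/% (2L * rec_samples))
  }
  before <- if (j > 1L) sum(spr[seq_len(j - 1L)]) else 0L
  out <- vector(if (raw_bytes) "list" else "list", n_rec)
  for (r in seq_len(n_rec)) {
    seek(con, hdr$header_bytes + 2L * ((r - 1L) * rec_samples + before))
    if (raw_bytes) {
      out[[r]] <- readBin(con, "raw", n = 2L * spr[j])
    } else {
      out[[r]] <- readBin(con, "integer", n = spr[j], size = 2L,
                          signed = TRUE, endian = "little")
    }
  }
  if (raw_bytes) do.call(c, out) else as.numeric(do.call(c, out))
}
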