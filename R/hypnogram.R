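#' Sleep stages understood by the package
#'
#' Stages are stored R&K-style (`S1`, `S2`, `S3`) to match per-stage summary
#' tables; AASM tokens (`N1`, `N2`, `N3`, `R`) are accepted on input.
#' @format Character vector of the five stage codes.
#' @export
STAGE_CODES <- c("W", "REM", "S1", "S2", "S3")

# token -> canonical stage code (case-insensitive lookup, names uppercased)
.stage_synonyms <- c(
  "W" = "W", "WAKE" = "W", "0" = "W",
  "REM" = "REM", "R" = "REM", "5" = "REM",
  "S1" = "S1", "N1" = "S1", "1" = "S1", "NREM1" = "S1", "STAGE1" = "S1",
  "S2" = "S2", "N2" = "S2", "2" = "S2", "NREM2" = "S2", "STAGE2" = "S2",
  "S3" = "S3", "N3" = "S3", "3" = "S3", "4" = "S3", "S4" = "S3",
  "NREM3" = "S3", "SWS" = "S3", "STAGE3" = "S3"
)

.map_stage_token <- function(token) {
  key <- toupper(trimws(token))
  out <- unname(.stage_synonyms[key])
  out
}

#' Construct a hypnogram
#'
#' A hypnogram is the per-epoch sleep-stage sequence of one night, starting at
#' recording time 0. Epoch `k` (1-based) covers the half-open interval
#' `[(k-1) * epoch_len, k * epoch_len)` seconds.
#'
#' @param stages Character vector of stage codes; AASM synonyms (`N1`..`N3`,
#'   `R`) are mapped to the stored vocabulary `W, REM, S1, S2, S3`.
#' @param epoch_len Seconds per epoch (default 30, the AASM staging epoch).
#' @return An object of class `hypnogram`.
#' @examples
#' hyp <- hypnogram(c("W", "N2", "R", "R"))
#' stage_intervals(hyp)
#' @export
hypnogram <- function(stages, epoch_len = 30) {
  if (length(stages) < 1L) stop("`stages` must contain at least one epoch")
  if (!is.numeric(epoch_len) || length(epoch_len) != 1L || epoch_len <= 0) {
    stop("`epoch_len` must be a single positive number of seconds")
  }
  mapped <- .map_stage_token(as.character(stages))
  bad <- which(is.na(mapped))
  if (length(bad) > 0L) {
    stop(sprintf(
      "unknown stage token(s): %s (epoch %s)",
      paste(unique(stages[bad]), collapse = ", "),
      paste(utils::head(bad, 5L), collapse = ", ")
    ))
  }
  structure(
    list(stages = mapped, epoch_len = as.numeric(epoch_len)),
    class = "hypnogram"
  )
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$stages, levels = STAGE_CODES))
  cat(sprintf(
    "<hypnogram> %d x %g-s epochs (%.1f min): %s\n",
    length(x$stages), x$epoch_len, length(x$stages) * x$epoch_len / 60,
    paste(sprintf("%s=%d", names(tab), tab), collapse = " ")
  ))
  invisible(x)
}

#' @export
length.hypnogram <- function(x) length(x$stages)

#' Contiguous stage intervals of a hypnogram
#'
#' Collapses the epoch sequence into maximal runs of one stage.
#'
#' @param hyp A [hypnogram()].
#' @param stage Optional stage code (or `"NREM"` for the union of S1--S3) to
#'   restrict to.
#' @return A tibble with columns `stage`, `start`, `end` (seconds, half-open
#'   intervals).
#' @export
stage_intervals <- function(hyp, stage = NULL) {
  stopifnot(inherits(hyp, "hypnogram"))
  r <- rle(hyp$stages)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  out <- tibble::tibble(
    stage = r$values,
    start = starts * hyp$epoch_len,
    end = ends * hyp$epoch_len
  )
  if (!is.null(stage)) {
    keep_codes <- if (identical(stage, "NREM")) c("S1", "S2", "S3") else stage
    out <- out[out$stage %in% keep_codes, , drop = FALSE]
  }
  out
}

#' Total time in a stage
#' @param hyp A [hypnogram()].
#' @param stage A stage code, or `"NREM"` for S1+S2+S3.
#' @return Seconds spent in the stage.
#' @export
stage_seconds <- function(hyp, stage) {
  codes <- if (identical(stage, "NREM")) c("S1", "S2", "S3") else stage
  sum(hyp$stages %in% codes) * hyp$epoch_len
}

#' Read a hypnogram from file
#'
#' Three dialects are supported:
#' \describe{
#'   \item{`csv`}{two columns `onset_seconds,stage` (header optional); rows
#'     must advance in 30-s steps from 0.}
#'   \item{`txt`}{one stage token per line, one 30-s epoch per line.}
#'   \item{`edf_annotations`}{an EDF+ file whose `EDF Annotations` channel
#'     carries one stage annotation per 30-s epoch (text mappable to the
#'     stage vocabulary).}
#' }
#'
#' @param path File to read.
#' @param dialect One of `"csv"`, `"txt"`, `"edf_annotations"`; `"auto"`
#'   guesses from the file extension (`.edf` / comma present / otherwise txt).
#' @param epoch_len Seconds per epoch (default 30).
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path, dialect = c("auto", "csv", "txt", "edf_annotations"),
                           epoch_len = 30) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("hypnogram file not found: %s", path))
  if (dialect == "auto") {
    dialect <- if (grepl("\\.edf$", path, ignore.case = TRUE)) {
      "edf_annotations"
    } else {
      first <- readLines(path, n = 1L, warn = FALSE)
      if (length(first) && grepl(",", first)) "csv" else "txt"
    }
  }
  if (dialect == "edf_annotations") {
    ann <- read_edf_annotations(path)
    stg <- ann[!is.na(.map_stage_token(ann$text)), , drop = FALSE]
    if (nrow(stg) == 0L) stop("no stage annotations found in EDF+ file")
    stg <- stg[order(stg$onset), ]
    return(hypnogram(stg$text, epoch_len = epoch_len))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(sprintf("empty hypnogram file: %s", path))
  if (dialect == "csv") {
    if (grepl("[A-Za-z]", sub(",.*$", "", lines[1]))) lines <- lines[-1] # header
    parts <- strsplit(lines, ",")
    bad <- which(vapply(parts, length, 1L) < 2L)
    if (length(bad)) stop(sprintf("malformed CSV hypnogram at line %d", bad[1]))
    onset <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
    token <- trimws(vapply(parts, `[[`, "", 2L))
    if (anyNA(onset)) stop("non-numeric onset in hypnogram CSV")
    ord <- order(onset)
    onset <- onset[ord]; token <- token[ord]
    step <- diff(onset)
    if (length(step) && any(abs(step - epoch_len) > 1e-6)) {
      stop("hypnogram CSV onsets must advance by one epoch length")
    }
  } else {
    token <- trimws(lines)
  }
  mapped <- .map_stage_token(token)
  if (anyNA(mapped)) {
    bad <- which(is.na(mapped))[1]
    stop(sprintf("unknown stage token '%s' at line %d", token[bad], bad))
  }
  hypnogram(token, epoch_len = epoch_len)
}

#' Write a hypnogram to file
#'
#' @param hyp A [hypnogram()].
#' @param path Output file.
#' @param dialect `"csv"` (`onset_seconds,stage`) or `"txt"` (one token per
#'   line).
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(hyp, path, dialect = c("csv", "txt")) {
  stopifnot(inherits(hyp, "hypnogram"))
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    onset <- (seq_along(hyp$stages) - 1L) * hyp$epoch_len
    writeLines(sprintf("%g,%s", onset, hyp$stages), path)
  } else {
    writeLines(hyp$stages, path)
  }
  invisible(path)
}
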