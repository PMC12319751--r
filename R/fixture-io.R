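FIXTURE_FORMAT_VERSION <- 1L

#' Write a recording + events to the portable fixture container
#'
#' The fixture is a directory holding Arrow Feather tables plus a JSON header,
#' readable from both R (`arrow`) and Python (`pyarrow`):
#' \describe{
#'   \item{`meta.json`}{`format_version`, `sfreq`, `first_sample_time`,
#'     `run_starts`.}
#'   \item{`channels.feather`}{`name`, `kind`, `pair_id`, `pos_x`, `pos_y`.}
#'   \item{`data.feather`}{float64 matrix, one column per channel,
#'     `n_samples` rows.}
#'   \item{`events.feather`}{`onset_sample`, `label`, `task`, `run`, `block`,
#'     `duration_s`.}
#' }
#' The round trip is lossless for data, channel metadata and events.
#'
#' @param recording a [Recording-class]
#' @param events an event table
#' @param path directory to create/overwrite
#' @return `path`, invisibly
#' @export
writeFixture <- function(recording, events, path) {
  validateEventTable(events)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(format_version = FIXTURE_FORMAT_VERSION,
               sfreq = recording@sfreq,
               first_sample_time = recording@firstSampleTime,
               run_starts = recording@runStarts)
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  arrow::write_feather(recording@channels, file.path(path, "channels.feather"))
  dat <- as.data.frame(t(recording@data))
  names(dat) <- recording@channels$name
  arrow::write_feather(dat, file.path(path, "data.feather"))
  arrow::write_feather(events, file.path(path, "events.feather"))
  invisible(path)
}

#' Read a fixture container
#'
#' @param path fixture directory written by [writeFixture()]
#' @return list with elements `recording` ([Recording-class]) and `events`
#' @export
readFixture <- function(path) {
  metaFile <- file.path(path, "meta.json")
  stopIfNot(file.exists(metaFile), "not a fixture container (no meta.json): %s",
            path)
  meta <- jsonlite::read_json(metaFile, simplifyVector = TRUE)
  stopIfNot(identical(as.integer(meta$format_version), FIXTURE_FORMAT_VERSION),
            "fixture format version mismatch: expected %d, found %s",
            FIXTURE_FORMAT_VERSION, as.character(meta$format_version))
  stopIfNot(file.exists(file.path(path, "events.feather")),
            "fixture is missing its events table: %s", path)
  ch <- as.data.frame(arrow::read_feather(file.path(path, "channels.feather")))
  ch$pair_id <- as.integer(ch$pair_id)
  dat <- as.data.frame(arrow::read_feather(file.path(path, "data.feather")))
  ev <- as.data.frame(arrow::read_feather(file.path(path, "events.feather")))
  ev$onset_sample <- as.integer(ev$onset_sample)
  ev$run <- as.integer(ev$run)
  ev$block <- as.integer(ev$block)
  validateEventTable(ev)
  mat <- t(as.matrix(dat))
  dimnames(mat) <- NULL
  rec <- new("Recording", data = mat, channels = ch,
             sfreq = meta$sfreq, firstSampleTime = meta$first_sample_time,
             runStarts = as.integer(meta$run_starts))
  list(recording = rec, events = ev)
}

fifBridge <- function(args) {
  script <- system.file("python", "fif_bridge.py", package = "micica")
  stopIfNot(nzchar(script), "FIF bridge script not found in the installed package")
  python <- Sys.which("python")
  stopIfNot(nzchar(python),
            "FIF support needs a `python` with mne + pyarrow on the PATH")
  out <- suppressWarnings(system2(python, c(shQuote(script), args),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop(sprintf("FIF bridge failed: %s", paste(out, collapse = "\n")),
         call. = FALSE)
  invisible(out)
}

#' Read a Neuromag FIF file
#'
#' Ingests a FIF recording through the MNE bridge: channel kinds are taken
#' from the FIF channel types, stim-channel transitions become event rows, and
#' gradiometer pair ids are derived from the Neuromag sensor-element naming
#' (the two planar gradiometers of an element share all but the last digit).
#' Requires a `python` interpreter with `mne` and `pyarrow` on the PATH.
#'
#' @param path a FIF file
#' @return list with elements `recording` and `events`
#' @export
readFif <- function(path) {
  stopIfNot(file.exists(path), "cannot read FIF file: %s", path)
  tmp <- tempfile("fif_fixture_")
  on.exit(unlink(tmp, recursive = TRUE))
  fifBridge(c("from-fif", shQuote(path), shQuote(tmp)))
  res <- readFixture(tmp)
  stopIfNot(any(res$recording@channels$kind == "grad"),
            "FIF file contains no gradiometer channels")
  res
}

#' Write a recording to a Neuromag FIF file
#'
#' Counterpart of [readFif()] (events are encoded on a stim channel; run and
#' block structure beyond the stim codes is not representable in a single FIF
#' and is dropped). Data are stored in double precision.
#'
#' @param recording a [Recording-class]
#' @param events an event table
#' @param path output `.fif` path
#' @return `path`, invisibly
#' @export
writeFif <- function(recording, events, path) {
  tmp <- tempfile("fif_fixture_")
  on.exit(unlink(tmp, recursive = TRUE))
  writeFixture(recording, events, tmp)
  fifBridge(c("to-fif", shQuote(tmp), shQuote(path)))
  invisible(path)
}
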