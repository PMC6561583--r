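#' Construct a multichannel LFP recording
#'
#' A `lfp_recording` bundles a channels-by-samples LFP matrix with its
#' sampling rate, per-channel depths along the probe shank, a stimulus event
#' table, and a per-channel quality mask. Time is in seconds with t = 0 at
#' the first sample; sample `i` (1-based) covers time `(i - 1) / fs`. All
#' analysis windows are half-open `[a, b)`.
#'
#' @param lfp numeric matrix, channels x samples, in mV.
#' @param fs sampling rate in Hz.
#' @param channel_depths numeric vector of electrode depths in micrometers,
#'   strictly monotone along the shank (one per channel).
#' @param stim_table data.frame with columns `onset_s` (stimulus onset in
#'   seconds) and `velocity_deg_s` (deflection velocity; may be `NA`).
#' @param channel_mask logical vector, `TRUE` for good channels. Defaults to
#'   all good.
#' @param meta free-form named list of provenance information.
#' @return An object of class `lfp_recording`.
#' @export
lfp_recording <- function(lfp, fs, channel_depths, stim_table,
                          channel_mask = NULL, meta = list()) {
  if (!is.matrix(lfp)) stop("`lfp` must be a channels x samples matrix")
  storage.mode(lfp) <- "double"
  n_ch <- nrow(lfp)
  if (length(channel_depths) != n_ch)
    stop("`channel_depths` length (", length(channel_depths),
         ") does not match channel count (", n_ch, ")")
  if (is.null(channel_mask)) channel_mask <- rep(TRUE, n_ch)
  if (length(channel_mask) != n_ch)
    stop("`channel_mask` length does not match channel count")
  if (!is.data.frame(stim_table) || !all(c("onset_s") %in% names(stim_table)))
    stop("`stim_table` must be a data.frame with an `onset_s` column")
  if (is.null(stim_table$velocity_deg_s))
    stim_table$velocity_deg_s <- rep(NA_real_, nrow(stim_table))
  rec <- structure(
    list(lfp = lfp, fs = fs, channel_depths = as.numeric(channel_depths),
         stim_table = stim_table[, c("onset_s", "velocity_deg_s")],
         channel_mask = as.logical(channel_mask), meta = meta),
    class = "lfp_recording")
  validate_recording(rec)
  rec
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$lfp), ncol(x$lfp), x$fs, rec_duration(x)))
  cat(sprintf("  depths: %g..%g um; %d/%d channels good; %d stimuli\n",
              min(x$channel_depths), max(x$channel_depths),
              sum(x$channel_mask), length(x$channel_mask),
              nrow(x$stim_table)))
  invisible(x)
}

rec_duration <- function(rec) ncol(rec$lfp) / rec$fs

#' Validate an `lfp_recording`
#'
#' Checks the container invariants: onsets inside `[0, duration)`, and
#' strictly monotone depths for unmasked channels.
#'
#' @param rec an `lfp_recording`.
#' @return `rec`, invisibly. Errors name the violated field.
#' @export
validate_recording <- function(rec) {
  dur <- rec_duration(rec)
  on <- rec$stim_table$onset_s
  if (length(on) && (any(on < 0) || any(on >= dur)))
    stop("stim_table: stimulus onsets must lie in [0, duration)")
  if (length(on) > 1 && any(diff(on) <= 0))
    stop("stim_table: stimulus onsets must be strictly increasing")
  d <- rec$channel_depths[rec$channel_mask]
  if (length(d) > 1) {
    dd <- diff(d)
    if (!(all(dd > 0) || all(dd < 0)))
      stop("channel_depths: depths of unmasked channels must be strictly monotone")
  }
  invisible(rec)
}

#' Write a recording to disk
#'
#' The container is a JSON sidecar (`<stem>.json`) describing the recording
#' plus a raw little-endian binary (`<stem>.lfp.bin`) holding the LFP matrix
#' in column-major channels-x-samples order, and a CSV stimulus table
#' (`<stem>.stim.csv`). `dtype = "float64"` round-trips losslessly;
#' `"float32"` halves the footprint at reduced precision.
#'
#' @param rec an `lfp_recording`.
#' @param stem path stem; the three container files are derived from it.
#' @param dtype `"float64"` (default) or `"float32"` storage for the LFP.
#' @return `stem`, invisibly.
#' @export
write_recording <- function(rec, stem, dtype = c("float64", "float32")) {
  dtype <- match.arg(dtype)
  validate_recording(rec)
  size <- if (dtype == "float64") 8L else 4L
  con <- file(paste0(stem, ".lfp.bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$lfp), con, size = size, endian = "little")
  utils::write.csv(rec$stim_table, paste0(stem, ".stim.csv"),
                   row.names = FALSE)
  side <- list(
    format = "lfpstate-recording", version = 1L,
    n_channels = nrow(rec$lfp), n_samples = ncol(rec$lfp),
    fs = rec$fs, dtype = dtype, layout = "channels_x_samples_colmajor",
    unit = "mV",
    channel_depths_um = rec$channel_depths,
    channel_mask = rec$channel_mask,
    meta = rec$meta)
  jsonlite::write_json(side, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' Read a recording written by [write_recording()]
#'
#' @param stem path stem used when writing.
#' @return An `lfp_recording`. Missing container files or datasets, shape
#'   mismatches, and non-monotone depths raise named errors.
#' @export
read_recording <- function(stem) {
  side_path <- paste0(stem, ".json")
  bin_path <- paste0(stem, ".lfp.bin")
  stim_path <- paste0(stem, ".stim.csv")
  for (p in c(side_path, bin_path, stim_path))
    if (!file.exists(p)) stop("recording container is missing file: ", p)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  for (f in c("n_channels", "n_samples", "fs", "dtype", "channel_depths_um"))
    if (is.null(side[[f]])) stop("recording sidecar is missing dataset: ", f)
  n_ch <- side$n_channels; n_s <- side$n_samples
  size <- if (identical(side$dtype, "float64")) 8L else 4L
  expect_bytes <- as.numeric(n_ch) * n_s * size
  if (file.info(bin_path)$size != expect_bytes)
    stop("lfp binary shape mismatch: expected ", n_ch, " x ", n_s,
         " (", expect_bytes, " bytes), found ", file.info(bin_path)$size)
  con <- file(bin_path, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = n_ch * n_s, size = size, endian = "little")
  stim <- utils::read.csv(stim_path)
  meta <- side$meta
  if (is.null(meta)) meta <- list()
  lfp_recording(matrix(v, nrow = n_ch, ncol = n_s), fs = as.numeric(side$fs),
                channel_depths = side$channel_depths_um,
                stim_table = stim,
                channel_mask = if (is.null(side$channel_mask)) NULL
                               else side$channel_mask,
                meta = as.list(meta))
}

# Sample index (1-based) of the first sample at or after time t.
time_to_sample <- function(t, fs) as.integer(floor(t * fs + 1e-9)) + 1L

# Indices covering the half-open window [a, b) in seconds.
window_samples <- function(a, b, fs) {
  i0 <- time_to_sample(a, fs)
  n <- as.integer(round((b - a) * fs))
  seq.int(i0, length.out = n)
}
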