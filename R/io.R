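#' Write a recording and its reference vitals to HDF5
#'
#' Layout: datasets `/amplitude` (bins x samples), `/hr`, `/rr`,
#' `/ref_time` (the 3 Hz reference streams), with the radar geometry
#' stored as attributes of `/amplitude`.
#'
#' @param sim A list with `recording` and `vitals`, as returned by
#'   [simulate_recording()].
#' @param path Output `.h5` path (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_recording_h5 <- function(sim, path) {
  stopifnot(inherits(sim$recording, "baseband_recording"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  suppressMessages(rhdf5::h5write(sim$recording$amplitude, path, "amplitude"))
  rhdf5::h5write(sim$vitals$hr, path, "hr")
  rhdf5::h5write(sim$vitals$rr, path, "rr")
  rhdf5::h5write(sim$vitals$time, path, "ref_time")
  fid <- rhdf5::H5Fopen(path)
  did <- rhdf5::H5Dopen(fid, "amplitude")
  g <- sim$recording$geometry
  for (nm in c("n_bins", "bin_length", "range_offset", "zone_start",
               "zone_end", "fs", "carrier_freq", "sensitivity")) {
    rhdf5::h5writeAttribute(g[[nm]], did, nm)
  }
  rhdf5::h5writeAttribute(sim$recording$t0, did, "t0")
  rhdf5::H5Dclose(did)
  rhdf5::H5Fclose(fid)
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a recording written by [write_recording_h5()]
#'
#' @param path Input `.h5` path.
#' @return A list with `recording` and `vitals`, as from
#'   [simulate_recording()].
#' @export
read_recording_h5 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  at <- lapply(rhdf5::h5readAttributes(path, "amplitude"), as.vector)
  need <- c("n_bins", "bin_length", "range_offset", "zone_start",
            "zone_end", "fs", "carrier_freq", "sensitivity")
  missing_at <- setdiff(need, names(at))
  if (length(missing_at) > 0) {
    stop("malformed recording file ", path, ": missing geometry attribute(s) ",
         paste(missing_at, collapse = ", "))
  }
  geometry <- radar_geometry(
    n_bins = at$n_bins, bin_length = at$bin_length,
    range_offset = at$range_offset, zone_start = at$zone_start,
    zone_end = at$zone_end, fs = at$fs, carrier_freq = at$carrier_freq,
    sensitivity = at$sensitivity)
  amp <- rhdf5::h5read(path, "amplitude")
  vitals <- tibble::tibble(
    time = as.numeric(rhdf5::h5read(path, "ref_time")),
    hr = as.numeric(rhdf5::h5read(path, "hr")),
    rr = as.numeric(rhdf5::h5read(path, "rr")))
  rhdf5::h5closeAll()
  list(recording = baseband_recording(amp, geometry, t0 = at$t0 %||% 0),
       vitals = vitals)
}

#' Write a recording as CSV (fallback container)
#'
#' Writes three sibling files: `<prefix>_amplitude.csv` (one column per
#' range bin, one row per time sample), `<prefix>_vitals.csv`
#' (`time, hr, rr`), and `<prefix>_geometry.json`.
#'
#' @param sim A list with `recording` and `vitals`.
#' @param prefix Output path prefix.
#' @return The three paths, invisibly.
#' @export
write_recording_csv <- function(sim, prefix) {
  stopifnot(inherits(sim$recording, "baseband_recording"))
  amp <- t(sim$recording$amplitude)
  colnames(amp) <- paste0("bin", seq_len(ncol(amp)))
  paths <- paste0(prefix, c("_amplitude.csv", "_vitals.csv", "_geometry.json"))
  readr::write_csv(tibble::as_tibble(amp), paths[1])
  readr::write_csv(sim$vitals, paths[2])
  jsonlite::write_json(
    c(unclass(sim$recording$geometry), list(t0 = sim$recording$t0)),
    paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a recording written by [write_recording_csv()]
#'
#' @param prefix Path prefix used at write time.
#' @return A list with `recording` and `vitals`.
#' @export
read_recording_csv <- function(prefix) {
  paths <- paste0(prefix, c("_amplitude.csv", "_vitals.csv", "_geometry.json"))
  for (p in paths) if (!file.exists(p)) stop("no such file: ", p)
  g <- jsonlite::read_json(paths[3], simplifyVector = TRUE)
  geometry <- radar_geometry(
    n_bins = g$n_bins, bin_length = g$bin_length,
    range_offset = g$range_offset, zone_start = g$zone_start,
    zone_end = g$zone_end, fs = g$fs, carrier_freq = g$carrier_freq,
    sensitivity = g$sensitivity)
  amp <- readr::read_csv(paths[1], show_col_types = FALSE,
                         col_types = readr::cols(.default = "d"))
  if (ncol(amp) != geometry$n_bins) {
    stop(sprintf("amplitude CSV has %d bin columns, geometry says %d",
                 ncol(amp), geometry$n_bins))
  }
  vitals <- readr::read_csv(paths[2], show_col_types = FALSE,
                            col_types = readr::cols(.default = "d"))
  missing_cols <- setdiff(c("time", "hr", "rr"), names(vitals))
  if (length(missing_cols) > 0) {
    stop("vitals CSV missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  list(recording = baseband_recording(t(as.matrix(amp)), geometry,
                                      t0 = g$t0 %||% 0),
       vitals = vitals)
}

#' Write / read the epoch table
#'
#' Columns: `epoch_index`, `start_s`, `movement`, `kept`, `hr_label`,
#' `rr_label`. The epoch length is re-derivable from the `start_s` spacing.
#'
#' @param epochs Epoch tibble (after [apply_exclusion()] and
#'   [label_epochs()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_epoch_table <- function(epochs, path) {
  out <- tibble::tibble(
    epoch_index = epochs$epoch,
    start_s = epochs$start_s,
    movement = epochs$movement,
    kept = if ("kept" %in% names(epochs)) epochs$kept else TRUE,
    hr_label = if ("hr_label" %in% names(epochs)) epochs$hr_label else NA_real_,
    rr_label = if ("rr_label" %in% names(epochs)) epochs$rr_label else NA_real_)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_epoch_table
#' @export
read_epoch_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("epoch_index", "start_s", "movement", "kept")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    stop("epoch table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  tab
}

#' Write the fold-by-fold agreement report as CSV
#'
#' Column layout follows the standard fold x (RR block, HR block) table:
#' `fold, rr_mae, rr_corr, rr_bias, rr_loa, hr_mae, hr_corr, hr_bias,
#' hr_loa`.
#'
#' @param report An [evaluate_cv()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  readr::write_csv(report_table(report), path)
  invisible(path)
}

#' Save / load a trained model checkpoint
#'
#' @param model A `vitals_model`.
#' @param path Checkpoint path (`.rds`).
#' @return `path` / the restored model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "vitals_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "vitals_model")) stop("not a vitals_model checkpoint: ", path)
  m
}
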