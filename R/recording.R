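#' Construct an MSNA recording
#'
#' An `msna_recording` bundles the aligned 1 kHz channels of a
#' microneurography session: the integrated MSNA neurogram (volts), the ECG
#' (arbitrary units) and, when available, continuous blood pressure (mmHg),
#' together with subject metadata. All channels share one uniform time grid.
#'
#' @param msna numeric vector, integrated MSNA in volts. Required.
#' @param ecg optional numeric vector, same length as `msna`.
#' @param bp optional numeric vector (mmHg), same length as `msna`.
#' @param sample_rate sampling rate in Hz of the supplied vectors. Inputs not
#'   at 1000 Hz are linearly resampled to 1000 Hz and flagged.
#' @param subject_height_cm optional subject height in cm (used by the
#'   burst-latency model).
#' @param subject_id free-text identifier.
#' @param resampled logical flag, set automatically when resampling occurred.
#' @return an object of class `msna_recording` with elements `time` (s),
#'   `msna`, `ecg`, `bp`, `sample_rate`, `subject_height_cm`, `subject_id`,
#'   `resampled`.
#' @export
msna_recording <- function(msna, ecg = NULL, bp = NULL, sample_rate = 1000,
                           subject_height_cm = NULL, subject_id = "",
                           resampled = FALSE) {
  if (!is.numeric(msna) || length(msna) < 1L)
    stop_arg("'msna' must be a non-empty numeric vector")
  assert_scalar_num(sample_rate, "sample_rate", positive = TRUE)
  for (nm in c("ecg", "bp")) {
    ch <- get(nm)
    if (!is.null(ch) && length(ch) != length(msna))
      stop_arg("channel '%s' has length %d but msna has length %d",
               nm, length(ch), length(msna))
  }
  if (!is.null(subject_height_cm)) {
    assert_scalar_num(subject_height_cm, "subject_height_cm")
    if (subject_height_cm <= 0) stop_arg("'subject_height_cm' must be positive")
  }
  rec <- structure(list(
    time = NULL, msna = as.numeric(msna),
    ecg = if (is.null(ecg)) NULL else as.numeric(ecg),
    bp = if (is.null(bp)) NULL else as.numeric(bp),
    sample_rate = as.numeric(sample_rate),
    subject_height_cm = subject_height_cm,
    subject_id = subject_id, resampled = isTRUE(resampled)
  ), class = "msna_recording")
  if (rec$sample_rate != 1000) rec <- resample_recording(rec, 1000) else {
    rec$time <- (seq_along(rec$msna) - 1) / rec$sample_rate
  }
  rec
}

#' @export
print.msna_recording <- function(x, ...) {
  cat(sprintf("<msna_recording> %s: %.1f s at %g Hz (%d samples)\n",
              if (nzchar(x$subject_id)) x$subject_id else "unnamed",
              length(x$msna) / x$sample_rate, x$sample_rate, length(x$msna)))
  cat(sprintf("  channels: msna%s%s%s\n",
              if (is.null(x$ecg)) "" else ", ecg",
              if (is.null(x$bp)) "" else ", bp",
              if (x$resampled) "  [resampled]" else ""))
  invisible(x)
}

#' @export
length.msna_recording <- function(x) length(x$msna)

# Linear resampling of all channels onto a uniform target grid.
# Resampling a recording already at the target rate is the identity.
resample_recording <- function(rec, target_rate = 1000) {
  if (rec$sample_rate == target_rate) {
    rec$time <- (seq_along(rec$msna) - 1) / rec$sample_rate
    return(rec)
  }
  dur <- (length(rec$msna) - 1) / rec$sample_rate
  old_t <- (seq_along(rec$msna) - 1) / rec$sample_rate
  new_t <- seq(0, dur, by = 1 / target_rate)
  for (nm in c("msna", "ecg", "bp")) {
    if (!is.null(rec[[nm]]))
      rec[[nm]] <- approx(old_t, rec[[nm]], xout = new_t)$y
  }
  rec$time <- new_t
  rec$sample_rate <- target_rate
  rec$resampled <- TRUE
  rec
}

#' Read a delimited-text recording export
#'
#' Laboratory acquisition systems export multi-channel recordings as plain
#' text with one header line and one numeric column per channel. Because
#' column names vary between systems, the mapping from channel role to column
#' name is explicit. Input not sampled at 1000 Hz (judged from the time
#' column, or from `sample_rate`) is linearly resampled to 1000 Hz and the
#' recording flagged as resampled.
#'
#' @param path file path; whitespace- or comma-delimited text with a header.
#' @param column_map named list/character vector mapping roles `time`,
#'   `msna`, `ecg`, `bp` to column names in the file. Only `msna` is
#'   mandatory. Default assumes columns are named after their role.
#' @param sample_rate rate of the file in Hz; if `NULL` it is inferred from
#'   the time column (1000 Hz assumed when no time column is mapped).
#' @param subject_height_cm,subject_id metadata passed to [msna_recording()].
#' @return an [msna_recording()].
#' @export
read_recording <- function(path,
                           column_map = c(time = "time", msna = "msna",
                                          ecg = "ecg", bp = "bp"),
                           sample_rate = NULL,
                           subject_height_cm = NULL, subject_id = NULL) {
  if (!file.exists(path)) stop_arg("file not found: %s", path)
  if (file.size(path) == 0L) stop_arg("empty input file: %s", path)
  column_map <- as.list(column_map)
  if (is.null(column_map$msna)) stop_arg("column_map must map the 'msna' channel")
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (nrow(dt) == 0L) stop_arg("empty input file: %s", path)
  if (!column_map$msna %in% names(dt))
    stop_arg("format error: required MSNA column '%s' not found (columns: %s)",
             column_map$msna, paste(names(dt), collapse = ", "))
  grab <- function(role) {
    col <- column_map[[role]]
    if (is.null(col) || !col %in% names(dt)) return(NULL)
    v <- dt[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      stop_arg("parse error: non-numeric value in column '%s' at data row %d",
               col, if (length(bad)) bad[1] else 1L)
    }
    v
  }
  tm <- grab("time")
  if (is.null(sample_rate)) {
    sample_rate <- if (!is.null(tm) && length(tm) > 1L) {
      1 / median(diff(tm))
    } else 1000
  }
  msna_recording(
    msna = grab("msna"), ecg = grab("ecg"), bp = grab("bp"),
    sample_rate = round(sample_rate, 6),
    subject_height_cm = subject_height_cm,
    subject_id = subject_id %||% sub("\\.[^.]*$", "", basename(path))
  )
}

#' Write a recording as delimited text
#'
#' Writes a tab-separated file (header `time msna ecg bp`, absent channels
#' omitted) readable by [read_recording()] with the default column map.
#'
#' @param recording an [msna_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "msna_recording"))
  cols <- list(time = recording$time, msna = recording$msna)
  if (!is.null(recording$ecg)) cols$ecg <- recording$ecg
  if (!is.null(recording$bp)) cols$bp <- recording$bp
  data.table::fwrite(as.data.frame(cols), path, sep = "\t")
  invisible(path)
}

annotation_columns <- c(
  "peak_index", "peak_time_s", "peak_height_v", "prominence_v", "width_ms",
  "nn1_p_pos", "nn2_p_pos", "nn3_p_pos", "nn1_label", "nn2_label", "nn3_label",
  "timing_likelihood", "quality_median", "quality_likelihood",
  "quality_truncated", "composite"
)

#' Write a per-peak annotation table
#'
#' One CSV row per candidate peak with a fixed column order
#' (`peak_index, peak_time_s, peak_height_v, prominence_v, width_ms,
#' nn1_p_pos, nn2_p_pos, nn3_p_pos, nn1_label, nn2_label, nn3_label,
#' timing_likelihood, quality_median, quality_likelihood, quality_truncated,
#' composite`). Floating-point values are written with 6 decimals, so a
#' round-trip through [read_annotation_table()] reproduces values within
#' 1e-6.
#'
#' @param annotations a data frame of annotations as produced by
#'   [annotate_recording()] (an empty data frame yields a header-only file).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(annotations, path) {
  ann <- as.data.frame(annotations)
  missing_cols <- setdiff(annotation_columns, names(ann))
  for (m in missing_cols) ann[[m]] <- numeric(nrow(ann))
  ann <- ann[, annotation_columns, drop = FALSE]
  num <- vapply(ann, is.double, logical(1))
  ann[num] <- lapply(ann[num], function(v) sprintf("%.6f", v))
  ok <- tryCatch({
    suppressWarnings(utils::write.table(ann, path, sep = ",",
                                        row.names = FALSE, quote = FALSE))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_arg("cannot write annotation table to '%s': %s",
                            path, conditionMessage(ok))
  invisible(path)
}

#' Read back an annotation table written by [write_annotation_table()]
#' @param path CSV path.
#' @return data frame with the documented annotation columns.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop_arg("file not found: %s", path)
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(annotation_columns, names(ann))
  if (length(missing_cols))
    stop_arg("not an annotation table (missing columns: %s)",
             paste(missing_cols, collapse = ", "))
  ann
}
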