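# Reading and writing GaitPDB-format VGRF records and the demographics
# table. This is the single I/O boundary shared by real and synthetic data.
#
# File dialect: plain whitespace-delimited numeric text, one sample per
# line, 19 columns: time [s], L1..L8, R1..R8 (plantar sensors, N),
# TotalL, TotalR (per-foot total force, N). Lines starting with '#' are
# ignored so fixtures can carry provenance headers.

#' Construct a VGRF gait signal
#'
#' @param subject_id Subject identifier (string).
#' @param time_s Strictly increasing time vector in seconds.
#' @param channels Numeric matrix with one row per sample and exactly 18
#'   columns: 8 left sensors, 8 right sensors, left total force, right
#'   total force (Newtons).
#' @param sampling_rate_hz Sampling rate in Hz (100 for GaitPDB data).
#' @return A `gait_signal` object.
#' @export
gait_signal <- function(subject_id, time_s, channels, sampling_rate_hz = 100) {
  channels <- as.matrix(channels)
  assert_that(nrow(channels) >= 1, "gait_signal: record must contain at least one sample")
  assert_that(ncol(channels) == 18L,
              "gait_signal: expected 18 channel columns, got %d", ncol(channels))
  assert_that(length(time_s) == nrow(channels),
              "gait_signal: time vector and channel rows disagree")
  assert_that(all(is.finite(time_s)) && all(is.finite(channels)),
              "gait_signal: non-finite values in record")
  assert_that(length(time_s) < 2 || all(diff(time_s) > 0),
              "gait_signal: time must be strictly increasing")
  assert_that(is.numeric(sampling_rate_hz) && sampling_rate_hz > 0,
              "gait_signal: sampling rate must be positive")
  structure(list(subject_id = as.character(subject_id),
                 sampling_rate_hz = sampling_rate_hz,
                 time_s = as.numeric(time_s),
                 channels = unname(channels)),
            class = "gait_signal")
}

#' @export
print.gait_signal <- function(x, ...) {
  cat(sprintf("<gait_signal> subject=%s  %d samples @ %g Hz (%.1f s), 18 channels\n",
              x$subject_id, nrow(x$channels), x$sampling_rate_hz,
              nrow(x$channels) / x$sampling_rate_hz))
  invisible(x)
}

#' Read a VGRF record in GaitPDB text format
#'
#' Expects whitespace-delimited numeric text with 19 columns (time + 18
#' channels). Comment lines starting with `#` are skipped.
#'
#' @param path File path.
#' @param subject_id Subject identifier to attach to the record.
#' @param sampling_rate Sampling rate in Hz.
#' @return A [gait_signal()].
#' @export
read_vgrf_file <- function(path, subject_id, sampling_rate = 100) {
  assert_that(file.exists(path), "read_vgrf_file: no such file: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  assert_that(length(lines) >= 1, "read_vgrf_file: %s contains no data lines", path)
  toks <- strsplit(trimws(lines), "\\s+")
  nfield <- lengths(toks)
  bad <- which(nfield != 19L)
  if (length(bad) > 0) {
    stop_gaitxai("read_vgrf_file: %s line %d has %d columns, expected 19 (time + 18 channels)",
                 path, bad[1], nfield[bad[1]], class = "gaitxai_format_error")
  }
  vals <- suppressWarnings(as.numeric(unlist(toks)))
  if (anyNA(vals)) {
    bad_line <- ceiling(which(is.na(vals))[1] / 19)
    stop_gaitxai("read_vgrf_file: non-numeric token on data line %d of %s",
                 bad_line, path, class = "gaitxai_parse_error")
  }
  m <- matrix(vals, ncol = 19L, byrow = TRUE)
  gait_signal(subject_id, time_s = m[, 1], channels = m[, -1, drop = FALSE],
              sampling_rate_hz = sampling_rate)
}

#' Write a VGRF record in GaitPDB text format
#'
#' Values are written with 6 significant digits (below sensor noise).
#'
#' @param signal A [gait_signal()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_vgrf_file <- function(signal, path) {
  assert_that(inherits(signal, "gait_signal"), "write_vgrf_file: not a gait_signal")
  m <- cbind(signal$time_s, signal$channels)
  txt <- apply(format(m, digits = 6, scientific = FALSE, trim = TRUE), 1L, paste, collapse = " ")
  ok <- tryCatch({ writeLines(txt, path); TRUE }, error = function(e) FALSE)
  assert_that(ok, "write_vgrf_file: cannot write %s", path)
  invisible(path)
}

#' Construct/validate a demographics table
#'
#' @param df Data frame with columns `subject_id`, `group` (`"CO"` or
#'   `"PD"`), `hy_stage` (0 for controls, > 0 for patients) and optionally
#'   `updrs`, `tug_s`, `speed_m_s`.
#' @return The validated data frame with class `subject_table`.
#' @export
subject_table <- function(df) {
  req <- c("subject_id", "group", "hy_stage")
  missing_cols <- setdiff(req, names(df))
  assert_that(length(missing_cols) == 0,
              "subject_table: missing required columns: %s", paste(missing_cols, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  df$hy_stage <- as.numeric(df$hy_stage)
  dup <- df$subject_id[duplicated(df$subject_id)]
  assert_that(length(dup) == 0, "subject_table: duplicate subject_id: %s",
              paste(unique(dup), collapse = ", "))
  assert_that(all(df$group %in% c("CO", "PD")),
              "subject_table: group must be CO or PD")
  assert_that(all(is.finite(df$hy_stage)) && all(df$hy_stage >= 0),
              "subject_table: hy_stage must be a number >= 0")
  bad_co <- df$group == "CO" & df$hy_stage > 0
  assert_that(!any(bad_co), "subject_table: control subjects must have hy_stage 0 (%s)",
              paste(df$subject_id[bad_co], collapse = ", "))
  bad_pd <- df$group == "PD" & df$hy_stage <= 0
  assert_that(!any(bad_pd), "subject_table: PD subjects must have hy_stage > 0 (%s)",
              paste(df$subject_id[bad_pd], collapse = ", "))
  class(df) <- c("subject_table", "data.frame")
  df
}

#' Read the demographics CSV
#'
#' @param path CSV file with header; required columns `subject_id`,
#'   `group`, `hy_stage`.
#' @return A validated [subject_table()].
#' @export
read_demographics <- function(path) {
  assert_that(file.exists(path), "read_demographics: no such file: %s", path)
  subject_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write the demographics CSV
#'
#' @param table A [subject_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_demographics <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
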