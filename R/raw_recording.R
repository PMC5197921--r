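#' Construct a raw tri-axial recording
#'
#' Container for one device's raw accelerometer stream: irregular sample
#' times in seconds since `start_time` and x/y/z acceleration in units of
#' g (1 g = 9.81 m/s\eqn{^2}).
#'
#' @param participant_id,device_id character identifiers.
#' @param start_time `POSIXct` (UTC) instant of `t = 0`.
#' @param t numeric vector of sample times in seconds, strictly increasing.
#' @param xyz numeric matrix with `length(t)` rows and 3 columns (g).
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(participant_id, device_id, start_time, t, xyz) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L || nrow(xyz) != length(t))
    stopf("'xyz' must be a length(t) x 3 matrix")
  if (length(t) < 2L) stopf("a recording needs at least 2 samples")
  if (is.unsorted(t, strictly = TRUE))
    stopf("sample times must be strictly increasing")
  if (anyNA(xyz) || any(!is.finite(xyz)))
    stopf("acceleration values must be finite")
  structure(
    list(participant_id = as.character(participant_id),
         device_id = as.character(device_id),
         start_time = as.POSIXct(start_time, tz = "UTC"),
         t = as.numeric(t),
         xyz = unname(xyz)),
    class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  dur <- diff(range(x$t))
  cat(sprintf("<raw_recording> participant %s, device %s\n",
              x$participant_id, x$device_id))
  cat(sprintf("  start %s UTC, %.2f h, %d samples (~%.1f Hz)\n",
              format(x$start_time, "%Y-%m-%d %H:%M:%S"), dur / 3600,
              length(x$t), (length(x$t) - 1) / dur))
  invisible(x)
}

#' Duration of a raw recording in seconds
#' @param rec a `raw_recording`.
#' @return numeric seconds between first and last sample.
#' @export
recording_duration <- function(rec) diff(range(rec$t))

#' Write / read a raw recording as delimited text
#'
#' Plain-text interchange format: `#key=value` header lines
#' (`participant_id`, `device_id`, `start_time` in ISO 8601,
#' `schema_version`) followed by a tab-separated table with columns
#' `time` (seconds since start), `x`, `y`, `z` (g).
#'
#' @param rec a `raw_recording`.
#' @param path file path.
#' @return `write_raw_recording()` returns `path` invisibly;
#'   `read_raw_recording()` returns a `raw_recording`.
#' @export
write_raw_recording <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- sprintf("#%s=%s", c("schema_version", "participant_id", "device_id",
                             "start_time"),
                 c("1", rec$participant_id, rec$device_id,
                   format(rec$start_time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")))
  writeLines(c(hdr, "time\tx\ty\tz"), con)
  body <- sprintf("%.6f\t%.6f\t%.6f\t%.6f",
                  rec$t, rec$xyz[, 1], rec$xyz[, 2], rec$xyz[, 3])
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_raw_recording
#' @export
read_raw_recording <- function(path) {
  lines <- readLines(path, n = 10L)
  hdr_n <- sum(startsWith(lines, "#"))
  kv <- strsplit(sub("^#", "", lines[seq_len(hdr_n)]), "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  dat <- utils::read.table(path, skip = hdr_n, header = TRUE, sep = "\t")
  raw_recording(meta[["participant_id"]], meta[["device_id"]],
                as.POSIXct(meta[["start_time"]],
                           format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                dat$time, as.matrix(dat[, c("x", "y", "z")]))
}
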