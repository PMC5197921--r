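# Internal numeric helpers shared across stages.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Butterworth band-pass design (via signal::butter) plus the per-unit-input
# steady-state filter state used by the zero-phase C++ kernel. Cached per
# (low, high, order, rate) since design is comparatively expensive.
.filter_cache <- new.env(parent = emptyenv())

bandpass_coefs <- function(low_hz = 0.2, high_hz = 15, order = 4, rate_hz = 50) {
  key <- paste(low_hz, high_hz, order, rate_hz, sep = "|")
  hit <- .filter_cache[[key]]
  if (!is.null(hit)) return(hit)
  flt <- signal::butter(order, c(low_hz, high_hz) / (rate_hz / 2), type = "pass")
  b <- as.numeric(flt$b)
  a <- as.numeric(flt$a)
  m <- length(a)
  # Steady-state state vector for direct-form II transposed: solve
  # (I - C^T) zi = b[-1] - a[-1] * b[1], C the companion matrix of a.
  comp <- rbind(-a[-1], cbind(diag(m - 2), 0))
  zi <- solve(diag(m - 1) - t(comp), b[-1] - a[-1] * b[1])
  out <- list(b = b, a = a, zi = zi, padlen = 3 * (m - 1))
  assign(key, out, envir = .filter_cache)
  out
}

# Zero-phase band-pass of a numeric vector (no NAs). Exposed internally;
# user-facing entry point is bandpass_magnitude().
zerophase_bandpass <- function(x, coefs) {
  cpp_filtfilt(coefs$b, coefs$a, x, coefs$zi, as.integer(coefs$padlen))
}

# Binned statistics of a vector by a 0-based integer bin index aligned to
# 0:(ngroups-1): one C pass returning count, sum, sum of squares and sum
# of absolute values per bin, NA dropped.
bin_moments <- function(x, idx0, ngroups) {
  cpp_bin_moments(as.numeric(x), as.integer(idx0), as.integer(ngroups))
}

group_sums <- function(x, idx0, ngroups) {
  m <- bin_moments(x, idx0, ngroups)
  list(sum = m[, "sum"], n = m[, "n"])
}

# Seconds elapsed since the (UTC) midnight preceding a POSIXct instant.
sec_of_day <- function(time) {
  lt <- as.POSIXlt(time, tz = "UTC")
  lt$hour * 3600 + lt$min * 60 + lt$sec
}

midnight_of <- function(time) {
  as.POSIXct(trunc(as.POSIXlt(time, tz = "UTC"), "days"))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, min = NULL, max = NULL) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (!is.null(min) && x < min) stopf("'%s' must be >= %g", name, min)
  if (!is.null(max) && x > max) stopf("'%s' must be <= %g", name, max)
  invisible(x)
}
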