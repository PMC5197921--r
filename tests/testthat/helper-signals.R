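# Bench fixtures built in code: tiny deterministic recordings and
# magnitude series for direct feature/filter checks.

T0 <- as.POSIXct("2024-01-08 00:00:00", tz = "UTC")

# A constant-gravity recording with optional per-axis Gaussian noise.
gravity_recording <- function(duration_s = 60, rate_hz = 30,
                              g_vec = c(0, 0, 1), noise_sd_g = 0,
                              start_time = T0, id = "B001",
                              seed = 1) {
  set.seed(seed)
  t <- seq(0, duration_s, by = 1 / rate_hz)
  n <- length(t)
  xyz <- matrix(rep(g_vec, each = n), n, 3) +
    matrix(rnorm(3 * n, 0, noise_sd_g), n, 3)
  raw_recording(id, "D1", start_time, t, xyz)
}

# Magnitude series wrapped around an arbitrary band-passed-style signal,
# for feeding the feature extractors directly.
bench_magnitude <- function(m_mg, rate_hz = 50, t0 = T0, id = "B001") {
  structure(list(participant_id = id, rate_hz = rate_hz, t0 = t0,
                 m_mg = as.numeric(m_mg)),
            class = "magnitude_series")
}

# A recording whose orientation sweeps the sphere through scripted still
# poses (10 s each) separated by fast movements: gives autocalibration a
# rich, known geometry. gain/offset are applied as the sensor model.
posed_recording <- function(n_poses = 60, rate_hz = 30,
                            gain = c(1, 1, 1), offset_mg = c(0, 0, 0),
                            noise_sd_g = 0.002, move_s = 2, still_s = 22,
                            id = "B002", seed = 2,
                            duration_pad_s = 0) {
  set.seed(seed)
  dirs <- matrix(rnorm(3 * n_poses), n_poses, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  seg <- still_s + move_s
  t <- seq(0, n_poses * seg + duration_pad_s, by = 1 / rate_hz)
  n <- length(t)
  pose <- pmin(floor(t / seg) + 1L, n_poses)
  frac <- (t - (pose - 1) * seg) / move_s  # <1 during the move phase
  moving <- frac < 1
  xyz <- dirs[pose, , drop = FALSE]
  prev <- dirs[pmax(pose - 1L, 1L), , drop = FALSE]
  w <- pmin(pmax(frac, 0), 1)
  xyz <- prev * (1 - w) + xyz * w
  xyz <- xyz / sqrt(rowSums(xyz^2))
  # high-frequency shake while moving so move windows are not "still"
  shake <- 0.1 * sin(2 * pi * 8 * t) * moving
  xyz <- xyz + cbind(shake, -shake, shake)
  xyz <- xyz + matrix(rnorm(3 * n, 0, noise_sd_g), n, 3)
  for (j in 1:3) xyz[, j] <- xyz[, j] * gain[j] + offset_mg[j] / 1000
  raw_recording(id, "D1", T0, t, xyz)
}

# Small simulation configs used across tests.
tiny_config <- function(...) {
  sim_config(n_per_group = 1, n_days = 1, partial_first_min = 60,
             partial_last_min = 60, split_devices = FALSE, ...)
}
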