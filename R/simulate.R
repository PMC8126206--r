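#' Laboratory fall protocol
#'
#' The standard protocol: seven fall types, of which types 1--6 are
#' performed in four directions and type 7 (fall while walking backward)
#' only backward; every (type, direction) pair is repeated three times per
#' subject, giving 75 trials per subject.
#'
#' @return A data.frame with one row per valid (fall_type, direction) pair:
#'   columns `fall_type`, `type_name`, `direction`.
#' @export
fall_protocol <- function() {
  types <- fall_type_names()
  dirs <- fall_directions()
  rows <- expand.grid(direction = dirs, fall_type = 1:6,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- rbind(rows[, c("fall_type", "direction")],
                data.frame(fall_type = 7L, direction = "backward"))
  rows$type_name <- types[rows$fall_type]
  rows[, c("fall_type", "type_name", "direction")]
}

#' @rdname fall_protocol
#' @return `fall_type_names()`: the seven fall-type names, indexed 1--7.
#' @export
fall_type_names <- function() {
  c("fall-while-standing", "fall-while-standing-up",
    "fall-while-sitting-down", "fall-while-stooping-down",
    "fall-while-walking", "fall-while-jumping",
    "fall-while-walking-backward")
}

#' @rdname fall_protocol
#' @return `fall_directions()`: the four fall directions.
#' @export
fall_directions <- function() {
  c("forward", "backward", "right-lateral", "left-lateral")
}

check_type_direction <- function(fall_type, direction) {
  fall_type <- as.integer(fall_type)
  if (is.na(fall_type) || fall_type < 1L || fall_type > 7L) {
    stop("protocol error: fall_type must be 1..7", call. = FALSE)
  }
  if (!direction %in% fall_directions()) {
    stop("protocol error: unknown direction '", direction, "'", call. = FALSE)
  }
  if (fall_type == 7L && direction != "backward") {
    stop("protocol error: fall type 7 (walking backward) admits only the ",
         "backward direction", call. = FALSE)
  }
  invisible(TRUE)
}

#' Default elapsed-time table
#'
#' Mean and standard deviation (seconds) of the elapsed time of a trial --
#' from the start of the pre-fall activity to the end of the recovery --
#' for every fall type and direction, as used by the simulator.
#'
#' @return A data.frame with columns `fall_type`, `direction`, `mean_s`,
#'   `sd_s`.
#' @export
elapsed_time_defaults <- function() {
  m <- rbind(
    c(14.89, 2.03, 14.91, 2.53, 15.58, 2.32, 15.35, 1.95),
    c(16.66, 3.01, 17.00, 2.58, 17.07, 1.83, 17.33, 1.67),
    c(16.44, 1.88, 15.91, 1.85, 15.90, 1.85, 15.69, 1.72),
    c(17.68, 1.35, 20.56, 2.73, 18.61, 2.13, 19.07, 1.82),
    c(15.52, 1.97, 16.46, 1.93, 15.65, 1.73, 15.81, 1.55),
    c(19.04, 2.23, 19.64, 2.62, 19.11, 2.41, 19.02, 2.36))
  dirs <- fall_directions()
  out <- do.call(rbind, lapply(1:6, function(ty) {
    data.frame(fall_type = ty, direction = dirs,
               mean_s = m[ty, c(1, 3, 5, 7)], sd_s = m[ty, c(2, 4, 6, 8)])
  }))
  out <- rbind(out, data.frame(fall_type = 7L, direction = "backward",
                               mean_s = 19.17, sd_s = 1.80))
  rownames(out) <- NULL
  out
}

#' Simulator configuration
#'
#' Parameters of the synthetic fall-trial generator. The elapsed time of
#' each trial is drawn from a per-(type, direction) normal law (see
#' [elapsed_time_defaults()]); free-fall and impact have fixed short
#' duration ranges, and the remaining elapsed time is split between
#' pre-fall, resting and recovery. Static bookends are added before and
#' after the elapsed span. Acceleration is in g (resting resultant around
#' 1), angular velocity in deg/s.
#'
#' @param fs Sampling rate in Hz.
#' @param elapsed Elapsed-time table, a data.frame like
#'   [elapsed_time_defaults()].
#' @param frac_prefall,frac_resting,frac_recovery Nominal fractions of the
#'   trial body allotted to pre-fall, resting and recovery.
#' @param frac_initial Nominal fraction for the initial-static bookend; the
#'   ending-static bookend takes the remainder.
#' @param frac_jitter Log-scale jitter applied per trial to the fractions.
#' @param freefall_range,impact_range Duration ranges in seconds.
#' @param freefall_floor Resultant-acceleration floor (g) reached at the
#'   end of the free-fall phase.
#' @param freefall_shape Exponent of the free-fall magnitude decay; values
#'   above 1 make the early free-fall resemble the preceding activity.
#' @param freefall_gyro Peak angular velocity (deg/s) reached while toppling.
#' @param impact_peak_range Peak impact acceleration range (g).
#' @param impact_gyro_range Peak impact angular-velocity range (deg/s).
#' @param static_noise_sd,gyro_noise_sd Accelerometer (g) / gyroscope
#'   (deg/s) noise during quiet standing.
#' @param motion_noise_sd,motion_gyro_noise_sd Noise during active phases.
#' @param gait_amp,gait_freq Walking oscillation amplitude (g) and stride
#'   frequency (Hz).
#' @param hop_amp,hop_period Jumping hop amplitude (g) and period (s).
#' @param ending_tilt Residual forward tilt (g projection) of the posture
#'   after getting up, distinguishing ending- from initial-static.
#' @param ending_noise_mult Noise multiplier for the ending-static phase
#'   (post-exertion sway).
#' @param subject_amp_sd,subject_tempo_sd Log-sd of per-subject amplitude
#'   and tempo multipliers.
#' @param subject_time_frac Fraction of the elapsed-time standard deviation
#'   attributed to a per-subject offset (the rest is per-trial).
#' @return A validated list of class `simulator_config`.
#' @export
simulator_config <- function(fs = 128,
                             elapsed = elapsed_time_defaults(),
                             frac_prefall = 0.25,
                             frac_resting = 0.25,
                             frac_recovery = 0.20,
                             frac_initial = 0.15,
                             frac_jitter = 0.05,
                             freefall_range = c(0.3, 0.6),
                             impact_range = c(0.2, 0.5),
                             freefall_floor = 0.3,
                             freefall_shape = 2,
                             freefall_gyro = 160,
                             impact_peak_range = c(3, 6),
                             impact_gyro_range = c(150, 400),
                             static_noise_sd = 0.02,
                             gyro_noise_sd = 1.5,
                             motion_noise_sd = 0.03,
                             motion_gyro_noise_sd = 3,
                             gait_amp = 0.22,
                             gait_freq = 1.8,
                             hop_amp = 1.1,
                             hop_period = 0.7,
                             ending_tilt = 0.08,
                             ending_noise_mult = 1.5,
                             subject_amp_sd = 0.15,
                             subject_tempo_sd = 0.08,
                             subject_time_frac = 0.5) {
  cfg <- as.list(environment())
  validate_simulator_config(cfg)
  structure(cfg, class = "simulator_config")
}

validate_simulator_config <- function(cfg) {
  stopifnot(cfg$fs > 0)
  sds <- c(cfg$frac_jitter, cfg$static_noise_sd, cfg$gyro_noise_sd,
           cfg$motion_noise_sd, cfg$motion_gyro_noise_sd,
           cfg$subject_amp_sd, cfg$subject_tempo_sd)
  if (any(sds < 0)) stop("simulator config: sds must be >= 0", call. = FALSE)
  fr <- c(cfg$frac_prefall, cfg$frac_resting, cfg$frac_recovery,
          cfg$frac_initial)
  if (any(fr <= 0) || sum(fr) >= 1) {
    stop("simulator config: phase fractions must be positive and leave a ",
         "positive ending-static remainder", call. = FALSE)
  }
  if (cfg$freefall_floor < 0 || cfg$freefall_floor >= 1) {
    stop("simulator config: free-fall floor must lie in [0, 1) g",
         call. = FALSE)
  }
  if (cfg$impact_peak_range[1] <= 1) {
    stop("simulator config: impact peak must exceed 1 g", call. = FALSE)
  }
  for (nm in c("freefall_range", "impact_range", "impact_peak_range",
               "impact_gyro_range")) {
    r <- cfg[[nm]]
    if (length(r) != 2L || r[1] > r[2] || r[1] < 0) {
      stop("simulator config: ", nm, " must be an increasing pair",
           call. = FALSE)
    }
  }
  need <- c("fall_type", "direction", "mean_s", "sd_s")
  if (!all(need %in% names(cfg$elapsed))) {
    stop("simulator config: elapsed table needs columns ",
         paste(need, collapse = ","), call. = FALSE)
  }
  invisible(TRUE)
}

# Counter-based seed derivation: every trial and subject substream hashes
# (seed, keys...) into its own 31-bit seed, so any subset of the protocol
# regenerates identically without consuming a shared RNG stream.
derive_seed <- function(seed, ...) {
  keys <- c(as.numeric(seed), as.numeric(c(...)))
  state <- 0
  for (k in keys) {
    state <- (state * 69069 + abs(k) + 1) %% 2147483647
  }
  as.integer(state %% 2147483646) + 1L
}

with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

unit3 <- function(v) v / sqrt(sum(v * v))

# Spherical interpolation between two unit vectors; t is a vector in [0,1].
# Returns a length(t) x 3 matrix.
slerp_rows <- function(u, v, t) {
  d <- max(-1, min(1, sum(u * v)))
  ang <- acos(d)
  if (ang < 1e-8) {
    return(matrix(rep(u, each = length(t)), ncol = 3))
  }
  s <- sin(ang)
  outer(sin((1 - t) * ang) / s, u) + outer(sin(t * ang) / s, v)
}

lying_vector <- function(direction) {
  switch(direction,
         "forward"       = c(0.95, 0, 0.31),
         "backward"      = c(-0.95, 0, 0.31),
         "right-lateral" = c(0, 0.95, 0.31),
         "left-lateral"  = c(0, -0.95, 0.31))
}

# Axis (1=x,2=y) and sign loaded by the impact, and the gyro axis (1=gx
# roll, 2=gy pitch) about which the body topples, per fall direction.
direction_axes <- function(direction) {
  switch(direction,
         "forward"       = list(acc_axis = 1L, acc_sign = 1,  gyr_axis = 2L, gyr_sign = 1),
         "backward"      = list(acc_axis = 1L, acc_sign = -1, gyr_axis = 2L, gyr_sign = -1),
         "right-lateral" = list(acc_axis = 2L, acc_sign = 1,  gyr_axis = 1L, gyr_sign = 1),
         "left-lateral"  = list(acc_axis = 2L, acc_sign = -1, gyr_axis = 1L, gyr_sign = -1))
}

noise_mat <- function(n, k, sd) matrix(rnorm(n * k, 0, sd), n, k)

sim_static <- function(n, u, acc_sd, gyr_sd) {
  acc <- matrix(rep(u, each = n), n, 3) + noise_mat(n, 3, acc_sd)
  gyr <- noise_mat(n, 3, gyr_sd)
  cbind(acc, gyr)
}

sim_prefall <- function(n, fall_type, cfg, am, tempo) {
  fs <- cfg$fs
  t <- (seq_len(n) - 1) / fs
  acc <- cbind(0, 0, rep(1, n))
  gyr <- matrix(0, n, 3)
  if (fall_type %in% c(5L, 7L)) {          # gait oscillation
    f <- cfg$gait_freq * tempo
    A <- cfg$gait_amp * am
    ph <- runif(3, 0, 2 * pi)
    acc[, 3] <- 1 + A * sin(2 * pi * f * t + ph[1]) +
      0.35 * A * sin(4 * pi * f * t + ph[2])
    acc[, 1] <- 0.5 * A * sin(2 * pi * f * t + ph[1] + pi / 2)
    acc[, 2] <- 0.3 * A * sin(pi * f * t + ph[3])
    gyr[, 1] <- 20 * am * sin(2 * pi * f * t + ph[2])
    gyr[, 2] <- 30 * am * sin(2 * pi * f * t + ph[1])
    gyr[, 3] <- 25 * am * sin(pi * f * t + ph[3])
  } else if (fall_type == 1L) {            # anticipatory standing sway
    ph <- runif(2, 0, 2 * pi)
    acc[, 1] <- 0.05 * am * sin(2 * pi * 0.4 * tempo * t + ph[1])
    acc[, 2] <- 0.04 * am * sin(2 * pi * 0.3 * tempo * t + ph[2])
    gyr[, 1] <- 4 * am * sin(2 * pi * 0.35 * t + ph[2])
    gyr[, 2] <- 5 * am * sin(2 * pi * 0.4 * t + ph[1])
  } else if (fall_type %in% c(2L, 3L)) {   # stand-up / sit-down transition
    sgn <- if (fall_type == 2L) 1 else -1
    dur <- min(1.5, 0.6 * n / fs)
    t0 <- (n / fs - dur) / 2
    tau <- pmin(pmax((t - t0) / dur, 0), 1)
    b <- sin(pi * tau)
    acc[, 3] <- 1 + sgn * 0.22 * am * b
    acc[, 1] <- 0.18 * am * b
    gyr[, 2] <- sgn * 50 * am * b
    gyr[, 1] <- 10 * am * b
  } else if (fall_type == 4L) {            # stooping: slow pitch excursion
    dur <- 0.7 * n / fs
    t0 <- 0.15 * n / fs
    tau <- pmin(pmax((t - t0) / dur, 0), 1)
    b <- sin(pi * tau)
    acc[, 1] <- 0.35 * am * b
    acc[, 3] <- 1 - 0.08 * am * b
    gyr[, 2] <- 40 * am * sin(2 * pi * tau)
    gyr[, 1] <- 8 * am * b
  } else if (fall_type == 6L) {            # repeated hops
    p <- cfg$hop_period / tempo
    hop_starts <- seq(0.3, n / fs - 0.3, by = p)
    for (h in hop_starts) {
      up <- which(t >= h & t < h + 0.12)
      dn <- which(t >= h - 0.15 & t < h)
      if (length(up)) {
        acc[up, 3] <- acc[up, 3] +
          cfg$hop_amp * am * sin(pi * (t[up] - h) / 0.12)
        gyr[up, 2] <- gyr[up, 2] + 60 * am * sin(pi * (t[up] - h) / 0.12)
      }
      if (length(dn)) {
        acc[dn, 3] <- acc[dn, 3] -
          0.35 * am * sin(pi * (t[dn] - (h - 0.15)) / 0.15)
      }
    }
  }
  acc <- acc + noise_mat(n, 3, cfg$motion_noise_sd)
  gyr <- gyr + noise_mat(n, 3, cfg$motion_gyro_noise_sd)
  cbind(acc, gyr)
}

sim_freefall <- function(n, lying, axes, cfg, am) {
  tau <- (seq_len(n) - 1) / max(n - 1, 1)
  mag <- 1 - (1 - cfg$freefall_floor) * tau^cfg$freefall_shape
  orient <- slerp_rows(c(0, 0, 1), lying, 0.5 * tau)
  acc <- orient * mag + noise_mat(n, 3, 0.04)
  gyr <- noise_mat(n, 3, 5)
  gyr[, axes$gyr_axis] <- gyr[, axes$gyr_axis] +
    axes$gyr_sign * cfg$freefall_gyro * am * tau^2
  cbind(acc, gyr)
}

sim_impact <- function(n, lying, axes, cfg, am) {
  fs <- cfg$fs
  t <- (seq_len(n) - 1) / fs
  peak <- runif(1, cfg$impact_peak_range[1], cfg$impact_peak_range[2]) * am
  w <- min(0.06, n / fs / 2)
  spike <- ifelse(t < w, peak * sin(pi * t / w), 0)
  ring <- ifelse(t >= w,
                 0.45 * peak * exp(-(t - w) / 0.12) * cos(2 * pi * 14 * (t - w)),
                 0)
  # secondary contacts while the body settles (hip then trunk/shoulder,
  # mattress rebound): one or two smaller bumps later in the phase
  n_bounce <- 1L + (runif(1) < 0.6)
  bounce_t <- sort(runif(n_bounce, 0.25, 0.85)) * n / fs
  bounce_a <- runif(n_bounce, 0.25, 0.5) * peak
  for (b in seq_len(n_bounce)) {
    inb <- t >= bounce_t[b] & t < bounce_t[b] + 0.05
    spike[inb] <- spike[inb] +
      bounce_a[b] * sin(pi * (t[inb] - bounce_t[b]) / 0.05)
    ring <- ring + ifelse(t >= bounce_t[b] + 0.05,
                          0.5 * bounce_a[b] *
                            exp(-(t - bounce_t[b] - 0.05) / 0.1) *
                            cos(2 * pi * 12 * (t - bounce_t[b] - 0.05)),
                          0)
  }
  acc <- matrix(rep(lying, each = n), n, 3)
  acc[, axes$acc_axis] <- acc[, axes$acc_axis] +
    axes$acc_sign * (spike + ring)
  acc[, 3] <- acc[, 3] + 0.5 * spike + 0.4 * ring
  other <- if (axes$acc_axis == 1L) 2L else 1L
  acc[, other] <- acc[, other] + 0.15 * spike
  gpeak <- runif(1, cfg$impact_gyro_range[1], cfg$impact_gyro_range[2]) * am
  gyr <- noise_mat(n, 3, 8)
  gdec <- gpeak * exp(-t / 0.12) * cos(2 * pi * 8 * t)
  for (b in seq_len(n_bounce)) {
    gdec <- gdec + ifelse(t >= bounce_t[b],
                          0.4 * gpeak * exp(-(t - bounce_t[b]) / 0.1) *
                            cos(2 * pi * 10 * (t - bounce_t[b])),
                          0)
  }
  gyr[, axes$gyr_axis] <- gyr[, axes$gyr_axis] + axes$gyr_sign * gdec
  gyr[, 3] <- gyr[, 3] + 0.3 * gdec
  acc <- acc + noise_mat(n, 3, 0.05)
  cbind(acc, gyr)
}

sim_resting <- function(n, lying, axes, cfg, am) {
  t <- (seq_len(n) - 1) / cfg$fs
  acc <- matrix(rep(lying, each = n), n, 3) +
    noise_mat(n, 3, 0.75 * cfg$static_noise_sd)
  acc[, axes$acc_axis] <- acc[, axes$acc_axis] +
    0.01 * am * sin(2 * pi * 0.25 * t)   # breathing
  gyr <- noise_mat(n, 3, 0.7 * cfg$gyro_noise_sd)
  cbind(acc, gyr)
}

sim_recovery <- function(n, lying, u_end, cfg, am, tempo) {
  fs <- cfg$fs
  t <- (seq_len(n) - 1) / fs
  tau <- (seq_len(n) - 1) / max(n - 1, 1)
  ease <- tau * tau * (3 - 2 * tau)
  orient <- slerp_rows(lying, u_end, ease)
  env <- sin(pi * tau)
  mag <- 1 + 0.12 * am * sin(2 * pi * 1.3 * tempo * t) * env
  ph <- runif(3, 0, 2 * pi)
  acc <- orient * mag + noise_mat(n, 3, 0.04)
  gyr <- noise_mat(n, 3, 3)
  gyr[, 1] <- gyr[, 1] + 35 * am * sin(2 * pi * 1.0 * tempo * t + ph[1]) * env
  gyr[, 2] <- gyr[, 2] + 45 * am * sin(2 * pi * 1.1 * tempo * t + ph[2]) * env
  gyr[, 3] <- gyr[, 3] + 25 * am * sin(2 * pi * 0.8 * tempo * t + ph[3]) * env
  cbind(acc, gyr)
}

#' Generate one synthetic fall trial
#'
#' Produces a labelled trial that traverses the seven phases in canonical
#' order. The elapsed time (pre-fall start to recovery end) is drawn from
#' the configured normal law for the (type, direction) pair, truncated to
#' remain positive; free-fall and impact durations are drawn uniformly from
#' their configured ranges; the remainder of the elapsed span is split
#' between pre-fall, resting and recovery with jittered fractions. The
#' output is deterministic given `(config, seed, subject_seed)`.
#'
#' @param fall_type Fall type 1--7.
#' @param direction Fall direction; type 7 admits only `"backward"`.
#' @param subject_id Subject identifier (stored as metadata).
#' @param repetition Repetition number (stored as metadata).
#' @param config A [simulator_config()].
#' @param seed Integer seed for the trial's randomness.
#' @param subject_seed Seed for the per-subject multipliers (amplitude,
#'   tempo, timing offset). Trials sharing a `subject_seed` share a
#'   subject's movement signature; defaults to a hash of
#'   `(seed, subject_id)`.
#' @return A [trial_record()].
#' @export
generate_trial <- function(fall_type, direction, subject_id = 1L,
                           repetition = 1L, config = simulator_config(),
                           seed = 1L,
                           subject_seed = derive_seed(seed, 9001, subject_id)) {
  check_type_direction(fall_type, direction)
  validate_simulator_config(config)
  cfg <- config
  fs <- cfg$fs

  row <- cfg$elapsed[cfg$elapsed$fall_type == fall_type &
                       cfg$elapsed$direction == direction, ]
  if (nrow(row) != 1L) {
    stop("protocol error: no elapsed-time entry for type ", fall_type,
         " direction ", direction, call. = FALSE)
  }
  mean_e <- row$mean_s
  sd_e <- row$sd_s

  subj <- with_preserved_rng(subject_seed, {
    list(am = exp(rnorm(1, 0, cfg$subject_amp_sd)),
         tempo = exp(rnorm(1, 0, cfg$subject_tempo_sd)),
         time_z = rnorm(1),
         lying_jit = rnorm(3, 0, 0.04),
         end_jit = rnorm(2, 0, 0.02))
  })

  with_preserved_rng(seed, {
    time_off <- subj$time_z * cfg$subject_time_frac * sd_e
    resid_sd <- sqrt(max(0, 1 - cfg$subject_time_frac^2)) * sd_e
    ff_s <- runif(1, cfg$freefall_range[1], cfg$freefall_range[2])
    imp_s <- runif(1, cfg$impact_range[1], cfg$impact_range[2])
    floor_e <- ff_s + imp_s + 1.5
    T_e <- mean_e + time_off + rnorm(1, 0, resid_sd)
    while (T_e <= floor_e) T_e <- mean_e + time_off + rnorm(1, 0, resid_sd)

    body <- cfg$frac_prefall + cfg$frac_resting + cfg$frac_recovery
    T_tot <- (T_e - ff_s - imp_s) / body
    p <- c(cfg$frac_prefall, cfg$frac_resting, cfg$frac_recovery) *
      exp(rnorm(3, 0, cfg$frac_jitter))
    p <- p / sum(p) * body
    n_ff <- max(4L, as.integer(round(ff_s * fs)))
    n_imp <- max(4L, as.integer(round(imp_s * fs)))
    n_pre <- max(8L, as.integer(round(p[1] * T_tot * fs)))
    n_rest <- max(8L, as.integer(round(p[2] * T_tot * fs)))
    n_rec <- max(8L, as.integer(round(p[3] * T_tot * fs)))
    n_init <- max(8L, as.integer(round(cfg$frac_initial * T_tot * fs *
                                         exp(rnorm(1, 0, cfg$frac_jitter)))))
    frac_end <- 1 - cfg$frac_initial - body
    n_end <- max(8L, as.integer(round(frac_end * T_tot * fs *
                                        exp(rnorm(1, 0, cfg$frac_jitter)))))

    axes <- direction_axes(direction)
    lying <- unit3(lying_vector(direction) + subj$lying_jit)
    u_end <- unit3(c(cfg$ending_tilt + subj$end_jit[1],
                     0.03 + subj$end_jit[2], 1))

    parts <- list(
      sim_static(n_init, c(0, 0, 1), cfg$static_noise_sd, cfg$gyro_noise_sd),
      sim_prefall(n_pre, fall_type, cfg, subj$am, subj$tempo),
      sim_freefall(n_ff, lying, axes, cfg, subj$am),
      sim_impact(n_imp, lying, axes, cfg, subj$am),
      sim_resting(n_rest, lying, axes, cfg, subj$am),
      sim_recovery(n_rec, lying, u_end, cfg, subj$am, subj$tempo),
      sim_static(n_end, u_end, cfg$ending_noise_mult * cfg$static_noise_sd,
                 cfg$ending_noise_mult * cfg$gyro_noise_sd))
    sig <- do.call(rbind, parts)
    counts <- vapply(parts, nrow, integer(1))
    labels <- rep(0:6, counts)

    stream <- imu_stream(sig[, 1], sig[, 2], sig[, 3],
                         sig[, 4], sig[, 5], sig[, 6], fs = fs)
    trial_record(stream, phase_label_sequence(labels, fs = fs),
                 subject_id = subject_id, fall_type = fall_type,
                 direction = direction, repetition = repetition)
  })
}

#' Generate a full protocol dataset
#'
#' For each subject, every valid (type, direction) pair of
#' [fall_protocol()] is generated three times: 6 types x 4 directions x 3
#' repetitions + 1 type x 1 direction x 3 repetitions = 75 trials per
#' subject. Per-trial seeds are derived deterministically from `seed` and
#' the trial's protocol coordinates, so any subset regenerates identically.
#'
#' @param n_subjects Number of subjects (the standard protocol uses 7).
#' @param config A [simulator_config()].
#' @param seed Master integer seed.
#' @param repetitions Repetitions per (type, direction) pair (default 3).
#' @return An object of class `fall_dataset`: a list with `trials` (list of
#'   [trial_record()]), `config` and `seed`.
#' @export
generate_protocol_dataset <- function(n_subjects = 7L,
                                      config = simulator_config(),
                                      seed = 1L, repetitions = 3L) {
  stopifnot(n_subjects >= 1L, repetitions >= 1L)
  proto <- fall_protocol()
  dirs <- fall_directions()
  trials <- vector("list", n_subjects * nrow(proto) * repetitions)
  i <- 0L
  for (s in seq_len(n_subjects)) {
    subject_seed <- derive_seed(seed, 9001, s)
    for (r in seq_len(nrow(proto))) {
      ty <- proto$fall_type[r]
      di <- proto$direction[r]
      for (rep_i in seq_len(repetitions)) {
        i <- i + 1L
        trials[[i]] <- generate_trial(
          ty, di, subject_id = s, repetition = rep_i, config = config,
          seed = derive_seed(seed, s, ty, match(di, dirs), rep_i),
          subject_seed = subject_seed)
      }
    }
  }
  structure(list(trials = trials, config = config, seed = as.integer(seed)),
            class = "fall_dataset")
}

#' @export
print.fall_dataset <- function(x, ...) {
  subs <- vapply(x$trials, function(tr) tr$subject_id, integer(1))
  cat(sprintf("<fall_dataset> %d trials, %d subjects (seed %d)\n",
              length(x$trials), length(unique(subs)), x$seed))
  invisible(x)
}

#' Write / read a dataset as CSV files plus a manifest
#'
#' `write_dataset()` writes one stream/labels CSV pair per trial (the
#' [write_trial()] dialect), a `manifest.csv` with the protocol coordinates
#' and file names, and the simulator configuration as `config.yaml`.
#' `read_dataset()` reads them back.
#'
#' @param dataset A `fall_dataset`.
#' @param dir Output (input) directory.
#' @return `write_dataset()`: invisibly, the manifest path.
#'   `read_dataset()`: a `fall_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "fall_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(dataset$trials, function(tr) {
    stem <- sprintf("s%02d_t%d_%s_r%d", tr$subject_id, tr$fall_type,
                    tr$direction, tr$repetition)
    sp <- paste0(stem, "_stream.csv")
    lp <- paste0(stem, "_labels.csv")
    write_trial(tr, file.path(dir, sp), file.path(dir, lp))
    data.frame(subject_id = tr$subject_id, fall_type = tr$fall_type,
               direction = tr$direction, repetition = tr$repetition,
               stream_file = sp, labels_file = lp)
  })
  manifest <- do.call(rbind, rows)
  data.table::fwrite(manifest, file.path(dir, "manifest.csv"))
  cfg <- dataset$config
  cfg$elapsed <- as.list(cfg$elapsed)
  yaml::write_yaml(c(list(seed = dataset$seed), cfg),
                   file.path(dir, "config.yaml"))
  invisible(file.path(dir, "manifest.csv"))
}

#' @rdname write_dataset
#' @param fs Sampling rate used when no `config.yaml` is found.
#' @export
read_dataset <- function(dir, fs = 128) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) {
    stop("I/O error: no manifest.csv in ", dir, call. = FALSE)
  }
  manifest <- data.table::fread(mf, data.table = FALSE)
  cfg <- NULL
  seed <- NA_integer_
  cfp <- file.path(dir, "config.yaml")
  if (file.exists(cfp)) {
    raw <- yaml::read_yaml(cfp)
    seed <- raw$seed
    raw$seed <- NULL
    raw$elapsed <- as.data.frame(raw$elapsed)
    cfg <- do.call(simulator_config, raw)
    fs <- cfg$fs
  }
  trials <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    read_trial(file.path(dir, m$stream_file), file.path(dir, m$labels_file),
               fs = fs, subject_id = m$subject_id, fall_type = m$fall_type,
               direction = m$direction, repetition = m$repetition)
  })
  structure(list(trials = trials, config = cfg, seed = seed),
            class = "fall_dataset")
}
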