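# Synthetic trajectory generators. Both motility phenotypes are modeled as
# mean-reverting (Ornstein-Uhlenbeck-type) processes so their stationary
# variances are known in closed form and the analysis stages can be tested
# against them:
#  - the migratory phenotype is a persistent random walk whose velocity is an
#    exactly discretized OU process (ensemble MSD follows the Fürth law
#    MSD(t) = 4 D (t - P (1 - exp(-t/P))) with D = sigma_v^2 * P);
#  - the oscillatory phenotype (anchored cell with strong protrusive nuclear
#    jitter) is an anti-persistent AR(1) around a fixed anchor with stationary
#    per-axis SD a, tuned so the mean per-frame step equals step_scale.

#' Parameters of the persistent-random-walk (migratory) track model
#'
#' @param mean_speed Mean instantaneous speed, um/s. The per-axis velocity SD
#'   is `mean_speed / sqrt(pi/2)` (2-D Rayleigh speed).
#' @param persistence_time_P Velocity correlation time P, seconds.
#' @param speed_sd Between-cell SD of mean speed, um/s; 0 (default) gives a
#'   homogeneous ensemble whose MSD is exactly of Fürth form.
#' @param n_frames,frame_interval Track length and sampling interval (s).
#' @return List of class `prw_params`.
#' @export
prw_params <- function(mean_speed = 0.1, persistence_time_P = 60,
                       speed_sd = 0, n_frames = 60, frame_interval = 10) {
  stopifnot(mean_speed > 0, persistence_time_P > 0, speed_sd >= 0,
            n_frames >= 2, frame_interval > 0)
  structure(list(mean_speed = mean_speed,
                 persistence_time_P = persistence_time_P,
                 speed_sd = speed_sd, n_frames = as.integer(n_frames),
                 frame_interval = frame_interval),
            class = "prw_params")
}

#' Parameters of the oscillatory (anchored) track model
#'
#' @param anchor_sd_a Stationary per-axis SD of the nuclear position around
#'   the anchor, um (spatial scale of confinement).
#' @param step_scale Mean per-frame step length, um/frame; large relative to
#'   `anchor_sd_a` produces the high-jitter, no-net-motion phenotype that
#'   inflates path length without net displacement.
#' @param n_frames,frame_interval Track length and sampling interval (s).
#' @return List of class `oscillatory_params`.
#' @export
oscillatory_params <- function(anchor_sd_a = 1, step_scale = 2,
                               n_frames = 60, frame_interval = 10) {
  stopifnot(anchor_sd_a > 0, step_scale > 0, n_frames >= 2,
            frame_interval > 0)
  # AR(1) coefficient giving mean step length step_scale at stationary SD a:
  # E|step| = a * sqrt(pi * (1 - phi)); phi < 0 = anti-persistent oscillation
  phi <- 1 - step_scale^2 / (pi * anchor_sd_a^2)
  if (phi <= -1)
    stop("step_scale too large for anchor_sd_a: no stationary AR(1) exists")
  structure(list(anchor_sd_a = anchor_sd_a, step_scale = step_scale,
                 phi = phi, n_frames = as.integer(n_frames),
                 frame_interval = frame_interval),
            class = "oscillatory_params")
}

track_df <- function(track_id, x, y, frame_interval) {
  n <- length(x)
  data.frame(track_id = track_id, frame = 0:(n - 1),
             t = (0:(n - 1)) * frame_interval, x = x, y = y, quality = 0)
}

#' Simulate one persistent-random-walk track
#'
#' Velocity follows a stationary OU process with correlation time P, exactly
#' discretized jointly with its position integral, so the ensemble MSD is the
#' Fürth curve at all lags with no time-step bias.
#'
#' @param p A [prw_params()] object.
#' @param track_id Track label.
#' @param start Length-2 numeric start position, um.
#' @param seed Optional integer seed fixing this track's randomness.
#' @return Single-track data frame (`track_id`, `frame`, `t`, `x`, `y`,
#'   `quality`).
#' @export
simulate_prw_track <- function(p = prw_params(), track_id = 1L,
                               start = c(0, 0), seed = NULL) {
  stopifnot(inherits(p, "prw_params"))
  if (!is.null(seed)) set.seed(seed)
  ms <- p$mean_speed
  if (p$speed_sd > 0) ms <- max(0.05 * p$mean_speed,
                                stats::rnorm(1, p$mean_speed, p$speed_sd))
  sigma_v <- ms / sqrt(pi / 2)
  P <- p$persistence_time_P
  dt <- p$frame_interval
  a <- exp(-dt / P)
  var_v <- sigma_v^2 * (1 - a^2)
  var_x <- sigma_v^2 * P^2 * (2 * dt / P - 3 + 4 * a - a^2)
  cov_xv <- sigma_v^2 * P * (1 - a)^2
  s_x <- sqrt(var_x)
  s_res <- sqrt(max(0, var_v - cov_xv^2 / var_x))
  n <- p$n_frames
  pos <- matrix(0, n, 2)
  pos[1, ] <- start
  v <- stats::rnorm(2, 0, sigma_v)
  for (k in 2:n) {
    z1 <- stats::rnorm(2)
    z2 <- stats::rnorm(2)
    eta_x <- s_x * z1
    eta_v <- (cov_xv / s_x) * z1 + s_res * z2
    pos[k, ] <- pos[k - 1, ] + P * (1 - a) * v + eta_x
    v <- a * v + eta_v
  }
  track_df(track_id, pos[, 1], pos[, 2], dt)
}

#' Simulate one oscillatory (anchored) track
#'
#' Position = anchor + anti-persistent AR(1) jitter with stationary per-axis
#' SD `anchor_sd_a` and mean per-frame step `step_scale`: the nucleus rattles
#' around a fixed spot, accruing path length but no net displacement.
#'
#' @param p An [oscillatory_params()] object.
#' @param track_id Track label.
#' @param anchor Length-2 anchor position, um.
#' @param seed Optional integer seed.
#' @return Single-track data frame.
#' @export
simulate_oscillatory_track <- function(p = oscillatory_params(),
                                       track_id = 1L, anchor = c(0, 0),
                                       seed = NULL) {
  stopifnot(inherits(p, "oscillatory_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- p$n_frames
  a_sd <- p$anchor_sd_a
  phi <- p$phi
  innov_sd <- a_sd * sqrt(1 - phi^2)
  pos <- matrix(0, n, 2)
  z <- stats::rnorm(2, 0, a_sd)
  pos[1, ] <- anchor + z
  for (k in 2:n) {
    z <- phi * z + stats::rnorm(2, 0, innov_sd)
    pos[k, ] <- anchor + z
  }
  track_df(track_id, pos[, 1], pos[, 2], p$frame_interval)
}

#' Simulate a ballistic (constant-velocity) track
#'
#' Exact straight-line fixture: `p_t = p_0 + v t`; CR = 1 for any positive
#' speed and `MSD(n dt) = (v n dt)^2`.
#'
#' @param speed Speed, um/s (>= 0; 0 gives a stationary track).
#' @param direction Angle in radians.
#' @param n_frames,frame_interval Track length and sampling interval (s).
#' @param track_id Track label.
#' @param start Length-2 start position, um.
#' @return Single-track data frame.
#' @export
simulate_ballistic_track <- function(speed = 0.1, direction = 0,
                                     n_frames = 60, frame_interval = 10,
                                     track_id = 1L, start = c(0, 0)) {
  stopifnot(speed >= 0, n_frames >= 2, frame_interval > 0)
  tt <- (0:(n_frames - 1)) * frame_interval
  track_df(track_id, start[1] + speed * cos(direction) * tt,
           start[2] + speed * sin(direction) * tt, frame_interval)
}

#' Simulate an ensemble of tracks as a track set
#'
#' @param n Number of tracks.
#' @param model `"prw"` or `"oscillatory"`.
#' @param p Parameter object matching `model` (defaults per model).
#' @param seed Integer seed fixing the whole ensemble.
#' @param spread SD of the random anchor/start positions, um.
#' @return A [track_set()].
#' @export
simulate_track_set <- function(n, model = c("prw", "oscillatory"), p = NULL,
                               seed = 1, spread = 50) {
  model <- match.arg(model)
  if (is.null(p)) p <- if (model == "prw") prw_params() else oscillatory_params()
  set.seed(seed)
  trs <- lapply(seq_len(n), function(i) {
    origin <- stats::rnorm(2, 0, spread)
    if (model == "prw") simulate_prw_track(p, track_id = i, start = origin)
    else simulate_oscillatory_track(p, track_id = i, anchor = origin)
  })
  track_set(do.call(rbind, trs),
            acquisition_info(frame_interval = p$frame_interval,
                             n_frames = p$n_frames))
}
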