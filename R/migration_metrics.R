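# Per-track migration statistics: total/maximum distance traveled, median
# speed, confinement ratio and its decay, time-averaged MSD, and the
# replicate-level curve aggregation used for population figures.

as_track_df <- function(tr, min_spots = 2) {
  if (inherits(tr, "track_set")) {
    ids <- unique(tr$spots$track_id)
    if (length(ids) != 1)
      stop("expected a single track; got a track_set with ", length(ids))
    tr <- tr$spots
  }
  stopifnot(is.data.frame(tr), all(c("x", "y") %in% names(tr)))
  if ("frame" %in% names(tr)) tr <- tr[order(tr$frame), , drop = FALSE]
  if (nrow(tr) < min_spots)
    stop("insufficient data: track has ", nrow(tr),
         " spot(s), need >= ", min_spots)
  tr
}

step_lengths <- function(tr) {
  sqrt(diff(tr$x)^2 + diff(tr$y)^2)
}

track_dt <- function(tr, frame_interval = NULL) {
  if (!is.null(frame_interval)) return(frame_interval)
  if (!"t" %in% names(tr)) stop("no time column and no frame_interval given")
  dts <- diff(tr$t)
  if (any(abs(dts - dts[1]) > 1e-9 * max(abs(dts[1]), 1)))
    stop("non-uniform frame interval")
  dts[1]
}

#' Total distance traveled (path length) of a track
#'
#' Sum of Euclidean step lengths between consecutive timepoints, the "total
#' distance traveled" statistic (symbol D in confinement-ratio notation).
#'
#' @param tr A single-track data frame (columns `x`, `y`, optionally `frame`,
#'   `t`) or a one-track `track_set`.
#' @return Path length in micrometers.
#' @export
path_length <- function(tr) {
  tr <- as_track_df(tr)
  sum(step_lengths(tr))
}

#' Net displacement of a track
#'
#' Euclidean distance from the first to the last spot (symbol d).
#'
#' @inheritParams path_length
#' @return Displacement in micrometers.
#' @export
displacement <- function(tr) {
  tr <- as_track_df(tr)
  n <- nrow(tr)
  sqrt((tr$x[n] - tr$x[1])^2 + (tr$y[n] - tr$y[1])^2)
}

#' Confinement ratio of a track
#'
#' CR = d / D, net displacement over path length: 1 for perfectly straight
#' motion, near 0 for confined or oscillatory motion. For a perfectly
#' stationary track (D = 0) the ratio is undefined and `NA` is returned; such
#' tracks are excluded from downstream statistics.
#'
#' @inheritParams path_length
#' @return Unitless ratio in \[0, 1\], or `NA` when D = 0.
#' @export
confinement_ratio <- function(tr) {
  tr <- as_track_df(tr)
  D <- sum(step_lengths(tr))
  if (D == 0) return(NA_real_)
  displacement(tr) / D
}

#' Maximum distance traveled
#'
#' In the default `all_pairs` mode, the maximal Euclidean distance between any
#' two timepoints of the track. `from_origin` instead takes the maximum
#' distance from the starting point, the convention of some tracking tools'
#' homonymous feature; both are exposed because exported feature tables do not
#' state which was used.
#'
#' @inheritParams path_length
#' @param mode `"all_pairs"` (default) or `"from_origin"`.
#' @return Distance in micrometers.
#' @export
max_distance_traveled <- function(tr, mode = c("all_pairs", "from_origin")) {
  mode <- match.arg(mode)
  tr <- as_track_df(tr)
  if (mode == "from_origin") {
    return(max(sqrt((tr$x - tr$x[1])^2 + (tr$y - tr$y[1])^2)))
  }
  max(stats::dist(cbind(tr$x, tr$y)))
}

#' Median instantaneous speed of a track
#'
#' Median of per-step speeds (step length divided by the frame interval).
#'
#' @inheritParams path_length
#' @param frame_interval Seconds between frames; inferred from the `t` column
#'   when omitted (it must then be uniform).
#' @return Speed in micrometers per second.
#' @export
median_speed <- function(tr, frame_interval = NULL) {
  tr <- as_track_df(tr)
  dt <- track_dt(tr, frame_interval)
  stats::median(step_lengths(tr) / dt)
}

#' Directionality-ratio (confinement-ratio) decay curve of a track
#'
#' For each timepoint t >= 1, the running ratio
#' `|p_t - p_0| / sum_{k<=t} |p_k - p_{k-1}|`. Its final value equals the
#' track's confinement ratio. Timepoints where the running path length is
#' still 0 have an undefined ratio and are carried as `NA` (excluded from
#' aggregation, not forced to 1).
#'
#' @inheritParams median_speed
#' @return Data frame with columns `t` (seconds, from the first step) and
#'   `value`.
#' @export
directionality_ratio_curve <- function(tr, frame_interval = NULL) {
  tr <- as_track_df(tr)
  n <- nrow(tr)
  if ("t" %in% names(tr)) {
    tt <- tr$t[-1]
  } else {
    dt <- track_dt(tr, frame_interval %||% 10)
    tt <- seq_len(n - 1) * dt
  }
  run_D <- cumsum(step_lengths(tr))
  disp <- sqrt((tr$x[-1] - tr$x[1])^2 + (tr$y[-1] - tr$y[1])^2)
  value <- ifelse(run_D > 0, disp / run_D, NA_real_)
  data.frame(t = tt, value = value)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Time-averaged mean square displacement of a track
#'
#' MSD with overlapping intervals: `MSD(n dt) = mean_i |p_{i+n} - p_i|^2` for
#' lags n = 1 .. T-1, the convention of the DIPER-style spreadsheet analysis.
#' Requires a gap-free track.
#'
#' @inheritParams median_speed
#' @return Data frame with columns `lag` (seconds) and `msd` (square
#'   micrometers).
#' @export
track_msd <- function(tr, frame_interval = NULL) {
  tr <- as_track_df(tr)
  if ("frame" %in% names(tr)) {
    fr <- tr$frame
    if (any(diff(fr) != 1)) stop("track has frame gaps; MSD needs gap-free tracks")
  }
  dt <- tryCatch(track_dt(tr, frame_interval), error = function(e) {
    if (is.null(frame_interval)) 10 else frame_interval
  })
  n <- nrow(tr)
  msd <- vapply(seq_len(n - 1), function(lag) {
    dx <- tr$x[(1 + lag):n] - tr$x[1:(n - lag)]
    dy <- tr$y[(1 + lag):n] - tr$y[1:(n - lag)]
    mean(dx^2 + dy^2)
  }, numeric(1))
  data.frame(lag = seq_len(n - 1) * dt, msd = msd)
}

#' Per-track metrics table of a track set
#'
#' One row per track with the five scalar migration statistics. Stationary
#' tracks get `NA` confinement ratio (flagged in `cr_defined`).
#'
#' @param ts A `track_set`.
#' @param replicate Optional replicate label recycled across rows.
#' @param mode Mode for [max_distance_traveled()].
#' @return Data frame ordered by `track_id` with columns `track_id`,
#'   `replicate`, `n_frames`, `path_length_D`, `displacement_d`,
#'   `confinement_ratio_CR`, `cr_defined`, `max_distance`, `median_speed`.
#' @export
metrics_table <- function(ts, replicate = NA_character_,
                          mode = c("all_pairs", "from_origin")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ts, "track_set"))
  trs <- tracks(ts)
  ids <- names(trs)
  ord <- order(suppressWarnings(as.numeric(ids)), ids)
  trs <- trs[ord]
  rows <- lapply(trs, function(tr) {
    cr <- confinement_ratio(tr)
    data.frame(
      n_frames = nrow(tr),
      path_length_D = path_length(tr),
      displacement_d = displacement(tr),
      confinement_ratio_CR = cr,
      cr_defined = !is.na(cr),
      max_distance = max_distance_traveled(tr, mode),
      median_speed = median_speed(tr,
        frame_interval = ts$acquisition$frame_interval)
    )
  })
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(track_id = names(trs), replicate = replicate,
                          stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

#' Aggregate per-cell curves into a population curve
#'
#' Two-stage aggregation of per-track curves (confinement-ratio decay or MSD):
#' within each replicate, the chosen statistic across cells at every abscissa
#' point (median for CR decay, mean for MSD, per the respective figure
#' conventions); then mean and SD across replicate summaries. Undefined
#' (`NA`) per-cell values are dropped per point.
#'
#' @param curves Long data frame with columns `replicate`, `abscissa`, `value`
#'   (one row per cell per point; a cell id column may be present and is
#'   ignored).
#' @param stat Within-replicate statistic, `"median"` or `"mean"`.
#' @return Data frame `abscissa`, `mean`, `sd`, `n_replicates`. SD is the
#'   sample SD over replicates (0 when only one replicate).
#' @export
aggregate_curves <- function(curves, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  stopifnot(is.data.frame(curves),
            all(c("replicate", "abscissa", "value") %in% names(curves)))
  reps <- split(curves, curves$replicate)
  if (!length(reps)) stop("no replicates to aggregate")
  absc <- sort(unique(reps[[1]]$abscissa))
  for (r in reps) {
    if (!identical(sort(unique(r$abscissa)), absc))
      stop("replicates have mismatched abscissas")
  }
  f <- if (stat == "median") stats::median else mean
  rep_curves <- vapply(reps, function(r) {
    vapply(absc, function(a) {
      v <- r$value[r$abscissa == a]
      v <- v[!is.na(v)]
      if (!length(v)) NA_real_ else f(v)
    }, numeric(1))
  }, numeric(length(absc)))
  rep_curves <- matrix(rep_curves, nrow = length(absc))
  m <- apply(rep_curves, 1, function(v) mean(v, na.rm = TRUE))
  s <- apply(rep_curves, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) 0 else stats::sd(v)
  })
  data.frame(abscissa = absc, mean = m, sd = s,
             n_replicates = length(reps))
}

#' Long table of per-track curves for a track set
#'
#' Convenience builder feeding [aggregate_curves()]: evaluates a per-track
#' curve function over all tracks and stacks the results with replicate and
#' track labels.
#'
#' @param ts A `track_set`.
#' @param what `"cr_decay"` or `"msd"`.
#' @param replicate Replicate label for all rows.
#' @param max_lag_fraction For MSD, keep lags up to this fraction of the
#'   track duration (1 = all lags). Estimates at long lags average few
#'   intervals and are noisy; population plots conventionally cap them.
#' @return Long data frame `replicate`, `track_id`, `abscissa`, `value`.
#' @export
curves_table <- function(ts, what = c("cr_decay", "msd"),
                         replicate = NA_character_, max_lag_fraction = 1) {
  what <- match.arg(what)
  stopifnot(inherits(ts, "track_set"))
  dt <- ts$acquisition$frame_interval
  rows <- lapply(tracks(ts), function(tr) {
    if (what == "cr_decay") {
      cv <- directionality_ratio_curve(tr, frame_interval = dt)
      data.frame(track_id = tr$track_id[1], abscissa = cv$t, value = cv$value)
    } else {
      cv <- track_msd(tr, frame_interval = dt)
      keep <- cv$lag <= max_lag_fraction * max(cv$lag)
      data.frame(track_id = tr$track_id[1], abscissa = cv$lag[keep],
                 value = cv$msd[keep])
    }
  })
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(replicate = replicate), out)
  rownames(out) <- NULL
  out
}

#' Fit the Fürth persistent-random-walk form to an ensemble MSD curve
#'
#' Fits `MSD(t) = 4 D (t - P (1 - exp(-t/P)))`, the two-dimensional
#' persistent-random-walk (Fürth) law, returning the motility coefficient D
#' and persistence time P.
#'
#' @param msd Data frame with columns `lag` (s) and `msd` (um^2), e.g. the
#'   mean of per-track MSD curves over an ensemble.
#' @return List with elements `D` (um^2/s), `P` (s) and the `fit` object.
#' @export
fit_furth_msd <- function(msd) {
  stopifnot(all(c("lag", "msd") %in% names(msd)), nrow(msd) >= 3)
  # slope at the longest lags approximates 4D; short-lag curvature sets P
  n <- nrow(msd)
  tail_idx <- max(2, n - 4):n
  slope <- stats::coef(stats::lm(msd$msd[tail_idx] ~ msd$lag[tail_idx]))[2]
  D0 <- max(slope / 4, 1e-8)
  P0 <- max(msd$lag[1], min(msd$lag[n] / 4, 60))
  fit <- minpack.lm::nlsLM(
    msd ~ 4 * D * (lag - P * (1 - exp(-lag / P))),
    data = msd,
    start = list(D = D0, P = P0),
    lower = c(D = 1e-10, P = 1e-3),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- stats::coef(fit)
  list(D = unname(cf["D"]), P = unname(cf["P"]), fit = fit)
}

#' Ensemble mean MSD over the tracks of a set
#'
#' @param ts A `track_set` of gap-free tracks with a common length.
#' @return Data frame `lag`, `msd` with the across-track mean at every lag.
#' @export
ensemble_msd <- function(ts) {
  stopifnot(inherits(ts, "track_set"))
  dt <- ts$acquisition$frame_interval
  curves <- lapply(tracks(ts), track_msd, frame_interval = dt)
  lags <- curves[[1]]$lag
  for (cv in curves) {
    if (!isTRUE(all.equal(cv$lag, lags)))
      stop("tracks have different lag grids")
  }
  msd <- rowMeans(vapply(curves, function(cv) cv$msd, numeric(length(lags))))
  data.frame(lag = lags, msd = msd)
}
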