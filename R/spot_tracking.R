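# Self-contained nucleus tracking: scale-normalized Laplacian-of-Gaussian
# spot detection with sub-pixel refinement, optimal frame-to-frame
# assignment, and greedy gap closing. Parameter defaults follow the
# published tracking settings (object diameter 10 um, quality threshold 0.2,
# linking max distance 10 um, gap-closing max distance 15 um, max frame gap
# 2). Pixel centers sit at (i - 0.5) * pixel_size in both axes.

#' Spot-detection parameters
#'
#' @param object_diameter Estimated object (nucleus) diameter, um. 10 by
#'   default; large-nucleus lines use 12 and primary cells 9.
#' @param quality_threshold Minimum detection quality (unitless). Quality is
#'   the scale-normalized LoG response at the maximum, scaled to the
#'   brightest-spot response of the frame stack, so the threshold is relative
#'   (the published 0.2 is tool-internal and unitless).
#' @param pixel_size Pixel size, um/px.
#' @return List of class `detection_params`.
#' @export
detection_params <- function(object_diameter = 10, quality_threshold = 0.2,
                             pixel_size = 0.65) {
  stopifnot(object_diameter > 0, quality_threshold >= 0, pixel_size > 0)
  structure(list(object_diameter = object_diameter,
                 quality_threshold = quality_threshold,
                 pixel_size = pixel_size),
            class = "detection_params")
}

#' Particle-linking parameters
#'
#' @param linking_max_distance Max frame-to-frame link distance, um.
#' @param gap_closing_max_distance Max distance bridged by gap closing, um.
#' @param gap_closing_max_frame_gap Max frame difference bridged (2 allows one
#'   missing frame).
#' @return List of class `linking_params`.
#' @export
linking_params <- function(linking_max_distance = 10,
                           gap_closing_max_distance = 15,
                           gap_closing_max_frame_gap = 2) {
  stopifnot(linking_max_distance > 0, gap_closing_max_distance > 0,
            gap_closing_max_frame_gap > 0)
  structure(list(linking_max_distance = linking_max_distance,
                 gap_closing_max_distance = gap_closing_max_distance,
                 gap_closing_max_frame_gap = as.integer(gap_closing_max_frame_gap)),
            class = "linking_params")
}

log_kernel <- function(sigma) {
  r <- max(2L, as.integer(ceiling(3.5 * sigma)))
  g <- seq(-r, r)
  gx <- exp(-g^2 / (2 * sigma^2))
  G <- outer(gx, gx)
  G <- G / sum(G)
  X2 <- outer(g^2, rep(1, length(g)))
  # scale-normalized negated LoG: sigma^2 * (-Laplacian of Gaussian)
  K <- -G * ((X2 + t(X2)) / sigma^2 - 2) / sigma^2 * sigma^2
  K - mean(K)  # zero-sum kernel: constant frames give zero response
}

log_response <- function(frame, sigma) {
  EBImage::filter2(frame, log_kernel(sigma), boundary = "replicate")
}

local_maxima_3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3 || nc < 3) return(cbind(row = integer(0), col = integer(0)))
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  ctr <- pad[2:(nr + 1), 2:(nc + 1)]
  is_max <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[2:(nr + 1) + dr, 2:(nc + 1) + dc]
    is_max <- is_max & (ctr > nb)
  }
  is_max[c(1, nr), ] <- FALSE
  is_max[, c(1, nc)] <- FALSE
  which(is_max, arr.ind = TRUE)
}

quad_offset <- function(lo, mid, hi) {
  den <- lo - 2 * mid + hi
  if (den >= 0) return(0)
  off <- 0.5 * (lo - hi) / den
  max(-0.5, min(0.5, off))
}

detect_spots_response <- function(resp, pixel_size) {
  mx <- local_maxima_3x3(resp)
  if (!nrow(mx)) {
    return(data.frame(x = numeric(0), y = numeric(0), response = numeric(0)))
  }
  out <- lapply(seq_len(nrow(mx)), function(i) {
    r <- mx[i, 1]; c <- mx[i, 2]
    dr <- quad_offset(resp[r - 1, c], resp[r, c], resp[r + 1, c])
    dc <- quad_offset(resp[r, c - 1], resp[r, c], resp[r, c + 1])
    data.frame(x = (c - 0.5 + dc) * pixel_size,
               y = (r - 0.5 + dr) * pixel_size,
               response = resp[r, c])
  })
  do.call(rbind, out)
}

#' Detect spots in a single frame
#'
#' Candidate spots are the local maxima of the scale-normalized negated
#' Laplacian-of-Gaussian response at sigma = diameter / (2 sqrt(2)); positions
#' are refined to sub-pixel accuracy by a per-axis quadratic fit. Quality is
#' the response scaled to the brightest maximum of the frame (or of the whole
#' stack when called through [detect_movie()]); spots below
#' `quality_threshold` are discarded.
#'
#' @param frame Numeric matrix (single-channel image; rows = y, cols = x).
#' @param p A [detection_params()] object.
#' @param response_scale Optional reference response used to normalize
#'   quality (e.g. the stack-wide maximum); defaults to this frame's maximum.
#' @return Data frame `x`, `y` (um), `quality`.
#' @export
detect_spots <- function(frame, p = detection_params(),
                         response_scale = NULL) {
  stopifnot(is.matrix(frame))
  sigma <- p$object_diameter / (2 * sqrt(2)) / p$pixel_size
  resp <- log_response(frame, sigma)
  det <- detect_spots_response(resp, p$pixel_size)
  if (!nrow(det)) return(data.frame(x = numeric(0), y = numeric(0),
                                    quality = numeric(0)))
  scale_ref <- response_scale %||% max(det$response)
  if (scale_ref <= 0) return(data.frame(x = numeric(0), y = numeric(0),
                                        quality = numeric(0)))
  det$quality <- det$response / scale_ref
  det <- det[det$quality >= p$quality_threshold & det$response > 0,
             c("x", "y", "quality")]
  rownames(det) <- NULL
  det
}

#' Detect spots in every frame of a movie
#'
#' Quality is normalized to the brightest-spot response of the whole stack so
#' one threshold applies across frames.
#'
#' @param stack List of frame matrices, or a 3-D array (row, col, frame).
#' @param p A [detection_params()] object.
#' @param frame_interval Seconds between frames.
#' @return Data frame `frame` (0-based), `t`, `x`, `y`, `quality`.
#' @export
detect_movie <- function(stack, p = detection_params(), frame_interval = 10) {
  if (is.array(stack) && length(dim(stack)) == 3)
    stack <- lapply(seq_len(dim(stack)[3]), function(k) stack[, , k])
  sigma <- p$object_diameter / (2 * sqrt(2)) / p$pixel_size
  dets <- lapply(stack, function(fr)
    detect_spots_response(log_response(fr, sigma), p$pixel_size))
  global_max <- max(c(0, unlist(lapply(dets, function(d) d$response))))
  rows <- lapply(seq_along(dets), function(k) {
    d <- dets[[k]]
    if (!nrow(d) || global_max <= 0) {
      return(data.frame(frame = integer(0), t = numeric(0), x = numeric(0),
                        y = numeric(0), quality = numeric(0)))
    }
    d$quality <- d$response / global_max
    d <- d[d$quality >= p$quality_threshold & d$response > 0, , drop = FALSE]
    data.frame(frame = rep(k - 1L, nrow(d)),
               t = rep((k - 1) * frame_interval, nrow(d)),
               x = d$x, y = d$y, quality = d$quality)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Jonker-style O(n^3) solver of the linear assignment problem
# (shortest augmenting paths with potentials). cost: n x m matrix, n <= m;
# returns for each row the assigned column.
lap_solve <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  INF <- 1e300
  u <- numeric(n)
  v <- numeric(m + 1)      # index 1 = virtual column
  p <- integer(m + 1)      # row assigned to column (0 = none)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(INF, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      cur <- cost[i0, ] - u[i0] - v[2:(m + 1)]
      upd <- !used[2:(m + 1)] & cur < minv[2:(m + 1)]
      minv[2:(m + 1)][upd] <- cur[upd]
      way[2:(m + 1)][upd] <- j0
      free <- which(!used[2:(m + 1)])
      j1 <- free[which.min(minv[free + 1])] + 1L
      delta <- minv[j1]
      for (jR in seq_len(m + 1)) {
        if (used[jR]) {
          if (p[jR] > 0) u[p[jR]] <- u[p[jR]] + delta
          v[jR] <- v[jR] - delta
        } else {
          minv[jR] <- minv[jR] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  rowsol <- integer(n)
  for (jR in 2:(m + 1)) if (p[jR] > 0) rowsol[p[jR]] <- jR - 1L
  rowsol
}

# Optimal one-to-one matching between two point sets with a hard radius:
# minimizes total squared distance over linked pairs while linking every
# pair that can be linked (unlinked points cost radius^2 each, so any link
# with d <= radius is preferred). Returns an integer vector over rows of a:
# index into b, or NA.
match_points <- function(a, b, radius) {
  n1 <- nrow(a); n2 <- nrow(b)
  if (n1 == 0 || n2 == 0) return(rep(NA_integer_, n1))
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  BIG <- 4 * radius^2 * (n1 + n2 + 1) + 1
  r2 <- radius^2
  C <- matrix(BIG, n1 + n2, n1 + n2)
  top <- d2
  top[top > r2] <- BIG
  C[1:n1, 1:n2] <- top
  for (i in 1:n1) C[i, n2 + i] <- r2
  for (j in 1:n2) C[n1 + j, j] <- r2
  C[(n1 + 1):(n1 + n2), (n2 + 1):(n2 + n1)] <- 0
  sol <- lap_solve(C)
  out <- rep(NA_integer_, n1)
  for (i in 1:n1) {
    j <- sol[i]
    if (j <= n2 && d2[i, j] <= r2) out[i] <- j
  }
  out
}

#' Link detected spots frame to frame into tracklets
#'
#' Consecutive frames are matched by an optimal one-to-one assignment
#' minimizing total squared distance among pairs within
#' `linking_max_distance`; unmatched spots terminate or start tracklets.
#'
#' @param spots Data frame `frame`, `x`, `y` (um), optionally `quality`, as
#'   from [detect_movie()].
#' @param p A [linking_params()] object.
#' @return The `spots` data frame with an added integer `tracklet` column.
#' @export
link_frames <- function(spots, p = linking_params()) {
  stopifnot(is.data.frame(spots), all(c("frame", "x", "y") %in% names(spots)))
  spots <- spots[order(spots$frame), , drop = FALSE]
  rownames(spots) <- NULL
  spots$tracklet <- NA_integer_
  if (!nrow(spots)) return(spots)
  frames <- sort(unique(spots$frame))
  next_id <- 0L
  idx_prev <- which(spots$frame == frames[1])
  spots$tracklet[idx_prev] <- next_id + seq_along(idx_prev)
  next_id <- next_id + length(idx_prev)
  for (k in seq_along(frames)[-1]) {
    gap_adjacent <- frames[k] - frames[k - 1] == 1
    idx_cur <- which(spots$frame == frames[k])
    assigned <- rep(NA_integer_, length(idx_cur))
    if (gap_adjacent && length(idx_prev)) {
      mm <- match_points(cbind(spots$x[idx_prev], spots$y[idx_prev]),
                         cbind(spots$x[idx_cur], spots$y[idx_cur]),
                         p$linking_max_distance)
      for (i in seq_along(idx_prev)) {
        if (!is.na(mm[i])) {
          spots$tracklet[idx_cur[mm[i]]] <- spots$tracklet[idx_prev[i]]
          assigned[mm[i]] <- 1L
        }
      }
    }
    new <- which(is.na(spots$tracklet[idx_cur]))
    if (length(new)) {
      spots$tracklet[idx_cur[new]] <- next_id + seq_along(new)
      next_id <- next_id + length(new)
    }
    idx_prev <- idx_cur
  }
  spots
}

#' Close gaps between tracklets
#'
#' Joins a tracklet end (frame f) to a later tracklet start (frame f + g)
#' when the frame difference g is at least 2 (a true gap; adjacent frames are
#' the linker's job) and at most `gap_closing_max_frame_gap`, and the
#' end-to-start distance is at most `gap_closing_max_distance` (so the
#' default gap of 2 frames bridges one missing frame). Candidate joins are taken
#' greedily by ascending distance. Bridged frames are left absent unless
#' `interpolate = TRUE` fills them linearly (such tracks otherwise fail the
#' complete-track filter).
#'
#' @param spots Data frame with `tracklet` column, as from [link_frames()].
#' @param p A [linking_params()] object.
#' @param frame_interval Seconds between frames.
#' @param interpolate Fill bridged frames by linear interpolation
#'   (default `FALSE`).
#' @return A [track_set()] with consecutive integer track ids.
#' @export
close_gaps <- function(spots, p = linking_params(), frame_interval = 10,
                       interpolate = FALSE) {
  stopifnot("tracklet" %in% names(spots))
  if (!nrow(spots)) {
    return(track_set(data.frame(track_id = integer(0), frame = integer(0),
                                x = numeric(0), y = numeric(0)),
                     acquisition_info(frame_interval = frame_interval)))
  }
  ids <- sort(unique(spots$tracklet))
  ends <- do.call(rbind, lapply(ids, function(id) {
    s <- spots[spots$tracklet == id, ]
    first <- s[which.min(s$frame), ]
    last <- s[which.max(s$frame), ]
    data.frame(id = id, f0 = first$frame, x0 = first$x, y0 = first$y,
               f1 = last$frame, x1 = last$x, y1 = last$y)
  }))
  cand <- NULL
  for (i in seq_len(nrow(ends))) for (j in seq_len(nrow(ends))) {
    if (i == j) next
    g <- ends$f0[j] - ends$f1[i]
    if (g < 2 || g > p$gap_closing_max_frame_gap) next
    d <- sqrt((ends$x0[j] - ends$x1[i])^2 + (ends$y0[j] - ends$y1[i])^2)
    if (d <= p$gap_closing_max_distance)
      cand <- rbind(cand, data.frame(from = ends$id[i], to = ends$id[j], d = d))
  }
  succ <- integer(0)
  if (!is.null(cand) && nrow(cand)) {
    cand <- cand[order(cand$d), , drop = FALSE]
    used_from <- used_to <- character(0)
    for (r in seq_len(nrow(cand))) {
      f <- as.character(cand$from[r]); t <- as.character(cand$to[r])
      if (f %in% used_from || t %in% used_to) next
      succ[f] <- cand$to[r]
      used_from <- c(used_from, f)
      used_to <- c(used_to, t)
    }
  }
  # resolve chains into final track ids
  has_pred <- as.integer(succ)
  roots <- ids[!(ids %in% has_pred)]
  track_of <- integer(0)
  tid <- 0L
  for (r in roots) {
    tid <- tid + 1L
    cur <- r
    repeat {
      track_of[as.character(cur)] <- tid
      nxt <- succ[as.character(cur)]
      if (is.na(nxt) || length(nxt) == 0) break
      cur <- nxt
    }
  }
  spots$track_id <- track_of[as.character(spots$tracklet)]
  out <- spots[!is.na(spots$track_id),
               c("track_id", "frame", "x", "y",
                 intersect("quality", names(spots)))]
  if (interpolate) {
    filled <- lapply(split(out, out$track_id), function(s) {
      s <- s[order(s$frame), ]
      full <- min(s$frame):max(s$frame)
      miss <- setdiff(full, s$frame)
      if (length(miss)) {
        xi <- stats::approx(s$frame, s$x, xout = miss)$y
        yi <- stats::approx(s$frame, s$y, xout = miss)$y
        add <- data.frame(track_id = s$track_id[1], frame = miss,
                          x = xi, y = yi)
        if ("quality" %in% names(s)) add$quality <- 0
        s <- rbind(s, add)
      }
      s[order(s$frame), ]
    })
    out <- do.call(rbind, filled)
  }
  track_set(out, acquisition_info(frame_interval = frame_interval))
}

#' Track a movie end to end
#'
#' [detect_movie()] + [link_frames()] + [close_gaps()] with the default
#' published parameter set.
#'
#' @param stack List of frame matrices or 3-D array.
#' @param dp,lp Detection and linking parameters.
#' @param frame_interval Seconds between frames.
#' @param interpolate Passed to [close_gaps()].
#' @return A [track_set()].
#' @export
track_movie <- function(stack, dp = detection_params(), lp = linking_params(),
                        frame_interval = 10, interpolate = FALSE) {
  spots <- detect_movie(stack, dp, frame_interval)
  linked <- link_frames(spots, lp)
  close_gaps(linked, lp, frame_interval, interpolate)
}

#' Compare computed tracks with ground truth
#'
#' A truth track counts as recovered complete when one computed track matches
#' it at every truth frame within `tol`. Reports the recovered fraction and
#' the mean position error over matched spots.
#'
#' @param computed,truth `track_set` objects on the same frame range.
#' @param tol Matching tolerance, um.
#' @return List `n_truth_tracks`, `n_recovered_complete`, `recovery_fraction`,
#'   `mean_position_error` (um; `NA` when nothing matched).
#' @export
evaluate_tracking <- function(computed, truth, tol = 1) {
  tr_truth <- tracks(truth)
  tr_comp <- tracks(computed)
  n_rec <- 0L
  errs <- numeric(0)
  for (tt in tr_truth) {
    best <- NULL
    best_err <- Inf
    for (tc in tr_comp) {
      common <- match(tt$frame, tc$frame)
      if (anyNA(common)) next
      d <- sqrt((tt$x - tc$x[common])^2 + (tt$y - tc$y[common])^2)
      if (all(d <= tol) && mean(d) < best_err) {
        best <- d
        best_err <- mean(d)
      }
    }
    if (!is.null(best)) {
      n_rec <- n_rec + 1L
      errs <- c(errs, best)
    }
  }
  list(n_truth_tracks = length(tr_truth),
       n_recovered_complete = n_rec,
       recovery_fraction = if (length(tr_truth)) n_rec / length(tr_truth) else NA_real_,
       mean_position_error = if (length(errs)) mean(errs) else NA_real_)
}
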