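# Vesicle-dispersion scoring of single-cell crops. The cell is segmented on
# a working copy (contrast stretch, Gaussian blur sigma = 2 px, Huang
# threshold, largest component); scoring then runs on the raw intensities
# with one of two procedures, both ending in the per-cell median of all
# mutual locus distances (micrometers):
#   grid   - tile the mask bounding box into square regions, median intensity
#            per square, positive when >= positivity_factor x the minimum
#            square median of that cell, loci = positive-square centroids;
#   maxima - local maxima inside the mask with prominence above a cutoff.

#' Grid-scoring parameters
#'
#' @param square_px Square edge, pixels (3 by default; at 0.1626 um/px a
#'   3 x 3 square covers 0.238 um^2).
#' @param positivity_factor A square is vesicle-positive when its median
#'   intensity is at least this factor times the per-cell minimum square
#'   median (2 by default).
#' @param min_positive_squares Minimum positive squares for a score.
#' @param inclusion Which squares of the bounding-box tiling belong to the
#'   cell: `"full"` (default) keeps squares lying entirely inside the mask,
#'   `"center"` keeps squares whose center pixel is inside. The full rule
#'   keeps boundary squares that straddle the cell edge — and whose median is
#'   dominated by background — out of the per-cell minimum that anchors the
#'   positivity threshold.
#' @return List of class `grid_params`.
#' @export
grid_params <- function(square_px = 3, positivity_factor = 2,
                        min_positive_squares = 2,
                        inclusion = c("full", "center")) {
  inclusion <- match.arg(inclusion)
  stopifnot(square_px >= 1, positivity_factor > 1, min_positive_squares >= 2)
  structure(list(square_px = as.integer(square_px),
                 positivity_factor = positivity_factor,
                 min_positive_squares = as.integer(min_positive_squares),
                 inclusion = inclusion),
            class = "grid_params")
}

#' Maxima-scoring parameters
#'
#' @param prominence Minimum prominence (intensity units of the stored bit
#'   depth) of a retained maximum; 200 by default, on the 16-bit scale of the
#'   acquisitions it was tuned on — scale it down for 8-bit data.
#' @param min_maxima Minimum number of maxima for a score.
#' @return List of class `maxima_params`.
#' @export
maxima_params <- function(prominence = 200, min_maxima = 2) {
  stopifnot(prominence > 0, min_maxima >= 2)
  structure(list(prominence = prominence, min_maxima = as.integer(min_maxima)),
            class = "maxima_params")
}

#' Huang fuzzy threshold of an intensity histogram
#'
#' Selects the threshold minimizing the Huang-Wang measure of fuzziness: for
#' each candidate cut, pixels are given a membership to their side's mean
#' intensity, `u(g) = 1 / (1 + |g - mu_side| / C)` with C the intensity
#' range, and the Shannon entropy of the memberships is minimized. The search
#' is exhaustive over all candidate cuts with non-empty sides; ties go to the
#' lower level. The background/foreground partition is `g <= threshold` vs
#' `g > threshold`.
#'
#' @param counts Histogram counts per level.
#' @param levels Intensity value of each bin (defaults to `0:(length-1)`).
#' @return The threshold level.
#' @export
huang_threshold <- function(counts, levels = seq_along(counts) - 1) {
  stopifnot(length(counts) == length(levels), all(counts >= 0))
  occ <- which(counts > 0)
  if (length(occ) < 2 || length(unique(levels[occ])) < 2)
    stop("degenerate input: histogram needs >= 2 distinct occupied levels")
  first <- occ[1]; last <- occ[length(occ)]
  C <- levels[last] - levels[first]
  cw <- cumsum(counts)
  cwx <- cumsum(counts * levels)
  total_w <- cw[length(counts)]
  total_wx <- cwx[length(counts)]
  best_E <- Inf
  best_t <- levels[first]
  shannon <- function(u) {
    s <- numeric(length(u))
    ok <- u > 0 & u < 1
    s[ok] <- -u[ok] * log(u[ok]) - (1 - u[ok]) * log(1 - u[ok])
    s
  }
  for (ti in first:(last - 1)) {
    w0 <- cw[ti]
    if (w0 == 0 || w0 == total_w) next
    mu0 <- cwx[ti] / w0
    mu1 <- (total_wx - cwx[ti]) / (total_w - w0)
    i0 <- 1:ti
    i1 <- (ti + 1):length(counts)
    u0 <- 1 / (1 + abs(levels[i0] - mu0) / C)
    u1 <- 1 / (1 + abs(levels[i1] - mu1) / C)
    E <- sum(counts[i0] * shannon(u0)) + sum(counts[i1] * shannon(u1))
    if (E < best_E - 1e-12) {
      best_E <- E
      best_t <- levels[ti]
    }
  }
  best_t
}

#' Segment a single cell from a crop
#'
#' Working-copy pipeline: linear contrast stretch saturating
#' `saturate_frac` of the pixels, Gaussian blur (sigma = 2 px), Huang
#' threshold, and the largest connected foreground component as the cell
#' mask. The raw image is left untouched for scoring. Masks touching the
#' image border are flagged (cells in contact with the edge or with other
#' cells are excluded from analysis).
#'
#' @param img Numeric intensity matrix.
#' @param sigma Blur SD in pixels.
#' @param saturate_frac Total fraction of pixels saturated by the stretch
#'   (half per tail).
#' @return List of class `cell_mask`: `mask` (logical matrix), `status`
#'   (`"ok"` or `"segmentation_failed"`), `touches_border`, `threshold`
#'   (on the stretched 0-255 scale).
#' @export
segment_cell <- function(img, sigma = 2, saturate_frac = 0.0035) {
  stopifnot(is.matrix(img))
  fail <- function() structure(list(mask = matrix(FALSE, nrow(img), ncol(img)),
                                    status = "segmentation_failed",
                                    touches_border = FALSE,
                                    threshold = NA_real_),
                               class = "cell_mask")
  if (diff(range(img)) == 0) return(fail())
  q <- stats::quantile(img, c(saturate_frac / 2, 1 - saturate_frac / 2),
                       names = FALSE)
  if (q[2] <= q[1]) q <- range(img)
  work <- pmin(pmax((img - q[1]) / (q[2] - q[1]), 0), 1) * 255
  kern_r <- 2 * ceiling(3 * sigma) + 1
  brush <- EBImage::makeBrush(kern_r, shape = "gaussian", sigma = sigma)
  work <- EBImage::filter2(work, brush, boundary = "replicate")
  h <- graphics::hist(work, breaks = seq(-0.5, 255.5, by = 1), plot = FALSE)
  thr <- tryCatch(huang_threshold(h$counts, 0:255),
                  error = function(e) NA_real_)
  if (is.na(thr)) return(fail())
  fg <- work > thr
  if (!any(fg)) return(fail())
  lab <- EBImage::bwlabel(EBImage::Image(fg * 1))
  lab <- EBImage::imageData(lab)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  mask <- lab == keep
  border <- any(mask[1, ]) || any(mask[nrow(mask), ]) ||
    any(mask[, 1]) || any(mask[, ncol(mask)])
  structure(list(mask = mask, status = "ok", touches_border = border,
                 threshold = thr),
            class = "cell_mask")
}

#' Median of all mutual pairwise distances of loci
#'
#' @param loci Two-column matrix or data frame of locus coordinates (um).
#' @return Median pairwise Euclidean distance; `NA` for fewer than 2 loci.
#' @export
median_pairwise_distance <- function(loci) {
  loci <- as.matrix(loci)
  if (nrow(loci) < 2) return(NA_real_)
  stats::median(stats::dist(loci))
}

dispersion_score_row <- function(cell_id, method, score, n_loci, status) {
  data.frame(cell_id = cell_id, method = method,
             median_pairwise_distance = score, n_loci = n_loci,
             status = status, stringsAsFactors = FALSE)
}

#' Grid dispersion score of one cell
#'
#' Tiles the mask's bounding box into `square_px`-sized squares, keeps the
#' squares belonging to the cell (see the `inclusion` rule of
#' [grid_params()]), takes each square's
#' median raw intensity, and marks squares positive when their median is at
#' least `positivity_factor` times the per-cell minimum square median. The
#' score is the median of all mutual distances between positive-square
#' centroids (square centers, converted to micrometers).
#'
#' @param img Raw intensity matrix (unprocessed copy).
#' @param mask A `cell_mask` from [segment_cell()] (or a logical matrix).
#' @param p A [grid_params()] object.
#' @param pixel_size Pixel size, um/px.
#' @param cell_id Label for the output row.
#' @return One-row data frame: `cell_id`, `method`, `median_pairwise_distance`
#'   (um), `n_loci`, `status` (`ok`, `too_few_loci` or `segmentation_failed`).
#' @export
grid_dispersion_score <- function(img, mask, p = grid_params(),
                                  pixel_size = 0.1626, cell_id = "cell") {
  if (inherits(mask, "cell_mask")) {
    if (mask$status != "ok")
      return(dispersion_score_row(cell_id, "grid", NA_real_, 0L,
                                  "segmentation_failed"))
    mask <- mask$mask
  }
  stopifnot(is.matrix(img), identical(dim(img), dim(mask)))
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  sq <- p$square_px
  centers <- NULL
  meds <- numeric(0)
  r0 <- rows[1]
  while (r0 + sq - 1 <= rows[2]) {
    c0 <- cols[1]
    while (c0 + sq - 1 <= cols[2]) {
      rr <- r0:(r0 + sq - 1)
      cc_rng <- c0:(c0 + sq - 1)
      keep <- if (p$inclusion == "full") {
        all(mask[rr, cc_rng])
      } else {
        # center pixel of the square (geometric center rounds down)
        mask[r0 + (sq - 1) %/% 2, c0 + (sq - 1) %/% 2]
      }
      if (keep) {
        meds <- c(meds, stats::median(img[rr, cc_rng]))
        centers <- rbind(centers, c(r0 + (sq - 1) / 2, c0 + (sq - 1) / 2))
      }
      c0 <- c0 + sq
    }
    r0 <- r0 + sq
  }
  if (!length(meds))
    return(dispersion_score_row(cell_id, "grid", NA_real_, 0L, "too_few_loci"))
  thr <- p$positivity_factor * min(meds)
  pos <- meds >= thr
  n <- sum(pos)
  if (n < p$min_positive_squares)
    return(dispersion_score_row(cell_id, "grid", NA_real_, as.integer(n),
                                "too_few_loci"))
  loci <- cbind(x = (centers[pos, 2] - 0.5) * pixel_size,
                y = (centers[pos, 1] - 0.5) * pixel_size)
  dispersion_score_row(cell_id, "grid", median_pairwise_distance(loci),
                       as.integer(n), "ok")
}

# Prominence of every local maximum by descending flood with union-find:
# processing pixels from bright to dim, a component dies when it merges into
# one with a higher peak; its prominence is peak - merge level. The highest
# peak of each connected region gets peak - (lowest level of the region).
maxima_prominence <- function(img, mask) {
  nr <- nrow(img); nc <- ncol(img)
  idx <- which(mask)
  if (!length(idx)) {
    return(data.frame(row = numeric(0), col = numeric(0),
                      value = numeric(0), prominence = numeric(0)))
  }
  ord <- idx[order(img[idx], decreasing = TRUE)]
  parent <- integer(nr * nc)           # 0 = unprocessed
  peak_val <- numeric(nr * nc)
  peak_id <- integer(nr * nc)          # representative pixel of the peak
  prom <- numeric(0)                   # by peak pixel (character index)
  plateau <- list()
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) {
      nxt <- parent[i]
      parent[i] <<- root
      i <- nxt
    }
    root
  }
  died <- character(0)
  for (pix in ord) {
    r <- (pix - 1L) %% nr + 1L
    c <- (pix - 1L) %/% nr + 1L
    v <- img[pix]
    nbr_roots <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
      q <- (cc - 1L) * nr + rr
      if (parent[q] != 0) nbr_roots <- c(nbr_roots, find(q))
    }
    nbr_roots <- unique(nbr_roots)
    if (!length(nbr_roots)) {
      parent[pix] <- pix
      peak_val[pix] <- v
      peak_id[pix] <- pix
      plateau[[as.character(pix)]] <- pix
    } else {
      # attach to the neighbor component with the highest peak
      main <- nbr_roots[which.max(peak_val[nbr_roots])]
      parent[pix] <- main
      if (v == peak_val[main] && length(nbr_roots) == 1) {
        # extends the summit plateau of its component
        key <- as.character(peak_id[main])
        plateau[[key]] <- c(plateau[[key]], pix)
      }
      for (other in nbr_roots) {
        if (other == main) next
        # component 'other' merges at level v and dies
        key <- as.character(peak_id[other])
        prom[key] <- peak_val[other] - v
        died <- c(died, key)
        parent[other] <- main
      }
    }
  }
  # surviving components: prominence relative to the lowest masked level
  roots <- unique(vapply(idx[parent[idx] != 0], find, integer(1)))
  vmin <- min(img[idx])
  for (rt in roots) {
    key <- as.character(peak_id[rt])
    if (!key %in% names(prom)) prom[key] <- peak_val[rt] - vmin
  }
  peaks <- as.integer(names(prom))
  out <- data.frame(
    row = vapply(as.character(peaks), function(k) mean((plateau[[k]] - 1) %% nr + 1), numeric(1)),
    col = vapply(as.character(peaks), function(k) mean((plateau[[k]] - 1) %/% nr + 1), numeric(1)),
    value = img[peaks],
    prominence = unname(prom)
  )
  rownames(out) <- NULL
  out
}

#' Find prominence-filtered local maxima inside a cell
#'
#' Local maxima of the raw image within the mask whose prominence — height
#' above the highest saddle connecting them to any higher maximum — exceeds
#' `p$prominence`. A connected summit plateau yields one locus at its
#' centroid.
#'
#' @param img Raw intensity matrix.
#' @param mask `cell_mask` or logical matrix.
#' @param p A [maxima_params()] object.
#' @param pixel_size Pixel size, um/px.
#' @return Data frame `x`, `y` (um), `value`, `prominence`; possibly empty.
#' @export
find_maxima <- function(img, mask, p = maxima_params(), pixel_size = 0.1626) {
  if (inherits(mask, "cell_mask")) {
    if (mask$status != "ok")
      return(data.frame(x = numeric(0), y = numeric(0), value = numeric(0),
                        prominence = numeric(0)))
    mask <- mask$mask
  }
  stopifnot(identical(dim(img), dim(mask)))
  pr <- maxima_prominence(img, mask)
  pr <- pr[pr$prominence > p$prominence, , drop = FALSE]
  data.frame(x = (pr$col - 0.5) * pixel_size,
             y = (pr$row - 0.5) * pixel_size,
             value = pr$value, prominence = pr$prominence)
}

#' Maxima dispersion score of one cell
#'
#' Median of all mutual distances between prominence-filtered maxima.
#'
#' @inheritParams find_maxima
#' @param cell_id Label for the output row.
#' @return One-row data frame as in [grid_dispersion_score()], method
#'   `"maxima"`.
#' @export
maxima_dispersion_score <- function(img, mask, p = maxima_params(),
                                    pixel_size = 0.1626, cell_id = "cell") {
  if (inherits(mask, "cell_mask") && mask$status != "ok")
    return(dispersion_score_row(cell_id, "maxima", NA_real_, 0L,
                                "segmentation_failed"))
  loci <- find_maxima(img, mask, p, pixel_size)
  n <- nrow(loci)
  if (n < p$min_maxima)
    return(dispersion_score_row(cell_id, "maxima", NA_real_, as.integer(n),
                                "too_few_loci"))
  dispersion_score_row(cell_id, "maxima",
                       median_pairwise_distance(loci[, c("x", "y")]),
                       as.integer(n), "ok")
}

#' Score a batch of single-cell crops
#'
#' Segments each crop and applies the requested scoring method(s). Crops
#' whose mask fails or touches the image border are excluded (status
#' `segmentation_failed` / `border`), matching the practice of dropping
#' edge- and contact-cells; exclusions stay in the output table with their
#' reason and `NA` score.
#'
#' @param crops Named list of intensity matrices (one cell per crop).
#' @param method `"grid"`, `"maxima"`, or both.
#' @param gp,mp Grid and maxima parameters.
#' @param pixel_size Pixel size, um/px.
#' @return Data frame of per-cell, per-method score rows.
#' @export
batch_score <- function(crops, method = c("grid", "maxima"),
                        gp = grid_params(), mp = maxima_params(),
                        pixel_size = 0.1626) {
  method <- match.arg(method, several.ok = TRUE)
  if (is.null(names(crops)))
    names(crops) <- sprintf("cell_%03d", seq_along(crops))
  rows <- lapply(names(crops), function(id) {
    img <- crops[[id]]
    seg <- segment_cell(img)
    per_method <- lapply(method, function(m) {
      if (seg$status != "ok")
        return(dispersion_score_row(id, m, NA_real_, 0L, "segmentation_failed"))
      if (seg$touches_border)
        return(dispersion_score_row(id, m, NA_real_, 0L, "border"))
      if (m == "grid") grid_dispersion_score(img, seg, gp, pixel_size, id)
      else maxima_dispersion_score(img, seg, mp, pixel_size, id)
    })
    do.call(rbind, per_method)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
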