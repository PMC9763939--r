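# Synthetic microscopy renderers with known ground truth. Nuclei and
# vesicles are rendered as 2-D Gaussians sampled at pixel centers
# ((i - 0.5) * pixel_size), over a constant background with additive
# Gaussian noise, on a 16-bit intensity scale.

#' Movie rendering parameters
#'
#' Defaults emulate widefield nucleus-stain acquisitions: a 512 px field at
#' 0.65 um/px, nuclei of ~5 um Gaussian SD footprint, amplitude 1000 counts
#' over a 200-count background with noise SD 100 (peak SNR 10).
#'
#' @param image_size Field edge, pixels (square field).
#' @param pixel_size um/px.
#' @param nucleus_sigma Gaussian SD of a rendered nucleus, pixels.
#' @param peak_intensity Peak amplitude added above background, counts.
#' @param background Constant background level, counts.
#' @param noise_sd Gaussian noise SD, counts.
#' @return List of class `render_params`.
#' @export
render_params <- function(image_size = 512, pixel_size = 0.65,
                          nucleus_sigma = 4, peak_intensity = 1000,
                          background = 200, noise_sd = 100) {
  stopifnot(image_size >= 16, pixel_size > 0, nucleus_sigma > 0,
            peak_intensity > 0, background >= 0, noise_sd >= 0)
  structure(list(image_size = as.integer(image_size), pixel_size = pixel_size,
                 nucleus_sigma = nucleus_sigma,
                 peak_intensity = peak_intensity, background = background,
                 noise_sd = noise_sd),
            class = "render_params")
}

add_gaussian_spot <- function(img, row0, col0, sigma, amp) {
  nr <- nrow(img); nc <- ncol(img)
  r <- ceiling(4 * sigma)
  r_lo <- max(1, floor(row0 - r)); r_hi <- min(nr, ceiling(row0 + r))
  c_lo <- max(1, floor(col0 - r)); c_hi <- min(nc, ceiling(col0 + r))
  if (r_lo > r_hi || c_lo > c_hi) return(img)  # spot entirely off-frame
  rows <- r_lo:r_hi
  cols <- c_lo:c_hi
  dr2 <- (rows - row0)^2
  dc2 <- (cols - col0)^2
  img[rows, cols] <- img[rows, cols] +
    amp * exp(-outer(dr2, dc2, "+") / (2 * sigma^2))
  img
}

#' Render a nucleus movie from ground-truth tracks
#'
#' Each track's nucleus is drawn per frame as a 2-D Gaussian at its true
#' position; background and Gaussian noise are added and intensities clamped
#' to the 16-bit range. Deterministic given `seed`.
#'
#' @param truth A `track_set` with positions in micrometers; every spot must
#'   lie inside the field.
#' @param p A [render_params()] object.
#' @param seed Integer seed for the noise.
#' @return List with `stack` (list of frame matrices) and `truth` (the input
#'   track set).
#' @export
render_movie <- function(truth, p = render_params(), seed = 1) {
  stopifnot(inherits(truth, "track_set"))
  fov <- p$image_size * p$pixel_size
  sp <- truth$spots
  if (any(sp$x < 0 | sp$x > fov | sp$y < 0 | sp$y > fov))
    stop("track leaves the field of view (", fov, " um)")
  set.seed(seed)
  frames <- sort(unique(sp$frame))
  stack <- lapply(frames, function(f) {
    img <- matrix(p$background, p$image_size, p$image_size)
    here <- sp[sp$frame == f, ]
    for (i in seq_len(nrow(here))) {
      img <- add_gaussian_spot(img, here$y[i] / p$pixel_size + 0.5,
                               here$x[i] / p$pixel_size + 0.5,
                               p$nucleus_sigma, p$peak_intensity)
    }
    if (p$noise_sd > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, p$noise_sd),
                          nrow(img), ncol(img))
    matrix(pmin(pmax(round(img), 0), 65535), nrow(img), ncol(img))
  })
  list(stack = stack, truth = truth)
}

#' Simulate a well-separated multi-cell movie scene
#'
#' Draws persistent-random-walk tracks started on a jittered grid and
#' redraws any track that leaves the field margin or comes closer than
#' `min_separation` to an already accepted track at any frame, so the scene
#' stays resolvable by single-particle tracking. Deterministic given `seed`.
#'
#' @param n_cells Number of cells.
#' @param p A [prw_params()] object.
#' @param rp A [render_params()] object (defines the field).
#' @param min_separation Minimum inter-cell distance at every frame, um.
#' @param margin Margin kept free at the field edge, um.
#' @param seed Integer seed.
#' @param max_tries Redraw attempts per cell before giving up.
#' @return A `track_set` of ground-truth tracks inside the field.
#' @export
simulate_movie_scene <- function(n_cells = 20, p = prw_params(),
                                 rp = render_params(), min_separation = 20,
                                 margin = 25, seed = 1, max_tries = 500) {
  fov <- rp$image_size * rp$pixel_size
  set.seed(seed)
  ncol_grid <- ceiling(sqrt(n_cells))
  nrow_grid <- ceiling(n_cells / ncol_grid)
  grid_pos <- function(n) {
    if (n == 1) return((margin + fov - margin) / 2)
    seq(margin, fov - margin, length.out = n)
  }
  gx <- grid_pos(ncol_grid)
  gy <- grid_pos(nrow_grid)
  starts <- expand.grid(x = gx, y = gy)[seq_len(n_cells), ]
  accepted <- list()
  for (i in seq_len(n_cells)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      jit <- stats::rnorm(2, 0, 2)
      tr <- simulate_prw_track(p, track_id = i,
                               start = c(starts$x[i] + jit[1],
                                         starts$y[i] + jit[2]))
      if (any(tr$x < margin / 2 | tr$x > fov - margin / 2 |
              tr$y < margin / 2 | tr$y > fov - margin / 2)) next
      clash <- FALSE
      for (other in accepted) {
        if (min(sqrt((tr$x - other$x)^2 + (tr$y - other$y)^2)) < min_separation) {
          clash <- TRUE
          break
        }
      }
      if (!clash) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place cell ", i, " without collisions")
    accepted[[i]] <- tr
  }
  track_set(do.call(rbind, accepted),
            acquisition_info(frame_interval = p$frame_interval,
                             n_frames = p$n_frames,
                             pixel_size = rp$pixel_size))
}

#' Vesicle-scene parameters
#'
#' Defaults emulate single-cell membrane-stain crops at 40x: a 128 px crop at
#' 0.1626 um/px, an elliptical cell of ~6 um radius with diffuse cytoplasmic
#' signal, and punctate vesicles either spread through the cytoplasm
#' (dispersed) or packed into a polar cap at the uropod (polarized).
#'
#' @param image_size Crop edge, pixels.
#' @param pixel_size um/px.
#' @param cell_radius Major semi-axis of the cell, um.
#' @param axis_ratio Minor/major axis ratio.
#' @param n_vesicles Number of vesicles.
#' @param mode `"polarized"` or `"dispersed"`.
#' @param cap_fraction Fraction of the cell area forming the uropod cap that
#'   holds the vesicles in polarized mode.
#' @param vesicle_sigma Gaussian SD of a vesicle, pixels.
#' @param vesicle_peak Vesicle peak amplitude above local signal, counts.
#' @param cytoplasm Diffuse intensity inside the cell, counts.
#' @param background Background level, counts.
#' @param noise_sd Gaussian noise SD, counts.
#' @return List of class `vesicle_scene_params`.
#' @export
vesicle_scene_params <- function(image_size = 128, pixel_size = 0.1626,
                                 cell_radius = 6, axis_ratio = 0.75,
                                 n_vesicles = 12,
                                 mode = c("dispersed", "polarized"),
                                 cap_fraction = 0.2, vesicle_sigma = 1.3,
                                 vesicle_peak = 800, cytoplasm = 250,
                                 background = 150, noise_sd = 25) {
  mode <- match.arg(mode)
  stopifnot(image_size >= 32, pixel_size > 0, cell_radius > 0,
            axis_ratio > 0, axis_ratio <= 1, n_vesicles >= 0,
            cap_fraction > 0, cap_fraction < 1, vesicle_sigma > 0,
            vesicle_peak > 0, noise_sd >= 0)
  structure(list(image_size = as.integer(image_size), pixel_size = pixel_size,
                 cell_radius = cell_radius, axis_ratio = axis_ratio,
                 n_vesicles = as.integer(n_vesicles), mode = mode,
                 cap_fraction = cap_fraction, vesicle_sigma = vesicle_sigma,
                 vesicle_peak = vesicle_peak, cytoplasm = cytoplasm,
                 background = background, noise_sd = noise_sd),
            class = "vesicle_scene_params")
}

# x-cut (as a fraction of the semi-axis) so that the cap {u > t} holds
# cap_fraction of the ellipse area (area fractions are invariant under the
# axis scaling, so the unit circle formula applies)
cap_cut <- function(cap_fraction) {
  f <- function(t) (acos(t) - t * sqrt(1 - t^2)) / pi - cap_fraction
  stats::uniroot(f, c(-1 + 1e-9, 1 - 1e-9))$root
}

#' Render a single-cell vesicle scene
#'
#' Elliptical cell of diffuse intensity over background, plus `n_vesicles`
#' Gaussian puncta at positions drawn uniformly over the cytoplasm
#' (`dispersed`) or uniformly over a polar cap holding `cap_fraction` of the
#' cell area (`polarized`, emulating uropod accumulation). Returns the image
#' and the true vesicle coordinates. Deterministic given `seed`.
#'
#' @param p A [vesicle_scene_params()] object.
#' @param seed Integer seed.
#' @param center Cell center in pixels; default is the crop center.
#' @return List `image` (matrix), `truth` (data frame `x`, `y` in um),
#'   `params`.
#' @export
render_vesicle_cell <- function(p = vesicle_scene_params(), seed = 1,
                                center = NULL) {
  set.seed(seed)
  n <- p$image_size
  a <- p$cell_radius / p$pixel_size            # major semi-axis, px
  b <- a * p$axis_ratio
  if (is.null(center)) center <- c(n / 2, n / 2)  # (col, row), px
  # cell body
  cols <- matrix(seq_len(n) - 0.5, n, n, byrow = TRUE)
  rows <- matrix(seq_len(n) - 0.5, n, n)
  inside <- ((cols - center[1]) / a)^2 + ((rows - center[2]) / b)^2 <= 1
  img <- matrix(p$background, n, n)
  img[inside] <- p$cytoplasm
  # sub-pixel edge softening only: the diffuse internalized stain fills the
  # cell as a plateau with a sharp roll-off at the membrane
  img <- EBImage::filter2(img, EBImage::makeBrush(3, "gaussian", sigma = 0.5),
                          boundary = "replicate")
  # vesicle positions: uniform over ellipse or over the +x polar cap
  tcut <- if (p$mode == "polarized") cap_cut(p$cap_fraction) else -2
  pts <- matrix(NA_real_, 0, 2)
  while (nrow(pts) < p$n_vesicles) {
    u <- stats::runif(2, -1, 1)
    if (sum(u^2) > 1) next
    if (u[1] <= tcut) next
    pts <- rbind(pts, u)
  }
  truth <- data.frame(x = numeric(0), y = numeric(0))
  if (p$n_vesicles > 0) {
    px_col <- center[1] + pts[, 1] * a
    px_row <- center[2] + pts[, 2] * b
    for (i in seq_len(nrow(pts))) {
      # +0.5 converts physical px coordinates to matrix index units
      img <- add_gaussian_spot(img, px_row[i] + 0.5, px_col[i] + 0.5,
                               p$vesicle_sigma, p$vesicle_peak)
    }
    truth <- data.frame(x = px_col * p$pixel_size, y = px_row * p$pixel_size)
  }
  if (p$noise_sd > 0)
    img <- img + matrix(stats::rnorm(n * n, 0, p$noise_sd), n, n)
  img <- matrix(pmin(pmax(round(img), 0), 65535), n, n)
  list(image = img, truth = truth, params = p)
}

#' Write an image stack as multi-page TIFF
#'
#' @param stack List of matrices on a 16-bit scale.
#' @param path Output TIFF path.
#' @export
write_stack_tiff <- function(stack, path) {
  if (is.matrix(stack)) stack <- list(stack)
  tiff::writeTIFF(lapply(stack, function(m) m / 65535), path,
                  bits.per.sample = 16L)
  invisible(NULL)
}

#' Read a single-channel TIFF (stack) into matrices on the 16-bit scale
#'
#' @param path TIFF path.
#' @return List of numeric matrices scaled to 0..65535.
#' @export
read_stack_tiff <- function(path) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  lapply(imgs, function(m) {
    if (length(dim(m)) == 3) m <- m[, , 1]
    m * 65535
  })
}
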