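disk_image <- function(size = 128, radius = 40, center = c(64, 64),
                       fg = 200, bg = 20, noise = 10, seed = 1) {
  set.seed(seed)
  cols <- matrix(seq_len(size) - 0.5, size, size, byrow = TRUE)
  rows <- matrix(seq_len(size) - 0.5, size, size)
  inside <- (cols - center[1])^2 + (rows - center[2])^2 <= radius^2
  img <- matrix(bg, size, size)
  img[inside] <- fg
  img + matrix(rnorm(size^2, 0, noise), size, size)
}

test_that("Huang threshold separates a two-level histogram and ignores padding", {
  counts <- numeric(256)
  counts[10 + 1] <- 500
  counts[200 + 1] <- 300
  thr <- huang_threshold(counts, 0:255)
  expect_gte(thr, 10)
  expect_lt(thr, 200)
  # the cut separates the two populations: only level 200 is foreground
  expect_true(all(c(10) <= thr) && all(c(200) > thr))

  # padding with empty bins leaves the threshold unchanged
  padded <- c(numeric(50), counts, numeric(50))
  expect_equal(huang_threshold(padded, -50:305), thr)

  expect_error(huang_threshold(c(0, 5, 0), 0:2), "degenerate")
})

test_that("Huang threshold equals exhaustive fuzziness minimization", {
  set.seed(20)
  for (i in 1:50) {
    mu <- sort(sample(20:235, 2))
    counts <- numeric(256)
    a <- round(500 * exp(-((0:255) - mu[1])^2 / (2 * runif(1, 3, 15)^2)))
    b <- round(300 * exp(-((0:255) - mu[2])^2 / (2 * runif(1, 3, 15)^2)))
    counts <- a + b + rpois(256, 0.5)
    thr <- huang_threshold(counts, 0:255)
    expect_equal(thr, o_huang_threshold(counts, 0:255))
  }
})

test_that("cell segmentation recovers a disk and flags degenerate inputs", {
  img <- disk_image()
  seg <- segment_cell(img)
  expect_equal(seg$status, "ok")
  expect_false(seg$touches_border)
  cols <- matrix(seq_len(128) - 0.5, 128, 128, byrow = TRUE)
  rows <- matrix(seq_len(128) - 0.5, 128, 128)
  truth <- (cols - 64)^2 + (rows - 64)^2 <= 40^2
  iou <- sum(seg$mask & truth) / sum(seg$mask | truth)
  expect_gte(iou, 0.95)

  expect_equal(segment_cell(matrix(7, 32, 32))$status, "segmentation_failed")

  border <- disk_image(center = c(10, 64))
  segb <- segment_cell(border)
  expect_equal(segb$status, "ok")
  expect_true(segb$touches_border)
})

test_that("grid score reproduces hand-computed square layouts", {
  # 1-px squares: two bright pixels 10 px apart -> 10 * 0.1626 um
  img <- matrix(10, 20, 20)
  img[5, 4] <- 100
  img[5, 14] <- 100
  mask <- matrix(TRUE, 20, 20)
  sc <- grid_dispersion_score(img, mask, grid_params(square_px = 1),
                              pixel_size = 0.1626)
  expect_equal(sc$status, "ok")
  expect_equal(sc$n_loci, 2L)
  expect_equal(sc$median_pairwise_distance, 1.626, tolerance = 1e-9)

  # 3-px squares: bright squares with centroids 9 px apart
  img3 <- matrix(10, 9, 33)
  img3[4:6, 1:3] <- 100
  img3[4:6, 10:12] <- 100
  mask3 <- matrix(FALSE, 9, 33)
  mask3[4:6, ] <- TRUE
  sc3 <- grid_dispersion_score(img3, mask3, grid_params(square_px = 3),
                               pixel_size = 0.1626)
  expect_equal(sc3$n_loci, 2L)
  expect_equal(sc3$median_pairwise_distance, 9 * 0.1626, tolerance = 1e-9)

  # a single positive square cannot yield distances
  img1 <- matrix(10, 9, 33)
  img1[4:6, 1:3] <- 100
  sc1 <- grid_dispersion_score(img1, mask3, grid_params(square_px = 3))
  expect_equal(sc1$status, "too_few_loci")
  expect_true(is.na(sc1$median_pairwise_distance))
})

test_that("grid score is invariant to intensity scaling and grid-aligned shifts", {
  sc0 <- render_vesicle_cell(vesicle_scene_params(noise_sd = 0), seed = 5)
  seg <- segment_cell(sc0$image)
  base <- grid_dispersion_score(sc0$image, seg)
  scaled <- grid_dispersion_score(sc0$image * 2, seg)
  expect_equal(scaled$median_pairwise_distance, base$median_pairwise_distance)
  expect_equal(scaled$n_loci, base$n_loci)

  # translations leave the score unchanged up to one grid quantization step
  # (segmentation can flip isolated threshold-grazing mask pixels, so even
  # square-aligned shifts are not bit-exact)
  sc_s <- render_vesicle_cell(vesicle_scene_params(noise_sd = 0), seed = 5,
                              center = c(64 + 6, 64 + 6))
  shifted <- grid_dispersion_score(sc_s$image, segment_cell(sc_s$image))
  expect_lt(abs(shifted$median_pairwise_distance -
                  base$median_pairwise_distance), 3 * 0.1626 / sqrt(2))
  sc_a <- render_vesicle_cell(vesicle_scene_params(noise_sd = 0), seed = 5,
                              center = c(64 + 1, 64 + 2))
  arb <- grid_dispersion_score(sc_a$image, segment_cell(sc_a$image))
  expect_lt(abs(arb$median_pairwise_distance - base$median_pairwise_distance),
            3 * 0.1626 / sqrt(2))
})

test_that("prominence-filtered maxima match crafted peak/saddle layouts", {
  mk <- function(v) {
    img <- matrix(0, 5, length(v))
    img[3, ] <- v
    img
  }
  mask_all <- function(img) matrix(TRUE, nrow(img), ncol(img))

  # one Gaussian-like peak of amplitude 1000
  single <- mk(c(0, 100, 500, 1000, 500, 100, 0))
  fm <- find_maxima(single, mask_all(single), maxima_params(200),
                    pixel_size = 1)
  expect_equal(nrow(fm), 1)
  expect_equal(fm$x, 4 - 0.5)
  expect_equal(fm$value, 1000)

  # two peaks joined by a 300 saddle: both have prominence 700
  twin <- mk(c(10, 500, 1000, 500, 300, 300, 500, 1000, 500, 10))
  fm2 <- find_maxima(twin, mask_all(twin), maxima_params(200), pixel_size = 1)
  expect_equal(nrow(fm2), 2)
  # the dying twin peak keeps prominence 700 (height above the 300 saddle);
  # the surviving one is referenced to the image minimum (0)
  expect_equal(sort(fm2$prominence), c(700, 1000))

  # a secondary bump of prominence 150 is merged at threshold 200
  bump <- mk(c(10, 500, 1000, 500, 300, 450, 300, 500, 1000, 500, 10))
  fm3 <- find_maxima(bump, mask_all(bump), maxima_params(200), pixel_size = 1)
  expect_equal(nrow(fm3), 2)
  expect_false(any(abs(fm3$value - 450) < 1e-9))
  # ... but kept once the threshold admits it
  fm4 <- find_maxima(bump, mask_all(bump), maxima_params(100), pixel_size = 1)
  expect_equal(nrow(fm4), 3)
})

test_that("prominences equal the exhaustive saddle-search oracle", {
  set.seed(33)
  for (i in 1:8) {
    img <- matrix(sample(seq_len(144)), 12, 12)  # distinct values
    mask <- matrix(TRUE, 12, 12)
    mine <- migrquant:::maxima_prominence(img, mask)
    orc <- o_prominences(img)
    mine <- mine[order(mine$row, mine$col), ]
    orc <- orc[order(orc$row, orc$col), ]
    expect_equal(nrow(mine), nrow(orc))
    expect_equal(mine$row, orc$row)
    expect_equal(mine$col, orc$col)
    expect_equal(mine$prominence, orc$prominence)
  }
})

test_that("maxima dispersion score is the median of mutual locus distances", {
  expect_equal(median_pairwise_distance(cbind(c(0, 1, 2), c(0, 0, 0))), 1)
  expect_equal(median_pairwise_distance(cbind(c(0, 4), c(0, 0))), 4)
  expect_true(is.na(median_pairwise_distance(cbind(1, 1))))

  img <- matrix(0, 31, 31)
  img[16, 3] <- 1000
  img[16, 28] <- 1000
  sc <- maxima_dispersion_score(img, matrix(TRUE, 31, 31),
                                maxima_params(200), pixel_size = 0.16)
  expect_equal(sc$n_loci, 2L)
  expect_equal(sc$median_pairwise_distance, 25 * 0.16, tolerance = 1e-9)

  nothing <- maxima_dispersion_score(matrix(0, 16, 16), matrix(TRUE, 16, 16))
  expect_equal(nothing$status, "too_few_loci")
})

test_that("both scores are invariant under joint intensity/prominence scaling", {
  sc0 <- render_vesicle_cell(vesicle_scene_params(noise_sd = 0), seed = 6)
  seg <- segment_cell(sc0$image)
  m1 <- maxima_dispersion_score(sc0$image, seg, maxima_params(200))
  m2 <- maxima_dispersion_score(sc0$image * 2, seg, maxima_params(400))
  expect_equal(m2$median_pairwise_distance, m1$median_pairwise_distance)
  expect_equal(m2$n_loci, m1$n_loci)
})

test_that("maxima are translation-invariant and recover truth when separated", {
  p <- vesicle_scene_params(n_vesicles = 8, noise_sd = 0)
  # fixed seed whose truth spots are pairwise well separated
  sc <- render_vesicle_cell(p, seed = 1)
  sep_px <- min(dist(as.matrix(sc$truth) / p$pixel_size))
  expect_gte(sep_px, 3)
  seg <- segment_cell(sc$image)
  m <- maxima_dispersion_score(sc$image, seg)
  truth_med <- median_pairwise_distance(sc$truth)
  expect_lt(abs(m$median_pairwise_distance - truth_med) / truth_med, 0.15)

  # whole-pixel translation moves the loci exactly
  img_t <- matrix(150, 128, 128)
  img_t[4:128, 6:128] <- sc$image[1:125, 1:123]
  m_t <- maxima_dispersion_score(img_t, segment_cell(img_t))
  expect_equal(m_t$median_pairwise_distance, m$median_pairwise_distance,
               tolerance = 1e-6)
})

test_that("batch scoring flags degenerate crops and matches single-cell calls", {
  crops <- list()
  for (i in 1:4) {
    crops[[sprintf("ok_%d", i)]] <-
      render_vesicle_cell(vesicle_scene_params(), seed = 40 + i)$image
  }
  crops$flat <- matrix(100, 128, 128)
  crops$edge <- render_vesicle_cell(vesicle_scene_params(),
                                    seed = 50, center = c(10, 64))$image
  out <- batch_score(crops, method = c("grid", "maxima"))
  expect_equal(nrow(out), 2 * length(crops))
  expect_true(all(out$status[out$cell_id == "flat"] == "segmentation_failed"))
  expect_true(all(out$status[out$cell_id == "edge"] == "border"))
  ok_rows <- out[out$cell_id == "ok_1" & out$method == "maxima", ]
  direct <- maxima_dispersion_score(crops$ok_1, segment_cell(crops$ok_1),
                                    cell_id = "ok_1")
  expect_equal(ok_rows$median_pairwise_distance,
               direct$median_pairwise_distance)
  # determinism: identical crops give identical rows
  again <- batch_score(crops["ok_1"], method = "grid")
  once <- batch_score(crops["ok_1"], method = "grid")
  expect_identical(again, once)
})
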