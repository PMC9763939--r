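test_that("scalar metrics reproduce hand-computed example tracks", {
  collinear <- make_track(c(0, 1, 2), c(0, 0, 0))
  backforth <- make_track(c(0, 1, 0), c(0, 0, 0))
  lshape <- make_track(c(0, 1, 1), c(0, 0, 1))

  expect_equal(path_length(collinear), 2)
  expect_equal(path_length(backforth), 2)
  expect_equal(path_length(lshape), 2)

  expect_equal(displacement(collinear), 2)
  expect_equal(displacement(backforth), 0)
  expect_equal(displacement(lshape), sqrt(2))

  expect_equal(confinement_ratio(collinear), 1)
  expect_equal(confinement_ratio(backforth), 0)
  expect_equal(confinement_ratio(lshape), sqrt(2) / 2)

  # stationary track: undefined CR, zero speed
  still <- make_track(rep(1, 5), rep(2, 5))
  expect_true(is.na(confinement_ratio(still)))
  expect_equal(median_speed(still), 0)

  expect_error(path_length(make_track(1, 1)), "insufficient")
})

test_that("max distance traveled honors its two modes", {
  straight <- make_track(c(0, 1, 2), c(0, 0, 0))
  expect_equal(max_distance_traveled(straight, "all_pairs"), 2)
  expect_equal(max_distance_traveled(straight, "from_origin"), 2)

  # all-pairs brute force on a triangle: farthest pair is (1,0)-(0.5,2)
  tri <- make_track(c(0, 1, 0.5), c(0, 0, 2))
  expect_equal(max_distance_traveled(tri), o_maxdist(tri))
  expect_equal(max_distance_traveled(tri), 2.0615528, tolerance = 1e-6)

  # bounded oscillation: value independent of duration
  osc <- make_track(rep(c(0, 3), 30), rep(0, 60))
  expect_equal(max_distance_traveled(osc), 3)
})

test_that("median speed uses per-step speeds over the frame interval", {
  tr <- make_track(c(0, 1, 3, 6), c(0, 0, 0, 0))  # steps 1, 2, 3 um at 10 s
  expect_equal(median_speed(tr), 0.2)
  expect_equal(median_speed(tr), o_median_speed(tr, 10))
  uniform <- make_track(cumsum(rep(1, 10)), rep(0, 10))
  expect_equal(median_speed(uniform), 0.1)
})

test_that("directionality-ratio decay matches per-timepoint hand computation", {
  straight <- make_track(c(0, 1, 2, 3), c(0, 0, 0, 0))
  expect_equal(directionality_ratio_curve(straight)$value, rep(1, 3))

  bf <- make_track(c(0, 1, 0), c(0, 0, 0))
  cv <- directionality_ratio_curve(bf)
  expect_equal(cv$value, c(1, 0))
  expect_equal(cv$t, c(10, 20))

  # final value equals the track's confinement ratio
  set.seed(11)
  tr <- random_track(25)
  cv2 <- directionality_ratio_curve(tr)
  expect_equal(cv2$value[length(cv2$value)], confinement_ratio(tr))
})

test_that("MSD uses overlapping intervals and matches closed forms", {
  still <- make_track(rep(0, 8), rep(0, 8))
  expect_true(all(track_msd(still)$msd == 0))

  # ballistic: MSD(n dt) = (v n dt)^2
  bal <- simulate_ballistic_track(speed = 0.1, n_frames = 20)
  m <- track_msd(bal)
  expect_equal(m$msd, (0.1 * m$lag)^2, tolerance = 1e-12)

  l <- make_track(c(0, 1, 1), c(0, 0, 1))
  expect_equal(track_msd(l)$msd, c(1, 2))

  gappy <- make_track(rnorm(5), rnorm(5))
  gappy$frame <- c(0, 1, 2, 4, 5)
  expect_error(track_msd(gappy), "gap")
})

test_that("all metrics agree with brute-force oracles on random tracks", {
  set.seed(123)
  for (i in 1:100) {
    T <- sample(3:20, 1)
    tr <- random_track(T)
    expect_equal(path_length(tr), o_path(tr), tolerance = 1e-12)
    expect_equal(displacement(tr), o_disp(tr), tolerance = 1e-12)
    expect_equal(confinement_ratio(tr), o_disp(tr) / o_path(tr),
                 tolerance = 1e-12)
    expect_equal(max_distance_traveled(tr), o_maxdist(tr), tolerance = 1e-12)
    expect_equal(median_speed(tr), o_median_speed(tr, 10), tolerance = 1e-12)
    expect_equal(directionality_ratio_curve(tr)$value, o_dir_curve(tr),
                 tolerance = 1e-12)
    expect_equal(track_msd(tr)$msd, o_msd(tr), tolerance = 1e-12)
  }
})

test_that("metric ordering invariants hold and CR*D recovers d", {
  set.seed(31)
  for (i in 1:25) {
    tr <- random_track(sample(5:40, 1))
    D <- path_length(tr)
    d <- displacement(tr)
    mx <- max_distance_traveled(tr)
    expect_lte(d, mx + 1e-12)
    expect_lte(mx, D + 1e-12)
    expect_equal(confinement_ratio(tr) * D, d, tolerance = 1e-9)
  }
})

test_that("metrics are invariant under rigid motions of the coordinates", {
  set.seed(99)
  tr <- random_track(30)
  base <- c(path_length(tr), displacement(tr), confinement_ratio(tr),
            max_distance_traveled(tr), median_speed(tr))
  for (i in 1:10) {
    th <- runif(1, 0, 2 * pi)
    shift <- rnorm(2, 0, 100)
    tr2 <- tr
    tr2$x <- cos(th) * tr$x - sin(th) * tr$y + shift[1]
    tr2$y <- sin(th) * tr$x + cos(th) * tr$y + shift[2]
    moved <- c(path_length(tr2), displacement(tr2), confinement_ratio(tr2),
               max_distance_traveled(tr2), median_speed(tr2))
    expect_equal(moved, base, tolerance = 1e-9)
  }
})

test_that("uncorrelated random walk has mean MSD 2 sigma^2 n (both axes)", {
  set.seed(5)
  sigma <- 0.7
  n_tracks <- 1000
  T <- 12
  acc <- numeric(T - 1)
  for (i in 1:n_tracks) {
    tr <- make_track(cumsum(rnorm(T, 0, sigma)), cumsum(rnorm(T, 0, sigma)))
    acc <- acc + track_msd(tr)$msd
  }
  mean_msd <- acc / n_tracks
  lags_n <- 1:(T - 1)
  expected <- 2 * sigma^2 * lags_n
  # compare the informative early lags (late lags average few intervals)
  expect_equal(mean_msd[1:6], expected[1:6], tolerance = 0.05)
})

test_that("curve aggregation pools within replicates then across them", {
  one <- data.frame(replicate = "r1", abscissa = c(1, 2), value = c(0.5, 0.4))
  agg1 <- aggregate_curves(one)
  expect_equal(agg1$mean, c(0.5, 0.4))
  expect_equal(agg1$sd, c(0, 0))

  two <- rbind(one, transform(one, replicate = "r2"))
  agg2 <- aggregate_curves(two)
  expect_equal(agg2$mean, c(0.5, 0.4))
  expect_equal(agg2$sd, c(0, 0))
  expect_equal(agg2$n_replicates, c(2, 2))

  # three replicates of ballistic tracks: aggregated MSD equals closed form
  long <- do.call(rbind, lapply(1:3, function(r) {
    ts <- track_set(do.call(rbind, lapply(1:4, function(i)
      simulate_ballistic_track(0.1, direction = i, n_frames = 10,
                               track_id = i))))
    curves_table(ts, "msd", replicate = paste0("r", r))
  }))
  agg3 <- aggregate_curves(long, stat = "mean")
  expect_equal(agg3$mean, (0.1 * agg3$abscissa)^2, tolerance = 1e-10)
  expect_equal(agg3$sd, rep(0, nrow(agg3)), tolerance = 1e-10)

  bad <- rbind(one, data.frame(replicate = "r3", abscissa = 3, value = 1))
  expect_error(aggregate_curves(bad), "mismatched")

  # undefined values are dropped per timepoint, not propagated
  withna <- rbind(one, data.frame(replicate = "r2", abscissa = c(1, 2),
                                  value = c(NA, 0.6)))
  aggna <- aggregate_curves(withna)
  expect_equal(aggna$mean, c(0.5, 0.5))
})

test_that("metrics_table matches the individual operations row by row", {
  set.seed(17)
  trs <- lapply(1:3, function(i) random_track(10))
  for (i in 1:3) trs[[i]]$track_id <- i
  ts <- track_set(do.call(rbind, trs))
  mt <- metrics_table(ts, replicate = "repA")
  expect_equal(nrow(mt), 3)
  expect_equal(mt$replicate, rep("repA", 3))
  for (i in 1:3) {
    expect_equal(mt$path_length_D[i], path_length(trs[[i]]))
    expect_equal(mt$max_distance[i], max_distance_traveled(trs[[i]]))
    expect_equal(mt$median_speed[i], median_speed(trs[[i]]))
  }
  # stationary track is carried with an undefined CR flag
  still <- make_track(rep(0, 10), rep(0, 10), track_id = 9L)
  ts2 <- track_set(rbind(trs[[1]], still))
  mt2 <- metrics_table(ts2)
  expect_false(mt2$cr_defined[mt2$track_id == "9"])
})

test_that("Fürth fit recovers the persistence time of a simulated ensemble", {
  ts <- simulate_track_set(300, "prw", seed = 21)
  fit <- fit_furth_msd(ensemble_msd(ts))
  expect_lt(abs(fit$P - 60) / 60, 0.25)
  expect_gt(fit$D, 0)
})
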