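test_that("segmentation recovers analytic ellipsoid volumes within 5%", {
  for (ax in list(c(5, 4, 3), c(2.5, 2.2, 2), c(8, 6, 4))) {
    cfg <- nucleus_config(semi_axes_um = ax, axis_jitter_sd = 0,
                          dapi_noise_sd = 0, n_signals_mean = 0,
                          n_signals_sd = 0, n_aggregates_mean = 0,
                          n_aggregates_sd = 0, flattening = 1)
    sim <- simulate_nucleus(cfg, seed = 1, channels = "DAPI",
                            n_signals = 0, n_aggregates = 0)
    mask <- segment_nucleus(sim$channels$DAPI)
    truth <- 4 / 3 * pi * prod(ax)
    expect_lt(abs(mask$volume_um3 - truth) / truth, 0.05)
  }
})

test_that("an all-zero stack raises 'no nucleus found'", {
  st <- image_stack(array(0, c(10, 12, 12)), voxel_spacing(), "DAPI")
  expect_error(segment_nucleus(st), "no nucleus found")
})

test_that("segmentation keeps only the largest of two disjoint nuclei", {
  sp <- voxel_spacing()
  d <- c(40, 60, 140)
  v <- array(0.02, d)
  fill_ellipsoid <- function(v, centre_vox, semi_vox, level) {
    z <- (seq_len(d[1]) - centre_vox[1]) / semi_vox[1]
    y <- (seq_len(d[2]) - centre_vox[2]) / semi_vox[2]
    x <- (seq_len(d[3]) - centre_vox[3]) / semi_vox[3]
    q <- outer(outer(z^2, y^2, `+`), x^2, `+`)
    v[q <= 1] <- level
    v
  }
  # large blob (left), small blob (right, ~half the linear size)
  v <- fill_ellipsoid(v, c(20, 30, 40), c(12, 20, 25), 1)
  v <- fill_ellipsoid(v, c(20, 30, 110), c(8, 12, 15), 1)
  mask <- segment_nucleus(image_stack(v, sp, "DAPI"))
  idx <- which(mask$mask, arr.ind = TRUE)
  expect_true(all(idx[, 3] < 80))  # only the left blob survives
  vol_large <- 4 / 3 * pi * (12 * sp$dz) * (20 * sp$dy) * (25 * sp$dx) / 1e9
  expect_lt(abs(mask$volume_um3 - vol_large) / vol_large, 0.06)
})

test_that("CD34 gating is boundary-inclusive and separates simulator pos/neg", {
  sp <- voxel_spacing()
  mask_src <- simulate_nucleus(tiny_nucleus_config(), seed = 2,
                               channels = "DAPI", n_signals = 0,
                               n_aggregates = 0)
  mask <- segment_nucleus(mask_src$channels$DAPI)
  d <- dim(mask$mask)
  uniform <- image_stack(array(0.2, d), sp, "FITC")
  expect_true(classify_cd34(uniform, mask, threshold = 0.2))
  zero <- image_stack(array(0, d), sp, "FITC")
  expect_false(classify_cd34(zero, mask, threshold = 0.1))

  pos <- simulate_nucleus(tiny_nucleus_config(cd34_positive = TRUE), seed = 3)
  neg <- simulate_nucleus(tiny_nucleus_config(cd34_positive = FALSE), seed = 3)
  mp <- segment_nucleus(pos$channels$DAPI)
  mn <- segment_nucleus(neg$channels$DAPI)
  expect_true(classify_cd34(pos$channels$FITC, mp))
  expect_false(classify_cd34(neg$channels$FITC, mn))
})

test_that("well-separated spots at SNR 10 are all found with sub-voxel accuracy", {
  cfg <- detector_test_config(noise_sd = 0.196)  # peak/noise ~ 10
  sim <- simulate_nucleus(cfg, seed = 21)
  q <- quantify_nucleus(sim$channels)
  expect_equal(nrow(q$signals), sim$truth$n_signals)
  obj <- sim$truth$objects
  for (i in seq_len(nrow(q$signals))) {
    d <- sqrt((obj$x_nm - q$signals$x_nm[i])^2 +
              (obj$y_nm - q$signals$y_nm[i])^2 +
              (obj$z_nm - q$signals$z_nm[i])^2)
    j <- which.min(d)
    expect_lt(abs(obj$x_nm[j] - q$signals$x_nm[i]), 102)
    expect_lt(abs(obj$y_nm[j] - q$signals$y_nm[i]), 102)
    expect_lt(abs(obj$z_nm[j] - q$signals$z_nm[i]), 200)
  }
})

test_that("a blank Cy3 channel yields zero detections, not an error", {
  sim <- simulate_nucleus(tiny_nucleus_config(), seed = 4,
                          n_signals = 0, n_aggregates = 0)
  q <- quantify_nucleus(sim$channels)
  expect_equal(nrow(q$signals), 0)
})

test_that("measured intensities are linear in true flux (ratio 2 recovered)", {
  sp <- voxel_spacing()
  d <- c(30, 60, 60)
  pos <- cbind(x = c(1500, 4500), y = c(3000, 3000), z = c(3000, 3000))
  st <- oracle_spot_stack(pos, c(100, 200), d, sp)
  det <- detect_spots(st, full_mask(st))
  expect_equal(nrow(det), 2)
  ratio <- max(det$intensity) / min(det$intensity)
  expect_lt(abs(ratio - 2), 0.1)

  # noiseless intensity ladder: R^2 >= 0.99 and near-unit slope
  pos <- cbind(x = seq(1500, 10500, length.out = 5), y = rep(3000, 5),
               z = rep(3000, 5))
  truth <- seq(50, 250, length.out = 5)
  st <- oracle_spot_stack(pos, truth, c(30, 60, 120), sp)
  det <- detect_spots(st, full_mask(st))
  expect_equal(nrow(det), 5)
  det <- det[order(det$x_nm), ]
  fit <- summary(lm(det$intensity ~ truth))
  expect_gt(fit$r.squared, 0.99)
  expect_lt(abs(coef(fit)[2, 1] - 1), 0.05)
})

test_that("two spots below the resolution limit merge into one aggregate call", {
  sp <- voxel_spacing()
  # five reference singles plus a pair 150 nm apart (unresolvable)
  pos <- rbind(cbind(x = c(1500, 4000, 6500, 1500, 6500),
                     y = c(1500, 1500, 1500, 4500, 4500), z = rep(2800, 5)),
               cbind(x = c(4000, 4150), y = c(4500, 4500), z = c(2800, 2800)))
  st <- oracle_spot_stack(pos, rep(100, 7), c(28, 60, 80), sp)
  det <- call_aggregates(detect_spots(st, full_mask(st)))
  expect_equal(nrow(det), 6)           # the close pair is one detection
  expect_equal(count_aggregates(det), 1)
  merged <- det[which.max(det$intensity), ]
  expect_true(merged$is_aggregate)
  expect_lt(abs(merged$intensity - 200) / 200, 0.1)
})

test_that("well-separated unit-intensity spots yield zero aggregates", {
  sp <- voxel_spacing()
  pos <- cbind(x = c(1500, 4000, 6500, 1500, 6500),
               y = c(1500, 1500, 1500, 4500, 4500), z = rep(2800, 5))
  st <- oracle_spot_stack(pos, rep(100, 5), c(28, 60, 80), sp)
  det <- call_aggregates(detect_spots(st, full_mask(st)))
  expect_equal(nrow(det), 5)
  expect_equal(count_aggregates(det), 0)
})

test_that("configured aggregates are recovered within one", {
  cfg <- tiny_nucleus_config(n_signals_mean = 14, n_signals_sd = 0)
  sim <- simulate_nucleus(cfg, seed = 31, n_signals = 14, n_aggregates = 4)
  q <- quantify_nucleus(sim$channels)
  expect_lte(abs(count_aggregates(q$signals) - 4), 1)
})

test_that("radial position is 0 at the centroid, ~1 at the boundary, mean ~3/4 in a sphere", {
  cfg <- nucleus_config(semi_axes_um = c(2.5, 2.5, 2.5), axis_jitter_sd = 0,
                        dapi_noise_sd = 0, flattening = 1, n_slices = 30)
  sim <- simulate_nucleus(cfg, seed = 6, channels = "DAPI",
                          n_signals = 0, n_aggregates = 0)
  mask <- segment_nucleus(sim$channels$DAPI)
  cen <- mask$centroid_nm
  at <- function(z, y, x) tibble::tibble(x_nm = x, y_nm = y, z_nm = z)
  expect_equal(radial_position(at(cen[1], cen[2], cen[3]), mask), 0)
  near_boundary <- at(cen[1], cen[2], cen[3] + 2400)
  expect_gt(radial_position(near_boundary, mask), 0.93)
  expect_error(radial_position(at(cen[1], cen[2], cen[3] + 4000), mask),
               "outside")

  # uniform points in the sphere: E[r/R] = 3/4
  set.seed(8)
  n <- 400
  g <- matrix(rnorm(3 * n), ncol = 3)
  g <- g / sqrt(rowSums(g^2)) * runif(n)^(1 / 3) * 2300
  pts <- tibble::tibble(x_nm = cen[3] + g[, 1], y_nm = cen[2] + g[, 2],
                        z_nm = cen[1] + g[, 3])
  r <- radial_position(pts, mask)
  expect_lt(abs(mean(r) - 0.75 * 2300 / 2500), 0.03)
})

test_that("detection recall and precision reach 0.95 at SNR 8", {
  recalls <- precisions <- numeric(0)
  for (seed in 41:46) {
    sim <- simulate_nucleus(detector_test_config(noise_sd = 0.245),
                            seed = seed)
    q <- quantify_nucleus(sim$channels)
    m <- match_detections(q$signals, sim$truth$objects)
    recalls <- c(recalls, m$recall)
    precisions <- c(precisions, m$precision)
  }
  expect_gte(mean(recalls), 0.95)
  expect_gte(mean(precisions), 0.95)
})
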