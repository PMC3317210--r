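test_that("the high threshold is 0.6 times the dimmest culture maximum", {
  expect_equal(compute_th(c(100, 120, 90)), 54)
  expect_equal(compute_th(200), 120)
  expect_error(compute_th(numeric()), "non-empty")
})

test_that("the low threshold is mean plus c standard deviations", {
  const <- array(3.7, c(5, 5, 2))
  expect_equal(compute_tl(const, 1.4), 3.7)
  expect_equal(compute_tl(const, 0), 3.7)
  set.seed(3)
  x <- array(rnorm(60000, 50, 5), c(100, 100, 6))
  expect_equal(compute_tl(x, 0), mean(x))
  # Gaussian tail: ~8% of pure-noise voxels exceed mean + 1.4 sd
  frac <- mean(x > compute_tl(x, 1.4))
  expect_lt(abs(frac - (1 - pnorm(1.4))), 0.01)
})

test_that("hysteresis keeps low pixels only when connected to a high pixel", {
  row <- array(c(1, 5, 3, 1, 4, 1), c(1, 6, 1))
  m <- hysteresis_threshold(row, 4.5, 2.5)
  expect_equal(as.logical(m), c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE))
  # collapse case: T_L = T_H reduces to plain thresholding
  set.seed(1)
  x <- array(runif(200, 0, 10), c(5, 10, 4))
  expect_equal(hysteresis_threshold(x, 6, 6), array(x > 6, dim(x)))
  expect_error(hysteresis_threshold(x, 2, 6), "t_h")
})

test_that("hysteresis matches the flood-fill oracle on random stacks", {
  set.seed(9)
  for (i in 1:100) {
    x <- array(runif(16 * 16 * 4, 0, 10), c(16, 16, 4))
    expect_identical(hysteresis_threshold(x, 8, 4),
                     hysteresis_floodfill(x, 8, 4))
  }
})

test_that("connected components labels and measures clusters", {
  ig <- array(0, c(20, 20, 1))
  ig[, , 1] <- render_cell(5, 5, 1000, 1, c(20, 20)) +
    render_cell(15, 15, 500, 1, c(20, 20))
  cc <- connected_components(array(ig > 1, dim(ig)), ig)
  expect_equal(nrow(cc$features), 2)
  expect_equal(cc$features$volume, as.integer(table(cc$labels[cc$labels > 0])),
               ignore_attr = TRUE)
  expect_equal(sort(cc$features$intensity), sort(c(
    sum(ig[cc$labels == 1]), sum(ig[cc$labels == 2]))))
  # center of mass near the rendered centers
  expect_equal(sort(cc$features$com_x), c(5, 15), tolerance = 0.05)
  empty <- connected_components(array(FALSE, c(4, 4, 2)),
                                array(0, c(4, 4, 2)))
  expect_equal(nrow(empty$features), 0)
})

test_that("detection finds every well-separated cluster on a phantom", {
  cfg <- small_config(seed = 31, split_prob = 0)
  ph <- generate_phantom(cfg)
  ig <- preprocess_stack(ph$stack, preprocess_config(
    next_blur_sigma = cfg$bleed_blur_sigma,
    next_attenuation = cfg$bleed_fraction))
  cult <- generate_culture_image(small_config(seed = 32, split_prob = 0), 60)
  cig <- suppressWarnings(preprocess_stack(cult$stack, preprocess_config(
    next_blur_sigma = cfg$bleed_blur_sigma,
    next_attenuation = cfg$bleed_fraction)))
  det <- detect_clusters(ig, detect_config(),
                         culture_maxima = culture_cluster_maxima(cig))
  kept <- det$features[det$features$kept, ]
  expect_equal(nrow(kept), cfg$n_clusters)   # no false negatives
  m <- match_to_truth(ph$truth, det$labels)
  expect_true(all(m$det_id > 0))
  expect_equal(length(unique(m$det_id)), cfg$n_clusters)  # no false positives
})

test_that("hysteresis mask is nested between the two plain thresholds", {
  set.seed(12)
  x <- array(runif(16 * 16 * 3, 0, 10), c(16, 16, 3))
  m <- hysteresis_threshold(x, 8, 4)
  expect_true(all(m[x > 8]))        # contains the high mask
  expect_true(all(x[m] > 4))        # contained in the low mask
  # raising T_L never grows any cluster: the new mask nests in the old
  m2 <- hysteresis_threshold(x, 8, 5)
  expect_true(all(m[m2]))
})

test_that("false-positive rules reject by volume and intensity ratio", {
  feats <- data.frame(id = 1:3, volume = c(500L, 10L, 10L),
                      intensity = c(5000, 5, 300),
                      ratio = c(10, 0.5, 30), slice_span = 1L)
  out <- reject_false_positives(feats, t_v = 100, ratio_range = c(1, 50))
  expect_equal(out$kept, c(FALSE, FALSE, TRUE))
  expect_equal(out$reject_reason, c("volume", "ratio_low", ""))
})

test_that("an injected oversized bright blob is rejected, true clusters kept", {
  cfg <- phantom_config(image_shape = c(3, 160, 160), n_clusters = 8,
                        cluster_size_pmf = 1, seed = 14, split_prob = 0)
  ph <- generate_phantom(cfg)
  stack <- ph$stack
  # a bright red autofluorescent region (gut-like): large and diffuse
  stack$red[20:59, 20:59, 2] <- stack$red[20:59, 20:59, 2] + 120
  ig <- preprocess_stack(stack, preprocess_config(
    next_blur_sigma = cfg$bleed_blur_sigma,
    next_attenuation = cfg$bleed_fraction,
    erosion_radius_px = 25))
  det <- detect_clusters(ig, detect_config(t_h = 60, t_l = 10, t_v = 500))
  rejected <- det$features[!det$features$kept, ]
  expect_true(any(rejected$reject_reason == "volume" &
                    rejected$volume > 500))
  m <- match_to_truth(ph$truth, det$labels)
  kept_ids <- det$features$id[det$features$kept]
  expect_true(all(m$det_id %in% kept_ids))
})

test_that("threshold report states the thresholds needed per object", {
  ig <- array(0, c(20, 20, 1))
  ig[, , 1] <- render_cell(10, 10, 1000, 1, c(20, 20))
  det <- detect_clusters(ig, detect_config(t_h = 50, t_l = 5))
  rep <- threshold_report(det, ig)
  expect_equal(nrow(rep), 1)
  expect_equal(rep$th_needed, max(ig))
  expect_lte(rep$tl_needed, 50)
})
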