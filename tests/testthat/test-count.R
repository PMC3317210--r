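test_that("singleton selection keeps single-slice clusters inside the windows", {
  feats <- data.frame(id = 1:4, volume = c(20L, 20L, 20L, 20L),
                      intensity = c(1000, 1000, 2000, 1000),
                      slice_span = c(1L, 2L, 1L, 1L),
                      kept = c(TRUE, TRUE, TRUE, FALSE))
  out <- select_singletons(feats, c(10, 30), c(800, 1200))
  expect_equal(out$id, 1L)   # multi-slice, off-window and rejected excluded
  expect_error(select_singletons(feats[0, ], c(0, 1), c(0, 1)), "no clusters")
  expect_error(select_singletons(feats, c(0, 1), c(0, 1)), "no singleton")
})

test_that("most true singletons fall inside automatic calibration windows", {
  # clean segmentation (no sectioning, bleed or noise): this exercises the
  # selection windows; noisy volumes attach occasional cross-slice speckle
  # to a cluster, which the single-slice rule then excludes by design
  cfg <- phantom_config(image_shape = c(5, 240, 240), n_clusters = 60,
                        intensity_cv = 0.05, split_prob = 0,
                        bleed_fraction = 0, noise_sd = 0, seed = 17)
  ph <- generate_phantom(cfg)
  ig <- preprocess_stack(ph$stack, preprocess_config(
    next_blur_sigma = cfg$bleed_blur_sigma,
    next_attenuation = cfg$bleed_fraction))
  det <- detect_clusters(ig, detect_config(t_h = 60, t_l = 8))
  rng <- singleton_ranges(det$features)
  singles <- select_singletons(det$features, rng$volume_range,
                               rng$intensity_range)
  m <- match_to_truth(ph$truth, det$labels)
  true_single_det <- m$det_id[m$n_cells == 1 & m$det_id > 0]
  expect_gte(mean(true_single_det %in% singles$id), 0.95)
})

test_that("single-cell fits recover the generating parameters", {
  patch <- render_cell(5.3, 7.8, 1000, 1.2, c(15, 11))
  for (method in c("nelder-mead", "lm")) {
    f <- fit_single_cell(patch, method = method)
    expect_true(f$converged)
    expect_equal(f$x, 5.3, tolerance = 0.01)
    expect_equal(f$y, 7.8, tolerance = 0.01)
    expect_equal(f$sigma, 1.2, tolerance = 0.01)
    expect_equal(f$I_t, 1000, tolerance = 0.01)
  }
  # initialization at the truth converges immediately with ~zero residual
  f0 <- fit_single_cell(patch, init = list(x = 5.3, y = 7.8, sigma = 1.2,
                                           I_t = 1000))
  expect_lt(f0$residual, 1e-6)
})

test_that("mean fitted intensity is unbiased under 2%-of-peak noise", {
  set.seed(23)
  peak <- max(render_cell(8, 8, 1000, 1, c(15, 15)))
  its <- replicate(100, {
    x <- 7.5 + runif(1); y <- 7.5 + runif(1)
    p <- render_cell(x, y, 1000, 1, c(15, 15)) +
      matrix(rnorm(225, 0, 0.02 * peak), 15, 15)
    fit_single_cell(p, method = "lm")$I_t
  })
  expect_equal(mean(its), 1000, tolerance = 0.02)
})

test_that("model calibration averages the single-cell fits", {
  fits <- list(list(sigma = 1, I_t = 100, converged = TRUE),
               list(sigma = 3, I_t = 300, converged = TRUE))
  m <- calibrate_model(fits, d_min = 2)
  expect_equal(m$sigma, 2)
  expect_equal(m$I_t, 200)
  one <- calibrate_model(fits[1], d_min = 1)
  expect_equal(one$sigma, 1)
  expect_error(calibrate_model(list(list(converged = FALSE))), "failed")
})

test_that("initial estimate rounds half-up and floors at one", {
  expect_equal(initial_estimate(200, 100), 2L)
  expect_equal(initial_estimate(250, 100), 3L)
  expect_equal(initial_estimate(30, 100), 1L)
  expect_error(initial_estimate(100, 0), "positive")
})

test_that("candidate range covers max(2, 30%) around the estimate", {
  expect_equal(candidate_range(3), 1:5)
  expect_equal(candidate_range(10), 7:13)
  expect_equal(candidate_range(1), 1:3)
})

test_that("the compiled mixture renderer agrees with render_cell", {
  set.seed(5)
  for (i in 1:10) {
    n <- sample(1:4, 1)
    pl <- data.frame(x = runif(n, 2, 10), y = runif(n, 2, 8),
                     home = 1L, z = 0)
    model <- toy_model(sigma = runif(1, 0.8, 1.5), I_t = runif(1, 500, 1500))
    got <- render_placements(pl, model, c(9, 11, 1))
    want <- Reduce(`+`, lapply(seq_len(n), function(j)
      render_cell(pl$x[j], pl$y[j], model$I_t, model$sigma, c(9, 11))))
    expect_equal(got[, , 1], want, tolerance = 1e-12)
  }
})

test_that("a rendered single cell is recovered within 0.1 px with ~zero error", {
  model <- toy_model()
  patch <- array(render_cell(6.4, 5.1, 1000, 1, c(11, 13)), c(11, 13, 1))
  f <- fit_n_cells(patch, 1, model, seed = 1)
  expect_true(f$converged)
  expect_equal(f$placements$x, 6.4, tolerance = 0.1)
  expect_equal(f$placements$y, 5.1, tolerance = 0.1)
  expect_lt(f$f_obj, 1e-3)
})

test_that("the objective is minimized at the true cell count", {
  model <- toy_model()
  cen <- rbind(c(7, 7), c(9.2, 7.4), c(7.5, 9.6), c(9.8, 9.9))
  p <- array(Reduce(`+`, lapply(1:4, function(i)
    render_cell(cen[i, 1], cen[i, 2], 1000, 1, c(16, 16)))), c(16, 16, 1))
  fo <- vapply(3:5, function(n) fit_n_cells(p, n, model, seed = n)$f_obj,
               numeric(1))
  expect_lt(fo[2], fo[1])
  expect_lt(fo[2], fo[3])
})

test_that("random restarts of the best count agree to within 0.1 px", {
  model <- toy_model()
  full <- render_cell(5, 5, 1000, 1, c(9, 11)) +
    render_cell(7, 5.3, 1000, 1, c(9, 11))
  patch <- array(full, c(9, 11, 1))
  cen <- t(vapply(1:20, function(s) {
    f <- fit_n_cells(patch, 2, model, seed = s, init = "random")
    o <- order(f$placements$x)
    c(f$placements$x[o], f$placements$y[o])
  }, numeric(4)))
  expect_lt(max(apply(cen, 2, function(v) diff(range(v)))), 0.1)
})

test_that("two barely-overlapping cells are counted as two (grid oracle)", {
  model <- toy_model()
  full <- render_cell(7, 8, 1000, 1, c(16, 16)) +
    render_cell(9, 8, 1000, 1, c(16, 16))
  patch <- array(full, c(16, 16, 1))
  res <- count_cluster(patch, model, seed = 1)
  expect_equal(res$n_est, 2L)
  # independent oracle: exhaustive grid search of the analytic objective
  sse1 <- Inf
  for (x in seq(6.5, 9.5, by = 0.1)) for (y in seq(7.5, 8.5, by = 0.1))
    sse1 <- min(sse1, sum((full - render_cell(x, y, 1000, 1, c(16, 16)))^2))
  sse2 <- Inf
  for (x1 in seq(6, 8, by = 0.25)) for (x2 in seq(8, 10, by = 0.25))
    sse2 <- min(sse2, sum((full -
      render_cell(x1, 8, 1000, 1, c(16, 16)) -
      render_cell(x2, 8, 1000, 1, c(16, 16)))^2))
  expect_lt(sse2, sse1)
  f1 <- res$candidates$f_obj[res$candidates$n == 1]
  expect_lt(abs(f1 - sse1) / sse1, 0.05)  # fitted F(1) matches the oracle
})

test_that("a singleton cluster is counted as one and selection is consistent", {
  model <- toy_model()
  patch <- array(render_cell(6, 6, 1000, 1, c(11, 11)), c(11, 11, 1))
  res <- count_cluster(patch, model, seed = 2)
  expect_equal(res$n_est, 1L)
  expect_equal(res$f_obj, min(res$candidates$f_obj[res$candidates$converged]))
  # the objective is quasi-convex around the truth: F(1) beats F(3)
  expect_lt(res$f_obj, res$candidates$f_obj[res$candidates$n == 3])
})

test_that("a sectioned cell's split fraction is recovered", {
  model <- toy_model()
  p <- array(0, c(11, 11, 2))
  cell <- render_cell(6.2, 5.9, 1000, 1, c(11, 11))
  p[, , 1] <- 0.7 * cell
  p[, , 2] <- 0.3 * cell
  f <- fit_n_cells(p, 1, model, seed = 3)
  expect_equal(f$placements$home, 1L)
  expect_equal(f$placements$z, 0.3, tolerance = 0.02)
  expect_lt(f$sse, 1)
})
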