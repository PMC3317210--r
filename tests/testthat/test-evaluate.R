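test_that("contingency tables tally paired counts", {
  tab <- build_contingency(c(1, 2, 3), c(1, 2, 3))
  expect_equal(diag(tab), c(1L, 1L, 1L), ignore_attr = TRUE)
  expect_equal(sum(tab) - sum(diag(tab)), 0)

  tab2 <- build_contingency(rep(2, 38), rep(2, 38))
  expect_equal(tab2["2", "2"], 38L)

  empty <- build_contingency(integer(), integer())
  expect_equal(dim(empty), c(0L, 0L))
  expect_error(build_contingency(1:3, 1:2), "equal length")
  # marginals match the inputs
  t3 <- build_contingency(c(1, 1, 2, 3), c(1, 2, 2, 3))
  expect_equal(rowSums(t3), c(`1` = 2, `2` = 1, `3` = 1), ignore_attr = TRUE)
  expect_equal(colSums(t3), c(`1` = 1, `2` = 2, `3` = 1), ignore_attr = TRUE)
})

test_that("Fleiss' kappa is 1 for diagonal tables and ~0 for random ones", {
  tab <- build_contingency(c(1, 1, 2, 2, 3), c(1, 1, 2, 2, 3))
  expect_equal(fleiss_kappa(tab)$kappa, 1)
  set.seed(4)
  a <- sample(1:4, 4000, replace = TRUE)
  b <- sample(1:4, 4000, replace = TRUE)
  k <- fleiss_kappa(build_contingency(a, b))
  expect_lt(abs(k$kappa), 0.05)
  expect_warning(fleiss_kappa(build_contingency(c(1, 1), c(1, 1))),
                 "undefined")
})

test_that("Fleiss' kappa matches a hand-computed three-subject example", {
  # subjects rated (1,1), (2,2), (1,2): P_bar = 2/3, p = (1/2, 1/2),
  # P_e = 1/2, kappa = 1/3; null SE = sqrt(1/3)
  tab <- build_contingency(c(1, 2, 1), c(1, 2, 2))
  k <- fleiss_kappa(tab)
  expect_equal(k$kappa, 1 / 3, tolerance = 1e-12)
  expect_equal(k$se, sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(k$p_bar, 2 / 3)
  expect_equal(k$p_e, 1 / 2)
})

test_that("kappa statistics stay within [-1, 1] on random tables", {
  set.seed(11)
  for (i in 1:20) {
    a <- sample(1:3, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    tab <- build_contingency(a, b)
    k <- fleiss_kappa(tab)$kappa
    expect_gte(k, -1); expect_lte(k, 1)
    ck <- cohen_kappa(tab)$kappa
    expect_gte(ck, -1); expect_lte(ck, 1)
  }
})

test_that("sensitivity and specificity follow one-vs-rest definitions", {
  ident <- build_contingency(c(1, 2, 3, 1), c(1, 2, 3, 1))
  ss <- sensitivity_specificity(ident)
  expect_true(all(ss$per_class$sensitivity == 1))
  expect_true(all(ss$per_class$specificity == 1))

  # one (true 3 -> est 2) error among ten true-3 clusters
  tr <- c(rep(3, 10), rep(1, 5)); es <- c(2, rep(3, 9), rep(1, 5))
  ss2 <- sensitivity_specificity(build_contingency(tr, es))
  expect_equal(ss2$per_class$sensitivity[3], 0.9)

  # random table equals a brute-force confusion computation
  set.seed(7)
  a <- sample(1:4, 200, replace = TRUE)
  b <- sample(1:4, 200, replace = TRUE)
  ss3 <- sensitivity_specificity(build_contingency(a, b))
  for (k in 1:4) {
    expect_equal(ss3$per_class$sensitivity[k], mean(b[a == k] == k))
    expect_equal(ss3$per_class$specificity[k], mean(b[a != k] != k))
  }
})

test_that("total count error reproduces the reference tallies", {
  expect_equal(total_count_error(rep(1, 499), c(rep(1, 497), rep(0, 2))),
               2 / 499, tolerance = 1e-12)
  expect_equal(round(total_count_error(rep(1, 393),
                                       c(rep(1, 386), rep(0, 7))), 4),
               0.0178)
  expect_equal(total_count_error(1:5, 1:5), 0)
  expect_error(total_count_error(c(0, 0), c(1, 1)), "undefined")
})

test_that("feature histograms locate the single-cell peak and its double", {
  cfg <- phantom_config(image_shape = c(1, 400, 400),
                        cluster_size_pmf = c(0.6, 0.4), intensity_cv = 0.05,
                        background_level = 0, noise_sd = 0, split_prob = 0,
                        bleed_fraction = 0, seed = 19)
  ph <- generate_phantom(phantom_config(image_shape = c(1, 400, 400),
                                        n_clusters = 80,
                                        cluster_size_pmf = c(0.6, 0.4),
                                        intensity_cv = 0.05,
                                        background_level = 0, noise_sd = 0,
                                        split_prob = 0, bleed_fraction = 0,
                                        seed = 19))
  ig <- ratio_threshold(ph$stack, 0)
  cc <- connected_components(array(ig > 1, dim(ig)), ig)
  h <- feature_histograms(cc$features)
  expect_equal(h$peaks$intensity, cfg$intensity_mean, tolerance = 0.1)
  # bimodal: mass near 2x the peak, valley at 1.5x
  d <- density(cc$features$intensity)
  at <- function(v) d$y[which.min(abs(d$x - v))]
  expect_gt(at(2 * h$peaks$intensity), at(1.5 * h$peaks$intensity))

  singles <- feature_histograms(cc$features[cc$features$intensity <
                                              1.5 * h$peaks$intensity, ])
  expect_equal(singles$peaks$intensity, cfg$intensity_mean, tolerance = 0.1)
  empty <- feature_histograms(cc$features[0, ])
  expect_equal(nrow(empty$intensity), 0)
  expect_true(is.na(empty$peaks$intensity))
})
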