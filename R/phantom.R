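#' Configuration for a synthetic cryo-imaging phantom
#'
#' Describes a volume of fluorescent cell clusters embedded in a
#' green-dominant autofluorescent background, emulating the statistical
#' structure of microsphere and quantum-dot-cell phantoms: single-pixel
#' scale sources rendered as pixel-integrated 2D Gaussians, per-source
#' intensity variation (coefficient of variation 0.05 for microspheres,
#' 0.15 for labeled cells), red-dominant sources (red/green about 8)
#' over a green-dominant background (red/green about 0.4), and subsurface
#' bleed-through of a blurred, attenuated copy of the next section.
#'
#' @param image_shape integer vector `(slices, rows, cols)`.
#' @param pixel_size_um in-plane pixel size (micrometres).
#' @param section_um section thickness (micrometres).
#' @param n_clusters number of clusters to place.
#' @param cluster_size_pmf probability mass over cells per cluster
#'   (sizes `1:length(pmf)`); must sum to 1.
#' @param sigma_px Gaussian width of a rendered source, pixels.
#' @param intensity_mean mean per-source total intensity (digital units).
#' @param intensity_cv fractional standard deviation of per-source total
#'   intensity; 0.05 emulates microspheres, 0.15 labeled cells.
#' @param min_sep_px minimum intra-cluster center spacing, pixels.
#' @param background_level mean green-channel autofluorescence.
#' @param background_rg_ratio red/green ratio of the background.
#' @param cell_rg_ratio red/green ratio of sources.
#' @param bleed_fraction fraction of a section's signal visible (blurred)
#'   in the image of the section above it, in `[0, 1)`.
#' @param bleed_blur_sigma blur width (pixels) of the bleed-through copy.
#' @param noise_sd additive Gaussian sensor noise SD (both channels).
#' @param split_prob probability that a source is sectioned, splitting its
#'   intensity between its home slice and the next.
#' @param background_amp relative amplitude of the smooth background field
#'   around `background_level`.
#' @param background_smooth_px correlation length (blur sigma) of the
#'   background field, pixels.
#' @param seed RNG seed used by [generate_phantom()]; `NULL` leaves the
#'   RNG state alone.
#' @param preset `"cell"` or `"microsphere"`; a microsphere preset only
#'   tightens `intensity_cv` to 0.05 unless given explicitly.
#' @return an object of class `phantom_config` (a validated list).
#' @export
phantom_config <- function(image_shape = c(8, 320, 320),
                           pixel_size_um = 15.6,
                           section_um = 40,
                           n_clusters = 200,
                           cluster_size_pmf = c(0.45, 0.22, 0.14, 0.11, 0.08),
                           sigma_px = 1.0,
                           intensity_mean = 1000,
                           intensity_cv = 0.15,
                           min_sep_px = 1.5,
                           background_level = 40,
                           background_rg_ratio = 0.4,
                           cell_rg_ratio = 8.0,
                           bleed_fraction = 0.15,
                           bleed_blur_sigma = 2,
                           noise_sd = 3,
                           split_prob = 0.3,
                           background_amp = 0.2,
                           background_smooth_px = 12,
                           seed = NULL,
                           preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("cell", "microsphere"))
    if (preset == "microsphere" && missing(intensity_cv)) intensity_cv <- 0.05
  }
  cfg <- list(image_shape = as.integer(image_shape),
              pixel_size_um = pixel_size_um, section_um = section_um,
              n_clusters = as.integer(n_clusters),
              cluster_size_pmf = cluster_size_pmf,
              sigma_px = sigma_px, intensity_mean = intensity_mean,
              intensity_cv = intensity_cv, min_sep_px = min_sep_px,
              background_level = background_level,
              background_rg_ratio = background_rg_ratio,
              cell_rg_ratio = cell_rg_ratio,
              bleed_fraction = bleed_fraction,
              bleed_blur_sigma = bleed_blur_sigma,
              noise_sd = noise_sd, split_prob = split_prob,
              background_amp = background_amp,
              background_smooth_px = background_smooth_px,
              seed = seed)
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  with(cfg, {
    if (length(image_shape) != 3 || any(image_shape < 1))
      stop("image_shape must be (slices, rows, cols), all >= 1")
    if (abs(sum(cluster_size_pmf) - 1) > 1e-8)
      stop("cluster_size_pmf must sum to 1")
    if (any(cluster_size_pmf < 0)) stop("cluster_size_pmf must be non-negative")
    if (sigma_px <= 0) stop("sigma_px must be positive")
    if (intensity_cv < 0) stop("intensity_cv must be >= 0")
    if (bleed_fraction < 0 || bleed_fraction >= 1)
      stop("bleed_fraction must be in [0, 1)")
    if (min_sep_px <= 0) stop("min_sep_px must be positive")
    if (intensity_mean <= 0) stop("intensity_mean must be positive")
    if (noise_sd < 0) stop("noise_sd must be >= 0")
    if (n_clusters < 0) stop("n_clusters must be >= 0")
  })
  invisible(cfg)
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf("<phantom_config> %d clusters in %d x %d x %d (slices x rows x cols)\n",
              x$n_clusters, x$image_shape[1], x$image_shape[2], x$image_shape[3]))
  cat(sprintf("  sigma %.2f px, I %.0f (CV %.0f%%), bleed %.0f%%, noise sd %.2g\n",
              x$sigma_px, x$intensity_mean, 100 * x$intensity_cv,
              100 * x$bleed_fraction, x$noise_sd))
  invisible(x)
}

#' Render one pixel-integrated Gaussian source
#'
#' Each pixel value is the exact integral of an isotropic 2D Gaussian of
#' total mass `I_t` over that pixel's unit square (error-function product),
#' so the sum over an unbounded patch equals `I_t` for any sub-pixel
#' placement. Pixel `(r, c)` is centred at coordinates `(y = r, x = c)`.
#'
#' @param x_c,y_c real-valued source center (x = column, y = row).
#' @param I_t total source intensity (> 0).
#' @param sigma_px Gaussian width in pixels (> 0).
#' @param patch_shape integer `(rows, cols)`.
#' @return numeric `rows x cols` matrix.
#' @export
render_cell <- function(x_c, y_c, I_t, sigma_px, patch_shape) {
  if (sigma_px <= 0) stop("sigma_px must be positive")
  if (I_t <= 0) stop("I_t must be positive")
  nr <- as.integer(patch_shape[1]); nc <- as.integer(patch_shape[2])
  rows <- seq_len(nr); cols <- seq_len(nc)
  roww <- pnorm((rows + 0.5 - y_c) / sigma_px) - pnorm((rows - 0.5 - y_c) / sigma_px)
  colw <- pnorm((cols + 0.5 - x_c) / sigma_px) - pnorm((cols - 0.5 - x_c) / sigma_px)
  I_t * outer(roww, colw)
}

# Place n points with pairwise distance >= min_sep inside a disc whose
# radius grows slowly with the attempt count; deterministic given RNG state.
place_cluster_cells <- function(n, min_sep) {
  pts <- matrix(0, n, 2)
  if (n == 1) return(pts)
  for (k in 2:n) {
    for (attempt in 1:400) {
      R <- min_sep * (0.6 * sqrt(n) + attempt / 60)
      ang <- runif(1, 0, 2 * pi)
      rad <- R * sqrt(runif(1))
      cand <- c(rad * cos(ang), rad * sin(ang))
      d <- sqrt(rowSums((pts[seq_len(k - 1), , drop = FALSE] -
                           matrix(cand, k - 1, 2, byrow = TRUE))^2))
      if (all(d >= min_sep)) { pts[k, ] <- cand; break }
      if (attempt == 400) stop("could not place cells within a cluster")
    }
  }
  pts
}

#' Generate a synthetic phantom stack with ground truth
#'
#' Places clusters of Gaussian sources without inter-cluster overlap,
#' renders them into the red channel (the green channel receives
#' `1/cell_rg_ratio` of each source), adds a smooth green-dominant
#' background, simulates subsurface bleed-through by adding a blurred,
#' attenuated copy of each section's signal to the image of the section
#' above it, and adds sensor noise. Reproducible under a fixed seed.
#'
#' @param config a [phantom_config].
#' @return an object of class `cryo_phantom`: a list with `stack`
#'   (a [fluor_stack]), `truth` (per-cell and per-cluster data frames) and
#'   `config`.
#' @export
generate_phantom <- function(config) {
  validate_phantom_config(config)
  with_seed(config$seed, generate_phantom_impl(config))
}

generate_phantom_impl <- function(cfg) {
  ns <- cfg$image_shape[1]; nr <- cfg$image_shape[2]; nc <- cfg$image_shape[3]
  sizes <- if (cfg$n_clusters > 0)
    sample.int(length(cfg$cluster_size_pmf), cfg$n_clusters, replace = TRUE,
               prob = cfg$cluster_size_pmf) else integer()
  max_n <- length(cfg$cluster_size_pmf)
  r_cluster <- cfg$min_sep_px * (1 + sqrt(max_n))
  sep_xy <- 2 * (3 * cfg$sigma_px + r_cluster) + 2
  border <- 3 * cfg$sigma_px + r_cluster + 2
  if (cfg$n_clusters > 0 && (nr - 2 * border < 1 || nc - 2 * border < 1))
    stop("image too small for any cluster placement")

  cx <- cy <- cs <- numeric(cfg$n_clusters)
  tries <- 0; max_tries <- max(1000, 1000 * cfg$n_clusters)
  for (i in seq_len(cfg$n_clusters)) {
    repeat {
      tries <- tries + 1
      if (tries > max_tries)
        stop(sprintf("infeasible cluster placement: %d clusters do not fit after %d tries",
                     cfg$n_clusters, max_tries))
      x <- runif(1, border + 1, nc - border)
      y <- runif(1, border + 1, nr - border)
      s <- sample.int(ns, 1)
      if (i == 1) { ok <- TRUE } else {
        prev <- seq_len(i - 1)
        near <- abs(cs[prev] - s) <= 2
        ok <- !any(near & sqrt((cx[prev] - x)^2 + (cy[prev] - y)^2) < sep_xy)
      }
      if (ok) { cx[i] <- x; cy[i] <- y; cs[i] <- s; break }
    }
  }

  red_sig <- array(0, c(nr, nc, ns))
  cells <- vector("list", cfg$n_clusters)
  half <- ceiling(5 * cfg$sigma_px) + 1
  cell_id <- 0
  for (i in seq_len(cfg$n_clusters)) {
    n <- sizes[i]
    off <- place_cluster_cells(n, cfg$min_sep_px)
    xs <- cx[i] + off[, 1]; ys <- cy[i] + off[, 2]
    I <- rnorm(n, cfg$intensity_mean, cfg$intensity_cv * cfg$intensity_mean)
    I <- pmax(I, 0.2 * cfg$intensity_mean)
    z <- ifelse(cs[i] < ns & runif(n) < cfg$split_prob, runif(n, 0.15, 0.5), 0)
    for (j in seq_len(n)) {
      cell_id <- cell_id + 1
      r0 <- max(1, floor(ys[j]) - half); r1 <- min(nr, ceiling(ys[j]) + half)
      c0 <- max(1, floor(xs[j]) - half); c1 <- min(nc, ceiling(xs[j]) + half)
      patch <- render_cell(xs[j] - c0 + 1, ys[j] - r0 + 1, I[j], cfg$sigma_px,
                           c(r1 - r0 + 1, c1 - c0 + 1))
      red_sig[r0:r1, c0:c1, cs[i]] <-
        red_sig[r0:r1, c0:c1, cs[i]] + (1 - z[j]) * patch
      if (z[j] > 0)
        red_sig[r0:r1, c0:c1, cs[i] + 1] <-
          red_sig[r0:r1, c0:c1, cs[i] + 1] + z[j] * patch
    }
    cells[[i]] <- data.frame(cluster_id = i,
                             cell_id = cell_id - n + seq_len(n),
                             x = xs, y = ys, slice = cs[i], z_frac = z,
                             intensity = I)
  }
  cells <- if (cfg$n_clusters > 0) do.call(rbind, cells) else
    data.frame(cluster_id = integer(), cell_id = integer(), x = numeric(),
               y = numeric(), slice = integer(), z_frac = numeric(),
               intensity = numeric())

  clusters <- if (cfg$n_clusters > 0) {
    m <- 3 * cfg$sigma_px
    do.call(rbind, lapply(seq_len(cfg$n_clusters), function(i) {
      cc <- cells[cells$cluster_id == i, , drop = FALSE]
      data.frame(cluster_id = i, n_cells = nrow(cc),
                 x0 = max(1, floor(min(cc$x) - m)),
                 x1 = min(nc, ceiling(max(cc$x) + m)),
                 y0 = max(1, floor(min(cc$y) - m)),
                 y1 = min(nr, ceiling(max(cc$y) + m)),
                 s0 = min(cc$slice),
                 s1 = max(cc$slice + (cc$z_frac > 0)))
    }))
  } else data.frame(cluster_id = integer(), n_cells = integer(),
                    x0 = integer(), x1 = integer(), y0 = integer(),
                    y1 = integer(), s0 = integer(), s1 = integer())

  green_sig <- red_sig / cfg$cell_rg_ratio

  # subsurface fluorescence: the image of section k also sees a blurred,
  # attenuated copy of the not-yet-cut section k + 1
  red <- red_sig; green <- green_sig
  if (cfg$bleed_fraction > 0 && ns > 1) {
    for (k in seq_len(ns - 1)) {
      red[, , k] <- red[, , k] + cfg$bleed_fraction *
        gaussian_blur2d(red_sig[, , k + 1], cfg$bleed_blur_sigma)
      green[, , k] <- green[, , k] + cfg$bleed_fraction *
        gaussian_blur2d(green_sig[, , k + 1], cfg$bleed_blur_sigma)
    }
  }

  if (cfg$background_level > 0) {
    for (k in seq_len(ns)) {
      f <- gaussian_blur2d(matrix(rnorm(nr * nc), nr, nc),
                           cfg$background_smooth_px)
      f <- f / max(sd(f), 1e-12)
      bg_g <- pmax(cfg$background_level * (1 + cfg$background_amp * f), 0)
      green[, , k] <- green[, , k] + bg_g
      red[, , k] <- red[, , k] + cfg$background_rg_ratio * bg_g
    }
  }

  if (cfg$noise_sd > 0) {
    red <- red + array(rnorm(length(red), 0, cfg$noise_sd), dim(red))
    green <- green + array(rnorm(length(green), 0, cfg$noise_sd), dim(green))
  }
  red <- pmax(red, 0); green <- pmax(green, 0)

  structure(list(stack = fluor_stack(red, green, cfg$pixel_size_um,
                                     cfg$section_um),
                 truth = list(cells = cells, clusters = clusters),
                 config = cfg),
            class = "cryo_phantom")
}

#' @export
print.cryo_phantom <- function(x, ...) {
  cat(sprintf("<cryo_phantom> %d clusters, %d cells\n",
              nrow(x$truth$clusters), nrow(x$truth$cells)))
  print(x$stack)
  invisible(x)
}

#' Generate a culture-like image of well-separated single cells
#'
#' Emulates an image of cells in culture used to calibrate the high
#' hysteresis threshold: one slice, singleton clusters only, no
#' bleed-through and no sectioning.
#'
#' @param config a [phantom_config]; slices, cluster-size distribution,
#'   bleed and sectioning are overridden.
#' @param n_cells number of singleton cells.
#' @return a `cryo_phantom` with a single-slice stack.
#' @export
generate_culture_image <- function(config, n_cells = 150) {
  cfg <- config
  cfg$image_shape <- c(1L, cfg$image_shape[2], cfg$image_shape[3])
  cfg$n_clusters <- as.integer(n_cells)
  cfg$cluster_size_pmf <- 1
  cfg$bleed_fraction <- 0
  cfg$split_prob <- 0
  class(cfg) <- "phantom_config"
  generate_phantom(cfg)
}

#' Write / read phantom ground truth as CSV
#'
#' Columns: `cluster_id, cell_id, x, y, slice, z_frac, intensity`.
#' `read_ground_truth()` rebuilds the per-cluster table from the cells.
#'
#' @param truth the `truth` element of a `cryo_phantom`.
#' @param path CSV file path.
#' @export
write_ground_truth <- function(truth, path) {
  write.csv(truth$cells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  cells <- read.csv(path)
  ids <- sort(unique(cells$cluster_id))
  clusters <- do.call(rbind, lapply(ids, function(i) {
    cc <- cells[cells$cluster_id == i, , drop = FALSE]
    data.frame(cluster_id = i, n_cells = nrow(cc),
               x0 = floor(min(cc$x)) , x1 = ceiling(max(cc$x)),
               y0 = floor(min(cc$y)), y1 = ceiling(max(cc$y)),
               s0 = min(cc$slice), s1 = max(cc$slice + (cc$z_frac > 0)))
  }))
  if (is.null(clusters))
    clusters <- data.frame(cluster_id = integer(), n_cells = integer())
  list(cells = cells, clusters = clusters)
}
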