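# Independent reference implementations used to cross-check the package's
# compiled kernels, plus small fixture builders.

# Brute-force grayscale reconstruction: geodesic dilation (8-connectivity,
# via EBImage's 3x3 dilation) followed by a pointwise minimum with the
# mask, iterated to the fixpoint.
reconstruct_bruteforce <- function(marker, mask) {
  M <- max(mask, 1e-12)
  J <- pmin(marker, mask)
  kern <- EBImage::makeBrush(3, "box")
  repeat {
    Jn <- pmin(matrix(as.numeric(EBImage::dilate(J / M, kern)) * M,
                      nrow(mask), ncol(mask)), mask)
    if (isTRUE(all.equal(Jn, J, tolerance = 0))) return(Jn)
    J <- Jn
  }
}

# Brute-force hysteresis by flood fill: seed at voxels above the high
# threshold and grow through 26-connected voxels above the low threshold.
hysteresis_floodfill <- function(x, t_h, t_l) {
  d <- dim(x)
  low <- x > t_l
  out <- array(FALSE, d)
  q <- which(x > t_h & low)
  out[q] <- TRUE
  q <- as.list(q)
  while (length(q)) {
    i <- q[[1]]; q <- q[-1]
    co <- arrayInd(i, d)
    for (dr in -1:1) for (dc in -1:1) for (ds in -1:1) {
      r <- co[1] + dr; cc <- co[2] + dc; s <- co[3] + ds
      if (r < 1 || r > d[1] || cc < 1 || cc > d[2] || s < 1 || s > d[3]) next
      j <- r + (cc - 1) * d[1] + (s - 1) * d[1] * d[2]
      if (low[j] && !out[j]) { out[j] <- TRUE; q <- c(q, j) }
    }
  }
  out
}

# Numerical pixel integration of the 2D Gaussian by midpoint supersampling
# (independent of the error-function evaluation in render_cell).
render_cell_supersample <- function(x_c, y_c, I_t, sigma, patch_shape,
                                    k = 21) {
  nr <- patch_shape[1]; nc <- patch_shape[2]
  out <- matrix(0, nr, nc)
  off <- (seq_len(k) - (k + 1) / 2) / k
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    xs <- cc + off; ys <- r + off
    gx <- dnorm(xs, x_c, sigma); gy <- dnorm(ys, y_c, sigma)
    out[r, cc] <- I_t * sum(outer(gy, gx)) / k^2
  }
  out
}

# A fixed single-cell model without running calibration.
toy_model <- function(sigma = 1, I_t = 1000, d_min = 1) {
  calibrate_model(list(list(sigma = sigma, I_t = I_t, converged = TRUE)),
                  d_min = d_min)
}

# Small, fast phantom configuration for unit tests.
small_config <- function(...) {
  phantom_config(image_shape = c(5, 160, 160), n_clusters = 20, ...)
}
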