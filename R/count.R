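#' Select singleton clusters for single-cell calibration
#'
#' Cells are 3-4 times smaller than the section thickness, so clusters
#' confined to a single section whose volume and integrated intensity fall
#' near the largest histogram peaks are assumed to be single cells.
#'
#' @param features cluster feature table (kept clusters are used when a
#'   `kept` column is present).
#' @param volume_range,intensity_range numeric `c(low, high)` windows.
#' @return the subset of `features` treated as singletons.
#' @export
select_singletons <- function(features, volume_range, intensity_range) {
  if (nrow(features) == 0) stop("no clusters to select singletons from")
  keep <- if ("kept" %in% names(features)) features$kept else TRUE
  sel <- keep & features$slice_span == 1 &
    features$volume >= volume_range[1] & features$volume <= volume_range[2] &
    features$intensity >= intensity_range[1] &
    features$intensity <= intensity_range[2]
  if (!any(sel)) stop("no singleton clusters found in the given ranges")
  features[sel, , drop = FALSE]
}

#' Singleton windows from feature histogram peaks
#'
#' Locates the dominant peak of the integrated-intensity distribution of
#' single-slice clusters (the single-cell peak; the two-cell peak sits at
#' about twice its location) and returns symmetric windows around it and
#' around the corresponding modal volume.
#'
#' @param features cluster feature table.
#' @param width half-width of the intensity window as a fraction of the
#'   peak location; 0.4 keeps the window below the two-cell peak.
#' @return list with `intensity_range` and `volume_range`.
#' @export
singleton_ranges <- function(features, width = 0.4) {
  keep <- if ("kept" %in% names(features)) features$kept else TRUE
  f <- features[keep & features$slice_span == 1, , drop = FALSE]
  if (nrow(f) == 0) stop("no single-slice clusters available")
  peak <- if (nrow(f) >= 5) {
    # bandwidth well below the single-cell spacing so the 1- and 2-cell
    # modes are not smoothed into one
    d <- density(f$intensity, bw = max(0.1 * median(f$intensity), 1e-9))
    d$x[which.max(d$y)]
  } else median(f$intensity)
  intensity_range <- peak * c(1 - width, 1 + width)
  inwin <- f$intensity >= intensity_range[1] & f$intensity <= intensity_range[2]
  vmode <- if (any(inwin)) median(f$volume[inwin]) else median(f$volume)
  list(intensity_range = intensity_range,
       volume_range = c(floor(0.4 * vmode), ceiling(1.9 * vmode)))
}

#' Fit a single pixel-integrated Gaussian to a cluster patch
#'
#' Least-squares fit of width, total intensity and sub-pixel center to a
#' 2D patch, with a derivative-free simplex (default) or a
#' Levenberg-Marquardt backend.
#'
#' @param patch 2D matrix (a one-slice 3D array is accepted).
#' @param method `"nelder-mead"` or `"lm"`.
#' @param init optional named list (`x`, `y`, `sigma`, `I_t`) of starting
#'   values; defaults to the intensity-weighted centroid and patch sum.
#' @return list with `x`, `y`, `sigma`, `I_t`, `residual` (sum of squared
#'   errors) and `converged`.
#' @export
fit_single_cell <- function(patch, method = c("nelder-mead", "lm"),
                            init = NULL) {
  method <- match.arg(method)
  if (length(dim(patch)) == 3) {
    if (dim(patch)[3] != 1) stop("fit_single_cell expects a single-slice patch")
    patch <- patch[, , 1]
  }
  stopifnot(is.matrix(patch))
  total <- sum(patch)
  if (total <= 0) stop("patch has no positive intensity")
  nr <- nrow(patch); nc <- ncol(patch)
  cx <- sum(colSums(patch) * seq_len(nc)) / total
  cy <- sum(rowSums(patch) * seq_len(nr)) / total
  p0 <- c(init$x %||% cx, init$y %||% cy, init$sigma %||% 1,
          init$I_t %||% total)
  model <- function(p) render_cell(p[1], p[2], abs(p[4]) + 1e-12,
                                   abs(p[3]) + 1e-6, c(nr, nc))
  if (method == "nelder-mead") {
    fn <- function(p) sum((patch - model(p))^2)
    res <- optim(p0, fn, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-12))
    p <- res$par; conv <- res$convergence == 0; rss <- res$value
  } else {
    resid <- function(p) as.numeric(patch - model(p))
    res <- minpack.lm::nls.lm(p0, fn = resid,
                              control = minpack.lm::nls.lm.control(maxiter = 500))
    p <- res$par; conv <- res$info %in% 1:4; rss <- sum(res$fvec^2)
  }
  list(x = p[1], y = p[2], sigma = abs(p[3]), I_t = abs(p[4]),
       residual = rss, converged = conv)
}

#' Average single-cell fits into the calibrated cell model
#'
#' @param fits list of results from [fit_single_cell()]; fits flagged
#'   non-converged are dropped.
#' @param d_min minimum allowed distance between fitted cell centers,
#'   in pixels (approximately one cell diameter).
#' @return an object of class `cell_model` with fields `sigma`, `I_t`,
#'   `d_min`, the per-fit spreads and the number of fits used.
#' @export
calibrate_model <- function(fits, d_min = 1) {
  stopifnot(d_min > 0)
  fits <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(fits) == 0) stop("all single-cell fits failed")
  sig <- vapply(fits, `[[`, numeric(1), "sigma")
  it <- vapply(fits, `[[`, numeric(1), "I_t")
  structure(list(sigma = mean(sig), I_t = mean(it), d_min = d_min,
                 sigma_sd = if (length(sig) > 1) sd(sig) else 0,
                 I_t_sd = if (length(it) > 1) sd(it) else 0,
                 n_fits = length(fits)),
            class = "cell_model")
}

#' @export
print.cell_model <- function(x, ...) {
  cat(sprintf("<cell_model> sigma = %.3f px (sd %.3f), I_t = %.1f (sd %.1f), D_min = %.2f px; %d singleton fits\n",
              x$sigma, x$sigma_sd, x$I_t, x$I_t_sd, x$d_min, x$n_fits))
  invisible(x)
}

#' Calibrate the cell model from a segmented volume
#'
#' Selects singleton clusters (windows from [singleton_ranges()] unless
#' given), fits each one with [fit_single_cell()] and averages the
#' parameters.
#'
#' @param igray working volume.
#' @param clusters a `cluster_set` from [detect_clusters()].
#' @param d_min minimum center separation for the model, pixels.
#' @param ranges optional list with `intensity_range` and `volume_range`.
#' @param pad patch padding in x and y, pixels.
#' @param method optimizer backend for [fit_single_cell()].
#' @return a `cell_model`.
#' @export
calibrate_cell_model <- function(igray, clusters, d_min = 1, ranges = NULL,
                                 pad = 2, method = "nelder-mead") {
  ranges <- ranges %||% singleton_ranges(clusters$features)
  singles <- select_singletons(clusters$features, ranges$volume_range,
                               ranges$intensity_range)
  fits <- lapply(seq_len(nrow(singles)), function(i) {
    p <- extract_patch(clusters$labels, igray, singles[i, ], pad = pad)
    tryCatch(fit_single_cell(p$patch, method = method),
             error = function(e) list(converged = FALSE))
  })
  calibrate_model(fits, d_min = d_min)
}

#' Initial estimate of cells per cluster
#'
#' Integrated cluster intensity divided by the single-cell intensity,
#' rounded half-up to the nearest integer and floored at one.
#'
#' @param intensity integrated cluster intensity (vectorized).
#' @param i_t calibrated single-cell total intensity (> 0).
#' @return integer vector of initial estimates.
#' @export
initial_estimate <- function(intensity, i_t) {
  if (i_t <= 0) stop("i_t must be positive")
  as.integer(pmax(1, round_half_up(intensity / i_t)))
}

#' Candidate cell counts around the initial estimate
#'
#' Integers within `max(2, 30%)` of the initial estimate, clipped below
#' at one (the 30% half-width is rounded half-up to an integer).
#'
#' @param n_init initial estimate (>= 1).
#' @return increasing integer vector of candidate counts.
#' @export
candidate_range <- function(n_init) {
  stopifnot(n_init >= 1)
  hw <- max(2, round_half_up(0.30 * n_init))
  seq.int(max(1, n_init - hw), n_init + hw)
}

#' Extract a padded cluster patch from the working volume
#'
#' The patch is the cluster bounding box padded by `pad` pixels in x and y
#' (recovering tail pixels missed by the low threshold); voxels belonging
#' to other labeled clusters are zeroed.
#'
#' @param labels label volume.
#' @param igray working volume.
#' @param feat one row of the cluster feature table.
#' @param pad padding in pixels.
#' @return list with `patch` (3D array) and `origin`
#'   (`c(row0, col0, slice0)`, 1-based).
#' @export
extract_patch <- function(labels, igray, feat, pad = 2) {
  d <- dim(as_volume(igray))
  r <- max(1, feat$y0 - pad):min(d[1], feat$y1 + pad)
  cc <- max(1, feat$x0 - pad):min(d[2], feat$x1 + pad)
  s <- feat$s0:feat$s1
  patch <- as_volume(igray)[r, cc, s, drop = FALSE]
  lab <- as_volume(labels)[r, cc, s, drop = FALSE]
  patch[lab != 0 & lab != feat$id] <- 0
  list(patch = patch, origin = c(r[1], cc[1], s[1]))
}

# Initial placements for n model cells by greedy matching pursuit: each
# cell is seeded at the maximum of the residual left after subtracting the
# model renderings of the cells already placed, so a merged pair (one
# joint intensity maximum) still seeds its second cell on the residual
# shoulder. Jitter is only used when the residual is exhausted.
init_placements <- function(patch, n, model, jitter_sd = 0.5) {
  d <- dim(patch)
  resid <- patch
  out <- data.frame(x = numeric(n), y = numeric(n), home = numeric(n))
  total <- sum(patch)
  if (total <= 0) total <- 1
  cx <- sum(patch * rep(seq_len(d[2]), each = d[1])) / total
  cy <- sum(patch * rep(seq_len(d[1]), times = d[2] * d[3])) / total
  for (k in seq_len(n)) {
    i <- which.max(resid)
    if (resid[i] > 0) {
      co <- arrayInd(i, d)
      x <- co[2]; y <- co[1]; s <- co[3]
    } else {
      x <- cx + rnorm(1, 0, jitter_sd)
      y <- cy + rnorm(1, 0, jitter_sd)
      s <- which.max(vapply(seq_len(d[3]), function(j) sum(patch[, , j]),
                            numeric(1)))
    }
    out$x[k] <- x; out$y[k] <- y; out$home[k] <- s
    resid <- resid - render_placements(data.frame(x = x, y = y,
                                                  home = s, z = 0),
                                       model, d)
  }
  out
}

# Random initial placements (restart studies): centers uniform over the
# patch, axial position uniform over the slice span.
random_placements <- function(patch, n) {
  d <- dim(patch)
  data.frame(x = runif(n, 0.5, d[2] + 0.5),
             y = runif(n, 0.5, d[1] + 0.5),
             home = runif(n, 1, d[3]))
}

#' Fit n model cells to a cluster patch
#'
#' Minimizes the sum over patch voxels of the squared difference between
#' the working volume and the superposition of `n` model cells with fixed
#' width and intensity and free sub-pixel centers; for multi-slice patches
#' each cell also has a free continuous axial position whose integer part
#' is the home slice and whose fractional part is the split fraction
#' apportioned to the next slice (a sectioned cell). Centers of
#' near-coplanar cells are kept at least `D_min` apart by a smooth
#' quadratic penalty, and all centers are confined to the patch domain.
#' Optimization uses the Nelder-Mead simplex, seeded at the brightest
#' local maxima.
#'
#' @param patch 3D patch from [extract_patch()].
#' @param n number of model cells (>= 1).
#' @param model a `cell_model`.
#' @param seed RNG seed for initialization randomness (reproducibility).
#' @param maxit iteration cap (default 10000).
#' @param reltol relative objective-change tolerance.
#' @param jitter_sd SD (pixels) of centroid jitter for surplus cells.
#' @param init `"residual"` (greedy matching-pursuit seeding, default) or
#'   `"random"` (uniform over the patch, for restart studies).
#' @return list with `placements` (data frame `x`, `y`, `home`, `z` in
#'   patch coordinates), `f_obj` (objective at the optimum, penalties
#'   included), `sse` (penalty-free residual), `converged`, `n`.
#' @export
fit_n_cells <- function(patch, n, model, seed = NULL, maxit = 10000,
                        reltol = 1e-6, jitter_sd = 0.5,
                        init = c("residual", "random")) {
  stopifnot(n >= 1, inherits(model, "cell_model"))
  init <- match.arg(init)
  patch <- as_volume(patch)
  d <- dim(patch)
  lambda <- model$I_t^2
  init <- with_seed(seed, switch(init,
    residual = init_placements(patch, n, model, jitter_sd),
    random = random_placements(patch, n)))
  single <- d[3] == 1
  p_full <- as.numeric(rbind(init$x, init$y, init$home))
  act <- if (single) which(rep(c(TRUE, TRUE, FALSE), n)) else seq_along(p_full)
  fn <- function(pa) {
    p <- p_full
    p[act] <- pa
    cpp_mix_obj(p, as.numeric(patch), as.integer(d),
                model$I_t, model$sigma, model$d_min, lambda)
  }
  res <- optim(p_full[act], fn, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = reltol))
  # restart once from the endpoint with a fresh simplex: guards against
  # premature simplex collapse on this multimodal objective
  res2 <- optim(res$par, fn, method = "Nelder-Mead",
                control = list(maxit = maxit, reltol = reltol))
  if (res2$value <= res$value) res <- res2
  # greedy reseat: a local minimum can strand two cells on one intensity
  # peak; relocating a cell to the maximum of the residual (patch minus
  # the other cells' model) repairs that. Costs one objective evaluation
  # per cell when already converged.
  p_best <- p_full
  p_best[act] <- res$par
  f_best <- res$value
  if (n > 1) {
    for (round in 1:2) {
      improved <- FALSE
      for (j in seq_len(n)) {
        others <- p_best[-(3 * j - 2):-(3 * j)]
        resid <- patch - array(cpp_render_mixture(others, as.integer(d),
                                                  model$I_t, model$sigma), d)
        i <- which.max(resid)
        if (resid[i] <= 0) next
        co <- arrayInd(i, d)
        p_try <- p_best
        p_try[(3 * j - 2):(3 * j)] <- c(co[2], co[1], co[3])
        f_try <- cpp_mix_obj(p_try, as.numeric(patch), as.integer(d),
                             model$I_t, model$sigma, model$d_min, lambda)
        if (f_try < f_best) {
          p_full <- p_try
          r2 <- optim(p_try[act], fn, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = reltol))
          if (r2$value < f_best) {
            f_best <- r2$value
            p_best <- p_full
            p_best[act] <- r2$par
            res <- r2
            improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
  }
  p_full <- p_best
  res$par <- p_best[act]
  res$value <- f_best
  p <- p_full
  p[act] <- res$par
  zc <- clamp(p[seq(3, 3 * n, by = 3)], 1, d[3])
  home <- pmin(as.integer(floor(zc)), d[3])
  placements <- data.frame(x = p[seq(1, 3 * n, by = 3)],
                           y = p[seq(2, 3 * n, by = 3)],
                           home = home, z = zc - home)
  sse <- sum((as.numeric(patch) -
                cpp_render_mixture(as.numeric(rbind(placements$x,
                                                    placements$y, zc)),
                                   as.integer(d), model$I_t,
                                   model$sigma))^2)
  list(placements = placements, f_obj = res$value, sse = sse,
       converged = res$convergence == 0, n = n)
}

#' Count the cells in one cluster
#'
#' Fits every candidate count from [candidate_range()] around the initial
#' estimate and designates the count with the minimal objective; exact
#' ties go to the smaller count. The result is flagged ambiguous when the
#' two best objectives differ by less than 20% (relative to the smaller).
#'
#' @param patch 3D cluster patch.
#' @param model a `cell_model`.
#' @param intensity integrated cluster intensity used for the initial
#'   estimate; defaults to the patch sum.
#' @param seed RNG seed (per-candidate seeds are derived from it).
#' @param ... passed to [fit_n_cells()].
#' @return list with `n_init`, `candidates` (data frame of `n`, `f_obj`,
#'   `sse`, `converged`), `n_est`, `f_obj`, `ambiguous`, `placements` of
#'   the chosen fit (`NULL` when no candidate converged).
#' @export
count_cluster <- function(patch, model, intensity = NULL, seed = NULL, ...) {
  patch <- as_volume(patch)
  intensity <- intensity %||% sum(patch)
  n0 <- initial_estimate(intensity, model$I_t)
  cand <- candidate_range(n0)
  fits <- lapply(seq_along(cand), function(i)
    fit_n_cells(patch, cand[i], model,
                seed = if (is.null(seed)) NULL else seed + i, ...))
  df <- data.frame(n = cand,
                   f_obj = vapply(fits, `[[`, numeric(1), "f_obj"),
                   sse = vapply(fits, `[[`, numeric(1), "sse"),
                   converged = vapply(fits, `[[`, logical(1), "converged"))
  ok <- which(df$converged)
  if (length(ok) == 0)
    return(list(n_init = n0, candidates = df, n_est = NA_integer_,
                f_obj = NA_real_, ambiguous = NA, placements = NULL))
  fo <- df$f_obj[ok]
  best <- ok[which(fo <= min(fo) * (1 + 1e-9))[1]]  # ties: smaller n
  amb <- if (length(ok) >= 2) {
    f_sorted <- sort(fo)[1:2]
    if (f_sorted[1] == 0) f_sorted[2] == 0 else
      (f_sorted[2] - f_sorted[1]) < 0.20 * f_sorted[1]
  } else FALSE
  list(n_init = n0, candidates = df, n_est = df$n[best],
       f_obj = df$f_obj[best], ambiguous = amb,
       placements = fits[[best]]$placements)
}

#' Count cells in every kept cluster of a segmented volume
#'
#' @param clusters a `cluster_set` from [detect_clusters()].
#' @param igray working volume.
#' @param model a `cell_model`.
#' @param pad patch padding in x and y, pixels.
#' @param seed base RNG seed; per-cluster seeds are derived from it.
#' @param ... passed to [fit_n_cells()].
#' @return an object of class `count_result`: a data frame with one row
#'   per kept cluster (`cluster_id`, `n_init`, `n_est`, `f_obj`,
#'   `ambiguous`, `converged`, cluster features), with the per-candidate
#'   objectives in `attr(, "candidates")` and the fitted cell placements
#'   (absolute stack coordinates) in `attr(, "placements")`.
#' @export
count_clusters <- function(clusters, igray, model, pad = 2, seed = 1, ...) {
  feats <- clusters$features[clusters$features$kept, , drop = FALSE]
  rows <- vector("list", nrow(feats))
  cands <- vector("list", nrow(feats))
  plc <- vector("list", nrow(feats))
  for (i in seq_len(nrow(feats))) {
    f <- feats[i, ]
    p <- extract_patch(clusters$labels, igray, f, pad = pad)
    res <- count_cluster(p$patch, model, intensity = f$intensity,
                         seed = seed + 101 * i, ...)
    rows[[i]] <- data.frame(cluster_id = f$id, n_init = res$n_init,
                            n_est = res$n_est, f_obj = res$f_obj,
                            ambiguous = res$ambiguous,
                            converged = !is.na(res$n_est),
                            intensity = f$intensity, volume = f$volume,
                            com_x = f$com_x, com_y = f$com_y,
                            com_z = f$com_z, slice_span = f$slice_span)
    cands[[i]] <- cbind(cluster_id = f$id, res$candidates)
    if (!is.null(res$placements)) {
      pl <- res$placements
      pl$x <- pl$x + p$origin[2] - 1
      pl$y <- pl$y + p$origin[1] - 1
      pl$home <- pl$home + p$origin[3] - 1L
      plc[[i]] <- cbind(cluster_id = f$id, pl)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = integer(), n_init = integer(),
               n_est = integer(), f_obj = numeric(), ambiguous = logical(),
               converged = logical(), intensity = numeric(),
               volume = integer(), com_x = numeric(), com_y = numeric(),
               com_z = numeric(), slice_span = integer())
  attr(out, "candidates") <- if (length(cands)) do.call(rbind, cands) else NULL
  attr(out, "placements") <- if (length(plc)) do.call(rbind, plc) else NULL
  class(out) <- c("count_result", class(out))
  out
}

#' @export
print.count_result <- function(x, ...) {
  cat(sprintf("<count_result> %d clusters, %d cells total; %d ambiguous, %d non-converged\n",
              nrow(x), sum(x$n_est, na.rm = TRUE),
              sum(x$ambiguous %in% TRUE), sum(!x$converged)))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' @export
summary.count_result <- function(object, ...) {
  tab <- table(factor(object$n_est))
  cat("Estimated cells per cluster:\n")
  print(tab)
  cat(sprintf("Total cells: %d; ambiguous clusters: %.1f%%; non-converged: %d\n",
              sum(object$n_est, na.rm = TRUE),
              100 * mean(object$ambiguous %in% TRUE),
              sum(!object$converged)))
  invisible(list(counts = tab, total = sum(object$n_est, na.rm = TRUE)))
}

#' @export
plot.count_result <- function(x, ...) {
  barplot(table(factor(x$n_est)), xlab = "estimated cells per cluster",
          ylab = "clusters", ...)
  invisible(x)
}

#' Render the fitted model image of a cluster
#'
#' Superposition of the fitted cell placements, for visual comparison with
#' the observed patch.
#'
#' @param placements data frame `x`, `y`, `home`, `z` in patch coordinates.
#' @param model a `cell_model`.
#' @param dims patch dimensions `(rows, cols, slices)`.
#' @return 3D numeric array.
#' @export
render_placements <- function(placements, model, dims) {
  par <- as.numeric(rbind(placements$x, placements$y,
                          placements$home + placements$z))
  array(cpp_render_mixture(par, as.integer(dims), model$I_t, model$sigma),
        dims)
}
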