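#' Detection configuration
#'
#' @param t_h high hysteresis threshold; `NULL` to calibrate from a
#'   culture image via [compute_th()].
#' @param t_l low hysteresis threshold; `NULL` to compute from the working
#'   volume via [compute_tl()].
#' @param c_low constant multiplying the image SD in the low-threshold
#'   rule (1.4 or greater suppresses most autofluorescence).
#' @param t_v maximum allowed cluster volume in voxels; larger clusters
#'   are rejected as false positives.
#' @param ratio_range allowed range of integrated-intensity-to-volume
#'   ratio, `c(low, high)`; clusters outside are rejected.
#' @param connectivity 3D voxel connectivity, 26 (default) or 6.
#' @return an object of class `detect_config`.
#' @export
detect_config <- function(t_h = NULL, t_l = NULL, c_low = 1.4,
                          t_v = 500, ratio_range = c(2, 2000),
                          connectivity = 26) {
  if (!is.null(t_h) && !is.null(t_l) && t_h <= t_l)
    stop("t_h must exceed t_l")
  if (c_low < 0) stop("c_low must be >= 0")
  if (t_v < 1) stop("t_v must be >= 1")
  if (length(ratio_range) != 2 || ratio_range[2] <= ratio_range[1])
    stop("ratio_range must be c(low, high) with high > low")
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  structure(list(t_h = t_h, t_l = t_l, c_low = c_low, t_v = t_v,
                 ratio_range = ratio_range, connectivity = connectivity),
            class = "detect_config")
}

#' High hysteresis threshold from culture cluster maxima
#'
#' `0.6 * min` of the per-cluster maximum intensities observed in an image
#' of well-separated cells in culture, guaranteeing that every cluster at
#' least as bright as the dimmest culture cell retains a high-threshold
#' voxel.
#'
#' @param culture_cluster_maxima numeric vector of per-cluster maximum
#'   intensities (non-empty).
#' @return the high threshold.
#' @export
compute_th <- function(culture_cluster_maxima) {
  if (length(culture_cluster_maxima) == 0)
    stop("culture_cluster_maxima must be non-empty")
  0.6 * min(culture_cluster_maxima)
}

#' Low hysteresis threshold from image statistics
#'
#' Mean plus `c_low` standard deviations of all voxel intensities of the
#' working volume (zeros included).
#'
#' @param igray working volume (array).
#' @param c_low non-negative constant, default 1.4.
#' @return the low threshold.
#' @export
compute_tl <- function(igray, c_low = 1.4) {
  if (c_low < 0) stop("c_low must be >= 0")
  v <- as.numeric(igray)
  s <- if (length(v) > 1) sd(v) else 0
  mean(v) + c_low * s
}

# 3D connected-component labels of a logical volume.
label_components <- function(mask, connectivity = 26) {
  mask <- as_volume(mask)
  lab <- cpp_label3d(as.logical(mask), as.integer(dim(mask)),
                     as.integer(connectivity))
  array(lab, dim(mask))
}

#' Hysteresis thresholding
#'
#' A voxel is retained when it exceeds the low threshold and belongs to a
#' low-threshold connected component containing at least one voxel above
#' the high threshold. Both comparisons are strict. Applied in 3D so a
#' sectioned cell split across adjacent slices stays one cluster.
#'
#' @param igray working volume (array; a matrix is treated as one slice).
#' @param t_h,t_l high and low thresholds, `t_h >= t_l`.
#' @param connectivity 26 (default) or 6.
#' @return logical array of the same dimensions.
#' @export
hysteresis_threshold <- function(igray, t_h, t_l, connectivity = 26) {
  if (t_h < t_l) stop("t_h must be >= t_l")
  x <- as_volume(igray)
  low <- x > t_l
  labels <- label_components(low, connectivity)
  keep <- unique(labels[x > t_h])
  keep <- keep[keep > 0]
  array(labels %in% keep, dim(x))
}

#' Connected components and cluster features
#'
#' Labels each maximal connected voxel set of a binary volume and computes
#' its features from the working volume: volume (voxel count), integrated
#' intensity, intensity/volume ratio, intensity-weighted center of mass,
#' bounding box and slice span.
#'
#' @param mask logical volume.
#' @param igray working volume of identical dimensions.
#' @param connectivity 26 (default) or 6.
#' @return a list with `labels` (integer array) and `features`
#'   (one row per cluster).
#' @export
connected_components <- function(mask, igray, connectivity = 26) {
  mask <- as_volume(mask)
  igray <- as_volume(igray)
  stopifnot(identical(dim(mask), dim(igray)))
  labels <- label_components(mask, connectivity)
  idx <- which(mask)
  if (length(idx) == 0) {
    features <- data.frame(id = integer(), volume = integer(),
                           intensity = numeric(), ratio = numeric(),
                           com_x = numeric(), com_y = numeric(),
                           com_z = numeric(), x0 = integer(), x1 = integer(),
                           y0 = integer(), y1 = integer(), s0 = integer(),
                           s1 = integer(), slice_span = integer())
    return(list(labels = labels, features = features))
  }
  lab <- labels[idx]
  co <- arrayInd(idx, dim(mask))
  val <- igray[idx]
  f <- factor(lab, levels = sort(unique(lab)))
  vol <- as.integer(tabulate(f))
  inten <- as.numeric(rowsum(val, f))
  wx <- as.numeric(rowsum(val * co[, 2], f)) / inten
  wy <- as.numeric(rowsum(val * co[, 1], f)) / inten
  wz <- as.numeric(rowsum(val * co[, 3], f)) / inten
  rng <- function(v, fn) as.integer(tapply(v, f, fn))
  features <- data.frame(id = as.integer(levels(f)), volume = vol,
                         intensity = inten, ratio = inten / vol,
                         com_x = wx, com_y = wy, com_z = wz,
                         x0 = rng(co[, 2], min), x1 = rng(co[, 2], max),
                         y0 = rng(co[, 1], min), y1 = rng(co[, 1], max),
                         s0 = rng(co[, 3], min), s1 = rng(co[, 3], max))
  features$slice_span <- features$s1 - features$s0 + 1L
  list(labels = labels, features = features)
}

#' Knowledge-based false-positive rejection
#'
#' Rejects clusters whose volume exceeds `t_v` (bright autofluorescent
#' regions such as gut or bone) or whose integrated-intensity-to-volume
#' ratio falls outside `ratio_range` (structures too dim or too bright to
#' be labeled cells). Each rejection records the rule that fired.
#'
#' @param features cluster feature table from [connected_components()].
#' @param t_v maximum volume in voxels.
#' @param ratio_range `c(low, high)` bounds on intensity/volume.
#' @return `features` with added `kept` (logical) and `reject_reason`
#'   (`""`, `"volume"`, `"ratio_low"` or `"ratio_high"`).
#' @export
reject_false_positives <- function(features, t_v = 500,
                                   ratio_range = c(2, 2000)) {
  reason <- rep("", nrow(features))
  reason[features$ratio > ratio_range[2]] <- "ratio_high"
  reason[features$ratio < ratio_range[1]] <- "ratio_low"
  reason[features$volume > t_v] <- "volume"
  features$kept <- reason == ""
  features$reject_reason <- reason
  features
}

#' Per-cluster maxima from a culture working volume
#'
#' Thresholds the culture volume at the low threshold, labels components
#' and returns each component's maximum intensity; components smaller than
#' `min_volume` voxels (noise speckle; a real cell covers several voxels
#' above the low threshold) are dropped. Feed the result to
#' [compute_th()].
#'
#' @param igray culture working volume.
#' @param c_low constant for [compute_tl()].
#' @param min_volume minimum component volume in voxels.
#' @param connectivity 26 or 6.
#' @return numeric vector of per-cluster maxima.
#' @export
culture_cluster_maxima <- function(igray, c_low = 1.4, min_volume = 5,
                                   connectivity = 26) {
  x <- as_volume(igray)
  tl <- compute_tl(x, c_low)
  cc <- connected_components(x > tl, x, connectivity)
  feats <- cc$features
  feats <- feats[feats$volume >= min_volume, , drop = FALSE]
  if (nrow(feats) == 0) stop("no clusters found in culture image")
  idx <- which(cc$labels > 0)
  lab <- cc$labels[idx]
  mx <- tapply(x[idx], lab, max)
  as.numeric(mx[as.character(feats$id)])
}

#' Segment and label fluorescent clusters
#'
#' Runs hysteresis thresholding, 3D connected-component analysis, feature
#' extraction and false-positive rejection on a working volume.
#'
#' @param igray working volume from [preprocess_stack()].
#' @param config a [detect_config].
#' @param culture_maxima optional per-cluster culture maxima used to set
#'   the high threshold when `config$t_h` is `NULL`.
#' @return an object of class `cluster_set`: `labels`, `features`
#'   (with kept/reject columns), and the thresholds used.
#' @export
detect_clusters <- function(igray, config = detect_config(),
                            culture_maxima = NULL) {
  stopifnot(inherits(config, "detect_config"))
  t_l <- config$t_l %||% compute_tl(igray, config$c_low)
  t_h <- config$t_h %||% (if (!is.null(culture_maxima))
    compute_th(culture_maxima) else
      stop("config$t_h is NULL and no culture_maxima supplied"))
  if (t_h < t_l)
    stop(sprintf("high threshold (%.3g) below low threshold (%.3g)", t_h, t_l))
  mask <- hysteresis_threshold(igray, t_h, t_l, config$connectivity)
  cc <- connected_components(mask, igray, config$connectivity)
  feats <- reject_false_positives(cc$features, config$t_v, config$ratio_range)
  structure(list(labels = cc$labels, features = feats,
                 t_h = t_h, t_l = t_l, connectivity = config$connectivity),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  f <- x$features
  cat(sprintf("<cluster_set> %d clusters (%d kept, %d rejected); T_H = %.3g, T_L = %.3g\n",
              nrow(f), sum(f$kept), sum(!f$kept), x$t_h, x$t_l))
  invisible(x)
}

#' Threshold diagnostic report
#'
#' For every labeled object, reports the statistics a user would need to
#' include or reject it: the high threshold must lie below the object's
#' maximum intensity, the low threshold below its minimum, and (when the
#' original two-channel stack is supplied) the ratio threshold below the
#' object's minimum red/green ratio. Replaces interactive threshold tuning
#' with the same informational content.
#'
#' @param clusters a `cluster_set` from [detect_clusters()].
#' @param igray the working volume used for detection.
#' @param stack optional [fluor_stack] for ratio columns.
#' @return data frame with one row per object.
#' @export
threshold_report <- function(clusters, igray, stack = NULL) {
  igray <- as_volume(igray)
  f <- clusters$features
  out <- f[, c("id", "volume", "intensity", "ratio", "slice_span",
               "kept", "reject_reason")]
  out$th_needed <- NA_real_   # T_H must be below this to include the object
  out$tl_needed <- NA_real_   # T_L must be below this to keep every voxel
  if (!is.null(stack)) out$trg_needed <- NA_real_
  for (i in seq_len(nrow(f))) {
    idx <- which(clusters$labels == f$id[i])
    v <- igray[idx]
    out$th_needed[i] <- max(v)
    out$tl_needed[i] <- min(v)
    if (!is.null(stack)) {
      r <- stack$red[idx]; g <- stack$green[idx]
      out$trg_needed[i] <- min(ifelse(g > 0, r / g, Inf))
    }
  }
  out
}
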