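#' Preprocessing configuration
#'
#' Parameters for converting an aligned two-channel stack into the
#' grayscale working volume: next-image subtraction of subsurface
#' fluorescence, background removal by morphological reconstruction, and
#' the red/green ratio threshold.
#'
#' @param next_blur_sigma blur width (pixels) applied to the next slice
#'   before subtraction; the same parametric family as the phantom's
#'   bleed-through blur.
#' @param next_attenuation multiplicative attenuation in `[0, 1)` applied
#'   to the blurred next slice.
#' @param erosion_radius_px radius (pixels) of the flat disk structuring
#'   element used to build the reconstruction marker; must exceed the
#'   radius of the largest expected cluster footprint.
#' @param ratio_threshold dimensionless red/green threshold; voxels with
#'   `red <= ratio_threshold * green` are suppressed.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(next_blur_sigma = 2, next_attenuation = 0.15,
                              erosion_radius_px = 10, ratio_threshold = 2) {
  if (next_attenuation < 0 || next_attenuation >= 1)
    stop("next_attenuation must be in [0, 1)")
  if (next_blur_sigma < 0) stop("next_blur_sigma must be >= 0")
  if (erosion_radius_px <= 0) stop("erosion_radius_px must be positive")
  if (ratio_threshold < 0) stop("ratio_threshold must be >= 0")
  structure(list(next_blur_sigma = next_blur_sigma,
                 next_attenuation = next_attenuation,
                 erosion_radius_px = erosion_radius_px,
                 ratio_threshold = ratio_threshold),
            class = "preprocess_config")
}

#' Next-image subtraction of subsurface fluorescence
#'
#' Each slice sees a blurred, attenuated copy of the section beneath it
#' (the next image in acquisition order). Subtracting
#' `attenuation * blur(slice k+1)` from slice `k` and clipping at zero
#' isolates the fluorescence within each section; the final slice passes
#' through unchanged. Applied per channel.
#'
#' @param stack a [fluor_stack].
#' @param blur_sigma_px blur width in pixels (>= 0).
#' @param attenuation multiplicative factor in `[0, 1)`.
#' @return a [fluor_stack] of the same geometry.
#' @export
next_image_subtract <- function(stack, blur_sigma_px = 2, attenuation = 0.15) {
  stopifnot(inherits(stack, "fluor_stack"))
  if (attenuation < 0 || attenuation >= 1)
    stop("attenuation must be in [0, 1)")
  if (blur_sigma_px < 0) stop("blur_sigma_px must be >= 0")
  ns <- n_slices(stack)
  if (ns < 2) {
    warning("single-slice stack: next-image subtraction is a pass-through")
    return(stack)
  }
  proc <- function(a) {
    out <- a
    for (k in seq_len(ns - 1))
      out[, , k] <- pmax(0, a[, , k] -
                           attenuation * gaussian_blur2d(a[, , k + 1], blur_sigma_px))
    out
  }
  fluor_stack(proc(stack$red), proc(stack$green),
              stack$pixel_size_um, stack$section_um)
}

# Grayscale erosion by a flat disk, border-clamped (minimum over in-image
# pixels under the disk). EBImage clamps grayscale to [0, 1], so rescale.
erode_disk <- function(image, radius) {
  stopifnot(radius > 0)
  kern <- EBImage::makeBrush(2 * as.integer(radius) + 1, shape = "disc")
  M <- max(image)
  if (M <= 0) return(image)
  out <- EBImage::erode(image / M, kern) * M
  matrix(as.numeric(out), nrow(image), ncol(image))
}

#' Autofluorescent background by morphological reconstruction
#'
#' The marker (the image eroded with a disk large enough to remove every
#' cluster) is geodesically dilated under the original image until stable,
#' yielding a smooth background that excludes all local maxima narrower
#' than the disk. The result is pointwise `<=` the input.
#'
#' @param image 2D numeric matrix (one channel of one section).
#' @param erosion_radius_px disk radius in pixels (> 0).
#' @return background image of the same dimensions.
#' @export
background_by_reconstruction <- function(image, erosion_radius_px = 10) {
  stopifnot(is.matrix(image))
  marker <- erode_disk(image, erosion_radius_px)
  cpp_reconstruct_dilate(marker, image)
}

#' Subtract the reconstructed background from every slice and channel
#'
#' @param stack a [fluor_stack].
#' @param erosion_radius_px disk radius passed to
#'   [background_by_reconstruction()].
#' @return a [fluor_stack] with the smooth background removed (clipped at
#'   zero).
#' @export
subtract_background <- function(stack, erosion_radius_px = 10) {
  stopifnot(inherits(stack, "fluor_stack"))
  proc <- function(a) {
    for (k in seq_len(dim(a)[3])) {
      bg <- background_by_reconstruction(a[, , k], erosion_radius_px)
      a[, , k] <- pmax(0, a[, , k] - bg)
    }
    a
  }
  fluor_stack(proc(stack$red), proc(stack$green),
              stack$pixel_size_um, stack$section_um)
}

#' Red/green ratio threshold to a grayscale working volume
#'
#' Keeps the red intensity of voxels whose red/green ratio exceeds the
#' threshold and zeroes the rest. The test is evaluated as
#' `red > threshold * green`, which is algebraically equivalent for
#' positive green and remains defined where green is zero (a zero-green
#' voxel passes whenever its red intensity is positive).
#'
#' @param stack a [fluor_stack] (both channels required).
#' @param ratio_threshold dimensionless threshold (>= 0).
#' @return 3D numeric array (the working volume) with `pixel_size_um` and
#'   `section_um` attributes.
#' @export
ratio_threshold <- function(stack, ratio_threshold = 2) {
  if (!inherits(stack, "fluor_stack") || is.null(stack$green))
    stop("ratio_threshold requires a two-channel fluor_stack")
  if (ratio_threshold < 0) stop("ratio_threshold must be >= 0")
  igray <- stack$red * (stack$red > ratio_threshold * stack$green)
  attr(igray, "pixel_size_um") <- stack$pixel_size_um
  attr(igray, "section_um") <- stack$section_um
  igray
}

#' Full preprocessing chain
#'
#' Next-image subtraction, then background removal by morphological
#' reconstruction, then the red/green ratio threshold, in that order.
#'
#' @param stack a [fluor_stack].
#' @param config a [preprocess_config].
#' @return the grayscale working volume (3D array).
#' @export
preprocess_stack <- function(stack, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  s <- if (n_slices(stack) > 1)
    next_image_subtract(stack, config$next_blur_sigma, config$next_attenuation)
  else stack
  s <- subtract_background(s, config$erosion_radius_px)
  ratio_threshold(s, config$ratio_threshold)
}
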