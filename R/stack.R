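#' Two-channel fluorescence image stack
#'
#' Container for an aligned 3D cryo-image volume with a red and a green
#' channel, stored as `[rows, cols, slices]` arrays in acquisition order,
#' plus the in-plane pixel size and section thickness.
#'
#' @param red,green numeric arrays (or matrices, promoted to one slice) of
#'   identical dimensions; digital intensity units, non-negative.
#' @param pixel_size_um in-plane pixel size in micrometres.
#' @param section_um section thickness in micrometres.
#' @return an object of class `fluor_stack`.
#' @export
fluor_stack <- function(red, green, pixel_size_um = 15.6, section_um = 40) {
  red <- as_volume(red)
  green <- as_volume(green)
  if (!identical(dim(red), dim(green)))
    stop("red and green channels must have identical dimensions")
  stopifnot(pixel_size_um > 0, section_um > 0)
  structure(list(red = red, green = green,
                 pixel_size_um = pixel_size_um, section_um = section_um),
            class = "fluor_stack")
}

#' @export
print.fluor_stack <- function(x, ...) {
  d <- dim(x$red)
  cat(sprintf("<fluor_stack> %d x %d pixels, %d slice(s)\n", d[1], d[2], d[3]))
  cat(sprintf("  pixel %.1f um, section %.0f um; red range [%.3g, %.3g]\n",
              x$pixel_size_um, x$section_um, min(x$red), max(x$red)))
  invisible(x)
}

#' @export
dim.fluor_stack <- function(x) dim(x$red)

n_slices <- function(stack) dim(stack$red)[3]

#' Write / read a stack as per-channel multi-page TIFF
#'
#' `write_stack()` writes `<prefix>_red.tif` and `<prefix>_green.tif` (one
#' page per section, 32-bit float) plus `<prefix>_meta.yaml` recording the
#' intensity scale and geometry; TIFF storage holds values in \[0, 1\], so
#' intensities are divided by a recorded scale on write and restored by
#' `read_stack()`.
#'
#' @param stack a [fluor_stack].
#' @param prefix path prefix for the three output files.
#' @return `write_stack()` returns the prefix invisibly; `read_stack()`
#'   returns a [fluor_stack].
#' @export
write_stack <- function(stack, prefix) {
  stopifnot(inherits(stack, "fluor_stack"))
  scale <- max(stack$red, stack$green, 1e-12)
  pages <- function(a) lapply(seq_len(dim(a)[3]), function(k) a[, , k] / scale)
  tiff::writeTIFF(pages(stack$red), paste0(prefix, "_red.tif"),
                  bits.per.sample = 32L)
  tiff::writeTIFF(pages(stack$green), paste0(prefix, "_green.tif"),
                  bits.per.sample = 32L)
  yaml::write_yaml(list(scale = scale,
                        pixel_size_um = stack$pixel_size_um,
                        section_um = stack$section_um,
                        dim = as.integer(dim(stack$red))),
                   paste0(prefix, "_meta.yaml"))
  invisible(prefix)
}

#' @rdname write_stack
#' @export
read_stack <- function(prefix) {
  meta <- yaml::read_yaml(paste0(prefix, "_meta.yaml"))
  rd <- function(ch) {
    pages <- tiff::readTIFF(paste0(prefix, "_", ch, ".tif"), all = TRUE)
    a <- array(0, dim = c(dim(pages[[1]]), length(pages)))
    for (k in seq_along(pages)) a[, , k] <- pages[[k]] * meta$scale
    a
  }
  fluor_stack(rd("red"), rd("green"),
              pixel_size_um = meta$pixel_size_um, section_um = meta$section_um)
}
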