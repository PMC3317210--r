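#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed`, restoring the caller's RNG
#' state afterwards so library functions do not perturb user randomness.
#' A `NULL` seed evaluates the code with the current RNG state.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Round half away from zero for positive x (base round() is round-half-even).
round_half_up <- function(x) floor(x + 0.5)

#' Separable Gaussian blur of a matrix
#'
#' Convolution with a truncated (4 sigma) Gaussian kernel along rows then
#' columns; near image borders the kernel is renormalized over in-image
#' pixels so flat fields are preserved. `sigma = 0` is the identity. The
#' same operator is used to simulate subsurface bleed-through in phantoms
#' and to model it during next-image subtraction, so the two stay in the
#' same parametric family.
#'
#' @param m numeric matrix.
#' @param sigma blur standard deviation in pixels.
#' @return blurred matrix of the same dimensions.
#' @export
gaussian_blur2d <- function(m, sigma) {
  stopifnot(is.matrix(m), sigma >= 0)
  if (sigma == 0) return(m)
  band <- function(n) {
    h <- max(1L, ceiling(4 * sigma))
    w <- dnorm(-h:h, sd = sigma)
    K <- matrix(0, n, n)
    for (d in -h:h) {
      i <- seq_len(n)
      j <- i + d
      ok <- j >= 1 & j <= n
      K[cbind(i[ok], j[ok])] <- w[d + h + 1]
    }
    K / rowSums(K)
  }
  Kr <- band(nrow(m))
  Kc <- band(ncol(m))
  Kr %*% m %*% t(Kc)
}

# Blur each slice of a 3D array in-plane.
blur_slices <- function(a, sigma) {
  if (sigma == 0) return(a)
  for (k in seq_len(dim(a)[3])) a[, , k] <- gaussian_blur2d(a[, , k], sigma)
  a
}

# Ensure an image is a 3D [rows, cols, slices] array.
as_volume <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  stopifnot(length(dim(x)) == 3L)
  x
}

#' Local maxima of a 3D intensity volume
#'
#' A voxel is a local maximum when its value is positive and strictly
#' greater than all of its 26 neighbours (out-of-volume neighbours count
#' as -Inf). Used to seed cell placements inside a cluster patch.
#'
#' @param a 3D numeric array.
#' @return data frame with columns `row`, `col`, `slice`, `value`,
#'   ordered by decreasing value.
#' @keywords internal
local_maxima3d <- function(a) {
  a <- as_volume(a)
  d <- dim(a)
  pad <- array(-Inf, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- a
  is_max <- array(TRUE, d)
  for (dr in -1:1) for (dc in -1:1) for (ds in -1:1) {
    if (dr == 0 && dc == 0 && ds == 0) next
    nb <- pad[(2:(d[1] + 1)) + dr, (2:(d[2] + 1)) + dc, (2:(d[3] + 1)) + ds,
              drop = FALSE]
    is_max <- is_max & (a > nb)
  }
  idx <- which(is_max & a > 0)
  if (length(idx) == 0)
    return(data.frame(row = integer(), col = integer(), slice = integer(),
                      value = numeric()))
  co <- arrayInd(idx, d)
  out <- data.frame(row = co[, 1], col = co[, 2], slice = co[, 3],
                    value = a[idx])
  out[order(-out$value), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
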