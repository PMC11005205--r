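#' Image grid geometry
#'
#' A light-weight description of a 3-D sampling grid: array dimensions,
#' voxel spacing in mm and the world-space position (mm) of voxel
#' `(0, 0, 0)`. Voxel indices are 0-based throughout the package; world
#' coordinates are `origin + spacing * index` along each axis, with all
#' volumes held in one fixed (RAS-like) anatomical axis convention.
#'
#' @param dim integer vector of length 3, each entry >= 8.
#' @param spacing numeric vector of length 3, mm per voxel, all > 0.
#' @param origin numeric vector of length 3, mm offset of the first voxel.
#' @return An object of class `image_grid`.
#' @export
image_grid <- function(dim, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  dim <- as.integer(dim)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(dim) == 3L, length(spacing) == 3L, length(origin) == 3L)
  if (any(spacing <= 0)) stop("all spacings must be > 0")
  structure(list(dim = dim, spacing = spacing, origin = origin),
            class = "image_grid")
}

grid_of <- function(x) image_grid(dim(x$voxels), x$spacing, x$origin)

same_grid <- function(a, b, tol = 1e-6) {
  identical(a$dim, b$dim) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

# 4x4 voxel (0-based, homogeneous) -> world mm matrix for a grid
grid_vox2world <- function(grid) {
  m <- diag(4)
  diag(m)[1:3] <- grid$spacing
  m[1:3, 4] <- grid$origin
  m
}

# N x 3 matrix of all 0-based voxel coordinates of a grid, C-order compatible
# with R array linearisation (x fastest).
grid_points <- function(grid) {
  d <- grid$dim
  cbind(
    rep.int(seq_len(d[1]) - 1L, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  )
}

vox_to_world <- function(grid, vox) {
  sweep(sweep(vox, 2, grid$spacing, "*"), 2, grid$origin, "+")
}

world_to_vox <- function(grid, world) {
  sweep(sweep(world, 2, grid$origin, "-"), 2, grid$spacing, "/")
}

#' 3-D scalar volume in Hounsfield units
#'
#' Container for a CT (or template) volume: a finite 3-D array of HU values
#' plus grid metadata. The native scan, the template and the warped scan are
#' all carried as `volume_image` objects.
#'
#' @param voxels 3-D numeric array of finite HU values, each dim >= 8.
#' @param spacing,origin grid metadata, see [image_grid()].
#' @param orientation axis convention code; volumes are reoriented to "RAS"
#'   on load and kept there.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         orientation = "RAS") {
  if (length(dim(voxels)) != 3L)
    stop("volume_image requires a 3-D array, got ",
         length(dim(voxels)), " dimensions")
  if (any(dim(voxels) < 8L))
    stop("each volume axis must have at least 8 voxels")
  if (!all(is.finite(voxels))) stop("voxel values must be finite")
  g <- image_grid(dim(voxels), spacing, origin)
  structure(list(voxels = voxels, spacing = g$spacing, origin = g$origin,
                 orientation = orientation),
            class = "volume_image")
}

#' Binary mask on an image grid
#'
#' @param voxels 3-D logical array.
#' @param spacing,origin grid metadata of the parent image.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L) stop("binary_mask requires a 3-D array")
  storage.mode(voxels) <- "logical"
  voxels[is.na(voxels)] <- FALSE
  g <- image_grid(dim(voxels), spacing, origin)
  structure(list(voxels = voxels, spacing = g$spacing, origin = g$origin),
            class = "binary_mask")
}

#' @export
print.volume_image <- function(x, ...) {
  cat("<volume_image> ", paste(dim(x$voxels), collapse = " x "),
      " voxels @ ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm; HU range [", signif(min(x$voxels), 4), ", ",
      signif(max(x$voxels), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", paste(dim(x$voxels), collapse = " x "),
      " voxels; ", sum(x$voxels), " set\n", sep = "")
  invisible(x)
}

#' Dice overlap coefficient between two masks
#'
#' `2 |A n B| / (|A| + |B|)`; returns 0 when both masks are empty-free of
#' overlap and `NaN` only when both are entirely empty.
#'
#' @param a,b `binary_mask` objects on the same grid.
#' @return Numeric scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"),
            identical(dim(a$voxels), dim(b$voxels)))
  na <- sum(a$voxels); nb <- sum(b$voxels)
  if (na + nb == 0L) return(NaN)
  2 * sum(a$voxels & b$voxels) / (na + nb)
}
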