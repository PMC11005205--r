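# Binary morphology on 3-D masks. The structuring element is a voxel-space
# ball: all integer offsets with dx^2 + dy^2 + dz^2 <= r^2 (radius 1 is the
# 6-neighbour cross). Outside-of-grid voxels count as background for both
# dilation and erosion.

ball_offsets <- function(radius) {
  r <- as.integer(radius)
  stopifnot(r >= 1L)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  g <- g[g$dx^2 + g$dy^2 + g$dz^2 <= radius^2, , drop = FALSE]
  as.matrix(g)
}

# shift a logical array by integer offset, filling with FALSE
shift_mask <- function(m, off) {
  d <- dim(m)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    o <- off[a]
    if (o >= 0) { dst[[a]] <- (1 + o):d[a]; src[[a]] <- 1:(d[a] - o) }
    else        { dst[[a]] <- 1:(d[a] + o); src[[a]] <- (1 - o):d[a] }
    if (abs(o) >= d[a]) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    m[src[[1]], src[[2]], src[[3]]]
  out
}

dilate_arr <- function(m, radius) {
  offs <- ball_offsets(radius)
  out <- array(FALSE, dim(m))
  for (i in seq_len(nrow(offs))) out <- out | shift_mask(m, offs[i, ])
  out
}

erode_arr <- function(m, radius) {
  offs <- ball_offsets(radius)
  out <- array(TRUE, dim(m))
  for (i in seq_len(nrow(offs))) out <- out & shift_mask(m, offs[i, ])
  out
}

#' Morphological dilation and erosion
#'
#' Ball-structuring-element binary morphology; radius is in voxels and
#' radius 1 corresponds to the 6-neighbour cross.
#'
#' @param mask a [binary_mask()].
#' @param radius_voxels positive integer radius of the ball element.
#' @return A `binary_mask` on the same grid.
#' @export
morph_dilate <- function(mask, radius_voxels = 1L) {
  stopifnot(inherits(mask, "binary_mask"), radius_voxels >= 1)
  binary_mask(dilate_arr(mask$voxels, radius_voxels),
              mask$spacing, mask$origin)
}

#' @rdname morph_dilate
#' @export
morph_erode <- function(mask, radius_voxels = 1L) {
  stopifnot(inherits(mask, "binary_mask"), radius_voxels >= 1)
  binary_mask(erode_arr(mask$voxels, radius_voxels),
              mask$spacing, mask$origin)
}

#' Morphological closing and opening
#'
#' Closing (dilation followed by erosion) fills cavities smaller than the
#' structuring element; opening (erosion followed by dilation) removes
#' speckles smaller than it. Used to repair fragmented K-means tissue masks
#' inside the atlas ROIs and to clean their boundaries.
#'
#' @inheritParams morph_dilate
#' @return A `binary_mask` on the same grid.
#' @export
morph_close <- function(mask, radius_voxels = 1L) {
  stopifnot(inherits(mask, "binary_mask"), radius_voxels >= 1)
  binary_mask(erode_arr(dilate_arr(mask$voxels, radius_voxels),
                        radius_voxels),
              mask$spacing, mask$origin)
}

#' @rdname morph_close
#' @export
morph_open <- function(mask, radius_voxels = 1L) {
  stopifnot(inherits(mask, "binary_mask"), radius_voxels >= 1)
  binary_mask(dilate_arr(erode_arr(mask$voxels, radius_voxels),
                         radius_voxels),
              mask$spacing, mask$origin)
}

#' Connected-component labelling and selection
#'
#' Components are defined by 6-connectivity (face adjacency). Component ids
#' are assigned in order of each component's smallest linear index
#' (C-order), which makes the size tie-break of [largest_component()]
#' deterministic: among equally large components the one with the smallest
#' minimum linear index wins.
#'
#' @param mask a [binary_mask()].
#' @return `label_components`: integer array of component ids (0 outside).
#' @export
label_components <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  lab <- .cc_label6(as.logical(mask$voxels), dim(mask$voxels))
  array(lab, dim(mask$voxels))
}

#' @rdname label_components
#' @return `largest_component`: a `binary_mask` containing only the largest
#'   component; an empty input yields an empty output.
#' @export
largest_component <- function(mask) {
  lab <- label_components(mask)
  if (max(lab) == 0L)
    return(binary_mask(array(FALSE, dim(mask$voxels)),
                       mask$spacing, mask$origin))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)  # first max = smallest component id = tie rule
  binary_mask(lab == keep, mask$spacing, mask$origin)
}

#' @rdname label_components
#' @param min_voxels components strictly smaller than this are removed.
#' @return `drop_small_components`: a `binary_mask` without the small
#'   components.
#' @export
drop_small_components <- function(mask, min_voxels) {
  lab <- label_components(mask)
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_voxels)
  binary_mask(array(lab %in% keep & lab > 0L, dim(lab)),
              mask$spacing, mask$origin)
}

#' Fill enclosed cavities of a mask
#'
#' Background components not connected to the array border are interior
#' cavities and are added to the mask.
#'
#' @param mask a [binary_mask()].
#' @return A `binary_mask`.
#' @export
fill_holes <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  inv <- binary_mask(!mask$voxels, mask$spacing, mask$origin)
  lab <- label_components(inv)
  d <- dim(lab)
  border <- unique(c(
    lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])]
  ))
  border <- border[border > 0L]
  filled <- mask$voxels | (lab > 0L & !(lab %in% border))
  binary_mask(filled, mask$spacing, mask$origin)
}
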