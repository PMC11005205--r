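#' Read a 3-D volume from NIfTI-1
#'
#' Reads a `.nii` or `.nii.gz` file, applies the format's scale/intercept
#' (handled by the NIfTI reader) and reorients the array to the package's
#' canonical RAS axis convention so that left/right labelling is consistent.
#'
#' @param path path to a NIfTI-1 file.
#' @return A [volume_image()].
#' @export
read_volume <- function(path) {
  arr <- read_nifti_canonical(path)
  volume_image(arr$data, spacing = arr$spacing, origin = arr$origin)
}

#' Write a volume (or mask / atlas) to NIfTI-1
#'
#' @param img a `volume_image`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_volume <- function(img, path) {
  stopifnot(inherits(img, "volume_image"))
  write_nifti_canonical(img$voxels, grid_of(img), path)
}

#' @rdname write_volume
#' @param mask a `binary_mask`; stored as uint8.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  arr <- array(as.integer(mask$voxels), dim(mask$voxels))
  write_nifti_canonical(arr, grid_of(mask), path, datatype = "uint8")
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  arr <- read_nifti_canonical(path)
  binary_mask(arr$data != 0, spacing = arr$spacing, origin = arr$origin)
}

#' @rdname write_volume
#' @param atlas an `roi_atlas`; the label table is written next to the image
#'   as a JSON sidecar `<path basename>.labels.json`.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "roi_atlas"))
  write_nifti_canonical(atlas$labels,
                        image_grid(dim(atlas$labels), atlas$spacing,
                                   atlas$origin),
                        path, datatype = "int16")
  sidecar <- atlas_sidecar_path(path)
  tab <- atlas$label_table
  entries <- stats::setNames(
    lapply(seq_len(nrow(tab)), function(i)
      list(name = tab$name[i], structure = tab$structure[i],
           side = tab$side[i], tissue_class = tab$tissue_class[i])),
    as.character(tab$label)
  )
  jsonlite::write_json(entries, sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname read_volume
#' @export
read_atlas <- function(path) {
  arr <- read_nifti_canonical(path)
  sidecar <- atlas_sidecar_path(path)
  if (file.exists(sidecar)) {
    entries <- jsonlite::read_json(sidecar)
    tab <- data.frame(
      label = as.integer(names(entries)),
      name = vapply(entries, `[[`, "", "name"),
      structure = vapply(entries, `[[`, "", "structure"),
      side = vapply(entries, `[[`, "", "side"),
      tissue_class = vapply(entries, `[[`, "", "tissue_class"),
      stringsAsFactors = FALSE, row.names = NULL
    )
  } else {
    tab <- roi_structures()
  }
  lab <- round(arr$data)
  storage.mode(lab) <- "integer"
  roi_atlas(lab, spacing = arr$spacing, origin = arr$origin,
            label_table = tab)
}

atlas_sidecar_path <- function(path) {
  base <- sub("\\.nii(\\.gz)?$", "", path)
  paste0(base, ".labels.json")
}

read_nifti_canonical <- function(path) {
  if (!file.exists(path)) stop("cannot read NIfTI file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read NIfTI file: ", path,
                                           " (", conditionMessage(e), ")"))
  nd <- length(dim(img))
  if (nd != 3L)
    stop("expected a 3-D payload in ", path, " but found ", nd, " dimensions")
  RNifti::orientation(img) <- "RAS"
  xf <- RNifti::xform(img)
  spacing <- RNifti::pixdim(img)[1:3]
  origin <- xf[1:3, 4]
  list(data = array(as.numeric(img), dim(img)), spacing = spacing,
       origin = origin)
}

write_nifti_canonical <- function(arr, grid, path, datatype = "auto") {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- grid$spacing
  m <- diag(4)
  diag(m)[1:3] <- grid$spacing
  m[1:3, 4] <- grid$origin
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
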