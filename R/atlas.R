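#' Canonical ROI structure table
#'
#' The nine labelled structures used for GWR computation: the paired gray
#' matter nuclei (caudate CN, putamen PU), the paired posterior limb of the
#' internal capsule (PIC) and the corpus callosum split into genu, body and
#' splenium. CN and PU are gray matter; PIC and the CC parts are white
#' matter. For GWR the CC parts are pooled into one CC structure and paired
#' structures are pooled across sides.
#'
#' @return data.frame with columns `label`, `name`, `structure`, `side`,
#'   `tissue_class`.
#' @export
roi_structures <- function() {
  data.frame(
    label = 1:9,
    name = c("CN_L", "CN_R", "PU_L", "PU_R", "PIC_L", "PIC_R",
             "CC_GENU", "CC_BODY", "CC_SPLENIUM"),
    structure = c("CN", "CN", "PU", "PU", "PIC", "PIC", "CC", "CC", "CC"),
    side = c("L", "R", "L", "R", "L", "R", "genu", "body", "splenium"),
    tissue_class = c("gray", "gray", "gray", "gray", "white", "white",
                     "white", "white", "white"),
    stringsAsFactors = FALSE
  )
}

#' Integer-labelled ROI atlas
#'
#' A label map over the template grid together with its label table. Label 0
#' is background. The invariants enforced: every non-zero voxel's label is
#' listed in the table, CN/PU map to gray and PIC/CC to white, and paired
#' structures are both present in the table.
#'
#' @param labels 3-D integer array (0 = background).
#' @param spacing,origin grid metadata, see [image_grid()].
#' @param label_table data.frame as returned by [roi_structures()]; rows may
#'   be a subset only for synthetic edge-case atlases.
#' @return Object of class `roi_atlas`.
#' @export
roi_atlas <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      label_table = roi_structures()) {
  if (length(dim(labels)) != 3L) stop("roi_atlas requires a 3-D label array")
  storage.mode(labels) <- "integer"
  g <- image_grid(dim(labels), spacing, origin)
  used <- sort(unique(labels[labels != 0L]))
  if (!all(used %in% label_table$label))
    stop("labels present in the map but absent from label_table: ",
         paste(setdiff(used, label_table$label), collapse = ", "))
  gray_ok <- label_table$structure[label_table$tissue_class == "gray"] %in%
    c("CN", "PU")
  white_ok <- label_table$structure[label_table$tissue_class == "white"] %in%
    c("PIC", "CC")
  if (!all(gray_ok) || !all(white_ok))
    stop("tissue_class must map CN/PU to gray and PIC/CC to white")
  structure(list(labels = labels, spacing = g$spacing, origin = g$origin,
                 label_table = label_table),
            class = "roi_atlas")
}

#' @export
print.roi_atlas <- function(x, ...) {
  counts <- tabulate(x$labels, nbins = max(x$label_table$label))
  cat("<roi_atlas> ", paste(dim(x$labels), collapse = " x "), " voxels; ",
      sum(counts > 0), "/", nrow(x$label_table), " labels non-empty\n",
      sep = "")
  invisible(x)
}

# logical mask of one label id
atlas_label_mask <- function(atlas, label) {
  binary_mask(atlas$labels == label, atlas$spacing, atlas$origin)
}

# voxel counts per label id (named by structure name)
atlas_counts <- function(atlas) {
  tab <- atlas$label_table
  n <- vapply(tab$label, function(l) sum(atlas$labels == l), integer(1))
  stats::setNames(n, tab$name)
}
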