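# Native-space HU statistics per structure and the two GWR formulas:
#   GWR_b = (CN + PU) / (CC + PIC)
#   GWR_s = PU / PIC
# Structure HU values are means over pooled bilateral voxels (and pooled CC
# parts); per-side / per-part breakdowns are retained so the alternative
# mean-of-side-means convention stays computable.

#' Per-structure HU statistics
#'
#' Computes mean, SD and voxel count per GWR structure (CN, PU, PIC, CC)
#' over the pooled bilateral voxels (CC pooled over genu/body/splenium),
#' with the per-side / per-part breakdown attached. If an HU inclusion
#' window is supplied, voxels outside `[lo, hi]` are discarded before
#' averaging.
#'
#' @param native_ct native-space [volume_image()].
#' @param native_rois native-space [roi_atlas()] (from
#'   [inverse_map_rois()]).
#' @param hu_window optional `c(lo, hi)` HU inclusion window;
#'   [hu_window_preset()] reproduces the (15, 100) filter of
#'   registration-only approaches. Default `NULL` (off).
#' @return A `structure_hu` object: data.frame `pooled` (structure, mean,
#'   sd, n, missing) and data.frame `parts` with the per-label breakdown.
#' @export
roi_statistics <- function(native_ct, native_rois, hu_window = NULL) {
  stopifnot(inherits(native_ct, "volume_image"),
            inherits(native_rois, "roi_atlas"),
            identical(dim(native_ct$voxels), dim(native_rois$labels)))
  tab <- native_rois$label_table
  vals_of <- function(lab) {
    v <- native_ct$voxels[native_rois$labels == lab]
    if (!is.null(hu_window))
      v <- v[v >= hu_window[1] & v <= hu_window[2]]
    v
  }
  part_vals <- lapply(tab$label, vals_of)
  parts <- data.frame(
    label = tab$label, name = tab$name, structure = tab$structure,
    mean = vapply(part_vals, function(v) if (length(v)) mean(v) else NA_real_,
                  numeric(1)),
    sd = vapply(part_vals, function(v) if (length(v) > 1) stats::sd(v)
                else NA_real_, numeric(1)),
    n = vapply(part_vals, length, integer(1)),
    stringsAsFactors = FALSE
  )
  pooled <- do.call(rbind, lapply(c("CN", "PU", "PIC", "CC"), function(s) {
    v <- unlist(part_vals[tab$structure == s], use.names = FALSE)
    data.frame(structure = s,
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               n = length(v),
               missing = length(v) == 0L,
               stringsAsFactors = FALSE)
  }))
  structure(list(pooled = pooled, parts = parts,
                 hu_window = hu_window), class = "structure_hu")
}

structure_mean <- function(s, name) {
  row <- s$pooled[s$pooled$structure == name, ]
  if (nrow(row) != 1L || row$missing) return(NA_real_)
  row$mean
}

#' Basal-ganglia and simplified GWR
#'
#' `gwr_b` is `(CN + PU) / (CC + PIC)` and `gwr_s` is `PU / PIC`, each on
#' the pooled structure means. When a required structure is missing or a
#' denominator is not positive the ratio is undefined and `NA` is returned
#' with an `undefined` attribute giving the reason (mirrors scans for which
#' a missing CC or CN makes the GWR impossible to evaluate).
#'
#' @param s a `structure_hu` from [roi_statistics()].
#' @return Numeric ratio, or `NA` with attribute `undefined`.
#' @export
gwr_b <- function(s) {
  stopifnot(inherits(s, "structure_hu"))
  cn <- structure_mean(s, "CN"); pu <- structure_mean(s, "PU")
  pic <- structure_mean(s, "PIC"); cc <- structure_mean(s, "CC")
  if (anyNA(c(cn, pu, pic, cc)))
    return(undefined_gwr("missing structure"))
  if (cc + pic <= 0) return(undefined_gwr("non-positive denominator"))
  (cn + pu) / (cc + pic)
}

#' @rdname gwr_b
#' @export
gwr_s <- function(s) {
  stopifnot(inherits(s, "structure_hu"))
  pu <- structure_mean(s, "PU"); pic <- structure_mean(s, "PIC")
  if (anyNA(c(pu, pic))) return(undefined_gwr("missing structure"))
  if (pic <= 0) return(undefined_gwr("non-positive denominator"))
  pu / pic
}

undefined_gwr <- function(reason) {
  structure(NA_real_, undefined = reason)
}

#' Manual-style circular ROI mean
#'
#' Mean HU over the in-plane pixels of one axial slice whose centres lie
#' within a circle of the given area (default approximately 10 mm^2, the
#' size used for physician-drawn ROIs). Provided as the comparison utility
#' for manual-versus-automated method studies.
#'
#' @param native_ct a [volume_image()].
#' @param slice_index 1-based axial slice index.
#' @param center_mm in-plane circle centre `c(x, y)` in world mm.
#' @param area_mm2 circle area in mm^2.
#' @return Mean HU over the included pixels (attribute `n_pixels`).
#' @export
manual_circle_mean <- function(native_ct, slice_index, center_mm,
                               area_mm2 = 10) {
  stopifnot(inherits(native_ct, "volume_image"))
  d <- dim(native_ct$voxels)
  if (slice_index < 1 || slice_index > d[3]) stop("slice index out of range")
  r <- sqrt(area_mm2 / pi)
  sp <- native_ct$spacing; or <- native_ct$origin
  xc <- or[1] + sp[1] * (seq_len(d[1]) - 1)
  yc <- or[2] + sp[2] * (seq_len(d[2]) - 1)
  if (center_mm[1] - r < min(xc) - sp[1] / 2 ||
      center_mm[1] + r > max(xc) + sp[1] / 2 ||
      center_mm[2] - r < min(yc) - sp[2] / 2 ||
      center_mm[2] + r > max(yc) + sp[2] / 2)
    stop("circle does not fit inside the slice")
  dx <- outer(xc - center_mm[1], rep(1, d[2]))
  dy <- outer(rep(1, d[1]), yc - center_mm[2])
  inside <- dx^2 + dy^2 <= r^2
  if (!any(inside)) stop("circle contains no pixel centres")
  vals <- native_ct$voxels[, , slice_index][inside]
  structure(mean(vals), n_pixels = sum(inside))
}

#' Assemble a per-case GWR result
#'
#' @param s a `structure_hu`.
#' @param qc a `qc_report` from [evaluate_case()]; excluded cases carry no
#'   GWR values.
#' @param provenance optional named list (input path, settings hash, seed).
#' @return A `gwr_result` list with `gwr_b`, `gwr_s`, `structure_hu`,
#'   `qc` and `provenance`.
#' @export
gwr_result <- function(s, qc, provenance = list()) {
  excluded <- !is.null(qc) && qc$status == "excluded"
  structure(list(
    gwr_b = if (excluded) NA_real_ else gwr_b(s),
    gwr_s = if (excluded) NA_real_ else gwr_s(s),
    structure_hu = s,
    qc = qc,
    provenance = provenance
  ), class = "gwr_result")
}

#' @export
print.gwr_result <- function(x, ...) {
  st <- if (is.null(x$qc)) "ok" else x$qc$status
  cat("<gwr_result> status=", st,
      " GWR_b=", signif(x$gwr_b, 5),
      " GWR_s=", signif(x$gwr_s, 5), "\n", sep = "")
  invisible(x)
}
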