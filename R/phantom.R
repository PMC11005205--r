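# Synthetic head phantom: a nested-ellipsoid head (scalp, skull, CSF rim,
# cortical gray matter ribbon, white matter sea, ventricles) carrying the
# nine GWR structures (paired CN / PU / PIC, three-part corpus callosum) at
# realistic Hounsfield units. All geometry is analytic, so native-space
# subjects are rasterised exactly (no interpolation) and every stage of the
# pipeline has exact ground truth.

#' Phantom specification
#'
#' Geometry and acquisition parameters of the synthetic head phantom.
#' Compartment HU defaults: air -1000, scalp 40, skull 900, CSF 8, white
#' matter 30, gray matter 38, so the healthy phantom's GWR is 38/30 = 1.267,
#' near the commonly cited normal value of about 1.3. Injury severity
#' `s` collapses the gray-white contrast linearly:
#' `GM(s) = GM0 - s * (GM0 - WM0)`.
#'
#' @param dim grid dimensions (voxels).
#' @param spacing voxel spacing in mm.
#' @param hu named list of compartment HU values.
#' @param psf_sigma in-plane/through-plane acquisition blur, voxels (0 = off).
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(96L, 96L, 80L), spacing = c(2, 2, 2),
                         hu = list(air = -1000, scalp = 40, skull = 900,
                                   csf = 8, wm = 30, gm = 38),
                         psf_sigma = 0.4) {
  structure(list(dim = as.integer(dim), spacing = as.numeric(spacing),
                 hu = hu, psf_sigma = psf_sigma),
            class = "phantom_spec")
}

# centre of the grid in world mm
phantom_center <- function(spec) (spec$dim - 1) * spec$spacing / 2

# semi-axes (mm) and centres (mm, relative to grid centre) of all ellipsoids
phantom_geometry <- function() {
  list(
    scalp = list(c = c(0, 0, 0), s = c(88, 75, 72)),
    skull_outer = list(c = c(0, 0, 0), s = c(82, 69, 66)),
    skull_inner = list(c = c(0, 0, 0), s = c(76, 63, 60)),
    brain = list(c = c(0, 0, 0), s = c(72, 59, 56)),
    wm_core = list(c = c(0, 0, 0), s = c(63, 50, 47)),
    vent_l = list(c = c(-9, -8, 2), s = c(6, 22, 8)),
    vent_r = list(c = c(9, -8, 2), s = c(6, 22, 8)),
    CN_L = list(c = c(-21, 14, 6), s = c(5.5, 10, 8)),
    CN_R = list(c = c(21, 14, 6), s = c(5.5, 10, 8)),
    PU_L = list(c = c(-34, 4, 2), s = c(6, 11, 8)),
    PU_R = list(c = c(34, 4, 2), s = c(6, 11, 8)),
    PIC_L = list(c = c(-26, -12, 2), s = c(4, 8, 7)),
    PIC_R = list(c = c(26, -12, 2), s = c(4, 8, 7)),
    CC_GENU = list(c = c(0, 30, 6), s = c(6, 7, 6)),
    CC_BODY = list(c = c(0, 6, 14), s = c(6, 20, 5)),
    CC_SPLENIUM = list(c = c(0, -22, 6), s = c(6, 7, 6)),
    lesion_blob = list(c = c(40, 20, 10), s = c(12, 12, 10))
  )
}

inside_ellipsoid <- function(pts, center, semi, margin = 0) {
  s <- semi + margin
  ((pts[, 1] - center[1]) / s[1])^2 +
    ((pts[, 2] - center[2]) / s[2])^2 +
    ((pts[, 3] - center[3]) / s[3])^2 <= 1
}

# Evaluate compartment membership, ROI label and HU at world-mm points in
# template anatomy space. Returns integer compartment codes (0 air, 1 scalp,
# 2 skull, 3 csf, 4 wm, 5 gm), roi labels (0..9) and HU at severity s.
phantom_eval <- function(pts, spec, severity = 0, lesion = "none") {
  geo <- phantom_geometry()
  ctr <- phantom_center(spec)
  p <- sweep(pts, 2, ctr, "-")
  n <- nrow(p)
  tab <- roi_structures()

  in_scalp <- inside_ellipsoid(p, geo$scalp$c, geo$scalp$s)
  in_sk_o <- inside_ellipsoid(p, geo$skull_outer$c, geo$skull_outer$s)
  in_sk_i <- inside_ellipsoid(p, geo$skull_inner$c, geo$skull_inner$s)
  in_brain <- inside_ellipsoid(p, geo$brain$c, geo$brain$s)
  in_core <- inside_ellipsoid(p, geo$wm_core$c, geo$wm_core$s)
  in_vent <- inside_ellipsoid(p, geo$vent_l$c, geo$vent_l$s) |
    inside_ellipsoid(p, geo$vent_r$c, geo$vent_r$s)

  roi <- integer(n)
  ablate <- logical(n)
  abl_cn <- lesion %in% c("cn_ablation", "cc_cn_ablation")
  abl_cc <- lesion %in% c("cc_ablation", "cc_cn_ablation")
  for (i in seq_len(nrow(tab))) {
    e <- geo[[tab$name[i]]]
    hit <- inside_ellipsoid(p, e$c, e$s) & roi == 0L & in_core & !in_vent
    roi[hit] <- tab$label[i]
    if ((abl_cn && tab$structure[i] == "CN") ||
        (abl_cc && tab$structure[i] == "CC"))
      ablate <- ablate | inside_ellipsoid(p, e$c, e$s, margin = 3)
  }

  comp <- integer(n)                      # air
  comp[in_scalp] <- 1L                    # scalp
  comp[in_sk_o] <- 2L                     # skull shell
  comp[in_sk_i] <- 3L                     # csf rim
  comp[in_brain] <- 4L                    # wm sea
  ribbon <- in_brain & !in_core
  comp[ribbon] <- 5L                      # gm cortical ribbon
  comp[in_brain & in_vent] <- 3L          # ventricles
  gray_roi <- roi %in% tab$label[tab$tissue_class == "gray"]
  comp[gray_roi] <- 5L                    # deep gray nuclei

  gm_hu <- spec$hu$gm - severity * (spec$hu$gm - spec$hu$wm)
  hu <- rep(spec$hu$air, n)
  hu[comp == 1L] <- spec$hu$scalp
  hu[comp == 2L] <- spec$hu$skull
  hu[comp == 3L] <- spec$hu$csf
  hu[comp == 4L] <- spec$hu$wm
  hu[comp == 5L] <- gm_hu

  if (lesion == "hyperdense") {
    blob <- in_brain & inside_ellipsoid(p, geo$lesion_blob$c,
                                        geo$lesion_blob$s)
    hu[blob] <- 75
  } else if (lesion == "asymmetry") {
    left <- p[, 1] < 0
    hu[comp == 5L & left] <- spec$hu$wm + 2
  }
  if (any(ablate)) {
    abl <- ablate & in_brain
    hu[abl] <- spec$hu$csf
    comp[abl] <- 3L
  }

  list(compartment = comp, roi = roi, hu = hu)
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

smooth_volume_arr <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  k <- gaussian_kernel(sigma)
  d <- dim(arr)
  v <- as.numeric(arr)
  for (ax in 1:3) v <- .conv_axis(v, d, k, ax)
  array(v, d)
}

#' Build the synthetic template, ROI atlas and brain mask
#'
#' Rasterises the phantom at identity pose on the template grid. The
#' template plays the role of the ROI-bearing registration target; the brain
#' mask covers all intracranial soft tissue (CSF, white and gray matter).
#' Deterministic: the template is noise-free (only the acquisition blur of
#' `spec$psf_sigma` is applied to the intensity volume; the atlas and mask
#' are crisp).
#'
#' @param spec a [phantom_spec()].
#' @return List with elements `template` ([volume_image()]),
#'   `atlas` ([roi_atlas()]) and `brain` ([binary_mask()]).
#' @export
make_template <- function(spec = phantom_spec()) {
  grid <- image_grid(spec$dim, spec$spacing, c(0, 0, 0))
  geo <- phantom_geometry()
  if (any(geo$scalp$s * 2 >= (spec$dim - 2) * spec$spacing))
    stop("phantom head does not fit the requested grid")
  pts <- vox_to_world(grid, grid_points(grid))
  ev <- phantom_eval(pts, spec)
  vol <- array(ev$hu, spec$dim)
  vol <- smooth_volume_arr(vol, spec$psf_sigma)
  list(
    template = volume_image(vol, spec$spacing, grid$origin),
    atlas = roi_atlas(array(ev$roi, spec$dim), spec$spacing, grid$origin),
    brain = binary_mask(array(ev$compartment %in% 3:5, spec$dim),
                        spec$spacing, grid$origin)
  )
}

#' Subject acquisition parameters
#'
#' @param severity injury severity in `[0, 1]`; 0 = healthy contrast,
#'   1 = complete loss of gray-white differentiation.
#' @param rotation_deg length-3 rotation (degrees, about x/y/z through the
#'   head centre) of the head relative to the template; `NULL` draws each
#'   angle uniformly in [-8, 8].
#' @param translation_mm length-3 translation (mm); `NULL` draws uniformly
#'   in [-8, 8].
#' @param deformation_amp amplitude (mm) of the smooth sinusoidal anatomical
#'   deformation; 0 disables it.
#' @param noise_sd acquisition noise SD in HU, injected before the
#'   reconstruction blur.
#' @param lesion one of `"none"`, `"hyperdense"`, `"asymmetry"`,
#'   `"cc_ablation"`, `"cn_ablation"`, `"cc_cn_ablation"`.
#' @param seed RNG seed for pose sampling and noise.
#' @return Object of class `subject_spec`.
#' @export
subject_spec <- function(severity = 0, rotation_deg = NULL,
                         translation_mm = NULL, deformation_amp = 2,
                         noise_sd = 2, lesion = "none", seed = 1L) {
  stopifnot(severity >= 0, severity <= 1)
  lesion <- match.arg(lesion, c("none", "hyperdense", "asymmetry",
                                "cc_ablation", "cn_ablation",
                                "cc_cn_ablation"))
  set.seed(seed)
  if (is.null(rotation_deg)) rotation_deg <- runif(3, -8, 8)
  if (is.null(translation_mm)) translation_mm <- runif(3, -8, 8)
  structure(list(severity = severity, rotation_deg = rotation_deg,
                 translation_mm = translation_mm,
                 deformation_amp = deformation_amp, noise_sd = noise_sd,
                 lesion = lesion, seed = as.integer(seed)),
            class = "subject_spec")
}

rotation_matrix <- function(deg) {
  r <- deg * pi / 180
  rx <- rbind(c(1, 0, 0), c(0, cos(r[1]), -sin(r[1])),
              c(0, sin(r[1]), cos(r[1])))
  ry <- rbind(c(cos(r[2]), 0, sin(r[2])), c(0, 1, 0),
              c(-sin(r[2]), 0, cos(r[2])))
  rz <- rbind(c(cos(r[3]), -sin(r[3]), 0), c(sin(r[3]), cos(r[3]), 0),
              c(0, 0, 1))
  rz %*% ry %*% rx
}

# Smooth, low-frequency sinusoidal displacement (mm) at world points,
# relative to the head centre. Max gradient ~ 2*pi*amp/lambda << 1, so the
# map stays diffeomorphic at the amplitudes used (<= 3 mm).
sinusoid_displacement <- function(p, amp) {
  if (amp <= 0) return(matrix(0, nrow(p), 3))
  lam <- c(150, 130, 140)
  cbind(
    amp * sin(2 * pi * p[, 2] / lam[1]) * cos(2 * pi * p[, 3] / lam[3]),
    amp * sin(2 * pi * p[, 3] / lam[2]) * cos(2 * pi * p[, 1] / lam[1]),
    amp * sin(2 * pi * p[, 1] / lam[3]) * cos(2 * pi * p[, 2] / lam[2])
  )
}

# native world point -> template anatomy world point (the generator's pull
# map: the native scan equals the template anatomy sampled through this map)
subject_pull_map <- function(subj, ctr) {
  R <- rotation_matrix(subj$rotation_deg)
  t <- subj$translation_mm
  amp <- subj$deformation_amp
  function(w) {
    p <- sweep(w, 2, ctr, "-")
    p <- p %*% t(R)
    p <- sweep(p, 2, t, "+")
    p <- p + sinusoid_displacement(p, amp)
    sweep(p, 2, ctr, "+")
  }
}

#' Generate a native-space subject CT with ground truth
#'
#' The native scan is the template anatomy at the requested severity viewed
#' through a rigid pose change plus a smooth sinusoidal deformation, with
#' acquisition noise and blur, and optionally a corrupting lesion. Because
#' the anatomy is analytic the native volume is rasterised exactly and the
#' ground-truth masks are crisp.
#'
#' @param tpl output of [make_template()].
#' @param subj a [subject_spec()].
#' @param spec the [phantom_spec()] used for the template.
#' @return List with `ct` (native [volume_image()]) and `truth`, a list
#'   holding the true native brain mask and ROI atlas, the rigid parameters,
#'   the native-to-template pull map (function on world points), the
#'   analytic structure HU and the analytic GWR values.
#' @export
make_subject <- function(tpl, subj = subject_spec(), spec = phantom_spec()) {
  grid <- grid_of(tpl$template)
  ctr <- phantom_center(spec)
  pull <- subject_pull_map(subj, ctr)
  pts <- vox_to_world(grid, grid_points(grid))
  ev <- phantom_eval(pull(pts), spec, severity = subj$severity,
                     lesion = subj$lesion)
  vol <- array(ev$hu, grid$dim)
  if (subj$noise_sd > 0) {
    set.seed(subj$seed + 1L)
    vol <- vol + array(rnorm(length(vol), 0, subj$noise_sd), dim(vol))
  }
  vol <- smooth_volume_arr(vol, spec$psf_sigma)

  gm_hu <- spec$hu$gm - subj$severity * (spec$hu$gm - spec$hu$wm)
  hu <- c(CN = gm_hu, PU = gm_hu, PIC = spec$hu$wm, CC = spec$hu$wm)
  truth <- list(
    subject = subj,
    rotation_deg = subj$rotation_deg,
    translation_mm = subj$translation_mm,
    center_mm = ctr,
    pull_map = pull,
    brain = binary_mask(array(ev$compartment %in% 3:5, grid$dim),
                        grid$spacing, grid$origin),
    rois = roi_atlas(array(ev$roi, grid$dim), grid$spacing, grid$origin),
    structure_hu = hu,
    gwr_b = (hu[["CN"]] + hu[["PU"]]) / (hu[["CC"]] + hu[["PIC"]]),
    gwr_s = hu[["PU"]] / hu[["PIC"]],
    severity = subj$severity
  )
  list(ct = volume_image(vol, grid$spacing, grid$origin), truth = truth)
}
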