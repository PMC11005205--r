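# Registration of a native CT (moving) to the template (fixed). The
# estimated mapping is kept in "pull" form: for a template-space point w the
# corresponding native-space point is A(w + v(w)) with A a rigid/affine
# world matrix and v a smooth displacement field on the template grid.
# The inverse (native -> template) is obtained by fixed-point inversion.

#' Registration settings
#'
#' @param stages character subset of `c("rigid", "affine", "deformable")`,
#'   at least one; applied in that order.
#' @param metric similarity for the rigid/affine stages: `"ncc"` (global
#'   normalized cross-correlation over the head mask; the default, suited to
#'   CT-to-CT where both images are in HU) or `"nmi"` (32-bin normalized
#'   mutual information).
#' @param iterations named list of per-stage caps (optimizer iterations for
#'   rigid/affine, demons sweeps for deformable), each >= 1.
#' @param shrink multi-resolution shrink factors, coarse to fine.
#' @param smooth_sigma Gaussian smoothing (voxels) of the demons update and
#'   field.
#' @param metric_window HU window selecting the template voxels the
#'   rigid/affine similarity is evaluated over. The default excludes air
#'   and bone: the bright skull shell is nearly elliptically symmetric and
#'   would otherwise dominate the metric while carrying little pose
#'   information; soft tissue (brain, CSF, scalp) constrains rotation far
#'   better.
#' @param seed RNG seed recorded for provenance (the optimisation itself is
#'   deterministic).
#' @return Object of class `registration_settings`.
#' @export
registration_settings <- function(stages = c("rigid", "affine", "deformable"),
                                  metric = c("ncc", "nmi"),
                                  iterations = list(rigid = 500L,
                                                    affine = 250L,
                                                    deformable = 30L),
                                  shrink = c(4L, 2L),
                                  smooth_sigma = 1.0,
                                  metric_window = c(-200, 150),
                                  seed = .gwrct_default_seed) {
  stages <- match.arg(stages, c("rigid", "affine", "deformable"),
                      several.ok = TRUE)
  if (length(stages) < 1L) stop("at least one registration stage required")
  metric <- match.arg(metric)
  if (any(unlist(iterations) < 1)) stop("iteration caps must be >= 1")
  structure(list(stages = stages, metric = metric, iterations = iterations,
                 shrink = as.integer(shrink), smooth_sigma = smooth_sigma,
                 metric_window = metric_window, seed = as.integer(seed)),
            class = "registration_settings")
}

# block-centre downsampled volume: grid spacing*f, origin shifted to block
# centres; volume smoothed for antialiasing then sampled.
downsample_volume <- function(img, f) {
  if (f == 1L) return(img)
  g <- grid_of(img)
  nd <- pmax(4L, as.integer(floor(g$dim / f)))
  sm <- smooth_volume_arr(img$voxels, f / 2)
  sub <- image_grid(nd, g$spacing * f, g$origin + (f - 1) / 2 * g$spacing)
  vox <- world_to_vox(g, vox_to_world(sub, grid_points(sub)))
  vals <- .sample_trilinear(as.numeric(sm), g$dim,
                            vox[, 1], vox[, 2], vox[, 3], min(img$voxels))
  volume_image(array(vals, nd), sub$spacing, sub$origin)
}

ncc_similarity <- function(a, b) {
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(0)
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
}

nmi_similarity <- function(a, b, bins = 32L) {
  ra <- range(a); rb <- range(b)
  if (diff(ra) == 0 || diff(rb) == 0) return(0)
  ia <- pmin(bins, 1L + floor((a - ra[1]) / diff(ra) * bins))
  ib <- pmin(bins, 1L + floor((b - rb[1]) / diff(rb) * bins))
  j <- tabulate((ib - 1L) * bins + ia, nbins = bins * bins) /
    length(a)
  pa <- tabulate(ia, nbins = bins) / length(a)
  pb <- tabulate(ib, nbins = bins) / length(b)
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  hj <- -sum(j[j > 0] * log(j[j > 0]))
  if (hj == 0) return(0)
  (ha + hb) / hj - 1
}

rigid_world_matrix <- function(par, center) {
  R <- rotation_matrix(par[1:3])
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- center - R %*% center + par[4:6]
  m
}

apply_world_matrix <- function(m, pts) {
  sweep(pts %*% t(m[1:3, 1:3]), 2, m[1:3, 4], "+")
}

# world-mm centroid of the above-threshold voxels
volume_centroid <- function(img, thr = -200) {
  idx <- which(img$voxels > thr)
  g <- grid_of(img)
  d <- g$dim
  i0 <- idx - 1L
  vox <- cbind(i0 %% d[1],
               (i0 %/% d[1]) %% d[2],
               i0 %/% (d[1] * d[2]))
  colMeans(vox_to_world(g, vox))
}

#' Register a native CT to the template
#'
#' Multi-resolution rigid and affine alignment by direct similarity
#' optimisation, followed by an optional demons-style deformable stage whose
#' smooth displacement field is numerically invertible. Deterministic for
#' fixed inputs and settings.
#'
#' @param moving native CT ([volume_image()]).
#' @param fixed template ([volume_image()]).
#' @param settings a [registration_settings()].
#' @return A `transform_pair`: the forward (template-to-native pull) affine
#'   and displacement field, grid metadata and a `meta` list with the final
#'   similarity, stage iterations and a low-confidence flag.
#' @export
register <- function(moving, fixed, settings = registration_settings()) {
  stopifnot(inherits(moving, "volume_image"), inherits(fixed, "volume_image"))
  if (stats::sd(moving$voxels) == 0 || stats::sd(fixed$voxels) == 0)
    stop("registration failure: constant input image")
  simfun <- if (settings$metric == "ncc") ncc_similarity else nmi_similarity

  gf <- grid_of(fixed)
  center <- colMeans(vox_to_world(gf, rbind(c(0, 0, 0), gf$dim - 1)))
  t0 <- volume_centroid(moving) - volume_centroid(fixed)
  par <- c(0, 0, 0, t0)
  A <- rigid_world_matrix(par, center)

  pyramids <- lapply(settings$shrink, function(f)
    list(fixed = downsample_volume(fixed, f),
         moving = downsample_volume(moving, f), f = f))

  mw <- settings$metric_window
  level_data <- function(pyr) {
    gfl <- grid_of(pyr$fixed)
    # exclude a 2-voxel shell around bone as well: voxels whose trilinear
    # samples can mix the bright skull are pose-sensitive aliasing, not
    # anatomy, and bias the optimum by degrees
    inwin <- pyr$fixed$voxels > mw[1] & pyr$fixed$voxels < mw[2]
    bone <- pyr$fixed$voxels >= mw[2]
    if (any(bone)) inwin <- inwin & !dilate_arr(bone, 2L)
    mask <- which(inwin)
    pts <- vox_to_world(gfl, grid_points(gfl))[mask, , drop = FALSE]
    fvals <- pyr$fixed$voxels[mask]
    gml <- grid_of(pyr$moving)
    mv <- as.numeric(pyr$moving$voxels)
    bg <- min(mv)
    list(pts = pts, fvals = fvals, gml = gml, mv = mv, bg = bg,
         mdim = gml$dim)
  }
  eval_affine <- function(m, ld) {
    q <- world_to_vox(ld$gml, apply_world_matrix(m, ld$pts))
    w <- .sample_trilinear(ld$mv, ld$mdim, q[, 1], q[, 2], q[, 3], ld$bg)
    simfun(w, ld$fvals)
  }

  it_used <- list()
  if ("rigid" %in% settings$stages) {
    for (pyr in pyramids) {
      ld <- level_data(pyr)
      obj <- function(p) -eval_affine(rigid_world_matrix(p, center), ld)
      # Nelder-Mead with one restart from the found vertex: the restart
      # rebuilds the simplex and recovers from premature shrinkage
      for (run in 1:2) {
        fit <- stats::optim(par, obj, method = "Nelder-Mead",
                            control = list(maxit = settings$iterations$rigid,
                                           reltol = 1e-9))
        par <- fit$par
        it_used$rigid <- (it_used$rigid %||% 0L) + fit$counts[["function"]]
      }
    }
    A <- rigid_world_matrix(par, center)
  }
  if ("affine" %in% settings$stages) {
    ld <- level_data(pyramids[[length(pyramids)]])
    base <- A
    scale12 <- c(rep(0.01, 9), rep(1, 3))
    with_delta <- function(d) {
      m <- base
      m[1:3, ] <- m[1:3, ] + matrix(d * scale12, 3, 4)
      m
    }
    # ridge on the deviation from the rigid result: the similarity is
    # nearly flat along small shears of smooth anatomy, and unpenalized
    # 12-parameter search drifts along that flat valley
    obj <- function(d) -eval_affine(with_delta(d), ld) + 1e-3 * sum(d^2)
    fit <- stats::optim(rep(0, 12), obj, method = "Nelder-Mead",
                        control = list(maxit = settings$iterations$affine,
                                       reltol = 1e-8))
    cand <- with_delta(fit$par)
    if (eval_affine(cand, ld) > eval_affine(base, ld)) A <- cand
    it_used$affine <- fit$counts[["function"]]
  }

  disp <- NULL
  if ("deformable" %in% settings$stages) {
    f <- settings$shrink[length(settings$shrink)]
    pyr <- pyramids[[length(pyramids)]]
    dem <- demons_stage(pyr$moving, pyr$fixed, A,
                        iters = settings$iterations$deformable,
                        sigma = settings$smooth_sigma)
    it_used$deformable <- dem$iters
    # upsample the field (world-mm components) to the full fixed grid
    gl <- grid_of(pyr$fixed)
    full_pts <- world_to_vox(gl, vox_to_world(gf, grid_points(gf)))
    disp <- array(0, c(gf$dim, 3))
    for (k in 1:3) {
      disp[, , , k] <- array(
        .sample_trilinear(as.numeric(dem$v[, , , k]), gl$dim,
                          full_pts[, 1], full_pts[, 2], full_pts[, 3], 0),
        gf$dim)
    }
  }

  pair <- structure(list(
    affine = A, disp = disp, fixed_grid = gf, moving_grid = grid_of(moving),
    meta = list(settings = settings, iterations = it_used)
  ), class = "transform_pair")

  # per-stage similarity on the full fixed grid (soft-tissue mask), used
  # to verify that similarity never decreases across stages
  full_mask <- which(fixed$voxels > mw[1] & fixed$voxels < mw[2])
  fvals_full <- fixed$voxels[full_mask]
  sim_of <- function(mat, dsp) {
    p <- structure(list(affine = mat, disp = dsp, fixed_grid = gf,
                        moving_grid = grid_of(moving), meta = list()),
                   class = "transform_pair")
    w <- resample(moving, p, gf)
    simfun(w$voxels[full_mask], fvals_full)
  }
  stage_sim <- c(initial = sim_of(rigid_world_matrix(c(0, 0, 0, t0), center),
                                  NULL))
  if ("rigid" %in% settings$stages || "affine" %in% settings$stages)
    stage_sim <- c(stage_sim, aligned = sim_of(A, NULL))
  if (!is.null(disp))
    stage_sim <- c(stage_sim, deformable = sim_of(A, disp))
  pair$meta$stage_similarity <- stage_sim

  warped <- resample(moving, pair, gf)
  final_sim <- simfun(as.numeric(warped$voxels), as.numeric(fixed$voxels))
  pair$meta$similarity <- final_sim
  pair$meta$low_confidence <- is.na(final_sim) || final_sim < 0.6
  pair
}

# demons-style deformable stage on the finest pyramid level; returns the
# displacement field v (world mm, dim x 3) with m(w) = A(w + v(w)).
demons_stage <- function(moving_l, fixed_l, A, iters, sigma) {
  gfl <- grid_of(fixed_l)
  gml <- grid_of(moving_l)
  d <- gfl$dim
  pts <- vox_to_world(gfl, grid_points(gfl))
  fvals <- as.numeric(fixed_l$voxels)
  mv <- as.numeric(moving_l$voxels)
  bg <- min(mv)
  sp <- gfl$spacing
  v <- array(0, c(d, 3))
  best_v <- v
  best_sim <- -Inf
  head <- fvals > -200
  for (it in seq_len(iters)) {
    w <- pts + cbind(as.numeric(v[, , , 1]), as.numeric(v[, , , 2]),
                     as.numeric(v[, , , 3]))
    q <- world_to_vox(gml, apply_world_matrix(A, w))
    warped <- .sample_trilinear(mv, gml$dim, q[, 1], q[, 2], q[, 3], bg)
    sim <- ncc_similarity(warped[head], fvals[head])
    if (sim > best_sim) { best_sim <- sim; best_v <- v }
    warr <- array(warped, d)
    gx <- array(0, d); gy <- array(0, d); gz <- array(0, d)
    gx[2:(d[1] - 1), , ] <- (warr[3:d[1], , ] - warr[1:(d[1] - 2), , ]) /
      (2 * sp[1])
    gy[, 2:(d[2] - 1), ] <- (warr[, 3:d[2], ] - warr[, 1:(d[2] - 2), ]) /
      (2 * sp[2])
    gz[, , 2:(d[3] - 1)] <- (warr[, , 3:d[3]] - warr[, , 1:(d[3] - 2)]) /
      (2 * sp[3])
    diffv <- fvals - warped
    g2 <- as.numeric(gx)^2 + as.numeric(gy)^2 + as.numeric(gz)^2
    denom <- g2 + (diffv / mean(sp))^2
    scale <- ifelse(denom > 1e-8, diffv / denom, 0)
    upd <- c(scale * as.numeric(gx), scale * as.numeric(gy),
             scale * as.numeric(gz))
    upd <- pmin(pmax(upd, -mean(sp)), mean(sp))
    upd <- array(upd, c(d, 3))
    for (k in 1:3) {
      v[, , , k] <- smooth_volume_arr(v[, , , k] +
                                        smooth_volume_arr(upd[, , , k],
                                                          sigma), sigma)
    }
  }
  list(v = best_v, iters = iters, similarity = best_sim)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# forward pull: template-space world points -> native-space world points
forward_points <- function(pair, pts_world) {
  w <- pts_world
  if (!is.null(pair$disp)) {
    g <- pair$fixed_grid
    vox <- world_to_vox(g, pts_world)
    for (k in 1:3) {
      w[, k] <- w[, k] +
        .sample_trilinear(as.numeric(pair$disp[, , , k]), g$dim,
                          vox[, 1], vox[, 2], vox[, 3], 0)
    }
  }
  apply_world_matrix(pair$affine, w)
}

# inverse pull: native-space world points -> template-space world points,
# by fixed-point inversion of w + v(w) (<= 50 iterations, tol 0.1 voxel)
inverse_points <- function(pair, pts_world, max_iter = 50L, tol = NULL) {
  Ainv <- solve(pair$affine)
  z <- apply_world_matrix(Ainv, pts_world)
  if (is.null(pair$disp)) return(z)
  g <- pair$fixed_grid
  if (is.null(tol)) tol <- 0.1 * min(g$spacing)
  x <- z
  for (i in seq_len(max_iter)) {
    vox <- world_to_vox(g, x)
    vx <- matrix(0, nrow(x), 3)
    for (k in 1:3) {
      vx[, k] <- .sample_trilinear(as.numeric(pair$disp[, , , k]), g$dim,
                                   vox[, 1], vox[, 2], vox[, 3], 0)
    }
    xn <- z - vx
    step <- max(abs(xn - x))
    x <- xn
    if (step < tol) break
  }
  x
}

#' Resample an image through a transform
#'
#' @param img source [volume_image()].
#' @param transform a `transform_pair` (its forward pull map is used), a
#'   4x4 world-coordinate pull matrix mapping target points to source
#'   points, or `NULL` for identity.
#' @param target_grid an [image_grid()] describing the output grid.
#' @param interpolation `"linear"` or `"nearest"` (nearest never invents
#'   values, required for label maps).
#' @param background value used outside the source field of view.
#' @return A [volume_image()] on `target_grid`.
#' @export
resample <- function(img, transform, target_grid,
                     interpolation = c("linear", "nearest"),
                     background = min(img$voxels)) {
  interpolation <- match.arg(interpolation)
  gs <- grid_of(img)
  pts <- vox_to_world(target_grid, grid_points(target_grid))
  if (is.null(transform)) {
    src <- pts
  } else if (inherits(transform, "transform_pair")) {
    src <- forward_points(transform, pts)
  } else if (is.matrix(transform) && all(dim(transform) == c(4, 4))) {
    src <- apply_world_matrix(transform, pts)
  } else stop("unsupported transform type")
  vox <- world_to_vox(gs, src)
  sampler <- if (interpolation == "linear") .sample_trilinear else
    .sample_nearest
  vals <- sampler(as.numeric(img$voxels), gs$dim,
                  vox[, 1], vox[, 2], vox[, 3], background)
  volume_image(array(vals, target_grid$dim), target_grid$spacing,
               target_grid$origin)
}

#' Map refined template-space ROIs back to native space
#'
#' Applies the inverse mapping with nearest-neighbour sampling, preserving
#' the label table. Structures empty in the input stay empty.
#'
#' @param refined template-space [roi_atlas()] (typically the refined
#'   atlas).
#' @param pair a `transform_pair` from [register()].
#' @param native_grid the native-space [image_grid()].
#' @return An [roi_atlas()] on the native grid.
#' @export
inverse_map_rois <- function(refined, pair, native_grid) {
  stopifnot(inherits(refined, "roi_atlas"),
            inherits(pair, "transform_pair"))
  pts <- vox_to_world(native_grid, grid_points(native_grid))
  tp <- inverse_points(pair, pts)
  g <- grid_of_atlas(refined)
  vox <- world_to_vox(g, tp)
  vals <- .sample_nearest(as.numeric(refined$labels), g$dim,
                          vox[, 1], vox[, 2], vox[, 3], 0)
  lab <- array(as.integer(round(vals)), native_grid$dim)
  roi_atlas(lab, native_grid$spacing, native_grid$origin,
            label_table = refined$label_table)
}

grid_of_atlas <- function(atlas) {
  image_grid(dim(atlas$labels), atlas$spacing, atlas$origin)
}

#' Registration accuracy score
#'
#' Dice overlap between the brain extracted from the warped CT and the
#' template brain mask, in `[0, 1]`. "Low registration accuracy" has no
#' canonical score; this Dice-based criterion (exclusion below 0.90 by
#' default at the QC stage) is this package's operational definition and
#' is configurable.
#'
#' @param warped the moving image resampled onto the template grid.
#' @param fixed the template image (unused beyond grid checks; kept so the
#'   score's signature states its inputs explicitly).
#' @param fixed_brain the template brain mask.
#' @return Numeric score in `[0, 1]`; 0 when brain extraction fails.
#' @export
registration_accuracy <- function(warped, fixed, fixed_brain) {
  stopifnot(identical(dim(warped$voxels), dim(fixed_brain$voxels)))
  eb <- tryCatch(brain_extract(warped), error = function(e) NULL)
  if (is.null(eb) || sum(eb$voxels) == 0L) return(0)
  dice(eb, fixed_brain)
}

#' Serialize a transform pair
#'
#' Writes the affine as JSON (`<path>.json`, row-major 4x4, plus stage
#' metadata) and, when present, the displacement field as a 4-D NIfTI
#' volume (`<path>_disp.nii.gz`, last axis = component, mm units).
#'
#' @param pair a `transform_pair` from [register()].
#' @param path output path stem (no extension).
#' @return Invisibly, the JSON path.
#' @export
write_transform <- function(pair, path) {
  stopifnot(inherits(pair, "transform_pair"))
  meta <- list(
    affine = as.numeric(t(pair$affine)),
    fixed_grid = pair$fixed_grid[c("dim", "spacing", "origin")],
    moving_grid = pair$moving_grid[c("dim", "spacing", "origin")],
    similarity = pair$meta$similarity,
    iterations = pair$meta$iterations,
    has_displacement = !is.null(pair$disp)
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(pair$disp)) {
    img <- RNifti::asNifti(pair$disp)
    RNifti::pixdim(img) <- pair$fixed_grid$spacing
    RNifti::writeNifti(img, paste0(path, "_disp.nii.gz"))
  }
  invisible(paste0(path, ".json"))
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  disp <- NULL
  if (isTRUE(meta$has_displacement)) {
    img <- RNifti::readNifti(paste0(path, "_disp.nii.gz"))
    disp <- array(as.numeric(img), dim(img))
  }
  fg <- image_grid(meta$fixed_grid$dim, meta$fixed_grid$spacing,
                   meta$fixed_grid$origin)
  mg <- image_grid(meta$moving_grid$dim, meta$moving_grid$spacing,
                   meta$moving_grid$origin)
  structure(list(
    affine = matrix(meta$affine, 4, 4, byrow = TRUE),
    disp = disp, fixed_grid = fg, moving_grid = mg,
    meta = list(similarity = meta$similarity,
                iterations = meta$iterations)
  ), class = "transform_pair")
}
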