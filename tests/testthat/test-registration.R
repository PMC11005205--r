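# Registration contract: resampling, self-registration, parameter
# recovery, inverse mapping, round-trip consistency and the accuracy score.

test_that("resample honours identity, integer shifts and constants", {
  set.seed(3)
  img <- volume_image(array(rnorm(10 * 10 * 10, 30, 5), c(10, 10, 10)),
                      spacing = c(2, 2, 2))
  g <- gwrct:::grid_of(img)
  out <- resample(img, NULL, g)
  expect_equal(out$voxels, img$voxels, tolerance = 1e-12)

  # pure +1 voxel shift along x via a world pull matrix, nearest neighbour
  m <- diag(4); m[1, 4] <- 2
  shifted <- resample(img, m, g, interpolation = "nearest")
  expect_equal(shifted$voxels[1:9, , ], img$voxels[2:10, , ],
               tolerance = 1e-12)

  const <- volume_image(array(7, c(8, 8, 8)))
  m2 <- diag(4); m2[1:3, 4] <- c(0.3, -0.4, 0.2)
  expect_true(all(abs(resample(const, m2, gwrct:::grid_of(const),
                               background = 7)$voxels - 7) < 1e-9))
})

test_that("self-registration is close to the identity mapping", {
  tpl <- fx_template()
  pair <- register(tpl$template, tpl$template,
                   registration_settings(stages = c("rigid", "affine")))
  g <- gwrct:::grid_of(tpl$template)
  pts <- gwrct:::vox_to_world(g, gwrct:::grid_points(g))
  moved <- gwrct:::forward_points(pair, pts)
  disp_vox <- sqrt(rowSums((moved - pts)^2)) / min(g$spacing)
  expect_lt(mean(disp_vox), 0.5)
})

test_that("known rigid pose is recovered within 1 degree and 1 mm", {
  rc <- fx_rigid_case()
  err <- rigid_error(rc$pair, rc$subj, fx_spec())
  expect_lt(err[["rot_deg"]], 1)
  expect_lt(err[["trans_mm"]], 1)
})

test_that("deformable registration restores brain overlap", {
  dc <- fx_deform_case()
  tpl <- fx_template()
  expect_gte(dice(brain_extract(dc$warped), tpl$brain), 0.95)
})

test_that("similarity never decreases across registration stages", {
  for (pair in list(fx_rigid_case()$pair, fx_deform_case()$pair)) {
    ss <- pair$meta$stage_similarity
    expect_true(all(diff(ss) >= -1e-6))
  }
})

test_that("registration is deterministic and rejects degenerate input", {
  tpl <- fx_template()
  rc <- fx_rigid_case()
  again <- register(rc$case$ct, tpl$template,
                    registration_settings(stages = c("rigid", "affine")))
  expect_identical(again$affine, rc$pair$affine)
  flat <- volume_image(array(0, c(16, 16, 16)))
  expect_error(register(flat, flat), "constant")
})

test_that("inverse mapping preserves labels and empty structures", {
  tpl <- fx_template()
  g <- gwrct:::grid_of(tpl$template)
  idpair <- structure(list(affine = diag(4), disp = NULL,
                           fixed_grid = g, moving_grid = g, meta = list()),
                      class = "transform_pair")
  back <- inverse_map_rois(tpl$atlas, idpair, g)
  expect_identical(back$labels, tpl$atlas$labels)

  # an atlas whose CC labels were emptied stays empty after mapping
  lab <- tpl$atlas$labels
  lab[lab %in% 7:9] <- 0L
  noCC <- roi_atlas(lab, tpl$atlas$spacing, tpl$atlas$origin)
  mapped <- inverse_map_rois(noCC, fx_rigid_case()$pair, g)
  expect_equal(sum(mapped$labels %in% 7:9), 0L)
})

test_that("inversely mapped ROIs overlap the generator's native truth", {
  rc <- fx_rigid_case()
  tpl <- fx_template()
  g <- gwrct:::grid_of(rc$case$ct)
  mapped <- inverse_map_rois(tpl$atlas, rc$pair, g)
  for (lab in 1:9) {
    a <- binary_mask(mapped$labels == lab, mapped$spacing, mapped$origin)
    b <- binary_mask(rc$case$truth$rois$labels == lab,
                     mapped$spacing, mapped$origin)
    expect_gte(dice(a, b), 0.85)
  }
})

test_that("forward-inverse round trip stays within one voxel on average", {
  for (pair in list(fx_rigid_case()$pair, fx_deform_case()$pair)) {
    tpl <- fx_template()
    g <- gwrct:::grid_of(tpl$template)
    idx <- which(tpl$brain$voxels)
    pts <- gwrct:::vox_to_world(g, gwrct:::grid_points(g))[idx, ]
    rt <- gwrct:::inverse_points(pair, gwrct:::forward_points(pair, pts))
    err_vox <- sqrt(rowSums((rt - pts)^2)) / min(g$spacing)
    expect_lt(mean(err_vox), 1)
  }
})

test_that("accuracy score behaves at its extremes and ranks quality", {
  # crisp (blur-free) phantom: self-accuracy is essentially perfect
  tpl0 <- fx("template0", make_template(phantom_spec(psf_sigma = 0)))
  expect_gte(registration_accuracy(tpl0$template, tpl0$template,
                                   tpl0$brain), 0.99)
  tpl <- fx_template()
  air <- volume_image(array(-1000, fx_spec()$dim), fx_spec()$spacing)
  expect_equal(registration_accuracy(air, tpl$template, tpl$brain), 0)

  rc <- fx_rigid_case()
  g <- gwrct:::grid_of(tpl$template)
  good <- registration_accuracy(resample(rc$case$ct, rc$pair, g),
                                tpl$template, tpl$brain)
  lame <- register(rc$case$ct, tpl$template,
                   registration_settings(
                     stages = "rigid",
                     iterations = list(rigid = 1L, affine = 1L,
                                       deformable = 1L)))
  bad <- registration_accuracy(resample(rc$case$ct, lame, g),
                               tpl$template, tpl$brain)
  expect_lt(bad, good)
})

test_that("transforms serialize and reload faithfully", {
  pair <- fx_deform_case()$pair
  stem <- tempfile()
  write_transform(pair, stem)
  back <- read_transform(stem)
  expect_equal(back$affine, pair$affine, tolerance = 1e-6)
  expect_equal(dim(back$disp), dim(pair$disp))
  expect_lt(max(abs(back$disp - pair$disp)), 1e-4)
  unlink(paste0(stem, c(".json", "_disp.nii.gz")))
})
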