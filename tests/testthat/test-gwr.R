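# Structure HU statistics, the two GWR formulas and the manual-style
# circular sampler.

make_uniform_case <- function() {
  # crisp uniform phantom: GM ROIs at 38, white ROIs at 30
  tpl <- fx_template()
  spec <- fx_spec()
  grid <- image_grid(spec$dim, spec$spacing)
  pts <- gwrct:::vox_to_world(grid, gwrct:::grid_points(grid))
  ev <- gwrct:::phantom_eval(pts, spec, severity = 0)
  list(ct = volume_image(array(ev$hu, spec$dim), spec$spacing),
       rois = tpl$atlas)
}

test_that("uniform regions give exact pooled means", {
  uc <- make_uniform_case()
  s <- roi_statistics(uc$ct, uc$rois)
  p <- s$pooled
  expect_equal(p$mean[p$structure == "CN"], 38)
  expect_equal(p$mean[p$structure == "PU"], 38)
  expect_equal(p$mean[p$structure == "PIC"], 30)
  expect_equal(p$mean[p$structure == "CC"], 30)
  expect_equal(gwr_b(s), 76 / 60, tolerance = 1e-12)
  expect_equal(gwr_s(s), 38 / 30, tolerance = 1e-12)
  # pooled mean lies between part means
  parts <- s$parts
  for (st in unique(parts$structure)) {
    pm <- p$mean[p$structure == st]
    expect_gte(pm, min(parts$mean[parts$structure == st]) - 1e-9)
    expect_lte(pm, max(parts$mean[parts$structure == st]) + 1e-9)
  }
})

test_that("noisy CN mean concentrates around truth at the CLT rate", {
  # pure-noise acquisition (no reconstruction blur) at identity pose
  cs <- fx("clt_case", {
    spec0 <- phantom_spec(psf_sigma = 0)
    tpl0 <- make_template(spec0)
    make_subject(tpl0, subject_spec(severity = 0,
                                    rotation_deg = c(0, 0, 0),
                                    translation_mm = c(0, 0, 0),
                                    deformation_amp = 0, noise_sd = 2,
                                    seed = 19L), spec0)
  })
  s <- roi_statistics(cs$ct, cs$truth$rois)
  cn <- s$pooled[s$pooled$structure == "CN", ]
  expect_gt(cn$n, 300)
  expect_lt(abs(cn$mean - 38), 3 * 2 / sqrt(cn$n))
})

test_that("the HU window excludes out-of-range voxels from the count", {
  v <- array(30, c(10, 10, 10))
  lab <- array(0L, c(10, 10, 10))
  lab[3:5, 3:5, 3:5] <- 3L          # PU_L
  v[3, 3, 3] <- 120                 # one artifact voxel
  s_all <- roi_statistics(volume_image(v), roi_atlas(lab))
  s_win <- roi_statistics(volume_image(v), roi_atlas(lab),
                          hu_window = hu_window_preset())
  expect_equal(s_all$parts$n[3], 27L)
  expect_equal(s_win$parts$n[3], 26L)
  expect_equal(s_win$parts$mean[3], 30)
})

test_that("GWR formulas match direct arithmetic and flag undefined cases", {
  mk <- function(cn, pu, pic, cc) {
    pooled <- data.frame(
      structure = c("CN", "PU", "PIC", "CC"),
      mean = c(cn, pu, pic, cc), sd = 1, n = c(10L, 10L, 10L, 10L),
      missing = is.na(c(cn, pu, pic, cc)))
    pooled$n[pooled$missing] <- 0L
    structure(list(pooled = pooled, parts = NULL, hu_window = NULL),
              class = "structure_hu")
  }
  expect_equal(gwr_b(mk(30, 30, 30, 30)), 1.0)
  expect_equal(gwr_b(mk(38, 40, 32, 30)), 78 / 62, tolerance = 1e-12)
  expect_equal(gwr_s(mk(38, 40, 32, 30)), 40 / 32, tolerance = 1e-12)
  expect_equal(gwr_s(mk(38, 40, 40, 30)), 1.0)

  ccless <- gwr_b(mk(38, 40, 32, NA))
  expect_true(is.na(ccless))
  expect_equal(attr(ccless, "undefined"), "missing structure")
  piczero <- gwr_s(mk(38, 40, 0, 30))
  expect_true(is.na(piczero))
})

test_that("GWR is invariant under positive rescaling of HU", {
  uc <- make_uniform_case()
  for (c_ in c(0.5, 2, 10)) {
    scaled <- volume_image(uc$ct$voxels * c_, uc$ct$spacing)
    s1 <- roi_statistics(uc$ct, uc$rois)
    s2 <- roi_statistics(scaled, uc$rois)
    expect_equal(gwr_b(s2), gwr_b(s1), tolerance = 1e-12)
    expect_equal(gwr_s(s2), gwr_s(s1), tolerance = 1e-12)
  }
})

test_that("circular sampler matches the exhaustive pixel oracle", {
  set.seed(8)
  v <- array(rnorm(50 * 50 * 8, 35, 4), c(50, 50, 8))
  img <- volume_image(v, spacing = c(1, 1, 5))
  for (case in list(c(25, 25, 10), c(12.3, 30.7, 10), c(40, 8.2, 6))) {
    got <- manual_circle_mean(img, 4L, case[1:2], case[3])
    r <- sqrt(case[3] / pi)
    inc <- matrix(FALSE, 50, 50)
    for (i in 1:50) for (j in 1:50) {
      inc[i, j] <- (i - 1 - case[1])^2 + (j - 1 - case[2])^2 <= r^2
    }
    expect_equal(as.numeric(got), mean(v[, , 4][inc]), tolerance = 1e-12)
    expect_equal(attr(got, "n_pixels"), sum(inc))
  }
  # 10 mm^2 at 1 mm pixels includes 9-13 pixel centres
  n <- attr(manual_circle_mean(img, 4L, c(25.4, 24.7), 10), "n_pixels")
  expect_gte(n, 9L); expect_lte(n, 13L)
})

test_that("circular sampler handles uniform regions and bounds", {
  img <- volume_image(array(35, c(20, 20, 8)), spacing = c(1, 1, 5))
  expect_equal(as.numeric(manual_circle_mean(img, 3L, c(10, 10), 10)), 35)
  expect_error(manual_circle_mean(img, 3L, c(0.5, 10), 10), "fit")
  expect_error(manual_circle_mean(img, 99L, c(10, 10), 10), "slice")
})

test_that("excluded cases never carry GWR values, ok cases always do", {
  qc_ok <- evaluate_case(0.97, attr(fx_severity_case(0)$result, "stages")$refined)
  s <- fx_severity_case(0)$result$structure_hu
  r_ok <- gwr_result(s, qc_ok)
  expect_false(is.na(r_ok$gwr_b))
  qc_bad <- evaluate_case(0.5, NULL)
  r_bad <- gwr_result(s, qc_bad)
  expect_true(is.na(r_bad$gwr_b) && is.na(r_bad$gwr_s))
})
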