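make_step_image <- function(thickness = 100, img_cfg = coarse_imaging()) {
  render_bscan(thickness, img_cfg)
}

test_that("masking is the identity for an empty box list", {
  b <- make_step_image()
  expect_identical(mask_regions(b, list())$intensity, b$intensity)
})

test_that("out-of-bounds mask boxes are rejected", {
  b <- make_step_image()
  expect_error(mask_regions(b, list(list(rows = c(0, 5), cols = c(1, 5)))),
               "out of image bounds")
  expect_error(mask_regions(b, list(list(rows = c(1, 5),
                                         cols = c(1, 10000)))),
               "out of image bounds")
})

test_that("masking the whole image makes every column undetected", {
  b <- make_step_image()
  whole <- list(list(rows = c(1, nrow(b$intensity)),
                     cols = c(1, ncol(b$intensity))))
  cv <- detect_interfaces(mask_regions(b, whole))
  expect_true(all(is.na(cv$surface_row)))
  expect_true(all(is.na(cv$substratum_row)))
})

test_that("masking floating artifacts restores artifact-free extraction", {
  ic <- imaging_config(noise_sd = 0, artifact_rate = 3)
  b <- render_bscan(rep(150, ic$n_cols), ic, seed = 11)
  expect_gt(length(b$truth$artifact_boxes), 0)
  unmasked <- thickness_profile(detect_interfaces(b), ic)
  expect_gt(unmasked$image_mean_um, 150)   # artifacts inflate thickness
  masked <- mask_regions(b, b$truth$artifact_boxes)
  pm <- thickness_profile(detect_interfaces(masked), ic)
  expect_lt(abs(pm$image_mean_um - 150), ic$axial_pixel)
})

test_that("noise-free interfaces are detected exactly", {
  ic <- coarse_imaging()
  set.seed(42)
  th <- runif(ic$n_cols, 50, 600)
  b <- render_bscan(th, ic)
  cv <- detect_interfaces(b)
  expect_identical(cv$surface_row, b$truth$surface_row)
  expect_identical(cv$substratum_row, b$truth$substratum_row)
})

test_that("a constant-intensity image yields no detections", {
  b <- make_step_image()
  b$intensity[] <- 57
  cv <- detect_interfaces(b)
  expect_true(all(is.na(cv$surface_row)))
})

test_that("zero-thickness columns report coinciding interfaces", {
  ic <- coarse_imaging()
  b <- render_bscan(0, ic)
  cv <- detect_interfaces(b)
  expect_true(all(cv$surface_row == cv$substratum_row))
  pr <- thickness_profile(cv, ic)
  expect_true(all(pr$thickness_um == 0))
  expect_true(all(pr$censored))
})

test_that("speckled images are detected within 2 rows of ground truth", {
  ic <- imaging_config(noise_sd = 8)
  hits <- 0L; total <- 0L
  for (s in 1:20) {
    set.seed(s)
    b <- render_bscan(runif(ic$n_cols, 80, 400), ic, seed = s + 500)
    cv <- detect_interfaces(b)
    ok <- abs(cv$surface_row - b$truth$surface_row) <= 2 &
      abs(cv$substratum_row - b$truth$substratum_row) <= 2
    hits <- hits + sum(ok, na.rm = TRUE)
    total <- total + length(ok)
  }
  expect_gt(hits / total, 0.95)
})

test_that("manual overrides replace rows only where specified", {
  ic <- coarse_imaging()
  b <- render_bscan(100, ic)
  cv <- detect_interfaces(b)
  expect_identical(manual_overrides(cv, NULL), cv)
  expect_identical(manual_overrides(cv, data.frame()), cv)

  ov <- data.frame(col_start = 1, col_end = 50, surface_row = NA,
                   substratum_row = 200)
  cv2 <- manual_overrides(cv, ov)
  expect_true(all(cv2$substratum_row[1:50] == 200))
  expect_identical(cv2$substratum_row[51:nrow(cv2)],
                   cv$substratum_row[51:nrow(cv)])
  expect_identical(cv2$surface_row, cv$surface_row)

  bad <- data.frame(col_start = 1, col_end = 10, surface_row = 220,
                    substratum_row = NA)
  expect_error(manual_overrides(manual_overrides(cv, ov), bad),
               "surface_row <= substratum_row")
  expect_error(manual_overrides(cv, data.frame(col_start = 0, col_end = 5,
                                               surface_row = 1,
                                               substratum_row = 2)),
               "out of bounds")
})

test_that("overrides repair an undetected stretch back to truth", {
  ic <- coarse_imaging()
  b <- render_bscan(200, ic)
  # wipe columns 1-40 so detection fails there
  bwiped <- mask_regions(b, list(list(rows = c(1, nrow(b$intensity)),
                                      cols = c(1, 40))))
  cv <- detect_interfaces(bwiped)
  expect_true(all(is.na(cv$surface_row[1:40])))
  ov <- data.frame(col_start = 1, col_end = 40,
                   surface_row = b$truth$surface_row[1],
                   substratum_row = b$truth$substratum_row[1])
  pr <- thickness_profile(manual_overrides(cv, ov), ic)
  expect_lt(abs(pr$image_mean_um - 200), ic$axial_pixel)
})

test_that("binary maps have column sums equal to interface separation", {
  ic <- coarse_imaging()
  b <- render_bscan(100, ic)
  cv <- detect_interfaces(b)
  # random plausible curves, including zero-thickness and undetected columns
  set.seed(9)
  nc <- nrow(cv)
  cv$substratum_row <- sample(50:200, nc, replace = TRUE)
  cv$surface_row <- cv$substratum_row - sample(0:40, nc, replace = TRUE)
  cv$surface_row[1:5] <- NA
  cv$substratum_row[1:5] <- NA
  bin <- binarize(b, cv)
  expect_identical(unname(colSums(bin)[6:nc]),
                   as.numeric(cv$substratum_row - cv$surface_row)[6:nc])
  expect_true(all(colSums(bin)[1:5] == 0))
})

test_that("thickness arithmetic and censoring follow the axial scale", {
  ic <- imaging_config(axial_pixel = 4.4, lateral_pixel = 4,
                       image_height = 1.1, noise_sd = 0)
  b <- render_bscan(44, ic)
  cv <- detect_interfaces(b)
  pr <- thickness_profile(cv, ic)
  expect_true(all(pr$thickness_um == 44))   # 10 rows x 4.4 um
  expect_false(any(pr$censored))

  # separation 0 -> 0 um, censored; half-limit policy vs exclusion
  cv0 <- cv; cv0$surface_row <- cv0$substratum_row
  p0 <- thickness_profile(cv0, ic)
  expect_true(all(p0$censored))
  expect_equal(p0$image_mean_um, ic$detection_limit / 2)
  pex <- thickness_profile(cv0, ic, censor_policy = "exclude")
  expect_true(is.na(pex$image_mean_um))
})

test_that("image means match brute-force recomputation with undetected columns", {
  ic <- coarse_imaging()
  b <- render_bscan(100, ic)
  cv <- detect_interfaces(b)
  set.seed(4)
  drop <- sample(nrow(cv), 0.3 * nrow(cv))
  cv$surface_row[drop] <- NA
  cv$substratum_row[drop] <- NA
  pr <- thickness_profile(cv, ic)
  manual <- (cv$substratum_row - cv$surface_row) * ic$axial_pixel
  manual[!is.na(manual) & manual < ic$detection_limit] <-
    ic$detection_limit / 2
  expect_equal(pr$image_mean_um, mean(manual, na.rm = TRUE))
  expect_equal(pr$fraction_undetected, 0.3)
  expect_false(pr$flagged)
  cv$surface_row[] <- NA; cv$substratum_row[] <- NA
  cv$surface_row[1] <- 10; cv$substratum_row[1] <- 20
  expect_true(thickness_profile(cv, ic)$flagged)
})

test_that("section aggregation reproduces grouped means and the layout", {
  lay <- hose_layout()
  expect_equal(n_images(lay), 1200)
  expect_equal(n_sections(lay), 200)
  expect_equal(images_per_section(lay), 6)

  expect_equal(aggregate_sections(list(top = rep(7.5, 6)),
                                  small_layout())$thickness_um[1], 7.5)

  set.seed(8)
  means <- list(top = runif(60, 10, 300), bottom = runif(60, 10, 300))
  agg <- aggregate_sections(means, small_layout())
  expect_equal(nrow(agg), 20)
  oracle <- c(tapply(means$top, rep(1:10, each = 6), mean),
              tapply(means$bottom, rep(1:10, each = 6), mean))
  expect_equal(agg$thickness_um, unname(oracle))
  # aggregation conserves the global mean under equal image counts
  expect_equal(mean(agg$thickness_um), mean(unlist(means)))
  expect_error(aggregate_sections(list(top = runif(7)), small_layout()),
               "not divisible")
})

test_that("noise-free render-detect-aggregate reproduces section means", {
  cfg <- small_cfg(seed = 3)
  sim <- simulate_hose(cfg)
  ic <- coarse_imaging()
  imgs <- render_hose_images(sim, ic, small_layout())
  ext <- extract_hose_thickness(imgs, ic, small_layout())
  truth <- field_section_means(sim$field)
  expect_identical(ext$section_id, truth$section_id)
  expect_lt(max(abs(ext$thickness_um - truth$true_thickness_um)),
            ic$axial_pixel)
})

test_that("detection after masking equals detection on an artifact-free render", {
  ic_clean <- imaging_config(noise_sd = 0)
  ic_art <- imaging_config(noise_sd = 0, artifact_rate = 3)
  th <- seq(100, 300, length.out = ic_clean$n_cols)
  clean <- detect_interfaces(render_bscan(th, ic_clean))
  b <- render_bscan(th, ic_art, seed = 21)
  masked <- detect_interfaces(mask_regions(b, b$truth$artifact_boxes))
  expect_true(all(abs(masked$surface_row - clean$surface_row) <= 1))
  expect_true(all(abs(masked$substratum_row - clean$substratum_row) <= 1))
})
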