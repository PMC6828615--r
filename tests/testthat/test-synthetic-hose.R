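test_that("degenerate no-noise configuration yields a constant field", {
  field <- generate_thickness_field(flat_cfg(baseline = 300))
  for (h in c("top", "bottom"))
    expect_true(all(field$halves[[h]]$thickness_um == 300))
  sec <- field_section_means(field)
  expect_equal(sec$true_thickness_um, rep(300, 20))
})

test_that("the same seed reproduces every artifact bit-identically", {
  cfg <- small_cfg(seed = 11, missing_section_prob = 0.1)
  sim1 <- simulate_hose(cfg)
  sim2 <- simulate_hose(cfg)
  expect_identical(sim1$sections, sim2$sections)
  expect_identical(sim1$community, sim2$community)
  # independent streams: regenerating one artifact does not shift others
  expect_identical(generate_community(cfg), sim1$community)
  expect_identical(generate_thickness_field(cfg)$halves,
                   sim1$field$halves)
})

test_that("invalid generator configurations are rejected", {
  expect_error(sim_config(hose_length = 121), "whole multiple")
  expect_error(sim_config(dominant_profile = c(a = 0.6, b = 0.5)),
               "sum to < 1")
  expect_error(sim_config(missing_section_prob = 1.5), "probability")
  expect_error(sim_config(n_taxa = 2), "smaller than")
  expect_error(sim_config(tcc_mean = -1), "positive")
  # baseline driving most of the hose negative
  expect_error(generate_thickness_field(
    sim_config(baseline_thickness = c(top = -500, bottom = 300),
               trend_slope = c(top = 1, bottom = 1))),
    "zero")
})

test_that("configured trend slopes are recovered by OLS on section means", {
  slopes <- vapply(1:30, function(s) {
    field <- generate_thickness_field(sim_config(seed = s))
    sec <- field_section_means(field)
    d <- sec[sec$half == "top", ]
    longitudinal_trend(d$true_thickness_um, d$position_cm)$slope
  }, numeric(1))
  # Monte-Carlo mean of the estimator should sit near the configured value
  expect_lt(abs(mean(slopes) - 0.83), 3 * stats::sd(slopes) / sqrt(30))
})

test_that("larger small-scale cv produces larger adjacent-section variation", {
  diffs <- vapply(1:50, function(s) {
    f1 <- generate_thickness_field(
      sim_config(smallscale_cv = c(top = 0.12, bottom = 0.12), seed = s))
    f2 <- generate_thickness_field(
      sim_config(smallscale_cv = c(top = 0.24, bottom = 0.24), seed = s))
    v1 <- adjacent_variation(
      field_section_means(f1)$true_thickness_um[1:100])$mean
    v2 <- adjacent_variation(
      field_section_means(f2)$true_thickness_um[1:100])$mean
    v2 - v1
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.9)   # paired ordering holds seed by seed
})

test_that("TCC is an exact affine function of thickness at rho = 1", {
  cfg <- sim_config(tcc_thickness_corr = 1, tcc_cv = 0.2, seed = 3)
  sec <- generate_tcc(generate_thickness_field(cfg), cfg)
  r <- stats::cor(sec$tcc_cells_per_cm2, sec$true_thickness_um)
  expect_equal(r, 1, tolerance = 1e-12)
})

test_that("TCC decouples from thickness at rho = 0", {
  rs <- vapply(1:100, function(s) {
    cfg <- sim_config(tcc_thickness_corr = 0, seed = s)
    sec <- generate_tcc(generate_thickness_field(cfg), cfg)
    stats::cor(sec$tcc_cells_per_cm2, sec$true_thickness_um)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.15)
})

test_that("default TCC emulates the observed concentration span", {
  cfg <- sim_config(seed = 21)
  sec <- generate_tcc(generate_thickness_field(cfg), cfg)
  tcc <- sec$tcc_cells_per_cm2
  expect_equal(mean(tcc), 2.4e7, tolerance = 0.1)
  expect_gt(min(tcc), 5e6)
  expect_lt(max(tcc), 5e7)
})

test_that("a single-taxon community is 100% that taxon in every section", {
  cfg <- sim_config(hose_length = 12, n_taxa = 1,
                    dominant_profile = c(solo = 0.99),
                    dominant_anticorr_pair = NULL,
                    step_changes = list(), reads_per_section = 1000,
                    missing_section_prob = 0, seed = 2)
  comm <- generate_community(cfg)
  ra <- relative_abundance(comm)
  expect_true(all(ra[1, ] == 1))
})

test_that("community columns sum to the read depth unless missing", {
  cfg <- small_cfg(seed = 5, missing_section_prob = 0.2)
  comm <- generate_community(cfg)
  miss <- attr(comm, "missing")
  expect_true(any(miss))
  cs <- colSums(comm)
  expect_true(all(is.na(cs[miss])))
  expect_true(all(cs[!miss] == cfg$reads_per_section))
  expect_identical(rownames(comm),
                   rownames(generate_community(small_cfg(seed = 99))))
})

test_that("realized top-3 dominance matches the configured profile", {
  shares <- vapply(1:20, function(s) {
    comm <- generate_community(sim_config(seed = s))
    top_share(dominant_taxa(comm), 3) / 100
  }, numeric(1))
  expect_lt(abs(mean(shares) - 0.577), 0.02)
})

test_that("a configured abundance step is recovered by window contrast", {
  diffs <- vapply(1:10, function(s) {
    cfg <- sim_config(seed = s)   # default step: +0.081, top sections 81-91
    comm <- generate_community(cfg)
    ra <- relative_abundance(comm)
    tm6_top <- ra["TM6_Dependentiae", 1:100]
    window_contrast(tm6_top, 70:80, 81:91)$difference
  }, numeric(1))
  expect_lt(abs(mean(diffs) - 0.081), 0.03)
})

test_that("negative expected proportions from steps are rejected", {
  cfg <- small_cfg(step_changes = list(
    list(taxon = "TM6_Dependentiae", half = "top", sections = 2:4,
         delta = -0.5)))
  expect_error(generate_community(cfg), "below zero")
})

test_that("anticorrelated dominant pair is negatively correlated", {
  cors <- vapply(1:10, function(s) {
    comm <- generate_community(sim_config(seed = s))
    ra <- relative_abundance(comm)
    stats::cor(ra["Cytophagaceae", ], ra["Bradyrhizobium", ],
               use = "complete.obs")
  }, numeric(1))
  expect_lt(mean(cors), -0.2)
})

test_that("rendered geometry follows the true thickness exactly", {
  ic <- coarse_imaging()
  b <- render_bscan(100, ic)
  sep <- b$truth$substratum_row - b$truth$surface_row
  expect_true(all(sep == round(100 / ic$axial_pixel)))
  b0 <- render_bscan(0, ic)
  expect_true(all(b0$truth$surface_row == b0$truth$substratum_row))
  expect_error(render_bscan(2000, ic), "exceeds the image height")
  expect_error(render_bscan(-5, ic), "non-negative")
  expect_error(render_bscan(rep(10, 7), ic), "per lateral column")
})

test_that("renders are deterministic given a seed", {
  ic <- imaging_config(noise_sd = 8, artifact_rate = 2)
  b1 <- render_bscan(rep(150, ic$n_cols), ic, seed = 7)
  b2 <- render_bscan(rep(150, ic$n_cols), ic, seed = 7)
  expect_identical(b1$intensity, b2$intensity)
  expect_identical(b1$truth, b2$truth)
})
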