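test_that("remaining_fraction follows the saturating-exponential kinetic", {
  p0 <- material_params("X", 0.5, max_shrinkage = 0.4, rate = 0.1)
  expect_identical(remaining_fraction(p0, 0), 1)
  none <- material_params("flat", 0.5, max_shrinkage = 0, rate = 0.2)
  expect_identical(remaining_fraction(none, 100), 1)
  # closed form evaluated independently: 1 - 0.4 * (1 - exp(-1))
  expect_equal(remaining_fraction(p0, 10), 0.7471517765, tolerance = 1e-9)
  expect_error(remaining_fraction(p0, -1), "finite and >= 0")
})

test_that("remaining_fraction is monotone in time and in shrinkage extent", {
  tgrid <- seq(0, 60, by = 0.5)
  for (f in c(0.1, 0.3, 0.6)) {
    p <- material_params("X", 0.5, max_shrinkage = f, rate = 0.12)
    v <- remaining_fraction(p, tgrid)
    expect_true(all(diff(v) < 0))
    expect_true(all(v > 1 - f))
  }
  for (tt in c(1, 5, 30)) {
    vals <- vapply(seq(0, 0.9, by = 0.1), function(f)
      remaining_fraction(material_params("X", 0.5, f, 0.12), tt), numeric(1))
    expect_true(all(diff(vals) <= 0))
  }
})

test_that("preset kinetics order inversely with crystallinity", {
  pres <- material_presets()
  cry <- vapply(pres, `[[`, numeric(1), "crystallinity")
  expect_equal(unname(cry[c("PVC", "PET", "HDPE")]), c(0.10, 0.35, 0.75))
  fin <- vapply(pres, function(p)
    100 * (1 - remaining_fraction(p, 39)), numeric(1))
  ord <- order(cry)
  expect_true(all(diff(fin[ord]) <= 0))
  expect_true(fin[["PVC"]] > fin[["PET"]])
  expect_true(fin[["PET"]] > fin[["HDPE"]])
  # deforming plastics straddle the screening thresholds; HDPE and the
  # non-plastic media sit below the lower one
  expect_gt(fin[["PVC"]], 20)
  expect_gt(fin[["PET"]], 8.1)
  expect_lt(fin[["HDPE"]], 8.1)
  expect_true(all(fin[c("Algae", "Kaolinite", "Cellulose", "SiltySoil")]
                  < 8.1))
})

test_that("make_particle_shape is deterministic, connected, area-calibrated", {
  m1 <- make_particle_shape(1, 1.0, 0, pixel_scale = 0.01, size = 128L)
  m2 <- make_particle_shape(1, 1.0, 0, pixel_scale = 0.01, size = 128L)
  expect_identical(m1, m2)
  # irregularity 0 -> disk of radius 50 px
  expect_equal(sum(m1), pi * 50^2, tolerance = 0.02)
  m3 <- make_particle_shape(2, 1.0, 0.5, pixel_scale = 0.01, size = 160L)
  expect_false(identical(m3[1:128, 1:128], m1))
  expect_equal(sum(m3), pi * 50^2, tolerance = 0.25)
  lab <- EBImage::bwlabel(EBImage::Image(m3 * 1))
  expect_equal(max(lab), 1)  # single connected component
  expect_error(
    make_particle_shape(1, 5, 0, pixel_scale = 0.01, size = 128L),
    "larger than frame")
})

test_that("generate_video carries consistent, monotone ground truth", {
  pres <- material_presets()
  sc <- scene_config()
  v <- generate_video(pres$PVC, sc, seed = 5)
  expect_length(v$frames, 40)
  # truth areas equal mask pixel count x pixel_scale^2
  a <- vapply(v$truth_masks, sum, numeric(1)) * sc$pixel_scale^2
  expect_equal(v$truth_areas, a)
  expect_true(all(diff(v$truth_areas) <= 0))
  # PVC preset: strict decrease over the first 10 frames
  expect_true(all(diff(v$truth_areas[1:10]) < 0))
  # rasterized areas track the analytic schedule within a one-pixel ring
  frac <- remaining_fraction(pres$PVC, v$times)
  perim_px <- 2 * pi * sqrt(sum(v$truth_masks[[1]]) / pi) + 8
  expect_true(all(abs(v$truth_areas - frac * v$truth_areas[1]) <=
                    perim_px * sc$pixel_scale^2))
  # HDPE-like preset barely shrinks
  vh <- generate_video(pres$HDPE, sc, seed = 5)
  expect_gte(vh$truth_areas[40] / vh$truth_areas[1], 0.95)
  # zero-shrinkage material: identical masks throughout
  flat <- material_params("flat", 0.5, 0, 0.1)
  vf <- generate_video(flat, tiny_scene(5L), seed = 2)
  for (i in 2:5) expect_identical(vf$truth_masks[[i]], vf$truth_masks[[1]])
  # bit-reproducible under seed
  v2 <- generate_video(pres$PVC, sc, seed = 5)
  expect_identical(v$frames, v2$frames)
  # contrast at the noise floor is flagged
  dim_mat <- material_params("dim", 0.5, 0.2, 0.05, contrast = 0.05)
  expect_warning(generate_video(dim_mat, tiny_scene(5L), seed = 1),
                 "noise floor")
})

test_that("profile tables have the assumed statistical structure", {
  clean <- material_params("clean", 0.5, 0.3, 0.1, profile_noise_sd = 0,
                           shrinkage_cv = 0, rate_cv = 0)
  tab <- generate_profile_table(clean, 3, times = c(0, 5, 10), seed = 1)
  expect_equal(nrow(tab), 9)
  expect_true(all(tab$percent_remaining[tab$time_s == 0] == 100))
  for (tt in c(5, 10))
    expect_equal(tab$percent_remaining[tab$time_s == tt],
                 rep(100 * (1 - 0.3 * (1 - exp(-0.1 * tt))), 3),
                 tolerance = 1e-12)
  # two identical materials, large n: group means within 3 standard errors
  a <- material_params("A", 0.4, 0.25, 0.1)
  b <- material_params("B", 0.4, 0.25, 0.1)
  tab2 <- generate_profile_table(list(a, b), 40, times = c(0, 10, 39),
                                 seed = 7)
  fin <- tab2[tab2$time_s == 39, ]
  ma <- mean(fin$percent_remaining[fin$material == "A"])
  mb <- mean(fin$percent_remaining[fin$material == "B"])
  se <- sqrt(stats::var(fin$percent_remaining[fin$material == "A"]) / 40 +
               stats::var(fin$percent_remaining[fin$material == "B"]) / 40)
  expect_lt(abs(ma - mb), 3 * se)
})

test_that("blinded generators shuffle but preserve composition and seed", {
  comps <- table1_compositions()
  expect_true(all(vapply(comps, sum, numeric(1)) == 40))
  b <- generate_blinded_profiles(c(PET = 5), seed = 3)
  expect_true(all(b$truth$material == "PET"))
  b2 <- generate_blinded_profiles(comps$sample2, seed = 9)
  expect_equal(sort(as.integer(table(b2$truth$material))),
               sort(as.integer(comps$sample2)))
  b3 <- generate_blinded_profiles(comps$sample2, seed = 9)
  expect_identical(b2$truth$material, b3$truth$material)
  expect_identical(b2$profiles, b3$profiles)
  # video-level twin hides the label on the videos themselves
  bs <- generate_blinded_sample(c(PET = 1, HDPE = 1), tiny_scene(4L),
                                seed = 2)
  expect_true(all(is.na(vapply(bs$videos, `[[`, character(1), "material"))))
  expect_setequal(bs$truth$material, c("PET", "HDPE"))
})
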