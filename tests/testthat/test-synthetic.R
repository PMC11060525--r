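test_that("rendering is a pure function of (spec, seed)", {
  spec <- default_class_specs()[["Pinus strobus"]]
  a <- render_grain(spec, seed = 17)
  b <- render_grain(spec, seed = 17)
  expect_identical(a, b)
  expect_false(identical(a, render_grain(spec, seed = 18)))
  expect_equal(dim(a), c(128, 128))
  expect_true(all(a >= 0 & a <= 1))
})

test_that("porate geometry is logged: pore count and equal angular spacing", {
  tri <- morphotype_spec("triporate", size_px = c(30, 0), pore_count = 3)
  g <- attr(render_grain(tri, seed = 5), "geometry")
  expect_equal(nrow(g$pore_centers), 3)
  gaps <- diff(sort(g$pore_angles))
  expect_equal(gaps, rep(2 * pi / 3, 2), tolerance = 1e-8)

  st <- morphotype_spec("stephanoporate", size_px = c(30, 0), pore_count = 5)
  g5 <- attr(render_grain(st, seed = 5), "geometry")
  expect_equal(nrow(g5$pore_centers), 5)
  expect_equal(diff(sort(g5$pore_angles)), rep(2 * pi / 5, 4),
               tolerance = 1e-8)
})

test_that("oversized grains are rejected", {
  big <- morphotype_spec("aporate", size_px = c(200, 1))
  expect_error(render_grain(big, seed = 1), "canvas")
})

test_that("an all-zero taphonomy config is the identity", {
  img <- render_grain(default_class_specs()[["Betula"]], seed = 3)
  expect_identical(degrade(img, taphonomy_config(), seed = 1), img)
})

test_that("occlusion at probability one logs a patch of the requested area", {
  img <- render_grain(default_class_specs()[["Picea"]], seed = 3)
  cfg <- taphonomy_config(occlusion_prob = 1, occlusion_area = 0.25)
  out <- degrade(img, cfg, seed = 9)
  log <- attr(out, "taphonomy")
  expect_equal(log$occlusion$area_fraction, 0.25)
  ## patch area ~ 25% of the grain bounding box
  rr <- attr(img, "geometry")$diameter / 2
  expect_equal(pi * log$occlusion$radius^2 / (2 * rr)^2, 0.25,
               tolerance = 1e-8)
  expect_identical(out, degrade(img, cfg, seed = 9))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("generate_dataset yields the requested class balance, reproducibly", {
  specs <- default_class_specs()[c("Betula", "Picea", "Quercus")]
  ds <- generate_dataset(specs, 10, seed = 4)
  expect_length(ds, 30)
  expect_equal(as.vector(table(ds$labels)), rep(10, 3))
  ds2 <- generate_dataset(specs, 10, seed = 4)
  expect_identical(ds$labels, ds2$labels)
  expect_identical(ds$images, ds2$images)
  expect_error(generate_dataset(list(), 5), "empty")
})

test_that("the full class-spec fixture matches the default taxonomy terminals", {
  tree <- build_hierarchy(default_taxonomy())
  expect_setequal(names(default_class_specs()), terminal_labels(tree))
})

test_that("fossil sequences return ground truth consistent with the draw", {
  ## degenerate composition: every non-marker object is Betula
  comp <- data.frame(depth_cm = c(10, 20, 30), Betula = 1)
  fs <- generate_fossil_sequence(comp, n_objects = 50, marker_dose = 0,
                                 seed = 6)
  expect_equal(fs$truth$Betula, rep(50, 3))
  expect_equal(fs$truth$marker_count, rep(0, 3))
  expect_equal(vapply(fs$samples, length, integer(1)), rep(50L, 3))

  ## marker dose: binomial count within 4 sd of n * dose
  comp2 <- data.frame(depth_cm = 1:5, Betula = 0.5, Picea = 0.5)
  fs2 <- generate_fossil_sequence(comp2, n_objects = 100, marker_dose = 0.1,
                                  seed = 7)
  expect_true(all(abs(fs2$truth$marker_count - 10) <= 4 * sqrt(100 * .1 * .9)))
  expect_equal(fs2$truth$marker_count, fs2$truth$Eucalyptus)
  ## per-sample counts are conserved
  cls <- setdiff(names(fs2$truth), c("sample_id", "depth_cm",
                                     "marker_count", "volume_cm3"))
  expect_equal(unname(rowSums(fs2$truth[, cls])), rep(100, 5))
  ## deterministic
  fs3 <- generate_fossil_sequence(comp2, n_objects = 100, marker_dose = 0.1,
                                  seed = 7)
  expect_identical(fs2$truth, fs3$truth)

  expect_error(generate_fossil_sequence(
    data.frame(depth_cm = 1, Betula = -0.5, Picea = 1.5), 10), "negative")
  expect_error(generate_fossil_sequence(
    data.frame(depth_cm = 1, Betula = 0.4, Picea = 0.4), 10), "sum to 1")
})

test_that("clean renders carry class signal a pixel centroid can read", {
  specs <- default_class_specs()[c("Juniperus/Thuja", "Abies balsamea",
                                   "Betula", "NPP/Minerals")]
  tr <- generate_dataset(specs, 25, seed = 11)
  te <- generate_dataset(specs, 10, seed = 12)
  acc <- centroid_baseline(tr, te)
  expect_gt(acc, 1 / 4)   # well above chance
})

test_that("heavier degradation monotonically hurts the pixel baseline", {
  specs <- default_class_specs()[c("Juniperus/Thuja", "NPP/Minerals",
                                   "Abies balsamea")]
  levels <- list(
    taphonomy_config(),
    taphonomy_config(fold_prob = 0.7, fold_darkening = 0.5,
                     occlusion_prob = 0.7, occlusion_area = 0.3,
                     blur_sigma = c(2, 4), speckle_sd = 0.12,
                     clump_prob = 0.4),
    taphonomy_config(fold_prob = 1, fold_darkening = 0.7,
                     occlusion_prob = 1, occlusion_area = 0.45,
                     blur_sigma = c(5, 8), speckle_sd = 0.25,
                     clump_prob = 0.7)
  )
  accs <- vapply(seq_along(levels), function(li) {
    mean(vapply(1:8, function(s) {
      tr <- generate_dataset(specs, 15, seed = 100 + s)
      te <- generate_dataset(specs, 10, taphonomy = levels[[li]],
                             seed = 200 + s)
      centroid_baseline(tr, te)
    }, numeric(1)))
  }, numeric(1))
  expect_true(accs[1] > accs[2] && accs[2] > accs[3])
})
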