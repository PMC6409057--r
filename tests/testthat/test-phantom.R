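test_that("noiseless sphere mask is exactly the ball of grid points", {
  spec <- phantom_spec(shape = c(40, 40, 34), equiv_radius = 10,
                       edge_blur_sigma = 0, noise_sigma = 0)
  ph <- generate_phantom(spec)
  expected <- ball_mask(c(40, 40, 34), (c(40, 40, 34) + 1) / 2, 10)
  expect_identical(sum(ph$gt_mask), sum(expected))
  expect_identical(ph$gt_mask, expected)
  # noiseless, blur-free: exactly two intensity levels
  expect_setequal(unique(as.numeric(ph$volume$data)), c(100, 60))
})

test_that("identical specs give bit-identical phantoms", {
  spec <- phantom_spec(shape = c(32, 32, 24), equiv_radius = 8,
                       texture_sigma = 0.1, noise_sigma = 12, seed = 11L)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$gt_mask, b$gt_mask)
})

test_that("ground truth is invariant to noise and texture settings", {
  base <- list(shape = c(32, 32, 24), equiv_radius = 8, seed = 5L)
  m0 <- generate_phantom(do.call(phantom_spec, base))$gt_mask
  m1 <- generate_phantom(do.call(phantom_spec, c(base, noise_sigma = 25)))$gt_mask
  m2 <- generate_phantom(do.call(phantom_spec, c(base, texture_sigma = 0.3)))$gt_mask
  expect_identical(m0, m1)
  expect_identical(m0, m2)
})

test_that("realized contrast matches the specified level under noise", {
  # Monte-Carlo over seeds: mean(tumor) - mean(background) ~ fg - bg = +60
  diffs <- vapply(1:20, function(s) {
    ph <- generate_phantom(phantom_spec(
      shape = c(40, 40, 30), equiv_radius = 10, intensity_bg = 100,
      intensity_fg = 160, edge_blur_sigma = 0, noise_sigma = 20, seed = s))
    v <- ph$volume$data
    mean(v[ph$gt_mask]) - mean(v[!ph$gt_mask])
  }, numeric(1))
  sem <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - 60), 3 * sem + 1e-9)
})

test_that("background variance grows strictly with noise_sigma", {
  bg_var <- function(ns) {
    mean(vapply(1:10, function(s) {
      ph <- generate_phantom(phantom_spec(shape = c(24, 24, 20),
                                          equiv_radius = 5, noise_sigma = ns,
                                          seed = s))
      var(ph$volume$data[!ph$gt_mask])
    }, numeric(1)))
  }
  v <- vapply(c(0, 5, 10, 20), bg_var, numeric(1))
  expect_true(all(diff(v) > 0))
})

test_that("phantom parameter validation rejects impossible specs", {
  expect_error(phantom_spec(shape = c(20, 20, 16), equiv_radius = 12), "fit")
  expect_error(phantom_spec(equiv_radius = 2), "equiv_radius")
  expect_error(phantom_spec(noise_sigma = -1), ">= 0")
})

test_that("ellipsoid and lobulated phantoms are valid and deterministic", {
  for (kind in c("ellipsoid", "lobulated")) {
    spec <- phantom_spec(shape = c(48, 48, 40), tumor_kind = kind,
                         equiv_radius = 8, seed = 3L)
    a <- generate_phantom(spec)
    b <- generate_phantom(spec)
    expect_identical(a$gt_mask, b$gt_mask)
    expect_gt(sum(a$gt_mask), 0)
  }
  # lobulated union is a superset of the parent sphere
  spec <- phantom_spec(shape = c(48, 48, 40), tumor_kind = "lobulated",
                       equiv_radius = 8, seed = 3L)
  parent <- ball_mask(c(48, 48, 40), (c(48, 48, 40) + 1) / 2, 8)
  m <- generate_phantom(spec)$gt_mask
  expect_true(all(m[parent]))
  expect_gt(sum(m), sum(parent))
})

test_that("generate_dataset draws reproducibly from the given ranges", {
  expect_error(generate_dataset(0), ">= 1")
  expect_error(generate_dataset(3, ranges = list(equiv_radius = c(10, 6))),
               "empty")
  # fixed-point ranges: identical geometry, different noise realizations
  set5 <- generate_dataset(5, ranges = list(equiv_radius = 8, noise_sigma = 10),
                           shape = c(32, 32, 24), seed = 2L)
  masks <- lapply(set5, `[[`, "gt_mask")
  expect_true(all(vapply(masks[-1], identical, logical(1), masks[[1]])))
  vols <- vapply(set5, function(p) p$volume$data[1], numeric(1))
  expect_gt(length(unique(vols)), 1)
  # uniform-radius oracle: mean of U(6, 30) is 18
  big <- generate_dataset(50, ranges = list(equiv_radius = c(6, 30),
                                            edge_blur_sigma = 0),
                          shape = c(80, 80, 80), seed = 7L)
  radii <- vapply(big, function(p) p$spec$equiv_radius, numeric(1))
  sem <- sd(radii) / sqrt(length(radii))
  expect_lt(abs(mean(radii) - 18), 3 * sem)
  # reproducible per seed
  big2 <- generate_dataset(50, ranges = list(equiv_radius = c(6, 30),
                                             edge_blur_sigma = 0),
                           shape = c(80, 80, 80), seed = 7L)
  expect_identical(radii,
                   vapply(big2, function(p) p$spec$equiv_radius, numeric(1)))
})
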