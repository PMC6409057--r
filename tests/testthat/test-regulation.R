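test_that("position probabilities are validated on the simplex", {
  p <- position_probs(0.78, 0.14, 0.08)
  expect_s3_class(p, "position_probs")
  expect_error(position_probs(0.5, 0.5, 0.5), "sum to 1")
  expect_error(position_probs(-0.1, 0.6, 0.5), "\\[0, 1\\]")
})

test_that("weight regulation reproduces the closed-form examples", {
  l <- regulate_lambdas(position_probs(1 / 3, 1 / 3, 1 / 3))
  expect_equal(unname(l[1]), exp(1))
  expect_equal(unname(l[2]), exp(1))
  l2 <- regulate_lambdas(position_probs(1, 0, 0))
  expect_equal(unname(l2[1]), exp(2))
  expect_equal(unname(l2[2]), exp(0.5))
  # deep-inside probabilities (0.78, 0.14, 0.08)
  l3 <- regulate_lambdas(position_probs(0.78, 0.14, 0.08))
  expect_equal(unname(l3[1]), exp(1.92 / 1.22), tolerance = 1e-12)
  expect_equal(unname(l3[2]), exp(1.22 / 1.92), tolerance = 1e-12)
})

test_that("weight regulation satisfies range, product, symmetry, direction", {
  set.seed(99)
  for (i in 1:1000) {
    p <- rsimplex()
    l <- regulate_lambdas(p)
    expect_true(all(l >= exp(0.5) - 1e-12 & l <= exp(2) + 1e-12))
    expect_gte(l[1] * l[2], exp(2) - 1e-12)
    lr <- regulate_lambdas(rev(p))
    expect_equal(unname(l[1]), unname(lr[2]), tolerance = 1e-12)
    if (p[1] > p[3]) expect_gt(l[1], l[2])
    if (p[1] < p[3]) expect_lt(l[1], l[2])
  }
})

test_that("window regulation follows both readings of the printed rule", {
  # near-boundary band
  expect_identical(regulate_window(position_probs(0.3, 0.5, 0.2)), 8L)
  lit <- regulation_config(window_rule = "literal")
  expect_identical(regulate_window(position_probs(1, 0, 0), lit), 25L)
  expect_identical(regulate_window(position_probs(0.45, 0.10, 0.45), lit), 5L)
  add <- regulation_config(window_rule = "additive")
  expect_identical(regulate_window(position_probs(1, 0, 0), add), 10L)
  expect_identical(regulate_window(position_probs(0.45, 0.10, 0.45), add), 5L)
  # monotone in |p1 - p3| outside the band, for both rules
  gaps <- seq(0, 1, by = 0.05)
  for (cfg in list(lit, add)) {
    radii <- vapply(gaps, function(g) {
      regulate_window(position_probs((1 + g) / 2 * 0.9, 0.1,
                                     (1 - g) / 2 * 0.9), cfg)
    }, integer(1))
    expect_true(all(diff(radii) >= 0))
  }
})

test_that("the geometric oracle maps contour offset to the three classes", {
  gt <- ball_mask(c(40, 40, 40), c(20, 20, 20), 10)
  sdist <- drls:::signed_distance_to_boundary(gt)
  req <- drls:::equiv_radius(gt)
  for (r0 in c(4, 7, 10, 13, 16)) {
    phi <- init_sdf_ball(c(40, 40, 40), c(20, 20, 20), r0)
    p <- oracle_position_probs(phi, gt, sigma_frac = 0.25)
    # simplex invariant
    expect_lt(abs(p$p1 + p$p2 + p$p3 - 1), 1e-12)
    # consistency with its defining statistic
    contour <- drls:::.contour_voxels_cpp(phi, c(40, 40, 40))
    s <- mean(sdist[contour]) / req
    expect_equal(p$p2, exp(-(s / 0.25)^2), tolerance = 1e-12)
    if (s < 0) expect_equal(p$p1, 1 - p$p2, tolerance = 1e-12)
    if (s > 0) expect_equal(p$p3, 1 - p$p2, tolerance = 1e-12)
  }
  # matched contour: near-boundary dominates; deep inside: p1 > 0.98
  p_match <- oracle_position_probs(init_sdf_ball(c(40, 40, 40),
                                                 c(20, 20, 20), 10), gt)
  expect_gt(p_match$p2, 0.8)
  p_deep <- oracle_position_probs(init_sdf_ball(c(40, 40, 40),
                                                c(20, 20, 20), 3), gt)
  expect_gt(p_deep$p1, 0.98)
  expect_error(oracle_position_probs(init_sdf_ball(c(40, 40, 40),
                                                   c(20, 20, 20), 3),
                                     array(FALSE, c(40, 40, 40))), "empty")
})

test_that("oracle probabilities are deterministic and move continuously", {
  gt <- ball_mask(c(30, 30, 30), c(15, 15, 15), 8)
  phi <- init_sdf_ball(c(30, 30, 30), c(15, 15, 15), 5)
  a <- oracle_position_probs(phi, gt)
  b <- oracle_position_probs(phi, gt)
  expect_identical(a, b)
  p2s <- vapply(seq(4, 12, by = 0.5), function(r) {
    oracle_position_probs(init_sdf_ball(c(30, 30, 30), c(15, 15, 15), r),
                          gt)$p2
  }, numeric(1))
  expect_equal(which.max(p2s), which.min(abs(seq(4, 12, by = 0.5) - 8)),
               tolerance = 2)
})

test_that("initialization selection maximizes the near-boundary response", {
  d <- c(60, 60, 60)
  gt <- ball_mask(d, c(30, 30, 30), 12)
  cls <- oracle_classifier(gt)
  vol <- array(0, d)
  sel <- select_initialization(vol, c(30, 30, 30), c(6, 10, 20, 30, 40), cls)
  expect_equal(sel$radius, 10)
  expect_equal(nrow(sel$candidates), 5)
  # single candidate
  sel1 <- select_initialization(vol, c(30, 30, 30), 15, cls)
  expect_equal(sel1$radius, 15)
  # exact tie: identical p2 for both candidates -> smaller radius wins
  tie_cls <- function(volume, phi) position_probs(0.2, 0.6, 0.2)
  sel2 <- select_initialization(vol, c(30, 30, 30), c(8, 12), tie_cls)
  expect_equal(sel2$radius, 8)
})
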