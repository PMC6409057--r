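test_that("init_sdf_ball is a signed distance function of the ball", {
  phi <- init_sdf_ball(c(31, 31, 31), c(16, 16, 16), 8)
  expect_equal(phi[16, 16, 16], -8)
  expect_equal(phi[24, 16, 16], 0) # exactly `radius` away
  expect_error(init_sdf_ball(c(10, 10, 10), c(5, 5, 5), 0), "radius")
  # gradient magnitude ~ 1 by central differences, interior voxels away
  # from the center singularity
  idx <- 2:30
  gx <- (phi[idx + 1, idx, idx] - phi[idx - 1, idx, idx]) / 2
  gy <- (phi[idx, idx + 1, idx] - phi[idx, idx - 1, idx]) / 2
  gz <- (phi[idx, idx, idx + 1] - phi[idx, idx, idx - 1]) / 2
  gm <- sqrt(gx^2 + gy^2 + gz^2)
  keep <- abs(phi[idx, idx, idx] + 8) > 3 # exclude the center cone tip
  expect_lt(max(abs(gm[keep] - 1)), 0.05)
})

test_that("smoothed Heaviside/Dirac form a consistent regularized pair", {
  eps <- 1.5
  expect_identical(smoothed_heaviside(0, eps), 0.5)
  expect_lt(abs(smoothed_heaviside(-10 * eps, eps) - 1), 1e-3)
  expect_lt(abs(smoothed_heaviside(10 * eps, eps)), 1e-3)
  phis <- seq(-2 * eps, 2 * eps, length.out = 41)
  H <- smoothed_heaviside(phis, eps)
  expect_true(all(diff(H) <= 0))      # monotone (interior weight)
  expect_true(all(H >= 0 & H <= 1))
  # analytic Dirac matches the finite-difference derivative magnitude
  test_pts <- seq(-1.4 * eps, 1.4 * eps, length.out = 20)
  h <- 1e-5
  fd <- -(smoothed_heaviside(test_pts + h, eps) -
            smoothed_heaviside(test_pts - h, eps)) / (2 * h)
  d <- smoothed_dirac(test_pts, eps)
  expect_lt(max(abs(fd - d)), 1e-4)
  expect_true(all(d >= 0))
  expect_equal(d, rev(d)) # symmetric
  expect_error(smoothed_heaviside(0, -1), "eps")
})

test_that("local_window_stats matches a brute-force voxel loop", {
  set.seed(42)
  d <- c(17, 15, 13)
  vol <- array(rnorm(prod(d), 70, 25), d)
  phi <- init_sdf_ball(d, c(9, 8, 7), 4.5)
  for (i in 1:5) {
    ctr <- c(sample(3:15, 1), sample(3:13, 1), sample(3:11, 1))
    got <- local_window_stats(vol, phi, ctr, rad = 4, eps = 1.5)
    ref <- brute_window_stats(vol, phi, ctr, rad = 4, eps = 1.5)
    expect_lt(abs(got$u_x - ref$u_x), 1e-10)
    expect_lt(abs(got$v_x - ref$v_x), 1e-10)
    expect_lt(abs(got$A_in - ref$A_in), 1e-10)
    expect_lt(abs(got$A_out - ref$A_out), 1e-10)
  }
})

test_that("local_window_stats handles constant, split and degenerate windows", {
  d <- c(12, 12, 12)
  vol <- array(7, d)
  phi <- init_sdf_ball(d, c(6, 6, 6), 3)
  st <- local_window_stats(vol, phi, c(6, 6, 6), rad = 3)
  expect_equal(st$u_x, 7)
  expect_equal(st$v_x, 7)
  expect_equal(st$A_in + st$A_out, 7^3)
  # two-level image split exactly by the zero level set, near-sharp Heaviside
  phi2 <- array(rep(seq(-5.5, 6.5, by = 1), each = 1), d) # plane at x = 6.5
  for (x in 1:12) phi2[x, , ] <- x - 6.5
  v2 <- array(0, d)
  v2[phi2 < 0] <- 10
  v2[phi2 > 0] <- 50
  st2 <- local_window_stats(v2, phi2, c(6, 6, 6), rad = 3, eps = 1e-6)
  expect_equal(st2$u_x, 10)
  expect_equal(st2$v_x, 50)
  # window entirely on one side: degenerate side flagged, full-window mean
  phi3 <- array(10, d)
  st3 <- local_window_stats(vol, phi3, c(6, 6, 6), rad = 2)
  expect_true(st3$degenerate)
  expect_equal(st3$u_x, 7)
})

test_that("region forces vanish on constant images and scale linearly", {
  d <- c(20, 20, 16)
  vol <- array(3, d)
  phi <- init_sdf_ball(d, c(10, 10, 8), 5)
  pts <- which(abs(phi) < 1, arr.ind = TRUE)[1:6, ]
  expect_equal(ms_force(vol, phi, pts, 4, 1, 1), rep(0, 6))
  expect_equal(um_force(vol, phi, pts, 4, 1, 1), rep(0, 6))
  # doubling lambda1 doubles the interior-fit component exactly
  set.seed(1)
  vol2 <- array(rnorm(prod(d), 50, 10), d)
  f_l1 <- um_force(vol2, phi, pts, 4, 1, 0)
  f_2l1 <- um_force(vol2, phi, pts, 4, 2, 0)
  expect_equal(f_2l1, 2 * f_l1, tolerance = 1e-12)
  # lambda2 = 0 isolates the interior-variance term (all non-negative speeds)
  expect_true(all(f_l1 >= 0))
})

test_that("um_force equals ms_force times the area when A_in = A_out", {
  # plane interface through the window center: interior and exterior halves
  d <- c(13, 13, 13)
  phi <- array(0, d)
  for (x in 1:13) phi[x, , ] <- x - 7 # odd symmetry about x = 7
  set.seed(2)
  vol <- array(rnorm(prod(d), 20, 5), d)
  ctr <- matrix(c(7, 7, 7), 1)
  st <- local_window_stats(vol, phi, c(7, 7, 7), rad = 3)
  expect_equal(st$A_in, st$A_out, tolerance = 1e-9)
  um <- um_force(vol, phi, ctr, 3, 1.2, 0.7)
  ms <- ms_force(vol, phi, ctr, 3, 1.2, 0.7)
  expect_equal(um, ms * st$A_in, tolerance = 1e-9)
})

test_that("speed is near zero at a true two-level step with equal weights", {
  # planar step: window statistics are symmetric about the interface
  d <- c(24, 16, 16)
  v <- array(100, d)
  v[1:12, , ] <- 40
  mkphi <- function(x0) {
    p <- array(0, d)
    for (x in 1:24) p[x, , ] <- x - x0
    p
  }
  phi_edge <- mkphi(12.5) # zero level set exactly at the intensity step
  phi_off <- mkphi(11.5)  # one voxel inside the dark side
  f_edge <- ms_force(v, phi_edge,
                     as.matrix(expand.grid(x = 12:13, y = 8:9, z = 8:9)),
                     4, 1, 1)
  f_off <- ms_force(v, phi_off,
                    as.matrix(expand.grid(x = 11:12, y = 8:9, z = 8:9)),
                    4, 1, 1)
  expect_lt(median(abs(f_edge)), 0.2 * median(abs(f_off)))
})

test_that("fused field kernel agrees with the per-point force API", {
  set.seed(7)
  d <- c(20, 18, 16)
  vol <- array(rnorm(prod(d), 50, 20), d)
  phi <- init_sdf_ball(d, c(10, 9, 8), 5)
  csI <- drls:::.integral_image_cpp(vol, d)
  csI2 <- drls:::.integral_image_cpp(vol * vol, d)
  ff <- drls:::.force_field_cpp(vol, phi, d, 4L, 1.3, 0.8, 1.5, 1L, csI, csI2)
  band <- which(abs(phi) < 1.5, arr.ind = TRUE)
  fpts <- ms_force(vol, phi, band, 4, 1.3, 0.8)
  expect_lt(max(abs(ff$speed[abs(phi) < 1.5] - fpts)), 1e-8)
})

test_that("curvature term recovers the mean curvature of a sphere", {
  phi <- init_sdf_ball(c(30, 30, 30), c(15.5, 15.5, 15.5), 8)
  ct <- curvature_term(phi, mu = 1, eps = 1.5)
  band <- abs(phi) < 0.2
  k <- ct[band] / smoothed_dirac(phi[band], 1.5)
  expect_true(all(abs(k - 2 / 8) < 0.15 * 2 / 8))
  # planar field: zero curvature
  lin <- array(0, c(12, 12, 12))
  for (x in 1:12) lin[x, , ] <- 0.7 * x - 4
  expect_lt(max(abs(curvature_term(lin, mu = 1))), 1e-6)
  # mu = 0: identically zero
  expect_identical(unique(as.numeric(curvature_term(phi, mu = 0))), 0)
})

test_that("reaction-diffusion stabilization behaves like explicit diffusion", {
  # harmonic (linear) field is a fixed point away from the zero-flux borders
  lin <- array(0, c(14, 14, 14))
  for (x in 1:14) lin[x, , ] <- 2 * x - 11
  out <- rd_stabilize(lin, nu = 1, substeps = 3, dtau = 0.1)
  expect_lt(max(abs(out[4:11, 4:11, 4:11] - lin[4:11, 4:11, 4:11])), 1e-8)
  # a kinked field gets smoother: max gradient magnitude strictly decreases
  kink <- array(0, c(14, 14, 14))
  for (x in 1:14) kink[x, , ] <- abs(x - 7.5) - 3
  gradmax <- function(p) {
    gx <- p[-1, , ] - p[-14, , ]
    max(abs(gx))
  }
  sm <- rd_stabilize(kink, nu = 1, substeps = 5, dtau = 0.15)
  expect_lt(gradmax(sm), gradmax(kink))
  expect_gt(max(abs(sm - kink)), 1e-6) # it did move near the kink
  # ball SDF: zero level set essentially unchanged by one default call
  phi <- init_sdf_ball(c(40, 40, 40), c(20.5, 20.5, 20.5), 10)
  post <- rd_stabilize(phi, nu = 1, substeps = 1, dtau = 0.1)
  pre_in <- phi < 0
  post_in <- post < 0
  dice <- 2 * sum(pre_in & post_in) / (sum(pre_in) + sum(post_in))
  expect_gte(dice, 0.99)
  expect_error(rd_stabilize(phi, nu = 1, dtau = 0.3), "stability")
})
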