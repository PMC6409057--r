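# shared fixtures and independent brute-force oracles

ball_mask <- function(shape, center, r) {
  dx <- (seq_len(shape[1]) - center[1])
  dy <- (seq_len(shape[2]) - center[2])
  dz <- (seq_len(shape[3]) - center[3])
  sqrt(outer(outer(dx^2, dy^2, `+`), dz^2, `+`)) <= r
}

# noiseless two-level test volume with a centered ball
two_level_volume <- function(shape = c(40, 40, 32), r = 8, fg = 40, bg = 100) {
  m <- ball_mask(shape, (shape + 1) / 2, r)
  v <- array(bg, shape)
  v[m] <- fg
  list(volume = v, mask = m)
}

# brute-force voxel-loop oracle for local window statistics
brute_window_stats <- function(vol, phi, center, rad, eps) {
  d <- dim(vol)
  sH <- sHI <- n <- tot <- 0
  for (x in max(1, center[1] - rad):min(d[1], center[1] + rad))
    for (y in max(1, center[2] - rad):min(d[2], center[2] + rad))
      for (z in max(1, center[3] - rad):min(d[3], center[3] + rad)) {
        h <- smoothed_heaviside(phi[x, y, z], eps)
        sH <- sH + h
        sHI <- sHI + h * vol[x, y, z]
        tot <- tot + vol[x, y, z]
        n <- n + 1
      }
  A_in <- sH
  A_out <- n - sH
  u <- if (A_in > 1e-9) sHI / A_in else tot / n
  v <- if (A_out > 1e-9) (tot - sHI) / A_out else tot / n
  list(u_x = u, v_x = v, A_in = A_in, A_out = A_out)
}

# brute-force all-pairs symmetric surface distances
brute_surface_metrics <- function(seg, gt, spacing = c(1, 1, 1)) {
  border <- function(m) {
    d <- dim(m)
    idx <- which(m, arr.ind = TRUE)
    keep <- apply(idx, 1, function(p) {
      for (ax in 1:3) for (s in c(-1, 1)) {
        q <- p
        q[ax] <- q[ax] + s
        if (q[ax] >= 1 && q[ax] <= d[ax] && !m[q[1], q[2], q[3]]) return(TRUE)
      }
      FALSE
    })
    idx[keep, , drop = FALSE]
  }
  bs <- border(seg)
  bg <- border(gt)
  dists <- function(a, b) {
    apply(a, 1, function(p) {
      dd <- sweep(b, 2, p)
      min(sqrt(colSums((t(dd) * spacing)^2)))
    })
  }
  pooled <- c(dists(bs, bg), dists(bg, bs))
  list(asd = mean(pooled), rmsd = sqrt(mean(pooled^2)))
}

# standard noiseless reference phantom (tumor radius 15, contrast 60)
reference_phantom <- function() {
  generate_phantom(phantom_spec(shape = c(80, 80, 60), equiv_radius = 15,
                                intensity_bg = 100, intensity_fg = 40,
                                edge_blur_sigma = 1, noise_sigma = 0,
                                seed = 1L))
}

# random point on the probability simplex
rsimplex <- function() {
  x <- -log(runif(3))
  x / sum(x)
}
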