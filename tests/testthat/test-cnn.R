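test_that("prelu matches its definition and degenerates to ReLU", {
  expect_equal(prelu(2, 0.7), 2)
  expect_equal(prelu(-2, 0.25), -0.5)
  set.seed(1)
  x <- array(rnorm(200), c(10, 20))
  expect_equal(prelu(x, 0), pmax(x, 0))
})

test_that("encode_input crops, resamples and z-scores deterministically", {
  ph <- generate_phantom(phantom_spec(shape = c(40, 40, 30), equiv_radius = 8,
                                      intensity_fg = 40, noise_sigma = 8,
                                      seed = 4L))
  phi <- init_sdf_ball(c(40, 40, 30), c(20.5, 20.5, 15.5), 8)
  t1 <- encode_input(ph$volume, phi, target_shape = c(32, 32, 16))
  t2 <- encode_input(ph$volume, phi, target_shape = c(32, 32, 16))
  expect_identical(t1, t2)
  expect_equal(dim(t1), c(32, 32, 16))
  expect_lt(abs(mean(t1)), 1e-6)
  expect_lt(abs(sd(t1) - 1), 1e-6)
  expect_error(encode_input(ph$volume, abs(phi) + 1), "interior")
})

test_that("network construction is seeded and counts parameters correctly", {
  # independent shape-arithmetic oracle for the parameter count
  count_oracle <- function(input_shape, depths, fc, pool_first) {
    d <- input_shape
    cin <- 1
    total <- 0
    for (b in 1:4) {
      total <- total + 27 * cin * depths[b] + depths[b] + # conv w + b
        2 * depths[b] +                                   # bn gamma/beta
        depths[b]                                         # prelu slopes
      pool <- if (b == 1) pool_first else TRUE
      if (pool) d <- pmax(1, d %/% 2)
      cin <- depths[b]
    }
    sizes <- c(prod(d) * cin, fc)
    for (l in seq_len(length(sizes) - 1)) {
      total <- total + sizes[l] * sizes[l + 1] + sizes[l + 1]
      if (l < length(sizes) - 1) total <- total + 1 # fc prelu slope
    }
    total
  }
  red <- network_spec_reduced()
  net <- build_network(red, seed = 1)
  expect_equal(net$n_params,
               count_oracle(c(40, 40, 20), c(8, 16, 32, 64), c(64, 32, 3),
                            TRUE))
  full <- network_spec()
  netf <- build_network(full, seed = 1)
  expect_equal(netf$n_params,
               count_oracle(c(80, 80, 40), c(16, 32, 64, 128),
                            c(256, 64, 3), FALSE))
  # same seed -> identical weights; different seed -> different
  expect_identical(build_network(red, seed = 7)$params,
                   build_network(red, seed = 7)$params)
  expect_false(identical(build_network(red, seed = 7)$params,
                         build_network(red, seed = 8)$params))
  # truncated-normal init: all weights within 2 sd
  w <- net$params$conv_w1
  expect_true(all(abs(w) <= 2 * red$init_sd))
})

test_that("the forward pass is a softmax over three classes", {
  net <- build_network(network_spec_reduced(), seed = 2)
  set.seed(5)
  x <- array(rnorm(40 * 40 * 20), c(40, 40, 20))
  p <- predict_tensor(net, x)
  expect_lt(abs(p$p1 + p$p2 + p$p3 - 1), 1e-5)
  expect_identical(p, predict_tensor(net, x)) # eval mode is deterministic
  expect_error(predict_tensor(net, array(0, c(10, 10, 10))), "shape")
})

test_that("training-set labels follow the signed-distance thresholds", {
  cases <- lapply(1:2, function(i) {
    generate_phantom(phantom_spec(shape = c(48, 48, 36),
                                  equiv_radius = 8 + 2 * i,
                                  intensity_fg = 40, edge_blur_sigma = 1,
                                  seed = i))
  })
  ex <- build_training_set(cases, target_shape = c(24, 24, 12))
  expect_length(ex, 10)
  labs <- vapply(ex, `[[`, integer(1), "label")
  svals <- vapply(ex, function(e) e$provenance$s, numeric(1))
  expect_identical(labs,
                   ifelse(svals < -0.25, 0L, ifelse(svals > 0.25, 2L, 1L)))
  expect_setequal(unique(labs), 0:2) # all three classes per default radii
  # the smallest contour (0.5x) is inside, the largest (1.6x) outside
  mult_order <- order(vapply(ex[1:5], function(e) e$provenance$radius,
                             numeric(1)))
  expect_equal(labs[mult_order][1], 0L)
  expect_equal(labs[mult_order][5], 2L)
  # label rule consistent with the geometric oracle's argmax away from the
  # class crossovers (the oracle's argmax switches at |s| = 0.25 sqrt(ln 2)
  # ~ 0.208, slightly inside the +-0.25 label margin)
  for (i in seq_along(ex)) {
    if (abs(abs(svals[i]) - 0.23) < 0.06) next
    case <- cases[[ex[[i]]$provenance$case]]
    phi <- init_sdf_ball(dim(case$gt_mask),
                         colMeans(which(case$gt_mask, arr.ind = TRUE)),
                         ex[[i]]$provenance$radius)
    p <- oracle_position_probs(phi, case$gt_mask, sigma_frac = 0.25)
    expect_equal(which.max(c(p$p1, p$p2, p$p3)) - 1L, labs[i])
  }
  # balancing keeps every class within 2x of the smallest
  exb <- build_training_set(cases, target_shape = c(24, 24, 12),
                            balance = TRUE, seed = 1)
  tb <- table(vapply(exb, `[[`, integer(1), "label"))
  expect_lte(max(tb), 2 * min(tb))
})

test_that("augmentation is seeded, label-preserving and uniform in angle", {
  ex <- list(tensor = array(rnorm(24 * 24 * 12), c(24, 24, 12)), label = 1L,
             provenance = list(case = 1, radius = 5, s = 0))
  a1 <- augment_example(ex, seed = 3)
  a2 <- augment_example(ex, seed = 3)
  expect_identical(a1$tensor, a2$tensor)
  expect_identical(a1$label, ex$label)
  expect_equal(dim(a1$tensor), dim(ex$tensor))
  th <- vapply(1:1000, function(s) augment_example(ex, seed = s)$transform$theta_deg,
               numeric(1))
  expect_gt(ks.test(th, "punif", -45, 45)$p.value, 0.01)
  sc <- vapply(1:200, function(s) augment_example(ex, seed = s)$transform$scale,
               numeric(1))
  expect_true(all(sc >= 0.8 & sc <= 1.2))
  sh <- t(vapply(1:200, function(s) augment_example(ex, seed = s)$transform$shift,
                 numeric(3)))
  expect_true(all(sh[, 1:2] %in% -2:2) && all(sh[, 3] %in% -1:1))
  # the identity affine map reproduces the tensor exactly
  ident <- drls:::.resample_affine_cpp(ex$tensor, dim(ex$tensor),
                                       dim(ex$tensor), as.numeric(diag(3)),
                                       c(0, 0, 0))
  expect_equal(ident, as.numeric(ex$tensor), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("the SGD-with-momentum rule damps weights under strong decay", {
  # two-parameter toy problem: zero data gradient isolates the -eta*w term
  w <- c(3, -2)
  v <- c(0, 0)
  norms <- numeric(50)
  for (i in 1:50) {
    st <- sgd_momentum_step(w, v, grad = c(0, 0), lr = 0.01, zeta = 0,
                            eta = 0.3)
    w <- st$w
    v <- st$v
    norms[i] <- sqrt(sum(w^2))
  }
  expect_true(all(diff(c(sqrt(13), norms)) < 0))
  expect_lt(norms[50], 1e-3)
  # single step matches the closed form
  st <- sgd_momentum_step(w = 2, v = 0.1, grad = 0.5, lr = 0.1, zeta = 0.9,
                          eta = 0.01)
  expect_equal(st$v, 0.9 * 0.1 - 0.1 * 0.5 - 0.01 * 2)
  expect_equal(st$w, 2 + st$v)
})

test_that("training starts near the uniform-prediction loss and can overfit", {
  # wider init than the default: with layer widths this small the default
  # scale makes activations decay geometrically and optimization crawls
  spec <- network_spec(input_shape = c(16, 16, 8), conv_depths = c(4, 4, 8, 8),
                       fc_sizes = c(16, 8, 3), pool_first = TRUE,
                       init_sd = 0.2)
  net <- build_network(spec, seed = 1)
  # spatially distinct patterns (per-example batch norm removes pure
  # mean/variance shifts, so the classes must differ in structure)
  set.seed(9)
  grid <- expand.grid(x = 1:16, y = 1:16, z = 1:8)
  pat0 <- array(sin(grid$x), c(16, 16, 8))
  pat1 <- array(sin(grid$y), c(16, 16, 8))
  pat2 <- array(sin(grid$x + grid$y), c(16, 16, 8))
  ex <- Map(function(p, lb) list(tensor = p + array(rnorm(16 * 16 * 8, sd = 0.1),
                                                    c(16, 16, 8)),
                                 label = lb),
            list(pat0, pat1, pat2), 0:2)
  fit <- train_classifier(net, ex,
                          training_config(epochs = 1, seed = 1))
  expect_lt(abs(fit$loss_history[1] - log(3)), 0.15)
  # eta = 0, many passes over three separable examples: loss -> ~0
  fit2 <- train_classifier(net, ex,
                           training_config(epochs = 80, weight_decay = 0,
                                           dropout_keep = 1, lr_init = 0.02,
                                           decay_steps = 5000, seed = 1))
  expect_lt(mean(tail(fit2$loss_history, 3)), 0.1)
  # reproducibility of the whole loop
  fit3 <- train_classifier(net, ex, training_config(epochs = 3, seed = 2))
  fit4 <- train_classifier(net, ex, training_config(epochs = 3, seed = 2))
  expect_identical(fit3$loss_history, fit4$loss_history)
  expect_identical(fit3$params, fit4$params)
  # a class missing from the training set is refused
  expect_error(train_classifier(net, ex[1:2], training_config(epochs = 1)),
               "three classes")
})

test_that("predict_position closes the loop from volume and contour", {
  spec <- network_spec(input_shape = c(16, 16, 8), conv_depths = c(4, 4, 8, 8),
                       fc_sizes = c(16, 8, 3), pool_first = TRUE)
  net <- build_network(spec, seed = 1)
  ph <- generate_phantom(phantom_spec(shape = c(32, 32, 24), equiv_radius = 6,
                                      intensity_fg = 40, seed = 2))
  phi <- init_sdf_ball(c(32, 32, 24), c(16.5, 16.5, 12.5), 6)
  p <- predict_position(net, ph$volume, phi)
  expect_s3_class(p, "position_probs")
  expect_identical(p, predict_position(net, ph$volume, phi))
})
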