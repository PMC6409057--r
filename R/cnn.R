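#' Parametric rectified linear unit
#'
#' `prelu(x, a)` equals `x` for `x > 0` and `a * x` otherwise, elementwise.
#' With `a = 0` it reduces to ReLU.
#'
#' @param x numeric vector or array.
#' @param a negative-side slope (scalar or object broadcastable over `x`).
#' @return Object shaped like `x`.
#' @export
prelu <- function(x, a) {
  ifelse(x > 0, x, a * x)
}

#' Network architecture specification
#'
#' Four convolutional blocks (3x3x3 kernels, batch norm, PReLU, 2x2x2 max
#' pooling) followed by three fully connected layers ending in a 3-node
#' softmax over the contour-position classes. The default profile takes an
#' 80x80x40 single-channel input with depths 16/32/64/128 and, per the
#' "except the first layer" reading adopted here, no pooling after the first
#' block (`pool_first = FALSE`). [network_spec_reduced()] is a desk-scale
#' profile (40x40x20 input, depths 8/16/32/64, pooling after every block)
#' used for fast training runs.
#'
#' @param input_shape integer length-3 input tensor shape.
#' @param conv_depths 4 convolutional feature-map counts.
#' @param fc_sizes hidden and output FC widths; last entry must be 3.
#' @param pool_first whether the first block is followed by max pooling.
#' @param dropout_keep keep probability of FC dropout during training.
#' @param prelu_init initial PReLU slope.
#' @param init_sd sd of the truncated-normal weight initialization
#'   (truncated at two standard deviations).
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(input_shape = c(80, 80, 40),
                         conv_depths = c(16, 32, 64, 128),
                         fc_sizes = c(256, 64, 3), pool_first = FALSE,
                         dropout_keep = 0.7, prelu_init = 0.25,
                         init_sd = 0.01) {
  input_shape <- as.integer(input_shape)
  conv_depths <- as.integer(conv_depths)
  fc_sizes <- as.integer(fc_sizes)
  if (length(conv_depths) != 4) stop("need exactly 4 convolutional depths")
  if (fc_sizes[length(fc_sizes)] != 3) stop("final FC layer must have 3 nodes")
  if (length(fc_sizes) != 3) stop("need exactly 3 fully connected layers")
  spec <- structure(list(input_shape = input_shape, conv_depths = conv_depths,
                         fc_sizes = fc_sizes, pool_first = pool_first,
                         dropout_keep = dropout_keep, prelu_init = prelu_init,
                         init_sd = init_sd),
                    class = "network_spec")
  g <- .layer_geometry(spec) # validates shape arithmetic
  if (any(vapply(g$blocks, function(b) any(b$out_dim < 1), logical(1)))) {
    stop("input_shape too small for the pooling cascade")
  }
  spec
}

#' @rdname network_spec
#' @export
network_spec_reduced <- function() {
  network_spec(input_shape = c(40, 40, 20), conv_depths = c(8, 16, 32, 64),
               fc_sizes = c(64, 32, 3), pool_first = TRUE)
}

# per-layer shape bookkeeping shared with the C++ kernels
.layer_geometry <- function(spec) {
  d <- spec$input_shape
  cin <- 1L
  blocks <- vector("list", 4)
  for (b in 1:4) {
    pool <- if (b == 1) isTRUE(spec$pool_first) else TRUE
    out_dim <- if (pool) pmax(1L, d %/% 2L) else d
    blocks[[b]] <- list(in_dim = d, conv_dim = d, out_dim = out_dim,
                        cin = cin, cout = spec$conv_depths[b],
                        pool = as.integer(pool))
    d <- out_dim
    cin <- spec$conv_depths[b]
  }
  flat <- prod(d) * cin
  list(blocks = blocks, fc = as.integer(c(flat, spec$fc_sizes)))
}

# truncated normal N(0, sd^2), truncated at +-2 sd
.rtruncnorm <- function(n, sd) {
  out <- rnorm(n, sd = sd)
  bad <- abs(out) > 2 * sd
  while (any(bad)) {
    out[bad] <- rnorm(sum(bad), sd = sd)
    bad <- abs(out) > 2 * sd
  }
  out
}

#' Build an untrained contour-position network
#'
#' Allocates and initializes all parameters: convolution and FC weights from
#' a truncated normal (two-sigma truncation), biases at zero, batch-norm
#' gamma 1 / beta 0 with unit running variance, PReLU slopes at
#' `spec$prelu_init`. Two builds with the same seed are identical.
#'
#' @param spec a [network_spec()].
#' @param seed integer seed for the weight draw.
#' @return An object of class `drls_cnn` with elements `spec`, `geom`,
#'   `params`, `state`, `n_params`, `trained`.
#' @export
build_network <- function(spec = network_spec(), seed = 1L) {
  g <- .layer_geometry(spec)
  params <- list()
  state <- list()
  with_seed(seed, {
    for (b in 1:4) {
      bl <- g$blocks[[b]]
      params[[paste0("conv_w", b)]] <-
        array(.rtruncnorm(27 * bl$cin * bl$cout, spec$init_sd),
              c(3, 3, 3, bl$cin, bl$cout))
      params[[paste0("conv_b", b)]] <- numeric(bl$cout)
      params[[paste0("bn_gamma", b)]] <- rep(1, bl$cout)
      params[[paste0("bn_beta", b)]] <- numeric(bl$cout)
      params[[paste0("prelu", b)]] <- rep(spec$prelu_init, bl$cout)
      state[[paste0("bn_mean", b)]] <- numeric(bl$cout)
      state[[paste0("bn_var", b)]] <- rep(1, bl$cout)
    }
    nfc <- length(g$fc) - 1
    for (l in seq_len(nfc)) {
      params[[paste0("fc_w", l)]] <-
        matrix(.rtruncnorm(g$fc[l] * g$fc[l + 1], spec$init_sd),
               g$fc[l], g$fc[l + 1])
      params[[paste0("fc_b", l)]] <- numeric(g$fc[l + 1])
      if (l < nfc) params[[paste0("fc_prelu", l)]] <- spec$prelu_init
    }
  })
  structure(list(spec = spec, geom = g, params = params, state = state,
                 n_params = sum(vapply(params, length, numeric(1))),
                 trained = FALSE, seed = as.integer(seed)),
            class = "drls_cnn")
}

#' @export
print.drls_cnn <- function(x, ...) {
  cat("<drls_cnn> input ", paste(x$spec$input_shape, collapse = "x"),
      ", depths ", paste(x$spec$conv_depths, collapse = "/"),
      ", ", format(x$n_params, big.mark = ","), " parameters, ",
      if (x$trained) "trained" else "untrained", "\n", sep = "")
  invisible(x)
}

#' Encode a (volume, contour) pair as a network input tensor
#'
#' Crops the intensity volume to the axis-aligned bounding box of the current
#' interior (`phi < 0`) expanded by 20% per side (clipped at the grid),
#' trilinearly resamples the crop to `target_shape`, and z-score normalizes
#' it. The contour's position and scale are conveyed by the crop geometry.
#' Deterministic.
#'
#' @param volume [scalar_volume()] or 3D array.
#' @param phi level-set array with a non-empty interior.
#' @param target_shape output tensor shape (default 80x80x40).
#' @return Numeric array of shape `target_shape` with mean 0 and sd 1.
#' @export
encode_input <- function(volume, phi, target_shape = c(80, 80, 40)) {
  v <- as_volume(volume)$data
  if (!all(dim(v) == dim(phi))) stop("volume and phi shapes differ")
  inside <- which(phi < 0, arr.ind = TRUE)
  if (nrow(inside) == 0) stop("zero level set is empty (no interior)")
  lo <- apply(inside, 2, min)
  hi <- apply(inside, 2, max)
  ext <- pmax(hi - lo + 1, 2)
  lo <- pmax(1, floor(lo - 0.2 * ext))
  hi <- pmin(dim(v), ceiling(hi + 0.2 * ext))
  if (any(hi - lo < 1)) stop("degenerate contour bounding box")
  crop <- v[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  target_shape <- as.integer(target_shape)
  sdim <- dim(crop)
  # output voxel o (0-based) -> source coordinate, endpoints mapped to endpoints
  scale <- (sdim - 1) / pmax(target_shape - 1, 1)
  A <- diag(scale)
  out <- .resample_affine_cpp(crop, sdim, target_shape, as.numeric(A),
                              c(0, 0, 0))
  s <- sd(out)
  if (s < 1e-12) {
    out[] <- 0
  } else {
    out <- (out - mean(out)) / s
  }
  dim(out) <- target_shape
  out
}

#' Build a labelled contour-position training set
#'
#' For every case, spherical contours are placed at the ground-truth centroid
#' with radii `multipliers * equivalent radius`; each contour is labelled by
#' its normalized mean signed distance `s` to the true boundary (the same
#' statistic the geometric oracle uses): `inside` if `s < -margin`,
#' `boundary` if `|s| <= margin`, `outside` if `s > margin`. Each example is
#' encoded with [encode_input()]. With `balance = TRUE`, majority classes are
#' subsampled (deterministically per `seed`) so that no class exceeds twice
#' the size of the smallest.
#'
#' @param cases list of lists with elements `volume` and `gt_mask` (the
#'   output of [generate_phantom()] works directly).
#' @param multipliers contour radii as fractions of the equivalent radius.
#' @param margin labelling threshold on `s` (default 0.25).
#' @param target_shape encoder output shape.
#' @param balance subsample majority classes to within 2x of the minority.
#' @param seed seed for the balancing subsample.
#' @return List of examples: `tensor`, `label` (0 inside / 1 boundary /
#'   2 outside), `provenance` (case, radius, s).
#' @export
build_training_set <- function(cases, multipliers = c(0.5, 0.75, 1, 1.25, 1.6),
                               margin = 0.25, target_shape = c(80, 80, 40),
                               balance = FALSE, seed = 1L) {
  examples <- list()
  for (ci in seq_along(cases)) {
    case <- cases[[ci]]
    gt <- as_mask(case$gt_mask)
    if (!any(gt)) stop("case ", ci, " has an empty ground-truth mask")
    vol <- as_volume(case$volume)
    d <- dim(gt)
    req <- equiv_radius(gt)
    idx <- which(gt, arr.ind = TRUE)
    centroid <- colMeans(idx)
    sdist <- signed_distance_to_boundary(gt)
    for (m in multipliers) {
      r <- m * req
      phi <- init_sdf_ball(d, centroid, r)
      if (!any(phi < 0)) {
        warning("case ", ci, ": contour at ", signif(r, 3),
                " voxels has no interior; skipped")
        next
      }
      contour <- .contour_voxels_cpp(phi, d)
      if (!any(contour)) {
        warning("case ", ci, ": contour at ", signif(r, 3),
                " voxels exceeds the VOI; skipped")
        next
      }
      s <- mean(sdist[contour]) / req
      label <- if (s < -margin) 0L else if (s > margin) 2L else 1L
      examples[[length(examples) + 1]] <- list(
        tensor = encode_input(vol, phi, target_shape), label = label,
        provenance = list(case = ci, radius = r, s = s))
    }
  }
  if (balance && length(examples)) {
    labels <- vapply(examples, `[[`, integer(1), "label")
    counts <- table(factor(labels, levels = 0:2))
    cap <- 2L * max(1L, min(counts[counts > 0]))
    keep <- with_seed(seed, {
      unlist(lapply(0:2, function(lb) {
        i <- which(labels == lb)
        if (length(i) > cap) sort(sample(i, cap)) else i
      }))
    })
    examples <- examples[sort(keep)]
  }
  examples
}

#' Randomly augment one training example
#'
#' One rotation by a uniform angle in [-45, 45] degrees about a uniformly
#' chosen principal axis, an isotropic scaling by a uniform factor in
#' [0.8, 1.2], and an integer-voxel translation uniform in x, y in
#' {-2..2} and z in {-1..1}, applied about the tensor center with trilinear
#' interpolation. The label is preserved; the draw is reproducible per seed.
#'
#' @param example an element of [build_training_set()]'s output.
#' @param seed integer seed.
#' @return An example of the same form; the sampled `theta_deg`, `axis`,
#'   `scale`, `shift` are recorded in `$transform`.
#' @export
augment_example <- function(example, seed = 1L) {
  x <- example$tensor
  d <- dim(x)
  pars <- with_seed(seed, {
    list(theta = runif(1, -45, 45), axis = sample(1:3, 1),
         scale = runif(1, 0.8, 1.2),
         shift = c(sample(-2:2, 1), sample(-2:2, 1), sample(-1:1, 1)))
  })
  th <- pars$theta * pi / 180
  R2 <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  R <- diag(3)
  ij <- setdiff(1:3, pars$axis)
  R[ij, ij] <- R2
  # output voxel -> source voxel: rotate back and unscale about the center
  A <- t(R) / pars$scale
  ctr <- (d - 1) / 2
  tvec <- ctr - A %*% (ctr + pars$shift)
  out <- .resample_affine_cpp(x, d, d, as.numeric(A), as.numeric(tvec))
  list(tensor = out, label = example$label, provenance = example$provenance,
       transform = list(theta_deg = pars$theta, axis = pars$axis,
                        scale = pars$scale, shift = pars$shift))
}

#' Training configuration
#'
#' Hyperparameters of the SGD-with-momentum training loop: single-example
#' batches, cross-entropy plus an L2 penalty `(eta/2)||w||^2` on the
#' convolution and FC weights, velocity update
#' `v <- momentum * v - lr * grad - eta * w`, staircase learning-rate decay
#' by `lr_decay` every `decay_steps` global steps, batch normalization over
#' the spatial positions of the single example (running statistics tracked
#' with decay `bn_decay`, used at evaluation), and inverted dropout with keep
#' probability `dropout_keep` on the hidden FC layers.
#'
#' @param lr_init initial learning rate.
#' @param lr_decay decay factor.
#' @param decay_steps steps between decays.
#' @param momentum momentum coefficient (zeta).
#' @param weight_decay L2 coefficient (eta).
#' @param bn_eps,bn_decay batch-norm variance floor and running-stat decay.
#' @param dropout_keep FC keep probability.
#' @param epochs maximum training epochs.
#' @param seed seed for shuffling and dropout.
#' @return An object of class `training_config`.
#' @export
training_config <- function(lr_init = 0.01, lr_decay = 0.1, decay_steps = 100,
                            momentum = 0.9, weight_decay = 4e-5,
                            bn_eps = 0.001, bn_decay = 0.9,
                            dropout_keep = 0.7, epochs = 10, seed = 1L) {
  stopifnot(lr_init > 0, lr_decay > 0, lr_decay <= 1, decay_steps >= 1,
            momentum >= 0, momentum < 1, weight_decay >= 0,
            dropout_keep > 0, dropout_keep <= 1, epochs >= 1)
  structure(list(lr_init = lr_init, lr_decay = lr_decay,
                 decay_steps = as.integer(decay_steps), momentum = momentum,
                 weight_decay = weight_decay, bn_eps = bn_eps,
                 bn_decay = bn_decay, dropout_keep = dropout_keep,
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "training_config")
}

#' One SGD-with-momentum parameter update
#'
#' The update rule used for every parameter tensor during training:
#' `v <- zeta * v - lr * grad - eta * w` followed by `w <- w + v` (the
#' weight-decay term `eta * w` is applied only to convolution and FC
#' weights; pass `eta = 0` for other parameters).
#'
#' @param w,v,grad parameter, velocity and gradient (same shape).
#' @param lr learning rate.
#' @param zeta momentum coefficient.
#' @param eta weight-decay coefficient.
#' @return List with updated `w` and `v`.
#' @export
sgd_momentum_step <- function(w, v, grad, lr, zeta = 0.9, eta = 0) {
  v <- zeta * v - lr * grad - eta * w
  list(w = w + v, v = v)
}

#' Train the contour-position classifier
#'
#' Runs the SGD loop of [training_config()] over the examples. When an
#' evaluation set is given, held-out 3-class accuracy is computed after each
#' epoch (evaluation mode: running batch-norm statistics, no dropout) and
#' training stops early once `stop_acc` is reached. All three classes must be
#' present in the training examples; a non-finite loss aborts with an error.
#'
#' @param net a [build_network()] object.
#' @param examples training examples (list of `tensor` + `label`).
#' @param cfg a [training_config()].
#' @param eval_examples optional held-out examples.
#' @param stop_acc early-stop accuracy threshold (0 disables).
#' @return The trained `drls_cnn` with `loss_history`, `eval_accuracy` and
#'   `epochs_run` attached.
#' @export
train_classifier <- function(net, examples, cfg = training_config(),
                             eval_examples = list(), stop_acc = 0) {
  if (!inherits(net, "drls_cnn")) stop("`net` must be a drls_cnn")
  labels <- vapply(examples, `[[`, integer(1), "label")
  if (!all(0:2 %in% labels)) {
    stop("training set must contain all three classes (got ",
         paste(sort(unique(labels)), collapse = ", "), ")")
  }
  tensors <- lapply(examples, function(e) .check_tensor(e$tensor, net$spec))
  ev <- lapply(eval_examples, function(e) .check_tensor(e$tensor, net$spec))
  ev_labels <- vapply(eval_examples, `[[`, integer(1), "label")
  fit <- with_seed(cfg$seed, {
    .cnn_train_cpp(tensors, labels, net$params, net$state, net$geom,
                   unclass(cfg), ev, as.integer(ev_labels), stop_acc)
  })
  if (isTRUE(fit$diverged)) {
    stop("training diverged (non-finite loss at step ",
         length(fit$loss_history), ")")
  }
  net$params <- fit$params
  net$state <- fit$state
  net$trained <- TRUE
  net$loss_history <- fit$loss_history
  net$eval_accuracy <- fit$eval_accuracy
  net$epochs_run <- fit$epochs_run
  net
}

.check_tensor <- function(x, spec) {
  if (!all(dim(x) == spec$input_shape)) {
    stop("tensor shape ", paste(dim(x), collapse = "x"),
         " does not match the network input ",
         paste(spec$input_shape, collapse = "x"))
  }
  storage.mode(x) <- "double"
  x
}

#' Predict class probabilities for a raw input tensor
#'
#' Evaluation-mode forward pass (running batch-norm statistics, no dropout).
#'
#' @param net a `drls_cnn`.
#' @param tensor input array of the network's input shape.
#' @return A [position_probs()].
#' @export
predict_tensor <- function(net, tensor) {
  tensor <- .check_tensor(tensor, net$spec)
  p <- .cnn_forward_cpp(tensor, net$params, net$state, net$geom, FALSE, 1,
                        0.001, 0.9)
  p <- p / sum(p)
  position_probs(p[1], p[2], p[3])
}

#' Predict the contour position for a (volume, contour) pair
#'
#' [encode_input()] followed by [predict_tensor()].
#'
#' @param net a `drls_cnn`.
#' @param volume [scalar_volume()] or 3D array.
#' @param phi level-set array.
#' @return A [position_probs()].
#' @export
predict_position <- function(net, volume, phi) {
  predict_tensor(net, encode_input(volume, phi, net$spec$input_shape))
}

#' CNN classifier closure for [evolve()]
#'
#' @param net a trained `drls_cnn`.
#' @return A function `(volume, phi) -> position_probs`.
#' @export
cnn_classifier <- function(net) {
  function(volume, phi) predict_position(net, volume, phi)
}
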