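# The fixed shallow CNN: conv(6 @ 5x5, valid) -> [BN] -> avgpool(2x2) ->
# conv(6 @ 5x5, valid) -> [BN] -> avgpool(2x2) -> flatten -> dense -> softmax,
# trained with SGD (momentum 0.9), constant learning rate 0.001, L2 weight
# decay 0.0005, cross-entropy loss. Convolution/pooling kernels live in
# src/cnn_ops.cpp; batch normalization, the dense head, and the optimizer are
# in R. Everything is seeded and single-threaded-deterministic.

#' CNN architecture configuration
#'
#' The fixed five-layer architecture for 64 x 160 inputs: two valid 5 x 5
#' convolution layers of 6 filters each, each followed (optionally) by batch
#' normalization and by non-overlapping 2 x 2 average pooling, then a single
#' fully connected softmax layer. For a 64 x 160 input the feature maps are
#' 60x156x6 -> 30x78x6 -> 26x74x6 -> 13x37x6 -> 2886 -> `n_classes`.
#'
#' @param n_classes Number of enrolled subjects (>= 2).
#' @param use_batchnorm Insert batch normalization between each convolution
#'   and its pooling layer (default `FALSE`).
#' @param bn_epsilon Numerical-stability constant added to the mini-batch
#'   variance (default 1e-5).
#' @param conv_filters Filters per convolution layer (default 6).
#' @param kernel Convolution kernel size (default `c(5, 5)`).
#' @param pool Average-pooling size/stride (default 2).
#' @return A `cnn_config`.
#' @export
cnn_config <- function(n_classes, use_batchnorm = FALSE, bn_epsilon = 1e-5,
                       conv_filters = 6L, kernel = c(5L, 5L), pool = 2L) {
  if (!is_count(n_classes, min = 2L)) stop_invalid("`n_classes` must be an integer >= 2")
  structure(
    list(n_classes = as.integer(n_classes), use_batchnorm = isTRUE(use_batchnorm),
         bn_epsilon = bn_epsilon, conv_filters = as.integer(conv_filters),
         kernel = as.integer(kernel), pool = as.integer(pool)),
    class = "cnn_config"
  )
}

#' Training configuration
#'
#' The fixed training hyperparameters: constant learning rate 0.001,
#' stochastic gradient descent with momentum 0.9, L2 weight decay 0.0005 on
#' convolution and dense weights, 30 epochs, and a mini-batch of 100 for a
#' single-condition dataset or 200 when REC and REO are combined (so both
#' give the same number of updates per epoch).
#'
#' @param learning_rate Constant step size (default 0.001).
#' @param momentum SGD momentum (default 0.9).
#' @param l2 Weight-decay coefficient on weights, not biases (default 5e-4).
#' @param batch_size Mini-batch size (default 100).
#' @param epochs Passes over the training set (default 30).
#' @param seed Integer seed driving initialization and shuffling.
#' @return A `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, momentum = 0.9, l2 = 5e-4,
                         batch_size = 100L, epochs = 30L, seed = 1L) {
  if (!is.numeric(learning_rate) || learning_rate < 0) {
    stop_invalid("`learning_rate` must be >= 0")
  }
  if (!is_count(batch_size, min = 1L)) stop_invalid("`batch_size` must be a positive integer")
  if (!is_count(epochs, min = 0L)) stop_invalid("`epochs` must be a non-negative integer")
  structure(
    list(learning_rate = learning_rate, momentum = momentum, l2 = l2,
         batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         seed = as.integer(seed)),
    class = "train_config"
  )
}

# Feature-map shape chain for a given input size.
cnn_shape_chain <- function(cfg, input_dim = c(64L, 160L)) {
  k <- cfg$kernel
  c1 <- c(input_dim - k + 1L, cfg$conv_filters)
  p1 <- c(c1[1:2] %/% cfg$pool, cfg$conv_filters)
  c2 <- c(p1[1:2] - k + 1L, cfg$conv_filters)
  p2 <- c(c2[1:2] %/% cfg$pool, cfg$conv_filters)
  list(input = c(input_dim, 1L), conv1 = c1, pool1 = p1, conv2 = c2,
       pool2 = p2, flatten = prod(p2), dense = cfg$n_classes)
}

#' Build the (untrained) CNN
#'
#' Instantiates the architecture of [cnn_config()] for 64 x 160 inputs.
#' Parameters are initialized at training time from the training seed
#' (Glorot-uniform weights, zero biases, unit/zero batch-norm scale/offset).
#'
#' @param cfg A `cnn_config`.
#' @param input_dim Input height x width (default `c(64, 160)`).
#' @return An `eeg_cnn` model handle carrying the config and shape chain.
#' @export
#' @examples
#' m <- build_model(cnn_config(n_classes = 5))
#' m$shapes$conv1
build_model <- function(cfg, input_dim = c(64L, 160L)) {
  stopifnot(inherits(cfg, "cnn_config"))
  shapes <- cnn_shape_chain(cfg, as.integer(input_dim))
  if (any(unlist(shapes[c("conv1", "conv2")]) < 1L)) {
    stop_invalid("input too small for the kernel chain")
  }
  structure(
    list(config = cfg, input_dim = as.integer(input_dim), shapes = shapes,
         params = NULL, trained = FALSE, history = NULL,
         label_levels = NULL, kind = NULL, bn_stats = NULL),
    class = "eeg_cnn"
  )
}

#' @export
print.eeg_cnn <- function(x, ...) {
  s <- x$shapes
  fmt <- function(d) paste(d, collapse = "x")
  cat(sprintf(
    "<eeg_cnn> %s: %s -> conv %s -> pool %s -> conv %s -> pool %s -> %d -> %d%s\n",
    if (x$trained) "trained" else "untrained", fmt(x$input_dim), fmt(s$conv1),
    fmt(s$pool1), fmt(s$conv2), fmt(s$pool2), s$flatten, s$dense,
    if (x$config$use_batchnorm) " (+BN)" else ""
  ))
  if (x$trained) {
    cat(sprintf("  arrangement %s, %d epochs, final val accuracy %.2f%%\n",
                x$kind, nrow(x$history), tail(x$history$val_accuracy, 1)))
  }
  invisible(x)
}

glorot_uniform <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dims)
}

# Parameter initialization; consumes RNG (caller seeds).
init_params <- function(model) {
  cfg <- model$config
  k <- cfg$kernel
  f <- cfg$conv_filters
  nf <- model$shapes$flatten
  p <- list(
    W1 = glorot_uniform(c(k, 1L, f), prod(k), prod(k) * f),
    b1 = numeric(f),
    W2 = glorot_uniform(c(k, f, f), prod(k) * f, prod(k) * f),
    b2 = numeric(f),
    Wd = glorot_uniform(c(nf, cfg$n_classes), nf, cfg$n_classes),
    bd = numeric(cfg$n_classes)
  )
  if (cfg$use_batchnorm) {
    p$gamma1 <- rep(1, f); p$beta1 <- numeric(f)
    p$gamma2 <- rep(1, f); p$beta2 <- numeric(f)
  }
  p
}

# ---- batch normalization ----------------------------------------------------

# Per-channel statistics of a (H, W, C, B) tensor: mean and population
# variance over everything but the channel dimension.
bn_channel_stats <- function(x) {
  d <- dim(x)
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
  m <- colMeans(xm)
  v <- colMeans(xm^2) - m^2
  list(mean = m, var = pmax(v, 0))
}

bn_apply <- function(x, gamma, beta, eps, stats) {
  d <- dim(x)
  invstd <- 1 / sqrt(stats$var + eps)
  sc <- gamma * invstd
  sh <- beta - stats$mean * sc
  xhat_scale <- rep(sc, each = d[1] * d[2])
  xhat_shift <- rep(sh, each = d[1] * d[2])
  # recycle (H*W*C) pattern across the batch dimension
  z <- x * as.vector(xhat_scale) + as.vector(xhat_shift)
  z
}

#' Batch normalization
#'
#' Standardizes activations with mini-batch statistics and applies the
#' learned affine transform: `xhat = (x - mean) / sqrt(var + eps)`,
#' `z = gamma * xhat + beta`. Variance is the population (1/n) variance of
#' the batch. For a 4-D `(H, W, C, B)` tensor, statistics are per channel
#' over all other dimensions; for a vector they are over its elements. At
#' inference the stored full-training-set statistics are used instead of
#' batch statistics (pass `mean`/`variance`).
#'
#' @param batch Numeric vector or 4-D array.
#' @param gamma,beta Learned scale and offset (scalar, or per channel for a
#'   4-D input). Defaults 1 and 0.
#' @param eps Stability constant added to the variance (default 1e-5).
#' @param mean,variance Optional stored statistics; when supplied the batch
#'   statistics are not computed (inference mode).
#' @return Normalized tensor of the same shape.
#' @export
#' @examples
#' batch_normalize(c(1, 3), eps = 0)
batch_normalize <- function(batch, gamma = 1, beta = 0, eps = 1e-5,
                            mean = NULL, variance = NULL) {
  stored <- !is.null(mean) && !is.null(variance)
  if (length(dim(batch)) == 4L) {
    if (!stored) {
      if (dim(batch)[4] < 2L) {
        stop_invalid("batch normalization needs a training batch of size >= 2")
      }
      s <- bn_channel_stats(batch)
    } else {
      s <- list(mean = mean, var = variance)
    }
    C <- dim(batch)[3]
    return(bn_apply(batch, rep_len(gamma, C), rep_len(beta, C), eps, s))
  }
  x <- as.numeric(batch)
  if (!stored) {
    if (length(x) < 2L) {
      stop_invalid("batch normalization needs a training batch of size >= 2")
    }
    mean <- base::mean(x)
    variance <- base::mean((x - mean)^2)
  }
  gamma * (x - mean) / sqrt(variance + eps) + beta
}

# Backward pass of batch normalization (training mode, per-channel stats).
bn_backward <- function(dz, x, gamma, eps, stats) {
  d <- dim(x)
  n <- d[1] * d[2] * d[4]
  invstd <- 1 / sqrt(stats$var + eps)
  xh <- bn_apply(x, rep(1, d[3]), rep(0, d[3]), eps, stats) # xhat
  ch <- function(a) {
    m <- matrix(aperm(a, c(1, 2, 4, 3)), ncol = d[3])
    colSums(m)
  }
  dgamma <- ch(dz * xh)
  dbeta <- ch(dz)
  g <- rep(gamma, each = d[1] * d[2])
  dxhat <- dz * as.vector(g)
  s1 <- ch(dxhat) / n
  s2 <- ch(dxhat * xh) / n
  e1 <- as.vector(rep(s1, each = d[1] * d[2]))
  e2 <- as.vector(rep(s2, each = d[1] * d[2]))
  einv <- as.vector(rep(invstd, each = d[1] * d[2]))
  dx <- einv * (dxhat - e1 - xh * e2)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- forward / backward -----------------------------------------------------

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# Forward pass over a (64, 160, 1, B) batch. `bn_mode` is "batch" during
# training or "stored" at inference; stored statistics come from
# model-level `bn_stats`. Returns activations needed for backprop.
cnn_forward <- function(params, cfg, x, bn_mode = c("stored", "batch"),
                        bn_stats = NULL, keep = FALSE) {
  bn_mode <- match.arg(bn_mode)
  a1 <- cpp_conv_forward(x, params$W1, params$b1)
  s1 <- s2 <- NULL
  if (cfg$use_batchnorm) {
    s1 <- if (bn_mode == "batch") bn_channel_stats(a1) else bn_stats$layer1
    n1 <- bn_apply(a1, params$gamma1, params$beta1, cfg$bn_epsilon, s1)
  } else {
    n1 <- a1
  }
  p1 <- cpp_avgpool_forward(n1, cfg$pool)
  a2 <- cpp_conv_forward(p1, params$W2, params$b2)
  if (cfg$use_batchnorm) {
    s2 <- if (bn_mode == "batch") bn_channel_stats(a2) else bn_stats$layer2
    n2 <- bn_apply(a2, params$gamma2, params$beta2, cfg$bn_epsilon, s2)
  } else {
    n2 <- a2
  }
  p2 <- cpp_avgpool_forward(n2, cfg$pool)
  B <- dim(x)[4]
  fl <- matrix(p2, ncol = B)                       # flatten x B
  logits <- crossprod(params$Wd, fl) + params$bd   # C x B
  probs <- softmax_cols(logits)
  out <- list(probs = probs)
  if (keep) {
    out <- c(out, list(x = x, a1 = a1, p1 = p1, a2 = a2, fl = fl,
                       stats1 = s1, stats2 = s2))
  }
  out
}

# Backward pass for mean cross-entropy; `fw` from cnn_forward(keep = TRUE),
# `y` 1-based class indices. Returns gradients named like params.
cnn_backward <- function(params, cfg, fw, y) {
  B <- length(y)
  dlogits <- fw$probs
  dlogits[cbind(y, seq_len(B))] <- dlogits[cbind(y, seq_len(B))] - 1
  dlogits <- dlogits / B
  g <- list(
    Wd = fw$fl %*% t(dlogits),
    bd = rowSums(dlogits)
  )
  dfl <- params$Wd %*% dlogits
  sp2 <- dim(fw$a2)
  dp2 <- array(dfl, c(sp2[1] %/% cfg$pool, sp2[2] %/% cfg$pool, sp2[3], B))
  dn2 <- cpp_avgpool_backward(dp2, cfg$pool, sp2[1], sp2[2])
  if (cfg$use_batchnorm) {
    bb <- bn_backward(dn2, fw$a2, params$gamma2, cfg$bn_epsilon, fw$stats2)
    g$gamma2 <- bb$dgamma; g$beta2 <- bb$dbeta
    da2 <- array(bb$dx, dim(fw$a2))
  } else {
    da2 <- dn2
  }
  cb2 <- cpp_conv_backward(fw$p1, params$W2, da2)
  g$W2 <- cb2$dw; g$b2 <- cb2$db
  sp1 <- dim(fw$a1)
  dn1 <- cpp_avgpool_backward(cb2$dx, cfg$pool, sp1[1], sp1[2])
  if (cfg$use_batchnorm) {
    bb <- bn_backward(dn1, fw$a1, params$gamma1, cfg$bn_epsilon, fw$stats1)
    g$gamma1 <- bb$dgamma; g$beta1 <- bb$dbeta
    da1 <- array(bb$dx, dim(fw$a1))
  } else {
    da1 <- dn1
  }
  cb1 <- cpp_conv_backward(fw$x, params$W1, da1)
  g$W1 <- cb1$dw; g$b1 <- cb1$db
  g
}

# ---- data marshalling -------------------------------------------------------

# Stack a list of arranged_inputs into (H, W, 1, B); images are fed as real
# values in 0..255 (the min-max scaling is taken as their normalization),
# matrices raw.
stack_inputs <- function(inputs, input_dim) {
  B <- length(inputs)
  kinds <- unique(vapply(inputs, `[[`, character(1), "kind"))
  if (length(kinds) != 1L) {
    stop_invalid("mixed arrangement kinds in one input set: ",
                 paste(kinds, collapse = ", "))
  }
  x <- array(0, c(input_dim, 1L, B))
  for (i in seq_len(B)) {
    v <- inputs[[i]]$values
    if (!all(dim(v) == input_dim)) {
      stop_invalid("input ", i, " has shape ", paste(dim(v), collapse = "x"),
                   ", expected ", paste(input_dim, collapse = "x"))
    }
    x[, , 1L, i] <- v
  }
  list(x = x, kind = kinds,
       subject = vapply(inputs, `[[`, integer(1), "subject_id"))
}

# Full-training-set BN statistics, computed layer by layer with the final
# parameters (layer-2 inputs are evaluated with layer-1 already using its
# stored statistics), in chunks to bound memory.
compute_bn_stats <- function(params, cfg, x, chunk = 256L) {
  B <- dim(x)[4]
  acc <- function() list(s = 0, ss = 0, n = 0)
  upd <- function(a, t) {
    d <- dim(t)
    m <- matrix(aperm(t, c(1, 2, 4, 3)), ncol = d[3])
    a$s <- a$s + colSums(m); a$ss <- a$ss + colSums(m^2)
    a$n <- a$n + nrow(m)
    a
  }
  fin <- function(a) list(mean = a$s / a$n,
                          var = pmax(a$ss / a$n - (a$s / a$n)^2, 0))
  a1acc <- acc()
  for (i in seq(1L, B, by = chunk)) {
    idx <- i:min(i + chunk - 1L, B)
    xb <- x[, , , idx, drop = FALSE]
    a1acc <- upd(a1acc, cpp_conv_forward(xb, params$W1, params$b1))
  }
  layer1 <- fin(a1acc)
  a2acc <- acc()
  for (i in seq(1L, B, by = chunk)) {
    idx <- i:min(i + chunk - 1L, B)
    xb <- x[, , , idx, drop = FALSE]
    a1 <- cpp_conv_forward(xb, params$W1, params$b1)
    n1 <- bn_apply(a1, params$gamma1, params$beta1, cfg$bn_epsilon, layer1)
    p1 <- cpp_avgpool_forward(n1, cfg$pool)
    a2acc <- upd(a2acc, cpp_conv_forward(p1, params$W2, params$b2))
  }
  list(layer1 = layer1, layer2 = fin(a2acc))
}

# Inference over a 4-D batch in chunks; returns C x B probabilities.
predict_probs <- function(model, x, chunk = 256L) {
  B <- dim(x)[4]
  out <- matrix(0, model$config$n_classes, B)
  for (i in seq(1L, B, by = chunk)) {
    idx <- i:min(i + chunk - 1L, B)
    xb <- x[, , , idx, drop = FALSE]
    out[, idx] <- cnn_forward(model$params, model$config, xb,
                              bn_mode = "stored",
                              bn_stats = model$bn_stats)$probs
  }
  out
}

# ---- training ---------------------------------------------------------------

#' Train the CNN on a dataset split
#'
#' Minimizes mean cross-entropy with mini-batch SGD (momentum, constant
#' learning rate, L2 decay on weights) for exactly `cfg$epochs` passes.
#' Initialization and shuffling derive from `cfg$seed`, so identical calls
#' give identical loss histories. With batch normalization enabled, training
#' uses mini-batch statistics; after every epoch (and finally) the
#' full-training-set statistics are computed and stored for inference.
#'
#' @param model An untrained model from [build_model()].
#' @param split A [split_segments()] result whose elements are
#'   `arranged_input`s of a single kind (see [arrange_segment()]).
#' @param cfg A [train_config()].
#' @return A trained `eeg_cnn` with `$history` (per-epoch loss and validation
#'   accuracy) and the subject-to-class mapping in `$label_levels`.
#' @export
train_model <- function(model, split, cfg = train_config()) {
  stopifnot(inherits(model, "eeg_cnn"), inherits(cfg, "train_config"))
  if (!inherits(split, "dataset_split")) stop_invalid("`split` must be a dataset_split")
  if (length(split$train) == 0L) stop_invalid("empty training set")
  tr <- stack_inputs(split$train, model$input_dim)
  va <- if (length(split$validation)) stack_inputs(split$validation, model$input_dim)
  if (!is.null(va) && va$kind != tr$kind) {
    stop_invalid("validation arrangement ", va$kind, " differs from training ", tr$kind)
  }
  levels <- sort(unique(tr$subject))
  if (length(levels) != model$config$n_classes) {
    stop_invalid("training labels cover ", length(levels), " subjects but ",
                 "model has ", model$config$n_classes, " classes")
  }
  y <- match(tr$subject, levels)
  yv <- if (!is.null(va)) match(va$subject, levels)
  n <- length(y)
  cfgm <- model$config
  with_seed(cfg$seed, {
    model$params <- init_params(model)
    vel <- lapply(model$params, function(p) p * 0)
    decayed <- c("W1", "W2", "Wd")
    history <- vector("list", cfg$epochs)
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        xb <- tr$x[, , , idx, drop = FALSE]
        yb <- y[idx]
        fw <- cnn_forward(model$params, cfgm, xb, bn_mode = "batch", keep = TRUE)
        p_true <- fw$probs[cbind(yb, seq_along(yb))]
        losses <- c(losses, -mean(log(pmax(p_true, 1e-12))))
        gr <- cnn_backward(model$params, cfgm, fw, yb)
        for (nm in names(model$params)) {
          g <- gr[[nm]]
          if (nm %in% decayed) g <- g + cfg$l2 * model$params[[nm]]
          vel[[nm]] <- cfg$momentum * vel[[nm]] - cfg$learning_rate * g
          model$params[[nm]] <- model$params[[nm]] + vel[[nm]]
        }
      }
      if (cfgm$use_batchnorm) {
        model$bn_stats <- compute_bn_stats(model$params, cfgm, tr$x)
      }
      val_acc <- if (!is.null(va)) {
        pred <- max.col(t(predict_probs(model, va$x)), ties.method = "first")
        100 * mean(pred == yv)
      } else {
        NA_real_
      }
      history[[epoch]] <- tibble::tibble(epoch = epoch,
                                         loss = mean(losses),
                                         val_accuracy = val_acc)
    }
    if (cfgm$use_batchnorm && is.null(model$bn_stats)) {
      model$bn_stats <- compute_bn_stats(model$params, cfgm, tr$x)
    }
    model$history <- if (cfg$epochs > 0) dplyr::bind_rows(history) else
      tibble::tibble(epoch = integer(), loss = numeric(),
                     val_accuracy = numeric())
  })
  model$trained <- TRUE
  model$label_levels <- levels
  model$kind <- tr$kind
  model$train_config <- cfg
  model
}

#' Observed feature-map shapes
#'
#' Pushes one input through the compiled layer chain and reports the actual
#' dimensions of every intermediate feature map (height x width x filters),
#' the flattened length and the class count -- the shape chain the
#' architecture prints for a 64 x 160 input is
#' 60x156x6 -> 30x78x6 -> 26x74x6 -> 13x37x6 -> 2886 -> n_classes.
#'
#' @param model An `eeg_cnn` (untrained models use freshly initialized
#'   parameters).
#' @param input A height-by-width numeric matrix (or `arranged_input`)
#'   matching the model's input size.
#' @return Named list of integer dimension vectors, one per stage.
#' @export
#' @examples
#' forward_shapes(build_model(cnn_config(5)))
forward_shapes <- function(model, input = NULL) {
  stopifnot(inherits(model, "eeg_cnn"))
  if (is.null(input)) input = matrix(0, model$input_dim[1], model$input_dim[2])
  if (inherits(input, "arranged_input")) input <- input$values
  params <- model$params %||% with_seed(0L, init_params(model))
  cfg <- model$config
  x <- array(input, c(dim(input), 1L, 1L))
  a1 <- cpp_conv_forward(x, params$W1, params$b1)
  p1 <- cpp_avgpool_forward(a1, cfg$pool)
  a2 <- cpp_conv_forward(p1, params$W2, params$b2)
  p2 <- cpp_avgpool_forward(a2, cfg$pool)
  fl <- as.vector(p2)
  logits <- crossprod(params$Wd, matrix(fl, ncol = 1)) + params$bd
  list(input = dim(x)[1:3], conv1 = dim(a1)[1:3], pool1 = dim(p1)[1:3],
       conv2 = dim(a2)[1:3], pool2 = dim(p2)[1:3],
       flatten = length(fl), dense = length(logits))
}

#' Predict subject identities
#'
#' Softmax class probabilities and argmax labels for a set of arranged
#' inputs, using stored batch-normalization statistics (predictions do not
#' depend on how inputs are grouped into batches).
#'
#' @param object A trained `eeg_cnn`.
#' @param inputs List of `arranged_input`s matching the trained kind.
#' @param ... Unused.
#' @return A tibble with `subject_id` (truth, if present), `.pred_class`
#'   (predicted subject id) and one `.prob_<id>` column per enrolled subject.
#' @export
predict.eeg_cnn <- function(object, inputs, ...) {
  if (!object$trained) stop_invalid("model is not trained")
  prob_names <- paste0(".prob_", object$label_levels)
  if (length(inputs) == 0L) {
    out <- tibble::tibble(subject_id = integer(), .pred_class = integer())
    out[prob_names] <- lapply(prob_names, function(x) numeric())
    return(out)
  }
  st <- stack_inputs(inputs, object$input_dim)
  if (st$kind != object$kind) {
    stop_invalid("inputs are ", st$kind, " but model was trained on ", object$kind)
  }
  pr <- predict_probs(object, st$x)
  cls <- object$label_levels[max.col(t(pr), ties.method = "first")]
  out <- tibble::tibble(subject_id = st$subject, .pred_class = cls)
  out[prob_names] <- as.data.frame(t(pr))
  out
}
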