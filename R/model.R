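#' Denoising network configuration
#'
#' The denoiser is a plain 3D convolutional stack in the residual-learning
#' denoising lineage: `n_layers` same-padded convolutions with 3x3x3 kernels
#' and no pooling; the first layer maps the single input channel to
#' `n_filters` channels and is followed by a rectifier; the hidden layers
#' keep `n_filters` channels with batch normalization and a rectifier; the
#' last layer maps back to one channel with no normalization and no
#' rectifier. In residual mode (default) the network predicts the noise map,
#' which is subtracted from the input. Trained with mean-squared-error loss
#' and stochastic gradient descent with momentum.
#'
#' Inputs are scaled by a global constant (the training set's
#' `norm_quantile` SUV quantile) before the network and unscaled after, so
#' SUV units are preserved end to end.
#'
#' @param n_layers convolution layers (>= 2; default 10).
#' @param n_filters channels in the hidden layers (default 68).
#' @param kernel 3 odd integers (default 3x3x3).
#' @param residual predict the noise map (default) rather than the clean
#'   image directly.
#' @param learning_rate,momentum,batch_size,epochs SGD hyperparameters.
#' @param seed seed for weight initialization and batch shuffling.
#' @param norm_quantile quantile of the training intensities used as the
#'   global normalization constant.
#' @param precision `"single"` (default) runs the convolutions in float32 —
#'   roughly twice the GEMM throughput, ample accuracy for SGD training and
#'   inference; `"double"` is available for numerical verification.
#' @return a `cnn_config` list.
#' @export
cnn_config <- function(n_layers = 10L, n_filters = 68L, kernel = c(3L, 3L, 3L),
                       residual = TRUE, learning_rate = 1e-3, momentum = 0.9,
                       batch_size = 8L, epochs = 20L, seed = 1L,
                       norm_quantile = 0.995,
                       precision = c("single", "double")) {
  stopifnot(n_layers >= 2L, n_filters >= 1L, length(kernel) == 3L,
            all(kernel %% 2 == 1), learning_rate > 0,
            momentum >= 0, momentum < 1, batch_size >= 1L, epochs >= 0L)
  structure(list(n_layers = as.integer(n_layers),
                 n_filters = as.integer(n_filters),
                 kernel = as.integer(kernel), residual = isTRUE(residual),
                 learning_rate = learning_rate, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 norm_quantile = norm_quantile,
                 precision = match.arg(precision)),
            class = "cnn_config")
}

layer_channels <- function(cfg) {
  list(c_in = c(1L, rep(cfg$n_filters, cfg$n_layers - 1L)),
       c_out = c(rep(cfg$n_filters, cfg$n_layers - 1L), 1L))
}

#' Build an (untrained) denoising network
#'
#' Initializes weights with He-scaled Gaussians (seeded), zero biases and
#' identity batch-norm parameters. Two builds with the same config are
#' identical.
#'
#' @param config a [cnn_config()].
#' @return a `pet_cnn` object.
#' @export
cnn_build <- function(config = cnn_config()) {
  stopifnot(inherits(config, "cnn_config"))
  ch <- layer_channels(config)
  k <- prod(config$kernel)
  withr::with_seed(config$seed, {
    W <- b <- vector("list", config$n_layers)
    for (l in seq_len(config$n_layers)) {
      fan_in <- ch$c_in[l] * k
      W[[l]] <- matrix(stats::rnorm(ch$c_out[l] * ch$c_in[l] * k,
                                    sd = sqrt(2 / fan_in)),
                       ch$c_in[l] * k, ch$c_out[l])
      b[[l]] <- rep(0, ch$c_out[l])
    }
    bn <- lapply(seq_len(config$n_layers), function(l) {
      if (l == 1L || l == config$n_layers) return(NULL)
      list(gamma = rep(1, ch$c_out[l]), beta = rep(0, ch$c_out[l]),
           rmean = rep(0, ch$c_out[l]), rvar = rep(1, ch$c_out[l]))
    })
    structure(list(config = config, W = W, b = b, bn = bn,
                   scale = NA_real_, residual_scale = 1,
                   loss = numeric(0), trained = FALSE),
              class = "pet_cnn")
  })
}

#' @rdname cnn_build
#' @param model a `pet_cnn`.
#' @return `n_parameters()`: the trainable parameter count (conv weights and
#'   biases plus batch-norm scale/shift).
#' @export
n_parameters <- function(model) {
  cfg <- model$config
  n <- sum(vapply(model$W, length, 1L)) + sum(vapply(model$b, length, 1L))
  n + 2L * cfg$n_filters * (cfg$n_layers - 2L)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# forward pass on X (nvox*batch x 1, already normalized); activations are
# channels-last (rows = voxels x batch, cols = channels). Returns the output
# and, when training, the per-layer caches needed for backprop.
cnn_forward <- function(model, X, dims, batch, training = FALSE) {
  cfg <- model$config
  L <- cfg$n_layers
  eps <- 1e-5
  caches <- if (training) vector("list", L)
  single <- identical(cfg$precision, "single")
  A <- X
  for (l in seq_len(L)) {
    Z <- conv3d_fwd(A, model$W[[l]], model$b[[l]], as.integer(dims),
                    cfg$kernel, as.integer(batch), single)
    cache <- if (training) list(input = A)
    if (!is.null(model$bn[[l]])) {
      bn <- model$bn[[l]]
      if (training) {
        mu <- colMeans(Z)
        v <- colMeans(Z * Z) - mu^2
        istd <- 1 / sqrt(v + eps)
        xhat <- Z
        for (c in seq_along(mu)) {
          xhat[, c] <- (Z[, c] - mu[c]) * istd[c]
          Z[, c] <- bn$gamma[c] * xhat[, c] + bn$beta[c]
        }
        cache$xhat <- xhat; cache$istd <- istd
        cache$mu <- mu; cache$var <- v
      } else {
        istd <- 1 / sqrt(bn$rvar + eps)
        for (c in seq_along(istd)) {
          Z[, c] <- bn$gamma[c] * ((Z[, c] - bn$rmean[c]) * istd[c]) +
            bn$beta[c]
        }
      }
    }
    if (l < L) {
      Z <- relu(Z)
      if (training) cache$mask <- Z > 0
    }
    if (training) caches[[l]] <- cache
    A <- Z
  }
  list(out = A, caches = caches)
}

# backward pass; returns gradient lists (input gradient is discarded)
cnn_backward <- function(model, caches, dOut, dims, batch) {
  cfg <- model$config
  L <- cfg$n_layers
  gW <- gb <- gG <- gB <- vector("list", L)
  dY <- dOut
  for (l in rev(seq_len(L))) {
    cache <- caches[[l]]
    if (l < L) dY <- dY * cache$mask
    if (!is.null(model$bn[[l]])) {
      bn <- model$bn[[l]]
      gG[[l]] <- colSums(dY * cache$xhat)
      gB[[l]] <- colSums(dY)
      m1 <- numeric(length(gG[[l]])); m2 <- m1
      for (c in seq_along(m1)) {
        dxc <- dY[, c] * bn$gamma[c]
        m1[c] <- mean(dxc)
        m2[c] <- mean(dxc * cache$xhat[, c])
        dY[, c] <- cache$istd[c] *
          (dxc - m1[c] - cache$xhat[, c] * m2[c])
      }
    }
    g <- conv3d_bwd(cache$input, model$W[[l]], dY, as.integer(dims),
                    cfg$kernel, as.integer(batch), l > 1L,
                    identical(cfg$precision, "single"))
    gW[[l]] <- g$dW
    gb[[l]] <- as.numeric(g$db)
    if (l > 1L) dY <- g$dX
  }
  list(W = gW, b = gb, gamma = gG, beta = gB)
}

#' Train the denoising network
#'
#' Minimizes the mean squared error between the network output and the
#' residual (noisy minus clean; default) or the clean target directly, by
#' stochastic gradient descent with momentum over seeded shuffled
#' mini-batches. Batch-norm running statistics are accumulated during
#' training and frozen for inference.
#'
#' @param model a `pet_cnn` from [cnn_build()].
#' @param pairs a tibble from [build_pairs()] (list-columns `noisy`,
#'   `clean`), or a list of `list(noisy=, clean=)` arrays of equal shape.
#' @param epochs,learning_rate,batch_size optional overrides of the config.
#' @param verbose print per-epoch loss.
#' @param log_file optional path; per-epoch loss is appended as CSV rows
#'   (`epoch,loss`) while training runs.
#' @return the trained `pet_cnn`, with `$loss` holding per-epoch mean loss.
#' @export
cnn_train <- function(model, pairs, epochs = NULL, learning_rate = NULL,
                      batch_size = NULL, verbose = FALSE,
                      log_file = NULL) {
  stopifnot(inherits(model, "pet_cnn"))
  cfg <- model$config
  epochs <- epochs %||% cfg$epochs
  lr <- learning_rate %||% cfg$learning_rate
  bs <- batch_size %||% cfg$batch_size
  if (inherits(pairs, "data.frame")) {
    pairs <- Map(function(n, c) list(noisy = n, clean = c),
                 pairs$noisy, pairs$clean)
  }
  if (length(pairs) == 0L) stop("`pairs` is empty", call. = FALSE)
  dims <- dim(pairs[[1]]$noisy)
  for (p in pairs) {
    if (!identical(dim(p$noisy), dims) || !identical(dim(p$clean), dims)) {
      stop("all pairs must share one shape", call. = FALSE)
    }
  }
  if (is.na(model$scale)) {
    model$scale <- stats::quantile(
      unlist(lapply(pairs, function(p) as.numeric(p$noisy))),
      cfg$norm_quantile, names = FALSE)
    if (model$scale <= 0) model$scale <- 1
  }
  s <- model$scale
  if (cfg$residual) {
    # standardize the residual target to unit variance so the loss (and
    # hence the gradients) are O(1) regardless of the noise level; the
    # network learns the noise map in these units and inference multiplies
    # the scale back
    res_sd <- stats::sd(unlist(lapply(pairs, function(p)
      as.numeric(p$noisy) - as.numeric(p$clean))))
    model$residual_scale <- if (is.finite(res_sd) && res_sd > 0) res_sd / s
                            else 1
  }
  rs <- model$residual_scale
  nvox <- prod(dims)
  mom <- cfg$momentum
  vW <- lapply(model$W, function(w) w * 0)
  vb <- lapply(model$b, function(x) x * 0)
  vG <- vB <- lapply(model$bn, function(x) if (is.null(x)) NULL else x$gamma * 0)
  bn_mom <- 0.1

  withr::with_seed(cfg$seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(pairs))
      ep_loss <- 0; ep_n <- 0L
      for (start in seq(1L, length(ord), by = bs)) {
        idx <- ord[start:min(start + bs - 1L, length(ord))]
        B <- length(idx)
        X <- matrix(unlist(lapply(pairs[idx],
                                  function(p) as.numeric(p$noisy))) / s,
                    ncol = 1)
        Cl <- matrix(unlist(lapply(pairs[idx],
                                   function(p) as.numeric(p$clean))) / s,
                     ncol = 1)
        target <- if (cfg$residual) (X - Cl) / rs else Cl
        fw <- cnn_forward(model, X, dims, B, training = TRUE)
        diff <- fw$out - target
        loss <- mean(diff * diff)
        if (!is.finite(loss)) {
          stop("training diverged (non-finite loss) at epoch ", ep,
               call. = FALSE)
        }
        ep_loss <- ep_loss + loss * B; ep_n <- ep_n + B
        dOut <- (2 / length(diff)) * diff
        g <- cnn_backward(model, fw$caches, dOut, dims, B)
        for (l in seq_len(cfg$n_layers)) {
          vW[[l]] <- mom * vW[[l]] - lr * g$W[[l]]
          model$W[[l]] <- model$W[[l]] + vW[[l]]
          vb[[l]] <- mom * vb[[l]] - lr * g$b[[l]]
          model$b[[l]] <- model$b[[l]] + vb[[l]]
          if (!is.null(model$bn[[l]])) {
            vG[[l]] <- mom * vG[[l]] - lr * g$gamma[[l]]
            vB[[l]] <- mom * vB[[l]] - lr * g$beta[[l]]
            model$bn[[l]]$gamma <- model$bn[[l]]$gamma + vG[[l]]
            model$bn[[l]]$beta <- model$bn[[l]]$beta + vB[[l]]
            model$bn[[l]]$rmean <- (1 - bn_mom) * model$bn[[l]]$rmean +
              bn_mom * fw$caches[[l]]$mu
            model$bn[[l]]$rvar <- (1 - bn_mom) * model$bn[[l]]$rvar +
              bn_mom * fw$caches[[l]]$var
          }
        }
      }
      model$loss <- c(model$loss, ep_loss / ep_n)
      if (verbose) {
        message(sprintf("epoch %d/%d  loss %.6g", ep, epochs,
                        ep_loss / ep_n))
      }
      if (!is.null(log_file)) {
        if (ep == 1L && !file.exists(log_file)) {
          cat("epoch,loss\n", file = log_file)
        }
        cat(sprintf("%d,%.10g\n", ep, ep_loss / ep_n), file = log_file,
            append = TRUE)
      }
    }
  })
  model$trained <- TRUE
  model
}

#' Denoise a whole volume
#'
#' Applies the network over sliding 5-slice windows with stride 1 and
#' averages the overlapping predictions per slice, so the output covers the
#' whole volume and has the input's shape. Inference uses frozen batch-norm
#' running statistics and is deterministic.
#'
#' @param model a trained `pet_cnn`.
#' @param volume a `pet_volume` (or 3D array) with at least `depth` slices.
#' @param chunk windows evaluated per forward pass (throughput knob only).
#' @return the denoised volume, same class and shape as the input.
#' @export
denoise_volume <- function(model, volume, chunk = 8L) {
  stopifnot(inherits(model, "pet_cnn"))
  cfg <- model$config
  depth <- 5L
  d <- dim(volume)
  if (d[3] < depth) {
    stop("volume has ", d[3], " slices; at least ", depth, " are required",
         call. = FALSE)
  }
  s <- if (is.na(model$scale)) 1 else model$scale
  x <- unclass(volume)
  starts <- seq_len(d[3] - depth + 1L)
  acc <- array(0, d)
  cnt <- numeric(d[3])
  dims <- c(d[1], d[2], depth)
  for (grp in split(starts, ceiling(seq_along(starts) / chunk))) {
    B <- length(grp)
    X <- matrix(unlist(lapply(grp, function(s0)
      as.numeric(x[, , s0:(s0 + depth - 1L)]))) / s, ncol = 1)
    out <- cnn_forward(model, X, dims, B, training = FALSE)$out
    pred <- if (cfg$residual) X - model$residual_scale * out else out
    pred <- array(pred * s, c(d[1], d[2], depth, B))
    for (bi in seq_len(B)) {
      sl <- grp[bi]:(grp[bi] + depth - 1L)
      acc[, , sl] <- acc[, , sl] + pred[, , , bi]
      cnt[sl] <- cnt[sl] + 1
    }
  }
  out <- sweep(acc, 3, cnt, `/`)
  if (inherits(volume, "pet_volume")) {
    out <- pet_volume(out, voxel_size(volume), attr(volume, "units"))
  }
  out
}

#' @export
print.pet_cnn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<pet_cnn> %d layers x %d filters (%s kernel), %s mode, %s\n",
    cfg$n_layers, cfg$n_filters, paste(cfg$kernel, collapse = "x"),
    if (cfg$residual) "residual" else "direct",
    if (x$trained) sprintf("trained %d epochs (final loss %.4g)",
                           length(x$loss), utils::tail(x$loss, 1))
    else "untrained"))
  cat(sprintf("  %s trainable parameters\n",
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' @rdname cnn_build
#' @param x a `pet_cnn`.
#' @param ... unused.
#' @export
tidy.pet_cnn <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss), loss = x$loss)
}

#' @rdname cnn_build
#' @export
glance.pet_cnn <- function(x, ...) {
  tibble::tibble(n_layers = x$config$n_layers,
                 n_filters = x$config$n_filters,
                 n_parameters = n_parameters(x),
                 residual = x$config$residual,
                 epochs_trained = length(x$loss),
                 final_loss = if (length(x$loss)) utils::tail(x$loss, 1)
                              else NA_real_)
}

#' @rdname cnn_build
#' @param object a `pet_cnn`.
#' @export
autoplot.pet_cnn <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "mean squared error",
                  title = "Training loss") +
    ggplot2::theme_minimal()
}

#' Save / load a trained network
#'
#' Checkpoints are a single plain-text JSON archive with the config and all
#' weights and batch-norm statistics embedded.
#'
#' @param model a `pet_cnn`.
#' @param path file path (`.json`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "pet_cnn"))
  payload <- list(
    config = unclass(model$config),
    W = lapply(model$W, function(w) list(dim = dim(w), v = as.numeric(w))),
    b = model$b,
    bn = model$bn,
    scale = model$scale, residual_scale = model$residual_scale,
    loss = model$loss, trained = model$trained)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  cfg <- do.call(cnn_config, p$config[names(p$config) %in%
                                        names(formals(cnn_config))])
  model <- cnn_build(cfg)
  model$W <- lapply(p$W, function(w) matrix(w$v, w$dim[1], w$dim[2]))
  model$b <- lapply(p$b, as.numeric)
  model$bn <- lapply(p$bn, function(x) {
    if (is.null(x) || length(x) == 0L) NULL else lapply(x, as.numeric)
  })
  model$scale <- p$scale
  model$residual_scale <- if (is.null(p$residual_scale)) 1
                          else p$residual_scale
  model$loss <- as.numeric(p$loss)
  model$trained <- isTRUE(p$trained)
  model
}
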