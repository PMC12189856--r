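# The hybrid classifier: two 1-D convolution+ReLU stages over the electrode
# axis (feature families as input channels), max pooling, batch
# normalization, a transformer block (multi-head self-attention with
# residual + layer norm, then a position-wise feed-forward with residual +
# layer norm), dropout, an LSTM over the electrode-derived sequence axis,
# and a dense softmax head. Trained with Adam on categorical cross-entropy.

#' Classifier configuration
#'
#' Layer widths are kept small enough for CPU training in minutes; every
#' value is exposed here. The model dimension is `conv_filters[2]`, and the
#' CNN output's electrode-derived axis is treated as the sequence (time)
#' axis of the transformer and LSTM.
#'
#' @param conv_filters Two positive integers: filters of the two
#'   convolution stages (default `c(32, 64)`; the second is the model
#'   dimension D).
#' @param kernel_size Convolution kernel length along the electrode axis
#'   (default 3, valid padding).
#' @param pool_size Max-pooling window/stride (default 2).
#' @param n_heads Number of attention heads (default 4). When `d_k` is left
#'   `NULL`, D must be divisible by `n_heads`.
#' @param d_k Per-head key/value dimension (default `D / n_heads`).
#' @param ff_dim Hidden width of the position-wise feed-forward (default 64).
#' @param lstm_units LSTM hidden-state size (default 64).
#' @param dropout_rate Dropout after the transformer block (default 0.3);
#'   the regularization ablation sets this to 0.
#' @param n_classes Number of output classes (2: PD vs HC).
#' @param learning_rate Adam step size (default 1e-3).
#' @param ablation `"none"` (full model), `"lstm"` (LSTM removed; the
#'   sequence is mean-pooled into the dense head) or `"regularization"`
#'   (dropout disabled; the Eq.-style batch normalization stays, being part
#'   of the convolutional stage proper).
#' @return A `ctesm_config`.
#' @export
ctesm_config <- function(conv_filters = c(32L, 64L), kernel_size = 3L,
                         pool_size = 2L, n_heads = 4L, d_k = NULL,
                         ff_dim = 64L, lstm_units = 64L, dropout_rate = 0.3,
                         n_classes = 2L, learning_rate = 1e-3,
                         ablation = c("none", "lstm", "regularization")) {
  ablation <- match.arg(ablation)
  if (length(conv_filters) != 2L || any(conv_filters < 1)) {
    stop_validation("field 'conv_filters' must be two positive integers")
  }
  check_positive_scalar(kernel_size, "kernel_size", integer = TRUE)
  check_positive_scalar(pool_size, "pool_size", integer = TRUE)
  check_positive_scalar(n_heads, "n_heads", integer = TRUE)
  check_positive_scalar(ff_dim, "ff_dim", integer = TRUE)
  check_positive_scalar(lstm_units, "lstm_units", integer = TRUE)
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop_validation("field 'dropout_rate' must be in [0, 1)")
  }
  D <- as.integer(conv_filters[2])
  if (is.null(d_k)) {
    if (D %% n_heads != 0) {
      stop_validation(sprintf(
        "model dimension %d not divisible by n_heads %d (set d_k explicitly)",
        D, n_heads))
    }
    d_k <- D %/% n_heads
  }
  check_positive_scalar(d_k, "d_k", integer = TRUE)
  if (ablation == "regularization") dropout_rate <- 0
  structure(
    list(conv_filters = as.integer(conv_filters),
         kernel_size = as.integer(kernel_size),
         pool_size = as.integer(pool_size),
         n_heads = as.integer(n_heads), d_k = as.integer(d_k),
         ff_dim = as.integer(ff_dim), lstm_units = as.integer(lstm_units),
         dropout_rate = dropout_rate, n_classes = as.integer(n_classes),
         learning_rate = learning_rate, ablation = ablation),
    class = "ctesm_config"
  )
}

#' Sequence length of the CNN output
#'
#' The electrode axis shrinks by `kernel_size - 1` at each of the two valid
#' convolutions and is then divided by the pooling stride:
#' `T = floor((n_channels - 2*(kernel_size - 1)) / pool_size)`.
#'
#' @param n_channels Number of input electrodes.
#' @param config A [ctesm_config()].
#' @return Integer sequence length T.
#' @export
cnn_output_length <- function(n_channels, config) {
  L2 <- n_channels - 2L * (config$kernel_size - 1L)
  if (L2 < config$pool_size) {
    stop_validation(sprintf(
      "%d channels too few for kernel %d + pool %d",
      n_channels, config$kernel_size, config$pool_size))
  }
  L2 %/% config$pool_size
}

init_params <- function(config, n_channels, n_features) {
  K <- config$kernel_size
  f1 <- config$conv_filters[1]
  D <- config$conv_filters[2]
  hk <- config$n_heads * config$d_k
  H <- config$lstm_units
  p <- list(
    W1 = glorot(K * n_features, f1, c(K, n_features, f1)),
    b1 = numeric(f1),
    W2 = glorot(K * f1, D, c(K, f1, D)),
    b2 = numeric(D),
    bn_gamma = rep(1, D),
    bn_beta = numeric(D),
    Wq = glorot(D, hk), Wk = glorot(D, hk), Wv = glorot(D, hk),
    Wo = glorot(hk, D),
    Wf1 = glorot(D, config$ff_dim), bf1 = numeric(config$ff_dim),
    Wf2 = glorot(config$ff_dim, D), bf2 = numeric(D)
  )
  if (config$ablation == "lstm") {
    p$Wout <- glorot(D, config$n_classes)
  } else {
    p$Wx <- glorot(D, 4 * H)
    p$Wh <- glorot(H, 4 * H)
    p$bl <- rep(c(0, 1, 0, 0), each = H)  # forget-gate bias init 1
    p$Wout <- glorot(H, config$n_classes)
  }
  p$bout <- numeric(config$n_classes)
  p
}

#' Convolutional front end
#'
#' Two convolution+ReLU stages along the electrode axis, max pooling and
#' batch normalization, reshaped into the B x T x D sequence the
#' transformer consumes. Exposed mainly for inspection and testing; the
#' training loop calls it internally.
#'
#' @param x Batch array B x n_channels x n_features.
#' @param params Parameter list of a model (see [ctesm_train()]).
#' @param config A [ctesm_config()].
#' @param train Use batch statistics (TRUE) or running statistics.
#' @param bn_state List with `mean`/`var` running statistics.
#' @return List with `y` (B x T x D sequence tensor) and caches.
#' @export
cnn_block <- function(x, params, config, train = FALSE, bn_state = NULL) {
  if (is.null(bn_state)) {
    bn_state <- list(mean = numeric(config$conv_filters[2]),
                     var = rep(1, config$conv_filters[2]))
  }
  c1 <- conv1d_forward(x, params$W1, params$b1)
  r1 <- relu_forward(c1$y)
  c2 <- conv1d_forward(r1$y, params$W2, params$b2)
  r2 <- relu_forward(c2$y)
  mp <- maxpool_forward(r2$y, config$pool_size)
  bn <- batchnorm_forward(mp$y, params$bn_gamma, params$bn_beta, train,
                          bn_state$mean, bn_state$var)
  list(y = bn$y,
       cache = list(c1 = c1$cache, r1 = r1$cache, c2 = c2$cache,
                    r2 = r2$cache, mp = mp$cache, bn = bn$cache),
       bn_state = list(mean = bn$run_mean, var = bn$run_var),
       pre_bn = mp$y)
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V` applied per attention head; heads are
#' concatenated and linearly projected. Exposed for testing and
#' interpretability (the returned `weights` are the per-head attention
#' maps).
#'
#' @param x Sequence tensor B x T x D.
#' @param params Model parameter list (uses `Wq`, `Wk`, `Wv`, `Wo`).
#' @param config A [ctesm_config()].
#' @return List with `y` (B x T x D) and `weights` (list of T x T
#'   attention matrices, one per batch element x head).
#' @export
attention_block <- function(x, params, config) {
  if (config$d_k <= 0) stop_validation("field 'd_k' must be positive")
  attention_forward(x, params$Wq, params$Wk, params$Wv, params$Wo,
                    config$n_heads, config$d_k)
}

# Full forward pass. Returns probabilities plus every cache needed by
# ctesm_backward. Dropout masks are drawn from the current RNG stream.
ctesm_forward <- function(params, x, config, train = FALSE, bn_state = NULL) {
  cnn <- cnn_block(x, params, config, train, bn_state)
  att <- attention_forward(cnn$y, params$Wq, params$Wk, params$Wv, params$Wo,
                           config$n_heads, config$d_k)
  res1 <- att$y + cnn$y
  ln1 <- layernorm_forward(res1)
  ff <- ffn_forward(ln1$y, params$Wf1, params$bf1, params$Wf2, params$bf2)
  res2 <- ff$y + ln1$y
  ln2 <- layernorm_forward(res2)
  dr <- dropout_forward(ln2$y, config$dropout_rate, train)
  if (config$ablation == "lstm") {
    seq_out <- apply(dr$y, c(1, 3), mean)            # B x D mean pool
    lstm_cache <- NULL
  } else {
    ls <- lstm_forward(dr$y, params$Wx, params$Wh, params$bl)
    seq_out <- ls$y
    lstm_cache <- ls$cache
  }
  logits <- sweep(seq_out %*% params$Wout, 2, params$bout, "+")
  probs <- softmax_rows(logits)
  list(probs = probs,
       cache = list(cnn = cnn$cache, att = att$cache, ln1 = ln1$cache,
                    ff = ff$cache, ln2 = ln2$cache, drop = dr$cache,
                    lstm = lstm_cache, seq_out = seq_out,
                    seq_dims = dim(dr$y)),
       bn_state = cnn$bn_state)
}

# dlogits: (probs - onehot)/B. Returns gradients named like params.
ctesm_backward <- function(params, config, cache, dlogits) {
  g <- list()
  g$Wout <- t(cache$seq_out) %*% dlogits
  g$bout <- colSums(dlogits)
  dseq <- dlogits %*% t(params$Wout)
  if (config$ablation == "lstm") {
    d <- cache$seq_dims
    ddrop <- array(0, d)
    for (t in seq_len(d[2])) ddrop[, t, ] <- dseq / d[2]
  } else {
    lb <- lstm_backward(dseq, cache$lstm)
    g$Wx <- lb$dWx; g$Wh <- lb$dWh; g$bl <- lb$db
    ddrop <- lb$dx
  }
  dln2 <- dropout_backward(ddrop, cache$drop)
  dres2 <- layernorm_backward(dln2, cache$ln2)
  fb <- ffn_backward(dres2, cache$ff)
  g$Wf1 <- fb$dW1; g$bf1 <- fb$db1; g$Wf2 <- fb$dW2; g$bf2 <- fb$db2
  dln1 <- fb$dx + dres2                       # residual
  dres1 <- layernorm_backward(dln1, cache$ln1)
  ab <- attention_backward(dres1, cache$att)
  g$Wq <- ab$dWq; g$Wk <- ab$dWk; g$Wv <- ab$dWv; g$Wo <- ab$dWo
  dcnn <- ab$dx + dres1                       # residual
  bnb <- batchnorm_backward(dcnn, cache$cnn$bn)
  g$bn_gamma <- bnb$dgamma; g$bn_beta <- bnb$dbeta
  dmp <- maxpool_backward(bnb$dx, cache$cnn$mp)
  dr2 <- relu_backward(dmp, cache$cnn$r2)
  cb2 <- conv1d_backward(dr2, cache$cnn$c2)
  g$W2 <- cb2$dW; g$b2 <- cb2$db
  dr1 <- relu_backward(cb2$dx, cache$cnn$r1)
  cb1 <- conv1d_backward(dr1, cache$cnn$c1)
  g$W1 <- cb1$dW; g$b1 <- cb1$db
  g
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

instances_to_array <- function(instances) {
  if (inherits(instances, "ctesm_augmented")) instances <- instances$instances
  m1 <- instances[[1]]$matrix
  arr <- array(0, c(length(instances), nrow(m1), ncol(m1)))
  for (i in seq_along(instances)) arr[i, , ] <- instances[[i]]$matrix
  arr
}

#' Train the classifier
#'
#' Mini-batch Adam on categorical cross-entropy. Feature columns are
#' z-scored with training-set statistics (stored in the model and reapplied
#' at prediction time). A fraction of the training instances is held aside
#' as a validation set; per-epoch train/validation loss and accuracy are
#' recorded in `history`.
#'
#' @param instances List of `ctesm_features`, or a `ctesm_augmented` set.
#' @param labels Optional label vector (defaults to the instances' labels).
#' @param config A [ctesm_config()].
#' @param epochs Training epochs (default 50).
#' @param batch_size Mini-batch size (default 32).
#' @param validation_split Fraction of instances held out for validation
#'   monitoring (default 0.1).
#' @param seed Single integer seed controlling weight initialization,
#'   shuffling, validation split and dropout.
#' @param verbose Print per-epoch progress.
#' @return A `ctesm_model`: parameters, config, feature scaling, batch-norm
#'   running statistics, class levels and a `history` data frame.
#' @export
ctesm_train <- function(instances, labels = NULL, config = ctesm_config(),
                        epochs = 50, batch_size = 32,
                        validation_split = 0.1, seed = 1L, verbose = FALSE) {
  if (inherits(instances, "ctesm_augmented")) instances <- instances$instances
  if (is.null(labels)) labels <- instance_labels(instances)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) {
    stop_validation("training data must contain at least 2 classes")
  }
  if (length(classes) != config$n_classes) {
    stop_validation(sprintf("found %d classes but config$n_classes = %d",
                            length(classes), config$n_classes))
  }
  x <- instances_to_array(instances)
  n <- dim(x)[1]
  y_idx <- match(labels, classes)

  feat_mean <- apply(x, 3, mean)
  feat_sd <- apply(x, 3, stats::sd)
  feat_sd[feat_sd == 0] <- 1
  for (j in seq_len(dim(x)[3])) {
    x[, , j] <- (x[, , j] - feat_mean[j]) / feat_sd[j]
  }

  feature_names <- instances[[1]]$feature_names
  n_channels <- dim(x)[2]
  cnn_output_length(n_channels, config)  # validates geometry early

  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        train_acc = numeric(), val_loss = numeric(),
                        val_acc = numeric())
  model_env <- with_seed(seed, {
    params <- init_params(config, n_channels, dim(x)[3])
    bn_state <- list(mean = numeric(config$conv_filters[2]),
                     var = rep(1, config$conv_filters[2]))
    opt <- adam_init(params)

    perm <- sample.int(n)
    n_val <- floor(validation_split * n)
    val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer(0)
    tr_idx <- setdiff(perm, val_idx)
    if (length(unique(y_idx[tr_idx])) < 2L) {
      stop_validation("training partition contains a single class")
    }

    eval_set <- function(idx) {
      fw <- ctesm_forward(params, x[idx, , , drop = FALSE], config,
                          train = FALSE, bn_state = bn_state)
      p <- fw$probs
      list(loss = -mean(log(pmax(p[cbind(seq_along(idx), y_idx[idx])], 1e-12))),
           acc = mean(max.col(p) == y_idx[idx]))
    }

    for (ep in seq_len(epochs)) {
      ord <- sample(tr_idx)
      ep_loss <- 0
      ep_correct <- 0
      for (start in seq(1, length(ord), by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, length(ord))]
        xb <- x[idx, , , drop = FALSE]
        fw <- ctesm_forward(params, xb, config, train = TRUE, bn_state)
        bn_state <- fw$bn_state
        p <- fw$probs
        B <- length(idx)
        Y <- matrix(0, B, config$n_classes)
        Y[cbind(seq_len(B), y_idx[idx])] <- 1
        ep_loss <- ep_loss - sum(log(pmax(p[Y == 1], 1e-12)))
        ep_correct <- ep_correct + sum(max.col(p) == y_idx[idx])
        grads <- ctesm_backward(params, config, fw$cache, (p - Y) / B)
        upd <- adam_step(params, grads, opt, config$learning_rate)
        params <- upd$params
        opt <- upd$state
      }
      val <- if (length(val_idx)) eval_set(val_idx) else list(loss = NA, acc = NA)
      history[ep, ] <- list(ep, ep_loss / length(ord),
                            ep_correct / length(ord), val$loss, val$acc)
      if (verbose) {
        message(sprintf(
          "epoch %3d  loss %.4f  acc %.3f  val_loss %s  val_acc %s",
          ep, history$train_loss[ep], history$train_acc[ep],
          format(val$loss, digits = 4), format(val$acc, digits = 3)))
      }
    }
    list(params = params, bn_state = bn_state)
  })

  structure(
    list(params = model_env$params, config = config,
         bn_state = model_env$bn_state, classes = classes,
         feat_mean = feat_mean, feat_sd = feat_sd,
         feature_names = feature_names, n_channels = n_channels,
         history = history, seed = seed),
    class = "ctesm_model"
  )
}

#' @export
print.ctesm_model <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf(
    "<ctesm_model> %s | D=%d heads=%d d_k=%d lstm=%s | %d epochs, train acc %.3f\n",
    if (x$config$ablation == "none") "full" else paste0("ablation:", x$config$ablation),
    x$config$conv_filters[2], x$config$n_heads, x$config$d_k,
    if (x$config$ablation == "lstm") "off" else x$config$lstm_units,
    nrow(x$history), last$train_acc))
  invisible(x)
}

#' Predict class probabilities or labels
#'
#' Inference mode: batch normalization uses the stored running statistics
#' and dropout is disabled, so predictions are per-instance deterministic
#' and independent of batch composition.
#'
#' @param object A `ctesm_model`.
#' @param instances List of `ctesm_features` (or `ctesm_augmented`).
#' @param type `"prob"` for the class-probability matrix, `"class"` for
#'   labels.
#' @param ... Unused.
#' @return Matrix of probabilities (rows sum to 1) or character vector.
#' @export
predict.ctesm_model <- function(object, instances, type = c("prob", "class"),
                                ...) {
  type <- match.arg(type)
  x <- instances_to_array(instances)
  for (j in seq_len(dim(x)[3])) {
    x[, , j] <- (x[, , j] - object$feat_mean[j]) / object$feat_sd[j]
  }
  fw <- ctesm_forward(object$params, x, object$config, train = FALSE,
                      bn_state = object$bn_state)
  colnames(fw$probs) <- object$classes
  if (type == "prob") fw$probs else object$classes[max.col(fw$probs)]
}

#' Split instances into train and test partitions
#'
#' @param instances List of `ctesm_features`.
#' @param test_fraction Fraction held out (default 0.2).
#' @param by `"frame"` (random over frames, the conventional protocol) or
#'   `"subject"` (whole subjects held out; leakage-safe when frames of one
#'   subject are correlated).
#' @param seed Integer seed.
#' @return List with `train` and `test` index vectors.
#' @export
split_instances <- function(instances, test_fraction = 0.2,
                            by = c("frame", "subject"), seed = 1L) {
  by <- match.arg(by)
  n <- length(instances)
  with_seed(seed, {
    if (by == "frame") {
      test <- sort(sample.int(n, round(test_fraction * n)))
    } else {
      subj <- vapply(instances, function(i) i$subject_id, character(1))
      lab <- instance_labels(instances)
      sub_lab <- tapply(lab, subj, `[`, 1)
      test_subj <- unlist(lapply(split(names(sub_lab), sub_lab), function(s) {
        sample(s, max(1L, round(test_fraction * length(s))))
      }))
      test <- sort(which(subj %in% test_subj))
    }
    list(train = setdiff(seq_len(n), test), test = test)
  })
}

#' Training-history curves
#'
#' @param x A `ctesm_model`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.ctesm_model <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_acc, h$val_acc), type = "l",
                    lty = 1, col = c("black", "red"),
                    xlab = "epoch", ylab = "accuracy", ...)
  graphics::legend("bottomright", c("train", "validation"), lty = 1,
                   col = c("black", "red"), bty = "n")
  invisible(x)
}
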