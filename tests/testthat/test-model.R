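# Architecture unit identities, an end-to-end numerical gradient check, and
# small training runs. Internal layer primitives are reached via ::: where
# no public surface exists.

test_that("attention with zero queries averages the values uniformly", {
  D <- 4L
  cfg <- ctesm_config(conv_filters = c(4L, D), n_heads = 2L, d_k = 2L)
  params <- list(Wq = matrix(0, D, D), Wk = diag(D), Wv = diag(D),
                 Wo = diag(D))
  withr::with_seed(1, x <- array(rnorm(2 * 3 * D), c(2, 3, D)))
  out <- attention_block(x, params, cfg)
  for (w in out$weights) {
    expect_equal(w, matrix(1 / 3, 3, 3), tolerance = 1e-12)
  }
  # output rows are the column-mean of V (= x, identity projections)
  for (b in 1:2) {
    vbar <- colMeans(matrix(x[b, , ], 3, D))
    for (t in 1:3) {
      expect_equal(out$y[b, t, ], vbar, tolerance = 1e-12)
    }
  }
})

test_that("single-position attention returns the values unchanged", {
  D <- 4L
  cfg <- ctesm_config(conv_filters = c(4L, D), n_heads = 2L, d_k = 2L)
  withr::with_seed(2, {
    params <- list(Wq = matrix(rnorm(D * D), D), Wk = matrix(rnorm(D * D), D),
                   Wv = diag(D), Wo = diag(D))
    x <- array(rnorm(3 * 1 * D), c(3, 1, D))
  })
  out <- attention_block(x, params, cfg)
  expect_equal(out$y, x, tolerance = 1e-12)
})

test_that("attention matches the hand-computed 2-position scalar case", {
  cfg <- ctesm_config(conv_filters = c(4L, 1L), n_heads = 1L, d_k = 1L)
  params <- list(Wq = matrix(1), Wk = matrix(1), Wv = matrix(1),
                 Wo = matrix(1))
  a <- 0.7; b <- -0.4
  x <- array(c(a, b), c(1, 2, 1))
  out <- attention_block(x, params, cfg)
  w11 <- exp(a * a) / (exp(a * a) + exp(a * b))
  w21 <- exp(b * a) / (exp(b * a) + exp(b * b))
  expect_equal(out$y[1, 1, 1], w11 * a + (1 - w11) * b, tolerance = 1e-12)
  expect_equal(out$y[1, 2, 1], w21 * a + (1 - w21) * b, tolerance = 1e-12)
})

test_that("layer normalization standardizes rows and ignores scale", {
  withr::with_seed(3, x <- array(rnorm(4 * 5 * 8, sd = 7), c(4, 5, 8)))
  ln <- ctesm:::layernorm_forward(x)
  xm <- matrix(ln$y, 20, 8)
  expect_lt(max(abs(rowMeans(xm))), 1e-6)
  expect_lt(max(abs(sqrt(rowMeans(xm^2)) - 1)), 1e-6)
  ln2 <- ctesm:::layernorm_forward(2 * x)
  expect_equal(ln$y, ln2$y, tolerance = 1e-6)
})

test_that("the softmax head emits probability vectors; zero logits are uniform", {
  withr::with_seed(4, m <- matrix(rnorm(12), 6, 2))
  p <- ctesm:::softmax_rows(m)
  expect_equal(unname(rowSums(p)), rep(1, 6), tolerance = 1e-12)
  expect_true(all(p > 0 & p < 1))
  expect_equal(ctesm:::softmax_rows(matrix(0, 3, 2)),
               matrix(0.5, 3, 2), tolerance = 1e-12)
})

test_that("one LSTM step equals the scalar gate-equation oracle", {
  withr::with_seed(5, {
    Wx <- matrix(rnorm(4), 1, 4)
    Wh <- matrix(rnorm(4), 1, 4)
    b <- rnorm(4)
    xv <- rnorm(1)
  })
  out <- ctesm:::lstm_forward(array(xv, c(1, 1, 1)), Wx, Wh, b)
  sig <- function(z) 1 / (1 + exp(-z))
  z <- xv * Wx[1, ] + b            # h0 = c0 = 0
  i_ <- sig(z[1]); f_ <- sig(z[2]); o_ <- sig(z[3]); g_ <- tanh(z[4])
  c1 <- i_ * g_
  expect_equal(out$y[1, 1], o_ * tanh(c1), tolerance = 1e-12)
})

test_that("the CNN block maps zeros to zeros and obeys the shape formula", {
  cfg <- tiny_model_config()
  params <- withr::with_seed(6, ctesm:::init_params(cfg, 12L, 5L))
  zero <- ctesm:::cnn_block(array(0, c(2, 12, 5)), params, cfg, train = FALSE)
  expect_true(all(zero$pre_bn == 0))   # ReLU(conv(0) + 0 bias) = 0, pooled
  withr::with_seed(7, x <- array(rnorm(2 * 12 * 5), c(2, 12, 5)))
  out <- ctesm:::cnn_block(x, params, cfg, train = TRUE)
  T_expected <- cnn_output_length(12L, cfg)
  expect_identical(dim(out$y), c(2L, T_expected, cfg$conv_filters[2]))
  expect_identical(T_expected, (12L - 2L * 2L) %/% 2L)
  # identical inputs in one batch give identical output rows
  x2 <- x
  x2[2, , ] <- x[1, , ]
  out2 <- ctesm:::cnn_block(x2, params, cfg, train = FALSE)
  expect_equal(out2$y[1, , ], out2$y[2, , ], tolerance = 1e-12)
})

test_that("backpropagation matches central-difference gradients", {
  cfg <- ctesm_config(conv_filters = c(4L, 6L), kernel_size = 3L,
                      pool_size = 2L, n_heads = 2L, d_k = 3L, ff_dim = 5L,
                      lstm_units = 4L, dropout_rate = 0)
  B <- 3L; C <- 9L; Fn <- 4L
  withr::with_seed(8, {
    x <- array(rnorm(B * C * Fn), c(B, C, Fn))
    y <- c(1L, 2L, 1L)
    params <- ctesm:::init_params(cfg, C, Fn)
  })
  loss_fn <- function(p) {
    fw <- ctesm:::ctesm_forward(p, x, cfg, train = TRUE)
    -mean(log(fw$probs[cbind(seq_len(B), y)]))
  }
  fw <- ctesm:::ctesm_forward(params, x, cfg, train = TRUE)
  Y <- matrix(0, B, 2)
  Y[cbind(seq_len(B), y)] <- 1
  grads <- ctesm:::ctesm_backward(params, cfg, fw$cache, (fw$probs - Y) / B)
  withr::with_seed(9, {
    for (nm in names(grads)) {
      for (rep in 1:3) {
        i <- sample(length(params[[nm]]), 1)
        eps <- 1e-5
        pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
        num <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
        ana <- grads[[nm]][i]
        expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4)
      }
    }
  })
})

test_that("training fits a linearly separable set and prediction is batch-stable", {
  inst <- separable_instances()
  m <- ctesm_train(inst, config = tiny_model_config(), epochs = 15,
                   batch_size = 16, seed = 3)
  expect_gte(utils::tail(m$history$train_acc, 1), 0.99)
  # loss trend decreases
  expect_lt(mean(utils::tail(m$history$train_loss, 3)),
            mean(utils::head(m$history$train_loss, 3)))
  p1 <- predict(m, inst, type = "prob")
  perm <- rev(seq_along(inst))
  p2 <- predict(m, inst[perm], type = "prob")
  expect_equal(p2[order(perm), ], p1, tolerance = 1e-10)
  expect_equal(unname(rowSums(p1)), rep(1, length(inst)), tolerance = 1e-6)
})

test_that("both ablation variants build and train", {
  inst <- separable_instances(n_per_class = 15)
  for (ab in c("lstm", "regularization")) {
    m <- ctesm_train(inst, config = tiny_model_config(ablation = ab),
                     epochs = 8, batch_size = 16, seed = 4)
    expect_s3_class(m, "ctesm_model")
    expect_gte(utils::tail(m$history$train_acc, 1), 0.9)
    expect_identical(m$config$ablation, ab)
  }
  # the regularization ablation forces dropout off
  expect_equal(ctesm_config(ablation = "regularization",
                            dropout_rate = 0.5)$dropout_rate, 0)
})

test_that("degenerate training inputs are rejected", {
  inst <- separable_instances(n_per_class = 5)
  one_class <- inst[instance_labels(inst) == "A"]
  expect_error(ctesm_train(one_class, config = tiny_model_config()),
               "2 classes", class = "ctesm_validation_error")
  expect_error(ctesm_config(conv_filters = c(8L, 10L), n_heads = 4L),
               "divisible", class = "ctesm_validation_error")
})

test_that("subject-wise splitting keeps subjects intact across partitions", {
  inst <- separable_instances(n_per_class = 10)
  # give each subject 2 frames
  inst2 <- c(inst, lapply(inst, function(i) {
    i$frame_index <- 2L
    i
  }))
  sp <- split_instances(inst2, 0.2, by = "subject", seed = 2)
  subj <- vapply(inst2, function(i) i$subject_id, character(1))
  expect_length(intersect(subj[sp$train], subj[sp$test]), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(inst2))
})
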