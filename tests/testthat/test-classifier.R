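make_blobs <- function(n_per = 100, seed = 51, sep = 6) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * 2), ncol = 2),
             matrix(rnorm(n_per * 2, mean = sep), ncol = 2))
  list(x = x, y = rep(c("a", "b"), each = n_per))
}

raw_model <- function(W, b, classes = paste0("C", seq_along(b))) {
  structure(list(W = W, b = b, classes = classes, n_features = ncol(W)),
            class = "savehsi_softmax")
}

test_that("softmax probabilities are stable, normalised and shift-invariant", {
  m <- raw_model(matrix(0, 4, 3), rep(0, 4))
  expect_equal(unname(softmax_probs(m, c(1, 2, 3))), rep(0.25, 4))
  # huge logits must not overflow: z = (1000, 0)
  m2 <- raw_model(matrix(c(1000, 0), 2, 1), c(0, 0))
  p <- softmax_probs(m2, 1)
  expect_true(all(is.finite(p)))
  expect_gt(p[1], 1 - 1e-12)
  # matches an independent per-class formulation 1 / sum_j exp(z_j - z_c)
  set.seed(52)
  W <- matrix(rnorm(15), 5, 3); b <- rnorm(5); x <- rnorm(3)
  z <- as.numeric(W %*% x + b)
  oracle <- vapply(1:5, function(c) 1 / sum(exp(z - z[c])), numeric(1))
  expect_equal(unname(softmax_probs(raw_model(W, b), x)), oracle,
               tolerance = 1e-12)
  # shift invariance
  expect_equal(softmax_probs(raw_model(W, b + 123), x),
               softmax_probs(raw_model(W, b), x), tolerance = 1e-12)
  expect_error(softmax_probs(raw_model(W, b), rnorm(4)), "feature length")
})

test_that("cross-entropy has its closed-form values and matches a per-sample loop", {
  expect_equal(cross_entropy(c(1, 0, 0), c(1, 0, 0)), 0, tolerance = 1e-9)
  for (C in c(2, 5, 8))
    expect_equal(cross_entropy(rep(1 / C, C), c(1, rep(0, C - 1))), log(C),
                 tolerance = 1e-12)
  set.seed(53)
  p <- matrix(runif(6 * 4), 6); p <- p / rowSums(p)
  y <- diag(4)[sample(1:4, 6, replace = TRUE), ]
  acc <- 0
  for (i in 1:6) acc <- acc - log(sum(p[i, ] * y[i, ]))
  expect_equal(cross_entropy(p, y), acc / 6, tolerance = 1e-12)
})

test_that("the analytic gradient matches central finite differences to 1e-5", {
  set.seed(54)
  x <- matrix(rnorm(20 * 5), 20, 5)
  labels <- sample(c("u", "v", "w"), 20, replace = TRUE)
  m <- raw_model(matrix(rnorm(15, sd = 0.1), 3, 5), rnorm(3, sd = 0.1),
                 classes = c("u", "v", "w"))
  g <- softmax_gradient(m, x, labels)
  y <- diag(3)[match(labels, m$classes), ]
  loss_at <- function(model) cross_entropy(softmax_probs(model, x), y)
  h <- 1e-6
  for (idx in list(c(1, 1), c(2, 3), c(3, 5))) {
    mp <- m; mp$W[idx[1], idx[2]] <- mp$W[idx[1], idx[2]] + h
    mm <- m; mm$W[idx[1], idx[2]] <- mm$W[idx[1], idx[2]] - h
    expect_equal(g$dW[idx[1], idx[2]], (loss_at(mp) - loss_at(mm)) / (2 * h),
                 tolerance = 1e-5)
  }
  for (c_idx in 1:3) {
    mp <- m; mp$b[c_idx] <- mp$b[c_idx] + h
    mm <- m; mm$b[c_idx] <- mm$b[c_idx] - h
    expect_equal(g$db[c_idx], (loss_at(mp) - loss_at(mm)) / (2 * h),
                 tolerance = 1e-5)
  }
})

test_that("training separates Gaussian blobs and is seed-reproducible", {
  blobs <- make_blobs()
  cfg <- train_config(epochs = 50, batch_size = 64, lr = 0.05, seed = 7)
  model <- train_softmax(blobs$x, blobs$y, cfg)
  cm <- evaluate_softmax(model, blobs$x, blobs$y)
  expect_equal(attr(metrics_from_confusion(cm), "accuracy"), 1.0)
  expect_true(all(cm$counts == diag(c(100, 100))))
  expect_lte(model$loss[length(model$loss)], model$initial_loss)
  # same config twice: bit-identical trajectory and confusion matrix
  model2 <- train_softmax(blobs$x, blobs$y, cfg)
  expect_identical(model$W, model2$W)
  expect_identical(evaluate_softmax(model2, blobs$x, blobs$y)$counts, cm$counts)
})

test_that("a zero learning rate leaves parameters at their initialisation", {
  blobs <- make_blobs(30)
  m1 <- train_softmax(blobs$x, blobs$y, train_config(epochs = 1, lr = 0, seed = 3))
  m5 <- train_softmax(blobs$x, blobs$y, train_config(epochs = 5, lr = 0, seed = 3))
  expect_identical(m1$W, m5$W)
  expect_identical(m1$b, m5$b)
})

test_that("full-batch training loss decreases monotonically on the convex blob problem", {
  blobs <- make_blobs(60)
  cfg <- train_config(epochs = 40, batch_size = 120, lr = 1e-3, seed = 11)
  model <- train_softmax(blobs$x, blobs$y, cfg)
  expect_true(all(diff(model$loss) <= 1e-9))
})

test_that("evaluation validates input and counts are additive", {
  blobs <- make_blobs(20)
  model <- train_softmax(blobs$x, blobs$y,
                         train_config(epochs = 20, lr = 0.05, seed = 2))
  cm1 <- evaluate_softmax(model, blobs$x, blobs$y)
  cm2 <- evaluate_softmax(model, rbind(blobs$x, blobs$x),
                          c(blobs$y, blobs$y))
  expect_equal(unname(cm2$counts), unname(2L * cm1$counts))
  expect_error(evaluate_softmax(model, blobs$x[0, , drop = FALSE],
                                character(0)), "empty")
  expect_error(train_softmax(blobs$x, rep("a", 40)), "2 classes")
})

test_that("frames flatten to luminance features at the requested size", {
  ph <- make_phantom(2, c(32, 32), "normal")
  f <- frame_to_features(ph$frame, size = 16)
  expect_length(f, 256)
  expect_true(all(f >= 0 & f <= 1))
  # a constant frame produces constant features at any size
  flat <- array(0.5, dim = c(8, 8, 3))
  expect_equal(frame_to_features(flat, 4), rep(0.5, 16), tolerance = 1e-12)
})
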