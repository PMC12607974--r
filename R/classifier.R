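# Reference multinomial logistic-regression classifier over flattened
# grayscale images, trained with first/second-moment gradient updates.

#' Training configuration for the reference classifier
#'
#' Defaults follow the usual desk-scale recipe: 300 epochs, batch size 64,
#' learning rate 1e-3, moment coefficients 0.9 / 0.999, stabiliser 1e-8.
#' Setting both moment coefficients to 0 degenerates the update to a
#' gradient-normalised SGD step. Bias correction of the moment estimates is
#' off by default (the update uses the raw moments).
#'
#' @param epochs Number of passes over the data (>= 1).
#' @param batch_size Minibatch size; capped at the dataset size.
#' @param lr Learning rate eta.
#' @param beta1,beta2 First/second moment coefficients in \[0, 1).
#' @param eps Denominator stabiliser (> 0).
#' @param seed RNG seed controlling initialisation and batch shuffling.
#' @param bias_correction Apply the 1/(1-beta^t) moment corrections.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 300, batch_size = 64, lr = 1e-3,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8, seed = 1,
                         bias_correction = FALSE) {
  if (epochs < 1) stop("epochs must be >= 1")
  if (beta1 < 0 || beta1 >= 1 || beta2 < 0 || beta2 >= 1)
    stop("moment coefficients must lie in [0, 1)")
  if (eps <= 0) stop("eps must be > 0")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
                 seed = as.integer(seed), bias_correction = bias_correction),
            class = "train_config")
}

#' Class probabilities of a softmax model
#'
#' P(y = c | x) = exp(z_c) / sum_j exp(z_j) with z = W x + b. The maximum
#' logit is subtracted before exponentiation, so arbitrarily large logits do
#' not overflow; the result is invariant to adding a constant to all logits.
#'
#' @param model A `savehsi_softmax` model (see [train_softmax()]).
#' @param x Feature vector of length `n_features`, or an n x n_features
#'   matrix of rows.
#' @return Probability vector summing to 1 (or n x C matrix of rows).
#' @export
softmax_probs <- function(model, x) {
  m <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(m) != ncol(model$W))
    stop(sprintf("feature length %d does not match model input size %d",
                 ncol(m), ncol(model$W)))
  z <- m %*% t(model$W)
  z <- sweep(z, 2, model$b, "+")          # n x C
  z <- z - apply(z, 1, max)
  e <- exp(z)
  p <- e / rowSums(e)
  colnames(p) <- model$classes
  if (!is.matrix(x)) p <- p[1, ]
  p
}

#' Mean cross-entropy loss
#'
#' Mean over samples of -log p(true class); probabilities are floored at
#' 1e-12 before the logarithm.
#'
#' @param probs n x C matrix of predicted probabilities (or a single
#'   probability vector).
#' @param onehot n x C one-hot matrix of true labels (or a single vector).
#' @return Nonnegative scalar loss; 0 only for perfectly confident correct
#'   predictions.
#' @export
cross_entropy <- function(probs, onehot) {
  p <- if (is.matrix(probs)) probs else matrix(probs, nrow = 1)
  y <- if (is.matrix(onehot)) onehot else matrix(onehot, nrow = 1)
  if (any(dim(p) != dim(y))) stop("probability and label shapes differ")
  ptrue <- rowSums(p * y)
  n_floored <- sum(ptrue < 1e-12)
  if (n_floored > 0)
    log_event("cross_entropy: floored %d probability value(s) at 1e-12", n_floored)
  mean(-log(pmax(ptrue, 1e-12)))
}

# internal: one-hot encode labels against a fixed class vector
onehot_encode <- function(labels, classes) {
  idx <- match(as.character(labels), classes)
  if (anyNA(idx)) stop("label not among model classes")
  y <- matrix(0, length(idx), length(classes))
  y[cbind(seq_along(idx), idx)] <- 1
  y
}

#' Gradient of the mean cross-entropy loss
#'
#' Analytic gradient (softmax minus one-hot, averaged over the batch) with
#' respect to the weight matrix and bias.
#'
#' @param model A `savehsi_softmax` model.
#' @param x n x n_features matrix.
#' @param labels Vector of class labels.
#' @return List with `dW` (C x n_features) and `db` (length C).
#' @export
softmax_gradient <- function(model, x, labels) {
  y <- onehot_encode(labels, model$classes)
  p <- softmax_probs(model, x)
  if (!is.matrix(p)) p <- matrix(p, nrow = 1)
  d <- unname(p - y)                       # n x C
  list(dW = t(d) %*% x / nrow(x), db = colMeans(d))
}

#' Train the reference softmax classifier
#'
#' Minibatch gradient training with exponential first and second moment
#' accumulators: m <- b1 m + (1-b1) g, v <- b2 v + (1-b2) g^2, and parameter
#' step theta <- theta - lr * m / (sqrt(v) + eps). The same seed yields a
#' bit-identical parameter trajectory.
#'
#' @param x n x n_features numeric matrix (rows are flattened images).
#' @param labels Class label per row (>= 2 distinct classes required).
#' @param cfg A [train_config()].
#' @return A `savehsi_softmax` model: `W`, `b`, `classes`, `n_features` and
#'   the per-epoch training `loss` trace.
#' @export
train_softmax <- function(x, labels, cfg = train_config()) {
  x <- as.matrix(x)
  classes <- sort(unique(as.character(labels)))
  if (length(classes) < 2) stop("training needs at least 2 classes")
  if (nrow(x) != length(labels)) stop("feature rows and labels differ in length")
  C <- length(classes); Fdim <- ncol(x); n <- nrow(x)
  y <- onehot_encode(labels, classes)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(cfg$seed)

  W <- matrix(stats::rnorm(C * Fdim, sd = 0.01), C, Fdim)
  b <- rep(0, C)
  mW <- matrix(0, C, Fdim); vW <- matrix(0, C, Fdim)
  mb <- rep(0, C); vb <- rep(0, C)
  model <- structure(list(W = W, b = b, classes = classes, n_features = Fdim),
                     class = "savehsi_softmax")
  bs <- min(cfg$batch_size, n)
  loss_trace <- numeric(cfg$epochs)
  t_step <- 0
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1, n)]
      g <- softmax_gradient(model, x[idx, , drop = FALSE],
                            labels[idx])
      t_step <- t_step + 1
      mW <- cfg$beta1 * mW + (1 - cfg$beta1) * g$dW
      vW <- cfg$beta2 * vW + (1 - cfg$beta2) * g$dW^2
      mb <- cfg$beta1 * mb + (1 - cfg$beta1) * g$db
      vb <- cfg$beta2 * vb + (1 - cfg$beta2) * g$db^2
      if (cfg$bias_correction) {
        c1 <- 1 - cfg$beta1^t_step; c2 <- 1 - cfg$beta2^t_step
        model$W <- model$W - cfg$lr * (mW / c1) / (sqrt(vW / c2) + cfg$eps)
        model$b <- model$b - cfg$lr * (mb / c1) / (sqrt(vb / c2) + cfg$eps)
      } else {
        model$W <- model$W - cfg$lr * mW / (sqrt(vW) + cfg$eps)
        model$b <- model$b - cfg$lr * mb / (sqrt(vb) + cfg$eps)
      }
    }
    loss_trace[epoch] <- cross_entropy(softmax_probs(model, x), y)
  }
  model$loss <- loss_trace
  model$initial_loss <- cross_entropy(
    softmax_probs(structure(list(W = W, b = b, classes = classes,
                                 n_features = Fdim),
                            class = "savehsi_softmax"), x), y)
  model
}

#' @export
print.savehsi_softmax <- function(x, ...) {
  cat(sprintf("Softmax classifier: %d classes x %d features\n",
              length(x$classes), x$n_features))
  if (!is.null(x$loss))
    cat(sprintf("  final training loss %.5f over %d epochs\n",
                x$loss[length(x$loss)], length(x$loss)))
  invisible(x)
}

#' Evaluate a softmax model into a confusion matrix
#'
#' Argmax prediction per sample; ties break toward the lowest class index.
#'
#' @param model A `savehsi_softmax` model.
#' @param x n x n_features matrix.
#' @param labels True class label per row.
#' @return A [confusion_matrix()] over the model's classes.
#' @export
evaluate_softmax <- function(model, x, labels) {
  x <- as.matrix(x)
  if (nrow(x) == 0) stop("empty dataset")
  p <- softmax_probs(model, x)
  if (!is.matrix(p)) p <- matrix(p, nrow = 1)
  pred <- model$classes[apply(p, 1, which.max)]
  k <- length(model$classes)
  counts <- matrix(0L, k, k)
  ti <- match(as.character(labels), model$classes)
  pi_ <- match(pred, model$classes)
  if (anyNA(ti)) stop("label not among model classes")
  for (i in seq_along(ti)) counts[ti[i], pi_[i]] <- counts[ti[i], pi_[i]] + 1L
  confusion_matrix(counts, model$classes)
}

#' Convert an RGB frame to flattened grayscale features
#'
#' Luminance-weighted channel mean (Rec. 709 weights) followed by bilinear
#' resize to `size` x `size` and row-major flattening.
#'
#' @param frame H x W x 3 RGB array in \[0, 1\].
#' @param size Output side length (default 256, giving 65,536 features).
#' @return Numeric feature vector of length `size^2`.
#' @export
frame_to_features <- function(frame, size = 256) {
  g <- 0.2126 * frame[, , 1] + 0.7152 * frame[, , 2] + 0.0722 * frame[, , 3]
  as.vector(t(resize_bilinear(g, size, size)))
}

#' Bilinear image resize
#'
#' @param m Numeric matrix.
#' @param h,w Output dimensions.
#' @return Resized h x w matrix.
#' @export
resize_bilinear <- function(m, h, w) {
  sr <- nrow(m); sc <- ncol(m)
  if (sr == h && sc == w) return(m)
  ri <- if (h == 1) rep(1, 1) else (seq_len(h) - 1) * (sr - 1) / (h - 1) + 1
  ci <- if (w == 1) rep(1, 1) else (seq_len(w) - 1) * (sc - 1) / (w - 1) + 1
  r0 <- pmin(floor(ri), sr - 1); r1 <- r0 + 1; fr <- ri - r0
  c0 <- pmin(floor(ci), sc - 1); c1 <- c0 + 1; fc <- ci - c0
  if (sr == 1) { r0 <- r1 <- rep(1, h); fr <- rep(0, h) }
  if (sc == 1) { c0 <- c1 <- rep(1, w); fc <- rep(0, w) }
  a <- m[r0, c0, drop = FALSE] * outer(1 - fr, 1 - fc) +
       m[r1, c0, drop = FALSE] * outer(fr, 1 - fc) +
       m[r0, c1, drop = FALSE] * outer(1 - fr, fc) +
       m[r1, c1, drop = FALSE] * outer(fr, fc)
  a
}
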