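# Colour-chart camera calibration: a third-order polynomial correction
# mapping camera-reported XYZ to chart-target XYZ.

#' Full cubic monomial term set over (X, Y, Z)
#'
#' Enumerates all monomials of total degree <= `degree` in three variables,
#' ordered by total degree then lexicographically: the constant term (which
#' doubles as the dark-offset channel), the three linear terms, six
#' quadratics and ten cubics — 20 terms for the default degree 3.
#'
#' @param degree Maximum total degree (1-3).
#' @return A term-set object: list of integer exponent triples with a
#'   `labels` attribute.
#' @export
cubic_terms <- function(degree = 3) {
  if (degree < 1 || degree > 3) stop("polynomial correction is limited to degree 3")
  terms <- list()
  for (d in 0:degree)
    for (i in d:0) for (j in (d - i):0) {
      k <- d - i - j
      terms[[length(terms) + 1L]] <- c(i, j, k)
    }
  lab <- vapply(terms, function(e) {
    if (all(e == 0)) return("1")
    paste0(mapply(function(v, p) if (p == 0) "" else if (p == 1) v
                  else paste0(v, p), c("X", "Y", "Z"), e), collapse = "")
  }, character(1))
  structure(terms, labels = lab, class = "savehsi_terms")
}

#' @export
print.savehsi_terms <- function(x, ...) {
  cat("Polynomial term set:", paste(attr(x, "labels"), collapse = " "), "\n")
  invisible(x)
}

#' Expand XYZ values into polynomial regression variables
#'
#' Evaluates every monomial in the term set at the given tristimulus values.
#' This is the variable-expansion stage of the camera correction: the
#' constant slot carries the dark offset, the linear slots the raw colour
#' response, and the higher-order slots the nonlinear response modifiers.
#'
#' @param xyz Length-3 XYZ vector or n x 3 matrix.
#' @param terms Term set from [cubic_terms()] (or a list of exponent triples).
#' @return Numeric vector (or n x n_terms matrix) of monomial values.
#' @export
expand_variables <- function(xyz, terms = cubic_terms()) {
  if (length(terms) == 0) stop("term set must be nonempty")
  degs <- vapply(terms, sum, numeric(1))
  if (any(degs > 3)) stop("term of degree > 3 in the expansion spec")
  m <- if (is.matrix(xyz)) xyz else matrix(xyz, nrow = 1)
  if (ncol(m) != 3) stop("XYZ input must have 3 components")
  out <- vapply(terms, function(e)
    m[, 1]^e[1] * m[, 2]^e[2] * m[, 3]^e[3], numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m))
  colnames(out) <- attr(terms, "labels")
  if (!is.matrix(xyz)) out <- out[1, ]
  out
}

# internal: per-row RMSE across XYZ components
row_rmse <- function(a, b) sqrt(rowMeans((a - b)^2))

#' Fit the polynomial camera correction from a colour chart
#'
#' Least-squares fit of a correction matrix C mapping expanded
#' camera-measured XYZ to the chart's target XYZ, for all 24 patches
#' simultaneously. Uses the minimum-norm pseudo-inverse solution (optionally
#' ridge-regularised), so near-degenerate designs — 24 patches against the
#' 20-term cubic basis — remain stable. Diagnostics record per-patch XYZ RMSE
#' and mean CIEDE2000 before and after correction.
#'
#' @param chart A colour chart (see [make_chart()] or [read_chart()]).
#' @param measured_xyz 24 x 3 matrix of camera-reported XYZ for the patches.
#' @param terms Polynomial term set, default full cubic.
#' @param ridge Nonnegative ridge penalty on the (non-constant) coefficients.
#' @param standardize Z-score the non-constant expanded variables before
#'   regression (off by default; both paths give identical predictions on
#'   noiseless in-family data).
#' @param white White point for the Delta-E diagnostics.
#' @return A `savehsi_calibration` object: terms, 3 x n_terms matrix `C`,
#'   standardisation record, and fit `diagnostics`.
#' @export
fit_correction <- function(chart, measured_xyz, terms = cubic_terms(),
                           ridge = 0, standardize = FALSE,
                           white = white_point_d65()) {
  target <- chart$xyz_target
  if (!is.matrix(measured_xyz) || nrow(measured_xyz) != nrow(target) ||
      ncol(measured_xyz) != 3)
    stop(sprintf("measured_xyz must be a %d x 3 matrix matching the chart",
                 nrow(target)))
  V <- expand_variables(measured_xyz, terms)
  center <- rep(0, ncol(V)); scale <- rep(1, ncol(V))
  if (standardize) {
    nonconst <- which(apply(V, 2, function(v) stats::sd(v) > 0))
    center[nonconst] <- colMeans(V[, nonconst, drop = FALSE])
    scale[nonconst] <- apply(V[, nonconst, drop = FALSE], 2, stats::sd)
  }
  Vs <- sweep(sweep(V, 2, center), 2, scale, "/")
  # minimum-norm least squares via SVD pseudo-inverse
  sv <- svd(Vs)
  tol <- max(dim(Vs)) * max(sv$d) * .Machine$double.eps
  keep <- sv$d > tol
  if (sum(keep) < length(sv$d) && ridge == 0)
    log_event("fit_correction: design rank %d < %d terms; using min-norm solution",
              sum(keep), ncol(Vs))
  if (!any(keep))
    stop("design matrix has no usable rank; reduce the term set")
  dinv <- if (ridge > 0) sv$d / (sv$d^2 + ridge) else
    ifelse(keep, 1 / sv$d, 0)
  Ct <- sv$v %*% (dinv * (t(sv$u) %*% target))  # n_terms x 3
  fitted <- Vs %*% Ct
  lab_t <- xyz_to_lab(target, white)
  diag_pre <- list(rmse = row_rmse(measured_xyz, target),
                   de00 = ciede2000(xyz_to_lab(measured_xyz, white), lab_t))
  diag_post <- list(rmse = row_rmse(fitted, target),
                    de00 = ciede2000(xyz_to_lab(pmax(fitted, 0), white), lab_t))
  model <- structure(list(
    terms = terms, C = t(Ct), center = center, scale = scale,
    standardize = standardize, ridge = ridge,
    diagnostics = list(
      rmse_pre = diag_pre$rmse, rmse_post = diag_post$rmse,
      mean_de00_pre = mean(diag_pre$de00), mean_de00_post = mean(diag_post$de00),
      de00_pre = diag_pre$de00, de00_post = diag_post$de00)),
    class = "savehsi_calibration")
  model
}

#' Apply a fitted camera correction
#'
#' @param model A `savehsi_calibration` from [fit_correction()].
#' @param xyz Length-3 XYZ vector or n x 3 matrix.
#' @return Corrected XYZ, negatives clamped to 0 (clamp count in the
#'   `"n_clamped"` attribute).
#' @export
apply_correction <- function(model, xyz) {
  if (!inherits(model, "savehsi_calibration") || is.null(model$C))
    stop("model is not a fitted calibration")
  V <- expand_variables(xyz, model$terms)
  Vm <- if (is.matrix(V)) V else matrix(V, nrow = 1)
  Vs <- sweep(sweep(Vm, 2, model$center), 2, model$scale, "/")
  out <- Vs %*% t(model$C)
  n_clamped <- sum(out < 0)
  if (n_clamped > 0)
    log_event("apply_correction: clamped %d negative value(s)", n_clamped)
  out <- pmax(out, 0)
  colnames(out) <- c("X", "Y", "Z")
  if (!is.matrix(xyz)) out <- structure(out[1, ], names = c("X", "Y", "Z"))
  attr(out, "n_clamped") <- n_clamped
  out
}

#' @export
print.savehsi_calibration <- function(x, ...) {
  d <- x$diagnostics
  cat("Camera calibration:", ncol(x$C), "polynomial terms\n")
  cat(sprintf("  chart RMSE (XYZ): %.4f -> %.4f\n",
              mean(d$rmse_pre), mean(d$rmse_post)))
  cat(sprintf("  mean Delta-E00 : %.4f -> %.4f\n",
              d$mean_de00_pre, d$mean_de00_post))
  invisible(x)
}

#' Serialise a calibration model to JSON
#'
#' Bit-stable across runs: the JSON encodes the term exponents, correction
#' matrix, standardisation record and diagnostics at full precision.
#'
#' @param model A `savehsi_calibration`.
#' @param path Output file.
#' @export
write_calibration <- function(model, path) {
  obj <- list(
    type = "savehsi_calibration",
    terms = lapply(model$terms, as.integer),
    term_labels = attr(model$terms, "labels"),
    C = model$C, center = model$center, scale = model$scale,
    standardize = model$standardize, ridge = model$ridge,
    diagnostics = model$diagnostics)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a calibration model written by [write_calibration()]
#' @param path JSON file path.
#' @return A `savehsi_calibration`.
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "savehsi_calibration"))
    stop("not a calibration model file: ", path)
  terms <- structure(lapply(seq_len(nrow(obj$terms)),
                            function(i) as.integer(obj$terms[i, ])),
                     labels = obj$term_labels, class = "savehsi_terms")
  structure(list(terms = terms, C = matrix(obj$C, nrow = 3),
                 center = obj$center, scale = obj$scale,
                 standardize = obj$standardize, ridge = obj$ridge,
                 diagnostics = obj$diagnostics),
            class = "savehsi_calibration")
}
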