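# Spectral reconstruction: PCA + multiple regression from corrected XYZ to
# 401-sample reflectance spectra, and whole-frame RGB -> hyperspectral cube
# conversion.

#' Render a reflectance spectrum to XYZ under an illuminant
#'
#' X = k * sum(S(l) R(l) xbar(l)) and likewise Y, Z, with the normaliser k
#' chosen so a perfect reflector has Y = 100.
#'
#' @param spectrum 401 reflectance samples on the package grid (or an
#'   n x 401 matrix of spectra in rows).
#' @param ill Illuminant list (see [illuminant_e()]).
#' @param cmf Colour-matching functions (see [cmf_cie1931()]).
#' @return Length-3 XYZ vector (or n x 3 matrix), internal Y = 100 scale.
#' @export
render_spectrum <- function(spectrum, ill = illuminant_e(), cmf = cmf_cie1931()) {
  if (!identical(ill$wavelengths, cmf$wavelengths))
    stop("illuminant and CMF wavelength grids do not match")
  check_grid(ill$wavelengths, "illuminant wavelengths")
  m <- if (is.matrix(spectrum)) spectrum else matrix(spectrum, nrow = 1)
  if (ncol(m) != N_BANDS)
    stop(sprintf("spectrum must have %d samples on the 380:780 nm grid", N_BANDS))
  k <- 100 / sum(ill$power * cmf$ybar)
  S <- ill$power
  out <- cbind(X = k * as.numeric(m %*% (S * cmf$xbar)),
               Y = k * as.numeric(m %*% (S * cmf$ybar)),
               Z = k * as.numeric(m %*% (S * cmf$zbar)))
  if (!is.matrix(spectrum)) out <- structure(out[1, ], names = c("X", "Y", "Z"))
  out
}

#' Camera-reported XYZ of a chart's measured patches
#'
#' Decodes the chart's measured sRGB values and maps them through the
#' primaries matrix — the uncorrected "camera XYZ" that calibration takes
#' as input.
#'
#' @param chart Chart with `rgb_measured` set (see [image_chart()]).
#' @param transfer,primaries Decode options (see [srgb_decode()]).
#' @return 24 x 3 matrix of XYZ values on the internal scale.
#' @export
chart_camera_xyz <- function(chart, transfer = "srgb",
                             primaries = srgb_primaries()) {
  if (is.null(chart$rgb_measured))
    stop("chart has no measured RGB values; image it first (see image_chart)")
  linear_rgb_to_xyz(srgb_decode(chart$rgb_measured, transfer), primaries)
}

#' Fit the XYZ-to-spectrum reconstruction model
#'
#' The training spectra (the chart's 24 reference reflectances) are
#' mean-centred and decomposed by PCA; the number of components k is the
#' smallest count whose cumulative explained variance reaches
#' `variance_threshold` (default 0.99, i.e. more than 99% of the spectral
#' information is retained). A multiple-regression map is then fit by least
#' squares from the polynomial expansion of each patch's corrected XYZ to its
#' principal-component scores. Set `direct = TRUE` to regress the centred
#' spectra on the expanded variables directly, bypassing the PCA scores.
#'
#' @param chart Colour chart carrying `rgb_measured` and 401 x 24
#'   `reflectance_ref`.
#' @param calib Fitted [fit_correction()] model.
#' @param variance_threshold Fraction of spectral variance to retain, in
#'   (0, 1\].
#' @param terms Polynomial term set for the regression input; defaults to
#'   the calibration's own term set.
#' @param direct Regress spectra directly instead of PCA scores.
#' @param transfer,primaries Camera decode options (see [srgb_decode()]).
#' @return A `savehsi_recon` object: mean spectrum, k x 401 orthonormal
#'   `basis`, k x n_terms `score_map`, `variance_retained`, and training
#'   diagnostics (per-patch spectral RMSE).
#' @export
fit_reconstruction <- function(chart, calib, variance_threshold = 0.99,
                               terms = calib$terms, direct = FALSE,
                               transfer = "srgb", primaries = srgb_primaries()) {
  if (variance_threshold <= 0 || variance_threshold > 1)
    stop("variance_threshold must be in (0, 1]")
  R <- chart$reflectance_ref                       # 401 x n_patch
  if (nrow(R) != N_BANDS) stop("chart spectra must be 401 x n_patch")
  n <- ncol(R)
  mean_spec <- rowMeans(R)
  Xc <- R - mean_spec
  sv <- svd(Xc)
  ev <- sv$d^2
  total <- sum(ev)
  if (total < 1e-20) {
    k <- 0L
    variance_retained <- 1
    basis <- matrix(0, nrow = 0, ncol = N_BANDS)
  } else {
    cumvar <- cumsum(ev) / total
    k <- which(cumvar >= variance_threshold)[1]
    variance_retained <- cumvar[k]
    basis <- t(sv$u[, seq_len(k), drop = FALSE])   # k x 401
  }
  xyz_cam <- chart_camera_xyz(chart, transfer, primaries)
  xyz_cor <- apply_correction(calib, xyz_cam)
  V <- expand_variables(xyz_cor, terms)            # n x n_terms

  pinv_fit <- function(A, B) {                     # min-norm solve A W' = B
    s <- svd(A)
    tol <- max(dim(A)) * max(s$d, 0) * .Machine$double.eps
    dinv <- ifelse(s$d > tol, 1 / s$d, 0)
    s$v %*% (dinv * (t(s$u) %*% B))
  }
  if (direct) {
    spec_map <- t(pinv_fit(V, t(Xc)))              # 401 x n_terms
    score_map <- NULL
    fitted <- mean_spec + spec_map %*% t(V)
  } else {
    spec_map <- NULL
    if (k > 0) {
      scores <- basis %*% Xc                       # k x n
      score_map <- t(pinv_fit(V, t(scores)))       # k x n_terms
      fitted <- mean_spec + t(basis) %*% (score_map %*% t(V))
    } else {
      score_map <- matrix(0, nrow = 0, ncol = ncol(V))
      fitted <- matrix(mean_spec, N_BANDS, n)
    }
  }
  train_rmse <- sqrt(colMeans((fitted - R)^2))
  structure(list(
    mean_spectrum = mean_spec, basis = basis, score_map = score_map,
    spec_map = spec_map, direct = direct, k = k,
    variance_retained = variance_retained, eigenvalues = ev,
    terms = terms, transfer = transfer, primaries = primaries,
    train_rmse = train_rmse), class = "savehsi_recon")
}

#' @export
print.savehsi_recon <- function(x, ...) {
  cat(sprintf("Spectral reconstruction model: %d principal component(s), %.3f%% variance retained\n",
              x$k, 100 * x$variance_retained))
  cat(sprintf("  training spectral RMSE: mean %.4g, max %.4g\n",
              mean(x$train_rmse), max(x$train_rmse)))
  invisible(x)
}

# internal: spectra (rows) from a matrix of sRGB rows
reconstruct_rows <- function(model, calib, rgb_rows) {
  xyz <- linear_rgb_to_xyz(srgb_decode(rgb_rows, model$transfer),
                           model$primaries)
  xyz <- apply_correction(calib, xyz)
  V <- expand_variables(xyz, model$terms)          # n x n_terms
  centred <- if (model$direct) {
    V %*% t(model$spec_map)
  } else if (model$k > 0) {
    (V %*% t(model$score_map)) %*% model$basis
  } else {
    matrix(0, nrow(V), N_BANDS)
  }
  spec <- sweep(centred, 2, model$mean_spectrum, "+")
  n_clip <- sum(spec < 0 | spec > 1.05)
  if (n_clip > 0)
    log_event("reconstruct: clipped %d reflectance value(s) to [0, 1.05]", n_clip)
  spec <- pmin(pmax(spec, 0), 1.05)
  attr(spec, "n_clipped") <- n_clip
  spec
}

#' Reconstruct a reflectance spectrum from one RGB colour
#'
#' Runs the full per-pixel chain: sRGB decode, camera XYZ, polynomial
#' correction, variable expansion, regression to principal-component scores,
#' and expansion against the PCA basis. Output reflectance is clipped to
#' \[0, 1.05\].
#'
#' @param model Fitted [fit_reconstruction()] model.
#' @param calib Fitted [fit_correction()] model.
#' @param rgb Length-3 sRGB vector in \[0, 1\].
#' @return Numeric vector of 401 reflectance samples.
#' @export
reconstruct_spectrum <- function(model, calib, rgb) {
  if (!inherits(model, "savehsi_recon")) stop("model is not a fitted reconstruction")
  if (length(rgb) != 3) stop("rgb must be a length-3 colour")
  spec <- reconstruct_rows(model, calib, matrix(rgb, nrow = 1))
  structure(as.numeric(spec), n_clipped = attr(spec, "n_clipped"))
}

#' Construct a hyperspectral cube object
#'
#' @param data H x W x 401 numeric array of reflectance values.
#' @return A `savehsi_cube` with the package wavelength grid attached.
#' @export
spectral_cube <- function(data) {
  if (length(dim(data)) != 3 || dim(data)[3] != N_BANDS)
    stop(sprintf("cube data must be H x W x %d", N_BANDS))
  if (any(!is.finite(data))) stop("cube data must be finite")
  structure(list(data = data, wavelengths = spectral_grid()),
            class = "savehsi_cube")
}

#' @export
print.savehsi_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Hyperspectral cube: %d x %d pixels, %d bands (380-780 nm)\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Convert an RGB frame into a hyperspectral cube
#'
#' Applies [reconstruct_spectrum()] to every pixel. Distinct RGB triples are
#' memoised: an 8-bit frame has at most 2^24 distinct colours and typically
#' far fewer, so each distinct colour's spectrum is computed once — results
#' are identical to the unmemoised path.
#'
#' @param model Fitted [fit_reconstruction()] model.
#' @param calib Fitted [fit_correction()] model.
#' @param frame H x W x 3 array of sRGB values in \[0, 1\] (e.g. from
#'   [read_frame()]).
#' @return A `savehsi_cube` of H x W x 401 reflectances.
#' @export
convert_image <- function(model, calib, frame) {
  d <- dim(frame)
  if (length(d) != 3 || d[3] != 3) stop("frame must be an H x W x 3 RGB array")
  if (d[1] < 1 || d[2] < 1) stop("frame has no pixels")
  px <- cbind(as.vector(frame[, , 1]), as.vector(frame[, , 2]),
              as.vector(frame[, , 3]))
  key <- paste(px[, 1], px[, 2], px[, 3])
  idx <- match(key, unique(key))
  uniq <- px[!duplicated(key), , drop = FALSE]
  spec_u <- reconstruct_rows(model, calib, uniq)   # n_uniq x 401
  cube <- array(spec_u[idx, ], dim = c(d[1], d[2], N_BANDS))
  spectral_cube(cube)
}
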