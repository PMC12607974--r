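# Colour-space conversions and colour-difference scoring.
#
# All spectral quantities live on a fixed 401-sample wavelength grid,
# 380-780 nm at 1 nm. Tristimulus values use an internal scale on which the
# reference white has Y = 100.

#' The package wavelength grid
#'
#' All spectra handled by this package are sampled on a common grid of 401
#' wavelengths, 380 to 780 nm in 1 nm steps.
#'
#' @return Integer vector of 401 wavelengths in nanometres.
#' @export
spectral_grid <- function() 380:780

N_BANDS <- 401L

# internal: validate that a wavelength vector is the package grid
check_grid <- function(wl, what = "wavelengths") {
  if (length(wl) != N_BANDS || any(wl != spectral_grid()))
    stop(sprintf("%s must be the 401-sample grid 380:780 nm", what))
  invisible(TRUE)
}

# internal: lightweight event log, silent unless option set
log_event <- function(fmt, ...) {
  if (isTRUE(getOption("savehsi.verbose", FALSE)))
    message(sprintf(fmt, ...))
  invisible(NULL)
}

#' Decode nonlinear sRGB values to linear RGB
#'
#' Applies the piecewise sRGB electro-optical transfer function (the "gamma"
#' linearisation step of the pipeline). Inputs are display-referred values in
#' \[0, 1\]; 8-bit images must be divided by 255 before calling.
#'
#' @param rgb Numeric vector or matrix of sRGB components in \[0, 1\].
#'   Matrices are treated component-wise (columns R, G, B).
#' @param transfer Either `"srgb"` (default, piecewise standard curve) or a
#'   single number giving a pure-power gamma exponent.
#' @return Linear RGB values, same shape as the input, in \[0, 1\].
#' @export
#' @examples
#' srgb_decode(c(0, 0.5, 1))
srgb_decode <- function(rgb, transfer = "srgb") {
  x <- as.numeric(rgb)
  bad <- which(x < 0 | x > 1 | !is.finite(x))
  if (length(bad)) {
    ch <- c("R", "G", "B")[((bad - 1L) %% 3L) + 1L]
    stop(sprintf("sRGB component out of [0,1] (channel %s, value %g)",
                 ch[1], x[bad[1]]))
  }
  out <- if (identical(transfer, "srgb")) {
    ifelse(x <= 0.04045, x / 12.92, ((x + 0.055) / 1.055)^2.4)
  } else {
    gamma <- as.numeric(transfer)
    if (!is.finite(gamma) || gamma <= 0) stop("gamma exponent must be > 0")
    x^gamma
  }
  attributes(out) <- attributes(rgb)
  out
}

#' Encode linear RGB to nonlinear sRGB
#'
#' Inverse of [srgb_decode()].
#'
#' @inheritParams srgb_decode
#' @param rgb Linear RGB values in \[0, 1\] (values are clipped to \[0, 1\]
#'   before encoding).
#' @return Display-referred sRGB values in \[0, 1\].
#' @export
srgb_encode <- function(rgb, transfer = "srgb") {
  x <- pmin(pmax(as.numeric(rgb), 0), 1)
  out <- if (identical(transfer, "srgb")) {
    ifelse(x <= 0.0031308, 12.92 * x, 1.055 * x^(1 / 2.4) - 0.055)
  } else {
    gamma <- as.numeric(transfer)
    x^(1 / gamma)
  }
  attributes(out) <- attributes(rgb)
  out
}

#' Standard sRGB to CIE XYZ primary matrix (D65 white)
#'
#' @return 3x3 matrix mapping linear sRGB (columns) to XYZ rows, on a scale
#'   where the white point has Y = 1 (multiply by 100 for the internal scale).
#' @export
srgb_primaries <- function() {
  matrix(c(0.4124564, 0.3575761, 0.1804375,
           0.2126729, 0.7151522, 0.0721750,
           0.0193339, 0.1191920, 0.9503041),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("X", "Y", "Z"), c("R", "G", "B")))
}

#' Convert linear RGB to CIE XYZ tristimulus values
#'
#' Linear map through a primaries matrix; by default the standard sRGB
#' matrix, so (1, 1, 1) maps to the D65 white point with Y = 100.
#'
#' @param lin Length-3 linear RGB vector, or an n x 3 matrix of rows.
#' @param primaries 3x3 matrix mapping linear RGB to XYZ (white Y = 1 scale).
#' @return XYZ values on the internal Y = 100 scale (vector or n x 3 matrix).
#' @export
linear_rgb_to_xyz <- function(lin, primaries = srgb_primaries()) {
  if (!is.matrix(primaries) || any(dim(primaries) != 3) ||
      !all(is.finite(primaries)) || abs(det(primaries)) < 1e-12)
    stop("primaries must be a finite, non-singular 3x3 matrix")
  if (is.matrix(lin)) {
    if (ncol(lin) != 3) stop("linear RGB matrix must have 3 columns")
    out <- 100 * (lin %*% t(primaries))
    colnames(out) <- c("X", "Y", "Z")
    out
  } else {
    if (length(lin) != 3) stop("linear RGB must have 3 components")
    out <- 100 * as.numeric(primaries %*% lin)
    names(out) <- c("X", "Y", "Z")
    out
  }
}

#' Inverse of [linear_rgb_to_xyz()]
#'
#' @param xyz XYZ values on the internal Y = 100 scale.
#' @inheritParams linear_rgb_to_xyz
#' @return Linear RGB values.
#' @export
xyz_to_linear_rgb <- function(xyz, primaries = srgb_primaries()) {
  inv <- solve(primaries)
  if (is.matrix(xyz)) (xyz / 100) %*% t(inv) else as.numeric(inv %*% (xyz / 100))
}

#' The piecewise cube-root function used by the Lab conversion
#'
#' For ratios above the standard CIE threshold 0.008856 the function is the
#' cube root; below it, the linear branch 7.787 n + 0.137931. The two
#' branches agree at the threshold to about 1e-4.
#'
#' @param n Numeric vector of tristimulus ratios.
#' @return f(n), same length as `n`.
#' @export
lab_f <- function(n) {
  stopifnot(all(is.finite(n)))
  ifelse(n > 0.008856, sign(n) * abs(n)^(1 / 3), 7.787 * n + 0.137931)
}

# inverse of lab_f (exact on both branches)
lab_f_inv <- function(fn) {
  thr <- lab_f(0.008856)
  ifelse(fn > thr, fn^3, (fn - 0.137931) / 7.787)
}

#' Convert XYZ to CIELAB
#'
#' L* = 116 f(Y/Yn) - 16, a* = 500 (f(X/Xn) - f(Y/Yn)),
#' b* = 200 (f(Y/Yn) - f(Z/Zn)), with f the piecewise [lab_f()].
#' Slightly negative L* arising from near-zero input on the linear branch is
#' clamped to 0 (reflective imagery cannot be darker than black); clamps are
#' counted in the `"n_clamped"` attribute.
#'
#' @param xyz Length-3 XYZ vector or n x 3 matrix, internal Y = 100 scale.
#' @param white Length-3 reference white (Xn, Yn, Zn), all positive,
#'   Yn = 100. Defaults to D65.
#' @return Lab values (vector or n x 3 matrix with columns L, a, b).
#' @export
xyz_to_lab <- function(xyz, white = white_point_d65()) {
  if (length(white) != 3 || any(!is.finite(white)) || any(white <= 0))
    stop("white point must be three positive tristimulus values")
  m <- if (is.matrix(xyz)) xyz else matrix(xyz, nrow = 1)
  if (ncol(m) != 3) stop("XYZ input must have 3 components")
  fx <- lab_f(m[, 1] / white[1])
  fy <- lab_f(m[, 2] / white[2])
  fz <- lab_f(m[, 3] / white[3])
  L <- 116 * fy - 16
  n_clamped <- sum(L < 0)
  if (n_clamped > 0) {
    log_event("xyz_to_lab: clamped %d negative L* value(s) to 0", n_clamped)
    L <- pmax(L, 0)
  }
  out <- cbind(L = L, a = 500 * (fx - fy), b = 200 * (fy - fz))
  if (!is.matrix(xyz)) {
    out <- structure(as.numeric(out), names = c("L", "a", "b"))
  }
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Convert CIELAB back to XYZ
#'
#' Exact inverse of [xyz_to_lab()] away from the L* clamp.
#'
#' @param lab Length-3 Lab vector or n x 3 matrix.
#' @inheritParams xyz_to_lab
#' @return XYZ values on the internal scale.
#' @export
lab_to_xyz <- function(lab, white = white_point_d65()) {
  m <- if (is.matrix(lab)) lab else matrix(lab, nrow = 1)
  fy <- (m[, 1] + 16) / 116
  fx <- fy + m[, 2] / 500
  fz <- fy - m[, 3] / 200
  out <- cbind(X = lab_f_inv(fx) * white[1],
               Y = lab_f_inv(fy) * white[2],
               Z = lab_f_inv(fz) * white[3])
  if (!is.matrix(lab)) out <- structure(as.numeric(out), names = c("X", "Y", "Z"))
  out
}

#' D65 white point on the internal scale
#' @return c(Xn, Yn, Zn) with Yn = 100.
#' @export
white_point_d65 <- function() c(Xn = 95.047, Yn = 100, Zn = 108.883)

#' CIEDE2000 colour difference
#'
#' The standard perceptual colour-difference formula between two CIELAB
#' colours, including the lightness, chroma and hue weighting functions and
#' the blue-region rotation term. Symmetric, nonnegative, and zero exactly
#' when the inputs are equal.
#'
#' @param lab1,lab2 Length-3 Lab vectors, or n x 3 matrices compared row-wise.
#' @param kL,kC,kH Parametric weighting factors (default 1).
#' @return Numeric vector of colour differences.
#' @export
#' @examples
#' ciede2000(c(50, 2.6772, -79.7751), c(50, 0, -82.7485))  # ~2.04
ciede2000 <- function(lab1, lab2, kL = 1, kC = 1, kH = 1) {
  m1 <- if (is.matrix(lab1)) lab1 else matrix(lab1, nrow = 1)
  m2 <- if (is.matrix(lab2)) lab2 else matrix(lab2, nrow = 1)
  if (ncol(m1) != 3 || ncol(m2) != 3 || nrow(m1) != nrow(m2))
    stop("Lab inputs must be length-3 vectors or matching n x 3 matrices")
  L1 <- m1[, 1]; a1 <- m1[, 2]; b1 <- m1[, 3]
  L2 <- m2[, 1]; a2 <- m2[, 2]; b2 <- m2[, 3]

  C1 <- sqrt(a1^2 + b1^2); C2 <- sqrt(a2^2 + b2^2)
  Cbar <- (C1 + C2) / 2
  G <- 0.5 * (1 - sqrt(Cbar^7 / (Cbar^7 + 25^7)))
  ap1 <- (1 + G) * a1; ap2 <- (1 + G) * a2
  Cp1 <- sqrt(ap1^2 + b1^2); Cp2 <- sqrt(ap2^2 + b2^2)

  hp <- function(ap, b) {
    h <- atan2(b, ap) * 180 / pi
    ifelse(ap == 0 & b == 0, 0, ifelse(h < 0, h + 360, h))
  }
  hp1 <- hp(ap1, b1); hp2 <- hp(ap2, b2)

  dLp <- L2 - L1
  dCp <- Cp2 - Cp1
  dh <- hp2 - hp1
  dhp <- ifelse(Cp1 * Cp2 == 0, 0,
                ifelse(abs(dh) <= 180, dh, ifelse(dh > 180, dh - 360, dh + 360)))
  dHp <- 2 * sqrt(Cp1 * Cp2) * sin(dhp / 2 * pi / 180)

  Lbp <- (L1 + L2) / 2
  Cbp <- (Cp1 + Cp2) / 2
  hsum <- hp1 + hp2
  habs <- abs(hp1 - hp2)
  hbp <- ifelse(Cp1 * Cp2 == 0, hsum,
         ifelse(habs <= 180, hsum / 2,
         ifelse(hsum < 360, (hsum + 360) / 2, (hsum - 360) / 2)))

  Tt <- 1 - 0.17 * cos((hbp - 30) * pi / 180) +
        0.24 * cos(2 * hbp * pi / 180) +
        0.32 * cos((3 * hbp + 6) * pi / 180) -
        0.20 * cos((4 * hbp - 63) * pi / 180)
  dtheta <- 30 * exp(-(((hbp - 275) / 25)^2))
  RC <- 2 * sqrt(Cbp^7 / (Cbp^7 + 25^7))
  SL <- 1 + 0.015 * (Lbp - 50)^2 / sqrt(20 + (Lbp - 50)^2)
  SC <- 1 + 0.045 * Cbp
  SH <- 1 + 0.015 * Cbp * Tt
  RT <- -sin(2 * dtheta * pi / 180) * RC

  sqrt((dLp / (kL * SL))^2 + (dCp / (kC * SC))^2 + (dHp / (kH * SH))^2 +
       RT * (dCp / (kC * SC)) * (dHp / (kH * SH)))
}

# ---- illuminants and colour-matching functions --------------------------

# piecewise Gaussian lobe used by the analytic CMF fit
cmf_lobe <- function(x, mu, s1, s2) {
  s <- ifelse(x < mu, s1, s2)
  exp(-0.5 * ((x - mu) / s)^2)
}

#' CIE 1931 2-degree colour-matching functions (analytic fit)
#'
#' Multi-lobe Gaussian approximation to the CIE 1931 standard observer on the
#' package wavelength grid. Accurate to a few percent of peak, which is ample
#' for the synthetic closed-loop experiments in this package; measured CMF
#' tables can be supplied through [read_cmf()] instead.
#'
#' @return List with `wavelengths` and nonnegative `xbar`, `ybar`, `zbar`,
#'   each of length 401.
#' @export
cmf_cie1931 <- function() {
  wl <- spectral_grid()
  xbar <- 1.056 * cmf_lobe(wl, 599.8, 37.9, 31.0) +
          0.362 * cmf_lobe(wl, 442.0, 16.0, 26.7) -
          0.065 * cmf_lobe(wl, 501.1, 20.4, 26.2)
  ybar <- 0.821 * cmf_lobe(wl, 568.8, 46.9, 40.5) +
          0.286 * cmf_lobe(wl, 530.9, 16.3, 31.1)
  zbar <- 1.217 * cmf_lobe(wl, 437.0, 11.8, 36.0) +
          0.681 * cmf_lobe(wl, 459.0, 26.0, 13.8)
  list(wavelengths = wl, xbar = pmax(xbar, 0), ybar = pmax(ybar, 0),
       zbar = pmax(zbar, 0))
}

#' Equal-energy illuminant
#'
#' Flat spectral power on the package grid. The neutral default when the
#' endoscope light-source spectrum has not been measured.
#'
#' @return List with `wavelengths` and `power` (401 samples).
#' @export
illuminant_e <- function() {
  list(wavelengths = spectral_grid(), power = rep(1, N_BANDS))
}

#' Phosphor-LED style illuminant
#'
#' Two-Gaussian model of a phosphor-converted white LED (narrow blue pump
#' plus broad phosphor emission), a realistic stand-in for a modern scope
#' light source in synthetic experiments.
#'
#' @param blue_peak,phosphor_peak Centre wavelengths in nm.
#' @param blue_sd,phosphor_sd Gaussian widths in nm.
#' @param blue_weight Relative height of the blue pump.
#' @return List with `wavelengths` and `power`.
#' @export
illuminant_led <- function(blue_peak = 450, phosphor_peak = 560,
                           blue_sd = 12, phosphor_sd = 60, blue_weight = 0.8) {
  wl <- spectral_grid()
  p <- blue_weight * exp(-0.5 * ((wl - blue_peak) / blue_sd)^2) +
       exp(-0.5 * ((wl - phosphor_peak) / phosphor_sd)^2)
  list(wavelengths = wl, power = p)
}

#' White point implied by an illuminant and colour-matching functions
#'
#' XYZ of a perfect reflector under the given illuminant, normalised so
#' Y = 100 (the internal scale).
#'
#' @param ill Illuminant list (see [illuminant_e()]).
#' @param cmf Colour-matching function list (see [cmf_cie1931()]).
#' @return Length-3 white point (Xn, Yn, Zn), Yn = 100.
#' @export
white_point_from <- function(ill = illuminant_e(), cmf = cmf_cie1931()) {
  render_spectrum(rep(1, N_BANDS), ill, cmf)
}

#' Read an illuminant from a plain-text table
#'
#' Expects a two-column whitespace- or comma-separated table (wavelength in
#' nm, spectral power), 401 rows on the package grid.
#'
#' @param path File path.
#' @return Illuminant list.
#' @export
read_illuminant <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "", comment.char = "#")
  if (ncol(tab) == 1) tab <- utils::read.csv(path)
  if (ncol(tab) < 2) stop("illuminant table needs wavelength and power columns")
  check_grid(tab[[1]], "illuminant wavelengths")
  if (any(tab[[2]] < 0)) stop("illuminant power must be nonnegative")
  list(wavelengths = as.integer(tab[[1]]), power = as.numeric(tab[[2]]))
}

#' Write an illuminant as a plain-text table
#' @param ill Illuminant list.
#' @param path File path.
#' @export
write_illuminant <- function(ill, path) {
  utils::write.table(data.frame(wavelength = ill$wavelengths, power = ill$power),
                     path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read colour-matching functions from a plain-text table
#'
#' Four columns: wavelength, xbar, ybar, zbar; 401 rows on the package grid.
#'
#' @param path File path.
#' @return CMF list as returned by [cmf_cie1931()].
#' @export
read_cmf <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "", comment.char = "#")
  if (ncol(tab) == 1) tab <- utils::read.csv(path)
  if (ncol(tab) < 4) stop("CMF table needs wavelength, xbar, ybar, zbar columns")
  check_grid(tab[[1]], "CMF wavelengths")
  if (any(tab[[2]] < 0 | tab[[3]] < 0 | tab[[4]] < 0))
    stop("CMF weights must be nonnegative")
  list(wavelengths = as.integer(tab[[1]]), xbar = as.numeric(tab[[2]]),
       ybar = as.numeric(tab[[3]]), zbar = as.numeric(tab[[4]]))
}

#' Write colour-matching functions as a plain-text table
#' @param cmf CMF list.
#' @param path File path.
#' @export
write_cmf <- function(cmf, path) {
  utils::write.table(data.frame(wavelength = cmf$wavelengths, xbar = cmf$xbar,
                                ybar = cmf$ybar, zbar = cmf$zbar),
                     path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
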