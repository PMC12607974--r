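# Image- and spectrum-agreement scores: SSIM, PSNR, spectral RMSE.

# internal: separable "valid" convolution of a matrix with a 1-D kernel
conv_valid <- function(m, kern) {
  n <- length(kern)
  rows_out <- nrow(m) - n + 1L
  cols_out <- ncol(m) - n + 1L
  if (rows_out < 1 || cols_out < 1)
    stop("image smaller than the filter window")
  tmp <- matrix(0, rows_out, ncol(m))
  for (i in seq_len(n)) tmp <- tmp + kern[i] * m[i:(i + rows_out - 1L), , drop = FALSE]
  out <- matrix(0, rows_out, cols_out)
  for (j in seq_len(n)) out <- out + kern[j] * tmp[, j:(j + cols_out - 1L), drop = FALSE]
  out
}

#' Structural similarity index (SSIM)
#'
#' Mean SSIM between two single-channel images, computed with a Gaussian
#' sliding window (default 11 x 11, sigma 1.5) and the standard stability
#' constants C1 = (K1 L)^2, C2 = (K2 L)^2 for dynamic range L. Local
#' statistics are taken over the interior (fully-covered) windows.
#'
#' @param a,b Numeric matrices of the same dimensions.
#' @param dynamic_range Value range L of the data (default 1 for reflectance
#'   or unit-scaled images).
#' @param window Window side length (odd, default 11).
#' @param sigma Gaussian window standard deviation (default 1.5).
#' @param K1,K2 Stability constants (defaults 0.01, 0.03).
#' @return Scalar mean SSIM in \[-1, 1\]; 1 for identical images.
#' @export
ssim <- function(a, b, dynamic_range = 1, window = 11, sigma = 1.5,
                 K1 = 0.01, K2 = 0.03) {
  if (!is.matrix(a) || !is.matrix(b) || any(dim(a) != dim(b)))
    stop("SSIM inputs must be matrices with identical dimensions")
  if (window %% 2 != 1 || window < 3) stop("window must be an odd size >= 3")
  half <- (window - 1) / 2
  kern <- exp(-0.5 * ((-half:half) / sigma)^2)
  kern <- kern / sum(kern)
  C1 <- (K1 * dynamic_range)^2
  C2 <- (K2 * dynamic_range)^2
  mu_a <- conv_valid(a, kern)
  mu_b <- conv_valid(b, kern)
  var_a <- conv_valid(a * a, kern) - mu_a^2
  var_b <- conv_valid(b * b, kern) - mu_b^2
  cov_ab <- conv_valid(a * b, kern) - mu_a * mu_b
  num <- (2 * mu_a * mu_b + C1) * (2 * cov_ab + C2)
  den <- (mu_a^2 + mu_b^2 + C1) * (var_a + var_b + C2)
  mean(num / den)
}

#' Peak signal-to-noise ratio (PSNR)
#'
#' 10 log10(peak^2 / MSE) in decibels; identical inputs (MSE = 0) return
#' `Inf`.
#'
#' @param a,b Numeric arrays of the same dimensions.
#' @param peak Dynamic range of the data (default 1).
#' @return PSNR in dB (`Inf` when the images are identical).
#' @export
psnr <- function(a, b, peak = 1) {
  if (!identical(dim(a), dim(b)) || length(a) != length(b))
    stop("PSNR inputs must have identical dimensions")
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Root-mean-square error between two reflectance spectra
#'
#' @param est,ref Numeric vectors of 401 reflectance samples on the package
#'   grid (any equal length is accepted for generality).
#' @return Nonnegative scalar; 0 iff the spectra are equal.
#' @export
spectral_rmse <- function(est, ref) {
  if (length(est) != length(ref))
    stop("spectra must share the same wavelength grid")
  sqrt(mean((est - ref)^2))
}

#' Full agreement report between two images
#'
#' @inheritParams ssim
#' @param peak Dynamic range for PSNR.
#' @return A `quality_report` list with `ssim`, `psnr` (dB, `Inf` flag for
#'   identical inputs) and `rmse` fields.
#' @export
quality_report <- function(a, b, dynamic_range = 1, peak = dynamic_range) {
  structure(list(ssim = ssim(a, b, dynamic_range),
                 psnr = psnr(a, b, peak),
                 rmse = sqrt(mean((a - b)^2))),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("SSIM %.4f | PSNR %s dB | RMSE %.5f\n", x$ssim,
              if (is.infinite(x$psnr)) "Inf" else sprintf("%.2f", x$psnr),
              x$rmse))
  invisible(x)
}
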