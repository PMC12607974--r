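# Eigenvector-based band selection and simulated narrow-band imaging.

#' Score and select informative spectral bands
#'
#' Per-band contribution scores are the variance-weighted sums of squared
#' principal-component loadings: score(l) = sum_j lambda_j * u_j(l)^2, the
#' standard eigenvector loading analysis of the spectral covariance. Bands
#' are then picked greedily by descending score, enforcing a minimum
#' wavelength separation so the selection spreads across distinct spectral
#' features rather than clustering on one peak.
#'
#' @param model Fitted [fit_reconstruction()] model with k >= 1 components.
#' @param n_bands Number of bands to select (1-401).
#' @param min_separation_nm Minimum spacing between selected bands in nm
#'   (default 10; set 0 to disable).
#' @return A `savehsi_bands` object: data frame with `index` (1-based
#'   position on the grid), `wavelength_nm` and `score`, sorted by index,
#'   plus the full score vector as an attribute.
#' @export
select_bands <- function(model, n_bands, min_separation_nm = 10) {
  if (!inherits(model, "savehsi_recon")) stop("model is not a fitted reconstruction")
  if (model$k < 1) stop("band selection needs a model with at least 1 component")
  if (n_bands < 1 || n_bands > N_BANDS)
    stop(sprintf("n_bands must be between 1 and %d", N_BANDS))
  lambda <- model$eigenvalues[seq_len(model$k)]
  scores <- colSums(lambda * model$basis^2)        # length 401, nonnegative
  wl <- spectral_grid()
  chosen <- integer(0)
  ord <- order(scores, decreasing = TRUE)
  for (i in ord) {
    if (length(chosen) >= n_bands) break
    if (min_separation_nm <= 0 ||
        all(abs(wl[i] - wl[chosen]) >= min_separation_nm))
      chosen <- c(chosen, i)
  }
  if (length(chosen) < n_bands) {
    log_event("select_bands: only %d bands satisfy the %g nm separation",
              length(chosen), min_separation_nm)
  }
  chosen <- sort(chosen)
  structure(data.frame(index = chosen, wavelength_nm = wl[chosen],
                       score = scores[chosen]),
            scores = scores, method = "variance-weighted squared loadings",
            class = c("savehsi_bands", "data.frame"))
}

#' Extract a narrow-band image from a hyperspectral cube
#'
#' Gaussian-weighted average of the cube's bands around a centre wavelength;
#' the FWHM sets the filter width and the weights are normalised to sum to
#' one, so a spectrally flat cube returns its flat value unchanged.
#'
#' @param cube A `savehsi_cube`.
#' @param center_nm Filter centre wavelength (within 380-780 nm).
#' @param fwhm_nm Full width at half maximum of the Gaussian window, > 0.
#' @return H x W matrix of band reflectance values in \[0, 1.05\].
#' @export
extract_band_image <- function(cube, center_nm, fwhm_nm = 30) {
  if (!inherits(cube, "savehsi_cube")) stop("cube must be a savehsi_cube")
  wl <- cube$wavelengths
  if (center_nm < min(wl) || center_nm > max(wl))
    stop("filter centre must lie within the 380-780 nm grid")
  if (fwhm_nm <= 0) stop("FWHM must be > 0")
  sigma <- fwhm_nm / (2 * sqrt(2 * log(2)))
  w <- exp(-0.5 * ((wl - center_nm) / sigma)^2)
  w <- w / sum(w)
  d <- dim(cube$data)
  flat <- matrix(cube$data, nrow = d[1] * d[2])    # pixels x bands
  matrix(flat %*% w, nrow = d[1], ncol = d[2])
}

#' Narrow-band imaging filter specification
#'
#' Defaults follow the physics of clinical narrow-band imaging: illumination
#' restricted to 415 nm (blue, surface capillaries) and 540 nm (green,
#' submucosal vessels), both haemoglobin absorption bands. The mixing matrix
#' maps the two band images to display RGB; the default feeds display green
#' and blue from the 415 nm image and display red from the 540 nm image,
#' scaled so a spectrally flat scene renders neutral — reproducing the
#' brown-surface / cyan-deep rendering convention.
#'
#' @param centers_nm Two filter centres in nm.
#' @param fwhm_nm Two FWHM values in nm.
#' @param mixing 3 x 2 matrix mapping c(band415, band540) to display R, G, B.
#' @return An `nbi_spec` list.
#' @export
nbi_spec <- function(centers_nm = c(415, 540), fwhm_nm = c(30, 30),
                     mixing = matrix(c(0, 1,
                                       1, 0,
                                       1, 0), nrow = 3, byrow = TRUE)) {
  if (length(centers_nm) != 2 || any(centers_nm < 380 | centers_nm > 780))
    stop("NBI centres must be two wavelengths within 380-780 nm")
  if (length(fwhm_nm) != 2 || any(fwhm_nm <= 0)) stop("FWHM values must be > 0")
  if (!is.matrix(mixing) || any(dim(mixing) != c(3, 2)))
    stop("mixing must be a 3 x 2 matrix")
  structure(list(centers_nm = centers_nm, fwhm_nm = fwhm_nm, mixing = mixing),
            class = "nbi_spec")
}

#' Simulate a narrow-band image from a hyperspectral cube
#'
#' Extracts the two narrow-band images, mixes them into display RGB channels
#' through the spec's mixing matrix, and applies the display transfer
#' function. Deterministic; a flat spectrum renders channel-equal (neutral)
#' under the default mixing.
#'
#' @param cube A `savehsi_cube` (e.g. from [convert_image()]).
#' @param spec An [nbi_spec()].
#' @return H x W x 3 display-referred RGB array in \[0, 1\].
#' @export
simulate_nbi <- function(cube, spec = nbi_spec()) {
  if (!inherits(spec, "nbi_spec")) stop("spec must be an nbi_spec")
  b1 <- extract_band_image(cube, spec$centers_nm[1], spec$fwhm_nm[1])
  b2 <- extract_band_image(cube, spec$centers_nm[2], spec$fwhm_nm[2])
  d <- dim(b1)
  bands <- rbind(as.vector(b1), as.vector(b2))     # 2 x pixels
  disp <- spec$mixing %*% bands                    # 3 x pixels
  out <- array(0, dim = c(d[1], d[2], 3))
  for (ch in 1:3)
    out[, , ch] <- srgb_encode(matrix(pmin(pmax(disp[ch, ], 0), 1), d[1], d[2]))
  out
}

#' Write a band selection as CSV
#' @param bands A `savehsi_bands` object.
#' @param path Output CSV path.
#' @export
write_bands <- function(bands, path) {
  utils::write.csv(as.data.frame(bands), path, row.names = FALSE)
  invisible(path)
}
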