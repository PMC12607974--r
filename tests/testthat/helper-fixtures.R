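# Shared fixtures: a fully imaged chart with fitted calibration and
# reconstruction, built once per seed on demand.

closed_loop_models <- function(seed = 1, noise_sd = 0, distortion = NULL) {
  cam <- synthetic_camera(noise_sd = noise_sd, distortion = distortion,
                          seed = seed)
  chart <- image_chart(make_chart(seed), cam)
  xyz_cam <- chart_camera_xyz(chart)
  calib <- fit_correction(chart, xyz_cam)
  recon <- fit_reconstruction(chart, calib)
  list(chart = chart, cam = cam, calib = calib, recon = recon)
}

# chart-like object around arbitrary reference spectra (401 x 24), imaged
# with a matched noiseless camera
chart_from_spectra <- function(R) {
  colnames(R) <- sprintf("patch%02d", seq_len(ncol(R)))
  chart <- structure(list(patch_ids = colnames(R), reflectance_ref = R,
                          xyz_target = render_spectrum(t(R)),
                          rgb_measured = NULL, ill = illuminant_e(),
                          cmf = cmf_cie1931(), mode = "custom", seed = NA),
                     class = "savehsi_chart")
  image_chart(chart, synthetic_camera())
}

luminance <- function(rgb_array) {
  0.2126 * rgb_array[, , 1] + 0.7152 * rgb_array[, , 2] +
    0.0722 * rgb_array[, , 3]
}
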