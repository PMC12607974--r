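# Format readers/writers, pipeline configuration and orchestration.
#
# Conventions: rasters are row-major with origin top-left; the cube band
# axis is last; cube files are an ENVI-style pair (text header + flat
# little-endian float32 binary, band-interleaved-by-pixel).

#' Read an RGB frame from a PNG file
#'
#' Grayscale input is replicated to 3 channels; an alpha channel is dropped.
#'
#' @param path PNG file path.
#' @return H x W x 3 array of sRGB values in \[0, 1\].
#' @export
read_frame <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] != 3) stop("frame must have 3 colour channels")
  img
}

#' Write an RGB frame to a PNG file
#' @param frame H x W x 3 array in \[0, 1\].
#' @param path Output path.
#' @export
write_frame <- function(frame, path) {
  png::writePNG(pmin(pmax(frame, 0), 1), path)
  invisible(path)
}

#' Write a hyperspectral cube as an ENVI-style pair
#'
#' Produces `<path>.hdr` (text header with samples/lines/bands, interleave
#' and the wavelength list) and `<path>.dat` (little-endian float32,
#' band-interleaved-by-pixel: all 401 bands of pixel (1,1), then pixel
#' (1,2), row-major).
#'
#' @param cube A `savehsi_cube`.
#' @param path Path stem (without extension).
#' @return The path stem, invisibly.
#' @export
write_cube <- function(cube, path) {
  if (!inherits(cube, "savehsi_cube")) stop("cube must be a savehsi_cube")
  d <- dim(cube$data)
  hdr <- c("ENVI",
           "description = {savehsi reflectance cube}",
           sprintf("samples = %d", d[2]),
           sprintf("lines = %d", d[1]),
           sprintf("bands = %d", d[3]),
           "header offset = 0", "file type = ENVI Standard",
           "data type = 4", "interleave = bip", "byte order = 0",
           "wavelength units = nm",
           paste0("wavelength = {", paste(cube$wavelengths, collapse = ", "), "}"))
  writeLines(hdr, paste0(path, ".hdr"))
  # BIP: bands fastest, then columns, then rows
  perm <- aperm(cube$data, c(3, 2, 1))
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(perm), con, size = 4, endian = "little")
  invisible(path)
}

# parse "key = value" lines of an ENVI header
parse_envi_header <- function(lines) {
  txt <- paste(lines, collapse = "\n")
  get1 <- function(key) {
    m <- regmatches(txt, regexec(paste0(key, "\\s*=\\s*([0-9]+)"), txt))[[1]]
    if (length(m) < 2) stop("cube header missing field: ", key)
    as.integer(m[2])
  }
  list(samples = get1("samples"), lines = get1("lines"), bands = get1("bands"))
}

#' Read a hyperspectral cube written by [write_cube()]
#'
#' @param path Path stem (without extension).
#' @return A `savehsi_cube`.
#' @export
read_cube <- function(path) {
  hdr <- parse_envi_header(readLines(paste0(path, ".hdr")))
  if (hdr$bands != N_BANDS)
    stop(sprintf("cube header declares %d bands; expected %d on the 380:780 nm grid",
                 hdr$bands, N_BANDS))
  n <- hdr$samples * hdr$lines * hdr$bands
  con <- file(paste0(path, ".dat"), "rb")
  on.exit(close(con))
  raw_vals <- readBin(con, numeric(), n = n, size = 4, endian = "little")
  if (length(raw_vals) != n) stop("cube data file is truncated")
  perm <- array(raw_vals, dim = c(hdr$bands, hdr$samples, hdr$lines))
  spectral_cube(aperm(perm, c(3, 2, 1)))
}

#' Write a colour chart as a directory of CSV tables
#'
#' `patches.csv` holds id, measured R, G, B and target X, Y, Z per patch;
#' `spectra.csv` holds wavelength plus one reflectance column per patch.
#'
#' @param chart A `savehsi_chart`.
#' @param dir Output directory.
#' @export
write_chart <- function(chart, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rgb <- if (is.null(chart$rgb_measured))
    matrix(NA_real_, length(chart$patch_ids), 3) else chart$rgb_measured
  patches <- data.frame(id = chart$patch_ids,
                        R = rgb[, 1], G = rgb[, 2], B = rgb[, 3],
                        X = chart$xyz_target[, 1], Y = chart$xyz_target[, 2],
                        Z = chart$xyz_target[, 3])
  utils::write.csv(patches, file.path(dir, "patches.csv"), row.names = FALSE)
  spectra <- data.frame(wavelength = spectral_grid(), chart$reflectance_ref,
                        check.names = FALSE)
  utils::write.csv(spectra, file.path(dir, "spectra.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a colour chart directory written by [write_chart()]
#'
#' @param dir Chart directory containing patches.csv and spectra.csv.
#' @param ill,cmf Rendering context to attach.
#' @return A `savehsi_chart`.
#' @export
read_chart <- function(dir, ill = illuminant_e(), cmf = cmf_cie1931()) {
  patches <- utils::read.csv(file.path(dir, "patches.csv"))
  if (nrow(patches) != 24)
    stop(sprintf("chart has %d patches; a calibration chart needs exactly 24",
                 nrow(patches)))
  spectra <- utils::read.csv(file.path(dir, "spectra.csv"), check.names = FALSE)
  check_grid(spectra[[1]], "chart spectra wavelengths")
  R <- as.matrix(spectra[, -1, drop = FALSE])
  if (ncol(R) != 24) stop("chart spectra table must have 24 patch columns")
  if (any(R < 0 | R > 1.05)) stop("chart reflectances must lie in [0, 1.05]")
  rgb <- as.matrix(patches[, c("R", "G", "B")])
  structure(list(patch_ids = as.character(patches$id), reflectance_ref = R,
                 xyz_target = as.matrix(patches[, c("X", "Y", "Z")]),
                 rgb_measured = if (anyNA(rgb)) NULL else rgb,
                 ill = ill, cmf = cmf, mode = "file", seed = NA),
            class = "savehsi_chart")
}

# ---- pipeline configuration ---------------------------------------------

default_config <- function() {
  list(seed = 1,
       out_dir = NULL,
       chart = list(mode = "random-smooth"),
       camera = list(noise_sd = 0, dark = 0),
       calibration = list(ridge = 0, standardize = FALSE, degree = 3),
       reconstruction = list(variance_threshold = 0.99),
       nbi = list(centers = c(415, 540), fwhm = c(30, 30)),
       phantom = list(class = "cancer", size = c(64, 64)),
       bands = list(n = 8, min_separation_nm = 10))
}

#' Validate a pipeline configuration
#'
#' Fills defaults and rejects unknown keys (top level and within sections)
#' before any computation runs.
#'
#' @param cfg A named list, or a path to a YAML/JSON config file.
#' @return The completed configuration list.
#' @export
pipeline_config <- function(cfg = list()) {
  if (is.character(cfg)) {
    cfg <- if (grepl("\\.json$", cfg)) jsonlite::read_json(cfg, simplifyVector = TRUE)
           else yaml::read_yaml(cfg)
  }
  def <- default_config()
  unknown <- setdiff(names(cfg), names(def))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (sec in names(cfg)) {
    if (is.list(def[[sec]]) && is.list(cfg[[sec]])) {
      bad <- setdiff(names(cfg[[sec]]), names(def[[sec]]))
      if (length(bad))
        stop(sprintf("unknown config key(s) in '%s': %s", sec,
                     paste(bad, collapse = ", ")))
      def[[sec]][names(cfg[[sec]])] <- cfg[[sec]]
    } else {
      def[[sec]] <- cfg[[sec]]
    }
  }
  if (is.null(def$out_dir)) stop("config must set out_dir")
  def
}

#' Run the full synthetic-to-evaluation pipeline
#'
#' Five stages with stable output names under the run directory:
#' `fixtures` (chart + camera), `calibrate` (polynomial correction),
#' `convert` (phantom frame to hyperspectral cube), `nbi` (simulated
#' narrow-band image + band selection), `evaluate` (spectral and image
#' quality scores). A `summary.json` records the package version, seed,
#' completed stages and an md5 checksum per output file; rerunning the same
#' configuration reproduces the checksums.
#'
#' @param cfg Configuration list or file path (see [pipeline_config()]).
#' @return Invisibly, the parsed summary list.
#' @export
run_pipeline <- function(cfg) {
  cfg <- pipeline_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  stages <- character(0)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    stages <<- c(stages, name)
    res
  }

  chart <- stage("fixtures", {
    cam <- synthetic_camera(noise_sd = cfg$camera$noise_sd,
                            dark = cfg$camera$dark, seed = cfg$seed)
    ch <- image_chart(make_chart(cfg$seed, cfg$chart$mode), cam)
    write_chart(ch, file.path(cfg$out_dir, "chart"))
    outputs <<- c(outputs, file.path(cfg$out_dir, "chart", "patches.csv"),
                  file.path(cfg$out_dir, "chart", "spectra.csv"))
    ch
  })

  calib <- stage("calibrate", {
    xyz_cam <- chart_camera_xyz(chart)
    m <- fit_correction(chart, xyz_cam,
                        terms = cubic_terms(cfg$calibration$degree),
                        ridge = cfg$calibration$ridge,
                        standardize = cfg$calibration$standardize)
    p <- file.path(cfg$out_dir, "calibration.json")
    write_calibration(m, p)
    outputs <<- c(outputs, p)
    m
  })

  converted <- stage("convert", {
    recon <- fit_reconstruction(chart, calib,
                                cfg$reconstruction$variance_threshold)
    ph <- make_phantom(cfg$seed, size = unlist(cfg$phantom$size),
                       class = cfg$phantom$class)
    cube <- convert_image(recon, calib, ph$frame)
    write_frame(ph$frame, file.path(cfg$out_dir, "frame_wli.png"))
    write_cube(cube, file.path(cfg$out_dir, "cube"))
    outputs <<- c(outputs, file.path(cfg$out_dir, "frame_wli.png"),
                  file.path(cfg$out_dir, "cube.hdr"),
                  file.path(cfg$out_dir, "cube.dat"))
    list(recon = recon, phantom = ph, cube = cube)
  })

  stage("nbi", {
    spec <- nbi_spec(unlist(cfg$nbi$centers), unlist(cfg$nbi$fwhm))
    nbi_img <- simulate_nbi(converted$cube, spec)
    write_frame(nbi_img, file.path(cfg$out_dir, "frame_nbi.png"))
    sel <- select_bands(converted$recon, cfg$bands$n,
                        cfg$bands$min_separation_nm)
    write_bands(sel, file.path(cfg$out_dir, "bands.csv"))
    outputs <<- c(outputs, file.path(cfg$out_dir, "frame_nbi.png"),
                  file.path(cfg$out_dir, "bands.csv"))
    NULL
  })

  stage("evaluate", {
    truth <- converted$phantom$cube$data
    est <- converted$cube$data
    per_pixel_rmse <- sqrt(apply((truth - est)^2, c(1, 2), mean))
    band_q <- quality_report(extract_band_image(converted$phantom$cube, 540),
                             extract_band_image(converted$cube, 540))
    metrics <- list(
      mean_spectral_rmse = mean(per_pixel_rmse),
      max_spectral_rmse = max(per_pixel_rmse),
      band540_ssim = band_q$ssim, band540_psnr = band_q$psnr,
      calibration_mean_de00_pre = calib$diagnostics$mean_de00_pre,
      calibration_mean_de00_post = calib$diagnostics$mean_de00_post,
      variance_retained = converted$recon$variance_retained)
    p <- file.path(cfg$out_dir, "metrics.json")
    jsonlite::write_json(metrics, p, auto_unbox = TRUE, digits = NA)
    outputs <<- c(outputs, p)
    NULL
  })

  checks <- tools::md5sum(outputs)
  summary <- list(package = "savehsi",
                  version = as.character(utils::packageVersion("savehsi")),
                  seed = cfg$seed, stages = stages,
                  checksums = as.list(checks))
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(summary)
}
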