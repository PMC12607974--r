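# Seeded synthetic generators: reflectance basis, colour charts, cameras,
# vascular phantoms and class-balanced datasets. Every generator is a pure
# function of its seed and parameters.

# run expr with a private, seeded RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

gauss <- function(wl, mu, sd) exp(-0.5 * ((wl - mu) / sd)^2)

#' The fixed low-dimensional reflectance basis of the synthetic world
#'
#' Natural and tissue reflectances are well approximated by a handful of
#' smooth components; the synthetic generators therefore draw every spectrum
#' from a fixed rank-3 affine family: a smooth mean curve plus three
#' unit-norm components. Component 1 is a haemoglobin-like absorber with
#' dips centred at 415 nm and 540 nm (a positive coefficient darkens those
#' bands); components 2 and 3 are broad smooth colour-variation curves.
#'
#' @return List with `mean` (length 401) and `basis` (401 x 3 matrix,
#'   unit-norm columns).
#' @export
reflectance_basis <- function() {
  wl <- spectral_grid()
  mean_spec <- 0.5 + 0.12 * gauss(wl, 620, 90) - 0.08 * gauss(wl, 450, 50)
  b1 <- -(0.9 * gauss(wl, 415, 20) + 0.7 * gauss(wl, 540, 25))  # absorber
  b2 <- gauss(wl, 480, 60) - gauss(wl, 650, 70)
  b3 <- gauss(wl, 720, 80) - 0.5 * gauss(wl, 500, 120)
  B <- cbind(b1, b2, b3)
  B <- sweep(B, 2, sqrt(colSums(B^2)), "/")
  list(mean = mean_spec, basis = B)
}

# coefficient box guaranteeing spectra stay inside [0, 1]:
# mean is within [0.42, 0.64]; worst-case basis excursion at these bounds
# keeps every spectrum in roughly [0.05, 0.95] (asserted in the generators)
COEF_BOX <- list(absorber = c(0, 1.6), c2 = c(-0.9, 0.9), c3 = c(-0.9, 0.9))

# spectra (401 x n) from a 3 x n coefficient matrix
spectra_from_coeffs <- function(coeffs) {
  rb <- reflectance_basis()
  s <- rb$mean + rb$basis %*% coeffs
  if (any(s < 0 | s > 1))
    stop("internal: synthetic spectrum left [0, 1]; coefficient box violated")
  s
}

#' Generate a synthetic 24-patch calibration chart
#'
#' `"random-smooth"` (default) draws 24 coefficient triples uniformly from
#' the admissible box of [reflectance_basis()], yielding smooth nonnegative
#' spectra in \[0, 1\]. `"standard"` returns a fixed deterministic 24-patch
#' layout spanning the same family (a synthetic stand-in for a measured
#' chart — it is not the X-Rite data). Target XYZ values are rendered from
#' the reference spectra under the supplied illuminant.
#'
#' @param seed Integer seed (ignored by `"standard"` mode).
#' @param mode `"random-smooth"` or `"standard"`.
#' @param ill,cmf Illuminant and colour-matching functions used for the
#'   target XYZ rendering.
#' @return A `savehsi_chart`: `patch_ids`, 401 x 24 `reflectance_ref`,
#'   24 x 3 `xyz_target`, `rgb_measured` (NULL until [image_chart()] is
#'   called), and the rendering context.
#' @export
make_chart <- function(seed = 1, mode = c("random-smooth", "standard"),
                       ill = illuminant_e(), cmf = cmf_cie1931()) {
  mode <- match.arg(mode)
  n <- 24L
  coeffs <- if (mode == "standard") {
    grid <- expand.grid(a = c(0.15, 0.65, 1.15, 1.45),
                        b = c(-0.6, 0, 0.6), cc = c(-0.5, 0.5))
    t(as.matrix(grid))[, seq_len(n)]
  } else {
    with_seed(seed, rbind(
      stats::runif(n, COEF_BOX$absorber[1], COEF_BOX$absorber[2]),
      stats::runif(n, COEF_BOX$c2[1], COEF_BOX$c2[2]),
      stats::runif(n, COEF_BOX$c3[1], COEF_BOX$c3[2])))
  }
  R <- spectra_from_coeffs(coeffs)
  colnames(R) <- sprintf("patch%02d", seq_len(n))
  structure(list(patch_ids = colnames(R), reflectance_ref = R,
                 xyz_target = render_spectrum(t(R), ill, cmf),
                 rgb_measured = NULL, ill = ill, cmf = cmf,
                 mode = mode, seed = seed),
            class = "savehsi_chart")
}

#' @export
print.savehsi_chart <- function(x, ...) {
  cat(sprintf("Colour chart: %d patches, %s mode%s\n",
              length(x$patch_ids), x$mode,
              if (is.null(x$rgb_measured)) " (not yet imaged)" else ""))
  invisible(x)
}

#' Define a synthetic camera
#'
#' The forward model used for closed-loop experiments. In `"matched"` mode
#' the camera's spectral response equals the rendering colorimetry: the
#' linear channel values are the (optionally distorted) scene XYZ mapped
#' through the inverse primaries, so the decode path inverts it exactly. In
#' `"direct"` mode the linear channels are inner products of the spectrum
#' with explicit sensitivity curves. Dark offset and seeded Gaussian noise
#' are added in the linear domain before the transfer encoding.
#'
#' @param mode `"matched"` or `"direct"`.
#' @param sensitivities 3 x 401 nonnegative matrix (rows R, G, B) for
#'   `"direct"` mode.
#' @param transfer Encoding transfer: `"srgb"`, `"identity"`, or a gamma
#'   exponent.
#' @param dark Dark offset added to linear channels.
#' @param noise_sd Gaussian noise standard deviation (linear domain).
#' @param distortion Optional function mapping an n x 3 XYZ matrix to a
#'   distorted n x 3 matrix (models the camera's nonlinear XYZ response;
#'   `"matched"` mode only).
#' @param seed Seed for the noise stream.
#' @param primaries Primaries matrix for `"matched"` mode.
#' @return A `savehsi_camera` list.
#' @export
synthetic_camera <- function(mode = c("matched", "direct"),
                             sensitivities = NULL, transfer = "srgb",
                             dark = 0, noise_sd = 0, distortion = NULL,
                             seed = 1, primaries = srgb_primaries()) {
  mode <- match.arg(mode)
  if (mode == "direct") {
    if (is.null(sensitivities) || !is.matrix(sensitivities) ||
        nrow(sensitivities) != 3 || ncol(sensitivities) != N_BANDS)
      stop("direct mode needs a 3 x 401 sensitivity matrix")
    if (any(sensitivities < 0)) stop("sensitivities must be nonnegative")
  }
  structure(list(mode = mode, sensitivities = sensitivities,
                 transfer = transfer, dark = dark, noise_sd = noise_sd,
                 distortion = distortion, seed = seed, primaries = primaries),
            class = "savehsi_camera")
}

# camera transfer encode
camera_encode <- function(x, transfer) {
  if (identical(transfer, "identity")) x else srgb_encode(x, transfer)
}

#' Image reflectance spectra with a synthetic camera
#'
#' @param cam A [synthetic_camera()].
#' @param spectra Length-401 spectrum or 401 x n matrix of spectra in
#'   columns.
#' @param ill Illuminant.
#' @param cmf Colour-matching functions.
#' @return n x 3 matrix (or length-3 vector) of encoded RGB values in
#'   \[0, 1\].
#' @export
render_with_camera <- function(cam, spectra, ill = illuminant_e(),
                               cmf = cmf_cie1931()) {
  single <- !is.matrix(spectra)
  S <- if (single) matrix(spectra, ncol = 1) else spectra
  if (nrow(S) != N_BANDS) stop("spectra must be on the 401-sample grid")
  lin <- if (cam$mode == "matched") {
    xyz <- render_spectrum(t(S), ill, cmf)
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    if (!is.null(cam$distortion)) xyz <- cam$distortion(xyz)
    xyz_to_linear_rgb(xyz, cam$primaries)
  } else {
    if (!identical(ill$wavelengths, cmf$wavelengths))
      stop("illuminant and CMF grids do not match")
    k <- 1 / sum(ill$power * cmf$ybar)
    t(k * cam$sensitivities %*% (ill$power * S))
  }
  lin <- lin + cam$dark
  if (cam$noise_sd > 0)
    lin <- lin + with_seed(cam$seed,
      matrix(stats::rnorm(length(lin), sd = cam$noise_sd), nrow(lin), 3))
  out <- camera_encode(pmin(pmax(lin, 0), 1), cam$transfer)
  colnames(out) <- c("R", "G", "B")
  if (single) out <- structure(out[1, ], names = c("R", "G", "B"))
  out
}

#' Image a chart's reference spectra with a synthetic camera
#'
#' Fills the chart's `rgb_measured` slot.
#'
#' @param chart A [make_chart()] chart.
#' @param cam A [synthetic_camera()].
#' @return The chart with `rgb_measured` set (24 x 3).
#' @export
image_chart <- function(chart, cam) {
  chart$rgb_measured <- render_with_camera(cam, chart$reflectance_ref,
                                           chart$ill, chart$cmf)
  chart$camera <- cam
  chart
}

#' The eight phantom tissue classes
#' @return Character vector of class names.
#' @export
phantom_classes <- function() {
  c("normal", "staining", "cancer", "varicose", "esophageal_junction",
    "inflammation", "duodenum", "stomach")
}

# per-class parameter presets: base coefficients in the reflectance basis,
# texture amplitude, vessel count range and vessel absorber boost
phantom_presets <- function() {
  list(
    normal              = list(base = c(0.45, 0.35, 0.10), tex = 0.10, nves = 2:4, boost = 0.45),
    staining            = list(base = c(0.30, -0.60, -0.35), tex = 0.14, nves = 1:3, boost = 0.40),
    cancer              = list(base = c(1.20, 0.05, -0.30), tex = 0.22, nves = 4:6, boost = 0.50),
    varicose            = list(base = c(0.75, 0.70, 0.40), tex = 0.12, nves = 5:7, boost = 0.55),
    esophageal_junction = list(base = c(0.55, -0.15, 0.55), tex = 0.16, nves = 2:4, boost = 0.45),
    inflammation        = list(base = c(1.00, -0.40, 0.10), tex = 0.18, nves = 3:5, boost = 0.50),
    duodenum            = list(base = c(0.25, 0.70, -0.40), tex = 0.12, nves = 2:3, boost = 0.40),
    stomach             = list(base = c(0.70, -0.65, -0.10), tex = 0.12, nves = 2:3, boost = 0.40))
}

# smooth 2-D noise field in [-1, 1]: low-res Gaussian grid, bilinear upsample
smooth_field <- function(h, w, res = 5) {
  g <- matrix(stats::rnorm(res * res), res, res)
  f <- resize_bilinear(g, h, w)
  mx <- max(abs(f), 1e-12)
  f / mx
}

# draw smooth vessel curves into a boolean mask
vessel_mask <- function(h, w, n_vessels, widths = 2:6) {
  mask <- matrix(FALSE, h, w)
  for (v in seq_len(n_vessels)) {
    x <- stats::runif(1, 1, w); y <- stats::runif(1, 1, h)
    ang <- stats::runif(1, 0, 2 * pi)
    wd <- sample(widths, 1)
    steps <- round(1.5 * max(h, w))
    for (s in seq_len(steps)) {
      ang <- ang + stats::rnorm(1, sd = 0.25)
      x <- x + cos(ang); y <- y + sin(ang)
      if (x < 1 || x > w || y < 1 || y > h) break
      r0 <- max(1, round(y - wd / 2)); r1 <- min(h, round(y + wd / 2))
      c0 <- max(1, round(x - wd / 2)); c1 <- min(w, round(x + wd / 2))
      mask[r0:r1, c0:c1] <- TRUE
    }
  }
  mask
}

#' Generate a vascular tissue phantom
#'
#' A seeded scene with a smoothly varying background drawn from the fixed
#' reflectance family, darkened vessel structures (random smooth curves
#' dilated to 2-6 px) whose absorber coefficient is boosted — so vessel
#' pixels reflect less near 415 nm and 540 nm than the background — and the
#' matching ground-truth hyperspectral cube. Eight per-class parameter
#' presets give distinguishable textures and base colours.
#'
#' @param seed Integer seed.
#' @param size Length-2 frame size (pixels), each >= 32.
#' @param class One of [phantom_classes()].
#' @param cam Camera used to render the white-light frame (default matched,
#'   noiseless).
#' @param ill,cmf Rendering illuminant and CMFs.
#' @param store_cube Keep the ground-truth cube (set FALSE when generating
#'   large datasets).
#' @return A `savehsi_phantom`: `frame` (H x W x 3 sRGB), `cube`
#'   (`savehsi_cube` or NULL), `vessel_mask`, `coeffs` (3 x H*W), `class`.
#' @export
make_phantom <- function(seed = 1, size = c(64, 64), class = "normal",
                         cam = synthetic_camera(), ill = illuminant_e(),
                         cmf = cmf_cie1931(), store_cube = TRUE) {
  if (!class %in% phantom_classes())
    stop("unknown phantom class: ", class)
  if (any(size < 32)) stop("phantom size must be at least 32 x 32")
  h <- size[1]; w <- size[2]
  preset <- phantom_presets()[[class]]
  with_seed(seed, {
    tex1 <- smooth_field(h, w); tex2 <- smooth_field(h, w); tex3 <- smooth_field(h, w)
    mask <- vessel_mask(h, w, sample(preset$nves, 1))
    c1 <- preset$base[1] + preset$tex * tex1 + preset$boost * mask
    c2 <- preset$base[2] + preset$tex * tex2
    c3 <- preset$base[3] + 0.5 * preset$tex * tex3
    # clamp into the admissible coefficient box (keeps spectra in [0, 1])
    c1 <- pmin(pmax(c1, COEF_BOX$absorber[1]), COEF_BOX$absorber[2])
    c2 <- pmin(pmax(c2, COEF_BOX$c2[1]), COEF_BOX$c2[2])
    c3 <- pmin(pmax(c3, COEF_BOX$c3[1]), COEF_BOX$c3[2])
    coeffs <- rbind(as.vector(c1), as.vector(c2), as.vector(c3))
    rb <- reflectance_basis()
    # frame rendering exploits linearity: XYZ = XYZ(mean) + M_B %*% coeffs
    xyz_mean <- render_spectrum(rb$mean, ill, cmf)
    M_B <- t(render_spectrum(t(rb$basis), ill, cmf))      # 3 x 3
    xyz <- t(xyz_mean + M_B %*% coeffs)                   # pixels x 3
    if (!is.null(cam$distortion) && cam$mode == "matched")
      xyz <- cam$distortion(xyz)
    lin <- if (cam$mode == "matched") xyz_to_linear_rgb(xyz, cam$primaries)
           else stop("phantom rendering requires a matched-mode camera")
    lin <- lin + cam$dark
    if (cam$noise_sd > 0)
      lin <- lin + matrix(stats::rnorm(length(lin), sd = cam$noise_sd),
                          nrow(lin), 3)
    rgb <- camera_encode(pmin(pmax(lin, 0), 1), cam$transfer)
    frame <- array(rgb, dim = c(h, w, 3))
    cube <- if (store_cube) {
      spec <- spectra_from_coeffs(coeffs)                 # 401 x pixels
      spectral_cube(array(t(spec), dim = c(h, w, N_BANDS)))
    } else NULL
    structure(list(frame = frame, cube = cube, vessel_mask = mask,
                   coeffs = coeffs, class = class, seed = seed),
              class = "savehsi_phantom")
  })
}

#' @export
print.savehsi_phantom <- function(x, ...) {
  d <- dim(x$frame)
  cat(sprintf("Phantom '%s': %d x %d px, %.1f%% vessel coverage%s\n",
              x$class, d[1], d[2], 100 * mean(x$vessel_mask),
              if (is.null(x$cube)) "" else ", ground-truth cube attached"))
  invisible(x)
}

#' Default class-balanced dataset layout
#'
#' The train/validation/test counts of the study dataset: 2400 frames in
#' total (1800/400/200), with the cancer and varicose classes at 480 frames
#' each (360/80/40) and the remaining six classes at 240 each (180/40/20).
#'
#' @return Data frame with class, train, validation and test columns.
#' @export
default_dataset_counts <- function() {
  cls <- phantom_classes()
  big <- cls %in% c("cancer", "varicose")
  data.frame(class = cls,
             train = ifelse(big, 360L, 180L),
             validation = ifelse(big, 80L, 40L),
             test = ifelse(big, 40L, 20L))
}

#' Generate a class-balanced phantom dataset on disk
#'
#' Emits `dir/<split>/<class>/img_NNNN.png` frames plus a `manifest.csv`
#' (path, class, split). Each frame gets its own sub-seed derived from the
#' master seed, so the dataset is byte-identical across reruns.
#'
#' @param dir Output directory (created if needed).
#' @param seed Master seed.
#' @param counts Layout table as in [default_dataset_counts()].
#' @param size Frame size in pixels.
#' @return Invisibly, the manifest data frame.
#' @export
make_dataset <- function(dir, seed = 1, counts = default_dataset_counts(),
                         size = c(64, 64)) {
  if (any(counts$train < 0 | counts$validation < 0 | counts$test < 0))
    stop("counts must be nonnegative")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  i <- 0L
  for (r in seq_len(nrow(counts))) {
    cls <- counts$class[r]
    for (split in c("train", "validation", "test")) {
      n <- counts[[split]][r]
      if (n == 0) next
      subdir <- file.path(dir, split, cls)
      dir.create(subdir, recursive = TRUE, showWarnings = FALSE)
      for (j in seq_len(n)) {
        i <- i + 1L
        sub_seed <- (seed * 10007L + i * 101L) %% 2147483647L
        ph <- make_phantom(sub_seed, size = size, class = cls,
                           store_cube = FALSE)
        rel <- file.path(split, cls, sprintf("img_%04d.png", j))
        png::writePNG(ph$frame, file.path(dir, rel))
        rows[[i]] <- data.frame(path = rel, class = cls, split = split)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
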