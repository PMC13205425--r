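# Synthetic two-class directional textures. Benign-like samples (class 0)
# carry a single sinusoidal grating at one orientation; melanoma-like samples
# (class 1) carry a grating at a different orientation plus, scaled by the
# heterogeneity parameter, a second grating at a rotated orientation —
# emulating directionally disorganized texture. Lesions are filled ellipses
# used as binary masks. Class difference lives purely in orientation and
# heterogeneity, never in mean intensity, so discriminating the classes
# requires genuinely directional features.

#' Synthetic texture dataset configuration
#'
#' Defaults define the package's standard benchmark conditions: 20 samples
#' per class of 64 x 64 pixels, class orientations 0 and pi/2, wavelength 6
#' pixels per cycle, heterogeneity 0.5, additive Gaussian noise with sd 5 on
#' the 0-255 intensity scale, and elliptical masks with semi-axes drawn from
#' 20-28 pixels.
#'
#' @param n_per_class samples per class.
#' @param image_size `c(height, width)` in pixels.
#' @param class0_orientation,class1_orientation grating orientations
#'   (radians, direction of intensity variation).
#' @param wavelength grating wavelength (pixels per cycle).
#' @param heterogeneity in `[0, 1]`; amplitude fraction of the second,
#'   rotated grating mixed into class-1 samples.
#' @param noise_sd Gaussian pixel noise standard deviation (0-255 scale).
#' @param base_intensity,amplitude grating offset and amplitude (0-255
#'   scale); identical for both classes.
#' @param mask_semiaxes `c(min, max)` range the two ellipse semi-axes are
#'   drawn from (pixels).
#' @param test_fraction held-out fraction for the stratified split.
#' @param seed RNG seed for the whole dataset.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_per_class = 20L, image_size = c(64L, 64L),
                         class0_orientation = 0, class1_orientation = pi / 2,
                         wavelength = 6, heterogeneity = 0.5, noise_sd = 5,
                         base_intensity = 128, amplitude = 40,
                         mask_semiaxes = c(20, 28), test_fraction = 0.2,
                         seed = 1L) {
  stopifnot(n_per_class >= 1L, length(image_size) == 2L, all(image_size >= 8L),
            wavelength >= 1, heterogeneity >= 0, heterogeneity <= 1,
            noise_sd >= 0, length(mask_semiaxes) == 2L,
            mask_semiaxes[1] <= mask_semiaxes[2],
            test_fraction > 0, test_fraction < 1)
  structure(list(n_per_class = as.integer(n_per_class),
                 image_size = as.integer(image_size),
                 class0_orientation = class0_orientation,
                 class1_orientation = class1_orientation,
                 wavelength = wavelength, heterogeneity = heterogeneity,
                 noise_sd = noise_sd, base_intensity = base_intensity,
                 amplitude = amplitude, mask_semiaxes = mask_semiaxes,
                 test_fraction = test_fraction, seed = as.integer(seed)),
            class = "synth_config")
}

grating <- function(h, w, theta, wavelength, phase = 0) {
  x <- matrix(seq_len(h), h, w)              # row coordinate
  y <- matrix(seq_len(w), h, w, byrow = TRUE)
  sin(2 * pi * (x * cos(theta) + y * sin(theta)) / wavelength + phase)
}

#' Generate one synthetic lesion sample
#'
#' Draws from the current RNG state (seed it, or use [generate_dataset()]
#' which seeds once per dataset). Each sample gets a random carrier phase, an
#' elliptical mask with randomized centre and semi-axes, and i.i.d. Gaussian
#' pixel noise; intensities are rounded and clipped to `[0, 255]` so samples
#' survive 8-bit PNG round trips exactly.
#'
#' @param cfg a `synth_config`.
#' @param label class label, 0 or 1.
#' @param id optional sample id string.
#' @return list with `image`, `mask`, `label`, `id` and a `provenance` list
#'   echoing the per-sample draws.
#' @export
generate_sample <- function(cfg, label, id = NULL) {
  stopifnot(inherits(cfg, "synth_config"), label %in% c(0L, 1L))
  h <- cfg$image_size[1]; w <- cfg$image_size[2]
  theta <- if (label == 0L) cfg$class0_orientation else cfg$class1_orientation
  phase <- runif(1, 0, 2 * pi)
  img <- cfg$base_intensity +
    cfg$amplitude * grating(h, w, theta, cfg$wavelength, phase)
  phase2 <- NA_real_
  if (label == 1L && cfg$heterogeneity > 0) {
    phase2 <- runif(1, 0, 2 * pi)
    img <- img + cfg$heterogeneity * cfg$amplitude *
      grating(h, w, cfg$class1_orientation + pi / 3, cfg$wavelength, phase2)
  }
  if (cfg$noise_sd > 0) img <- img + matrix(rnorm(h * w, 0, cfg$noise_sd), h, w)
  img <- pmin(pmax(round(img), 0), 255)

  ax <- runif(2, cfg$mask_semiaxes[1], cfg$mask_semiaxes[2])
  if (2 * ax[1] + 1 > h || 2 * ax[2] + 1 > w) {
    stop("ellipse with semi-axes ", paste(round(ax, 1), collapse = "/"),
         " cannot fit a ", h, "x", w, " image")
  }
  cx <- runif(1, ax[1] + 1, h - ax[1])
  cy <- runif(1, ax[2] + 1, w - ax[2])
  x <- matrix(seq_len(h), h, w)
  y <- matrix(seq_len(w), h, w, byrow = TRUE)
  mask <- (((x - cx) / ax[1])^2 + ((y - cy) / ax[2])^2 <= 1) + 0

  list(image = img, mask = mask, label = as.integer(label),
       id = id %||% sprintf("syn_c%d", label),
       provenance = list(theta = theta, phase = phase, phase2 = phase2,
                         center = c(cx, cy), semiaxes = ax))
}

#' Generate a full synthetic dataset with a stratified split
#'
#' Seeds the RNG once from `cfg$seed`, generates `2 * n_per_class` samples,
#' and splits each class into train/test at `test_fraction` (test size
#' `round(n_per_class * test_fraction)` per class, chosen at random).
#'
#' @param cfg a `synth_config`.
#' @return object of class `synth_dataset`: lists `train` and `test` of raw
#'   samples (uncropped image + mask + label), and `config`.
#' @export
generate_dataset <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  train <- list(); test <- list()
  n_test <- round(cfg$n_per_class * cfg$test_fraction)
  if (n_test < 1L || n_test >= cfg$n_per_class) {
    stop("test_fraction leaves an empty train or test split")
  }
  for (label in c(0L, 1L)) {
    samples <- lapply(seq_len(cfg$n_per_class), function(i) {
      generate_sample(cfg, label, id = sprintf("syn_c%d_%03d", label, i))
    })
    test_idx <- sort(sample.int(cfg$n_per_class, n_test))
    test <- c(test, samples[test_idx])
    train <- c(train, samples[-test_idx])
  }
  structure(list(train = train, test = test, config = cfg),
            class = "synth_dataset")
}

#' Write a synthetic dataset to disk
#'
#' Layout readable by [load_dataset()]: `images/<id>.png`,
#' `masks/<id>.png`, `labels.csv` (columns `id`, `image_path`, `mask_path`,
#' `label`, `split`) and `provenance.json` echoing the generating
#' configuration.
#'
#' @param ds a `synth_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synth_dataset"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (split in c("train", "test")) {
    for (s in ds[[split]]) {
      ipath <- file.path("images", paste0(s$id, ".png"))
      mpath <- file.path("masks", paste0(s$id, ".png"))
      png::writePNG(s$image / 255, file.path(dir, ipath))
      png::writePNG(s$mask, file.path(dir, mpath))
      rows[[length(rows) + 1L]] <- data.frame(
        id = s$id, image_path = ipath, mask_path = mpath,
        label = s$label, split = split, stringsAsFactors = FALSE)
    }
  }
  labels <- do.call(rbind, rows)
  labels <- labels[order(labels$id), , drop = FALSE]
  write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(ds$config), file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
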