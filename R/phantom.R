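# Digital phantoms: porous sponge mimetic and analytic axial thorax slice.
# Thorax geometry is built from ellipses so the radial forward model has an
# exact closed-form Fourier transform (enables oracle-level acquisition
# tests); the sponge is a rasterized thresholded random field sampled by a
# fine-grid discrete Fourier evaluation.

THORAX_LABELS <- c(background = 0L, left_lung = 1L, right_lung = 2L,
                   heart = 3L, chest_wall = 4L, effusion = 5L)

#' Porous sponge phantom mimicking lung parenchyma
#'
#' Generates a binary pore map by thresholding a Gaussian-smoothed random
#' field: pixels inside pores carry water fraction 1, pixels in the sponge
#' matrix 0. The threshold is chosen by rank so the mean water fraction of
#' the grid equals `fill_fraction` up to pixel-count rounding, which is what
#' lets a fill-fraction sweep stand in for doping a physical sponge with
#' increasing amounts of water.
#'
#' @param size_px Grid size in pixels (>= 64).
#' @param pore_scale_px Correlation length of the pore texture in pixels.
#' @param fill_fraction Target mean water fraction in \[0, 1\].
#' @param seed Integer seed; the phantom is reproducible for a fixed seed.
#' @param fov_mm Physical field of view of the grid in millimeters.
#' @return An object of class `sponge_phantom` with fields `grid` (numeric
#'   matrix of water fractions), `pore_scale_px`, `fill_fraction`, `seed`,
#'   `fov_mm` and `pixel_size_mm`.
#' @examples
#' sp <- make_sponge(64, fill_fraction = 0.3, seed = 1)
#' mean(sp$grid)
#' @export
make_sponge <- function(size_px = 128, pore_scale_px = 4, fill_fraction = 0.3,
                        seed = 1, fov_mm = 160) {
  stop_if(!is_scalar_num(size_px) || size_px < 64,
          "'size_px' must be at least 64")
  check_scalar(fill_fraction, "fill_fraction", 0, 1)
  check_scalar(pore_scale_px, "pore_scale_px", 0, Inf, open_lower = TRUE)
  n <- as.integer(size_px)
  grid <- with_seed(seed, {
    noise <- matrix(rnorm(n * n), n, n)
    # periodic Gaussian smoothing at the pore correlation length
    d <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    g1 <- exp(-d^2 / (2 * pore_scale_px^2))
    ker <- outer(g1, g1)
    field <- Re(fft(fft(noise) * fft(ker), inverse = TRUE)) / (n * n)
    k <- round(fill_fraction * n * n)
    out <- matrix(0, n, n)
    if (k > 0) {
      thr <- sort(field, decreasing = TRUE)[k]
      out[field >= thr] <- 1
      # rank threshold can over-select under ties; trim deterministically
      excess <- sum(out) - k
      if (excess > 0) out[which(out == 1)[seq_len(excess)]] <- 0
    }
    out
  })
  structure(list(grid = grid, pore_scale_px = pore_scale_px,
                 fill_fraction = fill_fraction, seed = as.integer(seed),
                 fov_mm = fov_mm, pixel_size_mm = fov_mm / n),
            class = "sponge_phantom")
}

#' @export
print.sponge_phantom <- function(x, ...) {
  cat(sprintf("Sponge phantom: %d px, fill %.3f (achieved %.3f), pore %g px\n",
              nrow(x$grid), x$fill_fraction, mean(x$grid), x$pore_scale_px))
  invisible(x)
}

# Generic ellipse-set phantom: `ellipses` is a data.frame with columns
# cx_mm, cy_mm (y positive = posterior), a_mm, b_mm, label, parent
# (label of the enclosing region, used for amplitude composition in the
# analytic Fourier forward model; every ellipse must lie inside its parent).
ellipse_phantom <- function(ellipses, tissue_table, pixel_size_mm, grid_px,
                            lung_water_fraction = NA_real_, seed = 1L,
                            offset_mm = c(0, 0)) {
  fov <- pixel_size_mm * grid_px
  obj <- structure(list(ellipses = ellipses, tissue_table = tissue_table,
                        lung_water_fraction = lung_water_fraction,
                        pixel_size_mm = pixel_size_mm, grid_px = as.integer(grid_px),
                        fov_mm = fov, offset_mm = offset_mm,
                        seed = as.integer(seed), label_map = NULL),
                   class = "thorax_slice")
  obj$label_map <- rasterize_labels(obj)
  obj
}

# pixel-center coordinates in mm; x = 0 sits at index n/2 + 1 to match the
# FFT convention of the gridding reconstruction, so phantom rasters and
# reconstructed images share a pixel grid
pixel_coords_mm <- function(grid_px, pixel_size_mm) {
  (seq_len(grid_px) - floor(grid_px / 2) - 1) * pixel_size_mm
}

rasterize_labels <- function(slice) {
  x <- pixel_coords_mm(slice$grid_px, slice$pixel_size_mm)
  lab <- matrix(THORAX_LABELS[["background"]], slice$grid_px, slice$grid_px)
  X <- matrix(x, slice$grid_px, slice$grid_px)
  Y <- matrix(x, slice$grid_px, slice$grid_px, byrow = TRUE)
  for (i in seq_len(nrow(slice$ellipses))) {
    e <- slice$ellipses[i, ]
    inside <- ((X - e$cx_mm - slice$offset_mm[1]) / e$a_mm)^2 +
      ((Y - e$cy_mm - slice$offset_mm[2]) / e$b_mm)^2 <= 1
    lab[inside] <- e$label
  }
  lab
}

#' Digital axial thorax slice phantom
#'
#' Builds a 2D axial slice at the level of the pulmonary arteries from
#' analytic ellipses: an outer chest wall, two non-overlapping lungs, a
#' heart, and optionally a dependent posterior-basal pleural effusion inside
#' the right lung. Lung tissue parameters come from
#' [lung_tissue_model()] at the requested water fraction, so the geometry is
#' identical across water fractions and only the lung proton density (and
#' its co-varying relaxation) changes.
#'
#' @param lung_water_fraction Lung water fraction in \[0.05, 0.6\].
#' @param effusion_present If `TRUE`, add a pleural effusion region
#'   (free-water signal) in the posterior base of the right lung.
#' @param pixel_size_mm Pixel size of the rasterized label map.
#' @param seed Integer seed recorded in the object (the default geometry is
#'   deterministic).
#' @param grid_px Raster size in pixels.
#' @param anchors Relaxation anchors for [lung_tissue_model()].
#' @return An object of class `thorax_slice` with fields `label_map`
#'   (integer matrix using the labels in `THORAX_LABELS`), `tissue_table`
#'   (label name -> [tissue_params()]), `ellipses`, `lung_water_fraction`,
#'   `pixel_size_mm`, `fov_mm` and `offset_mm`.
#' @examples
#' th <- make_thorax(0.2)
#' table(th$label_map)
#' @export
make_thorax <- function(lung_water_fraction = 0.2, effusion_present = FALSE,
                        pixel_size_mm = 3.125, seed = 1, grid_px = 128,
                        anchors = lung_anchors()) {
  check_scalar(lung_water_fraction, "lung_water_fraction", 0.05, 0.6)
  # reference geometry designed on a 400 mm FOV, scaled to the actual FOV
  s <- pixel_size_mm * grid_px / 400
  ell <- data.frame(
    cx_mm = c(0, -90, 90, 0) * s,
    cy_mm = c(0, 0, 0, 25) * s,
    a_mm = c(170, 48, 48, 40) * s,
    b_mm = c(120, 88, 88, 35) * s,
    label = THORAX_LABELS[c("chest_wall", "left_lung", "right_lung", "heart")],
    parent = THORAX_LABELS[c("background", "chest_wall", "chest_wall",
                             "chest_wall")]
  )
  if (isTRUE(effusion_present)) {
    ell <- rbind(ell, data.frame(
      cx_mm = 95 * s, cy_mm = 55 * s, a_mm = 28 * s, b_mm = 22 * s,
      label = THORAX_LABELS[["effusion"]],
      parent = THORAX_LABELS[["right_lung"]]))
  }
  lung <- lung_tissue_model(lung_water_fraction, anchors)
  tissue_table <- list(
    background = tissue_params(0, 1000, 10),
    left_lung = lung,
    right_lung = lung,
    heart = tissue_params(0.8, 1200, 25),
    chest_wall = tissue_params(0.7, 900, 20, fat_fraction = 0.3),
    effusion = lung_tissue_model(1, anchors)
  )
  obj <- ellipse_phantom(ell, tissue_table, pixel_size_mm, grid_px,
                         lung_water_fraction = lung_water_fraction,
                         seed = seed)
  obj
}

#' @export
print.thorax_slice <- function(x, ...) {
  cat(sprintf("Thorax slice: %d px (%.3g mm/px), lung water %.3g, regions: %s\n",
              x$grid_px, x$pixel_size_mm, x$lung_water_fraction,
              paste(names(THORAX_LABELS)[THORAX_LABELS %in% unique(c(x$label_map))],
                    collapse = ", ")))
  invisible(x)
}

#' Uniform disk phantom
#'
#' Single-ellipse phantom used for analytic checks of the acquisition and
#' reconstruction chain: its Fourier transform has the closed jinc form
#' `F(k) = ab J1(2 pi rho) / rho`, `rho = sqrt((a kx)^2 + (b ky)^2)`.
#'
#' @param radius_mm Disk radius.
#' @param tissue A [tissue_params()] object for the disk interior.
#' @param pixel_size_mm,grid_px Raster geometry.
#' @return A `thorax_slice` object with a single `heart`-labelled disk.
#' @export
make_disk_phantom <- function(radius_mm = 60,
                              tissue = tissue_params(0.5, 1200, 25),
                              pixel_size_mm = 3.125, grid_px = 128) {
  ell <- data.frame(cx_mm = 0, cy_mm = 0, a_mm = radius_mm, b_mm = radius_mm,
                    label = THORAX_LABELS[["heart"]],
                    parent = THORAX_LABELS[["background"]])
  tissue_table <- list(background = tissue_params(0, 1000, 10),
                       heart = tissue)
  ellipse_phantom(ell, tissue_table, pixel_size_mm, grid_px)
}

#' Rigid in-plane exercise motion model
#'
#' Motion is a rigid 2D translation with two components: a smooth sinusoidal
#' superior-inferior breathing displacement (projected in-plane along the
#' posterior axis), and sporadic "jitter bursts" — with probability
#' `jitter_burst_probability` per sampling event the slice is additionally
#' offset in a random direction by a random magnitude up to
#' `jitter_amplitude_mm`, emulating residual exercise-induced motion between
#' radial spokes.
#'
#' @param breathing_amplitude_mm Breathing displacement amplitude (>= 0).
#' @param breathing_period_s Breathing period in seconds (> 0).
#' @param jitter_amplitude_mm Maximum jitter offset magnitude (>= 0).
#' @param jitter_burst_probability Per-sampling-event jitter probability.
#' @param seed Integer seed; jitter is a deterministic function of
#'   `(seed, t)` so repeated evaluation at the same time reproduces the same
#'   offset.
#' @return An object of class `motion_model`.
#' @export
motion_model <- function(breathing_amplitude_mm = 0, breathing_period_s = 4,
                         jitter_amplitude_mm = 0,
                         jitter_burst_probability = 0, seed = 1) {
  check_scalar(breathing_amplitude_mm, "breathing_amplitude_mm", 0, Inf)
  check_scalar(breathing_period_s, "breathing_period_s", 0, Inf,
               open_lower = TRUE)
  check_scalar(jitter_amplitude_mm, "jitter_amplitude_mm", 0, Inf)
  check_scalar(jitter_burst_probability, "jitter_burst_probability", 0, 1)
  structure(list(breathing_amplitude_mm = breathing_amplitude_mm,
                 breathing_period_s = breathing_period_s,
                 jitter_amplitude_mm = jitter_amplitude_mm,
                 jitter_burst_probability = jitter_burst_probability,
                 seed = as.integer(seed)),
            class = "motion_model")
}

#' In-plane displacement of the motion model at a given time
#'
#' @param motion A [motion_model()] object.
#' @param t Time in seconds (>= 0).
#' @return Length-2 numeric `(dx, dy)` in millimeters.
#' @export
motion_displacement <- function(motion, t) {
  stop_if(!inherits(motion, "motion_model"), "'motion' must be a motion_model")
  check_scalar(t, "t", 0, Inf)
  d <- c(0, motion$breathing_amplitude_mm *
           sin(2 * pi * t / motion$breathing_period_s))
  if (motion$jitter_burst_probability > 0 && motion$jitter_amplitude_mm > 0) {
    jit <- with_seed(hash_seed(motion$seed, t), {
      if (runif(1) < motion$jitter_burst_probability) {
        ang <- runif(1, 0, 2 * pi)
        mag <- runif(1, 0, motion$jitter_amplitude_mm)
        c(cos(ang), sin(ang)) * mag
      } else c(0, 0)
    })
    d <- d + jit
  }
  d
}

#' Displace a phantom rigidly according to a motion model
#'
#' Applies the rigid in-plane translation of `motion` at time `t` to the
#' slice: the analytic ellipse set is shifted and the label map
#' re-rasterized. Translation conserves total proton density provided the
#' anatomy stays within the field of view (the default geometry leaves a
#' 30 mm margin). A zero-amplitude model returns the input unchanged.
#'
#' @param slice A `thorax_slice` object.
#' @param motion A [motion_model()] object.
#' @param t Time in seconds (>= 0).
#' @return A displaced `thorax_slice`.
#' @export
displace <- function(slice, motion, t) {
  stop_if(!inherits(slice, "thorax_slice"), "'slice' must be a thorax_slice")
  d <- motion_displacement(motion, t)
  if (all(d == 0)) return(slice)
  slice$offset_mm <- slice$offset_mm + d
  slice$label_map <- rasterize_labels(slice)
  slice
}

# per-label steady-state signal for a given sequence and echo
label_signals <- function(slice, seq, echo_index) {
  sig <- setNames(numeric(length(THORAX_LABELS)), names(THORAX_LABELS))
  for (nm in names(slice$tissue_table)) {
    sig[nm] <- spgr_signal(seq, slice$tissue_table[[nm]], echo_index)
  }
  sig
}

#' Rasterized signal image of a phantom
#'
#' Per-pixel spoiled gradient-echo signal of the phantom at one echo, useful
#' as a ground-truth reference image.
#'
#' @param slice A `thorax_slice` or `sponge_phantom`.
#' @param seq A [seq_params()] object.
#' @param echo_index 1-based echo index.
#' @return Numeric matrix of signal in AU.
#' @export
signal_image <- function(slice, seq, echo_index = 1L) {
  if (inherits(slice, "sponge_phantom")) {
    vals <- sort(unique(c(slice$grid)))
    sig <- vapply(vals, function(w)
      spgr_signal(seq, lung_tissue_model(w), echo_index), numeric(1))
    out <- matrix(sig[match(c(slice$grid), vals)], nrow(slice$grid))
    return(out)
  }
  stop_if(!inherits(slice, "thorax_slice"), "unsupported phantom class")
  sig <- label_signals(slice, seq, echo_index)
  lab_names <- names(THORAX_LABELS)[match(c(slice$label_map), THORAX_LABELS)]
  matrix(sig[lab_names], nrow(slice$label_map))
}

#' Lung region-of-interest mask of a thorax slice
#'
#' @param slice A `thorax_slice`.
#' @param include_effusion Include pleural-effusion pixels in the mask
#'   (mirrors the pre-hoc inclusion of effusions in the lung ROI).
#' @param grid_px Optional raster size; defaults to the slice's own grid.
#' @return A [lung_roi()] object.
#' @export
thorax_lung_mask <- function(slice, include_effusion = TRUE, grid_px = NULL) {
  stop_if(!inherits(slice, "thorax_slice"), "'slice' must be a thorax_slice")
  if (!is.null(grid_px) && grid_px != slice$grid_px) {
    slice$pixel_size_mm <- slice$fov_mm / grid_px
    slice$grid_px <- as.integer(grid_px)
    slice$label_map <- rasterize_labels(slice)
  }
  want <- THORAX_LABELS[c("left_lung", "right_lung")]
  if (include_effusion) want <- c(want, THORAX_LABELS[["effusion"]])
  mask <- matrix(slice$label_map %in% want, nrow(slice$label_map))
  lung_roi(mask, includes_effusion = include_effusion, label = "lungs")
}
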