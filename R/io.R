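# Delimited-text and image I/O for the toolkit's containers.

#' Read volume-time curves from CSV
#'
#' Expects columns `phase_ms`, `volume_ml`, `chamber`, `condition`; one
#' curve per chamber/condition combination.
#'
#' @param path CSV file path.
#' @return Named list of [volume_time_curve()] objects
#'   (`<chamber>_<condition>`).
#' @export
read_volume_curves <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("phase_ms", "volume_ml", "chamber", "condition")
  stop_if(!all(need %in% names(df)),
          paste("CSV must have columns:", paste(need, collapse = ", ")))
  sp <- split(df, interaction(df$chamber, df$condition, drop = TRUE, sep = "_"))
  lapply(sp, function(d) {
    d <- d[order(d$phase_ms), ]
    volume_time_curve(d$phase_ms, d$volume_ml, d$chamber[1], d$condition[1])
  })
}

#' Read or write a cohort table as CSV
#'
#' @param path CSV file path.
#' @param table A `cohort_table` (for writing).
#' @return For reading, a `cohort_table` with `group` as an ordered factor
#'   in the declared severity ordering.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stop_if(!all(c("subject_id", "group") %in% names(df)),
          "cohort CSV must have 'subject_id' and 'group' columns")
  stop_if(!all(df$group %in% COHORT_GROUPS),
          paste("group labels must be one of:",
                paste(COHORT_GROUPS, collapse = ", ")))
  df$group <- factor(df$group, levels = COHORT_GROUPS, ordered = TRUE)
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Write a map or phantom as NIfTI
#'
#' Writes a `pd_map` image (or a phantom's water-fraction/label raster)
#' as a NIfTI volume with the correct pixel dimensions, with a JSON
#' sidecar of generation parameters when `jsonlite` is available.
#' Requires the `RNifti` package.
#'
#' @param x A `pd_map`, `thorax_slice` or `sponge_phantom`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_nifti_map <- function(x, path) {
  stop_if(!requireNamespace("RNifti", quietly = TRUE),
          "'RNifti' is required for NIfTI export")
  if (inherits(x, "pd_map")) {
    img <- x$image; px <- x$pixel_size_mm; side <- x$provenance
  } else if (inherits(x, "thorax_slice")) {
    img <- x$label_map; px <- x$pixel_size_mm
    side <- list(lung_water_fraction = x$lung_water_fraction, seed = x$seed)
  } else if (inherits(x, "sponge_phantom")) {
    img <- x$grid; px <- x$pixel_size_mm
    side <- list(fill_fraction = x$fill_fraction, seed = x$seed,
                 pore_scale_px = x$pore_scale_px)
  } else stop("unsupported object for NIfTI export", call. = FALSE)
  nii <- RNifti::asNifti(img)
  RNifti::pixdim(nii) <- c(px, px)
  RNifti::writeNifti(nii, path)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    strip_classes <- function(x) {
      if (is.list(x)) lapply(unclass(x), strip_classes) else x
    }
    side <- strip_classes(side)
    jsonlite::write_json(side, paste0(sub("\\.nii(\\.gz)?$", "", path),
                                      ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Serialize radial k-space to JSON (and back)
#'
#' Plain-text container: trajectory, acquisition metadata, and the complex
#' samples as real/imaginary arrays. Requires `jsonlite`.
#'
#' @param kspace A `radial_kspace`.
#' @param path Output JSON path.
#' @return For reading, the reconstructed `radial_kspace`.
#' @export
write_kspace_json <- function(kspace, path) {
  stop_if(!requireNamespace("jsonlite", quietly = TRUE),
          "'jsonlite' is required for k-space serialization")
  tr <- kspace$trajectory
  obj <- list(
    trajectory = list(n_spokes = tr$n_spokes,
                      samples_per_spoke = tr$samples_per_spoke,
                      k_max = tr$k_max,
                      tr_s = if (tr$n_spokes > 1) diff(tr$spoke_times_s[1:2]) else 0.005),
    fov_mm = kspace$fov_mm, noise_sigma = kspace$noise_sigma,
    seed = kspace$seed,
    seq = unclass(kspace$seq),
    data_re = Re(kspace$data), data_im = Im(kspace$data)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_kspace_json
#' @export
read_kspace_json <- function(path) {
  stop_if(!requireNamespace("jsonlite", quietly = TRUE),
          "'jsonlite' is required for k-space serialization")
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- golden_angle_trajectory(obj$trajectory$n_spokes,
                                obj$trajectory$samples_per_spoke,
                                obj$trajectory$k_max,
                                obj$trajectory$tr_s)
  sq <- seq_params(obj$seq$flip_angle_deg, obj$seq$tr_ms,
                   obj$seq$echo_times_ms, obj$seq$fat_sat_enabled,
                   obj$seq$n_prep_reps)
  dims <- dim(obj$data_re)
  data <- array(complex(real = obj$data_re, imaginary = obj$data_im),
                dim = dims)
  structure(list(data = data, trajectory = tr, fov_mm = obj$fov_mm,
                 noise_sigma = obj$noise_sigma, seed = as.integer(obj$seed),
                 seq = sq),
            class = "radial_kspace")
}
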