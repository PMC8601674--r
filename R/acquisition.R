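# Golden-angle radial-out k-space sampling: trajectory generation and the
# forward model. Ellipse phantoms are sampled through their exact analytic
# Fourier transforms; sponge phantoms through a discrete Fourier evaluation
# on their fine rasterized grid (kept finer than the reconstruction grid so
# the forward and inverse models never share a discretization).

GOLDEN_ANGLE_RAD <- pi * (sqrt(5) - 1) / 2   # 111.2461... degrees

#' Golden-angle radial-out trajectory
#'
#' Spoke `i` (0-based) lies at angle `i * Delta mod 2pi` with the golden
#' angle `Delta = pi (sqrt(5) - 1) / 2` (111.2461 degrees), the increment
#' conventional in golden-angle radial MRI; any golden-ratio rotation gives
#' near-uniform angular coverage for every spoke count. Each spoke runs
#' center-out from k = 0 to `k_max`, sampling the DC point as its first
#' sample; angles accumulate over the full 2 pi because center-out spokes
#' cover half-lines.
#'
#' @param n_spokes Number of spokes (>= 1).
#' @param samples_per_spoke Samples along each spoke (>= 2), from 0 to
#'   `k_max` inclusive.
#' @param k_max Maximum spatial frequency in cycles/mm.
#' @param tr_s Time between spokes in seconds (sets `spoke_times_s`).
#' @return An object of class `radial_trajectory` with fields `n_spokes`,
#'   `samples_per_spoke`, `angles_rad`, `k_max`, `radii` (cycles/mm),
#'   `spoke_times_s` and `echo_index`.
#' @examples
#' tr <- golden_angle_trajectory(13, 33, 0.1)
#' diff(tr$angles_rad[1:2]) * 180 / pi
#' @export
golden_angle_trajectory <- function(n_spokes, samples_per_spoke = 65,
                                    k_max = 0.1, tr_s = 0.005) {
  stop_if(!is_scalar_num(n_spokes) || n_spokes < 1, "'n_spokes' must be >= 1")
  stop_if(!is_scalar_num(samples_per_spoke) || samples_per_spoke < 2,
          "'samples_per_spoke' must be >= 2")
  check_scalar(k_max, "k_max", 0, Inf, open_lower = TRUE)
  n <- as.integer(n_spokes)
  m <- as.integer(samples_per_spoke)
  structure(list(n_spokes = n, samples_per_spoke = m,
                 angles_rad = ((seq_len(n) - 1) * GOLDEN_ANGLE_RAD) %% (2 * pi),
                 k_max = k_max,
                 radii = seq(0, k_max, length.out = m),
                 spoke_times_s = (seq_len(n) - 1) * tr_s,
                 echo_index = 1L),
            class = "radial_trajectory")
}

#' @export
print.radial_trajectory <- function(x, ...) {
  cat(sprintf("Golden-angle radial trajectory: %d spokes x %d samples, k_max %.4g /mm\n",
              x$n_spokes, x$samples_per_spoke, x$k_max))
  invisible(x)
}

#' Nyquist k-space extent for a target grid
#'
#' @param grid_px Reconstruction grid size in pixels.
#' @param fov_mm Field of view in millimeters.
#' @return `grid_px / (2 * fov_mm)` in cycles/mm.
#' @export
nyquist_kmax <- function(grid_px, fov_mm) grid_px / (2 * fov_mm)

# kx, ky matrices [spoke, sample] for a trajectory
trajectory_k <- function(traj) {
  kx <- outer(cos(traj$angles_rad), traj$radii)
  ky <- outer(sin(traj$angles_rad), traj$radii)
  list(kx = kx, ky = ky)
}

# analytic FT of the ellipse set at (kx, ky), signal-weighted per region:
# each ellipse contributes (signal_inside - signal_parent) * jinc form.
ellipse_ft <- function(slice, seq, echo_index, kx, ky, extra_shift = c(0, 0)) {
  sig <- label_signals(slice, seq, echo_index)
  lab_name <- function(l) names(THORAX_LABELS)[match(l, THORAX_LABELS)]
  F <- matrix(0 + 0i, nrow(kx), ncol(kx))
  for (i in seq_len(nrow(slice$ellipses))) {
    e <- slice$ellipses[i, ]
    amp <- sig[[lab_name(e$label)]] - sig[[lab_name(e$parent)]]
    if (amp == 0) next
    rho <- sqrt((e$a_mm * kx)^2 + (e$b_mm * ky)^2)
    base <- matrix(pi * e$a_mm * e$b_mm, nrow(kx), ncol(kx))
    nz <- rho > 0
    base[nz] <- e$a_mm * e$b_mm * besselJ(2 * pi * rho[nz], 1) / rho[nz]
    cx <- e$cx_mm + slice$offset_mm[1] + extra_shift[1]
    cy <- e$cy_mm + slice$offset_mm[2] + extra_shift[2]
    F <- F + amp * base * exp(-2i * pi * (kx * cx + ky * cy))
  }
  F
}

# discrete Fourier evaluation of a rasterized signal image along one spoke;
# returns complex vector over the spoke's radii. Separable in x/y per spoke.
ndft_spoke <- function(img, x_mm, angle, radii) {
  kx <- radii * cos(angle)
  ky <- radii * sin(angle)
  ex <- exp(-2i * pi * outer(kx, x_mm))          # m x N
  ey <- exp(-2i * pi * outer(ky, x_mm))          # m x N
  # img rows index x, columns y: F = sum_x sum_y img e^{-i2pi(kx x + ky y)}
  rowSums((ex %*% img) * ey) * (x_mm[2] - x_mm[1])^2
}

#' Simulate golden-angle radial k-space acquisition of a phantom
#'
#' Forward model of the multiecho UTE sequence: every pixel (or analytic
#' region) carries its steady-state spoiled gradient-echo signal at each echo
#' time, and each spoke samples the 2D Fourier transform of that
#' signal-weighted phantom along its center-out line. When a motion model is
#' given the phantom is displaced to each spoke's timestamp before sampling
#' (all echoes of a spoke share its angle and displacement). Complex white
#' Gaussian noise of standard deviation `noise_sigma` is added per sample;
#' the result is deterministic for a fixed seed.
#'
#' @param phantom A `thorax_slice` (analytic ellipse transform) or
#'   `sponge_phantom` (fine-grid discrete Fourier evaluation).
#' @param seq A [seq_params()] object.
#' @param traj A [golden_angle_trajectory()] object.
#' @param motion Optional [motion_model()]; `NULL` for a static acquisition.
#' @param noise_sigma Complex noise standard deviation (AU).
#' @param seed Integer seed for the noise.
#' @return An object of class `radial_kspace` with `data` (complex array
#'   `[spoke, sample, echo]`), `trajectory`, `fov_mm`, `noise_sigma`, `seed`
#'   and `seq`.
#' @examples
#' ph <- make_disk_phantom(grid_px = 64, pixel_size_mm = 4)
#' ks <- sample_kspace(ph, seq_params(), golden_angle_trajectory(8, 17, 0.05))
#' dim(ks$data)
#' @export
sample_kspace <- function(phantom, seq, traj, motion = NULL,
                          noise_sigma = 0, seed = 1) {
  stop_if(!inherits(seq, "seq_params"), "'seq' must be a seq_params object")
  stop_if(!inherits(traj, "radial_trajectory"),
          "'traj' must be a radial_trajectory")
  stop_if(!is.null(motion) && !inherits(motion, "motion_model"),
          "'motion' must be NULL or a motion_model")
  check_scalar(noise_sigma, "noise_sigma", 0, Inf)
  n_echo <- length(seq$echo_times_ms)
  n <- traj$n_spokes
  m <- traj$samples_per_spoke
  data <- array(0 + 0i, dim = c(n, m, n_echo))
  shifts <- matrix(0, n, 2)
  if (!is.null(motion)) {
    for (i in seq_len(n)) {
      shifts[i, ] <- motion_displacement(motion, traj$spoke_times_s[i])
    }
  }
  if (inherits(phantom, "thorax_slice")) {
    k <- trajectory_k(traj)
    for (e in seq_len(n_echo)) {
      F <- ellipse_ft(phantom, seq, e, k$kx, k$ky)
      if (!is.null(motion)) {
        phase <- exp(-2i * pi * (k$kx * shifts[, 1] + k$ky * shifts[, 2]))
        F <- F * phase
      }
      data[, , e] <- F
    }
  } else if (inherits(phantom, "sponge_phantom")) {
    x_mm <- pixel_coords_mm(nrow(phantom$grid), phantom$pixel_size_mm)
    # binary water map: signal image is (per-echo scalar) x pore indicator,
    # so one spoke transform serves all echoes up to scaling
    imgs <- lapply(seq_len(n_echo), function(e) signal_image(phantom, seq, e))
    scal <- vapply(imgs, max, numeric(1))
    base_ok <- all(vapply(seq_len(n_echo), function(e) {
      isTRUE(all.equal(imgs[[e]], imgs[[1L]] * (scal[e] / max(scal[1L], .Machine$double.eps)),
                       tolerance = 1e-12))
    }, logical(1)))
    for (i in seq_len(n)) {
      f1 <- ndft_spoke(imgs[[1L]], x_mm, traj$angles_rad[i], traj$radii)
      for (e in seq_len(n_echo)) {
        fe <- if (base_ok && scal[1L] > 0) f1 * (scal[e] / scal[1L])
              else ndft_spoke(imgs[[e]], x_mm, traj$angles_rad[i], traj$radii)
        if (!is.null(motion)) {
          kx <- traj$radii * cos(traj$angles_rad[i])
          ky <- traj$radii * sin(traj$angles_rad[i])
          fe <- fe * exp(-2i * pi * (kx * shifts[i, 1] + ky * shifts[i, 2]))
        }
        data[i, , e] <- fe
      }
    }
  } else {
    stop("unsupported phantom class: ", paste(class(phantom), collapse = "/"),
         call. = FALSE)
  }
  if (noise_sigma > 0) {
    noise <- with_seed(seed, {
      complex(real = rnorm(length(data), 0, noise_sigma),
              imaginary = rnorm(length(data), 0, noise_sigma))
    })
    data <- data + array(noise, dim = dim(data))
  }
  structure(list(data = data, trajectory = traj, fov_mm = phantom$fov_mm,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 seq = seq),
            class = "radial_kspace")
}

#' @export
print.radial_kspace <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Radial k-space: %d spokes x %d samples x %d echoes, FOV %g mm, sigma %g\n",
              d[1], d[2], d[3], x$fov_mm, x$noise_sigma))
  invisible(x)
}
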