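# Independent oracles used across the suite. Each reimplements the checked
# quantity by brute force or closed form, sharing no code path with the
# package internals it verifies.

# direct conjugate-phase reconstruction: f(r_p) = sum_j w_j F_j e^{+i2pi k.r}
oracle_conjphase_recon <- function(kspace, weights, grid_px, echo = 1L) {
  tr <- kspace$trajectory
  fov <- kspace$fov_mm
  kx <- c(outer(cos(tr$angles_rad), tr$radii))
  ky <- c(outer(sin(tr$angles_rad), tr$radii))
  F <- c(kspace$data[, , echo]) * c(weights)
  x <- (seq_len(grid_px) - grid_px / 2 - 1) * fov / grid_px
  img <- matrix(0 + 0i, grid_px, grid_px)
  for (q in seq_len(grid_px)) {
    ph_y <- exp(2i * pi * ky * x[q])
    for (p in seq_len(grid_px)) {
      img[p, q] <- sum(F * exp(2i * pi * kx * x[p]) * ph_y)
    }
  }
  Mod(img)
}

# brute-force Jonckheere-Terpstra: direct double loop over observations
oracle_jt_stat <- function(x, g) {
  J <- 0
  n <- length(x)
  for (p in seq_len(n)) for (q in seq_len(n)) {
    if (g[p] < g[q]) {
      J <- J + (x[p] < x[q]) + 0.5 * (x[p] == x[q])
    }
  }
  J
}

# full permutation null of J by recursive enumeration of label assignments
oracle_jt_null <- function(x, sizes) {
  n <- length(x)
  out <- numeric(0)
  rec <- function(avail, si, lab) {
    if (si == length(sizes)) {
      lab[avail] <- si
      out[[length(out) + 1]] <<- oracle_jt_stat(x, lab)
      return(invisible())
    }
    for (pick in utils::combn(avail, sizes[si], simplify = FALSE)) {
      lab2 <- lab
      lab2[pick] <- si
      rec(setdiff(avail, pick), si + 1L, lab2)
    }
  }
  rec(seq_len(n), 1L, integer(n))
  unlist(out)
}

# exact signed-rank null by explicit enumeration of all 2^n sign vectors
oracle_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  list(v = v_obs,
       p_one = mean(v_all >= v_obs - 1e-9),
       p_two = min(1, 2 * min(mean(v_all >= v_obs - 1e-9),
                              mean(v_all <= v_obs + 1e-9))))
}

# closed-form FT of a centred disk of radius R and amplitude s
oracle_disk_ft <- function(s, R, kx, ky) {
  k <- sqrt(kx^2 + ky^2)
  out <- ifelse(k == 0, s * pi * R^2,
                s * R * besselJ(2 * pi * R * k, 1) / k)
  out
}

default_thorax_setup <- function(G = 64, fov = 400, n_spokes = 200,
                                 water = 0.2) {
  list(seq = seq_params(),
       slice = make_thorax(water, pixel_size_mm = fov / 128, grid_px = 128),
       traj = golden_angle_trajectory(n_spokes, G + 1L,
                                      nyquist_kmax(G, fov)),
       config = recon_config(grid_size_px = G),
       G = G, fov = fov)
}
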