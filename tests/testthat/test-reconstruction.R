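# Density compensation, gridding reconstruction, motion rejection,
# and multiecho TE=0 extrapolation

test_that("ramp density compensation follows the polar area element", {
  tr <- golden_angle_trajectory(10, 17, 0.1)
  w <- density_compensation(tr, "ramp")
  expect_equal(dim(w), c(10L, 17L))
  # proportional to radius away from the centre (outermost cell half-width)
  expect_equal(w[1, 2:16] / tr$radii[2:16], rep(w[1, 2] / tr$radii[2], 15),
               tolerance = 1e-12)
  expect_equal(w[1, 17], w[1, 2] / tr$radii[2] * tr$radii[17] / 2,
               tolerance = 1e-12)
  expect_true(all(w > 0))
  # total weight covers the sampled k-space disk
  expect_equal(sum(w), pi * tr$k_max^2, tolerance = 0.01)

  tr0 <- tr
  tr0$radii <- rep(0, 17)
  expect_error(density_compensation(tr0, "ramp"), "degenerate")
  expect_error(density_compensation(tr, "bogus"))
})

test_that("Pipe-Menon weights become near-uniform for uniform Cartesian sampling", {
  # uniformly dense Cartesian-equivalent sample cloud covering the
  # (periodic) grid: every cell sampled once
  g <- as.matrix(expand.grid(u = seq(-16, 15), v = seq(-16, 15)))
  # smooth non-uniform start away from the fixed point
  w <- 1 + 0.3 * sin(2 * pi * g[, 1] / 32) * sin(2 * pi * g[, 2] / 32)
  beta <- lungwater:::kb_beta(4, 2)
  for (it in 1:20) {
    gr <- lungwater:::grid_accumulate(g[, 1], g[, 2], complex(real = w),
                                      32L, 4, beta)
    cw <- lungwater:::interp_from_grid(Re(gr), g[, 1], g[, 2], 32L, 4, beta)
    w <- w / cw
  }
  cov_w <- sd(w) / mean(w)
  expect_lt(cov_w, 0.05)
})

test_that("gridding agrees with the conjugate-phase oracle and the analytic disk", {
  sq <- seq_params()
  tis <- tissue_params(0.5, 1200, 25)
  fov <- 256
  G <- 32
  ph <- make_disk_phantom(radius_mm = 60, tissue = tis,
                          pixel_size_mm = fov / 128, grid_px = 128)
  tr <- golden_angle_trajectory(64, G + 1L, nyquist_kmax(G, fov))
  ks <- sample_kspace(ph, sq, tr)
  cfg <- recon_config(grid_size_px = G)
  pd <- grid_reconstruct(ks, cfg)

  w <- density_compensation(tr, "ramp")
  oracle <- oracle_conjphase_recon(ks, w, G)
  nrmsd <- sqrt(mean((pd$image - oracle)^2)) / sqrt(mean(oracle^2))
  expect_lte(nrmsd, 0.05)

  # interior of the reconstructed disk recovers the signal amplitude
  s <- spgr_signal(sq, tis, 1L)
  x <- (seq_len(G) - G / 2 - 1) * fov / G
  interior <- outer(x^2, x^2, "+") < 40^2
  expect_lt(abs(mean(pd$image[interior]) - s) / s, 0.05)

  # bitwise-repeatable and zero-preserving
  expect_identical(grid_reconstruct(ks, cfg)$image, pd$image)
  ks0 <- ks
  ks0$data[] <- 0 + 0i
  expect_equal(max(grid_reconstruct(ks0, cfg)$image), 0)
  expect_error(grid_reconstruct(structure(list(data = complex(0)),
                                          class = "radial_kspace"), cfg),
               "empty")
})

test_that("full-chain reconstruction is linear in phantom proton density", {
  sq <- seq_params()
  fov <- 256
  G <- 32
  tr <- golden_angle_trajectory(64, G + 1L, nyquist_kmax(G, fov))
  cfg <- recon_config(grid_size_px = G)
  x <- (seq_len(G) - G / 2 - 1) * fov / G
  interior <- outer(x^2, x^2, "+") < 40^2
  means <- vapply(c(0.25, 0.5, 1), function(pdv) {
    ph <- make_disk_phantom(radius_mm = 60,
                            tissue = tissue_params(pdv, 1200, 25),
                            pixel_size_mm = fov / 128, grid_px = 128)
    mean(grid_reconstruct(sample_kspace(ph, sq, tr), cfg)$image[interior])
  }, numeric(1))
  expect_equal(means[2] / means[1], 2, tolerance = 0.01)
  expect_equal(means[3] / means[1], 4, tolerance = 0.01)
})

test_that("spoke-consistency filter keeps static data and flags jitter bursts", {
  setup <- default_thorax_setup()
  ks_static <- sample_kspace(setup$slice, setup$seq, setup$traj)
  f0 <- spoke_consistency_filter(ks_static)
  expect_equal(f0$rejected_spoke_fraction, 0)
  expect_true(all(f0$weights == 1))

  mo <- motion_model(jitter_amplitude_mm = 15, jitter_burst_probability = 0.2,
                     seed = 2)
  ks_mov <- sample_kspace(setup$slice, setup$seq, setup$traj, motion = mo)
  f1 <- spoke_consistency_filter(ks_mov)
  expect_gte(f1$rejected_spoke_fraction, 0.1)
  expect_lte(f1$rejected_spoke_fraction, 0.3)

  # infinite threshold keeps everything and reproduces the unfiltered image
  f_inf <- spoke_consistency_filter(ks_mov, threshold = Inf)
  expect_true(all(f_inf$weights == 1))
  cfg_inf <- recon_config(grid_size_px = setup$G, motion_filter_enabled = TRUE,
                          motion_filter_threshold = Inf)
  cfg_off <- recon_config(grid_size_px = setup$G)
  expect_equal(grid_reconstruct(ks_mov, cfg_inf)$image,
               grid_reconstruct(ks_mov, cfg_off)$image, tolerance = 1e-12)

  tr_small <- golden_angle_trajectory(4, 9, 0.05)
  ks_small <- sample_kspace(make_disk_phantom(pixel_size_mm = 4, grid_px = 64),
                            setup$seq, tr_small)
  expect_error(spoke_consistency_filter(ks_small), "at least 8")
})

test_that("TE=0 extrapolation recovers mono-exponential decay exactly", {
  tes <- c(0.1, 1.2, 2.3)
  s0 <- matrix(runif(16 * 16, 0.5, 2), 16, 16)
  t2s <- matrix(runif(16 * 16, 0.8, 30), 16, 16)
  stack <- array(0, c(16, 16, 3))
  for (e in 1:3) stack[, , e] <- s0 * exp(-tes[e] / t2s)
  ex <- lungwater:::te0_extrapolate(stack, tes)
  expect_equal(ex$image, s0, tolerance = 1e-10)
  expect_false(any(ex$fallback_mask))

  # identical echoes: zero decay returns the first-echo image
  flat <- array(rep(s0, 3), c(16, 16, 3))
  exf <- lungwater:::te0_extrapolate(flat, tes)
  expect_equal(exf$image, s0, tolerance = 1e-10)

  # zero pixels fall back to the first echo and are flagged
  stack0 <- stack
  stack0[1, 1, ] <- 0
  ex0 <- lungwater:::te0_extrapolate(stack0, tes)
  expect_true(ex0$fallback_mask[1, 1])
  expect_equal(ex0$image[1, 1], 0)
})

test_that("multiecho reconstruction modes are consistent", {
  sq <- seq_params()
  fov <- 256
  G <- 32
  ph <- make_disk_phantom(radius_mm = 60, tissue = tissue_params(0.5, 1200, 5),
                          pixel_size_mm = fov / 128, grid_px = 128)
  tr <- golden_angle_trajectory(64, G + 1L, nyquist_kmax(G, fov))
  ks <- sample_kspace(ph, sq, tr)

  pd_first <- reconstruct_pd(ks, recon_config(grid_size_px = G))
  expect_equal(pd_first$image, grid_reconstruct(ks, recon_config(grid_size_px = G))$image)

  pd_ex <- reconstruct_pd(ks, recon_config(grid_size_px = G,
                                           echo_combine = "te0_extrapolation"))
  # extrapolated interior approaches the decay-free steady-state amplitude
  a <- sq$flip_angle_deg * pi / 180
  e1 <- exp(-sq$tr_ms / 1200)
  s_no_decay <- 0.5 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
  x <- (seq_len(G) - G / 2 - 1) * fov / G
  interior <- outer(x^2, x^2, "+") < 40^2
  expect_lt(abs(mean(pd_ex$image[interior]) - s_no_decay) / s_no_decay, 0.05)

  ks1 <- ks
  ks1$data <- ks$data[, , 1, drop = FALSE]
  expect_error(reconstruct_pd(ks1, recon_config(grid_size_px = G,
                                                echo_combine = "te0_extrapolation")),
               "at least 2")
})
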