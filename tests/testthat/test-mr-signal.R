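# Spoiled gradient-echo signal model and Bloch-equation simulator

test_that("closed-form signal honours limiting cases and proportionality", {
  # fully relaxed 90 degree excitation at TE = 0 yields the full magnetization
  sq90 <- seq_params(flip_angle_deg = 90, tr_ms = 1e6,
                     echo_times_ms = c(0, 1))
  tis <- tissue_params(1, t1_ms = 1000, t2star_ms = 50)
  expect_equal(spgr_signal(sq90, tis, 1L), 1, tolerance = 1e-10)

  # zero proton density gives zero signal at any setting
  sq5 <- seq_params()
  expect_identical(spgr_signal(sq5, tissue_params(0, 1200, 1)), 0)

  # exact proportionality in proton density
  base <- spgr_signal(sq5, tissue_params(0.2, 1200, 1))
  for (c_scale in c(0.5, 1, 2.5, 4)) {
    expect_equal(spgr_signal(sq5, tissue_params(0.2 * c_scale, 1200, 1)),
                 c_scale * base, tolerance = 1e-12)
  }

  # signal strictly decreasing in echo time
  s_te <- vapply(1:3, function(e)
    spgr_signal(sq5, tissue_params(0.3, 1200, 1), e), numeric(1))
  expect_true(all(diff(s_te) < 0))
})

test_that("validation rejects bad sequence, tissue and echo inputs", {
  expect_error(seq_params(flip_angle_deg = 0), "flip_angle_deg")
  expect_error(seq_params(echo_times_ms = c(1, 1)), "strictly increasing")
  expect_error(seq_params(echo_times_ms = c(0.1, 6), tr_ms = 5), "tr_ms")
  expect_error(tissue_params(0.3, t1_ms = -1, t2star_ms = 1), "t1_ms")
  expect_error(tissue_params(0.3, t1_ms = 1, t2star_ms = 2), "t2star_ms")
  expect_error(spgr_signal(seq_params(), tissue_params(0.3, 1200, 1), 7L),
               "echo_index")
})

test_that("Bloch steady state matches the closed form across a parameter grid", {
  # reference case from the sequence's design point
  sq <- seq_params()
  tis <- tissue_params(0.3, t1_ms = 1200, t2star_ms = 1)
  bl <- bloch_simulate(sq, tis)
  expect_true(bl$converged)
  expect_length(bl$mz_trajectory, sq$n_prep_reps)
  expect_equal(bl$signal_per_echo[1], spgr_signal(sq, tis, 1L),
               tolerance = 1e-3)

  for (alpha in c(2, 5, 15, 40)) {
    for (tr in c(3, 5, 10)) {
      for (t1 in c(500, 1200, 3000)) {
        sqg <- seq_params(alpha, tr, c(0.1, tr / 2),
                          n_prep_reps = ceiling(18 * t1 / tr))
        tig <- tissue_params(0.7, t1, 20)
        blg <- bloch_simulate(sqg, tig)
        for (e in 1:2) {
          expect_equal(blg$signal_per_echo[e], spgr_signal(sqg, tig, e),
                       tolerance = 1e-3)
        }
      }
    }
  }
})

test_that("Bloch simulator handles zero flip, linearity in PD, and non-convergence", {
  tis <- tissue_params(0.5, 1200, 20)
  sq0 <- seq_params(flip_angle_deg = 1e-9)
  expect_lt(max(bloch_simulate(sq0, tis)$signal_per_echo), 1e-9)

  sq <- seq_params()
  s1 <- bloch_simulate(sq, tissue_params(0.25, 1200, 20))$signal_per_echo
  s2 <- bloch_simulate(sq, tissue_params(0.5, 1200, 20))$signal_per_echo
  expect_equal(s2, 2 * s1, tolerance = 1e-12)

  sq_short <- seq_params(n_prep_reps = 10)
  expect_warning(res <- bloch_simulate(sq_short,
                                       tissue_params(0.5, 3000, 20)),
                 "steady state")
  expect_false(res$converged)
})

test_that("small-angle limit removes the T1 dependence", {
  sq <- seq_params(flip_angle_deg = 0.1)
  a <- 0.1 * pi / 180
  lims <- vapply(c(500, 1200, 3000), function(t1) {
    spgr_signal(sq, tissue_params(0.4, t1, 10), 1L) / sin(a)
  }, numeric(1))
  # residual T1 dependence is second order in the flip angle
  expect_equal(lims, rep(0.4 * exp(-sq$echo_times_ms[1] / 10), 3),
               tolerance = 2e-3)
  expect_lt(diff(range(lims)) / mean(lims), 1e-3)
})

test_that("lung tissue model interpolates relaxation rates in water fraction", {
  an <- lung_anchors()
  full <- lung_tissue_model(1)
  expect_equal(full$proton_density, 1)
  expect_equal(full$t1_ms, an$t1_water_ms)
  expect_equal(full$t2star_ms, an$t2star_water_ms)

  dry <- lung_tissue_model(0)
  expect_equal(dry$proton_density, 0)
  expect_equal(dry$t1_ms, an$t1_dry_ms)

  # at the midpoint the rate is the arithmetic mean of the anchor rates
  mid <- lung_tissue_model(0.5)
  expect_equal(1 / mid$t1_ms,
               (1 / an$t1_dry_ms + 1 / an$t1_water_ms) / 2,
               tolerance = 1e-12)
  expect_error(lung_tissue_model(1.2), "water_fraction")
})

test_that("low flip angle preserves signal-water linearity; saturation breaks it", {
  rep5 <- linearity_scan(seq_params())
  expect_gte(rep5$pearson_r, 0.99)
  expect_false(rep5$nonlinear_flag)
  expect_gt(rep5$slope, 0)

  rep90 <- linearity_scan(seq_params(flip_angle_deg = 90))
  expect_lt(rep90$pearson_r, rep5$pearson_r)

  expect_error(linearity_scan(seq_params(), water_fractions = c(0.1, 0.4)),
               "at least 3")

  # monotone increasing signal in water fraction for low flip angles
  for (alpha in c(2, 5, 10)) {
    sq <- seq_params(flip_angle_deg = alpha)
    s <- vapply(seq(0.05, 0.6, by = 0.05), function(w)
      spgr_signal(sq, lung_tissue_model(w), 1L), numeric(1))
    expect_true(all(diff(s) > 0))
  }
})
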