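# Volume-time-curve metrics, reserve deltas, and PCr/ATP corrections

make_cosine_curve <- function(n = 200, edv = 130, sv = 60, period_ms = 1000,
                              noise_sd = 0, seed = NULL) {
  t <- seq(0, period_ms, length.out = n + 1)[1:n]
  v <- (edv - sv / 2) + (sv / 2) * cos(2 * pi * t / period_ms)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    v <- v + rnorm(n, 0, noise_sd)
  }
  volume_time_curve(t, pmax(v, 1), chamber = "LV")
}

test_that("peak filling rate matches the analytic cosine derivative", {
  # V(t) = 100 + 30 cos(2 pi t / T): peak dV/dt = 60 pi mL/s
  cur <- make_cosine_curve()
  peak <- peak_filling_rate(cur)
  expect_equal(peak, 60 * pi, tolerance = 0.015)

  per_edv <- peak_filling_rate(cur, normalization = "per_edv")
  expect_equal(per_edv, peak / 130, tolerance = 1e-9)

  # invariant to adding a constant volume; linear under volume scaling
  cur_off <- volume_time_curve(cur$times_ms, cur$volumes_ml + 50)
  expect_equal(peak_filling_rate(cur_off), peak, tolerance = 1e-9)
  cur_x2 <- volume_time_curve(cur$times_ms, cur$volumes_ml * 2)
  expect_equal(peak_filling_rate(cur_x2), 2 * peak, tolerance = 1e-9)
  expect_equal(peak_filling_rate(cur_x2, normalization = "per_edv"),
               peak_filling_rate(cur, normalization = "per_edv"),
               tolerance = 1e-9)

  mono <- volume_time_curve(seq(0, 900, length.out = 12),
                            seq(130, 70, length.out = 12))
  expect_error(peak_filling_rate(mono), "filling limb")
})

test_that("noisy 30-phase curves recover the analytic peak within 10%", {
  peaks <- vapply(1:20, function(sd) {
    peak_filling_rate(make_cosine_curve(n = 30, noise_sd = 1, seed = sd))
  }, numeric(1))
  expect_lt(abs(mean(peaks) - 60 * pi) / (60 * pi), 0.10)
})

test_that("chamber summary identities hold exactly", {
  cur <- make_cosine_curve()
  cs <- chamber_summary(cur)
  expect_equal(cs$edv_ml, 130, tolerance = 1e-6)
  expect_equal(cs$esv_ml, 70, tolerance = 1e-6)
  expect_equal(cs$sv_ml, cs$edv_ml - cs$esv_ml)
  expect_equal(cs$ef_percent, 100 * cs$sv_ml / cs$edv_ml)
  expect_equal(cs$ef_percent, 46.1538, tolerance = 1e-4)
  expect_equal(cs$sv_esv_ratio, 6 / 7, tolerance = 1e-6)

  flat <- volume_time_curve(seq(0, 900, length.out = 12), rep(100, 12))
  csf <- chamber_summary(flat)
  expect_equal(csf$sv_ml, 0)
  expect_equal(csf$ef_percent, 0)
})

test_that("reserve metrics are stress-minus-rest deltas", {
  rest <- chamber_summary(make_cosine_curve(edv = 130, sv = 60))
  stress <- chamber_summary(make_cosine_curve(edv = 140, sv = 80))
  d <- reserve_metrics(rest, stress,
                       rest_extra = c(ra_vol = 50),
                       stress_extra = c(ra_vol = 62))
  expect_equal(d$delta_edv_ml, 10, tolerance = 1e-6)
  expect_equal(d$delta_ra_vol, 12)
  expect_equal(d$delta_ef_percent,
               stress$ef_percent - rest$ef_percent)

  same <- reserve_metrics(rest, rest)
  expect_true(all(abs(unlist(same)) < 1e-12))

  rv <- chamber_summary(volume_time_curve(make_cosine_curve()$times_ms,
                                          make_cosine_curve()$volumes_ml,
                                          chamber = "RV"))
  expect_error(reserve_metrics(rest, rv), "mismatch")
})

test_that("PCr/ATP ratio applies saturation and blood corrections", {
  plain <- pcr_atp_ratio(energetics_measurement(2, 1))
  expect_equal(plain$pcr_atp_corrected, 2)

  # blood correction removes 0.4 * 0.5 from the ATP amplitude
  bc <- pcr_atp_ratio(energetics_measurement(2, 1.2, dpg_amp = 0.5,
                                             blood_coefficient = 0.4))
  expect_equal(bc$pcr_atp_corrected, 2)

  sat <- pcr_atp_ratio(energetics_measurement(2, 1, sat_factor_pcr = 1.2,
                                              sat_factor_atp = 0.8))
  expect_equal(sat$pcr_atp_corrected, 2 * 1.2 / 0.8)

  expect_error(pcr_atp_ratio(energetics_measurement(2, 1, dpg_amp = 2.5,
                                                    blood_coefficient = 0.4)),
               "non-positive ATP")
})

test_that("volume curves round-trip through CSV", {
  cur <- make_cosine_curve(n = 30)
  df <- data.frame(phase_ms = cur$times_ms, volume_ml = cur$volumes_ml,
                   chamber = "LV", condition = "rest")
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  curves <- read_volume_curves(path)
  expect_named(curves, "LV_rest")
  expect_equal(curves$LV_rest$volumes_ml, cur$volumes_ml)
  unlink(path)
})
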