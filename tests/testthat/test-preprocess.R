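test_that("optical density is zero for constant traces and gain invariant", {
  lay <- tiny_layout(2)
  ints <- array(runif(2 * 2 * 100, 500, 1500), c(2, 2, 100))
  const <- array(rep(c(800, 900, 1000, 1100), times = 100), c(2, 2, 100))
  od_const <- intensity_to_od(nirs_recording(lay, const, 25))
  expect_equal(max(abs(od_const$od)), 0)

  od1 <- intensity_to_od(nirs_recording(lay, ints, 25))
  od2 <- intensity_to_od(nirs_recording(lay, ints * 3.7, 25))
  expect_equal(od1$od, od2$od, tolerance = 1e-12)
  # zero temporal mean by construction
  expect_lt(max(abs(apply(od1$od, 1:2, mean))), 1e-12)
})

test_that("a halved intensity sample produces dOD = log 2", {
  lay <- tiny_layout(1)
  n <- 2000
  ints <- array(1, c(1, 2, n))
  ints[1, 1, 77] <- 0.5
  od <- intensity_to_od(nirs_recording(lay, ints, 25))
  expect_equal(od$od[1, 1, 77], log(2), tolerance = 1e-3)  # baseline ~1
  expect_lt(abs(od$od[1, 1, 10]), 1e-3)
})

test_that("Beer-Lambert inversion is the exact inverse of the forward model", {
  set.seed(4)
  hbo <- matrix(rnorm(600), 3)
  hbr <- matrix(rnorm(600, sd = 0.3), 3)
  od <- hemoglobin_to_od(hbo, hbr)
  ods <- structure(list(od = od, sampling_rate = 25, wavelengths = c(690, 830),
                        layout = tiny_layout(3)), class = "od_series")
  hb <- od_to_hemoglobin(ods)
  expect_lt(max(abs(hb$hbo - hbo)), 1e-10)
  expect_lt(max(abs(hb$hbr - hbr)), 1e-10)

  # zero in, zero out
  ods$od[] <- 0
  hb0 <- od_to_hemoglobin(ods)
  expect_equal(max(abs(hb0$hbo)), 0)
  expect_equal(max(abs(hb0$hbr)), 0)
})

test_that("swapping wavelength rows of dOD and extinction leaves output unchanged", {
  set.seed(5)
  hbo <- matrix(rnorm(200), 1); hbr <- matrix(rnorm(200, sd = .3), 1)
  E <- extinction_coefficients()
  od <- hemoglobin_to_od(hbo, hbr, extinction = E)
  mk <- function(odarr, wl, lay_wl) {
    lay <- tiny_layout(1); lay$wavelengths <- lay_wl
    structure(list(od = odarr, sampling_rate = 25, wavelengths = wl,
                   layout = lay), class = "od_series")
  }
  hb1 <- od_to_hemoglobin(mk(od, c(690, 830), c(690, 830)), extinction = E)
  od_sw <- od[, 2:1, , drop = FALSE]
  hb2 <- od_to_hemoglobin(mk(od_sw, c(830, 690), c(830, 690)),
                          extinction = E[2:1, ], dpf = c(6, 6))
  expect_equal(hb1$hbo, hb2$hbo, tolerance = 1e-12)
  expect_equal(hb1$hbr, hb2$hbr, tolerance = 1e-12)
})

test_that("a singular extinction table is rejected", {
  E <- rbind(`690` = c(HbO = 1, HbR = 2), `830` = c(HbO = 2, HbR = 4))
  ods <- structure(list(od = array(1, c(1, 2, 10)), sampling_rate = 25,
                        wavelengths = c(690, 830), layout = tiny_layout(1)),
                   class = "od_series")
  expect_error(od_to_hemoglobin(ods, extinction = E), "singular")
})

test_that("resampling has the defined length, preserves slow content and the mean", {
  t25 <- (0:(25 * 250 - 1)) / 25
  x <- sin(2 * pi * 0.05 * t25) + 2
  hb <- as_hb(matrix(x, 1), rate = 25)
  r2 <- resample_hemoglobin(hb, 2)
  expect_equal(ncol(r2$hbo), 500)
  expect_equal(r2$sampling_rate, 2)
  # identity at the current rate
  expect_identical(resample_hemoglobin(hb, 25), hb)
  # 0.05 Hz sinusoid survives 25 -> 4 Hz with <1% amplitude loss
  r4 <- resample_hemoglobin(hb, 4)
  amp_in <- diff(range(x)); amp_out <- diff(range(r4$hbo[1, 100:900]))
  expect_gt(amp_out / amp_in, 0.99)
  # mean preserved within 1%
  expect_lt(abs(mean(r4$hbo[1, ]) - mean(x)) / abs(mean(x)), 0.01)
  expect_error(resample_hemoglobin(hb, 0), "target_hz")
  expect_error(resample_hemoglobin(hb, 50), "target_hz")
})

test_that("band-pass keeps in-band tones and rejects out-of-band tones", {
  t4 <- (0:(4 * 600 - 1)) / 4
  s05 <- sin(2 * pi * 0.05 * t4)
  s03 <- sin(2 * pi * 0.3 * t4)
  k05 <- sd(bandpass_filter(s05, 0.01, 0.08, 4)) / sd(s05)
  k03 <- sd(bandpass_filter(s03, 0.01, 0.08, 4)) / sd(s03)
  expect_gt(k05, 0.95)       # passband attenuation < 5%
  expect_lt(k03, 0.10)       # respiratory-band tone rejected by the low band
  # an octave beyond the upper edge: > 90% attenuation
  s16 <- sin(2 * pi * 0.16 * t4)
  expect_lt(sd(bandpass_filter(s16, 0.01, 0.08, 4)) / sd(s16), 0.10)
  expect_equal(max(abs(bandpass_filter(numeric(1000), 0.01, 0.08, 4))), 0)
  expect_error(bandpass_filter(s05, 0.5, 3, 4), "infeasible")
  expect_error(bandpass_filter(s05, 0.2, 0.1, 4), "infeasible")
})
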