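test_that("two-site Stern-Volmer model has its defining identities", {
  cal <- sv_calibration(f1 = 0.8, Ksv = 0.05, R0 = 2)
  expect_equal(sv_forward(0, cal), 1)                       # f1 + f2
  expect_equal(sv_forward(1e9, cal), cal$f2, tolerance = 1e-6)
  expect_equal(sv_forward(19, cal), 0.8 / 1.95 + 0.2, tolerance = 1e-12)
  o2 <- seq(0, 25, by = 0.5)
  expect_true(all(diff(sv_forward(o2, cal)) < 0))           # strictly decreasing
  expect_error(sv_forward(-1, cal), "domain error")
  expect_error(sv_calibration(f1 = 1.2), "f1")
  expect_error(sv_calibration(Ksv = -1), "Ksv")
})

test_that("inversion is the exact inverse on the physical band", {
  for (cal in list(sv_calibration(0.8, 0.05, 2),
                   sv_calibration(0.93, 0.11, 1.4))) {
    o2 <- c(0, 0.3, 7.3, 19, 40)
    back <- sv_invert(sv_forward(o2, cal), cal)
    expect_equal(back$O2_percent, o2, tolerance = 1e-10)
    expect_true(all(back$qc_flag == "ok"))
  }
  cal <- sv_calibration(0.8, 0.05, 2)
  hi <- sv_invert(1.02, cal)
  expect_equal(hi$O2_percent, 0)
  expect_equal(hi$qc_flag, "clamped")
  lo <- sv_invert(cal$f2 * 0.99, cal)
  expect_true(is.na(lo$O2_percent))
  expect_equal(lo$qc_flag, "out_of_range")
})

test_that("two-point calibration solves Ksv exactly from the 19% level", {
  tru <- sv_calibration(f1 = 0.8, Ksv = 0.063, R0 = 2.2)
  pts <- data.frame(O2 = c(0, 0, 19, 19),
                    R = tru$R0 * sv_forward(c(0, 0, 19, 19), tru))
  cal <- calibrate(pts, mode = "two_point", f1_fixed = 0.8)
  expect_equal(cal$Ksv, tru$Ksv, tolerance = 1e-12)
  expect_equal(cal$R0, tru$R0)
  expect_equal(cal$f1 + cal$f2, 1)
  expect_error(calibrate(data.frame(O2 = c(5, 19), R = c(1.5, 1.2))),
               "zero-oxygen")
})

test_that("multi-point fit recovers the generating parameters", {
  tru <- sv_calibration(f1 = 0.85, Ksv = 0.04, R0 = 1.8)
  lv <- c(0, 5, 10, 19)
  pts <- data.frame(O2 = lv, R = tru$R0 * sv_forward(lv, tru))
  fit <- calibrate(pts, mode = "multi_point")
  expect_equal(fit$f1, 0.85, tolerance = 1e-6)
  expect_equal(fit$Ksv, 0.04, tolerance = 1e-6)
  expect_error(calibrate(data.frame(O2 = c(0, 19), R = c(1.8, 1.2)),
                         mode = "multi_point"), "identifiability")
})

test_that("multi-point recovery is unbiased under 1% noise (50 seeded reps)", {
  tru <- sv_calibration(f1 = 0.85, Ksv = 0.04, R0 = 1.8)
  lv <- rep(c(0, 5, 10, 19), each = 3)
  R_clean <- tru$R0 * sv_forward(lv, tru)
  fits <- withr::with_seed(101, {
    replicate(50, {
      pts <- data.frame(O2 = lv, R = R_clean * (1 + rnorm(length(lv), 0, 0.01)))
      cal <- calibrate(pts, mode = "multi_point")
      c(cal$f1, cal$Ksv)
    })
  })
  expect_equal(mean(fits[1, ]), 0.85, tolerance = 0.05)
  expect_equal(mean(fits[2, ]), 0.04, tolerance = 0.05)
})

test_that("ratio extraction is mean-red over mean-green per ROI disk", {
  H <- 41; W <- 41
  mk <- function(red, green) {
    fr <- array(0, dim = c(H, W, 3))
    fr[, , 1] <- red; fr[, , 2] <- green
    fr
  }
  rt <- data.frame(roi_id = 1, x_px = 20.5, y_px = 21, radius_px = 8,
                   zone = 1)
  stack <- list(frames = list(mk(120, 60)), timestamps = 0, roi_table = rt,
                bit_depth = 8)
  expect_equal(extract_ratios(stack)$R, 2)
  # half-disk at 100 / half at 200: means before the ratio -> 1.5
  red <- matrix(100, H, W); red[, 21:W] <- 200
  stack$frames <- list(mk(red, 100))
  expect_equal(extract_ratios(stack)$R, 1.5)
  # brute-force oracle on an arbitrary pattern
  set.seed(7)
  red <- matrix(runif(H * W, 50, 200), H, W)
  green <- matrix(runif(H * W, 40, 120), H, W)
  stack$frames <- list(mk(red, green))
  want <- disk_mean_brute(red, 20.5, 21, 8) / disk_mean_brute(green, 20.5, 21, 8)
  expect_equal(extract_ratios(stack)$R, want, tolerance = 1e-12)
  # zero reference channel flags but does not fail
  stack$frames <- list(mk(red, 0))
  out <- extract_ratios(stack)
  expect_true(is.na(out$R))
  expect_equal(out$qc_flag, "zero_reference")
  expect_error(extract_ratios(list(frames = list(mk(1, 1)),
                                   roi_table = NULL)), "ROI table")
})

test_that("per-ROI calibrations apply with a warned global fallback", {
  cal1 <- sv_calibration(0.8, 0.05, 2)
  cal2 <- sv_calibration(0.85, 0.04, 1.8)
  ratios <- data.frame(time_s = 0, roi_id = c(1, 2),
                       R = c(cal1$R0 * sv_forward(10, cal1),
                             cal2$R0 * sv_forward(4, cal2)),
                       qc_flag = "ok")
  out <- ratios_to_oxygen(ratios, list("1" = cal1, "2" = cal2))
  expect_equal(out$O2_percent, c(10, 4), tolerance = 1e-10)
  expect_warning(
    out2 <- ratios_to_oxygen(ratios, list("1" = cal1, global = cal1)),
    "global")
  expect_equal(out2$O2_percent[1], 10, tolerance = 1e-10)
})

test_that("bleaching flag needs persistent supra-physical readings", {
  base <- expand.grid(time_s = seq(0, 5400, by = 600), roi_id = 1:3)
  base$O2_percent <- 15
  base$qc_flag <- "ok"
  # ROI 2 ramps above 21% for 5 consecutive frames -> excluded wholesale
  sel <- base$roi_id == 2 & base$time_s >= 1800 & base$time_s <= 4200
  base$O2_percent[sel] <- 25
  out <- flag_bleached(base)
  expect_true(all(out$qc_flag[out$roi_id == 2] == "bleached"))
  expect_true(all(out$qc_flag[out$roi_id != 2] == "ok"))
  # a single-frame spike survives
  spike <- base
  spike$O2_percent[] <- 15
  spike$O2_percent[spike$roi_id == 3 & spike$time_s == 1200] <- 25
  expect_true(all(flag_bleached(spike)$qc_flag == "ok"))
})

test_that("response time interpolates the 90% excursion crossing", {
  # instantaneous step between two 10-min frames: at most one interval
  tstep <- c(0, 600, 1200, 1800, 2400, 3000)
  o2 <- c(19, 19, 0, 0, 0, 0)
  rt <- response_time(tstep, o2, plateau_frames = 1, t0 = 600)
  expect_lte(rt, 10)
  expect_gte(rt, 0)
  # exponential decay: t90 = tau ln(10)
  tau <- 300
  tt <- seq(0, 3600, by = 10)
  rexp <- response_time(tt, 19 * exp(-tt / tau), plateau_frames = 1)
  expect_equal(rexp * 60, tau * log(10), tolerance = 10 / (tau * log(10)))
  # flat series: no step detected
  expect_true(is.na(response_time(tt, rep(10, length(tt)))))
})
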