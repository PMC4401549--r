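make_beads <- function(gain = 1, noise = 0, channels = c("CD45", "cPARP"),
                       ref = c(806, 2159, 5824, 15638, 42000, 112000,
                               301000, 810000)) {
  chans <- lapply(setNames(channels, channels), function(ch)
    lapply(ref, function(r)
      if (noise == 0) rep(r * gain, 50) else rlnorm(200, log(r * gain), noise)))
  structure(list(plate = 1, reference_erf = ref, channels = chans),
            class = "scnp_beads")
}

test_that("identity beads fit slope 1 and intercept 0", {
  cal <- fit_erf_calibration(make_beads(gain = 1))
  expect_equal(cal$slope, rep(1, 2), tolerance = 1e-10)
  expect_equal(cal$intercept, rep(0, 2), tolerance = 1e-10)
  expect_equal(cal$r_squared, rep(1, 2), tolerance = 1e-10)
})

test_that("a 2x gain fits intercept log10(2) at slope 1", {
  cal <- fit_erf_calibration(make_beads(gain = 2))
  expect_equal(cal$slope, rep(1, 2), tolerance = 1e-10)
  expect_equal(cal$intercept, rep(log10(2), 2), tolerance = 1e-10)
})

test_that("noisy beads recover the calibration line within regression error", {
  set.seed(81)
  covered <- replicate(40, {
    b <- make_beads(gain = 1.5, noise = 0.05, channels = "CD45")
    med <- sapply(b$channels$CD45, median)
    fit <- lm(log10(med) ~ log10(b$reference_erf))
    se <- summary(fit)$coefficients[2, 2]
    cal <- fit_erf_calibration(b)
    abs(cal$slope - 1) <= 3 * se
  })
  expect_gte(mean(covered), 0.9)
})

test_that("calibration refuses unusable bead data", {
  b <- make_beads()
  b$channels$CD45 <- lapply(b$channels$CD45, function(x) x * 0) # zero medians
  expect_error(fit_erf_calibration(b), "resolvable peaks")
  b2 <- make_beads()
  expect_error(fit_erf_calibration(b2, saturation = 5000), "resolvable peaks")
  b3 <- make_beads()
  b3$reference_erf <- b3$reference_erf[1:5]
  expect_error(fit_erf_calibration(b3), "8 bead peaks")
})

test_that("applying a calibration preserves rank order and undoes plate gains", {
  set.seed(82)
  ev <- function(gain) {
    d <- data.frame(FSC = rlnorm(3000, 10, 0.3), SSC = rlnorm(3000, 9, 0.3),
                    CD45 = gain * rlnorm(3000, 6, 0.5),
                    cPARP = gain * rlnorm(3000, 5, 0.5))
    scnp_events(d, "w", "p", "BM", "unmodulated", 0.25)
  }
  cal1 <- fit_erf_calibration(make_beads(gain = 1, noise = 0.02))
  cal2 <- fit_erf_calibration(make_beads(gain = 2, noise = 0.02))
  raw1 <- ev(1); raw2 <- ev(2)
  e1 <- apply_calibration(raw1, cal1)
  e2 <- apply_calibration(raw2, cal2)
  expect_identical(e1$scale, "ERF")
  # identity-gain calibration leaves values essentially unchanged
  expect_equal(e1$data$CD45, raw1$data$CD45, tolerance = 0.05)
  # order preservation per channel
  expect_identical(order(e2$data$CD45), order(raw2$data$CD45))
  # two plates with gains 1x and 2x agree after calibration
  expect_lt(abs(log(median(e1$data$CD45) / median(e2$data$CD45))), 0.05)
})

test_that("calibrations round-trip through JSON with diagnostics intact", {
  set.seed(83)
  cal <- fit_erf_calibration(make_beads(gain = 1.7, noise = 0.03))
  path <- file.path(tempdir(), "cal.json")
  write_calibration(cal, path)
  back <- read_calibration(path)
  expect_equal(back$slope, cal$slope, tolerance = 1e-12)
  expect_equal(back$intercept, cal$intercept, tolerance = 1e-12)
  expect_identical(back$channel, cal$channel)
  expect_equal(attr(back, "plate"), attr(cal, "plate"))
  d <- data.frame(FSC = rlnorm(50, 10, 0.3), CD45 = rlnorm(50, 6, 0.5))
  e <- scnp_events(d, "w", "p", "BM", "unmodulated", 0.25)
  expect_equal(apply_calibration(e, back)$data$CD45,
               apply_calibration(e, cal)$data$CD45, tolerance = 1e-12)
  expect_error(read_calibration(file.path(tempdir(), "nope.json")), "not found")
})

test_that("uncalibrated channels are an error, scatter passes through", {
  cal <- fit_erf_calibration(make_beads(channels = "CD45"))
  d <- data.frame(FSC = rlnorm(100, 10, 0.3), CD45 = rlnorm(100, 6, 0.5),
                  pAKT = rlnorm(100, 5, 0.5))
  e <- scnp_events(d, "w", "p", "BM", "unmodulated", 0.25)
  expect_error(apply_calibration(e, cal), "uncalibrated channel")
  d2 <- d[c("FSC", "CD45")]
  e2 <- scnp_events(d2, "w", "p", "BM", "unmodulated", 0.25)
  out <- apply_calibration(e2, cal)
  expect_identical(out$data$FSC, d2$FSC)
  expect_error(apply_calibration(out, cal), "already")
})
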