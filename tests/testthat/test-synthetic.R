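test_that("generation is deterministic per recipe and seed", {
  r <- signal_recipe(duration = 10, seed = 42)
  s1 <- generate_signal(r)
  s2 <- generate_signal(r)
  expect_identical(s1, s2)
  s3 <- generate_signal(signal_recipe(duration = 10, seed = 43))
  expect_false(identical(s1$az, s3$az))
  # the generator leaves the global RNG stream untouched
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(generate_signal(r)); after <- runif(3)
  expect_identical(before, after)
})

test_that("a pure vertical tone reproduces the weighting-gain oracle", {
  r <- signal_recipe(duration = 30, fs = 512,
                     tones = data.frame(freq = 5, amp = 1),
                     broadband = list(low = 0.5, high = 20, level = 0),
                     shock = list(rate = 0, amplitude = 0, decay = 0.25,
                                  carrier = 4),
                     target_rms = NULL, axis_ratios = c(0, 0, 1), seed = 2)
  sig <- generate_signal(r)
  w <- apply_weighting(sig)
  n <- length(w$az)
  # frozen analog gain |H_Wk(5 Hz)| = 1.038826; amplitude 1 tone
  expect_equal(weighted_rms(w$az[seq(n / 2, n)]), 1.038826 / sqrt(2),
               tolerance = 0.01)
  expect_true(all(sig$ax == 0) && all(sig$ay == 0))
})

test_that("zero amplitudes give a zero signal", {
  r <- signal_recipe(duration = 5,
                     tones = data.frame(freq = 5, amp = 0),
                     broadband = list(low = 0.5, high = 20, level = 0),
                     shock = list(rate = 0, amplitude = 0, decay = 0.25,
                                  carrier = 4),
                     target_rms = NULL, seed = 1)
  sig <- generate_signal(r)
  expect_true(all(sig$az == 0) && all(sig$ax == 0))
})

test_that("calibration hits the target weighted resultant RMS within 2%", {
  for (seed in 1:5) {
    sig <- generate_signal(signal_recipe(duration = 30, seed = seed))
    aren <- wbv_assess(sig)$aren
    expect_lt(abs(aren - 0.5) / 0.5, 0.02)
  }
})

test_that("an unreachable RMS target is reported as infeasible", {
  r <- signal_recipe(duration = 30, seed = 1, target_rms = 0.01,
                     shock = list(rate = 30, amplitude = 5, decay = 0.3,
                                  carrier = 4))
  expect_error(generate_signal(r), "infeasible")
})

test_that("the dose grows with the shock rate at fixed weighted RMS", {
  vdv_at_rate <- function(rate, seed) {
    r <- signal_recipe(duration = 60, seed = seed,
                       shock = list(rate = rate, amplitude = 3, decay = 0.25,
                                    carrier = 4))
    wbv_assess(generate_signal(r))$vdvr
  }
  seeds <- 1:5
  med <- vapply(c(0, 3, 8), function(rate)
    stats::median(vapply(seeds, function(s) vdv_at_rate(rate, s),
                         numeric(1))), numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("spectral ranking finds the dominant vertical frequencies", {
  sig <- generate_signal(signal_recipe(duration = 30, seed = 11))
  bands <- spectrum_peaks(sig)
  in_band <- function(row, f) bands$low[row] <= f && f < bands$high[row]
  expect_true(in_band(1, 5))
  top3 <- vapply(c(3, 4, 5), function(f)
    any(vapply(1:3, in_band, logical(1), f = f)), logical(1))
  expect_true(all(top3))
  # a pure tone is ranked first wherever it is placed
  tone <- generate_signal(signal_recipe(
    duration = 20, tones = data.frame(freq = 3, amp = 1),
    broadband = list(low = 0.5, high = 20, level = 0),
    shock = list(rate = 0, amplitude = 0, decay = 0.25, carrier = 4),
    target_rms = NULL, seed = 3))
  tb <- spectrum_peaks(tone)
  expect_true(tb$low[1] <= 3 && 3 < tb$high[1])
  expect_error(spectrum_peaks(generate_signal(signal_recipe(duration = 2,
                                                            seed = 1))),
               "short")
})

test_that("band-limited noise alone has a flat spectral density", {
  # over 10 seeds, the median per-band density inside the noise band must
  # not concentrate: no band twice the median of the others
  dens <- sapply(1:10, function(seed) {
    # the broadband level is set relative to the tonal RMS, so a very large
    # level makes the noise dominate the (single, negligible) tone
    r <- signal_recipe(duration = 30, seed = seed,
                       tones = data.frame(freq = 5, amp = 1),
                       broadband = list(low = 0.5, high = 20, level = 1000),
                       shock = list(rate = 0, amplitude = 0, decay = 0.25,
                                    carrier = 4),
                       target_rms = NULL)
    sig <- generate_signal(r)
    b <- spectrum_peaks(sig)
    b <- b[b$center >= 2 & b$center <= 12, ]
    b$density[order(b$center)]
  })
  med <- apply(dens, 1, stats::median)
  expect_lt(max(med), 2 * stats::median(med))
})

test_that("recipes round-trip through YAML and JSON", {
  y <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("duration: 12", "fs: 128", "seed: 7", "target_rms: 0.4",
               "tones:", "  - [5, 1.0]", "  - [3, 0.6]"), y)
  r <- read_recipe(y)
  expect_equal(r$duration, 12)
  expect_equal(r$tones$freq, c(5, 3))
  expect_equal(r$target_rms, 0.4)
  j <- withr::local_tempfile(fileext = ".json")
  writeLines('{"duration": 8, "seed": 2, "shock": {"rate": 0}}', j)
  rj <- read_recipe(j)
  expect_equal(rj$duration, 8)
  expect_equal(rj$shock$rate, 0)
  expect_equal(rj$shock$carrier, 4)  # unspecified fields keep defaults
})
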