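# Re-referencing, FIR least-squares design, zero-phase filtering, band
# decomposition and segmentation.

test_that("re-referencing subtracts the reference and drops it", {
  data <- matrix(rep(c(1, 2, 3), times = 100), nrow = 3)  # constant rows 1, 2, 3
  rec <- recording(data, fs = 100, channel_labels = c("a", "b", "c"))
  out <- rereference(rec, "a")
  expect_equal(n_channels(out), 2L)
  expect_equal(out$channel_labels, c("b", "c"))
  expect_true(all(out$data[1, ] == 1) && all(out$data[2, ] == 2))

  # zero reference leaves other channels unchanged
  rec2 <- recording(rbind(0, matrix(rnorm(200), 2)), fs = 100,
                    channel_labels = c("ref", "x", "y"))
  out2 <- rereference(rec2, "ref")
  expect_equal(out2$data, rec2$data[-1, , drop = FALSE], ignore_attr = TRUE)

  # a channel equal to the reference stays, as all-zero
  rec3 <- recording(rbind(rec2$data[2, ], rec2$data[2, ]), fs = 100,
                    channel_labels = c("ref", "dup"))
  out3 <- rereference(rec3, "ref")
  expect_equal(n_channels(out3), 1L)
  expect_true(all(out3$data == 0))

  expect_error(rereference(rec, "nope"), "not found")
})

test_that("least-squares FIR taps are symmetric and meet the band spec", {
  fir <- design_fir_ls(band_spec("Alpha", 8, 13), fs = 500)
  expect_true(fir$n_taps %% 2L == 1L)
  expect_equal(fir$taps, rev(fir$taps))
  expect_gt(fir_gain(fir, 10.5), 0.99)
  expect_lt(fir_gain(fir, 10.5), 1.01)
  expect_lt(fir_gain(fir, 50), 0.1)
  # attenuation beyond the transition bands
  expect_lt(fir_gain(fir, 8 - 2 * fir$transition_width), 0.1)

  expect_error(design_fir_ls(band_spec("Alpha", 8, 13), 500, n_taps = 100),
               "odd")
  # Delta transition would cross 0 Hz with an oversized transition width
  expect_error(design_fir_ls(band_spec("Delta", 1.5, 4), 500,
                             transition_width = 2), "0 Hz")
  expect_error(design_fir_ls(band_spec("Gamma", 30, 80), 170), "Nyquist")
})

test_that("zero-phase filtering kills DC, preserves in-band amplitude at zero lag", {
  fir <- design_fir_ls(band_spec("Alpha", 8, 13), fs = 500)
  n <- 6000
  dc <- recording(matrix(1, 1, n), fs = 500)
  out <- filter_zero_phase(dc, fir)
  interior <- phasesom:::interior_index(out)
  expect_lt(max(abs(out$data[1, interior])), 1e-3)

  rec <- sine_recording(10, 500, 12)
  f <- filter_zero_phase(rec, fir)
  i <- phasesom:::interior_index(f)
  ratio <- max(abs(f$data[1, i]))
  expect_gt(ratio, 0.98); expect_lt(ratio, 1.02)
  cc <- stats::ccf(f$data[1, i], rec$data[1, i], lag.max = 25, plot = FALSE)
  expect_identical(as.integer(cc$lag[which.max(cc$acf)]), 0L)

  expect_error(filter_zero_phase(recording(matrix(rnorm(100), 1), 500), fir),
               "too short")
})

test_that("filtering twice equals one pass with the squared-response taps", {
  fir <- design_fir_ls(band_spec("Beta", 13, 30), fs = 250)
  set.seed(5)
  rec <- recording(matrix(rnorm(8000), 1), fs = 250)
  twice <- filter_zero_phase(filter_zero_phase(rec, fir), fir)
  g <- phasesom:::fft_conv(fir$taps, fir$taps)       # |H|^2 taps, still symmetric
  sq <- phasesom:::new_fir_spec(g, 250, fir$band, fir$transition_width,
                                "band-pass")
  once <- filter_zero_phase(rec, sq)
  i <- (2 * fir$n_taps):(8000 - 2 * fir$n_taps)
  expect_lt(max(abs(twice$data[1, i] - once$data[1, i])), 1e-8)
})

test_that("filtering is linear", {
  fir <- design_fir_ls(band_spec("Alpha", 8, 13), fs = 250)
  set.seed(9)
  x <- rnorm(5000); y <- rnorm(5000)
  f <- function(v) phasesom:::fir_filtfilt(v, fir$taps)
  expect_equal(f(2 * x - 3 * y), 2 * f(x) - 3 * f(y), tolerance = 1e-10)
})

test_that("50 Hz notch removes mains and spares in-band content", {
  rec50 <- sine_recording(50, 500, 12)
  out <- notch_50(rec50)
  i <- phasesom:::interior_index(out)
  expect_lt(max(abs(out$data[1, i])), 0.05)

  rec10 <- sine_recording(10, 500, 12)
  out10 <- notch_50(rec10)
  i <- phasesom:::interior_index(out10)
  ratio <- max(abs(out10$data[1, i]))
  expect_gt(ratio, 0.98); expect_lt(ratio, 1.02)

  z <- recording(matrix(0, 1, 6000), fs = 500)
  expect_true(all(notch_50(z)$data == 0))
  expect_error(notch_50(recording(matrix(rnorm(1000), 1), fs = 100)),
               "fs > 100")
})

test_that("band decomposition routes sinusoids to their own band only", {
  bands <- eeg_bands()
  rec <- sine_recording(10, 500, 40)
  out <- band_decompose(rec, bands)
  expect_named(out, names(bands))
  expect_true(all(vapply(out, function(r) all(dim(r$data) == dim(rec$data)),
                         logical(1))))
  amp <- vapply(out, function(r) {
    max(abs(r$data[1, phasesom:::interior_index(r)]))
  }, numeric(1))
  expect_gt(amp[["Alpha"]], 0.9)
  expect_true(all(amp[c("Delta", "Theta", "Beta", "Gamma")] < 0.1))

  t <- seq_len(20000) / 500
  mix <- recording(matrix(sin(2 * pi * 2 * t) + sin(2 * pi * 20 * t), 1),
                   fs = 500)
  outm <- band_decompose(mix, bands[c("Delta", "Beta")])
  i <- phasesom:::interior_index(outm$Delta)
  expect_lt(max(abs(outm$Delta$data[1, i] - sin(2 * pi * 2 * t)[i])), 0.06)
  expect_lt(max(abs(outm$Beta$data[1, i] - sin(2 * pi * 20 * t)[i])), 0.06)

  expect_error(band_decompose(rec, list(band_spec("hf", 100, 300))), "Nyquist")
})

test_that("band outputs of broadband noise are nearly orthogonal for non-adjacent bands", {
  set.seed(31)
  rec <- recording(matrix(rnorm(20000), 1), fs = 500)
  out <- band_decompose(rec, eeg_bands())
  i <- phasesom:::interior_index(out$Delta)
  nip <- function(a, b) {
    abs(sum(a[i] * b[i])) / sqrt(sum(a[i]^2) * sum(b[i]^2))
  }
  pairs <- list(c("Delta", "Alpha"), c("Delta", "Beta"), c("Delta", "Gamma"),
                c("Theta", "Beta"), c("Theta", "Gamma"), c("Alpha", "Gamma"))
  for (p in pairs) {
    expect_lt(nip(out[[p[1]]]$data[1, ], out[[p[2]]]$data[1, ]), 0.05)
  }
})

test_that("segmentation arithmetic and metadata inheritance", {
  rec <- recording(matrix(rnorm(2 * 3000), 2), fs = 10, group = "control")
  segs <- segment(rec, 15, 0)                 # 300 s / 15 s
  expect_length(segs, 20L)
  expect_true(all(vapply(segs, function(s) s$group == "control", logical(1))))

  rec60 <- recording(matrix(rnorm(600), 1), fs = 10)
  one <- segment(rec60, 60)
  expect_length(one, 1L)
  expect_equal(one[[1]]$data, rec60$data)

  segs2 <- segment(rec60, 15, 5)              # floor((60-15)/10)+1
  expect_length(segs2, 5L)

  expect_error(segment(rec60, 90), "longer than recording")
  expect_error(segment(rec60, 10, 10), "overlap_s")
})
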