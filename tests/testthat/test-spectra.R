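test_that("magnitude spectra behave linearly and hit the FFT oracle", {
  tb <- ft_timebase(1024, 1e5)
  instr <- instrument_config()
  # all-zero transient -> all-zero magnitudes
  sp0 <- to_spectrum(rep(0, 1024), tb, instr)
  expect_true(all(sp0$intensity == 0))
  expect_false(is.unsorted(sp0$mz, strictly = TRUE))
  # unit cosine at an exact bin frequency -> single dominant bin of N/2
  f_bin <- 10 * tb$sampling_rate / 1024
  s <- synthesize_transient(
    data.frame(amplitude = 1, tau = Inf, omega = 2 * pi * f_bin), tb, 0)
  sp <- to_spectrum(s, tb, instr)
  expect_equal(max(sp$intensity), 1024 / 2, tolerance = 1e-9)
  expect_equal(sp$frequency[which.max(sp$intensity)], f_bin)
  # scaling the transient scales the magnitudes
  sp3 <- to_spectrum(3 * as.numeric(s), tb, instr)
  expect_equal(sp3$intensity, 3 * sp$intensity, tolerance = 1e-12)
  expect_error(to_spectrum(numeric(0), tb), "empty")
})

test_that("spectral energy is proportional to transient energy", {
  tb <- ft_timebase(512, 1e5)
  set.seed(8)
  ratios <- replicate(10, {
    x <- rnorm(512); x <- x - mean(x)        # kill the DC bin exactly
    sp <- to_spectrum(x, tb)
    nyq <- length(sp$intensity)              # ordered by m/z: first freq last
    # Parseval: 2*sum(half) - nyquist correction = N * time energy
    i_nyq <- which.max(sp$frequency)
    (2 * sum(sp$intensity^2) - sp$intensity[i_nyq]^2) / sum(x^2)
  })
  expect_true(all(abs(ratios - 512) / 512 < 1e-9))
})

test_that("peak picking resolves synthetic peaks to sub-ppm accuracy", {
  # three Lorentzian peaks on a flat-noise spectrum at SNR 50
  mz <- seq(500, 900, length.out = 20000)
  truth <- c(620.1234, 700.5678, 850.9999)
  y <- rep(0, length(mz))
  for (m0 in truth) y <- y + 50 / (1 + ((mz - m0) / 0.05)^2)
  set.seed(2)
  y <- y + abs(rnorm(length(mz), sd = 1))
  sp <- structure(list(mz = mz, intensity = y,
                       frequency = rev(seq_along(mz))),
                  class = "ms_spectrum")
  pk <- pick_peaks(sp, snr_threshold = 10)
  expect_equal(nrow(pk), 3)
  for (m0 in truth) {
    d_ppm <- min(abs(pk$mz - m0)) / m0 * 1e6
    expect_lt(d_ppm, 1)
  }
  # flat zero spectrum -> no peaks
  sp_zero <- structure(list(mz = mz, intensity = rep(0, length(mz)),
                            frequency = rev(seq_along(mz))),
                       class = "ms_spectrum")
  expect_equal(nrow(pick_peaks(sp_zero)), 0)
  expect_error(pick_peaks(sp, noise_window = c(899.999, 900)), "50 samples")
})

test_that("pure-noise false positives are rare at threshold 5", {
  # Gaussian tail bound: P(N > 5 sd) ~ 2.9e-7; with local-maximum and
  # half-normal folding the expected count stays below 1 per 1e5 samples
  set.seed(3)
  n <- 1e5
  counts <- replicate(5, {
    y <- rnorm(n)
    sp <- structure(list(mz = seq(100, 1000, length.out = n), intensity = y,
                         frequency = rev(seq_len(n))),
                    class = "ms_spectrum")
    nrow(pick_peaks(sp, snr_threshold = 5))
  })
  expect_lt(mean(counts), 1)
})

test_that("ppm binning follows the greedy width rule", {
  # 2 ppm apart -> same bin
  t1 <- ppm_bin(list(data.frame(mz = c(400.0000, 400.0008),
                                intensity = c(1, 1))), width_ppm = 3)
  expect_equal(length(t1$mz), 1)
  # 10 ppm apart -> separate bins
  t2 <- ppm_bin(list(data.frame(mz = c(400.0000, 400.0040),
                                intensity = c(1, 1))), width_ppm = 3)
  expect_equal(length(t2$mz), 2)
  # intensity-weighted centroid
  t3 <- ppm_bin(list(data.frame(mz = c(400.0000, 400.0008),
                                intensity = c(3, 1))), width_ppm = 3)
  expect_equal(t3$mz, (3 * 400.0000 + 1 * 400.0008) / 4)
  expect_error(ppm_bin(list(data.frame(mz = -1, intensity = 1))),
               "negative")
})

test_that("ppm binning is idempotent and respects width bounds", {
  set.seed(5)
  lists <- lapply(1:4, function(i) {
    mz <- sort(runif(40, 400, 900))
    data.frame(mz = mz, intensity = runif(40, 0.5, 2))
  })
  tab <- ppm_bin(lists, width_ppm = 3)
  # column count never exceeds pooled peak count
  expect_lte(length(tab$mz), 160)
  # no two peaks more than 2x width apart share a bin: re-bin the table
  tab2 <- ppm_bin(peak_table_lists(tab), width_ppm = 3)
  expect_equal(tab2$mz, tab$mz, tolerance = 1e-12)
  expect_equal(tab2$intensity, tab$intensity, tolerance = 1e-12)
  # greedy rule: consecutive bin references differ by more than the width
  expect_true(all(diff(tab$mz) / tab$mz[-length(tab$mz)] * 1e6 > 0))
})

test_that("peaks far beyond twice the width never merge", {
  set.seed(6)
  mz <- sort(400 * cumprod(1 + runif(30, 7e-6, 5e-5)))  # >= 7 ppm gaps
  tab <- ppm_bin(list(data.frame(mz = mz, intensity = rep(1, 30))),
                 width_ppm = 3)
  expect_equal(length(tab$mz), 30)
})

test_that("TIC normalization scales rows to unit sum and keeps zeros", {
  m <- rbind(c(1, 2, 3), c(10, 0, 30), c(0, 0, 0))
  tab <- structure(list(mz = c(400, 500, 600), intensity = m, ppm = 3),
                   class = "peak_table")
  expect_warning(norm <- tic_normalize(tab), "all-zero")
  expect_equal(rowSums(norm$intensity)[1:2], c(1, 1),
               ignore_attr = TRUE)
  expect_equal(norm$intensity[3, ], c(0, 0, 0))
  # zero pattern preserved
  expect_equal(norm$intensity == 0, m == 0)
  # scale invariance
  tab10 <- tab; tab10$intensity <- tab10$intensity * 10
  expect_warning(norm10 <- tic_normalize(tab10), "all-zero")
  expect_equal(norm10$intensity, norm$intensity)
})

test_that("feature intersection keeps only shared bins", {
  mk <- function(mz) structure(list(mz = mz,
                                    intensity = matrix(seq_along(mz),
                                                       1),
                                    ppm = 3), class = "peak_table")
  shared <- c(400.0, 450.0, 500.0, 550.0, 600.0)
  t1 <- mk(sort(c(shared, c(410, 460, 510, 560, 610))))
  t2 <- mk(sort(c(shared + shared * 1e-6,       # 1 ppm off: still matches
                  c(420, 470, 520, 570, 620))))
  out <- intersect_features(list(t1, t2), tolerance_ppm = 3)
  expect_equal(length(out[[1]]$mz), 5)
  expect_equal(out[[1]]$mz, shared)
  # identical tables -> everything kept
  out_id <- intersect_features(list(t1, t1))
  expect_equal(out_id[[1]]$mz, t1$mz)
  # disjoint ranges -> empty + warning
  t3 <- mk(c(1000, 1100))
  expect_warning(out3 <- intersect_features(list(t1, t3)), "no shared")
  expect_equal(length(out3[[1]]$mz), 0)
})
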