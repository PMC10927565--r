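test_that("cyclotron relation matches the adopted constant and inverts", {
  instr <- instrument_config(B0 = 7)
  expect_equal(frequency_from_mz(400, instr), 1.535611e7 * 7 / 400)
  expect_equal(frequency_from_mz(400, instr), 268731.9, tolerance = 1e-6)
  # linear in B0
  expect_equal(frequency_from_mz(400, instrument_config(14)),
               2 * frequency_from_mz(400, instr))
  # exact round trip for random m/z values
  set.seed(1)
  mz <- runif(100, 100, 2000)
  expect_equal(mz_from_frequency(frequency_from_mz(mz, instr), instr), mz)
  expect_error(frequency_from_mz(-1, instr), "positive")
  expect_error(mz_from_frequency(0, instr), "positive")
})

test_that("theoretical resolution reproduces the instrument worked values", {
  instr <- instrument_config(B0 = 7)
  r_full <- theoretical_resolution(400, 1, instr, T_aqn = 0.731)
  expect_equal(signif(r_full, 2), 160000)
  r_short <- theoretical_resolution(400, 1, instr,
                                    T_aqn = 0.731 * 64000 / 1e6)
  expect_equal(round(r_short, -4), 10000)
  expect_error(theoretical_resolution(-400, 1, instr, 0.731), "> 0")
})

test_that("resolution is linear in z, B0, T_aqn and inverse in mass", {
  set.seed(42)
  for (i in 1:20) {
    mz <- runif(1, 100, 2000); z <- sample(1:3, 1)
    B0 <- runif(1, 1, 21); t_a <- runif(1, 0.01, 10)
    instr <- instrument_config(B0)
    base <- theoretical_resolution(mz, z, instr, t_a)
    expect_equal(theoretical_resolution(mz, z, instr, 2 * t_a), 2 * base)
    expect_equal(theoretical_resolution(mz, z, instrument_config(2 * B0),
                                        t_a), 2 * base)
    # m = mz*z: doubling z at fixed mz doubles m as well, net linear in z
    expect_equal(theoretical_resolution(2 * mz, z, instr, t_a), base / 2)
  }
})

test_that("isotope patterns match exact enumeration", {
  # H2: single peak at twice the proton-rich hydrogen mass
  p <- isotope_pattern("H2")
  expect_equal(p$mass[1], 2.015650, tolerance = 1e-6)
  expect_equal(p$abundance[1], 1)

  # C100: M+1/M0 ratio equals the binomial value
  p <- isotope_pattern("C100", min_abundance = 1e-6)
  tab <- meister:::.isotope_table$C
  expect_equal(p$abundance[2] / p$abundance[1],
               as.numeric(100 * tab[2, "abundance"] / tab[1, "abundance"]),
               tolerance = 1e-9)

  # CnHm formulas up to 20 atoms per element against brute-force
  # multinomial enumeration
  set.seed(7)
  for (i in 1:4) {
    n_c <- sample(1:20, 1); n_h <- sample(1:20, 1)
    counts <- c(C = n_c, H = n_h)
    oracle <- enumerate_isotopes(counts, meister:::.isotope_table)
    got <- isotope_pattern(sprintf("C%dH%d", n_c, n_h),
                           min_abundance = 1e-9)
    probs <- attr(got, "probability")
    for (j in seq_along(got$mass)) {
      k <- which.min(abs(oracle$m - got$mass[j]))
      expect_lt(abs(got$mass[j] - oracle$m[k]), 1e-6)
      expect_lt(abs(probs[j] - oracle$p[k]), 1e-9)
    }
  }
})

test_that("isotope abundance conventions hold for arbitrary formulas", {
  for (f in c("C6H12O6", "C42H82NO8P", "C10H15N5O10P2", "KCl")) {
    p <- isotope_pattern(f, min_abundance = 1e-4)
    expect_lte(sum(attr(p, "probability")), 1 + 1e-12)
    expect_equal(max(p$abundance), 1)
    expect_false(is.unsorted(p$mass))
  }
  expect_error(isotope_pattern("Xx3"), "unknown element")
})

test_that("adduct masses use the adopted cation constants", {
  expect_equal(adduct_mz(180.063388, "H"), 181.070664, tolerance = 1e-9)
  set.seed(3)
  m <- runif(5, 100, 1200)
  expect_equal(adduct_mz(m, "K") - adduct_mz(m, "Na"),
               rep(15.973940, 5), tolerance = 1e-9)
  expect_error(adduct_mz(0, "H"), "positive")
  expect_error(adduct_mz(100, "Li"))
})

test_that("synthesized transients follow the damped-sinusoid model", {
  tb <- ft_timebase(1024, 1e5)
  # no decay, zero frequency: constant 1
  s <- synthesize_transient(data.frame(amplitude = 1, tau = Inf, omega = 0),
                            tb, noise_sigma = 0)
  expect_equal(as.numeric(s), rep(1, 1024))
  # one full period with decay
  s <- synthesize_transient(
    data.frame(amplitude = 2, tau = 1, omega = 2 * pi * 100), tb, 0)
  i <- which.min(abs(tb$t - 0.01))
  expect_equal(s[i], 2 * exp(-0.01) * cos(2 * pi), tolerance = 1e-12)
  # pure-noise Monte Carlo: sample s.d. close to sigma
  tb_long <- ft_timebase(1e5, 1e5)
  s <- synthesize_transient(data.frame(amplitude = numeric(0),
                                       tau = numeric(0),
                                       omega = numeric(0)),
                            tb_long, noise_sigma = 0.5, seed = 11)
  expect_lt(abs(sd(s) - 0.5) / 0.5, 0.02)
  # errors
  expect_error(synthesize_transient(data.frame(amplitude = -1, tau = 1,
                                               omega = 1), tb),
               "amplitude")
  expect_error(synthesize_transient(data.frame(amplitude = 1, tau = 1,
                                               omega = 1), list()),
               "timebase")
})

test_that("signal model is linear in the component list", {
  tb <- ft_timebase(512, 1e5)
  set.seed(5)
  c1 <- data.frame(amplitude = runif(4), tau = runif(4, 0.1, 2),
                   omega = runif(4, 1e3, 1e5))
  c2 <- data.frame(amplitude = runif(3), tau = runif(3, 0.1, 2),
                   omega = runif(3, 1e3, 1e5))
  s_union <- synthesize_transient(rbind(c1, c2), tb, 0)
  s_sum <- synthesize_transient(c1, tb, 0) + synthesize_transient(c2, tb, 0)
  expect_equal(as.numeric(s_union), as.numeric(s_sum), tolerance = 1e-12)
})

test_that("region phantoms are labeled, deterministic and degenerate-safe", {
  rm1 <- make_region_map(50, 50, 8, seed = 2)
  expect_setequal(unique(as.vector(rm1)), 1:8)
  expect_identical(rm1, make_region_map(50, 50, 8, seed = 2))
  expect_false(identical(rm1, make_region_map(50, 50, 8, seed = 3)))
  expect_true(all(make_region_map(6, 6, 1, seed = 1) == 1))
  expect_error(make_region_map(2, 2, 9), "fewer pixels")
})

test_that("simulated MSI datasets carry coherent ground truth", {
  sim <- small_sim(seed = 4)
  expect_equal(nrow(sim$noisy), length(sim$region_map))
  expect_equal(dim(sim$clean), dim(sim$noisy))
  # same seed bit-identical, different seed different
  sim2 <- small_sim(seed = 4)
  expect_identical(sim$noisy, sim2$noisy)
  # noise statistics: mean ~ 0 and s.d. ~ sigma within 3 standard errors
  resid <- sim$noisy - sim$clean
  n <- length(resid)
  expect_lt(abs(mean(resid)), 3 * sim$noise_sigma / sqrt(n))
  expect_lt(abs(sd(resid) - sim$noise_sigma),
            3 * sim$noise_sigma / sqrt(2 * n))
})

test_that("clean pixel spectra peak at the reverse-calculated frequencies", {
  sim <- simulate_msi(height = 4, width = 4, n_regions = 1,
                      formulas = c("C42H82NO8P", "C27H46O"),
                      timebase = ft_timebase(8192), noise_sigma = 0,
                      pixel_sdlog = 0, seed = 9)
  mag <- Mod(stats::fft(sim$clean[1, ]))[1:4096]
  df <- sim$timebase$sampling_rate / 8192
  ions <- sim$ion_table
  # test isolated, strong components only (no neighbour within 3 bins)
  bin_of <- round(ions$frequency / df) + 1
  iso_ok <- vapply(seq_len(nrow(ions)), function(i)
    all(abs(bin_of[i] - bin_of[-i]) > 3), TRUE)
  strong <- ions$amplitude > 0.2 * max(ions$amplitude)
  idx <- which(iso_ok & strong)
  expect_gt(length(idx), 2)
  for (i in idx) {
    b <- bin_of[i]
    window <- mag[(b - 3):(b + 3)]
    local_max <- which.max(window) + b - 4
    expect_lte(abs(local_max - b), 1)
  }
})

test_that("empty regions trigger a warning and stay noise-only", {
  expect_warning(
    sim <- simulate_msi(height = 6, width = 6, n_regions = 3,
                        formulas = c("C6H12O6", "C5H5N5"),
                        region_assignments = list(1L, 2L, integer(0)),
                        timebase = ft_timebase(256), noise_sigma = 0,
                        seed = 1),
    "noise-only")
  # with zero noise, pixels of the formula-less region are exactly zero
  pix <- which(as.vector(sim$region_map) == 3)
  expect_true(all(sim$clean[pix, ] == 0))
  expect_false(3 %in% sim$ion_table$region)
})

test_that("simulated datasets survive a save/load round trip", {
  sim <- small_sim(seed = 2, n_points = 256, height = 4, width = 4)
  f <- tempfile(fileext = ".rds")
  save_simulated_msi(sim, f)
  expect_identical(load_simulated_msi(f), sim)
  fc <- tempfile(fileext = ".csv")
  write_ion_table(sim, fc)
  tab <- read.csv(fc)
  expect_equal(nrow(tab), nrow(sim$ion_table))
  unlink(c(f, fc))
})
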