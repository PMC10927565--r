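# Shared fixtures and independent oracles, built in code at test time.

# integer-shift an image, zero-filling uncovered pixels
shift_image <- function(img, dr, dc) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  rr <- seq_len(h) - dr; cc <- seq_len(w) - dc
  ok_r <- rr >= 1 & rr <= h; ok_c <- cc >= 1 & cc <= w
  out[ok_r, ok_c] <- img[rr[ok_r], cc[ok_c]]
  out
}

# smooth synthetic warp: global shift plus a one-period sinusoid
warp_image <- function(img, amp, shift, nearest = TRUE) {
  h <- nrow(img); w <- ncol(img)
  rr <- as.numeric(row(img)); cc <- as.numeric(col(img))
  pr <- rr + shift[1] + amp * sin(2 * pi * cc / w)
  pc <- cc + shift[2] + amp * cos(2 * pi * rr / h)
  v <- if (nearest) meister:::.sample_nearest(img, pr, pc)
  else meister:::.sample_bilinear(img, pr, pc)
  v[!is.finite(v)] <- 0
  matrix(v, h, w)
}

# exact aggregated isotope distribution by brute-force multinomial
# enumeration over the isotopes of one element, convolved across elements;
# independent of the package's polynomial-squaring implementation
enumerate_isotopes <- function(counts, iso_table) {
  conv <- function(a, b) {
    out <- new.env()
    res_shift <- c(); res_p <- c(); res_m <- c()
    for (i in seq_along(a$p)) for (j in seq_along(b$p)) {
      s <- a$shift[i] + b$shift[j]
      p <- a$p[i] * b$p[j]
      m <- a$m[i] + b$m[j]
      k <- match(s, res_shift)
      if (is.na(k)) {
        res_shift <- c(res_shift, s); res_p <- c(res_p, p)
        res_m <- c(res_m, p * m)
      } else {
        res_p[k] <- res_p[k] + p
        res_m[k] <- res_m[k] + p * m
      }
    }
    ord <- order(res_shift)
    list(shift = res_shift[ord], p = res_p[ord],
         m = (res_m / res_p)[ord])
  }
  one_element <- function(symbol, n) {
    iso <- iso_table[[symbol]]
    shifts <- round(iso[, "mass"] - iso[1, "mass"])
    dist <- list(shift = 0, p = 1, m = 0)
    atom <- list(shift = shifts, p = iso[, "abundance"],
                 m = iso[, "mass"])
    for (i in seq_len(n)) dist <- conv(dist, atom)
    dist
  }
  total <- list(shift = 0, p = 1, m = 0)
  for (el in names(counts))
    if (counts[[el]] > 0)
      total <- conv(total, one_element(el, counts[[el]]))
  total
}

# adjusted Rand index between two partitions
adjusted_rand <- function(a, b) {
  t <- table(a, b)
  A <- sum(choose(t, 2))
  B <- sum(choose(rowSums(t), 2)); C <- sum(choose(colSums(t), 2))
  D <- choose(sum(t), 2)
  (A - B * C / D) / ((B + C) / 2 - B * C / D)
}

# small simulated MSI dataset shared by spectral/reconstruction tests
small_sim <- function(seed = 1, n_points = 2048, height = 10, width = 10,
                      n_regions = 3, noise_sigma = 0.5) {
  simulate_msi(height = height, width = width, n_regions = n_regions,
               formulas = c("C42H82NO8P", "C40H80NO8P", "C27H46O",
                            "C39H79N2O6P"),
               timebase = ft_timebase(n_points),
               noise_sigma = noise_sigma, seed = seed)
}
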