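#' Magnitude mass spectrum of a transient
#'
#' Computes the magnitude of the discrete Fourier transform of a time-domain
#' transient (no apodization by default; a Hann window is available) and maps
#' the positive-frequency axis to m/z through the cyclotron relation. Because
#' m/z is inversely proportional to frequency the m/z axis is returned in
#' increasing order.
#'
#' @param transient numeric vector (or `transient` object); finite values.
#' @param timebase a [ft_timebase()]; taken from the transient attribute when
#'   omitted.
#' @param instrument an [instrument_config()].
#' @param zero_pad_to optional FFT length (>= signal length) for zero padding.
#' @param window `"none"` (default) or `"hann"`.
#' @param mz_range optional `c(lo, hi)` m/z window to retain.
#' @return Object of class `ms_spectrum`: list with `mz` (strictly
#'   increasing), `intensity` (>= 0) and `frequency` (Hz, same order).
#' @examples
#' tb <- ft_timebase(1024, 1e5)
#' s <- synthesize_transient(
#'   data.frame(amplitude = 1, tau = Inf, omega = 2 * pi * 1e4), tb)
#' sp <- to_spectrum(s, tb)
#' @export
to_spectrum <- function(transient, timebase = attr(transient, "timebase"),
                        instrument = instrument_config(),
                        zero_pad_to = NULL,
                        window = c("none", "hann"),
                        mz_range = NULL) {
  window <- match.arg(window)
  x <- as.numeric(transient)
  if (!length(x)) stop("empty transient", call. = FALSE)
  if (any(!is.finite(x))) stop("transient contains non-finite values",
                               call. = FALSE)
  if (is.null(timebase)) stop("`timebase` required", call. = FALSE)
  n <- length(x)
  if (window == "hann")
    x <- x * (0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n))
  if (!is.null(zero_pad_to)) {
    if (zero_pad_to < n) stop("`zero_pad_to` shorter than signal",
                              call. = FALSE)
    x <- c(x, numeric(zero_pad_to - n))
  }
  nfft <- length(x)
  mag <- Mod(stats::fft(x))
  half <- seq(2L, floor(nfft / 2) + 1L)    # positive frequencies, DC dropped
  freq <- (half - 1L) * timebase$sampling_rate / nfft
  mz <- mz_from_frequency(freq, instrument)
  ord <- order(mz)
  mz <- mz[ord]; inten <- mag[half][ord]; freq <- freq[ord]
  if (!is.null(mz_range)) {
    keep <- mz >= mz_range[1] & mz <= mz_range[2]
    mz <- mz[keep]; inten <- inten[keep]; freq <- freq[keep]
  }
  structure(list(mz = mz, intensity = inten, frequency = freq),
            class = "ms_spectrum")
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat(sprintf("Mass spectrum: %d points, m/z %.4f .. %.4f\n",
              length(x$mz), min(x$mz), max(x$mz)))
  invisible(x)
}

#' @export
plot.ms_spectrum <- function(x, ...) {
  graphics::plot(x$mz, x$intensity, type = "h", xlab = "m/z",
                 ylab = "intensity", ...)
  invisible(x)
}

#' Pick peak centroids from a mass spectrum
#'
#' Detects local maxima whose intensity exceeds `snr_threshold` times the
#' noise standard deviation, estimated from a signal-free noise window
#' (default: the top 5 percent of the m/z axis). Centroids are refined by
#' quadratic interpolation through the apex and its two neighbours.
#'
#' @param spectrum an [to_spectrum()] result.
#' @param snr_threshold signal-to-noise threshold (default 3).
#' @param noise_window `c(lo, hi)` m/z interval used to estimate the noise
#'   s.d.; must contain at least 50 samples. `NULL` uses the top 5 percent of
#'   the axis.
#' @return data.frame with columns `mz` (centroid), `intensity` (apex) and
#'   `snr`, sorted by m/z. Zero rows when nothing exceeds the threshold.
#' @export
pick_peaks <- function(spectrum, snr_threshold = 3, noise_window = NULL) {
  mz <- spectrum$mz; y <- spectrum$intensity
  n <- length(y)
  if (is.null(noise_window)) {
    lo <- stats::quantile(mz, 0.95)
    noise_window <- c(lo, max(mz))
  }
  in_win <- mz >= noise_window[1] & mz <= noise_window[2]
  if (sum(in_win) < 50)
    stop("noise window must contain at least 50 samples", call. = FALSE)
  noise_sd <- stats::sd(y[in_win])
  if (!is.finite(noise_sd) || noise_sd == 0) noise_sd <- .Machine$double.eps
  thr <- snr_threshold * noise_sd
  i <- which(y[-c(1, n)] > y[-c(n - 1, n)] & y[-c(1, n)] >= y[-c(1, 2)]) + 1L
  i <- i[y[i] >= thr]
  if (!length(i))
    return(data.frame(mz = numeric(0), intensity = numeric(0),
                      snr = numeric(0)))
  # quadratic vertex through (i-1, i, i+1) in index space, mapped to m/z
  y0 <- y[i - 1L]; y1 <- y[i]; y2 <- y[i + 1L]
  denom <- y0 - 2 * y1 + y2
  delta <- ifelse(abs(denom) > 0, 0.5 * (y0 - y2) / denom, 0)
  delta <- pmax(pmin(delta, 0.5), -0.5)
  mz_lo <- mz[pmax(i - 1L, 1L)]; mz_hi <- mz[pmin(i + 1L, n)]
  cent <- mz[i] + delta * (mz_hi - mz_lo) / 2
  out <- data.frame(mz = cent, intensity = y1, snr = y1 / noise_sd)
  out[order(out$mz), , drop = FALSE]
}

#' Bin peak lists on a ppm grid
#'
#' Pools the peak lists of all pixels/cells, sorts them by m/z, and clusters
#' them greedily: a peak joins the current bin iff it lies within `width_ppm`
#' (relative, parts-per-million) of the bin's reference, the first peak that
#' opened the bin; otherwise it opens a new bin. The bin centroid is the
#' intensity-weighted mean m/z of its members. Peaks from the same source
#' falling into one bin have their intensities summed.
#'
#' @param peaklists list of data.frames with columns `mz` and `intensity`
#'   (each sorted by `mz`).
#' @param width_ppm bin width in ppm (default 3).
#' @return Object of class `peak_table`: list with `mz` (bin centroids,
#'   increasing), `intensity` (matrix, one row per input list) and `ppm`.
#' @export
ppm_bin <- function(peaklists, width_ppm = 3) {
  if (inherits(peaklists, "peak_table")) peaklists <- peak_table_lists(peaklists)
  stopifnot(is.list(peaklists), length(peaklists) >= 1)
  src <- rep(seq_along(peaklists),
             vapply(peaklists, nrow, 1L))
  mz <- unlist(lapply(peaklists, `[[`, "mz"), use.names = FALSE)
  inten <- unlist(lapply(peaklists, `[[`, "intensity"), use.names = FALSE)
  if (any(mz < 0)) stop("negative m/z", call. = FALSE)
  if (!length(mz))
    return(structure(list(mz = numeric(0),
                          intensity = matrix(0, length(peaklists), 0),
                          ppm = width_ppm),
                     class = "peak_table"))
  ord <- order(mz)
  mz <- mz[ord]; inten <- inten[ord]; src <- src[ord]
  bin <- integer(length(mz))
  b <- 1L; ref <- mz[1]; bin[1] <- 1L
  if (length(mz) > 1) for (i in 2:length(mz)) {
    if ((mz[i] - ref) / ref * 1e6 <= width_ppm) {
      bin[i] <- b
    } else {
      b <- b + 1L; ref <- mz[i]; bin[i] <- b
    }
  }
  nb <- b
  fbin <- factor(bin, levels = seq_len(nb))
  centroid <- as.numeric(tapply(mz * inten, fbin, sum) /
                           tapply(inten, fbin, sum))
  # guard against zero-intensity bins
  zero <- !is.finite(centroid)
  if (any(zero))
    centroid[zero] <- as.numeric(tapply(mz, fbin, mean))[zero]
  mat <- matrix(0, length(peaklists), nb)
  idx <- cbind(src, bin)
  for (i in seq_along(mz)) mat[idx[i, 1], idx[i, 2]] <-
      mat[idx[i, 1], idx[i, 2]] + inten[i]
  structure(list(mz = centroid, intensity = mat, ppm = width_ppm),
            class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("Peak table: %d rows x %d m/z bins (%g ppm)\n",
              nrow(x$intensity), length(x$mz), x$ppm))
  invisible(x)
}

#' Split a peak table back into per-row peak lists
#' @param table a `peak_table`.
#' @return list of data.frames with columns `mz`, `intensity` (zero entries
#'   dropped).
#' @export
peak_table_lists <- function(table) {
  lapply(seq_len(nrow(table$intensity)), function(i) {
    keep <- table$intensity[i, ] > 0
    data.frame(mz = table$mz[keep], intensity = table$intensity[i, keep])
  })
}

#' Total-ion-count normalization
#'
#' Scales every nonzero row of a peak table to unit sum so that pixels or
#' cells become comparable; all-zero rows are left unchanged with a warning.
#'
#' @param table a `peak_table` (or plain intensity matrix).
#' @return Object of the same type with normalized rows.
#' @export
tic_normalize <- function(table) {
  mat <- if (inherits(table, "peak_table")) table$intensity else table
  rs <- rowSums(mat)
  zero <- rs == 0
  if (any(zero))
    warning(sum(zero), " all-zero row(s) left unnormalized")
  mat[!zero, ] <- mat[!zero, , drop = FALSE] / rs[!zero]
  if (inherits(table, "peak_table")) {
    table$intensity <- mat
    table
  } else mat
}

#' Restrict peak tables to shared m/z bins
#'
#' Keeps only the bins whose centroids can be matched across *all* tables
#' within `tolerance_ppm`, the retention rule used when assembling a
#' multi-section feature set. Matching is nearest-centroid within tolerance,
#' anchored on the first table; order is preserved.
#'
#' @param tables list of >= 2 `peak_table` objects.
#' @param tolerance_ppm match tolerance in ppm (default 3).
#' @return List of peak tables restricted to the shared bins (all share the
#'   first table's centroids as reference order).
#' @export
intersect_features <- function(tables, tolerance_ppm = 3) {
  stopifnot(length(tables) >= 2)
  ref <- tables[[1]]$mz
  keep_cols <- vector("list", length(tables))
  keep_cols[[1]] <- seq_along(ref)
  shared <- rep(TRUE, length(ref))
  for (j in 2:length(tables)) {
    other <- tables[[j]]$mz
    match_j <- integer(length(ref))
    for (i in seq_along(ref)) {
      if (!shared[i] || !length(other)) { shared[i] <- FALSE; next }
      d <- abs(other - ref[i]) / ref[i] * 1e6
      best <- which.min(d)
      if (d[best] <= tolerance_ppm) match_j[i] <- best else shared[i] <- FALSE
    }
    keep_cols[[j]] <- match_j
  }
  if (!any(shared))
    warning("no shared m/z bins across tables")
  out <- vector("list", length(tables))
  for (j in seq_along(tables)) {
    cols <- if (j == 1) which(shared) else keep_cols[[j]][shared]
    out[[j]] <- structure(list(mz = tables[[j]]$mz[cols],
                               intensity = tables[[j]]$intensity[, cols,
                                                                 drop = FALSE],
                               ppm = tables[[j]]$ppm),
                          class = "peak_table")
  }
  out
}
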