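#' Magnitude spectra of a whole transient block
#'
#' Column-wise FFT of a pixels x time block; returns the shared m/z axis and
#' the pixels x bins magnitude matrix (positive frequencies, DC dropped,
#' m/z increasing).
#'
#' @param block matrix, rows are pixels/cells.
#' @param timebase a [ft_timebase()].
#' @param instrument an [instrument_config()].
#' @return list with `mz`, `frequency` and `intensity` (matrix).
#' @export
block_spectra <- function(block, timebase, instrument = instrument_config()) {
  block <- .check_block(block)
  nfft <- ncol(block)
  mag <- Mod(stats::mvfft(t(block)))           # nfft x n
  half <- seq(2L, floor(nfft / 2) + 1L)
  freq <- (half - 1L) * timebase$sampling_rate / nfft
  mz <- mz_from_frequency(freq, instrument)
  ord <- order(mz)
  list(mz = mz[ord], frequency = freq[ord],
       intensity = t(mag[half, , drop = FALSE])[, ord, drop = FALSE])
}

# per-spectrum noise s.d. over a signal-free region: by convention the top
# `frac` of the m/z axis (lowest frequencies), where no simulated or lipid
# ions occur.
.noise_region <- function(mz, frac = 0.05) {
  mz >= stats::quantile(mz, 1 - frac)
}

#' Evaluate a reconstruction against a reference block
#'
#' Converts reference and reconstructed transient blocks into magnitude
#' spectra, extracts the intensities at a common set of peak centroids
#' (picked from the mean reference spectrum unless supplied), and reports:
#' per-pixel Pearson correlation between the two peak lists; per-feature
#' (ion-image) spatial correlation across pixels; per-peak SNR in both
#' blocks, where SNR is the mean peak intensity divided by the noise standard
#' deviation estimated over a signal-free spectral region; and the per-peak
#' SNR gain \eqn{20 \log_{10}(SNR_{recon}/SNR_{ref})} in dB.
#'
#' @param reference reference transient block (e.g. clean ground truth or
#'   full-transient measurement).
#' @param recon reconstructed block, same shape.
#' @param timebase,instrument acquisition description shared by both blocks.
#' @param peaks optional data.frame with a `mz` column fixing the evaluation
#'   centroids; default: [pick_peaks()] on the mean reference spectrum.
#' @param snr_threshold peak-picking threshold when `peaks` is `NULL`.
#' @param noise_frac fraction of the upper m/z axis treated as signal-free
#'   when estimating noise (default 0.05).
#' @return list with `peaks`, `per_pixel_r`, `per_feature_r`, `snr_ref`,
#'   `snr_recon`, `snr_gain_db` (per peak) and `mean_snr_gain_db`.
#'   Zero-variance vectors yield `NA` correlations.
#' @export
evaluate_reconstruction <- function(reference, recon, timebase,
                                    instrument = instrument_config(),
                                    peaks = NULL, snr_threshold = 5,
                                    noise_frac = 0.05) {
  ref_sp <- block_spectra(reference, timebase, instrument)
  rec_sp <- block_spectra(recon, timebase, instrument)
  if (!identical(dim(ref_sp$intensity), dim(rec_sp$intensity)))
    stop("reference and reconstruction shapes differ", call. = FALSE)
  # widen the signal-free window if 5% of a short axis is under 60 samples
  noise_frac <- max(noise_frac, min(1, 60 / length(ref_sp$mz)))
  if (is.null(peaks)) {
    mean_spec <- structure(list(mz = ref_sp$mz,
                                intensity = colMeans(ref_sp$intensity),
                                frequency = ref_sp$frequency),
                           class = "ms_spectrum")
    lo <- stats::quantile(ref_sp$mz, 1 - noise_frac)
    peaks <- pick_peaks(mean_spec, snr_threshold = snr_threshold,
                        noise_window = c(lo, max(ref_sp$mz)))
  }
  if (!nrow(peaks)) stop("no peaks to evaluate", call. = FALSE)
  idx <- vapply(peaks$mz, function(m) which.min(abs(ref_sp$mz - m)), 1L)
  P_ref <- ref_sp$intensity[, idx, drop = FALSE]
  P_rec <- rec_sp$intensity[, idx, drop = FALSE]

  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }
  per_pixel_r <- vapply(seq_len(nrow(P_ref)),
                        function(i) safe_cor(P_ref[i, ], P_rec[i, ]),
                        numeric(1))
  per_feature_r <- vapply(seq_len(ncol(P_ref)),
                          function(j) safe_cor(P_ref[, j], P_rec[, j]),
                          numeric(1))

  nz <- .noise_region(ref_sp$mz, noise_frac)
  noise_ref <- stats::sd(as.numeric(ref_sp$intensity[, nz]))
  noise_rec <- stats::sd(as.numeric(rec_sp$intensity[, nz]))
  noise_rec <- max(noise_rec, .Machine$double.eps)
  noise_ref <- max(noise_ref, .Machine$double.eps)
  snr_ref <- colMeans(P_ref) / noise_ref
  snr_recon <- colMeans(P_rec) / noise_rec
  gain <- 20 * log10(snr_recon / snr_ref)
  list(peaks = peaks,
       per_pixel_r = per_pixel_r,
       per_feature_r = per_feature_r,
       snr_ref = snr_ref, snr_recon = snr_recon,
       snr_gain_db = gain,
       mean_snr_gain_db = mean(gain[is.finite(gain)]))
}

#' Signal-to-noise ratio of a named peak
#'
#' @param intensity peak intensity (scalar or vector).
#' @param noise_sd standard deviation of the noise.
#' @return `intensity / noise_sd`.
#' @examples
#' snr(100, 5)  # 20
#' @export
snr <- function(intensity, noise_sd) {
  if (any(noise_sd <= 0)) stop("`noise_sd` must be positive", call. = FALSE)
  intensity / noise_sd
}
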