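#' Scaled simulation study of the reconstruction model
#'
#' Runs the standard validation experiment on a simulated MSI dataset:
#' train the deep autoencoder and latent regressor on a random fraction of
#' the noisy pixels, reconstruct every pixel from a short transient prefix,
#' and score the reconstructions at peak centroids picked from the mean
#' ground-truth (noiseless) spectrum. The headline metric is the mean
#' per-peak SNR gain in dB of the reconstruction over the noisy
#' full-transient reference; spectral and spatial fidelity are reported
#' against the noiseless ground truth.
#'
#' @param sim a [simulate_msi()] dataset.
#' @param train_frac fraction of pixels used for training (default 0.05).
#' @param short_frac fraction of the transient retained as the short prefix
#'   (default 0.04).
#' @param latent_dim latent dimension (default 32).
#' @param dae_epochs,regressor_epochs,batch_size training schedule (defaults
#'   20 / 50 / 128).
#' @param snr_threshold peak-picking threshold on the mean clean spectrum
#'   (default 5).
#' @param peak_subsample take every `peak_subsample`-th pixel when forming
#'   the mean clean spectrum (default 10; the mean is for centroid detection
#'   only).
#' @param seed integer seed for the training subset and network training.
#' @return list with `mean_snr_gain_db`, `median_snr_gain_db`,
#'   `median_per_pixel_r`, `median_per_feature_r`, `n_peaks`, `n_train`,
#'   `short_points` and the fitted `model`.
#' @export
reconstruction_study <- function(sim, train_frac = 0.05, short_frac = 0.04,
                                 latent_dim = 32, dae_epochs = 20,
                                 regressor_epochs = 50, batch_size = 128,
                                 snr_threshold = 5, peak_subsample = 10,
                                 seed = 1L) {
  stopifnot(inherits(sim, "simulated_msi"))
  n_pix <- nrow(sim$noisy)
  n_time <- ncol(sim$noisy)
  short <- max(2L, round(short_frac * n_time))
  set.seed(as.integer(seed))
  idx <- sample(n_pix, max(2L, round(train_frac * n_pix)))

  model <- meister(sim$noisy[idx, , drop = FALSE], short_points = short,
                   latent_dim = latent_dim,
                   dae_config = training_config(epochs = dae_epochs,
                                                batch_size = batch_size,
                                                seed = seed),
                   regressor_config = training_config(
                     epochs = regressor_epochs, batch_size = batch_size,
                     seed = seed))
  rec <- reconstruct(sim$noisy[, seq_len(short), drop = FALSE], model)

  sub <- seq(1, n_pix, by = peak_subsample)
  spc <- block_spectra(sim$clean[sub, , drop = FALSE], sim$timebase,
                       sim$instrument)
  mean_clean <- structure(list(mz = spc$mz,
                               intensity = colMeans(spc$intensity),
                               frequency = spc$frequency),
                          class = "ms_spectrum")
  peaks <- pick_peaks(mean_clean, snr_threshold = snr_threshold)
  rm(spc); gc(verbose = FALSE)

  ev_noisy <- evaluate_reconstruction(sim$noisy, rec, sim$timebase,
                                      sim$instrument, peaks = peaks)
  ev_clean <- evaluate_reconstruction(sim$clean, rec, sim$timebase,
                                      sim$instrument, peaks = peaks)
  list(mean_snr_gain_db = ev_noisy$mean_snr_gain_db,
       median_snr_gain_db = stats::median(
         ev_noisy$snr_gain_db[is.finite(ev_noisy$snr_gain_db)]),
       median_per_pixel_r = stats::median(ev_clean$per_pixel_r,
                                          na.rm = TRUE),
       median_per_feature_r = stats::median(ev_clean$per_feature_r,
                                            na.rm = TRUE),
       n_peaks = nrow(peaks), n_train = length(idx),
       short_points = short, model = model)
}
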