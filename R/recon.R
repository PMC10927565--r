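#' Training configuration for the reconstruction networks
#'
#' Defaults follow the standard schedule of the reconstruction model: the
#' autoencoder is trained for 20 epochs and the regressor for 50, both with
#' the Adam optimizer; the batch size is 128 for tissue pixels and 64 for
#' single cells; weight decay (the L2 penalty on all parameters) defaults to
#' 1e-5.
#'
#' @param epochs number of training epochs.
#' @param batch_size mini-batch size.
#' @param lr Adam learning rate (default 1e-5, a fine-tuning rate suited to
#'   the data-dependent initialization used by [fit_autoencoder()] and
#'   [fit_regressor()], which start at the linear solution).
#' @param weight_decay L2 penalty applied through the optimizer.
#' @param seed integer seed for shuffling and initialization.
#' @return list of class `training_config`.
#' @export
training_config <- function(epochs = 20, batch_size = 128, lr = 1e-5,
                            weight_decay = 1e-5, seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, lr > 0, weight_decay >= 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr = lr, weight_decay = weight_decay,
                 seed = as.integer(seed)),
            class = "training_config")
}

.check_block <- function(S) {
  if (!is.matrix(S)) S <- as.matrix(S)
  if (any(!is.finite(S))) stop("transient block contains NaN/Inf",
                               call. = FALSE)
  S
}

# per-row max-absolute normalization; returns list(X, scale)
.row_normalize <- function(S) {
  sc <- apply(abs(S), 1, max)
  sc[sc == 0] <- 1
  list(X = S / sc, scale = sc)
}

#' Fit the deep autoencoder of the reconstruction model
#'
#' Trains an encoder (fully connected layers of 512, 256 and 64 ReLU units
#' into a linear latent layer, default dimension 32) and a mirrored decoder
#' to reproduce full-length transients through the low-dimensional
#' bottleneck, minimizing mean squared error with L2 weight decay. Inputs are
#' normalized per transient by their maximum absolute value; the
#' normalization is inverted on output.
#'
#' Weights are initialized from the truncated SVD of the (normalized)
#' training block, embedded exactly into the ReLU pair structure, so training
#' starts from the rank-`latent_dim` linear-subspace solution and learns the
#' nonlinear residual; the parameters with the lowest full-data loss seen
#' during training are returned. For resonant signals, whose spectra are
#' sparse, the SVD is computed on a spectrally denoised copy of the training
#' block (`init = "denoised-svd"`): frequency bins of the block-averaged
#' magnitude spectrum below `median + 6 * MAD` are zeroed before the SVD, so
#' the principal directions are not contaminated by training noise. With
#' `init = "auto"` (default) this is used whenever the detected spectral
#' support retains at least half of the averaged spectral energy, and plain
#' SVD otherwise (dense-spectrum data). Latent directions whose singular
#' values sit in the noise bulk (below twice the median singular value)
#' start with zero decoder output — hard singular-value thresholding — and
#' can be recruited by training.
#'
#' @param S transient block: matrix, pixels/cells x time samples.
#' @param latent_dim latent dimension (default 32).
#' @param cfg a [training_config()].
#' @param init initialization scheme: `"auto"`, `"denoised-svd"` or
#'   `"svd"`.
#' @return Object of class `meister_dae` with fields `encoder`, `decoder`,
#'   `latent_dim`, `n_time`, `loss_curve` and the config.
#' @export
fit_autoencoder <- function(S, latent_dim = 32, cfg = training_config(),
                            init = c("auto", "denoised-svd", "svd")) {
  init <- match.arg(init)
  S <- .check_block(S)
  n <- nrow(S); d <- ncol(S)
  norm <- .row_normalize(S)
  X <- norm$X
  r <- latent_dim

  X_init <- X
  if (init != "svd") {
    F <- stats::mvfft(t(X))
    magbar <- rowMeans(Mod(F))
    thr <- stats::median(magbar) + 6 * stats::mad(magbar)
    keep <- magbar >= thr
    energy_frac <- sum(magbar[keep]^2) / max(sum(magbar^2),
                                             .Machine$double.eps)
    if (init == "denoised-svd" || energy_frac >= 0.5) {
      F[!keep, ] <- 0
      X_init <- t(Re(stats::mvfft(F, inverse = TRUE))) / d
    }
  }
  mu <- colMeans(X_init)
  Xc <- sweep(X_init, 2, mu)
  k <- min(r, n, d)
  sv <- svd(Xc, nu = 0, nv = k)
  P <- matrix(stats::rnorm(d * r, sd = 1 / sqrt(d)), d, r)
  P[, seq_len(k)] <- sv$v[, seq_len(k), drop = FALSE]
  thresh <- 2 * stats::median(sv$d)
  k_sig <- sum(sv$d[seq_len(k)] > thresh)
  P_dec <- P
  if (k_sig < r) P_dec[, (k_sig + 1):r] <- 0

  enc <- nn_init_linear_encoder(c(d, 512, 256, 64, r), P, mu,
                                seed = cfg$seed)
  dec <- nn_init_linear_decoder(c(r, 64, 256, 512, d), P_dec, mu,
                                seed = cfg$seed + 1L)

  trained <- .dae_train(enc, dec, X, cfg)
  structure(list(encoder = trained$enc, decoder = trained$dec,
                 latent_dim = r, n_time = d,
                 loss_curve = trained$curve, init_loss = trained$init_loss,
                 config = cfg),
            class = "meister_dae")
}

# joint encoder/decoder MSE training with Adam and best-epoch checkpointing
.dae_train <- function(enc, dec, X, cfg) {
  set.seed(cfg$seed)
  n <- nrow(X)
  st_e <- adam_init(enc); st_d <- adam_init(dec)
  full_loss <- function(e, d) mean((nn_forward(d, nn_forward(e, X)) - X)^2)
  loss0 <- full_loss(enc, dec)
  best <- list(enc = enc, dec = dec, loss = loss0)
  curve <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    idx <- sample.int(n)
    for (start in seq(1, n, by = cfg$batch_size)) {
      take <- idx[start:min(start + cfg$batch_size - 1L, n)]
      xb <- X[take, , drop = FALSE]
      hs_e <- nn_forward(enc, xb, keep = TRUE)
      z <- hs_e[[length(hs_e)]]
      hs_d <- nn_forward(dec, z, keep = TRUE)
      err <- hs_d[[length(hs_d)]] - xb
      G <- 2 * err / length(err)
      g_d <- nn_backprop(dec, hs_d, G)
      g_e <- nn_backprop(enc, hs_e, g_d$input_grad)
      upd <- adam_step(dec, st_d, g_d, lr = cfg$lr,
                       weight_decay = cfg$weight_decay)
      dec <- upd$net; st_d <- upd$state
      upd <- adam_step(enc, st_e, g_e, lr = cfg$lr,
                       weight_decay = cfg$weight_decay)
      enc <- upd$net; st_e <- upd$state
    }
    curve[ep] <- full_loss(enc, dec)
    if (!is.finite(curve[ep]))
      stop("autoencoder training diverged at epoch ", ep, call. = FALSE)
    if (curve[ep] <= best$loss)
      best <- list(enc = enc, dec = dec, loss = curve[ep])
  }
  list(enc = best$enc, dec = best$dec, curve = curve, init_loss = loss0)
}

#' Encode transients into latent features
#'
#' @param model a `meister_dae`.
#' @param S transient block with the training time length.
#' @return n x latent_dim matrix of latent vectors.
#' @export
encode <- function(model, S) {
  stopifnot(inherits(model, "meister_dae"))
  S <- .check_block(S)
  if (ncol(S) != model$n_time)
    stop("block has ", ncol(S), " time points; model expects ",
         model$n_time, call. = FALSE)
  nn_forward(model$encoder, .row_normalize(S)$X)
}

#' Fit the latent regressor from short transients
#'
#' Trains the network R(.) that maps short (truncated) transients to the
#' latent vectors of their full-length counterparts, minimizing MSE with an
#' L2 penalty on the regressor parameters. The architecture mirrors the
#' encoder (512, 256, 64 ReLU units into a linear output of the latent
#' dimension); weights start from the embedded ridge-regression solution.
#'
#' @param S_short truncated transient block (first `N_T'` samples), one row
#'   per training transient.
#' @param Z_target latent matrix from [encode()], same row count.
#' @param cfg a [training_config()]; use `batch_size = 64` for single cells.
#' @param ridge_lambda relative ridge parameter of the initialization.
#' @return Object of class `meister_regressor`.
#' @export
fit_regressor <- function(S_short, Z_target,
                          cfg = training_config(epochs = 50),
                          ridge_lambda = 1e-3) {
  S_short <- .check_block(S_short)
  Z_target <- as.matrix(Z_target)
  if (nrow(S_short) != nrow(Z_target))
    stop("row count mismatch: ", nrow(S_short), " transients vs ",
         nrow(Z_target), " latent vectors", call. = FALSE)
  d <- ncol(S_short); r <- ncol(Z_target)
  X <- .row_normalize(S_short)$X
  mu <- colMeans(X); zbar <- colMeans(Z_target)
  Xc <- sweep(X, 2, mu); Zc <- sweep(Z_target, 2, zbar)
  G <- crossprod(Xc) / nrow(Xc)
  B <- solve(G + ridge_lambda * mean(diag(G)) * diag(d),
             crossprod(Xc, Zc) / nrow(Xc))
  sizes <- c(d, 512, 256, 64, r)
  net <- nn_init_linear_encoder(sizes, B, mu, out_shift = zbar,
                                seed = cfg$seed + 2L)
  fit <- nn_train_mse(net, X, Z_target, epochs = cfg$epochs,
                      batch_size = cfg$batch_size, lr = cfg$lr,
                      weight_decay = cfg$weight_decay, seed = cfg$seed)
  structure(list(net = fit$net, n_short = d, latent_dim = r,
                 loss_curve = fit$loss_curve, init_loss = fit$init_loss,
                 config = cfg),
            class = "meister_regressor")
}

#' Fit the full reconstruction model
#'
#' Convenience wrapper that trains the deep autoencoder on full-length
#' transients, encodes them, and trains the latent regressor on their short
#' prefixes, returning a single model object whose [predict()] method
#' reconstructs full-length transients from short ones.
#'
#' @param S training transient block (full length).
#' @param short_points number of leading samples available at reconstruction
#'   time (`N_T'`).
#' @param latent_dim latent dimension (default 32).
#' @param dae_config,regressor_config [training_config()]s for the two
#'   networks.
#' @return Object of class `meister_model` with fields `dae` and `regressor`.
#' @examples
#' \donttest{
#' tb <- ft_timebase(512, 1e5)
#' sim <- simulate_msi(height = 6, width = 6, n_regions = 2,
#'                     formulas = c("C6H12O6", "C5H5N5"), timebase = tb,
#'                     noise_sigma = 0.2, seed = 1)
#' m <- meister(sim$noisy, short_points = 64, latent_dim = 8,
#'              dae_config = training_config(epochs = 5, batch_size = 16),
#'              regressor_config = training_config(epochs = 5, batch_size = 16))
#' rec <- predict(m, sim$noisy[, 1:64])
#' }
#' @export
meister <- function(S, short_points, latent_dim = 32,
                    dae_config = training_config(epochs = 20),
                    regressor_config = training_config(epochs = 50)) {
  S <- .check_block(S)
  if (short_points >= ncol(S))
    stop("`short_points` must be smaller than the full transient length",
         call. = FALSE)
  dae <- fit_autoencoder(S, latent_dim = latent_dim, cfg = dae_config)
  Z <- encode(dae, S)
  reg <- fit_regressor(S[, seq_len(short_points), drop = FALSE], Z,
                       cfg = regressor_config)
  structure(list(dae = dae, regressor = reg,
                 short_points = as.integer(short_points),
                 n_time = ncol(S), latent_dim = latent_dim),
            class = "meister_model")
}

#' Reconstruct full-length transients from short ones
#'
#' Applies the trained regressor to the (per-row max-abs normalized) short
#' transients, decodes the predicted latent vectors with the trained decoder,
#' and restores the per-row scale.
#'
#' @param S_short short transient block (`N_T'` columns).
#' @param model a `meister_model` (or a list with `dae` and `regressor`).
#' @return Reconstructed block, rows x full transient length.
#' @export
reconstruct <- function(S_short, model) {
  if (is.null(model$dae) || is.null(model$regressor))
    stop("model is not trained (missing dae or regressor)", call. = FALSE)
  S_short <- .check_block(S_short)
  if (ncol(S_short) != model$regressor$n_short)
    stop("short block has ", ncol(S_short),
         " columns; regressor expects ", model$regressor$n_short,
         call. = FALSE)
  norm <- .row_normalize(S_short)
  Z <- nn_forward(model$regressor$net, norm$X)
  out <- nn_forward(model$dae$decoder, Z)
  out * norm$scale
}

#' @export
predict.meister_model <- function(object, newdata, ...) {
  reconstruct(newdata, object)
}

#' @export
print.meister_dae <- function(x, ...) {
  cat(sprintf(
    "Deep autoencoder: %d -> 512 -> 256 -> 64 -> %d (latent) -> ... -> %d\n",
    x$n_time, x$latent_dim, x$n_time))
  cat(sprintf("  final training MSE %.3e (%d epochs)\n",
              min(c(x$init_loss, x$loss_curve)), length(x$loss_curve)))
  invisible(x)
}

#' @export
print.meister_regressor <- function(x, ...) {
  cat(sprintf("Latent regressor: %d -> 512 -> 256 -> 64 -> %d\n",
              x$n_short, x$latent_dim))
  invisible(x)
}

#' @export
print.meister_model <- function(x, ...) {
  cat(sprintf(
    "Reconstruction model: %d-point transients from %d-point prefixes (%.1f%%), latent %d\n",
    x$n_time, x$short_points, 100 * x$short_points / x$n_time,
    x$latent_dim))
  invisible(x)
}

#' @export
summary.meister_model <- function(object, ...) {
  print(object)
  cat("DAE loss curve: ", paste(sprintf("%.2e", object$dae$loss_curve),
                                collapse = " "), "\n")
  cat("Regressor loss curve: ",
      paste(sprintf("%.2e", object$regressor$loss_curve), collapse = " "),
      "\n")
  invisible(object)
}

#' Save or load a reconstruction model checkpoint
#'
#' Checkpoints are single portable files; the round-trip preserves all
#' weights bit-for-bit, so reloaded models produce identical outputs.
#'
#' @param model a `meister_model` (or `meister_dae` / `meister_regressor`).
#' @param path file path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
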