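#' Validate a pipeline configuration
#'
#' Checks the stage blocks of a pipeline configuration against the
#' preconditions of the corresponding module functions before anything
#' runs; a missing required field raises an error naming the field.
#'
#' @param config nested list (or path to a YAML/JSON file) with the
#'   optional stage blocks `simulate`, `reconstruct`, `spectra`, `register`,
#'   `integrate` and the top-level fields `seed` and `outdir`.
#' @return The normalized config (invisibly a list).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a file path",
                             call. = FALSE)
  need <- function(block, field, check = NULL) {
    if (is.null(config[[block]][[field]]))
      stop(sprintf("config field missing: %s$%s", block, field),
           call. = FALSE)
    v <- config[[block]][[field]]
    if (!is.null(check) && !check(v))
      stop(sprintf("config field invalid: %s$%s", block, field),
           call. = FALSE)
    v
  }
  if (is.null(config$seed))
    stop("config field missing: seed", call. = FALSE)
  if (is.null(config$outdir))
    stop("config field missing: outdir", call. = FALSE)
  if (!is.null(config$simulate)) {
    need("simulate", "height", function(x) x >= 1)
    need("simulate", "width", function(x) x >= 1)
    need("simulate", "n_points", function(x) x >= 2)
    nr <- config$simulate$n_regions
    if (!is.null(nr) && config$simulate$height * config$simulate$width < nr)
      stop("config field invalid: simulate$n_regions (more regions than pixels)",
           call. = FALSE)
  }
  if (!is.null(config$reconstruct)) {
    need("reconstruct", "short_points", function(x) x >= 1)
    need("reconstruct", "train_frac", function(x) x > 0 && x <= 1)
  }
  if (!is.null(config$register)) {
    if (!is.null(config$register$max_iter) && config$register$max_iter < 1)
      stop("config field invalid: register$max_iter", call. = FALSE)
  }
  invisible(config)
}

#' Run the simulation-to-integration pipeline
#'
#' Executes the configured stages in order — simulate, reconstruct, spectra,
#' register, integrate — writing every artifact into `outdir` and recording
#' a JSON manifest (files, stage metrics, timings, seed, package version).
#' Rerunning with the same config and seed reproduces the deterministic
#' stage metrics exactly.
#'
#' @param config see [validate_config()].
#' @return The manifest, invisibly; it is also written to
#'   `outdir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  manifest <- list(seed = seed,
                   package_version = as.character(utils::packageVersion("meister")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages = list())
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  add_stage <- function(name, files, metrics, secs) {
    manifest$stages[[name]] <<- list(files = files, metrics = metrics,
                                     seconds = round(secs, 2))
    write_manifest()
  }

  sim <- NULL; rec <- NULL; table <- NULL
  if (!is.null(config$simulate)) {
    t0 <- Sys.time()
    sc <- config$simulate
    sim <- simulate_msi(
      height = sc$height, width = sc$width,
      n_regions = sc$n_regions %||% 8,
      formulas = sc$formulas %||% .default_formulas,
      timebase = ft_timebase(sc$n_points,
                             sc$sampling_rate %||% 1.368e6),
      noise_sigma = sc$noise_sigma %||% 1,
      seed = seed)
    f <- file.path(outdir, "simulated_msi.rds")
    save_simulated_msi(sim, f)
    ft <- file.path(outdir, "ion_table.csv")
    write_ion_table(sim, ft)
    add_stage("simulate", c(f, ft),
              list(pixels = nrow(sim$noisy), ions = nrow(sim$ion_table)),
              as.numeric(Sys.time() - t0, units = "secs"))
  }
  if (!is.null(config$reconstruct)) {
    if (is.null(sim)) stop("reconstruct stage requires the simulate stage",
                           call. = FALSE)
    t0 <- Sys.time()
    rc <- config$reconstruct
    set.seed(seed)
    idx <- sample(nrow(sim$noisy),
                  max(2, round(rc$train_frac * nrow(sim$noisy))))
    model <- meister(
      sim$noisy[idx, , drop = FALSE], short_points = rc$short_points,
      latent_dim = rc$latent_dim %||% 32,
      dae_config = training_config(epochs = rc$dae_epochs %||% 20,
                                   batch_size = rc$batch_size %||% 128,
                                   seed = seed),
      regressor_config = training_config(
        epochs = rc$regressor_epochs %||% 50,
        batch_size = rc$batch_size %||% 128, seed = seed))
    rec <- reconstruct(sim$noisy[, seq_len(rc$short_points), drop = FALSE],
                       model)
    fm <- file.path(outdir, "recon_model.rds")
    save_model(model, fm)
    ev <- evaluate_reconstruction(sim$noisy, rec, sim$timebase,
                                  sim$instrument)
    add_stage("reconstruct", fm,
              list(mean_snr_gain_db = ev$mean_snr_gain_db,
                   median_per_pixel_r = stats::median(ev$per_pixel_r,
                                                      na.rm = TRUE)),
              as.numeric(Sys.time() - t0, units = "secs"))
  }
  if (!is.null(config$spectra)) {
    if (is.null(sim)) stop("spectra stage requires the simulate stage",
                           call. = FALSE)
    t0 <- Sys.time()
    spcfg <- config$spectra
    block <- if (!is.null(rec)) rec else sim$noisy
    sp <- block_spectra(block, sim$timebase, sim$instrument)
    mean_spec <- structure(list(mz = sp$mz,
                                intensity = colMeans(sp$intensity),
                                frequency = sp$frequency),
                           class = "ms_spectrum")
    nf <- max(0.05, min(1, 60 / length(sp$mz)))
    pk <- pick_peaks(mean_spec, snr_threshold = spcfg$snr %||% 3,
                     noise_window = c(stats::quantile(sp$mz, 1 - nf),
                                      max(sp$mz)))
    idx <- vapply(pk$mz, function(m) which.min(abs(sp$mz - m)), 1L)
    lists <- lapply(seq_len(nrow(sp$intensity)), function(i)
      data.frame(mz = pk$mz, intensity = sp$intensity[i, idx]))
    table <- ppm_bin(lists, width_ppm = spcfg$bin_ppm %||% 3)
    table <- suppressWarnings(tic_normalize(table))
    fi <- file.path(outdir, "peaks")
    write_imzml(table, data.frame(x = sim$coords[, 1],
                                  y = sim$coords[, 2]), fi)
    add_stage("spectra", paste0(fi, c(".imzML", ".ibd")),
              list(n_peaks = length(table$mz)),
              as.numeric(Sys.time() - t0, units = "secs"))
  }
  if (!is.null(config$register)) {
    if (is.null(table)) stop("register stage requires the spectra stage",
                             call. = FALSE)
    t0 <- Sys.time()
    rg <- config$register
    shape <- dim(sim$region_map)
    emb <- fit_parametric_embedding(table, seed = seed,
                                    min_train = min(nrow(table$intensity),
                                                    500))
    fimg <- feature_image(table, emb, shape)
    # synthetic anatomical reference: smoothed region phantom
    ref <- .smooth_labels(sim$region_map)
    tr <- register_pair(fimg, ref, max_iter = rg$max_iter %||% 200,
                        seed = seed)
    ft <- file.path(outdir, "transform.rds")
    saveRDS(tr, ft)
    add_stage("register", ft,
              list(mi_init = tr$mi_init, mi_final = tr$mi_final),
              as.numeric(Sys.time() - t0, units = "secs"))
  }
  if (!is.null(config$integrate)) {
    t0 <- Sys.time()
    ic <- config$integrate
    syn <- synth_multiscale(L = ic$L %||% 3, k = ic$k %||% 4,
                            noise = ic$noise %||% 0.05, seed = seed)
    cl <- cluster_cells(syn$cells, seed = seed)
    dicts <- lapply(sort(unique(cl)), function(l)
      learn_cluster_dictionary(syn$cells[cl == l, , drop = FALSE],
                               k = ic$k %||% 4, seed = seed))
    un <- build_union(dicts)
    fit <- uoss_fit(syn$Y, un$U)
    maps <- contribution_maps(fit$C, un$index, syn$coords)
    ev <- evaluate_fit(syn$Y, fit$C, un$U)
    fc <- file.path(outdir, "contribution_maps.rds")
    saveRDS(maps, fc)
    add_stage("integrate", fc,
              list(n_clusters = length(unique(cl)),
                   median_pixel_r = stats::median(ev$per_pixel_r,
                                                  na.rm = TRUE),
                   n_negative_spatial_r = ev$n_negative_spatial_r),
              as.numeric(Sys.time() - t0, units = "secs"))
  }
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  write_manifest()
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# blur a label map into a grayscale pseudo-anatomical reference
.smooth_labels <- function(labels, sigma = 1.5) {
  lab <- matrix(as.numeric(labels), nrow(labels), ncol(labels))
  k <- 2 * ceiling(2 * sigma) + 1
  off <- -(k %/% 2):(k %/% 2)
  kern <- exp(-off^2 / (2 * sigma^2)); kern <- kern / sum(kern)
  pad <- function(m) m[pmin(pmax(row(m), 1), nrow(m))]
  # separable convolution with edge replication
  h <- nrow(lab); w <- ncol(lab)
  tmp <- matrix(0, h, w)
  for (d in seq_along(off)) {
    rows <- pmin(pmax(seq_len(h) + off[d], 1), h)
    tmp <- tmp + kern[d] * lab[rows, , drop = FALSE]
  }
  out <- matrix(0, h, w)
  for (d in seq_along(off)) {
    cols <- pmin(pmax(seq_len(w) + off[d], 1), w)
    out <- out + kern[d] * tmp[, cols, drop = FALSE]
  }
  out
}
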