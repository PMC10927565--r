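#' Instrument configuration for an FT-ICR mass spectrometer
#'
#' Bundles the magnetic field strength with the two instrument constants used
#' by the signal model: the unperturbed cyclotron relation
#' \eqn{f = K \cdot B_0 / (m/z)} with \eqn{K = 1.535611\times 10^7}
#' Hz Da / (charge T), and the resolution prefactor \eqn{1.274\times 10^7} in
#' \eqn{m/\Delta m = 1.274\times 10^7 \, z B_0 T_{aqn} / m}.
#'
#' @param B0 magnetic field strength in tesla (default 7, a common FT-ICR
#'   field).
#' @return An object of class `instrument_config`.
#' @examples
#' instrument_config(B0 = 7)
#' @export
instrument_config <- function(B0 = 7) {
  if (!is.numeric(B0) || length(B0) != 1L || !is.finite(B0) || B0 <= 0)
    stop("`B0` must be a single positive number (tesla)", call. = FALSE)
  structure(list(B0 = B0,
                 cyclotron_constant = .cyclotron_constant,
                 resolution_constant = .resolution_constant),
            class = "instrument_config")
}

#' @export
print.instrument_config <- function(x, ...) {
  cat("FT-ICR instrument: B0 =", x$B0, "T;",
      "f = ", format(x$cyclotron_constant, digits = 7), "* B0 / (m/z) Hz\n")
  invisible(x)
}

#' Acquisition timebase for transient signals
#'
#' A transient is sampled at `n_points` equally spaced times starting at 0
#' with sampling rate `sampling_rate` (Hz), so its duration is
#' `n_points / sampling_rate` seconds. The default sampling rate, 1.368 MHz,
#' makes a one-million-point acquisition last 0.731 s, the standard
#' high-resolution setting this package scales down from.
#'
#' @param n_points number of discrete time samples (>= 2; powers of two keep
#'   the FFT fast).
#' @param sampling_rate sampling rate in Hz.
#' @return An object of class `timebase` with fields `n_points`,
#'   `sampling_rate`, `duration` and the sample times `t`.
#' @examples
#' tb <- ft_timebase(16384)
#' tb$duration
#' @export
ft_timebase <- function(n_points = 16384, sampling_rate = 1.368e6) {
  if (!is.numeric(n_points) || length(n_points) != 1L || n_points < 2)
    stop("`n_points` must be a single integer >= 2", call. = FALSE)
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("`sampling_rate` must be positive (Hz)", call. = FALSE)
  n_points <- as.integer(round(n_points))
  structure(list(n_points = n_points,
                 sampling_rate = sampling_rate,
                 duration = n_points / sampling_rate,
                 t = seq(0, by = 1 / sampling_rate,
                         length.out = n_points)),
            class = "timebase")
}

#' @export
print.timebase <- function(x, ...) {
  cat(sprintf("Timebase: %d points @ %.4g Hz (T = %.4g s)\n",
              x$n_points, x$sampling_rate, x$duration))
  invisible(x)
}

#' Convert m/z to cyclotron frequency and back
#'
#' Uses the unperturbed cyclotron relation
#' \eqn{f = K B_0 / (m/z)}; `mz_from_frequency()` is its exact inverse.
#'
#' @param mz mass-to-charge ratio(s) in Da per elementary charge (> 0).
#' @param frequency cyclotron frequency(ies) in Hz (> 0).
#' @param instrument an [instrument_config()].
#' @return Frequency in Hz (resp. m/z in Da/charge).
#' @examples
#' frequency_from_mz(400, instrument_config(7))
#' @export
frequency_from_mz <- function(mz, instrument = instrument_config()) {
  if (!is.numeric(mz) || any(!is.finite(mz)) || any(mz <= 0))
    stop("`mz` must be positive and finite", call. = FALSE)
  instrument$cyclotron_constant * instrument$B0 / mz
}

#' @rdname frequency_from_mz
#' @export
mz_from_frequency <- function(frequency, instrument = instrument_config()) {
  if (!is.numeric(frequency) || any(!is.finite(frequency)) ||
      any(frequency <= 0))
    stop("`frequency` must be positive and finite", call. = FALSE)
  instrument$cyclotron_constant * instrument$B0 / frequency
}

#' Theoretical FT-ICR mass resolution
#'
#' Evaluates \eqn{m/\Delta m = 1.274\times 10^7 \, z B_0 T_{aqn} / m}, the
#' theoretical resolving power of an FT-ICR acquisition of duration
#' \eqn{T_{aqn}} at magnetic field \eqn{B_0} for an ion of mass
#' \eqn{m = (m/z) \cdot z}. Resolution is proportional to the transient
#' duration, which is why shortened acquisitions trade resolution for
#' throughput.
#'
#' @param mz mass-to-charge ratio (Da/charge, > 0).
#' @param z charge state (> 0), default 1.
#' @param instrument an [instrument_config()].
#' @param T_aqn transient acquisition time in seconds (> 0).
#' @return Dimensionless resolving power.
#' @examples
#' # ~160,000 at m/z 400 for a 0.731 s transient at 7 T
#' theoretical_resolution(400, 1, instrument_config(7), T_aqn = 0.731)
#' @export
theoretical_resolution <- function(mz, z = 1, instrument = instrument_config(),
                                   T_aqn) {
  if (any(!is.finite(mz)) || any(mz <= 0)) stop("`mz` must be > 0", call. = FALSE)
  if (any(!is.finite(z)) || any(z <= 0)) stop("`z` must be > 0", call. = FALSE)
  if (any(!is.finite(T_aqn)) || any(T_aqn <= 0))
    stop("`T_aqn` must be > 0 (seconds)", call. = FALSE)
  m <- mz * z
  instrument$resolution_constant * z * instrument$B0 * T_aqn / m
}

#' Parse a molecular formula string
#'
#' Turns e.g. `"C42H82NO8P"` into a named integer vector of element counts.
#'
#' @param formula formula string, or an already-parsed named vector (returned
#'   unchanged).
#' @return Named integer vector of element counts.
#' @keywords internal
parse_formula <- function(formula) {
  if (is.numeric(formula) && !is.null(names(formula))) {
    counts <- formula
  } else {
    if (!is.character(formula) || length(formula) != 1L || !nzchar(formula))
      stop("`formula` must be a single non-empty string", call. = FALSE)
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
    toks <- regmatches(formula, list(m))[[1]]
    toks <- toks[nzchar(toks)]
    if (paste(toks, collapse = "") != formula)
      stop("unparseable formula: ", formula, call. = FALSE)
    el <- sub("^([A-Z][a-z]?).*$", "\\1", toks)
    ct <- sub("^[A-Z][a-z]?", "", toks)
    counts <- ifelse(nzchar(ct), as.numeric(ct), 1)
    names(counts) <- el
    counts <- tapply(counts, names(counts), sum)
    counts <- counts[order(names(counts))]
  }
  bad <- setdiff(names(counts), names(.isotope_table))
  if (length(bad))
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(counts < 0) || !length(counts))
    stop("formula must be non-empty with non-negative counts", call. = FALSE)
  storage.mode(counts) <- "integer"
  counts
}

# Convolve two aggregated isotope distributions indexed by integer nominal
# mass shift. Each is a list(prob, mass) where mass[k] is the
# abundance-weighted mean mass at shift k-1.
.iso_convolve <- function(a, b, tail_prob = 1e-15) {
  na <- length(a$prob); nb <- length(b$prob)
  n <- na + nb - 1L
  prob <- numeric(n); mmass <- numeric(n)
  for (i in seq_len(na)) {
    if (a$prob[i] <= 0) next
    idx <- i:(i + nb - 1L)
    pr <- a$prob[i] * b$prob
    prob[idx] <- prob[idx] + pr
    mmass[idx] <- mmass[idx] + pr * (a$mass[i] + b$mass)
  }
  keep <- prob > 0
  mmass[keep] <- mmass[keep] / prob[keep]
  # drop a negligible high-mass tail to keep the support compact
  cum <- rev(cumsum(rev(prob)))
  last <- max(which(cum > tail_prob))
  list(prob = prob[seq_len(last)], mass = mmass[seq_len(last)])
}

# Distribution of n atoms of one element by repeated squaring.
.iso_element <- function(symbol, n) {
  iso <- .isotope_table[[symbol]]
  shift <- as.integer(round(iso[, "mass"] - iso[1, "mass"]))
  base <- list(prob = numeric(max(shift) + 1L),
               mass = numeric(max(shift) + 1L))
  base$prob[shift + 1L] <- iso[, "abundance"]
  base$mass[shift + 1L] <- iso[, "mass"]
  out <- list(prob = 1, mass = 0)
  while (n > 0) {
    if (n %% 2 == 1) out <- .iso_convolve(out, base)
    n <- n %/% 2
    if (n > 0) base <- .iso_convolve(base, base)
  }
  out
}

#' Aggregated isotopic distribution of a chemical formula
#'
#' Computes the aggregated (nominal-mass-grouped) isotopologue distribution of
#' a molecular formula by exact convolution of the elemental isotope
#' polynomials, equivalent to the aggregated output of polynomial-based
#' isotope calculators. Peak masses are abundance-weighted centroid masses of
#' all isotopologues sharing a nominal mass shift.
#'
#' @param formula formula string (e.g. `"C100"`) or named element-count
#'   vector.
#' @param min_abundance relative abundance threshold; peaks whose abundance is
#'   below `min_abundance` times the base peak are dropped (default 1e-3).
#' @return An object of class `isotope_pattern`: a data.frame with columns
#'   `mass` (Da) and `abundance` (base peak = 1), sorted by mass, with the raw
#'   isotopologue probabilities (summing to <= 1 after truncation) in
#'   `attr(, "probability")`.
#' @examples
#' isotope_pattern("C6H12O6")
#' @export
isotope_pattern <- function(formula, min_abundance = 1e-3) {
  counts <- parse_formula(formula)
  counts <- counts[counts > 0]
  if (!length(counts))
    stop("formula must contain at least one atom", call. = FALSE)
  dist <- NULL
  for (el in names(counts)) {
    d <- .iso_element(el, counts[[el]])
    dist <- if (is.null(dist)) d else .iso_convolve(dist, d)
  }
  keep <- dist$prob >= min_abundance * max(dist$prob)
  out <- data.frame(mass = dist$mass[keep],
                    abundance = dist$prob[keep] / max(dist$prob))
  out <- out[order(out$mass), ]
  rownames(out) <- NULL
  structure(out, probability = dist$prob[keep],
            class = c("isotope_pattern", "data.frame"))
}

#' Adduct m/z of a neutral molecule
#'
#' Adds the mass of a singly charged cation (proton 1.007276 Da, sodium
#' 22.989218 Da or potassium 38.963158 Da, electron mass accounted for) to a
#' neutral monoisotopic mass.
#'
#' @param neutral_mass neutral mass in Da (> 0); vectorized.
#' @param adduct one of `"H"`, `"Na"`, `"K"`.
#' @return m/z of the singly charged adduct ion.
#' @examples
#' adduct_mz(180.063388, "H")   # 181.070664
#' @export
adduct_mz <- function(neutral_mass, adduct = c("H", "Na", "K")) {
  adduct <- match.arg(adduct)
  if (!is.numeric(neutral_mass) || any(!is.finite(neutral_mass)) ||
      any(neutral_mass <= 0))
    stop("`neutral_mass` must be positive", call. = FALSE)
  neutral_mass + .adduct_masses[[adduct]]
}

#' Synthesize a damped-sinusoid FT-ICR transient
#'
#' Evaluates the generic FT-ICR signal model
#' \deqn{s(t) = \sum_i A_i e^{-t/\tau_i} \cos(\omega_i t) + \varepsilon(t)}
#' on a timebase, where each component has initial amplitude \eqn{A_i}, decay
#' constant \eqn{\tau_i} (ion-collision damping) and angular cyclotron
#' frequency \eqn{\omega_i}, and \eqn{\varepsilon} is i.i.d. Gaussian noise.
#'
#' @param components a data.frame (or list of lists) with columns/fields
#'   `amplitude` (>= 0), `tau` (seconds, > 0, may be `Inf`) and `omega`
#'   (rad/s). May have zero rows.
#' @param timebase a [ft_timebase()].
#' @param noise_sigma standard deviation of the additive Gaussian noise
#'   (intensity units, >= 0).
#' @param seed integer seed for the noise realization; the result is
#'   deterministic given the seed.
#' @return Numeric vector of length `timebase$n_points` with class
#'   `transient` and the timebase attached as attribute `timebase`.
#' @examples
#' tb <- ft_timebase(1024, 1e5)
#' s <- synthesize_transient(
#'   data.frame(amplitude = 1, tau = Inf, omega = 2 * pi * 1e4), tb)
#' @export
synthesize_transient <- function(components, timebase, noise_sigma = 0,
                                 seed = 1L) {
  if (!inherits(timebase, "timebase") || timebase$n_points < 1)
    stop("`timebase` must be a non-empty ft_timebase()", call. = FALSE)
  if (!is.numeric(noise_sigma) || noise_sigma < 0)
    stop("`noise_sigma` must be >= 0", call. = FALSE)
  comp <- as.data.frame(components)
  s <- numeric(timebase$n_points)
  if (nrow(comp)) {
    if (any(comp$amplitude < 0))
      stop("component amplitudes must be >= 0", call. = FALSE)
    if (any(comp$tau <= 0))
      stop("component decay constants tau must be > 0", call. = FALSE)
    t <- timebase$t
    for (i in seq_len(nrow(comp))) {
      damp <- if (is.finite(comp$tau[i])) exp(-t / comp$tau[i]) else 1
      s <- s + comp$amplitude[i] * damp * cos(comp$omega[i] * t)
    }
  }
  if (noise_sigma > 0) {
    set.seed(as.integer(seed))
    s <- s + stats::rnorm(timebase$n_points, sd = noise_sigma)
  }
  structure(s, timebase = timebase, class = "transient")
}

#' Seeded Voronoi region phantom
#'
#' Partitions a `height` x `width` pixel grid into `n_regions` contiguous
#' regions by a seeded Voronoi tessellation (random centers, nearest-center
#' labels), a synthetic stand-in for an anatomical annotation volume.
#'
#' @param height,width grid dimensions in pixels.
#' @param n_regions number of regions (default 8).
#' @param seed integer seed; the same seed reproduces the same map.
#' @return Integer matrix (`height` x `width`) of labels in `1:n_regions`,
#'   with class `region_map`.
#' @examples
#' table(make_region_map(20, 20, 4, seed = 1))
#' @export
make_region_map <- function(height, width, n_regions = 8, seed = 1L) {
  if (n_regions < 1) stop("`n_regions` must be >= 1", call. = FALSE)
  if (height * width < n_regions)
    stop("grid has fewer pixels than regions", call. = FALSE)
  set.seed(as.integer(seed))
  # Centers drawn without replacement from the pixel grid so each region is
  # non-empty by construction of the nearest-center rule plus a repair pass.
  repeat {
    cx <- stats::runif(n_regions, 0.5, width + 0.5)
    cy <- stats::runif(n_regions, 0.5, height + 0.5)
    gx <- matrix(rep(seq_len(width), each = height), height, width)
    gy <- matrix(rep(seq_len(height), times = width), height, width)
    d2 <- sapply(seq_len(n_regions),
                 function(k) (gx - cx[k])^2 + (gy - cy[k])^2)
    lab <- max.col(-d2, ties.method = "first")
    if (length(unique(lab)) == n_regions) break
  }
  structure(matrix(as.integer(lab), height, width), class = "region_map")
}

#' Simulate a ground-truthed FT-ICR MSI dataset
#'
#' Generates per-pixel damped-sinusoid transients over a multi-region spatial
#' phantom. Each region carries a different combination of chemical formulas;
#' every formula contributes all three adducts (\[M+H\]+, \[M+Na\]+, \[M+K\]+)
#' and all isotopologues above `min_abundance`. Clean and noisy transient
#' blocks are returned together with the full ground truth (region map, ion
#' table, per-pixel amplitude factors).
#'
#' Amplitudes are drawn per formula and region (log-uniform in
#' `amplitude_range`), multiplied by fixed adduct efficiencies and isotope
#' abundances; each pixel additionally receives a log-normal scalar
#' brightness factor (`pixel_sdlog`) emulating per-pixel signal variation.
#'
#' @param region_map a [make_region_map()] matrix, or `NULL` to generate one
#'   with `height`, `width`, `n_regions`.
#' @param height,width,n_regions phantom geometry when `region_map` is `NULL`.
#' @param formulas character vector of molecular formulas (default: the
#'   bundled panel of 30 lipid-like formulas).
#' @param formulas_per_region how many formulas are assigned to each region
#'   (sampled with replacement across regions; every formula is used at least
#'   once). Default 10.
#' @param region_assignments optional list mapping each region to the indices
#'   of its formulas, overriding the random assignment; an empty entry leaves
#'   that region noise-only (with a warning).
#' @param adducts adduct set, default `c("H", "Na", "K")`.
#' @param instrument an [instrument_config()].
#' @param timebase a [ft_timebase()]; default 16,384 points at 1.368 MHz.
#' @param noise_sigma Gaussian noise s.d. in intensity units (default 1).
#' @param tau ICR decay constant in seconds applied to all components
#'   (default 1).
#' @param amplitude_range range for the per-formula, per-region base
#'   amplitudes (default `c(0.5, 1.5)`).
#' @param pixel_sdlog sdlog of the per-pixel log-normal brightness factor
#'   (default 0.2).
#' @param min_abundance isotopologue truncation threshold passed to
#'   [isotope_pattern()].
#' @param seed integer seed controlling all randomness.
#' @return An object of class `simulated_msi`: a list with `region_map`,
#'   `ion_table` (data.frame: formula, adduct, isotope_index, mz, frequency,
#'   region, amplitude), `timebase`, `instrument`, `clean` and `noisy` pixel x
#'   time matrices, `pixel_scale`, `coords`, `noise_sigma` and `seed`.
#' @examples
#' sim <- simulate_msi(height = 8, width = 8, n_regions = 2,
#'                     formulas = c("C6H12O6", "C5H5N5"),
#'                     timebase = ft_timebase(512), seed = 1)
#' dim(sim$noisy)
#' @export
simulate_msi <- function(region_map = NULL, height = 50, width = 50,
                         n_regions = 8,
                         formulas = .default_formulas,
                         formulas_per_region = 10,
                         region_assignments = NULL,
                         adducts = c("H", "Na", "K"),
                         instrument = instrument_config(),
                         timebase = ft_timebase(16384),
                         noise_sigma = 1, tau = 1,
                         amplitude_range = c(0.5, 1.5),
                         pixel_sdlog = 0.2,
                         min_abundance = 1e-3,
                         seed = 1L) {
  if (is.null(region_map))
    region_map <- make_region_map(height, width, n_regions, seed = seed)
  n_regions <- max(region_map)
  if (!length(formulas)) stop("need at least one formula", call. = FALSE)
  set.seed(as.integer(seed))

  # region -> formula assignment: each region draws `formulas_per_region`
  # formulas; every formula is guaranteed at least one region.
  if (is.null(region_assignments)) {
    fpr <- min(formulas_per_region, length(formulas))
    assign_list <- lapply(seq_len(n_regions),
                          function(r) sort(sample(length(formulas), fpr)))
    unused <- setdiff(seq_along(formulas), unlist(assign_list))
    for (f in unused) {
      r <- sample(n_regions, 1)
      assign_list[[r]] <- sort(union(assign_list[[r]], f))
    }
  } else {
    if (length(region_assignments) != n_regions)
      stop("`region_assignments` must have one entry per region",
           call. = FALSE)
    assign_list <- lapply(region_assignments, as.integer)
  }
  empty <- which(!vapply(assign_list, length, 1L))
  if (length(empty))
    warning("regions without formulas: ", paste(empty, collapse = ", "),
            "; their pixels are noise-only")

  # isotope patterns and adduct m/z per formula
  adduct_eff <- c(H = 1, Na = 0.4, K = 0.2)[adducts]
  patt <- lapply(formulas, isotope_pattern, min_abundance = min_abundance)
  ion_rows <- list()
  for (fi in seq_along(formulas)) {
    p <- patt[[fi]]
    regions <- which(vapply(assign_list, function(a) fi %in% a, TRUE))
    for (r in regions) {
      base_amp <- exp(stats::runif(1, log(amplitude_range[1]),
                                   log(amplitude_range[2])))
      for (ad in adducts) {
        mz <- p$mass + .adduct_masses[[ad]]
        ion_rows[[length(ion_rows) + 1L]] <- data.frame(
          formula = formulas[fi], adduct = ad,
          isotope_index = seq_len(nrow(p)) - 1L,
          mz = mz,
          frequency = frequency_from_mz(mz, instrument),
          region = r,
          amplitude = base_amp * adduct_eff[[ad]] * p$abundance)
      }
    }
  }
  ion_table <- do.call(rbind, ion_rows)
  rownames(ion_table) <- NULL

  # one clean template per region, then per-pixel scaling
  t <- timebase$t
  damp <- if (is.finite(tau)) exp(-t / tau) else rep(1, length(t))
  templates <- matrix(0, n_regions, timebase$n_points)
  for (r in seq_len(n_regions)) {
    rows <- ion_table[ion_table$region == r, ]
    if (!nrow(rows)) next
    for (i in seq_len(nrow(rows)))
      templates[r, ] <- templates[r, ] +
        rows$amplitude[i] * cos(2 * pi * rows$frequency[i] * t)
    templates[r, ] <- templates[r, ] * damp
  }

  n_pix <- length(region_map)
  pixel_scale <- stats::rlnorm(n_pix, meanlog = 0, sdlog = pixel_sdlog)
  lab <- as.vector(region_map)
  clean <- templates[lab, , drop = FALSE] * pixel_scale
  noisy <- clean
  if (noise_sigma > 0)
    noisy <- noisy + matrix(stats::rnorm(length(clean), sd = noise_sigma),
                            nrow = n_pix)

  coords <- cbind(x = as.vector(row(region_map)),
                  y = as.vector(col(region_map)))
  structure(list(region_map = region_map, ion_table = ion_table,
                 timebase = timebase, instrument = instrument,
                 clean = clean, noisy = noisy,
                 pixel_scale = pixel_scale, coords = coords,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "simulated_msi")
}

#' @export
print.simulated_msi <- function(x, ...) {
  cat(sprintf(
    "Simulated MSI: %d pixels x %d time points, %d regions, %d ions (sigma = %g)\n",
    nrow(x$noisy), ncol(x$noisy), max(x$region_map), nrow(x$ion_table),
    x$noise_sigma))
  invisible(x)
}

#' Persist or restore a simulated MSI dataset
#'
#' The dataset (clean and noisy blocks, region map, ion table, timebase and
#' all generation parameters) is stored in a single portable container; the
#' round-trip is bit-exact. The ion table can additionally be exported as CSV
#' with [write_ion_table()].
#'
#' @param sim a `simulated_msi` object.
#' @param path file path.
#' @return `load_simulated_msi()` returns the restored object.
#' @export
save_simulated_msi <- function(sim, path) {
  stopifnot(inherits(sim, "simulated_msi"))
  saveRDS(sim, path)
  invisible(path)
}

#' @rdname save_simulated_msi
#' @export
load_simulated_msi <- function(path) {
  sim <- readRDS(path)
  if (!inherits(sim, "simulated_msi"))
    stop("file does not contain a simulated_msi object", call. = FALSE)
  sim
}

#' @rdname save_simulated_msi
#' @export
write_ion_table <- function(sim, path) {
  stopifnot(inherits(sim, "simulated_msi"))
  utils::write.csv(sim$ion_table, path, row.names = FALSE)
  invisible(path)
}
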