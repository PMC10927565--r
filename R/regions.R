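#' Region-averaged spectral profiles
#'
#' Averages the feature intensities of all pixels sharing an anatomical
#' label, producing the region x feature profile matrix used for
#' region-specific analysis.
#'
#' @param table `peak_table` or pixels x features matrix, pixels aligned
#'   with `labels`.
#' @param labels integer/factor vector or matrix of region labels, one per
#'   pixel.
#' @param region_levels regions expected; defaults to the labels present.
#'   Regions absent from `labels` are dropped with a warning.
#' @return regions x features matrix with region labels as rownames and the
#'   per-region pixel counts in `attr(, "n_pixels")`.
#' @export
extract_region_profiles <- function(table, labels, region_levels = NULL) {
  X <- if (inherits(table, "peak_table")) table$intensity else as.matrix(table)
  lab <- as.vector(labels)
  if (length(lab) != nrow(X))
    stop("label count does not match pixel count", call. = FALSE)
  if (is.null(region_levels)) region_levels <- sort(unique(lab))
  missing_regions <- setdiff(region_levels, unique(lab))
  if (length(missing_regions)) {
    warning("region(s) absent from the label image, omitted: ",
            paste(missing_regions, collapse = ", "))
    region_levels <- setdiff(region_levels, missing_regions)
  }
  f <- factor(lab, levels = region_levels)
  keep <- !is.na(f)
  prof <- rowsum(X[keep, , drop = FALSE], f[keep]) /
    as.vector(table(f[keep]))
  attr(prof, "n_pixels") <- as.vector(table(f[keep]))
  prof
}

#' Differential feature analysis (rank-sum + BH)
#'
#' For every feature, compares the `group` samples against the `rest`
#' samples: the effect size is the log2 ratio of group means, significance
#' is the two-sided Wilcoxon rank-sum test, and p-values are adjusted with
#' the Benjamini-Hochberg procedure.
#'
#' @param group,rest samples x features intensity matrices with matched
#'   columns; at least 3 samples each.
#' @return data.frame with columns `feature`, `log2fc` (NA when the rest
#'   mean is zero), `p` and `q` (BH-adjusted, monotone in `p`).
#' @export
differential_features <- function(group, rest) {
  group <- as.matrix(group); rest <- as.matrix(rest)
  if (ncol(group) != ncol(rest))
    stop("feature columns differ", call. = FALSE)
  if (nrow(group) < 3 || nrow(rest) < 3)
    stop("need at least 3 samples per side", call. = FALSE)
  nf <- ncol(group)
  p <- numeric(nf); fc <- numeric(nf)
  for (j in seq_len(nf)) {
    g <- group[, j]; r <- rest[, j]
    mg <- mean(g); mr <- mean(r)
    fc[j] <- if (mr <= 0 || mg < 0) NA_real_ else log2(mg / mr)
    p[j] <- tryCatch(
      suppressWarnings(stats::wilcox.test(g, r, exact = NULL)$p.value),
      error = function(e) NA_real_)
  }
  q <- stats::p.adjust(p, method = "BH")
  data.frame(feature = seq_len(nf), log2fc = fc, p = p, q = q)
}
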