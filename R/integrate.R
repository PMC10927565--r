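#' Cross-annotate single-cell peak lists against tissue features
#'
#' Uses the tissue MSI feature list as the reference database: every cell
#' peak is assigned to the nearest tissue feature within a ppm window (ties
#' broken toward the lower m/z). Features detected in fewer than
#' `min_cell_frac` of the cells are discarded, then cells retaining fewer
#' than `min_feature_frac` of the remaining features are dropped.
#'
#' @param cell_peaklists list of per-cell data.frames with columns `mz` and
#'   `intensity`, each sorted by m/z.
#' @param tissue_features sorted numeric vector of tissue m/z features.
#' @param ppm match window in ppm (default 3).
#' @param min_cell_frac minimum fraction of cells a feature must appear in
#'   (default 0.05).
#' @param min_feature_frac minimum fraction of retained features a cell must
#'   carry (default 0.05).
#' @return Object of class `cell_feature_matrix`: list with `X` (cells x
#'   features, intensities), `mz` (feature m/z), `cells` (indices of kept
#'   cells) and a `report` of matched/dropped counts.
#' @export
cross_annotate <- function(cell_peaklists, tissue_features, ppm = 3,
                           min_cell_frac = 0.05, min_feature_frac = 0.05) {
  stopifnot(is.list(cell_peaklists), length(cell_peaklists) >= 1)
  tf <- sort(as.numeric(tissue_features))
  m <- length(cell_peaklists); n <- length(tf)
  X <- matrix(0, m, n)
  n_matched <- 0L; n_unmatched <- 0L
  for (i in seq_len(m)) {
    pl <- cell_peaklists[[i]]
    if (!nrow(pl)) next
    for (k in seq_len(nrow(pl))) {
      mz <- pl$mz[k]
      d <- abs(tf - mz) / mz * 1e6
      best <- which(d == min(d))[1]          # ties -> lower m/z
      if (d[best] <= ppm) {
        X[i, best] <- X[i, best] + pl$intensity[k]
        n_matched <- n_matched + 1L
      } else n_unmatched <- n_unmatched + 1L
    }
  }
  if (n_matched == 0L) {
    warning("no cell peaks matched any tissue feature")
    return(structure(list(X = matrix(0, 0, 0), mz = numeric(0),
                          cells = integer(0),
                          report = list(matched = 0L,
                                        unmatched = n_unmatched,
                                        features_dropped = n,
                                        cells_dropped = m)),
                     class = "cell_feature_matrix"))
  }
  feat_keep <- colMeans(X > 0) >= min_cell_frac
  Xf <- X[, feat_keep, drop = FALSE]
  cell_keep <- rowMeans(Xf > 0) >= min_feature_frac
  structure(list(X = Xf[cell_keep, , drop = FALSE],
                 mz = tf[feat_keep],
                 cells = which(cell_keep),
                 report = list(matched = n_matched,
                               unmatched = n_unmatched,
                               features_dropped = sum(!feat_keep),
                               cells_dropped = sum(!cell_keep))),
            class = "cell_feature_matrix")
}

#' @export
print.cell_feature_matrix <- function(x, ...) {
  cat(sprintf("Cell feature matrix: %d cells x %d features\n",
              nrow(x$X), ncol(x$X)))
  invisible(x)
}

#' Cluster single cells by their spectral features
#'
#' TIC-normalizes the cell x feature matrix, reduces it to `n_pcs` principal
#' components, builds a cosine k-nearest-neighbour graph (`n_neighbors`) and
#' partitions it with Leiden community detection at the given resolution.
#'
#' @param X a `cell_feature_matrix` or plain non-negative matrix.
#' @param n_neighbors neighbours of the kNN graph (default 30).
#' @param n_pcs number of principal components (default 40; reduced with a
#'   warning when fewer are available).
#' @param resolution Leiden resolution parameter (default 0.25).
#' @param seed integer seed (community detection is stochastic).
#' @return Integer vector of cluster labels (1-based).
#' @export
cluster_cells <- function(X, n_neighbors = 30, n_pcs = 40,
                          resolution = 0.25, seed = 1L) {
  M <- if (inherits(X, "cell_feature_matrix")) X$X else as.matrix(X)
  m <- nrow(M)
  if (m < n_neighbors + 1)
    stop("fewer cells than the neighbour count", call. = FALSE)
  M <- suppressWarnings(tic_normalize(M))
  max_pcs <- min(m - 1L, ncol(M))
  if (max_pcs < n_pcs) {
    warning("only ", max_pcs, " principal components available")
    n_pcs <- max_pcs
  }
  pc <- stats::prcomp(M, center = TRUE, scale. = FALSE,
                      rank. = n_pcs)$x
  # cosine kNN graph
  nr <- sqrt(rowSums(pc^2)); nr[nr == 0] <- 1
  U <- pc / nr
  sim <- tcrossprod(U)
  diag(sim) <- -Inf
  edges <- integer(0)
  for (i in seq_len(m)) {
    nb <- order(sim[i, ], decreasing = TRUE)[seq_len(n_neighbors)]
    edges <- c(edges, rbind(i, nb))
  }
  g <- igraph::simplify(igraph::make_graph(edges, n = m, directed = FALSE))
  set.seed(as.integer(seed))
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution,
                               n_iterations = 5)
  as.integer(igraph::membership(cl))
}

#' Learn a non-negative dictionary for one cell cluster
#'
#' Factorizes the non-negative cell x feature matrix of one cluster as
#' \eqn{X \approx W D} with \eqn{W \ge 0} (cells x k weights) and
#' \eqn{D \ge 0} (k x features dictionary) by multiplicative updates on the
#' Frobenius loss, initialized with NNDSVD (zeros replaced by the matrix
#' mean).
#'
#' @param X_l non-negative matrix of the cluster's cells (>= 2 rows).
#' @param k number of dictionary items (default 20; capped at
#'   `min(dim(X_l))`).
#' @param seed integer seed.
#' @param max_iter maximum multiplicative updates (default 500).
#' @param tol relative-change stopping tolerance (default 1e-5).
#' @return Object of class `cluster_dictionary`: list with `W`, `D`, `k`,
#'   `rel_error` (relative Frobenius reconstruction error) and `iterations`.
#' @export
learn_cluster_dictionary <- function(X_l, k = 20, seed = 1L,
                                     max_iter = 500, tol = 1e-5) {
  X_l <- as.matrix(X_l)
  if (any(X_l < 0)) stop("matrix must be non-negative", call. = FALSE)
  if (nrow(X_l) < 2) stop("need at least 2 cells", call. = FALSE)
  k_eff <- min(k, dim(X_l))
  set.seed(as.integer(seed))
  sv <- svd(X_l, nu = k_eff, nv = k_eff)
  W <- matrix(0, nrow(X_l), k_eff); D <- matrix(0, k_eff, ncol(X_l))
  # NNDSVD: split each singular pair into its positive and negative parts
  for (j in seq_len(k_eff)) {
    u <- sv$u[, j]; v <- sv$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    npos <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
    nneg <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
    if (j == 1 || npos >= nneg) {
      if (npos > 0) {
        W[, j] <- sqrt(sv$d[j] * npos) * up / sqrt(sum(up^2))
        D[j, ] <- sqrt(sv$d[j] * npos) * vp / sqrt(sum(vp^2))
      }
    } else if (nneg > 0) {
      W[, j] <- sqrt(sv$d[j] * nneg) * un / sqrt(sum(un^2))
      D[j, ] <- sqrt(sv$d[j] * nneg) * vn / sqrt(sum(vn^2))
    }
  }
  mean_x <- mean(X_l)
  W[W == 0] <- mean_x; D[D == 0] <- mean_x
  eps <- .Machine$double.eps
  err_prev <- Inf
  nx <- norm(X_l, "F")
  it_used <- max_iter
  for (it in seq_len(max_iter)) {
    W <- W * (X_l %*% t(D)) / (W %*% D %*% t(D) + eps)
    D <- D * (t(W) %*% X_l) / (t(W) %*% W %*% D + eps)
    err <- norm(X_l - W %*% D, "F") / nx
    if (is.finite(err_prev) && abs(err_prev - err) < tol * max(err, eps)) {
      it_used <- it
      break
    }
    err_prev <- err
  }
  structure(list(W = W, D = D, k = k_eff,
                 rel_error = norm(X_l - W %*% D, "F") / nx,
                 iterations = it_used, seed = as.integer(seed)),
            class = "cluster_dictionary")
}

#' @export
print.cluster_dictionary <- function(x, ...) {
  cat(sprintf(
    "Cluster dictionary: %d items x %d features (rel. error %.4f)\n",
    x$k, ncol(x$D), x$rel_error))
  invisible(x)
}

#' Stack per-cluster dictionaries into a union matrix
#'
#' @param dictionaries list of [learn_cluster_dictionary()] results sharing
#'   one feature list.
#' @return list with `U` ((sum of k) x features matrix, rows in cluster
#'   order) and `index` (data.frame mapping each row of `U` to its cluster
#'   and item).
#' @export
build_union <- function(dictionaries) {
  stopifnot(length(dictionaries) >= 1)
  nf <- vapply(dictionaries, function(d) ncol(d$D), 1L)
  if (length(unique(nf)) != 1)
    stop("dictionaries have differing feature counts", call. = FALSE)
  U <- do.call(rbind, lapply(dictionaries, `[[`, "D"))
  index <- data.frame(
    cluster = rep(seq_along(dictionaries),
                  vapply(dictionaries, function(d) as.integer(d$k), 1L)),
    item = unlist(lapply(dictionaries, function(d) seq_len(d$k))))
  list(U = U, index = index)
}

#' Union-of-subspaces non-negative fit of tissue pixels
#'
#' Solves, independently for every tissue pixel,
#' \deqn{C = \arg\min_{C \ge 0} \|Y - C U\|_F^2}
#' by non-negative least squares, where `U` stacks the single-cell
#' dictionaries of all clusters. All-zero dictionary rows are excluded from
#' the solve (their coefficients are fixed at 0) with a warning.
#'
#' @param Y tissue pixels x features matrix (non-negative).
#' @param U union dictionary matrix (rows = dictionary items).
#' @return list with `C` (pixels x items, non-negative), `objective`
#'   (\eqn{\|Y - CU\|_F^2}) and `residual_norm`.
#' @export
uoss_fit <- function(Y, U) {
  Y <- as.matrix(Y); U <- as.matrix(U)
  if (ncol(Y) != ncol(U))
    stop("Y and U must share the feature axis", call. = FALSE)
  if (any(Y < 0)) stop("Y must be non-negative", call. = FALSE)
  live <- rowSums(abs(U)) > 0
  if (!all(live))
    warning(sum(!live), " all-zero dictionary row(s); coefficients fixed at 0")
  A <- t(U[live, , drop = FALSE])          # features x live items
  C <- matrix(0, nrow(Y), nrow(U))
  for (i in seq_len(nrow(Y))) {
    y <- Y[i, ]
    if (all(y == 0)) next
    C[i, live] <- pracma::lsqnonneg(A, y)$x
  }
  obj <- norm(Y - C %*% U, "F")^2
  list(C = C, objective = obj, residual_norm = sqrt(obj))
}

#' Per-cluster contribution maps
#'
#' For every pixel and cluster, takes the Euclidean norm of that cluster's
#' block of UoSS coefficients and renders it at the pixel locations,
#' yielding one contribution image per cell cluster.
#'
#' @param C pixels x items coefficient matrix from [uoss_fit()].
#' @param index item-to-cluster map from [build_union()].
#' @param coords pixels x 2 matrix/data.frame of grid coordinates (`x` =
#'   row, `y` = column, 1-based), or `NULL` for a vector result.
#' @return list of matrices (or vectors when `coords` is `NULL`), one per
#'   cluster, named `cluster_<l>`.
#' @export
contribution_maps <- function(C, index, coords = NULL) {
  C <- as.matrix(C)
  clusters <- sort(unique(index$cluster))
  out <- vector("list", length(clusters))
  names(out) <- paste0("cluster_", clusters)
  for (li in seq_along(clusters)) {
    cols <- which(index$cluster == clusters[li])
    val <- sqrt(rowSums(C[, cols, drop = FALSE]^2))
    if (is.null(coords)) {
      out[[li]] <- val
    } else {
      coords <- as.matrix(coords)
      img <- matrix(0, max(coords[, 1]), max(coords[, 2]))
      img[coords] <- val
      out[[li]] <- img
    }
  }
  out
}

#' Goodness of the UoSS fit
#'
#' Pearson correlations between observed and fitted intensities: per pixel
#' (across features, 'spectral' correlation) and per feature (across pixels,
#' 'spatial' correlation), plus the count of features with negative spatial
#' correlation. Constant vectors yield `NA`.
#'
#' @param Y observed tissue matrix.
#' @param C fitted coefficients.
#' @param U union dictionary.
#' @return list with `per_pixel_r`, `per_feature_r`,
#'   `n_negative_spatial_r`, `fitted`.
#' @export
evaluate_fit <- function(Y, C, U) {
  Y <- as.matrix(Y)
  fitted <- as.matrix(C) %*% as.matrix(U)
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }
  per_pixel <- vapply(seq_len(nrow(Y)),
                      function(i) safe_cor(Y[i, ], fitted[i, ]), numeric(1))
  per_feature <- vapply(seq_len(ncol(Y)),
                        function(j) safe_cor(Y[, j], fitted[, j]),
                        numeric(1))
  list(per_pixel_r = per_pixel, per_feature_r = per_feature,
       n_negative_spatial_r = sum(per_feature < 0, na.rm = TRUE),
       fitted = fitted)
}

#' Synthetic multiscale single-cell + tissue dataset
#'
#' Draws `L` ground-truth non-negative dictionaries with cluster-specific
#' dominant features, generates single cells as noisy non-negative mixtures
#' of their cluster's dictionary items, and composes tissue pixels as
#' spatial mixtures of the cluster dictionaries over a pixel grid (one
#' smooth Gaussian-blob mixing map per cluster), with multiplicative
#' amplitude jitter and additive noise clipped at zero. Ground truth (cell
#' cluster labels, dictionaries, tissue coefficient matrix and mixing maps)
#' is returned for parameter-recovery studies.
#'
#' @param L number of cell clusters (default 3).
#' @param k dictionary items per cluster (default 4).
#' @param n_features feature count (default 60).
#' @param cells_per_cluster cells per cluster (default 200).
#' @param grid `c(height, width)` tissue grid (default `c(24, 24)`).
#' @param noise relative noise level (default 0.05).
#' @param seed integer seed.
#' @return list with `cells` (matrix), `cell_labels`, `dictionaries` (list
#'   of true k x n matrices), `Y` (pixels x features), `C_true`,
#'   `mixing_maps`, `coords`, `mz` (synthetic m/z axis).
#' @export
synth_multiscale <- function(L = 3, k = 4, n_features = 60,
                             cells_per_cluster = 200, grid = c(24, 24),
                             noise = 0.05, seed = 1L) {
  set.seed(as.integer(seed))
  n <- n_features
  # cluster-specific dominant blocks keep the clusters chemically distinct
  dicts <- vector("list", L)
  block <- split(seq_len(n), rep(seq_len(L), each = ceiling(n / L))[seq_len(n)])
  for (l in seq_len(L)) {
    D <- matrix(stats::rexp(k * n, rate = 10), k, n)     # faint background
    own <- block[[l]]
    D[, own] <- D[, own] + matrix(stats::rexp(k * length(own), rate = 0.5),
                                  k, length(own))
    dicts[[l]] <- D
  }
  # cells: W >= 0 mixing of the cluster's items + noise
  cells <- NULL; labels <- integer(0)
  for (l in seq_len(L)) {
    W <- matrix(stats::rgamma(cells_per_cluster * k, shape = 2,
                              rate = 2), cells_per_cluster, k)
    Xl <- W %*% dicts[[l]]
    Xl <- Xl + matrix(stats::rnorm(length(Xl), sd = noise * mean(Xl)),
                      nrow(Xl))
    cells <- rbind(cells, pmax(Xl, 0))
    labels <- c(labels, rep(l, cells_per_cluster))
  }
  # tissue: per-cluster smooth spatial mixing maps (Gaussian blobs)
  h <- grid[1]; w <- grid[2]
  rr <- row(matrix(0, h, w)); cc <- col(matrix(0, h, w))
  maps <- vector("list", L)
  for (l in seq_len(L)) {
    m <- matrix(0.05, h, w)
    for (bl in 1:2) {
      c0 <- c(stats::runif(1, 1, h), stats::runif(1, 1, w))
      s0 <- stats::runif(1, h / 6, h / 3)
      m <- m + exp(-((rr - c0[1])^2 + (cc - c0[2])^2) / (2 * s0^2))
    }
    maps[[l]] <- m
  }
  p <- h * w
  C_true <- matrix(0, p, k * L)
  for (l in seq_len(L)) {
    wts <- matrix(stats::rgamma(p * k, shape = 2, rate = 2), p, k)
    C_true[, (l - 1) * k + seq_len(k)] <- as.numeric(maps[[l]]) * wts
  }
  U_true <- do.call(rbind, dicts)
  Y <- C_true %*% U_true
  Y <- pmax(Y + matrix(stats::rnorm(length(Y), sd = noise * mean(Y)),
                       nrow(Y)), 0)
  coords <- cbind(x = as.numeric(rr), y = as.numeric(cc))
  list(cells = cells, cell_labels = labels, dictionaries = dicts,
       Y = Y, C_true = C_true, mixing_maps = maps, coords = coords,
       mz = 400 + seq_len(n) * 0.5, seed = as.integer(seed))
}
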