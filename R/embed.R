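# Parametric UMAP feature embedding for MSI sections.
#
# A neural encoder (256/128/64 ReLU units into a 3-dimensional linear output)
# is trained on a random pixel subset to minimize the UMAP cross-entropy
#   C = sum_{i!=j} v_ij log(v_ij/w_ij) + (1-v_ij) log((1-v_ij)/(1-w_ij))
# between high-dimensional fuzzy-neighbour weights v_ij and embedding
# similarities w_ij = (1 + a d^2b)^-1, jointly with a mirrored decoder
# minimizing reconstruction MSE. Because the map is parametric, all pixels of
# all sections embed into one shared space.

# kernel parameters fitted for min_dist = 0.1, spread = 1 (standard values)
.umap_a <- 1.576943
.umap_b <- 0.895061

# fuzzy simplicial set: smooth-kNN weights with per-point bandwidth chosen so
# the effective neighbour count is log2(k)
.umap_graph <- function(X, n_neighbors) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  target <- log2(n_neighbors)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[seq_len(n_neighbors)]
    d <- D[i, nb]
    rho <- min(d)
    lo <- 1e-6; hi <- 1e3
    for (it in 1:64) {
      sig <- (lo + hi) / 2
      s <- sum(exp(-pmax(d - rho, 0) / sig))
      if (s > target) hi <- sig else lo <- sig
    }
    rows[[i]] <- list(j = nb, v = exp(-pmax(d - rho, 0) / sig))
  }
  # symmetrize: v = v1 + v2 - v1*v2 on the union support
  V <- matrix(0, n, n)
  for (i in seq_len(n)) V[i, rows[[i]]$j] <- rows[[i]]$v
  V <- V + t(V) - V * t(V)
  idx <- which(V > 1e-8 & upper.tri(V), arr.ind = TRUE)
  list(i = idx[, 1], j = idx[, 2], v = V[cbind(idx[, 1], idx[, 2])], n = n)
}

#' Fit a parametric UMAP embedding of MSI features
#'
#' Trains the encoder/decoder pair on a random subset of pixels (default 10
#' percent, at least `min_train`) and returns a model that maps any pixel's
#' feature vector into the shared 3-dimensional embedding space.
#'
#' @param table a `peak_table` or plain pixels x features matrix (all
#'   sections row-bound together).
#' @param n_neighbors neighbourhood size of the fuzzy graph (default 15).
#' @param epochs training epochs over the positive edges (default 20).
#' @param train_frac fraction of pixels sampled for training (default 0.10).
#' @param min_train lower bound on the training subset size (default 500).
#' @param n_negative negative samples per positive edge (default 5).
#' @param lr Adam learning rate (default 1e-3).
#' @param recon_weight weight of the decoder reconstruction loss (default 1).
#' @param seed integer seed.
#' @return Object of class `embedding_model` with the encoder, decoder,
#'   feature scaling and training metadata.
#' @export
fit_parametric_embedding <- function(table, n_neighbors = 15, epochs = 20,
                                     train_frac = 0.10, min_train = 500,
                                     n_negative = 5, lr = 1e-3,
                                     recon_weight = 1, seed = 1L) {
  X <- if (inherits(table, "peak_table")) table$intensity else as.matrix(table)
  n <- nrow(X)
  if (n < n_neighbors + 1)
    stop("fewer pixels than the neighbour count", call. = FALSE)
  set.seed(as.integer(seed))
  n_train <- min(n, max(min_train, round(train_frac * n)))
  take <- sample.int(n, n_train)
  # feature standardization (stored in the model)
  ctr <- colMeans(X[take, , drop = FALSE])
  scl <- apply(X[take, , drop = FALSE], 2, stats::sd)
  scl[scl == 0] <- 1
  Xt <- sweep(sweep(X[take, , drop = FALSE], 2, ctr), 2, scl, "/")

  g <- .umap_graph(Xt, n_neighbors)
  d_in <- ncol(X)
  enc <- nn_new(c(d_in, 256, 128, 64, 3), seed = seed)
  dec <- nn_new(c(3, 64, 128, 256, d_in), seed = seed + 1L)
  st_e <- adam_init(enc); st_d <- adam_init(dec)
  a <- .umap_a; b <- .umap_b
  n_edges <- length(g$i)
  batch_edges <- min(256L, n_edges)
  eps <- 1e-3

  for (ep in seq_len(epochs)) {
    perm <- sample.int(n_edges)
    for (start in seq(1, n_edges, by = batch_edges)) {
      e <- perm[start:min(start + batch_edges - 1L, n_edges)]
      heads <- g$i[e]; tails <- g$j[e]
      negs <- sample.int(n_train, length(e) * n_negative, replace = TRUE)
      pts <- unique(c(heads, tails, negs))
      pos_map <- match(c(heads, tails, negs), pts)
      hs <- nn_forward(enc, Xt[pts, , drop = FALSE], keep = TRUE)
      Y <- hs[[length(hs)]]
      ne <- length(e)
      hi <- pos_map[seq_len(ne)]
      ti <- pos_map[ne + seq_len(ne)]
      ni <- matrix(pos_map[2 * ne + seq_len(ne * n_negative)], ne)
      Gy <- matrix(0, nrow(Y), 3)
      # attraction along positive edges
      diff <- Y[hi, , drop = FALSE] - Y[ti, , drop = FALSE]
      d2 <- rowSums(diff^2)
      coef <- g$v[e] * (2 * a * b * d2^(b - 1)) / (1 + a * d2^b)
      coef[!is.finite(coef)] <- 0
      gpos <- coef * diff
      for (kk in seq_len(ne)) {
        Gy[hi[kk], ] <- Gy[hi[kk], ] + gpos[kk, ]
        Gy[ti[kk], ] <- Gy[ti[kk], ] - gpos[kk, ]
      }
      # repulsion against sampled negatives
      for (q in seq_len(n_negative)) {
        diffn <- Y[hi, , drop = FALSE] - Y[ni[, q], , drop = FALSE]
        d2n <- rowSums(diffn^2)
        coefn <- (2 * b) / ((eps + d2n) * (1 + a * d2n^b))
        gneg <- -coefn * diffn
        for (kk in seq_len(ne)) {
          Gy[hi[kk], ] <- Gy[hi[kk], ] + gneg[kk, ]
          Gy[ni[kk, q], ] <- Gy[ni[kk, q], ] - gneg[kk, ]
        }
      }
      Gy <- Gy / ne
      # decoder reconstruction on the same points
      hs_d <- nn_forward(dec, Y, keep = TRUE)
      err <- hs_d[[length(hs_d)]] - Xt[pts, , drop = FALSE]
      Gd <- 2 * recon_weight * err / length(err)
      g_d <- nn_backprop(dec, hs_d, Gd)
      g_e <- nn_backprop(enc, hs, Gy + g_d$input_grad)
      upd <- adam_step(dec, st_d, g_d, lr = lr)
      dec <- upd$net; st_d <- upd$state
      upd <- adam_step(enc, st_e, g_e, lr = lr)
      enc <- upd$net; st_e <- upd$state
    }
  }
  structure(list(encoder = enc, decoder = dec, center = ctr, scale = scl,
                 n_neighbors = n_neighbors, train_frac = train_frac,
                 train_idx = take, seed = as.integer(seed)),
            class = "embedding_model")
}

#' @export
print.embedding_model <- function(x, ...) {
  cat(sprintf(
    "Parametric UMAP embedding: %d features -> 256 -> 128 -> 64 -> 3\n",
    length(x$center)))
  invisible(x)
}

#' Embed pixels with a trained parametric UMAP model
#'
#' @param model an `embedding_model`.
#' @param table `peak_table` or matrix with the training feature set.
#' @return pixels x 3 embedding matrix.
#' @export
embed_pixels <- function(model, table) {
  X <- if (inherits(table, "peak_table")) table$intensity else as.matrix(table)
  if (ncol(X) != length(model$center))
    stop("feature count mismatch: model trained on ", length(model$center),
         " features", call. = FALSE)
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  nn_forward(model$encoder, Xs)
}

#' Grayscale feature image of one MSI section
#'
#' Embeds the section's pixels into the three UMAP dimensions, min-max scales
#' each dimension to \[0,1\] as RGB channels, and converts to grayscale with
#' the luminance weights (0.299, 0.587, 0.114).
#'
#' @param table `peak_table` or matrix for one section (pixels in row-major
#'   grid order).
#' @param model a fitted [fit_parametric_embedding()] model.
#' @param shape `c(height, width)` of the section's pixel grid.
#' @return `height` x `width` matrix with values in \[0,1\].
#' @export
feature_image <- function(table, model, shape) {
  emb <- embed_pixels(model, table)
  rng <- apply(emb, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1
  rgb01 <- sweep(sweep(emb, 2, rng[1, ]), 2, span, "/")
  gray <- as.numeric(rgb01 %*% c(0.299, 0.587, 0.114))
  if (length(gray) != prod(shape))
    stop("pixel count does not match `shape`", call. = FALSE)
  matrix(gray, shape[1], shape[2])
}
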