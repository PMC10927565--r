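# Internal dense feed-forward network machinery (ReLU hidden layers, linear
# output) with Adam optimization. All operations are BLAS matmuls on
# row-major sample matrices (n x d). Not exported.

nn_new <- function(sizes, seed = 1L, init_sd = NULL) {
  set.seed(as.integer(seed))
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    sd <- if (is.null(init_sd)) sqrt(2 / sizes[l]) else init_sd
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1], sd = sd),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  list(sizes = sizes, W = W, b = b)
}

nn_forward <- function(net, X, keep = FALSE) {
  L <- length(net$W)
  h <- X
  hs <- if (keep) vector("list", L + 1L) else NULL
  if (keep) hs[[1]] <- h
  for (l in seq_len(L)) {
    a <- h %*% net$W[[l]]
    a <- sweep(a, 2, net$b[[l]], "+")
    h <- if (l < L) pmax(a, 0) else a      # ReLU hidden, linear output
    if (keep) hs[[l + 1L]] <- h
  }
  if (keep) hs else h
}

# Backprop from an arbitrary gradient G = dLoss/dOutput (n x out).
# Returns list(W = grads, b = grads).
nn_backprop <- function(net, hs, G) {
  L <- length(net$W)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- G
  for (l in L:1) {
    if (l < L) delta <- delta * (hs[[l + 1L]] > 0)   # ReLU derivative
    gW[[l]] <- crossprod(hs[[l]], delta)
    gb[[l]] <- colSums(delta)
    delta <- delta %*% t(net$W[[l]])
  }
  list(W = gW, b = gb, input_grad = delta)
}

adam_init <- function(net) {
  list(mW = lapply(net$W, function(w) w * 0),
       vW = lapply(net$W, function(w) w * 0),
       mb = lapply(net$b, function(x) x * 0),
       vb = lapply(net$b, function(x) x * 0),
       t = 0L)
}

adam_step <- function(net, st, grads, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t; bc2 <- 1 - beta2^st$t
  for (l in seq_along(net$W)) {
    g <- grads$W[[l]]
    if (weight_decay > 0) g <- g + weight_decay * net$W[[l]]
    st$mW[[l]] <- beta1 * st$mW[[l]] + (1 - beta1) * g
    st$vW[[l]] <- beta2 * st$vW[[l]] + (1 - beta2) * g * g
    net$W[[l]] <- net$W[[l]] -
      lr * (st$mW[[l]] / bc1) / (sqrt(st$vW[[l]] / bc2) + eps)
    g <- grads$b[[l]]
    st$mb[[l]] <- beta1 * st$mb[[l]] + (1 - beta1) * g
    st$vb[[l]] <- beta2 * st$vb[[l]] + (1 - beta2) * g * g
    net$b[[l]] <- net$b[[l]] -
      lr * (st$mb[[l]] / bc1) / (sqrt(st$vb[[l]] / bc2) + eps)
  }
  list(net = net, state = st)
}

# Train with MSE loss, mini-batches, Adam; keeps the parameters of the best
# epoch (lowest full-data loss, including the initial model).
nn_train_mse <- function(net, X, Y, epochs, batch_size, lr = 1e-4,
                         weight_decay = 0, seed = 1L) {
  set.seed(as.integer(seed))
  n <- nrow(X)
  st <- adam_init(net)
  full_loss <- function(nt) mean((nn_forward(nt, X) - Y)^2)
  loss0 <- full_loss(net)
  if (!is.finite(loss0)) stop("non-finite loss at initialization",
                              call. = FALSE)
  best <- list(net = net, loss = loss0)
  curve <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    for (start in seq(1, n, by = batch_size)) {
      take <- idx[start:min(start + batch_size - 1L, n)]
      hs <- nn_forward(net, X[take, , drop = FALSE], keep = TRUE)
      err <- hs[[length(hs)]] - Y[take, , drop = FALSE]
      G <- 2 * err / length(err)
      grads <- nn_backprop(net, hs, G)
      upd <- adam_step(net, st, grads, lr = lr,
                       weight_decay = weight_decay)
      net <- upd$net; st <- upd$state
    }
    curve[ep] <- full_loss(net)
    if (!is.finite(curve[ep]))
      stop("training diverged (non-finite loss) at epoch ", ep,
           call. = FALSE)
    if (curve[ep] <= best$loss) best <- list(net = net, loss = curve[ep])
  }
  list(net = best$net, loss_curve = curve, init_loss = loss0,
       best_loss = best$loss)
}

# --- Linear-map embedding into the ReLU pair structure -----------------------
#
# A linear map y = t(P) %*% (x - mu_in) + c can be represented exactly by a
# ReLU network by carrying each signed coordinate s_j as the pair
# (relu(s_j), relu(-s_j)) through the hidden layers (s = relu(s) - relu(-s)).
# This embeds the truncated-SVD (or ridge) solution as the network's starting
# point; remaining units get small random fan-in and zero fan-out so training
# can recruit them without perturbing the linear path.

nn_init_linear_encoder <- function(sizes, P, mu_in, out_shift = NULL,
                                   seed = 1L) {
  # sizes: c(d, h1, h2, ..., 2*r_or_more, r); P: d x r; output = t(P)(x-mu)+c
  set.seed(as.integer(seed))
  r <- ncol(P)
  L <- length(sizes) - 1L
  stopifnot(all(sizes[2:L] >= 2 * r), sizes[L + 1L] == r)
  W <- vector("list", L); b <- vector("list", L)
  s0 <- as.numeric(crossprod(P, mu_in))
  # layer 1: pairs (P, -P) plus random spare units
  W[[1]] <- matrix(stats::rnorm(sizes[1] * sizes[2],
                                sd = 0.01 / sqrt(sizes[1])),
                   sizes[1], sizes[2])
  W[[1]][, 1:r] <- P
  W[[1]][, (r + 1):(2 * r)] <- -P
  b[[1]] <- numeric(sizes[2])
  b[[1]][1:r] <- -s0
  b[[1]][(r + 1):(2 * r)] <- s0
  # middle layers: re-split the signed value, zero fan-out elsewhere
  pair_block <- rbind(cbind(diag(r), -diag(r)),
                      cbind(-diag(r), diag(r)))   # (2r) x (2r)
  if (L >= 2) for (l in 2:L) {
    W[[l]] <- matrix(0, sizes[l], sizes[l + 1L])
    if (l < L) {
      W[[l]][1:(2 * r), 1:(2 * r)] <- pair_block
      spare_in <- sizes[l] > 2 * r
      if (sizes[l + 1L] > 2 * r && spare_in)
        W[[l]][(2 * r + 1):sizes[l], (2 * r + 1):sizes[l + 1L]] <-
          stats::rnorm((sizes[l] - 2 * r) * (sizes[l + 1L] - 2 * r),
                       sd = 0.01 / sqrt(sizes[l]))
    } else {
      W[[l]][1:r, ] <- diag(r)
      W[[l]][(r + 1):(2 * r), ] <- -diag(r)
    }
    b[[l]] <- numeric(sizes[l + 1L])
  }
  if (!is.null(out_shift)) b[[L]] <- b[[L]] + out_shift
  list(sizes = sizes, W = W, b = b)
}

nn_init_linear_decoder <- function(sizes, P, mu_out, seed = 1L) {
  # sizes: c(r, h1, ..., d); output = P %*% z + mu_out
  set.seed(as.integer(seed))
  r <- sizes[1]
  L <- length(sizes) - 1L
  stopifnot(all(sizes[2:L] >= 2 * r))
  W <- vector("list", L); b <- vector("list", L)
  W[[1]] <- matrix(stats::rnorm(sizes[1] * sizes[2],
                                sd = 0.01 / sqrt(sizes[1])),
                   sizes[1], sizes[2])
  W[[1]][, 1:r] <- diag(r)
  W[[1]][, (r + 1):(2 * r)] <- -diag(r)
  b[[1]] <- numeric(sizes[2])
  pair_block <- rbind(cbind(diag(r), -diag(r)),
                      cbind(-diag(r), diag(r)))
  if (L >= 2) for (l in 2:L) {
    W[[l]] <- matrix(0, sizes[l], sizes[l + 1L])
    if (l < L) {
      W[[l]][1:(2 * r), 1:(2 * r)] <- pair_block
      if (sizes[l + 1L] > 2 * r && sizes[l] > 2 * r)
        W[[l]][(2 * r + 1):sizes[l], (2 * r + 1):sizes[l + 1L]] <-
          stats::rnorm((sizes[l] - 2 * r) * (sizes[l + 1L] - 2 * r),
                       sd = 0.01 / sqrt(sizes[l]))
    } else {
      W[[l]][1:r, ] <- t(P)
      W[[l]][(r + 1):(2 * r), ] <- -t(P)
    }
    b[[l]] <- numeric(sizes[l + 1L])
  }
  b[[L]] <- mu_out
  list(sizes = sizes, W = W, b = b)
}
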