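test_that("cross-annotation applies ppm matching and prevalence filters", {
  tissue <- c(400.0000, 500.0000)
  # one cell: 2 ppm peak matches, 20 ppm peak does not
  cell <- list(data.frame(mz = c(400.0008, 500.0100),
                          intensity = c(1, 1)))
  ann <- cross_annotate(cell, tissue, ppm = 3, min_cell_frac = 0,
                        min_feature_frac = 0)
  expect_equal(sum(ann$X > 0), 1)
  expect_equal(ann$report$matched, 1L)
  expect_equal(ann$report$unmatched, 1L)

  # feature present in 4 of 100 cells is dropped at the 5% rule
  cells <- c(replicate(4, data.frame(mz = 400.0000, intensity = 1),
                       simplify = FALSE),
             replicate(96, data.frame(mz = 500.0000, intensity = 1),
                       simplify = FALSE))
  ann2 <- cross_annotate(cells, tissue)
  expect_equal(length(ann2$mz), 1)
  expect_equal(ann2$mz, 500.0000)

  # exact matches retain everything
  cells3 <- replicate(10, data.frame(mz = tissue, intensity = c(2, 3)),
                      simplify = FALSE)
  ann3 <- cross_annotate(cells3, tissue)
  expect_equal(dim(ann3$X), c(10L, 2L))
  expect_true(all(ann3$X > 0))
  # no matches at all
  expect_warning(
    empty <- cross_annotate(list(data.frame(mz = 900, intensity = 1)),
                            tissue), "no cell peaks")
  expect_equal(dim(empty$X), c(0L, 0L))
})

test_that("cross-annotation is order-independent", {
  set.seed(1)
  tissue <- sort(runif(12, 400, 900))
  cells <- lapply(1:40, function(i) {
    mz <- sort(sample(tissue, 6) * (1 + runif(6, -2e-6, 2e-6)))
    data.frame(mz = mz, intensity = runif(6))
  })
  a <- cross_annotate(cells, tissue)
  perm <- sample(length(cells))
  b <- cross_annotate(cells[perm], tissue)
  expect_equal(a$mz, b$mz)
  expect_equal(a$X[perm, ], b$X)
})

test_that("designed cell populations are recovered by clustering", {
  syn <- synth_multiscale(L = 3, seed = 3)
  cl <- cluster_cells(syn$cells, seed = 7)
  expect_gt(adjusted_rand(cl, syn$cell_labels), 0.9)
  # permuting the cells permutes labels but preserves the partition
  set.seed(8)
  perm <- sample(nrow(syn$cells))
  cl_perm <- cluster_cells(syn$cells[perm, ], seed = 7)
  expect_gt(adjusted_rand(cl_perm, cl[perm]), 0.999)
  # one homogeneous population (single dictionary item, so no latent
  # substructure) stays one cluster at low resolution
  one <- synth_multiscale(L = 1, k = 1, cells_per_cluster = 300, seed = 5)
  expect_equal(length(unique(cluster_cells(one$cells, seed = 3))), 1)
  expect_error(cluster_cells(syn$cells[1:10, ]), "fewer cells")
})

test_that("dictionary learning is non-negative and recovers exact factorizations", {
  set.seed(2)
  W <- matrix(runif(30 * 3), 30, 3)
  D <- matrix(runif(3 * 20), 3, 20)
  fit <- learn_cluster_dictionary(W %*% D, k = 3, seed = 1,
                                  max_iter = 3000, tol = 1e-8)
  expect_true(all(fit$W >= 0))
  expect_true(all(fit$D >= 0))
  expect_lt(fit$rel_error, 1e-3)
  # default k is 20
  expect_equal(formals(learn_cluster_dictionary)$k, 20)
  expect_error(learn_cluster_dictionary(matrix(c(-1, 2, 3, 4), 2)),
               "non-negative")
  expect_error(learn_cluster_dictionary(matrix(1, 1, 4)), "2 cells")
})

test_that("union dictionaries stack in cluster order", {
  set.seed(3)
  dicts <- lapply(1:3, function(l)
    learn_cluster_dictionary(matrix(runif(40 * 12), 40, 12), k = 4,
                             seed = l))
  un <- build_union(dicts)
  expect_equal(dim(un$U), c(12L, 12L))          # 3 clusters x 4 items
  expect_equal(un$index$cluster, rep(1:3, each = 4))
  expect_equal(un$U[5:8, ], dicts[[2]]$D)
  # single dictionary: the union is the dictionary itself
  un1 <- build_union(dicts[1])
  expect_equal(un1$U, dicts[[1]]$D)
  bad <- dicts
  bad[[2]]$D <- bad[[2]]$D[, 1:5]
  expect_error(build_union(bad), "differing feature")
})

test_that("non-negative fitting recovers known coefficients", {
  set.seed(4)
  U <- matrix(rexp(8 * 40), 8, 40)
  C_true <- matrix(rexp(60 * 8), 60, 8)
  C_true[sample(length(C_true), 100)] <- 0
  Y <- C_true %*% U
  fit <- uoss_fit(Y, U)
  expect_true(all(fit$C >= 0))
  expect_gt(cor(as.numeric(fit$C), as.numeric(C_true)), 0.99)
  # zero pixel row stays zero
  Y2 <- rbind(Y, 0)
  fit2 <- uoss_fit(Y2, U)
  expect_true(all(fit2$C[61, ] == 0))
  # objective never exceeds the zero-solution bound
  expect_lte(fit$objective, norm(Y, "F")^2)
  # all-zero dictionary row: warned, coefficient pinned at zero
  U0 <- rbind(U, 0)
  expect_warning(fit3 <- uoss_fit(Y, U0), "all-zero")
  expect_true(all(fit3$C[, 9] == 0))
})

test_that("NNLS equals unconstrained least squares on interior solutions", {
  set.seed(5)
  U <- matrix(runif(4 * 30, 0.5, 2), 4, 30)
  C_true <- matrix(runif(10 * 4, 1, 3), 10, 4)   # strictly positive
  Y <- C_true %*% U
  fit <- uoss_fit(Y, U)
  ols <- t(solve(tcrossprod(U), U %*% t(Y)))
  expect_true(all(ols > 0))
  expect_equal(fit$C, ols, tolerance = 1e-6)
})

test_that("adding a dictionary never increases the UoSS objective", {
  set.seed(6)
  for (i in 1:5) {
    U1 <- matrix(rexp(6 * 25), 6, 25)
    U2 <- rbind(U1, matrix(rexp(3 * 25), 3, 25))
    Y <- matrix(rexp(15 * 25), 15, 25)
    f1 <- uoss_fit(Y, U1)
    f2 <- uoss_fit(Y, U2)
    expect_lte(f2$objective, f1$objective + 1e-8)
  }
})

test_that("contribution maps take per-cluster coefficient norms", {
  C <- matrix(0, 2, 4)
  C[1, 1:2] <- c(3, 4)                    # cluster 1 -> norm 5
  index <- data.frame(cluster = c(1, 1, 2, 2), item = c(1, 2, 1, 2))
  maps <- contribution_maps(C, index)
  expect_equal(maps$cluster_1, c(5, 0))
  expect_equal(maps$cluster_2, c(0, 0))
  expect_true(all(unlist(maps) >= 0))
  # rendering onto a grid
  maps_img <- contribution_maps(C, index,
                                coords = cbind(x = c(1, 2), y = c(1, 1)))
  expect_equal(maps_img$cluster_1[1, 1], 5)
})

test_that("fit evaluation reports spectral and spatial correlations", {
  set.seed(7)
  U <- matrix(rexp(5 * 30), 5, 30)
  C <- matrix(rexp(40 * 5), 40, 5)
  Y <- C %*% U
  ev <- evaluate_fit(Y, C, U)
  expect_true(all(abs(ev$per_pixel_r - 1) < 1e-12))
  expect_equal(ev$n_negative_spatial_r, 0)
  # noise ladder: median per-pixel correlation decreases with noise
  meds <- vapply(c(0.05, 0.5, 5), function(s) {
    Yn <- pmax(Y + matrix(rnorm(length(Y), sd = s * mean(Y)), nrow(Y)), 0)
    median(evaluate_fit(Yn, C, U)$per_pixel_r, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(meds) < 0))
  # anti-structured feature counts as negative spatial correlation
  Y2 <- Y
  Y2[, 1] <- max(Y[, 1]) - Y[, 1]
  ev2 <- evaluate_fit(Y2, C, U)
  expect_gte(ev2$n_negative_spatial_r, 1)
})

test_that("the multiscale generator is seeded and self-consistent", {
  s1 <- synth_multiscale(seed = 9)
  s2 <- synth_multiscale(seed = 9)
  expect_identical(s1, s2)
  s3 <- synth_multiscale(seed = 10)
  expect_false(identical(s1$cells, s3$cells))
  expect_true(all(s1$cells >= 0))
  expect_true(all(s1$Y >= 0))
  expect_equal(dim(s1$C_true), c(nrow(s1$Y), 3 * 4))
})

test_that("the full integration pipeline recovers the designed contributions", {
  syn <- synth_multiscale(seed = 11)
  cl <- cluster_cells(syn$cells, seed = 11)
  expect_gt(adjusted_rand(cl, syn$cell_labels), 0.9)
  dicts <- lapply(sort(unique(cl)), function(l)
    learn_cluster_dictionary(syn$cells[cl == l, , drop = FALSE], k = 4,
                             seed = 2))
  un <- build_union(dicts)
  fit <- uoss_fit(syn$Y, un$U)
  maps <- contribution_maps(fit$C, un$index, syn$coords)
  true_maps <- contribution_maps(
    syn$C_true, data.frame(cluster = rep(1:3, each = 4),
                           item = rep(1:4, 3)), syn$coords)
  best <- vapply(maps, function(m)
    max(vapply(true_maps, function(t) cor(as.numeric(m), as.numeric(t)),
               numeric(1))), numeric(1))
  expect_gt(median(best), 0.95)
})
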