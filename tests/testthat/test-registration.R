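test_that("parametric embedding separates distinct spectral populations", {
  set.seed(4)
  n <- 300; nf <- 20
  mu1 <- runif(nf); mu2 <- mu1 + sample(c(0, 3), nf, TRUE, c(0.6, 0.4))
  X <- rbind(matrix(rnorm(n / 2 * nf, rep(mu1, each = n / 2), 0.3), n / 2),
             matrix(rnorm(n / 2 * nf, rep(mu2, each = n / 2), 0.3), n / 2))
  lab <- rep(1:2, each = n / 2)
  em <- fit_parametric_embedding(X, min_train = 300, seed = 1)
  emb <- embed_pixels(em, X)
  expect_equal(ncol(emb), 3)               # three embedding dimensions
  sil <- cluster::silhouette(lab, dist(emb))
  expect_gt(mean(sil[, 3]), 0.5)
  # defaults: 10% training pixels
  expect_equal(formals(fit_parametric_embedding)$train_frac, 0.10)
  expect_error(fit_parametric_embedding(X[1:5, ], n_neighbors = 15),
               "fewer pixels")
})

test_that("feature images are deterministic gray images in [0,1]", {
  set.seed(1)
  X <- rbind(matrix(rnorm(200 * 10, 0, 0.2), 200),
             matrix(rnorm(200 * 10, 4, 0.2), 200))
  em <- fit_parametric_embedding(X, min_train = 200, epochs = 10, seed = 1)
  img1 <- feature_image(X, em, c(20, 20))
  img2 <- feature_image(X, em, c(20, 20))
  expect_identical(img1, img2)
  expect_true(all(img1 >= 0 & img1 <= 1))
  expect_equal(dim(img1), c(20, 20))
  # the two populations (first vs last 10 grid columns) differ in gray level
  expect_gt(abs(mean(img1[, 1:10]) - mean(img1[, 11:20])), 0.1)
  expect_error(feature_image(X[, 1:5], em, c(20, 20)), "feature")
})

test_that("self-registration stays at the identity", {
  ref <- meister:::.smooth_labels(make_region_map(48, 48, 4, seed = 2))
  tr <- register_pair(ref, ref, bspline = FALSE)
  # mean displacement of the recovered affine is below half a pixel
  rr <- as.numeric(row(ref)); cc <- as.numeric(col(ref))
  p <- meister:::.affine_apply(tr$affine, rr, cc)
  disp <- sqrt((p$r - rr)^2 + (p$c - cc)^2)
  expect_lt(mean(disp), 0.5)
  expect_error(register_pair(matrix(1, 10, 10), ref), "constant")
})

test_that("a known integer shift is recovered within a pixel", {
  ref <- meister:::.smooth_labels(make_region_map(64, 64, 5, seed = 3))
  mov <- shift_image(ref, 5, -3)
  tr <- register_pair(mov, ref, bspline = FALSE)
  expect_lt(abs(tr$affine[5] - 5), 1)
  expect_lt(abs(tr$affine[6] + 3), 1)
  # MI trace is non-decreasing
  expect_gte(tr$mi_affine, tr$mi_init)
})

test_that("registration of a warped phantom improves every region's Dice", {
  rm_ <- make_region_map(64, 64, 5, seed = 3)
  ref <- meister:::.smooth_labels(rm_)
  lab_warp <- warp_image(rm_, amp = 1, shift = c(3, -2))
  mov_warp <- warp_image(ref, amp = 1, shift = c(3, -2), nearest = FALSE)
  tr <- register_pair(mov_warp, ref, seed = 1)
  expect_gte(tr$mi_affine, tr$mi_init)
  expect_gte(tr$mi_final, tr$mi_affine)
  lab_reg <- apply_transform(lab_warp, tr, "nearest")
  for (r in 1:5) {
    expect_gt(dice(lab_reg == r, rm_ == r), dice(lab_warp == r, rm_ == r))
  }
})

test_that("transforms resample as declared", {
  ref <- meister:::.smooth_labels(make_region_map(40, 40, 3, seed = 4))
  # identity transform returns the image unchanged
  id <- identity_transform(dim(ref))
  expect_equal(apply_transform(ref, id), ref)
  # pure translation moves a compact object's centroid by the stated amount
  rr <- row(matrix(0, 40, 40)); cc <- col(matrix(0, 40, 40))
  blob <- exp(-((rr - 22)^2 + (cc - 19)^2) / (2 * 3^2))
  tr <- identity_transform(dim(blob))
  tr$affine <- c(1, 0, 0, 1, 4, -2)       # fixed -> moving: sample at +4,-2
  out <- apply_transform(blob, tr)
  m_in <- meister:::.moments(blob)$center
  m_out <- meister:::.moments(out)$center
  expect_lt(abs((m_in[1] - m_out[1]) - 4), 0.5)
  expect_lt(abs((m_in[2] - m_out[2]) + 2), 0.5)
  # affine round trip via the stored inverse
  mov <- shift_image(ref, 5, -3)
  tr2 <- register_pair(mov, ref, bspline = FALSE)
  fwd <- apply_transform(mov, tr2)
  back <- apply_transform(fwd, tr2, inverse = TRUE)
  inner <- 10:30
  expect_gt(cor(as.numeric(mov[inner, inner]),
                as.numeric(back[inner, inner])), 0.99)
  expect_error(apply_transform(matrix(0, 3, 3), tr2), "shape")
})

test_that("dice follows its definition and symmetry", {
  a <- matrix(FALSE, 20, 20); a[1:10, 1:10] <- TRUE     # |A| = 100
  b <- matrix(FALSE, 20, 20); b[6:15, 1:10] <- TRUE     # |B| = 100, 50 shared
  expect_equal(dice(a, b), 0.5)
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, !a), 0)
  expect_equal(dice(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 1)
  expect_equal(dice(a, b), dice(b, a))
  expect_error(dice(a, matrix(TRUE, 3, 3)), "shapes")
  set.seed(1)
  for (i in 1:10) {
    x <- matrix(runif(100) > 0.5, 10)
    y <- matrix(runif(100) > 0.5, 10)
    d <- dice(x, y)
    expect_true(d >= 0 && d <= 1)
    expect_equal(d, dice(y, x))
  }
})

test_that("region profiles are exact per-region means", {
  X <- rbind(matrix(1, 3, 4), matrix(5, 2, 4))
  labels <- c(1, 1, 1, 2, 2)
  prof <- extract_region_profiles(X, labels)
  expect_equal(unname(prof[1, ]), rep(1, 4))
  expect_equal(unname(prof[2, ]), rep(5, 4))
  expect_equal(attr(prof, "n_pixels"), c(3, 2))
  # uniform table -> identical profiles
  Xu <- matrix(2, 5, 4)
  pu <- extract_region_profiles(Xu, labels)
  expect_equal(unname(pu[1, ]), unname(pu[2, ]))
  # single-region map -> global mean
  p1 <- extract_region_profiles(X, rep(1, 5))
  expect_equal(unname(p1[1, ]), colMeans(X))
  # absent region warns
  expect_warning(extract_region_profiles(X, labels,
                                         region_levels = c(1, 2, 7)),
                 "omitted")
})

test_that("differential analysis computes fold changes, p and q", {
  set.seed(6)
  g <- matrix(rexp(5 * 4), 5, 4)
  # identical groups: log2FC 0, p near 1
  d0 <- differential_features(g, g)
  expect_equal(d0$log2fc, rep(0, 4))
  # doubling: log2FC exactly 1
  d1 <- differential_features(2 * g, g)
  expect_equal(d1$log2fc, rep(1, 4))
  # zero denominator -> NA fold change
  g0 <- g; r0 <- g; r0[, 1] <- 0
  expect_true(is.na(differential_features(g0, r0)$log2fc[1]))
  # BH q-values: q >= p and monotone in p
  set.seed(7)
  a <- matrix(rnorm(20 * 50), 20)
  b <- matrix(rnorm(20 * 50), 20)
  d <- differential_features(a, b)
  expect_true(all(d$q >= d$p - 1e-12))
  ord <- order(d$p)
  expect_true(all(diff(d$q[ord]) >= -1e-12))
  expect_error(differential_features(a[1:2, ], b), "3 samples")
})
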