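# Multimodal image registration: moment-initialized affine stage followed by
# a cubic B-spline free-form deformation, both maximizing mutual information
# (32-bin joint histogram). Transforms follow the resampling convention: they
# map fixed-image coordinates to moving-image coordinates.

.mi <- function(fixed, moving_vals, bins = 32) {
  # partial-volume joint histogram: each sample spreads linearly over the
  # two nearest bins on each axis, giving a smooth MI landscape
  ok <- is.finite(moving_vals)
  if (!any(ok)) return(-Inf)
  f <- fixed[ok]; m <- moving_vals[ok]
  fpos <- pmin(pmax(f, 0), 1) * (bins - 1) + 1
  mpos <- pmin(pmax(m, 0), 1) * (bins - 1) + 1
  f0 <- pmin(floor(fpos), bins - 1L); m0 <- pmin(floor(mpos), bins - 1L)
  wf <- fpos - f0; wm <- mpos - m0
  joint <- matrix(0, bins, bins)
  add <- function(i, j, w) {
    acc <- rowsum(w, (j - 1L) * bins + i)
    joint[as.integer(rownames(acc))] <<- joint[as.integer(rownames(acc))] +
      acc[, 1]
  }
  add(f0,      m0,      (1 - wf) * (1 - wm))
  add(f0 + 1L, m0,      wf * (1 - wm))
  add(f0,      m0 + 1L, (1 - wf) * wm)
  add(f0 + 1L, m0 + 1L, wf * wm)
  p <- joint / sum(joint)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / (px[row(p)[nz]] * py[col(p)[nz]])))
}

# partial-volume MI plus its derivative with respect to each moving-image
# sample value (pointwise log-likelihood-ratio differences between the two
# m-bins each sample straddles)
.mi_with_grad <- function(fixed, moving_vals, bins = 32) {
  n_all <- length(moving_vals)
  ok <- is.finite(moving_vals)
  g <- numeric(n_all)
  if (!any(ok)) return(list(mi = -Inf, grad = g))
  f <- fixed[ok]; m <- moving_vals[ok]
  fpos <- pmin(pmax(f, 0), 1) * (bins - 1) + 1
  mcl <- pmin(pmax(m, 0), 1)
  mpos <- mcl * (bins - 1) + 1
  f0 <- pmin(floor(fpos), bins - 1L); m0 <- pmin(floor(mpos), bins - 1L)
  wf <- fpos - f0; wm <- mpos - m0
  joint <- matrix(0, bins, bins)
  add <- function(i, j, w) {
    acc <- rowsum(w, (j - 1L) * bins + i)
    joint[as.integer(rownames(acc))] <<- joint[as.integer(rownames(acc))] +
      acc[, 1]
  }
  add(f0,      m0,      (1 - wf) * (1 - wm))
  add(f0 + 1L, m0,      wf * (1 - wm))
  add(f0,      m0 + 1L, (1 - wf) * wm)
  add(f0 + 1L, m0 + 1L, wf * wm)
  N <- sum(joint)
  p <- joint / N
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / (px[row(p)[nz]] * py[col(p)[nz]])))
  L <- matrix(0, bins, bins)
  L[nz] <- log(p[nz] / (px[row(p)[nz]] * py[col(p)[nz]]))
  inb <- m > 0 & m < 1                  # clamped samples have zero gradient
  gm <- (bins - 1) / N *
    ((1 - wf) * (L[cbind(f0, m0 + 1L)] - L[cbind(f0, m0)]) +
       wf * (L[cbind(f0 + 1L, m0 + 1L)] - L[cbind(f0 + 1L, m0)]))
  gm[!inb] <- 0
  g[ok] <- gm
  list(mi = mi, grad = g)
}

# bilinear sample with spatial derivatives; NA outside
.sample_bilinear_grad <- function(img, rr, cc) {
  h <- nrow(img); w <- ncol(img)
  n <- length(rr)
  val <- rep(NA_real_, n); dr_ <- numeric(n); dc_ <- numeric(n)
  ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
  r0 <- pmin(floor(rr[ok]), h - 1L); c0 <- pmin(floor(cc[ok]), w - 1L)
  fr <- rr[ok] - r0; fc <- cc[ok] - c0
  v00 <- img[cbind(r0, c0)];     v01 <- img[cbind(r0, c0 + 1)]
  v10 <- img[cbind(r0 + 1, c0)]; v11 <- img[cbind(r0 + 1, c0 + 1)]
  val[ok] <- v00 * (1 - fr) * (1 - fc) + v01 * (1 - fr) * fc +
    v10 * fr * (1 - fc) + v11 * fr * fc
  dr_[ok] <- (v10 - v00) * (1 - fc) + (v11 - v01) * fc
  dc_[ok] <- (v01 - v00) * (1 - fr) + (v11 - v10) * fr
  list(val = val, dr = dr_, dc = dc_)
}

.norm01 <- function(img) {
  r <- range(img)
  if (r[2] == r[1]) stop("constant image cannot be registered",
                         call. = FALSE)
  (img - r[1]) / (r[2] - r[1])
}

# bilinear sampling of `img` at (row, col) positions; NA outside
.sample_bilinear <- function(img, rr, cc) {
  h <- nrow(img); w <- ncol(img)
  out <- rep(NA_real_, length(rr))
  ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
  r0 <- floor(rr[ok]); c0 <- floor(cc[ok])
  r0 <- pmin(r0, h - 1L); c0 <- pmin(c0, w - 1L)
  fr <- rr[ok] - r0; fc <- cc[ok] - c0
  v00 <- img[cbind(r0, c0)];     v01 <- img[cbind(r0, c0 + 1)]
  v10 <- img[cbind(r0 + 1, c0)]; v11 <- img[cbind(r0 + 1, c0 + 1)]
  out[ok] <- v00 * (1 - fr) * (1 - fc) + v01 * (1 - fr) * fc +
    v10 * fr * (1 - fc) + v11 * fr * fc
  out
}

.sample_nearest <- function(img, rr, cc) {
  h <- nrow(img); w <- ncol(img)
  out <- rep(NA_real_, length(rr))
  ri <- round(rr); ci <- round(cc)
  ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
  out[ok] <- img[cbind(ri[ok], ci[ok])]
  out
}

# image moments: intensity-weighted centroid and principal-axis scales
.moments <- function(img) {
  w <- img - min(img)
  s <- sum(w)
  if (s == 0) w[] <- 1; s <- sum(w)
  rr <- row(img); cc <- col(img)
  mr <- sum(w * rr) / s; mc <- sum(w * cc) / s
  vr <- sum(w * (rr - mr)^2) / s
  vc <- sum(w * (cc - mc)^2) / s
  list(center = c(mr, mc), sd = sqrt(c(vr, vc)))
}

# cubic B-spline basis matrix for `n` sample positions over `nc` control
# points spaced `sp` apart (with one margin control point on each side)
.bspline_basis <- function(n, nc, sp) {
  B <- matrix(0, n, nc)
  pos <- (seq_len(n) - 1) / sp            # in control-grid units
  for (k in seq_len(nc)) {
    t <- pos - (k - 2)                    # control point k sits at (k-2)*sp
    at <- abs(t)
    val <- ifelse(at < 1, (4 - 6 * at^2 + 3 * at^3) / 6,
                  ifelse(at < 2, (2 - at)^3 / 6, 0))
    B[, k] <- val
  }
  B
}

.affine_apply <- function(par, rr, cc) {
  # par = (a11,a12,a21,a22,t1,t2); maps fixed (r,c) to moving coords
  list(r = par[1] * rr + par[2] * cc + par[5],
       c = par[3] * rr + par[4] * cc + par[6])
}

#' Register a moving image to a fixed reference
#'
#' Two-stage multimodal registration: a rigid/affine stage initialized from
#' image moments (centroid and principal-axis scales) and refined by
#' Nelder-Mead on the mutual information (MI) of a 32-bin joint histogram,
#' followed by a nonrigid cubic B-spline stage (control grid spacing
#' `grid_frac` of the image extent per dimension) optimized by a seeded
#' greedy local search that only accepts MI improvements, capped at
#' `max_iter` steps per stage. The returned MI trace is therefore
#' non-decreasing across stage boundaries.
#'
#' @param moving,fixed 2D numeric matrices (grayscale); must not be constant.
#' @param max_iter optimization step cap per stage (default 200).
#' @param bins histogram bins for MI (default 32).
#' @param bspline logical, run the B-spline stage (default TRUE).
#' @param grid_frac control-point spacing as a fraction of extent (default
#'   1/8).
#' @param step initial control-point perturbation in pixels (default 2).
#' @param seed seed for the B-spline search.
#' @return Object of class `section_transform`: affine parameters, inverse
#'   affine, B-spline control displacements + basis metadata, image shapes
#'   and the MI trace (`mi_init`, `mi_affine`, `mi_final`).
#' @export
register_pair <- function(moving, fixed, max_iter = 200, bins = 32,
                          bspline = TRUE, grid_frac = 1 / 8, step = 2,
                          lambda = 0.002, seed = 1L) {
  fixed_n <- .norm01(fixed); moving_n <- .norm01(moving)
  h <- nrow(fixed_n); w <- ncol(fixed_n)
  rr <- as.numeric(row(fixed_n)); cc <- as.numeric(col(fixed_n))
  fvals <- as.numeric(fixed_n)

  score_affine <- function(par) {
    p <- .affine_apply(par, rr, cc)
    .mi(fvals, .sample_bilinear(moving_n, p$r, p$c), bins)
  }
  mf <- .moments(fixed_n); mm <- .moments(moving_n)
  sc <- mm$sd / mf$sd
  sc[!is.finite(sc) | sc == 0] <- 1
  par0 <- c(sc[1], 0, 0, sc[2],
            mm$center[1] - sc[1] * mf$center[1],
            mm$center[2] - sc[2] * mf$center[2])
  mi_init <- score_affine(par0)
  # coarse translation sweep around two starting linear parts (the moment
  # scale estimate and the identity): image moments are biased by
  # out-of-overlap zeros, which can strand the refiners in a local MI basin
  par0_id <- c(1, 0, 0, 1,
               mm$center[1] - mf$center[1], mm$center[2] - mf$center[2])
  best0 <- par0; best_mi0 <- mi_init
  for (base in list(par0, par0_id)) for (dr in -6:6) for (dc in -6:6) {
    cand <- base; cand[5] <- base[5] + dr; cand[6] <- base[6] + dc
    v <- score_affine(cand)
    if (v > best_mi0) { best0 <- cand; best_mi0 <- v }
  }
  par0 <- best0
  # two independent refinements from the swept initialization: gradient
  # ascent on partial-volume MI and Nelder-Mead; the better final MI wins
  grad_ascent <- function(par, mi_cur) {
    lr_a <- 0.5
    ext <- max(h, w)
    for (it in seq_len(max_iter)) {
      p <- .affine_apply(par, rr, cc)
      sg <- .sample_bilinear_grad(moving_n, p$r, p$c)
      mg <- .mi_with_grad(fvals, sg$val, bins)
      gr <- mg$grad * sg$dr; gc <- mg$grad * sg$dc
      grad <- c(sum(gr * rr), sum(gr * cc), sum(gc * rr), sum(gc * cc),
                sum(gr), sum(gc))
      dirn <- grad * c(rep(1 / ext^2, 4), 1, 1)
      disp <- max(abs(dirn[1:4])) * ext + max(abs(dirn[5:6]))
      if (disp == 0) break
      cand <- par + (lr_a / disp) * dirn
      val <- score_affine(cand)
      if (val > mi_cur) {
        par <- cand; mi_cur <- val
        lr_a <- min(lr_a * 1.1, 0.5)
      } else {
        lr_a <- lr_a / 2
        if (lr_a < 1e-3) break
      }
    }
    list(par = par, mi = mi_cur)
  }
  ga <- grad_ascent(par0, best_mi0)
  opt <- stats::optim(par0, function(p) -score_affine(p),
                      method = "Nelder-Mead",
                      control = list(maxit = max_iter,
                                     parscale = c(0.1, 0.1, 0.1, 0.1, 1, 1)))
  if (ga$mi >= -opt$value && ga$mi >= best_mi0) {
    par_aff <- ga$par; mi_affine <- ga$mi
  } else if (-opt$value >= best_mi0) {
    par_aff <- opt$par; mi_affine <- -opt$value
  } else {
    par_aff <- par0; mi_affine <- best_mi0
  }

  # multilevel B-spline stage on top of the affine map: coarse-to-fine
  # control grids (spacing 4x, 2x, 1x `grid_frac` of extent), each level
  # refined by gradient ascent on partial-volume MI with backtracking;
  # level displacements compose additively
  levels <- list()
  mi_final <- mi_affine
  if (bspline) {
    p_aff <- .affine_apply(par_aff, rr, cc)
    base_r <- p_aff$r; base_c <- p_aff$c
    fracs <- unique(pmin(c(4, 2, 1) * grid_frac, 0.5))
    iters <- rep(max_iter, length(fracs))    # step cap applies per level
    cur <- mi_final
    for (lev in seq_along(fracs)) {
      sp_r <- max(h * fracs[lev], 2); sp_c <- max(w * fracs[lev], 2)
      ncr <- ceiling(h / sp_r) + 3L; ncc <- ceiling(w / sp_c) + 3L
      basis_r <- .bspline_basis(h, ncr, sp_r)
      basis_c <- .bspline_basis(w, ncc, sp_c)
      ctrl <- array(0, c(ncr, ncc, 2))
      cur <- .mi(fvals, .sample_bilinear(moving_n, base_r, base_c), bins)
      score_lvl <- function(ctrl) {
        dr <- basis_r %*% ctrl[, , 1] %*% t(basis_c)
        dc <- basis_r %*% ctrl[, , 2] %*% t(basis_c)
        .mi(fvals, .sample_bilinear(moving_n, base_r + as.numeric(dr),
                                    base_c + as.numeric(dc)), bins) -
          lambda * mean(ctrl^2)
      }
      lr <- step
      for (it in seq_len(iters[lev])) {
        dr <- basis_r %*% ctrl[, , 1] %*% t(basis_c)
        dc <- basis_r %*% ctrl[, , 2] %*% t(basis_c)
        sg <- .sample_bilinear_grad(moving_n, base_r + as.numeric(dr),
                                    base_c + as.numeric(dc))
        mg <- .mi_with_grad(fvals, sg$val, bins)
        Gr <- matrix(mg$grad * sg$dr, h, w)
        Gc <- matrix(mg$grad * sg$dc, h, w)
        grad <- array(0, c(ncr, ncc, 2))
        grad[, , 1] <- t(basis_r) %*% Gr %*% basis_c
        grad[, , 2] <- t(basis_r) %*% Gc %*% basis_c
        grad <- grad - 2 * lambda * ctrl / length(ctrl)
        gmax <- max(abs(grad))
        if (gmax == 0) break
        cand <- ctrl + (lr / gmax) * grad
        val <- score_lvl(cand)
        if (val > cur) {
          ctrl <- cand; cur <- val
          lr <- min(lr * 1.1, step)
        } else {
          lr <- lr / 2
          if (lr < 1e-3) break
        }
      }
      levels[[lev]] <- list(ctrl = ctrl, basis_r = basis_r,
                            basis_c = basis_c)
      dr <- basis_r %*% ctrl[, , 1] %*% t(basis_c)
      dc <- basis_r %*% ctrl[, , 2] %*% t(basis_c)
      base_r <- base_r + as.numeric(dr)
      base_c <- base_c + as.numeric(dc)
      cur <- .mi(fvals, .sample_bilinear(moving_n, base_r, base_c), bins)
    }
    mi_final <- max(cur, mi_affine)
  }
  structure(list(affine = par_aff,
                 affine_matrix = matrix(c(par_aff[1], par_aff[2], par_aff[5],
                                          par_aff[3], par_aff[4], par_aff[6]),
                                        2, 3, byrow = TRUE),
                 levels = levels,
                 fixed_shape = c(h, w),
                 moving_shape = dim(moving_n),
                 mi_init = mi_init, mi_affine = mi_affine,
                 mi_final = mi_final, bins = bins),
            class = "section_transform")
}

#' @export
print.section_transform <- function(x, ...) {
  cat(sprintf(
    "Section transform: affine + %s; MI %.4f -> %.4f -> %.4f\n",
    if (!length(x$levels)) "no B-spline"
    else sprintf("%d-level B-spline", length(x$levels)),
    x$mi_init, x$mi_affine, x$mi_final))
  invisible(x)
}

#' Identity transform for a given image shape
#' @param shape `c(height, width)`.
#' @return A `section_transform` with identity affine and no deformation.
#' @export
identity_transform <- function(shape) {
  structure(list(affine = c(1, 0, 0, 1, 0, 0),
                 affine_matrix = matrix(c(1, 0, 0, 0, 1, 0), 2, 3,
                                        byrow = TRUE),
                 levels = list(),
                 fixed_shape = shape, moving_shape = shape,
                 mi_init = NA_real_, mi_affine = NA_real_,
                 mi_final = NA_real_, bins = 32L),
            class = "section_transform")
}

#' Resample images through a section transform
#'
#' Applies the stored fixed-to-moving mapping to every image of a stack,
#' producing images in the fixed frame. Continuous images use bilinear
#' interpolation; label images should use `"nearest"`. Out-of-bounds samples
#' are filled with 0.
#'
#' @param images a matrix or a list of matrices in the moving frame.
#' @param transform a [register_pair()] result.
#' @param interpolation `"linear"` or `"nearest"`.
#' @param inverse logical: apply the inverse of the affine part only (for
#'   round-trip checks; the B-spline part is ignored when `TRUE`).
#' @return Same structure as `images`, resampled to the fixed frame.
#' @export
apply_transform <- function(images, transform,
                            interpolation = c("linear", "nearest"),
                            inverse = FALSE) {
  interpolation <- match.arg(interpolation)
  single <- is.matrix(images)
  imgs <- if (single) list(images) else images
  for (img in imgs)
    if (!all(dim(img) == transform$moving_shape) && !inverse)
      stop("image shape does not match the transform's moving shape",
           call. = FALSE)
  h <- transform$fixed_shape[1]; w <- transform$fixed_shape[2]
  rr <- as.numeric(row(matrix(0, h, w)))
  cc <- as.numeric(col(matrix(0, h, w)))
  if (inverse) {
    A <- matrix(transform$affine[c(1, 2, 3, 4)], 2, 2, byrow = TRUE)
    t_ <- transform$affine[5:6]
    Ai <- solve(A)
    pr <- Ai[1, 1] * (rr - t_[1]) + Ai[1, 2] * (cc - t_[2])
    pc <- Ai[2, 1] * (rr - t_[1]) + Ai[2, 2] * (cc - t_[2])
  } else {
    p <- .affine_apply(transform$affine, rr, cc)
    pr <- p$r; pc <- p$c
    for (lev in transform$levels) {
      dr <- lev$basis_r %*% lev$ctrl[, , 1] %*% t(lev$basis_c)
      dc <- lev$basis_r %*% lev$ctrl[, , 2] %*% t(lev$basis_c)
      pr <- pr + as.numeric(dr); pc <- pc + as.numeric(dc)
    }
  }
  out <- lapply(imgs, function(img) {
    v <- if (interpolation == "linear") .sample_bilinear(img, pr, pc)
    else .sample_nearest(img, pr, pc)
    v[!is.finite(v)] <- 0
    matrix(v, h, w)
  })
  if (single) out[[1]] else out
}

#' Dice overlap index of two binary masks
#'
#' \eqn{DI = 2|A \cap B| / (|A| + |B|)}; two empty masks have Dice 1 by
#' convention.
#'
#' @param label_mask,annotation_mask logical (or 0/1) matrices of equal
#'   shape.
#' @return Value in \[0, 1\].
#' @examples
#' dice(matrix(c(TRUE, TRUE, FALSE, FALSE), 2),
#'      matrix(c(TRUE, FALSE, TRUE, FALSE), 2))
#' @export
dice <- function(label_mask, annotation_mask) {
  if (!all(dim(label_mask) == dim(annotation_mask)))
    stop("mask shapes differ", call. = FALSE)
  a <- as.logical(label_mask); b <- as.logical(annotation_mask)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
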