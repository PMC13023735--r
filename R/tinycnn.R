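# Desk-scale convolutional backbone: a two-stage convolutional trunk with
# group feature standardization, a sigmoid multi-label classification head,
# and a lightweight 1x1-conv + bilinear-upsampling segmentation head sharing
# the trunk. The classification head scores every spatial position with a
# 1x1 linear map and pools the score map with log-sum-exp (LSE), the
# standard choice in weakly supervised chest-radiograph localization: unlike
# global average pooling it does not dilute small focal findings, and unlike
# a hard max its gradient spreads over all informative positions. The full
# backward pass is implemented analytically and verified against central
# finite differences in the tests. Group standardization (never batch
# statistics) keeps training stable at the tiny batch sizes typical of
# federated nodes; channel dropout before the classification head is applied
# at train time only.

#' Tiny model architecture specification
#'
#' @param h,w input image size (even numbers, >= 8).
#' @param m_classes number of pathology classes.
#' @param a_structures number of anatomical structure channels.
#' @param f1,f2 trunk channel widths.
#' @param group_size channel group size for feature standardization; groups
#'   are capped at the layer width.
#' @param dropout_p channel dropout probability before the classification
#'   head (train time only).
#' @param lse_sharpness sharpness of the log-sum-exp spatial pooling of the
#'   classification score map.
#' @param normalize apply group feature standardization after each trunk
#'   convolution. Standardization stabilizes end-to-end training, but it also
#'   couples every activation to image-global statistics, which a
#'   high-capacity head can exploit as a non-local shortcut; spatial
#'   attribution experiments should disable it.
#' @return object of class `tinycnn_spec` with the parameter shape registry.
#' @export
tinycnn_spec <- function(h, w, m_classes, a_structures = 6L, f1 = 4L, f2 = 8L,
                         group_size = 32L, dropout_p = 0.3, lse_sharpness = 8,
                         normalize = TRUE) {
  stopifnot(h %% 2 == 0, w %% 2 == 0, h >= 8, w >= 8)
  shapes <- list(
    conv1_w = c(3L, 3L, 1L, f1), conv1_b = f1,
    conv2_w = c(3L, 3L, f1, f2), conv2_b = f2,
    cls_w = c(m_classes, f2), cls_b = m_classes,
    seg_w = c(a_structures, f2), seg_b = a_structures
  )
  structure(list(h = h, w = w, m = m_classes, a = a_structures,
                 f1 = f1, f2 = f2, group_size = group_size,
                 dropout_p = dropout_p, lse_sharpness = lse_sharpness,
                 normalize = normalize, shapes = shapes),
            class = "tinycnn_spec")
}

#' Initialize tiny model parameters
#'
#' `init = "structured"` (default) builds a fixed-feature trunk in the
#' scattering-network spirit: the first stage consists of Gaussian-blur
#' filters with a ladder of negative biases, so after rectification each
#' channel is a smoothed intensity threshold; the second stage passes each
#' band through an identity and a center-surround (Laplacian) filter. This
#' gives a tiny grayscale trunk whose features can express "locally bright
#' region within a dark field" — the signature of focal radiographic
#' findings — without any trunk training. Heads are drawn N(0, 0.1).
#' `init = "random"` draws every weight N(0, 0.1) (biases zero).
#' Deterministic in `seed`.
#'
#' @param spec a [tinycnn_spec()].
#' @param seed integer seed.
#' @param init `"structured"` or `"random"`.
#' @return a `parameter_vector`.
#' @export
tinycnn_init <- function(spec, seed = 1L, init = c("structured", "random")) {
  init <- match.arg(init)
  with_seed(seed, {
    layers <- lapply(names(spec$shapes), function(nm) {
      d <- spec$shapes[[nm]]
      if (grepl("_b$", nm)) numeric(prod(d)) else array(stats::rnorm(prod(d), 0, 0.1), d)
    })
    names(layers) <- names(spec$shapes)
    if (init == "structured") {
      blur3 <- matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1) / 16, 3, 3)
      lap3 <- matrix(c(-1, -1, -1, -1, 8, -1, -1, -1, -1) / 8, 3, 3)
      idk <- matrix(0, 3, 3); idk[2, 2] <- 1
      c1w <- array(0, c(3, 3, 1, spec$f1))
      for (k in seq_len(spec$f1)) c1w[, , 1, k] <- blur3
      layers$conv1_w <- c1w
      layers$conv1_b <- -seq(0.15, 0.75, length.out = spec$f1)
      c2w <- array(0, c(3, 3, spec$f1, spec$f2))
      for (k in seq_len(spec$f2)) {
        src <- (k - 1L) %% spec$f1 + 1L
        c2w[, , src, k] <- if (k <= spec$f1) idk else lap3
      }
      layers$conv2_w <- c2w
      layers$conv2_b <- numeric(spec$f2)
    }
    param_pack(layers, spec$shapes)
  })
}

# ---- convolution via im2col ------------------------------------------------

im2col3 <- function(x) {
  # x: H x W x Cin -> (H*W) x (9*Cin) patch matrix for 3x3 same-padding conv
  h <- dim(x)[1]; w <- dim(x)[2]; cin <- dim(x)[3]
  pad <- array(0, c(h + 2L, w + 2L, cin))
  pad[2:(h + 1), 2:(w + 1), ] <- x
  out <- matrix(0, h * w, 9L * cin)
  t <- 0L
  for (ci in seq_len(cin)) for (dj in -1:1) for (di in -1:1) {
    t <- t + 1L
    out[, t] <- as.vector(pad[(1:h) + 1L + di, (1:w) + 1L + dj, ci])
  }
  out
}

wmat_from_array <- function(W4) {
  # 3 x 3 x Cin x Cout -> (9*Cin) x Cout, row order matching im2col3
  cin <- dim(W4)[3]; cout <- dim(W4)[4]
  out <- matrix(0, 9L * cin, cout)
  t <- 0L
  for (ci in seq_len(cin)) for (dj in -1:1) for (di in -1:1) {
    t <- t + 1L
    out[t, ] <- W4[di + 2L, dj + 2L, ci, ]
  }
  out
}

wmat_to_array <- function(Wm, cin, cout) {
  W4 <- array(0, c(3L, 3L, cin, cout))
  t <- 0L
  for (ci in seq_len(cin)) for (dj in -1:1) for (di in -1:1) {
    t <- t + 1L
    W4[di + 2L, dj + 2L, ci, ] <- Wm[t, ]
  }
  W4
}

conv3_forward <- function(x, W4, b) {
  h <- dim(x)[1]; w <- dim(x)[2]
  pat <- im2col3(x)
  y <- pat %*% wmat_from_array(W4)
  y <- sweep(y, 2L, b, "+")
  list(y = array(y, c(h, w, length(b))), pat = pat)
}

conv3_backward <- function(dY, pat, W4, xdim) {
  h <- xdim[1]; w <- xdim[2]; cin <- xdim[3]
  cout <- dim(dY)[3]
  dYm <- matrix(dY, h * w, cout)
  dWm <- crossprod(pat, dYm)
  db <- colSums(dYm)
  dPat <- dYm %*% t(wmat_from_array(W4))
  dpad <- array(0, c(h + 2L, w + 2L, cin))
  t <- 0L
  for (ci in seq_len(cin)) for (dj in -1:1) for (di in -1:1) {
    t <- t + 1L
    dpad[(1:h) + 1L + di, (1:w) + 1L + dj, ci] <-
      dpad[(1:h) + 1L + di, (1:w) + 1L + dj, ci] + matrix(dPat[, t], h, w)
  }
  list(dW = wmat_to_array(dWm, cin, cout), db = db,
       dX = dpad[2:(h + 1), 2:(w + 1), , drop = FALSE])
}

# ---- group feature standardization ----------------------------------------

GN_EPS <- 1e-5

gn_groups <- function(channels, group_size) {
  gs <- min(group_size, channels)
  split(seq_len(channels), ceiling(seq_len(channels) / gs))
}

gn_forward <- function(x, group_size) {
  xhat <- x
  cache <- list()
  for (g in gn_groups(dim(x)[3], group_size)) {
    xs <- x[, , g, drop = FALSE]
    mu <- mean(xs); v <- mean((xs - mu)^2)
    s <- sqrt(v + GN_EPS)
    xhat[, , g] <- (xs - mu) / s
    cache[[length(cache) + 1]] <- list(g = g, s = s)
  }
  list(y = xhat, cache = cache)
}

gn_backward <- function(dY, xhat, cache) {
  dX <- dY
  for (cc in cache) {
    g <- cc$g
    dy <- dY[, , g, drop = FALSE]
    xh <- xhat[, , g, drop = FALSE]
    dX[, , g] <- (dy - mean(dy) - xh * mean(dy * xh)) / cc$s
  }
  dX
}

avgpool2 <- function(x) {
  h <- dim(x)[1]; w <- dim(x)[2]; cc <- dim(x)[3]
  y <- (x[seq(1, h, 2), seq(1, w, 2), , drop = FALSE] +
          x[seq(2, h, 2), seq(1, w, 2), , drop = FALSE] +
          x[seq(1, h, 2), seq(2, w, 2), , drop = FALSE] +
          x[seq(2, h, 2), seq(2, w, 2), , drop = FALSE]) / 4
  y
}

avgpool2_backward <- function(dY, xdim) {
  dX <- array(0, xdim)
  h <- xdim[1]; w <- xdim[2]
  g <- dY / 4
  dX[seq(1, h, 2), seq(1, w, 2), ] <- g
  dX[seq(2, h, 2), seq(1, w, 2), ] <- g
  dX[seq(1, h, 2), seq(2, w, 2), ] <- g
  dX[seq(2, h, 2), seq(2, w, 2), ] <- g
  dX
}

# ---- forward / backward ----------------------------------------------------

#' Tiny model forward pass
#'
#' Runs the convolutional trunk and both heads on one image. Deterministic
#' given the parameters; dropout is only active when a `dropout_mask` is
#' supplied (training).
#'
#' @param params `parameter_vector` consistent with `spec`.
#' @param image numeric matrix `spec$h x spec$w` with values in `[0, 1]`.
#' @param spec a [tinycnn_spec()].
#' @param dropout_mask optional binary vector (length `spec$f2`) applied to
#'   the pooled trunk features with inverted-dropout scaling.
#' @return a prediction bundle: list with `class_probs` (length M, in
#'   `[0,1]`) and `seg_probs` (H x W x A in `[0,1]`), with the forward cache
#'   attached as attribute `"cache"` for [tinycnn_backward()].
#' @export
tiny_model_forward <- function(params, image, spec, dropout_mask = NULL) {
  stopifnot(inherits(spec, "tinycnn_spec"))
  if (!all(dim(image) == c(spec$h, spec$w))) stop("shape mismatch: image")
  if (length(params$values) != sum(vapply(spec$shapes, prod, numeric(1)))) {
    stop("shape mismatch: params inconsistent with registry")
  }
  L <- param_unpack(params)
  x3 <- array(image, c(spec$h, spec$w, 1L))
  c1 <- conv3_forward(x3, L$conv1_w, L$conv1_b)
  g1 <- if (spec$normalize) gn_forward(c1$y, spec$group_size) else list(y = c1$y, cache = NULL)
  a1 <- pmax(g1$y, 0)
  p1 <- avgpool2(a1)
  c2 <- conv3_forward(p1, L$conv2_w, L$conv2_b)
  g2 <- if (spec$normalize) gn_forward(c2$y, spec$group_size) else list(y = c2$y, cache = NULL)
  a2 <- pmax(g2$y, 0)
  h2 <- dim(a2)[1]; w2 <- dim(a2)[2]
  a2d <- a2
  if (!is.null(dropout_mask)) {
    for (k in seq_len(spec$f2)) {
      a2d[, , k] <- a2d[, , k] * dropout_mask[k] / (1 - spec$dropout_p)
    }
  }
  a2m <- matrix(a2d, h2 * w2, spec$f2)
  smap <- sweep(a2m %*% t(L$cls_w), 2L, L$cls_b, "+")
  r <- spec$lse_sharpness
  mx <- apply(smap, 2, max)
  logits_c <- mx + log(colMeans(exp(r * sweep(smap, 2L, mx)))) / r
  soft <- exp(r * sweep(smap, 2L, mx))
  soft <- sweep(soft, 2L, colSums(soft), "/")
  class_probs <- sigmoid(logits_c)
  zs <- array(0, c(h2, w2, spec$a))
  for (a in seq_len(spec$a)) {
    zs[, , a] <- matrix(matrix(a2, h2 * w2, spec$f2) %*% L$seg_w[a, ], h2, w2) + L$seg_b[a]
  }
  ps_half <- sigmoid(zs)
  ops <- upsample2_ops(h2, w2)
  seg_probs <- array(0, c(spec$h, spec$w, spec$a))
  for (a in seq_len(spec$a)) seg_probs[, , a] <- ops$up(ps_half[, , a])
  out <- list(class_probs = class_probs, seg_probs = seg_probs)
  attr(out, "cache") <- list(
    L = L, x3 = x3, c1 = c1, g1 = g1, a1 = a1, p1 = p1, c2 = c2, g2 = g2,
    a2 = a2, a2m = a2m, soft = soft, dropout_mask = dropout_mask,
    logits_c = logits_c, class_probs = class_probs, zs = zs,
    ps_half = ps_half, ops = ops, spec = spec)
  out
}

#' Tiny model backward pass
#'
#' Backpropagates loss gradients through the full model, returning the
#' gradient with respect to every parameter as a `parameter_vector`.
#'
#' @param bundle result of [tiny_model_forward()] (with its cache).
#' @param d_logits gradient of the loss w.r.t. the classification logits
#'   (length M); use `numeric(M)` when no classification loss is attached.
#' @param d_seg_probs gradient w.r.t. the full-resolution segmentation
#'   probabilities (H x W x A), e.g. from `composite_seg_grad()`; `NULL` for
#'   classification-only training.
#' @return `parameter_vector` of gradients (same registry as the parameters).
#' @export
tinycnn_backward <- function(bundle, d_logits, d_seg_probs = NULL) {
  cc <- attr(bundle, "cache")
  spec <- cc$spec
  L <- cc$L
  h2 <- dim(cc$a2)[1]; w2 <- dim(cc$a2)[2]
  d_a2 <- array(0, dim(cc$a2))
  d_seg_w <- array(0, dim(L$seg_w)); d_seg_b <- numeric(spec$a)
  if (!is.null(d_seg_probs)) {
    a2m <- matrix(cc$a2, h2 * w2, spec$f2)
    d_a2m <- matrix(0, h2 * w2, spec$f2)
    for (a in seq_len(spec$a)) {
      d_half <- cc$ops$down(d_seg_probs[, , a])
      d_z <- d_half * cc$ps_half[, , a] * (1 - cc$ps_half[, , a])
      dzv <- as.vector(d_z)
      d_seg_w[a, ] <- as.numeric(crossprod(a2m, dzv))
      d_seg_b[a] <- sum(dzv)
      d_a2m <- d_a2m + outer(dzv, L$seg_w[a, ])
    }
    d_a2 <- d_a2 + array(d_a2m, dim(cc$a2))
  }
  # classification head (LSE-pooled score map)
  d_smap <- sweep(cc$soft, 2L, d_logits, "*")
  d_cls_w <- crossprod(d_smap, cc$a2m)
  d_cls_b <- d_logits
  d_a2m_cls <- d_smap %*% L$cls_w
  d_a2_cls <- array(d_a2m_cls, dim(cc$a2))
  if (!is.null(cc$dropout_mask)) {
    for (k in seq_len(spec$f2)) {
      d_a2_cls[, , k] <- d_a2_cls[, , k] * cc$dropout_mask[k] / (1 - spec$dropout_p)
    }
  }
  d_a2 <- d_a2 + d_a2_cls
  # trunk stage 2
  d_g2 <- d_a2 * (cc$g2$y > 0)
  d_z2 <- if (is.null(cc$g2$cache)) d_g2 else gn_backward(d_g2, cc$g2$y, cc$g2$cache)
  bw2 <- conv3_backward(d_z2, cc$c2$pat, L$conv2_w, dim(cc$p1))
  # trunk stage 1
  d_a1 <- avgpool2_backward(bw2$dX, dim(cc$a1))
  d_g1 <- d_a1 * (cc$g1$y > 0)
  d_z1 <- if (is.null(cc$g1$cache)) d_g1 else gn_backward(d_g1, cc$g1$y, cc$g1$cache)
  bw1 <- conv3_backward(d_z1, cc$c1$pat, L$conv1_w, dim(cc$x3))
  param_pack(list(conv1_w = bw1$dW, conv1_b = bw1$db,
                  conv2_w = bw2$dW, conv2_b = bw2$db,
                  cls_w = d_cls_w, cls_b = d_cls_b,
                  seg_w = d_seg_w, seg_b = d_seg_b), spec$shapes)
}

#' Grad-CAM saliency heatmap
#'
#' Channel-weighted sum of the last trunk feature maps, with channel weights
#' equal to the spatially averaged gradients of the target class logit,
#' rectified at zero, bilinearly upsampled to the input resolution, and
#' min-max normalized to `[0, 1]`. An all-zero map is returned unchanged (the
#' normalization guard never divides by zero).
#'
#' @param params `parameter_vector`.
#' @param image input image matrix.
#' @param target_class class index in `1..M`.
#' @param spec a [tinycnn_spec()].
#' @return object of class `heatmap`: list with `values` (H x W in `[0,1]`)
#'   and `target_class`.
#' @export
gradcam <- function(params, image, target_class, spec) {
  if (target_class < 1 || target_class > spec$m) stop("class out of range")
  bundle <- tiny_model_forward(params, image, spec)
  cc <- attr(bundle, "cache")
  h2 <- dim(cc$a2)[1]; w2 <- dim(cc$a2)[2]
  # d logit_c / d a2[i, j, k] = soft[i, j] * cls_w[c, k]; the LSE softmax
  # weights sum to 1, so the spatially averaged gradient is exactly
  # cls_w[c, k] / (h2 * w2)
  alpha <- cc$L$cls_w[target_class, ] / (h2 * w2)
  cam <- matrix(0, h2, w2)
  for (k in seq_len(spec$f2)) cam <- cam + alpha[k] * cc$a2[, , k]
  cam <- pmax(cam, 0)
  cam_full <- resize_bilinear(cam, spec$h, spec$w)
  cam_full <- pmax(cam_full, 0)
  mx <- max(cam_full)
  if (mx > 0) cam_full <- cam_full / mx
  structure(list(values = cam_full, target_class = target_class),
            class = "heatmap")
}

#' Train the tiny model on a set of cases
#'
#' Full-batch Adam on the focal classification loss, optionally combined
#' with the composite segmentation loss when a prior atlas is supplied.
#' `train_trunk = FALSE` freezes the convolutional trunk and trains only the
#' heads on the (random) trunk features — the recommended regime when only a
#' handful of cases is available, where end-to-end updates would destroy the
#' trunk features faster than the heads can exploit them.
#'
#' @param cases list of `synthetic_case` objects.
#' @param spec a [tinycnn_spec()] matching the case dimensions.
#' @param steps number of Adam steps (each step uses the full case list).
#' @param lr Adam learning rate.
#' @param seed initialization/dropout seed.
#' @param gamma focal-loss exponent (0 = plain binary cross-entropy).
#' @param train_trunk update the convolutional trunk (default `TRUE`).
#' @param atlas optional [build_prior_atlas()] result; when supplied the
#'   composite segmentation loss is trained against the case masks.
#' @param lambdas segmentation loss weights.
#' @param use_dropout apply channel dropout during training.
#' @return the trained `parameter_vector`.
#' @export
tinycnn_train <- function(cases, spec, steps = 200L, lr = 0.1, seed = 1L,
                          gamma = 0, train_trunk = TRUE, atlas = NULL,
                          lambdas = c(0.3, 0.5, 0.2), use_dropout = FALSE) {
  pv <- tinycnn_init(spec, seed = seed)
  st <- adam_new(length(pv$values))
  trunk_len <- prod(c(3, 3, 1, spec$f1)) + spec$f1 +
    prod(c(3, 3, spec$f1, spec$f2)) + spec$f2
  drop_seeds <- derive_seeds(seed + 1L, steps)
  if (!train_trunk && is.null(atlas) && !use_dropout) {
    # frozen trunk, classification only: trunk features are fixed, so cache
    # them once and iterate on the head alone
    a2ms <- lapply(cases, function(cs) {
      attr(tiny_model_forward(pv, cs$image, spec), "cache")$a2m
    })
    labs <- do.call(rbind, lapply(cases, function(cs) cs$labels))
    r <- spec$lse_sharpness
    head_off <- trunk_len
    n_head <- spec$m * spec$f2 + spec$m
    for (step in seq_len(steps)) {
      gW <- matrix(0, spec$m, spec$f2); gb <- numeric(spec$m)
      L <- param_unpack(pv)
      for (i in seq_along(cases)) {
        smap <- sweep(a2ms[[i]] %*% t(L$cls_w), 2L, L$cls_b, "+")
        mx <- apply(smap, 2, max)
        logits <- mx + log(colMeans(exp(r * sweep(smap, 2L, mx)))) / r
        soft <- exp(r * sweep(smap, 2L, mx))
        soft <- sweep(soft, 2L, colSums(soft), "/")
        dlog <- as.numeric(focal_logit_grad(rbind(labs[i, ]),
                                            rbind(sigmoid(logits)), gamma = gamma))
        d_smap <- sweep(soft, 2L, dlog, "*")
        gW <- gW + crossprod(d_smap, a2ms[[i]]) / length(cases)
        gb <- gb + dlog / length(cases)
      }
      g <- numeric(length(pv$values))
      g[head_off + seq_len(n_head)] <- c(gW, gb)
      res <- adam_step(st, pv$values, g, lr, 0.9, 0.999)
      pv <- param_vector(res$w, spec$shapes)
      st <- res$state
    }
    return(pv)
  }
  for (step in seq_len(steps)) {
    gtot <- numeric(length(pv$values))
    mask <- if (use_dropout) {
      with_seed(drop_seeds[step],
                as.numeric(stats::runif(spec$f2) >= spec$dropout_p))
    } else NULL
    for (cs in cases) {
      b <- tiny_model_forward(pv, cs$image, spec, dropout_mask = mask)
      dlog <- as.numeric(focal_logit_grad(rbind(cs$labels),
                                          rbind(b$class_probs), gamma = gamma))
      dseg <- if (!is.null(atlas)) {
        composite_seg_grad(cs$masks, b$seg_probs, atlas, lambdas)
      } else NULL
      gtot <- gtot + tinycnn_backward(b, dlog, dseg)$values / length(cases)
    }
    if (!train_trunk) gtot[seq_len(trunk_len)] <- 0
    res <- adam_step(st, pv$values, gtot, lr, 0.9, 0.999)
    pv <- param_vector(res$w, spec$shapes)
    st <- res$state
  }
  pv
}

#' Export a heatmap as an 8-bit grayscale PNG
#' @param hm a `heatmap`.
#' @param path output file path.
#' @export
write_heatmap_png <- function(hm, path) {
  png::writePNG(hm$values, path)
  invisible(path)
}
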