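# Privacy attack battery and its scoring metrics: loss-threshold membership
# inference, gradient-matching reconstruction (gradient leakage / model
# inversion family), windowed structural similarity, and risk-reduction
# reporting.

#' Loss-threshold membership inference attack
#'
#' Classifies membership by thresholding the per-example loss: each set is
#' split in half, the threshold maximizing balanced accuracy is chosen on the
#' calibration halves, and the balanced accuracy (%) of the rule
#' "loss <= threshold means member" is reported on the disjoint evaluation
#' halves. Near 50% means the model leaks nothing usable; near 100% means
#' training membership is readable from the loss.
#'
#' @param model_loss_fn function mapping a dataset `list(x, y)` to the vector
#'   of per-example losses (e.g. built on [logistic_example_losses()]).
#' @param members dataset `list(x, y)` of training members.
#' @param non_members dataset `list(x, y)` disjoint from the training set.
#' @param seed seed for the calibration/evaluation split.
#' @return membership success rate in percent (balanced accuracy).
#' @export
membership_inference_attack <- function(model_loss_fn, members, non_members,
                                        seed = 1L) {
  lm_ <- model_loss_fn(members)
  ln_ <- model_loss_fn(non_members)
  if (length(lm_) == 0 || length(ln_) == 0) stop("both sets must be nonempty")
  with_seed(seed, {
    im <- sample.int(length(lm_)) <= length(lm_) / 2
    inn <- sample.int(length(ln_)) <= length(ln_) / 2
    cal_m <- lm_[im]; cal_n <- ln_[inn]
    ev_m <- lm_[!im]; ev_n <- ln_[!inn]
    cand <- sort(unique(c(cal_m, cal_n)))
    thr_grid <- c(cand[1] - 1e-9, (cand[-1] + cand[-length(cand)]) / 2,
                  cand[length(cand)] + 1e-9)
    bal <- vapply(thr_grid, function(th) {
      (mean(cal_m <= th) + mean(cal_n > th)) / 2
    }, numeric(1))
    th <- thr_grid[which.max(bal)]
    100 * (mean(ev_m <= th) + mean(ev_n > th)) / 2
  })
}

#' Gradient-matching reconstruction attack (gradient leakage)
#'
#' Starting from random noise, iteratively optimizes a dummy image (and a
#' continuous dummy label) so that its model gradient matches an observed
#' single-example gradient, by Adam on the squared gradient distance. The
#' attacker's gradient in the image is obtained from `grad_x_fn` when the
#' model admits one in closed form (the logistic learner does; see
#' [logistic_matching_grad()]), otherwise by forward finite differences.
#'
#' @param target_gradient observed flat gradient of one training example.
#' @param grad_fn function `(x_vec, y_vec) -> flat gradient` of the model
#'   under attack.
#' @param image_shape `c(h, w)` of the image to reconstruct.
#' @param n_labels length of the label vector.
#' @param iterations optimizer iterations (0 returns the initialization).
#' @param seed seed for the dummy initialization.
#' @param grad_x_fn optional function `(x, y, target) -> list(gx, gy)` giving
#'   the analytic gradient of the matching objective in the dummy image and
#'   label.
#' @param lr Adam step size.
#' @return list with `image` (h x w matrix, clipped to `[0,1]`), `label`, and
#'   `objective` (final squared gradient distance).
#' @export
gradient_leakage_attack <- function(target_gradient, grad_fn, image_shape,
                                    n_labels = 1L, iterations = 500L,
                                    seed = 1L, grad_x_fn = NULL, lr = 0.1) {
  d <- prod(image_shape)
  init <- with_seed(seed, list(x = stats::runif(d), y = rep(0.5, n_labels)))
  x <- init$x; y <- init$y
  obj <- function(x, y) sum((grad_fn(x, y) - target_gradient)^2)
  if (iterations > 0) {
    st <- adam_new(d + n_labels)
    for (it in seq_len(iterations)) {
      if (!is.null(grad_x_fn)) {
        g <- grad_x_fn(x, y, target_gradient)
      } else {
        f0 <- obj(x, y)
        h <- 1e-5
        gx <- vapply(seq_len(d), function(i) {
          xp <- x; xp[i] <- xp[i] + h
          (obj(xp, y) - f0) / h
        }, numeric(1))
        gy <- vapply(seq_len(n_labels), function(i) {
          yp <- y; yp[i] <- yp[i] + h
          (obj(x, yp) - f0) / h
        }, numeric(1))
        g <- list(gx = gx, gy = gy)
      }
      gv <- c(g$gx, g$gy)
      if (any(!is.finite(gv))) stop("non-finite matching objective")
      res <- adam_step(st, c(x, y), gv, lr, 0.9, 0.999)
      st <- res$state
      x <- clamp(res$w[seq_len(d)], 0, 1)
      y <- clamp(res$w[d + seq_len(n_labels)], 0, 1)
    }
  }
  list(image = matrix(x, image_shape[1], image_shape[2]), label = y,
       objective = obj(x, y))
}

#' Analytic matching gradient for the logistic learner
#'
#' Closed-form gradient of the squared gradient-matching objective when the
#' attacked model is the multi-label logistic learner, making the
#' reconstruction attack fast enough for repeated seeded experiments.
#'
#' @param params logistic parameters (flat or `parameter_vector`).
#' @return a `grad_x_fn` suitable for [gradient_leakage_attack()].
#' @export
logistic_matching_grad <- function(params) {
  v <- if (inherits(params, "parameter_vector")) params$values else params
  function(x, y, target) {
    p <- length(x); m <- length(y)
    W <- matrix(v[seq_len(p * m)], p, m)
    b <- v[p * m + seq_len(m)]
    pr <- sigmoid(as.numeric(crossprod(W, x)) + b)
    r <- (pr - y) / m                        # residual, length m
    gW <- outer(x, r)                        # model gradient blocks
    gb <- r
    tW <- matrix(target[seq_len(p * m)], p, m)
    tb <- target[p * m + seq_len(m)]
    eW <- gW - tW                            # matching residuals
    eb <- gb - tb
    # dF/dr (through both blocks), then chain to x and y
    dF_dr <- 2 * (as.numeric(crossprod(eW, x)) + eb)
    dr_dz <- pr * (1 - pr) / m
    dF_dz <- dF_dr * dr_dz
    gx <- 2 * as.numeric(eW %*% r) + as.numeric(W %*% dF_dz)
    gy <- -dF_dr / m
    list(gx = gx, gy = gy)
  }
}

#' Structural similarity index (SSIM)
#'
#' Windowed SSIM with the standard stabilizers `K1 = 0.01`, `K2 = 0.03`,
#' dynamic range 1, and a 7x7 Gaussian window (sigma 1.5); local statistics
#' are computed on all fully supported windows (valid convolution) and the
#' mean SSIM over windows is returned. 1 for identical images; lower values
#' mean poorer structural agreement.
#'
#' @param a,b numeric matrices of equal shape with values in `[0, 1]`.
#' @param sigma Gaussian window standard deviation.
#' @return scalar SSIM.
#' @export
ssim <- function(a, b, sigma = 1.5) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  K1 <- 0.01; K2 <- 0.03; L <- 1
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  k1 <- stats::dnorm(seq(-3, 3), sd = sigma)
  k1 <- k1 / sum(k1)
  win <- outer(k1, k1)
  fil <- function(m) {
    h <- nrow(m); w <- ncol(m)
    if (h < 7 || w < 7) stop("images must be at least 7x7")
    out <- matrix(0, h - 6, w - 6)
    for (i in 1:7) for (j in 1:7) {
      out <- out + win[i, j] * m[i:(h - 7 + i), j:(w - 7 + j)]
    }
    out
  }
  mu_a <- fil(a); mu_b <- fil(b)
  va <- fil(a * a) - mu_a^2
  vb <- fil(b * b) - mu_b^2
  cab <- fil(a * b) - mu_a * mu_b
  s <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(s)
}

#' Risk reduction of a privacy defense
#'
#' Percent improvement `100 * (baseline - defended) / baseline`, rounded to
#' one decimal for reporting. Positive values mean the defense reduced the
#' attack's effectiveness.
#'
#' @param defended attack metric under the defended model.
#' @param baseline attack metric without the defense (> 0).
#' @return risk reduction in percent (one decimal).
#' @export
risk_reduction <- function(defended, baseline) {
  if (baseline <= 0) stop("`baseline` must be > 0")
  round(100 * (baseline - defended) / baseline, 1)
}

#' Assemble an attack report row
#'
#' @param attack_name label for the attack.
#' @param metric_name `"success_rate_pct"` or `"ssim"`.
#' @param defended,baseline attack metric with and without the defense.
#' @return one-row data.frame with the defended value, baseline value, and
#'   risk reduction percent.
#' @export
attack_report <- function(attack_name, metric_name = c("success_rate_pct", "ssim"),
                          defended, baseline) {
  metric_name <- match.arg(metric_name)
  data.frame(attack = attack_name, metric = metric_name,
             defended = defended, baseline = baseline,
             risk_reduction_pct = risk_reduction(defended, baseline))
}
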