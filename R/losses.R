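# Segmentation and classification losses.
#
# The composite segmentation loss is
#   L_seg = lambda1 * L_BCE + lambda2 * L_Dice + lambda3 * L_prior
# with defaults (0.3, 0.5, 0.2). The BCE term is summed over structure
# channels and normalized by H*W (so with a single channel it reduces to the
# textbook per-pixel binary cross-entropy); the Dice term uses a global
# smoothing epsilon of 1e-6; the prior term is the per-pixel squared norm of
# the prediction masked by (1 - atlas probability), averaged over pixels.
# Every loss has a companion analytic gradient in the predicted
# probabilities, checked against central finite differences in the tests.

check_same_shape <- function(a, b) {
  da <- dim(a); db <- dim(b)
  if (is.null(da)) da <- length(a)
  if (is.null(db)) db <- length(b)
  if (!identical(as.integer(da), as.integer(db))) stop("shape mismatch")
}

seg_dims <- function(S) {
  d <- dim(S)
  if (is.null(d)) d <- c(length(S), 1L, 1L)
  if (length(d) == 2) d <- c(d, 1L)
  d
}

#' Binary cross-entropy segmentation loss
#'
#' Pixel-wise binary cross-entropy between a binary target tensor and a
#' predicted probability tensor, summed over structure channels and averaged
#' over the `H x W` pixel grid. Predictions are clamped to
#' `[1e-7, 1 - 1e-7]` before taking logarithms.
#'
#' @param S binary target tensor (H x W x A, or a matrix for A = 1).
#' @param S_hat predicted probabilities, same shape.
#' @return nonnegative scalar loss.
#' @export
bce_seg_loss <- function(S, S_hat) {
  check_same_shape(S, S_hat)
  d <- seg_dims(S)
  p <- clamp_prob(S_hat)
  -sum(S * log(p) + (1 - S) * log(1 - p)) / (d[1] * d[2])
}

bce_seg_grad <- function(S, S_hat) {
  d <- seg_dims(S)
  p <- clamp_prob(S_hat)
  g <- (-S / p + (1 - S) / (1 - p)) / (d[1] * d[2])
  g[S_hat < PROB_EPS | S_hat > 1 - PROB_EPS] <- 0  # clamped region is flat
  g
}

#' Dice segmentation loss
#'
#' One minus the (smoothed) Dice overlap coefficient computed over the whole
#' tensor: `1 - (2 * sum(S * S_hat) + eps) / (sum(S) + sum(S_hat) + eps)`.
#' Robust to foreground/background class imbalance; bounded in `[0, 1]`.
#'
#' @inheritParams bce_seg_loss
#' @param eps smoothing constant (default 1e-6).
#' @return scalar in `[0, 1]`.
#' @export
dice_loss <- function(S, S_hat, eps = 1e-6) {
  check_same_shape(S, S_hat)
  1 - (2 * sum(S * S_hat) + eps) / (sum(S) + sum(S_hat) + eps)
}

dice_grad <- function(S, S_hat, eps = 1e-6) {
  num <- 2 * sum(S * S_hat) + eps
  den <- sum(S) + sum(S_hat) + eps
  -(2 * S * den - num) / den^2
}

#' Anatomical prior regularization loss
#'
#' Mean over pixels of the squared Euclidean norm of the per-pixel structure
#' vector `S_hat * (1 - P)`: high-confidence predictions are penalized exactly
#' where the atlas assigns low probability to the structure.
#'
#' @param S_hat predicted probability tensor H x W x A.
#' @param P a [build_prior_atlas()] result, or a plain tensor of matching
#'   shape with entries in `[0, 1]`.
#' @return nonnegative scalar.
#' @export
prior_loss <- function(S_hat, P) {
  if (inherits(P, "prior_atlas")) P <- P$P
  check_same_shape(S_hat, P)
  d <- seg_dims(S_hat)
  sum((S_hat * (1 - P))^2) / (d[1] * d[2])
}

prior_grad <- function(S_hat, P) {
  if (inherits(P, "prior_atlas")) P <- P$P
  d <- seg_dims(S_hat)
  2 * S_hat * (1 - P)^2 / (d[1] * d[2])
}

#' Composite segmentation loss
#'
#' Weighted combination `lambda1 * BCE + lambda2 * Dice + lambda3 * Prior`
#' with the default weights `(0.3, 0.5, 0.2)`. Linear in the lambda weights.
#'
#' @inheritParams bce_seg_loss
#' @param P prior atlas (see [prior_loss()]).
#' @param lambdas nonnegative weight triple.
#' @return scalar loss.
#' @export
composite_seg_loss <- function(S, S_hat, P, lambdas = c(0.3, 0.5, 0.2)) {
  stopifnot(length(lambdas) == 3)
  if (any(lambdas < 0)) stop("`lambdas` must be nonnegative")
  lambdas[1] * bce_seg_loss(S, S_hat) + lambdas[2] * dice_loss(S, S_hat) +
    lambdas[3] * prior_loss(S_hat, P)
}

composite_seg_grad <- function(S, S_hat, P, lambdas = c(0.3, 0.5, 0.2)) {
  lambdas[1] * bce_seg_grad(S, S_hat) + lambdas[2] * dice_grad(S, S_hat) +
    lambdas[3] * prior_grad(S_hat, P)
}

#' Focal multi-label classification loss
#'
#' Mean over classes of `-weight_m * (1 - p_t)^gamma * log(p_t)`, where `p_t`
#' is the predicted probability of the true label (`p` for positives,
#' `1 - p` for negatives). With `gamma = 0` and unit weights this reduces to
#' the mean binary cross-entropy; `gamma = 2` (default) down-weights
#' well-classified examples, the standard choice for rare-finding
#' classification. Probabilities are clamped at 1e-7.
#'
#' @param labels binary vector length M.
#' @param probs predicted probabilities in (0, 1), length M.
#' @param class_weights per-class weights (e.g. [imbalance_weights()]);
#'   default all 1.
#' @param gamma focusing exponent (>= 0).
#' @return nonnegative scalar.
#' @export
focal_class_loss <- function(labels, probs, class_weights = NULL, gamma = 2) {
  if (length(labels) != length(probs)) stop("length mismatch")
  if (is.null(class_weights)) class_weights <- rep(1, length(labels))
  if (length(class_weights) != length(labels)) stop("length mismatch")
  p_t <- clamp_prob(ifelse(labels != 0, probs, 1 - probs))
  mean(-class_weights * (1 - p_t)^gamma * log(p_t))
}

# Gradient of the focal loss with respect to the pre-sigmoid logits; used by
# the local trainers. Vectorized over an n x M matrix of labels/probs.
focal_logit_grad <- function(labels, probs, class_weights = NULL, gamma = 2) {
  if (is.null(dim(labels))) { labels <- rbind(labels); probs <- rbind(probs) }
  M <- ncol(labels)
  if (is.null(class_weights)) class_weights <- rep(1, M)
  w <- matrix(class_weights, nrow(labels), M, byrow = TRUE)
  p <- clamp_prob(probs)
  p_t <- ifelse(labels != 0, p, 1 - p)
  # dL/dp_t, then chain through p_t = p or 1 - p and p = sigmoid(z)
  if (gamma == 0) {
    dL_dpt <- -w / p_t
  } else {
    dL_dpt <- -w * (-gamma * (1 - p_t)^(gamma - 1) * log(p_t) +
                      (1 - p_t)^gamma / p_t)
  }
  sign_t <- ifelse(labels != 0, 1, -1)
  dL_dpt * sign_t * p * (1 - p) / M
}
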