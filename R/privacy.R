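# Differential-privacy mechanics: per-example gradient clipping, the noisy
# lot-mean gradient, Gaussian-mechanism calibration, and privacy-budget
# composition across communication rounds.

#' Differential-privacy configuration
#'
#' @param clip_norm L2 clipping bound C (> 0, default 1).
#' @param noise_multiplier noise multiplier sigma (>= 0, default 1.1).
#' @param delta failure probability delta in (0, 1), default 1e-6.
#' @param lot_size lot (batch) size L; `NULL` means use the trainer's batch
#'   size.
#' @return object of class `dp_config`.
#' @export
dp_config <- function(clip_norm = 1.0, noise_multiplier = 1.1, delta = 1e-6,
                      lot_size = NULL) {
  if (clip_norm <= 0) stop("`clip_norm` must be > 0")
  if (noise_multiplier < 0) stop("`noise_multiplier` must be >= 0")
  if (delta <= 0 || delta >= 1) stop("`delta` must lie in (0, 1)")
  structure(list(clip_norm = clip_norm, noise_multiplier = noise_multiplier,
                 delta = delta, lot_size = lot_size), class = "dp_config")
}

#' Clip a gradient to an L2 norm bound
#'
#' Returns `g` unchanged when `||g||_2 <= C`, otherwise rescales it to norm
#' exactly `C`, preserving direction.
#'
#' @param g finite numeric gradient vector.
#' @param C clipping bound (> 0).
#' @return clipped gradient.
#' @export
clip_gradient <- function(g, C) {
  if (C <= 0) stop("`C` must be > 0")
  if (any(!is.finite(g))) stop("gradient must be finite")
  nrm <- sqrt(sum(g^2))
  if (nrm <= C) g else g * (C / nrm)
}

#' Differentially private lot-mean gradient
#'
#' Mean of the per-example clipped gradients plus a single Gaussian draw with
#' per-coordinate standard deviation `sigma * C` (one draw per lot).
#' Deterministic given `seed`.
#'
#' @param per_example_grads nonempty list of gradient vectors (one lot).
#' @param cfg a [dp_config()].
#' @param seed integer seed for the noise draw.
#' @return privatized mean gradient.
#' @export
dp_private_mean_gradient <- function(per_example_grads, cfg, seed = 1L) {
  if (length(per_example_grads) == 0) stop("empty lot")
  stopifnot(inherits(cfg, "dp_config"))
  if (!is.null(cfg$lot_size) && length(per_example_grads) != cfg$lot_size) {
    stop("lot size does not match `cfg$lot_size`")
  }
  clipped <- lapply(per_example_grads, clip_gradient, C = cfg$clip_norm)
  g <- Reduce(`+`, clipped) / length(clipped)
  if (cfg$noise_multiplier == 0) return(g)
  with_seed(seed, g + stats::rnorm(length(g), 0,
                                   cfg$noise_multiplier * cfg$clip_norm))
}

#' Gaussian-mechanism noise calibration
#'
#' The classical calibration `sigma = sqrt(2 * ln(1.25 / delta)) *
#' sensitivity / epsilon`, valid for `0 < epsilon < 1`.
#'
#' @param epsilon privacy parameter in (0, 1).
#' @param delta failure probability in (0, 1).
#' @param sensitivity L2 sensitivity of the released statistic.
#' @return required noise standard deviation.
#' @export
gaussian_sigma_for <- function(epsilon, delta, sensitivity = 1) {
  if (epsilon <= 0 || epsilon >= 1) {
    stop("classical Gaussian-mechanism bound requires 0 < epsilon < 1")
  }
  if (delta <= 0 || delta >= 1) stop("`delta` must lie in (0, 1)")
  sqrt(2 * log(1.25 / delta)) * sensitivity / epsilon
}

#' Privacy-budget composition across rounds
#'
#' Reports both basic composition `(T * eps, T * delta)` and the advanced
#' composition bound
#' `eps' = eps * sqrt(2 * T * ln(1 / delta_prime)) + T * eps * (exp(eps) - 1)`
#' at the caller-chosen slack `delta_prime`; the headline epsilon is the
#' tighter of the two.
#'
#' @param per_round_epsilon per-round epsilon.
#' @param per_round_delta per-round delta.
#' @param T_rounds number of rounds (>= 1).
#' @param delta_prime slack for the advanced bound (default 1e-6).
#' @return list with `basic` (epsilon, delta), `advanced` (epsilon, delta),
#'   and `headline_epsilon`.
#' @export
compose_privacy <- function(per_round_epsilon, per_round_delta, T_rounds,
                            delta_prime = 1e-6) {
  stopifnot(T_rounds >= 1)
  eps <- per_round_epsilon
  basic <- c(epsilon = T_rounds * eps, delta = T_rounds * per_round_delta)
  adv_eps <- eps * sqrt(2 * T_rounds * log(1 / delta_prime)) +
    T_rounds * eps * (exp(eps) - 1)
  advanced <- c(epsilon = adv_eps,
                delta = T_rounds * per_round_delta + delta_prime)
  list(basic = basic, advanced = advanced,
       headline_epsilon = min(basic["epsilon"], advanced["epsilon"]))
}
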