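# Aggregation rules, adaptive weighting, convergence detection, and
# communication-cost accounting for the synchronous star-topology protocol.

#' Construct a client update
#'
#' The unit a node sends back to the server after local training: its
#' parameters plus the metadata the aggregation rules consume.
#'
#' @param params `parameter_vector` (or plain numeric vector).
#' @param n_k local sample count (>= 1).
#' @param val_auc local validation AUC in `[0, 1]`.
#' @param diversity data diversity metric in `[0, 1]` (default: to be filled
#'   by the trainer with the normalized label-distribution entropy).
#' @param quality data quality metric in `[0, 1]`.
#' @return object of class `client_update`.
#' @export
client_update <- function(params, n_k, val_auc = NA_real_, diversity = NA_real_,
                          quality = NA_real_) {
  if (n_k < 1) stop("`n_k` must be >= 1")
  for (v in c(val_auc, diversity, quality)) {
    if (!is.na(v) && (v < 0 || v > 1)) stop("client metrics must lie in [0, 1]")
  }
  structure(list(params = params, n_k = n_k, val_auc = val_auc,
                 diversity = diversity, quality = quality),
            class = "client_update")
}

update_values <- function(u) {
  if (inherits(u$params, "parameter_vector")) u$params$values else u$params
}

rebuild_params <- function(values, template) {
  if (inherits(template$params, "parameter_vector")) {
    param_vector(values, template$params$shapes)
  } else {
    values
  }
}

check_consistent_updates <- function(updates) {
  if (length(updates) == 0) stop("`updates` must be nonempty")
  lens <- vapply(updates, function(u) length(update_values(u)), numeric(1))
  if (length(unique(lens)) != 1) stop("shape mismatch across client updates")
}

#' Sample-size-weighted federated averaging (FedAvg)
#'
#' The global parameters are the weighted mean of the client parameters with
#' weights `n_k / n`.
#'
#' @param updates nonempty list of [client_update()]s with consistent shapes.
#' @return aggregated parameters (same representation as the inputs).
#' @export
fedavg <- function(updates) {
  check_consistent_updates(updates)
  n <- sum(vapply(updates, function(u) u$n_k, numeric(1)))
  acc <- numeric(length(update_values(updates[[1]])))
  for (u in updates) acc <- acc + (u$n_k / n) * update_values(u)
  rebuild_params(acc, updates[[1]])
}

#' FedProx local objective
#'
#' The proximal local objective `F_k(w) + (mu / 2) * ||w - w_t||^2`, tying
#' local iterates to the current global model.
#'
#' @param local_loss either the local loss value at `w`, or a function of `w`
#'   returning it.
#' @param w local parameters (`parameter_vector` or numeric).
#' @param w_t current global parameters, same shape.
#' @param mu proximal coefficient (>= 0).
#' @return scalar objective value.
#' @export
fedprox_local_objective <- function(local_loss, w, w_t, mu) {
  if (mu < 0) stop("`mu` must be >= 0")
  wv <- if (inherits(w, "parameter_vector")) w$values else w
  wtv <- if (inherits(w_t, "parameter_vector")) w_t$values else w_t
  if (length(wv) != length(wtv)) stop("shape mismatch")
  f <- if (is.function(local_loss)) local_loss(w) else local_loss
  f + (mu / 2) * sum((wv - wtv)^2)
}

#' Component weights for the composite confidence score
#'
#' @param omega nonnegative triple on the probability simplex (sum 1,
#'   tolerance 1e-9); defaults to uniform.
#' @param learning_rate projected-gradient step size for the server-side
#'   update (default 0.01).
#' @param warmup_rounds number of initial rounds during which the weights are
#'   pinned uniform (default 10).
#' @return object of class `component_weights`.
#' @export
component_weights <- function(omega = rep(1 / 3, 3), learning_rate = 0.01,
                              warmup_rounds = 10L) {
  if (length(omega) != 3 || any(omega < -1e-9) || abs(sum(omega) - 1) > 1e-9) {
    stop("`omega` must be a nonnegative triple summing to 1")
  }
  structure(list(omega = pmax(omega, 0), learning_rate = learning_rate,
                 warmup_rounds = as.integer(warmup_rounds)),
            class = "component_weights")
}

#' Composite confidence score of a client
#'
#' Convex combination `omega1 * acc + omega2 * div + omega3 * qual` of a
#' client's local validation accuracy, data diversity, and data quality
#' metrics; lies in `[0, 1]` whenever its inputs do.
#'
#' @param acc,div,qual metrics in `[0, 1]`.
#' @param omega a [component_weights()] object or a simplex triple.
#' @return scalar confidence in `[0, 1]`.
#' @export
confidence_score <- function(acc, div, qual, omega = component_weights()) {
  if (inherits(omega, "component_weights")) omega <- omega$omega
  if (abs(sum(omega) - 1) > 1e-6 || any(omega < -1e-9)) {
    stop("`omega` must lie on the probability simplex")
  }
  for (v in c(acc, div, qual)) if (v < 0 || v > 1) stop("metrics must lie in [0, 1]")
  omega[1] * acc + omega[2] * div + omega[3] * qual
}

#' Softmax client weights from validation AUCs
#'
#' Per-round aggregation weights `exp(AUC_k / tau) / sum_j exp(AUC_j / tau)`,
#' computed with max-subtraction for numerical stability. A small temperature
#' concentrates weight on the best-performing client; a large temperature
#' approaches uniform averaging (standard FedAvg behavior).
#'
#' @param val_aucs numeric vector of client validation AUCs.
#' @param tau temperature (> 0), default 0.5.
#' @return object of class `aggregation_weights`: list with `per_client`
#'   (nonnegative, sums to 1) and `temperature`.
#' @export
softmax_client_weights <- function(val_aucs, tau = 0.5) {
  if (tau <= 0) stop("`tau` must be > 0")
  z <- val_aucs / tau
  z <- z - max(z)
  w <- exp(z) / sum(exp(z))
  structure(list(per_client = w, temperature = tau),
            class = "aggregation_weights")
}

#' Confidence-weighted aggregation
#'
#' Global parameters as the normalized weighted mean of client parameters
#' with per-client weight `alpha_i * c_i` (data-quantity weight times
#' confidence score). Reduces exactly to [fedavg()] when all confidences are
#' equal and `alpha_i = n_k / n`.
#'
#' @param updates list of [client_update()]s.
#' @param alpha nonnegative data-quantity weights, length K.
#' @param c_scores nonnegative confidence scores, length K (an
#'   `aggregation_weights` object is also accepted).
#' @return aggregated parameters.
#' @export
confidence_weighted_aggregate <- function(updates, alpha, c_scores) {
  check_consistent_updates(updates)
  if (inherits(c_scores, "aggregation_weights")) c_scores <- c_scores$per_client
  if (length(alpha) != length(updates) || length(c_scores) != length(updates)) {
    stop("`alpha` and `c_scores` must have one entry per update")
  }
  if (any(alpha < 0) || any(c_scores < 0)) stop("weights must be nonnegative")
  wts <- alpha * c_scores
  den <- sum(wts)
  if (den < 1e-12) stop("aggregation weights sum below 1e-12")
  wts <- wts / den
  acc <- numeric(length(update_values(updates[[1]])))
  for (i in seq_along(updates)) acc <- acc + wts[i] * update_values(updates[[i]])
  rebuild_params(acc, updates[[1]])
}

#' Euclidean projection onto the probability simplex
#'
#' Sorting-based algorithm: the projection of `v` is
#' `pmax(v - theta, 0)` with `theta` the largest shift making the positive
#' part sum to 1. Idempotent, and never increases the distance to any simplex
#' point.
#'
#' @param v finite numeric vector (nonempty).
#' @return nonnegative vector summing to 1.
#' @export
project_to_simplex <- function(v) {
  if (length(v) == 0) stop("`v` must be nonempty")
  if (any(!is.finite(v))) stop("`v` must be finite")
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - 1) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

#' Server-side update of the component weights
#'
#' During the warm-up phase (rounds 1 to `omega$warmup_rounds`) the weights
#' stay uniform at 1/3. Afterwards one projected-gradient step is taken:
#' `omega <- project_to_simplex(omega - learning_rate * grad)`.
#'
#' @param omega a [component_weights()] object.
#' @param val_loss_grad gradient triple of the server validation loss in the
#'   component weights (see [component_weight_gradient()]).
#' @param round current communication round (>= 1).
#' @return updated `component_weights`.
#' @export
update_component_weights <- function(omega, val_loss_grad, round) {
  stopifnot(inherits(omega, "component_weights"), round >= 1)
  if (round <= omega$warmup_rounds) {
    omega$omega <- rep(1 / 3, 3)
    return(omega)
  }
  omega$omega <- project_to_simplex(omega$omega - omega$learning_rate * val_loss_grad)
  omega
}

#' Finite-difference gradient of a validation loss in the component weights
#'
#' Central differences along simplex-tangent directions `e_j - (1/3) * 1`
#' (each probe renormalized onto the simplex), so the loss is only ever
#' evaluated at valid weightings.
#'
#' @param val_loss_fn function taking a simplex triple and returning the
#'   server validation loss.
#' @param omega current simplex triple (or `component_weights`).
#' @param h step size.
#' @return numeric gradient triple.
#' @export
component_weight_gradient <- function(val_loss_fn, omega, h = 1e-3) {
  if (inherits(omega, "component_weights")) omega <- omega$omega
  vapply(1:3, function(j) {
    t_j <- -rep(1 / 3, 3); t_j[j] <- t_j[j] + 1
    up <- project_to_simplex(omega + h * t_j)
    dn <- project_to_simplex(omega - h * t_j)
    (val_loss_fn(up) - val_loss_fn(dn)) / (2 * h)
  }, numeric(1))
}

#' Detect the convergence round from a validation-AUC trajectory
#'
#' Plateau rule: the first round whose global validation AUC is within `tol`
#' of the maximum over the subsequent `window` rounds; if no round satisfies
#' the rule (e.g. the curve is still rising), the last round is returned.
#'
#' @param logs a `fed_fit`, a data.frame with a `global_val_auc` column, or a
#'   numeric AUC vector.
#' @param tol plateau tolerance (default 0.001).
#' @param window look-ahead window in rounds (default 5).
#' @return integer round index.
#' @export
detect_convergence <- function(logs, tol = 0.001, window = 5L) {
  auc <- if (inherits(logs, "fed_fit")) logs$logs$global_val_auc
  else if (is.data.frame(logs)) logs$global_val_auc
  else as.numeric(logs)
  n <- length(auc)
  if (n == 0) stop("`logs` must be nonempty")
  if (n >= 2) {
    for (r in seq_len(n - 1)) {
      fut <- auc[(r + 1):min(r + window, n)]
      if (auc[r] >= max(fut) - tol) return(r)
    }
  }
  n
}

#' Communication-cost accounting
#'
#' Per-round payload and total upload bandwidth for a synchronous federation:
#' `total_gb = payload_mb * rounds * nodes / 1000`, reported to one decimal.
#' When `compressed = FALSE` the payload is first divided by the gradient
#' compression ratio (default 4:1). Totals count one upload per client per
#' round; the server broadcast is the same size again and is reported
#' separately by the trainer's logs.
#'
#' @param payload_mb parameter payload per node per round, in MB.
#' @param rounds number of communication rounds (> 0).
#' @param nodes number of client nodes (> 0).
#' @param compression_ratio gradient compression ratio (default 4).
#' @param compressed whether `payload_mb` is already compressed.
#' @return list with `per_round_mb` and `total_gb` (one decimal).
#' @export
comm_cost <- function(payload_mb, rounds, nodes, compression_ratio = 4.0,
                      compressed = TRUE) {
  if (payload_mb <= 0 || rounds <= 0 || nodes <= 0 || compression_ratio <= 0) {
    stop("all inputs must be positive")
  }
  per_round <- if (compressed) payload_mb else payload_mb / compression_ratio
  list(per_round_mb = per_round,
       total_gb = round(per_round * rounds * nodes / 1000, 1))
}
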