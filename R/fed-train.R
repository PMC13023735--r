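# The federation trainer: synchronous rounds of local training on each node
# followed by server-side aggregation. The default local learner is a
# multi-label logistic model on flattened (optionally downsampled) image
# features -- convex, fast, and exactly reproducible, which is what the
# protocol-level claims (aggregation identities, privacy directionality,
# heterogeneity robustness) need at desk scale. The tiny convolutional model
# shares the same loss/gradient interface and is used where spatial structure
# matters (Grad-CAM localization).

#' Federation configuration
#'
#' Defaults follow the reference training configuration: 5 local epochs per
#' round, 50 communication rounds, Adam with learning rate 3e-4 and
#' (beta1, beta2) = (0.9, 0.999), batch size 32, weight decay 1e-4,
#' cosine-annealed learning rate, aggregation temperature 0.5.
#'
#' @param K number of nodes (filled in by [fed_train()] if `NULL`).
#' @param E local epochs per round.
#' @param T_rounds communication rounds.
#' @param lr local Adam learning rate.
#' @param mu FedProx proximal coefficient (used when `method = "fedprox"`).
#' @param tau softmax aggregation temperature.
#' @param batch_size local minibatch size.
#' @param gamma focal-loss focusing exponent for local training.
#' @param class_weighting use inverse-frequency class weights locally.
#' @param weight_decay L2 weight decay.
#' @param adam_beta1,adam_beta2 Adam moment decays.
#' @param lr_schedule `"cosine"` (annealed over `T_rounds`) or `"constant"`.
#' @param dp optional [dp_config()] enabling differentially private local
#'   updates.
#' @param confidence_source `"softmax"` (temperature-softmax over client
#'   validation AUCs) or `"composite"` (accuracy/diversity/quality confidence
#'   scores with server-side adaptive component weights).
#' @param seed master seed; every stochastic choice in the run derives from it.
#' @return object of class `fed_config`.
#' @export
fed_config <- function(K = NULL, E = 5L, T_rounds = 50L, lr = 3e-4, mu = 0.01,
                       tau = 0.5, batch_size = 32L, gamma = 2,
                       class_weighting = TRUE, weight_decay = 1e-4,
                       adam_beta1 = 0.9, adam_beta2 = 0.999,
                       lr_schedule = c("cosine", "constant"), dp = NULL,
                       confidence_source = c("softmax", "composite"),
                       seed = 1L) {
  lr_schedule <- match.arg(lr_schedule)
  confidence_source <- match.arg(confidence_source)
  stopifnot(E >= 1, T_rounds >= 1, lr > 0, tau > 0, batch_size >= 1, mu >= 0)
  if (!is.null(dp) && !inherits(dp, "dp_config")) stop("`dp` must be a dp_config()")
  structure(list(K = K, E = as.integer(E), T_rounds = as.integer(T_rounds),
                 lr = lr, mu = mu, tau = tau, batch_size = as.integer(batch_size),
                 gamma = gamma, class_weighting = class_weighting,
                 weight_decay = weight_decay, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, lr_schedule = lr_schedule, dp = dp,
                 confidence_source = confidence_source, seed = seed),
            class = "fed_config")
}

#' Build a tabular design from a synthetic-cohort node
#'
#' Flattens each case image (after bilinear downsampling to `feature_size`)
#' into a feature row, grouped by the node's train/val/test split.
#'
#' @param node one node dataset from [simulate_cohort()] or
#'   [partition_cohort()].
#' @param feature_size `c(h, w)` feature resolution.
#' @return list with `train`, `val`, `test`, each `list(x, y)`.
#' @export
node_design <- function(node, feature_size = c(16L, 16L)) {
  feats <- t(vapply(node$cases, function(cs) {
    as.vector(resize_bilinear(cs$image, feature_size[1], feature_size[2]))
  }, numeric(prod(feature_size))))
  labs <- do.call(rbind, lapply(node$cases, function(cs) cs$labels))
  out <- lapply(c(train = "train", val = "val", test = "test"), function(s) {
    idx <- which(node$split == s)
    list(x = feats[idx, , drop = FALSE], y = labs[idx, , drop = FALSE])
  })
  out
}

is_design_node <- function(node) {
  is.list(node) && all(c("train", "val") %in% names(node)) &&
    is.list(node$train) && all(c("x", "y") %in% names(node$train))
}

as_design_nodes <- function(nodes, feature_size) {
  lapply(nodes, function(nd) {
    if (is_design_node(nd)) nd else node_design(nd, feature_size)
  })
}

# ---- logistic local learner -----------------------------------------------

logistic_shapes <- function(p, m) list(W = c(p, m), b = m)

#' Multi-label logistic predictions
#' @param params numeric parameter vector or `parameter_vector` for a
#'   `p`-feature, `M`-class logistic model.
#' @param x feature matrix `n x p`.
#' @return probability matrix `n x M`.
#' @export
logistic_probs <- function(params, x) {
  v <- if (inherits(params, "parameter_vector")) params$values else params
  p <- ncol(x)
  m <- length(v) / (p + 1)
  W <- matrix(v[seq_len(p * m)], p, m)
  b <- v[p * m + seq_len(m)]
  sigmoid(sweep(x %*% W, 2L, b, "+"))
}

#' Per-example classification losses of a logistic model
#'
#' Mean binary cross-entropy over classes for each example; the statistic the
#' loss-threshold membership-inference attack thresholds.
#' @inheritParams logistic_probs
#' @param y binary label matrix `n x M`.
#' @return numeric vector of length `n`.
#' @export
logistic_example_losses <- function(params, x, y) {
  pr <- clamp_prob(logistic_probs(params, x))
  -rowMeans(y * log(pr) + (1 - y) * log(1 - pr))
}

#' Flat gradient of the logistic loss for a single example
#'
#' Gradient of the mean-over-classes binary cross-entropy in the flat
#' parameter layout `c(W, b)`; the payload a gradient-leakage adversary
#' observes for a single-example batch.
#' @inheritParams logistic_probs
#' @param x feature vector (length p).
#' @param y binary label vector (length M).
#' @return numeric gradient vector of length `p * M + M`.
#' @export
logistic_single_grad <- function(params, x, y) {
  pr <- logistic_probs(params, rbind(x))
  r <- (pr[1, ] - y) / length(y)
  c(outer(x, r), r)
}

adam_new <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, w, g, lr, b1, b2, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- b1 * state$m + (1 - b1) * g
  state$v <- b2 * state$v + (1 - b2) * g^2
  mh <- state$m / (1 - b1^state$t)
  vh <- state$v / (1 - b2^state$t)
  list(w = w - lr * mh / (sqrt(vh) + eps), state = state)
}

# One round of local training from the current global parameters. Adam state
# is reset at the start of each round (it never travels over the wire).
local_train_logistic <- function(w_global, data, cfg, round_idx, round_seed,
                                 class_w, prox_mu = 0) {
  x <- data$x; y <- data$y
  n <- nrow(x); p <- ncol(x); m <- ncol(y)
  w <- w_global
  st <- adam_new(length(w))
  lr_t <- if (cfg$lr_schedule == "cosine") {
    cfg$lr * 0.5 * (1 + cos(pi * (round_idx - 1) / max(cfg$T_rounds, 1)))
  } else cfg$lr
  bs <- min(cfg$batch_size, n)
  with_seed(round_seed, {
    for (e in seq_len(cfg$E)) {
      ord <- if (bs < n) sample.int(n) else seq_len(n)
      nb <- ceiling(n / bs)
      for (b in seq_len(nb)) {
        idx <- ord[((b - 1) * bs + 1):min(b * bs, n)]
        xb <- x[idx, , drop = FALSE]; yb <- y[idx, , drop = FALSE]
        pr <- logistic_probs(w, xb)
        G <- focal_logit_grad(yb, pr, class_w, cfg$gamma)   # n_b x M, dL_i/dz
        if (is.null(cfg$dp)) {
          gW <- crossprod(xb, G) / nrow(xb)
          gb <- colMeans(G)
          g <- c(gW, gb)
        } else {
          g <- dp_batch_gradient(xb, G, cfg$dp)
        }
        g <- g + cfg$weight_decay * w
        if (prox_mu > 0) g <- g + prox_mu * (w - w_global)
        if (any(!is.finite(g))) stop("divergence: non-finite gradient in local training")
        res <- adam_step(st, w, g, lr_t, cfg$adam_beta1, cfg$adam_beta2)
        w <- res$w; st <- res$state
      }
    }
  })
  w
}

# Per-example clip + single Gaussian draw per lot, vectorized for the
# logistic learner: example i's flat gradient is (x_i (x) G_i, G_i).
dp_batch_gradient <- function(xb, G, dp) {
  nb <- nrow(xb)
  norms <- sqrt((rowSums(xb^2) + 1) * rowSums(G^2))
  fac <- pmin(1, dp$clip_norm / pmax(norms, 1e-12))
  Gc <- G * fac
  gW <- crossprod(xb, Gc) / nb
  gb <- colMeans(Gc)
  g <- c(gW, gb)
  g + stats::rnorm(length(g), 0, dp$noise_multiplier * dp$clip_norm)
}

# Macro AUC over label columns with both classes present; 0.5 if none.
macro_auc <- function(scores, labels) {
  ok <- which(apply(labels, 2, function(col) length(unique(col)) == 2))
  if (length(ok) == 0) return(0.5)
  mean(vapply(ok, function(j) roc_auc(scores[, j], labels[, j]), numeric(1)))
}

# Normalized Shannon entropy of a node's label distribution: the default
# data-diversity statistic for the composite confidence score.
label_diversity <- function(y) {
  counts <- colSums(y != 0)
  if (sum(counts) == 0) return(0)
  q <- counts / sum(counts)
  q <- q[q > 0]
  ent <- -sum(q * log(q))
  min(1, ent / log(max(ncol(y), 2)))
}

#' Train a federated model
#'
#' Runs the synchronous star-topology protocol: at each round the server
#' broadcasts the global parameters, every client performs `E` local epochs
#' on its own training split (Adam, optionally with a FedProx proximal pull
#' or differentially private gradients), transmits its parameter delta back,
#' and the server aggregates. `method = "centralized"` pools all training
#' data into one node and runs the same loop for the same gradient-step
#' budget, providing the reference upper bound. Fully deterministic given the
#' configuration seed.
#'
#' @param nodes list of node datasets: either synthetic-cohort nodes (from
#'   [simulate_cohort()] / [partition_cohort()]) or tabular nodes of the form
#'   `list(train = list(x, y), val = ..., test = ...)`.
#' @param method aggregation rule: `"fedavg"`, `"fedprox"`, `"confidence"`
#'   (confidence-weighted), or `"centralized"`.
#' @param config a [fed_config()].
#' @param feature_size downsampling resolution when cohort nodes are supplied.
#' @return object of class `fed_fit`: the fitted global model with per-round
#'   logs. Access the trajectory with `$logs` (data.frame: round, weights,
#'   `global_val_auc`, `bytes_sent`, `bytes_broadcast`, `epsilon_spent`), the
#'   parameters with [coef()], predictions with [predict()].
#' @export
fed_train <- function(nodes, method = c("fedavg", "fedprox", "confidence",
                                        "centralized"),
                      config = fed_config(), feature_size = c(16L, 16L)) {
  method <- match.arg(method)
  stopifnot(inherits(config, "fed_config"))
  nodes <- as_design_nodes(nodes, feature_size)
  if (length(nodes) < 1 || any(vapply(nodes, function(nd) nrow(nd$train$x), 0L) == 0)) {
    stop("need at least one node with a nonempty train split")
  }
  if (method == "centralized") {
    pooled <- list(
      train = list(x = do.call(rbind, lapply(nodes, function(n) n$train$x)),
                   y = do.call(rbind, lapply(nodes, function(n) n$train$y))),
      val = list(x = do.call(rbind, lapply(nodes, function(n) n$val$x)),
                 y = do.call(rbind, lapply(nodes, function(n) n$val$y))),
      test = list(x = do.call(rbind, lapply(nodes, function(n) n$test$x)),
                  y = do.call(rbind, lapply(nodes, function(n) n$test$y))))
    nodes <- list(pooled)
  }
  K <- length(nodes)
  p <- ncol(nodes[[1]]$train$x)
  m <- ncol(nodes[[1]]$train$y)
  n_k <- vapply(nodes, function(nd) nrow(nd$train$x), numeric(1))
  class_w <- lapply(nodes, function(nd) {
    if (config$class_weighting && any(colSums(nd$train$y) > 0)) {
      imbalance_weights(nd$train$y)
    } else rep(1, m)
  })
  div <- vapply(nodes, function(nd) label_diversity(nd$train$y), numeric(1))
  qual <- vapply(nodes, function(nd) {
    q <- attr(nd, "quality"); if (is.null(q)) 1 else q
  }, numeric(1))
  server_val <- list(
    x = do.call(rbind, lapply(nodes, function(n) n$val$x)),
    y = do.call(rbind, lapply(nodes, function(n) n$val$y)))

  n_par <- p * m + m
  w_global <- numeric(n_par)
  prox_mu <- if (method == "fedprox") config$mu else 0
  round_seeds <- matrix(derive_seeds(config$seed, config$T_rounds * K),
                        config$T_rounds, K)
  eps_round <- if (!is.null(config$dp)) {
    sqrt(2 * log(1.25 / config$dp$delta)) / config$dp$noise_multiplier
  } else 0
  omega <- component_weights()
  logs <- vector("list", config$T_rounds)
  client_auc <- matrix(NA_real_, config$T_rounds, K)

  for (t in seq_len(config$T_rounds)) {
    updates <- vector("list", K)
    for (k in seq_len(K)) {
      w_k <- local_train_logistic(w_global, nodes[[k]]$train, config, t,
                                  round_seeds[t, k], class_w[[k]], prox_mu)
      auc_k <- if (nrow(nodes[[k]]$val$x) > 0) {
        macro_auc(logistic_probs(w_k, nodes[[k]]$val$x), nodes[[k]]$val$y)
      } else 0.5
      client_auc[t, k] <- auc_k
      updates[[k]] <- client_update(w_k, n_k[k], val_auc = auc_k,
                                    diversity = div[k], quality = qual[k])
    }
    if (method %in% c("fedavg", "fedprox", "centralized")) {
      wts <- n_k / sum(n_k)
      w_global <- fedavg(updates)
    } else {
      alpha <- n_k / sum(n_k)
      if (config$confidence_source == "softmax") {
        cs <- softmax_client_weights(client_auc[t, ], config$tau)$per_client
      } else {
        if (t > omega$warmup_rounds) {
          loss_fn <- function(om) {
            cc <- vapply(seq_len(K), function(k) {
              confidence_score(client_auc[t, k], div[k], qual[k], om)
            }, numeric(1))
            w_try <- confidence_weighted_aggregate(updates, alpha, cc)
            pr <- clamp_prob(logistic_probs(w_try, server_val$x))
            -mean(server_val$y * log(pr) + (1 - server_val$y) * log(1 - pr))
          }
          grad <- component_weight_gradient(loss_fn, omega)
          omega <- update_component_weights(omega, grad, t)
        }
        cs <- vapply(seq_len(K), function(k) {
          confidence_score(client_auc[t, k], div[k], qual[k], omega)
        }, numeric(1))
      }
      w_eff <- alpha * cs
      wts <- w_eff / sum(w_eff)
      w_global <- confidence_weighted_aggregate(updates, alpha, cs)
    }
    if (any(!is.finite(w_global))) stop("divergence: non-finite global parameters at round ", t)
    g_auc <- macro_auc(logistic_probs(w_global, server_val$x), server_val$y)
    logs[[t]] <- c(round = t, global_val_auc = g_auc,
                   bytes_sent = K * n_par * 4,
                   bytes_broadcast = K * n_par * 4,
                   epsilon_spent = t * eps_round,
                   stats::setNames(wts, paste0("w", seq_len(K))))
  }
  logs <- as.data.frame(do.call(rbind, logs))
  fit <- structure(list(
    method = method, config = config, model = "logistic",
    params = param_vector(w_global, logistic_shapes(p, m)),
    logs = logs, client_val_auc = client_auc,
    convergence_round = detect_convergence(logs$global_val_auc),
    p = p, m = m, n_k = n_k, omega = omega,
    server_val = server_val), class = "fed_fit")
  fit
}

#' @export
print.fed_fit <- function(x, ...) {
  cat("Federated model fit (", x$method, ")\n", sep = "")
  cat(sprintf("  nodes: %d  rounds: %d  local epochs: %d\n",
              length(x$n_k), x$config$T_rounds, x$config$E))
  cat(sprintf("  parameters: %d (logistic, %d features, %d classes)\n",
              length(x$params$values), x$p, x$m))
  cat(sprintf("  final global validation AUC: %.3f (convergence at round %d)\n",
              utils::tail(x$logs$global_val_auc, 1), x$convergence_round))
  if (!is.null(x$config$dp)) {
    cat(sprintf("  DP enabled: sigma = %.2f, C = %.2f, cumulative eps = %.2f\n",
                x$config$dp$noise_multiplier, x$config$dp$clip_norm,
                utils::tail(x$logs$epsilon_spent, 1)))
  }
  invisible(x)
}

#' @export
summary.fed_fit <- function(object, ...) {
  logs <- object$logs
  out <- list(
    method = object$method,
    convergence_round = object$convergence_round,
    final_auc = utils::tail(logs$global_val_auc, 1),
    auc_at_convergence = logs$global_val_auc[object$convergence_round],
    total_upload_gb = sum(logs$bytes_sent) / 1e9,
    epsilon_spent = utils::tail(logs$epsilon_spent, 1),
    client_val_auc = object$client_val_auc)
  class(out) <- "summary.fed_fit"
  out
}

#' @export
print.summary.fed_fit <- function(x, ...) {
  cat("Federated fit summary\n")
  cat(sprintf("  method: %s\n  convergence round: %d (AUC %.3f)\n",
              x$method, x$convergence_round, x$auc_at_convergence))
  cat(sprintf("  final global validation AUC: %.3f\n", x$final_auc))
  cat(sprintf("  total upload: %.4f GB\n", x$total_upload_gb))
  if (x$epsilon_spent > 0) cat(sprintf("  privacy budget spent (basic composition): %.2f\n", x$epsilon_spent))
  invisible(x)
}

#' @export
coef.fed_fit <- function(object, ...) object$params$values

#' @export
predict.fed_fit <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  pr <- logistic_probs(object$params, newdata)
  if (type == "response") pr else log(pr / (1 - pr))
}

#' @export
plot.fed_fit <- function(x, ...) {
  graphics::plot(x$logs$round, x$logs$global_val_auc, type = "l",
                 xlab = "communication round", ylab = "global validation AUC",
                 main = sprintf("Convergence (%s)", x$method), ...)
  graphics::abline(v = x$convergence_round, lty = 2, col = "grey40")
  invisible(x)
}
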