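test_that("fedavg is the sample-size-weighted mean", {
  u <- list(client_update(1.0, 10), client_update(3.0, 30))
  expect_equal(fedavg(u), 2.5)
  # identical clients -> unchanged; single client -> unchanged
  pv <- param_vector(rnorm(6), list(w = 6L))
  same <- list(client_update(pv, 5), client_update(pv, 17))
  expect_equal(fedavg(same)$values, pv$values)
  expect_equal(fedavg(list(client_update(pv, 3)))$values, pv$values)
  expect_error(fedavg(list()), "nonempty")
  expect_error(fedavg(list(client_update(1:2, 1), client_update(1:3, 1))),
               "shape")
})

test_that("the FedProx objective adds the proximal quadratic", {
  w <- c(1, 2, 2); wt <- c(0, 0, 0)
  expect_equal(fedprox_local_objective(5, w, w, mu = 10), 5)   # w = w_t
  expect_equal(fedprox_local_objective(3, w, wt, mu = 0), 3)   # mu = 0
  expect_equal(fedprox_local_objective(0, w, wt, mu = 2), 9)   # (2/2)*9
  expect_equal(fedprox_local_objective(function(x) sum(x), w, wt, 2), 5 + 9)
  expect_error(fedprox_local_objective(0, w, wt, mu = -1), "mu")
})

test_that("confidence scores are convex combinations", {
  expect_equal(confidence_score(0.8, 0.5, 1.0, c(0.5, 0.3, 0.2)), 0.75)
  expect_equal(confidence_score(0.6, 0.6, 0.6, c(0.2, 0.5, 0.3)), 0.6)
  expect_equal(confidence_score(0.9, 0.1, 0.2, c(1, 0, 0)), 0.9)
  expect_error(confidence_score(0.5, 0.5, 0.5, c(0.6, 0.6, 0.6)), "simplex")
  expect_error(confidence_score(1.5, 0.5, 0.5, c(1, 0, 0)), "\\[0, 1\\]")
})

test_that("softmax client weights hit their stated values and limits", {
  w <- softmax_client_weights(c(0.9, 0.8), tau = 0.5)
  expect_equal(w$per_client, c(1, exp(-0.2)) / (1 + exp(-0.2)), tolerance = 1e-6)
  expect_equal(w$per_client[1], 0.5498, tolerance = 1e-4)
  # equal AUCs -> uniform
  expect_equal(softmax_client_weights(rep(0.77, 4), 0.5)$per_client, rep(0.25, 4))
  # tau -> infinity: uniform; tau -> 0: concentrates on the argmax
  expect_equal(softmax_client_weights(c(0.9, 0.6, 0.3), 1e6)$per_client,
               rep(1 / 3, 3), tolerance = 1e-6)
  hard <- softmax_client_weights(c(0.9, 0.6, 0.3), 1e-3)$per_client
  expect_equal(hard, c(1, 0, 0), tolerance = 1e-9)
  expect_error(softmax_client_weights(c(0.5, 0.5), 0), "tau")
  # weights always conserve mass
  for (i in 1:10) {
    set.seed(i)
    ww <- softmax_client_weights(runif(5), runif(1, 0.1, 2))$per_client
    expect_true(all(ww >= 0))
    expect_equal(sum(ww), 1, tolerance = 1e-9)
  }
})

test_that("confidence-weighted aggregation generalizes FedAvg", {
  u <- list(client_update(1.0, 1), client_update(3.0, 1))
  expect_equal(confidence_weighted_aggregate(u, c(0.5, 0.5), c(1, 3)), 2.5)
  # equal confidences with alpha = n_k / n reduce exactly to FedAvg weighting
  for (i in 1:10) {
    set.seed(i)
    ups <- lapply(1:4, function(k) {
      client_update(param_vector(rnorm(8), list(w = 8L)), sample(1:50, 1))
    })
    n_k <- vapply(ups, function(x) x$n_k, numeric(1))
    agg <- confidence_weighted_aggregate(ups, n_k / sum(n_k), rep(0.7, 4))
    expect_equal(agg$values, fedavg(ups)$values, tolerance = 1e-9)
  }
  # a zero-confidence client has no influence
  u2 <- list(client_update(c(100, 100), 1), client_update(c(2, 4), 1))
  expect_equal(confidence_weighted_aggregate(u2, c(0.5, 0.5), c(0, 1)), c(2, 4))
  expect_error(confidence_weighted_aggregate(u2, c(1, 1), c(0, 0)), "1e-12")
})

test_that("simplex projection matches the active-set oracle", {
  expect_equal(project_to_simplex(c(1, 1, 1) / 3), c(1, 1, 1) / 3)
  expect_equal(project_to_simplex(c(1, 1, 1)), rep(1 / 3, 3))
  expect_equal(project_to_simplex(c(1.2, -0.2, 0)), c(1, 0, 0))
  for (i in 1:25) {
    set.seed(i)
    v <- rnorm(3, 0, 2)
    p <- project_to_simplex(v)
    expect_equal(p, simplex_projection_oracle(v), tolerance = 1e-9)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_true(all(p >= 0))
    # idempotent; never increases distance to any simplex point
    expect_equal(project_to_simplex(p), p, tolerance = 1e-12)
    q <- simplex_projection_oracle(rnorm(3))
    expect_lte(sum((p - q)^2), sum((v - q)^2) + 1e-12)
  }
  expect_error(project_to_simplex(numeric(0)), "nonempty")
  expect_error(project_to_simplex(c(1, NA)), "finite")
})

test_that("component weights stay uniform in warm-up then take projected steps", {
  om <- component_weights()
  for (r in c(1, 5, 10)) {
    expect_equal(update_component_weights(om, c(9, 9, 9), r)$omega, rep(1 / 3, 3))
  }
  # zero gradient leaves omega unchanged after warm-up
  expect_equal(update_component_weights(om, c(0, 0, 0), 11)$omega, rep(1 / 3, 3))
  # gradient (1, 0, 0): projection of (1/3 - 0.01, 1/3, 1/3)
  up <- update_component_weights(om, c(1, 0, 0), 11)
  expect_equal(up$omega, simplex_projection_oracle(c(1 / 3 - 0.01, 1 / 3, 1 / 3)),
               tolerance = 1e-12)
  # finite-difference gradient of a known quadratic on the simplex
  loss <- function(o) sum((o - c(0.6, 0.3, 0.1))^2)
  g <- component_weight_gradient(loss, c(1 / 3, 1 / 3, 1 / 3), h = 1e-4)
  # tangent-direction derivative of the quadratic: 2 * (omega - target) . t_j
  tg <- vapply(1:3, function(j) {
    t_j <- -rep(1 / 3, 3); t_j[j] <- t_j[j] + 1
    sum(2 * (rep(1 / 3, 3) - c(0.6, 0.3, 0.1)) * t_j)
  }, numeric(1))
  expect_equal(g, tg, tolerance = 1e-6)
})

test_that("convergence detection applies the plateau rule", {
  expect_equal(detect_convergence(rep(0.8, 10)), 1)              # flat
  rising <- seq(0.5, 0.9, length.out = 12)
  expect_equal(detect_convergence(rising, tol = 0.001), 12)      # never plateaus
  curve <- c(seq(0.5, 0.85, length.out = 7), rep(0.85, 8))
  r <- detect_convergence(curve, tol = 0.001, window = 5)
  expect_gte(r, 7 - 5)
  expect_lte(r, 7)
  expect_error(detect_convergence(numeric(0)), "nonempty")
})

test_that("communication cost reproduces the upload arithmetic", {
  cc <- comm_cost(94.3, 47, 4)
  expect_equal(cc$per_round_mb, 94.3)
  expect_equal(cc$total_gb, 17.7)
  expect_equal(comm_cost(94.3, 63, 4)$total_gb, 23.8)
  # uncompressed payload divided by the 4:1 ratio
  expect_equal(comm_cost(377.2, 47, 4, compressed = FALSE)$per_round_mb, 94.3)
  expect_error(comm_cost(94.3, 0, 4), "positive")
})

test_that("federated training is deterministic and reduces as expected", {
  nodes <- list(make_logistic_node(300, default_W, default_b, 11),
                make_logistic_node(300, default_W, default_b, 22))
  cfg <- fed_config(E = 2, T_rounds = 4, lr = 0.05, seed = 7, gamma = 0,
                    class_weighting = FALSE)
  f1 <- fed_train(nodes, "fedavg", cfg)
  f2 <- fed_train(nodes, "fedavg", cfg)
  expect_identical(f1$logs, f2$logs)
  expect_identical(coef(f1), coef(f2))
  # round-log invariants: weights sum to 1, monotone privacy budget
  wcols <- paste0("w", 1:2)
  expect_equal(rowSums(f1$logs[, wcols]), rep(1, 4), tolerance = 1e-9)
  expect_true(all(diff(f1$logs$epsilon_spent) >= 0))
  # K = 1 federated equals centralized bit-for-step
  k1 <- fed_train(nodes[1], "fedavg", cfg)
  ce <- fed_train(nodes[1], "centralized", cfg)
  expect_identical(coef(k1), coef(ce))
  expect_identical(k1$logs$global_val_auc, ce$logs$global_val_auc)
  # identical data on K clients, E = 1, full batch: one centralized step
  nd <- nodes[[1]]
  cfg_fb <- fed_config(E = 1, T_rounds = 1, lr = 0.05, batch_size = 10000,
                       seed = 5, gamma = 0, class_weighting = FALSE)
  f3 <- fed_train(list(nd, nd, nd), "fedavg", cfg_fb)
  f4 <- fed_train(list(nd), "fedavg", cfg_fb)
  expect_lt(max(abs(coef(f3) - coef(f4))), 1e-10)
})

test_that("fed_fit methods expose the fitted model", {
  nodes <- list(make_logistic_node(200, default_W, default_b, 31))
  fit <- fed_train(nodes, "fedavg",
                   fed_config(E = 2, T_rounds = 3, lr = 0.05, seed = 1))
  expect_s3_class(fit, "fed_fit")
  expect_length(coef(fit), 2 * 2 + 2)
  newx <- matrix(rnorm(10), 5, 2)
  pr <- predict(fit, newx)
  expect_identical(dim(pr), c(5L, 2L))
  expect_true(all(pr > 0 & pr < 1))
  lnk <- predict(fit, newx, type = "link")
  expect_equal(1 / (1 + exp(-lnk)), pr, tolerance = 1e-12)
  expect_output(print(fit), "Federated model fit")
  expect_output(print(summary(fit)), "convergence round")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("confidence-weighted training runs with both confidence sources", {
  nodes <- list(make_logistic_node(150, default_W, default_b, 41),
                make_logistic_node(150, default_W, default_b, 42))
  for (src in c("softmax", "composite")) {
    fit <- fed_train(nodes, "confidence",
                     fed_config(E = 1, T_rounds = 3, lr = 0.05, seed = 2,
                                confidence_source = src))
    expect_equal(rowSums(fit$logs[, c("w1", "w2")]), rep(1, 3), tolerance = 1e-9)
    expect_true(all(is.finite(coef(fit))))
  }
})
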