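# Shared fixtures: all data is generated in code at test time.

neutral_profile <- function(m = 5L) {
  institution_profile(rep(1 / m, m), gain = 1, bias = 0, noise_sd = 0,
                      resolution_scale = 1)
}

# Multi-label logistic ground truth with standard-normal features; returns a
# tabular node with the requested split sizes.
make_logistic_node <- function(n_train, W, b, seed, n_val = 200L, n_test = 200L) {
  p <- nrow(W); m <- ncol(W)
  gen <- function(n, s) {
    set.seed(s)
    x <- matrix(stats::rnorm(n * p), n, p)
    pr <- 1 / (1 + exp(-(x %*% W + matrix(b, n, m, byrow = TRUE))))
    list(x = x, y = matrix(stats::rbinom(n * m, 1, pr), n, m))
  }
  list(train = gen(n_train, seed), val = gen(n_val, seed + 1L),
       test = gen(n_test, seed + 2L))
}

default_W <- matrix(c(1.5, -2, 0.8, 1.2), 2, 2)
default_b <- c(0.3, -0.5)

# Blob-vs-normal cohort for the explainability experiments: positives carry
# one focal bright opacity at a random in-lung location.
make_blob_cohort <- function(n_per_class = 15L, size = c(32L, 32L)) {
  prof <- neutral_profile(5L)
  c(lapply(seq_len(n_per_class), function(i) {
    generate_case(prof, 5L, size, seed = 100L + i, labels = c(1, 0, 0, 0, 0))
  }),
  lapply(seq_len(n_per_class), function(i) {
    generate_case(prof, 5L, size, seed = 200L + i, labels = c(0, 0, 0, 0, 0))
  }))
}

# Exact Euclidean projection onto the simplex by active-set enumeration:
# for every support set S the unconstrained stationary point is
# v_S + (1 - sum(v_S)) / |S|; the feasible candidate closest to v is the
# projection. Independent of the sorting-based implementation.
simplex_projection_oracle <- function(v) {
  n <- length(v)
  best <- NULL; best_d <- Inf
  for (mask in seq_len(2^n - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    x <- numeric(n)
    x[S] <- v[S] + (1 - sum(v[S])) / length(S)
    if (all(x >= -1e-12)) {
      d <- sum((x - v)^2)
      if (d < best_d) { best_d <- d; best <- pmax(x, 0) }
    }
  }
  best
}

write_temp_yaml <- function(cfg) {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  path
}

small_experiment_config <- function(out_dir) {
  list(output_dir = out_dir,
       seed_list = 1L,
       methods = c("fedavg", "centralized"),
       cohort = list(n_cases = 40, K = 2, m_classes = 5, size = c(32, 32),
                     dirichlet_beta = 0.5, split = c(0.7, 0.1, 0.2),
                     heterogeneity = "photometric"),
       federation = list(E = 1, T_rounds = 3, lr = 0.05,
                         feature_size = c(8, 8), batch_size = 16))
}
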