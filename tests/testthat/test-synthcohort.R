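test_that("case generation is deterministic and respects invariants", {
  prof <- neutral_profile()
  cs1 <- generate_case(prof, 5, c(32, 32), seed = 42)
  cs2 <- generate_case(prof, 5, c(32, 32), seed = 42)
  expect_identical(cs1, cs2)
  expect_true(all(cs1$image >= 0 & cs1$image <= 1))
  expect_true(all(cs1$masks %in% c(0, 1)))
  expect_identical(dim(cs1$masks), c(32L, 32L, 6L))
  # xai mask nonzero iff at least one positive label
  for (sd in 1:10) {
    cs <- generate_case(prof, 5, c(32, 32), seed = sd)
    expect_identical(any(cs$xai_mask != 0), any(cs$labels == 1))
  }
  # institution effects change the image but not determinism
  shifted <- institution_profile(rep(0.2, 5), gain = 1.1, bias = 0.02,
                                 noise_sd = 0.03, resolution_scale = 0.9)
  cs3 <- generate_case(shifted, 5, c(32, 32), seed = 42)
  expect_false(identical(cs3$image, cs1$image))
  expect_true(all(cs3$image >= 0 & cs3$image <= 1))
})

test_that("a neutral profile with all-negative labels renders the clean template", {
  cs <- generate_case(neutral_profile(), 5, c(32, 32), seed = 7,
                      labels = rep(0, 5), return_template = TRUE)
  expect_equal(cs$image, attr(cs, "template"))
  expect_true(all(cs$xai_mask == 0))
})

test_that("the cardiomegaly-like label enlarges the heart mask", {
  prof <- neutral_profile()
  for (sd in c(7, 19, 33)) {
    neg <- generate_case(prof, 5, c(32, 32), seed = sd, labels = rep(0, 5))
    pos <- generate_case(prof, 5, c(32, 32), seed = sd, labels = c(0, 1, 0, 0, 0))
    expect_gt(sum(pos$masks[, , "heart"]), sum(neg$masks[, , "heart"]))
  }
})

test_that("generation rejects invalid inputs", {
  prof <- neutral_profile()
  expect_error(generate_case(prof, 5, c(16, 32), seed = 1), "size")
  expect_error(generate_case(prof, 4, c(32, 32), seed = 1), "label_prior")
  expect_error(institution_profile(c(0.5, 0.4)), "sum to 1")
  expect_error(institution_profile(rep(0.25, 4), noise_sd = -1), "noise_sd")
})

test_that("prior atlas is the per-pixel mask frequency", {
  prof <- neutral_profile()
  cs <- generate_case(prof, 5, c(32, 32), seed = 3, labels = rep(0, 5))
  # identical cases: atlas equals the mask tensor
  at <- build_prior_atlas(rep(list(cs), 10))
  expect_equal(at$P, cs$masks)
  expect_equal(at$n_source_cases, 10)
  # disjoint masks on a channel: 0.5 on the union, 0 elsewhere
  a <- cs; b <- cs
  a$masks[] <- 0; b$masks[] <- 0
  a$masks[1:4, 1:4, 1] <- 1
  b$masks[10:12, 10:12, 1] <- 1
  at2 <- build_prior_atlas(list(a, b))
  expect_equal(at2$P[1:4, 1:4, 1], matrix(0.5, 4, 4))
  expect_equal(at2$P[10:12, 10:12, 1], matrix(0.5, 3, 3))
  expect_equal(sum(at2$P), (16 + 9) * 0.5)
  # empty masks -> all zeros; bounds always hold
  expect_true(all(at2$P >= 0 & at2$P <= 1))
  expect_equal(sum(build_prior_atlas(list(a))$P[, , 2:6]), 0)
  # inconsistent shapes rejected
  small <- generate_case(prof, 5, c(34, 34), seed = 3)
  expect_error(build_prior_atlas(list(cs, small)), "inconsistent")
})

test_that("split counts reproduce the 70/10/20 arithmetic", {
  expect_identical(unname(split_counts(112120)),
                   c(78484L, 11212L, 22424L))
  sc <- split_counts(997, c(0.7, 0.1, 0.2))
  expect_equal(sum(sc), 997)
})

test_that("partitioning conserves cases and induces the requested skew", {
  prof <- neutral_profile()
  cases <- lapply(1:120, function(i) generate_case(prof, 5, c(32, 32), seed = i))
  spec <- partition_spec(K = 3, dirichlet_beta = 0.5, seed = 9)
  nodes <- partition_cohort(cases, spec)
  # conservation: every case in exactly one node, splits partition each node
  ids <- unlist(lapply(nodes, function(nd) {
    vapply(nd$cases, function(cs) cs$case_id, character(1))
  }))
  expect_setequal(ids, vapply(cases, function(cs) cs$case_id, character(1)))
  expect_equal(length(ids), 120)
  for (nd in nodes) {
    expect_equal(length(nd$split), length(nd$cases))
    expect_identical(unname(split_counts(length(nd$cases), spec$split)),
                     unname(c(sum(nd$split == "train"), sum(nd$split == "val"),
                              sum(nd$split == "test"))))
  }
  # K = 1: everything in one node
  one <- partition_cohort(cases, partition_spec(K = 1, seed = 2))
  expect_length(one, 1)
  expect_length(one[[1]]$cases, 120)
  expect_error(partition_cohort(cases[1:2], partition_spec(K = 3, seed = 1)),
               "K > n_cases")
})

test_that("very large dirichlet beta approaches the global label frequencies", {
  prof <- institution_profile(c(0.5, 0.25, 0.15, 0.07, 0.03), noise_sd = 0)
  cases <- lapply(1:600, function(i) generate_case(prof, 5, c(32, 32), seed = i))
  glob <- colMeans(do.call(rbind, lapply(cases, function(cs) cs$labels)))
  nodes <- partition_cohort(cases, partition_spec(K = 4, dirichlet_beta = 1e6,
                                                  seed = 5))
  for (nd in nodes) {
    freq <- colMeans(do.call(rbind, lapply(nd$cases, function(cs) cs$labels)))
    expect_lt(max(abs(freq - glob)), 0.05)
  }
})

test_that("inverse-frequency weights follow the capped mean-1 rule", {
  y <- cbind(rep(1, 2), rep(c(1, 0), 1))
  # balanced two-class labels -> weights (1, 1)
  bal <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(imbalance_weights(bal), c(1, 1))
  # counts (90, 10) of n = 100 -> normalized (0.2, 1.8)
  y2 <- cbind(c(rep(1, 90), rep(0, 10)), c(rep(0, 90), rep(1, 10)))
  expect_equal(imbalance_weights(y2), c(0.2, 1.8))
  # absent class capped at 10x the largest observed weight (pre-normalization)
  y3 <- cbind(c(rep(1, 9), 0), rep(0, 10))
  raw <- c(10 / 9, 10 * 10 / 9)
  expect_equal(imbalance_weights(y3), raw / mean(raw))
  expect_error(imbalance_weights(matrix(0, 0, 2)), "nonempty")
})

test_that("skewed priors can reach severe class imbalance", {
  prof <- institution_profile(c(0.85, 0.12, 0.02, 0.008, 0.002),
                              noise_sd = 0, p_normal = 0.2)
  labs <- t(vapply(1:800, function(i) {
    generate_case(prof, 5, c(32, 32), seed = 5000 + i)$labels
  }, integer(5)))
  ratio <- max_imbalance(labs)
  expect_gte(ratio, 100)
})

test_that("uncertain labels map to negative and augmentation stays in range", {
  expect_identical(resolve_uncertain_labels(c(-1L, 0L, 1L)), c(0L, 0L, 1L))
  img <- generate_case(neutral_profile(), 5, c(32, 32), seed = 1)$image
  set.seed(11)
  for (i in 1:5) {
    aug <- augment_image(img)
    expect_identical(dim(aug), dim(img))
    expect_true(all(aug >= 0 & aug <= 1))
  }
})

test_that("simulate_cohort builds K heterogeneous nodes with splits", {
  nodes <- simulate_cohort(60, K = 3, m_classes = 5, size = c(32, 32), seed = 4)
  expect_length(nodes, 3)
  expect_equal(sum(vapply(nodes, function(nd) length(nd$cases), 0L)), 60)
  sm <- cohort_summary(nodes)
  expect_equal(sm$n_train + sm$n_val + sm$n_test, sm$n)
  # deterministic
  nodes2 <- simulate_cohort(60, K = 3, m_classes = 5, size = c(32, 32), seed = 4)
  expect_identical(nodes[[2]]$cases[[5]]$image, nodes2[[2]]$cases[[5]]$image)
})
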