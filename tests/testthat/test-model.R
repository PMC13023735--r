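test_that("tiny model forward is deterministic with bounded outputs", {
  spec <- tinycnn_spec(16, 16, m_classes = 3, a_structures = 2, f1 = 3, f2 = 4)
  pv <- tinycnn_init(spec, seed = 5)
  set.seed(1)
  img <- matrix(runif(256), 16, 16)
  b1 <- tiny_model_forward(pv, img, spec)
  b2 <- tiny_model_forward(pv, img, spec)
  expect_identical(b1$class_probs, b2$class_probs)
  expect_identical(b1$seg_probs, b2$seg_probs)
  expect_true(all(b1$class_probs >= 0 & b1$class_probs <= 1))
  expect_true(all(b1$seg_probs >= 0 & b1$seg_probs <= 1))
  expect_identical(dim(b1$seg_probs), c(16L, 16L, 2L))
  # zero parameters -> sigmoid(0) = 0.5 everywhere
  zero <- param_vector(numeric(length(pv$values)), spec$shapes)
  expect_true(all(tiny_model_forward(zero, img, spec)$class_probs == 0.5))
  expect_error(tiny_model_forward(pv, matrix(0, 8, 8), spec), "shape")
})

test_that("parameter vector enforces its registry and round-trips checkpoints", {
  shapes <- list(a = c(2L, 3L), b = 4L)
  pv <- param_vector(1:10, shapes)
  expect_length(pv, 10)
  expect_equal(fedradsim:::param_get(pv, "a"), matrix(1:6, 2, 3))
  expect_equal(fedradsim:::param_get(pv, "b"), 7:10)
  expect_error(param_vector(1:9, shapes), "registry")
  expect_error(param_vector(c(1:9, NA), shapes), "finite")
  path <- tempfile()
  write_checkpoint(param_vector(rnorm(10), shapes), path)
  rt <- read_checkpoint(path)
  expect_length(rt, 10)
  expect_true(file.exists(paste0(path, ".json")))
})

test_that("model gradients pass the central-difference check", {
  spec <- tinycnn_spec(16, 16, m_classes = 3, a_structures = 2, f1 = 3, f2 = 4)
  set.seed(9)
  img <- matrix(runif(256), 16, 16)
  S <- array(rbinom(512, 1, 0.3), c(16, 16, 2))
  P <- array(runif(512), c(16, 16, 2))
  y <- c(1, 0, 1)
  for (ini in c("random", "structured")) {
    pv <- tinycnn_init(spec, seed = 5, init = ini)
    loss_fn <- function(values) {
      b <- tiny_model_forward(param_vector(values, spec$shapes), img, spec)
      focal_class_loss(y, b$class_probs) + composite_seg_loss(S, b$seg_probs, P)
    }
    b <- tiny_model_forward(pv, img, spec)
    dlog <- as.numeric(fedradsim:::focal_logit_grad(rbind(y), rbind(b$class_probs)))
    dseg <- fedradsim:::composite_seg_grad(S, b$seg_probs, P)
    g <- fedradsim:::tinycnn_backward(b, dlog, dseg)
    set.seed(1)
    idx <- sample(length(pv$values), 40)
    h <- 1e-5
    fd <- vapply(idx, function(i) {
      up <- pv$values; dn <- pv$values
      up[i] <- up[i] + h; dn[i] <- dn[i] - h
      (loss_fn(up) - loss_fn(dn)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(fd - g$values[idx]) / pmax(abs(fd), 1e-4)), 1e-4)
  }
})

test_that("heatmaps respect the normalization contract", {
  spec <- tinycnn_spec(16, 16, m_classes = 3, a_structures = 2, f1 = 3, f2 = 4)
  pv <- tinycnn_init(spec, seed = 5)
  img <- generate_case(neutral_profile(), 5, c(32, 32), seed = 1)$image
  img <- resize_bilinear(img, 16, 16)
  hm <- gradcam(pv, img, 1, spec)
  expect_true(all(hm$values >= 0 & hm$values <= 1))
  if (any(hm$values > 0)) expect_equal(max(hm$values), 1)
  # all-zero class weights -> zero gradient -> all-zero map, guard leaves zeros
  L <- fedradsim:::param_unpack(pv)
  L$cls_w[2, ] <- 0
  pz <- fedradsim:::param_pack(L, spec$shapes)
  expect_true(all(gradcam(pz, img, 2, spec)$values == 0))
  expect_error(gradcam(pv, img, 9, spec), "class out of range")
})

test_that("a model trained on blob cases localizes them via Grad-CAM", {
  # frozen structured trunk without global standardization (which otherwise
  # offers a non-local shortcut), heads trained 200 Adam steps, fixed seed
  spec <- tinycnn_spec(32, 32, 5, 6, normalize = FALSE)
  cohort <- make_blob_cohort(15)
  pv <- tinycnn_train(cohort, spec, steps = 200, lr = 0.1, seed = 3,
                      train_trunk = FALSE)
  pos <- cohort[1:15]; neg <- cohort[16:30]
  p_pos <- vapply(pos, function(cs) tiny_model_forward(pv, cs$image, spec)$class_probs[1], numeric(1))
  p_neg <- vapply(neg, function(cs) tiny_model_forward(pv, cs$image, spec)$class_probs[1], numeric(1))
  expect_gt(mean(p_pos), mean(p_neg))
  hits <- vapply(pos, function(cs) {
    pointing_game(gradcam(pv, cs$image, 1, spec), cs$xai_mask)
  }, logical(1))
  # chance rate is the blob area fraction (~1.6%); localization must be
  # far above it
  expect_gte(sum(hits), 8)
})

test_that("dropout masks rescale features only at train time", {
  spec <- tinycnn_spec(16, 16, m_classes = 2, a_structures = 2, f1 = 3, f2 = 4)
  pv <- tinycnn_init(spec, seed = 2)
  set.seed(3)
  img <- matrix(runif(256), 16, 16)
  plain <- tiny_model_forward(pv, img, spec)
  full_mask <- rep(1, 4)
  dropped <- tiny_model_forward(pv, img, spec, dropout_mask = full_mask)
  # all-ones mask at p = 0.3 scales features by 1/0.7: differs from eval mode
  expect_false(identical(plain$class_probs, dropped$class_probs))
  zero_mask <- rep(0, 4)
  gone <- tiny_model_forward(pv, img, spec, dropout_mask = zero_mask)
  expect_true(all(gone$class_probs == 0.5))  # only the bias remains (zero)
})
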