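test_that("rank AUC matches pairwise concordance and an independent package", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0)), 0.75)
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)  # all ties
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
  # invariant under strictly monotone transforms
  set.seed(2)
  s <- rnorm(40); y <- rbinom(40, 1, 0.5)
  expect_equal(roc_auc(s, y), roc_auc(exp(s), y))
  expect_equal(roc_auc(s, y), roc_auc(qlogis(plogis(s)), y))
  # cross-check against pROC on random data
  skip_if_not_installed("pROC")
  for (i in 1:5) {
    set.seed(i)
    s <- runif(50); y <- rbinom(50, 1, 0.4)
    if (length(unique(y)) < 2) next
    ref <- as.numeric(suppressMessages(pROC::auc(y, s, direction = "<")))
    expect_equal(roc_auc(s, y), ref, tolerance = 1e-12)
  }
})

test_that("threshold metrics follow the confusion matrix", {
  # TP=3, FN=1, FP=1, TN=5
  scores <- c(0.9, 0.8, 0.7, 0.2, 0.6, 0.1, 0.2, 0.3, 0.4, 0.45)
  labels <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  tm <- threshold_metrics(scores, labels, threshold = 0.5)
  expect_equal(unname(tm["sensitivity"]), 0.75)
  expect_equal(unname(tm["specificity"]), 5 / 6)
  expect_equal(unname(tm["f1"]), 0.75)
  # perfect classifier; degenerate all-positive prediction
  expect_equal(unname(threshold_metrics(c(0.9, 0.1), c(1, 0))), c(1, 1, 1))
  ap <- threshold_metrics(c(0.9, 0.8), c(1, 0), threshold = 0.5)
  expect_equal(unname(ap[c("sensitivity", "specificity")]), c(1, 0))
  expect_error(threshold_metrics(1:3 / 3, c(1, 1, 1)), "both classes")
})

test_that("macro averaging reproduces the fairness-table arithmetic", {
  tbl <- rbind(node_metrics(1, 0.871, 0.812, 0.823, 0.891),
               node_metrics(2, 0.884, 0.829, 0.841, 0.903),
               node_metrics(3, 0.893, 0.844, 0.857, 0.912),
               node_metrics(4, 0.862, 0.798, 0.811, 0.878))
  ma <- macro_average(tbl)
  expect_equal(unname(ma$report["sensitivity"]), 0.833)
  expect_equal(unname(ma$report["f1"]), 0.821)
  expect_equal(unname(ma$mean["auc"]), 0.8775)
  expect_equal(unname(ma$report["specificity"]), 0.896)
  # sample standard deviation convention
  expect_equal(unname(ma$sd["auc"]), sd(tbl$auc))
  # permutation invariance; single node has sd 0
  expect_equal(macro_average(tbl[c(3, 1, 4, 2), ])$mean, ma$mean)
  one <- macro_average(node_metrics(1, 0.9, 0.8, 0.7, 0.95))
  expect_equal(unname(one$sd), rep(0, 4))
})

test_that("retention expresses federated performance as a percentage", {
  expect_equal(retention(0.911, 0.922), 98.8)
  expect_equal(retention(0.5, 0.5), 100.0)
  expect_equal(retention(0.163, 0.204), 79.9)
  expect_error(retention(0.5, 0), "centralized")
})

test_that("BLEU-n applies clipped precisions and the brevity penalty", {
  ref <- tokenize("the cat sat on mat")
  cand <- tokenize("the cat sat")
  expect_equal(bleu_n(cand, list(ref), 1), exp(1 - 5 / 3), tolerance = 1e-6)
  # identical candidate/reference -> 1 for any order up to the length
  for (n in 1:3) expect_equal(bleu_n(ref, list(ref), n), 1.0)
  # disjoint vocabulary -> 0
  expect_equal(bleu_n(tokenize("x y z"), list(ref), 1), 0)
  # clipping: repeated candidate token cannot overcount
  expect_equal(bleu_n(c("the", "the", "the"), list(ref), 1), 1 / 3 * exp(1 - 5 / 3))
  expect_error(bleu_n(character(0), list(ref), 1), "empty")
})

test_that("ROUGE-L uses the LCS F-measure", {
  a <- tokenize("a b c")
  expect_equal(rouge_l(a, a), 1.0)
  expect_equal(rouge_l(a, tokenize("a x c")), 2 / 3, tolerance = 1e-9)
  expect_equal(rouge_l(a, tokenize("p q r")), 0)
  # beta weighting: recall-heavy by default
  cand <- tokenize("a b"); ref <- tokenize("a b c d")
  r <- 2 / 4; p <- 2 / 2; beta <- 1.2
  expect_equal(rouge_l(cand, ref), (1 + beta^2) * r * p / (r + beta^2 * p))
  expect_error(rouge_l(character(0), a), "empty")
})

test_that("CIDEr-n averages TF-IDF cosines over references", {
  corpus <- list(list(tokenize("pleural effusion on the right")),
                 list(tokenize("clear lungs no findings")),
                 list(tokenize("cardiomegaly with congestion")))
  cand <- tokenize("pleural effusion on the right")
  expect_equal(cider_n(cand, list(cand), 1, corpus), 1.0)
  expect_equal(cider_n(cand, list(tokenize("zebra giraffe")), 1, corpus), 0)
  # one identical and one disjoint reference -> mean of 1 and 0
  two <- list(cand, tokenize("zebra giraffe"))
  expect_equal(cider_n(cand, two, 1, corpus), 0.5)
  # n-gram order above the candidate length -> 0 by convention
  expect_equal(cider_n(tokenize("short"), list(cand), 4, corpus), 0)
  expect_error(cider_n(cand, list(cand), 1, list()), "nonempty")
  # mean over orders stays in [0, 1]
  cm <- cider_mean(cand, list(cand), corpus)
  expect_gte(cm, 0); expect_lte(cm, 1)
})

test_that("tokenization lowercases and strips punctuation", {
  expect_identical(tokenize("No acute findings."),
                   c("no", "acute", "findings"))
  expect_identical(tokenize("  Mild,   cardiomegaly!  "),
                   c("mild", "cardiomegaly"))
})

test_that("attention IoU and the pointing game score localization", {
  ann <- matrix(0, 4, 4); ann[1:2, 1:2] <- 1
  hm_exact <- matrix(0, 4, 4); hm_exact[1:2, 1:2] <- 1
  expect_equal(attention_iou(hm_exact, ann), 1.0)
  hm_disjoint <- matrix(0, 4, 4); hm_disjoint[3:4, 3:4] <- 1
  expect_equal(attention_iou(hm_disjoint, ann), 0)
  # 2-pixel regions overlapping in 1 pixel -> 1/3
  a2 <- matrix(0, 4, 4); a2[1, 1:2] <- 1
  h2 <- matrix(0, 4, 4); h2[1, 2:3] <- 1
  expect_equal(attention_iou(h2, a2), 1 / 3)
  expect_equal(attention_iou(matrix(0, 4, 4), matrix(0, 4, 4)), 1)  # both empty
  # pointing game: peak inside annotation hits
  peak <- matrix(0, 4, 4); peak[2, 2] <- 1
  expect_true(pointing_game(peak, ann))
  # uniform heatmap: row-major tie-break picks (1, 1)
  excl <- matrix(1, 4, 4); excl[1, 1] <- 0
  expect_false(pointing_game(matrix(0.5, 4, 4), excl))
  expect_true(pointing_game(matrix(0.5, 4, 4), matrix(1, 4, 4)))
  expect_error(pointing_game(peak, matrix(0, 4, 4)), "empty annotation")
})
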