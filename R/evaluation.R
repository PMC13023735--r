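# Classification, fairness, explainability-localization, and report-text
# metrics.

#' Rank-based ROC AUC
#'
#' Probability that a random positive outranks a random negative, with ties
#' counted 0.5 (the Wilcoxon rank statistic). Invariant under strictly
#' monotone transforms of the scores.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (both classes must be present).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels != 0
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold classification metrics
#'
#' Sensitivity, specificity, and F1 from the confusion matrix at a decision
#' threshold (prediction positive when `score >= threshold`).
#'
#' @inheritParams roc_auc
#' @param threshold decision threshold (default 0.5).
#' @return named vector `c(sensitivity, specificity, f1)`.
#' @export
threshold_metrics <- function(scores, labels, threshold = 0.5) {
  pos <- labels != 0
  if (!any(pos) || all(pos)) stop("both classes must be present")
  pred <- scores >= threshold
  tp <- sum(pred & pos); fn <- sum(!pred & pos)
  fp <- sum(pred & !pos); tn <- sum(!pred & !pos)
  c(sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    f1 = if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn))
}

#' Per-node metric record
#'
#' @param node node index.
#' @param auc,f1,sensitivity,specificity metrics in `[0, 1]`.
#' @return one-row data.frame.
#' @export
node_metrics <- function(node, auc, f1, sensitivity, specificity) {
  for (v in c(auc, f1, sensitivity, specificity)) {
    if (v < 0 || v > 1) stop("metrics must lie in [0, 1]")
  }
  data.frame(node = node, auc = auc, f1 = f1,
             sensitivity = sensitivity, specificity = specificity)
}

#' Macro average of per-node metrics
#'
#' Unweighted arithmetic mean of each metric across nodes (the "global
#' average" row of a fairness table), with the companion sample standard
#' deviation; the `report` element rounds to the three decimals used for
#' tabulation. Commutes with permutation of the nodes.
#'
#' @param metrics data.frame with columns `auc`, `f1`, `sensitivity`,
#'   `specificity` (one row per node), e.g. built with [node_metrics()].
#' @return list with `mean`, `sd` (sample sd; 0 for a single node), and
#'   `report` (means rounded to 3 decimals).
#' @export
macro_average <- function(metrics) {
  if (nrow(metrics) == 0) stop("`metrics` must be nonempty")
  cols <- c("auc", "f1", "sensitivity", "specificity")
  mu <- vapply(cols, function(cn) mean(metrics[[cn]]), numeric(1))
  sdv <- vapply(cols, function(cn) {
    if (nrow(metrics) < 2) 0 else stats::sd(metrics[[cn]])
  }, numeric(1))
  list(mean = mu, sd = sdv, report = round(mu, 3))
}

#' Performance retention of a federated model
#'
#' `100 * federated / centralized`, in percent, one-decimal reporting: how
#' much of the centralized reference performance the federated model keeps.
#'
#' @param federated_metric metric of the federated model.
#' @param centralized_metric metric of the centralized reference (> 0).
#' @return retention percentage (one decimal).
#' @export
retention <- function(federated_metric, centralized_metric) {
  if (centralized_metric <= 0) stop("`centralized_metric` must be > 0")
  round(100 * federated_metric / centralized_metric, 1)
}

# ---- report-text metrics ---------------------------------------------------

#' Tokenize report text
#'
#' Lowercases, strips punctuation, and splits on whitespace. The fixed
#' tokenization used by all text metrics in the package.
#' @param text character scalar.
#' @return character vector of tokens.
#' @export
tokenize <- function(text) {
  s <- tolower(text)
  s <- gsub("[[:punct:]]", " ", s)
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  toks[nzchar(toks)]
}

ngrams <- function(tokens, k) {
  if (length(tokens) < k) return(character(0))
  vapply(seq_len(length(tokens) - k + 1), function(i) {
    paste(tokens[i:(i + k - 1)], collapse = " ")
  }, character(1))
}

#' BLEU-n score
#'
#' Geometric mean of the modified k-gram precisions for k = 1..n (clipped
#' per reference), multiplied by the brevity penalty
#' `BP = 1` if the candidate is longer than the closest reference, else
#' `exp(1 - r / c)`. Reference-length ties break toward the shorter
#' reference. Zero if any k-gram precision is zero.
#'
#' @param candidate character vector of candidate tokens.
#' @param references list of reference token vectors.
#' @param n maximum n-gram order (>= 1).
#' @return BLEU-n in `[0, 1]`.
#' @export
bleu_n <- function(candidate, references, n = 4L) {
  if (length(candidate) == 0) stop("empty candidate")
  if (!is.list(references)) references <- list(references)
  stopifnot(n >= 1)
  precisions <- vapply(seq_len(n), function(k) {
    cg <- ngrams(candidate, k)
    if (length(cg) == 0) return(0)
    ct <- table(cg)
    clipped <- 0
    for (g in names(ct)) {
      maxref <- max(vapply(references, function(r) sum(ngrams(r, k) == g), numeric(1)))
      clipped <- clipped + min(ct[[g]], maxref)
    }
    clipped / length(cg)
  }, numeric(1))
  if (any(precisions == 0)) return(0)
  c_len <- length(candidate)
  rl <- vapply(references, length, numeric(1))
  r_len <- rl[order(abs(rl - c_len), rl)][1]
  bp <- if (c_len > r_len) 1 else exp(1 - r_len / c_len)
  bp * exp(mean(log(precisions)))
}

lcs_length <- function(a, b) {
  la <- length(a); lb <- length(b)
  dp <- matrix(0L, la + 1, lb + 1)
  for (i in seq_len(la)) for (j in seq_len(lb)) {
    dp[i + 1, j + 1] <- if (a[i] == b[j]) dp[i, j] + 1L else max(dp[i, j + 1], dp[i + 1, j])
  }
  dp[la + 1, lb + 1]
}

#' ROUGE-L score
#'
#' Longest-common-subsequence F-measure
#' `(1 + beta^2) * R * P / (R + beta^2 * P)` with `R = LCS / |reference|`,
#' `P = LCS / |candidate|`, and `beta = 1.2` by default. Zero when the LCS is
#' empty.
#'
#' @param candidate,reference nonempty token vectors.
#' @param beta recall weight.
#' @return ROUGE-L in `[0, 1]`.
#' @export
rouge_l <- function(candidate, reference, beta = 1.2) {
  if (length(candidate) == 0 || length(reference) == 0) stop("empty input")
  l <- lcs_length(candidate, reference)
  if (l == 0) return(0)
  r <- l / length(reference); p <- l / length(candidate)
  (1 + beta^2) * r * p / (r + beta^2 * p)
}

#' CIDEr-n score
#'
#' Mean over the references of the cosine similarity between TF-IDF-weighted
#' n-gram count vectors of the candidate and each reference. Document
#' frequencies come from `corpus` (a collection of reference sets);
#' `idf = log(N / df)` with unseen n-grams treated as frequency-one
#' (`df = 1`). An n-gram order exceeding the candidate length scores 0 by
#' convention, as does a zero TF-IDF vector.
#'
#' @param candidate candidate token vector.
#' @param references list of reference token vectors for this case.
#' @param n n-gram order.
#' @param corpus nonempty list of reference sets (each a list of token
#'   vectors) supplying document frequencies.
#' @return CIDEr-n score.
#' @export
cider_n <- function(candidate, references, n = 4L, corpus) {
  if (length(corpus) == 0) stop("`corpus` must be nonempty")
  if (!is.list(references)) references <- list(references)
  N <- length(corpus)
  doc_grams <- lapply(corpus, function(refset) {
    if (!is.list(refset)) refset <- list(refset)
    unique(unlist(lapply(refset, ngrams, k = n)))
  })
  idf <- function(g) {
    df <- sum(vapply(doc_grams, function(d) g %in% d, logical(1)))
    log(N / max(df, 1))
  }
  tfidf <- function(tokens) {
    gs <- ngrams(tokens, n)
    if (length(gs) == 0) return(numeric(0))
    tf <- table(gs)
    v <- as.numeric(tf) * vapply(names(tf), idf, numeric(1))
    names(v) <- names(tf)
    v
  }
  gc_ <- tfidf(candidate)
  if (length(gc_) == 0) return(0)
  cosines <- vapply(references, function(r) {
    gr <- tfidf(r)
    if (length(gr) == 0) return(0)
    common <- intersect(names(gc_), names(gr))
    num <- sum(gc_[common] * gr[common])
    den <- sqrt(sum(gc_^2)) * sqrt(sum(gr^2))
    if (den == 0) 0 else num / den
  }, numeric(1))
  mean(cosines)
}

#' Mean CIDEr over orders 1..4
#' @inheritParams cider_n
#' @export
cider_mean <- function(candidate, references, corpus) {
  mean(vapply(1:4, function(k) cider_n(candidate, references, k, corpus),
              numeric(1)))
}

# ---- explainability localization -------------------------------------------

#' Attention IoU between a saliency map and an annotation
#'
#' Binarizes the heatmap at `threshold` and returns intersection over union
#' with the annotation mask; 1 when both are empty.
#'
#' @param heatmap a `heatmap` (from [gradcam()]) or a numeric matrix.
#' @param annotation binary matrix of the same shape.
#' @param threshold heatmap binarization threshold.
#' @return IoU in `[0, 1]`.
#' @export
attention_iou <- function(heatmap, annotation, threshold = 0.5) {
  hv <- if (inherits(heatmap, "heatmap")) heatmap$values else heatmap
  if (!identical(dim(hv), dim(annotation))) stop("shape mismatch")
  hb <- hv >= threshold
  ab <- annotation != 0
  un <- sum(hb | ab)
  if (un == 0) return(1)
  sum(hb & ab) / un
}

#' Pointing-game hit
#'
#' Whether the heatmap's argmax pixel (first in row-major order on ties)
#' falls inside the annotation.
#'
#' @inheritParams attention_iou
#' @return logical hit flag.
#' @export
pointing_game <- function(heatmap, annotation) {
  hv <- if (inherits(heatmap, "heatmap")) heatmap$values else heatmap
  if (!identical(dim(hv), dim(annotation))) stop("shape mismatch")
  if (!any(annotation != 0)) stop("empty annotation")
  mx <- max(hv)
  hits <- which(hv == mx, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  annotation[hits[1, 1], hits[1, 2]] != 0
}
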