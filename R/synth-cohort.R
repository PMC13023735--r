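# Procedural radiograph-like cohort generation.
#
# Cases are rendered from a parametric anatomy: two lung ellipses, a heart
# ellipse, a tracheal band, a diaphragm band, an aortic knob, and the two
# costophrenic angles (A = 6 structure channels). Positive pathology labels
# perturb the image in label-specific, spatially localized ways and write the
# perturbed region into an explainability ground-truth mask. Institutional
# domain shift (gain/bias/noise/resolution) is applied last.

STRUCTURE_NAMES <- c("lungs", "heart", "trachea", "diaphragm",
                     "aortic_knob", "costophrenic_angles")

#' Institution acquisition profile
#'
#' Describes one institution's photometric domain shift and local pathology
#' prevalence. `gain` and `bias` model detector calibration differences,
#' `noise_sd` the acquisition noise, and `resolution_scale` an effective
#' resolution loss (the image is rendered, downscaled by this factor and
#' upscaled back). `label_prior` is the institution's distribution over
#' pathology classes for the primary finding of a case.
#'
#' @param label_prior probability vector over the pathology classes; must sum
#'   to 1 (tolerance 1e-9).
#' @param gain multiplicative intensity factor.
#' @param bias additive intensity offset.
#' @param noise_sd standard deviation of additive Gaussian pixel noise
#'   (must be >= 0).
#' @param resolution_scale effective resolution factor in (0, 1].
#' @param p_normal probability that a case carries no positive finding.
#' @return an object of class `institution_profile`.
#' @export
institution_profile <- function(label_prior, gain = 1, bias = 0,
                                noise_sd = 0.02, resolution_scale = 1,
                                p_normal = 0.35) {
  stopifnot(is.numeric(label_prior), length(label_prior) >= 2)
  if (abs(sum(label_prior) - 1) > 1e-9) {
    stop("`label_prior` must sum to 1 (tolerance 1e-9)")
  }
  if (any(label_prior < 0)) stop("`label_prior` entries must be nonnegative")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (resolution_scale <= 0 || resolution_scale > 1) {
    stop("`resolution_scale` must be in (0, 1]")
  }
  structure(list(gain = gain, bias = bias, noise_sd = noise_sd,
                 resolution_scale = resolution_scale,
                 label_prior = label_prior, p_normal = p_normal),
            class = "institution_profile")
}

# Ellipse indicator on the pixel grid; centers/radii in normalized [0,1]
# coordinates (x = column fraction, y = row fraction), origin top-left.
ellipse_mask <- function(h, w, cx, cy, rx, ry) {
  x <- matrix(seq(0.5 / w, 1 - 0.5 / w, length.out = w), h, w, byrow = TRUE)
  y <- matrix(seq(0.5 / h, 1 - 0.5 / h, length.out = h), h, w)
  ((x - cx) / rx)^2 + ((y - cy) / ry)^2 <= 1
}

band_mask <- function(h, w, x0, x1, y0, y1) {
  x <- matrix(seq(0.5 / w, 1 - 0.5 / w, length.out = w), h, w, byrow = TRUE)
  y <- matrix(seq(0.5 / h, 1 - 0.5 / h, length.out = h), h, w)
  x >= x0 & x <= x1 & y >= y0 & y <= y1
}

# Draw per-case anatomy geometry with mild jitter. All jitter comes from the
# active RNG stream.
sample_geometry <- function() {
  j <- function(x, s = 0.015) x + stats::runif(1, -s, s)
  sc <- function() stats::runif(1, 0.94, 1.06)
  list(
    body = c(cx = j(0.50), cy = j(0.55), rx = 0.42 * sc(), ry = 0.46 * sc()),
    lung_l = c(cx = j(0.32), cy = j(0.44), rx = 0.155 * sc(), ry = 0.25 * sc()),
    lung_r = c(cx = j(0.68), cy = j(0.44), rx = 0.155 * sc(), ry = 0.25 * sc()),
    heart = c(cx = j(0.54), cy = j(0.60), rx = 0.145 * sc(), ry = 0.125 * sc()),
    trachea = c(x0 = 0.48, x1 = 0.52, y0 = j(0.10), y1 = j(0.38)),
    diaphragm = c(x0 = 0.12, x1 = 0.88, y0 = j(0.73), y1 = j(0.80)),
    aortic_knob = c(cx = j(0.585, 0.01), cy = j(0.385, 0.01),
                    rx = 0.045 * sc(), ry = 0.04 * sc()),
    cp_l = c(cx = 0.19, cy = 0.68, rx = 0.055, ry = 0.05),
    cp_r = c(cx = 0.81, cy = 0.68, rx = 0.055, ry = 0.05)
  )
}

# Render image + structure masks from geometry. `heart_scale` > 1 enlarges the
# heart ellipse (cardiomegaly-like finding), affecting both image and mask.
render_anatomy <- function(geom, h, w, heart_scale = 1) {
  em <- function(p, s = 1) ellipse_mask(h, w, p["cx"], p["cy"], p["rx"] * s, p["ry"] * s)
  bm <- function(p) band_mask(h, w, p["x0"], p["x1"], p["y0"], p["y1"])
  body <- em(geom$body)
  lung_l <- em(geom$lung_l); lung_r <- em(geom$lung_r)
  lungs <- lung_l | lung_r
  heart <- em(geom$heart, heart_scale)
  trachea <- bm(geom$trachea) & body
  diaphragm <- bm(geom$diaphragm) & body
  knob <- em(geom$aortic_knob)
  cp <- (em(geom$cp_l) | em(geom$cp_r)) & body

  img <- matrix(0.12, h, w)
  img[body] <- 0.55
  img[lungs] <- 0.28
  img[diaphragm] <- 0.65
  img[heart] <- 0.78
  img[trachea] <- 0.70
  img[knob] <- 0.80
  img[cp & !diaphragm] <- 0.40

  masks <- array(0, dim = c(h, w, 6L),
                 dimnames = list(NULL, NULL, STRUCTURE_NAMES))
  masks[, , 1] <- lungs * 1
  masks[, , 2] <- heart * 1
  masks[, , 3] <- trachea * 1
  masks[, , 4] <- diaphragm * 1
  masks[, , 5] <- knob * 1
  masks[, , 6] <- cp * 1
  list(image = img, masks = masks, lung_l = lung_l, lung_r = lung_r,
       geom = geom)
}

# Label-specific localized perturbations. Effect type cycles when m_classes
# exceeds the five base pathologies. Returns modified image, possibly modified
# masks (cardiomegaly), and the per-label region.
apply_pathology <- function(render, label_idx, h, w) {
  base_type <- (label_idx - 1L) %% 5L + 1L
  geom <- render$geom
  img <- render$image
  region <- matrix(FALSE, h, w)
  if (base_type == 1L) {           # focal bright opacity inside one lung
    side <- if (stats::runif(1) < 0.5) geom$lung_l else geom$lung_r
    cx <- side["cx"] + stats::runif(1, -0.5, 0.5) * side["rx"]
    cy <- side["cy"] + stats::runif(1, -0.5, 0.5) * side["ry"]
    region <- ellipse_mask(h, w, cx, cy, 0.07, 0.06)
    img[region] <- clamp(img[region] + 0.35, 0, 1)
  } else if (base_type == 2L) {    # enlarged heart silhouette
    enlarged <- ellipse_mask(h, w, geom$heart["cx"], geom$heart["cy"],
                             geom$heart["rx"] * 1.35, geom$heart["ry"] * 1.35)
    img[enlarged] <- 0.78
    render$masks[, , 2] <- enlarged * 1
    region <- enlarged
  } else if (base_type == 3L) {    # basal effusion-like bright layer
    side <- if (stats::runif(1) < 0.5) render$lung_l else render$lung_r
    y <- matrix(seq(0.5 / h, 1 - 0.5 / h, length.out = h), h, w)
    region <- side & (y > stats::runif(1, 0.52, 0.58))
    img[region] <- clamp(img[region] + 0.32, 0, 1)
  } else if (base_type == 4L) {    # apical lucent band
    pick_l <- stats::runif(1) < 0.5
    side <- if (pick_l) render$lung_l else render$lung_r
    sg <- if (pick_l) geom$lung_l else geom$lung_r
    y <- matrix(seq(0.5 / h, 1 - 0.5 / h, length.out = h), h, w)
    region <- side & (y < sg["cy"] - 0.55 * sg["ry"])
    img[region] <- clamp(img[region] - 0.22, 0, 1)
  } else {                         # small bright nodule
    side <- if (stats::runif(1) < 0.5) geom$lung_l else geom$lung_r
    cx <- side["cx"] + stats::runif(1, -0.6, 0.6) * side["rx"]
    cy <- side["cy"] + stats::runif(1, -0.6, 0.6) * side["ry"]
    region <- ellipse_mask(h, w, cx, cy, 0.028, 0.026)
    img[region] <- clamp(img[region] + 0.4, 0, 1)
  }
  render$image <- img
  render$region <- region
  render
}

#' Generate one synthetic radiograph-like case
#'
#' Renders a procedural grayscale "radiograph" with per-structure binary masks,
#' a multi-label pathology vector, and an explainability ground-truth mask
#' covering the regions perturbed by positive findings. The institution's
#' photometric shift (gain, bias, noise, resolution) is applied last and the
#' image clipped to `[0, 1]`. Output is a pure function of `(arguments, seed)`.
#'
#' @param profile an [institution_profile()].
#' @param m_classes number of pathology classes (>= 2).
#' @param size integer `c(H, W)`, both >= 32.
#' @param seed integer seed for this case.
#' @param labels optional binary vector of length `m_classes` overriding label
#'   drawing (used e.g. to render matched positive/negative pairs).
#' @param institution node index recorded on the case.
#' @param case_id identifier; defaults to one derived from the seed.
#' @param return_template if `TRUE`, attach the unperturbed anatomy image
#'   (before pathology and institutional effects) as attribute `"template"`.
#' @return an object of class `synthetic_case`: list with `image` (H x W in
#'   `[0,1]`), `masks` (H x W x 6 binary), `labels`, `xai_mask`, `case_id`,
#'   `institution`, `primary` (index of the primary finding, 0 if none).
#' @export
generate_case <- function(profile, m_classes, size = c(64L, 64L), seed = 1L,
                          labels = NULL, institution = 1L,
                          case_id = NULL, return_template = FALSE) {
  stopifnot(inherits(profile, "institution_profile"))
  if (length(size) != 2 || any(size < 32)) stop("`size` must be c(H, W) with H, W >= 32")
  if (m_classes < 2) stop("`m_classes` must be >= 2")
  if (length(profile$label_prior) != m_classes) {
    stop("`label_prior` length must equal `m_classes`")
  }
  h <- as.integer(size[1]); w <- as.integer(size[2])
  seeds <- derive_seeds(seed, 4L)

  render <- with_seed(seeds[1], render_anatomy(sample_geometry(), h, w))
  if (isTRUE(return_template)) template <- render$image

  primary <- 0L
  if (is.null(labels)) {
    drawn <- with_seed(seeds[2], {
      if (stats::runif(1) < profile$p_normal) {
        list(lab = integer(m_classes), primary = 0L)
      } else {
        pr <- sample.int(m_classes, 1, prob = profile$label_prior)
        # co-occurring secondary findings follow the prevalence profile, so
        # rare classes stay rare (severe class imbalance is reachable)
        co <- pmin(0.3 * profile$label_prior, 0.5)
        lab <- as.integer(stats::runif(m_classes) < co)
        lab[pr] <- 1L
        list(lab = lab, primary = pr)
      }
    })
    labels <- drawn$lab
    primary <- drawn$primary
  } else {
    if (length(labels) != m_classes) stop("`labels` must have length `m_classes`")
    labels <- as.integer(labels != 0)
    primary <- if (any(labels == 1L)) which(labels == 1L)[1] else 0L
  }

  xai <- matrix(0, h, w)
  render <- with_seed(seeds[3], {
    for (m in which(labels == 1L)) {
      render <- apply_pathology(render, m, h, w)
      xai[render$region] <- 1
    }
    render$xai <- xai
    render
  })
  xai <- render$xai

  img <- with_seed(seeds[4], {
    im <- render$image
    if (profile$resolution_scale < 1) {
      hs <- max(8L, round(h * profile$resolution_scale))
      ws <- max(8L, round(w * profile$resolution_scale))
      im <- resize_bilinear(resize_bilinear(im, hs, ws), h, w)
    }
    im <- profile$gain * im + profile$bias
    if (profile$noise_sd > 0) {
      im <- im + matrix(stats::rnorm(h * w, 0, profile$noise_sd), h, w)
    }
    clamp(im, 0, 1)
  })

  out <- structure(
    list(image = img, masks = render$masks, labels = labels,
         xai_mask = xai, case_id = if (is.null(case_id)) sprintf("case_%d", seed) else case_id,
         institution = institution, primary = primary),
    class = "synthetic_case")
  if (isTRUE(return_template)) attr(out, "template") <- template
  out
}

#' Build an anatomical prior atlas from cases
#'
#' The atlas entry `P[i, j, a]` is the fraction of source cases whose mask
#' channel `a` is 1 at pixel `(i, j)` — an empirical spatial probability map of
#' where each anatomical structure is expected. It drives the anatomical-prior
#' regularization term of the composite segmentation loss.
#'
#' @param cases nonempty list of `synthetic_case` objects with identical
#'   dimensions.
#' @return object of class `prior_atlas`: list with `P` (H x W x A in
#'   `[0,1]`) and `n_source_cases`.
#' @export
build_prior_atlas <- function(cases) {
  if (length(cases) == 0) stop("`cases` must be a nonempty list")
  dims <- dim(cases[[1]]$masks)
  P <- array(0, dim = dims, dimnames = dimnames(cases[[1]]$masks))
  for (cs in cases) {
    if (!identical(dim(cs$masks), dims)) stop("inconsistent mask shapes across cases")
    P <- P + cs$masks
  }
  structure(list(P = P / length(cases), n_source_cases = length(cases)),
            class = "prior_atlas")
}

#' Exact split counts for train/validation/test fractions
#'
#' Computes the integer split sizes used throughout the partitioner:
#' `round(f_train * n)` training cases, `round(f_val * n)` validation cases,
#' and the remainder for testing.
#'
#' @param n number of cases.
#' @param fractions positive numeric triple summing to 1.
#' @return named integer vector `c(train, val, test)`.
#' @export
split_counts <- function(n, fractions = c(0.7, 0.1, 0.2)) {
  stopifnot(length(fractions) == 3, all(fractions > 0))
  if (abs(sum(fractions) - 1) > 1e-9) stop("`fractions` must sum to 1")
  n_train <- as.integer(round(fractions[1] * n))
  n_val <- as.integer(round(fractions[2] * n))
  c(train = n_train, val = n_val, test = as.integer(n) - n_train - n_val)
}

#' Partition specification for heterogeneous nodes
#'
#' @param K number of institutional nodes (>= 2 for heterogeneity studies;
#'   K = 1 is allowed and assigns everything to a single node).
#' @param dirichlet_beta concentration of the symmetric Dirichlet controlling
#'   label skew across nodes; small values give strongly non-IID nodes.
#' @param n_cases expected cohort size (validated against the cases supplied).
#' @param seed partition seed.
#' @param split train/val/test fractions.
#' @return object of class `partition_spec`.
#' @export
partition_spec <- function(K, dirichlet_beta = 0.5, n_cases = NULL, seed = 1L,
                           split = c(0.7, 0.1, 0.2)) {
  stopifnot(K >= 1, dirichlet_beta > 0)
  if (abs(sum(split) - 1) > 1e-9 || any(split <= 0)) {
    stop("split fractions must be positive and sum to 1")
  }
  structure(list(K = as.integer(K), dirichlet_beta = dirichlet_beta,
                 n_cases = n_cases, seed = seed, split = split),
            class = "partition_spec")
}

# Symmetric Dirichlet draw via normalized gammas.
rdirichlet1 <- function(k, beta) {
  g <- stats::rgamma(k, shape = beta, rate = 1)
  if (sum(g) == 0) g <- rep(1, k)
  g / sum(g)
}

# Greedy stratified split with exact global counts: cases are walked in
# stratum order (random within stratum) and each is assigned to the split with
# the largest remaining relative deficit, so per-stratum proportions track the
# target fractions while totals hit split_counts() exactly.
assign_splits <- function(primary_labels, fractions) {
  n <- length(primary_labels)
  counts <- split_counts(n, fractions)
  target <- as.numeric(counts)
  filled <- c(0, 0, 0)
  ord <- order(primary_labels, stats::runif(n))
  out <- character(n)
  names_s <- c("train", "val", "test")
  for (i in ord) {
    deficit <- ifelse(target > 0, (target - filled) / target, -Inf)
    s <- which.max(deficit)
    out[i] <- names_s[s]
    filled[s] <- filled[s] + 1
  }
  factor(out, levels = names_s)
}

#' Partition a cohort into heterogeneous institutional nodes
#'
#' Induces label skew by drawing, for every node, class proportions from a
#' symmetric Dirichlet with concentration `dirichlet_beta`; each case is then
#' assigned to a node with probability proportional to the nodes' weights for
#' its primary finding. Within each node, cases are split into
#' train/validation/test with per-label stratification and exact
#' [split_counts()] totals. Every case is assigned to exactly one node and one
#' split.
#'
#' @param cases list of `synthetic_case` objects.
#' @param spec a [partition_spec()].
#' @return list of `K` node datasets, each a list with `cases`, `split`
#'   (factor train/val/test per case), and `institution`.
#' @export
partition_cohort <- function(cases, spec) {
  stopifnot(inherits(spec, "partition_spec"))
  n <- length(cases)
  if (!is.null(spec$n_cases) && spec$n_cases != n) {
    stop("`spec$n_cases` does not match the number of cases supplied")
  }
  if (spec$K > n) stop("more nodes than cases (K > n_cases)")
  prim <- vapply(cases, function(cs) cs$primary, integer(1))
  classes <- sort(unique(prim))
  with_seed(spec$seed, {
    q <- t(vapply(seq_len(spec$K), function(k) {
      rdirichlet1(length(classes), spec$dirichlet_beta)
    }, numeric(length(classes))))  # K x n_classes
    if (spec$K == 1) q <- matrix(1, 1, length(classes))
    node <- integer(n)
    for (ci in seq_along(classes)) {
      idx <- which(prim == classes[ci])
      p <- q[, ci] / sum(q[, ci])
      node[idx] <- sample.int(spec$K, length(idx), replace = TRUE, prob = p)
    }
    # guarantee every node is nonempty
    for (k in seq_len(spec$K)) {
      if (!any(node == k)) {
        donor <- which.max(tabulate(node, spec$K))
        node[which(node == donor)[1]] <- k
      }
    }
    lapply(seq_len(spec$K), function(k) {
      idx <- which(node == k)
      ncases <- lapply(cases[idx], function(cs) { cs$institution <- k; cs })
      list(cases = ncases,
           split = assign_splits(prim[idx], spec$split),
           institution = k)
    })
  })
}

#' Inverse-class-frequency oversampling weights
#'
#' Computes per-class weights `n / count_m`, with absent classes capped at ten
#' times the largest observed weight (no infinities), then normalizes the
#' vector to mean 1.
#'
#' @param labels binary matrix `n x M`.
#' @return numeric weight vector of length `M` with mean 1.
#' @export
imbalance_weights <- function(labels) {
  if (is.null(dim(labels)) || nrow(labels) == 0) stop("`labels` must be a nonempty matrix")
  n <- nrow(labels)
  counts <- colSums(labels != 0)
  w <- ifelse(counts > 0, n / counts, NA_real_)
  if (all(is.na(w))) stop("no class is present in `labels`")
  cap <- 10 * max(w, na.rm = TRUE)
  w[is.na(w)] <- cap
  w / mean(w)
}

#' Maximum class imbalance ratio of a label matrix
#'
#' Ratio of the most to the least frequent class, over classes with at least
#' one positive.
#' @param labels binary matrix `n x M`.
#' @return single number (>= 1), `Inf` if only one class is present.
#' @export
max_imbalance <- function(labels) {
  counts <- colSums(labels != 0)
  counts <- counts[counts > 0]
  if (length(counts) < 2) return(Inf)
  max(counts) / min(counts)
}

# ---- training-time augmentation (flips, small rotations, photometric jitter,
# occasional blur); applied to images only, never at validation/test time.

rotate_image <- function(img, angle_deg, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  th <- angle_deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  # inverse map
  sr <- cy + cos(th) * (rr - cy) + sin(th) * (cc - cx)
  sc <- cx - sin(th) * (rr - cy) + cos(th) * (cc - cx)
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  getpix <- function(r, c) {
    ok <- r >= 1 & r <= h & c >= 1 & c <= w
    v <- matrix(fill, h, w)
    v[ok] <- img[cbind(r[ok], c[ok])]
    v
  }
  getpix(r0, c0) * (1 - fr) * (1 - fc) + getpix(r0 + 1, c0) * fr * (1 - fc) +
    getpix(r0, c0 + 1) * (1 - fr) * fc + getpix(r0 + 1, c0 + 1) * fr * fc
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(2.5 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  pad <- function(m, side) m  # edge handled by renormalization below
  conv1 <- function(m, along_rows) {
    h <- nrow(m); w <- ncol(m)
    out <- matrix(0, h, w); wt <- matrix(0, h, w)
    for (o in seq(-r, r)) {
      kv <- k[o + r + 1]
      if (along_rows) {
        src <- (1:h) + o
        ok <- src >= 1 & src <= h
        out[ok, ] <- out[ok, ] + kv * m[src[ok], , drop = FALSE]
        wt[ok, ] <- wt[ok, ] + kv
      } else {
        src <- (1:w) + o
        ok <- src >= 1 & src <= w
        out[, ok] <- out[, ok] + kv * m[, src[ok], drop = FALSE]
        wt[, ok] <- wt[, ok] + kv
      }
    }
    out / wt
  }
  conv1(conv1(img, TRUE), FALSE)
}

#' Stochastic training-time augmentation
#'
#' Random horizontal flip (p = 0.5), rotation within +/-10 degrees, brightness
#' and contrast jitter with factors in `[0.8, 1.2]`, and Gaussian blur with
#' sigma in `[0.1, 2]` applied with probability 0.2. Intended for training
#' images only.
#'
#' @param image numeric matrix in `[0,1]`.
#' @return augmented image, clipped to `[0,1]`.
#' @export
augment_image <- function(image) {
  img <- image
  if (stats::runif(1) < 0.5) img <- img[, ncol(img):1]
  img <- rotate_image(img, stats::runif(1, -10, 10))
  bf <- stats::runif(1, 0.8, 1.2)           # brightness factor
  cf <- stats::runif(1, 0.8, 1.2)           # contrast factor
  m <- mean(img)
  img <- (img - m) * cf + m * bf
  if (stats::runif(1) < 0.2) img <- gaussian_blur(img, stats::runif(1, 0.1, 2))
  clamp(img, 0, 1)
}

#' Map an uncertain-label code to the training label space
#'
#' The label schema admits an "uncertain" code (-1); at training time it is
#' mapped to negative (the U-Zeros policy for uncertainty labels).
#' @param labels integer vector/matrix with values in `{-1, 0, 1}`.
#' @return binary labels with uncertain entries set to 0.
#' @export
resolve_uncertain_labels <- function(labels) {
  labels[labels == -1] <- 0L
  labels
}

#' Simulate a multi-institutional cohort
#'
#' High-level generator: builds `K` institution profiles with photometric
#' domain shift and label priors drawn from a symmetric Dirichlet
#' (concentration `dirichlet_beta`, small values = strong label skew), renders
#' each node's cases, and splits them train/validation/test with per-label
#' stratification.
#'
#' @param n_cases total number of cases (>= K).
#' @param K number of institutional nodes.
#' @param m_classes number of pathology classes.
#' @param size image size `c(H, W)`.
#' @param dirichlet_beta Dirichlet concentration for per-node label priors.
#' @param split train/val/test fractions.
#' @param seed master seed.
#' @param heterogeneity one of `"photometric"` (default: gain/bias/noise/
#'   resolution differ across nodes) or `"none"`.
#' @return list of `K` node datasets (as in [partition_cohort()]), with the
#'   node profiles attached as attribute `"profiles"`.
#' @export
simulate_cohort <- function(n_cases, K = 4L, m_classes = 5L,
                            size = c(64L, 64L), dirichlet_beta = 0.5,
                            split = c(0.7, 0.1, 0.2), seed = 1L,
                            heterogeneity = c("photometric", "none")) {
  heterogeneity <- match.arg(heterogeneity)
  stopifnot(n_cases >= K)
  seeds <- derive_seeds(seed, 3L)
  profiles <- with_seed(seeds[1], {
    lapply(seq_len(K), function(k) {
      prior <- rdirichlet1(m_classes, dirichlet_beta)
      if (heterogeneity == "photometric") {
        institution_profile(prior,
                            gain = stats::runif(1, 0.85, 1.15),
                            bias = stats::runif(1, -0.06, 0.06),
                            noise_sd = stats::runif(1, 0.01, 0.05),
                            resolution_scale = stats::runif(1, 0.8, 1))
      } else {
        institution_profile(prior, gain = 1, bias = 0, noise_sd = 0.02,
                            resolution_scale = 1)
      }
    })
  })
  per_node <- rep(n_cases %/% K, K)
  if (n_cases %% K > 0) per_node[seq_len(n_cases %% K)] <- per_node[seq_len(n_cases %% K)] + 1L
  case_seeds <- derive_seeds(seeds[2], n_cases)
  split_seeds <- derive_seeds(seeds[3], K)
  idx0 <- 0L
  nodes <- lapply(seq_len(K), function(k) {
    ids <- idx0 + seq_len(per_node[k])
    idx0 <<- idx0 + per_node[k]
    cases <- lapply(ids, function(i) {
      generate_case(profiles[[k]], m_classes, size, seed = case_seeds[i],
                    institution = k, case_id = sprintf("case_%05d", i))
    })
    prim <- vapply(cases, function(cs) cs$primary, integer(1))
    spl <- with_seed(split_seeds[k], assign_splits(prim, split))
    list(cases = cases, split = spl, institution = k)
  })
  attr(nodes, "profiles") <- profiles
  nodes
}

#' Per-node cohort summary
#'
#' @param nodes list of node datasets.
#' @return data.frame with one row per node: case count, split counts, class
#'   frequencies, and maximum class imbalance.
#' @export
cohort_summary <- function(nodes) {
  rows <- lapply(nodes, function(nd) {
    labs <- do.call(rbind, lapply(nd$cases, function(cs) cs$labels))
    freq <- colMeans(labs)
    data.frame(node = nd$institution, n = length(nd$cases),
               n_train = sum(nd$split == "train"),
               n_val = sum(nd$split == "val"),
               n_test = sum(nd$split == "test"),
               max_imbalance = max_imbalance(labs),
               t(matrix(freq, dimnames = list(paste0("freq_", seq_along(freq)), NULL))))
  })
  do.call(rbind, rows)
}
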