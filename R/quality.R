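# ---------------------------------------------------------------------------
# Referenceless image quality: ENL, CNR, BRISQUE natural-scene-statistics
# features, score summaries and checkpoint selection.
# ---------------------------------------------------------------------------

get_pixels <- function(image) {
  if (inherits(image, "bscan")) image$pixels
  else if (is.matrix(image)) image
  else stop("expected a bscan or a numeric matrix")
}

# rect = (row, col, height, width), 1-based
rect_values <- function(px, r) {
  r <- as.integer(r)
  if (length(r) != 4L || r[3L] < 1L || r[4L] < 1L ||
      r[1L] < 1L || r[2L] < 1L ||
      r[1L] + r[3L] - 1L > nrow(px) || r[2L] + r[4L] - 1L > ncol(px))
    stop("rectangle does not lie inside the image")
  as.numeric(px[r[1L]:(r[1L] + r[3L] - 1L), r[2L]:(r[2L] + r[4L] - 1L)])
}

rects_overlap <- function(a, b) {
  !(a[1L] + a[3L] - 1L < b[1L] || b[1L] + b[3L] - 1L < a[1L] ||
    a[2L] + a[4L] - 1L < b[2L] || b[2L] + b[4L] - 1L < a[2L])
}

#' Region annotation for quality metrics
#'
#' Pairs a homogeneous tissue region of interest with a tissue-free
#' background region on one image. Rectangles are `(row, col, height,
#' width)`, 1-based, must not overlap.
#'
#' @param roi_rect,bg_rect integer length-4 rectangles.
#' @param image_id identifier of the annotated image.
#' @return an object of class `roi_annotation`.
#' @export
roi_annotation <- function(roi_rect, bg_rect, image_id = "") {
  if (rects_overlap(roi_rect, bg_rect))
    stop("ROI and background rectangles overlap")
  structure(list(roi_rect = as.integer(roi_rect),
                 bg_rect = as.integer(bg_rect), image_id = image_id),
            class = "roi_annotation")
}

#' Equivalent number of looks
#'
#' ENL = (background mean)^2 / (background variance), measured over a
#' tissue-free homogeneous region. On fully developed speckle averaged over
#' L looks this estimates L. The variance uses denominator n - 1. Invariant
#' to positive rescaling of intensities.
#'
#' @param image a [bscan()] or numeric matrix.
#' @param bg background rectangle `(row, col, height, width)`.
#' @return scalar ENL.
#' @export
enl <- function(image, bg) {
  v <- rect_values(get_pixels(image), bg)
  if (length(v) < 2L) stop("background region must contain >= 2 pixels")
  s2 <- stats::var(v)
  if (s2 == 0) stop("undefined ENL: background region has zero variance")
  mean(v)^2 / s2
}

#' Contrast-to-noise ratio
#'
#' CNR = (ROI mean - background mean) / background standard deviation
#' (denominator n - 1). Invariant to positive rescaling and to constant
#' intensity offsets.
#'
#' @param image a [bscan()] or numeric matrix.
#' @param roi,bg rectangles `(row, col, height, width)`.
#' @return scalar CNR.
#' @export
cnr <- function(image, roi, bg) {
  px <- get_pixels(image)
  vr <- rect_values(px, roi)
  vb <- rect_values(px, bg)
  s <- stats::sd(vb)
  if (is.na(s) || s == 0)
    stop("undefined CNR: background region has zero standard deviation")
  (mean(vr) - mean(vb)) / s
}

# -- BRISQUE features --------------------------------------------------------

# cached grids for the generalised-Gaussian shape lookups
ggd_cache <- new.env(parent = emptyenv())

ggd_grids <- function() {
  if (is.null(ggd_cache$gam)) {
    gam <- seq(0.2, 10, by = 0.001)
    ggd_cache$gam <- gam
    # GGD: rho(gamma) = Gamma(1/g) Gamma(3/g) / Gamma(2/g)^2
    ggd_cache$r_ggd <- exp(lgamma(1 / gam) + lgamma(3 / gam) -
                             2 * lgamma(2 / gam))
    # AGGD: r(alpha) = Gamma(2/a)^2 / (Gamma(1/a) Gamma(3/a))
    ggd_cache$r_aggd <- exp(2 * lgamma(2 / gam) - lgamma(1 / gam) -
                              lgamma(3 / gam))
  }
  ggd_cache
}

fit_ggd <- function(x) {
  g <- ggd_grids()
  sigma_sq <- mean(x^2)
  e_abs <- mean(abs(x))
  rho <- sigma_sq / e_abs^2
  alpha <- g$gam[which.min(abs(g$r_ggd - rho))]
  c(alpha, sigma_sq)
}

fit_aggd <- function(x) {
  g <- ggd_grids()
  left <- x[x < 0]; right <- x[x >= 0]
  sig_l <- sqrt(mean(left^2)); sig_r <- sqrt(mean(right^2))
  gh <- sig_l / sig_r
  rhat <- mean(abs(x))^2 / mean(x^2)
  rhatnorm <- rhat * (gh^3 + 1) * (gh + 1) / (gh^2 + 1)^2
  alpha <- g$gam[which.min((g$r_aggd - rhatnorm)^2)]
  eta <- (sig_r - sig_l) * exp(lgamma(2 / alpha) - lgamma(1 / alpha))
  c(alpha, eta, sig_l^2, sig_r^2)
}

gaussian_kernel7 <- function() {
  s <- 7 / 6
  g <- outer(-3:3, -3:3, function(i, j) exp(-(i^2 + j^2) / (2 * s^2)))
  g / sum(g)
}

blur7 <- function(m) {
  k <- matrix(gaussian_kernel7(), 49, 1)
  conv2d_forward(array(m, c(dim(m), 1L)), k, 0, 7L, 1L, 3L, TRUE)$out[, , 1L]
}

# mean-subtracted contrast-normalised coefficients on a 0..255 scale
mscn_coefficients <- function(px) {
  m <- px * 255
  mu <- blur7(m)
  sigma <- sqrt(pmax(blur7(m^2) - mu^2, 0))
  (m - mu) / (sigma + 1)
}

scale_half <- function(px) {
  out <- EBImage::resize(px, w = max(1L, floor(nrow(px) / 2)),
                         h = max(1L, floor(ncol(px) / 2)))
  matrix(as.numeric(out), nrow = max(1L, floor(nrow(px) / 2)))
}

#' BRISQUE natural-scene-statistics features
#'
#' The 36-dimensional feature vector of the blind/referenceless spatial
#' quality evaluator: mean-subtracted contrast-normalised (MSCN)
#' coefficients are fitted with a generalised Gaussian (2 features), and
#' the four orientation products of neighbouring MSCN coefficients
#' (horizontal, vertical, both diagonals) with asymmetric generalised
#' Gaussians (4 features each), at the native scale and once more after
#' halving the resolution: (2 + 16) x 2 = 36 features.
#'
#' @param image a [bscan()] or numeric matrix (at least 32 x 32).
#' @return numeric vector of length 36.
#' @export
brisque_features <- function(image) {
  px <- get_pixels(image)
  if (nrow(px) < 32L || ncol(px) < 32L)
    stop("BRISQUE requires an image of at least 32 x 32")
  if (max(px) - min(px) < 1e-12)
    stop("undefined BRISQUE score: constant image degenerates the ",
         "contrast normalisation")
  feats <- c()
  for (scale in 1:2) {
    z <- mscn_coefficients(px)
    H <- nrow(z); W <- ncol(z)
    pairs <- list(z[, -W] * z[, -1L],                  # horizontal
                  z[-H, ] * z[-1L, ],                  # vertical
                  z[-H, -W] * z[-1L, -1L],             # main diagonal
                  z[-1L, -W] * z[-H, -1L])             # secondary diagonal
    feats <- c(feats, fit_ggd(as.numeric(z)),
               unlist(lapply(pairs, function(p) fit_aggd(as.numeric(p)))))
    px <- scale_half(px)
  }
  feats
}

#' Fit the default BRISQUE scorer from reference and distorted image sets
#'
#' The canonical BRISQUE regression stage is a support-vector model trained
#' on an externally rated corpus of pristine and distorted images; that
#' corpus cannot ship with a package, so the pluggable default scorer is
#' trained the same way on two user-supplied anchor sets: a Fisher
#' discriminant axis through the 36 natural-scene-statistics features,
#' pointing from the `reference` (high-quality) set towards the
#' `distorted` (low-quality) set. Scores are standardised so the reference
#' set sits near 0 with unit spread; higher scores mean lower perceptual
#' quality, matching the BRISQUE convention.
#'
#' @param reference list of high-quality anchor [bscan()] images.
#' @param distorted list of low-quality anchor [bscan()] images.
#' @param ridge regularisation added to the pooled covariance diagonal.
#' @return an object of class `brisque_scorer` (callable via
#'   [brisque_score()]).
#' @export
fit_brisque_scorer <- function(reference, distorted, ridge = 1e-6) {
  if (length(reference) < 2L || length(distorted) < 2L)
    stop("need >= 2 images in each anchor set")
  Fr <- t(vapply(reference, brisque_features, numeric(36L)))
  Fd <- t(vapply(distorted, brisque_features, numeric(36L)))
  S <- (stats::cov(Fr) + stats::cov(Fd)) / 2
  S <- S + diag(ridge + 1e-10 * mean(diag(S)), 36L)
  mu_r <- colMeans(Fr)
  w <- solve(S, colMeans(Fd) - mu_r)
  scale <- stats::sd(Fr %*% w)
  if (!is.finite(scale) || scale == 0) scale <- 1
  structure(list(mu = mu_r, w = as.numeric(w), scale = scale,
                 n = nrow(Fr) + nrow(Fd)),
            class = "brisque_scorer")
}

#' BRISQUE score of an image
#'
#' Extracts the 36 natural-scene-statistics features
#' ([brisque_features()]) and maps them to a scalar with a pluggable
#' scorer: either a `brisque_scorer` from [fit_brisque_scorer()] or any
#' function taking the feature vector. Lower scores indicate higher
#' perceptual quality (given a scorer fitted on high-quality references).
#'
#' @param image a [bscan()] or numeric matrix.
#' @param scorer a `brisque_scorer` or a `function(features) -> numeric`.
#' @return scalar score.
#' @export
brisque_score <- function(image, scorer) {
  if (missing(scorer) || is.null(scorer))
    stop("no scorer configured: fit one with fit_brisque_scorer() or ",
         "supply a scoring function")
  f <- brisque_features(image)
  if (inherits(scorer, "brisque_scorer"))
    return(sum((f - scorer$mu) * scorer$w) / scorer$scale)
  if (is.function(scorer)) return(scorer(f))
  stop("scorer must be a brisque_scorer or a function")
}

# -- checkpoint evaluation and selection -------------------------------------

#' Score the images generated by every checkpoint
#'
#' Converts every image with every generator checkpoint and scores each
#' output with `metric`, returning one row per checkpoint with the mean and
#' standard deviation of the scores (the data behind a score-versus-epoch
#' training curve).
#'
#' @param checkpoints a data.frame with columns `epoch` and `path` (as
#'   returned by [cut_train()]) or a list of `cut_generator` objects.
#' @param images non-empty list of [bscan()] images to convert.
#' @param metric `function(bscan) -> numeric` applied to each converted
#'   image.
#' @return data.frame with columns epoch, mean, sd, n.
#' @export
evaluate_checkpoints <- function(checkpoints, images, metric) {
  if (length(images) == 0L) stop("no images to evaluate")
  gens <- if (is.data.frame(checkpoints)) {
    if (nrow(checkpoints) == 0L) stop("no checkpoints to evaluate")
    lapply(checkpoints$path, load_checkpoint)
  } else {
    if (length(checkpoints) == 0L) stop("no checkpoints to evaluate")
    checkpoints
  }
  rows <- lapply(gens, function(gen) {
    scores <- vapply(images, function(im) metric(convert_bscan(gen, im)),
                     numeric(1))
    data.frame(epoch = gen$epoch, mean = mean(scores),
               sd = stats::sd(scores), n = length(scores))
  })
  do.call(rbind, rows)
}

#' Select a checkpoint from a score table
#'
#' Picks the epoch whose mean score is minimal (`mode = "lowest"`, used for
#' the model that generates the clean Seven-Lines style) or maximal
#' (`mode = "highest"`, for the Macular-Cube-generating model). Ties break
#' to the earliest epoch.
#'
#' @param score_table data.frame with columns `epoch` and `mean` (from
#'   [evaluate_checkpoints()]).
#' @param mode `"lowest"` or `"highest"`.
#' @return the selected epoch (integer).
#' @export
select_checkpoint <- function(score_table, mode = c("lowest", "highest")) {
  mode <- match.arg(mode)
  if (is.null(score_table) || nrow(score_table) == 0L)
    stop("empty score table")
  tab <- score_table[order(score_table$epoch), , drop = FALSE]
  i <- if (mode == "lowest") which.min(tab$mean) else which.max(tab$mean)
  tab$epoch[i]
}

#' Summarise a score distribution
#'
#' Sample mean, sample standard deviation and adjusted Fisher-Pearson
#' skewness (`G1 = g1 * sqrt(n (n-1)) / (n - 2)`); a constant sample
#' reports skewness 0 by convention.
#'
#' @param scores numeric vector of length >= 2.
#' @return named list with `mean`, `sd`, `skewness`, `n`.
#' @export
summarize_scores <- function(scores) {
  n <- length(scores)
  if (n < 2L) stop("need at least 2 scores")
  m <- mean(scores)
  s <- stats::sd(scores)
  skew <- if (s == 0 || n < 3L) 0 else {
    m2 <- mean((scores - m)^2)
    m3 <- mean((scores - m)^3)
    g1 <- m3 / m2^1.5
    g1 * sqrt(n * (n - 1)) / (n - 2)
  }
  list(mean = m, sd = s, skewness = skew, n = n)
}

#' Plot score distributions of several image sets
#'
#' One histogram per named set with a dashed line at the set mean -- the
#' visual used to compare quality-score distributions of original and
#' converted image sets.
#'
#' @param score_sets named list of numeric score vectors.
#' @param file optional PNG path; when given the plot is written there.
#' @return invisibly, the per-set [summarize_scores()] list.
#' @export
plot_score_histograms <- function(score_sets, file = NULL) {
  stopifnot(is.list(score_sets), length(score_sets) >= 1L,
            !is.null(names(score_sets)))
  if (!is.null(file)) {
    grDevices::png(file, width = 480L * length(score_sets), height = 480L)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(1L, length(score_sets)))
  on.exit(graphics::par(op), add = TRUE)
  sums <- lapply(names(score_sets), function(nm) {
    s <- score_sets[[nm]]
    graphics::hist(s, main = nm, xlab = "score", col = "grey85",
                   border = "grey40")
    graphics::abline(v = mean(s), lty = 2L, lwd = 2L)
    summarize_scores(s)
  })
  names(sums) <- names(score_sets)
  invisible(sums)
}

#' Score a set of images with several metrics
#'
#' Applies named metric functions to every image and returns a long-format
#' table (image_id, metric, value), the on-disk quality-report layout.
#'
#' @param images list of [bscan()] objects.
#' @param metrics named list of `function(bscan) -> numeric`.
#' @return data.frame with columns image_id, metric, value.
#' @export
score_images <- function(images, metrics) {
  stopifnot(length(images) > 0L, length(metrics) > 0L,
            !is.null(names(metrics)))
  rows <- list()
  for (mname in names(metrics)) {
    vals <- vapply(images, metrics[[mname]], numeric(1))
    ids <- vapply(images, function(im) im$source_id, character(1))
    rows[[mname]] <- data.frame(image_id = ids, metric = mname,
                                value = vals, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
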