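# ---------------------------------------------------------------------------
# Automatic separability experiment: train an external preset classifier on
# original images, then test whether converted images are assigned their
# target preset.
# ---------------------------------------------------------------------------

#' Balanced train/validation/test split
#'
#' Sizes follow the floor-remainder rule: `val = floor(f_val n)`,
#' `test = floor(f_test n)`, `train = n - val - test` (the remainder goes to
#' the training set), so sizes are deterministic in `n` and independent of
#' the seed; memberships depend only on the seed. When `labels` are given
#' the assignment is per class, keeping every split balanced to within one
#' image per class.
#'
#' @param n dataset size (>= 5).
#' @param fractions length-3 numeric summing to 1 (train, val, test).
#' @param seed shuffling seed.
#' @param labels optional class label per element (length `n`).
#' @return list with `sizes` (named train/val/test) and index vectors
#'   `train`, `val`, `test`.
#' @export
split_dataset <- function(n, fractions = c(0.6, 0.2, 0.2), seed = 1L,
                          labels = NULL) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  if (n < 5L) stop("dataset too small to split (need n >= 5)")
  n_val <- floor(fractions[2L] * n)
  n_test <- floor(fractions[3L] * n)
  n_train <- n - n_val - n_test
  if (n_train < 1L || n_val < 1L || n_test < 1L)
    stop("dataset too small for non-empty splits")
  if (is.null(labels)) labels <- rep("all", n)
  stopifnot(length(labels) == n)
  classes <- sort(unique(labels))
  with_seed(seed, {
    alloc <- function(total, per_class_n) {
      base <- floor(total * per_class_n / n)
      deficit <- total - sum(base)
      if (deficit > 0) {
        bump <- sample(seq_along(base), deficit)
        base[bump] <- base[bump] + 1L
      }
      base
    }
    nk <- vapply(classes, function(k) sum(labels == k), integer(1))
    val_k <- alloc(n_val, nk)
    test_k <- alloc(n_test, nk)
    idx <- list(train = integer(0), val = integer(0), test = integer(0))
    for (i in seq_along(classes)) {
      members <- sample(which(labels == classes[i]))
      idx$val <- c(idx$val, members[seq_len(val_k[i])])
      members <- members[-seq_len(val_k[i])]
      idx$test <- c(idx$test, members[seq_len(test_k[i])])
      idx$train <- c(idx$train, members[-seq_len(test_k[i])])
    }
    list(sizes = c(train = n_train, val = n_val, test = n_test),
         train = sort(idx$train), val = sort(idx$val), test = sort(idx$test))
  })
}

#' Classification accuracy from confusion counts
#'
#' `(TP + TN) / (TP + TN + FP + FN)`. In the separability experiment the
#' positives are the images of the target class of the model under test.
#'
#' @param tp,tn,fp,fn non-negative confusion counts, not all zero.
#' @return scalar accuracy in [0, 1].
#' @export
accuracy <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("all counts are zero")
  unname((tp + tn) / sum(counts))
}

#' Classifier training configuration
#'
#' The desk-scale backbone is a small 3-stage strided CNN with global
#' average pooling (a few thousand parameters): the experiment's logic, not
#' the backbone capacity, is what the separability test exercises. Input
#' images are used at native size; augmentation is horizontal flips only.
#'
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param batch_size gradients are averaged over this many images per
#'   update step.
#' @param width base channel width.
#' @param flip random horizontal flips during training.
#' @param restarts independent training restarts; the restart with the
#'   lowest validation loss is kept (small nets on small data occasionally
#'   land in a poor basin).
#' @param backbone `"small_cnn"` (a DenseNet-scale backbone is not
#'   provided in this implementation).
#' @param seed master seed.
#' @return an object of class `classifier_config`.
#' @export
classifier_config <- function(epochs = 16L, lr = 1e-2, batch_size = 8L,
                              width = 8L, flip = TRUE, restarts = 3L,
                              backbone = "small_cnn", seed = 1L) {
  if (!identical(backbone, "small_cnn"))
    stop("only the 'small_cnn' backbone is available in this build")
  structure(list(epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size),
                 width = as.integer(width), flip = isTRUE(flip),
                 restarts = as.integer(restarts),
                 backbone = backbone, seed = as.integer(seed)),
            class = "classifier_config")
}

# Three strided conv-relu stages; the head reads global channel statistics
# (mean and standard deviation) pooled from EVERY stage, not only the last:
# the preset difference is a noise-texture difference, carried by
# fine-scale statistics that deep striding averages away.
build_classifier_net <- function(width) {
  list(net = nn_sequential(list(
         nn_conv(1L, width, 3L, stride = 2L, pad = 1L, init = "he"),
         nn_relu(),
         nn_conv(width, 2L * width, 3L, stride = 2L, pad = 1L, init = "he"),
         nn_relu(),
         nn_conv(2L * width, 4L * width, 3L, stride = 2L, pad = 1L,
                 init = "he"),
         nn_relu())),
       taps = c(1L, 3L, 5L),                  # relu outputs, 0-based
       head = nn_dense(2L * (width + 2L * width + 4L * width), 2L))
}

# mean + log-sd per channel of one feature map (population denominator;
# the log puts channel noise energies on a decibel-like scale so the head
# sees comparably scaled features)
pool_stats <- function(f, eps = 1e-8) {
  d <- dim(f)
  m <- matrix(f, d[1L] * d[2L], d[3L])
  mu <- colMeans(m)
  s <- sqrt(colMeans(sweep(m, 2L, mu)^2) + eps)
  list(feat = c(mu, log(s)), mu = mu, s = s, d = d)
}

classifier_logits <- function(clf, px) {
  px <- px - min(px)
  if (max(px) > 0) px <- px / max(px)        # per-image min-max
  tape <- seq_forward(clf$net, as_tensor(px), taps = clf$taps)
  pools <- lapply(as.character(clf$taps),
                  function(k) pool_stats(tape$taps[[k]]))
  feats <- matrix(unlist(lapply(pools, `[[`, "feat")), 1L)
  hw <- forward.dense(clf$head, feats)
  list(logits = as.numeric(hw$out), tape = tape, hcache = hw$cache,
       pools = pools)
}

# backward from logit gradients through pooling into the conv stack
classifier_backward <- function(clf, fw, dz) {
  gfeat <- as.numeric(backward.dense(clf$head, fw$hcache, matrix(dz, 1L)))
  off <- 0L
  extra <- list()
  g_last <- NULL
  for (j in seq_along(fw$pools)) {
    p <- fw$pools[[j]]
    nf <- length(p$feat)
    gf <- gfeat[off + seq_len(nf)]
    off <- off + nf
    C <- length(p$mu)
    n <- p$d[1L] * p$d[2L]
    tap_key <- as.character(clf$taps[j])
    f <- fw$tape$taps[[tap_key]]
    m <- matrix(f, n, C)
    ctr <- sweep(m, 2L, p$mu)
    gmat <- matrix(gf[seq_len(C)] / n, n, C, byrow = TRUE) +
      ctr * matrix(gf[C + seq_len(C)] / (n * p$s^2), n, C, byrow = TRUE)
    gcube <- array(gmat, p$d)
    if (j == length(fw$pools)) g_last <- gcube else extra[[tap_key]] <- gcube
  }
  seq_backward(clf$net, fw$tape, g_last, extra = extra)
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

#' Train a binary preset classifier
#'
#' Trains the desk-scale CNN to distinguish the two scanning presets,
#' tracking per-epoch training/validation loss and accuracy, and returns
#' the weights from the epoch with the lowest validation loss (early
#' stopping with full-curve retention).
#'
#' @param train_set,val_set non-empty lists of [bscan()] images; both
#'   presets must appear in each.
#' @param config a [classifier_config()].
#' @return list with `classifier` (class `preset_classifier`), `curves`
#'   (data.frame epoch/train_loss/val_loss/train_acc/val_acc) and
#'   `best_epoch`.
#' @export
train_classifier <- function(train_set, val_set,
                             config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  if (length(train_set) == 0L || length(val_set) == 0L)
    stop("both splits must be non-empty")
  classes <- sort(unique(vapply(train_set, function(b) b$preset,
                                character(1))))
  val_classes <- sort(unique(vapply(val_set, function(b) b$preset,
                                    character(1))))
  if (length(classes) < 2L || length(val_classes) < 2L)
    stop("both presets must be present in each split")
  labels <- match(vapply(train_set, function(b) b$preset, character(1)),
                  classes)
  vlabels <- match(vapply(val_set, function(b) b$preset, character(1)),
                   classes)

  one_run <- function(run_seed) with_seed(run_seed, {
    clf <- build_classifier_net(config$width)
    clf$classes <- classes
    class(clf) <- "preset_classifier"
    curves <- vector("list", config$epochs)
    best <- list(loss = Inf, state = NULL, epoch = NA_integer_)
    t_step <- 0L
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(seq_along(train_set))
      tl <- 0; tacc <- 0
      in_batch <- 0L
      nn_zero_grads(clf$net); nn_zero_grads(clf$head)
      for (i in ord) {
        px <- train_set[[i]]$pixels
        if (config$flip && stats::runif(1) < 0.5) px <- px[, ncol(px):1L]
        fw <- classifier_logits(clf, px)
        p <- softmax(fw$logits)
        y <- labels[i]
        tl <- tl + (-log(max(p[y], 1e-12)))
        tacc <- tacc + as.numeric(which.max(p) == y)
        dz <- (p - as.numeric(seq_len(2L) == y)) / config$batch_size
        classifier_backward(clf, fw, dz)
        in_batch <- in_batch + 1L
        if (in_batch == config$batch_size || i == ord[length(ord)]) {
          t_step <- t_step + 1L
          nn_adam_step(clf$net, config$lr, t_step, 0.9, 0.999)
          nn_adam_step(clf$head, config$lr, t_step, 0.9, 0.999)
          nn_zero_grads(clf$net); nn_zero_grads(clf$head)
          in_batch <- 0L
        }
      }
      vl <- 0; vacc <- 0
      for (i in seq_along(val_set)) {
        p <- softmax(classifier_logits(clf, val_set[[i]]$pixels)$logits)
        vl <- vl + (-log(max(p[vlabels[i]], 1e-12)))
        vacc <- vacc + as.numeric(which.max(p) == vlabels[i])
      }
      vl <- vl / length(val_set)
      curves[[epoch]] <- data.frame(
        epoch = epoch, train_loss = tl / length(train_set),
        val_loss = vl, train_acc = tacc / length(train_set),
        val_acc = vacc / length(val_set))
      if (vl < best$loss) {
        best <- list(loss = vl,
                     state = list(net = nn_state(clf$net),
                                  head = nn_state(clf$head)),
                     epoch = epoch)
      }
    }
    nn_load_state(clf$net, best$state$net)
    nn_load_state(clf$head, best$state$head)
    list(classifier = clf, curves = do.call(rbind, curves),
         best_epoch = best$epoch, best_val_loss = best$loss)
  })
  runs <- lapply(seq_len(config$restarts),
                 function(r) one_run(config$seed + 1000L * (r - 1L)))
  best_run <- runs[[which.min(vapply(runs, `[[`, 0, "best_val_loss"))]]
  best_run[c("classifier", "curves", "best_epoch")]
}

#' Predict the scanning preset of an image
#'
#' @param clf a `preset_classifier` from [train_classifier()].
#' @param image a [bscan()].
#' @return list with `preset` (predicted label) and `prob` (named class
#'   probabilities).
#' @export
predict_preset <- function(clf, image) {
  stopifnot(inherits(clf, "preset_classifier"))
  p <- softmax(classifier_logits(clf, get_pixels(image))$logits)
  names(p) <- clf$classes
  list(preset = clf$classes[which.max(p)], prob = p)
}

#' Evaluate classifier accuracy on a labelled set
#'
#' @param clf a `preset_classifier`.
#' @param images list of [bscan()] with truthful `preset` labels.
#' @return fraction of correct predictions.
#' @export
classifier_accuracy <- function(clf, images) {
  preds <- vapply(images, function(im) predict_preset(clf, im)$preset,
                  character(1))
  truth <- vapply(images, function(im) im$preset, character(1))
  mean(preds == truth)
}

#' Separability test on converted images
#'
#' Classifies every synthetic (converted) image with a preset classifier
#' trained on original images only and reports the fraction assigned to the
#' target preset. Positives are the images of the target class, so
#' TP counts synthetic images recognised as their target preset and FN
#' those still assigned their original preset; the design offers no true
#' negatives or false positives, hence specificity is not computable.
#'
#' @param clf a `preset_classifier` trained on original images.
#' @param synthetic_images non-empty list of converted [bscan()] images.
#' @param target_preset the preset the images were converted into.
#' @return an object of class `separability_report`: confusion counts,
#'   accuracy, and bookkeeping fields.
#' @export
synthetic_separability_test <- function(clf, synthetic_images,
                                        target_preset) {
  if (length(synthetic_images) == 0L) stop("empty synthetic image set")
  preds <- vapply(synthetic_images,
                  function(im) predict_preset(clf, im)$preset, character(1))
  tp <- sum(preds == target_preset)
  fn <- sum(preds != target_preset)
  structure(list(counts = c(TP = tp, TN = 0L, FP = 0L, FN = fn),
                 accuracy = accuracy(tp, 0L, 0L, fn),
                 target_preset = target_preset,
                 n = length(synthetic_images),
                 specificity = NA_real_),
            class = "separability_report")
}

#' @export
print.separability_report <- function(x, ...) {
  cat(sprintf(
    "<separability: %d synthetic images, %.1f%% assigned target preset '%s'\n",
    x$n, 100 * x$accuracy, x$target_preset))
  cat(sprintf("  TP %d FN %d (no TN/FP in this design; specificity n/a)>\n",
              x$counts["TP"], x$counts["FN"]))
  invisible(x)
}
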