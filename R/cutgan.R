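# ---------------------------------------------------------------------------
# Contrastive unpaired translation GAN: encoder-decoder generator, patch
# discriminator, projection heads, training schedule and inference.
# ---------------------------------------------------------------------------

#' Training configuration for the translation GAN
#'
#' Defaults follow the full-scale recipe: residual generator with nine
#' residual blocks, inputs resized to 286 then randomly cropped to 256,
#' Adam with beta1 = 0.5, beta2 = 0.999 at learning rate 2e-4, 400 epochs
#' with the rate decaying linearly to zero over the last 200, a generator
#' checkpoint every 20 epochs, contrastive temperature tau = 0.07 and
#' encoder taps at atomic layers {0, 4, 8, 12, 16}. The contrastive weights,
#' patches per layer and embedding width follow the conventions of this
#' architecture family.
#'
#' @param epochs total training epochs.
#' @param decay_start_epoch last epoch of the constant-rate plateau;
#'   the rate decays linearly to 0 between here and `epochs`.
#' @param lr Adam learning rate.
#' @param adam_beta1,adam_beta2 Adam moment decay rates.
#' @param resize images are bilinearly resized to this side length...
#' @param crop ...then randomly cropped to this side length (<= resize).
#' @param checkpoint_interval epochs between saved generator checkpoints.
#' @param tau contrastive softmax temperature.
#' @param nce_layers 0-based atomic encoder layer indices tapped for the
#'   contrastive loss (0 is the input itself).
#' @param patches_per_layer locations sampled per tapped layer.
#' @param lambda_nce_x,lambda_nce_y weights of the contrastive loss on
#'   source-class and target-class (identity) images.
#' @param gan_mode `"least_squares"` (default; stabler) or `"vanilla"`.
#' @param width generator base channel width; encoder stages use width,
#'   2 width, 4 width.
#' @param n_res_blocks residual blocks at the bottleneck.
#' @param d_width discriminator base width.
#' @param embed_dim projection-head embedding dimension.
#' @param flip random horizontal flips during training.
#' @param seed master seed fanning out to shuffling, crops and patch
#'   sampling.
#' @return an object of class `training_config`.
#' @export
training_config <- function(epochs = 400L, decay_start_epoch = 200L,
                            lr = 2e-4, adam_beta1 = 0.5, adam_beta2 = 0.999,
                            resize = 286L, crop = 256L,
                            checkpoint_interval = 20L, tau = 0.07,
                            nce_layers = c(0L, 4L, 8L, 12L, 16L),
                            patches_per_layer = 256L,
                            lambda_nce_x = 1, lambda_nce_y = 1,
                            gan_mode = c("least_squares", "vanilla"),
                            width = 64L, n_res_blocks = 9L, d_width = 64L,
                            embed_dim = 256L, flip = FALSE, seed = 1L) {
  gan_mode <- match.arg(gan_mode)
  if (decay_start_epoch > epochs)
    stop("decay_start_epoch must be <= epochs")
  if (crop > resize) stop("crop must be <= resize")
  if (lr <= 0 || tau <= 0 || lambda_nce_x <= 0 || lambda_nce_y <= 0)
    stop("rates and loss weights must be > 0")
  max_layer <- 9L + n_res_blocks
  if (any(nce_layers < 0L) || any(nce_layers > max_layer))
    stop("nce_layers must address existing encoder layers (0..",
         max_layer, ")")
  structure(list(epochs = as.integer(epochs),
                 decay_start_epoch = as.integer(decay_start_epoch),
                 lr = lr, adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 resize = as.integer(resize), crop = as.integer(crop),
                 checkpoint_interval = as.integer(checkpoint_interval),
                 tau = tau, nce_layers = as.integer(sort(nce_layers)),
                 patches_per_layer = as.integer(patches_per_layer),
                 lambda_nce_x = lambda_nce_x, lambda_nce_y = lambda_nce_y,
                 gan_mode = gan_mode, width = as.integer(width),
                 n_res_blocks = as.integer(n_res_blocks),
                 d_width = as.integer(d_width),
                 embed_dim = as.integer(embed_dim), flip = isTRUE(flip),
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Desk-scale training configuration
#'
#' A reduced recipe sized for CPU-only experiments on 64 x 64 phantoms:
#' three residual blocks at width 16, resize 72 / crop 64, encoder taps
#' {0, 4, 8, 12}, 64 patches per layer, 64-dimensional embeddings, and a
#' short schedule with checkpoints every few epochs. All other conventions
#' (Adam moments, learning rate, temperature, loss weights) are unchanged
#' from [training_config()].
#'
#' @param epochs,checkpoint_interval,seed overridable schedule knobs.
#' @param ... further overrides passed to [training_config()].
#' @return a `training_config`.
#' @export
desk_training_config <- function(epochs = 12L, checkpoint_interval = 4L,
                                 seed = 1L, ...) {
  args <- list(epochs = as.integer(epochs),
               decay_start_epoch = as.integer(ceiling(epochs / 2)),
               resize = 72L, crop = 64L,
               checkpoint_interval = as.integer(checkpoint_interval),
               nce_layers = c(0L, 4L, 8L, 12L), patches_per_layer = 64L,
               width = 16L, n_res_blocks = 3L, d_width = 16L,
               embed_dim = 64L, seed = as.integer(seed))
  over <- list(...)
  args[names(over)] <- over
  do.call(training_config, args)
}

#' Learning rate at a given epoch
#'
#' Constant plateau up to `decay_start_epoch`, then linear decay reaching 0
#' at the final epoch:
#' `lr * (epochs - epoch) / (epochs - decay_start_epoch)`.
#'
#' @param config a [training_config()].
#' @param epoch epoch in 1..epochs.
#' @return the learning rate.
#' @export
lr_at_epoch <- function(config, epoch) {
  stopifnot(inherits(config, "training_config"))
  if (epoch < 1 || epoch > config$epochs) stop("epoch out of range")
  if (epoch <= config$decay_start_epoch) return(config$lr)
  config$lr * (config$epochs - epoch) /
    (config$epochs - config$decay_start_epoch)
}

#' Epochs at which checkpoints are saved
#'
#' Multiples of `checkpoint_interval` up to `epochs`, plus the final epoch
#' when it is not itself a multiple; the count is
#' `floor(epochs / interval)` (+1 in that case).
#'
#' @param config a [training_config()].
#' @return increasing integer vector of epochs.
#' @export
checkpoint_epochs <- function(config) {
  stopifnot(inherits(config, "training_config"))
  eps <- seq_len(config$epochs %/% config$checkpoint_interval) *
    config$checkpoint_interval
  if (length(eps) == 0L || eps[length(eps)] != config$epochs)
    eps <- c(eps, config$epochs)
  as.integer(eps)
}

# channel count of the encoder feature map at a 0-based atomic layer index
channels_at_layer <- function(width, layer) {
  if (layer == 0L) 1L
  else if (layer <= 3L) width
  else if (layer <= 6L) 2L * width
  else 4L * width
}

#' Build a translation generator
#'
#' Encoder-decoder residual network: a 7x7 reflection-padded stem, two
#' stride-2 downsampling stages (width, 2 width, 4 width channels), n
#' residual blocks, two nearest-neighbour-upsample + convolution stages and
#' a 7x7 output head squashed onto [0, 1]. Instance normalisation
#' throughout. Atomic layers are indexed from 0 (the input itself) so the
#' contrastive taps resolve as in the reference backbone; projection heads
#' (two-layer MLPs, one per tap) embed feature columns into unit-norm
#' vectors.
#'
#' @param config a [training_config()] (width, residual blocks, taps,
#'   embedding dimension are read from it).
#' @param target_preset preset name stamped onto converted images.
#' @param seed weight-initialisation seed.
#' @return an object of class `cut_generator`.
#' @export
build_generator <- function(config, target_preset = "seven_lines",
                            seed = 1L) {
  stopifnot(inherits(config, "training_config"))
  w <- config$width
  with_seed(seed, {
    enc <- list(
      nn_identity(),                                        # 0: input tap
      nn_conv(1L, w, 7L, pad = 3L, pad_mode = "reflect"),   # 1
      nn_instnorm(),                                        # 2
      nn_relu(),                                            # 3
      nn_conv(w, 2L * w, 3L, stride = 2L, pad = 1L),        # 4
      nn_instnorm(),                                        # 5
      nn_relu(),                                            # 6
      nn_conv(2L * w, 4L * w, 3L, stride = 2L, pad = 1L),   # 7
      nn_instnorm(),                                        # 8
      nn_relu()                                             # 9
    )
    res <- lapply(seq_len(config$n_res_blocks),
                  function(i) nn_resblock(4L * w))          # 10 .. 9+n
    dec <- list(
      nn_upsample2(),
      nn_conv(4L * w, 2L * w, 3L, pad = 1L),
      nn_instnorm(),
      nn_relu(),
      nn_upsample2(),
      nn_conv(2L * w, w, 3L, pad = 1L),
      nn_instnorm(),
      nn_relu(),
      nn_conv(w, 1L, 7L, pad = 3L, pad_mode = "reflect"),
      nn_tanh01()
    )
    net <- nn_sequential(c(enc, res, dec))
    heads <- lapply(config$nce_layers, function(l) {
      ch <- channels_at_layer(w, l)
      list(l1 = nn_dense(ch, config$embed_dim),
           l2 = nn_dense(config$embed_dim, config$embed_dim))
    })
    names(heads) <- as.character(config$nce_layers)
    structure(list(net = net, heads = heads, width = w,
                   n_res_blocks = config$n_res_blocks,
                   nce_layers = config$nce_layers,
                   n_enc = max(config$nce_layers) + 1L,
                   embed_dim = config$embed_dim, tau = config$tau,
                   target_preset = target_preset, epoch = 0L),
              class = "cut_generator")
  })
}

# Patch discriminator: 4x4 stride-2 convolutions emitting per-patch scores.
build_discriminator <- function(config, seed = 1L) {
  w <- config$d_width
  with_seed(seed, {
    layers <- list(
      nn_conv(1L, w, 4L, stride = 2L, pad = 1L),
      nn_lrelu(0.2),
      nn_conv(w, 2L * w, 4L, stride = 2L, pad = 1L),
      nn_instnorm(),
      nn_lrelu(0.2),
      nn_conv(2L * w, 1L, 4L, stride = 1L, pad = 1L)
    )
    if (config$gan_mode == "vanilla")
      layers <- c(layers, list(nn_sigmoid()))
    nn_sequential(layers)
  })
}

# -- projection heads --------------------------------------------------------

head_forward <- function(head, X) {
  f1 <- forward.dense(head$l1, X)
  r <- pmax(f1$out, 0)
  f2 <- forward.dense(head$l2, r)
  nrm <- sqrt(rowSums(f2$out^2)) + 1e-10
  list(out = f2$out / nrm,
       cache = list(c1 = f1$cache, mask = f1$out > 0, c2 = f2$cache,
                    z = f2$out, nrm = nrm))
}

head_backward <- function(head, cache, g) {
  # through row normalisation z / ||z||
  zdir <- cache$z / cache$nrm
  gz <- (g - zdir * rowSums(g * zdir)) / cache$nrm
  gr <- backward.dense(head$l2, cache$c2, gz)
  backward.dense(head$l1, cache$c1, gr * cache$mask)
}

# flatten a [H, W, C] cube to a (H*W) x C matrix of feature columns
flat_features <- function(f) {
  d <- dim(f)
  matrix(f, d[1L] * d[2L], d[3L])
}

#' Sample embedded patch features for the contrastive loss
#'
#' For every tapped encoder layer, draws `n_patches` spatial locations
#' uniformly without replacement (shared between the two feature maps),
#' embeds the corresponding feature columns of the original image `x` and
#' of the synthesised image `x_hat` through that layer's two-layer MLP head
#' and unit-normalises them. Queries come from the synthesised image,
#' positives from the same locations of the original; the negatives of a
#' query are the embeddings of the other sampled locations of the original
#' image.
#'
#' @param x,x_hat [bscan()] images of identical shape.
#' @param gen a [build_generator()] object (encoder and heads).
#' @param n_patches locations sampled per layer.
#' @param seed sampling seed.
#' @return an object of class `patch_features`: per layer, `queries`,
#'   `positives` (rows are unit-norm embeddings) and `locations`; plus the
#'   temperature `tau`.
#' @export
sample_patch_features <- function(x, x_hat, gen, n_patches = 64L, seed = 1L) {
  stopifnot(inherits(gen, "cut_generator"))
  px <- as_tensor(x$pixels); pf <- as_tensor(x_hat$pixels)
  if (!identical(dim(px), dim(pf))) stop("x and x_hat must share a shape")
  tx <- seq_forward(gen$net, px, n_layers = gen$n_enc, taps = gen$nce_layers)
  tf <- seq_forward(gen$net, pf, n_layers = gen$n_enc, taps = gen$nce_layers)
  layers <- with_seed(seed, {
    out <- list()
    for (l in as.character(gen$nce_layers)) {
      Fk <- flat_features(tx$taps[[l]])
      Fq <- flat_features(tf$taps[[l]])
      if (n_patches > nrow(Fk))
        stop("n_patches exceeds available spatial locations at layer ", l)
      locs <- sample.int(nrow(Fk), n_patches)
      out[[l]] <- list(
        queries = head_forward(gen$heads[[l]], Fq[locs, , drop = FALSE])$out,
        positives = head_forward(gen$heads[[l]], Fk[locs, , drop = FALSE])$out,
        locations = locs)
    }
    out
  })
  structure(list(layers = layers, tau = gen$tau), class = "patch_features")
}

# Contrastive pass used inside training: embeds sampled columns of the
# source-tape taps (keys) and of an encoder-only tape on `out_img`
# (queries), computes the loss, and returns the gradient w.r.t. out_img
# plus per-tap gradients to inject into the source tape.
nce_pass <- function(gen, src_taps, out_img, n_patches) {
  tapE <- seq_forward(gen$net, out_img, n_layers = gen$n_enc,
                      taps = gen$nce_layers)
  L <- length(gen$nce_layers)
  gF_out <- list()
  gF_src <- list()
  total <- 0
  for (l in as.character(gen$nce_layers)) {
    fk <- src_taps[[l]]; fq <- tapE$taps[[l]]
    d <- dim(fq)
    Fk <- flat_features(fk); Fq <- flat_features(fq)
    locs <- sample.int(nrow(Fk), min(n_patches, nrow(Fk)))
    hq <- head_forward(gen$heads[[l]], Fq[locs, , drop = FALSE])
    hk <- head_forward(gen$heads[[l]], Fk[locs, , drop = FALSE])
    ll <- nce_layer_loss(hq$out, hk$out, gen$tau, grad = TRUE)
    total <- total + ll$loss
    gXq <- head_backward(gen$heads[[l]], hq$cache, ll$gQ / L)
    gXk <- head_backward(gen$heads[[l]], hk$cache, ll$gK / L)
    gq <- matrix(0, nrow(Fq), ncol(Fq)); gq[locs, ] <- gXq
    gk <- matrix(0, nrow(Fk), ncol(Fk)); gk[locs, ] <- gXk
    gF_out[[l]] <- array(gq, d)
    gF_src[[l]] <- array(gk, dim(fk))
  }
  g_img <- seq_backward(gen$net, tapE, array(0, dim(tapE$out)),
                        extra = gF_out, n_layers = gen$n_enc)
  list(loss = total / L, g_img = g_img, g_src = gF_src)
}

# -- image preprocessing -----------------------------------------------------

resize_image <- function(px, side) {
  if (nrow(px) == side && ncol(px) == side) return(px)
  out <- EBImage::resize(px, w = side, h = side)
  matrix(pmin(pmax(as.numeric(out), 0), 1), side, side)
}

random_crop <- function(px, side) {
  r0 <- if (nrow(px) > side) sample.int(nrow(px) - side, 1L) else 1L
  c0 <- if (ncol(px) > side) sample.int(ncol(px) - side, 1L) else 1L
  px[r0:(r0 + side - 1L), c0:(c0 + side - 1L)]
}

preprocess_train <- function(px, config) {
  px <- resize_image(px, config$resize)
  px <- random_crop(px, config$crop)
  if (config$flip && stats::runif(1) < 0.5) px <- px[, ncol(px):1L]
  px
}

# -- LSGAN / vanilla gradient helpers ---------------------------------------

d_loss_grads <- function(d_real, d_fake, mode) {
  n_r <- length(d_real); n_f <- length(d_fake)
  if (mode == "least_squares") {
    list(loss_real = 0.5 * mean((d_real - 1)^2),
         loss_fake = 0.5 * mean(d_fake^2),
         g_real = (d_real - 1) / n_r,
         g_fake = d_fake / n_f)
  } else {
    eps <- 1e-7
    dr <- pmin(pmax(d_real, eps), 1 - eps)
    df <- pmin(pmax(d_fake, eps), 1 - eps)
    list(loss_real = -mean(log(dr)),
         loss_fake = -mean(log(1 - df)),
         g_real = -1 / (dr * n_r),
         g_fake = 1 / ((1 - df) * n_f))
  }
}

g_gan_loss_grad <- function(d_fake, mode) {
  n <- length(d_fake)
  if (mode == "least_squares") {
    list(loss = mean((d_fake - 1)^2), g = 2 * (d_fake - 1) / n)
  } else {
    eps <- 1e-7
    df <- pmin(pmax(d_fake, eps), 1 - eps)
    list(loss = -mean(log(df)), g = -1 / (df * n))
  }
}

#' Train a preset-translation model
#'
#' Trains the contrastive unpaired translation GAN on two unpaired image
#' sets. Per iteration one source image `x` and one target image `y` are
#' resized, randomly cropped and fed through: a discriminator update
#' (real = `y`, fake = `G(x)` detached), then a generator update whose
#' objective is the adversarial term plus `lambda_nce_x` times the patchwise
#' contrastive loss between `x` and `G(x)` plus `lambda_nce_y` times the
#' same loss between `y` and `G(y)` (the identity regulariser). A generator
#' checkpoint is saved every `checkpoint_interval` epochs and at the final
#' epoch, and a per-epoch loss trace with the six series G_GAN, D_real,
#' D_fake, G, NCE, NCE_Y is written to `losses.csv`. Fully seeded.
#'
#' @param source_set,target_set non-empty lists of [bscan()] images of the
#'   source (X) and target (Y) preset.
#' @param config a [training_config()].
#' @param out_dir directory receiving checkpoints and the loss trace.
#' @param target_preset preset name stamped on converted images (defaults to
#'   the preset of the first target image).
#' @param verbose print per-epoch losses.
#' @return list with `generator` (final state), `checkpoints` (data.frame
#'   epoch/path), and `losses` (the trace data.frame).
#' @export
cut_train <- function(source_set, target_set, config, out_dir,
                      target_preset = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "training_config"))
  if (length(source_set) == 0L || length(target_set) == 0L)
    stop("both image sets must be non-empty")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(target_preset)) target_preset <- target_set[[1L]]$preset

  gen <- build_generator(config, target_preset, seed = config$seed)
  disc <- build_discriminator(config, seed = config$seed + 1L)
  n_iter <- min(length(source_set), length(target_set))
  ckpt_eps <- checkpoint_epochs(config)
  trace <- vector("list", config$epochs)
  ckpts <- list()
  t_g <- 0L; t_d <- 0L

  with_seed(config$seed + 2L, {
    for (epoch in seq_len(config$epochs)) {
      lr <- lr_at_epoch(config, epoch)
      xi <- sample(seq_along(source_set))[seq_len(n_iter)]
      yi <- sample(seq_along(target_set))[seq_len(n_iter)]
      acc <- c(G_GAN = 0, D_real = 0, D_fake = 0, G = 0, NCE = 0, NCE_Y = 0)
      for (it in seq_len(n_iter)) {
        x <- as_tensor(preprocess_train(source_set[[xi[it]]]$pixels, config))
        y <- as_tensor(preprocess_train(target_set[[yi[it]]]$pixels, config))

        tapeGx <- seq_forward(gen$net, x, taps = gen$nce_layers)
        fake <- tapeGx$out

        # --- discriminator update (fake detached) ---
        nn_zero_grads(disc)
        tapeDr <- seq_forward(disc, y)
        tapeDf <- seq_forward(disc, fake)
        dl <- d_loss_grads(as.numeric(tapeDr$out), as.numeric(tapeDf$out),
                           config$gan_mode)
        seq_backward(disc, tapeDr, array(dl$g_real, dim(tapeDr$out)))
        seq_backward(disc, tapeDf, array(dl$g_fake, dim(tapeDf$out)))
        t_d <- t_d + 1L
        nn_adam_step(disc, lr, t_d, config$adam_beta1, config$adam_beta2)

        # --- generator + heads update ---
        nn_zero_grads(gen$net); nn_zero_grads(gen$heads)
        tapeDg <- seq_forward(disc, fake)
        gg <- g_gan_loss_grad(as.numeric(tapeDg$out), config$gan_mode)
        g_fake <- seq_backward(disc, tapeDg, array(gg$g, dim(tapeDg$out)))

        nx <- nce_pass(gen, tapeGx$taps, fake, config$patches_per_layer)
        g_fake <- g_fake + config$lambda_nce_x * nx$g_img
        extra_x <- lapply(nx$g_src, function(g) config$lambda_nce_x * g)
        seq_backward(gen$net, tapeGx, g_fake, extra = extra_x)

        tapeGy <- seq_forward(gen$net, y, taps = gen$nce_layers)
        ny <- nce_pass(gen, tapeGy$taps, tapeGy$out,
                       config$patches_per_layer)
        extra_y <- lapply(ny$g_src, function(g) config$lambda_nce_y * g)
        seq_backward(gen$net, tapeGy, config$lambda_nce_y * ny$g_img,
                     extra = extra_y)

        # discriminator gradients picked up during the generator pass are
        # discarded at the next discriminator update's zeroing
        t_g <- t_g + 1L
        nn_adam_step(gen$net, lr, t_g, config$adam_beta1, config$adam_beta2)
        nn_adam_step(gen$heads, lr, t_g, config$adam_beta1,
                     config$adam_beta2)

        g_total <- gg$loss + config$lambda_nce_x * nx$loss +
          config$lambda_nce_y * ny$loss
        losses <- c(gg$loss, dl$loss_real, dl$loss_fake, g_total, nx$loss,
                    ny$loss)
        if (any(!is.finite(losses)))
          stop("non-finite loss at epoch ", epoch, ", iteration ", it,
               " (G_GAN=", signif(gg$loss, 4), ", NCE=", signif(nx$loss, 4),
               "); training aborted")
        acc <- acc + losses
      }
      row <- as.list(acc / n_iter)
      trace[[epoch]] <- data.frame(epoch = epoch, as.data.frame(row))
      if (verbose)
        message(sprintf(
          "epoch %3d lr %.2e G_GAN %.3f D_real %.3f D_fake %.3f NCE %.3f NCE_Y %.3f",
          epoch, lr, row$G_GAN, row$D_real, row$D_fake, row$NCE, row$NCE_Y))
      if (epoch %in% ckpt_eps) {
        gen$epoch <- epoch
        path <- save_checkpoint(gen, config, trace[[epoch]], out_dir)
        ckpts[[length(ckpts) + 1L]] <- data.frame(epoch = epoch, path = path,
                                                  stringsAsFactors = FALSE)
      }
    }
  })
  losses <- do.call(rbind, trace)
  utils::write.csv(losses, file.path(out_dir, "losses.csv"),
                   row.names = FALSE)
  list(generator = gen, checkpoints = do.call(rbind, ckpts), losses = losses)
}

# -- checkpoint I/O ----------------------------------------------------------

save_checkpoint <- function(gen, config, loss_row, out_dir) {
  path <- file.path(out_dir, sprintf("ckpt_e%04d.rds", gen$epoch))
  saveRDS(list(state = nn_state(gen$net), heads_state = nn_state(gen$heads),
               epoch = gen$epoch, width = gen$width,
               n_res_blocks = gen$n_res_blocks,
               nce_layers = gen$nce_layers, embed_dim = gen$embed_dim,
               tau = gen$tau, target_preset = gen$target_preset),
          path)
  sidecar <- sub("\\.rds$", ".json", path)
  jsonlite::write_json(
    list(epoch = gen$epoch, config = unclass(config),
         losses = as.list(loss_row)),
    sidecar, auto_unbox = TRUE, digits = NA)
  path
}

#' Load a generator checkpoint
#'
#' @param path an `.rds` checkpoint written by [cut_train()].
#' @return a `cut_generator`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- training_config(
    epochs = max(ck$epoch, 1L), decay_start_epoch = max(ck$epoch, 1L),
    resize = 64L, crop = 64L, nce_layers = ck$nce_layers, tau = ck$tau,
    width = ck$width, n_res_blocks = ck$n_res_blocks,
    embed_dim = ck$embed_dim)
  gen <- build_generator(cfg, ck$target_preset, seed = 1L)
  nn_load_state(gen$net, ck$state)
  nn_load_state(gen$heads, ck$heads_state)
  gen$epoch <- ck$epoch
  gen
}

# reflection-pad a matrix on the bottom/right up to a stride multiple
pad_to_multiple <- function(px, m) {
  H <- nrow(px); W <- ncol(px)
  H2 <- ceiling(H / m) * m; W2 <- ceiling(W / m) * m
  if (H2 > H) px <- px[c(seq_len(H), (H - 1L):(2L * H - H2)), , drop = FALSE]
  if (W2 > W) px <- px[, c(seq_len(W), (W - 1L):(2L * W - W2)), drop = FALSE]
  px
}

#' Convert a B-scan to the generator's target preset
#'
#' Runs the trained generator on an image. Arbitrary sizes are handled by
#' reflection-padding to the generator's stride multiple (4) and cropping
#' back; output values are clipped to [0, 1] and the result is labelled
#' `provenance = "synthetic"` with the generator's target preset.
#' Deterministic given the weights.
#'
#' @param gen a `cut_generator`.
#' @param image a [bscan()] at least 16 x 16.
#' @return the converted [bscan()].
#' @export
convert_bscan <- function(gen, image) {
  stopifnot(inherits(gen, "cut_generator"), inherits(image, "bscan"))
  px <- image$pixels
  if (nrow(px) < 16L || ncol(px) < 16L)
    stop("image smaller than the generator's minimum size (16 x 16)")
  padded <- pad_to_multiple(px, 4L)
  out <- seq_forward(gen$net, as_tensor(padded))$out
  out <- out[seq_len(nrow(px)), seq_len(ncol(px)), 1L]
  bscan(pmin(pmax(out, 0), 1), preset = gen$target_preset,
        provenance = "synthetic", source_id = image$source_id)
}
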