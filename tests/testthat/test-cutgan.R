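test_that("learning rate plateaus then decays linearly to zero", {
  cfg <- training_config()
  expect_equal(lr_at_epoch(cfg, 100L), 2e-4)
  expect_equal(lr_at_epoch(cfg, 200L), 2e-4)
  expect_equal(lr_at_epoch(cfg, 300L), 1e-4)   # decay-window midpoint
  expect_equal(lr_at_epoch(cfg, 400L), 0)
  expect_error(lr_at_epoch(cfg, 0L), "range")
  expect_error(lr_at_epoch(cfg, 401L), "range")

  lrs <- vapply(1:400, function(e) lr_at_epoch(cfg, e), numeric(1))
  expect_true(all(diff(lrs) <= 0))             # non-increasing
  knees <- which(abs(diff(diff(lrs))) > 1e-12) # exactly one slope change
  expect_equal(knees + 1L, 200L)               # ...at the decay start epoch
})

test_that("checkpoint epochs follow the interval-plus-final rule", {
  expect_length(checkpoint_epochs(training_config()), 20L)
  expect_equal(checkpoint_epochs(training_config(epochs = 40L,
                                                 decay_start_epoch = 20L)),
               c(20L, 40L))
  expect_equal(
    checkpoint_epochs(training_config(epochs = 50L, decay_start_epoch = 25L,
                                      checkpoint_interval = 20L)),
    c(20L, 40L, 50L))
})

test_that("training config enforces its invariants", {
  expect_error(training_config(epochs = 100L, decay_start_epoch = 150L),
               "decay_start")
  expect_error(training_config(resize = 100L, crop = 120L), "crop")
  expect_error(training_config(nce_layers = c(0L, 40L)), "encoder layers")
  expect_error(desk_training_config(lambda_nce_x = 0), "> 0")
})

test_that("a smoke training run completes with finite losses and checkpoints", {
  td <- withr::local_tempdir()
  X <- make_test_images(preset_macular_cube(), 4L, size = 36L, seed_off = 0L)
  Y <- make_test_images(preset_seven_lines(), 4L, size = 36L,
                        seed_off = 500L)
  cfg <- smoke_config(epochs = 3L, interval = 2L, seed = 9L)
  res <- cut_train(X, Y, cfg, td)

  expect_equal(res$checkpoints$epoch, c(2L, 3L))
  expect_true(all(file.exists(res$checkpoints$path)))
  expect_true(all(file.exists(sub("rds$", "json", res$checkpoints$path))))
  expect_true(file.exists(file.path(td, "losses.csv")))
  expect_equal(names(res$losses),
               c("epoch", "G_GAN", "D_real", "D_fake", "G", "NCE", "NCE_Y"))
  expect_equal(nrow(res$losses), 3L)
  expect_true(all(is.finite(as.matrix(res$losses))))
  expect_error(cut_train(list(), Y, cfg, td), "non-empty")
})

test_that("conversion preserves shape and range and is deterministic", {
  cfg <- smoke_config()
  gen <- build_generator(cfg, "seven_lines", seed = 3L)
  for (d in list(c(64L, 64L), c(131L, 97L))) {
    img <- bscan(matrix(stats::runif(prod(d)), d[1L], d[2L]),
                 "macular_cube", source_id = "t")
    out <- convert_bscan(gen, img)
    expect_identical(dim(out$pixels), d)
    expect_true(all(out$pixels >= 0 & out$pixels <= 1))
    expect_equal(out$provenance, "synthetic")
    expect_equal(out$preset, "seven_lines")
    expect_identical(convert_bscan(gen, img)$pixels, out$pixels)
  }
  tiny <- bscan(matrix(0.5, 8L, 8L) + diag(8L) * 0.1, "macular_cube")
  expect_error(convert_bscan(gen, tiny), "minimum size")
})

test_that("patch feature sampling honours counts, norms and seeding", {
  cfg <- smoke_config()
  gen <- build_generator(cfg, "seven_lines", seed = 4L)
  img <- make_test_images(preset_macular_cube(), 1L, size = 32L)[[1L]]
  fake <- convert_bscan(gen, img)
  pfs <- sample_patch_features(img, fake, gen, n_patches = 12L, seed = 21L)

  expect_s3_class(pfs, "patch_features")
  expect_length(pfs$layers, length(gen$nce_layers))
  for (l in pfs$layers) {
    expect_equal(nrow(l$queries), 12L)
    expect_equal(nrow(l$positives), 12L)      # one positive per query;
    expect_length(unique(l$locations), 12L)   # negatives are the other 11
    expect_equal(sqrt(rowSums(l$queries^2)), rep(1, 12L), tolerance = 1e-6)
    expect_equal(sqrt(rowSums(l$positives^2)), rep(1, 12L),
                 tolerance = 1e-6)
  }
  again <- sample_patch_features(img, fake, gen, n_patches = 12L, seed = 21L)
  expect_identical(lapply(pfs$layers, `[[`, "locations"),
                   lapply(again$layers, `[[`, "locations"))
  expect_gte(patchwise_nce_loss(pfs), 0)
  expect_error(sample_patch_features(img, fake, gen, n_patches = 1e5L,
                                     seed = 1L), "exceeds")
})
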