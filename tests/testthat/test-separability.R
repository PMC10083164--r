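test_that("split sizes follow the floor-remainder rule", {
  labels <- rep(c("a", "b"), each = 517L)
  sp <- split_dataset(1034L, seed = 3L, labels = labels)
  expect_equal(unname(sp$sizes), c(622L, 206L, 206L))
  expect_equal(split_dataset(10L, seed = 1L)$sizes,
               c(train = 6L, val = 2L, test = 2L))
  expect_equal(split_dataset(11L, seed = 1L)$sizes,
               c(train = 7L, val = 2L, test = 2L))
  expect_error(split_dataset(4L), "too small")
  expect_error(split_dataset(100L, fractions = c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("splits partition the data, balance classes, and depend on seed only through membership", {
  labels <- rep(c("a", "b"), each = 50L)
  s1 <- split_dataset(100L, seed = 1L, labels = labels)
  s2 <- split_dataset(100L, seed = 2L, labels = labels)
  expect_equal(s1$sizes, s2$sizes)               # sizes seed-independent
  expect_false(identical(s1$val, s2$val))        # membership seed-dependent
  expect_identical(split_dataset(100L, seed = 1L, labels = labels), s1)

  all_idx <- sort(c(s1$train, s1$val, s1$test))
  expect_identical(all_idx, 1:100)               # exact partition
  for (part in list(s1$train, s1$val, s1$test)) {
    counts <- table(labels[part])
    expect_lte(max(counts) - min(counts), 1L)    # balance within 1 image
  }
})

test_that("accuracy is the confusion-count quotient", {
  expect_equal(accuracy(2, 3, 0, 0), 1)
  expect_equal(accuracy(9, 9, 1, 1), 0.9)
  expect_equal(accuracy(0, 0, 1, 1), 0)
  expect_error(accuracy(0, 0, 0, 0), "zero")
  expect_error(accuracy(-1, 1, 1, 1), "non-negative")
})

test_that("the classifier trains, early-stops on validation loss, and separates raw presets", {
  tr <- c(make_test_images(preset_macular_cube(), 16L, size = 48L,
                           seed_off = 0L),
          make_test_images(preset_seven_lines(), 16L, size = 48L,
                           seed_off = 300L))
  va <- c(make_test_images(preset_macular_cube(), 6L, size = 48L,
                           seed_off = 600L),
          make_test_images(preset_seven_lines(), 6L, size = 48L,
                           seed_off = 900L))
  fit <- train_classifier(tr, va, classifier_config(epochs = 12L,
                                                    batch_size = 4L,
                                                    seed = 2L))

  expect_equal(nrow(fit$curves), 12L)            # one row per epoch
  expect_equal(fit$best_epoch,
               fit$curves$epoch[which.min(fit$curves$val_loss)])
  te <- c(make_test_images(preset_macular_cube(), 8L, size = 48L,
                           seed_off = 1200L),
          make_test_images(preset_seven_lines(), 8L, size = 48L,
                           seed_off = 1500L))
  expect_gte(classifier_accuracy(fit$classifier, te), 0.8)

  only_one <- make_test_images(preset_macular_cube(), 4L, size = 48L)
  expect_error(train_classifier(only_one, va), "both presets")
})

test_that("the separability report is internally consistent", {
  # a stub classifier exercises the report independently of training
  clf <- structure(list(classes = c("macular_cube", "seven_lines")),
                   class = "preset_classifier")
  imgs <- make_test_images(preset_seven_lines(), 7L, size = 48L)
  with_mocked_bindings(
    predict_preset = function(clf, image) {
      list(preset = if (mean(image$pixels) > 0.2) "seven_lines"
           else "macular_cube")
    },
    {
      rep <- synthetic_separability_test(clf, imgs, "seven_lines")
      expect_equal(sum(rep$counts), 7L)                 # conservation
      expect_equal(rep$accuracy,
                   accuracy(rep$counts["TP"], rep$counts["TN"],
                            rep$counts["FP"], rep$counts["FN"]))
      expect_true(is.na(rep$specificity))
      all_right <- synthetic_separability_test(
        clf, imgs[vapply(imgs, function(i) mean(i$pixels) > 0.2, TRUE)],
        "seven_lines")
      expect_equal(all_right$accuracy, 1)
    }
  )
  expect_error(synthetic_separability_test(clf, list(), "seven_lines"),
               "empty")
})
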