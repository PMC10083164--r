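test_that("ENL matches its closed form and fails on degenerate regions", {
  set.seed(1)
  m <- matrix(stats::rexp(100L * 100L), 100L, 100L)  # unit-mean exponential
  e <- enl(m, c(1L, 1L, 100L, 100L))
  expect_lt(abs(e - 1), 3 * sqrt(20 / 1e4))          # within ~3 SE of 1

  expect_equal(enl(m * 7.3, c(1L, 1L, 100L, 100L)), e, tolerance = 1e-12)
  expect_error(enl(matrix(0.5, 10L, 10L), c(1L, 1L, 10L, 10L)), "variance")
  expect_error(enl(m, c(90L, 90L, 20L, 20L)), "inside")
})

test_that("CNR matches direct substitution and its invariances", {
  px <- matrix(0, 4L, 4L)
  px[1L, 1:3] <- c(8, 10, 12)   # background: mean 10, sd 2
  px[3L, 1:2] <- c(20, 20)      # ROI: mean 20
  roi <- c(3L, 1L, 1L, 2L); bg <- c(1L, 1L, 1L, 3L)
  expect_equal(cnr(px, roi, bg), 5)
  expect_equal(cnr(px * 3, roi, bg), 5, tolerance = 1e-12)      # scaling
  expect_equal(cnr(px + 11, roi, bg), 5, tolerance = 1e-12)     # offset
  same <- px; same[3L, 1:2] <- 10
  expect_equal(cnr(same, roi, bg), 0)
  expect_error(cnr(matrix(1, 5L, 5L), c(1L, 1L, 2L, 2L), c(4L, 4L, 2L, 2L)),
               "standard deviation")
})

test_that("ROI annotations reject overlapping rectangles", {
  expect_error(roi_annotation(c(1L, 1L, 5L, 5L), c(3L, 3L, 5L, 5L)),
               "overlap")
  a <- roi_annotation(c(10L, 1L, 5L, 5L), c(1L, 1L, 5L, 5L), "img1")
  expect_s3_class(a, "roi_annotation")
})

test_that("BRISQUE features have the published dimensionality and determinism", {
  img <- make_test_images(preset_macular_cube(), 1L, size = 64L)[[1L]]
  f <- brisque_features(img)
  expect_length(f, 36L)                       # 18 per scale, 2 scales
  expect_true(all(is.finite(f)))
  expect_identical(brisque_features(img), f)
  expect_error(brisque_features(matrix(0.5, 64L, 64L)), "constant")
  expect_error(brisque_features(matrix(stats::runif(100L), 10L, 10L)),
               "32 x 32")
})

test_that("the fitted scorer orders images along the clean-to-noisy axis", {
  clean <- make_test_images(preset_seven_lines(), 12L, size = 64L,
                            seed_off = 40L)
  noisy <- make_test_images(preset_macular_cube(), 12L, size = 64L,
                            seed_off = 80L)
  scorer <- fit_brisque_scorer(clean, noisy)
  s_clean <- vapply(clean, function(im) brisque_score(im, scorer),
                    numeric(1))
  s_noisy <- vapply(noisy, function(im) brisque_score(im, scorer),
                    numeric(1))
  expect_gt(mean(s_noisy), mean(s_clean))     # higher score = lower quality
  expect_lt(abs(mean(s_clean)), 1)            # reference anchored near 0
  # held-out images from each preset fall on the correct side
  c2 <- make_test_images(preset_seven_lines(), 4L, size = 64L,
                         seed_off = 700L)
  n2 <- make_test_images(preset_macular_cube(), 4L, size = 64L,
                         seed_off = 800L)
  expect_gt(mean(vapply(n2, function(im) brisque_score(im, scorer), 0)),
            mean(vapply(c2, function(im) brisque_score(im, scorer), 0)))
  expect_error(brisque_score(clean[[1L]], NULL), "scorer")
  # a plain function is accepted as a pluggable scorer
  expect_equal(brisque_score(clean[[1L]], function(f) f[1L]),
               brisque_features(clean[[1L]])[1L])
})

test_that("checkpoint tables have one row per checkpoint and stable means", {
  cfg <- smoke_config()
  gens <- lapply(1:2, function(i) {
    g <- build_generator(cfg, "seven_lines", seed = i)
    g$epoch <- 10L * i
    g
  })
  imgs <- make_test_images(preset_macular_cube(), 3L, size = 32L)
  metric <- function(im) mean(im$pixels)
  tab <- evaluate_checkpoints(gens, imgs, metric)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$epoch, c(10L, 20L))
  expect_equal(tab$n, c(3L, 3L))
  shuffled <- evaluate_checkpoints(gens, imgs[c(3L, 1L, 2L)], metric)
  expect_equal(shuffled$mean, tab$mean, tolerance = 1e-12)
  expect_error(evaluate_checkpoints(gens, list(), metric), "images")
})

test_that("checkpoint selection takes extrema with earliest-epoch ties", {
  tab <- data.frame(epoch = c(20L, 40L, 60L), mean = c(3, 1, 2))
  expect_equal(select_checkpoint(tab, "lowest"), 40L)
  expect_equal(select_checkpoint(tab, "highest"), 20L)
  tie <- data.frame(epoch = c(20L, 40L), mean = c(1, 1))
  expect_equal(select_checkpoint(tie, "lowest"), 20L)
  expect_equal(select_checkpoint(tie[2:1, ], "lowest"), 20L) # order-proof
  expect_error(select_checkpoint(tab[0, ], "lowest"), "empty")
})

test_that("score summaries match the moment formulas", {
  s <- summarize_scores(c(1, 1, 1, 1))
  expect_equal(s$sd, 0)
  expect_equal(s$skewness, 0)
  expect_equal(summarize_scores(c(-1, 0, 1))$skewness, 0)

  set.seed(5)
  x <- stats::rexp(200L)
  s <- summarize_scores(x)
  n <- length(x)
  g1 <- mean((x - mean(x))^3) / mean((x - mean(x))^2)^1.5
  expect_equal(s$mean, mean(x))
  expect_equal(s$sd, stats::sd(x))
  expect_equal(s$skewness, g1 * sqrt(n * (n - 1)) / (n - 2),
               tolerance = 1e-12)
  expect_gt(s$skewness, 0)   # exponential samples are right-skewed
  expect_error(summarize_scores(3), "at least 2")
})

test_that("histogram export writes a file and returns the set summaries", {
  f <- file.path(withr::local_tempdir(), "hist.png")
  set.seed(9)
  out <- plot_score_histograms(list(original = stats::rexp(50L),
                                    synthetic = stats::rexp(50L) + 1), f)
  expect_true(file.exists(f) && file.size(f) > 0)
  expect_named(out, c("original", "synthetic"))
  expect_equal(out$original$n, 50L)
})

test_that("score tables are long-format with one row per image and metric", {
  imgs <- make_test_images(preset_seven_lines(), 3L, size = 48L)
  tab <- score_images(imgs, list(mean_px = function(im) mean(im$pixels),
                                 max_px = function(im) max(im$pixels)))
  expect_equal(nrow(tab), 6L)
  expect_setequal(unique(tab$metric), c("mean_px", "max_px"))
  expect_equal(tab$value[tab$metric == "mean_px"],
               vapply(imgs, function(im) mean(im$pixels), numeric(1)))
})
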