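# Brute-force oracles: literal summation of the published loss expressions,
# written independently of the package's vectorised implementations.

oracle_adversarial <- function(dr, df) {
  acc_r <- 0
  for (v in dr) acc_r <- acc_r + log(v)
  acc_f <- 0
  for (v in df) acc_f <- acc_f + log(1 - v)
  acc_r / length(dr) + acc_f / length(df)
}

oracle_nce <- function(q, qp, qm, tau) {
  num <- exp(sum(q * qp) / tau)
  den <- num
  for (n in seq_len(nrow(qm))) den <- den + exp(sum(q * qm[n, ]) / tau)
  -log(num / den)
}

test_that("adversarial loss matches direct substitution and its supremum", {
  expect_equal(adversarial_loss(rep(0.5, 4), rep(0.5, 4), "vanilla"),
               -2 * log(2), tolerance = 1e-12)
  # perfect discrimination approaches the supremum 0
  eps <- 1e-9
  expect_equal(adversarial_loss(1 - eps, eps, "vanilla"), 0,
               tolerance = 1e-6)
  expect_error(adversarial_loss(c(0.2, 1.2), 0.5, "vanilla"), "\\(0, 1\\)")
  # generator terms
  expect_equal(adversarial_loss(NULL, 0.5, "vanilla", term = "generator"),
               log(2), tolerance = 1e-12)
  expect_equal(adversarial_loss(1, 0.25, "least_squares",
                                term = "generator"), 0.5625)
})

test_that("adversarial loss equals element-wise brute-force evaluation", {
  set.seed(101)
  for (i in 1:100) {
    dr <- stats::runif(sample(1:8, 1), 0.01, 0.99)
    df <- stats::runif(sample(1:8, 1), 0.01, 0.99)
    expect_equal(adversarial_loss(dr, df, "vanilla"),
                 oracle_adversarial(dr, df), tolerance = 1e-6)
  }
})

test_that("the contrastive term reduces to uniform softmax on equal similarities", {
  d <- 8L
  q <- rep(1 / sqrt(d), d)
  expect_equal(nce_term(q, q, rbind(q), tau = 0.07), log(2),
               tolerance = 1e-12)
  qm <- matrix(q, 255L, d, byrow = TRUE)
  expect_equal(nce_term(q, q, qm, tau = 0.07), log(256), tolerance = 1e-12)
  expect_error(nce_term(q, q[-1], rbind(q)), "dimension")
  expect_error(nce_term(q, q, rbind(q), tau = 0), "tau")
})

test_that("the contrastive term matches naive exp/sum evaluation", {
  set.seed(202)
  for (i in 1:100) {
    d <- sample(2:6, 1)
    N <- sample(1:8, 1)
    q <- unit_rows(1, d)[1, ]
    qp <- unit_rows(1, d)[1, ]
    qm <- unit_rows(N, d)
    tau <- stats::runif(1, 0.05, 1)
    expect_equal(nce_term(q, qp, qm, tau), oracle_nce(q, qp, qm, tau),
                 tolerance = 1e-6)
    expect_gte(nce_term(q, qp, qm, tau), 0)
  }
})

test_that("the contrastive term decreases as the positive similarity grows", {
  set.seed(7)
  d <- 6L
  qm <- unit_rows(4L, d)
  q <- unit_rows(1, d)[1, ]
  # rotate a positive towards q: similarity sweeps a grid, loss must fall
  sims <- seq(-0.9, 0.9, by = 0.1)
  base <- unit_rows(1, d)[1, ]
  perp <- base - sum(base * q) * q
  perp <- perp / sqrt(sum(perp^2))
  losses <- vapply(sims, function(s) {
    qp <- s * q + sqrt(1 - s^2) * perp
    nce_term(q, qp, qm, tau = 0.07)
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("patchwise loss equals the explicit double loop and is mean-invariant", {
  pfs <- make_patch_features(n_layers = 3L, S = 5L, d = 4L, seed = 33L)
  loop <- local({
    per_layer <- vapply(pfs$layers, function(l) {
      vals <- vapply(seq_len(nrow(l$queries)), function(s) {
        nce_term(l$queries[s, ], l$positives[s, ],
                 l$positives[-s, , drop = FALSE], pfs$tau)
      }, numeric(1))
      mean(vals)
    }, numeric(1))
    mean(per_layer)
  })
  expect_equal(patchwise_nce_loss(pfs), loop, tolerance = 1e-6)

  # duplicating every layer leaves the mean unchanged
  dup <- pfs
  dup$layers <- c(pfs$layers, pfs$layers)
  expect_equal(patchwise_nce_loss(dup), patchwise_nce_loss(pfs),
               tolerance = 1e-12)

  # single layer, single location is not defined without negatives, so the
  # smallest uniform case uses two locations with orthogonal embeddings
  one <- make_patch_features(1L, 2L, 4L, seed = 1L)
  one$layers[[1]]$queries <- diag(4L)[1:2, ]
  one$layers[[1]]$positives <- diag(4L)[3:4, ]
  expect_equal(patchwise_nce_loss(one), log(2), tolerance = 1e-12)

  empty <- structure(list(layers = list(), tau = 0.07),
                     class = "patch_features")
  expect_error(patchwise_nce_loss(empty), "empty")
})
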