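# ---------------------------------------------------------------------------
# GAN and patchwise contrastive losses.
# ---------------------------------------------------------------------------

#' Adversarial loss
#'
#' The two-player objective coupling generator and discriminator. In
#' `"vanilla"` mode the discriminator term is the value the discriminator
#' maximises, `mean(log D(y)) + mean(log(1 - D(G(x))))`, requiring scores in
#' (0, 1); the generator term is the non-saturating loss
#' `-mean(log D(G(x)))` (to be minimised). In `"least_squares"` mode
#' squared-error targets 1/0 replace the logarithms: the discriminator term
#' is `-(mean((D(y)-1)^2) + mean(D(G(x))^2))` (again a value to maximise)
#' and the generator term `mean((D(G(x))-1)^2)`.
#'
#' @param d_on_real discriminator scores on real target-class images (may be
#'   `NULL` for the generator term, which does not use them).
#' @param d_on_fake discriminator scores on generated images.
#' @param mode `"vanilla"` or `"least_squares"`.
#' @param term `"discriminator"` (default) or `"generator"`.
#' @return a scalar.
#' @export
adversarial_loss <- function(d_on_real, d_on_fake,
                             mode = c("vanilla", "least_squares"),
                             term = c("discriminator", "generator")) {
  mode <- match.arg(mode)
  term <- match.arg(term)
  d_on_fake <- as.numeric(d_on_fake)
  if (mode == "vanilla") {
    chk <- c(if (term == "discriminator") as.numeric(d_on_real), d_on_fake)
    if (any(chk <= 0 | chk >= 1))
      stop("vanilla adversarial loss requires scores strictly inside (0, 1)")
    if (term == "discriminator")
      return(mean(log(as.numeric(d_on_real))) + mean(log(1 - d_on_fake)))
    return(-mean(log(d_on_fake)))
  }
  if (term == "discriminator")
    return(-(mean((as.numeric(d_on_real) - 1)^2) + mean(d_on_fake^2)))
  mean((d_on_fake - 1)^2)
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Single patchwise noise-contrastive term
#'
#' The (N+1)-way cross-entropy classifying the positive example against N
#' negatives by scaled dot-product similarity:
#' `-log[ exp(q.q+ / tau) / (exp(q.q+ / tau) + sum_n exp(q.qn- / tau)) ]`,
#' computed with a log-sum-exp stabilisation. Always >= 0.
#'
#' @param q query embedding (numeric vector).
#' @param q_plus positive embedding, same length as `q`.
#' @param q_minus matrix of N negative embeddings (rows), same width.
#' @param tau temperature (> 0), default 0.07.
#' @return scalar cross-entropy.
#' @export
nce_term <- function(q, q_plus, q_minus, tau = 0.07) {
  if (tau <= 0) stop("tau must be > 0")
  q_minus <- rbind(q_minus)
  if (length(q) != length(q_plus) || ncol(q_minus) != length(q))
    stop("embedding dimensions do not match")
  if (nrow(q_minus) < 1L) stop("at least one negative is required")
  sims <- c(sum(q * q_plus), as.numeric(q_minus %*% q)) / tau
  logsumexp(sims) - sims[1L]
}

# Vectorised softmax cross-entropy over one layer's embeddings, with
# gradients. Q: S x d queries (synthesised image), K: S x d keys (original
# image); positive of query s is key s, negatives are the other S - 1 keys.
nce_layer_loss <- function(Q, K, tau, grad = FALSE) {
  logits <- tcrossprod(Q, K) / tau               # S x S
  m <- apply(logits, 1L, max)
  z <- exp(logits - m)
  p <- z / rowSums(z)
  S <- nrow(Q)
  loss <- -mean(log(p[cbind(seq_len(S), seq_len(S))]))
  if (!grad) return(list(loss = loss))
  dlog <- p
  diag(dlog) <- diag(dlog) - 1
  dlog <- dlog / S
  list(loss = loss, gQ = (dlog %*% K) / tau, gK = crossprod(dlog, Q) / tau)
}

#' Patchwise contrastive loss over a feature set
#'
#' Mean over selected encoder layers and sampled locations of [nce_term()],
#' using, for each query, the embeddings of the other sampled locations of
#' the original image as negatives.
#'
#' @param pfs a `patch_features` object from [sample_patch_features()].
#' @return scalar loss.
#' @export
patchwise_nce_loss <- function(pfs) {
  stopifnot(inherits(pfs, "patch_features"))
  if (length(pfs$layers) == 0L) stop("empty layer set")
  per_layer <- vapply(pfs$layers, function(l) {
    nce_layer_loss(l$queries, l$positives, pfs$tau)$loss
  }, numeric(1))
  mean(per_layer)
}
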