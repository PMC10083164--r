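#' @useDynLib octpreset, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Minimal CNN framework.
#
# Feature maps are numeric arrays [H, W, C]; batches are of size one (the
# translation networks train image-by-image). Layers are environments holding
# parameters and accumulated gradients; forward passes return a "tape" (the
# per-layer caches) so that several passes through the same network can be
# alive at once and back-propagated independently -- the generator update
# needs simultaneous tapes for G(x), G(y) and two encoder-only passes.
# ---------------------------------------------------------------------------

as_tensor <- function(x) {
  if (length(dim(x)) == 2L) array(x, c(dim(x), 1L)) else x
}

new_layer <- function(.cls, ...) {
  e <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  e$params <- character(0)
  class(e) <- c(.cls, "nn_layer")
  e
}

init_weight <- function(n_in, n_out, sd = 0.02) {
  matrix(stats::rnorm(n_in * n_out, sd = sd), n_in, n_out)
}

# -- convolution (pad applied here; C++ kernel assumes pad 0) ----------------

# init: "gauss" = N(0, 0.02) (suits norm-rescaled GAN stacks), "he" =
# N(0, sqrt(2 / fan_in)) (suits plain conv-relu stacks without norms)
nn_conv <- function(in_ch, out_ch, k, stride = 1L, pad = 0L,
                    pad_mode = c("zero", "reflect"),
                    init = c("gauss", "he")) {
  init <- match.arg(init)
  sd <- if (init == "he") sqrt(2 / (k * k * in_ch)) else 0.02
  l <- new_layer("conv", k = as.integer(k), stride = as.integer(stride),
                 pad = as.integer(pad), pad_mode = match.arg(pad_mode),
                 in_ch = in_ch, out_ch = out_ch,
                 W = init_weight(k * k * in_ch, out_ch, sd = sd),
                 b = numeric(out_ch))
  l$gW <- l$W * 0; l$gb <- l$b * 0
  l$params <- c("W", "b")
  l
}

forward.conv <- function(l, x) {
  fw <- conv2d_forward(x, l$W, l$b, l$k, l$stride, l$pad,
                       l$pad_mode == "reflect")
  list(out = fw$out, cache = list(col = fw$col, d = dim(x)))
}

backward.conv <- function(l, cache, g) {
  bw <- conv2d_backward(cache$col, l$W, g, cache$d[1L], cache$d[2L],
                        cache$d[3L], l$k, l$stride, l$pad,
                        l$pad_mode == "reflect")
  l$gW <- l$gW + bw$gw
  l$gb <- l$gb + bw$gb
  bw$gx
}

# -- instance normalisation (non-affine) -------------------------------------

nn_instnorm <- function(eps = 1e-5) new_layer("instnorm", eps = eps)

forward.instnorm <- function(l, x) {
  d <- dim(x); n <- d[1L] * d[2L]
  m <- matrix(x, n, d[3L])
  mu <- colMeans(m)
  ctr <- sweep(m, 2L, mu)
  sd_ <- sqrt(colMeans(ctr^2) + l$eps)
  y <- sweep(ctr, 2L, sd_, "/")
  list(out = array(y, d), cache = list(y = y, sd = sd_, d = d))
}

backward.instnorm <- function(l, cache, g) {
  d <- cache$d
  gm <- matrix(g, d[1L] * d[2L], d[3L])
  gy <- gm - matrix(colMeans(gm), nrow(gm), ncol(gm), byrow = TRUE) -
    cache$y * matrix(colMeans(gm * cache$y), nrow(gm), ncol(gm), byrow = TRUE)
  array(sweep(gy, 2L, cache$sd, "/"), d)
}

# -- pointwise activations ---------------------------------------------------

nn_relu <- function() new_layer("relu")
forward.relu <- function(l, x) list(out = pmax(x, 0), cache = x > 0)
backward.relu <- function(l, cache, g) g * cache

nn_lrelu <- function(alpha = 0.2) new_layer("lrelu", alpha = alpha)
forward.lrelu <- function(l, x) {
  list(out = ifelse(x > 0, x, l$alpha * x), cache = x > 0)
}
backward.lrelu <- function(l, cache, g) ifelse(cache, g, l$alpha * g)

# tanh squashed onto [0, 1]: images live on that range
nn_tanh01 <- function() new_layer("tanh01")
forward.tanh01 <- function(l, x) {
  y <- (tanh(x) + 1) / 2
  list(out = y, cache = y)
}
backward.tanh01 <- function(l, cache, g) g * (1 - (2 * cache - 1)^2) / 2

nn_sigmoid <- function() new_layer("sigmoid")
forward.sigmoid <- function(l, x) {
  y <- 1 / (1 + exp(-x))
  list(out = y, cache = y)
}
backward.sigmoid <- function(l, cache, g) g * cache * (1 - cache)

# -- nearest-neighbour 2x upsampling ----------------------------------------

nn_upsample2 <- function() new_layer("upsample2")
forward.upsample2 <- function(l, x) {
  d <- dim(x)
  y <- x[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), ,
         drop = FALSE]
  list(out = y, cache = d)
}
backward.upsample2 <- function(l, cache, g) {
  H2 <- dim(g)[1L]; W2 <- dim(g)[2L]
  o <- seq(1L, H2, 2L); e <- seq(2L, H2, 2L)
  oc <- seq(1L, W2, 2L); ec <- seq(2L, W2, 2L)
  g[o, oc, , drop = FALSE] + g[e, oc, , drop = FALSE] +
    g[o, ec, , drop = FALSE] + g[e, ec, , drop = FALSE]
}

# -- residual block: x + IN(conv(relu(IN(conv(x))))) -------------------------

nn_resblock <- function(ch) {
  new_layer("resblock", body = list(
    nn_conv(ch, ch, 3L, pad = 1L, pad_mode = "reflect"),
    nn_instnorm(),
    nn_relu(),
    nn_conv(ch, ch, 3L, pad = 1L, pad_mode = "reflect"),
    nn_instnorm()
  ))
}

forward.resblock <- function(l, x) {
  h <- x
  caches <- vector("list", length(l$body))
  for (i in seq_along(l$body)) {
    fw <- nn_forward(l$body[[i]], h)
    h <- fw$out
    caches[[i]] <- fw$cache
  }
  list(out = x + h, cache = caches)
}

backward.resblock <- function(l, cache, g) {
  gh <- g
  for (i in rev(seq_along(l$body)))
    gh <- nn_backward(l$body[[i]], cache[[i]], gh)
  g + gh
}

# -- identity (used as the index-0 tap point) --------------------------------

nn_identity <- function() new_layer("identity")
forward.identity <- function(l, x) list(out = x, cache = NULL)
backward.identity <- function(l, cache, g) g

# -- dense layer on row-matrices --------------------------------------------

nn_dense <- function(n_in, n_out) {
  l <- new_layer("dense", W = init_weight(n_in, n_out), b = numeric(n_out))
  l$gW <- l$W * 0; l$gb <- l$b * 0
  l$params <- c("W", "b")
  l
}
forward.dense <- function(l, x) {
  list(out = sweep(x %*% l$W, 2L, l$b, "+"), cache = x)
}
backward.dense <- function(l, cache, g) {
  l$gW <- l$gW + crossprod(cache, g)
  l$gb <- l$gb + colSums(g)
  g %*% t(l$W)
}

# -- dispatch ----------------------------------------------------------------

nn_forward <- function(l, x) {
  switch(class(l)[1L],
    conv = forward.conv(l, x), instnorm = forward.instnorm(l, x),
    relu = forward.relu(l, x), lrelu = forward.lrelu(l, x),
    tanh01 = forward.tanh01(l, x), sigmoid = forward.sigmoid(l, x),
    upsample2 = forward.upsample2(l, x), resblock = forward.resblock(l, x),
    identity = forward.identity(l, x), dense = forward.dense(l, x),
    stop("unknown layer kind: ", class(l)[1L]))
}

nn_backward <- function(l, cache, g) {
  switch(class(l)[1L],
    conv = backward.conv(l, cache, g), instnorm = backward.instnorm(l, cache, g),
    relu = backward.relu(l, cache, g), lrelu = backward.lrelu(l, cache, g),
    tanh01 = backward.tanh01(l, cache, g), sigmoid = backward.sigmoid(l, cache, g),
    upsample2 = backward.upsample2(l, cache, g),
    resblock = backward.resblock(l, cache, g),
    identity = backward.identity(l, cache, g),
    dense = backward.dense(l, cache, g),
    stop("unknown layer kind: ", class(l)[1L]))
}

# -- sequential container ----------------------------------------------------

nn_sequential <- function(layers) structure(list(layers = layers),
                                            class = "nn_sequential")

# Forward through layers 1..n_layers. `taps` are 0-based atomic layer indices
# (tap l = output of R-list layer l + 1). Returns out, per-layer caches, and
# the tapped feature maps.
seq_forward <- function(net, x, n_layers = NULL, taps = NULL) {
  layers <- net$layers
  n <- if (is.null(n_layers)) length(layers) else n_layers
  caches <- vector("list", n)
  tapped <- list()
  h <- x
  for (i in seq_len(n)) {
    fw <- nn_forward(layers[[i]], h)
    h <- fw$out
    caches[[i]] <- fw$cache
    if (!is.null(taps) && (i - 1L) %in% taps)
      tapped[[as.character(i - 1L)]] <- h
  }
  list(out = h, caches = caches, taps = tapped)
}

# Backward through the first n_layers of the tape. `extra` is a named list of
# gradients to inject at tapped outputs (names are 0-based layer indices).
seq_backward <- function(net, tape, g, extra = NULL, n_layers = NULL) {
  layers <- net$layers
  n <- if (is.null(n_layers)) length(tape$caches) else n_layers
  for (i in rev(seq_len(n))) {
    key <- as.character(i - 1L)
    if (!is.null(extra) && !is.null(extra[[key]])) g <- g + extra[[key]]
    g <- nn_backward(layers[[i]], tape$caches[[i]], g)
  }
  g
}

# -- parameter bookkeeping ---------------------------------------------------

nn_param_layers <- function(x) {
  if (inherits(x, "nn_sequential")) {
    return(unlist(lapply(x$layers, nn_param_layers), recursive = FALSE))
  }
  if (inherits(x, "nn_layer")) {
    if (class(x)[1L] == "resblock") {
      return(unlist(lapply(x$body, nn_param_layers), recursive = FALSE))
    }
    if (length(x$params)) return(list(x))
    return(list())
  }
  if (is.list(x)) return(unlist(lapply(x, nn_param_layers), recursive = FALSE))
  list()
}

nn_zero_grads <- function(x) {
  for (l in nn_param_layers(x))
    for (p in l$params) assign(paste0("g", p), get(p, envir = l) * 0, envir = l)
  invisible(NULL)
}

# Adam with bias correction; `t` is the global step count.
nn_adam_step <- function(x, lr, t, beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  for (l in nn_param_layers(x)) {
    for (p in l$params) {
      g <- get(paste0("g", p), envir = l)
      mn <- paste0("adam_m_", p); vn <- paste0("adam_v_", p)
      m <- if (exists(mn, envir = l)) get(mn, envir = l) else g * 0
      v <- if (exists(vn, envir = l)) get(vn, envir = l) else g * 0
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      assign(mn, m, envir = l); assign(vn, v, envir = l)
      mh <- m / (1 - beta1^t); vh <- v / (1 - beta2^t)
      assign(p, get(p, envir = l) - lr * mh / (sqrt(vh) + eps), envir = l)
    }
  }
  invisible(NULL)
}

# -- (de)serialisable weight snapshots ---------------------------------------

nn_state <- function(x) {
  lapply(nn_param_layers(x), function(l) {
    s <- lapply(l$params, function(p) get(p, envir = l))
    names(s) <- l$params
    s
  })
}

nn_load_state <- function(x, state) {
  pls <- nn_param_layers(x)
  stopifnot(length(pls) == length(state))
  for (i in seq_along(pls))
    for (p in pls[[i]]$params) assign(p, state[[i]][[p]], envir = pls[[i]])
  invisible(x)
}
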