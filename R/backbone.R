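# Compact convolutional backbone, CPU-scale. Four conv blocks with ReLU on a
# 32x32 stem reduction of the 224x224x3 model input, followed by a linear
# head on the flattened last feature map. Convolutions are implemented as
# im2col gathers + dense matrix products; the backward scatter uses a
# precomputed sparse matrix. Activations are stored as N x (H*W*C) matrices
# in channel-major layout (column index = pixel + (channel-1)*H*W, pixels in
# R column-major order).

.stem_pool_factor <- 7L # 224 -> 32

# Fixed stem: channel mean then 7x7 non-overlapping average pooling.
# Parameter-free, hence shared by the frozen and fine-tuned regimes.
stem_reduce <- function(x) {
  stopifnot(length(dim(x)) == 3, dim(x)[1] %% .stem_pool_factor == 0,
            dim(x)[2] %% .stem_pool_factor == 0)
  m <- (x[, , 1] + x[, , 2] + x[, , 3]) / 3
  f <- .stem_pool_factor
  h <- nrow(m) %/% f
  w <- ncol(m) %/% f
  a <- array(m, c(f, h, f * w))
  m1 <- colMeans(a)                 # h x (f*w), mean over row blocks
  dim(m1) <- c(h, f, w)
  m2 <- apply(m1, c(1, 3), mean)    # h x w
  as.vector(m2)
}

#' Prepare model inputs for the compact backbone
#'
#' Runs [to_model_input()] and the backbone's fixed stem reduction on a list
#' of grayscale images, returning the matrix the trainer consumes. An
#' optional augmentation policy is applied between the two steps (training
#' split only; per-image seeds derive from `rng_seed`).
#'
#' @param images list of grayscale image matrices (0..255).
#' @param policy optional [augment_policy()]; `NULL` = no augmentation.
#' @param rng_seed root seed for per-image augmentation draws.
#' @return numeric matrix, one row per image (32 x 32 stem features).
#' @export
prepare_inputs <- function(images, policy = NULL, rng_seed = 1) {
  n <- length(images)
  out <- matrix(0, n, 32L * 32L)
  for (i in seq_len(n)) {
    x <- to_model_input(images[[i]])
    if (!is.null(policy) && policy$enabled)
      x <- augment(x, policy, seed_stream(rng_seed, i - 1))
    out[i, ] <- stem_reduce(x)
  }
  out
}

# architecture: list of conv layer specs for 32x32x1 input
.compact_arch_spec <- function() {
  list(
    list(k = 5L, s = 1L, p = 2L, f = 8L),
    list(k = 3L, s = 2L, p = 1L, f = 16L),
    list(k = 3L, s = 2L, p = 1L, f = 32L),
    list(k = 3L, s = 2L, p = 1L, f = 64L)
  )
}

# Precompute gather indices and the backward scatter matrix for one conv
# layer. Returns layer metadata.
.conv_meta <- function(hin, win, cin, k, s, p, f) {
  ho <- (hin + 2L * p - k) %/% s + 1L
  wo <- (win + 2L * p - k) %/% s + 1L
  P <- ho * wo
  Q <- k * k * cin
  # output positions in column-major order over (yo, xo)
  yo <- rep(seq_len(ho), times = wo)
  xo <- rep(seq_len(wo), each = ho)
  y0 <- (yo - 1L) * s - p # zero-based top row of patch
  x0 <- (xo - 1L) * s - p
  # patch element offsets (dy, dx, c), dy fastest
  dy <- rep(seq_len(k) - 1L, times = k * cin)
  dx <- rep(rep(seq_len(k) - 1L, each = k), times = cin)
  cc <- rep(seq_len(cin) - 1L, each = k * k)
  # idx[q, p]: linear input index (1-based) or pad
  Y <- outer(dy, y0, `+`) # Q x P, zero-based rows
  X <- outer(dx, x0, `+`)
  C <- matrix(cc, Q, P)
  inside <- Y >= 0L & Y < hin & X >= 0L & X < win
  lin <- Y + X * hin + C * (hin * win) + 1L
  pad_col <- hin * win * cin + 1L
  idx <- ifelse(inside, lin, pad_col)
  # gather/scatter use q-major column order (column (q-1)*P + p), so that a
  # plain dim<- turns the N x (P*Q) gather into the (N*P) x Q patch matrix
  idxvec <- as.vector(t(idx))
  rows <- seq_len(P * Q) # r = (q-1)*P + p, p fastest
  keep <- as.vector(t(inside))
  S <- Matrix::sparseMatrix(i = rows[keep], j = idxvec[keep], x = 1,
                            dims = c(P * Q, hin * win * cin))
  list(hin = hin, win = win, cin = cin, k = k, s = s, p = p, f = f,
       ho = ho, wo = wo, P = P, Q = Q, idxvec = idxvec,
       pad_col = pad_col, S = S)
}

.compact_arch <- function(hin = 32L, win = 32L, cin = 1L) {
  layers <- list()
  for (spec in .compact_arch_spec()) {
    m <- .conv_meta(hin, win, cin, spec$k, spec$s, spec$p, spec$f)
    layers[[length(layers) + 1]] <- m
    hin <- m$ho; win <- m$wo; cin <- m$f
  }
  list(layers = layers, feat_dim = hin * win * cin)
}

# He-normal initialization of all parameters (conv stack + head)
.init_params <- function(arch, n_classes, seed) {
  with_seed(seed, {
    conv_w <- lapply(arch$layers, function(m)
      matrix(stats::rnorm(m$Q * m$f, 0, sqrt(2 / m$Q)), m$Q, m$f))
    conv_b <- lapply(arch$layers, function(m) numeric(m$f))
    # zero-initialized probe head: symmetric start, ties broken by the
    # first gradient step
    head_w <- matrix(0, arch$feat_dim, n_classes)
    head_b <- numeric(n_classes)
    list(conv_w = conv_w, conv_b = conv_b, head_w = head_w, head_b = head_b)
  })
}

# forward one conv layer; X is N x (hin*win*cin). Returns list(out, cache).
.conv_forward <- function(X, meta, W, b) {
  N <- nrow(X)
  Xa <- cbind(X, 0)
  col <- Xa[, meta$idxvec, drop = FALSE]          # N x (P*Q), q-major
  dim(col) <- c(N * meta$P, meta$Q)
  Y <- col %*% W
  Y <- sweep(Y, 2, b, `+`)
  pre <- Y
  Y[Y < 0] <- 0
  out <- Y
  dim(out) <- c(N, meta$P * meta$f)               # channel-major
  list(out = out, col = col, pre = pre)
}

# backward one conv layer. dOut is N x (P*f). Returns list(dX, dW, db).
.conv_backward <- function(dOut, meta, W, cache, need_dx = TRUE) {
  N <- nrow(dOut)
  dY <- dOut
  dim(dY) <- c(N * meta$P, meta$f)
  dY <- dY * (cache$pre > 0)
  dW <- crossprod(cache$col, dY)
  db <- colSums(dY)
  dX <- NULL
  if (need_dx) {
    dcol <- dY %*% t(W)                           # (N*P) x Q
    dim(dcol) <- c(N, meta$P * meta$Q)            # q-major columns
    dX <- as.matrix(dcol %*% meta$S)              # N x (hin*win*cin)
  }
  list(dX = dX, dW = dW, db = db)
}

# full backbone forward; X is N x 1024 stem output. Returns features
# (N x feat_dim) and per-layer caches when requested.
backbone_forward <- function(params, arch, X, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(arch$layers)) else NULL
  A <- X
  for (i in seq_along(arch$layers)) {
    fw <- .conv_forward(A, arch$layers[[i]], params$conv_w[[i]],
                        params$conv_b[[i]])
    if (keep_cache) {
      fw$input <- A
      caches[[i]] <- fw
    }
    A <- fw$out
  }
  list(features = A, caches = caches)
}

# softmax cross-entropy loss and gradient; y is integer class index vector
.softmax_ce <- function(logits, y) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  p <- e / rowSums(e)
  n <- nrow(logits)
  loss <- -mean(log(pmax(p[cbind(seq_len(n), y)], 1e-12)))
  g <- p
  g[cbind(seq_len(n), y)] <- g[cbind(seq_len(n), y)] - 1
  list(loss = loss, grad = g / n, probs = p)
}

# AdamW state and update (decoupled weight decay)
.adamw_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)

.adamw_step <- function(params, grads, state, lr, wd = 1e-4,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    step <- (state$m[[k]] / b1t) / (sqrt(state$v[[k]] / b2t) + eps)
    params[[k]] <- params[[k]] - lr * (step + wd * params[[k]])
  }
  list(params = params, state = state)
}

# flatten/unflatten param lists for the optimizer
.flatten_params <- function(p) {
  out <- list()
  for (i in seq_along(p$conv_w)) {
    out[[paste0("cw", i)]] <- p$conv_w[[i]]
    out[[paste0("cb", i)]] <- p$conv_b[[i]]
  }
  out$hw <- p$head_w
  out$hb <- p$head_b
  out
}

.unflatten_params <- function(fl, n_layers) {
  list(conv_w = lapply(seq_len(n_layers), function(i) fl[[paste0("cw", i)]]),
       conv_b = lapply(seq_len(n_layers), function(i) fl[[paste0("cb", i)]]),
       head_w = fl$hw, head_b = fl$hb)
}

#' Checksum of a classifier's frozen backbone parameters
#'
#' A cheap fingerprint of the convolutional-stack parameters, used to verify
#' the freeze contract of linear probing (the checksum must be identical
#' before and after [linear_probe()] training).
#'
#' @param model a trained classifier (see [linear_probe()]).
#' @return numeric scalar.
#' @export
backbone_checksum <- function(model) {
  v <- c(unlist(model$params$conv_w), unlist(model$params$conv_b))
  sum(v * seq_along(v) %% 97)
}
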