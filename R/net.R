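# Minimal convolutional network engine used by the compact detector.
#
# Feature maps are stored as dense matrices with one row per pixel and one
# column per channel; a batch of N images stacks rows image-major, pixels
# row-major within an image.  3x3 same-padding convolutions are evaluated as
# k*k shifted matrix products against per-offset weight blocks, which keeps
# everything inside BLAS.  For a fixed kernel offset the map from output
# pixel to padded input pixel is injective, so the backward scatter-add is a
# plain indexed assignment with no collisions; the same holds for
# non-overlapping 2x2 max-pooling windows.

conv_geom <- function(H, W, k = 3L) {
  pad <- (k - 1L) %/% 2L
  Hp <- H + 2L * pad
  Wp <- W + 2L * pad
  r <- rep(seq_len(H), each = W)
  cc <- rep(seq_len(W), times = H)
  inner <- (r + pad - 1L) * Wp + (cc + pad)
  idx <- vector("list", k * k)
  j <- 0L
  for (dr in seq_len(k)) {
    for (dc in seq_len(k)) {
      j <- j + 1L
      idx[[j]] <- (r + dr - 2L) * Wp + (cc + dc - 1L)
    }
  }
  list(H = H, W = W, k = k, kk = k * k, HW = H * W, LP = Hp * Wp,
       inner = inner, idx = idx, batch = new.env(parent = emptyenv()))
}

conv_batch_idx <- function(g, N) {
  key <- as.character(N)
  b <- get0(key, envir = g$batch)
  if (!is.null(b)) return(b)
  off <- rep((seq_len(N) - 1L) * g$LP, each = g$HW)
  b <- list(inner = rep(g$inner, N) + off,
            idx = lapply(g$idx, function(ix) rep(ix, N) + off))
  assign(key, b, envir = g$batch)
  b
}

conv_layer_init <- function(cin, cout, k = 3L, w_sd = NULL, bias = 0) {
  if (is.null(w_sd)) w_sd <- sqrt(2 / (k * k * cin))  # He initialization
  list(W = matrix(rnorm(k * k * cin * cout, sd = w_sd), k * k * cin, cout),
       b = rep(bias, cout), cin = cin, cout = cout)
}

conv_forward <- function(X, lay, g, N) {
  bi <- conv_batch_idx(g, N)
  Xp <- matrix(0, g$LP * N, lay$cin)
  Xp[bi$inner, ] <- X
  Y <- matrix(lay$b, nrow = g$HW * N, ncol = lay$cout, byrow = TRUE)
  for (j in seq_len(g$kk)) {
    rows <- ((j - 1L) * lay$cin + 1L):(j * lay$cin)
    Y <- Y + Xp[bi$idx[[j]], , drop = FALSE] %*% lay$W[rows, , drop = FALSE]
  }
  list(Y = Y, Xp = Xp)
}

conv_backward <- function(dY, cache, lay, g, N) {
  bi <- conv_batch_idx(g, N)
  dW <- matrix(0, nrow(lay$W), ncol(lay$W))
  dXp <- matrix(0, g$LP * N, lay$cin)
  for (j in seq_len(g$kk)) {
    rows <- ((j - 1L) * lay$cin + 1L):(j * lay$cin)
    dW[rows, ] <- crossprod(cache$Xp[bi$idx[[j]], , drop = FALSE], dY)
    dXp[bi$idx[[j]], ] <- dXp[bi$idx[[j]], , drop = FALSE] +
      dY %*% t(lay$W[rows, , drop = FALSE])
  }
  list(dW = dW, db = colSums(dY), dX = dXp[bi$inner, , drop = FALSE])
}

pool_geom <- function(H, W) {
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  Ho <- H %/% 2L
  Wo <- W %/% 2L
  ro <- rep(seq_len(Ho), each = Wo)
  co <- rep(seq_len(Wo), times = Ho)
  r0 <- (ro - 1L) * 2L
  c0 <- (co - 1L) * 2L
  idx4 <- cbind(r0 * W + c0 + 1L, r0 * W + c0 + 2L,
                (r0 + 1L) * W + c0 + 1L, (r0 + 1L) * W + c0 + 2L)
  list(HW = H * W, HWo = Ho * Wo, idx4 = idx4,
       batch = new.env(parent = emptyenv()))
}

pool_batch_idx <- function(g, N) {
  key <- as.character(N)
  b <- get0(key, envir = g$batch)
  if (!is.null(b)) return(b)
  off <- rep((seq_len(N) - 1L) * g$HW, each = g$HWo)
  b <- g$idx4[rep(seq_len(g$HWo), N), , drop = FALSE] + off
  assign(key, b, envir = g$batch)
  b
}

pool_forward <- function(X, g, N) {
  idx4 <- pool_batch_idx(g, N)
  M <- nrow(idx4)
  C <- ncol(X)
  Y <- matrix(0, M, C)
  arg <- matrix(0L, M, C)
  sel <- seq_len(M)
  for (ch in seq_len(C)) {
    V <- matrix(X[, ch][idx4], M, 4L)
    w <- max.col(V, ties.method = "first")
    Y[, ch] <- V[cbind(sel, w)]
    arg[, ch] <- idx4[cbind(sel, w)]
  }
  list(Y = Y, arg = arg, n_in = nrow(X))
}

pool_backward <- function(dY, cache) {
  dX <- matrix(0, cache$n_in, ncol(dY))
  for (ch in seq_len(ncol(dY))) {
    dX[cbind(cache$arg[, ch], ch)] <- dY[, ch]
  }
  dX
}

# ---- network: 3 conv+pool stages (stride 8), then cls + box heads ----------

net_init <- function(input_size, n_anchors_per_cell,
                     channels = c(16L, 32L, 48L), prior_prob = 0.01) {
  stopifnot(input_size %% 8L == 0L)
  s <- input_size
  geoms <- list(
    c1 = conv_geom(s, s), p1 = pool_geom(s, s),
    c2 = conv_geom(s %/% 2L, s %/% 2L), p2 = pool_geom(s %/% 2L, s %/% 2L),
    c3 = conv_geom(s %/% 4L, s %/% 4L), p3 = pool_geom(s %/% 4L, s %/% 4L),
    head = conv_geom(s %/% 8L, s %/% 8L)
  )
  A <- n_anchors_per_cell
  layers <- list(
    conv1 = conv_layer_init(1L, channels[1]),
    conv2 = conv_layer_init(channels[1], channels[2]),
    conv3 = conv_layer_init(channels[2], channels[3]),
    # classification bias starts at the focal-loss prior so an untrained
    # network scores every anchor near prior_prob, not 0.5
    cls = conv_layer_init(channels[3], A, w_sd = 0.01,
                          bias = -log((1 - prior_prob) / prior_prob)),
    box = conv_layer_init(channels[3], 4L * A, w_sd = 0.01)
  )
  list(layers = layers, geoms = geoms, input_size = input_size,
       n_anchors_per_cell = A, n_cells = (s %/% 8L)^2)
}

net_forward <- function(net, X, N, keep_cache = TRUE) {
  g <- net$geoms
  L <- net$layers
  c1 <- conv_forward(X, L$conv1, g$c1, N)
  a1 <- pmax(c1$Y, 0)
  p1 <- pool_forward(a1, g$p1, N)
  c2 <- conv_forward(p1$Y, L$conv2, g$c2, N)
  a2 <- pmax(c2$Y, 0)
  p2 <- pool_forward(a2, g$p2, N)
  c3 <- conv_forward(p2$Y, L$conv3, g$c3, N)
  a3 <- pmax(c3$Y, 0)
  p3 <- pool_forward(a3, g$p3, N)
  cl <- conv_forward(p3$Y, L$cls, g$head, N)
  bx <- conv_forward(p3$Y, L$box, g$head, N)
  out <- list(logits = cl$Y, box = bx$Y)
  if (keep_cache) {
    out$cache <- list(c1 = c1, a1 = a1, p1 = p1, c2 = c2, a2 = a2, p2 = p2,
                      c3 = c3, a3 = a3, p3 = p3, cl = cl, bx = bx)
  }
  out
}

net_backward <- function(net, fwd, dlogits, dbox, N) {
  g <- net$geoms
  L <- net$layers
  ch <- fwd$cache
  b_cl <- conv_backward(dlogits, ch$cl, L$cls, g$head, N)
  b_bx <- conv_backward(dbox, ch$bx, L$box, g$head, N)
  d <- pool_backward(b_cl$dX + b_bx$dX, ch$p3)
  d <- d * (ch$a3 > 0)
  b3 <- conv_backward(d, ch$c3, L$conv3, g$c3, N)
  d <- pool_backward(b3$dX, ch$p2)
  d <- d * (ch$a2 > 0)
  b2 <- conv_backward(d, ch$c2, L$conv2, g$c2, N)
  d <- pool_backward(b2$dX, ch$p1)
  d <- d * (ch$a1 > 0)
  b1 <- conv_backward(d, ch$c1, L$conv1, g$c1, N)
  list(conv1 = b1, conv2 = b2, conv3 = b3, cls = b_cl, box = b_bx)
}

# ---- Adam optimizer ---------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(l) list(
    mW = matrix(0, nrow(l$W), ncol(l$W)), vW = matrix(0, nrow(l$W), ncol(l$W)),
    mb = numeric(length(l$b)), vb = numeric(length(l$b))
  ))
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (nm in names(layers)) {
    s <- state[[nm]]
    gW <- grads[[nm]]$dW
    gb <- grads[[nm]]$db
    s$mW <- beta1 * s$mW + (1 - beta1) * gW
    s$vW <- beta2 * s$vW + (1 - beta2) * gW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * gb
    s$vb <- beta2 * s$vb + (1 - beta2) * gb^2
    layers[[nm]]$W <- layers[[nm]]$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    layers[[nm]]$b <- layers[[nm]]$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[nm]] <- s
  }
  list(layers = layers, state = state)
}

# image matrix (H x W) -> pixel-row-major column vector matching the engine
img_to_row_major <- function(img) {
  matrix(as.vector(t(img)), ncol = 1L)
}
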