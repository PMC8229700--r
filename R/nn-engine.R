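# Minimal CNN engine on BLAS matrix products.
#
# Batch layout: a matrix X of shape (h*w*c) x N, each column one image,
# flattened column-major as an (h, w, c) array (row index fastest, then
# column, then channel). Convolutions use gather-index im2col plans that are
# computed per (layer, input size) and cached; gradients scatter back with
# rowsum(). All learnable layers implement forward/backward pairs; training
# is plain SGD with momentum.

conv_plan <- function(h, w, cin, k, stride, pad) {
  hp <- h + 2L * pad; wp <- w + 2L * pad
  ho <- (hp - k) %/% stride + 1L
  wo <- (wp - k) %/% stride + 1L
  if (ho < 1 || wo < 1) abort("Feature map too small for this layer.")
  # original pixels inside the padded flat layout
  rr <- pad + seq_len(h)
  cc <- pad + seq_len(w) - 1L
  inner_hw <- as.vector(outer(rr, hp * cc, "+"))
  inner <- as.vector(outer(inner_hw, hp * wp * (seq_len(cin) - 1L), "+"))
  # within-patch offsets (k x k x cin), patch-fastest ordering
  po <- as.vector(outer(0:(k - 1L), hp * (0:(k - 1L)), "+"))
  patch_off <- as.vector(outer(po, hp * wp * (0:(cin - 1L)), "+"))
  # top-left 1-based index of each output position (ho fastest)
  pos <- as.vector(outer(stride * (0:(ho - 1L)), hp * stride * (0:(wo - 1L)), "+")) + 1L
  gidx <- as.vector(outer(patch_off, pos, "+"))
  list(hp = hp, wp = wp, ho = ho, wo = wo, k = k, cin = cin,
       inner = inner, gidx = gidx, ug = sort(unique(gidx)),
       npad = hp * wp * cin)
}

conv_forward <- function(X, plan, W, b, n_out) {
  N <- ncol(X)
  Xp <- matrix(0, plan$npad, N)
  Xp[plan$inner, ] <- X
  M <- Xp[plan$gidx, , drop = FALSE]
  kkc <- plan$k^2 * plan$cin
  P <- plan$ho * plan$wo
  dim(M) <- c(kkc, P * N)
  Y <- crossprod(W, M) + b          # cout x (P*N); b recycles down columns
  dim(Y) <- c(n_out, P, N)
  Y <- aperm(Y, c(2, 1, 3))
  dim(Y) <- c(P * n_out, N)
  list(out = Y, M = M)
}

conv_backward <- function(dY, cache, plan, W, n_out) {
  N <- ncol(dY)
  P <- plan$ho * plan$wo
  dim(dY) <- c(P, n_out, N)
  dY <- aperm(dY, c(2, 1, 3))
  dim(dY) <- c(n_out, P * N)
  dW <- tcrossprod(cache$M, dY)     # kkc x cout
  db <- rowSums(dY)
  dM <- crossprod(t(W), dY)         # kkc x (P*N)  == W %*% dY
  kkc <- plan$k^2 * plan$cin
  dim(dM) <- c(kkc * P, N)
  dXp <- matrix(0, plan$npad, N)
  dXp[plan$ug, ] <- rowsum(dM, plan$gidx, reorder = TRUE)
  dX <- dXp[plan$inner, , drop = FALSE]
  list(dX = dX, dW = dW, db = db)
}

pool_plan <- function(h, w, c, k, stride, pad) {
  hp <- h + 2L * pad; wp <- w + 2L * pad
  ho <- (hp - k) %/% stride + 1L
  wo <- (wp - k) %/% stride + 1L
  rr <- pad + seq_len(h)
  cc <- pad + seq_len(w) - 1L
  inner_hw <- as.vector(outer(rr, hp * cc, "+"))
  inner <- as.vector(outer(inner_hw, hp * wp * (seq_len(c) - 1L), "+"))
  po <- as.vector(outer(0:(k - 1L), hp * (0:(k - 1L)), "+"))
  pos <- as.vector(outer(stride * (0:(ho - 1L)), hp * stride * (0:(wo - 1L)), "+")) + 1L
  pos_all <- as.vector(outer(pos, hp * wp * (0:(c - 1L)), "+"))
  gidx <- as.vector(outer(po, pos_all, "+"))
  list(hp = hp, wp = wp, ho = ho, wo = wo, k = k, c = c,
       inner = inner, gidx = gidx, npad = hp * wp * c)
}

pool_forward <- function(X, plan) {
  N <- ncol(X)
  Xp <- matrix(-Inf, plan$npad, N)
  Xp[plan$inner, ] <- X
  M <- Xp[plan$gidx, , drop = FALSE]
  kk <- plan$k^2
  S <- plan$ho * plan$wo * plan$c    # slots per image
  dim(M) <- c(kk, S * N)
  val <- M[1, ]
  amx <- rep(1L, S * N)
  for (j in 2:kk) {
    upd <- M[j, ] > val
    val[upd] <- M[j, upd]
    amx[upd] <- j
  }
  out <- matrix(val, S, N)
  list(out = out, amx = amx)
}

pool_backward <- function(dY, cache, plan) {
  N <- ncol(dY)
  kk <- plan$k^2
  S <- plan$ho * plan$wo * plan$c
  slot <- rep.int(seq_len(S) - 1L, N)
  pidx <- plan$gidx[slot * kk + cache$amx]          # padded flat index, per image
  li <- pidx + rep(seq_len(N) - 1L, each = S) * plan$npad
  dXp <- matrix(0, plan$npad, N)
  dXp[li] <- as.vector(dY)   # 2x2/stride-2 windows never overlap
  dXp[plan$inner, , drop = FALSE]
}

bn_forward <- function(X, P, C, gamma, beta, run_mean, run_var,
                       training, momentum = 0.1, eps = 1e-5) {
  N <- ncol(X)
  dim(X) <- c(P, C, N)
  Z <- aperm(X, c(1, 3, 2))
  dim(Z) <- c(P * N, C)
  if (training) {
    mu <- colMeans(Z)
    v <- colMeans(Z^2) - mu^2
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean; v <- run_var
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- (Z - rep(mu, each = P * N)) * rep(istd, each = P * N)
  Y <- xhat * rep(gamma, each = P * N) + rep(beta, each = P * N)
  dim(Y) <- c(P, N, C)
  Y <- aperm(Y, c(1, 3, 2))
  dim(Y) <- c(P * C, N)
  list(out = Y, xhat = xhat, istd = istd, run_mean = run_mean,
       run_var = run_var)
}

bn_backward <- function(dY, cache, P, C, gamma) {
  N <- ncol(dY)
  dim(dY) <- c(P, C, N)
  dZ <- aperm(dY, c(1, 3, 2))
  dim(dZ) <- c(P * N, C)
  m <- P * N
  xhat <- cache$xhat
  dgamma <- colSums(dZ * xhat)
  dbeta <- colSums(dZ)
  gi <- rep(gamma * cache$istd, each = m)
  dx <- gi * (dZ - rep(dbeta / m, each = m) - xhat * rep(dgamma / m, each = m))
  dim(dx) <- c(P, N, C)
  dx <- aperm(dx, c(1, 3, 2))
  dim(dx) <- c(P * C, N)
  list(dX = dx, dgamma = dgamma, dbeta = dbeta)
}

gmp_forward <- function(X, P, C) {
  N <- ncol(X)
  dim(X) <- c(P, C * N)
  val <- X[1, ]
  amx <- rep(1L, C * N)
  if (P > 1) {
    for (j in 2:P) {
      upd <- X[j, ] > val
      val[upd] <- X[j, upd]
      amx[upd] <- j
    }
  }
  list(out = matrix(val, C, N), amx = amx)
}

gmp_backward <- function(dY, cache, P, C) {
  N <- ncol(dY)
  li <- cache$amx + (seq_len(C * N) - 1L) * P
  dX <- numeric(P * C * N)
  dX[li] <- as.vector(dY)
  matrix(dX, P * C, N)
}

softmax_probs <- function(logits) {
  z <- logits - rep(apply(logits, 2, max), each = nrow(logits))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(logits))
}

cross_entropy_loss <- function(probs, y_idx) {
  N <- ncol(probs)
  p <- probs[cbind(y_idx, seq_len(N))]
  -mean(log(pmax(p, 1e-12)))
}
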