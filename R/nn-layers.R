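# Low-level neural network primitives with explicit forward/backward
# passes. Tensor conventions:
#   image batches   : array (H, W, C, B)
#   token matrices  : matrix (rows = tokens or samples, cols = features)
# Every forward returns list(out, cache); every backward takes (cache,
# grad wrt out) and returns list(dx, and parameter gradients).

# ---- convolution (stride-s, zero padding, im2col) -------------------------

# Precompute the im2col gather index for one padded image. Rows are output
# positions (column-major over Ho x Wo), columns kernel taps (row offset
# fastest, then column offset, then input channel).
im2col_index <- function(h, w, c_in, k, stride, pad) {
  hp <- h + 2L * pad
  wp <- w + 2L * pad
  ho <- (hp - k) %/% stride + 1L
  wo <- (wp - k) %/% stride + 1L
  i_vec <- rep(seq_len(ho), times = wo)
  j_vec <- rep(seq_len(wo), each = ho)
  base_r <- (i_vec - 1L) * stride
  base_c <- (j_vec - 1L) * stride
  off_r <- rep(rep(seq_len(k), times = k), times = c_in)
  off_c <- rep(rep(seq_len(k), each = k), times = c_in)
  off_ch <- rep(seq_len(c_in), each = k * k)
  idx <- outer(base_r, off_r, "+") +
    hp * outer(base_c, off_c - 1L, "+") +
    matrix((off_ch - 1L) * hp * wp,
      nrow = length(base_r),
      ncol = length(off_ch), byrow = TRUE
    )
  list(idx = idx, ho = ho, wo = wo, hp = hp, wp = wp)
}

pad_batch <- function(x, pad) {
  if (pad == 0) {
    return(x)
  }
  d <- dim(x)
  out <- array(0, dim = c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  out
}

# x: (H, W, Cin, B); W: matrix (k*k*Cin) x Cout; b: length Cout
conv_forward <- function(x, W, b, stride = 2L, pad = 1L) {
  d <- dim(x)
  k <- as.integer(sqrt(nrow(W) / d[3]))
  ii <- im2col_index(d[1], d[2], d[3], k, stride, pad)
  xp <- pad_batch(x, pad)
  lp <- ii$hp * ii$wp * d[3]
  P <- nrow(ii$idx)
  B <- d[4]
  X2 <- matrix(0, nrow = B * P, ncol = ncol(ii$idx))
  xp_vec <- as.vector(xp)
  for (bi in seq_len(B)) {
    X2[(bi - 1L) * P + seq_len(P), ] <- xp_vec[ii$idx + (bi - 1L) * lp]
  }
  y_mat <- X2 %*% W
  y_mat <- sweep(y_mat, 2, b, "+")
  cout <- ncol(W)
  y <- aperm(array(y_mat, dim = c(P, B, cout)), c(1, 3, 2))
  dim(y) <- c(ii$ho, ii$wo, cout, B)
  list(
    out = y,
    cache = list(
      X2 = X2, W = W, ii = ii, in_dim = d, stride = stride,
      pad = pad, lp = lp, P = P, B = B
    )
  )
}

conv_backward <- function(cache, dy) {
  P <- cache$P
  B <- cache$B
  cout <- ncol(cache$W)
  dy_mat <- aperm(array(dy, dim = c(P, cout, B)), c(1, 3, 2))
  dim(dy_mat) <- c(P * B, cout)
  dW <- crossprod(cache$X2, dy_mat)
  db <- colSums(dy_mat)
  dX2 <- tcrossprod(dy_mat, cache$W)
  d <- cache$in_dim
  dxp_vec <- numeric(cache$lp * B)
  offs <- (seq_len(B) - 1L) * cache$lp
  for (q in seq_len(ncol(cache$ii$idx))) {
    gi <- as.vector(outer(cache$ii$idx[, q], offs, "+"))
    dxp_vec[gi] <- dxp_vec[gi] + dX2[, q]
  }
  dxp <- array(dxp_vec, dim = c(cache$ii$hp, cache$ii$wp, d[3], B))
  pad <- cache$pad
  dx <- dxp[pad + seq_len(d[1]), pad + seq_len(d[2]), , , drop = FALSE]
  dim(dx) <- d
  list(dx = dx, dW = dW, db = db)
}

# ---- pointwise and pooling ------------------------------------------------

relu_forward <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_backward <- function(cache, dy) dy * cache

# (H, W, C, B) -> (B x C)
gap_forward <- function(x) {
  d <- dim(x)
  m <- matrix(x, nrow = d[1] * d[2], ncol = d[3] * d[4])
  cm <- colMeans(m)
  out <- t(matrix(cm, nrow = d[3], ncol = d[4]))
  list(out = out, cache = d)
}

gap_backward <- function(cache, dy) {
  d <- cache
  vals <- as.vector(t(dy)) / (d[1] * d[2])
  array(rep(vals, each = d[1] * d[2]), dim = d)
}

# ---- dense ----------------------------------------------------------------

dense_forward <- function(x, W, b) {
  y <- x %*% W
  y <- sweep(y, 2, b, "+")
  list(out = y, cache = list(x = x, W = W))
}

dense_backward <- function(cache, dy) {
  list(
    dx = tcrossprod(dy, cache$W),
    dW = crossprod(cache$x, dy),
    db = colSums(dy)
  )
}

# ---- layer norm over the feature dimension --------------------------------

layernorm_forward <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- sweep(xhat, 2, gamma, "*")
  out <- sweep(out, 2, beta, "+")
  list(out = out, cache = list(xhat = xhat, inv = inv, gamma = gamma))
}

layernorm_backward <- function(cache, dy) {
  xhat <- cache$xhat
  d <- ncol(xhat)
  dxhat <- sweep(dy, 2, cache$gamma, "*")
  s1 <- rowSums(dxhat)
  s2 <- rowSums(dxhat * xhat)
  dx <- (cache$inv / d) * (d * dxhat - s1 - xhat * s2)
  list(
    dx = dx,
    dgamma = colSums(dy * xhat),
    dbeta = colSums(dy)
  )
}

# ---- softmax / cross-entropy ----------------------------------------------

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- multi-head self-attention over one specimen's tokens -----------------

mha_forward <- function(x, p, n_heads) {
  d <- ncol(x)
  dh <- d %/% n_heads
  q <- sweep(x %*% p$Wq, 2, p$bq, "+")
  k <- sweep(x %*% p$Wk, 2, p$bk, "+")
  v <- sweep(x %*% p$Wv, 2, p$bv, "+")
  o <- matrix(0, nrow(x), d)
  att <- vector("list", n_heads)
  for (hi in seq_len(n_heads)) {
    cols <- (hi - 1L) * dh + seq_len(dh)
    s <- tcrossprod(q[, cols, drop = FALSE], k[, cols, drop = FALSE]) /
      sqrt(dh)
    a <- softmax_rows(s)
    att[[hi]] <- a
    o[, cols] <- a %*% v[, cols, drop = FALSE]
  }
  y <- sweep(o %*% p$Wo, 2, p$bo, "+")
  list(
    out = y,
    cache = list(
      x = x, q = q, k = k, v = v, o = o, att = att,
      n_heads = n_heads, dh = dh, p = p
    )
  )
}

mha_backward <- function(cache, dy) {
  p <- cache$p
  x <- cache$x
  dh <- cache$dh
  dWo <- crossprod(cache$o, dy)
  dbo <- colSums(dy)
  do <- tcrossprod(dy, p$Wo)
  dq <- matrix(0, nrow(x), ncol(x))
  dk <- dq
  dv <- dq
  for (hi in seq_len(cache$n_heads)) {
    cols <- (hi - 1L) * dh + seq_len(dh)
    a <- cache$att[[hi]]
    do_h <- do[, cols, drop = FALSE]
    v_h <- cache$v[, cols, drop = FALSE]
    da <- tcrossprod(do_h, v_h)
    dv[, cols] <- crossprod(a, do_h)
    # softmax jacobian per row
    ds <- a * (da - rowSums(da * a))
    ds <- ds / sqrt(dh)
    dq[, cols] <- ds %*% cache$k[, cols, drop = FALSE]
    dk[, cols] <- crossprod(ds, cache$q[, cols, drop = FALSE])
  }
  dx <- tcrossprod(dq, p$Wq) + tcrossprod(dk, p$Wk) + tcrossprod(dv, p$Wv)
  list(
    dx = dx,
    dWq = crossprod(x, dq), dbq = colSums(dq),
    dWk = crossprod(x, dk), dbk = colSums(dk),
    dWv = crossprod(x, dv), dbv = colSums(dv),
    dWo = dWo, dbo = dbo
  )
}

# ---- parameter-tree utilities ---------------------------------------------

# Apply f(leaf, path) over every numeric leaf of a nested parameter list,
# returning a tree of the same shape.
tree_map <- function(tree, f, path = character()) {
  if (is.list(tree)) {
    out <- lapply(seq_along(tree), function(i) {
      nm <- names(tree)[i] %||% as.character(i)
      tree_map(tree[[i]], f, c(path, nm))
    })
    names(out) <- names(tree)
    out
  } else {
    f(tree, path)
  }
}

# Elementwise combine two same-shape trees.
tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- lapply(seq_along(a), function(i) tree_map2(a[[i]], b[[i]], f))
    names(out) <- names(a)
    out
  } else {
    f(a, b)
  }
}

n_parameters <- function(params) {
  length(unlist(params, use.names = FALSE))
}
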