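# 3D convolution and batch-normalisation primitives.
#
# All layer maths is expressed as dense GEMMs so R's BLAS does the work:
# convolution is im2col (a cached gather index per layer geometry and
# batch size) followed by one matrix product per batch; the col2im
# scatter in the backward pass is a cached sparse matrix product.
#
# Activation layout throughout: a batch is a matrix of shape
# V x (B * C) where V = spatial voxels, B = batch size, C = channels;
# column (b + (c-1)*B) holds channel c of subject b. With this layout
# the im2col product P %*% W is already the next activation after a
# plain dim<- reshape, so no array transposition is ever needed.

# Geometry of one conv layer: per-output-voxel gather indices.
# Zero padding is encoded as index 0 (row 1 of the zero-padded input).
make_conv_geom <- function(in_dim, k = 3L, stride = 1L, pad = 1L) {
  in_dim <- as.integer(in_dim)
  out_dim <- (in_dim + 2L * pad - k) %/% stride + 1L
  if (any(out_dim < 1L))
    stop_bad_arg("input shape ", paste(in_dim, collapse = "x"),
                 " too small for a k=", k, " stride=", stride, " conv")
  og <- expand.grid(x = seq_len(out_dim[1L]), y = seq_len(out_dim[2L]),
                    z = seq_len(out_dim[3L]))
  kg <- expand.grid(kx = seq_len(k), ky = seq_len(k), kz = seq_len(k))
  K <- k^3
  V_out <- nrow(og)
  idx <- matrix(0L, V_out, K)
  for (t in seq_len(K)) {
    ix <- (og$x - 1L) * stride - pad + kg$kx[t]
    iy <- (og$y - 1L) * stride - pad + kg$ky[t]
    iz <- (og$z - 1L) * stride - pad + kg$kz[t]
    ok <- ix >= 1L & ix <= in_dim[1L] & iy >= 1L & iy <= in_dim[2L] &
      iz >= 1L & iz <= in_dim[3L]
    idx[, t] <- ifelse(ok, voxel_index(ix, iy, iz, in_dim), 0L)
  }
  list(in_dim = in_dim, out_dim = out_dim, k = k, K = K,
       stride = stride, pad = pad,
       V_in = prod(in_dim), V_out = prod(out_dim),
       idx = idx)
}

# gather index into the zero-padded batch matrix, shaped so that
# Apad[lin] reshaped to (V_out*B) x (K*C_in) is the im2col matrix
conv_lin_index <- function(geom, c_in, B) {
  V <- geom$V_out; K <- geom$K
  npr <- geom$V_in + 1L
  i1 <- geom$idx + 1L
  arr <- array(0L, c(V, B, K))
  for (t in seq_len(K)) arr[, , t] <- i1[, t]
  v_obt <- as.integer(arr)
  VBK <- V * B * K
  lin <- integer(VBK * c_in)
  for (cc in seq_len(c_in)) {
    offs <- (seq_len(B) - 1L + (cc - 1L) * B) * npr
    lin[(cc - 1L) * VBK + seq_len(VBK)] <-
      v_obt + rep(rep(offs, each = V), times = K)
  }
  lin
}

# cache of gather/scatter structures, keyed by geometry, C_in and B
get_conv_cache <- function(env, gkey, geom, c_in, B, need_scatter = FALSE) {
  key <- paste(gkey, c_in, B, sep = "|")
  entry <- env[[key]]
  if (is.null(entry)) {
    entry <- list(lin = conv_lin_index(geom, c_in, B))
    env[[key]] <- entry
  }
  if (need_scatter && is.null(entry$scatter)) {
    npr <- geom$V_in + 1L
    row <- (entry$lin - 1L) %% npr          # 0 = zero-padding, dropped
    col <- (entry$lin - 1L) %/% npr
    keep <- which(row > 0L)
    entry$scatter <- Matrix::sparseMatrix(
      i = row[keep] + col[keep] * geom$V_in, j = keep, x = 1,
      dims = c(geom$V_in * B * c_in, length(entry$lin)))
    env[[key]] <- entry
  }
  entry
}

# forward: A is V_in x (B*C_in); returns Y = V_out x (B*C_out)
conv_fwd <- function(p, geom, gkey, A, c_in, B, env, keep_cache = FALSE) {
  c_out <- ncol(p$W)
  cc <- get_conv_cache(env, gkey, geom, c_in, B)
  Apad <- rbind(0, A)
  P <- Apad[cc$lin]
  dim(P) <- c(geom$V_out * B, geom$K * c_in)
  Y <- P %*% p$W
  Y <- Y + rep(p$b, each = nrow(Y))
  dim(Y) <- c(geom$V_out, B * c_out)
  list(Y = Y, cache = if (keep_cache) list(P = P) else NULL)
}

# backward: dY is V_out x (B*C_out); returns dA and parameter grads
conv_bwd <- function(p, geom, gkey, dY, cache, c_in, B, env) {
  c_out <- ncol(p$W)
  cc <- get_conv_cache(env, gkey, geom, c_in, B, need_scatter = TRUE)
  dim(dY) <- c(geom$V_out * B, c_out)
  dW <- crossprod(cache$P, dY)
  db <- colSums(dY)
  dP <- tcrossprod(dY, p$W)                       # (V_out*B) x (K*C_in)
  dim(dP) <- NULL
  dA <- as.numeric(cc$scatter %*% dP)
  dim(dA) <- c(geom$V_in, B * c_in)
  list(dA = dA, dW = dW, db = db)
}

conv_init <- function(geom, c_in, c_out, gain = sqrt(2)) {
  fan_in <- geom$K * c_in
  list(W = matrix(rnorm(fan_in * c_out, 0, gain / sqrt(fan_in)),
                  fan_in, c_out),
       b = numeric(c_out))
}

bn_init <- function(c_ch) {
  list(gamma = rep(1, c_ch), beta = numeric(c_ch))
}

bn_buffers_init <- function(c_ch) {
  list(mean = numeric(c_ch), var = rep(1, c_ch))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# per-column a*x + b without sweep()'s transposition overhead
col_axpb <- function(A, a, b) {
  V <- nrow(A)
  A * rep(a, each = V) + rep(b, each = V)
}

# train-mode forward; updates running stats in `buf` (returned)
bn_fwd_train <- function(p, buf, A, C, B) {
  ch <- rep(seq_len(C), each = B)
  m <- nrow(A) * B
  colm <- colMeans(A)
  colm2 <- colMeans(A * A)
  mu <- as.numeric(rowsum(colm, ch)) / B
  ex2 <- as.numeric(rowsum(colm2, ch)) / B
  v <- pmax(ex2 - mu^2, 0)
  ivar <- 1 / sqrt(v + BN_EPS)
  xhat <- col_axpb(A, ivar[ch], -mu[ch] * ivar[ch])
  Y <- col_axpb(xhat, p$gamma[ch], p$beta[ch])
  buf$mean <- (1 - BN_MOMENTUM) * buf$mean + BN_MOMENTUM * mu
  buf$var <- (1 - BN_MOMENTUM) * buf$var + BN_MOMENTUM * v * m / max(m - 1, 1)
  list(Y = Y, buf = buf, cache = list(xhat = xhat, ivar = ivar, ch = ch, m = m))
}

bn_fwd_infer <- function(p, buf, A, C, B) {
  ch <- rep(seq_len(C), each = B)
  ivar <- 1 / sqrt(buf$var + BN_EPS)
  col_axpb(A, p$gamma[ch] * ivar[ch],
           p$beta[ch] - buf$mean[ch] * p$gamma[ch] * ivar[ch])
}

bn_bwd <- function(p, dY, cache) {
  ch <- cache$ch; m <- cache$m
  dgamma <- as.numeric(rowsum(colSums(dY * cache$xhat), ch))
  dbeta <- as.numeric(rowsum(colSums(dY), ch))
  V <- nrow(dY)
  dxhat <- dY * rep(p$gamma[ch], each = V)
  s1 <- as.numeric(rowsum(colSums(dxhat), ch))
  s2 <- as.numeric(rowsum(colSums(dxhat * cache$xhat), ch))
  # dx = ivar/m * (m*dxhat - s1 - xhat*s2), s1/s2 broadcast per channel
  dA <- (dxhat - col_axpb(cache$xhat, s2[ch] / m, s1[ch] / m)) *
    rep(cache$ivar[ch], each = V)
  list(dA = dA, dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(A) A * (A > 0)
relu_bwd <- function(dY, A_pre) dY * (A_pre > 0)
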