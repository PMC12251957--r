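# Minimal neural-network primitives with hand-written backpropagation.
# Feature maps are 4-d arrays [H, W, C, B] (batch last). Convolutions use
# im2col so the inner loop is a BLAS matrix product; layers are environments
# holding parameters, gradients and forward caches. Everything is plain R:
# sizes in this package are desk-scale (<= 256 x 256 with narrow widths).

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  e$grads <- list()
  class(e) <- c(paste0("nn_", type), "nn_layer")
  e
}

# --- im2col / col2im --------------------------------------------------------

# Batched im2col: [H, W, C, B] -> (H*W*B) x (k*k*C) patch matrix. Rows run
# over (H, W, B) in column-major order (matching chan_mat); column blocks
# are ordered offset-major (row offset fastest), channels inner. The whole
# batch becomes a single BLAS matmul per convolution.
im2col <- function(x4, k) {
  d <- dim(x4); H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  p <- (k - 1L) %/% 2L
  xq <- array(0, c(H + 2L * p, W + 2L * p, B, C))
  xq[p + seq_len(H), p + seq_len(W), , ] <- aperm(x4, c(1, 2, 4, 3))
  P <- matrix(0, H * W * B, k * k * C)
  o <- 0L
  for (dj in 0:(k - 1L)) for (di in 0:(k - 1L)) {
    P[, o * C + seq_len(C)] <-
      xq[di + seq_len(H), dj + seq_len(W), , , drop = FALSE]
    o <- o + 1L
  }
  P
}

# Inverse scatter of im2col for gradients: (H*W*B) x (k*k*C) -> [H, W, C, B].
col2im <- function(dP, H, W, C, B, k) {
  p <- (k - 1L) %/% 2L
  dxq <- array(0, c(H + 2L * p, W + 2L * p, B, C))
  o <- 0L
  for (dj in 0:(k - 1L)) for (di in 0:(k - 1L)) {
    dxq[di + seq_len(H), dj + seq_len(W), , ] <-
      dxq[di + seq_len(H), dj + seq_len(W), , , drop = FALSE] +
      array(dP[, o * C + seq_len(C)], c(H, W, B, C))
    o <- o + 1L
  }
  aperm(dxq[p + seq_len(H), p + seq_len(W), , , drop = FALSE],
        c(1, 2, 4, 3))
}

# --- conv2d (same padding, stride 1) ---------------------------------------

conv_layer <- function(k, cin, cout, init_scale = sqrt(2 / (k * k * cin))) {
  new_layer("conv", k = as.integer(k), cin = cin, cout = cout,
            W = matrix(stats::rnorm(k * k * cin * cout, sd = init_scale),
                       k * k * cin, cout),
            b = numeric(cout))
}

# keep = FALSE drops the patch-matrix cache (inference: no backward pass),
# which matters at full scale where patch matrices run to hundreds of MB.
conv_fw <- function(ly, x, keep = TRUE) {
  d <- dim(x); H <- d[1]; W <- d[2]; B <- d[4]
  P <- im2col(x, ly$k)
  Y <- sweep(P %*% ly$W, 2, ly$b, "+")
  ly$cache <- if (keep) list(P = P, H = H, W = W, B = B) else NULL
  chan_arr(Y, c(H, W, ly$cout, B))
}

conv_bw <- function(ly, dy) {
  cc <- ly$cache
  dY <- chan_mat(dy)
  ly$grads <- list(W = crossprod(cc$P, dY), b = colSums(dY))
  col2im(dY %*% t(ly$W), cc$H, cc$W, ly$cin, cc$B, ly$k)
}

# --- batch normalization ----------------------------------------------------

bn_layer <- function(C, momentum = 0.1, eps = 1e-5) {
  new_layer("bn", C = C, momentum = momentum, eps = eps,
            gamma = rep(1, C), beta = numeric(C),
            run_mean = numeric(C), run_var = rep(1, C))
}

# [H, W, C, B] -> (H*W*B) x C matrix and back
chan_mat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
}
chan_arr <- function(M, d) {
  aperm(array(M, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

bn_fw <- function(ly, x, train) {
  d <- dim(x)
  M <- chan_mat(x)
  if (train) {
    mu <- colMeans(M)
    va <- colMeans(M * M) - mu^2  # population variance
    ly$run_mean <- (1 - ly$momentum) * ly$run_mean + ly$momentum * mu
    ly$run_var  <- (1 - ly$momentum) * ly$run_var  + ly$momentum * va
  } else {
    mu <- ly$run_mean; va <- ly$run_var
  }
  inv_sd <- 1 / sqrt(va + ly$eps)
  xhat <- sweep(sweep(M, 2, mu, "-"), 2, inv_sd, "*")
  Y <- sweep(sweep(xhat, 2, ly$gamma, "*"), 2, ly$beta, "+")
  ly$cache <- list(xhat = xhat, inv_sd = inv_sd, d = d, train = train)
  chan_arr(Y, d)
}

bn_bw <- function(ly, dy) {
  cc <- ly$cache
  dY <- chan_mat(dy)
  dgamma <- colSums(dY * cc$xhat)
  dbeta <- colSums(dY)
  if (cc$train) {
    n <- nrow(dY)
    t1 <- sweep(dY, 2, dbeta / n, "-")
    t2 <- sweep(cc$xhat, 2, dgamma / n, "*")
    dX <- sweep((t1 - t2), 2, ly$gamma * cc$inv_sd, "*")
  } else {
    dX <- sweep(dY, 2, ly$gamma * cc$inv_sd, "*")
  }
  ly$grads <- list(gamma = dgamma, beta = dbeta)
  chan_arr(dX, cc$d)
}

# --- dense ------------------------------------------------------------------

dense_layer <- function(cin, cout, init_scale = sqrt(2 / cin)) {
  new_layer("dense", cin = cin, cout = cout,
            W = matrix(stats::rnorm(cin * cout, sd = init_scale), cin, cout),
            b = numeric(cout))
}

dense_fw <- function(ly, X) {
  ly$cache <- list(X = X)
  sweep(X %*% ly$W, 2, ly$b, "+")
}

dense_bw <- function(ly, dY, accumulate = FALSE) {
  g <- list(W = crossprod(ly$cache$X, dY), b = colSums(dY))
  if (accumulate && length(ly$grads)) {
    g$W <- g$W + ly$grads$W
    g$b <- g$b + ly$grads$b
  }
  ly$grads <- g
  dY %*% t(ly$W)
}

# --- stateless ops (caches returned to the caller) -------------------------

relu_fw <- function(x) {
  mask <- x > 0
  list(y = x * mask, mask = mask)
}
relu_bw <- function(dy, mask) dy * mask

sigmoid <- function(x) 1 / (1 + exp(-x))

maxpool_fw <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]
  i1 <- seq(1L, H, 2L); i2 <- i1 + 1L
  j1 <- seq(1L, W, 2L); j2 <- j1 + 1L
  a <- list(x[i1, j1, , , drop = FALSE], x[i2, j1, , , drop = FALSE],
            x[i1, j2, , , drop = FALSE], x[i2, j2, , , drop = FALSE])
  y <- pmax(a[[1]], a[[2]], a[[3]], a[[4]])
  which_max <- (a[[1]] == y) * 1L
  which_max[which_max == 0 & a[[2]] == y] <- 2L
  which_max[which_max == 0 & a[[3]] == y] <- 3L
  which_max[which_max == 0] <- 4L
  list(y = y, which = which_max, d = d)
}

maxpool_bw <- function(dy, cache) {
  d <- cache$d
  dx <- array(0, d)
  i1 <- seq(1L, d[1], 2L); j1 <- seq(1L, d[2], 2L)
  dx[i1, j1, , ]           <- dy * (cache$which == 1L)
  dx[i1 + 1L, j1, , ]      <- dy * (cache$which == 2L)
  dx[i1, j1 + 1L, , ]      <- dy * (cache$which == 3L)
  dx[i1 + 1L, j1 + 1L, , ] <- dy * (cache$which == 4L)
  dx
}

upsample_fw <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
    drop = FALSE]
}

upsample_bw <- function(dy) {
  d <- dim(dy)
  i1 <- seq(1L, d[1], 2L); j1 <- seq(1L, d[2], 2L)
  dy[i1, j1, , , drop = FALSE] + dy[i1 + 1L, j1, , , drop = FALSE] +
    dy[i1, j1 + 1L, , , drop = FALSE] + dy[i1 + 1L, j1 + 1L, , , drop = FALSE]
}

# --- CBAM: channel then spatial attention ----------------------------------

cbam_layer <- function(C, reduction = 16L, spatial_kernel = 7L) {
  assert_that(C %% reduction == 0 && C >= reduction,
              "CBAM requires channel count (", C,
              ") divisible by the reduction ratio (", reduction, ")",
              class = "pseudonir_config_error")
  new_layer("cbam", C = C, reduction = reduction, k = spatial_kernel,
            fc1 = dense_layer(C, C %/% reduction),
            fc2 = dense_layer(C %/% reduction, C),
            sconv = conv_layer(spatial_kernel, 2L, 1L,
                               init_scale = sqrt(2 / (spatial_kernel^2 * 2))))
}

cbam_fw <- function(ly, x, keep = TRUE) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  # channel attention: per-image global average + max pooling over space
  avg <- matrix(0, B, C); mx <- matrix(0, B, C); mx_idx <- matrix(0L, B, C)
  for (b in seq_len(B)) {
    M <- matrix(x[, , , b], nrow = H * W, ncol = C)
    avg[b, ] <- colMeans(M)
    mx_idx[b, ] <- max.col(t(M), ties.method = "first")
    mx[b, ] <- M[cbind(mx_idx[b, ], seq_len(C))]
  }
  h_avg <- relu_fw(dense_fw(ly$fc1, avg))
  z_avg <- dense_fw(ly$fc2, h_avg$y)
  h_mx <- relu_fw(dense_fw(ly$fc1, mx))   # shared weights, second pass
  cache_fc1_mx <- ly$fc1$cache
  z_mx <- dense_fw(ly$fc2, h_mx$y)
  cache_fc2_mx <- ly$fc2$cache
  s <- sigmoid(z_avg + z_mx)              # B x C channel gates
  x1 <- x * aperm(array(s, c(B, C, H, W)), c(3, 4, 2, 1))
  # spatial attention: channel-wise mean + max maps -> k x k conv -> gate
  amap <- array(0, c(H, W, 1L, B)); mmap <- array(0, c(H, W, 1L, B))
  cmax_idx <- array(0L, c(H, W, B))
  for (b in seq_len(B)) {
    M <- matrix(x1[, , , b], nrow = H * W, ncol = C)
    amap[, , 1L, b] <- rowMeans(M)
    idx <- max.col(M, ties.method = "first")
    cmax_idx[, , b] <- idx
    mmap[, , 1L, b] <- M[cbind(seq_len(H * W), idx)]
  }
  smap_pre <- conv_fw(ly$sconv, abind4(amap, mmap), keep = keep)
  smap <- sigmoid(smap_pre)
  y <- x1 * smap[, , rep(1L, C), , drop = FALSE]
  ly$cache <- if (keep) list(x = x, s = s, x1 = x1, smap = smap,
                   h_avg = h_avg, h_mx = h_mx, avg_in = avg,
                   cache_fc1_mx = cache_fc1_mx, cache_fc2_mx = cache_fc2_mx,
                   mx_idx = mx_idx, cmax_idx = cmax_idx, d = d) else NULL
  y
}

cbam_bw <- function(ly, dy) {
  cc <- ly$cache; d <- cc$d
  H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  smap_full <- cc$smap[, , rep(1L, C), , drop = FALSE]
  dx1 <- dy * smap_full
  dsmap <- array(0, c(H, W, 1L, B))
  dsmap[, , 1L, ] <- apply(dy * cc$x1, c(1, 2, 4), sum)
  dsmap_pre <- dsmap * cc$smap * (1 - cc$smap)
  dcat <- conv_bw(ly$sconv, dsmap_pre)
  damap <- dcat[, , 1L, , drop = FALSE]
  dmmap <- dcat[, , 2L, , drop = FALSE]
  # scatter spatial-map grads back into x1
  for (b in seq_len(B)) {
    da <- matrix(damap[, , 1L, b] / C, nrow = H * W, ncol = C)
    idx <- as.vector(cc$cmax_idx[, , b])
    dmm <- matrix(0, H * W, C)
    dmm[cbind(seq_len(H * W), idx)] <- as.vector(dmmap[, , 1L, b])
    dx1[, , , b] <- dx1[, , , b] + array(da + dmm, c(H, W, C))
  }
  # channel gate: y1 = x * s
  ds <- matrix(0, B, C)
  for (b in seq_len(B))
    ds[b, ] <- colSums(matrix(dx1[, , , b] * cc$x[, , , b],
                              nrow = H * W, ncol = C))
  dx <- dx1 * aperm(array(cc$s, c(B, C, H, W)), c(3, 4, 2, 1))
  dz <- ds * cc$s * (1 - cc$s)
  # shared MLP: replay caches for each pooled branch
  ly$fc2$cache <- cc$cache_fc2_mx
  dh_mx <- dense_bw(ly$fc2, dz)
  ly$fc1$cache <- cc$cache_fc1_mx
  dmx <- dense_bw(ly$fc1, relu_bw(dh_mx, cc$h_mx$mask))
  ly$fc2$cache <- list(X = cc$h_avg$y)
  dh_avg <- dense_bw(ly$fc2, dz, accumulate = TRUE)
  ly$fc1$cache <- list(X = cc$avg_in)
  davg <- dense_bw(ly$fc1, relu_bw(dh_avg, cc$h_avg$mask), accumulate = TRUE)
  # scatter pooled-branch grads back into x
  for (b in seq_len(B)) {
    dM <- matrix(davg[b, ] / (H * W), nrow = H * W, ncol = C, byrow = TRUE)
    dM[cbind(cc$mx_idx[b, ], seq_len(C))] <-
      dM[cbind(cc$mx_idx[b, ], seq_len(C))] + dmx[b, ]
    dx[, , , b] <- dx[, , , b] + array(dM, c(H, W, C))
  }
  dx
}

# concatenate two 4-d tensors along the channel axis
abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# --- MLP channel mixer ------------------------------------------------------
# BatchNorm -> reshape (H*W*B) x C -> Dense(C -> e*C) + ReLU ->
# Dense(e*C -> C) -> add the normalized input back -> reshape.

mixer_layer <- function(C, expansion = 4L) {
  new_layer("mixer", C = C, expansion = expansion,
            bn = bn_layer(C),
            fc1 = dense_layer(C, C * expansion),
            fc2 = dense_layer(C * expansion, C))
}

mixer_fw <- function(ly, x, train, keep = TRUE) {
  d <- dim(x)
  xbn <- bn_fw(ly$bn, x, train)
  Xr <- chan_mat(xbn)
  h <- relu_fw(dense_fw(ly$fc1, Xr))
  Z <- dense_fw(ly$fc2, h$y)
  ly$cache <- if (keep) list(h = h, d = d) else NULL
  chan_arr(Z + Xr, d)
}

mixer_bw <- function(ly, dy) {
  cc <- ly$cache
  dZres <- chan_mat(dy)
  dh <- dense_bw(ly$fc2, dZres)
  dXr <- dense_bw(ly$fc1, relu_bw(dh, cc$h$mask)) + dZres
  bn_bw(ly$bn, chan_arr(dXr, cc$d))
}

# --- multi-scale convolution block -----------------------------------------
# Three parallel same-padded convs (3/5/7), channel concat, 1x1 reduction,
# then a second channel mixer with a residual add: out = mixer(f) + f.

msc_layer <- function(C, kernels = c(3L, 5L, 7L), expansion = 4L) {
  assert_that(all(kernels %% 2 == 1), "MSC kernels must be odd",
              class = "pseudonir_config_error")
  new_layer("msc", C = C, kernels = kernels,
            branches = lapply(kernels, function(k) conv_layer(k, C, C)),
            reduce = conv_layer(1L, C * length(kernels), C),
            mixer = mixer_layer(C, expansion))
}

msc_fw <- function(ly, x, train, keep = TRUE) {
  feats <- lapply(ly$branches, conv_fw, x = x, keep = keep)
  cat <- Reduce(abind4, feats)
  fmsc <- conv_fw(ly$reduce, cat, keep = keep)
  y <- mixer_fw(ly$mixer, fmsc, train, keep = keep) + fmsc
  ly$cache <- if (keep) list(d = dim(x)) else NULL
  y
}

msc_bw <- function(ly, dy) {
  dfmsc <- mixer_bw(ly$mixer, dy) + dy
  dcat <- conv_bw(ly$reduce, dfmsc)
  C <- ly$C
  dx <- 0
  for (i in seq_along(ly$branches)) {
    dfi <- dcat[, , (i - 1L) * C + seq_len(C), , drop = FALSE]
    dx <- dx + conv_bw(ly$branches[[i]], dfi)
  }
  dx
}

# --- parameter bookkeeping and Adam ----------------------------------------

# All trainable layer environments reachable from a layer/network structure.
collect_layers <- function(x) {
  if (inherits(x, "nn_layer")) {
    fields <- setdiff(sort(ls(x)), c("cache", "grads"))  # deterministic order
    inner <- lapply(mget(fields, envir = x), collect_layers)
    return(c(list(x), unlist(inner, recursive = FALSE)))
  }
  if (is.list(x)) return(unlist(lapply(x, collect_layers), recursive = FALSE))
  NULL
}

layer_param_names <- function(ly) {
  switch(ly$type,
         conv = c("W", "b"), dense = c("W", "b"), bn = c("gamma", "beta"),
         character(0))
}

n_parameters <- function(x) {
  lys <- collect_layers(x)
  sum(vapply(lys, function(ly)
    sum(vapply(layer_param_names(ly), function(nm) length(ly[[nm]]), 0)), 0))
}

snapshot_params <- function(x) {
  lapply(collect_layers(x), function(ly) {
    keep <- c(layer_param_names(ly),
              intersect(c("run_mean", "run_var"), names(ly)))
    mget(keep, envir = ly)
  })
}

restore_params <- function(x, snap) {
  lys <- collect_layers(x)
  for (i in seq_along(lys))
    for (nm in names(snap[[i]])) assign(nm, snap[[i]][[nm]], envir = lys[[i]])
  invisible(x)
}

make_adam <- function(net, lr = 2e-4, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  lys <- Filter(function(ly) length(layer_param_names(ly)) > 0,
                collect_layers(net))
  st <- new.env(parent = emptyenv())
  st$lr <- lr; st$t <- 0L
  st$m <- lapply(lys, function(ly)
    lapply(mget(layer_param_names(ly), envir = ly), function(p) p * 0))
  st$v <- st$m
  st$step <- function() {
    st$t <- st$t + 1L
    bc1 <- 1 - beta1^st$t; bc2 <- 1 - beta2^st$t
    for (i in seq_along(lys)) {
      ly <- lys[[i]]
      for (nm in layer_param_names(ly)) {
        g <- ly$grads[[nm]]
        if (is.null(g)) next
        st$m[[i]][[nm]] <- beta1 * st$m[[i]][[nm]] + (1 - beta1) * g
        st$v[[i]][[nm]] <- beta2 * st$v[[i]][[nm]] + (1 - beta2) * g * g
        upd <- (st$m[[i]][[nm]] / bc1) /
          (sqrt(st$v[[i]][[nm]] / bc2) + eps)
        assign(nm, ly[[nm]] - st$lr * upd, envir = ly)
      }
    }
  }
  st
}
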