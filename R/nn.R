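# Compact convolutional network used by the ranking model, implemented with
# vectorized im2col convolutions so everything reduces to dense matrix
# multiplies. Architecture: two 3x3 stride-2 conv blocks (ReLU) producing a
# per-pixel feature map at 1/4 resolution, then either a 1x1 per-pixel
# classification head (segmentation pretraining) or global average pooling
# plus two fully connected layers yielding the scalar ranking score f(x).
# Everything is deterministic given the seed: no threads, no dropout.

.nn_cache <- new.env(parent = emptyenv())

# index matrix mapping each (output position, patch offset, channel) of a
# 3x3 pad-1 convolution to a linear index into the zero-padded input batch
.conv_indices <- function(h, w, c, stride, batch) {
  key <- paste(h, w, c, stride, batch, sep = "_")
  hit <- .nn_cache[[key]]
  if (!is.null(hit)) return(hit)
  hp <- h + 2L; wp <- w + 2L
  ho <- (h + 2L - 3L) %/% stride + 1L
  wo <- (w + 2L - 3L) %/% stride + 1L
  io <- rep(seq_len(ho), wo); jo <- rep(seq_len(wo), each = ho)
  base <- (io - 1L) * stride + ((jo - 1L) * stride) * hp
  offs <- expand.grid(dr = 1:3, dc = 1:3, ch = seq_len(c))
  idx0 <- matrix(0L, ho * wo, nrow(offs))
  for (k in seq_len(nrow(offs))) {
    idx0[, k] <- base + offs$dr[k] + (offs$dc[k] - 1L) * hp +
      (offs$ch[k] - 1L) * hp * wp
  }
  per_img <- hp * wp * c
  idx <- idx0[rep(seq_len(ho * wo), batch), , drop = FALSE] +
    rep((seq_len(batch) - 1L) * per_img, each = ho * wo)
  out <- list(idx = idx, ho = ho, wo = wo, hp = hp, wp = wp, c = c,
              batch = batch, h = h, w = w)
  .nn_cache[[key]] <- out
  out
}

.pad_batch <- function(x) {
  d <- dim(x)  # (h, w, c, b)
  a <- array(0, c(d[1] + 2L, d[2] + 2L, d[3], d[4]))
  a[2:(d[1] + 1L), 2:(d[2] + 1L), , ] <- x
  as.numeric(a)
}

.conv_fwd <- function(xflat, ci, w, b) {
  xcol <- matrix(xflat[ci$idx], nrow(ci$idx), ncol(ci$idx))
  y <- xcol %*% w
  y <- y + rep(b, each = nrow(y))
  list(y = y, xcol = xcol)
}

.conv_bwd <- function(dy, xcol, ci, w, need_dx = TRUE) {
  dw <- crossprod(xcol, dy)
  db <- colSums(dy)
  dx <- NULL
  if (need_dx) {
    dxcol <- tcrossprod(dy, w)
    g <- numeric(ci$hp * ci$wp * ci$c * ci$batch)
    for (k in seq_len(ncol(dxcol))) {
      ik <- ci$idx[, k]
      g[ik] <- g[ik] + dxcol[, k]
    }
    ga <- array(g, c(ci$hp, ci$wp, ci$c, ci$batch))
    dx <- ga[2:(ci$h + 1L), 2:(ci$w + 1L), , , drop = FALSE]
  }
  list(dw = dw, db = db, dx = dx)
}

# matrix (positions*batch x channels) -> padded flat input of the next layer
.y_to_padded <- function(y, ci_prev, channels) {
  a <- array(y, c(ci_prev$ho, ci_prev$wo, ci_prev$batch, channels))
  .pad_batch(aperm(a, c(1, 2, 4, 3)))
}

.net_new <- function(config, seed = 1L) {
  c1 <- config$conv_channels[1]; c2 <- config$conv_channels[2]
  h <- config$fc_hidden; k <- config$n_classes
  withr::with_seed(as.integer(seed), {
    init <- function(nr, nc) matrix(rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
    list(
      w1 = init(27, c1), b1 = numeric(c1),
      w2 = init(9 * c1, c2), b2 = numeric(c2),
      wp = init(c2, k), bp = numeric(k),
      wf1 = init(c2, h), bf1 = numeric(h),
      wf2 = init(h, 1), bf2 = numeric(1),
      config = config
    )
  })
}

# forward through the two conv blocks; x is (h, w, 3, b)
.net_features <- function(net, x) {
  d <- dim(x)
  ci1 <- .conv_indices(d[1], d[2], 3L, 2L, d[4])
  f1 <- .conv_fwd(.pad_batch(x), ci1, net$w1, net$b1)
  a1 <- pmax(f1$y, 0)
  c1 <- ncol(a1)
  ci2 <- .conv_indices(ci1$ho, ci1$wo, c1, 2L, d[4])
  f2 <- .conv_fwd(.y_to_padded(a1, ci1, c1), ci2, net$w2, net$b2)
  a2 <- pmax(f2$y, 0)
  list(a2 = a2, state = list(ci1 = ci1, ci2 = ci2, xcol1 = f1$xcol,
                             xcol2 = f2$xcol, y1 = f1$y, y2 = f2$y,
                             batch = d[4]))
}

# backprop da2 (gradient at the post-ReLU feature map) into conv weights
.net_features_bwd <- function(net, da2, st) {
  dy2 <- da2 * (st$y2 > 0)
  b2g <- .conv_bwd(dy2, st$xcol2, st$ci2, net$w2, need_dx = TRUE)
  # b2g$dx is (ho1, wo1, c1, b); reorder to rows = position-within-image, b blocks
  da1 <- matrix(aperm(b2g$dx, c(1, 2, 4, 3)), nrow(st$y1), ncol(st$y1))
  dy1 <- da1 * (st$y1 > 0)
  b1g <- .conv_bwd(dy1, st$xcol1, st$ci1, net$w1, need_dx = FALSE)
  list(dw1 = b1g$dw, db1 = b1g$db, dw2 = b2g$dw, db2 = b2g$db)
}

# pooled features per image; pool_w: optional per-pixel weights
# (n_positions x batch matrix) for masked average pooling
.net_pool <- function(a2, st, pool_w = NULL) {
  npos <- st$ci2$ho * st$ci2$wo
  grp <- rep(seq_len(st$batch), each = npos)
  if (is.null(pool_w)) {
    g <- rowsum(a2, grp) / npos
    wvec <- NULL
  } else {
    wvec <- as.numeric(pool_w)
    tot <- pmax(rowsum(wvec, grp), 1e-8)
    g <- rowsum(a2 * wvec, grp) / as.numeric(tot)
  }
  list(g = g, grp = grp, npos = npos, wvec = wvec)
}

.net_head <- function(net, g) {
  h1p <- g %*% net$wf1
  h1p <- h1p + rep(net$bf1, each = nrow(h1p))
  h1 <- pmax(h1p, 0)
  f <- h1 %*% net$wf2 + net$bf2[1]
  list(f = as.numeric(f), h1 = h1, h1p = h1p)
}

# scalar scores for an image batch; returns scores + full state for backward
.net_score <- function(net, x, pool_w = NULL) {
  ft <- .net_features(net, x)
  pl <- .net_pool(ft$a2, ft$state, pool_w)
  hd <- .net_head(net, pl$g)
  list(f = hd$f, ft = ft, pl = pl, hd = hd)
}

# backprop df (one gradient per image) through head, pooling and convs
.net_score_bwd <- function(net, fw, df) {
  dfm <- matrix(df, ncol = 1)
  dwf2 <- crossprod(fw$hd$h1, dfm)
  dbf2 <- sum(df)
  dh1 <- tcrossprod(dfm, net$wf2) * (fw$hd$h1p > 0)
  dwf1 <- crossprod(fw$pl$g, dh1)
  dbf1 <- colSums(dh1)
  dg <- tcrossprod(dh1, net$wf1)
  if (is.null(fw$pl$wvec)) {
    da2 <- dg[fw$pl$grp, , drop = FALSE] / fw$pl$npos
  } else {
    tot <- pmax(rowsum(fw$pl$wvec, fw$pl$grp), 1e-8)
    da2 <- dg[fw$pl$grp, , drop = FALSE] *
      (fw$pl$wvec / as.numeric(tot)[fw$pl$grp])
  }
  cg <- .net_features_bwd(net, da2, fw$ft$state)
  c(cg, list(dwf1 = dwf1, dbf1 = dbf1, dwf2 = dwf2, dbf2 = dbf2))
}

# per-pixel classification head for segmentation pretraining
.net_pretrain_fwd <- function(net, x) {
  ft <- .net_features(net, x)
  logits <- ft$a2 %*% net$wp
  logits <- logits + rep(net$bp, each = nrow(logits))
  list(logits = logits, ft = ft)
}

# cross-entropy with optional per-class weights (used to counter the heavy
# background-class imbalance in segmentation pretraining)
.softmax_ce <- function(logits, y, class_w = NULL) {
  m <- apply(logits, 1, max)
  z <- exp(logits - m)
  p <- z / rowSums(z)
  n <- nrow(logits)
  eps <- 1e-12
  wy <- if (is.null(class_w)) rep(1, n) else class_w[y]
  tot <- sum(wy)
  loss <- -sum(wy * log(p[cbind(seq_len(n), y)] + eps)) / tot
  dl <- p
  dl[cbind(seq_len(n), y)] <- dl[cbind(seq_len(n), y)] - 1
  list(loss = loss, dlogits = dl * (wy / tot), p = p)
}

.adam_init <- function(net) {
  pars <- .net_par_names()
  list(m = lapply(pars, function(p) net[[p]] * 0),
       v = lapply(pars, function(p) net[[p]] * 0),
       t = 0)
}

.net_par_names <- function() {
  c("w1", "b1", "w2", "b2", "wp", "bp", "wf1", "bf1", "wf2", "bf2")
}

.adam_step <- function(net, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  opt$t <- opt$t + 1
  pars <- .net_par_names()
  names(opt$m) <- pars; names(opt$v) <- pars
  for (p in pars) {
    gname <- paste0("d", p)
    g <- grads[[gname]]
    if (is.null(g)) next
    opt$m[[p]] <- beta1 * opt$m[[p]] + (1 - beta1) * g
    opt$v[[p]] <- beta2 * opt$v[[p]] + (1 - beta2) * g^2
    mhat <- opt$m[[p]] / (1 - beta1^opt$t)
    vhat <- opt$v[[p]] / (1 - beta2^opt$t)
    net[[p]] <- net[[p]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(net = net, opt = opt)
}

.stack_images <- function(images) {
  d <- dim(images[[1]])
  array(unlist(images, use.names = FALSE), c(d[1], d[2], d[3], length(images)))
}

# nearest-neighbor downsample of an h x w matrix to the feature-map grid
# (factor 4: two stride-2 convolutions), sampling at input row/col 4i - 2
.downsample_map <- function(m, factor = 4L) {
  ho <- (nrow(m) + 2L - 3L) %/% 2L + 1L
  ho <- (ho + 2L - 3L) %/% 2L + 1L
  wo <- ho  # square images throughout
  ri <- pmin(4L * seq_len(ho) - 2L, nrow(m))
  ci <- pmin(4L * seq_len(wo) - 2L, ncol(m))
  m[ri, ci, drop = FALSE]
}
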