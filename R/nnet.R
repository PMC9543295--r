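# Minimal CNN primitives for the desk-scale segmentation models: im2col
# convolutions on per-slice planes, 2x2 average pooling, nearest-neighbour
# upsampling, ReLU, softmax / branched-sigmoid heads, Adam. Everything is
# plain matrix algebra so training is deterministic under a fixed seed on a
# single thread.

# Precompute padded-image gather indices for a kxk convolution at the given
# plane size and dilation (zero padding, "same" output size).
conv_prep <- function(H, W, k, dil = 1L) {
  p <- as.integer(dil * (k - 1L) %/% 2L)
  Hp <- H + 2L * p; Wp <- W + 2L * p
  offs <- seq.int(-(k - 1L) %/% 2L, (k - 1L) %/% 2L) * dil
  ii <- rep(seq_len(H), times = W) + p
  jj <- rep(seq_len(W), each = H) + p
  idx <- matrix(0L, H * W, k * k)
  t <- 0L
  for (oj in offs) for (oi in offs) {
    t <- t + 1L
    idx[, t] <- (jj + oj - 1L) * Hp + (ii + oi)
  }
  list(idx = idx, Hp = Hp, Wp = Wp, p = p, H = H, W = W)
}

conv_fwd <- function(x, lay, cp) {
  cin <- dim(x)[3]
  k2 <- ncol(cp$idx)
  xp <- array(0, c(cp$Hp, cp$Wp, cin))
  xp[cp$p + seq_len(cp$H), cp$p + seq_len(cp$W), ] <- x
  X <- matrix(0, cp$H * cp$W, k2 * cin)
  for (c in seq_len(cin)) {
    m <- xp[, , c]
    X[, ((c - 1L) * k2 + 1L):(c * k2)] <- m[cp$idx]
  }
  out <- X %*% lay$W
  out <- out + rep(lay$b, each = nrow(out))
  list(out = array(out, c(cp$H, cp$W, ncol(lay$W))), X = X)
}

conv_bwd <- function(dout, lay, X, cp, cin) {
  dmat <- matrix(dout, cp$H * cp$W, length(lay$b))
  dW <- crossprod(X, dmat)
  db <- colSums(dmat)
  dX <- tcrossprod(dmat, lay$W)
  k2 <- ncol(cp$idx)
  dx <- array(0, c(cp$H, cp$W, cin))
  for (c in seq_len(cin)) {
    dm <- matrix(0, cp$Hp, cp$Wp)
    blk <- dX[, ((c - 1L) * k2 + 1L):(c * k2), drop = FALSE]
    for (j in seq_len(k2))
      dm[cp$idx[, j]] <- dm[cp$idx[, j]] + blk[, j]
    dx[, , c] <- dm[cp$p + seq_len(cp$H), cp$p + seq_len(cp$W)]
  }
  list(dx = dx, dW = dW, db = db)
}

# 1x1 convolution = per-pixel linear map.
conv1_fwd <- function(x, lay) {
  d <- dim(x)
  X <- matrix(x, d[1] * d[2], d[3])
  out <- X %*% lay$W
  out <- out + rep(lay$b, each = nrow(out))
  list(out = array(out, c(d[1], d[2], ncol(lay$W))), X = X)
}

conv1_bwd <- function(dout, lay, X, dimx) {
  dmat <- matrix(dout, nrow(X), length(lay$b))
  list(dx = array(tcrossprod(dmat, lay$W), dimx),
       dW = crossprod(X, dmat), db = colSums(dmat))
}

relu_fwd <- function(x) pmax(x, 0)
relu_bwd <- function(dout, x) dout * (x > 0)

pool_fwd <- function(x) {
  d <- dim(x)
  i1 <- seq(1L, d[1], 2L); i2 <- seq(2L, d[1], 2L)
  j1 <- seq(1L, d[2], 2L); j2 <- seq(2L, d[2], 2L)
  (x[i1, j1, , drop = FALSE] + x[i2, j1, , drop = FALSE] +
   x[i1, j2, , drop = FALSE] + x[i2, j2, , drop = FALSE]) / 4
}

pool_bwd <- function(dout, dimx) {
  dx <- array(0, dimx)
  g <- dout / 4
  i1 <- seq(1L, dimx[1], 2L); i2 <- seq(2L, dimx[1], 2L)
  j1 <- seq(1L, dimx[2], 2L); j2 <- seq(2L, dimx[2], 2L)
  dx[i1, j1, ] <- g; dx[i2, j1, ] <- g; dx[i1, j2, ] <- g; dx[i2, j2, ] <- g
  dx
}

up_fwd <- function(x) {
  d <- dim(x)
  out <- array(0, c(2L * d[1], 2L * d[2], d[3]))
  i1 <- seq(1L, 2L * d[1], 2L); i2 <- i1 + 1L
  j1 <- seq(1L, 2L * d[2], 2L); j2 <- j1 + 1L
  out[i1, j1, ] <- x; out[i2, j1, ] <- x; out[i1, j2, ] <- x; out[i2, j2, ] <- x
  out
}

up_bwd <- function(dout) {
  d <- dim(dout)
  i1 <- seq(1L, d[1], 2L); i2 <- i1 + 1L
  j1 <- seq(1L, d[2], 2L); j2 <- j1 + 1L
  dout[i1, j1, , drop = FALSE] + dout[i2, j1, , drop = FALSE] +
    dout[i1, j2, , drop = FALSE] + dout[i2, j2, , drop = FALSE]
}

he_init <- function(k2cin, cout) {
  list(W = matrix(stats::rnorm(k2cin * cout, sd = sqrt(2 / k2cin)), k2cin, cout),
       b = rep(0, cout))
}

# Architecture table: all four variants share one small encoder-decoder
# trunk; they differ in skip connections, bottleneck dilation, head shape
# and input mode.
arch_info <- function(arch) {
  switch(arch,
    spcnet_like = list(skips = FALSE, branched = FALSE, dil = 1L, input_mode = "stack3"),
    unet_like = list(skips = TRUE, branched = FALSE, dil = 1L, input_mode = "stack3"),
    branched_unet_like = list(skips = TRUE, branched = TRUE, dil = 1L, input_mode = "stack3"),
    deeplab_like_2d = list(skips = FALSE, branched = FALSE, dil = 2L, input_mode = "single_slice"),
    stop("unknown arch: ", arch))
}

net_init <- function(arch, cin, width) {
  ai <- arch_info(arch)
  w <- width
  dec1_in <- if (ai$skips) 4L * w else 2L * w
  dec2_in <- if (ai$skips) 2L * w else w
  params <- list(
    c1 = he_init(9L * cin, w),
    c2 = he_init(9L * w, 2L * w),
    c3 = he_init(9L * 2L * w, 2L * w),
    c4 = he_init(9L * dec1_in, w),
    c5 = he_init(9L * dec2_in, w))
  if (ai$branched) {
    params$head_c <- he_init(w, 1L)   # cancer-vs-normal logit
    params$head_a <- he_init(w, 1L)   # aggressive-vs-indolent logit
  } else {
    params$head <- he_init(w, 3L)
  }
  params
}

n_params <- function(params)
  sum(vapply(params, function(l) length(l$W) + length(l$b), numeric(1)))

# conv_prep set for a plane size (levels 1, 1/2, 1/4).
make_cps <- function(H, W, dil) {
  if (H %% 4L != 0L || W %% 4L != 0L)
    stop("in-plane dimensions must be divisible by 4")
  list(l1 = conv_prep(H, W, 3L),
       l2 = conv_prep(H %/% 2L, W %/% 2L, 3L),
       l3 = conv_prep(H %/% 4L, W %/% 4L, 3L, dil),
       l4 = conv_prep(H %/% 2L, W %/% 2L, 3L),
       l5 = conv_prep(H, W, 3L))
}

net_forward <- function(params, x, ai, cps) {
  ca <- list()
  f1 <- conv_fwd(x, params$c1, cps$l1); a1 <- relu_fwd(f1$out)
  p1 <- pool_fwd(a1)
  f2 <- conv_fwd(p1, params$c2, cps$l2); a2 <- relu_fwd(f2$out)
  p2 <- pool_fwd(a2)
  f3 <- conv_fwd(p2, params$c3, cps$l3); a3 <- relu_fwd(f3$out)
  u1 <- up_fwd(a3)
  d1in <- if (ai$skips) abind3(u1, a2) else u1
  f4 <- conv_fwd(d1in, params$c4, cps$l4); a4 <- relu_fwd(f4$out)
  u2 <- up_fwd(a4)
  d2in <- if (ai$skips) abind3(u2, a1) else u2
  f5 <- conv_fwd(d2in, params$c5, cps$l5); a5 <- relu_fwd(f5$out)
  HW <- dim(x)[1] * dim(x)[2]
  if (ai$branched) {
    hc <- conv1_fwd(a5, params$head_c)
    ha <- conv1_fwd(a5, params$head_a)
    pc <- stats::plogis(as.vector(hc$out))
    pa <- stats::plogis(as.vector(ha$out))
    probs <- cbind(1 - pc, pc * (1 - pa), pc * pa)
    ca <- list(f1 = f1, a1 = a1, p1 = p1, f2 = f2, a2 = a2, p2 = p2,
               f3 = f3, a3 = a3, u1 = u1, d1in = d1in, f4 = f4, a4 = a4,
               u2 = u2, d2in = d2in, f5 = f5, a5 = a5,
               hc = hc, ha = ha, pc = pc, pa = pa, x = x)
  } else {
    hd <- conv1_fwd(a5, params$head)
    L <- matrix(hd$out, HW, 3L)
    L <- L - apply(L, 1, max)
    E <- exp(L)
    probs <- E / rowSums(E)
    ca <- list(f1 = f1, a1 = a1, p1 = p1, f2 = f2, a2 = a2, p2 = p2,
               f3 = f3, a3 = a3, u1 = u1, d1in = d1in, f4 = f4, a4 = a4,
               u2 = u2, d2in = d2in, f5 = f5, a5 = a5, hd = hd, x = x)
  }
  list(probs = probs, cache = ca)
}

abind3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

# Weighted masked cross-entropy loss and its gradient at the head.
# y: integer vector (HW), 0 = ignore (outside prostate), 1..3 = class.
# wclass: per-class weights. Returns loss and per-unit head gradients.
ce_loss <- function(probs, y, wclass) {
  keep <- y > 0L
  wt <- numeric(length(y))
  wt[keep] <- wclass[y[keep]]
  tot <- sum(wt)
  if (tot <= 0) return(list(loss = NA_real_, wt = wt, tot = tot))
  py <- probs[cbind(which(keep), y[keep])]
  loss <- sum(wt[keep] * (-log(pmax(py, 1e-12)))) / tot
  list(loss = loss, wt = wt, tot = tot)
}

net_backward <- function(params, ca, probs, y, wclass, ai, cps) {
  HW <- length(y)
  lw <- ce_loss(probs, y, wclass)
  g <- lw$wt / lw$tot
  grads <- list()
  d <- dim(ca$a5)
  if (ai$branched) {
    pc <- ca$pc; pa <- ca$pa
    dlc <- g * ifelse(y == 1L, pc, -(1 - pc))
    dla <- g * ifelse(y == 2L, pa, ifelse(y == 3L, -(1 - pa), 0))
    dlc[y == 0L] <- 0; dla[y == 0L] <- 0
    bc <- conv1_bwd(array(dlc, c(d[1], d[2], 1L)), params$head_c, ca$hc$X, d)
    ba <- conv1_bwd(array(dla, c(d[1], d[2], 1L)), params$head_a, ca$ha$X, d)
    grads$head_c <- list(W = bc$dW, b = bc$db)
    grads$head_a <- list(W = ba$dW, b = ba$db)
    da5 <- bc$dx + ba$dx
  } else {
    Y <- matrix(0, HW, 3L)
    keep <- y > 0L
    Y[cbind(which(keep), y[keep])] <- 1
    dlog <- g * (probs - Y)
    dlog[!keep, ] <- 0
    bh <- conv1_bwd(array(dlog, c(d[1], d[2], 3L)), params$head, ca$hd$X, d)
    grads$head <- list(W = bh$dW, b = bh$db)
    da5 <- bh$dx
  }
  da5 <- relu_bwd(da5, ca$f5$out)
  cin5 <- dim(ca$d2in)[3]
  b5 <- conv_bwd(da5, params$c5, ca$f5$X, cps$l5, cin5)
  grads$c5 <- list(W = b5$dW, b = b5$db)
  if (ai$skips) {
    w <- dim(ca$u2)[3]
    du2 <- b5$dx[, , seq_len(w), drop = FALSE]
    da1_skip <- b5$dx[, , w + seq_len(dim(ca$a1)[3]), drop = FALSE]
  } else {
    du2 <- b5$dx
    da1_skip <- 0
  }
  da4 <- up_bwd(du2)
  da4 <- relu_bwd(da4, ca$f4$out)
  cin4 <- dim(ca$d1in)[3]
  b4 <- conv_bwd(da4, params$c4, ca$f4$X, cps$l4, cin4)
  grads$c4 <- list(W = b4$dW, b = b4$db)
  if (ai$skips) {
    w2 <- dim(ca$u1)[3]
    du1 <- b4$dx[, , seq_len(w2), drop = FALSE]
    da2_skip <- b4$dx[, , w2 + seq_len(dim(ca$a2)[3]), drop = FALSE]
  } else {
    du1 <- b4$dx
    da2_skip <- 0
  }
  da3 <- up_bwd(du1)
  da3 <- relu_bwd(da3, ca$f3$out)
  b3 <- conv_bwd(da3, params$c3, ca$f3$X, cps$l3, dim(ca$p2)[3])
  grads$c3 <- list(W = b3$dW, b = b3$db)
  da2 <- pool_bwd(b3$dx, dim(ca$a2)) + da2_skip
  da2 <- relu_bwd(da2, ca$f2$out)
  b2 <- conv_bwd(da2, params$c2, ca$f2$X, cps$l2, dim(ca$p1)[3])
  grads$c2 <- list(W = b2$dW, b = b2$db)
  da1 <- pool_bwd(b2$dx, dim(ca$a1)) + da1_skip
  da1 <- relu_bwd(da1, ca$f1$out)
  b1 <- conv_bwd(da1, params$c1, ca$f1$X, cps$l1, dim(ca$x)[3])
  grads$c1 <- list(W = b1$dW, b = b1$db)
  list(grads = grads, loss = lw$loss)
}

adam_init <- function(params)
  lapply(params, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                  mb = l$b * 0, vb = l$b * 0))

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(params)) {
    s <- state[[nm]]; g <- grads[[nm]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    mhW <- s$mW / (1 - beta1^t); vhW <- s$vW / (1 - beta2^t)
    mhb <- s$mb / (1 - beta1^t); vhb <- s$vb / (1 - beta2^t)
    params[[nm]]$W <- params[[nm]]$W - lr * mhW / (sqrt(vhW) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * mhb / (sqrt(vhb) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}
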