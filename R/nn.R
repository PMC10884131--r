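# Minimal convolutional network engine used by the translation module.
#
# No deep-learning framework is available for R in the target environment,
# so the few layer types the cycle-consistent model needs are implemented
# directly: 3x3 same-padding convolution (im2col + BLAS matmul), 1x1
# convolution, (leaky) ReLU, 2x2 mean pooling, nearest-neighbor 2x
# upsampling, and channel concatenation, each with a hand-derived backward
# pass. Feature maps are channel-first arrays (C, H, W, B): a conv output
# `W %*% Xcol` is then already in memory order, and the backward data pass
# is itself a 3x3 convolution of the upstream gradient with a permuted
# kernel, so no scatter loops or axis permutations are needed anywhere.

.nn_cache <- new.env(parent = emptyenv())

# im2col index vector for a 3x3 same convolution on a channel-first padded
# (C, H+2, W+2, B) array. Xcol row r = (k-1)*C + ci, k enumerating the nine
# offsets dh fastest; column = pixel (H fastest) then sample.
im2col_idx <- function(C, H, W, B) {
  key <- paste(C, H, W, B, sep = "x")
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  Hp <- H + 2L; Wp <- W + 2L
  # linear index of (ci, h, w, b): ci + (h-1)C + (w-1)C*Hp + (b-1)C*Hp*Wp
  shifts <- as.vector(outer((0:2) * C, (0:2) * C * Hp, "+"))   # dh fastest
  rowshift <- rep(shifts, each = C) + rep(0:(C - 1), times = 9)
  win <- as.vector(outer((0:(H - 1)) * C, (0:(W - 1)) * C * Hp, "+")) + 1L
  colbase <- rep(win, times = B) + rep((0:(B - 1)) * C * Hp * Wp, each = H * W)
  idx <- as.integer(outer(rowshift, colbase, "+"))
  .nn_cache[[key]] <- idx
  idx
}

conv_par <- function(cin, cout, k = 3L, init = c("he", "zero", "small")) {
  init <- match.arg(init)
  n <- k * k * cin
  W <- switch(init,
              he = matrix(stats::rnorm(cout * n, sd = sqrt(2 / n)), cout, n),
              zero = matrix(0, cout, n),
              small = matrix(stats::rnorm(cout * n, sd = 0.05), cout, n))
  list(W = W, b = numeric(cout), k = as.integer(k), cin = as.integer(cin))
}

im2col <- function(x) {
  d <- dim(x)
  im2col_cpp(x, d[1], d[2], d[3], d[4])
}

conv_fwd <- function(par, x) {
  d <- dim(x)
  Xcol <- if (par$k == 1L) { dim(x) <- c(d[1], prod(d[-1])); x } else im2col(x)
  Y <- par$W %*% Xcol + par$b
  dim(Y) <- c(nrow(par$W), d[2], d[3], d[4])
  list(y = Y, cache = list(Xcol = Xcol, dims = d))
}

# Rearranged kernel for the backward data pass: 3x3 conv of dY whose
# coefficient for (input channel ci, offset k, output channel co) is
# W[co, (flip(k)-1)*C + ci].
backward_kernel <- function(par) {
  C <- par$cin; Cout <- nrow(par$W)
  Wk <- array(par$W, c(Cout, C, 9L))                  # [co, ci, k]
  Wb <- aperm(Wk[, , 9:1, drop = FALSE], c(2, 1, 3))  # [ci, co, k_flipped]
  matrix(Wb, C, 9L * Cout)   # columns ordered co fastest within each offset,
                             # matching im2col's row order for a Cout input
}

conv_bwd <- function(par, cache, dy) {
  d <- cache$dims
  Cout <- nrow(par$W)
  dYm <- dy; dim(dYm) <- c(Cout, prod(d[2:4]))
  dW <- tcrossprod(dYm, cache$Xcol)
  db <- rowSums(dYm)
  if (par$k == 1L) {
    dx <- crossprod(par$W, dYm)
    dim(dx) <- d
  } else {
    dim(dy) <- c(Cout, d[2], d[3], d[4])
    dx <- backward_kernel(par) %*% im2col(dy)
    dim(dx) <- d
  }
  list(dW = dW, db = db, dx = dx)
}

relu_fwd <- function(x, leak = 0) {
  m <- x > 0
  list(y = x * (m + leak * (1 - m)), mask = m)
}
relu_bwd <- function(mask, dy, leak = 0) dy * (mask + leak * (1 - mask))

pool_fwd <- function(x) {
  d <- dim(x)
  o <- seq(1L, d[2], 2L); e <- o + 1L
  (x[, o, o, , drop = FALSE] + x[, e, o, , drop = FALSE] +
     x[, o, e, , drop = FALSE] + x[, e, e, , drop = FALSE]) / 4
}
pool_bwd <- function(dy) {
  d <- dim(dy)
  dy[, rep(seq_len(d[2]), each = 2L), rep(seq_len(d[3]), each = 2L), ,
     drop = FALSE] / 4
}

up_fwd <- function(x) {
  d <- dim(x)
  x[, rep(seq_len(d[2]), each = 2L), rep(seq_len(d[3]), each = 2L), ,
    drop = FALSE]
}
up_bwd <- function(dy) {
  d <- dim(dy)
  o <- seq(1L, d[2], 2L); e <- o + 1L
  dy[, o, o, , drop = FALSE] + dy[, e, o, , drop = FALSE] +
    dy[, o, e, , drop = FALSE] + dy[, e, e, , drop = FALSE]
}

concat_ch <- function(a, b) {
  da <- dim(a); db_ <- dim(b)
  y <- array(0, c(da[1] + db_[1], da[2], da[3], da[4]))
  y[seq_len(da[1]), , , ] <- a
  y[da[1] + seq_len(db_[1]), , , ] <- b
  y
}

# ---- U-Net generator (3 resolution levels, global residual) ---------------

gen_init <- function(width = 8L) {
  w <- as.integer(width)
  structure(list(c1 = conv_par(1L, w), c2 = conv_par(w, 2L * w),
                 cb = conv_par(2L * w, 2L * w), d2 = conv_par(4L * w, w),
                 d1 = conv_par(2L * w, w),
                 out = conv_par(w, 1L, k = 1L, init = "zero")),
            net = "generator")
}

gen_fwd <- function(par, x, need_cache = TRUE) {
  f1 <- conv_fwd(par$c1, x);  r1 <- relu_fwd(f1$y)
  p1 <- pool_fwd(r1$y)
  f2 <- conv_fwd(par$c2, p1); r2 <- relu_fwd(f2$y)
  p2 <- pool_fwd(r2$y)
  fb <- conv_fwd(par$cb, p2); rb <- relu_fwd(fb$y)
  u2 <- up_fwd(rb$y)
  k2 <- concat_ch(u2, r2$y)
  g2 <- conv_fwd(par$d2, k2); s2 <- relu_fwd(g2$y)
  u1 <- up_fwd(s2$y)
  k1 <- concat_ch(u1, r1$y)
  g1 <- conv_fwd(par$d1, k1); s1 <- relu_fwd(g1$y)
  fo <- conv_fwd(par$out, s1$y)
  # multiplicative residual: a learned gain field, the natural form for an
  # attenuation correction (zero background stays zero; the zero-initialized
  # head makes the untrained generator an exact identity)
  y <- x * (1 + fo$y)
  cache <- if (need_cache)
    list(f1 = f1$cache, m1 = r1$mask, f2 = f2$cache, m2 = r2$mask,
         fb = fb$cache, mb = rb$mask, g2 = g2$cache, s2 = s2$mask,
         g1 = g1$cache, s1 = s1$mask, fo = fo$cache, w = gen_width(par),
         x = x, gain = 1 + fo$y)
  list(y = y, cache = cache)
}

gen_width <- function(par) nrow(par$c1$W)

gen_bwd <- function(par, cache, dy) {
  w <- cache$w
  bo <- conv_bwd(par$out, cache$fo, dy * cache$x)
  ds1 <- relu_bwd(cache$s1, bo$dx)
  b1 <- conv_bwd(par$d1, cache$g1, ds1)
  du1 <- b1$dx[seq_len(w), , , , drop = FALSE]
  dr1_skip <- b1$dx[w + seq_len(w), , , , drop = FALSE]
  ds2 <- relu_bwd(cache$s2, up_bwd(du1))
  b2 <- conv_bwd(par$d2, cache$g2, ds2)
  du2 <- b2$dx[seq_len(2L * w), , , , drop = FALSE]
  dr2_skip <- b2$dx[2L * w + seq_len(2L * w), , , , drop = FALSE]
  drb <- relu_bwd(cache$mb, up_bwd(du2))
  bb <- conv_bwd(par$cb, cache$fb, drb)
  dr2 <- relu_bwd(cache$m2, pool_bwd(bb$dx) + dr2_skip)
  b2e <- conv_bwd(par$c2, cache$f2, dr2)
  dr1 <- relu_bwd(cache$m1, pool_bwd(b2e$dx) + dr1_skip)
  b1e <- conv_bwd(par$c1, cache$f1, dr1)
  grads <- list(c1 = list(W = b1e$dW, b = b1e$db),
                c2 = list(W = b2e$dW, b = b2e$db),
                cb = list(W = bb$dW, b = bb$db),
                d2 = list(W = b2$dW, b = b2$db),
                d1 = list(W = b1$dW, b = b1$db),
                out = list(W = bo$dW, b = bo$db))
  list(grads = grads, dx = b1e$dx + dy * cache$gain)  # product rule, gain path
}

# ---- patch discriminator ---------------------------------------------------

# The discriminator front end mean-pools the image before any convolution:
# the two domains differ in pixel-level noise texture (native PET vs
# bilinearly magnified SPECT), and an unblurred patch classifier latches
# onto that texture instead of the intensity structure the translation is
# supposed to fix. Three further downsampling levels give a receptive
# field (~52 input pixels) covering a myocardial arc; without that reach
# the classifier cannot tell an attenuation-dimmed band from background
# and collapses to a constant.
disc_init <- function(width = 8L) {
  w <- as.integer(width)
  structure(list(c1 = conv_par(1L, w), c2 = conv_par(w, 2L * w),
                 c3 = conv_par(2L * w, 2L * w),
                 out = conv_par(2L * w, 1L, k = 1L, init = "small")),
            net = "discriminator")
}

# Per-sample standardization of the discriminator input (the instance-norm
# convention of the cycle-translation architecture family). This makes D
# blind to global brightness -- a nuisance mode introduced by per-stack
# max-normalization under different noise textures -- which otherwise
# dominates the adversarial game as an unstable G/D see-saw; with it, only
# structural (spatially patterned) differences carry gradient.
innorm_fwd <- function(x) {
  d <- dim(x)
  y <- x; sds <- numeric(d[4])
  for (b in seq_len(d[4])) {
    v <- x[, , , b]
    mu <- mean(v); sd_ <- sqrt(mean((v - mu)^2) + 1e-8)
    y[, , , b] <- (v - mu) / sd_
    sds[b] <- sd_
  }
  list(y = y, sds = sds)
}
innorm_bwd <- function(cache, dy) {
  d <- dim(dy)
  dx <- dy
  for (b in seq_len(d[4])) {
    g <- dy[, , , b]; yb <- cache$y[, , , b]
    dx[, , , b] <- (g - mean(g) - yb * mean(g * yb)) / cache$sds[b]
  }
  dx
}

disc_fwd <- function(par, x, need_cache = TRUE) {
  x <- pool_fwd(x)                      # blur front end (see above)
  nz <- innorm_fwd(x); x <- nz$y
  f1 <- conv_fwd(par$c1, x);  r1 <- relu_fwd(f1$y, leak = 0.2)
  p1 <- pool_fwd(r1$y)
  f2 <- conv_fwd(par$c2, p1); r2 <- relu_fwd(f2$y, leak = 0.2)
  p2 <- pool_fwd(r2$y)
  f3 <- conv_fwd(par$c3, p2); r3 <- relu_fwd(f3$y, leak = 0.2)
  p3 <- pool_fwd(r3$y)
  fo <- conv_fwd(par$out, p3)
  cache <- if (need_cache)
    list(f1 = f1$cache, m1 = r1$mask, f2 = f2$cache, m2 = r2$mask,
         f3 = f3$cache, m3 = r3$mask, fo = fo$cache,
         nz = list(y = x, sds = nz$sds))
  list(y = fo$y, cache = cache)
}

disc_bwd <- function(par, cache, dy) {
  bo <- conv_bwd(par$out, cache$fo, dy)
  dr3 <- relu_bwd(cache$m3, pool_bwd(bo$dx), leak = 0.2)
  b3 <- conv_bwd(par$c3, cache$f3, dr3)
  dr2 <- relu_bwd(cache$m2, pool_bwd(b3$dx), leak = 0.2)
  b2 <- conv_bwd(par$c2, cache$f2, dr2)
  dr1 <- relu_bwd(cache$m1, pool_bwd(b2$dx), leak = 0.2)
  b1 <- conv_bwd(par$c1, cache$f1, dr1)
  grads <- list(c1 = list(W = b1$dW, b = b1$db),
                c2 = list(W = b2$dW, b = b2$db),
                c3 = list(W = b3$dW, b = b3$db),
                out = list(W = bo$dW, b = bo$db))
  list(grads = grads, dx = pool_bwd(innorm_bwd(cache$nz, b1$dx)))
}

# ---- parameter bookkeeping -------------------------------------------------

grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) {
    a[[nm]]$W <- a[[nm]]$W + b[[nm]]$W
    a[[nm]]$b <- a[[nm]]$b + b[[nm]]$b
  }
  a
}

# Global L2-norm gradient clipping (shared across all layers of one net).
grads_clip <- function(g, max_norm) {
  tot <- sqrt(sum(vapply(g, function(l) sum(l$W^2) + sum(l$b^2), 0)))
  if (is.finite(tot) && tot > max_norm) {
    sc <- max_norm / tot
    g <- lapply(g, function(l) list(W = l$W * sc, b = l$b * sc))
  }
  g
}

opt_init <- function(par, optimizer = "momentum") {
  state <- lapply(par, function(l) list(W = l$W * 0, b = l$b * 0))
  if (optimizer == "adam")
    state <- list(m = state, v = state, t = 0L)
  state
}

# One optimizer step. "momentum": classical SGD with momentum
# (v <- mu v - lr g; p <- p + v). "adam": Adam with beta1 = momentum
# coefficient (GAN convention: a low beta1 such as 0.5), beta2 = 0.999.
opt_step <- function(par, grads, state, lr, momentum,
                     optimizer = "momentum") {
  if (optimizer == "momentum") {
    for (nm in names(grads)) {
      state[[nm]]$W <- momentum * state[[nm]]$W - lr * grads[[nm]]$W
      state[[nm]]$b <- momentum * state[[nm]]$b - lr * grads[[nm]]$b
      par[[nm]]$W <- par[[nm]]$W + state[[nm]]$W
      par[[nm]]$b <- par[[nm]]$b + state[[nm]]$b
    }
  } else {
    b1 <- momentum; b2 <- 0.999; eps <- 1e-8
    state$t <- state$t + 1L
    corr <- sqrt(1 - b2^state$t) / (1 - b1^state$t)
    for (nm in names(grads)) {
      for (fld in c("W", "b")) {
        g <- grads[[nm]][[fld]]
        state$m[[nm]][[fld]] <- b1 * state$m[[nm]][[fld]] + (1 - b1) * g
        state$v[[nm]][[fld]] <- b2 * state$v[[nm]][[fld]] + (1 - b2) * g^2
        par[[nm]][[fld]] <- par[[nm]][[fld]] -
          lr * corr * state$m[[nm]][[fld]] / (sqrt(state$v[[nm]][[fld]]) + eps)
      }
    }
  }
  list(par = par, state = state)
}

# Apply a network (parameter list, or a plain function for testing) forward.
net_apply <- function(net, x) {
  if (is.function(net)) return(net(x))
  switch(attr(net, "net"),
         generator = gen_fwd(net, x, need_cache = FALSE)$y,
         discriminator = disc_fwd(net, x, need_cache = FALSE)$y,
         stop("not a network"))
}

# Stack a list of equally sized matrices into a channel-first (1, H, W, B)
# batch (each H x W image becomes one sample with a single channel).
batch_array <- function(imgs) {
  if (is.array(imgs) && length(dim(imgs)) == 4L) return(imgs)
  if (is.matrix(imgs)) imgs <- list(imgs)
  d <- dim(imgs[[1]])
  x <- array(unlist(imgs), c(d[1], d[2], 1L, length(imgs)))  # H, W, 1, B
  aperm(x, c(3, 1, 2, 4))
}

# First sample of a channel-first batch back to an H x W matrix.
batch_to_matrix <- function(x, b = 1L) {
  d <- dim(x)
  matrix(x[1L, , , b], d[2], d[3])
}
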