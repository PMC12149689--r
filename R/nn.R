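# Minimal neural-network primitives in base R: conv / relu / linear layers
# with hand-written backprop (im2col + BLAS matmul), a bidirectional LSTM,
# and Adam. One sample at a time; layers are environments so the forward
# cache and gradients live next to the parameters. Desk-scale by design.

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

new_layer <- function(type, ...) {
  l <- new.env(parent = emptyenv())
  l$type <- type
  args <- list(...)
  for (nm in names(args)) assign(nm, args[[nm]], envir = l)
  l
}

nn_conv <- function(cin, cout, k = 3L, stride = 1L, dilation = 1L,
                    pad = ((k - 1L) * dilation) %/% 2L, bias_init = 0) {
  l <- new_layer("conv", cin = cin, cout = cout, k = k, stride = stride,
                 dilation = dilation, pad = pad)
  l$W <- he_init(k * k * cin, cout, fan_in = k * k * cin)
  l$b <- rep(bias_init, cout)
  l$param_names <- c("W", "b")
  l
}

nn_relu <- function() {
  l <- new_layer("relu")
  l$param_names <- character()
  l
}

nn_linear <- function(din, dout, bias_init = 0) {
  l <- new_layer("linear", din = din, dout = dout)
  l$W <- he_init(din, dout, fan_in = din)
  l$b <- rep(bias_init, dout)
  l$param_names <- c("W", "b")
  l
}

# im2col index plan for a given input geometry; cached on the layer.
# `idx` holds the linear indices into the padded input for a one-shot
# gather: column block order is (ki, kj, channel), matching col2im below.
conv_plan <- function(l, H, W) {
  key <- paste(H, W)
  if (identical(l$plan_key, key)) return(l$plan)
  k <- l$k; s <- l$stride; p <- l$pad
  dil <- l$dilation %||% 1L
  keff <- (k - 1L) * dil + 1L
  Hp <- H + 2L * p; Wp <- W + 2L * p
  H0 <- (Hp - keff) %/% s + 1L; W0 <- (Wp - keff) %/% s + 1L
  r0 <- seq(1L, by = s, length.out = H0)
  c0 <- seq(1L, by = s, length.out = W0)
  cin <- l$cin
  base <- outer(r0, (c0 - 1L) * Hp, "+")  # H0 x W0 linear index, channel 1
  idx <- integer(H0 * W0 * k * k * cin)
  n0 <- H0 * W0
  pos <- 0L
  for (kj in seq_len(k)) {
    for (ki in seq_len(k)) {
      off <- (ki - 1L) * dil + (kj - 1L) * dil * Hp
      for (ch in seq_len(cin)) {
        idx[pos + seq_len(n0)] <- as.integer(base) + off +
          (ch - 1L) * Hp * Wp
        pos <- pos + n0
      }
    }
  }
  l$plan <- list(H = H, W = W, Hp = Hp, Wp = Wp, H0 = H0, W0 = W0,
                 r0 = r0, c0 = c0, idx = idx)
  l$plan_key <- key
  l$plan
}

conv_forward <- function(l, x) {
  d <- dim(x)
  pl <- conv_plan(l, d[1], d[2])
  cin <- l$cin; k <- l$k; p <- l$pad
  if (p > 0L) {
    xp <- array(0, c(pl$Hp, pl$Wp, cin))
    xp[p + seq_len(d[1]), p + seq_len(d[2]), ] <- x
  } else {
    xp <- x
  }
  n0 <- pl$H0 * pl$W0
  cols <- xp[pl$idx]
  dim(cols) <- c(n0, k * k * cin)
  l$cache_cols <- cols
  y <- cols %*% l$W
  y <- y + rep(l$b, each = n0)
  array(y, c(pl$H0, pl$W0, l$cout))
}

conv_backward <- function(l, dy) {
  pl <- l$plan
  k <- l$k; cin <- l$cin; p <- l$pad
  dil <- l$dilation %||% 1L
  n0 <- pl$H0 * pl$W0
  dY <- matrix(dy, n0, l$cout)
  l$dW <- l$dW + crossprod(l$cache_cols, dY)
  l$db <- l$db + colSums(dY)
  # the network's first layer needs no input gradient
  if (isTRUE(l$skip_input_grad)) return(NULL)
  dcols <- tcrossprod(dY, l$W)  # n0 x (k*k*cin)
  dxp <- array(0, c(pl$Hp, pl$Wp, cin))
  blk <- 0L
  for (kj in seq_len(k)) {
    for (ki in seq_len(k)) {
      ro <- pl$r0 + (ki - 1L) * dil
      co <- pl$c0 + (kj - 1L) * dil
      dxp[ro, co, ] <- dxp[ro, co, , drop = FALSE] +
        array(dcols[, blk + seq_len(cin)], c(pl$H0, pl$W0, cin))
      blk <- blk + cin
    }
  }
  dxp[p + seq_len(pl$H), p + seq_len(pl$W), , drop = FALSE]
}

layer_forward <- function(l, x) {
  switch(l$type,
    conv = conv_forward(l, x),
    relu = { l$cache_mask <- x > 0; x * l$cache_mask },
    linear = {
      xv <- as.numeric(x)
      l$cache_x <- xv
      as.numeric(crossprod(l$W, xv)) + l$b
    },
    stop("unknown layer type: ", l$type)
  )
}

layer_backward <- function(l, dy) {
  switch(l$type,
    conv = conv_backward(l, dy),
    relu = dy * l$cache_mask,
    linear = {
      dyv <- as.numeric(dy)
      l$dW <- l$dW + outer(l$cache_x, dyv)
      l$db <- l$db + dyv
      as.numeric(l$W %*% dyv)
    },
    stop("unknown layer type: ", l$type)
  )
}

net_forward <- function(layers, x) {
  for (l in layers) x <- layer_forward(l, x)
  x
}

net_backward <- function(layers, dy) {
  for (l in rev(layers)) dy <- layer_backward(l, dy)
  dy
}

zero_grads <- function(layers) {
  for (l in layers) {
    for (p in l$param_names) {
      assign(paste0("d", p), get(p, envir = l) * 0, envir = l)
    }
  }
  invisible(layers)
}

adam_step <- function(layers, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (l in layers) {
    for (p in l$param_names) {
      g <- get(paste0("d", p), envir = l)
      mres <- paste0("m_", p); vres <- paste0("v_", p)
      m <- if (exists(mres, envir = l, inherits = FALSE)) get(mres, envir = l) else g * 0
      v <- if (exists(vres, envir = l, inherits = FALSE)) get(vres, envir = l) else g * 0
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      assign(mres, m, envir = l)
      assign(vres, v, envir = l)
      mh <- m / (1 - beta1^t)
      vh <- v / (1 - beta2^t)
      assign(p, get(p, envir = l) - lr * mh / (sqrt(vh) + eps), envir = l)
    }
  }
  invisible(layers)
}

# Parameter (de)serialization: environments -> plain lists and back, so
# checkpoints are ordinary R objects and checksums are reproducible.
net_state <- function(layers) {
  lapply(layers, function(l) {
    st <- lapply(l$param_names, function(p) get(p, envir = l))
    names(st) <- l$param_names
    st
  })
}

net_load_state <- function(layers, state) {
  stopifnot(length(layers) == length(state))
  for (i in seq_along(layers)) {
    for (p in names(state[[i]])) assign(p, state[[i]][[p]], envir = layers[[i]])
  }
  invisible(layers)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# --- bidirectional LSTM -----------------------------------------------------

nn_lstm_dir <- function(din, dh) {
  l <- new_layer("lstm_dir", din = din, dh = dh)
  s <- 1 / sqrt(dh)
  l$Wx <- matrix(stats::rnorm(din * 4 * dh, 0, s), din, 4 * dh)
  l$Wh <- matrix(stats::rnorm(dh * 4 * dh, 0, s), dh, 4 * dh)
  l$b <- rep(0, 4 * dh)
  l$b[dh + seq_len(dh)] <- 1  # forget-gate bias
  l$param_names <- c("Wx", "Wh", "b")
  l
}

# X: T x din. Returns H: T x dh; caches everything needed for BPTT.
# The input projection is hoisted out of the recurrence (one T x 4dh
# matmul); only the hidden-to-hidden product stays in the time loop.
lstm_dir_forward <- function(l, X) {
  Tn <- nrow(X); dh <- l$dh
  H <- matrix(0, Tn, dh); C <- matrix(0, Tn, dh)
  G <- matrix(0, Tn, 4 * dh)  # [i | f | g | o], post-activation
  Ax <- X %*% l$Wx + rep(l$b, each = Tn)
  hprev <- rep(0, dh); cprev <- rep(0, dh)
  i1 <- seq_len(dh); i2 <- dh + i1; i3 <- 2 * dh + i1; i4 <- 3 * dh + i1
  for (t in seq_len(Tn)) {
    a <- Ax[t, ] + as.numeric(hprev %*% l$Wh)
    i <- sigmoid(a[i1]); f <- sigmoid(a[i2])
    g <- tanh(a[i3]); o <- sigmoid(a[i4])
    c <- f * cprev + i * g
    h <- o * tanh(c)
    G[t, ] <- c(i, f, g, o)
    C[t, ] <- c; H[t, ] <- h
    hprev <- h; cprev <- c
  }
  l$cache <- list(X = X, H = H, C = C, G = G)
  H
}

lstm_dir_backward <- function(l, dH) {
  ca <- l$cache
  X <- ca$X; H <- ca$H; C <- ca$C; G <- ca$G
  Tn <- nrow(X); dh <- l$dh
  dA <- matrix(0, Tn, 4 * dh)  # pre-activation gate gradients
  dh_next <- rep(0, dh); dc_next <- rep(0, dh)
  i1 <- seq_len(dh); i2 <- dh + i1; i3 <- 2 * dh + i1; i4 <- 3 * dh + i1
  zero <- rep(0, dh)
  for (t in rev(seq_len(Tn))) {
    i <- G[t, i1]; f <- G[t, i2]; g <- G[t, i3]; o <- G[t, i4]
    c <- C[t, ]
    cprev <- if (t > 1) C[t - 1, ] else zero
    dh_t <- dH[t, ] + dh_next
    tc <- tanh(c)
    do <- dh_t * tc
    dc <- dh_t * o * (1 - tc^2) + dc_next
    di <- dc * g; df <- dc * cprev; dg <- dc * i
    dc_next <- dc * f
    da <- c(di * i * (1 - i), df * f * (1 - f),
            dg * (1 - g^2), do * o * (1 - o))
    dA[t, ] <- da
    dh_next <- as.numeric(l$Wh %*% da)
  }
  Hprev <- rbind(zero, H[-Tn, , drop = FALSE])
  l$dWx <- l$dWx + crossprod(X, dA)
  l$dWh <- l$dWh + crossprod(Hprev, dA)
  l$db <- l$db + colSums(dA)
  dA %*% t(l$Wx)
}

# Bidirectional LSTM stack + linear readout: the phase regression head.
# The head is an environment so forward caches persist for backprop.
new_bilstm_head <- function(din, dh, n_layers = 2L) {
  head <- new.env(parent = emptyenv())
  layers <- list()
  d <- din
  for (i in seq_len(n_layers)) {
    layers[[length(layers) + 1L]] <- nn_lstm_dir(d, dh)  # forward dir
    layers[[length(layers) + 1L]] <- nn_lstm_dir(d, dh)  # backward dir
    d <- 2L * dh
  }
  head$layers <- layers
  head$readout <- nn_linear(d, 1L)
  head$dh <- dh
  head$n_layers <- n_layers
  head$din <- din
  head
}

bilstm_forward <- function(head, X) {
  for (i in seq_len(head$n_layers)) {
    lf <- head$layers[[2L * i - 1L]]
    lb <- head$layers[[2L * i]]
    Hf <- lstm_dir_forward(lf, X)
    Hb <- lstm_dir_forward(lb, X[rev(seq_len(nrow(X))), , drop = FALSE])
    Hb <- Hb[rev(seq_len(nrow(Hb))), , drop = FALSE]
    X <- cbind(Hf, Hb)
  }
  head$cache_top <- X
  y <- as.numeric(X %*% head$readout$W) + head$readout$b
  head$cache_y <- y
  y
}

bilstm_backward <- function(head, dy) {
  X <- head$cache_top
  ro <- head$readout
  ro$dW <- ro$dW + crossprod(X, matrix(dy, ncol = 1L))
  ro$db <- ro$db + sum(dy)
  dX <- matrix(dy, ncol = 1L) %*% t(ro$W)  # T x 2dh
  for (i in rev(seq_len(head$n_layers))) {
    lf <- head$layers[[2L * i - 1L]]
    lb <- head$layers[[2L * i]]
    dh <- head$dh
    dHf <- dX[, seq_len(dh), drop = FALSE]
    dHb <- dX[, dh + seq_len(dh), drop = FALSE]
    dXf <- lstm_dir_backward(lf, dHf)
    dXb <- lstm_dir_backward(lb, dHb[rev(seq_len(nrow(dHb))), , drop = FALSE])
    dXb <- dXb[rev(seq_len(nrow(dXb))), , drop = FALSE]
    dX <- dXf + dXb
  }
  dX
}

bilstm_all_layers <- function(head) c(head$layers, list(head$readout))
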