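# Minimal sequence-network engine (internal).
#
# The stage classifier and angle predictors are deliberately tiny networks
# (one or two convolution blocks, one recurrent layer, small dense heads),
# so they are implemented directly on base-R matrix algebra: explicit
# forward/backward passes per layer and an Adam optimizer.  Activations of
# a sequence are carried as a list over timesteps of (batch x channels)
# matrices, which keeps the 1-D convolution and the LSTM recursion short
# and transparent.  Gradient correctness is pinned down by finite-
# difference tests rather than by construction.

.glorot <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

# ---- layer constructors (params drawn from the current RNG state) -------

.layer_conv1d <- function(c_in, c_out, kernel = 3L) {
  list(type = "conv1d", c_in = c_in, c_out = c_out, kernel = kernel,
       params = list(W = .glorot(kernel * c_in, c_out),
                     b = matrix(0, 1, c_out)))
}

.layer_relu <- function() list(type = "relu", params = list())

.layer_maxpool <- function(kernel = 2L)
  list(type = "maxpool", kernel = kernel, params = list())

.layer_lstm <- function(d_in, hidden) {
  list(type = "lstm", d_in = d_in, hidden = hidden,
       params = list(Wx = .glorot(d_in, 4 * hidden),
                     Wh = .glorot(hidden, 4 * hidden),
                     b = matrix(rep(c(0, 1, 0, 0), each = hidden), 1,
                                4 * hidden)))  # forget-gate bias 1
}

.layer_last <- function() list(type = "last", params = list())
.layer_flatten <- function() list(type = "flatten", params = list())

.layer_dense <- function(d_in, d_out, relu = FALSE) {
  list(type = "dense", d_in = d_in, d_out = d_out, relu = relu,
       params = list(W = .glorot(d_in, d_out), b = matrix(0, 1, d_out)))
}

# ---- forward / backward ---------------------------------------------------

.seq_zeros <- function(B, C) matrix(0, B, C)

.fwd_conv1d <- function(layer, x) {
  Tn <- length(x); B <- nrow(x[[1]]); k <- layer$kernel
  half <- (k - 1L) %/% 2L
  z <- .seq_zeros(B, layer$c_in)
  cat_t <- vector("list", Tn)
  out <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    cols <- lapply((t - half):(t + half), function(s)
      if (s < 1L || s > Tn) z else x[[s]])
    cat_t[[t]] <- do.call(cbind, cols)
    out[[t]] <- cat_t[[t]] %*% layer$params$W +
      matrix(layer$params$b, B, layer$c_out, byrow = TRUE)
  }
  list(out = out, cache = list(cat_t = cat_t, Tn = Tn, B = B))
}

.bwd_conv1d <- function(layer, cache, dout) {
  Tn <- cache$Tn; k <- layer$kernel; half <- (k - 1L) %/% 2L
  c_in <- layer$c_in
  dW <- 0 * layer$params$W; db <- 0 * layer$params$b
  dx <- replicate(Tn, .seq_zeros(cache$B, c_in), simplify = FALSE)
  for (t in seq_len(Tn)) {
    dW <- dW + crossprod(cache$cat_t[[t]], dout[[t]])
    db <- db + colSums(dout[[t]])
    dcat <- dout[[t]] %*% t(layer$params$W)
    for (j in seq_len(k)) {
      s <- t - half + j - 1L
      if (s >= 1L && s <= Tn)
        dx[[s]] <- dx[[s]] + dcat[, ((j - 1L) * c_in + 1L):(j * c_in),
                                  drop = FALSE]
    }
  }
  list(dx = dx, grads = list(W = dW, b = db))
}

.fwd_relu <- function(layer, x) {
  if (is.list(x)) {
    out <- lapply(x, function(m) m * (m > 0))
    list(out = out, cache = lapply(x, function(m) m > 0))
  } else {
    list(out = x * (x > 0), cache = x > 0)
  }
}

.bwd_relu <- function(layer, cache, dout) {
  dx <- if (is.list(dout)) Map(function(d, m) d * m, dout, cache)
        else dout * cache
  list(dx = dx, grads = list())
}

# stride-1 max pooling with "same" length: out[t] = max over x[t .. t+k-1]
.fwd_maxpool <- function(layer, x) {
  Tn <- length(x); k <- layer$kernel
  out <- vector("list", Tn); amax <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    hi <- min(Tn, t + k - 1L)
    o <- x[[t]]; a <- matrix(1L, nrow(o), ncol(o))
    for (j in seq_len(hi - t)) {                 # ties keep the earlier frame
      m <- x[[t + j]] > o
      o[m] <- x[[t + j]][m]; a[m] <- j + 1L
    }
    out[[t]] <- o; amax[[t]] <- a
  }
  list(out = out, cache = list(amax = amax, Tn = Tn))
}

.bwd_maxpool <- function(layer, cache, dout) {
  Tn <- cache$Tn
  dx <- replicate(Tn, 0 * dout[[1]], simplify = FALSE)
  for (t in seq_len(Tn)) {
    a <- cache$amax[[t]]
    for (off in sort(unique(as.vector(a)))) {
      s <- t + off - 1L
      mask <- a == off
      dx[[s]] <- dx[[s]] + dout[[t]] * mask
    }
  }
  list(dx = dx, grads = list())
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.fwd_lstm <- function(layer, x) {
  Tn <- length(x); B <- nrow(x[[1]]); H <- layer$hidden
  h <- .seq_zeros(B, H); cc <- .seq_zeros(B, H)
  gates <- vector("list", Tn); hs <- vector("list", Tn)
  cs <- vector("list", Tn); cprev <- vector("list", Tn)
  bmat <- matrix(layer$params$b, B, 4 * H, byrow = TRUE)
  for (t in seq_len(Tn)) {
    z <- x[[t]] %*% layer$params$Wx + h %*% layer$params$Wh + bmat
    ig <- .sigmoid(z[, 1:H, drop = FALSE])
    fg <- .sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    gg <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
    og <- .sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
    cprev[[t]] <- cc
    cc <- fg * cc + ig * gg
    h <- og * tanh(cc)
    gates[[t]] <- list(i = ig, f = fg, g = gg, o = og)
    hs[[t]] <- h; cs[[t]] <- cc
  }
  list(out = hs, cache = list(x = x, gates = gates, hs = hs, cs = cs,
                              cprev = cprev, Tn = Tn, B = B, H = H))
}

.bwd_lstm <- function(layer, cache, dout) {
  Tn <- cache$Tn; B <- cache$B; H <- cache$H
  dWx <- 0 * layer$params$Wx; dWh <- 0 * layer$params$Wh
  db <- 0 * layer$params$b
  dx <- vector("list", Tn)
  dh_next <- .seq_zeros(B, H); dc_next <- .seq_zeros(B, H)
  for (t in rev(seq_len(Tn))) {
    g <- cache$gates[[t]]
    tc <- tanh(cache$cs[[t]])
    dh <- dout[[t]] + dh_next
    do_ <- dh * tc * g$o * (1 - g$o)
    dc <- dh * g$o * (1 - tc^2) + dc_next
    di <- dc * g$g * g$i * (1 - g$i)
    df <- dc * cache$cprev[[t]] * g$f * (1 - g$f)
    dg <- dc * g$i * (1 - g$g^2)
    dz <- cbind(di, df, dg, do_)
    dWx <- dWx + crossprod(cache$x[[t]], dz)
    hprev <- if (t > 1L) cache$hs[[t - 1L]] else .seq_zeros(B, H)
    dWh <- dWh + crossprod(hprev, dz)
    db <- db + colSums(dz)
    dx[[t]] <- dz %*% t(layer$params$Wx)
    dh_next <- dz %*% t(layer$params$Wh)
    dc_next <- dc * g$f
  }
  list(dx = dx, grads = list(Wx = dWx, Wh = dWh, b = db))
}

.fwd_last <- function(layer, x)
  list(out = x[[length(x)]], cache = list(Tn = length(x), B = nrow(x[[1]]),
                                          C = ncol(x[[1]])))

.bwd_last <- function(layer, cache, dout) {
  dx <- replicate(cache$Tn, matrix(0, cache$B, cache$C), simplify = FALSE)
  dx[[cache$Tn]] <- dout
  list(dx = dx, grads = list())
}

.fwd_flatten <- function(layer, x)
  list(out = do.call(cbind, x),
       cache = list(Tn = length(x), C = ncol(x[[1]])))

.bwd_flatten <- function(layer, cache, dout) {
  dx <- lapply(seq_len(cache$Tn), function(t)
    dout[, ((t - 1L) * cache$C + 1L):(t * cache$C), drop = FALSE])
  list(dx = dx, grads = list())
}

.fwd_dense <- function(layer, x) {
  z <- x %*% layer$params$W +
    matrix(layer$params$b, nrow(x), layer$d_out, byrow = TRUE)
  out <- if (layer$relu) z * (z > 0) else z
  list(out = out, cache = list(x = x, mask = if (layer$relu) z > 0 else NULL))
}

.bwd_dense <- function(layer, cache, dout) {
  if (layer$relu) dout <- dout * cache$mask
  list(dx = dout %*% t(layer$params$W),
       grads = list(W = crossprod(cache$x, dout), b = colSums(dout)))
}

.fwd_dispatch <- list(conv1d = .fwd_conv1d, relu = .fwd_relu,
                      maxpool = .fwd_maxpool, lstm = .fwd_lstm,
                      last = .fwd_last, flatten = .fwd_flatten,
                      dense = .fwd_dense)
.bwd_dispatch <- list(conv1d = .bwd_conv1d, relu = .bwd_relu,
                      maxpool = .bwd_maxpool, lstm = .bwd_lstm,
                      last = .bwd_last, flatten = .bwd_flatten,
                      dense = .bwd_dense)

.net_forward <- function(net, x, keep_cache = TRUE) {
  caches <- vector("list", length(net))
  for (l in seq_along(net)) {
    r <- .fwd_dispatch[[net[[l]]$type]](net[[l]], x)
    x <- r$out
    if (keep_cache) caches[[l]] <- r$cache
  }
  list(out = x, caches = caches)
}

.net_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net))
  for (l in rev(seq_along(net))) {
    r <- .bwd_dispatch[[net[[l]]$type]](net[[l]], caches[[l]], dout)
    dout <- r$dx
    grads[[l]] <- r$grads
  }
  grads
}

# ---- losses ---------------------------------------------------------------

.softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# y: integer class vector (1-based); returns mean cross-entropy and dlogits
.loss_softmax_ce <- function(logits, y) {
  p <- .softmax(logits)
  B <- nrow(logits)
  idx <- cbind(seq_len(B), y)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dl <- p
  dl[idx] <- dl[idx] - 1
  list(loss = loss, dlogits = dl / B)
}

.loss_mse <- function(pred, y) {
  B <- nrow(pred)
  d <- pred - y
  list(loss = mean(d^2), dlogits = 2 * d / (B * ncol(pred)))
}

# ---- optimizer ------------------------------------------------------------

.adam_init <- function(net) {
  lapply(net, function(l) lapply(l$params, function(p)
    list(m = 0 * p, v = 0 * p)))
}

.adam_step <- function(net, grads, opt, lr, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(net)) {
    for (nm in names(net[[l]]$params)) {
      g <- grads[[l]][[nm]]
      if (is.null(g)) next
      if (is.null(dim(g)) && !is.null(dim(net[[l]]$params[[nm]])))
        g <- array(g, dim(net[[l]]$params[[nm]]))
      st <- opt[[l]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mh <- st$m / (1 - beta1^t)
      vh <- st$v / (1 - beta2^t)
      net[[l]]$params[[nm]] <- net[[l]]$params[[nm]] -
        lr * mh / (sqrt(vh) + eps)
      opt[[l]][[nm]] <- st
    }
  }
  list(net = net, opt = opt)
}

# ---- shared training loop -------------------------------------------------

# X: array (n, T, C) -> list over timesteps of (n x C) matrices
.seq_slice <- function(X) {
  Tn <- dim(X)[2]
  lapply(seq_len(Tn), function(t) {
    m <- X[, t, , drop = FALSE]
    dim(m) <- dim(m)[c(1, 3)]
    m
  })
}

.train_network <- function(net, X_tr, y_tr, X_va, y_va, loss_fn,
                           epochs, batch_size, lr) {
  n <- dim(X_tr)[1]
  opt <- .adam_init(net)
  hist_tr <- numeric(epochs); hist_va <- numeric(epochs)
  step <- 0L
  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    losses <- c()
    for (b0 in seq(1L, n, by = batch_size)) {
      idx <- perm[b0:min(n, b0 + batch_size - 1L)]
      xb <- .seq_slice(X_tr[idx, , , drop = FALSE])
      yb <- if (is.matrix(y_tr)) y_tr[idx, , drop = FALSE] else y_tr[idx]
      fw <- .net_forward(net, xb)
      ls <- loss_fn(fw$out, yb)
      grads <- .net_backward(net, fw$caches, ls$dlogits)
      step <- step + 1L
      upd <- .adam_step(net, grads, opt, lr, step)
      net <- upd$net; opt <- upd$opt
      losses <- c(losses, ls$loss)
    }
    hist_tr[ep] <- mean(losses)
    va <- .net_forward(net, .seq_slice(X_va), keep_cache = FALSE)
    hist_va[ep] <- loss_fn(va$out, if (is.matrix(y_va)) y_va else y_va)$loss
  }
  list(net = net, history = data.frame(epoch = seq_len(epochs),
                                       train = hist_tr, val = hist_va))
}
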