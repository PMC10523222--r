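## Internal neural-network primitives for the posture classifier.
## Everything operates on one sequence at a time: X is a T x C matrix with
## time in rows. Gradients are hand-derived and validated against
## finite differences in the test suite.

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

## --- temporal (1D) convolution, valid padding, stride 1 ----------------

## Unroll K consecutive frames per output step: (T-K+1) x (K*Cin),
## offset-major column layout.
im2col <- function(X, K) {
  Tn <- nrow(X)
  Tout <- Tn - K + 1L
  do.call(cbind, lapply(seq_len(K), function(j) X[j:(Tout + j - 1L), , drop = FALSE]))
}

conv1d_forward <- function(X, W, b, K) {
  Z <- im2col(X, K)
  A <- Z %*% W + matrix(b, nrow(Z), length(b), byrow = TRUE)
  list(A = A, Z = Z, Tin = nrow(X), Cin = ncol(X))
}

conv1d_backward <- function(dA, cache, W, K) {
  dW <- crossprod(cache$Z, dA)
  db <- colSums(dA)
  dZ <- dA %*% t(W)
  dX <- matrix(0, cache$Tin, cache$Cin)
  Tout <- nrow(dA)
  for (j in seq_len(K)) {
    cols <- ((j - 1L) * cache$Cin + 1L):(j * cache$Cin)
    dX[j:(Tout + j - 1L), ] <- dX[j:(Tout + j - 1L), ] + dZ[, cols, drop = FALSE]
  }
  list(dX = dX, dW = dW, db = db)
}

## --- LSTM (single direction) -------------------------------------------

## Gate order in the 4H-wide weight blocks: input, forget, cell, output.
lstm_init <- function(cin, H) {
  b <- rep(0, 4L * H)
  b[(H + 1L):(2L * H)] <- 1   # forget-gate bias 1: standard stable init
  list(Wx = glorot(cin, 4L * H), Wh = glorot(H, 4L * H), b = b)
}

sigm <- function(x) 1 / (1 + exp(-x))

lstm_forward <- function(X, p) {
  Tn <- nrow(X)
  H <- nrow(p$Wh)
  XW <- X %*% p$Wx
  I <- F_ <- G <- O <- C <- tanhC <- Hs <- Hprev <- matrix(0, Tn, H)
  h <- c_ <- rep(0, H)
  i1 <- 1:H; i2 <- (H + 1L):(2L * H); i3 <- (2L * H + 1L):(3L * H)
  i4 <- (3L * H + 1L):(4L * H)
  for (t in seq_len(Tn)) {
    Hprev[t, ] <- h
    a <- XW[t, ] + h %*% p$Wh + p$b
    i <- sigm(a[i1]); f <- sigm(a[i2]); g <- tanh(a[i3]); o <- sigm(a[i4])
    c_prev <- c_
    c_ <- f * c_prev + i * g
    tc <- tanh(c_)
    h <- o * tc
    I[t, ] <- i; F_[t, ] <- f; G[t, ] <- g; O[t, ] <- o
    C[t, ] <- c_; tanhC[t, ] <- tc; Hs[t, ] <- h
  }
  list(h_last = h,
       cache = list(X = X, I = I, F_ = F_, G = G, O = O, C = C,
                    tanhC = tanhC, Hs = Hs, Hprev = Hprev))
}

## Backprop-through-time. External gradient arrives only at the final
## hidden state (the classifier reads the last state of each direction).
lstm_backward <- function(d_hlast, ca, p) {
  Tn <- nrow(ca$X)
  H <- length(d_hlast)
  dA <- matrix(0, Tn, 4L * H)
  dh <- d_hlast
  dc <- rep(0, H)
  i1 <- 1:H; i2 <- (H + 1L):(2L * H); i3 <- (2L * H + 1L):(3L * H)
  i4 <- (3L * H + 1L):(4L * H)
  tWh <- t(p$Wh)
  for (t in Tn:1) {
    i <- ca$I[t, ]; f <- ca$F_[t, ]; g <- ca$G[t, ]; o <- ca$O[t, ]
    tc <- ca$tanhC[t, ]
    c_prev <- if (t > 1L) ca$C[t - 1L, ] else rep(0, H)
    do_ <- dh * tc
    dct <- dh * o * (1 - tc^2) + dc
    di <- dct * g
    df <- dct * c_prev
    dg <- dct * i
    da <- numeric(4L * H)
    da[i1] <- di * i * (1 - i)
    da[i2] <- df * f * (1 - f)
    da[i3] <- dg * (1 - g^2)
    da[i4] <- do_ * o * (1 - o)
    dA[t, ] <- da
    dh <- as.vector(da %*% tWh)
    dc <- dct * f
  }
  list(dWx = crossprod(ca$X, dA),
       dWh = crossprod(ca$Hprev, dA),
       db = colSums(dA),
       dX = dA %*% t(p$Wx))
}

## --- dropout (inverted) -------------------------------------------------

dropout_forward <- function(H, rate, training) {
  if (!training || rate <= 0) return(list(H = H, mask = NULL))
  mask <- matrix(stats::runif(length(H)) >= rate, nrow(H)) / (1 - rate)
  list(H = H * mask, mask = mask)
}

dropout_backward <- function(dH, mask) {
  if (is.null(mask)) dH else dH * mask
}

## --- full model: parameters, forward, loss gradient ---------------------

init_params <- function(cfg) {
  p <- list()
  cin <- 20L
  if (cfg$variant %in% c("full", "conv_only")) {
    p$conv <- vector("list", length(cfg$conv_kernels))
    for (l in seq_along(cfg$conv_kernels)) {
      K <- cfg$conv_kernels[l]
      cout <- cfg$conv_filters[l]
      p$conv[[l]] <- list(W = glorot(K * cin, cout), b = rep(0, cout))
      cin <- cout
    }
  }
  if (cfg$variant %in% c("full", "lstm_only")) {
    H <- cfg$lstm_units %/% 2L   # "64 outputs" = 32 per direction, concatenated
    p$lstm_fwd <- lstm_init(cin, H)
    p$lstm_bwd <- lstm_init(cin, H)
    feat <- cfg$lstm_units
  } else {
    feat <- cin
  }
  p$fc <- list(W = glorot(feat, cfg$fc_units), b = rep(0, cfg$fc_units))
  p$out <- list(W = glorot(cfg$fc_units, cfg$n_classes), b = rep(0, cfg$n_classes))
  p
}

## Minimum temporal length a variant can ingest (valid-padding shrinkage).
min_input_length <- function(cfg) {
  if (cfg$variant %in% c("full", "conv_only")) {
    sum(cfg$conv_kernels - 1L) + 1L
  } else {
    1L
  }
}

## Forward pass for one T x 20 sequence. Returns class probabilities
## (order: correct, incorrect) and, when training, the caches needed for
## the backward pass.
model_forward <- function(params, cfg, X, training = FALSE) {
  caches <- list()
  H <- X
  if (cfg$variant %in% c("full", "conv_only")) {
    caches$conv <- vector("list", length(cfg$conv_kernels))
    for (l in seq_along(cfg$conv_kernels)) {
      K <- cfg$conv_kernels[l]
      fw <- conv1d_forward(H, params$conv[[l]]$W, params$conv[[l]]$b, K)
      R <- pmax(fw$A, 0)
      dr <- dropout_forward(R, cfg$dropout, training)
      caches$conv[[l]] <- list(fw = fw, mask = dr$mask)
      H <- dr$H
    }
  }
  if (cfg$variant %in% c("full", "lstm_only")) {
    fwd <- lstm_forward(H, params$lstm_fwd)
    Hrev <- H[nrow(H):1, , drop = FALSE]
    bwd <- lstm_forward(Hrev, params$lstm_bwd)
    feat <- c(fwd$h_last, bwd$h_last)
    caches$lstm <- list(fwd = fwd$cache, bwd = bwd$cache, Tc = nrow(H))
  } else {
    feat <- colMeans(H)
    caches$pool_T <- nrow(H)
  }
  a_fc <- as.vector(feat %*% params$fc$W) + params$fc$b
  r_fc <- pmax(a_fc, 0)
  dr_fc <- dropout_forward(matrix(r_fc, 1L), cfg$dropout, training)
  f <- as.vector(dr_fc$H)
  logits <- as.vector(f %*% params$out$W) + params$out$b
  z <- logits - max(logits)
  probs <- exp(z) / sum(exp(z))
  caches$feat <- feat; caches$a_fc <- a_fc; caches$fc_mask <- dr_fc$mask
  caches$f <- f; caches$probs <- probs
  list(probs = probs, caches = caches)
}

## Cross-entropy loss and gradients for one (X, y) pair; y is 1 for
## "correct", 2 for "incorrect".
loss_and_grads <- function(params, cfg, X, y, training = TRUE) {
  fw <- model_forward(params, cfg, X, training = training)
  ca <- fw$caches
  probs <- fw$probs
  loss <- -log(max(probs[y], 1e-12))
  g <- zero_like(params)

  dlogits <- probs
  dlogits[y] <- dlogits[y] - 1
  g$out$W <- outer(ca$f, dlogits)
  g$out$b <- dlogits
  df <- as.vector(params$out$W %*% dlogits)
  df <- as.vector(dropout_backward(matrix(df, 1L), ca$fc_mask))
  da_fc <- df * (ca$a_fc > 0)
  g$fc$W <- outer(ca$feat, da_fc)
  g$fc$b <- da_fc
  dfeat <- as.vector(params$fc$W %*% da_fc)

  if (cfg$variant %in% c("full", "lstm_only")) {
    Hd <- cfg$lstm_units %/% 2L
    bf <- lstm_backward(dfeat[1:Hd], ca$lstm$fwd, params$lstm_fwd)
    bb <- lstm_backward(dfeat[(Hd + 1L):(2L * Hd)], ca$lstm$bwd, params$lstm_bwd)
    g$lstm_fwd <- list(Wx = bf$dWx, Wh = bf$dWh, b = bf$db)
    g$lstm_bwd <- list(Wx = bb$dWx, Wh = bb$dWh, b = bb$db)
    dH <- bf$dX + bb$dX[nrow(bb$dX):1, , drop = FALSE]
  } else {
    Tc <- ca$pool_T
    dH <- matrix(dfeat / Tc, Tc, length(dfeat), byrow = TRUE)
  }

  if (cfg$variant %in% c("full", "conv_only")) {
    for (l in rev(seq_along(cfg$conv_kernels))) {
      cc <- ca$conv[[l]]
      dR <- dropout_backward(dH, cc$mask)
      dA <- dR * (cc$fw$A > 0)
      bk <- conv1d_backward(dA, cc$fw, params$conv[[l]]$W, cfg$conv_kernels[l])
      g$conv[[l]] <- list(W = bk$dW, b = bk$db)
      dH <- bk$dX
    }
  }
  list(loss = loss, grads = g, probs = probs)
}

## --- parameter-tree utilities and Adam ----------------------------------

zero_like <- function(p) {
  rapply(p, function(m) m * 0, how = "replace")
}

tree_axpy <- function(acc, g, a = 1) {
  if (is.list(acc)) {
    for (n in seq_along(acc)) acc[[n]] <- tree_axpy(acc[[n]], g[[n]], a)
    acc
  } else acc + a * g
}

tree_scale <- function(p, a) rapply(p, function(m) m * a, how = "replace")

n_params <- function(p) sum(rapply(p, length, how = "unlist"))

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  tt <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (n in seq_along(p)) {
        r <- upd(p[[n]], g[[n]], m[[n]], v[[n]])
        out_p[[n]] <- r$p; out_m[[n]] <- r$m; out_v[[n]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^tt)
    vhat <- v / (1 - beta2^tt)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = tt))
}
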