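# Internal two-layer stacked LSTM engine.
#
# Pure R on BLAS-backed matrix products: the batch sizes (<= 240), sequence
# lengths (~10) and hidden sizes used here keep all heavy work inside
# crossprod()/%*%, so a compiled kernel buys little. Analytic gradients are
# verified against central finite differences in the test suite.
#
# Parameter layout per layer: W (D_in x 4H), U (H x 4H), b (4H), with gate
# column blocks ordered i (input), f (forget), g (candidate), o (output).
# Head: fc$W (H x n_classes), fc$b (n_classes).

.sigmoid <- function(x) 1 / (1 + exp(-x))

# uniform(-1/sqrt(H), 1/sqrt(H)) init for all tensors; draws come from the
# caller's (seeded) RNG stream
.lstm_init_params <- function(input_dim, hidden_dim, num_classes, num_layers = 2L) {
  H <- hidden_dim
  k <- 1 / sqrt(H)
  ru <- function(n) stats::runif(n, -k, k)
  layers <- vector("list", num_layers)
  d_in <- input_dim
  for (l in seq_len(num_layers)) {
    layers[[l]] <- list(W = matrix(ru(d_in * 4L * H), d_in, 4L * H),
                        U = matrix(ru(H * 4L * H), H, 4L * H),
                        b = ru(4L * H))
    d_in <- H
  }
  list(layers = layers,
       fc = list(W = matrix(ru(H * num_classes), H, num_classes),
                 b = ru(num_classes)))
}

# xs: list of N matrices (B x D_in). Returns probs (B x n_classes), the
# pre-dropout last hidden state of the top layer, and caches for backprop.
.lstm_forward <- function(params, xs, dropout_p = 0, train = FALSE) {
  N <- length(xs)
  B <- nrow(xs[[1L]])
  n_layers <- length(params$layers)
  caches <- vector("list", n_layers)
  inp <- xs
  for (l in seq_len(n_layers)) {
    lay <- params$layers[[l]]
    H <- ncol(lay$U)/4L
    h <- matrix(0, B, H); cs <- matrix(0, B, H)
    hs <- vector("list", N)
    cache <- vector("list", N)
    brow <- matrix(lay$b, B, 4L * H, byrow = TRUE)
    gi <- 1:H; gf <- (H + 1L):(2L * H); gg <- (2L * H + 1L):(3L * H); go <- (3L * H + 1L):(4L * H)
    for (t in seq_len(N)) {
      A <- inp[[t]] %*% lay$W + h %*% lay$U + brow
      i <- .sigmoid(A[, gi, drop = FALSE])
      f <- .sigmoid(A[, gf, drop = FALSE])
      g <- tanh(A[, gg, drop = FALSE])
      o <- .sigmoid(A[, go, drop = FALSE])
      c_new <- f * cs + i * g
      tc <- tanh(c_new)
      h_new <- o * tc
      cache[[t]] <- list(x = inp[[t]], hprev = h, cprev = cs,
                         i = i, f = f, g = g, o = o, tc = tc)
      h <- h_new; cs <- c_new; hs[[t]] <- h_new
    }
    caches[[l]] <- cache
    inp <- hs
  }
  hN <- inp[[N]]
  if (train && dropout_p > 0) {
    mask <- (matrix(stats::runif(length(hN)), nrow(hN), ncol(hN)) >= dropout_p) /
      (1 - dropout_p)
    hd <- hN * mask
  } else {
    mask <- NULL
    hd <- hN
  }
  logits <- hd %*% params$fc$W + matrix(params$fc$b, B, length(params$fc$b), byrow = TRUE)
  z <- logits - apply(logits, 1L, max)
  ez <- exp(z)
  probs <- ez / rowSums(ez)
  list(probs = probs, hN = hN, hd = hd, mask = mask, caches = caches, N = N, B = B)
}

# mean cross-entropy of forward output `fw` against 1-based class vector y
.ce_loss <- function(fw, y) {
  p <- fw$probs[cbind(seq_along(y), y)]
  -mean(log(pmax(p, 1e-300)))
}

# BPTT through one LSTM layer.
# dh_ext: list of N external gradients into h_t (NULL entries allowed).
.lstm_layer_backward <- function(lay, cache, dh_ext, need_dx = TRUE) {
  N <- length(cache)
  B <- nrow(cache[[1L]]$i); H <- ncol(cache[[1L]]$i)
  gW <- matrix(0, nrow(lay$W), ncol(lay$W))
  gU <- matrix(0, H, 4L * H)
  gb <- numeric(4L * H)
  dh_rec <- matrix(0, B, H); dc_rec <- matrix(0, B, H)
  dx <- if (need_dx) vector("list", N) else NULL
  tU <- t(lay$U); tW <- t(lay$W)
  for (t in rev(seq_len(N))) {
    cc <- cache[[t]]
    dh <- dh_rec
    if (!is.null(dh_ext[[t]])) dh <- dh + dh_ext[[t]]
    dc <- dc_rec + dh * cc$o * (1 - cc$tc^2)
    do_ <- dh * cc$tc
    di <- dc * cc$g
    df <- dc * cc$cprev
    dg <- dc * cc$i
    dA <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    gW <- gW + crossprod(cc$x, dA)
    gU <- gU + crossprod(cc$hprev, dA)
    gb <- gb + colSums(dA)
    dh_rec <- dA %*% tU
    dc_rec <- dc * cc$f
    if (need_dx) dx[[t]] <- dA %*% tW
  }
  list(gW = gW, gU = gU, gb = gb, dx = dx)
}

# full backward pass; y is a 1-based class index vector
.lstm_backward <- function(params, fw, y) {
  B <- fw$B; N <- fw$N
  dlogits <- fw$probs
  dlogits[cbind(seq_len(B), y)] <- dlogits[cbind(seq_len(B), y)] - 1
  dlogits <- dlogits / B
  gfcW <- crossprod(fw$hd, dlogits)
  gfcb <- colSums(dlogits)
  dhd <- tcrossprod(dlogits, params$fc$W)
  dhN <- if (is.null(fw$mask)) dhd else dhd * fw$mask
  n_layers <- length(params$layers)
  glayers <- vector("list", n_layers)
  # top layer: only the last step receives an external gradient
  dh_ext <- vector("list", N)
  dh_ext[[N]] <- dhN
  for (l in rev(seq_len(n_layers))) {
    bk <- .lstm_layer_backward(params$layers[[l]], fw$caches[[l]], dh_ext,
                               need_dx = (l > 1L))
    glayers[[l]] <- list(W = bk$gW, U = bk$gU, b = bk$gb)
    if (l > 1L) dh_ext <- bk$dx # layer below gets gradient at every step
  }
  list(layers = glayers, fc = list(W = gfcW, b = gfcb))
}

# elementwise RMSProp: cache <- rho*cache + (1-rho)*g^2;
# p <- p - lr * g / (sqrt(cache) + eps). Walks the nested param list.
.rmsprop_step <- function(params, grads, state, lr, rho, eps) {
  step1 <- function(p, g, s) {
    s2 <- rho * s + (1 - rho) * g * g
    list(p = p - lr * g / (sqrt(s2) + eps), s = s2)
  }
  for (l in seq_along(params$layers)) {
    for (nm in c("W", "U", "b")) {
      r <- step1(params$layers[[l]][[nm]], grads$layers[[l]][[nm]],
                 state$layers[[l]][[nm]])
      params$layers[[l]][[nm]] <- r$p
      state$layers[[l]][[nm]] <- r$s
    }
  }
  for (nm in c("W", "b")) {
    r <- step1(params$fc[[nm]], grads$fc[[nm]], state$fc[[nm]])
    params$fc[[nm]] <- r$p
    state$fc[[nm]] <- r$s
  }
  list(params = params, state = state)
}

.rmsprop_init_state <- function(params) {
  zero_like <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  list(layers = lapply(params$layers, function(l) lapply(l, zero_like)),
       fc = lapply(params$fc, zero_like))
}

# Stack a list of feature_sequence matrices (N x D each) into the forward
# pass input: a list of N matrices (B x D), one per time step.
.stack_sequences <- function(seqs) {
  N <- nrow(seqs[[1L]])
  lapply(seq_len(N), function(t)
    do.call(rbind, lapply(seqs, function(s) s[t, , drop = FALSE])))
}

# Row-subset a stacked input list
.subset_steps <- function(xs, idx) {
  lapply(xs, function(m) m[idx, , drop = FALSE])
}
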