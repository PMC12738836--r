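# Neural-network primitives (forward + backward), matrix-based.
#
# Activations between convolutional layers are stored position-major: a batch
# of n sequences of length L with C channels is the matrix (n*L, C) whose row
# r corresponds to sample ((r-1) %% n) + 1 at position floor((r-1)/n) + 1.
# This makes a k-tap convolution k dense matrix products (one per tap) on
# contiguous row blocks, which is what keeps a pure-R implementation fast.
# Every *_forward returns list(out, cache); every *_backward mirrors it.

sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- 1-D convolution (same-length padding) --------------------------------

# broadcast-add a length-C vector to every row of an (N, C) matrix
addrow <- function(X, b) X + rep(b, each = nrow(X))

conv1d_forward <- function(Xm, n, L, W, b) {
  k <- dim(W)[1]; cin <- dim(W)[2]; cout <- dim(W)[3]
  p <- (k - 1L) %/% 2L # kernels are odd, padding exact
  Lp <- L + 2L * p
  Xpad <- matrix(0, n * Lp, cin)
  Xpad[(p * n + 1L):((p + L) * n), ] <- Xm
  Y <- matrix(rep(b, each = n * L), n * L, cout)
  for (d in seq_len(k)) {
    rows <- ((d - 1L) * n + 1L):((d + L - 1L) * n)
    Y <- Y + Xpad[rows, , drop = FALSE] %*% matrix(W[d, , ], cin, cout)
  }
  list(out = Y, cache = list(Xpad = Xpad, n = n, L = L, W = W))
}

conv1d_backward <- function(dY, cache) {
  W <- cache$W; n <- cache$n; L <- cache$L
  k <- dim(W)[1]; cin <- dim(W)[2]; cout <- dim(W)[3]
  p <- (k - 1L) %/% 2L
  dW <- array(0, dim(W))
  dXpad <- matrix(0, nrow(cache$Xpad), cin)
  for (d in seq_len(k)) {
    rows <- ((d - 1L) * n + 1L):((d + L - 1L) * n)
    Xb <- cache$Xpad[rows, , drop = FALSE]
    dW[d, , ] <- crossprod(Xb, dY)
    dXpad[rows, ] <- dXpad[rows, ] + dY %*% t(matrix(W[d, , ], cin, cout))
  }
  list(
    dX = dXpad[(p * n + 1L):((p + L) * n), , drop = FALSE],
    dW = dW, db = colSums(dY)
  )
}

## ---- batch normalisation ---------------------------------------------------

bn_forward <- function(X, gamma, beta, rm, rv, training, momentum = 0.1,
                       eps = 1e-5) {
  N <- nrow(X)
  if (training) {
    mu <- colMeans(X)
    Xc <- X - rep(mu, each = N)
    v <- colMeans(Xc * Xc)
    invstd <- 1 / sqrt(v + eps)
    xhat <- Xc * rep(invstd, each = N)
    rm_new <- (1 - momentum) * rm + momentum * mu
    rv_new <- (1 - momentum) * rv + momentum * v * N / max(N - 1, 1)
  } else {
    invstd <- 1 / sqrt(rv + eps)
    xhat <- (X - rep(rm, each = N)) * rep(invstd, each = N)
    rm_new <- rm; rv_new <- rv
  }
  out <- xhat * rep(gamma, each = N) + rep(beta, each = N)
  list(
    out = out,
    cache = list(xhat = xhat, invstd = invstd, gamma = gamma,
                 training = training),
    rm = rm_new, rv = rv_new
  )
}

bn_backward <- function(dY, cache) {
  N <- nrow(dY); C <- ncol(dY)
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  g_inv <- cache$gamma * cache$invstd
  if (cache$training) {
    dX <- (dY - matrix(dbeta / N, N, C, byrow = TRUE) -
             xhat * matrix(dgamma / N, N, C, byrow = TRUE)) *
      matrix(g_inv, N, C, byrow = TRUE)
  } else {
    dX <- dY * matrix(g_inv, N, C, byrow = TRUE)
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

## ---- squeeze-and-excitation channel attention -----------------------------

se_forward <- function(X, n, L, W1, b1, W2, b2, ablate = FALSE) {
  C <- ncol(X)
  if (ablate) {
    return(list(out = X, cache = list(ablate = TRUE, n = n, L = L)))
  }
  s <- matrix(0, n, C)
  for (c in seq_len(C)) s[, c] <- rowMeans(matrix(X[, c], n, L))
  z1 <- addrow(s %*% W1, b1)
  a1 <- pmax(z1, 0)
  z2 <- addrow(a1 %*% W2, b2)
  g <- sigmoid(z2)
  Gexp <- g[rep(seq_len(n), L), , drop = FALSE]
  list(
    out = X * Gexp,
    cache = list(X = X, s = s, z1 = z1, a1 = a1, g = g, Gexp = Gexp,
                 W1 = W1, W2 = W2, n = n, L = L, ablate = FALSE)
  )
}

se_backward <- function(dY, cache) {
  if (isTRUE(cache$ablate)) {
    return(list(dX = dY, dW1 = NULL, db1 = NULL, dW2 = NULL, db2 = NULL))
  }
  n <- cache$n; L <- cache$L; C <- ncol(dY)
  dX <- dY * cache$Gexp
  prod_ <- dY * cache$X
  dg <- matrix(0, n, C)
  for (c in seq_len(C)) dg[, c] <- rowSums(matrix(prod_[, c], n, L))
  dz2 <- dg * cache$g * (1 - cache$g)
  dW2 <- crossprod(cache$a1, dz2)
  db2 <- colSums(dz2)
  da1 <- dz2 %*% t(cache$W2)
  dz1 <- da1 * (cache$z1 > 0)
  dW1 <- crossprod(cache$s, dz1)
  db1 <- colSums(dz1)
  ds <- dz1 %*% t(cache$W1)
  dX <- dX + ds[rep(seq_len(n), L), , drop = FALSE] / L
  list(dX = dX, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

## ---- max pooling (kernel = stride = 2 along the position axis) ------------

maxpool_forward <- function(X, n, L, pool = 2L) {
  T_ <- L %/% pool
  stopifnot(pool == 2L)
  odd_rows <- rep((seq(1L, 2L * T_, by = 2L) - 1L) * n, each = n) +
    rep(seq_len(n), T_)
  even_rows <- odd_rows + n
  A <- X[odd_rows, , drop = FALSE]
  B <- X[even_rows, , drop = FALSE]
  take_a <- A >= B
  list(
    out = A * take_a + B * !take_a,
    cache = list(take_a = take_a, odd_rows = odd_rows, even_rows = even_rows,
                 n = n, L = L, C = ncol(X))
  )
}

maxpool_backward <- function(dY, cache) {
  dX <- matrix(0, cache$n * cache$L, cache$C)
  dX[cache$odd_rows, ] <- dY * cache$take_a
  dX[cache$even_rows, ] <- dY * (!cache$take_a)
  dX
}

## ---- dropout (inverted) ----------------------------------------------------

dropout_forward <- function(X, p, training) {
  if (!training || p <= 0) {
    return(list(out = X, cache = NULL))
  }
  mask <- matrix(
    (runif(length(X)) >= p) / (1 - p),
    nrow(X), ncol(X)
  )
  list(out = X * mask, cache = mask)
}

dropout_backward <- function(dY, cache) {
  if (is.null(cache)) dY else dY * cache
}

## ---- LSTM (one direction) --------------------------------------------------
# Gate layout in the 4H-wide weight matrices: [input, forget, cell, output].

lstm_dir_forward <- function(Xm, n, T_, Wx, Wh, b, reverse = FALSE) {
  XW <- addrow(Xm %*% Wx, b) # input projections for all timesteps at once
  res <- lstm_forward_cpp(XW, Wh, n, T_, reverse)
  list(out = res$H,
       cache = list(G = res$G, C = res$C, H = res$H, Xm = Xm, Wx = Wx,
                    Wh = Wh, n = n, T_ = T_, reverse = reverse))
}

lstm_dir_backward <- function(dH, cache) {
  r <- lstm_backward_cpp(dH, cache$Wh, cache$G, cache$C, cache$H,
                         cache$n, cache$T_, cache$reverse)
  list(dX = r$dZ %*% t(cache$Wx), dWx = crossprod(cache$Xm, r$dZ),
       dWh = r$dWh, db = colSums(r$dZ))
}

## ---- multi-head scaled-dot-product self-attention -------------------------

# Internally the (n*T, D) position-major matrices are reordered sample-major
# (all T rows of sample 1, then sample 2, ...) so per-sample blocks are
# contiguous; `ord`/`inv` convert between the layouts. Per-sample, per-head
# attention matrices are cached as a list (h fastest), and materialised into
# the (n, heads, T, T) trace array only on request.

attention_forward <- function(Hm, n, T_, heads, Wq, bq, Wk, bk, Wv, bv,
                              Wo, bo, need_alpha = FALSE) {
  D <- ncol(Hm)
  dk <- D %/% heads
  scal <- 1 / sqrt(dk)
  ord <- rep(seq_len(n), each = T_) + (seq_len(T_) - 1L) * n # sample-major
  Q <- addrow(Hm %*% Wq, bq)[ord, , drop = FALSE]
  K <- addrow(Hm %*% Wk, bk)[ord, , drop = FALSE]
  V <- addrow(Hm %*% Wv, bv)[ord, , drop = FALSE]
  fw <- attn_forward_cpp(Q, K, V, n, T_, heads)
  inv <- integer(n * T_); inv[ord] <- seq_len(n * T_)
  out <- addrow(fw$Ctx[inv, , drop = FALSE] %*% Wo, bo)
  res <- list(
    out = out,
    cache = list(Hm = Hm, Q = Q, K = K, V = V, Ctx = fw$Ctx, A = fw$A,
                 ord = ord, inv = inv, n = n, T_ = T_, heads = heads, dk = dk,
                 Wq = Wq, Wk = Wk, Wv = Wv, Wo = Wo)
  )
  if (need_alpha) res$alpha <- alpha_array(fw$A, n, heads, T_)
  res
}

# cube (T, T, n*heads) with head fastest within sample -> (n, heads, T, T)
alpha_array <- function(A, n, heads, T_) {
  aperm(array(A, c(T_, T_, heads, n)), c(4, 3, 1, 2))
}

attention_backward <- function(dOut, cache) {
  dbo <- colSums(dOut)
  dCtx <- (dOut %*% t(cache$Wo))[cache$ord, , drop = FALSE] # sample-major
  dWo <- crossprod(cache$Ctx[cache$inv, , drop = FALSE], dOut)
  bw <- attn_backward_cpp(cache$Q, cache$K, cache$V, cache$A, dCtx,
                          cache$n, cache$T_, cache$heads)
  dQ <- bw$dQ[cache$inv, , drop = FALSE]
  dK <- bw$dK[cache$inv, , drop = FALSE]
  dV <- bw$dV[cache$inv, , drop = FALSE]
  Hm <- cache$Hm
  list(
    dX = dQ %*% t(cache$Wq) + dK %*% t(cache$Wk) + dV %*% t(cache$Wv),
    dWq = crossprod(Hm, dQ), dbq = colSums(dQ),
    dWk = crossprod(Hm, dK), dbk = colSums(dK),
    dWv = crossprod(Hm, dV), dbv = colSums(dV),
    dWo = dWo, dbo = dbo
  )
}

## ---- misc ------------------------------------------------------------------

softmax_rows <- function(Z) {
  E <- exp(Z - max(Z)) # global shift: exact for row-wise softmax
  E / rowSums(E)
}

# linear rescaling of a profile to length L_out (identity when lengths match)
interp_linear <- function(values, L_out) {
  Lf <- length(values)
  if (Lf == L_out) return(as.numeric(values))
  if (Lf == 1L) return(rep(as.numeric(values), L_out))
  approx(
    x = seq(1, L_out, length.out = Lf), y = values, xout = seq_len(L_out)
  )$y
}

#' Moving-average smoothing with shrink-to-valid edges
#'
#' Centered moving average of width `window`; near the edges the window
#' shrinks to the valid range instead of padding.
#'
#' @param x Numeric vector.
#' @param window Window width in positions (>= 1).
#' @return Smoothed numeric vector, same length.
#' @export
moving_average <- function(x, window) {
  window <- max(1L, as.integer(window))
  L <- length(x)
  left <- ceiling((window - 1) / 2)
  right <- floor((window - 1) / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(L) - left, 1L)
  hi <- pmin(seq_len(L) + right, L)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
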