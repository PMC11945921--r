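# Internal neural-network primitives. Activations travel as arrays of
# dimension (channels, positions, batch); convolutions are computed as one
# BLAS matrix product over an im2col expansion. Everything here is plain R
# so training is bit-reproducible on a single CPU thread.

conv1d_init <- function(cin, cout, k) {
  list(W = matrix(stats::rnorm(cout * cin * k, 0, sqrt(2 / (cin * k))),
                  cout, cin * k),
       b = numeric(cout))
}

conv1d_fwd <- function(A, W, b, k, stride = 1L, pad = 0L) {
  d <- dim(A)
  cin <- d[1]; L <- d[2]; B <- d[3]
  if (pad > 0L) {
    Ap <- array(0, c(cin, L + 2L * pad, B))
    Ap[, (pad + 1L):(pad + L), ] <- A
    A <- Ap
    L <- L + 2L * pad
  }
  if (L < k) stop_input("input too short for this convolution")
  if (!is.double(A)) storage.mode(A) <- "double"
  Acol <- im2col_cpp(A, cin, L, B, k, stride)
  P <- (L - k) %/% stride + 1L
  out <- W %*% Acol + b
  dim(out) <- c(nrow(W), P, B)
  list(out = out,
       cache = list(Acol = Acol, dimA = c(cin, L, B), pad = pad, P = P,
                    k = k, stride = stride))
}

conv1d_bwd <- function(dOut, cache, W) {
  cout <- dim(dOut)[1]
  dO <- dOut
  dim(dO) <- c(cout, length(dO) %/% cout)
  dW <- tcrossprod(dO, cache$Acol)
  db <- rowSums(dO)
  dAcol <- crossprod(W, dO)
  cin <- cache$dimA[1]; L <- cache$dimA[2]; B <- cache$dimA[3]
  dA <- col2im_cpp(dAcol, cin, L, B, cache$k, cache$stride)
  if (cache$pad > 0L) {
    dA <- dA[, (cache$pad + 1L):(L - cache$pad), , drop = FALSE]
  }
  list(dA = dA, dW = dW, db = db)
}

relu_fwd <- function(x) list(out = pmax(x, 0), mask = x > 0)
relu_bwd <- function(dout, mask) dout * mask

maxpool2_fwd <- function(A) {
  d <- dim(A)
  P2 <- d[2] %/% 2L
  i1 <- seq_len(P2) * 2L - 1L
  A1 <- A[, i1, , drop = FALSE]
  A2 <- A[, i1 + 1L, , drop = FALSE]
  take1 <- A1 >= A2
  list(out = pmax(A1, A2), take1 = take1, dimA = d, i1 = i1)
}

maxpool2_bwd <- function(dout, cache) {
  dA <- array(0, cache$dimA)
  d1 <- dout * cache$take1
  d2 <- dout * !cache$take1
  dA[, cache$i1, ] <- d1
  dA[, cache$i1 + 1L, ] <- d2
  dA
}

dropout_fwd <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(out = x, mask = NULL))
  mask <- array((stats::runif(length(x)) >= rate) / (1 - rate), dim(x))
  list(out = x * mask, mask = mask)
}

dropout_bwd <- function(dout, mask) if (is.null(mask)) dout else dout * mask

dense_init <- function(nin, nout) {
  list(W = matrix(stats::rnorm(nout * nin, 0, sqrt(2 / nin)), nout, nin),
       b = numeric(nout))
}

dense_fwd <- function(X, W, b) W %*% X + b
dense_bwd <- function(dout, X, W) {
  list(dX = crossprod(W, dout), dW = tcrossprod(dout, X),
       db = rowSums(dout))
}

# Capsule squash v = (||s|| / (1 + ||s||^2)) * s = (||s||^2 / (1 + ||s||^2))
# * s / ||s||: direction preserved, ||v|| = ||s||^2 / (1 + ||s||^2) < 1.
squash_fwd <- function(S) {
  d <- dim(S)
  M <- matrix(S, d[1])
  n2 <- colSums(M * M)
  n <- sqrt(n2)
  f <- n / (1 + n2)
  out <- M * rep(f, each = d[1])
  dim(out) <- d
  list(out = out, S = M, n = n, n2 = n2, f = f, dimS = d)
}

# dv/ds = f(n) I + (f'(n)/n) s s^T with f(n) = n/(1+n^2),
# f'(n) = (1-n^2)/(1+n^2)^2; both factors vanish at the origin.
squash_bwd <- function(dV, cache) {
  d <- cache$dimS
  dVm <- matrix(dV, d[1])
  dot <- colSums(cache$S * dVm)
  fp_over_n <- (1 - cache$n2) / ((1 + cache$n2)^2 * pmax(cache$n, 1e-12))
  fp_over_n[cache$n < 1e-12] <- 0
  dS <- dVm * rep(cache$f, each = d[1]) +
    cache$S * rep(fp_over_n * dot, each = d[1])
  dim(dS) <- d
  dS
}

softmax_rows <- function(S) {
  m <- S[, 1]
  for (j in seq_len(ncol(S))[-1]) m <- pmax(m, S[, j])
  e <- exp(S - m)
  e / rowSums(e)
}

# Softmax over the second dimension of a (Q, R, B) array, loop-free over
# everything except the (small) R axis.
softmax_dim2 <- function(b) {
  d <- dim(b)
  Q <- d[1]; R <- d[2]; B <- d[3]
  m <- b[, 1, ]
  for (r in seq_len(R)[-1]) m <- pmax(m, b[, r, ])
  e <- b
  for (r in seq_len(R)) e[, r, ] <- exp(b[, r, ] - m)
  tot <- e[, 1, ]
  for (r in seq_len(R)[-1]) tot <- tot + e[, r, ]
  for (r in seq_len(R)) e[, r, ] <- e[, r, ] / tot
  e
}

# Routing-by-agreement over Uhat (D, Q, R, B). Logits start at zero; each
# iteration takes the softmax over output capsules, forms the weighted
# vote sums, squashes, and (except on the last pass) adds the
# prediction/output agreement to the logits. The inner loops run in
# compiled code; C is treated as a constant of the backward pass, so the
# backward cache only needs the final C and the pre-squash vote sums.
routing_fwd <- function(Uhat, iters) {
  d <- dim(Uhat)
  res <- routing_cpp(Uhat, d[1], d[2], d[3], d[4], iters)
  sq <- squash_fwd(res$s)
  list(v = sq$out, C = res$C, squash_cache = sq)
}

# Backward through the routed sum for a given upstream gradient on the
# pre-squash vote sums ds (D, R, B): dUhat[d,q,r,b] = C[q,r,b] * ds[d,r,b].
routing_bwd_uhat <- function(ds, C) {
  D <- dim(ds)[1]; R <- dim(ds)[2]; B <- dim(ds)[3]
  Q <- dim(C)[1]
  routing_grad_cpp(ds, C, D, Q, R, B)
}

attention_init <- function(d) {
  s <- sqrt(1 / d)
  list(Wq = matrix(stats::rnorm(d * d, 0, s), d, d),
       Wk = matrix(stats::rnorm(d * d, 0, s), d, d),
       Wv = matrix(stats::rnorm(d * d, 0, s), d, d))
}

# Scaled dot-product self-attention with a residual connection over an
# activation array (channels d, positions P, batch B).
attention_fwd <- function(A, p) {
  d <- dim(A)[1]; B <- dim(A)[3]
  out <- array(0, dim(A))
  caches <- vector("list", B)
  for (b in seq_len(B)) {
    X <- matrix(A[, , b], d)
    Q <- p$Wq %*% X
    K <- p$Wk %*% X
    V <- p$Wv %*% X
    S <- crossprod(Q, K) / sqrt(d)
    Aw <- softmax_rows(S)
    out[, , b] <- V %*% t(Aw) + X
    caches[[b]] <- list(X = X, Q = Q, K = K, V = V, Aw = Aw)
  }
  list(out = out, caches = caches)
}

attention_bwd <- function(dOut, caches, p) {
  d <- dim(dOut)[1]; B <- dim(dOut)[3]
  dA <- array(0, dim(dOut))
  dWq <- 0 * p$Wq; dWk <- 0 * p$Wk; dWv <- 0 * p$Wv
  for (b in seq_len(B)) {
    cb <- caches[[b]]
    dO <- matrix(dOut[, , b], d)
    dV <- dO %*% cb$Aw
    dAw <- crossprod(dO, cb$V)
    # softmax backward, row-wise
    rs <- rowSums(dAw * cb$Aw)
    dS <- (dAw - rs) * cb$Aw
    dQ <- cb$K %*% t(dS) / sqrt(d)
    dK <- cb$Q %*% dS / sqrt(d)
    dX <- dO + crossprod(p$Wq, dQ) + crossprod(p$Wk, dK) +
      crossprod(p$Wv, dV)
    dWq <- dWq + dQ %*% t(cb$X)
    dWk <- dWk + dK %*% t(cb$X)
    dWv <- dWv + dV %*% t(cb$X)
    dA[, , b] <- dX
  }
  list(dA = dA, dWq = dWq, dWk = dWk, dWv = dWv)
}

# Adam optimiser over an arbitrary nested list of numeric arrays.
adam_init <- function(params) {
  rapply(params, function(p) list(m = 0 * p, v = 0 * p),
         how = "list", classes = "ANY")
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, s) {
    if (is.list(p)) {
      out_p <- p
      out_s <- s
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], s[[nm]])
        out_p[[nm]] <- r$p
        out_s[[nm]] <- r$s
      }
      list(p = out_p, s = out_s)
    } else {
      m <- beta1 * s$m + (1 - beta1) * g
      v <- beta2 * s$v + (1 - beta2) * g * g
      mh <- m / (1 - beta1^t)
      vh <- v / (1 - beta2^t)
      list(p = p - lr * mh / (sqrt(vh) + eps), s = list(m = m, v = v))
    }
  }
  walk(params, grads, state)
}

zero_like <- function(params) rapply(params, function(p) 0 * p, how = "list")

count_params <- function(params) {
  sum(unlist(rapply(params, length, how = "unlist")))
}
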