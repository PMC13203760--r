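# Float network internals: im2col convolution, batch norm, pooling, dense
# layers, softmax cross-entropy, backprop and Adam.  Kept in plain matrix
# arithmetic; batch tensors are (batch, time, channels) arrays whose
# flattening order (batch fastest, then time, then channels) is relied on
# throughout, including by the flatten layer and the quantized engine.

# --- layer building blocks ----------------------------------------------

im2col <- function(A, K) {
  d <- dim(A)                                 # (B, T, C)
  t_out <- d[[2L]] - K + 1L
  M <- matrix(0, d[[1L]] * t_out, K * d[[3L]])
  for (c in seq_len(d[[3L]]))
    for (k in seq_len(K)) {
      sl <- A[, k:(k + t_out - 1L), c]
      M[, (c - 1L) * K + k] <- as.vector(sl)
    }
  M
}

col2im <- function(dM, B, T_in, C, K) {
  t_out <- T_in - K + 1L
  dA <- array(0, c(B, T_in, C))
  for (c in seq_len(C))
    for (k in seq_len(K)) {
      g <- matrix(dM[, (c - 1L) * K + k], B, t_out)
      dA[, k:(k + t_out - 1L), c] <- dA[, k:(k + t_out - 1L), c] + g
    }
  dA
}

conv_forward <- function(A, W, b) {
  K <- dim(W)[[1L]]
  d <- dim(A)
  t_out <- d[[2L]] - K + 1L
  M <- im2col(A, K)
  W2 <- matrix(W, K * d[[3L]], dim(W)[[3L]])
  Z <- M %*% W2
  Z <- sweep(Z, 2L, b, "+")
  dim(Z) <- c(d[[1L]], t_out, dim(W)[[3L]])
  list(out = Z, M = M, in_dim = d)
}

conv_backward <- function(dZ, cache, W) {
  d <- dim(dZ)                                # (B, t_out, Cout)
  K <- dim(W)[[1L]]
  cin <- dim(W)[[2L]]
  dZ2 <- dZ; dim(dZ2) <- c(d[[1L]] * d[[2L]], d[[3L]])
  W2 <- matrix(W, K * cin, d[[3L]])
  dW2 <- crossprod(cache$M, dZ2)
  db <- colSums(dZ2)
  dM <- tcrossprod(dZ2, W2)                   # (B*t_out) x (K*Cin)
  dA <- col2im(dM, cache$in_dim[[1L]], cache$in_dim[[2L]], cin, K)
  dW <- array(dW2, dim(W))
  list(dA = dA, dW = dW, db = db)
}

bn_forward <- function(Z, par, training, eps = 1e-3, momentum = 0.9) {
  d <- dim(Z)
  Zm <- Z; dim(Zm) <- c(d[[1L]] * d[[2L]], d[[3L]])
  if (training) {
    mu <- colMeans(Zm)
    va <- colMeans(Zm^2) - mu^2
    par$running_mean <- momentum * par$running_mean + (1 - momentum) * mu
    par$running_var <- momentum * par$running_var + (1 - momentum) * va
  } else {
    mu <- par$running_mean
    va <- par$running_var
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(Zm, 2L, mu, "-"), 2L, inv, "*")
  Y <- sweep(sweep(xhat, 2L, par$gamma, "*"), 2L, par$beta, "+")
  dim(Y) <- d
  list(out = Y, par = par, xhat = xhat, inv = inv, dim = d)
}

bn_backward <- function(dY, cache, gamma) {
  d <- cache$dim
  dYm <- dY; dim(dYm) <- c(d[[1L]] * d[[2L]], d[[3L]])
  N <- nrow(dYm)
  dgamma <- colSums(dYm * cache$xhat)
  dbeta <- colSums(dYm)
  dxhat <- sweep(dYm, 2L, gamma, "*")
  # dx = inv/N * (N*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dX <- sweep(N * dxhat, 2L, s1, "-") -
    sweep(cache$xhat, 2L, s2, "*")
  dX <- sweep(dX, 2L, cache$inv / N, "*")
  dim(dX) <- d
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

maxpool_forward <- function(A, pool = 2L) {
  d <- dim(A)
  t_out <- d[[2L]] %/% pool
  a1 <- A[, seq(1L, by = pool, length.out = t_out), , drop = FALSE]
  a2 <- A[, seq(2L, by = pool, length.out = t_out), , drop = FALSE]
  first <- a1 >= a2
  out <- ifelse(first, a1, a2)
  dim(out) <- c(d[[1L]], t_out, d[[3L]])
  list(out = out, first = first, in_dim = d, pool = pool)
}

maxpool_backward <- function(dY, cache) {
  d <- cache$in_dim
  t_out <- dim(dY)[[2L]]
  dA <- array(0, d)
  dA[, seq(1L, by = cache$pool, length.out = t_out), ] <- dY * cache$first
  dA[, seq(2L, by = cache$pool, length.out = t_out), ] <- dY * !cache$first
  dA
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# --- weight initialization ----------------------------------------------

init_weights <- function(arch) {
  shapes <- arch_shapes(arch)
  shape <- c(arch$input_len, 1L)
  w <- vector("list", length(arch$layers))
  glorot <- function(fan_in, fan_out, dims) {
    lim <- sqrt(6 / (fan_in + fan_out))
    array(stats::runif(prod(dims), -lim, lim), dims)
  }
  for (i in seq_along(arch$layers)) {
    ly <- arch$layers[[i]]
    if (ly$type == "conv") {
      cin <- shape[[2L]]
      w[[i]] <- list(W = glorot(ly$kernel * cin, ly$kernel * ly$filters,
                                c(ly$kernel, cin, ly$filters)),
                     b = numeric(ly$filters))
      if (isTRUE(ly$batch_norm))
        w[[i]] <- c(w[[i]], list(gamma = rep(1, ly$filters),
                                 beta = numeric(ly$filters),
                                 running_mean = numeric(ly$filters),
                                 running_var = rep(1, ly$filters)))
    } else if (ly$type == "dense") {
      w[[i]] <- list(W = glorot(shape[[1L]], ly$units,
                                c(shape[[1L]], ly$units)),
                     b = numeric(ly$units))
    }
    shape <- shapes[[i]]
  }
  w
}

# --- forward / backward --------------------------------------------------

nn_forward <- function(weights, arch, X, training = FALSE, dropout = 0,
                       bn_momentum = 0.9) {
  B <- nrow(X)
  A <- array(X, c(B, ncol(X), 1L))
  caches <- vector("list", length(arch$layers))
  for (i in seq_along(arch$layers)) {
    ly <- arch$layers[[i]]
    if (ly$type == "conv") {
      cf <- conv_forward(A, weights[[i]]$W, weights[[i]]$b)
      cache <- list(conv = cf)
      Z <- cf$out
      if (isTRUE(ly$batch_norm)) {
        bf <- bn_forward(Z, weights[[i]], training, momentum = bn_momentum)
        weights[[i]] <- bf$par
        cache$bn <- bf
        Z <- bf$out
      }
      cache$pre <- Z
      A <- Z * (Z > 0)                         # ReLU
      caches[[i]] <- cache
    } else if (ly$type == "maxpool") {
      mf <- maxpool_forward(A, ly$pool)
      caches[[i]] <- mf
      A <- mf$out
    } else if (ly$type == "flatten") {
      d <- dim(A)
      caches[[i]] <- list(in_dim = d)
      dim(A) <- c(d[[1L]], d[[2L]] * d[[3L]])
    } else if (ly$type == "dense") {
      if (isTRUE(ly$dropout_before) && training && dropout > 0) {
        mask <- matrix(stats::runif(length(A)) >= dropout,
                       nrow(A), ncol(A)) / (1 - dropout)
        A <- A * mask
        caches[[i]] <- list(mask = mask)
      }
      Z <- sweep(A %*% weights[[i]]$W, 2L, weights[[i]]$b, "+")
      caches[[i]] <- c(caches[[i]], list(X = A, pre = Z))
      A <- if (ly$activation == "softmax") softmax_rows(Z) else Z * (Z > 0)
    }
  }
  list(out = A, caches = caches, weights = weights)
}

nn_backward <- function(weights, arch, fwd, Y1hot) {
  caches <- fwd$caches
  B <- nrow(Y1hot)
  grads <- vector("list", length(arch$layers))
  # softmax + cross-entropy gradient at the logits
  dA <- (fwd$out - Y1hot) / B
  for (i in rev(seq_along(arch$layers))) {
    ly <- arch$layers[[i]]
    if (ly$type == "dense") {
      dZ <- if (ly$activation == "softmax") dA else dA * (caches[[i]]$pre > 0)
      grads[[i]] <- list(W = crossprod(caches[[i]]$X, dZ), b = colSums(dZ))
      dA <- tcrossprod(dZ, weights[[i]]$W)
      if (!is.null(caches[[i]]$mask)) dA <- dA * caches[[i]]$mask
    } else if (ly$type == "flatten") {
      dim(dA) <- caches[[i]]$in_dim
    } else if (ly$type == "maxpool") {
      dA <- maxpool_backward(dA, caches[[i]])
    } else if (ly$type == "conv") {
      dZ <- dA * (caches[[i]]$pre > 0)
      g <- list()
      if (isTRUE(ly$batch_norm)) {
        bb <- bn_backward(dZ, caches[[i]]$bn, weights[[i]]$gamma)
        g$gamma <- bb$dgamma
        g$beta <- bb$dbeta
        dZ <- bb$dX
      }
      cb <- conv_backward(dZ, caches[[i]]$conv, weights[[i]]$W)
      g$W <- cb$dW
      g$b <- cb$db
      grads[[i]] <- g
      dA <- cb$dA
    }
  }
  grads
}

# --- Adam ----------------------------------------------------------------

adam_init <- function(weights) {
  lapply(weights, function(w) {
    if (is.null(w)) return(NULL)
    nm <- intersect(c("W", "b", "gamma", "beta"), names(w))
    stats <- lapply(w[nm], function(p) list(m = p * 0, v = p * 0))
    stats
  })
}

adam_step <- function(weights, grads, state, t, lr = 0.001, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(weights)) {
    if (is.null(grads[[i]])) next
    for (nm in names(state[[i]])) {
      g <- grads[[i]][[nm]]
      if (is.null(g)) next
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      weights[[i]][[nm]] <- weights[[i]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[nm]] <- st
    }
  }
  list(weights = weights, state = state)
}

cross_entropy <- function(P, Y1hot) {
  -mean(log(pmax(rowSums(P * Y1hot), 1e-12)))
}

labels_to_onehot <- function(labels) {
  idx <- match(labels, BEAT_CLASSES)
  if (anyNA(idx)) tb_stop("labels outside {N, V, S}",
                          class = "tinybeat_data_error")
  Y <- matrix(0, length(idx), length(BEAT_CLASSES))
  Y[cbind(seq_along(idx), idx)] <- 1
  Y
}
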