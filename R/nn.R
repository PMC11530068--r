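# Minimal CNN engine on base-R matrix algebra.
#
# A batch is a (D x B) matrix of flattened (H, W, C) images in column-major
# (row, col, channel) order. Convolutions are valid (no padding) and use a
# precomputed im2col index map so the forward pass is a single gather plus
# one matrix product per layer; the transposed scatter (col2im) in the
# backward pass is a rowsum over the same map. 2x2 max-pooling (stride 2)
# tracks argmaxes for its backward pass; dense layers are plain GEMMs.
# Training minimizes the mean squared Euclidean distance between the
# softmax output and the simplex target.

nn_dims_index <- function(h, w, c_) function(i, j, ch) i + (j - 1L) * h +
  (ch - 1L) * h * w

# --- layer constructors (geometry precomputed, weights seeded by caller) ---

nn_conv_layer <- function(in_dim, kernel, filters) {
  H <- in_dim[1]; W <- in_dim[2]; C <- in_dim[3]
  Ho <- H - kernel + 1L; Wo <- W - kernel + 1L
  stopifnot(Ho >= 1, Wo >= 1)
  P <- Ho * Wo; Q <- kernel * kernel * C
  lin <- nn_dims_index(H, W, C)
  # im2col map: q runs fastest over (di, dj, ch), then p over (io, jo)
  io <- rep(seq_len(Ho), times = Wo)
  jo <- rep(seq_len(Wo), each = Ho)
  di <- rep(seq_len(kernel), times = kernel * C)
  dj <- rep(rep(seq_len(kernel), each = kernel), times = C)
  ch <- rep(seq_len(C), each = kernel * kernel)
  idx <- as.integer(outer(lin(di, dj, ch) - lin(1L, 1L, 1L),
                          lin(io, jo, 1L), "+"))
  list(type = "conv", in_dim = in_dim, out_dim = c(Ho, Wo, filters),
       kernel = kernel, Q = Q, P = P, filters = filters, idx = idx,
       W = matrix(0, Q, filters), b = numeric(filters))
}

nn_relu_layer <- function(in_dim) {
  list(type = "relu", in_dim = in_dim, out_dim = in_dim)
}

nn_pool_layer <- function(in_dim) {
  H <- in_dim[1]; W <- in_dim[2]; C <- in_dim[3]
  Ho <- H %/% 2L; Wo <- W %/% 2L
  stopifnot(Ho >= 1, Wo >= 1)
  lin <- nn_dims_index(H, W, C)
  io <- rep(seq_len(Ho), times = Wo * C)
  jo <- rep(rep(seq_len(Wo), each = Ho), times = C)
  ch <- rep(seq_len(C), each = Ho * Wo)
  base_i <- 2L * io - 1L; base_j <- 2L * jo - 1L
  pidx <- rbind(lin(base_i, base_j, ch), lin(base_i + 1L, base_j, ch),
                lin(base_i, base_j + 1L, ch), lin(base_i + 1L, base_j + 1L, ch))
  list(type = "pool", in_dim = in_dim, out_dim = c(Ho, Wo, C),
       pidx = pidx, PoC = Ho * Wo * C, D_in = H * W * C)
}

# global average pooling over spatial positions: (H, W, C) -> C
nn_gap_layer <- function(in_dim) {
  list(type = "gap", in_dim = in_dim, out_dim = in_dim[3],
       P = in_dim[1] * in_dim[2], C = in_dim[3])
}

nn_dense_layer <- function(in_dim, units) {
  din <- prod(in_dim)
  list(type = "dense", in_dim = in_dim, out_dim = units,
       W = matrix(0, din, units), b = numeric(units))
}

# He-normal initialization of every weighted layer, seeded.
nn_init <- function(net, seed) {
  with_seed_ms(seed, {
    for (i in seq_along(net$layers)) {
      ly <- net$layers[[i]]
      if (ly$type %in% c("conv", "dense")) {
        fan_in <- nrow(ly$W)
        net$layers[[i]]$W <- matrix(stats::rnorm(length(ly$W)) *
                                      sqrt(2 / fan_in),
                                    nrow(ly$W), ncol(ly$W))
        net$layers[[i]]$b <- numeric(length(ly$b))
      }
    }
  })
  net
}

nn_param_count <- function(net) {
  sum(vapply(net$layers, function(ly)
    if (!is.null(ly$W)) length(ly$W) + length(ly$b) else 0L, numeric(1)))
}

# forward pass; returns logits (K x B) and per-layer caches for backward
nn_forward <- function(net, X) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type == "conv") {
      B <- ncol(X)
      A <- matrix(X[ly$idx, , drop = FALSE], ly$Q, ly$P * B)
      Z <- crossprod(A, ly$W)
      Z <- Z + matrix(ly$b, nrow(Z), ly$filters, byrow = TRUE)
      X <- matrix(aperm(array(Z, c(ly$P, B, ly$filters)), c(1, 3, 2)),
                  ly$P * ly$filters, B)
      caches[[i]] <- list(A = A, B = B)
    } else if (ly$type == "relu") {
      caches[[i]] <- list(mask = X > 0)
      X <- X * caches[[i]]$mask
    } else if (ly$type == "pool") {
      B <- ncol(X)
      M <- matrix(X[as.vector(ly$pidx), , drop = FALSE], 4L, ly$PoC * B)
      mx <- pmax(M[1, ], M[2, ], M[3, ], M[4, ])
      wm <- max.col(t(M), ties.method = "first")
      caches[[i]] <- list(wm = wm, B = B)
      X <- matrix(mx, ly$PoC, B)
    } else if (ly$type == "gap") {
      B <- ncol(X)
      caches[[i]] <- list(B = B)
      X <- matrix(colMeans(matrix(X, ly$P, ly$C * B)), ly$C, B)
    } else if (ly$type == "dense") {
      caches[[i]] <- list(X = X)
      X <- crossprod(ly$W, X) + ly$b
    }
    caches[[i]]$out <- X
  }
  list(logits = X, caches = caches)
}

# backward pass from dLogits; returns gradients per layer and, when
# `stop_layer` is given, the gradient flowing into that layer's output.
nn_backward <- function(net, caches, dX, stop_layer = 0L) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    if (i == stop_layer) return(list(grads = grads, d_feature = dX))
    ly <- net$layers[[i]]
    cc <- caches[[i]]
    if (ly$type == "dense") {
      grads[[i]] <- list(W = cc$X %*% t(dX), b = rowSums(dX))
      dX <- ly$W %*% dX
    } else if (ly$type == "relu") {
      dX <- dX * cc$mask
    } else if (ly$type == "gap") {
      dX <- matrix(rep(as.vector(dX) / ly$P, each = ly$P),
                   ly$P * ly$C, cc$B)
    } else if (ly$type == "pool") {
      B <- cc$B
      dm <- as.vector(dX)
      n <- ly$PoC
      jseq <- seq_len(n * B)
      rows <- ly$pidx[cbind(cc$wm, ((jseq - 1L) %% n) + 1L)]
      bcol <- ((jseq - 1L) %/% n) + 1L
      dIn <- matrix(0, ly$D_in, B)
      dIn[cbind(rows, bcol)] <- dm
      dX <- dIn
    } else if (ly$type == "conv") {
      B <- cc$B
      dZ <- matrix(aperm(array(dX, c(ly$P, ly$filters, B)), c(1, 3, 2)),
                   ly$P * B, ly$filters)
      grads[[i]] <- list(W = cc$A %*% dZ, b = colSums(dZ))
      dA <- ly$W %*% t(dZ)
      dXcol <- matrix(dA, ly$Q * ly$P, B)
      dX <- rowsum(dXcol, group = ly$idx)
    }
  }
  list(grads = grads, d_feature = NULL)
}

nn_softmax <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# MSE-on-softmax loss and its gradient w.r.t. logits.
# loss = mean_b ||softmax(z_b) - y_b||^2
nn_mse_softmax <- function(logits, Y) {
  P <- nn_softmax(logits)
  B <- ncol(P)
  diff <- P - Y
  loss <- sum(diff^2) / B
  g <- 2 * diff / B
  dz <- P * sweep(g, 2, colSums(g * P))
  list(loss = loss, dlogits = dz, probs = P)
}

# --- Adam optimizer state over the net's weighted layers ---

adam_init <- function(net) {
  st <- list(t = 0L, m = list(), v = list())
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (!is.null(ly$W)) {
      st$m[[i]] <- list(W = ly$W * 0, b = ly$b * 0)
      st$v[[i]] <- list(W = ly$W * 0, b = ly$b * 0)
    }
  }
  st
}

adam_step <- function(net, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t; bc2 <- 1 - beta2^st$t
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in c("W", "b")) {
      st$m[[i]][[nm]] <- beta1 * st$m[[i]][[nm]] + (1 - beta1) * g[[nm]]
      st$v[[i]][[nm]] <- beta2 * st$v[[i]][[nm]] + (1 - beta2) * g[[nm]]^2
      upd <- (st$m[[i]][[nm]] / bc1) /
        (sqrt(st$v[[i]][[nm]] / bc2) + eps)
      net$layers[[i]][[nm]] <- net$layers[[i]][[nm]] - lr * upd
    }
  }
  list(net = net, state = st)
}

# --- architectures ---

# ~40k-parameter CNN:
# conv3x3(16) > pool > conv3x3(32) > pool > conv3x3(64) > pool > fc64 > fc3
nn_build_tiny <- function(input_size) {
  d <- as.integer(input_size)
  layers <- list()
  l1 <- nn_conv_layer(d, 3L, 16L)
  layers <- c(layers, list(l1), list(nn_relu_layer(l1$out_dim)))
  p1 <- nn_pool_layer(l1$out_dim); layers <- c(layers, list(p1))
  l2 <- nn_conv_layer(p1$out_dim, 3L, 32L)
  layers <- c(layers, list(l2), list(nn_relu_layer(l2$out_dim)))
  p2 <- nn_pool_layer(l2$out_dim); layers <- c(layers, list(p2))
  l3 <- nn_conv_layer(p2$out_dim, 3L, 64L)
  layers <- c(layers, list(l3), list(nn_relu_layer(l3$out_dim)))
  feature_layer <- 8L   # conv3 + relu output: last conv feature map
  p3 <- nn_pool_layer(l3$out_dim); layers <- c(layers, list(p3))
  d1 <- nn_dense_layer(p3$out_dim, 64L)
  layers <- c(layers, list(d1), list(nn_relu_layer(64L)))
  d2 <- nn_dense_layer(64L, 3L); layers <- c(layers, list(d2))
  list(layers = layers, input_size = d, feature_layer = feature_layer,
       feature_dim = l3$out_dim)
}
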