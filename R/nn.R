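# Minimal reverse-mode engine for the neural predictor heads.
#
# Values are matrices (pooled batches, N x D) or 3-d arrays ("cubes",
# L x D x N) for position-resolved batches; variable-length inputs are
# padded and carried with an explicit mask (L x N, 1 = real token) so that
# padded positions can never influence outputs. Heavy batched products run
# through compiled kernels.

# ---- tape ----------------------------------------------------------------

.nn_env <- new.env(parent = emptyenv())

ag_tape_begin <- function() {
  .nn_env$tape <- list()
  invisible(NULL)
}

.ag_node <- function(value, parents = list(), backward = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$parents <- parents
  node$backward <- backward
  node$grad <- NULL
  .nn_env$tape[[length(.nn_env$tape) + 1]] <- node
  node
}

ag_var <- function(value) .ag_node(value)

# single reverse sweep; `out`/`grad_out` may be lists of seeds so that
# multitask losses propagate in one pass (two sweeps would double-count)
ag_backward <- function(out, grad_out) {
  if (!is.list(out) || is.environment(out)) {
    out <- list(out); grad_out <- list(grad_out)
  }
  for (i in seq_along(out)) {
    o <- out[[i]]
    o$grad <- if (is.null(o$grad)) grad_out[[i]] else o$grad + grad_out[[i]]
  }
  tape <- .nn_env$tape
  for (k in rev(seq_along(tape))) {
    node <- tape[[k]]
    if (is.null(node$grad) || is.null(node$backward)) next
    gs <- node$backward(node$grad)
    for (i in seq_along(node$parents)) {
      p <- node$parents[[i]]
      if (is.null(gs[[i]])) next
      p$grad <- if (is.null(p$grad)) gs[[i]] else p$grad + gs[[i]]
    }
  }
  invisible(NULL)
}

# ---- ops -----------------------------------------------------------------

ag_mm <- function(A, B) {
  .ag_node(A$value %*% B$value, list(A, B), function(G)
    list(G %*% t(B$value), t(A$value) %*% G))
}

# cube (L,D,N) times shared weight (D,K) -> cube (L,K,N)
.cube_mm_val <- function(X, W) {
  d <- dim(X)
  m <- matrix(aperm(X, c(1, 3, 2)), nrow = d[1] * d[3])
  r <- m %*% W
  aperm(array(r, c(d[1], d[3], ncol(W))), c(1, 3, 2))
}

ag_cube_mm <- function(X, W) {
  .ag_node(.cube_mm_val(X$value, W$value), list(X, W), function(G) {
    d <- dim(X$value)
    Xm <- matrix(aperm(X$value, c(1, 3, 2)), nrow = d[1] * d[3])
    Gm <- matrix(aperm(G, c(1, 3, 2)), nrow = d[1] * d[3])
    dW <- t(Xm) %*% Gm
    dXm <- Gm %*% t(W$value)
    dX <- aperm(array(dXm, c(d[1], d[3], d[2])), c(1, 3, 2))
    list(dX, dW)
  })
}

# batched matmul over slices; only the (F,F) and (F,T) variants are used
ag_bmm <- function(A, B, tb = FALSE) {
  .ag_node(.bmm_cpp(A$value, B$value, FALSE, tb), list(A, B), function(G) {
    if (!tb) {
      list(.bmm_cpp(G, B$value, FALSE, TRUE),
           .bmm_cpp(A$value, G, TRUE, FALSE))
    } else {
      list(.bmm_cpp(G, B$value, FALSE, FALSE),
           .bmm_cpp(G, A$value, TRUE, FALSE))
    }
  })
}

ag_add <- function(A, B) {
  .ag_node(A$value + B$value, list(A, B), function(G) list(G, G))
}

# bias over the feature dimension (columns for matrices, dim 2 for cubes)
ag_add_bias <- function(X, b) {
  v <- X$value
  if (length(dim(v)) == 3) {
    out <- v + rep(b$value, each = dim(v)[1])
    .ag_node(out, list(X, b), function(G)
      list(G, apply(G, 2, sum)))
  } else {
    out <- sweep(v, 2, b$value, "+")
    .ag_node(out, list(X, b), function(G) list(G, colSums(G)))
  }
}

ag_relu <- function(X) {
  keep <- X$value > 0
  .ag_node(X$value * keep, list(X), function(G) list(G * keep))
}

ag_scale <- function(X, s) {
  .ag_node(X$value * s, list(X), function(G) list(G * s))
}

ag_const_add <- function(X, C) {
  .ag_node(X$value + C, list(X), function(G) list(G))
}

# column slice of a cube (used to split attention heads)
ag_cols <- function(X, idx) {
  .ag_node(X$value[, idx, , drop = FALSE], list(X), function(G) {
    dX <- array(0, dim(X$value))
    dX[, idx, ] <- G
    list(dX)
  })
}

ag_cat_cols <- function(parts) {
  vals <- lapply(parts, function(p) p$value)
  d1 <- dim(vals[[1]])
  widths <- vapply(vals, function(v) dim(v)[2], numeric(1))
  out <- array(0, c(d1[1], sum(widths), d1[3]))
  off <- 0
  for (v in vals) {
    out[, off + seq_len(dim(v)[2]), ] <- v
    off <- off + dim(v)[2]
  }
  .ag_node(out, parts, function(G) {
    off <- 0
    lapply(vals, function(v) {
      g <- G[, off + seq_len(dim(v)[2]), , drop = FALSE]
      off <<- off + dim(v)[2]
      g
    })
  })
}

# row-wise softmax per slice with key mask; masked keys get probability 0
ag_masked_softmax <- function(S, key_mask) {
  P <- .masked_softmax_cpp(S$value, key_mask)
  .ag_node(P, list(S), function(G) {
    PG <- P * G
    d <- dim(P)
    ones <- array(1, c(d[2], 1, d[3]))
    rs <- .bmm_cpp(PG, ones, FALSE, FALSE) # (Q,1,N)
    rs_mat <- matrix(rs, d[1], d[3])
    rs3 <- aperm(array(rs_mat, c(d[1], d[3], d[2])), c(1, 3, 2))
    list(P * (G - rs3))
  })
}

# masked mean over positions: cube (L,D,N) + mask (L,N) -> matrix (N,D)
ag_masked_meanpool <- function(X, mask) {
  d <- dim(X$value)
  len <- pmax(colSums(mask), 1)
  mask3 <- aperm(array(mask, c(d[1], d[3], d[2])), c(1, 3, 2))
  Xm <- X$value * mask3
  s <- colSums(matrix(Xm, nrow = d[1])) # (D*N)
  val <- t(matrix(s, d[2], d[3])) / len # (N,D)
  .ag_node(val, list(X), function(G) {
    Gn <- G / len # (N,D)
    g3 <- aperm(array(t(Gn), c(d[2], d[3], d[1])), c(3, 1, 2))
    list(g3 * mask3)
  })
}

# ---- parameters and optimizer --------------------------------------------

nn_init_param <- function(nr, nc = NULL, scale = NULL) {
  if (is.null(nc)) return(numeric(nr)) # bias
  if (is.null(scale)) scale <- sqrt(2 / (nr + nc))
  matrix(rnorm(nr * nc, sd = scale), nr, nc)
}

adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(params, grads, st) {
  st$t <- st$t + 1
  for (k in names(params)) {
    g <- grads[[k]]
    if (is.null(g)) next
    st$m[[k]] <- st$beta1 * st$m[[k]] + (1 - st$beta1) * g
    st$v[[k]] <- st$beta2 * st$v[[k]] + (1 - st$beta2) * g^2
    mhat <- st$m[[k]] / (1 - st$beta1^st$t)
    vhat <- st$v[[k]] / (1 - st$beta2^st$t)
    params[[k]] <- params[[k]] - st$lr * mhat / (sqrt(vhat) + st$eps)
  }
  list(params = params, state = st)
}

# ---- batching ------------------------------------------------------------

# pad a list of L_i x D matrices into a cube (Lmax, D, N) + mask (Lmax, N)
pad_batch <- function(mats, Lmax = NULL) {
  D <- ncol(mats[[1]])
  lens <- vapply(mats, nrow, numeric(1))
  if (is.null(Lmax)) Lmax <- max(lens)
  N <- length(mats)
  X <- array(0, c(Lmax, D, N))
  mask <- matrix(0, Lmax, N)
  for (i in seq_len(N)) {
    X[seq_len(lens[i]), , i] <- mats[[i]]
    mask[seq_len(lens[i]), i] <- 1
  }
  list(X = X, mask = mask, lens = lens)
}

# sinusoidal position encoding (Lmax x D), zeroed later by masks
posenc <- function(Lmax, D) {
  pos <- seq_len(Lmax)
  pe <- matrix(0, Lmax, D)
  for (j in seq_len(D)) {
    w <- 1 / 10000^((2 * ((j - 1) %/% 2)) / D)
    pe[, j] <- if (j %% 2 == 1) sin(pos * w) else cos(pos * w)
  }
  pe
}

# add a (Lmax x D) position table to every slice of a cube
ag_add_posenc <- function(X, pe) {
  d <- dim(X$value)
  ag_const_add(X, array(pe[seq_len(d[1]), seq_len(d[2])], d))
}

# ---- losses (value + gradient wrt the network output) --------------------

loss_bce_logits <- function(z, y) {
  z <- as.numeric(z); n <- length(z)
  p <- 1 / (1 + exp(-z))
  eps <- 1e-12
  list(value = -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps)),
       grad = matrix((p - y) / n, ncol = 1))
}

loss_mse <- function(z, y) {
  z <- as.numeric(z); n <- length(z)
  r <- z - y
  list(value = mean(r^2), grad = matrix(2 * r / n, ncol = 1))
}

loss_huber <- function(z, y, delta) {
  z <- as.numeric(z); n <- length(z)
  r <- z - y
  list(value = mean(huber_loss(r, delta)),
       grad = matrix(pmin(pmax(r, -delta), delta) / n, ncol = 1))
}

# 3-class softmax cross-entropy; y in 1..K
loss_softmax_ce <- function(Z, y, K = 3) {
  n <- nrow(Z)
  m <- apply(Z, 1, max)
  E <- exp(Z - m)
  P <- E / rowSums(E)
  idx <- cbind(seq_len(n), y)
  G <- P
  G[idx] <- G[idx] - 1
  list(value = -mean(log(P[idx] + 1e-12)), grad = G / n)
}

# ---- multi-head attention block ------------------------------------------

# parameters for one cross/self-attention block at model width D
mha_init <- function(D, ff = 2 * D) {
  list(Wq = nn_init_param(D, D), Wk = nn_init_param(D, D),
       Wv = nn_init_param(D, D), Wo = nn_init_param(D, D),
       bo = nn_init_param(D),
       W1 = nn_init_param(D, ff), b1 = nn_init_param(ff),
       W2 = nn_init_param(ff, D), b2 = nn_init_param(D))
}

# queries from Xq, keys/values from Xk (self-attention: Xq == Xk);
# returns the block output node (residual + feed-forward + residual)
mha_forward <- function(p, Xq, Xk, key_mask, n_heads) {
  D <- ncol(p$Wq$value)
  dk <- D / n_heads
  Q <- ag_cube_mm(Xq, p$Wq)
  K <- ag_cube_mm(Xk, p$Wk)
  V <- ag_cube_mm(Xk, p$Wv)
  heads <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1) * dk + 1):(h * dk)
    S <- ag_scale(ag_bmm(ag_cols(Q, idx), ag_cols(K, idx), tb = TRUE),
                  1 / sqrt(dk))
    P <- ag_masked_softmax(S, key_mask)
    heads[[h]] <- ag_bmm(P, ag_cols(V, idx))
  }
  O <- ag_add_bias(ag_cube_mm(ag_cat_cols(heads), p$Wo), p$bo)
  Z <- ag_add(Xq, O)
  Ff <- ag_add_bias(ag_cube_mm(
    ag_relu(ag_add_bias(ag_cube_mm(Z, p$W1), p$b1)), p$W2), p$b2)
  ag_add(Z, Ff)
}

# wrap a flat named list of parameter arrays into tape leaves
params_as_nodes <- function(params) lapply(params, ag_var)

collect_grads <- function(nodes) lapply(nodes, function(n) n$grad)
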