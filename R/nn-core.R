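# Numerical core of the graph-attention classifier: parameter initialization,
# layer forward/backward passes and the Adam optimizer. Everything operates on
# a "batch": the block-diagonal union of molecular graphs, so one epoch is a
# handful of large vectorized matrix operations rather than a loop over
# molecules (the per-graph self-attention and pooling steps still loop, on
# small matrices).
#
# All gradients are derived by hand and guarded by a finite-difference check
# in the test suite.

glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

# scatter-add rowsum: sums rows of `mat` by index `idx` into an n-row matrix
group_rowsum <- function(mat, idx, n) {
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = 1)
  gr <- rowsum(mat, idx)
  out <- matrix(0, n, ncol(mat))
  out[as.integer(rownames(gr)), ] <- gr
  out
}

leaky_relu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)
elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)

# ---- batch construction ----------------------------------------------------

# Assemble MoleculeGraph objects (a subset of a dataset) into one batch.
# Self-loop arcs with zero edge features are appended for every node, so
# attention always has at least one incoming arc per node.
build_batch <- function(graphs, labels = NULL) {
  nf <- lapply(graphs, function(g) g@nodeFeatures)
  sizes <- vapply(nf, nrow, integer(1))
  offsets <- cumsum(c(0L, sizes[-length(sizes)]))
  X <- do.call(rbind, nf)
  N <- nrow(X)

  el <- lapply(seq_along(graphs), function(k) {
    e <- graphs[[k]]@edgeList
    if (nrow(e) > 0) e + offsets[k] else e
  })
  edges <- do.call(rbind, el)
  efeat <- do.call(rbind, lapply(graphs, function(g) g@edgeFeatures))
  # self loops
  edges <- rbind(edges, cbind(from = seq_len(N), to = seq_len(N)))
  efeat <- rbind(efeat, matrix(0, N, ncol(efeat)))

  graph_id <- rep(seq_along(graphs), times = sizes)
  node_idx <- split(seq_len(N), graph_id)
  list(X = X, edges = edges, efeat = efeat, graph_id = graph_id,
       node_idx = node_idx, n_graphs = length(graphs), N = N,
       y = if (is.null(labels)) NULL else as.numeric(labels))
}

# ---- GAT convolution layer -------------------------------------------------

gat_init <- function(fin, hidden, heads, edge_dim) {
  dh <- hidden %/% heads
  stopifnot(dh * heads == hidden)
  list(W = glorot(fin, hidden),
       a_src = glorot(dh, heads),
       a_dst = glorot(dh, heads),
       a_edge = glorot(edge_dim, heads),
       b = rep(0, hidden))
}

gat_forward <- function(p, X, edges, efeat, N) {
  heads <- ncol(p$a_src)
  dh <- nrow(p$a_src)
  from <- edges[, 1]; to <- edges[, 2]
  Z <- X %*% p$W
  out_pre <- matrix(0, N, heads * dh)
  cache <- list(Z = Z, heads = vector("list", heads))
  e_sc <- efeat %*% p$a_edge                     # E x heads
  for (h in seq_len(heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    Zh <- Z[, cols, drop = FALSE]
    s <- drop(Zh %*% p$a_src[, h])
    t <- drop(Zh %*% p$a_dst[, h])
    epre <- s[from] + t[to] + e_sc[, h]
    eact <- leaky_relu(epre)
    w <- exp(eact - max(eact))
    denom <- drop(group_rowsum(w, to, N)) + 1e-12
    alpha <- w / denom[to]
    outh <- group_rowsum(alpha * Zh[from, , drop = FALSE], to, N)
    out_pre[, cols] <- outh
    cache$heads[[h]] <- list(alpha = alpha, epre = epre, Zh = Zh)
  }
  out_pre <- sweep(out_pre, 2, p$b, "+")
  out <- elu(out_pre)
  cache$out_pre <- out_pre
  list(out = out, cache = cache)
}

gat_backward <- function(p, dout, X, edges, efeat, N, cache) {
  heads <- ncol(p$a_src)
  dh <- nrow(p$a_src)
  from <- edges[, 1]; to <- edges[, 2]
  dpre <- dout * ifelse(cache$out_pre > 0, 1, exp(pmin(cache$out_pre, 0)))
  db <- colSums(dpre)
  Z <- cache$Z
  dZ <- matrix(0, nrow(Z), ncol(Z))
  da_src <- matrix(0, dh, heads)
  da_dst <- matrix(0, dh, heads)
  da_edge <- matrix(0, ncol(efeat), heads)
  for (h in seq_len(heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    ch <- cache$heads[[h]]
    dh_out <- dpre[, cols, drop = FALSE]
    dmsg <- dh_out[to, , drop = FALSE]                     # E x dh
    dalpha <- rowSums(dmsg * ch$Zh[from, , drop = FALSE])
    dZh <- group_rowsum(ch$alpha * dmsg, from, N)
    # grouped softmax backward
    sdot <- drop(group_rowsum(ch$alpha * dalpha, to, N))
    dea <- ch$alpha * (dalpha - sdot[to])
    depre <- dea * ifelse(ch$epre > 0, 1, 0.2)
    ds <- drop(group_rowsum(depre, from, N))
    dt <- drop(group_rowsum(depre, to, N))
    da_edge[, h] <- drop(crossprod(efeat, depre))
    dZh <- dZh + outer(ds, p$a_src[, h]) + outer(dt, p$a_dst[, h])
    da_src[, h] <- drop(crossprod(ch$Zh, ds))
    da_dst[, h] <- drop(crossprod(ch$Zh, dt))
    dZ[, cols] <- dZh
  }
  list(dX = dZ %*% t(p$W),
       grads = list(W = crossprod(X, dZ), a_src = da_src, a_dst = da_dst,
                    a_edge = da_edge, b = db))
}

# ---- multi-head self-attention over node embeddings (per graph) ------------

mhsa_init <- function(hidden, heads) {
  list(Wq = glorot(hidden, hidden), Wk = glorot(hidden, hidden),
       Wv = glorot(hidden, hidden), Wo = glorot(hidden, hidden),
       bo = rep(0, hidden))
}

mhsa_forward <- function(p, X, node_idx, heads, keep_attention = FALSE) {
  H <- ncol(X)
  dh <- H %/% heads
  out <- X
  caches <- vector("list", length(node_idx))
  attn <- if (keep_attention) vector("list", length(node_idx)) else NULL
  for (gi in seq_along(node_idx)) {
    ix <- node_idx[[gi]]
    Xg <- X[ix, , drop = FALSE]
    Q <- Xg %*% p$Wq; K <- Xg %*% p$Wk; V <- Xg %*% p$Wv
    O <- matrix(0, nrow(Xg), H)
    hc <- vector("list", heads)
    if (keep_attention) attn[[gi]] <- vector("list", heads)
    for (h in seq_len(heads)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      Ap <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dh)
      Ap <- sweep(Ap, 1, apply(Ap, 1, max))
      A <- exp(Ap); A <- A / rowSums(A)
      O[, cols] <- A %*% V[, cols, drop = FALSE]
      hc[[h]] <- A
      if (keep_attention) attn[[gi]][[h]] <- A
    }
    out[ix, ] <- Xg + O %*% p$Wo
    caches[[gi]] <- list(Q = Q, K = K, V = V, O = O, A = hc, Xg = Xg)
  }
  out <- sweep(out, 2, p$bo, "+")
  list(out = out, cache = caches, attention = attn)
}

mhsa_backward <- function(p, dout, X, node_idx, heads, cache) {
  H <- ncol(X)
  dh <- H %/% heads
  dX <- dout                      # residual path
  g <- list(Wq = matrix(0, H, H), Wk = matrix(0, H, H), Wv = matrix(0, H, H),
            Wo = matrix(0, H, H), bo = colSums(dout))
  for (gi in seq_along(node_idx)) {
    ix <- node_idx[[gi]]
    cg <- cache[[gi]]
    dg <- dout[ix, , drop = FALSE]
    dO <- dg %*% t(p$Wo)
    g$Wo <- g$Wo + crossprod(cg$O, dg)
    dQ <- matrix(0, length(ix), H); dK <- dQ; dV <- dQ
    for (h in seq_len(heads)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      A <- cg$A[[h]]
      dOh <- dO[, cols, drop = FALSE]
      dA <- tcrossprod(dOh, cg$V[, cols, drop = FALSE])
      dV[, cols] <- crossprod(A, dOh)
      dAp <- A * (dA - rowSums(A * dA))
      dQ[, cols] <- dAp %*% cg$K[, cols, drop = FALSE] / sqrt(dh)
      dK[, cols] <- crossprod(dAp, cg$Q[, cols, drop = FALSE]) / sqrt(dh)
    }
    dX[ix, ] <- dX[ix, ] + dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
    g$Wq <- g$Wq + crossprod(cg$Xg, dQ)
    g$Wk <- g$Wk + crossprod(cg$Xg, dK)
    g$Wv <- g$Wv + crossprod(cg$Xg, dV)
  }
  list(dX = dX, grads = g)
}

# ---- readout: concat(global max pool, global mean pool) --------------------

pool_forward <- function(X, node_idx) {
  G <- length(node_idx)
  H <- ncol(X)
  U <- matrix(0, G, 2 * H)
  argmax <- vector("list", G)
  for (gi in seq_len(G)) {
    ix <- node_idx[[gi]]
    Xg <- X[ix, , drop = FALSE]
    am <- max.col(t(Xg), ties.method = "first")   # per-column argmax
    U[gi, 1:H] <- Xg[cbind(am, seq_len(H))]
    U[gi, (H + 1):(2 * H)] <- colMeans(Xg)
    argmax[[gi]] <- ix[am]
  }
  list(out = U, argmax = argmax)
}

pool_backward <- function(dU, X, node_idx, argmax) {
  H <- ncol(X)
  dX <- matrix(0, nrow(X), H)
  for (gi in seq_along(node_idx)) {
    ix <- node_idx[[gi]]
    idx <- cbind(argmax[[gi]], seq_len(H))
    dX[idx] <- dX[idx] + dU[gi, 1:H]
    dX[ix, ] <- dX[ix, ] +
      matrix(dU[gi, (H + 1):(2 * H)], length(ix), H, byrow = TRUE) / length(ix)
  }
  dX
}

# ---- fully connected head --------------------------------------------------

fc_init <- function(nin, nhid, nout = 1L) {
  list(W1 = glorot(nin, nhid), b1 = rep(0, nhid),
       W2 = glorot(nhid, nout), b2 = rep(0, nout))
}

fc_forward <- function(p, U, drop_mask = NULL) {
  Hpre <- sweep(U %*% p$W1, 2, p$b1, "+")
  Hact <- pmax(Hpre, 0)
  Hd <- if (is.null(drop_mask)) Hact else Hact * drop_mask
  Z <- sweep(Hd %*% p$W2, 2, p$b2, "+")
  list(out = Z, cache = list(U = U, Hpre = Hpre, Hd = Hd, drop_mask = drop_mask))
}

fc_backward <- function(p, dZ, cache) {
  if (is.null(dim(dZ))) dZ <- matrix(dZ, ncol = 1)
  dHd <- dZ %*% t(p$W2)
  dH <- dHd * (cache$Hpre > 0)
  if (!is.null(cache$drop_mask)) dH <- dH * cache$drop_mask
  list(dU = dH %*% t(p$W1),
       grads = list(W1 = crossprod(cache$U, dH), b1 = colSums(dH),
                    W2 = crossprod(cache$Hd, dZ), b2 = colSums(dZ)))
}

# ---- loss ------------------------------------------------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

# class-weighted binary cross-entropy with logits; returns loss and dL/dz
bce_loss <- function(z, y, w) {
  z <- drop(z)
  loss_i <- pmax(z, 0) - y * z + log1p(exp(-abs(z)))
  wsum <- sum(w)
  list(loss = sum(w * loss_i) / wsum,
       dz = w * (sigmoid(z) - y) / wsum)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  zero <- rapply(params, function(x) x * 0, how = "replace")
  list(m = zero, v = zero, t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (k in seq_along(p)) {
        r <- walk(p[[k]], g[[k]], m[[k]], v[[k]])
        out_p[[k]] <- r$p; out_m[[k]] <- r$m; out_v[[k]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m2 <- beta1 * m + (1 - beta1) * g
      v2 <- beta2 * v + (1 - beta2) * g^2
      mhat <- m2 / (1 - beta1^t)
      vhat <- v2 / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m2, v = v2)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  state$m <- r$m; state$v <- r$v
  list(params = r$p, state = state)
}
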