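# Low-level neural-network primitives with hand-derived reverse-mode
# gradients. Everything operates on plain matrices; a "layer" is a pair of
# functions, forward returning (out, cache) and backward consuming
# (dout, cache) and returning (dx, parameter gradients).

linear_fwd <- function(x, p) {
  list(out = x %*% p$W + matrix(p$b, nrow(x), length(p$b), byrow = TRUE),
       cache = x)
}

linear_bwd <- function(dout, cache, p) {
  list(dx = dout %*% t(p$W),
       grads = list(W = crossprod(cache, dout), b = colSums(dout)))
}

relu_fwd <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bwd <- function(dout, cache) dout * cache

LN_EPS <- 1e-5

layernorm_fwd <- function(x, p) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  out <- xhat * matrix(p$g, nrow(x), ncol(x), byrow = TRUE) +
    matrix(p$b, nrow(x), ncol(x), byrow = TRUE)
  list(out = out, cache = list(xhat = xhat, inv = inv))
}

layernorm_bwd <- function(dout, cache, p) {
  xhat <- cache$xhat
  dxhat <- dout * matrix(p$g, nrow(dout), ncol(dout), byrow = TRUE)
  # per-row: dx = inv * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat))
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dx = dx,
       grads = list(g = colSums(dout * xhat), b = colSums(dout)))
}

# numerically safe row softmax; -Inf entries (masked keys) get probability 0
row_softmax <- function(z) {
  m <- apply(z, 1, max)
  e <- exp(z - m)
  e / rowSums(e)
}

# Multi-head self-attention with an additive per-head pre-softmax bias.
# x: N x H; bias: N x N x nh array (or NULL); attn_mask: logical N (TRUE =
# attend); p holds Wq,bq,Wk,bk,Wv,bv,Wo,bo.
attention_fwd <- function(x, p, bias, n_heads, attn_mask = NULL) {
  n <- nrow(x); h <- ncol(x); dh <- h / n_heads
  Q <- x %*% p$Wq + matrix(p$bq, n, h, byrow = TRUE)
  K <- x %*% p$Wk + matrix(p$bk, n, h, byrow = TRUE)
  V <- x %*% p$Wv + matrix(p$bv, n, h, byrow = TRUE)
  O <- matrix(0, n, h)
  A <- vector("list", n_heads)
  for (hd in seq_len(n_heads)) {
    idx <- ((hd - 1) * dh + 1):(hd * dh)
    S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sqrt(dh)
    if (!is.null(bias)) S <- S + bias[, , hd]
    if (!is.null(attn_mask)) S[, !attn_mask] <- -Inf
    A[[hd]] <- row_softmax(S)
    O[, idx] <- A[[hd]] %*% V[, idx, drop = FALSE]
  }
  out <- O %*% p$Wo + matrix(p$bo, n, h, byrow = TRUE)
  list(out = out, cache = list(x = x, Q = Q, K = K, V = V, A = A, O = O,
                               n_heads = n_heads))
}

attention_bwd <- function(dout, cache, p) {
  x <- cache$x; n <- nrow(x); h <- ncol(x)
  nh <- cache$n_heads; dh <- h / nh
  dWo <- crossprod(cache$O, dout)
  dbo <- colSums(dout)
  dO <- dout %*% t(p$Wo)
  dQ <- matrix(0, n, h); dK <- matrix(0, n, h); dV <- matrix(0, n, h)
  dbias <- array(0, c(n, n, nh))
  for (hd in seq_len(nh)) {
    idx <- ((hd - 1) * dh + 1):(hd * dh)
    A <- cache$A[[hd]]
    dOh <- dO[, idx, drop = FALSE]
    dA <- tcrossprod(dOh, cache$V[, idx, drop = FALSE])
    dV[, idx] <- crossprod(A, dOh)
    dS <- A * (dA - rowSums(dA * A))
    dbias[, , hd] <- dS
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE] / sqrt(dh)
    dK[, idx] <- crossprod(dS, cache$Q[, idx, drop = FALSE]) / sqrt(dh)
  }
  dx <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  list(dx = dx, dbias = dbias,
       grads = list(Wq = crossprod(x, dQ), bq = colSums(dQ),
                    Wk = crossprod(x, dK), bk = colSums(dK),
                    Wv = crossprod(x, dV), bv = colSums(dV),
                    Wo = dWo, bo = dbo))
}

mlp_fwd <- function(x, p, dropout = 0, training = FALSE) {
  l1 <- linear_fwd(x, list(W = p$W1, b = p$b1))
  r <- relu_fwd(l1$out)
  h1 <- r$out
  dmask <- NULL
  if (training && dropout > 0) {
    dmask <- matrix(stats::rbinom(length(h1), 1, 1 - dropout) / (1 - dropout),
                    nrow(h1), ncol(h1))
    h1 <- h1 * dmask
  }
  l2 <- linear_fwd(h1, list(W = p$W2, b = p$b2))
  list(out = l2$out, cache = list(x = x, rmask = r$cache, h1 = h1,
                                  dmask = dmask))
}

mlp_bwd <- function(dout, cache, p) {
  dW2 <- crossprod(cache$h1, dout)
  db2 <- colSums(dout)
  dh1 <- dout %*% t(p$W2)
  if (!is.null(cache$dmask)) dh1 <- dh1 * cache$dmask
  dh1 <- relu_bwd(dh1, cache$rmask)
  dW1 <- crossprod(cache$x, dh1)
  db1 <- colSums(dh1)
  list(dx = dh1 %*% t(p$W1),
       grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

# One transformer block: two biased attention layers and one MLP, each with
# pre-layer-normalization and a residual connection.
block_fwd <- function(x, p, bias, n_heads, dropout = 0, training = FALSE,
                      attn_mask = NULL) {
  ln1 <- layernorm_fwd(x, p$ln1)
  a1 <- attention_fwd(ln1$out, p$att1, bias, n_heads, attn_mask)
  x1 <- x + a1$out
  ln2 <- layernorm_fwd(x1, p$ln2)
  a2 <- attention_fwd(ln2$out, p$att2, bias, n_heads, attn_mask)
  x2 <- x1 + a2$out
  ln3 <- layernorm_fwd(x2, p$ln3)
  m <- mlp_fwd(ln3$out, p$mlp, dropout, training)
  list(out = x2 + m$out,
       cache = list(ln1 = ln1$cache, a1 = a1$cache, ln2 = ln2$cache,
                    a2 = a2$cache, ln3 = ln3$cache, mlp = m$cache))
}

block_bwd <- function(dout, cache, p) {
  mb <- mlp_bwd(dout, cache$mlp, p$mlp)
  l3 <- layernorm_bwd(mb$dx, cache$ln3, p$ln3)
  dx2 <- dout + l3$dx
  a2 <- attention_bwd(dx2, cache$a2, p$att2)
  l2 <- layernorm_bwd(a2$dx, cache$ln2, p$ln2)
  dx1 <- dx2 + l2$dx
  a1 <- attention_bwd(dx1, cache$a1, p$att1)
  l1 <- layernorm_bwd(a1$dx, cache$ln1, p$ln1)
  list(dx = dx1 + l1$dx,
       dbias = a1$dbias + a2$dbias,
       grads = list(ln1 = l1$grads, att1 = a1$grads, ln2 = l2$grads,
                    att2 = a2$grads, ln3 = l3$grads, mlp = mb$grads))
}

# ---- parameter-tree utilities -------------------------------------------

is_leaf <- function(x) is.numeric(x)

tree_map <- function(f, tree, ...) {
  extra <- list(...)
  if (is_leaf(tree)) return(do.call(f, c(list(tree), extra)))
  out <- lapply(tree, tree_map, f = f, ...)
  out
}

tree_map2 <- function(f, a, b) {
  if (is_leaf(a)) return(f(a, b))
  stopifnot(length(a) == length(b))
  stats::setNames(lapply(seq_along(a), function(i) tree_map2(f, a[[i]], b[[i]])),
                  names(a))
}

tree_add <- function(a, b) tree_map2(`+`, a, b)
tree_scale <- function(a, s) tree_map(function(x) x * s, a)
tree_zeros_like <- function(a) tree_map(function(x) x * 0, a)

# flatten a parameter tree into a named list of leaves ("path/to/leaf")
flatten_tree <- function(tree, prefix = "") {
  if (is_leaf(tree)) return(stats::setNames(list(tree), prefix))
  out <- list()
  nm <- names(tree)
  if (is.null(nm)) nm <- as.character(seq_along(tree))
  for (i in seq_along(tree)) {
    out <- c(out, flatten_tree(tree[[i]],
                               if (prefix == "") nm[i] else paste(prefix, nm[i], sep = "/")))
  }
  out
}

# write flattened leaves back into a tree with the same shape
unflatten_into <- function(tree, leaves, prefix = "") {
  if (is_leaf(tree)) {
    v <- leaves[[prefix]]
    attributes(v) <- attributes(tree)
    return(v)
  }
  nm <- names(tree)
  if (is.null(nm)) nm <- as.character(seq_along(tree))
  for (i in seq_along(tree)) {
    tree[[i]] <- unflatten_into(tree[[i]], leaves,
                                if (prefix == "") nm[i] else paste(prefix, nm[i], sep = "/"))
  }
  tree
}

n_tree_params <- function(tree) {
  sum(vapply(flatten_tree(tree), length, integer(1)))
}

# Glorot-style initialisers; callers manage the RNG state.
init_linear <- function(n_in, n_out, scale = 1) {
  list(W = matrix(stats::rnorm(n_in * n_out, 0, scale * sqrt(2 / (n_in + n_out))),
                  n_in, n_out),
       b = numeric(n_out))
}

init_layernorm <- function(h) list(g = rep(1, h), b = numeric(h))

init_attention <- function(h) {
  l <- function() init_linear(h, h)
  q <- l(); k <- l(); v <- l(); o <- l()
  list(Wq = q$W, bq = q$b, Wk = k$W, bk = k$b,
       Wv = v$W, bv = v$b, Wo = o$W, bo = o$b)
}

init_block <- function(h, mlp_hidden) {
  m1 <- init_linear(h, mlp_hidden)
  m2 <- init_linear(mlp_hidden, h)
  list(ln1 = init_layernorm(h), att1 = init_attention(h),
       ln2 = init_layernorm(h), att2 = init_attention(h),
       ln3 = init_layernorm(h),
       mlp = list(W1 = m1$W, b1 = m1$b, W2 = m2$W, b2 = m2$b))
}

# run body with a private RNG stream, restoring the caller's state
with_seed <- function(seed, body) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  body
}
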