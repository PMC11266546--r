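#' Backbone configuration
#'
#' Hyper-parameters of the distance-biased atom-token graph transformer. The
#' defaults size the backbone at roughly a million parameters: element
#' embedding width `embed_dim = 20`, two physical channels (partial charge,
#' SASA/100), token width `token_dim = 128`, four blocks of two biased
#' attention layers (8 heads) plus one MLP, `rbf_k = 16` Gaussian radial basis
#' kernels with bandwidths log-spaced over 0.5-20 Angstrom, four categorical
#' distance classes with boundaries at 2.2 / 4.0 / 8.0 Angstrom (covalent,
#' first shell, mid-range, long-range), and a Linear-ReLU-Linear classifier
#' with 128 and 20 neurons.
#'
#' @param embed_dim element-embedding width.
#' @param phys_dim number of physical feature channels.
#' @param token_dim hidden width H (divisible by `n_heads`).
#' @param n_blocks number of attention blocks.
#' @param n_heads attention heads per layer.
#' @param rbf_k number of radial basis kernels.
#' @param rbf_bandwidths kernel bandwidths (Angstrom); default log-spaced
#'   over `[0.5, 20]`.
#' @param n_distance_classes number of categorical distance classes.
#' @param class_boundaries ascending class boundaries (Angstrom),
#'   `n_distance_classes - 1` values.
#' @param classifier_hidden hidden width of the masked-AA classifier.
#' @param mlp_mult MLP hidden width as a multiple of `token_dim`.
#' @param head_n_blocks attention blocks in the ddG regression head.
#' @param dropout dropout rate applied during training.
#' @return a `backbone_config` list.
#' @export
backbone_config <- function(embed_dim = 20L, phys_dim = 2L, token_dim = 128L,
                            n_blocks = 4L, n_heads = 8L, rbf_k = 16L,
                            rbf_bandwidths = NULL, n_distance_classes = 4L,
                            class_boundaries = c(2.2, 4.0, 8.0),
                            classifier_hidden = 128L, mlp_mult = 4L,
                            head_n_blocks = 2L, dropout = 0.1) {
  if (is.null(rbf_bandwidths)) {
    rbf_bandwidths <- exp(seq(log(0.5), log(20), length.out = rbf_k))
  }
  stopifnot(token_dim %% n_heads == 0,
            length(rbf_bandwidths) == rbf_k,
            all(rbf_bandwidths > 0),
            length(class_boundaries) == n_distance_classes - 1L,
            !is.unsorted(class_boundaries, strictly = TRUE))
  structure(list(embed_dim = embed_dim, phys_dim = phys_dim,
                 token_dim = token_dim, n_blocks = n_blocks, n_heads = n_heads,
                 rbf_k = rbf_k, rbf_bandwidths = rbf_bandwidths,
                 n_distance_classes = n_distance_classes,
                 class_boundaries = class_boundaries,
                 classifier_hidden = classifier_hidden, mlp_mult = mlp_mult,
                 head_n_blocks = head_n_blocks, dropout = dropout),
            class = "backbone_config")
}

#' Desk-scale configuration
#'
#' A small configuration (token width 32, two blocks, four heads, one-block
#' regression head, no dropout) used throughout the test-suite and worked
#' examples so that training runs complete in seconds to minutes on one CPU.
#'
#' @param ... overrides passed to [backbone_config()].
#' @return a `backbone_config`.
#' @export
desk_config <- function(...) {
  args <- utils::modifyList(
    list(token_dim = 32L, n_blocks = 2L, n_heads = 4L, classifier_hidden = 32L,
         mlp_mult = 2L, head_n_blocks = 1L, dropout = 0),
    list(...))
  do.call(backbone_config, args)
}

#' Gaussian radial-basis encoding of a distance matrix
#'
#' Entry `(i, j, k)` is `exp(-D[i,j]^2 / (2 * s_k^2))` for bandwidth `s_k`.
#'
#' @param D N x N distance matrix.
#' @param bandwidths positive bandwidths (Angstrom).
#' @return N x N x K array.
#' @export
rbf_encode <- function(D, bandwidths) {
  if (any(bandwidths <= 0)) stop("RBF bandwidths must be positive")
  n <- nrow(D)
  out <- array(0, c(n, n, length(bandwidths)))
  for (k in seq_along(bandwidths)) {
    out[, , k] <- exp(-D^2 / (2 * bandwidths[k]^2))
  }
  out
}

#' One-hot categorical encoding of a distance matrix
#'
#' Bins are `[0, b1]`, `(b1, b2]`, `(b2, b3]`, `(b3, Inf)` (closed on the
#' right: a distance equal to a boundary falls in the lower bin).
#'
#' @param D N x N distance matrix.
#' @param boundaries ascending boundary values (Angstrom).
#' @return N x N x (length(boundaries) + 1) one-hot array.
#' @export
categorize_distance <- function(D, boundaries) {
  stopifnot(!is.unsorted(boundaries, strictly = TRUE))
  n <- nrow(D)
  nc <- length(boundaries) + 1L
  idx <- matrix(1L, n, n)
  for (b in boundaries) idx <- idx + (D > b)
  out <- array(0, c(n, n, nc))
  for (k in seq_len(nc)) out[, , k] <- (idx == k) * 1
  out
}

# distance features flattened to (N^2) x (K + C) for the bias linear map
distance_features <- function(D, config) {
  k <- rbf_encode(D, config$rbf_bandwidths)
  c_ <- categorize_distance(D, config$class_boundaries)
  n <- nrow(D)
  cbind(matrix(k, n * n, config$rbf_k), matrix(c_, n * n, config$n_distance_classes))
}

#' Structure-aware attention bias
#'
#' Concatenates the Gaussian RBF and categorical encodings of the pairwise
#' distance matrix and maps them through a linear layer to one additive
#' pre-softmax bias per attention head. The same bias tensor is added in
#' every attention layer of the stack that owns `bias_params`.
#'
#' @param D N x N distance matrix.
#' @param bias_params list with `W` ((K+C) x n_heads) and `b` (n_heads).
#' @param config a `backbone_config`.
#' @return N x N x n_heads array.
#' @export
attention_bias <- function(D, bias_params, config) {
  feats <- distance_features(D, config)
  if (ncol(feats) != nrow(bias_params$W)) {
    stop("bias weight shape mismatch: features have ", ncol(feats),
         " channels, weights expect ", nrow(bias_params$W))
  }
  n <- nrow(D)
  B <- feats %*% bias_params$W +
    matrix(bias_params$b, n * n, config$n_heads, byrow = TRUE)
  array(B, c(n, n, config$n_heads))
}

#' Initialise a backbone model
#'
#' @param config a `backbone_config`.
#' @param seed integer seed fixing the initialisation.
#' @return object of class `backbone_model` with `config`, `params`,
#'   `n_params`.
#' @export
init_backbone <- function(config = backbone_config(), seed = 1L) {
  h <- config$token_dim
  params <- with_seed(seed, {
    list(
      embed = matrix(stats::rnorm(length(ELEMENT_VOCAB) * config$embed_dim, 0, 0.1),
                     length(ELEMENT_VOCAB), config$embed_dim),
      in_proj = init_linear(config$embed_dim + config$phys_dim, h),
      bias_lin = init_linear(config$rbf_k + config$n_distance_classes,
                             config$n_heads),
      blocks = lapply(seq_len(config$n_blocks), function(i)
        init_block(h, config$mlp_mult * h)),
      final_ln = init_layernorm(h),
      clf1 = init_linear(h, config$classifier_hidden),
      clf2 = init_linear(config$classifier_hidden, 20L, scale = 0.1)
    )
  })
  structure(list(config = config, params = params,
                 n_params = n_tree_params(params)),
            class = "backbone_model")
}

#' @export
print.backbone_model <- function(x, ...) {
  cat("atom graph-transformer backbone: H=", x$config$token_dim, ", ",
      x$config$n_blocks, " blocks x (2 attention + MLP), ",
      x$config$n_heads, " heads, ", format(x$n_params, big.mark = ","),
      " parameters\n", sep = "")
  invisible(x)
}

env_input_features <- function(env, config) {
  phys <- env$phys
  if (any(!is.finite(phys))) {
    stop("microenvironment has missing physical features; run ",
         "assign_partial_charges() and compute_sasa() on the structure first")
  }
  cbind(phys[, 1], phys[, 2] / 100)  # charge ~O(1); SASA rescaled to ~O(1)
}

#' Backbone forward pass
#'
#' Embeds element classes, concatenates physical features, projects to the
#' token width and runs the distance-biased attention blocks. Returns the
#' final-layer token states (after the closing layer normalization).
#'
#' @param model a `backbone_model`.
#' @param env a `microenv`.
#' @param training apply dropout? Default `FALSE`.
#' @param keep_cache keep intermediate activations for backpropagation?
#' @param params optional parameter tree overriding `model$params`.
#' @return list with `states` (N x H) and, if requested, `cache`.
#' @export
backbone_forward <- function(model, env, training = FALSE, keep_cache = FALSE,
                             params = NULL) {
  p <- if (is.null(params)) model$params else params
  cfg <- model$config
  n <- nrow(env$coords)
  if (n == 0L) stop("empty microenvironment")
  feats <- env_input_features(env, cfg)
  e <- p$embed[env$elements, , drop = FALSE]
  x0 <- cbind(e, feats)
  proj <- linear_fwd(x0, p$in_proj)
  x <- proj$out
  bias <- attention_bias(env$D, p$bias_lin, cfg)
  caches <- vector("list", cfg$n_blocks)
  for (b in seq_len(cfg$n_blocks)) {
    blk <- block_fwd(x, p$blocks[[b]], bias, cfg$n_heads,
                     dropout = cfg$dropout, training = training)
    x <- blk$out
    if (keep_cache) caches[[b]] <- blk$cache
  }
  fin <- layernorm_fwd(x, p$final_ln)
  out <- list(states = fin$out)
  if (keep_cache) {
    out$cache <- list(x0 = x0, proj_in = proj$cache, blocks = caches,
                      final_in = fin$cache, env = env)
  }
  out
}

# Backpropagate dstates through the backbone; returns parameter gradients.
backbone_backward <- function(model, cache, dstates, params = NULL) {
  p <- if (is.null(params)) model$params else params
  cfg <- model$config
  fin <- layernorm_bwd(dstates, cache$final_in, p$final_ln)
  dx <- fin$dx
  n <- nrow(dx)
  dbias <- array(0, c(n, n, cfg$n_heads))
  gblocks <- vector("list", cfg$n_blocks)
  for (b in rev(seq_len(cfg$n_blocks))) {
    bb <- block_bwd(dx, cache$blocks[[b]], p$blocks[[b]])
    dx <- bb$dx
    dbias <- dbias + bb$dbias
    gblocks[[b]] <- bb$grads
  }
  proj <- linear_bwd(dx, cache$proj_in, p$in_proj)
  dx0 <- proj$dx
  # element-embedding gradient: scatter-add token rows by element index
  dembed <- matrix(0, length(ELEMENT_VOCAB), cfg$embed_dim)
  de <- dx0[, seq_len(cfg$embed_dim), drop = FALSE]
  for (el in unique(cache$env$elements)) {
    rows <- cache$env$elements == el
    dembed[el, ] <- colSums(de[rows, , drop = FALSE])
  }
  feats <- distance_features(cache$env$D, cfg)
  dB <- matrix(dbias, n * n, cfg$n_heads)
  list(embed = dembed,
       in_proj = proj$grads,
       bias_lin = list(W = crossprod(feats, dB), b = colSums(dB)),
       blocks = gblocks,
       final_ln = fin$grads)
}

# classifier forward over pooled states; returns probs and cache
classifier_fwd <- function(states, pool_mask, p) {
  if (!any(pool_mask)) stop("empty pooling shell: no atoms within the pooling cutoff")
  pooled <- colMeans(states[pool_mask, , drop = FALSE])
  l1 <- linear_fwd(matrix(pooled, 1), p$clf1)
  r <- relu_fwd(l1$out)
  l2 <- linear_fwd(r$out, p$clf2)
  z <- drop(l2$out)
  pr <- drop(row_softmax(matrix(z, 1)))
  list(probs = stats::setNames(pr, AA_ORDER),
       cache = list(pooled = pooled, l1_in = l1$cache, rmask = r$cache,
                    l2_in = l2$cache, pool_mask = pool_mask,
                    n_states = nrow(states)))
}

# backward from dlogits (length 20) to dstates + classifier grads
classifier_bwd <- function(dlogits, cache, p) {
  l2 <- linear_bwd(matrix(dlogits, 1), cache$l2_in, p$clf2)
  dh <- relu_bwd(l2$dx, cache$rmask)
  l1 <- linear_bwd(dh, cache$l1_in, p$clf1)
  dpooled <- drop(l1$dx)
  dstates <- matrix(0, cache$n_states, length(dpooled))
  k <- sum(cache$pool_mask)
  dstates[cache$pool_mask, ] <- matrix(dpooled / k, k, length(dpooled),
                                       byrow = TRUE)
  list(dstates = dstates, clf1 = l1$grads, clf2 = l2$grads)
}

#' Predict the masked amino acid of a microenvironment
#'
#' Mean-pools the final-layer states of all atom tokens inside the pooling
#' shell (within 8 Angstrom of the masked C-alpha by default) and passes them
#' through the Linear-ReLU-Linear classifier and a softmax.
#'
#' @param model a `backbone_model`.
#' @param env a `microenv`.
#' @return named numeric vector of 20 amino-acid likelihoods (sums to 1).
#' @export
predict_masked_aa <- function(model, env) {
  fw <- backbone_forward(model, env)
  classifier_fwd(fw$states, env$pool_mask, model$params)$probs
}

#' Cross-entropy pretraining loss
#'
#' @param probs 20-vector of amino-acid likelihoods (or a matrix, one row per
#'   example).
#' @param label amino-acid code(s), 1- or 3-letter.
#' @return mean negative log-likelihood of the labels.
#' @export
pretrain_loss <- function(probs, label) {
  if (is.null(dim(probs))) probs <- matrix(probs, 1)
  idx <- aa_index(label)
  stopifnot(nrow(probs) == length(idx))
  -mean(log(pmax(probs[cbind(seq_len(nrow(probs)), idx)], 1e-12)))
}
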