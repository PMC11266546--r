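#' Initialise a ddG prediction model
#'
#' Couples a (pretrained or fresh) backbone with a Siamese regression head.
#' The head appends one structural amino-acid embedding as a CLS token to the
#' backbone's token states, contextualizes it through its own distance-biased
#' attention blocks (weights shared between the "From" and "To" branches),
#' subtracts the two contextualized CLS states and decodes the difference
#' with a single linear map. With the decoder bias fixed at zero (the
#' default) self-mutations are exactly 0 kcal/mol and predictions are exactly
#' antisymmetric, mirroring the state-function property of Gibbs free energy.
#'
#' @param config a `backbone_config`; ignored when `backbone` is given.
#' @param seed initialisation seed.
#' @param backbone an existing `backbone_model` to adopt.
#' @param use_bias train a decoder bias? Default `FALSE` (bias fixed at 0).
#' @return object of class `ddg_model`.
#' @export
init_ddg_model <- function(config = backbone_config(), seed = 1L,
                           backbone = NULL, use_bias = FALSE) {
  if (is.null(backbone)) backbone <- init_backbone(config, seed)
  cfg <- backbone$config
  if (cfg$classifier_hidden != cfg$token_dim) {
    stop("structural AA embeddings require classifier_hidden == token_dim (",
         cfg$classifier_hidden, " != ", cfg$token_dim, ")")
  }
  h <- cfg$token_dim
  head <- with_seed(seed + 1L, {
    list(bias_lin = init_linear(cfg$rbf_k + cfg$n_distance_classes, cfg$n_heads),
         blocks = lapply(seq_len(cfg$head_n_blocks), function(i)
           init_block(h, cfg$mlp_mult * h)),
         final_ln = init_layernorm(h),
         w = stats::rnorm(h, 0, 0.1),
         b = 0)
  })
  params <- list(bb = backbone$params, head = head)
  structure(list(config = cfg, params = params, use_bias = use_bias,
                 n_params = n_tree_params(params), ema = NULL,
                 history = NULL),
            class = "ddg_model")
}

#' @export
print.ddg_model <- function(x, ...) {
  cat("ddG graph-transformer (", format(x$n_params, big.mark = ","),
      " parameters; head: ", x$config$head_n_blocks,
      " block(s); decoder bias ",
      if (x$use_bias) "trainable" else "fixed at 0", ")\n", sep = "")
  if (!is.null(x$history)) {
    cat("  trained ", nrow(x$history), " iterations; final loss ",
        signif(utils::tail(x$history$loss, 1), 4), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.ddg_model <- function(object, ...) {
  print(object)
  emb <- extract_aa_embeddings(object)
  cat("  structural AA embeddings: 20 x ", ncol(emb),
      " (|row| range ", paste(signif(range(sqrt(rowSums(emb^2))), 3),
                              collapse = " - "), ")\n", sep = "")
  invisible(object)
}

#' @export
coef.ddg_model <- function(object, ...) {
  list(decoder = object$params$head$w, decoder_bias = object$params$head$b,
       aa_embeddings = extract_aa_embeddings(object))
}

# backbone-model view over the bb half of a ddg model's parameter tree
backbone_view <- function(model, params = NULL) {
  p <- if (is.null(params)) model$params$bb else params$bb
  structure(list(config = model$config, params = p,
                 n_params = n_tree_params(p)),
            class = "backbone_model")
}

active_params <- function(model, use_ema = TRUE) {
  if (use_ema && !is.null(model$ema)) model$ema else model$params
}

#' Extract structural amino-acid embeddings
#'
#' Row `a` is the weight vector of output neuron `a` in the final linear
#' layer of the masked-residue classifier — a structure-contextualized
#' embedding of amino acid `a` learned during self-supervised pretraining.
#'
#' @param model a `ddg_model` or `backbone_model`.
#' @param use_ema read from EMA shadow weights when available.
#' @return 20 x H matrix, rows in canonical AA order.
#' @export
extract_aa_embeddings <- function(model, use_ema = TRUE) {
  p <- if (inherits(model, "ddg_model")) active_params(model, use_ema)$bb
       else model$params
  W <- p$clf2$W
  if (ncol(W) != 20L) stop("classifier final layer must have 20 outputs, has ",
                           ncol(W))
  emb <- t(W)
  rownames(emb) <- AA_ORDER
  emb
}

# head bias tensor for an environment extended with one CLS row: token-token
# entries come from the head's bias linear map, CLS row/column are zero
head_bias_full <- function(feats, p_head, n, n_heads) {
  B <- feats %*% p_head$bias_lin$W +
    matrix(p_head$bias_lin$b, n * n, n_heads, byrow = TRUE)
  out <- array(0, c(n + 1L, n + 1L, n_heads))
  out[seq_len(n), seq_len(n), ] <- array(B, c(n, n, n_heads))
  out
}

head_branch_fwd <- function(model, params, states, e_vec, bias_full,
                            training = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  x <- rbind(states, matrix(e_vec, 1))
  caches <- vector("list", cfg$head_n_blocks)
  for (b in seq_len(cfg$head_n_blocks)) {
    blk <- block_fwd(x, params$head$blocks[[b]], bias_full, cfg$n_heads,
                     dropout = cfg$dropout, training = training)
    x <- blk$out
    if (keep_cache) caches[[b]] <- blk$cache
  }
  fin <- layernorm_fwd(x, params$head$final_ln)
  u <- fin$out[nrow(x), ]
  out <- list(u = u)
  if (keep_cache) out$cache <- list(blocks = caches, final_in = fin$cache,
                                    n = nrow(states))
  out
}

# backward from dU (gradient on the CLS state) through one head branch
head_branch_bwd <- function(model, params, cache, dU) {
  cfg <- model$config
  n1 <- cache$n + 1L
  dfin <- matrix(0, n1, cfg$token_dim)
  dfin[n1, ] <- dU
  fin <- layernorm_bwd(dfin, cache$final_in, params$head$final_ln)
  dx <- fin$dx
  dbias <- array(0, c(n1, n1, cfg$n_heads))
  gblocks <- vector("list", cfg$head_n_blocks)
  for (b in rev(seq_len(cfg$head_n_blocks))) {
    bb <- block_bwd(dx, cache$blocks[[b]], params$head$blocks[[b]])
    dx <- bb$dx
    dbias <- dbias + bb$dbias
    gblocks[[b]] <- bb$grads
  }
  list(dstates = dx[seq_len(cache$n), , drop = FALSE],
       de = dx[n1, ],
       dbias_tt = dbias[seq_len(cache$n), seq_len(cache$n), , drop = FALSE],
       grads = list(blocks = gblocks, final_ln = fin$grads))
}

#' Contextualize a structural amino-acid embedding against a microenvironment
#'
#' Appends the embedding as a CLS token to the backbone token states and runs
#' the regression head's attention blocks (the Siamese branch). Returns the
#' final CLS state.
#'
#' @param model a `ddg_model`.
#' @param env a `microenv`.
#' @param aa_embedding length-H numeric vector (one row of
#'   [extract_aa_embeddings()]).
#' @param states optional precomputed backbone token states for `env`.
#' @param use_ema use EMA weights when available.
#' @return length-H numeric vector.
#' @export
contextualize <- function(model, env, aa_embedding, states = NULL,
                          use_ema = TRUE) {
  p <- active_params(model, use_ema)
  if (length(aa_embedding) != model$config$token_dim) {
    stop("aa_embedding has length ", length(aa_embedding), ", expected ",
         model$config$token_dim)
  }
  if (is.null(states)) {
    states <- backbone_forward(backbone_view(model, p), env)$states
  }
  n <- nrow(states)
  feats <- distance_features(env$D, model$config)
  bias <- head_bias_full(feats, p$head, n, model$config$n_heads)
  head_branch_fwd(model, p, states, aa_embedding, bias)$u
}

#' Predict the ddG of a point mutation from one masked microenvironment
#'
#' Runs the Siamese head for the "From" and "To" amino acids against the same
#' masked microenvironment and decodes the difference of the contextualized
#' CLS states: `ddg = w . (u_to - u_from)` (+ decoder bias when enabled),
#' positive values destabilizing. The same microenvironment serves any (from,
#' to) pair, so the "from" amino acid need not be the wild type.
#'
#' @param model a `ddg_model`.
#' @param env a `microenv`.
#' @param from_aa,to_aa amino-acid codes (1- or 3-letter).
#' @param use_ema use EMA weights when available.
#' @return one-row data.frame: structure_id, chain, position, from_aa, to_aa,
#'   ddg_pred_kcal_mol.
#' @export
predict_ddg <- function(model, env, from_aa, to_aa, use_ema = TRUE) {
  p <- active_params(model, use_ema)
  from <- aa_to_one(from_aa); to <- aa_to_one(to_aa)
  states <- backbone_forward(backbone_view(model, p), env)$states
  emb <- extract_aa_embeddings(model, use_ema)
  feats <- distance_features(env$D, model$config)
  bias <- head_bias_full(feats, p$head, nrow(states), model$config$n_heads)
  u_from <- head_branch_fwd(model, p, states, emb[from, ], bias)$u
  u_to <- head_branch_fwd(model, p, states, emb[to, ], bias)$u
  ddg <- sum(p$head$w * (u_to - u_from)) + if (model$use_bias) p$head$b else 0
  data.frame(structure_id = env$meta$structure_id, chain = env$meta$chain,
             position = env$meta$residue_number, from_aa = from, to_aa = to,
             ddg_pred_kcal_mol = ddg, stringsAsFactors = FALSE)
}

#' Predict ddG for a table of mutation records
#'
#' @param object a `ddg_model`.
#' @param records ddG-record data.frame (columns protein_id, chain, position,
#'   from_aa, to_aa).
#' @param structures named list of featurized `protein_structure` objects
#'   keyed by protein_id.
#' @param radius microenvironment radius (Angstrom).
#' @param use_ema use EMA weights when available.
#' @param ... unused.
#' @return numeric vector of predictions (kcal/mol), NA for records whose
#'   structure or residue cannot be resolved.
#' @export
predict.ddg_model <- function(object, records, structures, radius = 16,
                              use_ema = TRUE, ...) {
  p <- active_params(object, use_ema)
  emb <- extract_aa_embeddings(object, use_ema)
  key <- paste(records$protein_id, records$chain, records$position)
  preds <- rep(NA_real_, nrow(records))
  for (k in unique(key)) {
    rows <- which(key == k)
    r1 <- records[rows[1], ]
    s <- structures[[r1$protein_id]]
    if (is.null(s)) next
    env <- tryCatch(build_masked_microenv(s, r1$chain, r1$position,
                                          radius = radius),
                    error = function(e) NULL)
    if (is.null(env)) next
    states <- backbone_forward(backbone_view(object, p), env)$states
    feats <- distance_features(env$D, object$config)
    bias <- head_bias_full(feats, p$head, nrow(states), object$config$n_heads)
    aas <- unique(c(records$from_aa[rows], records$to_aa[rows]))
    u <- sapply(aas, function(a)
      head_branch_fwd(object, p, states, emb[aa_to_one(a), ], bias)$u)
    off <- if (object$use_bias) p$head$b else 0
    for (i in rows) {
      preds[i] <- sum(p$head$w *
                        (u[, records$to_aa[i]] - u[, records$from_aa[i]])) + off
    }
  }
  preds
}

#' Deep mutational scan from a single structure
#'
#' For every residue of the selected chains, builds one masked
#' microenvironment, contextualizes all 20 structural amino-acid embeddings
#' once, and emits the 19 predictions from the wild-type residue to every
#' other amino acid (20 branch runs, not 380, per residue). Residues lacking
#' a C-alpha or with a non-standard identity are skipped with a warning.
#'
#' @param model a `ddg_model`.
#' @param structure a featurized `protein_structure`.
#' @param chains chain ids to scan; default all.
#' @param radius microenvironment radius (Angstrom).
#' @param use_ema use EMA weights when available.
#' @return data.frame sorted by (chain, position, to_aa) with columns
#'   structure_id, chain, position, from_aa, to_aa, ddg_pred_kcal_mol.
#' @export
dms_scan <- function(model, structure, chains = NULL, radius = 16,
                     use_ema = TRUE) {
  p <- active_params(model, use_ema)
  emb <- extract_aa_embeddings(model, use_ema)
  a <- structure$atoms[!structure$atoms$is_hetero, , drop = FALSE]
  if (!is.null(chains)) a <- a[a$chain_id %in% chains, , drop = FALSE]
  res <- unique(a[, c("chain_id", "residue_number", "residue_name")])
  out <- vector("list", nrow(res))
  skipped <- character(0)
  for (i in seq_len(nrow(res))) {
    wt <- unname(AA_ONE[res$residue_name[i]])
    tag <- paste0(res$chain_id[i], ":", res$residue_number[i])
    if (is.na(wt)) { skipped <- c(skipped, tag); next }
    env <- tryCatch(
      build_masked_microenv(structure, res$chain_id[i], res$residue_number[i],
                            radius = radius),
      error = function(e) NULL)
    if (is.null(env)) { skipped <- c(skipped, tag); next }
    states <- backbone_forward(backbone_view(model, p), env)$states
    feats <- distance_features(env$D, model$config)
    bias <- head_bias_full(feats, p$head, nrow(states), model$config$n_heads)
    u <- sapply(AA_ORDER, function(aa)
      head_branch_fwd(model, p, states, emb[aa, ], bias)$u)
    diff <- u - u[, wt]
    ddg <- drop(crossprod(diff, p$head$w)) +
      if (model$use_bias) p$head$b else 0
    to <- setdiff(AA_ORDER, wt)
    out[[i]] <- data.frame(structure_id = structure$id,
                           chain = res$chain_id[i],
                           position = res$residue_number[i],
                           from_aa = wt, to_aa = to,
                           ddg_pred_kcal_mol = unname(ddg[to]),
                           stringsAsFactors = FALSE)
  }
  if (length(skipped) > 0L) {
    warning("skipped ", length(skipped), " residue(s) without C-alpha or ",
            "standard identity: ", paste(utils::head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) ", ...")
  }
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  out <- out[order(out$chain, out$position, out$to_aa), ]
  rownames(out) <- NULL
  out
}

#' Save / load a model checkpoint
#'
#' A checkpoint stores the configuration, live and EMA parameters and a
#' schema version; round-trips are bit-exact.
#'
#' @param model a `ddg_model` or `backbone_model`.
#' @param path checkpoint file path.
#' @return `path` (save) / the restored model (load).
#' @export
save_model <- function(model, path) {
  saveRDS(list(schema = 1L, class = class(model)[1],
               config = unclass(model$config), model = unclass(model)), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$schema) || ck$schema != 1L) stop("unknown checkpoint schema")
  m <- ck$model
  m$config <- structure(ck$config, class = "backbone_config")
  structure(m, class = ck$class)
}
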