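#' Huber loss
#'
#' `0.5 r^2` for `|r| <= delta`, `delta * (|r| - 0.5 delta)` beyond; both
#' branches and their gradients match at `|r| = delta`.
#'
#' @param residual numeric vector of residuals (kcal/mol).
#' @param delta transition point; default 1.
#' @return numeric vector of per-residual losses.
#' @export
huber_loss <- function(residual, delta = 1) {
  stopifnot(delta > 0)
  a <- abs(residual)
  ifelse(a <= delta, 0.5 * residual^2, delta * (a - 0.5 * delta))
}

huber_grad <- function(residual, delta = 1) {
  ifelse(abs(residual) <= delta, residual, delta * sign(residual))
}

#' Exponential-moving-average update of shadow parameters
#'
#' `shadow <- eta * shadow + (1 - eta) * live`, applied leaf-wise to
#' parameter trees (or plain numerics). Evaluation uses the shadow weights.
#'
#' @param shadow current shadow parameters (tree or numeric).
#' @param live live parameters of the same shape.
#' @param eta decay; default 0.99.
#' @return updated shadow.
#' @export
ema_update <- function(shadow, live, eta = 0.99) {
  if (is_leaf(shadow)) {
    stopifnot(length(shadow) == length(live))
    return(eta * shadow + (1 - eta) * live)
  }
  tree_map2(function(s, l) eta * s + (1 - eta) * l, shadow, live)
}

#' Training configuration
#'
#' Defaults follow the full-scale recipe: Huber loss with delta = 1, AdamW
#' (betas 0.9/0.999, eps 1e-8) with learning rate 5e-5 for regression-head
#' parameters and 2e-5 for backbone parameters, effective batch 960 as
#' micro-batch 240 with 4 accumulation steps, weight decay 0.1, optimizer EMA
#' with eta = 0.99, 750 iterations. The small-dataset recipe freezes the
#' backbone (lr 5e-7 from a pretrained start, 5e-5 from scratch, batch 1024,
#' 500 iterations). `preset = "desk"` scales everything to single-CPU sizes
#' used by the test-suite.
#'
#' @param preset `"paper"` (full-scale defaults), `"small"` (frozen-backbone
#'   small-dataset recipe) or `"desk"`.
#' @param ... field overrides.
#' @return a `train_config` list.
#' @export
train_config <- function(preset = c("paper", "small", "desk"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    paper = list(loss_delta = 1, head_lr = 5e-5, backbone_lr = 2e-5, lr = 1e-3,
                 micro_batch = 240L, accum_steps = 4L, weight_decay = 0.1,
                 ema_eta = 0.99, iterations = 750L, freeze_backbone = FALSE,
                 freeze_embeddings = FALSE, seed = 1L),
    small = list(loss_delta = 1, head_lr = 5e-7, backbone_lr = 0, lr = 1e-3,
                 micro_batch = 1024L, accum_steps = 1L, weight_decay = 0.1,
                 ema_eta = 0.99, iterations = 500L, freeze_backbone = TRUE,
                 freeze_embeddings = TRUE, seed = 1L),
    desk = list(loss_delta = 1, head_lr = 2e-3, backbone_lr = 1e-3, lr = 2e-3,
                micro_batch = 16L, accum_steps = 1L, weight_decay = 0.01,
                ema_eta = 0.99, iterations = 400L, freeze_backbone = FALSE,
                freeze_embeddings = FALSE, seed = 1L))
  cfg <- utils::modifyList(base, list(...))
  cfg$betas <- cfg$betas %||% c(0.9, 0.999)
  cfg$eps <- cfg$eps %||% 1e-8
  stopifnot(cfg$head_lr >= 0, cfg$backbone_lr >= 0, cfg$micro_batch >= 1,
            cfg$accum_steps >= 1)
  structure(cfg, class = "train_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- AdamW over flattened leaf lists ------------------------------------

adamw_init <- function(leaves) {
  list(m = lapply(leaves, function(x) x * 0),
       v = lapply(leaves, function(x) x * 0),
       t = 0L)
}

adamw_step <- function(leaves, grads, state, lr_of, config) {
  state$t <- state$t + 1L
  b1 <- config$betas[1]; b2 <- config$betas[2]
  c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
  for (nm in names(leaves)) {
    lr <- lr_of(nm)
    if (lr <= 0) next
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    upd <- (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + config$eps)
    # decoupled weight decay, applied to weights but not biases/gains
    wd <- if (grepl("(^|/)(W|W1|W2|Wq|Wk|Wv|Wo|embed|w)$", nm)) config$weight_decay else 0
    leaves[[nm]] <- leaves[[nm]] - lr * (upd + wd * leaves[[nm]])
  }
  list(leaves = leaves, state = state)
}

# shuffled index stream that reshuffles when exhausted
index_stream <- function(n) {
  pool <- sample(n)
  pos <- 0L
  function(k) {
    out <- integer(0)
    while (length(out) < k) {
      if (pos >= length(pool)) { pool <<- sample(n); pos <<- 0L }
      take <- min(k - length(out), length(pool) - pos)
      out <- c(out, pool[(pos + 1L):(pos + take)])
      pos <<- pos + take
    }
    out
  }
}

resolve_environments <- function(records, structures, radius) {
  key <- paste(records$protein_id, records$chain, records$position, sep = "\r")
  envs <- list()
  bad <- character(0)
  for (k in unique(key)) {
    r <- records[key == k, ][1, ]
    s <- structures[[r$protein_id]]
    env <- if (is.null(s)) NULL else
      tryCatch(build_masked_microenv(s, r$chain, r$position, radius = radius),
               error = function(e) NULL)
    if (is.null(env)) bad <- c(bad, k) else envs[[k]] <- env
  }
  resolved <- !(key %in% bad)
  if (!any(resolved)) stop("no record could be resolved to a microenvironment")
  if (length(bad) > 0L) {
    warning(sum(!resolved), " record(s) skipped: unresolvable to a ",
            "microenvironment (", length(bad), " position(s))")
  }
  list(envs = envs, key = key, resolved = resolved)
}

#' Fine-tune a ddG model on mutation records
#'
#' AdamW with per-group learning rates (head vs backbone), gradient
#' accumulation, Huber loss, optimizer EMA, and seeded shuffling. With
#' `freeze_backbone = TRUE` the backbone token states are computed once per
#' microenvironment and reused, and backbone parameters stay bit-identical;
#' the structural AA embeddings (classifier final layer) remain trainable
#' unless `freeze_embeddings = TRUE`.
#'
#' @param model a `ddg_model`.
#' @param records ddG record data.frame (train split).
#' @param structures named list of featurized `protein_structure` objects.
#' @param config a [train_config()].
#' @param radius microenvironment radius (Angstrom).
#' @param verbose print progress every 50 iterations.
#' @return the trained `ddg_model`, with `$history` (iteration, loss) and
#'   `$ema` shadow weights used for prediction.
#' @export
finetune_run <- function(model, records, structures, config = train_config("desk"),
                         radius = 16, verbose = FALSE) {
  cfg <- model$config
  res <- resolve_environments(records, structures, radius)
  records <- records[res$resolved, ]
  key <- res$key[res$resolved]
  envs <- res$envs

  # per-environment immutable caches
  feats <- lapply(envs, function(e) distance_features(e$D, cfg))
  frozen_states <- NULL
  if (config$freeze_backbone) {
    bbv <- backbone_view(model)
    frozen_states <- lapply(envs, function(e) backbone_forward(bbv, e)$states)
  }

  leaves <- flatten_tree(model$params)
  opt <- adamw_init(leaves)
  shadow <- leaves
  lr_of <- function(nm) {
    if (startsWith(nm, "head/")) {
      if (nm == "head/b" && !model$use_bias) 0 else config$head_lr
    } else if (nm == "bb/clf2/W" && !config$freeze_embeddings) {
      if (config$freeze_backbone) config$head_lr else config$backbone_lr
    } else if (config$freeze_backbone) 0 else config$backbone_lr
  }

  from_idx <- aa_index(records$from_aa)
  to_idx <- aa_index(records$to_aa)
  history <- numeric(config$iterations)

  with_seed(config$seed, {
    next_idx <- index_stream(nrow(records))
    for (it in seq_len(config$iterations)) {
      gacc <- lapply(leaves, function(x) x * 0)
      batch_loss <- 0
      n_seen <- 0L
      params <- unflatten_into(model$params, leaves)
      for (acc in seq_len(config$accum_steps)) {
        idx <- next_idx(config$micro_batch)
        for (i in idx) {
          sg <- ddg_sample_grad(model, params, envs[[key[i]]], feats[[key[i]]],
                                frozen_states[[key[i]]],
                                from_idx[i], to_idx[i], records$ddg[i], config)
          batch_loss <- batch_loss + sg$loss
          n_seen <- n_seen + 1L
          for (nm in names(sg$grads)) {
            gacc[[nm]] <- gacc[[nm]] + sg$grads[[nm]]
          }
        }
      }
      gacc <- lapply(gacc, function(g) g / n_seen)
      st <- adamw_step(leaves, gacc, opt, lr_of, config)
      leaves <- st$leaves; opt <- st$state
      shadow <- mapply(function(s, l) config$ema_eta * s + (1 - config$ema_eta) * l,
                       shadow, leaves, SIMPLIFY = FALSE)
      history[it] <- batch_loss / n_seen
      if (verbose && it %% 50 == 0) {
        message("iter ", it, " loss ", signif(history[it], 4))
      }
    }
  })
  model$params <- unflatten_into(model$params, leaves)
  model$ema <- unflatten_into(model$params, shadow)
  model$history <- data.frame(iteration = seq_len(config$iterations),
                              loss = history)
  model
}

# forward + backward for one (env, from, to, ddg) sample; returns flattened
# gradient contributions and the sample loss
ddg_sample_grad <- function(model, params, env, feats, frozen_states,
                            from_idx, to_idx, target, config) {
  cfg <- model$config
  bb_free <- !config$freeze_backbone
  if (is.null(frozen_states)) {
    bf <- backbone_forward(backbone_view(model, params), env, training = bb_free,
                           keep_cache = bb_free)
    states <- bf$states
  } else {
    states <- frozen_states
  }
  emb <- t(params$bb$clf2$W)
  n <- nrow(states)
  bias <- head_bias_full(feats, params$head, n, cfg$n_heads)
  fw_from <- head_branch_fwd(model, params, states, emb[from_idx, ], bias,
                             training = TRUE, keep_cache = TRUE)
  fw_to <- head_branch_fwd(model, params, states, emb[to_idx, ], bias,
                           training = TRUE, keep_cache = TRUE)
  pred <- sum(params$head$w * (fw_to$u - fw_from$u)) +
    if (model$use_bias) params$head$b else 0
  r <- pred - target
  dpred <- huber_grad(r, config$loss_delta)

  bw_to <- head_branch_bwd(model, params, fw_to$cache, dpred * params$head$w)
  bw_from <- head_branch_bwd(model, params, fw_from$cache, -dpred * params$head$w)

  ghead <- tree_add(bw_to$grads, bw_from$grads)
  ghead$w <- dpred * (fw_to$u - fw_from$u)
  ghead$b <- if (model$use_bias) dpred else 0
  dbias_tt <- bw_to$dbias_tt + bw_from$dbias_tt
  dB <- matrix(dbias_tt, n * n, cfg$n_heads)
  ghead$bias_lin <- list(W = crossprod(feats, dB), b = colSums(dB))

  grads <- flatten_tree(list(head = ghead))
  # embedding gradients land in the classifier final layer
  if (!config$freeze_embeddings) {
    dW <- matrix(0, nrow(params$bb$clf2$W), 20L)
    dW[, to_idx] <- bw_to$de
    dW[, from_idx] <- dW[, from_idx] + bw_from$de
    grads[["bb/clf2/W"]] <- dW
  }
  if (bb_free) {
    dstates <- bw_to$dstates + bw_from$dstates
    gb <- backbone_backward(backbone_view(model, params), bf$cache, dstates)
    gb$clf1 <- list(W = params$bb$clf1$W * 0, b = params$bb$clf1$b * 0)
    gW2 <- grads[["bb/clf2/W"]] %||% (params$bb$clf2$W * 0)
    gb$clf2 <- list(W = gW2, b = params$bb$clf2$b * 0)
    gflat <- flatten_tree(list(bb = gb))
    grads[names(gflat)] <- gflat
  }
  list(loss = huber_loss(r, config$loss_delta), grads = grads)
}

#' Pretrain a backbone on masked-residue recovery
#'
#' Cross-entropy training of the masked-amino-acid classifier with AdamW
#' (single learning rate `config$lr`), gradient accumulation, optimizer EMA
#' and seeded shuffling.
#'
#' @param model a `backbone_model`.
#' @param environments list of `microenv` objects with `label_aa` set.
#' @param config a [train_config()].
#' @param verbose print progress every 50 iterations.
#' @return the trained `backbone_model` with `$history` and `$ema`.
#' @export
pretrain_run <- function(model, environments, config = train_config("desk"),
                         verbose = FALSE) {
  has_label <- !vapply(environments, function(e) is.null(e$label_aa), TRUE)
  if (!all(has_label)) {
    warning(sum(!has_label), " environment(s) without labels skipped")
    environments <- environments[has_label]
  }
  if (length(environments) == 0L) stop("no labelled environments")
  labels <- vapply(environments, function(e) aa_index(e$label_aa), 1L)
  leaves <- flatten_tree(model$params)
  opt <- adamw_init(leaves)
  shadow <- leaves
  lr_of <- function(nm) config$lr
  history <- numeric(config$iterations)
  with_seed(config$seed, {
    next_idx <- index_stream(length(environments))
    for (it in seq_len(config$iterations)) {
      gacc <- lapply(leaves, function(x) x * 0)
      batch_loss <- 0; n_seen <- 0L
      params <- unflatten_into(model$params, leaves)
      mm <- model; mm$params <- params
      for (acc in seq_len(config$accum_steps)) {
        idx <- next_idx(config$micro_batch)
        for (i in idx) {
          fw <- backbone_forward(mm, environments[[i]], training = TRUE,
                                 keep_cache = TRUE)
          cl <- classifier_fwd(fw$states, environments[[i]]$pool_mask, params)
          loss <- -log(max(cl$probs[labels[i]], 1e-12))
          dlogits <- cl$probs
          dlogits[labels[i]] <- dlogits[labels[i]] - 1
          cb <- classifier_bwd(dlogits, cl$cache, params)
          g <- backbone_backward(mm, fw$cache, cb$dstates)
          g$clf1 <- cb$clf1; g$clf2 <- cb$clf2
          gflat <- flatten_tree(g)
          for (nm in names(gflat)) gacc[[nm]] <- gacc[[nm]] + gflat[[nm]]
          batch_loss <- batch_loss + loss
          n_seen <- n_seen + 1L
        }
      }
      gacc <- lapply(gacc, function(g) g / n_seen)
      st <- adamw_step(leaves, gacc, opt, lr_of, config)
      leaves <- st$leaves; opt <- st$state
      shadow <- mapply(function(s, l) config$ema_eta * s + (1 - config$ema_eta) * l,
                       shadow, leaves, SIMPLIFY = FALSE)
      history[it] <- batch_loss / n_seen
      if (verbose && it %% 50 == 0) {
        message("iter ", it, " loss ", signif(history[it], 4))
      }
    }
  })
  model$params <- unflatten_into(model$params, leaves)
  model$ema <- unflatten_into(model$params, shadow)
  model$history <- data.frame(iteration = seq_len(config$iterations),
                              loss = history)
  model
}

#' Masked-residue recovery accuracy of a backbone
#'
#' @param model a `backbone_model` (EMA weights used when present).
#' @param environments labelled `microenv` list.
#' @param use_ema use EMA weights when available.
#' @return fraction of environments whose top-likelihood amino acid matches
#'   the label.
#' @export
masked_accuracy <- function(model, environments, use_ema = TRUE) {
  m <- model
  if (use_ema && !is.null(model$ema)) m$params <- model$ema
  hits <- vapply(environments, function(e) {
    which.max(predict_masked_aa(m, e)) == aa_index(e$label_aa)
  }, TRUE)
  mean(hits)
}
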