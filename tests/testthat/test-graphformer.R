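test_that("RBF encoding matches the closed form and is monotone", {
  bw <- desk_config()$rbf_bandwidths
  D0 <- matrix(0, 2, 2)
  expect_true(all(rbf_encode(D0, bw) == 1))
  d_seq <- seq(0.5, 20, length.out = 30)
  for (k in c(1, 8, 16)) {
    v <- exp(-d_seq^2 / (2 * bw[k]^2))
    expect_true(all(diff(v) < 0 | v[-1] == 0))  # strict until underflow
  }
  withr::local_seed(2)
  D <- pairwise_distances(matrix(rnorm(30, sd = 5), ncol = 3))
  enc <- rbf_encode(D, bw)
  for (k in seq_along(bw)) {
    expect_lt(max(abs(enc[, , k] - exp(-D^2 / (2 * bw[k]^2)))), 1e-9)
  }
  expect_error(rbf_encode(D, c(1, -1)), "positive")
})

test_that("distance categorization is one-hot with closed-right bins", {
  b <- c(2.2, 4, 8)
  D <- matrix(c(0, 2.2, 4.0001, 9, 3, 8, 1, 2.3, 0), 3, 3)
  oh <- categorize_distance(D, b)
  expect_true(all(apply(oh, c(1, 2), sum) == 1))
  expect_equal(which(oh[1, 1, ] == 1), 1L)  # zero distance -> first bin
  expect_equal(which(oh[2, 1, ] == 1), 1L)  # exactly at boundary -> lower bin
  expect_equal(which(oh[1, 2, ] == 1), 4L)  # 9 is beyond the last boundary
  expect_equal(which(oh[3, 2, ] == 1), 3L)  # 8 falls in (4, 8]
})

test_that("attention bias equals a hand-computed concat + matmul oracle", {
  cfg <- desk_config()
  withr::local_seed(6)
  D <- pairwise_distances(matrix(rnorm(15, sd = 4), ncol = 3))
  W <- matrix(rnorm(20 * cfg$n_heads, sd = 0.3), 20, cfg$n_heads)
  b <- rnorm(cfg$n_heads)
  bias <- attention_bias(D, list(W = W, b = b), cfg)
  for (i in 1:5) for (j in 1:5) {
    feat <- c(exp(-D[i, j]^2 / (2 * cfg$rbf_bandwidths^2)),
              as.numeric(seq_len(4) ==
                           1 + sum(D[i, j] > cfg$class_boundaries)))
    expect_equal(bias[i, j, ], drop(feat %*% W) + b, tolerance = 1e-9)
  }
  # zero weights give an all-zero bias
  z <- attention_bias(D, list(W = W * 0, b = b * 0), cfg)
  expect_true(all(z == 0))
  # consistent row/column permutation permutes the bias identically
  perm <- c(3, 1, 5, 2, 4)
  bp <- attention_bias(D[perm, perm], list(W = W, b = b), cfg)
  expect_equal(bp, bias[perm, perm, ], tolerance = 1e-12)
  expect_error(attention_bias(D, list(W = W[1:5, , drop = FALSE], b = b), cfg),
               "mismatch")
})

test_that("backbone outputs are token-permutation equivariant", {
  env <- fx_env()
  m <- mutstab:::backbone_view(fx_model())
  out <- backbone_forward(m, env)$states
  withr::local_seed(1)
  perm <- sample(nrow(env$coords))
  envp <- env
  envp$coords <- env$coords[perm, ]
  envp$elements <- env$elements[perm]
  envp$phys <- env$phys[perm, ]
  envp$D <- env$D[perm, perm]
  envp$pool_mask <- env$pool_mask[perm]
  outp <- backbone_forward(m, envp)$states
  expect_lt(max(abs(outp - out[perm, ])), 1e-8)
})

test_that("backbone outputs are SE(3) invariant and finite under fuzzing", {
  env <- fx_env()
  m <- mutstab:::backbone_view(fx_model())
  ref <- backbone_forward(m, env)$states
  withr::local_seed(7)
  for (i in 1:25) {
    er <- rotate_env(env, random_rotation(), shift = rnorm(3, sd = 20))
    expect_lt(max(abs(backbone_forward(m, er)$states - ref)), 1e-5)
  }
  # fuzz: random environments never produce NaN/Inf
  envs <- make_pretrain_toy(40, seed = 77)
  for (e in envs) {
    st <- backbone_forward(m, e)$states
    expect_true(all(is.finite(st)))
  }
})

test_that("masked-AA likelihoods are a proper distribution", {
  pr <- predict_masked_aa(mutstab:::backbone_view(fx_model()), fx_env())
  expect_length(pr, 20)
  expect_true(all(pr >= 0))
  expect_equal(sum(pr), 1, tolerance = 1e-6)
})

test_that("mean pooling is invariant to duplicating pooled tokens", {
  m <- fx_model()
  env <- fx_env()
  states <- backbone_forward(mutstab:::backbone_view(m), env)$states
  a <- mutstab:::classifier_fwd(states, env$pool_mask, m$params$bb)$probs
  dup_states <- rbind(states, states[env$pool_mask, , drop = FALSE])
  dup_mask <- c(env$pool_mask, rep(TRUE, sum(env$pool_mask)))
  b <- mutstab:::classifier_fwd(dup_states, dup_mask, m$params$bb)$probs
  expect_equal(a, b, tolerance = 1e-12)
  # empty pooling shell errors at pooling time
  expect_error(mutstab:::classifier_fwd(states, rep(FALSE, nrow(states)),
                                        m$params$bb), "pooling")
})

test_that("pretraining loss has its closed-form values", {
  expect_equal(pretrain_loss(rep(1 / 20, 20), "A"), log(20))
  p <- numeric(20); p[aa_index("W")] <- 1
  expect_equal(pretrain_loss(p, "W"), 0)
  # batch mean equals the per-example loop oracle
  withr::local_seed(3)
  probs <- t(apply(matrix(runif(100), 5), 1, function(x) {
    x <- c(x, runif(10)); x / sum(x)
  }))
  labs <- sample(mutstab:::AA_ORDER, 5)
  oracle <- mean(vapply(1:5, function(i)
    -log(probs[i, aa_index(labs[i])]), numeric(1)))
  expect_equal(pretrain_loss(probs, labs), oracle, tolerance = 1e-12)
})

test_that("analytic gradients match finite differences on a small model", {
  cfg <- desk_config(token_dim = 16L, n_blocks = 1L, n_heads = 2L,
                     classifier_hidden = 16L)
  m <- init_backbone(cfg, seed = 5)
  env <- make_pretrain_toy(1, seed = 12)[[1]]
  loss_fn <- function(params) {
    fw <- backbone_forward(m, env, params = params)
    cl <- mutstab:::classifier_fwd(fw$states, env$pool_mask, params)
    pretrain_loss(cl$probs, env$label_aa)
  }
  fw <- backbone_forward(m, env, keep_cache = TRUE)
  cl <- mutstab:::classifier_fwd(fw$states, env$pool_mask, m$params)
  dlogits <- cl$probs
  idx <- aa_index(env$label_aa)
  dlogits[idx] <- dlogits[idx] - 1
  cb <- mutstab:::classifier_bwd(dlogits, cl$cache, m$params)
  g <- mutstab:::backbone_backward(m, fw$cache, cb$dstates)
  g$clf1 <- cb$clf1; g$clf2 <- cb$clf2
  fl_p <- mutstab:::flatten_tree(m$params)
  fl_g <- mutstab:::flatten_tree(g)
  withr::local_seed(21)
  eps <- 1e-5
  for (nm in names(fl_p)) {
    i <- sample(length(fl_p[[nm]]), 1)
    pp <- fl_p; pp[[nm]][i] <- pp[[nm]][i] + eps
    pm <- fl_p; pm[[nm]][i] <- pm[[nm]][i] - eps
    fd <- (loss_fn(mutstab:::unflatten_into(m$params, pp)) -
             loss_fn(mutstab:::unflatten_into(m$params, pm))) / (2 * eps)
    an <- fl_g[[nm]][i]
    expect_lt(abs(fd - an) / max(1e-4, abs(fd) + abs(an)), 1e-4)
  }
})

test_that("default configuration lands near the stated parameter budget", {
  m <- init_backbone(backbone_config(), seed = 1)
  expect_gt(m$n_params, 0.9e6)
  expect_lt(m$n_params, 1.4e6)
})
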