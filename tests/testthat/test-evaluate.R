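test_that("stability classes use the +/-0.5 kcal/mol boundaries inclusively", {
  expect_equal(as.character(classify_ddg(c(-0.6, -0.5, 0, 0.5, 0.51))),
               c("stabilizing", "neutral", "neutral", "neutral", "destabilizing"))
  expect_error(classify_ddg(NA_real_))
})

test_that("metric suite matches a brute-force oracle on a hand-made set", {
  pred <- c(-1.2, -0.4, 0.3, 1.5, -0.8, 2.0)
  truth <- c(-1.0, 0.2, 0.5, 1.8, -1.5, 1.2)
  ms <- metric_suite(pred, truth, threshold = 0)
  expect_equal(ms$pearson, cor(pred, truth), tolerance = 1e-9)
  expect_equal(ms$spearman, cor(pred, truth, method = "spearman"),
               tolerance = 1e-9)
  expect_equal(ms$rmse, sqrt(mean((pred - truth)^2)), tolerance = 1e-9)
  # brute-force confusion counts: stabilizing iff value < 0
  tp <- 2; fp <- 1; fn <- 0; tn <- 3
  expect_equal(ms$precision, tp / (tp + fp))
  expect_equal(ms$recall, tp / (tp + fn))
  expect_equal(ms$mcc, (tp * tn - fp * fn) /
                 sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)),
               tolerance = 1e-9)
  # rank-based AUROC oracle: P(score_pos > score_neg) with -pred as score
  pos <- -pred[truth < 0]; neg <- -pred[truth >= 0]
  pairs <- expand.grid(p = pos, n = neg)
  auroc_oracle <- mean(pairs$p > pairs$n) + 0.5 * mean(pairs$p == pairs$n)
  expect_equal(ms$auroc, auroc_oracle, tolerance = 1e-9)
})

test_that("metric suite agrees with the oracle on random paired sets", {
  withr::local_seed(14)
  for (trial in 1:30) {
    n <- sample(10:60, 1)
    truth <- rnorm(n, 0.6, 1.3)
    pred <- truth * 0.7 + rnorm(n, 0, 0.8)
    if (length(unique(truth < 0)) < 2) next
    ms <- metric_suite(pred, truth)
    pos <- -pred[truth < 0]; neg <- -pred[truth >= 0]
    gr <- expand.grid(p = pos, n = neg)
    expect_equal(ms$auroc, mean(gr$p > gr$n) + 0.5 * mean(gr$p == gr$n),
                 tolerance = 1e-9)
    expect_equal(ms$rmse, sqrt(mean((pred - truth)^2)), tolerance = 1e-9)
  }
})

test_that("degenerate metric inputs are reported as undefined, not zero", {
  pred <- c(1, 2, 3, 4)
  truth <- c(0.5, 1, 2, 3)  # single class: nothing stabilizing
  ms <- metric_suite(pred, truth)
  expect_true(is.na(ms$auroc))
  expect_true(is.na(ms$mcc))
  expect_true(is.na(ms$precision))
  # identical vectors: perfect regression metrics
  ms2 <- metric_suite(c(-1, 0, 2), c(-1, 0, 2))
  expect_equal(ms2$pearson, 1)
  expect_equal(ms2$rmse, 0)
  ms3 <- metric_suite(c(-1, 0, 2), c(1, 0, -2))
  expect_equal(ms3$pearson, -1)
})

test_that("threshold sweep composition matches a filter-and-count oracle", {
  withr::local_seed(6)
  truth <- rnorm(200, 0.5, 1.2)
  pred <- truth + rnorm(200, 0, 0.6)
  taus <- c(-1.5, -0.5, 0, 0.5)
  sw <- threshold_sweep(pred, truth, taus)
  cls <- classify_ddg(truth)
  for (i in seq_along(taus)) {
    sel <- pred < taus[i]
    expect_equal(sw$n_selected[i], sum(sel))
    if (sum(sel) > 0) {
      expect_equal(sw$frac_stabilizing[i], mean(cls[sel] == "stabilizing"))
      expect_equal(sw$frac_stabilizing[i] + sw$frac_neutral[i] +
                     sw$frac_destabilizing[i], 1)
    }
    expect_equal(sw$recall_stabilizing[i],
                 sum(sel & cls == "stabilizing") / sum(cls == "stabilizing"))
  }
  # all predictions above all thresholds: empty selections everywhere
  sw0 <- threshold_sweep(rep(5, 10), truth[1:10], taus)
  expect_true(all(sw0$n_selected == 0))
  expect_true(all(is.na(sw0$frac_stabilizing)))
  # perfectly calibrated predictions select only true stabilizers at -0.5
  sw1 <- threshold_sweep(truth, truth, -0.5)
  expect_equal(sw1$frac_stabilizing, 1.0)
})

test_that("mutation-type matrix counts, zero diagonal, coverage and balance", {
  recs <- fx_tp_records()
  mt <- mutation_type_matrix(recs)
  expect_equal(sum(mt$matrix), nrow(recs))
  expect_true(all(diag(mt$matrix) == 0))
  expect_equal(mt$coverage, 6 / 380)
  # a fully TP-balanced set has every off-diagonal cell at 1/380
  full <- expand.grid(from_aa = mutstab:::AA_ORDER, to_aa = mutstab:::AA_ORDER,
                      stringsAsFactors = FALSE)
  full <- full[full$from_aa != full$to_aa, ]
  full$protein_id <- "p"; full$chain <- "A"; full$position <- 1L
  full$ddg <- 0.1; full$provenance <- "TP"; full$source <- "s"
  mtf <- mutation_type_matrix(full, normalize = TRUE)
  expect_equal(mtf$coverage, 1.0)
  off <- mtf$matrix[row(mtf$matrix) != col(mtf$matrix)]
  expect_true(all(abs(off - 1 / 380) < 1e-12))
  expect_equal(unique(round(100 * off, 2)), 0.26)
})

test_that("RSA analysis partitions amino-acid classes as published", {
  expect_length(mutstab:::POLAR_AA, 10)
  expect_length(mutstab:::HYDROPHOBIC_AA, 7)
  expect_length(intersect(mutstab:::POLAR_AA, mutstab:::HYDROPHOBIC_AA), 0)
  expect_setequal(setdiff(mutstab:::AA_ORDER,
                          c(mutstab:::POLAR_AA, mutstab:::HYDROPHOBIC_AA)),
                  c("G", "C", "P"))

  s <- fx_helix()
  recs <- data.frame(protein_id = "helix10", chain = "A",
                     position = c(3L, 4L, 5L, 7L, 9L),
                     from_aa = c("D", "E", "F", "H", "K"),
                     to_aa = c("K", "A", "W", "Q", "M"),
                     ddg = c(-1.2, 0.3, 0.8, -0.7, 1.5),
                     provenance = "original", source = "s",
                     stringsAsFactors = FALSE)
  pred <- c(-1.0, 0.5, 0.6, -0.2, 1.2)
  out <- rsa_analysis(recs, pred, list(helix10 = s))
  expect_equal(sum(out$n), 5L)  # all five records fall in a bin and a class
  expect_true(all(out$aa_class %in% c("polar", "hydrophobic")))
  # a record on a missing structure is skipped with a warning
  recs2 <- recs; recs2$protein_id[1] <- "ghost"
  expect_warning(out2 <- rsa_analysis(recs2, pred, list(helix10 = s)),
                 "skipped")
  expect_equal(sum(out2$n), 4L)
})

test_that("free and buried residues land in extreme RSA bins", {
  free <- featurize_structure(make_helix_structure("A", id = "freeA", seed = 1))
  expect_gt(residue_rsa(free)$rsa, 0.5)
  # the middle residue of a long helix is the most buried
  long <- featurize_structure(make_helix_structure(strrep("L", 15), id = "lng",
                                                   seed = 1),
                              n_sphere_points = 240L)
  r <- residue_rsa(long)
  expect_lt(r$rsa[8], min(r$rsa[c(1, 15)]))
  expect_true(all(r$rsa <= 1))
})
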