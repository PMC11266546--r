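# Evaluation metrics oriented at stabilizing-mutation discovery: regression
# metrics are complemented by classification metrics because test sets are
# dominated by destabilizing mutations and correlation alone does not reward
# finding the rare stabilizing ones.

#' Three-way stability class of a ddG value
#'
#' Stabilizing below -0.5 kcal/mol, destabilizing above +0.5 kcal/mol,
#' neutral in between (boundaries inclusive: |ddg| <= 0.5 is neutral). The
#' +/-0.5 kcal/mol band reflects average experimental error.
#'
#' @param ddg numeric vector (kcal/mol).
#' @return factor with levels stabilizing, neutral, destabilizing.
#' @export
classify_ddg <- function(ddg) {
  stopifnot(all(is.finite(ddg)))
  factor(ifelse(ddg < -0.5, "stabilizing",
                ifelse(ddg > 0.5, "destabilizing", "neutral")),
         levels = c("stabilizing", "neutral", "destabilizing"))
}

#' Regression and stabilizing-classification metrics
#'
#' Pearson and Spearman correlation, RMSE, and binary classification metrics
#' for the stabilizing class, where a mutation counts as (predicted)
#' stabilizing iff its (predicted) ddG lies below `threshold`. AUROC scores
#' the stabilizing class with the negated prediction (more negative = higher
#' score). With a single experimental class, AUROC and MCC are `NA`
#' (undefined), not 0.
#'
#' @param predictions,experimental paired numeric vectors (kcal/mol).
#' @param threshold classification boundary (kcal/mol); default 0.
#' @return list of class `metric_report`: pearson, spearman, rmse, mcc,
#'   auroc, precision, recall, threshold, n.
#' @export
metric_suite <- function(predictions, experimental, threshold = 0) {
  stopifnot(length(predictions) == length(experimental),
            length(predictions) >= 2L)
  ok <- is.finite(predictions) & is.finite(experimental)
  p <- predictions[ok]; e <- experimental[ok]
  truth <- e < threshold
  pred_pos <- p < threshold
  tp <- sum(truth & pred_pos); fp <- sum(!truth & pred_pos)
  fn <- sum(truth & !pred_pos); tn <- sum(!truth & !pred_pos)
  mcc <- {
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    if (length(unique(truth)) < 2L || den == 0) NA_real_
    else (tp * tn - fp * fn) / den
  }
  auroc <- if (length(unique(truth)) < 2L) NA_real_ else {
    as.numeric(pROC::auc(pROC::roc(response = truth, predictor = -p,
                                   levels = c(FALSE, TRUE),
                                   direction = "<", quiet = TRUE)))
  }
  structure(list(
    pearson = stats::cor(p, e),
    spearman = stats::cor(p, e, method = "spearman"),
    rmse = sqrt(mean((p - e)^2)),
    mcc = mcc,
    auroc = auroc,
    precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
    recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    threshold = threshold,
    n = length(p)), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("metrics (n=", x$n, ", stabilizing threshold ", x$threshold,
      " kcal/mol):\n", sep = "")
  cat(sprintf("  pearson %.3f  spearman %.3f  rmse %.3f kcal/mol\n",
              x$pearson, x$spearman, x$rmse))
  cat(sprintf("  precision %.3f  recall %.3f  AUROC %s  MCC %s\n",
              x$precision, x$recall,
              ifelse(is.na(x$auroc), "NA", sprintf("%.3f", x$auroc)),
              ifelse(is.na(x$mcc), "NA", sprintf("%.3f", x$mcc))))
  invisible(x)
}

#' Composition of selected mutations across prediction thresholds
#'
#' For each threshold tau, restricts to mutations predicted below tau and
#' reports the fraction that are experimentally stabilizing / neutral /
#' destabilizing (per [classify_ddg()]) plus the recall of all experimental
#' stabilizers captured. Empty selections report count 0 and `NA` fractions.
#'
#' @param predictions,experimental paired numeric vectors (kcal/mol).
#' @param thresholds numeric thresholds (kcal/mol).
#' @return data.frame with one row per threshold.
#' @export
threshold_sweep <- function(predictions, experimental,
                            thresholds = c(-2, -1.5, -1, -0.5, 0)) {
  stopifnot(length(predictions) == length(experimental))
  cls <- classify_ddg(experimental)
  n_stab <- sum(cls == "stabilizing")
  out <- lapply(thresholds, function(tau) {
    sel <- predictions < tau
    n <- sum(sel)
    frac <- function(lv) if (n == 0) NA_real_ else mean(cls[sel] == lv)
    data.frame(threshold = tau, n_selected = n,
               frac_stabilizing = frac("stabilizing"),
               frac_neutral = frac("neutral"),
               frac_destabilizing = frac("destabilizing"),
               recall_stabilizing = if (n_stab == 0) NA_real_ else
                 sum(sel & cls == "stabilizing") / n_stab)
  })
  do.call(rbind, out)
}

#' Mutation-type matrix of a ddG record set
#'
#' Counts records per ordered (from, to) amino-acid pair over the 20 x 20
#' grid (diagonal structurally zero; 380 possible types) and reports the
#' coverage — the fraction of the 380 off-diagonal cells with at least one
#' record.
#'
#' @param records ddG records.
#' @param normalize return fractions instead of counts.
#' @return list of class `mutation_type_matrix` with `matrix` (20 x 20) and
#'   `coverage`.
#' @export
mutation_type_matrix <- function(records, normalize = FALSE) {
  records <- as_ddg_records(records)
  m <- matrix(0, 20, 20, dimnames = list(from = AA_ORDER, to = AA_ORDER))
  tab <- table(factor(records$from_aa, AA_ORDER), factor(records$to_aa, AA_ORDER))
  m[] <- as.numeric(tab)
  stopifnot(all(diag(m) == 0))
  coverage <- sum(m > 0) / 380
  if (normalize && sum(m) > 0) m <- m / sum(m)
  structure(list(matrix = m, coverage = coverage, n = nrow(records)),
            class = "mutation_type_matrix")
}

#' @export
print.mutation_type_matrix <- function(x, ...) {
  cat("mutation-type matrix: ", x$n, " records covering ",
      round(100 * x$coverage, 1), "% of the 380 types\n", sep = "")
  invisible(x)
}

#' RSA-stratified precision/recall for polar vs hydrophobic mutations
#'
#' Bins records by the relative solvent accessibility of the wild-type
#' residue (residue SASA over the per-AA theoretical maximum, capped at 1)
#' and reports stabilizing precision and recall per bin for mutations whose
#' wild-type residue is polar (S,T,N,Q,D,E,R,K,H,Y) vs hydrophobic
#' (L,M,I,V,F,W,A); G, C and P belong to neither class and are excluded.
#'
#' @param records ddG records with paired predictions.
#' @param predictions numeric predictions aligned with `records`.
#' @param structures named list of featurized structures (SASA computed).
#' @param bins upper RSA bin edges; default `c(0.05, 0.25, 0.5, 1)`.
#' @param threshold stabilizing boundary (kcal/mol); default 0.
#' @return data.frame: bin, aa_class, n, precision, recall.
#' @export
rsa_analysis <- function(records, predictions, structures,
                         bins = c(0.05, 0.25, 0.5, 1), threshold = 0) {
  records <- as_ddg_records(records)
  stopifnot(length(predictions) == nrow(records))
  rsa_tabs <- lapply(structures, residue_rsa)
  rsa <- rep(NA_real_, nrow(records))
  for (i in seq_len(nrow(records))) {
    tab <- rsa_tabs[[records$protein_id[i]]]
    if (is.null(tab)) next
    j <- which(tab$chain_id == records$chain[i] &
                 tab$residue_number == records$position[i])
    if (length(j) == 1L) rsa[i] <- tab$rsa[j]
  }
  if (any(is.na(rsa))) {
    warning(sum(is.na(rsa)), " record(s) without a resolvable structure/residue skipped")
  }
  cls <- ifelse(records$from_aa %in% POLAR_AA, "polar",
                ifelse(records$from_aa %in% HYDROPHOBIC_AA, "hydrophobic", NA))
  keep <- !is.na(rsa) & !is.na(cls)
  bin_id <- findInterval(rsa, c(-Inf, bins), left.open = TRUE)
  bin_lab <- paste0("(", c(0, utils::head(bins, -1)), ",", bins, "]")
  out <- expand.grid(bin = bin_lab, aa_class = c("polar", "hydrophobic"),
                     stringsAsFactors = FALSE)
  out$n <- 0L; out$precision <- NA_real_; out$recall <- NA_real_
  for (r in seq_len(nrow(out))) {
    sel <- keep & bin_lab[pmin(bin_id, length(bin_lab))] == out$bin[r] &
      cls == out$aa_class[r]
    out$n[r] <- sum(sel)
    if (out$n[r] == 0L) next
    truth <- records$ddg[sel] < threshold
    pred <- predictions[sel] < threshold
    tp <- sum(truth & pred)
    out$precision[r] <- if (sum(pred) == 0) NA_real_ else tp / sum(pred)
    out$recall[r] <- if (sum(truth) == 0) NA_real_ else tp / sum(truth)
  }
  attr(out, "threshold") <- threshold
  out
}
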