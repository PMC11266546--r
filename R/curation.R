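# Leakage-aware dataset assembly: any training protein whose sequence
# identity to a test protein reaches 30% is removed, a threshold inside the
# "twilight zone" below which most protein pairs adopt different folds.

#' Global sequence identity between two protein sequences
#'
#' Needleman-Wunsch global alignment with BLOSUM62 and affine gap penalties
#' (open 11, extend 1); identity is the number of identical aligned positions
#' divided by the alignment length (gaps included).
#'
#' @param seq_a,seq_b amino-acid sequence strings.
#' @return identity fraction in `[0, 1]`.
#' @export
sequence_identity <- function(seq_a, seq_b) {
  if (nchar(seq_a) == 0L || nchar(seq_b) == 0L) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
  Biostrings::pid(aln, type = "PID1") / 100
}

max_identity_to_reference <- function(seq, ref_seqs) {
  if (length(ref_seqs) == 0L) return(0)
  max(vapply(ref_seqs, function(r) sequence_identity(seq, r), numeric(1)))
}

mmseqs_available <- function() nzchar(Sys.which("mmseqs"))

# external-clusterer backend: MMseqs2 easy-search with the exact flags used
# for the reference pipeline; returns candidate ids hitting the reference at
# or above the identity threshold
mmseqs_hits <- function(cand_seqs, ref_seqs, threshold) {
  td <- tempfile("mmseqs")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  qf <- file.path(td, "query.fasta"); tf <- file.path(td, "target.fasta")
  write_fasta(cand_seqs, qf); write_fasta(ref_seqs, tf)
  out <- file.path(td, "hits.m8")
  status <- system2("mmseqs",
                    c("easy-search", qf, tf, out, file.path(td, "tmp"),
                      "-c", "0.3", "-s", "7.5", "--seq-id-mode", "1"),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("mmseqs easy-search failed with status ", status)
  hits <- utils::read.table(out, sep = "\t", stringsAsFactors = FALSE)
  unique(hits[[1]][hits[[3]] >= threshold])
}

#' Remove candidate proteins homologous to a reference set
#'
#' Every candidate protein whose maximum sequence identity to any reference
#' protein is at or above `threshold` is removed together with its records.
#' The backend is MMseqs2 (`easy-search -c 0.3 -s 7.5 --seq-id-mode 1`) when
#' a binary is on the PATH, and the built-in global aligner
#' ([sequence_identity()]) otherwise; the backend used is recorded in the
#' report. Note the two backends can differ for short-overlap homologs
#' (MMseqs2's coverage mode vs global identity).
#'
#' @param records candidate ddG records.
#' @param sequences named character vector of candidate protein sequences
#'   (names = protein_id).
#' @param ref_sequences named character vector of reference (test) sequences.
#' @param threshold identity threshold; default 0.30.
#' @param backend `"auto"`, `"builtin"` or `"mmseqs"`.
#' @return list with `records` (filtered), `removed_proteins`, `report`
#'   (backend, per-protein max identity for removed entries).
#' @export
homology_filter <- function(records, sequences, ref_sequences,
                            threshold = 0.30, backend = "auto") {
  records <- as_ddg_records(records)
  prot <- unique(records$protein_id)
  missing <- setdiff(prot, names(sequences))
  if (length(missing) > 0L) {
    stop("missing sequence(s) for protein(s): ", paste(missing, collapse = ", "))
  }
  backend <- match.arg(backend, c("auto", "builtin", "mmseqs"))
  if (backend == "auto") backend <- if (mmseqs_available()) "mmseqs" else "builtin"
  if (length(ref_sequences) == 0L) {
    return(list(records = records, removed_proteins = character(0),
                report = list(backend = backend, threshold = threshold,
                              max_identity = stats::setNames(numeric(0), character(0)))))
  }
  if (backend == "mmseqs") {
    removed <- mmseqs_hits(sequences[prot], ref_sequences, threshold)
    ids <- stats::setNames(rep(NA_real_, length(removed)), removed)
  } else {
    ids <- vapply(prot, function(p)
      max_identity_to_reference(sequences[[p]], ref_sequences), numeric(1))
    removed <- prot[ids >= threshold]
    ids <- ids[order(-ids)]
  }
  list(records = records[!(records$protein_id %in% removed), ],
       removed_proteins = removed,
       report = list(backend = backend, threshold = threshold,
                     max_identity = ids))
}

#' Assemble a leakage-free training set
#'
#' Concatenates the source tables, resolves duplicates by maximum absolute
#' ddG, and removes proteins homologous to the reference test set at the
#' identity threshold. Stage counts are logged in the returned report.
#'
#' @param sources list of ddG record data.frames.
#' @param sequences named candidate sequences (all source proteins).
#' @param ref_records reference (test) ddG records.
#' @param ref_sequences named reference sequences.
#' @param threshold identity threshold; default 0.30.
#' @param backend see [homology_filter()].
#' @return list of class `dataset_split` with `train`, `test`,
#'   `similarity_report` and `stage_counts`.
#' @export
assemble_training_set <- function(sources, sequences, ref_records,
                                  ref_sequences, threshold = 0.30,
                                  backend = "auto") {
  stopifnot(is.list(sources), length(sources) >= 1L)
  concat <- do.call(rbind, lapply(sources, as_ddg_records))
  rownames(concat) <- NULL
  dedup <- dedup_max_abs(concat)
  hf <- homology_filter(dedup, sequences, ref_sequences, threshold, backend)
  structure(list(train = hf$records,
                 test = as_ddg_records(ref_records),
                 similarity_report = hf$report,
                 removed_proteins = hf$removed_proteins,
                 stage_counts = c(concatenated = nrow(concat),
                                  deduplicated = nrow(dedup),
                                  homology_filtered = nrow(hf$records))),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat("dataset_split: ", nrow(x$train), " train / ", nrow(x$test),
      " test records\n  stages: ",
      paste(names(x$stage_counts), x$stage_counts, sep = "=", collapse = " -> "),
      "\n  homology backend: ", x$similarity_report$backend,
      " (threshold ", x$similarity_report$threshold, "), ",
      length(x$removed_proteins), " protein(s) removed\n", sep = "")
  invisible(x)
}

#' Audit the cross-split identity barrier
#'
#' Recomputes all pairwise train-vs-test identities with the built-in
#' aligner (backend-independent) and reports the maximum.
#'
#' @param split a `dataset_split`.
#' @param sequences named sequences covering all train proteins.
#' @param ref_sequences named sequences covering all test proteins.
#' @return list with `max_identity`, `worst_pair`, and the full matrix.
#' @export
audit_split <- function(split, sequences, ref_sequences) {
  train_prot <- unique(split$train$protein_id)
  m <- matrix(0, length(train_prot), length(ref_sequences),
              dimnames = list(train_prot, names(ref_sequences)))
  for (p in train_prot) {
    for (r in names(ref_sequences)) {
      m[p, r] <- sequence_identity(sequences[[p]], ref_sequences[[r]])
    }
  }
  wi <- which(m == max(m), arr.ind = TRUE)[1, , drop = FALSE]
  list(max_identity = max(m),
       worst_pair = c(rownames(m)[wi[1]], colnames(m)[wi[2]]),
       identities = m)
}

#' Filter a cDNA-proteolysis-style stability table
#'
#' Keeps natural (non-de-novo) domains, single-substitution mutations (e.g.
#' `A10V`; multi-mutant strings like `A10V:G20S` and indels are dropped), and
#' rows with a wild-type structure PDB id; then removes proteins homologous
#' to the reference set.
#'
#' @param table data.frame with columns `protein_id`, `domain_class`
#'   (`"natural"` / `"de novo"`), `mutation`, `wt_pdb`, `ddg`, and optionally
#'   `chain`.
#' @param ref_sequences reference sequences for the homology filter (omit to
#'   skip filtering).
#' @param sequences candidate sequences (required with `ref_sequences`).
#' @param threshold identity threshold; default 0.30.
#' @return validated ddG records.
#' @export
filter_cdna_subset <- function(table, ref_sequences = NULL, sequences = NULL,
                               threshold = 0.30) {
  req <- c("protein_id", "domain_class", "mutation", "wt_pdb", "ddg")
  missing <- setdiff(req, names(table))
  if (length(missing) > 0L) {
    stop("cDNA table lacks column(s): ", paste(missing, collapse = ", "))
  }
  t1 <- table[tolower(table$domain_class) %in% c("natural"), , drop = FALSE]
  single <- grepl("^[A-Z][0-9]+[A-Z]$", t1$mutation)
  t2 <- t1[single, , drop = FALSE]
  t3 <- t2[!is.na(t2$wt_pdb) & t2$wt_pdb != "", , drop = FALSE]
  if (nrow(t3) == 0L) return(as_ddg_records(t3[, 0])[0, ])
  recs <- data.frame(
    protein_id = t3$protein_id,
    pdb_id = t3$wt_pdb,
    chain = if ("chain" %in% names(t3)) t3$chain else "A",
    position = as.integer(gsub("[A-Z]", "", t3$mutation)),
    from_aa = substr(t3$mutation, 1, 1),
    to_aa = substring(t3$mutation, nchar(t3$mutation)),
    ddg = t3$ddg,
    provenance = "original",
    source = "cdna",
    stringsAsFactors = FALSE)
  recs <- as_ddg_records(recs)
  if (!is.null(ref_sequences)) {
    recs <- homology_filter(recs, sequences, ref_sequences, threshold)$records
  }
  recs
}
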