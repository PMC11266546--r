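# Thermodynamic augmentation of ddG tables. Both techniques exploit Gibbs
# free energy being a state function: reversibility (TR) swaps from/to and
# negates ddG; permutation (TP) combines the n measurements characterised at
# one position into all n(n-1) ordered mutations among the non-wild-type
# amino acids, ddG(ai -> aj) = ddG(wt -> aj) - ddG(wt -> ai).

DDG_COLUMNS <- c("protein_id", "pdb_id", "chain", "position", "from_aa",
                 "to_aa", "ddg", "provenance", "source")

#' Validate (and normalise) a ddG record table
#'
#' Checks the schema, coerces AA codes to one-letter, and verifies that
#' from != to and ddg is finite.
#'
#' @param records data.frame with the ddG record columns (`pdb_id` and
#'   `source` optional).
#' @return the normalised data.frame.
#' @export
as_ddg_records <- function(records) {
  if (!"pdb_id" %in% names(records)) records$pdb_id <- NA_character_
  if (!"source" %in% names(records)) records$source <- "unknown"
  if (!"provenance" %in% names(records)) records$provenance <- "original"
  missing <- setdiff(DDG_COLUMNS, names(records))
  if (length(missing) > 0L) {
    stop("ddG table lacks column(s): ", paste(missing, collapse = ", "))
  }
  records <- records[, DDG_COLUMNS]
  records$from_aa <- aa_to_one(records$from_aa)
  records$to_aa <- aa_to_one(records$to_aa)
  if (any(records$from_aa == records$to_aa)) {
    stop("record(s) with from_aa == to_aa are not mutations")
  }
  if (any(!is.finite(records$ddg))) stop("non-finite ddg value(s)")
  if (!all(records$provenance %in% c("original", "TP", "TR"))) {
    stop("provenance must be one of original, TP, TR")
  }
  records
}

position_key <- function(records) {
  chain <- records$chain
  if (any(is.na(chain) | chain == "")) {
    warning("record(s) lacking a chain id: falling back to protein-wide ",
            "position keys")
    chain[is.na(chain) | chain == ""] <- "*"
  }
  paste(records$protein_id, chain, records$position, sep = "\r")
}

#' Thermodynamic reversibility (TR) augmentation of records
#'
#' Swaps the wild-type and mutant amino acids and negates the ddG; the
#' operation is an involution on (from, to, ddg).
#'
#' @param records original ddG records.
#' @return data.frame of TR records, one per input.
#' @export
reverse_records <- function(records) {
  records <- as_ddg_records(records)
  if (!all(records$provenance == "original")) {
    stop("TR applies to original records only")
  }
  out <- records
  out$from_aa <- records$to_aa
  out$to_aa <- records$from_aa
  out$ddg <- -records$ddg
  out$provenance <- "TR"
  out
}

#' Thermodynamic permutations (TP) at one position
#'
#' Given the n deduplicated measurements wt -> a_i at a single (protein,
#' chain, position) with a common wild type, emits all n(n-1) ordered
#' mutations a_i -> a_j with ddg_j - ddg_i. No output involves the wild-type
#' amino acid on either side.
#'
#' @param records original records at one position (distinct `to_aa`).
#' @return data.frame of TP records (empty for n = 1).
#' @export
permute_position <- function(records) {
  records <- as_ddg_records(records)
  if (!all(records$provenance == "original")) {
    stop("TP applies to original records only")
  }
  if (length(unique(position_key(records))) != 1L) {
    stop("permute_position() expects records at a single position")
  }
  if (length(unique(records$from_aa)) != 1L) {
    stop("conflicting wild-type amino acids at one position: ",
         paste(unique(records$from_aa), collapse = ", "),
         "; a single reference state is required")
  }
  if (anyDuplicated(records$to_aa)) {
    stop("duplicate mutant amino acids at one position; run dedup_max_abs() first")
  }
  n <- nrow(records)
  if (n < 2L) return(records[0, ])
  ij <- expand.grid(i = seq_len(n), j = seq_len(n))
  ij <- ij[ij$i != ij$j, ]
  out <- records[ij$i, ]
  out$from_aa <- records$to_aa[ij$i]
  out$to_aa <- records$to_aa[ij$j]
  out$ddg <- records$ddg[ij$j] - records$ddg[ij$i]
  out$provenance <- "TP"
  rownames(out) <- NULL
  out
}

#' Resolve duplicate measurements by maximum absolute ddG
#'
#' Groups with identical (protein, chain, position, from, to) collapse to the
#' member with the largest `|ddg|`; exact ties keep the first in input order
#' (stable). Idempotent.
#'
#' @param records ddG records.
#' @return deduplicated records in input order.
#' @export
dedup_max_abs <- function(records) {
  records <- as_ddg_records(records)
  key <- paste(position_key(records), records$from_aa, records$to_aa)
  ord <- order(-abs(records$ddg), seq_len(nrow(records)))
  keep <- sort(ord[!duplicated(key[ord])])
  out <- records[keep, ]
  rownames(out) <- NULL
  out
}

#' Augment a deduplicated ddG dataset with TP and/or TR records
#'
#' Applies [permute_position()] per position and/or [reverse_records()],
#' drops generated records that collide with an existing experimental
#' measurement (originals win), and reports per-provenance counts.
#'
#' @param records deduplicated original records.
#' @param tp,tr which augmentations to generate.
#' @return list with `records` (original + augmentations) and `report`
#'   (counts: original, TP, TR, collisions_dropped, total).
#' @export
augment_dataset <- function(records, tp = TRUE, tr = FALSE) {
  records <- as_ddg_records(records)
  if (!all(records$provenance == "original")) {
    stop("augment_dataset() expects original records")
  }
  key <- position_key(records)
  gen <- list()
  if (tp) {
    gen$TP <- do.call(rbind, lapply(split(records, key), permute_position))
  }
  if (tr) {
    gen$TR <- reverse_records(records)
  }
  gen <- do.call(rbind, gen)
  n_coll <- 0L
  if (!is.null(gen) && nrow(gen) > 0L) {
    rownames(gen) <- NULL
    mut_key <- function(r) paste(position_key(r), r$from_aa, r$to_aa)
    coll <- mut_key(gen) %in% mut_key(records)
    n_coll <- sum(coll)
    gen <- gen[!coll, ]
  }
  out <- rbind(records, gen)
  rownames(out) <- NULL
  report <- c(original = nrow(records),
              TP = sum(out$provenance == "TP"),
              TR = sum(out$provenance == "TR"),
              collisions_dropped = n_coll,
              total = nrow(out))
  list(records = out, report = report)
}

#' Read / write ddG record CSV files
#'
#' The documented schema: `protein_id, pdb_id, chain, position, from_aa,
#' to_aa, ddg, provenance, source`; ddG in kcal/mol, positive destabilizing.
#'
#' @param path CSV path.
#' @return data.frame of validated records.
#' @export
read_ddg_csv <- function(path) {
  as_ddg_records(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_ddg_csv
#' @param records records to write.
#' @export
write_ddg_csv <- function(records, path) {
  utils::write.csv(as_ddg_records(records), path, row.names = FALSE)
  invisible(path)
}
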