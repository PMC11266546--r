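#' Parse a protein structure from a PDB file
#'
#' Reads ATOM/HETATM records into a `protein_structure` object: a data frame of
#' atom records (serial, name, element class, residue, chain, author residue
#' numbering with insertion codes, coordinates in Angstrom, occupancy) plus
#' per-atom physical feature columns (`partial_charge`, `sasa`) initialised to
#' `NA` until [assign_partial_charges()] and [compute_sasa()] are run.
#'
#' Alternate locations are resolved to the conformer with the highest
#' occupancy (ties keep the first in file order). Waters are excluded by
#' default; other hetero atoms are retained unless `keep_hetero = FALSE`.
#' Hydrogens are kept if present in the file and never added.
#'
#' @param path path to a PDB file.
#' @param model_index 1-based model to extract from multi-model files.
#' @param keep_hetero keep non-water HETATM records? Default `TRUE`.
#' @param keep_waters keep water molecules? Default `FALSE`.
#' @return an object of class `protein_structure`.
#' @export
parse_structure <- function(path, model_index = 1L, keep_hetero = TRUE,
                            keep_waters = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e)))
  n_models <- nrow(pdb$xyz)
  if (is.null(n_models) || n_models < 1L || nrow(pdb$atom) == 0L) {
    stop("no atoms parsed from '", path, "'")
  }
  if (model_index < 1L || model_index > n_models) {
    stop("model ", model_index, " not present (file has ", n_models, " model",
         if (n_models > 1L) "s", ")")
  }
  at <- pdb$atom
  xyz <- matrix(pdb$xyz[model_index, ], ncol = 3L, byrow = TRUE)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]

  if (!keep_waters) at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), ]
  if (!keep_hetero) at <- at[at$type == "ATOM", ]
  if (nrow(at) == 0L) stop("model ", model_index, " of '", path,
                           "' contains no atoms after filtering")

  # altloc resolution: highest occupancy wins, first-in-file breaks ties
  ins <- ifelse(is.na(at$insert) | at$insert == "", "", at$insert)
  key <- paste(at$chain, at$resno, ins, at$resid, at$elety, sep = "\r")
  occ <- ifelse(is.na(at$o), 1, at$o)
  ord <- order(-occ, seq_len(nrow(at)))
  keep <- ord[!duplicated(key[ord])]
  at <- at[sort(keep), ]
  ins <- ins[sort(keep)]

  elem <- at$elesy
  if (is.null(elem)) elem <- rep(NA_character_, nrow(at))
  miss <- is.na(elem) | trimws(elem) == ""
  elem[miss] <- substr(gsub("[^A-Za-z].*", "", at$elety[miss]), 1, 1)

  atoms <- data.frame(
    serial = at$eleno,
    atom_name = at$elety,
    element = element_class(elem),
    residue_name = at$resid,
    chain_id = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    residue_number = at$resno,
    insert = ins,
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    is_hetero = at$type != "ATOM",
    partial_charge = NA_real_,
    sasa = NA_real_,
    stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in '", path, "'")
  }
  new_protein_structure(atoms,
                        id = sub("\\.(pdb|ent)(\\.gz)?$", "",
                                 basename(path), ignore.case = TRUE))
}

new_protein_structure <- function(atoms, id = "structure", resolution = NA_real_) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1L)
  structure(list(atoms = atoms, id = id, resolution = resolution),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  res <- unique(x$atoms[, c("chain_id", "residue_number", "insert")])
  cat("protein_structure '", x$id, "': ", nrow(x$atoms), " atoms, ",
      nrow(res), " residues, ", length(unique(x$atoms$chain_id)),
      " chain(s)\n", sep = "")
  invisible(x)
}

atom_coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Write a structure back to PDB format
#'
#' @param structure a `protein_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  a <- structure$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = ifelse(a$is_hetero, "HETATM", "ATOM"),
                   resno = a$residue_number, resid = a$residue_name,
                   eleno = a$serial, elety = a$atom_name,
                   chain = a$chain_id, insert = ifelse(a$insert == "", NA, a$insert),
                   o = a$occupancy, b = rep(0, nrow(a)))
  invisible(path)
}

#' Per-chain amino-acid sequences of a structure
#'
#' Derives one-letter sequences from residue names in author numbering order;
#' non-standard residues become `X`. Hetero-only "residues" (ligands) are
#' skipped.
#'
#' @param structure a `protein_structure`.
#' @return named character vector, one sequence per chain.
#' @export
structure_sequences <- function(structure) {
  a <- structure$atoms[!structure$atoms$is_hetero, , drop = FALSE]
  if (nrow(a) == 0L) return(character(0))
  out <- vapply(split(a, a$chain_id), function(ch) {
    res <- ch[!duplicated(paste(ch$residue_number, ch$insert)), ]
    res <- res[order(res$residue_number, res$insert), ]
    one <- AA_ONE[res$residue_name]
    paste(ifelse(is.na(one), "X", one), collapse = "")
  }, character(1))
  out
}

#' Write per-chain sequences to a FASTA file
#'
#' @param sequences named character vector (names become record ids), or a
#'   `protein_structure` whose chain sequences are exported as `id_chain`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (inherits(sequences, "protein_structure")) {
    seqs <- structure_sequences(sequences)
    names(seqs) <- paste(sequences$id, names(seqs), sep = "_")
    sequences <- seqs
  }
  stopifnot(length(sequences) >= 1L, !is.null(names(sequences)))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}

#' Assign per-atom partial charges from a lookup table
#'
#' Every atom receives the charge tabulated for its (residue name, atom name)
#' pair; atoms absent from the table get 0.0 and are counted in a single
#' warning. The count is also stored as `attr(structure, "n_uncharged")`.
#'
#' @param structure a `protein_structure`.
#' @param charge_table data.frame with columns `residue_name`, `atom_name`,
#'   `charge`; defaults to [default_charge_table()].
#' @return the structure with `partial_charge` filled in.
#' @export
assign_partial_charges <- function(structure, charge_table = default_charge_table()) {
  stopifnot(all(c("residue_name", "atom_name", "charge") %in% names(charge_table)))
  key <- paste(charge_table$residue_name, charge_table$atom_name, sep = "\r")
  if (anyDuplicated(key)) stop("charge table has duplicate (residue, atom) entries")
  lookup <- stats::setNames(charge_table$charge, key)
  akey <- paste(structure$atoms$residue_name, trimws(structure$atoms$atom_name),
                sep = "\r")
  q <- unname(lookup[akey])
  n_missing <- sum(is.na(q))
  if (n_missing > 0L) {
    warning(n_missing, " atom(s) not in the charge table; assigned 0.0")
    q[is.na(q)] <- 0
  }
  structure$atoms$partial_charge <- q
  attr(structure, "n_uncharged") <- n_missing
  structure
}

# Deterministic golden-spiral unit sphere points (n x 3).
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom SASA in Angstrom^2 by the Shrake-Rupley rolling-probe method with
#' a deterministic golden-spiral point set, computed on the full structure
#' (features describe the native, unmasked environment). Radii come from a
#' bundled per-element van der Waals table.
#'
#' @param structure a `protein_structure`.
#' @param probe_radius probe (solvent) radius in Angstrom; default 1.4.
#' @param n_sphere_points test points per atom; default 960.
#' @param rotation optional 3x3 rotation applied to the point set (testing aid).
#' @return the structure with the `sasa` column filled in.
#' @export
compute_sasa <- function(structure, probe_radius = 1.4, n_sphere_points = 960L,
                         rotation = NULL) {
  xyz <- atom_coords(structure)
  n <- nrow(xyz)
  if (n == 0L) stop("structure has no atoms")
  pts <- golden_spiral_points(n_sphere_points)
  if (!is.null(rotation)) pts <- pts %*% t(rotation)
  radii <- unname(VDW_RADII[structure$atoms$element]) + probe_radius
  # neighbour lists from squared pairwise distances
  d2 <- as.matrix(stats::dist(xyz))^2
  sasa <- numeric(n)
  for (i in seq_len(n)) {
    ri <- radii[i]
    cand <- which(d2[i, ] < (ri + radii)^2 & seq_len(n) != i)
    if (length(cand) == 0L) {
      sasa[i] <- 4 * pi * ri^2
      next
    }
    p <- pts * ri
    p <- sweep(p, 2, xyz[i, ], "+")
    free <- rep(TRUE, n_sphere_points)
    for (j in cand) {
      if (!any(free)) break
      dj <- (p[free, 1] - xyz[j, 1])^2 + (p[free, 2] - xyz[j, 2])^2 +
        (p[free, 3] - xyz[j, 3])^2
      free[free] <- dj > radii[j]^2
    }
    sasa[i] <- 4 * pi * ri^2 * sum(free) / n_sphere_points
  }
  structure$atoms$sasa <- sasa
  structure
}

#' Per-residue SASA and relative solvent accessibility
#'
#' Sums atom SASA within each residue and normalises by the bundled
#' theoretical maximum for the residue's amino acid, capped at 1.
#'
#' @param structure a `protein_structure` with SASA computed.
#' @return data.frame with chain_id, residue_number, residue_name, sasa, rsa.
#' @export
residue_rsa <- function(structure) {
  a <- structure$atoms
  if (all(is.na(a$sasa))) stop("run compute_sasa() first")
  key <- paste(a$chain_id, a$residue_number, a$insert, sep = "\r")
  agg <- rowsum(a$sasa, key, reorder = FALSE)
  first <- !duplicated(key)
  res <- data.frame(chain_id = a$chain_id[first],
                    residue_number = a$residue_number[first],
                    residue_name = a$residue_name[first],
                    sasa = agg[, 1],
                    stringsAsFactors = FALSE)
  one <- AA_ONE[res$residue_name]
  res$rsa <- ifelse(is.na(one), NA_real_,
                    pmin(1, res$sasa / unname(MAX_SASA[one])))
  rownames(res) <- NULL
  res
}
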