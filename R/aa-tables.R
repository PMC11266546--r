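#' Amino-acid reference tables
#'
#' Canonical orderings, code conversions and bundled physical reference data
#' used across the package: van der Waals radii for solvent-accessibility
#' calculations, an AMBER-style partial-charge lookup, theoretical maximum
#' solvent accessibilities for RSA, and the polar / hydrophobic partition used
#' in surface-bias analyses.
#'
#' @name aa_tables
NULL

# Canonical 20-amino-acid ordering. Row order of the classifier output layer,
# of structural amino-acid embeddings, and of mutation-type matrices.
AA_ORDER <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA_THREE <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
              G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
              M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
              S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")

AA_ONE <- stats::setNames(names(AA_THREE), AA_THREE)

#' Convert amino-acid codes to the canonical one-letter alphabet
#'
#' Accepts one-letter or three-letter codes (any case) and returns upper-case
#' one-letter codes. Unknown codes raise an error.
#'
#' @param aa character vector of amino-acid codes.
#' @return character vector of one-letter codes.
#' @export
aa_to_one <- function(aa) {
  aa <- toupper(as.character(aa))
  out <- ifelse(nchar(aa) == 3, unname(AA_ONE[aa]), aa)
  bad <- is.na(out) | !(out %in% AA_ORDER)
  if (any(bad)) {
    stop("unknown amino-acid code(s): ", paste(unique(aa[bad]), collapse = ", "))
  }
  out
}

#' Index of an amino acid in the canonical 20-letter ordering
#' @param aa character vector of AA codes (1- or 3-letter).
#' @return integer vector in 1..20.
#' @export
aa_index <- function(aa) match(aa_to_one(aa), AA_ORDER)

# Element classes recognised by the model; everything else maps to "other".
ELEMENT_VOCAB <- c("C", "N", "O", "S", "P", "H", "other")

element_class <- function(element) {
  e <- toupper(trimws(element))
  e[!(e %in% c("C", "N", "O", "S", "P", "H"))] <- "other"
  e
}

# van der Waals radii (Angstrom) by element class, Bondi-style values.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               H = 1.20, other = 1.80)

# Theoretical maximum solvent accessibility per residue (Angstrom^2),
# Tien et al. (2013) theoretical values; used to normalise residue SASA to RSA.
MAX_SASA <- c(A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
              Q = 225.0, E = 223.0, G = 104.0, H = 224.0, I = 197.0,
              L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
              S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0)

# Polar / hydrophobic partition used in RSA-stratified analyses.
# G, C and P belong to neither class.
POLAR_AA <- c("S", "T", "N", "Q", "D", "E", "R", "K", "H", "Y")
HYDROPHOBIC_AA <- c("L", "M", "I", "V", "F", "W", "A")

# Kyte-Doolittle hydropathy, residue volume (A^3), net charge at pH 7 and a
# polarity flag; standardised columns are used by the synthetic planted task.
AA_PROPERTIES <- local({
  kd <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
          I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
          R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)
  vol <- c(A = 88.6, C = 108.5, D = 111.1, E = 138.4, F = 189.9, G = 60.1,
           H = 153.2, I = 166.7, K = 168.6, L = 166.7, M = 162.9, N = 114.1,
           P = 112.7, Q = 143.8, R = 173.4, S = 89.0, T = 116.1, V = 140.0,
           W = 227.8, Y = 193.6)
  chg <- c(A = 0, C = 0, D = -1, E = -1, F = 0, G = 0, H = 0.1, I = 0, K = 1,
           L = 0, M = 0, N = 0, P = 0, Q = 0, R = 1, S = 0, T = 0, V = 0,
           W = 0, Y = 0)
  pol <- as.numeric(AA_ORDER %in% POLAR_AA)
  m <- cbind(hydropathy = scale(kd[AA_ORDER])[, 1],
             volume = scale(vol[AA_ORDER])[, 1],
             charge = chg[AA_ORDER],
             polarity = pol - mean(pol))
  rownames(m) <- AA_ORDER
  m
})

#' Bundled AMBER-style partial-charge table
#'
#' A per-(residue, atom name) lookup of partial charges in elementary-charge
#' units. Backbone atoms carry AMBER ff94-style values shared across residues
#' (glycine and proline excepted where the topology differs); beta carbons get
#' residue-specific values. The table is deliberately compact: atoms absent
#' from it are assigned 0.0 by [assign_partial_charges()] and counted in the
#' warning summary. Swap in a full forcefield table via the `charge_table`
#' argument for production charges.
#'
#' @return data.frame with columns `residue_name`, `atom_name`, `charge`.
#' @export
default_charge_table <- function() {
  res <- unname(AA_THREE)
  # shared backbone values (ff94 generic)
  bb <- do.call(rbind, lapply(res, function(r) {
    data.frame(residue_name = r,
               atom_name = c("N", "H", "CA", "HA", "C", "O", "OXT"),
               charge = c(-0.4157, 0.2719, 0.0337, 0.0823, 0.5973, -0.5679, -0.8055),
               stringsAsFactors = FALSE)
  }))
  # glycine: no CB, distinct CA charge; proline: no amide H
  bb$charge[bb$residue_name == "GLY" & bb$atom_name == "CA"] <- -0.0252
  bb <- bb[!(bb$residue_name == "PRO" & bb$atom_name == "H"), ]
  cb_charge <- c(ALA = -0.1825, ARG = -0.0007, ASN = -0.2041, ASP = -0.0303,
                 CYS = -0.1231, GLN = -0.0036, GLU = 0.0560, HIS = -0.0462,
                 ILE = 0.1303, LEU = -0.1102, LYS = -0.0094, MET = 0.0342,
                 PHE = -0.0343, PRO = -0.0070, SER = 0.2117, THR = 0.3654,
                 TRP = -0.0050, TYR = -0.0014, VAL = 0.2985)
  cb <- data.frame(residue_name = names(cb_charge), atom_name = "CB",
                   charge = unname(cb_charge), stringsAsFactors = FALSE)
  rbind(bb, cb)
}
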