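#' Pairwise Euclidean distances between atom coordinates
#'
#' @param coords N x 3 matrix of coordinates in Angstrom.
#' @return N x N symmetric distance matrix with zero diagonal.
#' @export
pairwise_distances <- function(coords) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L, nrow(coords) >= 1L)
  as.matrix(stats::dist(coords))
}

#' First-contact-shell pooling mask
#'
#' Marks atoms whose distance to the (removed) target residue's C-alpha is at
#' most `cutoff` (closed ball: atoms exactly at the cutoff are included). The
#' final-layer states of these atoms are mean-pooled before classification.
#'
#' @param coords N x 3 coordinate matrix.
#' @param center length-3 center (the masked residue's C-alpha).
#' @param cutoff pooling radius in Angstrom; default 8.
#' @return logical vector of length N.
#' @export
pooling_mask <- function(coords, center, cutoff = 8.0) {
  stopifnot(cutoff > 0, length(center) == 3L)
  coords <- as.matrix(coords)
  d <- sqrt(colSums((t(coords) - as.numeric(center))^2))
  d <= cutoff
}

#' Build the masked microenvironment of a residue
#'
#' Removes every atom of the target residue, keeps all remaining atoms within
#' `radius` of the target's C-alpha (closed ball), and records the removed
#' residue's amino acid as the self-supervision label. Environments larger
#' than `max_tokens` are truncated by ascending distance to the center
#' (logged via a message).
#'
#' @param structure a `protein_structure` with charges and SASA assigned.
#' @param chain chain identifier.
#' @param residue_number author residue number.
#' @param radius environment radius in Angstrom; default 16.
#' @param pool_cutoff pooling-shell radius; default 8.
#' @param max_tokens token cap; default 512.
#' @return an object of class `microenv` with fields `center`, `elements`
#'   (integer codes into the element vocabulary), `phys` (N x 2: partial
#'   charge, SASA), `coords`, `D` (N x N distances), `pool_mask`, `label_aa`,
#'   and `meta`.
#' @export
build_masked_microenv <- function(structure, chain, residue_number,
                                  radius = 16.0, pool_cutoff = 8.0,
                                  max_tokens = 512L) {
  if (radius <= 0) stop("environment radius must be positive")
  a <- structure$atoms
  in_res <- a$chain_id == chain & a$residue_number == residue_number
  if (!any(in_res)) {
    stop("residue ", chain, ":", residue_number, " not found in structure '",
         structure$id, "'")
  }
  ca <- which(in_res & trimws(a$atom_name) == "CA")
  if (length(ca) == 0L) {
    stop("residue ", chain, ":", residue_number, " has no C-alpha atom")
  }
  center <- as.numeric(a[ca[1], c("x", "y", "z")])
  label <- AA_ONE[a$residue_name[ca[1]]]

  rest <- a[!in_res, , drop = FALSE]
  coords <- as.matrix(rest[, c("x", "y", "z")])
  d <- sqrt(colSums((t(coords) - center)^2))
  keep <- d <= radius
  if (!any(keep)) {
    stop("no atoms within ", radius, " A of residue ", chain, ":",
         residue_number, " (isolated residue)")
  }
  rest <- rest[keep, , drop = FALSE]
  d <- d[keep]
  if (nrow(rest) > max_tokens) {
    ord <- order(d)[seq_len(max_tokens)]
    message("microenvironment truncated from ", nrow(rest), " to ",
            max_tokens, " tokens by distance")
    rest <- rest[sort(ord), , drop = FALSE]
  }
  coords <- unname(as.matrix(rest[, c("x", "y", "z")]))
  phys <- cbind(partial_charge = rest$partial_charge, sasa = rest$sasa)
  structure(list(
    center = center,
    elements = match(rest$element, ELEMENT_VOCAB),
    phys = phys,
    coords = coords,
    D = pairwise_distances(coords),
    pool_mask = pooling_mask(coords, center, pool_cutoff),
    label_aa = if (is.na(label)) NULL else unname(label),
    meta = list(structure_id = structure$id, chain = chain,
                residue_number = residue_number, radius = radius,
                pool_cutoff = pool_cutoff)
  ), class = "microenv")
}

#' @export
print.microenv <- function(x, ...) {
  cat("microenv: ", nrow(x$coords), " atom tokens around ",
      x$meta$structure_id, " ", x$meta$chain, ":", x$meta$residue_number,
      " (radius ", x$meta$radius, " A, ", sum(x$pool_mask),
      " in pooling shell", if (!is.null(x$label_aa)) paste0(", label ", x$label_aa),
      ")\n", sep = "")
  invisible(x)
}

# internal validator used by property tests
validate_microenv <- function(env) {
  stopifnot(inherits(env, "microenv"),
            nrow(env$coords) >= 1L,
            nrow(env$coords) == length(env$elements),
            nrow(env$coords) == nrow(env$phys),
            isTRUE(all.equal(env$D, t(env$D))),
            all(diag(env$D) == 0))
  invisible(TRUE)
}
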