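# Deterministic generators for toy structures, ddG tables with the
# multi-measurement-per-position layout that thermodynamic permutation
# requires, a planted antisymmetric regression task, and toy pretraining
# microenvironments. Everything is bit-reproducible under its seed.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# internal-coordinate atom placement: position d with |c-d| = bond,
# angle(b,c,d) = angle and dihedral(a,b,c,d) = dihedral (degrees)
place_atom <- function(a, b, c_, bond, angle, dihedral) {
  angle <- angle * pi / 180
  dihedral <- dihedral * pi / 180
  bc <- c_ - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(angle),
          bond * sin(angle) * cos(dihedral),
          bond * sin(angle) * sin(dihedral))
  c_ + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Generate an ideal alpha-helix toy structure
#'
#' Builds a poly-peptide backbone with ideal helix dihedrals (phi = -57, psi =
#' -47 degrees, omega = 180) and standard bond geometry, a carbonyl oxygen per
#' residue, and one side-chain pseudo-atom (a carbon at the C-beta position)
#' for every residue except glycine. Optional Gaussian coordinate jitter
#' (seeded) perturbs the ideal geometry.
#'
#' @param sequence one-letter amino-acid string (or vector of codes).
#' @param id structure identifier.
#' @param chain chain identifier.
#' @param seed seed for the jitter stream.
#' @param jitter_sd coordinate jitter standard deviation in Angstrom
#'   (default 0 = ideal geometry).
#' @return a `protein_structure`.
#' @export
make_helix_structure <- function(sequence, id = "synthetic_helix", chain = "A",
                                 seed = 1L, jitter_sd = 0) {
  aa <- if (length(sequence) == 1L && nchar(sequence[1]) > 1L) {
    strsplit(sequence, "")[[1]]
  } else as.character(sequence)
  aa <- aa_to_one(aa)
  n <- length(aa)
  stopifnot(n >= 1L)
  phi <- -57; psi <- -47; omega <- 180

  rows <- list()
  add <- function(name, element, resno, resname, xyz) {
    rows[[length(rows) + 1L]] <<- data.frame(
      atom_name = name, element = element, residue_name = resname,
      residue_number = resno, x = xyz[1], y = xyz[2], z = xyz[3],
      stringsAsFactors = FALSE)
  }

  # first residue seeded explicitly
  N <- c(0, 0, 0)
  CA <- c(1.458, 0, 0)
  C <- CA + 1.525 * c(cos(pi - 111.2 * pi / 180), sin(pi - 111.2 * pi / 180), 0)
  prevN <- N; prevCA <- CA; prevC <- C
  for (i in seq_len(n)) {
    res3 <- AA_THREE[aa[i]]
    if (i > 1L) {
      N <- place_atom(prevN, prevCA, prevC, 1.329, 116.2, psi)
      CA <- place_atom(prevCA, prevC, N, 1.458, 121.7, omega)
      C <- place_atom(prevC, N, CA, 1.525, 111.2, phi)
    }
    O <- place_atom(N, CA, C, 1.231, 120.8, psi + 180)
    add("N", "N", i, res3, N)
    add("CA", "C", i, res3, CA)
    add("C", "C", i, res3, C)
    add("O", "O", i, res3, O)
    if (aa[i] != "G") {
      CB <- place_atom(N, C, CA, 1.521, 110.4, 122.5)
      add("CB", "C", i, res3, CB)
    }
    prevN <- N; prevCA <- CA; prevC <- C
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  atoms$chain_id <- chain
  atoms$insert <- ""
  atoms$occupancy <- 1
  atoms$is_hetero <- FALSE
  atoms$partial_charge <- NA_real_
  atoms$sasa <- NA_real_
  if (jitter_sd > 0) {
    jit <- with_seed(seed, matrix(stats::rnorm(3 * nrow(atoms), 0, jitter_sd),
                                  ncol = 3))
    atoms$x <- atoms$x + jit[, 1]
    atoms$y <- atoms$y + jit[, 2]
    atoms$z <- atoms$z + jit[, 3]
  }
  atoms <- atoms[, c("serial", "atom_name", "element", "residue_name",
                     "chain_id", "residue_number", "insert", "x", "y", "z",
                     "occupancy", "is_hetero", "partial_charge", "sasa")]
  new_protein_structure(atoms, id = id)
}

#' Attach physical features to a structure
#'
#' Convenience wrapper running [assign_partial_charges()] and
#' [compute_sasa()].
#'
#' @param structure a `protein_structure`.
#' @param charge_table charge lookup; default [default_charge_table()].
#' @param probe_radius,n_sphere_points passed to [compute_sasa()].
#' @return featurized `protein_structure`.
#' @export
featurize_structure <- function(structure, charge_table = default_charge_table(),
                                probe_radius = 1.4, n_sphere_points = 960L) {
  structure <- suppressWarnings(assign_partial_charges(structure, charge_table))
  compute_sasa(structure, probe_radius, n_sphere_points)
}

#' Generate a synthetic ddG table with TP-compatible layout
#'
#' Emulates the statistical structure of empirical stability tables: several
#' characterized mutant amino acids per position, and a destabilizing-skewed
#' ddG distribution. Each position carries a planted per-amino-acid potential
#' `g`; a measurement of wild-type wt to mutant a has
#' `ddg = (g[a] + native_bias) - g[wt] + noise`, so thermodynamic permutations
#' built from the table satisfy additivity exactly at zero noise (the native
#' bias cancels) while originals stay mostly destabilizing.
#'
#' @param structures list of `protein_structure` objects (or one structure).
#' @param plan data.frame with columns `structure_id`, `chain`, `position`,
#'   `n_mutants`; defaults to 3 mutants at every 3rd position of each
#'   structure.
#' @param g named 20-vector of per-AA potentials (kcal/mol); default drawn
#'   `N(0, 0.8)` under `seed`.
#' @param native_bias destabilizing offset (kcal/mol); default 1.0.
#' @param noise_sd measurement noise (kcal/mol); default 0.3, matching the
#'   +/-0.5 kcal/mol experimental-error convention.
#' @param seed RNG seed.
#' @return data.frame of ddG records (provenance `original`).
#' @export
make_ddg_table <- function(structures, plan = NULL, g = NULL,
                           native_bias = 1.0, noise_sd = 0.3, seed = 1L) {
  if (inherits(structures, "protein_structure")) structures <- list(structures)
  names(structures) <- vapply(structures, `[[`, "", "id")
  with_seed(seed, {
    if (is.null(g)) g <- stats::setNames(stats::rnorm(20, 0, 0.8), AA_ORDER)
    if (is.null(plan)) {
      plan <- do.call(rbind, lapply(structures, function(s) {
        seqs <- structure_sequences(s)
        pos <- seq(2, nchar(seqs[1]) - 1, by = 3)
        data.frame(structure_id = s$id, chain = names(seqs)[1], position = pos,
                   n_mutants = 3L, stringsAsFactors = FALSE)
      }))
    }
    recs <- lapply(seq_len(nrow(plan)), function(i) {
      s <- structures[[plan$structure_id[i]]]
      seqs <- structure_sequences(s)
      wt <- unname(substr(seqs[plan$chain[i]], plan$position[i], plan$position[i]))
      n_mut <- min(plan$n_mutants[i], 19L)
      mut <- sample(setdiff(AA_ORDER, wt), n_mut)
      data.frame(protein_id = s$id, pdb_id = s$id, chain = plan$chain[i],
                 position = plan$position[i], from_aa = wt, to_aa = mut,
                 ddg = unname((g[mut] + native_bias) - g[wt] +
                                stats::rnorm(n_mut, 0, noise_sd)),
                 provenance = "original", source = "synthetic",
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    out
  })
}

# standardized per-AA planted property embedding and the scalar channel used
# by the microenvironment-coupled term
planted_phi <- function() AA_PROPERTIES
planted_psi <- function() AA_PROPERTIES[, "volume"]

#' Generate the planted antisymmetric regression task
#'
#' Builds jittered helix structures and ddG records whose targets are, by
#' construction, antisymmetric in (from, to):
#' `ddg = w* . (phi(to) - phi(from)) + gamma * density(position) *
#' (psi(to) - psi(from)) + noise`, where `phi` is a fixed per-AA property
#' embedding, `psi` its volume channel, and `density` the standardised count
#' of atoms within 8 Angstrom of the position's C-alpha — a signal only
#' visible through the microenvironment. Train and test records come from
#' disjoint positions.
#'
#' @param n_structures number of toy structures.
#' @param n_residues residues per structure.
#' @param pairs_per_position mutation pairs sampled at each position.
#' @param gamma weight of the microenvironment-coupled term.
#' @param noise_sd target noise (kcal/mol).
#' @param test_frac fraction of positions held out.
#' @param seed RNG seed.
#' @return list with `structures` (featurized), `train`, `test` (ddG record
#'   data frames) and `truth` (the planted parameters).
#' @export
make_planted_task <- function(n_structures = 4L, n_residues = 24L,
                              pairs_per_position = 6L, gamma = 0.5,
                              noise_sd = 0.1, test_frac = 0.25, seed = 1L) {
  w_star <- c(hydropathy = 0.8, volume = 1.0, charge = 0.5, polarity = 0.3)
  phi <- planted_phi()
  psi <- planted_psi()
  with_seed(seed, {
    structures <- lapply(seq_len(n_structures), function(i) {
      seq_i <- paste(sample(AA_ORDER, n_residues, replace = TRUE), collapse = "")
      featurize_structure(
        make_helix_structure(seq_i, id = sprintf("planted_%02d", i),
                             seed = seed + i, jitter_sd = 0.3),
        n_sphere_points = 240L)
    })
    names(structures) <- vapply(structures, `[[`, "", "id")

    # density: atoms within 8 A of each position's C-alpha, standardised
    pos_tab <- do.call(rbind, lapply(structures, function(s) {
      a <- s$atoms
      ca <- a[trimws(a$atom_name) == "CA", ]
      dens <- vapply(seq_len(nrow(ca)), function(j) {
        sum(sqrt((a$x - ca$x[j])^2 + (a$y - ca$y[j])^2 + (a$z - ca$z[j])^2) <= 8)
      }, numeric(1))
      data.frame(structure_id = s$id, chain = ca$chain_id,
                 position = ca$residue_number,
                 wt = AA_ONE[ca$residue_name], density = dens,
                 stringsAsFactors = FALSE)
    }))
    pos_tab <- pos_tab[pos_tab$position > 1 & pos_tab$position < n_residues, ]
    pos_tab$density <- as.numeric(scale(pos_tab$density))

    recs <- do.call(rbind, lapply(seq_len(nrow(pos_tab)), function(i) {
      from <- sample(AA_ORDER, pairs_per_position, replace = TRUE)
      to <- vapply(from, function(f) sample(setdiff(AA_ORDER, f), 1), "")
      ddg <- drop((phi[to, , drop = FALSE] - phi[from, , drop = FALSE]) %*% w_star) +
        gamma * pos_tab$density[i] * (psi[to] - psi[from]) +
        stats::rnorm(pairs_per_position, 0, noise_sd)
      data.frame(protein_id = pos_tab$structure_id[i],
                 pdb_id = pos_tab$structure_id[i],
                 chain = pos_tab$chain[i], position = pos_tab$position[i],
                 from_aa = from, to_aa = to, ddg = unname(ddg),
                 provenance = "original", source = "planted",
                 stringsAsFactors = FALSE)
    }))
    rownames(recs) <- NULL

    pos_key <- paste(pos_tab$structure_id, pos_tab$position)
    test_pos <- sample(pos_key, ceiling(length(pos_key) * test_frac))
    rec_key <- paste(recs$protein_id, recs$position)
    list(structures = structures,
         train = recs[!(rec_key %in% test_pos), ],
         test = recs[rec_key %in% test_pos, ],
         truth = list(w = w_star, gamma = gamma, noise_sd = noise_sd))
  })
}

#' Generate toy pretraining microenvironments with a planted label signal
#'
#' Builds microenvironments directly: a random background atom cloud plus a
#' number of oxygen atoms in the pooling shell that deterministically encodes
#' the masked residue's identity (one of `classes`). A small backbone must
#' learn to count/compose pooled element features, which it does within a few
#' hundred steps.
#'
#' @param n_env number of environments.
#' @param classes amino-acid labels to plant; default A, S, L.
#' @param seed RNG seed.
#' @return list of `microenv` objects with `label_aa` set.
#' @export
make_pretrain_toy <- function(n_env = 150L, classes = c("A", "S", "L"),
                              seed = 1L) {
  n_signal <- stats::setNames(2L + 5L * (seq_along(classes) - 1L), classes)
  with_seed(seed, {
    lapply(seq_len(n_env), function(i) {
      lab <- classes[1 + (i - 1) %% length(classes)]
      nb <- 18L
      # background shell outside the pooling radius
      dir <- matrix(stats::rnorm(3 * nb), ncol = 3)
      dir <- dir / sqrt(rowSums(dir^2))
      bg <- dir * stats::runif(nb, 9, 14)
      # signal atoms inside the pooling shell
      ns <- n_signal[lab]
      dir_s <- matrix(stats::rnorm(3 * ns), ncol = 3)
      dir_s <- dir_s / sqrt(rowSums(dir_s^2))
      sig <- dir_s * stats::runif(ns, 3, 7)
      coords <- rbind(bg, sig)
      elements <- c(sample(match(c("C", "N"), ELEMENT_VOCAB), nb, replace = TRUE),
                    rep(match("O", ELEMENT_VOCAB), ns))
      phys <- cbind(stats::rnorm(nrow(coords), 0, 0.2),
                    stats::runif(nrow(coords), 0, 60))
      structure(list(
        center = c(0, 0, 0),
        elements = elements,
        phys = phys,
        coords = coords,
        D = pairwise_distances(coords),
        pool_mask = pooling_mask(coords, c(0, 0, 0), 8),
        label_aa = lab,
        meta = list(structure_id = sprintf("toy_%04d", i), chain = "A",
                    residue_number = i, radius = 16, pool_cutoff = 8)
      ), class = "microenv")
    })
  })
}
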