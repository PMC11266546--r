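# Shared fixtures, built once per test run. Heavier objects are memoised so
# individual test files stay cheap.

fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = fixture_cache)) {
    assign(name, force(expr), envir = fixture_cache)
  }
  get(name, envir = fixture_cache)
}

# a 10-residue featurized helix used across modules
fx_helix <- function() {
  memo("helix10", featurize_structure(
    make_helix_structure("ACDEFGHIKL", id = "helix10", seed = 1),
    n_sphere_points = 240L))
}

fx_env <- function() {
  memo("env5", build_masked_microenv(fx_helix(), "A", 5, radius = 16))
}

fx_model <- function() {
  memo("model_desk", init_ddg_model(desk_config(), seed = 42))
}

# a single-atom structure builder for SASA tests
atom_structure <- function(coords, element = "C") {
  coords <- matrix(coords, ncol = 3)
  mutstab:::new_protein_structure(data.frame(
    serial = seq_len(nrow(coords)), atom_name = element, element = element,
    residue_name = "ALA", chain_id = "A", residue_number = seq_len(nrow(coords)),
    insert = "", x = coords[, 1], y = coords[, 2], z = coords[, 3],
    occupancy = 1, is_hetero = FALSE, partial_charge = 0, sasa = NA_real_,
    stringsAsFactors = FALSE))
}

random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3))
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rotate_structure <- function(structure, R, shift = c(0, 0, 0)) {
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")]) %*% t(R)
  structure$atoms$x <- xyz[, 1] + shift[1]
  structure$atoms$y <- xyz[, 2] + shift[2]
  structure$atoms$z <- xyz[, 3] + shift[3]
  structure
}

rotate_env <- function(env, R, shift = c(0, 0, 0)) {
  env$coords <- sweep(env$coords %*% t(R), 2, shift, "+")
  env$center <- drop(R %*% env$center) + shift
  env$D <- pairwise_distances(env$coords)
  env
}

# tiny ddG fixture: 3 positions with 1, 2 and 3 measurements
fx_tp_records <- function() {
  data.frame(
    protein_id = "prot1", pdb_id = "prot1", chain = "A",
    position = c(5L, 7L, 7L, 9L, 9L, 9L),
    from_aa = c("A", "G", "G", "L", "L", "L"),
    to_aa = c("V", "W", "R", "A", "D", "F"),
    ddg = c(1.0, 2.0, -0.5, 0.3, 1.7, -1.1),
    provenance = "original", source = "fixture",
    stringsAsFactors = FALSE)
}
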