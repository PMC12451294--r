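# Shared in-code fixtures and independent oracles for the test-suite.

library(tibble)

# ---- small molecules ----

mol_benzene <- function() {
  ang <- 2 * pi * (0:5) / 6
  list(atoms = tibble(element = "C", x = 1.39 * cos(ang), y = 1.39 * sin(ang),
                      z = 0, charge = 0L),
       bonds = tibble(i = 1:6, j = c(2:6, 1L), order = c(1L, 2L, 1L, 2L, 1L, 2L)))
}

mol_methanol <- function() {
  list(atoms = tibble(element = c("C", "O"), x = c(0, 1.43), y = 0, z = 0,
                      charge = 0L),
       bonds = tibble(i = 1L, j = 2L, order = 1L))
}

# acetate anion CH3-COO(-): carboxylate group C2, O3, O4
mol_acetate <- function() {
  list(atoms = tibble(element = c("C", "C", "O", "O"),
                      x = c(-1.5, 0, 0.6, 0.6),
                      y = c(0, 0, 1.1, -1.1),
                      z = 0,
                      charge = c(0L, 0L, -1L, 0L)),
       bonds = tibble(i = c(1L, 2L, 2L), j = c(2L, 3L, 4L),
                      order = c(1L, 1L, 2L)))
}

mol_butane <- function() {
  list(atoms = tibble(element = "C", x = c(0, 1.53, 2.04, 3.57),
                      y = c(0, 0, 1.44, 1.44), z = 0, charge = 0L),
       bonds = tibble(i = 1:3, j = 2:4, order = 1L))
}

as_library <- function(mol, mol_id = "mol", conformer_id = 1L, active = NULL) {
  lib <- tibble(mol_id = mol_id, conformer_id = conformer_id,
                atoms = list(mol$atoms), bonds = list(mol$bonds))
  if (!is.null(active)) lib$active <- active
  lib
}

# ---- PDB text builders ----

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          element = substr(name, 1, 1)) {
  name_fmt <- if (nchar(name) < 4) sprintf(" %-3s", name) else
    sprintf("%-4s", name)
  sprintf("ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name_fmt, resname, chain, resno, x, y, z, 1.0, 0.0,
          toupper(element))
}

# A three-residue synthetic chain: ALA at origin, GLY at +15 x, SER at +30 x.
pdb_three_residues <- function() {
  lines <- c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 0.0, 0.0, 0.0),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.5, 0.0, 0.0),
    pdb_atom_line(3, "C", "ALA", "A", 1, 2.2, 1.3, 0.0),
    pdb_atom_line(4, "O", "ALA", "A", 1, 1.6, 2.4, 0.0),
    pdb_atom_line(5, "CB", "ALA", "A", 1, 2.3, -1.2, 0.7),
    pdb_atom_line(6, "N", "GLY", "A", 2, 15.0, 0.0, 0.0),
    pdb_atom_line(7, "CA", "GLY", "A", 2, 16.5, 0.0, 0.0),
    pdb_atom_line(8, "C", "GLY", "A", 2, 17.2, 1.3, 0.0),
    pdb_atom_line(9, "O", "GLY", "A", 2, 16.6, 2.4, 0.0),
    pdb_atom_line(10, "N", "SER", "A", 3, 30.0, 0.0, 0.0),
    pdb_atom_line(11, "CA", "SER", "A", 3, 31.5, 0.0, 0.0),
    pdb_atom_line(12, "OG", "SER", "A", 3, 32.2, 1.3, 0.0),
    "END")
  paste(lines, collapse = "\n")
}

# ---- independent oracles ----

# brute-force k nearest pocket atoms for each query point
oracle_knn <- function(query, pocket_xyz, k) {
  t(apply(phoregen:::cross_dist(query, pocket_xyz), 1, function(row)
    sort(order(row)[seq_len(k)])))
}

# exhaustive assignment enumeration + Kabsch for pharmacophore matching
oracle_match <- function(features, query, rmsd_tol = 1.0) {
  nq <- nrow(query)
  qpos <- as.matrix(query[, c("x", "y", "z")])
  fpos <- as.matrix(features[, c("x", "y", "z")])
  cand <- lapply(seq_len(nq), function(i) which(features$type == query$type[i]))
  best <- Inf
  rec <- function(i, used, assign_vec) {
    if (i > nq) {
      fit <- kabsch(fpos[assign_vec, , drop = FALSE], qpos)
      best <<- min(best, fit$rmsd)
      return(invisible(NULL))
    }
    for (f in cand[[i]]) {
      if (f %in% used) next
      rec(i + 1, c(used, f), c(assign_vec, f))
    }
    invisible(NULL)
  }
  rec(1, integer(0), integer(0))
  list(matched = is.finite(best) && best <= rmsd_tol, rmsd = best)
}

random_feature_set <- function(n, spread = 5) {
  tibble(type = sample(feature_types(), n, replace = TRUE),
         x = runif(n, -spread, spread), y = runif(n, -spread, spread),
         z = runif(n, -spread, spread))
}

rotate_pocket <- function(pocket, R, shift = c(0, 0, 0)) {
  xyz <- as.matrix(pocket[, c("x", "y", "z")]) %*% t(R)
  pocket$x <- xyz[, 1] + shift[1]
  pocket$y <- xyz[, 2] + shift[2]
  pocket$z <- xyz[, 3] + shift[3]
  pocket
}

tiny_config <- function() {
  denoiser_config(n_layers = 2L, ds = 16L, dv = 4L, n_rbf = 8L, T = 50L)
}
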