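# Synthetic fixtures with planted ground truth.
#
# The generators and the feature detectors are co-designed: every planted
# site is realised by a minimal residue template whose detected feature
# sits exactly at the planted position, and every ligand-side feature by
# a minimal molecular fragment. This gives every downstream module a
# known answer without any external dataset.

#' Fixture specification
#'
#' Study-condition defaults for the synthetic data: pockets carry 3-8
#' planted complementary sites (uniformly typed) inside a 6 Angstrom
#' ball with at least 3 Angstroms separation, wrapped in a neutral
#' 16-atom shell at 9 Angstroms; training pharmacophores sit at the
#' complementary positions with 0.3 Angstrom Gaussian jitter; screening
#' libraries hold 20 actives and 180 decoys with 3 conformers per
#' molecule.
#'
#' @param n_sites Planted sites per pocket; `NULL` draws uniformly from
#'   `site_range` per pocket.
#' @param site_range Range for random site counts (default `3:8`, the
#'   training-size convention).
#' @param site_radius,min_separation,shell_atoms,shell_radius Pocket
#'   geometry in Angstroms.
#' @param jitter_sd Gaussian jitter of training centers (Angstroms).
#' @param n_train Number of training pairs.
#' @param n_actives,n_decoys,conformers_per_molecule Library composition.
#' @param seed Master seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_sites = NULL, site_range = 3:8, site_radius = 6,
                         min_separation = 3, shell_atoms = 16L,
                         shell_radius = 9, jitter_sd = 0.3, n_train = 2000L,
                         n_actives = 20L, n_decoys = 180L,
                         conformers_per_molecule = 3L, seed = 1L) {
  structure(list(n_sites = n_sites, site_range = site_range,
                 site_radius = site_radius, min_separation = min_separation,
                 shell_atoms = shell_atoms, shell_radius = shell_radius,
                 jitter_sd = jitter_sd, n_train = n_train,
                 n_actives = n_actives, n_decoys = n_decoys,
                 conformers_per_molecule = conformers_per_molecule,
                 seed = seed), class = "fixture_spec")
}

# Sites in a ball with minimum separation (rejection sampling).
sample_sites <- function(n, radius, min_sep) {
  pts <- matrix(NA_real_, 0, 3)
  guard <- 0
  while (nrow(pts) < n) {
    guard <- guard + 1
    if (guard > 10000) abort("Could not place fixture sites; relax the spec.")
    p <- runif(3, -radius, radius)
    if (sqrt(sum(p^2)) > radius) next
    if (nrow(pts) > 0 && min(cross_dist(matrix(p, 1), pts)) < min_sep) next
    pts <- rbind(pts, p)
  }
  pts
}

# Minimal residue template realising one protein-side feature exactly at
# the origin; returns a tibble of atoms (element, x, y, z, resname,
# atom_name).
site_residue_template <- function(type) {
  tpl <- switch(type,
    HydrogenAcceptor = tibble(element = "O", x = 0, y = 0, z = 0,
                              resname = "GLY", atom_name = "O"),
    HydrogenDonor = tibble(element = "N", x = 0, y = 0, z = 0,
                           resname = "GLY", atom_name = "N"),
    NegativeIon = tibble(element = c("C", "O", "O"),
                         x = c(-0.8, 0.4, 0.4), y = c(0, 1.05, -1.05),
                         z = c(0, 0, 0), resname = "ASP",
                         atom_name = c("CG", "OD1", "OD2")),
    PositiveIon = tibble(element = c("N", "C", "C"),
                         x = c(0, 1.5, 2.9), y = c(0, 0, 0.5), z = c(0, 0, 0),
                         resname = "LYS", atom_name = c("NZ", "CE", "CD")),
    Aromatic = {
      ang <- 2 * pi * (0:5) / 6
      tibble(element = "C", x = 1.39 * cos(ang), y = 1.39 * sin(ang), z = 0,
             resname = "PHE",
             atom_name = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"))
    },
    Hydrophobic = tibble(element = "C",
                         x = 0.6 * c(0.9, -0.9, -0.9, 0.9),
                         y = 0.6 * c(0.9, -0.9, 0.9, -0.9),
                         z = 0.6 * c(0.9, 0.9, -0.9, -0.9),
                         resname = "LEU",
                         atom_name = c("CB", "CG", "CD1", "CD2")),
    abort(paste0("No residue template for type ", type)))
  tpl
}

#' Generate a toy pocket with planted complementary sites
#'
#' Builds a pocket whose [detect_pocket_features()] output equals the
#' planted site list exactly: each site is a minimal residue template
#' (randomly oriented) whose feature centroid is the planted position,
#' and the surrounding shell consists of feature-free CA-only glycines.
#'
#' @param spec A [fixture_spec()].
#' @param seed Integer seed (defaults to the spec's).
#' @return List with `pocket` (a `phg_pocket`) and `sites` (tibble
#'   `type`, `x`, `y`, `z` of protein-side features).
#' @export
make_toy_pocket <- function(spec = fixture_spec(), seed = spec$seed) {
  with_seed(seed, {
    n_sites <- spec$n_sites %||% sample(spec$site_range, 1L)
    pos <- sample_sites(n_sites, spec$site_radius, spec$min_separation)
    types <- sample(feature_types(), n_sites, replace = TRUE)
    el <- list(); xyz <- list(); rn <- list(); an <- list(); res <- list()
    for (i in seq_len(n_sites)) {
      tpl <- site_residue_template(types[i])
      rot <- random_rotation()
      el[[i]] <- tpl$element
      xyz[[i]] <- sweep(coord_matrix(tpl) %*% t(rot), 2, pos[i, ], `+`)
      rn[[i]] <- tpl$resname
      an[[i]] <- tpl$atom_name
      res[[i]] <- rep(i, nrow(tpl))
    }
    shell <- spec$shell_radius * fibonacci_sphere(spec$shell_atoms) %*%
      t(random_rotation())
    j <- n_sites + 1L
    el[[j]] <- rep("C", spec$shell_atoms)
    xyz[[j]] <- shell
    rn[[j]] <- rep("GLY", spec$shell_atoms)
    an[[j]] <- rep("CA", spec$shell_atoms)
    res[[j]] <- n_sites + seq_len(spec$shell_atoms)
    coords <- do.call(rbind, xyz)
    pocket <- new_pocket(tibble(
      element = unlist(el), x = coords[, 1], y = coords[, 2], z = coords[, 3],
      chain = "A", resno = as.integer(unlist(res)), resname = unlist(rn),
      atom_name = unlist(an)))
    sites <- tibble(type = types, x = pos[, 1], y = pos[, 2], z = pos[, 3])
    list(pocket = pocket, sites = sites)
  })
}

#' Generate training pairs with planted ground truth
#'
#' Each pair holds a toy pocket and a pharmacophore whose centers are the
#' complementary ligand-side features of the planted sites, displaced by
#' Gaussian jitter. At zero jitter every pair has validity exactly 1.
#'
#' @param spec A [fixture_spec()].
#' @param n Number of pairs (defaults to `spec$n_train`).
#' @param seed Master seed (defaults to the spec's).
#' @return Tibble with list-columns `pocket`, `pharmacophore`, `sites`.
#' @export
make_training_pairs <- function(spec = fixture_spec(), n = spec$n_train,
                                seed = spec$seed) {
  rows <- purrr::map(seq_len(n), function(i) {
    si <- substream_seed(seed, "train_pair", i)
    fx <- make_toy_pocket(spec, seed = si)
    ph <- with_seed(substream_seed(seed, "train_jitter", i), {
      jit <- matrix(rnorm(nrow(fx$sites) * 3, sd = spec$jitter_sd),
                    ncol = 3)
      pharmacophore(tibble(
        type = complement_type(fx$sites$type),
        x = fx$sites$x + jit[, 1],
        y = fx$sites$y + jit[, 2],
        z = fx$sites$z + jit[, 3]))
    })
    tibble(pocket = list(fx$pocket), pharmacophore = list(ph),
           sites = list(fx$sites))
  })
  bind_rows(rows)
}

# Minimal molecular fragment realising one ligand-side feature at the
# origin. Fragments are disconnected components within one SDF record.
feature_fragment <- function(type) {
  switch(type,
    HydrogenDonor = list(atoms = tibble(element = "O", x = 0, y = 0, z = 0,
                                        charge = 0L),
                         bonds = tibble(i = integer(), j = integer(),
                                        order = integer())),
    HydrogenAcceptor = list(
      atoms = tibble(element = c("O", "C", "C"), x = c(0, 1.4, -1.4),
                     y = c(0, 0.2, 0.2), z = 0, charge = 0L),
      bonds = tibble(i = c(1L, 1L), j = c(2L, 3L), order = c(1L, 1L))),
    Hydrophobic = list(
      atoms = tibble(element = "C", x = c(-1.2, 0, 1.2), y = c(-0.4, 0.8, -0.4),
                     z = 0, charge = 0L),
      bonds = tibble(i = c(1L, 2L), j = c(2L, 3L), order = c(1L, 1L))),
    Aromatic = {
      ang <- 2 * pi * (0:5) / 6
      list(atoms = tibble(element = "C", x = 1.39 * cos(ang),
                          y = 1.39 * sin(ang), z = 0, charge = 0L),
           bonds = tibble(i = 1:6, j = c(2:6, 1L), order = 4L))
    },
    PositiveIon = list(atoms = tibble(element = "N", x = 0, y = 0, z = 0,
                                      charge = 1L),
                       bonds = tibble(i = integer(), j = integer(),
                                      order = integer())),
    NegativeIon = list(
      atoms = tibble(element = c("C", "O", "O"), x = c(-0.8, 0.4, 0.4),
                     y = c(0, 1.05, -1.05), z = 0, charge = c(0L, 0L, -1L)),
      bonds = tibble(i = c(1L, 1L), j = c(2L, 3L), order = c(2L, 1L))),
    abort(paste0("No fragment for type ", type)))
}

# Assemble fragments (one per requested feature position) into a single
# conformer, applying a random rigid orientation per fragment.
assemble_fragments <- function(types, positions) {
  atoms <- list(); bonds <- list(); offset <- 0L
  for (i in seq_along(types)) {
    fr <- feature_fragment(types[i])
    xyz <- coord_matrix(fr$atoms) %*% t(random_rotation())
    xyz <- sweep(xyz, 2, positions[i, ], `+`)
    atoms[[i]] <- mutate(fr$atoms, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    if (nrow(fr$bonds) > 0) {
      bonds[[length(bonds) + 1]] <- mutate(fr$bonds, i = .data$i + offset,
                                           j = .data$j + offset)
    }
    offset <- offset + nrow(fr$atoms)
  }
  list(atoms = bind_rows(atoms),
       bonds = if (length(bonds)) bind_rows(bonds) else
         tibble(i = integer(), j = integer(), order = integer()))
}

#' Generate a toy screening library for a known pharmacophore
#'
#' Actives carry one conformer whose feature set embeds the truth
#' pharmacophore within 0.5 Angstroms (plus a distractor fragment), and
#' further conformers expanded about the centroid far beyond the match
#' tolerance. Decoys realise the same center positions (strongly
#' jittered) entirely with fragments of a feature type the query does
#' not use, so no type-consistent assignment to all query centers can
#' exist — they cannot match by construction, independent of the
#' matcher.
#'
#' @param spec A [fixture_spec()].
#' @param ph_truth The planted-truth pharmacophore the actives embed.
#' @param seed Master seed (defaults to the spec's).
#' @return A library tibble with an `active` label column.
#' @export
make_toy_library <- function(spec = fixture_spec(), ph_truth, seed = spec$seed) {
  ph_truth <- validate_pharmacophore(as_tibble(ph_truth))
  qpos <- ph_positions(ph_truth)
  centroid <- colMeans(qpos)
  decoy_type <- if (all(ph_truth$type == "Hydrophobic")) "Aromatic" else
    "Hydrophobic"
  rows <- list()
  for (a in seq_len(spec$n_actives)) {
    id <- sprintf("act_%03d", a)
    confs <- with_seed(substream_seed(seed, "active", a), {
      # one distractor fragment per molecule so every conformer has the
      # same atom count (a LigandRecord invariant)
      distractor <- sample(feature_types(), 1)
      far_dir <- rnorm(3); far_dir <- far_dir / sqrt(sum(far_dir^2))
      far <- centroid + far_dir * (max(cross_dist(matrix(centroid, 1),
                                                  qpos)) + 4)
      purrr::map(seq_len(spec$conformers_per_molecule), function(cf) {
        if (cf == 1) {
          jit <- matrix(rnorm(nrow(qpos) * 3), ncol = 3)
          jit <- jit / sqrt(rowSums(jit^2)) * runif(nrow(qpos), 0, 0.3)
          conf <- assemble_fragments(c(ph_truth$type, distractor),
                                     rbind(qpos + jit, far))
          rot <- random_rotation()
          shift <- runif(3, -2, 2)
          xyz <- sweep(coord_matrix(conf$atoms) %*% t(rot), 2, shift, `+`)
          conf$atoms <- mutate(conf$atoms, x = xyz[, 1], y = xyz[, 2],
                               z = xyz[, 3])
          conf
        } else {
          # expanded about the centroid: cannot match within tolerance
          pos <- sweep(2.5 * sweep(qpos, 2, centroid), 2, centroid, `+`)
          far_s <- centroid + 2.5 * (far - centroid)
          assemble_fragments(c(ph_truth$type, distractor),
                             rbind(pos, matrix(far_s, 1)))
        }
      })
    })
    rows[[length(rows) + 1]] <- tibble(
      mol_id = id, conformer_id = seq_along(confs),
      atoms = purrr::map(confs, "atoms"), bonds = purrr::map(confs, "bonds"),
      active = TRUE)
  }
  for (d in seq_len(spec$n_decoys)) {
    id <- sprintf("dec_%03d", d)
    confs <- with_seed(substream_seed(seed, "decoy", d), {
      purrr::map(seq_len(spec$conformers_per_molecule), function(cf) {
        jit <- matrix(rnorm(nrow(qpos) * 3, sd = 2), ncol = 3)
        assemble_fragments(rep(decoy_type, nrow(qpos)), qpos + jit)
      })
    })
    rows[[length(rows) + 1]] <- tibble(
      mol_id = id, conformer_id = seq_along(confs),
      atoms = purrr::map(confs, "atoms"), bonds = purrr::map(confs, "bonds"),
      active = FALSE)
  }
  bind_rows(rows)
}
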