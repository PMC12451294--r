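# Ligand and pocket feature detection, interaction extraction,
# subsampling augmentation, and validity.

test_that("benzene yields exactly one aromatic feature at the ring centroid", {
  m <- mol_benzene()
  f <- detect_ligand_features(m$atoms, m$bonds)
  expect_equal(nrow(f), 1)
  expect_equal(f$type, "Aromatic")
  expect_equal(c(f$x, f$y, f$z), c(0, 0, 0), tolerance = 1e-12)
})

test_that("methanol has one donor and one acceptor, both on the oxygen", {
  m <- mol_methanol()
  f <- detect_ligand_features(m$atoms, m$bonds)
  expect_setequal(f$type, c("HydrogenDonor", "HydrogenAcceptor"))
  expect_equal(nrow(f), 2)
  expect_true(all(abs(f$x - 1.43) < 1e-12))
})

test_that("acetate yields one negative-ion feature at the carboxylate centroid", {
  m <- mol_acetate()
  f <- detect_ligand_features(m$atoms, m$bonds)
  neg <- f[f$type == "NegativeIon", ]
  expect_equal(nrow(neg), 1)
  # hand-computed centroid of C2, O3, O4 from the fixture coordinates
  expect_equal(c(neg$x, neg$y, neg$z),
               c((0 + 0.6 + 0.6) / 3, (0 + 1.1 - 1.1) / 3, 0),
               tolerance = 1e-12)
})

test_that("butane yields a single hydrophobic cluster centroid", {
  m <- mol_butane()
  f <- detect_ligand_features(m$atoms, m$bonds)
  expect_equal(f$type, "Hydrophobic")
  expect_equal(f$x, mean(m$atoms$x), tolerance = 1e-12)
})

test_that("glycine residue contributes backbone donor and acceptor only", {
  pdb <- paste(c(
    pdb_atom_line(1, "N", "GLY", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "GLY", "A", 1, 1.5, 0, 0),
    pdb_atom_line(3, "C", "GLY", "A", 1, 2.2, 1.3, 0),
    pdb_atom_line(4, "O", "GLY", "A", 1, 1.6, 2.4, 0), "END"),
    collapse = "\n")
  pocket <- read_pocket(pdb, residues = 1)
  f <- detect_pocket_features(pocket)
  expect_setequal(f$type, c("HydrogenDonor", "HydrogenAcceptor"))
  expect_equal(nrow(f), 2)
})

test_that("aspartate contributes a negative ion at the carboxylate centroid", {
  pdb <- paste(c(
    pdb_atom_line(1, "CG", "ASP", "A", 1, 0, 0, 0, element = "C"),
    pdb_atom_line(2, "OD1", "ASP", "A", 1, 0.6, 1.1, 0, element = "O"),
    pdb_atom_line(3, "OD2", "ASP", "A", 1, 0.6, -1.1, 0, element = "O"),
    "END"), collapse = "\n")
  pocket <- read_pocket(pdb, residues = 1)
  f <- detect_pocket_features(pocket)
  neg <- f[f$type == "NegativeIon", ]
  expect_equal(nrow(neg), 1)
  expect_equal(c(neg$x, neg$y, neg$z), c(0.4, 0, 0), tolerance = 1e-12)
})

test_that("planted fixture sites are detected exactly", {
  for (seed in c(3, 17, 99)) {
    fx <- make_toy_pocket(fixture_spec(n_sites = 6), seed = seed)
    f <- detect_pocket_features(fx$pocket)
    expect_equal(nrow(f), nrow(fx$sites))
    a <- dplyr::arrange(f, type, x)
    b <- dplyr::arrange(fx$sites, type, x)
    expect_equal(a$type, b$type)
    expect_equal(as.matrix(a[, c("x", "y", "z")]),
                 as.matrix(b[, c("x", "y", "z")]), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("interaction extraction keeps features within threshold only", {
  # pocket: one glycine backbone acceptor (O) at the origin
  pdb <- paste(c(pdb_atom_line(1, "O", "GLY", "A", 1, 0, 0, 0), "END"),
               collapse = "\n")
  pocket <- read_pocket(pdb, residues = 1)
  near <- tibble(type = "HydrogenDonor", x = 2.8, y = 0, z = 0)
  far <- tibble(type = "HydrogenDonor", x = 9.0, y = 0, z = 0)
  ph <- extract_interaction_pharmacophore(pocket, dplyr::bind_rows(near, far))
  expect_equal(nrow(ph), 1)
  expect_equal(ph$x, 2.8)
  expect_error(extract_interaction_pharmacophore(pocket, far), "No interactions")
  expect_error(
    extract_interaction_pharmacophore(pocket, near[0, ]), "No interactions")
})

test_that("subsampling draws uniform subsets of 3-8 centers", {
  set.seed(11)
  ph10 <- pharmacophore(random_feature_set(10))
  for (i in 1:25) {
    sub <- subsample_pharmacophore(ph10, seed = i)
    expect_gte(nrow(sub), 3)
    expect_lte(nrow(sub), 8)
    expect_true(all(paste(sub$type, sub$x) %in% paste(ph10$type, ph10$x)))
  }
  ph3 <- pharmacophore(random_feature_set(3))
  expect_equal(nrow(subsample_pharmacophore(ph3, seed = 1)), 3)
  ph2 <- pharmacophore(random_feature_set(2))
  expect_error(subsample_pharmacophore(ph2, seed = 1), "at least 3")
})

test_that("subsampled centers appear with uniform frequency", {
  ph10 <- pharmacophore(random_feature_set(10))
  counts <- integer(10)
  withr::with_seed(5, {
    for (i in 1:4000) {
      sub <- subsample_pharmacophore(ph10)
      counts[match(sub$x, ph10$x)] <- counts[match(sub$x, ph10$x)] + 1L
    }
  })
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.001)
})

test_that("validity is the fraction of centers near complementary features", {
  pdb <- paste(c(pdb_atom_line(1, "O", "GLY", "A", 1, 0, 0, 0), "END"),
               collapse = "\n")
  pocket <- read_pocket(pdb, residues = 1)
  at_feature <- pharmacophore(tibble(type = "HydrogenDonor", x = 0, y = 0, z = 0))
  expect_equal(pharmacophore_validity(at_feature, pocket), 1.0)
  lost <- pharmacophore(tibble(type = "HydrogenDonor", x = 100, y = 0, z = 0))
  expect_equal(pharmacophore_validity(lost, pocket), 0.0)
  half <- pharmacophore(tibble(type = "HydrogenDonor", x = c(0, 100),
                               y = 0, z = 0))
  expect_equal(pharmacophore_validity(half, pocket), 0.5)
})

test_that("validity never increases when thresholds shrink", {
  rules <- complementarity_rules()
  fx <- make_toy_pocket(fixture_spec(n_sites = 5), seed = 8)
  set.seed(2)
  ph <- pharmacophore(tibble(type = complement_type(fx$sites$type),
                             x = fx$sites$x + rnorm(5), y = fx$sites$y,
                             z = fx$sites$z))
  v_prev <- Inf
  for (shrink in c(1, 0.6, 0.3, 0.1)) {
    r <- dplyr::mutate(rules, threshold = threshold * shrink)
    v <- pharmacophore_validity(ph, fx$pocket, r)
    expect_lte(v, min(v_prev, 1))
    expect_gte(v, 0)
    v_prev <- v
  }
})

test_that("extracted interaction centers are a subset of ligand features", {
  fx <- make_toy_pocket(fixture_spec(n_sites = 6), seed = 31)
  set.seed(31)
  feats <- random_feature_set(12, spread = 7)
  ph <- tryCatch(extract_interaction_pharmacophore(fx$pocket, feats),
                 error = function(e) NULL)
  if (!is.null(ph)) {
    key_all <- paste(feats$type, round(feats$x, 9), round(feats$y, 9))
    key_ph <- paste(ph$type, round(ph$x, 9), round(ph$y, 9))
    expect_true(all(key_ph %in% key_all))
  } else {
    succeed()
  }
})
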