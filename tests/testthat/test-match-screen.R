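# Pharmacophore matching, screening, and retrospective metrics.

test_that("matching accepts identical and rigidly moved feature sets", {
  set.seed(1)
  q <- pharmacophore(random_feature_set(4))
  f <- q[, c("type", "x", "y", "z")]
  m <- match_pharmacophore(f, q)
  expect_true(m$matched)
  expect_lt(m$rmsd, 1e-9)

  R <- phoregen:::random_rotation()
  xyz <- as.matrix(f[, c("x", "y", "z")]) %*% t(R)
  f2 <- f
  f2$x <- xyz[, 1] + 7; f2$y <- xyz[, 2] - 3; f2$z <- xyz[, 3] + 1
  m2 <- match_pharmacophore(f2, q)
  expect_true(m2$matched)
  expect_lt(m2$rmsd, 1e-9)
  expect_equal(m2$aligned, as.matrix(q[, c("x", "y", "z")]),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("match decisions are invariant under rigid transforms", {
  set.seed(8)
  for (i in 1:20) {
    q <- pharmacophore(random_feature_set(sample(2:5, 1)))
    f <- random_feature_set(sample(3:8, 1))
    base <- match_pharmacophore(f, q)
    R <- phoregen:::random_rotation()
    xyz <- as.matrix(f[, c("x", "y", "z")]) %*% t(R)
    f2 <- f
    f2$x <- xyz[, 1] - 4; f2$y <- xyz[, 2]; f2$z <- xyz[, 3] + 9
    moved <- match_pharmacophore(f2, q)
    expect_equal(moved$matched, base$matched)
    if (is.finite(base$rmsd)) expect_equal(moved$rmsd, base$rmsd,
                                           tolerance = 1e-6)
  }
})

test_that("matcher agrees with exhaustive assignment enumeration", {
  set.seed(5)
  for (i in 1:60) {
    nq <- sample(2:5, 1)
    q <- pharmacophore(random_feature_set(nq, spread = 4))
    f <- random_feature_set(sample(nq:8, 1), spread = 4)
    # mix in near-matching instances so both branches are exercised
    if (i %% 3 == 0) {
      f <- dplyr::bind_rows(
        dplyr::mutate(q[, c("type", "x", "y", "z")],
                      x = x + rnorm(nq, sd = 0.4)),
        f)
    }
    mine <- match_pharmacophore(f, q)
    oracle <- oracle_match(f, q)
    expect_equal(mine$matched, oracle$matched)
    if (mine$matched) expect_equal(mine$rmsd, oracle$rmsd, tolerance = 1e-6)
  }
})

test_that("screening hits molecules whose conformers match", {
  set.seed(2)
  fx <- make_toy_pocket(fixture_spec(n_sites = 4), seed = 2)
  truth <- pharmacophore(tibble(type = complement_type(fx$sites$type),
                                x = fx$sites$x, y = fx$sites$y,
                                z = fx$sites$z))
  lib <- make_toy_library(fixture_spec(n_actives = 3L, n_decoys = 5L,
                                       conformers_per_molecule = 3L),
                          truth, seed = 4)
  res <- screen_library(lib, truth)
  expect_true(all(res$hit[res$active]))
  expect_false(any(res$hit[!res$active]))
  # only the embedding conformer of each active matches
  expect_true(all(res$best_conformer[res$active] == 1L))

  empty <- screen_library(lib[0, ], truth)
  expect_equal(nrow(empty), 0)
})

test_that("enrichment factor follows its definition and conventions", {
  res <- tibble(mol_id = sprintf("m%03d", 1:100),
                hit = c(rep(TRUE, 20), rep(FALSE, 80)),
                active = c(rep(TRUE, 5), rep(FALSE, 45),
                           rep(TRUE, 45), rep(FALSE, 5)))
  # 20 hits, 5 active; database 50/100 actives
  ef <- enrichment_factor(res)
  expect_equal(ef$ef, (5 / 20) / (50 / 100))
  # db of 1000 with 50 actives; 20 hits of which 5 active -> EF = 5
  ef2 <- enrichment_factor(res, n_actives_db = 50, n_total_db = 1000)
  expect_equal(ef2$ef, 5.0)
  # hits = entire database -> EF exactly 1
  all_hits <- dplyr::mutate(res, hit = TRUE)
  expect_equal(enrichment_factor(all_hits)$ef, 1.0)
  # zero hits -> undefined flag
  no_hits <- dplyr::mutate(res, hit = FALSE)
  ef0 <- enrichment_factor(no_hits)
  expect_false(ef0$defined)
  expect_true(is.na(ef0$ef))
  expect_error(enrichment_factor(dplyr::mutate(res, active = FALSE)),
               "active")
})

test_that("precision/recall/F1 match hand arithmetic and conventions", {
  # TP=5, FP=15, FN=45
  res <- tibble(mol_id = sprintf("m%03d", 1:100),
                hit = c(rep(TRUE, 20), rep(FALSE, 80)),
                active = c(rep(TRUE, 5), rep(FALSE, 15),
                           rep(TRUE, 45), rep(FALSE, 35)))
  prf <- precision_recall_f1(res)
  expect_equal(prf$precision, 0.25)
  expect_equal(prf$recall, 0.1)
  expect_equal(prf$f1, 2 * 0.25 * 0.1 / 0.35, tolerance = 1e-12)
  # perfect retrieval
  perfect <- dplyr::mutate(res, hit = active)
  expect_equal(precision_recall_f1(perfect)$f1, 1.0)
  # zero hits: precision defined as 0, F1 = 0
  none <- dplyr::mutate(res, hit = FALSE)
  prf0 <- precision_recall_f1(none)
  expect_equal(prf0$precision, 0)
  expect_equal(prf0$f1, 0)
})

test_that("metrics agree with brute-force set counting on random configs", {
  set.seed(9)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    res <- tibble(mol_id = sprintf("m%03d", 1:n),
                  hit = runif(n) < runif(1),
                  active = runif(n) < runif(1))
    if (sum(res$active) == 0) res$active[1] <- TRUE
    hits <- res$mol_id[res$hit]
    actives <- res$mol_id[res$active]
    tp <- length(intersect(hits, actives))
    fp <- length(setdiff(hits, actives))
    fn <- length(setdiff(actives, hits))
    prf <- precision_recall_f1(res)
    expect_equal(prf$tp, tp)
    expect_equal(prf$fp, fp)
    expect_equal(prf$fn, fn)
    ef <- enrichment_factor(res)
    if (length(hits) == 0) {
      expect_false(ef$defined)
    } else {
      expect_equal(ef$ef, (tp / length(hits)) /
                     (length(actives) / n), tolerance = 1e-12)
    }
  }
})

test_that("query-size filtering keeps queries at or below the cutoff", {
  summaries <- tibble(query_id = c("a", "b", "c"),
                      n_hits = c(2000L, 2001L, 7L))
  kept <- filter_queries(summaries, max_hits = 2000)
  expect_equal(kept$query_id, c("a", "c"))
  # default cutoff: 1% of the database
  kept2 <- filter_queries(summaries, db_size = 200000)
  expect_equal(kept2$query_id, c("a", "c"))
  expect_equal(nrow(filter_queries(summaries[0, ], max_hits = 10)), 0)
})

test_that("receptor exclusion rejects hits clashing with the pocket", {
  set.seed(3)
  q <- pharmacophore(random_feature_set(3))
  lib <- tibble(mol_id = "hit", conformer_id = 1L,
                atoms = list(tibble(element = "O", x = q$x, y = q$y, z = q$z,
                                    charge = 0L)),
                bonds = list(tibble(i = integer(), j = integer(),
                                    order = integer())))
  lib$features <- list(q[, c("type", "x", "y", "z")])
  q$type <- "HydrogenDonor"
  lib$features[[1]]$type <- "HydrogenDonor"
  res_plain <- screen_library(lib, q)
  expect_true(res_plain$hit)
  # a pocket atom sitting on a query center triggers the exclusion filter
  clash_pdb <- paste(c(pdb_atom_line(1, "CA", "GLY", "A", 1,
                                     q$x[1], q$y[1], q$z[1]), "END"),
                     collapse = "\n")
  clash_pocket <- read_pocket(clash_pdb, residues = 1)
  res_excl <- screen_library(lib, q, receptor = clash_pocket)
  expect_false(res_excl$hit)
})

test_that("EF of uniformly random hit sets concentrates at one", {
  # a random selection is neither enriched nor depleted on average
  n <- 400L
  actives <- c(rep(TRUE, 80), rep(FALSE, 320))
  efs <- withr::with_seed(17, purrr::map_dbl(1:1000, function(i) {
    hit <- sample(c(rep(TRUE, 40), rep(FALSE, n - 40)))
    enrichment_factor(tibble(mol_id = as.character(seq_len(n)),
                             hit = hit, active = actives))$ef
  }))
  se <- sd(efs) / sqrt(length(efs))
  expect_lt(abs(mean(efs) - 1), 3 * se + 1e-3)
})
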