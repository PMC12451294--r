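# Ligand-protein feature complementarity.
#
# One threshold table serves both training-data extraction and validity
# scoring, so the two uses cannot drift apart. The default thresholds are
# standard interaction-geometry ranges (hydrogen bonds ~4 A, hydrophobic/
# aromatic stacking and ionic pairs ~5 A) and ship as a YAML config.

#' Default ligand-protein complementarity rules
#'
#' Each row pairs a ligand-side feature type with a complementary
#' protein-side type and an interaction distance threshold in Angstroms.
#' The table is read from the packaged YAML config
#' (`inst/extdata/complementarity.yaml`), so deployments can swap in their
#' own calibrated thresholds.
#'
#' @param path Optional path to a YAML rules file with entries
#'   `ligand`, `protein`, `threshold`.
#' @return Tibble with columns `ligand`, `protein`, `threshold`.
#' @export
complementarity_rules <- function(path = NULL) {
  path <- path %||% system.file("extdata", "complementarity.yaml",
                                package = "phoregen")
  raw <- yaml::read_yaml(path)
  rules <- bind_rows(purrr::map(raw$rules, as_tibble))
  assert_feature_type(rules$ligand)
  assert_feature_type(rules$protein)
  stopifnot(all(rules$threshold > 0))
  if (!all(feature_types() %in% rules$ligand)) {
    abort("Complementarity rules must cover every ligand feature type.")
  }
  rules
}

#' Complement of a protein-side feature type
#'
#' The ligand-side partner used when planting fixture pharmacophores:
#' donors pair with acceptors, ions pair oppositely, hydrophobic and
#' aromatic pair with themselves.
#'
#' @param protein_type Character vector of protein feature types.
#' @return Character vector of ligand feature types.
#' @export
complement_type <- function(protein_type) {
  assert_feature_type(protein_type)
  map <- c(HydrogenAcceptor = "HydrogenDonor",
           HydrogenDonor = "HydrogenAcceptor",
           Hydrophobic = "Hydrophobic",
           Aromatic = "Aromatic",
           NegativeIon = "PositiveIon",
           PositiveIon = "NegativeIon")
  unname(map[protein_type])
}

#' Extract the interaction pharmacophore of a posed ligand
#'
#' Keeps every ligand feature that lies within the rule threshold of a
#' complementary protein-side feature; the retained center takes the
#' ligand feature's position and type. This is the training-data
#' construction applied to each protein-ligand complex.
#'
#' @param pocket A `phg_pocket`.
#' @param ligand_features Tibble of ligand features (`type`, `x`, `y`,
#'   `z`), posed in the pocket frame.
#' @param rules Complementarity rule table (default packaged rules).
#' @param pocket_features Optional precomputed pocket feature tibble.
#' @return A pharmacophore of the surviving centers.
#' @export
extract_interaction_pharmacophore <- function(pocket, ligand_features,
                                              rules = complementarity_rules(),
                                              pocket_features = NULL) {
  if (nrow(ligand_features) == 0) {
    abort("No interactions: the ligand has no detectable features.")
  }
  pf <- pocket_features %||% detect_pocket_features(pocket)
  keep <- interacting_centers(ligand_features, pf, rules)
  if (!any(keep)) {
    abort("No interactions: no ligand feature lies within threshold of a complementary pocket feature.")
  }
  pharmacophore(ligand_features[keep, ])
}

interacting_centers <- function(centers, pocket_features, rules) {
  if (nrow(pocket_features) == 0) return(rep(FALSE, nrow(centers)))
  d <- cross_dist(coord_matrix(centers), coord_matrix(pocket_features))
  purrr::map_lgl(seq_len(nrow(centers)), function(i) {
    r <- rules[rules$ligand == centers$type[i], , drop = FALSE]
    if (nrow(r) == 0) return(FALSE)
    any(purrr::map_lgl(seq_len(nrow(r)), function(k) {
      j <- which(pocket_features$type == r$protein[k])
      length(j) > 0 && any(d[i, j] <= r$threshold[k])
    }))
  })
}

#' Pharmacophore validity against a pocket
#'
#' The fraction of centers that lie within the interaction-type threshold
#' of a complementary feature in the binding pocket; 1 means every center
#' is geometrically plausible, 0 none.
#'
#' @param ph A pharmacophore.
#' @param pocket A `phg_pocket`.
#' @param rules Complementarity rule table.
#' @param pocket_features Optional precomputed pocket features.
#' @return A fraction in `[0, 1]`.
#' @export
pharmacophore_validity <- function(ph, pocket, rules = complementarity_rules(),
                                   pocket_features = NULL) {
  ph <- validate_pharmacophore(as_tibble(ph))
  pf <- pocket_features %||% detect_pocket_features(pocket)
  mean(interacting_centers(ph, pf, rules))
}
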