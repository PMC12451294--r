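# Protein-side complementary feature detection.
#
# Residue-table rules: backbone N-H donates (except proline), backbone
# carbonyl O accepts, and side chains contribute by residue name. The
# rules tolerate partial residues (missing atoms contribute nothing),
# which both matches crystallographic reality and lets the synthetic
# fixtures plant single-feature sites.

POCKET_AROMATIC_RINGS <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CE2", "CD2", "CE3", "CZ3", "CH2", "CZ2"))
)

POCKET_HYDROPHOBIC <- list(
  ALA = c("CB"),
  VAL = c("CB", "CG1", "CG2"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  MET = c("CB", "CG", "CE"),
  PRO = c("CB", "CG", "CD")
)

#' Detect complementary features on a protein pocket
#'
#' @param pocket A `phg_pocket` tibble.
#' @return Tibble of protein-side features: `type`, `x`, `y`, `z`.
#' @export
detect_pocket_features <- function(pocket) {
  stopifnot(is_pocket(pocket))
  feats <- list()
  add <- function(type, xyz) {
    xyz <- unname(xyz)
    feats[[length(feats) + 1]] <<- tibble(type = type, x = xyz[1], y = xyz[2],
                                          z = xyz[3])
  }
  known <- c("GLY", "ALA", "VAL", "LEU", "ILE", "MET", "PRO", "PHE", "TYR",
             "TRP", "HIS", "SER", "THR", "CYS", "ASN", "GLN", "ASP", "GLU",
             "LYS", "ARG")
  res_split <- split(seq_len(nrow(pocket)),
                     paste(pocket$chain, pocket$resno, pocket$resname))
  for (idx in res_split) {
    res <- pocket[idx, ]
    rn <- res$resname[1]
    if (!(rn %in% known)) {
      inform(paste0("Residue ", rn, " has no feature rules; skipped."))
      next
    }
    at <- function(name) {
      hit <- which(res$atom_name == name)
      if (length(hit) == 0) NULL else c(res$x[hit[1]], res$y[hit[1]], res$z[hit[1]])
    }
    centroid_of <- function(names) {
      ps <- purrr::compact(purrr::map(names, at))
      if (length(ps) < length(names)) return(NULL)
      colMeans(do.call(rbind, ps))
    }
    # backbone
    bbN <- at("N")
    if (!is.null(bbN) && rn != "PRO") add("HydrogenDonor", bbN)
    bbO <- at("O")
    if (!is.null(bbO)) add("HydrogenAcceptor", bbO)
    # side-chain donors/acceptors
    side_da <- list(SER = "OG", THR = "OG1", TYR = "OH")
    if (rn %in% names(side_da)) {
      p <- at(side_da[[rn]])
      if (!is.null(p)) { add("HydrogenDonor", p); add("HydrogenAcceptor", p) }
    }
    if (rn %in% c("ASN", "GLN")) {
      o <- at(if (rn == "ASN") "OD1" else "OE1")
      nn <- at(if (rn == "ASN") "ND2" else "NE2")
      if (!is.null(o)) add("HydrogenAcceptor", o)
      if (!is.null(nn)) add("HydrogenDonor", nn)
    }
    # charged side chains
    if (rn == "ASP") {
      p <- centroid_of(c("CG", "OD1", "OD2"))
      if (!is.null(p)) add("NegativeIon", p)
    }
    if (rn == "GLU") {
      p <- centroid_of(c("CD", "OE1", "OE2"))
      if (!is.null(p)) add("NegativeIon", p)
    }
    if (rn == "LYS") {
      p <- at("NZ")
      if (!is.null(p)) add("PositiveIon", p)
    }
    if (rn == "ARG") {
      p <- centroid_of(c("CZ", "NE", "NH1", "NH2"))
      if (!is.null(p)) add("PositiveIon", p)
    }
    if (rn == "HIS") {
      p <- centroid_of(POCKET_AROMATIC_RINGS$HIS[[1]])
      if (!is.null(p)) add("PositiveIon", p)
    }
    # aromatic rings
    if (rn %in% names(POCKET_AROMATIC_RINGS)) {
      for (ring in POCKET_AROMATIC_RINGS[[rn]]) {
        p <- centroid_of(ring)
        if (!is.null(p)) add("Aromatic", p)
      }
    }
    # aliphatic side chains
    if (rn %in% names(POCKET_HYDROPHOBIC)) {
      p <- centroid_of(POCKET_HYDROPHOBIC[[rn]])
      if (!is.null(p)) add("Hydrophobic", p)
    }
  }
  if (length(feats) == 0) {
    return(tibble(type = character(), x = double(), y = double(), z = double()))
  }
  bind_rows(feats)
}
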