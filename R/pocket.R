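#' Read a protein binding pocket from a PDB structure
#'
#' Selects pocket atoms either by distance to a reference ligand
#' (ligand mode) or by an explicit residue list (residue mode). Waters
#' and the reference ligand itself are always excluded; only protein
#' `ATOM` records are considered. The returned pocket is a tibble of
#' typed atoms with 3D coordinates in Angstroms, one row per atom.
#'
#' @param pdb Path to a PDB file, or PDB text (a character vector of
#'   lines or a single string with newlines).
#' @param ligand Optional reference-ligand coordinates: an n x 3 numeric
#'   matrix or a data frame with `x`, `y`, `z` columns. Atoms within
#'   `radius` of any ligand atom are kept.
#' @param residues Optional residue selector: integer residue numbers, or
#'   strings of the form `"A:45"` (chain:resno).
#' @param radius Cutoff in Angstroms for ligand mode (default 8).
#' @return A `phg_pocket` tibble with columns `element`, `x`, `y`, `z`,
#'   `chain`, `resno`, `resname`, `atom_name`, `atom_type`.
#' @export
read_pocket <- function(pdb, ligand = NULL, residues = NULL, radius = 8) {
  if (is.null(ligand) && is.null(residues)) {
    abort("read_pocket() needs either a `ligand` coordinate selector or a `residues` list.")
  }
  if (!is.null(ligand) && radius <= 0) abort("`radius` must be positive in ligand mode.")
  lines <- pdb_lines(pdb)
  validate_pdb_lines(lines)
  path <- tempfile(fileext = ".pdb")
  on.exit(unlink(path))
  writeLines(lines, path)
  pdbobj <- bio3d::read.pdb(path, verbose = FALSE)
  at <- as_tibble(pdbobj$atom)
  at <- filter(at, .data$type == "ATOM",
               !.data$resid %in% c("HOH", "WAT", "DOD"))
  if (nrow(at) > 0 && !is.null(ligand)) {
    lig <- if (is.data.frame(ligand)) coord_matrix(ligand) else as.matrix(ligand)
    stopifnot(ncol(lig) == 3)
    # drop any protein atom coincident with the reference ligand
    d <- cross_dist(as.matrix(at[, c("x", "y", "z")]), lig)
    at <- at[apply(d, 1, min) > 1e-6, , drop = FALSE]
    d <- cross_dist(as.matrix(at[, c("x", "y", "z")]), lig)
    keep <- apply(d, 1, min) <= radius
    at <- at[keep, , drop = FALSE]
  } else if (nrow(at) > 0) {
    sel <- parse_residue_selector(residues)
    key <- if (all(is.na(sel$chain))) as.character(at$resno) else
      paste(at$chain, at$resno, sep = ":")
    want <- if (all(is.na(sel$chain))) as.character(sel$resno) else
      paste(sel$chain, sel$resno, sep = ":")
    at <- at[key %in% want, , drop = FALSE]
  }
  if (nrow(at) == 0) {
    abort("Empty pocket: the selector matched no protein atoms.")
  }
  el <- at$elesy
  if (is.null(el) || all(is.na(el)) || all(el == "")) el <- element_from_name(at$elety)
  el[is.na(el) | el == ""] <- element_from_name(at$elety[is.na(el) | el == ""])
  new_pocket(tibble(
    element = el, x = at$x, y = at$y, z = at$z,
    chain = as.character(at$chain), resno = as.integer(at$resno),
    resname = as.character(at$resid), atom_name = as.character(at$elety)))
}

new_pocket <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  atoms <- as_tibble(atoms)
  pos <- as.matrix(atoms[, c("x", "y", "z")])
  if (nrow(atoms) == 0) abort("A pocket must contain at least one atom.")
  if (!all(is.finite(pos))) abort("Pocket coordinates must be finite.")
  atoms$atom_type <- atom_type_index(atoms$element)
  class(atoms) <- c("phg_pocket", class(tibble()))
  atoms
}

is_pocket <- function(x) inherits(x, "phg_pocket")

#' @export
print.phg_pocket <- function(x, ...) {
  cat("# Pocket:", nrow(x), "atom(s),", length(unique(paste(x$chain, x$resno))),
      "residue(s)\n")
  NextMethod()
}

pdb_lines <- function(pdb) {
  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) {
    return(readLines(pdb, warn = FALSE))
  }
  strsplit(paste(pdb, collapse = "\n"), "\n", fixed = TRUE)[[1]]
}

validate_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  atom_idx <- which(rec %in% c("ATOM  ", "HETATM"))
  for (i in atom_idx) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      abort(paste0("Malformed PDB ATOM/HETATM record at line ", i,
                   ": fewer than 54 columns."))
    }
    coords <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (any(is.na(suppressWarnings(as.numeric(coords))))) {
      abort(paste0("Malformed PDB ATOM/HETATM record at line ", i,
                   ": non-numeric coordinate field."))
    }
  }
  invisible(lines)
}

parse_residue_selector <- function(residues) {
  if (is.numeric(residues)) {
    return(list(chain = rep(NA_character_, length(residues)),
                resno = as.integer(residues)))
  }
  parts <- strsplit(as.character(residues), ":", fixed = TRUE)
  chain <- purrr::map_chr(parts, function(p) if (length(p) == 2) p[1] else NA_character_)
  resno <- purrr::map_int(parts, function(p) as.integer(p[length(p)]))
  list(chain = chain, resno = resno)
}

element_from_name <- function(atom_name) {
  nm <- gsub("[0-9']", "", trimws(atom_name))
  two <- c("CL", "BR", "FE", "ZN", "MG", "NA", "SE")
  el <- ifelse(toupper(nm) %in% two,
               paste0(substr(nm, 1, 1), tolower(substr(nm, 2, 2))),
               substr(nm, 1, 1))
  el
}

#' Write a pocket as PDB text
#'
#' Used by the fixture generator and the command-line tools; emits fixed
#' column `ATOM` records.
#'
#' @param pocket A `phg_pocket`.
#' @param path Optional output file.
#' @return Character vector of PDB lines (invisibly when written).
#' @export
write_pocket_pdb <- function(pocket, path = NULL) {
  stopifnot(is_pocket(pocket))
  lines <- character(nrow(pocket))
  for (i in seq_len(nrow(pocket))) {
    a <- pocket[i, ]
    name <- a$atom_name
    name_fmt <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
    lines[i] <- sprintf(
      "ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i, name_fmt, a$resname, a$chain, a$resno, a$x, a$y, a$z, 1.0, 0.0,
      toupper(a$element))
  }
  lines <- c(lines, "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
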