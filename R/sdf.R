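# Multi-conformer ligand libraries.
#
# A library is a tibble with one row per conformer: columns `mol_id`,
# `conformer_id`, list-columns `atoms` (element, x, y, z, charge) and
# `bonds` (i, j, order), plus an optional `active` label column.

#' Read a multi-conformer ligand library from SDF
#'
#' Parses a V2000 SDF (via ChemmineR) and groups conformers by molecule
#' identifier: the `mol_id` data field when present, otherwise the
#' molecule title line. Repeated identifiers become conformers of one
#' molecule. Formal charges are taken from `M CHG` lines (which override
#' the legacy atom-block charge column, as the format prescribes).
#'
#' @param sdf Path to an SDF file, or SDF text.
#' @return A library tibble; zero rows (with a warning) for an empty file.
#' @export
read_ligand_library <- function(sdf) {
  if (length(sdf) == 1 && !grepl("\n", sdf) && file.exists(sdf)) {
    sdf <- readLines(sdf, warn = FALSE)
  } else {
    # collapse-then-split preserves empty lines, which SDF needs
    sdf <- strsplit(paste(sdf, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  }
  if (length(sdf) == 0 || all(trimws(sdf) == "")) {
    warn("Empty SDF input: returning an empty library.")
    return(empty_library())
  }
  path <- tempfile(fileext = ".sdf")
  on.exit(unlink(path))
  writeLines(sdf, path)
  sdfset <- tryCatch(ChemmineR::read.SDFset(path),
                     error = function(e) abort(paste0("SDF parse error: ", conditionMessage(e))))
  ok <- ChemmineR::validSDF(sdfset)
  if (!all(ok)) {
    abort(paste0("Truncated or invalid SDF record at index ",
                 paste(which(!ok), collapse = ", "), "."))
  }
  raw_records <- split_sdf_records(sdf)
  if (length(raw_records) != length(sdfset)) {
    abort("SDF parse error: record count mismatch while reading charges.")
  }
  sdf_list <- ChemmineR::SDFset2SDF(sdfset)
  rows <- purrr::map(seq_along(sdf_list), function(i) {
    s <- sdf_list[[i]]
    ab <- ChemmineR::atomblock(s)
    bb <- ChemmineR::bondblock(s)
    el <- sub("_.*$", "", rownames(ab))
    charge <- sdf_charges(raw_records[[i]], nrow(ab), ab)
    db <- ChemmineR::datablock(s)
    hd <- ChemmineR::header(s)
    id <- if ("mol_id" %in% names(db)) unname(db[["mol_id"]]) else
      if ("Molecule_Name" %in% names(hd)) trimws(hd[["Molecule_Name"]]) else ""
    if (length(id) != 1 || is.na(id) || id == "") id <- paste0("mol_", i)
    bonds <- if (is.null(dim(bb)) || nrow(bb) == 0) {
      tibble(i = integer(), j = integer(), order = integer())
    } else {
      tibble(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
             order = as.integer(bb[, 3]))
    }
    tibble(mol_id = id,
           atoms = list(tibble(element = el, x = unname(ab[, 1]),
                               y = unname(ab[, 2]), z = unname(ab[, 3]),
                               charge = charge)),
           bonds = list(bonds))
  })
  lib <- bind_rows(rows)
  lib <- lib |>
    group_by(.data$mol_id) |>
    mutate(conformer_id = row_number()) |>
    ungroup()
  counts <- lib |>
    mutate(n_atoms = purrr::map_int(.data$atoms, nrow)) |>
    group_by(.data$mol_id) |>
    summarise(ok = length(unique(.data$n_atoms)) == 1)
  if (!all(counts$ok)) {
    abort(paste0("Inconsistent atom counts across conformers of molecule(s): ",
                 paste(counts$mol_id[!counts$ok], collapse = ", ")))
  }
  lib[, c("mol_id", "conformer_id", "atoms", "bonds")]
}

empty_library <- function() {
  tibble(mol_id = character(), conformer_id = integer(),
         atoms = list(), bonds = list())
}

split_sdf_records <- function(lines) {
  ends <- which(trimws(lines) == "$$$$")
  if (length(ends) == 0) return(list(lines))
  starts <- c(1L, head(ends, -1) + 1L)
  purrr::map2(starts, ends, function(s, e) lines[s:e])
}

# Formal charges for one raw SDF record: M CHG lines override the legacy
# atom-block charge-code column.
sdf_charges <- function(record_lines, n_atoms, atomblock) {
  charge <- rep(0L, n_atoms)
  code_col <- which(colnames(atomblock) == "C6")
  if (length(code_col) == 1) {
    codes <- atomblock[, code_col]
    legacy <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)
    hit <- as.character(codes) %in% names(legacy)
    charge[hit] <- legacy[as.character(codes[hit])]
  }
  chg_lines <- grep("^M  CHG", record_lines, value = TRUE)
  if (length(chg_lines) > 0) {
    charge <- rep(0L, n_atoms)  # M CHG supersedes the column entirely
    for (ln in chg_lines) {
      vals <- as.integer(strsplit(trimws(substr(ln, 10, nchar(ln))), "\\s+")[[1]])
      n <- as.integer(substr(ln, 7, 9))
      for (k in seq_len(n)) {
        charge[vals[2 * k - 1]] <- vals[2 * k]
      }
    }
  }
  charge
}

#' Write a ligand library as SDF text
#'
#' Emits V2000 records, one per conformer, with the molecule identifier
#' both as the title line and as a `mol_id` data field; formal charges are
#' written as `M CHG` lines.
#'
#' @param library A library tibble (see [read_ligand_library()]).
#' @param path Optional output file.
#' @return Character vector of SDF lines (invisibly when written).
#' @export
write_sdf <- function(library, path = NULL) {
  out <- character(0)
  for (r in seq_len(nrow(library))) {
    at <- library$atoms[[r]]
    bd <- library$bonds[[r]]
    lines <- c(library$mol_id[r], "  phoregen          3D", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(at), nrow(bd)))
    for (i in seq_len(nrow(at))) {
      lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                                at$x[i], at$y[i], at$z[i], at$element[i]))
    }
    for (b in seq_len(nrow(bd))) {
      lines <- c(lines, sprintf("%3d%3d%3d  0", bd$i[b], bd$j[b], bd$order[b]))
    }
    chg <- which(at$charge != 0)
    if (length(chg) > 0) {
      for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
        lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(grp)),
                                 paste0(sprintf("%4d%4d", grp, at$charge[grp]),
                                        collapse = "")))
      }
    }
    lines <- c(lines, "M  END",
               "> <mol_id>", library$mol_id[r], "", "$$$$")
    out <- c(out, lines)
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
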