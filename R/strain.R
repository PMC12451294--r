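# Conformer strain energy: single-point energy minus the energy after
# local geometry optimisation, under a classical force field.
#
# The default evaluator drives the OpenBabel command-line tools
# (obenergy / obabel --minimize) with the Universal Force Field; energies
# are converted from OpenBabel's kJ/mol to kcal/mol. Any object with
# `energy(sdf_lines)` and `minimize(sdf_lines)` functions can be plugged
# in instead (e.g. an external conformer pipeline).

KJ_PER_KCAL <- 4.184

#' UFF evaluator backed by the OpenBabel command-line tools
#'
#' @param ff Force-field name understood by OpenBabel (default `"UFF"`).
#' @param steps Maximum minimisation steps (default 2500).
#' @param crit Convergence criterion on the energy (default 1e-8).
#' @return An evaluator: list with `energy` (SDF lines -> kcal/mol) and
#'   `minimize` (SDF lines -> SDF lines) functions.
#' @export
openbabel_uff <- function(ff = "UFF", steps = 2500L, crit = 1e-8) {
  if (Sys.which("obenergy") == "" || Sys.which("obabel") == "") {
    abort("OpenBabel tools (obenergy/obabel) not found on PATH; strain energies need them.")
  }
  energy <- function(sdf_lines) {
    f <- tempfile(fileext = ".sdf")
    on.exit(unlink(f))
    writeLines(sdf_lines, f)
    out <- suppressWarnings(system2("obenergy", c("-ff", ff, f),
                                    stdout = TRUE, stderr = FALSE))
    line <- grep("^TOTAL ENERGY", out, value = TRUE)
    if (length(line) == 0) abort("obenergy reported no total energy.")
    val <- as.numeric(sub("^TOTAL ENERGY = *([-0-9.eE+]+).*$", "\\1",
                          line[length(line)]))
    if (grepl("kJ/mol", line[length(line)])) val <- val / KJ_PER_KCAL
    val
  }
  minimize <- function(sdf_lines) {
    fin <- tempfile(fileext = ".sdf"); fout <- tempfile(fileext = ".sdf")
    on.exit(unlink(c(fin, fout)))
    writeLines(sdf_lines, fin)
    suppressWarnings(system2("obabel", c(fin, "-O", fout, "--minimize",
                                         "--ff", ff, "--steps", steps,
                                         "--crit", format(crit)),
                             stdout = FALSE, stderr = FALSE))
    if (!file.exists(fout) || length(readLines(fout, warn = FALSE)) < 4) {
      abort("obabel minimisation produced no output.")
    }
    readLines(fout, warn = FALSE)
  }
  # explicit hydrogen completion; minimisation adds hydrogens on its own,
  # so both energies must see the same hydrogen-complete molecule
  hydrogenate <- function(sdf_lines) {
    fin <- tempfile(fileext = ".sdf"); fout <- tempfile(fileext = ".sdf")
    on.exit(unlink(c(fin, fout)))
    writeLines(sdf_lines, fin)
    suppressWarnings(system2("obabel", c(fin, "-O", fout, "-h"),
                             stdout = FALSE, stderr = FALSE))
    if (!file.exists(fout) || length(readLines(fout, warn = FALSE)) < 4) {
      abort("obabel hydrogen addition produced no output.")
    }
    readLines(fout, warn = FALSE)
  }
  list(energy = energy, minimize = minimize, hydrogenate = hydrogenate,
       name = paste0("openbabel-", ff))
}

#' Strain energy of conformers
#'
#' `E(input geometry) - E(locally minimised geometry)` in kcal/mol for
#' every conformer of a library. Values are non-negative up to the
#' minimiser's convergence slack; large values flag unphysical poses.
#'
#' @param library A library tibble (see [read_ligand_library()]).
#' @param evaluator A force-field evaluator (default [openbabel_uff()]).
#' @return The library's `mol_id`/`conformer_id` columns plus
#'   `strain_kcal`.
#' @export
strain_energy <- function(library, evaluator = openbabel_uff()) {
  stopifnot(nrow(library) >= 1)
  strain <- purrr::map_dbl(seq_len(nrow(library)), function(r) {
    rec <- library[r, , drop = FALSE]
    sdf <- write_sdf(rec)
    if (!is.null(evaluator$hydrogenate)) sdf <- evaluator$hydrogenate(sdf)
    e0 <- tryCatch(evaluator$energy(sdf), error = function(e)
      abort(paste0("Force-field evaluation failed for molecule ",
                   rec$mol_id, ": ", conditionMessage(e))))
    e1 <- evaluator$energy(evaluator$minimize(sdf))
    e0 - e1
  })
  tibble(mol_id = library$mol_id, conformer_id = library$conformer_id,
         strain_kcal = strain)
}
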