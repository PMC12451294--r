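# Ligand pharmacophore feature detection.
#
# Rule families (Pharmit-inspired, operating on the SDF bond graph):
#  * HydrogenDonor:    N/O bearing >= 1 hydrogen (explicit or implicit)
#  * HydrogenAcceptor: N/O with an available lone pair and no positive
#                      formal charge
#  * Aromatic:         centroid of each 5/6-membered aromatic ring
#  * Hydrophobic:      centroid of each connected cluster of >= 3
#                      non-aromatic carbons with no attached heteroatom
#  * PositiveIon:      N with positive formal charge, or the centroid of
#                      an amidine/guanidine group
#  * NegativeIon:      carboxylate/sulfate/phosphate group centroid, or
#                      any atom with negative formal charge

DEFAULT_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1,
                     Br = 1, I = 1, H = 1)

#' Detect pharmacophore features on a ligand conformer
#'
#' @param atoms Tibble with columns `element`, `x`, `y`, `z`, `charge`.
#' @param bonds Tibble with columns `i`, `j`, `order` (order 4 marks an
#'   aromatic bond).
#' @param mol_id Identifier used in error messages.
#' @return Tibble of features: `type`, `x`, `y`, `z`.
#' @export
detect_ligand_features <- function(atoms, bonds, mol_id = "ligand") {
  stopifnot(is.data.frame(atoms), is.data.frame(bonds))
  n <- nrow(atoms)
  el <- atoms$element
  charge <- atoms$charge %||% rep(0L, n)
  pos <- coord_matrix(atoms)

  adj <- vector("list", n)
  border <- matrix(0L, n, n)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds$i[b]; j <- bonds$j[b]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    border[i, j] <- border[j, i] <- bonds$order[b]
  }
  degree <- purrr::map_int(adj, length)
  exp_h <- purrr::map_int(seq_len(n), function(i) sum(el[adj[[i]]] == "H"))

  # bond-order sum counting aromatic bonds as 1.5
  bosum <- purrr::map_dbl(seq_len(n), function(i) {
    o <- border[i, adj[[i]]]
    sum(ifelse(o == 4, 1.5, o))
  })
  val <- unname(DEFAULT_VALENCE[el])
  val[is.na(val)] <- 0
  # charge-adjusted valence for N (+1 -> 4) and O (-1 -> 1) and the like
  val <- val + ifelse(el %in% c("N", "P"), charge,
               ifelse(el %in% c("O", "S"), charge, 0))
  has_explicit_h <- any(el == "H")
  imp_h <- if (has_explicit_h) rep(0L, n) else
    pmax(0L, as.integer(round(val - bosum)))
  n_h <- exp_h + imp_h

  rings <- aromatic_rings(el, adj, border, mol_id)
  aromatic_atom <- rep(FALSE, n)
  for (r in rings) aromatic_atom[r] <- TRUE

  feats <- list()
  add <- function(type, xyz) {
    xyz <- unname(xyz)
    feats[[length(feats) + 1]] <<- tibble(type = type, x = xyz[1], y = xyz[2],
                                          z = xyz[3])
  }

  is_no <- el %in% c("N", "O")
  for (i in which(is_no & n_h >= 1)) add("HydrogenDonor", pos[i, ])
  heavy_deg <- purrr::map_int(seq_len(n), function(i) sum(el[adj[[i]]] != "H"))
  acceptor <- is_no & charge <= 0 &
    ifelse(el == "N", heavy_deg + n_h <= 3, TRUE)
  for (i in which(acceptor)) add("HydrogenAcceptor", pos[i, ])

  for (r in rings) add("Aromatic", colMeans(pos[r, , drop = FALSE]))

  # hydrophobic: carbons (non-aromatic) whose neighbours are all C or H
  plain_c <- which(el == "C" & !aromatic_atom &
                   purrr::map_lgl(seq_len(n), function(i)
                     all(el[adj[[i]]] %in% c("C", "H"))))
  if (length(plain_c) >= 3) {
    unvisited <- plain_c
    while (length(unvisited) > 0) {
      queue <- unvisited[1]; members <- integer(0)
      while (length(queue) > 0) {
        v <- queue[1]; queue <- queue[-1]
        if (!(v %in% unvisited)) next
        unvisited <- setdiff(unvisited, v)
        members <- c(members, v)
        queue <- c(queue, intersect(adj[[v]], unvisited))
      }
      if (length(members) >= 3) {
        add("Hydrophobic", colMeans(pos[members, , drop = FALSE]))
      }
    }
  }

  guanidine_c <- integer(0)
  for (i in which(el == "C")) {
    nb_n <- adj[[i]][el[adj[[i]]] == "N"]
    if (length(nb_n) >= 2 && any(border[i, nb_n] == 2)) {
      guanidine_c <- c(guanidine_c, i)
      add("PositiveIon", colMeans(pos[c(i, nb_n), , drop = FALSE]))
    }
  }
  guan_n <- unique(unlist(adj[guanidine_c]))
  for (i in which(el == "N" & charge > 0)) {
    if (!(i %in% guan_n)) add("PositiveIon", pos[i, ])
  }

  # acid groups: C/S/P centre with >= 2 terminal oxygens
  grouped_o <- integer(0)
  for (i in which(el %in% c("C", "S", "P"))) {
    nb_o <- adj[[i]][el[adj[[i]]] == "O" & heavy_deg[adj[[i]]] == 1]
    if (length(nb_o) >= 2 && any(charge[nb_o] < 0 | border[i, nb_o] == 2)) {
      grouped_o <- c(grouped_o, nb_o)
      add("NegativeIon", colMeans(pos[c(i, nb_o), , drop = FALSE]))
    }
  }
  for (i in which(charge < 0)) {
    if (!(i %in% grouped_o)) add("NegativeIon", pos[i, ])
  }

  if (length(feats) == 0) {
    return(tibble(type = character(), x = double(), y = double(), z = double()))
  }
  bind_rows(feats)
}

# 5/6-membered rings considered aromatic: every ring atom is C/N/O/S and
# every ring bond is either marked aromatic (order 4) or the ring carries
# an alternating pattern (each ring atom is in >= 1 double/aromatic bond).
aromatic_rings <- function(el, adj, border, mol_id) {
  n <- length(el)
  edges <- which(upper.tri(border) & border > 0, arr.ind = TRUE)
  if (nrow(edges) == 0) return(list())
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  rings <- tryCatch(small_rings(g, max_size = 6),
                    error = function(e) abort(paste0(
                      "Could not perceive rings/aromaticity for molecule ",
                      mol_id, ": ", conditionMessage(e))))
  keep <- list()
  for (r in rings) {
    if (!(length(r) %in% c(5L, 6L))) next
    if (!all(el[r] %in% c("C", "N", "O", "S"))) next
    cyc <- c(r, r[1])
    orders <- purrr::map_int(seq_along(r), function(k)
      as.integer(border[cyc[k], cyc[k + 1]]))
    if (all(orders == 4L)) { keep[[length(keep) + 1]] <- r; next }
    sp2 <- purrr::map_lgl(r, function(i)
      any(border[i, adj[[i]]] %in% c(2L, 4L)))
    if (all(sp2)) keep[[length(keep) + 1]] <- r
  }
  keep
}

# All simple cycles of length <= max_size, deduplicated, via DFS from each
# edge. Molecules here are small, so exhaustive search is fine.
small_rings <- function(g, max_size = 6) {
  n <- igraph::vcount(g)
  adj <- igraph::as_adj_list(g)
  adj <- purrr::map(adj, as.integer)
  found <- new.env()
  out <- list()
  walk <- function(path) {
    last <- path[length(path)]
    for (nb in adj[[last]]) {
      if (nb == path[1] && length(path) >= 3) {
        key <- paste(sort(path), collapse = "-")
        if (is.null(found[[key]])) {
          found[[key]] <- TRUE
          out[[length(out) + 1]] <<- path
        }
      } else if (!(nb %in% path) && length(path) < max_size && nb > path[1]) {
        walk(c(path, nb))
      }
    }
  }
  for (v in seq_len(n)) walk(v)
  out
}

#' Detect features for every conformer of a library
#'
#' Adds a `features` list-column with the per-conformer feature tibbles.
#'
#' @param library A library tibble.
#' @return The library with a `features` list-column.
#' @export
featurize_library <- function(library) {
  library$features <- purrr::pmap(
    list(library$atoms, library$bonds, library$mol_id),
    function(a, b, id) detect_ligand_features(a, b, mol_id = id))
  library
}
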