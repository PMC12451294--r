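# Heterogeneous pocket-pharmacophore graph.
#
# Pharmacophore nodes are fully connected among themselves; each center is
# connected to its k nearest retained protein atoms; protein atoms are
# connected to each other within a distance cutoff. Edges are stored
# directed-symmetric (both directions) for message passing. Node indexing
# puts the N pharmacophore nodes first, then the M protein nodes.

#' Build the pocket-pharmacophore graph
#'
#' The retained protein node set is the union, over pharmacophore
#' centers, of each center's `k` nearest pocket atoms.
#'
#' @param pocket A `phg_pocket`.
#' @param ph A pharmacophore, or an N x 3 coordinate matrix (for noise
#'   initialisation during sampling).
#' @param features Optional N x 6 feature matrix when `ph` is a matrix;
#'   defaults to the one-hot encoding when `ph` is a pharmacophore.
#' @param k Neighbour count for pharm-protein wiring (default 8; clamped
#'   to the pocket size with a warning).
#' @param protein_cutoff Protein-protein edge cutoff in Angstroms
#'   (default 4.5).
#' @return A `phg_graph` list: `x_pharm` (N x 3), `f_pharm` (N x 6),
#'   `x_prot` (M x 3), `a_prot` (M x na one-hot), `edge_src`, `edge_dst`,
#'   `edge_type` (1 = pharm-pharm, 2 = pharm-protein, 3 =
#'   protein-protein), `frame_offset`, and the wiring parameters.
#' @export
build_graph <- function(pocket, ph, features = NULL, k = 8L,
                        protein_cutoff = 4.5) {
  stopifnot(is_pocket(pocket), k >= 1)
  if (is_pharmacophore(ph) || (is.data.frame(ph) && "type" %in% names(ph))) {
    ph <- validate_pharmacophore(as_tibble(ph))
    xp <- ph_positions(ph)
    fp <- feature_onehot(ph$type)
  } else {
    xp <- as.matrix(ph)
    stopifnot(ncol(xp) == 3)
    fp <- features %||% matrix(0, nrow(xp), n_feature_types())
  }
  n <- nrow(xp)
  if (n < 1) abort("Graph needs at least one pharmacophore node.")
  xa <- coord_matrix(pocket)
  m_all <- nrow(xa)
  if (k > m_all) {
    warn(paste0("k = ", k, " exceeds pocket size ", m_all, "; clamping."))
    k <- m_all
  }
  d <- cross_dist(xp, xa)
  knn <- t(apply(d, 1, function(row) order(row)[seq_len(k)]))
  if (k == 1) knn <- matrix(knn, ncol = 1)
  kept <- sort(unique(as.integer(knn)))
  m <- length(kept)
  x_prot <- xa[kept, , drop = FALSE]
  a_prot <- atom_onehot(pocket$element[kept])

  src <- integer(0); dst <- integer(0); typ <- integer(0)
  if (n > 1) {
    pp <- expand.grid(i = seq_len(n), j = seq_len(n))
    pp <- pp[pp$i != pp$j, ]
    src <- c(src, pp$i); dst <- c(dst, pp$j); typ <- c(typ, rep(1L, nrow(pp)))
  }
  for (i in seq_len(n)) {
    nb <- n + match(knn[i, ], kept)
    src <- c(src, nb, rep(i, k)); dst <- c(dst, rep(i, k), nb)
    typ <- c(typ, rep(2L, 2 * k))
  }
  if (m > 1) {
    dp <- cross_dist(x_prot, x_prot)
    pairs <- which(dp <= protein_cutoff & upper.tri(dp), arr.ind = TRUE)
    if (nrow(pairs) > 0) {
      a <- n + pairs[, 1]; b <- n + pairs[, 2]
      src <- c(src, a, b); dst <- c(dst, b, a)
      typ <- c(typ, rep(3L, 2 * nrow(pairs)))
    }
  }
  structure(list(
    x_pharm = xp, f_pharm = fp, x_prot = x_prot, a_prot = a_prot,
    edge_src = src, edge_dst = dst, edge_type = typ,
    frame_offset = c(0, 0, 0), k = k, protein_cutoff = protein_cutoff,
    pocket_index = kept), class = "phg_graph")
}

#' @export
print.phg_graph <- function(x, ...) {
  cat("# Pocket-pharmacophore graph:", nrow(x$x_pharm), "pharm node(s),",
      nrow(x$x_prot), "protein node(s),", length(x$edge_src), "directed edge(s)\n")
  invisible(x)
}

#' Center a graph on its protein centroid
#'
#' Translates all coordinates so the protein-node centroid sits at the
#' origin and records the applied offset, making the denoiser's frame
#' translation-free. [uncenter_frame()] restores the original
#' coordinates exactly.
#'
#' @param g A `phg_graph`.
#' @return The centered (or restored) graph.
#' @export
center_frame <- function(g) {
  ctr <- colMeans(g$x_prot)
  g$x_prot <- sweep(g$x_prot, 2, ctr)
  g$x_pharm <- sweep(g$x_pharm, 2, ctr)
  g$frame_offset <- g$frame_offset + ctr
  g
}

#' @rdname center_frame
#' @export
uncenter_frame <- function(g) {
  off <- g$frame_offset
  g$x_prot <- sweep(g$x_prot, 2, off, `+`)
  g$x_pharm <- sweep(g$x_pharm, 2, off, `+`)
  g$frame_offset <- c(0, 0, 0)
  g
}

#' Dump a graph to JSON (debugging aid)
#'
#' @param g A `phg_graph`.
#' @param path Optional output file.
#' @return JSON text.
#' @export
graph_to_json <- function(g, path = NULL) {
  obj <- list(x_pharm = g$x_pharm, f_pharm = g$f_pharm, x_prot = g$x_prot,
              a_prot = g$a_prot, edge_src = g$edge_src, edge_dst = g$edge_dst,
              edge_type = g$edge_type, frame_offset = g$frame_offset)
  txt <- jsonlite::toJSON(obj, digits = NA)
  if (!is.null(path)) writeLines(as.character(txt), path)
  as.character(txt)
}
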