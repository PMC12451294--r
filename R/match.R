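# Pharmacophore matching: injective type-consistent assignment of
# conformer features to all query centers, scored by closed-form
# least-squares rigid superposition (Kabsch).

#' Least-squares rigid superposition of paired points
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' `source` rows mapped onto `target` rows (Kabsch algorithm).
#'
#' @param source,target n x 3 matrices of paired coordinates.
#' @return List with `rmsd`, `rotation` (3 x 3), `translation` (length
#'   3), and `aligned` (the transformed source points).
#' @export
kabsch <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  stopifnot(nrow(source) == nrow(target), ncol(source) == 3, ncol(target) == 3)
  cs <- colMeans(source); ct <- colMeans(target)
  P <- sweep(source, 2, cs); Q <- sweep(target, 2, ct)
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  aligned <- sweep(P %*% t(R), 2, ct, `+`)
  rmsd <- sqrt(mean(rowSums((aligned - target)^2)))
  list(rmsd = rmsd, rotation = R, translation = ct - as.numeric(cs %*% t(R)),
       aligned = aligned)
}

#' Match conformer features against a pharmacophore query
#'
#' A conformer matches if some injective type-consistent assignment of
#' its features to all query centers admits a rigid superposition with
#' RMSD at most `rmsd_tol` (1 Angstrom by default, the screening
#' criterion). The search enumerates assignments with
#' distance-compatibility pruning: a partial assignment is abandoned when
#' some pairwise center distance disagrees with the corresponding feature
#' distance by more than `2 * sqrt(N) * rmsd_tol` — the provable bound
#' under which no pruned completion can reach RMSD <= `rmsd_tol`, so the
#' decision equals exhaustive enumeration.
#'
#' @param features Tibble of conformer features (`type`, `x`, `y`, `z`).
#' @param query A pharmacophore.
#' @param rmsd_tol RMSD tolerance in Angstroms (default 1.0).
#' @return List with `matched`, `rmsd` (the minimising RMSD, `Inf` when
#'   no type-consistent assignment survives), `assignment` (feature row
#'   index per query center), and `aligned` (feature positions mapped
#'   into the query frame, for receptor-exclusion filtering).
#' @export
match_pharmacophore <- function(features, query, rmsd_tol = 1.0) {
  query <- validate_pharmacophore(as_tibble(query))
  nq <- nrow(query)
  qpos <- ph_positions(query)
  if (nrow(features) == 0) {
    return(list(matched = FALSE, rmsd = Inf, assignment = NULL, aligned = NULL))
  }
  fpos <- coord_matrix(features)
  cand <- purrr::map(seq_len(nq), function(i) which(features$type == query$type[i]))
  if (any(purrr::map_int(cand, length) == 0)) {
    return(list(matched = FALSE, rmsd = Inf, assignment = NULL, aligned = NULL))
  }
  qd <- cross_dist(qpos, qpos)
  fd <- cross_dist(fpos, fpos)
  prune <- 2 * sqrt(nq) * rmsd_tol

  # assign rarest-candidate centers first
  ord <- order(purrr::map_int(cand, length))
  best <- list(rmsd = Inf, assignment = NULL, aligned = NULL)
  assign_vec <- integer(nq)

  recurse <- function(pos) {
    if (pos > nq) {
      fit <- kabsch(fpos[assign_vec, , drop = FALSE], qpos)
      if (fit$rmsd < best$rmsd) {
        best <<- list(rmsd = fit$rmsd, assignment = assign_vec,
                      aligned = fit$aligned)
      }
      return(invisible(NULL))
    }
    ci <- ord[pos]
    for (f in cand[[ci]]) {
      if (f %in% assign_vec[ord[seq_len(pos - 1)]]) next
      ok <- TRUE
      for (prev in seq_len(pos - 1)) {
        cj <- ord[prev]
        if (abs(qd[ci, cj] - fd[f, assign_vec[cj]]) > prune) { ok <- FALSE; break }
      }
      if (!ok) next
      assign_vec[ci] <<- f
      recurse(pos + 1)
      assign_vec[ci] <<- 0L
    }
    invisible(NULL)
  }
  recurse(1)
  list(matched = is.finite(best$rmsd) && best$rmsd <= rmsd_tol,
       rmsd = best$rmsd, assignment = best$assignment, aligned = best$aligned)
}
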