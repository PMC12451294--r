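# Library screening and retrospective evaluation metrics.

#' Screen a ligand library with a pharmacophore query
#'
#' A molecule is a hit if any of its conformers matches the query (see
#' [match_pharmacophore()]); the best-matching conformer (lowest RMSD) is
#' recorded, one entry per molecule, mirroring the one-conformer-per-
#' molecule convention of pharmacophore search results.
#'
#' @param library A library tibble; features are computed on the fly when
#'   the `features` list-column is absent. An optional `active` logical
#'   column (or the `actives` argument) supplies labels.
#' @param query A pharmacophore.
#' @param rmsd_tol RMSD tolerance in Angstroms (default 1.0).
#' @param actives Optional character vector of active molecule ids.
#' @param receptor Optional `phg_pocket`; when given, hits whose aligned
#'   feature positions fall within `exclusion_radius` of any pocket heavy
#'   atom are rejected (receptor exclusion, off by default).
#' @param exclusion_radius Steric clash radius in Angstroms (default 1.5).
#' @param query_id Identifier stored on the result.
#' @return A `phg_screen` tibble: one row per molecule with `mol_id`,
#'   `hit`, `best_rmsd`, `best_conformer` and (when labels are known)
#'   `active`.
#' @export
screen_library <- function(library, query, rmsd_tol = 1.0, actives = NULL,
                           receptor = NULL, exclusion_radius = 1.5,
                           query_id = "query") {
  query <- validate_pharmacophore(as_tibble(query))
  if (nrow(library) == 0) {
    res <- tibble(mol_id = character(), hit = logical(), best_rmsd = double(),
                  best_conformer = integer(), active = logical())
    return(new_screen(res, query_id, rmsd_tol))
  }
  if (!"features" %in% names(library)) library <- featurize_library(library)
  prot_xyz <- if (!is.null(receptor)) coord_matrix(receptor) else NULL
  per_conf <- purrr::map(seq_len(nrow(library)), function(r) {
    m <- match_pharmacophore(library$features[[r]], query, rmsd_tol)
    if (m$matched && !is.null(prot_xyz)) {
      if (min(cross_dist(m$aligned, prot_xyz)) < exclusion_radius) {
        m$matched <- FALSE
        m$rmsd <- Inf
      }
    }
    tibble(mol_id = library$mol_id[r], conformer_id = library$conformer_id[r],
           matched = m$matched, rmsd = m$rmsd)
  })
  res <- bind_rows(per_conf) |>
    group_by(.data$mol_id) |>
    summarise(hit = any(.data$matched),
              best_rmsd = if (any(.data$matched))
                min(.data$rmsd[.data$matched]) else Inf,
              best_conformer = if (any(.data$matched))
                .data$conformer_id[.data$matched][which.min(.data$rmsd[.data$matched])]
              else NA_integer_) |>
    ungroup()
  labels <- NULL
  if (!is.null(actives)) {
    labels <- tibble(mol_id = unique(res$mol_id),
                     active = unique(res$mol_id) %in% actives)
  } else if ("active" %in% names(library)) {
    labels <- distinct(library[, c("mol_id", "active")])
  }
  if (!is.null(labels)) res <- left_join(res, labels, by = "mol_id")
  new_screen(res, query_id, rmsd_tol)
}

new_screen <- function(res, query_id, rmsd_tol) {
  attr(res, "query_id") <- query_id
  attr(res, "rmsd_tol") <- rmsd_tol
  class(res) <- c("phg_screen", class(tibble()))
  res
}

#' Enrichment factor of a screen result
#'
#' `EF = (actives among hits / hits) / (actives in database / database
#' size)`: 1 equals random selection, above 1 an enriched hit list. A
#' query with zero hits has undefined EF and is flagged for exclusion
#' from aggregation.
#'
#' @param result A `phg_screen` with an `active` column.
#' @param n_actives_db,n_total_db Database composition; defaults are
#'   taken from the result's own label column.
#' @return A one-row tibble: `ef`, `defined`, `n_hits`, `n_active_hits`.
#' @export
enrichment_factor <- function(result, n_actives_db = NULL, n_total_db = NULL) {
  n_total_db <- n_total_db %||% nrow(result)
  n_actives_db <- n_actives_db %||% sum(result$active)
  if (n_total_db <= 0) abort("Database size must be positive.")
  if (n_actives_db <= 0) abort("Database must contain at least one active.")
  hits <- result[result$hit, , drop = FALSE]
  if (nrow(hits) == 0) {
    return(tibble(ef = NA_real_, defined = FALSE, n_hits = 0L,
                  n_active_hits = 0L))
  }
  frac_hits <- sum(hits$active) / nrow(hits)
  frac_db <- n_actives_db / n_total_db
  tibble(ef = frac_hits / frac_db, defined = TRUE, n_hits = nrow(hits),
         n_active_hits = sum(hits$active))
}

#' Precision, recall and F1 of a screen result
#'
#' True positives are actives in the hit list, false positives decoys in
#' the hit list, false negatives actives missed. Precision is defined as
#' 0 (not undefined) for a zero-hit query so that F1 = 0; only EF carries
#' an undefined flag.
#'
#' @param result A `phg_screen`.
#' @param actives Optional character vector of active ids (defaults to
#'   the result's `active` column).
#' @return A one-row tibble: `precision`, `recall`, `f1`, `tp`, `fp`,
#'   `fn`.
#' @export
precision_recall_f1 <- function(result, actives = NULL) {
  act <- if (!is.null(actives)) result$mol_id %in% actives else result$active
  if (is.null(act)) abort("No activity labels available.")
  tp <- sum(result$hit & act)
  fp <- sum(result$hit & !act)
  fn <- sum(!result$hit & act)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  tibble(precision = precision, recall = recall, f1 = f1,
         tp = tp, fp = fp, fn = fn)
}

#' Filter queries by hit-list size
#'
#' Retains queries whose hit count does not exceed `max_hits` (by
#' default 1% of the database size), discarding unspecific queries.
#'
#' @param results A tibble of per-query summaries with an `n_hits`
#'   column, or a list of `phg_screen` results.
#' @param max_hits Maximum allowed hit count; default `0.01 * db_size`.
#' @param db_size Database size used for the default cutoff.
#' @return The retained rows (or list elements), in input order.
#' @export
filter_queries <- function(results, max_hits = NULL, db_size = NULL) {
  if (is.null(max_hits)) {
    if (is.null(db_size)) abort("Provide `max_hits` or `db_size`.")
    max_hits <- 0.01 * db_size
  }
  if (is.data.frame(results)) {
    return(results[results$n_hits <= max_hits, , drop = FALSE])
  }
  keep <- purrr::map_lgl(results, function(r) sum(r$hit) <= max_hits)
  results[keep]
}

#' Summarise one screen into a metric report row
#'
#' @param result A `phg_screen` with labels.
#' @param n_actives_db,n_total_db Database composition (defaulted from
#'   the labels).
#' @return One-row tibble: `query_id`, `n_hits`, `ef`, `ef_defined`,
#'   `precision`, `recall`, `f1`.
#' @export
screen_metrics <- function(result, n_actives_db = NULL, n_total_db = NULL) {
  efr <- enrichment_factor(result, n_actives_db, n_total_db)
  prf <- precision_recall_f1(result)
  tibble(query_id = attr(result, "query_id") %||% "query",
         n_hits = efr$n_hits, ef = efr$ef, ef_defined = efr$defined,
         precision = prf$precision, recall = prf$recall, f1 = prf$f1)
}

#' Plot a screen result
#'
#' Best-RMSD distribution of hits, split by activity label when known.
#'
#' @param object A `phg_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phg_screen <- function(object, ...) {
  hits <- object[object$hit, , drop = FALSE]
  p <- ggplot2::ggplot(hits, ggplot2::aes(x = .data$best_rmsd)) +
    ggplot2::geom_histogram(bins = 20) +
    ggplot2::labs(x = "Best conformer RMSD (Å)", y = "Hits")
  if ("active" %in% names(hits)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$active),
                                 labeller = ggplot2::label_both)
  }
  p
}
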