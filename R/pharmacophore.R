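#' Construct a pharmacophore
#'
#' A pharmacophore is a set of typed interaction points (centers), each a
#' 3D position in Angstroms plus one of the six feature types and a query
#' tolerance radius. It is represented as a tibble with columns `type`,
#' `x`, `y`, `z`, `radius` and class `phg_pharmacophore`, so it composes
#' with dplyr verbs.
#'
#' @param centers A data frame with columns `type`, `x`, `y`, `z` and
#'   optionally `radius`.
#' @param radius Default tolerance radius in Angstroms for centers lacking
#'   one. The 1 Angstrom default mirrors the RMSD matching tolerance used
#'   in screening.
#' @return A `phg_pharmacophore` tibble.
#' @examples
#' pharmacophore(data.frame(type = "Aromatic", x = 0, y = 0, z = 0))
#' @export
pharmacophore <- function(centers, radius = 1.0) {
  stopifnot(is.data.frame(centers))
  need <- c("type", "x", "y", "z")
  miss <- setdiff(need, names(centers))
  if (length(miss) > 0) {
    abort(paste0("pharmacophore() needs columns: ", paste(miss, collapse = ", ")))
  }
  ph <- as_tibble(centers)
  if (!"radius" %in% names(ph)) ph$radius <- radius
  ph <- ph[, c("type", "x", "y", "z", "radius")]
  validate_pharmacophore(ph)
}

validate_pharmacophore <- function(ph) {
  if (nrow(ph) < 1) abort("A pharmacophore needs at least one center.")
  assert_feature_type(ph$type)
  pos <- as.matrix(ph[, c("x", "y", "z")])
  if (!all(is.finite(pos))) abort("Pharmacophore center positions must be finite.")
  if (!all(ph$radius > 0)) abort("Pharmacophore center radii must be positive.")
  class(ph) <- c("phg_pharmacophore", class(tibble()))
  ph
}

is_pharmacophore <- function(x) inherits(x, "phg_pharmacophore")

#' @export
print.phg_pharmacophore <- function(x, ...) {
  cat("# Pharmacophore:", nrow(x), "center(s)\n")
  NextMethod()
}

ph_positions <- function(ph) coord_matrix(ph)

#' Randomly subsample pharmacophore centers
#'
#' Training-data augmentation: draws a subset size uniformly from
#' `[min_n, min(max_n, n)]` and keeps a uniform without-replacement subset
#' of the centers. Training samples carry between three and eight centers.
#'
#' @param ph A pharmacophore.
#' @param min_n,max_n Bounds on the subsampled size (defaults 3 and 8).
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used.
#' @return A pharmacophore with between `min_n` and `max_n` centers, each
#'   belonging to the input.
#' @export
subsample_pharmacophore <- function(ph, min_n = 3L, max_n = 8L, seed = NULL) {
  ph <- validate_pharmacophore(as_tibble(ph))
  n <- nrow(ph)
  if (n < min_n) {
    abort(paste0("Pharmacophore has ", n, " centers; at least ", min_n,
                 " are required for subsampling (sample excluded from training)."))
  }
  draw <- function() {
    sizes <- seq(min_n, min(max_n, n))
    size <- if (length(sizes) == 1) sizes else sample(sizes, 1L)
    keep <- sort(sample.int(n, size))
    ph[keep, ]
  }
  out <- if (is.null(seed)) draw() else with_seed(seed, draw())
  validate_pharmacophore(out)
}

#' Plot a pharmacophore
#'
#' Projects centers onto two chosen axes, colour-coded by feature type.
#'
#' @param object A pharmacophore.
#' @param axes Character vector of length 2 among `c("x","y","z")`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phg_pharmacophore <- function(object, axes = c("x", "y"), ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data[[axes[1]]], y = .data[[axes[2]]], colour = .data$type)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "Feature", x = paste0(axes[1], " (Å)"),
                  y = paste0(axes[2], " (Å)"))
}
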