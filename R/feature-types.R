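#' Pharmacophore feature types
#'
#' The six pharmacophore feature classes, in the canonical order used for
#' one-hot encoding throughout the package. The spelling matches the
#' Pharmit query dialect.
#'
#' @return Character vector of length 6.
#' @examples
#' feature_types()
#' @export
feature_types <- function() {
  c("HydrogenAcceptor", "HydrogenDonor", "Hydrophobic",
    "Aromatic", "NegativeIon", "PositiveIon")
}

#' @rdname feature_types
#' @export
n_feature_types <- function() 6L

assert_feature_type <- function(type) {
  bad <- setdiff(unique(type), feature_types())
  if (length(bad) > 0) {
    abort(paste0(
      "Unknown feature type(s): ", paste(bad, collapse = ", "),
      ". Valid types are: ", paste(feature_types(), collapse = ", "), "."))
  }
  invisible(type)
}

#' One-hot encode feature types
#'
#' @param type Character vector of feature type labels.
#' @return A `length(type)` x 6 matrix with a single 1 per row, columns in
#'   [feature_types()] order.
#' @export
feature_onehot <- function(type) {
  assert_feature_type(type)
  idx <- match(type, feature_types())
  m <- matrix(0, length(type), n_feature_types(),
              dimnames = list(NULL, feature_types()))
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

# Supported element table for pocket atom typing; the final slot collects
# everything else so the one-hot dimension is fixed.
#' Pocket atom-type vocabulary
#'
#' Elements distinguished in the protein-node one-hot encoding; any other
#' element maps to the final `other` slot.
#'
#' @return Character vector of length 10.
#' @export
atom_type_vocab <- function() {
  c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "other")
}

atom_type_index <- function(element) {
  idx <- match(element, atom_type_vocab())
  idx[is.na(idx)] <- length(atom_type_vocab())
  idx
}

atom_onehot <- function(element) {
  idx <- atom_type_index(element)
  m <- matrix(0, length(idx), length(atom_type_vocab()),
              dimnames = list(NULL, atom_type_vocab()))
  m[cbind(seq_along(idx), idx)] <- 1
  m
}
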