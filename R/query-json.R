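#' Write a pharmacophore as a Pharmit-dialect JSON query
#'
#' Serialises the centers as a JSON object with a `points` array; each
#' point carries `name` (feature label), `x`, `y`, `z`, `radius` and
#' `enabled = true`. `parse_query(write_query(ph))` recovers the
#' pharmacophore exactly (coordinates kept to full double precision).
#'
#' @param ph A pharmacophore.
#' @param path Optional file path; if `NULL` the JSON text is returned.
#' @return JSON text (invisibly when written to `path`).
#' @export
write_query <- function(ph, path = NULL) {
  ph <- validate_pharmacophore(as_tibble(ph))
  points <- purrr::pmap(ph, function(type, x, y, z, radius) {
    list(name = type, x = x, y = y, z = z, radius = radius, enabled = TRUE)
  })
  txt <- jsonlite::toJSON(list(points = points), auto_unbox = TRUE, digits = NA,
                          pretty = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(as.character(txt), path)
  invisible(as.character(txt))
}

#' Parse a Pharmit-dialect JSON query
#'
#' Reads a JSON object with a `points` array. Points with
#' `enabled = false` are skipped; unknown feature names are rejected with
#' an error listing the six valid labels.
#'
#' @param json_text JSON text, or a path to a JSON file.
#' @return A pharmacophore.
#' @export
parse_query <- function(json_text) {
  if (length(json_text) == 1 && !grepl("[{\\[]", json_text) && file.exists(json_text)) {
    json_text <- paste(readLines(json_text, warn = FALSE), collapse = "\n")
  }
  obj <- jsonlite::fromJSON(json_text, simplifyVector = FALSE)
  if (is.null(obj$points)) abort("Query JSON must contain a 'points' array.")
  pts <- purrr::keep(obj$points, function(p) isTRUE(p$enabled %||% TRUE))
  if (length(pts) == 0) abort("Query contains no enabled points.")
  centers <- purrr::map(pts, function(p) {
    assert_feature_type(p$name)
    tibble(type = p$name, x = as.numeric(p$x), y = as.numeric(p$y),
           z = as.numeric(p$z), radius = as.numeric(p$radius %||% 1.0))
  })
  pharmacophore(bind_rows(centers))
}
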