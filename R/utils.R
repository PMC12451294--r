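# Internal utilities: seeded substreams and small geometry helpers.

#' Derive a reproducible substream seed
#'
#' A single user-facing seed fans out to independent named substreams
#' (data shuffling, noise draws, parameter initialisation, per-sample
#' generation). The derivation is a fixed integer hash of the stream name
#' folded into the master seed, kept within the 32-bit range R requires.
#'
#' @param seed Integer master seed.
#' @param name Character stream name.
#' @param index Optional integer index for per-item streams.
#' @return An integer seed.
#' @export
substream_seed <- function(seed, name, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (cp in utf8ToInt(name)) h <- (h * 131 + cp) %% 2147483629
  s <- (as.double(seed) %% 2147483629) * 48271 %% 2147483629
  as.integer((s + h + 1299721 * (as.double(index) %% 1601)) %% 2147483629)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Pairwise Euclidean distances between the rows of two n x 3 matrices.
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# Uniformly random rotation matrix (det +1) via QR of a Gaussian matrix.
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

coord_matrix <- function(df) {
  unname(as.matrix(df[, c("x", "y", "z")]))
}

# Roughly even directions on the unit sphere (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
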