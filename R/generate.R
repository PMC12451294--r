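# Ancestral sampling: generate a pharmacophore for a pocket by iterative
# denoising from random initialisation.
#
# All Gaussian draws are made in a canonical pocket frame (principal axes
# of the protein coordinates, signs fixed by third moments, det +1) and
# rotated into the world frame. With a fixed seed this makes sampling
# exactly equivariant: rotating the pocket rotates the output centers.

canonical_rotation <- function(coords) {
  ctr <- colMeans(coords)
  xc <- sweep(coords, 2, ctr)
  ev <- eigen(cov(xc), symmetric = TRUE)
  R <- ev$vectors
  for (j in 1:3) {
    m3 <- sum((xc %*% R[, j])^3)
    if (m3 < 0) R[, j] <- -R[, j]
  }
  if (det(R) < 0) R[, 3] <- -R[, 3]
  R
}

# All Gaussian draws used by one generation run, taken from one seeded
# substream in canonical-frame coordinates. The initial state depends on
# the pocket only through its centroid and principal frame, never on the
# pharmacophore layout of its sites.
generation_draws <- function(n_centers, T, seed) {
  with_seed(substream_seed(seed, "sample"), {
    list(init_x = matrix(rnorm(n_centers * 3), n_centers, 3),
         init_f = matrix(rnorm(n_centers * 6), n_centers, 6),
         step_x = purrr::map(seq_len(T), function(i)
           matrix(rnorm(n_centers * 3), n_centers, 3)),
         step_f = purrr::map(seq_len(T), function(i)
           matrix(rnorm(n_centers * 6), n_centers, 6)))
  })
}

#' Generate a pharmacophore for a pocket
#'
#' Initialises `n_centers` pharmacophore nodes with random feature
#' vectors and random coordinates near the center of the binding pocket,
#' then runs the ancestral denoising chain of the variance-preserving
#' diffusion process with the trained denoiser. The graph is wired from
#' the current noisy coordinates exactly as during training and, by
#' default, rewired at every step as the centers move. The final feature
#' type of each center is the argmax over its 6-dimensional feature
#' vector; coordinates are returned in the original pocket frame.
#' Deterministic given `seed`, and exactly equivariant: rotating the
#' pocket rotates the output (noise is drawn in a canonical pocket
#' frame).
#'
#' @param pocket A `phg_pocket`.
#' @param model A trained `phg_denoiser` (pass `allow_untrained = TRUE`
#'   to sample from random weights, e.g. for diagnostics).
#' @param n_centers Number of centers to generate.
#' @param seed Integer seed.
#' @param init_spread Standard deviation (Angstroms) of the initial
#'   coordinate noise about the pocket centroid. The default 1 matches
#'   the unit-variance terminal state of the variance-preserving
#'   forward process.
#' @param T Optional override of the step count (default: the model's
#'   schedule, 1000 at full scale).
#' @param rewire Rebuild the graph topology from current coordinates at
#'   every step (default `TRUE`, matching the training-time wiring;
#'   `FALSE` wires once from the initial positions and holds the
#'   topology fixed).
#' @param allow_untrained Permit sampling with untrained weights.
#' @return A pharmacophore with exactly `n_centers` centers.
#' @export
generate <- function(pocket, model, n_centers, seed = 1L, init_spread = 1,
                     T = NULL, rewire = TRUE, allow_untrained = FALSE) {
  stopifnot(is_pocket(pocket), inherits(model, "phg_denoiser"), n_centers >= 1)
  if (!model$trained && !allow_untrained) {
    abort("Model is untrained; pass allow_untrained = TRUE to sample anyway.")
  }
  cfg <- model$config
  T <- as.integer(T %||% cfg$T)
  sched <- make_schedule(T, cfg$power, cfg$clip)
  prot_xyz <- coord_matrix(pocket)
  Rc <- canonical_rotation(prot_xyz)
  ctr <- colMeans(prot_xyz)
  ij <- which(matrix(TRUE, n_centers, n_centers) & !diag(n_centers),
              arr.ind = TRUE)
  prep <- list(x_pocket = sweep(prot_xyz, 2, ctr),
               a_pocket = atom_onehot(pocket$element),
               pp_pairs = which(cross_dist(prot_xyz, prot_xyz) <=
                                  cfg$protein_cutoff &
                                  upper.tri(diag(nrow(prot_xyz))),
                                arr.ind = TRUE),
               pharm_src = as.integer(ij[, 1]),
               pharm_dst = as.integer(ij[, 2]))

  draws <- generation_draws(n_centers, T, seed)
  z <- list(coords = init_spread * draws$init_x %*% t(Rc),
            feats = draws$init_f)
  r_max <- sqrt(max(rowSums(prep$x_pocket^2))) + 3
  w <- wire_state(z$coords, prep, cfg)

  for (t in seq(T, 1L)) {
    if (rewire && t < T) w <- wire_state(z$coords, prep, cfg)
    g <- list(x_prot = prep$x_pocket[w$kept, , drop = FALSE],
              a_prot = prep$a_pocket[w$kept, , drop = FALSE],
              edge_src = w$src, edge_dst = w$dst, edge_type = w$typ)
    eps_hat <- denoise_step(model, g, z, t)
    s <- t - 1L
    a_t <- sched$alpha[t + 1]; s_t <- sched$sigma[t + 1]
    a_s <- sched$alpha[s + 1]; s_s <- sched$sigma[s + 1]
    a_ts <- a_t / a_s
    s2_ts <- s_t^2 - a_ts^2 * s_s^2
    post_sd <- if (s == 0) 0 else sqrt(s2_ts) * s_s / s_t
    # x0-parameterised posterior with clamping of the denoised estimate:
    # the polynomial schedule's tail amplifies the state by 1/alpha_{t|s}
    # per step, so an unclamped chain can diverge when the high-t noise
    # prediction is imperfect. Coordinates are clamped radially to the
    # pocket radius plus margin (rotation covariant), features to a
    # generous interval around the scaled one-hot range.
    posterior <- function(zc, x0_hat, xi) {
      (a_ts * s_s^2 / s_t^2) * zc + (a_s * s2_ts / s_t^2) * x0_hat +
        post_sd * xi
    }
    x0_c <- (z$coords - s_t * eps_hat$coords) / a_t
    rad <- sqrt(rowSums(x0_c^2))
    x0_c <- x0_c * pmin(1, r_max / pmax(rad, 1e-12))
    x0_f <- pmin(pmax((z$feats - s_t * eps_hat$feats) / a_t, -1), 1)
    z <- list(coords = posterior(z$coords, x0_c, draws$step_x[[t]] %*% t(Rc)),
              feats = posterior(z$feats, x0_f, draws$step_f[[t]]))
    if (any(!is.finite(z$coords)) || any(!is.finite(z$feats))) {
      abort(paste0("Non-finite state during sampling at step ", t, "."))
    }
  }
  coords <- sweep(z$coords, 2, ctr, `+`)
  types <- feature_types()[apply(z$feats, 1, which.max)]
  pharmacophore(tibble(type = types, x = coords[, 1], y = coords[, 2],
                       z = coords[, 3]))
}

#' Generate a batch of pharmacophores of several sizes
#'
#' The screening protocol samples several pharmacophores per size (e.g.
#' five each of sizes 3-8, thirty per target) with independent seeded
#' substreams.
#'
#' @param pocket A `phg_pocket`.
#' @param model A trained `phg_denoiser`.
#' @param sizes Integer vector of center counts (default `3:8`).
#' @param reps Samples per size (default 5).
#' @param seed Master seed.
#' @param ... Passed on to [generate()].
#' @return A tibble with one row per sample: `size`, `rep`, `seed`, and a
#'   `pharmacophore` list-column.
#' @export
generate_batch <- function(pocket, model, sizes = 3:8, reps = 5, seed = 1L,
                           ...) {
  stopifnot(length(sizes) >= 1)
  if (reps == 0) {
    return(tibble(size = integer(), rep = integer(), seed = integer(),
                  pharmacophore = list()))
  }
  grid <- expand.grid(rep = seq_len(reps), size = as.integer(sizes))
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    s <- substream_seed(seed, "generate_batch", i)
    tibble(size = grid$size[i], rep = grid$rep[i], seed = s,
           pharmacophore = list(generate(pocket, model, grid$size[i],
                                         seed = s, ...)))
  })
  bind_rows(rows)
}
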