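# Training loop: Adam on the noise-prediction MSE over batched graphs.

# Walk two parallel parameter trees applying f leaf-wise; named levels
# are matched by name so leaf ordering cannot drift between trees.
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    nms <- names(a)
    if (!is.null(nms) && !anyNA(nms) && all(nms != "")) {
      return(setNames(lapply(nms, function(k) tree_map2(f, a[[k]], b[[k]])),
                      nms))
    }
    return(purrr::map2(a, b, function(x, y) tree_map2(f, x, y)))
  }
  f(a, b)
}

tree_sum <- function(f, a) {
  if (is.list(a)) return(sum(purrr::map_dbl(a, function(x) tree_sum(f, x))))
  f(a)
}

# Precompute the static parts of one training pair: the full pocket in
# the pocket-centroid frame, its atom encodings and protein-protein
# adjacency, and the clean pharmacophore state in the same frame. The
# frame is the full-pocket centroid (not a retained subset), so it does
# not depend on the per-draw wiring; the network itself only sees
# coordinate differences and is translation invariant.
prepare_pair <- function(pocket, ph, cfg) {
  n <- nrow(ph)
  if (n > 8L) ph <- subsample_pharmacophore(ph)
  xa <- coord_matrix(pocket)
  ctr <- colMeans(xa)
  xa <- sweep(xa, 2, ctr)
  pp_pairs <- which(cross_dist(xa, xa) <= cfg$protein_cutoff &
                      upper.tri(diag(nrow(xa))), arr.ind = TRUE)
  ij <- which(matrix(TRUE, n, n) & !diag(n), arr.ind = TRUE)
  list(x_pocket = xa, a_pocket = atom_onehot(pocket$element),
       pp_pairs = pp_pairs,
       pharm_src = as.integer(ij[, 1]), pharm_dst = as.integer(ij[, 2]),
       z0 = list(coords = sweep(ph_positions(ph), 2, ctr),
                 feats = cfg$feat_scale * feature_onehot(ph$type)),
       n_pharm = n)
}

# Wire one graph state: pharm nodes fully connected, each pharm node to
# its k nearest pocket atoms (union retained), retained protein pairs
# within the cutoff. Wiring is computed from the current (noised) pharm
# coordinates, exactly as at sampling time.
wire_state <- function(coords, prep, cfg) {
  n <- nrow(coords)
  m_all <- nrow(prep$x_pocket)
  k <- min(cfg$k, m_all)
  d <- cross_dist(coords, prep$x_pocket)
  knn <- matrix(0L, n, k)
  for (i in seq_len(n)) knn[i, ] <- order(d[i, ])[seq_len(k)]
  kept <- sort(unique(as.integer(knn)))
  # pharm-protein edges, both directions
  pP_pharm <- rep(seq_len(n), each = k)
  pP_prot <- n + match(as.integer(t(knn)), kept)
  src <- c(prep$pharm_src, pP_prot, pP_pharm)
  dst <- c(prep$pharm_dst, pP_pharm, pP_prot)
  typ <- c(rep(1L, length(prep$pharm_src)), rep(2L, 2L * n * k))
  if (nrow(prep$pp_pairs) > 0) {
    keep_row <- prep$pp_pairs[, 1] %in% kept & prep$pp_pairs[, 2] %in% kept
    if (any(keep_row)) {
      a <- n + match(prep$pp_pairs[keep_row, 1], kept)
      b <- n + match(prep$pp_pairs[keep_row, 2], kept)
      src <- c(src, a, b); dst <- c(dst, b, a)
      typ <- c(typ, rep(3L, 2L * length(a)))
    }
  }
  list(kept = kept, src = src, dst = dst, typ = typ)
}

# Concatenate prepared pairs into one block-diagonal batch graph. All
# pharm nodes come first (graph by graph), then all protein nodes.
assemble_batch <- function(pairs, ts, sched, cfg, noise_seed) {
  nb <- length(pairs)
  noised <- with_seed(noise_seed, purrr::map(seq_len(nb), function(i) {
    noise_sample(pairs[[i]]$z0, sched, ts[i])
  }))
  wired <- purrr::map(seq_len(nb), function(i)
    wire_state(noised[[i]]$z$coords, pairs[[i]], cfg))
  n_pharm <- purrr::map_int(pairs, "n_pharm")
  n_prot <- purrr::map_int(wired, function(w) length(w$kept))
  off_pharm <- cumsum(c(0L, head(n_pharm, -1)))
  off_prot <- sum(n_pharm) + cumsum(c(0L, head(n_prot, -1)))
  coords <- do.call(rbind, purrr::map(noised, function(x) x$z$coords))
  feats <- do.call(rbind, purrr::map(noised, function(x) x$z$feats))
  eps <- list(coords = do.call(rbind, purrr::map(noised, function(x) x$eps$coords)),
              feats = do.call(rbind, purrr::map(noised, function(x) x$eps$feats)))
  x_prot <- do.call(rbind, purrr::map(seq_len(nb), function(i)
    pairs[[i]]$x_pocket[wired[[i]]$kept, , drop = FALSE]))
  a_prot <- do.call(rbind, purrr::map(seq_len(nb), function(i)
    pairs[[i]]$a_pocket[wired[[i]]$kept, , drop = FALSE]))
  edges <- purrr::map(seq_len(nb), function(i) {
    w <- wired[[i]]
    np <- n_pharm[i]
    remap <- function(idx) {
      out <- idx + off_pharm[i]
      prot <- idx > np
      out[prot] <- idx[prot] - np + off_prot[i]
      out
    }
    list(src = remap(w$src), dst = remap(w$dst), type = w$typ)
  })
  t_nodes <- c(rep(ts, n_pharm), rep(ts, n_prot)) / sched_T(sched)
  list(X = rbind(coords, x_prot),
       S_raw = scalar_inputs(sum(n_pharm), sum(n_prot), feats, a_prot, t_nodes),
       edge_src = unlist(purrr::map(edges, "src")),
       edge_dst = unlist(purrr::map(edges, "dst")),
       edge_type = unlist(purrr::map(edges, "type")),
       n_pharm = sum(n_pharm), eps = eps)
}

#' Train the equivariant denoiser
#'
#' Optimises the noise-prediction MSE with Adam (defaults: learning rate
#' 1e-4, batch size 24, 80 epochs — the full-scale training settings;
#' toy runs use [toy_train_config()]). Gradients are clipped at a global
#' norm of 1 for CPU-scale stability. A single seed fans out to data
#' shuffling, noise draws, and parameter initialisation via named
#' substreams, so identical seeds give identical loss curves.
#'
#' @param pairs Training data: a tibble with list-columns `pocket` and
#'   `pharmacophore` (as from [make_training_pairs()]), or a plain list
#'   of `list(pocket =, pharmacophore =)`. Pharmacophores with more than
#'   8 centers are subsampled; those with fewer than 3 are dropped with a
#'   warning.
#' @param config Architecture configuration ([denoiser_config()]).
#' @param epochs,lr,batch_size,grad_clip Optimiser settings.
#' @param seed Master seed.
#' @param checkpoint_path Optional path; when given, the model is
#'   checkpointed there after every epoch.
#' @param log_path Optional CSV path for the per-epoch loss curve.
#' @param verbose Print per-epoch mean loss.
#' @return A trained `phg_denoiser` whose `history` holds the loss curve.
#' @export
train_denoiser <- function(pairs, config = denoiser_config(), epochs = 80L,
                           lr = 1e-4, batch_size = 24L, grad_clip = 1.0,
                           seed = 1L, checkpoint_path = NULL, log_path = NULL,
                           verbose = FALSE) {
  if (is.data.frame(pairs)) {
    pairs <- purrr::map2(pairs$pocket, pairs$pharmacophore,
                         function(p, ph) list(pocket = p, pharmacophore = ph))
  }
  if (length(pairs) == 0) abort("Empty training dataset.")
  sizes <- purrr::map_int(pairs, function(p) nrow(p$pharmacophore))
  if (any(sizes < 3L)) {
    warn(paste0(sum(sizes < 3L), " pair(s) with fewer than 3 centers excluded",
                " from training."))
    pairs <- pairs[sizes >= 3L]
    if (length(pairs) == 0) abort("Empty training dataset after exclusions.")
  }
  cfg <- config
  sched <- make_schedule(cfg$T, cfg$power, cfg$clip)
  prepared <- purrr::map(pairs, function(p)
    prepare_pair(p$pocket, p$pharmacophore, cfg))

  params <- init_params(cfg, seed = substream_seed(seed, "init"))
  mstate <- tree_map2(function(a, b) 0 * a, params, params)
  vstate <- mstate
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  step <- 0L
  history <- tibble(epoch = integer(), mean_loss = double())

  for (ep in seq_len(epochs)) {
    ord <- with_seed(substream_seed(seed, "shuffle", ep),
                     sample.int(length(prepared)))
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    ep_losses <- numeric(0)
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      draw_seed <- substream_seed(seed, "noise", ep * 100000L + bi)
      ts <- with_seed(substream_seed(seed, "tstep", ep * 100000L + bi),
                      sample.int(cfg$T, length(idx), replace = TRUE))
      batch <- assemble_batch(prepared[idx], ts, sched, cfg, draw_seed)
      step_out <- denoiser_train_step(params, cfg, batch$X, batch$S_raw,
                                      batch$edge_src, batch$edge_dst,
                                      batch$edge_type, batch$n_pharm,
                                      batch$eps)
      ep_losses <- c(ep_losses, step_out$loss)
      grads <- step_out$grads
      gnorm <- sqrt(tree_sum(function(a) sum(a^2), grads))
      if (is.finite(gnorm) && gnorm > grad_clip) {
        scale <- grad_clip / gnorm
        grads <- tree_map2(function(a, b) a * scale, grads, grads)
      }
      step <- step + 1L
      mstate <- tree_map2(function(m, g) b1 * m + (1 - b1) * g, mstate, grads)
      vstate <- tree_map2(function(v, g) b2 * v + (1 - b2) * g^2, vstate, grads)
      corr <- lr * sqrt(1 - b2^step) / (1 - b1^step)
      upd <- tree_map2(function(m, v) corr * m / (sqrt(v) + adam_eps),
                       mstate, vstate)
      params <- tree_map2(function(p, u) p - u, params, upd)
    }
    history <- bind_rows(history, tibble(epoch = ep, mean_loss = mean(ep_losses)))
    if (verbose) {
      inform(sprintf("[train] epoch %d/%d mean loss %.5f", ep, epochs,
                     mean(ep_losses)))
    }
    model <- new_denoiser(params, cfg, history, trained = TRUE)
    if (!is.null(checkpoint_path)) save_denoiser(model, checkpoint_path)
    if (!is.null(log_path)) readr::write_csv(history, log_path)
  }
  new_denoiser(params, cfg, history, trained = TRUE)
}

#' Toy-scale training settings
#'
#' The desk-scale configuration used by the test-suite and the worked
#' examples: the full 4-layer 64/16 architecture with a shortened
#' 200-step schedule, 20 epochs at learning rate 1e-3, batch size 8
#' (more optimiser steps per epoch at this data scale), and `k = 16`
#' pocket neighbours per center — on ~30-atom fixture pockets each
#' center then sees half the pocket directly, which the site-recovery
#' study needs. A full fixture-training run stays within minutes on one
#' CPU while leaving the architecture itself untouched.
#'
#' @return List with `config`, `epochs`, `lr`, `batch_size`.
#' @export
toy_train_config <- function() {
  list(config = denoiser_config(T = 200L, k = 16L), epochs = 20L, lr = 1e-3,
       batch_size = 8L)
}
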