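# Geometric vector perceptron (GVP) style message passing, with analytic
# backpropagation.
#
# Node state is split into invariant scalar channels (an n x ds matrix)
# and equivariant vector channels, represented as a list of three n x dv
# matrices (the x/y/z components). Every vector operation is either a
# linear mix of channels or a scaling by an invariant gate, so rotation
# equivariance of the vector path (and invariance of the scalar path)
# holds exactly by construction; no cross products are used, so the
# network is equivariant under the full orthogonal group including
# reflections.

# ---- vector-channel helpers ----
#
# Vector channels are stored stacked: a (3n) x c matrix whose row blocks
# are the x, y and z components. Channel mixes and gatings then run as
# single large matrix products instead of three small ones.

sv_zeros <- function(n, c) matrix(0, 3L * n, c)

sv_mix <- function(V, W) tcrossprod(V, W)

sv_mix_back <- function(dOut, W) dOut %*% W

sv_norm <- function(V, n, eps2 = 1e-8) {
  i <- seq_len(n)
  sqrt(V[i, , drop = FALSE]^2 + V[n + i, , drop = FALSE]^2 +
         V[2L * n + i, , drop = FALSE]^2 + eps2)
}

# per-channel gating by an invariant n x c gate
sv_scale <- function(V, g) V * rbind(g, g, g)

sv_index <- function(V, idx, n) {
  V[c(idx, idx + n, idx + 2L * n), , drop = FALSE]
}

# componentwise dot across the three blocks -> n x c
sv_dot <- function(A, B, n) {
  D <- A * B
  i <- seq_len(n)
  D[i, , drop = FALSE] + D[n + i, , drop = FALSE] +
    D[2L * n + i, , drop = FALSE]
}

scatter_add <- function(mat, idx, n) {
  out <- matrix(0, n, ncol(mat))
  agg <- rowsum(mat, idx)
  out[as.integer(rownames(agg)), ] <- agg
  out
}

sv_scatter <- function(V, idx, n_edges_n, n) {
  scatter_add(V, c(idx, idx + n, idx + 2L * n), 3L * n)
}

silu_from_sig <- function(x, s) x * s

# derivative of silu given the cached sigmoid
silu_grad_from_sig <- function(x, s) s * (1 + x * (1 - s))

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- parameter initialisation ----

glorot <- function(nout, nin) {
  matrix(rnorm(nout * nin, sd = 1 / sqrt(nin)), nout, nin)
}

#' Denoiser architecture configuration
#'
#' Tunable architecture and wiring defaults for the equivariant graph
#' denoiser: `n_layers` message-passing layers with `ds` scalar and `dv`
#' vector channels, `n_rbf` Gaussian radial basis functions spanning
#' `[0, rbf_max]` Angstroms for edge distances, a sinusoidal time
#' embedding, pharm-protein wiring via `k` nearest neighbours and a
#' protein-protein cutoff. One-hot features are scaled by `feat_scale`
#' before noising (standard practice for categorical diffusion in this
#' model family) and unscaled at decoding.
#'
#' @param n_layers,ds,dv,n_rbf,rbf_max Architecture sizes.
#' @param k,protein_cutoff Graph wiring parameters (Angstroms for the
#'   cutoff).
#' @param T,power,clip Noise-schedule parameters (see [make_schedule()]).
#' @param feat_scale One-hot scaling constant (default 0.25).
#' @param ... Overrides stored verbatim.
#' @return A named list.
#' @export
denoiser_config <- function(n_layers = 4L, ds = 64L, dv = 16L, n_rbf = 16L,
                            rbf_max = 10, k = 8L, protein_cutoff = 4.5,
                            T = 1000L, power = 2, clip = 1e-4,
                            feat_scale = 0.25, ...) {
  c(list(n_layers = n_layers, ds = ds, dv = dv, n_rbf = n_rbf,
         rbf_max = rbf_max, k = k, protein_cutoff = protein_cutoff,
         T = as.integer(T), power = power, clip = clip,
         feat_scale = feat_scale, d_in = 26L), list(...))
}

init_params <- function(config, seed = 1L) {
  ds <- config$ds; dv <- config$dv; n_rbf <- config$n_rbf
  d_edge_s <- 2L * ds + n_rbf + 3L
  with_seed(seed, {
    layers <- purrr::map(seq_len(config$n_layers), function(l) {
      list(
        edge = list(
          Wh = glorot(dv, dv + 1L),
          Ws = glorot(ds, d_edge_s + dv), bs = rep(0, ds),
          Wg = glorot(dv, ds), bg = rep(0, dv),
          Wmu = glorot(dv, dv)),
        node = list(
          Uh = glorot(dv, 2L * dv),
          Us = glorot(ds, 2L * ds + dv), bu = rep(0, ds),
          Ug = glorot(dv, ds), bg = rep(0, dv),
          Umu = glorot(dv, dv)))
    })
    list(
      emb = list(W = glorot(ds, config$d_in), b = rep(0, ds)),
      layers = layers,
      out = list(wv = rnorm(dv, sd = 1 / sqrt(dv)),
                 Wf = glorot(6L, ds), bf = rep(0, 6L)))
  })
}

# ---- input featurisation ----

time_embedding <- function(t_frac) {
  cbind(t_frac,
        sin(2 * pi * t_frac), cos(2 * pi * t_frac),
        sin(4 * pi * t_frac), cos(4 * pi * t_frac),
        sin(8 * pi * t_frac), cos(8 * pi * t_frac),
        sin(16 * pi * t_frac), cos(16 * pi * t_frac))
}

rbf_expand <- function(d, n_rbf, rbf_max) {
  mu <- seq(0, rbf_max, length.out = n_rbf)
  w <- mu[2] - mu[1]
  exp(-((matrix(d, length(d), n_rbf) -
           matrix(mu, length(d), n_rbf, byrow = TRUE)) / w)^2)
}

# Scalar node inputs for a (possibly batched) graph state.
scalar_inputs <- function(n_pharm, n_prot, z_feats, a_prot, t_frac_nodes) {
  n <- n_pharm + n_prot
  is_pharm <- c(rep(1, n_pharm), rep(0, n_prot))
  feats <- rbind(z_feats, matrix(0, n_prot, ncol(z_feats)))
  atoms <- rbind(matrix(0, n_pharm, ncol(a_prot)), a_prot)
  cbind(is_pharm, feats, atoms, time_embedding(t_frac_nodes))
}

# ---- forward / backward core ----
#
# X: n x 3 positions (pharm nodes first), S_raw: n x d_in scalar inputs,
# edges as index vectors with types. Returns eps_x (n_pharm x 3), eps_f
# (n_pharm x 6) and, when want_cache, everything backward() needs.

forward_core_r <- function(params, config, X, S_raw, edge_src, edge_dst,
                         edge_type, n_pharm, want_cache = FALSE) {
  n <- nrow(X)
  dv <- config$dv
  ne <- length(edge_src)
  dx <- X[edge_src, 1] - X[edge_dst, 1]
  dy <- X[edge_src, 2] - X[edge_dst, 2]
  dz <- X[edge_src, 3] - X[edge_dst, 3]
  d <- sqrt(dx^2 + dy^2 + dz^2 + 1e-12)
  U <- matrix(c(dx / d, dy / d, dz / d), 3L * ne, 1L)
  rbf <- rbf_expand(d, config$n_rbf, config$rbf_max)
  et <- matrix(0, ne, 3)
  et[cbind(seq_len(ne), edge_type)] <- 1
  edge_static <- cbind(rbf, et)
  deg <- tabulate(edge_dst, nbins = n)
  inv_deg <- 1 / pmax(deg, 1L)
  inv_deg3 <- rep(inv_deg, 3L)

  S <- tcrossprod(S_raw, params$emb$W) +
    matrix(params$emb$b, n, length(params$emb$b), byrow = TRUE)
  V <- sv_zeros(n, dv)

  caches <- vector("list", config$n_layers)
  for (l in seq_len(config$n_layers)) {
    pe <- params$layers[[l]]$edge
    pn <- params$layers[[l]]$node

    VinE <- cbind(sv_index(V, edge_src, n), U)
    VhE <- sv_mix(VinE, pe$Wh)
    nhE <- sv_norm(VhE, ne)
    # scalar edge input = [S_dst, S_src, edge_static, nhE]; the node
    # terms are computed once per node and gathered per edge
    ds_ <- config$ds
    Ws_dst <- pe$Ws[, seq_len(ds_), drop = FALSE]
    Ws_src <- pe$Ws[, ds_ + seq_len(ds_), drop = FALSE]
    Ws_es <- pe$Ws[, 2 * ds_ + seq_len(ncol(edge_static)), drop = FALSE]
    Ws_nh <- pe$Ws[, ncol(pe$Ws) - dv + seq_len(dv), drop = FALSE]
    base_dst <- tcrossprod(S, Ws_dst) +
      matrix(pe$bs, n, length(pe$bs), byrow = TRUE)
    base_src <- tcrossprod(S, Ws_src)
    preE <- base_dst[edge_dst, , drop = FALSE] +
      base_src[edge_src, , drop = FALSE] +
      tcrossprod(edge_static, Ws_es) + tcrossprod(nhE, Ws_nh)
    sigE <- sigmoid(preE)
    smE <- silu_from_sig(preE, sigE)
    gpreE <- tcrossprod(smE, pe$Wg) +
      matrix(pe$bg, ne, length(pe$bg), byrow = TRUE)
    gE <- sigmoid(gpreE)
    VmuE <- sv_mix(VhE, pe$Wmu)
    VmE <- sv_scale(VmuE, gE)

    s_agg <- scatter_add(smE, edge_dst, n) * inv_deg
    V_agg <- scatter_add(VmE, c(edge_dst, edge_dst + n, edge_dst + 2L * n),
                         3L * n) * inv_deg3

    VinN <- cbind(V, V_agg)
    VhN <- sv_mix(VinN, pn$Uh)
    nhN <- sv_norm(VhN, n)
    inN <- cbind(S, s_agg, nhN)
    preN <- tcrossprod(inN, pn$Us) +
      matrix(pn$bu, n, length(pn$bu), byrow = TRUE)
    sigN <- sigmoid(preN)
    suN <- silu_from_sig(preN, sigN)
    gpreN <- tcrossprod(suN, pn$Ug) +
      matrix(pn$bg, n, length(pn$bg), byrow = TRUE)
    gN <- sigmoid(gpreN)
    VmuN <- sv_mix(VhN, pn$Umu)
    VuN <- sv_scale(VmuN, gN)

    if (want_cache) {
      caches[[l]] <- list(S_in = S, VinE = VinE, VhE = VhE, nhE = nhE,
                          preE = preE, sigE = sigE, smE = smE, gE = gE,
                          VmuE = VmuE, inN = inN, VinN = VinN, VhN = VhN,
                          nhN = nhN, preN = preN, sigN = sigN, suN = suN,
                          gN = gN, VmuN = VmuN)
    }
    S <- S + suN
    V <- V + VuN
  }

  pharm <- seq_len(n_pharm)
  Sp <- S[pharm, , drop = FALSE]
  eps_f <- Sp %*% t(params$out$Wf) +
    matrix(params$out$bf, n_pharm, 6L, byrow = TRUE)
  wv <- params$out$wv
  eps_x <- matrix(sv_index(V, pharm, n) %*% wv, n_pharm, 3L)
  if (any(!is.finite(eps_x)) || any(!is.finite(eps_f))) {
    abort("Denoiser produced non-finite output (training instability).")
  }
  out <- list(eps_x = eps_x, eps_f = eps_f)
  if (want_cache) {
    out$cache <- list(caches = caches, S_raw = S_raw, S_final = S,
                      V_final = V, edge_src = edge_src, edge_dst = edge_dst,
                      edge_static = edge_static, inv_deg = inv_deg, n = n,
                      ne = ne, n_pharm = n_pharm)
  }
  out
}

backward_core_r <- function(params, config, fwd, d_eps_x, d_eps_f) {
  cache <- fwd$cache
  n <- cache$n; ne <- cache$ne; n_pharm <- cache$n_pharm
  ds <- config$ds; dv <- config$dv
  pharm <- seq_len(n_pharm)
  grads <- list(emb = list(), layers = vector("list", config$n_layers),
                out = list())

  Sp <- cache$S_final[pharm, , drop = FALSE]
  grads$out$Wf <- crossprod(d_eps_f, Sp)
  grads$out$bf <- colSums(d_eps_f)
  dS <- matrix(0, n, ds)
  dS[pharm, ] <- d_eps_f %*% params$out$Wf

  wv <- params$out$wv
  dex <- as.numeric(d_eps_x)          # stacked (3*np) vector
  Vp <- sv_index(cache$V_final, pharm, n)
  grads$out$wv <- as.numeric(crossprod(Vp, dex))
  dV <- sv_zeros(n, dv)
  dV[c(pharm, pharm + n, pharm + 2L * n), ] <- outer(dex, wv)

  for (l in rev(seq_len(config$n_layers))) {
    cl <- cache$caches[[l]]
    pe <- params$layers[[l]]$edge
    pn <- params$layers[[l]]$node
    gl <- list(edge = list(), node = list())

    # ---- node update backward ----
    dVu <- dV
    dgN <- sv_dot(dVu, cl$VmuN, n)
    dVmuN <- sv_scale(dVu, cl$gN)
    dgpreN <- dgN * cl$gN * (1 - cl$gN)
    gl$node$Ug <- crossprod(dgpreN, cl$suN)
    gl$node$bg <- colSums(dgpreN)
    dsu <- dS + dgpreN %*% pn$Ug
    dpreN <- dsu * silu_grad_from_sig(cl$preN, cl$sigN)
    gl$node$Us <- crossprod(dpreN, cl$inN)
    gl$node$bu <- colSums(dpreN)
    dcomb <- dpreN %*% pn$Us
    dsvN <- dcomb[, seq_len(2 * ds), drop = FALSE]
    dnhN <- dcomb[, 2 * ds + seq_len(dv), drop = FALSE]
    dVhN <- sv_scale(cl$VhN, dnhN / cl$nhN)
    dVhN <- dVhN + sv_mix_back(dVmuN, pn$Umu)
    gl$node$Umu <- crossprod(dVmuN, cl$VhN)
    dVinN <- sv_mix_back(dVhN, pn$Uh)
    gl$node$Uh <- crossprod(dVhN, cl$VinN)

    dS_node <- dS + dsvN[, seq_len(ds), drop = FALSE]
    ds_agg <- dsvN[, ds + seq_len(ds), drop = FALSE]
    dV_node <- dV + dVinN[, seq_len(dv), drop = FALSE]
    dV_agg <- dVinN[, dv + seq_len(dv), drop = FALSE]

    # ---- aggregation backward ----
    inv_deg_e <- cache$inv_deg[cache$edge_dst]
    dsmE <- ds_agg[cache$edge_dst, , drop = FALSE] * inv_deg_e
    dVmE <- (dV_agg * rep(cache$inv_deg, 3L))[
      c(cache$edge_dst, cache$edge_dst + n, cache$edge_dst + 2L * n), ,
      drop = FALSE]

    # ---- edge message backward ----
    dgE <- sv_dot(dVmE, cl$VmuE, ne)
    dVmuE <- sv_scale(dVmE, cl$gE)
    dgpreE <- dgE * cl$gE * (1 - cl$gE)
    gl$edge$Wg <- crossprod(dgpreE, cl$smE)
    gl$edge$bg <- colSums(dgpreE)
    dsmE <- dsmE + dgpreE %*% pe$Wg
    dpreE <- dsmE * silu_grad_from_sig(cl$preE, cl$sigE)
    Ws_dst <- pe$Ws[, seq_len(ds), drop = FALSE]
    Ws_src <- pe$Ws[, ds + seq_len(ds), drop = FALSE]
    Ws_nh <- pe$Ws[, ncol(pe$Ws) - dv + seq_len(dv), drop = FALSE]
    sc_dst <- scatter_add(dpreE, cache$edge_dst, n)
    sc_src <- scatter_add(dpreE, cache$edge_src, n)
    gl$edge$Ws <- cbind(crossprod(sc_dst, cl$S_in),
                        crossprod(sc_src, cl$S_in),
                        crossprod(dpreE, cache$edge_static),
                        crossprod(dpreE, cl$nhE))
    gl$edge$bs <- colSums(dpreE)
    dnhE <- dpreE %*% Ws_nh
    dVhE <- sv_scale(cl$VhE, dnhE / cl$nhE)
    dVhE <- dVhE + sv_mix_back(dVmuE, pe$Wmu)
    gl$edge$Wmu <- crossprod(dVmuE, cl$VhE)
    dVinE <- sv_mix_back(dVhE, pe$Wh)
    gl$edge$Wh <- crossprod(dVhE, cl$VinE)

    dS <- dS_node + sc_dst %*% Ws_dst + sc_src %*% Ws_src
    dV <- dV_node +
      scatter_add(dVinE[, seq_len(dv), drop = FALSE],
                  c(cache$edge_src, cache$edge_src + n,
                    cache$edge_src + 2L * n), 3L * n)
    grads$layers[[l]] <- gl
  }

  grads$emb$W <- crossprod(dS, cache$S_raw)
  grads$emb$b <- colSums(dS)
  grads
}

# ---- compiled core wrappers ----
#
# Production forward/training passes run through the C++ core
# (src/gvp_core.cpp); the R implementation above is the reference the
# test-suite checks it against.

denoiser_forward <- function(params, config, X, S_raw, edge_src, edge_dst,
                             edge_type, n_pharm) {
  .gvp_core(params, config$n_layers, config$ds, config$dv, config$n_rbf,
            config$rbf_max, X, S_raw, as.integer(edge_src),
            as.integer(edge_dst), as.integer(edge_type), as.integer(n_pharm),
            FALSE, matrix(0, 1, 1), matrix(0, 1, 1))
}

denoiser_train_step <- function(params, config, X, S_raw, edge_src, edge_dst,
                                edge_type, n_pharm, eps_true) {
  out <- .gvp_core(params, config$n_layers, config$ds, config$dv,
                   config$n_rbf, config$rbf_max, X, S_raw,
                   as.integer(edge_src), as.integer(edge_dst),
                   as.integer(edge_type), as.integer(n_pharm), TRUE,
                   eps_true$coords, eps_true$feats)
  out$grads <- match_shapes(out$grads, params)
  out
}

# coerce gradient leaves to the shapes of the parameter leaves (the
# compiled core returns every leaf as a matrix)
match_shapes <- function(grads, params) {
  if (is.list(params)) {
    nms <- names(params)
    if (!is.null(nms) && all(nms != "")) {
      return(setNames(lapply(nms, function(k)
        match_shapes(grads[[k]], params[[k]])), nms))
    }
    return(purrr::map2(grads, params, match_shapes))
  }
  if (!is.matrix(params)) return(as.numeric(grads))
  grads
}
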