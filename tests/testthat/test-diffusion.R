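# Noise schedule, forward noising, loss, and the denoiser contract.

test_that("schedules are variance-preserving with correct endpoints", {
  for (T in c(50L, 200L, 1000L)) {
    for (power in c(1, 2, 3)) {
      s <- make_schedule(T, power)
      expect_lt(max(abs(s$alpha^2 + s$sigma^2 - 1)), 1e-9)
      expect_true(all(diff(s$alpha) <= 1e-12))
      expect_gte(s$alpha[1], 1 - 1e-3)
      expect_lte(s$alpha[T + 1], 1e-3)
      expect_lt(s$sigma[1], 0.05)
      expect_gt(s$sigma[T + 1], 0.999)
    }
  }
})

test_that("noising follows z_t = alpha*z0 + sigma*eps", {
  z0 <- list(coords = matrix(c(1, 0, 0), 1, 3), feats = matrix(0, 1, 6))
  # alpha = 1, sigma = 0 leaves the sample untouched
  s <- make_schedule(10)
  s$alpha[1] <- 1; s$sigma[1] <- 0
  ns <- noise_sample(z0, s, 0L, seed = 1)
  expect_identical(ns$z$coords, z0$coords)
  # hand arithmetic at alpha = 0.8, sigma = 0.6
  s$alpha[3] <- 0.8; s$sigma[3] <- 0.6
  ns2 <- noise_sample(z0, s, 2L, seed = 7)
  expect_equal(ns2$z$coords, 0.8 * z0$coords + 0.6 * ns2$eps$coords,
               tolerance = 1e-12)
  expect_equal(ns2$z$feats, 0.6 * ns2$eps$feats, tolerance = 1e-12)
})

test_that("noised-state moments match the closed-form marginal", {
  sched <- make_schedule(100L)
  z0 <- list(coords = matrix(c(2, -1, 0.5), 1, 3), feats = matrix(0.25, 1, 6))
  n_draw <- 4000
  for (t in c(10L, 60L, 95L)) {
    draws <- withr::with_seed(t, purrr::map(seq_len(n_draw), function(i)
      noise_sample(z0, sched, t)$z$coords[1, 1]))
    v <- unlist(draws)
    a <- sched$alpha[t + 1]; s <- sched$sigma[t + 1]
    se_mean <- s / sqrt(n_draw)
    expect_lt(abs(mean(v) - a * z0$coords[1, 1]), 3 * se_mean)
    se_var <- s^2 * sqrt(2 / (n_draw - 1))
    expect_lt(abs(stats::var(v) - s^2), 3 * se_var)
  }
})

test_that("mse loss equals the mean of squared componentwise differences", {
  set.seed(3)
  eps <- list(coords = matrix(rnorm(12), 4, 3), feats = matrix(rnorm(24), 4, 6))
  expect_equal(mse_loss(eps, eps), 0)
  plus1 <- list(coords = eps$coords + 1, feats = eps$feats + 1)
  expect_equal(mse_loss(plus1, eps), 1.0, tolerance = 1e-12)
  other <- list(coords = matrix(rnorm(12), 4, 3), feats = matrix(rnorm(24), 4, 6))
  byhand <- mean(c((other$coords - eps$coords)^2, (other$feats - eps$feats)^2))
  expect_equal(mse_loss(other, eps), byhand, tolerance = 1e-12)
  bad <- list(coords = matrix(0, 3, 3), feats = matrix(0, 3, 6))
  expect_error(mse_loss(bad, eps), "Shape mismatch")
})

test_that("denoiser output is rotation equivariant and permutation covariant", {
  cfg <- tiny_config()
  model <- init_denoiser(cfg, seed = 5)
  fx <- make_toy_pocket(fixture_spec(n_sites = 5), seed = 5)
  set.seed(5)
  g <- center_frame(build_graph(fx$pocket, matrix(rnorm(15, sd = 2), 5, 3),
                                k = cfg$k))
  z <- list(coords = g$x_pharm, feats = matrix(rnorm(30), 5, 6))
  out <- denoise_step(model, g, z, 25L)

  R <- phoregen:::random_rotation()
  g_rot <- g
  g_rot$x_prot <- g$x_prot %*% t(R)
  g_rot$x_pharm <- g$x_pharm %*% t(R)
  out_rot <- denoise_step(model, g_rot,
                          list(coords = z$coords %*% t(R), feats = z$feats),
                          25L)
  expect_lt(max(abs(out_rot$coords - out$coords %*% t(R))), 1e-4)
  expect_lt(max(abs(out_rot$feats - out$feats)), 1e-4)

  # permuting pharmacophore nodes permutes the outputs identically
  perm <- c(3L, 1L, 5L, 2L, 4L)
  g_perm <- g
  g_perm$x_pharm <- g$x_pharm[perm, ]
  inv <- order(perm)
  remap <- function(idx) ifelse(idx <= 5, inv[pmin(idx, 5)], idx)
  g_perm$edge_src <- remap(g$edge_src)
  g_perm$edge_dst <- remap(g$edge_dst)
  out_perm <- denoise_step(model, g_perm,
                           list(coords = z$coords[perm, ],
                                feats = z$feats[perm, ]), 25L)
  expect_equal(out_perm$coords, out$coords[perm, ], tolerance = 1e-10)
  expect_equal(out_perm$feats, out$feats[perm, ], tolerance = 1e-10)

  # determinism
  out2 <- denoise_step(model, g, z, 25L)
  expect_identical(out2, out)
})

test_that("analytic gradients agree with finite differences", {
  cfg <- denoiser_config(n_layers = 2L, ds = 6L, dv = 3L, n_rbf = 4L, T = 50L)
  set.seed(42)
  params <- phoregen:::init_params(cfg, seed = 3)
  n_pharm <- 3L; n <- 8L
  X <- matrix(rnorm(n * 3, sd = 3), n, 3)
  S_raw <- cbind(matrix(rnorm(n * 17), n, 17),
                 phoregen:::time_embedding(rep(0.3, n)))
  src <- integer(0); dst <- integer(0); typ <- integer(0)
  for (i in 1:n) for (j in 1:n) {
    if (i != j && runif(1) < 0.6) {
      src <- c(src, i); dst <- c(dst, j); typ <- c(typ, sample(1:3, 1))
    }
  }
  tgt_x <- matrix(rnorm(n_pharm * 3), n_pharm, 3)
  tgt_f <- matrix(rnorm(n_pharm * 6), n_pharm, 6)
  loss_fn <- function(p) {
    out <- phoregen:::forward_core_r(p, cfg, X, S_raw, src, dst, typ, n_pharm)
    sum(out$eps_x * tgt_x) + sum(out$eps_f * tgt_f) +
      0.5 * sum(out$eps_x^2) + 0.5 * sum(out$eps_f^2)
  }
  fwd <- phoregen:::forward_core_r(params, cfg, X, S_raw, src, dst, typ,
                                 n_pharm, want_cache = TRUE)
  gr <- phoregen:::backward_core_r(params, cfg, fwd, tgt_x + fwd$eps_x,
                                 tgt_f + fwd$eps_f)
  get <- function(tree, path) {
    for (k in path) {
      tree <- tree[[if (grepl("^[0-9]+$", k)) as.integer(k) else k]]
    }
    tree
  }
  setv <- function(tree, path, val) {
    k <- path[1]
    ki <- if (grepl("^[0-9]+$", k)) as.integer(k) else k
    if (length(path) == 1) {
      tree[[ki]] <- val
    } else {
      tree[[ki]] <- setv(tree[[ki]], path[-1], val)
    }
    tree
  }
  paths <- list(c("emb", "W"), c("layers", "1", "edge", "Ws"),
                c("layers", "1", "edge", "Wh"), c("layers", "1", "edge", "Wg"),
                c("layers", "1", "edge", "Wmu"), c("layers", "2", "node", "Us"),
                c("layers", "2", "node", "Uh"), c("layers", "2", "node", "Umu"),
                c("layers", "1", "edge", "bs"), c("out", "wv"),
                c("out", "Wf"))
  h <- 1e-6
  for (pth in paths) {
    leaf <- get(params, pth); gleaf <- get(gr, pth)
    for (ii in sample(length(leaf), min(4, length(leaf)))) {
      lp <- leaf; lp[ii] <- lp[ii] + h
      lm <- leaf; lm[ii] <- lm[ii] - h
      num <- (loss_fn(setv(params, pth, lp)) -
                loss_fn(setv(params, pth, lm))) / (2 * h)
      rel <- abs(num - gleaf[ii]) / max(1e-6, abs(num) + abs(gleaf[ii]))
      expect_lt(rel, 1e-4)
    }
  }
})

test_that("compiled core matches the reference implementation exactly", {
  cfg <- denoiser_config(n_layers = 3L, ds = 16L, dv = 5L, n_rbf = 8L,
                         T = 50L)
  set.seed(7)
  params <- phoregen:::init_params(cfg, seed = 3)
  n_pharm <- 6L; n <- 20L
  X <- matrix(rnorm(n * 3, sd = 3), n, 3)
  S_raw <- cbind(matrix(rnorm(n * 17), n, 17),
                 phoregen:::time_embedding(rep(0.4, n)))
  src <- integer(0); dst <- integer(0); typ <- integer(0)
  for (i in 1:n) for (j in 1:n) {
    if (i != j && runif(1) < 0.3) {
      src <- c(src, i); dst <- c(dst, j); typ <- c(typ, sample(1:3, 1))
    }
  }
  eps_t <- list(coords = matrix(rnorm(n_pharm * 3), n_pharm, 3),
                feats = matrix(rnorm(n_pharm * 6), n_pharm, 6))
  cpp <- phoregen:::denoiser_train_step(params, cfg, X, S_raw, src, dst,
                                        typ, n_pharm, eps_t)
  ref <- phoregen:::forward_core_r(params, cfg, X, S_raw, src, dst, typ,
                                   n_pharm, want_cache = TRUE)
  expect_equal(cpp$eps_x, ref$eps_x, tolerance = 1e-12)
  expect_equal(cpp$eps_f, ref$eps_f, tolerance = 1e-12)
  expect_equal(cpp$loss,
               mse_loss(list(coords = ref$eps_x, feats = ref$eps_f), eps_t),
               tolerance = 1e-12)
  n_comp <- 9 * n_pharm
  gr <- phoregen:::backward_core_r(params, cfg, ref,
                                   2 * (ref$eps_x - eps_t$coords) / n_comp,
                                   2 * (ref$eps_f - eps_t$feats) / n_comp)
  dev <- max(abs(unlist(phoregen:::tree_map2(function(a, b) max(abs(a - b)),
                                             gr, cpp$grads))))
  expect_lt(dev, 1e-10)
})

test_that("checkpoints reload bit-exactly", {
  model <- init_denoiser(tiny_config(), seed = 2)
  path <- withr::local_tempfile(fileext = ".rds")
  save_denoiser(model, path)
  back <- load_denoiser(path)
  expect_identical(back, model)
  other <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), other)
  expect_error(load_denoiser(other), "checkpoint")
})
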