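# Training loop behaviour and ancestral sampling contracts (desk-scale
# configurations; the full toy-scale run lives in the acceptance tests).

small_pairs <- function(n, seed = 77) {
  make_training_pairs(fixture_spec(n_sites = 4, shell_atoms = 10L,
                                   n_train = n), seed = seed)
}

test_that("training reduces the loss and is seed-reproducible", {
  pairs <- small_pairs(48)
  cfg <- tiny_config()
  m1 <- train_denoiser(pairs, config = cfg, epochs = 4L, lr = 1e-3,
                       batch_size = 16L, seed = 9)
  expect_lt(m1$history$mean_loss[4], m1$history$mean_loss[1])
  expect_true(all(is.finite(m1$history$mean_loss)))
  m2 <- train_denoiser(pairs, config = cfg, epochs = 4L, lr = 1e-3,
                       batch_size = 16L, seed = 9)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  expect_error(train_denoiser(list(), config = cfg), "Empty")
})

test_that("denoising loss stays finite across the whole time range", {
  pairs <- small_pairs(8)
  cfg <- tiny_config()
  model <- train_denoiser(pairs, config = cfg, epochs = 1L, lr = 1e-3,
                          batch_size = 8L, seed = 3)
  sched <- make_schedule(cfg$T, cfg$power, cfg$clip)
  prep <- phoregen:::prepare_pair(pairs$pocket[[1]], pairs$pharmacophore[[1]],
                                  cfg)
  losses <- purrr::map_dbl(c(0L, 1L, 10L, 25L, 40L, 50L), function(t) {
    ns <- noise_sample(prep$z0, sched, t, seed = 4)
    w <- phoregen:::wire_state(ns$z$coords, prep, cfg)
    g <- list(x_prot = prep$x_pocket[w$kept, , drop = FALSE],
              a_prot = prep$a_pocket[w$kept, , drop = FALSE],
              edge_src = w$src, edge_dst = w$dst, edge_type = w$typ)
    eps_hat <- denoise_step(model, g, ns$z, t)
    mse_loss(eps_hat, ns$eps)
  })
  expect_true(all(is.finite(losses)))
  # predicting noise on a nearly-clean input is no harder than at full noise
  expect_lt(losses[1], 5)
})

test_that("generation honours the requested size for sizes 1-12", {
  fx <- make_toy_pocket(fixture_spec(n_sites = 4), seed = 13)
  model <- init_denoiser(tiny_config(), seed = 1)
  for (nctr in c(1L, 2L, 5L, 8L, 12L)) {
    ph <- generate(fx$pocket, model, nctr, seed = 21, allow_untrained = TRUE)
    expect_equal(nrow(ph), nctr)
    expect_true(all(ph$type %in% feature_types()))
  }
  expect_error(generate(fx$pocket, model, 4), "untrained")
})

test_that("generation is deterministic and rotation equivariant", {
  fx <- make_toy_pocket(fixture_spec(n_sites = 5), seed = 23)
  model <- init_denoiser(tiny_config(), seed = 4)
  a <- generate(fx$pocket, model, 4, seed = 11, allow_untrained = TRUE)
  b <- generate(fx$pocket, model, 4, seed = 11, allow_untrained = TRUE)
  expect_identical(a, b)

  R <- phoregen:::random_rotation()
  rot <- rotate_pocket(fx$pocket, R)
  c_rot <- generate(rot, model, 4, seed = 11, allow_untrained = TRUE)
  expect_equal(as.matrix(c_rot[, c("x", "y", "z")]),
               as.matrix(a[, c("x", "y", "z")]) %*% t(R), tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(c_rot$type, a$type)
})

test_that("batch generation produces the requested size/replicate grid", {
  fx <- make_toy_pocket(fixture_spec(n_sites = 4), seed = 3)
  model <- init_denoiser(tiny_config(), seed = 2)
  batch <- generate_batch(fx$pocket, model, sizes = 3:8, reps = 5, seed = 1,
                          allow_untrained = TRUE)
  expect_equal(nrow(batch), 30)
  expect_equal(unname(table(batch$size)), rep(5L, 6), ignore_attr = TRUE)
  expect_equal(purrr::map_int(batch$pharmacophore, nrow), batch$size)
  expect_equal(nrow(generate_batch(fx$pocket, model, sizes = 3:8, reps = 0,
                                   seed = 1)), 0)
})

test_that("initial sampling state is independent of the site layout", {
  # with alpha_T ~ 0 the chain starts from pure noise about the pocket
  # centroid: the init draws depend on the pocket only through centroid
  # and principal frame, so their moments are layout-free
  init_means <- purrr::map(c(101, 202), function(pocket_seed) {
    fx <- make_toy_pocket(fixture_spec(n_sites = 4), seed = pocket_seed)
    ctr <- colMeans(as.matrix(fx$pocket[, c("x", "y", "z")]))
    Rc <- phoregen:::canonical_rotation(as.matrix(fx$pocket[, c("x", "y", "z")]))
    xs <- purrr::map(1:300, function(s) {
      d <- phoregen:::generation_draws(3, 1L, s)
      sweep(2 * d$init_x %*% t(Rc), 2, ctr, `+`) - rep(ctr, each = 3)
    })
    do.call(rbind, xs)
  })
  for (m in init_means) {
    # mean ~ 0 (3 SE), sd ~ init_spread = 2
    expect_lt(max(abs(colMeans(m))), 3 * 2 / sqrt(900))
    expect_equal(unname(apply(m, 2, sd)), rep(2, 3), tolerance = 0.15)
  }
})

test_that("tidiers expose the training history and model summary", {
  pairs <- small_pairs(8)
  model <- train_denoiser(pairs, config = tiny_config(), epochs = 2L,
                          lr = 1e-3, batch_size = 8L, seed = 2)
  td <- generics::tidy(model)
  expect_equal(names(td), c("epoch", "mean_loss"))
  expect_equal(nrow(td), 2)
  gl <- generics::glance(model)
  expect_true(gl$trained)
  expect_equal(gl$epochs, 2L)
  p <- ggplot2::autoplot(model)
  expect_s3_class(p, "ggplot")
})
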