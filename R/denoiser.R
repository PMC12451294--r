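# The denoiser model object: parameters + configuration + training history.

new_denoiser <- function(params, config, history = NULL, trained = FALSE) {
  structure(list(params = params, config = config,
                 history = history %||% tibble(epoch = integer(),
                                               mean_loss = double()),
                 trained = trained),
            class = "phg_denoiser")
}

#' Initialise an untrained denoiser
#'
#' @param config Architecture configuration from [denoiser_config()].
#' @param seed Integer seed for parameter initialisation.
#' @return A `phg_denoiser`.
#' @export
init_denoiser <- function(config = denoiser_config(), seed = 1L) {
  new_denoiser(init_params(config, seed = substream_seed(seed, "init")), config)
}

#' @export
print.phg_denoiser <- function(x, ...) {
  np <- sum(unlist(rapply(x$params, length, how = "list")))
  cat("# Equivariant graph denoiser:", x$config$n_layers, "layer(s), widths",
      paste0(x$config$ds, "/", x$config$dv), "-", np, "parameters;",
      if (x$trained) "trained" else "untrained", "\n")
  invisible(x)
}

#' Predict the noise on a noised graph state
#'
#' Runs the equivariant denoiser on a centered pocket-pharmacophore graph
#' whose pharmacophore nodes carry a noised state. The coordinate output
#' transforms as vectors under rotation of all input coordinates; the
#' feature output is rotation invariant. The call is deterministic given
#' `(model, g, z, t)`.
#'
#' @param model A `phg_denoiser`.
#' @param g A centered `phg_graph`.
#' @param z Noised pharm state: list with `coords` (N x 3) and `feats`
#'   (N x 6).
#' @param t Integer diffusion step.
#' @return List with predicted noise `coords` (N x 3) and `feats` (N x 6).
#' @export
denoise_step <- function(model, g, z, t) {
  cfg <- model$config
  stopifnot(t >= 0, t <= cfg$T)
  n_pharm <- nrow(z$coords)
  n_prot <- nrow(g$x_prot)
  X <- rbind(z$coords, g$x_prot)
  S_raw <- scalar_inputs(n_pharm, n_prot, z$feats, g$a_prot,
                         rep(t / cfg$T, n_pharm + n_prot))
  out <- denoiser_forward(model$params, cfg, X, S_raw, g$edge_src,
                          g$edge_dst, g$edge_type, n_pharm)
  list(coords = out$eps_x, feats = out$eps_f)
}

#' Save / load a denoiser checkpoint
#'
#' The checkpoint is a versioned container holding the configuration,
#' parameters and training history; reloading is bit-exact
#' (`identical()` to the saved object).
#'
#' @param model A `phg_denoiser`.
#' @param path Checkpoint file path.
#' @return `load_denoiser()` returns the model; `save_denoiser()` its
#'   input, invisibly.
#' @export
save_denoiser <- function(model, path) {
  stopifnot(inherits(model, "phg_denoiser"))
  saveRDS(list(format = "phoregen-checkpoint", version = 1L, model = model),
          path)
  invisible(model)
}

#' @rdname save_denoiser
#' @export
load_denoiser <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "phoregen-checkpoint")) {
    abort("Not a phoregen checkpoint file.")
  }
  obj$model
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a denoiser
#'
#' @param x A `phg_denoiser`.
#' @param ... Unused.
#' @return Tibble with `epoch` and `mean_loss`.
#' @export
tidy.phg_denoiser <- function(x, ...) x$history

#' One-row model summary
#'
#' @param x A `phg_denoiser`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.phg_denoiser <- function(x, ...) {
  tibble(n_layers = x$config$n_layers, ds = x$config$ds, dv = x$config$dv,
         n_params = sum(unlist(rapply(x$params, length, how = "list"))),
         trained = x$trained,
         epochs = nrow(x$history),
         final_loss = if (nrow(x$history)) x$history$mean_loss[nrow(x$history)] else NA_real_)
}

#' Plot the training loss curve
#'
#' @param object A `phg_denoiser`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phg_denoiser <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(x = .data$epoch,
                                               y = .data$mean_loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Mean MSE loss")
}
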