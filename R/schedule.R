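# Variance-preserving polynomial noise schedule and forward noising.

#' Variance-preserving polynomial noise schedule
#'
#' Builds the signal/noise coefficient arrays over `t = 0..T` with
#' `alpha_t = (1 - 2*clip) * (1 - (t/T)^power)^2 + clip` and
#' `sigma_t = sqrt(1 - alpha_t^2)`, so the variance-preserving identity
#' `alpha_t^2 + sigma_t^2 = 1` holds by construction, `alpha` decreases
#' monotonically, and the endpoints sit within `clip` of 1 and 0.
#'
#' @param T Number of diffusion steps (default 1000, the generation
#'   default).
#' @param power Polynomial power (default 2).
#' @param clip Endpoint clamp keeping `alpha` strictly inside (0, 1)
#'   (default 1e-4).
#' @return A `phg_schedule` tibble with columns `t`, `alpha`, `sigma`.
#' @export
make_schedule <- function(T = 1000L, power = 2, clip = 1e-4) {
  stopifnot(T >= 1, power > 0, clip > 0, clip < 0.5)
  t <- 0:T
  base <- (1 - (t / T)^power)^2
  alpha <- (1 - 2 * clip) * base + clip
  sigma <- sqrt(1 - alpha^2)
  sched <- tibble(t = t, alpha = alpha, sigma = sigma)
  attr(sched, "T") <- as.integer(T)
  attr(sched, "power") <- power
  attr(sched, "clip") <- clip
  class(sched) <- c("phg_schedule", class(tibble()))
  sched
}

sched_T <- function(sched) attr(sched, "T")

#' Forward noising of a clean pharmacophore state
#'
#' Applies `z_t = alpha_t * z0 + sigma_t * eps` with independent standard
#' Gaussian noise per component, identically to the coordinate block and
#' the (scaled) one-hot feature block, and returns the drawn noise for
#' loss computation.
#'
#' @param z0 Clean state: list with `coords` (N x 3) and `feats` (N x 6,
#'   already in scaled space).
#' @param sched A `phg_schedule`.
#' @param t Integer step in `0..T`.
#' @param seed Optional integer seed for the draw.
#' @return List with `z` (noised state), `eps` (the drawn noise) and `t`.
#' @export
noise_sample <- function(z0, sched, t, seed = NULL) {
  T <- sched_T(sched)
  stopifnot(t >= 0, t <= T)
  a <- sched$alpha[t + 1]; s <- sched$sigma[t + 1]
  draw <- function() {
    list(coords = matrix(rnorm(length(z0$coords)), nrow(z0$coords)),
         feats = matrix(rnorm(length(z0$feats)), nrow(z0$feats)))
  }
  eps <- if (is.null(seed)) draw() else with_seed(seed, draw())
  list(z = list(coords = a * z0$coords + s * eps$coords,
                feats = a * z0$feats + s * eps$feats),
       eps = eps, t = t)
}

#' Mean squared error between predicted and true noise
#'
#' The training loss: the mean of squared componentwise differences over
#' all pharmacophore-node coordinate and feature components.
#'
#' @param eps_hat,eps Lists with matching `coords` and `feats` matrices.
#' @return A scalar.
#' @export
mse_loss <- function(eps_hat, eps) {
  if (!identical(dim(eps_hat$coords), dim(eps$coords)) ||
      !identical(dim(eps_hat$feats), dim(eps$feats))) {
    abort("Shape mismatch between predicted and true noise.")
  }
  d <- c(eps_hat$coords - eps$coords, eps_hat$feats - eps$feats)
  mean(d^2)
}
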