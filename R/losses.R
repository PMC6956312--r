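#' Objective-function configuration
#'
#' Weights and constants of the composite training objective: the
#' gradient-penalty weight (10), the structural-loss and adversarial-loss
#' weights (0.5 and 0.0025), and the SSIM constants (11x11 window,
#' K1 = 0.01, K2 = 0.03 on a dynamic range of 1 for normalized data).
#'
#' @param lambda_gp gradient-penalty weight.
#' @param lambda_sl structural (SSIM) loss weight.
#' @param lambda_al adversarial loss weight.
#' @param ssim_window odd window side, >= 3.
#' @param K1,K2 SSIM stabilization constants.
#' @param dynamic_range dynamic range R of the voxel values.
#' @param ssim_window_type `"uniform"` (default) or `"gaussian"`
#'   (sd 1.5, the classic SSIM weighting).
#' @return a `loss_config`.
#' @export
loss_config <- function(lambda_gp = 10, lambda_sl = 0.5, lambda_al = 0.0025,
                        ssim_window = 11L, K1 = 0.01, K2 = 0.03,
                        dynamic_range = 1.0,
                        ssim_window_type = c("uniform", "gaussian")) {
  ssim_window_type <- match.arg(ssim_window_type)
  if (lambda_gp < 0 || lambda_sl < 0 || lambda_al < 0)
    stop("loss weights must be non-negative")
  if (ssim_window < 3 || ssim_window %% 2 == 0)
    stop("ssim_window must be odd and >= 3")
  structure(list(lambda_gp = lambda_gp, lambda_sl = lambda_sl,
                 lambda_al = lambda_al, ssim_window = as.integer(ssim_window),
                 K1 = K1, K2 = K2, dynamic_range = dynamic_range,
                 ssim_window_type = ssim_window_type),
            class = "loss_config")
}

# Coerce a batch (Nb x Ns x N x N x 1 array, list of samples, or a single
# sample) to a list of Ns x N x N arrays.
.batch_samples <- function(X) {
  if (is.list(X)) return(lapply(X, function(x) {
    d <- dim(x)
    if (length(d) == 4) array(x, dim = d[1:3]) else x
  }))
  d <- dim(X)
  if (length(d) == 5)
    lapply(seq_len(d[1]), function(i) array(X[i, , , , 1], dim = d[2:4]))
  else if (length(d) == 4) list(array(X, dim = d[1:3]))
  else if (length(d) == 3) list(X)
  else stop("cannot interpret batch of dimensionality ", length(d))
}

#' Mean squared error over a batch (per-sample voxel normalization)
#'
#' `L2 = (1 / (Ns*N*N)) * sum_i || Y_i - X_i ||^2`: the squared error is
#' summed over the mini-batch and normalized by the voxels of a single
#' sample (no division by the batch size).
#'
#' @param X,Y batches of identical shape (`Nb x Ns x N x N x 1` arrays or
#'   lists of samples).
#' @return scalar loss.
#' @export
mse_loss <- function(X, Y) {
  xs <- .batch_samples(X); ys <- .batch_samples(Y)
  if (length(xs) != length(ys)) stop("mse_loss: batch sizes differ")
  tot <- 0
  for (i in seq_along(xs)) {
    if (!identical(dim(xs[[i]]), dim(ys[[i]])))
      stop("mse_loss: sample shapes differ")
    tot <- tot + sum((ys[[i]] - xs[[i]])^2) / length(xs[[i]])
  }
  tot
}

# band matrix performing a 1-D valid weighted correlation
.band_matrix <- function(n, k) {
  L <- length(k)
  m <- n - L + 1L
  if (m < 1) stop("image smaller than the SSIM window")
  B <- matrix(0, m, n)
  for (j in seq_len(L)) B[cbind(seq_len(m), seq_len(m) + j - 1L)] <- k[j]
  B
}

.ssim_kernel <- function(config) {
  L <- config$ssim_window
  if (config$ssim_window_type == "gaussian") {
    t <- seq_len(L) - (L + 1) / 2
    k <- exp(-t^2 / (2 * 1.5^2))
  } else k <- rep(1, L)
  k / sum(k)
}

# SSIM map and its intermediates over valid windows
.ssim_stats <- function(X, Y, config) {
  k <- .ssim_kernel(config)
  Br <- .band_matrix(nrow(X), k)
  Bc <- .band_matrix(ncol(X), k)
  w2 <- function(M) Br %*% M %*% t(Bc)
  mx <- w2(X); my <- w2(Y)
  sxx <- w2(X * X) - mx^2
  syy <- w2(Y * Y) - my^2
  sxy <- w2(X * Y) - mx * my
  C1 <- (config$K1 * config$dynamic_range)^2
  C2 <- (config$K2 * config$dynamic_range)^2
  A1 <- 2 * mx * my + C1
  A2 <- 2 * sxy + C2
  B1 <- mx^2 + my^2 + C1
  B2 <- sxx + syy + C2
  list(S = (A1 * A2) / (B1 * B2), mx = mx, my = my, sxx = sxx, sxy = sxy,
       A1 = A1, A2 = A2, B1 = B1, B2 = B2, Br = Br, Bc = Bc)
}

#' Structural similarity index of two 2D images
#'
#' Mean over sliding windows (11x11 by default) of the product of the
#' luminance, contrast and structure comparisons
#' `(2*mu_y*mu_x + C1)(2*sigma_yx + C2) /
#'  ((mu_y^2 + mu_x^2 + C1)(sigma_y^2 + sigma_x^2 + C2))`
#' with `C1 = (K1*R)^2`, `C2 = (K2*R)^2`. Equals 1 iff the images are
#' identical, and is symmetric in its arguments.
#'
#' @param X,Y numeric matrices of identical shape, at least as large as the
#'   window.
#' @param config a [loss_config()].
#' @return scalar SSIM index.
#' @export
ssim_index <- function(X, Y, config = loss_config()) {
  if (!identical(dim(X), dim(Y))) stop("ssim_index: shapes differ")
  mean(.ssim_stats(X, Y, config)$S)
}

# d mean(S) / dX for fixed Y (matrix of the same shape as X)
.ssim_grad <- function(X, Y, config = loss_config()) {
  st <- .ssim_stats(X, Y, config)
  np <- length(st$S)
  F1 <- 2 * st$my * st$A2 / (st$B1 * st$B2) -
    2 * st$mx * st$A1 * st$A2 / (st$B1^2 * st$B2)
  F2 <- -st$A1 * st$A2 / (st$B1 * st$B2^2)
  F3 <- 2 * st$A1 / (st$B1 * st$B2)
  up <- function(M) t(st$Br) %*% M %*% st$Bc    # adjoint of the valid correlation
  (up(F1) + 2 * X * up(F2) - 2 * up(F2 * st$mx) +
      Y * up(F3) - up(F3 * st$my)) / np
}

#' Structural loss over a batch
#'
#' `Lsl = (1/Nb) * sum_i (1 - SSIM(Y_i, X_i))`, with the SSIM of a 3D sample
#' computed slice-wise with the 2D window and averaged over its slices.
#'
#' @param X,Y batches of identical shape.
#' @param config a [loss_config()].
#' @return scalar loss in `[0, 2]`.
#' @export
ssim_loss <- function(X, Y, config = loss_config()) {
  xs <- .batch_samples(X); ys <- .batch_samples(Y)
  if (length(xs) != length(ys)) stop("ssim_loss: batch sizes differ")
  vals <- vapply(seq_along(xs), function(i) {
    d <- dim(xs[[i]])
    mean(vapply(seq_len(d[1]), function(s)
      ssim_index(xs[[i]][s, , ], ys[[i]][s, , ], config), numeric(1)))
  }, numeric(1))
  mean(1 - vals)
}

# gradient of ssim_loss w.r.t. X, as a list of sample arrays
.ssim_loss_grad <- function(X, Y, config = loss_config()) {
  xs <- .batch_samples(X); ys <- .batch_samples(Y)
  nb <- length(xs)
  lapply(seq_len(nb), function(i) {
    d <- dim(xs[[i]])
    g <- array(0, dim = d)
    for (s in seq_len(d[1]))
      g[s, , ] <- -.ssim_grad(xs[[i]][s, , ], ys[[i]][s, , ], config) / (nb * d[1])
    g
  })
}

#' Adversarial loss of the generator
#'
#' `Lal = -E[ D(G(IFewV)) ]`: the negated batch mean of the critic's score
#' of the generated volumes.
#'
#' @param critic a critic accepted by [critic_value()].
#' @param fake batch of generated samples.
#' @return scalar loss.
#' @export
adversarial_loss <- function(critic, fake) {
  xs <- .batch_samples(fake)
  vals <- vapply(xs, function(x)
    critic_value(critic, array(x, dim = c(dim(x), 1))), numeric(1))
  -mean(vals)
}

#' WGAN gradient penalty
#'
#' Samples `alpha ~ U[0,1]` per batch element, forms the interpolate
#' `alpha * real + (1 - alpha) * fake`, and returns
#' `lambda * mean( (|| grad_x D(x_interp) ||_2 - 1)^2 )` — the gradient is
#' taken with respect to the interpolated input, following the WGAN-GP
#' convention.
#'
#' @param critic a critic accepted by [critic_input_grad()].
#' @param real,fake batches of identical shape.
#' @param config a [loss_config()] (uses `lambda_gp`).
#' @param seed seed for the alpha draws.
#' @return scalar penalty.
#' @export
gradient_penalty <- function(critic, real, fake, config = loss_config(),
                             seed = 1L) {
  rs <- .batch_samples(real); fs <- .batch_samples(fake)
  if (length(rs) != length(fs)) stop("gradient_penalty: batch sizes differ")
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  alphas <- stats::runif(length(rs))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  pen <- vapply(seq_along(rs), function(i) {
    xb <- alphas[i] * rs[[i]] + (1 - alphas[i]) * fs[[i]]
    g <- critic_input_grad(critic, array(xb, dim = c(dim(xb), 1)))
    (sqrt(sum(g^2)) - 1)^2
  }, numeric(1))
  config$lambda_gp * mean(pen)
}

#' Composite generator objective
#'
#' `LG = lambda_al * Lal + lambda_sl * Lsl + L2`, returned with its
#' component breakdown. With `critic = NULL` (or `lambda_al = 0`) the
#' adversarial term is dropped; with `lambda_sl = 0` the objective reduces
#' to plain MSE.
#'
#' @param X generated batch; @param Y ground-truth batch.
#' @param critic optional critic for the adversarial term.
#' @param config a [loss_config()].
#' @return list with `total`, `L2`, `Lsl`, `Lal`.
#' @export
generator_objective <- function(X, Y, critic = NULL, config = loss_config()) {
  L2 <- mse_loss(X, Y)
  Lsl <- if (config$lambda_sl > 0) ssim_loss(X, Y, config) else 0
  Lal <- if (!is.null(critic) && config$lambda_al > 0)
    adversarial_loss(critic, X) else 0
  list(total = config$lambda_al * Lal + config$lambda_sl * Lsl + L2,
       L2 = L2, Lsl = Lsl, Lal = Lal)
}

#' Critic objective (to be minimized)
#'
#' `mean(D(fake)) - mean(D(real)) + gradient penalty` — the inner
#' minimization of the WGAN-GP framework.
#'
#' @param critic a critic.
#' @param real,fake batches of identical shape.
#' @param config a [loss_config()].
#' @param seed seed for the interpolation draws.
#' @return scalar objective.
#' @export
critic_objective <- function(critic, real, fake, config = loss_config(),
                             seed = 1L) {
  rs <- .batch_samples(real); fs <- .batch_samples(fake)
  vr <- vapply(rs, function(x) critic_value(critic, array(x, dim = c(dim(x), 1))), numeric(1))
  vf <- vapply(fs, function(x) critic_value(critic, array(x, dim = c(dim(x), 1))), numeric(1))
  mean(vf) - mean(vr) + gradient_penalty(critic, real, fake, config, seed)
}
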