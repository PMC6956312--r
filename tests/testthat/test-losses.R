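test_that("batch MSE uses per-sample voxel normalization and sums over the batch", {
  z <- array(0, dim = c(1, 9, 64, 64, 1))
  o <- z + 1
  expect_equal(mse_loss(o, o), 0)
  expect_equal(mse_loss(z, o), 1.0)           # (9*64*64)/(9*64*64)
  z2 <- array(0, dim = c(2, 9, 64, 64, 1)); o2 <- z2 + 1
  expect_equal(mse_loss(z2, o2), 2.0)         # sum over batch, no /Nb
  expect_error(mse_loss(z, o2), "batch sizes")
})

test_that("SSIM equals one iff identical, is symmetric, and matches the constant-image closed form", {
  set.seed(1)
  X <- matrix(runif(32 * 32), 32)
  expect_equal(ssim_index(X, X), 1)
  Y <- matrix(runif(32 * 32), 32)
  expect_equal(ssim_index(X, Y), ssim_index(Y, X), tolerance = 1e-12)
  expect_lt(ssim_index(X, Y), 1)
  # constant images a = 0.5, b = 0.6 with R = 1: windows have zero variance
  A <- matrix(0.5, 16, 16); B <- matrix(0.6, 16, 16)
  C1 <- 1e-4
  expect_equal(ssim_index(A, B), (2 * 0.3 + C1) / (0.25 + 0.36 + C1),
               tolerance = 1e-12)
  expect_error(ssim_index(matrix(0, 8, 8), matrix(0, 8, 8)), "window")
})

test_that("SSIM agrees with a direct per-window reference implementation", {
  ref_ssim <- function(X, Y, w = 11, K1 = 0.01, K2 = 0.03) {
    C1 <- K1^2; C2 <- K2^2
    n <- nrow(X); m <- ncol(X); vals <- c()
    for (i in 1:(n - w + 1)) for (j in 1:(m - w + 1)) {
      xs <- X[i:(i + w - 1), j:(j + w - 1)]
      ys <- Y[i:(i + w - 1), j:(j + w - 1)]
      mx <- mean(xs); my <- mean(ys)
      # population (window-mean) moments
      sx <- mean(xs^2) - mx^2; sy <- mean(ys^2) - my^2
      sxy <- mean(xs * ys) - mx * my
      vals <- c(vals, (2 * mx * my + C1) * (2 * sxy + C2) /
                  ((mx^2 + my^2 + C1) * (sx + sy + C2)))
    }
    mean(vals)
  }
  set.seed(2)
  for (k in 1:3) {
    X <- matrix(runif(32 * 32), 32)
    Y <- pmin(pmax(X + rnorm(32 * 32, 0, 0.1), 0), 1)
    expect_equal(ssim_index(X, Y), ref_ssim(X, Y), tolerance = 1e-6)
  }
})

test_that("gaussian-window SSIM differs from uniform but keeps the identity property", {
  set.seed(3)
  X <- matrix(runif(24 * 24), 24)
  Y <- matrix(runif(24 * 24), 24)
  cfg_g <- loss_config(ssim_window_type = "gaussian")
  expect_equal(ssim_index(X, X, cfg_g), 1)
  expect_false(isTRUE(all.equal(ssim_index(X, Y, cfg_g), ssim_index(X, Y))))
})

test_that("structural loss is zero at equality, bounded, and consistent with per-sample calls", {
  set.seed(4)
  X <- array(runif(2 * 3 * 16 * 16), dim = c(2, 3, 16, 16, 1))
  expect_equal(ssim_loss(X, X), 0)
  Y <- array(runif(2 * 3 * 16 * 16), dim = c(2, 3, 16, 16, 1))
  l <- ssim_loss(X, Y)
  expect_gte(l, 0); expect_lte(l, 2)
  # adversarially anti-correlated inputs stay within [0, 2]
  A <- matrix(rep(c(0, 1), 128), 16)
  B <- 1 - A
  expect_lte(ssim_loss(array(A, dim = c(1, 1, 16, 16, 1)),
                       array(B, dim = c(1, 1, 16, 16, 1))), 2)
  # batch mean equals the mean of single-sample losses
  la <- ssim_loss(X[1, , , , , drop = FALSE], Y[1, , , , , drop = FALSE])
  lb <- ssim_loss(X[2, , , , , drop = FALSE], Y[2, , , , , drop = FALSE])
  expect_equal(l, (la + lb) / 2, tolerance = 1e-12)
})

test_that("SSIM gradient matches finite differences", {
  set.seed(5)
  X <- matrix(runif(20 * 20), 20)
  Y <- matrix(runif(20 * 20), 20)
  g <- dearct:::.ssim_grad(X, Y)
  eps <- 1e-6
  for (k in 1:6) {
    i <- sample(length(X), 1)
    Xp <- X; Xp[i] <- Xp[i] + eps
    Xm <- X; Xm[i] <- Xm[i] - eps
    num <- (ssim_index(Xp, Y) - ssim_index(Xm, Y)) / (2 * eps)
    expect_equal(num, g[i], tolerance = 1e-6)
  }
})

test_that("adversarial loss is the negated critic mean and scales linearly", {
  w <- array(rnorm(3 * 8 * 8), dim = c(3, 8, 8))
  lc1 <- linear_critic(w * 0, b = 4)            # constant critic c -> -c
  fake <- array(runif(2 * 3 * 8 * 8), dim = c(2, 3, 8, 8, 1))
  expect_equal(adversarial_loss(lc1, fake), -4)
  lcw <- linear_critic(w)
  x1 <- array(runif(3 * 8 * 8), dim = c(1, 3, 8, 8, 1))
  expect_equal(adversarial_loss(lcw, x1), -sum(w * x1[1, , , , 1]),
               tolerance = 1e-12)
  lc2 <- linear_critic(2 * w)
  expect_equal(adversarial_loss(lc2, x1), 2 * adversarial_loss(lcw, x1),
               tolerance = 1e-12)
})

test_that("gradient penalty of a linear critic is analytic and alpha-independent", {
  set.seed(6)
  w <- array(rnorm(3 * 8 * 8), dim = c(3, 8, 8))
  w1 <- w / sqrt(sum(w^2))                      # unit gradient norm
  real <- array(runif(2 * 3 * 8 * 8), dim = c(2, 3, 8, 8, 1))
  fake <- array(runif(2 * 3 * 8 * 8), dim = c(2, 3, 8, 8, 1))
  expect_equal(gradient_penalty(linear_critic(w1), real, fake), 0,
               tolerance = 1e-12)
  # norm 3 with lambda 10: penalty 10*(3-1)^2 = 40, independent of the draws
  w3 <- 3 * w1
  expect_equal(gradient_penalty(linear_critic(w3), real, fake, seed = 1), 40,
               tolerance = 1e-10)
  expect_equal(gradient_penalty(linear_critic(w3), real, fake, seed = 99), 40,
               tolerance = 1e-10)
})

test_that("generator objective recomposes from its components with the published weights", {
  cfg <- loss_config()
  expect_equal(cfg$lambda_sl, 0.5)
  expect_equal(cfg$lambda_al, 0.0025)
  expect_equal(cfg$lambda_gp, 10)
  # components (Lal, Lsl, L2) = (2, 0.4, 0.01) -> 0.0025*2 + 0.5*0.4 + 0.01
  expect_equal(0.0025 * 2 + 0.5 * 0.4 + 0.01, 0.215)
  set.seed(7)
  X <- array(runif(2 * 3 * 16 * 16), dim = c(2, 3, 16, 16, 1))
  Y <- array(runif(2 * 3 * 16 * 16), dim = c(2, 3, 16, 16, 1))
  w <- array(rnorm(3 * 16 * 16), dim = c(3, 16, 16))
  ob <- generator_objective(X, Y, critic = linear_critic(w), config = cfg)
  expect_equal(ob$total, cfg$lambda_al * ob$Lal + cfg$lambda_sl * ob$Lsl + ob$L2,
               tolerance = 1e-12)
  expect_equal(ob$L2, mse_loss(X, Y))
  expect_equal(ob$Lal, adversarial_loss(linear_critic(w), X))
  # perfect reconstruction and zero critic give exactly zero
  z <- generator_objective(Y, Y, critic = linear_critic(w * 0), config = cfg)
  expect_equal(z$total, 0)
  # MSE-only ablation path
  cfg0 <- loss_config(lambda_sl = 0, lambda_al = 0)
  ob0 <- generator_objective(X, Y, critic = linear_critic(w), config = cfg0)
  expect_equal(ob0$total, ob0$L2)
  expect_equal(ob0$Lsl, 0); expect_equal(ob0$Lal, 0)
})

test_that("critic objective follows the Wasserstein-plus-penalty form", {
  set.seed(8)
  real <- array(runif(2 * 3 * 8 * 8), dim = c(2, 3, 8, 8, 1))
  fake <- array(runif(2 * 3 * 8 * 8), dim = c(2, 3, 8, 8, 1))
  # zero critic: zero gradient everywhere -> penalty 10*(0-1)^2 = 10
  w0 <- array(0, dim = c(3, 8, 8))
  expect_equal(critic_objective(linear_critic(w0), real, fake), 10)
  # unit-norm linear critic with real == fake: Wasserstein term and penalty vanish
  w <- array(rnorm(3 * 8 * 8), dim = c(3, 8, 8)); w <- w / sqrt(sum(w^2))
  expect_equal(critic_objective(linear_critic(w), real, real), 0,
               tolerance = 1e-12)
  # deterministic given the interpolation seed
  lcs <- linear_critic(w, b = 0)
  expect_equal(critic_objective(lcs, real, fake, seed = 3),
               critic_objective(lcs, real, fake, seed = 3))
  # lowering critic(real) by delta raises the objective by delta: shift the
  # real batch along w so D(real') = D(real) - delta while the (constant)
  # input gradient, hence the penalty, is untouched
  d <- 0.7
  shift <- d * w / sum(w^2)
  real2 <- real
  for (i in 1:2) real2[i, , , , 1] <- real[i, , , , 1] - shift
  expect_equal(critic_objective(lcs, real2, fake, seed = 3) -
                 critic_objective(lcs, real, fake, seed = 3), d,
               tolerance = 1e-9)
})

test_that("gradient-penalty parameter gradients (double backprop) match finite differences", {
  set.seed(9)
  cr <- build_discriminator(tiny_disc_config(), input_shape = c(3, 12, 12, 1), seed = 9)
  x <- array(rnorm(12 * 12 * 3), dim = c(12, 12, 3, 1))
  lam <- 10
  pen_of <- function(crit) {
    f <- dearct:::.c_forward(crit, x, cache = TRUE)
    g <- dearct:::.c_backward(crit, f$cache, params = FALSE)$gx
    lam * (sqrt(sum(g^2)) - 1)^2
  }
  f0 <- dearct:::.c_forward(cr, x, cache = TRUE)
  b0 <- dearct:::.c_backward(cr, f0$cache, params = FALSE)
  g <- b0$gx; gn <- sqrt(sum(g^2))
  r <- 2 * lam * (gn - 1) / gn * g
  zero <- lapply(cr$layers, function(l)
    list(gw = array(0, dim = dim(l$W)), gb = numeric(length(l$b))))
  gp <- dearct:::.c_gp_param_grads(cr, f0$cache, b0$u, r, zero)
  eps <- 1e-5
  for (nm in c("conv1", "conv3", "conv6", "fc1", "fc2")) {
    i <- sample(length(cr$layers[[nm]]$W), 1)
    cp <- cr; cp$layers[[nm]]$W[i] <- cp$layers[[nm]]$W[i] + eps
    cm <- cr; cm$layers[[nm]]$W[i] <- cm$layers[[nm]]$W[i] - eps
    num <- (pen_of(cp) - pen_of(cm)) / (2 * eps)
    expect_equal(num, gp[[nm]]$gw[i], tolerance = 1e-3, label = nm)
  }
})
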