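test_that("generator parameter counts reproduce the published budgets exactly", {
  expect_identical(count_parameters(build_generator(generator_config("dear-2d"))),
                   3459749)
  expect_identical(count_parameters(build_generator(generator_config("dear-2d-i"))),
                   5519329)
  expect_identical(count_parameters(build_generator(generator_config("dear-3d"))),
                   5123617)
})

test_that("a single padded 3x3x3 convolution with one input and output channel has 28 parameters", {
  ly <- dearct:::.init_layer(list(name = "t", kernel = c(3L, 3L, 3L),
                                  cin = 1L, cout = 1L, pad = "same"))
  expect_identical(length(ly$W) + length(ly$b), 28L)
})

test_that("2D generator counts are quadratic in the uniform width", {
  cnt <- function(f) count_parameters(build_generator(
    generator_config("custom", mode = "2d", base_filters = f)))
  # fit a*F^2 + b*F + c on three small widths, then predict F = 38
  fs <- c(2, 3, 4)
  M <- cbind(fs^2, fs, 1)
  abc <- unname(solve(M, vapply(fs, cnt, numeric(1))))
  expect_equal(abc[1] * 38^2 + abc[2] * 38 + abc[3], 3459749, tolerance = 1e-9)
  expect_equal(abc[1] * 48^2 + abc[2] * 48 + abc[3], 5519329, tolerance = 1e-9)
})

test_that("model summary subtotals add up to the total count", {
  g <- build_generator(generator_config("dear-2d"))
  df <- model_summary(g)
  expect_equal(sum(df$parameters), count_parameters(g))
  jp <- tempfile(fileext = ".json")
  model_summary(g, jp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(sum(back$parameters), count_parameters(g))
  unlink(jp)
})

test_that("shape trace: encoder sides 64-62-60-58-56 and back, slices constant", {
  tr <- generator_shape_trace(generator_config("dear-3d"), c(9, 64, 64))
  expect_equal(lapply(tr$encoder, function(d) d[2]), list(62, 60, 58, 56))
  expect_true(all(vapply(tr$encoder, `[[`, numeric(1), 1) == 9))
  expect_equal(tr$output, c(9, 64, 64))
  # fully convolutional: any side >= 9 propagates, including 512
  expect_equal(generator_shape_trace(generator_config("dear-3d"), c(9, 512, 512))$output,
               c(9, 512, 512))
  expect_error(generator_shape_trace(generator_config("dear-3d"), c(9, 8, 8)),
               "collapses")
})

test_that("a freshly built generator is the identity and forward shapes match the trace", {
  cfg <- tiny_gen_config()
  gen <- build_generator(cfg, seed = 2)
  x <- array(runif(9 * 16 * 16), dim = c(9, 16, 16))
  y <- generator_apply(gen, x)
  expect_identical(dim(y), dim(x))
  expect_equal(y, x, tolerance = 0)          # zero-initialized recon conv
  # same weights applied at a different spatial size (fully convolutional)
  x2 <- array(runif(9 * 24 * 24), dim = c(9, 24, 24))
  expect_identical(dim(generator_apply(gen, x2)), dim(x2))
  # batch form
  xb <- array(runif(2 * 9 * 16 * 16), dim = c(2, 9, 16, 16, 1))
  expect_identical(dim(generator_apply(gen, xb)), dim(xb))
})

test_that("generator initialization is deterministic given config and seed", {
  g1 <- build_generator(tiny_gen_config(), seed = 9)
  g2 <- build_generator(tiny_gen_config(), seed = 9)
  g3 <- build_generator(tiny_gen_config(), seed = 10)
  expect_identical(g1$layers$down1$W, g2$layers$down1$W)
  expect_false(identical(g1$layers$down1$W, g3$layers$down1$W))
})

test_that("generator backward gradients agree with finite differences", {
  cfg <- tiny_gen_config()
  gen <- build_generator(cfg, seed = 3)
  gen$layers$recon$W[] <- rnorm(length(gen$layers$recon$W), 0, 0.1)
  xin <- array(rnorm(11 * 11 * 3), dim = c(11, 11, 3, 1))
  loss_of <- function(g) sum(dearct:::.g_forward(g, xin)^2)
  fw <- dearct:::.g_forward(gen, xin, cache = TRUE)
  grads <- dearct:::.g_backward(gen, fw$cache, 2 * fw$out)
  eps <- 1e-6
  set.seed(31)
  for (nm in c("down1", "enc2_l3", "enc4_l1", "up1", "dec1_l5", "up4",
               "dec4_l2", "recon")) {
    i <- sample(length(gen$layers[[nm]]$W), 1)
    gp <- gen; gp$layers[[nm]]$W[i] <- gp$layers[[nm]]$W[i] + eps
    gm <- gen; gm$layers[[nm]]$W[i] <- gm$layers[[nm]]$W[i] - eps
    num <- (loss_of(gp) - loss_of(gm)) / (2 * eps)
    expect_lt(abs(num - grads[[nm]]$gw[i]) / max(1, abs(grads[[nm]]$gw[i])),
              1e-4, label = sprintf("dW[%s] mismatch", nm))
    gp <- gen; gp$layers[[nm]]$b[1] <- gp$layers[[nm]]$b[1] + eps
    gm <- gen; gm$layers[[nm]]$b[1] <- gm$layers[[nm]]$b[1] - eps
    num <- (loss_of(gp) - loss_of(gm)) / (2 * eps)
    expect_lt(abs(num - grads[[nm]]$gb[1]) / max(1, abs(grads[[nm]]$gb[1])),
              1e-4, label = sprintf("db[%s] mismatch", nm))
  }
})

test_that("critic emits one scalar per sample and obeys the ceil-halving shape trace", {
  tr <- critic_shape_trace(discriminator_config(), c(9, 64, 64))
  expect_equal(vapply(tr, `[[`, numeric(1), 1), c(9, 5, 3, 2, 1, 1, 1))
  expect_equal(vapply(tr, `[[`, numeric(1), 2), c(64, 32, 16, 8, 4, 2, 1))
  cr <- build_discriminator(tiny_disc_config(), input_shape = c(9, 16, 16, 1), seed = 4)
  xb <- array(runif(3 * 9 * 16 * 16), dim = c(3, 9, 16, 16, 1))
  v <- critic_value(cr, xb)
  expect_length(v, 3)
  expect_true(all(is.finite(v)))
  # zeroed weights give exactly zero output
  for (nm in names(cr$layers)) { cr$layers[[nm]]$W[] <- 0; cr$layers[[nm]]$b[] <- 0 }
  expect_equal(critic_value(cr, xb), c(0, 0, 0))
  expect_error(build_discriminator(tiny_disc_config(), input_shape = c(9, 4, 4, 1)),
               "too small")
  expect_error(discriminator_config(conv_filters = c(8, 8)), "six")
})

test_that("critic parameter and input gradients agree with finite differences", {
  set.seed(5)
  cr <- build_discriminator(tiny_disc_config(), input_shape = c(5, 12, 12, 1), seed = 5)
  x <- array(rnorm(12 * 12 * 5), dim = c(12, 12, 5, 1))
  fw <- dearct:::.c_forward(cr, x, cache = TRUE)
  bw <- dearct:::.c_backward(cr, fw$cache)
  eps <- 1e-6
  for (nm in names(cr$layers)) {
    i <- sample(length(cr$layers[[nm]]$W), 1)
    cp <- cr; cp$layers[[nm]]$W[i] <- cp$layers[[nm]]$W[i] + eps
    cm <- cr; cm$layers[[nm]]$W[i] <- cm$layers[[nm]]$W[i] - eps
    num <- (dearct:::.c_forward(cp, x) - dearct:::.c_forward(cm, x)) / (2 * eps)
    expect_equal(num, bw$grads[[nm]]$gw[i], tolerance = 1e-5, label = nm)
  }
  i <- 77
  xp <- x; xp[i] <- xp[i] + eps
  xm <- x; xm[i] <- xm[i] - eps
  num <- (dearct:::.c_forward(cr, xp) - dearct:::.c_forward(cr, xm)) / (2 * eps)
  expect_equal(num, bw$gx[i], tolerance = 1e-5)
})
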