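# Trainer mechanics at deliberately tiny scale (random stacks, 12x12 patches,
# 2-filter networks): these tests exercise seeding, the schedule, the
# alternating updates and the ablation masks, not reconstruction quality.

tiny_train_config <- function(..., epochs = 1L, adversarial = FALSE, seed = 1L) {
  train_config(batch_size = 4L, epochs = epochs, n_critic = 2L, seed = seed,
               generator = tiny_gen_config(base_filters = 2L),
               discriminator = tiny_disc_config(),
               adversarial = adversarial, ...)
}

test_that("identical seeds give identical step-0 losses and final weights", {
  st <- random_stacks(8, ns = 9L, N = 12L)
  r1 <- train_dear(tiny_train_config(), st)
  r2 <- train_dear(tiny_train_config(), st)
  expect_identical(r1$history$LG[1], r2$history$LG[1])
  expect_identical(r1$generator$layers$recon$W, r2$generator$layers$recon$W)
  r3 <- train_dear(tiny_train_config(seed = 2L), st)
  expect_false(identical(r1$history$LG[1], r3$history$LG[1]))
})

test_that("the learning rate halves at every epoch boundary", {
  st <- random_stacks(8, ns = 9L, N = 12L)
  cfg <- tiny_train_config(epochs = 3L)
  r <- train_dear(cfg, st)
  lr_by_epoch <- tapply(r$history$lr, r$history$epoch, unique)
  expect_equal(as.numeric(lr_by_epoch), c(1e-4, 5e-5, 2.5e-5))
})

test_that("generator and critic parameter sets are disjoint under the alternating updates", {
  st <- random_stacks(8, ns = 9L, N = 12L)
  cfg <- tiny_train_config(adversarial = TRUE, epochs = 1L)
  r <- train_dear(cfg, st)
  # rebuild the initial nets with the same seeds: critic must have moved,
  # and a generator-only step must leave a critic untouched (and vice versa)
  g0 <- build_generator(cfg$generator, seed = cfg$seed)
  c0 <- build_discriminator(cfg$discriminator, input_shape = c(9L, 12L, 12L, 1L),
                            seed = cfg$seed + 1L)
  expect_false(identical(r$generator$layers$down1$W, g0$layers$down1$W))
  expect_false(identical(r$critic$layers$conv1$W, c0$layers$conv1$W))
  # a manual generator step with a frozen critic leaves the critic bitwise intact
  it <- batch_iterator(st, nb = 4L, seed = 1L)
  batch <- it()
  before <- r$critic
  gs <- dearct:::.generator_step(r$generator, r$critic, batch, cfg)
  expect_identical(r$critic, before)
  expect_true(all(c("grads", "L2", "Lsl", "Lal", "total") %in% names(gs)))
})

test_that("history exposes every loss component and the composite recomposes", {
  st <- random_stacks(8, ns = 9L, N = 12L)
  csv <- tempfile(fileext = ".csv")
  cfg <- tiny_train_config(adversarial = TRUE, history_csv = csv)
  r <- train_dear(cfg, st)
  h <- r$history
  expect_true(all(c("step", "epoch", "lr", "L2", "Lsl", "Lal", "LG",
                    "critic_obj", "gp") %in% names(h)))
  expect_equal(h$LG, cfg$loss$lambda_al * h$Lal + cfg$loss$lambda_sl * h$Lsl + h$L2,
               tolerance = 1e-12)
  expect_true(file.exists(csv))
  expect_equal(nrow(utils::read.csv(csv)), nrow(h))
  unlink(csv)
})

test_that("checkpoints round-trip through the native serialization", {
  st <- random_stacks(8, ns = 9L, N = 12L)
  dir <- tempfile()
  cfg <- tiny_train_config(checkpoint_dir = dir)
  r <- train_dear(cfg, st)
  f <- list.files(dir, full.names = TRUE)
  expect_length(f, 1)
  ck <- load_checkpoint(f[1])
  expect_identical(ck$generator$layers$recon$W, r$generator$layers$recon$W)
  unlink(dir, recursive = TRUE)
})

test_that("validation with an identity generator reproduces the input metrics", {
  set.seed(5)
  mk <- function() new_volume(array(runif(9 * 24 * 24), dim = c(9, 24, 24)),
                              "normalized", 1)
  pairs <- list(list(few = mk(), full = mk()), list(few = mk(), full = mk()))
  idgen <- build_generator(tiny_gen_config(), seed = 1)  # zero recon = identity
  tab <- validate_generator(idgen, pairs, ns = 9L)
  expect_equal(nrow(tab), 2)
  direct <- metrics_table(lapply(pairs, `[[`, "few"), lapply(pairs, `[[`, "full"))
  expect_equal(tab$psnr_db, direct$psnr_db, tolerance = 1e-12)
  expect_equal(tab$ssim, direct$ssim, tolerance = 1e-12)
  s <- attr(tab, "summary")
  expect_equal(s$mean[1], mean(tab$psnr_db))
})

test_that("ablation masks hold: MSE-only logs zero Lsl/Lal and no-GAN variants never build a critic", {
  st3 <- random_stacks(8, ns = 9L, N = 12L)
  st2 <- random_stacks(8, ns = 1L, N = 12L, seed = 2L)
  set.seed(6)
  mk <- function() new_volume(array(runif(9 * 12 * 12), dim = c(9, 12, 12)),
                              "normalized", 1)
  vp <- list(list(few = mk(), full = mk()))
  base <- tiny_train_config(adversarial = TRUE)
  out <- ablation_suite(base, st3, st2, vp)
  expect_named(out, c("DEAR-2D1", "DEAR-2D2", "DEAR-2D-i", "DEAR-3D1", "DEAR-3D"))
  h1 <- out[["DEAR-2D1"]]$result$history
  expect_true(all(h1$Lsl == 0) && all(h1$Lal == 0))
  expect_null(out[["DEAR-3D1"]]$result$critic)
  expect_null(out[["DEAR-2D2"]]$result$critic)
  expect_false(is.null(out[["DEAR-3D"]]$result$critic))
  # the widened 2D variant really is wider
  f1 <- out[["DEAR-2D2"]]$result$generator$config$down_filters[1]
  f2 <- out[["DEAR-2D-i"]]$result$generator$config$down_filters[1]
  expect_gt(f2, f1)
  # all five produce metric tables of identical shape
  shapes <- vapply(out, function(v) dim(v$metrics), integer(2))
  expect_true(all(shapes[1, ] == shapes[1, 1]) && all(shapes[2, ] == shapes[2, 1]))
})

test_that("empty datasets and degenerate configs are rejected", {
  expect_error(train_dear(tiny_train_config(), list()), "empty")
  expect_error(train_config(batch_size = 0), "batch_size")
  expect_error(train_config(lr_init = -1), "lr_init")
  expect_error(train_config(n_critic = 0), "n_critic")
})
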