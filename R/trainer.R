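#' Training configuration
#'
#' Optimization schedule of the WGAN-GP framework: Adam with
#' `beta1 = 0.9`, `beta2 = 0.999`, learning rate initialized at `1e-4` and
#' halved after each epoch (both networks share the schedule), mini-batch
#' size 10, and `n_critic` critic updates per generator update (5, the
#' WGAN-GP convention).
#'
#' @param batch_size mini-batch size.
#' @param lr_init initial learning rate.
#' @param lr_decay per-epoch multiplicative decay (0.5 = halving).
#' @param adam_beta1,adam_beta2 Adam moment decays.
#' @param n_critic critic updates per generator update.
#' @param epochs training epochs.
#' @param seed seed controlling initialization, shuffling and interpolation
#'   draws.
#' @param loss a [loss_config()].
#' @param generator a [generator_config()].
#' @param discriminator a [discriminator_config()] (ignored when
#'   `adversarial = FALSE`).
#' @param adversarial build and train a critic? Disabled for the
#'   MSE/MSE+SSIM ablation variants.
#' @param grad_clip optional gradient-norm clip (off by default).
#' @param nan_guard abort on non-finite losses (on; the error retains the
#'   last written checkpoint when `checkpoint_dir` is set).
#' @param history_csv optional path for the per-step loss log.
#' @param checkpoint_dir optional directory for per-epoch checkpoints.
#' @return a `train_config`.
#' @export
train_config <- function(batch_size = 10L, lr_init = 1e-4, lr_decay = 0.5,
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         n_critic = 5L, epochs = 20L, seed = 1L,
                         loss = loss_config(),
                         generator = generator_config("custom", base_filters = 8L),
                         discriminator = discriminator_config(),
                         adversarial = TRUE,
                         grad_clip = Inf, nan_guard = TRUE,
                         history_csv = NULL, checkpoint_dir = NULL) {
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (lr_init <= 0) stop("lr_init must be positive")
  if (n_critic < 1) stop("n_critic must be >= 1")
  structure(list(batch_size = as.integer(batch_size), lr_init = lr_init,
                 lr_decay = lr_decay, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, n_critic = as.integer(n_critic),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 loss = loss, generator = generator,
                 discriminator = discriminator, adversarial = adversarial,
                 grad_clip = grad_clip, nan_guard = nan_guard,
                 history_csv = history_csv, checkpoint_dir = checkpoint_dir),
            class = "train_config")
}

# --- Adam ------------------------------------------------------------------

.adam_new <- function(model) {
  st <- lapply(model$layers, function(l)
    list(mW = array(0, dim = dim(l$W) %||% length(l$W)), vW = array(0, dim = dim(l$W) %||% length(l$W)),
         mb = numeric(length(l$b)), vb = numeric(length(l$b))))
  list(state = st, t = 0L)
}

.adam_update <- function(model, opt, grads, lr, b1, b2, clip = Inf, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
  if (is.finite(clip)) {
    gn <- sqrt(sum(vapply(grads, function(g) sum(g$gw^2) + sum(g$gb^2), numeric(1))))
    if (gn > clip) grads <- lapply(grads, function(g)
      list(gw = g$gw * clip / gn, gb = g$gb * clip / gn))
  }
  for (nm in names(model$layers)) {
    g <- grads[[nm]]; s <- opt$state[[nm]]; l <- model$layers[[nm]]
    s$mW <- b1 * s$mW + (1 - b1) * g$gw
    s$vW <- b2 * s$vW + (1 - b2) * g$gw^2
    s$mb <- b1 * s$mb + (1 - b1) * g$gb
    s$vb <- b2 * s$vb + (1 - b2) * g$gb^2
    l$W <- l$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    l$b <- l$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    opt$state[[nm]] <- s
    model$layers[[nm]] <- l
  }
  list(model = model, opt = opt)
}

# --- steps -----------------------------------------------------------------

# batch (Nb x Ns x N x N x 1) -> list of internal slice-last samples
# (N x N x Ns x 1)
.batch_to_samples4 <- function(B) {
  d <- dim(B)
  lapply(seq_len(d[1]), function(i)
    array(aperm(array(B[i, , , , 1], dim = d[2:4]), c(2, 3, 1)),
          dim = c(d[3], d[4], d[2], 1)))
}

.generator_step <- function(generator, critic, batch, config) {
  xs <- .batch_to_samples4(batch$few)
  ys <- .batch_to_samples4(batch$full)
  nb <- length(xs)
  outs <- vector("list", nb); caches <- vector("list", nb)
  for (i in seq_len(nb)) {
    fw <- .g_forward(generator, xs[[i]], cache = TRUE)
    outs[[i]] <- fw$out; caches[[i]] <- fw$cache
  }
  lc <- config$loss
  # semantic (slice-first) views for the slice-wise losses
  sem <- function(o) aperm(array(o, dim = dim(o)[1:3]), c(3, 1, 2))
  X3 <- lapply(outs, sem)
  Y3 <- lapply(ys, sem)
  L2 <- mse_loss(X3, Y3)
  Lsl <- if (lc$lambda_sl > 0) ssim_loss(X3, Y3, lc) else 0
  sgr <- if (lc$lambda_sl > 0)
    lapply(.ssim_loss_grad(X3, Y3, lc), function(g) aperm(g, c(2, 3, 1)))
  else NULL
  Lal <- 0
  adv_gx <- NULL
  if (!is.null(critic) && lc$lambda_al > 0) {
    vals <- numeric(nb); adv_gx <- vector("list", nb)
    for (i in seq_len(nb)) {
      fw <- .c_forward(critic, outs[[i]], cache = TRUE)
      vals[i] <- fw$value
      adv_gx[[i]] <- .c_backward(critic, fw$cache, params = FALSE)$gx
    }
    Lal <- -mean(vals)
  }
  grads <- .empty_grads(generator)
  nvox <- length(X3[[1]])
  for (i in seq_len(nb)) {
    gX <- 2 * (outs[[i]] - ys[[i]]) / nvox             # d L2 / d X_i
    if (!is.null(sgr))
      gX <- gX + lc$lambda_sl * array(sgr[[i]], dim = dim(gX))
    if (!is.null(adv_gx))
      gX <- gX - lc$lambda_al / nb * adv_gx[[i]]
    grads <- .g_backward(generator, caches[[i]], gX, grads)
  }
  total <- lc$lambda_al * Lal + lc$lambda_sl * Lsl + L2
  list(grads = grads, L2 = L2, Lsl = Lsl, Lal = Lal, total = total,
       fake = outs)
}

.critic_step <- function(critic, real_s, fake_s, config) {
  nb <- length(real_s)
  lc <- config$loss
  grads <- lapply(critic$layers, function(l)
    list(gw = array(0, dim = dim(l$W) %||% length(l$W)), gb = numeric(length(l$b))))
  acc <- function(a, b) {
    for (nm in names(a)) {
      a[[nm]]$gw <- a[[nm]]$gw + b[[nm]]$gw
      a[[nm]]$gb <- a[[nm]]$gb + b[[nm]]$gb
    }
    a
  }
  vf <- numeric(nb); vr <- numeric(nb)
  for (i in seq_len(nb)) {
    fw <- .c_forward(critic, fake_s[[i]], cache = TRUE)
    vf[i] <- fw$value
    grads <- acc(grads, .c_backward(critic, fw$cache, upstream = 1 / nb)$grads)
    fw <- .c_forward(critic, real_s[[i]], cache = TRUE)
    vr[i] <- fw$value
    grads <- acc(grads, .c_backward(critic, fw$cache, upstream = -1 / nb)$grads)
  }
  # gradient penalty with fresh interpolation draws
  alphas <- stats::runif(nb)
  pens <- numeric(nb)
  for (i in seq_len(nb)) {
    xb <- alphas[i] * real_s[[i]] + (1 - alphas[i]) * fake_s[[i]]
    fw <- .c_forward(critic, xb, cache = TRUE)
    bw <- .c_backward(critic, fw$cache, params = FALSE)
    g <- bw$gx
    gn <- sqrt(sum(g^2))
    pens[i] <- (gn - 1)^2
    if (gn > 1e-12) {
      r <- (2 * lc$lambda_gp / nb) * (gn - 1) / gn * g
      grads <- .c_gp_param_grads(critic, fw$cache, bw$u, r, grads)
    }
  }
  obj <- mean(vf) - mean(vr) + lc$lambda_gp * mean(pens)
  list(grads = grads, objective = obj, gp = lc$lambda_gp * mean(pens),
       wasserstein = mean(vr) - mean(vf))
}

#' Train a DEAR generator under the WGAN-GP framework
#'
#' Alternating optimization: per mini-batch, `n_critic` critic updates
#' (Wasserstein difference plus gradient penalty) followed by one generator
#' update of the composite objective. The learning rate of both optimizers
#' halves at every epoch boundary. Fully deterministic given
#' `config$seed`.
#'
#' @param config a [train_config()].
#' @param stacks training stacks from [build_3d_stacks()].
#' @param quiet suppress progress output.
#' @return list with the trained `generator`, the `critic` (or `NULL`), and
#'   a `history` data.frame (per generator step: epoch, learning rate and
#'   all loss components).
#' @export
train_dear <- function(config, stacks, quiet = TRUE) {
  if (length(stacks) == 0) stop("train_dear: empty dataset")
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(config$seed)
  generator <- build_generator(config$generator, seed = config$seed)
  critic <- NULL
  if (config$adversarial && config$loss$lambda_al > 0) {
    d <- dim(stacks[[1]]$few)
    critic <- build_discriminator(config$discriminator,
                                  input_shape = c(d, 1L),
                                  seed = config$seed + 1L)
  }
  g_opt <- .adam_new(generator)
  c_opt <- if (!is.null(critic)) .adam_new(critic) else NULL
  it <- batch_iterator(stacks, nb = config$batch_size, seed = config$seed + 2L)
  steps_per_epoch <- length(stacks) %/% config$batch_size
  hist <- list()
  step <- 0L
  last_ckpt <- NULL
  for (epoch in seq_len(config$epochs)) {
    lr <- config$lr_init * config$lr_decay^(epoch - 1)
    for (k in seq_len(steps_per_epoch)) {
      batch <- it()
      step <- step + 1L
      cobj <- NA_real_; gpv <- NA_real_
      if (!is.null(critic)) {
        real_s <- .batch_to_samples4(batch$full)
        fake_s <- lapply(.batch_to_samples4(batch$few), function(x)
          .g_forward(generator, x))
        for (j in seq_len(config$n_critic)) {
          cs <- .critic_step(critic, real_s, fake_s, config)
          up <- .adam_update(critic, c_opt, cs$grads, lr,
                             config$adam_beta1, config$adam_beta2,
                             config$grad_clip)
          critic <- up$model; c_opt <- up$opt
        }
        cobj <- cs$objective; gpv <- cs$gp
      }
      gs <- .generator_step(generator, critic, batch, config)
      if (config$nan_guard && !is.finite(gs$total)) {
        msg <- sprintf("non-finite generator loss at step %d", step)
        if (!is.null(last_ckpt)) msg <- paste0(msg, "; last checkpoint: ", last_ckpt)
        stop(msg)
      }
      up <- .adam_update(generator, g_opt, gs$grads, lr,
                         config$adam_beta1, config$adam_beta2,
                         config$grad_clip)
      generator <- up$model; g_opt <- up$opt
      hist[[step]] <- data.frame(step = step, epoch = epoch, lr = lr,
                                 L2 = gs$L2, Lsl = gs$Lsl, Lal = gs$Lal,
                                 LG = gs$total, critic_obj = cobj, gp = gpv)
      if (!quiet)
        message(sprintf("epoch %d step %d lr %.2e LG %.5f", epoch, step, lr, gs$total))
    }
    if (!is.null(config$checkpoint_dir)) {
      dir.create(config$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      last_ckpt <- file.path(config$checkpoint_dir, sprintf("epoch%03d.rds", epoch))
      save_checkpoint(list(generator = generator, critic = critic,
                           epoch = epoch), last_ckpt)
    }
  }
  history <- do.call(rbind, hist)
  if (!is.null(config$history_csv))
    utils::write.csv(history, config$history_csv, row.names = FALSE)
  list(generator = generator, critic = critic, history = history,
       config = config)
}

#' Save / load model checkpoints
#' @param object model or list of models.
#' @param path file path (`.rds`).
#' @return `path` (save) or the restored object (load).
#' @export
save_checkpoint <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

#' Validate a generator on paired volumes
#'
#' Runs sliding-window inference on each few-view volume and tabulates
#' PSNR/SSIM/RMSE against the paired ground truth, with mean/STD
#' aggregation.
#'
#' @param generator a `dear_generator` (or function; see
#'   [reconstruct_volume()]).
#' @param pairs list of `list(few = , full = )` normalized volume pairs.
#' @param ns inference window length.
#' @param config a [loss_config()].
#' @return a [metrics_table()] data.frame.
#' @export
validate_generator <- function(generator, pairs, ns = 9L,
                               config = loss_config()) {
  restored <- lapply(pairs, function(p) reconstruct_volume(generator, p$few, ns))
  metrics_table(restored, lapply(pairs, `[[`, "full"), config)
}

#' Train the five ablation variants
#'
#' Trains, with shared seed and data, the five objective/architecture
#' combinations of the ablation study: MSE-only 2D, MSE+SSIM 2D, the
#' widened MSE+SSIM 2D, MSE+SSIM 3D without the adversarial framework, and
#' the full 3D network with WGAN-GP. Widths are taken from `base$generator`
#' so the suite can run at reduced scale; the widened variant scales them
#' by 48/38 as in the reference configuration.
#'
#' @param base a [train_config()]; its generator config supplies the 3D
#'   widths.
#' @param stacks3d training stacks with `ns >= 9` slices.
#' @param stacks2d single-slice stacks (`ns = 1`) for the 2D variants.
#' @param val_pairs paired validation volumes.
#' @return named list of variant results, each
#'   `list(result, metrics)`.
#' @export
ablation_suite <- function(base, stacks3d, stacks2d, val_pairs) {
  f <- base$generator$down_filters[1]
  fi <- max(f + 1L, as.integer(round(f * 48 / 38)))
  mk <- function(mode, filters, lambda_sl, adversarial) {
    cfg <- base
    cfg$generator <- generator_config("custom", mode = mode, base_filters = filters,
                                      dense_output = base$generator$dense_output)
    cfg$discriminator$mode <- mode
    cfg$discriminator$kernel <- if (mode == "3d") c(3L, 3L, 3L) else c(1L, 3L, 3L)
    cfg$loss$lambda_sl <- lambda_sl
    cfg$adversarial <- adversarial
    if (!adversarial) cfg$loss$lambda_al <- 0
    cfg
  }
  variants <- list(
    "DEAR-2D1" = list(cfg = mk("2d", f, 0, FALSE), stacks = stacks2d, ns = 1L),
    "DEAR-2D2" = list(cfg = mk("2d", f, base$loss$lambda_sl, FALSE), stacks = stacks2d, ns = 1L),
    "DEAR-2D-i" = list(cfg = mk("2d", fi, base$loss$lambda_sl, FALSE), stacks = stacks2d, ns = 1L),
    "DEAR-3D1" = list(cfg = mk("3d", f, base$loss$lambda_sl, FALSE), stacks = stacks3d, ns = 9L),
    "DEAR-3D" = list(cfg = mk("3d", f, base$loss$lambda_sl, TRUE), stacks = stacks3d, ns = 9L))
  lapply(variants, function(v) {
    res <- train_dear(v$cfg, v$stacks)
    met <- if (!is.null(val_pairs))
      validate_generator(res$generator, val_pairs, ns = v$ns) else NULL
    list(result = res, metrics = met)
  })
}
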