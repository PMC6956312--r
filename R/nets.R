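#' Generator configuration
#'
#' Describes a DEAR generator: a U-net-style encoder-decoder with four
#' unpadded stride-1 down-sampling convolutions and four transpose
#' up-sampling convolutions (kernel `1x3x3`), a DenseNet-style dense block
#' after each sampler (zero-padded `3x3x3` kernels in 3D, `3x3` in 2D,
#' growth-rate filters, each layer consuming the concatenation of the block
#' input and all previous layer outputs), full-concatenation conveying paths
#' from each encoder stage to the size-matched decoder stage, a shortcut
#' conveying the deepest down-sampler output around the fourth dense block
#' into the first up-sampler, an output-stage dense block with four growth
#' layers, and a final linear 1-filter reconstruction convolution consuming
#' the concatenation of the last up-sampler output and the last feature map,
#' to which the network input is added (residual learning of the inverse
#' artifact amplitude).
#'
#' Named variants:
#' * `"dear-3d"` — 3D kernels in the dense blocks, canonical stage widths
#'   `48, 66, 80, 112` (mirrored in the decoder) and growth 20
#'   (5,123,617 parameters);
#' * `"dear-2d"` — 2D dense blocks, every convolution 38 filters
#'   (3,459,749 parameters);
#' * `"dear-2d-i"` — widened 2D variant, 48 filters everywhere
#'   (5,519,329 parameters).
#'
#' @param variant `"dear-3d"`, `"dear-2d"`, `"dear-2d-i"` or `"custom"`.
#' @param mode `"3d"` or `"2d"` (dense-block kernel dimensionality);
#'   implied by named variants.
#' @param base_filters single width applied to every sampler and dense layer
#'   (used by `"custom"`, e.g. reduced test-scale networks).
#' @param down_filters,up_filters length-4 sampler widths.
#' @param growth dense-block growth rate (single value or length 8:
#'   4 encoder + 4 decoder blocks).
#' @param dense_output `"concat"` (default; the configuration matching the
#'   published parameter budgets) or `"last"` (slim variant: blocks emit
#'   only their final feature maps).
#' @return a `generator_config`.
#' @export
generator_config <- function(variant = c("custom", "dear-3d", "dear-2d", "dear-2d-i"),
                             mode = c("3d", "2d"),
                             base_filters = 8L,
                             down_filters = NULL, up_filters = NULL,
                             growth = NULL,
                             dense_output = c("concat", "last")) {
  variant <- match.arg(variant)
  dense_output <- match.arg(dense_output)
  if (variant == "dear-3d") {
    mode <- "3d"; down_filters <- c(48L, 66L, 80L, 112L)
    up_filters <- rev(down_filters); growth <- rep(20L, 8)
  } else if (variant == "dear-2d") {
    mode <- "2d"; down_filters <- rep(38L, 4); up_filters <- rep(38L, 4)
    growth <- rep(38L, 8)
  } else if (variant == "dear-2d-i") {
    mode <- "2d"; down_filters <- rep(48L, 4); up_filters <- rep(48L, 4)
    growth <- rep(48L, 8)
  } else {
    mode <- match.arg(mode)
    if (is.null(down_filters)) down_filters <- rep(as.integer(base_filters), 4)
    if (is.null(up_filters)) up_filters <- rev(down_filters)
    if (is.null(growth)) growth <- rep(as.integer(base_filters), 8)
  }
  if (length(growth) == 1) growth <- rep(growth, 8)
  stopifnot(length(down_filters) == 4, length(up_filters) == 4,
            length(growth) == 8)
  structure(
    list(variant = variant, mode = mode,
         down_filters = as.integer(down_filters),
         up_filters = as.integer(up_filters),
         growth = as.integer(growth),
         dense_output = dense_output,
         sampler_kernel = c(3L, 3L, 1L),
         dense_kernel = if (mode == "3d") c(3L, 3L, 3L) else c(3L, 3L, 1L),
         n_stages = 4L, dense_layers = 5L),
    class = "generator_config")
}

# Full layer layout (names, kernels, channel widths, padding) implied by a
# generator config. Single source of truth for building, counting and the
# forward/backward passes.
.gen_layout <- function(config) {
  d <- config$down_filters; p <- config$up_filters
  ge <- config$growth[1:4]; gd <- config$growth[5:8]
  concat <- config$dense_output == "concat"
  ly <- list(); Ew <- integer(4)
  add <- function(name, kernel, cin, cout, pad)
    ly[[name]] <<- list(name = name, kernel = kernel, cin = as.integer(cin),
                        cout = as.integer(cout), pad = pad)
  cin <- 1L
  for (s in 1:4) {
    add(sprintf("down%d", s), config$sampler_kernel, cin, d[s], "valid")
    for (l in 1:5)
      add(sprintf("enc%d_l%d", s, l), config$dense_kernel,
          d[s] + (l - 1L) * ge[s], ge[s], "same")
    Ew[s] <- if (concat) d[s] + 5L * ge[s] else ge[s]
    cin <- Ew[s]
  }
  add("up1", config$sampler_kernel, Ew[4] + d[4], p[1], "full")
  for (s in 1:3) {
    w <- p[s] + Ew[4 - s]
    for (l in 1:5)
      add(sprintf("dec%d_l%d", s, l), config$dense_kernel,
          w + (l - 1L) * gd[s], gd[s], "same")
    ow <- if (concat) w + 5L * gd[s] else gd[s]
    add(sprintf("up%d", s + 1), config$sampler_kernel, ow, p[s + 1], "full")
  }
  for (l in 1:4)
    add(sprintf("dec4_l%d", l), config$dense_kernel,
        p[4] + (l - 1L) * gd[4], gd[4], "same")
  add("recon", config$dense_kernel, p[4] + gd[4], 1L, "same")
  list(layers = ly, E_widths = Ew)
}

#' Build a DEAR generator
#'
#' Instantiates the network described by a [generator_config()] with
#' He-normal weights (seeded, hence reproducible). The final reconstruction
#' convolution is zero-initialized, so a freshly built generator is exactly
#' the identity map — the residual starting point for artifact learning.
#'
#' @param config a [generator_config()].
#' @param seed RNG seed for the weight initialization.
#' @return a `dear_generator`.
#' @export
build_generator <- function(config, seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  lay <- .gen_layout(config)
  layers <- lapply(lay$layers, .init_layer)
  rec <- layers$recon
  rec$W[] <- 0; rec$b[] <- 0
  layers$recon <- rec
  structure(list(config = config, layers = layers, E_widths = lay$E_widths),
            class = "dear_generator")
}

#' @export
print.dear_generator <- function(x, ...) {
  cat(sprintf("<dear_generator> %s (%s), %d layers, %s parameters\n",
              x$config$variant, x$config$mode, length(x$layers),
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#'
#' Total number of trainable scalars (weights plus biases) of a built
#' generator or discriminator.
#'
#' @param model a `dear_generator` or `dear_critic`.
#' @return integer-valued count.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$layers, function(l) length(l$W) + length(l$b), numeric(1)))
}

#' Per-layer architecture summary
#'
#' @param model a `dear_generator` or `dear_critic`.
#' @param json_path optional path; when given, the summary is also written
#'   as JSON.
#' @return data.frame with one row per layer (kernel, channels, parameters).
#' @export
model_summary <- function(model, json_path = NULL) {
  df <- do.call(rbind, lapply(model$layers, function(l) {
    data.frame(layer = l$name,
               kernel = paste(l$kernel, collapse = "x"),
               in_channels = l$cin, out_channels = l$cout,
               padding = l$pad %||% "same",
               parameters = length(l$W) + length(l$b))
  }))
  rownames(df) <- NULL
  if (!is.null(json_path))
    jsonlite::write_json(df, json_path, dataframe = "rows", auto_unbox = TRUE)
  df
}

#' Spatial shape trace of a generator
#'
#' Propagates an input shape analytically through the encoder and decoder:
#' each unpadded sampler changes the padded spatial sides by exactly -2/+2
#' while the slice dimension is untouched, so the output shape equals the
#' input shape for any input with sides of at least 9 pixels (the network is
#' fully convolutional).
#'
#' @param config a [generator_config()].
#' @param input_shape `c(D, H, W)` of one sample.
#' @return list with per-stage shapes (`encoder`, `decoder`, `output`).
#' @export
generator_shape_trace <- function(config, input_shape = c(9, 64, 64)) {
  d <- input_shape
  enc <- vector("list", 4)
  for (s in 1:4) {
    d <- c(d[1], d[2] - 2, d[3] - 2)
    if (any(d < 1)) stop(sprintf("shape trace: encoder stage down%d collapses (%s)",
                                 s, paste(d, collapse = "x")))
    enc[[s]] <- d
  }
  dec <- vector("list", 4)
  for (s in 1:4) {
    d <- c(d[1], d[2] + 2, d[3] + 2)
    dec[[s]] <- d
  }
  if (!all(d == input_shape)) stop("shape trace: decoder does not restore the input shape")
  list(encoder = enc, decoder = dec, output = d)
}

# ---------------------------------------------------------------------------
# generator forward / backward

# Dense-block forward. Returns list(cat, caches); cat = [input, x1..xL].
.dense_fwd <- function(layers, names, x) {
  caches <- vector("list", length(names))
  cat <- x
  for (i in seq_along(names)) {
    ly <- layers[[names[i]]]
    z <- .conv_fwd(ly, cat)
    a <- .relu(z)
    caches[[i]] <- list(input = cat, mask = z > 0, name = names[i])
    cat <- .chcat(cat, a)
  }
  list(cat = cat, caches = caches)
}

# Dense-block backward. g_cat is the gradient w.r.t. the full concatenation;
# returns gradient w.r.t. the block input plus per-layer parameter grads.
.dense_bwd <- function(layers, caches, g_cat, grads) {
  for (i in rev(seq_along(caches))) {
    cc <- caches[[i]]
    ly <- layers[[cc$name]]
    win <- dim(cc$input)[4]
    g_a <- .chslice(g_cat, win + 1L, win + ly$cout)
    g_cat <- .chslice(g_cat, 1L, win)
    gz <- g_a * cc$mask
    wb <- .conv_bwd_wb(ly, cc$input, gz)
    grads[[cc$name]]$gw <- grads[[cc$name]]$gw + wb$gw
    grads[[cc$name]]$gb <- grads[[cc$name]]$gb + wb$gb
    g_cat <- g_cat + .conv_bwd_data(ly, gz, dim(cc$input))
  }
  list(g_input = g_cat, grads = grads)
}

# Forward pass for one sample x (D x H x W x 1). With cache = TRUE the
# returned object supports .g_backward().
.g_forward <- function(model, x, cache = FALSE) {
  L <- model$layers
  concat <- model$config$dense_output == "concat"
  if (!concat) stop("forward pass implements the concatenating wiring; rebuild with dense_output = 'concat'")
  cc <- list(x = x)
  E <- vector("list", 4); down_out <- vector("list", 4)
  cur <- x
  for (s in 1:4) {
    nm <- sprintf("down%d", s)
    z <- .conv_fwd(L[[nm]], cur)
    a <- .relu(z)
    if (cache) cc[[nm]] <- list(input = cur, mask = z > 0)
    down_out[[s]] <- a
    blk <- .dense_fwd(L, sprintf("enc%d_l%d", s, 1:5), a)
    if (cache) cc[[sprintf("enc%d", s)]] <- blk$caches
    E[[s]] <- blk$cat
    cur <- blk$cat
  }
  b_in <- .chcat(E[[4]], down_out[[4]])
  z <- .conv_fwd(L$up1, b_in)
  u <- .relu(z)
  if (cache) cc$up1 <- list(input = b_in, mask = z > 0)
  for (s in 1:3) {
    blk_in <- .chcat(u, E[[4 - s]])
    blk <- .dense_fwd(L, sprintf("dec%d_l%d", s, 1:5), blk_in)
    if (cache) cc[[sprintf("dec%d", s)]] <- blk$caches
    nm <- sprintf("up%d", s + 1)
    z <- .conv_fwd(L[[nm]], blk$cat)
    u <- .relu(z)
    if (cache) cc[[nm]] <- list(input = blk$cat, mask = z > 0)
  }
  blk <- .dense_fwd(L, sprintf("dec4_l%d", 1:4), u)
  if (cache) cc$dec4 <- blk$caches
  g4 <- L$dec4_l4$cout
  wid <- dim(blk$cat)[4]
  x4 <- .chslice(blk$cat, wid - g4 + 1L, wid)
  rin <- .chcat(u, x4)
  y <- .conv_fwd(L$recon, rin)
  if (cache) cc$recon <- list(input = rin)
  out <- y + x
  if (cache) list(out = out, cache = cc) else out
}

.empty_grads <- function(model) {
  lapply(model$layers, function(l)
    list(gw = array(0, dim = dim(l$W)), gb = numeric(length(l$b))))
}

# Backward pass for one sample; gout has the shape of the output.
# Returns per-layer parameter gradients (the gradient w.r.t. the input is
# not needed for generator training).
.g_backward <- function(model, cache, gout, grads = .empty_grads(model)) {
  L <- model$layers
  # residual add: gout flows into recon output (and into the input, unused)
  rc <- cache$recon
  wb <- .conv_bwd_wb(L$recon, rc$input, gout)
  grads$recon$gw <- grads$recon$gw + wb$gw
  grads$recon$gb <- grads$recon$gb + wb$gb
  grin <- .conv_bwd_data(L$recon, gout, dim(rc$input))
  p4 <- L$up4$cout; g4 <- L$dec4_l4$cout
  g_u <- .chslice(grin, 1L, p4)
  g_x4 <- .chslice(grin, p4 + 1L, p4 + g4)
  # output dense block: seed the concat gradient with the recon contributions
  full_w <- p4 + 4L * g4
  g_cat <- .zeros_like_ch(cache$dec4[[1]]$input, full_w)
  g_cat[, , , (full_w - g4 + 1L):full_w] <-
    g_cat[, , , (full_w - g4 + 1L):full_w, drop = FALSE] + g_x4
  g_cat[, , , 1:p4] <- g_cat[, , , 1:p4, drop = FALSE] + g_u
  db <- .dense_bwd(L, cache$dec4, g_cat, grads)
  grads <- db$grads
  g_up_out <- db$g_input
  # decoder stages 3..1
  g_E <- vector("list", 4)
  for (s in 3:1) {
    nm <- sprintf("up%d", s + 1)
    uc <- cache[[nm]]
    gz <- g_up_out * uc$mask
    wb <- .conv_bwd_wb(L[[nm]], uc$input, gz)
    grads[[nm]]$gw <- grads[[nm]]$gw + wb$gw
    grads[[nm]]$gb <- grads[[nm]]$gb + wb$gb
    g_cat <- .conv_bwd_data(L[[nm]], gz, dim(uc$input))
    db <- .dense_bwd(L, cache[[sprintf("dec%d", s)]], g_cat, grads)
    grads <- db$grads
    g_blk_in <- db$g_input
    ps <- L[[sprintf("up%d", s)]]$cout
    g_up_out <- .chslice(g_blk_in, 1L, ps)
    gE <- .chslice(g_blk_in, ps + 1L, dim(g_blk_in)[4])
    g_E[[4 - s]] <- if (is.null(g_E[[4 - s]])) gE else g_E[[4 - s]] + gE
  }
  # bottleneck up-sampler
  uc <- cache$up1
  gz <- g_up_out * uc$mask
  wb <- .conv_bwd_wb(L$up1, uc$input, gz)
  grads$up1$gw <- grads$up1$gw + wb$gw
  grads$up1$gb <- grads$up1$gb + wb$gb
  g_bin <- .conv_bwd_data(L$up1, gz, dim(uc$input))
  E4w <- model$E_widths[4]; d4 <- L$down4$cout
  gE <- .chslice(g_bin, 1L, E4w)
  g_E[[4]] <- if (is.null(g_E[[4]])) gE else g_E[[4]] + gE
  g_down4_short <- .chslice(g_bin, E4w + 1L, E4w + d4)
  # encoder stages 4..1
  g_next <- NULL   # gradient flowing into E[[s]] from down_{s+1}
  for (s in 4:1) {
    g_cat <- g_E[[s]]
    if (!is.null(g_next)) g_cat <- g_cat + g_next
    db <- .dense_bwd(L, cache[[sprintf("enc%d", s)]], g_cat, grads)
    grads <- db$grads
    g_a <- db$g_input
    if (s == 4) g_a <- g_a + g_down4_short
    nm <- sprintf("down%d", s)
    dc <- cache[[nm]]
    gz <- g_a * dc$mask
    wb <- .conv_bwd_wb(L[[nm]], dc$input, gz)
    grads[[nm]]$gw <- grads[[nm]]$gw + wb$gw
    grads[[nm]]$gb <- grads[[nm]]$gb + wb$gb
    if (s > 1) g_next <- .conv_bwd_data(L[[nm]], gz, dim(dc$input))
  }
  grads
}

#' Apply a generator to a 3D sample or batch
#'
#' @param generator a `dear_generator`.
#' @param x one sample (`D x H x W` array or `D x H x W x 1`) or a batch
#'   (`Nb x D x H x W x 1`).
#' @return restored data with the same shape as the input.
#' @export
generator_apply <- function(generator, x) {
  d <- dim(x)
  run1 <- function(x3) {                     # x3: S x N x N (semantic)
    xi <- array(aperm(x3, c(2, 3, 1)), dim = c(dim(x3)[2], dim(x3)[3], dim(x3)[1], 1))
    y <- .g_forward(generator, xi)
    aperm(array(y, dim = dim(xi)[1:3]), c(3, 1, 2))
  }
  if (length(d) == 5) {
    out <- x
    for (i in seq_len(d[1]))
      out[i, , , , 1] <- run1(array(x[i, , , , 1], dim = d[2:4]))
    return(out)
  }
  if (length(d) == 4) return(array(run1(array(x, dim = d[1:3])), dim = d))
  run1(x)
}

# ---------------------------------------------------------------------------
# discriminator (Wasserstein critic)

#' Discriminator (critic) configuration
#'
#' Six zero-padded stride-2 convolutions (`3x3x3`, leaky ReLU slope 0.2)
#' followed by two fully connected layers; the final output is an unbounded
#' scalar (Wasserstein critic, no final nonlinearity).
#'
#' @param conv_filters six convolution widths.
#' @param fc_units two fully connected widths, the last must be 1.
#' @param mode `"3d"` or `"2d"`; in 2D the kernels are `1x3x3` and the
#'   slice dimension of the input is 1.
#' @param leaky_slope negative-part slope of the activations.
#' @return a `discriminator_config`.
#' @export
discriminator_config <- function(conv_filters = c(64L, 64L, 128L, 128L, 256L, 256L),
                                 fc_units = c(1024L, 1L),
                                 mode = c("3d", "2d"),
                                 leaky_slope = 0.2) {
  mode <- match.arg(mode)
  if (length(conv_filters) != 6) stop("discriminator: six convolution widths required")
  if (length(fc_units) != 2 || fc_units[2] != 1)
    stop("discriminator: fc_units must be length 2 ending in 1")
  structure(list(conv_filters = as.integer(conv_filters),
                 fc_units = as.integer(fc_units), mode = mode,
                 kernel = if (mode == "3d") c(3L, 3L, 3L) else c(3L, 3L, 1L),
                 leaky_slope = leaky_slope),
            class = "discriminator_config")
}

#' Build the Wasserstein critic
#'
#' @param config a [discriminator_config()].
#' @param input_shape `c(D, H, W, 1)` of one sample; fixes the flatten size
#'   of the first fully connected layer.
#' @param seed RNG seed for initialization.
#' @return a `dear_critic`.
#' @export
build_discriminator <- function(config, input_shape = c(9L, 64L, 64L, 1L),
                                seed = 1L) {
  if (length(input_shape) == 3) input_shape <- c(input_shape, 1L)
  if (min(input_shape[2:3]) < 8)
    stop("discriminator: input too small for six stride-2 reductions")
  # internal layout is slice-last: (H, W, S, C)
  input_int <- c(input_shape[2], input_shape[3], input_shape[1], input_shape[4])
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  layers <- list()
  d <- as.integer(input_int[1:3]); cin <- as.integer(input_int[4])
  shapes <- list(d)
  for (i in 1:6) {
    desc <- list(name = sprintf("conv%d", i), kernel = config$kernel,
                 cin = cin, cout = config$conv_filters[i], pad = "same2")
    layers[[desc$name]] <- .init_layer(desc)
    d <- as.integer(ceiling(d / 2)); cin <- config$conv_filters[i]
    shapes[[i + 1]] <- d
  }
  flat <- prod(d) * cin
  mk_fc <- function(name, nin, nout) {
    list(name = name, kernel = c(1L, 1L, 1L), cin = nin, cout = nout,
         W = matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nout, nin),
         b = numeric(nout), fc = TRUE)
  }
  layers$fc1 <- mk_fc("fc1", flat, config$fc_units[1])
  layers$fc2 <- mk_fc("fc2", config$fc_units[1], 1L)
  structure(list(config = config, layers = layers,
                 input_shape = as.integer(input_shape),
                 conv_shapes = shapes, flat = flat),
            class = "dear_critic")
}

#' @export
print.dear_critic <- function(x, ...) {
  cat(sprintf("<dear_critic> %s, input %s, %s parameters\n", x$config$mode,
              paste(x$input_shape, collapse = "x"),
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Slice/spatial shape trace of the critic
#'
#' Stride-2 SAME convolutions reduce every dimension by ceil division;
#' for a 9x64x64 input the slice dimension goes 9-5-3-2-1-1-1.
#'
#' @param config a [discriminator_config()].
#' @param input_shape `c(D, H, W)`.
#' @return list of per-layer shapes (including the input).
#' @export
critic_shape_trace <- function(config, input_shape = c(9, 64, 64)) {
  d <- as.integer(input_shape)
  out <- list(d)
  for (i in 1:6) { d <- as.integer(ceiling(d / 2)); out[[i + 1]] <- d }
  out
}

.c_forward <- function(critic, x, cache = FALSE) {
  sl <- critic$config$leaky_slope
  cc <- list()
  cur <- x
  for (i in 1:6) {
    nm <- sprintf("conv%d", i)
    ly <- critic$layers[[nm]]
    z <- .sconv_fwd(ly, cur)
    if (cache) cc[[nm]] <- list(input = cur, mask = ifelse(z > 0, 1, sl),
                                xdim = dim(cur))
    cur <- .lrelu(z, sl)
  }
  convdim <- dim(cur)
  v <- as.numeric(cur)
  ly <- critic$layers$fc1
  z <- as.numeric(ly$W %*% v + ly$b)
  if (cache) cc$fc1 <- list(input = v, mask = ifelse(z > 0, 1, sl))
  a <- ifelse(z > 0, z, sl * z)
  ly <- critic$layers$fc2
  val <- as.numeric(ly$W %*% a + ly$b)
  if (cache) {
    cc$fc2 <- list(input = a)
    cc$convdim <- convdim
    list(value = val, cache = cc)
  } else val
}

# Backward through the critic from d(value) = upstream.
# Returns list(gx = input gradient, u = per-layer pre-activation gradients,
# grads = parameter gradients if wanted).
.c_backward <- function(critic, cache, upstream = 1, params = TRUE) {
  L <- critic$layers
  grads <- if (params) lapply(L, function(l)
    list(gw = array(0, dim = dim(l$W) %||% c(length(l$W))), gb = numeric(length(l$b)))) else NULL
  u <- list()
  d2 <- upstream                               # scalar: grad at fc2 output
  u$fc2 <- d2
  if (params) {
    grads$fc2$gw <- matrix(d2 * cache$fc2$input, 1)
    grads$fc2$gb <- d2
  }
  ga <- as.numeric(t(L$fc2$W) * d2)
  d1 <- ga * cache$fc1$mask
  u$fc1 <- d1
  if (params) {
    grads$fc1$gw <- outer(d1, cache$fc1$input)
    grads$fc1$gb <- d1
  }
  gv <- as.numeric(t(L$fc1$W) %*% d1)
  g <- array(gv, dim = cache$convdim)
  for (i in 6:1) {
    nm <- sprintf("conv%d", i)
    cc <- cache[[nm]]
    gz <- g * cc$mask
    u[[nm]] <- gz
    if (params) {
      wb <- .sconv_bwd_wb(L[[nm]], cc$input, gz)
      grads[[nm]]$gw <- wb$gw
      grads[[nm]]$gb <- wb$gb
    }
    g <- .sconv_bwd_data(L[[nm]], gz, cc$xdim)
  }
  list(gx = g, u = u, grads = grads)
}

# Gradient-penalty parameter gradients by double backpropagation.
# With piecewise-linear activations the input gradient at fixed masks is
# g = W1' M1 W2' ... WK' 1; for any cotangent r, d(r.g)/dWk equals the
# ordinary weight-gradient form with "input" = the mask-linearized forward
# propagation of r and "output gradient" = the cached backward quantities u_k.
.c_gp_param_grads <- function(critic, cache, u, r, grads) {
  L <- critic$layers
  t <- r
  for (i in 1:6) {
    nm <- sprintf("conv%d", i)
    cc <- cache[[nm]]
    wb <- .sconv_bwd_wb(L[[nm]], t, u[[nm]])
    grads[[nm]]$gw <- grads[[nm]]$gw + wb$gw
    # biases do not influence the input gradient (a.e.)
    t_pre <- .sconv_fwd(L[[nm]], t, bias = FALSE)
    t <- t_pre * cc$mask
  }
  tv <- as.numeric(t)
  grads$fc1$gw <- grads$fc1$gw + outer(u$fc1, tv)
  t1 <- as.numeric(L$fc1$W %*% tv) * cache$fc1$mask
  grads$fc2$gw <- grads$fc2$gw + matrix(u$fc2 * t1, 1)
  grads
}

#' Evaluate a critic on a sample or batch
#'
#' Generic scalar scoring interface shared by the trained critic and the
#' analytic linear critic used in closed-form checks.
#'
#' @param critic a `dear_critic` or [linear_critic()].
#' @param x one sample (`D x H x W x 1`) or a batch (`Nb x D x H x W x 1`).
#' @return numeric vector of critic values (one per sample).
#' @export
critic_value <- function(critic, x) UseMethod("critic_value")

#' @export
critic_value.dear_critic <- function(critic, x) {
  perm1 <- function(x3) array(aperm(x3, c(2, 3, 1)),
                              dim = c(dim(x3)[2], dim(x3)[3], dim(x3)[1], 1))
  d <- dim(x)
  if (length(d) == 5) {
    vapply(seq_len(d[1]), function(i)
      .c_forward(critic, perm1(array(x[i, , , , 1], dim = d[2:4]))),
      numeric(1))
  } else .c_forward(critic, perm1(array(x, dim = d[1:3])))
}

#' Gradient of the critic value with respect to its input
#'
#' @param critic a `dear_critic` or [linear_critic()].
#' @param x one sample (`D x H x W x 1` array).
#' @return array of the same shape as `x`.
#' @export
critic_input_grad <- function(critic, x) UseMethod("critic_input_grad")

#' @export
critic_input_grad.dear_critic <- function(critic, x) {
  d <- dim(x)
  xi <- array(aperm(array(x, dim = d[1:3]), c(2, 3, 1)),
              dim = c(d[2], d[3], d[1], 1))
  fw <- .c_forward(critic, xi, cache = TRUE)
  g <- .c_backward(critic, fw$cache, params = FALSE)$gx
  array(aperm(array(g, dim = dim(xi)[1:3]), c(3, 1, 2)), dim = d)
}

#' Analytic linear critic
#'
#' `D(x) = <w, x> + b` — a critic whose input gradient is constant, used to
#' verify the gradient penalty in closed form (a linear critic with
#' `||w|| = g` must incur penalty `lambda * (g - 1)^2` for every
#' interpolation point).
#'
#' @param w weight array (same shape as one sample).
#' @param b offset.
#' @return a `dear_linear_critic`.
#' @export
linear_critic <- function(w, b = 0) {
  structure(list(w = w, b = b, layers = list(list(W = w, b = b))),
            class = "dear_linear_critic")
}

#' @export
critic_value.dear_linear_critic <- function(critic, x) {
  d <- dim(x)
  if (length(d) == 5) {
    vapply(seq_len(d[1]), function(i)
      sum(as.numeric(critic$w) * as.numeric(x[i, , , , 1])) + critic$b,
      numeric(1))
  } else sum(as.numeric(critic$w) * as.numeric(x)) + critic$b
}

#' @export
critic_input_grad.dear_linear_critic <- function(critic, x) {
  array(critic$w, dim = dim(x))
}
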