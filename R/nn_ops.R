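# Low-level neural-network primitives on channel-last tensors.
#
# Feature maps are numeric arrays dim = c(D, H, W, C); weights are arrays
# dim = c(kd, kh, kw, Cin, Cout). Convolutions run in C++ (src/conv3d.cpp).
# Padding modes: "valid" (none), "same" (k-1)/2, "full" (k-1). Up-sampling
# transpose convolutions with stride 1 are realized as full-padding
# convolutions, which grow each padded side by k-1.

.pad_of <- function(kernel, mode) {
  switch(mode,
         valid = c(0L, 0L, 0L),
         same = as.integer((kernel - 1L) / 2L),
         full = as.integer(kernel - 1L),
         stop("unknown padding mode ", mode))
}

.out_dim <- function(ind, kernel, pad) as.integer(ind + 2L * pad - kernel + 1L)

.conv_fwd <- function(layer, x, bias = TRUE) {
  xd <- dim(x)
  pad <- .pad_of(layer$kernel, layer$pad)
  outd <- .out_dim(xd[1:3], layer$kernel, pad)
  if (any(outd < 1))
    stop(sprintf("layer %s: input %s too small for kernel/padding",
                 layer$name, paste(xd[1:3], collapse = "x")))
  b <- if (bias) layer$b else numeric(length(layer$b))
  .nn_conv3d_fwd(x, as.integer(xd), layer$W, as.integer(dim(layer$W)), b,
                 c(1L, 1L, 1L), pad, outd)
}

.conv_bwd_data <- function(layer, gy, xdim) {
  pad <- .pad_of(layer$kernel, layer$pad)
  outd <- .out_dim(xdim[1:3], layer$kernel, pad)
  .nn_conv3d_bwd_data(gy, as.integer(xdim), layer$W,
                      as.integer(dim(layer$W)), c(1L, 1L, 1L), pad, outd)
}

.conv_bwd_wb <- function(layer, x, gy) {
  xd <- dim(x)
  pad <- .pad_of(layer$kernel, layer$pad)
  outd <- .out_dim(xd[1:3], layer$kernel, pad)
  .nn_conv3d_bwd_wb(x, as.integer(xd), gy, as.integer(dim(layer$W)),
                    c(1L, 1L, 1L), pad, outd)
}

# stride-2 SAME convolution (ceil semantics) used by the critic
.sconv_geom <- function(ind, kernel) {
  outd <- as.integer(ceiling(ind / 2))
  padt <- pmax((outd - 1L) * 2L + kernel - ind, 0L)
  list(out = outd, pad = as.integer(padt %/% 2L))
}

.sconv_fwd <- function(layer, x, bias = TRUE) {
  xd <- dim(x)
  g <- .sconv_geom(xd[1:3], layer$kernel)
  b <- if (bias) layer$b else numeric(length(layer$b))
  .nn_conv3d_fwd(x, as.integer(xd), layer$W, as.integer(dim(layer$W)), b,
                 c(2L, 2L, 2L), g$pad, g$out)
}

.sconv_bwd_data <- function(layer, gy, xdim) {
  g <- .sconv_geom(xdim[1:3], layer$kernel)
  .nn_conv3d_bwd_data(gy, as.integer(xdim), layer$W,
                      as.integer(dim(layer$W)), c(2L, 2L, 2L), g$pad, g$out)
}

.sconv_bwd_wb <- function(layer, x, gy) {
  xd <- dim(x)
  g <- .sconv_geom(xd[1:3], layer$kernel)
  .nn_conv3d_bwd_wb(x, as.integer(xd), gy, as.integer(dim(layer$W)),
                    c(2L, 2L, 2L), g$pad, g$out)
}

.relu <- function(z) { z[z < 0] <- 0; z }
.lrelu <- function(z, slope = 0.2) ifelse(z > 0, z, slope * z)

# channel-last concatenation / slicing (O(1) layout copies)
.chcat <- function(a, b) {
  da <- dim(a); db <- dim(b)
  if (!all(da[1:3] == db[1:3]))
    stop("channel concat: spatial dimensions disagree (",
         paste(da[1:3], collapse = "x"), " vs ", paste(db[1:3], collapse = "x"), ")")
  array(c(a, b), dim = c(da[1:3], da[4] + db[4]))
}

.chslice <- function(x, from, to) {
  d <- dim(x)
  nv <- prod(d[1:3])
  array(x[(nv * (from - 1) + 1):(nv * to)], dim = c(d[1:3], to - from + 1L))
}

.zeros_like_ch <- function(x, nch) {
  d <- dim(x)
  array(0, dim = c(d[1:3], nch))
}

# He-normal initialization for a layer descriptor
.init_layer <- function(desc) {
  ntap <- prod(desc$kernel)
  fan_in <- ntap * desc$cin
  W <- array(stats::rnorm(ntap * desc$cin * desc$cout, 0, sqrt(2 / fan_in)),
             dim = c(desc$kernel, desc$cin, desc$cout))
  c(desc, list(W = W, b = numeric(desc$cout)))
}
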