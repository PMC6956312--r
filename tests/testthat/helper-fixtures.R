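# Shared fixtures: small geometries, phantoms and reduced network configs.
# Everything is generated in code at test time.

small_geometry <- function(image_size = 64L, pixel_mm = 2.656, n_views_full = 256L) {
  fanbeam_geometry(image_size = image_size, pixel_size_mm = pixel_mm,
                   n_views_full = n_views_full)
}

small_spec <- function(seed = 1L, size = 64L, n_slices = 9L, ...) {
  args <- list(seed = seed, size = size, n_slices = n_slices,
               body_axes_mm = c(30, 55), pixel_size_mm = 2.656)
  args <- utils::modifyList(args, list(...))
  do.call(phantom_spec, args)
}

# centered disc image in the grid convention of the projector
disc_image <- function(n, pixel_mm, radius_mm, value) {
  half <- (n - 1) / 2
  xs <- ((seq_len(n) - 1) - half) * pixel_mm
  ys <- (half - (seq_len(n) - 1)) * pixel_mm
  X <- matrix(xs, n, n, byrow = TRUE)
  Y <- matrix(ys, n, n)
  ifelse(X^2 + Y^2 <= radius_mm^2, value, 0)
}

# paired stacks cut from simulated volume pairs on a regular origin grid
make_stacks <- function(pairs, size, stride, ns) {
  out <- list()
  for (p in pairs) {
    k <- patch_grid_axis_count(dim(p$full$data)[2], size, stride)
    offs <- (seq_len(k) - 1L) * stride
    orig <- expand.grid(row = offs, col = offs)
    out <- c(out, build_3d_stacks(p, orig, size = size, ns = ns,
                                  patient = p$patient))
  }
  out
}

tiny_gen_config <- function(mode = "3d", base_filters = 2L)
  generator_config("custom", mode = mode, base_filters = base_filters)

tiny_disc_config <- function(mode = "3d")
  discriminator_config(conv_filters = c(4L, 4L, 8L, 8L, 8L, 8L),
                       fc_units = c(16L, 1L), mode = mode)

# random paired stacks (no physics) for trainer mechanics tests
random_stacks <- function(n, ns = 9L, N = 12L, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) list(
    few = array(runif(ns * N * N), dim = c(ns, N, N)),
    full = array(runif(ns * N * N), dim = c(ns, N, N)),
    provenance = list(patient = 1L, slice = 0L, row = 0L, col = 0L)))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(1e-12, abs(expected)), tol)
}
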