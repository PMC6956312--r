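#' Normalize a volume from HU to [0, 1]
#'
#' Linear map `lo -> 0`, `hi -> 1`, clipped to `[0, 1]`. The same window must
#' be applied to both members of a training pair so they share a scale; the
#' package default window is (-1000, 2000) HU, applied per corpus. Already
#' normalized volumes are returned unchanged (idempotence).
#'
#' @param volume a `dear_volume` in HU.
#' @param window length-2 numeric `(lo_hu, hi_hu)` with `lo < hi`.
#' @return a normalized `dear_volume`.
#' @export
normalize_volume <- function(volume, window = c(-1000, 2000)) {
  if (window[1] >= window[2])
    stop("normalize_volume: window must satisfy lo < hi")
  if (volume$units == "normalized") return(volume)
  x <- (volume$data - window[1]) / (window[2] - window[1])
  x[x < 0] <- 0; x[x > 1] <- 1
  v <- new_volume(x, units = "normalized",
                  pixel_size_mm = volume$pixel_size_mm,
                  slice_thickness_mm = volume$slice_thickness_mm)
  attr(v, "window") <- window
  v
}

#' Invert the normalization map
#'
#' Maps a normalized volume back to HU with the same window. Exact (to
#' floating point) for voxels that were not clipped.
#'
#' @param volume a normalized `dear_volume`.
#' @param window the window used by [normalize_volume()].
#' @return a `dear_volume` in HU.
#' @export
denormalize_volume <- function(volume, window = c(-1000, 2000)) {
  if (volume$units != "normalized")
    stop("denormalize_volume: volume is not normalized")
  x <- volume$data * (window[2] - window[1]) + window[1]
  new_volume(x, units = "HU", pixel_size_mm = volume$pixel_size_mm,
             slice_thickness_mm = volume$slice_thickness_mm)
}

#' Number of patch origins per axis
#'
#' Default (`"exclusive"`) convention: `K = floor((n_img - size) / stride)`
#' origin positions per axis, i.e. multiples of the stride with an exclusive
#' upper bound — the convention under which 2566 images of 512x512 yield
#' exactly 502,936 patches of 64 with stride 32. The `"inclusive"` fallback
#' adds the boundary position (`K + 1` per axis).
#'
#' @param n_img image side.
#' @param size patch side.
#' @param stride origin stride.
#' @param convention `"exclusive"` (default) or `"inclusive"`.
#' @return integer origin count per axis.
#' @export
patch_grid_axis_count <- function(n_img, size = 64L, stride = 32L,
                                  convention = c("exclusive", "inclusive")) {
  convention <- match.arg(convention)
  if (size > n_img) stop("patch size exceeds image size")
  if (stride < 1) stop("stride must be >= 1")
  k <- floor((n_img - size) / stride)
  as.integer(if (convention == "inclusive") k + 1L else k)
}

#' Extract a regular grid of 2D patches
#'
#' Patch origins lie at `(r*stride, c*stride)` for
#' `r, c = 0, ..., K-1` with `K` given by [patch_grid_axis_count()]; every
#' patch is fully inside the image.
#'
#' @param image square numeric matrix.
#' @param size patch side (64 in the reference pipeline).
#' @param stride origin stride (32 in the reference pipeline).
#' @param convention origin-count convention, see [patch_grid_axis_count()].
#' @return list with `origins` (data.frame of 0-based `row`/`col`) and
#'   `patches` (list of `size x size` matrices, row-major over the grid).
#' @export
extract_patch_grid <- function(image, size = 64L, stride = 32L,
                               convention = c("exclusive", "inclusive")) {
  convention <- match.arg(convention)
  n_img <- nrow(image)
  if (ncol(image) != n_img) stop("extract_patch_grid: image must be square")
  k <- patch_grid_axis_count(n_img, size, stride, convention)
  if (k == 0)
    return(list(origins = data.frame(row = integer(0), col = integer(0)),
                patches = list()))
  offs <- (seq_len(k) - 1L) * stride
  origins <- expand.grid(row = offs, col = offs, KEEP.OUT.ATTRS = FALSE)
  patches <- lapply(seq_len(nrow(origins)), function(i) {
    r <- origins$row[i]; c <- origins$col[i]
    image[(r + 1):(r + size), (c + 1):(c + size)]
  })
  list(origins = origins, patches = patches)
}

#' Paired 3D patch stacks from a volume pair
#'
#' For each 2D patch origin, one `Ns`-slice stack is cut per starting slice
#' (stride one along the slice axis), pairing the few-view and full-view
#' members identically. With `S` slices this yields `S - Ns + 1` stacks per
#' origin.
#'
#' @param volume_pair `list(few = , full = )` of normalized `dear_volume`s
#'   with identical shapes (a [make_paired_dataset()] element works as is).
#' @param origins data.frame of 0-based `row`/`col` origins (from
#'   [extract_patch_grid()]), or `NULL` to use the full patch grid.
#' @param size patch side.
#' @param ns slices per stack (9 in the reference setting).
#' @param patient patient identifier stored in the provenance.
#' @return list of stacks: each `list(few, full, provenance)` where `few` and
#'   `full` are `ns x size x size` arrays and `provenance` records
#'   `(patient, slice, row, col)`.
#' @export
build_3d_stacks <- function(volume_pair, origins = NULL, size = 64L, ns = 9L,
                            patient = volume_pair$patient %||% 1L) {
  few <- volume_pair$few; full <- volume_pair$full
  if (!identical(dim(few$data), dim(full$data)))
    stop("build_3d_stacks: paired volumes must share dimensions")
  d <- dim(full$data); S <- d[1]
  if (S < ns) stop("build_3d_stacks: volume has fewer slices than ns")
  if (is.null(origins)) {
    k <- patch_grid_axis_count(d[2], size, 32L)
    offs <- if (k > 0) (seq_len(k) - 1L) * 32L else integer(0)
    origins <- expand.grid(row = offs, col = offs, KEEP.OUT.ATTRS = FALSE)
  }
  stacks <- vector("list", nrow(origins) * (S - ns + 1))
  idx <- 1L
  for (i in seq_len(nrow(origins))) {
    r <- origins$row[i]; c <- origins$col[i]
    rs <- (r + 1):(r + size); cs <- (c + 1):(c + size)
    for (s0 in seq_len(S - ns + 1)) {
      sl <- s0:(s0 + ns - 1)
      stacks[[idx]] <- list(
        few = few$data[sl, rs, cs, drop = FALSE],
        full = full$data[sl, rs, cs, drop = FALSE],
        provenance = list(patient = patient, slice = s0 - 1L,
                          row = r, col = c))
      idx <- idx + 1L
    }
  }
  stacks
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Seeded mini-batch iterator over patch stacks
#'
#' Shuffles the stacks with a seeded RNG, emits batches of exactly `nb`
#' samples as `nb x ns x N x N x 1` arrays (short final batches are
#' dropped), reshuffles at every epoch boundary and signals it.
#'
#' @param stacks list of stacks from [build_3d_stacks()].
#' @param nb mini-batch size (10 in the reference setting).
#' @param seed RNG seed controlling the shuffling.
#' @return a function; each call returns
#'   `list(few, full, provenance, epoch, step, new_epoch)` where `few`/`full`
#'   are `nb x ns x N x N x 1` arrays.
#' @export
batch_iterator <- function(stacks, nb = 10L, seed = 1L) {
  if (nb < 1) stop("batch_iterator: nb must be >= 1")
  if (length(stacks) < nb)
    stop("batch_iterator: need at least nb stacks")
  n <- length(stacks)
  steps_per_epoch <- n %/% nb
  epoch <- 0L; pos <- 0L; order <- NULL; step <- 0L
  reshuffle <- function() {
    epoch <<- epoch + 1L
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed + epoch - 1L)
    order <<- sample.int(n)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    pos <<- 0L
  }
  function() {
    new_epoch <- FALSE
    if (is.null(order) || pos + nb > steps_per_epoch * nb) {
      reshuffle(); new_epoch <- TRUE
    }
    sel <- order[(pos + 1):(pos + nb)]
    pos <<- pos + nb
    step <<- step + 1L
    d <- dim(stacks[[sel[1]]]$few)
    few <- array(0, dim = c(nb, d[1], d[2], d[3], 1))
    full <- array(0, dim = c(nb, d[1], d[2], d[3], 1))
    for (i in seq_along(sel)) {
      few[i, , , , 1] <- stacks[[sel[i]]]$few
      full[i, , , , 1] <- stacks[[sel[i]]]$full
    }
    list(few = few, full = full,
         provenance = lapply(stacks[sel], `[[`, "provenance"),
         epoch = epoch, step = step, new_epoch = new_epoch,
         steps_per_epoch = steps_per_epoch)
  }
}
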