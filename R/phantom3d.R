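#' Phantom specification
#'
#' Parameters of the seeded CT-like phantom generator. Phantoms are
#' piecewise-constant ellipse composites: an air background (-1000 HU), a
#' soft-tissue body ellipse (40 HU), nested organ ellipses
#' (40 HU + organ contrast) and spherical low-contrast lesions
#' (local value + lesion contrast). Ellipse centers and semi-axes drift
#' smoothly from slice to slice (a reflected random walk), emulating the
#' ~1 mm slice-to-slice continuity of contiguous abdominal CT series.
#'
#' All `*_hu` arguments are ranges (length-2, lo <= hi) sampled uniformly;
#' `n_organs`/`n_lesions` are integer ranges. Identical spec and seed give
#' bit-identical volumes.
#'
#' @param seed integer RNG seed.
#' @param size pixels per side (square slices).
#' @param n_slices number of slices (>= 9, so that 9-slice stacks exist).
#' @param body_axes_mm range of body-ellipse semi-axes in mm.
#' @param n_organs integer range of organ count.
#' @param organ_contrast_hu organ contrast range relative to 40 HU soft tissue.
#' @param n_lesions integer range of lesion count.
#' @param lesion_radius_mm lesion radius range in mm.
#' @param lesion_contrast_hu lesion contrast range (low contrast, negative).
#' @param drift_scale per-slice random-walk standard deviation in mm.
#' @param noise_sigma_hu additive Gaussian noise level in HU.
#' @param texture_amplitude_hu amplitude of an optional smooth low-frequency
#'   texture added inside the body (0 keeps regions exactly piecewise
#'   constant, which analytic tests rely on).
#' @param pixel_size_mm in-plane pixel size in mm.
#' @param slice_thickness_mm slice spacing in mm.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(seed = 1L, size = 512L, n_slices = 9L,
                         body_axes_mm = c(90, 160),
                         n_organs = c(2L, 5L),
                         organ_contrast_hu = c(-80, 120),
                         n_lesions = c(1L, 3L),
                         lesion_radius_mm = c(3, 8),
                         lesion_contrast_hu = c(-40, -10),
                         drift_scale = 0.5,
                         noise_sigma_hu = 5,
                         texture_amplitude_hu = 0,
                         pixel_size_mm = 0.664,
                         slice_thickness_mm = 1) {
  spec <- list(seed = as.integer(seed), size = as.integer(size),
               n_slices = as.integer(n_slices),
               body_axes_mm = as.numeric(body_axes_mm),
               n_organs = as.integer(n_organs),
               organ_contrast_hu = as.numeric(organ_contrast_hu),
               n_lesions = as.integer(n_lesions),
               lesion_radius_mm = as.numeric(lesion_radius_mm),
               lesion_contrast_hu = as.numeric(lesion_contrast_hu),
               drift_scale = drift_scale,
               noise_sigma_hu = noise_sigma_hu,
               texture_amplitude_hu = texture_amplitude_hu,
               pixel_size_mm = pixel_size_mm,
               slice_thickness_mm = slice_thickness_mm)
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (spec$size <= 0) stop("phantom spec: size must be positive")
  if (spec$n_slices < 9) stop("phantom spec: n_slices must be >= 9")
  rng <- function(r, nm) {
    if (length(r) != 2 || r[1] > r[2])
      stop(sprintf("phantom spec: %s must be a non-empty range (lo <= hi)", nm))
  }
  rng(spec$body_axes_mm, "body_axes_mm")
  rng(spec$n_organs, "n_organs")
  rng(spec$organ_contrast_hu, "organ_contrast_hu")
  rng(spec$n_lesions, "n_lesions")
  rng(spec$lesion_radius_mm, "lesion_radius_mm")
  rng(spec$lesion_contrast_hu, "lesion_contrast_hu")
  if (spec$n_organs[1] < 0 || spec$n_lesions[1] < 0)
    stop("phantom spec: counts must be non-negative")
  if (spec$drift_scale < 0 || spec$noise_sigma_hu < 0)
    stop("phantom spec: drift_scale and noise_sigma_hu must be non-negative")
  half_fov <- spec$size * spec$pixel_size_mm / 2
  if (spec$body_axes_mm[2] >= half_fov)
    stop("phantom spec: body semi-axes exceed the field of view")
  invisible(spec)
}

runif1 <- function(r) if (r[1] == r[2]) r[1] else stats::runif(1, r[1], r[2])
rint1 <- function(r) if (r[1] == r[2]) r[1] else sample(seq(r[1], r[2]), 1)

# Reflect a random-walk proposal into [lo, hi].
.reflect <- function(x, lo, hi) {
  if (hi <= lo) return(lo)
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}

# Deterministic builder shared by generate_phantom_volume() and
# generate_lesion_mask(): one seeded pass produces both the HU volume and
# the aligned lesion mask, so the two exported functions can never drift
# apart. The caller's RNG state is preserved.
.phantom_build <- function(spec) {
  validate_phantom_spec(spec)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  N <- spec$size; S <- spec$n_slices
  px <- spec$pixel_size_mm; dz <- spec$slice_thickness_mm
  half <- (N - 1) / 2
  xs <- ((seq_len(N) - 1) - half) * px       # column -> x (mm)
  ys <- (half - (seq_len(N) - 1)) * px       # row    -> y (mm)
  X <- matrix(xs, N, N, byrow = TRUE)
  Y <- matrix(ys, N, N)

  half_fov <- N * px / 2
  walk <- function(x0, lo, hi, sd) {
    out <- numeric(S); out[1] <- x0
    if (S > 1) for (s in 2:S)
      out[s] <- .reflect(out[s - 1] + stats::rnorm(1, 0, sd), lo, hi)
    out
  }

  # body ellipse per slice
  ax0 <- runif1(spec$body_axes_mm); ay0 <- runif1(spec$body_axes_mm)
  cx0 <- stats::runif(1, -5, 5); cy0 <- stats::runif(1, -5, 5)
  body <- list(
    cx = walk(cx0, -10, 10, spec$drift_scale),
    cy = walk(cy0, -10, 10, spec$drift_scale),
    ax = walk(ax0, spec$body_axes_mm[1], min(spec$body_axes_mm[2], half_fov - 2), spec$drift_scale),
    ay = walk(ay0, spec$body_axes_mm[1], min(spec$body_axes_mm[2], half_fov - 2), spec$drift_scale))

  # organs: nested ellipses with per-slice drift
  n_org <- rint1(spec$n_organs)
  organs <- vector("list", n_org)
  if (n_org > 0) for (k in seq_len(n_org)) {
    fr <- stats::runif(1, 0.05, 0.55); th <- stats::runif(1, 0, 2 * pi)
    oa <- stats::runif(1, 0.08, 0.3) * ax0
    ob <- stats::runif(1, 0.08, 0.3) * ay0
    organs[[k]] <- list(
      cx = walk(fr * ax0 * cos(th) + cx0, -0.6 * ax0, 0.6 * ax0, spec$drift_scale),
      cy = walk(fr * ay0 * sin(th) + cy0, -0.6 * ay0, 0.6 * ay0, spec$drift_scale),
      ax = walk(oa, 0.05 * ax0, 0.35 * ax0, spec$drift_scale),
      ay = walk(ob, 0.05 * ay0, 0.35 * ay0, spec$drift_scale),
      hu = 40 + runif1(spec$organ_contrast_hu))
  }

  # lesions: spheres (3D) placed well inside the body; the z-extent is
  # clipped to the volume when a sphere cannot fit axially
  n_les <- rint1(spec$n_lesions)
  lesions <- vector("list", n_les)
  if (n_les > 0) for (k in seq_len(n_les)) {
    r <- runif1(spec$lesion_radius_mm)
    fr <- stats::runif(1, 0.05, 0.5); th <- stats::runif(1, 0, 2 * pi)
    zmax <- (S - 1) * dz
    zc <- if (2 * r < zmax) stats::runif(1, r, zmax - r) else zmax / 2
    lesions[[k]] <- list(
      cx = fr * 0.8 * ax0 * cos(th) + cx0,
      cy = fr * 0.8 * ay0 * sin(th) + cy0,
      zc = zc, r = r,
      contrast = runif1(spec$lesion_contrast_hu))
  }

  vol <- array(-1000, dim = c(S, N, N))
  mask <- array(FALSE, dim = c(S, N, N))
  inside <- function(cx, cy, ax, ay) ((X - cx) / ax)^2 + ((Y - cy) / ay)^2 <= 1

  tex <- NULL
  if (spec$texture_amplitude_hu > 0) {
    f1 <- stats::runif(2, 0.5, 2); ph <- stats::runif(2, 0, 2 * pi)
    tex <- spec$texture_amplitude_hu *
      sin(2 * pi * f1[1] * X / (N * px) + ph[1]) *
      cos(2 * pi * f1[2] * Y / (N * px) + ph[2])
  }

  noise <- if (spec$noise_sigma_hu > 0)
    array(stats::rnorm(S * N * N, 0, spec$noise_sigma_hu), dim = c(S, N, N)) else NULL

  lesion_base <- rep(NA_real_, n_les)
  for (s in seq_len(S)) {
    sl <- matrix(-1000, N, N)
    bmask <- inside(body$cx[s], body$cy[s], body$ax[s], body$ay[s])
    sl[bmask] <- 40
    if (n_org > 0) for (k in seq_len(n_org)) {
      om <- inside(organs[[k]]$cx[s], organs[[k]]$cy[s],
                   organs[[k]]$ax[s], organs[[k]]$ay[s]) & bmask
      sl[om] <- organs[[k]]$hu
    }
    if (!is.null(tex)) sl[bmask] <- sl[bmask] + tex[bmask]
    if (n_les > 0) for (k in seq_len(n_les)) {
      les <- lesions[[k]]
      dz2 <- ((s - 1) * dz - les$zc)^2
      if (dz2 >= les$r^2) next
      rho <- sqrt(les$r^2 - dz2)
      lm <- ((X - les$cx)^2 + (Y - les$cy)^2 <= rho^2) & bmask
      if (!any(lm)) next
      if (is.na(lesion_base[k])) {
        # underlying composite value at the lesion center (pre-lesion)
        j <- which.min(abs(xs - les$cx)); i <- which.min(abs(ys - les$cy))
        lesion_base[k] <- sl[i, j]
      }
      sl[lm] <- lesion_base[k] + les$contrast
      msl <- mask[s, , ]; msl[lm] <- TRUE; mask[s, , ] <- msl
    }
    vol[s, , ] <- sl
  }
  if (!is.null(noise)) vol <- vol + noise

  list(volume = new_volume(vol, units = "HU", pixel_size_mm = px,
                           slice_thickness_mm = dz),
       mask = mask,
       meta = list(body = body, organs = organs, lesions = lesions,
                   lesion_base = lesion_base))
}

#' Generate a CT-like phantom volume
#'
#' Builds the HU-valued volume described by `spec` (see [phantom_spec()]).
#' Deterministic: the same spec (including seed) always yields bit-identical
#' output; the caller's RNG state is untouched.
#'
#' @param spec a [phantom_spec()].
#' @return a `dear_volume` in HU units, with lesion metadata attached as
#'   `attr(, "lesions")`.
#' @export
generate_phantom_volume <- function(spec) {
  b <- .phantom_build(spec)
  v <- b$volume
  attr(v, "lesions") <- b$meta$lesions
  attr(v, "lesion_base") <- b$meta$lesion_base
  v
}

#' Lesion mask aligned with the generated phantom
#'
#' Marks exactly the voxels painted as lesions by [generate_phantom_volume()]
#' for the same spec. Rebuilt from the same seeded draw, so volume and mask
#' can never disagree.
#'
#' @param spec the same [phantom_spec()] passed to the volume generator.
#' @return logical 3D array, `n_slices x N x N`.
#' @export
generate_lesion_mask <- function(spec) {
  .phantom_build(spec)$mask
}

#' Simulate a paired few-view / full-view dataset
#'
#' For each synthetic patient, the ground truth is the phantom volume and the
#' few-view input is its slice-wise FBP reconstruction from `n_views_few`
#' projections (75 by default), both normalized to `[0, 1]` with a shared
#' window. Patient `i` uses seed `spec$seed + i - 1`.
#'
#' @param spec a [phantom_spec()]; its `size`/`pixel_size_mm` must match
#'   `geometry`.
#' @param n_patients number of phantoms to simulate.
#' @param geometry a [fanbeam_geometry()].
#' @param n_views_few number of views for the degraded input.
#' @param window HU normalization window applied to both members of a pair.
#' @return list of `n_patients` elements, each
#'   `list(full, few, patient, seed)` of normalized `dear_volume`s.
#' @export
make_paired_dataset <- function(spec, n_patients, geometry, n_views_few = 75L,
                                window = c(-1000, 2000)) {
  if (n_views_few > geometry$n_views_full)
    stop("n_views_few exceeds the full view count of the geometry")
  if (spec$size != geometry$image_size)
    stop("phantom size and geometry image_size differ")
  out <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    sp <- spec; sp$seed <- spec$seed + i - 1L
    full_hu <- generate_phantom_volume(sp)
    few_hu <- simulate_fewview_volume(full_hu, geometry, n_views = n_views_few)
    out[[i]] <- list(full = normalize_volume(full_hu, window),
                     few = normalize_volume(few_hu, window),
                     patient = i, seed = sp$seed)
  }
  out
}

#' Write a dataset manifest
#'
#' Writes each pair as NIfTI files plus a JSON manifest (patient id, seed,
#' file paths).
#'
#' @param dataset result of [make_paired_dataset()].
#' @param dir output directory.
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(dataset, function(p) {
    fp <- file.path(dir, sprintf("patient%03d_full.nii.gz", p$patient))
    qp <- file.path(dir, sprintf("patient%03d_few.nii.gz", p$patient))
    write_volume_nifti(p$full, fp)
    write_volume_nifti(p$few, qp)
    list(patient = p$patient, seed = p$seed, full = fp, few = qp)
  })
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  invisible(mp)
}
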