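#' Fan-beam acquisition geometry
#'
#' Equiangular fan-beam geometry for slice-wise simulation. The detector arc
#' is sized to cover the image-diagonal field of view plus a 2% margin, with
#' angular sampling chosen so the detector spacing projected to the
#' isocenter equals the pixel size.
#'
#' @param source_detector_mm distance source to detector array (mm).
#' @param source_isocenter_mm distance source to isocenter (mm).
#' @param pixel_size_mm image pixel size (mm).
#' @param image_size image side in pixels.
#' @param n_views_full number of views of a full acquisition.
#' @param n_detectors detector sample count; derived from the field of view
#'   when `NULL`.
#' @param scan_range_rad angular scan range (full scan, `2*pi`).
#' @return a `fanbeam_geometry` object.
#' @export
fanbeam_geometry <- function(source_detector_mm = 1085.6,
                             source_isocenter_mm = 595.0,
                             pixel_size_mm = 0.664,
                             image_size = 512L,
                             n_views_full = 2304L,
                             n_detectors = NULL,
                             scan_range_rad = 2 * pi) {
  if (source_detector_mm <= source_isocenter_mm || source_isocenter_mm <= 0)
    stop("geometry requires source_detector_mm > source_isocenter_mm > 0")
  if (n_views_full < 1) stop("n_views_full must be >= 1")
  r_fov <- image_size * pixel_size_mm / 2 * sqrt(2) * 1.02
  if (r_fov >= source_isocenter_mm)
    stop("field of view exceeds the source-isocenter distance; fan cannot cover it")
  dg <- pixel_size_mm / source_isocenter_mm
  gmax <- asin(r_fov / source_isocenter_mm)
  if (is.null(n_detectors)) {
    halfn <- ceiling(gmax / dg)
    n_detectors <- 2L * as.integer(halfn) + 1L
  }
  halfn <- (n_detectors - 1L) / 2
  g <- structure(
    list(source_detector_mm = source_detector_mm,
         source_isocenter_mm = source_isocenter_mm,
         pixel_size_mm = pixel_size_mm,
         image_size = as.integer(image_size),
         n_views_full = as.integer(n_views_full),
         n_detectors = as.integer(n_detectors),
         detector_sampling = "equiangular",
         scan_range_rad = scan_range_rad,
         gamma_spacing_rad = dg,
         gammas = (seq_len(n_detectors) - 1 - halfn) * dg),
    class = "fanbeam_geometry")
  if (max(g$gammas) < gmax - 1e-12)
    stop("detector arc does not cover the image-support fan")
  g
}

#' @export
print.fanbeam_geometry <- function(x, ...) {
  cat(sprintf("<fanbeam_geometry> SDD %.1f mm, SID %.1f mm, %d detectors (equiangular), %d full views, image %dpx @ %.3f mm\n",
              x$source_detector_mm, x$source_isocenter_mm, x$n_detectors,
              x$n_views_full, x$image_size, x$pixel_size_mm))
  invisible(x)
}

#' Equally spaced view angles over the scan range
#' @param geometry a [fanbeam_geometry()].
#' @param n_views number of views.
#' @return numeric vector of strictly increasing angles in `[0, scan_range)`.
#' @export
view_angles <- function(geometry, n_views) {
  if (n_views < 1) stop("n_views must be >= 1")
  (seq_len(n_views) - 1) * geometry$scan_range_rad / n_views
}

#' Fan-beam forward projection of a single slice
#'
#' Computes line integrals along fan rays from `n_views` equally spaced
#' source positions over the full scan range. The operator is linear in the
#' image; integrals are evaluated by bilinear sampling at half-pixel steps.
#'
#' @param image square numeric matrix matching `geometry$image_size`.
#' @param geometry a [fanbeam_geometry()].
#' @param n_views number of views.
#' @return a `dear_sinogram`: list with `data` (`n_views x n_detectors`),
#'   `view_angles_rad`, and the geometry.
#' @export
forward_project_slice <- function(image, geometry, n_views = geometry$n_views_full) {
  if (!is.matrix(image) || nrow(image) != ncol(image))
    stop("forward_project_slice: image must be a square matrix")
  if (nrow(image) != geometry$image_size)
    stop("forward_project_slice: image size does not match geometry")
  betas <- view_angles(geometry, n_views)
  sino <- .fan_forward(image, geometry$pixel_size_mm,
                       geometry$source_isocenter_mm,
                       betas, geometry$gammas,
                       step_mm = geometry$pixel_size_mm / 2)
  structure(list(data = sino, view_angles_rad = betas, geometry = geometry),
            class = "dear_sinogram")
}

# Discrete equiangular ramp kernel g(n * dgamma); "hann" applies a Hann
# window to the ramp's frequency response.
.fan_filter_fft <- function(nd, dg, nfft, filter = c("ramp", "hann")) {
  filter <- match.arg(filter)
  n <- -(nd - 1):(nd - 1)
  gker <- numeric(length(n))
  gker[n == 0] <- 1 / (8 * dg^2)
  odd <- n %% 2 != 0
  gker[odd] <- -0.5 / (pi * sin(n[odd] * dg))^2
  gpad <- numeric(nfft)
  gpad[seq_along(gker)] <- gker
  G <- stats::fft(gpad)
  if (filter == "hann") {
    w <- 0.5 * (1 + cos(2 * pi * (seq_len(nfft) - 1) / nfft))
    G <- G * w
  }
  G
}

#' Filtered back-projection of a fan-beam sinogram
#'
#' Weighted equiangular fan-beam FBP: cosine ray weighting, ramp filtering of
#' each view (FFT-based, Ram-Lak by default, Hann optional) and
#' distance-weighted backprojection onto the image grid. Negative values are
#' retained.
#'
#' @param sinogram a `dear_sinogram` from [forward_project_slice()].
#' @param geometry a [fanbeam_geometry()]; must match the sinogram.
#' @param filter `"ramp"` (default) or `"hann"`.
#' @return reconstructed square matrix (`image_size` x `image_size`).
#' @export
fbp_slice <- function(sinogram, geometry = sinogram$geometry,
                      filter = c("ramp", "hann")) {
  filter <- match.arg(filter)
  p <- sinogram$data
  nd <- geometry$n_detectors
  nv <- length(sinogram$view_angles_rad)
  if (ncol(p) != nd || nrow(p) != nv)
    stop("fbp_slice: sinogram does not match geometry/view count")
  dg <- geometry$gamma_spacing_rad
  sid <- geometry$source_isocenter_mm
  # cosine weighting
  p1 <- sweep(p, 2, sid * cos(geometry$gammas), `*`)
  # FFT row filtering
  nfft <- 2^ceiling(log2(3 * nd))
  G <- .fan_filter_fft(nd, dg, nfft, filter)
  A <- matrix(0, nfft, nv)
  A[seq_len(nd), ] <- t(p1)
  Q <- Re(stats::mvfft(stats::mvfft(A) * G, inverse = TRUE)) / nfft
  qf <- t(Q[nd:(2 * nd - 1), , drop = FALSE]) * dg
  dbeta <- geometry$scan_range_rad / nv
  .fan_backproject(qf, geometry$pixel_size_mm, sid,
                   sinogram$view_angles_rad, geometry$gammas,
                   geometry$image_size, dbeta)
}

#' Replace each slice of a volume with its few-view FBP reconstruction
#'
#' Applies [forward_project_slice()] + [fbp_slice()] slice by slice,
#' simulating a few-view acquisition of the input volume. Units are
#' preserved (HU in, HU-scale out); negative overshoots of the FBP are kept.
#'
#' @param volume a `dear_volume` (typically in HU, before normalization).
#' @param geometry a [fanbeam_geometry()] matching the volume grid.
#' @param n_views number of simulated views (75 for the few-view setting).
#' @param filter FBP filter, see [fbp_slice()].
#' @return a `dear_volume` of identical shape and units.
#' @export
simulate_fewview_volume <- function(volume, geometry, n_views = 75L,
                                    filter = c("ramp", "hann")) {
  filter <- match.arg(filter)
  if (n_views < 1) stop("simulate_fewview_volume: n_views must be >= 1")
  d <- dim(volume$data)
  if (d[2] != geometry$image_size)
    stop("simulate_fewview_volume: volume does not match geometry image size")
  out <- array(0, dim = d)
  for (s in seq_len(d[1])) {
    sino <- forward_project_slice(volume$data[s, , ], geometry, n_views)
    out[s, , ] <- fbp_slice(sino, geometry, filter)
  }
  new_volume(out, units = volume$units, pixel_size_mm = volume$pixel_size_mm,
             slice_thickness_mm = volume$slice_thickness_mm)
}

#' Persist a sinogram as flat binary plus a JSON sidecar
#' @param sinogram a `dear_sinogram`.
#' @param path base path; writes `<path>.bin` and `<path>.json`.
#' @return base path, invisibly.
#' @export
write_sinogram <- function(sinogram, path) {
  con <- file(paste0(path, ".bin"), "wb")
  writeBin(as.numeric(sinogram$data), con, size = 8)
  close(con)
  g <- sinogram$geometry
  jsonlite::write_json(
    list(n_views = nrow(sinogram$data), n_detectors = ncol(sinogram$data),
         view_angles_rad = sinogram$view_angles_rad,
         geometry = list(sdd_mm = g$source_detector_mm,
                         sid_mm = g$source_isocenter_mm,
                         pixel_mm = g$pixel_size_mm,
                         image_size = g$image_size,
                         n_views_full = g$n_views_full,
                         n_detectors = g$n_detectors)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a sinogram written by [write_sinogram()]
#' @param path base path used when writing.
#' @return a `dear_sinogram`.
#' @export
read_sinogram <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(paste0(path, ".bin"), "rb")
  v <- readBin(con, "numeric", n = meta$n_views * meta$n_detectors, size = 8)
  close(con)
  geom <- fanbeam_geometry(source_detector_mm = meta$geometry$sdd_mm,
                           source_isocenter_mm = meta$geometry$sid_mm,
                           pixel_size_mm = meta$geometry$pixel_mm,
                           image_size = meta$geometry$image_size,
                           n_views_full = meta$geometry$n_views_full,
                           n_detectors = meta$geometry$n_detectors)
  structure(list(data = matrix(v, meta$n_views, meta$n_detectors),
                 view_angles_rad = meta$view_angles_rad,
                 geometry = geom),
            class = "dear_sinogram")
}
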