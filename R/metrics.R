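#' Peak signal-to-noise ratio
#'
#' `10 * log10(peak^2 / MSE)` in dB. Identical inputs return `Inf` (the
#' documented sentinel). The peak is fixed at 1 for normalized data.
#'
#' @param x,y numeric arrays of identical shape.
#' @param peak signal peak (1 on the normalized scale).
#' @return PSNR in dB.
#' @export
psnr <- function(x, y, peak = 1.0) {
  if (!identical(dim(x) %||% length(x), dim(y) %||% length(y)))
    stop("psnr: shapes differ")
  mse <- mean((x - y)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Root mean squared error
#'
#' Square root of the voxel-mean squared difference (on the normalized
#' `[0, 1]` scale in the reference pipeline).
#'
#' @param x,y numeric arrays of identical shape.
#' @return scalar RMSE.
#' @export
rmse <- function(x, y) {
  if (!identical(dim(x) %||% length(x), dim(y) %||% length(y)))
    stop("rmse: shapes differ")
  sqrt(mean((x - y)^2))
}

#' Volume-level SSIM
#'
#' Slice-wise SSIM averaged over slices.
#'
#' @param x,y 3D arrays (`n_slices x N x N`) of identical shape.
#' @param config a [loss_config()].
#' @return scalar mean SSIM.
#' @export
ssim_volume <- function(x, y, config = loss_config()) {
  d <- dim(x)
  mean(vapply(seq_len(d[1]), function(s)
    ssim_index(x[s, , ], y[s, , ], config), numeric(1)))
}

#' Whole-volume inference with sliding 9-slice windows
#'
#' Applies a (fully convolutional) generator to every window of `ns`
#' consecutive slices with stride 1 and fuses the overlapping predictions.
#' With `fusion = "average"` every output slice is the uniform mean of the
#' 1 to `ns` window predictions covering it (weights summing to one);
#' `"center"` keeps only each window's center slice where available.
#'
#' @param generator a `dear_generator`, or any function mapping an
#'   `ns x N x N` array to an array of the same shape.
#' @param fewview a `dear_volume` (normalized) with at least `ns` slices.
#' @param ns window length (9 in the reference setting).
#' @param fusion `"average"` (default) or `"center"`.
#' @return a restored `dear_volume`.
#' @export
reconstruct_volume <- function(generator, fewview, ns = 9L,
                               fusion = c("average", "center")) {
  fusion <- match.arg(fusion)
  apply_fn <- if (is.function(generator)) generator else
    function(x) generator_apply(generator, x)
  d <- dim(fewview$data); S <- d[1]
  if (S < ns) stop("reconstruct_volume: fewer slices than the window length")
  acc <- array(0, dim = d)
  wgt <- numeric(S)
  for (s0 in seq_len(S - ns + 1)) {
    sl <- s0:(s0 + ns - 1)
    pred <- apply_fn(array(fewview$data[sl, , ], dim = c(ns, d[2], d[3])))
    if (fusion == "average") {
      acc[sl, , ] <- array(acc[sl, , ], dim = dim(pred)) + pred
      wgt[sl] <- wgt[sl] + 1
    } else {
      cs <- s0 + (ns - 1L) %/% 2L
      keep <- if (s0 == 1) 1:(cs - s0 + 1) else
        if (s0 == S - ns + 1) (cs - s0 + 1):ns else (cs - s0 + 1)
      for (k in keep) {
        acc[s0 + k - 1, , ] <- pred[k, , ]
        wgt[s0 + k - 1] <- 1
      }
    }
  }
  if (fusion == "average") for (s in seq_len(S)) acc[s, , ] <- acc[s, , ] / wgt[s]
  if (fewview$units == "normalized") {
    # residual predictions can overshoot slightly; clamp to the dynamic range
    acc[acc < 0] <- 0; acc[acc > 1] <- 1
  }
  new_volume(acc, units = fewview$units, pixel_size_mm = fewview$pixel_size_mm,
             slice_thickness_mm = fewview$slice_thickness_mm)
}

#' Per-volume quality metrics with mean/STD aggregation
#'
#' Computes PSNR, SSIM and RMSE of each restored volume against its ground
#' truth and aggregates mean and standard deviation over the rows
#' (the mean +/- STD reporting convention).
#'
#' @param restored,reference lists of `dear_volume`s (or single volumes).
#' @param config a [loss_config()] for the SSIM constants.
#' @return data.frame of per-volume rows, with a `summary` attribute holding
#'   the mean and sd of each metric.
#' @export
metrics_table <- function(restored, reference, config = loss_config()) {
  if (inherits(restored, "dear_volume")) restored <- list(restored)
  if (inherits(reference, "dear_volume")) reference <- list(reference)
  rows <- do.call(rbind, lapply(seq_along(restored), function(i) {
    x <- restored[[i]]$data; y <- reference[[i]]$data
    data.frame(volume = i,
               psnr_db = psnr(x, y),
               ssim = ssim_volume(x, y, config),
               rmse = rmse(x, y))
  }))
  attr(rows, "summary") <- data.frame(
    metric = c("psnr_db", "ssim", "rmse"),
    mean = c(mean(rows$psnr_db), mean(rows$ssim), mean(rows$rmse)),
    sd = c(stats::sd(rows$psnr_db), stats::sd(rows$ssim), stats::sd(rows$rmse)))
  rows
}

#' Write a metrics table (per-volume rows plus a summary row) as CSV
#' @param table result of [metrics_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(table, path) {
  s <- attr(table, "summary")
  out <- rbind(table,
               data.frame(volume = NA, psnr_db = s$mean[1], ssim = s$mean[2],
                          rmse = s$mean[3]))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
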