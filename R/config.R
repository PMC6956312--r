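#' Read a YAML run configuration
#'
#' Parses a run configuration with the keys used by the command-line
#' interface and fills package defaults for everything omitted:
#' `geometry.sdd_mm`, `geometry.sid_mm`, `geometry.pixel_mm`,
#' `geometry.image_size`, `geometry.n_views_full`; `sim.n_views_few`,
#' `sim.filter`; `phantom.*` (any [phantom_spec()] argument);
#' `patch.size`, `patch.stride`, `patch.ns`, `patch.origin_convention`;
#' `normalize.lo_hu`, `normalize.hi_hu`; `train.*` (any [train_config()]
#' scalar argument plus `generator.variant` / `generator.base_filters` /
#' `generator.mode`).
#'
#' @param path YAML file path (`NULL` returns pure defaults).
#' @return list with `geometry`, `phantom`, `sim`, `patch`, `normalize`
#'   and `train` components ready for the pipeline functions.
#' @export
read_run_config <- function(path = NULL) {
  y <- if (is.null(path)) list() else yaml::read_yaml(path)
  gy <- y$geometry %||% list()
  geometry <- fanbeam_geometry(
    source_detector_mm = gy$sdd_mm %||% 1085.6,
    source_isocenter_mm = gy$sid_mm %||% 595.0,
    pixel_size_mm = gy$pixel_mm %||% 0.664,
    image_size = gy$image_size %||% 512L,
    n_views_full = gy$n_views_full %||% 2304L)
  ph <- y$phantom %||% list()
  ph$size <- ph$size %||% geometry$image_size
  ph$pixel_size_mm <- ph$pixel_size_mm %||% geometry$pixel_size_mm
  phantom <- do.call(phantom_spec, ph)
  sim <- list(n_views_few = (y$sim %||% list())$n_views_few %||% 75L,
              filter = (y$sim %||% list())$filter %||% "ramp")
  pt <- y$patch %||% list()
  patch <- list(size = pt$size %||% 64L, stride = pt$stride %||% 32L,
                ns = pt$ns %||% 9L,
                origin_convention = pt$origin_convention %||% "exclusive")
  nm <- y$normalize %||% list()
  normalize <- c(nm$lo_hu %||% -1000, nm$hi_hu %||% 2000)
  tr <- y$train %||% list()
  gcfg <- tr$generator %||% list()
  gen <- generator_config(variant = gcfg$variant %||% "custom",
                          mode = gcfg$mode %||% "3d",
                          base_filters = gcfg$base_filters %||% 8L)
  lcfg <- tr$loss %||% list()
  loss <- loss_config(lambda_gp = lcfg$lambda_gp %||% 10,
                      lambda_sl = lcfg$lambda_sl %||% 0.5,
                      lambda_al = lcfg$lambda_al %||% 0.0025,
                      ssim_window = lcfg$ssim_window %||% 11L)
  dcfg <- tr$discriminator %||% list()
  disc <- discriminator_config(
    conv_filters = dcfg$conv_filters %||% c(64L, 64L, 128L, 128L, 256L, 256L),
    fc_units = dcfg$fc_units %||% c(1024L, 1L),
    mode = gen$mode)
  train <- train_config(batch_size = tr$batch_size %||% 10L,
                        lr_init = tr$lr_init %||% 1e-4,
                        lr_decay = tr$lr_decay %||% 0.5,
                        n_critic = tr$n_critic %||% 5L,
                        epochs = tr$epochs %||% 20L,
                        seed = tr$seed %||% 1L,
                        loss = loss, generator = gen, discriminator = disc,
                        adversarial = tr$adversarial %||% TRUE,
                        history_csv = tr$history_csv,
                        checkpoint_dir = tr$checkpoint_dir)
  list(geometry = geometry, phantom = phantom, sim = sim, patch = patch,
       normalize = normalize, train = train)
}
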