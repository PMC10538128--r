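#' Toolkit configuration
#'
#' Reads a YAML configuration file and merges it over the package
#' defaults.  Recognised sections and keys:
#' \describe{
#'   \item{sensor}{`K`, `coverage`, `insulation_thickness`, `screen_radius`.}
#'   \item{grid}{`fine_n`, `recon_n`.}
#'   \item{fov}{`radius_px` (reconstruction pixels).}
#'   \item{phantom}{arguments of [phantom_config()].}
#'   \item{dataset}{`train_per_class`, `train_random`, `test_per_class`,
#'     `snr_db`.}
#' }
#'
#' @param file optional path to a YAML file; `NULL` for pure defaults.
#' @param ... named overrides merged last, e.g. `grid = list(fine_n = 64)`.
#' @return nested list of class `cceit_config`.
#' @export
cceit_config <- function(file = NULL, ...) {
  cfg <- list(
    sensor = list(K = 32L, coverage = 0.8, insulation_thickness = 0.08,
                  screen_radius = 1.1),
    grid = list(fine_n = 256L, recon_n = 64L),
    fov = list(radius_px = FOV_RADIUS_PX),
    phantom = unclass(phantom_config()),
    dataset = list(train_per_class = 9375L, train_random = 44000L,
                   test_per_class = 2500L, snr_db = 60)
  )
  merge_rec <- function(a, b) {
    for (nm in names(b))
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
        merge_rec(a[[nm]], b[[nm]]) else b[[nm]]
    a
  }
  if (!is.null(file)) cfg <- merge_rec(cfg, yaml::read_yaml(file))
  over <- list(...)
  if (length(over)) cfg <- merge_rec(cfg, over)
  structure(cfg, class = "cceit_config")
}

#' Build geometry objects from a configuration
#'
#' @param cfg a [cceit_config()].
#' @return list with `sensor`, `grid`, `fov`, `phantom` objects.
#' @export
config_geometry <- function(cfg = cceit_config()) {
  sensor <- cceit_sensor(K = cfg$sensor$K, coverage = cfg$sensor$coverage,
                         insulation_thickness = cfg$sensor$insulation_thickness,
                         screen_radius = cfg$sensor$screen_radius)
  grid <- cceit_grid(fine_n = cfg$grid$fine_n, recon_n = cfg$grid$recon_n,
                     sensor = sensor)
  fov <- build_fov_mask(grid, cfg$fov$radius_px * grid$h_recon)
  phantom <- do.call(phantom_config, cfg$phantom)
  list(sensor = sensor, grid = grid, fov = fov, phantom = phantom)
}
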