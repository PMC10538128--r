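# Shared lazy fixtures: geometry objects and calibrations are expensive
# enough to build once and reuse across test files.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

default_sensor <- function() fixture("sensor", cceit_sensor)

grid64 <- function() fixture("grid64", function()
  cceit_grid(fine_n = 64, sensor = default_sensor()))

fov64 <- function() fixture("fov64", function() build_fov_mask(grid64()))

calib64 <- function() fixture("calib64", function()
  calibrate(default_sensor(), grid64(), fov64()))

# small 8-electrode sensor on a coarse grid for Jacobian oracles
toy_sensor <- function() fixture("toy_sensor", function()
  cceit_sensor(K = 8, coverage = 0.7, insulation_thickness = 0.25,
               screen_radius = 1.35))

toy_grid <- function() fixture("toy_grid", function()
  cceit_grid(fine_n = 16, recon_n = 16, sensor = toy_sensor()))

toy_fov <- function() fixture("toy_fov", function()
  build_fov_mask(toy_grid(), fov_radius = 0.8))

toy_calib <- function() fixture("toy_calib", function()
  calibrate(toy_sensor(), toy_grid(), toy_fov()))

# brute-force pairwise AUC estimator: P(score_pos > score_neg) + 0.5 P(tie)
pairwise_auc <- function(scores, positive) {
  sp <- scores[positive]; sn <- scores[!positive]
  cmp <- outer(sp, sn, ">") + 0.5 * outer(sp, sn, "==")
  mean(cmp)
}

# central-difference gradient of a scalar function
numeric_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, 0)
}
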