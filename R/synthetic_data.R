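# Synthetic inputs with known ground truth: oxygen phantom fields, rendered
# Stern-Volmer sensor stacks, and zone-graded staining image sets. Every
# stochastic output is driven by the seed in the spec and is bit-reproducible.

#' Phantom specification for synthetic sensor data
#'
#' Scenario and acquisition parameters for [make_oxygen_phantom()] and
#' [render_sensor_stack()]. Defaults mirror the bench protocol: 10-min frame
#' cadence, 2-hour run, three-zone oxygen targets inside the measured bands
#' (19 / 13 / 7 % O2 without cells), 1% multiplicative (photon-like)
#' channel noise, and a 16-bit camera.
#'
#' @param scenario `"uniform"`, `"step_switch"` or `"three_zone_steady"`.
#' @param seed integer seed; mandatory for any stochastic output.
#' @param frame_interval_s,duration_s acquisition cadence and span (s).
#' @param zone_targets plateau %O2 per zone after the gas switch.
#' @param tau_s relaxation time constant(s) per zone (recycled), governing
#'   the step_switch exponential approach.
#' @param noise_sigma multiplicative Gaussian sigma per channel
#'   (`c(red =, green =)`).
#' @param calib true [sv_calibration()] used to render ratios.
#' @param gain_green green-channel gain (camera counts); red follows as
#'   `gain_green * R0 * sv_forward(O2)`.
#' @param background background level outside sensor disks (counts).
#' @param bit_depth camera bit depth (8 or 16).
#' @param px_size_m pixel pitch of the rendered image (m/px); the 1.5 mm
#'   sensor disks are drawn at this scale.
#' @return object of class `oxz_phantom_spec`.
#' @export
phantom_spec <- function(scenario = c("step_switch", "uniform",
                                      "three_zone_steady"),
                         seed = 1L,
                         frame_interval_s = 600, duration_s = 7200,
                         zone_targets = c(19, 13, 7), tau_s = 450,
                         noise_sigma = c(red = 0.01, green = 0.01),
                         calib = sv_calibration(f1 = 0.8, Ksv = 0.05, R0 = 2),
                         gain_green = 20000, background = 500,
                         bit_depth = 16, px_size_m = 100e-6) {
  scenario <- match.arg(scenario)
  if (any(noise_sigma < 0)) stop("configuration error: noise sigma must be >= 0")
  if (is.null(seed) || !is.finite(seed)) {
    stop("configuration error: a seed is mandatory")
  }
  structure(list(scenario = scenario, seed = as.integer(seed),
                 frame_interval_s = frame_interval_s,
                 duration_s = duration_s, zone_targets = zone_targets,
                 tau_s = rep_len(tau_s, 3), noise_sigma = noise_sigma,
                 calib = calib, gain_green = gain_green,
                 background = background, bit_depth = as.integer(bit_depth),
                 px_size_m = px_size_m),
            class = "oxz_phantom_spec")
}

#' Oxygen phantom field with known ground truth
#'
#' Generates a width-homogeneous %O2 field over the chamber length:
#' `uniform` is 19% everywhere; `step_switch` relaxes each zone
#' exponentially from 19% toward its target with time constant `tau_s`;
#' `three_zone_steady` is a static piecewise-smooth profile (logistic blends
#' of width `blend_mm` across the zone boundaries).
#'
#' @param spec a [phantom_spec()].
#' @param geometry a [device_geometry()].
#' @param nx_field samples along the chamber length.
#' @param blend_mm spatial blend width of the steady profile (mm).
#' @return object of class `oxz_phantom`: `x` (m), `times` (s), matrix `O2`
#'   (times x positions, % O2) and the spec.
#' @export
make_oxygen_phantom <- function(spec, geometry = device_geometry(),
                                nx_field = 400, blend_mm = 2) {
  L <- geometry$chamber_length
  x <- (seq_len(nx_field) - 0.5) * L / nx_field
  zones <- zone_of(x, geometry = geometry)
  times <- switch(spec$scenario,
                  three_zone_steady = 0,
                  seq(0, spec$duration_s, by = spec$frame_interval_s))
  O2 <- switch(spec$scenario,
    uniform = matrix(19, length(times), nx_field),
    step_switch = {
      tgt <- spec$zone_targets[zones]
      tau <- spec$tau_s[zones]
      t(vapply(times, function(t) tgt + (19 - tgt) * exp(-t / tau),
               numeric(nx_field)))
    },
    three_zone_steady = {
      b <- geometry$zone_boundaries * L
      w <- blend_mm * 1e-3
      lvl <- spec$zone_targets
      s1 <- stats::plogis((x - b[1]) / (w / 4))
      s2 <- stats::plogis((x - b[2]) / (w / 4))
      matrix(lvl[1] + (lvl[2] - lvl[1]) * s1 + (lvl[3] - lvl[2]) * s2,
             1, nx_field)
    })
  structure(list(x = x, times = times, O2 = O2, spec = spec,
                 geometry = geometry, zones = zones),
            class = "oxz_phantom")
}

#' Zone plateau means of a phantom at its final frame
#' @param phantom an [make_oxygen_phantom()] result.
#' @return named numeric, mean %O2 per zone at the last time point.
#' @export
phantom_zone_means <- function(phantom) {
  last <- phantom$O2[nrow(phantom$O2), ]
  tapply(last, phantom$zones, mean)
}

#' Render a ratiometric sensor image stack from an oxygen field
#'
#' The inverse of the measurement model: within each sensor disk the green
#' (reference) channel is a constant gain and the red (oxygen-sensitive)
#' channel is `gain_green * R0 * sv_forward(O2)`; both receive per-pixel
#' multiplicative Gaussian noise, pixels outside the disks get the
#' background level, and everything is quantised to the camera bit depth.
#' The blue channel is unused (zero).
#'
#' @param phantom an [make_oxygen_phantom()] result.
#' @param spec the [phantom_spec()] (defaults to the phantom's own).
#' @param geometry a [device_geometry()].
#' @param roi_table optional ROI table (`roi_id`, `x_px`, `y_px`,
#'   `radius_px`, `zone`); derived from the geometry's sensor layout by
#'   default.
#' @return RGB stack: list with `frames` (H x W x 3 integer arrays),
#'   `timestamps`, `roi_table`, `bit_depth`, and ground `truth`.
#' @export
render_sensor_stack <- function(phantom, spec = phantom$spec,
                                geometry = phantom$geometry,
                                roi_table = NULL) {
  px <- spec$px_size_m
  W <- max(20L, round(geometry$chamber_length / px))
  H <- max(10L, round(geometry$chamber_width / px))
  if (is.null(roi_table)) {
    rc <- geometry$roi_centers
    roi_table <- data.frame(roi_id = seq_len(nrow(rc)),
                            x_px = rc$x / px + 0.5,
                            y_px = rc$y / px + 0.5,
                            radius_px = geometry$roi_diameter / 2 / px,
                            zone = zone_of(rc$x, geometry = geometry))
  }
  ok <- roi_table$x_px - roi_table$radius_px >= 0.5 &
    roi_table$x_px + roi_table$radius_px <= W + 0.5 &
    roi_table$y_px - roi_table$radius_px >= 0.5 &
    roi_table$y_px + roi_table$radius_px <= H + 0.5
  if (!all(ok)) stop("rendering error: ROI disks outside image bounds")

  dmax <- 2^spec$bit_depth - 1
  cal <- spec$calib
  disk <- matrix(FALSE, H, W)
  roi_of_px <- matrix(0L, H, W)
  for (k in seq_len(nrow(roi_table))) {
    m <- roi_disk_mask(c(H, W), roi_table$x_px[k], roi_table$y_px[k],
                       roi_table$radius_px[k])
    disk <- disk | m
    roi_of_px[m] <- k
  }
  xcol <- (seq_len(W) - 0.5) * px   # physical x of each pixel column

  frames <- withr::with_seed(spec$seed, {
    lapply(seq_along(phantom$times), function(fi) {
      O2col <- stats::approx(phantom$x, phantom$O2[fi, ], xout = xcol,
                             rule = 2)$y
      O2px <- matrix(O2col, H, W, byrow = TRUE)
      green <- matrix(spec$background, H, W)
      red <- matrix(spec$background, H, W)
      green[disk] <- spec$gain_green
      red[disk] <- spec$gain_green * cal$R0 * sv_forward(O2px[disk], cal)
      if (max(red, green) > dmax) {
        stop("rendering error: gains drive pixel values out of the dtype range")
      }
      if (spec$noise_sigma["red"] > 0) {
        red <- red * (1 + stats::rnorm(length(red), 0, spec$noise_sigma["red"]))
      }
      if (spec$noise_sigma["green"] > 0) {
        green <- green * (1 + stats::rnorm(length(green), 0,
                                           spec$noise_sigma["green"]))
      }
      fr <- array(0, dim = c(H, W, 3))
      fr[, , 1] <- pmin(pmax(round(red), 0), dmax)
      fr[, , 2] <- pmin(pmax(round(green), 0), dmax)
      fr
    })
  })
  truth <- list(calib = cal[c("f1", "f2", "Ksv", "R0")],
                scenario = spec$scenario,
                zone_targets = spec$zone_targets,
                roi_O2 = lapply(seq_along(phantom$times), function(fi) {
                  stats::approx(phantom$x, phantom$O2[fi, ],
                                xout = roi_table$x_px * px - 0.5 * px,
                                rule = 2)$y
                }))
  list(frames = frames, timestamps = phantom$times, roi_table = roi_table,
       bit_depth = spec$bit_depth, truth = truth)
}

#' Render a zone-graded staining image set
#'
#' Synthetic imaging sites for the quantification pipeline: nuclei as
#' non-overlapping disks in the blue channel; in `role = "viability"` mode
#' the green channel marks live cells and the red channel dead cells (a
#' seeded Bernoulli split at the requested viability); in `role = "albumin"`
#' mode the red channel carries per-cell albumin intensity equal to the
#' zone gain times a lognormal per-cell factor, emulating the periportal >
#' pericentral albumin gradient.
#'
#' @param zone_gains albumin gain per zone (zone 1 first).
#' @param n_sites imaging sites per zone.
#' @param cells_per_site nuclei per site.
#' @param viability_true true live fraction (0-1) for viability mode.
#' @param role `"albumin"` or `"viability"`.
#' @param img_size image height/width (px).
#' @param nucleus_radius_px nucleus disk radius.
#' @param seed integer seed (mandatory).
#' @param max_tries placement retries per nucleus before a placement error.
#' @return list of sites, each a list with `red`, `green`, `blue` matrices
#'   (8-bit scale), `zone`, `site_id`, `role`; ground truth in
#'   `attr(, "truth")`.
#' @export
render_staining_set <- function(zone_gains = c(3, 2, 1), n_sites = 12,
                                cells_per_site = 60, viability_true = 0.95,
                                role = c("albumin", "viability"),
                                img_size = c(128, 128),
                                nucleus_radius_px = 4, seed = 1L,
                                max_tries = 200) {
  role <- match.arg(role)
  if (n_sites < 1) stop("configuration error: n_sites must be >= 1")
  H <- img_size[1]; W <- img_size[2]; r <- nucleus_radius_px
  draw_disks <- function(canvas, cx, cy, rad, val) {
    for (i in seq_along(cx)) {
      m <- roi_disk_mask(c(H, W), cx[i], cy[i], rad)
      canvas[m] <- canvas[m] + val[i]
    }
    canvas
  }
  sites <- withr::with_seed(as.integer(seed), {
    out <- list()
    truth_rows <- list()
    sid <- 0L
    for (zone in 1:3) {
      for (s in seq_len(n_sites)) {
        sid <- sid + 1L
        cx <- numeric(0); cy <- numeric(0)
        for (cell in seq_len(cells_per_site)) {
          placed <- FALSE
          # separation 2r + 2 px keeps rendered disks from touching even
          # diagonally (pixel gap > sqrt(2)), so component counting
          # recovers the exact cell number
          sep2 <- (2 * r + 2)^2
          for (try in seq_len(max_tries)) {
            px <- stats::runif(1, r + 1, W - r)
            py <- stats::runif(1, r + 1, H - r)
            if (!length(cx) || all((cx - px)^2 + (cy - py)^2 >= sep2)) {
              cx <- c(cx, px); cy <- c(cy, py); placed <- TRUE; break
            }
          }
          if (!placed) {
            stop("placement error: cell density too high for non-overlapping nuclei")
          }
        }
        n <- length(cx)
        blue <- draw_disks(matrix(0, H, W), cx, cy, r, rep(180, n))
        red <- matrix(0, H, W); green <- matrix(0, H, W)
        live <- rep(TRUE, n)
        alb <- NA_real_
        if (role == "viability") {
          live <- stats::runif(n) < viability_true
          green <- draw_disks(green, cx[live], cy[live], r,
                              rep(200, sum(live)))
          if (any(!live)) {
            red <- draw_disks(red, cx[!live], cy[!live], r,
                              rep(200, sum(!live)))
          }
        } else {
          percell <- zone_gains[zone] * stats::rlnorm(n, 0, 0.3) * 25
          red <- draw_disks(red, cx, cy, r, percell)
          alb <- mean(percell)
        }
        blue <- pmin(blue, 255); red <- pmin(red, 255); green <- pmin(green, 255)
        out[[sid]] <- list(red = red, green = green, blue = blue,
                           zone = zone, site_id = sid, role = role)
        truth_rows[[sid]] <- data.frame(site_id = sid, zone = zone,
                                        n_cells = n, n_live = sum(live),
                                        zone_gain = zone_gains[zone],
                                        mean_albumin = alb)
      }
    }
    attr(out, "truth") <- do.call(rbind, truth_rows)
    out
  })
  sites
}
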