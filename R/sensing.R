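# Two-site Stern-Volmer ratiometric oxygen sensing:
#   R/R0 = f1 / (1 + Ksv [O2]) + f2,   f2 = 1 - f1,
# with R the red(oxygen-sensitive)/green(reference) ratio and R0 its value
# at zero oxygen.

#' Stern-Volmer calibration object
#'
#' @param f1 quenchable dye fraction (0 < f1 <= 1); `f2 = 1 - f1` is implied.
#' @param Ksv quenching constant (per %O2 by convention here; the unit is
#'   recorded in `Ksv_unit`).
#' @param R0 red/green ratio at zero oxygen.
#' @param scope `"global"` or `"roi"`; `roi_id` when scope is per-ROI.
#' @param Ksv_unit unit label for `Ksv`.
#' @param diagnostics optional list (residual norm, n points, mode).
#' @return object of class `sv_calibration`.
#' @export
sv_calibration <- function(f1 = 0.8, Ksv = 0.05, R0 = 1,
                           scope = "global", roi_id = NA,
                           Ksv_unit = "per_percent_O2", diagnostics = NULL) {
  if (!is.finite(f1) || f1 <= 0 || f1 > 1) stop("calibration error: need 0 < f1 <= 1")
  if (!is.finite(Ksv) || Ksv <= 0) stop("calibration error: Ksv must be positive")
  if (!is.finite(R0) || R0 <= 0) stop("calibration error: R0 must be positive")
  structure(list(f1 = f1, f2 = 1 - f1, Ksv = Ksv, R0 = R0, scope = scope,
                 roi_id = roi_id, Ksv_unit = Ksv_unit,
                 diagnostics = diagnostics),
            class = "sv_calibration")
}

#' Two-site Stern-Volmer forward model
#'
#' @param O2 oxygen level(s), % (>= 0).
#' @param calib an [sv_calibration()].
#' @return R/R0, strictly decreasing in O2, 1 at O2 = 0, -> f2 as O2 -> Inf.
#' @export
sv_forward <- function(O2, calib) {
  if (any(O2 < 0)) stop("domain error: negative oxygen")
  calib$f1 / (1 + calib$Ksv * O2) + calib$f2
}

#' Invert the two-site Stern-Volmer model
#'
#' Closed-form inverse `O2 = (f1 / (R/R0 - f2) - 1) / Ksv` on the physical
#' band `f2 < R/R0 <= 1`. Values above 1 are clamped to 0% O2 and flagged;
#' values at or below `f2` have no physical preimage (possible bleaching)
#' and come back `NA` with flag `"out_of_range"`.
#'
#' @param R_over_R0 normalised ratio(s).
#' @param calib an [sv_calibration()].
#' @return data.frame with columns `O2_percent` and `qc_flag`
#'   (`"ok"`, `"clamped"`, `"out_of_range"`).
#' @export
sv_invert <- function(R_over_R0, calib) {
  O2 <- rep(NA_real_, length(R_over_R0))
  flag <- rep("ok", length(R_over_R0))
  hi <- !is.na(R_over_R0) & R_over_R0 > 1
  O2[hi] <- 0; flag[hi] <- "clamped"
  bad <- !is.na(R_over_R0) & R_over_R0 <= calib$f2
  flag[bad] <- "out_of_range"
  ok <- !is.na(R_over_R0) & !hi & !bad
  O2[ok] <- (calib$f1 / (R_over_R0[ok] - calib$f2) - 1) / calib$Ksv
  flag[is.na(R_over_R0)] <- "no_signal"
  data.frame(O2_percent = O2, qc_flag = flag)
}

#' Fit a Stern-Volmer calibration
#'
#' Two-point mode (the bench protocol: 19% and 0% frames around each
#' measurement) cannot identify `f1` and `Ksv` jointly, so it fixes
#' `f1 = f1_fixed` and solves `Ksv` exactly from the highest-oxygen point.
#' Multi-point mode least-squares fits both parameters (with `f2 = 1 - f1`
#' constrained) and needs at least 3 distinct oxygen levels.
#'
#' @param points data.frame with columns `O2` (%) and `R` (ratio); several
#'   replicate rows per level are averaged. Must include O2 = 0 (defines R0).
#' @param mode `"two_point"` or `"multi_point"`.
#' @param f1_fixed fixed quenchable fraction for two-point mode.
#' @return an [sv_calibration()] with fit diagnostics.
#' @export
calibrate <- function(points, mode = c("two_point", "multi_point"),
                      f1_fixed = 0.8) {
  mode <- match.arg(mode)
  stopifnot(all(c("O2", "R") %in% names(points)))
  if (!any(points$O2 == 0)) {
    stop("calibration error: a zero-oxygen point is required to define R0")
  }
  lv <- stats::aggregate(R ~ O2, data = points, FUN = mean)
  R0 <- lv$R[lv$O2 == 0]
  if (mode == "two_point") {
    if (is.null(f1_fixed)) {
      stop("identifiability error: two_point mode requires f1_fixed (or use multi_point with >= 3 levels)")
    }
    top <- lv[which.max(lv$O2), ]
    if (top$O2 <= 0) stop("calibration error: need a nonzero oxygen point")
    rr <- top$R / R0
    if (rr <= 1 - f1_fixed || rr >= 1) {
      stop("calibration error: ratio at the high-oxygen point outside the physical band")
    }
    Ksv <- (f1_fixed / (rr - (1 - f1_fixed)) - 1) / top$O2
    return(sv_calibration(f1 = f1_fixed, Ksv = Ksv, R0 = R0,
                          diagnostics = list(mode = "two_point",
                                             n = nrow(points),
                                             residual_norm = 0)))
  }
  if (length(unique(lv$O2)) < 3) {
    stop("identifiability error: multi_point mode needs >= 3 distinct O2 levels")
  }
  dat <- data.frame(O2 = points$O2, rr = points$R / R0)
  fit <- minpack.lm::nlsLM(rr ~ f1 / (1 + Ksv * O2) + (1 - f1),
                           data = dat,
                           start = list(f1 = 0.8, Ksv = 0.05),
                           lower = c(f1 = 1e-6, Ksv = 1e-9),
                           upper = c(f1 = 1, Ksv = Inf))
  cf <- stats::coef(fit)
  sv_calibration(f1 = unname(cf["f1"]), Ksv = unname(cf["Ksv"]), R0 = R0,
                 diagnostics = list(mode = "multi_point", n = nrow(points),
                                    residual_norm = sqrt(sum(stats::resid(fit)^2))))
}

# -- ROI ratio extraction -----------------------------------------------------

roi_disk_mask <- function(dim_hw, cx, cy, radius) {
  # pixel centres at integer coordinates; membership inclusive
  rows <- matrix(seq_len(dim_hw[1]), dim_hw[1], dim_hw[2])
  cols <- matrix(seq_len(dim_hw[2]), dim_hw[1], dim_hw[2], byrow = TRUE)
  (cols - cx)^2 + (rows - cy)^2 <= radius^2
}

#' Per-ROI red/green ratios from an RGB stack
#'
#' For every frame and sensor ROI, computes `R = mean(red) / mean(green)`
#' over the ROI disk (pixel centre within radius, inclusive) - the means are
#' taken per channel before the ratio. Frames where the green mean is zero
#' are flagged, not fatal.
#'
#' @param stack an RGB stack as produced by [render_sensor_stack()] or
#'   [read_stack()]: list with `frames` (list of H x W x 3 arrays),
#'   `timestamps` (s), and `roi_table` (`roi_id`, `x_px`, `y_px`,
#'   `radius_px`, `zone`).
#' @return data.frame `time_s`, `roi_id`, `zone`, `R`, `qc_flag`.
#' @export
extract_ratios <- function(stack) {
  rt <- stack$roi_table
  if (is.null(rt) || nrow(rt) == 0) stop("precondition error: empty ROI table")
  d <- dim(stack$frames[[1]])[1:2]
  masks <- lapply(seq_len(nrow(rt)), function(k) {
    roi_disk_mask(d, rt$x_px[k], rt$y_px[k], rt$radius_px[k])
  })
  out <- do.call(rbind, lapply(seq_along(stack$frames), function(fi) {
    fr <- stack$frames[[fi]]
    red <- fr[, , 1]; green <- fr[, , 2]
    R <- numeric(nrow(rt)); flag <- rep("ok", nrow(rt))
    for (k in seq_len(nrow(rt))) {
      g <- mean(green[masks[[k]]])
      if (!is.finite(g) || g <= 0) {
        R[k] <- NA_real_; flag[k] <- "zero_reference"
      } else {
        R[k] <- mean(red[masks[[k]]]) / g
      }
    }
    data.frame(time_s = stack$timestamps[fi], roi_id = rt$roi_id,
               zone = rt$zone, R = R, qc_flag = flag)
  }))
  rownames(out) <- NULL
  out
}

#' Convert ROI ratios to oxygen
#'
#' Applies [sv_invert()] per entry using the ROI's own calibration, falling
#' back to a global calibration (with a warning) for ROIs without one.
#' QC flags from the ratio stage are propagated; inversion flags override
#' `"ok"`.
#'
#' @param ratios data.frame from [extract_ratios()].
#' @param calibs either a single [sv_calibration()] (global) or a named list
#'   keyed by `roi_id`.
#' @return the input with an `O2_percent` column and updated `qc_flag`.
#' @export
ratios_to_oxygen <- function(ratios, calibs) {
  global <- if (inherits(calibs, "sv_calibration")) calibs else calibs[["global"]]
  get_cal <- function(id) {
    if (inherits(calibs, "sv_calibration")) return(calibs)
    cal <- calibs[[as.character(id)]]
    if (is.null(cal)) {
      if (is.null(global)) stop("calibration error: no calibration for ROI ", id)
      warning("no per-ROI calibration for ROI ", id, "; using global")
      cal <- global
    }
    cal
  }
  ratios$O2_percent <- NA_real_
  for (id in unique(ratios$roi_id)) {
    cal <- get_cal(id)
    sel <- ratios$roi_id == id
    inv <- sv_invert(ratios$R[sel] / cal$R0, cal)
    ratios$O2_percent[sel] <- inv$O2_percent
    keep <- ratios$qc_flag[sel] == "ok"
    ratios$qc_flag[sel][keep] <- inv$qc_flag[keep]
  }
  ratios
}

#' Flag bleached sensor ROIs
#'
#' A sensor flake losing reference dye reads supra-physical oxygen; ROIs
#' whose O2 exceeds `max_physical_O2 + margin` for at least
#' `min_consecutive` consecutive frames are excluded wholesale (flag
#' `"bleached"`). Single-frame spikes are kept.
#'
#' @param series data.frame with `roi_id`, `time_s`, `O2_percent`, `qc_flag`.
#' @param max_physical_O2 physical ceiling (%), default 19.
#' @param margin tolerance above the ceiling (% O2), default 2.
#' @param min_consecutive persistence requirement, default 3 frames.
#' @return the input with `qc_flag = "bleached"` on excluded ROIs.
#' @export
flag_bleached <- function(series, max_physical_O2 = 19, margin = 2,
                          min_consecutive = 3) {
  lim <- max_physical_O2 + margin
  for (id in unique(series$roi_id)) {
    sel <- which(series$roi_id == id)
    d <- series[sel, ]
    d <- d[order(d$time_s), ]
    over <- !is.na(d$O2_percent) & d$O2_percent > lim
    r <- rle(over)
    if (any(r$values & r$lengths >= min_consecutive)) {
      series$qc_flag[sel] <- "bleached"
    }
  }
  series
}

#' Sensor response time to a step
#'
#' Time from step initiation until the signal completes `fraction` (default
#' 90%) of its plateau-to-plateau excursion, with linear interpolation
#' between frames. Plateaus are the means of the first and last
#' `plateau_frames` samples. Returns `NA` when the excursion is below
#' `noise_floor` (no step detected).
#'
#' @param time_s sample times (s); `O2` the single-ROI oxygen series (%).
#' @param fraction completed fraction defining the response, default 0.9
#'   (t90).
#' @param t0 step initiation time (s), default the first sample time.
#' @param plateau_frames samples averaged for each plateau.
#' @param noise_floor minimum excursion (% O2) to accept a step.
#' @return response time in minutes, or `NA_real_`.
#' @export
response_time <- function(time_s, O2, fraction = 0.9, t0 = min(time_s),
                          plateau_frames = 3, noise_floor = 0.5) {
  ord <- order(time_s)
  time_s <- time_s[ord]; O2 <- O2[ord]
  k <- min(plateau_frames, length(O2))
  p0 <- mean(utils::head(O2, k))
  p1 <- mean(utils::tail(O2, k))
  if (abs(p1 - p0) < noise_floor) return(NA_real_)
  target <- p0 + fraction * (p1 - p0)
  crossed <- if (p1 < p0) O2 <= target else O2 >= target
  idx <- which(crossed & time_s >= t0)
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  if (i == 1) return((time_s[1] - t0) / 60)
  # linear interpolation within the crossing frame interval
  tcross <- time_s[i - 1] + (target - O2[i - 1]) / (O2[i] - O2[i - 1]) *
    (time_s[i] - time_s[i - 1])
  (tcross - t0) / 60
}
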