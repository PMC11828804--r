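#' Device geometry for the two-layer zonation chip
#'
#' Describes the reduced 2-D (x--z) cross-section of the device: a lower PDMS
#' gas layer carrying two serpentine gas channels, a cell-culture chamber in
#' the upper PDMS layer, and the positions of the circular oxygen-sensor
#' sections (ROIs) on the chamber floor. `x = 0` is the medium inlet at the
#' high-oxygen end, `z = 0` the glass slide.
#'
#' The chamber footprint is not part of the device's published dimensions;
#' the defaults used here are reconstructions: `chamber_height` equals the
#' 1 mm PMMA mould sheet; `chamber_width` satisfies the parallel-plate
#' shear constraint tau = 6 mu Q / (w h^2) = 3.4e-6 Pa at 0.5 uL/min; and
#' `chamber_length` makes the chamber volume seeded at 400k cells/mL hold
#' the cell count implied by the reported 1.3 mM outlet glucose drop at
#' 0.5 uL/min (N = dC Q / r, about 2.7e5 cells). All three are plain
#' arguments and can be overridden from a config file.
#'
#' @param chamber_length,chamber_width,chamber_height chamber dimensions (m).
#' @param gas_layer_thickness thickness of the lower gas-network layer (m).
#' @param cell_layer_thickness thickness of the upper layer containing the
#'   chamber (m); total device height is the sum of the two layers.
#' @param gas_channel_width,gas_channel_height gas channel cross-section (m).
#' @param zone_boundaries two strictly increasing fractions in (0, 1)
#'   splitting the chamber length into zones 1 (high O2), 2, 3 (low O2).
#' @param roi_centers data.frame with columns `x`, `y` (m) giving sensor
#'   section centres; default places ten sensors spread over the three zones.
#' @param roi_diameter sensor section diameter (m), 1.5 mm punch.
#' @return object of class `oxz_geometry`.
#' @export
device_geometry <- function(chamber_length = 49.4e-3,
                            chamber_width = 13.7e-3,
                            chamber_height = 1.0e-3,
                            gas_layer_thickness = 2e-3,
                            cell_layer_thickness = 3e-3,
                            gas_channel_width = 0.2e-3,
                            gas_channel_height = 0.1e-3,
                            zone_boundaries = c(1, 2) / 3,
                            roi_centers = NULL,
                            roi_diameter = 1.5e-3) {
  dims <- c(chamber_length = chamber_length, chamber_width = chamber_width,
            chamber_height = chamber_height,
            gas_layer_thickness = gas_layer_thickness,
            cell_layer_thickness = cell_layer_thickness,
            gas_channel_width = gas_channel_width,
            gas_channel_height = gas_channel_height,
            roi_diameter = roi_diameter)
  if (any(!is.finite(dims)) || any(dims <= 0)) {
    stop("configuration error: all device dimensions must be positive, got ",
         paste(names(dims)[dims <= 0 | !is.finite(dims)], collapse = ", "))
  }
  if (chamber_height >= cell_layer_thickness) {
    stop("configuration error: chamber_height must be smaller than cell_layer_thickness")
  }
  if (gas_channel_height >= gas_layer_thickness) {
    stop("configuration error: gas_channel_height must be smaller than gas_layer_thickness")
  }
  if (length(zone_boundaries) != 2 || any(diff(zone_boundaries) <= 0) ||
      any(zone_boundaries <= 0) || any(zone_boundaries >= 1)) {
    stop("configuration error: zone_boundaries must be 2 strictly increasing fractions in (0,1)")
  }
  if (is.null(roi_centers)) {
    fx <- c(0.06, 0.15, 0.24, 0.40, 0.49, 0.58, 0.70, 0.79, 0.88, 0.96)
    roi_centers <- data.frame(x = fx * chamber_length, y = chamber_width / 2)
  }
  roi_centers <- as.data.frame(roi_centers)
  stopifnot(all(c("x", "y") %in% names(roi_centers)))
  inside <- roi_centers$x >= 0 & roi_centers$x <= chamber_length &
    roi_centers$y >= 0 & roi_centers$y <= chamber_width
  if (!all(inside)) {
    stop("configuration error: ROI centres must lie inside the chamber footprint")
  }
  structure(list(chamber_length = chamber_length,
                 chamber_width = chamber_width,
                 chamber_height = chamber_height,
                 gas_layer_thickness = gas_layer_thickness,
                 cell_layer_thickness = cell_layer_thickness,
                 gas_channel_width = gas_channel_width,
                 gas_channel_height = gas_channel_height,
                 zone_boundaries = as.numeric(zone_boundaries),
                 roi_centers = roi_centers,
                 roi_diameter = roi_diameter),
            class = "oxz_geometry")
}

#' Physical transport parameters
#'
#' All constants of the transport model, defaulting to the published values:
#' diffusivities of glucose and oxygen in medium and of oxygen in PDMS, the
#' PDMS:medium partition coefficient, the PDMS saturation concentration at
#' the 19% reference gas level, Michaelis-Menten constant and per-cell
#' oxygen consumption rate, the necrosis cutoff, the per-cell glucose uptake
#' rate, and the medium's density and viscosity.
#'
#' `N_total` (total seeded cells) and `A_culture` (culture area) default to
#' the seeding density times the chamber volume of `geometry` and the
#' chamber footprint area.
#'
#' @param geometry an [device_geometry()] used for the derived defaults.
#' @param seeding_density_per_mL cell seeding density (cells/mL), default 4e5.
#' @param D_glucose_medium,D_O2_medium,D_O2_pdms diffusivities (m^2/s).
#' @param partition_K PDMS:medium oxygen partition coefficient (>= 1).
#' @param C_sat_pdms oxygen saturation in PDMS at the reference level (mol/m^3).
#' @param Km Michaelis-Menten constant (mol/m^3).
#' @param q_cell per-cell oxygen consumption rate (mol/s).
#' @param N_total total cell count; `A_culture` culture area (m^2).
#' @param C_necrosis necrosis oxygen cutoff (mol/m^3), must be < `Km`.
#' @param glucose_uptake glucose uptake (mol/min per 1e6 cells).
#' @param mu dynamic viscosity (Pa s); `rho` density (kg/m^3).
#' @param C_glucose_in inlet glucose concentration (mol/m^3).
#' @param reference_O2_percent gas level (%) at which `C_sat_pdms` applies.
#' @return object of class `oxz_params`.
#' @export
transport_params <- function(geometry = device_geometry(),
                             seeding_density_per_mL = 4e5,
                             D_glucose_medium = 6.16e-10,
                             D_O2_medium = 2.69e-9,
                             D_O2_pdms = 3.25e-9,
                             partition_K = 10,
                             C_sat_pdms = 1.8,
                             Km = 6.3e-3,
                             q_cell = 3.5e-16,
                             N_total = NULL,
                             A_culture = NULL,
                             C_necrosis = 1.0e-4,
                             glucose_uptake = 2.4e-9,
                             mu = 0.93e-3,
                             rho = 1009,
                             C_glucose_in = 5.5,
                             reference_O2_percent = 19) {
  if (is.null(A_culture)) {
    A_culture <- geometry$chamber_length * geometry$chamber_width
  }
  if (is.null(N_total)) {
    vol_mL <- geometry$chamber_length * geometry$chamber_width *
      geometry$chamber_height * 1e6   # m^3 -> mL
    N_total <- seeding_density_per_mL * vol_mL
  }
  p <- list(D_glucose_medium = D_glucose_medium, D_O2_medium = D_O2_medium,
            D_O2_pdms = D_O2_pdms, partition_K = partition_K,
            C_sat_pdms = C_sat_pdms, Km = Km, q_cell = q_cell,
            N_total = N_total, A_culture = A_culture,
            C_necrosis = C_necrosis, glucose_uptake = glucose_uptake,
            mu = mu, rho = rho, C_glucose_in = C_glucose_in,
            reference_O2_percent = reference_O2_percent)
  num <- unlist(p)
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("configuration error: all transport parameters must be strictly positive")
  }
  if (Km <= C_necrosis) stop("configuration error: Km must exceed C_necrosis")
  if (partition_K < 1) stop("configuration error: partition_K must be >= 1")
  structure(p, class = "oxz_params")
}

#' Zone of a footprint position
#'
#' Maps an (x, y) position on the chamber footprint to its oxygenation zone:
#' 1 at the high-oxygen inlet end, 3 at the nitrogen end. Points exactly on
#' a zone boundary belong to the lower-numbered zone.
#'
#' @param x,y position (m); `y` may be omitted (zones depend on x only).
#' @param geometry a [device_geometry()].
#' @return integer vector of zone ids in 1:3.
#' @export
zone_of <- function(x, y = NULL, geometry = device_geometry()) {
  L <- geometry$chamber_length
  if (any(x < 0 | x > L)) stop("domain error: x outside chamber footprint")
  if (!is.null(y) && any(y < 0 | y > geometry$chamber_width)) {
    stop("domain error: y outside chamber footprint")
  }
  frac <- x / L
  b <- geometry$zone_boundaries
  eps <- 1e-12   # boundary points (up to rounding) belong to the lower zone
  as.integer(1L + (frac > b[1] + eps) + (frac > b[2] + eps))
}

#' Multi-material finite-volume grid
#'
#' Discretises the 2-D vertical cross-section of the device on a uniform
#' rectilinear `nx` by `nz` grid spanning the full height (gas layer plus
#' upper layer). Cells are labelled `PDMS`, `MEDIUM` (the chamber, directly
#' above the gas layer) or `GAS` (the gas-channel band at the bottom, a
#' Dirichlet patch). Gas cells carry a source tag: `air` under zone 1, `n2`
#' under zone 3, and alternating stripes of the two at `stripe_pitch` under
#' zone 2 (the serpentine interleave); `zone2_mode = "mid"` instead tags
#' zone-2 gas cells `mid` for a single intermediate level.
#'
#' The gas-channel band is snapped to the grid: cells whose centre lies below
#' `gas_channel_height` (at least the bottom row). The PDMS membrane between
#' the gas band and the chamber floor must be resolved by at least 3 cells.
#'
#' @param geometry a [device_geometry()].
#' @param nx,nz number of cells along x and z (`nx >= 20`, `nz >= 10`).
#' @param zone2_mode `"stripes"` (default) or `"mid"`.
#' @param stripe_pitch full air+nitrogen period of the zone-2 interleave (m).
#' @return object of class `oxz_grid` with cell-centre coordinates `x`, `z`,
#'   spacings `dx`, `dz`, a material matrix `material` (`nz` rows from the
#'   glass up, `nx` columns from the inlet) and a `gas_source` matrix.
#' @export
build_grid <- function(geometry, nx = 100, nz = 50,
                       zone2_mode = c("stripes", "mid"),
                       stripe_pitch = 1.0e-3) {
  zone2_mode <- match.arg(zone2_mode)
  if (nx < 20 || nz < 10) stop("resolution error: need nx >= 20 and nz >= 10")
  H <- geometry$gas_layer_thickness + geometry$cell_layer_thickness
  L <- geometry$chamber_length
  dx <- L / nx
  dz <- H / nz
  x <- (seq_len(nx) - 0.5) * dx
  z <- (seq_len(nz) - 0.5) * dz

  gas_rows <- which(z < geometry$gas_channel_height)
  if (length(gas_rows) == 0) gas_rows <- 1L
  med_lo <- geometry$gas_layer_thickness
  med_hi <- med_lo + geometry$chamber_height
  med_rows <- which(z > med_lo & z < med_hi)
  membrane_rows <- which(z > max(z[gas_rows]) + dz / 2 - 1e-15 & z < med_lo)
  if (length(membrane_rows) < 3) {
    stop("resolution error: fewer than 3 cells across the PDMS membrane; increase nz")
  }
  if (length(med_rows) < 3) {
    stop("resolution error: fewer than 3 cells across the chamber; increase nz")
  }

  material <- matrix("PDMS", nz, nx)
  material[med_rows, ] <- "MEDIUM"
  material[gas_rows, ] <- "GAS"

  zones <- zone_of(x, geometry = geometry)
  gas_source <- matrix(NA_character_, nz, nx)
  src <- character(nx)
  src[zones == 1L] <- "air"
  src[zones == 3L] <- "n2"
  src[zones == 2L] <- if (zone2_mode == "mid") "mid" else "mix"
  gas_source[gas_rows, ] <- rep(src, each = length(gas_rows))

  # Air fraction of each gas cell: 1 under zone 1, 0 under zone 3; under
  # zone 2 the cell-averaged fraction of the air/nitrogen stripe square
  # wave (pitch = one air + one nitrogen stripe). Cell averaging renders
  # the sub-cell serpentine interleave consistently at any resolution.
  air_cum <- function(s) {
    # air measure of the square wave on [0, s] (air first, half the pitch)
    half <- stripe_pitch / 2
    floor(s / stripe_pitch) * half + pmin(s %% stripe_pitch, half)
  }
  frac <- numeric(nx)
  frac[zones == 1L] <- 1
  j2 <- which(zones == 2L)
  if (length(j2)) {
    if (zone2_mode == "mid") {
      frac[j2] <- 0.5
    } else {
      a <- x[j2] - dx / 2 - geometry$zone_boundaries[1] * L
      b <- a + dx
      frac[j2] <- (air_cum(b) - air_cum(a)) / dx
    }
  }
  gas_air_frac <- matrix(NA_real_, nz, nx)
  gas_air_frac[gas_rows, ] <- rep(frac, each = length(gas_rows))

  structure(list(nx = as.integer(nx), nz = as.integer(nz), dx = dx, dz = dz,
                 x = x, z = z, material = material, gas_source = gas_source,
                 gas_air_frac = gas_air_frac,
                 gas_rows = gas_rows, med_rows = med_rows,
                 membrane_rows = membrane_rows, zones_x = zones,
                 geometry = geometry, zone2_mode = zone2_mode,
                 stripe_pitch = stripe_pitch),
            class = "oxz_grid")
}

#' Enumerate PDMS/medium interface faces
#'
#' Returns one row per horizontal grid face separating a PDMS cell from a
#' MEDIUM cell, with the (row, column) indices of the two cells. These faces
#' carry the oxygen partition condition.
#'
#' @param grid an [build_grid()] result.
#' @return data.frame with columns `j` (x column), `i_pdms`, `i_medium`.
#' @export
interface_faces <- function(grid) {
  m <- grid$material
  out <- list()
  for (i in seq_len(grid$nz - 1)) {
    a <- m[i, ]; b <- m[i + 1, ]
    pm <- which(a == "PDMS" & b == "MEDIUM")
    mp <- which(a == "MEDIUM" & b == "PDMS")
    if (length(pm)) out[[length(out) + 1]] <-
        data.frame(j = pm, i_pdms = i, i_medium = i + 1)
    if (length(mp)) out[[length(out) + 1]] <-
        data.frame(j = mp, i_pdms = i + 1, i_medium = i)
  }
  do.call(rbind, out)
}

#' Uniform cell field on the culture surface
#'
#' Surface cell density per chamber-floor cell. Defaults to a uniform
#' distribution of `params$N_total` over the culture area.
#'
#' @param params a [transport_params()]; `grid` an [build_grid()].
#' @param grid finite-volume grid.
#' @param density optional vector of densities (cells/m^2), one per x column.
#' @return object of class `oxz_cells` with per-column `density` (cells/m^2).
#' @export
cell_field <- function(params, grid, density = NULL) {
  if (is.null(density)) {
    density <- rep(params$N_total / params$A_culture, grid$nx)
  }
  if (length(density) != grid$nx || any(density < 0)) {
    stop("configuration error: cell density must be non-negative, one value per column")
  }
  structure(list(density = density, alive = rep(TRUE, grid$nx)),
            class = "oxz_cells")
}

# psi is the partition-scaled oxygen variable: C_medium = psi, C_pdms = K*psi.
# Conversions between psi, medium concentration and gas-level percent.
psi_of_percent <- function(percent, params) {
  params$C_sat_pdms / params$partition_K *
    percent / params$reference_O2_percent
}

percent_of_psi <- function(psi, params) {
  psi * params$partition_K / params$C_sat_pdms * params$reference_O2_percent
}

#' @export
print.oxz_geometry <- function(x, ...) {
  cat("Zonation-chip geometry (mm):\n")
  cat(sprintf("  chamber  %.2f x %.2f x %.2f (L x W x H)\n",
              x$chamber_length * 1e3, x$chamber_width * 1e3,
              x$chamber_height * 1e3))
  cat(sprintf("  layers   gas %.2f, upper %.2f; gas channel %.2f x %.2f\n",
              x$gas_layer_thickness * 1e3, x$cell_layer_thickness * 1e3,
              x$gas_channel_width * 1e3, x$gas_channel_height * 1e3))
  cat(sprintf("  zones at x/L = %.3f, %.3f; %d ROIs of %.2f mm\n",
              x$zone_boundaries[1], x$zone_boundaries[2],
              nrow(x$roi_centers), x$roi_diameter * 1e3))
  invisible(x)
}

#' @export
print.oxz_grid <- function(x, ...) {
  cat(sprintf("FV grid %d x %d (dx %.3g mm, dz %.3g mm); materials: %s\n",
              x$nx, x$nz, x$dx * 1e3, x$dz * 1e3,
              paste(names(table(x$material)), collapse = ", ")))
  invisible(x)
}
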