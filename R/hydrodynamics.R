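#' Chamber flow specification
#'
#' @param flow_rate_uL_min volumetric flow rate in uL/min (the bench unit);
#'   alternatively give `Q_m3_s` directly in SI.
#' @param Q_m3_s flow rate in m^3/s; overrides `flow_rate_uL_min`.
#' @param body_force body force density (N/m^3), default 0.
#' @param outlet_pressure_Pa outlet pressure, default atmospheric.
#' @return object of class `oxz_flow`.
#' @export
flow_spec <- function(flow_rate_uL_min = 0.5, Q_m3_s = NULL,
                      body_force = 0, outlet_pressure_Pa = 101325) {
  if (is.null(Q_m3_s)) Q_m3_s <- flow_rate_uL_min * 1e-9 / 60
  if (!is.finite(Q_m3_s) || Q_m3_s < 0) {
    stop("configuration error: flow rate must be >= 0")
  }
  structure(list(Q = Q_m3_s, flow_rate_uL_min = Q_m3_s * 60 / 1e-9,
                 body_force = body_force,
                 outlet_pressure = outlet_pressure_Pa),
            class = "oxz_flow")
}

#' Plane-Poiseuille velocity profile in the chamber
#'
#' At the chamber's Reynolds numbers (<< 1) the steady laminar flow between
#' the chamber floor and ceiling is the fully developed plane-Poiseuille
#' profile u(z') = 6Q/(w h^3) z'(h - z') with no-slip walls, x-invariant.
#' The profile is sampled at medium cell centres and rescaled so that the
#' discrete depth-integrated flux equals Q exactly (midpoint sampling of the
#' parabola would otherwise be biased by O(dz^2)); this keeps downstream
#' advective mass balances exact.
#'
#' @param flow a [flow_spec()].
#' @param geometry a [device_geometry()].
#' @param grid an [build_grid()].
#' @return object of class `oxz_velocity`: matrix `u` (m/s, nz x nx, zero
#'   outside MEDIUM cells) plus `u_profile` (per medium row).
#' @export
poiseuille_profile <- function(flow, geometry, grid) {
  h <- geometry$chamber_height
  w <- geometry$chamber_width
  if (h <= 0 || w <= 0) stop("configuration error: zero chamber width/height")
  zp <- grid$z[grid$med_rows] - geometry$gas_layer_thickness
  u <- 6 * flow$Q / (w * h^3) * zp * (h - zp)
  # renormalise discrete flux to Q exactly
  flux <- sum(u) * grid$dz * w
  if (flux > 0) u <- u * (flow$Q / flux)
  U <- matrix(0, grid$nz, grid$nx)
  U[grid$med_rows, ] <- u
  structure(list(u = U, u_profile = u, Q = flow$Q), class = "oxz_velocity")
}

#' Wall shear stress on the culture surface
#'
#' Closed-form parallel-plate wall shear tau = 6 mu Q / (w h^2) at the
#' chamber floor where the cells sit. Strictly linear in Q. Note that
#' published 3-D simulated shear values for this device family are not
#' mutually linear in Q, so comparisons against them carry a wide tolerance.
#'
#' @param flow a [flow_spec()].
#' @param geometry a [device_geometry()].
#' @param params a [transport_params()] (supplies the viscosity `mu`).
#' @return shear stress (Pa).
#' @export
wall_shear <- function(flow, geometry, params = transport_params(geometry)) {
  h <- geometry$chamber_height
  w <- geometry$chamber_width
  if (h <= 0 || w <= 0) stop("configuration error: zero chamber width/height")
  6 * params$mu * flow$Q / (w * h^2)
}

#' Shear table over a set of flow rates
#'
#' @param flow_rates_uL_min numeric vector of flow rates (uL/min).
#' @param geometry,params device geometry and parameters.
#' @return data.frame with columns `flow_rate_uL_min`, `shear_Pa`.
#' @export
shear_table <- function(flow_rates_uL_min, geometry = device_geometry(),
                        params = transport_params(geometry)) {
  data.frame(flow_rate_uL_min = flow_rates_uL_min,
             shear_Pa = vapply(flow_rates_uL_min, function(q) {
               wall_shear(flow_spec(q), geometry, params)
             }, numeric(1)))
}
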