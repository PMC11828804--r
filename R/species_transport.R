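# Finite-volume transport on the multi-material grid.
#
# Oxygen is solved in the partition-scaled variable psi with C_medium = psi
# and C_pdms = K * psi: psi is continuous across the PDMS/medium interface,
# and the interface condition (flux continuity with concentration jump K)
# is exact by construction when the flux law uses the effective diffusivity
# D * S (S = K in PDMS, 1 in medium) with harmonic-mean face averaging.

# -- assembly helpers ---------------------------------------------------------

# Accumulates triplets for the diffusion operator A psi = b over active cells.
# Deff: effective diffusivity per cell; fixed: psi values of Dirichlet cells
# (gas channel band); bc: per-side list(type = "D"/"N", value =) with vectors
# along the side (left/right: length nz; bottom/top: length nx).
fv_diffusion <- function(grid, Deff, active, fixed, bc) {
  nz <- grid$nz; nx <- grid$nx
  dx <- grid$dx; dz <- grid$dz
  umap <- matrix(NA_integer_, nz, nx)
  umap[active] <- seq_len(sum(active))
  n <- sum(active)
  ti <- integer(0); tj <- integer(0); tv <- numeric(0)
  b <- numeric(n)
  diag_acc <- numeric(n)

  add_pairs <- function(ci, cj, ni, nj, area, dist) {
    ca <- active[cbind(ci, cj)]; na <- active[cbind(ni, nj)]
    cf <- !is.na(fixed[cbind(ci, cj)]); nf <- !is.na(fixed[cbind(ni, nj)])
    Dc <- Deff[cbind(ci, cj)]; Dn <- Deff[cbind(ni, nj)]
    # active-active: harmonic mean conductance
    k <- ca & na
    if (any(k)) {
      G <- 2 / (1 / Dc[k] + 1 / Dn[k]) * area / dist
      uc <- umap[cbind(ci[k], cj[k])]; un <- umap[cbind(ni[k], nj[k])]
      diag_acc[uc] <<- diag_acc[uc] + G
      diag_acc[un] <<- diag_acc[un] + G
      ti <<- c(ti, uc, un); tj <<- c(tj, un, uc); tv <<- c(tv, -G, -G)
    }
    # active-fixed: gas value applies at the shared face (well-mixed gas)
    k <- ca & nf
    if (any(k)) {
      G <- Dc[k] * area / (dist / 2)
      uc <- umap[cbind(ci[k], cj[k])]
      diag_acc[uc] <<- diag_acc[uc] + G
      b[uc] <<- b[uc] + G * fixed[cbind(ni[k], nj[k])]
    }
    k <- na & cf
    if (any(k)) {
      G <- Dn[k] * area / (dist / 2)
      un <- umap[cbind(ni[k], nj[k])]
      diag_acc[un] <<- diag_acc[un] + G
      b[un] <<- b[un] + G * fixed[cbind(ci[k], cj[k])]
    }
    # active-inactive (blocked): no flux -> nothing to add
  }

  if (nx > 1) {
    i <- rep(seq_len(nz), nx - 1)
    j <- rep(seq_len(nx - 1), each = nz)
    add_pairs(i, j, i, j + 1, area = dz, dist = dx)
  }
  if (nz > 1) {
    i <- rep(seq_len(nz - 1), nx)
    j <- rep(seq_len(nx), each = nz - 1)
    add_pairs(i, j, i + 1, j, area = dx, dist = dz)
  }

  add_side <- function(ci, cj, spec, area, dist) {
    k <- active[cbind(ci, cj)]
    if (!any(k)) return(invisible())
    uc <- umap[cbind(ci[k], cj[k])]
    Dc <- Deff[cbind(ci[k], cj[k])]
    type <- spec$type[k]; val <- spec$value[k]
    d <- type == "D"
    if (any(d)) {
      G <- Dc[d] * area / (dist / 2)
      diag_acc[uc[d]] <<- diag_acc[uc[d]] + G
      b[uc[d]] <<- b[uc[d]] + G * val[d]
    }
    nn <- type == "N"
    if (any(nn)) b[uc[nn]] <<- b[uc[nn]] + val[nn] * area  # inward flux
  }
  add_side(seq_len(nz), rep(1L, nz), bc$left, area = dz, dist = dx)
  add_side(seq_len(nz), rep(nx, nz), bc$right, area = dz, dist = dx)
  add_side(rep(1L, nx), seq_len(nx), bc$bottom, area = dx, dist = dz)
  add_side(rep(nz, nx), seq_len(nx), bc$top, area = dx, dist = dz)

  ti <- c(ti, seq_len(n)); tj <- c(tj, seq_len(n)); tv <- c(tv, diag_acc)
  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tv, dims = c(n, n))
  list(A = A, b = b, umap = umap, n = n)
}

# Upwind advection along +x with per-row velocity u (length nz); inlet
# Dirichlet C_in at j = 1, advective outflow at j = nx. Returns triplet
# additions and RHS for the active cells of `umap`.
fv_advection_x <- function(grid, u_rows, active, umap, C_in) {
  nz <- grid$nz; nx <- grid$nx; dz <- grid$dz
  ti <- integer(0); tj <- integer(0); tv <- numeric(0)
  b <- numeric(max(umap, na.rm = TRUE))
  for (i in which(u_rows > 0)) {
    uA <- u_rows[i] * dz
    cols <- which(active[i, ])
    for (j in cols) {
      uc <- umap[i, j]
      # east face: leaves cell j (into j+1 or out of the domain)
      ti <- c(ti, uc); tj <- c(tj, uc); tv <- c(tv, uA)
      if (j < nx && active[i, j + 1]) {
        un <- umap[i, j + 1]
        ti <- c(ti, un); tj <- c(tj, uc); tv <- c(tv, -uA)
      }
      if (j == 1) b[uc] <- b[uc] + uA * C_in  # advective inflow
    }
  }
  list(i = ti, j = tj, v = tv, b = b)
}

side_spec <- function(type, value) list(type = type, value = value)

# Oxygen BC sides: ambient Dirichlet on PDMS faces (device not sealed),
# no-flux on medium-layer side faces (advection handles inlet/outlet when on).
oxygen_bc_sides <- function(grid, params, ambient_percent) {
  amb <- psi_of_percent(ambient_percent, params)
  vert <- function() {
    type <- ifelse(grid$material[, 1] == "MEDIUM", "N", "D")
    side_spec(type, ifelse(type == "D", amb, 0))
  }
  list(left = vert(), right = vert(),
       bottom = side_spec(rep("N", grid$nx), rep(0, grid$nx)),  # glass
       top = side_spec(rep("D", grid$nx), rep(amb, grid$nx)))
}

gas_fixed_psi <- function(grid, params, gas_bc) {
  fixed <- matrix(NA_real_, grid$nz, grid$nx)
  g <- grid$material == "GAS"
  lev <- grid$gas_air_frac[g] * gas_bc$air +
    (1 - grid$gas_air_frac[g]) * gas_bc$n2
  if (!is.null(gas_bc$mid)) {
    lev[grid$gas_source[g] == "mid"] <- gas_bc$mid
  }
  fixed[g] <- psi_of_percent(lev, params)
  fixed
}

oxygen_Deff <- function(grid, params) {
  Deff <- matrix(params$D_O2_pdms * params$partition_K, grid$nz, grid$nx)
  Deff[grid$material == "MEDIUM"] <- params$D_O2_medium
  Deff[grid$material == "GAS"] <- params$D_O2_pdms * params$partition_K
  Deff
}

# -- reaction terms -----------------------------------------------------------

#' Michaelis-Menten oxygen consumption flux
#'
#' Areal oxygen uptake of the cell monolayer,
#' `(q N_t / A_t) C / (Km + C)`, gated by the necrosis cutoff: cells below
#' `C_necrosis` are dead and consume nothing (Heaviside step; an optional
#' smooth step of half-width `smooth_halfwidth` eases solver convergence).
#'
#' @param C_local local oxygen concentration(s) in the medium (mol/m^3).
#' @param params a [transport_params()].
#' @param density areal cell density (cells/m^2); defaults to
#'   `N_total / A_culture`.
#' @param smooth_halfwidth half-width of the smoothed necrosis step
#'   (mol/m^3); 0 (default) gives the hard Heaviside.
#' @return consumption flux (mol m^-2 s^-1), same length as `C_local`.
#' @export
ocr_flux <- function(C_local, params, density = NULL, smooth_halfwidth = 0) {
  if (any(C_local < 0)) stop("domain error: negative oxygen concentration")
  if (is.null(density)) density <- params$N_total / params$A_culture
  H <- if (smooth_halfwidth > 0) {
    pmin(pmax((C_local - params$C_necrosis + smooth_halfwidth) /
                (2 * smooth_halfwidth), 0), 1)
  } else {
    as.numeric(C_local >= params$C_necrosis)
  }
  params$q_cell * density * C_local / (params$Km + C_local) * H
}

# -- steady oxygen ------------------------------------------------------------

#' Steady oxygen field over the whole device
#'
#' Solves the steady diffusion(-advection) equation for oxygen across gas
#' channels, PDMS bulk and culture chamber: Dirichlet gas levels on the
#' channel band, ambient (reference-level) Dirichlet on PDMS faces exposed
#' to the atmosphere, partition condition `C_pdms = K C_medium` on the
#' PDMS/medium interfaces, and the Michaelis-Menten sink of [ocr_flux()] on
#' the chamber floor when `cells` are present. The nonlinear sink is
#' resolved by semi-implicit Picard iteration (the sink is linearised as
#' `k(C_prev) * C`, keeping the operator an M-matrix) to a relative
#' residual below `tol`.
#'
#' @param grid an [build_grid()].
#' @param params a [transport_params()].
#' @param cells optional [cell_field()]; `NULL` for the cell-free device.
#' @param gas_bc list with gas levels in percent O2 for the `air` and `n2`
#'   sources (and optionally `mid`), e.g. `list(air = 19, n2 = 0)`.
#' @param velocity optional [poiseuille_profile()] to include medium
#'   advection of oxygen (off by default, mirroring the gas-driven sensing
#'   runs where medium advection is second order).
#' @param ambient_percent oxygen level at atmosphere-exposed faces (%).
#' @param tol relative residual tolerance of the Picard iteration.
#' @param max_iter iteration cap; exceeding it is a solver error.
#' @param smooth_halfwidth necrosis step smoothing passed to [ocr_flux()].
#' @return object of class `oxz_field` with the full `psi` matrix
#'   (partition-scaled concentration, mol/m^3).
#' @export
steady_oxygen <- function(grid, params, cells = NULL,
                          gas_bc = list(air = 19, n2 = 0),
                          velocity = NULL,
                          ambient_percent = params$reference_O2_percent,
                          tol = 1e-10, max_iter = 200,
                          smooth_halfwidth = 0) {
  Deff <- oxygen_Deff(grid, params)
  fixed <- gas_fixed_psi(grid, params, gas_bc)
  active <- grid$material != "GAS"
  bc <- oxygen_bc_sides(grid, params, ambient_percent)
  if (!is.null(velocity)) {
    bc$left$type[grid$material[, 1] == "MEDIUM"] <- "D"
    bc$left$value[grid$material[, 1] == "MEDIUM"] <-
      psi_of_percent(ambient_percent, params)
  }
  sys <- fv_diffusion(grid, Deff, active, fixed, bc)
  A0 <- sys$A; b <- sys$b
  if (!is.null(velocity)) {
    adv <- fv_advection_x(grid, apply(velocity$u, 1, max), active, sys$umap,
                          C_in = psi_of_percent(ambient_percent, params))
    A0 <- A0 + Matrix::sparseMatrix(i = adv$i, j = adv$j, x = adv$v,
                                    dims = dim(A0))
    b <- b + adv$b
  }

  floor_row <- min(grid$med_rows)
  floor_ids <- sys$umap[floor_row, ]
  dens <- if (is.null(cells)) NULL else cells$density

  psi <- Matrix::solve(A0, b)  # cell-free / initial guess
  psi <- as.numeric(psi)
  iters <- 0L
  if (!is.null(cells)) {
    bscale <- max(abs(b))
    repeat {
      iters <- iters + 1L
      Cfloor <- pmax(psi[floor_ids], 0)
      H <- if (smooth_halfwidth > 0) {
        pmin(pmax((Cfloor - params$C_necrosis + smooth_halfwidth) /
                    (2 * smooth_halfwidth), 0), 1)
      } else as.numeric(Cfloor >= params$C_necrosis)
      kdiag <- params$q_cell * dens * H / (params$Km + Cfloor) * grid$dx
      K <- Matrix::sparseMatrix(i = floor_ids, j = floor_ids, x = kdiag,
                                dims = dim(A0))
      psi_new <- as.numeric(Matrix::solve(A0 + K, b))
      # true nonlinear residual at the new iterate
      Cn <- pmax(psi_new[floor_ids], 0)
      s <- ocr_flux(Cn, params, dens, smooth_halfwidth) * grid$dx
      res <- as.numeric(A0 %*% psi_new) - b
      res[floor_ids] <- res[floor_ids] + s
      rel <- max(abs(res)) / bscale
      conv <- rel < tol
      psi <- psi_new
      if (conv) break
      if (iters >= max_iter) {
        stop(sprintf("solver error: Picard iteration did not converge (relative residual %.3e after %d iterations)",
                     rel, iters))
      }
    }
    if (all(psi[floor_ids] < params$C_necrosis)) {
      warning("necrosis region occupies the entire culture surface")
    }
  }

  full <- fixed
  full[active] <- psi[sys$umap[active]]
  new_field(full, grid, params, species = "oxygen", iters = iters)
}

new_field <- function(psi, grid, params, species, time = 0, ...) {
  structure(list(psi = psi, grid = grid, params = params,
                 species = species, times = time, extra = list(...)),
            class = "oxz_field")
}

#' Oxygen percent map of a field
#'
#' Converts the partition-scaled oxygen variable to equivalent gas-phase
#' percent (19% corresponds to air-saturated medium / PDMS saturation).
#' @param field an `oxz_field` from [steady_oxygen()].
#' @return matrix of %O2 values.
#' @export
field_percent <- function(field) percent_of_psi(field$psi, field$params)

# -- transient oxygen ---------------------------------------------------------

#' Transient oxygen after a gas switch
#'
#' Backward-Euler (unconditionally stable) time integration of the oxygen
#' field. The initial condition is the steady state under `gas_bc_init`
#' (default: both channels at the 19% reference, the pre-switch
#' equilibration); at t = 0 the boundary switches to `gas_bc`. The storage
#' term uses the material solubility (PDMS holds K times more oxygen than
#' medium at equal psi), so diffusion time constants are material-correct.
#'
#' @inheritParams steady_oxygen
#' @param gas_bc_init gas levels before the switch.
#' @param gas_bc gas levels after the switch.
#' @param t_end simulated duration (s); `dt` backward-Euler step (s).
#' @param output_every snapshot cadence (s), default 600 s matching the
#'   10-min imaging interval.
#' @return object of class `oxz_series`: `times` (s) and a list of psi
#'   matrices `psi_list`.
#' @export
transient_oxygen <- function(grid, params, cells = NULL,
                             gas_bc = list(air = 19, n2 = 0),
                             gas_bc_init = list(air = 19, n2 = 19),
                             t_end = 7200, dt = 10, output_every = 600,
                             ambient_percent = params$reference_O2_percent) {
  if (dt <= 0 || t_end <= 0) stop("configuration error: dt and t_end must be positive")
  init <- steady_oxygen(grid, params, cells, gas_bc_init,
                        ambient_percent = ambient_percent)

  Deff <- oxygen_Deff(grid, params)
  fixed <- gas_fixed_psi(grid, params, gas_bc)
  active <- grid$material != "GAS"
  bc <- oxygen_bc_sides(grid, params, ambient_percent)
  sys <- fv_diffusion(grid, Deff, active, fixed, bc)

  S <- matrix(1, grid$nz, grid$nx)
  S[grid$material == "PDMS"] <- params$partition_K
  V <- grid$dx * grid$dz
  Mdiag <- numeric(sys$n)
  Mdiag[sys$umap[active]] <- S[active] * V   # storage per unknown

  psi <- numeric(sys$n)
  psi[sys$umap[active]] <- init$psi[active]

  floor_row <- min(grid$med_rows)
  floor_ids <- sys$umap[floor_row, ]
  dens <- if (is.null(cells)) NULL else cells$density

  Msys <- Matrix::sparseMatrix(i = seq_len(sys$n), j = seq_len(sys$n),
                               x = Mdiag / dt, dims = dim(sys$A))
  times <- c(0, seq(output_every, t_end, by = output_every))
  out <- vector("list", length(times))
  full0 <- gas_fixed_psi(grid, params, gas_bc_init)
  full0[active] <- init$psi[active]
  out[[1]] <- full0

  chol_cache <- NULL
  if (is.null(cells)) {
    chol_cache <- Matrix::Cholesky(Matrix::forceSymmetric(sys$A + Msys))
  }
  nsteps <- ceiling(t_end / dt)
  next_out <- 2L
  for (s in seq_len(nsteps)) {
    rhs <- sys$b + Mdiag / dt * psi
    if (is.null(cells)) {
      psi <- as.numeric(Matrix::solve(chol_cache, rhs))
    } else {
      Cfloor <- pmax(psi[floor_ids], 0)
      H <- as.numeric(Cfloor >= params$C_necrosis)
      kdiag <- params$q_cell * dens * H / (params$Km + Cfloor) * grid$dx
      K <- Matrix::sparseMatrix(i = floor_ids, j = floor_ids, x = kdiag,
                                dims = dim(sys$A))
      psi <- as.numeric(Matrix::solve(sys$A + Msys + K, rhs))
    }
    t_now <- s * dt
    while (next_out <= length(times) && t_now >= times[next_out] - 1e-9) {
      full <- fixed
      full[active] <- psi[sys$umap[active]]
      out[[next_out]] <- full
      next_out <- next_out + 1L
    }
  }
  structure(list(times = times, psi_list = out, grid = grid, params = params,
                 species = "oxygen"), class = "oxz_series")
}

# -- glucose ------------------------------------------------------------------

#' Steady glucose field in the culture chamber
#'
#' Advection-diffusion of glucose confined to the medium: Dirichlet inlet at
#' 5.5 mM, zero-diffusive-flux outflow, no-flux walls, and a constant
#' (zero-order) uptake flux `glucose_uptake * N_total / A_culture` on the
#' chamber floor. Uptake is regularised to cease smoothly where glucose is
#' exhausted, keeping concentrations non-negative. Advection uses first-order
#' upwinding (robust at the chamber's cell Peclet numbers).
#'
#' @inheritParams steady_oxygen
#' @param velocity a [poiseuille_profile()]; required.
#' @param exhaust_eps regularisation scale (mol/m^3) of the uptake cutoff.
#' @return `oxz_field` (psi = concentration, NA outside the medium) with
#'   extras `outlet` (flow-averaged outlet concentration, mol/m^3) and
#'   `inlet`.
#' @export
steady_glucose <- function(grid, params, velocity, cells = NULL,
                           exhaust_eps = 1e-3, tol = 1e-10, max_iter = 100) {
  if (missing(velocity) || is.null(velocity)) {
    stop("precondition error: steady_glucose requires a velocity field (poiseuille_profile)")
  }
  active <- grid$material == "MEDIUM"
  Deff <- matrix(params$D_glucose_medium, grid$nz, grid$nx)
  fixed <- matrix(NA_real_, grid$nz, grid$nx)
  # Danckwerts (closed) inlet: the total inlet flux is the advective
  # u * C_in supplied by the upwind scheme; no separate diffusive inlet
  # term. This keeps the chamber-wide mass balance exact and matches the
  # syringe-fed port better than an open Dirichlet face.
  bc <- list(
    left = side_spec(rep("N", grid$nz), rep(0, grid$nz)),
    right = side_spec(rep("N", grid$nz), rep(0, grid$nz)),
    bottom = side_spec(rep("N", grid$nx), rep(0, grid$nx)),
    top = side_spec(rep("N", grid$nx), rep(0, grid$nx)))
  sys <- fv_diffusion(grid, Deff, active, fixed, bc)
  u_rows <- numeric(grid$nz); u_rows[grid$med_rows] <- velocity$u_profile
  adv <- fv_advection_x(grid, u_rows, active, sys$umap,
                        C_in = params$C_glucose_in)
  A <- sys$A + Matrix::sparseMatrix(i = adv$i, j = adv$j, x = adv$v,
                                    dims = dim(sys$A))
  b <- sys$b + adv$b

  floor_row <- min(grid$med_rows)
  floor_ids <- sys$umap[floor_row, ]
  dens <- if (is.null(cells)) rep(0, grid$nx) else cells$density
  r_cell <- params$glucose_uptake / 1e6 / 60            # mol/s per cell
  f0 <- r_cell * dens                                   # mol m^-2 s^-1

  phi <- rep(1, grid$nx)
  C <- as.numeric(Matrix::solve(A, b - uptake_rhs(f0, phi, floor_ids, grid, sys$n)))
  iters <- 0L
  if (any(f0 > 0)) {
    repeat {
      iters <- iters + 1L
      Cf <- C[floor_ids]
      phi_new <- pmin(pmax(Cf, 0) / (pmax(Cf, 0) + exhaust_eps), 1)
      C_new <- as.numeric(Matrix::solve(A, b - uptake_rhs(f0, phi_new, floor_ids, grid, sys$n)))
      delta <- max(abs(C_new - C)) / max(abs(C_new))
      C <- C_new; phi <- phi_new
      if (delta < tol || iters >= max_iter) break
    }
    if (iters >= max_iter && delta >= 1e-6) {
      stop("solver error: glucose exhaustion iteration did not converge")
    }
  }
  C <- pmax(C, 0)

  full <- matrix(NA_real_, grid$nz, grid$nx)
  full[active] <- C[sys$umap[active]]
  outlet_ids <- sys$umap[grid$med_rows, grid$nx]
  outlet <- sum(velocity$u_profile * C[outlet_ids]) / sum(velocity$u_profile)
  new_field(full, grid, params, species = "glucose",
            outlet = outlet, inlet = params$C_glucose_in, iters = iters)
}

uptake_rhs <- function(f0, phi, floor_ids, grid, n) {
  r <- numeric(n)
  r[floor_ids] <- f0 * phi * grid$dx
  r
}

#' Analytic glucose mass balance
#'
#' Closed-form chamber-wide balance `C_out = C_in - r N_total / Q` (with a
#' floor at zero when demand exceeds supply), the independent oracle for the
#' outlet concentration of [steady_glucose()].
#'
#' @param Q flow rate (m^3/s), or an [flow_spec()].
#' @param params a [transport_params()].
#' @return outlet concentration (mol/m^3).
#' @export
glucose_mass_balance <- function(Q, params) {
  if (inherits(Q, "oxz_flow")) Q <- Q$Q
  if (Q <= 0) stop("domain error: Q must be positive")
  r_cell <- params$glucose_uptake / 1e6 / 60
  max(0, params$C_glucose_in - r_cell * params$N_total / Q)
}

# -- ROI extraction and stabilisation -----------------------------------------

#' ROI time series from a simulated field
#'
#' Area-weighted mean oxygen over each circular sensor footprint, evaluated
#' on the chamber-floor cell row (the sensor plane) with disk chord weights
#' along x, converted to percent O2.
#'
#' @param series an `oxz_series` from [transient_oxygen()] or an `oxz_field`.
#' @param geometry defaults to the grid's geometry.
#' @return data.frame with columns `time_s`, `roi_id`, `zone`, `O2_percent`.
#' @export
extract_roi_series <- function(series, geometry = NULL) {
  if (inherits(series, "oxz_field")) {
    series <- structure(list(times = series$times, psi_list = list(series$psi),
                             grid = series$grid, params = series$params,
                             species = series$species), class = "oxz_series")
  }
  grid <- series$grid
  params <- series$params
  if (is.null(geometry)) geometry <- grid$geometry
  rois <- geometry$roi_centers
  r <- geometry$roi_diameter / 2
  floor_row <- min(grid$med_rows)
  # weight of column j = exact area of the disk slice overlapping the cell,
  # A(u) = u sqrt(r^2 - u^2) + r^2 asin(u / r) evaluated on the overlap
  slice_area <- function(u) {
    u <- pmin(pmax(u, -r), r)
    u * sqrt(pmax(r^2 - u^2, 0)) + r^2 * asin(u / r)
  }
  masks <- lapply(seq_len(nrow(rois)), function(k) {
    lo <- grid$x - grid$dx / 2 - rois$x[k]
    hi <- grid$x + grid$dx / 2 - rois$x[k]
    w <- slice_area(hi) - slice_area(lo)
    j <- which(w > 0)
    if (!length(j)) {
      stop("resolution error: ROI footprint empty at this grid resolution")
    }
    list(j = j, w = w[j])
  })
  zones <- zone_of(rois$x, geometry = geometry)
  out <- do.call(rbind, lapply(seq_along(series$times), function(t_idx) {
    # sensor value at the chamber floor: linear extrapolation of the two
    # bottom medium rows to the wall (the cell-centre value sits dz/2 above
    # the floor, a visible bias wherever consumption steepens the profile)
    p1 <- series$psi_list[[t_idx]][floor_row, ]
    p2 <- series$psi_list[[t_idx]][floor_row + 1, ]
    psi_row <- pmax(p1 - (p2 - p1) / 2, 0)
    data.frame(time_s = series$times[t_idx],
               roi_id = seq_len(nrow(rois)),
               zone = zones,
               O2_percent = vapply(masks, function(m) {
                 percent_of_psi(sum(psi_row[m$j] * m$w) / sum(m$w), params)
               }, numeric(1)))
  }))
  rownames(out) <- NULL
  out
}

#' Stabilisation time of ROI curves
#'
#' Earliest time after which every ROI's change over each subsequent window
#' of length `window` stays below `tol_fraction` of full scale. Changes are
#' evaluated as `|x(t + window) - x(t)|` with linear interpolation, at every
#' sampled start time. Returns `NA` (not stabilised) when the last window of
#' the series still violates the tolerance.
#'
#' @param roi_series data.frame from [extract_roi_series()] (or any frame
#'   with `time_s`, `roi_id`, `O2_percent`).
#' @param window window length (s), default 600 (the imaging cadence).
#' @param tol_fraction tolerance as a fraction of full scale, default 1%.
#' @param full_scale signal full scale; defaults to the observed range over
#'   all ROIs and times.
#' @return stabilisation time (s), 0 if never violating, or `NA_real_`.
#' @export
stabilization_time <- function(roi_series, window = 600, tol_fraction = 0.01,
                               full_scale = NULL) {
  ts <- sort(unique(roi_series$time_s))
  if (diff(range(ts)) < 2 * window) {
    stop("precondition error: series must cover at least two windows")
  }
  if (is.null(full_scale)) full_scale <- diff(range(roi_series$O2_percent))
  if (full_scale == 0) return(0)
  starts <- ts[ts + window <= max(ts) + 1e-9]
  viol <- rep(FALSE, length(starts))
  for (id in unique(roi_series$roi_id)) {
    d <- roi_series[roi_series$roi_id == id, ]
    d <- d[order(d$time_s), ]
    x0 <- stats::approx(d$time_s, d$O2_percent, xout = starts)$y
    x1 <- stats::approx(d$time_s, d$O2_percent, xout = starts + window)$y
    viol <- viol | (abs(x1 - x0) >= tol_fraction * full_scale)
  }
  if (!any(viol)) return(0)
  last <- max(which(viol))
  if (last == length(starts)) return(NA_real_)
  starts[last + 1]
}

# -- 1-D PDMS slab ------------------------------------------------------------

#' Step response of a PDMS slab sensor assembly
#'
#' Transient 1-D diffusion through a PDMS slab after the gas side steps from
#' `level0` to `level1` at t = 0. Models the sensor-calibration assembly: a
#' sensor film on the outer face of the gas layer, whose polystyrene matrix
#' conducts oxygen poorly, so the outer face is closed (no-flux) by default
#' and the readout plane is that outer face. `far_bc = "ambient"` instead
#' holds the outer face at `level0`.
#'
#' @param thickness slab thickness (m), default the 2 mm gas layer.
#' @param D oxygen diffusivity in PDMS (m^2/s).
#' @param level0,level1 gas levels (% O2) before/after the step.
#' @param far_bc `"closed"` (default) or `"ambient"` outer face.
#' @param n cells across the slab; `dt` step (s); `t_end` duration (s);
#'   `output_dt` sampling cadence of the returned series (s).
#' @return data.frame with `time_s` and `O2_percent` at the sensor plane.
#' @export
slab_step_response <- function(thickness = 2e-3, D = 3.25e-9,
                               level0 = 19, level1 = 0,
                               far_bc = c("closed", "ambient"),
                               n = 200, dt = 5, t_end = 3600,
                               output_dt = 60) {
  far_bc <- match.arg(far_bc)
  if (dt <= 0 || t_end <= 0) stop("configuration error: dt and t_end must be positive")
  dx <- thickness / n
  G <- D / dx^2          # volumetric conductance between neighbours (per dt eq)
  main <- rep(1 / dt + 2 * G, n)
  main[n] <- 1 / dt + if (far_bc == "closed") G else 3 * G
  main[1] <- 1 / dt + 3 * G   # half-cell to the stepped Dirichlet face
  A <- Matrix::bandSparse(n, k = c(-1, 0, 1),
                          diagonals = list(rep(-G, n - 1), main, rep(-G, n - 1)))
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(A))
  bfix <- numeric(n)
  bfix[1] <- 2 * G * level1
  if (far_bc == "ambient") bfix[n] <- 2 * G * level0
  x <- rep(level0, n)
  times <- seq(0, t_end, by = output_dt)
  sensor <- numeric(length(times)); sensor[1] <- x[n]
  next_out <- 2L
  for (s in seq_len(ceiling(t_end / dt))) {
    x <- as.numeric(Matrix::solve(ch, x / dt + bfix))
    t_now <- s * dt
    while (next_out <= length(times) && t_now >= times[next_out] - 1e-9) {
      sensor[next_out] <- x[n]
      next_out <- next_out + 1L
    }
  }
  data.frame(time_s = times, O2_percent = sensor)
}
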