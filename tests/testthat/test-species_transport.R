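test_that("Michaelis-Menten consumption flux follows the kinetics", {
  s <- default_setup()
  p <- s$p
  sat <- p$q_cell * p$N_total / p$A_culture
  expect_equal(ocr_flux(p$Km, p), sat / 2, tolerance = 1e-15)
  expect_equal(ocr_flux(5e-5, p), 0)   # below the necrosis cutoff
  expect_equal(ocr_flux(0.18, p), sat * 0.18 / (p$Km + 0.18),
               tolerance = 1e-15)
  expect_error(ocr_flux(-0.01, p), "domain error")
  # smooth necrosis step: monotone ramp across the cutoff, saturates to 0/1
  w <- 0.1 * p$C_necrosis
  lo <- ocr_flux(p$C_necrosis - 2 * w, p, smooth_halfwidth = w)
  hi <- ocr_flux(p$C_necrosis + 2 * w, p, smooth_halfwidth = w)
  expect_equal(lo, 0)
  expect_gt(hi, 0)
})

test_that("diffusion assembly reproduces the linear 1-D column profile", {
  # single material, no flow, Dirichlet ends: exact linear solution
  nz <- 30
  grid1 <- list(nx = 1L, nz = nz, dx = 1e-3, dz = 5e-3 / nz)
  Deff <- matrix(2e-9, nz, 1)
  active <- matrix(TRUE, nz, 1)
  fixed <- matrix(NA_real_, nz, 1)
  c0 <- 2; c1 <- 5
  bc <- list(left = list(type = rep("N", nz), value = rep(0, nz)),
             right = list(type = rep("N", nz), value = rep(0, nz)),
             bottom = list(type = "D", value = c0),
             top = list(type = "D", value = c1))
  sys <- oxyzone:::fv_diffusion(grid1, Deff, active, fixed, bc)
  psi <- as.numeric(Matrix::solve(sys$A, sys$b))
  z <- (seq_len(nz) - 0.5) * grid1$dz
  expect_equal(psi, c0 + (c1 - c0) * z / (nz * grid1$dz), tolerance = 1e-10)
})

test_that("uniform gas levels give the exact constant oxygen solution", {
  s <- default_setup()
  ox <- steady_oxygen(s$gr, s$p, cells = NULL,
                      gas_bc = list(air = 19, n2 = 19))
  psi_ref <- s$p$C_sat_pdms / s$p$partition_K
  expect_equal(max(abs(ox$psi - psi_ref)) / psi_ref, 0, tolerance = 1e-8)
  # medium at C_sat/K, PDMS at C_sat
  C <- ox$psi
  expect_equal(C[s$gr$med_rows[1], 1], psi_ref, tolerance = 1e-8)
  expect_equal(field_percent(ox)[s$gr$med_rows[5], 17], 19, tolerance = 1e-6)
})

test_that("zone-patterned boundary produces ordered oxygen zones", {
  s <- default_setup()
  ox <- steady_oxygen(s$gr, s$p, cells = NULL, gas_bc = list(air = 19, n2 = 0))
  roi <- extract_roi_series(ox)
  zm <- tapply(roi$O2_percent, roi$zone, mean)
  expect_equal(unname(zm[1]), 19, tolerance = 0.06)
  expect_true(zm[1] > zm[2] && zm[2] > zm[3])
  # ROI means within the field's range over the sensor plane
  expect_true(all(roi$O2_percent >= 0 & roi$O2_percent <= 19 + 1e-9))
})

test_that("cellular consumption lowers oxygen pointwise", {
  s <- default_setup()
  off <- steady_oxygen(s$gr, s$p, cells = NULL, gas_bc = list(air = 19, n2 = 0))
  on <- steady_oxygen(s$gr, s$p, s$cells, gas_bc = list(air = 19, n2 = 0))
  expect_true(all(on$psi <= off$psi + 1e-12))
  expect_gt(max(off$psi - on$psi), 0)
})

test_that("partition interface carries the factor-10 concentration jump", {
  s <- default_setup()
  p <- s$p; gr <- s$gr
  # cell-free field: the face-value oracle is a linear extrapolation, which
  # the floor-cell consumption sink would bias without saying anything
  # about the interface scheme itself
  ox <- steady_oxygen(gr, p, cells = NULL, gas_bc = list(air = 19, n2 = 0))
  fc <- interface_faces(gr)
  up <- fc$i_medium > fc$i_pdms
  iP <- fc$i_pdms; iP2 <- ifelse(up, iP - 1, iP + 1)
  iM <- fc$i_medium; iM2 <- ifelse(up, iM + 1, iM - 1)
  # one-sided linear extrapolation of each material's profile to the face
  psifP <- ox$psi[cbind(iP, fc$j)] +
    (ox$psi[cbind(iP, fc$j)] - ox$psi[cbind(iP2, fc$j)]) / 2
  psifM <- ox$psi[cbind(iM, fc$j)] -
    (ox$psi[cbind(iM2, fc$j)] - ox$psi[cbind(iM, fc$j)]) / 2
  ratio <- p$partition_K * psifP / psifM   # C_pdms(face) / C_medium(face)
  expect_true(all(abs(ratio - p$partition_K) / p$partition_K < 0.01))
  # face-flux comparison: the half-cell fluxes on either side of the
  # flux-continuous face value agree with the harmonic-mean face flux
  DP <- p$D_O2_pdms * p$partition_K; DM <- p$D_O2_medium
  psif <- (DP * ox$psi[cbind(iP, fc$j)] + DM * ox$psi[cbind(iM, fc$j)]) /
    (DP + DM)
  fP <- DP * (ox$psi[cbind(iP, fc$j)] - psif) / (gr$dz / 2)
  fM <- DM * (psif - ox$psi[cbind(iM, fc$j)]) / (gr$dz / 2)
  G <- 2 / (1 / DP + 1 / DM) / gr$dz
  fface <- G * (ox$psi[cbind(iP, fc$j)] - ox$psi[cbind(iM, fc$j)])
  expect_equal(fP, fM, tolerance = 1e-12)
  expect_equal(fP, fface, tolerance = 1e-12)
})

test_that("closed system conserves total oxygen mass to 1e-10", {
  s <- default_setup()
  gr <- build_grid(s$g, nx = 24, nz = 20)
  nz <- gr$nz; nx <- gr$nx
  Deff <- oxyzone:::oxygen_Deff(gr, s$p)
  active <- matrix(TRUE, nz, nx)
  fixed <- matrix(NA_real_, nz, nx)
  noflux <- function(n) list(type = rep("N", n), value = rep(0, n))
  bc <- list(left = noflux(nz), right = noflux(nz),
             bottom = noflux(nx), top = noflux(nx))
  sys <- oxyzone:::fv_diffusion(gr, Deff, active, fixed, bc)
  S <- matrix(1, nz, nx); S[gr$material != "MEDIUM"] <- s$p$partition_K
  V <- gr$dx * gr$dz
  Mdiag <- numeric(sys$n); Mdiag[sys$umap[active]] <- S[active] * V
  set.seed(42)
  psi <- runif(sys$n, 0, 0.2)
  mass0 <- sum(Mdiag * psi)
  dt <- 5
  A <- sys$A + Matrix::sparseMatrix(i = seq_len(sys$n), j = seq_len(sys$n),
                                    x = Mdiag / dt, dims = dim(sys$A))
  for (step in 1:50) psi <- as.numeric(Matrix::solve(A, Mdiag / dt * psi))
  expect_equal(sum(Mdiag * psi), mass0, tolerance = 1e-10)
})

test_that("transient solver is steady under an unchanged boundary", {
  s <- default_setup()
  tr <- transient_oxygen(s$gr, s$p, cells = NULL,
                         gas_bc = list(air = 19, n2 = 19),
                         t_end = 1800, dt = 60)
  drift <- max(abs(tr$psi_list[[length(tr$psi_list)]] - tr$psi_list[[1]]))
  expect_lt(drift / max(tr$psi_list[[1]]), 1e-8)
})

test_that("gas switch separates ROI bands and stabilizes in tens of minutes", {
  s <- default_setup()
  tr <- transient_oxygen(s$gr, s$p, cells = NULL,
                         gas_bc = list(air = 19, n2 = 0))
  roi <- extract_roi_series(tr)
  last <- roi[roi$time_s == max(roi$time_s), ]
  zm <- tapply(last$O2_percent, last$zone, mean)
  expect_true(zm[1] > zm[2] && zm[2] > zm[3])
  expect_gt(zm[1] - zm[3], 10)   # clearly separated bands
  stab <- stabilization_time(roi)
  expect_gte(stab, 10 * 60)
  expect_lte(stab, 55 * 60)
})

test_that("slab step response matches the Fourier series solution", {
  D <- 3.25e-9; L <- 2e-3
  sim <- slab_step_response(thickness = L, D = D, dt = 2, t_end = 3000,
                            output_dt = 60)
  keep <- sim$time_s >= 60
  ana <- slab_series_closed(sim$time_s[keep], L, D)
  expect_equal(sim$O2_percent[keep], ana, tolerance = 0.01)
})

test_that("glucose solver obeys the integral mass balance at all flow rates", {
  s <- default_setup()
  for (q in c(5, 0.5, 0.2)) {
    v <- poiseuille_profile(flow_spec(q), s$g, s$gr)
    out <- steady_glucose(s$gr, s$p, v, s$cells)$extra$outlet
    expect_equal(out, glucose_mass_balance(flow_spec(q)$Q, s$p),
                 tolerance = 0.02)
  }
  # zero cells: outlet equals the 5.5 mM inlet
  v <- poiseuille_profile(flow_spec(0.5), s$g, s$gr)
  clean <- steady_glucose(s$gr, s$p, v, cells = NULL)$extra$outlet
  expect_equal(clean, s$p$C_glucose_in, tolerance = 1e-8)
  expect_error(steady_glucose(s$gr, s$p, NULL, s$cells), "precondition")
  # concentrations never negative, never above the inlet
  gl <- steady_glucose(s$gr, s$p, v, s$cells)
  expect_true(all(gl$psi[!is.na(gl$psi)] >= 0))
  expect_true(all(gl$psi[!is.na(gl$psi)] <= s$p$C_glucose_in + 1e-9))
})

test_that("analytic glucose balance has the right limits", {
  s <- default_setup()
  expect_equal(glucose_mass_balance(1e-3, s$p), s$p$C_glucose_in,
               tolerance = 1e-4)
  r_cell <- s$p$glucose_uptake / 1e6 / 60
  Q <- flow_spec(0.5)$Q
  expect_equal(glucose_mass_balance(Q, s$p),
               s$p$C_glucose_in - r_cell * s$p$N_total / Q, tolerance = 1e-15)
  # demand exceeding supply floors at zero
  expect_equal(glucose_mass_balance(1e-14, s$p), 0)
  expect_error(glucose_mass_balance(0, s$p), "domain error")
})

test_that("ROI extraction averages the sensor plane with disk weights", {
  s <- default_setup()
  gr <- s$gr
  # synthetic series: field linear in x at the sensor plane
  psi <- matrix(rep(seq(0.05, 0.15, length.out = gr$nx), each = gr$nz),
                gr$nz, gr$nx)
  ser <- structure(list(times = 0, psi_list = list(psi), grid = gr,
                        params = s$p, species = "oxygen"),
                   class = "oxz_series")
  roi <- extract_roi_series(ser)
  # linear-in-x field: ROI means ordered by ROI x position
  ord <- order(s$g$roi_centers$x)
  expect_true(all(diff(roi$O2_percent[ord]) > 0))
  # brute-force oracle: fine midpoint quadrature of the disk-slice area per
  # column (z-uniform field, so the wall extrapolation is the identity)
  r <- s$g$roi_diameter / 2
  for (k in seq_len(nrow(s$g$roi_centers))) {
    cx <- s$g$roi_centers$x[k]
    acc <- 0; wsum <- 0
    for (j in seq_len(gr$nx)) {
      xs <- seq(gr$x[j] - gr$dx / 2, gr$x[j] + gr$dx / 2,
                length.out = 2001)
      xm <- (xs[-1] + xs[-2001]) / 2
      chord <- 2 * sqrt(pmax(r^2 - (xm - cx)^2, 0))
      w <- sum(chord) * (xs[2] - xs[1])
      acc <- acc + w * psi[min(gr$med_rows), j]
      wsum <- wsum + w
    }
    expect_equal(roi$O2_percent[k],
                 oxyzone:::percent_of_psi(acc / wsum, s$p), tolerance = 1e-6)
  }
  # uniform reference field reads 19% at every ROI
  psi19 <- matrix(oxyzone:::psi_of_percent(19, s$p), gr$nz, gr$nx)
  ser19 <- structure(list(times = 0, psi_list = list(psi19), grid = gr,
                          params = s$p, species = "oxygen"),
                     class = "oxz_series")
  expect_equal(extract_roi_series(ser19)$O2_percent,
               rep(19, nrow(s$g$roi_centers)), tolerance = 1e-12)
})

test_that("stabilization criterion matches the exponential closed form", {
  tau <- 500; w <- 600; cad <- 600; A <- 14
  ts <- seq(0, 7200, by = cad)
  df <- data.frame(time_s = ts, roi_id = 1,
                   O2_percent = 5 + A * exp(-ts / tau))
  fs <- diff(range(df$O2_percent))
  # analytic: change over [s, s+w] is A e^{-s/tau} (1 - e^{-w/tau})
  s_star <- tau * log(A * (1 - exp(-w / tau)) / (0.01 * fs))
  viol <- ts[ts <= s_star & ts + w <= max(ts)]
  expected <- ts[max(which(ts %in% viol)) + 1]
  expect_equal(stabilization_time(df, window = w), expected)
  # constant series stabilizes immediately
  dfc <- data.frame(time_s = ts, roi_id = 1, O2_percent = 7)
  expect_equal(stabilization_time(dfc), 0)
  # a series still moving at its end is "not stabilized"
  dfn <- data.frame(time_s = ts, roi_id = 1, O2_percent = ts / 60)
  expect_true(is.na(stabilization_time(dfn, full_scale = 19)))
  expect_error(stabilization_time(df[1:2, ]), "two windows")
})
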