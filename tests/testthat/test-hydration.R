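make_particle_stream <- function(xyz_by_frame, cell, dt) {
  frame_stream(lapply(seq_along(xyz_by_frame), function(i) {
    frame(xyz_by_frame[[i]], cell, time = (i - 1) * dt)
  }))
}

test_that("central-difference velocities are exact for linear motion and continuous across the boundary", {
  dt <- 0.01
  cell <- c(5, 5, 5)
  # linear motion x = 3t
  xs <- lapply(0:10, function(t) matrix(c(3 * t * dt %% 5, 1, 1), 1, 3))
  vs <- velocities_from_positions(make_particle_stream(xs, cell, dt))
  expect_equal(as.numeric(vs$v[, 1, 1]), rep(3, 9), tolerance = 1e-9)

  # crossing the periodic boundary at constant speed: no velocity jump
  xs2 <- lapply(0:20, function(t) matrix(c((4.9 + 0.02 * t) %% 5, 1, 1), 1, 3))
  vs2 <- velocities_from_positions(make_particle_stream(xs2, cell, dt))
  expect_equal(as.numeric(vs2$v[, 1, 1]), rep(2, 19), tolerance = 1e-9)

  # sinusoid matches the analytic derivative to O(dt^2)
  t <- (0:200) * dt
  xs3 <- lapply(seq_along(t), function(i) matrix(c(2 + 0.5 * sin(t[i]), 1, 1), 1, 3))
  vs3 <- velocities_from_positions(make_particle_stream(xs3, cell, dt))
  analytic <- 0.5 * cos(t[2:200])
  expect_lt(max(abs(as.numeric(vs3$v[, 1, 1]) - analytic)), 0.5 * dt^2)
  expect_error(velocities_from_positions(make_particle_stream(xs3[1:2], cell, dt)),
               "at least 3")
})

test_that("FFT VACF equals the direct O(N^2) sum and averages over series", {
  # constant series: VACF = c^2 at all lags
  cv <- vacf_fft(rep(2, 50), dt = 1)
  expect_equal(cv$vacf, rep(4, 50), tolerance = 1e-10)
  expect_equal(cv$vacf[cv$lag == 0], 4)  # lag-0 mean squared value

  set.seed(19)
  for (i in 1:5) {
    x <- rnorm(100)
    a <- vacf_fft(x)
    b <- vacf_direct(x)
    expect_lt(max(abs(a$vacf - b$vacf)) / max(abs(b$vacf)), 1e-10)
  }
  # two particles with identical series: same curve as one
  x <- rnorm(64)
  one <- vacf_fft(x)
  two <- vacf_fft(rbind(x, x))
  expect_equal(two$vacf, one$vacf, tolerance = 1e-12)
  # chunked and averaged curves agree with the pooled computation
  y <- rnorm(64)
  pooled <- vacf_fft(rbind(x, y))
  avg <- average_vacf(list(vacf_fft(x), vacf_fft(y)))
  expect_equal(avg$vacf, pooled$vacf, tolerance = 1e-12)
})

test_that("Green-Kubo integration and the unit conversion are exact where closed forms exist", {
  zero <- data.frame(lag = 0:100, tau = (0:100) * 0.01, vacf = 0, count = 1)
  expect_equal(green_kubo_D(zero, 1)$D_cm2_s, 0)
  # exponential VACF: D -> a * tau_c
  tau <- (0:4000) * 0.001
  a <- 0.04; tau_c <- 0.2
  curve <- data.frame(lag = seq_along(tau) - 1, tau = tau,
                      vacf = a * exp(-tau / tau_c), count = 1)
  est <- green_kubo_D(curve, 4)
  expect_equal(est$D_nm2_ps, a * tau_c, tolerance = 1e-4)
  # hand unit check: 1 nm^2/ps = 1e-14 cm^2 / 1e-12 s = 1e-2 cm^2/s
  expect_equal(est$D_cm2_s, est$D_nm2_ps * 1e-2)
  expect_error(green_kubo_D(curve, 10), "exceeds")
})

test_that("the OU process recovers its analytic VACF and diffusion coefficient", {
  gamma <- 5; s <- sqrt(0.025)  # D = 5e-3 nm^2/ps
  ou <- generate_ou_process(gamma, s, n_steps = 2e5, dt = 0.01,
                            n_particles = 10, n_dim = 1, seed = 4)
  cv <- vacf_fft(t(ou$v), dt = 0.01, max_lag = 300)
  # VACF matches s^2 exp(-gamma tau) at short lags
  theo <- s^2 * exp(-gamma * cv$tau)
  expect_lt(max(abs(cv$vacf[cv$tau <= 0.4] - theo[cv$tau <= 0.4])) / s^2, 0.02)
  D <- green_kubo_D(cv, 2)
  expect_equal(D$D_nm2_ps, ou$truth$D_nm2_ps, tolerance = 0.08)
  # mean-square-displacement oracle agrees
  ou2 <- generate_ou_process(gamma, s, n_steps = 2e5, dt = 0.01,
                             n_particles = 10, n_dim = 1, seed = 5,
                             with_positions = TRUE)
  msd <- msd_diffusion(t(ou2$x), dt = 0.01, lags = c(5000, 10000, 15000))
  expect_equal(msd$D_nm2_ps, ou$truth$D_nm2_ps, tolerance = 0.1)
})

test_that("radial density recovers flat, excluded-core and planted profiles", {
  # per-bin tolerance scaled to the Poisson placement noise (3 sigma)
  pois_tol <- function(truth_density, r_lo, r_hi, h) {
    lam <- truth_density * pi * (r_hi^2 - r_lo^2) * h
    3 / sqrt(pmax(lam, 1))
  }
  flat <- function(r) 30
  dflat <- function(r) 5e-3
  cyl <- generate_solvated_cylinder(flat, dflat, box = c(6, 6, 4), n_frames = 3,
                                    dt = 0.01, seed = 6)
  breaks <- seq(0, 2.4, 0.4)
  prof <- radial_water_density(cyl$stream, cyl$system, cyl$axis_chain, breaks)
  h <- attr(prof, "axial_length")
  tol <- pois_tol(30, prof$r_lo, prof$r_hi, h)
  expect_true(all(abs(prof$density - 30) / 30 < tol))
  # occupancy-weighted mean density is unbiased
  expect_equal(sum(prof$density * prof$count) / sum(prof$count), 30,
               tolerance = 0.05)
  # integral identity: sum(density * shell volume) = mean in-range count
  vols <- pi * (prof$r_hi^2 - prof$r_lo^2) * h
  expect_equal(sum(prof$density * vols), sum(prof$count), tolerance = 1e-9)

  core <- function(r) if (r < 1) 0 else 30
  cyl2 <- generate_solvated_cylinder(core, dflat, box = c(6, 6, 4), n_frames = 3,
                                     dt = 0.01, seed = 7)
  prof2 <- radial_water_density(cyl2$stream, cyl2$system, cyl2$axis_chain, breaks)
  expect_equal(prof2$density[prof2$r_hi <= 1], c(0, 0))
  expect_gt(min(prof2$density[prof2$r_lo >= 1.2]), 15)

  ramp <- function(r) 10 + 8 * r
  cyl3 <- generate_solvated_cylinder(ramp, dflat, box = c(6, 6, 4), n_frames = 3,
                                     dt = 0.01, seed = 8)
  prof3 <- radial_water_density(cyl3$stream, cyl3$system, cyl3$axis_chain, breaks)
  truth3 <- ramp(prof3$r_mid)
  tol3 <- pois_tol(truth3, prof3$r_lo, prof3$r_hi, h)
  expect_true(all(abs(prof3$density - truth3) / truth3 < pmax(tol3, 0.1)))
})

test_that("the local diffusion profile is flat for homogeneous water and flags empty bins", {
  flat <- function(r) 12
  dflat <- function(r) 5e-3
  cyl <- generate_solvated_cylinder(flat, dflat, box = c(6, 6, 4),
                                    n_frames = 1500, dt = 0.01, seed = 9)
  breaks <- seq(0, 2.4, 0.6)
  prof <- local_diffusion_profile(cyl$stream, cyl$system, cyl$axis_chain,
                                  breaks, window = 2.5, tau_max = 1)
  expect_true(all(is.finite(prof$D_cm2_s)))
  expect_true(all(abs(prof$D_cm2_s - 5e-5) / 5e-5 < 0.15))
  expect_error(local_diffusion_profile(cyl$stream, cyl$system, cyl$axis_chain,
                                       breaks, window = 1.5, tau_max = 1),
               "2 \\* tau_max")

  # empty bins (excluded core) are NA, not zero
  core <- function(r) if (r < 1.2) 0 else 12
  cyl2 <- generate_solvated_cylinder(core, dflat, box = c(6, 6, 4),
                                     n_frames = 500, dt = 0.01, seed = 10)
  prof2 <- local_diffusion_profile(cyl2$stream, cyl2$system, cyl2$axis_chain,
                                   breaks, window = 2.5, tau_max = 1)
  expect_true(is.na(prof2$D_cm2_s[1]))
  expect_equal(prof2$n_series[1], 0)
})
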