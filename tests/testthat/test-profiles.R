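# Axial density, PMF inversion, barriers, order parameter, occupancy.

geomc <- channel_geometry(z_lumen = c(-0.7, 0.7), cross_section = c(1, 1),
                          n_monomers = 1)

test_that("uniform slab at bulk density gives n(z) = 1, and is linear", {
  # 28 bins of 0.05 nm, cross-section 1 nm^2: place exactly
  # bulk * 0.05 molecules per bin, uniformly, in every frame
  bulk <- 40
  per_bin <- bulk * 0.05  # = 2
  mids <- seq(-0.7 + 0.025, 0.7 - 0.025, by = 0.05)
  z <- as.vector(vapply(mids, function(m) m + c(-0.01, 0.01),
                        numeric(2)))
  co <- data.frame(frame = 1, id = seq_along(z), x = 0, y = 0, z = z)
  traj <- trajectory_set(0, co)
  prof <- axial_density(traj, geomc, bin_width = 0.05, bulk_density = bulk)
  expect_equal(prof$values, rep(1, 28), tolerance = 1e-9)
  # half density -> 0.5 everywhere
  co2 <- co[seq(1, nrow(co), by = 2), ]
  co2$id <- seq_len(nrow(co2))
  prof2 <- axial_density(trajectory_set(0, co2), geomc, bin_width = 0.05,
                         bulk_density = bulk)
  expect_equal(prof2$values, rep(0.5, 28), tolerance = 1e-9)
})

test_that("density binning matches the Boltzmann quadrature oracle", {
  U <- function(z) 1.5 * sin(3 * z)^2
  kT <- 0.0019872 * 300
  set.seed(101)
  # direct rejection sampling from exp(-U/kT) on the lumen
  np <- 2e6
  z <- runif(np, -0.7, 0.7)
  z <- z[runif(np) < exp(-U(z) / kT)]
  co <- data.frame(frame = 1, id = seq_along(z), x = 0, y = 0, z = z)
  prof <- axial_density(trajectory_set(0, co), geomc, bin_width = 0.05,
                        bulk_density = 1)
  pmf <- pmf_from_density(prof, temperature = 300,
                          reference_region = c(0, 0.05))
  Wref <- boltzmann_bin_W(U, prof$bin_edges, 300)
  Wref <- Wref - min(Wref[abs(pmf$mid) <= 0.05])
  expect_lt(max(abs(pmf$values - Wref)), 0.03)
})

test_that("PMF closed forms and masking behave", {
  edges <- seq(-0.7, 0.7, by = 0.1)
  ones <- axial_profile(edges, rep(1, 14), counts = rep(100, 14),
                        kind = "density")
  expect_equal(pmf_from_density(ones, temperature = 300,
                                reference_region = c(0, 1))$values,
               rep(0, 14))
  # n = e^-1 in one bin at 300 K -> 0.5962 kcal/mol
  vals <- rep(1, 14); vals[7] <- exp(-1)
  p <- pmf_from_density(axial_profile(edges, vals, counts = rep(100, 14),
                                      kind = "density"),
                        temperature = 300, reference_region = c(0.3, 1))
  expect_equal(p$values[7], 0.0019872 * 300, tolerance = 1e-4)
  expect_equal(round(p$values[7], 4), 0.5962)
  # zero-count bins are masked, never imputed
  cnt <- rep(100, 14); cnt[3] <- 0; vals3 <- rep(1, 14); vals3[3] <- 0
  p3 <- pmf_from_density(axial_profile(edges, vals3, counts = cnt,
                                       kind = "density"), 300, c(0.3, 1))
  expect_true(is.na(p3$values[3]))
  # negative densities are rejected
  neg <- axial_profile(edges, c(-1, rep(1, 13)), counts = rep(10, 14),
                       kind = "density")
  expect_error(pmf_from_density(neg), "negative")
  expect_error(pmf_from_density(p3), "density profile")
})

test_that("barrier heights are read off masked profiles correctly", {
  edges <- seq(-0.7, 0.7, by = 0.1)
  flat <- axial_profile(edges, rep(0.7, 14), counts = rep(10, 14),
                        kind = "pmf")
  expect_equal(barrier_height(flat), 0)
  # constructed water-like and urea-like profiles: 2.5 and 5.0 kcal/mol
  mids <- (edges[-1] + edges[-15]) / 2
  for (h in c(2.5, 5.0)) {
    w <- 0.3 + h * exp(-((mids - 0.05) / 0.15)^2)
    prof <- axial_profile(edges, w, counts = rep(10, 14), kind = "pmf")
    expect_equal(barrier_height(prof, region = c(-0.3, 0.3),
                                reference = c(-0.7, -0.5)),
                 h, tolerance = 0.01)
  }
  masked <- axial_profile(edges, c(rep(NA, 13), 1), counts = c(rep(0, 13), 5),
                          kind = "pmf")
  expect_error(barrier_height(masked, region = c(-0.7, 0)), "masked")
})

test_that("dipole order parameter: limits, symmetry, sign flip", {
  set.seed(111)
  n <- 6000
  z <- runif(n, -0.7, 0.7)
  co <- data.frame(frame = 1, id = 1:n, x = 0, y = 0, z = z,
                   ux = 0, uy = 0, uz = 1)
  aligned <- trajectory_set(0, co)
  p <- dipole_order_parameter(aligned, geomc, bin_width = 0.1)
  expect_equal(p$values, rep(1, 14))
  # isotropic dipoles: every bin within 3 SE of zero, bounded in [-1,1]
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  co$ux <- u[, 1]; co$uy <- u[, 2]; co$uz <- u[, 3]
  iso <- trajectory_set(0, co)
  pi_ <- dipole_order_parameter(iso, geomc, bin_width = 0.1)
  se <- pi_$sd / sqrt(pi_$counts)
  expect_true(all(abs(pi_$values) <= 3 * se))
  expect_true(all(abs(pi_$values) <= 1))
  # trajectory-wide dipole inversion flips the sign
  inv <- iso
  inv$coords$ux <- -inv$coords$ux
  inv$coords$uy <- -inv$coords$uy
  inv$coords$uz <- -inv$coords$uz
  p_inv <- dipole_order_parameter(inv, geomc, bin_width = 0.1)
  expect_equal(p_inv$values, -pi_$values)
  expect_error(dipole_order_parameter(make_traj(0, list(0)), geomc),
               "dipole")
})

test_that("an imposed orientation flip at the centre is recovered", {
  # preferred orientation +z below the centre, -z above, free rotation
  # in the vestibules -- the reorientation signature of proton exclusion
  profile_fn <- function(z) ifelse(abs(z) > 0.55, 0,
                                   -0.8 * tanh(6 * z))
  spec <- single_file_spec("brownian", pore_z_bounds = c(-0.7, 0.7),
                           D = 1, particle_radius = 0,
                           reservoir_density = 0, n_init = 10,
                           timestep = 1e-3, duration = 150,
                           sample_every = 2, seed = 115)
  traj <- simulate_single_file(spec, dipole_profile = profile_fn)
  prof <- dipole_order_parameter(traj, geomc, bin_width = 0.1)
  lower <- prof$values[prof$mid < -0.15 & prof$mid > -0.5]
  upper <- prof$values[prof$mid > 0.15 & prof$mid < 0.5]
  vestib <- prof$values[abs(prof$mid) > 0.6]
  expect_true(all(lower > 0.15))
  expect_true(all(upper < -0.15))
  expect_true(all(abs(vestib) < 0.1))
})

test_that("occupancy and crossing-time statistics", {
  traj <- make_traj(0:9 / 10, list(rep(0, 10), rep(1.2, 10)))
  oc <- occupancy_and_crossing(traj, geomc)
  expect_equal(oc$occupancy, 1)
  expect_true(is.na(oc$crossing_time_ns))
  # crossing time equals the event-table mean
  times <- seq(0, 0.4, by = 0.1)
  tcross <- make_traj(times, list(c(-1, -0.5, 0, 0.5, 1)))
  oc2 <- occupancy_and_crossing(tcross, geomc)
  expect_equal(oc2$crossing_time_ns, 0.3)
})

test_that("hopping occupancy agrees with the chain oracle (3 SE)", {
  q <- 0.75
  spec <- single_file_spec("hopping", n_sites = 4, reservoir_occupancy = q,
                           duration = 400, seed = 121)
  occ <- occupancy_and_crossing(simulate_single_file(spec),
                                pore_geom())$occupancy
  set.seed(122)
  orc <- oracle_hopping(n_sites = 4, q = q, p_hop = 0.1, p_ex = 0.5,
                        p_push = 0.1, n_steps = 50000, burnin = 5000)
  bm <- tapply(orc$occupancy, (seq_along(orc$occupancy) - 1) %/% 2000, mean)
  se <- sd(bm) / sqrt(length(bm))
  expect_lt(abs(occ - mean(orc$occupancy)), 3 * se + 0.08)
})
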