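# Translocation counting, turnover, p_d and collective-diffusion p_f.

geom1 <- channel_geometry(z_lumen = c(-0.7, 0.7), n_monomers = 1)

test_that("the three-state machine counts only complete translocations", {
  times <- seq(0, 0.4, by = 0.1)
  # canonical crossing
  ev <- detect_events(make_traj(times, list(c(-1, -0.5, 0, 0.5, 1))), geom1)
  expect_identical(nrow(ev$events), 1L)
  expect_identical(ev$events$direction, 1L)
  # bounce back to the entry side records nothing
  ev2 <- detect_events(make_traj(times, list(c(-1, -0.3, 0, -0.3, -1))),
                       geom1)
  expect_identical(nrow(ev2$events), 0L)
  # downward crossing
  ev3 <- detect_events(make_traj(times, list(c(1, 0.5, 0, -0.5, -1))), geom1)
  expect_identical(ev3$events$direction, -1L)
  # bounce then a real crossing: one event, entry time on final approach
  z <- c(-1, 0, -1, 0, 1)
  ev4 <- detect_events(make_traj(times, list(z)), geom1)
  expect_identical(nrow(ev4$events), 1L)
  expect_equal(ev4$events$t_enter, 0.3)
  expect_equal(ev4$events$t_exit, 0.4)
  # molecule vanishing mid-pore resets the state machine
  ev5 <- detect_events(make_traj(times, list(c(-1, 0, NA, 0, 1))), geom1)
  expect_identical(nrow(ev5$events), 0L)
})

test_that("the shipped fixture yields the reference turnover numbers", {
  path <- system.file("extdata", "utb_events_synthetic.tsv",
                      package = "waterperm")
  traj <- read_trajectory(path)
  geom <- channel_geometry(z_event = c(-0.75, 0.75), n_monomers = 3)
  ev <- detect_events(traj, geom)
  expect_identical(nrow(ev$events), 257L)
  tr <- turnover_rate(ev)
  expect_equal(round(tr$per_monomer_ns, 2), 0.43)
  expect_equal(round(tr$per_channel_s / 1e8, 1), 4.3)
  # the in-package generator reproduces the shipped file's events
  ev2 <- detect_events(synthetic_event_fixture(), geom)
  expect_identical(nrow(ev2$events), 257L)
})

test_that("turnover and p_d arithmetic follow their definitions", {
  ev <- detect_events(make_traj(seq(0, 100, by = 1),
                                list(rep(0, 101))), geom1)
  expect_identical(nrow(ev$events), 0L)
  tr <- turnover_rate(ev)
  expect_equal(tr$per_monomer_ns, 0)
  expect_equal(diffusional_permeability(ev)$value, 0)
  # q0 of 1 event/ns -> pd = vw * 1e9
  fake <- structure(list(events = data.frame(id = 1:200,
                                             t_enter = seq_len(200) / 2 - 0.4,
                                             t_exit = seq_len(200) / 2,
                                             direction = 1L),
                         duration = 100, n_monomers = 1),
                    class = "permeation_events")
  pd <- diffusional_permeability(fake)
  expect_equal(pd$q0, 1)
  expect_equal(pd$value, water_molecule_volume() * 1e9, tolerance = 1e-12)
  expect_equal(pd$value, 2.99e-14, tolerance = 0.002)
  expect_equal(pd$se, pd$value / sqrt(200), tolerance = 1e-9)
})

test_that("event counting and p_d agree with the brute-force chain oracle", {
  q <- 0.85
  spec <- single_file_spec("hopping", n_sites = 5, reservoir_occupancy = q,
                           hop_rate = 20, timestep = 0.005, duration = 400,
                           seed = 41)
  traj <- simulate_single_file(spec)
  ev <- detect_events(traj, pore_geom())
  pd <- diffusional_permeability(ev)

  set.seed(42)
  orc <- oracle_hopping(n_sites = 5, q = q, p_hop = 0.1, p_ex = 0.5,
                        p_push = 0.1, n_steps = 80000, burnin = 8000)
  q0_orc <- orc$crossings / (2 * 80000 * 0.005)
  pd_orc <- water_molecule_volume() * q0_orc * 1e9
  se_joint <- sqrt(pd$se^2 +
                   (water_molecule_volume() * sqrt(orc$crossings) /
                    (2 * 80000 * 0.005) * 1e9)^2)
  expect_lt(abs(pd$value - pd_orc), 3 * se_joint)
})

test_that("collective coordinate: statics, normalization, clipping", {
  # static trajectory -> n(t) identically zero
  cc0 <- collective_coordinate(make_traj(0:10 / 10,
                                         list(rep(0.2, 11), rep(-0.4, 11))),
                               geom1)
  expect_equal(cc0$n, rep(0, 11))
  # one molecule traversing the full lumen once -> total dn = 1
  z <- seq(-0.9, 0.9, length.out = 21)
  cc1 <- collective_coordinate(make_traj(0:20 / 10, list(z)), geom1)
  expect_equal(cc1$n[length(cc1$n)], 1, tolerance = 1e-9)
  # displacement outside the lumen contributes nothing
  cc2 <- collective_coordinate(make_traj(0:2 / 10,
                                         list(c(-1.4, -1.0, -0.8))), geom1)
  expect_equal(cc2$n, rep(0, 3))
})

test_that("MSD of n(t) for independent diffusers has slope 2 M D / L^2", {
  set.seed(52)
  M <- 4; D <- 0.5; L <- 1.4; dt <- 1e-3
  nf <- 40000
  # direct reflected random walks (independent of the simulator)
  paths <- replicate(M, {
    z <- cumsum(c(runif(1, -0.7, 0.7), rnorm(nf - 1, sd = sqrt(2 * D * dt))))
    # reflect into [-0.7, 0.7]
    z <- 0.7 - abs(abs(z + 0.7) %% (2 * 1.4) - 1.4) + 0  # fold
    z
  })
  traj <- make_traj((0:(nf - 1)) * dt,
                    lapply(seq_len(M), function(i) paths[, i]))
  cc <- collective_coordinate(traj, geom1)
  fit <- osmotic_permeability(cc, fit_window = 2:10)
  expect_equal(fit$D_n, M * D / L^2, tolerance = 0.12)
})

test_that("osmotic_permeability validates its window and degenerate input", {
  cc <- collective_coordinate(make_traj(0:99 / 10, list(rep(0, 100))), geom1)
  expect_equal(osmotic_permeability(cc, fit_window = 2:5)$value, 0)
  expect_error(osmotic_permeability(cc, fit_window = 2:50), "10x")
  expect_error(osmotic_permeability(cc, fit_window = c(0, 3)), "positive")
})

test_that("pf and pd are invariant under z-translation and time reversal", {
  spec <- single_file_spec("hopping", n_sites = 5,
                           reservoir_occupancy = 0.85, duration = 150,
                           seed = 61)
  traj <- simulate_single_file(spec)
  pd1 <- diffusional_permeability(detect_events(traj, pore_geom()))
  pf1 <- osmotic_permeability(collective_coordinate(traj, pore_geom()))

  shift <- traj
  shift$coords$z <- shift$coords$z + 2.5
  gs <- channel_geometry(z_lumen = c(-0.7, 0.7) + 2.5)
  expect_equal(diffusional_permeability(detect_events(shift, gs))$value,
               pd1$value)
  expect_equal(osmotic_permeability(collective_coordinate(shift, gs))$value,
               pf1$value, tolerance = 1e-9)

  rev_traj <- traj
  nf <- length(traj$times)
  rev_traj$coords$frame <- nf + 1L - rev_traj$coords$frame
  rev_traj$coords <- rev_traj$coords[order(rev_traj$coords$frame), ]
  expect_equal(diffusional_permeability(detect_events(rev_traj,
                                                      pore_geom()))$value,
               pd1$value)
  expect_equal(osmotic_permeability(collective_coordinate(rev_traj,
                                                          pore_geom()))$value,
               pf1$value, tolerance = 1e-9)
})

test_that("event count is invariant under frame subsampling by 2", {
  spec <- single_file_spec("hopping", n_sites = 4,
                           reservoir_occupancy = 0.85, hop_rate = 10,
                           timestep = 0.005, duration = 300, seed = 71)
  traj <- simulate_single_file(spec)
  ev_full <- detect_events(traj, pore_geom())
  sub <- traj
  keep <- seq(1, length(traj$times), by = 2)
  sub$times <- traj$times[keep]
  co <- traj$coords[traj$coords$frame %in% keep, ]
  co$frame <- match(co$frame, keep)
  sub$coords <- co
  ev_sub <- detect_events(sub, pore_geom())
  # crossings take many frames here; halving the rate must not lose events
  expect_lt(abs(nrow(ev_sub$events) - nrow(ev_full$events)),
            0.03 * nrow(ev_full$events) + 3)
})

test_that("pf >= pd on single-file trajectories", {
  for (s in c(81, 82)) {
    spec <- single_file_spec("hopping", n_sites = 5,
                             reservoir_occupancy = 0.9, duration = 200,
                             seed = s)
    traj <- simulate_single_file(spec)
    pd <- diffusional_permeability(detect_events(traj, pore_geom()))
    pf <- osmotic_permeability(collective_coordinate(traj, pore_geom()))
    expect_gt(pf$value, pd$value)
  }
})

test_that("Poisson SE of p_d covers the long-run rate at nominal level", {
  # many short replicates against one long-run reference
  spec_long <- single_file_spec("hopping", n_sites = 3,
                                reservoir_occupancy = 0.8, hop_rate = 20,
                                timestep = 0.005, duration = 3000,
                                sample_every = 2, seed = 90)
  ref <- diffusional_permeability(detect_events(simulate_single_file(spec_long),
                                                pore_geom()))$value
  set.seed(91)
  hits <- vapply(1:60, function(i) {
    spec <- single_file_spec("hopping", n_sites = 3,
                             reservoir_occupancy = 0.8, hop_rate = 20,
                             timestep = 0.005, duration = 150)
    pd <- diffusional_permeability(detect_events(simulate_single_file(spec),
                                                 pore_geom()))
    abs(pd$value - ref) <= 2 * pd$se
  }, NA)
  expect_gte(mean(hits), 0.85)
})
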