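#' Specify a synthetic single-file pore model
#'
#' Describes a stochastic stand-in for water motion through a narrow
#' single-file channel, in one of two interchangeable variants:
#'
#' * `"hopping"`: a discrete vacancy-hopping chain.  The pore is a row
#'   of `n_sites` hard-core sites; particles hop to adjacent empty
#'   sites with Metropolis acceptance on the site potential, and the
#'   two ends exchange particles with reservoir buffer slots held at a
#'   grand-canonical occupancy.  Exactly solvable occupancy statistics
#'   make this the oracle-friendly variant.
#' * `"brownian"`: overdamped Brownian dynamics on the channel axis
#'   with an external potential U(z), optional hard-core no-passing
#'   exclusion, reflecting outer walls, and grand-canonical insertion/
#'   deletion in buffer slabs beyond the pore ends.  This variant
#'   exercises continuous-coordinate binning and PMF code.
#'
#' Defaults mimic a UT-B-like pore: lumen length 1.4 nm and a
#' cross-section set by an effective pore radius of 0.221 nm.
#'
#' @param variant `"hopping"` or `"brownian"`.
#' @param n_sites Number of pore sites (hopping variant).
#' @param pore_z_bounds Pair, nm: axial span of the pore lumen.
#' @param hop_rate Hop attempt rate, 1/ns per particle (hopping).
#' @param knockon_rate Attempt rate of concerted knock-on block moves
#'   at each pore end, 1/ns (hopping variant; default `hop_rate`).
#'   These reversible collective moves leave the equilibrium occupancy
#'   statistics untouched but carry the concerted column transport
#'   characteristic of tight single-file pores.
#' @param D Axial diffusion constant, nm^2/ns (brownian).
#' @param pmf Optional data frame `(z, U)` tabulating an axial
#'   potential in kcal/mol; must cover `pore_z_bounds`.  `NULL` = flat.
#' @param reservoir_density Reservoir number density, molecules/nm^3.
#'   For the hopping variant this sets the buffer-slot occupancy via
#'   the grand-canonical single-site law q = a/(1+a), a = density x
#'   site volume, unless `reservoir_occupancy` overrides it.
#' @param reservoir_occupancy Optional direct buffer occupancy in
#'   (0, 1) (hopping variant); overrides `reservoir_density`.
#' @param particle_radius Hard-core radius, nm (brownian; 0 disables
#'   exclusion).
#' @param timestep Integration/attempt timestep, ns.
#' @param duration Simulated time, ns (excluding burn-in).
#' @param seed Optional integer seed applied at simulation start.
#' @param temperature K; sets Boltzmann factors for the pmf.
#' @param sample_every Record every k-th step.
#' @param burnin_frac Fraction of `duration` prepended and discarded
#'   before recording (default 10 percent).
#' @param exchange_rate Reservoir exchange attempt rate, 1/ns.
#' @param buffer_width Brownian buffer slab width, nm.
#' @param n_init Initial particle count for a closed brownian run
#'   (`reservoir_density = 0`): fixed-N dynamics with reflecting walls.
#' @param cross_section Pair `c(Lx, Ly)` nm used to convert densities
#'   to site/slab volumes.
#' @return An object of class `single_file_spec`.
#' @export
single_file_spec <- function(variant = c("hopping", "brownian"),
                             n_sites = 5L, pore_z_bounds = c(-0.7, 0.7),
                             hop_rate = 20, knockon_rate = NULL, D = 1,
                             pmf = NULL,
                             reservoir_density = 33.37,
                             reservoir_occupancy = NULL,
                             particle_radius = 0.14, timestep = 0.005,
                             duration = 100, seed = NULL,
                             temperature = 300, sample_every = 1L,
                             burnin_frac = 0.1, exchange_rate = NULL,
                             buffer_width = 0.3, n_init = 0L,
                             cross_section = c(0.442, 0.442)) {
  variant <- match.arg(variant)
  pore_z_bounds <- as.numeric(pore_z_bounds)
  if (length(pore_z_bounds) != 2L || pore_z_bounds[1] >= pore_z_bounds[2])
    stop("pore_z_bounds must be an ordered pair")
  if (timestep <= 0) stop("timestep must be positive")
  if (duration < 0) stop("duration must be non-negative")
  if (variant == "hopping" && hop_rate <= 0) stop("hop_rate must be positive")
  if (variant == "brownian" && D <= 0) stop("D must be positive")
  if (!is.null(pmf)) {
    if (!all(c("z", "U") %in% names(pmf)))
      stop("pmf must be a data frame with columns z and U")
    if (min(pmf$z) > pore_z_bounds[1] || max(pmf$z) < pore_z_bounds[2])
      stop("pmf table does not cover pore_z_bounds")
  }
  if (!is.null(reservoir_occupancy) &&
      (reservoir_occupancy <= 0 || reservoir_occupancy >= 1))
    stop("reservoir_occupancy must lie in (0, 1)")
  structure(list(variant = variant, n_sites = as.integer(n_sites),
                 pore_z_bounds = pore_z_bounds, hop_rate = hop_rate,
                 knockon_rate = if (is.null(knockon_rate)) hop_rate else
                   knockon_rate, D = D,
                 pmf = pmf, reservoir_density = reservoir_density,
                 reservoir_occupancy = reservoir_occupancy,
                 particle_radius = particle_radius, timestep = timestep,
                 duration = duration, seed = seed, temperature = temperature,
                 sample_every = as.integer(sample_every),
                 burnin_frac = burnin_frac,
                 exchange_rate = exchange_rate,
                 buffer_width = buffer_width, n_init = as.integer(n_init),
                 cross_section = as.numeric(cross_section)),
            class = "single_file_spec")
}

# Buffer occupancy implied by a spec (hopping variant).
buffer_occupancy <- function(spec) {
  if (!is.null(spec$reservoir_occupancy)) return(spec$reservoir_occupancy)
  a_site <- (spec$pore_z_bounds[2] - spec$pore_z_bounds[1]) / spec$n_sites
  v_site <- a_site * spec$cross_section[1] * spec$cross_section[2]
  act <- spec$reservoir_density * v_site
  act / (1 + act)
}

# z coordinates of hopping sites 0..n_sites+1 (buffers 0.15 nm beyond
# the pore ends, past the default event-plane hysteresis).
hopping_site_z <- function(spec) {
  zb <- spec$pore_z_bounds
  a <- (zb[2] - zb[1]) / spec$n_sites
  c(zb[1] - 0.15, zb[1] + (seq_len(spec$n_sites) - 0.5) * a, zb[2] + 0.15)
}

#' Simulate a synthetic single-file pore trajectory
#'
#' Runs the stochastic model described by a [single_file_spec()] and
#' returns a [trajectory_set()] in channel-aligned coordinates
#' (x = y = 0 on the pore axis).  Reservoir coupling lets particles
#' enter and leave at both pore ends; with hard-core exclusion the
#' axial order of in-pore particles is preserved exactly (no passing).
#' A burn-in of `burnin_frac * duration` is simulated and discarded
#' before the first recorded frame, so recorded statistics are
#' stationary.  With `duration = 0` only the initial configuration is
#' returned.
#'
#' @param spec A `single_file_spec`.
#' @param dipole_profile Optional function z -> mean cos(theta) in
#'   [-1, 1]; when given, unit dipole vectors are attached whose axial
#'   component fluctuates around the profile value.
#' @return A `trajectory_set`.
#' @export
simulate_single_file <- function(spec, dipole_profile = NULL) {
  stopifnot(inherits(spec, "single_file_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  dt <- spec$timestep
  n_steps <- round(spec$duration / dt)
  burnin <- round(spec$burnin_frac * n_steps)
  kT <- .kB * spec$temperature
  zb <- spec$pore_z_bounds

  if (spec$variant == "hopping") {
    zs <- hopping_site_z(spec)
    u_site <- if (is.null(spec$pmf)) rep(0, spec$n_sites) else
      approx(spec$pmf$z, spec$pmf$U, xout = zs[2:(spec$n_sites + 1)],
             rule = 2)$y / kT
    p_hop <- spec$hop_rate * dt
    if (p_hop > 0.5)
      warning("hop_rate * timestep > 0.5; reduce the timestep")
    # reservoir equilibration is fast compared with in-pore hopping
    ex <- if (is.null(spec$exchange_rate)) 5 * spec$hop_rate else
      spec$exchange_rate
    raw <- cpp_sim_hopping(spec$n_sites, buffer_occupancy(spec), p_hop,
                           min(ex * dt, 0.9),
                           min(spec$knockon_rate * dt, 0.9), u_site,
                           n_steps, spec$sample_every, burnin)
    z <- zs[raw$z + 1]
  } else {
    grid_z <- seq(zb[1] - spec$buffer_width, zb[2] + spec$buffer_width,
                  by = 0.01)
    u_tab <- if (is.null(spec$pmf)) numeric(0) else
      approx(spec$pmf$z, spec$pmf$U, xout = grid_z, rule = 2)$y / kT
    v_slab <- spec$buffer_width * spec$cross_section[1] * spec$cross_section[2]
    ex <- if (is.null(spec$exchange_rate)) 20 else spec$exchange_rate
    raw <- cpp_sim_brownian(zb[1], zb[2], spec$buffer_width, spec$D, dt,
                            n_steps, spec$sample_every, burnin,
                            spec$particle_radius, u_tab,
                            zb[1] - spec$buffer_width, 0.01,
                            spec$reservoir_density, v_slab, ex, spec$n_init)
    z <- raw$z
  }

  n_frames <- if (n_steps == 0) 1L else n_steps %/% spec$sample_every + 1L
  times <- (seq_len(n_frames) - 1L) * dt * spec$sample_every
  coords <- data.frame(frame = raw$frame + 1L, id = raw$id,
                       x = 0, y = 0, z = z)
  if (!is.null(dipole_profile)) {
    m <- pmin(1, pmax(-1, dipole_profile(coords$z)))
    uz <- pmin(1, pmax(-1, rnorm(nrow(coords), mean = m, sd = 0.4)))
    phi <- runif(nrow(coords), 0, 2 * pi)
    r <- sqrt(pmax(0, 1 - uz^2))
    coords$ux <- r * cos(phi)
    coords$uy <- r * sin(phi)
    coords$uz <- uz
  }
  trajectory_set(times, coords)
}

#' Generate a synthetic stopped-flow relaxation trace
#'
#' Produces `signal(t) = baseline + sum_i A_i exp(-k_i t)` plus
#' Gaussian noise, emulating averaged scattered-light or fluorescence
#' time courses from a rapid-mixing experiment.
#'
#' @param rates One or two positive exponential rate constants, 1/s.
#' @param amplitudes One amplitude per rate (signal units).
#' @param baseline Baseline signal level.
#' @param noise_sd Gaussian noise SD (signal units).
#' @param timestep Sampling interval, s.
#' @param duration Trace length, s; should cover at least 5/min(rates).
#' @param temperature K.
#' @param condition,direction Metadata labels carried on the trace.
#' @param seed Optional integer seed.
#' @return A `stopped_flow_trace`.
#' @export
generate_stoppedflow_trace <- function(rates, amplitudes = rep(1, length(rates)),
                                       baseline = 0, noise_sd = 0,
                                       timestep = NULL, duration = NULL,
                                       temperature = 288.15,
                                       condition = "osmotic",
                                       direction = "shrink", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rates <- as.numeric(rates)
  if (any(rates <= 0)) stop("rates must be positive")
  if (length(amplitudes) != length(rates))
    stop("one amplitude per rate is required")
  if (is.null(duration)) duration <- 6 / min(rates)
  if (is.null(timestep)) timestep <- duration / 500
  if (timestep <= 0 || duration <= 0) stop("zero-length sampling grid")
  if (duration < 5 / min(rates))
    warning("duration shorter than 5/min(rates); slow phase undersampled")
  times <- seq(0, duration, by = timestep)
  signal <- baseline
  for (i in seq_along(rates))
    signal <- signal + amplitudes[i] * exp(-rates[i] * times)
  if (noise_sd > 0) signal <- signal + rnorm(length(times), sd = noise_sd)
  stopped_flow_trace(times, signal, temperature = temperature,
                     condition = condition, direction = direction)
}

#' Generate an Arrhenius temperature series
#'
#' Rates following `rate(T) = prefactor * exp(-Ea / (R T))` with
#' optional multiplicative (log-normal) noise, emulating a set of
#' stopped-flow rate constants measured across temperatures.
#'
#' @param Ea Activation energy, kcal/mol (>= 0).
#' @param prefactor Pre-exponential factor, 1/s.
#' @param temperatures Vector of at least two distinct temperatures, K.
#' @param noise_cv Relative SD of the multiplicative noise.
#' @param seed Optional integer seed.
#' @return Data frame with columns `temperature` (K) and `rate` (1/s).
#' @export
generate_arrhenius_series <- function(Ea, prefactor, temperatures,
                                      noise_cv = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(unique(temperatures)) < 2)
    stop("at least two distinct temperatures are required")
  if (Ea < 0) stop("Ea must be non-negative")
  rate <- prefactor * exp(-Ea / (.kB * temperatures))
  if (noise_cv > 0)
    rate <- rate * exp(rnorm(length(rate), sd = noise_cv))
  data.frame(temperature = as.numeric(temperatures), rate = rate)
}
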