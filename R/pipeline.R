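#' Deterministic trajectory with a known number of translocations
#'
#' Constructs a synthetic trajectory containing exactly `n_events`
#' complete bidirectional translocations (alternating directions) plus
#' `n_bounce` molecules that enter the pore and retreat to their entry
#' side, over a fixed duration.  Every quantity is deterministic, so
#' the event counter's bookkeeping can be anchored to an exact count.
#' A copy generated with the defaults ships with the package as
#' `extdata/utb_events_synthetic.tsv` (a synthetic stand-in for a
#' channel trajectory, not simulation output).
#'
#' @param n_events Number of complete translocations.
#' @param n_bounce Number of enter-and-return excursions.
#' @param duration Trajectory length, ns.
#' @param dt Frame spacing, ns.
#' @return A `trajectory_set`; pair it with
#'   `channel_geometry(z_event = c(-0.75, 0.75), n_monomers = 3)`.
#' @export
synthetic_event_fixture <- function(n_events = 257, n_bounce = 40,
                                    duration = 200, dt = 0.1) {
  times <- seq(0, duration, by = dt)
  nf <- length(times)
  zpath_up <- c(-0.9, -0.4, 0, 0.4, 0.9)
  span <- length(zpath_up)
  recs <- vector("list", n_events + n_bounce)
  # spread starts evenly; leave room for the 5-frame path
  starts <- floor(seq(1, nf - span, length.out = n_events + n_bounce))
  for (i in seq_len(n_events)) {
    zp <- if (i %% 2L) zpath_up else rev(zpath_up)
    recs[[i]] <- data.frame(frame = starts[i] + 0:(span - 1L), id = i,
                            x = 0, y = 0, z = zp)
  }
  zbounce <- c(-0.9, -0.4, 0, -0.4, -0.9)
  for (j in seq_len(n_bounce)) {
    i <- n_events + j
    recs[[i]] <- data.frame(frame = starts[i] + 0:(span - 1L),
                            id = i, x = 0, y = 0, z = zbounce)
  }
  trajectory_set(times, do.call(rbind, recs))
}

default_config <- function() {
  list(
    mode = "full",
    geometry = list(z_lumen = c(-0.7, 0.7), z_event = NULL,
                    cross_section = c(0.442, 0.442), n_monomers = 1),
    simulation = list(variant = "hopping", n_sites = 5,
                      pore_z_bounds = c(-0.7, 0.7), hop_rate = 20,
                      timestep = 0.005, duration = 200,
                      reservoir_occupancy = 0.8),
    estimators = list(bin_width = 0.05, bulk_density = 33.37,
                      temperature = 300)
  )
}

build_geometry <- function(g) {
  channel_geometry(z_lumen = unlist(g$z_lumen),
                   z_event = if (is.null(g$z_event)) NULL else
                     unlist(g$z_event),
                   cross_section = if (is.data.frame(g$cross_section))
                     g$cross_section else unlist(g$cross_section),
                   n_monomers = if (is.null(g$n_monomers)) 1L else
                     g$n_monomers)
}

stage <- function(name, expr) {
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), name))
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the simulate/analyze pipeline
#'
#' Orchestrates an end-to-end run: generate or load a trajectory,
#' count translocations, estimate the single-channel p_d
#' (event counting) and p_f (collective diffusion), occupancy,
#' turnover and axial profiles, and emit a machine-readable summary.
#' All randomness is governed by `seed`; identical `(config, seed)`
#' pairs give identical reports.
#'
#' @param config A configuration list (see `Details`) or the path of a
#'   YAML file holding one.  Omitted entries take defaults describing
#'   a UT-B-like synthetic single-file pore.
#' @param seed Integer seed recorded in every output.
#' @param out_dir Optional output directory; when given, the report is
#'   written as `report.json`, plus event table and profile files.
#' @return The report, a nested list, invisibly when `out_dir` is set.
#'
#' @details Config entries: `mode` (`"simulate"`,
#'   `"analyze-trajectory"`, `"analyze-traces"` or `"full"`),
#'   `trajectory` (input path, analyze-trajectory mode), `traces`
#'   (list of trace file paths, analyze-traces mode), `cell`
#'   (arguments of [cell_params()]), `geometry`, `simulation`
#'   (arguments of [single_file_spec()]), `estimators` (`bin_width`,
#'   `bulk_density`, `temperature`, `fit_window`).
#' @export
run_pipeline <- function(config = list(), seed = 1, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  geom <- build_geometry(cfg$geometry)
  est <- cfg$estimators
  report <- list(seed = seed, mode = cfg$mode)

  traj <- NULL
  if (cfg$mode %in% c("simulate", "full")) {
    traj <- stage("simulate", {
      sim <- cfg$simulation
      sim$seed <- NULL  # the pipeline seed governs
      spec <- do.call(single_file_spec, sim)
      simulate_single_file(spec)
    })
    if (!is.null(out_dir) && cfg$mode == "simulate")
      write_trajectory(traj, file.path(out_dir, "trajectory.tsv"))
  }
  if (cfg$mode == "analyze-trajectory") {
    traj <- stage("load-trajectory", {
      if (is.null(cfg$trajectory)) stop("no trajectory path in config")
      if (!file.exists(cfg$trajectory))
        stop("trajectory file not found: ", cfg$trajectory)
      message("  input: ", cfg$trajectory, " md5=",
              unname(tools::md5sum(cfg$trajectory)))
      read_trajectory(cfg$trajectory)
    })
  }

  if (!is.null(traj) && cfg$mode != "simulate") {
    report$trajectory <- stage("analyze-trajectory", {
      ev <- detect_events(traj, geom)
      tr <- turnover_rate(ev)
      pd <- diffusional_permeability(ev)
      cc <- collective_coordinate(traj, geom)
      pf <- tryCatch(osmotic_permeability(cc, fit_window = est$fit_window),
                     error = function(e) NULL)
      occ <- occupancy_and_crossing(traj, geom, ev)
      out <- list(
        n_events = nrow(ev$events), duration_ns = ev$duration,
        n_monomers = geom$n_monomers,
        turnover_per_monomer_ns = tr$per_monomer_ns,
        turnover_per_channel_s = tr$per_channel_s,
        pd_cm3_s = pd$value, pd_se = pd$se,
        occupancy = occ$occupancy,
        crossing_time_ns = occ$crossing_time_ns)
      if (!is.null(pf)) {
        out$pf_cm3_s <- pf$value
        out$pf_se <- pf$se
        out$D_n_per_ns <- pf$D_n
        out$pf_over_pd_minus_1 <- if (pd$value > 0)
          single_file_N(pf$value, pd$value)$N else NA
      }
      if (!is.null(out_dir)) {
        write_events(ev, file.path(out_dir, "events.tsv"))
        dens <- axial_density(traj, geom, bin_width = est$bin_width,
                              bulk_density = est$bulk_density)
        write_profile(dens, file.path(out_dir, "density_profile.tsv"))
        pmf <- pmf_from_density(dens, temperature = est$temperature)
        write_profile(pmf, file.path(out_dir, "pmf_profile.tsv"))
      }
      out
    })
  }

  if (cfg$mode == "analyze-traces") {
    report$traces <- stage("analyze-traces", {
      if (is.null(cfg$traces)) stop("no trace paths in config")
      cell <- do.call(cell_params, if (is.null(cfg$cell)) list() else
        cfg$cell)
      lapply(cfg$traces, function(p) {
        message("  input: ", p, " md5=", unname(tools::md5sum(p)))
        trace <- read_trace(p)
        fit <- fit_exponential(trace)
        rec <- switch(trace$condition,
                      osmotic = osmotic_Pf(fit, cell),
                      `D2O-exchange` = diffusional_Pd(fit, cell),
                      NH3 = solute_permeability(fit, cell, "NH3"),
                      `H+` = solute_permeability(fit, cell, "H"),
                      osmotic_Pf(fit, cell))
        list(path = p, condition = trace$condition, k = fit$rates[1],
             k_se = fit$rate_se[1], kind = rec$kind,
             P_cm_s = rec$value)
      })
    })
  }

  if (!is.null(out_dir)) {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(report))
  }
  report
}
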