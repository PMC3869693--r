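#' Detect complete water translocations
#'
#' Scans each molecule's axial path with a three-state machine
#' (below | inside | above the event planes).  A permeation event is
#' recorded only for the complete sequence below -> inside -> above
#' (direction +1) or above -> inside -> below (direction -1); a
#' molecule that re-exits on its entry side records nothing.  The
#' state machine resets when a molecule disappears from the
#' trajectory, so reservoir exchange cannot stitch two molecules into
#' one event.  Entry time is the first frame inside the lumen on the
#' final approach; exit time is the first frame beyond the far plane.
#'
#' @param traj An unwrapped `trajectory_set`.
#' @param geom A [channel_geometry()]; `z_event` supplies the planes.
#' @return An object of class `permeation_events`: the event table
#'   (`id`, `t_enter`, `t_exit`, `direction`) plus trajectory duration
#'   and monomer count.
#' @export
detect_events <- function(traj, geom) {
  lo <- geom$z_event[1]; hi <- geom$z_event[2]
  co <- traj$coords
  times <- traj$times
  empty <- data.frame(id = integer(0), t_enter = numeric(0),
                      t_exit = numeric(0), direction = integer(0))
  dur <- if (length(times) > 1) diff(range(times)) else 0
  if (!nrow(co))
    return(structure(list(events = empty, duration = dur,
                          n_monomers = geom$n_monomers),
                     class = "permeation_events"))
  o <- order(co$id, co$frame)
  id <- co$id[o]; fr <- co$frame[o]; z <- co$z[o]
  n <- length(id)
  r <- ifelse(z < lo, -1L, ifelse(z > hi, 1L, 0L))
  newgrp <- c(TRUE, id[-1] != id[-n] | (fr[-1] - fr[-n]) != 1L)
  grp <- cumsum(newgrp)
  # first row of each constant-region run within a group
  run_start <- newgrp | c(TRUE, r[-1] != r[-n])
  ks <- which(run_start)
  v <- r[ks]; g <- grp[ks]; tt <- times[fr[ks]]; vid <- id[ks]
  m <- length(ks)
  if (m < 3)
    return(structure(list(events = empty, duration = dur,
                          n_monomers = geom$n_monomers),
                     class = "permeation_events"))
  i <- seq_len(m - 2)
  same <- g[i] == g[i + 1] & g[i] == g[i + 2]
  up <- same & v[i] == -1L & v[i + 1] == 0L & v[i + 2] == 1L
  dn <- same & v[i] == 1L & v[i + 1] == 0L & v[i + 2] == -1L
  hit <- which(up | dn)
  events <- data.frame(id = vid[hit],
                       t_enter = tt[hit + 1],
                       t_exit = tt[hit + 2],
                       direction = ifelse(up[hit], 1L, -1L))
  events <- events[order(events$t_exit), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(events = events, duration = dur,
                 n_monomers = geom$n_monomers),
            class = "permeation_events")
}

#' @export
print.permeation_events <- function(x, ...) {
  cat(sprintf("Permeation events: %d over %.4g ns (%d monomer(s))\n",
              nrow(x$events), x$duration, x$n_monomers))
  if (nrow(x$events)) {
    updn <- table(factor(x$events$direction, levels = c(-1, 1)))
    cat(sprintf("  direction -1: %d, +1: %d\n", updn[[1]], updn[[2]]))
  }
  invisible(x)
}

#' Write a permeation event table to a delimited file
#'
#' @param events A `permeation_events` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  write.table(events$events, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Water turnover rate from counted translocations
#'
#' @param events A `permeation_events` object.
#' @return List with `per_monomer_ns` (complete translocations per
#'   monomer per ns, both directions) and `per_channel_s` (the same
#'   rate expressed per channel per second, i.e. x 1e9).
#' @export
turnover_rate <- function(events) {
  if (events$duration <= 0) stop("trajectory duration must be positive")
  k <- nrow(events$events) / (events$duration * events$n_monomers)
  list(per_monomer_ns = k, per_channel_s = k * 1e9)
}

#' Diffusional single-channel permeability from event counting
#'
#' Quantifies the equilibrium flux through the pore: at equilibrium the
#' bidirectional translocation count splits evenly, so the
#' unidirectional rate is `q0 = N_events / (2 t n_monomers)` and
#' `p_d = v_w q0`.  The standard error comes from Poisson counting
#' statistics (sqrt of the event count).
#'
#' @param events A `permeation_events` object.
#' @param vw Volume of one water molecule, cm^3.
#' @return A `permeability_estimate` with `value` (p_d, cm^3/s), `se`,
#'   `q0` (unidirectional events/ns) and the event count.
#' @export
diffusional_permeability <- function(events, vw = water_molecule_volume()) {
  if (events$duration <= 0) stop("trajectory duration must be positive")
  nev <- nrow(events$events)
  q0 <- nev / (2 * events$duration * events$n_monomers)   # events/ns
  pd <- vw * q0 * 1e9                                      # cm^3/s
  se <- vw * sqrt(nev) / (2 * events$duration * events$n_monomers) * 1e9
  structure(list(kind = "pd", value = pd, se = se, q0 = q0,
                 n_events = nev, vw = vw),
            class = "permeability_estimate")
}

#' @export
print.permeability_estimate <- function(x, ...) {
  cat(sprintf("Single-channel %s = %.4g +/- %.2g cm^3/s", x$kind,
              x$value, x$se))
  if (!is.null(x$n_events)) cat(sprintf("  (%d events)", x$n_events))
  if (!is.null(x$D_n)) cat(sprintf("  (D_n = %.4g /ns)", x$D_n))
  cat("\n")
  invisible(x)
}

#' Collective coordinate of water in the pore
#'
#' Accumulates the in-lumen axial displacements of all waters,
#' normalized to the pore length L: per frame-to-frame step,
#' `dn = sum_i dz_i / L` over molecules inside the lumen at either
#' endpoint of the step, with displacements clipped to the lumen so
#' that molecules entering or leaving mid-step contribute only their
#' in-lumen portion.  A net advance of n by 1 corresponds to the
#' transport of one pore volume of water.
#'
#' @param traj An unwrapped `trajectory_set`.
#' @param geom A [channel_geometry()]; `z_lumen` defines the lumen.
#' @return An object of class `collective_coordinate`: `times` (ns),
#'   `n` (dimensionless, `n[1] = 0`) and `L` (nm).
#' @export
collective_coordinate <- function(traj, geom) {
  lo <- geom$z_lumen[1]; hi <- geom$z_lumen[2]
  L <- hi - lo
  times <- traj$times
  nf <- length(times)
  nn <- numeric(nf)
  co <- traj$coords
  if (nrow(co) && nf > 1) {
    o <- order(co$id, co$frame)
    id <- co$id[o]; fr <- co$frame[o]; z <- co$z[o]
    n <- length(id)
    step <- which(id[-1] == id[-n] & (fr[-1] - fr[-n]) == 1L)
    z0 <- z[step]; z1 <- z[step + 1]
    use <- (z0 >= lo & z0 <= hi) | (z1 >= lo & z1 <= hi)
    dz <- pmin(pmax(z1[use], lo), hi) - pmin(pmax(z0[use], lo), hi)
    dn <- rowsum(dz / L, fr[step][use])
    idx <- as.integer(rownames(dn))
    incr <- numeric(nf - 1)
    incr[idx] <- dn[, 1]
    nn <- c(0, cumsum(incr))
  }
  structure(list(times = times, n = nn, L = L),
            class = "collective_coordinate")
}

#' @export
print.collective_coordinate <- function(x, ...) {
  cat(sprintf("Collective coordinate: %d frames, net displacement %.3g pore lengths\n",
              length(x$times), x$n[length(x$n)]))
  invisible(x)
}

#' @export
plot.collective_coordinate <- function(x, ...) {
  plot(x$times, x$n, type = "l", xlab = "time (ns)",
       ylab = "collective coordinate n(t)", ...)
  invisible(x)
}

#' Osmotic single-channel permeability by collective diffusion
#'
#' Treats the collective coordinate n(t) as a one-dimensional diffusion
#' process and estimates its diffusion coefficient D_n from the slope
#' of the mean-squared displacement over a window of lag times
#' (averaged over all time origins); then `p_f = v_w D_n`.  The
#' default window spans lags of 2 to 20 sampling intervals
#' (log-spaced), excluding both the shortest lags (discretization) and
#' long lags (poorly averaged).  The standard error comes from block
#' averaging: D_n is re-estimated on `n_blocks` contiguous segments.
#'
#' @param cc A `collective_coordinate`.
#' @param vw Volume of one water molecule, cm^3.
#' @param fit_window Integer lags (in sampling intervals) for the MSD
#'   fit; default `2:20` log-spaced.
#' @param n_blocks Number of blocks for the SE (>= 5 recommended).
#' @return A `pf_fit` object (also a `permeability_estimate`) with
#'   `value` (p_f, cm^3/s), `se`, `D_n` (1/ns) and the MSD table.
#' @export
osmotic_permeability <- function(cc, vw = water_molecule_volume(),
                                 fit_window = NULL, n_blocks = 5) {
  nf <- length(cc$n)
  if (is.null(fit_window)) {
    fit_window <- unique(round(exp(seq(log(2), log(20), length.out = 10))))
  }
  fit_window <- sort(unique(as.integer(fit_window)))
  if (any(fit_window <= 0)) stop("fit window lags must be positive")
  if (max(fit_window) * 10 > nf)
    stop("trajectory must span at least 10x the fit window")
  dt <- if (nf > 1) cc$times[2] - cc$times[1] else stop("empty coordinate")

  msd_of <- function(n) {
    vapply(fit_window, function(lag) {
      d <- n[(lag + 1):length(n)] - n[1:(length(n) - lag)]
      mean(d * d)
    }, 0)
  }
  tau <- fit_window * dt
  msd <- msd_of(cc$n)
  fit <- lm(msd ~ tau)
  D_n <- unname(coef(fit)[2]) / 2            # 1/ns
  pf <- vw * D_n * 1e9                       # cm^3/s

  bl <- floor(nf / n_blocks)
  Db <- vapply(seq_len(n_blocks), function(b) {
    seg <- cc$n[((b - 1) * bl + 1):(b * bl)]
    if (length(seg) <= max(fit_window)) return(NA_real_)
    m <- msd_of(seg)
    unname(coef(lm(m ~ tau))[2]) / 2
  }, 0)
  Db <- Db[is.finite(Db)]
  se <- if (length(Db) > 1) vw * sd(Db) / sqrt(length(Db)) * 1e9 else NA_real_

  structure(list(kind = "pf", value = pf, se = se, D_n = D_n,
                 vw = vw, msd = data.frame(tau = tau, msd = msd),
                 fit = fit, block_D = Db),
            class = c("pf_fit", "permeability_estimate"))
}

#' @export
coef.pf_fit <- function(object, ...) {
  c(D_n = object$D_n, pf = object$value)
}

#' @export
plot.pf_fit <- function(x, ...) {
  plot(x$msd$tau, x$msd$msd, xlab = "lag (ns)",
       ylab = expression(paste("MSD of n(t)")), ...)
  abline(x$fit, col = 2)
  invisible(x)
}

#' @export
summary.pf_fit <- function(object, ...) {
  cat(sprintf("Collective-diffusion osmotic permeability\n  D_n = %.4g /ns\n  p_f = %.4g +/- %.2g cm^3/s\n  MSD window: %d lags, %.4g .. %.4g ns\n",
              object$D_n, object$value, object$se, nrow(object$msd),
              min(object$msd$tau), max(object$msd$tau)))
  invisible(object)
}
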