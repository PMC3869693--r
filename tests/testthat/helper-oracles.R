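# Independent brute-force oracles used across the suite.  These
# re-implement the quantities under test from first principles (plain R
# loops, direct quadrature, exhaustive enumeration) and never call the
# code paths they check.

# Plain-R re-simulation of the single-file hopping chain with the same
# transition rules as the package simulator: grand-canonical buffer
# slots (insert p_ex*q / delete p_ex*(1-q)), random-order Metropolis
# vacancy hops, and the reversible full-column knock-on.  Tracks pore
# occupancy per step and complete buffer-to-buffer traversals.
oracle_hopping <- function(n_sites, q, p_hop, p_ex, p_push, n_steps,
                           burnin = 0, u_site = rep(0, n_sites)) {
  ntot <- n_sites + 2
  u <- c(0, u_site, 0)
  p_ins <- p_ex * q
  p_del <- p_ex * (1 - q)
  occ <- integer(ntot)
  prev <- integer(0)       # per id: last buffer side visited (-1/+1)
  nid <- 0L
  act <- q / (1 - q)
  for (i in seq_len(ntot)) {
    qi <- if (i == 1 || i == ntot) q else {
      a <- act * exp(-u[i]); a / (1 + a)
    }
    if (runif(1) < qi) {
      nid <- nid + 1L
      occ[i] <- nid
      prev[nid] <- if (i <= (ntot + 1) / 2) -1L else 1L
    }
  }
  arrive <- function(site, id) {
    side <- if (site == 1) -1L else 1L
    cr <- !is.na(prev[id]) && prev[id] == -side
    prev[id] <<- side
    cr
  }
  occ_trace <- integer(n_steps)
  crossings <- 0L
  for (step in seq_len(burnin + n_steps)) {
    for (b in c(1L, ntot)) {
      if (occ[b]) {
        if (runif(1) < p_del) occ[b] <- 0L
      } else if (runif(1) < p_ins) {
        nid <- nid + 1L
        occ[b] <- nid
        prev[nid] <- if (b == 1L) -1L else 1L
      }
    }
    for (s in sample.int(ntot)) {
      if (!occ[s] || runif(1) >= p_hop) next
      t <- s + sample(c(-1L, 1L), 1)
      if (t < 1L || t > ntot || occ[t]) next
      du <- u[t] - u[s]
      if (du <= 0 || runif(1) < exp(-du)) {
        occ[t] <- occ[s]
        occ[s] <- 0L
        if ((t == 1L || t == ntot) && arrive(t, occ[t]) &&
            step > burnin)
          crossings <- crossings + 1L
      }
    }
    for (b in 1:2) {
      if (runif(1) >= p_push) next
      buf <- if (b == 1) 1L else ntot
      far <- if (b == 1) ntot else 1L
      dir <- if (b == 1) 1L else -1L
      if (!occ[buf] || occ[far]) next
      if (any(occ[2:(ntot - 1)] == 0L)) next
      idx <- if (b == 1) seq(ntot, 2L) else seq(1L, ntot - 1L)
      for (i in idx) occ[i] <- occ[i - dir]
      occ[buf] <- 0L
      if (arrive(far, occ[far]) && step > burnin)
        crossings <- crossings + 1L
    }
    if (step > burnin)
      occ_trace[step - burnin] <- sum(occ[2:(ntot - 1)] > 0L)
  }
  list(occupancy = occ_trace, crossings = crossings)
}

# Exhaustive all-pairs hydrogen-bond evaluation (triple loop, no
# vectorization) matching the geometric criterion.
hb_oracle <- function(waters, criterion, partners = NULL) {
  m <- nrow(waters)
  ww <- integer(m)
  wp <- integer(m)
  dev <- function(d, h, a) {
    v1 <- h - d; v2 <- a - h
    acos(min(1, max(-1, sum(v1 * v2) /
                      sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
  }
  getO <- function(i) as.numeric(waters[i, c("ox", "oy", "oz")])
  getH <- function(i, k)
    as.numeric(waters[i, paste0("h", k, c("x", "y", "z"))])
  donates <- function(i, A) {
    min(dev(getO(i), getH(i, 1), A), dev(getO(i), getH(i, 2), A)) <=
      criterion$max_angle
  }
  if (m > 1) {
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      if (sqrt(sum((getO(i) - getO(j))^2)) > criterion$max_DA_distance)
        next
      if (donates(i, getO(j))) { ww[i] <- ww[i] + 1L; ww[j] <- ww[j] + 1L }
      if (donates(j, getO(i))) { ww[i] <- ww[i] + 1L; ww[j] <- ww[j] + 1L }
    }
  }
  if (!is.null(partners) && nrow(partners)) {
    for (i in seq_len(m)) for (p in seq_len(nrow(partners))) {
      P <- as.numeric(partners[p, c("x", "y", "z")])
      if (sqrt(sum((getO(i) - P)^2)) > criterion$max_DA_distance) next
      hit <- if (partners$role[p] == "donor") {
        dev(P, as.numeric(partners[p, c("hx", "hy", "hz")]), getO(i)) <=
          criterion$max_angle
      } else donates(i, P)
      if (hit) wp[i] <- wp[i] + 1L
    }
  }
  list(water_water = ww, water_partner = wp)
}

# Quick trajectory constructor from per-molecule z paths on a common
# time grid.  `paths` is a named list id -> numeric z (NA = absent).
make_traj <- function(times, paths) {
  recs <- list()
  for (k in seq_along(paths)) {
    z <- paths[[k]]
    keep <- which(!is.na(z))
    recs[[k]] <- data.frame(frame = keep, id = k, x = 0, y = 0,
                            z = z[keep])
  }
  trajectory_set(times, do.call(rbind, recs))
}

# Bin-averaged Boltzmann reference for a potential U(z) in kcal/mol.
boltzmann_bin_W <- function(U, edges, temperature = 300) {
  kT <- 0.0019872 * temperature
  vapply(seq_len(length(edges) - 1), function(i) {
    -kT * log(stats::integrate(function(z) exp(-U(z) / kT), edges[i],
                               edges[i + 1])$value /
                (edges[i + 1] - edges[i]))
  }, 0)
}

# Shared geometry for the synthetic UT-B-like pore.
pore_geom <- function(n_monomers = 1)
  channel_geometry(z_lumen = c(-0.7, 0.7), n_monomers = n_monomers)
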