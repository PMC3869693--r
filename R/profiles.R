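#' Construct an axial profile
#'
#' Per-bin values along the pore axis: density ratio n(z), PMF W(z),
#' dipole order parameter, or mean hydrogen-bond count.
#'
#' @param bin_edges Bin boundaries, nm (length = bins + 1).
#' @param values Per-bin values; `NA` marks masked bins.
#' @param counts Observations per bin.
#' @param sd Per-bin standard deviation (optional).
#' @param kind Label: `"density"`, `"pmf"`, `"order"` or `"hbond"`.
#' @return An object of class `axial_profile`.
#' @export
axial_profile <- function(bin_edges, values, counts,
                          sd = rep(NA_real_, length(values)),
                          kind = "density") {
  if (length(values) != length(bin_edges) - 1L)
    stop("length(values) must equal length(bin_edges) - 1")
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(bin_edges = as.numeric(bin_edges),
                 mid = (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2,
                 values = as.numeric(values), counts = counts,
                 sd = as.numeric(sd), kind = kind),
            class = "axial_profile")
}

#' @export
print.axial_profile <- function(x, ...) {
  cat(sprintf("Axial profile (%s): %d bins over [%.3g, %.3g] nm\n",
              x$kind, length(x$values), min(x$bin_edges), max(x$bin_edges)))
  ok <- is.finite(x$values)
  if (any(ok))
    cat(sprintf("  value range: %.4g .. %.4g (%d masked bins)\n",
                min(x$values[ok]), max(x$values[ok]), sum(!ok)))
  invisible(x)
}

#' @export
plot.axial_profile <- function(x, ...) {
  ylab <- switch(x$kind, density = "n(z)", pmf = "W(z) (kcal/mol)",
                 order = expression(paste("<cos ", theta, ">")),
                 hbond = "H-bonds per water", x$kind)
  plot(x$mid, x$values, type = "b", xlab = "z (nm)", ylab = ylab, ...)
  invisible(x)
}

#' Export an axial profile as a delimited table
#'
#' @param profile An `axial_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  write.table(data.frame(z_mid = profile$mid, value = profile$values,
                         sd = profile$sd, count = profile$counts),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

profile_bins <- function(geom, bin_width, z_range) {
  if (is.null(z_range)) z_range <- geom$z_lumen
  nb <- max(1L, round(diff(z_range) / bin_width))
  seq(z_range[1], z_range[2], length.out = nb + 1L)
}

#' Axial water density normalized to bulk
#'
#' Histogram of water z positions converted to a number density using
#' the local pore cross-section, `rho(z) = counts / (n_frames Lx(z)
#' Ly(z) dz)`, then normalized by the bulk density:
#' `n(z) = rho(z) / rho_bulk`.  The default bulk density is the TIP3P
#' water value, 33.37 molecules/nm^3 (0.997 g/cm^3).
#'
#' @param traj A `trajectory_set`.
#' @param geom A [channel_geometry()] providing the cross-section.
#' @param bin_width Bin width, nm.
#' @param bulk_density Bulk number density, molecules/nm^3.
#' @param z_range Axial range to profile; default the lumen.
#' @return An `axial_profile` of kind `"density"`.
#' @export
axial_density <- function(traj, geom, bin_width = 0.05,
                          bulk_density = 33.37, z_range = NULL) {
  if (bin_width <= 0) stop("bin_width must be positive")
  edges <- profile_bins(geom, bin_width, z_range)
  nf <- length(traj$times)
  if (nf == 0) stop("empty trajectory")
  z <- traj$coords$z
  cnt <- as.vector(table(cut(z, edges, include.lowest = TRUE)))
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  area <- cross_section_area(geom, mid)
  if (any(area <= 0)) stop("zero cross-section in profiled region")
  rho <- cnt / (nf * area * diff(edges))
  axial_profile(edges, rho / bulk_density, counts = cnt, kind = "density")
}

#' Potential of mean force by Boltzmann inversion
#'
#' `W(z) = -kB T ln n(z)` in kcal/mol from a bulk-normalized density
#' profile.  Zero-count bins are masked (`NA`), never imputed, so
#' downstream barrier extraction cannot propagate infinities.  The
#' profile is shifted so that its minimum over a reference region
#' (bulk/vestibule, default |z| >= 0.9 nm) is zero; when no profiled
#' bin lies in the reference region the global minimum is used.
#'
#' @param profile An `axial_profile` of kind `"density"`.
#' @param temperature K.
#' @param reference_region Pair `c(a, b)`: bins with `a <= |z| <= b`
#'   anchor the zero of the PMF.
#' @return An `axial_profile` of kind `"pmf"` (kcal/mol).
#' @export
pmf_from_density <- function(profile, temperature = 300,
                             reference_region = c(0.9, Inf)) {
  if (profile$kind != "density")
    stop("pmf_from_density expects a density profile")
  n <- profile$values
  if (any(n < 0, na.rm = TRUE)) stop("negative densities")
  kT <- .kB * temperature
  w <- ifelse(profile$counts > 0 & n > 0, -kT * log(n), NA_real_)
  ref <- abs(profile$mid) >= reference_region[1] &
    abs(profile$mid) <= reference_region[2] & is.finite(w)
  shift <- if (any(ref)) min(w[ref]) else min(w, na.rm = TRUE)
  axial_profile(profile$bin_edges, w - shift, counts = profile$counts,
                kind = "pmf")
}

#' Barrier height from a PMF profile
#'
#' Maximum of the PMF inside `region` minus its minimum inside
#' `reference`, both restricted to unmasked bins.
#'
#' @param pmf An `axial_profile` of kind `"pmf"`.
#' @param region Pair `c(z_low, z_high)` for the barrier search.
#' @param reference Pair for the reference minimum; default the whole
#'   profiled range.
#' @return Barrier height in kcal/mol.
#' @export
barrier_height <- function(pmf, region = NULL, reference = NULL) {
  if (pmf$kind != "pmf") stop("barrier_height expects a pmf profile")
  mid <- pmf$mid; w <- pmf$values
  in_region <- if (is.null(region)) rep(TRUE, length(mid)) else
    mid >= region[1] & mid <= region[2]
  in_ref <- if (is.null(reference)) rep(TRUE, length(mid)) else
    mid >= reference[1] & mid <= reference[2]
  in_region <- in_region & is.finite(w)
  in_ref <- in_ref & is.finite(w)
  if (!any(in_region)) stop("barrier region is fully masked")
  if (!any(in_ref)) stop("reference region is fully masked")
  max(w[in_region]) - min(w[in_ref])
}

#' Water dipole order parameter along the pore
#'
#' Per-bin mean and SD of `cos(theta) = u . z_hat`, the cosine of the
#' angle between the water dipole moment and the pore axis.  A sign
#' reversal across the pore centre signals the dipole reorientation
#' that underlies proton exclusion; values near zero in the vestibules
#' indicate free rotation.
#'
#' @param traj A `trajectory_set` carrying unit dipole vectors.
#' @param geom A [channel_geometry()].
#' @param bin_width Bin width, nm.
#' @param z_range Axial range to profile; default the lumen.
#' @return An `axial_profile` of kind `"order"`.
#' @export
dipole_order_parameter <- function(traj, geom, bin_width = 0.05,
                                   z_range = NULL) {
  if (!isTRUE(traj$has_dipoles))
    stop("trajectory carries no dipole vectors")
  edges <- profile_bins(geom, bin_width, z_range)
  co <- traj$coords
  bin <- cut(co$z, edges, include.lowest = TRUE)
  mval <- tapply(co$uz, bin, mean)
  sval <- tapply(co$uz, bin, sd)
  cnt <- as.vector(table(bin))
  axial_profile(edges, as.vector(mval), counts = cnt,
                sd = as.vector(sval), kind = "order")
}

#' Mean lumen occupancy and crossing time
#'
#' Occupancy is the time-averaged number of waters whose z lies within
#' the lumen, per monomer; the crossing time is the mean
#' `t_exit - t_enter` over complete translocations (reported as `NA`
#' when there are none).
#'
#' @param traj A `trajectory_set`.
#' @param geom A [channel_geometry()].
#' @param events Optional `permeation_events` (computed if missing).
#' @return List with `occupancy` and `crossing_time_ns`.
#' @export
occupancy_and_crossing <- function(traj, geom, events = NULL) {
  nf <- length(traj$times)
  if (nf == 0) stop("empty trajectory")
  z <- traj$coords$z
  occ <- sum(z >= geom$z_lumen[1] & z <= geom$z_lumen[2]) /
    (nf * geom$n_monomers)
  if (is.null(events)) events <- detect_events(traj, geom)
  ct <- if (nrow(events$events)) {
    mean(events$events$t_exit - events$events$t_enter)
  } else NA_real_
  list(occupancy = occ, crossing_time_ns = ct)
}
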