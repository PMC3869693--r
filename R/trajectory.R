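#' Construct a trajectory set
#'
#' The central trajectory container: time-ordered positions of water
#' molecules in a channel-aligned coordinate frame (z along the pore
#' axis, positive towards the extracellular side, pore centre at z = 0).
#' Molecules may appear and disappear between frames (reservoir
#' exchange); identities are carried by `id`.
#'
#' @param times Numeric vector of frame times in ns, strictly increasing.
#' @param coords Data frame with columns `frame` (1-based frame index),
#'   `id` (molecule identifier, unique within a frame), `x`, `y`, `z`
#'   (nm), and optionally `ux`, `uy`, `uz` (unit dipole vector).
#' @param box Optional periodic box lengths `c(Lx, Ly, Lz)` in nm, or
#'   `NULL` for non-periodic data.
#' @return An object of class `trajectory_set`.
#' @export
trajectory_set <- function(times, coords, box = NULL) {
  times <- as.numeric(times)
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  need <- c("frame", "id", "x", "y", "z")
  if (!all(need %in% names(coords)))
    stop("coords must have columns frame, id, x, y, z")
  coords <- as.data.frame(coords)
  if (nrow(coords)) {
    if (any(coords$frame < 1L | coords$frame > length(times)))
      stop("coords$frame outside 1..length(times)")
    key <- coords$frame * (max(coords$id) + 1) + coords$id
    if (anyDuplicated(key))
      stop("duplicate molecule_id within a frame")
  }
  has_dip <- all(c("ux", "uy", "uz") %in% names(coords))
  if (has_dip && nrow(coords)) {
    nrm <- sqrt(coords$ux^2 + coords$uy^2 + coords$uz^2)
    if (any(abs(nrm - 1) > 1e-6))
      stop("dipole vectors must have unit norm (within 1e-6)")
  }
  structure(list(times = times, coords = coords, box = box,
                 has_dipoles = has_dip),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat("Trajectory set:", length(x$times), "frames,",
      length(unique(x$coords$id)), "molecules,",
      nrow(x$coords), "records\n")
  if (length(x$times))
    cat(sprintf("  time span: %.4g .. %.4g ns\n",
                x$times[1], x$times[length(x$times)]))
  if (!is.null(x$box))
    cat("  periodic box:", paste(signif(x$box, 4), collapse = " x "), "nm\n")
  if (isTRUE(x$has_dipoles)) cat("  dipole vectors present\n")
  invisible(x)
}

#' @export
plot.trajectory_set <- function(x, n_molecules = 8, ...) {
  ids <- unique(x$coords$id)
  ids <- head(ids, n_molecules)
  sub <- x$coords[x$coords$id %in% ids, ]
  plot(NA, xlim = range(x$times), ylim = range(sub$z),
       xlab = "time (ns)", ylab = "z (nm)", ...)
  for (i in seq_along(ids)) {
    s <- sub[sub$id == ids[i], ]
    lines(x$times[s$frame], s$z, col = i)
  }
  invisible(x)
}

#' Channel geometry description
#'
#' Axial extent of the pore lumen, the entry/exit planes used for
#' translocation counting, the pore cross-section, and the number of
#' conducting monomers.  Defaults describe a UT-B-like single-file pore:
#' a 1.4 nm lumen centred at z = 0 spanning the S_i, S_m and S_0 regions
#' (-0.7 to +0.7 nm) with event planes pushed 0.05 nm outward as a
#' hysteresis guard against boundary chatter.
#'
#' @param z_lumen Pair `c(z_low, z_high)` in nm: full lumen span used
#'   for occupancy, density and PMF statistics.
#' @param z_event Pair of entry/exit planes for event counting; default
#'   the lumen extended by `hysteresis` on each side.
#' @param cross_section Either a constant pair `c(Lx, Ly)` in nm or a
#'   data frame with columns `z`, `Lx`, `Ly` tabulating the pore size.
#' @param n_monomers Number of conducting monomers sharing the
#'   trajectory (integer >= 1).
#' @param hysteresis Outward extension of the event planes, nm.
#' @return An object of class `channel_geometry`.
#' @export
channel_geometry <- function(z_lumen = c(-0.7, 0.7), z_event = NULL,
                             cross_section = c(0.442, 0.442),
                             n_monomers = 1L, hysteresis = 0.05) {
  z_lumen <- as.numeric(z_lumen)
  if (length(z_lumen) != 2L || z_lumen[1] >= z_lumen[2])
    stop("z_lumen must be an ordered pair")
  if (is.null(z_event))
    z_event <- z_lumen + c(-1, 1) * hysteresis
  z_event <- as.numeric(z_event)
  if (length(z_event) != 2L || z_event[1] >= z_event[2])
    stop("z_event must be an ordered pair")
  if (is.data.frame(cross_section)) {
    if (!all(c("z", "Lx", "Ly") %in% names(cross_section)))
      stop("cross_section table needs columns z, Lx, Ly")
    if (any(cross_section$Lx <= 0) || any(cross_section$Ly <= 0))
      stop("cross-section dimensions must be positive")
  } else {
    cross_section <- as.numeric(cross_section)
    if (length(cross_section) != 2L || any(cross_section <= 0))
      stop("constant cross_section must be a positive pair c(Lx, Ly)")
  }
  n_monomers <- as.integer(n_monomers)
  if (n_monomers < 1L) stop("n_monomers must be >= 1")
  structure(list(z_lumen = z_lumen, z_event = z_event,
                 cross_section = cross_section, n_monomers = n_monomers),
            class = "channel_geometry")
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf("Channel geometry: lumen [%.3g, %.3g] nm, event planes [%.3g, %.3g] nm, %d monomer(s)\n",
              x$z_lumen[1], x$z_lumen[2], x$z_event[1], x$z_event[2],
              x$n_monomers))
  invisible(x)
}

# Cross-section area Lx*Ly (nm^2) at axial positions z.
cross_section_area <- function(geom, z) {
  cs <- geom$cross_section
  if (is.data.frame(cs)) {
    lx <- approx(cs$z, cs$Lx, xout = z, rule = 2)$y
    ly <- approx(cs$z, cs$Ly, xout = z, rule = 2)$y
    lx * ly
  } else {
    rep(cs[1] * cs[2], length(z))
  }
}

#' Write a trajectory to disk
#'
#' Two plain-text formats are supported.  `"table"` is the lossless
#' format: a whitespace-delimited table with columns `frame id time x y
#' z` (plus `ux uy uz` when dipoles are present).  `"xyz"` is standard
#' XYZ (count line, comment line with `time=`, then `W x y z` rows);
#' XYZ carries no molecule identities, so ids are regenerated from row
#' order on reading and the format is unsuitable for event counting.
#'
#' @param traj A `trajectory_set`.
#' @param path Output file path.
#' @param format `"table"` or `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("table", "xyz")) {
  format <- match.arg(format)
  co <- traj$coords
  if (format == "table") {
    df <- data.frame(frame = co$frame, id = co$id,
                     time = traj$times[co$frame],
                     x = co$x, y = co$y, z = co$z)
    if (isTRUE(traj$has_dipoles)) {
      df$ux <- co$ux; df$uy <- co$uy; df$uz <- co$uz
    }
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(names(df), collapse = "\t"), con)
    if (nrow(df)) {
      fmt <- df
      for (nm in setdiff(names(fmt), c("frame", "id")))
        fmt[[nm]] <- sprintf("%.6f", fmt[[nm]])
      writeLines(do.call(paste, c(unname(fmt), sep = "\t")), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (f in seq_along(traj$times)) {
      rows <- co[co$frame == f, ]
      writeLines(as.character(nrow(rows)), con)
      writeLines(sprintf("time=%.6f", traj$times[f]), con)
      if (nrow(rows))
        writeLines(sprintf("W %.6f %.6f %.6f", rows$x, rows$y, rows$z), con)
    }
  }
  invisible(path)
}

#' Read a trajectory from disk
#'
#' Counterpart of [write_trajectory()].  The table format restores
#' molecule identities and frame times; the XYZ format assigns ids by
#' row order within each frame.  A zero-frame file yields an empty
#' `trajectory_set`.
#'
#' @param path Input file path.
#' @param format `"auto"` (by extension), `"table"` or `"xyz"`.
#' @param box Optional periodic box to attach, `c(Lx, Ly, Lz)` nm.
#' @return A `trajectory_set`.
#' @export
read_trajectory <- function(path, format = c("auto", "table", "xyz"),
                            box = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "table"
  if (format == "table") {
    df <- read.table(path, header = TRUE)
    if (!nrow(df))
      return(trajectory_set(numeric(0),
                            data.frame(frame = integer(0), id = integer(0),
                                       x = numeric(0), y = numeric(0),
                                       z = numeric(0)), box = box))
    need <- c("frame", "id", "x", "y", "z")
    if (!all(need %in% names(df)))
      stop("trajectory table must have columns frame, id, x, y, z")
    frames <- sort(unique(df$frame))
    if ("time" %in% names(df)) {
      times <- vapply(frames, function(f) df$time[match(f, df$frame)], 0)
    } else {
      times <- as.numeric(frames)
    }
    df$frame <- match(df$frame, frames)
    keep <- intersect(c("frame", "id", "x", "y", "z", "ux", "uy", "uz"),
                      names(df))
    trajectory_set(times, df[keep], box = box)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    times <- numeric(0)
    recs <- list()
    i <- 1L; f <- 0L
    while (i <= length(lines)) {
      n <- suppressWarnings(as.integer(trimws(lines[i])))
      if (is.na(n)) stop(sprintf("xyz parse error at line %d: bad count", i))
      if (i + 1L > length(lines)) stop("xyz file truncated at comment line")
      f <- f + 1L
      cm <- lines[i + 1L]
      t <- suppressWarnings(as.numeric(sub(".*time=([0-9eE.+-]+).*", "\\1", cm)))
      times <- c(times, if (is.na(t)) f else t)
      if (n > 0) {
        if (i + 1L + n > length(lines))
          stop(sprintf("xyz frame %d is ragged: expected %d atom rows", f, n))
        block <- lines[(i + 2L):(i + 1L + n)]
        parts <- do.call(rbind, strsplit(trimws(block), "[[:space:]]+"))
        if (ncol(parts) < 4)
          stop(sprintf("xyz frame %d is ragged: need element + 3 coordinates", f))
        recs[[f]] <- data.frame(frame = f, id = seq_len(n),
                                x = as.numeric(parts[, 2]),
                                y = as.numeric(parts[, 3]),
                                z = as.numeric(parts[, 4]))
      } else {
        recs[[f]] <- data.frame(frame = integer(0), id = integer(0),
                                x = numeric(0), y = numeric(0), z = numeric(0))
      }
      i <- i + 2L + n
    }
    coords <- if (length(recs)) do.call(rbind, recs) else
      data.frame(frame = integer(0), id = integer(0),
                 x = numeric(0), y = numeric(0), z = numeric(0))
    trajectory_set(times, coords, box = box)
  }
}

#' Unwrap periodic z coordinates along the pore axis
#'
#' Applies minimum-image unwrapping to each molecule's z displacement
#' between consecutive frames so that translocation paths are
#' continuous, then optionally re-centres z.  Non-periodic input (no
#' box) is returned unchanged.  A molecule absent for one or more
#' frames has its unwrapping restarted at the gap (with a warning),
#' since the minimum-image correction is only valid frame to frame.
#'
#' @param traj A `trajectory_set`.
#' @param box Periodic box `c(Lx, Ly, Lz)` nm; defaults to `traj$box`.
#' @param recenter Optional z offset to subtract (e.g. the pore
#'   midpoint) so that the pore centre sits at z = 0.
#' @return A `trajectory_set` with continuous per-molecule z paths.
#' @export
wrap_to_axis <- function(traj, box = traj$box, recenter = NULL) {
  co <- traj$coords
  if (!is.null(box)) {
    Lz <- box[3]
    if (any(box <= 0)) stop("box lengths must be positive")
    o <- order(co$id, co$frame)
    z <- co$z[o]; id <- co$id[o]; fr <- co$frame[o]
    n <- length(z)
    if (n > 1) {
      same <- id[-1] == id[-n]
      gap <- same & (fr[-1] - fr[-n] > 1L)
      if (any(gap))
        warning(sprintf("%d molecule frame gap(s); unwrapping restarted there",
                        sum(gap)))
      dz <- z[-1] - z[-n]
      corr <- ifelse(same & !gap, -Lz * round(dz / Lz), 0)
      # cumulative correction, reset at each new molecule or gap
      grp <- cumsum(c(TRUE, !(same & !gap)))
      ccorr <- c(0, corr)
      ccorr <- ave(ccorr, grp, FUN = cumsum)
      z <- z + ccorr
    }
    co$z[o] <- z
  }
  if (!is.null(recenter)) co$z <- co$z - recenter
  out <- traj
  out$coords <- co
  out
}
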