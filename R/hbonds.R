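#' Geometric hydrogen-bond criterion
#'
#' The de facto standard geometric criterion for trajectory analysis:
#' a donor-acceptor pair is hydrogen bonded when the donor-acceptor
#' heavy-atom distance is at most `max_DA_distance` and the D-H...A
#' arrangement deviates from linearity by at most `max_angle` (i.e.
#' the angle between the D->H and H->A directions).
#'
#' @param max_DA_distance Donor-acceptor cutoff, nm (default 0.35).
#' @param max_angle Maximum deviation from linearity, degrees
#'   (default 30; must lie in (0, 90)).
#' @return An object of class `hbond_criterion`.
#' @export
hbond_criterion <- function(max_DA_distance = 0.35, max_angle = 30) {
  if (max_DA_distance <= 0) stop("max_DA_distance must be positive")
  if (max_angle <= 0 || max_angle >= 90)
    stop("max_angle must lie in (0, 90) degrees")
  structure(list(max_DA_distance = max_DA_distance, max_angle = max_angle),
            class = "hbond_criterion")
}

# Deviation from linearity (degrees) of D-H...A for row-matched
# coordinate matrices d, h, a (n x 3).
hb_deviation <- function(d, h, a) {
  v1 <- h - d
  v2 <- a - h
  n1 <- sqrt(rowSums(v1 * v1))
  n2 <- sqrt(rowSums(v2 * v2))
  cosang <- rowSums(v1 * v2) / (n1 * n2)
  cosang <- pmin(1, pmax(-1, cosang))
  acos(cosang) * 180 / pi
}

#' Count hydrogen bonds in one configuration of waters
#'
#' Exhaustive pair evaluation for a single frame of water molecules,
#' each given by an oxygen position and two hydrogen positions.  A
#' directed bond i -> j exists when the O_i - O_j distance passes the
#' cutoff and either hydrogen of i satisfies the linearity criterion
#' towards O_j.  The returned per-water count is the number of bonds
#' each molecule participates in (as donor or acceptor), so a single
#' bond contributes one to both partners.
#'
#' Optionally a static table of external partner sites (e.g.
#' pore-lining protein atoms) is scanned as well: partner donors
#' (with their own hydrogen coordinates) donate to the water oxygen,
#' and water hydrogens donate to partner acceptors.
#'
#' @param waters Data frame with columns `ox, oy, oz, h1x, h1y, h1z,
#'   h2x, h2y, h2z` (nm), one row per water.
#' @param criterion An [hbond_criterion()].
#' @param partners Optional data frame with columns `x, y, z`, `role`
#'   (`"donor"` or `"acceptor"`), and `hx, hy, hz` for donors.
#' @return List with `water_water` and `water_partner`: integer bond
#'   participation counts per water.
#' @export
count_hbonds <- function(waters, criterion = hbond_criterion(),
                         partners = NULL) {
  m <- nrow(waters)
  ww <- integer(m)
  wp <- integer(m)
  O <- as.matrix(waters[, c("ox", "oy", "oz")])
  H1 <- as.matrix(waters[, c("h1x", "h1y", "h1z")])
  H2 <- as.matrix(waters[, c("h2x", "h2y", "h2z")])
  if (m > 1) {
    dx <- outer(O[, 1], O[, 1], "-")
    dy <- outer(O[, 2], O[, 2], "-")
    dz <- outer(O[, 3], O[, 3], "-")
    dd <- sqrt(dx^2 + dy^2 + dz^2)
    cand <- which(upper.tri(dd) & dd <= criterion$max_DA_distance,
                  arr.ind = TRUE)
    if (nrow(cand)) {
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        # i donates to j
        dev_ij <- hb_deviation(rbind(O[i, ], O[i, ]),
                               rbind(H1[i, ], H2[i, ]),
                               rbind(O[j, ], O[j, ]))
        if (min(dev_ij) <= criterion$max_angle) {
          ww[i] <- ww[i] + 1L
          ww[j] <- ww[j] + 1L
        }
        # j donates to i
        dev_ji <- hb_deviation(rbind(O[j, ], O[j, ]),
                               rbind(H1[j, ], H2[j, ]),
                               rbind(O[i, ], O[i, ]))
        if (min(dev_ji) <= criterion$max_angle) {
          ww[i] <- ww[i] + 1L
          ww[j] <- ww[j] + 1L
        }
      }
    }
  }
  if (!is.null(partners) && nrow(partners) && m > 0) {
    P <- as.matrix(partners[, c("x", "y", "z")])
    is_don <- partners$role == "donor"
    for (i in seq_len(m)) {
      d <- sqrt(colSums((t(P) - O[i, ])^2))
      near <- which(d <= criterion$max_DA_distance)
      for (p in near) {
        if (is_don[p]) {
          hp <- as.numeric(partners[p, c("hx", "hy", "hz")])
          dev <- hb_deviation(rbind(P[p, ]), rbind(hp), rbind(O[i, ]))
        } else {
          dev <- min(hb_deviation(rbind(O[i, ], O[i, ]),
                                  rbind(H1[i, ], H2[i, ]),
                                  rbind(P[p, ], P[p, ])))
        }
        if (min(dev) <= criterion$max_angle) wp[i] <- wp[i] + 1L
      }
    }
  }
  list(water_water = ww, water_partner = wp)
}

#' Hydrogen-bond profiles along the pore
#'
#' Counts, frame by frame, the hydrogen bonds each water participates
#' in (water-water, and optionally water-partner against a static site
#' table), then bins the per-water counts by the water oxygen z
#' coordinate.  This mirrors the familiar picture for single-file
#' pores: ~3 bonds per water in the vestibules, dropping in the
#' selectivity region where pore-lining partners replace waters.
#'
#' @param waters Data frame with columns `frame`, `ox, oy, oz,
#'   h1x..h2z` (nm); one row per water observation.
#' @param geom A [channel_geometry()].
#' @param criterion An [hbond_criterion()].
#' @param partners Optional partner-site table (see [count_hbonds()]).
#' @param bin_width Bin width, nm.
#' @param z_range Axial range; default the lumen.
#' @return List of `axial_profile`s: `water_water` and (when partners
#'   are given) `water_partner`.
#' @export
hbond_profile <- function(waters, geom, criterion = hbond_criterion(),
                          partners = NULL, bin_width = 0.05,
                          z_range = NULL) {
  edges <- profile_bins(geom, bin_width, z_range)
  frames <- unique(waters$frame)
  zs <- numeric(0); cw <- integer(0); cp <- integer(0)
  for (f in frames) {
    w <- waters[waters$frame == f, , drop = FALSE]
    res <- count_hbonds(w, criterion, partners)
    zs <- c(zs, w$oz)
    cw <- c(cw, res$water_water)
    cp <- c(cp, res$water_partner)
  }
  bin <- cut(zs, edges, include.lowest = TRUE)
  prof <- function(v) {
    axial_profile(edges, as.vector(tapply(v, bin, mean)),
                  counts = as.vector(table(bin)),
                  sd = as.vector(tapply(v, bin, sd)), kind = "hbond")
  }
  out <- list(water_water = prof(cw))
  if (!is.null(partners)) out$water_partner <- prof(cp)
  out
}
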