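# Selectivity-filter state: S0-S4 site geometry from the oxygen-ring
# planes, per-frame occupancy (ion / water / vacant), and carbonyl
# flips.

SF_PLANE_ROLES <- c("T_OG1", "T_O", "V_O", "G1_O", "Y_O", "G2_O")
SF_SITE_NAMES <- c("Scav", "S4", "S3", "S2", "S1", "S0")

#' Selectivity-filter site geometry for one frame
#'
#' The filter's oxygen rings (threonine hydroxyl, then the four
#' backbone carbonyl rings of TVGYG) define five contiguous cages:
#' S4 = \[T_OG1, T_O\], S3 = \[T_O, V_O\], S2 = \[V_O, G1_O\],
#' S1 = \[G1_O, Y_O\], S0 = \[Y_O, G2_O\], plus the cavity vestibule
#' Scav = \[T_OG1 - w_cav, T_OG1\].  Plane z is the subunit mean of the
#' ring-atom z.  A frame whose planes are not strictly increasing is
#' flagged (distorted filter) rather than raising.
#'
#' @param frame atoms x 3 coordinate matrix (nm).
#' @param annotation [channel_annotation].
#' @param w_cav width of the cavity vestibule below the filter, nm.
#' @param r_site radial cutoff from the pore axis for site membership,
#'   nm.
#' @return object of class `site_geometry`: `planes` (named z of the 6
#'   oxygen planes), `sites` (2-column matrix of \[lo, hi) intervals,
#'   rows Scav, S4..S0), `axis_xy`, `r_site`, `valid`.
#' @export
site_boundaries <- function(frame, annotation, w_cav = 0.4, r_site = 0.35) {
  planes <- vapply(SF_PLANE_ROLES, function(role)
    mean(frame[role_indices(annotation, role), 3]), 0)
  ox <- unlist(annotation$roles[SF_PLANE_ROLES])
  axis_xy <- colMeans(frame[ox, 1:2, drop = FALSE])
  valid <- all(diff(planes) > 0)
  lo <- c(planes[1] - w_cav, planes[-length(planes)])
  hi <- planes
  sites <- cbind(lo = unname(lo), hi = unname(hi))
  rownames(sites) <- SF_SITE_NAMES
  structure(list(planes = planes, sites = sites, axis_xy = axis_xy,
                 r_site = r_site, valid = valid),
            class = "site_geometry")
}

# Particles (given indices) assigned to a site: z in [lo, hi) and
# within r_site of the axis.  Returns indices into `idx`.
particles_in_site <- function(frame, idx, geometry, site) {
  if (!length(idx)) return(integer())
  iv <- geometry$sites[site, ]
  z <- frame[idx, 3]
  r <- sqrt((frame[idx, 1] - geometry$axis_xy[1])^2 +
              (frame[idx, 2] - geometry$axis_xy[2])^2)
  which(z >= iv[1] & z < iv[2] & r < geometry$r_site)
}

#' Classify a filter site as ion, water or vacant
#'
#' A particle occupies the site if its z lies in the site interval and
#' it is within the radial cutoff of the pore axis.  If both an ion and
#' a water qualify, the particle closest to the site centre (interval
#' midpoint, on the axis) wins; an empty site is vacant.
#'
#' @param frame atoms x 3 coordinate matrix (nm).
#' @param geometry [site_boundaries()] result for the same frame.
#' @param site one of `"Scav"`, `"S4"` ... `"S0"`.
#' @param annotation [channel_annotation].
#' @return `"ion"`, `"water"` or `"vacant"`.
#' @export
classify_site <- function(frame, geometry, site, annotation) {
  centre <- c(geometry$axis_xy, mean(geometry$sites[site, ]))
  best <- "vacant"; best_d2 <- Inf
  for (sp in c("ion", "water")) {
    idx <- if (sp == "ion") annotation$ion_indices
           else annotation$water_oxygen_indices
    hit <- particles_in_site(frame, idx, geometry, site)
    if (length(hit)) {
      d2 <- rowSums(sweep(frame[idx[hit], , drop = FALSE], 2, centre)^2)
      if (min(d2) < best_d2) { best_d2 <- min(d2); best <- sp }
    }
  }
  best
}

# Per-frame site occupancy for one replica: character matrix
# frames x sites; invalid frames are NA rows.
replica_site_states <- function(rep, annotation, w_cav = 0.4,
                                r_site = 0.35, sites = SF_SITE_NAMES) {
  nf <- dim(rep$coords)[1]
  out <- matrix(NA_character_, nf, length(sites),
                dimnames = list(NULL, sites))
  for (f in seq_len(nf)) {
    frame <- rep$coords[f, , ]
    geom <- site_boundaries(frame, annotation, w_cav, r_site)
    if (!geom$valid) next
    for (s in sites) out[f, s] <- classify_site(frame, geom, s, annotation)
  }
  out
}

#' Site occupancy fractions with replica-bootstrap CIs
#'
#' For every filter site, the fractions of frames in which the site is
#' occupied by an ion, by water, or vacant.  Fractions sum to one by
#' construction.  Point estimates are means of the per-replica
#' fractions; CIs resample replicas ([bootstrap_ci()]).  Frames with a
#' non-monotonic (distorted) filter are excluded and counted in
#' `n_excluded`.
#'
#' @param ensemble annotated [trajectory_ensemble].
#' @param annotation optional [channel_annotation] override.
#' @param sites site names to report (default Scav plus S4..S0).
#' @param w_cav,r_site geometry parameters, nm.
#' @param level,n_boot,seed bootstrap CI parameters.
#' @return `data.table` with one row per site x species: `site`,
#'   `species`, `fraction`, `ci_low`, `ci_high`, `n_frames`,
#'   `n_excluded`.
#' @export
occupancy_table <- function(ensemble, annotation = NULL,
                            sites = SF_SITE_NAMES, w_cav = 0.4,
                            r_site = 0.35, level = 0.95, n_boot = 20000L,
                            seed = 0L) {
  ann <- if (!is.null(annotation)) annotation else ensemble$annotation
  if (is.null(ann)) stop("annotation error: ensemble is not annotated")
  per_rep <- lapply(ensemble$replicas, replica_site_states, annotation = ann,
                    w_cav = w_cav, r_site = r_site, sites = sites)
  nrep <- length(per_rep)
  n_excluded <- sum(vapply(per_rep, function(m) sum(is.na(m[, 1])), 0L))
  n_valid <- sum(vapply(per_rep, function(m) sum(!is.na(m[, 1])), 0L))
  if (n_valid == 0L) stop("empty result: all frames flagged as distorted")
  rows <- list()
  for (s in sites) {
    frac <- function(states, what) {
      v <- states[, s]; v <- v[!is.na(v)]
      if (!length(v)) return(NA_real_)
      mean(v == what)
    }
    for (what in c("ion", "water", "vacant")) {
      fr <- vapply(per_rep, frac, 0, what = what)
      fr <- fr[!is.na(fr)]
      ci <- if (length(fr) >= 2L) {
        b <- bootstrap_ci(fr, mean, n_boot = n_boot, level = level,
                          seed = seed)
        c(b$ci_low, b$ci_high)
      } else c(NA_real_, NA_real_)
      rows[[length(rows) + 1L]] <-
        data.table(site = s, species = what, fraction = mean(fr),
                   ci_low = ci[1], ci_high = ci[2], n_frames = n_valid,
                   n_excluded = n_excluded)
    }
  }
  rbindlist(rows)
}

#' Detect carbonyl flips of a filter residue
#'
#' A carbonyl is flipped in a frame when the angle between its C->O
#' vector and a per-subunit reference orientation exceeds
#' `theta_flip`.  The reference is the normalised component-wise median
#' C->O direction over the first replica.
#'
#' @param ensemble annotated [trajectory_ensemble].
#' @param annotation optional override.
#' @param role_c,role_o roles of the carbonyl C and O atoms (default
#'   the S3-forming valine carbonyl).
#' @param theta_flip flip threshold in degrees.
#' @return `data.table` (`replica`, `frame`, `subunit`, `angle`,
#'   `flipped`); attribute `flip_fraction` is the overall flipped
#'   fraction.
#' @export
detect_flips <- function(ensemble, annotation = NULL, role_c = "V_C",
                         role_o = "V_O", theta_flip = 90) {
  ann <- if (!is.null(annotation)) annotation else ensemble$annotation
  if (is.null(ann)) stop("annotation error: ensemble is not annotated")
  ic <- role_indices(ann, role_c); io <- role_indices(ann, role_o)
  nsub <- length(ic)
  unit_vecs <- function(rep, s) {
    v <- rep$coords[, io[s], ] - rep$coords[, ic[s], ]
    v <- matrix(v, ncol = 3L)
    v / sqrt(rowSums(v^2))
  }
  # reference orientation: median direction in the first replica
  ref <- lapply(seq_len(nsub), function(s) {
    u <- unit_vecs(ensemble$replicas[[1]], s)
    m <- apply(u, 2L, stats::median)
    m / sqrt(sum(m^2))
  })
  out <- rbindlist(lapply(seq_along(ensemble$replicas), function(r) {
    rep <- ensemble$replicas[[r]]
    nf <- dim(rep$coords)[1]
    rbindlist(lapply(seq_len(nsub), function(s) {
      u <- unit_vecs(rep, s)
      cosang <- pmin(1, pmax(-1, u %*% ref[[s]]))
      ang <- acos(cosang) * 180 / pi
      data.table(replica = r, frame = seq_len(nf), subunit = s,
                 angle = as.numeric(ang),
                 flipped = as.numeric(ang) > theta_flip)
    }))
  }))
  setattr(out, "flip_fraction", mean(out$flipped))
  out[]
}
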