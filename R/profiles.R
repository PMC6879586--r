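# Axial ion densities treated as approximate free-energy profiles
# (F = -ln rho / rho_max, kT), and HOLE-style pore radius profiles.

#' Gaussian kernel density / free-energy profile along the pore axis
#'
#' Gaussian KDE of axial positions on a grid, normalised to integrate
#' to one over the grid (trapezoid rule), with
#' `F = -ln(density / max density)` so the global minimum sits at 0 kT.
#' The automatic bandwidth is Scott's rule, `sd(z) * n^(-1/5)`.
#'
#' @param z_samples axial sample positions, nm (>= 2 values).
#' @param grid evaluation grid covering the sample range, nm.
#' @param bandwidth `"auto"` (Scott) or a fixed value in nm.
#' @return object of class `free_energy_profile`: `data.table` with
#'   columns `z`, `density` (1/nm), `F` (kT); attributes `bandwidth`
#'   and `n_samples`.
#' @export
kde_profile <- function(z_samples, grid, bandwidth = "auto") {
  z_samples <- as.numeric(z_samples)
  n <- length(z_samples)
  if (n < 2L) stop("kde_profile() needs at least 2 samples")
  bw <- if (identical(bandwidth, "auto"))
    stats::sd(z_samples) * n^(-1 / 5) else as.numeric(bandwidth)
  if (!is.finite(bw) || bw <= 0) stop("invalid bandwidth")
  dens <- numeric(length(grid))
  # chunk the sample axis to bound memory on large n
  chunk <- max(1L, floor(5e6 / length(grid)))
  for (i0 in seq(1L, n, by = chunk)) {
    idx <- i0:min(n, i0 + chunk - 1L)
    dens <- dens + rowSums(stats::dnorm(outer(grid, z_samples[idx], "-"),
                                        sd = bw))
  }
  dens <- dens / n
  area <- trapz(grid, dens)
  if (area <= 0) stop("degenerate density (zero mass on grid)")
  dens <- dens / area
  F <- -log(dens / max(dens))
  out <- data.table(z = grid, density = dens, F = F)
  setattr(out, "bandwidth", bw)
  setattr(out, "n_samples", n)
  setattr(out, "class", c("free_energy_profile", class(out)))
  out[]
}

trapz <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1]) / 2)

#' Pointwise coverage-factor CI over replica profiles
#'
#' Half-width per grid point: Student-t quantile at `level` with
#' n_replicas - 1 degrees of freedom times the standard error of the
#' replica mean.
#'
#' @param per_replica_profiles replicas x grid matrix of profile values
#'   on a common grid.
#' @param level confidence level.
#' @return numeric vector of half-widths (one per grid point).
#' @export
profile_ci <- function(per_replica_profiles, level = 0.95) {
  m <- as.matrix(per_replica_profiles)
  n <- nrow(m)
  if (n < 2L) stop("profile_ci() needs at least 2 replicas")
  sem <- apply(m, 2L, stats::sd) / sqrt(n)
  stats::qt(1 - (1 - level) / 2, df = n - 1) * sem
}

#' Ensemble ion free-energy profile along the filter axis
#'
#' Collects ion z positions relative to the instantaneous T_OG1 plane
#' (removing channel drift), computes a per-replica KDE free-energy
#' profile, and averages F over replicas with a coverage-factor CI.
#' Only ions within `r_cut` of the pore axis and inside the z window
#' are collected.
#'
#' @param ensemble annotated [trajectory_ensemble].
#' @param grid z grid relative to the T_OG1 plane, nm.
#' @param bandwidth `"auto"` or fixed nm (a fixed bandwidth makes
#'   profiles comparable across opening levels).
#' @param r_cut radial cutoff, nm.
#' @param level CI level.
#' @return `data.table` `z`, `F` (replica-mean, min 0), `ci`
#'   (half-width), `density` (replica-mean); attribute
#'   `per_replica_F`.
#' @export
ion_density_profile <- function(ensemble, grid = seq(-0.6, 1.9, by = 0.01),
                                bandwidth = 0.03, r_cut = 0.6,
                                level = 0.95) {
  ann <- ensemble$annotation
  if (is.null(ann)) stop("annotation error: ensemble is not annotated")
  ion <- ann$ion_indices
  per_rep <- lapply(ensemble$replicas, function(rep) {
    nf <- dim(rep$coords)[1]
    b <- sf_bounds_from_annotation(rep, ann)
    axy <- pore_axis_xy(rep, ann)
    zrel <- sweep(matrix(rep$coords[, ion, 3], nrow = nf), 1, b$z_low)
    r <- sqrt((matrix(rep$coords[, ion, 1], nrow = nf) - axy[, 1])^2 +
                (matrix(rep$coords[, ion, 2], nrow = nf) - axy[, 2])^2)
    keep <- r < r_cut & zrel >= grid[1] & zrel <= grid[length(grid)]
    zrel[keep]
  })
  usable <- vapply(per_rep, length, 0L) >= 2L
  if (!any(usable)) stop("no ion samples inside the profile window")
  profs <- lapply(per_rep[usable], kde_profile, grid = grid,
                  bandwidth = bandwidth)
  Fmat <- do.call(rbind, lapply(profs, function(p) p$F))
  dmat <- do.call(rbind, lapply(profs, function(p) p$density))
  Fmean <- colMeans(Fmat); Fmean <- Fmean - min(Fmean)
  ci <- if (nrow(Fmat) >= 2L) profile_ci(Fmat, level) else rep(NA_real_,
                                                               ncol(Fmat))
  out <- data.table(z = grid, F = Fmean, ci = ci, density = colMeans(dmat))
  setattr(out, "per_replica_F", Fmat)
  out[]
}

#' Height of the barrier between two filter sites
#'
#' Max F over the boundary window minus min F over the upstream site
#' window (e.g. the S4/S3 barrier seen from S4).
#'
#' @param profile `data.table` with `z` and `F`.
#' @param site_window,z_boundary_window length-2 z ranges (nm).
#' @return barrier height in kT.
#' @export
barrier_height <- function(profile, site_window, z_boundary_window) {
  inb <- profile$z >= z_boundary_window[1] & profile$z <= z_boundary_window[2]
  ins <- profile$z >= site_window[1] & profile$z <= site_window[2]
  if (!any(inb) || !any(ins)) stop("windows fall outside the profile grid")
  max(profile$F[inb]) - min(profile$F[ins])
}

# ---------------------------------------------------------------------------
# Pore radius (HOLE-style)
# ---------------------------------------------------------------------------

#' Element-keyed van der Waals radii (nm)
#'
#' Element inferred from the first letter of the atom name.  The exact
#' table is a dialect choice; override entries via `table`.
#'
#' @param atom_names character vector of atom names.
#' @param table named radii in nm.
#' @export
vdw_radii <- function(atom_names,
                      table = c(H = 0.12, C = 0.17, N = 0.155, O = 0.152,
                                S = 0.18)) {
  el <- substr(gsub("^[0-9]+", "", atom_names), 1, 1)
  r <- unname(table[el])
  r[is.na(r)] <- 0.17
  r
}

#' HOLE-style pore radius profile
#'
#' Per z slice, the pore radius is the largest sphere centred on the
#' slice plane that touches no atom:
#' `max over c of min over atoms (|atom - (c, z)| - vdw)`, found by
#' multi-start Nelder-Mead seeded on the previous slice centre (plus
#' jittered starts), clipped to \[0, r_max\].
#'
#' @param frame atoms x 3 coordinate matrix, nm.
#' @param protein_atoms atom indices forming the pore wall.
#' @param vdw per-atom van der Waals radii, nm (recycled to the atom
#'   selection); see [vdw_radii()].
#' @param grid z grid, nm.
#' @param r_max cap for open space, nm.
#' @param axis_xy initial in-plane centre guess (default origin-of-mass
#'   of the selection).
#' @param n_starts extra jittered optimiser starts per slice.
#' @return object of class `pore_profile`: `data.table` with `z`,
#'   `radius`, `cx`, `cy`, `converged`.
#' @export
pore_radius_profile <- function(frame, protein_atoms, vdw, grid,
                                r_max = 1.5, axis_xy = NULL,
                                n_starts = 4L) {
  if (!length(protein_atoms)) {
    out <- data.table(z = grid, radius = r_max, cx = 0, cy = 0,
                      converged = TRUE)
    setattr(out, "class", c("pore_profile", class(out)))
    return(out[])
  }
  P <- frame[protein_atoms, , drop = FALSE]
  vdw <- rep_len(vdw, nrow(P))
  if (is.null(axis_xy)) axis_xy <- colMeans(P[, 1:2, drop = FALSE])
  prev <- axis_xy
  res <- vector("list", length(grid))
  for (k in seq_along(grid)) {
    zk <- grid[k]
    # atoms too far in z can never bound the sphere
    near <- abs(P[, 3] - zk) <= r_max + max(vdw) + 0.2
    if (!any(near)) {
      res[[k]] <- data.table(z = zk, radius = r_max, cx = prev[1],
                             cy = prev[2], converged = TRUE)
      next
    }
    A <- P[near, , drop = FALSE]; va <- vdw[near]
    clearance <- function(c2) {
      d <- sqrt((A[, 1] - c2[1])^2 + (A[, 2] - c2[2])^2 + (A[, 3] - zk)^2)
      min(d - va)
    }
    starts <- rbind(prev, axis_xy,
                    matrix(rep(prev, n_starts), ncol = 2, byrow = TRUE) +
                      matrix(stats::runif(2 * n_starts, -0.15, 0.15),
                             ncol = 2))
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      opt <- stats::optim(starts[s, ], function(c2) -clearance(c2),
                          method = "Nelder-Mead",
                          control = list(reltol = 1e-10, maxit = 500))
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    rad <- min(max(-best$value, 0), r_max)
    if (-best$value > 0 && -best$value < r_max) prev <- best$par
    res[[k]] <- data.table(z = zk, radius = rad, cx = best$par[1],
                           cy = best$par[2],
                           converged = best$convergence == 0L)
  }
  out <- rbindlist(res)
  setattr(out, "class", c("pore_profile", class(out)))
  out[]
}

#' Minimum-radius constriction report
#'
#' Locates the narrowest point of a pore profile and flags whether it
#' falls below the hydrated-K+ threshold radius.
#'
#' @param profile [pore_radius_profile()] result (needs `z`,
#'   `radius`).
#' @param threshold flag threshold, nm (0.4 nm is the conventional
#'   hydrated-K+ radius).
#' @return list `min_radius`, `z_min`, `below_threshold`.
#' @export
constriction_report <- function(profile, threshold = 0.4) {
  i <- which.min(profile$radius)
  list(min_radius = profile$radius[i], z_min = profile$z[i],
       below_threshold = profile$radius[i] < threshold)
}
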