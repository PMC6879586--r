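# Permeation-event counting and current estimation.  One completed
# filter traversal per elementary charge; 1 net crossing/ns = e/ns =
# 160.2176634 pA.

#' Elementary charge per nanosecond, in pA
#' @export
PA_PER_CROSSING_NS <- 160.2176634

#' Membrane voltage from an applied electric field
#'
#' In field-driven permeation simulations the voltage drop across the
#' periodic box is the applied field times the box length along the
#' field axis, `V = E * L_z`.
#'
#' @param E applied field, mV/nm.
#' @param L_z box length along z, nm (> 0).
#' @return voltage in mV.
#' @export
compute_voltage <- function(E, L_z) {
  if (any(L_z <= 0)) stop("L_z must be positive")
  E * L_z
}

#' Approximate salt molarity of a simulation box
#'
#' Quick solvent-ratio estimate: ion count over water count times the
#' molar concentration of pure water (55.345 mol/L), the standard way
#' of stating the salt concentration of a solvated MD system.
#'
#' @param n_water number of water molecules.
#' @param n_ion number of salt ion pairs (use the counter-ion count).
#' @return concentration in mol/L.
#' @export
salt_concentration <- function(n_water, n_ion) {
  if (n_water <= 0) stop("n_water must be positive")
  n_ion / n_water * 55.345
}

# Per-frame filter bounds from the annotation: bottom of the S4 cage
# (threonine OG1 hydroxyl ring) and top of S0 (outer glycine carbonyl
# ring).
sf_bounds_from_annotation <- function(replica, annotation) {
  lo_idx <- role_indices(annotation, "T_OG1")
  hi_idx <- role_indices(annotation, "G2_O")
  nf <- dim(replica$coords)[1]
  z_low <- rowMeans(matrix(replica$coords[, lo_idx, 3], nrow = nf))
  z_high <- rowMeans(matrix(replica$coords[, hi_idx, 3], nrow = nf))
  list(z_low = z_low, z_high = z_high)
}

# Per-frame pore axis (x, y) as the centroid of the filter oxygens.
pore_axis_xy <- function(replica, annotation) {
  ox <- unlist(annotation$roles[c("T_OG1", "T_O", "V_O", "G1_O", "Y_O", "G2_O")])
  nf <- dim(replica$coords)[1]
  cbind(rowMeans(matrix(replica$coords[, ox, 1], nrow = nf)),
        rowMeans(matrix(replica$coords[, ox, 2], nrow = nf)))
}

#' Count ion or water crossings of the selectivity filter
#'
#' Runs a hysteretic 3-state machine (below | inside | above) per
#' particle: an outward event completes when a particle last seen below
#' `z_low - delta` is later seen above `z_high + delta`; inward events
#' are the mirror image.  Consecutive-frame z jumps larger than half
#' the box are periodic wraps and never count.  With `radial_check`,
#' a traversal observed inside the bounds must pass within `r_cut` of
#' the pore axis; a direct below-to-above jump with no observed inside
#' frame still counts (sparse sampling).
#'
#' @param replica a [replica()].
#' @param annotation [channel_annotation] (used for default bounds,
#'   axis, and particle selection).
#' @param sf_bounds either NULL (per-frame bounds from the T_OG1 and
#'   G2_O oxygen rings) or `c(z_low, z_high)` in nm.
#' @param species `"ion"` or `"water"`.
#' @param delta hysteresis margin, nm.
#' @param radial_check require passage near the pore axis.
#' @param r_cut radial cutoff from the pore axis, nm.
#' @param replica_id id stored in the event table.
#' @return `data.table` of events: `particle` (atom index), `species`,
#'   `direction` (+1 outward, -1 inward), `entry_frame`,
#'   `completion_frame` (1-based), `replica`.  Attributes `first_side`
#'   and `last_side` give per-particle compartment bookkeeping.
#' @export
count_crossings <- function(replica, annotation, sf_bounds = NULL,
                            species = c("ion", "water"), delta = 0.1,
                            radial_check = TRUE, r_cut = 0.6,
                            replica_id = 1L) {
  species <- match.arg(species)
  idx <- if (species == "ion") annotation$ion_indices
         else annotation$water_oxygen_indices
  nf <- dim(replica$coords)[1]
  if (!length(idx))
    return(empty_event_table())
  z <- matrix(replica$coords[, idx, 3], nrow = nf)
  if (is.null(sf_bounds)) {
    b <- sf_bounds_from_annotation(replica, annotation)
    z_low <- b$z_low; z_high <- b$z_high
  } else {
    z_low <- rep(sf_bounds[1], nf); z_high <- rep(sf_bounds[2], nf)
  }
  if (any(z_low >= z_high))
    stop("geometry error: z_low >= z_high in filter bounds")
  if (radial_check) {
    axy <- pore_axis_xy(replica, annotation)
    r <- sqrt((matrix(replica$coords[, idx, 1], nrow = nf) - axy[, 1])^2 +
                (matrix(replica$coords[, idx, 2], nrow = nf) - axy[, 2])^2)
  } else r <- matrix(numeric(0), 0, 0)
  res <- .count_crossings_core(z, r, z_low, z_high, replica$box[, 3],
                               delta, r_cut, radial_check)
  ev <- data.table(particle = idx[res$particle], species = species,
                   direction = res$direction, entry_frame = res$entry_frame,
                   completion_frame = res$completion_frame,
                   replica = replica_id)
  setattr(ev, "first_side", res$first_side)
  setattr(ev, "last_side", res$last_side)
  ev[]
}

empty_event_table <- function() {
  data.table(particle = integer(), species = character(),
             direction = integer(), entry_frame = integer(),
             completion_frame = integer(), replica = integer())
}

#' Count crossings across all replicas of an ensemble
#'
#' @param ensemble annotated [trajectory_ensemble].
#' @param ... passed to [count_crossings()].
#' @inheritParams count_crossings
#' @return combined event `data.table`.
#' @export
count_crossings_ensemble <- function(ensemble, annotation = NULL,
                                     species = "ion", ...) {
  ann <- if (!is.null(annotation)) annotation else ensemble$annotation
  if (is.null(ann)) stop("annotation error: ensemble is not annotated")
  rbindlist(lapply(seq_along(ensemble$replicas), function(i)
    count_crossings(ensemble$replicas[[i]], ann, species = species,
                    replica_id = i, ...)))
}

#' Convert permeation events to a single-channel current with CI
#'
#' Net outward count times the elementary charge over the sampled time:
#' `I = 160.2176634 (n_out - n_in) / T` pA with `T` in ns.  The
#' confidence interval is a replica-level percentile bootstrap of the
#' per-replica currents.
#'
#' @param events event table from [count_crossings_ensemble()] (needs a
#'   `replica` and `direction` column); may be empty.
#' @param replica_times per-replica sampled times in ns (named or in
#'   replica order); a scalar is recycled using `n_replicas`.
#' @param n_replicas number of replicas (inferred from
#'   `length(replica_times)` when > 1).
#' @param level CI level.
#' @param n_boot,seed bootstrap parameters (see [bootstrap_ci()]).
#' @return object of class `current_estimate`: `n_out`, `n_in`,
#'   `T_total` (ns), `current`, `ci_low`, `ci_high` (pA) and
#'   `per_replica` currents.
#' @export
compute_current <- function(events, replica_times, n_replicas = NULL,
                            level = 0.95, n_boot = 20000L, seed = 0L) {
  if (length(replica_times) == 1L && !is.null(n_replicas))
    replica_times <- rep(replica_times, n_replicas)
  nrep <- length(replica_times)
  if (any(replica_times <= 0)) stop("replica times must be positive")
  T_total <- sum(replica_times)
  net <- integer(nrep); n_out <- 0L; n_in <- 0L
  if (nrow(events)) {
    agg <- as.data.table(events)[, .(net = sum(direction),
                                     out = sum(direction > 0),
                                     inw = sum(direction < 0)), by = replica]
    net[agg$replica] <- agg$net
    n_out <- sum(agg$out); n_in <- sum(agg$inw)
  }
  per_rep <- PA_PER_CROSSING_NS * net / replica_times
  current <- PA_PER_CROSSING_NS * sum(net) / T_total
  if (nrep >= 2L) {
    b <- bootstrap_ci(per_rep, mean, n_boot = n_boot, level = level,
                      seed = seed)
    ci <- c(b$ci_low, b$ci_high)
  } else ci <- c(NA_real_, NA_real_)
  structure(list(n_out = n_out, n_in = n_in, T_total = T_total,
                 current = current, ci_low = ci[1], ci_high = ci[2],
                 level = level, per_replica = per_rep),
            class = "current_estimate")
}

#' @export
print.current_estimate <- function(x, ...) {
  cat(sprintf("current: %.3f pA  [%.3f, %.3f]  (n_out=%d, n_in=%d, T=%.1f ns)\n",
              x$current, x$ci_low, x$ci_high, x$n_out, x$n_in, x$T_total))
  invisible(x)
}

#' Census of waters and ions in the cavity
#'
#' Counts water oxygens and ions within `radius` of the centre of mass
#' of the gate-level alanine CA ring (role `"A88"`), the conventional
#' cavity definition.
#'
#' @param frame atoms x 3 coordinate matrix (nm).
#' @param annotation [channel_annotation].
#' @param radius census radius, nm.
#' @return named vector `c(n_water, n_ion)`.
#' @export
cavity_census <- function(frame, annotation, radius = 1.0) {
  if (radius <= 0) stop("radius must be positive")
  a88 <- role_indices(annotation, "A88")
  com <- colMeans(frame[a88, , drop = FALSE])
  count_within <- function(idx) {
    if (!length(idx)) return(0L)
    d2 <- rowSums(sweep(frame[idx, , drop = FALSE], 2, com)^2)
    sum(d2 < radius^2)
  }
  c(n_water = count_within(annotation$water_oxygen_indices),
    n_ion = count_within(annotation$ion_indices))
}

#' Cavity census averaged over an ensemble
#'
#' @param ensemble annotated [trajectory_ensemble].
#' @param radius census radius, nm.
#' @return `data.table` with per-replica mean water and ion counts.
#' @export
cavity_census_ensemble <- function(ensemble, radius = 1.0) {
  ann <- ensemble$annotation
  rbindlist(lapply(seq_along(ensemble$replicas), function(i) {
    rep <- ensemble$replicas[[i]]
    nf <- dim(rep$coords)[1]
    counts <- vapply(seq_len(nf), function(f)
      cavity_census(rep$coords[f, , ], ann, radius), c(n_water = 0, n_ion = 0))
    data.table(replica = i, n_water = mean(counts[1, ]),
               n_ion = mean(counts[2, ]))
  }))
}
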