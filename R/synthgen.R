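# Synthetic channel ensembles with ground truth.  A pseudo-atom
# tetramer (gate beads P19/F97/A88/I84, filter oxygens, T59 CA/CG,
# M1/M2 helix beads) whose gate opening g drives the filter spread
# s = a + c*g + noise; ions hop between compartments
# {bulk_below, cavity, S4..S0, bulk_above} as a continuous-time Markov
# chain under a voltage tilt, with single-file exclusion; waters enter
# filter sites with an opening-dependent probability and block ion
# entry; everything is jittered by thermal coordinate noise and every
# stochastic element is logged.

SYNTH_COMPARTMENTS <- c("bulk_below", "cavity", "S4", "S3", "S2", "S1",
                        "S0", "bulk_above")

#' Specification of a synthetic channel ensemble
#'
#' Defaults state the emulated world: a tetramer with 0.3 nm oxygen
#' plane spacing, ten 500 ns replicas (output every 0.1 ns), a gate
#' opening of 1.66 nm (the opening of maximal current), filter spread
#' coupled to the gate as `s = a + c g`, an S4/S3 barrier that grows
#' quadratically as the filter narrows below its optimum, a voltage
#' tilt per hop, and water entry into S4/S1 switching on for spreads
#' above the optimum.
#'
#' @param n_replicas number of replicas.
#' @param g gate opening (A88 CA-CA opposite distance, nm) per replica
#'   (recycled).
#' @param t_total sampled time per replica, ns.
#' @param dt output frame spacing, ns.
#' @param seed RNG seed (generation is bit-reproducible given the
#'   seed).
#' @param plane_z z of the six filter oxygen planes (T_OG1 .. G2_O),
#'   nm, strictly increasing.
#' @param box box lengths, nm.
#' @param voltage applied membrane voltage, mV (metadata; the kinetic
#'   effect enters via `delta_volt`).
#' @param coupling_a,coupling_c intercept/slope of the gate-to-filter
#'   coupling `s = a + c g` (nm).
#' @param sigma_g,sigma_T,sigma_xyz per-frame gate fluctuation, filter
#'   spread noise, and isotropic coordinate jitter (nm).
#' @param n_ions number of ions.
#' @param k0 attempt frequency for filter hops, 1/ns.
#' @param k_bulk bulk <-> cavity exchange rate, 1/ns.
#' @param k_recycle rate of periodic re-entry (top bulk to bottom
#'   bulk), 1/ns.
#' @param B_entry,B_low,B_mid,B_exit fixed boundary barriers, kT
#'   (cavity/S4, S3/S2, S2/S1 and S1/S0, S0/top).
#' @param B0,kappa,s_opt S4/S3 barrier model
#'   `B = B0 + kappa (s_opt - s)^2` for `s < s_opt`, else `B0` (kT,
#'   kT/nm^2, nm).
#' @param delta_volt voltage tilt per hop, kT (forward rates gain
#'   `exp(+delta/2)`, backward `exp(-delta/2)`).
#' @param water_sites filter sites waters may occupy.
#' @param kw_in,kw_out water entry attempt rate and exit rate, 1/ns
#'   (`kw_in = 0` ablates the water mechanism).
#' @param s_wet,w_wet midpoint and width (nm) of the logistic
#'   water-entry probability `p_w(s)`.
#' @param flip_in,flip_out carbonyl flip-in (scaled by `p_w`) and
#'   flip-out rates, 1/ns.
#' @param cavity_cap maximum ions in the cavity.
#' @param n_cavity_water cavity water count per replica; default grows
#'   linearly with gate opening from ~40 (smallest openings stay
#'   hydrated) to 100.
#' @param planted_rate if non-NULL, replaces the hop chain by
#'   scheduled outward crossings at this exact net Poisson rate per ns
#'   (calibration mode).
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(n_replicas = 10L, g = 1.66, t_total = 500,
                       dt = 0.1, seed = 1L,
                       plane_z = c(0, 0.3, 0.6, 0.9, 1.2, 1.5),
                       box = c(6, 6, 7), voltage = 300,
                       coupling_a = 0.27, coupling_c = 1 / 3,
                       sigma_g = 0.02, sigma_T = 0.01, sigma_xyz = 0.02,
                       n_ions = 6L, k0 = 5, k_bulk = 2, k_recycle = 2,
                       B_entry = 0.5, B_low = 0.2, B_mid = 0.8,
                       B_exit = 0.5, B0 = 0.8, kappa = 300,
                       s_opt = 0.823, delta_volt = 1.5,
                       water_sites = c("S4", "S1"), kw_in = 2,
                       kw_out = 0.5, s_wet = 0.875, w_wet = 0.015,
                       flip_in = 1, flip_out = 1, cavity_cap = 3L,
                       n_cavity_water = NULL, planted_rate = NULL) {
  if (any(diff(plane_z) <= 0))
    stop("value error: plane_z must be strictly increasing")
  if (dt <= 0 || t_total < dt) stop("value error: bad t_total/dt")
  g <- rep_len(g, n_replicas)
  if (is.null(n_cavity_water))
    n_cavity_water <- round(40 + 60 * pmin(pmax((g - 1.3) / 0.6, 0), 1))
  n_cavity_water <- rep_len(n_cavity_water, n_replicas)
  spec <- list(n_replicas = as.integer(n_replicas), g = g,
               t_total = t_total, dt = dt, seed = as.integer(seed),
               plane_z = plane_z, box = box, voltage = voltage,
               coupling_a = coupling_a, coupling_c = coupling_c,
               sigma_g = sigma_g, sigma_T = sigma_T,
               sigma_xyz = sigma_xyz, n_ions = as.integer(n_ions),
               k0 = k0, k_bulk = k_bulk, k_recycle = k_recycle,
               B_entry = B_entry, B_low = B_low, B_mid = B_mid,
               B_exit = B_exit, B0 = B0, kappa = kappa, s_opt = s_opt,
               delta_volt = delta_volt, water_sites = water_sites,
               kw_in = kw_in, kw_out = kw_out, s_wet = s_wet,
               w_wet = w_wet, flip_in = flip_in, flip_out = flip_out,
               cavity_cap = as.integer(cavity_cap),
               n_cavity_water = n_cavity_water,
               planted_rate = planted_rate)
  structure(spec, class = "synth_spec")
}

# Water-entry probability as a function of filter spread.
p_water <- function(spec, s) stats::plogis((s - spec$s_wet) / spec$w_wet)

# S4/S3 barrier: grows quadratically as the filter narrows below its
# conductive optimum, flat above it.
b_s4s3 <- function(spec, s)
  spec$B0 + spec$kappa * pmax(spec$s_opt - s, 0)^2

# Per-boundary forward (up) and backward rates at spread s.
boundary_rates <- function(spec, s) {
  B <- c(0, spec$B_entry, b_s4s3(spec, s), spec$B_low, spec$B_mid,
         spec$B_mid, spec$B_exit)
  base <- c(spec$k_bulk, rep(spec$k0, 6))
  tilt <- spec$delta_volt / 2
  list(fwd = base * exp(-B + tilt), bwd = base * exp(-B - tilt))
}

#' Rate matrix of the ion hop chain
#'
#' Single-ion continuous-time Markov chain over
#' bulk_below, cavity, S4, S3, S2, S1, S0, bulk_above, with periodic
#' re-entry from the top bulk to the bottom bulk closing the cycle.
#'
#' @param spec [synth_spec()].
#' @param s filter spread, nm.
#' @return 8 x 8 generator matrix Q (1/ns).
#' @export
hop_rate_matrix <- function(spec, s) {
  r <- boundary_rates(spec, s)
  n <- 8L
  Q <- matrix(0, n, n, dimnames = list(SYNTH_COMPARTMENTS,
                                       SYNTH_COMPARTMENTS))
  for (i in 1:7) {
    Q[i, i + 1] <- r$fwd[i]
    if (i < 7) Q[i + 1, i] <- r$bwd[i]
    # no backward hop across the top boundary: exits recycle instead
  }
  Q[8, 1] <- spec$k_recycle
  diag(Q) <- -rowSums(Q)
  Q
}

#' Stationary distribution of the ion hop chain
#'
#' @inheritParams hop_rate_matrix
#' @return named probability vector over the 8 compartments.
#' @export
hop_stationary <- function(spec, s) {
  Q <- hop_rate_matrix(spec, s)
  # solve pi Q = 0, sum(pi) = 1
  A <- rbind(t(Q), rep(1, nrow(Q)))
  b <- c(rep(0, nrow(Q)), 1)
  pi <- qr.solve(A, b)
  stats::setNames(pmax(pi, 0) / sum(pmax(pi, 0)), SYNTH_COMPARTMENTS)
}

# --------------------------------------------------------------------------
# Pseudo-atom template
# --------------------------------------------------------------------------

# Per-subunit atom template: resid/resname/name plus the radial model
# rho(t) = rho0 + cg * g_t + cs * s_t and fixed z.  The TVGYG motif
# occupies resids 59-63 so annotation-by-motif works on written files.
synth_atom_template <- function(spec) {
  z <- spec$plane_z
  ztop <- 0.3
  m2w <- function(zz) (ztop - zz) / (ztop - (-2.0))
  m1w <- function(zz) (0.4 - zz) / (0.4 - (-2.2))
  tpl <- rbind(
    data.table(resid = 19L, resname = "PRO", name = "CA",
               rho0 = 0.30, cg = 0.5, cs = 0, z = -2.2),
    data.table(resid = c(30L, 40L, 50L), resname = "LEU", name = "CA",
               rho0 = 0.55 * (1 - m1w(c(-1.6, -0.8, 0.0))) +
                 0.30 * m1w(c(-1.6, -0.8, 0.0)),
               cg = 0.5 * m1w(c(-1.6, -0.8, 0.0)), cs = 0,
               z = c(-1.6, -0.8, 0.0)),
    data.table(resid = 59L, resname = "THR",
               name = c("CA", "CG2", "OG1", "O"),
               rho0 = c(0, -0.05, 0.25, 0.25), cg = 0,
               cs = c(0.5, 0.5, 0, 0), z = c(z[1], -0.15, z[1], z[2])),
    data.table(resid = 60L, resname = "VAL", name = c("C", "O"),
               rho0 = 0.25, cg = 0, cs = 0,
               z = c(z[3] - 0.12, z[3])),
    data.table(resid = 61L, resname = "GLY", name = "O",
               rho0 = 0.25, cg = 0, cs = 0, z = z[4]),
    data.table(resid = 62L, resname = "TYR", name = "O",
               rho0 = 0.25, cg = 0, cs = 0, z = z[5]),
    data.table(resid = 63L, resname = "GLY", name = "O",
               rho0 = 0.25, cg = 0, cs = 0, z = z[6]),
    data.table(resid = 84L, resname = "ILE", name = "CD",
               rho0 = 0.40, cg = 0, cs = 0.5, z = -0.15),
    data.table(resid = 88L, resname = "ALA", name = "CA",
               rho0 = 0, cg = 0.5, cs = 0, z = -1.5),
    data.table(resid = c(90L, 92L, 94L), resname = "LEU", name = "CA",
               rho0 = 0.35 * (1 - m2w(c(-1.0, -0.4, 0.1))) +
                 0.10 * m2w(c(-1.0, -0.4, 0.1)),
               cg = 0.5 * m2w(c(-1.0, -0.4, 0.1)), cs = 0,
               z = c(-1.0, -0.4, 0.1)),
    data.table(resid = 97L, resname = "PHE", name = "CA",
               rho0 = 0.10, cg = 0.5, cs = 0, z = -2.0))
  tpl
}

# Full topology (atom table): 4 subunits, SF waters, cavity/parked
# water slots, ions.  Returns list(topology, layout) where layout
# carries the index bookkeeping used by the generator.
synth_topology <- function(spec, n_water_slots = 110L) {
  tpl <- synth_atom_template(spec)
  nsub <- 4L
  prot <- rbindlist(lapply(seq_len(nsub), function(s) {
    d <- copy(tpl)
    d[, subunit := s]
    d
  }))
  n_sfw <- length(spec$water_sites)
  n_wat <- n_water_slots + n_sfw
  wat <- data.table(resid = 1000L + seq_len(n_wat), resname = "SOL",
                    name = "OW", rho0 = NA_real_, cg = NA_real_,
                    cs = NA_real_, z = NA_real_, subunit = NA_integer_)
  ion <- data.table(resid = 3000L + seq_len(spec$n_ions), resname = "K",
                    name = "K", rho0 = NA_real_, cg = NA_real_,
                    cs = NA_real_, z = NA_real_, subunit = NA_integer_)
  all <- rbindlist(list(prot, wat, ion))
  all[, serial := .I]
  topology <- all[, .(serial, name, resname,
                      chain = NA_character_, resid,
                      x = 0, y = 0, z = ifelse(is.na(z), 0, z))]
  layout <- list(
    n_protein = nrow(prot), angles = (seq_len(nsub) - 1) * pi / 2,
    tpl = tpl, n_per_sub = nrow(tpl),
    sf_water_idx = nrow(prot) + seq_len(n_sfw),
    cavity_water_idx = nrow(prot) + n_sfw + seq_len(n_water_slots),
    ion_idx = nrow(prot) + n_wat + seq_len(spec$n_ions),
    v_o_rows = which(prot$resname == "VAL" & prot$name == "O"),
    subunit_of = prot$subunit)
  list(topology = topology, layout = layout)
}

synth_role_config <- function() {
  list(sf = list(motif = "TVGYG"),
       gate = list(P19 = "19:CA", F97 = "97:CA", A88 = "88:CA",
                   I84_tip = "84:CD", T59_CG = "59:CG2"),
       species = list(ion = "K", water_oxygen = "SOL:OW"))
}

#' Write the role-config file matching generated ensembles
#' @param path output path.
#' @export
write_synth_role_config <- function(path) {
  writeLines(c("[sf]", "motif = TVGYG", "[gate]", "P19 = 19:CA",
               "F97 = 97:CA", "A88 = 88:CA", "I84_tip = 84:CD",
               "T59_CG = 59:CG2", "[species]", "ion = K",
               "water_oxygen = SOL:OW"), path)
  invisible(path)
}

# --------------------------------------------------------------------------
# Dynamics
# --------------------------------------------------------------------------

# z of each compartment centre (ion placement), from the plane grid.
compartment_z <- function(spec) {
  z <- spec$plane_z
  mid <- (z[-length(z)] + z[-1]) / 2
  c(bulk_below = -2.8, cavity = -1.2, S4 = mid[1], S3 = mid[2],
    S2 = mid[3], S1 = mid[4], S0 = mid[5], bulk_above = 2.6)
}

site_comp_index <- function(site) match(site, SYNTH_COMPARTMENTS)

# Simulate one replica's ion/water/flip dynamics.  Returns compartment
# matrix (frames x ions), water occupancy (frames x water sites), flip
# matrix (frames x 4), hop log, and the per-frame g_t / s_t series.
simulate_replica_dynamics <- function(spec, g_rep) {
  nf <- as.integer(round(spec$t_total / spec$dt))
  g_t <- g_rep + stats::rnorm(nf, 0, spec$sigma_g)
  s_t <- spec$coupling_a + spec$coupling_c * g_t +
    stats::rnorm(nf, 0, spec$sigma_T)
  nio <- spec$n_ions
  comp <- matrix(0L, nf, nio)
  # one ion starts in the cavity, the rest in the bottom bulk
  state <- if (nio > 0L) c(2L, rep(1L, nio - 1L)) else integer(0)
  wsites <- site_comp_index(spec$water_sites)
  wocc <- matrix(FALSE, nf, length(wsites))
  wstate <- rep(FALSE, length(wsites))
  fstate <- rep(FALSE, 4L)
  flips <- matrix(FALSE, nf, 4L)
  hops <- list(time = numeric(), ion = integer(), from = integer(),
               to = integer())
  nh <- 0L
  pw_t <- p_water(spec, s_t)
  p_flip_out <- 1 - exp(-spec$flip_out * spec$dt)
  for (f in seq_len(nf)) {
    t0 <- (f - 1L) * spec$dt
    # water occupancy update (frame-resolution Markov chain); waters
    # may not enter a site holding an ion
    if (length(wsites)) {
      p_in <- 1 - exp(-spec$kw_in * pw_t[f] * spec$dt)
      for (wi in seq_along(wsites)) {
        if (wstate[wi]) {
          if (stats::runif(1) < 1 - exp(-spec$kw_out * spec$dt))
            wstate[wi] <- FALSE
        } else if (!any(state == wsites[wi]) && stats::runif(1) < p_in) {
          wstate[wi] <- TRUE
        }
      }
      wocc[f, ] <- wstate
    }
    # carbonyl flips, driven by the same wetting probability
    p_fin <- 1 - exp(-spec$flip_in * pw_t[f] * spec$dt)
    for (su in 1:4) {
      if (fstate[su]) { if (stats::runif(1) < p_flip_out) fstate[su] <- FALSE }
      else if (stats::runif(1) < p_fin) fstate[su] <- TRUE
    }
    flips[f, ] <- fstate
    comp[f, ] <- state
    # ion hops: exact event-driven simulation with rates held constant
    # over the frame interval
    r <- boundary_rates(spec, s_t[f])
    t_now <- t0; t_end <- t0 + spec$dt
    repeat {
      moves_ion <- integer(); moves_to <- integer(); moves_rate <- numeric()
      site_taken <- function(cmp) {
        (cmp >= 3L && cmp <= 7L) &&
          (any(state == cmp) || (cmp %in% wsites && wstate[match(cmp, wsites)]))
      }
      for (i in seq_len(nio)) {
        c_i <- state[i]
        if (c_i < 8L) {  # upward move
          to <- c_i + 1L
          ok <- if (to == 2L) sum(state == 2L) < spec$cavity_cap
                else if (to == 8L) TRUE else !site_taken(to)
          if (ok) {
            moves_ion <- c(moves_ion, i); moves_to <- c(moves_to, to)
            moves_rate <- c(moves_rate, r$fwd[c_i])
          }
        }
        if (c_i > 1L && c_i < 8L) {  # downward move
          to <- c_i - 1L
          ok <- if (to == 1L) TRUE
                else if (to == 2L) sum(state == 2L) < spec$cavity_cap
                else !site_taken(to)
          if (ok && c_i >= 2L && c_i <= 7L) {
            # no downward re-entry from the top bulk (recycle instead)
            moves_ion <- c(moves_ion, i); moves_to <- c(moves_to, to)
            moves_rate <- c(moves_rate, r$bwd[c_i - 1L])
          }
        }
        if (c_i == 8L) {  # periodic re-entry at the bottom
          moves_ion <- c(moves_ion, i); moves_to <- c(moves_to, 1L)
          moves_rate <- c(moves_rate, spec$k_recycle)
        }
      }
      Rtot <- sum(moves_rate)
      if (Rtot <= 0) break
      t_now <- t_now + stats::rexp(1, Rtot)
      if (t_now >= t_end) break
      j <- sample.int(length(moves_rate), 1L, prob = moves_rate)
      nh <- nh + 1L
      hops$time[nh] <- t_now; hops$ion[nh] <- moves_ion[j]
      hops$from[nh] <- state[moves_ion[j]]; hops$to[nh] <- moves_to[j]
      state[moves_ion[j]] <- moves_to[j]
    }
  }
  list(comp = comp, water = wocc, flips = flips, g_t = g_t, s_t = s_t,
       hops = as.data.table(hops))
}

# Planted-rate dynamics: scheduled outward crossings at an exact
# Poisson rate; each crossing walks one ion through the compartments
# one frame per step, then recycles it.
simulate_planted_rate <- function(spec, rate) {
  nf <- as.integer(round(spec$t_total / spec$dt))
  g_t <- spec$g[1] + stats::rnorm(nf, 0, spec$sigma_g)
  s_t <- spec$coupling_a + spec$coupling_c * g_t +
    stats::rnorm(nf, 0, spec$sigma_T)
  nio <- spec$n_ions
  path <- c(2L, 3L, 4L, 5L, 6L, 7L, 8L)  # cavity then S4..S0, top
  dwell_top <- 5L
  transit <- length(path) + dwell_top
  # draw exactly Poisson(rate * T) crossings and schedule them inside a
  # window that always allows completion, so the realised per-replica
  # count is unbiased for the planted rate
  margin <- (transit + 2L) * spec$dt
  n_ev <- stats::rpois(1, rate * spec$t_total)
  starts <- sort(stats::runif(n_ev, 0, max(spec$dt, spec$t_total - margin)))
  comp <- matrix(1L, nf, nio)
  free_at <- rep(1L, nio)  # first frame at which each ion is idle
  launched <- 0L
  for (tv in starts) {
    f0 <- min(nf, as.integer(floor(tv / spec$dt)) + 1L)
    i <- which.min(free_at)
    f0 <- max(f0, free_at[i])
    if (f0 + length(path) - 1L > nf) next  # cannot complete in time
    for (k in seq_along(path)) comp[f0 + k - 1L, i] <- path[k]
    last <- min(nf, f0 + length(path) - 1L + dwell_top)
    if (last >= f0 + length(path))
      comp[(f0 + length(path)):last, i] <- 8L
    free_at[i] <- last + 1L
    launched <- launched + 1L
  }
  list(comp = comp, water = matrix(FALSE, nf, length(spec$water_sites)),
       flips = matrix(FALSE, nf, 4L), g_t = g_t, s_t = s_t,
       hops = data.table(time = numeric(), ion = integer(),
                         from = integer(), to = integer()),
       n_launched = launched)
}

# Net completed below->above crossings from a compartment matrix,
# using the same side bookkeeping as the coordinate-space counter
# (below = bulk_below/cavity, above = bulk_above; recycle resets).
truth_net_crossings <- function(comp) {
  net <- 0L
  for (i in seq_len(ncol(comp))) {
    side <- 0L; prev <- comp[1L, i]
    sd0 <- function(cmp) if (cmp <= 2L) -1L else if (cmp == 8L) 1L else 0L
    side <- sd0(prev)
    for (f in 2:nrow(comp)) {
      cur <- comp[f, i]
      if (prev == 8L && cur != 8L) {  # recycle teleport: reset
        side <- sd0(cur); prev <- cur; next
      }
      s <- sd0(cur)
      if (s != 0L && side != 0L && s != side) net <- net + s
      if (s != 0L) side <- s
      prev <- cur
    }
  }
  net
}

# --------------------------------------------------------------------------
# Coordinate emission
# --------------------------------------------------------------------------

emit_replica_coords <- function(spec, topo, dyn, n_cav) {
  lay <- topo$layout
  nf <- length(dyn$g_t)
  na <- nrow(topo$topology)
  coords <- array(0, c(nf, na, 3L))
  nps <- lay$n_per_sub
  tpl <- lay$tpl
  for (su in 1:4) {
    th <- lay$angles[su]
    rows <- (su - 1L) * nps + seq_len(nps)
    for (k in seq_len(nps)) {
      rho <- tpl$rho0[k] + tpl$cg[k] * dyn$g_t + tpl$cs[k] * dyn$s_t
      coords[, rows[k], 1] <- rho * cos(th)
      coords[, rows[k], 2] <- rho * sin(th)
      coords[, rows[k], 3] <- tpl$z[k]
    }
    # flipped valine carbonyl O: swings from axial (+z from C) to
    # radial-outward
    vo <- rows[which(tpl$resname == "VAL" & tpl$name == "O")]
    fl <- dyn$flips[, su]
    if (any(fl)) {
      coords[fl, vo, 1] <- 0.45 * cos(th)
      coords[fl, vo, 2] <- 0.45 * sin(th)
      coords[fl, vo, 3] <- spec$plane_z[3] - 0.18
    }
  }
  cz <- compartment_z(spec)
  # ions: compartment centres; bulk ions sit off-axis at per-ion angles
  ion_angle <- 2 * pi * (seq_len(spec$n_ions) - 1) / spec$n_ions
  for (i in seq_len(spec$n_ions)) {
    ci <- dyn$comp[, i]
    zc <- cz[ci]
    in_bulk <- ci == 1L | ci == 8L
    rho <- ifelse(in_bulk, 1.3, ifelse(ci == 2L, 0.15, 0))
    coords[, lay$ion_idx[i], 1] <- rho * cos(ion_angle[i])
    coords[, lay$ion_idx[i], 2] <- rho * sin(ion_angle[i])
    coords[, lay$ion_idx[i], 3] <- zc
  }
  # filter-site waters: at the site centre while occupying it, parked
  # high above and off-axis otherwise
  if (length(lay$sf_water_idx)) {
    for (wi in seq_along(lay$sf_water_idx)) {
      occ <- dyn$water[, wi]
      zc <- cz[site_comp_index(spec$water_sites[wi])]
      coords[, lay$sf_water_idx[wi], 1] <- ifelse(occ, 0, 1.8)
      coords[, lay$sf_water_idx[wi], 2] <- ifelse(occ, 0, 1.0 * wi)
      coords[, lay$sf_water_idx[wi], 3] <- ifelse(occ, zc, 2.9)
    }
  }
  # cavity waters: first n_cav slots resampled uniformly in a 0.9 nm
  # ball around the A88 ring centre; the rest parked in the bottom bulk
  ncw <- length(lay$cavity_water_idx)
  active <- seq_len(min(n_cav, ncw))
  if (length(active)) {
    nact <- length(active)
    u <- stats::runif(nf * nact)^(1 / 3) * 0.9
    phi <- stats::runif(nf * nact, 0, 2 * pi)
    cth <- stats::runif(nf * nact, -1, 1)
    sth <- sqrt(1 - cth^2)
    coords[, lay$cavity_water_idx[active], 1] <- u * sth * cos(phi)
    coords[, lay$cavity_water_idx[active], 2] <- u * sth * sin(phi)
    coords[, lay$cavity_water_idx[active], 3] <- -1.5 + u * cth
  }
  if (ncw > length(active)) {
    parked <- lay$cavity_water_idx[(length(active) + 1L):ncw]
    ang <- 2 * pi * seq_along(parked) / length(parked)
    coords[, parked, 1] <- rep(2.0 * cos(ang), each = nf)
    coords[, parked, 2] <- rep(2.0 * sin(ang), each = nf)
    coords[, parked, 3] <- -2.9
  }
  if (spec$sigma_xyz > 0)
    coords <- coords + array(stats::rnorm(length(coords), 0,
                                          spec$sigma_xyz), dim(coords))
  coords
}

# --------------------------------------------------------------------------
# Public generator
# --------------------------------------------------------------------------

#' Generate a synthetic channel ensemble with ground truth
#'
#' @param spec a [synth_spec()].
#' @return list with `ensemble` (annotated [trajectory_ensemble]),
#'   `annotation`, `topology` (atom table for writing files), and
#'   `truth`: per-replica hop logs, compartment matrices
#'   (frames x ions), water-site occupancy, flip matrices, per-frame
#'   `g_t`/`s_t`, net crossings per replica, and (in planted-rate
#'   mode) the realised crossing count.
#' @export
generate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  topo <- synth_topology(spec)
  ann <- build_annotation(topo$topology, synth_role_config())
  with_seed(spec$seed, {
    reps <- vector("list", spec$n_replicas)
    truth <- list(hops = list(), comp = list(), water = list(),
                  flips = list(), g_t = list(), s_t = list(),
                  net_crossings = integer(spec$n_replicas))
    for (r in seq_len(spec$n_replicas)) {
      dyn <- if (is.null(spec$planted_rate))
        simulate_replica_dynamics(spec, spec$g[r])
      else simulate_planted_rate(spec, spec$planted_rate)
      coords <- emit_replica_coords(spec, topo, dyn,
                                    spec$n_cavity_water[r])
      nf <- dim(coords)[1]
      reps[[r]] <- replica(coords, spec$box,
                           times = seq_len(nf) * spec$dt,
                           meta = list(voltage_mV = spec$voltage,
                                       g = spec$g[r], seed = spec$seed,
                                       replica = r))
      truth$hops[[r]] <- dyn$hops
      truth$comp[[r]] <- dyn$comp
      truth$water[[r]] <- dyn$water
      truth$flips[[r]] <- dyn$flips
      truth$g_t[[r]] <- dyn$g_t
      truth$s_t[[r]] <- dyn$s_t
      truth$net_crossings[r] <- truth_net_crossings(dyn$comp)
    }
    ens <- trajectory_ensemble(reps, annotation = ann)
    list(ensemble = ens, annotation = ann, topology = topo$topology,
         truth = truth)
  })
}

#' Generate a planted-mode ensemble for functional mode analysis
#'
#' Frames are `mean + q(t) mode + isotropic noise`; the scalar target
#' is `q(t)` plus noise at the requested signal-to-noise ratio, so the
#' generative R-squared is `snr / (1 + snr)`.
#'
#' @param n_frames,n_atoms ensemble size (coordinate dimension is
#'   `3 n_atoms`).
#' @param planted_mode unit-norm mode of length `3 n_atoms`
#'   (default: a random unit vector).
#' @param snr variance ratio var(q) / var(target noise); `Inf` gives a
#'   noiseless target.
#' @param seed RNG seed.
#' @param sigma_iso isotropic coordinate noise, nm.
#' @return list: `X` (frames x 3M), `target`, `mode`, `q`,
#'   `r2_generative`.
#' @export
generate_fma_ensemble <- function(n_frames, n_atoms, planted_mode = NULL,
                                  snr = 11.5, seed = 1L,
                                  sigma_iso = 0.05) {
  if (snr <= 0) stop("value error: snr must be positive")
  p <- 3L * n_atoms
  with_seed(seed, {
    if (is.null(planted_mode)) {
      planted_mode <- stats::rnorm(p)
      planted_mode <- planted_mode / sqrt(sum(planted_mode^2))
    }
    stopifnot(abs(sum(planted_mode^2) - 1) < 1e-6)
    q <- stats::rnorm(n_frames)
    X <- outer(q, planted_mode)
    if (sigma_iso > 0)
      X <- X + matrix(stats::rnorm(n_frames * p, 0, sigma_iso),
                      n_frames, p)
    noise_sd <- if (is.finite(snr)) stats::sd(q) / sqrt(snr) else 0
    target <- q + stats::rnorm(n_frames, 0, noise_sd)
    list(X = X, target = target, mode = planted_mode, q = q,
         r2_generative = if (is.finite(snr)) snr / (1 + snr) else 1)
  })
}

#' Run the full gating-curve experiment over a series of openings
#'
#' Generates one ensemble per spec (differing in gate opening g), runs
#' crossing counting, current estimation, site occupancy and cavity
#' census, and returns the synthetic gating curve.
#'
#' @param spec_series list of [synth_spec()]s.
#' @param n_boot bootstrap resamples for the per-level current CI.
#' @param delta,r_cut counter parameters (see [count_crossings()]).
#' @return `data.table`: per level `g`, `s_mean`, `current`, `ci_low`,
#'   `ci_high`, ion/water fractions for S4..S1, and the mean cavity
#'   water count.
#' @export
gating_curve_experiment <- function(spec_series, n_boot = 2000L,
                                    delta = 0.1, r_cut = 0.6) {
  if (!length(spec_series)) stop("value error: empty spec series")
  rows <- lapply(spec_series, function(sp) {
    gen <- generate_ensemble(sp)
    ev <- count_crossings_ensemble(gen$ensemble, species = "ion",
                                   delta = delta, r_cut = r_cut)
    cur <- compute_current(ev, replica_times = sp$t_total,
                           n_replicas = sp$n_replicas, n_boot = n_boot,
                           seed = sp$seed)
    occ <- occupancy_table(gen$ensemble, n_boot = 200L, seed = sp$seed)
    cen <- cavity_census_ensemble(gen$ensemble)
    getf <- function(st, sp)
      occ$fraction[occ$site == st & occ$species == sp]
    data.table(g = mean(sp$g), s_mean = mean(unlist(gen$truth$s_t)),
               current = cur$current, ci_low = cur$ci_low,
               ci_high = cur$ci_high,
               ion_S4 = getf("S4", "ion"), ion_S3 = getf("S3", "ion"),
               ion_S2 = getf("S2", "ion"), ion_S1 = getf("S1", "ion"),
               water_S4 = getf("S4", "water"),
               water_S1 = getf("S1", "water"),
               cavity_waters = mean(cen$n_water),
               cavity_ions = mean(cen$n_ion),
               net_crossings = sum(gen$truth$net_crossings))
  })
  rbindlist(rows)
}
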