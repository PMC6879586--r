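# Independent oracles and small fixture builders shared across tests.
# These deliberately use different algorithmic routes than the package
# implementation they check.

# Run-length-based crossing enumerator: segment each particle's z
# series at periodic wraps, drop non-definitive frames, and read events
# off sign changes between runs of definitive labels.  Same rules as
# count_crossings() (no radial check), entirely different formulation.
oracle_count_crossings <- function(z, z_low, z_high, delta = 0.1,
                                   lz = Inf) {
  nf <- nrow(z)
  p_out <- list(); d_out <- list(); e_out <- list(); c_out <- list()
  n_seg <- 0L
  for (p in seq_len(ncol(z))) {
    zp <- z[, p]
    d <- ifelse(zp > z_high + delta, 1L, ifelse(zp < z_low - delta, -1L, 0L))
    wrap <- c(FALSE, abs(diff(zp)) > lz / 2)
    seg <- cumsum(wrap)
    for (s in unique(seg)) {
      idx <- which(seg == s)
      lab <- d[idx]
      keep <- lab != 0L
      if (sum(keep) < 2L) next
      fr <- idx[keep]; lb <- lab[keep]
      r <- rle(lb)
      if (length(r$lengths) < 2L) next
      ends <- cumsum(r$lengths)
      k <- 2:length(r$values)
      n_seg <- n_seg + 1L
      p_out[[n_seg]] <- rep.int(p, length(k))
      d_out[[n_seg]] <- r$values[k]
      e_out[[n_seg]] <- fr[ends[k - 1L]]
      c_out[[n_seg]] <- fr[ends[k - 1L] + 1L]
    }
  }
  data.frame(particle = as.integer(unlist(p_out)),
             direction = as.integer(unlist(d_out)),
             entry_frame = as.integer(unlist(e_out)),
             completion_frame = as.integer(unlist(c_out)))
}

# Exhaustive 2-D grid search for the largest clear sphere in a slice.
oracle_pore_radius <- function(frame, atoms, vdw, z, r_max = 1.5,
                               lim = 1.0, step = 0.01) {
  A <- frame[atoms, , drop = FALSE]
  vdw <- rep_len(vdw, nrow(A))
  cx <- seq(-lim, lim, by = step)
  grid <- as.matrix(expand.grid(x = cx, y = cx))
  best <- -Inf
  for (i in seq_len(nrow(A))) {
    d <- sqrt((grid[, 1] - A[i, 1])^2 + (grid[, 2] - A[i, 2])^2 +
                (z - A[i, 3])^2) - vdw[i]
    best <- if (i == 1) d else pmin(best, d)
  }
  min(max(max(best), 0), r_max)
}

# Minimal hand-built annotation: one role atom per subunit at given
# indices (bypasses file parsing entirely).
toy_annotation <- function(roles, ions = integer(), waters = integer(),
                           n_subunits = NULL) {
  if (is.null(n_subunits)) n_subunits <- length(roles[[1]])
  structure(list(n_subunits = n_subunits, roles = roles,
                 ion_indices = ions, water_oxygen_indices = waters),
            class = "channel_annotation")
}

# Four atoms at the corners of a square of side `side` in the z = z0
# plane, ordered counterclockwise (so subunits 1/3 and 2/4 are
# diagonal).
square_coords <- function(side = 1, z0 = 0) {
  h <- side / 2
  rbind(c(-h, -h, z0), c(h, -h, z0), c(h, h, z0), c(-h, h, z0))
}

# Toy multi-chain PDB with one TVGYG filter strand per chain (or two
# when `two_pore`), written to a temp file; returns the path.
write_toy_channel_pdb <- function(path = tempfile(fileext = ".pdb"),
                                  n_chains = 4L, two_pore = FALSE,
                                  drop_motif_chain = 0L) {
  res_atoms <- list(THR = c("CA", "OG1", "O", "CG2"), VAL = c("C", "O"),
                    GLY = c("O"), TYR = c("O"), GLY2 = c("O"))
  lines <- character()
  serial <- 0L
  strand <- function(chain, resid0, xoff) {
    resn <- c("THR", "VAL", "GLY", "TYR", "GLY")
    out <- character()
    for (i in seq_along(resn)) {
      atoms <- res_atoms[[c("THR", "VAL", "GLY", "TYR", "GLY2")[i]]]
      for (a in atoms) {
        serial <<- serial + 1L
        out <- c(out, sprintf(
          "ATOM  %5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial, a, resn[i], chain, resid0 + i - 1L,
          xoff + i * 1.0, serial %% 7 * 0.5, i * 3.0))
      }
    }
    out
  }
  for (ci in seq_len(n_chains)) {
    chain <- LETTERS[ci]
    if (ci == drop_motif_chain) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        serial, "CA", "ALA", chain, 10L, 0, 0, 0))
      next
    }
    lines <- c(lines, strand(chain, 59L, 0))
    if (two_pore) lines <- c(lines, strand(chain, 159L, 20))
  }
  writeLines(c(lines, "END"), path)
  path
}

# Small deterministic ensemble wrapper for geometry / series tests.
toy_ensemble <- function(coord_list, box = c(5, 5, 5), annotation = NULL) {
  reps <- lapply(coord_list, function(co)
    replica(co, box, times = seq_len(dim(co)[1])))
  trajectory_ensemble(reps, annotation = annotation)
}
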