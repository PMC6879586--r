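#' @useDynLib kgating, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

# Internal units: nm (length), ns (time), pA (current), mV (voltage),
# kT (energy), degrees (angles).  Source formats are converted on read.

ANGSTROM_PER_NM <- 10

# ---------------------------------------------------------------------------
# Structures (atom tables)
# ---------------------------------------------------------------------------

#' Read a structure file (PDB or GRO) into an atom table
#'
#' @param path file path; format chosen by extension (`.pdb` / `.gro`).
#' @return a `data.table` with columns `serial`, `name`, `resname`,
#'   `resid`, `chain` (NA for GRO), `x`, `y`, `z` in nm, and attribute
#'   `box` (nm, length 3 or NA).
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         pdb = read_pdb_atoms(path),
         gro = read_gro_frame(path),
         stop("unsupported structure format: .", ext))
}

read_pdb_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  at <- grepl("^(ATOM  |HETATM)", lines)
  # stop at first ENDMDL so multi-model files yield the first model
  endm <- which(grepl("^ENDMDL", lines))
  if (length(endm)) at[seq_along(at) > endm[1]] <- FALSE
  rec <- lines[at]
  if (!length(rec)) stop("format error: no ATOM records in ", path)
  dt <- data.table(
    serial  = suppressWarnings(as.integer(substr(rec, 7, 11))),
    name    = trimws(substr(rec, 13, 16)),
    resname = trimws(substr(rec, 18, 21)),
    chain   = trimws(substr(rec, 22, 22)),
    resid   = suppressWarnings(as.integer(substr(rec, 23, 26))),
    x = as.numeric(substr(rec, 31, 38)) / ANGSTROM_PER_NM,
    y = as.numeric(substr(rec, 39, 46)) / ANGSTROM_PER_NM,
    z = as.numeric(substr(rec, 47, 54)) / ANGSTROM_PER_NM)
  dt[chain == "", chain := NA_character_]
  cr <- grep("^CRYST1", lines, value = TRUE)
  box <- if (length(cr)) as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                                      substr(cr[1], 25, 33))) / ANGSTROM_PER_NM
         else rep(NA_real_, 3)
  setattr(dt, "box", box)
  dt[]
}

read_gro_frame <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[2]))
  if (is.na(n) || length(lines) < n + 3L)
    stop("format error: malformed GRO file ", path)
  rec <- lines[3:(2 + n)]
  dt <- data.table(
    serial  = seq_len(n),
    name    = trimws(substr(rec, 11, 15)),
    resname = trimws(substr(rec, 6, 10)),
    chain   = NA_character_,
    resid   = as.integer(substr(rec, 1, 5)),
    x = as.numeric(substr(rec, 21, 28)),
    y = as.numeric(substr(rec, 29, 36)),
    z = as.numeric(substr(rec, 37, 44)))
  box <- as.numeric(strsplit(trimws(lines[n + 3L]), "\\s+")[[1]])[1:3]
  setattr(dt, "box", box)
  dt[]
}

#' Write an atom table plus coordinates as a (multi-frame) GRO file
#'
#' @param topology atom table as returned by [read_structure()].
#' @param coords either an atoms x 3 matrix or a frames x atoms x 3
#'   array, nm.
#' @param path output path.
#' @param box length-3 vector or frames x 3 matrix of box lengths (nm).
#' @param times frame times (ns), written into the title line.
#' @export
write_gro <- function(topology, coords, path, box = attr(topology, "box"),
                      times = NULL) {
  if (length(dim(coords)) == 2L) coords <- array(coords, c(1L, dim(coords)))
  nf <- dim(coords)[1]; na <- dim(coords)[2]
  if (na != nrow(topology)) stop("format error: coords/topology atom mismatch")
  if (is.null(dim(box))) box <- matrix(rep(box, each = nf), nrow = nf)
  if (is.null(times)) times <- (seq_len(nf) - 1) * 1.0
  con <- file(path, "w"); on.exit(close(con))
  hdr <- sprintf("%5d%-5s%5s%5d",
                 topology$resid %% 100000L, topology$resname,
                 topology$name, topology$serial %% 100000L)
  for (f in seq_len(nf)) {
    writeLines(sprintf("synthetic channel t= %.6f", times[f] * 1000), con)
    writeLines(sprintf("%5d", na), con)
    writeLines(sprintf("%s%8.3f%8.3f%8.3f", hdr,
                       coords[f, , 1], coords[f, , 2], coords[f, , 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", box[f, 1], box[f, 2], box[f, 3]),
               con)
  }
  invisible(path)
}

#' Write coordinates as a PDB file (multi-MODEL when several frames)
#'
#' @inheritParams write_gro
#' @export
write_pdb <- function(topology, coords, path, box = attr(topology, "box")) {
  if (length(dim(coords)) == 2L) coords <- array(coords, c(1L, dim(coords)))
  nf <- dim(coords)[1]
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(box) && all(is.finite(box)))
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                       box[1] * 10, box[2] * 10, box[3] * 10), con)
  chain <- ifelse(is.na(topology$chain), "A", topology$chain)
  nm <- ifelse(nchar(topology$name) < 4L,
               sprintf(" %-3s", topology$name), topology$name)
  for (f in seq_len(nf)) {
    if (nf > 1L) writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                       topology$serial %% 100000L, nm,
                       substr(topology$resname, 1, 3), chain,
                       topology$resid %% 10000L,
                       coords[f, , 1] * 10, coords[f, , 2] * 10,
                       coords[f, , 3] * 10), con)
    if (nf > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Trajectories
# ---------------------------------------------------------------------------

#' Read a trajectory file into coordinates, box and times
#'
#' Supports multi-frame GRO (text), multi-MODEL PDB (text) and
#' CHARMM/NAMD-style DCD (binary).  XTC/TRR are not supported; convert
#' with standard MD tooling first.
#'
#' @param path trajectory file.
#' @param dt frame spacing in ns used when the format carries no times
#'   (DCD, PDB).
#' @return list with `coords` (frames x atoms x 3 array, nm), `box`
#'   (frames x 3, nm), `times` (ns).
#' @export
read_trajectory <- function(path, dt = 1.0) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         gro = read_gro_trajectory(path),
         dcd = read_dcd(path, dt = dt),
         pdb = read_pdb_trajectory(path, dt = dt),
         stop("unsupported trajectory format: .", ext))
}

read_gro_trajectory <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list(); boxes <- list(); times <- numeric()
  i <- 1L; f <- 0L
  while (i <= length(lines)) {
    n <- as.integer(trimws(lines[i + 1L]))
    if (is.na(n)) stop("format error: malformed GRO frame at line ", i)
    rec <- lines[(i + 2L):(i + 1L + n)]
    f <- f + 1L
    frames[[f]] <- cbind(as.numeric(substr(rec, 21, 28)),
                         as.numeric(substr(rec, 29, 36)),
                         as.numeric(substr(rec, 37, 44)))
    boxes[[f]] <- as.numeric(strsplit(trimws(lines[i + 2L + n]), "\\s+")[[1]])[1:3]
    tm <- regmatches(lines[i], regexpr("t=\\s*[-0-9.eE+]+", lines[i]))
    times[f] <- if (length(tm)) as.numeric(sub("t=\\s*", "", tm)) / 1000 else f - 1
    i <- i + 3L + n
  }
  na <- nrow(frames[[1]])
  if (!all(vapply(frames, nrow, 0L) == na))
    stop("format error: varying atom count across GRO frames")
  coords <- array(0, c(f, na, 3L))
  for (k in seq_len(f)) coords[k, , ] <- frames[[k]]
  list(coords = coords, box = do.call(rbind, boxes), times = times)
}

read_pdb_trajectory <- function(path, dt = 1.0) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (!length(starts)) {
    top <- read_pdb_atoms(path)
    coords <- array(unlist(top[, .(x, y, z)]), c(1L, nrow(top), 3L))
    bx <- attr(top, "box")
    return(list(coords = coords, box = matrix(bx, 1L), times = 0))
  }
  ends <- grep("^ENDMDL", lines)
  frames <- lapply(seq_along(starts), function(k) {
    rec <- lines[(starts[k] + 1L):(ends[k] - 1L)]
    rec <- rec[grepl("^(ATOM  |HETATM)", rec)]
    cbind(as.numeric(substr(rec, 31, 38)), as.numeric(substr(rec, 39, 46)),
          as.numeric(substr(rec, 47, 54))) / ANGSTROM_PER_NM
  })
  na <- nrow(frames[[1]])
  if (!all(vapply(frames, nrow, 0L) == na))
    stop("format error: varying atom count across PDB models")
  coords <- array(0, c(length(frames), na, 3L))
  for (k in seq_along(frames)) coords[k, , ] <- frames[[k]]
  cr <- grep("^CRYST1", lines, value = TRUE)
  bx <- if (length(cr)) as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                                     substr(cr[1], 25, 33))) / ANGSTROM_PER_NM
        else rep(NA_real_, 3)
  list(coords = coords, box = matrix(rep(bx, each = length(frames)), ncol = 3),
       times = (seq_along(frames) - 1) * dt)
}

#' Write a DCD trajectory (CHARMM format, unit cell records included)
#'
#' @param coords frames x atoms x 3 array, nm.
#' @param path output file.
#' @param box frames x 3 matrix or length-3 vector of box lengths, nm.
#' @export
write_dcd <- function(coords, path, box) {
  nf <- dim(coords)[1]; na <- dim(coords)[2]
  if (is.null(dim(box))) box <- matrix(rep(box, each = nf), nrow = nf)
  con <- file(path, "wb"); on.exit(close(con))
  rec <- function(writer) {
    # Fortran unformatted record: payload length, payload, payload length
    raw <- writer()
    writeBin(length(raw), con, size = 4L, endian = "little")
    writeBin(raw, con)
    writeBin(length(raw), con, size = 4L, endian = "little")
  }
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[10] <- 0L; icntrl[11] <- 1L  # unit-cell flag
  icntrl[20] <- 24L
  rec(function() c(writeBin(charToRaw("CORD"), raw()),
                   writeBin(icntrl, raw(), size = 4L, endian = "little")))
  title <- sprintf("%-80s", "synthetic trajectory written by kgating")
  rec(function() c(writeBin(1L, raw(), size = 4L, endian = "little"),
                   charToRaw(title)))
  rec(function() writeBin(as.integer(na), raw(), size = 4L, endian = "little"))
  for (f in seq_len(nf)) {
    cell <- c(box[f, 1] * 10, 0, box[f, 2] * 10, 0, 0, box[f, 3] * 10)
    rec(function() writeBin(cell, raw(), size = 8L, endian = "little"))
    for (d in 1:3)
      rec(function() writeBin(as.numeric(coords[f, , d] * 10), raw(),
                              size = 4L, endian = "little"))
  }
  invisible(path)
}

#' Read a DCD trajectory
#'
#' @param path DCD file.
#' @param dt frame spacing in ns (DCD stores no physical times).
#' @return same shape as [read_trajectory()].
#' @export
read_dcd <- function(path, dt = 1.0) {
  con <- file(path, "rb"); on.exit(close(con))
  rec <- function() {
    n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (!length(n)) return(NULL)
    payload <- readBin(con, "raw", n)
    n2 <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (n2 != n) stop("format error: corrupt DCD record")
    payload
  }
  hdr <- rec()
  if (rawToChar(hdr[1:4]) != "CORD") stop("format error: not a DCD file")
  icntrl <- readBin(hdr[-(1:4)], "integer", 20L, size = 4L, endian = "little")
  nf <- icntrl[1]; has_cell <- icntrl[11] == 1L
  rec()  # titles
  na <- readBin(rec(), "integer", 1L, size = 4L, endian = "little")
  coords <- array(0, c(nf, na, 3L))
  box <- matrix(NA_real_, nf, 3L)
  for (f in seq_len(nf)) {
    if (has_cell) {
      cell <- readBin(rec(), "double", 6L, size = 8L, endian = "little")
      box[f, ] <- cell[c(1, 3, 6)] / 10
    }
    for (d in 1:3)
      coords[f, , d] <- readBin(rec(), "double", na, size = 4L,
                                endian = "little") / 10
  }
  list(coords = coords, box = box, times = (seq_len(nf) - 1) * dt)
}

# ---------------------------------------------------------------------------
# Ensembles
# ---------------------------------------------------------------------------

#' Construct a replica of a trajectory ensemble
#'
#' @param coords frames x atoms x 3 array, nm.
#' @param box frames x 3 matrix of box lengths, nm.
#' @param times frame times in ns, strictly increasing.
#' @param meta named list (force field label, voltage mV, restraint
#'   scheme name, seed, ...).
#' @export
replica <- function(coords, box, times, meta = list()) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  nf <- dim(coords)[1]
  if (is.null(dim(box))) box <- matrix(rep(box, each = nf), nrow = nf)
  if (nrow(box) != nf || length(times) != nf)
    stop("replica(): frames mismatch between coords, box, times")
  if (nf > 1L && any(diff(times) <= 0))
    stop("replica(): times must be strictly increasing")
  if (any(box <= 0)) stop("replica(): box lengths must be positive")
  structure(list(coords = coords, box = box, times = as.numeric(times),
                 meta = meta), class = "kgating_replica")
}

#' Bundle replicas (plus optional annotation) into a trajectory ensemble
#'
#' @param replicas list of [replica()] objects sharing an atom count.
#' @param annotation optional [channel_annotation].
#' @export
trajectory_ensemble <- function(replicas, annotation = NULL) {
  if (!length(replicas)) stop("trajectory_ensemble(): no replicas")
  natoms <- vapply(replicas, function(r) dim(r$coords)[2], 0L)
  if (length(unique(natoms)) != 1L)
    stop("trajectory_ensemble(): replicas disagree on atom count")
  structure(list(replicas = replicas, annotation = annotation,
                 n_atoms = natoms[1]), class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  nf <- vapply(x$replicas, function(r) dim(r$coords)[1], 0L)
  cat(sprintf("trajectory_ensemble: %d replicas, %d atoms, %s frames each\n",
              length(x$replicas), x$n_atoms,
              paste(unique(nf), collapse = "/")))
  if (!is.null(x$annotation))
    cat(sprintf("  annotated: %d subunits, %d ions, %d waters\n",
                x$annotation$n_subunits, length(x$annotation$ion_indices),
                length(x$annotation$water_oxygen_indices)))
  invisible(x)
}

#' Total sampled time of an ensemble (ns)
#' @param ensemble a [trajectory_ensemble].
#' @export
total_time <- function(ensemble) {
  sum(vapply(ensemble$replicas, function(r) {
    t <- r$times
    if (length(t) < 2L) 0 else (t[length(t)] - t[1]) * length(t) / (length(t) - 1)
  }, 0))
}

#' Load structure + trajectories + roles into a trajectory ensemble
#'
#' One replica per trajectory file.  Coordinates are converted to nm
#' whatever the source format's native unit.
#'
#' @param structure_path PDB or GRO structure.
#' @param trajectory_paths character vector of trajectory files.
#' @param annotation_config optional role-config file path (see
#'   [read_role_config()]); when given, the annotation is attached.
#' @param meta list of per-replica metadata lists (recycled).
#' @param dt fallback frame spacing (ns) for formats without times.
#' @export
load_ensemble <- function(structure_path, trajectory_paths,
                          annotation_config = NULL, meta = list(), dt = 1.0) {
  top <- read_structure(structure_path)
  reps <- lapply(seq_along(trajectory_paths), function(i) {
    tr <- read_trajectory(trajectory_paths[i], dt = dt)
    if (dim(tr$coords)[2] != nrow(top))
      stop("format error: trajectory ", trajectory_paths[i], " has ",
           dim(tr$coords)[2], " atoms, structure has ", nrow(top))
    m <- if (length(meta)) meta[[((i - 1L) %% length(meta)) + 1L]] else list()
    replica(tr$coords, tr$box, tr$times, m)
  })
  ann <- if (!is.null(annotation_config))
    build_annotation(top, read_role_config(annotation_config)) else NULL
  trajectory_ensemble(reps, ann)
}

# ---------------------------------------------------------------------------
# Role annotation
# ---------------------------------------------------------------------------

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
            GLU = "E", GLY = "G", HIS = "H", HSD = "H", ILE = "I", LEU = "L",
            LYS = "K", MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T",
            TRP = "W", TYR = "Y", VAL = "V")

SF_MOTIF_ROLES <- list(  # role -> (motif position, atom name)
  T_OG1 = c(1L, "OG1"), T_O = c(1L, "O"), T_CA = c(1L, "CA"),
  V_C   = c(2L, "C"),   V_O = c(2L, "O"),
  G1_O  = c(3L, "O"),   Y_O = c(4L, "O"), G2_O = c(5L, "O"))

#' Read a role-configuration file
#'
#' Plain-text sections `[sf]`, `[gate]`, `[species]` with `key = value`
#' lines.  In `[sf]`, either `motif = TVGYG` (auto-detect, one hit per
#' filter strand) or explicit `ROLE = resid:atom` entries.  `[gate]`
#' entries are `ROLE = resid:atom[,resid:atom...]`.  `[species]` uses
#' `ion = RESNAME[,...]` and `water_oxygen = RESNAME:ATOM[,...]`.
#'
#' @param path config file.
#' @return nested named list by section.
#' @export
read_role_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list(); section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      cfg[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(section)) stop("annotation error: key outside section: ", ln)
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      cfg[[section]][[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
    } else stop("annotation error: unparsable config line: ", ln)
  }
  cfg
}

# Split chains: explicit PDB chains, else segment GRO-style tables at
# residue-number restarts.
chain_ids <- function(topology) {
  if (!all(is.na(topology$chain))) return(topology$chain)
  restart <- c(FALSE, diff(topology$resid) < 0)
  as.character(cumsum(restart) + 1L)
}

# Find TVGYG-like motif occurrences; returns list of integer vectors of
# residue row-groups (5 resids) per hit, in atom-table order.
find_motif_hits <- function(topology, motif = "TVGYG") {
  ch <- chain_ids(topology)
  hits <- list()
  for (cc in unique(ch)) {
    sub <- topology[ch == cc]
    res <- unique(sub[, .(resid, resname)])
    seq1 <- unname(AA3TO1[res$resname])
    seq1[is.na(seq1)] <- "X"
    sq <- paste(seq1, collapse = "")
    pos <- gregexpr(motif, sq, fixed = TRUE)[[1]]
    if (pos[1] == -1L)
      stop("annotation error: chain ", cc, " contains no ", motif, " motif")
    for (p in pos)
      hits[[length(hits) + 1L]] <-
        list(chain = cc, resids = res$resid[p:(p + nchar(motif) - 1L)])
  }
  hits
}

#' Build a channel annotation from a topology and a role config
#'
#' Maps structural roles (selectivity-filter oxygens, gate CA atoms,
#' side-chain contacts, ion and water species) to atom indices per
#' subunit.  The filter may be located by TVGYG motif search (exactly
#' one hit per chain strand required) or by explicit residue:atom
#' entries.  A dimeric two-pore (K2P-like) topology with two motifs per
#' chain yields four filter strands from two chains.
#'
#' @param topology atom table from [read_structure()].
#' @param role_config nested list from [read_role_config()] (or built
#'   in code with the same shape).
#' @return object of class `channel_annotation`.
#' @export
build_annotation <- function(topology, role_config) {
  topology <- as.data.table(topology)
  ch <- chain_ids(topology)
  roles <- list()

  find_atoms <- function(spec) {
    # "resid:atom[,resid:atom...]" -> atom indices across all subunits
    parts <- strsplit(spec, ",", fixed = TRUE)[[1]]
    idx <- integer()
    for (p in trimws(parts)) {
      ra <- strsplit(p, ":", fixed = TRUE)[[1]]
      if (length(ra) != 2L) stop("annotation error: bad atom spec '", p, "'")
      hit <- which(topology$resid == as.integer(ra[1]) & topology$name == ra[2])
      idx <- c(idx, hit)
    }
    sort(idx)
  }

  sf_cfg <- role_config$sf
  if (!is.null(sf_cfg$motif)) {
    hits <- find_motif_hits(topology, sf_cfg$motif)
    per_chain <- table(vapply(hits, `[[`, "", "chain"))
    n_strands <- length(hits)
    if (!n_strands %in% c(2L, 4L))
      stop("annotation error: found ", n_strands,
           " filter strands; expected 2 or 4")
    for (role in names(SF_MOTIF_ROLES)) {
      pos <- as.integer(SF_MOTIF_ROLES[[role]][1])
      atname <- SF_MOTIF_ROLES[[role]][2]
      idx <- vapply(hits, function(h) {
        j <- which(ch == h$chain & topology$resid == h$resids[pos] &
                     topology$name == atname)
        if (length(j) != 1L)
          stop("annotation error: role ", role, " not found once in chain ",
               h$chain, " resid ", h$resids[pos])
        j
      }, 0L)
      roles[[role]] <- idx
    }
  }
  # explicit entries override / supplement motif assignment
  for (key in setdiff(names(sf_cfg), "motif")) roles[[key]] <- find_atoms(sf_cfg[[key]])
  for (key in names(role_config$gate)) roles[[key]] <- find_atoms(role_config$gate[[key]])

  needed <- names(SF_MOTIF_ROLES)
  missing <- setdiff(needed, names(roles))
  if (length(missing))
    stop("annotation error: unmapped filter roles: ",
         paste(missing, collapse = ", "))
  n_strands <- length(roles[["T_OG1"]])
  for (role in needed)
    if (length(roles[[role]]) != n_strands)
      stop("annotation error: role ", role, " present in ",
           length(roles[[role]]), " strands, expected ", n_strands)

  ions <- integer(); waters <- integer()
  sp <- role_config$species
  if (!is.null(sp$ion)) {
    rn <- trimws(strsplit(sp$ion, ",")[[1]])
    ions <- which(topology$resname %in% rn)
  }
  if (!is.null(sp$water_oxygen)) {
    for (p in trimws(strsplit(sp$water_oxygen, ",")[[1]])) {
      ra <- strsplit(p, ":", fixed = TRUE)[[1]]
      waters <- c(waters, which(topology$resname == ra[1] &
                                  topology$name == ra[2]))
    }
    waters <- sort(unique(waters))
  }
  protein <- sort(unique(unlist(roles)))
  if (length(intersect(ions, waters)) || length(intersect(ions, protein)) ||
      length(intersect(waters, protein)))
    stop("annotation error: ion/water/protein index sets overlap")

  structure(list(n_subunits = n_strands, roles = roles,
                 ion_indices = ions, water_oxygen_indices = waters),
            class = "channel_annotation")
}

#' @export
print.channel_annotation <- function(x, ...) {
  cat(sprintf("channel_annotation: %d subunits, roles: %s\n", x$n_subunits,
              paste(names(x$roles), collapse = ", ")))
  cat(sprintf("  ions: %d, water oxygens: %d\n", length(x$ion_indices),
              length(x$water_oxygen_indices)))
  invisible(x)
}

# Fetch role atom indices, with a clear error for unknown roles.
role_indices <- function(annotation, role) {
  idx <- annotation$roles[[role]]
  if (is.null(idx)) stop("annotation error: role '", role, "' not annotated")
  idx
}

# ---------------------------------------------------------------------------
# Restraint schemes (activation-gate opening series)
# ---------------------------------------------------------------------------

#' Construct a gate restraint scheme
#'
#' Cross-subunit CA-CA distance restraints applied to the ends of the
#' pore-lining helices (P19 on M1, F97 on M2), opposite and adjacent
#' subunit pairs, with a harmonic force constant.
#'
#' @param name label, e.g. `"3LDC"`.
#' @param d_p19_opposite,d_p19_adjacent,d_f97_opposite,d_f97_adjacent
#'   restrained distances in nm.
#' @param k force constant, kJ/mol/nm^2.
#' @export
restraint_scheme <- function(name, d_p19_opposite, d_p19_adjacent,
                             d_f97_opposite, d_f97_adjacent, k = 1000) {
  d <- c(d_p19_opposite, d_p19_adjacent, d_f97_opposite, d_f97_adjacent)
  if (any(!is.finite(d)) || any(d <= 0))
    stop("restraint distances must be positive and finite")
  if (d_p19_opposite < d_p19_adjacent || d_f97_opposite < d_f97_adjacent)
    stop("opposite-pair distance must be >= adjacent (square-like gate)")
  structure(list(name = name, d_p19_opposite = d_p19_opposite,
                 d_p19_adjacent = d_p19_adjacent,
                 d_f97_opposite = d_f97_opposite,
                 d_f97_adjacent = d_f97_adjacent, k = k),
            class = "restraint_scheme")
}

#' Derive an opening series from a base restraint scheme
#'
#' Adds each offset uniformly to all four restrained distances (the
#' "base +/- x" construction used to sweep gate opening), preserving
#' the force constant.
#'
#' @param base a [restraint_scheme()].
#' @param offsets numeric offsets in nm.
#' @return list of restraint schemes named `"<base> + x"` / `"<base> - x"`.
#' @export
make_restraint_series <- function(base, offsets) {
  stopifnot(inherits(base, "restraint_scheme"), all(is.finite(offsets)))
  lapply(offsets, function(o) {
    nm <- if (o == 0) base$name else
      sprintf("%s %s %.3g", base$name, ifelse(o > 0, "+", "-"), abs(o))
    d <- c(base$d_p19_opposite, base$d_p19_adjacent,
           base$d_f97_opposite, base$d_f97_adjacent) + o
    if (any(d <= 0)) stop("offset ", o, " gives non-positive distance")
    restraint_scheme(nm, d[1], d[2], d[3], d[4], base$k)
  })
}

# ---------------------------------------------------------------------------
# Tidy tables
# ---------------------------------------------------------------------------

#' Write records as a tidy (long-format) CSV table
#'
#' One observation per row.  Values survive a write/read round trip to
#' full double precision.
#'
#' @param records a data.frame/data.table, or a list of named lists
#'   sharing one schema.
#' @param path output CSV path.
#' @export
write_tidy <- function(records, path) {
  if (is.data.frame(records)) {
    dt <- as.data.table(records)
  } else if (is.list(records)) {
    if (!length(records)) stop("write_tidy(): empty record list needs a schema; pass a 0-row data.frame")
    nms <- lapply(records, names)
    if (!all(vapply(nms, identical, TRUE, y = nms[[1]])))
      stop("schema error: records do not share one schema")
    dt <- rbindlist(lapply(records, as.data.table))
  } else stop("schema error: unsupported records type")
  fwrite(dt, path)
  invisible(path)
}

#' Read a tidy CSV table written by [write_tidy()]
#' @param path CSV path.
#' @export
read_tidy <- function(path) fread(path)
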