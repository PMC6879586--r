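# Order parameters tracked along gating: cross-subunit distances at the
# activation gate (P19/F97/A88), filter opening at T59, side-chain
# contacts, helix bend, and rigid-body superposition for mode analyses.

frame_coords <- function(replica_or_matrix, frame = NULL) {
  x <- replica_or_matrix
  if (inherits(x, "kgating_replica")) x <- x$coords
  if (length(dim(x)) == 3L) {
    if (is.null(frame)) stop("frame index required for a trajectory array")
    return(x[frame, , , drop = TRUE])
  }
  x
}

# Diagonal pairing of 4 subunits: partner of subunit 1 is the farthest
# role atom in the supplied frame; held fixed by callers across frames.
subunit_pairing <- function(coords, annotation, role = "A88") {
  idx <- role_indices(annotation, role)
  if (length(idx) != 4L) stop("pairing needs 4 subunits for role ", role)
  p <- coords[idx, , drop = FALSE]
  d1 <- sqrt(rowSums((p[2:4, , drop = FALSE] -
                        matrix(p[1, ], 3, 3, byrow = TRUE))^2))
  opp <- 1L + which.max(d1)
  rest <- setdiff(2:4, opp)
  list(opposite = list(c(1L, opp), rest),
       adjacent = list(c(1L, rest[1]), c(1L, rest[2]),
                       c(opp, rest[1]), c(opp, rest[2])))
}

#' Cross-subunit distance for a structural role
#'
#' For a tetramer, `"opposite"` averages the two diagonal CA-CA pair
#' distances (the convention used for gate-opening measures at P19, F97
#' and A88; asymmetric subunit placement is absorbed by the average),
#' `"adjacent"` averages the four neighbour pairs, and
#' `"mean_all_pairs"` averages all unordered pairs.  For a dimer all
#' modes reduce to the single pair distance.
#'
#' @param frame atoms x 3 coordinate matrix (nm), or a replica plus
#'   `frame_index`.
#' @param annotation [channel_annotation].
#' @param role annotated role name (e.g. `"A88"`, `"T_CA"`).
#' @param mode `"opposite"`, `"adjacent"` or `"mean_all_pairs"`.
#' @param pairing optional pairing from an earlier frame (see
#'   [order_parameter_series()]); recomputed from `frame` when NULL.
#' @param frame_index frame number when `frame` is a replica.
#' @return distance in nm.
#' @export
cross_distance <- function(frame, annotation, role,
                           mode = c("opposite", "adjacent", "mean_all_pairs"),
                           pairing = NULL, frame_index = NULL) {
  mode <- match.arg(mode)
  xyz <- frame_coords(frame, frame_index)
  idx <- role_indices(annotation, role)
  if (length(idx) < 2L) stop("annotation error: role ", role,
                             " present in fewer than 2 subunits")
  p <- xyz[idx, , drop = FALSE]
  n <- nrow(p)
  pair_d <- function(pr) sqrt(sum((p[pr[1], ] - p[pr[2], ])^2))
  if (n == 2L) return(pair_d(c(1L, 2L)))
  if (mode == "mean_all_pairs") {
    cmb <- utils::combn(n, 2L)
    return(mean(apply(cmb, 2L, pair_d)))
  }
  if (n != 4L) stop("opposite/adjacent modes require 2 or 4 subunits")
  if (is.null(pairing)) pairing <- subunit_pairing(xyz, annotation, role)
  mean(vapply(pairing[[mode]], pair_d, 0))
}

#' Within-subunit contact distance between two roles
#'
#' Mean over subunits of the atom-atom distance between `roleA` and
#' `roleB` in the same subunit (e.g. the I84 side-chain tip to T59 CG
#' hydrophobic contact).
#'
#' @inheritParams cross_distance
#' @param roleA,roleB annotated roles with equal subunit counts.
#' @return distance in nm.
#' @export
contact_distance <- function(frame, annotation, roleA, roleB,
                             frame_index = NULL) {
  xyz <- frame_coords(frame, frame_index)
  ia <- role_indices(annotation, roleA)
  ib <- role_indices(annotation, roleB)
  if (length(ia) != length(ib))
    stop("annotation error: subunit count differs between ", roleA,
         " and ", roleB)
  mean(sqrt(rowSums((xyz[ia, , drop = FALSE] - xyz[ib, , drop = FALSE])^2)))
}

#' Helix bend angle from three landmark atoms
#'
#' Bend is 180 degrees minus the angle at the hinge, averaged over
#' subunits; a straight helix gives 0.
#'
#' @param frame atoms x 3 coordinate matrix (nm).
#' @param triplets list (one per subunit) of integer vectors
#'   `c(start, hinge, end)` of atom indices.
#' @return bend in degrees.
#' @export
helix_bend <- function(frame, triplets) {
  if (is.numeric(triplets)) triplets <- list(triplets)
  bends <- vapply(triplets, function(tr) {
    a <- frame[tr[1], ]; h <- frame[tr[2], ]; b <- frame[tr[3], ]
    v1 <- a - h; v2 <- b - h
    n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
    if (n1 < 1e-12 || n2 < 1e-12)
      stop("helix_bend(): coincident landmark atoms")
    cosang <- max(-1, min(1, sum(v1 * v2) / (n1 * n2)))
    180 - acos(cosang) * 180 / pi
  }, 0)
  mean(bends)
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation + translation minimising the RMSD of
#' `fit_atoms` between `coords` and `reference`, and applies it to all
#' atoms of `coords`.  Reflections are excluded (determinant +1).
#'
#' @param coords atoms x 3 matrix to transform (nm).
#' @param reference atoms x 3 matrix with the same atom count.
#' @param fit_atoms indices of atoms used for the fit (default: all).
#' @return transformed atoms x 3 matrix; attributes `rotation` (3 x 3),
#'   `translation` and `rmsd` (fit-atom RMSD after superposition).
#' @export
superpose <- function(coords, reference, fit_atoms = seq_len(nrow(coords))) {
  if (length(fit_atoms) < 3L)
    stop("superpose(): need at least 3 fit atoms")
  A <- coords[fit_atoms, , drop = FALSE]
  B <- reference[fit_atoms, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  if (qr(A0)$rank < 2L) stop("superpose(): fit atoms are collinear")
  s <- svd(crossprod(A0, B0))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  out <- sweep(sweep(coords, 2, ca) %*% R, 2, cb, `+`)
  fit <- out[fit_atoms, , drop = FALSE]
  rmsd <- sqrt(mean(rowSums((fit - B)^2)))
  structure(out, rotation = R, translation = cb - c(ca %*% R), rmsd = rmsd)
}

#' Per-frame order-parameter series over an ensemble
#'
#' Computes a named scalar order parameter for every frame of every
#' replica.  For cross distances the diagonal pairing is fixed from the
#' first frame of the first replica so noisy frames cannot flip the
#' pairing.
#'
#' @param ensemble [trajectory_ensemble] with annotation, or pass
#'   `annotation` explicitly.
#' @param what `"cross"` or `"contact"`.
#' @param role role for `"cross"`; for `"contact"` supply `roleA`,
#'   `roleB`.
#' @param mode pairing mode for cross distances.
#' @param annotation optional [channel_annotation] override.
#' @param roleA,roleB contact roles.
#' @return a `data.table` with columns `replica`, `frame`, `time`,
#'   `value` (class `order_parameter_series`, attribute `name`).
#' @export
order_parameter_series <- function(ensemble, what = c("cross", "contact"),
                                   role = NULL, mode = "opposite",
                                   annotation = NULL, roleA = NULL,
                                   roleB = NULL) {
  what <- match.arg(what)
  ann <- if (!is.null(annotation)) annotation else ensemble$annotation
  if (is.null(ann)) stop("annotation error: ensemble is not annotated")
  pairing <- NULL
  if (what == "cross" && length(role_indices(ann, role)) == 4L)
    pairing <- subunit_pairing(ensemble$replicas[[1]]$coords[1, , ], ann, role)
  out <- rbindlist(lapply(seq_along(ensemble$replicas), function(r) {
    rep <- ensemble$replicas[[r]]
    nf <- dim(rep$coords)[1]
    vals <- vapply(seq_len(nf), function(f) {
      xyz <- rep$coords[f, , ]
      if (what == "cross")
        cross_distance(xyz, ann, role, mode, pairing = pairing)
      else contact_distance(xyz, ann, roleA, roleB)
    }, 0)
    data.table(replica = r, frame = seq_len(nf), time = rep$times,
               value = vals)
  }))
  setattr(out, "name",
          if (what == "cross") paste0(role, "_", mode)
          else paste0(roleA, "-", roleB))
  setattr(out, "class", c("order_parameter_series", class(out)))
  out[]
}

#' Per-replica means of an order-parameter series
#' @param series result of [order_parameter_series()].
#' @export
series_replica_means <- function(series) {
  as.data.table(series)[, .(mean_value = mean(value)), by = replica]
}
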