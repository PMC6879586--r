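# Partial-least-squares functional mode analysis: the collective
# coordinate motion maximally correlated with a scalar order parameter
# (here typically the filter opening at the S4 threonine), and its
# ensemble-weighted variant (ewMCM = covariance-weighted regression
# vector), cross-validated on held-out frames.

#' Flatten (and superpose) ensemble frames into a coordinate matrix
#'
#' Every frame is rigid-body superposed onto the ensemble mean of the
#' selected atoms (one refinement pass), then flattened to a row of the
#' frames x 3M matrix.
#'
#' @param ensemble [trajectory_ensemble].
#' @param atoms atom indices to analyse (default: all annotated role
#'   atoms, the pseudo-mainchain).
#' @param superpose remove rigid-body motion first (default TRUE).
#' @return list: `X` (frames x 3M, nm), `replica` (frame origin),
#'   `atoms`, `mean` (M x 3 reference used for the fit).
#' @export
fma_coordinate_matrix <- function(ensemble, atoms = NULL, superpose = TRUE) {
  if (is.null(atoms)) {
    ann <- ensemble$annotation
    if (is.null(ann)) stop("give `atoms` or an annotated ensemble")
    atoms <- sort(unique(unlist(ann$roles)))
  }
  frames <- list(); repid <- integer()
  for (r in seq_along(ensemble$replicas)) {
    co <- ensemble$replicas[[r]]$coords
    for (f in seq_len(dim(co)[1])) {
      frames[[length(frames) + 1L]] <- co[f, atoms, , drop = TRUE]
      repid <- c(repid, r)
    }
  }
  if (superpose) {
    ref <- frames[[1]]
    frames <- lapply(frames, function(fr) unclass(superpose(fr, ref)))
    m <- Reduce(`+`, frames) / length(frames)
    frames <- lapply(frames, function(fr) unclass(superpose(fr, m)))
    ref <- Reduce(`+`, frames) / length(frames)
  } else ref <- Reduce(`+`, frames) / length(frames)
  X <- do.call(rbind, lapply(frames, as.vector))
  list(X = X, replica = repid, atoms = atoms, mean = ref)
}

# Contiguous half split per replica: first half of each replica's
# frames trains, the second half validates (respects autocorrelation).
contiguous_half_split <- function(replica_ids) {
  train <- logical(length(replica_ids))
  for (r in unique(replica_ids)) {
    i <- which(replica_ids == r)
    train[i[seq_len(floor(length(i) / 2))]] <- TRUE
  }
  train
}

#' Fit a PLS functional mode model (matrix interface)
#'
#' PLS1 with NIPALS-style sequential deflation on the training half:
#' each component's weight vector is `X' y` of the deflated data.  The
#' regression vector beta maps centred coordinates to the target; the
#' maximally correlated mode (MCM) is beta normalised, and the
#' ensemble-weighted MCM (ewMCM) is the training covariance applied to
#' beta, normalised and oriented so that increasing projection
#' increases the target.
#'
#' @param X frames x 3M coordinate matrix (already superposed).
#' @param y scalar target per frame.
#' @param n_components number of PLS components (reduced with a warning
#'   when the data rank is lower).
#' @param train logical frame mask (TRUE = training); default first
#'   half.
#' @param mean_structure optional M x 3 matrix stored for
#'   interpolation.
#' @return object of class `collective_mode`.
#' @export
pls_fma <- function(X, y, n_components = 30L, train = NULL,
                    mean_structure = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (length(y) != n) stop("target length must equal frame count")
  if (stats::sd(y) == 0) stop("value error: constant target (zero variance)")
  if (is.null(train)) train <- seq_len(n) <= floor(n / 2)
  if (sum(train) < 10L || sum(!train) < 10L)
    stop("value error: fewer than 10 frames per half")
  Xt <- X[train, , drop = FALSE]; yt <- y[train]
  xbar <- colMeans(Xt); ybar <- mean(yt)
  Xc <- sweep(Xt, 2, xbar); yc <- yt - ybar
  p <- ncol(X)
  k <- min(n_components, nrow(Xt) - 1L, p)
  W <- matrix(0, p, k); P <- matrix(0, p, k); Q <- numeric(k)
  Xk <- Xc; yk <- yc
  used <- 0L
  for (a in seq_len(k)) {
    w <- crossprod(Xk, yk)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break  # rank exhausted
    w <- w / nw
    t <- Xk %*% w
    tt <- sum(t^2)
    if (tt < 1e-24) break
    pl <- crossprod(Xk, t) / tt
    q <- sum(yk * t) / tt
    Xk <- Xk - t %*% t(pl)
    yk <- yk - q * t
    used <- a
    W[, a] <- w; P[, a] <- pl; Q[a] <- q
  }
  if (used == 0L) stop("value error: target uncorrelated with coordinates")
  if (used < min(n_components, k))
    warning("rank deficient: reduced to ", used, " PLS components")
  W <- W[, seq_len(used), drop = FALSE]
  P <- P[, seq_len(used), drop = FALSE]
  Q <- Q[seq_len(used)]
  beta <- as.numeric(W %*% solve(crossprod(P, W), Q))
  mcm <- beta / sqrt(sum(beta^2))
  # ensemble weighting: covariance of the training coordinates
  Cbeta <- crossprod(Xc, Xc %*% beta) / (nrow(Xc) - 1L)
  ewmcm <- as.numeric(Cbeta) / sqrt(sum(Cbeta^2))
  predict_y <- function(Xnew) as.numeric(sweep(Xnew, 2, xbar) %*% beta) + ybar
  yhat_all <- predict_y(X)
  r_train <- stats::cor(yhat_all[train], y[train])
  r_valid <- stats::cor(yhat_all[!train], y[!train])
  proj_all <- as.numeric(sweep(X, 2, xbar) %*% ewmcm)
  if (stats::cor(proj_all, y) < 0) {
    ewmcm <- -ewmcm
    proj_all <- -proj_all
  }
  structure(list(mean = if (!is.null(mean_structure)) mean_structure
                 else if (p %% 3L == 0L) matrix(xbar, ncol = 3L)
                 else xbar,
                 xbar = xbar, ybar = ybar, beta = beta, mcm = mcm,
                 ewmcm = ewmcm, n_components = used, r_train = r_train,
                 r_valid = r_valid,
                 proj_range = range(proj_all), train = train,
                 predict = predict_y),
            class = "collective_mode")
}

#' @export
print.collective_mode <- function(x, ...) {
  cat(sprintf("collective_mode: %d PLS components, r_train=%.4f, r_valid=%.4f\n",
              x$n_components, x$r_train, x$r_valid))
  invisible(x)
}

#' Fit a PLS functional mode model on an ensemble
#'
#' Convenience wrapper: superposes the frames, builds the coordinate
#' matrix, extracts the target series, and fits [pls_fma()] on the
#' contiguous first half of every replica.
#'
#' @param ensemble annotated [trajectory_ensemble].
#' @param target an [order_parameter_series()] (matched by frame
#'   order) or numeric vector of length total frames.
#' @param n_components PLS components (default 30).
#' @param atoms atom selection (default all annotated roles).
#' @return `collective_mode` (see [pls_fma()]).
#' @export
fit_pls_fma <- function(ensemble, target, n_components = 30L, atoms = NULL) {
  cm <- fma_coordinate_matrix(ensemble, atoms = atoms)
  y <- if (is.data.frame(target)) target$value else as.numeric(target)
  if (length(y) != nrow(cm$X))
    stop("target length must equal total frame count")
  train <- contiguous_half_split(cm$replica)
  mode <- pls_fma(cm$X, y, n_components = n_components, train = train,
                  mean_structure = cm$mean)
  mode$atoms <- cm$atoms
  mode
}

#' Train/validation correlation of a fitted mode
#'
#' Re-evaluates the fitted model on the training and held-out halves;
#' validation frames never enter the fit.
#'
#' @param mode a `collective_mode`.
#' @param X frames x 3M matrix (same construction as the fit).
#' @param y target per frame.
#' @return named vector `c(r_train, r_valid)`.
#' @export
cross_validate <- function(mode, X, y) {
  if (sum(mode$train) < 10L || sum(!mode$train) < 10L)
    stop("value error: fewer than 10 frames per half")
  yhat <- mode$predict(as.matrix(X))
  c(r_train = stats::cor(yhat[mode$train], y[mode$train]),
    r_valid = stats::cor(yhat[!mode$train], y[!mode$train]))
}

#' Interpolate structures along the ewMCM
#'
#' Structures `mean + alpha * ewmcm` for `alpha` linearly spaced
#' between the minimum and maximum observed frame projections.
#'
#' @param mode fitted `collective_mode`.
#' @param n_structures number of interpolated structures (>= 2).
#' @return list of M x 3 coordinate matrices; attribute `alpha`.
#' @export
interpolate_mode <- function(mode, n_structures = 21L) {
  if (n_structures < 2L) stop("value error: n_structures must be >= 2")
  alpha <- seq(mode$proj_range[1], mode$proj_range[2],
               length.out = n_structures)
  mvec <- mode$xbar
  out <- lapply(alpha, function(a)
    matrix(mvec + a * mode$ewmcm, ncol = 3L))
  attr(out, "alpha") <- alpha
  out
}

#' Principal component analysis of ensemble coordinates
#'
#' Eigen-decomposition of the coordinate covariance of superposed
#' frames, for comparison with the correlation-driven ewMCM.
#'
#' @param X frames x 3M matrix (superposed), or an annotated
#'   [trajectory_ensemble].
#' @param n_modes number of modes to return.
#' @param atoms atom selection when `X` is an ensemble.
#' @return list: `modes` (3M x n_modes, unit columns), `eigenvalues`
#'   (non-increasing, all of them), `mean`.
#' @export
pca_modes <- function(X, n_modes = 5L, atoms = NULL) {
  if (inherits(X, "trajectory_ensemble"))
    X <- fma_coordinate_matrix(X, atoms = atoms)$X
  X <- as.matrix(X)
  if (n_modes > ncol(X)) stop("value error: n_modes exceeds 3M")
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar)
  C <- crossprod(Xc) / (nrow(Xc) - 1L)
  e <- eigen(C, symmetric = TRUE)
  list(modes = e$vectors[, seq_len(n_modes), drop = FALSE],
       eigenvalues = pmax(e$values, 0), mean = xbar)
}
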