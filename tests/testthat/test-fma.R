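test_that("noiseless rank-1 target is fit perfectly with one component", {
  fx <- generate_fma_ensemble(400, 20, snr = Inf, seed = 2,
                              sigma_iso = 0)
  m <- pls_fma(fx$X, fx$target, n_components = 1)
  expect_equal(m$r_train, 1, tolerance = 1e-6)
  expect_equal(m$r_valid, 1, tolerance = 1e-6)
  expect_gt(abs(sum(m$ewmcm * fx$mode)), 0.999)
  expect_equal(sqrt(sum(m$mcm^2)), 1, tolerance = 1e-12)
  expect_equal(sqrt(sum(m$ewmcm^2)), 1, tolerance = 1e-12)
  # constant target -> value error
  expect_error(pls_fma(fx$X, rep(1, 400)), "constant target")
  # too few frames per half -> value error
  expect_error(pls_fma(fx$X[1:12, ], fx$target[1:12]), "10 frames")
})

test_that("planted mode is recovered at generative R^2 = 0.92", {
  snr <- 0.92 / (1 - 0.92)
  fx <- generate_fma_ensemble(2000, 50, snr = snr, seed = 5)
  expect_equal(fx$r2_generative, 0.92)
  m <- pls_fma(fx$X, fx$target, n_components = 30)
  # r_valid ~ sqrt(R^2) = 0.959 within 0.02 (coordinate noise and the
  # finite validation half both enter)
  expect_lt(abs(m$r_valid - sqrt(0.92)), 0.02)
  expect_gte(abs(sum(m$ewmcm * fx$mode)), 0.95)
  expect_gte(m$r_train, m$r_valid - 0.05)
})

test_that("cross-validation separates halves and bounds null targets", {
  fx <- generate_fma_ensemble(600, 30, snr = Inf, seed = 6,
                              sigma_iso = 0)
  m <- pls_fma(fx$X, fx$target, n_components = 1)
  cv <- cross_validate(m, fx$X, fx$target)
  expect_equal(unname(cv), c(1, 1), tolerance = 1e-6)
  # pure-noise target: |r_valid| < 3/sqrt(n_valid) for most seeds
  ok <- vapply(1:10, function(s) {
    fx2 <- generate_fma_ensemble(800, 10, snr = 1, seed = 100 + s)
    set.seed(300 + s)
    y_noise <- stats::rnorm(800)
    m2 <- suppressWarnings(pls_fma(fx2$X, y_noise, n_components = 5))
    abs(m2$r_valid) < 3 / sqrt(400)
  }, TRUE)
  expect_gte(mean(ok), 0.8)
  # overfitting direction: r_train >= r_valid - 0.05 across seeds
  dir_ok <- vapply(1:8, function(s) {
    fx3 <- generate_fma_ensemble(500, 20, snr = 3, seed = 200 + s)
    m3 <- pls_fma(fx3$X, fx3$target, n_components = 10)
    m3$r_train >= m3$r_valid - 0.05
  }, TRUE)
  expect_true(all(dir_ok))
})

test_that("full-rank PLS equals the least-squares oracle", {
  # 50-atom instance, k = rank(X): PLS prediction must match lm()
  set.seed(12)
  n <- 80; p <- 30
  X <- matrix(rnorm(n * p), n, p)
  beta_true <- rnorm(p)
  y <- X %*% beta_true + rnorm(n, sd = 0.3)
  train <- seq_len(n) <= 40
  m <- pls_fma(X, y, n_components = 30, train = train)
  fit <- lm(y[train] ~ X[train, ])
  beta_ols <- coef(fit)[-1]
  expect_equal(unname(m$beta), unname(beta_ols), tolerance = 1e-6)
})

test_that("mode interpolation spans the observed projection range", {
  fx <- generate_fma_ensemble(300, 15, snr = 5, seed = 9)
  m <- pls_fma(fx$X, fx$target, n_components = 5)
  ends <- interpolate_mode(m, 2)
  expect_length(ends, 2L)
  proj <- function(st) sum((as.vector(st) - m$xbar) * m$ewmcm)
  expect_equal(proj(ends[[1]]), m$proj_range[1], tolerance = 1e-9)
  expect_equal(proj(ends[[2]]), m$proj_range[2], tolerance = 1e-9)
  tri <- interpolate_mode(m, 3)
  expect_equal(as.vector(tri[[2]]),
               as.vector((tri[[1]] + tri[[3]]) / 2), tolerance = 1e-12)
  expect_error(interpolate_mode(m, 1), "value error")
})

test_that("PCA finds planted modes and satisfies the trace identity", {
  fx <- generate_fma_ensemble(1500, 25, snr = Inf, seed = 14,
                              sigma_iso = 0.03)
  pc <- pca_modes(fx$X, 3)
  expect_gte(abs(sum(pc$modes[, 1] * fx$mode)), 0.99)
  expect_true(all(diff(pc$eigenvalues) <= 1e-12))
  Xc <- scale(fx$X, scale = FALSE)
  expect_equal(sum(pc$eigenvalues), sum(apply(Xc, 2, var)),
               tolerance = 1e-9)
  # isotropic noise: no dominant mode at frames >> 3M
  set.seed(15)
  iso <- matrix(rnorm(4000 * 30), 4000, 30)
  pci <- pca_modes(iso, 2)
  expect_lt(pci$eigenvalues[1] / pci$eigenvalues[2], 1.5)
  expect_error(pca_modes(iso, 31), "value error")
})

test_that("modes are invariant to rigid-body motion after superposition", {
  sp <- synth_spec(n_replicas = 2, g = c(1.5, 1.8), t_total = 15,
                   dt = 0.1, seed = 16, n_ions = 0, n_cavity_water = 0)
  gen <- generate_ensemble(sp)
  t59 <- order_parameter_series(gen$ensemble, "cross", role = "T_CA")
  m1 <- fit_pls_fma(gen$ensemble, t59, n_components = 5)
  # rotate + translate every frame of a copy
  th <- 0.6
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  ens2 <- gen$ensemble
  for (r in seq_along(ens2$replicas)) {
    co <- ens2$replicas[[r]]$coords
    for (f in seq_len(dim(co)[1]))
      co[f, , ] <- sweep(co[f, , ] %*% R, 2, c(1, -2, 0.5), `+`)
    ens2$replicas[[r]]$coords <- co
  }
  m2 <- fit_pls_fma(ens2, t59, n_components = 5)
  expect_equal(abs(m1$r_valid), abs(m2$r_valid), tolerance = 1e-6)
  # the mode itself agrees up to the rotation applied to each atom
  M <- length(m1$ewmcm) / 3
  v1 <- matrix(m1$ewmcm, ncol = 3)
  v2 <- matrix(m2$ewmcm, ncol = 3)
  align <- abs(sum(v1 * (v2 %*% t(R))))
  expect_gt(align, 0.98)
})

test_that("gate-driven coupling concentrates the ewMCM on moving atoms", {
  # gate motion linearly drives the filter spread: the ewMCM's squared
  # displacement should live on the atoms whose radius follows g or s
  sp <- synth_spec(n_replicas = 2, g = 1.66, t_total = 100, dt = 0.1,
                   seed = 17, n_ions = 0, n_cavity_water = 0,
                   sigma_g = 0.06, sigma_T = 0.005, sigma_xyz = 0.01)
  gen <- generate_ensemble(sp)
  t59 <- order_parameter_series(gen$ensemble, "cross", role = "T_CA")
  m <- fit_pls_fma(gen$ensemble, t59, n_components = 10)
  expect_gt(m$r_valid, 0.8)
  tpl <- kgating:::synth_atom_template(sp)
  moving_res <- tpl$resid[tpl$cg != 0 | tpl$cs != 0]
  atom_resid <- rep(tpl$resid, 4)[match(m$atoms,
                                        seq_len(4 * nrow(tpl)))]
  w <- rowSums(matrix(m$ewmcm, ncol = 3)^2)
  frac_moving <- sum(w[atom_resid %in% moving_res]) / sum(w)
  expect_gte(frac_moving, 0.7)
})
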