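# Direct access to the crossing state machine for constructed z traces
# (single particle, constant bounds, no radial check).
run_counter <- function(z, z_low = 0, z_high = 1.5, delta = 0.1,
                        lz = 100) {
  nf <- length(z)
  res <- kgating:::.count_crossings_core(
    matrix(z, ncol = 1), matrix(numeric(0), 0, 0), rep(z_low, nf),
    rep(z_high, nf), rep(lz, nf), delta, 0.6, FALSE)
  data.frame(direction = res$direction, entry = res$entry_frame,
             done = res$completion_frame)
}

test_that("voltage from applied field is the exact product", {
  expect_equal(compute_voltage(30, 10), 300)
  expect_equal(compute_voltage(0, 10), 0)
  expect_equal(compute_voltage(15, 10), 150)
  # linear in both arguments
  expect_equal(compute_voltage(2 * 30, 10), 2 * compute_voltage(30, 10))
  expect_equal(compute_voltage(30, 2 * 10), 2 * compute_voltage(30, 10))
  expect_error(compute_voltage(30, 0), "positive")
})

test_that("hand-traced state machine events", {
  # rises from below to above: one outward event completing on the
  # last frame (frames 1-based)
  ev <- run_counter(c(-1.0, -0.2, 0.7, 1.6, 2.0))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$direction, 1L)
  expect_equal(ev$done, 5L)
  expect_equal(ev$entry, 2L)  # last frame definitively below
  # excursion into the filter that returns -> no event
  expect_equal(nrow(run_counter(c(-1.0, 0.5, 1.0, 0.3, -1.0))), 0L)
  # inward crossing is the mirror image
  ev2 <- run_counter(c(2.0, 0.7, -0.5))
  expect_equal(ev2$direction, -1L)
  # hysteresis: z touching the bound but not the margin does not flip
  expect_equal(nrow(run_counter(c(-1.0, 1.55, -1.0, 1.55, -1.0))), 0L)
  # direct below->above jump with no inside frame still counts
  expect_equal(nrow(run_counter(c(-1.0, 2.0))), 1L)
})

test_that("periodic wraps are never crossings", {
  # jump of 18 with box 20 is a wrap: particle re-enters below, no event
  ev <- run_counter(c(2.5, 2.6, -15.5, -15.4), lz = 20)
  expect_equal(nrow(ev), 0L)
  # the same displacement in a huge box is a genuine (inward) crossing
  ev2 <- run_counter(c(2.5, 2.6, -15.5, -15.4), lz = 1e6)
  expect_equal(ev2$direction, -1L)
})

test_that("radial check vetoes off-axis traversals", {
  nf <- 5L
  z <- c(-1, -0.2, 0.7, 1.7, 2.0)
  r_on <- matrix(c(2, 2, 0.1, 2, 2), ncol = 1)   # passes near the axis
  r_off <- matrix(c(2, 2, 1.5, 2, 2), ncol = 1)  # stays off-axis
  args <- list(matrix(z, ncol = 1), z_low = rep(0, nf),
               z_high = rep(1.5, nf), lz = rep(100, nf))
  on <- kgating:::.count_crossings_core(args[[1]], r_on, args$z_low,
                                        args$z_high, args$lz, 0.1, 0.6,
                                        TRUE)
  off <- kgating:::.count_crossings_core(args[[1]], r_off, args$z_low,
                                         args$z_high, args$lz, 0.1, 0.6,
                                         TRUE)
  expect_length(on$direction, 1L)
  expect_length(off$direction, 0L)
})

test_that("counter matches the run-length oracle on random walks", {
  set.seed(99)
  for (trial in 1:5) {
    np <- 60L; nf <- 800L
    z <- apply(matrix(rnorm(nf * np, sd = 0.35), nf, np), 2, cumsum) +
      rep(runif(np, -4, 4), each = nf)
    res <- kgating:::.count_crossings_core(
      z, matrix(numeric(0), 0, 0), rep(0, nf), rep(1.5, nf),
      rep(1e6, nf), 0.1, 0.6, FALSE)
    got <- data.frame(particle = res$particle, direction = res$direction,
                      entry_frame = res$entry_frame,
                      completion_frame = res$completion_frame)
    want <- oracle_count_crossings(z, 0, 1.5, delta = 0.1)
    o <- order(got$particle, got$completion_frame)
    ow <- order(want$particle, want$completion_frame)
    expect_equal(got[o, ], want[ow, ], ignore_attr = TRUE)
  }
})

test_that("conservation and antisymmetry invariants hold", {
  set.seed(123)
  np <- 40L; nf <- 600L
  z <- apply(matrix(rnorm(nf * np, sd = 0.4), nf, np), 2, cumsum) +
    rep(runif(np, -3, 3), each = nf)
  core <- function(zm) kgating:::.count_crossings_core(
    zm, matrix(numeric(0), 0, 0), rep(0, nrow(zm)), rep(1.5, nrow(zm)),
    rep(1e6, nrow(zm)), 0.1, 0.6, FALSE)
  res <- core(z)
  # conservation: per-particle net events equal the change of
  # compartment label between first and last definitive sighting
  net <- rep(0L, np)
  if (length(res$particle))
    for (k in seq_along(res$particle))
      net[res$particle[k]] <- net[res$particle[k]] + res$direction[k]
  expect_equal(2L * net, res$last_side - res$first_side)
  # antisymmetry: reversing time swaps outward and inward counts
  rev_res <- core(z[nf:1, , drop = FALSE])
  expect_equal(sum(res$direction > 0), sum(rev_res$direction < 0))
  expect_equal(sum(res$direction < 0), sum(rev_res$direction > 0))
})

test_that("current conversion and bootstrap CI behave", {
  ev1 <- data.frame(particle = 1L, species = "ion", direction = 1L,
                    entry_frame = 1L, completion_frame = 2L,
                    replica = 1L)
  cur <- compute_current(ev1, replica_times = 1, n_replicas = 1)
  expect_equal(cur$current, 160.2176634, tolerance = 1e-9)
  # no events -> 0 pA
  cur0 <- compute_current(ev1[0, ], replica_times = 100, n_replicas = 4)
  expect_equal(cur0$current, 0)
  expect_equal(cur0$ci_low, 0)
  # 53 net crossings in 500 ns -> ~17 pA (the single-channel scale)
  ev53 <- data.frame(particle = 1L, species = "ion",
                     direction = rep(1L, 53), entry_frame = 1L,
                     completion_frame = 2L, replica = 1L)
  expect_equal(compute_current(ev53, 500, n_replicas = 1)$current,
               53 * 160.2176634 / 500, tolerance = 1e-9)
  expect_equal(round(compute_current(ev53, 500, n_replicas = 1)$current,
                     2), 16.98)
  expect_error(compute_current(ev1, 0, n_replicas = 1), "positive")
})

test_that("cavity census counts within the A88 sphere", {
  ann <- toy_annotation(list(A88 = 1:4), ions = 10:11, waters = 5:9)
  co <- matrix(0, 11, 3)
  co[1:4, ] <- square_coords(0.5, z0 = 0)          # A88 ring, COM origin
  co[5:7, 1] <- 0.5                                 # 3 waters at 0.5 nm
  co[8:9, 1] <- 1.5                                 # 2 waters at 1.5 nm
  co[10, 3] <- 0.2; co[11, 3] <- 3                  # 1 ion in, 1 out
  cen <- cavity_census(co, ann, radius = 1.0)
  expect_equal(unname(cen), c(3L, 1L))
  # brute-force all-pairs check on a random frame
  set.seed(5)
  co2 <- matrix(runif(33, -2, 2), 11, 3)
  cen2 <- cavity_census(co2, ann, radius = 1.0)
  com <- colMeans(co2[1:4, ])
  bw <- sum(sqrt(colSums((t(co2[5:9, ]) - com)^2)) < 1)
  bi <- sum(sqrt(colSums((t(co2[10:11, ]) - com)^2)) < 1)
  expect_equal(unname(cen2), c(bw, bi))
  expect_error(cavity_census(co, ann, radius = -1), "positive")
})
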