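# Build a bare filter frame: 4 subunits x 6 oxygen rings at given
# plane heights (ring radius 0.25), plus optional particles appended.
make_filter_frame <- function(planes = c(0, 0.3, 0.6, 0.9, 1.2, 1.5),
                              extra = NULL) {
  th <- (0:3) * pi / 2
  prot <- do.call(rbind, lapply(seq_along(planes), function(k)
    cbind(0.25 * cos(th), 0.25 * sin(th), planes[k])))
  roles <- lapply(seq_along(planes), function(k) (k - 1L) * 4L + 1:4)
  names(roles) <- c("T_OG1", "T_O", "V_O", "G1_O", "Y_O", "G2_O")
  frame <- rbind(prot, extra)
  n <- nrow(prot)
  list(frame = frame, roles = roles, n_protein = n)
}

test_that("site boundaries come from the oxygen-ring planes", {
  ff <- make_filter_frame()
  ann <- toy_annotation(ff$roles)
  geom <- site_boundaries(ff$frame, ann)
  expect_true(geom$valid)
  expect_equal(unname(geom$planes), c(0, 0.3, 0.6, 0.9, 1.2, 1.5))
  expect_equal(unname(geom$sites["S4", ]), c(0, 0.3))
  expect_equal(unname(geom$sites["S0", ]), c(1.2, 1.5))
  expect_equal(unname(geom$sites["Scav", ]), c(-0.4, 0))
  # one subunit displaced +0.04 shifts the 4-subunit plane mean +0.01
  f2 <- ff$frame
  f2[1, 3] <- f2[1, 3] + 0.04
  expect_equal(unname(site_boundaries(f2, ann)$planes[1]), 0.01)
  # swapped planes flag the frame instead of crashing
  ff_bad <- make_filter_frame(planes = c(0, 0.6, 0.3, 0.9, 1.2, 1.5))
  expect_false(site_boundaries(ff_bad$frame,
                               toy_annotation(ff_bad$roles))$valid)
})

test_that("classify_site applies the closest-particle tie-break", {
  ff <- make_filter_frame(extra = rbind(c(0, 0, 0.15),    # ion at S4 centre
                                        c(0, 0, 0.75)))   # water at S2 centre
  ann <- toy_annotation(ff$roles, ions = ff$n_protein + 1L,
                        waters = ff$n_protein + 2L)
  geom <- site_boundaries(ff$frame, ann)
  expect_equal(classify_site(ff$frame, geom, "S4", ann), "ion")
  expect_equal(classify_site(ff$frame, geom, "S2", ann), "water")
  expect_equal(classify_site(ff$frame, geom, "S3", ann), "vacant")
  # both species in one site: water closer to the centre wins
  ff2 <- make_filter_frame(extra = rbind(c(0, 0, 0.25),   # ion, 0.10 off
                                         c(0, 0, 0.10)))  # water, 0.05 off
  ann2 <- toy_annotation(ff2$roles, ions = ff2$n_protein + 1L,
                         waters = ff2$n_protein + 2L)
  geom2 <- site_boundaries(ff2$frame, ann2)
  expect_equal(classify_site(ff2$frame, geom2, "S4", ann2), "water")
  # off-axis particle beyond r_site does not occupy the site
  ff3 <- make_filter_frame(extra = rbind(c(0.5, 0, 0.15)))
  ann3 <- toy_annotation(ff3$roles, ions = ff3$n_protein + 1L)
  geom3 <- site_boundaries(ff3$frame, ann3)
  expect_equal(classify_site(ff3$frame, geom3, "S4", ann3), "vacant")
})

test_that("occupancy fractions sum to one and match planted states", {
  # 2 replicas x 4 frames with a K+ pinned at the S4 centre throughout
  ff <- make_filter_frame(extra = rbind(c(0, 0, 0.15)))
  ann <- toy_annotation(ff$roles, ions = ff$n_protein + 1L)
  co <- array(rep(ff$frame, each = 4), c(4, nrow(ff$frame), 3))
  ens <- toy_ensemble(list(co, co), annotation = ann)
  occ <- occupancy_table(ens, n_boot = 100L)
  expect_equal(occ$fraction[occ$site == "S4" & occ$species == "ion"], 1)
  sums <- tapply(occ$fraction, occ$site, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # all frames distorted -> empty-result error
  ffb <- make_filter_frame(planes = c(0, 0.6, 0.3, 0.9, 1.2, 1.5))
  annb <- toy_annotation(ffb$roles)
  cob <- array(rep(ffb$frame, each = 2), c(2, nrow(ffb$frame), 3))
  expect_error(occupancy_table(toy_ensemble(list(cob), annotation = annb)),
               "empty result")
})

test_that("synthetic occupancies match the hop-chain stationary law", {
  sp <- synth_spec(n_replicas = 2, g = 1.66, t_total = 150, dt = 0.1,
                   seed = 31, n_ions = 1, kw_in = 0, sigma_g = 0,
                   sigma_T = 0, cavity_cap = 1)
  gen <- generate_ensemble(sp)
  s <- sp$coupling_a + sp$coupling_c * 1.66
  pi_th <- hop_stationary(sp, s)
  occ <- occupancy_table(gen$ensemble, n_boot = 100L)
  comp <- do.call(rbind, gen$truth$comp)
  for (site in c("S4", "S3", "S2", "S1", "S0")) {
    emp <- occ$fraction[occ$site == site & occ$species == "ion"]
    # Monte-Carlo SE from 30 contiguous batches of the truth series
    x <- as.integer(comp[, 1] == match(site, SYNTH_COMPARTMENTS))
    bm <- colMeans(matrix(x[1:(30 * (length(x) %/% 30))], ncol = 30))
    se <- sd(bm) / sqrt(30)
    expect_lt(abs(emp - pi_th[[site]]), 3 * se + 1e-3)
  }
})

test_that("water occupancy of S4/S1 rises with the planted opening", {
  frac_w <- vapply(c(1.66, 1.85, 2.0), function(g) {
    sp <- synth_spec(n_replicas = 2, g = g, t_total = 40, dt = 0.1,
                     seed = 77)
    occ <- occupancy_table(generate_ensemble(sp)$ensemble, n_boot = 50L)
    mean(occ$fraction[occ$site %in% c("S4", "S1") &
                        occ$species == "water"])
  }, 0)
  expect_true(all(diff(frac_w) > 0))
})

test_that("carbonyl flips are detected against the reference orientation", {
  # 1 replica, 8 frames, 4 subunits; C at the V_O ring displaced in -z
  ff <- make_filter_frame()
  n <- nrow(ff$frame)
  frame <- rbind(ff$frame, sweep(ff$frame[ff$roles$V_O, ], 2,
                                 c(0, 0, 0.12)))
  roles <- c(ff$roles, list(V_C = n + 1:4))
  ann <- toy_annotation(roles)
  co <- array(rep(frame, each = 8), c(8, nrow(frame), 3))
  ens <- toy_ensemble(list(co), annotation = ann)
  fl <- detect_flips(ens, role_c = "V_C", role_o = "V_O")
  expect_equal(attr(fl, "flip_fraction"), 0)
  # rotate one subunit's O by 180 degrees about its C for half the
  # frames of a second replica (the first replica sets the reference):
  # flip fraction there is 1/4 subunits * 1/2 the time = 0.125
  co2 <- co
  vo1 <- ff$roles$V_O[1]
  co2[1:4, vo1, 3] <- co2[1:4, n + 1, 3] - 0.12
  ens2 <- toy_ensemble(list(co, co2), annotation = ann)
  fl2 <- detect_flips(ens2, role_c = "V_C", role_o = "V_O")
  expect_equal(mean(fl2$flipped[fl2$replica == 2]), 0.125)
  expect_equal(mean(fl2$flipped[fl2$replica == 1]), 0)
  # zero threshold: any noise flips
  co3 <- co + array(rnorm(length(co), sd = 1e-4), dim(co))
  ens3 <- toy_ensemble(list(co3), annotation = ann)
  fl3 <- detect_flips(ens3, role_c = "V_C", role_o = "V_O",
                      theta_flip = 0)
  expect_gt(attr(fl3, "flip_fraction"), 0.9)
})
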