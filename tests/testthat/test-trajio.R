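test_that("structure and trajectory formats round-trip coordinates", {
  sp <- synth_spec(n_replicas = 1, t_total = 0.5, dt = 0.1, seed = 11)
  gen <- generate_ensemble(sp)
  top <- gen$topology
  co <- gen$ensemble$replicas[[1]]$coords
  box <- gen$ensemble$replicas[[1]]$box

  # GRO: fixed-format text with 3 decimals -> 1e-3 nm precision
  g <- tempfile(fileext = ".gro")
  write_gro(top, co, g, box = box,
            times = gen$ensemble$replicas[[1]]$times)
  tr <- read_trajectory(g)
  expect_equal(dim(tr$coords), dim(co))
  expect_lt(max(abs(tr$coords - co)), 1e-3 + 1e-12)
  expect_equal(tr$box[1, ], box[1, ], tolerance = 1e-4)
  expect_equal(tr$times, gen$ensemble$replicas[[1]]$times,
               tolerance = 1e-6)

  # PDB: Angstrom text, 1e-3 A -> 1e-4 nm
  p <- tempfile(fileext = ".pdb")
  write_pdb(top, co, p, box = box[1, ])
  trp <- read_trajectory(p, dt = 0.1)
  expect_lt(max(abs(trp$coords - co)), 1e-4 + 1e-12)

  # DCD: float32 binary, ~1e-6 relative
  d <- tempfile(fileext = ".dcd")
  write_dcd(co, d, box)
  trd <- read_dcd(d, dt = 0.1)
  expect_lt(max(abs(trd$coords - co)), 1e-6)
  expect_equal(trd$box, box, tolerance = 1e-6)
})

test_that("load_ensemble attaches replicas and validates atom counts", {
  sp <- synth_spec(n_replicas = 2, t_total = 0.5, dt = 0.1, seed = 12)
  gen <- generate_ensemble(sp)
  dir <- tempfile(); dir.create(dir)
  sfile <- file.path(dir, "structure.gro")
  write_gro(gen$topology, gen$ensemble$replicas[[1]]$coords[1, , ],
            sfile, box = sp$box)
  tfiles <- vapply(1:2, function(r) {
    f <- file.path(dir, sprintf("rep%d.gro", r))
    write_gro(gen$topology, gen$ensemble$replicas[[r]]$coords, f,
              box = gen$ensemble$replicas[[r]]$box,
              times = gen$ensemble$replicas[[r]]$times)
    f
  }, "")
  cfg <- file.path(dir, "roles.cfg")
  write_synth_role_config(cfg)
  ens <- load_ensemble(sfile, tfiles, annotation_config = cfg)
  expect_s3_class(ens, "trajectory_ensemble")
  expect_length(ens$replicas, 2L)
  expect_equal(ens$annotation$n_subunits, 4L)
  expect_lt(max(abs(ens$replicas[[2]]$coords -
                      gen$ensemble$replicas[[2]]$coords)), 1e-3 + 1e-12)
  # reloaded annotation maps the same atoms as the generated one
  expect_equal(ens$annotation$roles, gen$annotation$roles)
  expect_equal(ens$annotation$ion_indices, gen$annotation$ion_indices)

  # wrong atom count -> format error
  bad <- file.path(dir, "bad.gro")
  write_gro(gen$topology[1:10, ],
            gen$ensemble$replicas[[1]]$coords[, 1:10, , drop = FALSE],
            bad, box = sp$box)
  expect_error(load_ensemble(sfile, bad), "format error")
})

test_that("load_ensemble is unit-invariant across source formats", {
  # identical coordinates written as GRO (nm) and PDB (Angstrom) load
  # to the same internal nm values
  sp <- synth_spec(n_replicas = 1, t_total = 0.3, dt = 0.1, seed = 13)
  gen <- generate_ensemble(sp)
  co <- round(gen$ensemble$replicas[[1]]$coords, 3)  # common precision
  g <- tempfile(fileext = ".gro"); p <- tempfile(fileext = ".pdb")
  write_gro(gen$topology, co, g, box = sp$box)
  write_pdb(gen$topology, co, p, box = sp$box)
  expect_equal(read_trajectory(g)$coords, read_trajectory(p)$coords,
               tolerance = 1e-9)
})

test_that("build_annotation finds filter strands by motif", {
  # 4-chain tetramer: one TVGYG per chain
  top4 <- read_structure(write_toy_channel_pdb(n_chains = 4))
  cfg <- list(sf = list(motif = "TVGYG"))
  ann <- build_annotation(top4, cfg)
  expect_equal(ann$n_subunits, 4L)
  expect_length(ann$roles$T_OG1, 4L)
  expect_true(all(top4$name[ann$roles$G2_O] == "O"))
  expect_true(all(top4$resname[ann$roles$T_OG1] == "THR"))

  # dimeric two-pore topology: two motifs per chain -> 4 strands
  top2 <- read_structure(write_toy_channel_pdb(n_chains = 2,
                                               two_pore = TRUE))
  ann2 <- build_annotation(top2, cfg)
  expect_equal(ann2$n_subunits, 4L)
  expect_equal(sort(unique(top2$chain[ann2$roles$T_CA])), c("A", "B"))

  # chain lacking the motif -> annotation error
  topbad <- read_structure(write_toy_channel_pdb(n_chains = 4,
                                                 drop_motif_chain = 2))
  expect_error(build_annotation(topbad, cfg), "annotation error")
})

test_that("restraint series reproduces the opening-sweep arithmetic", {
  # printed restraint tables: base crystal-structure schemes offset
  # uniformly on all four distances, force constant preserved
  ldc <- restraint_scheme("3LDC", 3.6, 2.55, 3.66, 2.6, k = 1000)
  s <- make_restraint_series(ldc, 0.6)[[1]]
  expect_equal(c(s$d_p19_opposite, s$d_p19_adjacent, s$d_f97_opposite,
                 s$d_f97_adjacent, s$k), c(4.2, 3.15, 4.26, 3.2, 1000))
  lnq <- restraint_scheme("1LNQ", 4.3, 3.0, 4.0, 2.8, k = 1000)
  s2 <- make_restraint_series(lnq, -0.2)[[1]]
  expect_equal(c(s2$d_p19_opposite, s2$d_p19_adjacent, s2$d_f97_opposite,
                 s2$d_f97_adjacent), c(4.1, 2.8, 3.8, 2.6))
  # zero offset is the identity
  expect_equal(make_restraint_series(ldc, 0)[[1]], ldc)
  # additivity: series(base, a+b) == series(series(base, a), b)
  ab <- make_restraint_series(ldc, 0.5)[[1]]
  a_b <- make_restraint_series(make_restraint_series(ldc, 0.2)[[1]],
                               0.3)[[1]]
  for (f in c("d_p19_opposite", "d_p19_adjacent", "d_f97_opposite",
              "d_f97_adjacent", "k"))
    expect_equal(ab[[f]], a_b[[f]])
  expect_error(make_restraint_series(ldc, -5), "non-positive")
})

test_that("tidy tables round-trip losslessly", {
  dt <- data.frame(site = rep(c("S1", "S2", "S3", "S4"), each = 3),
                   species = rep(c("ion", "water", "vacant"), 4),
                   fraction = runif(12), level = "g=1.66")
  f <- tempfile(fileext = ".csv")
  write_tidy(dt, f)
  back <- read_tidy(f)
  expect_equal(back$fraction, dt$fraction, tolerance = 1e-9)
  expect_equal(back$site, dt$site)
  expect_equal(nrow(back), 12L)

  # list-of-records interface and schema error
  recs <- list(list(a = 1, b = "x"), list(a = 2, b = "y"))
  write_tidy(recs, f)
  expect_equal(read_tidy(f)$a, c(1, 2))
  expect_error(write_tidy(list(list(a = 1), list(b = 2)), f), "schema")

  # empty table -> header-only file
  write_tidy(dt[0, ], f)
  expect_equal(nrow(read_tidy(f)), 0L)
  expect_equal(names(read_tidy(f)), names(dt))
})
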