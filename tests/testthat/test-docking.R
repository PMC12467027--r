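test_that("Metropolis decisions follow the closed-form acceptance law", {
  # downhill always accepted
  expect_true(all(metropolis_accept(rep(-1, 100), 300)))
  expect_true(all(metropolis_accept(rep(0, 100), 0)))
  # uphill at T = 0 always rejected
  expect_false(any(metropolis_accept(rep(1, 100), 0)))
  # at delta E = kB T ln 2 the acceptance probability is exactly 1/2
  set.seed(61)
  acc <- metropolis_accept(rep(KB_KCAL * 300 * log(2), 2e4), 300)
  expect_equal(mean(acc), 0.5, tolerance = 0.015)
})

test_that("a stage with zero move caps returns the start pose unchanged", {
  fm <- random_fragmaps(n = 6, seed = 71)
  lig <- make_ligand("steroid_acid")
  p <- pose(lig, sweep(lig$xyz, 2, c(1, 1, 1), "+"))
  st <- protocol_stage(200, 300, 0, 0, 0)
  set.seed(72)
  out <- run_stage(p, st, fm)
  expect_identical(out$final$xyz, p$xyz)
})

test_that("stage sampling is seed-deterministic", {
  fm <- random_fragmaps(n = 8, seed = 81)
  lig <- make_ligand("steroid_glycine")
  p <- pose(lig, sweep(lig$xyz, 2, c(2, 2, 2), "+"))
  st <- protocol_stage(2000, 300, 1, 180, 180)
  set.seed(82); a <- run_stage(p, st, fm)
  set.seed(82); b <- run_stage(p, st, fm)
  expect_identical(a$final$xyz, b$final$xyz)
  expect_identical(a$best$lgfe, b$best$lgfe)
})

test_that("the chain is strictly downhill at zero temperature", {
  fm <- random_fragmaps(n = 8, seed = 91)
  lig <- make_ligand("steroid_acid")
  p <- pose(lig, sweep(lig$xyz, 2, c(3, 3, 3), "+"))
  st <- protocol_stage(5000, 0, 0.5, 30, 30)
  set.seed(92)
  out <- run_stage(p, st, fm, return_log = TRUE)
  expect_identical(out$n_uphill_at_T0, 0L)
  lg <- out$log
  expect_false(any(lg$accepted & lg$delta_e > 0 & lg$temperature <= 0))
  # and the annealing ramp is linear from start to end
  st_sa <- protocol_stage(1000, c(300, 0), 0.2, 9, 9)
  set.seed(93)
  sa <- run_stage(p, st_sa, fm, return_log = TRUE)
  expect_equal(sa$log$temperature[1], 300)
  expect_equal(sa$log$temperature[1000], 0)
  expect_equal(diff(sa$log$temperature),
               rep(-300 / 999, 999), tolerance = 1e-9)
})

test_that("docking a probe recovers the exhaustive voxel optimum", {
  spec <- grid_spec(dims = c(16, 16, 16))
  fm <- make_fragmap_set(list(planted_well(c(8, 8, 8), -5, 2, "APOLAR")),
                         spec)
  probe <- make_ligand("probe_atom")
  dr <- dock(probe, start_region(center = c(8, 8, 8), radius = 6), fm,
             seed = 101,
             protocol = docking_protocol(max_cycles = 100,
                                         check_interval = 100))
  enum_min <- min(fm$maps$APOLAR$values)
  expect_equal(dr$best_pose$lgfe, enum_min, tolerance = 1e-6)
  expect_true(dr$converged)
  # seed reproducibility end-to-end
  dr2 <- dock(probe, start_region(center = c(8, 8, 8), radius = 6), fm,
              seed = 101,
              protocol = docking_protocol(max_cycles = 100,
                                          check_interval = 100))
  expect_identical(dr$best_pose$xyz, dr2$best_pose$xyz)
  expect_identical(dr$n_cycles_run, dr2$n_cycles_run)
})

test_that("docking on a flat zero map scores zero and ranks poses consistently", {
  spec <- grid_spec(dims = c(10, 10, 10))
  fm <- make_fragmap_set(list(), spec)
  probe <- make_ligand("probe_atom")
  prot <- docking_protocol(
    stages = list(protocol_stage(500, 300, 1, 180, 180),
                  protocol_stage(500, 300, 0.2, 9, 60),
                  protocol_stage(2000, c(300, 0), 0.2, 9, 9)),
    max_cycles = 10, check_interval = 10)
  dr <- dock(probe, start_region(center = c(5, 5, 5), radius = 4), fm,
             protocol = prot, seed = 111)
  expect_identical(dr$best_pose$lgfe, 0)
  expect_true(all(vapply(dr$top_poses, function(p) p$lgfe, numeric(1)) == 0))
  expect_true(dr$converged)
})

test_that("with two wells the deeper one wins", {
  spec <- grid_spec(dims = c(26, 12, 12))
  fm <- make_fragmap_set(list(planted_well(c(5, 6, 6), -5, 2, "APOLAR"),
                              planted_well(c(20, 6, 6), -2, 2, "APOLAR")),
                         spec)
  probe <- make_ligand("probe_atom")
  dr <- dock(probe, start_region(lower = c(0, 0, 0), upper = c(25, 11, 11)),
             fm, seed = 121,
             protocol = docking_protocol(max_cycles = 100,
                                         check_interval = 100))
  expect_lt(sqrt(sum((pose_com(dr$best_pose) - c(5, 6, 6))^2)), 1.5)
  expect_equal(dr$best_pose$lgfe, min(fm$maps$APOLAR$values),
               tolerance = 1e-6)
})

test_that("the incumbent-best LGFE never increases across a cycle's stages", {
  fm <- steroid_well_maps(c(12, 12, 12))
  lig <- make_ligand("steroid_acid")
  set.seed(131)
  p <- pose(lig, sweep(sweep(lig$xyz, 2, center_of_mass(lig$xyz, lig$masses)),
                       2, c(12, 12, 12), "+"))
  start_lgfe <- lgfe(p, fm)$lgfe
  for (st in docking_protocol()$stages) {
    out <- run_stage(p, st, fm)
    # a stage's best is never worse than its start or its final pose
    expect_lte(out$best$lgfe, start_lgfe + 1e-12)
    expect_lte(out$best$lgfe, out$final$lgfe + 1e-12)
    p <- out$final
    start_lgfe <- out$final$lgfe
  }
  # at the dock level the reported best is the minimum over retained poses
  dr <- dock(lig, start_region(center = c(12, 12, 12), radius = 6), fm,
             protocol = docking_protocol(
               stages = docking_protocol()$stages, max_cycles = 6,
               check_interval = 6), seed = 132)
  lgfes <- vapply(dr$top_poses, function(q) q$lgfe, numeric(1))
  expect_identical(dr$best_pose$lgfe, min(lgfes))
  expect_true(all(diff(lgfes) >= 0))
})

test_that("protocol constructors validate and docking rejects bad regions", {
  expect_error(protocol_stage(0, 300, 1, 180, 180), "n_steps")
  expect_error(protocol_stage(10, 300, -1, 180, 180), "caps")
  expect_error(docking_protocol(convergence_tol = 0), "convergence_tol")
  expect_error(docking_protocol(max_cycles = 10, check_interval = 100),
               "check_interval")
  expect_error(start_region(), "empty")
  spec <- grid_spec(dims = c(6, 6, 6))
  fm <- make_fragmap_set(list(), spec)
  expect_error(dock(make_ligand("probe_atom"),
                    start_region(center = c(100, 0, 0), radius = 1), fm),
               "outside")
})
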