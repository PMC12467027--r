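test_that("planted wells produce the stated free-energy field", {
  spec <- grid_spec(dims = c(11, 11, 11))
  w <- planted_well(c(5, 5, 5), -3, 2, "APOLAR")
  fm <- make_fragmap_set(list(w), spec, noise_sd = 0)
  expect_equal(gfe_at(fm$maps$APOLAR, c(5, 5, 5)), -3, tolerance = 1e-12)
  # empty well list, no noise: all voxels 0
  fm0 <- make_fragmap_set(list(), spec, noise_sd = 0)
  expect_true(all(vapply(fm0$maps, function(m) all(m$values == 0),
                         logical(1))))
  # two wells: global minimum voxel at the deeper center (exhaustive scan)
  w2 <- planted_well(c(2, 2, 2), -1.5, 1.5, "APOLAR")
  fm2 <- make_fragmap_set(list(w, w2), spec, noise_sd = 0)
  v <- fm2$maps$APOLAR$values
  am <- which(v == min(v), arr.ind = TRUE)[1, ]
  expect_equal(unname(am), c(6, 6, 6))  # voxel centered at (5,5,5)
})

test_that("fragmap generation is rejected for out-of-box wells and is seed-deterministic", {
  spec <- grid_spec(dims = c(6, 6, 6))
  expect_error(make_fragmap_set(list(planted_well(c(20, 0, 0), -1, 1,
                                                  "MEOO")), spec),
               "outside")
  w <- list(planted_well(c(3, 3, 3), -2, 1.5, "HBACC"))
  a <- make_fragmap_set(w, spec, noise_sd = 0.3, seed = 11)
  b <- make_fragmap_set(w, spec, noise_sd = 0.3, seed = 11)
  d <- make_fragmap_set(w, spec, noise_sd = 0.3, seed = 12)
  expect_identical(a$maps$HBACC$values, b$maps$HBACC$values)
  expect_false(identical(a$maps$HBACC$values, d$maps$HBACC$values))
})

test_that("with zero noise each map's argmin voxel is its deepest planted center", {
  spec <- grid_spec(dims = c(13, 13, 13))
  wells <- list(planted_well(c(3, 3, 3), -2.5, 1.5, "MEOO"),
                planted_well(c(9, 9, 9), -1.0, 1.5, "MEOO"),
                planted_well(c(6, 6, 6), -4.0, 2.0, "ACEC"))
  fm <- make_fragmap_set(wells, spec, noise_sd = 0)
  am_meoo <- which(fm$maps$MEOO$values == min(fm$maps$MEOO$values),
                   arr.ind = TRUE)[1, ]
  am_acec <- which(fm$maps$ACEC$values == min(fm$maps$ACEC$values),
                   arr.ind = TRUE)[1, ]
  expect_equal(unname(am_meoo) - 1, c(3, 3, 3))
  expect_equal(unname(am_acec) - 1, c(6, 6, 6))
})

test_that("exclusion shapes mark exactly the covered voxel centers", {
  spec <- grid_spec(dims = c(21, 21, 21))
  ex <- make_exclusion(list(list(kind = "sphere", center = c(0, 0, 0),
                                 radius = 3)), spec)
  expect_true(is_excluded(ex, c(0, 0, 0)))
  expect_false(is_excluded(ex, c(10, 0, 0)))
  ex0 <- make_exclusion(list(), spec)
  expect_false(any(ex0$mask))
  # slab z < 0 on a grid symmetric about z = 0 excludes exactly half
  spec_s <- grid_spec(origin = c(0, 0, -1.5), dims = c(2, 2, 4))
  exs <- make_exclusion(list(list(kind = "slab", axis = 3,
                                  min = -Inf, max = -1e-9)), spec_s)
  expect_identical(sum(exs$mask), 2L * 2L * 2L)
})

test_that("ligand templates have the documented topology", {
  p <- make_ligand("probe_atom")
  expect_identical(nrow(p$atoms), 1L)
  expect_identical(nrow(p$bonds), 0L)
  expect_length(p$dihedrals, 0)
  # rod: collinear, ring-free, only terminal torsions -> none rotatable
  r <- make_ligand("rigid_rod")
  expect_length(r$dihedrals, 0)
  expect_identical(nrow(r$bonds), 2L)
  # conjugation extends the tail
  acid <- make_ligand("steroid_acid")
  gly <- make_ligand("steroid_glycine")
  tau <- make_ligand("steroid_taurine")
  expect_gt(nrow(gly$atoms), nrow(acid$atoms))
  expect_gt(nrow(tau$atoms), nrow(gly$atoms))
  # shared 4-ring core: first core atoms identical across templates
  n_core <- 19  # 18 ring carbons + ring hydroxyl oxygen
  expect_identical(acid$xyz[seq_len(n_core), ], gly$xyz[seq_len(n_core), ])
  expect_identical(acid$xyz[seq_len(n_core), ], tau$xyz[seq_len(n_core), ])
  expect_gt(length(acid$dihedrals), 0)
  expect_error(make_ligand("nope"), "probe_atom")
})

test_that("synthetic trajectories honor sigma, seed and frame count", {
  cs0 <- covariance_spec(4, 0, frame_interval = 0.5)
  t0 <- make_trajectory(cs0, 5, seed = 1)
  expect_true(all(t0$trajectory$coords[1, , ] == t0$trajectory$coords[3, , ]))
  expect_identical(unname(t0$truth$rmsf[1]), 0)
  cs <- covariance_spec(6, 0.5)
  a <- make_trajectory(cs, 50, seed = 5)
  b <- make_trajectory(cs, 50, seed = 5)
  expect_identical(a$trajectory$coords, b$trajectory$coords)
  expect_identical(dim(a$trajectory$coords), c(50L, 6L, 3L))
  expect_equal(unname(a$truth$rmsf), rep(0.5 * sqrt(3), 6))
})

test_that("covariance construction rejects invalid correlation structures", {
  expect_error(covariance_spec(6, 0.5, domains = list(A = 1:2, B = 3:4),
                               block_pairs = list(list("A", "B", 1.2))),
               "rho")
  expect_error(covariance_spec(6, 0.5, domains = list(A = 1:2),
                               block_pairs = list(list("A", "Z", 0.5))),
               "unknown domain")
  expect_error(make_trajectory(covariance_spec(4, 0.5), 1), "n_frames")
})

test_that("AR(1) mode keeps the marginal fluctuation scale", {
  cs <- covariance_spec(4, 0.5)
  tr <- make_trajectory(cs, 4000, seed = 2, ar1_phi = 0.5)$trajectory
  r <- rmsf(tr, fit = FALSE)
  expect_equal(unname(r), rep(0.5 * sqrt(3), 4), tolerance = 0.06)
})

test_that("receptor fixture labels the activation machinery and round-trips as PDB", {
  fx <- make_receptor_fixture()
  sel <- fx$selections
  expect_identical(sum(fx$atoms$resid == sel$lock_a), 1L)
  expect_identical(sum(fx$atoms$resid == sel$lock_b), 1L)
  expect_identical(fx$atoms$resname[fx$atoms$resid == sel$lock_a], "ARG")
  expect_identical(fx$atoms$resname[fx$atoms$resid == sel$lock_b], "GLU")
  expect_length(sel$npxxy, 5)
  expect_identical(fx$atoms$resname[fx$atoms$resid %in% sel$npxxy][c(1, 2, 5)],
                   c("ASN", "PRO", "TYR"))
  # every residue assigned to a TM domain
  expect_true(all(fx$domains %in% paste0("TM", 1:7)))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_receptor_pdb(fx, f)
  back <- read_receptor_pdb(f)
  expect_equal(back$xyz, fx$xyz, tolerance = 1e-3)
  expect_identical(back$atoms$resid, fx$atoms$resid)
  # active state breaks the lock: larger inter-residue distance
  act <- make_receptor_fixture("active")
  d_inact <- sqrt(sum((fx$xyz[fx$atoms$resid == sel$lock_a, ] -
                         fx$xyz[fx$atoms$resid == sel$lock_b, ])^2))
  d_act <- sqrt(sum((act$xyz[act$atoms$resid == sel$lock_a, ] -
                       act$xyz[act$atoms$resid == sel$lock_b, ])^2))
  expect_gt(d_act, d_inact)
})

test_that("trajectory text format round-trips coordinates and metadata", {
  cs <- covariance_spec(5, 0.3, frame_interval = 2)
  tr <- make_trajectory(cs, 7, seed = 3)$trajectory
  f <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(tr, f)
  back <- read_trajectory(f)
  expect_equal(back$coords, tr$coords, tolerance = 1e-5)
  expect_identical(back$time_per_frame, 2)
  expect_identical(back$atoms$resid, tr$atoms$resid)
})
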