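test_that("Kabsch superposition recovers rigid motions and matches a grid-search oracle", {
  set.seed(181)
  A <- matrix(rnorm(30), 10, 3)
  # identical coordinates: zero
  expect_equal(kabsch_superpose(A, A)$rmsd, 0, tolerance = 1e-12)
  # arbitrary rigid copy: zero within numerical precision
  R <- fragdock:::random_rotation_matrix()
  B <- sweep(A %*% t(R), 2, c(4, -2, 7), "+")
  fit <- kabsch_superpose(B, A)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  # 4-point crafted case vs dense rotation-grid minimization
  P <- rbind(c(0, 0, 0), c(1.4, 0, 0), c(0, 1.1, 0.3), c(0.5, 0.4, 1.2))
  Q <- rbind(c(0.1, 0, 0), c(1.5, 0.2, 0), c(-0.2, 1.0, 0.4),
             c(0.6, 0.3, 1.1))
  got <- kabsch_superpose(P, Q)$rmsd
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  grid_rmsd <- function(angles) {
    rz1 <- fragdock::rotation_matrix(c(0, 0, 1), angles[1])
    ry <- fragdock::rotation_matrix(c(0, 1, 0), angles[2])
    rz2 <- fragdock::rotation_matrix(c(0, 0, 1), angles[3])
    sqrt(mean(rowSums((Pc %*% t(rz2 %*% ry %*% rz1) - Qc)^2)))
  }
  coarse <- expand.grid(a = seq(0, 2 * pi, by = 6 * pi / 180),
                        b = seq(0, pi, by = 6 * pi / 180),
                        c = seq(0, 2 * pi, by = 6 * pi / 180))
  vals <- apply(coarse, 1, grid_rmsd)
  b0 <- as.numeric(coarse[which.min(vals), ])
  fine <- expand.grid(a = b0[1] + seq(-0.06, 0.06, by = 0.004),
                      b = b0[2] + seq(-0.06, 0.06, by = 0.004),
                      c = b0[3] + seq(-0.06, 0.06, by = 0.004))
  oracle <- min(apply(fine, 1, grid_rmsd))
  expect_equal(got, oracle, tolerance = 1e-3)
  expect_lte(got, oracle + 1e-9)  # Kabsch is the true minimum
  # degenerate selections rejected
  expect_error(kabsch_superpose(A[1:2, ], A[1:2, ]), "3 atoms")
  L <- cbind(0:4, 0, 0)
  expect_error(kabsch_superpose(L, L), "collinear")
})

test_that("RMSD series is zero for static trajectories and exact for a crafted case", {
  fx <- make_receptor_fixture()
  nf <- 4
  coords <- array(rep(fx$xyz, each = nf), c(nf, nrow(fx$xyz), 3))
  tr <- trajectory(coords, fx$atoms)
  expect_equal(rmsd_series(tr), rep(0, nf), tolerance = 1e-10)
  # crafted 2-frame case: frame 2 displaces one atom by 1 A after perfect fit
  # on the remaining atoms -> rmsd = sqrt(1/n) over the measured selection
  xyz2 <- fx$xyz
  fitsel <- seq_len(nrow(xyz2) - 1)
  xyz2[nrow(xyz2), ] <- xyz2[nrow(xyz2), ] + c(1, 0, 0)
  coords2 <- array(NA_real_, c(2, nrow(xyz2), 3))
  coords2[1, , ] <- fx$xyz; coords2[2, , ] <- xyz2
  tr2 <- trajectory(coords2, fx$atoms)
  r <- rmsd_series(tr2, reference = fx$xyz, fit_selection = fitsel,
                   measure_selection = nrow(xyz2))
  expect_equal(r[1], 0, tolerance = 1e-10)
  expect_equal(r[2], 1, tolerance = 1e-6)
})

test_that("RMSF recovers the isotropic closed form and vanishes under pure rigid motion", {
  cs <- covariance_spec(8, 0.5)
  tr <- make_trajectory(cs, 4000, seed = 191)$trajectory
  r <- rmsf(tr, fit = FALSE)
  expect_equal(unname(r), rep(0.5 * sqrt(3), 8), tolerance = 0.05)
  # static: exactly zero
  cs0 <- covariance_spec(4, 0)
  tr0 <- make_trajectory(cs0, 10, seed = 1)$trajectory
  expect_equal(unname(rmsf(tr0, fit = FALSE)), rep(0, 4))
  # rigid-body-only motion is removed by the superposition fit
  fx <- make_receptor_fixture()
  nf <- 6
  coords <- array(NA_real_, c(nf, nrow(fx$xyz), 3))
  set.seed(192)
  for (f in seq_len(nf)) {
    R <- fragdock:::random_rotation_matrix()
    coords[f, , ] <- sweep(fx$xyz %*% t(R), 2, rnorm(3, 0, 5), "+")
  }
  trr <- trajectory(coords, fx$atoms)
  expect_lt(max(rmsf(trr, fit = TRUE)), 1e-6)
})

test_that("RMSF distributions summarize sites correctly", {
  v <- c(`1` = 0.2, `2` = 0.4, `3` = 0.6, `4` = 0.8)
  d <- rmsf_distribution(v, site = c(1, 2, 3, 4))
  expect_equal(d$mean, 0.5)
  expect_equal(d$q1, unname(quantile(v, 0.25)))
  expect_equal(d$q3, unname(quantile(v, 0.75)))
  # all-equal values: zero IQR
  d0 <- rmsf_distribution(c(`1` = 0.3, `2` = 0.3, `3` = 0.3))
  expect_identical(d0$iqr, 0)
  # site = everything equals the global summary
  expect_identical(rmsf_distribution(v), d)
  expect_error(rmsf_distribution(v, site = c(1, 99)), "99")
})

test_that("COM distance series matches hand computation", {
  atoms <- data.frame(resid = c(1, 1, 2, 2), resname = "ALA", name = "CA",
                      heavy = TRUE, mass = c(12, 12, 12, 36))
  coords <- array(NA_real_, c(2, 4, 3))
  coords[1, , ] <- rbind(c(0, 0, 0), c(2, 0, 0), c(5, 0, 0), c(9, 0, 0))
  coords[2, , ] <- rbind(c(0, 0, 0), c(2, 0, 0), c(1, 3, 0), c(1, 7, 0))
  tr <- trajectory(coords, atoms)
  d <- com_distance_series(tr, by_resid(1), by_resid(2))
  # frame 1: COM(A) = (1,0,0); COM(B) = ((5*12+9*36)/48,0,0) = (8,0,0)
  expect_equal(d[1], 7)
  # frame 2: COM(B) = (1, (3*12+7*36)/48, 0) = (1, 6, 0); dist to (1,0,0)=6
  expect_equal(d[2], 6)
  # identical selections: zero
  expect_equal(com_distance_series(tr, by_resid(1), by_resid(1)),
               c(0, 0))
  # two single atoms 5 A apart
  a2 <- data.frame(resid = 1:2, resname = "X", name = "CA", heavy = TRUE,
                   mass = 12)
  c2 <- array(NA_real_, c(1, 2, 3))
  c2[1, , ] <- rbind(c(0, 0, 0), c(0, 5, 0))
  expect_equal(com_distance_series(trajectory(c2, a2), 1, 2), 5)
})

test_that("contact fractions count frames exactly, boundary inclusive", {
  # residue 1 fixed at origin; ligand atom approaches in a known pattern
  atoms <- data.frame(resid = c(1, 99), resname = c("ALA", "LIG"),
                      name = c("CA", "C1"), heavy = TRUE, mass = 12)
  nf <- 100
  coords <- array(0, c(nf, 2, 3))
  dists <- c(rep(2, 59), 3, rep(10, 40))  # exactly 60 frames at <= 3 A
  coords[, 2, 1] <- dists
  tr <- trajectory(coords, atoms)
  cf <- contact_fraction(tr, ligand_selection = 2, residue_list = 1,
                         cutoff = 3)
  expect_identical(unname(cf), 60)
  # always far: 0; always near: 100
  expect_identical(unname(contact_fraction(tr, 2, 1, cutoff = 1)), 0)
  expect_identical(unname(contact_fraction(tr, 2, 1, cutoff = 11)), 100)
  # monotone in the cutoff
  cuts <- c(1, 2.5, 3, 5, 11)
  vals <- vapply(cuts, function(cc)
    unname(contact_fraction(tr, 2, 1, cutoff = cc)), numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_error(contact_fraction(tr, 2, residue_list = 42, cutoff = 3), "42")
  # hydrogens are ignored in the distance criterion
  atoms_h <- atoms; atoms_h$heavy <- c(TRUE, TRUE)
  tr_h <- trajectory(coords, atoms_h)
  atomsH2 <- rbind(atoms, data.frame(resid = 99, resname = "LIG",
                                     name = "H1", heavy = FALSE, mass = 1))
  coordsH <- array(0, c(nf, 3, 3))
  coordsH[, 2, 1] <- dists
  coordsH[, 3, 1] <- 0.5  # hydrogen always close, must not count
  trH <- trajectory(coordsH, atomsH2)
  expect_identical(unname(contact_fraction(trH, c(2, 3), 1, cutoff = 3)), 60)
})

test_that("the activation trace sits at the reference markers for reference-only trajectories", {
  inact <- make_receptor_fixture("inactive")
  act <- make_receptor_fixture("active")
  sel <- inact$selections
  nf <- 3
  mk_traj <- function(xyz) {
    coords <- array(rep(xyz, each = nf), c(nf, nrow(xyz), 3))
    trajectory(coords, inact$atoms)
  }
  tr_i <- mk_traj(inact$xyz)
  at <- activation_trace(tr_i, by_resid(sel$lock_a), by_resid(sel$lock_b),
                         by_resid(sel$npxxy), inact$xyz, act$xyz)
  expect_equal(at$npxxy_rmsd, rep(0, nf), tolerance = 1e-10)
  expect_equal(at$lock_distance,
               rep(at$markers["inactive", "lock_distance"], nf),
               tolerance = 1e-10)
  tr_a <- mk_traj(act$xyz)
  at2 <- activation_trace(tr_a, by_resid(sel$lock_a), by_resid(sel$lock_b),
                          by_resid(sel$npxxy), inact$xyz, act$xyz)
  expect_equal(at2$lock_distance[1], at$markers["active", "lock_distance"],
               tolerance = 1e-10)
  expect_equal(at2$npxxy_rmsd[1], at$markers["active", "npxxy_rmsd"],
               tolerance = 1e-10)
  # interpolating inactive -> active produces a monotone trace
  lam <- seq(0, 1, length.out = 5)
  coords <- array(NA_real_, c(5, nrow(inact$xyz), 3))
  for (f in 1:5)
    coords[f, , ] <- (1 - lam[f]) * inact$xyz + lam[f] * act$xyz
  at3 <- activation_trace(trajectory(coords, inact$atoms),
                          by_resid(sel$lock_a), by_resid(sel$lock_b),
                          by_resid(sel$npxxy), inact$xyz, act$xyz)
  expect_true(all(diff(at3$lock_distance) > 0))
  expect_true(all(diff(at3$npxxy_rmsd) > 0))
})

test_that("moving averages are block means with a partial trailing block", {
  # constant series: unchanged
  expect_equal(moving_average(rep(2.5, 9), 3, 1), rep(2.5, 3))
  # window of one frame: identity
  expect_equal(moving_average(1:7, 1, 1), as.numeric(1:7))
  # ramp 1..10 in 5-frame blocks: (3, 8)
  expect_equal(moving_average(1:10, 5, 1), c(3, 8))
  # trailing partial block averaged over its own length
  expect_equal(moving_average(1:7, 5, 1), c(3, 6.5))
  # mean preserved for exact divisions
  set.seed(201)
  s <- rnorm(60)
  expect_equal(mean(moving_average(s, 15, 1)), mean(s), tolerance = 1e-12)
  expect_error(moving_average(1:5, 0.5, 1), "window")
})

test_that("LMI is 1 on the diagonal, symmetric, bounded, and near zero for independent residues", {
  cs <- covariance_spec(6, 0.5)
  tr <- make_trajectory(cs, 3000, seed = 211)$trajectory
  lm <- lmi_matrix(tr, fit = FALSE)
  expect_equal(unname(diag(lm)), rep(1, 6))
  expect_equal(unclass(lm), t(unclass(lm)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(lm >= 0 & lm <= 1))
  expect_lt(max(lm[upper.tri(lm)]), 0.1)
})

test_that("LMI recovers a planted correlation and is rigid-motion invariant with fit", {
  cs <- covariance_spec(30, 0.5, domains = list(A = 1:5, B = 6:10),
                        block_pairs = list(list("A", "B", 0.8)))
  mt <- make_trajectory(cs, 4000, seed = 221)
  lm <- lmi_matrix(mt$trajectory, fit = FALSE)
  expect_equal(lm[1, 6], 0.8, tolerance = 0.05)
  expect_lt(lm[20, 25], 0.1)
  # apply a global rigid motion per frame: fit = TRUE restores the signal
  tr2 <- mt$trajectory
  set.seed(222)
  for (f in seq_len(dim(tr2$coords)[1])) {
    R <- fragdock:::random_rotation_matrix()
    tr2$coords[f, , ] <- sweep(tr2$coords[f, , ] %*% t(R), 2,
                               rnorm(3, 0, 3), "+")
  }
  # the fit-based estimate is unchanged by the imposed rigid motion
  # (superposition itself absorbs some collective signal, so the comparison
  # is fit-vs-fit, not fit-vs-raw)
  lm_fit_moved <- lmi_matrix(tr2, fit = TRUE)
  lm_fit_orig <- lmi_matrix(mt$trajectory, fit = TRUE)
  expect_equal(lm_fit_moved[1, 6], lm_fit_orig[1, 6], tolerance = 1e-6)
  expect_equal(unclass(lm_fit_moved), unclass(lm_fit_orig),
               tolerance = 1e-6)
})

test_that("region detection reports exactly the planted domain pairs", {
  cs <- covariance_spec(10, 0.5, domains = list(A = 1:3, B = 4:6, C = 7:8),
                        block_pairs = list(list("A", "B", 0.9)))
  mt <- make_trajectory(cs, 4000, seed = 231)
  lm <- lmi_matrix(mt$trajectory, fit = FALSE)
  reg <- high_correlation_regions(lm, 0.625, mt$truth$domain_map)
  expect_identical(nrow(reg), 1L)
  expect_identical(reg$domain_i, "A")
  expect_identical(reg$domain_j, "B")
  expect_identical(reg$n_pairs, 9L)
  expect_identical(reg$residues_i, "1-3")
  expect_identical(reg$residues_j, "4-6")
  # threshold above everything: empty; threshold 0: all inter-domain pairs
  expect_identical(nrow(high_correlation_regions(lm, 0.999,
                                                 mt$truth$domain_map)), 0L)
  all_pairs <- high_correlation_regions(lm, 0, mt$truth$domain_map)
  expect_identical(sum(all_pairs$n_pairs),
                   nrow(attr(all_pairs, "pairs")))
})
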