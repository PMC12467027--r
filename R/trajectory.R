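#' Construct a trajectory
#'
#' Frames x atoms x 3 coordinates in Angstrom with a per-atom table giving
#' residue id, residue name, atom name, heavy-atom flag and mass.
#'
#' @param coords array with dim (n_frames, n_atoms, 3)
#' @param atoms data.frame with columns `resid`, `resname`, `name`,
#'   `heavy`, `mass` (missing columns get defaults)
#' @param time_per_frame ns between frames
#' @return an object of class `fd_trajectory`
#' @export
trajectory <- function(coords, atoms, time_per_frame = 1) {
  coords <- as.array(coords)
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("coords must be a (frames x atoms x 3) array")
  if (dim(coords)[1] < 1L) stop("need at least one frame")
  n_atoms <- dim(coords)[2]
  if (nrow(atoms) != n_atoms) stop("atom table does not match coords")
  if (is.null(atoms$resname)) atoms$resname <- "ALA"
  if (is.null(atoms$name)) atoms$name <- "CA"
  if (is.null(atoms$heavy)) atoms$heavy <- TRUE
  if (is.null(atoms$mass)) atoms$mass <- 12.011
  if (is.null(atoms$resid)) stop("atom table needs a resid column")
  structure(list(coords = coords, atoms = atoms,
                 time_per_frame = time_per_frame),
            class = "fd_trajectory")
}

#' @export
print.fd_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<fd_trajectory: %d frames, %d atoms, %d residues, %.3g ns/frame>\n",
              d[1], d[2], length(unique(x$atoms$resid)), x$time_per_frame))
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1]

#' Resolve an atom selection
#'
#' `sel` may be NULL (all atoms), a logical vector, integer atom indices,
#' or a numeric/integer vector of residue ids wrapped with [by_resid()].
#'
#' @param traj an [trajectory()]
#' @param sel selection
#' @return integer atom indices
#' @export
resolve_selection <- function(traj, sel) {
  n <- nrow(traj$atoms)
  if (is.null(sel)) return(seq_len(n))
  if (inherits(sel, "fd_resid_sel")) {
    idx <- which(traj$atoms$resid %in% unclass(sel))
    missing <- setdiff(unclass(sel), traj$atoms$resid)
    if (length(missing))
      stop("residue(s) absent from topology: ",
           paste(missing, collapse = ", "))
    return(idx)
  }
  if (is.logical(sel)) { stopifnot(length(sel) == n); return(which(sel)) }
  sel <- as.integer(sel)
  if (any(sel < 1L | sel > n)) stop("atom indices out of range")
  sel
}

#' Select atoms by residue id
#' @param resids residue ids
#' @return a selection usable wherever a selection is accepted
#' @export
by_resid <- function(resids) structure(as.integer(resids),
                                       class = "fd_resid_sel")

#' Analysis parameters for trajectory metrics
#'
#' @param contact_cutoff heavy-atom close-contact distance, Angstrom
#'   (default 3.0)
#' @param lmi_threshold normalized-LMI threshold for region detection
#'   (default 0.625)
#' @param ma_window moving-average window, ns (default 15)
#' @param reference reference structure (n_atoms x 3) for RMSD, or NULL
#'   for the first frame
#' @return an object of class `analysis_config`
#' @export
analysis_config <- function(contact_cutoff = 3.0, lmi_threshold = 0.625,
                            ma_window = 15, reference = NULL) {
  if (contact_cutoff <= 0) stop("contact_cutoff must be > 0")
  if (lmi_threshold < 0 || lmi_threshold > 1)
    stop("lmi_threshold must be in [0, 1]")
  structure(list(contact_cutoff = contact_cutoff,
                 lmi_threshold = lmi_threshold, ma_window = ma_window,
                 reference = reference),
            class = "analysis_config")
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation (determinant +1) and translation minimizing
#' the RMSD between `mobile` and `reference` over the selected atoms:
#' `fitted = (mobile - com_mobile) %*% t(R) + com_reference`. Fewer than 3
#' selected atoms, or a collinear selection, is rejected (the rotation is
#' then under-determined).
#'
#' @param mobile,reference n x 3 coordinate matrices
#' @param selection row indices used for the fit (default all)
#' @return list with `rotation` (3x3), `translation` (applied after
#'   rotation), `rmsd` (Angstrom, over the selection after fitting), and
#'   `fitted` (all mobile atoms transformed)
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  mobile <- rbind_points(mobile); reference <- rbind_points(reference)
  stopifnot(nrow(mobile) == nrow(reference))
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  if (length(selection) < 3L)
    stop("need at least 3 atoms for superposition")
  P <- mobile[selection, , drop = FALSE]
  Q <- reference[selection, , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv_chk <- svd(Pc)
  if (sv_chk$d[2] < 1e-8 * max(sv_chk$d[1], 1e-300))
    stop("selected atoms are collinear; superposition is under-determined")
  H <- crossprod(Pc, Qc)               # 3x3
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)   # fitted = R %*% p
  fitted_sel <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted_sel - Qc)^2)))
  translation <- cq - as.vector(R %*% cp)
  fitted <- sweep(mobile %*% t(R), 2, translation, "+")
  list(rotation = R, translation = translation, rmsd = rmsd,
       fitted = fitted)
}

#' Per-frame RMSD after superposition
#'
#' Each frame is superposed onto the reference over `fit_selection`; the
#' RMSD is then measured over `measure_selection` (default: the fit
#' selection).
#'
#' @param traj an [trajectory()]
#' @param reference n_atoms x 3 matrix (default: first frame)
#' @param fit_selection,measure_selection selections (see
#'   [resolve_selection()])
#' @return numeric vector, one RMSD (Angstrom) per frame
#' @export
rmsd_series <- function(traj, reference = NULL, fit_selection = NULL,
                        measure_selection = NULL) {
  if (is.null(reference)) reference <- traj$coords[1, , ]
  reference <- rbind_points(reference)
  if (nrow(reference) != nrow(traj$atoms))
    stop("reference does not match the trajectory's atoms")
  fit_idx <- resolve_selection(traj, fit_selection)
  meas_idx <- if (is.null(measure_selection)) fit_idx
              else resolve_selection(traj, measure_selection)
  if (length(meas_idx) == 0L) stop("empty measure selection")
  vapply(seq_len(n_frames(traj)), function(f) {
    fit <- kabsch_superpose(traj$coords[f, , ], reference, fit_idx)
    dev <- fit$fitted[meas_idx, , drop = FALSE] -
      reference[meas_idx, , drop = FALSE]
    sqrt(mean(rowSums(dev^2)))
  }, numeric(1))
}

#' Per-residue root-mean-square fluctuation
#'
#' With `fit = TRUE` every frame is first superposed (over the selection)
#' onto the mean structure, removing global rigid motion; with
#' `fit = FALSE` raw coordinates are used (appropriate when the input has
#' no rigid-body drift, e.g. synthetic displacement trajectories). The
#' per-atom RMSF `sqrt(<|r - <r>|^2>)` is averaged over each residue's
#' selected atoms.
#'
#' @param traj an [trajectory()]
#' @param selection atoms to analyze (default all)
#' @param fit superpose frames onto the mean structure first?
#' @return named numeric vector, RMSF in Angstrom per residue id
#' @export
rmsf <- function(traj, selection = NULL, fit = TRUE) {
  if (n_frames(traj) < 2L) stop("need at least 2 frames for RMSF")
  idx <- resolve_selection(traj, selection)
  if (length(idx) == 0L) stop("empty selection")
  nf <- n_frames(traj)
  X <- traj$coords[, idx, , drop = FALSE]
  if (fit) {
    ref <- X[1, , ]
    for (f in seq_len(nf))
      X[f, , ] <- kabsch_superpose(X[f, , ], ref)$fitted
    mref <- apply(X, c(2, 3), mean)
    for (f in seq_len(nf))
      X[f, , ] <- kabsch_superpose(X[f, , ], mref)$fitted
  }
  mu <- apply(X, c(2, 3), mean)
  sq <- matrix(0, nf, length(idx))
  for (d in 1:3)
    sq <- sq + sweep(matrix(X[, , d], nrow = nf), 2, mu[, d])^2
  atom_rmsf <- sqrt(colMeans(sq))
  resid <- traj$atoms$resid[idx]
  out <- tapply(atom_rmsf, factor(resid, levels = unique(resid)), mean)
  res <- as.numeric(out)
  names(res) <- names(out)
  ord <- suppressWarnings(as.numeric(names(res)))
  if (!anyNA(ord)) res <- res[order(ord)]
  res
}

#' Summarize the RMSF distribution over a site's residues
#'
#' @param rmsf_values named per-residue RMSF vector (from [rmsf()])
#' @param site residue ids of the site (default: all residues)
#' @return list with `n`, `mean`, `median`, `q1`, `q3`, `iqr`, `min`,
#'   `max` and the site `values`
#' @export
rmsf_distribution <- function(rmsf_values, site = NULL) {
  if (is.null(site)) {
    v <- rmsf_values
  } else {
    site <- as.character(site)
    missing <- setdiff(site, names(rmsf_values))
    if (length(missing))
      stop("site residue(s) absent: ", paste(missing, collapse = ", "))
    v <- rmsf_values[site]
  }
  if (length(v) == 0L) stop("empty site")
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  list(n = length(v), mean = mean(v), median = q[2], q1 = q[1], q3 = q[3],
       iqr = q[3] - q[1], min = min(v), max = max(v), values = v)
}

#' Center-of-mass distance between two selections, per frame
#'
#' @param traj an [trajectory()]
#' @param selA,selB selections (see [resolve_selection()])
#' @return numeric vector, Angstrom per frame
#' @export
com_distance_series <- function(traj, selA, selB) {
  ia <- resolve_selection(traj, selA)
  ib <- resolve_selection(traj, selB)
  if (length(ia) == 0L || length(ib) == 0L) stop("empty selection")
  ma <- traj$atoms$mass[ia]; mb <- traj$atoms$mass[ib]
  vapply(seq_len(n_frames(traj)), function(f) {
    ca <- center_of_mass(traj$coords[f, ia, , drop = TRUE], ma)
    cb <- center_of_mass(traj$coords[f, ib, , drop = TRUE], mb)
    sqrt(sum((ca - cb)^2))
  }, numeric(1))
}

#' Close-contact fraction per residue
#'
#' For each residue of `residue_list`, the percentage of frames in which
#' any non-hydrogen ligand atom lies within `cutoff` of any non-hydrogen
#' atom of that residue. A distance exactly equal to the cutoff counts as
#' a contact.
#'
#' @param traj an [trajectory()]
#' @param ligand_selection selection of ligand atoms
#' @param residue_list residue ids to report
#' @param cutoff Angstrom (default 3.0)
#' @return named numeric vector of percentages in `[0, 100]`
#' @export
contact_fraction <- function(traj, ligand_selection, residue_list,
                             cutoff = 3.0) {
  il <- resolve_selection(traj, ligand_selection)
  il <- il[traj$atoms$heavy[il]]
  if (length(il) == 0L) stop("no heavy atoms in the ligand selection")
  nf <- n_frames(traj)
  out <- numeric(length(residue_list))
  names(out) <- as.character(residue_list)
  for (k in seq_along(residue_list)) {
    ir <- which(traj$atoms$resid == residue_list[k] & traj$atoms$heavy)
    if (length(ir) == 0L)
      stop("residue absent from topology: ", residue_list[k])
    hits <- vapply(seq_len(nf), function(f) {
      L <- traj$coords[f, il, , drop = FALSE]
      Rr <- traj$coords[f, ir, , drop = FALSE]
      dim(L) <- c(length(il), 3); dim(Rr) <- c(length(ir), 3)
      d2 <- outer(rowSums(L^2), rowSums(Rr^2), "+") - 2 * (L %*% t(Rr))
      min(d2) <= cutoff^2 + 1e-12
    }, logical(1))
    out[k] <- 100 * sum(hits) / nf
  }
  out
}

#' Ionic-lock / NPxxY activation trace
#'
#' The two-dimensional activation metric: per frame, the center-of-mass
#' distance between the two ionic-lock partner selections, paired with the
#' RMSD of the NPxxY-motif selection relative to the inactive reference
#' (after fitting on the motif). Marker values computed from the inactive
#' and active reference structures are reported alongside.
#'
#' @param traj an [trajectory()]
#' @param lock_selA,lock_selB selections of the two lock partners
#' @param npxxy_selection selection of the NPxxY motif
#' @param inactive_ref,active_ref n_atoms x 3 reference coordinates
#' @return an object of class `activation_trace`: `lock_distance`,
#'   `npxxy_rmsd` (per frame), and `markers` (a 2 x 2 data.frame of the
#'   reference values)
#' @export
activation_trace <- function(traj, lock_selA, lock_selB, npxxy_selection,
                             inactive_ref, active_ref) {
  inactive_ref <- rbind_points(inactive_ref)
  active_ref <- rbind_points(active_ref)
  lock <- com_distance_series(traj, lock_selA, lock_selB)
  np <- rmsd_series(traj, inactive_ref, fit_selection = npxxy_selection)
  marker_of <- function(ref) {
    rt <- trajectory(array(ref, c(1, nrow(ref), 3)), traj$atoms,
                     traj$time_per_frame)
    c(lock = com_distance_series(rt, lock_selA, lock_selB),
      npxxy = rmsd_series(rt, inactive_ref,
                          fit_selection = npxxy_selection))
  }
  markers <- rbind(inactive = marker_of(inactive_ref),
                   active = marker_of(active_ref))
  colnames(markers) <- c("lock_distance", "npxxy_rmsd")
  structure(list(lock_distance = lock, npxxy_rmsd = np,
                 markers = as.data.frame(markers)),
            class = "activation_trace")
}

#' Block moving average of a time series
#'
#' Non-overlapping block means: the series is cut into consecutive blocks
#' of `floor(window / time_per_frame)` frames and each block is averaged
#' ("calculated every window"); a trailing partial block is averaged over
#' its actual length. With a one-frame window this is the identity.
#'
#' @param series numeric vector
#' @param window block length in ns
#' @param time_per_frame ns per frame
#' @return numeric vector of block means
#' @export
moving_average <- function(series, window, time_per_frame = 1) {
  if (window < time_per_frame)
    stop("window must be at least one frame long")
  bl <- max(1L, floor(window / time_per_frame))
  grp <- (seq_along(series) - 1L) %/% bl
  as.numeric(tapply(series, factor(grp, levels = unique(grp)), mean))
}

#' Linear mutual information correlation matrix
#'
#' For each residue (one representative point per residue: the first
#' selected atom of the residue, conventionally the alpha-carbon), the
#' Gaussian mutual information between 3D displacement vectors,
#' `I = (1/2) (ln det C_i + ln det C_j - ln det C_ij)` with 3x3 marginal
#' and 6x6 joint covariances, normalized to a correlation-like scale as
#' `sqrt(1 - exp(-2 I / 3))`. The diagonal is 1 and the matrix is
#' symmetric with entries in `[0, 1]`.
#'
#' @param traj an [trajectory()]
#' @param selection atoms to consider (one per residue is used)
#' @param fit superpose frames onto the mean structure first (removes
#'   global rigid motion)?
#' @return matrix with residue ids as dimnames, class `lmi_matrix`
#' @export
lmi_matrix <- function(traj, selection = NULL, fit = FALSE) {
  idx <- resolve_selection(traj, selection)
  resid <- traj$atoms$resid[idx]
  rep_idx <- idx[!duplicated(resid)]
  resids <- traj$atoms$resid[rep_idx]
  nr <- length(rep_idx)
  nf <- n_frames(traj)
  if (nf < 10L) stop("too few frames for a covariance estimate")
  X <- traj$coords[, rep_idx, , drop = FALSE]
  if (fit) {
    ref <- X[1, , ]
    for (f in seq_len(nf)) X[f, , ] <- kabsch_superpose(X[f, , ], ref)$fitted
    mref <- apply(X, c(2, 3), mean)
    for (f in seq_len(nf)) X[f, , ] <- kabsch_superpose(X[f, , ], mref)$fitted
  }
  # flatten to frames x (3 nr): columns (res1 xyz, res2 xyz, ...)
  M <- matrix(0, nf, 3 * nr)
  for (d in 1:3) M[, seq(d, by = 3, length.out = nr)] <- X[, , d]
  C <- stats::cov(M)
  logdet3 <- numeric(nr)
  for (i in seq_len(nr)) {
    ci <- C[(3 * i - 2):(3 * i), (3 * i - 2):(3 * i)]
    ld <- determinant(ci, logarithm = TRUE)
    if (ld$sign <= 0)
      stop("singular residue covariance; need more frames or regularization")
    logdet3[i] <- as.numeric(ld$modulus)
  }
  out <- diag(1, nr)
  for (i in seq_len(nr)) {
    bi <- (3 * i - 2):(3 * i)
    for (j in seq_len(nr)) {
      if (j >= i) next
      bj <- (3 * j - 2):(3 * j)
      cij <- C[c(bi, bj), c(bi, bj)]
      ld <- determinant(cij, logarithm = TRUE)
      if (ld$sign <= 0)
        stop("singular joint covariance; need more frames or regularization")
      I <- 0.5 * (logdet3[i] + logdet3[j] - as.numeric(ld$modulus))
      r <- sqrt(max(0, 1 - exp(-2 * I / 3)))
      out[i, j] <- out[j, i] <- min(1, r)
    }
  }
  dimnames(out) <- list(resids, resids)
  class(out) <- c("lmi_matrix", class(out))
  out
}

#' Detect high-correlation inter-domain regions
#'
#' Collects off-diagonal LMI entries above `threshold` between residues of
#' distinct named domains and groups them per domain pair, reporting the
#' contiguous residue runs involved on each side. Residues absent from
#' `domain_map` fall in an "other" domain.
#'
#' @param lmi an [lmi_matrix()]
#' @param threshold LMI threshold (conventionally 0.625)
#' @param domain_map named character vector mapping residue id -> domain
#'   name (e.g. "TM1".."TM7")
#' @return data.frame with one row per domain pair (`domain_i`,
#'   `domain_j`, `n_pairs`, `max_lmi`, `residues_i`, `residues_j`);
#'   attribute `"pairs"` holds the individual residue pairs
#' @export
high_correlation_regions <- function(lmi, threshold = 0.625, domain_map) {
  resids <- rownames(lmi)
  dom <- domain_map[resids]
  dom[is.na(dom)] <- "other"
  nr <- nrow(lmi)
  pr <- which(upper.tri(lmi) & lmi > threshold, arr.ind = TRUE)
  if (nrow(pr)) {
    keep <- dom[pr[, 1]] != dom[pr[, 2]]
    pr <- pr[keep, , drop = FALSE]
  }
  if (nrow(pr) == 0L) {
    out <- data.frame(domain_i = character(0), domain_j = character(0),
                      n_pairs = integer(0), max_lmi = numeric(0),
                      residues_i = character(0), residues_j = character(0))
    attr(out, "pairs") <- data.frame(res_i = integer(0), res_j = integer(0),
                                     lmi = numeric(0))
    return(out)
  }
  # canonical domain-pair key with sorted domain names
  di <- dom[pr[, 1]]; dj <- dom[pr[, 2]]
  swap <- di > dj
  tmp <- pr[swap, 1]; pr[swap, 1] <- pr[swap, 2]; pr[swap, 2] <- tmp
  d1 <- pmin(di, dj); d2 <- pmax(di, dj)
  key <- paste(d1, d2, sep = "|")
  pairs_df <- data.frame(res_i = as.integer(resids[pr[, 1]]),
                         res_j = as.integer(resids[pr[, 2]]),
                         lmi = lmi[pr], domain_i = d1, domain_j = d2)
  groups <- split(seq_len(nrow(pairs_df)), key)
  rows <- lapply(groups, function(g) {
    data.frame(domain_i = pairs_df$domain_i[g[1]],
               domain_j = pairs_df$domain_j[g[1]],
               n_pairs = length(g),
               max_lmi = max(pairs_df$lmi[g]),
               residues_i = runs_to_string(pairs_df$res_i[g]),
               residues_j = runs_to_string(pairs_df$res_j[g]))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$max_lmi), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pairs") <- pairs_df
  out
}
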