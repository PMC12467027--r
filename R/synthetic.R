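#' A planted Gaussian free-energy well
#'
#' Ground-truth feature for synthetic fragment maps: an isotropic Gaussian
#' free-energy profile `depth * exp(-|r - center|^2 / (2 width^2))`
#' (depth negative = favorable) on one map type.
#'
#' @param center length-3 numeric, Angstrom
#' @param depth kcal/mol at the well center (negative = favorable)
#' @param width isotropic Gaussian sigma, Angstrom (> 0)
#' @param map_type one of [MAP_TYPES]
#' @return an object of class `planted_well`
#' @export
planted_well <- function(center, depth, width, map_type) {
  if (width <= 0) stop("width must be > 0")
  if (!map_type %in% MAP_TYPES)
    stop("map_type must be one of: ", paste(MAP_TYPES, collapse = ", "))
  structure(list(center = as.numeric(center), depth = depth, width = width,
                 map_type = map_type), class = "planted_well")
}

#' Generate a fragment-map set with planted wells
#'
#' Each of the eight map types gets a grid equal to the sum of its wells'
#' Gaussian free-energy profiles plus i.i.d. Gaussian noise. The returned
#' ground-truth record lists every well; an identical seed reproduces the
#' grids bit for bit.
#'
#' @param wells list of [planted_well()]s (must lie inside the grid box)
#' @param spec a [grid_spec()]
#' @param noise_sd i.i.d. noise standard deviation, kcal/mol
#' @param seed integer seed or NULL
#' @param exclusion an [exclusion_map()] to attach, or NULL
#' @param temperature Kelvin for the set
#' @param cap clamp magnitude for the grids (default 1000, i.e. effectively
#'   unclamped for realistic depths)
#' @return a [fragmap_set()]; attribute `"ground_truth"` is a data.frame
#'   of the planted wells
#' @export
make_fragmap_set <- function(wells, spec, noise_sd = 0, seed = NULL,
                             exclusion = NULL, temperature = 300,
                             cap = 1000) {
  stopifnot(inherits(spec, "grid_spec"))
  up <- grid_upper(spec)
  for (w in wells) {
    stopifnot(inherits(w, "planted_well"))
    if (any(w$center < spec$origin) || any(w$center > up))
      stop(sprintf("well center (%.2f, %.2f, %.2f) lies outside the grid box",
                   w$center[1], w$center[2], w$center[3]))
  }
  xs <- voxel_centers(spec, 1)
  ys <- voxel_centers(spec, 2)
  zs <- voxel_centers(spec, 3)
  with_seed(seed, {
    maps <- lapply(MAP_TYPES, function(mt) {
      vals <- array(0, spec$dims)
      for (w in wells) {
        if (w$map_type != mt) next
        gx <- exp(-(xs - w$center[1])^2 / (2 * w$width^2))
        gy <- exp(-(ys - w$center[2])^2 / (2 * w$width^2))
        gz <- exp(-(zs - w$center[3])^2 / (2 * w$width^2))
        vals <- vals + w$depth * (gx %o% gy %o% gz)
      }
      if (noise_sd > 0)
        vals <- vals + array(rnorm(prod(spec$dims), 0, noise_sd), spec$dims)
      gfe_grid(spec, mt, vals, cap = cap)
    })
    names(maps) <- MAP_TYPES
    fs <- fragmap_set(maps, exclusion = exclusion,
                      temperature = temperature)
    attr(fs, "ground_truth") <- data.frame(
      map_type = vapply(wells, `[[`, character(1), "map_type"),
      cx = vapply(wells, function(w) w$center[1], numeric(1)),
      cy = vapply(wells, function(w) w$center[2], numeric(1)),
      cz = vapply(wells, function(w) w$center[3], numeric(1)),
      depth = vapply(wells, `[[`, numeric(1), "depth"),
      width = vapply(wells, `[[`, numeric(1), "width"))
    fs
  })
}

#' Build an exclusion map from geometric shapes
#'
#' A voxel is excluded exactly when its center falls inside at least one
#' shape. Shapes are spheres (`list(kind = "sphere", center, radius)`) or
#' axis-aligned slabs (`list(kind = "slab", axis, min, max)`, closed
#' bounds, `axis` in 1:3).
#'
#' @param shapes list of shape descriptions (possibly empty)
#' @param spec a [grid_spec()]
#' @return an [exclusion_map()]
#' @export
make_exclusion <- function(shapes, spec) {
  mask <- array(FALSE, spec$dims)
  xs <- voxel_centers(spec, 1)
  ys <- voxel_centers(spec, 2)
  zs <- voxel_centers(spec, 3)
  for (sh in shapes) {
    if (identical(sh$kind, "sphere")) {
      dx2 <- (xs - sh$center[1])^2
      dy2 <- (ys - sh$center[2])^2
      dz2 <- (zs - sh$center[3])^2
      inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= sh$radius^2
    } else if (identical(sh$kind, "slab")) {
      ax <- list(xs, ys, zs)[[sh$axis]]
      hit <- ax >= (sh$min %||% -Inf) & ax <= (sh$max %||% Inf)
      inside <- array(FALSE, spec$dims)
      if (sh$axis == 1) inside[hit, , ] <- TRUE
      if (sh$axis == 2) inside[, hit, ] <- TRUE
      if (sh$axis == 3) inside[, , hit] <- TRUE
    } else {
      stop("unknown shape kind: ", sh$kind %||% "<missing>")
    }
    mask <- mask | inside
  }
  exclusion_map(spec, mask)
}

# ---- ligand templates -----------------------------------------------------

LIGAND_TEMPLATES <- c("probe_atom", "rigid_rod", "steroid_acid",
                      "steroid_glycine", "steroid_taurine")

# Four linearly fused hexagons (18 carbons) standing in for the steroid
# ring system; planar, 1.45 A edges, united-atom (no hydrogens).
steroid_core <- function() {
  r <- 1.45
  centers <- (0:3) * (2 * r * cos(pi / 6))
  pts <- list()
  for (cx in centers) {
    for (k in 0:5) {
      a <- pi / 6 + k * pi / 3      # pointy-left/right hexagon
      p <- round(c(cx + r * cos(a), r * sin(a), 0), 3)
      key <- paste(p, collapse = ",")
      pts[[key]] <- p
    }
  }
  xyz <- do.call(rbind, unname(pts))
  bonds <- list()
  for (i in seq_len(nrow(xyz))) {
    for (j in seq_len(i - 1L)) {
      if (sum((xyz[i, ] - xyz[j, ])^2) < 1.6^2)
        bonds[[length(bonds) + 1L]] <- c(j, i)
    }
  }
  list(xyz = xyz, bonds = do.call(rbind, bonds))
}

# Append tail atoms bonded in a chain starting from `anchor`.
add_tail <- function(core, anchor, tail_xyz, tail_elements, tail_classes,
                     tail_bonds) {
  n0 <- nrow(core$xyz)
  xyz <- rbind(core$xyz, tail_xyz)
  bonds <- rbind(core$bonds,
                 cbind(anchor, n0 + 1L),
                 if (nrow(tail_bonds)) tail_bonds + n0 else NULL)
  list(xyz = xyz, bonds = bonds, n0 = n0,
       elements = c(rep("C", n0), tail_elements),
       classes = c(rep("CAL", n0), tail_classes))
}

chain_bonds <- function(edges) {
  if (length(edges) == 0L) return(matrix(integer(0), ncol = 2))
  matrix(unlist(edges), ncol = 2, byrow = TRUE)
}

#' Build a ligand from a named template
#'
#' Schematic, united-atom test ligands: `probe_atom` (one apolar carbon),
#' `rigid_rod` (three collinear carbons, no rotatable torsions),
#' and three steroid-like templates sharing one fused 4-ring core with a
#' ring hydroxyl, differing only in the tail: a carboxylic-acid tail
#' (`steroid_acid`), its glycine-conjugate extension (`steroid_glycine`,
#' amide + glycine carboxylate) and its taurine-conjugate extension
#' (`steroid_taurine`, amide + ethyl-sulfonate). Geometry is schematic by
#' design; atom classes follow [default_rules()].
#'
#' @param template_name one of `probe_atom`, `rigid_rod`, `steroid_acid`,
#'   `steroid_glycine`, `steroid_taurine`
#' @return an [ligand()]
#' @export
make_ligand <- function(template_name) {
  if (!template_name %in% LIGAND_TEMPLATES)
    stop("unknown template '", template_name, "'; valid names: ",
         paste(LIGAND_TEMPLATES, collapse = ", "))
  if (template_name == "probe_atom") {
    return(ligand("C", "CAL", matrix(0, 1, 3), name = "probe_atom"))
  }
  if (template_name == "rigid_rod") {
    xyz <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(3, 0, 0))
    return(ligand(rep("C", 3), rep("CAL", 3), xyz,
                  bonds = rbind(c(1, 2), c(2, 3)), name = "rigid_rod"))
  }
  core <- steroid_core()
  # ring hydroxyl on the leftmost lower junction carbon
  oh_anchor <- which.min(core$xyz[, 1] + 0.1 * core$xyz[, 2])
  oh <- core$xyz[oh_anchor, ] + c(-1.0, -1.0, 0)
  core$xyz <- rbind(core$xyz, round(oh, 3))
  core$bonds <- rbind(core$bonds, c(oh_anchor, nrow(core$xyz)))
  n_core <- nrow(core$xyz)
  # tail anchor: rightmost upper junction carbon
  anchor <- which.max(core$xyz[, 1] - 0.1 * core$xyz[, 2])
  a <- core$xyz[anchor, ]
  if (template_name == "steroid_acid") {
    tail_xyz <- rbind(a + c(1.2, 0.9, 0),        # C19
                      a + c(2.7, 0.9, 0),        # C20
                      a + c(3.9, 1.8, 0),        # C21 carboxylate C
                      a + c(5.1, 1.5, 0.4),      # O
                      a + c(3.8, 3.0, -0.4))     # O
    tail_el <- c("C", "C", "C", "O", "O")
    tail_cl <- c("CAL", "CAL", "CCX", "OAC", "OAC")
    tail_b <- chain_bonds(list(c(1, 2), c(2, 3), c(3, 4), c(3, 5)))
  } else if (template_name == "steroid_glycine") {
    tail_xyz <- rbind(a + c(1.2, 0.9, 0),        # C19
                      a + c(2.7, 0.9, 0),        # C20
                      a + c(3.9, 1.8, 0),        # C21 amide C
                      a + c(3.8, 3.0, -0.4),     # O (amide)
                      a + c(5.1, 1.2, 0.2),      # N
                      a + c(6.4, 1.9, 0.2),      # C glycine CH2
                      a + c(7.6, 1.0, 0.4),      # C carboxylate
                      a + c(8.8, 1.5, 0.4),      # O
                      a + c(7.5, -0.2, 0.5))     # O
    tail_el <- c("C", "C", "C", "O", "N", "C", "C", "O", "O")
    tail_cl <- c("CAL", "CAL", "CAM", "OAC", "NDA", "CAL", "CCX",
                 "OAC", "OAC")
    tail_b <- chain_bonds(list(c(1, 2), c(2, 3), c(3, 4), c(3, 5),
                               c(5, 6), c(6, 7), c(7, 8), c(7, 9)))
  } else {
    tail_xyz <- rbind(a + c(1.2, 0.9, 0),        # C19
                      a + c(2.7, 0.9, 0),        # C20
                      a + c(3.9, 1.8, 0),        # C21 amide C
                      a + c(3.8, 3.0, -0.4),     # O (amide)
                      a + c(5.1, 1.2, 0.2),      # N
                      a + c(6.4, 1.9, 0.2),      # C
                      a + c(7.7, 1.1, 0.3),      # C
                      a + c(9.2, 1.9, 0.3),      # S
                      a + c(10.3, 0.9, 0.5),     # O
                      a + c(9.3, 2.8, 1.4),      # O
                      a + c(9.4, 2.6, -1.0))     # O
    tail_el <- c("C", "C", "C", "O", "N", "C", "C", "S", "O", "O", "O")
    tail_cl <- c("CAL", "CAL", "CAM", "OAC", "NDA", "CAL", "CAL", "SUL",
                 "OAC", "OAC", "OAC")
    tail_b <- chain_bonds(list(c(1, 2), c(2, 3), c(3, 4), c(3, 5),
                               c(5, 6), c(6, 7), c(7, 8), c(8, 9),
                               c(8, 10), c(8, 11)))
  }
  built <- add_tail(core, anchor, round(tail_xyz, 3), tail_el, tail_cl,
                    tail_b)
  ligand(built$elements, built$classes, built$xyz, bonds = built$bonds,
         name = template_name)
}

# ---- synthetic trajectories ----------------------------------------------

#' Specify the covariance of a synthetic Gaussian trajectory
#'
#' One representative (alpha-carbon-like) atom per residue. Per axis, all
#' residues fluctuate with standard deviation `sigma`; a block pair
#' `list(domain_i, domain_j, rho)` plants correlation `rho` between every
#' pair of distinct residues in the union of the two domains (the compound-
#' symmetric construction keeps the covariance positive definite, which is
#' checked at construction). The three axes are independent, so the
#' normalized linear mutual information between an inter-domain residue
#' pair equals `rho` exactly and per-residue RMSF equals `sigma * sqrt(3)`.
#'
#' @param n_residues number of residues
#' @param sigma per-axis fluctuation, Angstrom
#' @param domains named list of residue index vectors (domain definitions)
#' @param block_pairs list of `list(domain_i, domain_j, rho)` with
#'   `0 <= rho < 1`
#' @param frame_interval ns per frame
#' @return an object of class `covariance_spec` with the per-axis
#'   covariance matrix in `$Sigma`
#' @export
covariance_spec <- function(n_residues, sigma, domains = list(),
                            block_pairs = list(), frame_interval = 1) {
  n_residues <- as.integer(n_residues)
  if (sigma < 0) stop("sigma must be >= 0")
  K <- diag(1, n_residues)
  for (bp in block_pairs) {
    di <- bp[[1]]; dj <- bp[[2]]; rho <- bp[[3]]
    if (rho < 0 || rho >= 1) stop("rho must satisfy 0 <= rho < 1")
    if (!di %in% names(domains) || !dj %in% names(domains))
      stop("block pair references unknown domain(s): ", di, ", ", dj)
    members <- union(domains[[di]], domains[[dj]])
    if (any(members < 1L | members > n_residues))
      stop("domain residue indices out of range")
    for (u in members) for (v in members) if (u != v) K[u, v] <- rho
  }
  Sigma <- sigma^2 * K
  if (sigma > 0) {
    ok <- tryCatch({ chol(K); TRUE }, error = function(e) FALSE)
    if (!ok) stop("resulting covariance matrix is not positive definite")
  }
  structure(list(n_residues = n_residues, sigma = sigma, domains = domains,
                 block_pairs = block_pairs,
                 frame_interval = frame_interval, Sigma = Sigma,
                 corr = K),
            class = "covariance_spec")
}

#' Generate a synthetic Gaussian trajectory with analytic ground truth
#'
#' Frames are draws of residue displacement vectors about fixed mean
#' positions with the covariance of `spec`, independent across the three
#' axes. By default frames are i.i.d., giving closed-form truth: RMSF =
#' `sigma * sqrt(3)` per residue and normalized LMI = `rho` for planted
#' pairs (0 elsewhere). `ar1_phi` switches to a stationary AR(1) frame-to-
#' frame autocorrelation (same marginal covariance; useful for moving-
#' average behavior) for which no LMI claim is made.
#'
#' @param spec a [covariance_spec()]
#' @param n_frames number of frames (>= 2)
#' @param seed integer seed or NULL
#' @param ar1_phi AR(1) autocorrelation in `[0, 1)`; 0 = i.i.d. frames
#' @return list with `trajectory` (an [trajectory()]), `truth` (list with
#'   per-residue `rmsf`, matrix `lmi`, and the `domain_map`)
#' @export
make_trajectory <- function(spec, n_frames, seed = NULL, ar1_phi = 0) {
  stopifnot(inherits(spec, "covariance_spec"))
  n_frames <- as.integer(n_frames)
  if (n_frames < 2L) stop("n_frames must be >= 2")
  if (ar1_phi < 0 || ar1_phi >= 1) stop("ar1_phi must be in [0, 1)")
  nr <- spec$n_residues
  # fixed mean positions: residues on a gentle helix (non-collinear, so
  # superposition-based analyses remain well-posed on the fixture)
  i <- seq_len(nr)
  mean_pos <- cbind(3 * cos(0.6 * i), 3 * sin(0.6 * i), 1.5 * i)
  L <- if (spec$sigma > 0) t(chol(spec$corr)) else NULL
  coords <- with_seed(seed, {
    arr <- array(0, c(n_frames, nr, 3))
    for (d in 1:3) {
      if (is.null(L)) {
        disp <- matrix(0, n_frames, nr)
      } else {
        Z <- matrix(rnorm(n_frames * nr), n_frames, nr)
        disp <- spec$sigma * (Z %*% t(L))
        if (ar1_phi > 0) {
          sc <- sqrt(1 - ar1_phi^2)
          for (f in 2:n_frames)
            disp[f, ] <- ar1_phi * disp[f - 1, ] + sc * disp[f, ]
        }
      }
      arr[, , d] <- sweep(disp, 2, mean_pos[, d], "+")
    }
    arr
  })
  atoms <- data.frame(resid = seq_len(nr), resname = "ALA", name = "CA",
                      heavy = TRUE, mass = 12.011)
  traj <- trajectory(coords, atoms, time_per_frame = spec$frame_interval)
  lmi_true <- spec$corr
  diag(lmi_true) <- 1
  dimnames(lmi_true) <- list(seq_len(nr), seq_len(nr))
  domain_map <- rep(NA_character_, nr)
  for (nm in names(spec$domains)) domain_map[spec$domains[[nm]]] <- nm
  names(domain_map) <- seq_len(nr)
  list(trajectory = traj,
       truth = list(rmsf = stats::setNames(rep(spec$sigma * sqrt(3), nr),
                                           seq_len(nr)),
                    lmi = lmi_true,
                    domain_map = domain_map))
}

# ---- receptor fixture -----------------------------------------------------

#' Toy seven-helix receptor fixture with labeled functional selections
#'
#' A schematic helical bundle (alpha-carbon only, seven 20-residue
#' helices on a circle) carrying labeled stand-ins for the ionic-lock
#' partners (an arginine on TM3, residue 123, and a glutamate on TM6,
#' residue 360), the TM7 NPxxY motif (residues 410-414), and two
#' allosteric-groove residue sets on the intracellular ends of TM3/TM4
#' ("as34") and TM5/TM6 ("as56"). The `active` state displaces the TM6
#' intracellular half outward (breaking the lock) and distorts the NPxxY
#' motif, mimicking the conformational signature of receptor activation.
#'
#' @param state "inactive" (default) or "active"
#' @return list with `xyz` (n x 3, Angstrom, 3-decimal precision),
#'   `atoms` (resid/resname/name/heavy/mass table), `selections`
#'   (`lock_a`, `lock_b`, `npxxy`, `as34`, `as56` as residue ids) and
#'   `domains` (named residue -> TM map)
#' @export
make_receptor_fixture <- function(state = c("inactive", "active")) {
  state <- match.arg(state)
  helix_resnos <- list(TM1 = 31:50, TM2 = 61:80, TM3 = 111:130,
                       TM4 = 161:180, TM5 = 201:220, TM6 = 351:370,
                       TM7 = 401:420)
  n_hel <- length(helix_resnos)
  rise <- 1.5; wobble_r <- 2.3; ring_r <- 11
  xyz <- NULL; resid <- integer(0)
  for (h in seq_len(n_hel)) {
    th <- 2 * pi * (h - 1) / n_hel
    cx <- ring_r * cos(th); cy <- ring_r * sin(th)
    resnos <- helix_resnos[[h]]
    i <- seq_along(resnos)
    z <- (i - mean(i)) * rise
    if (h %% 2 == 0) z <- -z          # antiparallel bundle
    ph <- (i - 1) * 100 * pi / 180
    hx <- cx + wobble_r * cos(ph + th)
    hy <- cy + wobble_r * sin(ph + th)
    xyz <- rbind(xyz, cbind(hx, hy, z))
    resid <- c(resid, resnos)
  }
  resname <- rep("ALA", length(resid))
  resname[resid == 123] <- "ARG"
  resname[resid == 360] <- "GLU"
  resname[resid %in% 410:414] <- c("ASN", "PRO", "LEU", "ILE", "TYR")
  if (state == "active") {
    # swing the intracellular half of TM6 outward and distort NPxxY
    tm6_ic <- resid %in% 351:360
    th6 <- 2 * pi * 5 / n_hel
    xyz[tm6_ic, 1] <- xyz[tm6_ic, 1] + 5 * cos(th6)
    xyz[tm6_ic, 2] <- xyz[tm6_ic, 2] + 5 * sin(th6)
    np <- which(resid %in% 410:414)
    xyz[np, 1] <- xyz[np, 1] + c(0.5, 1.2, 1.8, 1.2, 0.5)
    xyz[np, 3] <- xyz[np, 3] + c(0.4, 0.8, 1.2, 0.8, 0.4)
  }
  xyz <- round(unname(xyz), 3)
  domains <- rep(names(helix_resnos),
                 vapply(helix_resnos, length, integer(1)))
  names(domains) <- resid
  list(xyz = xyz,
       atoms = data.frame(resid = resid, resname = resname, name = "CA",
                          heavy = TRUE, mass = 12.011),
       selections = list(lock_a = 123, lock_b = 360, npxxy = 410:414,
                         as34 = c(125:129, 167:171),
                         as56 = c(215:219, 352:356)),
       domains = domains)
}
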