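#' One sampling stage of the docking protocol
#'
#' A fixed number of Metropolis MC steps with move-magnitude caps and a
#' temperature that is either fixed or ramped linearly from
#' `temperature[1]` to `temperature[2]` across the steps (simulated
#' annealing).
#'
#' @param n_steps number of MC steps (>= 1)
#' @param temperature Kelvin; length 1 (fixed) or 2 (linear start, end)
#' @param max_translation Angstrom
#' @param max_rotation degrees
#' @param max_dihedral degrees
#' @return an object of class `protocol_stage`
#' @export
protocol_stage <- function(n_steps, temperature, max_translation,
                           max_rotation, max_dihedral) {
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop("n_steps must be >= 1")
  if (!length(temperature) %in% 1:2 || any(temperature < 0))
    stop("temperature must be 1 or 2 non-negative values")
  if (any(c(max_translation, max_rotation, max_dihedral) < 0))
    stop("move caps must be >= 0")
  structure(list(n_steps = n_steps, temperature = as.numeric(temperature),
                 max_translation = max_translation,
                 max_rotation = max_rotation,
                 max_dihedral = max_dihedral),
            class = "protocol_stage")
}

#' The docking protocol: three stages plus the cycle/convergence loop
#'
#' Defaults are the standard exhaustive-mode protocol: (1) 10,000 MC steps
#' at 300 K with moves up to 1 Angstrom / 180 deg / 180 deg; (2) 10,000
#' local MC steps at 300 K with moves up to 0.2 Angstrom / 9 deg / 60 deg;
#' (3) 40,000 simulated-annealing steps cooled linearly from 300 to 0 K
#' with moves up to 0.2 Angstrom / 9 deg / 9 deg. The cycle of the three
#' stages is repeated up to 1000 times; every 100th cycle the LGFE spread
#' among the top three (deduplicated) poses is checked and sampling stops
#' as converged when it is below 0.03 kcal/mol.
#'
#' @param stages list of three [protocol_stage()]s
#' @param max_cycles maximum number of cycles (default 1000)
#' @param check_interval cycles between convergence checks (default 100)
#' @param convergence_tol kcal/mol (default 0.03)
#' @param top_k number of top poses compared (default 3)
#' @return an object of class `docking_protocol`
#' @export
docking_protocol <- function(stages = list(
                               protocol_stage(10000, 300, 1.0, 180, 180),
                               protocol_stage(10000, 300, 0.2, 9, 60),
                               protocol_stage(40000, c(300, 0), 0.2, 9, 9)),
                             max_cycles = 1000, check_interval = 100,
                             convergence_tol = 0.03, top_k = 3) {
  if (convergence_tol <= 0) stop("convergence_tol must be > 0")
  if (check_interval > max_cycles)
    stop("check_interval must be <= max_cycles")
  stopifnot(all(vapply(stages, inherits, logical(1), "protocol_stage")))
  structure(list(stages = stages, max_cycles = as.integer(max_cycles),
                 check_interval = as.integer(check_interval),
                 convergence_tol = convergence_tol,
                 top_k = as.integer(top_k)),
            class = "docking_protocol")
}

#' A reduced protocol for desk-scale block scans
#'
#' Scales the per-stage step counts of the default protocol by `factor`
#' and shortens the cycle loop; used by [identify_hotspots()] where many
#' blocks are docked.
#'
#' @param factor step-count scale (default 0.1)
#' @param max_cycles,check_interval cycle loop parameters
#' @param convergence_tol,top_k as in [docking_protocol()]
#' @return a [docking_protocol()]
#' @export
reduced_protocol <- function(factor = 0.1, max_cycles = 20,
                             check_interval = 10, convergence_tol = 0.03,
                             top_k = 3) {
  full <- docking_protocol()
  stages <- lapply(full$stages, function(s) {
    protocol_stage(max(1L, as.integer(round(s$n_steps * factor))),
                   s$temperature, s$max_translation, s$max_rotation,
                   s$max_dihedral)
  })
  docking_protocol(stages, max_cycles = max_cycles,
                   check_interval = check_interval,
                   convergence_tol = convergence_tol, top_k = top_k)
}

#' Metropolis acceptance decision
#'
#' Downhill or neutral proposals (`delta_energy <= 0`) are always accepted;
#' at zero temperature uphill proposals are always rejected; otherwise an
#' uphill proposal is accepted with probability
#' `exp(-delta_energy / (kB T))`.
#'
#' @param delta_energy kcal/mol (vectorized)
#' @param temperature Kelvin, >= 0
#' @return logical vector
#' @export
metropolis_accept <- function(delta_energy, temperature) {
  if (temperature < 0) stop("temperature must be >= 0")
  out <- delta_energy <= 0
  up <- !out
  if (any(up) && temperature > 0) {
    p <- exp(-delta_energy[up] / (KB_KCAL * temperature))
    out[up] <- runif(sum(up)) < p
  }
  out
}

# Marshal ligand/map data for the compiled engine.
engine_args <- function(lig, fragmaps, rules, config) {
  mt <- classify(lig, rules, strict = config$strict)
  map_names <- names(fragmaps$maps)
  map_idx <- match(mt, map_names) - 1L
  map_idx[is.na(map_idx)] <- -1L
  spec <- fragmaps$exclusion$spec
  list(map_idx = as.integer(map_idx),
       heavy = !lig$atoms$is_h,
       mass = lig$masses,
       grids = lapply(fragmaps$maps, function(g) as.vector(g$values)),
       excl = as.vector(fragmaps$exclusion$mask),
       origin = spec$origin, spacing = spec$spacing,
       dims = spec$dims,
       dihedrals = lig$dihedrals,
       clash_pairs = nonbonded_pairs(lig),
       excl_penalty = config$exclusion_penalty,
       barrier = config$dihedral_barrier,
       clash_dist = config$clash_distance,
       clash_k = config$clash_stiffness,
       intra_weight = config$intra_weight)
}

#' Run one protocol stage from a starting pose
#'
#' Executes exactly `stage$n_steps` Metropolis proposals, each a uniformly
#' chosen move kind (translate / rotate / dihedral, the latter only for
#' flexible ligands) within the stage's caps, with acceptance energy
#' `LGFE + intramolecular`. Simulated-annealing stages ramp the
#' temperature linearly across steps. Returns the final pose and the
#' best-LGFE pose seen.
#'
#' @param start an [pose()]
#' @param stage a [protocol_stage()]
#' @param fragmaps a [fragmap_set()]
#' @param rules a [classification_rules()] object
#' @param config a [scoring_config()]
#' @param return_log keep the per-step (temperature, delta E, accepted)
#'   trace?
#' @return list with `final` and `best` poses (scored), `n_accepted`, and
#'   optionally `log`
#' @export
run_stage <- function(start, stage, fragmaps, rules = default_rules(),
                      config = scoring_config(), return_log = FALSE) {
  ea <- engine_args(start$ligand, fragmaps, rules, config)
  tt <- stage$temperature
  res <- cpp_mc_stage(start$xyz, ea$map_idx, ea$heavy, ea$mass, ea$grids,
                      ea$excl, ea$origin, ea$spacing, ea$dims,
                      ea$dihedrals, ea$clash_pairs, ea$excl_penalty,
                      ea$barrier, ea$clash_dist, ea$clash_k,
                      ea$intra_weight,
                      stage$n_steps, tt[1], tt[length(tt)],
                      stage$max_translation, stage$max_rotation,
                      stage$max_dihedral, return_log)
  final <- pose(start$ligand, res$final_xyz, lgfe = res$final_lgfe)
  best <- pose(start$ligand, res$best_xyz, lgfe = res$best_lgfe)
  out <- list(final = final, best = best, n_accepted = res$n_accepted,
              n_uphill_at_T0 = res$n_uphill_at_T0)
  if (return_log) out$log <- res$log
  out
}

#' Define where docking cycles start
#'
#' A sphere (`center`, `radius`) or axis-aligned box (`lower`, `upper`)
#' from which each cycle draws a uniform random center-of-mass placement.
#'
#' @param center,radius sphere definition, Angstrom
#' @param lower,upper box definition, Angstrom
#' @return an object of class `start_region`
#' @export
start_region <- function(center = NULL, radius = NULL, lower = NULL,
                         upper = NULL) {
  if (!is.null(center)) {
    if (is.null(radius) || radius < 0) stop("sphere needs radius >= 0")
    return(structure(list(kind = "sphere", center = as.numeric(center),
                          radius = radius), class = "start_region"))
  }
  if (is.null(lower) || is.null(upper)) stop("empty start region")
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (any(upper < lower)) stop("box upper must be >= lower")
  structure(list(kind = "box", lower = lower, upper = upper),
            class = "start_region")
}

sample_in_region <- function(region) {
  if (region$kind == "sphere") {
    if (region$radius == 0) return(region$center)
    repeat {
      u <- runif(3, -1, 1)
      if (sum(u^2) <= 1) return(region$center + u * region$radius)
    }
  }
  runif(3, region$lower, region$upper)
}

region_center <- function(region) {
  if (region$kind == "sphere") region$center
  else (region$lower + region$upper) / 2
}

# Deduplicate LGFE-sorted poses: keep a pose only if its COM is >= min_sep
# from every already-kept pose; ties in LGFE resolve by retention order
# (lower LGFE kept first).
dedup_poses <- function(coms, lgfes, min_sep = 0.5) {
  ord <- order(lgfes)
  keep <- integer(0)
  for (i in ord) {
    if (length(keep) == 0L) { keep <- i; next }
    d2 <- colSums((t(coms[keep, , drop = FALSE]) - coms[i, ])^2)
    if (all(d2 >= min_sep^2)) keep <- c(keep, i)
  }
  keep
}

#' Dock a ligand against a fragment-map set
#'
#' Each cycle draws a uniform random center-of-mass placement in
#' `region` with a uniform random orientation, then runs the protocol's
#' three stages; the best-LGFE pose seen in the cycle is retained. Every
#' `check_interval` cycles the retained poses are deduplicated (center-of-
#' mass distance < 0.5 Angstrom keeps the lower LGFE) and sampling stops,
#' flagged converged, when the LGFE spread between rank 1 and rank
#' `top_k` (or the lowest available rank when fewer distinct poses exist)
#' is below `convergence_tol`. The result's best pose is the lowest-LGFE
#' pose overall.
#'
#' @param lig an [ligand()]
#' @param region a [start_region()]
#' @param fragmaps a [fragmap_set()]
#' @param rules a [classification_rules()] object
#' @param protocol a [docking_protocol()]
#' @param config a [scoring_config()]
#' @param seed integer seed for reproducibility, or NULL
#' @param dedup_radius COM distance below which poses are duplicates
#' @return an object of class `docking_result`: `best_pose`, `top_poses`
#'   (deduplicated, LGFE-ranked), `n_cycles_run`, `converged`, `seed`
#' @export
dock <- function(lig, region, fragmaps, rules = default_rules(),
                 protocol = docking_protocol(), config = scoring_config(),
                 seed = NULL, dedup_radius = 0.5) {
  stopifnot(inherits(region, "start_region"))
  spec <- fragmaps$exclusion$spec
  ctr <- region_center(region)
  up <- grid_upper(spec)
  if (any(ctr < spec$origin - spec$spacing) || any(ctr > up + spec$spacing))
    stop("start_region lies outside the map box")
  ea <- engine_args(lig, fragmaps, rules, config)
  with_seed(seed, {
    n_max <- protocol$max_cycles
    coms <- matrix(NA_real_, n_max, 3)
    lgfes <- rep(NA_real_, n_max)
    xyzs <- vector("list", n_max)
    converged <- FALSE
    n_run <- 0L
    base_xyz <- sweep(lig$xyz, 2, center_of_mass(lig$xyz, lig$masses))
    for (cyc in seq_len(n_max)) {
      com0 <- sample_in_region(region)
      R <- random_rotation_matrix()
      xyz <- sweep(base_xyz %*% t(R), 2, com0, "+")
      best_lgfe <- Inf
      best_xyz <- xyz
      for (st in protocol$stages) {
        tt <- st$temperature
        res <- cpp_mc_stage(xyz, ea$map_idx, ea$heavy, ea$mass, ea$grids,
                            ea$excl, ea$origin, ea$spacing, ea$dims,
                            ea$dihedrals, ea$clash_pairs, ea$excl_penalty,
                            ea$barrier, ea$clash_dist, ea$clash_k,
                            ea$intra_weight,
                            st$n_steps, tt[1], tt[length(tt)],
                            st$max_translation, st$max_rotation,
                            st$max_dihedral, FALSE)
        xyz <- res$final_xyz
        if (res$best_lgfe < best_lgfe) {
          best_lgfe <- res$best_lgfe
          best_xyz <- res$best_xyz
        }
      }
      n_run <- cyc
      coms[cyc, ] <- center_of_mass(best_xyz, lig$masses)
      lgfes[cyc] <- best_lgfe
      xyzs[[cyc]] <- best_xyz
      if (cyc %% protocol$check_interval == 0L) {
        keep <- dedup_poses(coms[seq_len(cyc), , drop = FALSE],
                            lgfes[seq_len(cyc)], dedup_radius)
        k <- min(protocol$top_k, length(keep))
        spread <- lgfes[keep[k]] - lgfes[keep[1]]
        if (spread < protocol$convergence_tol) { converged <- TRUE; break }
      }
    }
    keep <- dedup_poses(coms[seq_len(n_run), , drop = FALSE],
                        lgfes[seq_len(n_run)], dedup_radius)
    top <- lapply(keep, function(i) pose(lig, xyzs[[i]], lgfe = lgfes[i]))
    structure(list(best_pose = top[[1]], top_poses = top,
                   n_cycles_run = n_run, converged = converged,
                   seed = seed),
              class = "docking_result")
  })
}

#' @export
print.docking_result <- function(x, ...) {
  cat(sprintf("<docking_result: best LGFE %.3f kcal/mol, %d cycles, %s, %d distinct poses>\n",
              x$best_pose$lgfe, x$n_cycles_run,
              if (x$converged) "converged" else "not converged",
              length(x$top_poses)))
  invisible(x)
}
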