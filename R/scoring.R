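#' Scoring configuration
#'
#' Houses the exclusion penalty added to the ligand GFE for non-hydrogen
#' atoms overlapping the exclusion map (default 1000 kcal/mol) and the
#' parameters of the intramolecular-energy surrogate used in the Metropolis
#' criterion: a 3-fold cosine barrier on each rotatable torsion and a
#' harmonic soft-sphere clash penalty for nonbonded heavy-atom pairs closer
#' than the clash distance.
#'
#' @param exclusion_penalty kcal/mol, > 0 (default 1000)
#' @param dihedral_barrier torsion barrier height, kcal/mol
#' @param clash_distance heavy-atom clash onset distance, Angstrom
#' @param clash_stiffness kcal/mol/A^2
#' @param intra_weight weight of the intramolecular term in the acceptance
#'   energy (LGFE + intra_weight * E_intra)
#' @param strict reject atoms whose map type is absent from the map set
#'   (default: treat as bulk, contributing 0)
#' @return an object of class `scoring_config`
#' @export
scoring_config <- function(exclusion_penalty = 1000, dihedral_barrier = 2.0,
                           clash_distance = 2.0, clash_stiffness = 50,
                           intra_weight = 1.0, strict = FALSE) {
  if (exclusion_penalty <= 0) stop("exclusion_penalty must be > 0")
  structure(list(exclusion_penalty = exclusion_penalty,
                 dihedral_barrier = dihedral_barrier,
                 clash_distance = clash_distance,
                 clash_stiffness = clash_stiffness,
                 intra_weight = intra_weight,
                 strict = strict),
            class = "scoring_config")
}

#' Atomic GFE contributions
#'
#' For each (coordinate, map type) pair: a location inside the exclusion
#' map scores the exclusion penalty; an unmapped atom scores 0; otherwise
#' the nearest-voxel GFE of the matching map. Hydrogens should be passed
#' as "unmapped" (only non-hydrogen atoms are scored).
#'
#' @param coords n x 3 matrix (or length-3 vector), Angstrom
#' @param map_types character vector (length n or 1) of map types or
#'   "unmapped"
#' @param fragmaps a [fragmap_set()]
#' @param config a [scoring_config()]
#' @return numeric vector of per-atom GFE values, kcal/mol
#' @export
atomic_gfe <- function(coords, map_types, fragmaps,
                       config = scoring_config()) {
  coords <- rbind_points(coords)
  n <- nrow(coords)
  if (length(map_types) == 1L) map_types <- rep(map_types, n)
  stopifnot(length(map_types) == n)
  bad <- !(map_types %in% c(MAP_TYPES, "unmapped"))
  if (any(bad)) stop("invalid map type(s): ",
                     paste(unique(map_types[bad]), collapse = ", "))
  out <- numeric(n)
  excluded <- is_excluded(fragmaps$exclusion, coords)
  out[excluded] <- config$exclusion_penalty
  todo <- !excluded & map_types != "unmapped"
  for (mt in unique(map_types[todo])) {
    sel <- todo & map_types == mt
    g <- fragmaps$maps[[mt]]
    if (is.null(g)) {
      if (config$strict)
        stop("map type '", mt, "' absent from the fragmap set")
      next  # permissive: bulk, 0
    }
    out[sel] <- gfe_at(g, coords[sel, , drop = FALSE])
  }
  out
}

#' Ligand GFE (LGFE) of a pose
#'
#' The predicted binding strength: the sum of atomic GFE contributions over
#' non-hydrogen atoms, including the exclusion penalty for atoms overlapping
#' the exclusion map.
#'
#' @param p an [pose()]
#' @param fragmaps a [fragmap_set()]
#' @param rules a [classification_rules()] object
#' @param config a [scoring_config()]
#' @return list with `lgfe` (kcal/mol) and `atomic` (per-atom breakdown,
#'   zeros for hydrogens; sums to `lgfe`)
#' @export
lgfe <- function(p, fragmaps, rules = default_rules(),
                 config = scoring_config()) {
  mt <- classify(p$ligand, rules, strict = config$strict)
  atomic <- numeric(nrow(p$xyz))
  heavy <- !p$ligand$atoms$is_h
  if (any(heavy)) {
    atomic[heavy] <- atomic_gfe(p$xyz[heavy, , drop = FALSE], mt[heavy],
                                fragmaps, config)
  }
  list(lgfe = sum(atomic), atomic = atomic)
}

#' Intramolecular energy surrogate
#'
#' A simple internal-coordinate energy standing in for a force-field
#' intramolecular term in the Metropolis criterion: a 3-fold cosine barrier
#' `(V/2)(1 + cos 3*phi)` on each rotatable torsion plus a harmonic
#' soft-sphere penalty `(k/2)(d_clash - r)^2` for every nonbonded
#' heavy-atom pair closer than the clash distance. Depends only on internal
#' coordinates, so it is invariant under rigid translation and rotation.
#'
#' @param p an [pose()]
#' @param config a [scoring_config()]
#' @return kcal/mol
#' @export
intramolecular_energy <- function(p, config = scoring_config()) {
  lig <- p$ligand
  e <- 0
  for (dih in lig$dihedrals) {
    phi <- dihedral_angle(p$xyz, dih$atoms)
    e <- e + 0.5 * config$dihedral_barrier * (1 + cos(3 * phi))
  }
  pairs <- nonbonded_pairs(lig)
  if (nrow(pairs)) {
    d <- sqrt(rowSums((p$xyz[pairs[, 1], , drop = FALSE] -
                         p$xyz[pairs[, 2], , drop = FALSE])^2))
    close <- d < config$clash_distance
    if (any(close))
      e <- e + sum(0.5 * config$clash_stiffness *
                     (config$clash_distance - d[close])^2)
  }
  e
}

#' Score a pose in place
#'
#' Fills `lgfe`, `atomic_gfe` and `intramolecular_energy`.
#'
#' @inheritParams lgfe
#' @return the scored [pose()]
#' @export
score_pose <- function(p, fragmaps, rules = default_rules(),
                       config = scoring_config()) {
  s <- lgfe(p, fragmaps, rules, config)
  p$lgfe <- s$lgfe
  p$atomic_gfe <- s$atomic
  p$intramolecular_energy <- intramolecular_energy(p, config)
  p
}
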