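#' Construct a ligand model
#'
#' A ligand carries classified atoms, Cartesian coordinates, a bond list,
#' and rotatable dihedrals. Rotatable dihedrals are derived from the bond
#' graph by the rule: a bond is rotatable iff it is a non-ring single bond
#' with at least one heavy atom on each side beyond the bond itself
#' (terminal-bond torsions are excluded). Each rotatable dihedral records
#' the set of downstream atoms a rotation moves.
#'
#' @param elements character vector of element symbols
#' @param classes character vector of atom-class labels (scoring classes)
#' @param xyz n x 3 coordinate matrix, Angstrom
#' @param bonds m x 2 integer matrix of 1-based atom index pairs (may have
#'   zero rows)
#' @param is_h logical; hydrogen flags (default: element == "H")
#' @param name optional label
#' @return an object of class `fd_ligand`
#' @export
ligand <- function(elements, classes, xyz, bonds = NULL, is_h = NULL,
                   name = "ligand") {
  xyz <- rbind_points(xyz)
  n <- nrow(xyz)
  if (length(elements) != n || length(classes) != n)
    stop("elements, classes and xyz must agree in length")
  if (any(!is.finite(xyz))) stop("coordinates must be finite")
  if (is.null(is_h)) is_h <- elements == "H"
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) && (any(bonds < 1L) || any(bonds > n)))
    stop("bond indices out of range")
  dihedrals <- derive_rotatable_dihedrals(bonds, is_h, n)
  structure(list(
    atoms = data.frame(element = elements, class = classes, is_h = is_h,
                       stringsAsFactors = FALSE),
    xyz = unname(xyz),
    bonds = bonds,
    dihedrals = dihedrals,
    masses = element_mass(elements),
    name = name
  ), class = "fd_ligand")
}

#' @export
print.fd_ligand <- function(x, ...) {
  cat(sprintf("<fd_ligand '%s': %d atoms (%d heavy), %d bonds, %d rotatable dihedrals>\n",
              x$name, nrow(x$atoms), sum(!x$atoms$is_h), nrow(x$bonds),
              length(x$dihedrals)))
  invisible(x)
}

adjacency_list <- function(bonds, n) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# Connected component containing `start`, with bond (a, b) removed.
component_without_bond <- function(adj, start, a, b) {
  seen <- logical(length(adj))
  stack <- start
  seen[start] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (w in adj[[v]]) {
      if ((v == a && w == b) || (v == b && w == a)) next
      if (!seen[w]) { seen[w] <- TRUE; stack <- c(stack, w) }
    }
  }
  which(seen)
}

# A bond is in a ring iff its endpoints stay connected when it is removed.
bond_in_ring <- function(adj, a, b) {
  b %in% component_without_bond(adj, a, a, b)
}

derive_rotatable_dihedrals <- function(bonds, is_h, n) {
  if (nrow(bonds) == 0L) return(list())
  adj <- adjacency_list(bonds, n)
  out <- list()
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    if (is_h[i] || is_h[j]) next
    heavy_nb_i <- setdiff(adj[[i]][!is_h[adj[[i]]]], j)
    heavy_nb_j <- setdiff(adj[[j]][!is_h[adj[[j]]]], i)
    if (length(heavy_nb_i) == 0L || length(heavy_nb_j) == 0L) next
    if (bond_in_ring(adj, i, j)) next
    a <- min(heavy_nb_i); b <- min(heavy_nb_j)
    moving <- setdiff(component_without_bond(adj, j, i, j), j)
    out[[length(out) + 1L]] <- list(atoms = c(a, i, j, b), moving = moving)
  }
  out
}

# Heavy-atom pairs separated by >2 bonds (excludes 1-2 and 1-3 pairs); used
# for the soft-sphere clash term.
nonbonded_pairs <- function(lig) {
  n <- nrow(lig$atoms)
  heavy <- which(!lig$atoms$is_h)
  if (length(heavy) < 2L) return(matrix(integer(0), ncol = 2))
  adj <- adjacency_list(lig$bonds, n)
  near <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nb <- adj[[i]]
    near[i, nb] <- TRUE
    for (j in nb) near[i, adj[[j]]] <- TRUE  # 1-3
  }
  out <- list()
  for (a in seq_along(heavy)) {
    for (b in seq_len(a - 1L)) {
      i <- heavy[a]; j <- heavy[b]
      if (!near[i, j] && i != j) out[[length(out) + 1L]] <- c(j, i)
    }
  }
  if (length(out) == 0L) return(matrix(integer(0), ncol = 2))
  do.call(rbind, out)
}

#' Atom-class to map-type classification rules
#'
#' A named character vector mapping atom-class labels to fragment-map types
#' (or `"unmapped"`). Every referenced map type must be one of the eight
#' [MAP_TYPES].
#'
#' @param entries named character vector, class -> map type
#' @param provenance free-text note on where the table came from
#' @return an object of class `classification_rules`
#' @export
classification_rules <- function(entries, provenance = "") {
  bad <- setdiff(unique(entries), c(MAP_TYPES, "unmapped"))
  if (length(bad))
    stop("unknown map type(s) in rules: ", paste(bad, collapse = ", "))
  structure(list(entries = entries, provenance = provenance),
            class = "classification_rules")
}

#' Default classification rules for the shipped ligand templates
#'
#' Schematic stand-in table: aliphatic carbon scores on the hydrophobic map,
#' heterocycle carbon on GEHC, donor nitrogen on HBDON, carbonyl/acceptor
#' oxygen on HBACC, protonated amine nitrogen on MAMN, carboxylate carbon on
#' ACEC, hydroxyl oxygen on MEOO, amide carbon on FORC. Sulfur is carried
#' for geometry only (unmapped).
#'
#' @return a [classification_rules()] object
#' @export
default_rules <- function() {
  classification_rules(c(
    CAL = "APOLAR",   # aliphatic/aromatic carbon
    CHC = "GEHC",     # heterocycle carbon
    NDA = "HBDON",    # amide/amine donor nitrogen
    OAC = "HBACC",    # carbonyl / anionic oxygen (acceptor)
    NPO = "MAMN",     # protonated / quaternary amine nitrogen
    CCX = "ACEC",     # carboxylate carbon
    OHX = "MEOO",     # hydroxyl oxygen
    CAM = "FORC",     # amide carbonyl carbon
    SUL = "unmapped", # sulfur: geometry only
    HX  = "unmapped"  # hydrogen
  ), provenance = "shipped defaults covering the synthetic templates")
}

#' Read a classification rule file
#'
#' Plain-text two-column table (class, map_type), `#` comments allowed.
#'
#' @param path rule file
#' @return a [classification_rules()] object
#' @export
read_classification_rules <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE,
                           col.names = c("class", "map_type"))
  classification_rules(stats::setNames(tab$map_type, tab$class),
                       provenance = path)
}

#' Write a classification rule file
#' @param rules a [classification_rules()] object
#' @param path output file
#' @return `path`, invisibly
#' @export
write_classification_rules <- function(rules, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# atom_class  map_type", con)
  writeLines(sprintf("%-10s %s", names(rules$entries), rules$entries), con)
  invisible(path)
}

#' Assign a map type to every atom of a ligand
#'
#' Hydrogens are always unmapped (only non-hydrogen atoms are scored). In
#' permissive mode (default) heavy atoms whose class is absent from the
#' rules are unmapped and contribute zero GFE; strict mode rejects them.
#'
#' @param lig an [ligand()]
#' @param rules a [classification_rules()] object
#' @param strict reject unknown classes?
#' @return character vector of map types (`"unmapped"` where not scored)
#' @export
classify <- function(lig, rules = default_rules(), strict = FALSE) {
  cls <- lig$atoms$class
  out <- unname(rules$entries[cls])
  unknown <- is.na(out)
  if (strict && any(unknown & !lig$atoms$is_h))
    stop("atom class(es) not in rules: ",
         paste(unique(cls[unknown & !lig$atoms$is_h]), collapse = ", "))
  out[unknown] <- "unmapped"
  out[lig$atoms$is_h] <- "unmapped"
  out
}

#' Mass-weighted center of mass
#'
#' @param coords n x 3 matrix
#' @param masses numeric vector (default: equal masses)
#' @return length-3 numeric
#' @export
center_of_mass <- function(coords, masses = NULL) {
  coords <- rbind_points(coords)
  if (nrow(coords) == 0L) stop("empty selection: no atoms for center of mass")
  if (is.null(masses)) masses <- rep(1, nrow(coords))
  if (length(masses) != nrow(coords)) stop("masses length mismatch")
  colSums(coords * masses) / sum(masses)
}

#' A placed ligand conformation
#'
#' @param lig the parent [ligand()]
#' @param xyz n x 3 coordinates (default: the ligand's template coordinates)
#' @param lgfe,atomic_gfe,intramolecular_energy filled by [score_pose()]
#' @return an object of class `fd_pose`
#' @export
pose <- function(lig, xyz = lig$xyz, lgfe = NA_real_, atomic_gfe = NULL,
                 intramolecular_energy = NA_real_) {
  xyz <- rbind_points(xyz)
  stopifnot(nrow(xyz) == nrow(lig$atoms))
  structure(list(ligand = lig, xyz = unname(xyz), lgfe = lgfe,
                 atomic_gfe = atomic_gfe,
                 intramolecular_energy = intramolecular_energy),
            class = "fd_pose")
}

#' Center of mass of a pose
#' @param p an [pose()]
#' @return length-3 numeric
#' @export
pose_com <- function(p) center_of_mass(p$xyz, p$ligand$masses)

#' Describe a Monte Carlo move
#'
#' Three kinds: `translate` (rigid shift), `rotate` (rigid rotation about
#' the center of mass), `dihedral` (rotation of the downstream atoms about
#' a rotatable bond). Each can either carry an explicit displacement
#' (`delta` / `axis`+`angle` / `angle`) or a `max` cap from which
#' [apply_move()] samples uniformly: translation = uniform random direction
#' with magnitude uniform in `[0, max]`; rotation = uniform random axis with
#' angle uniform in `[-max, max]`; dihedral likewise on its torsion angle.
#' Angles are in degrees.
#'
#' @param kind "translate", "rotate" or "dihedral"
#' @param max magnitude cap (Angstrom or degrees), used when sampling
#' @param delta explicit translation 3-vector
#' @param axis explicit rotation axis
#' @param angle explicit angle, degrees
#' @param dihedral 1-based index of the target rotatable dihedral
#' @return an object of class `fd_move`
#' @export
mc_move <- function(kind = c("translate", "rotate", "dihedral"),
                    max = NULL, delta = NULL, axis = NULL, angle = NULL,
                    dihedral = NULL) {
  kind <- match.arg(kind)
  if (kind == "dihedral" && is.null(dihedral))
    stop("dihedral moves need a target dihedral index")
  structure(list(kind = kind, max = max, delta = delta, axis = axis,
                 angle = angle, dihedral = dihedral), class = "fd_move")
}

#' Apply a Monte Carlo move to a pose
#'
#' Rigid moves preserve all bond lengths and angles exactly (up to floating
#' point); dihedral moves rotate only the recorded downstream atom set about
#' the bond axis. Sampled components draw from R's RNG.
#'
#' @param p an [pose()]
#' @param move an [mc_move()]
#' @return a new, unscored [pose()]
#' @export
apply_move <- function(p, move) {
  stopifnot(inherits(p, "fd_pose"), inherits(move, "fd_move"))
  xyz <- p$xyz
  if (move$kind == "translate") {
    delta <- move$delta
    if (is.null(delta)) {
      u <- rnorm(3); nu <- sqrt(sum(u^2))
      u <- if (nu < 1e-12) c(1, 0, 0) else u / nu
      delta <- u * runif(1, 0, move$max %||% 0)
    }
    xyz <- sweep(xyz, 2, delta, "+")
  } else if (move$kind == "rotate") {
    axis <- move$axis
    angle <- move$angle
    if (is.null(axis)) { axis <- rnorm(3); if (sum(axis^2) < 1e-12) axis <- c(0, 0, 1) }
    if (is.null(angle)) angle <- runif(1, -(move$max %||% 0), move$max %||% 0)
    if (angle != 0) {
      com <- center_of_mass(xyz, p$ligand$masses)
      R <- rotation_matrix(axis, angle * pi / 180)
      xyz <- sweep(sweep(xyz, 2, com) %*% t(R), 2, com, "+")
    }
  } else {
    k <- move$dihedral
    if (k < 1L || k > length(p$ligand$dihedrals))
      stop("dihedral index out of range: ", k)
    angle <- move$angle
    if (is.null(angle)) angle <- runif(1, -(move$max %||% 0), move$max %||% 0)
    if (angle != 0) {
      dih <- p$ligand$dihedrals[[k]]
      jatom <- dih$atoms[2]; katom <- dih$atoms[3]
      axis <- xyz[katom, ] - xyz[jatom, ]
      R <- rotation_matrix(axis, angle * pi / 180)
      mov <- dih$moving
      xyz[mov, ] <- sweep(sweep(xyz[mov, , drop = FALSE], 2, xyz[katom, ]) %*%
                            t(R), 2, xyz[katom, ], "+")
    }
  }
  pose(p$ligand, xyz)
}

# Signed dihedral angle (radians) for atom quadruple rows of xyz.
dihedral_angle <- function(xyz, quad) {
  b1 <- xyz[quad[2], ] - xyz[quad[1], ]
  b2 <- xyz[quad[3], ] - xyz[quad[2], ]
  b3 <- xyz[quad[4], ] - xyz[quad[3], ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  nb2 <- sqrt(sum(b2^2))
  atan2(sum(m1 * n2) / nb2, sum(n1 * n2))
}
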