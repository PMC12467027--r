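#' Regular grid specification
#'
#' Defines a regular orthogonal lattice of voxels. `origin` is the Cartesian
#' position (in Angstrom) of the center of the first voxel; voxel centers sit
#' at `origin + (i-1) * spacing` along each axis.
#'
#' @param origin length-3 numeric, Angstrom
#' @param spacing voxel spacing, Angstrom (default 1.0, the conventional map
#'   resolution)
#' @param dims length-3 positive integer voxel counts
#' @return an object of class `grid_spec`
#' @export
grid_spec <- function(origin = c(0, 0, 0), spacing = 1.0, dims) {
  origin <- as.numeric(origin)
  dims <- as.integer(dims)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be a finite 3-vector")
  if (length(spacing) != 1L || !is.finite(spacing) || spacing <= 0)
    stop("spacing must be a single positive number")
  if (length(dims) != 3L || any(dims < 1L))
    stop("dims must be three counts >= 1")
  structure(list(origin = origin, spacing = as.numeric(spacing), dims = dims),
            class = "grid_spec")
}

#' Voxel center coordinates along one axis
#' @param spec a [grid_spec()]
#' @param axis 1, 2 or 3
#' @return numeric vector of voxel-center coordinates
#' @export
voxel_centers <- function(spec, axis) {
  spec$origin[axis] + (seq_len(spec$dims[axis]) - 1) * spec$spacing
}

# Upper corner of the grid bounding box (center of the last voxel).
grid_upper <- function(spec) spec$origin + (spec$dims - 1L) * spec$spacing

#' Map Cartesian points to nearest-voxel indices
#'
#' Points are assigned to the voxel whose center is nearest; a point exactly
#' midway between two voxel centers is assigned to the higher-index voxel
#' (round-half-up in fractional grid coordinates). Points outside the grid
#' get NA indices.
#'
#' @param spec a [grid_spec()]
#' @param points n x 3 matrix (or length-3 vector) of coordinates, Angstrom
#' @return n x 3 integer matrix of 1-based voxel indices, NA where outside
#' @export
voxel_index <- function(spec, points) {
  points <- rbind_points(points)
  idx <- floor(sweep(points, 2, spec$origin) / spec$spacing + 0.5) + 1
  for (a in 1:3) idx[idx[, a] < 1L | idx[, a] > spec$dims[a], a] <- NA_integer_
  out <- matrix(as.integer(idx), ncol = 3)
  out[!stats::complete.cases(out), ] <- NA_integer_
  out
}

rbind_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  if (ncol(points) != 3L) stop("points must have 3 columns")
  points
}

#' Grid free energy (GFE) map
#'
#' A voxelized free-energy field in kcal/mol for one functional-group map
#' type. Values are clamped to `[-cap, +cap]` at construction.
#'
#' @param spec a [grid_spec()]
#' @param map_type one of [MAP_TYPES]
#' @param values numeric array with dims `spec$dims`, kcal/mol
#' @param cap clamp magnitude, kcal/mol
#' @return an object of class `gfe_grid`
#' @export
gfe_grid <- function(spec, map_type, values, cap = 3) {
  stopifnot(inherits(spec, "grid_spec"))
  if (!map_type %in% MAP_TYPES)
    stop("map_type must be one of: ", paste(MAP_TYPES, collapse = ", "))
  values <- as.array(values)
  if (!identical(dim(values), as.integer(spec$dims)))
    stop("values dims do not match grid spec")
  if (any(!is.finite(values))) stop("grid values must be finite")
  values <- pmin(pmax(values, -cap), cap)
  structure(list(spec = spec, map_type = map_type, values = values,
                 cap = cap),
            class = "gfe_grid")
}

#' Exclusion map: solute/water-forbidden voxels
#'
#' @param spec a [grid_spec()]
#' @param mask logical array with dims `spec$dims`; TRUE = forbidden
#' @return an object of class `exclusion_map`
#' @export
exclusion_map <- function(spec, mask) {
  stopifnot(inherits(spec, "grid_spec"))
  mask <- as.array(mask)
  if (!identical(dim(mask), as.integer(spec$dims)))
    stop("mask dims do not match grid spec")
  storage.mode(mask) <- "logical"
  structure(list(spec = spec, mask = mask), class = "exclusion_map")
}

#' A set of fragment maps sharing one grid
#'
#' @param maps named list of [gfe_grid()]s keyed by map type
#' @param exclusion an [exclusion_map()], or NULL for none (an all-FALSE map
#'   is substituted)
#' @param temperature Kelvin; used for the Boltzmann weighting in
#'   [overlap_coefficient()] and available to the docking engine
#' @return an object of class `fragmap_set`
#' @export
fragmap_set <- function(maps, exclusion = NULL, temperature = 300) {
  if (length(maps) == 0L) stop("need at least one map")
  if (is.null(names(maps)) || any(names(maps) == ""))
    stop("maps must be a named list keyed by map type")
  specs <- lapply(maps, function(m) m$spec)
  ref <- specs[[1]]
  same <- vapply(specs, function(s) identical(unclass(s), unclass(ref)),
                 logical(1))
  if (!all(same)) stop("all grids in a fragmap_set must share one grid_spec")
  for (nm in names(maps)) {
    if (maps[[nm]]$map_type != nm)
      stop("map list name '", nm, "' disagrees with its map_type")
  }
  if (is.null(exclusion)) {
    exclusion <- exclusion_map(ref, array(FALSE, ref$dims))
  } else if (!identical(unclass(exclusion$spec), unclass(ref))) {
    stop("exclusion map grid_spec differs from the maps'")
  }
  structure(list(maps = maps, exclusion = exclusion,
                 temperature = temperature,
                 boltzmann_constant = KB_KCAL),
            class = "fragmap_set")
}

#' Boltzmann transform from fragment occupancy to grid free energy
#'
#' `GFE_v = -kB * T * ln(occupancy_v / bulk_value)`, clamped to
#' `[-cap, +cap]`. Zero occupancy (never-visited voxel) maps to `+cap`.
#'
#' @param occupancy non-negative numeric array of voxel occupancies
#' @param bulk_value bulk occupancy used for normalization (> 0, same units)
#' @param temperature Kelvin
#' @param cap clamp magnitude in kcal/mol (default 3; prevents unbounded
#'   values from empty voxels)
#' @param spec [grid_spec()] for the result
#' @param map_type map type tag for the result
#' @return a [gfe_grid()]
#' @export
occupancy_to_gfe <- function(occupancy, bulk_value, temperature = 300,
                             cap = 3, spec, map_type) {
  occupancy <- as.array(occupancy)
  if (any(!is.finite(occupancy)) || any(occupancy < 0))
    stop("occupancy must be finite and non-negative")
  if (bulk_value <= 0) stop("bulk_value must be > 0")
  if (temperature <= 0) stop("temperature must be > 0")
  g <- array(cap, dim(occupancy))
  pos <- occupancy > 0
  g[pos] <- -KB_KCAL * temperature * log(occupancy[pos] / bulk_value)
  g <- pmin(pmax(g, -cap), cap)
  gfe_grid(spec, map_type, g, cap = cap)
}

#' Look up grid free energy at Cartesian points
#'
#' Nearest-voxel lookup by default (matching the voxel-binned semantics of
#' the maps); trilinear interpolation is available and agrees with
#' nearest-voxel at voxel centers. Points outside the grid return 0 (bulk).
#'
#' @param grid a [gfe_grid()]
#' @param points n x 3 matrix or length-3 vector, Angstrom
#' @param mode "nearest" or "trilinear"
#' @return numeric vector of GFE values, kcal/mol
#' @export
gfe_at <- function(grid, points, mode = c("nearest", "trilinear")) {
  mode <- match.arg(mode)
  points <- rbind_points(points)
  if (mode == "nearest") {
    idx <- voxel_index(grid$spec, points)
    out <- numeric(nrow(points))
    ok <- stats::complete.cases(idx)
    if (any(ok)) out[ok] <- grid$values[idx[ok, , drop = FALSE]]
    return(out)
  }
  trilinear_at(grid, points)
}

# Trilinear interpolation on voxel centers; values beyond the outermost
# centers blend toward bulk (0).
trilinear_at <- function(grid, points) {
  spec <- grid$spec
  f <- sweep(points, 2, spec$origin) / spec$spacing  # fractional coords
  out <- numeric(nrow(points))
  d <- spec$dims
  for (p in seq_len(nrow(points))) {
    fp <- f[p, ]
    if (any(fp < -0.5 | fp > d - 0.5)) { out[p] <- 0; next }
    i0 <- floor(fp); w <- fp - i0
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      ii <- i0 + c(dx, dy, dz) + 1
      wt <- prod(ifelse(c(dx, dy, dz) == 1, w, 1 - w))
      v <- if (all(ii >= 1 & ii <= d)) grid$values[ii[1], ii[2], ii[3]] else 0
      acc <- acc + wt * v
    }
    out[p] <- acc
  }
  out
}

#' Test points against the exclusion map
#'
#' Nearest-voxel mask lookup; points outside the grid are never excluded
#' (bulk convention).
#'
#' @param excl an [exclusion_map()]
#' @param points n x 3 matrix or length-3 vector, Angstrom
#' @return logical vector
#' @export
is_excluded <- function(excl, points) {
  points <- rbind_points(points)
  idx <- voxel_index(excl$spec, points)
  out <- logical(nrow(points))
  ok <- stats::complete.cases(idx)
  if (any(ok)) out[ok] <- excl$mask[idx[ok, , drop = FALSE]]
  out
}

#' Overlap coefficient between two GFE maps
#'
#' Convergence statistic for map comparison: each map is converted to a
#' Boltzmann probability over its voxels, `p_v = exp(-GFE_v / (kB T))`
#' normalized to sum to 1, and the overlap is `sum_v min(p_v(a), p_v(b))`,
#' which lies in `[0, 1]` and equals 1 iff the normalized weights agree.
#' A value above 0.7 is the conventional convergence threshold.
#'
#' @param a,b [gfe_grid()]s sharing one grid spec and map type
#' @param temperature Kelvin for the Boltzmann weighting
#' @return scalar in `[0, 1]`
#' @export
overlap_coefficient <- function(a, b, temperature = 300) {
  if (!identical(unclass(a$spec), unclass(b$spec)))
    stop("grids must share one grid_spec")
  if (!identical(a$map_type, b$map_type))
    stop("grids must share one map_type")
  pa <- exp(-a$values / (KB_KCAL * temperature))
  pb <- exp(-b$values / (KB_KCAL * temperature))
  pa <- pa / sum(pa)
  pb <- pb / sum(pb)
  sum(pmin(pa, pb))
}
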