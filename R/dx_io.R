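#' Write a GFE grid in DX volumetric format
#'
#' Standard OpenDX scalar-field layout: a `gridpositions` object giving
#' counts, origin and three diagonal `delta` rows, a `gridconnections`
#' object, and the data array with the last (z) index varying fastest,
#' three values per line. The map type is recorded in a leading comment so
#' a round trip preserves it.
#'
#' @param grid a [gfe_grid()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_dx <- function(grid, path) {
  spec <- grid$spec
  d <- spec$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# GFE fragment map, DX scalar field",
    sprintf("# map_type %s", grid$map_type),
    sprintf("# cap %.6g", grid$cap),
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f",
            spec$origin[1], spec$origin[2], spec$origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", spec$spacing),
    sprintf("delta 0.000000 %.6f 0.000000", spec$spacing),
    sprintf("delta 0.000000 0.000000 %.6f", spec$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))
  ), con)
  vals <- sprintf("%.6e", as.vector(aperm(grid$values, c(3, 2, 1))))  # z fastest
  pad <- (-length(vals)) %% 3L
  if (pad) vals <- c(vals, rep("", pad))
  m <- matrix(vals, nrow = 3)
  writeLines(trimws(apply(m, 2, paste, collapse = " ")), con)
  invisible(path)
}

#' Read a GFE grid from a DX file
#'
#' Accepts the layout written by [write_dx()] (and the common OpenDX
#' variant thereof): diagonal deltas with equal spacing on all axes.
#' Malformed headers are rejected with a message naming the offending line.
#'
#' @param path DX file
#' @param map_type override for the map type; by default taken from the
#'   `# map_type` comment, falling back to "APOLAR"
#' @param cap clamp for the resulting grid; defaults to the `# cap` comment
#'   if present, else the max absolute value read
#' @return a [gfe_grid()]
#' @export
read_dx <- function(path, map_type = NULL, cap = NULL) {
  lines <- readLines(path)
  fail <- function(i, why) {
    stop(sprintf("malformed DX header at line %d ('%s'): %s",
                 i, lines[i], why))
  }
  for (ln in grep("^#", lines, value = TRUE)) {
    if (is.null(map_type) && grepl("^# map_type ", ln))
      map_type <- sub("^# map_type ", "", ln)
    if (is.null(cap) && grepl("^# cap ", ln))
      cap <- as.numeric(sub("^# cap ", "", ln))
  }
  ipos <- grep("^object 1 class gridpositions", lines)
  if (length(ipos) != 1L)
    stop("malformed DX file: no 'object 1 class gridpositions' line")
  toks <- strsplit(trimws(lines[ipos]), "\\s+")[[1]]
  counts <- suppressWarnings(as.integer(utils::tail(toks, 3)))
  if (any(is.na(counts)) || any(counts < 1L)) fail(ipos, "bad voxel counts")
  iorg <- grep("^origin", lines)
  if (length(iorg) != 1L) stop("malformed DX file: no 'origin' line")
  origin <- suppressWarnings(
    as.numeric(strsplit(trimws(lines[iorg]), "\\s+")[[1]][-1]))
  if (length(origin) != 3L || any(is.na(origin))) fail(iorg, "bad origin")
  idel <- grep("^delta", lines)
  if (length(idel) != 3L) stop("malformed DX file: need three 'delta' lines")
  deltas <- t(vapply(idel, function(i) {
    v <- suppressWarnings(
      as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]][-1]))
    if (length(v) != 3L || any(is.na(v))) fail(i, "bad delta row")
    v
  }, numeric(3)))
  diag_d <- diag(deltas)
  if (any(abs(deltas - diag(diag_d, 3)) > 1e-9))
    fail(idel[1], "only diagonal (axis-aligned) deltas are supported")
  if (max(diag_d) - min(diag_d) > 1e-9)
    fail(idel[1], "anisotropic spacing is not supported")
  idat <- grep("^object 3 class array", lines)
  if (length(idat) != 1L)
    stop("malformed DX file: no 'object 3 class array' line")
  n_items <- suppressWarnings(as.integer(
    sub(".*items\\s+(\\d+)\\s+data follows.*", "\\1", lines[idat])))
  if (is.na(n_items)) fail(idat, "cannot parse item count")
  if (n_items != prod(counts)) fail(idat, "item count != product of counts")
  body <- lines[(idat + 1L):length(lines)]
  body <- body[!grepl("^(#|object|attribute|component)", body)]
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(body), "\\s+"))))
  vals <- vals[!is.na(vals)]
  if (length(vals) < n_items)
    stop(sprintf("DX data section has %d values, expected %d",
                 length(vals), n_items))
  vals <- vals[seq_len(n_items)]
  arr <- aperm(array(vals, dim = rev(counts)), c(3, 2, 1))
  spec <- grid_spec(origin = origin, spacing = diag_d[1], dims = counts)
  if (is.null(cap)) cap <- max(abs(arr), 1e-12)
  gfe_grid(spec, map_type %||% "APOLAR", arr, cap = cap)
}
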