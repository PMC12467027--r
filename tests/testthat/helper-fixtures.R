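# Shared fixture builders. All fixtures are generated in code.

# Small random GFE map set on an n^3 grid (all eight map types).
random_fragmaps <- function(n = 8, seed = 1, cap = 5, spacing = 1,
                            origin = c(0, 0, 0)) {
  spec <- grid_spec(origin = origin, spacing = spacing, dims = rep(n, 3))
  with_seed(seed, {
    maps <- lapply(MAP_TYPES, function(mt)
      gfe_grid(spec, mt, array(rnorm(n^3), rep(n, 3)), cap = cap))
    names(maps) <- MAP_TYPES
    fragmap_set(maps)
  })
}

# Independent brute-force LGFE oracle: nearest-voxel lookup and summation
# written from scratch against the raw arrays (no package scoring path).
brute_force_lgfe <- function(xyz, map_types, fragmaps, penalty = 1000) {
  spec <- fragmaps$exclusion$spec
  total <- 0
  for (a in seq_len(nrow(xyz))) {
    mt <- map_types[a]
    if (mt == "unmapped") next
    idx <- integer(3)
    outside <- FALSE
    for (d in 1:3) {
      i <- floor((xyz[a, d] - spec$origin[d]) / spec$spacing + 0.5) + 1
      if (i < 1 || i > spec$dims[d]) { outside <- TRUE; break }
      idx[d] <- i
    }
    if (outside) next
    if (fragmaps$exclusion$mask[idx[1], idx[2], idx[3]]) {
      total <- total + penalty
    } else {
      total <- total + fragmaps$maps[[mt]]$values[idx[1], idx[2], idx[3]]
    }
  }
  total
}

# Multi-map planted well at one center covering the atom classes of the
# steroid templates.
steroid_well_maps <- function(center, depth = -3, width = 4,
                              dims = c(24, 24, 24), seed = NULL,
                              types = c("APOLAR", "MEOO", "ACEC", "HBACC",
                                        "FORC", "HBDON")) {
  spec <- grid_spec(dims = dims)
  wells <- lapply(types, function(mt) planted_well(center, depth, width, mt))
  make_fragmap_set(wells, spec, seed = seed)
}

# Two-frame helper: pairwise distance matrix of a coordinate set.
pairwise_dists <- function(xyz) as.matrix(stats::dist(xyz))
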