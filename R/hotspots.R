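#' Partition a bounding box into overlapping cubic blocks
#'
#' Block lower corners sit on a lattice of stride `edge - overlap` starting
#' at the box's lower corner; corners are placed at every stride multiple
#' strictly below the box extent, so the union of blocks always covers the
#' box (the last block along an axis may extend past the upper face).
#'
#' @param lower,upper box corners, Angstrom
#' @param edge cube edge, Angstrom (> 0)
#' @param overlap overlap between adjacent blocks, Angstrom (< edge)
#' @return data.frame with block `id`, center coordinates `cx, cy, cz`,
#'   and `edge`
#' @export
partition_space <- function(lower, upper, edge, overlap = 0) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (edge <= 0) stop("edge must be > 0")
  if (overlap >= edge) stop("overlap must be < edge")
  if (any(upper < lower)) stop("upper must be >= lower")
  stride <- edge - overlap
  corners <- lapply(1:3, function(a) {
    len <- upper[a] - lower[a]
    if (edge >= len) return(lower[a])
    k <- 0:ceiling(len / stride)
    cand <- lower[a] + k * stride
    cand[cand < upper[a] - 1e-9]
  })
  grid <- expand.grid(x = corners[[1]], y = corners[[2]], z = corners[[3]])
  data.frame(id = seq_len(nrow(grid)),
             cx = grid$x + edge / 2, cy = grid$y + edge / 2,
             cz = grid$z + edge / 2, edge = edge)
}

#' Leader clustering of docked poses
#'
#' Iterative neighbor-count clustering: the pose with the most neighbors
#' (center-of-mass distance <= `radius`) becomes a cluster center; it and
#' its neighbors are removed and the procedure repeats until no poses
#' remain. Neighbor-count ties resolve to the tied pose with the lower
#' LGFE (then lower index, for determinism).
#'
#' @param coms n x 3 matrix of pose centers of mass
#' @param lgfes length-n LGFE values
#' @param radius clustering radius, Angstrom (> 0)
#' @return list of clusters, each `list(center, members)` of row indices
#'   (the center is included among its members)
#' @export
cluster_poses <- function(coms, lgfes, radius) {
  if (radius <= 0) stop("radius must be > 0")
  coms <- rbind_points(coms)
  n <- nrow(coms)
  if (n == 0L) return(list())
  stopifnot(length(lgfes) == n)
  alive <- rep(TRUE, n)
  out <- list()
  d2 <- as.matrix(stats::dist(coms))^2
  r2 <- radius^2
  while (any(alive)) {
    idx <- which(alive)
    counts <- vapply(idx, function(i) sum(d2[i, idx] <= r2), integer(1))
    best <- counts == max(counts)
    cand <- idx[best]
    center <- cand[order(lgfes[cand], cand)][1]
    members <- idx[d2[center, idx] <= r2]
    alive[members] <- FALSE
    out[[length(out) + 1L]] <- list(center = center, members = members)
  }
  out
}

#' Global binding-site search: block docking, two-round clustering, ranking
#'
#' Docks every ligand of the panel in every cubic block of the search box,
#' pools the (deduplicated) poses per ligand, keeps poses more favorable
#' than `lgfe_cutoff`, clusters them per ligand to find local binding sites
#' (round 1), then clusters the round-1 centers across all ligands to find
#' common sites (round 2). Each final cluster is scored by the mean, over
#' the ligands present in it, of that ligand's best member LGFE, and
#' clusters are ranked ascending (rank 1 = most favorable).
#'
#' @param panel named list of [ligand()]s
#' @param fragmaps a [fragmap_set()]
#' @param rules a [classification_rules()] object
#' @param protocol a [docking_protocol()]; default [reduced_protocol()]
#'   for desk-scale block scans
#' @param config a [scoring_config()]
#' @param lower,upper search box (default: the map bounding box)
#' @param block_edge,block_overlap block partition, Angstrom
#' @param cluster_radius COM clustering radius, Angstrom
#' @param lgfe_cutoff poses with LGFE above this are not binding-site
#'   evidence and are dropped before clustering (kcal/mol)
#' @param lgfe_keep_frac in addition to `lgfe_cutoff`, a pose is kept only
#'   if it is at least this fraction as favorable as the same ligand's best
#'   pose (default 0.5); screens out shallow-rim poses without an absolute
#'   scale. Set to 0 to disable.
#' @param min_ligands a final cluster must contain at least this many panel
#'   ligands (default: a majority); round-2 clustering exists to find sites
#'   common to the panel, so single-ligand stragglers are not reported
#' @param pool_poses "all" (default) pools every distinct cycle pose of
#'   every block dock; "best" keeps only each block's best pose per ligand.
#'   Sampling is not confined to a block, so "best" can lose shallower
#'   sites when a deeper one is within diffusion reach
#' @param seed integer seed
#' @return data.frame of hotspots: `rank`, `cx, cy, cz` (center pose COM),
#'   `avg_lgfe`, `n_ligands`, and one `lgfe_<name>` column per panel
#'   ligand (NA where absent); attribute `"clusters"` holds the member
#'   detail
#' @export
identify_hotspots <- function(panel, fragmaps, rules = default_rules(),
                              protocol = reduced_protocol(),
                              config = scoring_config(),
                              lower = NULL, upper = NULL,
                              block_edge = 12, block_overlap = 3,
                              cluster_radius = 3.5, lgfe_cutoff = -0.5,
                              lgfe_keep_frac = 0.5,
                              min_ligands = ceiling(length(panel) / 2),
                              pool_poses = c("all", "best"), seed = NULL) {
  pool_poses <- match.arg(pool_poses)
  if (length(panel) == 0L) stop("ligand panel is empty")
  if (is.null(names(panel)))
    names(panel) <- paste0("ligand", seq_along(panel))
  spec <- fragmaps$exclusion$spec
  if (is.null(lower)) lower <- spec$origin
  if (is.null(upper)) upper <- grid_upper(spec)
  blocks <- partition_space(lower, upper, block_edge, block_overlap)

  with_seed(seed, {
    # per-ligand pose pools from exhaustive per-block docking
    pools <- lapply(names(panel), function(nm) {
      lig <- panel[[nm]]
      coms <- list(); lgfes <- list()
      for (b in seq_len(nrow(blocks))) {
        ctr <- c(blocks$cx[b], blocks$cy[b], blocks$cz[b])
        reg <- start_region(lower = pmax(ctr - block_edge / 2, lower),
                            upper = pmin(ctr + block_edge / 2, upper))
        dr <- dock(lig, reg, fragmaps, rules, protocol, config)
        keep <- if (pool_poses == "best") dr$top_poses[1] else dr$top_poses
        coms[[b]] <- t(vapply(keep, pose_com, numeric(3)))
        lgfes[[b]] <- vapply(keep, function(p) p$lgfe, numeric(1))
      }
      list(coms = do.call(rbind, coms), lgfes = unlist(lgfes))
    })
    names(pools) <- names(panel)

    # round 1: per-ligand clustering of favorable poses
    centers <- list()
    for (nm in names(pools)) {
      thr <- lgfe_cutoff
      best <- min(pools[[nm]]$lgfes)
      if (lgfe_keep_frac > 0 && best < 0)
        thr <- min(thr, lgfe_keep_frac * best)
      keep <- pools[[nm]]$lgfes <= thr
      if (!any(keep)) next
      coms <- pools[[nm]]$coms[keep, , drop = FALSE]
      lg <- pools[[nm]]$lgfes[keep]
      cl <- cluster_poses(coms, lg, cluster_radius)
      for (c1 in cl) {
        centers[[length(centers) + 1L]] <- list(
          ligand = nm, com = coms[c1$center, ],
          lgfe = min(lg[c1$members]))  # ligand's best member in the site
      }
    }
    if (length(centers) == 0L) {
      out <- data.frame(rank = integer(0), cx = numeric(0), cy = numeric(0),
                        cz = numeric(0), avg_lgfe = numeric(0),
                        n_ligands = integer(0))
      attr(out, "clusters") <- list()
      return(out)
    }

    # round 2: cluster the round-1 centers across ligands
    c_coms <- t(vapply(centers, function(x) x$com, numeric(3)))
    c_lgfe <- vapply(centers, function(x) x$lgfe, numeric(1))
    c_lig <- vapply(centers, function(x) x$ligand, character(1))
    cl2 <- cluster_poses(c_coms, c_lgfe, cluster_radius)

    rows <- lapply(cl2, function(cc) {
      ligs <- c_lig[cc$members]
      per_lig <- tapply(c_lgfe[cc$members], ligs, min)
      list(com = c_coms[cc$center, ], avg = mean(per_lig),
           per_lig = per_lig, n = length(per_lig), members = cc$members)
    })
    rows <- Filter(function(r) r$n >= min_ligands, rows)
    if (length(rows) == 0L) {
      out <- data.frame(rank = integer(0), cx = numeric(0), cy = numeric(0),
                        cz = numeric(0), avg_lgfe = numeric(0),
                        n_ligands = integer(0))
      attr(out, "clusters") <- list()
      return(out)
    }
    ord <- order(vapply(rows, `[[`, numeric(1), "avg"))
    rows <- rows[ord]
    out <- data.frame(
      rank = seq_along(rows),
      cx = vapply(rows, function(r) r$com[1], numeric(1)),
      cy = vapply(rows, function(r) r$com[2], numeric(1)),
      cz = vapply(rows, function(r) r$com[3], numeric(1)),
      avg_lgfe = vapply(rows, `[[`, numeric(1), "avg"),
      n_ligands = vapply(rows, `[[`, integer(1), "n"))
    for (nm in names(panel)) {
      out[[paste0("lgfe_", nm)]] <- vapply(rows, function(r) {
        if (nm %in% names(r$per_lig)) unname(r$per_lig[nm]) else NA_real_
      }, numeric(1))
    }
    attr(out, "clusters") <- rows
    attr(out, "parameters") <- list(block_edge = block_edge,
                                    block_overlap = block_overlap,
                                    cluster_radius = cluster_radius,
                                    lgfe_cutoff = lgfe_cutoff)
    out
  })
}
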