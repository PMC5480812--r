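#' Parameters of the synthetic connectome generator
#'
#' Defines the statistical structure of generated connectomes: an even
#' number of nodes split symmetrically across two hemispheres on a regular
#' grid, streamline counts whose expectation decays with inter-centroid
#' distance, planted hub nodes whose connections are boosted (rich-club
#' structure), homotopic interhemispheric edges routed through midline
#' "callosal" voxels, and multiplicative log-normal noise separating
#' subjects and repeated scans.
#'
#' @param n_nodes Even number of regions (default 80; 40 per hemisphere).
#' @param grid_shape,spacing Trajectory grid (default 64^3 voxels at 2 mm,
#'   origin centered so world coordinates span symmetrically around 0).
#' @param decay_length Distance constant (mm) of the streamline-count decay
#'   \code{exp(-d / decay_length)}.
#' @param density_length Distance constant (mm) of the edge-existence
#'   probability \code{exp(-d / density_length)}; short-range pairs connect
#'   almost surely, long-range pairs sparsely.
#' @param base_count Expected streamline count at zero distance.
#' @param hub_count Number of planted hub nodes (even; split across
#'   hemispheres).
#' @param hub_multiplier Count multiplier per hub endpoint.
#' @param homotopic_multiplier Count multiplier for homotopic (mirror-pair)
#'   interhemispheric edges, which always exist.
#' @param interhemispheric_density Multiplier on the existence probability
#'   of non-homotopic interhemispheric pairs; < 1 reproduces the callosal
#'   bottleneck (cross-hemisphere edges are systematically sparser than
#'   intra-hemisphere edges in tractography).
#' @param interhemispheric_weight Multiplier on the expected streamline
#'   count of interhemispheric pairs.
#' @param midline_fraction Fraction of interhemispheric trajectories routed
#'   through the callosal midline region (the rest detour inferiorly).
#' @param callosal_z,detour_z World z ranges (mm) of callosal and detour
#'   midline crossings.
#' @param min_separation Minimum inter-centroid distance within a
#'   hemisphere (mm); regions of an ~80-node parcellation are this far
#'   apart, so no edge can be engulfed whole by a focal lesion.
#' @param tube_radius Radius (mm) of the volumetric tube into which each
#'   trajectory polyline is dilated; fiber bundles have finite
#'   cross-section, which bounds the trajectory fraction a focal lesion can
#'   remove.
#' @param domain_extent Length-3 fractions of the grid half-extent occupied
#'   by the node cloud along x, y, z. Distinct extents (default wide
#'   anterior-posterior, flat superior-inferior, mimicking head geometry)
#'   keep the low diffusion gradients — interhemispheric, then
#'   anterior-posterior, then superior-inferior — spectrally separated
#'   rather than degenerate.
#' @param subject_sd,scan_sd Log-normal sd of the subject-level and
#'   scan-level multiplicative weight noise.
#' @param volume_meanlog,volume_sdlog Log-normal parameters of region
#'   volumes (voxels).
#' @return An object of class \code{generator_params}.
#' @export
generator_params <- function(n_nodes = 80,
                             grid_shape = c(64, 64, 64),
                             spacing = 2,
                             decay_length = 20,
                             density_length = 60,
                             base_count = 1500,
                             hub_count = 8,
                             hub_multiplier = 3,
                             homotopic_multiplier = 2,
                             interhemispheric_density = 0.3,
                             interhemispheric_weight = 0.5,
                             midline_fraction = 1,
                             callosal_z = c(15, 40),
                             detour_z = c(-45, -20),
                             domain_extent = c(0.85, 0.9, 0.5),
                             min_separation = 16,
                             tube_radius = 3,
                             subject_sd = 0.3,
                             scan_sd = 0.1,
                             volume_meanlog = log(300),
                             volume_sdlog = 0.3) {
  stopifnot(n_nodes >= 4, n_nodes %% 2 == 0,
            decay_length > 0, density_length > 0, base_count > 0,
            hub_count >= 0, hub_count %% 2 == 0, hub_multiplier >= 1,
            midline_fraction >= 0, midline_fraction <= 1,
            subject_sd >= 0, scan_sd >= 0)
  grid_shape <- as.integer(grid_shape)
  origin <- -(grid_shape - 1L) * spacing / 2   # world coords symmetric in 0
  structure(list(n_nodes = n_nodes,
                 grid = voxel_grid(origin, spacing, grid_shape),
                 decay_length = decay_length,
                 density_length = density_length,
                 base_count = base_count,
                 hub_count = hub_count,
                 hub_multiplier = hub_multiplier,
                 homotopic_multiplier = homotopic_multiplier,
                 interhemispheric_density = interhemispheric_density,
                 interhemispheric_weight = interhemispheric_weight,
                 midline_fraction = midline_fraction,
                 callosal_z = callosal_z,
                 detour_z = detour_z,
                 domain_extent = as.numeric(domain_extent),
                 min_separation = min_separation,
                 tube_radius = tube_radius,
                 subject_sd = subject_sd,
                 scan_sd = scan_sd,
                 volume_meanlog = volume_meanlog,
                 volume_sdlog = volume_sdlog),
            class = "generator_params")
}

# Sample voxels along a polyline (list of world points), optionally dilated
# into a tube of the given radius (mm); returns unique 0-based voxels,
# clipped to the grid. The tube emulates the volumetric cross-section of a
# fiber bundle, so a focal lesion removes a bounded fraction of the edge.
voxelize_polyline <- function(points, grid, tube_radius = 0) {
  step <- min(grid$spacing) / 2
  pts <- list()
  for (k in seq_len(length(points) - 1L)) {
    a <- points[[k]]; b <- points[[k + 1L]]
    len <- sqrt(sum((b - a)^2))
    tt <- seq(0, 1, length.out = max(2L, ceiling(len / step) + 1L))
    pts[[k]] <- cbind(a[1] + tt * (b[1] - a[1]),
                      a[2] + tt * (b[2] - a[2]),
                      a[3] + tt * (b[3] - a[3]))
  }
  vox <- world_to_voxel(do.call(rbind, pts), grid)
  vox <- vox[!duplicated(vox), , drop = FALSE]
  if (tube_radius > 0) {
    rad <- floor(tube_radius / grid$spacing)
    off <- as.matrix(expand.grid(-rad[1]:rad[1], -rad[2]:rad[2],
                                 -rad[3]:rad[3]))
    off <- off[colSums((t(off) * grid$spacing)^2) <= tube_radius^2, ,
               drop = FALSE]
    vox <- cbind(rep(vox[, 1L], each = nrow(off)) + off[, 1L],
                 rep(vox[, 2L], each = nrow(off)) + off[, 2L],
                 rep(vox[, 3L], each = nrow(off)) + off[, 3L])
    vox <- vox[!duplicated(vox), , drop = FALSE]
  }
  vox <- vox[in_grid(vox, grid), , drop = FALSE]
  as_voxel_matrix(vox)
}

#' Generate a synthetic connectome with edge trajectories
#'
#' Places \code{n_nodes/2} region centroids in the right half-grid and their
#' mirror images on the left, draws directed streamline counts with
#' distance-decaying expectation (boosted between hubs and for homotopic
#' pairs), normalizes them to adjacency weights by summed region volumes,
#' and embeds every edge as a discretized straight (intra-hemispheric) or
#' single-bend (interhemispheric, through midline voxels) polyline with
#' per-voxel streamline counts for both directions. Regeneration is
#' attempted when a draw comes out disconnected.
#'
#' @param params A [generator_params()].
#' @param seed Integer seed; the same seed reproduces the output exactly.
#' @param max_retry Retry limit for disconnected draws.
#' @return List with \code{connectome}, \code{trajectories}
#'   (\code{edge_trajectories}), and \code{hubs} (planted hub node ids).
#' @export
generate_connectome <- function(params = generator_params(), seed = 1,
                                max_retry = 10) {
  stopifnot(inherits(params, "generator_params"))
  seeds <- derive_seeds(seed, max_retry)
  for (attempt in seq_len(max_retry)) {
    out <- with_seed(seeds[attempt], generate_connectome_once(params))
    es <- eigendecompose(build_laplacian(out$connectome))
    if (n_zero_modes(es) == 1L) return(out)
  }
  stop("generator produced a disconnected graph in every retry", call. = FALSE)
}

generate_connectome_once <- function(params) {
  p <- params
  n <- p$n_nodes
  nh <- n %/% 2L
  grid <- p$grid
  ext <- (grid$shape - 1) * grid$spacing / 2   # world half-extent
  # right-hemisphere centroids; left is the exact mirror in x
  de <- p$domain_extent
  # rejection-sample right-hemisphere centroids at min_separation spacing
  rx <- ry <- rz <- numeric(nh)
  placed <- 0L
  tries <- 0L
  while (placed < nh) {
    if ((tries <- tries + 1L) > 200L * nh)
      stop("cannot place nodes at the requested separation", call. = FALSE)
    cx <- stats::runif(1, 0.15 * ext[1], de[1] * ext[1])
    cy <- stats::runif(1, -de[2] * ext[2], de[2] * ext[2])
    cz <- stats::runif(1, -de[3] * ext[3], de[3] * ext[3])
    if (placed > 0L) {
      d2 <- (rx[seq_len(placed)] - cx)^2 + (ry[seq_len(placed)] - cy)^2 +
        (rz[seq_len(placed)] - cz)^2
      if (min(d2) < p$min_separation^2) next
    }
    placed <- placed + 1L
    rx[placed] <- cx; ry[placed] <- cy; rz[placed] <- cz
  }
  centroid <- rbind(cbind(-rx, ry, rz), cbind(rx, ry, rz))
  node_ids <- c(sprintf("L%02d", seq_len(nh)), sprintf("R%02d", seq_len(nh)))
  hemisphere <- rep(c("left", "right"), each = nh)
  volume <- pmax(50, round(stats::rlnorm(n, p$volume_meanlog, p$volume_sdlog)))
  hubs <- if (p$hub_count > 0) {
    h <- sample.int(nh, p$hub_count %/% 2L)
    c(node_ids[h], node_ids[nh + h])
  } else character()
  is_hub <- node_ids %in% hubs
  d <- as.matrix(stats::dist(centroid))
  mirror_pair <- outer(seq_len(n), seq_len(n), function(i, j)
    abs(i - j) == nh)
  boost <- outer(ifelse(is_hub, p$hub_multiplier, 1),
                 ifelse(is_hub, p$hub_multiplier, 1))
  boost[mirror_pair] <- boost[mirror_pair] * p$homotopic_multiplier
  cross <- outer(hemisphere, hemisphere, "!=")
  boost[cross] <- boost[cross] * p$interhemispheric_weight
  mu <- p$base_count * exp(-d / p$decay_length) * boost
  exist_prob <- exp(-d / p$density_length)
  exist_prob[cross] <- exist_prob[cross] * p$interhemispheric_density
  exist_prob[mirror_pair] <- 1
  ut <- upper.tri(d)
  exist <- matrix(FALSE, n, n)
  exist[ut] <- stats::runif(sum(ut)) < exist_prob[ut]
  exist <- exist | t(exist)
  S <- matrix(0, n, n)
  draw <- which(exist)                       # both directions, independent
  S[draw] <- stats::rpois(length(draw), mu[draw])
  diag(S) <- 0
  dimnames(S) <- list(node_ids, node_ids)
  A <- build_adjacency(S, volume)
  conn <- connectome(A, node_ids, hemisphere, centroid, volume)

  # trajectories for every nonzero undirected edge
  pos <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  directed <- vector("list", 2L * nrow(pos))
  dnames <- character(2L * nrow(pos))
  consensus <- vector("list", nrow(pos))
  cnames <- character(nrow(pos))
  for (e in seq_len(nrow(pos))) {
    i <- pos[e, 1L]; j <- pos[e, 2L]
    pts <- if (hemisphere[i] == hemisphere[j]) {
      list(centroid[i, ], centroid[j, ])
    } else {
      zr <- if (stats::runif(1) < p$midline_fraction) p$callosal_z else p$detour_z
      # keep the bend inside the grid so midline voxels are never clipped
      zr <- pmin(pmax(zr, -0.95 * ext[3]), 0.95 * ext[3])
      bend <- c(0,
                max(-0.95 * ext[2], min(0.95 * ext[2],
                  mean(centroid[c(i, j), 2]) + stats::rnorm(1, 0, 4))),
                stats::runif(1, zr[1], zr[2]))
      list(centroid[i, ], bend, centroid[j, ])
    }
    vox <- voxelize_polyline(pts, grid, tube_radius = p$tube_radius)
    lam <- min(1000, max(5, S[i, j] + S[j, i]))
    fwd <- data.frame(vox, count = 1L + stats::rpois(nrow(vox), lam))
    rev <- data.frame(vox, count = 1L + stats::rpois(nrow(vox), lam))
    directed[[2L * e - 1L]] <- fwd
    directed[[2L * e]] <- rev
    dnames[2L * e - 1L] <- directed_key(node_ids[i], node_ids[j])
    dnames[2L * e] <- directed_key(node_ids[j], node_ids[i])
    consensus[[e]] <- consensus_edge_mask(fwd, rev)
    cnames[e] <- edge_key(node_ids[i], node_ids[j])
  }
  names(directed) <- dnames
  names(consensus) <- cnames
  traj <- edge_trajectories(grid, directed, consensus = consensus)
  list(connectome = conn, trajectories = traj, hubs = hubs)
}

#' Generate a test-retest cohort
#'
#' Builds one template anatomy (shared centroids, trajectories and grid —
#' the synthetic analog of spatially registered subjects), then derives each
#' subject by multiplying the template weights with subject-level log-normal
#' noise, and each scan by further scan-level log-normal noise. Noise is
#' applied to the upper triangle and mirrored, so scans remain symmetric
#' with the template's zero pattern.
#'
#' @param params A [generator_params()].
#' @param n_subjects Number of subjects (>= 1).
#' @param n_scans Scans per subject (default 2, the test-retest design).
#' @param seed Integer seed.
#' @return An object of class \code{cohort}: \code{template},
#'   \code{trajectories}, \code{hubs}, and \code{subjects} — a list whose
#'   elements hold \code{latent} (the subject's noiseless connectome) and
#'   \code{scans} (list of \code{connectome}).
#' @export
generate_cohort <- function(params = generator_params(), n_subjects,
                            n_scans = 2, seed = 1) {
  stopifnot(n_subjects >= 1, n_scans >= 1)
  seeds <- derive_seeds(seed, 1L + n_subjects)
  base <- generate_connectome(params, seed = seeds[1L])
  ut <- upper.tri(base$connectome$adjacency)
  perturb <- function(conn, sd, seed) {
    out <- conn
    noise <- with_seed(seed, exp(stats::rnorm(sum(ut), 0, sd)))
    A <- out$adjacency
    A[ut] <- A[ut] * noise
    A[lower.tri(A)] <- t(A)[lower.tri(A)]
    out$adjacency <- A
    out
  }
  subjects <- lapply(seq_len(n_subjects), function(s) {
    sub_seeds <- derive_seeds(seeds[1L + s], 1L + n_scans)
    latent <- perturb(base$connectome, params$subject_sd, sub_seeds[1L])
    scans <- lapply(seq_len(n_scans), function(k)
      perturb(latent, params$scan_sd, sub_seeds[1L + k]))
    list(latent = latent, scans = scans)
  })
  structure(list(template = base$connectome,
                 trajectories = base$trajectories,
                 hubs = base$hubs, subjects = subjects,
                 params = params, seed = seed),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects x %d scans, %d nodes\n",
              length(x$subjects), length(x$subjects[[1L]]$scans),
              n_nodes(x$template)))
  invisible(x)
}

# Flat list of all scan connectomes (subject-major order).
cohort_scans <- function(cohort) {
  unlist(lapply(cohort$subjects, `[[`, "scans"), recursive = FALSE)
}

#' Synthesize a callosal-agenesis variant
#'
#' Emulates congenital absence of the corpus callosum with compensatory
#' "replacement" tracts: all edges whose trajectories cross the callosal
#' midline region are removed, and a fraction \code{compensation} of their
#' total weight is re-added on detour edges whose trajectories cross the
#' midline inferiorly, outside the callosal region. Detour weight is
#' distributed over the strongest removed edges' node pairs, proportionally
#' to their original weights.
#'
#' @param x A \code{connectome}.
#' @param traj Matching \code{edge_trajectories}.
#' @param compensation Fraction in [0, 1] of removed callosal weight
#'   restored through detours; 0 reproduces the virtual callosotomy exactly.
#' @param plane_x Midline plane (mm).
#' @param z_range Callosal z range of the cut (world mm); must lie above the
#'   detour range.
#' @param detour_z World z range of detour crossings.
#' @param n_detour Number of detour edges (capped at the number of removed
#'   edges).
#' @param tube_radius Tube radius (mm) of the detour trajectories.
#' @param seed Seed for detour trajectory jitter.
#' @return List with \code{connectome} and \code{trajectories} (callosal
#'   edges removed, detour trajectories added).
#' @export
generate_agcc_variant <- function(x, traj, compensation = 0.25, plane_x = 0,
                                  z_range = c(0, Inf),
                                  detour_z = c(-45, -20), n_detour = 6,
                                  tube_radius = 3, seed = 1) {
  stopifnot(compensation >= 0)
  if (compensation > 1)
    stop("compensation exceeds the removed-weight conservation cap",
         call. = FALSE)
  if (detour_z[2L] >= z_range[1L])
    stop("detour_z must lie entirely below the callosal z_range", call. = FALSE)
  cut_conn <- virtual_callosotomy(x, traj, plane_x = plane_x,
                                  z_range = z_range)
  cut_keys <- attr(cut_conn, "cut_edges")
  out_traj <- traj
  if (length(cut_keys)) {
    ends <- split_edge_key(cut_keys)
    ii <- match(ends[, 1L], x$node_ids)
    jj <- match(ends[, 2L], x$node_ids)
    w_cut <- x$adjacency[cbind(ii, jj)]
    # drop removed edges' trajectories
    out_traj$consensus[cut_keys] <- NULL
    drop_dir <- c(directed_key(ends[, 1L], ends[, 2L]),
                  directed_key(ends[, 2L], ends[, 1L]))
    out_traj$directed[intersect(drop_dir, names(out_traj$directed))] <- NULL
    attr(out_traj, "voxel_table") <- NULL
    if (compensation > 0) {
      ord <- order(-w_cut)
      take <- ord[seq_len(min(n_detour, length(ord)))]
      w_add <- compensation * sum(w_cut) * w_cut[take] / sum(w_cut[take])
      jitter <- with_seed(seed, stats::rnorm(length(take), 0, 3))
      ext <- (traj$grid$shape - 1) * traj$grid$spacing / 2
      bend_z <- max(-0.95 * ext[3], min(0.95 * ext[3], mean(detour_z)))
      for (k in seq_along(take)) {
        e <- take[k]
        a <- ii[e]; b <- jj[e]
        bend <- c(plane_x,
                  max(-0.95 * ext[2], min(0.95 * ext[2],
                    mean(x$centroid[c(a, b), 2]) + jitter[k])),
                  bend_z)
        vox <- voxelize_polyline(list(x$centroid[a, ], bend,
                                      x$centroid[b, ]), traj$grid,
                                 tube_radius = tube_radius)
        w_vox <- voxel_to_world(vox, traj$grid)
        on_callosal <- abs(w_vox[, 1L] - plane_x) <= traj$grid$spacing[1L] / 2 &
          w_vox[, 3L] >= z_range[1L] & w_vox[, 3L] <= z_range[2L]
        if (any(on_callosal))
          stop("detour trajectory crosses the callosal region; widen detour_z",
               call. = FALSE)
        counts <- data.frame(vox, count = 10L)
        key_ab <- edge_key(x$node_ids[a], x$node_ids[b])
        out_traj$directed[[directed_key(x$node_ids[a], x$node_ids[b])]] <- counts
        out_traj$directed[[directed_key(x$node_ids[b], x$node_ids[a])]] <- counts
        out_traj$consensus[[key_ab]] <- vox
        cut_conn$adjacency[a, b] <- cut_conn$adjacency[a, b] + w_add[k]
        cut_conn$adjacency[b, a] <- cut_conn$adjacency[a, b]
      }
    }
  }
  attr(cut_conn, "cut_edges") <- cut_keys
  validate_connectome(cut_conn)
  list(connectome = cut_conn, trajectories = out_traj)
}

#' Toy tract atlas from trajectory geometry
#'
#' Partitions the union of consensus-mask voxels into spatial blocks
#' (octants around the white-matter median point), standing in for an
#' anatomical tract atlas at synthetic-data scale.
#'
#' @param traj An \code{edge_trajectories}.
#' @param n_tracts 8 (octants) or 4 (quadrants in x/z).
#' @return A [tract_atlas()].
#' @export
generate_tract_atlas <- function(traj, n_tracts = 8) {
  stopifnot(n_tracts %in% c(4L, 8L))
  wm <- white_matter_voxels(traj)
  w <- voxel_to_world(wm, traj$grid)
  med <- apply(w, 2L, stats::median)
  lab <- 1L + (w[, 1L] > med[1L]) + 2L * (w[, 3L] > med[3L])
  if (n_tracts == 8L) lab <- lab + 4L * (w[, 2L] > med[2L])
  tract_atlas(traj$grid, wm, lab)
}
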