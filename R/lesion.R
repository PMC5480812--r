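#' Define a focal spherical lesion
#'
#' A virtual spherical white-matter lesion. Edges whose consensus trajectory
#' mask intersects the sphere are weakened in proportion to the fraction of
#' their trajectory volume removed, modulated by a stoppage parameter:
#' \code{A'ij = Aij - stoppage * f * Aij} with \code{f} = (consensus voxels
#' inside the sphere) / (total consensus voxels of the edge). Stoppage 1
#' means the lesioned volume blocks streamlines completely.
#'
#' @param center Length-3 world coordinates of the lesion center (mm).
#' @param diameter Sphere diameter in mm (default 12).
#' @param stoppage Blocking fraction in (0, 1].
#' @return An object of class \code{lesion}.
#' @export
lesion <- function(center, diameter = 12, stoppage = 1) {
  stopifnot(length(center) == 3L, diameter > 0, stoppage > 0, stoppage <= 1)
  structure(list(center = as.numeric(center), diameter = diameter,
                 stoppage = stoppage), class = "lesion")
}

#' Voxelize a sphere on a grid
#'
#' Returns every voxel whose center lies within \code{diameter/2} of the
#' given center point (world mm). An empty set (with a warning) results when
#' the sphere misses the grid entirely.
#'
#' @param center Length-3 world coordinates (mm), or a [lesion()].
#' @param grid A [voxel_grid()].
#' @param diameter Sphere diameter in mm (taken from the lesion if one is
#'   given).
#' @return Integer matrix of 0-based voxel indices (columns vx, vy, vz).
#' @export
voxelize_sphere <- function(center, grid, diameter = 12) {
  if (inherits(center, "lesion")) {
    diameter <- center$diameter
    center <- center$center
  }
  stopifnot(inherits(grid, "voxel_grid"), diameter > 0)
  r <- diameter / 2
  lo <- pmax(0L, as.integer(ceiling((center - r - grid$origin) / grid$spacing)))
  hi <- pmin(grid$shape - 1L,
             as.integer(floor((center + r - grid$origin) / grid$spacing)))
  if (any(lo > hi)) {
    warning("sphere does not intersect the grid")
    return(as_voxel_matrix(matrix(integer(), ncol = 3L)))
  }
  vox <- as.matrix(expand.grid(vx = lo[1]:hi[1], vy = lo[2]:hi[2],
                               vz = lo[3]:hi[3]))
  ctr <- voxel_to_world(vox, grid)
  d2 <- (ctr[, 1] - center[1])^2 + (ctr[, 2] - center[2])^2 +
    (ctr[, 3] - center[3])^2
  out <- as_voxel_matrix(vox[d2 <= r^2, , drop = FALSE])
  if (nrow(out) == 0L) warning("sphere does not cover any voxel center")
  out
}

# Per-edge fraction of consensus voxels inside a set of voxel linear indices.
# Returns named numeric (edge key -> fraction), only edges touched.
edge_removed_fraction <- function(traj, sphere_lin) {
  evt <- edge_voxel_table(traj)
  if (length(sphere_lin) == 0L) return(numeric())
  hit <- evt$table[data.table::data.table(lin = sphere_lin), on = "lin",
                   nomatch = NULL]
  if (nrow(hit) == 0L) return(numeric())
  counts <- hit[, .N, by = "edge"]
  stats::setNames(counts$N / evt$sizes[counts$edge], counts$edge)
}

# Check that every positive edge has a nonempty consensus mask.
check_trajectory_coverage <- function(x, traj) {
  A <- x$adjacency
  pos <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  if (nrow(pos) == 0L) return(invisible(TRUE))
  keys <- edge_key(x$node_ids[pos[, 1L]], x$node_ids[pos[, 2L]])
  sizes <- vapply(traj$consensus[keys], function(m) if (is.null(m)) 0L else nrow(m),
                  integer(1))
  if (any(sizes == 0L))
    stop("edges with positive weight but empty consensus mask: ",
         paste(utils::head(keys[sizes == 0L], 5L), collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

#' Apply a spherical lesion to a connectome
#'
#' Weakens every edge whose consensus mask intersects the lesion sphere by
#' \code{stoppage * f} of its weight, where f is the removed fraction of the
#' edge's trajectory volume (voxel-count ratio). Untouched edges are
#' unchanged and symmetry is preserved.
#'
#' @param x A \code{connectome}.
#' @param traj Matching \code{edge_trajectories} (must cover all positive
#'   edges).
#' @param les A [lesion()].
#' @return The perturbed \code{connectome}; attribute \code{"edge_fractions"}
#'   holds the per-edge removed fractions.
#' @export
apply_lesion <- function(x, traj, les) {
  stopifnot(inherits(x, "connectome"), inherits(traj, "edge_trajectories"),
            inherits(les, "lesion"))
  check_trajectory_coverage(x, traj)
  sph <- suppressWarnings(voxelize_sphere(les$center, traj$grid, les$diameter))
  f <- edge_removed_fraction(traj, voxel_to_linear(sph, traj$grid))
  out <- x
  if (length(f)) {
    ends <- split_edge_key(names(f))
    ii <- match(ends[, 1L], x$node_ids)
    jj <- match(ends[, 2L], x$node_ids)
    ok <- !is.na(ii) & !is.na(jj)
    idx <- cbind(ii[ok], jj[ok])
    mult <- 1 - les$stoppage * f[ok]
    out$adjacency[idx] <- out$adjacency[idx] * mult
    out$adjacency[idx[, 2:1, drop = FALSE]] <- out$adjacency[idx]
  }
  attr(out, "edge_fractions") <- f
  out
}

#' Eigenvalue decrease caused by one lesion
#'
#' Applies the lesion, re-eigendecomposes the lesioned Laplacian, matches
#' the requested reference eigenmode by inner product (rank window of
#' \code{window}), and returns the decrease of the matched eigenvalue,
#' \code{lambda_ref - lambda_matched}. If the lesion disconnects the graph a
#' value is still returned and the \code{"disconnected"} attribute is set.
#'
#' @param x A \code{connectome}.
#' @param traj Matching \code{edge_trajectories}.
#' @param les A [lesion()].
#' @param mode Eigenmode index (ascending-eigenvalue rank) of interest.
#' @param reference Eigensystem of the unlesioned connectome; computed when
#'   omitted.
#' @param window Matching window (see [match_eigenmode()]).
#' @return Scalar importance, with attributes \code{matched_index} and
#'   \code{disconnected}. May be slightly negative in degenerate near-tie
#'   cases; values are reported unclipped.
#' @export
importance_at <- function(x, traj, les, mode, reference = NULL, window = 2) {
  if (is.null(reference)) reference <- eigendecompose(build_laplacian(x))
  lesioned <- apply_lesion(x, traj, les)
  es <- eigendecompose(build_laplacian(lesioned))
  m <- match_eigenmode(reference$vectors[, mode], es, mode, window)
  structure(reference$values[mode] - es$values[m$matched_index],
            matched_index = m$matched_index,
            disconnected = n_zero_modes(es) > n_zero_modes(reference))
}

# Core lesion scan shared by importance_map() and stoppage_sweep():
# evaluates the eigenvalue decrease at every lesion center for each
# (stoppage, mode) combination, re-using the sphere/edge geometry across
# stoppages and one eigendecomposition per (center, stoppage) across modes.
lesion_scan <- function(x, traj, modes, stoppages, diameter = 12, stride = 1,
                        window = 2, centers = NULL) {
  stopifnot(stride >= 1, all(stoppages > 0), all(stoppages <= 1))
  check_trajectory_coverage(x, traj)
  grid <- traj$grid
  if (is.null(centers)) {
    wm <- white_matter_voxels(traj)
    if (nrow(wm) == 0L) stop("no consensus voxels (empty map)", call. = FALSE)
    if (stride > 1L) {
      keep <- wm[, 1L] %% stride == 0L & wm[, 2L] %% stride == 0L &
        wm[, 3L] %% stride == 0L
      wm <- wm[keep, , drop = FALSE]
    }
    centers <- wm
  } else {
    centers <- as_voxel_matrix(centers)
  }
  ref <- eigendecompose(build_laplacian(x))
  A <- x$adjacency
  ctr_world <- voxel_to_world(centers, grid)
  nC <- nrow(centers); nS <- length(stoppages); nM <- length(modes)
  values <- array(0, dim = c(nC, nS, nM),
                  dimnames = list(NULL, paste0("s", stoppages),
                                  paste0("mode", modes)))
  matched <- array(rep(modes, each = nC * nS), dim = c(nC, nS, nM))
  disconnected <- matrix(FALSE, nC, nS)
  refvecs <- ref$vectors[, modes, drop = FALSE]
  # integer edge ids + endpoint indices, resolved once
  evt <- edge_voxel_table(traj)
  keys <- names(evt$sizes)
  ends <- split_edge_key(keys)
  end_i <- match(ends[, 1L], x$node_ids)
  end_j <- match(ends[, 2L], x$node_ids)
  lookup <- data.table::data.table(
    lin = evt$table$lin, eid = match(evt$table$edge, keys))
  data.table::setkey(lookup, lin)
  sizes <- unname(evt$sizes)
  # sphere voxel-offset stencil, shared by all centers
  r <- diameter / 2
  rad <- floor(r / grid$spacing)
  off <- as.matrix(expand.grid(-rad[1]:rad[1], -rad[2]:rad[2],
                               -rad[3]:rad[3]))
  off <- off[colSums((t(off) * grid$spacing)^2) <= r^2, , drop = FALSE]
  nzero <- n_zero_modes(ref)
  for (ci in seq_len(nC)) {
    sph <- sweep(off, 2L, centers[ci, ], "+")
    sph <- sph[in_grid(sph, grid), , drop = FALSE]
    if (nrow(sph) == 0L) next
    hit <- lookup[data.table::data.table(lin = voxel_to_linear(sph, grid)),
                  on = "lin", nomatch = NULL]
    if (nrow(hit) == 0L) next
    cnt <- tabulate(hit$eid, nbins = length(keys))
    touched <- which(cnt > 0L & !is.na(end_i) & !is.na(end_j))
    if (!length(touched)) next
    fr <- cnt[touched] / sizes[touched]
    idx <- rbind(cbind(end_i[touched], end_j[touched]),
                 cbind(end_j[touched], end_i[touched]))
    w0 <- A[idx]
    fr2 <- rep(fr, 2L)
    for (si in seq_len(nS)) {
      A2 <- A
      A2[idx] <- w0 * (1 - stoppages[si] * fr2)
      L2 <- -A2
      diag(L2) <- rowSums(A2)
      es <- eigendecompose(L2)
      disconnected[ci, si] <- n_zero_modes(es) > nzero
      for (mi in seq_len(nM)) {
        m <- match_eigenmode(refvecs[, mi], es, modes[mi], window)
        matched[ci, si, mi] <- m$matched_index
        values[ci, si, mi] <- ref$values[modes[mi]] - es$values[m$matched_index]
      }
    }
  }
  list(grid = grid, centers = centers, stoppages = stoppages, modes = modes,
       values = values, matched = matched, disconnected = disconnected,
       diameter = diameter, stride = stride, reference = ref)
}

#' Voxelwise eigenmode importance map
#'
#' Places a spherical lesion at every white-matter voxel (any voxel covered
#' by a consensus mask, optionally strided) and records the decrease of the
#' matched eigenvalue. Voxels outside the white matter have importance 0 by
#' definition.
#'
#' @inheritParams lesion_scan
#' @param x A \code{connectome}.
#' @param traj Matching \code{edge_trajectories}.
#' @param mode Eigenmode index (one per map; see [stoppage_sweep()] to batch
#'   modes and stoppages).
#' @param stoppage Blocking fraction in (0, 1].
#' @param diameter Lesion diameter in mm.
#' @param stride Evaluate only voxels whose indices are multiples of
#'   \code{stride} (1 = every white-matter voxel).
#' @param window Eigenmode matching window.
#' @return An object of class \code{importance_map}: grid, evaluated voxels,
#'   values, and the lesion parameters used.
#' @export
importance_map <- function(x, traj, mode, stoppage = 1, diameter = 12,
                           stride = 1, window = 2) {
  scan <- lesion_scan(x, traj, modes = mode, stoppages = stoppage,
                      diameter = diameter, stride = stride, window = window)
  new_importance_map(scan, 1L, 1L)
}

new_importance_map <- function(scan, si, mi) {
  structure(list(grid = scan$grid, voxels = scan$centers,
                 values = scan$values[, si, mi],
                 mode = scan$modes[mi], stoppage = scan$stoppages[si],
                 diameter = scan$diameter, stride = scan$stride,
                 disconnected = scan$disconnected[, si]),
            class = "importance_map")
}

#' @export
print.importance_map <- function(x, ...) {
  cat(sprintf(
    "<importance_map> mode %d, stoppage %.2f, %d voxels, max %.4g\n",
    x$mode, x$stoppage, nrow(x$voxels),
    if (length(x$values)) max(x$values) else NA_real_))
  invisible(x)
}

#' Stoppage-parameter robustness of importance maps
#'
#' Computes importance maps for each requested eigenmode at each stoppage
#' value and correlates, per mode, every pair of stoppage settings across
#' the evaluated white-matter voxels (Pearson).
#'
#' @inheritParams importance_map
#' @param modes Eigenmode indices (default 2:4).
#' @param stoppages Stoppage values (default 0.25, 0.5, 0.75, 1).
#' @return List with \code{correlations} (data.frame mode, stoppage_a,
#'   stoppage_b, r) and \code{maps} (list of \code{importance_map}, named
#'   \code{"mode<m>_s<stoppage>"}).
#' @export
stoppage_sweep <- function(x, traj, modes = 2:4,
                           stoppages = c(0.25, 0.5, 0.75, 1),
                           diameter = 12, stride = 1, window = 2) {
  if (length(stoppages) < 2L)
    stop("need at least two stoppage values", call. = FALSE)
  scan <- lesion_scan(x, traj, modes = modes, stoppages = stoppages,
                      diameter = diameter, stride = stride, window = window)
  maps <- list()
  rows <- list()
  for (mi in seq_along(modes)) {
    for (si in seq_along(stoppages)) {
      maps[[sprintf("mode%d_s%g", modes[mi], stoppages[si])]] <-
        new_importance_map(scan, si, mi)
    }
    for (a in seq_along(stoppages)) {
      for (b in seq_along(stoppages)) {
        if (a >= b) next
        va <- scan$values[, a, mi]; vb <- scan$values[, b, mi]
        if (stats::sd(va) == 0 || stats::sd(vb) == 0)
          stop("importance map is constant; correlation undefined", call. = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          mode = modes[mi], stoppage_a = stoppages[a],
          stoppage_b = stoppages[b], r = stats::cor(va, vb))
      }
    }
  }
  list(correlations = do.call(rbind, rows), maps = maps)
}

#' Export an importance (or density) map
#'
#' Writes a sparse TSV (vx, vy, vz, value) and, optionally, a dense NIfTI
#' volume whose affine encodes the grid (voxel-center convention).
#'
#' @param map An \code{importance_map} or \code{density_map}.
#' @param prefix Path prefix.
#' @param nifti Also write \code{<prefix>.nii.gz}.
#' @return Paths written, invisibly.
#' @export
write_map <- function(map, prefix, nifti = FALSE) {
  tsv <- paste0(prefix, ".tsv")
  utils::write.table(
    data.frame(map$voxels, value = map$values), tsv, sep = "\t",
    quote = FALSE, row.names = FALSE)
  paths <- c(tsv = tsv)
  if (nifti) {
    nii <- paste0(prefix, ".nii.gz")
    RNifti::writeNifti(as_nifti_volume(map), nii)
    paths <- c(paths, nifti = nii)
  }
  invisible(paths)
}

#' Dense volume from a sparse map
#'
#' @param map An object with fields grid, voxels, values.
#' @return For \code{as_volume()}, a dense array of the grid shape (zero
#'   outside the map's support); \code{as_nifti_volume()} wraps it as an
#'   RNifti image with the grid affine.
#' @export
as_volume <- function(map) {
  arr <- array(0, dim = map$grid$shape)
  arr[voxel_to_linear(map$voxels, map$grid)] <- map$values
  arr
}

#' @rdname as_volume
#' @export
as_nifti_volume <- function(map) {
  arr <- as_volume(map)
  affine <- rbind(cbind(diag(map$grid$spacing), map$grid$origin), c(0, 0, 0, 1))
  img <- RNifti::asNifti(arr)
  RNifti::`qform<-`(img, structure(affine, code = 2L))
}
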