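#' Identify rich-club nodes
#'
#' Returns the set of high-degree nodes used for rich-club edge
#' classification: either an explicit node list (preferred when hubs are
#' known, e.g. planted by the synthetic generator), a degree threshold
#' \code{k} (nodes with degree > k), or the top \code{top_frac} of nodes by
#' degree. Degree is binary (edge count) by default, or weighted strength.
#'
#' @param x A \code{connectome}.
#' @param k Degree threshold; nodes with degree strictly above it are rich.
#' @param top_frac Fraction of nodes (by descending degree) to take when
#'   \code{k} is missing (default 0.15).
#' @param weighted Use weighted strength instead of binary degree.
#' @param nodes Explicit character vector of rich node ids; returned
#'   verbatim (after membership check).
#' @return Character vector of rich node ids; empty with a warning when no
#'   node qualifies (all edges then classify as local).
#' @export
rich_club_nodes <- function(x, k = NULL, top_frac = 0.15, weighted = FALSE,
                            nodes = NULL) {
  stopifnot(inherits(x, "connectome"))
  if (!is.null(nodes)) {
    bad <- setdiff(nodes, x$node_ids)
    if (length(bad)) stop("unknown node ids: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    return(as.character(nodes))
  }
  deg <- if (weighted) node_strength(x) else rowSums(x$adjacency > 0)
  rich <- if (!is.null(k)) {
    stopifnot(k >= 0)
    x$node_ids[deg > k]
  } else {
    n_rich <- max(1L, floor(top_frac * n_nodes(x)))
    x$node_ids[order(-deg)][seq_len(n_rich)]
  }
  if (!length(rich)) warning("no rich-club nodes found; all edges are local")
  rich
}

#' Classify edges by rich-club membership
#'
#' Splits the nonzero edges into rich-club (RC: both endpoints rich),
#' feeder (FC: exactly one rich endpoint) and local (LC: neither).
#'
#' @param x A \code{connectome}.
#' @param rich Character vector of rich node ids (subset of the nodes).
#' @return data.frame (i, j, weight, category) with one row per unordered
#'   nonzero edge; category is a factor with levels RC, FC, LC.
#' @export
classify_edges <- function(x, rich) {
  stopifnot(inherits(x, "connectome"), all(rich %in% x$node_ids))
  pos <- which(upper.tri(x$adjacency) & x$adjacency > 0, arr.ind = TRUE)
  i <- x$node_ids[pos[, 1L]]
  j <- x$node_ids[pos[, 2L]]
  n_rich <- (i %in% rich) + (j %in% rich)
  data.frame(i = i, j = j, weight = x$adjacency[pos],
             category = factor(c("LC", "FC", "RC")[n_rich + 1L],
                               levels = c("RC", "FC", "LC")),
             stringsAsFactors = FALSE)
}

#' Voxelwise edge-density map
#'
#' Counts, for every voxel, how many edges of a chosen subset have a
#' consensus trajectory mask covering that voxel.
#'
#' @param traj An \code{edge_trajectories}.
#' @param edges Edge subset: a data.frame with columns i, j (e.g. rows of
#'   [classify_edges()] output), a character vector of \code{"i|j"} keys, or
#'   \code{NULL} for all edges.
#' @return An object of class \code{density_map} (grid, voxels, values);
#'   voxels not covered by any selected edge are omitted (value 0). An empty
#'   subset yields an all-zero (empty-support) map.
#' @export
edge_density_map <- function(traj, edges = NULL) {
  stopifnot(inherits(traj, "edge_trajectories"))
  keys <- if (is.null(edges)) names(traj$consensus)
  else if (is.data.frame(edges)) edge_key(edges$i, edges$j)
  else as.character(edges)
  keys <- intersect(keys, names(traj$consensus))
  evt <- edge_voxel_table(traj)$table
  sub <- evt[evt$edge %in% keys, ]
  if (nrow(sub) == 0L) {
    return(structure(list(grid = traj$grid,
                          voxels = as_voxel_matrix(matrix(integer(), ncol = 3)),
                          values = numeric(), edges = keys),
                     class = "density_map"))
  }
  counts <- table(sub$lin)
  lin <- as.integer(names(counts))
  structure(list(grid = traj$grid, voxels = linear_to_voxel(lin, traj$grid),
                 values = as.numeric(counts), edges = keys),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %d edges, %d covered voxels, max count %d\n",
              length(x$edges), nrow(x$voxels),
              if (length(x$values)) as.integer(max(x$values)) else 0L))
  invisible(x)
}

#' Correlate two voxel maps over a mask
#'
#' Pearson correlation between two maps (importance or density) evaluated
#' over a common voxel mask, with a 95% confidence interval from the Fisher
#' z transform (n = number of mask voxels). Map values are taken as 0 on
#' mask voxels outside a map's support.
#'
#' @param map_a,map_b Objects with fields grid, voxels, values (on the same
#'   grid).
#' @param mask Voxel matrix (vx, vy, vz) defining the comparison domain,
#'   e.g. the white-matter voxel set; defaults to the union of the two
#'   supports.
#' @return List with \code{r}, \code{lower}, \code{upper}, \code{n}.
#' @export
correlate_maps <- function(map_a, map_b, mask = NULL) {
  if (!grids_equal(map_a$grid, map_b$grid))
    stop("maps must share a grid", call. = FALSE)
  grid <- map_a$grid
  lin_a <- voxel_to_linear(map_a$voxels, grid)
  lin_b <- voxel_to_linear(map_b$voxels, grid)
  lin_m <- if (is.null(mask)) sort(unique(c(lin_a, lin_b)))
  else voxel_to_linear(as_voxel_matrix(mask), grid)
  if (!length(lin_m)) stop("mask is empty", call. = FALSE)
  va <- map_a$values[match(lin_m, lin_a)]; va[is.na(va)] <- 0
  vb <- map_b$values[match(lin_m, lin_b)]; vb[is.na(vb)] <- 0
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("a map is constant on the mask; correlation undefined", call. = FALSE)
  r <- stats::cor(va, vb)
  n <- length(lin_m)
  if (n > 3L && abs(r) < 1) {
    z <- atanh(r)
    half <- stats::qnorm(0.975) / sqrt(n - 3)
    ci <- tanh(c(z - half, z + half))
  } else ci <- c(NA_real_, NA_real_)
  list(r = r, lower = ci[1L], upper = ci[2L], n = n)
}

#' Cross-map correlation matrix
#'
#' Pairwise Pearson correlations between several maps over one mask; used
#' for the eigenmode-importance versus edge-density comparison and the
#' importance-map cross-correlation heatmap.
#'
#' @param maps Named list of map objects on a shared grid.
#' @param mask Voxel mask (see [correlate_maps()]).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
map_correlation_matrix <- function(maps, mask = NULL) {
  k <- length(maps)
  nm <- names(maps) %||% paste0("map_", seq_len(k))
  out <- diag(1, k)
  dimnames(out) <- list(nm, nm)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (a < b)
      out[a, b] <- out[b, a] <- correlate_maps(maps[[a]], maps[[b]], mask)$r
  }
  out
}
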