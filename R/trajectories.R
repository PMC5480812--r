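#' Edge trajectory sets
#'
#' Stores the geographic embedding of connectome edges on a regular voxel
#' grid: for each ordered node pair, the voxels its streamlines traverse with
#' per-voxel streamline counts; and for each undirected edge, the consensus
#' voxel mask (union of the top-ranked voxels of the two directions, see
#' [consensus_edge_mask()]).
#'
#' @param grid A [voxel_grid()].
#' @param directed Named list; element \code{"i->j"} is a data.frame with
#'   columns vx, vy, vz (0-based voxel indices) and count (> 0).
#' @param consensus Named list; element \code{"i|j"} (ids sorted) is an
#'   integer matrix of consensus voxels (columns vx, vy, vz). If \code{NULL},
#'   masks are computed from \code{directed} with \code{retain_fraction}.
#' @param retain_fraction Per-direction fraction of non-zero voxels retained
#'   when deriving consensus masks (default 0.95).
#' @return An object of class \code{edge_trajectories}.
#' @export
edge_trajectories <- function(grid, directed, consensus = NULL,
                              retain_fraction = 0.95) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.null(consensus)) {
    pairs <- unique(lapply(strsplit(names(directed), "->", fixed = TRUE),
                           function(p) sort(p)))
    consensus <- list()
    for (p in pairs) {
      key <- edge_key(p[1L], p[2L])
      consensus[[key]] <- consensus_edge_mask(
        directed[[directed_key(p[1L], p[2L])]],
        directed[[directed_key(p[2L], p[1L])]],
        retain_fraction = retain_fraction)
    }
  }
  structure(list(grid = grid, directed = directed, consensus = consensus),
            class = "edge_trajectories")
}

directed_key <- function(i, j) paste0(i, "->", j)

edge_key <- function(i, j) {
  p <- cbind(as.character(i), as.character(j))
  swap <- p[, 1L] > p[, 2L]
  p[swap, ] <- p[swap, 2:1]
  paste0(p[, 1L], "|", p[, 2L])
}

split_edge_key <- function(key) {
  do.call(rbind, strsplit(key, "|", fixed = TRUE))
}

#' @export
print.edge_trajectories <- function(x, ...) {
  nv <- sum(vapply(x$consensus, nrow, integer(1)))
  cat(sprintf("<edge_trajectories> %d edges, %d consensus voxels total\n",
              length(x$consensus), nv))
  print(x$grid)
  invisible(x)
}

#' Consensus voxel mask of an edge
#'
#' For each tractography direction of an edge, keeps the top
#' \code{retain_fraction} of its non-zero voxels ranked by streamline count
#' (\code{ceiling(fraction * n)} voxels; the weakest are dropped), then
#' returns the union of the two retained sets. With
#' \code{retain_fraction = 1} this is simply the union of all non-zero
#' voxels.
#'
#' @param fwd,rev Data frames (vx, vy, vz, count) of non-zero voxels for the
#'   two directions; either may be \code{NULL} or empty.
#' @param retain_fraction Fraction in (0, 1] of non-zero voxels to retain per
#'   direction.
#' @return Integer matrix of unique voxels (columns vx, vy, vz). Empty (0-row)
#'   with a warning when both directions are empty.
#' @export
consensus_edge_mask <- function(fwd, rev, retain_fraction = 0.95) {
  stopifnot(retain_fraction > 0, retain_fraction <= 1)
  top <- function(d) {
    if (is.null(d) || nrow(d) == 0L) return(NULL)
    d <- d[d$count > 0, , drop = FALSE]
    if (nrow(d) == 0L) return(NULL)
    k <- ceiling(retain_fraction * nrow(d))
    ord <- order(-d$count)       # stable: ties keep input order
    as_voxel_matrix(d[ord[seq_len(k)], c("vx", "vy", "vz")])
  }
  parts <- list(top(fwd), top(rev))
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts)) {
    warning("both directions empty; consensus mask is empty")
    return(as_voxel_matrix(matrix(integer(), ncol = 3L)))
  }
  all <- do.call(rbind, parts)
  as_voxel_matrix(all[!duplicated(all), , drop = FALSE])
}

# Long-format lookup table of consensus voxels, cached on the object:
# data.table(lin, edge) keyed on lin, plus per-edge total voxel counts.
# Used by lesion and density computations.
edge_voxel_table <- function(traj) {
  cached <- attr(traj, "voxel_table")
  if (!is.null(cached)) return(cached)
  keys <- names(traj$consensus)
  sizes <- vapply(traj$consensus, nrow, integer(1))
  keep <- sizes > 0L
  dt <- data.table::data.table(
    lin = unlist(lapply(traj$consensus[keep], voxel_to_linear,
                        grid = traj$grid), use.names = FALSE),
    edge = rep(keys[keep], sizes[keep]))
  data.table::setkey(dt, lin)
  structure(list(table = dt, sizes = sizes), class = "edge_voxel_table")
}

# All voxels covered by at least one consensus mask ("white matter" voxels).
white_matter_voxels <- function(traj) {
  lin <- unique(edge_voxel_table(traj)$table$lin)
  linear_to_voxel(sort(lin), traj$grid)
}

#' Write / read edge trajectories as plain-text tables
#'
#' Writes \code{<prefix>_trajectories.tsv} (i, j, vx, vy, vz, count; one row
#' per directed-edge voxel), \code{<prefix>_consensus.tsv} (i, j, vx, vy, vz)
#' and a JSON grid sidecar \code{<prefix>_grid.json}.
#'
#' @param traj An \code{edge_trajectories} object.
#' @param prefix Path prefix.
#' @return Paths written, invisibly; \code{read_trajectories()} returns an
#'   \code{edge_trajectories}.
#' @export
write_trajectories <- function(traj, prefix) {
  stopifnot(inherits(traj, "edge_trajectories"))
  dpath <- paste0(prefix, "_trajectories.tsv")
  cpath <- paste0(prefix, "_consensus.tsv")
  gpath <- paste0(prefix, "_grid.json")
  dkeys <- names(traj$directed)
  dn <- vapply(traj$directed, nrow, integer(1))
  ends <- do.call(rbind, strsplit(dkeys, "->", fixed = TRUE))
  dtab <- data.frame(i = rep(ends[, 1L], dn), j = rep(ends[, 2L], dn),
                     do.call(rbind, lapply(traj$directed,
                                           `[`, c("vx", "vy", "vz", "count"))),
                     row.names = NULL)
  utils::write.table(dtab, dpath, sep = "\t", quote = FALSE, row.names = FALSE)
  ckeys <- names(traj$consensus)
  cn <- vapply(traj$consensus, nrow, integer(1))
  cends <- split_edge_key(ckeys)
  ctab <- data.frame(i = rep(cends[, 1L], cn), j = rep(cends[, 2L], cn),
                     do.call(rbind, traj$consensus), row.names = NULL)
  utils::write.table(ctab, cpath, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(origin = traj$grid$origin,
                            spacing = traj$grid$spacing,
                            shape = traj$grid$shape),
                       gpath, digits = NA)
  invisible(c(trajectories = dpath, consensus = cpath, grid = gpath))
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(prefix) {
  g <- jsonlite::read_json(paste0(prefix, "_grid.json"), simplifyVector = TRUE)
  grid <- voxel_grid(g$origin, g$spacing, g$shape)
  dtab <- utils::read.delim(paste0(prefix, "_trajectories.tsv"),
                            colClasses = c("character", "character",
                                           "integer", "integer", "integer",
                                           "numeric"))
  directed <- split(dtab[, c("vx", "vy", "vz", "count")],
                    directed_key(dtab$i, dtab$j))
  directed <- lapply(directed, function(d) { rownames(d) <- NULL; d })
  ctab <- utils::read.delim(paste0(prefix, "_consensus.tsv"),
                            colClasses = c("character", "character",
                                           "integer", "integer", "integer"))
  consensus <- lapply(split(ctab[, c("vx", "vy", "vz")],
                            edge_key(ctab$i, ctab$j)), as_voxel_matrix)
  edge_trajectories(grid, directed, consensus = consensus)
}
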