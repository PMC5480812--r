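#' Construct a structural connectome
#'
#' A connectome is an undirected, weighted graph over gray-matter regions:
#' a symmetric non-negative adjacency matrix plus per-node metadata
#' (hemisphere, centroid in mm, region volume in voxels). Edge weights are
#' unitless streamline densities (streamline counts normalized by the summed
#' volumes of the two endpoint regions; see [build_adjacency()]).
#'
#' @param adjacency N x N numeric matrix; symmetric, entrywise >= 0, zero
#'   diagonal.
#' @param node_ids Character vector of N unique region labels.
#' @param hemisphere Character vector of N values in \code{"left"}/\code{"right"}.
#' @param centroid N x 3 numeric matrix of region centroids (mm).
#' @param volume Numeric vector of N region volumes (voxel counts, > 0).
#' @return An object of class \code{connectome}.
#' @seealso [build_adjacency()], [prune_nodes()], [build_laplacian()]
#' @export
connectome <- function(adjacency, node_ids, hemisphere, centroid, volume) {
  adjacency <- as.matrix(adjacency)
  node_ids <- as.character(node_ids)
  centroid <- matrix(as.numeric(centroid), ncol = 3L,
                     dimnames = list(NULL, c("x", "y", "z")))
  obj <- structure(
    list(node_ids = node_ids,
         hemisphere = as.character(hemisphere),
         centroid = centroid,
         volume = as.numeric(volume),
         adjacency = adjacency),
    class = "connectome")
  dimnames(obj$adjacency) <- list(node_ids, node_ids)
  validate_connectome(obj)
  obj
}

#' Validate connectome invariants
#'
#' Checks symmetry, non-negativity, zero diagonal and metadata lengths.
#' Called by all constructors; exported so that objects modified by hand can
#' be re-checked.
#'
#' @param x A \code{connectome}.
#' @param tol Relative tolerance for the symmetry check.
#' @return \code{x}, invisibly; errors describe the violated invariant.
#' @export
validate_connectome <- function(x, tol = 1e-9) {
  A <- x$adjacency
  n <- nrow(A)
  if (ncol(A) != n) stop("adjacency must be square", call. = FALSE)
  if (!is_symmetric_matrix(A, tol)) stop("adjacency must be symmetric", call. = FALSE)
  if (any(A < 0)) stop("adjacency must be entrywise >= 0", call. = FALSE)
  if (any(abs(diag(A)) > 0)) stop("adjacency must have zero diagonal", call. = FALSE)
  for (f in c("node_ids", "hemisphere", "volume")) {
    if (length(x[[f]]) != n)
      stop(sprintf("%s must have length %d", f, n), call. = FALSE)
  }
  if (nrow(x$centroid) != n) stop("centroid must have one row per node", call. = FALSE)
  if (anyDuplicated(x$node_ids)) stop("node_ids must be unique", call. = FALSE)
  if (!all(x$hemisphere %in% c("left", "right")))
    stop("hemisphere must be 'left' or 'right'", call. = FALSE)
  if (any(x$volume <= 0)) stop("volumes must be > 0", call. = FALSE)
  invisible(x)
}

#' @export
print.connectome <- function(x, ...) {
  n <- length(x$node_ids)
  nz <- sum(x$adjacency[upper.tri(x$adjacency)] > 0)
  cat(sprintf("<connectome> %d nodes (%d left / %d right), %d edges, density %.2f\n",
              n, sum(x$hemisphere == "left"), sum(x$hemisphere == "right"),
              nz, nz / (n * (n - 1) / 2)))
  invisible(x)
}

n_nodes <- function(x) length(x$node_ids)

# Weighted degree (strength) per node.
node_strength <- function(x) rowSums(x$adjacency)

#' Build a volume-normalized adjacency matrix
#'
#' Converts a directed streamline-count matrix into undirected streamline
#' densities: each direction is normalized by the summed source and target
#' region volumes and the two directions are averaged, giving
#' \code{Aij = (Sij + Sji) / (2 * (Vi + Vj))}. The normalization prevents
#' large regions from appearing strongly connected merely because they seed
#' or receive many streamlines.
#'
#' @param streamlines N x N non-negative matrix of directed streamline counts
#'   \code{S[i, j]} = streamlines seeded in region i reaching region j. The
#'   diagonal is ignored.
#' @param volumes Numeric vector of N region volumes (voxel counts, > 0).
#' @return Symmetric N x N adjacency matrix with zero diagonal.
#' @export
build_adjacency <- function(streamlines, volumes) {
  S <- as.matrix(streamlines)
  n <- nrow(S)
  if (ncol(S) != n) stop("streamlines must be square", call. = FALSE)
  if (any(S < 0)) stop("streamline counts must be >= 0", call. = FALSE)
  volumes <- as.numeric(volumes)
  if (length(volumes) != n) stop("need one volume per node", call. = FALSE)
  if (any(volumes <= 0)) stop("volumes must be > 0", call. = FALSE)
  vsum <- outer(volumes, volumes, "+")
  A <- (S + t(S)) / (2 * vsum)
  diag(A) <- 0
  dimnames(A) <- dimnames(S)
  A
}

#' Remove excluded and disconnected nodes
#'
#' Drops an explicit list of regions (e.g. poles with spuriously weak
#' tractography) and then, iteratively, every node whose weighted degree is
#' at or below \code{min_degree} (default 0: only fully disconnected nodes).
#' Iteration runs to a fixed point so the result never contains a node that
#' the rule would remove, making the operation idempotent.
#'
#' @param x A \code{connectome}.
#' @param exclude Character vector of node ids to remove unconditionally.
#' @param min_degree Weighted-degree threshold; nodes with strength
#'   \code{<= min_degree} are removed (when \code{min_degree} is 0, only
#'   zero-strength nodes go).
#' @return The pruned \code{connectome}; attribute \code{"removal_log"} is a
#'   data.frame (node_id, reason) recording every removal.
#' @export
prune_nodes <- function(x, exclude = character(), min_degree = 0) {
  stopifnot(inherits(x, "connectome"), min_degree >= 0)
  missing_ids <- setdiff(exclude, x$node_ids)
  if (length(missing_ids))
    stop("unknown node ids in exclude: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  log <- data.frame(node_id = character(), reason = character(),
                    stringsAsFactors = FALSE)
  keep <- !(x$node_ids %in% exclude)
  if (any(!keep))
    log <- rbind(log, data.frame(node_id = x$node_ids[!keep],
                                 reason = "excluded"))
  out <- subset_connectome(x, keep)
  repeat {
    weak <- if (min_degree > 0) node_strength(out) <= min_degree
            else node_strength(out) == 0
    if (!any(weak)) break
    log <- rbind(log, data.frame(node_id = out$node_ids[weak],
                                 reason = "below_degree_threshold"))
    out <- subset_connectome(out, !weak)
  }
  if (n_nodes(out) < 2L)
    stop("pruning left fewer than 2 nodes (degenerate graph)", call. = FALSE)
  attr(out, "removal_log") <- log
  out
}

subset_connectome <- function(x, keep) {
  structure(
    list(node_ids = x$node_ids[keep],
         hemisphere = x$hemisphere[keep],
         centroid = x$centroid[keep, , drop = FALSE],
         volume = x$volume[keep],
         adjacency = x$adjacency[keep, keep, drop = FALSE]),
    class = "connectome")
}

#' Entrywise mean of connectomes over an identical node set
#'
#' Used to form the mean connectome whose eigenmodes serve as the matching
#' reference for a cohort. Node metadata is taken from the first input.
#'
#' @param connectomes List of \code{connectome} objects sharing node ids in
#'   the same order.
#' @return A \code{connectome} with the entrywise-mean adjacency.
#' @export
average_connectomes <- function(connectomes) {
  stopifnot(length(connectomes) >= 1L)
  ref <- connectomes[[1L]]
  for (cn in connectomes[-1L]) {
    if (!identical(cn$node_ids, ref$node_ids))
      stop("all connectomes must share the same node set and order", call. = FALSE)
  }
  A <- Reduce(`+`, lapply(connectomes, `[[`, "adjacency")) / length(connectomes)
  out <- ref
  out$adjacency <- A
  validate_connectome(out)
  out
}

#' Write / read a connectome as TSV tables
#'
#' \code{write_connectome()} writes two plain-text files under \code{prefix}:
#' \code{<prefix>_adjacency.tsv} (square matrix, header = node ids) and
#' \code{<prefix>_nodes.tsv} (node_id, hemisphere, x_mm, y_mm, z_mm,
#' volume_voxels). \code{read_connectome()} reads them back.
#'
#' @param x A \code{connectome}.
#' @param prefix Path prefix for the two files.
#' @return \code{write_connectome()}: the two paths, invisibly;
#'   \code{read_connectome()}: a \code{connectome}.
#' @export
write_connectome <- function(x, prefix) {
  stopifnot(inherits(x, "connectome"))
  adj_path <- paste0(prefix, "_adjacency.tsv")
  node_path <- paste0(prefix, "_nodes.tsv")
  adj <- as.data.frame(x$adjacency)
  names(adj) <- x$node_ids
  utils::write.table(adj, adj_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- data.frame(node_id = x$node_ids, hemisphere = x$hemisphere,
                     x_mm = x$centroid[, 1], y_mm = x$centroid[, 2],
                     z_mm = x$centroid[, 3], volume_voxels = x$volume)
  utils::write.table(meta, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(adjacency = adj_path, nodes = node_path))
}

#' @rdname write_connectome
#' @export
read_connectome <- function(prefix) {
  adj <- utils::read.delim(paste0(prefix, "_adjacency.tsv"),
                           check.names = FALSE)
  meta <- utils::read.delim(paste0(prefix, "_nodes.tsv"))
  connectome(as.matrix(adj), node_ids = meta$node_id,
             hemisphere = meta$hemisphere,
             centroid = cbind(meta$x_mm, meta$y_mm, meta$z_mm),
             volume = meta$volume_voxels)
}
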