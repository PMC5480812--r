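#' Graph Laplacian of a connectome
#'
#' Builds the (unnormalized) graph Laplacian \code{L = D - A}, with
#' \code{D = diag(rowSums(A))}. For a symmetric adjacency L is symmetric
#' positive semidefinite with zero row sums; its eigenmodes govern linear
#' diffusion on the graph, \code{dx/dt = -beta * L x}.
#'
#' @param x A \code{connectome} or a symmetric adjacency matrix.
#' @param tol Relative symmetry tolerance.
#' @return N x N Laplacian matrix (dimnames = node ids when available).
#' @export
build_laplacian <- function(x, tol = 1e-9) {
  A <- if (inherits(x, "connectome")) x$adjacency else as.matrix(x)
  if (!is_symmetric_matrix(A, tol))
    stop("adjacency must be symmetric", call. = FALSE)
  L <- -A
  diag(L) <- rowSums(A) - diag(A)
  L
}

#' Eigendecomposition of a symmetric Laplacian
#'
#' Returns eigenvalues in ascending order (slow modes first) with orthonormal
#' eigenvectors. For a connected graph exactly one eigenvalue is zero (the
#' constant steady-state mode); each additional connected component adds
#' another zero eigenvalue. Each eigenvector's sign is fixed so that its
#' largest-magnitude entry is positive, making the decomposition
#' reproducible; degenerate eigenvalues are returned with an (arbitrary but
#' deterministic) orthonormal basis of their subspace.
#'
#' @param L Symmetric matrix (typically from [build_laplacian()]).
#' @param tol Relative symmetry tolerance.
#' @return An object of class \code{eigensystem}: list with \code{values}
#'   (ascending) and \code{vectors} (columns are unit-norm eigenmodes).
#' @export
eigendecompose <- function(L, tol = 1e-9) {
  L <- as.matrix(L)
  if (!is_symmetric_matrix(L, tol))
    stop("L must be symmetric", call. = FALSE)
  e <- eigen((L + t(L)) / 2, symmetric = TRUE)
  idx <- rev(seq_along(e$values))  # ascending
  values <- e$values[idx]
  vectors <- e$vectors[, idx, drop = FALSE]
  for (k in seq_len(ncol(vectors))) {
    i <- which.max(abs(vectors[, k]))
    if (vectors[i, k] < 0) vectors[, k] <- -vectors[, k]
  }
  rownames(vectors) <- rownames(L)
  structure(list(values = values, vectors = vectors), class = "eigensystem")
}

#' @export
print.eigensystem <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("<eigensystem> %d modes; lambda_1..4 = %s\n", n,
              paste(signif(x$values[seq_len(min(4, n))], 4), collapse = ", ")))
  invisible(x)
}

# Number of eigenvalues indistinguishable from zero (connected components).
n_zero_modes <- function(es, rel_tol = 1e-9) {
  scale <- max(abs(es$values), 1e-300)
  sum(abs(es$values) <= rel_tol * scale)
}

#' Match an eigenmode across decompositions
#'
#' Eigenvector order can switch between subjects (or after a perturbation)
#' when neighboring eigenvalues are close. Given a reference mode, finds the
#' candidate mode with the largest absolute inner product within a rank
#' window around the reference's position, and the sign making the inner
#' product non-negative. In practice matched modes sit within two rank steps
#' of each other, hence the default window.
#'
#' @param reference Unit-norm reference eigenvector.
#' @param candidates An \code{eigensystem} to search.
#' @param ref_index Rank of the reference mode (1-based, ascending
#'   eigenvalues); the window is centered here.
#' @param window Search half-width in rank steps (\code{Inf} searches all
#'   modes).
#' @return List with \code{matched_index}, \code{sign} (+1/-1),
#'   \code{inner_product} (absolute, in [0, 1]) and \code{step_offset}.
#' @export
match_eigenmode <- function(reference, candidates, ref_index, window = 2) {
  stopifnot(inherits(candidates, "eigensystem"), window >= 0)
  n <- length(candidates$values)
  if (length(reference) != nrow(candidates$vectors))
    stop("reference dimension does not match candidates", call. = FALSE)
  lo <- if (is.finite(window)) max(1L, ref_index - window) else 1L
  hi <- if (is.finite(window)) min(n, ref_index + window) else n
  idx <- lo:hi
  ips <- abs(as.numeric(crossprod(candidates$vectors[, idx, drop = FALSE],
                                  reference)))
  if (max(ips) < 1e-12)
    warning("reference is orthogonal to every candidate in the window")
  # prefer smaller rank offset on ties
  best <- idx[order(-ips, abs(idx - ref_index))][1L]
  raw <- sum(reference * candidates$vectors[, best])
  list(matched_index = best,
       sign = if (raw >= 0) 1 else -1,
       inner_product = abs(raw),
       step_offset = abs(best - ref_index))
}

#' Angle variance of an eigenmode across a cohort
#'
#' For each subject, matches the reference eigenmode (typically from the
#' mean connectome) to the subject's eigensystem and reports the angle
#' between the two vectors, minimized over the matching window and over sign
#' (an eigenmode is identical under sign reversal). Angles are in degrees,
#' in [0, 90]; the inner product is clipped to [-1, 1] before acos to absorb
#' rounding.
#'
#' @param reference Unit-norm reference eigenvector.
#' @param subjects List of \code{eigensystem} objects (one per subject).
#' @param ref_index Rank of the reference mode.
#' @param window Matching window (see [match_eigenmode()]).
#' @return List with per-subject \code{angles} (degrees), \code{mean}, and
#'   95% confidence bounds \code{lower}/\code{upper}.
#' @export
angle_variance <- function(reference, subjects, ref_index, window = 2) {
  angles <- vapply(subjects, function(es) {
    m <- match_eigenmode(reference, es, ref_index, window)
    acos(min(1, max(-1, m$inner_product))) * 180 / pi
  }, numeric(1))
  ci <- mean_ci(angles)
  list(angles = angles, mean = unname(ci["mean"]),
       lower = unname(ci["lower"]), upper = unname(ci["upper"]))
}

#' Normalize an eigenspectrum by its mean
#'
#' Divides each eigenvalue by the mean of the whole spectrum (including the
#' zero eigenvalue), so that spectra of subjects with different overall
#' connectivity scales become comparable; the output has mean exactly 1.
#' \code{exclude_zero = TRUE} instead normalizes by the mean of the non-zero
#' eigenvalues (sensitivity variant).
#'
#' @param values Numeric vector of eigenvalues.
#' @param exclude_zero Drop (near-)zero eigenvalues from the normalizing
#'   mean.
#' @param zero_tol Relative tolerance used to identify zero eigenvalues.
#' @return Normalized eigenvalues.
#' @export
normalize_spectrum <- function(values, exclude_zero = FALSE, zero_tol = 1e-9) {
  stopifnot(length(values) > 0)
  denom <- if (exclude_zero) {
    nz <- values[abs(values) > zero_tol * max(abs(values), 1e-300)]
    mean(nz)
  } else mean(values)
  if (!is.finite(denom) || denom == 0)
    stop("cannot normalize an all-zero spectrum", call. = FALSE)
  values / denom
}

#' Solve the network diffusion equation
#'
#' Evolves \code{dx/dt = -beta * L x} to time t via the spectral solution
#' \code{x(t) = Q exp(-Lambda beta t) Q' x0}. The projection on mode i
#' decays as \code{exp(-beta * lambda_i * t)}, so 1/lambda_i is the mode's
#' characteristic time; the zero mode carries the conserved total, and for
#' large t the state approaches the uniform vector with entries
#' \code{mean(x0)} on a connected graph.
#'
#' @param L Symmetric Laplacian, or an \code{eigensystem}.
#' @param x0 Initial per-node state vector.
#' @param beta Diffusion rate constant (> 0, default 1).
#' @param t Time (>= 0); may be a vector.
#' @return If t is scalar, the state vector x(t); otherwise a matrix with one
#'   column per time point.
#' @export
solve_network_diffusion <- function(L, x0, beta = 1, t) {
  if (beta <= 0) stop("beta must be > 0", call. = FALSE)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  es <- if (inherits(L, "eigensystem")) L else eigendecompose(L)
  if (length(x0) != nrow(es$vectors))
    stop("x0 dimension does not match L", call. = FALSE)
  coef <- as.numeric(crossprod(es$vectors, x0))
  out <- vapply(t, function(tt) {
    as.numeric(es$vectors %*% (exp(-es$values * beta * tt) * coef))
  }, numeric(length(x0)))
  if (length(t) == 1L) as.numeric(out) else out
}

#' Export an eigensystem as TSV tables
#'
#' Writes \code{<prefix>_eigenvalues.tsv} (mode, eigenvalue, normalized) and
#' \code{<prefix>_eigenvectors.tsv} (node rows, mode columns) for external
#' plotting of glass-brain node-value figures.
#'
#' @param es An \code{eigensystem}.
#' @param prefix Path prefix.
#' @param node_ids Optional node labels for the eigenvector rows.
#' @return Paths written, invisibly.
#' @export
write_eigensystem <- function(es, prefix, node_ids = NULL) {
  vpath <- paste0(prefix, "_eigenvalues.tsv")
  qpath <- paste0(prefix, "_eigenvectors.tsv")
  utils::write.table(
    data.frame(mode = seq_along(es$values), eigenvalue = es$values,
               normalized = normalize_spectrum(es$values)),
    vpath, sep = "\t", quote = FALSE, row.names = FALSE)
  Q <- as.data.frame(es$vectors)
  names(Q) <- paste0("mode_", seq_along(es$values))
  if (!is.null(node_ids)) Q <- cbind(node_id = node_ids, Q)
  utils::write.table(Q, qpath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(eigenvalues = vpath, eigenvectors = qpath))
}
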