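# Internal helpers shared across modules.

#' Define a regular voxel grid
#'
#' Describes the regular grid on which edge trajectories, lesions, importance
#' maps and atlases live. Voxel indices are 0-based; the world coordinate of a
#' voxel center is \code{origin + spacing * index} (voxel-center convention).
#'
#' @param origin Numeric length-3, world coordinates (mm) of the center of
#'   voxel (0, 0, 0).
#' @param spacing Numeric scalar or length-3, voxel spacing in mm (> 0).
#' @param shape Integer length-3, number of voxels along each axis.
#' @return An object of class \code{voxel_grid}.
#' @export
voxel_grid <- function(origin, spacing, shape) {
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  shape <- as.integer(shape)
  stopifnot(length(origin) == 3L, length(spacing) == 3L, length(shape) == 3L)
  if (any(spacing <= 0)) stop("grid spacing must be > 0", call. = FALSE)
  if (any(shape < 1L)) stop("grid shape must be >= 1", call. = FALSE)
  structure(list(origin = origin, spacing = spacing, shape = shape),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d, spacing %s mm, origin (%s) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              paste(format(x$spacing), collapse = " x "),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

# 0-based voxel indices (k x 3) -> world coordinates of voxel centers (k x 3)
voxel_to_world <- function(vox, grid) {
  vox <- as_voxel_matrix(vox)
  sweep(sweep(vox, 2L, grid$spacing, "*"), 2L, grid$origin, "+")
}

# world coords -> nearest 0-based voxel index
world_to_voxel <- function(xyz, grid) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  v <- round(sweep(sweep(xyz, 2L, grid$origin, "-"), 2L, grid$spacing, "/"))
  storage.mode(v) <- "integer"
  v
}

# 0-based voxel indices -> 1-based linear index (x fastest)
voxel_to_linear <- function(vox, grid) {
  vox <- as_voxel_matrix(vox)
  1L + vox[, 1L] + grid$shape[1L] * (vox[, 2L] + grid$shape[2L] * vox[, 3L])
}

linear_to_voxel <- function(lin, grid) {
  lin0 <- as.integer(lin) - 1L
  nx <- grid$shape[1L]; ny <- grid$shape[2L]
  cbind(vx = lin0 %% nx,
        vy = (lin0 %/% nx) %% ny,
        vz = lin0 %/% (nx * ny))
}

in_grid <- function(vox, grid) {
  vox <- as_voxel_matrix(vox)
  vox[, 1L] >= 0L & vox[, 1L] < grid$shape[1L] &
    vox[, 2L] >= 0L & vox[, 2L] < grid$shape[2L] &
    vox[, 3L] >= 0L & vox[, 3L] < grid$shape[3L]
}

as_voxel_matrix <- function(vox) {
  if (is.data.frame(vox)) vox <- as.matrix(vox[, 1:3])
  if (is.null(dim(vox))) vox <- matrix(vox, ncol = 3L)
  storage.mode(vox) <- "integer"
  dimnames(vox) <- list(NULL, c("vx", "vy", "vz"))
  vox
}

grids_equal <- function(a, b, tol = 1e-9) {
  all(a$shape == b$shape) &&
    max(abs(a$origin - b$origin)) <= tol &&
    max(abs(a$spacing - b$spacing)) <= tol
}

# Run code with a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive independent substream seeds from a root seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

is_symmetric_matrix <- function(m, tol = 1e-9) {
  is.matrix(m) && nrow(m) == ncol(m) &&
    max(abs(m - t(m))) <= tol * max(1, max(abs(m)))
}

# Mean and two-sided 95% t confidence interval.
mean_ci <- function(x, level = 0.95) {
  x <- x[is.finite(x)]
  n <- length(x)
  m <- mean(x)
  if (n < 2L) return(c(mean = m, lower = NA_real_, upper = NA_real_))
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1L) * stats::sd(x) / sqrt(n)
  c(mean = m, lower = m - half, upper = m + half)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
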