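#' Tract atlas on a trajectory grid
#'
#' A label volume assigning voxels to named white-matter tracts; used to
#' aggregate voxelwise importance to tract level before reliability
#' analysis. Any labeling on the working grid is accepted (the canonical
#' use is a 48-tract DTI atlas; the synthetic generator emits a toy
#' partition).
#'
#' @param grid A [voxel_grid()].
#' @param voxels Integer matrix / data.frame of labeled voxels (vx, vy, vz).
#' @param labels Integer tract id (>= 1) per voxel row.
#' @param tract_names Optional character vector naming tract ids.
#' @return An object of class \code{tract_atlas}.
#' @export
tract_atlas <- function(grid, voxels, labels, tract_names = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  voxels <- as_voxel_matrix(voxels)
  labels <- as.integer(labels)
  stopifnot(nrow(voxels) == length(labels), all(labels >= 1L))
  if (is.null(tract_names))
    tract_names <- paste0("tract_", sort(unique(labels)))
  structure(list(grid = grid, voxels = voxels, labels = labels,
                 tract_names = tract_names), class = "tract_atlas")
}

#' @export
print.tract_atlas <- function(x, ...) {
  cat(sprintf("<tract_atlas> %d tracts, %d labeled voxels\n",
              length(unique(x$labels)), nrow(x$voxels)))
  invisible(x)
}

#' Mean importance per tract
#'
#' Averages map values over the voxels of each tract label; background
#' (unlabeled) voxels are excluded. Only voxels where the map was evaluated
#' (its lesion centers) contribute; a tract with no evaluated voxel gets
#' \code{NA} with a warning.
#'
#' @param map An \code{importance_map} (or any object with grid/voxels/
#'   values).
#' @param atlas A [tract_atlas()] on the same grid.
#' @return Named numeric vector of per-tract means (names = tract names).
#' @export
aggregate_importance_by_tract <- function(map, atlas) {
  if (!grids_equal(map$grid, atlas$grid))
    stop("map and atlas grids differ", call. = FALSE)
  map_lin <- voxel_to_linear(map$voxels, map$grid)
  atlas_lin <- voxel_to_linear(atlas$voxels, atlas$grid)
  ids <- sort(unique(atlas$labels))
  hit <- match(atlas_lin, map_lin)
  out <- vapply(ids, function(tid) {
    vals <- map$values[hit[atlas$labels == tid]]
    vals <- vals[!is.na(vals)]
    if (!length(vals)) NA_real_ else mean(vals)
  }, numeric(1))
  names(out) <- atlas$tract_names[ids]
  if (anyNA(out))
    warning("tracts with no evaluated map voxels: ",
            paste(names(out)[is.na(out)], collapse = ", "))
  out
}

#' Intraclass correlation coefficient (variance-ratio form)
#'
#' Test-retest reliability of a measurement taken twice per subject:
#' \code{sigma1} is the mean over subjects of the within-subject (scan-pair)
#' variance, \code{sigma2} the variance over subjects of the scan-pair
#' means, and \code{ICC = sigma2 / (sigma1 + sigma2)}. Sample variance
#' (n-1 denominator) is used throughout; with two scans per subject the ICC
#' ratio itself is invariant to that convention. This is the direct
#' variance-ratio ICC, not the ANOVA ICC(2,1).
#'
#' More than two scans per subject are accepted as a natural extension (the
#' per-subject variance is then taken over all scans).
#'
#' @param values Numeric matrix, subjects x scans (>= 2 subjects, >= 2
#'   scans).
#' @return List with \code{sigma1}, \code{sigma2}, \code{icc}, and
#'   \code{band} (clinical reporting label: poor < 0.4, fair-to-good
#'   0.4-0.75, excellent > 0.75). ICC is \code{NA} (flagged by a warning)
#'   when both variance components vanish.
#' @export
icc <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("need >= 2 subjects and >= 2 scans", call. = FALSE)
  within <- apply(values, 1L, stats::var)
  means <- rowMeans(values)
  sigma1 <- mean(within)
  sigma2 <- stats::var(means)
  if (sigma1 + sigma2 == 0) {
    warning("both variance components are zero; ICC undefined")
    return(list(sigma1 = 0, sigma2 = 0, icc = NA_real_, band = NA_character_))
  }
  val <- sigma2 / (sigma1 + sigma2)
  list(sigma1 = sigma1, sigma2 = sigma2, icc = val, band = icc_band(val))
}

icc_band <- function(x) {
  ifelse(x < 0.4, "poor", ifelse(x <= 0.75, "fair-to-good", "excellent"))
}

#' Per-tract reliability table
#'
#' Applies [icc()] tract by tract to per-scan mean importance values.
#'
#' @param values 3-D array subjects x scans x tracts (tract dimnames used
#'   when present), or a list of subjects x scans matrices, one per tract.
#' @return data.frame (tract, mean, sigma1, sigma2, icc, band) mirroring a
#'   per-tract bar/point reliability figure.
#' @export
reliability_table <- function(values) {
  if (is.array(values) && length(dim(values)) == 3L) {
    tracts <- dimnames(values)[[3L]] %||% paste0("tract_", seq_len(dim(values)[3L]))
    values <- lapply(seq_len(dim(values)[3L]), function(k) values[, , k])
    names(values) <- tracts
  }
  stopifnot(is.list(values))
  tracts <- names(values) %||% paste0("tract_", seq_along(values))
  rows <- lapply(seq_along(values), function(k) {
    r <- icc(values[[k]])
    data.frame(tract = tracts[k], mean = mean(values[[k]]),
               sigma1 = r$sigma1, sigma2 = r$sigma2, icc = r$icc,
               band = r$band, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
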