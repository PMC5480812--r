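#' Virtual callosotomy
#'
#' Removes every edge whose consensus trajectory mask passes through the
#' midline callosal plane: a voxel counts as on the plane when its world x
#' coordinate lies within half a voxel of \code{plane_x} (and, optionally,
#' its z coordinate within \code{z_range}, since the corpus callosum is a
#' bounded midline structure — commissural detours below it can then be
#' spared). Affected edges are cut entirely (exclusion-mask semantics:
#' streamlines through the callosum are removed, so a purely callosal edge
#' keeps zero weight), not proportionally weakened.
#'
#' @param x A \code{connectome}.
#' @param traj Matching \code{edge_trajectories}.
#' @param plane_x Sagittal plane position in mm (default 0).
#' @param z_range Length-2 numeric; only mask voxels with world z inside
#'   this range trigger a cut (default the whole plane).
#' @return The cut \code{connectome}; attributes \code{"cut_edges"}
#'   (character keys) and \code{"disconnected"} (logical; TRUE when the cut
#'   disconnects the graph, as expected when no non-callosal
#'   interhemispheric edges exist).
#' @export
virtual_callosotomy <- function(x, traj, plane_x = 0,
                                z_range = c(-Inf, Inf)) {
  stopifnot(inherits(x, "connectome"), inherits(traj, "edge_trajectories"))
  grid <- traj$grid
  half <- grid$spacing[1L] / 2
  crosses <- vapply(traj$consensus, function(m) {
    if (nrow(m) == 0L) return(FALSE)
    w <- voxel_to_world(m, grid)
    any(abs(w[, 1L] - plane_x) <= half &
          w[, 3L] >= z_range[1L] & w[, 3L] <= z_range[2L])
  }, logical(1))
  cut <- names(crosses)[crosses]
  out <- x
  if (length(cut)) {
    ends <- split_edge_key(cut)
    ii <- match(ends[, 1L], x$node_ids)
    jj <- match(ends[, 2L], x$node_ids)
    ok <- !is.na(ii) & !is.na(jj)
    out$adjacency[cbind(ii[ok], jj[ok])] <- 0
    out$adjacency[cbind(jj[ok], ii[ok])] <- 0
  }
  es <- eigendecompose(build_laplacian(out))
  attr(out, "cut_edges") <- cut
  attr(out, "disconnected") <- n_zero_modes(es) > 1L
  out
}

#' Compare eigenspectra across subject groups
#'
#' For each subject in each cohort, eigendecomposes the Laplacian,
#' normalizes the spectrum by its mean, and extracts the second eigenvalue
#' (the rate of left-right diffusion). Reports per-group mean with 95%
#' confidence bounds and pairwise two-sample t-tests (alpha 0.05,
#' uncorrected). Normalization is reported both including and excluding the
#' zero eigenvalue(s) in the mean.
#'
#' @param cohorts Named list of cohorts (e.g. control, agcc, callosotomy);
#'   each a list of \code{connectome} objects.
#' @param mode Eigenvalue rank to compare (default 2).
#' @return An object of class \code{group_comparison}: \code{subjects}
#'   (data.frame group, subject, lambda_raw, lambda_norm,
#'   lambda_norm_nonzero), \code{summary} (per-group mean and CI), and
#'   \code{tests} (pairwise t-test table).
#' @export
compare_groups <- function(cohorts, mode = 2) {
  stopifnot(is.list(cohorts), length(cohorts) >= 1L,
            all(vapply(cohorts, length, integer(1)) >= 1L))
  nm <- names(cohorts) %||% paste0("group_", seq_along(cohorts))
  rows <- list()
  for (g in seq_along(cohorts)) {
    for (s in seq_along(cohorts[[g]])) {
      es <- eigendecompose(build_laplacian(cohorts[[g]][[s]]))
      rows[[length(rows) + 1L]] <- data.frame(
        group = nm[g], subject = s,
        lambda_raw = es$values[mode],
        lambda_norm = normalize_spectrum(es$values)[mode],
        lambda_norm_nonzero = normalize_spectrum(es$values,
                                                 exclude_zero = TRUE)[mode],
        stringsAsFactors = FALSE)
    }
  }
  subjects <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(nm, function(g) {
    ci <- mean_ci(subjects$lambda_norm[subjects$group == g])
    data.frame(group = g, n = sum(subjects$group == g),
               mean = ci["mean"], lower = ci["lower"], upper = ci["upper"],
               row.names = NULL)
  }))
  tests <- list()
  if (length(nm) > 1L) {
    for (a in seq_along(nm)) for (b in seq_along(nm)) {
      if (a >= b) next
      xa <- subjects$lambda_norm[subjects$group == nm[a]]
      xb <- subjects$lambda_norm[subjects$group == nm[b]]
      p <- if (length(xa) > 1L && length(xb) > 1L &&
               (stats::sd(xa) > 0 || stats::sd(xb) > 0))
        stats::t.test(xa, xb)$p.value
      else if (isTRUE(all.equal(mean(xa), mean(xb)))) 1 else NA_real_
      tests[[length(tests) + 1L]] <- data.frame(
        group_a = nm[a], group_b = nm[b], p_value = p,
        significant = !is.na(p) & p < 0.05, stringsAsFactors = FALSE)
    }
    tests <- do.call(rbind, tests)
  } else tests <- NULL
  structure(list(mode = mode, subjects = subjects, summary = summ,
                 tests = tests), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> normalized eigenvalue %d\n", x$mode))
  print(x$summary, row.names = FALSE)
  if (!is.null(x$tests)) print(x$tests, row.names = FALSE)
  invisible(x)
}

#' Detect eigenmode splitting after interhemispheric disconnection
#'
#' When the hemispheres are disconnected, a bilateral control eigenmode
#' typically splits into two lesioned-system modes, one supported on each
#' hemisphere (the block-diagonal Laplacian limit). For each control mode,
#' the \code{n_match} lesioned modes with the largest absolute inner product
#' are reported along with each lesioned mode's hemispheric support
#' fraction (share of squared eigenvector mass per hemisphere; the two
#' fractions sum to 1). A split is declared when the two best matches have
#' at least \code{support_threshold} of their mass in opposite hemispheres.
#'
#' @param control,lesioned \code{eigensystem} objects over the same node
#'   ordering.
#' @param hemisphere Per-node hemisphere labels ("left"/"right").
#' @param top_k Number of control modes to analyze (modes 1..top_k).
#' @param n_match Matches reported per control mode (default 2).
#' @param support_threshold Minimum hemispheric support fraction for a split
#'   (default 0.9; the fully disconnected limit gives 1.0, the margin
#'   absorbs residual coupling).
#' @return An object of class \code{split_report}: data.frame with one row
#'   per (control mode, match rank): matched index, |inner product|,
#'   left/right support of the matched mode, and a per-control-mode
#'   \code{split} flag.
#' @export
detect_mode_splitting <- function(control, lesioned, hemisphere, top_k = 4,
                                  n_match = 2, support_threshold = 0.9) {
  stopifnot(inherits(control, "eigensystem"), inherits(lesioned, "eigensystem"),
            nrow(control$vectors) == nrow(lesioned$vectors),
            length(hemisphere) == nrow(control$vectors))
  left <- hemisphere == "left"
  n <- length(lesioned$values)
  support_left <- colSums(lesioned$vectors[left, , drop = FALSE]^2)
  rows <- list()
  for (m in seq_len(min(top_k, length(control$values)))) {
    ips <- abs(as.numeric(crossprod(lesioned$vectors, control$vectors[, m])))
    best <- order(-ips)[seq_len(min(n_match, n))]
    sl <- support_left[best]
    split <- length(best) >= 2L &&
      ((sl[1L] >= support_threshold && 1 - sl[2L] >= support_threshold) ||
         (1 - sl[1L] >= support_threshold && sl[2L] >= support_threshold))
    rows[[m]] <- data.frame(
      control_mode = m, match_rank = seq_along(best), matched_index = best,
      inner_product = ips[best], support_left = sl, support_right = 1 - sl,
      split = split)
  }
  structure(do.call(rbind, rows), class = c("split_report", "data.frame"))
}
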