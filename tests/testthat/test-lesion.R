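test_that("sphere voxelization matches brute-force enumeration", {
  g <- voxel_grid(origin = c(0, 0, 0), spacing = 1, shape = c(30, 30, 30))
  center <- c(14.2, 15.7, 13.1)
  got <- voxelize_sphere(center, g, diameter = 12)
  # brute force over the whole grid
  all_vox <- as.matrix(expand.grid(vx = 0:29, vy = 0:29, vz = 0:29))
  d2 <- (all_vox[, 1] - center[1])^2 + (all_vox[, 2] - center[2])^2 +
    (all_vox[, 3] - center[3])^2
  expect_setequal(spectralconn:::voxel_to_linear(got, g),
                  spectralconn:::voxel_to_linear(all_vox[d2 <= 36, ], g))

  # sub-voxel sphere on a voxel center selects exactly that voxel
  tiny <- voxelize_sphere(c(5, 5, 5), g, diameter = 0.5)
  expect_equal(nrow(tiny), 1L)
  expect_equal(as.integer(tiny), c(5L, 5L, 5L))

  expect_warning(out <- voxelize_sphere(c(-100, 0, 0), g, diameter = 12),
                 "does not intersect")
  expect_equal(nrow(out), 0L)
})

test_that("lesions weaken edges by removed volume fraction times stoppage", {
  sys2 <- two_node_system(weight = 1, n_vox = 10)
  # sphere covering the full 10-voxel trajectory
  all_in <- lesion(center = c(-0.5, 0, 0), diameter = 30, stoppage = 1)
  out <- apply_lesion(sys2$connectome, sys2$trajectories, all_in)
  expect_equal(out$adjacency["a", "b"], 0)

  # sphere covering exactly 5 of 10 voxels: weight halves at stoppage 1
  # trajectory voxels at world x = -5..4 (vx 5..14), y = z = 0
  half <- lesion(center = c(-3, 0, 0), diameter = 4.2, stoppage = 1)
  covered <- voxelize_sphere(half$center, sys2$grid, half$diameter)
  out <- apply_lesion(sys2$connectome, sys2$trajectories, half)
  f <- attr(out, "edge_fractions")[["a|b"]]
  expect_equal(f, 0.5)
  expect_equal(out$adjacency["a", "b"], 0.5)
  expect_symmetric(out$adjacency)

  # small stoppage leaves the connectome almost unchanged
  soft <- lesion(center = c(-0.5, 0, 0), diameter = 30, stoppage = 1e-9)
  out <- apply_lesion(sys2$connectome, sys2$trajectories, soft)
  expect_equal(out$adjacency["a", "b"], 1, tolerance = 1e-8)

  # positive weight without a consensus mask is a data inconsistency
  broken <- sys2$trajectories
  broken$consensus[["a|b"]] <- broken$consensus[["a|b"]][0, , drop = FALSE]
  expect_error(apply_lesion(sys2$connectome, broken, all_in),
               "empty consensus mask")
})

test_that("importance is the matched eigenvalue decrease", {
  sys2 <- two_node_system(weight = 1)
  # full removal of the only edge: lambda2 drops 2 -> 0
  les <- lesion(center = c(0, 0, 0), diameter = 40, stoppage = 1)
  imp <- importance_at(sys2$connectome, sys2$trajectories, les, mode = 2)
  expect_equal(as.numeric(imp), 2)
  expect_true(attr(imp, "disconnected"))

  # lesion far from every trajectory: importance 0
  far <- lesion(center = c(8, 8, 8), diameter = 2, stoppage = 1)
  expect_equal(as.numeric(
    importance_at(sys2$connectome, sys2$trajectories, far, mode = 2)), 0)
})

test_that("importance agrees with first-order perturbation for small lesions", {
  gen <- generate_connectome(small_params(), seed = 31)
  cn <- gen$connectome; traj <- gen$trajectories
  ref <- eigendecompose(build_laplacian(cn))
  wm <- spectralconn:::white_matter_voxels(traj)
  set.seed(41)
  centers <- wm[sample(nrow(wm), 25), , drop = FALSE]
  world <- spectralconn:::voxel_to_world(centers, traj$grid)
  checked <- 0L
  for (k in seq_len(nrow(centers))) {
    les <- lesion(world[k, ], diameter = 12, stoppage = 0.05)
    pert <- apply_lesion(cn, traj, les)
    dL <- build_laplacian(cn) - build_laplacian(pert)
    v <- ref$vectors[, 2]
    first_order <- as.numeric(t(v) %*% dL %*% v)
    if (first_order < 1e-8) next
    imp <- as.numeric(importance_at(cn, traj, les, mode = 2,
                                    reference = ref))
    expect_lt(abs(imp - first_order) / imp, 0.1)
    checked <- checked + 1L
  }
  expect_gt(checked, 5L)
})

test_that("importance maps are supported on the lesioned trajectory neighborhood", {
  sys2 <- two_node_system(weight = 2, n_vox = 10)
  map <- importance_map(sys2$connectome, sys2$trajectories, mode = 2,
                        stoppage = 1, diameter = 4)
  # evaluated centers are exactly the white-matter (consensus) voxels
  expect_equal(nrow(map$voxels), 10L)
  expect_true(all(map$values > 0))

  # doubling all weights doubles every importance value
  dbl <- sys2$connectome
  dbl$adjacency <- 2 * dbl$adjacency
  map2 <- importance_map(dbl, sys2$trajectories, mode = 2,
                         stoppage = 1, diameter = 4)
  expect_equal(map2$values, 2 * map$values, tolerance = 1e-9)
})

test_that("index-matched importance values are non-negative", {
  gen <- generate_connectome(small_params(), seed = 32)
  scan <- spectralconn:::lesion_scan(gen$connectome, gen$trajectories,
                                     modes = 2:3, stoppages = 1, stride = 3,
                                     window = 0)
  expect_gt(nrow(scan$centers), 20L)
  expect_true(all(scan$values >= -1e-9 * max(abs(scan$values))))
})

test_that("importance grows with the stoppage parameter", {
  gen <- generate_connectome(small_params(), seed = 33)
  scan <- spectralconn:::lesion_scan(gen$connectome, gen$trajectories,
                                     modes = 2, stoppages = c(0.25, 0.5, 1),
                                     stride = 3, window = 0)
  v <- scan$values[, , 1]
  expect_true(all(diff(t(v)) >= -1e-9))
})

test_that("stoppage sweep correlates maps of the same mode", {
  gen <- generate_connectome(small_params(), seed = 34)
  sw <- stoppage_sweep(gen$connectome, gen$trajectories, modes = 2,
                       stoppages = c(0.5, 0.5, 1), stride = 3)
  tab <- sw$correlations
  # identical stoppage values give r = 1 exactly
  expect_equal(tab$r[tab$stoppage_a == 0.5 & tab$stoppage_b == 0.5], 1)
  expect_true(all(tab$r <= 1 & tab$r >= -1))
  expect_error(stoppage_sweep(gen$connectome, gen$trajectories, modes = 2,
                              stoppages = 1), "at least two")
})

test_that("stoppage-correlation is invariant to global weight rescaling", {
  gen <- generate_connectome(small_params(), seed = 35)
  sw1 <- stoppage_sweep(gen$connectome, gen$trajectories, modes = 2,
                        stoppages = c(0.5, 1), stride = 4)
  scaled <- gen$connectome
  scaled$adjacency <- 3.7 * scaled$adjacency
  sw2 <- stoppage_sweep(scaled, gen$trajectories, modes = 2,
                        stoppages = c(0.5, 1), stride = 4)
  expect_equal(sw1$correlations$r, sw2$correlations$r, tolerance = 1e-9)
})

test_that("perturbed eigenvectors rotate far less than subjects differ", {
  # lesion-induced angle change should sit well below between-subject
  # angles; this is a property of the full-scale study conditions, where a
  # 12 mm lesion is small relative to the white matter
  params <- generator_params()
  cohort <- generate_cohort(params, n_subjects = 5, n_scans = 1, seed = 51)
  scans <- lapply(cohort$subjects, function(s) s$scans[[1]])
  mean_cn <- average_connectomes(scans)
  ref <- eigendecompose(build_laplacian(mean_cn))
  subj_es <- lapply(scans, function(cn) eigendecompose(build_laplacian(cn)))
  between <- angle_variance(ref$vectors[, 2], subj_es, 2)$mean

  gen1 <- scans[[1]]
  wm <- spectralconn:::white_matter_voxels(cohort$trajectories)
  set.seed(61)
  world <- spectralconn:::voxel_to_world(
    wm[sample(nrow(wm), 10), , drop = FALSE], cohort$trajectories$grid)
  es1 <- eigendecompose(build_laplacian(gen1))
  pert_angles <- vapply(seq_len(10), function(k) {
    pert <- apply_lesion(gen1, cohort$trajectories,
                         lesion(world[k, ], diameter = 12, stoppage = 1))
    esp <- eigendecompose(build_laplacian(pert))
    angle_variance(es1$vectors[, 2], list(esp), 2)$angles[[1]]
  }, numeric(1))
  expect_lt(mean(pert_angles), between / 5)
})

test_that("map export writes sparse TSV and a NIfTI volume", {
  sys2 <- two_node_system()
  map <- importance_map(sys2$connectome, sys2$trajectories, mode = 2,
                        stoppage = 1, diameter = 4)
  paths <- write_map(map, file.path(tempdir(), "imap"), nifti = TRUE)
  tab <- read.delim(paths[["tsv"]])
  expect_equal(nrow(tab), nrow(map$voxels))
  img <- RNifti::readNifti(paths[["nifti"]])
  expect_equal(dim(img), map$grid$shape)
  expect_equal(sum(img), sum(map$values), tolerance = 1e-6)
})
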