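test_that("virtual callosotomy cuts exactly the plane-crossing edges", {
  gen <- generate_connectome(small_params(), seed = 17)
  cn <- gen$connectome
  cut <- virtual_callosotomy(cn, gen$trajectories)
  cross <- outer(cn$hemisphere, cn$hemisphere, "!=")
  # default generator routes every interhemispheric edge through the midline
  expect_equal(sum(cut$adjacency[cross]), 0)
  # intra-hemisphere edges untouched
  expect_equal(cut$adjacency[!cross], cn$adjacency[!cross])
  expect_true(attr(cut, "disconnected"))
  # hemispheres joined only through plane-crossing edges: lambda2 becomes 0
  es <- eigendecompose(build_laplacian(cut))
  expect_lt(abs(es$values[2]), 1e-9 * max(es$values))

  # a connectome with no plane-crossing masks is unchanged
  cut2 <- virtual_callosotomy(cut, gen$trajectories, plane_x = 200)
  expect_equal(cut2$adjacency, cut$adjacency)
  expect_length(attr(cut2, "cut_edges"), 0L)
})

test_that("callosotomy never raises any eigenvalue", {
  cohort <- generate_cohort(small_params(), n_subjects = 3, n_scans = 1,
                            seed = 18)
  for (s in cohort$subjects) {
    cn <- s$scans[[1]]
    cut <- virtual_callosotomy(cn, cohort$trajectories)
    e0 <- eigendecompose(build_laplacian(cn))$values
    e1 <- eigendecompose(build_laplacian(cut))$values
    expect_true(all(e1 <= e0 + 1e-9 * max(e0)))
  }
})

test_that("group comparison reports normalized second eigenvalues and tests", {
  cohort <- generate_cohort(small_params(), n_subjects = 4, n_scans = 1,
                            seed = 19)
  controls <- lapply(cohort$subjects, function(s) s$scans[[1]])
  cuts <- lapply(controls, virtual_callosotomy, traj = cohort$trajectories)
  comp <- compare_groups(list(control = controls, callosotomy = cuts))

  expect_equal(nrow(comp$subjects), 8L)
  raw_con <- comp$subjects$lambda_raw[comp$subjects$group == "control"]
  raw_cut <- comp$subjects$lambda_raw[comp$subjects$group == "callosotomy"]
  expect_true(all(raw_cut <= raw_con))
  expect_equal(max(abs(raw_cut)), 0, tolerance = 1e-9)

  # identical cohorts: equal means, p = 1
  same <- compare_groups(list(a = controls, b = controls))
  expect_equal(same$summary$mean[1], same$summary$mean[2])
  expect_equal(same$tests$p_value, 1, tolerance = 1e-9)

  # both normalization conventions are reported
  expect_true(all(c("lambda_norm", "lambda_norm_nonzero") %in%
                    names(comp$subjects)))
})

test_that("mode splitting is detected for disconnected hemispheres", {
  gen <- generate_connectome(small_params(), seed = 20)
  cn <- gen$connectome
  es_con <- eigendecompose(build_laplacian(cn))
  cut <- virtual_callosotomy(cn, gen$trajectories)
  es_cut <- eigendecompose(build_laplacian(cut))
  rep <- detect_mode_splitting(es_con, es_cut, cn$hemisphere, top_k = 4)

  # support fractions sum to one per matched mode
  expect_equal(rep$support_left + rep$support_right,
               rep(1, nrow(rep)), tolerance = 1e-9)
  # disconnected lesioned modes live in one hemisphere each
  expect_true(all(pmax(rep$support_left, rep$support_right) > 0.999))
  # the constant mode always splits into the two per-component zero modes;
  # splitting of higher bilateral modes needs near-mirror hemispheres and is
  # asserted on full-scale cohorts elsewhere
  expect_true(rep$split[rep$control_mode == 1 & rep$match_rank == 1])

  # identity case: every mode maps to itself, nothing splits
  self <- detect_mode_splitting(es_con, es_con, cn$hemisphere, top_k = 4)
  first <- self[self$match_rank == 1, ]
  expect_equal(first$matched_index, first$control_mode)
  expect_equal(first$inner_product, rep(1, 4), tolerance = 1e-9)
  expect_false(any(self$split))
})

test_that("two identical disconnected hemispheres give exact per-side modes", {
  # block-diagonal construction: left block == right block
  ids <- c("L1", "L2", "L3", "R1", "R2", "R3")
  B <- matrix(c(0, 2, 1, 2, 0, 3, 1, 3, 0), 3)
  A <- rbind(cbind(B, matrix(0, 3, 3)), cbind(matrix(0, 3, 3), B))
  dimnames(A) <- list(ids, ids)
  les <- connectome(A, ids, hemisphere = rep(c("left", "right"), each = 3),
                    centroid = rbind(cbind(-10, 1:3, 0), cbind(10, 1:3, 0)),
                    volume = rep(1, 6))
  es_les <- eigendecompose(build_laplacian(les))
  # connected control analog: same blocks plus a weak bridge
  A2 <- A; A2["L1", "R1"] <- A2["R1", "L1"] <- 0.01
  es_con <- eigendecompose(build_laplacian(A2))
  rep <- detect_mode_splitting(es_con, es_les,
                               rep(c("left", "right"), each = 3), top_k = 4)
  hemi_support <- pmax(rep$support_left, rep$support_right)
  expect_equal(hemi_support[rep$control_mode > 2],
               rep(1, sum(rep$control_mode > 2)), tolerance = 1e-9)
})

test_that("synthetic AgCC replaces callosal weight with inferior detours", {
  gen <- generate_connectome(small_params(), seed = 22)
  cn <- gen$connectome; traj <- gen$trajectories
  z_cut <- c(0, Inf)

  # compensation 0 reproduces the z-restricted callosotomy exactly
  agcc0 <- generate_agcc_variant(cn, traj, compensation = 0,
                                 z_range = z_cut)
  cut <- virtual_callosotomy(cn, traj, z_range = z_cut)
  expect_equal(agcc0$connectome$adjacency, cut$adjacency)

  agcc <- generate_agcc_variant(cn, traj, compensation = 0.3,
                                z_range = z_cut)
  l2_0 <- eigendecompose(build_laplacian(agcc0$connectome))$values[2]
  l2_c <- eigendecompose(build_laplacian(agcc$connectome))$values[2]
  expect_gt(l2_c, l2_0)

  # total re-added weight matches the compensation fraction
  removed <- sum(cn$adjacency - agcc0$connectome$adjacency) / 2
  added <- sum(agcc$connectome$adjacency - agcc0$connectome$adjacency) / 2
  expect_equal(added, 0.3 * removed, tolerance = 1e-9)

  # no trajectory of the AgCC variant crosses the callosal region
  grid <- traj$grid
  half <- grid$spacing[1] / 2
  for (m in agcc$trajectories$consensus) {
    w <- spectralconn:::voxel_to_world(m, grid)
    expect_false(any(abs(w[, 1]) <= half & w[, 3] >= z_cut[1]))
  }

  expect_error(generate_agcc_variant(cn, traj, compensation = 1.5),
               "cap")
})

test_that("group ordering control > AgCC > callosotomy on compensated cohorts", {
  cohort <- generate_cohort(small_params(), n_subjects = 4, n_scans = 1,
                            seed = 23)
  controls <- lapply(cohort$subjects, function(s) s$scans[[1]])
  cuts <- lapply(controls, virtual_callosotomy, traj = cohort$trajectories,
                 z_range = c(0, Inf))
  agcc <- lapply(controls, function(cn)
    generate_agcc_variant(cn, cohort$trajectories, compensation = 0.3,
                          z_range = c(0, Inf))$connectome)
  comp <- compare_groups(list(control = controls, agcc = agcc,
                              callosotomy = cuts))
  m <- setNames(comp$summary$mean, comp$summary$group)
  expect_gt(m[["control"]], m[["agcc"]])
  expect_gt(m[["agcc"]], m[["callosotomy"]])
})
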