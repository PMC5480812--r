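# Fixtures built in code; no data files.

# Hand-made connectome: 6 nodes, 3 per hemisphere, explicit weights.
tiny_connectome <- function() {
  ids <- c("L1", "L2", "L3", "R1", "R2", "R3")
  A <- matrix(0, 6, 6, dimnames = list(ids, ids))
  A["L1", "L2"] <- 4; A["L2", "L3"] <- 3; A["L1", "L3"] <- 1
  A["R1", "R2"] <- 4; A["R2", "R3"] <- 3; A["R1", "R3"] <- 1
  A["L1", "R1"] <- 0.5                      # single callosal edge
  A <- A + t(A)
  connectome(A, ids,
             hemisphere = rep(c("left", "right"), each = 3),
             centroid = rbind(c(-20, 0, 0), c(-30, 20, 0), c(-25, -20, 10),
                              c(20, 0, 0), c(30, 20, 0), c(25, -20, 10)),
             volume = c(100, 120, 90, 100, 120, 90))
}

# 2-node connectome with a straight-line trajectory on a small 1 mm grid.
two_node_system <- function(weight = 1, n_vox = 11) {
  ids <- c("a", "b")
  A <- matrix(c(0, weight, weight, 0), 2, dimnames = list(ids, ids))
  conn <- connectome(A, ids, hemisphere = c("left", "right"),
                     centroid = rbind(c(-5, 0, 0), c(5, 0, 0)),
                     volume = c(10, 10))
  grid <- voxel_grid(origin = c(-10, -10, -10), spacing = 1, shape = c(21, 21, 21))
  vox <- cbind(vx = seq(5L, 5L + n_vox - 1L), vy = 10L, vz = 10L)
  d <- data.frame(vox, count = 5L)
  traj <- edge_trajectories(grid, stats::setNames(list(d, d),
                                                  c("a->b", "b->a")),
                            consensus = list("a|b" = as.matrix(vox[, 1:3])))
  list(connectome = conn, trajectories = traj, grid = grid)
}

# Small, fast generator settings used across tests (20 nodes on a 32^3 grid).
small_params <- function(...) {
  args <- utils::modifyList(
    list(n_nodes = 20, grid_shape = c(32, 32, 32), spacing = 2,
         min_separation = 12, tube_radius = 2),
    list(...))
  do.call(generator_params, args)
}

expect_symmetric <- function(A, tol = 1e-12) {
  expect_lt(max(abs(A - t(A))), tol * max(1, max(abs(A))))
}
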