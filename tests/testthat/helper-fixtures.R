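# Small planar two-link hinge fixture used across the unit tests: link A and
# link B joined by one pin, smooth periodic relative rotation, landmark pairs
# on each link, optional seeded periodic artifact injection.

two_link_topology <- function() {
  linkage_topology(
    links = c("A", "B"),
    joints = data.frame(joint = "J", proximal = "A", distal = "B",
                        neutral_offset = 0, stringsAsFactors = FALSE),
    root = "A", upright_angle = 0,
    landmarks = list(A = rbind(c(-0.15, 0), c(0.15, 0)),
                     B = rbind(c(-0.12, 0), c(0.12, 0))),
    com_local = list(A = c(0, 0), B = c(0, 0)))
}

# Rigid hinge motion: A translates and rotates smoothly, B rotates relative
# to A about the shared pin. Joint locals: (0.25, 0) in A, (-0.2, 0) in B.
two_link_poses <- function(grid) {
  u <- grid$phase
  ang_a <- 0.4 * sin(u) + 0.1 * cos(2 * u)
  o_a <- cbind(0.05 * cos(u), 1 + 0.03 * sin(u))
  ps_a <- pose_series(o_a, ang_a)
  beta <- 0.8 * cos(u) + 0.2 * sin(2 * u)          # relative hinge angle
  ang_b <- ang_a + beta
  joint <- to_global(ps_a, c(0.25, 0))
  j_b <- c(-0.2, 0)
  o_b <- joint - cbind(cos(ang_b) * j_b[1] - sin(ang_b) * j_b[2],
                       sin(ang_b) * j_b[1] + cos(ang_b) * j_b[2])
  list(A = ps_a, B = pose_series(o_b, ang_b),
       joint = joint, j_a = c(0.25, 0), j_b = j_b)
}

two_link_fixture <- function(N = 64, K = 2, amplitude = 0, seed = 1) {
  grid <- cycle_grid(N, period = 1)
  topo <- two_link_topology()
  poses <- two_link_poses(grid)
  landmarks <- landmark_trajectories(poses[c("A", "B")], topo, grid)
  lm_frames <- marker_frames(landmarks, topo)
  profiles <- sta_profiles(seed, names(landmarks$m), K = K,
                           amplitude = amplitude)
  markers <- if (amplitude > 0)
    inject_sta(landmarks, lm_frames, profiles, topo)
  else landmarks
  list(topology = topo, grid = grid, poses = poses, landmarks = landmarks,
       lm_frames = lm_frames, profiles = profiles, markers = markers)
}

random_pose <- function() planar_pose(stats::runif(2, -1, 1),
                                      stats::runif(1, -pi, pi))

expect_equal_mat <- function(a, b, tol = 1e-12) {
  expect_lt(max(abs(a - b)), tol)
}
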