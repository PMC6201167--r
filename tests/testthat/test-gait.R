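test_that("the seven-link fixture produces 14 rigid, pin-consistent marker
           trajectories with the prescribed segment lengths", {
  fx <- gait_fixture(seed = 1, N = 100, sta_amplitude = 0)
  expect_length(fx$markers$m, 14)
  # joint constraint holds exactly at every pin of the true motion
  g <- stafree:::seven_link_geometry(fx$params)
  pins <- list(`l-H` = list("HAT", g$hat_hip, "l-T", g$thigh_hip),
               `l-K` = list("l-T", g$thigh_knee, "l-S", g$shank_knee),
               `l-A` = list("l-S", g$shank_ankle, "l-F", g$foot_ankle))
  for (nm in names(pins)) {
    p <- pins[[nm]]
    r <- joint_residual(fx$poses[[p[[1]]]], fx$poses[[p[[3]]]], p[[2]], p[[4]])
    expect_lt(r$sum_norm, 1e-10)
  }
  # thigh hip-knee distance is l_Thigh at every sample; shank likewise
  for (s in c("l", "r")) {
    dT <- sqrt(rowSums((fx$joints[[paste0(s, "-K")]] -
                          fx$joints[[paste0(s, "-H")]])^2))
    expect_equal(range(dT), rep(0.420, 2), tolerance = 1e-12)
    dS <- sqrt(rowSums((fx$joints[[paste0(s, "-A")]] -
                          fx$joints[[paste0(s, "-K")]])^2))
    expect_equal(range(dS), rep(0.379, 2), tolerance = 1e-12)
  }
  # inter-landmark distances constant per link
  for (l in fx$topology$links) {
    d <- sqrt(rowSums((fx$markers$m[[paste0(l, "2")]] -
                         fx$markers$m[[paste0(l, "1")]])^2))
    expect_lt(diff(range(d)), 1e-12)
  }
})

test_that("the prescribed gait program is band-limited and closes the cycle", {
  p <- gait_params()
  # evaluating the closed-form program at u and u + 2pi gives identical
  # kinematics: the construction is exactly periodic
  k1 <- gait_kinematics(p, cycle_grid(40))
  k2 <- gait_kinematics(p, cycle_grid(80))
  for (l in k1$topology$links) {
    expect_equal_mat(k1$link_kin[[l]]$com, k2$link_kin[[l]]$com[seq(2, 80, 2), ],
                     1e-12)
    expect_equal(k1$link_kin[[l]]$ang, k2$link_kin[[l]]$ang[seq(2, 80, 2)],
                 tolerance = 1e-12)
  }
  # angle ranges are gait-like
  ang <- k1$angles
  expect_lt(max(abs(ang$root)), 0.06)
  expect_lt(max(abs(ang$joint$`l-H`)), 0.4)
  expect_gt(min(ang$joint$`l-K`), -0.05)
  expect_lt(max(ang$joint$`l-K`), 1.2)
  expect_lt(max(abs(ang$joint$`l-A`)), 0.35)
  # the two legs are half a cycle out of phase
  expect_equal(ang$joint$`l-H`[1:20], ang$joint$`r-H`[21:40], tolerance = 1e-12)
})

test_that("angle conventions invert: joint_angles on the true landmark
           frames returns the program angles", {
  fx <- gait_fixture(seed = 1, N = 80, sta_amplitude = 0)
  ang <- joint_angles(fx$lm_frames, fx$topology)
  expect_equal(ang$root, fx$angles$root, tolerance = 1e-10)
  for (j in names(fx$angles$joint))
    expect_equal(ang$joint[[j]], fx$angles$joint[[j]], tolerance = 1e-10)
})

test_that("artifact profiles are seeded, bounded and decay as 1/k", {
  pr1 <- sta_profiles(5, c("a", "b"), K = 4, amplitude = 0.01)
  pr2 <- sta_profiles(5, c("a", "b"), K = 4, amplitude = 0.01)
  expect_identical(pr1, pr2)
  pr3 <- sta_profiles(6, c("a", "b"), K = 4, amplitude = 0.01)
  expect_false(identical(pr1$a$qx, pr3$a$qx))
  z <- sta_profiles(7, "m", K = 4, amplitude = 0)
  expect_equal(max(abs(c(z$m$qx, z$m$qy))), 0)
  # triangle-inequality bound on the evaluated series
  grid <- cycle_grid(200)
  bound <- 2 * 0.01 * sum(1 / (1:4))
  for (mk in names(pr1)) {
    e <- eval_sta(pr1[[mk]], grid)
    expect_lte(max(abs(e)), bound)
  }
})

test_that("artifact injection is the landmark-frame construction", {
  fx <- gait_fixture(seed = 3, N = 80, sta_amplitude = 0.01)
  # zero profiles: identity
  zero <- sta_profiles(1, names(fx$landmarks$m), K = 4, amplitude = 0)
  same <- inject_sta(fx$landmarks, fx$lm_frames, zero, fx$topology)
  for (mk in names(same$m))
    expect_identical(same$m[[mk]], fx$landmarks$m[[mk]])
  # explicit reconstruction: m = o_lm + R_lm (local + e)
  mk <- "l-T1"
  e <- eval_sta(fx$profiles[[mk]], fx$grid)
  local <- to_local(fx$lm_frames$`l-T`, fx$landmarks$m[[mk]])
  expect_equal_mat(fx$markers$m[[mk]],
                   to_global(fx$lm_frames$`l-T`, local + e), 1e-10)
  # inter-marker distance varies once xi != 0
  d <- sqrt(rowSums((fx$markers$m[["l-T2"]] - fx$markers$m[["l-T1"]])^2))
  expect_gt(diff(range(d)), 1e-4)
})

test_that("landmark trajectories transform equivariantly with the poses", {
  fx <- gait_fixture(seed = 2, N = 60, sta_amplitude = 0)
  move <- planar_pose(c(0.3, 1.2), -0.6)
  moved_poses <- lapply(fx$poses, function(ps)
    compose_pose(pose_series(matrix(rep(move$o, each = 60), 60, 2),
                             rep(move$ang, 60)), ps))
  lm2 <- landmark_trajectories(moved_poses, fx$topology, fx$grid)
  for (mk in names(lm2$m))
    expect_equal_mat(lm2$m[[mk]], to_global(move, fx$landmarks$m[[mk]]), 1e-10)
})

test_that("synthetic ground reaction forces are periodic, swing-silent and
           weight-consistent", {
  fx <- gait_fixture(seed = 1, N = 200, sta_amplitude = 0)
  grf <- fx$grf
  expect_equal(max(abs(grf$left$force[!grf$left$stance, ])), 0)
  expect_equal(max(abs(grf$right$force[!grf$right$stance, ])), 0)
  total_v <- mean(grf$left$force[, 2] + grf$right$force[, 2])
  expect_equal(total_v, grf$weight, tolerance = 0.02 * grf$weight)
  expect_gte(min(grf$left$force[, 2]), 0)
  # seam continuity: stance starts at the cycle boundary with zero force
  expect_lt(abs(grf$left$force[200, 2] - grf$left$force[1, 2]),
            0.02 * grf$weight)
  expect_error(gait_grf(fx$grid, fx$params,
                        options = list(stance_fraction = 1.2)),
               "stance_fraction")
})

test_that("identical seeds give bit-identical fixtures", {
  f1 <- gait_fixture(seed = 11, N = 50, sta_amplitude = 0.01)
  f2 <- gait_fixture(seed = 11, N = 50, sta_amplitude = 0.01)
  expect_identical(f1$markers$m, f2$markers$m)
  expect_identical(f1$profiles, f2$profiles)
  expect_length(subject_seeds(1), 7)
  expect_true(all(subject_seeds(3) == 300 + 1:7))
})
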