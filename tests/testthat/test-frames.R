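test_that("pair frames follow the midpoint / marker-axis construction", {
  p <- pair_frame(c(1, 1), c(3, 1))
  expect_equal(p$o, c(2, 1))
  expect_equal_mat(p$R, diag(2))
  p2 <- pair_frame(c(0, 0), c(0, 2))          # 90 degree CCW frame
  expect_equal(p2$o, c(0, 1))
  expect_equal_mat(p2$R, matrix(c(0, 1, -1, 0), 2, 2))
  expect_error(pair_frame(c(1, 1), c(1, 1)), "coincident")
})

test_that("pair frames are always proper rotations", {
  set.seed(4)
  for (i in 1:25) {
    p <- pair_frame(runif(2), runif(2) + 1.5)
    expect_lt(max(abs(crossprod(p$R) - diag(2))), 1e-12)
    expect_equal(det(p$R), 1, tolerance = 1e-12)
  }
})

test_that("local/global maps are exact inverses", {
  pose <- planar_pose(c(1, 0), pi / 2)
  expect_equal(to_global(pose, c(1, 0)), c(1, 1), tolerance = 1e-12)
  expect_equal(to_global(planar_pose(), c(0.2, 0)), c(0.2, 0))
  set.seed(5)
  for (i in 1:20) {
    ps <- random_pose()
    x <- runif(2, -2, 2)
    expect_equal(to_local(ps, to_global(ps, x)), x, tolerance = 1e-12)
  }
  # series forms agree with scalar forms
  grid <- cycle_grid(16)
  ser <- pose_series(matrix(rnorm(32), 16, 2), runif(16, -pi, pi))
  pts <- matrix(rnorm(32), 16, 2)
  g <- to_global(ser, pts)
  for (n in c(1, 7, 16))
    expect_equal(g[n, ], to_global(stafree:::pose_at(ser, n), pts[n, ]),
                 tolerance = 1e-12)
  expect_equal_mat(to_local(ser, g), pts, 1e-12)
})

test_that("pose composition and factorisation round trip", {
  expect_equal(compose_pose(planar_pose(), random_pose())$o,
               compose_pose(planar_pose(), random_pose())$o,
               tolerance = 2)                  # smoke: callable
  set.seed(6)
  for (i in 1:20) {
    parent <- random_pose(); child <- random_pose()
    rel <- relative_pose(child, parent)
    back <- compose_pose(parent, rel)
    expect_equal(back$o, child$o, tolerance = 1e-12)
    expect_equal_mat(back$R, child$R, 1e-12)
  }
  p <- random_pose()
  rel <- relative_pose(p, p)
  expect_equal(rel$o, c(0, 0), tolerance = 1e-12)
  expect_equal_mat(rel$R, diag(2), 1e-12)
})

test_that("two-instant joint solve recovers hinge locals exactly", {
  fx <- two_link_fixture(N = 48)
  sol <- solve_joint_two_instants(fx$poses$A, fx$poses$B, 5, 20)
  expect_equal(sol$j_a, fx$poses$j_a, tolerance = 1e-10)
  expect_equal(sol$j_b, fx$poses$j_b, tolerance = 1e-10)
  # identical relative rotation at the two instants is degenerate
  same <- pose_series(matrix(rnorm(20), 10, 2), rep(0.3, 10))
  other <- pose_series(matrix(rnorm(20), 10, 2), rep(-0.1, 10))
  expect_error(solve_joint_two_instants(same, other, 2, 9), "degenerate")
  # frames built so both links predict a common global joint at two instants
  g <- c(0.4, -0.2)
  ja <- c(0.15, -0.05); jb <- c(-0.1, 0.3)
  loc_min_g <- function(ang, j) t(vapply(ang, function(a)
    g - as.numeric(rot2(a) %*% j), numeric(2)))
  fa2 <- pose_series(loc_min_g(c(0, 0.5), ja), c(0, 0.5))
  fb2 <- pose_series(loc_min_g(c(0.2, -0.4), jb), c(0.2, -0.4))
  sol2 <- solve_joint_two_instants(fa2, fb2, 1, 2)
  expect_equal(sol2$j_a, ja, tolerance = 1e-10)
  expect_equal(sol2$j_b, jb, tolerance = 1e-10)
})

test_that("joint residuals match a brute-force recomputation", {
  fx <- two_link_fixture(N = 32)
  j_a <- c(0.22, 0.05); j_b <- c(-0.18, -0.02)
  r <- joint_residual(fx$poses$A, fx$poses$B, j_a, j_b)
  for (n in c(1, 9, 32)) {
    pa <- stafree:::pose_at(fx$poses$A, n)
    pb <- stafree:::pose_at(fx$poses$B, n)
    expect_equal(r$residual[n, ],
                 to_global(pa, j_a) - to_global(pb, j_b), tolerance = 1e-12)
  }
  expect_equal(r$sum_norm, sum(sqrt(rowSums(r$residual^2))))
  # true locals close the hinge exactly
  r0 <- joint_residual(fx$poses$A, fx$poses$B, fx$poses$j_a, fx$poses$j_b)
  expect_lt(r0$sum_norm, 1e-10)
  # identity rotations: shifting one local by delta gives a constant residual
  ida <- pose_series(matrix(0, 8, 2), rep(0, 8))
  idb <- pose_series(matrix(0, 8, 2), rep(0, 8))
  rd <- joint_residual(ida, idb, c(0.3, -0.1), c(0, 0))
  expect_equal_mat(rd$residual, matrix(rep(c(0.3, -0.1), each = 8), 8, 2))
})

test_that("all-samples joint solve agrees with the two-instant solve on rigid data", {
  fx <- two_link_fixture(N = 40)
  lsq <- solve_joint_lsq(fx$poses$A, fx$poses$B)
  expect_equal(lsq$j_a, fx$poses$j_a, tolerance = 1e-9)
  expect_equal(lsq$j_b, fx$poses$j_b, tolerance = 1e-9)
  expect_lt(lsq$cost, 1e-18)
})

test_that("frame constructions are equivariant under global rigid motion", {
  fx <- two_link_fixture(N = 36, K = 2, amplitude = 0.01, seed = 3)
  move <- planar_pose(c(2.5, -1), 1.1)
  moved <- transform_markers(fx$markers, move)
  f1 <- marker_frames(fx$markers, fx$topology)
  f2 <- marker_frames(moved, fx$topology)
  for (l in c("A", "B")) {
    expect_equal_mat(f2[[l]]$o, to_global(move, f1[[l]]$o), 1e-10)
    d <- (f2[[l]]$ang - f1[[l]]$ang - move$ang) %% (2 * pi)
    expect_lt(max(pmin(d, 2 * pi - d)), 1e-10)
  }
  # joint residual of given locals is invariant
  r1 <- joint_residual(f1$A, f1$B, c(0.25, 0), c(-0.2, 0))
  r2 <- joint_residual(f2$A, f2$B, c(0.25, 0), c(-0.2, 0))
  expect_equal(r1$sum_norm, r2$sum_norm, tolerance = 1e-10)
})

test_that("joint angle conventions: clockwise positive, zero at reference", {
  grid <- cycle_grid(8)
  topo <- two_link_topology()
  aligned <- list(A = pose_series(matrix(0, 8, 2), rep(0, 8)),
                  B = pose_series(matrix(1, 8, 2), rep(0, 8)))
  ang <- joint_angles(aligned, topo)
  expect_equal(ang$root, rep(0, 8))
  expect_equal(ang$joint$J, rep(0, 8))
  # distal rotated -0.3 rad (clockwise) => joint angle +0.3
  cw <- list(A = aligned$A,
             B = pose_series(matrix(1, 8, 2), rep(-0.3, 8)))
  expect_equal(joint_angles(cw, topo)$joint$J, rep(0.3, 8))
  # consistency: recomposing rotations from the angles reproduces the poses
  fx <- two_link_fixture(N = 32)
  ja <- joint_angles(list(A = fx$poses$A, B = fx$poses$B), topo)
  rebuilt_b <- fx$poses$A$ang - ja$joint$J
  d <- (rebuilt_b - fx$poses$B$ang) %% (2 * pi)
  expect_lt(max(pmin(d, 2 * pi - d)), 1e-12)
})

test_that("angle unwrapping is continuous around the cycle", {
  u <- seq(0, 2 * pi, length.out = 100)
  wrapped <- atan2(sin(3 * u), cos(3 * u))
  un <- unwrap_angle(wrapped)
  expect_lt(max(abs(diff(un))), pi)
  expect_equal(un, un[1] + (3 * u - 3 * u[1]), tolerance = 1e-12)
})
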