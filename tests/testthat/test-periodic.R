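make_d2_markers <- function(dser, grid) {
  # one marker pinned at the origin, the other on the x-axis at distance d[n]
  list(m1 = matrix(0, grid$N, 2), m2 = cbind(dser, 0))
}

test_that("distance spectrum: constant distance has no harmonics", {
  grid <- cycle_grid(60)
  mk <- make_d2_markers(rep(0.35, 60), grid)
  sp <- distance_sq_spectrum(mk$m1, mk$m2, grid, K = 4)
  expect_equal(sp$gamma, 0.35^2, tolerance = 1e-12)
  expect_lt(max(abs(c(sp$alpha, sp$beta))), 1e-12)
  expect_error(distance_sq_spectrum(mk$m1, mk$m2, cycle_grid(30), K = 4),
               "8K")
})

test_that("distance spectrum matches the hand-derived single-harmonic case", {
  # d[n] = d + eps cos(u): d^2 series is d^2 + eps^2/2 + 2 d eps cos
  # + (eps^2/2) cos 2u, from squaring and product-to-sum
  grid <- cycle_grid(80)
  d <- 0.4; eps <- 0.03
  mk <- make_d2_markers(d + eps * cos(grid$phase), grid)
  sp <- distance_sq_spectrum(mk$m1, mk$m2, grid, K = 2)
  expect_equal(sp$gamma, d^2 + eps^2 / 2, tolerance = 1e-12)
  expect_equal(sp$alpha, c(2 * d * eps, eps^2 / 2, 0, 0), tolerance = 1e-12)
  expect_lt(max(abs(sp$beta)), 1e-12)
})

test_that("distance spectrum agrees with an explicit DFT oracle", {
  fx <- two_link_fixture(N = 64, K = 2, amplitude = 0.01, seed = 9)
  mk <- stafree:::link_markers(fx$markers, "A")
  sp <- distance_sq_spectrum(mk$m1, mk$m2, fx$grid, K = 2)
  d2 <- rowSums((mk$m2 - mk$m1)^2)
  n <- seq_len(64)
  for (k in 1:4) {   # independent trigonometric sums
    expect_equal(sp$alpha[k], 2 * mean(d2 * cos(2 * pi * k * n / 64)),
                 tolerance = 1e-12)
    expect_equal(sp$beta[k], 2 * mean(d2 * sin(2 * pi * k * n / 64)),
                 tolerance = 1e-12)
  }
  expect_equal(sp$gamma, mean(d2), tolerance = 1e-12)
})

test_that("shape residual is zero at the generating parameters and has
           length 4K+1", {
  set.seed(10)
  grid <- cycle_grid(120)
  K <- 4
  C <- 0.3
  xi_x <- runif(2 * K, -1, 1) * 0.02 / rep(1:K, 2)
  xi_y <- runif(2 * K, -1, 1) * 0.02 / rep(1:K, 2)
  B <- fourier_basis(grid, K)
  d <- sqrt((C + B %*% xi_x)^2 + (B %*% xi_y)^2)
  mk <- make_d2_markers(as.numeric(d), grid)
  sp <- distance_sq_spectrum(mk$m1, mk$m2, grid, K)
  r <- shape_residual(c(C, xi_x, xi_y), sp, grid)
  expect_length(r, 17)                      # 4K + 1 equations for K = 4
  expect_lt(max(abs(r)), 1e-12)
  expect_gt(max(abs(shape_residual(c(C * 1.01, xi_x, xi_y), sp, grid))), 1e-5)
})

test_that("shape residual matches a symbolic product-to-sum expansion (K=1)", {
  # (C + a cos + b sin)^2 + (a2 cos + b2 sin)^2 expands to
  #   C^2 + (a^2+b^2+a2^2+b2^2)/2
  # + 2Ca cos + 2Cb sin + ((a^2-b^2+a2^2-b2^2)/2) cos2 + (ab + a2 b2) sin2
  grid <- cycle_grid(50)
  par_d <- c(0.25, 0.02, -0.015, 0.01, 0.006)   # data-generating parameters
  par_m <- c(0.26, 0.018, -0.01, 0.012, 0.004)  # model parameters
  spec_of <- function(p)
    c(p[1]^2 + sum(p[2:5]^2) / 2,
      2 * p[1] * p[2], (p[2]^2 - p[3]^2 + p[4]^2 - p[5]^2) / 2,
      2 * p[1] * p[3], p[2] * p[3] + p[4] * p[5])
  B <- fourier_basis(grid, 1)
  d <- sqrt((par_d[1] + B %*% par_d[2:3])^2 + (B %*% par_d[4:5])^2)
  mk <- make_d2_markers(as.numeric(d), grid)
  sp <- distance_sq_spectrum(mk$m1, mk$m2, grid, K = 1)
  r <- shape_residual(par_m, sp, grid)
  sym <- spec_of(par_m) - spec_of(par_d)
  # residual layout: gamma, alpha_1, alpha_2, beta_1, beta_2
  expect_equal(r, sym[c(1, 2, 3, 4, 5)], tolerance = 1e-12)
})

test_that("shape solve recovers generating parameters; xi_y up to sign", {
  set.seed(12)
  grid <- cycle_grid(100)
  for (K in c(1, 2)) {
    C <- 0.32
    xi_x <- runif(2 * K, -1, 1) * 0.015 / rep(1:K, 2)
    xi_y <- runif(2 * K, -1, 1) * 0.015 / rep(1:K, 2)
    B <- fourier_basis(grid, K)
    d <- sqrt((C + B %*% xi_x)^2 + (B %*% xi_y)^2)
    mk <- make_d2_markers(as.numeric(d), grid)
    sp <- distance_sq_spectrum(mk$m1, mk$m2, grid, K)
    sol <- solve_shape(sp, list(C = mean(d), xi_x = xi_x * 0.8,
                                xi_y = rep(0, 2 * K)), grid)
    expect_equal(sol$C, C, tolerance = 1e-8)
    expect_equal(sol$xi_x, xi_x, tolerance = 1e-7)
    expect_lt(min(sqrt(sum((sol$xi_y - xi_y)^2)),
                  sqrt(sum((sol$xi_y + xi_y)^2))), 1e-7)
  }
})

test_that("zero artifact yields C = marker distance and xi = 0", {
  fx <- two_link_fixture(N = 48, amplitude = 0)
  mk <- stafree:::link_markers(fx$markers, "A")
  sp <- distance_sq_spectrum(mk$m1, mk$m2, fx$grid, K = 2)
  sol <- solve_shape(sp, list(C = 0.3, xi_x = rep(0, 4), xi_y = rep(0, 4)),
                     fx$grid)
  expect_equal(sol$C, 0.3, tolerance = 1e-10)
  expect_lt(max(abs(c(sol$xi_x, sol$xi_y))), 1e-10)
})

test_that("a bad initialisation is never silently wrong", {
  set.seed(13)
  grid <- cycle_grid(100)
  K <- 2
  C <- 0.3
  xi_x <- runif(2 * K, -1, 1) * 0.02 / rep(1:K, 2)
  xi_y <- runif(2 * K, -1, 1) * 0.02 / rep(1:K, 2)
  B <- fourier_basis(grid, K)
  d <- sqrt((C + B %*% xi_x)^2 + (B %*% xi_y)^2)
  mk <- make_d2_markers(as.numeric(d), grid)
  sp <- distance_sq_spectrum(mk$m1, mk$m2, grid, K)
  res <- tryCatch(
    solve_shape(sp, list(C = 40, xi_x = rep(0.5, 4), xi_y = rep(-0.4, 4)),
                grid),
    error = function(e) e)
  if (!inherits(res, "error")) {
    # if it converged anyway, the root must genuinely satisfy the identity
    expect_lt(max(abs(shape_residual(c(res$C, res$xi_x, res$xi_y), sp, grid))),
              1e-9 * sp$gamma)
  } else {
    expect_match(conditionMessage(res), "init|root")
  }
})

test_that("the distance identity is blind to the xi_y sign and to (C, xi_x)
           negation, and enumeration recovers the generating root", {
  set.seed(14)
  grid <- cycle_grid(100)
  K <- 2
  C <- 0.28
  xi_x <- runif(2 * K, -1, 1) * 0.02 / rep(1:K, 2)
  xi_y <- runif(2 * K, -1, 1) * 0.02 / rep(1:K, 2)
  B <- fourier_basis(grid, K)
  ser <- function(C, xx, xy) (C + B %*% xx)^2 + (B %*% xy)^2
  expect_equal_mat(ser(C, xi_x, xi_y), ser(C, xi_x, -xi_y), 1e-14)
  expect_equal_mat(ser(C, xi_x, xi_y), ser(-C, -xi_x, xi_y), 1e-14)
  d <- sqrt(ser(C, xi_x, xi_y))
  mk <- make_d2_markers(as.numeric(d), grid)
  sp <- distance_sq_spectrum(mk$m1, mk$m2, grid, K)
  cands <- enumerate_shape_roots(sp, grid)
  expect_gt(length(cands), 1)           # spurious roots exist
  errs <- vapply(cands, function(cd)
    abs(cd$C - C) + sqrt(sum((cd$xi_x - xi_x)^2)) +
      min(sqrt(sum((cd$xi_y - xi_y)^2)), sqrt(sum((cd$xi_y + xi_y)^2))), 0)
  expect_lt(min(errs), 1e-9)            # generating root is among them
  for (cd in cands) {                   # and each one is a genuine root
    expect_lt(max(abs(shape_residual(c(cd$C, cd$xi_x, cd$xi_y), sp, grid))),
              1e-8 * sp$gamma)
    expect_gt(cd$C, 0)
  }
})

test_that("marker-frame pose within the landmark frame follows the closed
           form, including the small-angle limit", {
  grid <- cycle_grid(60)
  K <- 2
  # zero coefficient difference: no tilt, origin excursion = P q
  q <- sta_coeffs(c(0.01, 0, 0.004, 0), c(0, 0.006, 0, 0))
  par0 <- shape_params(0.3, rep(0, 4), rep(1e-300, 4))
  ps <- marker_frame_in_landmark(par0, q, grid)
  expect_lt(max(abs(ps$ang)), 1e-12)
  B <- fourier_basis(grid, K)
  expect_equal_mat(ps$o, cbind(B %*% q$qx, B %*% q$qy), 1e-12)
  # single small sine in xi_y: theta ~ (eps/C) sin(u) to O(eps^2)
  eps <- 1e-4; C <- 0.3
  par1 <- shape_params(C, rep(0, 4), c(0, 0, eps, 0))
  th <- stafree:::shape_tilt(par1, grid)
  expect_lt(max(abs(th - (eps / C) * sin(grid$phase))), (eps / C)^2 * 2)
  # rotations stay proper, markers crossing is rejected
  expect_error(
    marker_frame_in_landmark(shape_params(0.01, c(0.02, 0, 0, 0), rep(0, 4)),
                             q, grid),
    "cross")
})

test_that("the linear stage recovers coefficients and locals built forward,
           and is exact-zero for clean data", {
  fx <- two_link_fixture(N = 64, K = 2, amplitude = 0.008, seed = 21)
  fit <- sta_assimilate(fx$markers, fx$topology, method = "periodic", K = 2)
  co <- coef(fit)
  for (mk in names(fx$profiles)) {
    expect_equal(unname(co[mk, 1:4]), fx$profiles[[mk]]$qx, tolerance = 1e-7)
    expect_equal(unname(co[mk, 5:8]), fx$profiles[[mk]]$qy, tolerance = 1e-7)
  }
  # locals match the rigid-truth joint position in the landmark frame
  la <- to_local(stafree:::pose_at(fx$lm_frames$A, 1),
                 fx$poses$joint[1, ])
  expect_equal(fit$locals$J$A, la, tolerance = 1e-7)
  # clean data: all coefficients vanish, locals equal the two-instant solve
  fx0 <- two_link_fixture(N = 64, amplitude = 0)
  fit0 <- sta_assimilate(fx0$markers, fx0$topology, method = "periodic", K = 2)
  expect_lt(max(abs(coef(fit0))), 1e-9)
  two <- solve_joint_two_instants(fx0$lm_frames$A, fx0$lm_frames$B, 4, 22)
  expect_equal(fit0$locals$J$A, two$j_a, tolerance = 1e-8)
  expect_equal(fit0$locals$J$B, two$j_b, tolerance = 1e-8)
})

test_that("reconstruction invariants: markers reproduced, constant recovered
           distance, artifact-free output on clean input", {
  fx <- two_link_fixture(N = 64, K = 2, amplitude = 0.008, seed = 22)
  fit <- sta_assimilate(fx$markers, fx$topology, method = "periodic", K = 2)
  # recovered landmark markers: inter-marker distance constant = C
  lm <- fitted(fit)
  for (l in c("A", "B")) {
    d <- sqrt(rowSums((lm$m[[paste0(l, "2")]] - lm$m[[paste0(l, "1")]])^2))
    expect_lt(diff(range(d)), 1e-9)
    expect_equal(mean(d), fit$shapes[[l]]$C, tolerance = 1e-9)
  }
  # recovered landmark markers match the clean fixture markers
  for (mk in names(fx$landmarks$m))
    expect_equal_mat(lm$m[[mk]], fx$landmarks$m[[mk]], 1e-7)
  # clean input: output markers equal input markers exactly
  fx0 <- two_link_fixture(N = 64, amplitude = 0)
  fit0 <- sta_assimilate(fx0$markers, fx0$topology, method = "periodic", K = 2)
  for (mk in names(fx0$markers$m))
    expect_equal_mat(fitted(fit0)$m[[mk]], fx0$markers$m[[mk]], 1e-9)
})

test_that("running the pipeline on its own corrected output finds no
           artifact (idempotence)", {
  fx <- two_link_fixture(N = 64, K = 2, amplitude = 0.008, seed = 23)
  fit <- sta_assimilate(fx$markers, fx$topology, method = "periodic", K = 2)
  fit2 <- sta_assimilate(fitted(fit), fx$topology, method = "periodic", K = 2)
  expect_lt(max(abs(coef(fit2))), 1e-7)
})

test_that("the proposed solution's joint cost never exceeds the baseline's", {
  fx <- two_link_fixture(N = 64, K = 2, amplitude = 0.01, seed = 24)
  fitp <- sta_assimilate(fx$markers, fx$topology, method = "periodic", K = 2)
  fitn <- sta_assimilate(fx$markers, fx$topology, method = "naive")
  expect_lte(fitp$solver$cost_norm, fitn$solver$cost_norm + 1e-12)
})

test_that("the full pipeline is equivariant under global rigid motion", {
  fx <- two_link_fixture(N = 64, K = 2, amplitude = 0.008, seed = 25)
  move <- planar_pose(c(1.5, -0.8), 0.9)
  fit1 <- sta_assimilate(fx$markers, fx$topology, method = "periodic", K = 2)
  fit2 <- sta_assimilate(transform_markers(fx$markers, move), fx$topology,
                         method = "periodic", K = 2)
  expect_equal_mat(fit2$joints$J, to_global(move, fit1$joints$J), 1e-8)
  expect_equal(fit2$angles$joint$J, fit1$angles$joint$J, tolerance = 1e-8)
  expect_equal(coef(fit2), coef(fit1), tolerance = 1e-7)
})
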