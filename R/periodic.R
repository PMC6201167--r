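#' Fourier spectrum of the squared inter-marker distance
#'
#' The squared distance between a link's two captured markers is independent
#' of the coordinate system and, under periodic artifact, is band-limited to
#' twice the artifact order (squaring doubles the bandwidth). It is fitted
#' with a constant term at order `2K`, giving the data side of the shape
#' identification: `gamma + sum_k alpha_k cos + beta_k sin`, `k = 1..2K`.
#'
#' @param m1,m2 `N x 2` global marker trajectories of one link.
#' @param grid a [cycle_grid()].
#' @param K artifact expansion order (the fit is at order `2K`; requires
#'   `N >= 8K + 2`).
#' @return object of class `"dist_spectrum"`: list with `K`, `gamma`,
#'   `alpha` (length `2K`), `beta` (length `2K`).
#' @export
distance_sq_spectrum <- function(m1, m2, grid, K) {
  if (grid$N < 8 * K + 2)
    stop("distance_sq_spectrum: need N >= 8K + 2 samples for order-2K fit")
  d2 <- rowSums((m2 - m1)^2)
  f <- fourier_fit(d2, grid, 2 * K, dc = TRUE)
  structure(list(K = K, gamma = f$dc, alpha = f$coef[1:(2 * K), 1],
                 beta = f$coef[(2 * K + 1):(4 * K), 1]),
            class = "dist_spectrum")
}

#' Shape parameters of one link
#'
#' The inter-landmark distance `C` and the coefficient differences
#' `xi_x = q2_x - q1_x`, `xi_y = q2_y - q1_y` between the two markers' STA
#' expansions, which together determine the squared inter-marker distance
#' `(C + P xi_x)^2 + (P xi_y)^2` and the tilt of the marker frame relative to
#' the landmark frame.
#'
#' @param C inter-landmark distance, meters, positive.
#' @param xi_x,xi_y length-`2K` coefficient difference vectors, meters.
#' @param diagnostics optional list (solver report).
#' @return object of class `"shape_params"`.
#' @export
shape_params <- function(C, xi_x, xi_y, diagnostics = NULL) {
  if (length(xi_x) != length(xi_y) || length(xi_x) %% 2 != 0)
    stop("shape_params: xi_x and xi_y must have equal, even length (2K)")
  if (C <= 0) stop("shape_params: C must be positive")
  structure(list(C = C, xi_x = as.numeric(xi_x), xi_y = as.numeric(xi_y),
                 K = length(xi_x) / 2, diagnostics = diagnostics),
            class = "shape_params")
}

#' @export
print.shape_params <- function(x, ...) {
  cat(sprintf("<shape_params> C = %.6g m, K = %d, |xi_x| = %.3g, |xi_y| = %.3g\n",
              x$C, x$K, sqrt(sum(x$xi_x^2)), sqrt(sum(x$xi_y^2))))
  invisible(x)
}

#' Residual of the term-wise distance-spectrum identity
#'
#' Evaluates the model series `(C + P[n] xi_x)^2 + (P[n] xi_y)^2` on the grid,
#' Fourier-fits it with a constant at order `2K` (numerically realising the
#' product-to-sum expansion of the squared series), and returns the
#' model-minus-data coefficient differences `[gamma; alpha_1..2K;
#' beta_1..2K]` - exactly `4K + 1` components. A root of this map identifies
#' the link's shape parameters.
#'
#' @param par numeric vector `c(C, xi_x, xi_y)` of length `4K + 1`.
#' @param spectrum a [distance_sq_spectrum()] result.
#' @param grid a [cycle_grid()].
#' @return numeric residual vector of length `4K + 1` (m^2).
#' @export
shape_residual <- function(par, spectrum, grid) {
  K <- spectrum$K
  C <- par[1]
  xi_x <- par[2:(2 * K + 1)]
  xi_y <- par[(2 * K + 2):(4 * K + 1)]
  B <- fourier_basis(grid, K)
  s <- (C + B %*% xi_x)^2 + (B %*% xi_y)^2
  f <- fourier_fit(s, grid, 2 * K, dc = TRUE)
  c(f$dc - spectrum$gamma,
    f$coef[1:(2 * K), 1] - spectrum$alpha,
    f$coef[(2 * K + 1):(4 * K), 1] - spectrum$beta)
}

# Deterministic warm start for xi_y: with xi_y = 0 the residual map is at a
# singular point (xi_y enters only quadratically), so a Newton-family solver
# cannot leave it. The unexplained constant power p of the spectrum at the
# (C, xi_x)-only fit satisfies p ~ |xi_y|^2 / 2; seed xi_y flat at that norm.
warm_start_xi_y <- function(C, xi_x, spectrum) {
  p <- spectrum$gamma - (C^2 + sum(xi_x^2) / 2)
  nrm <- sqrt(2 * max(p, 0))
  rep(nrm / sqrt(length(xi_x)), length(xi_x))
}

#' Solve the 4K+1 quadratic shape system for one link
#'
#' Root-finds [shape_residual()] by Levenberg-Marquardt, starting from the
#' baseline initialisation (mean distance and marker-frame x residual fit).
#' The `(-C, -xi_x)` gauge copy is removed by reflecting to `C > 0`; the
#' remaining `xi_y -> -xi_y` sign branch leaves the distance invariant and is
#' resolved later by the joint-constraint cost, so the returned `xi_y` is in a
#' canonical branch (first component of largest magnitude positive).
#'
#' @param spectrum a [distance_sq_spectrum()] result.
#' @param init list with `C`, `xi_x`, `xi_y` (from [naive_sta_init()]).
#' @param grid a [cycle_grid()].
#' @param tol residual tolerance relative to `gamma` (m^2).
#' @param maxit maximum Levenberg-Marquardt iterations.
#' @return a [shape_params()] with solver diagnostics (residual norm,
#'   iterations, convergence message, warm-start norm).
#' @export
solve_shape <- function(spectrum, init, grid, tol = 1e-9, maxit = 200) {
  K <- spectrum$K
  if (init$C <= 0) stop("solve_shape: initial C must be positive")
  xi_y0 <- init$xi_y
  r0 <- shape_residual(c(init$C, init$xi_x, rep(0, 2 * K)), spectrum, grid)
  if (sqrt(sum(r0^2)) <= tol * max(spectrum$gamma, .Machine$double.eps)) {
    # the identity already holds with xi_y = 0: keep the parsimonious root
    # (a Newton step from floor-level residual would otherwise inflate tiny
    # spectrum noise into sqrt-scale xi_y components)
    pats <- list(rep(0, 2 * K))
  } else {
    if (sqrt(sum(xi_y0^2)) < 1e-12)
      xi_y0 <- warm_start_xi_y(init$C, init$xi_x, spectrum)
    # alternate warm-start sign patterns, tried in turn if the first run fails
    pats <- list(xi_y0, -xi_y0,
                 xi_y0 * rep(c(1, -1), length.out = 2 * K),
                 c(xi_y0[1:K], -xi_y0[(K + 1):(2 * K)]))
  }
  best <- NULL
  for (xi_y_try in pats) {
    fit <- minpack.lm::nls.lm(
      par = c(init$C, init$xi_x, xi_y_try),
      fn = shape_residual, spectrum = spectrum, grid = grid,
      control = minpack.lm::nls.lm.control(maxiter = maxit, ftol = 1e-15,
                                           ptol = 1e-15, gtol = 0))
    rn <- sqrt(sum(fit$fvec^2))
    if (is.null(best) || rn < best$rn) best <- list(fit = fit, rn = rn)
    if (rn <= tol * max(spectrum$gamma, .Machine$double.eps)) break
  }
  fit <- best$fit
  par <- fit$par
  C <- par[1]; xi_x <- par[2:(2 * K + 1)]; xi_y <- par[(2 * K + 2):(4 * K + 1)]
  if (C < 0) { C <- -C; xi_x <- -xi_x }          # gauge reflection
  if (C <= 0)
    stop("solve_shape: degenerate solution with C = 0")
  if (best$rn > tol * max(spectrum$gamma, .Machine$double.eps))
    stop(sprintf(paste0("solve_shape: no root found (residual %.3g m^2 vs ",
                        "tolerance %.3g); the initialisation may be in a ",
                        "spurious basin - supply a different init"),
                 best$rn, tol * spectrum$gamma))
  lead <- which.max(abs(xi_y))
  flipped <- length(xi_y) > 0 && xi_y[lead] < 0
  if (flipped) xi_y <- -xi_y                      # canonical sign branch
  shape_params(C, xi_x, xi_y,
               diagnostics = list(residual_norm = best$rn,
                                  iterations = fit$niter,
                                  message = fit$message,
                                  canonical_flip = flipped))
}

#' Marker-frame excursion and tilt within the landmark frame
#'
#' From the shape parameters and the first marker's STA coefficients, the
#' marker-coordinate system's pose relative to the (unknown) landmark frame
#' follows in closed form: tilt `theta[n] = atan2(P xi_y, C + P xi_x)`
#' (two-argument form, branch-safe) and origin excursion
#' `o[n] = (P (q1 + q2)_x, P (q1 + q2)_y) / 2`.
#'
#' @param params a [shape_params()].
#' @param q1 the first marker's [sta_coeffs()].
#' @param grid a [cycle_grid()].
#' @return a [pose_series()] (origin in meters, angle in radians), plus
#'   attribute `"q2"` with the second marker's implied coefficients.
#' @export
marker_frame_in_landmark <- function(params, q1, grid) {
  B <- fourier_basis(grid, params$K)
  cx <- params$C + B %*% params$xi_x
  if (any(cx <= 0))
    stop("marker_frame_in_landmark: markers cross (C + P xi_x <= 0); geometry degenerate")
  theta <- atan2(B %*% params$xi_y, cx)
  q2 <- sta_coeffs(q1$qx + params$xi_x, q1$qy + params$xi_y)
  o <- cbind(B %*% (q1$qx + q2$qx), B %*% (q1$qy + q2$qy)) / 2
  ps <- pose_series(o, theta)
  attr(ps, "q2") <- q2
  ps
}

# Tilt series alone (does not need q1): theta[n] = atan2(P xi_y, C + P xi_x).
shape_tilt <- function(params, grid, sign_y = 1) {
  B <- fourier_basis(grid, params$K)
  cx <- params$C + B %*% params$xi_x
  if (any(cx <= 0))
    stop("shape_tilt: markers cross (C + P xi_x <= 0); geometry degenerate")
  as.numeric(atan2(sign_y * (B %*% params$xi_y), cx))
}

# Per-link building blocks of the linear joint-constraint system, for one
# sign assignment of xi_y: the 2N x 4K coefficient block (rotated Fourier
# basis), the 2N x 2 local-joint block (landmark-frame rotation), the marker
# frame origins and the known xi contribution, rows x/y interleaved.
link_block <- function(frame, shape, sign_y, P, grid) {
  K <- shape$K; N <- grid$N
  tilt <- shape_tilt(shape, grid, sign_y)
  ang <- frame$ang - tilt
  ca <- cos(ang); sa <- sin(ang)
  odd <- seq(1, 2 * N, by = 2)
  Bq <- matrix(0, 2 * N, 4 * K)
  Bq[odd, 1:(2 * K)] <- P * ca
  Bq[odd, (2 * K + 1):(4 * K)] <- -P * sa
  Bq[odd + 1, 1:(2 * K)] <- P * sa
  Bq[odd + 1, (2 * K + 1):(4 * K)] <- P * ca
  Lb <- matrix(0, 2 * N, 2)
  Lb[odd, ] <- cbind(ca, -sa)
  Lb[odd + 1, ] <- cbind(sa, ca)
  ovec <- numeric(2 * N)
  ovec[odd] <- frame$o[, 1]
  ovec[odd + 1] <- frame$o[, 2]
  xi <- c(shape$xi_x, sign_y * shape$xi_y)
  list(Bq = Bq, Lb = Lb, o = ovec, Bxi = as.numeric(Bq %*% xi), ang = ang)
}

# Least-squares cost of a single joint's sub-system with both adjacent links'
# coefficients and the joint locals free: zero (to round-off) exactly when
# both links' shape parameters are consistent with the rigid pin joint.
pair_joint_cost <- function(block_a, block_b) {
  M <- cbind(-block_a$Bq, block_b$Bq, block_a$Lb, -block_b$Lb)
  rhs <- -block_a$o + block_a$Bxi / 2 + block_b$o - block_b$Bxi / 2
  fit <- stats::lm.fit(M, rhs)
  sum(fit$residuals^2)
}

# Build and solve the global linear joint-constraint system for given per-link
# xi_y sign assignments. Unknowns: per link the first marker's coefficients
# (2K for x, 2K for y), then per joint the two adjacent links' constant local
# joint positions (2 + 2). Rows: 2 per joint per sample.
assemble_system <- function(markers, topology, shapes, grid, signs,
                            rank_tol = 1e-10) {
  K <- shapes[[1]]$K
  L <- length(topology$links)
  J <- nrow(topology$joints)
  N <- grid$N
  P <- fourier_basis(grid, K)
  frames <- marker_frames(markers, topology)
  blocks <- lapply(topology$links, function(l)
    link_block(frames[[l]], shapes[[l]], signs[[l]], P, grid))
  names(blocks) <- topology$links
  ang_lm <- lapply(blocks, `[[`, "ang")
  ncols <- 4 * K * L + 4 * J
  qcol <- function(l) (match(l, topology$links) - 1) * 4 * K + seq_len(4 * K)
  lcol <- function(j, side) 4 * K * L + (j - 1) * 4 + (side - 1) * 2 + 1:2
  M <- matrix(0, 2 * N * J, ncols)
  rhs <- numeric(2 * N * J)
  for (j in seq_len(J)) {
    a <- topology$joints$proximal[j]; b <- topology$joints$distal[j]
    rows <- (j - 1) * 2 * N + seq_len(2 * N)
    M[rows, qcol(a)] <- -blocks[[a]]$Bq
    M[rows, qcol(b)] <- blocks[[b]]$Bq
    M[rows, lcol(j, 1)] <- blocks[[a]]$Lb
    M[rows, lcol(j, 2)] <- -blocks[[b]]$Lb
    rhs[rows] <- -blocks[[a]]$o + blocks[[a]]$Bxi / 2 +
      blocks[[b]]$o - blocks[[b]]$Bxi / 2
  }
  sv <- svd(M)
  rank <- sum(sv$d > rank_tol * sv$d[1])
  dinv <- ifelse(sv$d > rank_tol * sv$d[1], 1 / sv$d, 0)
  x <- sv$v %*% (dinv * crossprod(sv$u, rhs))   # minimum-norm solution
  res <- rhs - M %*% x
  rn <- sqrt(res[odd_all <- seq(1, length(res), 2)]^2 + res[odd_all + 1]^2)
  gap_rms <- vapply(seq_len(J), function(j)
    sqrt(sum(res[(j - 1) * 2 * N + seq_len(2 * N)]^2) / N), 0)
  names(gap_rms) <- topology$joints$joint
  q1 <- lapply(topology$links, function(l) {
    v <- x[qcol(l)]
    sta_coeffs(v[1:(2 * K)], v[(2 * K + 1):(4 * K)])
  })
  names(q1) <- topology$links
  locals <- list()
  for (j in seq_len(J)) {
    locals[[topology$joints$joint[j]]] <- stats::setNames(
      list(as.numeric(x[lcol(j, 1)]), as.numeric(x[lcol(j, 2)])),
      c(topology$joints$proximal[j], topology$joints$distal[j]))
  }
  list(q1 = q1, locals = locals, cost_sq = sum(res^2), cost_norm = sum(rn),
       gap_rms = gap_rms,
       rank = rank, ncols = ncols, null_dim = ncols - rank,
       cond = sv$d[1] / sv$d[max(rank, 1)],
       ang_lm = ang_lm, frames = frames, signs = signs)
}

#' Linear joint-constraint solve for STA coefficients and joint locals
#'
#' With each link's shape parameters known, the joint-constraint cost becomes
#' linear in the remaining unknowns: the first marker's STA coefficients per
#' link and the constant local joint positions per link-joint incidence. This
#' builds the single global least-squares system over all joints and samples
#' and returns its minimum-norm solution. The `xi_y` sign ambiguity of each
#' link (the distance spectrum cannot see the sign) is resolved greedily: each
#' link's branch is flipped in turn and kept when the final cost decreases.
#'
#' @param markers a [marker_set()] of captured markers.
#' @param topology a [linkage_topology()].
#' @param shapes named list of per-link [shape_params()].
#' @param grid a [cycle_grid()].
#' @param branch `"tree"` (default) propagates relative signs joint by joint
#'   from the root link via pair-cost comparison and resolves the remaining
#'   global two-fold branch by full-system cost; `"greedy"` flips one link at
#'   a time; `"fixed"` keeps the canonical branches as given.
#' @param rank_tol relative singular-value cutoff for the rank report.
#' @return list with per-link `q1` ([sta_coeffs()]), per-joint `locals`,
#'   per-link chosen `signs`, both cost readings (`cost_sq`, `cost_norm`),
#'   per-joint `gap_rms`, and `rank`/`null_dim`/`cond` diagnostics.
#' @export
assemble_solve <- function(markers, topology, shapes, grid,
                           branch = c("tree", "greedy", "fixed"),
                           rank_tol = 1e-10) {
  branch <- match.arg(branch)
  if (branch == "tree") {
    frames <- marker_frames(markers, topology)
    P <- fourier_basis(grid, shapes[[1]]$K)
    s1 <- resolve_signs(topology, shapes, frames, P, grid)
    sol <- assemble_system(markers, topology, shapes, grid, s1, rank_tol)
  } else {
    signs <- stats::setNames(as.list(rep(1, length(topology$links))),
                             topology$links)
    sol <- assemble_system(markers, topology, shapes, grid, signs, rank_tol)
    if (branch == "greedy") {
      for (l in topology$links) {
        if (sqrt(sum(shapes[[l]]$xi_y^2)) < 1e-14) next  # sign is moot
        alt <- signs; alt[[l]] <- -alt[[l]]
        cand <- assemble_system(markers, topology, shapes, grid, alt, rank_tol)
        if (cand$cost_sq < sol$cost_sq) { sol <- cand; signs <- alt }
      }
    }
  }
  if (sol$null_dim > 0)
    warning(sprintf("assemble_solve: rank-deficient system (null space dimension %d)",
                    sol$null_dim))
  sol
}

# Resolve each link's xi_y sign branch from the joint constraint. For every
# joint all four sign combinations of the two adjacent links are scored by
# the pair sub-system: only the pair of physical branches closes the joint
# exactly (the jointly mirrored pair is close but measurably inconsistent),
# so the arg-min identifies both links' branches at once. Each link takes
# the vote from its lowest-cost joint; links with negligible xi_y keep +1.
resolve_signs <- function(topology, shapes, frames, P, grid) {
  links <- topology$links
  blk <- list()
  for (l in links)
    blk[[l]] <- lapply(c(1, -1), function(s)
      link_block(frames[[l]], shapes[[l]], s, P, grid))
  vote_sign <- stats::setNames(rep(1, length(links)), links)
  vote_cost <- stats::setNames(rep(Inf, length(links)), links)
  for (i in seq_len(nrow(topology$joints))) {
    a <- topology$joints$proximal[i]; b <- topology$joints$distal[i]
    best <- Inf; besta <- 1; bestb <- 1
    for (ia in 1:2) for (ib in 1:2) {
      cost <- pair_joint_cost(blk[[a]][[ia]], blk[[b]][[ib]])
      if (cost < best) {
        best <- cost; besta <- c(1, -1)[ia]; bestb <- c(1, -1)[ib]
      }
    }
    if (best < vote_cost[a]) { vote_cost[a] <- best; vote_sign[a] <- besta }
    if (best < vote_cost[b]) { vote_cost[b] <- best; vote_sign[b] <- bestb }
  }
  out <- as.list(vote_sign)
  for (l in links) if (sqrt(sum(shapes[[l]]$xi_y^2)) < 1e-14) out[[l]] <- 1
  out
}

# Reconstruct the full artifact-free result from the solved pieces.
reconstruct_impl <- function(markers, topology, shapes, sol, grid) {
  K <- shapes[[1]]$K
  lm_frames <- list(); sta <- list(); landmark_markers <- list()
  joints_by_link <- list()
  for (l in topology$links) {
    s <- shapes[[l]]
    q1 <- sol$q1[[l]]
    q2 <- sta_coeffs(q1$qx + s$xi_x, q1$qy + sol$signs[[l]] * s$xi_y)
    sta[[paste0(l, "1")]] <- q1
    sta[[paste0(l, "2")]] <- q2
    B <- fourier_basis(grid, K)
    o_m <- cbind(B %*% (q1$qx + q2$qx), B %*% (q1$qy + q2$qy)) / 2
    lm <- pose_series(sol$frames[[l]]$o - cbind(
      cos(sol$ang_lm[[l]]) * o_m[, 1] - sin(sol$ang_lm[[l]]) * o_m[, 2],
      sin(sol$ang_lm[[l]]) * o_m[, 1] + cos(sol$ang_lm[[l]]) * o_m[, 2]),
      sol$ang_lm[[l]])
    lm_frames[[l]] <- lm
    landmark_markers[[paste0(l, "1")]] <- to_global(lm, c(-s$C / 2, 0))
    landmark_markers[[paste0(l, "2")]] <- to_global(lm, c(s$C / 2, 0))
  }
  joints <- list()
  for (j in seq_len(nrow(topology$joints))) {
    jt <- topology$joints[j, ]
    loc <- sol$locals[[jt$joint]]
    pa <- to_global(lm_frames[[jt$proximal]], loc[[jt$proximal]])
    pb <- to_global(lm_frames[[jt$distal]], loc[[jt$distal]])
    joints[[jt$joint]] <- (pa + pb) / 2
    joints_by_link[[jt$proximal]] <- c(joints_by_link[[jt$proximal]], jt$joint)
    joints_by_link[[jt$distal]] <- c(joints_by_link[[jt$distal]], jt$joint)
  }
  angles <- joint_angles(lm_frames, topology)
  lengths <- link_length_series(topology, lm_frames, joints)
  list(lm_frames = lm_frames, sta = sta, landmark_markers = landmark_markers,
       shapes = shapes, locals = sol$locals, joints = joints, angles = angles,
       lengths = lengths, signs = sol$signs,
       solver = list(cost_sq = sol$cost_sq, cost_norm = sol$cost_norm,
                     gap_rms = sol$gap_rms, rank = sol$rank,
                     null_dim = sol$null_dim, cond = sol$cond))
}

# Per-link length series: joint-to-joint distance for links spanning two
# distinct joints (thigh, shank); CoM-to-joint distance otherwise (feet, and
# the HAT, whose two hip joints coincide), when the topology carries the CoM
# landmark-frame position.
link_length_series <- function(topology, frames, joints) {
  out <- list()
  for (l in topology$links) {
    jn <- topology$joints$joint[topology$joints$proximal == l |
                                topology$joints$distal == l]
    if (length(jn) >= 2) {
      d <- sqrt(rowSums((joints[[jn[1]]] - joints[[jn[2]]])^2))
      if (mean(d) > 1e-6) {
        out[[l]] <- d
        next
      }
    }
    if (length(jn) >= 1 && !is.null(topology$com_local[[l]])) {
      com <- to_global(frames[[l]], topology$com_local[[l]])
      out[[l]] <- sqrt(rowSums((com - joints[[jn[1]]])^2))
    }
  }
  out
}

#' Enumerate all exact roots of the distance-spectrum identity
#'
#' The squared inter-marker distance determines the complex series
#' `z = (C + P xi_x) + i (P xi_y)` only through `|z|^2`, and a band-limited
#' `|z|^2` factors through its associated degree-4K polynomial: each of the
#' `2K` conjugate-reciprocal zero pairs can be flipped, so the `4K + 1`
#' quadratic system has up to `2^(2K)` exact roots (beyond the `C > 0` and
#' `xi_y` sign gauges). This enumerates them all by polynomial rooting -
#' the joint constraint, not the distance, must pick the physical one.
#'
#' @param spectrum a [distance_sq_spectrum()] result.
#' @param grid a [cycle_grid()].
#' @param polish_tol keep only candidates whose [shape_residual()] norm is
#'   below `polish_tol * gamma` after a short Levenberg-Marquardt polish.
#' @return list of candidates, each a list with `C`, `xi_x`, `xi_y`
#'   (canonical `xi_y` branch), deduplicated.
#' @export
enumerate_shape_roots <- function(spectrum, grid, polish_tol = 1e-8) {
  K <- spectrum$K
  phi <- complex(real = c(spectrum$gamma, spectrum$alpha / 2),
                 imaginary = c(0, -spectrum$beta / 2))
  G <- c(Conj(rev(phi[-1])), phi)           # coefficients of zeta^0 .. zeta^4K
  r <- polyroot(G)
  r <- r[order(Mod(r))]
  inside <- r[seq_len(2 * K)]
  outside <- r[(2 * K + 1):(4 * K)]
  partner <- vapply(inside, function(p)
    outside[which.min(Mod(outside - 1 / Conj(p)))], complex(1))
  out <- list(); seen <- character()
  for (mask in 0:(2^(2 * K) - 1)) {
    pick <- ifelse(bitwAnd(mask, 2^(seq_len(2 * K) - 1)) > 0, partner, inside)
    u <- 1 + 0i
    for (root in pick) u <- c(0i, u) - c(root * u, 0i)   # u <- u * (x - root)
    uK <- u[K + 1]
    if (Mod(uK) < 1e-12 * max(Mod(u))) next              # would give C = 0
    cc <- sqrt(spectrum$gamma / sum(Mod(u)^2)) * Conj(uK) / Mod(uK)
    q <- cc * u                                          # z coeffs, k = -K..K
    C <- Re(q[K + 1])
    if (C <= 0) next
    a <- b <- ap <- bp <- numeric(K)
    for (k in 1:K) {
      gk <- (q[K + 1 + k] + Conj(q[K + 1 - k])) / 2
      hk <- (q[K + 1 + k] - Conj(q[K + 1 - k])) / (2i)
      a[k] <- 2 * Re(gk); b[k] <- -2 * Im(gk)
      ap[k] <- 2 * Re(hk); bp[k] <- -2 * Im(hk)
    }
    xi_x <- c(a, b)
    xi_y <- c(ap, bp)
    if (xi_y[which.max(abs(xi_y))] < 0) xi_y <- -xi_y    # canonical branch
    raw <- sqrt(sum(shape_residual(c(C, xi_x, xi_y), spectrum, grid)^2))
    if (raw > 1e-12 * spectrum$gamma) {
      # polynomial rooting left residual error: polish by Levenberg-Marquardt
      fit <- minpack.lm::nls.lm(
        par = c(C, xi_x, xi_y), fn = shape_residual,
        spectrum = spectrum, grid = grid,
        control = minpack.lm::nls.lm.control(maxiter = 50, ftol = 1e-15,
                                             ptol = 1e-15, gtol = 0))
      if (sqrt(sum(fit$fvec^2)) > polish_tol * spectrum$gamma) next
      p <- fit$par
      C <- p[1]; xi_x <- p[2:(2 * K + 1)]; xi_y <- p[(2 * K + 2):(4 * K + 1)]
      if (C < 0) { C <- -C; xi_x <- -xi_x }
      if (xi_y[which.max(abs(xi_y))] < 0) xi_y <- -xi_y
    }
    key <- paste(signif(c(C, xi_x, xi_y), 7), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    # physically the markers never cross: C + P xi_x must stay positive
    if (min(C + fourier_basis(grid, K) %*% xi_x) <= 0) next
    out[[length(out) + 1]] <- list(C = C, xi_x = xi_x, xi_y = xi_y)
  }
  out
}

# Score one link's candidate shapes by the joint constraint: for each
# candidate, the SUM over the link's joints of the pair-joint cost, where
# each joint's cost is minimised over both links' xi_y sign branches and the
# neighbour's current shape is held fixed. A single joint barely
# discriminates (its sub-system has many near-zero wrong configurations);
# only the physical root zeroes every adjacent joint simultaneously.
score_link_candidates <- function(link, cands, markers, topology, shapes,
                                  signs, grid, frames, P) {
  jt <- topology$joints[topology$joints$proximal == link |
                        topology$joints$distal == link, , drop = FALSE]
  nb_blocks <- lapply(seq_len(nrow(jt)), function(i) {
    nb <- if (jt$proximal[i] == link) jt$distal[i] else jt$proximal[i]
    lapply(c(1, -1), function(s) link_block(frames[[nb]], shapes[[nb]],
                                            s, P, grid))
  })
  vapply(cands, function(cd) {
    sh <- shape_params(cd$C, cd$xi_x, cd$xi_y)
    bl <- lapply(if (sum(cd$xi_y^2) > 1e-28) c(1, -1) else 1,
                 function(s) link_block(frames[[link]], sh, s, P, grid))
    total <- 0
    for (i in seq_len(nrow(jt))) {
      best <- Inf
      for (b in bl) for (nb in nb_blocks[[i]]) {
        cost <- if (jt$proximal[i] == link) pair_joint_cost(b, nb)
                else pair_joint_cost(nb, b)
        best <- min(best, cost)
      }
      total <- total + best
    }
    total
  }, 0)
}

# Detect links whose shape solution is a spurious root of the distance
# identity and replace it by an enumerated alternative. The search is
# monotone coordinate descent on the FULL joint-constraint cost (the only
# quantity that certifies a configuration: single joints admit exact wrong
# fits): per link, candidates are shortlisted by the cheap pair-cost sum and
# accepted only when the full system cost decreases. gap_tol is the RMS
# joint-gap (meters) below which the configuration counts as consistent.
same_root <- function(cd, sh) {
  abs(cd$C - sh$C) + sqrt(sum((cd$xi_x - sh$xi_x)^2)) +
    sqrt(sum((cd$xi_y - sh$xi_y)^2)) < 1e-10
}

repair_shapes <- function(markers, topology, shapes, grid, sol,
                          gap_tol = 1e-8, rank_tol = 1e-10, max_swaps = 6,
                          shortlist = 6, npairs = 6, verbose = FALSE) {
  K <- shapes[[1]]$K
  P <- fourier_basis(grid, K)
  frames <- marker_frames(markers, topology)
  cand_cache <- list()
  cands_of <- function(l) {
    if (is.null(cand_cache[[l]])) {
      mk <- link_markers(markers, l)
      spec <- distance_sq_spectrum(mk$m1, mk$m2, grid, K)
      cand_cache[[l]] <<- enumerate_shape_roots(spec, grid)
    }
    cand_cache[[l]]
  }
  as_shape <- function(cd, sc = NA_real_)
    shape_params(cd$C, cd$xi_x, cd$xi_y,
                 diagnostics = list(repaired = TRUE, pair_cost = sc))
  repaired <- character()
  for (round in seq_len(max_swaps)) {
    if (all(sol$gap_rms <= gap_tol)) break
    # Phase 1 - single-link swaps, best-first: evaluate every shortlisted
    # replacement by its FULL system cost and keep only the best. A swap to
    # the physical root collapses the cost by orders of magnitude, while
    # swaps that corrupt a sound link change it marginally, so best-first
    # acceptance does not trade a true root away.
    best <- NULL
    for (l in topology$links) {
      cands <- cands_of(l)
      if (!length(cands)) next
      sc <- score_link_candidates(l, cands, markers, topology, shapes,
                                  sol$signs, grid, frames, P)
      for (ci in order(sc)[seq_len(min(shortlist, length(sc)))]) {
        if (same_root(cands[[ci]], shapes[[l]])) next
        trial <- shapes
        trial[[l]] <- as_shape(cands[[ci]], sc[ci])
        cand_sol <- assemble_solve(markers, topology, trial, grid,
                                   branch = "tree", rank_tol = rank_tol)
        if (is.null(best) || cand_sol$cost_sq < best$sol$cost_sq)
          best <- list(links = l, shapes = trial, sol = cand_sol)
      }
    }
    # Phase 2 - joint pair swaps: when the two links flanking a bad joint
    # are BOTH on spurious roots, no single swap helps much. The physical
    # pair closes its joint sub-system exactly, so rank all candidate pairs
    # of the worst joints by pair cost and verify the leaders by full cost.
    for (j in order(-sol$gap_rms)) {
      if (sol$gap_rms[j] <= gap_tol) next
      a <- topology$joints$proximal[j]; b <- topology$joints$distal[j]
      ca <- cands_of(a); cb <- cands_of(b)
      if (!length(ca) || !length(cb)) next
      bl_a <- lapply(ca, function(cd) lapply(c(1, -1), function(s)
        link_block(frames[[a]], as_shape(cd), s, P, grid)))
      bl_b <- lapply(cb, function(cd) lapply(c(1, -1), function(s)
        link_block(frames[[b]], as_shape(cd), s, P, grid)))
      pc <- matrix(Inf, length(ca), length(cb))
      for (ia in seq_along(ca)) for (ib in seq_along(cb))
        for (sa in 1:2) for (sb in 1:2)
          pc[ia, ib] <- min(pc[ia, ib],
                            pair_joint_cost(bl_a[[ia]][[sa]], bl_b[[ib]][[sb]]))
      ord <- order(pc)[seq_len(min(npairs, length(pc)))]
      for (k in ord) {
        ia <- (k - 1) %% length(ca) + 1
        ib <- (k - 1) %/% length(ca) + 1
        if (same_root(ca[[ia]], shapes[[a]]) &&
            same_root(cb[[ib]], shapes[[b]])) next
        trial <- shapes
        trial[[a]] <- as_shape(ca[[ia]], pc[ia, ib])
        trial[[b]] <- as_shape(cb[[ib]], pc[ia, ib])
        cand_sol <- assemble_solve(markers, topology, trial, grid,
                                   branch = "tree", rank_tol = rank_tol)
        if (is.null(best) || cand_sol$cost_sq < best$sol$cost_sq)
          best <- list(links = c(a, b), shapes = trial, sol = cand_sol)
      }
      break                                   # one joint per round
    }
    if (is.null(best) || best$sol$cost_sq >= sol$cost_sq * (1 - 1e-9)) break
    shapes <- best$shapes; sol <- best$sol
    repaired <- union(repaired, best$links)
    if (verbose)
      message(sprintf("repair: swapped %s (cost %.3g)",
                      paste(best$links, collapse = "+"), sol$cost_sq))
  }
  list(shapes = shapes, sol = sol, repaired = repaired)
}

# Full proposed pipeline: baseline init -> per-link shape solve -> linear
# joint-constraint solve -> reconstruction.
assimilate_periodic_impl <- function(markers, topology, K,
                                     shape_tol = 1e-9, shape_maxit = 200,
                                     branch = "tree", rank_tol = 1e-10,
                                     repair = TRUE, gap_tol = 1e-8) {
  init <- naive_sta_init(markers, topology, K)
  grid <- markers$grid
  shapes <- list()
  for (l in topology$links) {
    mk <- link_markers(markers, l)
    spec <- distance_sq_spectrum(mk$m1, mk$m2, grid, K)
    shapes[[l]] <- tryCatch(
      solve_shape(spec, list(C = init$C[[l]], xi_x = init$xi[[l]]$x,
                             xi_y = init$xi[[l]]$y),
                  grid, tol = shape_tol, maxit = shape_maxit),
      error = function(e) {
        # Levenberg-Marquardt found no root from the baseline init: fall back
        # to the enumerated factorization closest to the init.
        cands <- enumerate_shape_roots(spec, grid)
        if (!length(cands))
          stop(sprintf("shape stage failed for link %s: %s",
                       l, conditionMessage(e)), call. = FALSE)
        prox <- vapply(cands, function(cd)
          (cd$C - init$C[[l]])^2 + sum((cd$xi_x - init$xi[[l]]$x)^2), 0)
        cd <- cands[[which.min(prox)]]
        shape_params(cd$C, cd$xi_x, cd$xi_y,
                     diagnostics = list(residual_norm = NA_real_,
                                        iterations = NA_integer_,
                                        message = "enumeration fallback",
                                        canonical_flip = FALSE))
      })
  }
  sol <- assemble_solve(markers, topology, shapes, grid,
                        branch = branch, rank_tol = rank_tol)
  repaired <- character()
  if (repair && any(sol$gap_rms > gap_tol)) {
    rp <- repair_shapes(markers, topology, shapes, grid, sol,
                        gap_tol = gap_tol, rank_tol = rank_tol)
    shapes <- rp$shapes; sol <- rp$sol; repaired <- rp$repaired
  }
  out <- reconstruct_impl(markers, topology, shapes, sol, grid)
  out$init <- init
  out$solver$repaired <- repaired
  out
}
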