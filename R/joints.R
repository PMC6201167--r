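#' Solve the constant local joint position from two time instants
#'
#' For a pin joint between links a and b whose frames are rigidly fixed to the
#' links, the joint has constant local coordinates `j_a`, `j_b` satisfying
#' `o_a[n] + R_a[n] j_a = o_b[n] + R_b[n] j_b` at every sample. Evaluating the
#' constraint at two instants with different relative rotation gives a 4x4
#' linear system whose solution is exact for rigid, artifact-free data.
#'
#' @param frames_a,frames_b [pose_series()] of the two links.
#' @param n1,n2 two distinct sample indices.
#' @param cond_tol condition-number threshold above which the stacked matrix is
#'   declared degenerate (relative rotation essentially equal at the two
#'   instants).
#' @return list with `j_a` and `j_b`, the local joint positions (length-2).
#' @export
solve_joint_two_instants <- function(frames_a, frames_b, n1, n2,
                                     cond_tol = 1e8) {
  if (n1 == n2) stop("solve_joint_two_instants: n1 and n2 must differ")
  M <- rbind(cbind(rot2(frames_a$ang[n1]), -rot2(frames_b$ang[n1])),
             cbind(rot2(frames_a$ang[n2]), -rot2(frames_b$ang[n2])))
  rhs <- c(frames_b$o[n1, ] - frames_a$o[n1, ],
           frames_b$o[n2, ] - frames_a$o[n2, ])
  sv <- svd(M)$d
  if (sv[4] <= 0 || sv[1] / sv[4] > cond_tol)
    stop(sprintf(paste0("solve_joint_two_instants: degenerate motion ",
                        "(condition number %.3g); relative rotation at the two ",
                        "instants is too similar"),
                 if (sv[4] > 0) sv[1] / sv[4] else Inf))
  x <- solve(M, rhs)
  list(j_a = x[1:2], j_b = x[3:4])
}

#' All-samples least-squares joint solve
#'
#' Least-squares generalisation of [solve_joint_two_instants()] over the whole
#' cycle: the pair of constant locals minimising the summed squared joint gap.
#' On rigid artifact-free data it agrees with the two-instant solve; on
#' artifact-affected data it is the baseline joint estimate.
#'
#' @param frames_a,frames_b [pose_series()] of the two links.
#' @param context joint label used in error messages.
#' @param rank_tol relative singular-value tolerance for rank deficiency.
#' @return list with `j_a`, `j_b`, and `cost` (the achieved sum of squared
#'   residual norms).
#' @export
solve_joint_lsq <- function(frames_a, frames_b, context = "joint",
                            rank_tol = 1e-10) {
  N <- length(frames_a)
  ca <- cos(frames_a$ang); sa <- sin(frames_a$ang)
  cb <- cos(frames_b$ang); sb <- sin(frames_b$ang)
  A <- matrix(0, 2 * N, 4)
  odd <- seq(1, 2 * N, by = 2)
  A[odd, 1] <- ca; A[odd, 2] <- -sa; A[odd, 3] <- -cb; A[odd, 4] <- sb
  A[odd + 1, 1] <- sa; A[odd + 1, 2] <- ca; A[odd + 1, 3] <- -sb; A[odd + 1, 4] <- -cb
  rhs <- numeric(2 * N)
  rhs[odd] <- frames_b$o[, 1] - frames_a$o[, 1]
  rhs[odd + 1] <- frames_b$o[, 2] - frames_a$o[, 2]
  sv <- svd(A)
  if (sv$d[4] < rank_tol * sv$d[1])
    stop(sprintf(paste0("solve_joint_lsq: insufficient relative rotation at %s ",
                        "(rank-deficient system)"), context))
  x <- sv$v %*% (crossprod(sv$u, rhs) / sv$d)
  res <- rhs - A %*% x
  list(j_a = x[1:2], j_b = x[3:4], cost = sum(res^2))
}

#' Per-sample joint-constraint residual
#'
#' The gap between the two links' predictions of the joint's global position,
#' `(o_a + R_a j_a) - (o_b + R_b j_b)`, per sample, with the summed Euclidean
#' norm (the cost the assimilation minimises, in its unsquared form).
#'
#' @param frames_a,frames_b [pose_series()] of the two links.
#' @param j_a,j_b constant local joint positions.
#' @return list with `residual` (`N x 2`), `sum_norm` and `sum_sq`.
#' @export
joint_residual <- function(frames_a, frames_b, j_a, j_b) {
  r <- to_global(frames_a, j_a) - to_global(frames_b, j_b)
  nr <- sqrt(rowSums(r^2))
  list(residual = r, sum_norm = sum(nr), sum_sq = sum(nr^2))
}

#' Joint angles and root tilt from link frames
#'
#' Converts per-link frame series into the model's angle conventions: the root
#' link's absolute tilt relative to its upright reference, and per-joint
#' relative angles of the distal link with respect to the proximal link,
#' sign-flipped so that clockwise rotation is positive. Each link's frame
#' angle is first corrected by the topology's constant `axis_offset` (landmark
#' frame to link frame), and all series are unwrapped to be continuous over
#' the cycle.
#'
#' @param frames named list of [pose_series()] keyed by link id (marker,
#'   landmark, or link frames; the constant offsets cancel in comparisons as
#'   long as both sides use the same frames).
#' @param topology a [linkage_topology()].
#' @return list with `root` (tilt series of the root link, radians, clockwise
#'   positive) and `joint` (named list of per-joint angle series).
#' @export
joint_angles <- function(frames, topology) {
  psi <- lapply(topology$links, function(l)
    unwrap_angle(frames[[l]]$ang + topology$axis_offset[[l]]))
  names(psi) <- topology$links
  root <- -(psi[[topology$root]] - topology$upright_angle)
  root <- root - 2 * pi * round(mean(root) / (2 * pi))
  jt <- lapply(seq_len(nrow(topology$joints)), function(i) {
    j <- topology$joints[i, ]
    th <- -(psi[[j$distal]] - psi[[j$proximal]]) + j$neutral_offset
    th - 2 * pi * round(mean(th) / (2 * pi))
  })
  names(jt) <- topology$joints$joint
  list(root = root, joint = jt)
}
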