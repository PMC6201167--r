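#' 2x2 proper rotation from an angle
#'
#' Counterclockwise-positive planar rotation matrix.
#' @param a angle in radians.
#' @return 2x2 matrix.
#' @export
rot2 <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)

#' Extract the angle of a proper planar rotation
#' @param R 2x2 proper rotation matrix.
#' @return angle in radians in (-pi, pi], via atan2 of the first column.
#' @export
rot_angle <- function(R) atan2(R[2, 1], R[1, 1])

check_rotation <- function(R, tol = 1e-8) {
  if (max(abs(crossprod(R) - diag(2))) > tol || det(R) < 0)
    stop("planar_pose: rotation must be proper orthonormal (R'R = I, det = +1)")
  invisible(TRUE)
}

#' Planar pose (origin + proper rotation)
#'
#' The (o, A) pairs of the algorithm: origin in meters, rotation as a 2x2
#' proper orthonormal matrix. The matrix is authoritative; the angle is kept
#' alongside for convenience and extracted by [rot_angle()].
#'
#' @param origin length-2 numeric, meters.
#' @param rotation 2x2 proper rotation matrix, or a single angle in radians.
#' @return object of class `"planar_pose"` with fields `o`, `R`, `ang`.
#' @export
planar_pose <- function(origin = c(0, 0), rotation = diag(2)) {
  if (length(rotation) == 1) rotation <- rot2(rotation)
  check_rotation(rotation)
  structure(list(o = as.numeric(origin), R = rotation, ang = rot_angle(rotation)),
            class = "planar_pose")
}

#' @export
print.planar_pose <- function(x, ...) {
  cat(sprintf("<planar_pose> o = (%.4g, %.4g), angle = %.4g rad\n",
              x$o[1], x$o[2], x$ang))
  invisible(x)
}

#' Time series of planar poses on a cycle grid
#'
#' Stored as an `N x 2` origin matrix plus a length-`N` angle vector; rotation
#' matrices are materialised on demand. All algorithm frames (marker,
#' landmark, link) over a cycle are `pose_series` objects.
#'
#' @param origin `N x 2` matrix of origins (meters).
#' @param angle length-`N` vector of rotation angles (radians, CCW positive).
#' @return object of class `"pose_series"`.
#' @export
pose_series <- function(origin, angle) {
  origin <- as.matrix(origin)
  if (ncol(origin) != 2 || nrow(origin) != length(angle))
    stop("pose_series: origin must be N x 2 with N matching angle length")
  if (any(!is.finite(origin)) || any(!is.finite(angle)))
    stop("pose_series: non-finite pose data")
  structure(list(o = unname(origin), ang = as.numeric(angle)), class = "pose_series")
}

#' @export
print.pose_series <- function(x, ...) {
  cat(sprintf("<pose_series> N = %d samples\n", nrow(x$o)))
  invisible(x)
}

#' @export
length.pose_series <- function(x) nrow(x$o)

pose_at <- function(ps, n) planar_pose(ps$o[n, ], rot2(ps$ang[n]))

#' Build the pair frame from two points
#'
#' The frame used for both the landmark- and the marker-coordinate systems:
#' origin at the midpoint of the two points, x-axis the unit vector from the
#' first point to the second, y-axis its 90-degree counterclockwise rotation
#' (columns `d/|d|` and `R(pi/2) d/|d|`).
#'
#' @param p1,p2 length-2 points (meters).
#' @param eps minimum separation below which the pair is degenerate.
#' @return a [planar_pose()].
#' @export
pair_frame <- function(p1, p2, eps = 1e-9) {
  d <- p2 - p1
  nd <- sqrt(sum(d^2))
  if (nd <= eps)
    stop(sprintf("pair_frame: coincident points (separation %.3g m)", nd))
  u <- d / nd
  planar_pose((p1 + p2) / 2, matrix(c(u[1], u[2], -u[2], u[1]), 2, 2))
}

#' Pair frames along two marker trajectories
#'
#' Vectorised [pair_frame()] over a cycle: one frame per sample from the two
#' markers of a link.
#'
#' @param m1,m2 `N x 2` trajectory matrices.
#' @param eps minimum separation.
#' @param context label used in degenerate-pair error messages.
#' @return a [pose_series()].
#' @export
pair_frame_series <- function(m1, m2, eps = 1e-9, context = "link") {
  d <- m2 - m1
  nd <- sqrt(rowSums(d^2))
  if (any(nd <= eps))
    stop(sprintf("pair_frame_series: coincident markers on %s at sample %d",
                 context, which(nd <= eps)[1]))
  pose_series((m1 + m2) / 2, atan2(d[, 2], d[, 1]))
}

#' Map points between a pose's local frame and the global frame
#'
#' `to_global` computes `origin + R %*% local`; `to_local` is its exact
#' inverse. Both accept a single [planar_pose()] with a point or point matrix,
#' or a [pose_series()] with either a constant local point or an `N x 2`
#' series of points.
#'
#' @param pose a [planar_pose()] or [pose_series()].
#' @param p length-2 point or `N x 2` matrix.
#' @return point(s) in the other frame, matching the shape of `p`.
#' @export
to_global <- function(pose, p) {
  if (inherits(pose, "planar_pose")) {
    if (is.null(dim(p))) return(pose$o + as.numeric(pose$R %*% p))
    return(sweep(p %*% t(pose$R), 2, pose$o, `+`))
  }
  stopifnot(inherits(pose, "pose_series"))
  ca <- cos(pose$ang); sa <- sin(pose$ang)
  if (is.null(dim(p))) {
    cbind(pose$o[, 1] + ca * p[1] - sa * p[2],
          pose$o[, 2] + sa * p[1] + ca * p[2])
  } else {
    cbind(pose$o[, 1] + ca * p[, 1] - sa * p[, 2],
          pose$o[, 2] + sa * p[, 1] + ca * p[, 2])
  }
}

#' @rdname to_global
#' @export
to_local <- function(pose, p) {
  if (inherits(pose, "planar_pose")) {
    if (is.null(dim(p))) return(as.numeric(crossprod(pose$R, p - pose$o)))
    return(sweep(p, 2, pose$o, `-`) %*% pose$R)
  }
  stopifnot(inherits(pose, "pose_series"))
  ca <- cos(pose$ang); sa <- sin(pose$ang)
  if (is.null(dim(p))) p <- matrix(p, nrow(pose$o), 2, byrow = TRUE)
  dx <- p[, 1] - pose$o[, 1]; dy <- p[, 2] - pose$o[, 2]
  cbind(ca * dx + sa * dy, -sa * dx + ca * dy)
}

#' Compose and factor planar poses
#'
#' `compose_pose(parent, child)` expresses a pose given in the parent frame in
#' the global frame: origin `o_p + R_p o_c`, rotation `R_p R_c`.
#' `relative_pose(child, parent)` is the inverse factorisation, the child pose
#' expressed in the parent frame, so that
#' `compose_pose(parent, relative_pose(child, parent)) == child`.
#' Both work element-wise on [pose_series()] pairs.
#'
#' @param parent,child,x [planar_pose()] or [pose_series()] objects (matching
#'   types).
#' @return object of the same type.
#' @export
compose_pose <- function(parent, child) {
  if (inherits(parent, "planar_pose")) {
    return(planar_pose(parent$o + as.numeric(parent$R %*% child$o),
                       parent$R %*% child$R))
  }
  pose_series(to_global(parent, child$o), parent$ang + child$ang)
}

#' @rdname compose_pose
#' @export
relative_pose <- function(x, parent) {
  if (inherits(parent, "planar_pose")) {
    return(planar_pose(as.numeric(crossprod(parent$R, x$o - parent$o)),
                       crossprod(parent$R, x$R)))
  }
  pose_series(to_local(parent, x$o), x$ang - parent$ang)
}

#' Unwrap a cyclic angle series by nearest-branch continuation
#'
#' @param a angle series in radians.
#' @return continuous series with jumps larger than pi removed.
#' @export
unwrap_angle <- function(a) {
  d <- diff(a)
  a + c(0, cumsum(-2 * pi * round(d / (2 * pi))))
}
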