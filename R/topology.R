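#' Linkage topology of a planar multi-rigid-link model
#'
#' Declares the links (each carrying exactly two marker slots), the pin joints
#' connecting them, and optional per-link geometry used by the gait fixture and
#' by link-frame reconstruction:
#'
#' * `landmarks`: per-link 2x2 matrix of landmark local coordinates in the
#'   link frame (row 1 = landmark 1), needed only to synthesise data;
#' * `com_local`: per-link CoM position expressed in the landmark frame,
#'   needed to reconstruct the CoM-anchored link frame from landmark frames;
#' * `axis_offset`: constant rotation (radians) from a link's landmark frame
#'   to its link frame, used when converting frame angles to link angles.
#'
#' @param links character vector of link identifiers.
#' @param joints data frame with columns `joint`, `proximal`, `distal` and
#'   optionally `neutral_offset` (radians added to the relative angle so the
#'   reference posture reads zero).
#' @param root identifier of the root link (its absolute tilt is reported);
#'   defaults to the first link.
#' @param upright_angle link-frame angle of the root link in the reference
#'   (upright) posture, radians.
#' @param landmarks,com_local named lists keyed by link id (optional).
#' @param axis_offset named numeric vector keyed by link id (optional,
#'   default 0).
#' @return object of class `"linkage_topology"`.
#' @export
linkage_topology <- function(links, joints, root = links[1],
                             upright_angle = 0,
                             landmarks = NULL, com_local = NULL,
                             axis_offset = NULL) {
  links <- as.character(links)
  joints <- as.data.frame(joints, stringsAsFactors = FALSE)
  if (!all(c("joint", "proximal", "distal") %in% names(joints)))
    stop("linkage_topology: joints needs columns joint, proximal, distal")
  if (is.null(joints$neutral_offset)) joints$neutral_offset <- 0
  bad <- setdiff(c(joints$proximal, joints$distal), links)
  if (length(bad)) stop("linkage_topology: joint references unknown link: ",
                        paste(bad, collapse = ", "))
  if (any(joints$proximal == joints$distal))
    stop("linkage_topology: a joint must reference two distinct links")
  # connectivity check over the joint graph
  reached <- links[1]
  repeat {
    grow <- unique(c(joints$distal[joints$proximal %in% reached],
                     joints$proximal[joints$distal %in% reached]))
    grow <- setdiff(grow, reached)
    if (!length(grow)) break
    reached <- c(reached, grow)
  }
  if (!setequal(reached, links))
    stop("linkage_topology: joint graph is not connected")
  off <- stats::setNames(rep(0, length(links)), links)
  if (!is.null(axis_offset)) off[names(axis_offset)] <- axis_offset
  structure(list(links = links, joints = joints, root = root,
                 upright_angle = upright_angle,
                 landmarks = landmarks, com_local = com_local,
                 axis_offset = off),
            class = "linkage_topology")
}

#' @export
print.linkage_topology <- function(x, ...) {
  cat(sprintf("<linkage_topology> %d links, %d joints (root: %s)\n",
              length(x$links), nrow(x$joints), x$root))
  invisible(x)
}

marker_labels <- function(topology) {
  as.vector(t(outer(topology$links, c("1", "2"), paste0)))
}

#' Marker trajectory set over one cycle
#'
#' A named collection of `N x 2` global marker trajectories (meters), two per
#' link, with the sampling grid. Marker names are `<link>1` and `<link>2`.
#'
#' @param m named list of `N x 2` matrices.
#' @param grid a [cycle_grid()].
#' @param topology optional [linkage_topology()]; when given, completeness is
#'   checked (both markers of every link present).
#' @return object of class `"marker_set"`.
#' @export
marker_set <- function(m, grid, topology = NULL) {
  m <- lapply(m, function(x) unname(as.matrix(x)))
  ns <- vapply(m, nrow, 1L)
  if (length(unique(ns)) != 1 || ns[1] != grid$N)
    stop("marker_set: all trajectories must have N rows matching the grid")
  if (any(vapply(m, function(x) any(!is.finite(x)) || ncol(x) != 2, TRUE)))
    stop("marker_set: trajectories must be finite N x 2 matrices")
  if (!is.null(topology)) {
    miss <- setdiff(marker_labels(topology), names(m))
    if (length(miss))
      stop("marker_set: missing marker trajectories: ", paste(miss, collapse = ", "))
  }
  structure(list(m = m, grid = grid), class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> %d markers x %d samples\n", length(x$m), x$grid$N))
  invisible(x)
}

link_markers <- function(markers, link) {
  list(m1 = markers$m[[paste0(link, "1")]], m2 = markers$m[[paste0(link, "2")]])
}

#' Marker frames of every link
#'
#' Builds the pair frame of each link's two markers at every sample
#' (midpoint origin, x-axis from marker 1 to marker 2). Applied to captured
#' markers this is the marker-coordinate system; applied to landmark markers
#' it is the landmark-coordinate system.
#'
#' @param markers a [marker_set()].
#' @param topology a [linkage_topology()].
#' @return named list of [pose_series()], one per link.
#' @export
marker_frames <- function(markers, topology) {
  out <- lapply(topology$links, function(l) {
    mk <- link_markers(markers, l)
    pair_frame_series(mk$m1, mk$m2, context = l)
  })
  stats::setNames(out, topology$links)
}

#' Apply a rigid transform to every marker trajectory
#'
#' Utility for equivariance checks: maps each global trajectory through a
#' fixed planar pose.
#'
#' @param markers a [marker_set()].
#' @param pose a [planar_pose()].
#' @return transformed [marker_set()].
#' @export
transform_markers <- function(markers, pose) {
  marker_set(lapply(markers$m, function(x) to_global(pose, x)), markers$grid)
}
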