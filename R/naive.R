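#' Constant local joint positions on marker frames (baseline)
#'
#' The uncorrected baseline treats the marker-coordinate system of each link
#' (built directly from the captured, artifact-affected markers) as if it were
#' rigidly fixed to the link, and estimates for every joint the pair of
#' constant local positions minimising the summed squared joint gap over the
#' cycle. With artifact present no constant pair closes the gap exactly; the
#' achieved cost is reported.
#'
#' @param markers a [marker_set()] of captured markers.
#' @param topology a [linkage_topology()].
#' @return list with `frames` (marker frames per link), and per-joint entries
#'   `locals` (list with the two links' local positions keyed by link id),
#'   `cost_sq` and `cost_norm`.
#' @export
estimate_constant_joints <- function(markers, topology) {
  frames <- marker_frames(markers, topology)
  jl <- list(); cost_sq <- c(); cost_norm <- c()
  for (i in seq_len(nrow(topology$joints))) {
    j <- topology$joints[i, ]
    sol <- solve_joint_lsq(frames[[j$proximal]], frames[[j$distal]],
                           context = j$joint)
    loc <- stats::setNames(list(sol$j_a, sol$j_b), c(j$proximal, j$distal))
    jl[[j$joint]] <- loc
    r <- joint_residual(frames[[j$proximal]], frames[[j$distal]],
                        sol$j_a, sol$j_b)
    cost_sq[j$joint] <- r$sum_sq
    cost_norm[j$joint] <- r$sum_norm
  }
  list(frames = frames, locals = jl, cost_sq = cost_sq, cost_norm = cost_norm)
}

# Naive assimilation: marker frames as link frames, joint trajectories as the
# midpoint of the two adjacent links' predictions. No artifact is removed.
naive_assimilate_impl <- function(markers, topology) {
  est <- estimate_constant_joints(markers, topology)
  joints <- list()
  for (i in seq_len(nrow(topology$joints))) {
    j <- topology$joints[i, ]
    loc <- est$locals[[j$joint]]
    pa <- to_global(est$frames[[j$proximal]], loc[[j$proximal]])
    pb <- to_global(est$frames[[j$distal]], loc[[j$distal]])
    joints[[j$joint]] <- (pa + pb) / 2
  }
  ang <- joint_angles(est$frames, topology)
  list(frames = est$frames, locals = est$locals, joints = joints,
       angles = ang, cost_sq = est$cost_sq, cost_norm = est$cost_norm)
}

#' Rough STA estimate from the baseline (initialisation)
#'
#' Expresses each captured marker in its own link's marker frame, subtracts
#' the cycle mean (the landmark position within that frame is unknown, so only
#' the zero-mean part is recoverable), and Fourier-fits the residual at order
#' `K`. Because the two markers define their frame, the residual lies entirely
#' along the frame's x-axis: marker j sits at `(-1)^j * d[n]/2` where `d[n]`
#' is the inter-marker distance. The fit therefore seeds the x coefficients
#' and the inter-landmark distance; the y coefficient difference is seeded by
#' the shape solver's warm start, not here.
#'
#' @param markers a [marker_set()].
#' @param topology a [linkage_topology()].
#' @param K Fourier order of the artifact expansion.
#' @return list with per-marker initial [sta_coeffs()] (`q`), and per-link
#'   `C` (mean inter-marker distance) and `xi` (initial coefficient
#'   differences, a list with `x` and `y`).
#' @export
naive_sta_init <- function(markers, topology, K) {
  frames <- marker_frames(markers, topology)
  q <- list(); C <- c(); xi <- list()
  for (l in topology$links) {
    mk <- link_markers(markers, l)
    loc1 <- to_local(frames[[l]], mk$m1)
    loc2 <- to_local(frames[[l]], mk$m2)
    r1 <- scale(loc1, scale = FALSE)
    r2 <- scale(loc2, scale = FALSE)
    q[[paste0(l, "1")]] <- fit_sta(r1, markers$grid, K)
    q[[paste0(l, "2")]] <- fit_sta(r2, markers$grid, K)
    C[l] <- mean(sqrt(rowSums((mk$m2 - mk$m1)^2)))
    xi[[l]] <- list(x = q[[paste0(l, "2")]]$qx - q[[paste0(l, "1")]]$qx,
                    y = q[[paste0(l, "2")]]$qy - q[[paste0(l, "1")]]$qy)
  }
  list(q = q, C = C, xi = xi)
}
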