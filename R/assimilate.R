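#' Assimilate one cycle of marker data into a planar multi-rigid-link model
#'
#' Fits captured, possibly artifact-affected marker trajectories spanning
#' exactly one movement cycle to a planar pin-jointed rigid-link model.
#'
#' `method = "periodic"` (the default) removes the soft tissue artifact under
#' the assumption that it is periodic over the cycle: each marker's artifact
#' is expanded in an order-`K` Fourier series in its link's landmark frame;
#' per-link shape parameters (inter-landmark distance and coefficient
#' differences) are identified from the spectrum of the squared inter-marker
#' distance; the remaining coefficients and the constant local joint positions
#' then follow from one linear joint-constraint least-squares problem, and the
#' artifact-free landmark kinematics are reconstructed.
#'
#' `method = "naive"` is the uncorrected baseline: marker-pair frames are
#' taken as link frames and only constant local joint positions are fitted,
#' so the artifact propagates into the result.
#'
#' @param markers a [marker_set()] (or anything [read_markers()] returns).
#' @param topology a [linkage_topology()].
#' @param method `"periodic"` or `"naive"`.
#' @param K Fourier order of the artifact expansion (default 4).
#' @param control list of solver settings: `shape_tol` (relative residual
#'   tolerance of the shape root-solve, default `1e-9`), `shape_maxit`
#'   (default 200), `branch` (`"tree"`, `"greedy"` or `"fixed"` sign-branch
#'   resolution), `repair` (logical, default `TRUE`: re-select spurious
#'   distance-identity roots by joint-constraint cost), `gap_tol` (RMS joint
#'   gap in meters above which repair engages, default `1e-8`), `rank_tol`
#'   (default `1e-10`).
#' @return an object of class `"sta_assim"` with, among others, components
#'   `frames` (per-link [pose_series()]; landmark frames for the periodic
#'   method, marker frames for the baseline), `joints` (per-joint global
#'   trajectories), `angles` (root tilt and per-joint angle series),
#'   `lengths` (per-link length series), and for the periodic method `sta`
#'   (per-marker [sta_coeffs()]), `shapes`, `landmark_markers` and a `solver`
#'   report.
#' @seealso [gait_fixture()] for synthetic data, [inverse_dynamics()] and
#'   [evaluate_assimilation()] for downstream evaluation.
#' @examples
#' fx <- gait_fixture(seed = 1, N = 100, sta_amplitude = 0.005)
#' fit <- sta_assimilate(fx$markers, fx$topology)
#' print(fit)
#' max(abs(fit$angles$joint$`l-K` - fx$angles$joint$`l-K`))
#' @export
sta_assimilate <- function(markers, topology,
                           method = c("periodic", "naive"), K = 4,
                           control = list()) {
  method <- match.arg(method)
  stopifnot(inherits(markers, "marker_set"), inherits(topology, "linkage_topology"))
  marker_set(markers$m, markers$grid, topology)   # completeness check
  ctl <- utils::modifyList(list(shape_tol = 1e-9, shape_maxit = 200,
                                branch = "tree", repair = TRUE,
                                gap_tol = 1e-8, rank_tol = 1e-10), control)
  if (method == "naive") {
    res <- naive_assimilate_impl(markers, topology)
    out <- list(method = "naive", K = K, grid = markers$grid,
                topology = topology, markers = markers,
                frames = res$frames, locals = res$locals, joints = res$joints,
                angles = res$angles,
                lengths = link_length_series(topology, res$frames, res$joints),
                sta = NULL,
                solver = list(cost_sq = sum(res$cost_sq),
                              cost_norm = sum(res$cost_norm),
                              per_joint_cost_sq = res$cost_sq))
  } else {
    if (markers$grid$N < 8 * K + 2)
      stop("sta_assimilate: need N >= 8K + 2 samples for the periodic method")
    res <- assimilate_periodic_impl(markers, topology, K,
                                    shape_tol = ctl$shape_tol,
                                    shape_maxit = ctl$shape_maxit,
                                    branch = ctl$branch,
                                    rank_tol = ctl$rank_tol,
                                    repair = ctl$repair,
                                    gap_tol = ctl$gap_tol)
    out <- list(method = "periodic", K = K, grid = markers$grid,
                topology = topology, markers = markers,
                frames = res$lm_frames, locals = res$locals,
                joints = res$joints, angles = res$angles,
                lengths = res$lengths, sta = res$sta,
                shapes = res$shapes, signs = res$signs,
                landmark_markers = res$landmark_markers,
                init = res$init, solver = res$solver)
  }
  class(out) <- c(paste0("sta_assim_", method), "sta_assim")
  out
}

#' @export
print.sta_assim <- function(x, ...) {
  cat(sprintf("Marker-data assimilation (%s method)\n", x$method))
  cat(sprintf("  %d links, %d joints, N = %d samples, K = %d\n",
              length(x$topology$links), nrow(x$topology$joints), x$grid$N, x$K))
  cat(sprintf("  joint-constraint cost: sum|r| = %.4g m, sum r^2 = %.4g m^2\n",
              x$solver$cost_norm, x$solver$cost_sq))
  if (x$method == "periodic")
    cat(sprintf("  linear stage rank %d/%d (condition %.3g)\n",
                x$solver$rank, x$solver$rank + x$solver$null_dim, x$solver$cond))
  invisible(x)
}

#' @export
summary.sta_assim <- function(object, ...) {
  rs <- residuals(object)
  s <- list(method = object$method, K = object$K, N = object$grid$N,
            solver = object$solver,
            max_joint_gap = apply(rs, 2, max),
            mean_length = vapply(object$lengths, mean, 0),
            range_length = vapply(object$lengths, function(x) diff(range(x)), 0))
  if (object$method == "periodic") {
    s$C <- vapply(object$shapes, function(p) p$C, 0)
    s$shape_residual <- vapply(object$shapes,
                               function(p) p$diagnostics$residual_norm, 0)
    s$sta_scale <- vapply(object$sta,
                          function(q) sqrt(sum(q$qx^2 + q$qy^2)), 0)
  }
  class(s) <- "summary.sta_assim"
  s
}

#' @export
print.summary.sta_assim <- function(x, ...) {
  cat(sprintf("Assimilation summary (%s method, K = %d, N = %d)\n",
              x$method, x$K, x$N))
  cat("  per-joint max constraint gap (m):\n")
  print(signif(x$max_joint_gap, 4))
  cat("  mean link length (m) and within-cycle range (m):\n")
  print(cbind(mean = signif(x$mean_length, 7),
              range = signif(x$range_length, 4)))
  if (!is.null(x$C)) {
    cat("  identified inter-landmark distances C (m):\n")
    print(signif(x$C, 7))
  }
  invisible(x)
}

#' Extract the fitted STA Fourier coefficients
#'
#' @param object an `sta_assim` fit.
#' @param ... unused.
#' @return for the periodic method, a matrix with one row per marker and
#'   columns `ax1..axK, bx1..bxK, ay1..ayK, by1..byK` (meters); the baseline
#'   estimates no artifact and returns `NULL`.
#' @export
coef.sta_assim <- function(object, ...) {
  if (is.null(object$sta)) return(NULL)
  K <- object$K
  out <- t(vapply(object$sta, function(q) c(q$qx, q$qy), numeric(4 * K)))
  colnames(out) <- c(paste0("ax", 1:K), paste0("bx", 1:K),
                     paste0("ay", 1:K), paste0("by", 1:K))
  out
}

#' Joint-constraint residual norms of a fit
#'
#' @param object an `sta_assim` fit.
#' @param ... unused.
#' @return `N x J` matrix of per-sample joint-gap norms (meters), one column
#'   per joint, evaluated in the fit's own frames.
#' @export
residuals.sta_assim <- function(object, ...) {
  J <- nrow(object$topology$joints)
  out <- matrix(0, object$grid$N, J,
                dimnames = list(NULL, object$topology$joints$joint))
  for (j in seq_len(J)) {
    jt <- object$topology$joints[j, ]
    loc <- object$locals[[jt$joint]]
    r <- joint_residual(object$frames[[jt$proximal]],
                        object$frames[[jt$distal]],
                        loc[[jt$proximal]], loc[[jt$distal]])
    out[, j] <- sqrt(rowSums(r$residual^2))
  }
  out
}

#' Model-implied marker trajectories
#'
#' For the periodic method, the recovered artifact-free landmark markers; the
#' baseline removes nothing, so its fitted markers are the input markers.
#'
#' @param object an `sta_assim` fit.
#' @param ... unused.
#' @return a [marker_set()].
#' @export
fitted.sta_assim <- function(object, ...) {
  if (object$method == "periodic")
    marker_set(object$landmark_markers, object$grid)
  else
    object$markers
}

#' Predict kinematic quantities from a fit
#'
#' @param object an `sta_assim` fit.
#' @param type `"angles"` (root tilt + joint angle series), `"joints"`
#'   (per-joint global trajectories), `"markers"` (artifact-free markers, as
#'   [fitted.sta_assim()]), or `"frames"` (per-link [pose_series()]).
#' @param ... unused.
#' @export
predict.sta_assim <- function(object,
                              type = c("angles", "joints", "markers", "frames"),
                              ...) {
  switch(match.arg(type),
         angles = object$angles,
         joints = object$joints,
         markers = fitted(object),
         frames = object$frames)
}

#' Plot assimilated joint angles over the cycle
#'
#' One panel per angle (root tilt plus each joint), against cycle phase.
#'
#' @param x an `sta_assim` fit.
#' @param truth optional reference angle list (same shape as `x$angles`) drawn
#'   dashed for comparison.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sta_assim <- function(x, truth = NULL, ...) {
  ang <- x$angles
  nm <- c(paste0(x$topology$root, " tilt"), names(ang$joint))
  series <- c(list(ang$root), ang$joint)
  tr <- if (!is.null(truth)) c(list(truth$root), truth$joint)
  op <- graphics::par(mfrow = grDevices::n2mfrow(length(series)),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  ph <- seq_len(x$grid$N) / x$grid$N
  for (i in seq_along(series)) {
    graphics::plot(ph, series[[i]], type = "l", xlab = "cycle phase",
                   ylab = "angle (rad)", main = nm[i], ...)
    if (!is.null(tr)) graphics::lines(ph, tr[[i]], lty = 2, col = 2)
  }
  invisible(x)
}

#' Simulate artifact-affected marker sets from a fitted model
#'
#' Parametric re-simulation: draws fresh periodic artifact profiles at the
#' scale of the fitted coefficients (or uses supplied profiles) and injects
#' them into the fit's recovered landmark kinematics, giving surrogate marker
#' sets with the same rigid motion but new artifact.
#'
#' @param object a periodic-method `sta_assim` fit.
#' @param nsim number of surrogate marker sets.
#' @param seed integer seed for the profile draws.
#' @param profiles optional list of per-marker [sta_coeffs()] to inject
#'   instead of random draws (used for all `nsim` replicates).
#' @param ... unused.
#' @return list of `nsim` [marker_set()] objects.
#' @export
simulate.sta_assim <- function(object, nsim = 1, seed = 1, profiles = NULL, ...) {
  if (object$method != "periodic")
    stop("simulate: only periodic-method fits carry an artifact model")
  amp <- max(abs(coef(object)))
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    pr <- if (is.null(profiles))
      sta_profiles(seed + s - 1, names(object$sta), K = object$K,
                   amplitude = max(amp, 1e-6))
    else profiles
    out[[s]] <- inject_sta(marker_set(object$landmark_markers, object$grid),
                           object$frames, pr, object$topology)
  }
  out
}
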