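#' Spectral derivative of a periodic series
#'
#' Fits the one-cycle signal with a Fourier series (constant plus harmonics up
#' to `floor((N - 2) / 4)`), differentiates term by term analytically, and
#' re-evaluates on the grid. Exact for band-limited signals; the grid must
#' carry the cycle `period`.
#'
#' @param x length-`N` vector or `N x m` matrix (columns differentiated
#'   independently).
#' @param grid a [cycle_grid()] with `period` set (seconds).
#' @param order derivative order, 1 or 2.
#' @return series of the same shape, in units of `x` per second (or second^2).
#' @export
spectral_derivative <- function(x, grid, order = 1) {
  if (is.null(grid$period))
    stop("spectral_derivative: grid period (seconds) is required")
  if (!order %in% c(1, 2)) stop("spectral_derivative: order must be 1 or 2")
  vec <- is.null(dim(x))
  Kd <- floor((grid$N - 2) / 4)
  f <- fourier_fit(as.matrix(x), grid, Kd, dc = TRUE)
  w <- 2 * pi * seq_len(Kd) / grid$period
  a <- f$coef[1:Kd, , drop = FALSE]
  b <- f$coef[(Kd + 1):(2 * Kd), , drop = FALSE]
  if (order == 1) {
    dcoef <- rbind(w * b, -w * a)        # d/dt: cos' = -w sin, sin' = w cos
    dc <- rep(0, ncol(a))
  } else {
    dcoef <- rbind(-w^2 * a, -w^2 * b)
    dc <- rep(0, ncol(a))
  }
  out <- fourier_eval(dcoef, grid, dc = dc)
  if (vec) as.numeric(out) else out
}

# Planar recursive Newton-Euler over one open chain, ordered distal ->
# proximal. Each element: mass (kg), inertia (kg m^2 about the CoM),
# com (N x 2), ang (N, link angle, CCW), joint (N x 2, global position of the
# joint to the *next* element), optionally ext_force (N x 2) and ext_cop
# (N x 2) for an external load. Returns per-element joint force and torque
# (the action of the next, more proximal element on this one), CCW-positive.
newton_euler_chain <- function(chain, grid, g = 9.81) {
  N <- grid$N
  cross2 <- function(r, f) r[, 1] * f[, 2] - r[, 2] * f[, 1]
  F_prev <- matrix(0, N, 2); tau_prev <- numeric(N); joint_prev <- NULL
  out <- vector("list", length(chain))
  for (k in seq_along(chain)) {
    lk <- chain[[k]]
    acc <- spectral_derivative(lk$com, grid, order = 2)
    alpha <- spectral_derivative(unwrap_angle(lk$ang), grid, order = 2)
    ext <- if (is.null(lk$ext_force)) matrix(0, N, 2) else lk$ext_force
    grav <- cbind(rep(0, N), -lk$mass * g)
    Fk <- lk$mass * acc + F_prev - grav - ext
    tau <- lk$inertia * alpha + tau_prev -
      cross2(lk$joint - lk$com, Fk) -
      if (is.null(lk$ext_cop)) 0 else cross2(lk$ext_cop - lk$com, ext)
    if (!is.null(joint_prev))
      tau <- tau + cross2(joint_prev - lk$com, F_prev)
    out[[k]] <- list(force = Fk, torque = tau)
    F_prev <- Fk; tau_prev <- tau; joint_prev <- lk$joint
  }
  out
}

# Link CoM series and link angles from an assimilation fit: the fit's frames
# (landmark frames for the periodic method, marker frames for the baseline)
# plus the topology's CoM-in-landmark-frame geometry.
rebuild_kinematics <- function(fit) {
  topo <- fit$topology
  lk <- lapply(topo$links, function(l) {
    com <- if (!is.null(topo$com_local[[l]]))
      to_global(fit$frames[[l]], topo$com_local[[l]])
    else fit$frames[[l]]$o
    list(com = com, ang = fit$frames[[l]]$ang + topo$axis_offset[[l]])
  })
  names(lk) <- topo$links
  list(link_kin = lk, joints = fit$joints)
}

#' Planar inverse dynamics of the seven-link gait model
#'
#' Recursive Newton-Euler per leg, foot to shank to thigh, using the supplied
#' per-foot ground reaction force and centre of pressure; accelerations come
#' from spectral differentiation of the periodic CoM and angle series.
#' Reported torques follow the model's clockwise-positive angle convention.
#'
#' @param kin either the output of [gait_kinematics()] (or a [gait_fixture()]
#'   entry `$kin`) or an `sta_assim` fit, from which CoM kinematics are
#'   rebuilt via the topology's CoM geometry.
#' @param params a [gait_params()].
#' @param grf a [gait_grf()] result (the same object should be used for every
#'   kinematics input being compared).
#' @param grid a [cycle_grid()] with `period` set.
#' @param g gravitational acceleration, m/s^2 (default 9.81, acting in -y).
#' @return list with per-joint torque series (N m, clockwise positive), named
#'   `l-H`, `l-K`, `l-A`, `r-H`, `r-K`, `r-A`.
#' @export
inverse_dynamics <- function(kin, params, grf, grid, g = 9.81) {
  if (inherits(kin, "sta_assim")) kin <- rebuild_kinematics(kin)
  if (!is.null(kin$kin)) kin <- kin$kin
  lk <- kin$link_kin; joints <- kin$joints
  if (is.null(lk) || is.null(joints))
    stop("inverse_dynamics: kin must carry link_kin and joints")
  if (nrow(lk[[1]]$com) != grid$N)
    stop("inverse_dynamics: kinematics and grid sample counts differ")
  torque <- list()
  for (s in c("l", "r")) {
    fgrf <- if (s == "l") grf$left else grf$right
    chain <- list(
      c(lk[[paste0(s, "-F")]],
        list(mass = params$m_Foot, inertia = params$I_Foot,
             joint = joints[[paste0(s, "-A")]],
             ext_force = fgrf$force, ext_cop = fgrf$cop)),
      c(lk[[paste0(s, "-S")]],
        list(mass = params$m_Shank, inertia = params$I_Shank,
             joint = joints[[paste0(s, "-K")]])),
      c(lk[[paste0(s, "-T")]],
        list(mass = params$m_Thigh, inertia = params$I_Thigh,
             joint = joints[[paste0(s, "-H")]])))
    ne <- newton_euler_chain(chain, grid, g = g)
    # clockwise-positive reporting matches the joint-angle sign convention
    torque[[paste0(s, "-A")]] <- -ne[[1]]$torque
    torque[[paste0(s, "-K")]] <- -ne[[2]]$torque
    torque[[paste0(s, "-H")]] <- -ne[[3]]$torque
  }
  torque[c("l-H", "r-H", "l-K", "r-K", "l-A", "r-A")]
}

#' Compare an assimilation against the true kinematics
#'
#' Computes per-angle and per-torque error series with max-abs and RMS
#' summaries, and the per-link estimated length series (mean and within-cycle
#' range). The same ground reaction force is applied to both kinematics, so
#' torque differences reflect the kinematic errors only.
#'
#' @param truth a [gait_kinematics()] output or [gait_fixture()] list.
#' @param fit an `sta_assim` fit of the corresponding markers.
#' @param grf a [gait_grf()] result.
#' @param params a [gait_params()].
#' @return list with `angle` (per-angle list of `error`, `max_abs`, `rms`),
#'   `torque` (likewise per joint), `length` (per-link `mean`, `range`,
#'   `series`), and the two torque sets.
#' @export
evaluate_assimilation <- function(truth, fit, grf, params = gait_params()) {
  kin <- if (!is.null(truth$kin)) truth$kin else truth
  grid <- kin$grid
  ang_t <- c(list(root = kin$angles$root), kin$angles$joint)
  ang_e <- c(list(root = fit$angles$root), fit$angles$joint)
  angle <- lapply(names(ang_t), function(nm) {
    err <- ang_e[[nm]] - ang_t[[nm]]
    list(error = err, max_abs = max(abs(err)), rms = sqrt(mean(err^2)))
  })
  names(angle) <- names(ang_t)
  tau_t <- inverse_dynamics(kin, params, grf, grid)
  tau_e <- inverse_dynamics(fit, params, grf, grid)
  torque <- lapply(names(tau_t), function(nm) {
    err <- tau_e[[nm]] - tau_t[[nm]]
    list(error = err, max_abs = max(abs(err)), rms = sqrt(mean(err^2)))
  })
  names(torque) <- names(tau_t)
  len <- lapply(fit$lengths, function(x)
    list(mean = mean(x), range = diff(range(x)), series = x))
  list(angle = angle, torque = torque, length = len,
       tau_true = tau_t, tau_est = tau_e)
}
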