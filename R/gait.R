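#' Body-segment parameters of the seven-link sagittal-plane model
#'
#' Masses, lengths, CoM-joint offsets and moments of inertia of the
#' head-arms-trunk (HAT), thigh, shank and foot links of a planar seven-link
#' human walking model. Defaults are the standard parameter set for this
#' model.
#'
#' @param ... named overrides of individual entries.
#' @return named list of class `"gait_params"` (units: kg, m, kg m^2).
#' @export
gait_params <- function(...) {
  p <- list(
    m_HAT = 40.548, m_Thigh = 6.882, m_Shank = 3.162, m_Foot = 0.682,
    l_HAT = 0.536, l_Thigh = 0.420, l_Shank = 0.379, l_Foot = 0.122,
    d_HAT_Hip = 0.204, d_Hip_Thigh = 0.200, d_Knee_Shank = 0.154,
    d_Ankle_Foot = 0.050, d_Ankle_Heel = 0.079,
    I_HAT = 1.09933, I_Thigh = 0.09485, I_Shank = 0.03001, I_Foot = 0.00014)
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("gait_params: unknown parameter(s): ",
                        paste(bad, collapse = ", "))
  p[names(over)] <- over
  if (any(unlist(p) <= 0)) stop("gait_params: all parameters must be positive")
  structure(p, class = "gait_params")
}

# Link-frame geometry of the fixture (x-axis from CoM toward the distal end).
# Foot: ankle sits above and slightly behind the CoM; heel and metatarsal lie
# on the frame's x-axis, d_Ankle_Heel from the ankle and l_Foot apart.
seven_link_geometry <- function(p) {
  foot_ankle <- c(-0.03, sqrt(p$d_Ankle_Foot^2 - 0.03^2))
  heel_x <- foot_ankle[1] - sqrt(p$d_Ankle_Heel^2 - foot_ankle[2]^2)
  list(
    hat_hip   = c(p$d_HAT_Hip, 0),
    thigh_hip  = c(-p$d_Hip_Thigh, 0),
    thigh_knee = c(p$l_Thigh - p$d_Hip_Thigh, 0),
    shank_knee  = c(-p$d_Knee_Shank, 0),
    shank_ankle = c(p$l_Shank - p$d_Knee_Shank, 0),
    foot_ankle = foot_ankle,
    foot_heel  = c(heel_x, 0),
    foot_toe   = c(heel_x + p$l_Foot, 0),
    hat_lm  = rbind(c(-0.30, 0), c(0, 0)))   # C7-like and xiphoid-like
}

#' Seven-link gait topology
#'
#' Links HAT, left/right thigh (`l-T`, `r-T`), shank (`l-S`, `r-S`) and foot
#' (`l-F`, `r-F`), connected by the hip, knee and ankle pin joints of each
#' leg. Landmark pairs sit on each link's long axis (thigh: hip and knee
#' ends; shank: knee and ankle ends; HAT: C7-like and xiphoid-like points;
#' foot: heel and metatarsal), so every landmark frame's x-axis coincides with
#' the link frame's and the frame-to-frame `axis_offset` is zero. The ankle's
#' `neutral_offset` of `pi/2` accounts for the foot frame being horizontal in
#' the upright reference posture while the shank frame points down.
#'
#' @param params a [gait_params()].
#' @return a [linkage_topology()] carrying landmark local positions and the
#'   CoM position in each link's landmark frame.
#' @export
seven_link_topology <- function(params = gait_params()) {
  g <- seven_link_geometry(params)
  links <- c("HAT", "l-T", "r-T", "l-S", "r-S", "l-F", "r-F")
  joints <- data.frame(
    joint = c("l-H", "r-H", "l-K", "r-K", "l-A", "r-A"),
    proximal = c("HAT", "HAT", "l-T", "r-T", "l-S", "r-S"),
    distal = c("l-T", "r-T", "l-S", "r-S", "l-F", "r-F"),
    neutral_offset = c(0, 0, 0, 0, pi / 2, pi / 2),
    stringsAsFactors = FALSE)
  lm <- list(HAT = g$hat_lm)
  for (s in c("l", "r")) {
    lm[[paste0(s, "-T")]] <- rbind(g$thigh_hip, g$thigh_knee)
    lm[[paste0(s, "-S")]] <- rbind(g$shank_knee, g$shank_ankle)
    lm[[paste0(s, "-F")]] <- rbind(g$foot_heel, g$foot_toe)
  }
  # CoM (link-frame origin) expressed in each landmark frame: landmark frames
  # share the link frame's axes, origin at the landmark midpoint.
  com <- lapply(lm, function(m) -colMeans(m))
  linkage_topology(links, joints, root = "HAT", upright_angle = -pi / 2,
                   landmarks = lm, com_local = com)
}

default_gait_options <- function() {
  list(period = 1.1, hat_height = 1.05, sway = 0.02, bob = 0.02,
       progression = 0,
       hip_amp = 0.30, hip_amp2 = 0.06,
       knee_mean = 0.55, knee_amp = 0.50, knee_phase = 2.5, knee_amp2 = 0.05,
       ankle_amp = 0.18, ankle_phase = 1.2, ankle_amp2 = 0.10,
       ankle_phase2 = 0.8,
       hat_amp = 0.04, hat_phase = 0.5,
       stance_fraction = 0.62)
}

# Prescribed band-limited joint-angle trajectories with gait-like ranges
# (hip ~ +/-0.35 rad, knee ~ 0..1.1 rad, ankle ~ +/-0.3 rad, HAT tilt
# ~ +/-0.05 rad); the two legs are half a cycle out of phase.
gait_angle_program <- function(grid, opt) {
  u <- grid$phase
  leg <- function(u) list(
    hip = opt$hip_amp * cos(u) + opt$hip_amp2 * sin(2 * u),
    knee = opt$knee_mean + opt$knee_amp * cos(u - opt$knee_phase) +
      opt$knee_amp2 * sin(2 * u),
    ankle = opt$ankle_amp * sin(u + opt$ankle_phase) +
      opt$ankle_amp2 * sin(2 * u + opt$ankle_phase2))
  l <- leg(u); r <- leg(u + pi)
  list(root = opt$hat_amp * sin(2 * u + opt$hat_phase),
       joint = list(`l-H` = l$hip, `r-H` = r$hip,
                    `l-K` = l$knee, `r-K` = r$knee,
                    `l-A` = l$ankle, `r-A` = r$ankle))
}

#' Generate true (artifact-free) seven-link gait kinematics
#'
#' Prescribes smooth, band-limited periodic joint-angle trajectories with
#' gait-like ranges and a periodic HAT translation (a treadmill-style frame:
#' the cycle closes exactly), then runs forward kinematics through the chain.
#' All link lengths are exactly the model parameters at every sample, so the
#' output is an exactly rigid, exactly periodic pin-jointed motion that
#' downstream modules can treat as ground truth.
#'
#' @param params a [gait_params()].
#' @param grid a [cycle_grid()]; its `period` defaults from the options.
#' @param options named overrides of the gait program (amplitudes, phases,
#'   `hat_height`, `sway`, `bob`, `stance_fraction`, `period`).
#' @return list with `topology`, `angles` (root tilt + per-joint series,
#'   clockwise positive), `link_kin` (per-link CoM series and link-frame
#'   angle), `poses` (per-link link-frame [pose_series()]), `joints`
#'   (per-joint global trajectories), `grid`, `params`, `options`.
#' @export
gait_kinematics <- function(params = gait_params(), grid = cycle_grid(200),
                            options = list()) {
  opt <- utils::modifyList(default_gait_options(), options)
  if (is.null(grid$period)) grid$period <- opt$period
  g <- seven_link_geometry(params)
  topo <- seven_link_topology(params)
  ang <- gait_angle_program(grid, opt)
  u <- grid$phase
  o_hat <- cbind(opt$sway * sin(u) + opt$progression * u / (2 * pi),
                 opt$hat_height + opt$bob * cos(2 * u))
  phi <- list(HAT = -pi / 2 - ang$root)
  for (s in c("l", "r")) {
    phi[[paste0(s, "-T")]] <- phi$HAT - ang$joint[[paste0(s, "-H")]]
    phi[[paste0(s, "-S")]] <- phi[[paste0(s, "-T")]] - ang$joint[[paste0(s, "-K")]]
    phi[[paste0(s, "-F")]] <- phi[[paste0(s, "-S")]] -
      ang$joint[[paste0(s, "-A")]] + pi / 2
  }
  rotxy <- function(a, v) cbind(cos(a) * v[1] - sin(a) * v[2],
                                sin(a) * v[1] + cos(a) * v[2])
  com <- list(HAT = o_hat)
  joints <- list()
  for (s in c("l", "r")) {
    Tn <- paste0(s, "-T"); Sn <- paste0(s, "-S"); Fn <- paste0(s, "-F")
    hip <- o_hat + rotxy(phi$HAT, g$hat_hip)
    com[[Tn]] <- hip - rotxy(phi[[Tn]], g$thigh_hip)
    knee <- com[[Tn]] + rotxy(phi[[Tn]], g$thigh_knee)
    com[[Sn]] <- knee - rotxy(phi[[Sn]], g$shank_knee)
    ankle <- com[[Sn]] + rotxy(phi[[Sn]], g$shank_ankle)
    com[[Fn]] <- ankle - rotxy(phi[[Fn]], g$foot_ankle)
    joints[[paste0(s, "-H")]] <- hip
    joints[[paste0(s, "-K")]] <- knee
    joints[[paste0(s, "-A")]] <- ankle
  }
  poses <- lapply(topo$links, function(l) pose_series(com[[l]], phi[[l]]))
  names(poses) <- topo$links
  link_kin <- lapply(topo$links, function(l) list(com = com[[l]], ang = phi[[l]]))
  names(link_kin) <- topo$links
  list(topology = topo, angles = ang, link_kin = link_kin, poses = poses,
       joints = joints[topo$joints$joint], grid = grid, params = params,
       options = opt)
}

#' Landmark-marker trajectories of a link-pose set
#'
#' Maps each link's two landmark local positions (from the topology) through
#' its link-frame pose series, giving the global trajectories of the
#' artifact-free landmark markers (two per link).
#'
#' @param poses named list of link-frame [pose_series()].
#' @param topology a [linkage_topology()] carrying `landmarks`.
#' @param grid a [cycle_grid()].
#' @return a [marker_set()] with `2 * length(links)` trajectories.
#' @export
landmark_trajectories <- function(poses, topology, grid) {
  m <- list()
  for (l in topology$links) {
    lm <- topology$landmarks[[l]]
    if (is.null(lm)) stop("landmark_trajectories: topology has no landmarks for ", l)
    m[[paste0(l, "1")]] <- to_global(poses[[l]], lm[1, ])
    m[[paste0(l, "2")]] <- to_global(poses[[l]], lm[2, ])
  }
  marker_set(m, grid, topology)
}

#' Seeded periodic STA profiles
#'
#' Draws per-marker, per-axis Fourier coefficients uniformly in
#' `amplitude * (-1, 1) / k` (a `1/k` harmonic decay), reproducibly from the
#' seed. The default centimeter-scale amplitude matches skin-marker artifact
#' magnitudes reported for gait.
#'
#' @param seed integer seed.
#' @param markers character vector of marker names (or a [marker_set()]).
#' @param K expansion order (default 4).
#' @param amplitude base amplitude in meters (default 0.01); 0 gives zero
#'   artifact.
#' @return named list of [sta_coeffs()], one per marker, with attributes
#'   `seed` and `amplitude`.
#' @export
sta_profiles <- function(seed, markers, K = 4, amplitude = 0.01) {
  if (inherits(markers, "marker_set")) markers <- names(markers$m)
  if (amplitude < 0) stop("sta_profiles: amplitude must be >= 0")
  set.seed(as.integer(seed))
  decay <- rep(1 / seq_len(K), 2)      # cosine block then sine block
  out <- lapply(markers, function(mk) {
    sta_coeffs(stats::runif(2 * K, -amplitude, amplitude) * decay,
               stats::runif(2 * K, -amplitude, amplitude) * decay)
  })
  names(out) <- markers
  attr(out, "seed") <- seed
  attr(out, "amplitude") <- amplitude
  out
}

#' Seed presets emulating a panel of subjects
#'
#' @param base base integer seed.
#' @param n number of subjects (default 7).
#' @return integer vector of `n` derived seeds.
#' @export
subject_seeds <- function(base = 1, n = 7) as.integer(base) * 100L + seq_len(n)

#' Inject periodic STA into landmark-marker trajectories
#'
#' Adds each marker's evaluated Fourier artifact in its link's landmark frame
#' and maps it out through the frame's rotation:
#' `m[n] = o_lm[n] + R_lm[n] (m_local + e[n])`, which given artifact-free
#' input markers equals `m_clean[n] + R_lm[n] e[n]`.
#'
#' @param landmarks a [marker_set()] of artifact-free landmark markers.
#' @param lm_frames named list of landmark-frame [pose_series()] per link
#'   (e.g. from [marker_frames()] on the clean markers).
#' @param profiles per-marker [sta_coeffs()] list from [sta_profiles()].
#' @param topology a [linkage_topology()].
#' @return a [marker_set()] of artifact-affected markers.
#' @export
inject_sta <- function(landmarks, lm_frames, profiles, topology) {
  out <- landmarks$m
  for (l in topology$links) {
    ca <- cos(lm_frames[[l]]$ang); sa <- sin(lm_frames[[l]]$ang)
    for (j in 1:2) {
      mk <- paste0(l, j)
      e <- eval_sta(profiles[[mk]], landmarks$grid)
      out[[mk]] <- out[[mk]] + cbind(ca * e[, 1] - sa * e[, 2],
                                     sa * e[, 1] + ca * e[, 2])
    }
  }
  marker_set(out, landmarks$grid, topology)
}

#' Synthetic periodic ground reaction forces
#'
#' Smooth periodic per-foot vertical force (double-hump over stance, zero in
#' swing, scaled so the cycle-mean total vertical force equals body weight),
#' a small braking-then-propulsion horizontal component, and a
#' heel-to-metatarsal progressing centre of pressure. The same GRF is meant
#' to be supplied to the true and the assimilated kinematics, so torque
#' comparisons do not depend on its exact shape.
#'
#' @param grid a [cycle_grid()].
#' @param params a [gait_params()].
#' @param kin optional [gait_kinematics()] output used to place the centre of
#'   pressure under the moving foot; without it the CoP progresses over a
#'   nominal foot line at the origin.
#' @param options list; `stance_fraction` in (0, 1) (default 0.62; left
#'   stance starts at phase 0, right half a cycle later).
#' @param g gravitational acceleration, m/s^2.
#' @return list with `left`/`right` (each `force` `N x 2` in newtons, `cop`
#'   `N x 2` in meters, `stance` logical mask) and `weight` (N).
#' @export
gait_grf <- function(grid, params = gait_params(), kin = NULL,
                     options = list(), g = 9.81) {
  opt <- utils::modifyList(default_gait_options(), options)
  fr <- opt$stance_fraction
  if (fr <= 0 || fr >= 1) stop("gait_grf: stance_fraction must be in (0, 1)")
  mass <- params$m_HAT + 2 * (params$m_Thigh + params$m_Shank + params$m_Foot)
  W <- mass * g
  ph <- grid$phase / (2 * pi)            # cycle fraction in (0, 1]
  one_foot <- function(offset, heel, toe) {
    s <- (ph - offset) %% 1 / fr         # normalised stance phase
    stance <- s < 1
    s[!stance] <- 0
    hump <- sin(pi * s)^2 * (1 + 0.6 * cos(2 * pi * s))
    fy <- ifelse(stance, hump, 0)
    fx <- ifelse(stance, -0.15 * sin(2 * pi * s) * sin(pi * s), 0)
    if (is.null(heel)) {
      cop <- cbind(-0.05 + 0.12 * s, 0)
    } else {
      cop <- cbind((1 - s) * heel[, 1] + s * toe[, 1], 0)
    }
    list(fy = fy, fx = fx, cop = cop, stance = stance)
  }
  lmk <- if (!is.null(kin))
    landmark_trajectories(kin$poses, kin$topology, grid)
  hp <- function(side, which) {
    if (is.null(lmk)) NULL else lmk$m[[paste0(side, "-F", which)]]
  }
  L <- one_foot(0, hp("l", 1), hp("l", 2))
  R <- one_foot(0.5, hp("r", 1), hp("r", 2))
  scale <- W / mean(L$fy + R$fy)
  pack <- function(f) list(force = cbind(f$fx * W, f$fy * scale),
                           cop = f$cop, stance = f$stance)
  list(left = pack(L), right = pack(R), weight = W)
}

#' One-stop seven-link gait fixture with seeded STA injection
#'
#' Generates the full synthetic evaluation setup: true kinematics, clean
#' landmark markers, seeded periodic artifact profiles, artifact-affected
#' markers, and ground reaction forces.
#'
#' @param seed integer seed driving the artifact draw.
#' @param N samples per cycle (default 200).
#' @param sta_amplitude artifact amplitude in meters (default 0.01).
#' @param K artifact Fourier order (default 4).
#' @param params a [gait_params()].
#' @param options gait program overrides (see [gait_kinematics()]).
#' @return list with `topology`, `grid`, `params`, `kin` (true kinematics),
#'   `angles`, `joints`, `poses`, `landmarks` (clean [marker_set()]),
#'   `lm_frames` (true landmark frames), `profiles`, `markers`
#'   (artifact-affected [marker_set()]), `grf`, `seed`.
#' @export
gait_fixture <- function(seed = 1, N = 200, sta_amplitude = 0.01, K = 4,
                         params = gait_params(), options = list()) {
  opt <- utils::modifyList(default_gait_options(), options)
  grid <- cycle_grid(N, period = opt$period)
  kin <- gait_kinematics(params, grid, opt)
  landmarks <- landmark_trajectories(kin$poses, kin$topology, grid)
  lm_frames <- marker_frames(landmarks, kin$topology)
  profiles <- sta_profiles(seed, names(landmarks$m), K = K,
                           amplitude = sta_amplitude)
  markers <- inject_sta(landmarks, lm_frames, profiles, kin$topology)
  grf <- gait_grf(grid, params, kin = kin, options = opt)
  list(topology = kin$topology, grid = grid, params = params, kin = kin,
       angles = kin$angles, joints = kin$joints, poses = kin$poses,
       landmarks = landmarks, lm_frames = lm_frames, profiles = profiles,
       markers = markers, grf = grf, seed = seed)
}
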