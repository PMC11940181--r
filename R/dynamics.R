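#' Torque-driven spring-damper pose simulation
#'
#' Integrates the decoupled per-joint-axis dynamics
#' `I th'' = tau(t) - k (th - th0) - c th' + limit penalty`
#' with a fixed-step classical 4th-order Runge-Kutta scheme.  The limit
#' penalty is a one-sided stiff torsional spring engaging outside the joint's
#' angular range (anatomical joint laxity constrained by ligaments).  Each
#' axis uses the chain inertia frozen at the rest pose.  This lumped
#' per-articulation model is a deliberate simplification of fully coupled
#' rigid-body dynamics; it is closed-form testable against the damped
#' harmonic oscillator.
#'
#' @param skeleton a `rebiom_hand`
#' @param torque named numeric vector (constant torque, N.mm) or a function
#'   `tau(t)` returning one; missing axes get 0
#' @param duration simulated time (s)
#' @param dt fixed step (s)
#' @param init optional named starting angles (rad); default rest pose
#' @param limit_gain stiffness multiplier of the one-sided limit spring
#' @param record_every store every n-th step (default 10)
#' @return object of class `rebiom_trajectory`: `time`, `angles` (matrix,
#'   one row per stored sample), `velocity`, `energy` (spring + kinetic, per
#'   stored sample), `fingertips` (list of 5x3 matrices, one per sample)
#' @export
simulate_pose <- function(skeleton, torque = NULL, duration = 0.05, dt = 1e-4,
                          init = NULL, limit_gain = 400, record_every = 10L) {
  stopifnot(dt > 0, duration > 0)
  ax <- skeleton$axis_names
  n <- length(ax)
  k <- c <- I <- th0 <- lo <- hi <- numeric(n)
  i <- 1L
  for (j in skeleton$joints) for (a in seq_len(nrow(j$axes))) {
    k[i] <- j$k
    c[i] <- if (length(j$c) >= a) j$c[a] else j$c[1]
    I[i] <- j$inertia[a]
    th0[i] <- j$theta0[a]
    lo[i] <- j$limits[a, 1]; hi[i] <- j$limits[a, 2]
    i <- i + 1L
  }
  names(k) <- unlist(lapply(skeleton$joints, `[[`, "axis_names"))
  ord <- match(ax, names(k))
  k <- k[ord]; c <- c[ord]; I <- I[ord]; th0 <- th0[ord]
  lo <- lo[ord]; hi <- hi[ord]

  tau_fn <- if (is.function(torque)) {
    function(t) expand_named(torque(t), ax)
  } else {
    tv <- expand_named(torque, ax)
    function(t) tv
  }
  th <- expand_named(init, ax) + 0
  if (!is.null(init)) th <- expand_named(init, ax)
  w <- numeric(n)
  accel <- function(t, th, w) {
    pen <- limit_gain * k * (pmax(lo - th, 0) - pmax(th - hi, 0))
    (tau_fn(t) - k * (th - th0) - c * w + pen) / I
  }
  n_steps <- ceiling(duration / dt)
  keep <- seq(0, n_steps, by = record_every)
  times <- keep * dt
  A <- matrix(0, length(keep), n, dimnames = list(NULL, ax))
  W <- matrix(0, length(keep), n, dimnames = list(NULL, ax))
  E <- numeric(length(keep))
  store <- function(slot, th, w) {
    A[slot, ] <<- th; W[slot, ] <<- w
    E[slot] <<- sum(0.5 * I * w^2 + 0.5 * k * (th - th0)^2)
  }
  slot <- 1L
  store(slot, th, w)
  for (s in seq_len(n_steps)) {
    t <- (s - 1) * dt
    k1w <- accel(t, th, w);                k1t <- w
    k2w <- accel(t + dt / 2, th + dt / 2 * k1t, w + dt / 2 * k1w)
    k2t <- w + dt / 2 * k1w
    k3w <- accel(t + dt / 2, th + dt / 2 * k2t, w + dt / 2 * k2w)
    k3t <- w + dt / 2 * k2w
    k4w <- accel(t + dt, th + dt * k3t, w + dt * k3w)
    k4t <- w + dt * k3w
    th <- th + dt / 6 * (k1t + 2 * k2t + 2 * k3t + k4t)
    w <- w + dt / 6 * (k1w + 2 * k2w + 2 * k3w + k4w)
    if (any(!is.finite(w)) || max(abs(w)) > 1e6)
      stop("integration unstable (joint velocity diverging); reduce dt")
    if (s %in% keep) { slot <- slot + 1L; store(slot, th, w) }
  }
  tips <- lapply(seq_along(times), function(r)
    forward_kinematics(skeleton, clamp_to_limits(skeleton, A[r, ]),
                       check_limits = FALSE)$fingertips)
  structure(list(time = times, angles = A, velocity = W, energy = E,
                 fingertips = tips),
            class = "rebiom_trajectory")
}

expand_named <- function(x, ax) {
  out <- stats::setNames(rep(0, length(ax)), ax)
  if (!is.null(x)) {
    if (is.null(names(x)) && length(x) == length(ax)) names(x) <- ax
    out[names(x)] <- x
  }
  out
}

clamp_to_limits <- function(skeleton, angles) {
  th <- expand_named(angles, skeleton$axis_names)
  for (j in skeleton$joints) {
    a <- th[j$axis_names]
    th[j$axis_names] <- pmin(pmax(a, j$limits[, 1]), j$limits[, 2])
  }
  th
}

#' Build a pose trajectory from key poses
#'
#' Linearly interpolates between successive named poses (each a named angle
#' vector) on a uniform time grid, clamping to joint limits; used to realise
#' reference pose bundles.
#'
#' @param skeleton a `rebiom_hand`
#' @param poses list of named angle vectors (way-points)
#' @param samples_per_leg interpolation samples between way-points
#' @param dt nominal time step between samples (s)
#' @return a `rebiom_trajectory` (with `waypoint_index` marking the sample of
#'   each way-point)
#' @export
make_trajectory <- function(skeleton, poses, samples_per_leg = 5L, dt = 0.01) {
  ax <- skeleton$axis_names
  mats <- lapply(poses, expand_named, ax = ax)
  rows <- list(mats[[1]])
  wp <- 1L
  for (p in seq_len(length(mats) - 1)) {
    for (s in seq_len(samples_per_leg)) {
      a <- s / samples_per_leg
      rows[[length(rows) + 1]] <- (1 - a) * mats[[p]] + a * mats[[p + 1]]
    }
    wp <- c(wp, length(rows))
  }
  A <- do.call(rbind, rows)
  A <- t(apply(A, 1, function(r) clamp_to_limits(skeleton, r)))
  colnames(A) <- ax
  times <- (seq_len(nrow(A)) - 1) * dt
  tips <- lapply(seq_len(nrow(A)), function(r)
    forward_kinematics(skeleton, A[r, ], check_limits = FALSE)$fingertips)
  structure(list(time = times, angles = A, velocity = NULL,
                 energy = NULL, fingertips = tips, waypoint_index = wp),
            class = "rebiom_trajectory")
}

#' @export
print.rebiom_trajectory <- function(x, ...) {
  cat(sprintf("<pose trajectory: %d samples over %.3f s, %d axes>\n",
              nrow(x$angles), max(x$time), ncol(x$angles)))
  invisible(x)
}
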