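#' Reference pose-trajectory bundle
#'
#' Constructs the clinical reference motions for a built skeleton:
#' the Kapandji opposition sequence (positions 0-10, thumb driven to each
#' target by damped-least-squares inverse kinematics within joint limits),
#' the seven Fugl-Meyer positions (placed inside the default template
#' bands), per-finger pinch poses, the peace/rock/three dactylonomy signs,
#' and a spherical-grasp pose.
#'
#' @param skeleton a `rebiom_hand`
#' @param kapandji_tol IK acceptance distance per target (mm); targets that
#'   cannot be reached within limits raise an error naming the position
#' @return list: `kapandji` (`rebiom_trajectory` + `poses` + `residuals`),
#'   `fma_poses` (named list of 7 angle vectors), `pinch` (list per finger),
#'   `signs` (named list), `grasp_spherical` (angle vector)
#' @export
gen_trajectories <- function(skeleton, kapandji_tol = 4) {
  targets <- skeleton$kapandji_targets
  poses <- list()
  residuals <- numeric(nrow(targets))
  for (i in seq_len(nrow(targets))) {
    ik <- ik_thumb(skeleton, targets[i, ])
    if (ik$residual > kapandji_tol)
      stop(sprintf("Kapandji position %d unreachable within joint limits (residual %.1f mm)",
                   i - 1L, ik$residual))
    poses[[i]] <- ik$angles
    residuals[i] <- ik$residual
  }
  kap_traj <- make_trajectory(skeleton, poses, samples_per_leg = 4L)

  tpl <- fma_templates(skeleton)
  fma_poses <- lapply(tpl, function(t) {
    th <- stats::setNames((t$min + t$max) / 2, t$axis)
    clamp_to_limits(skeleton, th)[t$axis]
  })

  curl <- function(d, mcp, pip, dip = 0) {
    short <- as.character(d)
    if (d == 1)
      stats::setNames(c(mcp, pip), c("MCP1_flex", "IP1"))
    else
      stats::setNames(c(mcp, pip, dip),
                      paste0(c("MCP", "PIP", "DIP"), short,
                             c("_flex", "", "")))
  }
  pinch <- lapply(2:5, function(d) {
    tip_target <- forward_kinematics(skeleton,
                                     curl(d, 0.5, 0.7, 0.4),
                                     check_limits = FALSE)$fingertips[d, ]
    ik <- ik_thumb(skeleton, tip_target, base = curl(d, 0.5, 0.7, 0.4))
    ik$angles
  })
  names(pinch) <- c("index", "middle", "ring", "small")

  full_curl <- function(ds) {
    Reduce(c, lapply(ds, function(d) curl(d, 1.0, 1.3, 0.9)))
  }
  signs <- list(
    peace = c(full_curl(c(4, 5)), curl(1, 0.6, 0.8)),
    rock = c(full_curl(c(3, 4))),
    three = c(full_curl(c(5)), curl(1, 0.6, 0.8))
  )
  # the rest pose is already semi-flexed, so the spherical grasp (67 mm
  # ball) needs only a light additional curl to put all five tips on the
  # sphere shell
  grasp <- clamp_to_limits(skeleton, c(
    stats::setNames(rep(0.09, 4), paste0("MCP", 2:5, "_flex")),
    stats::setNames(rep(0.10, 4), paste0("PIP", 2:5)),
    stats::setNames(rep(0.06, 4), paste0("DIP", 2:5)),
    CMC1_flex = 0.10, MCP1_flex = 0.075, IP1 = 0.075))
  kap_traj$poses <- poses
  kap_traj$residuals <- residuals
  list(kapandji = kap_traj,
       fma_poses = fma_poses, pinch = pinch, signs = signs,
       grasp_spherical = grasp)
}

#' Damped-least-squares thumb inverse kinematics
#'
#' Drives the thumb tip toward a 3D target over the thumb's five joint axes
#' (CMC flex/abd, MCP flex/abd, IP), projecting onto joint limits each step.
#' Other joints are held at `base` (default rest).
#'
#' @param skeleton a `rebiom_hand`
#' @param target 3-vector (mm)
#' @param base named angles for the non-thumb joints
#' @param max_iter,lambda iteration cap and damping factor
#' @return list: `angles` (full named pose), `residual` (mm)
#' @export
ik_thumb <- function(skeleton, target, base = NULL, max_iter = 120L,
                     lambda = 4) {
  ax <- c("CMC1_flex", "CMC1_abd", "MCP1_flex", "MCP1_abd", "IP1")
  th <- expand_named(base, skeleton$axis_names)
  lim <- limits_for(skeleton, ax)
  tip <- function(th) forward_kinematics(skeleton, th,
                                         check_limits = FALSE)$fingertips[1, ]
  cur <- tip(th)
  best <- list(th = th, res = sqrt(sum((cur - target)^2)))
  h <- 1e-4
  for (it in seq_len(max_iter)) {
    err <- target - cur
    res <- sqrt(sum(err^2))
    if (res < best$res) best <- list(th = th, res = res)
    if (res < 1e-3) break
    J <- matrix(0, 3, length(ax))
    for (q in seq_along(ax)) {
      th2 <- th; th2[ax[q]] <- th2[ax[q]] + h
      J[, q] <- (tip(th2) - cur) / h
    }
    JtJ <- crossprod(J) + lambda * diag(length(ax))
    step <- as.vector(solve(JtJ, crossprod(J, err)))
    step <- pmin(pmax(step, -0.25), 0.25)
    th[ax] <- pmin(pmax(th[ax] + step, lim[, 1]), lim[, 2])
    cur <- tip(th)
  }
  res <- sqrt(sum((cur - target)^2))
  if (res < best$res) best <- list(th = th, res = res)
  list(angles = best$th, residual = best$res)
}

limits_for <- function(skeleton, axes) {
  out <- matrix(0, length(axes), 2)
  for (j in skeleton$joints) {
    hit <- match(j$axis_names, axes)
    ok <- !is.na(hit)
    if (any(ok)) out[hit[ok], ] <- j$limits[ok, , drop = FALSE]
  }
  out
}
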