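#' Kapandji thumb-opposition score
#'
#' Scores a trajectory against the 11 target locations (positions 0-10)
#' derived from the skeleton's rest geometry: a position is achieved when
#' the thumb tip passes within `tolerance` of its target at any trajectory
#' sample.  The score is the highest `n` such that positions 1..n are all
#' achieved (10 = normal thumb function); position 0 is reported in the
#' flags but does not contribute to the score.
#'
#' @param skeleton a `rebiom_hand`
#' @param trajectory a `rebiom_trajectory`
#' @param tolerance touch tolerance in mm (default 5)
#' @return list: `score` (integer 0-10), `achieved` (logical, names
#'   `pos0`..`pos10`), `min_dist` (mm per position)
#' @export
kapandji_score <- function(skeleton, trajectory, tolerance = 5) {
  targets <- skeleton$kapandji_targets
  thumb_tips <- do.call(rbind, lapply(trajectory$fingertips,
                                      function(m) m[1, ]))
  min_dist <- vapply(seq_len(nrow(targets)), function(i)
    min(sqrt(rowSums(sweep(thumb_tips, 2, targets[i, ])^2))), 0)
  achieved <- min_dist <= tolerance
  names(achieved) <- names(min_dist) <- paste0("pos", 0:10)
  run <- achieved[-1]                      # positions 1..10
  score <- if (!run[1]) 0L else {
    miss <- which(!run)
    if (length(miss) == 0) 10L else miss[1] - 1L
  }
  list(score = as.integer(score), achieved = achieved, min_dist = min_dist)
}

#' Default Fugl-Meyer hand-position templates
#'
#' Seven positions (full extension, full flexion, hook grip, key grip,
#' tripod grip, spherical grip, cylindrical grip) expressed as per-joint
#' angle bands relative to the rest pose.  The neutral all-zero pose sits in
#' the full-extension band only.
#'
#' @param skeleton a `rebiom_hand`
#' @return named list; each element is a data.frame with columns `axis`,
#'   `min`, `max`
#' @export
fma_templates <- function(skeleton) {
  ax <- skeleton$axis_names
  flex_f <- grep("^(MCP[2-5]_flex|PIP|DIP)", ax, value = TRUE)
  mcp_f <- grep("^MCP[2-5]_flex", ax, value = TRUE)
  pipdip <- grep("^(PIP|DIP)", ax, value = TRUE)
  thumb_f <- c("CMC1_flex", "MCP1_flex", "IP1")
  band <- function(axes, min, max)
    data.frame(axis = axes, min = min, max = max)
  list(
    full_extension = band(ax, -0.15, 0.15),
    full_flexion = rbind(band(flex_f, 0.55, 1.6), band(thumb_f, 0.3, 1.2)),
    hook_grip = rbind(band(pipdip, 0.7, 1.6), band(mcp_f, -0.25, 0.25)),
    key_grip = rbind(band(mcp_f, 0.4, 1.1), band(grep("^PIP", ax, value = TRUE), 0.4, 1.2),
                     band("CMC1_flex", 0.25, 0.9), band("IP1", 0.25, 1.0)),
    tripod_grip = rbind(band(c("MCP2_flex", "MCP3_flex"), 0.3, 0.9),
                        band(c("PIP2", "PIP3"), 0.3, 1.0),
                        band(c("MCP4_flex", "MCP5_flex"), 0.8, 1.3),
                        band(c("CMC1_flex", "MCP1_flex"), 0.2, 0.9)),
    spherical_grip = rbind(band(mcp_f, 0.2, 0.7), band(pipdip, 0.18, 0.8),
                           band(c("CMC1_flex", "MCP1_flex", "IP1"), 0.15, 0.8)),
    cylindrical_grip = rbind(band(mcp_f, 0.45, 1.05), band(pipdip, 0.5, 1.25),
                             band("CMC1_flex", 0.3, 1.0), band("IP1", 0.3, 1.1))
  )
}

#' Fugl-Meyer pose battery
#'
#' Checks each supplied pose against its position template: pass iff every
#' banded joint angle lies inside its band.
#'
#' @param skeleton a `rebiom_hand`
#' @param poses named list of angle vectors; names must match template names
#' @param templates template list (default [fma_templates()])
#' @return named logical vector of pass flags (one per supplied pose)
#' @export
fma_pose_battery <- function(skeleton, poses, templates = fma_templates(skeleton)) {
  unknown <- setdiff(names(poses), names(templates))
  if (length(unknown) > 0)
    stop("unknown FMA position name(s): ", paste(unknown, collapse = ", "))
  vapply(names(poses), function(nm) {
    th <- expand_named(poses[[nm]], skeleton$axis_names)
    tpl <- templates[[nm]]
    all(th[tpl$axis] >= tpl$min & th[tpl$axis] <= tpl$max)
  }, TRUE)
}

#' Spherical-grip contact force distribution
#'
#' Distributes a prescribed total grip force over the fingertip contacts of
#' a grasp pose: contact magnitudes solve a non-negative least-squares
#' problem minimising the net force-and-torque residual on the gripped
#' sphere subject to the magnitudes summing exactly to `total`.  The
#' equality-and-nonnegativity constrained quadratic programme is solved
#' exactly by active-set enumeration (the contact count is small).
#'
#' @param skeleton a `rebiom_hand`
#' @param pose named angle vector of the grasp
#' @param total total grip force in N (a maximum male grip strength lies
#'   between 400 and 600 N)
#' @param sphere_diameter gripped sphere diameter in mm (default 67)
#' @param sphere_center optional 3-vector; when missing, fitted to the posed
#'   fingertips at the given radius
#' @param contact_tol fingertip-to-surface distance below which a digit is
#'   in contact (mm)
#' @return object of class `rebiom_grip`: `contacts` (data.frame digit,
#'   x, y, z, magnitude), `normals`, `total`, `residual` (net wrench
#'   residual norm)
#' @export
grasp_contact_forces <- function(skeleton, pose, total,
                                 sphere_diameter = 67,
                                 sphere_center = NULL, contact_tol = 6) {
  stopifnot(total > 0)
  r <- sphere_diameter / 2
  tips <- forward_kinematics(skeleton, pose, check_limits = FALSE)$fingertips
  if (is.null(sphere_center)) {
    ctr <- colMeans(tips)
    for (it in 1:50) {
      diff <- sweep(tips, 2, ctr)
      dist <- sqrt(rowSums(diff^2))
      res <- dist - r
      J <- -diff / dist
      step <- tryCatch(qr.solve(J, -res), error = function(e) rep(0, 3))
      ctr <- ctr + step
      if (sqrt(sum(step^2)) < 1e-10) break
    }
    sphere_center <- ctr
  }
  dist <- sqrt(rowSums(sweep(tips, 2, sphere_center)^2))
  in_contact <- abs(dist - r) <= contact_tol
  if (sum(in_contact) < 3)
    stop("grasp not closed: only ", sum(in_contact),
         " fingertip(s) contact the sphere (need >= 3)")
  pts <- tips[in_contact, , drop = FALSE]
  nrm <- normalize_rows(sweep(pts, 2, sphere_center) * -1)  # inward
  sol <- solve_grip_forces(pts, nrm, sphere_center, total)
  structure(list(contacts = data.frame(digit = which(in_contact),
                                       x = pts[, 1], y = pts[, 2], z = pts[, 3],
                                       magnitude = sol$magnitudes),
                 normals = nrm, total = total, residual = sol$residual,
                 sphere_center = sphere_center, radius = r),
            class = "rebiom_grip")
}

#' @export
print.rebiom_grip <- function(x, ...) {
  cat(sprintf("<spherical grip: %d contacts, total %.1f N, wrench residual %.3g>\n",
              nrow(x$contacts), x$total, x$residual))
  invisible(x)
}

#' Sum-constrained non-negative force solver
#'
#' Minimises `|sum m_i n_i|^2 + |sum m_i (p_i - c) x n_i / r|^2` subject to
#' `sum m_i = total`, `m_i >= 0`, by enumerating active sets and solving the
#' KKT system on each support; exact for small contact counts.
#'
#' @param points contact points (k x 3)
#' @param normals inward unit normals (k x 3)
#' @param center sphere centre
#' @param total prescribed total magnitude (N)
#' @return list: `magnitudes` (length k, sums to `total`), `residual`
#' @export
solve_grip_forces <- function(points, normals, center, total) {
  k <- nrow(points)
  stopifnot(k >= 1, nrow(normals) == k, total > 0)
  lever <- sweep(points, 2, center)
  r_scale <- max(sqrt(rowSums(lever^2)), 1)
  A <- rbind(t(normals), t(cross3(lever, normals)) / max(r_scale))
  # tiny ridge: among degenerate zero-residual solutions, pick the
  # minimum-norm one (equal magnitudes under full symmetry)
  ridge <- 1e-9 * max(colSums(A^2), 1)
  best <- NULL
  for (mask in seq_len(2^k - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    As <- A[, S, drop = FALSE]
    H <- 2 * (crossprod(As) + ridge * diag(length(S)))
    KKT <- rbind(cbind(H, rep(1, length(S))), c(rep(1, length(S)), 0))
    sol <- tryCatch(solve(KKT, c(rep(0, length(S)), total)),
                    error = function(e) NULL)
    if (is.null(sol)) next
    m <- sol[seq_along(S)]
    if (any(m < -1e-9)) next
    m <- pmax(m, 0)
    m <- m * total / sum(m)
    obj <- sum((A[, S, drop = FALSE] %*% m)^2) + ridge * sum(m^2)
    if (is.null(best) || obj < best$obj - 1e-12)
      best <- list(obj = obj, m = stats::setNames(rep(0, k), NULL), S = S, ms = m)
  }
  if (is.null(best)) stop("force distribution infeasible")
  mags <- rep(0, k)
  mags[best$S] <- best$ms
  list(magnitudes = mags, residual = sqrt(best$obj))
}
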