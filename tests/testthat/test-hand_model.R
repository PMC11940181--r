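test_that("the default skeleton satisfies every structural count", {
  sk <- default_hand()
  expect_length(sk$bones, 27)
  groups <- vapply(sk$bones, `[[`, "", "group")
  expect_equal(sum(groups == "carpal"), 8)
  expect_equal(sum(groups == "metacarpal"), 5)
  expect_equal(sum(groups %in% c("proximal", "middle", "distal")), 14)
  kinds <- vapply(sk$joints, `[[`, "", "kind")
  expect_equal(sum(kinds == "revolute"), 9)
  expect_equal(sum(kinds == "universal"), 6)
  expect_length(sk$joints, 15)
  expect_equal(enumerate_dof(sk, "model"), 21L)
  expect_equal(enumerate_dof(mode = "anatomical"), 27L)
  # rest pose is interference-free by construction
  expect_equal(nrow(sk$interference), 0)
})

test_that("skeleton assembly rejects malformed inputs", {
  gs <- gen_skeleton()
  broken <- gs$bones
  broken[["dp_small"]] <- NULL
  expect_error(build_skeleton(broken, gs$joints), "27 bones")
  dup <- gs$bones
  dup$dp_small$number <- dup$dp_ring$number
  dup$dp_small$digit <- dup$dp_ring$digit
  expect_error(build_skeleton(dup, gs$joints), "duplicate")
  cyc <- gs$bones
  cyc$pp_index$parent <- "dp_index"
  cyc$mp_index$parent <- "pp_index"
  cyc$dp_index$parent <- "mp_index"
  expect_error(build_skeleton(cyc, gs$joints), "cycle|no path")
  badj <- gs$joints
  badj$PIP_index$limits <- matrix(c(1.5, -1), 1)
  expect_error(build_skeleton(gs$bones, badj), "limits")
})

test_that("removing the thumb chain removes exactly the thumb DoF", {
  sk <- default_hand()
  thumb_joints <- c("CMC_thumb", "MCP_thumb", "IP_thumb")
  reduced <- sk
  reduced$joints <- sk$joints[setdiff(names(sk$joints), thumb_joints)]
  expect_equal(enumerate_dof(reduced, "model"), 21L - 5L)
})

test_that("uniform scaling obeys the length/volume/inertia scaling laws", {
  sk <- default_hand()
  sk2 <- scale_skeleton(sk, 2)
  expect_equal(sk2$bones$mc_index$volume, 8 * sk$bones$mc_index$volume,
               tolerance = 1e-9)
  expect_equal(sk2$bones$mc_index$mass, 8 * sk$bones$mc_index$mass,
               tolerance = 1e-9)
  expect_equal(sk2$joints$MCP_index$inertia,
               32 * sk$joints$MCP_index$inertia, tolerance = 1e-9)
  # fingertip span scales linearly
  span <- function(s) max(stats::dist(s$fingertips))
  expect_equal(span(sk2), 2 * span(sk), tolerance = 1e-9)
  # round trip
  back <- scale_skeleton(sk2, 0.5)
  expect_equal(back$fingertips, sk$fingertips, tolerance = 1e-9)
  expect_equal(back$bones$dp_small$mass, sk$bones$dp_small$mass,
               tolerance = 1e-9)
})

test_that("forward kinematics composes correctly along the chain", {
  sk <- default_hand()
  fk0 <- forward_kinematics(sk)
  for (nm in names(fk0$transforms))
    expect_lt(max(abs(fk0$transforms[[nm]] - diag(4))), 1e-12)
  # single DIP flexion moves only the distal phalanx
  phi <- 0.4
  fk1 <- forward_kinematics(sk, c(DIP3 = phi))
  moved <- names(Filter(function(T) max(abs(T - diag(4))) > 1e-12,
                        fk1$transforms))
  expect_equal(moved, "dp_middle")
  j <- sk$joints$DIP_middle
  want <- rigid_transform(rotation_about_axis(j$axes[1, ], phi),
                          j$cor - rotation_about_axis(j$axes[1, ], phi) %*% j$cor)
  expect_lt(max(abs(fk1$transforms$dp_middle - want)), 1e-12)
  # chain composition equals the explicit product of per-joint matrices
  th <- c(MCP2_flex = 0.3, MCP2_abd = -0.1, PIP2 = 0.5, DIP2 = 0.2)
  fk2 <- forward_kinematics(sk, th)
  about <- function(joint, angles) {
    R <- rotation_about_axis(joint$axes[1, ], angles[1])
    if (nrow(joint$axes) > 1)
      R <- R %*% rotation_about_axis(joint$axes[2, ], angles[2])
    rigid_transform(R, joint$cor - R %*% joint$cor)
  }
  want2 <- about(sk$joints$MCP_index, c(0.3, -0.1)) %*%
    about(sk$joints$PIP_index, 0.5) %*%
    about(sk$joints$DIP_index, 0.2)
  expect_lt(max(abs(fk2$transforms$dp_index - want2)), 1e-12)
  expect_error(forward_kinematics(sk, c(PIP2 = 3)), "out of limits")
})

test_that("pose dynamics match the closed-form damped oscillator", {
  sk <- default_hand()
  # equilibrium: zero torque from rest stays at rest
  tr0 <- simulate_pose(sk, torque = NULL, duration = 0.01, dt = 1e-4)
  expect_lt(max(abs(tr0$angles)), 1e-15)
  # underdamped joint: light damping override on one PIP
  sk2 <- sk
  sk2$joints$PIP_index$c <- 0.05
  tau <- 8
  tr <- simulate_pose(sk2, torque = c(PIP2 = tau), duration = 0.05, dt = 1e-4)
  j <- sk2$joints$PIP_index
  want <- damped_step_response(tr$time, j$inertia[1], 0.05, j$k, tau)
  expect_lt(max(abs(tr$angles[, "PIP2"] - want)), 1e-4)
  # steady state theta0 + tau/k after >= 10 time constants (overdamped default)
  tr2 <- simulate_pose(sk, torque = c(DIP4 = 5), duration = 1.2, dt = 2e-4,
                       record_every = 200)
  expect_equal(unname(tr2$angles[nrow(tr2$angles), "DIP4"]),
               5 / sk$joints$DIP_ring$k,
               tolerance = 1e-3)
})

test_that("dissipation and joint-limit invariants hold along trajectories", {
  sk <- default_hand()
  tr <- simulate_pose(sk, torque = NULL, duration = 0.04, dt = 1e-4,
                      init = c(PIP2 = 0.8, MCP3_flex = 0.5, IP1 = -0.3))
  expect_true(all(diff(tr$energy) <= 1e-12))
  # torque pushing into a limit: violation stays under 0.5 degrees
  tr2 <- simulate_pose(sk, torque = c(DIP2 = 100), duration = 0.4, dt = 5e-5,
                       record_every = 100)
  hi <- sk$joints$DIP_index$limits[1, 2]
  expect_lt(max(tr2$angles[, "DIP2"]) - hi, 0.5 * pi / 180)
})

test_that("Kapandji scoring is correct and monotone", {
  sk <- default_hand()
  bundle <- default_bundle()
  ks <- kapandji_score(sk, bundle$kapandji)
  expect_equal(ks$score, 10L)
  expect_true(all(ks$achieved))
  # rest-pose-only trajectory scores 0
  rest <- make_trajectory(sk, list(sk$rest_pose, sk$rest_pose))
  expect_equal(kapandji_score(sk, rest)$score, 0L)
  # trajectory reaching targets 1-4 only scores 4; adding targets never lowers
  scores <- vapply(2:11, function(k) {
    part <- make_trajectory(sk, bundle$kapandji$poses[1:k],
                            samples_per_leg = 4)
    kapandji_score(sk, part)$score
  }, 0L)
  expect_equal(scores[4], 4L)   # poses for positions 0..4 reach targets 1-4
  expect_true(all(diff(scores) >= 0))
  expect_equal(scores[10], 10L)
})

test_that("the FMA battery passes its reference poses and only those", {
  sk <- default_hand()
  bundle <- default_bundle()
  flags <- fma_pose_battery(sk, bundle$fma_poses)
  expect_length(flags, 7)
  expect_true(all(flags))
  # neutral (all-zero, full extension) pose passes only full_extension
  zero <- stats::setNames(rep(0, 21), sk$axis_names)
  tpl <- fma_templates(sk)
  z <- vapply(names(tpl), function(nm)
    fma_pose_battery(sk, stats::setNames(list(zero), nm)), TRUE)
  expect_true(z[["full_extension"]])
  expect_false(any(z[setdiff(names(z), "full_extension")]))
  # violating one band by 2x the band width fails that position
  bad <- bundle$fma_poses$hook_grip
  bad["PIP3"] <- tpl$hook_grip$max[tpl$hook_grip$axis == "PIP3"] + 0.6
  expect_false(fma_pose_battery(sk, list(hook_grip = bad))[["hook_grip"]])
  expect_error(fma_pose_battery(sk, list(fist = zero)), "unknown")
})

test_that("grasp force distribution conserves the total and respects symmetry", {
  sk <- default_hand()
  bundle <- default_bundle()
  g <- grasp_contact_forces(sk, bundle$grasp_spherical, total = 475)
  expect_gte(nrow(g$contacts), 3)
  expect_equal(sum(g$contacts$magnitude), 475, tolerance = 1e-6)
  expect_true(all(g$contacts$magnitude >= 0))
  # symmetric 5-contact ring: equal shares
  th <- 2 * pi * (0:4) / 5
  pts <- cbind(cos(th), sin(th), 0) * 33.5
  sol <- solve_grip_forces(pts, -pts / 33.5, c(0, 0, 0), 475)
  expect_equal(sol$magnitudes, rep(95, 5), tolerance = 1e-4)
  # doubling the total doubles every magnitude
  sol2 <- solve_grip_forces(pts, -pts / 33.5, c(0, 0, 0), 950)
  expect_equal(sol2$magnitudes, 2 * sol$magnitudes, tolerance = 1e-6)
  # 4 random contacts: matches a brute-force simplex grid search
  set.seed(7)
  p4 <- normalize_rows(matrix(stats::rnorm(12), 4, 3)) * 30
  n4 <- -p4 / 30
  sol4 <- solve_grip_forces(p4, n4, c(0, 0, 0), 100)
  A <- rbind(t(n4), t(cross3_test(p4, n4)) / 30)
  grid <- seq(0, 1, by = 0.02)
  best <- Inf
  for (a in grid) for (b in grid) for (cc in grid) {
    if (a + b + cc > 1) next
    m <- c(a, b, cc, 1 - a - b - cc) * 100
    best <- min(best, sqrt(sum((A %*% m)^2)))
  }
  expect_lte(sol4$residual, best + 1e-6)
  # fewer than 3 contacts is not a closed grasp
  open_pose <- stats::setNames(rep(-0.4, 4), paste0("MCP", 2:5, "_flex"))
  expect_error(grasp_contact_forces(sk, open_pose, total = 100,
                                    contact_tol = 0.5),
               "not closed")
})
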