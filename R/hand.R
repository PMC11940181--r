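#' Synthetic 27-bone hand skeleton generator
#'
#' Generates the full hand fixture: 8 compact carpal bones (a fixed wrist
#' block), 5 metacarpals and 14 phalanges (the thumb has no middle phalanx),
#' placed in a natural semi-flexed resting posture in the toolkit frame
#' (+x radial, +y distal, +z dorsal).  Finger metacarpals are rigidly
#' attached to the carpal block (their carpometacarpal joints are
#' near-immobile); the articulating joint set is 9 revolute (PIP, DIP, thumb
#' IP) + 6 universal (finger MCPs, thumb MCP, thumb CMC) = 21 rotational DoF.
#'
#' Every placement is deterministic in `hand_length` and `seed`; joint
#' centres of rotation are the generated condylar head centres (ground
#' truth).
#'
#' @param hand_length overall hand length scale in mm (default 180, an adult
#'   male hand)
#' @param seed RNG seed (the skeleton itself is deterministic; the seed is
#'   recorded for provenance)
#' @param resolution bone mesh resolution multiplier (1 = default)
#' @return list with `bones` (list of bone records: name, group, number,
#'   digit, mesh, tip), `joints` (list of joint configs), `hand_length`
#' @export
gen_skeleton <- function(hand_length = 180, seed = 1L, resolution = 1) {
  stopifnot(hand_length > 0)
  s <- hand_length / 180
  n_ax <- max(14L, round(26 * resolution))
  n_sg <- max(10L, round(16 * resolution))

  digits <- c("thumb", "index", "middle", "ring", "small")
  mc_len <- c(48, 68, 65, 58, 52) * s
  pp_len <- c(34, 40, 44, 41, 33) * s
  mp_len <- c(NA, 24, 28, 26, 19) * s
  dp_len <- c(24, 18, 19, 18, 17) * s
  origins <- rbind(c(22, 14, -8), c(17, 22, 0), c(5, 24, 0),
                   c(-8, 23, 0), c(-20, 19, 0)) * s
  plane_ang <- c(50, 10, 0, -9, -18) * pi / 180    # toward +x (radial)
  palmar0 <- c(0.55, 0, 0, 0, 0)                   # built-in metacarpal tilt
  # built-in rest flexion (rad) applied at MCP(|CMC for thumb), PIP, DIP
  rest_flex <- list(thumb = c(0.15, 0.15),          # MCP, IP
                    finger = c(0.90, 1.00, 0.50))   # MCP, PIP, DIP

  bone_dims <- function(len) {
    list(base = 1.2 + 0.04 * len, shaft = 1.1 + 0.035 * len,
         head = 1.5 + 0.05 * len)
  }
  gap <- 2.6 * s

  bones <- list()
  joints <- list()
  carp_names <- c("scaphoid", "lunate", "triquetrum", "pisiform",
                  "trapezium", "trapezoid", "capitate", "hamate")
  carp_x <- c(14, 5, -5, -14, 14, 5, -5, -14) * s
  carp_y <- c(-14, -16, -15, -13, -2, -4, -3, -1) * s
  carp_r <- c(4.2, 4.0, 3.9, 3.6, 4.1, 3.8, 4.3, 4.0) * s
  for (i in 1:8) {
    mesh <- mesh_icosphere(carp_r[i], subdiv = 1L,
                           center = c(carp_x[i], carp_y[i], 0))
    bones[[carp_names[i]]] <- list(name = carp_names[i], group = "carpal",
                                   number = i, digit = NA_integer_,
                                   mesh = mesh, parent = NA_character_,
                                   joint = NA_character_, tip = NULL)
  }

  place_bone <- function(len, dims, base, dirv, flex_axis) {
    # neck stations clear of both end caps for every bone length
    s1 <- max(0.18, dims$base / len + 0.05)
    s2 <- min(0.82, 1 - 1.6 * dims$head / len - 0.02)
    b <- gen_bone(length = len, base_radius = dims$base,
                  shaft_radius = dims$shaft, head_radius = dims$head,
                  neck_stations = c(s1, s2),
                  n_axial = n_ax, n_seg = n_sg)
    zc <- cross_unit(flex_axis, dirv)
    R <- cbind(flex_axis, dirv, zc)
    mesh <- transform_geometry(b$mesh, rigid_transform(R, base))
    head_center <- base + dirv * (len - dims$head)
    tip <- base + dirv * len
    list(mesh = mesh, head_center = head_center, head_radius = dims$head,
         tip = tip, truth = b$truth)
  }

  fingertips <- matrix(NA_real_, 5, 3)
  for (d in 1:5) {
    dg <- digits[d]
    if (d == 1) {
      # the thumb column is pronated so that CMC flexion sweeps the tip
      # across the palm (opposition); its flexion axis points distal-dorsal
      fx <- c(0.23, 0.66, 0.71)
      fx <- fx / sqrt(sum(fx^2))
      dir0 <- c(-0.10, 0.75, -0.55)
      dirv <- dir0 - sum(dir0 * fx) * fx
      dirv <- dirv / sqrt(sum(dirv^2))
    } else {
      u0 <- c(sin(plane_ang[d]), cos(plane_ang[d]), 0)
      fx <- cross_unit(c(0, 0, 1), u0)  # flexion axis (rotation toward palm)
      dirv <- rot_axis(u0, fx, palmar0[d])
    }
    base <- origins[d, ]

    mc_name <- paste0("mc_", dg)
    dims <- bone_dims(mc_len[d])
    pb <- place_bone(mc_len[d], dims, base, dirv, fx)
    bones[[mc_name]] <- list(name = mc_name, group = "metacarpal",
                             number = 8L + as.integer(d), digit = as.integer(d), mesh = pb$mesh,
                             parent = "carpal_block",
                             joint = if (d == 1) paste0("CMC_", dg) else NA_character_,
                             tip = pb$tip)
    if (d == 1) {
      joints[[paste0("CMC_", dg)]] <- list(
        name = paste0("CMC_", dg), kind = "universal",
        parent = "carpal_block", child = mc_name,
        cor = base, axes = rbind(fx, cross_unit(dirv, fx)),
        limits = rbind(c(-1.2, 1.2), c(-0.8, 0.8)),
        axis_names = c("CMC1_flex", "CMC1_abd"))
    }

    flex <- if (d == 1) rest_flex$thumb else rest_flex$finger
    seg_lens <- if (d == 1) c(pp_len[d], dp_len[d])
                else c(pp_len[d], mp_len[d], dp_len[d])
    seg_groups <- if (d == 1) c("proximal", "distal")
                  else c("proximal", "middle", "distal")
    seg_numbers <- if (d == 1) c(14L, 16L) else c(14L, 15L, 16L)
    jnames <- if (d == 1) c(paste0("MCP_", dg), paste0("IP_", dg))
              else c(paste0("MCP_", dg), paste0("PIP_", dg), paste0("DIP_", dg))
    jkinds <- if (d == 1) c("universal", "revolute")
              else c("universal", "revolute", "revolute")
    short <- c(thumb = "1", index = "2", middle = "3", ring = "4", small = "5")[dg]
    janames <- if (d == 1)
      list(c(paste0("MCP", short, "_flex"), paste0("MCP", short, "_abd")),
           paste0("IP", short))
    else list(c(paste0("MCP", short, "_flex"), paste0("MCP", short, "_abd")),
              paste0("PIP", short), paste0("DIP", short))
    jlimits <- if (d == 1)
      list(rbind(c(-0.6, 1.2), c(-0.35, 0.35)), matrix(c(-0.45, 1.4), 1))
    else list(rbind(c(-0.9, 1.2), c(-0.35, 0.35)),
              matrix(c(-1.0, 1.5), 1), matrix(c(-0.6, 1.2), 1))

    prev_name <- mc_name
    prev_head <- pb$head_center
    prev_head_r <- pb$head_radius
    for (k in seq_along(seg_lens)) {
      dirv <- rot_axis(dirv, fx, flex[k])
      dims <- bone_dims(seg_lens[k])
      base <- prev_head + dirv * (prev_head_r + gap)
      name <- paste0(substr(seg_groups[k], 1, 1), "p_", dg)
      pbk <- place_bone(seg_lens[k], dims, base, dirv, fx)
      jn <- jnames[k]
      bones[[name]] <- list(name = name, group = seg_groups[k],
                            number = seg_numbers[k], digit = as.integer(d),
                            mesh = pbk$mesh, parent = prev_name,
                            joint = jn, tip = pbk$tip)
      axes <- if (jkinds[k] == "universal") rbind(fx, cross_unit(dirv, fx))
              else matrix(fx, 1)
      joints[[jn]] <- list(name = jn, kind = jkinds[k],
                           parent = prev_name, child = name,
                           cor = prev_head, axes = axes,
                           limits = jlimits[[k]],
                           axis_names = janames[[k]])
      prev_name <- name
      prev_head <- pbk$head_center
      prev_head_r <- pbk$head_radius
    }
    fingertips[d, ] <- bones[[prev_name]]$tip
  }
  # default per-articulation torsional spring parameters; damping is left
  # unset so build_skeleton derives it from the damping ratio zeta and the
  # chain inertia of each axis (uniform response character across joints)
  for (j in names(joints)) {
    joints[[j]]$k <- 50      # N.mm/rad
    joints[[j]]$zeta <- 0.7  # dimensionless damping ratio
    joints[[j]]$theta0 <- rep(0, nrow(joints[[j]]$axes))
  }
  list(bones = bones, joints = joints, hand_length = hand_length,
       fingertips = fingertips, seed = seed)
}

cross_unit <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  v / sqrt(sum(v^2))
}

rot_axis <- function(v, axis, angle) as.vector(rotation_about_axis(axis, angle) %*% v)

#' Assemble and validate a hand skeleton
#'
#' Checks the structural contract (27 bones; 8 carpals / 5 metacarpals / 14
#' phalanges; unique numbering; an acyclic joint graph reaching every
#' non-carpal bone from the fixed carpal block; 9 revolute + 6 universal
#' joints with orthogonal universal axes and well-ordered limits), computes
#' per-bone mass properties, per-joint-axis chain inertia (inertia of the
#' distal sub-chain about the joint axis at rest, frozen for simulation),
#' rest-pose fingertips, and the Kapandji target locations derived from the
#' rest geometry.
#'
#' @param bones,joints as produced by [gen_skeleton()] (or equivalent user
#'   configuration with meshes, numbering and joint parameters)
#' @param density bone density g/mm^3
#' @param check_interference run [interference_check()] on the rest pose and
#'   store the result (default TRUE)
#' @return object of class `rebiom_hand`
#' @export
build_skeleton <- function(bones, joints, density = 1e-3,
                           check_interference = TRUE) {
  if (is.list(bones) && !is.null(bones$bones) && is.null(joints)) {
    joints <- bones$joints; bones <- bones$bones
  }
  if (length(bones) != 27)
    stop("expected 27 bones, got ", length(bones))
  groups <- vapply(bones, `[[`, "", "group")
  gcount <- table(factor(groups, levels = c("carpal", "metacarpal",
                                            "proximal", "middle", "distal")))
  if (gcount[["carpal"]] != 8 || gcount[["metacarpal"]] != 5 ||
      sum(gcount[c("proximal", "middle", "distal")]) != 14)
    stop("group split must be 8 carpals / 5 metacarpals / 14 phalanges; got ",
         paste(gcount, collapse = "/"))
  numbers <- vapply(bones, `[[`, 0L, "number")
  key <- paste(numbers, vapply(bones, function(b)
    if (is.na(b$digit)) 0L else b$digit, 0L))
  if (anyNA(numbers) || anyDuplicated(key))
    stop("missing or duplicate bone numbers in the numbering map")
  kinds <- vapply(joints, `[[`, "", "kind")
  if (sum(kinds == "revolute") != 9 || sum(kinds == "universal") != 6)
    stop("joint set must be 9 revolute + 6 universal; got ",
         sum(kinds == "revolute"), "+", sum(kinds == "universal"))
  for (j in joints) {
    if (j$kind == "universal" &&
        abs(sum(j$axes[1, ] * j$axes[2, ])) > 1e-8)
      stop("universal joint ", j$name, " axes are not orthogonal")
    if (any(j$limits[, 1] >= j$limits[, 2]))
      stop("joint ", j$name, " has limits with min >= max")
    if (j$k < 0 || (!is.null(j$c) && any(j$c < 0)))
      stop("joint ", j$name, " has negative spring/damper parameters")
  }
  # tree check: every non-carpal reachable from the carpal block, no cycles
  non_carpal <- names(bones)[groups != "carpal"]
  child_of <- vapply(joints, `[[`, "", "child")
  if (anyDuplicated(child_of)) stop("joint graph is not a tree (shared child)")
  for (nm in non_carpal) {
    seen <- character()
    cur <- nm
    repeat {
      p <- bones[[cur]]$parent
      if (is.null(p) || is.na(p)) stop("bone ", nm, " has no path to the carpal block")
      if (p == "carpal_block") break
      if (p %in% seen) stop("cycle in the joint graph at ", p)
      seen <- c(seen, p)
      cur <- p
    }
  }
  # mass properties per bone
  for (nm in names(bones)) {
    mp <- mass_properties(bones[[nm]]$mesh, density = density)
    bones[[nm]]$mass <- mp$mass
    bones[[nm]]$volume <- mp$volume
    bones[[nm]]$cog <- mp$centroid
    bones[[nm]]$inertia <- mp$inertia
  }
  # distal subtree of each joint
  children_map <- split(vapply(bones[non_carpal], `[[`, "", "name"),
                        vapply(bones[non_carpal], `[[`, "", "parent"))
  subtree <- function(root) {
    out <- root; frontier <- root
    while (length(frontier) > 0) {
      nxt <- unlist(children_map[frontier], use.names = FALSE)
      out <- c(out, nxt); frontier <- nxt
    }
    out
  }
  for (jn in names(joints)) {
    j <- joints[[jn]]
    chain <- subtree(j$child)
    iner <- numeric(nrow(j$axes))
    for (ax in seq_len(nrow(j$axes))) {
      a <- j$axes[ax, ]
      tot <- 0
      for (b in chain) {
        bb <- bones[[b]]
        r <- bb$cog - j$cor
        perp2 <- sum(r^2) - sum(r * a)^2
        tot <- tot + as.numeric(t(a) %*% bb$inertia %*% a) + bb$mass * perp2
      }
      iner[ax] <- tot * 1e-6   # g.mm^2 -> N.mm.s^2/rad
    }
    joints[[jn]]$inertia <- iner
    joints[[jn]]$dof <- nrow(j$axes)
    # torsional damping: explicit c (N.mm.s/rad) wins; otherwise derived per
    # axis from the damping ratio so every joint shares the same response
    # character regardless of its chain inertia
    if (is.null(j$c)) {
      zeta <- if (is.null(j$zeta)) 0.7 else j$zeta
      joints[[jn]]$c <- 2 * zeta * sqrt(j$k * iner)
    } else if (length(j$c) == 1) {
      joints[[jn]]$c <- rep(j$c, nrow(j$axes))
    }
  }
  axis_names <- unlist(lapply(joints, `[[`, "axis_names"), use.names = FALSE)
  if (anyDuplicated(axis_names)) stop("duplicate joint axis names")
  digits_chain <- lapply(1:5, function(d)
    names(bones)[vapply(bones, function(b) identical(b$digit, d) ||
                          (!is.na(b$digit) && b$digit == d), TRUE)])
  tips <- do.call(rbind, lapply(1:5, function(d) {
    dist <- bones[[grep("^dp_", digits_chain[[d]], value = TRUE)]]
    dist$tip
  }))
  sk <- structure(list(bones = bones, joints = joints,
                       axis_names = axis_names,
                       rest_pose = stats::setNames(rep(0, length(axis_names)),
                                                   axis_names),
                       fingertips = tips,
                       digits = digits_chain),
                  class = "rebiom_hand")
  sk$kapandji_targets <- kapandji_targets(sk)
  if (check_interference) {
    meshes <- lapply(bones, `[[`, "mesh")
    sk$interference <- interference_check(meshes, clearance = 0)
  }
  sk
}

#' @export
print.rebiom_hand <- function(x, ...) {
  kinds <- vapply(x$joints, `[[`, "", "kind")
  cat(sprintf("<hand skeleton: %d bones, %d joints (%d revolute + %d universal), %d DoF>\n",
              length(x$bones), length(x$joints),
              sum(kinds == "revolute"), sum(kinds == "universal"),
              enumerate_dof(x, "model")))
  invisible(x)
}

#' Degree-of-freedom count
#'
#' `"model"` sums the per-joint DoF of the built joint graph (21 for the
#' default skeleton).  `"anatomical"` returns the textbook enumeration: 4
#' DoF per finger (x4), 5 for the thumb, 6 for wrist rotation/translation =
#' 27.
#'
#' @param skeleton a `rebiom_hand` (required for model mode)
#' @param mode `"model"` or `"anatomical"`
#' @return integer DoF count
#' @export
enumerate_dof <- function(skeleton = NULL, mode = c("model", "anatomical")) {
  mode <- match.arg(mode)
  if (mode == "anatomical") return(4L * 4L + 5L + 6L)
  stopifnot(inherits(skeleton, "rebiom_hand"))
  sum(vapply(skeleton$joints, function(j) nrow(j$axes), 0L))
}

#' Uniform scaling of a hand skeleton ("what-if" dimensioning)
#'
#' Lengths scale by `s`, areas by `s^2`, volumes and masses by `s^3`
#' (density fixed), inertia by `s^5`; joint centres and targets transform
#' accordingly.  Spring and damper parameters are left unchanged.
#'
#' @param skeleton a `rebiom_hand`
#' @param s scale factor (> 0)
#' @return scaled `rebiom_hand`
#' @export
scale_skeleton <- function(skeleton, s) {
  stopifnot(s > 0)
  sk <- skeleton
  for (nm in names(sk$bones)) {
    b <- sk$bones[[nm]]
    b$mesh$vertices <- b$mesh$vertices * s
    b$mass <- b$mass * s^3
    b$volume <- b$volume * s^3
    b$cog <- b$cog * s
    b$inertia <- b$inertia * s^5
    if (!is.null(b$tip)) b$tip <- b$tip * s
    sk$bones[[nm]] <- b
  }
  for (jn in names(sk$joints)) {
    sk$joints[[jn]]$cor <- sk$joints[[jn]]$cor * s
    sk$joints[[jn]]$inertia <- sk$joints[[jn]]$inertia * s^5
  }
  sk$fingertips <- sk$fingertips * s
  sk$kapandji_targets <- sk$kapandji_targets * s
  sk
}

#' Forward kinematics
#'
#' Composes rigid transforms down the joint tree: each joint rotates its
#' distal sub-chain about its rest-pose centre of rotation and axes; the
#' carpal block (and the rigidly attached finger metacarpals' frames) stay
#' put.  Angles are deviations from the rest pose.
#'
#' @param skeleton a `rebiom_hand`
#' @param angles named numeric vector over `skeleton$axis_names` (missing
#'   names default to 0)
#' @param check_limits error when an angle exceeds its joint limits
#' @return list: `transforms` (named list of 4x4 per bone), `fingertips`
#'   (5x3 matrix)
#' @export
forward_kinematics <- function(skeleton, angles = NULL, check_limits = TRUE) {
  th <- skeleton$rest_pose
  if (!is.null(angles)) {
    if (is.null(names(angles)) && length(angles) == length(th))
      names(angles) <- names(th)
    th[names(angles)] <- angles
  }
  if (check_limits) {
    for (j in skeleton$joints) {
      a <- th[j$axis_names]
      bad <- a < j$limits[, 1] - 1e-9 | a > j$limits[, 2] + 1e-9
      if (any(bad))
        stop("angle out of limits at joint ", j$name, " (",
             paste(j$axis_names[bad], collapse = ", "), ")")
    }
  }
  joint_T <- function(j) {
    R <- rotation_about_axis(j$axes[1, ], th[[j$axis_names[1]]])
    if (nrow(j$axes) > 1)
      R <- R %*% rotation_about_axis(j$axes[2, ], th[[j$axis_names[2]]])
    T <- diag(4)
    T[1:3, 1:3] <- R
    T[1:3, 4] <- j$cor - R %*% j$cor
    T
  }
  joints_by_child <- stats::setNames(skeleton$joints,
                                     vapply(skeleton$joints, `[[`, "", "child"))
  transforms <- list()
  get_T <- function(nm) {
    if (!is.null(transforms[[nm]])) return(transforms[[nm]])
    b <- skeleton$bones[[nm]]
    T <- if (is.na(b$parent) || b$parent == "carpal_block") diag(4)
         else get_T(b$parent)
    if (!is.null(joints_by_child[[nm]]))
      T <- T %*% joint_T(joints_by_child[[nm]])
    transforms[[nm]] <<- T
    T
  }
  for (nm in names(skeleton$bones)) get_T(nm)
  tips <- skeleton$fingertips
  for (d in 1:5) {
    dp_name <- grep("^dp_", skeleton$digits[[d]], value = TRUE)
    T <- transforms[[dp_name]]
    tips[d, ] <- as.vector(T[1:3, 1:3] %*% skeleton$fingertips[d, ] + T[1:3, 4])
  }
  list(transforms = transforms, fingertips = tips)
}

# Kapandji target locations 0-10 from the rest geometry (Fig 27a layout):
# 0 radial side of the index proximal phalanx; 1 radial side of the index
# fingertip; 2-5 index..small fingertips; 6 small DIP crease; 7 small PIP
# crease; 8 small MCP crease; 9 small-metacarpal midshaft (proximal palm);
# 10 base of the small metacarpal (distal palm crease proxy).
kapandji_targets <- function(sk) {
  palmar <- c(0, 0, -1)
  tip <- sk$fingertips
  radial <- function(d) {
    j <- sk$joints[[paste0("MCP_", c("thumb", "index", "middle", "ring", "small")[d])]]
    j$axes[1, ] * -1   # flexion axis points ulnar; radial is its negative
  }
  pp2 <- sk$bones[["pp_index"]]
  pp2_mid <- colMeans(pp2$mesh$vertices)
  off <- 3.2
  t0 <- pp2_mid + radial(2) * (2.5 * off)
  t1 <- tip[2, ] + radial(2) * off
  t2 <- tip[2, ]; t3 <- tip[3, ]; t4 <- tip[4, ]; t5 <- tip[5, ]
  corDIP5 <- sk$joints[["DIP_small"]]$cor
  corPIP5 <- sk$joints[["PIP_small"]]$cor
  corMCP5 <- sk$joints[["MCP_small"]]$cor
  mc5 <- sk$bones[["mc_small"]]
  mc5_mid <- colMeans(mc5$mesh$vertices)
  mc5_base <- mc5_mid + (corMCP5 - mc5_mid) * -0.8
  rbind(t0, t1, t2, t3, t4, t5,
        corDIP5 + palmar * off, corPIP5 + palmar * (off + 1),
        corMCP5 + palmar * (off + 2), mc5_mid + palmar * (off + 2),
        mc5_base + palmar * (off + 2))
}
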