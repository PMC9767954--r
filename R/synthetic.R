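# Synthetic hand generator: a forward-kinematic 21-point hand model, a
# moment-based feature sampler, and a study-shaped cohort builder.
#
# The kinematic model lives in dimensionless model units with the wrist at
# the origin, the palm in the z = 0 plane, fingers pointing toward +y, and
# the palmar side toward -z. Positive flexion bends a chain palmar-ward.
# Every finger is a planar chain built by successive rotations about one
# axis, so each configured joint angle is reproduced exactly by the emitted
# landmarks (to floating-point precision). Webspace angles, thumb-ray
# elevation, and the standardized tip gap are available as exact pose
# targets: the generator solves the remaining free degrees of freedom
# (proximal tilt, build-plane orientation, whole-digit rotations) so the
# computed feature equals the requested value.

#' Default hand skeleton
#'
#' Segment lengths and palm geometry of the synthetic hand, in model units
#' (roughly palm lengths). Proportions follow typical adult hand anthropometry.
#'
#' @param index_mcp,middle_mcp,ring_mcp,little_mcp Palm-plane (x, y)
#'   positions of the finger MCP landmarks.
#' @param thumb_cmc Palm-plane (x, y) position of the thumb CMC landmark.
#' @param finger_segments Named list of proximal/middle/distal phalanx
#'   lengths for the four fingers.
#' @param thumb_segments Thumb CMC-MCP, MCP-IP, IP-tip segment lengths.
#' @return An object of class `hand_skeleton`.
#' @export
hand_skeleton <- function(index_mcp = c(0.30, 1.00),
                          middle_mcp = c(0.08, 1.05),
                          ring_mcp = c(-0.12, 1.00),
                          little_mcp = c(-0.32, 0.90),
                          thumb_cmc = c(0.46, 0.32),
                          finger_segments = list(index = c(0.45, 0.26, 0.22),
                                                 middle = c(0.50, 0.30, 0.24),
                                                 ring = c(0.46, 0.28, 0.22),
                                                 little = c(0.36, 0.22, 0.19)),
                          thumb_segments = c(0.40, 0.32, 0.25)) {
  sk <- list(mcp = list(index = index_mcp, middle = middle_mcp,
                        ring = ring_mcp, little = little_mcp),
             thumb_cmc = thumb_cmc,
             finger_segments = finger_segments,
             thumb_segments = thumb_segments)
  lens <- c(unlist(finger_segments), thumb_segments)
  if (any(lens <= 0)) {
    hs_error("all skeleton segment lengths must be > 0", "hs_generation_error")
  }
  structure(sk, class = "hand_skeleton")
}

#' Pose parameters for the forward-kinematic hand
#'
#' @param thumb,index,middle,ring,little Per-digit flexion angle triples in
#'   degrees (thumb: CMC/MCP/IP; fingers: MCP/PIP/DIP). Moderate
#'   hyperextension (negative values) is allowed.
#' @param plane_azimuth Named vector of per-finger build-plane rotations
#'   about the finger's own base direction, in degrees (0 = pure palmar
#'   flexion, 90 = in-palm abduction). Joint angles are invariant to it.
#' @param web3,web4 Optional exact webspace-angle targets (degrees). When
#'   set, the flanking finger's MCP flexion and build plane are solved so
#'   the middle/ring (resp. ring/little) ray angle equals the target; the
#'   finger's distal flexion angles are kept.
#' @param thumb_elevation Optional exact elevation target (degrees) of the
#'   thumb MCP-to-tip ray out of the palm plane; realized by rotating the
#'   whole thumb, which preserves all thumb joint angles.
#' @param thumb_opposition Rotation (degrees) of the whole thumb about the
#'   palm normal toward the fingers, emulating opposition. Preserves all
#'   thumb joint angles and the thumb-ray elevation.
#' @param tip_gap Optional exact standardized thumb-to-index tip distance
#'   target; realized by rotating the index finger about its own base
#'   direction, which preserves all index joint angles.
#' @param rotation Global z-y-x Euler rotation (degrees).
#' @param translation Global translation 3-vector.
#' @param jitter_sd Isotropic Gaussian landmark jitter SD (model units).
#' @return An object of class `hand_pose`.
#' @export
pose_parameters <- function(thumb = c(0, 0, 0), index = c(0, 0, 0),
                            middle = c(0, 0, 0), ring = c(0, 0, 0),
                            little = c(0, 0, 0),
                            plane_azimuth = c(index = 0, middle = 0,
                                              ring = 0, little = 0),
                            web3 = NULL, web4 = NULL,
                            thumb_elevation = NULL, thumb_opposition = 0,
                            tip_gap = NULL,
                            rotation = c(0, 0, 0), translation = c(0, 0, 0),
                            jitter_sd = 0) {
  flexion <- list(thumb = thumb, index = index, middle = middle,
                  ring = ring, little = little)
  for (nm in names(flexion)) {
    f <- flexion[[nm]]
    if (length(f) != 3L || !all(is.finite(f)) || any(f < -60) || any(f > 160)) {
      hs_error(sprintf("invalid flexion angles for %s: need 3 finite values in [-60, 160]", nm),
               "hs_generation_error")
    }
  }
  if (!is.null(tip_gap) && tip_gap < 0) {
    hs_error("tip_gap target must be nonnegative", "hs_generation_error")
  }
  if (jitter_sd < 0) {
    hs_error("jitter_sd must be nonnegative", "hs_generation_error")
  }
  structure(list(flexion = flexion, plane_azimuth = plane_azimuth,
                 web3 = web3, web4 = web4,
                 thumb_elevation = thumb_elevation,
                 thumb_opposition = thumb_opposition, tip_gap = tip_gap,
                 rotation = rotation, translation = translation,
                 jitter_sd = jitter_sd),
            class = "hand_pose")
}

# Planar chain from base point m along base direction u0: joint directions
# are successive rotations about `axis` by the cumulative flexion angles.
chain_points <- function(m, u0, axis, flex, segs) {
  cum <- cumsum(flex)
  dirs <- lapply(cum, function(a) rotate_about(u0, axis, a))
  pts <- matrix(NA_real_, 3L, 3L)
  p <- m
  for (k in 1:3) {
    p <- p + segs[k] * dirs[[k]]
    pts[k, ] <- p
  }
  pts
}

# In-plane tilt (degrees) of the MCP-to-tip ray relative to the base
# direction, for a planar chain with distal flexions gamma2/gamma3 and
# proximal tilt t1: tilt = t1 + ray_offset(gamma2, gamma3).
ray_offset <- function(segs, pip, dip) {
  g <- deg2rad(c(0, pip, pip + dip))
  rad2deg(atan2(sum(segs * sin(g)), sum(segs * cos(g))))
}

#' Forward kinematics: pose to 21-point landmark set
#'
#' Deterministic given `seed` (the seed only feeds landmark jitter). With
#' zero jitter, every configured joint angle is reproduced exactly by
#' [joint_angle()] on the emitted landmarks, and the `web3`/`web4`/
#' `thumb_elevation`/`tip_gap` targets are reproduced exactly by the
#' corresponding features.
#'
#' @param skeleton A [hand_skeleton].
#' @param pose A [pose_parameters] object.
#' @param seed Optional integer seed for jitter.
#' @param gesture,subject_id,hand_side,repetition,label Metadata attached to
#'   the returned record. Left hands are emitted mirrored (x negated) from
#'   the canonical right-hand model.
#' @return A [hand_landmarks] object.
#' @export
forward_kinematics <- function(skeleton, pose, seed = NULL, gesture = "G1",
                               subject_id = "sim", hand_side = "right",
                               repetition = 1L, label = "none") {
  P <- matrix(0, 21L, 3L)
  z <- c(0, 0, 1)

  # thumb: planar chain in the vertical plane through its base direction
  cmc <- c(skeleton$thumb_cmc, 0)
  u_t <- unit_vec(cmc, "thumb base")
  a_t <- unit_vec(cross3(z, u_t))
  tpts <- chain_points(cmc, u_t, a_t, pose$flexion$thumb, skeleton$thumb_segments)
  thumb <- rbind(cmc, tpts)
  if (!is.null(pose$thumb_elevation)) {
    ray <- thumb[4L, ] - thumb[2L, ]
    # full signed in-plane angle of the (planar) thumb ray from the palm plane
    alpha <- rad2deg(atan2(ray[3L], sum(ray * u_t)))
    # +delta about a_t lowers the signed elevation by delta; aim at -E (palmar)
    delta <- alpha + pose$thumb_elevation
    thumb <- t(apply(thumb, 1L, rotate_about, axis = a_t, theta_deg = delta))
  }
  # The thumb may still be swung about the palm normal (opposition) below:
  # that rotation preserves all thumb joint angles and the ray elevation.
  P[lm_row(1:4), ] <- thumb

  finger_rows <- list(index = 5:8, middle = 9:12, ring = 13:16, little = 17:20)

  build_normal <- function(name) {
    m <- c(skeleton$mcp[[name]], 0)
    u0 <- unit_vec(m, paste(name, "base"))
    a0 <- unit_vec(cross3(z, u0))
    psi <- pose$plane_azimuth[[name]] %||% 0
    ax <- if (abs(psi) > 1e-12) rotate_about(a0, u0, psi) else a0
    rbind(m, chain_points(m, u0, ax, pose$flexion[[name]], skeleton$finger_segments[[name]]))
  }

  # Solve the proximal tilt and build plane of `name` so that the angle
  # between its MCP-to-tip ray and `ref_ray` equals `target` exactly.
  build_webspace <- function(name, ref_ray, target) {
    m <- c(skeleton$mcp[[name]], 0)
    u0 <- unit_vec(m, paste(name, "base"))
    segs <- skeleton$finger_segments[[name]]
    flex <- pose$flexion[[name]]
    cx <- cross3(u0, ref_ray)
    ax <- if (vec_norm(cx) > 1e-9) cx / vec_norm(cx) else unit_vec(cross3(z, u0))
    A <- angle_between(u0, ref_ray)
    t1 <- (A - target) - ray_offset(segs, flex[2L], flex[3L])
    rbind(m, chain_points(m, u0, ax, c(t1, flex[2L], flex[3L]), segs))
  }

  P[lm_row(finger_rows$middle), ] <- build_normal("middle")
  ray_middle <- P[lm_row(12L), ] - P[lm_row(9L), ]
  P[lm_row(finger_rows$ring), ] <-
    if (is.null(pose$web3)) build_normal("ring")
    else build_webspace("ring", ray_middle, pose$web3)
  ray_ring <- P[lm_row(16L), ] - P[lm_row(13L), ]
  P[lm_row(finger_rows$little), ] <-
    if (is.null(pose$web4)) build_normal("little")
    else build_webspace("little", ray_ring, pose$web4)

  idx <- build_normal("index")
  if (!is.null(pose$tip_gap)) {
    # Rotate the index finger about its own base direction (preserves all
    # index joint angles) until the standardized thumb-to-index tip distance
    # hits the target. If unreachable at the configured thumb opposition,
    # widen the search over opposition angles (which preserve all thumb
    # features) before declaring the draw infeasible.
    m <- idx[1L, ]
    u0 <- unit_vec(m, "index base")
    rel <- sweep(idx[2:4, , drop = FALSE], 2L, m)
    D <- pose$tip_gap * skeleton$thumb_segments[3L]
    omega0 <- pose$thumb_opposition %||% 0
    psi_grid <- seq(-180, 180, by = 5)
    solved <- FALSE
    lo_all <- Inf
    hi_all <- -Inf
    offsets <- seq(-55, 75, by = 5)
    for (omega_extra in offsets[order(abs(offsets))]) {
      thumb_try <- t(apply(thumb, 1L, rotate_about, axis = z,
                           theta_deg = omega0 + omega_extra))
      tip_t <- thumb_try[4L, ]
      gap <- function(psi) {
        vec_norm(m + rotate_about(rel[3L, ], u0, psi) - tip_t) - D
      }
      # vectorized Rodrigues sweep of the index tip circle
      th <- deg2rad(psi_grid)
      base <- m - tip_t
      r3 <- rel[3L, ]
      cx <- cross3(u0, r3)
      ax <- u0 * sum(u0 * r3)
      tips <- outer(cos(th), r3) + outer(sin(th), cx) +
        outer(1 - cos(th), ax) + matrix(base, length(th), 3L, byrow = TRUE)
      fg <- sqrt(rowSums(tips^2)) - D
      lo_all <- min(lo_all, min(fg) + D)
      hi_all <- max(hi_all, max(fg) + D)
      sc <- which(fg[-length(fg)] * fg[-1L] <= 0)
      if (length(sc) == 0L) next
      # deterministic pick: bracket closest to the unrotated index plane
      k <- sc[which.min(abs(psi_grid[sc] + psi_grid[sc + 1L]) / 2)]
      psi <- if (gap(psi_grid[k]) == 0) psi_grid[k] else
        stats::uniroot(gap, c(psi_grid[k], psi_grid[k + 1L]), tol = 1e-11)$root
      idx[2:4, ] <- t(apply(rel, 1L, rotate_about, axis = u0, theta_deg = psi)) +
        matrix(m, 3L, 3L, byrow = TRUE)
      P[lm_row(1:4), ] <- thumb_try
      solved <- TRUE
      break
    }
    if (!solved) {
      hs_error(sprintf("infeasible tip_gap target %.4f: achievable standardized range is [%.4f, %.4f]",
                       pose$tip_gap, lo_all / skeleton$thumb_segments[3L],
                       hi_all / skeleton$thumb_segments[3L]),
               "hs_infeasible_error")
    }
  } else if (abs(pose$thumb_opposition %||% 0) > 1e-12) {
    P[lm_row(1:4), ] <- t(apply(thumb, 1L, rotate_about, axis = z,
                                theta_deg = pose$thumb_opposition))
  }
  P[lm_row(finger_rows$index), ] <- idx

  rot <- pose$rotation %||% c(0, 0, 0)
  if (any(rot != 0)) P <- P %*% t(euler_rotation(rot))
  tr <- pose$translation %||% c(0, 0, 0)
  if (any(tr != 0)) P <- sweep(P, 2L, tr, `+`)
  if (pose$jitter_sd > 0) {
    jit <- function() matrix(rnorm(63L, 0, pose$jitter_sd), 21L, 3L)
    P <- P + if (is.null(seed)) jit() else withr::with_seed(seed, jit())
  }
  if (hand_side == "left") P[, 1L] <- -P[, 1L]
  hand_landmarks(P, subject_id, hand_side, gesture, repetition, label = label)
}

# ---- moment-based samplers -------------------------------------------------

# Component (non-sum) features of a gesture with their group moments and
# kinematic feasibility bounds for truncation.
component_moments <- function(gesture, group) {
  ref <- feature_reference()
  ref <- ref[ref$gesture == gesture & ref$kind != "angle-sum", , drop = FALSE]
  ref <- ref[order(ref$number), , drop = FALSE]
  mean_col <- if (group == "target") "mean_target" else "mean_nontarget"
  sd_col <- if (group == "target") "sd_target" else "sd_nontarget"
  lower <- ifelse(ref$signed, -150, ifelse(ref$kind == "webspace-angle", 0.05,
                                           ifelse(ref$name == "dis_tip", 0.02, 0)))
  upper <- ifelse(ref$signed, ifelse(ref$name == "ag_palmab", 0, -0.01),
                  ifelse(ref$name == "dis_tip", 6, 150))
  lower[ref$name == "ag_palmab"] <- -89
  data.frame(name = ref$name, mean = ref[[mean_col]], sd = ref[[sd_col]],
             lower = lower, upper = upper, stringsAsFactors = FALSE)
}

add_sum_features <- function(df, gesture) {
  if (gesture == "G2") {
    df$ag_ring <- df$ag_ring_PIP + df$ag_ring_DIP
    df$ag_little <- df$ag_little_PIP + df$ag_little_DIP
  } else if (gesture == "G3") {
    df$ag_thumb <- df$ag_thumb_CMC + df$ag_thumb_MCP + df$ag_thumb_IP
    df$ag_index <- df$ag_index_MCP + df$ag_index_PIP + df$ag_index_DIP
  }
  df[, gesture_features(gesture), drop = FALSE]
}

resolve_group <- function(profile, gesture) {
  if (inherits(profile, "injury_profile")) profile$gesture_group[[gesture]]
  else match.arg(profile, c("target", "non-target"))
}

#' Injury profile: which group a hand belongs to per gesture task
#'
#' @param injury One of `"none"`, `"radial"`, `"ulnar"`, `"median"`,
#'   `"ulnar+median"`.
#' @return An `injury_profile` with the injury and the target/non-target
#'   group assignment for each of the three gesture tasks.
#' @export
injury_profile <- function(injury = INJURY_LABELS) {
  injury <- match.arg(injury)
  nerves <- if (injury == "none") character(0) else strsplit(injury, "+", fixed = TRUE)[[1L]]
  grp <- vapply(c("G1", "G2", "G3"), function(g) {
    if (gesture_target_nerve(g) %in% nerves) "target" else "non-target"
  }, character(1L))
  structure(list(injury = injury, gesture_group = grp), class = "injury_profile")
}

# Core Gaussian sampler. `hand` assigns records to hands for the
# hierarchical model: each hand draws a latent severity per feature and the
# repetitions scatter around it with SD = rep_noise_frac * group SD, keeping
# the marginal variance at the configured group SD. `rho` adds uniform
# correlation across features through a shared standard-normal factor.
# With `truncate`, out-of-bound draws (kinematically infeasible values) are
# rejected and redrawn at the repetition level.
draw_component_matrix <- function(gesture, group, n, rho = 0, hand = NULL,
                                  rep_noise_frac = 0, truncate = FALSE) {
  mom <- component_moments(gesture, group)
  p <- nrow(mom)
  if (n == 0L) {
    out <- as.data.frame(matrix(numeric(0), 0L, p, dimnames = list(NULL, mom$name)))
    return(out)
  }
  if (is.null(hand)) hand <- seq_len(n)
  hands <- unique(hand)
  hidx <- match(hand, hands)
  sb <- sqrt(max(0, 1 - rep_noise_frac^2))
  sr <- rep_noise_frac
  zc <- rnorm(length(hands))
  latent <- sapply(seq_len(p), function(j) {
    zi <- rnorm(length(hands))
    mom$mean[j] + mom$sd[j] * sb * (sqrt(rho) * zc + sqrt(1 - rho) * zi)
  })
  latent <- matrix(latent, length(hands), p)
  vals <- latent[hidx, , drop = FALSE] +
    matrix(rnorm(n * p), n, p) * matrix(mom$sd * sr, n, p, byrow = TRUE)
  if (sr == 0) {
    vals <- latent[hidx, , drop = FALSE]
  }
  if (truncate) {
    for (round in 1:80) {
      bad <- which(sweep(vals, 2L, mom$lower, `<`) | sweep(vals, 2L, mom$upper, `>`))
      if (length(bad) == 0L) break
      col <- (bad - 1L) %/% n + 1L
      redraw <- mom$mean[col] + mom$sd[col] * rnorm(length(bad))
      vals[bad] <- redraw
    }
    vals <- sweep(sweep(vals, 2L, mom$lower, pmax), 2L, mom$upper, pmin)
  }
  out <- as.data.frame(vals)
  names(out) <- mom$name
  # per-record latent severity (used for feasibility retries at the
  # repetition level in the cohort builder)
  attr(out, "latent_records") <- latent[hidx, , drop = FALSE]
  out
}

#' Sample feature vectors from the group moment model
#'
#' Draws the gesture's component features as independent Gaussians (optional
#' uniform correlation `rho`) with the configured group means and SDs, then
#' derives the sum features exactly. This is the moment-based shortcut that
#' bypasses kinematics; no feasibility truncation is applied.
#'
#' @param profile An [injury_profile], or directly `"target"`/`"non-target"`.
#' @param gesture `"G1"`, `"G2"`, or `"G3"`.
#' @param n Number of records.
#' @param seed Integer seed; same seed, same sample.
#' @param rho Uniform between-feature correlation in \[0, 1\].
#' @return Data frame with the gesture's feature columns in registry order.
#' @export
sample_features <- function(profile, gesture, n, seed = 1L, rho = 0) {
  group <- resolve_group(profile, gesture)
  withr::with_seed(seed, {
    df <- draw_component_matrix(gesture, group, n, rho = rho)
    add_sum_features(df, gesture)
  })
}

# Map one row of drawn component features to a pose realizing them exactly.
invert_pose <- function(gesture, v, jitter_sd = 0, rotation = c(0, 0, 0),
                        translation = c(0, 0, 0)) {
  if (gesture == "G1") {
    pose_parameters(thumb = c(6, v[["ag_thumb_MCP"]], 8),
                    index = c(v[["ag_index_MCP"]], 4, 3),
                    middle = c(v[["ag_middle_MCP"]], 4, 3),
                    ring = c(v[["ag_ring_MCP"]], 4, 3),
                    little = c(v[["ag_little_MCP"]], 5, 4),
                    rotation = rotation, translation = translation,
                    jitter_sd = jitter_sd)
  } else if (gesture == "G2") {
    pose_parameters(thumb = c(6, 8, 10),
                    index = c(3, 4, 3),
                    middle = c(2, 3, 2),
                    ring = c(0, v[["ag_ring_PIP"]], v[["ag_ring_DIP"]]),
                    little = c(0, v[["ag_little_PIP"]], v[["ag_little_DIP"]]),
                    web3 = v[["web3"]], web4 = v[["web4"]],
                    rotation = rotation, translation = translation,
                    jitter_sd = jitter_sd)
  } else {
    pose_parameters(thumb = c(-v[["ag_thumb_CMC"]], -v[["ag_thumb_MCP"]],
                              -v[["ag_thumb_IP"]]),
                    index = c(-v[["ag_index_MCP"]], -v[["ag_index_PIP"]],
                              -v[["ag_index_DIP"]]),
                    middle = c(12, 18, 10), ring = c(14, 20, 12),
                    little = c(12, 16, 10),
                    thumb_elevation = -v[["ag_palmab"]],
                    thumb_opposition = 55,
                    tip_gap = v[["dis_tip"]],
                    rotation = rotation, translation = translation,
                    jitter_sd = jitter_sd)
  }
}

#' Sample gesture records through the kinematic model
#'
#' Draws feature values from the group's Gaussian moments (truncated at
#' kinematic feasibility), inverts each draw to pose parameters, and emits
#' landmark records through [forward_kinematics()]. With zero jitter the
#' features computed from the emitted landmarks equal the drawn values to
#' floating-point precision; jitter adds landmark-level noise on top.
#'
#' @inheritParams sample_features
#' @param skeleton A [hand_skeleton].
#' @param jitter_sd Landmark jitter SD (model units).
#' @param hand_side `"left"` or `"right"` (left hands are mirrored).
#' @param subject_prefix Prefix for generated subject identifiers.
#' @param max_retries Redraws allowed per record when a drawn combination is
#'   kinematically infeasible (mainly extreme tip-gap draws).
#' @return A [cohort_table] with attribute `"drawn_features"` (the feature
#'   values each record was generated from) and `"n_retries"`.
#' @export
sample_gesture <- function(profile, gesture, n, seed = 1L,
                           skeleton = hand_skeleton(), jitter_sd = 0,
                           hand_side = "right", subject_prefix = NULL,
                           max_retries = 60L) {
  group <- resolve_group(profile, gesture)
  label <- if (inherits(profile, "injury_profile")) profile$injury
           else if (group == "target") gesture_target_nerve(gesture) else "none"
  prefix <- subject_prefix %||% paste0("sim_", gesture, "_",
                                       if (group == "target") "T" else "N")
  withr::with_seed(seed, {
    records <- vector("list", n)
    drawn <- vector("list", n)
    retries <- 0L
    for (i in seq_len(n)) {
      done <- FALSE
      for (attempt in seq_len(max_retries)) {
        v <- as.list(draw_component_matrix(gesture, group, 1L, truncate = TRUE))
        pose <- invert_pose(gesture, v, jitter_sd = jitter_sd,
                            rotation = runif(3L, -20, 20),
                            translation = runif(3L, -0.3, 0.3))
        rec <- tryCatch(
          forward_kinematics(skeleton, pose, gesture = gesture,
                             subject_id = sprintf("%s%04d", prefix, i),
                             hand_side = hand_side, label = label),
          hs_infeasible_error = function(e) NULL
        )
        if (!is.null(rec)) {
          records[[i]] <- rec
          drawn[[i]] <- as.data.frame(v)
          done <- TRUE
          break
        }
        retries <- retries + 1L
      }
      if (!done) {
        hs_error(sprintf("record %d: no kinematically feasible draw after %d retries",
                         i, max_retries),
                 "hs_generation_error")
      }
    }
    cohort <- cohort_table(records, provenance = sprintf("synthetic %s %s", gesture, group))
    drawn_df <- if (n > 0L) add_sum_features(do.call(rbind, drawn), gesture)
                else add_sum_features(draw_component_matrix(gesture, group, 0L), gesture)
    structure(cohort, drawn_features = drawn_df, n_retries = retries)
  })
}

# ---- study-shaped cohort ---------------------------------------------------

#' Configuration for the study-shaped synthetic cohort
#'
#' Defaults mirror the reference study: 22 patients with the injury mix of
#' [reference_patients()] (all unilateral), 34 healthy volunteers, both
#' hands imaged, 3 gestures, 4 repetitions each -- 1,344 records, 448 per
#' gesture task. Repetitions of one hand share a latent per-hand severity
#' draw; repetition noise defaults to 25% of the group SD so that the
#' marginal feature distributions keep the configured group moments.
#'
#' @param patients Patient table as in [reference_patients()].
#' @param n_volunteers Number of healthy volunteers.
#' @param repetitions Repetitions per hand and gesture (1-4).
#' @param test_fraction Held-out fraction for the stratified split.
#' @param rep_noise_frac Repetition-noise SD as a fraction of group SD.
#' @param rho Uniform between-feature correlation within a group.
#' @param jitter_sd Landmark jitter SD (kinematic method only).
#' @param split_unit `"image"` (default: stratified sampling over individual
#'   records) or `"hand"` (leakage-safe variant keeping all repetitions of a
#'   hand on one side of the split).
#' @param skeleton A [hand_skeleton] (kinematic method only).
#' @return A `study_config` list.
#' @export
study_config <- function(patients = reference_patients(), n_volunteers = 34L,
                         repetitions = 4L, test_fraction = 0.25,
                         rep_noise_frac = 0.25, rho = 0, jitter_sd = 0,
                         split_unit = c("image", "hand"),
                         skeleton = hand_skeleton()) {
  split_unit <- match.arg(split_unit)
  if (repetitions < 1L || repetitions > 4L) {
    hs_error("repetitions must be in 1..4", "hs_generation_error")
  }
  if (nrow(patients) > 0L) {
    if (!all(c("subject_id", "injured_side", "radial", "ulnar", "median") %in%
             names(patients))) {
      hs_error("patients table must have subject_id, injured_side, radial, ulnar, median",
               "hs_generation_error")
    }
    if (any(!patients$radial & !patients$ulnar & !patients$median)) {
      hs_error("every patient must have at least one injured nerve",
               "hs_generation_error")
    }
  }
  structure(list(patients = patients, n_volunteers = as.integer(n_volunteers),
                 repetitions = as.integer(repetitions),
                 test_fraction = test_fraction,
                 rep_noise_frac = rep_noise_frac, rho = rho,
                 jitter_sd = jitter_sd, split_unit = split_unit,
                 skeleton = skeleton),
            class = "study_config")
}

injury_string <- function(radial, ulnar, median) {
  nerves <- c("radial", "ulnar", "median")[c(radial, ulnar, median)]
  if (length(nerves) == 0L) "none" else paste(nerves, collapse = "+")
}

# Hand-level roster: one row per (subject, side) with its injury label.
cohort_hands <- function(config) {
  pats <- config$patients
  rows <- list()
  for (i in seq_len(nrow(pats))) {
    for (side in c("left", "right")) {
      lab <- if (side == pats$injured_side[i]) {
        injury_string(pats$radial[i], pats$ulnar[i], pats$median[i])
      } else "none"
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = pats$subject_id[i], hand_side = side, label = lab,
        stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(config$n_volunteers)) {
    for (side in c("left", "right")) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sprintf("V%02d", i), hand_side = side, label = "none",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Build the study-shaped synthetic cohort
#'
#' Emits the full subjects x hands x gestures x repetitions record grid with
#' per-gesture target/non-target grouping (a hand is "target" for a gesture
#' iff it is injured in that gesture's nerve; hands with other injuries and
#' healthy hands are non-target) and a stratified train/test split.
#'
#' @param config A [study_config].
#' @param seed Integer seed driving all draws and the split.
#' @param method `"kinematic"` (default; emits landmark records through the
#'   forward model and computes features from them) or `"moments"` (samples
#'   feature values directly from the group Gaussians, no landmarks).
#' @return A `synthetic_cohort`: list with `landmarks` (a [cohort_table], or
#'   `NULL` for the moments method), `features` (named list of per-gesture
#'   feature tables with `group` and `split` columns), `config`, `seed`,
#'   `method`.
#' @export
build_study_cohort <- function(config = study_config(), seed = 1L,
                               method = c("kinematic", "moments")) {
  method <- match.arg(method)
  hands <- cohort_hands(config)
  hands$hand_id <- paste(hands$subject_id, hands$hand_side, sep = ":")
  gestures <- c("G1", "G2", "G3")
  features <- list()
  all_records <- list()

  for (gi in seq_along(gestures)) {
    g <- gestures[gi]
    nerve <- gesture_target_nerve(g)
    target_hand <- vapply(strsplit(hands$label, "+", fixed = TRUE),
                          function(x) nerve %in% x, logical(1L))
    grid <- hands[rep(seq_len(nrow(hands)), each = config$repetitions), ]
    grid$repetition <- rep(seq_len(config$repetitions), nrow(hands))
    grid$group <- ifelse(rep(target_hand, each = config$repetitions),
                         "target", "non-target")
    rownames(grid) <- NULL

    mom_names <- component_moments(g, "target")$name
    latents <- matrix(NA_real_, nrow(grid), length(mom_names))
    vals <- withr::with_seed(derive_seed(seed, 100 + gi), {
      out <- matrix(NA_real_, nrow(grid), length(mom_names))
      colnames(out) <- mom_names
      for (grp in c("target", "non-target")) {
        sel <- which(grid$group == grp)
        if (length(sel) == 0L) next
        m <- draw_component_matrix(g, grp, length(sel), rho = config$rho,
                                   hand = match(grid$hand_id[sel],
                                                unique(grid$hand_id[sel])),
                                   rep_noise_frac = config$rep_noise_frac,
                                   truncate = (method == "kinematic"))
        out[sel, ] <- as.matrix(m)
        latents[sel, ] <- attr(m, "latent_records")
      }
      out
    })

    if (method == "kinematic") {
      recs <- withr::with_seed(derive_seed(seed, 200 + gi), {
        lapply(seq_len(nrow(grid)), function(i) {
          v <- vals[i, ]
          mom <- component_moments(g, grid$group[i])
          for (attempt in 1:60) {
            pose <- invert_pose(g, as.list(v),
                                jitter_sd = config$jitter_sd,
                                rotation = runif(3L, -20, 20),
                                translation = runif(3L, -0.3, 0.3))
            rec <- tryCatch(
              forward_kinematics(config$skeleton, pose, gesture = g,
                                 subject_id = grid$subject_id[i],
                                 hand_side = grid$hand_side[i],
                                 repetition = grid$repetition[i],
                                 label = grid$label[i]),
              hs_infeasible_error = function(e) NULL)
            if (!is.null(rec)) return(rec)
            # redraw this repetition around the hand's latent severity;
            # escalate to fresh group-level draws if the latent itself sits
            # in a kinematically unreachable corner
            v <- if (attempt <= 30L) {
              clamp(latents[i, ] + mom$sd * max(config$rep_noise_frac, 0.25) * rnorm(length(v)),
                    mom$lower, mom$upper)
            } else {
              clamp(mom$mean + mom$sd * rnorm(length(v)), mom$lower, mom$upper)
            }
            names(v) <- mom$name
          }
          hs_error(sprintf("record %s: no kinematically feasible draw after 60 retries",
                           paste(grid$subject_id[i], grid$hand_side[i], g,
                                 grid$repetition[i], sep = ":")),
                   "hs_generation_error")
        })
      })
      all_records <- c(all_records, recs)
      feat <- extract_features(cohort_table(recs), g)
    } else {
      feat <- cbind(
        data.frame(record_id = paste(grid$subject_id, grid$hand_side, g,
                                     grid$repetition, sep = ":"),
                   subject_id = grid$subject_id, hand_side = grid$hand_side,
                   gesture = g, repetition = grid$repetition,
                   label = grid$label, stringsAsFactors = FALSE),
        add_sum_features(as.data.frame(vals), g)
      )
    }
    feat$group <- grid$group
    feat$split <- stratified_split(grid$group, test_fraction = config$test_fraction,
                                   seed = derive_seed(seed, 300 + gi),
                                   unit = if (config$split_unit == "hand") grid$hand_id else NULL)
    features[[g]] <- feat
  }

  structure(list(
    landmarks = if (method == "kinematic") {
      cohort_table(all_records, provenance = sprintf("synthetic study cohort (seed %d)", seed))
    },
    features = features, config = config, seed = seed, method = method
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  n <- sum(vapply(x$features, nrow, integer(1L)))
  cat(sprintf("<synthetic_cohort: %d records (%s method, seed %d)>\n",
              n, x$method, x$seed))
  for (g in names(x$features)) {
    f <- x$features[[g]]
    cat(sprintf("  %s: %d records (%d target / %d non-target), split %d train / %d test\n",
                g, nrow(f), sum(f$group == "target"), sum(f$group == "non-target"),
                sum(f$split == "train"), sum(f$split == "test")))
  }
  invisible(x)
}
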