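# Geometric primitives and the 23 predetermined gesture features.
#
# Landmarks follow the standard 21-point hand skeleton, 0-indexed:
# 0 wrist; 1-4 thumb CMC, MCP, IP, TIP; 5-8 index MCP, PIP, DIP, TIP;
# 9-12 middle; 13-16 ring; 17-20 little.

# Row in the 21x3 point matrix for a 0-based landmark index.
lm_row <- function(i) i + 1L

# (previous, joint, next) landmark triplets defining each supported joint.
JOINT_TRIPLETS <- list(
  thumb_CMC  = c(0L, 1L, 2L),
  thumb_MCP  = c(1L, 2L, 3L),
  thumb_IP   = c(2L, 3L, 4L),
  index_MCP  = c(0L, 5L, 6L),
  index_PIP  = c(5L, 6L, 7L),
  index_DIP  = c(6L, 7L, 8L),
  middle_MCP = c(0L, 9L, 10L),
  middle_PIP = c(9L, 10L, 11L),
  middle_DIP = c(10L, 11L, 12L),
  ring_MCP   = c(0L, 13L, 14L),
  ring_PIP   = c(13L, 14L, 15L),
  ring_DIP   = c(14L, 15L, 16L),
  little_MCP = c(0L, 17L, 18L),
  little_PIP = c(17L, 18L, 19L),
  little_DIP = c(18L, 19L, 20L)
)

#' Angle between two 3-D vectors
#'
#' Returns the unsigned angle between two vectors as
#' \eqn{\theta = \arccos(v_1 \cdot v_2 / (|v_1||v_2|))} in degrees. The
#' normalized dot product is clamped to \[-1, 1\] to guard against rounding
#' just outside the arccos domain.
#'
#' @param v1,v2 Numeric 3-vectors with nonzero norm.
#' @return Angle in degrees, in \[0, 180\].
#' @examples
#' angle_between(c(1, 0, 0), c(0, 1, 0)) # 90
#' angle_between(c(1, 0, 0), c(1, 1, 0)) # 45
#' @export
angle_between <- function(v1, v2) {
  u1 <- unit_vec(v1, "first vector")
  u2 <- unit_vec(v2, "second vector")
  # atan2 form of the clamped-arccos definition: identical values, but
  # numerically stable for near-parallel vectors
  rad2deg(atan2(vec_norm(cross3(u1, u2)), clamp(sum(u1 * u2), -1, 1)))
}

#' Euclidean distance between two landmarks
#'
#' @param p1,p2 Numeric 3-vectors of finite coordinates.
#' @return Nonnegative distance in model units.
#' @export
euclid_distance <- function(p1, p2) {
  if (!all(is.finite(p1)) || !all(is.finite(p2))) {
    hs_error("landmark coordinates must be finite", "hs_geometry_error")
  }
  vec_norm(p1 - p2)
}

#' Standardize a distance by a reference distance
#'
#' Divides a raw distance by a subject-intrinsic reference distance (here the
#' thumb tip-to-IP segment), yielding a dimensionless, camera- and
#' scale-invariant value.
#'
#' @param d_original Raw distance.
#' @param d_standard Reference distance, strictly positive.
#' @return `d_original / d_standard`.
#' @export
standardize_distance <- function(d_original, d_standard) {
  if (!is.finite(d_standard) || d_standard <= 0) {
    hs_error("degenerate geometry: standard distance must be > 0",
             "hs_geometry_error")
  }
  d_original / d_standard
}

points_matrix <- function(lms) {
  if (inherits(lms, "hand_landmarks")) lms$points else lms
}

#' Joint flexion angle at a named hand joint
#'
#' Angle between the proximal segment direction (previous landmark to the
#' joint) and the distal segment direction (joint to the following landmark).
#' A perfectly straight chain gives 0. For the finger MCP joints the proximal
#' segment runs from the single wrist landmark to the MCP, the only
#' construction available on a skeleton without metacarpal-base landmarks;
#' extended-hand MCP angles are therefore small but nonzero in practice.
#'
#' @param lms A [hand_landmarks] object or a 21x3 point matrix.
#' @param joint Joint name, e.g. `"index_MCP"`; one of `names(JOINT_TRIPLETS)`:
#'   thumb CMC/MCP/IP and MCP/PIP/DIP of the four fingers.
#' @return Angle in degrees, in \[0, 180\].
#' @export
joint_angle <- function(lms, joint) {
  pts <- points_matrix(lms)
  trip <- JOINT_TRIPLETS[[joint]]
  if (is.null(trip)) {
    hs_error(sprintf("unknown joint '%s'", joint), "hs_geometry_error")
  }
  p <- pts[lm_row(trip[1L]), ]
  q <- pts[lm_row(trip[2L]), ]
  r <- pts[lm_row(trip[3L]), ]
  if (vec_norm(q - p) < 1e-12 || vec_norm(r - q) < 1e-12) {
    hs_error(sprintf("degenerate geometry at joint '%s': coincident adjacent landmarks (%d, %d, %d)",
                     joint, trip[1L], trip[2L], trip[3L]),
             "hs_geometry_error")
  }
  angle_between(q - p, r - q)
}

#' Webspace angle between adjacent fingers
#'
#' Angle between the whole-finger direction rays (MCP to fingertip) flanking
#' the webspace: third webspace = middle/ring, fourth = ring/little. Captures
#' finger adduction ability; a persistently abducted little finger
#' (Wartenberg sign) enlarges the fourth webspace angle.
#'
#' @param lms A [hand_landmarks] object or 21x3 point matrix.
#' @param web `"third"` or `"fourth"`.
#' @return Angle in degrees, in \[0, 180\].
#' @export
webspace_angle <- function(lms, web = c("third", "fourth")) {
  web <- match.arg(web)
  pts <- points_matrix(lms)
  ray <- function(mcp, tip) {
    v <- pts[lm_row(tip), ] - pts[lm_row(mcp), ]
    if (vec_norm(v) < 1e-12) {
      hs_error("degenerate geometry: zero-length finger ray", "hs_geometry_error")
    }
    v
  }
  if (web == "third") {
    angle_between(ray(9L, 12L), ray(13L, 16L))
  } else {
    angle_between(ray(13L, 16L), ray(17L, 20L))
  }
}

#' Thumb palmar abduction angle (signed)
#'
#' Elevation of the thumb ray (thumb MCP to thumb tip) out of the palm plane
#' spanned by the wrist, index MCP, and little MCP landmarks, returned
#' negated so that larger (less negative) values indicate reduced palmar
#' abduction -- the ape-hand pattern of median nerve palsy. The elevation is
#' unsigned (measured as distance from the plane), which keeps the feature
#' invariant under reflection of the landmark set.
#'
#' @param lms A [hand_landmarks] object or 21x3 point matrix.
#' @return Negated elevation angle in degrees, in \[-90, 0\].
#' @export
palmar_abduction_angle <- function(lms) {
  pts <- points_matrix(lms)
  wrist <- pts[lm_row(0L), ]
  imcp <- pts[lm_row(5L), ]
  lmcp <- pts[lm_row(17L), ]
  n <- cross3(imcp - wrist, lmcp - wrist)
  if (vec_norm(n) < 1e-10) {
    hs_error("degenerate geometry: palm-plane landmarks (wrist, index MCP, little MCP) are collinear",
             "hs_geometry_error")
  }
  nh <- n / vec_norm(n)
  ray <- pts[lm_row(4L), ] - pts[lm_row(2L), ]
  if (vec_norm(ray) < 1e-12) {
    hs_error("degenerate geometry: zero-length thumb ray", "hs_geometry_error")
  }
  elev <- rad2deg(asin(clamp(abs(sum(ray * nh)) / vec_norm(ray), 0, 1)))
  -elev
}

#' Standardized thumb-to-index tip distance
#'
#' Distance between thumb tip (landmark 4) and index tip (landmark 8),
#' divided by the thumb tip-to-IP distance (landmarks 4-3). The ratio is
#' dimensionless and invariant under global scaling; 0 means perfect pinch
#' contact.
#'
#' @param lms A [hand_landmarks] object or 21x3 point matrix.
#' @return Dimensionless nonnegative ratio.
#' @export
tip_distance <- function(lms) {
  pts <- points_matrix(lms)
  d_std <- euclid_distance(pts[lm_row(4L), ], pts[lm_row(3L), ])
  if (d_std < 1e-12) {
    hs_error("degenerate geometry: thumb tip and IP landmarks coincide",
             "hs_geometry_error")
  }
  standardize_distance(euclid_distance(pts[lm_row(4L), ], pts[lm_row(8L), ]), d_std)
}

#' Registry of the 23 predetermined features
#'
#' One row per feature: its number (01-23), name, owning gesture, kind, and
#' whether the raw angle is negated (`signed`). Negation is applied to the
#' pinch-gesture joint angles and the palmar abduction angle so that "higher
#' value = more abnormal" holds uniformly for every feature, which is what
#' lets a single greater-than rule direction drive the classifier. Sum
#' features (`ag_ring`, `ag_little`, `ag_thumb`, `ag_index`) are exact sums
#' of their component features.
#'
#' @return A data frame with columns `number`, `name`, `gesture`, `kind`,
#'   `signed`.
#' @export
feature_registry <- function() {
  data.frame(
    number = 1:23,
    name = c("ag_thumb_MCP", "ag_index_MCP", "ag_middle_MCP", "ag_ring_MCP",
             "ag_little_MCP",
             "ag_ring_PIP", "ag_ring_DIP", "ag_ring", "ag_little_PIP",
             "ag_little_DIP", "ag_little", "web3", "web4",
             "ag_thumb_CMC", "ag_thumb_MCP", "ag_thumb_IP", "ag_thumb",
             "ag_index_MCP", "ag_index_PIP", "ag_index_DIP", "ag_index",
             "ag_palmab", "dis_tip"),
    gesture = rep(c("G1", "G2", "G3"), c(5L, 8L, 10L)),
    kind = c(rep("joint-angle", 5L),
             "joint-angle", "joint-angle", "angle-sum",
             "joint-angle", "joint-angle", "angle-sum",
             "webspace-angle", "webspace-angle",
             "joint-angle", "joint-angle", "joint-angle", "angle-sum",
             "joint-angle", "joint-angle", "joint-angle", "angle-sum",
             "palmar-abduction-angle", "standardized-distance"),
    signed = c(rep(FALSE, 13L), rep(TRUE, 9L), FALSE),
    stringsAsFactors = FALSE
  )
}

#' Names of the features registered for one gesture
#'
#' @param gesture `"G1"`, `"G2"`, or `"G3"`.
#' @return Character vector of feature names in registry order.
#' @export
gesture_features <- function(gesture) {
  reg <- feature_registry()
  reg$name[reg$gesture == gesture]
}

#' Compute the feature vector of one gesture record
#'
#' Evaluates exactly the features registered for the record's gesture:
#' * G1 (digit abduction/extension, radial nerve): MCP joint angles of all
#'   five digits.
#' * G2 (digit adduction, ulnar nerve): ring and little PIP/DIP angles, their
#'   per-finger sums, and the third and fourth webspace angles.
#' * G3 (tip pinch, median nerve): thumb CMC/MCP/IP and index MCP/PIP/DIP
#'   angles (all negated) with their per-digit sums, the signed palmar
#'   abduction angle, and the standardized tip distance.
#'
#' @param lms A [hand_landmarks] object with its `gesture` field set, or a
#'   21x3 point matrix plus an explicit `gesture`.
#' @param gesture Optional gesture override.
#' @return Named numeric vector of feature values (degrees for angles,
#'   dimensionless for `dis_tip`), with attribute `"gesture"`.
#' @export
compute_features <- function(lms, gesture = NULL) {
  gesture <- gesture %||% (if (inherits(lms, "hand_landmarks")) lms$gesture else NULL)
  if (is.null(gesture) || !gesture %in% c("G1", "G2", "G3")) {
    hs_error("gesture must be one of 'G1', 'G2', 'G3'", "hs_validation_error")
  }
  pts <- points_matrix(lms)
  vals <- switch(
    gesture,
    G1 = c(
      ag_thumb_MCP  = joint_angle(pts, "thumb_MCP"),
      ag_index_MCP  = joint_angle(pts, "index_MCP"),
      ag_middle_MCP = joint_angle(pts, "middle_MCP"),
      ag_ring_MCP   = joint_angle(pts, "ring_MCP"),
      ag_little_MCP = joint_angle(pts, "little_MCP")
    ),
    G2 = {
      rp <- joint_angle(pts, "ring_PIP")
      rd <- joint_angle(pts, "ring_DIP")
      lp <- joint_angle(pts, "little_PIP")
      ld <- joint_angle(pts, "little_DIP")
      c(ag_ring_PIP = rp, ag_ring_DIP = rd, ag_ring = rp + rd,
        ag_little_PIP = lp, ag_little_DIP = ld, ag_little = lp + ld,
        web3 = webspace_angle(pts, "third"),
        web4 = webspace_angle(pts, "fourth"))
    },
    G3 = {
      tc <- -joint_angle(pts, "thumb_CMC")
      tm <- -joint_angle(pts, "thumb_MCP")
      ti <- -joint_angle(pts, "thumb_IP")
      im <- -joint_angle(pts, "index_MCP")
      ip <- -joint_angle(pts, "index_PIP")
      id <- -joint_angle(pts, "index_DIP")
      c(ag_thumb_CMC = tc, ag_thumb_MCP = tm, ag_thumb_IP = ti,
        ag_thumb = tc + tm + ti,
        ag_index_MCP = im, ag_index_PIP = ip, ag_index_DIP = id,
        ag_index = im + ip + id,
        ag_palmab = palmar_abduction_angle(pts),
        dis_tip = tip_distance(pts))
    }
  )
  if (!all(is.finite(vals))) {
    bad <- names(vals)[!is.finite(vals)]
    hs_error(sprintf("non-finite feature value(s): %s", paste(bad, collapse = ", ")),
             "hs_geometry_error")
  }
  structure(vals, gesture = gesture)
}

#' Extract a feature table from a cohort
#'
#' Applies [compute_features()] to every record of one gesture in a cohort
#' table, returning metadata columns plus one column per registered feature.
#'
#' @param cohort A [cohort_table].
#' @param gesture Gesture to extract (`"G1"`, `"G2"`, `"G3"`). If `NULL`, a
#'   named list with one table per gesture present is returned.
#' @return A data frame (or named list of data frames) with columns
#'   `record_id`, `subject_id`, `hand_side`, `gesture`, `repetition`, `label`
#'   and the gesture's feature names.
#' @export
extract_features <- function(cohort, gesture = NULL) {
  if (is.null(gesture)) {
    gs <- intersect(c("G1", "G2", "G3"), unique(cohort$gesture))
    return(setNames(lapply(gs, function(g) extract_features(cohort, g)), gs))
  }
  rows <- which(cohort$gesture == gesture)
  feats <- gesture_features(gesture)
  meta <- cohort[rows, c("subject_id", "hand_side", "gesture", "repetition", "label"),
                 drop = FALSE]
  vals <- matrix(NA_real_, length(rows), length(feats),
                 dimnames = list(NULL, feats))
  for (k in seq_along(rows)) {
    lms <- cohort_record(cohort, rows[k])
    vals[k, ] <- tryCatch(
      compute_features(lms),
      handscreen_error = function(e) {
        hs_error(sprintf("record %s: %s", record_key(lms), conditionMessage(e)),
                 "hs_geometry_error")
      }
    )
  }
  out <- cbind(record_id = record_keys(cohort)[rows], meta,
               as.data.frame(vals), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
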