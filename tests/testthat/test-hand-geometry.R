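test_that("geometric primitives match analytic values", {
  expect_equal(angle_between(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(angle_between(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(angle_between(c(1, 0, 0), c(1, 1, 0)), 45)
  expect_equal(angle_between(c(1, 0, 0), c(-1, 0, 0)), 180)
  expect_error(angle_between(c(0, 0, 0), c(1, 0, 0)), class = "hs_geometry_error")

  expect_equal(euclid_distance(c(0, 0, 0), c(1, 2, 2)), 3)
  expect_equal(euclid_distance(c(1, 1, 1), c(1, 1, 1)), 0)
  expect_equal(euclid_distance(c(1, 1, 1), c(2, 2, 2)), sqrt(3))

  expect_equal(standardize_distance(2, 2), 1)
  expect_equal(standardize_distance(0, 5), 0)
  expect_equal(standardize_distance(4, 2), 2)
  expect_error(standardize_distance(1, 0), class = "hs_geometry_error")
})

test_that("a fully extended flat hand has zero joint angles everywhere", {
  lms <- flat_hand()
  for (joint in names(handscreen:::JOINT_TRIPLETS)) {
    expect_lt(joint_angle(lms, joint), 1e-9)
  }
  expect_lt(max(abs(compute_features(lms, "G1"))), 1e-9)
})

test_that("joint angles recover configured flexions and grow monotonically", {
  sk <- hand_skeleton()
  lms <- forward_kinematics(sk, pose_parameters(index = c(19.02, 4, 3)))
  expect_equal(joint_angle(lms, "index_MCP"), 19.02, tolerance = 1e-6)

  angles <- vapply(c(5, 15, 30, 55, 80), function(a) {
    joint_angle(forward_kinematics(sk, pose_parameters(index = c(a, 10, 5))),
                "index_MCP")
  }, numeric(1))
  expect_true(all(diff(angles) > 0))
})

test_that("webspace angles respond to abduction of the correct finger only", {
  sk <- hand_skeleton()
  base <- forward_kinematics(sk, pose_parameters())
  # abduct the little finger in the palm plane: web4 grows, web3 untouched
  sweep <- lapply(c(0, 5, 10), function(a) {
    forward_kinematics(sk, pose_parameters(
      little = c(a, 0, 0),
      plane_azimuth = c(index = 0, middle = 0, ring = 0, little = 90)))
  })
  w4 <- vapply(sweep, webspace_angle, numeric(1), web = "fourth")
  w3 <- vapply(sweep, webspace_angle, numeric(1), web = "third")
  expect_true(all(diff(w4) > 1))
  expect_equal(w3, rep(w3[1L], 3L), tolerance = 1e-9)

  # exact webspace targets are reproduced
  lms <- forward_kinematics(sk, pose_parameters(
    ring = c(0, 13.81, 13.05), web3 = 8.33))
  expect_equal(webspace_angle(lms, "third"), 8.33, tolerance = 1e-6)

  # two parallel finger rays form a zero-degree webspace
  pts <- flat_hand()$points
  pts[14:17, ] <- sweep(pts[10:13, ], 2L, c(-0.2, 0, 0), `+`)
  expect_equal(webspace_angle(pts, "third"), 0, tolerance = 1e-9)
})

test_that("palmar abduction is the negated thumb-ray elevation", {
  sk <- hand_skeleton()
  # thumb ray lying in the palm plane
  expect_equal(palmar_abduction_angle(flat_hand()$points), 0, tolerance = 1e-9)

  lms <- forward_kinematics(sk, pose_parameters(
    thumb = c(10, 20, 15), thumb_elevation = 19.95))
  expect_equal(palmar_abduction_angle(lms), -19.95, tolerance = 1e-6)

  # reducing the elevation strictly increases the returned value
  vals <- vapply(c(30, 20, 10, 4), function(e) {
    palmar_abduction_angle(forward_kinematics(sk, pose_parameters(
      thumb = c(10, 20, 15), thumb_elevation = e)))
  }, numeric(1))
  expect_true(all(diff(vals) > 0))

  # collinear palm landmarks are a degenerate geometry
  pts <- flat_hand()$points
  pts[18L, ] <- 2 * pts[6L, ]
  pts[1L, ] <- c(0, 0, 0)
  pts[6L, ] <- c(0.3, 1, 0)
  pts[18L, ] <- c(0.6, 2, 0)
  expect_error(palmar_abduction_angle(pts), "collinear", class = "hs_geometry_error")
})

test_that("tip distance is a scale-invariant standardized ratio", {
  pts <- flat_hand()$points
  pts[9L, ] <- pts[5L, ]   # index tip touches thumb tip
  expect_equal(tip_distance(pts), 0)

  # tip gap equal to the thumb tip-IP length gives exactly 1
  gap <- euclid_distance(pts[5L, ], pts[4L, ])
  pts2 <- flat_hand()$points
  pts2[9L, ] <- pts2[5L, ] + c(gap, 0, 0)
  expect_equal(tip_distance(pts2), 1, tolerance = 1e-12)
  expect_equal(tip_distance(pts2 * 2), tip_distance(pts2), tolerance = 1e-12)
})

test_that("feature vectors have the registered layout and exact sums", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 23L)
  expect_equal(unname(table(reg$gesture)[c("G1", "G2", "G3")]),
               c(5L, 8L, 10L), ignore_attr = TRUE)

  lms <- forward_kinematics(hand_skeleton(), random_pose(11), gesture = "G2")
  f2 <- compute_features(lms)
  expect_named(f2, gesture_features("G2"))
  expect_identical(f2[["ag_ring"]], f2[["ag_ring_PIP"]] + f2[["ag_ring_DIP"]])
  expect_identical(f2[["ag_little"]], f2[["ag_little_PIP"]] + f2[["ag_little_DIP"]])

  lms3 <- forward_kinematics(hand_skeleton(), random_pose(12), gesture = "G3")
  f3 <- compute_features(lms3)
  expect_named(f3, gesture_features("G3"))
  expect_identical(f3[["ag_thumb"]],
                   f3[["ag_thumb_CMC"]] + f3[["ag_thumb_MCP"]] + f3[["ag_thumb_IP"]])
  expect_identical(f3[["ag_index"]],
                   f3[["ag_index_MCP"]] + f3[["ag_index_PIP"]] + f3[["ag_index_DIP"]])
  # starred pinch-gesture angles are nonpositive by construction
  expect_true(all(f3[reg$name[reg$gesture == "G3" & reg$signed]] <= 0))

  # additivity on a constructed claw pose
  lms2 <- forward_kinematics(hand_skeleton(),
                             pose_parameters(ring = c(0, 13.81, 13.05)),
                             gesture = "G2")
  expect_equal(compute_features(lms2)[["ag_ring"]], 26.86, tolerance = 1e-6)
})

test_that("features are invariant under rigid motion and reflection", {
  sk <- hand_skeleton()
  for (g in c("G1", "G2", "G3")) {
    pose <- random_pose(20 + match(g, c("G1", "G2", "G3")))
    ref <- compute_features(forward_kinematics(sk, pose, gesture = g))
    moved <- pose
    moved$rotation <- c(33, -21, 57)
    moved$translation <- c(1.5, -2.2, 0.7)
    f_moved <- compute_features(forward_kinematics(sk, moved, gesture = g))
    expect_equal(f_moved, ref, tolerance = 1e-9)

    # reflection (the left-hand mirror) leaves every feature unchanged
    mirrored <- forward_kinematics(sk, pose, gesture = g, hand_side = "left")
    expect_equal(compute_features(mirrored), ref, tolerance = 1e-9)
  }
})
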