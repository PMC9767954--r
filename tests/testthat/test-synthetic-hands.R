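test_that("the identity pose is a straight planar hand, reproducibly", {
  lms <- forward_kinematics(hand_skeleton(), pose_parameters())
  for (joint in names(handscreen:::JOINT_TRIPLETS)) {
    expect_lt(joint_angle(lms, joint), 1e-9)
  }
  expect_true(all(abs(lms$points[, 3L]) < 1e-12))

  pose <- pose_parameters(index = c(30, 10, 5), jitter_sd = 0.01)
  a <- forward_kinematics(hand_skeleton(), pose, seed = 5)
  b <- forward_kinematics(hand_skeleton(), pose, seed = 5)
  expect_identical(a$points, b$points)
  c <- forward_kinematics(hand_skeleton(), pose, seed = 6)
  expect_false(identical(a$points, c$points))

  lms30 <- forward_kinematics(hand_skeleton(), pose_parameters(index = c(30, 0, 0)))
  expect_equal(joint_angle(lms30, "index_MCP"), 30, tolerance = 1e-6)

  expect_error(pose_parameters(index = c(400, 0, 0)), class = "hs_generation_error")
})

test_that("moment sampling recovers the configured group moments", {
  ref <- feature_reference()
  n <- 20000
  f <- sample_features("non-target", "G1", n, seed = 801)
  row <- ref[ref$number == 1L, ]
  expect_equal(mean(f$ag_thumb_MCP), row$mean_nontarget,
               tolerance = 3 * row$sd_nontarget / sqrt(n))
  expect_equal(sd(f$ag_thumb_MCP), row$sd_nontarget,
               tolerance = 3 * row$sd_nontarget / sqrt(2 * n))

  ft <- sample_features("target", "G2", n, seed = 802)
  w <- ref[ref$name == "web3" & ref$gesture == "G2", ]
  expect_equal(mean(ft$web3), w$mean_target,
               tolerance = 3 * w$sd_target / sqrt(n))

  # sums are exact sums of their sampled components
  expect_identical(ft$ag_ring, ft$ag_ring_PIP + ft$ag_ring_DIP)

  expect_identical(sample_features("target", "G2", 100, seed = 7),
                   sample_features("target", "G2", 100, seed = 7))
  expect_false(identical(sample_features("target", "G2", 100, seed = 7),
                         sample_features("target", "G2", 100, seed = 8)))

  # degenerate full correlation: perfect rank correlation between features
  fr <- sample_features("non-target", "G1", 500, seed = 803, rho = 1)
  expect_equal(cor(fr$ag_thumb_MCP, fr$ag_index_MCP, method = "spearman"), 1)

  expect_equal(nrow(sample_features("target", "G1", 0, seed = 1)), 0L)
})

test_that("kinematic sampling reproduces each drawn feature vector exactly", {
  for (g in c("G1", "G2", "G3")) {
    for (grp in c("target", "non-target")) {
      ch <- sample_gesture(grp, g, 25, seed = 810 + match(g, c("G1", "G2", "G3")))
      drawn <- attr(ch, "drawn_features")
      computed <- extract_features(ch, g)
      expect_lt(max(abs(as.matrix(computed[, names(drawn)]) - as.matrix(drawn))),
                1e-6)
    }
  }
  expect_equal(nrow(sample_gesture("target", "G2", 0, seed = 1)), 0L)
})

test_that("kinematic draws follow the feasibility-truncated Gaussian", {
  # G1 thumb MCP angles are truncated at 0; compare against the closed-form
  # truncated-normal mean
  n <- 400
  ch <- sample_gesture("non-target", "G1", n, seed = 820)
  f <- extract_features(ch, "G1")
  mu <- 5.49; s <- 3.59
  a <- -mu / s
  trunc_mean <- mu + s * dnorm(a) / (1 - pnorm(a))
  expect_equal(mean(f$ag_thumb_MCP), trunc_mean, tolerance = 4 * s / sqrt(n))
  expect_true(all(f$ag_thumb_MCP >= 0))
})

test_that("injury profiles assign target groups by innervation", {
  p <- injury_profile("ulnar+median")
  expect_equal(unname(p$gesture_group), c("non-target", "target", "target"))
  expect_equal(unname(injury_profile("radial")$gesture_group),
               c("target", "non-target", "non-target"))
  expect_equal(unname(injury_profile("none")$gesture_group),
               rep("non-target", 3L))
})

test_that("the study cohort respects the configured bookkeeping arithmetic", {
  # reduced configuration: closed-form expectations
  pats <- reference_patients()[1:4, ]   # 2 ulnar+median, 2 radial
  cfg <- study_config(patients = pats, n_volunteers = 3L, repetitions = 2L)
  coh <- build_study_cohort(cfg, seed = 3, method = "moments")
  n_subj <- 4 + 3
  expect_equal(sum(vapply(coh$features, nrow, integer(1))), n_subj * 2 * 3 * 2)
  g1 <- coh$features$G1
  expect_equal(nrow(g1), n_subj * 2 * 2)
  expect_equal(sum(g1$group == "target"), 2 * 1 * 2)   # radial patients
  expect_equal(sum(coh$features$G2$group == "target"), 2 * 1 * 2)
  expect_equal(sum(coh$features$G3$group == "target"), 2 * 1 * 2)
  expect_false(any(duplicated(g1$record_id)))

  # split: per-stratum rounding of the 3:1 ratio
  for (g in names(coh$features)) {
    f <- coh$features[[g]]
    for (grp in unique(f$group)) {
      n_g <- sum(f$group == grp)
      expect_equal(sum(f$group == grp & f$split == "test"), round(n_g / 4))
    }
  }

  # deterministic rebuild
  coh2 <- build_study_cohort(cfg, seed = 3, method = "moments")
  expect_identical(coh$features, coh2$features)

  # hand-level split mode keeps a hand's repetitions together
  cfgh <- study_config(patients = pats, n_volunteers = 6L, repetitions = 2L,
                       split_unit = "hand")
  cohh <- build_study_cohort(cfgh, seed = 4, method = "moments")
  fh <- cohh$features$G1
  hand <- paste(fh$subject_id, fh$hand_side)
  expect_true(all(rowSums(table(hand, fh$split) > 0) == 1L))
})

test_that("kinematic and moment cohorts expose the same feature layout", {
  pats <- reference_patients()[c(3, 6, 13), ]  # one radial, one ulnar, one median
  cfg <- study_config(patients = pats, n_volunteers = 2L, repetitions = 2L)
  kin <- build_study_cohort(cfg, seed = 5, method = "kinematic")
  mom <- build_study_cohort(cfg, seed = 5, method = "moments")
  expect_identical(lapply(kin$features, names), lapply(mom$features, names))
  expect_s3_class(kin$landmarks, "cohort_table")
  expect_null(mom$landmarks)
  expect_equal(nrow(kin$landmarks), 3 * 2 * 2 * 5)
  # landmark-derived features respect group separation direction on average
  g1 <- kin$features$G1
  expect_gt(mean(g1$ag_thumb_MCP[g1$group == "target"]),
            mean(g1$ag_thumb_MCP[g1$group == "non-target"]))
})
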