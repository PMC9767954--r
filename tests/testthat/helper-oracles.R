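# Shared oracles and fixture builders, independent of the implementation
# paths they check.

# All-pairs Mann-Whitney concordance: fraction of (positive, negative) score
# pairs that are concordant, with half credit for ties.
auc_bruteforce <- function(scores, pos) {
  sp <- scores[pos]
  sn <- scores[!pos]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Closed-form AUC between two Gaussian score distributions.
auc_binormal <- function(mu0, sd0, mu1, sd1) {
  pnorm((mu1 - mu0) / sqrt(sd0^2 + sd1^2))
}

# A flat, fully extended synthetic right hand.
flat_hand <- function(gesture = "G1") {
  forward_kinematics(hand_skeleton(), pose_parameters(), gesture = gesture)
}

# Small valid cohort with mixed metadata for I/O tests.
make_test_cohort <- function(n_subjects = 2L) {
  records <- list()
  for (s in seq_len(n_subjects)) {
    for (side in c("left", "right")) {
      for (g in c("G1", "G2")) {
        pose <- pose_parameters(index = c(5 * s, 4, 3), ring = c(2, 8, 6))
        records[[length(records) + 1L]] <- forward_kinematics(
          hand_skeleton(), pose, gesture = g,
          subject_id = sprintf("S%02d", s), hand_side = side,
          repetition = s, label = if (s == 1L) "none" else "ulnar")
      }
    }
  }
  cohort_table(records, provenance = "test fixture")
}

# Random landmark set (valid geometry) for invariance checks.
random_pose <- function(seed, with_targets = FALSE) {
  set.seed(seed)
  pose_parameters(
    thumb = runif(3, 2, 35),
    index = c(runif(1, 1, 45), runif(1, 1, 70), runif(1, 1, 50)),
    middle = c(runif(1, 1, 45), runif(1, 1, 70), runif(1, 1, 50)),
    ring = c(runif(1, 1, 45), runif(1, 1, 70), runif(1, 1, 50)),
    little = c(runif(1, 1, 45), runif(1, 1, 70), runif(1, 1, 50)),
    plane_azimuth = c(index = runif(1, -25, 25), middle = runif(1, -25, 25),
                      ring = runif(1, -25, 25), little = runif(1, -25, 25)),
    web3 = if (with_targets) runif(1, 0.5, 14),
    web4 = if (with_targets) runif(1, 0.5, 16),
    thumb_elevation = if (with_targets) runif(1, 1, 45)
  )
}
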