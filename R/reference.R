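# Clinical reference values embedded as generator defaults.
#
# The group moments, t-test P values, and training-set AUCs below were
# observed in a clinical calibration cohort of 22 patients with unilateral
# radial, ulnar, or median nerve injury and 34 healthy volunteers (1,344
# gesture images). They parameterize the synthetic generators and the worked
# examples; they are not recomputed by the package.

#' Reference moments and AUCs of the 23 predetermined features
#'
#' For every feature: the non-target and target group mean and standard
#' deviation (degrees; dimensionless for `dis_tip`), the two-sided
#' independent t-test P value between the groups, and the training-set AUC
#' observed in the clinical calibration cohort. Per gesture task, "target"
#' means hands injured in that gesture's nerve; "non-target" pools hands
#' with other nerve injuries and healthy hands. These moments are the default
#' distributions of the synthetic generators.
#'
#' @return A data frame joining [feature_registry()] with columns
#'   `mean_nontarget`, `sd_nontarget`, `mean_target`, `sd_target`, `p_value`,
#'   `auc`.
#' @export
feature_reference <- function() {
  reg <- feature_registry()
  ref <- data.frame(
    number = 1:23,
    mean_nontarget = c(5.49, 8.46, 4.87, 6.99, 13.75,
                       6.75, 4.74, 11.49, 7.02, 5.85, 12.87, 1.58, 1.75,
                       -28.16, -24.10, -42.20, -94.47,
                       -32.72, -70.28, -36.99, -139.99, -19.95, 0.72),
    sd_nontarget = c(3.59, 3.30, 2.39, 3.14, 6.37,
                     7.08, 6.28, 12.51, 4.48, 5.72, 9.57, 1.00, 1.51,
                     6.62, 9.88, 19.62, 19.51,
                     5.41, 18.33, 13.85, 19.53, 8.34, 0.28),
    mean_target = c(21.36, 19.02, 17.44, 19.80, 24.73,
                    13.81, 13.05, 26.87, 12.46, 13.70, 26.16, 6.50, 8.33,
                    -30.16, -30.61, -39.89, -100.66,
                    -29.91, -55.08, -40.21, -125.21, -9.30, 1.19),
    sd_target = c(7.27, 9.95, 11.74, 11.87, 16.13,
                  12.95, 15.13, 27.13, 9.35, 12.43, 21.39, 1.83, 5.27,
                  5.61, 12.01, 28.04, 30.51,
                  6.87, 25.78, 28.77, 49.30, 4.43, 0.81),
    p_value = c(0.00, 0.00, 0.00, 0.00, 0.00,
                0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00,
                0.19, 0.01, 0.72, 0.38, 0.03, 0.02, 0.62, 0.20, 0.00, 0.02),
    auc = c(0.95, 0.85, 0.89, 0.85, 0.68,
            0.68, 0.68, 0.67, 0.66, 0.71, 0.66, 0.99, 0.89,
            0.59, 0.65, 0.49, 0.61, 0.39, 0.33, 0.54, 0.60, 0.87, 0.66)
  )
  merge(reg, ref, by = "number", sort = TRUE)
}

#' Patient mix of the reference study cohort
#'
#' The 22 patients of the clinical calibration cohort: injured side and the
#' injured nerve(s). Ten patients had an isolated radial nerve injury, five
#' ulnar, one median, and six combined ulnar and median injuries; all were
#' unilateral. This table is the default patient configuration of
#' [build_study_cohort()].
#'
#' @return A data frame with columns `subject_id`, `injured_side`, `radial`,
#'   `ulnar`, `median`.
#' @export
reference_patients <- function() {
  side <- c("right", "left", "left", "left", "right", "right", "left",
            "right", "right", "left", "right", "right", "right", "left",
            "left", "left", "right", "left", "right", "left", "left", "right")
  radial <- c(3, 4, 5, 9, 10, 14, 15, 16, 17, 20)
  ulnar <- c(1, 2, 6, 7, 8, 11, 12, 18, 19, 21, 22)
  median <- c(1, 2, 11, 13, 18, 19, 21)
  data.frame(
    subject_id = sprintf("P%02d", 1:22),
    injured_side = side,
    radial = 1:22 %in% radial,
    ulnar = 1:22 %in% ulnar,
    median = 1:22 %in% median,
    stringsAsFactors = FALSE
  )
}

# Gesture -> nerve whose injury defines that gesture's target group.
GESTURE_NERVE <- c(G1 = "radial", G2 = "ulnar", G3 = "median")

#' Nerve targeted by a gesture task
#'
#' @param gesture `"G1"`, `"G2"`, or `"G3"`.
#' @return `"radial"`, `"ulnar"`, or `"median"`.
#' @export
gesture_target_nerve <- function(gesture) {
  unname(GESTURE_NERVE[[gesture]])
}
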