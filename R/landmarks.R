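# Landmark records, cohort tables, file I/O, and the tracker adapter
# interface.
#
# On-disk schema (CSV): one row per gesture record with metadata columns
# subject_id, hand_side, handedness, gesture, repetition, label followed by
# 63 coordinate columns x0, y0, z0, ..., x20, y20, z20 (landmark-major). The
# JSON mirror nests each record's points as a 21x3 array. Coordinates are
# dimensionless model units; downstream features are scale-free by
# construction (angles) or by standardization (dis_tip).

COORD_COLS <- as.vector(t(outer(0:20, c("x", "y", "z"),
                                function(i, a) paste0(a, i))))
META_COLS <- c("subject_id", "hand_side", "handedness", "gesture",
               "repetition", "label")
INJURY_LABELS <- c("none", "radial", "ulnar", "median", "ulnar+median")

#' One 21-point hand landmark record
#'
#' Bundles an ordered 21x3 landmark matrix (rows are landmarks 0-20 of the
#' standard hand skeleton) with its capture metadata.
#'
#' @param points Numeric 21x3 matrix of finite landmark coordinates.
#' @param subject_id Subject identifier.
#' @param hand_side `"left"` or `"right"`: which of the subject's hands.
#' @param gesture `"G1"`, `"G2"`, or `"G3"`.
#' @param repetition Integer 1-4.
#' @param handedness `"left"` or `"right"`: anatomical handedness of the
#'   imaged hand (defaults to `hand_side`).
#' @param label Injury annotation: one of `"none"`, `"radial"`, `"ulnar"`,
#'   `"median"`, `"ulnar+median"`.
#' @return An object of class `hand_landmarks`.
#' @export
hand_landmarks <- function(points, subject_id, hand_side, gesture, repetition,
                           handedness = hand_side, label = "none") {
  lms <- structure(
    list(points = points, subject_id = as.character(subject_id),
         hand_side = hand_side, handedness = handedness, gesture = gesture,
         repetition = as.integer(repetition), label = label),
    class = "hand_landmarks"
  )
  validate_hand_landmarks(lms)
  lms
}

validate_hand_landmarks <- function(lms) {
  pts <- lms$points
  if (!is.matrix(pts) || nrow(pts) != 21L || ncol(pts) != 3L) {
    hs_error(sprintf("record %s: expected exactly 21 landmark points with 3 coordinates, got %s",
                     record_key(lms),
                     if (is.matrix(pts)) paste0(nrow(pts), "x", ncol(pts)) else class(pts)[1L]),
             "hs_validation_error")
  }
  if (!all(is.finite(pts))) {
    hs_error(sprintf("record %s: non-finite landmark coordinate(s)", record_key(lms)),
             "hs_validation_error")
  }
  if (!lms$gesture %in% c("G1", "G2", "G3")) {
    hs_error(sprintf("record %s: gesture must be G1, G2, or G3", record_key(lms)),
             "hs_validation_error")
  }
  if (is.na(lms$repetition) || lms$repetition < 1L || lms$repetition > 4L) {
    hs_error(sprintf("record %s: repetition must be an integer in 1..4", record_key(lms)),
             "hs_validation_error")
  }
  if (!lms$hand_side %in% c("left", "right") ||
      !lms$handedness %in% c("left", "right")) {
    hs_error(sprintf("record %s: hand_side and handedness must be 'left' or 'right'",
                     record_key(lms)),
             "hs_validation_error")
  }
  if (!lms$label %in% INJURY_LABELS) {
    hs_error(sprintf("record %s: unknown injury label '%s'", record_key(lms), lms$label),
             "hs_validation_error")
  }
  invisible(lms)
}

record_key <- function(lms) {
  paste(lms$subject_id, lms$hand_side, lms$gesture, lms$repetition, sep = ":")
}

#' Record keys of a cohort table
#'
#' @param cohort A [cohort_table].
#' @return Character vector `subject:hand:gesture:repetition`, one per row.
#' @export
record_keys <- function(cohort) {
  paste(cohort$subject_id, cohort$hand_side, cohort$gesture,
        cohort$repetition, sep = ":")
}

#' @export
print.hand_landmarks <- function(x, ...) {
  cat(sprintf("<hand_landmarks %s: %s hand, gesture %s, rep %d, label %s>\n",
              record_key(x), x$handedness, x$gesture, x$repetition, x$label))
  invisible(x)
}

#' Build a cohort table from landmark records
#'
#' A cohort table is a flat data frame (class `cohort_table`) with one row
#' per gesture record: the metadata columns plus 63 coordinate columns
#' `x0, y0, z0, ..., z20`. The record key `(subject_id, hand_side, gesture,
#' repetition)` must be unique.
#'
#' @param records List of [hand_landmarks] objects.
#' @param provenance Free-text source tag stored as an attribute.
#' @return A `cohort_table`.
#' @export
cohort_table <- function(records = list(), provenance = "unspecified") {
  if (length(records) == 0L) {
    df <- as.data.frame(setNames(rep(list(character(0)), 4L),
                                 c("subject_id", "hand_side", "handedness", "gesture")))
    df$repetition <- integer(0)
    df$label <- character(0)
    for (cc in COORD_COLS) df[[cc]] <- numeric(0)
    return(as_cohort_table(df, provenance = provenance))
  }
  meta <- do.call(rbind, lapply(records, function(r) {
    data.frame(subject_id = r$subject_id, hand_side = r$hand_side,
               handedness = r$handedness, gesture = r$gesture,
               repetition = r$repetition, label = r$label,
               stringsAsFactors = FALSE)
  }))
  coords <- do.call(rbind, lapply(records, function(r) as.vector(t(r$points))))
  colnames(coords) <- COORD_COLS
  as_cohort_table(cbind(meta, as.data.frame(coords)), provenance = provenance)
}

#' Validate a plain data frame as a cohort table
#'
#' Checks the column schema, coordinate finiteness, field domains, and
#' record-key uniqueness. All failing records are reported together; nothing
#' is silently dropped.
#'
#' @param df Data frame in the cohort schema.
#' @param provenance Free-text source tag.
#' @return The validated `cohort_table`.
#' @export
as_cohort_table <- function(df, provenance = "unspecified") {
  missing_cols <- setdiff(c(META_COLS, COORD_COLS), names(df))
  if (length(missing_cols) > 0L) {
    hs_error(sprintf("schema error: missing column(s) %s",
                     paste(missing_cols, collapse = ", ")),
             "hs_schema_error")
  }
  df <- df[, c(META_COLS, COORD_COLS), drop = FALSE]
  df$repetition <- as.integer(df$repetition)
  problems <- character(0)
  if (nrow(df) > 0L) {
    keys <- paste(df$subject_id, df$hand_side, df$gesture, df$repetition, sep = ":")
    coord <- as.matrix(df[, COORD_COLS, drop = FALSE])
    bad_coord <- !apply(is.finite(coord), 1L, all)
    bad_gesture <- !df$gesture %in% c("G1", "G2", "G3")
    bad_rep <- is.na(df$repetition) | df$repetition < 1L | df$repetition > 4L
    bad_side <- !df$hand_side %in% c("left", "right") |
      !df$handedness %in% c("left", "right")
    bad_label <- !df$label %in% INJURY_LABELS
    dup <- duplicated(keys) | duplicated(keys, fromLast = TRUE)
    report <- function(mask, what) {
      if (any(mask)) sprintf("%s: %s", what, paste(unique(keys[mask]), collapse = ", "))
    }
    problems <- c(
      report(bad_coord, "non-finite coordinates"),
      report(bad_gesture, "invalid gesture"),
      report(bad_rep, "repetition outside 1..4"),
      report(bad_side, "invalid hand side/handedness"),
      report(bad_label, "unknown injury label"),
      report(dup, "duplicate record key")
    )
    problems <- problems[!vapply(problems, is.null, logical(1L))]
  }
  if (length(problems) > 0L) {
    hs_error(paste0("cohort validation failed\n  ",
                    paste(unlist(problems), collapse = "\n  ")),
             "hs_validation_error")
  }
  structure(df, class = c("cohort_table", "data.frame"), provenance = provenance)
}

#' Extract one record of a cohort as a hand_landmarks object
#'
#' @param cohort A [cohort_table].
#' @param i Row index.
#' @return A [hand_landmarks] object.
#' @export
cohort_record <- function(cohort, i) {
  row <- cohort[i, , drop = FALSE]
  pts <- matrix(as.numeric(row[1L, COORD_COLS]), nrow = 21L, ncol = 3L,
                byrow = TRUE)
  hand_landmarks(pts, row$subject_id, row$hand_side, row$gesture,
                 row$repetition, handedness = row$handedness,
                 label = row$label)
}

#' Read a cohort of landmark records
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; inferred from the file extension when
#'   omitted.
#' @return A validated [cohort_table]. Any invalid record aborts the read
#'   with a message naming the offending record keys.
#' @export
read_landmarks <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    hs_error(sprintf("file not found: %s", path), "hs_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    return(as_cohort_table(df, provenance = path))
  }
  recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  records <- lapply(recs, function(r) {
    pts <- if (is.matrix(r$points)) r$points else {
      do.call(rbind, lapply(r$points, function(p) as.numeric(unlist(p))))
    }
    if (!is.matrix(pts) || nrow(pts) != 21L || ncol(pts) != 3L) {
      hs_error(sprintf("record %s:%s:%s:%s: expected exactly 21 points with 3 coordinates",
                       r$subject_id %||% "?", r$hand_side %||% "?",
                       r$gesture %||% "?", r$repetition %||% "?"),
               "hs_validation_error")
    }
    hand_landmarks(pts, r$subject_id, r$hand_side, r$gesture, r$repetition,
                   handedness = r$handedness %||% r$hand_side,
                   label = r$label %||% "none")
  })
  cohort_table(records, provenance = path)
}

#' Write a cohort of landmark records
#'
#' The written file round-trips through [read_landmarks()] with coordinate
#' equality to at least 1e-12 (15 significant digits are written).
#'
#' @param cohort A [cohort_table].
#' @param path Output file path.
#' @param format `"csv"` or `"json"`; inferred from the extension when
#'   omitted.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(cohort, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  ok <- tryCatch({
    if (format == "csv") {
      write.csv(as.data.frame(cohort), path, row.names = FALSE)
    } else {
      recs <- lapply(seq_len(nrow(cohort)), function(i) {
        r <- cohort_record(cohort, i)
        list(subject_id = r$subject_id, hand_side = r$hand_side,
             handedness = r$handedness, gesture = r$gesture,
             repetition = r$repetition, label = r$label,
             points = apply(r$points, 1L, as.list, simplify = FALSE))
      })
      jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    hs_error(sprintf("cannot write '%s': %s", path, conditionMessage(ok)),
             "hs_io_error")
  }
  invisible(path)
}

#' Canonicalize a hand record to right-hand convention
#'
#' Left hands are mirrored about the x-axis (x negated) into right-hand
#' convention; right hands are returned unchanged. All 23 features are
#' reflection-invariant, so canonicalization never changes feature values;
#' it exists so that downstream sign conventions are well defined. The
#' operation is an involution: canonicalizing a left-hand record twice
#' restores the original coordinates.
#'
#' @param lms A [hand_landmarks] object.
#' @return The canonicalized [hand_landmarks] object.
#' @export
canonicalize_hand <- function(lms) {
  validate_hand_landmarks(lms)
  if (lms$handedness == "right") {
    return(lms)
  }
  out <- lms
  out$points[, 1L] <- -out$points[, 1L]
  out
}

# ---- tracker adapter -------------------------------------------------------

the_tracker <- new.env(parent = emptyenv())

#' Marker for an image in which no hand was detected
#'
#' @return The not-detected sentinel.
#' @export
not_detected <- function() {
  structure(list(), class = "hs_not_detected")
}

#' @rdname not_detected
#' @param x Object to test.
#' @export
is_not_detected <- function(x) inherits(x, "hs_not_detected")

#' Register an external image-to-landmark tracker
#'
#' The package does not bundle a hand tracker; any callable taking one image
#' handle and returning a [hand_landmarks] object (or [not_detected()]) can
#' be plugged in, e.g. a wrapper around an external pose-estimation model.
#'
#' @param fun Adapter function, or `NULL` to unregister.
#' @return The previous adapter, invisibly.
#' @export
set_tracker_adapter <- function(fun) {
  if (!is.null(fun) && !is.function(fun)) {
    hs_error("tracker adapter must be a function or NULL", "hs_capability_error")
  }
  old <- the_tracker$adapter
  the_tracker$adapter <- fun
  invisible(old)
}

#' Run the registered tracker over image sources
#'
#' Applies the registered adapter to each image handle. Images in which no
#' hand is detected are excluded from the returned cohort and counted; the
#' recognition rate is reported alongside, mirroring the exclusion
#' bookkeeping of a screening study.
#'
#' @param sources List of opaque image handles understood by the adapter.
#' @return A list with elements `cohort` ([cohort_table]), `n_total`,
#'   `n_excluded`, `excluded` (indices), and `recognition_rate` (percent).
#' @export
track_images <- function(sources) {
  adapter <- the_tracker$adapter
  if (is.null(adapter)) {
    hs_error(paste("no tracker adapter registered; register one with",
                   "set_tracker_adapter() or supply landmark files via read_landmarks()"),
             "hs_capability_error")
  }
  results <- lapply(sources, adapter)
  excluded <- which(vapply(results, is_not_detected, logical(1L)))
  kept <- results[setdiff(seq_along(results), excluded)]
  rep <- recognition_report(length(sources), length(excluded))
  list(cohort = cohort_table(kept, provenance = "tracker"),
       n_total = rep$n_total, n_excluded = rep$n_excluded,
       excluded = excluded, recognition_rate = rep$recognition_rate)
}

#' Recognition-rate report
#'
#' @param n_total Number of images submitted to the tracker.
#' @param n_excluded Number of images with no detected hand.
#' @return List with `n_total`, `n_excluded`, `n_recognized`, and
#'   `recognition_rate` in percent.
#' @export
recognition_report <- function(n_total, n_excluded) {
  if (n_total < 0 || n_excluded < 0 || n_excluded > n_total) {
    hs_error("invalid exclusion counts", "hs_validation_error")
  }
  list(n_total = n_total, n_excluded = n_excluded,
       n_recognized = n_total - n_excluded,
       recognition_rate = if (n_total > 0) 100 * (n_total - n_excluded) / n_total else NA_real_)
}
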