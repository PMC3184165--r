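#' Construct an AIM rating session
#'
#' One abnormal-involuntary-movement (AIM) rating session: the animal is
#' observed for 1 minute every 20 minutes and scored 0-4 in each of four
#' categories (limb, axial, orolingual, rotational/locomotor), where 0 is no
#' abnormal movement and 4 a constant, uninterruptible one.
#'
#' @param animal_id Animal identifier.
#' @param session Session index (1-8; sessions are rated every other day
#'   over the 15-day treatment).
#' @param scores Integer matrix, timepoints x 4 categories, all values in
#'   0-4.
#' @return An object of class `aim_session`.
#' @export
aim_session <- function(animal_id, session, scores) {
  stopifnot(is.matrix(scores))
  if (ncol(scores) != 4L) {
    stop("scores must have exactly 4 categories (columns)", call. = FALSE)
  }
  if (anyNA(scores) || any(scores != round(scores)) ||
      any(scores < 0) || any(scores > 4)) {
    stop("scores must be integers in 0-4", call. = FALSE)
  }
  colnames(scores) <- c("limb", "axial", "orolingual", "locomotor")
  structure(list(animal_id = animal_id, session = as.integer(session),
                 scores = scores),
            class = "aim_session")
}

#' Total AIM score of one session
#'
#' Sum over all timepoints and all four categories.
#'
#' @param s An [aim_session].
#' @return Integer session score.
#' @export
session_score <- function(s) {
  stopifnot(inherits(s, "aim_session"))
  as.integer(sum(s$scores))
}

#' Cumulative dyskinesia score over all rated sessions
#'
#' The per-animal severity measure used for correlation with peptide levels:
#' the sum of session scores over all rated sessions. By default all four
#' AIM categories are included; `drop_locomotor = TRUE` excludes the
#' rotational/locomotor category, a common variant in this literature.
#'
#' @param sessions List of [aim_session] for one animal; session indices
#'   must be unique.
#' @param drop_locomotor Logical; exclude the locomotor category.
#' @return Integer cumulative score.
#' @export
cumulative_score <- function(sessions, drop_locomotor = FALSE) {
  stopifnot(length(sessions) >= 1L)
  idx <- vapply(sessions, function(s) s$session, integer(1))
  if (anyDuplicated(idx)) stop("duplicate session index", call. = FALSE)
  as.integer(sum(vapply(sessions, function(s) {
    sc <- s$scores
    if (drop_locomotor) sc <- sc[, c("limb", "axial", "orolingual"),
                                 drop = FALSE]
    sum(sc)
  }, numeric(1))))
}

#' Construct a cylinder-test record
#'
#' Forelimb-asymmetry assay: wall touches with the left and right forepaw
#' while rearing in a glass cylinder (design target 20 touches total).
#'
#' @param animal_id Animal identifier.
#' @param occasion `"pre"` or `"post"` (before and at the end of treatment).
#' @param left,right Non-negative integer touch counts.
#' @return An object of class `cylinder_test`.
#' @export
cylinder_test <- function(animal_id, occasion = c("pre", "post"),
                          left, right) {
  occasion <- match.arg(occasion)
  if (left < 0 || right < 0 || left != round(left) || right != round(right)) {
    stop("touch counts must be non-negative integers", call. = FALSE)
  }
  structure(list(animal_id = animal_id, occasion = occasion,
                 left = as.integer(left), right = as.integer(right)),
            class = "cylinder_test")
}

#' Percent left-forelimb use and the inclusion rule
#'
#' Percent of wall touches made with the left (lesion-contralateral)
#' forelimb. Animals are included in the study only when they use the
#' contralateral forelimb strictly less than 30% of the time, corresponding
#' to roughly 70% striatal dopamine depletion.
#'
#' @param test A [cylinder_test] with at least one touch.
#' @return A list with `percent` (0-100) and `include` (logical,
#'   `percent < 30`).
#' @export
percent_left_use <- function(test) {
  stopifnot(inherits(test, "cylinder_test"))
  total <- test$left + test$right
  if (total <= 0) stop("zero total touches", call. = FALSE)
  pct <- 100 * test$left / total
  list(percent = pct, include = pct < 30)
}

#' Change in forelimb asymmetry between the two cylinder tests
#'
#' Difference in percent left-forelimb use, post minus pre; positive values
#' mean improved use of the impaired limb.
#'
#' @param pre,post [cylinder_test] records for the same animal.
#' @return Percentage-point difference.
#' @export
asymmetry_change <- function(pre, post) {
  percent_left_use(post)$percent - percent_left_use(pre)$percent
}

#' Fit a linear dyskinesia trajectory
#'
#' Least-squares line `score = m * day + b` through the per-session scores,
#' the two-parameter model describing dyskinesia development: low- and
#' high-dyskinetic animals share similar slopes but differ sharply in
#' offset.
#'
#' @param day Numeric vector of treatment days (>= 2 distinct values).
#' @param score Session scores, same length.
#' @return An object of class `trajectory`: list with `m` (slope,
#'   score/day), `b` (intercept, score) and `sigma` (residual sd).
#' @export
fit_trajectory <- function(day, score) {
  stopifnot(length(day) == length(score))
  if (length(unique(day)) < 2L) {
    stop("need at least 2 distinct days", call. = FALSE)
  }
  fit <- stats::lm(score ~ day)
  # noiseless lines are legitimate input; silence the perfect-fit warning
  sigma <- suppressWarnings(summary(fit)$sigma)
  structure(list(m = unname(stats::coef(fit)[2L]),
                 b = unname(stats::coef(fit)[1L]),
                 sigma = sigma),
            class = "trajectory")
}

#' Predicted day at which a trajectory reaches a threshold score
#'
#' Solves `threshold = m * day + b` for `day`, e.g. the projected number of
#' treatment days for a low-dyskinetic animal to reach the high-dyskinetic
#' score range.
#'
#' @param traj A [fit_trajectory()] result with positive slope.
#' @param threshold Target score.
#' @return Day (possibly fractional).
#' @export
predict_day_to <- function(traj, threshold) {
  stopifnot(inherits(traj, "trajectory"))
  if (traj$m <= 0) {
    stop("threshold unreachable: non-positive slope", call. = FALSE)
  }
  (threshold - traj$b) / traj$m
}

#' Read / write behavior tables
#'
#' Long-format CSVs: AIM scores as
#' `animal,session,timepoint,category,score` and cylinder tests as
#' `animal,occasion,left,right`.
#'
#' @param sessions Named list (by animal) of lists of [aim_session].
#' @param path CSV file path.
#' @export
write_aim_csv <- function(sessions, path) {
  rows <- list()
  for (an in names(sessions)) {
    for (s in sessions[[an]]) {
      sc <- s$scores
      rows[[length(rows) + 1L]] <- data.frame(
        animal = an, session = s$session,
        timepoint = rep(seq_len(nrow(sc)), times = 4L),
        category = rep(colnames(sc), each = nrow(sc)),
        score = as.vector(sc), stringsAsFactors = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_aim_csv
#' @export
read_aim_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(animal = "character"))
  out <- list()
  for (an in unique(df$animal)) {
    da <- df[df$animal == an, ]
    out[[an]] <- lapply(sort(unique(da$session)), function(si) {
      ds <- da[da$session == si, ]
      tp <- sort(unique(ds$timepoint))
      cats <- c("limb", "axial", "orolingual", "locomotor")
      m <- matrix(0L, nrow = length(tp), ncol = 4L,
                  dimnames = list(NULL, cats))
      for (cat in cats) {
        dc <- ds[ds$category == cat, ]
        m[match(dc$timepoint, tp), cat] <- dc$score
      }
      aim_session(an, si, m)
    })
  }
  out
}
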