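#' Tumor volume from caliper measurements
#'
#' \code{volume = length^2 * width * 0.5234} (mm3); note the formula is not
#' symmetric in its arguments.
#'
#' @param length,width Caliper measurements in mm (non-negative); vectorized.
#' @return Volumes in mm3.
#' @export
tumor_volume <- function(length, width) {
  if (any(length < 0) || any(width < 0)) stop("measurements must be >= 0")
  length^2 * width * 0.5234
}

#' Classify a tumor-volume trajectory after androgen withdrawal
#'
#' Threshold crossings are evaluated at measurement days only (strict
#' inequalities, no interpolation): initial response = first volume
#' < 300 mm3, regression = first < 150 mm3, complete regression = first
#' < 100 mm3, recurrence = first volume > 500 mm3 after the regression day.
#' Final status precedence: recurrent, then complete regression (final
#' measured volume < 100), then stable disease (regressed, final volume in
#' (100, 500]); a tumor that never regressed below 150 is non_regressed.
#'
#' @param traj Data frame with \code{day} and either \code{volume_mm3} or
#'   \code{length_mm}/\code{width_mm}; at least 2 measurements, days
#'   strictly increasing.
#' @param thresholds Named numeric vector \code{initial}, \code{regression},
#'   \code{complete}, \code{recurrence} (defaults 300/150/100/500 mm3).
#' @return One-row data frame: \code{initial_response_day},
#'   \code{regression_day}, \code{complete_regression} (+ day),
#'   \code{recurrence} (+ day), \code{final_status}.
#' @export
classify_trajectory <- function(traj,
                                thresholds = c(initial = 300,
                                               regression = 150,
                                               complete = 100,
                                               recurrence = 500)) {
  if (is.null(traj) || nrow(traj) == 0) stop("empty trajectory")
  if (nrow(traj) < 2) stop("need at least 2 measurements")
  if (!"volume_mm3" %in% names(traj)) {
    if (!all(c("length_mm", "width_mm") %in% names(traj)))
      stop("need volume_mm3 or length_mm/width_mm columns")
    traj$volume_mm3 <- tumor_volume(traj$length_mm, traj$width_mm)
  }
  traj <- traj[order(traj$day), , drop = FALSE]
  if (any(diff(traj$day) <= 0)) stop("days must be strictly increasing")
  day <- traj$day; v <- traj$volume_mm3
  if (any(v <= 0)) stop("volumes must be positive")

  first_day <- function(sel) if (any(sel)) day[which(sel)[1]] else NA_real_
  init_day <- first_day(v < thresholds["initial"])
  reg_day <- first_day(v < thresholds["regression"])
  comp_day <- first_day(v < thresholds["complete"])
  rec_day <- if (!is.na(reg_day))
    first_day(v > thresholds["recurrence"] & day > reg_day) else NA_real_

  final_v <- v[length(v)]
  status <- if (!is.na(rec_day)) "recurrent"
    else if (is.na(reg_day)) "non_regressed"
    else if (final_v < thresholds["complete"]) "complete_regression"
    else "stable_disease"

  data.frame(initial_response_day = init_day, regression_day = reg_day,
             complete_regression = !is.na(comp_day),
             complete_regression_day = comp_day,
             recurrence = !is.na(rec_day), recurrence_day = rec_day,
             final_status = status, stringsAsFactors = FALSE)
}

#' Classify every animal of a trajectory set
#'
#' @param trajectories Long data frame \code{animal_id}, \code{arm},
#'   \code{day}, \code{volume_mm3} (or caliper columns), optionally
#'   \code{censored_day} (constant per animal; NA = uncensored).
#' @param thresholds Passed to \code{\link{classify_trajectory}}; censored
#'   animals are classified on measurements before their censoring day and
#'   flagged.
#' @return Data frame, one row per animal: \code{animal_id}, \code{arm},
#'   \code{censored}, plus the \code{\link{classify_trajectory}} columns.
#' @export
classify_trajectories <- function(trajectories,
                                  thresholds = c(initial = 300,
                                                 regression = 150,
                                                 complete = 100,
                                                 recurrence = 500)) {
  stopifnot(all(c("animal_id", "day") %in% names(trajectories)))
  ids <- unique(trajectories$animal_id)
  res <- lapply(ids, function(id) {
    sub <- trajectories[trajectories$animal_id == id, , drop = FALSE]
    cens_day <- if ("censored_day" %in% names(sub)) sub$censored_day[1]
                else NA_real_
    if (!is.na(cens_day)) sub <- sub[sub$day <= cens_day, , drop = FALSE]
    cls <- classify_trajectory(sub, thresholds)
    cbind(data.frame(animal_id = id,
                     arm = if ("arm" %in% names(sub)) sub$arm[1] else NA,
                     censored = !is.na(cens_day),
                     censored_day = cens_day, stringsAsFactors = FALSE),
          cls)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Interval status summary of a classified cohort
#'
#' At each interval endpoint (default every 4 weeks up to 50 weeks) every
#' non-censored animal is in exactly one state: \code{recurrent} once its
#' recurrence day has passed (absorbing); otherwise
#' \code{complete_regression} if its last measured volume at or before the
#' endpoint is < 100 mm3; otherwise \code{stable_disease}. Animals drop from
#' the denominator after their censoring day.
#'
#' @param classifications Output of \code{\link{classify_trajectories}}.
#' @param trajectories The trajectory data frame the classifications came
#'   from (volumes are needed to evaluate current status).
#' @param interval Days between summary points (default 28).
#' @param horizon_weeks Final week summarized (default 50).
#' @param complete_threshold Volume below which current status is complete
#'   regression (default 100 mm3).
#' @return Data frame \code{day}, \code{week}, \code{n},
#'   \code{frac_complete_regression}, \code{frac_stable_disease},
#'   \code{frac_recurrent}; fractions sum to 1 whenever \code{n > 0}.
#' @export
interval_status_summary <- function(classifications, trajectories,
                                    interval = 28, horizon_weeks = 50,
                                    complete_threshold = 100) {
  if (!"volume_mm3" %in% names(trajectories))
    trajectories$volume_mm3 <- tumor_volume(trajectories$length_mm,
                                            trajectories$width_mm)
  endpoints <- seq(interval, horizon_weeks * 7, by = interval)
  res <- lapply(endpoints, function(ep) {
    cls <- classifications
    if ("censored_day" %in% names(cls))
      cls <- cls[is.na(cls$censored_day) | cls$censored_day > ep, ,
                 drop = FALSE]
    n <- nrow(cls)
    if (n == 0)
      return(data.frame(day = ep, week = ep / 7, n = 0L,
                        frac_complete_regression = NA_real_,
                        frac_stable_disease = NA_real_,
                        frac_recurrent = NA_real_))
    state <- vapply(seq_len(n), function(i) {
      if (isTRUE(cls$recurrence[i]) && cls$recurrence_day[i] <= ep)
        return("recurrent")
      sub <- trajectories[trajectories$animal_id == cls$animal_id[i] &
                          trajectories$day <= ep, , drop = FALSE]
      last_v <- if (nrow(sub)) sub$volume_mm3[which.max(sub$day)] else NA_real_
      if (!is.na(last_v) && last_v < complete_threshold) "complete_regression"
      else "stable_disease"
    }, character(1))
    data.frame(day = ep, week = ep / 7, n = n,
               frac_complete_regression = mean(state == "complete_regression"),
               frac_stable_disease = mean(state == "stable_disease"),
               frac_recurrent = mean(state == "recurrent"))
  })
  do.call(rbind, res)
}

#' Recurred / non-recurred contingency table for two arms
#'
#' Censored animals are excluded. Rows are recurred/not, columns the two
#' arms, ready for \code{\link{fisher_exact}}.
#'
#' @param classifications Output of \code{\link{classify_trajectories}}.
#' @param arm_a,arm_b Arm labels to compare.
#' @return 2x2 integer matrix.
#' @export
recurrence_contingency <- function(classifications, arm_a, arm_b) {
  cls <- classifications[!classifications$censored, , drop = FALSE]
  a <- cls[cls$arm == arm_a, , drop = FALSE]
  b <- cls[cls$arm == arm_b, , drop = FALSE]
  m <- matrix(c(sum(a$final_status == "recurrent"),
                sum(a$final_status != "recurrent"),
                sum(b$final_status == "recurrent"),
                sum(b$final_status != "recurrent")),
              nrow = 2, dimnames = list(c("recurred", "not_recurred"),
                                        c(arm_a, arm_b)))
  m
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact conditional test with both margins fixed: the two-sided p-value
#' sums the hypergeometric probabilities of all tables no more probable than
#' the observed one (with the customary 1e-7 relative tolerance for ties).
#' The odds ratio reported is the sample ad/bc (0 or Inf flagged by value).
#'
#' @param table 2x2 matrix (or vector a, b, c, d column-wise) of
#'   non-negative integer counts.
#' @return List: \code{p_two_sided}, \code{odds_ratio}.
#' @export
fisher_exact <- function(table) {
  x <- as.vector(table)
  if (length(x) != 4) stop("need a 2x2 table")
  if (any(x < 0) || any(x != round(x))) stop("counts must be non-negative integers")
  a <- x[1]; c_ <- x[2]; b <- x[3]; d <- x[4]   # column-major 2x2
  m <- a + b          # row 1 total
  n <- c_ + d         # row 2 total
  k <- a + c_         # column 1 total
  orat <- (a * d) / (b * c_)
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0)
    return(list(p_two_sided = 1, odds_ratio = orat))
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  d_obs <- stats::dhyper(a, m, n, k)
  p <- sum(dens[dens <= d_obs * (1 + 1e-7)])
  list(p_two_sided = min(p, 1), odds_ratio = orat)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t with Satterthwaite degrees of freedom
#' (wraps \code{stats::t.test}).
#'
#' @param a,b Numeric samples (each n >= 2).
#' @return List: \code{t}, \code{df}, \code{p_two_sided}.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("need at least 2 values per sample")
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_two_sided = tt$p.value)
}

#' Two-tailed Pearson correlation test
#'
#' Sample correlation with p-value from
#' \code{t = r sqrt((n - 2) / (1 - r^2))} on n - 2 df
#' (wraps \code{stats::cor.test}).
#'
#' @param x,y Numeric vectors, equal length, n >= 3, both with nonzero
#'   variance.
#' @return List: \code{r}, \code{p_two_sided}, \code{n}.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_two_sided = ct$p.value, n = length(x))
}
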