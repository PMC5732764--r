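#' Normal-relative z-scores of tumor expression
#'
#' Standardizes each gene's tumor expression against the normal-tissue
#' samples of the same cohort: on the log-CPM scale,
#' \code{z = (x_tumor - mean(normals)) / sd(normals)} with the sample (n-1)
#' standard deviation. Genes constant across the normals are dropped and
#' reported.
#'
#' @param cohort An \code{\link{ExpressionCohort}} with at least 2 normals.
#' @param prior_count Passed to \code{\link{logcpm_transform}}.
#' @return Genes x tumor-samples matrix of z-scores; attribute
#'   \code{dropped_genes} lists genes with zero normal variance.
#' @export
normal_relative_zscores <- function(cohort, prior_count = 0.5) {
  stopifnot(inherits(cohort, "ExpressionCohort"))
  if (sum(cohort$condition == "normal") < 2)
    stop("need at least 2 normal samples")
  factors <- scale_normalize(cohort$counts)
  logmat <- logcpm_transform(cohort$counts, factors, prior_count = prior_count)
  xn <- logmat[, cohort$condition == "normal", drop = FALSE]
  xt <- logmat[, cohort$condition == "tumor", drop = FALSE]
  mu <- rowMeans(xn)
  sd_n <- sqrt(rowSums((xn - mu)^2) / (ncol(xn) - 1))
  keep <- sd_n > 0
  z <- (xt[keep, , drop = FALSE] - mu[keep]) / sd_n[keep]
  structure(z, dropped_genes = rownames(logmat)[!keep])
}

#' Per-patient pathway dysregulation score
#'
#' Aggregates a patient's normal-relative z-scores over a pathway:
#' \code{sum(|z|) / sqrt(n)} over the pathway genes present in the z matrix
#' (absolute mode, the default, mirrors the cohort-level absolute pathway
#' score); the signed variant sums z itself.
#'
#' @param z Genes x patients z-score matrix
#'   (\code{\link{normal_relative_zscores}}).
#' @param pathway Character vector of gene ids.
#' @param mode \code{"absolute"} (default) or \code{"signed"}.
#' @param name Pathway label recorded in the output.
#' @return Data frame \code{patient_id}, \code{pathway}, \code{score}.
#' @export
patient_pathway_score <- function(z, pathway, mode = c("absolute", "signed"),
                                  name = "pathway") {
  mode <- match.arg(mode)
  present <- intersect(pathway, rownames(z))
  if (length(present) == 0) stop("no pathway genes in z matrix: ", name)
  zz <- z[present, , drop = FALSE]
  if (mode == "absolute") zz <- abs(zz)
  data.frame(patient_id = colnames(z), pathway = name,
             score = colSums(zz) / sqrt(length(present)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Quartile stratification of patient scores
#'
#' Cut points are the 25th/50th/75th empirical percentiles (type-7, linear
#' interpolation); a score at or below a cut point goes to the lower
#' quartile, so ties at a cut resolve in stable input order toward Q1.
#' Q1 = low, Q2/Q3 = intermediate, Q4 = high dysregulation.
#'
#' @param scores Numeric vector of patient scores.
#' @return Factor with levels Q1-Q4, same length/order as \code{scores}.
#'   All-equal scores collapse to Q1 with a warning.
#' @export
quartile_stratify <- function(scores) {
  if (length(scores) == 0) stop("empty scores")
  if (anyNA(scores)) stop("scores must be non-missing")
  q <- stats::quantile(scores, probs = c(0.25, 0.5, 0.75), type = 7,
                       names = FALSE)
  if (q[1] == q[3])
    warning("degenerate score distribution: quartile cut points coincide")
  lab <- ifelse(scores <= q[1], "Q1",
         ifelse(scores <= q[2], "Q2",
         ifelse(scores <= q[3], "Q3", "Q4")))
  factor(lab, levels = c("Q1", "Q2", "Q3", "Q4"))
}

# Administrative censoring of a survival table at `horizon` years: later
# times are censored at the horizon; an event at exactly the horizon counts.
censor_at_horizon <- function(records, horizon) {
  stopifnot(all(c("time_years", "event") %in% names(records)))
  if (any(!is.finite(records$time_years)) || any(records$time_years < 0))
    stop("times must be finite and non-negative")
  over <- records$time_years > horizon
  records$event[over] <- 0L
  records$time_years[over] <- horizon
  records
}

#' Kaplan-Meier estimate of recurrence-free survival
#'
#' Product-limit estimate \code{S(t_k) = prod_{j<=k} (1 - d_j/n_j)} with
#' administrative censoring at the horizon (events at exactly the horizon
#' still count). Wraps \code{survival::survfit}.
#'
#' @param records Data frame with \code{time_years} and \code{event} (1 =
#'   biochemical recurrence, 0 = censored).
#' @param horizon Administrative censoring horizon in years (default 5);
#'   \code{Inf} disables it.
#' @return Data frame of class \code{km_curve}: \code{time}, \code{n_risk},
#'   \code{n_event}, \code{n_censor}, \code{survival}.
#' @export
km_estimate <- function(records, horizon = 5) {
  if (nrow(records) == 0) stop("empty survival table")
  records <- censor_at_horizon(records, horizon)
  fit <- survival::survfit(survival::Surv(time_years, event) ~ 1,
                           data = records)
  structure(data.frame(time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, n_censor = fit$n.censor,
                       survival = fit$surv),
            class = c("km_curve", "data.frame"), n = nrow(records))
}

# Median survival time of a km_curve: first time S <= 0.5, +Inf if never.
km_median <- function(curve) {
  hit <- which(curve$survival <= 0.5)
  if (length(hit)) curve$time[min(hit)] else Inf
}

#' Two-group log-rank test of recurrence-free survival
#'
#' Standard log-rank statistic with hypergeometric variance at each distinct
#' event time, referred to chi-square on 1 df; wraps
#' \code{survival::survdiff} after administrative censoring at the horizon.
#'
#' @param group_a,group_b Survival tables (\code{time_years}, \code{event}).
#' @param horizon Administrative censoring horizon in years (default 5).
#' @return List: \code{chi2}, \code{p}, \code{n} (per group),
#'   \code{events} (per group).
#' @export
logrank_test <- function(group_a, group_b, horizon = 5) {
  if (nrow(group_a) == 0 || nrow(group_b) == 0) stop("empty group")
  a <- censor_at_horizon(group_a, horizon)
  b <- censor_at_horizon(group_b, horizon)
  d <- rbind(data.frame(time_years = a$time_years, event = a$event, g = "A"),
             data.frame(time_years = b$time_years, event = b$event, g = "B"))
  sd_ <- survival::survdiff(survival::Surv(time_years, event) ~ g, data = d)
  chi2 <- unname(sd_$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       n = unname(sd_$n), events = unname(sd_$obs))
}

#' Score, stratify and test a cohort against biochemical recurrence
#'
#' End-to-end convenience: normal-relative z-scores, per-patient pathway
#' score, quartile stratification, per-quartile Kaplan-Meier curves, and the
#' Q1-versus-Q4 log-rank test.
#'
#' @param cohort An \code{\link{ExpressionCohort}}.
#' @param survival_table Data frame \code{patient_id}, \code{time_years},
#'   \code{event}; patient ids must match the cohort's tumor sample ids.
#' @param pathway Character vector of gene ids.
#' @param horizon Years (default 5).
#' @param mode Patient-score mode, see \code{\link{patient_pathway_score}}.
#' @param name Pathway label.
#' @return List: \code{patient_scores} (with quartile), \code{km} (named list
#'   of \code{km_curve} per quartile), \code{logrank} (Q1 vs Q4 result).
#' @export
stratify_cohort <- function(cohort, survival_table, pathway, horizon = 5,
                            mode = "absolute", name = "pathway") {
  z <- normal_relative_zscores(cohort)
  ps <- patient_pathway_score(z, pathway, mode = mode, name = name)
  idx <- match(ps$patient_id, survival_table$patient_id)
  if (anyNA(idx)) stop("survival table lacks some tumor samples")
  ps$quartile <- quartile_stratify(ps$score)
  surv <- survival_table[idx, , drop = FALSE]
  km <- lapply(levels(ps$quartile), function(q) {
    rows <- which(ps$quartile == q)
    if (length(rows)) km_estimate(surv[rows, , drop = FALSE], horizon) else NULL
  })
  names(km) <- levels(ps$quartile)
  lr <- logrank_test(surv[ps$quartile == "Q1", , drop = FALSE],
                     surv[ps$quartile == "Q4", , drop = FALSE],
                     horizon = horizon)
  list(patient_scores = ps, km = km, logrank = lr)
}
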