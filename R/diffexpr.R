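#' Trimmed-mean-of-M-values scale factors
#'
#' Computes per-sample scale normalization factors for a tumor/normal count
#' matrix using the trimmed mean of M-values (TMM): pairwise log-ratios
#' against a reference sample are doubly trimmed (30% on M, 5% on A) and
#' averaged with inverse asymptotic-variance weights. The reference is the
#' sample whose upper-quartile count (scaled by library size) is closest to
#' the cohort mean upper quartile. Factors are rescaled to have geometric
#' mean 1, so the effective library size of sample j is
#' \code{colSums(counts)[j] * factors[j]}.
#'
#' @param cohort An \code{\link{ExpressionCohort}}, or a non-negative count
#'   matrix (genes x samples).
#' @param logratio_trim Fraction of most extreme M-values trimmed from each
#'   tail (default 0.30).
#' @param sum_trim Fraction trimmed on the A (average log-expression) scale
#'   (default 0.05).
#' @return Named numeric vector of positive scale factors, one per sample,
#'   with geometric mean 1.
#' @examples
#' counts <- matrix(rpois(200, 50), nrow = 50,
#'                  dimnames = list(NULL, paste0("s", 1:4)))
#' scale_normalize(counts)
#' @export
scale_normalize <- function(cohort, logratio_trim = 0.3, sum_trim = 0.05) {
  counts <- if (inherits(cohort, "ExpressionCohort")) cohort$counts else as.matrix(cohort)
  if (any(counts < 0)) stop("counts must be non-negative")
  lib <- colSums(counts)
  if (any(lib <= 0)) {
    bad <- colnames(counts)[lib <= 0]
    if (is.null(bad)) bad <- which(lib <= 0)
    stop("sample(s) with zero total count: ", paste(bad, collapse = ", "))
  }
  ns <- ncol(counts)
  # reference: upper quartile (library-size scaled) closest to the mean
  f75 <- vapply(seq_len(ns), function(j)
    stats::quantile(counts[, j], probs = 0.75, names = FALSE), numeric(1)) / lib
  ref <- if (stats::median(f75) < 1e-20) which.max(colSums(sqrt(counts)))
         else which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ns), function(j)
    tmm_pair_factor(counts[, j], counts[, ref], lib[j], lib[ref],
                    logratio_trim, sum_trim), numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# One TMM factor of `obs` against reference `ref`, both with known library sizes.
tmm_pair_factor <- function(obs, ref, n_obs, n_ref, logratio_trim, sum_trim) {
  logR <- log2((obs / n_obs) / (ref / n_ref))
  absE <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  fin <- is.finite(logR) & is.finite(absE)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (length(logR) == 0L || max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * sum_trim) + 1
  hiS <- n + 1 - loS
  keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
          (rank(absE) >= loS & rank(absE) <= hiS)
  f <- sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (is.na(f)) f <- 0
  2^f
}

#' Log counts-per-million transform
#'
#' \code{log2((count + prior_count) / (effective library size + 1) * 1e6)},
#' where the effective library size is the raw column total multiplied by its
#' scale factor.
#'
#' @param cohort An \code{\link{ExpressionCohort}} or count matrix.
#' @param factors Per-sample scale factors (from \code{\link{scale_normalize}});
#'   defaults to all 1.
#' @param prior_count Pseudo-count added to every entry before the log
#'   (default 0.5); keeps zeros finite.
#' @return Real matrix, genes x samples, same dimnames as the counts.
#' @export
logcpm_transform <- function(cohort, factors = NULL, prior_count = 0.5) {
  counts <- if (inherits(cohort, "ExpressionCohort")) cohort$counts else as.matrix(cohort)
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  if (length(factors) != ncol(counts)) stop("one factor per sample required")
  eff <- colSums(counts) * factors
  log2(sweep(counts + prior_count, 2, eff + 1, "/") * 1e6)
}

#' Empirical-Bayes moderated t-test of tumor versus normal
#'
#' Per-gene tumor-minus-normal contrast on a transformed expression matrix
#' with residual variances shrunk toward a common prior. Residual variances
#' s_g^2 (df d_g) are modeled as scaled-F around a prior s0^2 with d0 prior
#' degrees of freedom; d0 and s0^2 are estimated by moment matching on
#' log s_g^2 via the digamma/trigamma relations. The posterior variance is
#' \deqn{\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)}
#' and \code{t_mod = log2FC / (s_g c_g)} is referred to a t distribution on
#' d_g + d0 degrees of freedom.
#'
#' @param logmat Transformed matrix (genes x samples), e.g. from
#'   \code{\link{logcpm_transform}}.
#' @param condition Per-sample labels, "tumor" or "normal".
#' @param pair_id Optional per-sample pair labels; when supplied the fit is on
#'   within-pair tumor-minus-normal differences (pairing must be complete).
#' @param weights \code{"none"} (default) or \code{"trend"}: the trend mode
#'   fits a lowess of per-gene sqrt residual sd against mean log-CPM and uses
#'   the inverse fourth power of the fit as a per-gene precision weight.
#' @param d0 Optional override of the prior degrees of freedom: \code{0}
#'   disables shrinkage (ordinary t), \code{Inf} forces complete shrinkage.
#'   Default \code{NULL} estimates it from the data.
#' @param var_floor Floor applied to residual variances before shrinkage so
#'   zero-residual genes keep a defined statistic.
#' @return A \code{DEResult}: data frame with columns \code{gene_id},
#'   \code{log2FC}, \code{t_mod}, \code{df_total}, \code{p}, \code{padj},
#'   \code{mean_logcpm}, plus attributes \code{d0}, \code{s02},
#'   \code{df_residual} and the group sizes.
#' @export
fit_moderated_t <- function(logmat, condition, pair_id = NULL,
                            weights = c("none", "trend"), d0 = NULL,
                            var_floor = 1e-10) {
  weights <- match.arg(weights)
  logmat <- as.matrix(logmat)
  condition <- as.character(condition)
  if (length(condition) != ncol(logmat)) stop("one condition per sample required")
  if (!all(condition %in% c("tumor", "normal")))
    stop("condition must be 'tumor' or 'normal'")
  n_t <- sum(condition == "tumor"); n_n <- sum(condition == "normal")
  if (n_t < 2 || n_n < 2) stop("need at least 2 samples per condition")

  if (!is.null(pair_id)) {
    pair_id <- as.character(pair_id)
    tum <- which(condition == "tumor"); nor <- which(condition == "normal")
    if (!setequal(pair_id[tum], pair_id[nor]) ||
        anyDuplicated(pair_id[tum]) || anyDuplicated(pair_id[nor]))
      stop("pairing must be complete: one tumor and one normal per pair_id")
    nor <- nor[match(pair_id[tum], pair_id[nor])]
    d <- logmat[, tum, drop = FALSE] - logmat[, nor, drop = FALSE]
    np <- ncol(d)
    lfc <- rowMeans(d)
    s2 <- rowSums((d - lfc)^2) / (np - 1)
    df_res <- np - 1
    c2 <- 1 / np
  } else {
    xt <- logmat[, condition == "tumor", drop = FALSE]
    xn <- logmat[, condition == "normal", drop = FALSE]
    mt <- rowMeans(xt); mn <- rowMeans(xn)
    lfc <- mt - mn
    rss <- rowSums((xt - mt)^2) + rowSums((xn - mn)^2)
    df_res <- n_t + n_n - 2
    s2 <- rss / df_res
    c2 <- 1 / n_t + 1 / n_n
  }
  s2 <- pmax(s2, var_floor)
  mean_logcpm <- rowMeans(logmat)

  w <- rep(1, nrow(logmat))
  if (weights == "trend") {
    fit <- stats::lowess(mean_logcpm, sqrt(sqrt(s2)), f = 0.5)
    l <- stats::approx(fit$x, fit$y, xout = mean_logcpm, rule = 2)$y
    w <- 1 / pmax(l, 1e-6)^4
  }
  s2w <- s2 * w

  if (is.null(d0)) {
    eb <- fit_f_prior(s2w, df_res)
  } else {
    if (d0 < 0) stop("d0 must be non-negative")
    s02 <- if (is.infinite(d0)) {
      e <- log(s2w) - digamma(df_res / 2) + log(df_res / 2)
      exp(mean(e))
    } else if (d0 == 0) NA_real_ else {
      e <- log(s2w) - digamma(df_res / 2) + log(df_res / 2)
      exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    }
    eb <- list(d0 = d0, s02 = s02)
  }
  s2_post <- if (is.infinite(eb$d0)) rep(eb$s02, length(s2w))
             else (eb$d0 * ifelse(eb$d0 == 0, 0, eb$s02) + df_res * s2w) /
                  (eb$d0 + df_res)
  df_total <- df_res + eb$d0
  t_mod <- lfc / sqrt(s2_post / w * c2)
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)

  out <- data.frame(
    gene_id = if (is.null(rownames(logmat))) as.character(seq_len(nrow(logmat)))
              else rownames(logmat),
    log2FC = lfc, t_mod = t_mod, df_total = df_total,
    p = p, padj = bh_adjust(p), mean_logcpm = mean_logcpm,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(out, class = c("DEResult", "data.frame"),
            d0 = eb$d0, s02 = eb$s02, df_residual = df_res,
            n_tumor = n_t, n_normal = n_n, weights = weights)
}

# Moment-matching fit of the scaled-F prior on residual variances:
# log s^2 has mean digamma(d/2) - log(d/2) + log s0^2 and excess variance
# trigamma(d0/2) beyond trigamma(d/2); invert the trigamma by Newton steps.
fit_f_prior <- function(s2, df_res) {
  z <- log(s2)
  e <- z - digamma(df_res / 2) + log(df_res / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1) - trigamma(df_res / 2)
  if (is.na(evar) || evar <= 0)
    return(list(d0 = Inf, s02 = exp(emean)))
  d0 <- 2 * trigamma_inverse(evar)
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment: \code{padj_(i) = min_{j >= i} m p_(j) / j}, capped
#' at 1 and mapped back to input order. Thin wrapper over
#' \code{stats::p.adjust(method = "BH")}.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Tumor-versus-normal differential expression pipeline
#'
#' Convenience wrapper: drops genes with zero counts in every sample
#' (recorded in the result), computes TMM scale factors, log-CPM transforms,
#' and fits the empirical-Bayes moderated t.
#'
#' @param cohort An \code{\link{ExpressionCohort}}.
#' @param paired Fit on within-pair differences (requires \code{pair_id} in
#'   the cohort). Default \code{FALSE} (two-group).
#' @param weights Passed to \code{\link{fit_moderated_t}}.
#' @param prior_count Passed to \code{\link{logcpm_transform}}.
#' @return A \code{DEResult}; attribute \code{dropped_genes} lists all-zero
#'   genes excluded before fitting.
#' @export
diff_expression <- function(cohort, paired = FALSE, weights = "none",
                            prior_count = 0.5) {
  stopifnot(inherits(cohort, "ExpressionCohort"))
  all_zero <- rowSums(cohort$counts) == 0
  counts <- cohort$counts[!all_zero, , drop = FALSE]
  factors <- scale_normalize(counts)
  logmat <- logcpm_transform(counts, factors, prior_count = prior_count)
  pid <- if (paired) {
    if (is.null(cohort$pair_id)) stop("paired fit requires pair_id in the cohort")
    cohort$pair_id
  } else NULL
  de <- fit_moderated_t(logmat, cohort$condition, pair_id = pid,
                        weights = weights)
  attr(de, "dropped_genes") <- rownames(cohort$counts)[all_zero]
  attr(de, "scale_factors") <- factors
  de
}

#' @export
print.DEResult <- function(x, ...) {
  cat(sprintf("DEResult: %d genes (%d tumor vs %d normal)\n",
              nrow(x), attr(x, "n_tumor"), attr(x, "n_normal")))
  cat(sprintf("  prior df d0 = %.4g, prior variance s0^2 = %.4g\n",
              attr(x, "d0"), attr(x, "s02")))
  cat(sprintf("  genes at padj < 0.05: %d\n", sum(x$padj < 0.05)))
  invisible(x)
}
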