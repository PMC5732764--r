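# Small deterministic fixtures shared across test files.

# Tiny count cohort with named genes/samples; pairs T_i/N_i.
toy_cohort <- function(n_genes = 50, n_pairs = 4, seed = 101) {
  set.seed(seed)
  counts <- matrix(rnbinom(n_genes * 2 * n_pairs,
                           mu = rlnorm(n_genes, log(100), 1), size = 10),
                   nrow = n_genes,
                   dimnames = list(paste0("g", seq_len(n_genes)),
                                   c(paste0("T", seq_len(n_pairs)),
                                     paste0("N", seq_len(n_pairs)))))
  ExpressionCohort(counts, rep(c("tumor", "normal"), each = n_pairs),
                   pair_id = rep(paste0("P", seq_len(n_pairs)), 2))
}

# Beta matrix built directly from explicit per-group values for one CpG of
# interest plus flat background rows.
toy_beta <- function(control, depleted, n_bg = 5, bg = 0.5) {
  m <- rbind(cg_test = c(control, depleted),
             matrix(bg, n_bg, length(control) + length(depleted),
                    dimnames = list(paste0("bg", seq_len(n_bg)), NULL)))
  colnames(m) <- c(paste0("ctl_", seq_along(control)),
                   paste0("dep_", seq_along(depleted)))
  BetaMatrix(m, c(rep("control", length(control)),
                  rep("depleted", length(depleted))))
}

# Exhaustive log-space hypergeometric upper tail: P(X >= x) for
# X ~ Hyper(N, K, n), summed term by term via lchoose.
hyper_tail_oracle <- function(x, K, N, n) {
  support <- max(0, n - (N - K)):min(n, K)
  support <- support[support >= x]
  if (length(support) == 0) return(0)
  sum(exp(lchoose(K, support) + lchoose(N - K, n - support) - lchoose(N, n)))
}

# Exhaustive two-sided Fisher p for a 2x2 table via lchoose enumeration.
fisher_oracle <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  support <- max(0, k - n):min(k, m)
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  p_obs <- exp(lchoose(m, a) + lchoose(n, c_) - lchoose(m + n, k))
  sum(exp(logp)[exp(logp) <= p_obs * (1 + 1e-7)])
}

# Straightforward reimplementation of the doubly trimmed, precision-weighted
# mean of M-values, written independently of the package's vectorized path.
tmm_oracle <- function(counts) {
  lib <- colSums(counts)
  f75 <- sapply(seq_len(ncol(counts)), function(j)
    unname(quantile(counts[, j], 0.75)) / lib[j])
  ref <- which.min(abs(f75 - mean(f75)))
  one <- function(j) {
    o <- counts[, j]; r <- counts[, ref]
    M <- log2((o / lib[j]) / (r / lib[ref]))
    A <- (log2(o / lib[j]) + log2(r / lib[ref])) / 2
    w <- (lib[j] - o) / (lib[j] * o) + (lib[ref] - r) / (lib[ref] * r)
    ok <- is.finite(M) & is.finite(A)
    M <- M[ok]; A <- A[ok]; w <- w[ok]
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }
  f <- sapply(seq_len(ncol(counts)), one)
  f / exp(mean(log(f)))
}
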