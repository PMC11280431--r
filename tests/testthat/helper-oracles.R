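# Independent brute-force oracles used to validate the normalization and
# multiple-testing surfaces. These re-derive each quantity from its
# definition and share no code with the implementation under test.

# Weighted trimmed mean of M-values: doubly trimmed (30% of M-values, 5% of
# A-values per tail), inverse-asymptotic-variance weighted mean of per-gene
# log2 ratios against the reference column, factors rescaled to geometric
# mean 1. Reference = column whose upper-quartile count fraction is closest
# to the mean of those fractions.
tmm_oracle <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  lib <- colSums(counts)
  f75 <- apply(counts, 2, stats::quantile, p = 0.75) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  one <- function(j) {
    obs <- counts[, j]; rfc <- counts[, ref]
    nO <- lib[j]; nR <- lib[ref]
    logR <- log2((obs / nO) / (rfc / nR))
    absE <- (log2(obs / nO) + log2(rfc / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - rfc) / nR / rfc
    fin <- is.finite(logR) & is.finite(absE)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
    loS <- floor(n * sum_trim) + 1;     hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
            rank(absE) >= loS & rank(absE) <= hiS
    2^(sum(logR[keep] / v[keep]) / sum(1 / v[keep]))
  }
  f <- vapply(seq_len(ncol(counts)), one, 0)
  f / exp(mean(log(f)))
}

# Median of count-to-geometric-mean ratios over rows positive in all samples.
median_ratio_oracle <- function(counts) {
  loggeo <- rowMeans(log(counts))
  vapply(seq_len(ncol(counts)), function(j) {
    r <- log(counts[, j]) - loggeo
    exp(stats::median(r[is.finite(loggeo) & counts[, j] > 0]))
  }, 0)
}

# Benjamini-Hochberg step-up from its definition: sort, scale by m/rank,
# enforce monotonicity from the largest p down, clip at 1, unsort.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# Two-group Poisson GLM (log link, known offsets) likelihood-ratio statistic
# in closed form: group-wise MLE mu_j = (sum y in group / sum N in group) * N_j.
poisson_lrt_oracle <- function(y, eff_lib, group) {
  loglik <- function(mu) sum(y * log(mu) - mu)
  r1 <- vapply(split(seq_along(y), group),
               function(i) sum(y[i]) / sum(eff_lib[i]), 0)
  mu1 <- r1[as.character(group)] * eff_lib
  mu0 <- sum(y) / sum(eff_lib) * eff_lib
  2 * (loglik(mu1) - loglik(mu0))
}

# Rank-sum AUROC of a score for separating positives from negatives.
auroc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Minimal engine-result table for exercising consensus logic without engines.
fake_engine <- function(ids, lfc, fdr, logcpm = 5, engine = "fake") {
  data.frame(mirna_id = ids, log2FC = lfc, FC = 2^lfc, logCPM = logcpm,
             statistic = NA_real_, p_value = pmin(fdr, 1), FDR = fdr,
             engine = engine, stringsAsFactors = FALSE)
}

# Small four-group config for fast end-to-end tests.
tiny_config <- function(seed = 1, ...) {
  sim_config(n_mirnas = 200,
             group_sizes = c("UA-N" = 8, "UA-OC" = 10, "AF" = 8, "AC" = 6),
             seed = seed, ...)
}
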