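# independent brute-force oracles used to cross-check the implementation

# attainable correlation range for a Bernoulli pair by brute-force search
# over valid 2x2 joint tables (grid on the joint success probability)
oracle_correlation_range <- function(p1, p2, grid_n = 200001L) {
  lo <- max(0, p1 + p2 - 1)
  hi <- min(p1, p2)
  p11 <- seq(lo, hi, length.out = grid_n)
  r <- (p11 - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  range(r)
}

# Pearson GOF statistic by direct tabulation over all 2^n categories,
# written independently of the package internals (string patterns)
oracle_chisq_stat <- function(x) {
  m <- nrow(x); n <- ncol(x)
  phat <- colMeans(x)
  keep <- phat > 0 & phat < 1
  x <- x[, keep, drop = FALSE]
  phat <- phat[keep]
  k <- ncol(x)
  if (k < 2) return(NULL)
  pats <- apply(expand.grid(rep(list(c("0", "1")), k))[, k:1, drop = FALSE],
                1, paste0, collapse = "")
  pats <- sort(pats)  # lexicographic = binary order with site k as LSB
  obs_str <- apply(x, 1, paste0, collapse = "")
  stat <- 0
  for (pat in pats) {
    O <- sum(obs_str == pat)
    bits <- as.integer(strsplit(pat, "")[[1]])
    E <- m * prod(ifelse(bits == 1, phat, 1 - phat))
    stat <- stat + (O - E)^2 / E
  }
  list(stat = stat, df = 2^k - 1 - k)
}

# two-sided Fisher p by enumeration of all tables with the observed
# margins (probability-mass rule, relative tolerance 1e-7)
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  support <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- dhyper(support, c1, N - c1, r1)
  p_obs <- dhyper(a, c1, N - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# conditional-MLE odds ratio by maximizing the noncentral hypergeometric
# likelihood over log(psi)
oracle_fisher_or <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  support <- max(0, r1 + c1 - N):min(r1, c1)
  if (length(support) == 1L) return(NA_real_)  # degenerate margins
  if (a == min(support)) return(0)
  if (a == max(support)) return(Inf)
  w <- lchoose(c1, support) + lchoose(N - c1, r1 - support)
  negll <- function(lp) {
    lw <- w + support * lp
    -(w[support == a] + a * lp - matrixStats_logsumexp(lw))
  }
  exp(optimize(negll, c(-30, 30), tol = 1e-10)$minimum)
}

matrixStats_logsumexp <- function(x) {
  mx <- max(x)
  mx + log(sum(exp(x - mx)))
}

# empirical pattern frequencies vs a theoretical distribution: chi-square
# GOF p-value with df = (#cells with positive probability) - 1
oracle_freq_gof_p <- function(counts, q) {
  keep <- q > 0
  stat <- sum((counts[keep] - sum(counts) * q[keep])^2 / (sum(counts) * q[keep]))
  pchisq(stat, sum(keep) - 1, lower.tail = FALSE)
}

# correlation between two sites implied by a pattern distribution
implied_pairwise_cor <- function(q, n, i, j) {
  B <- mentropy::pattern_matrix(n)
  pi_ <- sum(q[B[, i] == 1])
  pj_ <- sum(q[B[, j] == 1])
  pij <- sum(q[B[, i] == 1 & B[, j] == 1])
  (pij - pi_ * pj_) / sqrt(pi_ * (1 - pi_) * pj_ * (1 - pj_))
}

# toy read matrix with the given per-pattern counts (index convention:
# last site = least-significant bit)
reads_from_counts <- function(counts, n) {
  B <- mentropy::pattern_matrix(n)
  do.call(rbind, lapply(seq_along(counts), function(i) {
    B[rep(i, counts[i]), , drop = FALSE]
  }))
}
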