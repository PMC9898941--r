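# chi-square goodness-of-fit tests for spatial correlation on a CpG segment

# core computation shared by the public tests and the simulation engines.
# qfun(phat_kept, kept_index) returns null pattern probabilities for the
# non-degenerate sites; NULL qfun means the independence null.
chisq_core <- function(x, qfun = NULL) {
  m <- nrow(x)
  phat <- colMeans(x)
  kept <- which(phat > 0 & phat < 1)
  k <- length(kept)
  if (k < 2L) {
    return(list(testable = FALSE, k = k, kept = kept, m = m, phat = phat,
                statistic = NA_real_, df = NA_integer_, p.value = NA_real_,
                observed = NULL, expected = NULL, min_expected = NA_real_))
  }
  xk <- x[, kept, drop = FALSE]
  O <- tabulate(pattern_index(xk) + 1L, nbins = 2^k)
  q <- if (is.null(qfun)) {
    pk <- phat[kept]
    B <- pattern_matrix(k)
    as.vector(exp(B %*% log(pk) + (1 - B) %*% log(1 - pk)))
  } else {
    qfun(phat[kept], kept)
  }
  E <- m * q
  ratio <- (O - E)^2 / E
  ratio[E == 0 & O == 0] <- 0  # cannot occur under the independence null
  stat <- sum(ratio)
  df <- 2^k - 1L - k
  list(testable = TRUE, k = k, kept = kept, m = m, phat = phat,
       statistic = stat, df = df,
       p.value = pchisq(stat, df, lower.tail = FALSE),
       observed = O, expected = E, min_expected = min(E))
}

make_gof <- function(core, alpha, method, reason = NULL) {
  nm <- if (core$k >= 1L) rownames(pattern_matrix(max(core$k, 1L))) else NULL
  if (!is.null(core$observed)) names(core$observed) <- nm
  if (!is.null(core$expected)) names(core$expected) <- nm
  structure(list(
    statistic = core$statistic, df = core$df, p.value = core$p.value,
    observed = core$observed, expected = core$expected,
    k = core$k, sites_used = core$kept, m = core$m,
    min_expected = core$min_expected, testable = core$testable,
    alpha = alpha, method = method, reason = reason
  ), class = "meth_gof")
}

#' Chi-square test for the existence of spatial correlation
#'
#' Tests the null hypothesis of no spatial correlation
#' (`r_ij = 0` for all site pairs) on an n-CpG segment by a Pearson
#' goodness-of-fit test of the observed pattern counts `O_i` against the
#' expected counts `E_i = m q_i`, where the `q_i` come from the
#' independent-site product form with the per-site methylation levels
#' plugged in:
#' `chi^2 = sum_i (O_i - E_i)^2 / E_i`.
#'
#' Sites whose estimated methylation level is exactly 0 or 1 carry no
#' degrees of freedom; they are dropped and the test runs on the
#' remaining `k` sites over `2^k` pattern cells with
#' `df = 2^k - 1 - k` (k estimated probabilities are lost).  When fewer
#' than two non-degenerate sites remain the segment is reported
#' untestable rather than an error.  No minimum-expected-count rule or
#' continuity correction is applied; `min_expected` is recorded for
#' diagnostics.
#'
#' @param reads an `m`-by-`n` binary read matrix, `n >= 2`.
#' @param alpha significance level carried as metadata (the result always
#'   holds the p-value).
#' @return an object of class `"meth_gof"` with elements `statistic`,
#'   `df`, `p.value`, `observed`, `expected`, `k`, `sites_used`, `m`,
#'   `min_expected`, `testable`.
#' @examples
#' x <- rbind(matrix(0L, 20, 4), matrix(1L, 20, 4))
#' chi_square_spatial_test(x) # statistic 280 on 11 df
#' @export
chi_square_spatial_test <- function(reads, alpha = 0.05) {
  reads <- as.matrix(reads)
  stopifnot(is_binary_matrix(reads), nrow(reads) >= 1, ncol(reads) >= 2)
  make_gof(chisq_core(reads), alpha, "independence null")
}

#' Chi-square test against a hypothesized correlation structure
#'
#' Extension of [chi_square_spatial_test()] in which the null hypothesis
#' specifies a spatial-correlation structure instead of independence:
#' the expected counts are `E_i = m q_i` with `q_i` computed from the
#' latent-Gaussian pattern distribution at the plug-in methylation
#' levels and the hypothesized exchangeable or AR(1) correlation `r`.
#' Because `r` is fixed by the hypothesis (not estimated), the degrees
#' of freedom remain `2^k - 1 - k`.  If `r` is infeasible for the
#' estimated marginals the segment is reported untestable with the
#' violated bound as `reason`.  For AR(1), site distances are measured on
#' the original segment even when degenerate sites are dropped.
#'
#' @inheritParams chi_square_spatial_test
#' @param structure `"exchangeable"` or `"ar1"`.
#' @param r hypothesized correlation parameter.
#' @return an object of class `"meth_gof"`; at `r = 0` identical to
#'   [chi_square_spatial_test()].
#' @export
chi_square_structured_test <- function(reads, structure = c("exchangeable", "ar1"),
                                       r, alpha = 0.05) {
  reads <- as.matrix(reads)
  structure <- match.arg(structure)
  stopifnot(is_binary_matrix(reads), nrow(reads) >= 1, ncol(reads) >= 2)
  n <- ncol(reads)
  Rfull <- if (structure == "exchangeable") {
    matrix(r, n, n)
  } else {
    r^abs(outer(seq_len(n), seq_len(n), "-"))
  }
  diag(Rfull) <- 1
  method <- sprintf("structured null (%s, r = %g)", structure, r)

  qfun <- function(pk, kept) {
    params <- bernoulli_params(pk, R = Rfull[kept, kept, drop = FALSE])
    pattern_distribution(params)$q
  }
  # feasibility failures surface as errors from bernoulli_params; convert
  core <- tryCatch(chisq_core(reads, qfun), error = function(e) e)
  if (inherits(core, "error")) {
    base <- chisq_core(reads, NULL)
    base$testable <- FALSE
    base$statistic <- NA_real_; base$df <- NA_integer_; base$p.value <- NA_real_
    base$observed <- NULL; base$expected <- NULL; base$min_expected <- NA_real_
    return(make_gof(base, alpha, method, reason = conditionMessage(core)))
  }
  make_gof(core, alpha, method)
}

#' Expected pattern counts under the independence null
#'
#' `E_i = m q_i` with the `q_i` computed from the independent-site
#' product form at the plug-in per-site methylation levels.  All sites
#' are used as-is (degenerate sites simply give zero-probability cells);
#' the counts sum to `m`.
#'
#' @inheritParams chi_square_spatial_test
#' @return named numeric vector of length `2^n`.
#' @examples
#' expected_counts_independent(rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1)))
#' @export
expected_counts_independent <- function(reads) {
  reads <- as.matrix(reads)
  stopifnot(is_binary_matrix(reads), nrow(reads) >= 1)
  m <- nrow(reads)
  m * independent_pattern_probs(colMeans(reads))
}

#' @export
print.meth_gof <- function(x, ...) {
  cat("Chi-square goodness-of-fit test for spatial correlation\n")
  cat("null:", x$method, "  reads m =", x$m, "\n")
  if (!x$testable) {
    cat("untestable: fewer than 2 non-degenerate sites",
        if (!is.null(x$reason)) paste0("(", x$reason, ")"), "\n")
  } else {
    cat(sprintf("X-squared = %.4g, df = %d, p-value = %.4g\n",
                x$statistic, x$df, x$p.value))
    cat(sprintf("sites used k = %d, min expected count = %.3g\n",
                x$k, x$min_expected))
  }
  invisible(x)
}
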