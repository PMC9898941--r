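# bipolar-locus classification, DMR testing, and 2x2 association analysis

#' Criteria for bipolar methylated loci
#'
#' A segment is called bipolar methylated when its reads concentrate on
#' the all-methylated and all-unmethylated patterns: non-extreme mean
#' methylation level together with an observed entropy below the
#' theoretical entropy under strong exchangeable spatial correlation.
#' The defaults mirror the operational rule `MML in (0.2, 0.8)` and
#' `OME < S(MML; r = 0.6)`; raising `r_threshold` lowers the threshold
#' curve and is therefore more stringent.
#'
#' @param mml_low,mml_high open MML window bounds.
#' @param r_threshold exchangeable correlation of the threshold entropy
#'   curve, in `[0, 1]`.
#' @param n segment size the criteria apply to.
#' @param require_spatial if `TRUE`, additionally require the spatial
#'   chi-square test to be significant at `alpha` (strict mode; off by
#'   default, matching the two-condition rule).
#' @param alpha significance level used by the strict mode.
#' @return an object of class `"bipolar_criteria"`.
#' @export
bipolar_criteria <- function(mml_low = 0.2, mml_high = 0.8,
                             r_threshold = 0.6, n = 4,
                             require_spatial = FALSE, alpha = 0.05) {
  stopifnot(mml_low >= 0, mml_high <= 1, mml_low < mml_high,
            r_threshold >= 0, r_threshold <= 1, n >= 1)
  structure(list(mml_low = mml_low, mml_high = mml_high,
                 r_threshold = r_threshold, n = as.integer(n),
                 require_spatial = require_spatial, alpha = alpha),
            class = "bipolar_criteria")
}

#' Classify segments as bipolar methylated loci
#'
#' Flags a segment as bipolar when `mml_low < MML < mml_high` and
#' `OME < S(MML; n, r_threshold)`, the theoretical entropy at the
#' segment's MML under exchangeable correlation `r_threshold`
#' ([me_exchangeable()]).  The spatial-test p-value does not gate the
#' flag unless `require_spatial` was set in the criteria.
#'
#' The flag is monotone in the threshold: raising `r_threshold` lowers
#' the entropy curve, so the flagged set can only shrink.
#'
#' @param stats a data frame with columns `mml` and `ome` (and `chisq_p`
#'   when the criteria demand the spatial test), e.g. from
#'   [segment_stats_table()].
#' @param criteria a [bipolar_criteria()] object.
#' @return logical vector, one flag per row of `stats`.
#' @export
classify_bipolar <- function(stats, criteria = bipolar_criteria()) {
  stopifnot(inherits(criteria, "bipolar_criteria"),
            all(c("mml", "ome") %in% names(stats)))
  mml <- stats$mml; ome <- stats$ome
  flag <- mml > criteria$mml_low & mml < criteria$mml_high
  if (any(flag)) {
    thr <- me_exchangeable(criteria$n, mml[flag], criteria$r_threshold)
    flag[flag] <- ome[flag] < thr
  }
  if (criteria$require_spatial) {
    if (!"chisq_p" %in% names(stats))
      stop("strict mode requires a `chisq_p` column")
    flag <- flag & !is.na(stats$chisq_p) & stats$chisq_p < criteria$alpha
  }
  flag
}

#' Differential methylation test between two samples of a segment
#'
#' Compares the mean methylation levels of the same segment in two
#' samples by a Pearson chi-square test (1 df, no continuity correction)
#' on the 2x2 table of methylated versus unmethylated calls pooled over
#' all sites and reads: the methylated count of a sample is
#' `m * n * MML`.  A zero margin (e.g. both samples fully methylated)
#' yields p-value 1 and a `degenerate` flag rather than an error.
#'
#' @param segment_a,segment_b read matrices (or `"meth_segment"`
#'   objects) of the same segment in the two samples.
#' @param alpha significance level; the segment is called a DMR when
#'   `p.value < alpha`.
#' @return an object of class `"dmr_result"`: list with `statistic`,
#'   `df`, `p.value`, `table`, `dmr`, `degenerate`, `alpha`.
#' @examples
#' a <- matrix(1L, 20, 4); b <- matrix(0L, 20, 4)
#' dmr_test(a, b)
#' @export
dmr_test <- function(segment_a, segment_b, alpha = 0.05) {
  xa <- if (inherits(segment_a, "meth_segment")) segment_a$x else as.matrix(segment_a)
  xb <- if (inherits(segment_b, "meth_segment")) segment_b$x else as.matrix(segment_b)
  stopifnot(is_binary_matrix(xa), is_binary_matrix(xb))
  dmr_test_counts(sum(xa), length(xa) - sum(xa),
                  sum(xb), length(xb) - sum(xb), alpha = alpha)
}

#' @rdname dmr_test
#' @param meth_a,unmeth_a,meth_b,unmeth_b pooled methylated and
#'   unmethylated call counts of the two samples (alternative entry
#'   point when only summary counts are available).
#' @export
dmr_test_counts <- function(meth_a, unmeth_a, meth_b, unmeth_b,
                            alpha = 0.05) {
  tab <- matrix(c(meth_a, unmeth_a, meth_b, unmeth_b), nrow = 2,
                byrow = TRUE,
                dimnames = list(c("sample_a", "sample_b"),
                                c("methylated", "unmethylated")))
  stopifnot(all(tab >= 0), sum(tab) > 0)
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    stat <- 0; p <- 1
  } else {
    N <- sum(tab)
    stat <- N * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
      prod(rowSums(tab), colSums(tab))
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(list(statistic = stat, df = 1L, p.value = p, table = tab,
                 dmr = !degenerate && p < alpha, degenerate = degenerate,
                 alpha = alpha),
            class = "dmr_result")
}

#' @export
print.dmr_result <- function(x, ...) {
  cat("DMR chi-square test (pooled methylated/unmethylated counts)\n")
  print(x$table)
  if (x$degenerate) {
    cat("degenerate margin: p-value set to 1\n")
  } else {
    cat(sprintf("X-squared = %.4g, df = 1, p-value = %.4g (DMR at %.3g: %s)\n",
                x$statistic, x$p.value, x$alpha, x$dmr))
  }
  invisible(x)
}

#' Fisher's exact test for a 2x2 contingency table
#'
#' Two-sided Fisher's exact test with the conditional maximum-likelihood
#' odds ratio, as used to assess the association between bipolar
#' methylated loci and DMRs.  The two-sided p-value sums the
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table (with a
#' 1e-7 relative tolerance guarding floating-point ties); the odds-ratio
#' estimate is the conditional MLE under the noncentral hypergeometric
#' model, which may be 0 or infinite for tables with an empty cell.
#'
#' @param table a 2x2 matrix of non-negative counts, or a length-4
#'   vector `c(a, b, c, d)` filled row-wise.
#' @return an object of class `"fisher_result"`: list with
#'   `p_two_sided`, `odds_ratio`, `table`.
#' @examples
#' fisher_exact_2x2(c(161, 30, 527, 248))
#' @export
fisher_exact_2x2 <- function(table) {
  if (is.numeric(table) && length(table) == 4L && is.null(dim(table)))
    table <- matrix(table, nrow = 2, byrow = TRUE)
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2L), all(table >= 0),
            all(table == round(table)), sum(table) > 0)
  ft <- fisher.test(table)
  structure(list(p_two_sided = ft$p.value,
                 odds_ratio = unname(ft$estimate),
                 table = table),
            class = "fisher_result")
}

#' @export
print.fisher_result <- function(x, ...) {
  cat("Fisher's exact test (two-sided)\n")
  print(x$table)
  cat(sprintf("p-value = %.4g, odds ratio (conditional MLE) = %.4g\n",
              x$p_two_sided, x$odds_ratio))
  invisible(x)
}

#' Association between two per-segment flag vectors
#'
#' Cross-tabulates two logical flag vectors aligned on the same segment
#' list (e.g. DMR status against bipolar status on the common CpG
#' segments) and applies [fisher_exact_2x2()].  The first flag indexes
#' the rows of the table, the second the columns, with `TRUE` first, so
#' `association_analysis(dmr, bipolar)` reproduces a table with rows
#' DMR/non-DMR and columns bipolar/non-bipolar.
#'
#' @param flags_a,flags_b logical vectors of equal length.
#' @return list with elements `table` (2x2 matrix), `fisher`
#'   (`"fisher_result"`) and `venn` (counts `both`, `a_only`, `b_only`,
#'   `neither`).
#' @export
association_analysis <- function(flags_a, flags_b) {
  if (length(flags_a) != length(flags_b))
    stop("flag vectors must be aligned on the same segment list (lengths ",
         length(flags_a), " and ", length(flags_b), ")")
  flags_a <- as.logical(flags_a); flags_b <- as.logical(flags_b)
  tab <- matrix(c(sum(flags_a & flags_b), sum(flags_a & !flags_b),
                  sum(!flags_a & flags_b), sum(!flags_a & !flags_b)),
                nrow = 2, byrow = TRUE,
                dimnames = list(a = c("TRUE", "FALSE"),
                                b = c("TRUE", "FALSE")))
  list(table = tab, fisher = fisher_exact_2x2(tab),
       venn = c(both = tab[1, 1], a_only = tab[1, 2],
                b_only = tab[2, 1], neither = tab[2, 2]))
}
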