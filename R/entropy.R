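# methylation entropy (parameter side) and OME / ML / MML (statistic side)

#' Methylation entropy of a pattern distribution
#'
#' Shannon entropy, in bits, of the joint distribution of methylation
#' states across the n sites of a CpG segment:
#' `S = -sum_i q_i log2(q_i)` with the convention `0 log 0 := 0`.
#' The result lies in `[0, n]`; it is maximal (`n` bits) for the uniform
#' distribution over patterns and zero for a point mass.
#'
#' @param dist a [pattern_distribution()] object, or a bare numeric
#'   probability vector of length `2^n` (must be non-negative and sum to
#'   1 within 1e-6).
#' @return entropy in bits.
#' @examples
#' methylation_entropy(pattern_distribution(bernoulli_params(c(0.5, 0.5))))
#' methylation_entropy(c(0.5, 0, 0, 0.5)) # two equiprobable patterns: 1 bit
#' @export
methylation_entropy <- function(dist) {
  q <- if (inherits(dist, "pattern_distribution")) dist$q else as.numeric(dist)
  if (any(q < 0)) stop("pattern probabilities must be non-negative")
  if (abs(sum(q) - 1) > 1e-6) stop("pattern probabilities must sum to 1")
  entropy_bits(q)
}

#' Methylation entropy under independent CpG sites
#'
#' With no spatial correlation the joint pattern distribution factorizes
#' and the methylation entropy reduces to a sum of per-site binary
#' entropies:
#' `S = -sum_i [ (1 - p_i) log2(1 - p_i) + p_i log2(p_i) ]`,
#' i.e. `-n [ (1-p) log2(1-p) + p log2(p) ]` under homogeneous
#' methylation.
#'
#' @param p vector of per-site methylation probabilities in `[0, 1]`.
#' @return entropy in bits.
#' @examples
#' me_independent(c(0.5, 0.5)) # 2 bits
#' me_independent(0.3)
#' @export
me_independent <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1))
  sum(binary_entropy(p))
}

#' Observed methylation entropy of a read matrix
#'
#' The plug-in entropy of the empirical pattern frequencies among the `m`
#' reads fully covering the segment:
#' `S_hat = -sum_i (O_i / m) log2(O_i / m)`, with `0 log 0 := 0`.
#' Bounded by `min(n, log2(m))`.  Note the plug-in estimator is biased
#' downward at small `m` (patterns that happen not to be observed
#' contribute nothing); no bias correction is applied.
#'
#' @param reads an `m`-by-`n` binary matrix (rows = reads, columns = CpG
#'   sites).
#' @return observed methylation entropy in bits.
#' @examples
#' x <- rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1))
#' observed_me(x) # bipolar: 1 bit
#' @export
observed_me <- function(reads) {
  reads <- as.matrix(reads)
  stopifnot(is_binary_matrix(reads), nrow(reads) >= 1)
  entropy_bits(pattern_counts(reads) / nrow(reads))
}

#' Per-site methylation levels and mean methylation level
#'
#' The methylation level (ML) of site `j` is the column mean
#' `x_bar_j = (1/m) sum_i x_ij`; the mean methylation level (MML) is the
#' average of the `n` site levels, equivalently the grand mean of the
#' read matrix.
#'
#' @inheritParams observed_me
#' @return list with elements `ml` (numeric vector of length `n`) and
#'   `mml` (scalar).
#' @examples
#' methylation_levels(rbind(c(1, 0), c(1, 1)))
#' @export
methylation_levels <- function(reads) {
  reads <- as.matrix(reads)
  stopifnot(is_binary_matrix(reads), nrow(reads) >= 1)
  ml <- colMeans(reads)
  list(ml = ml, mml = mean(ml))
}

#' Methylation entropy under homogeneous exchangeable correlation
#'
#' Evaluates the methylation entropy `S(p, r)` of an n-CpG segment with
#' homogeneous methylation probability `p` and exchangeable spatial
#' correlation `r`, via the latent-Gaussian pattern distribution.  At
#' `r = 0` this reduces to the independent-site closed form; at `r = 1`
#' only the all-methylated and all-unmethylated patterns survive and `S`
#' collapses to the binary entropy of `p`.  Used as the threshold curve
#' for bipolar-locus classification.
#'
#' @param n segment size.
#' @param p homogeneous methylation probability (vectorized).
#' @param r exchangeable correlation in `[0, 1]`.
#' @return entropy values in bits, same length as `p`.
#' @seealso [me_curve()], [classify_bipolar()]
#' @export
me_exchangeable <- function(n, p, r) {
  stopifnot(n >= 1, n == round(n), r >= 0, r <= 1, all(p >= 0 & p <= 1))
  vapply(p, function(pp) {
    if (pp <= 0 || pp >= 1) return(0)
    if (r == 0) return(n * binary_entropy(pp))
    if (r >= 1) return(binary_entropy(pp))
    params <- bernoulli_params(pp, n = n, structure = "exchangeable", r = r)
    entropy_bits(pattern_distribution(params)$q)
  }, 0)
}

#' Theoretical entropy-versus-probability curve
#'
#' Tabulates the analytical relation `S(p)` between methylation entropy
#' and methylation probability for an n-CpG segment under homogeneous
#' methylation and exchangeable spatial correlation `r`.  The curve is
#' symmetric about `p = 0.5`, maximized there, and decreases pointwise as
#' `r` grows from 0 (independent sites, `S = n h(p)`) to 1 (perfectly
#' correlated sites, `S = h(p)`), where `h` is the binary entropy.
#'
#' @param n segment size.
#' @param r exchangeable correlation in `[0, 1]`.
#' @param p_grid grid of methylation probabilities, strictly inside
#'   (0, 1); the default steps by 0.005.
#' @return a data frame with columns `p` and `S` (bits); attributes `n`
#'   and `r` record the curve parameters.
#' @examples
#' head(me_curve(4, 0.6, p_grid = c(0.1, 0.3, 0.5)))
#' @export
me_curve <- function(n, r, p_grid = seq(0.005, 0.995, by = 0.005)) {
  stopifnot(all(p_grid > 0 & p_grid < 1))
  out <- data.frame(p = p_grid, S = me_exchangeable(n, p_grid, r))
  attr(out, "n") <- n
  attr(out, "r") <- r
  out
}
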