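#' Parameters of the correlated Bernoulli methylation model
#'
#' The methylation pattern of an n-CpG segment is modelled as a binary
#' random vector `X = (X_1, ..., X_n)` with marginals
#' `X_i ~ Bernoulli(p_i)` and between-site (spatial) correlations
#' `cor(X_i, X_j) = r_ij`.  `bernoulli_params()` builds and validates the
#' parameter object, either from an explicit correlation matrix `R` or
#' from one of the named structures:
#'
#' * `"independent"`: `R` is the identity;
#' * `"exchangeable"`: `r_ij = r` for all pairs (compound symmetry);
#' * `"ar1"`: `r_ij = r^|i - j|` (first-order autoregressive decay).
#'
#' A scalar `p` with `n` supplied gives homogeneous methylation
#' (`p_i = p` for all sites).  Not every correlation is attainable by a
#' binary pair: each `r_ij` must lie within the Frechet bounds for the
#' marginals `(p_i, p_j)` (see [pairwise_correlation_bounds()]); the
#' constructor enforces this.  Degenerate sites (`p_i` of exactly 0 or 1)
#' are allowed but must be uncorrelated with every other site.
#'
#' @param p methylation probabilities: a vector of length `n`, or a scalar
#'   recycled to `n` (homogeneous methylation).
#' @param R optional n-by-n correlation matrix; overrides `structure`.
#' @param n number of CpG sites; defaults to `length(p)`.
#' @param structure correlation structure used when `R` is missing.
#' @param r scalar correlation parameter for the exchangeable and AR(1)
#'   structures.
#' @return an object of class `"bernoulli_params"`: a list with elements
#'   `n`, `p` and `R`.
#' @seealso [pattern_distribution()], [sample_reads()],
#'   [build_latent_model()]
#' @examples
#' bernoulli_params(0.5, n = 4, structure = "exchangeable", r = 0.6)
#' bernoulli_params(c(0.3, 0.6), structure = "ar1", r = 0.4)
#' @export
bernoulli_params <- function(p, R = NULL, n = length(p),
                             structure = c("independent", "exchangeable", "ar1"),
                             r = 0) {
  stopifnot(is.numeric(p), length(p) >= 1L, n >= 1, n == round(n))
  if (length(p) == 1L) p <- rep(p, n)
  if (length(p) != n)
    stop("`p` must have length 1 or `n` (", n, "), got ", length(p))
  if (any(p < 0 | p > 1)) stop("methylation probabilities must lie in [0, 1]")

  if (is.null(R)) {
    structure <- match.arg(structure)
    if (structure != "independent") {
      stopifnot(is.numeric(r), length(r) == 1L)
      if (abs(r) > 1) stop("`r` must lie in [-1, 1]")
    }
    R <- switch(structure,
      independent  = diag(n),
      exchangeable = matrix(r, n, n),
      ar1          = r^abs(outer(seq_len(n), seq_len(n), "-"))
    )
    diag(R) <- 1
  } else {
    R <- as.matrix(R)
  }

  obj <- structure(list(n = as.integer(n), p = as.numeric(p), R = R),
                   class = "bernoulli_params")
  validate_bernoulli_params(obj)
  obj
}

# check symmetry, unit diagonal, pairwise feasibility, degenerate sites
validate_bernoulli_params <- function(params) {
  n <- params$n; p <- params$p; R <- params$R
  if (!is.matrix(R) || any(dim(R) != n))
    stop("`R` must be an ", n, "-by-", n, " matrix")
  if (any(abs(R - t(R)) > 1e-12)) stop("`R` must be symmetric")
  if (any(abs(diag(R) - 1) > 1e-12)) stop("`R` must have unit diagonal")
  if (any(abs(R) > 1 + 1e-12)) stop("correlations must lie in [-1, 1]")
  deg <- p <= 0 | p >= 1
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      rij <- R[i, j]
      if (deg[i] || deg[j]) {
        if (abs(rij) > 1e-12)
          stop("site ", i, " or ", j, " has a degenerate methylation ",
               "probability; its correlation must be 0, got ", rij)
        next
      }
      b <- pairwise_correlation_bounds(p[i], p[j])
      if (rij < b[1] - 1e-9 || rij > b[2] + 1e-9)
        stop(sprintf(
          "correlation r[%d,%d] = %.4g outside the feasible range [%.4g, %.4g] for marginals (%.4g, %.4g)",
          i, j, rij, b[1], b[2], p[i], p[j]))
    }
  }
  invisible(params)
}

#' @export
print.bernoulli_params <- function(x, ...) {
  cat("Correlated Bernoulli methylation model: n =", x$n, "CpG sites\n")
  cat("p:", format(x$p, digits = 4), "\n")
  off <- x$R[upper.tri(x$R)]
  if (all(abs(off) < 1e-12)) {
    cat("R: identity (independent sites)\n")
  } else if (length(unique(signif(off, 10))) == 1L) {
    cat("R: exchangeable, r =", format(off[1], digits = 4), "\n")
  } else {
    cat("R:\n"); print(round(x$R, 4))
  }
  invisible(x)
}

#' Attainable correlation range for a bivariate Bernoulli pair
#'
#' Two binary variables with marginals `p_i` and `p_j` cannot attain every
#' correlation in `[-1, 1]`: the joint success probability
#' `P(X_i = 1, X_j = 1)` is constrained to the Frechet interval
#' `[max(0, p_i + p_j - 1), min(p_i, p_j)]`, which maps on the correlation
#' scale to the interval returned here.  The full range `[-1, 1]` is
#' attained only for `p_i = p_j = 1/2` (upper end requires `p_i = p_j`).
#'
#' @param p_i,p_j marginal methylation probabilities, strictly inside
#'   (0, 1); correlation is undefined for a degenerate marginal.
#' @return numeric vector `c(r_min, r_max)`.
#' @examples
#' pairwise_correlation_bounds(0.5, 0.5) # c(-1, 1)
#' pairwise_correlation_bounds(0.3, 0.7) # upper bound 3/7
#' @export
pairwise_correlation_bounds <- function(p_i, p_j) {
  stopifnot(is.numeric(p_i), is.numeric(p_j),
            length(p_i) == 1L, length(p_j) == 1L)
  if (p_i <= 0 || p_i >= 1 || p_j <= 0 || p_j >= 1)
    stop("correlation is undefined for degenerate marginals (p of 0 or 1)")
  s <- sqrt(p_i * (1 - p_i) * p_j * (1 - p_j))
  lower <- (max(0, p_i + p_j - 1) - p_i * p_j) / s
  upper <- (min(p_i, p_j) - p_i * p_j) / s
  c(max(-1, lower), min(1, upper))
}
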