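# latent multivariate-normal construction of the correlated Bernoulli model

# bivariate standard-normal CDF P(Z1 <= z1, Z2 <= z2) at correlation rho.
# TVPACK is deterministic with ~1e-14 absolute accuracy; the degenerate
# correlations have closed forms.
phi2 <- function(z1, z2, rho) {
  if (rho == 0) return(pnorm(z1) * pnorm(z2))
  if (rho >= 1) return(pnorm(min(z1, z2)))
  if (rho <= -1) return(max(0, pnorm(z1) + pnorm(z2) - 1))
  as.numeric(mvtnorm::pmvnorm(
    upper = c(z1, z2), corr = matrix(c(1, rho, rho, 1), 2L),
    algorithm = mvtnorm::TVPACK()))
}

# MVN CDF P(Z <= z) for arbitrary dimension; deterministic algorithms only
mvn_cdf <- function(z, Sigma) {
  d <- length(z)
  if (d == 1L) return(pnorm(z))
  if (d == 2L) return(phi2(z[1], z[2], Sigma[1, 2]))
  alg <- if (d == 3L) mvtnorm::TVPACK() else mvtnorm::Miwa(steps = 512L)
  as.numeric(mvtnorm::pmvnorm(upper = z, corr = Sigma, algorithm = alg))
}

#' Latent normal correlation matching a Bernoulli-scale correlation
#'
#' In the latent-Gaussian (thresholding) construction, site `i` is
#' methylated when a standard-normal variable falls below
#' `z_i = qnorm(p_i)`.  For a pair of sites the Bernoulli-scale
#' correlation `r_ij` determines the joint success probability
#' `P11 = r_ij * sqrt(p_i (1-p_i) p_j (1-p_j)) + p_i p_j`, and the latent
#' correlation `rho` is the root of
#' `Phi2(z_i, z_j; rho) = P11`,
#' where `Phi2` is the bivariate standard-normal CDF.  The left side is
#' strictly increasing in `rho`, so the root is found by safeguarded
#' Newton iteration (the derivative is the bivariate normal density at
#' `(z_i, z_j)`) bracketed in `[-1, 1]`, to residual `<= 1e-8`.
#'
#' @param p_i,p_j marginal methylation probabilities in (0, 1).
#' @param r_ij Bernoulli-scale correlation; must lie within
#'   [pairwise_correlation_bounds()] for the marginals.
#' @return the latent correlation `rho` in `[-1, 1]`.
#' @examples
#' solve_latent_correlation(0.5, 0.5, 0.5) # sin(pi/4) = 0.7071
#' @export
solve_latent_correlation <- function(p_i, p_j, r_ij) {
  if (p_i <= 0 || p_i >= 1 || p_j <= 0 || p_j >= 1)
    stop("correlation is undefined for degenerate marginals (p of 0 or 1)")
  b <- pairwise_correlation_bounds(p_i, p_j)
  if (r_ij < b[1] - 1e-9 || r_ij > b[2] + 1e-9)
    stop(sprintf(
      "r_ij = %.6g violates the feasible range [%.6g, %.6g] for marginals (%.4g, %.4g)",
      r_ij, b[1], b[2], p_i, p_j))

  z1 <- qnorm(p_i); z2 <- qnorm(p_j)
  target <- r_ij * sqrt(p_i * (1 - p_i) * p_j * (1 - p_j)) + p_i * p_j
  # comonotone / antithetic limits of Phi2
  hi_val <- pnorm(min(z1, z2))
  lo_val <- max(0, p_i + p_j - 1)
  if (target >= hi_val - 1e-12) return(1)
  if (target <= lo_val + 1e-12) return(-1)

  lo <- -1; hi <- 1
  rho <- max(min(r_ij, 0.999), -0.999)  # start near the Bernoulli-scale value
  for (iter in 1:200) {
    f <- phi2(z1, z2, rho) - target
    if (abs(f) <= 1e-9) break
    if (f > 0) hi <- rho else lo <- rho
    dens <- exp(-(z1^2 - 2 * rho * z1 * z2 + z2^2) / (2 * (1 - rho^2))) /
      (2 * pi * sqrt(1 - rho^2))
    step <- rho - f / dens
    rho <- if (is.finite(step) && step > lo && step < hi) step else (lo + hi) / 2
  }
  if (abs(phi2(z1, z2, rho) - target) > 1e-8)
    stop("latent-correlation solver failed to reach residual tolerance")
  rho
}

#' Latent multivariate-normal model for a correlated Bernoulli vector
#'
#' Determines the dichotomization thresholds `z_i = qnorm(p_i)` and the
#' latent correlation matrix `Sigma` such that thresholding a standard
#' multivariate normal vector with correlation `Sigma` at `z` (site `i`
#' methylated when `Z_i <= z_i`) reproduces the marginals `p` exactly and
#' the pairwise Bernoulli correlations `R` within solver tolerance.
#' `Sigma` is assembled from pairwise [solve_latent_correlation()] calls;
#' a valid set of pairwise correlations is not guaranteed to form a
#' positive semi-definite matrix, in which case `Sigma` is projected to
#' the nearest correlation matrix (the repair is flagged and refused if
#' any entry moves by more than 0.01).
#'
#' @param params a [bernoulli_params()] object with all `p_i` strictly
#'   inside (0, 1).
#' @return an object of class `"latent_gaussian_model"`: list with
#'   elements `z`, `Sigma`, `repaired` and `max_perturbation`.
#' @export
build_latent_model <- function(params) {
  stopifnot(inherits(params, "bernoulli_params"))
  n <- params$n; p <- params$p; R <- params$R
  if (any(p <= 0 | p >= 1))
    stop("latent model requires all methylation probabilities strictly inside (0, 1)")
  z <- qnorm(p)
  Sigma <- diag(n)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        rho <- tryCatch(
          solve_latent_correlation(p[i], p[j], R[i, j]),
          error = function(e) stop("latent solve failed for site pair (",
                                   i, ", ", j, "): ", conditionMessage(e)))
        Sigma[i, j] <- Sigma[j, i] <- rho
      }
    }
  }
  repaired <- FALSE; max_pert <- 0
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    fixed <- as.matrix(Matrix::nearPD(Sigma, corr = TRUE)$mat)
    max_pert <- max(abs(fixed - Sigma))
    if (max_pert > 0.01)
      stop("latent correlation matrix is not positive semi-definite and the ",
           "nearest-correlation repair perturbs entries by ",
           format(max_pert, digits = 3), " (> 0.01); refusing")
    warning("latent correlation matrix repaired to nearest correlation matrix; ",
            "max entry perturbation ", format(max_pert, digits = 3))
    Sigma <- fixed
    repaired <- TRUE
  }
  structure(list(z = z, Sigma = Sigma, repaired = repaired,
                 max_perturbation = max_pert),
            class = "latent_gaussian_model")
}

#' @export
print.latent_gaussian_model <- function(x, ...) {
  cat("Latent Gaussian dichotomization model, n =", length(x$z), "\n")
  cat("thresholds z:", format(x$z, digits = 4), "\n")
  cat("Sigma:\n"); print(round(x$Sigma, 4))
  if (x$repaired)
    cat("note: Sigma repaired (max perturbation ",
        format(x$max_perturbation, digits = 3), ")\n", sep = "")
  invisible(x)
}

# symmetric matrix square root tolerant of PSD-singular Sigma
matrix_sqrt <- function(Sigma) {
  e <- eigen(Sigma, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}
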