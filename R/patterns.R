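# pattern distribution and read sampling under the correlated Bernoulli model

#' Joint distribution of the methylation pattern
#'
#' Computes the probabilities `q_0, ..., q_{2^n - 1}` of the `2^n`
#' methylation patterns of an n-CpG segment under a correlated Bernoulli
#' model.  Pattern index `i`, written in binary with the *last* CpG site
#' as least-significant bit, identifies the pattern (so `q_1` is
#' `[0, ..., 0, 1]`; see [pattern_matrix()]).
#'
#' The computation picks the cheapest exact route available: the product
#' form for independent sites; the closed bivariate form for `n = 2`
#' (`P11 = r sqrt(p_1 q_1 p_2 q_2) + p_1 p_2`); an exact one-dimensional
#' Gaussian integral when the latent correlation matrix is compound
#' symmetric (the exchangeable case); and otherwise inclusion-exclusion
#' over multivariate-normal CDF evaluations on the latent model of
#' [build_latent_model()].  Sites with degenerate `p_i` (0 or 1) are held
#' constant and excluded from the latent construction.  The result is
#' renormalized after computation; a deviation of the raw sum from 1
#' beyond 1e-6 is an error.
#'
#' @param params a [bernoulli_params()] object.
#' @param method `"auto"` (default) selects the route as described;
#'   `"mvn"` forces the general inclusion-exclusion route (useful for
#'   cross-checking; requires a non-singular latent correlation matrix).
#' @return an object of class `"pattern_distribution"`: list with
#'   elements `n` and `q` (named numeric vector of length `2^n`).
#' @examples
#' pattern_distribution(bernoulli_params(c(0.3, 0.6)))
#' pattern_distribution(bernoulli_params(0.5, n = 2, structure = "exchangeable", r = 0.5))
#' @export
pattern_distribution <- function(params, method = c("auto", "mvn")) {
  stopifnot(inherits(params, "bernoulli_params"))
  method <- match.arg(method)
  n <- params$n; p <- params$p
  deg <- p <= 0 | p >= 1
  keep <- which(!deg)
  k <- length(keep)

  if (k == 0L) {
    qk <- 1
  } else {
    sub <- structure(list(n = k, p = p[keep],
                          R = params$R[keep, keep, drop = FALSE]),
                     class = "bernoulli_params")
    qk <- pattern_kernel(sub, method)
  }

  B <- pattern_matrix(n)
  if (k == n) {
    q <- qk
  } else {
    # expand: patterns inconsistent with the constant sites have probability 0
    fixed <- round(p[deg])
    ok <- rep(TRUE, 2^n)
    dsites <- which(deg)
    for (a in seq_along(dsites)) ok <- ok & (B[, dsites[a]] == fixed[a])
    q <- numeric(2^n)
    if (k == 0L) {
      q[ok] <- 1
    } else {
      sub_idx <- as.integer(B[ok, keep, drop = FALSE] %*% 2^((k - 1):0))
      q[ok] <- qk[sub_idx + 1L]
    }
  }

  q <- pmax(q, 0)
  tot <- sum(q)
  if (abs(tot - 1) > 1e-6)
    stop("pattern probabilities sum to ", format(tot, digits = 10),
         "; numerical failure in the latent-CDF evaluation")
  q <- q / tot
  names(q) <- rownames(B)
  structure(list(n = n, q = q), class = "pattern_distribution")
}

# distribution kernel for non-degenerate marginals
pattern_kernel <- function(params, method) {
  k <- params$n; p <- params$p; R <- params$R
  off <- R[upper.tri(R)]
  if (method == "auto") {
    if (k == 1L) return(c(1 - p, p))
    if (all(abs(off) < 1e-12)) return(unname(independent_pattern_probs(p)))
    if (k == 2L) {
      p11 <- R[1, 2] * sqrt(prod(p * (1 - p))) + p[1] * p[2]
      return(c(1 - p[1] - p[2] + p11, p[2] - p11, p[1] - p11, p11))
    }
  }
  lat <- build_latent_model(params)
  z <- lat$z; Sigma <- lat$Sigma
  so <- Sigma[upper.tri(Sigma)]
  cs <- length(so) > 0 && all(abs(so - so[1]) < 1e-12) && so[1] >= 0
  if (method == "auto" && cs) {
    if (so[1] >= 1 - 1e-9) return(comonotone_probs(z, k))
    return(cs_pattern_probs(z, so[1], k))
  }
  orthant_probs(z, Sigma, k)
}

# cache of Gauss-Hermite rules (Golub-Welsch), keyed by node count
.gh_cache <- new.env(parent = emptyenv())

# standard-normal quadrature nodes/weights: int f dPhi ~ sum w_i f(x_i)
gauss_hermite_normal <- function(k) {
  key <- as.character(k)
  if (!is.null(.gh_cache[[key]])) return(.gh_cache[[key]])
  i <- seq_len(k - 1L)
  J <- matrix(0, k, k)
  J[cbind(i, i + 1L)] <- J[cbind(i + 1L, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  rule <- list(x = sqrt(2) * e$values, w = e$vectors[1, ]^2)
  .gh_cache[[key]] <- rule
  rule
}

# exchangeable latent correlation: Sigma = (1-rho) I + rho J admits the
# one-factor representation Z_i = sqrt(rho) W + sqrt(1-rho) e_i, reducing
# each pattern probability to a 1-D Gaussian integral.  Evaluated by
# Gauss-Hermite quadrature (node count grown with rho as the integrand
# steepens; absolute accuracy ~1e-7 or better up to rho = 0.975), with
# adaptive quadrature beyond that.
cs_pattern_probs <- function(z, rho, k) {
  B <- pattern_matrix(k)
  sr <- sqrt(rho); sc <- sqrt(1 - rho)
  if (rho <= 0.975) {
    rule <- gauss_hermite_normal(if (rho <= 0.8) 128L else 400L)
    G <- outer(rule$x, z, function(w, zz) pnorm((zz - sr * w) / sc))
    return(vapply(seq_len(2^k), function(i) {
      f <- rule$w
      for (j in seq_len(k)) f <- f * (if (B[i, j] == 1L) G[, j] else 1 - G[, j])
      sum(f)
    }, 0))
  }
  cell <- function(zm, zu) {  # site thresholds of methylated/unmethylated sets
    f <- function(w) {
      g <- dnorm(w)
      for (zz in zm) g <- g * pnorm((zz - sr * w) / sc)
      for (zz in zu) g <- g * pnorm((zz - sr * w) / sc, lower.tail = FALSE)
      g
    }
    integrate(f, -Inf, Inf, rel.tol = 1e-10, abs.tol = 1e-13)$value
  }
  if (length(unique(z)) == 1L) {
    # homogeneous thresholds: probability depends on the methylated count only
    a <- vapply(0:k, function(s) cell(rep(z[1], s), rep(z[1], k - s)), 0)
    return(a[rowSums(B) + 1L])
  }
  vapply(seq_len(2^k), function(i) {
    m <- B[i, ] == 1L
    cell(z[m], z[!m])
  }, 0)
}

# perfect latent correlation: all Z_i equal a single W; site i methylated
# iff W <= z_i, so only "threshold" patterns have positive probability
comonotone_probs <- function(z, k) {
  B <- pattern_matrix(k)
  vapply(seq_len(2^k), function(i) {
    m <- B[i, ] == 1L
    hi <- if (any(m)) pnorm(min(z[m])) else 1
    lo <- if (any(!m)) pnorm(max(z[!m])) else 0
    max(0, hi - lo)
  }, 0)
}

# general route: P(X = b) by inclusion-exclusion over MVN CDF evaluations,
# P = sum over subsets A of the unmethylated set of (-1)^|A| Phi(z_{M u A}).
# Each site subset's CDF is needed by many patterns, so the 2^k subset
# CDFs are evaluated once and combined afterwards.
orthant_probs <- function(z, Sigma, k) {
  B <- pattern_matrix(k)
  bit <- 2^(seq_len(k) - 1L)
  cdf <- numeric(2^k)  # indexed by site-subset bitmask + 1
  cdf[1] <- 1
  for (s in seq_len(2^k - 1L)) {
    idx <- which(bitwAnd(s, bit) > 0)
    cdf[s + 1L] <- mvn_cdf(z[idx], Sigma[idx, idx, drop = FALSE])
  }
  vapply(seq_len(2^k), function(i) {
    M <- which(B[i, ] == 1L)
    U <- which(B[i, ] == 0L)
    mmask <- sum(bit[M])
    nu <- length(U)
    total <- 0
    for (s in 0:(2^nu - 1L)) {
      inA <- bitwAnd(s, 2^(seq_len(nu) - 1L)) > 0
      amask <- sum(bit[U[inA]])
      total <- total + (-1)^sum(inA) * cdf[mmask + amask + 1L]
    }
    total
  }, 0)
}

#' @export
print.pattern_distribution <- function(x, ...) {
  cat("Methylation pattern distribution, n =", x$n, "sites (",
      2^x$n, "patterns )\n")
  print(round(x$q, 6))
  cat("entropy:", format(entropy_bits(x$q), digits = 6), "bits\n")
  invisible(x)
}

#' Sample reads from the correlated Bernoulli methylation model
#'
#' Draws `m` independent reads (rows) from the model by latent-Gaussian
#' thresholding: each row is a multivariate-normal draw under the latent
#' correlation `Sigma`, dichotomized at the thresholds `z_i = qnorm(p_i)`
#' (site methylated when the latent value is below its threshold, so that
#' `P(state = 1) = p_i`).  Degenerate sites are filled with their constant
#' state.  Deterministic given `seed`; the caller's RNG state is left
#' untouched when a seed is supplied.
#'
#' @param params a [bernoulli_params()] object.
#' @param m number of reads (>= 1).
#' @param seed optional integer seed.
#' @return an `m`-by-`n` integer matrix with entries in `{0, 1}`.
#' @examples
#' x <- sample_reads(bernoulli_params(0.5, n = 4, structure = "exchangeable", r = 0.6),
#'                   m = 50, seed = 1)
#' colMeans(x)
#' @export
sample_reads <- function(params, m, seed = NULL) {
  stopifnot(inherits(params, "bernoulli_params"), m >= 1, m == round(m))
  n <- params$n; p <- params$p
  deg <- p <= 0 | p >= 1
  keep <- which(!deg)
  k <- length(keep)
  x <- matrix(0L, nrow = m, ncol = n)
  for (j in which(deg)) x[, j] <- as.integer(round(p[j]))
  if (k > 0L) {
    sub <- structure(list(n = k, p = p[keep],
                          R = params$R[keep, keep, drop = FALSE]),
                     class = "bernoulli_params")
    lat <- build_latent_model(sub)
    A <- matrix_sqrt(lat$Sigma)
    Z <- with_rng(seed, matrix(rnorm(m * k), m, k) %*% A)
    x[, keep] <- (sweep(Z, 2L, lat$z, "<=")) * 1L
  }
  x
}
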