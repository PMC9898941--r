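# internal helpers shared across modules

# cache of pattern matrices, keyed by as.character(n)
.pattern_cache <- new.env(parent = emptyenv())

#' Enumerate the 2^n methylation patterns of an n-CpG segment
#'
#' Returns a `2^n` by `n` 0/1 matrix whose row `i + 1` is the binary
#' expansion of pattern index `i`, with the *last* CpG site as the
#' least-significant bit.  Under this convention pattern index 1 is
#' `[0, ..., 0, 1]` (only the last site methylated), matching the listing
#' order used throughout the package for pattern distributions and
#' observed counts.
#'
#' @param n number of CpG sites (integer >= 1).
#' @return integer matrix of dimension `2^n` by `n`.
#' @examples
#' pattern_matrix(2)
#' @export
pattern_matrix <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1, n == round(n))
  key <- as.character(n)
  if (!is.null(.pattern_cache[[key]])) return(.pattern_cache[[key]])
  idx <- 0:(2^n - 1)
  B <- vapply(seq_len(n), function(j) as.integer((idx %/% 2^(n - j)) %% 2),
              integer(2^n))
  B <- matrix(B, nrow = 2^n, ncol = n)
  rownames(B) <- apply(B, 1L, paste0, collapse = "")
  .pattern_cache[[key]] <- B
  B
}

# map each row of a binary matrix to its pattern index (0-based)
pattern_index <- function(x) {
  n <- ncol(x)
  as.integer(x %*% 2^((n - 1):0))
}

# observed pattern counts O_0 .. O_{2^n - 1}
pattern_counts <- function(x) {
  n <- ncol(x)
  counts <- tabulate(pattern_index(x) + 1L, nbins = 2^n)
  names(counts) <- rownames(pattern_matrix(n))
  counts
}

# product-form pattern probabilities for independent sites (Eq.-2 style):
# q_i = prod_j p_j^{b_ij} (1-p_j)^{1-b_ij}; safe at p_j in {0,1}
independent_pattern_probs <- function(p) {
  n <- length(p)
  B <- pattern_matrix(n)
  q <- rep(1, 2^n)
  for (j in seq_len(n)) q <- q * ifelse(B[, j] == 1L, p[j], 1 - p[j])
  names(q) <- rownames(B)
  q
}

# binary (single-site) Shannon entropy in bits, 0 log 0 := 0
binary_entropy <- function(p) {
  h <- numeric(length(p))
  ok <- p > 0 & p < 1
  h[ok] <- -(p[ok] * log2(p[ok]) + (1 - p[ok]) * log2(1 - p[ok]))
  h
}

# entropy in bits of a probability vector, 0 log 0 := 0
entropy_bits <- function(q) {
  q <- q[q > 0]
  -sum(q * log2(q))
}

# evaluate expr with a temporarily fixed RNG seed (NULL = use current RNG)
with_rng <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# derive a reproducible child seed (< 2^31) from a master seed and index
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 7919) %% 2147483629) + 1L
}

is_binary_matrix <- function(x) {
  is.matrix(x) && is.numeric(x) && all(x %in% c(0, 1))
}

# stable text rendering for TSV output: 6 significant digits
format_num <- function(x) {
  out <- as.character(signif(x, 6L))
  out[is.na(x)] <- "NA"
  out
}
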