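# simulation engines: calibration/power of the spatial test, the
# OME-vs-MML study, and a two-sample synthetic-data generator

#' Configuration for the spatial-test calibration and power study
#'
#' Describes one batch of replicated n-CpG segments for
#' [simulate_type1()] (structure `"independent"`) or [simulate_power()]
#' (structure `"exchangeable"` or `"ar1"` with correlation `r`).  Each
#' replicate draws a fresh per-site methylation-probability vector from
#' `Unif(mp_low, mp_high)` (nonhomogeneous methylation) and samples `m`
#' reads.
#'
#' @param n_values segment sizes to cover.
#' @param m_values sequencing depths to cover.
#' @param structure correlation structure under which reads are drawn.
#' @param r correlation parameter (ignored for `"independent"`).
#' @param replicates number of replicates per (n, m) cell; conventional
#'   choices are 10000 under the null and 1000 under the alternative.
#' @param mp_low,mp_high support of the per-site methylation-probability
#'   draw; the default `Unif(0.3, 0.7)` avoids near-degenerate sites.
#' @param alpha nominal significance level.
#' @param seed master seed; every (n, m) cell derives an independent
#'   child seed from it, so single cells are reproducible in isolation.
#' @return an object of class `"sim1_config"`.
#' @export
sim1_config <- function(n_values = c(2, 3, 4),
                        m_values = c(20, 40, 60, 80, 100),
                        structure = c("independent", "exchangeable", "ar1"),
                        r = NA_real_,
                        replicates = 10000,
                        mp_low = 0.3, mp_high = 0.7,
                        alpha = 0.05, seed = NULL) {
  structure <- match.arg(structure)
  stopifnot(replicates >= 1, mp_low < mp_high, mp_low > 0, mp_high < 1,
            alpha > 0, alpha <= 1)
  if (structure != "independent") stopifnot(is.finite(r), r >= 0, r <= 1)
  structure(list(n_values = n_values, m_values = m_values,
                 structure = structure, r = r, replicates = replicates,
                 mp_low = mp_low, mp_high = mp_high, alpha = alpha,
                 seed = seed),
            class = "sim1_config")
}

#' Empirical type-I error of the spatial-correlation test
#'
#' For every (n, m) cell: repeatedly draw per-site methylation
#' probabilities from `Unif(mp_low, mp_high)`, sample `m` reads with
#' independent sites, run [chi_square_spatial_test()], and record
#' rejections at level `alpha`.  Untestable replicates (fewer than two
#' non-degenerate sites) count as non-rejections.  Deterministic given
#' the config seed.
#'
#' @param config a [sim1_config()] with structure `"independent"`.
#' @return data frame with columns `n`, `m`, `replicates`, `rejections`,
#'   `type1`; the config is attached as attribute `"config"`.
#' @export
simulate_type1 <- function(config = sim1_config()) {
  stopifnot(inherits(config, "sim1_config"),
            config$structure == "independent")
  run_sim1(config, power = FALSE)
}

#' Empirical power of the spatial-correlation test
#'
#' As [simulate_type1()], but reads are drawn from the correlated
#' Bernoulli model via [sample_reads()] (latent-Gaussian thresholding)
#' under the configured exchangeable or AR(1) structure.  Methylation
#' probability vectors for which the configured `r` is infeasible are
#' redrawn (up to 100 times; the redraw count is attached as attribute
#' `"redraws"`).
#'
#' @param config a [sim1_config()] with structure `"exchangeable"` or
#'   `"ar1"` and a finite `r`.
#' @return data frame with columns `structure`, `r`, `n`, `m`,
#'   `replicates`, `rejections`, `power`.
#' @export
simulate_power <- function(config) {
  stopifnot(inherits(config, "sim1_config"),
            config$structure %in% c("exchangeable", "ar1"))
  run_sim1(config, power = TRUE)
}

run_sim1 <- function(config, power) {
  cells <- expand.grid(m = config$m_values, n = config$n_values)
  redraws_total <- 0L
  res <- lapply(seq_len(nrow(cells)), function(ci) {
    n <- cells$n[ci]; m <- cells$m[ci]
    seed <- if (is.null(config$seed)) NULL else child_seed(config$seed, ci)
    rej <- with_rng(seed, {
      count <- 0L
      for (rep in seq_len(config$replicates)) {
        if (!power) {
          p <- runif(n, config$mp_low, config$mp_high)
          x <- matrix(rbinom(m * n, 1L, rep(p, each = m)), m, n)
        } else {
          params <- NULL
          for (try in 1:100) {
            p <- runif(n, config$mp_low, config$mp_high)
            params <- tryCatch(
              bernoulli_params(p, n = n, structure = config$structure,
                               r = config$r),
              error = function(e) NULL)
            if (!is.null(params)) break
            redraws_total <<- redraws_total + 1L
          }
          if (is.null(params))
            stop("could not draw a feasible methylation-probability vector ",
                 "after 100 attempts (r = ", config$r, ")")
          x <- sample_reads(params, m)
        }
        pv <- chisq_core(x)$p.value
        if (!is.na(pv) && pv < config$alpha) count <- count + 1L
      }
      count
    })
    data.frame(n = n, m = m, replicates = config$replicates,
               rejections = rej, rate = rej / config$replicates)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$n, out$m), , drop = FALSE]
  rownames(out) <- NULL
  if (power) {
    out <- cbind(structure = config$structure, r = config$r, out)
    names(out)[names(out) == "rate"] <- "power"
  } else {
    names(out)[names(out) == "rate"] <- "type1"
  }
  attr(out, "config") <- config
  if (power) attr(out, "redraws") <- redraws_total
  out
}

#' Configuration for the OME-versus-MML study
#'
#' Describes a population of hypothetical n-CpG segments with
#' homogeneous methylation and exchangeable spatial correlation: each
#' segment draws `p` from `p_dist` and `r` from `r_dist`, except for a
#' fraction `frac_null` of segments with no spatial correlation
#' (`r = 0`).  Reads are sampled independently at each depth in
#' `m_values`.
#'
#' @param n_segments number of segments.
#' @param n segment size.
#' @param frac_null fraction of segments with `r = 0`.
#' @param m_values sequencing depths.
#' @param p_range,r_range supports of the uniform draws for `p` and `r`.
#' @param alpha significance level for the spatial test.
#' @param seed master seed.
#' @return an object of class `"sim2_config"`.
#' @export
sim2_config <- function(n_segments = 500, n = 4, frac_null = 0.1,
                        m_values = c(20, 40, 60, 80, 100),
                        p_range = c(0, 1), r_range = c(0, 1),
                        alpha = 0.05, seed = NULL) {
  stopifnot(n_segments >= 1, frac_null >= 0, frac_null <= 1,
            n >= 2, alpha > 0, alpha <= 1)
  structure(list(n_segments = n_segments, n = n, frac_null = frac_null,
                 m_values = m_values, p_range = p_range, r_range = r_range,
                 alpha = alpha, seed = seed),
            class = "sim2_config")
}

#' Empirical relation between OME and MML over simulated segments
#'
#' Draws the segment population of a [sim2_config()], samples reads at
#' each depth, and records per (segment, depth): the true `p` and `r`,
#' the null flag, MML, OME, and the spatial-test p-value.  Segments that
#' are untestable at a given depth (fewer than two non-degenerate sites,
#' which happens for `p` near 0 or 1 at low depth) are reported as
#' non-significant.  A per-depth detection summary — how many truly
#' correlated and how many null segments are significant at `alpha` —
#' is attached as attribute `"detection"`.
#'
#' @param config a [sim2_config()].
#' @return data frame with columns `segment`, `p`, `r`, `null`, `m`,
#'   `mml`, `ome`, `p_value`, `significant`.
#' @export
simulate_ome_mml <- function(config = sim2_config()) {
  stopifnot(inherits(config, "sim2_config"))
  G <- config$n_segments
  n_null <- round(config$frac_null * G)
  seed0 <- if (is.null(config$seed)) NULL else child_seed(config$seed, 0L)
  pars <- with_rng(seed0, {
    data.frame(segment = seq_len(G),
               p = runif(G, config$p_range[1], config$p_range[2]),
               r = runif(G, config$r_range[1], config$r_range[2]),
               null = seq_len(G) <= n_null)
  })
  pars$r[pars$null] <- 0

  rows <- vector("list", G)
  for (g in seq_len(G)) {
    params <- bernoulli_params(pars$p[g], n = config$n,
                               structure = if (pars$r[g] == 0) "independent"
                                           else "exchangeable",
                               r = pars$r[g])
    seed_g <- if (is.null(config$seed)) NULL else child_seed(config$seed, g)
    rows[[g]] <- with_rng(seed_g, {
      do.call(rbind, lapply(config$m_values, function(m) {
        x <- sample_reads(params, m)
        lev <- methylation_levels(x)
        pv <- chisq_core(x)$p.value
        data.frame(segment = g, p = pars$p[g], r = pars$r[g],
                   null = pars$null[g], m = m, mml = lev$mml,
                   ome = observed_me(x), p_value = pv,
                   significant = !is.na(pv) && pv < config$alpha)
      }))
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  detection <- do.call(rbind, lapply(config$m_values, function(m) {
    sub <- out[out$m == m, ]
    data.frame(m = m,
               significant_correlated = sum(sub$significant & !sub$null),
               n_correlated = sum(!sub$null),
               significant_null = sum(sub$significant & sub$null),
               n_null = sum(sub$null))
  }))
  attr(out, "detection") <- detection
  attr(out, "config") <- config
  out
}

#' Synthetic two-sample per-read methylation calls
#'
#' Generates paired per-read call sets emulating a two-cell-type
#' experiment (e.g. neuron and glia) with planted bipolar/DMR structure:
#' in planted segments sample A is strongly methylated
#' (homogeneous `p_high`, exchangeable `r_within`) while sample B is
#' strongly unmethylated (`p_low`), so their pooled reads concentrate on
#' the all-methylated and all-unmethylated patterns (a bipolar locus)
#' and the two samples differ in methylation level (a DMR).  Background
#' segments use independent sites at `p = 0.5` in both samples.  Every
#' read covers all `n_sites` of its segment; segments are spaced widely
#' enough that no sliding window straddles two of them.
#'
#' @param n_segments total segments on the synthetic chromosome.
#' @param n_planted number of planted bipolar/DMR segments (the first
#'   `n_planted` segments).
#' @param n_sites CpG sites per segment.
#' @param m reads per segment per sample.
#' @param p_high,p_low homogeneous methylation probabilities of the
#'   planted segments in samples A and B.
#' @param r_within exchangeable within-sample correlation of planted
#'   segments.
#' @param seed optional seed.
#' @return list with elements `sample_a` and `sample_b` (`"meth_reads"`
#'   objects), and `truth`: a data frame with `chrom`, `start`, `end`
#'   and the `planted` flag per segment.
#' @export
simulate_two_sample_calls <- function(n_segments = 30, n_planted = 10,
                                      n_sites = 4, m = 100,
                                      p_high = 0.9, p_low = 0.1,
                                      r_within = 0.8, seed = NULL) {
  stopifnot(n_planted <= n_segments)
  site_template <- seq(0L, by = 30L, length.out = n_sites)
  make_sample <- function(tag, p_planted, seed) {
    recs <- with_rng(seed, {
      lapply(seq_len(n_segments), function(g) {
        planted <- g <= n_planted
        params <- if (planted) {
          bernoulli_params(p_planted, n = n_sites,
                           structure = "exchangeable", r = r_within)
        } else {
          bernoulli_params(0.5, n = n_sites)
        }
        x <- sample_reads(params, m)
        sites <- 10000L * g + site_template  # 0-based
        list(sites = sites, x = x, g = g)
      })
    })
    out <- data.frame(
      read_id = unlist(lapply(recs, function(r)
        sprintf("%s_seg%03d_r%03d", tag, r$g, seq_len(m)))),
      chrom = "chrS",
      stringsAsFactors = FALSE)
    out$sites <- unlist(lapply(recs, function(r)
      replicate(m, r$sites, simplify = FALSE)), recursive = FALSE)
    out$states <- unlist(lapply(recs, function(r)
      lapply(seq_len(m), function(i) as.integer(r$x[i, ]))),
      recursive = FALSE)
    class(out) <- c("meth_reads", "data.frame")
    out
  }
  seed_a <- if (is.null(seed)) NULL else child_seed(seed, 1L)
  seed_b <- if (is.null(seed)) NULL else child_seed(seed, 2L)
  truth <- data.frame(
    chrom = "chrS",
    start = 10000L * seq_len(n_segments) + site_template[1],
    end = 10000L * seq_len(n_segments) + site_template[n_sites] + 2L,
    planted = seq_len(n_segments) <= n_planted)
  list(sample_a = make_sample("a", p_high, seed_a),
       sample_b = make_sample("b", p_low, seed_b),
       truth = truth)
}

#' Write per-read methylation calls
#'
#' Serializes a `"meth_reads"` object in the package's per-read TSV
#' dialect (1-based positions); the inverse of
#' [read_methylation_calls()].
#'
#' @param records a `"meth_reads"` object.
#' @param path output path.
#' @export
write_methylation_calls <- function(records, path) {
  stopifnot(inherits(records, "meth_reads"))
  lines <- vapply(seq_len(nrow(records)), function(i) {
    paste(records$read_id[i], records$chrom[i],
          paste(records$sites[[i]] + 1L, collapse = ","),
          paste(records$states[[i]], collapse = ""),
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
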