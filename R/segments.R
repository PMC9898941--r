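# per-read methylation call ingestion, segment extraction, and writers
#
# Input dialect ("epiread-like" TSV), one read per line, 4 tab-separated
# columns:
#   read_id  chrom  positions  states
# where positions is a comma-separated strictly ascending list of 1-based
# CpG cytosine positions (forward strand) and states is a same-length
# string over {0,1}.  Lines starting with '#' are comments.  Coordinates
# are converted to 0-based internally; BED output is 0-based half-open
# and spans the CpG dinucleotides (first cytosine to last G).

#' Read per-read methylation calls
#'
#' Parses the package's per-read TSV dialect (see the format description
#' in the package vignette): columns `read_id`, `chrom`, `positions`
#' (comma-separated ascending 1-based CpG positions) and `states`
#' (same-length string over `{0,1}`).  Malformed lines raise an error
#' naming the line number; positions are converted to 0-based.
#'
#' @param path path to the calls file.
#' @return an object of class `"meth_reads"`: a data frame with columns
#'   `read_id`, `chrom` and list-columns `sites` (0-based integer
#'   vectors) and `states` (integer vectors).
#' @export
read_methylation_calls <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  rec <- vector("list", length(keep))
  for (ii in seq_along(keep)) {
    ln <- keep[ii]
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 4L)
      stop("line ", ln, ": expected 4 tab-separated fields, got ",
           length(fields))
    pos_chr <- strsplit(fields[3], ",", fixed = TRUE)[[1]]
    pos <- suppressWarnings(as.integer(pos_chr))
    if (anyNA(pos) || length(pos) == 0L)
      stop("line ", ln, ": unparsable positions field '", fields[3], "'")
    if (any(diff(pos) <= 0))
      stop("line ", ln, ": positions must be strictly ascending")
    if (any(pos < 1L))
      stop("line ", ln, ": positions are 1-based and must be >= 1")
    st_chr <- strsplit(fields[4], "", fixed = TRUE)[[1]]
    if (length(st_chr) != length(pos))
      stop("line ", ln, ": states string length (", length(st_chr),
           ") does not match number of positions (", length(pos), ")")
    if (!all(st_chr %in% c("0", "1")))
      stop("line ", ln, ": non-binary methylation state character in '",
           fields[4], "'")
    rec[[ii]] <- list(read_id = fields[1], chrom = fields[2],
                      sites = pos - 1L, states = as.integer(st_chr))
  }
  out <- data.frame(
    read_id = vapply(rec, `[[`, "", "read_id"),
    chrom = vapply(rec, `[[`, "", "chrom"),
    stringsAsFactors = FALSE
  )
  out$sites <- lapply(rec, `[[`, "sites")
  out$states <- lapply(rec, `[[`, "states")
  class(out) <- c("meth_reads", "data.frame")
  out
}

#' Extract deeply covered n-CpG segments
#'
#' Slides a window of `n` consecutive distinct CpG coordinates along each
#' chromosome (step 1 in `"sliding"` mode, step `n` in `"disjoint"`
#' mode), collects the reads whose covered sites include all `n` window
#' coordinates, and emits the window as a segment when at least
#' `min_depth` such reads exist.  Reads only partially covering a window
#' are excluded from it (no imputation).  Output order is deterministic:
#' by chromosome name, then window start.
#'
#' @param records a `"meth_reads"` object from [read_methylation_calls()].
#' @param n segment size (number of CpG sites per window).
#' @param min_depth minimum number of fully covering reads.
#' @param mode `"sliding"` (default, every window) or `"disjoint"`
#'   (non-overlapping windows).
#' @return list of `"meth_segment"` objects, each a list with elements
#'   `chrom`, `sites` (0-based coordinates, length `n`), `x` (the
#'   `m`-by-`n` read matrix) and `m`.
#' @export
extract_segments <- function(records, n = 4, min_depth = 20,
                             mode = c("sliding", "disjoint")) {
  stopifnot(inherits(records, "meth_reads"), n >= 1, min_depth >= 1)
  mode <- match.arg(mode)
  segments <- list()
  for (chrom in sort(unique(records$chrom))) {
    idx <- which(records$chrom == chrom)
    all_sites <- sort(unique(unlist(records$sites[idx])))
    C <- length(all_sites)
    if (C < n) next
    # reads-by-sites state matrix, NA where a read does not cover a site
    cover <- matrix(NA_integer_, nrow = length(idx), ncol = C)
    for (a in seq_along(idx)) {
      pos <- match(records$sites[[idx[a]]], all_sites)
      cover[a, pos] <- records$states[[idx[a]]]
    }
    starts <- if (mode == "sliding") seq_len(C - n + 1L)
              else seq.int(1L, C - n + 1L, by = n)
    for (s in starts) {
      cols <- s:(s + n - 1L)
      block <- cover[, cols, drop = FALSE]
      full <- which(rowSums(is.na(block)) == 0L)
      if (length(full) >= min_depth) {
        segments[[length(segments) + 1L]] <- structure(
          list(chrom = chrom, sites = all_sites[cols],
               x = block[full, , drop = FALSE], m = length(full)),
          class = "meth_segment")
      }
    }
  }
  segments
}

#' Per-segment summary statistics
#'
#' Composes the statistic-side quantities of one segment into a one-row
#' data frame: per-site methylation levels, MML, OME, the spatial
#' chi-square test, the entropy threshold (the theoretical entropy at the
#' segment's MML under exchangeable correlation `r_threshold`), and the
#' bipolar flag from [classify_bipolar()].  Coordinates are 0-based
#' half-open and span the CpG dinucleotides (`start` = first cytosine,
#' `end` = last cytosine + 2).
#'
#' @param segment a `"meth_segment"` object (or a list with elements
#'   `chrom`, `sites`, `x`, `m`).
#' @param r_threshold exchangeable correlation defining the bipolar
#'   entropy threshold curve.
#' @param mml_window open MML interval `(low, high)` for the bipolar
#'   flag.
#' @return one-row data frame with columns `chrom`, `start`, `end`,
#'   `n_sites`, `m`, `site_ml` (comma-joined), `mml`, `ome`,
#'   `entropy_threshold`, `r_threshold`, `chisq_stat`, `chisq_df`,
#'   `chisq_p`, `testable`, `bipolar`.
#' @export
segment_statistics <- function(segment, r_threshold = 0.6,
                               mml_window = c(0.2, 0.8)) {
  x <- segment$x
  n <- ncol(x)
  lev <- methylation_levels(x)
  ome <- observed_me(x)
  gof <- chi_square_spatial_test(x)
  crit <- bipolar_criteria(mml_low = mml_window[1], mml_high = mml_window[2],
                           r_threshold = r_threshold, n = n)
  thr <- me_exchangeable(n, lev$mml, r_threshold)
  flag <- classify_bipolar(data.frame(mml = lev$mml, ome = ome), crit)
  data.frame(
    chrom = segment$chrom,
    start = segment$sites[1],
    end = segment$sites[n] + 2L,
    n_sites = n,
    m = segment$m,
    site_ml = paste(format_num(lev$ml), collapse = ","),
    mml = lev$mml,
    ome = ome,
    entropy_threshold = thr,
    r_threshold = r_threshold,
    chisq_stat = gof$statistic,
    chisq_df = ifelse(gof$testable, gof$df, NA_integer_),
    chisq_p = gof$p.value,
    testable = gof$testable,
    bipolar = flag,
    stringsAsFactors = FALSE
  )
}

#' Summarize a list of segments into a statistics table
#'
#' @param segments list of `"meth_segment"` objects from
#'   [extract_segments()].
#' @inheritParams segment_statistics
#' @return data frame with one row per segment (zero-row with the full
#'   column set for an empty list).
#' @export
segment_stats_table <- function(segments, r_threshold = 0.6,
                                mml_window = c(0.2, 0.8)) {
  if (length(segments) == 0L) {
    return(data.frame(
      chrom = character(), start = integer(), end = integer(),
      n_sites = integer(), m = integer(), site_ml = character(),
      mml = numeric(), ome = numeric(), entropy_threshold = numeric(),
      r_threshold = numeric(), chisq_stat = numeric(),
      chisq_df = integer(), chisq_p = numeric(), testable = logical(),
      bipolar = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(segments, segment_statistics,
                        r_threshold = r_threshold, mml_window = mml_window))
}

segment_stats_columns <- c(
  "chrom", "start", "end", "n_sites", "m", "site_ml", "mml", "ome",
  "entropy_threshold", "r_threshold", "chisq_stat", "chisq_df",
  "chisq_p", "testable", "bipolar")

#' Write and read segment statistics tables
#'
#' `write_segment_stats()` writes the statistics table as TSV with a
#' fixed column order and stable float formatting (6 significant
#' digits), so identical input yields byte-identical output.
#' `read_segment_stats()` reads such a file back.
#'
#' @param stats data frame from [segment_stats_table()].
#' @param path output (input) file path.
#' @return `write_segment_stats()` returns `path` invisibly;
#'   `read_segment_stats()` returns the data frame.
#' @export
write_segment_stats <- function(stats, path) {
  stopifnot(all(segment_stats_columns %in% names(stats)))
  out <- stats[, segment_stats_columns, drop = FALSE]
  for (col in c("mml", "ome", "entropy_threshold", "r_threshold",
                "chisq_stat", "chisq_p")) {
    out[[col]] <- format_num(out[[col]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' @rdname write_segment_stats
#' @export
read_segment_stats <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             colClasses = c(
               chrom = "character", start = "integer", end = "integer",
               n_sites = "integer", m = "integer", site_ml = "character",
               mml = "numeric", ome = "numeric",
               entropy_threshold = "numeric", r_threshold = "numeric",
               chisq_stat = "numeric", chisq_df = "integer",
               chisq_p = "numeric", testable = "logical",
               bipolar = "logical"))
}

#' Write bipolar loci as BED6
#'
#' Emits the bipolar-flagged segments as a BED6 file (0-based half-open
#' coordinates, name `"bipolar"`, score `round(1000 (1 - OME / n))`
#' clamped to `[0, 1000]` so that lower-entropy loci score higher,
#' strand `"."`).
#'
#' @inheritParams write_segment_stats
#' @export
write_bipolar_bed <- function(stats, path) {
  bip <- stats[stats$bipolar %in% TRUE, , drop = FALSE]
  score <- if (nrow(bip)) {
    pmin(1000L, pmax(0L, as.integer(round(1000 * (1 - bip$ome / bip$n_sites)))))
  } else integer()
  bed <- data.frame(chrom = bip$chrom, start = bip$start, end = bip$end,
                    name = rep("bipolar", nrow(bip)), score = score,
                    strand = rep(".", nrow(bip)), stringsAsFactors = FALSE)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
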