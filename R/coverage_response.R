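#' Quartile-trimmed (Q2Q3) mean coverage of a genome
#'
#' Mean per-base coverage after discarding the lowest and highest
#' quartiles of positions (`floor(n/4)` positions per tail), robust to
#' highly conserved genes (inflated coverage) and genomic islands
#' (depressed coverage). Ties are broken by position index, so the
#' result is deterministic and invariant to permutation of positions.
#'
#' @param per_base_coverage Numeric vector of non-negative per-position
#'   coverages, length >= 4.
#' @return Trimmed mean coverage.
#' @examples
#' q2q3_mean_coverage(0:7)  # mean(2,3,4,5) = 3.5
#' @export
q2q3_mean_coverage <- function(per_base_coverage) {
  n <- length(per_base_coverage)
  if (n < 4) stop("need at least 4 positions for Q2Q3 trimming")
  if (any(per_base_coverage < 0) || any(!is.finite(per_base_coverage)))
    stop("coverage must be finite and non-negative")
  k <- n %/% 4
  xs <- sort(per_base_coverage)   # stable; ties keep position order
  mean(xs[(k + 1):(n - k)])
}

#' Depth-normalize and log-transform a coverage value
#'
#' Coverage per million library reads, then `log10(x + 1)`.
#'
#' @param q2q3_mean Trimmed mean coverage.
#' @param library_reads Total reads in the sample's library.
#' @param pseudocount Added before the log (default 1).
#' @return Log-scale normalized coverage.
#' @export
normalize_coverage <- function(q2q3_mean, library_reads, pseudocount = 1) {
  stopifnot(all(library_reads > 0), all(q2q3_mean >= 0))
  log10(q2q3_mean / (library_reads / 1e6) + pseudocount)
}

#' One-sided two-sample rank-sum p-value
#'
#' Tests whether `x` tends to exceed `y`. For tie-free groups of at most
#' 8 the exact Wilcoxon null (stats::pwilcox) is used; with ties and
#' small groups the permutation null is enumerated over all group
#' assignments using midranks; larger groups use the normal approximation
#' with continuity correction.
#'
#' @param x,y Numeric samples (amended and baseline groups).
#' @return One-sided p-value for `x > y` in distribution.
#' @export
rank_sum_p <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  has_ties <- anyDuplicated(pooled) > 0
  if (m <= 8 && n <= 8) {
    if (!has_ties) {
      u <- sum(rank(pooled)[seq_len(m)]) - m * (m + 1) / 2
      # P(U >= u) under the exact null
      return(stats::pwilcox(u - 1, m, n, lower.tail = FALSE))
    }
    r <- rank(pooled)   # midranks
    w_obs <- sum(r[seq_len(m)])
    combs <- utils::combn(m + n, m)
    w_all <- apply(combs, 2, function(i) sum(r[i]))
    return(mean(w_all >= w_obs - 1e-12))
  }
  stats::wilcox.test(x, y, alternative = "greater", exact = FALSE,
                     correct = TRUE)$p.value
}

#' Coverage response of MAGs to substrate amendment
#'
#' For each MAG, normalizes trimmed mean coverages to sequencing depth,
#' log-transforms them, and tests whether coverage in amended samples
#' exceeds that in unamended baseline (t0) samples with a one-sided
#' rank-sum test. A MAG is called enriched when p < `alpha` and the
#' amended median exceeds the t0 median.
#'
#' @param coverage Data frame with columns `mag_id`, `sample_id`,
#'   `group` (`"amended"` or `"t0"`), `q2q3_mean`, `library_reads`.
#' @param alpha Significance level (default 0.05).
#' @param pseudocount Pseudocount of [normalize_coverage()].
#' @return Data frame with one row per MAG: medians of normalized
#'   coverage per group, `p_value`, `enriched`, and `untestable` when a
#'   group has fewer than 2 samples.
#' @export
normalize_and_test <- function(coverage, alpha = 0.05, pseudocount = 1) {
  need <- c("mag_id", "sample_id", "group", "q2q3_mean", "library_reads")
  miss <- setdiff(need, names(coverage))
  if (length(miss))
    stop("coverage table missing column(s): ", paste(miss, collapse = ", "))
  if (!all(coverage$group %in% c("amended", "t0")))
    stop("group must be 'amended' or 't0'")
  coverage$norm <- normalize_coverage(coverage$q2q3_mean,
                                      coverage$library_reads, pseudocount)
  out <- do.call(rbind, lapply(split(coverage, coverage$mag_id),
                               function(d) {
    a <- d$norm[d$group == "amended"]
    b <- d$norm[d$group == "t0"]
    if (length(a) < 2 || length(b) < 2) {
      return(data.frame(mag_id = d$mag_id[1],
                        median_amended = stats::median(a),
                        median_t0 = stats::median(b),
                        p_value = NA_real_, enriched = NA,
                        untestable = TRUE))
    }
    p <- rank_sum_p(a, b)
    data.frame(mag_id = d$mag_id[1],
               median_amended = stats::median(a),
               median_t0 = stats::median(b),
               p_value = p,
               enriched = p < alpha &&
                 stats::median(a) > stats::median(b),
               untestable = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Fraction of cells carrying a gene, from metagenomic read hits
#'
#' Under the assumptions that the gene is single-copy, each read maps to
#' one gene copy, and a universal single-copy gene of the same length
#' would make up `benchmark_fraction` of the metagenome, the fraction of
#' cells carrying the gene is the gene's read fraction divided by the
#' benchmark fraction.
#'
#' @param gene_hits Reads hitting the gene.
#' @param total_reads Total metagenome reads.
#' @param benchmark_fraction Read fraction a universal single-copy gene
#'   would occupy (default 0.001, i.e. 0.1%, a conservative 16S-like
#'   benchmark).
#' @return Estimated fraction of cells carrying the gene.
#' @examples
#' gene_cell_fraction(248, 31e6)  # ~0.008 of cells
#' @export
gene_cell_fraction <- function(gene_hits, total_reads,
                               benchmark_fraction = 0.001) {
  stopifnot(total_reads > 0, benchmark_fraction > 0,
            benchmark_fraction < 1, gene_hits >= 0)
  if (any(gene_hits > total_reads))
    stop("gene_hits cannot exceed total_reads")
  (gene_hits / total_reads) / benchmark_fraction
}
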