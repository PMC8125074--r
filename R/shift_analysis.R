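#' Analysis settings for the density-shift statistic
#'
#' @param shift_threshold Minimum labeled-minus-control weighted-mean
#'   density difference (g/ml) called significant. Default 0.005 g/ml,
#'   which corresponds to roughly 9 atom percent excess across the marine
#'   GC range (see [excess_atom_fraction()]).
#' @param ks_alpha Significance level of the Kolmogorov-Smirnov normality
#'   filter applied to each OTU's density distribution in both gradients.
#' @param min_total_reads OTUs with fewer total reads than this, summed
#'   over all fractions of both gradients, are removed.
#' @param top_n Number of most abundant OTUs retained per gradient pair.
#' @param dna_floor Fractions with less DNA than this (ng) are excluded
#'   from distributions (kept in files).
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(shift_threshold = 0.005, ks_alpha = 0.05,
                            min_total_reads = 10, top_n = 200,
                            dna_floor = 0.1) {
  stopifnot(shift_threshold > 0, ks_alpha > 0, min_total_reads > 0,
            top_n > 0, dna_floor >= 0)
  structure(list(shift_threshold = shift_threshold, ks_alpha = ks_alpha,
                 min_total_reads = min_total_reads, top_n = top_n,
                 dna_floor = dna_floor),
            class = "analysis_config")
}

# Indices of fractions usable for distributions: measurable DNA.
.analyzed_idx <- function(profile, dna_floor) {
  which(profile$fractions$dna_ng >= dna_floor & profile$fractions$dna_ng > 0)
}

#' Per-OTU normalized density distribution
#'
#' For each analyzed fraction f the OTU's DNA mass is estimated as its
#' relative read abundance in that fraction times the fraction's total
#' DNA, and the resulting masses are normalized to sum to 1 over the
#' gradient:
#' \deqn{mass_f = \frac{count_{otu,f}}{\sum_j count_{j,f}}\; dna_f,
#'       \qquad p_f = mass_f / \sum_f mass_f.}
#' Fractions below the DNA floor are excluded.
#'
#' @param profile A [gradient_profile()].
#' @param otu_id OTU column name.
#' @param dna_floor Minimum DNA mass (ng) for a fraction to be analyzed.
#' @return Object of class `otu_density_distribution` with fields
#'   `otu_id`, `densities`, `weights`, `total_reads` — or `NULL` when the
#'   OTU is absent (no reads in any analyzed fraction).
#' @export
build_distribution <- function(profile, otu_id, dna_floor = 0.1) {
  if (!(otu_id %in% colnames(profile$counts)))
    stop("OTU '", otu_id, "' not present in profile ", profile$sample_id)
  idx <- .analyzed_idx(profile, dna_floor)
  if (!length(idx)) return(NULL)
  cnt <- profile$counts[idx, otu_id]
  tot <- rowSums(profile$counts[idx, , drop = FALSE])
  dna <- profile$fractions$dna_ng[idx]
  mass <- ifelse(tot > 0, cnt / tot, 0) * dna
  if (sum(mass) <= 0) return(NULL)   # "absent" outcome
  structure(list(otu_id = otu_id,
                 densities = profile$fractions$density[idx],
                 weights = unname(mass / sum(mass)),
                 total_reads = sum(cnt)),
            class = "otu_density_distribution")
}

#' Weighted-mean buoyant density of an OTU distribution
#'
#' @param dist An `otu_density_distribution`.
#' @return \eqn{WM = \sum_f \rho_f p_f} in g/ml.
#' @export
weighted_mean_density <- function(dist) {
  stopifnot(inherits(dist, "otu_density_distribution"))
  sum(dist$densities * dist$weights)
}

.weighted_sd <- function(dist) {
  wm <- weighted_mean_density(dist)
  sqrt(sum(dist$weights * (dist$densities - wm)^2))
}

#' Asymptotic Kolmogorov survival function
#'
#' \eqn{Q(\lambda) = 2\sum_{k\ge 1} (-1)^{k-1} e^{-2k^2\lambda^2}},
#' the limiting p-value of the KS statistic at \eqn{\lambda = \sqrt{n} D}.
#'
#' @param lambda Non-negative scaled statistic.
#' @return P-value in \[0, 1\].
#' @export
kolmogorov_pvalue <- function(lambda) {
  vapply(lambda, function(l) {
    if (!is.finite(l)) return(NA_real_)
    if (l < 0.05) return(1)
    k <- seq_len(101)
    p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * l^2))
    min(max(p, 0), 1)
  }, numeric(1))
}

#' Normality filter for an OTU density distribution
#'
#' Spurious OTUs (chimeras, contaminant spikes) tend to show ragged or
#' multimodal density distributions; genuine gradient bands are close to
#' Gaussian. The weighted empirical CDF of the distribution is compared
#' against a normal CDF with the distribution's own weighted mean and SD:
#' D is the largest discrepancy over the fraction densities (both sides
#' of each ECDF step), and the p-value comes from the asymptotic
#' Kolmogorov distribution with effective n equal to the number of
#' fractions carrying weight.
#'
#' @param dist An `otu_density_distribution`.
#' @return The KS p-value, or `NA` when fewer than 4 fractions carry
#'   weight (an "untestable" distribution, which fails the filter).
#' @export
ks_normality <- function(dist) {
  stopifnot(inherits(dist, "otu_density_distribution"))
  n_eff <- sum(dist$weights > 0)
  if (n_eff < 4) return(NA_real_)
  sdw <- .weighted_sd(dist)
  if (sdw <= 0) return(NA_real_)
  wm <- weighted_mean_density(dist)
  ecdf_hi <- cumsum(dist$weights)
  ecdf_lo <- c(0, ecdf_hi[-length(ecdf_hi)])
  phi <- stats::pnorm(dist$densities, mean = wm, sd = sdw)
  d <- max(abs(ecdf_hi - phi), abs(ecdf_lo - phi))
  kolmogorov_pvalue(sqrt(n_eff) * d)
}

#' Paired labeled/control density-shift analysis
#'
#' The core Tag-SIP statistic. For every OTU passing the abundance
#' filters, computes the weighted-mean density in the control (12C) and
#' labeled (13C) gradients, their difference `delta_wm`, KS normality
#' p-values in both gradients, a significance call
#' (`delta_wm > shift_threshold` and normality passed in both), and the
#' excess atom fraction implied by the shift.
#'
#' Filters: OTUs with fewer than `min_total_reads` reads summed over both
#' gradients are removed; the remaining OTUs are ranked by their summed
#' per-fraction relative abundance across both gradients (ties broken by
#' OTU id) and the `top_n` most abundant are kept. OTUs absent from
#' either gradient's analyzed fractions are reported with `NA` statistics
#' and `significant = FALSE`.
#'
#' @param labeled 13C [gradient_profile()].
#' @param control 12C [gradient_profile()].
#' @param model A [labeling_model()].
#' @param cfg An [analysis_config()].
#' @param taxonomy Optional named character vector, OTU id -> taxonomy.
#' @return Data frame (class `shift_results`) with one row per analyzed
#'   OTU: `otu_id, taxonomy, ks_p_12C, ks_p_13C, wm_12C, wm_13C,
#'   delta_wm, passed_normality, significant, eaf, ape`.
#' @export
compare_gradients <- function(labeled, control, model = labeling_model(),
                              cfg = analysis_config(), taxonomy = NULL) {
  stopifnot(inherits(labeled, "gradient_profile"),
            inherits(control, "gradient_profile"))
  shared <- intersect(otu_ids(labeled), otu_ids(control))
  if (!length(shared)) stop("gradients share no OTUs")
  universe <- union(otu_ids(labeled), otu_ids(control))
  lab_cnt <- .expand_counts(labeled$counts, universe)
  ctl_cnt <- .expand_counts(control$counts, universe)

  for (p in list(labeled, control))
    if (length(.analyzed_idx(p, cfg$dna_floor)) < 5)
      stop("gradient '", p$sample_id,
           "' has fewer than 5 analyzed fractions")

  total_reads <- colSums(lab_cnt) + colSums(ctl_cnt)
  keep <- names(total_reads)[total_reads >= cfg$min_total_reads]

  score <- .abundance_score(lab_cnt, cfg$dna_floor, labeled) +
    .abundance_score(ctl_cnt, cfg$dna_floor, control)
  keep <- keep[order(-score[keep], keep)]
  keep <- utils::head(keep, cfg$top_n)

  rows <- lapply(keep, function(otu) {
    d13 <- if (otu %in% otu_ids(labeled))
      build_distribution(labeled, otu, cfg$dna_floor) else NULL
    d12 <- if (otu %in% otu_ids(control))
      build_distribution(control, otu, cfg$dna_floor) else NULL
    if (is.null(d13) || is.null(d12)) {
      return(data.frame(otu_id = otu, ks_p_12C = NA_real_,
                        ks_p_13C = NA_real_, wm_12C = NA_real_,
                        wm_13C = NA_real_, delta_wm = NA_real_,
                        passed_normality = FALSE, significant = FALSE,
                        eaf = NA_real_, ape = NA_real_))
    }
    wm12 <- weighted_mean_density(d12)
    wm13 <- weighted_mean_density(d13)
    delta <- wm13 - wm12
    p12 <- ks_normality(d12)
    p13 <- ks_normality(d13)
    passed <- isTRUE(p12 > cfg$ks_alpha) && isTRUE(p13 > cfg$ks_alpha)
    eaf <- excess_atom_fraction(wm12, delta, model)
    data.frame(otu_id = otu, ks_p_12C = p12, ks_p_13C = p13,
               wm_12C = wm12, wm_13C = wm13, delta_wm = delta,
               passed_normality = passed,
               significant = passed && delta > cfg$shift_threshold,
               eaf = eaf, ape = 100 * eaf)
  })
  res <- do.call(rbind, rows)
  res$taxonomy <- if (is.null(taxonomy)) NA_character_ else
    unname(taxonomy[res$otu_id])
  res <- res[c("otu_id", "taxonomy", setdiff(names(res),
                                             c("otu_id", "taxonomy")))]
  rownames(res) <- NULL
  class(res) <- c("shift_results", "data.frame")
  attr(res, "config") <- cfg
  res
}

.expand_counts <- function(counts, universe) {
  out <- matrix(0, nrow(counts), length(universe),
                dimnames = list(rownames(counts), universe))
  out[, colnames(counts)] <- counts
  out
}

# Summed per-fraction relative read abundance over analyzed fractions.
.abundance_score <- function(counts, dna_floor, profile) {
  idx <- .analyzed_idx(profile, dna_floor)
  cnt <- counts[idx, , drop = FALSE]
  tot <- rowSums(cnt)
  rel <- cnt / ifelse(tot > 0, tot, 1)
  colSums(rel)
}

#' Summarize a shift analysis
#'
#' @param object A `shift_results` data frame.
#' @param ... Unused.
#' @return List with counts of OTUs analyzed, passing the normality
#'   filter, and called significant.
#' @export
summary.shift_results <- function(object, ...) {
  list(n_analyzed = nrow(object),
       n_passed_normality = sum(object$passed_normality, na.rm = TRUE),
       n_significant = sum(object$significant, na.rm = TRUE))
}
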