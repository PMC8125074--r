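#!/usr/bin/env Rscript
# Step 4: MAG abundance response to amendment. Simulates per-base
# coverage vectors for a panel of MAGs across amended and t0 metagenomes
# (responders gain coverage under amendment), summarizes each with the
# quartile-trimmed Q2Q3 mean, normalizes to sequencing depth,
# log-transforms, and calls enrichment with a one-sided rank-sum test.
# Ends with the single-copy-gene cell-fraction estimate.

suppressPackageStartupMessages(library(tagsip))

set.seed(20210516)
dir.create("results/coverage", showWarnings = FALSE, recursive = TRUE)

n_mags <- 12
responders <- sprintf("MAG%02d", 1:4)
mags <- sprintf("MAG%02d", 1:n_mags)
samples <- data.frame(
  sample_id = c(paste0("amended_", 1:4), paste0("t0_", 1:4)),
  group = rep(c("amended", "t0"), each = 4),
  library_reads = round(runif(8, 1.5e7, 3.5e7))
)

# per-base coverage: negative binomial around a MAG- and sample-specific
# mean; responders are ~8x more abundant in amended samples
rows <- list()
for (m in mags) {
  base <- runif(1, 3, 20)
  for (i in seq_len(nrow(samples))) {
    mu <- base * if (m %in% responders &&
                       samples$group[i] == "amended") 8 else 1
    mu <- mu * samples$library_reads[i] / 2.5e7   # depth effect
    depth_vec <- rnbinom(20000, mu = mu, size = 5)
    rows[[length(rows) + 1]] <- data.frame(
      mag_id = m, sample_id = samples$sample_id[i],
      group = samples$group[i],
      q2q3_mean = q2q3_mean_coverage(depth_vec),
      library_reads = samples$library_reads[i])
  }
}
coverage <- do.call(rbind, rows)
write.table(coverage, "results/coverage/q2q3_coverage.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

calls <- normalize_and_test(coverage)
write.table(calls, "results/coverage/response_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("%d of %d MAGs significantly more abundant under amendment (p < 0.05):\n",
            sum(calls$enriched, na.rm = TRUE), nrow(calls)))
sig <- calls[which(calls$enriched), ]
for (i in seq_len(nrow(sig)))
  cat(sprintf("  %s: p = %.4f, median log10 coverage %.2f (amended) vs %.2f (t0)\n",
              sig$mag_id[i], sig$p_value[i], sig$median_amended[i],
              sig$median_t0[i]))

# log-scale coverage heatmap
coverage$norm <- normalize_coverage(coverage$q2q3_mean,
                                    coverage$library_reads)
p <- ggplot2::ggplot(coverage, ggplot2::aes(sample_id, mag_id,
                                            fill = norm)) +
  ggplot2::geom_tile() +
  ggplot2::scale_fill_viridis_c(name = "log10 cov/Mread") +
  ggplot2::theme_minimal() +
  ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                     hjust = 1))
ggplot2::ggsave("results/coverage/heatmap.png", p, width = 6,
                height = 4, dpi = 150)

# how common is a degradation gene? 248 read hits in a 31-million-read
# metagenome against a conservative 0.1% single-copy benchmark
frac <- gene_cell_fraction(248, 31e6, benchmark_fraction = 0.001)
cat(sprintf("Gene cell fraction: 248 hits / 3.1e7 reads vs 0.1%% benchmark -> %.4f (%.0f per 10,000 cells).\n",
            frac, 1e4 * frac))
cat("Wrote results/coverage/{q2q3_coverage,response_calls}.tsv, heatmap.png\n")
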