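#!/usr/bin/env Rscript
# Step 1: generate the paired 13C/12C gradient fixture used by the
# downstream analyses. A study-like community (200 taxa, lognormal
# abundances, 30 labeled taxa including two dominant heavily labeled
# degraders) is fractionated in silico into 50 fractions spanning
# 1.66-1.77 g/ml, with multinomial amplicon sampling, DNA quantification
# noise and refractometer noise at their default settings.

suppressPackageStartupMessages(library(tagsip))

seed <- 20210515
dir <- "results/fixture"
fx <- make_study_fixture(seed = seed, dir = dir)

truth <- fx$truth
cat(sprintf("Simulated %d taxa (%d labeled, EAF %.2f-%.2f).\n",
            nrow(truth), sum(truth$true_eaf > 0),
            min(truth$true_eaf[truth$true_eaf > 0]),
            max(truth$true_eaf)))
cat(sprintf("Dominant taxa: %s\n",
            paste(sprintf("%s (%.1f%% abundance, EAF %.2f)",
                          truth$otu_id[order(-truth$rel_abundance)][1:2],
                          100 * sort(truth$rel_abundance,
                                     decreasing = TRUE)[1:2],
                          truth$true_eaf[order(-truth$rel_abundance)][1:2]),
                  collapse = ", ")))
cat("Wrote:", paste(fx$paths, collapse = ", "), "\n")
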