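#!/usr/bin/env Rscript
# Generate the synthetic dataset: a 2-chromosome-pair diploid genome
# with 100 loci (80 allelic, 20 haplotype-unique), expression counts for
# 9 tissues x 3 replicates, nine ChIP mark tracks (+ input) per haplotype
# for leaf and root, cytosine reports, and a two-group metabolite table
# using the default DAM composition (683 metabolites, 423 up / 260 down).
# All downstream scripts work from the files written here.

library(haplase)

outdir <- "results/simdata"
cfg <- sim_config(seed = 20240901 %% 2147483647)
sim <- simulate_all(cfg, outdir)

cat("Wrote synthetic inputs to", outdir, "\n")
cat(sprintf("  allele pairs: %d, haplotype-unique genes: %d\n",
            nrow(sim$truth$allele_map), nrow(sim$truth$unique_genes)))
cat(sprintf("  samples: %d, marks: %d per haplotype and tissue\n",
            ncol(sim$expr$values), length(cfg$mark_names)))
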