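#!/usr/bin/env Rscript
# Haplotype mark asymmetry: RPKM-style occupancy (gene body +/- 1 kb) of the
# active marks per haplotype, compared across dominance classes
# (dominant-minus-recessive median difference, Wilcoxon vs the balanced
# class, per-class CV), plus genome-wide weighted methylation per context.

library(haplase)

d <- "results/simdata"
pairs <- read.delim("results/allele_pairs.tsv")
dominance <- read.delim("results/dominance.tsv")
gm_a <- read_gene_models(file.path(d, "genes_ha.gff3"))
gm_b <- read_gene_models(file.path(d, "genes_hb.gff3"))

marks <- c("H3K36me3", "H3K4me3", "H3K27ac", "H3K9me2")
occ <- function(hap, gm) {
  out <- lapply(marks, function(m) gene_mark_occupancy(
    read_bedgraph(file.path(d, "marks",
                            sprintf("root_h%s_%s.bedGraph", hap, m))), gm))
  names(out) <- marks
  out
}
asym <- asymmetry_summary(occ("a", gm_a), occ("b", gm_b), pairs, dominance)
write.table(asym, "results/mark_asymmetry.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Occupancy asymmetry by dominance class (root tissue):\n")
print(asym[asym$mark == "H3K36me3", ], row.names = FALSE)

meth_levels <- do.call(rbind, lapply(c(ha = "meth_ha.tsv", hb = "meth_hb.tsv"),
                                     function(f) {
  recs <- read_cytosine_report(file.path(d, f))
  data.frame(haplotype = toupper(sub("meth_(h.)\\.tsv", "\\1", f)),
             t(vapply(c("CG", "CHG", "CHH"), function(cx)
               weighted_methylation_level(recs, context = cx)$level, 0)))
}))
write.table(meth_levels, "results/methylation_levels.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Genome-wide weighted methylation (fraction):\n")
print(meth_levels, row.names = FALSE)
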