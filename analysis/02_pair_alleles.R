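#!/usr/bin/env Rscript
# Identify allelic gene pairs from synteny: apply the three block-retention
# rules (homologous chromosomes, <= 3x length ratio, >= 50% aligned
# coverage), score anchors by global CDS identity, and keep reciprocal best
# matches. Unmatched genes are haplotype-unique.

library(haplase)

d <- "results/simdata"
gm_a <- read_gene_models(file.path(d, "genes_ha.gff3"))
gm_b <- read_gene_models(file.path(d, "genes_hb.gff3"))
cds_a <- read_cds_fasta(file.path(d, "cds_ha.fa"))
cds_b <- read_cds_fasta(file.path(d, "cds_hb.fa"))

blocks <- read_synteny(file.path(d, "synteny.tsv"))
kept <- filter_synteny_blocks(blocks)
anchors <- do.call(rbind, lapply(kept$anchors, parse_anchors))
scored <- score_anchor_pairs(anchors, cds_a, cds_b)
pairing <- pair_alleles(kept, gm_a$genes$gene_id, gm_b$genes$gene_id, scored)

write.table(pairing$pairs, "results/allele_pairs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(pairing$unique_a, "results/unique_genes_ha.txt")
writeLines(pairing$unique_b, "results/unique_genes_hb.txt")

truth <- read.delim(file.path(d, "truth_allele_map.tsv"))
hit <- mean(paste(truth$gene_a, truth$gene_b) %in%
              paste(pairing$pairs$gene_a, pairing$pairs$gene_b))
cat(sprintf("Retained %d/%d blocks; paired %d loci (%.1f%% of truth); %d + %d unique genes\n",
            nrow(kept), nrow(blocks), nrow(pairing$pairs), 100 * hit,
            length(pairing$unique_a), length(pairing$unique_b)))
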