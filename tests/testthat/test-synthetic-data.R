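# The generator's outputs are the ground truth for every downstream test:
# counts forced by parameters, planted signals at their configured strengths,
# byte-level determinism, and round-trips through the package readers.

test_that("locus counts are forced by the configuration", {
  cfg <- sim_config(n_chromosome_pairs = 2, n_loci_per_chromosome = 50,
                    allelic_fraction = 0.8, seed = 7)
  g <- generate_haplotype_pair(cfg)
  expect_equal(nrow(g$truth$allele_map), 80)
  expect_equal(nrow(g$truth$unique_genes), 20)
  expect_equal(nrow(g$models_a$genes) + nrow(g$models_b$genes), 180)
  # every allelic locus appears exactly once
  expect_false(anyDuplicated(g$truth$allele_map$locus_id) > 0)
  expect_false(any(g$truth$allele_map$gene_a %in% g$truth$unique_genes$gene_id))
})

test_that("configuration errors are rejected", {
  expect_error(sim_config(n_loci_per_chromosome = 0), "positive")
  expect_error(sim_config(nb_dispersion = 0), "dispersion")
  expect_error(sim_config(bin_width = 100), "200")
  expect_error(sim_config(bias_fractions = c(no_bias = 0.5, smaller = 0.2,
                                             larger = 0.2, largest = 0.2)),
               "sum to 1")
  expect_error(sim_config(methylation_beta_params = list(CG = c(1, 1))),
               "context")
})

test_that("allelic CDS pairs diverge to the configured identity", {
  cfg <- sim_config(n_chromosome_pairs = 2, n_loci_per_chromosome = 60,
                    allelic_fraction = 1, seed = 11)
  g <- generate_haplotype_pair(cfg)
  expect_gte(nrow(g$truth$allele_map), 100)
  ident <- vapply(seq_len(nrow(g$truth$allele_map)), function(i) {
    a <- strsplit(g$cds_a[[g$truth$allele_map$gene_a[i]]], "")[[1]]
    b <- strsplit(g$cds_b[[g$truth$allele_map$gene_b[i]]], "")[[1]]
    mean(a == b)
  }, 0)
  expect_gte(mean(ident), 0.955)
  expect_lte(mean(ident), 0.972)
})

test_that("the generator is byte-deterministic in the seed", {
  cfg <- sim_config(n_chromosome_pairs = 1, n_loci_per_chromosome = 8,
                    n_tissues = 2, meth_sites_per_chrom = 300,
                    n_metabolites = 40, n_dam_up = 10, n_dam_down = 5,
                    seed = 99)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  unlink(c(d1, d2), recursive = TRUE)
  simulate_all(cfg, d1, tissues_with_marks = "leaf")
  simulate_all(cfg, d2, tissues_with_marks = "leaf")
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("planted bias fractions match the configuration within rounding", {
  s <- small_sim()
  pb <- s$truth$planted_bias
  pb1 <- pb[pb$tissue == pb$tissue[1], ]
  n <- nrow(pb1)
  frac <- table(factor(pb1$category,
                       levels = names(s$cfg$bias_fractions))) / n
  expect_true(all(abs(frac - s$cfg$bias_fractions) <= 1 / n + 1e-12))
})

test_that("planted expression ratios respect the category bands", {
  cfg <- sim_config(n_chromosome_pairs = 2, n_loci_per_chromosome = 250,
                    bias_fractions = c(no_bias = 0.4, smaller = 0,
                                       larger = 0, largest = 0.6),
                    n_tissues = 2, seed = 5)
  g <- generate_haplotype_pair(cfg)
  ex <- simulate_expression(cfg, g)
  pb <- ex$truth$planted_bias
  pb <- pb[pb$tissue == pb$tissue[1], ]
  am <- ex$truth$allele_map
  mean_a <- rowMeans(ex$expr$values[am$gene_a, , drop = FALSE])
  mean_b <- rowMeans(ex$expr$values[am$gene_b, , drop = FALSE])
  hi <- pmax(mean_a, mean_b); lo <- pmin(mean_a, mean_b)
  largest <- pb$category == "largest"
  # empirical dominant/recessive mean ratio at the planted loci
  expect_gte(mean(hi[largest] / pmax(lo[largest], 1e-9)), 8 * 0.8)
  nb <- pb$category == "no_bias"
  expect_lt(abs(log2(mean(mean_a[nb]) / mean(mean_b[nb]))), 0.2)
})

test_that("dominant-allele gene bodies carry the planted mark enrichment", {
  s <- small_sim()
  mk <- simulate_marks(s$cfg, s$genome, s$truth, tissue = "leaf")
  pb <- s$truth$planted_bias
  pb <- pb[pb$tissue == pb$tissue[1], ]
  am <- s$truth$allele_map
  biased <- which(pb$category %in% c("larger", "largest"))
  expect_gte(length(biased), 2)  # fixture plants ~7% biased loci
  body_mean <- function(tracks, gm, gid) {
    g <- gm$genes[gm$genes$gene_id == gid, ]
    x <- tracks$H3K36me3$counts[[g$chrom]]
    bb <- (g$start %/% 200 + 1):((g$end - 1) %/% 200 + 1)
    mean(x[bb])
  }
  ratios <- vapply(biased, function(i) {
    ma <- body_mean(mk$tracks_a, s$genome$models_a, am$gene_a[i])
    mb <- body_mean(mk$tracks_b, s$genome$models_b, am$gene_b[i])
    if (pb$direction[i] == "HA") ma / mb else mb / ma
  }, 0)
  agg <- mean(ratios)
  expect_gt(agg, s$cfg$mark_enrichment * 0.6)
})

test_that("the control track is independent of the marks", {
  cfg <- sim_config(n_chromosome_pairs = 1, n_loci_per_chromosome = 550,
                    n_tissues = 2, seed = 13)
  g <- generate_haplotype_pair(cfg)
  ex <- simulate_expression(cfg, g)
  mk <- simulate_marks(cfg, g, ex$truth, tissue = "leaf")
  ctrl <- unlist(mk$control_a$counts)
  expect_gte(length(ctrl), 1e4)
  for (m in c("H3K36me3", "H3K9me2")) {
    r <- cor(ctrl, unlist(mk$tracks_a[[m]]$counts))
    expect_lte(abs(r), 0.1)
  }
})

test_that("methylation levels land on the context targets", {
  cfg <- sim_config(n_chromosome_pairs = 1, n_loci_per_chromosome = 50,
                    meth_sites_per_chrom = 50000, seed = 17)
  g <- generate_haplotype_pair(cfg)
  meth <- simulate_methylation(cfg, g)
  recs <- rbind(meth$HA, meth$HB)
  expect_gte(nrow(recs), 1e5)
  cg <- weighted_methylation_level(recs, context = "CG")$level
  expect_gte(cg, 0.78); expect_lte(cg, 0.84)
  # per-site levels always proportions
  cov <- recs$count_methylated + recs$count_unmethylated
  lev <- recs$count_methylated[cov > 0] / cov[cov > 0]
  expect_true(all(lev >= 0 & lev <= 1))
  # collapsed Beta -> exactly zero methylation
  cfg0 <- sim_config(n_chromosome_pairs = 1, n_loci_per_chromosome = 10,
                     meth_sites_per_chrom = 500,
                     methylation_beta_params = list(CG = c(0, 1),
                                                    CHG = c(0, 1),
                                                    CHH = c(0, 1)),
                     seed = 3)
  g0 <- generate_haplotype_pair(cfg0)
  m0 <- suppressWarnings(simulate_methylation(cfg0, g0))
  expect_identical(weighted_methylation_level(m0$HA)$level, 0)
})

test_that("planted metabolites separate and replicates agree", {
  cfg <- sim_config(n_metabolites = 683, n_dam_up = 200, n_dam_down = 150,
                    metabolite_effect = 3, metabolite_noise_sd = 0.3,
                    seed = 19)
  met <- simulate_metabolome(cfg)
  m <- as.matrix(met$table[, -1])
  rownames(m) <- met$table$metabolite
  lfc <- log2(rowMeans(m[, 1:3]) / rowMeans(m[, 4:6]))
  up <- met$planted_dams$status == "up"
  expect_gte(mean(lfc[up] >= 1), 0.95)
  null <- met$planted_dams$status == "null"
  expect_lt(abs(mean(lfc[null])), 0.1)
  cfg2 <- sim_config(n_metabolites = 200, n_dam_up = 50, n_dam_down = 50,
                     metabolite_noise_sd = 0.05, seed = 19)
  met2 <- simulate_metabolome(cfg2)
  m2 <- as.matrix(met2$table[, -1])
  expect_gt(cor(log2(m2[, 1]), log2(m2[, 2])), 0.95)
  expect_error(simulate_metabolome(sim_config(n_metabolites = 10,
                                              n_dam_up = 8, n_dam_down = 8)),
               "exceed")
})

test_that("emitted files round-trip through the package readers", {
  cfg <- sim_config(n_chromosome_pairs = 1, n_loci_per_chromosome = 6,
                    n_tissues = 2, meth_sites_per_chrom = 200,
                    n_metabolites = 30, n_dam_up = 5, n_dam_down = 5,
                    seed = 23)
  out <- file.path(tempdir(), "roundtrip")
  unlink(out, recursive = TRUE)
  sim <- simulate_all(cfg, out, tissues_with_marks = "leaf")
  gm <- read_gene_models(sim$paths$gff_a)
  expect_equal(sort(gm$genes$gene_id), sort(sim$genome$models_a$genes$gene_id))
  ga <- sim$genome$models_a$genes[order(sim$genome$models_a$genes$gene_id), ]
  gr <- gm$genes[match(ga$gene_id, gm$genes$gene_id), ]
  expect_equal(gr$start, ga$start)
  expect_equal(gr$end, ga$end)
  expect_equal(gr$strand, ga$strand)
  expect_identical(read_cds_fasta(sim$paths$cds_a), sim$genome$cds_a)
  em <- read_counts(sim$paths$counts, sim$paths$gene_lengths)
  expect_equal(unname(em$values),
               unname(sim$expr$values[rownames(em$values), ]))
  tr <- read_bedgraph(file.path(sim$paths$marks_dir,
                                "leaf_ha_H3K36me3.bedGraph"))
  expect_identical(tr$counts[[1]],
                   sim$marks$leaf$tracks_a$H3K36me3$counts[[1]])
  syn <- read_synteny(sim$paths$synteny)
  expect_equal(syn$block_id, sim$genome$synteny$block_id)
  meth <- read_cytosine_report(sim$paths$meth_a)
  expect_equal(meth$count_methylated, sim$methylation$HA$count_methylated)
  met <- read_metabolite_table(sim$paths$metabolites)
  expect_equal(met$metabolite, sim$metabolome$table$metabolite)
  unlink(out, recursive = TRUE)
})
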