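# Synteny-block filtering (three retention rules) and reciprocal-best allele
# pairing.

mk_block <- function(id = "b1", chrom_a = "HA_chr1", chrom_b = "HB_chr1",
                     len_a = 1e5, len_b = 1e5, cov_a = 1, cov_b = 1,
                     anchors = "a1=b1") {
  data.frame(block_id = id, chrom_a = chrom_a, start_a = 0, end_a = len_a,
             chrom_b = chrom_b, start_b = 0, end_b = len_b,
             orientation = "same", coverage_a = cov_a, coverage_b = cov_b,
             anchors = anchors)
}

test_that("the three block rules reject and retain as specified", {
  hm <- c(HA_chr1 = "HB_chr1", HA_chr2 = "HB_chr2")
  # rule ii: 100 kb vs 350 kb exceeds the 3x ratio
  expect_equal(nrow(filter_synteny_blocks(mk_block(len_a = 1e5, len_b = 3.5e5),
                                          hm)), 0)
  # rule iii: one-sided coverage below half
  expect_equal(nrow(filter_synteny_blocks(mk_block(cov_a = 0.6, cov_b = 0.4),
                                          hm)), 0)
  # rule i: non-homologous chromosomes
  expect_equal(nrow(filter_synteny_blocks(
    mk_block(chrom_a = "HA_chr1", chrom_b = "HB_chr2"), hm)), 0)
  # clean block retained
  expect_equal(nrow(filter_synteny_blocks(mk_block(), hm)), 1)
  # boundaries are inclusive: ratio exactly 3, coverage exactly 0.5
  expect_equal(nrow(filter_synteny_blocks(
    mk_block(len_a = 1e5, len_b = 3e5, cov_a = 0.5, cov_b = 0.5), hm)), 1)
  expect_error(filter_synteny_blocks(mk_block(chrom_a = "HA_chr9"), hm),
               "absent")
})

test_that("filtering matches the brute-force rule oracle on random blocks", {
  set.seed(101)
  n <- 200
  chroms_a <- sprintf("HA_chr%d", 1:4)
  hm <- c(stats::setNames(sprintf("HB_chr%d", 1:4), chroms_a))
  blocks <- do.call(rbind, lapply(seq_len(n), function(i) {
    mk_block(id = sprintf("b%03d", i),
             chrom_a = sample(chroms_a, 1),
             chrom_b = sample(sprintf("HB_chr%d", 1:4), 1),
             len_a = runif(1, 1e4, 5e5), len_b = runif(1, 1e4, 5e5),
             cov_a = runif(1), cov_b = runif(1))
  }))
  got <- filter_synteny_blocks(blocks, hm)
  expect_identical(got$block_id, blocks$block_id[oracle_filter_blocks(blocks, hm)])
})

test_that("pairing keeps reciprocal best matches one-to-one", {
  blocks <- mk_block(anchors = "a1=b1")
  sim <- data.frame(gene_a = "a1", gene_b = "b1", similarity = 0.97)
  res <- pair_alleles(blocks, "a1", "b1", sim)
  expect_equal(nrow(res$pairs), 1)
  expect_equal(res$pairs$gene_a, "a1")
  expect_length(res$unique_a, 0)

  # a1's best is b2, but b2's best is a3: a1 stays unpaired
  blocks2 <- mk_block(anchors = "a1=b1,a1=b2,a3=b2")
  sim2 <- data.frame(gene_a = c("a1", "a1", "a3"),
                     gene_b = c("b1", "b2", "b2"),
                     similarity = c(0.80, 0.90, 0.95))
  res2 <- pair_alleles(blocks2, c("a1", "a3"), c("b1", "b2"), sim2)
  expect_false("a1" %in% res2$pairs$gene_a)
  expect_true(all(c("a3") %in% res2$pairs$gene_a))
  expect_true("a1" %in% res2$unique_a)

  # genes on rejected blocks come out unique
  rejected <- filter_synteny_blocks(mk_block(cov_a = 0.1, cov_b = 0.1),
                                    c(HA_chr1 = "HB_chr1"))
  res3 <- pair_alleles(rejected, "a1", "b1", sim)
  expect_equal(nrow(res3$pairs), 0)
  expect_identical(res3$unique_a, "a1")
  expect_identical(res3$unique_b, "b1")

  expect_error(pair_alleles(blocks, c("a1", "x"), c("x", "b1"), sim),
               "duplicate")
})

test_that("pairing accounting and label-swap involution hold", {
  s <- small_sim()
  g <- s$genome
  blocks <- g$synteny
  anchors <- do.call(rbind, lapply(blocks$anchors, parse_anchors))
  sim <- score_anchor_pairs(anchors, g$cds_a, g$cds_b)
  genes_a <- g$models_a$genes$gene_id
  genes_b <- g$models_b$genes$gene_id
  res <- pair_alleles(filter_synteny_blocks(blocks), genes_a, genes_b, sim)
  expect_equal(2 * nrow(res$pairs) + length(res$unique_a) +
                 length(res$unique_b), length(genes_a) + length(genes_b))
  # swapping haplotype labels swaps the pair columns, same locus set
  blocks_sw <- blocks
  blocks_sw[, c("chrom_a", "start_a", "end_a", "coverage_a")] <-
    blocks[, c("chrom_b", "start_b", "end_b", "coverage_b")]
  blocks_sw[, c("chrom_b", "start_b", "end_b", "coverage_b")] <-
    blocks[, c("chrom_a", "start_a", "end_a", "coverage_a")]
  blocks_sw$anchors <- vapply(blocks$anchors, function(a) {
    p <- parse_anchors(a)
    paste(paste0(p$gene_b, "=", p$gene_a), collapse = ",")
  }, "")
  sim_sw <- data.frame(gene_a = sim$gene_b, gene_b = sim$gene_a,
                       similarity = sim$similarity)
  hm_sw <- stats::setNames(sub("HB_", "HA_", unique(blocks_sw$chrom_a)),
                           unique(blocks_sw$chrom_a))
  res_sw <- pair_alleles(filter_synteny_blocks(blocks_sw, hm_sw),
                         genes_b, genes_a, sim_sw)
  key <- function(a, b) sort(paste(a, b))
  expect_identical(key(res$pairs$gene_a, res$pairs$gene_b),
                   key(res_sw$pairs$gene_b, res_sw$pairs$gene_a))
})

test_that("noise-free blocks recover at least 99% of true allele pairs", {
  s <- small_sim()
  g <- s$genome
  anchors <- do.call(rbind, lapply(g$synteny$anchors, parse_anchors))
  sim <- score_anchor_pairs(anchors, g$cds_a, g$cds_b)
  res <- pair_alleles(filter_synteny_blocks(g$synteny),
                      g$models_a$genes$gene_id, g$models_b$genes$gene_id, sim)
  truth_key <- paste(g$truth$allele_map$gene_a, g$truth$allele_map$gene_b)
  got_key <- paste(res$pairs$gene_a, res$pairs$gene_b)
  expect_gte(mean(truth_key %in% got_key), 0.99)
  # unique genes recovered too
  expect_setequal(res$unique_a,
                  g$truth$unique_genes$gene_id[
                    g$truth$unique_genes$haplotype == "HA"])
})
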