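# Expression bins, metagene profiles and exon-position signal.

test_that("expression bins use the right-closed boundaries", {
  b <- expression_bins(c(g1 = 0, g2 = 0.5, g3 = 10, g4 = 15, g5 = 25,
                         g6 = 1))
  expect_identical(as.character(b),
                   c("0", "0-1", "1-10", "10-20", ">20", "0-1"))
  expect_error(expression_bins(-1), "negative")
})

flat_track <- function(value, n_bins = 500, lib = 1e6) {
  binned_track(list(chr1 = rep(as.integer(value), n_bins)),
               library_size = lib)
}

test_that("a constant track profiles flat at its density in every stratum", {
  track <- flat_track(4)            # density 4 / 0.2 kb / 1 ppm-unit
  dens <- 4 / 0.2 / (track$library_size / 1e6)
  genes <- data.frame(gene_id = paste0("g", 1:6), chrom = "chr1",
                      start = seq(2000, 52000, by = 10000),
                      end = seq(2000, 52000, by = 10000) + c(1900, 2500, 3100,
                                                             1700, 2300, 900),
                      strand = rep(c("+", "-"), 3))
  strata <- rep(c("low", "high"), 3)
  prof <- metagene_profile(track, genes, strata)
  expect_equal(prof$signal, rep(dens, nrow(prof)), tolerance = 1e-9)
  # stratified means recombine to the unstratified profile
  all_prof <- metagene_profile(track, genes)
  by_pos <- tapply(prof$signal * prof$n_genes, prof$position, sum) /
    tapply(prof$n_genes, prof$position, sum)
  expect_equal(as.numeric(by_pos), all_prof$signal, tolerance = 1e-9)
})

test_that("profiles are strand-oriented 5prime to 3prime", {
  # signal hugging the genomic left end of a minus-strand gene body is the
  # gene's 3' end and must appear on the right of the profile
  x <- integer(200); x[11:15] <- 50L   # bp [2000, 3000)
  track <- binned_track(list(chr1 = x), library_size = 1e6)
  gene_minus <- data.frame(gene_id = "g1", chrom = "chr1",
                           start = 2000L, end = 6000L, strand = "-")
  prof <- metagene_profile(track, gene_minus)
  body <- prof$signal[prof$region == "body"]
  expect_gt(mean(body[16:20]), mean(body[1:5]))
  gene_plus <- transform(gene_minus, strand = "+")
  prof_p <- metagene_profile(track, gene_plus)
  expect_equal(prof_p$signal[prof_p$region == "body"], rev(body))
})

test_that("strand reversal of genes and track leaves profiles invariant", {
  set.seed(31)
  n_bins <- 300
  x <- as.integer(rpois(n_bins, 3) + rbinom(n_bins, 1, 0.1) * 20)
  track <- binned_track(list(chr1 = x), library_size = 1e6)
  L <- n_bins * 200L
  genes <- data.frame(gene_id = paste0("g", 1:4), chrom = "chr1",
                      start = c(4000L, 14000L, 24000L, 40000L),
                      end = c(8000L, 20000L, 30000L, 50000L),
                      strand = c("+", "-", "+", "-"))
  rev_track <- binned_track(list(chr1 = rev(x)), library_size = 1e6)
  rev_genes <- transform(genes, start = L - end, end = L - start,
                         strand = ifelse(strand == "+", "-", "+"))
  p1 <- metagene_profile(track, genes)
  p2 <- metagene_profile(rev_track, rev_genes)
  expect_equal(p1$signal, p2$signal, tolerance = 1e-9)
})

test_that("gene-body-confined signal elevates body over flank bins", {
  s <- small_sim()
  mk <- simulate_marks(s$cfg, s$genome, s$truth, tissue = "leaf")
  fpkm <- normalize_expression(s$expr, "FPKM")
  g <- s$genome$models_a$genes
  mean_fpkm <- rowMeans(fpkm$values)[g$gene_id]
  strata <- expression_bins(mean_fpkm)
  prof <- metagene_profile(mk$tracks_a$H3K36me3, g, strata)
  body <- mean(prof$signal[prof$region == "body"], na.rm = TRUE)
  flank <- mean(prof$signal[prof$region != "body"], na.rm = TRUE)
  expect_gt(body, 1.5 * flank)
})

test_that("exon-position signal isolates the contributing regions", {
  s <- small_sim()
  gm <- s$genome$models_a
  # uniform track: equal per-kb signal across the regions
  lens <- s$truth$chrom_lengths
  uni <- binned_track(stats::setNames(lapply(
    grep("^HA", names(lens), value = TRUE),
    function(ch) rep(3L, lens[[ch]] %/% 200)),
    grep("^HA", names(lens), value = TRUE)), library_size = 1e6)
  es <- exon_position_signal(uni, gm)
  expect_equal(es$exon1, es$exon2, tolerance = 1e-9)
  expect_equal(es$exon2, es$exon3, tolerance = 1e-9)
  expect_equal(es$utr5_cds1, es$exon1, tolerance = 1e-9)

  # reads confined to one exon3
  g1 <- gm$genes[1, ]
  ex3 <- gm$exons[gm$exons$gene_id == g1$gene_id & gm$exons$rank == 3, ]
  x <- stats::setNames(lapply(grep("^HA", names(lens), value = TRUE),
                              function(ch) integer(lens[[ch]] %/% 200)),
                       grep("^HA", names(lens), value = TRUE))
  bb <- (ex3$start %/% 200 + 1):((ex3$end - 1) %/% 200 + 1)
  x[[g1$chrom]][bb] <- 10L
  sparse <- binned_track(x, library_size = 1e6)
  es1 <- exon_position_signal(sparse, gm)
  row1 <- es1[es1$gene_id == g1$gene_id, ]
  expect_gt(row1$exon3, 0)
  if (g1$strand == "+") expect_equal(row1$exon1, 0)
})

test_that("planted exon-3 deposition separates the two tissues", {
  s <- small_sim()
  leaf <- simulate_marks(s$cfg, s$genome, s$truth, tissue = "leaf",
                         exon3_boost = 1)
  root <- simulate_marks(s$cfg, s$genome, s$truth, tissue = "root",
                         exon3_boost = 2)
  gm <- s$genome$models_a
  es_leaf <- exon_position_signal(leaf$tracks_a$H3K36me3, gm)
  es_root <- exon_position_signal(root$tracks_a$H3K36me3, gm)
  rel <- function(es) mean(es$exon3, na.rm = TRUE) /
    mean(es$exon1, na.rm = TRUE)
  expect_gt(rel(es_root), rel(es_leaf))
})
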