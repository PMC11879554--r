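## Synthetic diploid genome generator. Every downstream input (gene models,
## allele CDS pairs, synteny blocks, counts, ChIP tracks, cytosine reports,
## metabolite tables) can be produced with known ground truth, so the whole
## pipeline is testable without external sequencing data.

# propose a mutated base with transition:transversion ratio 2
propose_base <- function(base) {
  tvs <- setdiff(c("A", "C", "G", "T"), c(base, TRANSITION[[base]]))
  sample(c(TRANSITION[[base]], tvs), 1, prob = c(0.5, 0.25, 0.25))
}

random_cds <- function(n_codons) {
  body <- sample(setdiff(SENSE_CODONS, "ATG"), n_codons - 2L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

#' Diverge a CDS to a target identity under purifying-like constraint
#'
#' The number of substituted sites is Binomial(L, 1 - identity), so the
#' expected pairwise identity equals the target. Substitutions are applied
#' codon-wise with a transition:transversion ratio of 2; proposals creating
#' stop codons are rejected, and nonsynonymous proposals are retained only
#' with probability \code{ns_acceptance} (re-proposed otherwise), which
#' yields Ka/Ks well below 1 as seen for allele pairs under purifying
#' selection.
#'
#' @param cds CDS string (length divisible by 3, leading ATG, trailing stop)
#' @param target_identity expected fraction of identical sites
#' @param ns_acceptance retention probability for nonsynonymous proposals
#' @return mutated CDS string
#' @export
diverge_cds <- function(cds, target_identity, ns_acceptance = 0.3) {
  L <- nchar(cds)
  chars <- strsplit(cds, "")[[1]]
  mutable <- 4:(L - 3L)              # keep start and stop codons intact
  m <- rbinom(1, L, 1 - target_identity)
  m <- min(m, length(mutable))
  if (m == 0) return(cds)
  sites <- sample(mutable, m)
  for (s in sites) {
    ci <- (s - 1L) %/% 3L            # 0-based codon index
    pos <- s - ci * 3L               # 1..3 within codon
    codon <- paste(chars[(ci * 3L + 1L):(ci * 3L + 3L)], collapse = "")
    accepted <- NA_character_
    last <- NA_character_
    for (try in 1:20) {
      nb <- propose_base(chars[s])
      cand <- codon
      substr(cand, pos, pos) <- nb
      if (cand %in% STOP_CODONS) next
      last <- nb
      if (codon_aa(cand) == codon_aa(codon) || runif(1) < ns_acceptance) {
        accepted <- nb
        break
      }
    }
    if (is.na(accepted)) accepted <- last
    if (!is.na(accepted)) chars[s] <- accepted
  }
  paste(chars, collapse = "")
}

# fixed 3-exon architecture relative to the gene start (0-based half-open)
gene_architecture <- function(cfg) {
  e <- cfg$exon_lengths; i <- cfg$intron_length
  starts <- c(0L, e[1] + i, e[1] + i + e[2] + i)
  exons <- data.frame(start = starts, end = starts + e)
  len <- exons$end[3]
  list(exons = exons, gene_length = len)
}

# CDS genomic intervals given strand, with fixed 5'/3' UTR lengths
cds_intervals <- function(exons, strand, utr5, utr3) {
  if (strand == "+") {
    cds <- exons
    cds$start[1] <- cds$start[1] + utr5
    cds$end[3] <- cds$end[3] - utr3
  } else {
    cds <- exons
    cds$start[1] <- cds$start[1] + utr3
    cds$end[3] <- cds$end[3] - utr5
  }
  cds
}

#' Generate a haplotype-resolved gene complement with known allele pairs
#'
#' Produces matched gene models for haplotypes HA and HB, allele CDS pairs
#' diverged to the configured identity, synteny blocks connecting homologous
#' chromosome pairs, and the ground truth of the construction. Allelic loci
#' carry one gene per haplotype at the same coordinates; the remaining loci
#' carry a haplotype-unique gene on one haplotype only (alternating), so
#' exactly \code{round(allelic_fraction * total)} allele pairs exist.
#'
#' @param config a \code{\link{sim_config}}
#' @return list with \code{models_a}, \code{models_b} (gene_models),
#'   \code{cds_a}, \code{cds_b} (named vectors), \code{synteny} (data.frame),
#'   \code{chrom_lengths} (named, per haplotype chromosome) and \code{truth}
#' @export
generate_haplotype_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 11L))
  arch <- gene_architecture(config)
  n_chr <- config$n_chromosome_pairs
  n_loci <- config$n_loci_per_chromosome
  total <- n_chr * n_loci
  n_allelic <- round(config$allelic_fraction * total)
  allelic <- rep(FALSE, total)
  allelic[sample.int(total, n_allelic)] <- TRUE
  uniq_hap <- rep(c("HA", "HB"), length.out = total - n_allelic)

  step <- arch$gene_length + config$intergenic_bp
  chrom_len <- n_loci * step + config$intergenic_bp
  chrom_len <- as.integer(ceiling(chrom_len / config$bin_width) *
                            config$bin_width)
  cds_len <- sum(config$exon_lengths) - config$utr5_length - config$utr3_length

  genes <- list(); exons <- list(); cds_iv <- list()
  cds_a <- character(0); cds_b <- character(0)
  allele_map <- list(); uniques <- list(); syn <- list()
  u <- 0L; k <- 0L
  for (ch in seq_len(n_chr)) {
    anchors <- character(0)
    for (j in seq_len(n_loci)) {
      k <- k + 1L
      gstart <- config$intergenic_bp + (j - 1L) * step
      strand <- sample(c("+", "-"), 1)
      locus <- sprintf("locus%02d_%04d", ch, j)
      seq_a <- random_cds(cds_len %/% 3L)
      haps <- if (allelic[k]) c("HA", "HB") else {
        u <- u + 1L
        uniq_hap[u]
      }
      ids <- character(0)
      for (hap in haps) {
        gid <- sprintf("Sn%s%02dg%04d", sub("H", "", hap), ch, j)
        ids[hap] <- gid
        chrom <- sprintf("%s_chr%d", hap, ch)
        ex <- arch$exons
        genes[[gid]] <- data.frame(gene_id = gid, haplotype = hap,
                                   chrom = chrom, start = gstart,
                                   end = gstart + arch$gene_length,
                                   strand = strand)
        exons[[gid]] <- data.frame(gene_id = gid, start = gstart + ex$start,
                                   end = gstart + ex$end, rank = 1:3)
        civ <- cds_intervals(ex, strand, config$utr5_length,
                             config$utr3_length)
        cds_iv[[gid]] <- data.frame(gene_id = gid, start = gstart + civ$start,
                                    end = gstart + civ$end)
        if (hap == "HA") cds_a[gid] <- seq_a
        else cds_b[gid] <- if (allelic[k])
          diverge_cds(seq_a, config$target_cds_identity,
                      config$ns_acceptance) else seq_a
      }
      if (allelic[k]) {
        allele_map[[locus]] <- data.frame(locus_id = locus,
                                          gene_a = ids[["HA"]],
                                          gene_b = ids[["HB"]])
        anchors <- c(anchors, paste0(ids[["HA"]], "=", ids[["HB"]]))
      } else {
        uniques[[locus]] <- data.frame(locus_id = locus,
                                       gene_id = ids[[1]],
                                       haplotype = haps[[1]])
      }
    }
    syn[[ch]] <- data.frame(block_id = sprintf("block%02d", ch),
                            chrom_a = sprintf("HA_chr%d", ch), start_a = 0L,
                            end_a = chrom_len,
                            chrom_b = sprintf("HB_chr%d", ch), start_b = 0L,
                            end_b = chrom_len,
                            orientation = "same",
                            coverage_a = 1, coverage_b = 1,
                            anchors = paste(anchors, collapse = ","))
  }
  gtab <- do.call(rbind, genes)
  etab <- do.call(rbind, exons)
  ctab <- do.call(rbind, cds_iv)
  split_gm <- function(hap) {
    sel <- gtab$haplotype == hap
    ids <- gtab$gene_id[sel]
    gene_models(gtab[sel, ], etab[etab$gene_id %in% ids, ],
                ctab[ctab$gene_id %in% ids, ])
  }
  chrom_lengths <- stats::setNames(
    rep(chrom_len, 2 * n_chr),
    c(sprintf("HA_chr%d", seq_len(n_chr)), sprintf("HB_chr%d", seq_len(n_chr))))
  truth <- list(allele_map = do.call(rbind, allele_map),
                unique_genes = if (length(uniques)) do.call(rbind, uniques)
                               else data.frame(locus_id = character(0),
                                               gene_id = character(0),
                                               haplotype = character(0)),
                chrom_lengths = chrom_lengths)
  rownames(truth$allele_map) <- NULL
  rownames(truth$unique_genes) <- NULL
  list(models_a = split_gm("HA"), models_b = split_gm("HB"),
       cds_a = cds_a, cds_b = cds_b,
       synteny = do.call(rbind, syn),
       chrom_lengths = chrom_lengths,
       truth = truth)
}
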