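## Allelic gene identification from synteny blocks, following three block
## filtering rules: (i) the paired regions lie on a homologous chromosome
## pair, (ii) neither segment is more than three times the length of its
## counterpart, and (iii) the aligned portion covers at least half of each
## region. Genes are then paired within retained blocks by reciprocal best
## CDS similarity; genes matched in no retained block are haplotype-unique.

#' Filter synteny blocks by the three retention rules
#'
#' A block is retained iff (i) its two chromosomes form a designated
#' homologous pair, (ii) max(lenA, lenB) / min(lenA, lenB) <= 3, and
#' (iii) both aligned coverages are >= 0.5. Both boundary cases are
#' inclusive.
#'
#' @param blocks synteny data.frame (see \code{\link{write_synteny}})
#' @param homolog_map named character vector pairing each HA chromosome with
#'   its HB homolog; defaults to matching chromosome indices
#'   (\code{HA_chrN <-> HB_chrN})
#' @return the retained subset of \code{blocks}
#' @export
filter_synteny_blocks <- function(blocks, homolog_map = NULL) {
  if (is.null(homolog_map)) {
    chroms <- unique(blocks$chrom_a)
    homolog_map <- stats::setNames(sub("^HA_", "HB_", chroms), chroms)
  }
  if (!all(blocks$chrom_a %in% names(homolog_map)))
    stop("block references a chromosome absent from homolog_map")
  len_a <- blocks$end_a - blocks$start_a
  len_b <- blocks$end_b - blocks$start_b
  ratio <- pmax(len_a, len_b) / pmin(len_a, len_b)
  keep <- homolog_map[blocks$chrom_a] == blocks$chrom_b &
    ratio <= 3 &
    blocks$coverage_a >= 0.5 & blocks$coverage_b >= 0.5
  blocks[keep, , drop = FALSE]
}

#' Global CDS identity scores for candidate gene pairs
#'
#' Convenience scorer for \code{\link{pair_alleles}}: aligns each anchor pair
#' codon-aware and returns the nucleotide identity.
#'
#' @param anchor_pairs data.frame gene_a, gene_b
#' @param cds_a,cds_b named CDS vectors
#' @return \code{anchor_pairs} with an added \code{similarity} column
#' @export
score_anchor_pairs <- function(anchor_pairs, cds_a, cds_b) {
  sim <- mapply(function(a, b) {
    aln <- align_codon_pair(cds_a[[a]], cds_b[[b]])
    pair_identity(aln)
  }, anchor_pairs$gene_a, anchor_pairs$gene_b)
  anchor_pairs$similarity <- as.numeric(sim)
  anchor_pairs
}

#' Pair alleles within retained synteny blocks
#'
#' Within each retained block, a gene and its closest counterpart on the
#' opposite haplotype are paired when they are reciprocal best matches by
#' similarity, keeping pairs strictly one-to-one (two genes per locus).
#' Genes matched in no retained block are reported haplotype-unique.
#'
#' @param filtered_blocks output of \code{\link{filter_synteny_blocks}}
#' @param genes_a,genes_b gene_id vectors for HA and HB (the universe
#'   considered; anything unpaired ends up in the unique lists)
#' @param similarity data.frame gene_a, gene_b, similarity covering the
#'   anchor pairs of the retained blocks (see
#'   \code{\link{score_anchor_pairs}})
#' @return list with \code{pairs} (locus_id, gene_a, gene_b, source_block,
#'   similarity), \code{unique_a}, \code{unique_b}
#' @export
pair_alleles <- function(filtered_blocks, genes_a, genes_b, similarity) {
  if (length(intersect(genes_a, genes_b)))
    stop("duplicate gene_id across haplotypes")
  pairs <- list()
  taken_a <- character(0); taken_b <- character(0)
  for (i in seq_len(nrow(filtered_blocks))) {
    anc <- parse_anchors(filtered_blocks$anchors[i])
    anc <- merge(anc, similarity, by = c("gene_a", "gene_b"))
    anc <- anc[!(anc$gene_a %in% taken_a) & !(anc$gene_b %in% taken_b), ,
               drop = FALSE]
    if (!nrow(anc)) next
    # reciprocal best match: a's best b must have a as its best a
    best_b_for_a <- tapply(seq_len(nrow(anc)), anc$gene_a,
                           function(ix) ix[which.max(anc$similarity[ix])])
    best_a_for_b <- tapply(seq_len(nrow(anc)), anc$gene_b,
                           function(ix) ix[which.max(anc$similarity[ix])])
    reciprocal <- intersect(unlist(best_b_for_a), unlist(best_a_for_b))
    if (!length(reciprocal)) next
    sel <- anc[sort(reciprocal), , drop = FALSE]
    sel$source_block <- filtered_blocks$block_id[i]
    pairs[[length(pairs) + 1L]] <- sel
    taken_a <- c(taken_a, sel$gene_a)
    taken_b <- c(taken_b, sel$gene_b)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(gene_a = character(0), gene_b = character(0),
               similarity = numeric(0), source_block = character(0))
  pairs <- pairs[order(pairs$gene_a), , drop = FALSE]
  pairs <- data.frame(locus_id = sprintf("locus%05d", seq_len(nrow(pairs))),
                      gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                      source_block = pairs$source_block,
                      similarity = pairs$similarity)
  list(pairs = pairs,
       unique_a = setdiff(genes_a, pairs$gene_a),
       unique_b = setdiff(genes_b, pairs$gene_b))
}
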