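## Allele-specific expression: normalization, per-tissue bias categories and
## haplotype-dominance aggregation.
##
## Categories follow the four-way scheme applied per tissue: no significant
## difference (P >= 0.05); smaller (FC <= 2, P < 0.05); larger
## (2 < FC < 8, P < 0.05); largest (FC >= 8, P < 0.05); with loci below a
## combined 1-TPM expression floor left untested.

#' Normalize a count matrix to TPM or FPKM
#'
#' TPM: length-normalized rates scaled so every sample sums to 1e6.
#' FPKM: count * 1e9 / (library_size * length).
#'
#' @param em an \code{\link{expression_matrix}} of raw counts
#' @param method "TPM" or "FPKM"
#' @return an \code{expression_matrix} of normalized values
#' @export
normalize_expression <- function(em, method = c("TPM", "FPKM")) {
  method <- match.arg(method)
  stopifnot(inherits(em, "expression_matrix"))
  len <- em$gene_lengths[rownames(em$values)]
  if (any(is.na(len)) || any(len <= 0))
    stop("every gene needs a positive length")
  lib <- colSums(em$values)
  if (any(lib == 0)) stop("zero library size in at least one sample")
  if (method == "TPM") {
    rate <- em$values / len
    vals <- sweep(rate, 2, colSums(rate), "/") * 1e6
  } else {
    vals <- sweep(em$values, 2, lib, "/") / len * 1e9
  }
  expression_matrix(vals, em$sample_meta, em$gene_lengths)
}

# Welch t-test p on log2(x+1); identical-sample degenerate case -> p = 1
welch_p <- function(x, y) {
  lx <- log2(x + 1); ly <- log2(y + 1)
  if (sd(lx) == 0 && sd(ly) == 0) {
    return(if (isTRUE(all.equal(mean(lx), mean(ly)))) 1 else 0)
  }
  tryCatch(t.test(lx, ly)$p.value, error = function(e) 1)
}

#' Classify allelic expression bias in one tissue
#'
#' Loci with combined mean TPM below 1 are \code{not_expressed}. Otherwise a
#' two-sided Welch t-test on log2(TPM + 1) across replicates is combined
#' with the fold change log2fc = log2((meanA + c) / (meanB + c)),
#' pseudocount c = 0.1: p >= 0.05 gives \code{no_bias}; under p < 0.05,
#' |log2fc| <= 1 is \code{smaller}, 1 < |log2fc| < 3 \code{larger} and
#' |log2fc| >= 3 \code{largest}.
#'
#' @param pairs data.frame locus_id, gene_a, gene_b
#' @param tpm TPM-normalized \code{\link{expression_matrix}}
#' @param tissue tissue label present in the sample metadata
#' @param pseudocount fold-change stabilizer (TPM units)
#' @param alpha significance level
#' @param min_tpm combined-expression floor
#' @return data.frame locus_id, tissue, mean_a, mean_b, log2fc, p_value,
#'   category, direction
#' @export
classify_allelic_bias <- function(pairs, tpm, tissue, pseudocount = 0.1,
                                  alpha = 0.05, min_tpm = 1) {
  stopifnot(inherits(tpm, "expression_matrix"))
  meta <- tpm$sample_meta
  sel <- meta$sample[meta$tissue == tissue]
  if (length(sel) < 2) stop("need >= 2 replicates in the tissue")
  A <- tpm$values[pairs$gene_a, sel, drop = FALSE]
  B <- tpm$values[pairs$gene_b, sel, drop = FALSE]
  mean_a <- rowMeans(A); mean_b <- rowMeans(B)
  log2fc <- log2((mean_a + pseudocount) / (mean_b + pseudocount))
  p <- vapply(seq_len(nrow(pairs)), function(i) welch_p(A[i, ], B[i, ]), 0)
  testable <- (mean_a + mean_b) >= min_tpm
  category <- rep("not_expressed", nrow(pairs))
  afc <- abs(log2fc)
  category[testable & p >= alpha] <- "no_bias"
  category[testable & p < alpha & afc <= 1] <- "smaller"
  category[testable & p < alpha & afc > 1 & afc < 3] <- "larger"
  category[testable & p < alpha & afc >= 3] <- "largest"
  direction <- ifelse(category %in% c("not_expressed", "no_bias"), "none",
                      ifelse(log2fc > 0, "HA", "HB"))
  data.frame(locus_id = pairs$locus_id, tissue = tissue,
             mean_a = mean_a, mean_b = mean_b,
             log2fc = log2fc, p_value = p,
             category = category, direction = direction,
             row.names = NULL)
}

#' Bias calls for every tissue
#'
#' @inheritParams classify_allelic_bias
#' @return row-bound bias calls over all tissues in the metadata
#' @export
classify_all_tissues <- function(pairs, tpm, ...) {
  tissues <- unique(tpm$sample_meta$tissue)
  do.call(rbind, lapply(tissues, function(tt)
    classify_allelic_bias(pairs, tpm, tt, ...)))
}

#' Aggregate per-tissue bias calls into haplotype dominance classes
#'
#' A locus is an ASEG (HA_gt_HB or HA_lt_HB) when at least one tissue calls
#' it larger or largest (i.e. FC > 2 at p < 0.05) and all such tissues agree
#' on the biased side; direction conflicts or no qualifying tissue give
#' HA_eq_HB. Also reports the fraction of allelic loci whose non-no_bias
#' category and direction are identical in every testable tissue
#' (cross-tissue consistency).
#'
#' @param calls bias calls over all tissues
#'   (\code{\link{classify_all_tissues}})
#' @return list with \code{dominance} (locus_id, class, n_supporting,
#'   supporting_tissues) and \code{consistency_fraction}
#' @export
aggregate_asegs <- function(calls) {
  if (anyDuplicated(calls[, c("locus_id", "tissue")]))
    stop("duplicate locus within a tissue")
  by_locus <- split(calls, calls$locus_id)
  rows <- lapply(by_locus, function(d) {
    qual <- d[d$category %in% c("larger", "largest"), , drop = FALSE]
    cls <- if (nrow(qual) == 0 || length(unique(qual$direction)) > 1)
      "HA_eq_HB" else if (qual$direction[1] == "HA") "HA_gt_HB" else
        "HA_lt_HB"
    data.frame(locus_id = d$locus_id[1], class = cls,
               n_supporting = if (cls == "HA_eq_HB") 0L else nrow(qual),
               supporting_tissues = if (cls == "HA_eq_HB") "" else
                 paste(qual$tissue, collapse = ","))
  })
  dominance <- do.call(rbind, rows)
  rownames(dominance) <- NULL
  testable <- calls[calls$category != "not_expressed", , drop = FALSE]
  cons <- vapply(split(testable, testable$locus_id), function(d) {
    nrow(d) > 0 && all(d$category != "no_bias") &&
      length(unique(paste(d$category, d$direction))) == 1
  }, TRUE)
  list(dominance = dominance,
       consistency_fraction = sum(cons) / length(by_locus))
}

#' Summarize dominance classes as counts and percentages
#'
#' @param dominance dominance table from \code{\link{aggregate_asegs}}, or a
#'   named count vector with entries HA_gt_HB, HA_lt_HB, HA_eq_HB
#' @return data.frame class, n, percent (percent of all loci)
#' @export
dominance_summary <- function(dominance) {
  lv <- c("HA_gt_HB", "HA_lt_HB", "HA_eq_HB")
  counts <- if (is.data.frame(dominance)) {
    table(factor(dominance$class, levels = lv))
  } else {
    stopifnot(all(lv %in% names(dominance)))
    dominance[lv]
  }
  n <- as.numeric(counts)
  data.frame(class = lv, n = n, percent = 100 * n / sum(n))
}
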