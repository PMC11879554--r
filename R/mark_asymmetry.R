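## Haplotype histone-mark occupancy, asymmetry across dominance classes and
## weighted DNA-methylation levels.

# mean signal components over [start, end) on a binned track:
# returns sum of overlap-weighted counts
track_interval_sum <- function(track, chrom, start, end) {
  x <- track$counts[[chrom]]
  if (is.null(x)) stop("chromosome absent from track")
  bw <- track$bin_width
  n <- length(x)
  start <- max(start, 0L); end <- min(end, n * bw)
  if (end <= start) return(0)
  first <- start %/% bw + 1L
  last <- (end - 1L) %/% bw + 1L
  idx <- first:last
  ov_start <- pmax(start, (idx - 1L) * bw)
  ov_end <- pmin(end, idx * bw)
  sum(x[idx] * (ov_end - ov_start) / bw)
}

#' Histone-mark occupancy over a gene body with flanks
#'
#' RPKM-style: overlap-weighted read sum over [start - flank, end + flank)
#' scaled by 1e9 / (library_size * region_length). Flanks are truncated at
#' chromosome ends, and the truncated length is what normalizes.
#'
#' @param track a \code{\link{binned_track}}
#' @param genes gene table (gene_id, chrom, start, end) or a
#'   \code{gene_models} object
#' @param flank_bp flank added on both sides (default 1 kb)
#' @return data.frame gene_id, occupancy
#' @export
gene_mark_occupancy <- function(track, genes, flank_bp = 1000L) {
  if (inherits(genes, "gene_models")) genes <- genes$genes
  if (!all(genes$chrom %in% names(track$counts)))
    stop("gene outside track")
  occ <- vapply(seq_len(nrow(genes)), function(i) {
    chrom <- genes$chrom[i]
    lim <- length(track$counts[[chrom]]) * track$bin_width
    s <- max(genes$start[i] - flank_bp, 0L)
    e <- min(genes$end[i] + flank_bp, lim)
    reads <- track_interval_sum(track, chrom, s, e)
    reads * 1e9 / (track$library_size * (e - s))
  }, 0)
  data.frame(gene_id = genes$gene_id, occupancy = occ)
}

#' Occupancy asymmetry across haplotype dominance classes
#'
#' For each dominance class and mark: the median occupancy difference
#' (dominant minus recessive allele; HA minus HB for the balanced class),
#' a two-sided Wilcoxon rank-sum P comparing the class's differences with
#' the balanced class, and the coefficient of variation of occupancy within
#' the class (pooled over both alleles).
#'
#' @param occ_a,occ_b named lists (by mark) of occupancy tables for the HA
#'   and HB genes of each locus, rows aligned with \code{pairs}
#' @param pairs data.frame locus_id, gene_a, gene_b
#' @param dominance dominance table (\code{\link{aggregate_asegs}})
#' @return data.frame class, mark, n, median_diff, wilcox_p, cv, flagged
#' @export
asymmetry_summary <- function(occ_a, occ_b, pairs, dominance) {
  stopifnot(identical(names(occ_a), names(occ_b)))
  cls <- dominance$class[match(pairs$locus_id, dominance$locus_id)]
  out <- list()
  for (mk in names(occ_a)) {
    oa <- occ_a[[mk]]$occupancy[match(pairs$gene_a, occ_a[[mk]]$gene_id)]
    ob <- occ_b[[mk]]$occupancy[match(pairs$gene_b, occ_b[[mk]]$gene_id)]
    # dominant-minus-recessive difference per locus
    diff <- ifelse(cls == "HA_lt_HB", ob - oa, oa - ob)
    ref <- diff[cls == "HA_eq_HB"]
    for (cl in c("HA_gt_HB", "HA_lt_HB", "HA_eq_HB")) {
      d <- diff[cls == cl]
      vals <- c(oa[cls == cl], ob[cls == cl])
      flagged <- length(d) < 2
      wp <- if (flagged || cl == "HA_eq_HB" || length(ref) < 2) NA_real_ else
        suppressWarnings(wilcox.test(d, ref)$p.value)
      out[[paste(mk, cl)]] <- data.frame(
        class = cl, mark = mk, n = length(d),
        median_diff = if (length(d)) median(d) else NA_real_,
        wilcox_p = wp,
        cv = if (length(vals) > 1 && mean(vals) > 0)
          sd(vals) / mean(vals) else NA_real_,
        flagged = flagged)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Weighted DNA-methylation level of a region
#'
#' Total methylated reads over total coverage across the covered cytosines
#' of the requested context inside the region; zero-coverage sites are
#' excluded.
#'
#' @param records cytosine report data.frame
#'   (\code{\link{read_cytosine_report}})
#' @param chrom,start,end region (0-based half-open); NULL chrom means
#'   genome-wide
#' @param context one of CG, CHG, CHH, or "all"
#' @return list with \code{level} (NA when no covered site) and
#'   \code{n_sites}
#' @export
weighted_methylation_level <- function(records, chrom = NULL, start = NULL,
                                       end = NULL, context = "all") {
  d <- records
  if (!is.null(chrom)) {
    d <- d[d$chrom == chrom, , drop = FALSE]
    if (!is.null(start)) d <- d[d$pos > start & d$pos <= end, , drop = FALSE]
  }
  if (context != "all") d <- d[d$context == context, , drop = FALSE]
  cov <- d$count_methylated + d$count_unmethylated
  d <- d[cov > 0, , drop = FALSE]
  if (!nrow(d)) return(list(level = NA_real_, n_sites = 0L))
  list(level = sum(d$count_methylated) /
         sum(d$count_methylated + d$count_unmethylated),
       n_sites = nrow(d))
}
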