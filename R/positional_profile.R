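## Positional signal profiling: metagene (scaled gene body + fixed flanks)
## and exon-position summaries, stratified by expression bin or dominance
## class. Signal is reported as per-kb per-million density so a spatially
## constant track profiles flat at its constant density.

#' Assign genes to FPKM expression bins
#'
#' Bins: exactly 0; (0,1]; (1,10]; (10,20]; (20, Inf). Right-closed, so an
#' FPKM of exactly 10 falls in "1-10".
#'
#' @param fpkm named non-negative numeric vector
#' @return factor with levels "0", "0-1", "1-10", "10-20", ">20"
#' @export
expression_bins <- function(fpkm) {
  if (any(fpkm < 0)) stop("negative FPKM")
  lab <- c("0", "0-1", "1-10", "10-20", ">20")
  out <- cut(fpkm, breaks = c(-Inf, 0, 1, 10, 20, Inf), labels = lab,
             right = TRUE)
  stats::setNames(factor(out, levels = lab), names(fpkm))
}

# per-kb per-million density of [start,end) on a track
interval_density <- function(track, chrom, start, end) {
  if (end <= start) return(NA_real_)
  reads <- track_interval_sum(track, chrom, start, end)
  reads / ((end - start) / 1000) / (track$library_size / 1e6)
}

# density of a strand-oriented window split into nb equal bins;
# windows beyond chromosome ends contribute averaged covered width
window_bins <- function(track, chrom, start, end, strand, nb) {
  lim <- length(track$counts[[chrom]]) * track$bin_width
  edges <- seq(start, end, length.out = nb + 1)
  v <- vapply(seq_len(nb), function(i) {
    s <- max(edges[i], 0); e <- min(edges[i + 1], lim)
    if (e <= s) return(NA_real_)
    interval_density(track, chrom, s, e)
  }, 0)
  if (strand == "-") rev(v) else v
}

#' Metagene profile of a track over gene cohorts
#'
#' Each gene body is rescaled to \code{n_body_bins} equal bins; flanks of
#' \code{flank_bp} are profiled in fixed \code{flank_res}-bp bins. Profiles
#' are strand-oriented 5' to 3' and averaged within each stratum.
#'
#' @param track a \code{\link{binned_track}}
#' @param genes gene table (gene_id, chrom, start, end, strand) or
#'   \code{gene_models}
#' @param strata optional factor/character per gene; NULL profiles all genes
#'   as one cohort
#' @param n_body_bins body bins (default 20)
#' @param flank_bp flank size (default 1 kb)
#' @param flank_res flank bin width (default 50 bp, i.e. 20 bins per kb)
#' @return data.frame stratum, position (1..2*flank_bins+n_body_bins),
#'   region (upstream/body/downstream), signal, n_genes
#' @export
metagene_profile <- function(track, genes, strata = NULL, n_body_bins = 20L,
                             flank_bp = 1000L, flank_res = 50L) {
  if (inherits(genes, "gene_models")) genes <- genes$genes
  fb <- as.integer(flank_bp / flank_res)
  keep <- (genes$end - genes$start) >= n_body_bins
  if (any(!keep)) warning(sum(!keep), " gene(s) shorter than ",
                          n_body_bins, " bp skipped")
  genes <- genes[keep, , drop = FALSE]
  if (is.null(strata)) strata <- rep("all", nrow(genes)) else
    strata <- strata[keep]
  prof <- matrix(NA_real_, nrow(genes), 2L * fb + n_body_bins)
  for (i in seq_len(nrow(genes))) {
    ch <- genes$chrom[i]; s <- genes$start[i]; e <- genes$end[i]
    st <- genes$strand[i]
    up <- window_bins(track, ch, s - flank_bp, s, "+", fb)
    body <- window_bins(track, ch, s, e, "+", n_body_bins)
    down <- window_bins(track, ch, e, e + flank_bp, "+", fb)
    v <- c(up, body, down)
    if (st == "-") v <- rev(v)
    prof[i, ] <- v
  }
  region <- rep(c("upstream", "body", "downstream"),
                c(fb, n_body_bins, fb))
  out <- lapply(split(seq_len(nrow(genes)), strata), function(ix) {
    data.frame(stratum = unname(as.character(strata[ix[1]])),
               position = seq_len(ncol(prof)),
               region = region,
               signal = colMeans(prof[ix, , drop = FALSE], na.rm = TRUE),
               n_genes = length(ix))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Exon-position signal of a mark per gene
#'
#' Per-kb per-million density over the first three exons (in transcript
#' order), the union of the 5' UTR with the first CDS segment, and a
#' strand-oriented TSS +/- 1 kb window. Genes with fewer than three exons
#' get NA in the missing regions, genes without CDS get NA for utr5_cds1.
#'
#' @param track a \code{\link{binned_track}}
#' @param gm a \code{gene_models} object
#' @return data.frame gene_id, exon1, exon2, exon3, utr5_cds1, tss_1kb
#' @export
exon_position_signal <- function(track, gm) {
  stopifnot(inherits(gm, "gene_models"))
  g <- gm$genes
  ex_by <- split(gm$exons, gm$exons$gene_id)
  cds_by <- split(gm$cds, gm$cds$gene_id)
  rows <- lapply(seq_len(nrow(g)), function(i) {
    gid <- g$gene_id[i]; ch <- g$chrom[i]; st <- g$strand[i]
    ex <- ex_by[[gid]]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (st == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
    dens <- function(s, e) interval_density(track, ch, s, e)
    e123 <- rep(NA_real_, 3)
    for (k in seq_len(min(3L, nrow(ex))))
      e123[k] <- dens(ex$start[k], ex$end[k])
    cds <- cds_by[[gid]]
    u5c1 <- NA_real_
    if (!is.null(cds) && nrow(cds)) {
      cds <- cds[order(cds$start), , drop = FALSE]
      # first CDS segment in transcript order
      c1 <- if (st == "+") cds[1, ] else cds[nrow(cds), ]
      # 5' UTR: exonic sequence upstream of the CDS start
      if (st == "+") {
        u_s <- ex$start[1]; u_e <- c1$start
        span <- c(min(u_s, c1$start), max(u_e, c1$end))
        u5c1 <- dens(span[1], span[2])
      } else {
        u_e <- ex$end[1]; u_s <- c1$end
        span <- c(min(c1$start, u_s), max(c1$end, u_e))
        u5c1 <- dens(span[1], span[2])
      }
    }
    tss <- if (st == "+") g$start[i] else g$end[i]
    lim <- length(track$counts[[ch]]) * track$bin_width
    tsig <- dens(max(tss - 1000L, 0L), min(tss + 1000L, lim))
    data.frame(gene_id = gid, exon1 = e123[1], exon2 = e123[2],
               exon3 = e123[3], utr5_cds1 = u5c1, tss_1kb = tsig)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
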