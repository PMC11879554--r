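## File formats used by the pipeline. All internal coordinates are 0-based
## half-open; GFF3 (1-based inclusive) and bedGraph (0-based half-open) are
## converted at the boundary. Heavy lifting is delegated to rtracklayer /
## Biostrings / data.table.

#' Fixed-width binned read-count track
#'
#' @param counts named list (by chromosome) of non-negative integer bin counts
#' @param bin_width bin width in bp
#' @param library_size total mapped reads; defaults to the sum of all bins
#' @return object of class \code{binned_track}
#' @export
binned_track <- function(counts, bin_width = 200L,
                         library_size = sum(unlist(counts))) {
  stopifnot(is.list(counts), !is.null(names(counts)))
  counts <- lapply(counts, function(x) {
    if (any(x < 0)) stop("bin counts must be non-negative")
    as.integer(x)
  })
  structure(list(counts = counts, bin_width = as.integer(bin_width),
                 library_size = as.numeric(library_size)),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf("binned_track: %d chromosome(s), %d bp bins, library %.0f\n",
              length(x$counts), x$bin_width, x$library_size))
  invisible(x)
}

#' Write / read a binned track as bedGraph
#'
#' Zero bins are written explicitly so the full bin grid round-trips.
#'
#' @param track a \code{binned_track}
#' @param path output file
#' @export
write_bedgraph <- function(track, path) {
  n <- vapply(track$counts, length, 0L)
  starts <- unlist(lapply(n, function(k) (seq_len(k) - 1L) * track$bin_width),
                   use.names = FALSE)
  gr <- GenomicRanges::GRanges(
    rep(names(track$counts), n),
    IRanges::IRanges(start = starts + 1L, width = track$bin_width),
    score = unlist(track$counts, use.names = FALSE))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname write_bedgraph
#' @param bin_width expected bin width; runs in the file are re-expanded onto
#'   this grid (bedGraph writers may merge equal-value neighbours)
#' @return \code{read_bedgraph}: a \code{binned_track}
#' @export
read_bedgraph <- function(path, bin_width = 200L) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   score = gr$score)
  counts <- lapply(split(df, factor(df$chrom, levels = unique(df$chrom))),
                   function(d) {
    n <- max(d$end) %/% bin_width
    x <- integer(n)
    ix <- (d$start %/% bin_width) + 1L
    reps <- (d$end - d$start) %/% bin_width
    x[unlist(Map(seq, ix, ix + reps - 1L))] <-
      rep(as.integer(d$score), reps)
    x
  })
  binned_track(counts, bin_width = bin_width)
}

## ---- gene models ----------------------------------------------------------

#' Gene model container
#'
#' @param genes data.frame: gene_id, haplotype, chrom, start, end, strand
#' @param exons data.frame: gene_id, start, end, rank (genomic order)
#' @param cds data.frame: gene_id, start, end
#' @return object of class \code{gene_models}
#' @export
gene_models <- function(genes, exons, cds) {
  stopifnot(all(genes$start < genes$end))
  structure(list(genes = as.data.frame(genes),
                 exons = as.data.frame(exons),
                 cds = as.data.frame(cds)),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes on %d chromosome(s)\n",
              nrow(x$genes), length(unique(x$genes$chrom))))
  invisible(x)
}

#' Write gene models to GFF3
#'
#' Each feature carries a \code{gene_id} attribute so structure round-trips
#' exactly through \code{\link{read_gene_models}}.
#'
#' @param gm a \code{gene_models} object
#' @param path output GFF3 path
#' @export
write_gene_models <- function(gm, path) {
  g <- gm$genes
  feat <- list(
    GenomicRanges::GRanges(g$chrom,
      IRanges::IRanges(g$start + 1L, g$end), strand = g$strand,
      type = "gene", ID = g$gene_id, gene_id = g$gene_id,
      haplotype = g$haplotype))
  strand_of <- stats::setNames(g$strand, g$gene_id)
  chrom_of <- stats::setNames(g$chrom, g$gene_id)
  hap_of <- stats::setNames(g$haplotype, g$gene_id)
  for (part in c("exons", "cds")) {
    d <- gm[[part]]
    type <- if (part == "exons") "exon" else "CDS"
    feat[[part]] <- GenomicRanges::GRanges(chrom_of[d$gene_id],
      IRanges::IRanges(d$start + 1L, d$end),
      strand = strand_of[d$gene_id],
      type = type,
      ID = paste0(d$gene_id, ".", tolower(type), seq_len(nrow(d))),
      gene_id = d$gene_id,
      haplotype = hap_of[d$gene_id])
    if (type == "CDS") {
      # phase: bases to skip before the first full codon of each segment,
      # accumulated in transcript (strand-aware) order
      phase <- integer(nrow(d))
      for (gid in unique(d$gene_id)) {
        ix <- which(d$gene_id == gid)
        ix <- ix[order(d$start[ix],
                       decreasing = strand_of[[gid]] == "-")]
        lens <- d$end[ix] - d$start[ix]
        before <- cumsum(c(0L, lens))[seq_along(ix)]
        phase[ix] <- (3L - before %% 3L) %% 3L
      }
      feat[[part]]$phase <- phase
    }
  }
  gr <- suppressWarnings(do.call(c, unname(feat)))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' @param path GFF3 file written by \code{\link{write_gene_models}} or any
#'   GFF3 whose gene/exon/CDS features carry a \code{gene_id} attribute
#' @return a \code{gene_models} object
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (is.null(gr$gene_id)) stop("GFF3 features must carry a gene_id attribute")
  take <- function(type) {
    x <- gr[gr$type == type]
    data.frame(gene_id = x$gene_id,
               chrom = as.character(GenomicRanges::seqnames(x)),
               start = GenomicRanges::start(x) - 1L,
               end = GenomicRanges::end(x),
               strand = as.character(GenomicRanges::strand(x)),
               haplotype = if (!is.null(x$haplotype)) x$haplotype else NA,
               stringsAsFactors = FALSE)
  }
  g <- take("gene")
  ex <- take("exon")
  ex <- ex[order(ex$gene_id, ex$start), ]
  ex$rank <- stats::ave(ex$start, ex$gene_id, FUN = seq_along)
  cds <- take("CDS")
  cds <- cds[order(cds$gene_id, cds$start), ]
  gene_models(
    genes = g[, c("gene_id", "haplotype", "chrom", "start", "end", "strand")],
    exons = ex[, c("gene_id", "start", "end", "rank")],
    cds = cds[, c("gene_id", "start", "end")])
}

#' Write / read CDS sequences as FASTA
#' @param seqs named character vector of CDS sequences
#' @param path FASTA path
#' @export
write_cds_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_cds_fasta
#' @return \code{read_cds_fasta}: named character vector
#' @export
read_cds_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

## ---- synteny --------------------------------------------------------------

#' Write / read synteny blocks
#'
#' Tab-separated: block_id, chrom_a, start_a, end_a, chrom_b, start_b, end_b,
#' orientation, coverage_a, coverage_b, anchors (comma-separated
#' \code{geneA=geneB} pairs). Coordinates 0-based half-open.
#'
#' @param blocks data.frame in the layout above
#' @param path output path
#' @export
write_synteny <- function(blocks, path) {
  data.table::fwrite(blocks, path, sep = "\t")
  invisible(path)
}

#' @rdname write_synteny
#' @export
read_synteny <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t",
                                  colClasses = list(character = "anchors")))
}

#' Split the anchor column of a synteny block into gene-id pairs
#' @param anchors anchor string \code{"a1=b1,a2=b2"}
#' @return data.frame with columns gene_a, gene_b
#' @export
parse_anchors <- function(anchors) {
  pairs <- strsplit(unlist(strsplit(anchors, ",", fixed = TRUE)), "=",
                    fixed = TRUE)
  data.frame(gene_a = vapply(pairs, `[`, "", 1),
             gene_b = vapply(pairs, `[`, "", 2))
}

## ---- expression -----------------------------------------------------------

#' Expression matrix container
#'
#' @param values gene x sample numeric matrix
#' @param sample_meta data.frame: sample, tissue, replicate
#' @param gene_lengths named vector of transcript lengths (bp)
#' @return object of class \code{expression_matrix}
#' @export
expression_matrix <- function(values, sample_meta, gene_lengths) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("expression values must be non-negative")
  stopifnot(identical(colnames(values), sample_meta$sample))
  if (anyNA(sample_meta$tissue) || anyNA(sample_meta$replicate))
    stop("every sample needs tissue and replicate labels")
  structure(list(values = values,
                 sample_meta = as.data.frame(sample_meta),
                 gene_lengths = gene_lengths),
            class = "expression_matrix")
}

#' Write / read a count matrix with tissue_replicate sample columns
#' @param em an \code{expression_matrix}
#' @param path counts TSV path
#' @param lengths_path gene-length TSV path (gene_id, length)
#' @export
write_counts <- function(em, path, lengths_path) {
  d <- data.table::data.table(gene_id = rownames(em$values))
  d <- cbind(d, as.data.table_safe(em$values))
  data.table::fwrite(d, path, sep = "\t")
  data.table::fwrite(data.table::data.table(
    gene_id = names(em$gene_lengths), length = as.integer(em$gene_lengths)),
    lengths_path, sep = "\t")
  invisible(path)
}

as.data.table_safe <- function(m) data.table::as.data.table(as.data.frame(m))

#' @rdname write_counts
#' @return \code{read_counts}: an \code{expression_matrix} (sample metadata
#'   parsed from \code{tissue_replicate} column names)
#' @export
read_counts <- function(path, lengths_path) {
  d <- data.table::fread(path, sep = "\t")
  genes <- d$gene_id
  m <- as.matrix(d[, -1])
  rownames(m) <- genes
  parts <- strsplit(colnames(m), "_", fixed = TRUE)
  meta <- data.frame(sample = colnames(m),
                     tissue = vapply(parts, `[`, "", 1),
                     replicate = vapply(parts, `[`, "", 2))
  len <- data.table::fread(lengths_path, sep = "\t")
  expression_matrix(m, meta, stats::setNames(len$length, len$gene_id))
}

## ---- methylation ----------------------------------------------------------

#' Write / read a Bismark-style cytosine report
#'
#' Headerless TSV: chrom, pos (1-based), strand, count_methylated,
#' count_unmethylated, context, trinucleotide.
#'
#' @param records data.frame in the layout above
#' @param path output path
#' @export
write_cytosine_report <- function(records, path) {
  data.table::fwrite(records, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_cytosine_report
#' @export
read_cytosine_report <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = FALSE,
    col.names = c("chrom", "pos", "strand", "count_methylated",
                  "count_unmethylated", "context", "trinucleotide"))
  as.data.frame(d)
}

## ---- metabolome -----------------------------------------------------------

#' Write / read a metabolite intensity table
#'
#' TSV with a \code{metabolite} column and \code{group_replicate} sample
#' columns (two groups).
#'
#' @param table data.frame: metabolite + sample columns
#' @param path output path
#' @export
write_metabolite_table <- function(table, path) {
  data.table::fwrite(table, path, sep = "\t")
  invisible(path)
}

#' @rdname write_metabolite_table
#' @export
read_metabolite_table <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}
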