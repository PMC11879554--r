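## Allele-pair divergence: codon-aware alignment, percent identity, NG86
## Ka/Ks with Jukes-Cantor correction, and the fourfold-degenerate
## transversion rate (4DTv).

#' Codon-aware global alignment of two CDS sequences
#'
#' The sequences are translated, aligned globally at the protein level
#' (match +1, mismatch 0, gap -1) and the alignment is back-threaded to
#' codons. Trailing bases that do not fill a codon are trimmed with a
#' warning; if both sequences contain an internal stop the pair is rejected.
#'
#' @param cds_a,cds_b nucleotide strings over A, C, G, T, N
#' @return object of class \code{codon_alignment}: list with
#'   \code{codon_a}, \code{codon_b} (per-column codons, \code{"---"} for a
#'   gap) and \code{n_codons}
#' @export
align_codon_pair <- function(cds_a, cds_b) {
  trim <- function(s) {
    if (nchar(s) < 3) stop("CDS shorter than one codon")
    extra <- nchar(s) %% 3L
    if (extra) {
      warning("CDS length not a multiple of 3; trailing bases trimmed")
      s <- substr(s, 1, nchar(s) - extra)
    }
    s
  }
  cds_a <- trim(toupper(cds_a)); cds_b <- trim(toupper(cds_b))
  prot <- function(s) {
    as.character(Biostrings::translate(Biostrings::DNAString(s),
                                       if.fuzzy.codon = "solve"))
  }
  pa <- prot(cds_a); pb <- prot(cds_b)
  internal_stop <- function(p) grepl("\\*", substr(p, 1, nchar(p) - 1))
  if (internal_stop(pa) && internal_stop(pb))
    stop("internal stop codon in both sequences")
  letters_aa <- unique(c(strsplit(paste0(pa, pb), "")[[1]], "X"))
  subm <- matrix(0, length(letters_aa), length(letters_aa),
                 dimnames = list(letters_aa, letters_aa))
  diag(subm) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa), Biostrings::AAString(pb),
    substitutionMatrix = subm, gapOpening = 0, gapExtension = 1,
    type = "global")
  sa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  codons_of <- function(s) substring(s, seq(1, nchar(s), 3),
                                     seq(3, nchar(s), 3))
  ca <- codons_of(cds_a); cb <- codons_of(cds_b)
  ia <- 0L; ib <- 0L
  col_a <- character(length(sa)); col_b <- character(length(sb))
  for (i in seq_along(sa)) {
    if (sa[i] == "-") col_a[i] <- "---" else {
      ia <- ia + 1L; col_a[i] <- ca[ia]
    }
    if (sb[i] == "-") col_b[i] <- "---" else {
      ib <- ib + 1L; col_b[i] <- cb[ib]
    }
  }
  structure(list(codon_a = col_a, codon_b = col_b,
                 n_codons = length(col_a)),
            class = "codon_alignment")
}

# columns where both codons are ungapped and unambiguous
ungapped_columns <- function(aln) {
  ok <- aln$codon_a != "---" & aln$codon_b != "---" &
    !grepl("[^ACGT]", aln$codon_a) & !grepl("[^ACGT]", aln$codon_b)
  list(a = aln$codon_a[ok], b = aln$codon_b[ok])
}

# fraction of the three possible changes at each position that are
# synonymous; changes to stop codons count as nonsynonymous
codon_syn_sites <- function(codon) {
  if (codon %in% STOP_CODONS) return(0)
  aa <- codon_aa(codon)
  s <- 0
  for (pos in 1:3) {
    orig <- substr(codon, pos, pos)
    for (nb in setdiff(BASES, orig)) {
      cand <- codon
      substr(cand, pos, pos) <- nb
      if (!(cand %in% STOP_CODONS) && codon_aa(cand) == aa)
        s <- s + 1 / 3
    }
  }
  s
}

# average synonymous / nonsynonymous difference counts between two codons
# over all shortest mutational pathways; pathways through stop codons are
# excluded (all pathways used if every one is blocked)
codon_path_differences <- function(c1, c2) {
  diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(diff_pos)
  if (nd == 0) return(c(sd = 0, nd = 0))
  orders <- permutations_of(nd)
  res <- matrix(NA_real_, nrow(orders), 2)
  blocked <- logical(nrow(orders))
  for (i in seq_len(nrow(orders))) {
    cur <- c1; sd <- 0; ndn <- 0; hit_stop <- FALSE
    for (p in diff_pos[orders[i, ]]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (nxt %in% STOP_CODONS) hit_stop <- TRUE
      if (!(cur %in% STOP_CODONS) && !(nxt %in% STOP_CODONS) &&
          codon_aa(cur) == codon_aa(nxt)) sd <- sd + 1 else ndn <- ndn + 1
      cur <- nxt
    }
    res[i, ] <- c(sd, ndn)
    blocked[i] <- hit_stop
  }
  use <- if (all(blocked)) rep(TRUE, nrow(orders)) else !blocked
  c(sd = mean(res[use, 1]), nd = mean(res[use, 2]))
}

#' NG86 Ka/Ks from a codon alignment
#'
#' Fractional site counting: each codon position contributes the fraction of
#' its three possible changes that are synonymous; site totals are averaged
#' between the two sequences. Observed differences at multi-difference
#' codons are averaged over all shortest mutational pathways (pathways
#' through stop codons excluded). Proportions are corrected with
#' Jukes-Cantor, d = -(3/4) log(1 - (4/3) p).
#'
#' @param aln a \code{codon_alignment}
#' @return data.frame with S, N, Sd, Nd, pS, pN, Ks, Ka, ka_ks and a logical
#'   \code{undefined} flag (Ks = 0, or a proportion beyond the correction's
#'   domain)
#' @export
ng86_ka_ks <- function(aln) {
  cols <- ungapped_columns(aln)
  if (!length(cols$a)) stop("no ungapped codon columns")
  S <- mean(c(sum(vapply(cols$a, codon_syn_sites, 0)),
              sum(vapply(cols$b, codon_syn_sites, 0))))
  ncod <- length(cols$a)
  N <- 3 * ncod - S
  dd <- mapply(codon_path_differences, cols$a, cols$b)
  Sd <- sum(dd["sd", ]); Nd <- sum(dd["nd", ])
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) {
    if (p >= 3 / 4) return(NA_real_)
    -3 / 4 * log(1 - 4 / 3 * p)
  }
  Ks <- jc(pS); Ka <- jc(pN)
  undefined <- is.na(Ks) || is.na(Ka) || Ks == 0
  data.frame(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
             Ks = Ks, Ka = Ka,
             ka_ks = if (!undefined) Ka / Ks else NA_real_,
             undefined = undefined)
}

# codons whose third position is fourfold degenerate
FOURFOLD_PREFIXES <- local({
  pre <- unique(substr(SENSE_CODONS, 1, 2))
  keep <- vapply(pre, function(p) {
    aas <- vapply(BASES, function(b) codon_aa(paste0(p, b)), "")
    length(unique(aas)) == 1
  }, TRUE)
  pre[keep]
})

#' Fourfold-degenerate transversion rate (4DTv)
#'
#' Eligible sites are codon columns where both codons belong to a fourfold-
#' degenerate family and agree at the first two positions; the statistic is
#' the fraction of eligible sites whose third positions differ by a
#' transversion.
#'
#' @param aln a \code{codon_alignment}
#' @return list with \code{four_dtv} (NA when no eligible site),
#'   \code{n_sites}, \code{n_transversions}
#' @export
four_dtv <- function(aln) {
  cols <- ungapped_columns(aln)
  n_sites <- 0L; n_tv <- 0L
  for (i in seq_along(cols$a)) {
    ca <- cols$a[i]; cb <- cols$b[i]
    pa <- substr(ca, 1, 2); pb <- substr(cb, 1, 2)
    if (pa != pb) next
    if (!(pa %in% FOURFOLD_PREFIXES)) next
    n_sites <- n_sites + 1L
    b3a <- substr(ca, 3, 3); b3b <- substr(cb, 3, 3)
    if (b3a != b3b && is_transversion(b3a, b3b)) n_tv <- n_tv + 1L
  }
  list(four_dtv = if (n_sites) n_tv / n_sites else NA_real_,
       n_sites = n_sites, n_transversions = n_tv)
}

#' Nucleotide identity of a codon alignment
#'
#' Matching ungapped nucleotide columns over total ungapped columns.
#'
#' @param aln a \code{codon_alignment}
#' @return proportion in [0, 1]
#' @export
pair_identity <- function(aln) {
  cols <- ungapped_columns(aln)
  if (!length(cols$a)) stop("no aligned columns")
  na <- unlist(strsplit(cols$a, ""))
  nb <- unlist(strsplit(cols$b, ""))
  mean(na == nb)
}

#' Divergence statistics for a table of allele pairs
#'
#' @param pairs data.frame with gene_a, gene_b (and optionally locus_id)
#' @param cds_a,cds_b named CDS vectors
#' @return per-pair data.frame of identity, NG86 statistics and 4DTv
#' @export
divergence_table <- function(pairs, cds_a, cds_b) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    aln <- align_codon_pair(cds_a[[pairs$gene_a[i]]],
                            cds_b[[pairs$gene_b[i]]])
    ng <- ng86_ka_ks(aln)
    fd <- four_dtv(aln)
    cbind(data.frame(locus_id = pairs$locus_id[i] %||% NA,
                     gene_a = pairs$gene_a[i], gene_b = pairs$gene_b[i],
                     identity = pair_identity(aln)),
          ng, data.frame(four_dtv = fd$four_dtv,
                         fourfold_sites = fd$n_sites))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
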