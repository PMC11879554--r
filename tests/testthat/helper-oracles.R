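# Independent oracles used to cross-check the package's implementations.
# These deliberately share no code with the package: translation goes through
# seqinr, permutations and site counts are enumerated with plain loops.

.oracle_aa_cache <- new.env(parent = emptyenv())

oracle_translate <- function(codon) {
  hit <- .oracle_aa_cache[[codon]]
  if (!is.null(hit)) return(hit)
  aa <- paste(seqinr::translate(strsplit(codon, "")[[1]]), collapse = "")
  .oracle_aa_cache[[codon]] <- aa
  aa
}

oracle_is_stop <- function(codon) oracle_translate(codon) == "*"

# fraction of the 9 single-base changes of a codon that are synonymous
# (changes to stops count as nonsynonymous), per NG86 site counting
oracle_syn_sites <- function(codon) {
  aa <- oracle_translate(codon)
  s <- 0
  for (pos in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, pos, pos)) next
      mut <- codon
      substr(mut, pos, pos) <- b
      if (!oracle_is_stop(mut) && oracle_translate(mut) == aa) s <- s + 1 / 3
    }
  }
  s
}

oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in oracle_perms(v[-i]))
      out[[length(out) + 1]] <- c(v[i], rest)
  out
}

# mean synonymous/nonsynonymous step counts over shortest pathways between
# two codons, skipping pathways through stop codons (all used if every one
# is blocked)
oracle_path_diff <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(0, 0))
  paths <- oracle_perms(pos)
  stats <- lapply(paths, function(ord) {
    cur <- c1; sd <- 0; nd <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (oracle_is_stop(nxt)) blocked <- TRUE
      syn <- !oracle_is_stop(cur) && !oracle_is_stop(nxt) &&
        oracle_translate(cur) == oracle_translate(nxt)
      if (syn) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd, blocked)
  })
  m <- do.call(rbind, stats)
  use <- if (all(m[, 3] == 1)) rep(TRUE, nrow(m)) else m[, 3] == 0
  c(mean(m[use, 1]), mean(m[use, 2]))
}

# full NG86 on two equal-length, gap-free CDS strings
oracle_ng86 <- function(cds1, cds2) {
  stopifnot(nchar(cds1) == nchar(cds2), nchar(cds1) %% 3 == 0)
  split_codons <- function(s) substring(s, seq(1, nchar(s), 3),
                                        seq(3, nchar(s), 3))
  c1 <- split_codons(cds1); c2 <- split_codons(cds2)
  S1 <- sum(vapply(c1, oracle_syn_sites, 0))
  S2 <- sum(vapply(c2, oracle_syn_sites, 0))
  S <- (S1 + S2) / 2
  N <- 3 * length(c1) - S
  sd <- 0; nd <- 0
  for (i in seq_along(c1)) {
    d <- oracle_path_diff(c1[i], c2[i])
    sd <- sd + d[1]; nd <- nd + d[2]
  }
  pS <- sd / S; pN <- nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = sd, Nd = nd, pS = pS, pN = pN,
       Ks = jc(pS), Ka = jc(pN))
}

# random gap-free CDS pair for oracle comparisons
oracle_random_cds_pair <- function(n_codons, p_mut = 0.05) {
  sense <- setdiff(names(Biostrings::GENETIC_CODE)[
    Biostrings::GENETIC_CODE != "*"], "ATG")
  a <- paste(c("ATG", sample(sense, n_codons - 1, replace = TRUE)),
             collapse = "")
  chars <- strsplit(a, "")[[1]]
  for (i in seq_along(chars)) {
    if (runif(1) < p_mut) {
      cand <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
      old <- chars[i]
      chars[i] <- cand
      codon_i <- (i - 1) %/% 3
      codon <- paste(chars[(codon_i * 3 + 1):(codon_i * 3 + 3)],
                     collapse = "")
      if (oracle_is_stop(codon)) chars[i] <- old   # keep sequences stop-free
    }
  }
  list(a = a, b = paste(chars, collapse = ""))
}

# brute-force evaluation of the three synteny retention rules
oracle_filter_blocks <- function(blocks, homolog_map) {
  keep <- logical(nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    rule1 <- !is.na(homolog_map[b$chrom_a]) &&
      homolog_map[[b$chrom_a]] == b$chrom_b
    la <- b$end_a - b$start_a
    lb <- b$end_b - b$start_b
    rule2 <- (la <= 3 * lb) && (lb <= 3 * la)
    rule3 <- b$coverage_a >= 0.5 && b$coverage_b >= 0.5
    keep[i] <- rule1 && rule2 && rule3
  }
  keep
}

# triple-loop topological overlap
oracle_tom <- function(a) {
  n <- nrow(a)
  a <- as.matrix(a); diag(a) <- 0
  k <- rowSums(a)
  tom <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { tom[i, j] <- 1; next }
      l <- 0
      for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  tom
}
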