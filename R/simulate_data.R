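## Downstream synthetic inputs: expression counts, ChIP tracks, cytosine
## reports and metabolite intensities, all planted from the ground truth of
## generate_haplotype_pair().

# allocate category counts that match the configured fractions within
# rounding, then shuffle
allocate_categories <- function(n, fractions) {
  counts <- floor(fractions * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(fractions * n - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  sample(rep(names(fractions), counts))
}

#' Simulate an expression count matrix with planted allelic bias
#'
#' Counts are negative binomial around per-locus base means. Each allelic
#' locus is planted into one of four bias categories; the HA:HB mean ratio is
#' 1 (no_bias), in (1,2] (smaller), in (2,8) (larger) or >= 8 (largest), with
#' the biased side chosen at random and held consistent across tissues.
#' Across tissues, every locus follows one of \code{n_programs} latent
#' tissue-expression programs (both alleles share the locus's program), which
#' gives the data co-expression module structure without touching the
#' within-tissue allelic ratios.
#'
#' @param config a \code{\link{sim_config}}
#' @param genome result of \code{\link{generate_haplotype_pair}}
#' @param n_programs number of latent tissue programs
#' @param program_sd log-sd of the per-program tissue multipliers
#' @return list with \code{expr} (an \code{expression_matrix} of raw counts)
#'   and \code{truth} (the genome truth extended with \code{planted_bias}:
#'   locus x tissue category, direction and log2 mean ratio, and
#'   \code{expression_program}: locus -> program)
#' @export
simulate_expression <- function(config, genome, n_programs = 3L,
                                program_sd = 0.6) {
  stopifnot(inherits(config, "sim_config"))
  if (config$nb_dispersion <= 0) stop_config("dispersion must be positive")
  set.seed(child_seed(config$seed, 23L))
  truth <- genome$truth
  am <- truth$allele_map
  n_allelic <- nrow(am)
  category <- allocate_categories(n_allelic, config$bias_fractions)
  direction <- ifelse(category == "no_bias", "none",
                      sample(c("HA", "HB"), n_allelic, replace = TRUE))
  lfc_mag <- vapply(category, function(cat) switch(cat,
    no_bias = 0,
    smaller = runif(1, 1e-3, 1),
    larger  = runif(1, 1, 3),
    largest = 3 + stats::rexp(1, rate = 1.5)), 0)
  lfc <- ifelse(direction == "HB", -lfc_mag, lfc_mag)

  tissues <- tissue_names(config$n_tissues)
  reps <- seq_len(config$n_replicates)
  samples <- as.vector(outer(tissues, reps, function(t, r)
    paste0(t, "_rep", r)))
  meta <- data.frame(sample = samples,
                     tissue = rep(tissues, times = config$n_replicates),
                     replicate = rep(paste0("rep", reps),
                                     each = config$n_tissues))
  meta <- meta[order(meta$sample), ]
  rownames(meta) <- NULL

  all_genes <- c(genome$models_a$genes$gene_id, genome$models_b$genes$gene_id)
  base_locus <- stats::setNames(
    stats::rlnorm(n_allelic, log(config$base_mean), 0.5), am$locus_id)
  mu <- matrix(0, nrow = length(all_genes), ncol = length(meta$sample),
               dimnames = list(all_genes, meta$sample))
  # latent tissue-expression programs shared by both alleles of a locus
  profiles <- matrix(stats::rlnorm(n_programs * length(tissues), 0,
                                   program_sd),
                     n_programs, length(tissues),
                     dimnames = list(NULL, tissues))
  program <- sample.int(n_programs, n_allelic, replace = TRUE)
  for (i in seq_len(n_allelic)) {
    b <- base_locus[i]
    fx <- profiles[program[i], meta$tissue]
    mu[am$gene_a[i], ] <- b * 2^(lfc[i] / 2) * fx
    mu[am$gene_b[i], ] <- b * 2^(-lfc[i] / 2) * fx
  }
  ug <- truth$unique_genes
  prog_u <- integer(0)
  if (nrow(ug)) {
    base_u <- stats::rlnorm(nrow(ug), log(config$base_mean), 0.5)
    prog_u <- sample.int(n_programs, nrow(ug), replace = TRUE)
    for (i in seq_len(nrow(ug)))
      mu[ug$gene_id[i], ] <- base_u[i] * profiles[prog_u[i], meta$tissue]
  }
  counts <- matrix(rnbinom(length(mu), mu = mu,
                           size = 1 / config$nb_dispersion),
                   nrow = nrow(mu), dimnames = dimnames(mu))
  lens <- stats::setNames(rep(sum(config$exon_lengths), length(all_genes)),
                          all_genes)
  truth$planted_bias <- do.call(rbind, lapply(tissues, function(tt)
    data.frame(locus_id = am$locus_id, tissue = tt, category = category,
               direction = direction, log2_ratio = lfc)))
  rownames(truth$planted_bias) <- NULL
  truth$expression_program <- data.frame(
    locus_id = c(am$locus_id, ug$locus_id),
    program = c(program, prog_u))
  truth$program_profiles <- profiles
  list(expr = expression_matrix(counts, meta, lens), truth = truth)
}

# bins (1-based indices) overlapped by a 0-based half-open interval
bins_overlapping <- function(start, end, bin_width) {
  (start %/% bin_width + 1L):((end - 1L) %/% bin_width + 1L)
}

#' Simulate binned ChIP tracks for one tissue
#'
#' Background chromatin follows the configured generating chain
#' (\code{hmm_truth}): a hidden state path is sampled per chromosome and mark
#' presence drawn from the state's emission probabilities. On top of that,
#' gene bodies couple the active marks (H3K36me3, H3K4me3, H3K27ac) to
#' expression and bias side: both alleles of unbiased loci and all
#' haplotype-unique genes are mark-positive, while for biased (larger /
#' largest) loci only the dominant allele is positive and the recessive
#' allele is forced to background. Counts are Poisson with mean
#' \code{lambda_bg} (absent) or \code{lambda_bg * mark_enrichment} (present).
#' A control track is independent Poisson background. Optionally the
#' third-exon bins of H3K36me3 gain a further multiplier, used to emulate a
#' tissue with exon-3-skewed deposition.
#'
#' @param config a \code{\link{sim_config}}
#' @param genome result of \code{\link{generate_haplotype_pair}}
#' @param truth truth list containing \code{planted_bias} (from
#'   \code{\link{simulate_expression}})
#' @param tissue tissue label (seeds the tracks independently per tissue)
#' @param exon3_boost multiplier on the H3K36me3 Poisson mean in bins
#'   overlapping third exons of marked genes
#' @return list with \code{tracks_a}, \code{tracks_b} (named lists of
#'   \code{binned_track} per mark), \code{control_a}, \code{control_b} and
#'   \code{state_path} (per-chromosome generating states)
#' @export
simulate_marks <- function(config, genome, truth, tissue = "leaf",
                           exon3_boost = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (config$bin_width != 200) stop_config("bin width must be 200")
  set.seed(child_seed(config$seed, 37L + 101L * match(tissue,
    c("leaf", "root", tissue))))
  active_marks <- intersect(c("H3K36me3", "H3K4me3", "H3K27ac"),
                            config$mark_names)
  pb <- truth$planted_bias[truth$planted_bias$tissue ==
                             truth$planted_bias$tissue[1], ]
  biased <- pb$category %in% c("larger", "largest")
  dominant <- stats::setNames(pb$direction, pb$locus_id)
  am <- truth$allele_map
  model <- config$hmm_truth

  out <- list(state_path = list())
  for (hap in c("a", "b")) {
    gm <- genome[[paste0("models_", hap)]]
    other <- if (hap == "a") "gene_b" else "gene_a"
    this <- if (hap == "a") "gene_a" else "gene_b"
    chroms <- unique(gm$genes$chrom)
    # genes whose bodies carry active marks on this haplotype
    marked <- c(am[[this]][!biased],                       # unbiased loci
                am[[this]][biased & dominant[am$locus_id] ==
                             toupper(paste0("H", hap))],   # dominant allele
                truth$unique_genes$gene_id[
                  truth$unique_genes$haplotype ==
                    toupper(paste0("H", hap))])
    suppressed <- am[[this]][biased & dominant[am$locus_id] !=
                               toupper(paste0("H", hap))]
    tracks <- list()
    states <- list()
    presence <- list()
    for (ch in chroms) {
      n_bins <- genome$chrom_lengths[[ch]] %/% config$bin_width
      s <- integer(n_bins)
      s[1] <- sample.int(model$K, 1, prob = model$initial)
      for (t in seq_len(n_bins - 1))
        s[t + 1] <- sample.int(model$K, 1, prob = model$transition[s[t], ])
      states[[ch]] <- s
      pres <- matrix(rbinom(n_bins * length(config$mark_names), 1,
                            model$emission[s, config$mark_names]),
                     n_bins, length(config$mark_names),
                     dimnames = list(NULL, config$mark_names))
      g <- gm$genes[gm$genes$chrom == ch, ]
      for (i in seq_len(nrow(g))) {
        bb <- bins_overlapping(g$start[i], g$end[i], config$bin_width)
        if (g$gene_id[i] %in% marked) pres[bb, active_marks] <- 1L
        if (g$gene_id[i] %in% suppressed) pres[bb, active_marks] <- 0L
      }
      presence[[ch]] <- pres
    }
    for (mk in config$mark_names) {
      counts <- lapply(chroms, function(ch) {
        pres <- presence[[ch]][, mk]
        lam <- config$lambda_bg *
          ifelse(pres == 1, config$mark_enrichment, 1)
        if (mk == "H3K36me3" && exon3_boost != 1) {
          gch <- gm$genes[gm$genes$chrom == ch, ]
          # third exon in transcript order: genomic rank 3 on "+", 1 on "-"
          want_rank <- stats::setNames(ifelse(gch$strand == "+", 3L, 1L),
                                       gch$gene_id)
          ex3 <- gm$exons[gm$exons$gene_id %in% gch$gene_id, ]
          ex3 <- ex3[ex3$rank == want_rank[ex3$gene_id], ]
          for (i in seq_len(nrow(ex3))) {
            bb <- bins_overlapping(ex3$start[i], ex3$end[i], config$bin_width)
            lam[bb] <- lam[bb] * ifelse(pres[bb] == 1, exon3_boost, 1)
          }
        }
        rpois(length(lam), lam)
      })
      names(counts) <- chroms
      tracks[[mk]] <- binned_track(counts, config$bin_width)
    }
    ctrl <- lapply(chroms, function(ch)
      rpois(genome$chrom_lengths[[ch]] %/% config$bin_width,
            config$lambda_bg))
    names(ctrl) <- chroms
    out[[paste0("tracks_", hap)]] <- tracks
    out[[paste0("control_", hap)]] <- binned_track(ctrl, config$bin_width)
    out$state_path[[toupper(paste0("H", hap))]] <- states
  }
  out
}

#' Simulate per-cytosine methylation reports
#'
#' Per-site methylation probabilities are Beta-distributed with
#' context-specific shapes; methylated read counts are Binomial given a
#' shifted negative-binomial coverage (>= 1 for covered sites, with a
#' configurable zero-coverage fraction exercising the exclusion path).
#'
#' @param config a \code{\link{sim_config}}
#' @param genome result of \code{\link{generate_haplotype_pair}}
#' @return named list (HA, HB) of cytosine-report data.frames
#' @export
simulate_methylation <- function(config, genome) {
  stopifnot(inherits(config, "sim_config"))
  bp <- config$methylation_beta_params
  if (!all(c("CG", "CHG", "CHH") %in% names(bp)))
    stop_config("methylation_beta_params must cover CG, CHG, CHH")
  set.seed(child_seed(config$seed, 53L))
  tri <- c(CG = "CGA", CHG = "CAG", CHH = "CAT")
  out <- list()
  for (hap in c("HA", "HB")) {
    chroms <- grep(paste0("^", hap), names(genome$chrom_lengths),
                   value = TRUE)
    recs <- lapply(chroms, function(ch) {
      n <- config$meth_sites_per_chrom
      pos <- sort(sample.int(genome$chrom_lengths[[ch]], n))
      context <- sample(c("CG", "CHG", "CHH"), n, replace = TRUE,
                        prob = c(0.30, 0.25, 0.45))
      p <- numeric(n)
      for (cx in c("CG", "CHG", "CHH")) {
        sel <- context == cx
        p[sel] <- rbeta(sum(sel), bp[[cx]][1], bp[[cx]][2])
      }
      cov <- 1L + rnbinom(n, mu = config$meth_coverage_mu - 1, size = 5)
      cov[runif(n) < config$meth_zero_fraction] <- 0L
      meth <- rbinom(n, cov, p)
      data.frame(chrom = ch, pos = pos,
                 strand = sample(c("+", "-"), n, replace = TRUE),
                 count_methylated = meth,
                 count_unmethylated = cov - meth,
                 context = context,
                 trinucleotide = tri[context])
    })
    out[[hap]] <- do.call(rbind, recs)
    rownames(out[[hap]]) <- NULL
  }
  out
}

#' Simulate a two-group metabolite intensity table with planted DAMs
#'
#' Intensities are log-normal; planted up/down metabolites are shifted by
#' +/- \code{metabolite_effect} in log2 space between the groups, and
#' replicates add Gaussian log2 noise.
#'
#' @param config a \code{\link{sim_config}}
#' @param groups two group labels (group 1 is the "up" side)
#' @return list with \code{table} (metabolite x sample data.frame) and
#'   \code{planted_dams} (metabolite, status in up/down/null)
#' @export
simulate_metabolome <- function(config, groups = c("root", "leaf")) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_replicates < 2) stop_config("need >= 2 replicates per group")
  if (config$n_dam_up + config$n_dam_down > config$n_metabolites)
    stop_config("planted DAMs exceed the number of metabolites")
  set.seed(child_seed(config$seed, 71L))
  n <- config$n_metabolites
  ids <- sprintf("met%04d", seq_len(n))
  status <- sample(rep(c("up", "down", "null"),
                       c(config$n_dam_up, config$n_dam_down,
                         n - config$n_dam_up - config$n_dam_down)))
  base <- rnorm(n, 15, 2)
  shift <- ifelse(status == "up", config$metabolite_effect / 2,
                  ifelse(status == "down", -config$metabolite_effect / 2, 0))
  reps <- seq_len(config$n_replicates)
  tab <- data.frame(metabolite = ids)
  for (r in reps)
    tab[[paste0(groups[1], "_", r)]] <-
      2^(base + shift + rnorm(n, 0, config$metabolite_noise_sd))
  for (r in reps)
    tab[[paste0(groups[2], "_", r)]] <-
      2^(base - shift + rnorm(n, 0, config$metabolite_noise_sd))
  list(table = tab,
       planted_dams = data.frame(metabolite = ids, status = status))
}

#' Run the full generator and write every pipeline input to disk
#'
#' @param config a \code{\link{sim_config}}
#' @param outdir output directory (created if absent)
#' @param tissues_with_marks tissues for which ChIP tracks are written; the
#'   second one (if any) receives the exon-3 H3K36me3 boost
#' @param exon3_boost see \code{\link{simulate_marks}}
#' @return invisible list with the generated objects, the ground truth and a
#'   \code{paths} manifest
#' @export
simulate_all <- function(config, outdir,
                         tissues_with_marks = c("leaf", "root"),
                         exon3_boost = 2) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)
  genome <- generate_haplotype_pair(config)
  write_gene_models(genome$models_a, p("genes_ha.gff3"))
  write_gene_models(genome$models_b, p("genes_hb.gff3"))
  write_cds_fasta(genome$cds_a, p("cds_ha.fa"))
  write_cds_fasta(genome$cds_b, p("cds_hb.fa"))
  write_synteny(genome$synteny, p("synteny.tsv"))

  ex <- simulate_expression(config, genome)
  write_counts(ex$expr, p("counts.tsv"), p("gene_lengths.tsv"))
  truth <- ex$truth

  dir.create(p("marks"), showWarnings = FALSE)
  marks <- list()
  for (ti in seq_along(tissues_with_marks)) {
    tissue <- tissues_with_marks[ti]
    mk <- simulate_marks(config, genome, truth, tissue = tissue,
                         exon3_boost = if (ti == 2) exon3_boost else 1)
    marks[[tissue]] <- mk
    for (hap in c("a", "b")) {
      for (m in names(mk[[paste0("tracks_", hap)]]))
        write_bedgraph(mk[[paste0("tracks_", hap)]][[m]],
                       p("marks", sprintf("%s_h%s_%s.bedGraph", tissue, hap, m)))
      write_bedgraph(mk[[paste0("control_", hap)]],
                     p("marks", sprintf("%s_h%s_control.bedGraph", tissue, hap)))
    }
  }
  truth$state_path <- lapply(marks, `[[`, "state_path")

  meth <- simulate_methylation(config, genome)
  write_cytosine_report(meth$HA, p("meth_ha.tsv"))
  write_cytosine_report(meth$HB, p("meth_hb.tsv"))

  met <- simulate_metabolome(config)
  write_metabolite_table(met$table, p("metabolites.tsv"))
  truth$planted_dams <- met$planted_dams

  data.table::fwrite(truth$allele_map, p("truth_allele_map.tsv"), sep = "\t")
  data.table::fwrite(truth$expression_program,
                     p("truth_expression_program.tsv"), sep = "\t")
  data.table::fwrite(truth$planted_bias, p("truth_planted_bias.tsv"),
                     sep = "\t")
  data.table::fwrite(truth$planted_dams, p("truth_planted_dams.tsv"),
                     sep = "\t")

  invisible(list(genome = genome, expr = ex$expr, marks = marks,
                 methylation = meth, metabolome = met, truth = truth,
                 paths = list(
                   gff_a = p("genes_ha.gff3"), gff_b = p("genes_hb.gff3"),
                   cds_a = p("cds_ha.fa"), cds_b = p("cds_hb.fa"),
                   synteny = p("synteny.tsv"),
                   counts = p("counts.tsv"),
                   gene_lengths = p("gene_lengths.tsv"),
                   marks_dir = p("marks"),
                   meth_a = p("meth_ha.tsv"), meth_b = p("meth_hb.tsv"),
                   metabolites = p("metabolites.tsv"))))
}
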