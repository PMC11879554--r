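---
title: "Methods: haplotype-resolved allelic expression and epigenome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype-resolved allelic expression and epigenome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`haplase` implements the analysis chain used to study allelic imbalance in a
highly heterozygous diploid plant genome assembled into two phased haplotypes
(HA and HB): pairing allelic genes through synteny, quantifying their sequence
divergence, classifying per-tissue allele-specific expression (ASE),
segmenting the epigenome into chromatin states, relating histone-mark
occupancy and DNA methylation to the dominant allele, profiling H3K36me3
positionally, calling differential metabolites, and detecting co-expression
modules. A synthetic-data generator produces every input with known ground
truth, so each stage is testable end to end without any external sequencing
data.

The `analysis/` directory contains the numbered drivers
(`01_simulate.R` … `09_coexpression.R`); every computation they perform lives
in the package and is unit-tested.

# Allele pairing

Synteny blocks between the haplotypes are filtered by three rules before any
gene is paired: (i) the two regions must lie on a designated homologous
chromosome pair, (ii) neither segment may exceed three times the length of
its counterpart, and (iii) the aligned portion must cover at least 50% of
each region. Both boundary cases are read inclusively: a ratio of exactly 3 and a
coverage of exactly 0.5 are retained, treating the thresholds as limits
that may be met but not crossed. The homolog map is an explicit
input, defaulting to equal chromosome indices (`HA_chrN` with `HB_chrN`).
Region coverage is taken from the block table; when built from anchors it is
the aligned anchor span over the region span, evaluated on both sides.

Within retained blocks, genes are paired to their closest counterpart on the
opposite haplotype by global CDS alignment identity, and a pair is kept only
when it is a *reciprocal* best match. Reciprocity is a deliberate design choice — it keeps pairs strictly
one-to-one (two genes per locus, the defining property of an allelic
locus) and gives a determinate resolution of multi-gene ties inside a
block, which closest-match pairing alone does not.

# Divergence statistics

Each paired CDS couple is translated and aligned globally at the protein
level (match +1, mismatch 0, gap −1), then back-threaded to codons. Gapped
columns are excluded from all site counts. Sequences whose length is not a
multiple of 3 are trimmed with a warning; a pair with internal stop codons in
both members is rejected.

Ka/Ks uses the Nei–Gojobori (1986) counting method: each codon position
contributes the fraction of its three possible changes that are synonymous,
site totals are averaged between the two sequences, and observed differences
at multi-difference codons are averaged over all shortest mutational
pathways. Pathways passing through stop codons are excluded (all pathways are
used if every one is blocked), and changes *to* stop codons count as
nonsynonymous in the site fractions. Proportions are corrected with
Jukes–Cantor, `d = -(3/4) log(1 - (4/3) p)`; `p >= 3/4` is flagged
undefined, as is Ka/Ks when Ks = 0. NG86 is a deliberate concrete choice among the counting-method family:
it is the most transparent member — fully checkable against a brute-force pathway-enumeration oracle, which the test
suite does at 1e-12 on random 300-codon pairs.

4DTv is the fraction of fourfold-degenerate third-codon sites (both codons in
a fourfold family, first two positions identical) whose third bases differ by
a transversion. Only the standard genetic code is supported.

# ASE classification

Counts are normalized to TPM (each sample sums to 1e6) for testing, or FPKM
(`count * 1e9 / (library * length)`) for expression binning. Per tissue,
a locus with combined mean TPM below 1 is *not expressed*. Otherwise the
four-way scheme applies: no bias when `P >= 0.05`; at `P < 0.05`, fold
changes up to 2 are *smaller*, between 2 and 8 *larger*, and 8 or more
*largest* (boundaries at exactly 2 and 8 go to smaller and largest respectively).
The per-locus test is a two-sided Welch t-test on `log2(TPM + 1)` across replicates, with no multiple-testing correction: the categories are defined on raw
per-tissue `P < 0.05`, and correcting would redefine them. Fold changes
are computed on replicate means with a pseudocount of 0.1 TPM.

A locus is an ASEG when at least one tissue calls it larger/largest
(FC > 2, P < 0.05) and all such tissues agree on the biased side;
conflicting directions demote it to balanced. Under this "one qualifying tissue, consistent direction" rule the
dominance summary is pure count arithmetic — e.g. 1677 + 1724 = 3401 ASEGs
among 35 307 loci gives 4.75% / 4.89% / 90.36% — which the acceptance
suite checks exactly.

# Chromatin states

ChIP read counts in fixed 200-bp bins are binarized per mark: a bin is
positive when its count is improbable under a Poisson background,
`P(X >= count; lambda) < 1e-4`, where `lambda` is the input-control count
scaled to the mark's library size and floored at the genome-wide mean of the
scaled control (so empty control bins cannot promote single reads). Without
a control, the global mean mark count serves as `lambda`.

The state model is a hidden Markov model with independent Bernoulli
emissions per mark. Baum–Welch EM runs over chromosomes as independent
sequences sharing one parameter set; emissions are initialized from
k-means++ cluster means of the binary vectors and transitions start at 0.9
self-transition. EM stops when the log-likelihood gain falls below `tol`
(default 1e-4) or at `max_iter` (default 100); the trace is retained and is
non-decreasing by construction. Decoding is maximum-posterior per bin
(forward–backward) rather than Viterbi, matching per-bin state assignment
semantics; posterior ties resolve to the lowest state index. Emission
probabilities are clamped to `[1e-6, 1 - 1e-6]` for numerical stability, and
the forward pass uses per-step scaling.

The number of states is not selected automatically: `sweep_state_count()`
reports log-likelihood and BIC across candidate K and leaves the choice to
the analyst, since in practice the state count is picked for
interpretability. Feature enrichment of a state is
`(overlap/state coverage) / (feature coverage/genome)`, in base pairs.

# Mark asymmetry and methylation

Occupancy is RPKM-style over the gene body with a configurable flank
(default 1 kb): overlap-weighted read sum times `1e9 / (library * length)`.
The occupancy window (gene body ± flank) is a package convention; the
statistic is scale-invariant by construction.
Class-level summaries report the median dominant-minus-recessive difference,
a two-sided Wilcoxon rank-sum P against the balanced class, and the
coefficient of variation per class and mark. DNA methylation is quantified
but plays no role in ASEG classification, so that any association between methylation and expression bias remains
an observable result rather than a built-in assumption.

The weighted methylation level of a region is total methylated reads over
total coverage across covered cytosines of the requested context;
zero-coverage sites are excluded, and an empty region is flagged undefined
rather than returned as 0.

# Positional profiles

Metagene profiles rescale each gene body to 20 bins and profile 1-kb flanks
in fixed 50-bp bins (20 per kb, matching the body-bin granularity); signal
is per-kb per-million density, so a spatially constant track profiles flat
at its constant density regardless of stratification. Minus-strand genes are
reversed so profiles read 5′→3′. Flanks beyond chromosome ends are truncated
and averaged over the covered width; genes shorter than the body-bin count
are skipped with a warning. FPKM strata are `{0}`, `(0,1]`, `(1,10]`, `(10,20]`, `(20,∞)`;
range boundaries are read right-closed, so an FPKM of exactly 10 falls in
the 1–10 bin. The exon-level summary reports per-kb per-million
signal over the first three exons in transcript order, the 5′ UTR plus first CDS segment, and a strand-oriented TSS ± 1 kb
window.

# Metabolome

Differential metabolites require all three gates: `VIP >= 1`,
`|log2FC| >= 1`, and Welch `P < 0.05` on log2 intensities. VIP comes from a
PLS-DA fitted by NIPALS on autoscaled intensities against the centered
two-group indicator, `VIP_j = sqrt(p * sum_a(SSY_a w_aj^2) / sum_a SSY_a)`,
which guarantees `sum(VIP^2) = p` for the modeled metabolites. We use
PLS-DA rather than OPLS-DA: the orthogonal filtering step changes neither
the thresholding logic nor the VIP identity, at the cost of extra machinery.
Two components are the default. Zero intensities are imputed to half the
metabolite's minimum positive value (a common metabolomics convention) and
flagged; zero-variance metabolites are excluded from the PLS model with an
NA score.

One caveat worth naming: when *every* metabolite discriminates the groups
(the generator's default composition plants 423 + 260 = 683 DAMs among 683
compounds, with no nulls), the VIP gate cannot pass them all — mean VIP² is identically 1 — so roughly
the weaker half fall below threshold. The pipeline does not force such a table to come back fully significant;
it reports what the thresholds yield.

# Co-expression

The network is unsigned: adjacency `|cor|^power`, with the power chosen as
the smallest candidate whose scale-free topology fit R² exceeds 0.85
(log-frequency vs log-connectivity regression over 10 connectivity bins);
if none qualifies the maximum candidate is used with a warning. TOM is
`(sum_u a_iu a_uj + a_ij) / (min(k_i,k_j) + 1 - a_ij)` with unit diagonal.
Modules come from average-linkage clustering on `1 - TOM` with a *static*
cut, a minimum size of 40 and iterative eigengene merging at correlation
distance 0.15; the dynamic hybrid tree cut is deliberately out of scope.
The default cut height is 0.95: on a `1 - TOM` dissimilarity the
uninformative merges concentrate just below 1, so a quantile-based cut
lands above them and collapses everything into one cluster, whereas a fixed
0.95 separates planted blocks cleanly (this is verified in the tests).
Eigengenes are unit-norm first principal components with the sign anchored
to positive correlation with the module's mean expression; module–trait
association is a Pearson correlation with a t-distribution P on n−2 degrees
of freedom.

# The synthetic-data generator

The generator's defaults are the reference conditions the pipeline targets:

* 96.35% expected allelic CDS identity. Divergence is applied codon-wise
  with a transition:transversion ratio of 2; the substitution count is
  Binomial(L, 1 − identity), so the identity target is met in expectation,
  and nonsynonymous proposals are retained with probability 0.3 (stops
  never), giving median Ka/Ks well below 1 — a purifying-selection analogue
  without a full evolutionary simulator.
* Bias categories `no_bias/smaller/larger/largest` at 0.90/0.03/0.04/0.03 by
  default, planted as HA:HB mean-ratio shifts of 1, (1,2], (2,8) and ≥8 with
  the biased side held consistent across tissues; counts are negative
  binomial (dispersion 0.05, base mean 200, 9 tissues × 3 replicates).
* Genes have a fixed 3-exon architecture (400/500/600 bp exons, 200-bp
  introns, 100-bp 5′ UTR, 200-bp 3′ UTR), which keeps exon-position logic
  exercised while making the CDS length (1200 nt) deterministic.
* Background chromatin follows a 4-state generating chain (active,
  Polycomb-like, heterochromatic, quiescent); gene bodies couple the active
  marks (H3K36me3, H3K4me3, H3K27ac) to expression and bias side — the
  dominant allele of a biased locus is mark-positive, the recessive allele
  is forced to background — with Poisson counts at background mean 1 and
  8-fold enrichment when present. A root-like tissue can additionally double
  H3K36me3 over third exons (in transcript order).
* Methylation levels are Beta-distributed per context with means 0.8107
  (CG), 0.5423 (CHG), 0.1037 (CHH) at concentration 2; coverage is a shifted
  negative binomial ≥ 1 with a 2% zero-coverage fraction exercising the
  exclusion path.
* The metabolite table defaults to an all-DAM composition: 683 compounds,
  423 planted up and 260 down at |log2FC| = 3 with replicate noise SD 0.3
  (log2 scale).
* Across tissues each locus follows one of 3 latent expression programs
  (log-sd 0.6), shared by both alleles, giving the data genuine
  co-expression structure without touching within-tissue allelic ratios.

One master seed drives everything; submodules derive child seeds at fixed
offsets so any stage regenerates independently, and identical configurations
produce byte-identical files.

What the generator does *not* emulate: read-level artifacts (mapping bias,
duplicates, bisulfite conversion failure), linked variation along
chromosomes, realistic gene-length and exon-number variation, correlated
replicate structure beyond shared means, and ChIP replicate variance (the noise levels are free parameters of the
generator, not estimates from any real library). Passing tests
therefore demonstrate correctness of the statistical machinery under the
stated generative model, not robustness to every artifact of real libraries.

# Problem sizes

The shipped analyses and tests run at desk scale, chosen to finish in
minutes on one core: a 2-chromosome-pair, 100-locus genome for the
end-to-end workflow; 50 000 bins × 5 marks for chromatin-state parameter
recovery (emission L∞ error ≤ 0.05 after label matching); 1000 loci ×
9 tissues for ASE recovery (≥ 90% of planted larger/largest loci recovered
with the correct direction, ≤ 5% false ASEGs among unbiased loci); 100
random 300-codon pairs for the NG86 oracle equivalence; 100 000 cytosines
for methylation targets. Genome-scale figures (tens of thousands of loci, hundreds of megabases of
signal) are outside these desk-scale runs, and the package makes no claims
at that scale.

# Known limitations

* NG86 only; maximum-likelihood Ka/Ks and Ks-peak dating are out of scope.
* The static tree cut can split a sprawling module that a dynamic cut would
  keep; `cut_height` is exposed for that reason.
* `pair_alleles` resolves reciprocal best matches greedily block by block;
  a gene whose best counterpart lies in a different retained block than the
  one linking them is left unpaired rather than globally optimized.
* The Welch test on three replicates has limited power near the FC = 2
  boundary; recovery figures are reported at the planted effect sizes.
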