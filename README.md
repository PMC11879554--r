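# haplase

Analysis of allelic imbalance in a haplotype-resolved diploid plant genome.
When a heterozygous genome is assembled into two complete phased haplotypes
(HA and HB), each locus carries two resolvable alleles, and the interesting
questions become quantitative: which allele pairs exist (synteny), how far
they have diverged (Ka/Ks, 4DTv, identity), which are expressed
allele-specifically and in which tissues, and whether the biased side
carries a distinct epigenetic state (histone marks, chromatin states, DNA
methylation) — plus the downstream metabolic and co-expression context.

`haplase` implements that chain as a tested R package with an analysis
workflow on top, and ships a synthetic-data generator that emulates every input with known
ground truth, so the whole pipeline is verifiable without any external
sequencing data.

## What it computes

* **Allele pairing** — synteny blocks filtered by three rules (homologous
  chromosome pair; segment length ratio ≤ 3; aligned coverage ≥ 50% on both
  sides), then reciprocal-best CDS-identity matching within blocks;
  unmatched genes are haplotype-unique.
* **Divergence** — codon-aware protein-level alignment; NG86 Ka/Ks with
  fractional site counting, shortest-pathway averaging and Jukes–Cantor
  correction `d = −(3/4)·ln(1 − (4/3)p)`; 4DTv (transversions at
  fourfold-degenerate third positions); percent identity.
* **ASE** — TPM/FPKM normalization; per-tissue four-way bias categories
  (no bias at P ≥ 0.05; smaller FC ≤ 2, larger 2 < FC < 8, largest FC ≥ 8,
  all at P < 0.05, Welch t-test on log2(TPM+1)); aggregation into
  HA > HB / HA < HB / HA = HB dominance classes.
* **Chromatin states** — Poisson-tail binarization of 200-bp ChIP bins
  against an input control; K-state HMM with independent Bernoulli
  emissions fitted by Baum–Welch; posterior decoding; per-state feature
  enrichment; a state-count sweep reporting log-likelihood and BIC.
* **Mark asymmetry & methylation** — RPKM-style gene occupancy per
  haplotype; dominant-minus-recessive differences per dominance class with
  Wilcoxon tests and CVs; weighted methylation level
  Σ methylated / Σ coverage per context (CG/CHG/CHH).
* **Positional profiles** — metagene curves (TSS−1 kb … TES+1 kb, 20 body
  bins, 50-bp flank bins) stratified by FPKM bins `{0, 0–1, 1–10, 10–20,
  >20}`; exon 1/2/3, 5′ UTR+CDS1 and TSS ± 1 kb signal.
* **Metabolome** — NIPALS PLS-DA VIP scores (`Σ VIP² = p` identity) and DAM
  calls at VIP ≥ 1, |log2FC| ≥ 1, P < 0.05.
* **Co-expression** — soft threshold by scale-free fit > 0.85, unsigned
  TOM, static-cut average-linkage modules (min size 40, eigengene merge at
  0.15), module–trait correlation.

## Worked example

The `analysis/` scripts run the full chain on a generated 2-chromosome-pair,
100-locus dataset and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_pair_alleles.R
Rscript analysis/03_divergence.R
Rscript analysis/04_ase.R          # ... through 09_coexpression.R
```

Output of the first stages (verbatim):

```
Wrote synthetic inputs to results/simdata
  allele pairs: 80, haplotype-unique genes: 20
Retained 2/2 blocks; paired 80 loci (100.0% of truth); 10 + 10 unique genes
Divergence over 80 allele pairs:
  mean CDS identity: 96.32%
  median Ka/Ks: 0.589 (91% of pairs under purifying selection)
  mean 4DTv: 0.018 over 197 fourfold sites/pair on average
Haplotype dominance classes:
    class  n percent
 HA_gt_HB  2    2.50
 HA_lt_HB  3    3.75
 HA_eq_HB 75   93.75
ASEGs: 5 of 80 loci; cross-tissue consistent bias at 3.75% of loci
```

Reading: all 80 planted allele pairs were recovered from the filtered
synteny blocks; their coding sequences are ~96.3% identical with median
Ka/Ks below 1 (purifying-selection analogue of the generator); five loci
qualify as allele-specifically expressed with a consistent dominant
haplotype, the rest are balanced. Later stages report the H3K36me3
occupancy excess on the dominant allele, genome-wide methylation near
81%/54%/10% for CG/CHG/CHH, the root-vs-leaf exon-3 H3K36me3 ratio, DAM
counts, and two co-expression modules matching the planted expression
programs.

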