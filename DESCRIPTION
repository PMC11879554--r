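Package: haplase
Title: Haplotype-Resolved Allele-Specific Expression and Epigenome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for phased diploid plant genomes: syntenic
    allele pairing between haplotypes with rule-based block filtering,
    codon-aware allele divergence statistics (NG86 Ka/Ks, 4DTv, percent
    identity), per-tissue allelic expression bias classification and
    haplotype-dominance aggregation, chromatin-state segmentation with a
    multivariate Bernoulli hidden Markov model over binarized 200-bp ChIP
    bins, haplotype histone-mark asymmetry and weighted DNA-methylation
    quantification, positional (metagene and exon-level) signal profiling,
    PLS-DA VIP differential-metabolite calling, and co-expression module
    detection via topological overlap. Includes a synthetic-data generator
    that emulates every pipeline input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    seqinr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
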