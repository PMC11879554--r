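## Genetic-code lookups shared by the CDS generator and the divergence
## statistics. Standard code only.

SENSE_CODONS <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc[gc != "*"])
})
STOP_CODONS <- c("TAA", "TAG", "TGA")
TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
BASES <- c("A", "C", "G", "T")
PURINES <- c("A", "G")

codon_aa <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

is_transversion <- function(b1, b2) {
  (b1 %in% PURINES) != (b2 %in% PURINES)
}
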