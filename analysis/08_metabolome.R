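#!/usr/bin/env Rscript
# Differential metabolite calling: PLS-DA VIP (NIPALS, 2 components) plus
# thresholds VIP >= 1, |log2FC| >= 1, Welch P < 0.05 on the root-vs-leaf
# intensity table.

library(haplase)

d <- "results/simdata"
mt <- metabolite_table(read_metabolite_table(file.path(d, "metabolites.tsv")))
vip <- plsda_vip(mt, n_components = 2)
dam <- call_dams(mt, vip)
write.table(dam$calls, "results/dam_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(as.list(dam$summary), "results/dam_summary.json",
                     auto_unbox = TRUE)

planted <- read.delim(file.path(d, "truth_planted_dams.tsv"))
tab <- table(called = dam$calls$status,
             planted = planted$status[match(dam$calls$metabolite,
                                            planted$metabolite)])
cat(sprintf("DAMs: %d up, %d down of %d metabolites (VIP >= 1, |log2FC| >= 1, P < 0.05)\n",
            dam$summary["n_up"], dam$summary["n_down"], dam$summary["n_total"]))
cat("Called vs planted status:\n")
print(tab)
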