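#!/usr/bin/env Rscript
# Step 2 — collapse sequences into named haplotypes and tabulate
# frequencies; mark which haplotypes are new to the reference library.

library(barcodegap)

records <- join_metadata(read_barcode_fasta("results/data/sequences.fasta"),
                         read_sample_metadata("results/data/samples.tsv"))
reference <- read_reference_library("results/data/reference.fasta",
                                    "results/data/reference.tsv")

aligned <- trim_to_region(records, mode = "auto")
cat(sprintf("aligned %d sequences to a shared %d bp window\n",
            nrow(aligned$records), aligned$length))

tab <- name_haplotypes(collapse_haplotypes(aligned))
tab <- new_vs_reference(tab, reference)
write_haplotype_table(tab, "results/haplotypes.tsv")

cat(sprintf("%d haplotypes across %d species groups; %d new to the reference\n",
            nrow(tab), length(unique(tab$group)), sum(tab$new)))
cat("largest groups:\n")
top <- tab[order(-tab$count), c("group", "haplotype", "count", "frequency")]
print(utils::head(top, 8), row.names = FALSE)
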