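#!/usr/bin/env Rscript
# Step 5 — molecular identification against the reference library,
# discrepancy/hybrid flagging, and the geography-structured population
# distance table for the species sampled at several locations.

library(barcodegap)

records <- join_metadata(read_barcode_fasta("results/data/sequences.fasta"),
                         read_sample_metadata("results/data/samples.tsv"))
reference <- read_reference_library("results/data/reference.fasta",
                                    "results/data/reference.tsv")
aligned <- trim_to_region(records, mode = "auto")

tab <- name_haplotypes(collapse_haplotypes(aligned))
asg <- identify_all(tab, reference)
flags <- flag_discrepancies(asg, tab, aligned$records)
write.table(flags, "results/identification_flags.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("flagged %d discrepancies (%d with hybrid evidence) among %d samples:\n",
            sum(flags$discrepancy), sum(flags$hybrid_evidence), nrow(flags)))
print(flags[flags$discrepancy, ], row.names = FALSE)

# population table over the geographically split species (several sampling
# locations -> location-resolved haplotype groups)
multi_loc <- unique(aligned$records$species[
  ave(aligned$records$location, aligned$records$species,
      FUN = function(x) length(unique(x))) > 1])
for (sp in multi_loc) {
  sub <- aligned$records[aligned$records$species == sp &
                         !(aligned$records$hybrid_suspect %in% TRUE), ]
  tab_loc <- name_haplotypes(collapse_haplotypes(sub,
                                                 group_key = "species+location"))
  if (nrow(tab_loc) < 2) next
  dm <- k2p_matrix(tab_loc)
  groups <- split(tab_loc$haplotype, sub(".* @ ", "", tab_loc$group))
  pt <- population_table(dm, groups)
  out <- sprintf("results/population_table_%s.tsv", gsub("\\W+", "_", sp))
  write_population_table(pt, out)
  cat(sprintf("\npopulation distances for %s (written to %s):\n", sp, out))
  print(pt, row.names = FALSE)
}
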