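#!/usr/bin/env Rscript
# Step 2 — genome composition statistics.
#
# Reads the simulated dataset and computes, per strain, the composition row
# of a Table-1-style report: overall GC, CDS GC, GC at third codon
# positions, coding density, assembled size, and the IS-element landscape
# (per-family counts and the largest element-free region).  Pseudogene
# exclusion from the CDS statistics happens in step 3 once calls exist;
# here every annotated CDS counts.
suppressMessages(library(reducto))

rd <- read_dataset("results/dataset")
reports <- lapply(rd$strains, stats_report)

tab <- do.call(rbind, lapply(reports, function(s) {
  data.frame(strain_id = s$strain_id,
             subspecies = rd$meta$subspecies[match(s$strain_id, rd$meta$strain_id)],
             assembled_bp = s$assembled_size,
             gc_pct = s$printed["overall_gc_pct"],
             cds_gc_pct = s$printed["cds_gc_pct"],
             gc3_pct = s$printed["gc3_pct"],
             coding_pct = s$printed["coding_density_pct"],
             n_cds = s$n_cds, n_is = sum(s$is_counts),
             is_free_bp = s$is_free_width,
             stringsAsFactors = FALSE)
}))
rownames(tab) <- NULL
write.table(tab, "results/genome_stats.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

fam <- do.call(rbind, lapply(reports, function(s) {
  if (!length(s$is_counts)) return(NULL)
  data.frame(strain_id = s$strain_id, family = names(s$is_counts),
             count = unname(s$is_counts), stringsAsFactors = FALSE)
}))
write.table(fam, "results/is_families.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

print(tab, row.names = FALSE)
agg <- tapply(tab$n_is, tab$subspecies, mean)
cat(sprintf("\nmean IS load: lactis-like %.1f vs bulgaricus-like %.1f (planted contrast)\n",
            agg["lactis"], agg["bulgaricus"]))
cat("largest IS-free region:",
    tab$strain_id[which.max(tab$is_free_bp)],
    max(tab$is_free_bp), "bp\n")
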