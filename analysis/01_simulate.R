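#!/usr/bin/env Rscript
# Step 1 — simulate the study dataset.
#
# Builds the planted ancestral pangenome and evolves the 5+5 strain panel
# (lactis-like vs bulgaricus-like clade) with ground truth, then writes the
# dataset (FASTA + GFF3 + protein FASTA + truth/metadata TSV) together with
# the MLST scheme and the synthetic pathway definitions that later steps
# consume.  Everything downstream of this script works from these files.
suppressMessages(library(reducto))

seed <- 1L
out <- "results/dataset"
study <- simulate_study(seed = seed)
emit_dataset(study$strains, out)

# sidecar files: marker scheme and pathway definitions
write.table(data.frame(locus = names(study$mlst_scheme),
                       gene_id = unname(study$mlst_scheme)),
            file.path(out, "mlst_scheme.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
yaml::write_yaml(list(substrates = lapply(study$pathway_defs, function(d) {
  lapply(d$groups, function(g) list(genes = g$genes,
                                    transporter = g$transporter))
})), file.path(out, "pathway_defs.yaml"))

cat("strains:", length(study$strains), " genes:",
    nrow(study$ancestor$gene_table), " seed:", seed, "\n")
cat("planted statuses:\n")
print(table(study$truth$status))
cat("planted clade-specific sets:",
    length(study$planted$spec_lactis), "lactis /",
    length(study$planted$spec_bulg), "bulgaricus;",
    "rescue pseudogenisations:",
    length(study$planted$rescue_lactis), "/",
    length(study$planted$rescue_bulg), "\n")
cat("dataset written to", out, "\n")
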