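#!/usr/bin/env Rscript
# Step 3 — pseudogene-fragment detection.
#
# For every strain, every annotated CDS is searched (six-frame, translated)
# against the proteins of the other strains; CDS aligning with anomalously
# longer or shorter proteins (strict +/-10%) have those proteins
# back-aligned to the genomic context, and a CDS is marked a
# pseudogene-fragment when the chained back-alignment exceeds the CDS and
# shows a frameshift or in-frame stop.  Calls are scored against the
# planted truth.
suppressMessages(library(reducto))

rd <- read_dataset("results/dataset")
pro <- strain_proteomes(rd$strains)
params <- pseudo_params()

calls <- do.call(rbind, lapply(names(rd$strains), function(sid) {
  message("calling ", sid)
  call_pseudogenes(rd$strains[[sid]], pro[pro$strain_id != sid, ], params)
}))
write.table(calls, "results/pseudogene_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

per_strain <- table(calls$strain_id[calls$verdict == "pseudogene_fragment"])
cat("pseudogene-fragment calls per strain:\n")
print(per_strain)

m <- caller_metrics(calls, rd$truth, rd$strains)
cat(sprintf("\nagainst planted truth: %d false positives / %d intact CDS tested; recall %.0f%% of %d detectable lesions; worst frameshift localisation %d bp\n",
            m$false_positives, m$n_intact_tested, 100 * m$recall,
            m$n_target, m$max_fs_error))
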