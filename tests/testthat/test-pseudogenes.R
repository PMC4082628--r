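# gene with helpers to plant lesions at exact positions
make_gene <- function(n_codons, seed = 1) {
  set.seed(seed)
  reducto:::random_orf(3 * n_codons, 0.5)
}

test_that("length anomaly uses a strict +/-10% threshold on the CDS length", {
  expect_false(length_anomaly(100, 100))
  expect_true(length_anomaly(100, 111))   # 11% longer
  expect_false(length_anomaly(100, 110))  # exactly 10%: not anomalous
  expect_true(length_anomaly(100, 89))    # 11% shorter
  expect_false(length_anomaly(100, 90))
  expect_error(length_anomaly(0, 50))
})

test_that("translated search finds an exact back-translation at full score", {
  g <- make_gene(100, seed = 2)
  prot <- sub("\\*$", "", reducto:::translate_nt(g))
  db <- data.frame(strain_id = "ref", protein_id = c("target", "decoy"),
                   sequence = c(prot, random_protein(90)),
                   stringsAsFactors = FALSE)
  hits <- translated_search(g, db, pseudo_params())
  expect_equal(hits$protein[1], "ref|target")
  expect_equal(hits$strand[1], "+")
  expect_equal(hits$frame[1], 0)
  mat <- reducto:::get_submat("BLOSUM62")
  pv <- strsplit(prot, "")[[1]]
  expect_equal(hits$score[1], sum(mat[cbind(pv, pv)]))
  # reverse-complement CDS is found on the minus strand
  hits_rc <- translated_search(reducto:::revcomp_chr(g), db, pseudo_params())
  expect_equal(hits_rc$protein[1], "ref|target")
  expect_equal(hits_rc$strand[1], "-")
})

test_that("degenerate translated-search inputs are rejected", {
  expect_error(translated_search("AT", data.frame(strain_id = "r",
    protein_id = "p", sequence = "MKV")), "shorter than 3")
  expect_error(translated_search("ATGAAA", data.frame(strain_id = character(0),
    protein_id = character(0), sequence = character(0))), "empty")
})

test_that("a mid-gene frameshift confines single-frame alignments to one side", {
  g <- make_gene(120, seed = 3)
  prot <- sub("\\*$", "", reducto:::translate_nt(g))
  # +1 insertion after codon 60
  gfs <- paste0(substr(g, 1, 180), "G", substr(g, 181, nchar(g)))
  genome <- paste0(random_dna_chr(300), gfs, random_dna_chr(300))
  back <- back_align(prot, genome, 301, 300 + nchar(gfs), pseudo_params())
  seg <- back$segments[back$segments$chained, ]
  expect_gt(nrow(seg), 1)
  expect_true(all(seg$p_end - seg$p_start + 1 <= 0.62 * nchar(prot)))
  expect_equal(length(back$frameshifts), 1)
  expect_lt(abs(back$frameshifts[1] - (300 + 180)), 60)
})

test_that("back-alignment of an intact gene yields one clean segment", {
  g <- make_gene(150, seed = 4)
  prot <- sub("\\*$", "", reducto:::translate_nt(g))
  genome <- paste0(random_dna_chr(500), g, random_dna_chr(500))
  back <- back_align(prot, genome, 501, 500 + nchar(g), pseudo_params())
  seg <- back$segments[back$segments$chained, ]
  expect_equal(nrow(seg), 1)
  expect_equal(c(seg$p_start, seg$p_end), c(1, nchar(prot)))
  expect_length(back$frameshifts, 0)
  expect_length(back$internal_stops, 0)
  expect_equal(back$extent, c(501, 500 + 3 * nchar(prot)))
  expect_error(back_align(prot, genome, 0, 100), "outside genome")
})

test_that("an in-frame stop inside the aligned span is located exactly", {
  g <- make_gene(150, seed = 5)
  prot <- sub("\\*$", "", reducto:::translate_nt(g))
  # plant TAA at codon 50
  gstop <- paste0(substr(g, 1, 147), "TAA", substr(g, 151, nchar(g)))
  genome <- paste0(random_dna_chr(400), gstop, random_dna_chr(400))
  back <- back_align(prot, genome, 401, 400 + nchar(gstop), pseudo_params())
  expect_true(length(back$internal_stops) >= 1)
  expect_equal(back$internal_stops[1], 400 + 148)
  expect_length(back$frameshifts, 0)
})

test_that("classification requires anomaly, extent excess and lesion evidence", {
  study <- toy_study()
  calls <- toy_calls()
  m <- caller_metrics(calls, study$truth, study$strains)
  expect_equal(m$false_positives, 0)
  expect_equal(m$recall, 1)
  expect_true(m$evidence_ok)
  expect_lte(m$max_fs_error, pseudo_params()$chain_max_gap)
  # verdict invariant: every fragment call carries the anomaly plus a lesion
  frag <- calls[calls$verdict == "pseudogene_fragment", ]
  expect_true(all(grepl("length_anomaly", frag$evidence)))
  expect_true(all(grepl("frameshift|internal_stop", frag$evidence)))
})

test_that("calls are independent of protein-database order", {
  study <- toy_study()
  st <- study$strains[[1]]
  pro <- strain_proteomes(study$strains)
  db <- pro[pro$strain_id != st$strain_id, ]
  c1 <- call_pseudogenes(st, db, pseudo_params())
  set.seed(99)
  c2 <- call_pseudogenes(st, db[sample(nrow(db)), ], pseudo_params())
  expect_equal(c1, c2)
})
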