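test_that("zero-rate evolution reproduces the ancestral concatenation", {
  anc <- generate_ancestor(12, c(300, 600), 0.5, seed = 3)
  st <- evolve_strain(anc, evolution_params("s0", "lactis", seed = 9))
  expected <- paste0(
    paste0(vapply(seq_len(12), function(i) {
      g <- as.character(anc$genes[[i]])
      if (anc$gene_table$strand[i] == "-") g <- reducto:::revcomp_chr(g)
      paste0(as.character(anc$spacers[[i]]), g)
    }, character(1)), collapse = ""),
    as.character(anc$spacers[[13]]), anc$rrna_spacer, anc$rrna)
  expect_identical(st$genome, expected)
  expect_true(all(st$truth$status == "intact"))
  expect_true(all(is.na(st$truth$lesion_type)))
  # annotated CDS lengths equal ancestral gene lengths
  cds <- st$features[st$features$type == "CDS", ]
  expect_equal(cds$end - cds$start + 1,
               anc$gene_table$length[match(cds$gene_id, anc$gene_table$gene_id)])
})

test_that("evolution is deterministic for a fixed seed", {
  anc <- generate_ancestor(10, c(300, 600), 0.5, seed = 3)
  p <- evolution_params("s1", "lactis", substitution_rate = 0.02,
                        loss_prob = 0.2, pseudo_prob = 0.2, seed = 11)
  expect_identical(evolve_strain(anc, p), evolve_strain(anc, p))
})

test_that("gene-loss count stays within binomial sampling bounds", {
  anc <- generate_ancestor(500, c(300, 300), 0.5, seed = 5)
  st <- evolve_strain(anc, evolution_params("s1", "lactis",
                                            loss_prob = 0.2, seed = 21))
  n_absent <- sum(st$truth$status == "absent")
  sigma <- sqrt(500 * 0.2 * 0.8)
  expect_lt(abs(n_absent - 100), 4 * sigma)
})

test_that("status draws follow forced assignments and protections", {
  anc <- generate_ancestor(10, c(300, 600), 0.5, seed = 3)
  st <- evolve_strain(anc, evolution_params(
    "s1", "lactis", loss_prob = 1, seed = 2,
    protected_genes = "g0001",
    forced_status = c(g0002 = "intact", g0003 = "pseudogene:premature_stop")))
  tr <- setNames(st$truth$status, st$truth$gene_id)
  expect_equal(unname(tr[c("g0001", "g0002", "g0003")]),
               c("intact", "intact", "pseudogene"))
  expect_true(all(tr[paste0("g000", 4:9)] == "absent"))
})

test_that("a planted frameshift changes the conceptual translation only downstream", {
  anc <- generate_ancestor(8, c(450, 450), 0.5, seed = 13)
  st <- evolve_strain(anc, evolution_params(
    "s1", "lactis", seed = 4,
    forced_status = c(g0002 = "pseudogene:frameshift")))
  tr <- st$truth[st$truth$gene_id == "g0002", ]
  expect_equal(tr$status, "pseudogene")
  cds <- st$features[st$features$gene_id == "g0002", ]
  seq <- substr(st$genome, cds$start, cds$end)
  if (cds$strand == "-") seq <- reducto:::revcomp_chr(seq)
  obs <- sub("\\*$", "", reducto:::translate_nt(seq))
  anc_prot <- sub("\\*$", "", reducto:::translate_nt(as.character(anc$genes[["g0002"]])))
  k <- tr$lesion_offset %/% 3          # codons upstream of the lesion
  expect_identical(substr(obs, 1, k), substr(anc_prot, 1, k))
  expect_false(identical(obs, anc_prot))
  # re-annotated fragment is anomalously short (the detection trigger)
  expect_gt(nchar(anc_prot), 1.1 * nchar(obs))
})

test_that("IS insertions land in intergenic spacers only and are bounded", {
  anc <- generate_ancestor(20, c(300, 600), 0.5, seed = 6)
  isl <- setNames(c(reducto:::random_dna(500, 0.5),
                    reducto:::random_dna(700, 0.5)), c("IS30", "ISL3"))
  st <- evolve_strain(anc, evolution_params(
    "s1", "lactis", substitution_rate = 0.01, pseudo_prob = 0.2,
    is_library = isl, n_is_insertions = 8, seed = 31))
  f <- st$features
  cds <- f[f$type == "CDS", ]
  ise <- f[f$type == "mobile_genetic_element", ]
  expect_equal(nrow(ise), 8)
  overlaps <- outer(ise$start, cds$end, "<=") & outer(ise$end, cds$start, ">=")
  expect_false(any(overlaps))
  expect_true(all(ise$family %in% c("IS30", "ISL3")))
  # more insertions than spacers is rejected
  expect_error(
    evolve_strain(anc, evolution_params("s2", "lactis", is_library = isl,
                                        n_is_insertions = 1000, seed = 1)),
    "exceeds")
})

test_that("evolution-parameter invariants are enforced", {
  expect_error(evolution_params("s", loss_prob = 0.7, pseudo_prob = 0.5),
               "<= 1")
  expect_error(evolution_params("s", substitution_rate = 1.2), "\\[0, 1\\]")
  expect_error(evolution_params("s", pseudo_mix = c(frameshift = 0.5,
                                                    premature_stop = 0.2,
                                                    truncation = 0.2)),
               "summing to 1")
})
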