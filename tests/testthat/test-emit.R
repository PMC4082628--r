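test_that("GFF3 emission conforms to 1-based inclusive coordinates", {
  anc <- generate_ancestor(3, c(300, 300), 0.5, seed = 2, rrna_len = 0)
  st <- evolve_strain(anc, evolution_params("sX", "lactis", seed = 1))
  d <- withr::local_tempdir()
  emit_dataset(list(st), d)
  lines <- readLines(file.path(d, "sX.gff3"))
  cds_lines <- grep("\tCDS\t", lines, value = TRUE)
  expect_length(cds_lines, 3)
  f <- do.call(rbind, strsplit(cds_lines, "\t"))
  # first gene follows the 200-bp spacer: starts at 201, 1-based inclusive
  expect_equal(as.integer(f[1, 4]), 201)
  expect_equal(as.integer(f[1, 5]), 201 + 300 - 1)
})

test_that("write + read round-trips the dataset exactly", {
  anc <- generate_ancestor(15, c(300, 600), 0.5, seed = 8)
  isl <- setNames(reducto:::random_dna(400, 0.5), "IS30")
  s1 <- evolve_strain(anc, evolution_params(
    "sA", "lactis", substitution_rate = 0.01, loss_prob = 0.1,
    pseudo_prob = 0.15, is_library = isl, n_is_insertions = 3, seed = 5))
  s2 <- evolve_strain(anc, evolution_params("sB", "bulgaricus", seed = 6))
  d <- withr::local_tempdir()
  emit_dataset(list(s1, s2), d)
  rd <- read_dataset(d)

  expect_identical(rd$strains$sA$genome, s1$genome)
  expect_identical(rd$strains$sB$genome, s2$genome)
  emitted_cols <- c("type", "feature_id", "gene_id", "start", "end",
                    "strand", "family")
  f1 <- s1$features[, emitted_cols]; rownames(f1) <- NULL
  expect_identical(rd$strains$sA$features, f1)
  expect_identical(rd$strains$sA$proteins, s1$proteins)
  expect_equal(rd$truth, rbind(s1$truth, s2$truth), ignore_attr = TRUE)
  expect_identical(stats::setNames(rd$meta$subspecies, rd$meta$strain_id),
                   c(sA = "lactis", sB = "bulgaricus"))
})

test_that("truth table has one row per strain x (ancestral + HGT) gene", {
  study <- toy_study()
  n_strains <- length(study$strains)
  n_genes <- nrow(study$ancestor$gene_table)
  n_hgt <- length(study$planted$hgt)
  expect_equal(nrow(study$truth), n_strains * (n_genes + n_hgt))
  expect_false(any(duplicated(study$truth[, c("strain_id", "gene_id")])))
  # lesion fields set iff status is pseudogene
  ps <- study$truth$status == "pseudogene"
  expect_true(all(!is.na(study$truth$lesion_type[ps])))
  expect_true(all(is.na(study$truth$lesion_type[!ps])))
})

test_that("emitting an empty strain list is rejected", {
  expect_error(emit_dataset(list(), tempdir()), "non-empty")
})
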