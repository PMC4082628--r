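test_that("GC content counts G+C over unambiguous bases", {
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("AATT"), 0)
  expect_equal(gc_content("ACGT"), 0.5)
  expect_equal(gc_content("ACGTNNNN"), 0.5)  # N excluded from denominator
  expect_error(gc_content(""), "empty")
  expect_error(gc_content("ACGR"), "only ACGTN")
  # strand invariance
  set.seed(1)
  s <- random_dna_chr(500, 0.42)
  expect_equal(gc_content(s), gc_content(reducto:::revcomp_chr(s)))
})

test_that("GC3 matches a direct per-base counting oracle", {
  expect_equal(gc3("ATGAAGTTG"), 1)       # all codons end G
  expect_equal(gc3("ATTAAATTT"), 0)
  set.seed(2)
  cds <- vapply(1:100, function(i) random_dna_chr(3 * sample(20:80, 1), 0.6),
                character(1))
  oracle <- {
    third <- unlist(lapply(cds, function(s) {
      v <- strsplit(s, "")[[1]]; v[seq(3, length(v), 3)]
    }))
    sum(third %in% c("G", "C")) / length(third)
  }
  expect_equal(gc3(cds), oracle, tolerance = 1e-12)
  expect_warning(got <- gc3(c("ATGAAGTTG", "ACGTA")), "skipped")
  expect_equal(got, 1)
  expect_error(suppressWarnings(gc3("ACGTA")), "no valid CDS")
})

test_that("coding density uses interval-union semantics", {
  expect_equal(coding_density(1000, 1, 500), 50)
  expect_equal(coding_density(1000, c(1, 1), c(500, 500)), 50)  # overlap once
  expect_equal(coding_density(1000, c(1, 401), c(500, 700)), 70)
  set.seed(3)
  for (r in 1:8) {
    n <- sample(1:20, 1)
    st <- sample(900, n, replace = TRUE)
    en <- pmin(1000, st + sample(0:200, n, replace = TRUE))
    bitmap <- logical(1000)
    for (i in seq_len(n)) bitmap[st[i]:en[i]] <- TRUE
    expect_equal(coding_density(1000, st, en), 100 * mean(bitmap))
  }
  expect_error(coding_density(100, 50, 101), "outside")
})

test_that("genome-size estimation adds gap estimates to assembled length", {
  expect_equal(as.numeric(estimate_genome_size(c(600, 400))), 1000)
  expect_false(attr(estimate_genome_size(c(600, 400)), "estimated"))
  expect_equal(as.numeric(estimate_genome_size(c(600, 400), 75)), 1075)
  expect_true(attr(estimate_genome_size(c(600, 400), 75), "estimated"))
  expect_error(estimate_genome_size(c(600, 400), -5), "negative")
  expect_error(estimate_genome_size(c(600, 400, 200), 75), "one gap estimate")
})

test_that("IS landscape: counts, density and the largest element-free region", {
  # no elements on a circular genome: free interval is the whole genome
  l0 <- is_landscape(10000, data.frame(family = character(0),
                                       start = integer(0), end = integer(0)))
  expect_equal(l0$free_width, 10000)

  set.seed(4)
  for (r in 1:8) {
    n <- sample(2:15, 1)
    st <- sort(sample(9000, n))
    ann <- data.frame(family = sample(c("IS30", "IS256", "ISL3"), n, TRUE),
                      start = st, end = pmin(10000, st + 500))
    land_c <- is_landscape(10000, ann, circular = TRUE)
    land_l <- is_landscape(10000, ann, circular = FALSE)
    # oracle: exhaustive boundary-gap scan
    gaps <- c()
    for (i in seq_len(n - 1)) gaps <- c(gaps, ann$start[i + 1] - ann$end[i] - 1)
    wrap <- (10000 - ann$end[n]) + ann$start[1] - 1
    lin <- c(gaps, ann$start[1] - 1, 10000 - ann$end[n])
    expect_equal(land_c$free_width, max(c(gaps, wrap), 0))
    expect_equal(land_l$free_width, max(lin, 0))
    # circular max gap >= linear internal max gap
    expect_gte(land_c$free_width, max(c(gaps, 0)))
    expect_equal(sum(land_c$family_counts), n)
  }
})

test_that("stats report assembles the composition row of one strain", {
  study <- toy_study()
  st <- study$strains[[1]]
  rep <- stats_report(st, pseudo_calls = toy_calls())
  expect_s3_class(rep, "stats_report")
  expect_equal(rep$assembled_size, nchar(st$genome))
  expect_true(rep$printed["overall_gc_pct"] > 40 &&
                rep$printed["overall_gc_pct"] < 60)
  expect_true(rep$coding_density > 0 && rep$coding_density < 100)
  expect_gte(rep$estimated_size, rep$assembled_size)
})
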