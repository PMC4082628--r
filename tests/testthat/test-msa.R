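test_that("identical sequences align without gaps", {
  set.seed(1)
  s <- random_dna_chr(200)
  al <- progressive_align(c(a = s, b = s))
  expect_equal(al$ncol, 200)
  expect_false(any(grepl("-", al$aln, fixed = TRUE)))
})

test_that("a single 3-nt insertion produces one 3-column gap block", {
  set.seed(2)
  base <- random_dna_chr(150)
  withins <- paste0(substr(base, 1, 75), "TTT", substr(base, 76, 150))
  al <- progressive_align(c(x = base, y = base, z = withins))
  m <- msa_matrix(al)
  expect_equal(ncol(m), 153)
  for (row in c("x", "y")) {
    gaps <- which(m[row, ] == "-")
    expect_length(gaps, 3)
    expect_true(all(diff(gaps) == 1))
  }
  expect_false(any(m["z", ] == "-"))
})

test_that("input order does not change the induced pairwise identity matrix", {
  set.seed(3)
  base <- random_dna_chr(300)
  mut <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    i <- sample(length(v), k)
    v[i] <- vapply(v[i], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    paste(v, collapse = "")
  }
  seqs <- c(a = base, b = mut(base, 6), c = mut(base, 12), d = mut(base, 40))
  D1 <- distance_matrix(progressive_align(seqs), "p")
  perm <- seqs[c("c", "a", "d", "b")]
  D2 <- distance_matrix(progressive_align(perm), "p")
  expect_equal(D1[rownames(D2), colnames(D2)], D2)
})

test_that("protein profiles align under BLOSUM scoring", {
  set.seed(4)
  p <- random_protein(120)
  q <- paste0(substr(p, 1, 60), substr(p, 64, 120))  # 3-residue deletion
  al <- progressive_align(c(a = p, b = q), type = "protein")
  m <- msa_matrix(al)
  expect_equal(sum(m["b", ] == "-"), 3)
  expect_false(any(m["a", ] == "-"))
})

test_that("alignment inputs are validated", {
  expect_error(progressive_align(c(a = "ACGT")), "at least 2")
  expect_error(progressive_align(c("ACGT", "ACGT")), "unique non-empty names")
  expect_error(progressive_align(c(a = "ACGT", a = "ACGA")), "unique")
})
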