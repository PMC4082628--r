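test_that("identical sequences align with identity 1 and full coverage", {
  set.seed(1)
  p <- random_protein(100)
  h <- local_align(c(a = p), c(b = p))
  expect_equal(h$identity, 1)
  expect_equal(h$longest_coverage, 1)
  expect_equal(c(h$q_start, h$q_end), c(1, 100))
})

test_that("local alignment is symmetric in score, identity and coverage", {
  set.seed(2)
  for (r in 1:5) {
    a <- c(a = random_protein(sample(40:120, 1)))
    b <- c(b = mutate_protein(random_protein(80), 10))
    h1 <- local_align(a, b)
    h2 <- local_align(b, a)
    expect_equal(h1$score, h2$score)
    expect_equal(h1$identity, h2$identity)
    expect_equal(h1$longest_coverage, h2$longest_coverage)
  }
})

test_that("optimal local score matches a quadratic DP oracle", {
  mat <- reducto:::get_submat("BLOSUM62")
  set.seed(3)
  for (r in 1:12) {
    a <- random_protein(sample(30:50, 1))
    b <- if (r %% 2) random_protein(sample(30:50, 1)) else mutate_protein(a, 8)
    h <- local_align(c(a = a), c(b = b))
    expect_equal(h$score, sw_oracle(a, b, mat), tolerance = 1e-9)
  }
})

test_that("degenerate alignment inputs are rejected", {
  expect_error(local_align(c(a = ""), c(b = "MKV")), "empty")
  expect_error(local_align(c(a = "MKV"), c(b = "MKV"),
                           cluster_params(matrix_name = "NOSUCH")),
               "unknown substitution matrix")
})

test_that("bit score and e-value follow the Karlin-Altschul form", {
  # doubling the search space doubles E; higher score shrinks it
  e1 <- reducto:::ka_evalue(100, 100, 1e5)
  e2 <- reducto:::ka_evalue(100, 100, 2e5)
  e3 <- reducto:::ka_evalue(120, 100, 1e5)
  expect_equal(e2 / e1, 2)
  expect_lt(e3, e1)
})
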