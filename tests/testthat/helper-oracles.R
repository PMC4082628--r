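# Independent oracles and shared fixtures for the test suite.

# Quadratic Smith-Waterman with affine gaps (Gotoh), plain R; a gap of
# length k costs gap_open + k * gap_extend (the pairwiseAlignment
# convention).  Returns the optimal local score only.
sw_oracle <- function(a, b, mat, gap_open = 11, gap_extend = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      X[i, j] <- max(H[i - 1, j] - gap_open - gap_extend,
                     X[i - 1, j] - gap_extend)
      Y[i, j] <- max(H[i, j - 1] - gap_open - gap_extend,
                     Y[i, j - 1] - gap_extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[av[i - 1], bv[j - 1]],
                     X[i, j], Y[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

random_protein <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"), n, replace = TRUE),
        collapse = "")
}

random_dna_chr <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# point-mutate a protein at k positions (no indels)
mutate_protein <- function(s, k) {
  v <- strsplit(s, "")[[1]]
  idx <- sample(length(v), k)
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
           "M", "F", "P", "S", "T", "W", "Y", "V")
  for (i in idx) v[i] <- sample(setdiff(aas, v[i]), 1)
  paste(v, collapse = "")
}

# small two-clade study shared across test files (built once per run)
.fixture_cache <- new.env(parent = emptyenv())
toy_study <- function() {
  if (is.null(.fixture_cache$study)) {
    .fixture_cache$study <- simulate_study(
      seed = 42, n_genes = 45, n_per_clade = 3, n_pathways = 3,
      n_specific = c(lactis = 3, bulgaricus = 2),
      n_rescue = c(lactis = 1, bulgaricus = 1),
      n_is = c(lactis = 6, bulgaricus = 2))
  }
  .fixture_cache$study
}

toy_calls <- function() {
  if (is.null(.fixture_cache$calls)) {
    study <- toy_study()
    pro <- strain_proteomes(study$strains)
    .fixture_cache$calls <- do.call(rbind, lapply(names(study$strains),
      function(sid) {
        call_pseudogenes(study$strains[[sid]],
                         pro[pro$strain_id != sid, ], pseudo_params())
      }))
  }
  .fixture_cache$calls
}

# canonical bipartition string for a tip subset, matching tree_bipartitions
canon_split <- function(tips_in, all_tips) {
  ref <- sort(all_tips)[1]
  side <- if (ref %in% tips_in) sort(setdiff(all_tips, tips_in)) else sort(tips_in)
  paste(side, collapse = "|")
}

table3_path <- function() {
  system.file("extdata", "fermentation_profiles.tsv", package = "reducto")
}
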