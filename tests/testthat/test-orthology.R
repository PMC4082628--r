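make_proteome <- function(strain_ids, seqs_per_strain) {
  do.call(rbind, lapply(strain_ids, function(s) {
    data.frame(strain_id = s, protein_id = names(seqs_per_strain[[s]]),
               sequence = unname(seqs_per_strain[[s]]), is_pseudo = FALSE,
               stringsAsFactors = FALSE)
  }))
}

test_that("identity at exactly the threshold yields no edge (strict inequality)", {
  set.seed(4)
  base <- random_protein(100)
  v <- strsplit(base, "")[[1]]
  idx <- seq(5, by = 4, length.out = 22)      # interior, flanked by matches
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
           "M", "F", "P", "S", "T", "W", "Y", "V")
  for (i in idx) v[i] <- sample(setdiff(aas, v[i]), 1)
  mut22 <- paste(v, collapse = "")
  h <- local_align(c(a = base), c(b = mut22))
  # construction check: ungapped full-length alignment, identity exactly 0.78
  expect_equal(h$identity, 0.78)
  expect_equal(h$longest_coverage, 1)
  pro <- make_proteome(c("s1", "s2"),
                       list(s1 = c(p1 = base), s2 = c(p1 = mut22)))
  expect_equal(nrow(similarity_edges(pro)), 0)
  # one mutation fewer crosses the threshold
  v[idx[22]] <- strsplit(base, "")[[1]][idx[22]]
  mut21 <- paste(v, collapse = "")
  pro$sequence[2] <- mut21
  expect_equal(nrow(similarity_edges(pro)), 1)
})

test_that("edge set equals brute-force all-pairs threshold evaluation", {
  set.seed(5)
  fams <- lapply(1:12, function(i) random_protein(sample(60:140, 1)))
  seqs <- list(
    s1 = setNames(vapply(fams, identity, character(1)), paste0("p", 1:12)),
    s2 = setNames(vapply(fams, function(f) mutate_protein(f, sample(0:20, 1)),
                         character(1)), paste0("p", 1:12)),
    s3 = setNames(c(vapply(fams[1:6], function(f)
      mutate_protein(f, sample(0:30, 1)), character(1)),
      vapply(1:4, function(i) random_protein(80), character(1))),
      paste0("p", 1:10)))
  pro <- make_proteome(c("s1", "s2", "s3"), seqs)
  params <- cluster_params()
  got <- similarity_edges(pro, params)
  keys <- paste(pro$strain_id, pro$protein_id, sep = "|")
  sn <- sum(nchar(pro$sequence))
  exp_edges <- character(0)
  for (i in seq_len(nrow(pro) - 1)) for (j in (i + 1):nrow(pro)) {
    if (pro$strain_id[i] == pro$strain_id[j]) next
    h <- local_align(setNames(pro$sequence[i], keys[i]),
                     setNames(pro$sequence[j], keys[j]), params,
                     search_n = sn)
    if (h$evalue < params$evalue_max && h$identity > params$identity_min &&
        h$longest_coverage > params$coverage_min) {
      exp_edges <- c(exp_edges, paste(sort(c(keys[i], keys[j])), collapse = "~"))
    }
  }
  got_keys <- apply(got[, c("p1", "p2")], 1, function(x)
    paste(sort(x), collapse = "~"))
  expect_setequal(got_keys, exp_edges)
  expect_gt(length(exp_edges), 0)
})

test_that("pseudo-flagged proteins are rejected from clustering input", {
  pro <- data.frame(strain_id = "s1", protein_id = "p1",
                    sequence = "MKVLL", is_pseudo = TRUE)
  expect_error(similarity_edges(pro), "non-pseudogene")
})

test_that("single linkage equals connected components (union-find vs igraph)", {
  skip_if_not_installed("igraph")
  set.seed(6)
  for (rep in 1:5) {
    n <- 60
    pro <- data.frame(strain_id = paste0("s", rep(1:6, each = 10)),
                      protein_id = paste0("p", rep(1:10, times = 6)),
                      sequence = "MKV", is_pseudo = FALSE)
    keys <- paste(pro$strain_id, pro$protein_id, sep = "|")
    m <- sample(0:80, 1)
    e_idx <- matrix(sample(n, 2 * m, replace = TRUE), ncol = 2)
    e_idx <- e_idx[e_idx[, 1] != e_idx[, 2], , drop = FALSE]
    edges <- data.frame(p1 = keys[e_idx[, 1]], p2 = keys[e_idx[, 2]],
                        stringsAsFactors = FALSE)
    cl <- cluster_single_linkage(pro, edges)
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = keys)
    memb <- igraph::components(g)$membership[cl$key]
    # identical partitions: group labels in bijection with components
    expect_equal(length(unique(cl$group_id)), length(unique(memb)))
    expect_true(all(tapply(memb, cl$group_id,
                           function(x) length(unique(x)) == 1)))
  }
})

test_that("single-linkage transitivity links a-b-c chains; singletons stand alone", {
  pro <- data.frame(strain_id = c("s1", "s2", "s3", "s1"),
                    protein_id = c("a", "b", "c", "d"),
                    sequence = "MKV", is_pseudo = FALSE)
  edges <- data.frame(p1 = c("s1|a", "s2|b"), p2 = c("s2|b", "s3|c"))
  cl <- cluster_single_linkage(pro, edges)
  expect_equal(length(unique(cl$group_id)), 2)
  expect_equal(length(unique(cl$group_id[cl$protein_id != "d"])), 1)
  expect_error(cluster_single_linkage(pro,
    data.frame(p1 = "s1|a", p2 = "s9|zz")), "not in proteome")
  # no edges: all singletons
  cl0 <- cluster_single_linkage(pro, edges[0, ])
  expect_equal(length(unique(cl0$group_id)), 4)
})

test_that("core partition categories match a direct per-group evaluation", {
  set.seed(7)
  meta <- c(s1 = "lactis", s2 = "lactis", s3 = "bulgaricus", s4 = "bulgaricus")
  for (rep in 1:10) {
    rows <- list()
    for (g in 1:25) {
      present <- names(meta)[runif(4) < 0.7]
      for (s in present) {
        rows[[length(rows) + 1]] <- data.frame(
          group_id = sprintf("OG%04d", g), strain_id = s,
          protein_id = paste0("g", g), key = paste0(s, "|g", g))
      }
    }
    groups <- do.call(rbind, rows)
    pt <- partition_core(groups, meta, first = "lactis")
    # oracle: direct per-group scan
    cnt <- c(A = 0, B = 0, C = 0, D = 0); core <- 0
    for (g in unique(groups$group_id)) {
      s <- unique(groups$strain_id[groups$group_id == g])
      n_lac <- sum(meta[s] == "lactis"); n_bul <- sum(meta[s] == "bulgaricus")
      if (n_lac == 2 && n_bul == 2) core <- core + 1
      if (n_lac == 2 && n_bul == 0) cnt["A"] <- cnt["A"] + 1
      if (n_lac == 2 && n_bul > 0 && n_bul < 2) cnt["B"] <- cnt["B"] + 1
      if (n_bul == 2 && n_lac == 0) cnt["C"] <- cnt["C"] + 1
      if (n_bul == 2 && n_lac > 0 && n_lac < 2) cnt["D"] <- cnt["D"] + 1
    }
    expect_equal(pt$counts, cnt)
    expect_equal(pt$overall_core, core)
    # invariance under row order
    perm <- groups[sample(nrow(groups)), ]
    expect_equal(partition_core(perm, meta, first = "lactis")$counts, cnt)
  }
})

test_that("identical proteomes give an all-core partition with empty categories", {
  set.seed(8)
  seqs <- setNames(vapply(1:8, function(i) random_protein(80), character(1)),
                   paste0("p", 1:8))
  pro <- make_proteome(paste0("s", 1:4),
                       setNames(rep(list(seqs), 4), paste0("s", 1:4)))
  meta <- setNames(c("lactis", "lactis", "bulgaricus", "bulgaricus"),
                   paste0("s", 1:4))
  cl <- cluster_single_linkage(pro, similarity_edges(pro))
  pt <- partition_core(cl, meta)
  expect_equal(pt$overall_core, 8)
  expect_equal(unname(pt$counts), c(0, 0, 0, 0))
  expect_error(partition_core(cl, c(meta[1:3], s4 = "third")), "exactly two")
})

test_that("fragment rescue counts groups with opposite-subspecies fragments", {
  groups <- data.frame(group_id = c("OG0001", "OG0001", "OG0002"),
                       strain_id = c("s1", "s2", "s1"),
                       protein_id = c("x", "x", "y"),
                       key = c("s1|x", "s2|x", "s1|y"))
  meta <- c(s1 = "lactis", s2 = "lactis", s3 = "bulgaricus")
  calls <- data.frame(strain_id = "s3", cds_id = "x",
                      verdict = "pseudogene_fragment", best_hit = "s1|x",
                      stringsAsFactors = FALSE)
  r <- fragment_rescue(c("OG0001", "OG0002"), groups, calls, meta, "bulgaricus")
  expect_equal(r$n_rescued, 1)
  expect_equal(r$rescued, "OG0001")
  expect_equal(fragment_rescue("OG0001", groups, calls[0, ], meta,
                               "bulgaricus")$n_rescued, 0)
})
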